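---
title: "Multimodal context mining: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimodal context mining: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(contextmine)
library(dplyr)
```

# The problem

`contextmine` infers a person's context at two levels of abstraction from
heterogeneous sensor streams. *Low-level contexts* (LLCs) are atomic
recognized states in three categories: a physical activity (8 labels), an
emotional state (4 labels) and a location (5 personal places). *High-level
contexts* (HLCs) are abstract states — Inactivity, OfficeWork, Exercising,
HavingMeal, Housework — defined as combinations of concurrent LLCs. The
pipeline is event-driven end to end: sensory packets are routed to
recognizers, per-recognizer decisions are fused, changes are notified, and
every low-level change triggers re-inference of the high-level state.

# Recognizer models

## Inertial activity (k-NN)

Phone and watch accelerometer/gyroscope streams at 50 Hz are segmented into
non-overlapping 3-s windows (150 samples). Per channel we extract mean,
zero-crossing rate, maximum, minimum, standard deviation, the three
quartiles (linear interpolation between order statistics), range and the
first `m = 5` real-cepstrum coefficients (inverse transform of the log
magnitude spectrum, floored at `1e-12` so constant channels stay finite).
Classification is k-nearest neighbours with `k = 3` on z-score-standardized
features under Euclidean distance.

Two choices here were genuinely open:

* **Orientation independence.** The phone may sit anywhere on the body in
  any orientation, so phone features are computed only on the acceleration
  and rate-of-turn *magnitude* channels, which are invariant under any
  rotation of the sensor triad. The watch position is known (wrist), so its
  six raw axes are kept alongside its two magnitudes. This gives
  `(2 + 8) × 14 = 140` features.
* **Vote ties.** With `k = 3` a 1-1-1 split is possible; the label of the
  single nearest neighbour wins, with lexicographic order as a last-resort
  tie-break, making prediction fully deterministic.

A window carrying only one device's channels gets the missing device's
features imputed with training means (equivalently, zeros in standardized
space) and is logged.

## Skeleton activity (decision tree)

20-joint depth-camera skeleton tracks are segmented into 3-s windows with
50% overlap (hop 1.5 s). For each configured joint pair we take the
Euclidean inter-joint distance and the elevation angle of the joint-joint
vector against the camera's horizontal plane (`atan2(dy, sqrt(dx² + dz²))`,
y up, range [−π/2, π/2]; coincident joints define angle 0), then the mean
and standard deviation (population convention) of each over the window's
frames. The default pair list is the 19 bone edges of the skeleton
hierarchy plus six cross-limb pairs (hand–hand, hand–head ×2, foot–foot,
hand–hip ×2) — 25 pairs, 100 features — because the full quadratic pair set
adds little beyond redundancy; the list is an argument everywhere.
Classification is a CART tree (Gini, minimum leaf 2, no depth limit).
Walking and Running are excluded by contract: ambulation leaves the
camera's field of view, and training sets containing them are rejected.

## Audio emotion (RBF SVM)

Call audio at 44.1 kHz passes energy-threshold voice-activity detection on
25 ms frames with 10 ms hop. The threshold is 1.5 × the median frame
energy, capped 20 dB below the peak frame energy and floored at an absolute
silence level of `1e-8`. The cap matters: a pause-free utterance has every
frame at the median, so a pure median rule would mark nothing voiced; the
floor keeps digital silence fully unvoiced. Voiced audio is trimmed, cut
into non-overlapping 3-s segments, and the segment order is permuted with a
seeded RNG before feature extraction; the output carries no original-order
metadata, which is the point of the privacy-preserving randomization
(shuffling before or after extraction is equivalent for that purpose, since
features are per-segment).

Per segment, over voiced frames only: log mean-square energy (mean, sd),
pitch (mean, sd, range) by autocorrelation peak in the 60–400 Hz band with
parabolic interpolation around the winning lag (≤ 5 Hz error on pure tones
across 80–350 Hz), energy functionals (min, max, skewness), and 13 MFCCs
(c0–c12; 26-band mel filterbank, Hamming window; mean and sd each) — 34
features. Classification is a one-vs-one RBF SVM with `gamma = 0.01` and
`C = 1` on standardized features; a coarse grid search around these values
is available but off by default.

## Location (personal maps)

GPS fixes (1 Hz) resolve against a per-user map of named places via
haversine distance on the IUGG mean Earth radius (6 371 008.8 m): the
nearest place within its radius wins, ties break lexicographically, and
everything else is `Unknown`. The default radius is 50 m. Direct radius
matching replaces any external reverse-geocoding service while preserving
the physical-to-personal mapping contract. A location stream silent for
more than 5 s finalizes the open location context; the threshold is this
package's choice, since signal loss handling has no canonical value.

# Fusion and notification

Decisions are fused every 3 s, in slots aligned to the session origin
(the phase is otherwise arbitrary). *Vertical* fusion reduces one
recognizer's decisions within a slot to a simple-majority label, ties going
to the most recent decision (recency as a freshness proxy). *Horizontal*
fusion combines the per-recognizer labels of one category by weighted
majority voting with weights 0.5076 (inertial) and 0.4924 (skeleton),
proportional to measured recognizer performance (`w_i = a_i / Σ a_j`); the
margin is small but means every two-way disagreement resolves to the
inertial vote. Weights of absent recognizers are dropped and the rest
renormalized, so a lone recognizer carries weight 1; emotion and location
have single recognizers and pass through the same code path as the
identity. Notification is change-only: an event fires only when the fused
label differs from the last notified one, and a FINAL marker closes an
open context when a stream ceases.

# High-level inference

A low-level change triggers: store update (close the open context of that
category, open the new one), retrieval of the user's concurrent contexts
(half-open intervals `[t_start, t_end)`; an instant equal to `t_end` is
outside), instantiation of an unclassified HLC, verification (≤ 1
constituent per category, single user, legal labels, all intervals
containing the start), and classification against a definitional model.
Events sharing a timestamp and user are treated as one synchronization
batch — all store mutations land before inference runs once — so a
simultaneous activity+location handover never produces a spurious
intermediate composition. A finalization re-runs inference on the reduced
composition.

The definitional model is a priority-ordered table, config-driven
(YAML/JSON) so alternative semantics can be dropped in:

```{r defs}
hlc_definitions() %>% mutate(across(c(activities, locations, emotions),
                                    ~ sapply(.x, paste, collapse = ",")))
```

Open design points resolved here: a class may own several rows (Exercising:
gym exercise, or running anywhere) while priorities stay unique; the most
specific definition (fewest ANY fields) ranks highest; a category missing
from a composition matches ANY but never an explicit set, because a
definition that *requires* a location cannot be asserted without one; and
every default definition leaves emotions at ANY — high-level classes anchor
on activity and place, which is exactly why emotion misrecognitions cannot
corrupt the high-level timeline (a property the tests assert exactly).
Verification and classification reproduce observable subsumption-style
behaviour only; no description-logic tableau reasoning is attempted.

# Synthetic data: what it emulates and what it does not

The generator stands in for a multimodal data collection: 10 training
subjects and 5 held-out scenario subjects, each with seeded multiplicative
offsets on signature parameters (amplitude, frequency, wrist tilt, pitch,
energy, body scale) so leave-one-subject-out folds face genuinely shifted
distributions. Activities imprint a gravity component, a sinusoidal motion
component at a class-specific amplitude/frequency along a random fixed
direction, and Gaussian noise; Eating is wrist-dominant with a 0.3 duty
cycle; passive postures differ in wrist tilt. Skeleton streams are template
poses with class-specific periodic limb displacement and 1 cm joint jitter.
Audio is a 5-partial harmonic source with per-burst pitch and energy drawn
from per-emotion signatures, raised-cosine onsets and interleaved silences.
The high-arousal pair (Anger/Happiness) and the low-arousal pair
(Neutral/Sadness) overlap by construction, so the emotion benchmark bar
(macro-F ≥ 0.75) is deliberately lower than the activity bars (≥ 0.90) and
the confusion structure concentrates within those pairs.

What passing these benchmarks shows is that the pipeline's machinery —
windowing, features, classifiers, fusion, notification, high-level
inference — is correct and well-calibrated *under the generative
assumptions*. It does not show field performance: real inertial data has
gait asymmetry and device artefacts, real speech has phonetic content and
channel noise, and real GPS has urban-canyon dropout, none of which are
modelled. Signature parameters were calibrated once against the benchmark
bars and then frozen.

# Problem sizes and numerical choices

The shipped evaluation uses 60 s per (subject, activity) of inertial and
skeleton data, 30 s per (subject, emotion) of audio, and five held-out
subjects replaying an eight-step, one-minute-per-step scenario — sizes
chosen so the full cycle (generate, cross-validate, replay) completes in
minutes on one core while keeping every class's support in the hundreds of
windows. Window sample counts use `round(window_s × rate)`; out-of-order
packets are rejected rather than reordered; buffers are keyed per (user,
recognizer); scoring excludes slots whose interior overlaps a script step
boundary, since no transition/null-class rejection is modelled. All
randomness flows through explicit integer seeds; two runs of
simulate → train → replay with the same seed are byte-identical.

# Known limitations

Single-process, in-memory operation: no transport, back-pressure or
distributed deployment. The context store is an append-only in-process log
with interval filters, not a triple store, though instances can be exported
as Turtle. Physiological and video emotion recognition, audio activity
recognition, and skeleton estimation from raw depth imagery are out of
scope — the skeleton recognizer starts from joint coordinates. Processing
latency is not modelled; replay alignment assumes the in-process pipeline
is delay-free.
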