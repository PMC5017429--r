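# deterministic sub-seed derivation (kept below 2^31)
derive_seed <- function(seed, ...) {
  parts <- paste(c(seed, ...), collapse = "/")
  codes <- utf8ToInt(parts)
  s <- 0
  for (c in codes) s <- (s * 31 + c) %% 2147483647
  as.integer(s)
}

# per-subject multiplicative offsets so leave-one-subject-out folds face a
# genuinely shifted distribution
subject_offsets <- function(subject, seed) {
  withr::with_seed(derive_seed(seed, "subject", subject), {
    list(amp = runif(1, 0.85, 1.15),
         freq = runif(1, 0.93, 1.07),
         tilt = runif(1, -8, 8) * pi / 180,
         f0 = runif(1, 0.92, 1.08),
         energy = runif(1, 0.8, 1.2),
         scale = runif(1, 0.94, 1.06))
  })
}

#' Synthetic activity signatures
#'
#' The parametric signature each activity imprints on the inertial
#' generator: motion amplitude (m/s^2), dominant frequency (Hz; 0 for
#' aperiodic, noise-only classes), noise level, watch gravity tilt (the
#' angle of the wrist relative to vertical, a stable cue for the passive
#' postures) and a burst duty cycle (Eating's intermittent wrist movements;
#' 1 means continuous motion). Signatures are pairwise distinct in
#' (amplitude, frequency) space; their only contract is that the LOSO
#' benchmark bars hold on data generated from them.
#'
#' @return A tibble, one row per activity.
#' @export
activity_signatures <- function() {
  tibble::tribble(
    ~activity,    ~amp, ~freq, ~noise_sd, ~watch_tilt_deg, ~duty,
    "Sitting",     0.1,   0,     0.05,     40,              1,
    "Standing",    0.15,  0,     0.08,     10,              1,
    "LyingDown",   0.08,  0,     0.04,     90,              1,
    "Walking",     2,     2,     0.3,      15,              1,
    "Running",     6,     3,     0.5,      20,              1,
    "Eating",      1.5,   1.2,   0.15,     55,              0.3,
    "Stretching",  3,     0.2,   0.2,      25,              1,
    "Sweeping",    2.5,   1,     0.3,      45,              1
  )
}

random_rotation <- function() {
  # QR of a Gaussian matrix, sign-fixed: uniform random rotation
  qr_d <- qr(matrix(rnorm(9), 3, 3))
  q <- qr.Q(qr_d)
  q * sign(diag(qr.R(qr_d)))[col(q)]
}

#' Generate a synthetic inertial stream
#'
#' Emulates a phone + watch 3-axis accelerometer/gyroscope recording of one
#' activity: per device, a gravity component (the phone in a random, fixed
#' orientation; the watch tilted by the activity's wrist angle), a
#' sinusoidal motion component at the signature's amplitude and frequency
#' along a random fixed direction (gated by the burst duty cycle for
#' intermittent activities), and Gaussian noise. Reproducible for a fixed
#' seed.
#'
#' @param activity One of [activity_labels()].
#' @param duration Seconds.
#' @param rate Sampling rate, Hz.
#' @param seed Integer seed.
#' @param subject Optional subject id; adds seeded per-subject offsets on
#'   amplitude, frequency and wrist tilt.
#' @return A tibble with `t` plus the 12 channels of
#'   `inertial_channel_names()`.
#' @export
gen_inertial <- function(activity, duration, rate = 50, seed = 1,
                         subject = NULL) {
  sig <- activity_signatures()
  sig <- sig[sig$activity == activity, ]
  if (nrow(sig) == 0) stop("unknown activity: ", activity)
  off <- if (is.null(subject)) list(amp = 1, freq = 1, tilt = 0) else
    subject_offsets(subject, seed)
  n <- round(duration * rate)
  t <- (seq_len(n) - 1) / rate
  amp <- sig$amp * off$amp
  freq <- sig$freq * off$freq
  withr::with_seed(derive_seed(seed, "inertial", activity, subject %||% ""), {
    out <- matrix(0, n, 12, dimnames = list(NULL, inertial_channel_names()))
    g <- 9.81
    env <- if (sig$duty < 1) {
      as.numeric((t * 0.3) %% 1 < sig$duty)  # 0.3 Hz burst cycle
    } else {
      rep(1, n)
    }
    for (device in c("phone", "watch")) {
      # device-specific motion strength: Eating is wrist-dominant
      dev_amp <- amp * if (activity == "Eating" && device == "phone") 0.2 else 1
      grav <- if (device == "phone") {
        random_rotation() %*% c(0, 0, g)
      } else {
        tilt <- sig$watch_tilt_deg * pi / 180 + off$tilt
        c(g * sin(tilt), g * cos(tilt), 0)
      }
      dir_a <- rnorm(3); dir_a <- dir_a / sqrt(sum(dir_a^2))
      dir_g <- rnorm(3); dir_g <- dir_g / sqrt(sum(dir_g^2))
      phase <- runif(1, 0, 2 * pi)
      motion <- if (freq > 0) {
        dev_amp * sin(2 * pi * freq * t + phase) * env
      } else {
        rep(0, n)
      }
      acc <- outer(motion, dir_a) + matrix(grav, n, 3, byrow = TRUE) +
        matrix(rnorm(3 * n, sd = sig$noise_sd), n, 3)
      gyr <- outer(0.5 * motion, dir_g) +
        matrix(rnorm(3 * n, sd = sig$noise_sd * 0.5), n, 3)
      cols <- paste(device, c("ax", "ay", "az", "gx", "gy", "gz"), sep = "_")
      out[, cols] <- cbind(acc, gyr)
    }
    dplyr::bind_cols(tibble::tibble(t = t), tibble::as_tibble(out))
  })
}

# canonical 20-joint standing pose, y up, ~2.5 m from the camera
base_pose <- function() {
  coords <- rbind(
    head            = c(0, 1.70, 2.5),
    shoulder_center = c(0, 1.45, 2.5),
    spine           = c(0, 1.15, 2.5),
    hip_center      = c(0, 0.95, 2.5),
    shoulder_l      = c(-0.20, 1.45, 2.5),
    elbow_l         = c(-0.28, 1.18, 2.5),
    wrist_l         = c(-0.30, 0.95, 2.5),
    hand_l          = c(-0.31, 0.88, 2.5),
    shoulder_r      = c(0.20, 1.45, 2.5),
    elbow_r         = c(0.28, 1.18, 2.5),
    wrist_r         = c(0.30, 0.95, 2.5),
    hand_r          = c(0.31, 0.88, 2.5),
    hip_l           = c(-0.12, 0.95, 2.5),
    knee_l          = c(-0.13, 0.50, 2.5),
    ankle_l         = c(-0.14, 0.08, 2.5),
    foot_l          = c(-0.14, 0.02, 2.6),
    hip_r           = c(0.12, 0.95, 2.5),
    knee_r          = c(0.13, 0.50, 2.5),
    ankle_r         = c(0.14, 0.08, 2.5),
    foot_r          = c(0.14, 0.02, 2.6)
  )
  colnames(coords) <- c("x", "y", "z")
  coords
}

# static template pose per indoor activity
template_pose <- function(activity) {
  p <- base_pose()
  lower <- function(joints, dy) p[joints, "y"] <<- p[joints, "y"] + dy
  if (activity %in% c("Sitting", "Eating")) {
    # hips drop, knees forward
    torso <- c("head", "shoulder_center", "spine", "hip_center",
               "shoulder_l", "elbow_l", "wrist_l", "hand_l",
               "shoulder_r", "elbow_r", "wrist_r", "hand_r",
               "hip_l", "hip_r")
    lower(torso, -0.40)
    p[c("knee_l", "knee_r"), "y"] <- 0.45
    p[c("knee_l", "knee_r"), "z"] <- 2.2
    p[c("ankle_l", "ankle_r", "foot_l", "foot_r"), "z"] <- 2.2
  }
  if (activity == "Eating") {
    # right hand lifted toward the mouth
    p["hand_r", ] <- p["head", ] + c(0.08, -0.12, -0.05)
    p["wrist_r", ] <- p["hand_r", ] + c(0.03, -0.08, 0)
    p["elbow_r", "y"] <- p["hand_r", "y"] - 0.25
  }
  if (activity == "LyingDown") {
    # body rotated onto the horizontal plane: x spans height, y flat
    stand <- base_pose()
    p[, "x"] <- stand[, "y"] - 0.85
    p[, "y"] <- 0.25 + 0.15 * abs(stand[, "x"])
    p[, "z"] <- 2.5 + stand[, "x"] * 0.3
  }
  if (activity == "Stretching") {
    # arms raised overhead
    p[c("wrist_l", "hand_l"), "y"] <- c(1.85, 1.95)
    p[c("wrist_r", "hand_r"), "y"] <- c(1.85, 1.95)
    p[c("elbow_l", "elbow_r"), "y"] <- 1.65
    p[c("hand_l", "wrist_l"), "x"] <- -0.12
    p[c("hand_r", "wrist_r"), "x"] <- 0.12
  }
  if (activity == "Sweeping") {
    # slight forward bend, hands together on the broom
    p[c("head", "shoulder_center"), "z"] <- 2.42
    p[c("head", "shoulder_center"), "y"] <- p[c("head", "shoulder_center"), "y"] - 0.12
    p[c("hand_l", "hand_r"), ] <- matrix(c(-0.05, 0.85, 2.35,
                                           0.05, 0.95, 2.38), 2, 3, byrow = TRUE)
    p[c("wrist_l", "wrist_r"), ] <- p[c("hand_l", "hand_r"), ] +
      matrix(c(0, 0.08, 0.02), 2, 3, byrow = TRUE)
  }
  p
}

# joints animated per class, with displacement amplitude (m) and rate (Hz)
motion_spec <- function(activity) {
  switch(activity,
    Sitting    = list(joints = c("hand_l", "hand_r"), amp = 0.01, freq = 0.3,
                      axis = c(1, 0, 0)),
    Standing   = list(joints = c("shoulder_l", "shoulder_r", "head"),
                      amp = 0.02, freq = 0.25, axis = c(1, 0, 0)),
    LyingDown  = list(joints = c("hand_r"), amp = 0.01, freq = 0.2,
                      axis = c(0, 0, 1)),
    Eating     = list(joints = c("hand_r", "wrist_r"), amp = 0.12, freq = 0.3,
                      axis = c(0, 1, 0)),
    Stretching = list(joints = c("hand_l", "hand_r", "wrist_l", "wrist_r",
                                 "elbow_l", "elbow_r"),
                      amp = 0.25, freq = 0.2, axis = c(0, 1, 0)),
    Sweeping   = list(joints = c("hand_l", "hand_r", "wrist_l", "wrist_r"),
                      amp = 0.30, freq = 1, axis = c(1, 0, 0.3)),
    stop("unknown indoor activity: ", activity)
  )
}

#' Generate a synthetic skeleton stream
#'
#' Emulates a depth camera's 20-joint 3D skeleton track for one of the six
#' indoor activities: a class-specific template pose plus class-specific
#' periodic limb displacement and Gaussian joint jitter. Walking and
#' Running are rejected -- ambulation leaves the camera's field of view.
#'
#' @param activity One of [indoor_activity_labels()].
#' @param duration Seconds.
#' @param fps Frames per second.
#' @param seed Integer seed.
#' @param subject Optional subject id (seeded body-scale and amplitude
#'   offsets).
#' @return A tibble with `t` and 60 coordinate columns `<joint>_{x,y,z}`
#'   (metres, camera frame, y up).
#' @export
gen_skeleton <- function(activity, duration, fps = 30, seed = 1,
                         subject = NULL) {
  if (!activity %in% indoor_activity_labels()) {
    stop("skeleton streams cover indoor activities only; got: ", activity)
  }
  off <- if (is.null(subject)) list(amp = 1, freq = 1, scale = 1) else
    subject_offsets(subject, seed)
  n <- round(duration * fps)
  t <- (seq_len(n) - 1) / fps
  pose <- template_pose(activity) * off$scale
  ms <- motion_spec(activity)
  axis <- ms$axis / sqrt(sum(ms$axis^2))
  withr::with_seed(derive_seed(seed, "skeleton", activity, subject %||% ""), {
    phase <- runif(1, 0, 2 * pi)
    disp <- ms$amp * off$amp * sin(2 * pi * ms$freq * off$freq * t + phase)
    joints <- skeleton_joint_names()
    out <- matrix(0, n, 60)
    colnames(out) <- as.vector(vapply(joints, coord_cols, character(3)))
    for (j in joints) {
      base <- matrix(pose[j, ], n, 3, byrow = TRUE)
      if (j %in% ms$joints) base <- base + outer(disp, axis)
      base <- base + matrix(rnorm(3 * n, sd = 0.01), n, 3)
      out[, coord_cols(j)] <- base
    }
    dplyr::bind_cols(tibble::tibble(t = t), tibble::as_tibble(out))
  })
}

#' Synthetic emotion signatures
#'
#' Acoustic parameters of the vocal source emulated per emotion: pitch mean
#' and spread (Hz), RMS energy level and spread, and vibrato depth. The
#' high-arousal pair (Anger/Happiness: loud, high pitch) and the
#' low-arousal pair (Neutral/Sadness: soft, low pitch) overlap by design,
#' so the emotion benchmark is intentionally harder than the activity one
#' and its confusion structure concentrates within the pairs.
#'
#' @return A tibble, one row per emotion.
#' @export
emotion_signatures <- function() {
  tibble::tribble(
    ~emotion,    ~f0_mean, ~f0_sd, ~energy, ~energy_sd, ~vibrato,
    "Anger",       230,      25,    0.30,     0.08,      0.025,
    "Happiness",   250,      35,    0.24,     0.06,      0.015,
    "Neutral",     135,      12,    0.12,     0.03,      0.006,
    "Sadness",     112,      15,    0.055,    0.015,     0.004
  )
}

#' Generate a synthetic call-audio stream
#'
#' Emulates one side of a phone conversation expressing a single emotion:
#' voiced bursts (harmonic source with 5 partials at a per-burst pitch
#' drawn from the signature, raised-cosine onsets/offsets, mild vibrato)
#' interleaved with short silences, so voice-activity detection has real
#' work to do.
#'
#' @param emotion One of [emotion_labels()].
#' @param duration Seconds.
#' @param rate Sampling rate, Hz.
#' @param seed Integer seed.
#' @param subject Optional subject id (seeded pitch/energy offsets).
#' @return Numeric signal in `[-1, 1]`.
#' @export
gen_audio <- function(emotion, duration, rate = 44100, seed = 1,
                      subject = NULL) {
  sig <- emotion_signatures()
  sig <- sig[sig$emotion == emotion, ]
  if (nrow(sig) == 0) stop("unknown emotion: ", emotion)
  off <- if (is.null(subject)) list(f0 = 1, energy = 1) else
    subject_offsets(subject, seed)
  n <- round(duration * rate)
  withr::with_seed(derive_seed(seed, "audio", emotion, subject %||% ""), {
    x <- numeric(n)
    pos <- 1
    while (pos < n) {
      burst_s <- runif(1, 0.6, 1.2)
      gap_s <- runif(1, 0.15, 0.35)
      nb <- min(round(burst_s * rate), n - pos + 1)
      if (nb > rate * 0.05) {
        tt <- (seq_len(nb) - 1) / rate
        f0 <- max(80, min(350, rnorm(1, sig$f0_mean * off$f0, sig$f0_sd)))
        a <- max(0.01, rnorm(1, sig$energy * off$energy, sig$energy_sd))
        vib <- 1 + sig$vibrato * sin(2 * pi * 5 * tt + runif(1, 0, 2 * pi))
        phase_inc <- 2 * pi * f0 * vib / rate
        ph <- cumsum(phase_inc)
        burst <- numeric(nb)
        for (h in 1:5) burst <- burst + (a / h) * sin(h * ph + runif(1, 0, 2 * pi))
        # raised-cosine fade over 30 ms at both ends
        nf <- min(round(0.03 * rate), floor(nb / 2))
        fade <- 0.5 * (1 - cos(pi * seq_len(nf) / nf))
        envl <- c(fade, rep(1, nb - 2 * nf), rev(fade))
        x[pos:(pos + nb - 1)] <- burst * envl
      }
      pos <- pos + nb + round(gap_s * rate)
    }
    x <- x + rnorm(n, sd = 1e-4)  # sensor noise floor
    pmin(pmax(x, -1), 1)
  })
}

#' Default personal place map
#'
#' Five personal places on a ~1 km urban grid, each with a 50 m matching
#' radius.
#'
#' @param user_id User the map belongs to.
#' @return A [personal_map()].
#' @export
default_personal_map <- function(user_id = "u1") {
  personal_map(user_id, tibble::tribble(
    ~label,       ~lat,    ~lon,     ~radius_m,
    "Home",       37.2400, 127.0800, 50,
    "Office",     37.2500, 127.0850, 50,
    "Restaurant", 37.2450, 127.0920, 50,
    "Gym",        37.2520, 127.0750, 50,
    "Mall",       37.2380, 127.0950, 50
  ))
}

#' Generate a synthetic GPS fix stream
#'
#' Emits one fix per `1/rate` seconds: during a dwell, Gaussian jitter
#' (default sd 5 m) around the place centre; when consecutive steps name
#' different places and `transit_s > 0`, a linear interpolation between the
#' two centres is inserted (extending the timeline by `transit_s` per
#' transition).
#'
#' @param steps Data frame with columns `label` (place name in the map) and
#'   `duration` (seconds).
#' @param map A [personal_map()].
#' @param rate Fix rate, Hz.
#' @param seed Integer seed.
#' @param jitter_m Positional noise, metres (1 sigma per axis).
#' @param transit_s Travel time inserted between different places.
#' @return A tibble of fixes `t`, `lat`, `lon`.
#' @export
gen_gps <- function(steps, map, rate = 1, seed = 1, jitter_m = 5,
                    transit_s = 0) {
  pl <- map$places
  bad <- setdiff(steps$label, pl$label)
  if (length(bad) > 0) stop("place(s) not in map: ", paste(bad, collapse = ", "))
  m_per_deg <- pi * 6371008.8 / 180
  withr::with_seed(derive_seed(seed, "gps"), {
    fixes <- list()
    t0 <- 0
    prev <- NULL
    for (i in seq_len(nrow(steps))) {
      place <- pl[pl$label == steps$label[i], ]
      if (!is.null(prev) && transit_s > 0 && prev$label != place$label) {
        nt <- round(transit_s * rate)
        frac <- seq_len(nt) / (nt + 1)
        fixes[[length(fixes) + 1L]] <- tibble::tibble(
          t = t0 + (seq_len(nt) - 1) / rate,
          lat = prev$lat + frac * (place$lat - prev$lat),
          lon = prev$lon + frac * (place$lon - prev$lon)
        )
        t0 <- t0 + nt / rate
      }
      nf <- round(steps$duration[i] * rate)
      fixes[[length(fixes) + 1L]] <- tibble::tibble(
        t = t0 + (seq_len(nf) - 1) / rate,
        lat = place$lat + rnorm(nf, sd = jitter_m / m_per_deg),
        lon = place$lon + rnorm(nf, sd = jitter_m /
                                  (m_per_deg * cos(place$lat * pi / 180)))
      )
      t0 <- t0 + nf / rate
      prev <- place
    }
    dplyr::bind_rows(fixes)
  })
}

#' Default run-through scenario script
#'
#' Eight one-minute steps covering all five high-level context classes and
#' most low-level labels, emulating a scripted run-through where each
#' action lasts approximately one minute.
#'
#' @return A tibble with columns `duration`, `activity`, `emotion`
#'   (`NA` = no phone call in that step), `location`.
#' @export
default_scenario_script <- function() {
  tibble::tribble(
    ~duration, ~activity,    ~emotion,    ~location,
    60,        "Sitting",    "Neutral",   "Office",
    60,        "Standing",   "Neutral",   "Office",
    60,        "Walking",    "Happiness", "Gym",
    60,        "Running",    "Happiness", "Gym",
    60,        "Eating",     "Neutral",   "Restaurant",
    60,        "Sweeping",   "Anger",     "Home",
    60,        "Stretching", "Neutral",   "Gym",
    60,        "LyingDown",  "Sadness",   "Home"
  )
}

#' Generate a full multimodal scenario
#'
#' Renders a scenario script into a time-ordered stream of sensory packets
#' across all modalities plus the exact ground-truth context timeline for
#' scoring. Inertial, GPS and audio streams cover every step; skeleton
#' packets are emitted only for indoor activities performed at Home, where
#' the depth camera is installed. Packets are chunked at 3 s (1 s for GPS).
#'
#' @param script Scenario script as in [default_scenario_script()].
#' @param user_id Subject identifier (also keys the per-subject signature
#'   offsets).
#' @param map A [personal_map()] for the user.
#' @param seed Integer seed.
#' @param audio_rate Audio sampling rate, Hz; the spec-level 44.1 kHz by
#'   default.
#' @return A list with `packets` (list of [sensory_packet()], time-ordered),
#'   `truth` (tibble `category`, `label`, `t_start`, `t_end`) and `script`.
#' @export
gen_scenario <- function(script, user_id = "u1",
                         map = default_personal_map(user_id), seed = 1,
                         audio_rate = 44100) {
  stopifnot(all(script$duration > 0))
  check_labels(script$activity, "activity")
  check_labels(script$location, "location")
  check_labels(script$emotion[!is.na(script$emotion)], "emotion")
  packets <- list()
  truth <- list()
  t0 <- 0
  add_packet <- function(p) packets[[length(packets) + 1L]] <<- p
  chunk_stream <- function(mat, rate, t_start, modality, chunk_s = 3) {
    n <- nrow(mat)
    starts <- seq.int(1L, n, by = round(chunk_s * rate))
    for (s in starts) {
      e <- min(n, s + round(chunk_s * rate) - 1L)
      add_packet(sensory_packet(user_id, modality,
                                t_start + (s - 1) / rate, rate,
                                mat[s:e, , drop = FALSE]))
    }
  }
  for (i in seq_len(nrow(script))) {
    st <- script[i, ]
    step_seed <- derive_seed(seed, "step", i)
    inert <- gen_inertial(st$activity, st$duration, seed = step_seed,
                          subject = user_id)
    chunk_stream(as.matrix(inert[, -1]), 50, t0, "inertial")
    if (st$activity %in% indoor_activity_labels() && st$location == "Home") {
      skel <- gen_skeleton(st$activity, st$duration, seed = step_seed,
                           subject = user_id)
      chunk_stream(as.matrix(skel[, -1]), 30, t0, "skeleton")
    }
    if (!is.na(st$emotion)) {
      aud <- gen_audio(st$emotion, st$duration, rate = audio_rate,
                       seed = step_seed, subject = user_id)
      chunk_stream(matrix(aud, ncol = 1), audio_rate, t0, "audio")
      truth[[length(truth) + 1L]] <- tibble::tibble(
        category = "emotion", label = st$emotion,
        t_start = t0, t_end = t0 + st$duration)
    }
    gps <- gen_gps(tibble::tibble(label = st$location, duration = st$duration),
                   map, seed = derive_seed(step_seed, "gps", i))
    gm <- as.matrix(gps[, c("lat", "lon")])
    chunk_stream(gm, 1, t0, "gps", chunk_s = 1)
    truth[[length(truth) + 1L]] <- tibble::tibble(
      category = "activity", label = st$activity,
      t_start = t0, t_end = t0 + st$duration)
    truth[[length(truth) + 1L]] <- tibble::tibble(
      category = "location", label = st$location,
      t_start = t0, t_end = t0 + st$duration)
    t0 <- t0 + st$duration
  }
  ord <- order(purrr::map_dbl(packets, "t_start"),
               purrr::map_chr(packets, "modality"))
  list(packets = packets[ord],
       truth = dplyr::arrange(dplyr::bind_rows(truth), .data$t_start,
                              .data$category),
       script = script)
}

#' Generate a multimodal training corpus
#'
#' Builds the window/segment-level feature datasets used to train and
#' cross-validate the recognizers: for each of `n_subjects` synthetic
#' subjects, every activity (inertial windows), every indoor activity
#' (skeleton windows) and every emotion (shuffled audio segments). Each
#' subject carries seeded offsets on the signature parameters, so
#' leave-one-subject-out folds test genuine generalization.
#'
#' @param n_subjects Number of training subjects.
#' @param seed Integer seed.
#' @param inertial_s,skeleton_s,audio_s Seconds of data per (subject, class).
#' @return A list of three tibbles (`inertial`, `skeleton`, `emotion`), each
#'   with a `subject` column, a label column and feature columns.
#' @export
gen_training_data <- function(n_subjects = 10, seed = 1, inertial_s = 60,
                              skeleton_s = 60, audio_s = 30) {
  subjects <- sprintf("S%02d", seq_len(n_subjects))
  inertial <- purrr::map_dfr(subjects, function(sub) {
    purrr::map_dfr(activity_labels(), function(act) {
      stream <- gen_inertial(act, inertial_s, seed = seed, subject = sub)
      mat <- as.matrix(stream[, -1])
      win <- 150
      n_win <- nrow(mat) %/% win
      purrr::map_dfr(seq_len(n_win), function(w) {
        feats <- inertial_features(mat[((w - 1) * win + 1):(w * win), ])
        dplyr::bind_cols(tibble::tibble(subject = sub, activity = act), feats)
      })
    })
  })
  skeleton <- purrr::map_dfr(subjects, function(sub) {
    purrr::map_dfr(indoor_activity_labels(), function(act) {
      stream <- gen_skeleton(act, skeleton_s, seed = seed, subject = sub)
      fps <- 30
      win <- 3 * fps
      hop <- win / 2
      starts <- seq.int(1L, nrow(stream) - win + 1L, by = hop)
      purrr::map_dfr(starts, function(s) {
        feats <- skeleton_features(stream[s:(s + win - 1L), ])
        dplyr::bind_cols(tibble::tibble(subject = sub, activity = act), feats)
      })
    })
  })
  emotion <- purrr::map_dfr(subjects, function(sub) {
    purrr::map_dfr(emotion_labels(), function(emo) {
      x <- gen_audio(emo, audio_s, seed = seed, subject = sub)
      segs <- segment_and_shuffle(x, 44100, seed = derive_seed(seed, sub, emo))
      segs <- segs[segs$voiced_fraction > 0, ]
      purrr::map_dfr(segs$samples, function(s) {
        dplyr::bind_cols(tibble::tibble(subject = sub, emotion = emo),
                         audio_features(s, 44100))
      })
    })
  })
  list(inertial = inertial, skeleton = skeleton, emotion = emotion)
}
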