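# Default high-level context definitions.
#
# A class is asserted for a composition of concurrent low-level contexts
# when its activity is in `activities`, its location is in `locations`
# (or locations is ANY) and its emotion is in `emotions` (or ANY).
# A category absent from the composition matches ANY but never an explicit
# set. Lower priority number wins when several definitions match.
# Emotions are deliberately ANY everywhere: high-level classes are anchored
# on activity and place, so emotion misrecognitions cannot corrupt them.
definitions:
  - class: OfficeWork
    activities: [Sitting]
    locations: [Office]
    emotions: ANY
    priority: 1
  - class: HavingMeal
    activities: [Eating]
    locations: [Home, Restaurant]
    emotions: ANY
    priority: 2
  - class: Housework
    activities: [Sweeping]
    locations: [Home]
    emotions: ANY
    priority: 3
  - class: Exercising
    activities: [Running, Stretching, Walking]
    locations: [Gym]
    emotions: ANY
    priority: 4
  - class: Exercising
    activities: [Running]
    locations: ANY
    emotions: ANY
    priority: 5
  - class: Inactivity
    activities: [Sitting, Standing, LyingDown]
    locations: ANY
    emotions: ANY
    priority: 6
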