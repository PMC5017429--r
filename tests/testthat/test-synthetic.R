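test_that("generators are deterministic for a fixed seed", {
  expect_identical(gen_inertial("Running", 3, seed = 5, subject = "S01"),
                   gen_inertial("Running", 3, seed = 5, subject = "S01"))
  expect_identical(gen_skeleton("Eating", 3, seed = 5, subject = "S01"),
                   gen_skeleton("Eating", 3, seed = 5, subject = "S01"))
  expect_identical(gen_audio("Sadness", 2, seed = 5, subject = "S01"),
                   gen_audio("Sadness", 2, seed = 5, subject = "S01"))
  map <- default_personal_map()
  steps <- tibble::tibble(label = "Gym", duration = 10)
  expect_identical(gen_gps(steps, map, seed = 5), gen_gps(steps, map, seed = 5))
  # different seeds genuinely differ
  expect_false(identical(gen_audio("Sadness", 2, seed = 5),
                         gen_audio("Sadness", 2, seed = 6)))
})

test_that("sitting windows are near-still; running beats walking in frequency", {
  sit <- gen_inertial("Sitting", 3, seed = 2)
  amag <- sqrt(rowSums(as.matrix(sit[, c("watch_ax", "watch_ay",
                                         "watch_az")])^2))
  expect_lt(sd(amag), 0.2)

  dom_freq <- function(activity) {
    st <- gen_inertial(activity, 10, seed = 2)
    x <- sqrt(rowSums(as.matrix(st[, c("watch_ax", "watch_ay",
                                       "watch_az")])^2))
    x <- x - mean(x)
    spec <- Mod(fft(x))^2
    freqs <- (seq_along(x) - 1) * 50 / length(x)
    keep <- freqs > 0.5 & freqs < 10
    freqs[keep][which.max(spec[keep])]
  }
  expect_gt(dom_freq("Running"), dom_freq("Walking"))
  expect_error(gen_inertial("Jogging", 3), "unknown")
})

test_that("audio signatures order energies and include silences", {
  e_mean <- function(emotion) {
    x <- gen_audio(emotion, 5, seed = 8)
    mean(contextmine:::frame_energy(contextmine:::frame_signal(x, 44100)))
  }
  expect_gt(e_mean("Anger"), e_mean("Sadness"))
  vf <- mean(vad_mask(gen_audio("Neutral", 10, seed = 8), 44100))
  expect_lt(vf, 1)
  expect_gt(vf, 0.2)
  expect_error(gen_audio("Bored", 2), "unknown")
})

test_that("gps dwells resolve to their place and counts follow the rate", {
  map <- default_personal_map()
  fixes <- gen_gps(tibble::tibble(label = "Home", duration = 60), map,
                   seed = 3)
  expect_identical(nrow(fixes), 60L)
  labels <- resolve_place(fixes, map)$label
  expect_gte(mean(labels == "Home"), 0.99)
  # transit midpoint between distant places resolves to Unknown
  fx <- gen_gps(tibble::tibble(label = c("Home", "Mall"),
                               duration = c(10, 10)),
                map, seed = 3, transit_s = 30)
  mid <- fx[fx$t >= 20 & fx$t < 30, ]
  expect_true(any(resolve_place(mid, map)$label == "Unknown"))
  expect_error(gen_gps(tibble::tibble(label = "School", duration = 5), map),
               "not in map")
})

test_that("scenario rendering produces aligned packets and ground truth", {
  script <- default_scenario_script()
  script$duration <- rep(12, nrow(script))
  sc <- gen_scenario(script, user_id = "S11", seed = 4)
  expect_gte(sum(script$duration), 96)
  # ground-truth run boundaries equal script step boundaries
  act <- dplyr::filter(sc$truth, category == "activity")
  expect_equal(act$t_start, cumsum(c(0, script$duration[-nrow(script)])))
  expect_equal(act$t_end - act$t_start, script$duration)
  expect_identical(act$label, script$activity)
  # packets are time-ordered
  t_starts <- purrr::map_dbl(sc$packets, "t_start")
  expect_true(all(diff(t_starts) >= 0))
  # same seed reproduces the stream byte for byte
  sc2 <- gen_scenario(script, user_id = "S11", seed = 4)
  expect_identical(purrr::map(sc$packets, "samples"),
                   purrr::map(sc2$packets, "samples"))
  # skeleton packets appear only for indoor steps at Home
  skel_t <- purrr::map_dbl(purrr::keep(sc$packets, ~ .x$modality == "skeleton"),
                           "t_start")
  home_indoor <- which(script$location == "Home" &
                         script$activity %in% indoor_activity_labels())
  starts <- cumsum(c(0, script$duration[-nrow(script)]))
  in_windows <- purrr::map_lgl(skel_t, function(t) {
    any(t >= starts[home_indoor] & t < starts[home_indoor] +
          script$duration[home_indoor])
  })
  expect_true(all(in_windows))
  expect_gt(length(skel_t), 0)
})

test_that("per-subject offsets shift the signatures between subjects", {
  a <- gen_inertial("Walking", 5, seed = 1, subject = "S01")
  b <- gen_inertial("Walking", 5, seed = 1, subject = "S02")
  expect_false(identical(a, b))
})
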