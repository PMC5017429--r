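test_that("per-channel descriptors match closed-form values", {
  # constant channel: degenerate but well-defined
  expect_equal(zero_crossing_rate(rep(9.8, 150)), 0)
  const_feats <- contextmine:::channel_features(rep(9.8, 150), cep_order = 5)
  expect_equal(unname(const_feats["mean"]), 9.8)
  expect_equal(unname(const_feats["range"]), 0)
  expect_true(all(is.finite(const_feats)))

  # 2 Hz unit sine at 50 Hz over 3 s: 12 zero crossings expected in closed
  # form (2 crossings per cycle x 6 cycles); verified against an
  # independent sign-change count on the same samples
  x <- sin(2 * pi * 2 * (0:149) / 50)
  oracle_count <- {
    y <- x - sum(x) / length(x)
    n_cross <- 0L
    for (i in 2:length(y)) if (y[i - 1] * y[i] < 0) n_cross <- n_cross + 1L
    n_cross
  }
  expect_equal(zero_crossing_rate(x) * 149, oracle_count)
  expect_lte(abs(oracle_count - 2 * 2 * 3), 1)  # within one crossing of 2fT
  expect_equal(max(x), 1, tolerance = 1e-2)
  expect_equal(min(x), -1, tolerance = 1e-2)

  # quartiles of 1..150 under linear interpolation between order statistics
  q <- contextmine:::channel_features(as.numeric(1:150), 5)[c("q1", "q2", "q3")]
  expect_equal(unname(q), c(38.25, 75.5, 112.75))
})

test_that("cepstrum coefficients are finite and length m for any channel", {
  for (x in list(rep(0, 150), rnorm(150), sin(2 * pi * 5 * (0:149) / 50))) {
    cc <- real_cepstrum(x, 5)
    expect_length(cc, 5)
    expect_true(all(is.finite(cc)))
  }
})

test_that("feature vector has fixed layout and finite values", {
  withr::with_seed(1, {
    w <- gen_inertial("Walking", 3, seed = 3)
    f <- inertial_features(as.matrix(w[, -1]))
    expect_identical(ncol(f), 140L)   # 10 effective channels x (9 + 5)
    expect_true(all(is.finite(unlist(f))))
  })
})

test_that("phone features are invariant to device rotation", {
  w <- as.matrix(gen_inertial("Sweeping", 3, seed = 5)[, -1])
  rot <- withr::with_seed(11, contextmine:::random_rotation())
  w_rot <- w
  for (triad in list(1:3, 4:6)) {  # phone accel and gyro triads
    w_rot[, triad] <- w[, triad] %*% t(rot)
  }
  f <- inertial_features(w)
  f_rot <- inertial_features(w_rot)
  phone_cols <- grep("^phone_", names(f))
  expect_equal(as.numeric(f[phone_cols]), as.numeric(f_rot[phone_cols]),
               tolerance = 1e-8)
})

test_that("k-NN predictions match the exhaustive oracle on random sets", {
  withr::with_seed(101, {
    for (rep in 1:60) {
      n <- sample(5:20, 1)
      case <- random_knn_case(n, n_classes = sample(2:4, 1), d = sample(2:4, 1))
      df <- dplyr::bind_cols(tibble::as_tibble(case$x),
                             tibble::tibble(activity = case$y))
      model <- fit_knn(df, k = 3)
      queries <- matrix(rnorm(5 * ncol(case$x)), 5,
                        dimnames = list(NULL, colnames(case$x)))
      got <- predict(model, queries)$.pred
      want <- apply(queries, 1, function(q) oracle_knn(case$x, case$y, 3, q))
      expect_identical(got, unname(want))
    }
  })
})

test_that("constructed vote ties resolve to the nearest single neighbour", {
  # three neighbours with three distinct labels: a forced 1-1-1 tie
  x <- matrix(c(1, 0, -1, 0, 0, 1), 3, 2, byrow = TRUE,
              dimnames = list(NULL, c("f1", "f2")))
  y <- c("Walking", "Sitting", "Running")
  df <- dplyr::bind_cols(tibble::as_tibble(x), tibble::tibble(activity = y))
  model <- fit_knn(df, k = 3)
  # query nearest the Walking point: the single nearest neighbour decides
  got <- predict(model, matrix(c(0.3, 0.05), 1,
                               dimnames = list(NULL, c("f1", "f2"))))
  expect_identical(got$.pred, oracle_knn(x, y, 3, c(0.3, 0.05)))
  expect_identical(got$.pred, "Walking")
  v <- got$votes[[1]]
  expect_identical(v[order(names(v))],
                   c(Running = 1L, Sitting = 1L, Walking = 1L))
})

test_that("k-NN degenerate cases behave per contract", {
  case <- withr::with_seed(7, random_knn_case(10, n_classes = 1))
  df <- dplyr::bind_cols(tibble::as_tibble(case$x),
                         tibble::tibble(activity = case$y))
  model <- fit_knn(df, k = 3)
  q <- matrix(rnorm(3), 1, dimnames = list(NULL, colnames(case$x)))
  expect_identical(predict(model, q)$.pred, case$y[1])
  expect_error(fit_knn(df, k = 0), "at least 1")
  expect_error(fit_knn(df, k = 11), "exceeds")
  expect_error(fit_knn(dplyr::mutate(df, activity = "Jogging")), "unknown")
  expect_error(predict(model, matrix(0, 1, 2)), "features")
  # exact training-row query whose neighbourhood is single-class
  expect_identical(predict(model, case$x[1, , drop = FALSE])$.pred, case$y[1])
})
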