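decisions_tbl <- function(labels, rid = "r1", t = seq_along(labels)) {
  tibble::tibble(recognizer_id = rid, user_id = "u1", category = "activity",
                 label = labels, t = t)
}

test_that("vertical fusion takes the slot majority, recency on ties", {
  expect_identical(vertical_fuse(decisions_tbl(c("Walking", "Walking",
                                                 "Sitting"))), "Walking")
  expect_identical(vertical_fuse(decisions_tbl(character(0))), NA_character_)
  # all two-decision tie cases: the later decision wins
  labs <- c("Sitting", "Walking", "Eating")
  for (a in labs) for (b in setdiff(labs, a)) {
    expect_identical(vertical_fuse(decisions_tbl(c(a, b))), b)
    expect_identical(vertical_fuse(decisions_tbl(c(a, b), t = c(5, 2))), a)
  }
  mixed <- dplyr::bind_rows(decisions_tbl("Walking", "r1"),
                            decisions_tbl("Walking", "r2"))
  expect_error(vertical_fuse(mixed), "single recognizer")
})

test_that("weighted voting favours the inertial recognizer on disagreement", {
  w <- activity_fusion_weights()
  for (a in activity_labels()) for (b in activity_labels()) {
    fused <- horizontal_fuse(c(inertial_knn = a, skeleton_tree = b), w)
    expect_identical(fused, a)  # agreement trivially returns the common vote
  }
})

test_that("absent recognizers renormalize; lone voters carry weight 1", {
  w <- activity_fusion_weights()
  for (lb in activity_labels()) {
    expect_identical(horizontal_fuse(c(skeleton_tree = lb), w), lb)
    expect_identical(horizontal_fuse(c(inertial_knn = lb), w), lb)
  }
  expect_identical(horizontal_fuse(c(inertial_knn = NA_character_,
                                     skeleton_tree = "Sitting"), w), "Sitting")
  expect_identical(horizontal_fuse(stats::setNames(character(0), character(0)),
                                   w), NA_character_)
  expect_error(horizontal_fuse(c(other = "Sitting"), w), "missing")
})

test_that("equal weights reduce to plain majority; scaling is irrelevant", {
  withr::with_seed(41, {
    for (rep in 1:200) {
      n <- sample(1:5, 1)
      ids <- paste0("r", seq_len(n))
      votes <- setNames(sample(activity_labels()[1:3], n, replace = TRUE), ids)
      w_eq <- setNames(rep(1, n), ids)
      got <- horizontal_fuse(votes, w_eq)
      counts <- table(votes)
      top <- sort(names(counts)[counts == max(counts)])[1]  # same tie rule
      expect_identical(got, top)
      # pre-normalization scale invariance
      expect_identical(horizontal_fuse(votes, w_eq * 37.5), got)
    }
  })
})

test_that("weight estimation normalizes accuracies", {
  expect_equal(estimate_weights(c(a = 0.8, b = 0.8)), c(a = 0.5, b = 0.5))
  expect_equal(estimate_weights(c(a = 0.9, b = 0.6)), c(a = 0.6, b = 0.4))
  expect_error(estimate_weights(c(a = 0, b = 0)), "positive")
  # the shipped weights imply a plausible accuracy ratio close to 1
  w <- activity_fusion_weights()
  expect_equal(unname(w[1] / w[2]), 1.031, tolerance = 1e-3)
})

test_that("change-only notification equals run-length boundaries", {
  withr::with_seed(53, {
    for (rep in 1:100) {
      stream <- sample(activity_labels()[1:3], sample(5:30, 1), replace = TRUE)
      notifier <- context_notifier()
      events <- purrr::compact(purrr::map(seq_along(stream), function(i) {
        notify_change(notifier, "u1", "activity", stream[i], i * 3)
      }))
      expect_length(events, length(rle(stream)$lengths))
    }
  })
  # the spec'd example: repeated Standing produces no second event
  notifier <- context_notifier()
  expect_s3_class(notify_change(notifier, "u1", "activity", "Standing", 0),
                  "tbl_df")
  expect_null(notify_change(notifier, "u1", "activity", "Standing", 3))
  ev <- notify_change(notifier, "u1", "activity", "Walking", 6)
  expect_identical(ev$kind, "change")
})

test_that("finalization closes the open context exactly once", {
  notifier <- context_notifier()
  expect_null(notify_change(notifier, "u1", "location", NA, 0))  # nothing open
  notify_change(notifier, "u1", "location", "Home", 0)
  fin <- notify_change(notifier, "u1", "location", NA, 10)
  expect_identical(fin$kind, "final")
  # after finalization the same label notifies again
  ev <- notify_change(notifier, "u1", "location", "Home", 12)
  expect_identical(ev$kind, "change")
})

test_that("fuse_decisions buckets by slot and notifies changes only", {
  # two recognizers disagreeing in slot 0, agreeing in slot 1, silent slot 2,
  # then a change in slot 3
  d <- dplyr::bind_rows(
    decisions_tbl(c("Walking", "Walking"), "inertial_knn", t = c(0, 1)),
    decisions_tbl("Sitting", "skeleton_tree", t = 0.5),
    decisions_tbl("Walking", "inertial_knn", t = 3.5),
    decisions_tbl("Walking", "skeleton_tree", t = 4),
    decisions_tbl("Sitting", "inertial_knn", t = 9.1)
  )
  out <- fuse_decisions(d)
  fused <- dplyr::arrange(out$fused, t)
  expect_equal(fused$label, c("Walking", "Walking", "Sitting"))
  expect_equal(out$events$label, c("Walking", "Sitting"))
  expect_equal(out$events$t, c(0, 9))
})
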