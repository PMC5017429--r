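change_event <- function(category, label, t, user = "u1") {
  tibble::tibble(user_id = user, category = category, label = label, t = t,
                 kind = "change")
}
final_event <- function(category, t, user = "u1") {
  tibble::tibble(user_id = user, category = category, label = NA_character_,
                 t = t, kind = "final")
}

test_that("notifications map to open/close transitions in the store", {
  store <- context_store()
  map_notification(store, change_event("activity", "Standing", 0))
  new <- map_notification(store, change_event("activity", "Walking", 10))
  llc <- store_records(store, "llc")
  expect_equal(llc$t_end, c(10, NA))
  expect_identical(new$label, "Walking")
  # final closes without opening
  map_notification(store, final_event("activity", 50))
  llc <- store_records(store, "llc")
  expect_equal(llc$t_end, c(10, 50))
  expect_identical(sum(is.na(llc$t_end)), 0L)
  expect_error(map_notification(store, change_event("activity", "Jogging", 60)),
               "unknown")
})

test_that("at most one open context per user and category, always", {
  withr::with_seed(61, {
    for (rep in 1:20) {
      store <- context_store()
      t <- 0
      for (i in 1:30) {
        cat <- sample(context_categories(), 1)
        t <- t + runif(1, 0.5, 5)
        if (runif(1) < 0.2) {
          map_notification(store, final_event(cat, t))
        } else {
          lb <- sample(contextmine:::category_labels(cat), 1)
          map_notification(store, change_event(cat, lb, t))
        }
        open <- dplyr::filter(store_records(store, "llc"), is.na(t_end))
        expect_false(any(duplicated(paste(open$user_id, open$category))))
      }
    }
  })
})

test_that("concurrency queries respect the half-open convention", {
  store <- context_store()
  map_notification(store, change_event("emotion", "Neutral", 0))
  map_notification(store, final_event("emotion", 20))
  map_notification(store, change_event("location", "Office", 0))
  map_notification(store, final_event("location", 10))
  got <- query_concurrent(store, "u1", 10)
  expect_identical(got$category, "emotion")   # [0,20) contains 10; [0,10) not
  expect_identical(nrow(query_concurrent(store, "u1", 25)), 0L)
})

test_that("concurrency queries match a linear interval scan on random stores", {
  withr::with_seed(67, {
    for (rep in 1:50) {
      store <- context_store()
      n <- sample(5:25, 1)
      for (i in seq_len(n)) {
        cat <- sample(context_categories(), 1)
        lb <- sample(contextmine:::category_labels(cat), 1)
        t0 <- runif(1, 0, 50)
        t1 <- if (runif(1) < 0.3) NA_real_ else t0 + runif(1, 0.1, 20)
        store$llc <- dplyr::bind_rows(store$llc, tibble::tibble(
          user_id = "u1", category = cat, label = lb, t_start = t0, t_end = t1))
      }
      tq <- sample(c(runif(1, 0, 60), store$llc$t_start[1],
                     store$llc$t_end[!is.na(store$llc$t_end)][1]), 1)
      excl <- sample(c(NA, context_categories()), 1)
      got <- query_concurrent(store, "u1", tq,
                              exclude_category = if (is.na(excl)) NULL else excl)
      keep <- logical(nrow(store$llc))
      for (i in seq_len(nrow(store$llc))) {
        row <- store$llc[i, ]
        inside <- row$t_start <= tq && (is.na(row$t_end) || tq < row$t_end)
        keep[i] <- inside && (is.na(excl) || row$category != excl)
      }
      expect_equal(got, store$llc[keep, ])
    }
  })
})

test_that("instantiation composes the new context with its concurrents", {
  store <- context_store()
  map_notification(store, change_event("emotion", "Neutral", 0))
  map_notification(store, change_event("location", "Restaurant", 2))
  new <- map_notification(store, change_event("activity", "Eating", 5))
  hlc <- build_hlc(new, query_concurrent(store, "u1", 5,
                                         exclude_category = "activity"))
  expect_identical(nrow(hlc$constituents), 3L)
  expect_identical(infer_hlc(hlc)$hlc_class, "HavingMeal")

  solo <- build_hlc(new, store_records(store, "llc")[0, ])
  expect_identical(nrow(solo$constituents), 1L)
  # duplicate category among constituents signals corruption
  expect_error(build_hlc(new, new), "duplicate")
})

test_that("invalid compositions infer as Unclassified with a reason", {
  bad <- high_level_context("u1", dplyr::bind_rows(
    low_level_context("u1", "activity", "Sitting", 90),
    low_level_context("u1", "activity", "Walking", 95)), 100)
  out <- infer_hlc(bad)
  expect_identical(out$hlc_class, "Unclassified")
  expect_match(out$invalid_reason, "duplicate")
})

test_that("high-level notification fires on class changes only", {
  store <- context_store()
  notifier <- context_notifier()
  h1 <- infer_hlc(compose_hlc("Sitting", "Office", t = 10))
  h2 <- infer_hlc(compose_hlc("Sitting", "Office", "Anger", t = 20))
  h3 <- infer_hlc(compose_hlc("Eating", "Restaurant", t = 30))
  expect_s3_class(notify_hlc(store, notifier, h1), "tbl_df")
  expect_null(notify_hlc(store, notifier, h2))   # composition changed, class not
  ev <- notify_hlc(store, notifier, h3)
  expect_identical(ev$label, "HavingMeal")
  # every classified context is persisted regardless of notification
  expect_identical(nrow(store_records(store, "hlc")), 3L)
  expect_equal(store_records(store, "hlc")$t_end, c(20, 30, NA))
})

test_that("high-level change events equal class run boundaries", {
  withr::with_seed(71, {
    for (rep in 1:30) {
      compositions <- purrr::map(seq_len(sample(5:15, 1)), function(i) {
        compose_hlc(sample(activity_labels(), 1),
                    sample(c(location_labels(), NA), 1), t = i * 10)
      })
      store <- context_store(); notifier <- context_notifier()
      classes <- purrr::map_chr(compositions, ~ infer_hlc(.x)$hlc_class)
      events <- purrr::compact(purrr::map(compositions, function(h) {
        notify_hlc(store, notifier, infer_hlc(h))
      }))
      expect_length(events, length(rle(classes)$lengths))
    }
  })
})

test_that("the engine replays an event log deterministically", {
  events <- dplyr::bind_rows(
    change_event("activity", "Sitting", 0),
    change_event("location", "Office", 0),
    change_event("emotion", "Neutral", 0),
    change_event("activity", "Eating", 60),
    change_event("location", "Restaurant", 60),
    change_event("activity", "Sweeping", 120),
    change_event("location", "Home", 120),
    final_event("emotion", 120),
    final_event("activity", 180)
  )
  out1 <- run_hlca(events)
  out2 <- run_hlca(events)
  expect_equal(out1$hlc_timeline, out2$hlc_timeline)
  expect_identical(out1$hlc_events$label,
                   c("OfficeWork", "HavingMeal", "Housework", "Unclassified"))
  # a final on the activity drops the composition to location-only
  last <- dplyr::slice_tail(out1$hlc_timeline, n = 1)
  expect_identical(last$hlc_class, "Unclassified")
  expect_true(is.na(last$activity))
})

test_that("corrupting emotion labels never changes the high-level timeline", {
  base_events <- dplyr::bind_rows(
    change_event("activity", "Sitting", 0),
    change_event("location", "Office", 0),
    change_event("emotion", "Neutral", 0),
    change_event("emotion", "Anger", 30),
    change_event("activity", "Eating", 60),
    change_event("location", "Restaurant", 60),
    change_event("emotion", "Happiness", 90)
  )
  ref <- run_hlca(base_events)$hlc_timeline
  withr::with_seed(73, {
    for (rep in 1:10) {
      corrupted <- base_events
      em <- corrupted$category == "emotion"
      corrupted$label[em] <- sample(emotion_labels(), sum(em), replace = TRUE)
      got <- run_hlca(corrupted)$hlc_timeline
      expect_identical(got$hlc_class, ref$hlc_class)
      expect_equal(got$t_start, ref$t_start)
    }
  })
})
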