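test_that("well-formed compositions validate; malformed ones return reasons", {
  ok <- compose_hlc("Sitting", "Office")
  expect_true(validate_hlc(ok)$valid)

  dup <- high_level_context("u1", dplyr::bind_rows(
    low_level_context("u1", "activity", "Sitting", 90),
    low_level_context("u1", "activity", "Walking", 95)
  ), 100)
  v <- validate_hlc(dup)
  expect_false(v$valid)
  expect_match(v$reason, "duplicate")

  # constituent that ended before the instance started is not concurrent
  stale <- high_level_context("u1", dplyr::bind_rows(
    low_level_context("u1", "activity", "Sitting", 50, 90),
    low_level_context("u1", "location", "Office", 50)
  ), 100)
  v <- validate_hlc(stale)
  expect_false(v$valid)
  expect_match(v$reason, "concurrent")

  # half-open boundary: a context ending exactly at t_start does not contain it
  edge <- high_level_context("u1",
    low_level_context("u1", "activity", "Sitting", 50, 100), 100)
  expect_false(validate_hlc(edge)$valid)

  mixed <- high_level_context("u1", dplyr::bind_rows(
    low_level_context("u1", "activity", "Sitting", 90),
    low_level_context("u2", "location", "Office", 90)
  ), 100)
  expect_false(validate_hlc(mixed)$valid)
})

test_that("default definitions assign the expected classes", {
  defs <- hlc_definitions()
  expect_identical(classify_hlc(compose_hlc("Sitting", "Office", "Neutral"),
                                defs), "OfficeWork")
  expect_identical(classify_hlc(compose_hlc("Eating", "Restaurant"), defs),
                   "HavingMeal")
  expect_identical(classify_hlc(compose_hlc("Sweeping", "Home"), defs),
                   "Housework")
  expect_identical(classify_hlc(compose_hlc("Running", "Mall"), defs),
                   "Exercising")
  # a location-requiring definition cannot fire without a location
  expect_identical(classify_hlc(compose_hlc("Sitting"), defs), "Inactivity")
  expect_identical(classify_hlc(compose_hlc("Eating"), defs), "Unclassified")
  expect_error(classify_hlc(compose_hlc("Sitting"), defs[0, ]), "empty")
})

test_that("classification matches the brute-force matcher on the full grid", {
  defs <- hlc_definitions()
  grid <- expand.grid(activity = activity_labels(),
                      location = c(location_labels(), NA),
                      emotion = c(emotion_labels(), NA),
                      stringsAsFactors = FALSE)
  got <- purrr::pmap_chr(grid, function(activity, location, emotion) {
    classify_hlc(compose_hlc(activity, location, emotion), defs)
  })
  want <- purrr::pmap_chr(grid, function(activity, location, emotion) {
    oracle_classify(activity, location, emotion, defs)
  })
  expect_identical(got, want)
})

test_that("emotion never influences the class under the default definitions", {
  defs <- hlc_definitions()
  grid <- expand.grid(activity = activity_labels(),
                      location = c(location_labels(), NA),
                      stringsAsFactors = FALSE)
  for (i in seq_len(nrow(grid))) {
    classes <- purrr::map_chr(c(emotion_labels(), NA), function(em) {
      classify_hlc(compose_hlc(grid$activity[i], grid$location[i], em), defs)
    })
    expect_length(unique(classes), 1)
  }
})

test_that("classify_hlc is pure: repeated calls agree", {
  defs <- hlc_definitions()
  h <- compose_hlc("Stretching", "Gym", "Happiness")
  expect_identical(classify_hlc(h, defs), classify_hlc(h, defs))
})

test_that("definition configs load, validate and reject bad entries", {
  path <- system.file("extdata", "hlc_definitions.yaml",
                      package = "contextmine")
  defs <- load_hlc_definitions(path)
  expect_setequal(unique(defs$hlc_class), hlc_labels())
  expect_identical(dplyr::arrange(defs, priority), dplyr::arrange(
    hlc_definitions(), priority))

  tmp <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("definitions:",
               "  - class: Exercising",
               "    activities: [Jogging]",
               "    locations: ANY",
               "    priority: 1"), tmp)
  expect_error(load_hlc_definitions(tmp), "Jogging")

  writeLines(c("definitions:",
               "  - {class: Inactivity, activities: [Sitting], priority: 1}",
               "  - {class: Housework, activities: [Sweeping], priority: 1}"),
             tmp)
  expect_error(load_hlc_definitions(tmp), "unique")
})

test_that("turtle export writes one subject block per classified context", {
  tl <- tibble::tibble(user_id = "u1",
                       hlc_class = c("OfficeWork", "HavingMeal"),
                       activity = c("Sitting", "Eating"),
                       emotion = NA_character_,
                       location = c("Office", "Restaurant"),
                       t_start = c(0, 60), t_end = c(60, NA))
  tmp <- withr::local_tempfile(fileext = ".ttl")
  export_contexts_ttl(tl, tmp)
  ttl <- readLines(tmp)
  expect_length(grep("a ctx:", ttl), 2)
  expect_length(grep("hasEndTime", ttl), 1)
})
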