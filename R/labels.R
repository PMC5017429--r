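#' Context label vocabularies
#'
#' The fixed label sets recognized by the pipeline: eight physical
#' activities, four emotions, five personal locations and five high-level
#' context classes. All classifiers, fusers and the definitional model
#' validate their labels against these sets.
#'
#' @return A character vector of labels, in canonical order.
#' @examples
#' activity_labels()
#' hlc_labels()
#' @export
activity_labels <- function() {
  c("Eating", "Running", "Sitting", "Standing", "Walking",
    "Stretching", "Sweeping", "LyingDown")
}

#' @rdname activity_labels
#' @export
emotion_labels <- function() {
  c("Anger", "Happiness", "Neutral", "Sadness")
}

#' @rdname activity_labels
#' @export
location_labels <- function() {
  c("Home", "Office", "Restaurant", "Gym", "Mall")
}

#' @rdname activity_labels
#' @export
hlc_labels <- function() {
  c("Inactivity", "OfficeWork", "Exercising", "HavingMeal", "Housework")
}

#' @rdname activity_labels
#' @export
context_categories <- function() {
  c("activity", "emotion", "location")
}

# labels legal for one low-level category
category_labels <- function(category) {
  switch(category,
    activity = activity_labels(),
    emotion  = emotion_labels(),
    location = location_labels(),
    stop("unknown context category: ", category)
  )
}

# The six activities observable indoors by the skeleton recognizer
# (everything but ambulation, which leaves the camera's field of view).
#' @rdname activity_labels
#' @export
indoor_activity_labels <- function() {
  setdiff(activity_labels(), c("Walking", "Running"))
}

check_labels <- function(labels, category, what = "label") {
  legal <- category_labels(category)
  bad <- setdiff(labels, legal)
  if (length(bad) > 0) {
    stop("unknown ", category, " ", what, "(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  invisible(labels)
}
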