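#' Low-level context records
#'
#' A low-level context (LLC) is an atomic recognized state -- one physical
#' activity, emotion or location -- held by one user over a time interval.
#' Intervals are half-open `[t_start, t_end)` in float seconds; an open
#' (still running) context has `t_end = NA`.
#'
#' @param user_id Character user identifier.
#' @param category One of `"activity"`, `"emotion"`, `"location"`.
#' @param label A label legal for `category` (see [activity_labels()]).
#' @param t_start Start time, seconds.
#' @param t_end End time in seconds, or `NA` for an open context.
#' @return A one-row tibble with columns `user_id`, `category`, `label`,
#'   `t_start`, `t_end`.
#' @examples
#' low_level_context("u1", "activity", "Sitting", 100)
#' @export
low_level_context <- function(user_id, category, label, t_start, t_end = NA_real_) {
  category <- match.arg(category, context_categories())
  check_labels(label, category)
  if (!is.na(t_end) && t_end <= t_start) {
    stop("t_end must exceed t_start (or be NA for an open context)")
  }
  tibble::tibble(
    user_id = as.character(user_id), category = category, label = label,
    t_start = as.numeric(t_start), t_end = as.numeric(t_end)
  )
}

# half-open containment: t in [t_start, t_end), open end contains all t >= start
interval_contains <- function(t_start, t_end, t) {
  t_start <= t & (is.na(t_end) | t < t_end)
}

#' High-level context instances
#'
#' A high-level context (HLC) is an abstract user state (e.g. OfficeWork)
#' composed of concurrent low-level contexts, at most one per category.
#' A freshly built instance is unclassified (`hlc_class = NA`) until
#' [infer_hlc()] assigns a class or `"Unclassified"`.
#'
#' @param user_id Character user identifier.
#' @param constituents Tibble of low-level contexts (rows as produced by
#'   [low_level_context()]), at most one per category.
#' @param t_start Start time of the instance, seconds.
#' @param t_end End time or `NA` while open.
#' @param hlc_class Optional class label (normally assigned by [infer_hlc()]).
#' @return An object of class `hlc`.
#' @export
high_level_context <- function(user_id, constituents, t_start, t_end = NA_real_,
                               hlc_class = NA_character_) {
  structure(
    list(user_id = as.character(user_id),
         hlc_class = hlc_class,
         constituents = constituents,
         t_start = as.numeric(t_start),
         t_end = as.numeric(t_end)),
    class = "hlc"
  )
}

#' @export
print.hlc <- function(x, ...) {
  cls <- if (is.na(x$hlc_class)) "<unclassified>" else x$hlc_class
  cat(sprintf("High-level context: %s (user %s, t_start %.3g)\n",
              cls, x$user_id, x$t_start))
  parts <- purrr::pmap_chr(x$constituents[c("category", "label")],
                           function(category, label) paste0(category, "=", label))
  cat("  constituents:", paste(parts, collapse = ", "), "\n")
  invisible(x)
}

#' Verify the consistency of a high-level context instance
#'
#' Checks the structural and semantic consistency of an unclassified
#' high-level context: a single user across all constituents, at most one
#' constituent per category, every label legal for its category, and every
#' constituent interval containing the instance start time under the
#' half-open convention.
#'
#' @param hlc An [high_level_context()] object.
#' @return A list with `valid` (logical) and `reason` (`NA` when valid).
#'   Invalidity is a return value, never an error.
#' @examples
#' llc <- low_level_context("u1", "activity", "Sitting", 100)
#' validate_hlc(high_level_context("u1", llc, 100))
#' @export
validate_hlc <- function(hlc) {
  cons <- hlc$constituents
  invalid <- function(reason) list(valid = FALSE, reason = reason)
  if (nrow(cons) == 0) return(invalid("no constituents"))
  if (any(duplicated(cons$category))) return(invalid("duplicate category"))
  if (!all(cons$user_id == hlc$user_id)) return(invalid("mixed users"))
  for (i in seq_len(nrow(cons))) {
    legal <- tryCatch(
      cons$label[i] %in% category_labels(cons$category[i]),
      error = function(e) FALSE
    )
    if (!legal) return(invalid(paste0("illegal label ", cons$label[i],
                                      " for category ", cons$category[i])))
  }
  contained <- interval_contains(cons$t_start, cons$t_end, hlc$t_start)
  if (!all(contained)) return(invalid("constituent not concurrent with t_start"))
  list(valid = TRUE, reason = NA_character_)
}

any_token <- "ANY"

is_any <- function(x) length(x) == 1 && identical(as.character(x), any_token)

#' Default high-level context definitions
#'
#' The definitional model mapping compositions of concurrent low-level
#' contexts to high-level context classes. Each row is one definition:
#' a class is asserted when the composition's activity is in
#' `activities`, its location is in `locations` (or `locations` is `"ANY"`),
#' and likewise for `emotions`. A category missing from the composition
#' matches `"ANY"` but never an explicit set: a definition that requires a
#' location cannot fire without one. When several definitions match, the
#' lowest `priority` number wins; `Exercising` holds two rows (gym exercise
#' and running anywhere), so class labels may repeat while priorities stay
#' unique. All default definitions leave `emotions = "ANY"`: high-level
#' classes are anchored on activity and place, never on emotional state.
#'
#' @return A tibble with columns `hlc_class`, `activities`, `locations`,
#'   `emotions` (list-columns of label vectors or the `"ANY"` token) and
#'   integer `priority`.
#' @examples
#' hlc_definitions()
#' @export
hlc_definitions <- function() {
  defs <- tibble::tibble(
    hlc_class = c("OfficeWork", "HavingMeal", "Housework",
                  "Exercising", "Exercising", "Inactivity"),
    activities = list("Sitting", "Eating", "Sweeping",
                      c("Running", "Stretching", "Walking"), "Running",
                      c("Sitting", "Standing", "LyingDown")),
    locations = list("Office", c("Home", "Restaurant"), "Home",
                     "Gym", any_token, any_token),
    emotions = list(any_token, any_token, any_token,
                    any_token, any_token, any_token),
    priority = 1:6
  )
  validate_hlc_definitions(defs)
}

validate_hlc_definitions <- function(defs) {
  stopifnot(is.data.frame(defs),
            all(c("hlc_class", "activities", "locations", "emotions",
                  "priority") %in% names(defs)))
  if (nrow(defs) == 0) stop("definition set is empty")
  if (anyDuplicated(defs$priority)) stop("definition priorities must be unique")
  bad_class <- setdiff(defs$hlc_class, hlc_labels())
  if (length(bad_class) > 0) {
    stop("unknown high-level class(es): ", paste(bad_class, collapse = ", "))
  }
  for (i in seq_len(nrow(defs))) {
    acts <- defs$activities[[i]]
    if (length(acts) == 0 || is_any(acts)) {
      stop("required activities must be a non-empty explicit set (row ", i, ")")
    }
    check_labels(acts, "activity")
    if (!is_any(defs$locations[[i]])) check_labels(defs$locations[[i]], "location")
    if (!is_any(defs$emotions[[i]])) check_labels(defs$emotions[[i]], "emotion")
  }
  defs$priority <- as.integer(defs$priority)
  dplyr::arrange(tibble::as_tibble(defs), .data$priority)
}

#' Load high-level context definitions from a config file
#'
#' Reads a YAML or JSON file describing the definitional model, validates
#' label legality and priority uniqueness, and returns the definition table.
#' The expected layout is a list of entries with fields `class`,
#' `activities`, `locations`, `emotions` (label vectors or the string
#' `"ANY"`) and `priority`. The packaged default lives at
#' `system.file("extdata", "hlc_definitions.yaml", package = "contextmine")`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` config file.
#' @return A validated definitions tibble, ordered by priority.
#' @export
load_hlc_definitions <- function(path) {
  if (!file.exists(path)) stop("definition config not found: ", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.null(raw$definitions)) raw <- raw$definitions
  defs <- purrr::map_dfr(raw, function(d) {
    tibble::tibble(
      hlc_class = d$class,
      activities = list(unlist(d$activities)),
      locations = list(unlist(d$locations %||% any_token)),
      emotions = list(unlist(d$emotions %||% any_token)),
      priority = d$priority
    )
  })
  validate_hlc_definitions(defs)
}

# does one definition row match an (activity, location, emotion) composition?
# missing categories are NA and match only ANY
definition_matches <- function(def_activities, def_locations, def_emotions,
                               activity, location, emotion) {
  match_slot <- function(allowed, value, required = FALSE) {
    if (required) return(!is.na(value) && value %in% allowed)
    if (is_any(allowed)) return(TRUE)
    !is.na(value) && value %in% allowed
  }
  match_slot(def_activities, activity, required = TRUE) &&
    match_slot(def_locations, location) &&
    match_slot(def_emotions, emotion)
}

#' Classify a high-level context against the definitional model
#'
#' Finds the highest-priority definition satisfied by the composition of a
#' validated high-level context and returns its class, or `"Unclassified"`
#' when no definition matches. Classification is a pure function of the
#' composition and the definition table.
#'
#' @param hlc A validated [high_level_context()].
#' @param defs Definition table from [hlc_definitions()] or
#'   [load_hlc_definitions()].
#' @return A single class label (possibly `"Unclassified"`).
#' @examples
#' cons <- dplyr::bind_rows(
#'   low_level_context("u1", "activity", "Sitting", 100),
#'   low_level_context("u1", "location", "Office", 90)
#' )
#' classify_hlc(high_level_context("u1", cons, 100), hlc_definitions())
#' @export
classify_hlc <- function(hlc, defs = hlc_definitions()) {
  if (is.null(defs) || nrow(defs) == 0) stop("definition set is empty")
  cons <- hlc$constituents
  slot <- function(cat) {
    lab <- cons$label[cons$category == cat]
    if (length(lab) == 0) NA_character_ else lab[[1]]
  }
  activity <- slot("activity")
  location <- slot("location")
  emotion <- slot("emotion")
  defs <- dplyr::arrange(defs, .data$priority)
  for (i in seq_len(nrow(defs))) {
    if (definition_matches(defs$activities[[i]], defs$locations[[i]],
                           defs$emotions[[i]], activity, location, emotion)) {
      return(defs$hlc_class[[i]])
    }
  }
  "Unclassified"
}

#' Verify then classify a high-level context
#'
#' Runs [validate_hlc()] and, when the instance is consistent,
#' [classify_hlc()]. Invalid instances come back `"Unclassified"` with the
#' verification reason attached, mirroring a reasoner that refuses to assert
#' a class over an inconsistent individual.
#'
#' @inheritParams classify_hlc
#' @return The input `hlc` with `hlc_class` filled in and, when invalid,
#'   an `invalid_reason` element.
#' @export
infer_hlc <- function(hlc, defs = hlc_definitions()) {
  verdict <- validate_hlc(hlc)
  if (!verdict$valid) {
    hlc$hlc_class <- "Unclassified"
    hlc$invalid_reason <- verdict$reason
    return(hlc)
  }
  hlc$hlc_class <- classify_hlc(hlc, defs)
  hlc
}

#' Export context instances as RDF Turtle
#'
#' Serializes low-level and high-level context timelines as simple Turtle
#' triples (`hasActivity`, `hasEmotion`, `hasLocation`, `hasStartTime`,
#' `hasEndTime`) so instances can be loaded into an external triple store.
#'
#' @param hlc_timeline Tibble of classified high-level contexts as returned
#'   by [replay_scenario()]'s `hlc_timeline` (columns `user_id`, `hlc_class`,
#'   `t_start`, `t_end`, and optionally `activity`/`emotion`/`location`).
#' @param path Output file path.
#' @param base IRI prefix for minted instance identifiers.
#' @return Invisibly, the path written.
#' @export
export_contexts_ttl <- function(hlc_timeline, path,
                                base = "http://example.org/context#") {
  lines <- c(sprintf("@prefix ctx: <%s> .", base),
             "@prefix xsd: <http://www.w3.org/2001/XMLSchema#> .")
  for (i in seq_len(nrow(hlc_timeline))) {
    row <- hlc_timeline[i, ]
    iri <- sprintf("ctx:hlc_%s_%d", row$user_id, i)
    preds <- sprintf("a ctx:%s", row$hlc_class)
    for (cat in c("activity", "emotion", "location")) {
      pred <- paste0("has", toupper(substr(cat, 1, 1)), substr(cat, 2, nchar(cat)))
      if (cat %in% names(row) && !is.na(row[[cat]])) {
        preds <- c(preds, sprintf("ctx:%s ctx:%s", pred, row[[cat]]))
      }
    }
    preds <- c(preds, sprintf("ctx:hasStartTime \"%g\"^^xsd:double", row$t_start))
    if (!is.na(row$t_end)) {
      preds <- c(preds, sprintf("ctx:hasEndTime \"%g\"^^xsd:double", row$t_end))
    }
    lines <- c(lines,
               paste0(iri, " ", paste(preds, collapse = " ;\n    "), " ."))
  }
  writeLines(lines, path)
  invisible(path)
}
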