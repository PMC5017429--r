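#' Vertical fusion of one recognizer's decisions within a slot
#'
#' Aggregates all decisions a single recognizer delivered within one fusion
#' slot into one label by simple majority. An empty slot yields `NA`
#' ("no decision"). Ties break in favour of the most recent decision among
#' the tied labels -- recency as a freshness proxy.
#'
#' @param decisions Data frame with columns `recognizer_id`, `label`, `t`
#'   (one recognizer, one user, one slot). Zero rows allowed.
#' @return A single label, or `NA_character_` for an empty slot.
#' @examples
#' vertical_fuse(tibble::tibble(recognizer_id = "r", t = 1:3,
#'                              label = c("Walking", "Walking", "Sitting")))
#' @export
vertical_fuse <- function(decisions) {
  if (is.null(decisions) || nrow(decisions) == 0) return(NA_character_)
  if (length(unique(decisions$recognizer_id)) > 1) {
    stop("vertical fusion aggregates decisions of a single recognizer")
  }
  counts <- table(decisions$label)
  top <- names(counts)[counts == max(counts)]
  if (length(top) == 1) return(top)
  tied <- decisions[decisions$label %in% top, ]
  tied$label[which.max(tied$t)]
}

#' Horizontal fusion across recognizers: weighted majority voting
#'
#' Combines the per-recognizer labels of one context category into a single
#' label by weighted majority voting: the label maximizing the summed
#' weights of the recognizers voting for it wins. Weights of absent
#' recognizers are dropped and the remaining weights renormalized, so a
#' lone recognizer always carries weight 1. The default activity weights
#' (0.5076 inertial, 0.4924 skeleton/video) subtly favour the inertial
#' recognizer, so every two-way disagreement resolves to its vote.
#' Weighted-sum ties break lexicographically by label.
#'
#' @param votes Named character vector or one-row data frame:
#'   `recognizer_id -> label`. `NA` labels are treated as absent.
#' @param weights Named positive weights covering the voting recognizers;
#'   any overall scale (weights need not sum to 1 before renormalization).
#' @return The fused label, or `NA_character_` when no recognizer voted.
#' @examples
#' horizontal_fuse(c(inertial_knn = "Walking", skeleton_tree = "Sitting"),
#'                 activity_fusion_weights())
#' @export
horizontal_fuse <- function(votes, weights) {
  if (is.data.frame(votes)) votes <- unlist(votes[1, , drop = TRUE])
  votes <- votes[!is.na(votes)]
  if (length(votes) == 0) return(NA_character_)
  if (!all(names(votes) %in% names(weights))) {
    stop("weights missing for recognizer(s): ",
         paste(setdiff(names(votes), names(weights)), collapse = ", "))
  }
  w <- weights[names(votes)]
  if (any(w <= 0)) stop("weights must be positive")
  w <- w / sum(w)
  tally <- tapply(w, votes, sum)
  top <- names(tally)[tally == max(tally)]
  sort(top)[1]
}

#' Default activity fusion weights
#'
#' Weights for the two activity recognizers, proportional to each
#' recognizer's measured recognition performance: 0.5076 for the inertial
#' k-NN and 0.4924 for the skeleton decision tree.
#'
#' @return Named numeric vector summing to 1.
#' @export
activity_fusion_weights <- function() {
  c(inertial_knn = 0.5076, skeleton_tree = 0.4924)
}

#' Estimate fusion weights from recognizer accuracies
#'
#' Normalizes per-recognizer accuracy estimates into voting weights:
#' `w_i = a_i / sum(a)`.
#'
#' @param accuracies Named numeric vector of accuracies in `(0, 1]`.
#' @return Named weights summing to 1.
#' @examples
#' estimate_weights(c(inertial_knn = 0.9, skeleton_tree = 0.6))
#' @export
estimate_weights <- function(accuracies) {
  if (length(accuracies) == 0 || any(accuracies < 0) || sum(accuracies) == 0) {
    stop("accuracies must be non-negative with a positive sum")
  }
  accuracies / sum(accuracies)
}

#' Change-only context notifier
#'
#' Tracks, per (user, category), the last notified label and the start time
#' of the open context, and emits an event only when the newly fused label
#' differs from the last notified one. A `FINAL` marker closes the open
#' context (setting its end time) without opening a new one -- used when a
#' category's data stream ceases.
#'
#' @return `context_notifier()`: a notifier object with empty state.
#' @export
context_notifier <- function() {
  env <- new.env(parent = emptyenv())
  env$state <- list()  # key "user|category" -> list(label, t_start)
  structure(env, class = "context_notifier")
}

notifier_key <- function(user_id, category) paste(user_id, category, sep = "|")

#' @rdname context_notifier
#' @param notifier A `context_notifier`.
#' @param user_id,category Stream identity.
#' @param label Newly fused label, or `NA` to finalize the open context.
#' @param t Event time, seconds.
#' @return `notify_change()`: a one-row event tibble
#'   (`user_id`, `category`, `label`, `t`, `kind` = `"change"`/`"final"`),
#'   or `NULL` when no notification is due. State updates on emission only.
#' @export
notify_change <- function(notifier, user_id, category, label, t) {
  stopifnot(inherits(notifier, "context_notifier"))
  key <- notifier_key(user_id, category)
  st <- notifier$state[[key]]
  if (is.na(label)) {  # finalization
    if (is.null(st)) {
      cm_log("debug", "finalization with no open %s context for %s; ignored",
             category, user_id)
      return(NULL)
    }
    notifier$state[[key]] <- NULL
    return(tibble::tibble(user_id = user_id, category = category,
                          label = NA_character_, t = t, kind = "final"))
  }
  check_labels(label, category)
  if (!is.null(st) && identical(st$label, label)) return(NULL)
  notifier$state[[key]] <- list(label = label, t_start = t)
  tibble::tibble(user_id = user_id, category = category, label = label,
                 t = t, kind = "change")
}

#' Fuse per-slot recognizer decisions into notification events
#'
#' Drives the full unification stage over a decision stream: decisions are
#' bucketed into fusion slots of `slot` seconds aligned to the session
#' origin, vertically fused per recognizer within each slot, horizontally
#' fused per category across recognizers, and passed through a change-only
#' notifier. Slots in which a category received no decision emit nothing
#' (the previous context simply persists); a final marker can be injected
#' by the caller via [notify_change()] when a stream provably ceased.
#'
#' @param decisions Data frame with columns `recognizer_id`, `user_id`,
#'   `category`, `label`, `t`.
#' @param weights Named weight vector covering all recognizer ids present.
#' @param slot Fusion slot length, seconds.
#' @param notifier Optional existing [context_notifier()] to continue from.
#' @return A list with `events` (tibble of change/final events) and
#'   `fused` (tibble of per-slot fused labels per user and category).
#' @export
fuse_decisions <- function(decisions, weights = activity_fusion_weights(),
                           slot = 3, notifier = context_notifier()) {
  decisions <- tibble::as_tibble(decisions)
  fused <- decisions |>
    dplyr::mutate(slot_idx = floor(.data$t / slot)) |>
    dplyr::group_by(.data$user_id, .data$category, .data$slot_idx,
                    .data$recognizer_id) |>
    dplyr::group_modify(~ tibble::tibble(label = vertical_fuse(
      dplyr::mutate(.x, recognizer_id = .y$recognizer_id)))) |>
    dplyr::group_by(.data$user_id, .data$category, .data$slot_idx) |>
    dplyr::group_modify(function(d, g) {
      v <- setNames(d$label, d$recognizer_id)
      w <- if (g$category %in% names(weights) && is.list(weights)) {
        weights[[g$category]]
      } else {
        weights
      }
      # single-recognizer categories fuse as the identity (weight 1)
      if (!all(names(v) %in% names(w))) {
        w <- c(w, setNames(rep(1, sum(!names(v) %in% names(w))),
                           setdiff(names(v), names(w))))
      }
      tibble::tibble(label = horizontal_fuse(v, w))
    }) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$slot_idx, .data$user_id, .data$category) |>
    dplyr::mutate(t = .data$slot_idx * slot)
  events <- purrr::pmap_dfr(
    fused[c("user_id", "category", "label", "t")],
    function(user_id, category, label, t) {
      ev <- notify_change(notifier, user_id, category, label, t)
      if (is.null(ev)) tibble::tibble() else ev
    }
  )
  list(events = events, fused = fused)
}
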