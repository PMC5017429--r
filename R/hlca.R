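#' Append-only context store
#'
#' In-process persistence for low- and high-level context records, indexed
#' by user, category and time interval. The store maintains the invariants
#' that at most one low-level context per (user, category) and at most one
#' high-level context per user are open (`t_end = NA`) at any time.
#'
#' @return `context_store()`: an empty store.
#' @export
context_store <- function() {
  env <- new.env(parent = emptyenv())
  env$llc <- tibble::tibble(user_id = character(), category = character(),
                            label = character(), t_start = numeric(),
                            t_end = numeric())
  env$hlc <- tibble::tibble(user_id = character(), hlc_class = character(),
                            activity = character(), emotion = character(),
                            location = character(), t_start = numeric(),
                            t_end = numeric())
  structure(env, class = "context_store")
}

#' @export
print.context_store <- function(x, ...) {
  cat(sprintf("Context store: %d low-level, %d high-level records\n",
              nrow(x$llc), nrow(x$hlc)))
  invisible(x)
}

#' @rdname context_store
#' @param store A `context_store`.
#' @param which `"llc"` or `"hlc"`.
#' @return `store_records()`: the requested records as a tibble.
#' @export
store_records <- function(store, which = c("llc", "hlc")) {
  which <- match.arg(which)
  store[[which]]
}

open_llc_index <- function(store, user_id, category) {
  which(store$llc$user_id == user_id & store$llc$category == category &
          is.na(store$llc$t_end))
}

#' Map a low-level notification event into the store
#'
#' Interprets a change or finalization event from the low-level notifier
#' and updates the store's open context for the event's (user, category):
#' a change event closes the previous open context at the event time (if
#' any) and opens a new one; a final event only closes. Returns the newly
#' opened low-level context for change events (`NULL` for finals), which
#' is what triggers high-level inference.
#'
#' @param store A [context_store()].
#' @param event One-row event tibble as produced by [notify_change()].
#' @return The new open low-level context (one-row tibble) or `NULL`.
#' @export
map_notification <- function(store, event) {
  stopifnot(inherits(store, "context_store"))
  user_id <- event$user_id; category <- event$category
  open_i <- open_llc_index(store, user_id, category)
  if (identical(event$kind, "final")) {
    if (length(open_i) == 1) {
      store$llc$t_end[open_i] <- event$t
    } else {
      cm_log("debug", "final event for %s/%s with no open context", user_id,
             category)
    }
    return(invisible(NULL))
  }
  check_labels(event$label, category)
  if (length(open_i) == 1) store$llc$t_end[open_i] <- event$t
  new_llc <- low_level_context(user_id, category, event$label, event$t)
  store$llc <- dplyr::bind_rows(store$llc, new_llc)
  invisible(new_llc)
}

#' Query low-level contexts concurrent with an instant
#'
#' Returns every stored low-level context of a user whose half-open
#' interval `[t_start, t_end)` contains `t` (an open context contains every
#' `t >= t_start`), excluding one category -- typically the category of the
#' new context that triggered the query.
#'
#' @param store A [context_store()].
#' @param user_id User to query.
#' @param t Query instant, seconds.
#' @param exclude_category Category to omit (or `NULL` for none).
#' @return A tibble of matching low-level contexts (possibly empty).
#' @export
query_concurrent <- function(store, user_id, t, exclude_category = NULL) {
  llc <- store$llc
  hit <- llc$user_id == user_id &
    interval_contains(llc$t_start, llc$t_end, t)
  if (!is.null(exclude_category)) hit <- hit & llc$category != exclude_category
  llc[hit, ]
}

#' Build an unclassified high-level context
#'
#' Combines a newly opened low-level context with the concurrent contexts
#' of the other categories into an unclassified high-level context starting
#' at the new context's start time.
#'
#' @param new_llc One-row tibble: the just-opened low-level context.
#' @param concurrent Tibble of concurrent low-level contexts from
#'   [query_concurrent()] at `new_llc$t_start`.
#' @return An unclassified [high_level_context()].
#' @export
build_hlc <- function(new_llc, concurrent) {
  cons <- dplyr::bind_rows(new_llc, concurrent)
  if (anyDuplicated(cons$category)) {
    stop("duplicate category among constituents: store invariant violated")
  }
  high_level_context(new_llc$user_id, cons, new_llc$t_start)
}

#' High-level context notifier and persistence
#'
#' Persists every classified high-level context in the store (closing the
#' user's previously open one) and emits a notification event only when the
#' class differs from the last notified class for that user: changes in the
#' low-level composition that leave the class unchanged are stored but not
#' communicated.
#'
#' @param store A [context_store()].
#' @param notifier A [context_notifier()] dedicated to high-level classes.
#' @param hlc A classified [high_level_context()] (from [infer_hlc()]).
#' @return A one-row event tibble, or `NULL` when the class is unchanged.
#' @export
notify_hlc <- function(store, notifier, hlc) {
  stopifnot(inherits(store, "context_store"),
            inherits(notifier, "context_notifier"))
  if (is.na(hlc$hlc_class)) stop("high-level context is not classified")
  open_i <- which(store$hlc$user_id == hlc$user_id & is.na(store$hlc$t_end))
  if (length(open_i) == 1) store$hlc$t_end[open_i] <- hlc$t_start
  slot <- function(cat) {
    lab <- hlc$constituents$label[hlc$constituents$category == cat]
    if (length(lab) == 0) NA_character_ else lab[[1]]
  }
  store$hlc <- dplyr::bind_rows(store$hlc, tibble::tibble(
    user_id = hlc$user_id, hlc_class = hlc$hlc_class,
    activity = slot("activity"), emotion = slot("emotion"),
    location = slot("location"), t_start = hlc$t_start, t_end = NA_real_
  ))
  key <- notifier_key(hlc$user_id, "hlc")
  st <- notifier$state[[key]]
  if (!is.null(st) && identical(st$label, hlc$hlc_class)) return(NULL)
  notifier$state[[key]] <- list(label = hlc$hlc_class, t_start = hlc$t_start)
  tibble::tibble(user_id = hlc$user_id, category = "hlc",
                 label = hlc$hlc_class, t = hlc$t_start, kind = "change")
}

#' Run the high-level context engine over a low-level event stream
#'
#' The end-to-end HLCA loop: each low-level notification event is mapped
#' into the store; a change event triggers synchronization (concurrent
#' context query at the new context's start), instantiation of an
#' unclassified high-level context, verification and classification against
#' the definitional model, persistence, and change-only high-level
#' notification. A finalization event re-runs inference with the reduced
#' composition (the remaining concurrent contexts), so the high-level state
#' tracks the loss of a category.
#'
#' @param events Tibble of low-level events (columns `user_id`, `category`,
#'   `label`, `t`, `kind`), time-ordered.
#' @param defs Definition table (see [hlc_definitions()]).
#' @param store Optional existing [context_store()].
#' @return A list with `store`, `hlc_events` (change notifications) and
#'   `hlc_timeline` (all persisted classified contexts).
#' @export
run_hlca <- function(events, defs = hlc_definitions(), store = context_store()) {
  notifier <- context_notifier()
  hlc_events <- list()
  events <- dplyr::arrange(tibble::as_tibble(events), .data$t)
  # events sharing a timestamp and user are one synchronization batch: all
  # low-level mutations land first, then inference runs once, so a
  # simultaneous activity+location handover never yields a spurious
  # intermediate composition
  batches <- split(events, paste(format(events$t, digits = 12), events$user_id))
  batches <- batches[order(purrr::map_dbl(batches, ~ .x$t[1]))]
  for (batch in batches) {
    for (i in seq_len(nrow(batch))) map_notification(store, batch[i, ])
    user <- batch$user_id[1]
    t <- batch$t[1]
    cons <- query_concurrent(store, user, t)
    if (nrow(cons) == 0) next
    hlc <- infer_hlc(high_level_context(user, cons, t), defs)
    out <- notify_hlc(store, notifier, hlc)
    if (!is.null(out)) hlc_events[[length(hlc_events) + 1L]] <- out
  }
  list(store = store,
       hlc_events = dplyr::bind_rows(hlc_events),
       hlc_timeline = store$hlc)
}
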