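#' Confusion matrix over a fixed label set
#'
#' @param truth,pred Character vectors of true and predicted labels.
#' @param labels Ordered label set defining the matrix dimensions.
#' @return An object of class `confusion_matrix` wrapping an integer
#'   `true x predicted` count matrix.
#' @export
confusion_matrix <- function(truth, pred, labels = sort(unique(c(truth, pred)))) {
  stopifnot(length(truth) == length(pred))
  tab <- table(factor(truth, levels = labels), factor(pred, levels = labels))
  m <- matrix(as.integer(tab), nrow = length(labels),
              dimnames = list(truth = labels, predicted = labels))
  structure(list(counts = m, labels = labels), class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  print(x$counts)
  invisible(x)
}

# elementwise sum of confusion matrices over the same label set
sum_confusion <- function(cms) {
  labels <- cms[[1]]$labels
  counts <- Reduce(`+`, purrr::map(cms, "counts"))
  structure(list(counts = counts, labels = labels), class = "confusion_matrix")
}

#' @method tidy confusion_matrix
#' @export
tidy.confusion_matrix <- function(x, ...) {
  as.data.frame(as.table(x$counts), stringsAsFactors = FALSE) |>
    tibble::as_tibble() |>
    dplyr::rename(n = "Freq")
}

#' @method glance confusion_matrix
#' @export
glance.confusion_matrix <- function(x, ...) {
  tibble::tibble(n = sum(x$counts),
                 accuracy = sum(diag(x$counts)) / max(1, sum(x$counts)),
                 macro_f = macro_f(x))
}

#' @method autoplot confusion_matrix
#' @export
autoplot.confusion_matrix <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$truth,
                                   fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), colour = "white") +
    ggplot2::scale_y_discrete(limits = rev(object$labels)) +
    ggplot2::scale_fill_gradient(low = "grey20", high = "firebrick") +
    ggplot2::labs(x = "predicted", y = "actual") +
    ggplot2::theme_minimal()
}

#' Per-class and macro F-scores from a confusion matrix
#'
#' `F_c = 2 P R / (P + R)`, with precision, recall and F defined as 0 where
#' the denominator vanishes (e.g. a class with no support). The macro score
#' is the unweighted mean over classes.
#'
#' @param cm A [confusion_matrix()].
#' @return `f_score()`: a tibble with `label`, `support`, `precision`,
#'   `recall`, `f`. `macro_f()`: a single number.
#' @export
f_score <- function(cm) {
  m <- cm$counts
  tp <- diag(m)
  support <- rowSums(m)
  predicted <- colSums(m)
  precision <- ifelse(predicted > 0, tp / predicted, 0)
  recall <- ifelse(support > 0, tp / support, 0)
  f <- ifelse(precision + recall > 0,
              2 * precision * recall / (precision + recall), 0)
  tibble::tibble(label = cm$labels, support = as.integer(support),
                 precision = unname(precision), recall = unname(recall),
                 f = unname(f))
}

#' @rdname f_score
#' @export
macro_f <- function(cm) {
  mean(f_score(cm)$f)
}

#' Leave-one-subject-out cross-validation of a recognizer
#'
#' For each subject in the dataset: train the recognizer on all other
#' subjects and test on the held-out one. Fold confusion matrices are
#' summed elementwise into the pooled matrix.
#'
#' @param data Feature tibble with a `subject` column and the recognizer's
#'   label column, as produced by [gen_training_data()].
#' @param kind `"inertial"` (k-NN), `"skeleton"` (decision tree) or
#'   `"emotion"` (RBF SVM).
#' @return A list with `folds` (tibble of per-fold confusion matrices and
#'   macro F), `pooled` (summed [confusion_matrix()]), `per_class`
#'   (pooled F-score table) and `macro_f`.
#' @export
loso_evaluate <- function(data, kind = c("inertial", "skeleton", "emotion")) {
  kind <- match.arg(kind)
  label_col <- if (kind == "emotion") "emotion" else "activity"
  labels <- switch(kind, inertial = activity_labels(),
                   skeleton = indoor_activity_labels(),
                   emotion = emotion_labels())
  subjects <- unique(data$subject)
  if (length(subjects) < 2) stop("LOSO needs at least two subjects")
  missing_cls <- setdiff(labels, unique(data[[label_col]]))
  if (length(missing_cls) > 0) {
    stop("class(es) absent from the dataset: ",
         paste(missing_cls, collapse = ", "))
  }
  fit_fun <- switch(kind,
    inertial = function(d) fit_knn(d, label = label_col),
    skeleton = function(d) fit_activity_tree(d, label = label_col),
    emotion = function(d) fit_emotion_svm(d, label = label_col))
  folds <- purrr::map(subjects, function(sub) {
    train <- dplyr::filter(data, .data$subject != sub) |>
      dplyr::select(-"subject")
    test <- dplyr::filter(data, .data$subject == sub) |>
      dplyr::select(-"subject")
    model <- fit_fun(train)
    pred <- predict(model, test)$.pred
    confusion_matrix(test[[label_col]], pred, labels)
  })
  pooled <- sum_confusion(folds)
  list(
    folds = tibble::tibble(subject = subjects, cm = folds,
                           macro_f = purrr::map_dbl(folds, macro_f)),
    pooled = pooled,
    per_class = f_score(pooled),
    macro_f = macro_f(pooled)
  )
}

#' Train all recognizers on a synthetic corpus
#'
#' @param training Corpus list from [gen_training_data()].
#' @return Named list of fitted models, keyed by the recognizer ids used in
#'   fusion (`inertial_knn`, `skeleton_tree`, `emotion_svm`).
#' @export
train_recognizers <- function(training) {
  list(
    inertial_knn = fit_knn(dplyr::select(training$inertial, -"subject")),
    skeleton_tree = fit_activity_tree(dplyr::select(training$skeleton,
                                                    -"subject")),
    emotion_svm = fit_emotion_svm(dplyr::select(training$emotion, -"subject"))
  )
}

# run one recognizer over one ready window; NULL when it abstains
recognize_window <- function(recognizer_id, window, models, map) {
  switch(recognizer_id,
    inertial_knn = {
      feats <- inertial_features(window$samples)
      predict(models$inertial_knn, feats)$.pred
    },
    skeleton_tree = {
      frames <- tibble::as_tibble(window$samples)
      feats <- skeleton_features(frames)
      predict(models$skeleton_tree, feats)$.pred
    },
    emotion_svm = {
      x <- window$samples[, 1]
      mask <- vad_mask(x, window$rate)
      if (!any(mask)) return(NULL)
      feats <- audio_features(x, window$rate)
      predict(models$emotion_svm, feats)$.pred
    },
    location_geo = {
      fix <- tibble::tibble(t = window$t_start,
                            lat = window$samples[1, 1],
                            lon = window$samples[1, 2])
      lab <- resolve_place(fix, map)$label
      if (lab == "Unknown") NULL else lab
    },
    stop("no recognizer bound to id: ", recognizer_id)
  )
}

replay_registry <- function() {
  reg <- recognizer_registry()
  register_recognizer(reg, "inertial_knn", "inertial", 3, 3)
  register_recognizer(reg, "skeleton_tree", "skeleton", 3, 1.5)
  register_recognizer(reg, "emotion_svm", "audio", 3, 3)
  register_recognizer(reg, "location_geo", "gps", 1, 1)
  reg
}

recognizer_category <- function(recognizer_id) {
  c(inertial_knn = "activity", skeleton_tree = "activity",
    emotion_svm = "emotion", location_geo = "location")[[recognizer_id]]
}

#' Replay a scenario through the full pipeline
#'
#' Drives a scenario's packet stream end to end: router, per-recognizer
#' window buffers, trained recognizers, vertical and horizontal decision
#' fusion every `slot` seconds, change-only low-level notification, and the
#' high-level context engine. A location stream silent for more than
#' `gps_dropout_s` seconds finalizes the open location context.
#'
#' @param scenario Output of [gen_scenario()].
#' @param models Trained recognizers from [train_recognizers()].
#' @param map The user's [personal_map()].
#' @param defs High-level definition table.
#' @param weights Activity fusion weights (single-recognizer categories are
#'   fused as the identity).
#' @param slot Fusion slot, seconds.
#' @param gps_dropout_s Location finalization threshold, seconds.
#' @return A list with `decisions`, `fused`, `llc_events`, `hlc_events`,
#'   `hlc_timeline` and the final `store`.
#' @export
replay_scenario <- function(scenario, models, map,
                            defs = hlc_definitions(),
                            weights = activity_fusion_weights(), slot = 3,
                            gps_dropout_s = 5) {
  registry <- replay_registry()
  buffers <- new.env(parent = emptyenv())
  decisions <- list()
  for (packet in scenario$packets) {
    for (rid in route_packet(registry, packet)) {
      key <- paste(packet$user_id, rid, sep = "|")
      if (is.null(buffers[[key]])) {
        spec <- registry$specs[registry$specs$recognizer_id == rid, ]
        buffers[[key]] <- stream_buffer(spec$min_window, spec$hop)
      }
      for (window in push_and_emit(buffers[[key]], packet)) {
        label <- recognize_window(rid, window, models, map)
        if (!is.null(label)) {
          decisions[[length(decisions) + 1L]] <- tibble::tibble(
            recognizer_id = rid, user_id = packet$user_id,
            category = recognizer_category(rid), label = label,
            t = window$t_start)
        }
      }
    }
  }
  decisions <- dplyr::bind_rows(decisions)
  fusion <- fuse_decisions(decisions, weights = weights, slot = slot)
  events <- fusion$events
  # GPS dropout: finalize the location context when fixes cease for too long
  loc <- dplyr::filter(fusion$fused, .data$category == "location")
  finals <- list()
  for (uid in unique(loc$user_id)) {
    tt <- sort(loc$t[loc$user_id == uid])
    gaps <- which(diff(tt) > gps_dropout_s)
    for (g in gaps) {
      finals[[length(finals) + 1L]] <- tibble::tibble(
        user_id = uid, category = "location", label = NA_character_,
        t = tt[g] + slot, kind = "final")
    }
  }
  events <- dplyr::arrange(dplyr::bind_rows(events, finals), .data$t)
  hlca <- run_hlca(events, defs = defs)
  list(decisions = decisions, fused = fusion$fused, llc_events = events,
       hlc_events = hlca$hlc_events, hlc_timeline = hlca$hlc_timeline,
       store = hlca$store)
}

# ground-truth label of a category at an instant, NA when none scripted
truth_at <- function(truth, category, t) {
  hit <- truth$category == category &
    interval_contains(truth$t_start, truth$t_end, t)
  if (!any(hit)) NA_character_ else truth$label[hit][1]
}

#' Score a replay against the scenario ground truth
#'
#' Aligns predicted and actual context timelines at fusion-slot resolution.
#' Low-level predictions are the fused per-slot labels, carried forward
#' while no new fusion output arrives (contexts persist between change
#' notifications); the high-level prediction at a slot is the class of the
#' persisted high-level context containing the slot start. Slots whose
#' interior overlaps a script step boundary are marked as transitions and
#' excluded from the confusion matrices and F-scores, since no
#' transition/null-class rejection is modelled.
#'
#' @param replay Output of [replay_scenario()].
#' @param scenario The scenario that produced it.
#' @param defs Definition table used to derive the ground-truth high-level
#'   class of each slot's scripted composition.
#' @param slot Scoring slot, seconds (the fusion slot).
#' @return A list with `slots` (the aligned comparison tibble), `f_scores`
#'   (per category and class), `accuracy` (per-category slot accuracy) and
#'   `hlc_accuracy`.
#' @export
score_replay <- function(replay, scenario, defs = hlc_definitions(), slot = 3) {
  total <- sum(scenario$script$duration)
  bounds <- cumsum(scenario$script$duration)
  bounds <- bounds[-length(bounds)]
  slot_t <- seq(0, total - slot, by = slot)
  transition <- purrr::map_lgl(slot_t, function(t) {
    any(bounds > t & bounds < t + slot)
  })
  user <- scenario$packets[[1]]$user_id
  truth <- scenario$truth

  # predicted LLC label per slot: fused output, carried forward
  fused <- replay$fused
  pred_cat <- function(category, t) {
    rows <- fused[fused$category == category & fused$user_id == user &
                    fused$t <= t, ]
    if (nrow(rows) == 0) NA_character_ else rows$label[which.max(rows$t)]
  }
  truth_hlc_at <- function(t) {
    cons <- purrr::compact(purrr::map(context_categories(), function(cat) {
      lab <- truth_at(truth, cat, t)
      if (is.na(lab)) NULL else low_level_context(user, cat, lab, 0)
    }))
    if (length(cons) == 0) return(NA_character_)
    classify_hlc(high_level_context(user, dplyr::bind_rows(cons), 0), defs)
  }
  hlc_tl <- replay$hlc_timeline
  pred_hlc_at <- function(t) {
    hit <- which(interval_contains(hlc_tl$t_start, hlc_tl$t_end, t))
    if (length(hit) == 0) NA_character_ else
      hlc_tl$hlc_class[hit[length(hit)]]
  }
  slots <- purrr::map_dfr(seq_along(slot_t), function(i) {
    t <- slot_t[i]
    mid <- t + slot / 2
    dplyr::bind_rows(
      purrr::map_dfr(context_categories(), function(cat) {
        tibble::tibble(slot_t = t, category = cat,
                       truth = truth_at(truth, cat, mid),
                       pred = pred_cat(cat, t),
                       transition = transition[i])
      }),
      tibble::tibble(slot_t = t, category = "hlc",
                     truth = truth_hlc_at(mid), pred = pred_hlc_at(t),
                     transition = transition[i])
    )
  })
  scored <- dplyr::filter(slots, !.data$transition, !is.na(.data$truth))
  per_cat <- scored |>
    dplyr::group_by(.data$category) |>
    dplyr::summarise(
      n_slots = dplyr::n(),
      accuracy = mean(.data$pred == .data$truth, na.rm = FALSE),
      .groups = "drop"
    )
  fsc <- scored |>
    dplyr::group_by(.data$category) |>
    dplyr::group_modify(function(d, g) {
      labs <- sort(unique(c(d$truth, d$pred[!is.na(d$pred)])))
      f_score(confusion_matrix(d$truth, ifelse(is.na(d$pred), "none", d$pred),
                               union(labs, "none")))
    }) |>
    dplyr::ungroup()
  list(slots = slots, f_scores = fsc, accuracy = per_cat,
       hlc_accuracy = per_cat$accuracy[per_cat$category == "hlc"])
}

#' Timeline plot of actual versus predicted contexts
#'
#' @param slots The `slots` tibble from [score_replay()].
#' @return A ggplot object showing actual and predicted label tracks per
#'   category over time.
#' @export
plot_timeline <- function(slots) {
  df <- tidyr::pivot_longer(slots, c("truth", "pred"), names_to = "track",
                            values_to = "label")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$slot_t, y = .data$track,
                                   fill = .data$label)) +
    ggplot2::geom_tile() +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$category)) +
    ggplot2::labs(x = "time (s)", y = NULL) +
    ggplot2::theme_minimal()
}
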