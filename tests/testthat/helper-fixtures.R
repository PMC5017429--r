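# memoised heavy fixtures shared across test files
.fixtures <- new.env(parent = emptyenv())

# the 10-subject synthetic benchmark corpus used by the recognizer and
# end-to-end tests (fixed seed; per-subject signature offsets make the
# LOSO folds non-trivial)
benchmark_corpus <- function() {
  if (is.null(.fixtures$corpus)) {
    .fixtures$corpus <- gen_training_data(n_subjects = 10, seed = 42,
                                          inertial_s = 60, skeleton_s = 60,
                                          audio_s = 30)
  }
  .fixtures$corpus
}

benchmark_models <- function() {
  if (is.null(.fixtures$models)) {
    .fixtures$models <- train_recognizers(benchmark_corpus())
  }
  .fixtures$models
}

# tiny labelled 2-D training sets for k-NN oracle comparisons
random_knn_case <- function(n, n_classes = 3, d = 3) {
  x <- matrix(rnorm(n * d), n, d, dimnames = list(NULL, paste0("f", 1:d)))
  y <- sample(activity_labels()[seq_len(n_classes)], n, replace = TRUE)
  list(x = x, y = y)
}

# independent exhaustive k-NN oracle: plain loops, same standardization and
# tie contract as the documented model behaviour, no shared code
oracle_knn <- function(x, y, k, query) {
  ctr <- colMeans(x)
  scl <- apply(x, 2, sd)
  scl[scl == 0] <- 1
  xs <- t((t(x) - ctr) / scl)
  qs <- (query - ctr) / scl
  d <- numeric(nrow(xs))
  for (i in seq_len(nrow(xs))) d[i] <- sqrt(sum((xs[i, ] - qs)^2))
  ord <- order(d, method = "radix")[seq_len(k)]
  votes <- table(y[ord])
  top <- names(votes)[votes == max(votes)]
  if (length(top) == 1) return(top)
  best <- Inf; win <- NULL
  for (lb in sort(top)) {
    dist_lb <- min(d[ord][y[ord] == lb])
    if (dist_lb < best - 1e-12) { best <- dist_lb; win <- lb }
  }
  win
}

# brute-force high-level definition matcher used against classify_hlc
oracle_classify <- function(activity, location, emotion, defs) {
  defs <- defs[order(defs$priority), ]
  ok_slot <- function(allowed, value) {
    if (length(allowed) == 1 && identical(allowed, "ANY")) return(TRUE)
    !is.na(value) && value %in% allowed
  }
  for (i in seq_len(nrow(defs))) {
    if (!is.na(activity) && activity %in% defs$activities[[i]] &&
        ok_slot(defs$locations[[i]], location) &&
        ok_slot(defs$emotions[[i]], emotion)) {
      return(defs$hlc_class[[i]])
    }
  }
  "Unclassified"
}

compose_hlc <- function(activity, location = NA, emotion = NA, t = 100) {
  cons <- list(low_level_context("u1", "activity", activity, t - 10))
  if (!is.na(location)) {
    cons <- c(cons, list(low_level_context("u1", "location", location, t - 10)))
  }
  if (!is.na(emotion)) {
    cons <- c(cons, list(low_level_context("u1", "emotion", emotion, t - 10)))
  }
  high_level_context("u1", dplyr::bind_rows(cons), t)
}
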