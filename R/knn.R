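#' Fit a k-nearest-neighbour activity model
#'
#' Stores the training windows after z-score standardization (per-feature
#' training mean and standard deviation) and classifies queries by majority
#' vote among the `k` nearest neighbours under Euclidean distance. `k`
#' defaults to 3. Vote ties are broken by the nearest single neighbour:
#' among tied labels the one whose closest voting neighbour is nearest wins
#' (lexicographic label order as the final fallback). `NA` features
#' (e.g. an absent device) are imputed with training means.
#'
#' @param data Data frame of numeric features plus one label column.
#' @param label Name of the label column (default `"activity"`).
#' @param k Number of neighbours.
#' @param labels Legal label set; defaults to the eight activities.
#' @return An object of class `knn_model` with `predict()`, [tidy()] and
#'   [glance()] methods.
#' @export
fit_knn <- function(data, label = "activity", k = 3,
                    labels = activity_labels()) {
  stopifnot(is.data.frame(data), label %in% names(data))
  y <- as.character(data[[label]])
  bad <- setdiff(y, labels)
  if (length(bad) > 0) stop("unknown label(s): ", paste(bad, collapse = ", "))
  x <- as.matrix(dplyr::select(data, -dplyr::all_of(label)))
  storage.mode(x) <- "double"
  if (k < 1) stop("k must be at least 1")
  if (k > nrow(x)) stop("k exceeds the number of training rows")
  center <- colMeans(x, na.rm = TRUE)
  center[is.nan(center)] <- 0
  for (j in seq_len(ncol(x))) x[is.na(x[, j]), j] <- center[[j]]
  scale <- apply(x, 2, sd)
  scale[scale == 0 | is.na(scale)] <- 1
  xs <- sweep(sweep(x, 2, center), 2, scale, "/")
  structure(
    list(x = xs, y = y, k = as.integer(k), center = center, scale = scale,
         features = colnames(x), label = label, labels = labels,
         distance = "euclidean"),
    class = "knn_model"
  )
}

standardize_query <- function(model, newdata) {
  if (is.data.frame(newdata)) {
    if (model$label %in% names(newdata)) {
      newdata <- dplyr::select(newdata, -dplyr::all_of(model$label))
    }
    newdata <- as.matrix(newdata[, model$features, drop = FALSE])
  } else {
    newdata <- as.matrix(newdata)
    if (!is.null(colnames(newdata))) {
      newdata <- newdata[, model$features, drop = FALSE]
    }
  }
  if (ncol(newdata) != length(model$features)) {
    stop("query has ", ncol(newdata), " features; model expects ",
         length(model$features))
  }
  storage.mode(newdata) <- "double"
  xs <- sweep(sweep(newdata, 2, model$center), 2, model$scale, "/")
  xs[is.na(xs)] <- 0  # mean imputation in standardized space
  xs
}

#' Predict activities with a fitted k-NN model
#'
#' @param object A `knn_model` from [fit_knn()].
#' @param newdata Data frame or matrix of query feature rows.
#' @param ... Unused.
#' @return A tibble with one row per query: `.pred` (winning label) and
#'   `votes` (named integer vector of neighbour votes, as a list-column).
#' @export
predict.knn_model <- function(object, newdata, ...) {
  xq <- standardize_query(object, newdata)
  xt <- object$x
  # full distance matrix: queries x training rows
  d2 <- outer(rowSums(xq^2), rowSums(xt^2), "+") - 2 * tcrossprod(xq, xt)
  d2[d2 < 0] <- 0
  preds <- character(nrow(xq))
  votes <- vector("list", nrow(xq))
  for (i in seq_len(nrow(xq))) {
    ord <- order(d2[i, ], method = "radix")[seq_len(object$k)]
    nb_labels <- object$y[ord]
    counts <- sort(table(nb_labels), decreasing = TRUE)
    top <- names(counts)[counts == max(counts)]
    if (length(top) == 1) {
      win <- top
    } else {
      # nearest single neighbour among the tied labels decides
      nearest_of <- vapply(top, function(lb) min(d2[i, ord[nb_labels == lb]]),
                           numeric(1))
      win <- sort(top[nearest_of == min(nearest_of)])[1]
    }
    preds[i] <- win
    votes[[i]] <- setNames(as.integer(counts), names(counts))
  }
  tibble::tibble(.pred = preds, votes = votes)
}

#' @method tidy knn_model
#' @export
tidy.knn_model <- function(x, ...) {
  tbl <- table(factor(x$y, levels = x$labels))
  tibble::tibble(label = names(tbl), n_train = as.integer(tbl))
}

#' @method glance knn_model
#' @export
glance.knn_model <- function(x, ...) {
  tibble::tibble(n_train = nrow(x$x), n_features = ncol(x$x), k = x$k,
                 distance = x$distance)
}

#' @export
print.knn_model <- function(x, ...) {
  cat(sprintf("k-NN activity model: k=%d, %d reference rows, %d features\n",
              x$k, nrow(x$x), ncol(x$x)))
  invisible(x)
}
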