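#' Skeleton joint vocabulary and default joint pairs
#'
#' The 20-joint depth-camera skeleton used throughout the package, and the
#' default joint-pair list for feature extraction: the 19 bone edges of the
#' skeleton hierarchy plus six cross-limb pairs (hand-hand, hand-head x2,
#' foot-foot, hand-hip x2). An all-pairs list over 20 joints would be
#' quadratic (190 pairs) with little added information; the pair list is an
#' argument everywhere, so alternatives can be supplied.
#'
#' @return `skeleton_joint_names()`: character vector of 20 joint names.
#'   `skeleton_pairs()`: tibble with columns `from`, `to`.
#' @export
skeleton_joint_names <- function() {
  c("head", "shoulder_center", "spine", "hip_center",
    "shoulder_l", "elbow_l", "wrist_l", "hand_l",
    "shoulder_r", "elbow_r", "wrist_r", "hand_r",
    "hip_l", "knee_l", "ankle_l", "foot_l",
    "hip_r", "knee_r", "ankle_r", "foot_r")
}

#' @rdname skeleton_joint_names
#' @export
skeleton_pairs <- function() {
  bones <- matrix(c(
    "head", "shoulder_center",
    "shoulder_center", "spine",
    "spine", "hip_center",
    "shoulder_center", "shoulder_l",
    "shoulder_l", "elbow_l",
    "elbow_l", "wrist_l",
    "wrist_l", "hand_l",
    "shoulder_center", "shoulder_r",
    "shoulder_r", "elbow_r",
    "elbow_r", "wrist_r",
    "wrist_r", "hand_r",
    "hip_center", "hip_l",
    "hip_l", "knee_l",
    "knee_l", "ankle_l",
    "ankle_l", "foot_l",
    "hip_center", "hip_r",
    "hip_r", "knee_r",
    "knee_r", "ankle_r",
    "ankle_r", "foot_r"), ncol = 2, byrow = TRUE)
  cross <- matrix(c(
    "hand_l", "hand_r",
    "hand_l", "head",
    "hand_r", "head",
    "foot_l", "foot_r",
    "hand_l", "hip_l",
    "hand_r", "hip_r"), ncol = 2, byrow = TRUE)
  m <- rbind(bones, cross)
  tibble::tibble(from = m[, 1], to = m[, 2])
}

coord_cols <- function(joint) paste(joint, c("x", "y", "z"), sep = "_")

#' Per-frame spatial skeleton features
#'
#' For each configured joint pair, the Euclidean distance between the two
#' joints and the elevation angle of the joint-joint vector against the
#' horizontal plane of the camera frame (y up):
#' `atan2(dy, sqrt(dx^2 + dz^2))`, in `[-pi/2, pi/2]`. Coincident joints
#' give distance 0 and angle 0.
#'
#' @param frame A data frame of one or more skeleton frames with coordinate
#'   columns `<joint>_x`, `<joint>_y`, `<joint>_z` (metres, camera frame).
#' @param pairs Joint-pair tibble as from [skeleton_pairs()].
#' @return A tibble with one row per frame x pair: `frame`, `from`, `to`,
#'   `distance`, `angle`.
#' @export
skeleton_spatial_features <- function(frame, pairs = skeleton_pairs()) {
  if (nrow(pairs) == 0) stop("pairs list is empty")
  frame <- tibble::as_tibble(frame)
  purrr::pmap_dfr(pairs, function(from, to) {
    d <- as.matrix(frame[, coord_cols(to)]) - as.matrix(frame[, coord_cols(from)])
    dist <- unname(sqrt(rowSums(d^2)))
    horiz <- sqrt(d[, 1]^2 + d[, 3]^2)
    angle <- unname(atan2(d[, 2], horiz))
    angle[dist == 0] <- 0
    tibble::tibble(frame = seq_len(nrow(frame)), from = from, to = to,
                   distance = dist, angle = angle)
  })
}

#' Temporal skeleton window features
#'
#' Mean and standard deviation (population convention, so a single-frame
#' window yields sd 0) over the window's frames of each pair's distance and
#' angle, flattened into one feature row per window.
#'
#' @param frames Data frame of the window's frames (coordinate columns as in
#'   [skeleton_spatial_features()]).
#' @param pairs Joint-pair tibble.
#' @return A one-row tibble with `4 * nrow(pairs)` features named
#'   `<from>.<to>_{dist,angle}_{mean,sd}`.
#' @export
skeleton_features <- function(frames, pairs = skeleton_pairs()) {
  if (nrow(pairs) == 0) stop("pairs list is empty")
  if (nrow(frames) == 0) stop("window contains no frames")
  sp <- skeleton_spatial_features(frames, pairs)
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  agg <- sp |>
    dplyr::group_by(.data$from, .data$to) |>
    dplyr::summarise(
      dist_mean = mean(.data$distance), dist_sd = pop_sd(.data$distance),
      angle_mean = mean(.data$angle), angle_sd = pop_sd(.data$angle),
      .groups = "drop"
    )
  # restore the configured pair order
  agg <- dplyr::left_join(pairs, agg, by = c("from", "to"))
  long <- tidyr::pivot_longer(agg, cols = c("dist_mean", "dist_sd",
                                            "angle_mean", "angle_sd"))
  vals <- setNames(long$value, paste0(long$from, ".", long$to, "_", long$name))
  tibble::as_tibble(as.list(vals))
}

#' Fit a decision-tree model for indoor activities
#'
#' Classifies skeleton windows into the six indoor activities (all but
#' Walking and Running, which leave the camera's field of view) with a CART
#' decision tree (Gini impurity, minimum leaf size 2, no depth limit).
#' Training sets containing Walking or Running labels are rejected.
#'
#' @param data Data frame of window features plus one label column.
#' @param label Name of the label column.
#' @return An object of class `activity_tree`.
#' @export
fit_activity_tree <- function(data, label = "activity") {
  stopifnot(is.data.frame(data), label %in% names(data))
  y <- as.character(data[[label]])
  bad <- setdiff(y, indoor_activity_labels())
  if (length(bad) > 0) {
    stop("labels outside the indoor activity set: ", paste(bad, collapse = ", "))
  }
  if (length(unique(y)) == 1) {
    # degenerate single-class training: constant classifier
    return(structure(list(fit = NULL, constant = y[1], n_train = length(y),
                          label = label, labels = indoor_activity_labels()),
                     class = "activity_tree"))
  }
  df <- data
  df[[label]] <- factor(y, levels = indoor_activity_labels())
  fml <- stats::as.formula(paste(label, "~ ."))
  fit <- rpart::rpart(
    fml, data = df, method = "class",
    control = rpart::rpart.control(minsplit = 4, minbucket = 2, cp = 1e-4,
                                   xval = 0, maxdepth = 30),
    parms = list(split = "gini")
  )
  structure(list(fit = fit, label = label, labels = indoor_activity_labels()),
            class = "activity_tree")
}

#' @export
predict.activity_tree <- function(object, newdata, ...) {
  if (object$label %in% names(newdata)) {
    newdata <- dplyr::select(newdata, -dplyr::all_of(object$label))
  }
  if (!is.null(object$constant)) {
    return(tibble::tibble(.pred = rep(object$constant, nrow(newdata))))
  }
  p <- predict(object$fit, newdata = newdata, type = "class")
  tibble::tibble(.pred = as.character(p))
}

#' @method tidy activity_tree
#' @export
tidy.activity_tree <- function(x, ...) {
  imp <- if (is.null(x$fit)) NULL else x$fit$variable.importance
  if (is.null(imp)) return(tibble::tibble(feature = character(),
                                          importance = numeric()))
  tibble::tibble(feature = names(imp), importance = unname(imp))
}

#' @method glance activity_tree
#' @export
glance.activity_tree <- function(x, ...) {
  if (is.null(x$fit)) {
    return(tibble::tibble(n_train = x$n_train, n_leaves = 1L, n_splits = 0L))
  }
  frame <- x$fit$frame
  tibble::tibble(n_train = frame$n[1], n_leaves = sum(frame$var == "<leaf>"),
                 n_splits = sum(frame$var != "<leaf>"))
}

#' @export
print.activity_tree <- function(x, ...) {
  cat("Indoor-activity decision tree\n")
  print(x$fit)
  invisible(x)
}
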