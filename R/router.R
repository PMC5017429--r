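#' Sensory data packets
#'
#' The router's unit of work: a block of contiguous samples from one
#' modality of one user, plus the metadata needed to route and window it.
#'
#' @param user_id Character user identifier.
#' @param modality One of `"inertial"`, `"skeleton"`, `"audio"`, `"gps"`.
#' @param t_start Time of the first sample, seconds.
#' @param rate Sampling rate in Hz.
#' @param samples Numeric matrix, `n_samples x n_channels`; column names are
#'   the channel names. A plain vector is treated as one channel.
#' @return An object of class `sensory_packet`.
#' @export
sensory_packet <- function(user_id, modality, t_start, rate, samples) {
  modality <- match.arg(modality, c("inertial", "skeleton", "audio", "gps"))
  if (is.null(dim(samples))) samples <- matrix(samples, ncol = 1)
  samples <- as.matrix(samples)
  if (nrow(samples) < 1) stop("packet must contain at least one sample")
  if (rate <= 0) stop("sampling_rate must be positive")
  expected <- switch(modality, inertial = NULL, gps = 2, audio = 1, skeleton = NULL)
  if (!is.null(expected) && ncol(samples) != expected) {
    stop(modality, " packets must have ", expected, " channel(s)")
  }
  if (modality == "inertial" && ncol(samples) %% 6 != 0) {
    stop("inertial packets need 6 channels per device (3-axis accel + gyro)")
  }
  if (modality == "skeleton" && ncol(samples) %% 3 != 0) {
    stop("skeleton packets need 3 coordinate channels per joint")
  }
  structure(
    list(user_id = as.character(user_id), modality = modality,
         t_start = as.numeric(t_start), rate = as.numeric(rate),
         samples = samples),
    class = "sensory_packet"
  )
}

#' @export
print.sensory_packet <- function(x, ...) {
  cat(sprintf("<sensory_packet> %s/%s: %d x %d @ %g Hz, t_start=%.3f\n",
              x$user_id, x$modality, nrow(x$samples), ncol(x$samples),
              x$rate, x$t_start))
  invisible(x)
}

#' Recognizer registry and packet routing
#'
#' The router keeps a registry of subscribed recognizers and cross-matches
#' each incoming packet's modality against their accepted modalities;
#' packets are broadcast, so one packet may feed several recognizers, and
#' packets matching no subscription are dropped (with a message at the
#' `"debug"` log level).
#'
#' @return `recognizer_registry()` returns an empty registry.
#' @examples
#' reg <- recognizer_registry()
#' register_recognizer(reg, "inertial_knn", "inertial", min_window = 3, hop = 3)
#' register_recognizer(reg, "skeleton_tree", "skeleton", min_window = 3, hop = 1.5)
#' @export
recognizer_registry <- function() {
  env <- new.env(parent = emptyenv())
  env$specs <- tibble::tibble(
    recognizer_id = character(), modalities = list(),
    min_window = numeric(), hop = numeric()
  )
  structure(env, class = "recognizer_registry")
}

#' @rdname recognizer_registry
#' @param registry A [recognizer_registry()].
#' @param recognizer_id Unique recognizer identifier.
#' @param modalities Character vector of accepted modalities.
#' @param min_window Minimum window the recognizer needs, seconds.
#' @param hop Window advance, seconds; `0 < hop <= min_window`
#'   (`hop == min_window` gives non-overlapping windows, `min_window / 2`
#'   gives 50% overlap).
#' @export
register_recognizer <- function(registry, recognizer_id, modalities,
                                min_window, hop = min_window) {
  stopifnot(inherits(registry, "recognizer_registry"))
  if (min_window <= 0) stop("min_window must be positive")
  if (hop <= 0 || hop > min_window) stop("hop must satisfy 0 < hop <= min_window")
  if (recognizer_id %in% registry$specs$recognizer_id) {
    stop("recognizer_id already registered: ", recognizer_id)
  }
  registry$specs <- dplyr::bind_rows(
    registry$specs,
    tibble::tibble(recognizer_id = recognizer_id, modalities = list(modalities),
                   min_window = min_window, hop = hop)
  )
  invisible(recognizer_id)
}

#' @rdname recognizer_registry
#' @param packet A [sensory_packet()].
#' @return `route_packet()` returns the character vector of recognizer ids
#'   whose accepted modalities contain the packet's modality (possibly empty).
#' @export
route_packet <- function(registry, packet) {
  stopifnot(inherits(registry, "recognizer_registry"),
            inherits(packet, "sensory_packet"))
  if (nrow(registry$specs) == 0) stop("registry is empty")
  hit <- purrr::map_lgl(registry$specs$modalities, ~ packet$modality %in% .x)
  ids <- registry$specs$recognizer_id[hit]
  if (length(ids) == 0) {
    cm_log("debug", "dropping unmatched %s packet from %s",
           packet$modality, packet$user_id)
  }
  ids
}

#' Per-stream window buffer
#'
#' Caches incoming samples of one (user, recognizer) stream until the
#' recognizer's minimum window is available, then emits contiguous windows
#' of exactly `min_window` seconds advancing by `hop` seconds. Samples older
#' than the next window start are evicted; a partial trailing window is
#' retained for the next push. Out-of-order packets are rejected.
#'
#' @param min_window Window length, seconds.
#' @param hop Window advance, seconds.
#' @return A `stream_buffer` object.
#' @examples
#' buf <- stream_buffer(3, 3)
#' pkt <- sensory_packet("u1", "audio", 0, 50, sin(seq_len(30 * 50)))
#' wins <- push_and_emit(buf, pkt)
#' length(wins)   # 10 windows of 150 samples
#' @export
stream_buffer <- function(min_window, hop = min_window) {
  if (min_window <= 0) stop("min_window must be positive")
  if (hop <= 0 || hop > min_window) stop("hop must satisfy 0 < hop <= min_window")
  env <- new.env(parent = emptyenv())
  env$min_window <- min_window
  env$hop <- hop
  env$rate <- NULL
  env$data <- NULL          # retained samples (matrix)
  env$t0 <- NULL            # time of data[1, ]
  env$next_t <- NULL        # expected time of the next incoming sample
  env$meta <- NULL          # user_id / modality, fixed by the first packet
  structure(env, class = "stream_buffer")
}

#' @rdname stream_buffer
#' @param buffer A [stream_buffer()].
#' @param packet A [sensory_packet()] whose samples follow the buffer's last
#'   timestamp.
#' @return `push_and_emit()` returns a (possibly empty) list of
#'   `sensor_window` objects, each holding exactly `round(min_window * rate)`
#'   samples and its own `t_start`.
#' @export
push_and_emit <- function(buffer, packet) {
  stopifnot(inherits(buffer, "stream_buffer"),
            inherits(packet, "sensory_packet"))
  if (is.null(buffer$rate)) {
    buffer$rate <- packet$rate
    buffer$meta <- list(user_id = packet$user_id, modality = packet$modality)
    buffer$data <- packet$samples[0, , drop = FALSE]
    buffer$t0 <- packet$t_start
    buffer$next_t <- packet$t_start
  }
  if (abs(packet$rate - buffer$rate) > 1e-9) {
    stop("packet rate differs from the stream's rate")
  }
  # in-order check with half-a-sample tolerance
  if (packet$t_start < buffer$next_t - 0.5 / buffer$rate) {
    stop("out-of-order packet: t_start ", packet$t_start,
         " precedes buffer tail ", buffer$next_t)
  }
  buffer$data <- rbind(buffer$data, packet$samples)
  buffer$next_t <- packet$t_start + nrow(packet$samples) / buffer$rate

  win_n <- round(buffer$min_window * buffer$rate)
  hop_n <- max(1L, round(buffer$hop * buffer$rate))
  windows <- list()
  while (nrow(buffer$data) >= win_n) {
    idx <- seq_len(win_n)
    windows[[length(windows) + 1L]] <- structure(
      list(user_id = buffer$meta$user_id, modality = buffer$meta$modality,
           t_start = buffer$t0, rate = buffer$rate,
           samples = buffer$data[idx, , drop = FALSE]),
      class = "sensor_window"
    )
    keep <- if (hop_n >= nrow(buffer$data)) integer(0) else
      seq.int(hop_n + 1L, nrow(buffer$data))
    buffer$data <- buffer$data[keep, , drop = FALSE]
    buffer$t0 <- buffer$t0 + hop_n / buffer$rate
  }
  windows
}

# minimal logging with a package-level threshold
cm_log_level <- new.env(parent = emptyenv())
cm_log_level$threshold <- "info"

#' Set the package log level
#'
#' @param level One of `"debug"`, `"info"`, `"warn"`, `"silent"`.
#' @return The previous level, invisibly.
#' @export
set_log_level <- function(level = c("info", "debug", "warn", "silent")) {
  level <- match.arg(level)
  old <- cm_log_level$threshold
  cm_log_level$threshold <- level
  invisible(old)
}

cm_log <- function(level, fmt, ...) {
  order <- c(debug = 1, info = 2, warn = 3, silent = 4)
  if (order[[level]] >= order[[cm_log_level$threshold]] &&
      cm_log_level$threshold != "silent") {
    message(sprintf("[%s] %s", level, sprintf(fmt, ...)))
  }
  invisible(NULL)
}
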