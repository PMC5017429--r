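#' Minimal mono PCM WAV input/output
#'
#' Reads and writes 16-bit PCM mono RIFF/WAVE files, the interchange format
#' for the audio streams. Samples are scaled to `[-1, 1]`.
#'
#' @param path File path.
#' @return `read_wav()`: a list with `samples` (numeric vector) and `rate`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (riff != "RIFF") stop("not a RIFF file: ", path)
  readBin(con, "integer", 1, 4, endian = "little")  # chunk size
  wave <- readChar(con, 4, useBytes = TRUE)
  if (wave != "WAVE") stop("not a WAVE file: ", path)
  rate <- NULL; bits <- NULL; n_channels <- NULL; samples <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (id == "fmt ") {
      fmt <- readBin(con, "integer", 2, 2, endian = "little", signed = FALSE)
      if (fmt[1] != 1) stop("only PCM WAV is supported")
      n_channels <- fmt[2]
      rate <- readBin(con, "integer", 1, 4, endian = "little")
      readBin(con, "integer", 1, 4, endian = "little")  # byte rate
      readBin(con, "integer", 1, 2, endian = "little")  # block align
      bits <- readBin(con, "integer", 1, 2, endian = "little", signed = FALSE)
      extra <- size - 16
      if (extra > 0) readBin(con, "raw", extra)
    } else if (id == "data") {
      if (is.null(bits)) stop("malformed WAV: data before fmt")
      if (bits != 16) stop("only 16-bit PCM is supported")
      samples <- readBin(con, "integer", size / 2, 2, endian = "little",
                         signed = TRUE)
      break
    } else {
      readBin(con, "raw", size)
    }
  }
  if (is.null(samples)) stop("no data chunk found in ", path)
  if (n_channels != 1) stop("only mono WAV is supported")
  list(samples = samples / 32768, rate = rate)
}

#' @rdname read_wav
#' @param samples Numeric vector in `[-1, 1]` (values are clipped).
#' @param rate Sampling rate, Hz.
#' @return `write_wav()`: the path, invisibly.
#' @export
write_wav <- function(samples, rate, path) {
  pcm <- as.integer(round(pmin(pmax(samples, -1), 1) * 32767))
  con <- file(path, "wb")
  on.exit(close(con))
  data_size <- length(pcm) * 2L
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_size), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4, endian = "little")
  writeBin(1L, con, size = 2, endian = "little")           # PCM
  writeBin(1L, con, size = 2, endian = "little")           # mono
  writeBin(as.integer(rate), con, size = 4, endian = "little")
  writeBin(as.integer(rate * 2L), con, size = 4, endian = "little")
  writeBin(2L, con, size = 2, endian = "little")
  writeBin(16L, con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(data_size, con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

# cut a signal into frames (columns), dropping a trailing partial frame
frame_signal <- function(x, rate, frame_s = 0.025, hop_s = 0.010) {
  n_frame <- round(frame_s * rate)
  n_hop <- max(1L, round(hop_s * rate))
  starts <- seq.int(1L, by = n_hop, length.out = max(0L, (length(x) - n_frame) %/% n_hop + 1L))
  if (length(x) < n_frame) return(matrix(numeric(0), nrow = n_frame, ncol = 0))
  vapply(starts, function(s) x[s:(s + n_frame - 1L)], numeric(n_frame))
}

frame_energy <- function(frames) {
  if (length(frames) == 0) return(numeric(0))
  colMeans(frames^2)
}

#' Energy-threshold voice activity detection
#'
#' Marks 25 ms frames (10 ms hop) as voiced when their mean-square energy
#' exceeds an adaptive threshold: `factor` times the median frame energy,
#' capped at 20 dB below the peak frame energy (so a pause-free utterance
#' is fully voiced) and floored at an absolute silence level (so digital
#' silence is fully unvoiced).
#'
#' @param x Numeric signal.
#' @param rate Sampling rate, Hz.
#' @param factor Multiplier on the median frame energy.
#' @param frame_s,hop_s Frame geometry, seconds.
#' @param floor_energy Absolute silence floor (mean-square units).
#' @return Logical vector, one element per frame; zero-length for a signal
#'   shorter than one frame.
#' @export
vad_mask <- function(x, rate, factor = 1.5, frame_s = 0.025, hop_s = 0.010,
                     floor_energy = 1e-8) {
  if (length(x) == 0) stop("empty signal")
  e <- frame_energy(frame_signal(x, rate, frame_s, hop_s))
  if (length(e) == 0) return(logical(0))
  thr <- max(floor_energy, min(factor * median(e), max(e) * 1e-2))
  e > thr
}

#' Segment a call recording into shuffled 3-s pieces
#'
#' Trims leading and trailing silence (via [vad_mask()]), cuts the interior
#' into non-overlapping segments of `segment_s` seconds (a trailing partial
#' segment is dropped), and permutes the segment order with a seeded RNG.
#' The returned table carries no original-position metadata, so the
#' utterance order cannot be reconstructed downstream -- the point of the
#' privacy-preserving randomization.
#'
#' @inheritParams vad_mask
#' @param seed Integer seed for the permutation.
#' @param segment_s Segment length, seconds.
#' @return A tibble with `segment` (post-shuffle index), `samples`
#'   (list-column of numeric vectors) and `voiced_fraction`; zero rows when
#'   less than one segment of trimmed audio remains.
#' @export
segment_and_shuffle <- function(x, rate, seed, segment_s = 3,
                                factor = 1.5) {
  mask <- vad_mask(x, rate, factor = factor)
  empty <- tibble::tibble(segment = integer(), samples = list(),
                          voiced_fraction = numeric())
  if (!any(mask)) return(empty)
  n_hop <- round(0.010 * rate)
  n_frame <- round(0.025 * rate)
  first <- (which(mask)[1] - 1L) * n_hop + 1L
  last_frame <- dplyr::last(which(mask))
  # a voiced final frame keeps the trailing partial-frame residue
  last <- if (last_frame == length(mask)) length(x) else
    min(length(x), (last_frame - 1L) * n_hop + n_frame)
  xt <- x[first:last]
  seg_n <- round(segment_s * rate)
  n_seg <- length(xt) %/% seg_n
  if (n_seg == 0) return(empty)
  segs <- purrr::map(seq_len(n_seg), function(i) {
    xt[((i - 1L) * seg_n + 1L):(i * seg_n)]
  })
  vf <- purrr::map_dbl(segs, function(s) {
    m <- vad_mask(s, rate, factor = factor)
    if (length(m) == 0) 0 else mean(m)
  })
  perm <- withr::with_seed(seed, sample.int(n_seg))
  tibble::tibble(segment = seq_len(n_seg), samples = segs[perm],
                 voiced_fraction = vf[perm])
}

# triangular mel filterbank, n_mels x (nfft/2 + 1)
mel_filterbank <- function(rate, nfft, n_mels = 26, fmin = 0, fmax = rate / 2) {
  hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
  mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)
  mels <- seq(hz_to_mel(fmin), hz_to_mel(fmax), length.out = n_mels + 2)
  hz <- mel_to_hz(mels)
  bins <- floor((nfft + 1) * hz / rate)
  fb <- matrix(0, n_mels, nfft / 2 + 1)
  for (m in seq_len(n_mels)) {
    lo <- bins[m]; ce <- bins[m + 1]; hi <- bins[m + 2]
    if (ce > lo) {
      k <- lo:ce
      fb[m, k + 1] <- (k - lo) / (ce - lo)
    }
    if (hi > ce) {
      k <- ce:hi
      fb[m, k + 1] <- pmin(fb[m, k + 1] + 0, (hi - k) / (hi - ce))
    }
    fb[m, ce + 1] <- 1
  }
  fb
}

# orthogonal DCT-II matrix, n_out x n_in
dct_matrix <- function(n_out, n_in) {
  m <- outer(0:(n_out - 1), 0:(n_in - 1), function(k, n) {
    cos(pi * k * (2 * n + 1) / (2 * n_in))
  })
  m * sqrt(2 / n_in)
}

# per-frame pitch by autocorrelation peak in [f_lo, f_hi], with parabolic
# interpolation around the winning lag
frame_pitch <- function(frames, rate, f_lo = 60, f_hi = 400) {
  if (ncol(frames) == 0) return(numeric(0))
  n <- nrow(frames)
  nfft <- 2^ceiling(log2(2 * n))
  padded <- rbind(frames, matrix(0, nfft - n, ncol(frames)))
  spec <- mvfft(padded)
  ac <- Re(mvfft(Mod(spec)^2, inverse = TRUE)) / nfft
  lag_lo <- max(2L, floor(rate / f_hi))
  lag_hi <- min(n - 1L, ceiling(rate / f_lo))
  vapply(seq_len(ncol(frames)), function(j) {
    r <- ac[, j]
    if (r[1] <= 0) return(NA_real_)
    seg <- r[(lag_lo:lag_hi) + 1L]
    k <- which.max(seg)
    lag <- lag_lo + k - 1L
    # parabolic refinement on the autocorrelation peak
    if (k > 1 && k < length(seg)) {
      y1 <- seg[k - 1]; y2 <- seg[k]; y3 <- seg[k + 1]
      denom <- y1 - 2 * y2 + y3
      if (abs(denom) > 1e-12) lag <- lag + 0.5 * (y1 - y3) / denom
    }
    rate / lag
  }, numeric(1))
}

#' Audio segment feature vector
#'
#' Frame-level descriptors (25 ms frames, 10 ms hop) over the voiced frames
#' of a segment: log mean-square energy (mean, sd), autocorrelation pitch
#' in the 60--400 Hz band (mean, sd, range), energy functionals (min, max,
#' skewness) and the first 13 MFCCs c0..c12 (mean, sd each) from a 26-band
#' mel filterbank on Hamming-windowed frames. All statistics are computed
#' over voiced frames only, so silence neither dilutes the energy
#' statistics nor contributes spurious pitch estimates.
#'
#' @inheritParams vad_mask
#' @return A one-row tibble of 34 named features.
#' @export
audio_features <- function(x, rate, factor = 1.5) {
  frames <- frame_signal(x, rate)
  mask <- vad_mask(x, rate, factor = factor)
  if (!any(mask)) stop("segment has no voiced frames")
  voiced <- frames[, mask, drop = FALSE]
  e <- frame_energy(voiced)
  loge <- log(e + 1e-12)
  f0 <- frame_pitch(voiced, rate)
  f0 <- f0[is.finite(f0)]
  if (length(f0) == 0) f0 <- NA_real_
  n <- nrow(voiced)
  nfft <- 2^ceiling(log2(n))
  win <- 0.54 - 0.46 * cos(2 * pi * seq(0, n - 1) / (n - 1))
  padded <- rbind(voiced * win, matrix(0, nfft - n, ncol(voiced)))
  pow <- Mod(mvfft(padded))[seq_len(nfft / 2 + 1), , drop = FALSE]^2
  fb <- mel_filterbank(rate, nfft)
  logmel <- log(pmax(fb %*% pow, 1e-12))
  mfcc <- dct_matrix(13, nrow(fb)) %*% logmel    # 13 x n_frames, c0..c12
  sd_or_zero <- function(v) if (length(v) < 2) 0 else sd(v)
  feats <- c(
    loge_mean = mean(loge), loge_sd = sd_or_zero(loge),
    f0_mean = mean(f0), f0_sd = sd_or_zero(f0),
    f0_range = if (all(is.na(f0))) NA_real_ else diff(range(f0)),
    e_min = min(e), e_max = max(e),
    e_skew = if (length(e) < 3 || sd(e) == 0) 0 else e1071::skewness(e),
    setNames(rowMeans(mfcc), paste0("mfcc_c", 0:12, "_mean")),
    setNames(apply(mfcc, 1, sd_or_zero), paste0("mfcc_c", 0:12, "_sd"))
  )
  tibble::as_tibble(as.list(feats))
}

#' Fit an RBF support vector machine for emotion recognition
#'
#' One-vs-one multiclass SVM with a radial-basis kernel on standardized
#' audio features; the default hyper-parameters are `gamma = 0.01` and
#' `cost = 1`, with an optional coarse grid search over both.
#'
#' @param data Data frame of audio features plus one label column.
#' @param label Name of the label column.
#' @param gamma,cost RBF kernel width and soft-margin cost.
#' @param tune If `TRUE`, grid-search `gamma` and `cost` by 5-fold
#'   cross-validation around the defaults.
#' @return An object of class `emotion_svm`.
#' @export
fit_emotion_svm <- function(data, label = "emotion", gamma = 0.01, cost = 1,
                            tune = FALSE) {
  stopifnot(is.data.frame(data), label %in% names(data))
  y <- as.character(data[[label]])
  bad <- setdiff(y, emotion_labels())
  if (length(bad) > 0) stop("unknown emotion label(s): ",
                            paste(bad, collapse = ", "))
  x <- as.matrix(dplyr::select(data, -dplyr::all_of(label)))
  storage.mode(x) <- "double"
  yf <- factor(y, levels = emotion_labels())
  if (length(unique(y)) == 1) {
    # degenerate single-class training: constant classifier
    return(structure(list(fit = NULL, constant = y[1], gamma = gamma,
                          cost = cost, label = label, features = colnames(x)),
                     class = "emotion_svm"))
  }
  if (tune) {
    tuned <- e1071::tune.svm(x, yf, gamma = gamma * c(0.1, 1, 10),
                             cost = cost * c(0.1, 1, 10), kernel = "radial")
    gamma <- tuned$best.parameters$gamma
    cost <- tuned$best.parameters$cost
  }
  fit <- e1071::svm(x, yf, kernel = "radial", gamma = gamma, cost = cost,
                    scale = TRUE)
  structure(list(fit = fit, gamma = gamma, cost = cost, label = label,
                 features = colnames(x)),
            class = "emotion_svm")
}

#' @export
predict.emotion_svm <- function(object, newdata, ...) {
  if (is.data.frame(newdata) && object$label %in% names(newdata)) {
    newdata <- dplyr::select(newdata, -dplyr::all_of(object$label))
  }
  x <- as.matrix(newdata)[, object$features, drop = FALSE]
  if (!is.null(object$constant)) {
    return(tibble::tibble(.pred = rep(object$constant, nrow(x))))
  }
  tibble::tibble(.pred = as.character(predict(object$fit, x)))
}

#' @method tidy emotion_svm
#' @export
tidy.emotion_svm <- function(x, ...) {
  if (is.null(x$fit)) {
    return(tibble::tibble(label = x$constant, n_support = 0L))
  }
  sv <- x$fit$nSV
  tibble::tibble(label = levels(x$fit$fitted), n_support = as.integer(sv))
}

#' @method glance emotion_svm
#' @export
glance.emotion_svm <- function(x, ...) {
  tibble::tibble(gamma = x$gamma, cost = x$cost,
                 n_support = if (is.null(x$fit)) 0L else x$fit$tot.nSV,
                 kernel = "radial")
}

#' @export
print.emotion_svm <- function(x, ...) {
  cat(sprintf("Emotion SVM (RBF): gamma=%g, cost=%g, %d support vectors\n",
              x$gamma, x$cost, if (is.null(x$fit)) 0L else x$fit$tot.nSV))
  invisible(x)
}
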