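#' Zero-crossing rate
#'
#' Counts sign changes of the mean-removed signal, normalized by `n - 1`.
#' A constant channel has ZCR 0.
#'
#' @param x Numeric vector.
#' @return ZCR in `[0, 1]`.
#' @export
zero_crossing_rate <- function(x) {
  n <- length(x)
  if (n < 2) return(0)
  y <- x - mean(x)
  sum(y[-n] * y[-1] < 0) / (n - 1)
}

#' Real cepstrum coefficients
#'
#' First `m` coefficients of the real cepstrum: the inverse Fourier
#' transform of the log magnitude spectrum. The log is floored at `eps`
#' so constant (zero-spectrum) channels stay finite.
#'
#' @param x Numeric vector.
#' @param m Number of leading coefficients to return.
#' @param eps Floor applied to the magnitude spectrum before the log.
#' @return Numeric vector of length `m`.
#' @export
real_cepstrum <- function(x, m, eps = 1e-12) {
  n <- length(x)
  mag <- Mod(fft(x))
  ceps <- Re(fft(log(pmax(mag, eps)), inverse = TRUE)) / n
  ceps[seq_len(min(m, n))]
}

# the nine order/time statistics + m cepstrum coefficients for one channel
channel_features <- function(x, cep_order) {
  qs <- unname(quantile(x, c(0.25, 0.5, 0.75), type = 7))
  c(mean = mean(x), zcr = zero_crossing_rate(x), max = max(x), min = min(x),
    sd = sd(x), q1 = qs[1], q2 = qs[2], q3 = qs[3], range = max(x) - min(x),
    setNames(real_cepstrum(x, cep_order), paste0("cep", seq_len(cep_order))))
}

# device channel layout for a phone + watch inertial stream
inertial_channel_names <- function() {
  as.vector(outer(c("ax", "ay", "az", "gx", "gy", "gz"),
                  c("phone", "watch"),
                  function(s, d) paste(d, s, sep = "_")))
}

triad_magnitude <- function(samples, cols) {
  sqrt(rowSums(samples[, cols, drop = FALSE]^2))
}

#' Inertial window features
#'
#' Per-channel descriptors -- mean, zero-crossing rate, maximum, minimum,
#' standard deviation, the three quartiles (linear interpolation between
#' order statistics), range and the first `cep_order` real-cepstrum
#' coefficients -- over a 3-s window of phone + watch accelerometer and
#' gyroscope data.
#'
#' Phone placement and orientation are arbitrary, so phone features are
#' computed on the rotation-invariant acceleration and rate-of-turn
#' magnitude channels only; the watch sits on a known wrist, so its six raw
#' axes are used alongside its two magnitude channels. With the default
#' `cep_order = 5` this yields `(2 + 8) * 14 = 140` features. A window
#' carrying only one device's channels yields `NA` for the other device's
#' features; [fit_knn()] imputes those with training means.
#'
#' @param samples Numeric matrix (e.g. 150 x 12 for 3 s at 50 Hz), columns
#'   named as in `inertial_channel_names()`, or a `sensor_window`.
#' @param cep_order Number of cepstrum coefficients per channel.
#' @return A one-row tibble of named features.
#' @export
inertial_features <- function(samples, cep_order = 5) {
  if (inherits(samples, "sensor_window")) samples <- samples$samples
  samples <- as.matrix(samples)
  if (is.null(colnames(samples)) && ncol(samples) == 12) {
    colnames(samples) <- inertial_channel_names()
  }
  feats <- list()
  effective <- list()
  for (device in c("phone", "watch")) {
    acc <- paste(device, c("ax", "ay", "az"), sep = "_")
    gyr <- paste(device, c("gx", "gy", "gz"), sep = "_")
    present <- all(c(acc, gyr) %in% colnames(samples))
    if (present) {
      effective[[paste0(device, "_amag")]] <- triad_magnitude(samples, acc)
      effective[[paste0(device, "_gmag")]] <- triad_magnitude(samples, gyr)
      if (device == "watch") {
        for (ch in c(acc, gyr)) effective[[ch]] <- samples[, ch]
      }
    } else {
      effective[[paste0(device, "_amag")]] <- NULL
      cm_log("debug", "device '%s' absent from inertial window; features NA",
             device)
      nch <- if (device == "watch") 8 else 2
      chn <- if (device == "watch") {
        c(paste0(device, c("_amag", "_gmag")), acc, gyr)
      } else {
        paste0(device, c("_amag", "_gmag"))
      }
      for (ch in chn) effective[[ch]] <- NA
    }
  }
  # canonical ordering: phone magnitudes, watch magnitudes, watch raw axes
  order_names <- c("phone_amag", "phone_gmag", "watch_amag", "watch_gmag",
                   paste("watch", c("ax", "ay", "az", "gx", "gy", "gz"),
                         sep = "_"))
  out <- purrr::map(order_names, function(ch) {
    x <- effective[[ch]]
    if (length(x) == 1 && is.na(x)) {
      v <- rep(NA_real_, 9 + cep_order)
      names(v) <- names(channel_features(rep(0, 4), cep_order))
      v
    } else {
      channel_features(x, cep_order)
    }
  })
  names(out) <- order_names
  flat <- unlist(purrr::imap(out, function(v, ch) setNames(v, paste(ch, names(v), sep = "_"))))
  tibble::as_tibble(as.list(flat))
}
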