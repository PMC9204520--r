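# EMG conditioning chain: band-pass, offset correction, rectification,
# moving-average smoothing, and subject-level normalization.

#' Process a raw EMG signal into a linear envelope
#'
#' Zero-phase 4th-order Butterworth band-pass (default 10-300 Hz), mean
#' (offset) subtraction, full-wave rectification, and a centred moving
#' average (default 100 ms window).
#'
#' @param raw raw EMG samples (mV or arbitrary units).
#' @param sampling_rate sampling rate (Hz); must exceed twice the upper
#'   band edge.
#' @param band band-pass edges (Hz).
#' @param ma_window moving-average window (s).
#' @return numeric envelope, same length as `raw`.
#' @export
process_emg <- function(raw, sampling_rate, band = c(10, 300),
                        ma_window = 0.1) {
  if (!all(is.finite(raw))) stopf("raw signal contains non-finite values")
  if (sampling_rate <= 2 * band[2])
    stopf("sampling rate %.0f Hz cannot resolve the %g Hz band edge",
          sampling_rate, band[2])
  bf <- signal::butter(2, band / (sampling_rate / 2), type = "pass")
  x <- signal::filtfilt(bf, raw)
  x <- x - mean(x)
  x <- abs(x)
  w <- max(1L, round(ma_window * sampling_rate))
  if (w %% 2 == 0) w <- w + 1L
  env <- stats::filter(x, rep(1 / w, w), sides = 2)
  env <- as.numeric(env)
  # shrink the window near the edges instead of dropping samples
  half <- (w - 1L) / 2L
  n <- length(x)
  for (i in which(is.na(env))) {
    j0 <- max(1L, i - half); j1 <- min(n, i + half)
    env[i] <- mean(x[j0:j1])
  }
  env
}

#' Normalize EMG envelopes to the subject-level maximum
#'
#' Every sample of every trial is divided by the maximum envelope value
#' recorded across all supplied trials of the subject, so the global maximum
#' of the output is exactly 1.
#'
#' @param envelopes a list of numeric envelopes (or a single numeric vector).
#' @return list of normalized envelopes (or a vector if a vector was given).
#' @export
normalize_emg <- function(envelopes) {
  single <- !is.list(envelopes)
  if (single) envelopes <- list(envelopes)
  m <- max(vapply(envelopes, max, 0))
  if (m <= 0) stopf("global maximum is zero; cannot normalize")
  out <- lapply(envelopes, function(e) e / m)
  if (single) out[[1]] else out
}
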