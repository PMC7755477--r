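#' Welch power spectral density estimate
#'
#' Averaged modified periodogram: the signal is split into Hann-windowed
#' segments of \code{seg_len} samples with the given fractional overlap,
#' each segment is mean-detrended, and the one-sided periodograms are
#' averaged. Density scaling: integrating the returned PSD over frequency
#' recovers the signal variance (units uV^2/Hz for uV input).
#'
#' @param x numeric vector.
#' @param fs sampling rate (Hz).
#' @param seg_len segment length in samples (default one second of data).
#' @param overlap fractional overlap between segments (default 0.5).
#' @return A list with \code{freq} (Hz) and \code{psd}.
#' @export
welch_psd <- function(x, fs, seg_len = round(fs), overlap = 0.5) {
  n <- length(x)
  seg_len <- min(seg_len, n)
  step <- max(1L, round(seg_len * (1 - overlap)))
  starts <- seq(1L, n - seg_len + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(seg_len) / (seg_len + 1))  # Hann
  u <- fs * sum(w^2)
  nfreq <- seg_len %/% 2L + 1L
  acc <- numeric(nfreq)
  for (s in starts) {
    seg <- x[s:(s + seg_len - 1L)]
    seg <- (seg - mean(seg)) * w
    p <- Mod(stats::fft(seg))^2 / u
    p <- p[seq_len(nfreq)]
    # fold the negative frequencies into the one-sided estimate
    dbl <- 2:(nfreq - if (seg_len %% 2L == 0L) 1L else 0L)
    p[dbl] <- 2 * p[dbl]
    acc <- acc + p
  }
  list(freq = (seq_len(nfreq) - 1L) * fs / seg_len,
       psd = acc / length(starts))
}

# Band power (uV^2) from a welch_psd result by rectangle-rule integration.
band_power <- function(w, lo = 8, hi = 30) {
  df <- w$freq[2L] - w$freq[1L]
  sum(w$psd[w$freq >= lo & w$freq <= hi]) * df
}

# Per-trial PSD band-power features at named channels: log 8-30 Hz band
# power per channel plus the across-channel mean of those logs.
psd_features <- function(x, channels = c("C3", "Cz", "C4"),
                         window = c(0, 2)) {
  stopifnot(inherits(x, "epochs"))
  if (!is.null(window)) x <- crop_epochs(x, window)
  chi <- channel_index(x$montage, channels)
  n <- n_trials(x)
  feats <- matrix(0, n, length(channels) + 1L,
                  dimnames = list(NULL, c(channels, "mean")))
  for (i in seq_len(n)) {
    lp <- vapply(chi, function(ci)
      log(band_power(welch_psd(x$data[i, ci, ], x$fs))), 1.0)
    feats[i, ] <- c(lp, mean(lp))
  }
  feats
}

#' Class-average PSD curves at named channels
#'
#' Welch PSD per trial and channel, averaged within class — the standard
#' sanity check that motor imagery modulates mu/beta band power at the
#' sensorimotor channels (opposite directions at C3 and C4 for
#' lateralized tasks).
#'
#' @param x an \code{\link{epochs}} set.
#' @param channels channel labels (default C3, Cz, C4).
#' @param window cue-relative window (s), \code{NULL} for the whole trial.
#' @return Long data.frame: \code{class}, \code{channel}, \code{freq},
#'   \code{psd}.
#' @export
psd_curves <- function(x, channels = c("C3", "Cz", "C4"),
                       window = c(0, 2)) {
  stopifnot(inherits(x, "epochs"))
  if (!is.null(window)) x <- crop_epochs(x, window)
  chi <- channel_index(x$montage, channels)
  out <- list()
  for (cl in levels(x$labels)) {
    idx <- which(x$labels == cl)
    for (k in seq_along(channels)) {
      acc <- NULL
      for (i in idx) {
        w <- welch_psd(x$data[i, chi[k], ], x$fs)
        acc <- if (is.null(acc)) w$psd else acc + w$psd
      }
      out[[length(out) + 1L]] <- data.frame(
        class = cl, channel = channels[k], freq = w$freq,
        psd = acc / length(idx))
    }
  }
  do.call(rbind, out)
}
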