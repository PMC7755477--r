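#' Configuration for a synthetic motor-imagery session
#'
#' Bundles the generator parameters. The defaults emulate a typical
#' laboratory session: 64 channels at 500 Hz, 2.5 s trials covering 0.5 s
#' pre-cue to 2 s post-cue, 60 trials per class.
#'
#' @param n_channels number of channels (default 64).
#' @param fs sampling rate in Hz (default 500).
#' @param trial_len_s trial length in seconds (default 2.5; the trial spans
#'   \code{[-0.5, trial_len_s - 0.5)} s around the cue).
#' @param n_trials_per_class trials per class (default 60).
#' @param classes subset of \code{c("LH","RH","F","LH&RH","LH&F","RH&F")}.
#' @param snr_db band-power ratio (dB) of each task source over the
#'   background at that source's peak channel, in the unmodulated state.
#' @param erd_depth fractional band-variance modulation in [0, 1): an
#'   "active" source is scaled by \code{1 - erd_depth} contralaterally
#'   (desynchronization) and \code{1 + erd_depth} ipsilaterally.
#' @param eog_amplitude RMS amplitude (microvolts) of a frontal < 4 Hz
#'   ocular component; 0 disables it.
#' @param seed integer seed; the generator derives an independent substream
#'   per (class, trial) from it, so trial content does not depend on the
#'   order classes are listed in.
#' @return A validated list of class \code{sim_config}.
#' @export
sim_config <- function(n_channels = 64, fs = 500, trial_len_s = 2.5,
                       n_trials_per_class = 60,
                       classes = c("LH", "RH", "LH&F", "RH&F"),
                       snr_db = 10, erd_depth = 0.6,
                       eog_amplitude = 0, seed = 1L) {
  known <- c("LH", "RH", "F", "LH&RH", "LH&F", "RH&F")
  bad <- setdiff(classes, known)
  if (length(bad))
    stop("unknown class label(s): ", paste(bad, collapse = ", "),
         " (known: ", paste(known, collapse = ", "), ")", call. = FALSE)
  if (!(erd_depth >= 0 && erd_depth < 1))
    stop("erd_depth must be in [0, 1)", call. = FALSE)
  if (fs <= 0) stop("fs must be > 0", call. = FALSE)
  if (n_trials_per_class < 1) stop("n_trials_per_class must be > 0", call. = FALSE)
  structure(
    list(n_channels = as.integer(n_channels), fs = fs,
         trial_len_s = trial_len_s,
         n_trials_per_class = as.integer(n_trials_per_class),
         classes = classes, snr_db = snr_db, erd_depth = erd_depth,
         eog_amplitude = eog_amplitude, seed = as.integer(seed)),
    class = "sim_config")
}

# Per-class variance modulation of the three task sources (C3, C4, Cz).
# Single-limb imagery desynchronizes the contralateral source (factor 1-d)
# and synchronizes the ipsilateral one (1+d); feet imagery desynchronizes
# the midline source. Combined commands multiply their components' factors
# elementwise, which is what makes single-task filters transferable.
class_modulation <- function(class, d) {
  base <- switch(class,
    "LH" = c(C3 = 1 + d, C4 = 1 - d, Cz = 1),
    "RH" = c(C3 = 1 - d, C4 = 1 + d, Cz = 1),
    "F"  = c(C3 = 1,     C4 = 1,     Cz = 1 - d),
    "LH&RH" = class_modulation("LH", d) * class_modulation("RH", d),
    "LH&F"  = class_modulation("LH", d) * class_modulation("F", d),
    "RH&F"  = class_modulation("RH", d) * class_modulation("F", d),
    stop("unknown class label: ", class, call. = FALSE))
  base
}

# Real noise with a prescribed two-sided spectral weight profile, unit
# expected variance; `weights(f)` maps frequency (Hz) to amplitude weight.
shaped_noise <- function(n, fs, weights) {
  f <- c(seq(0, floor(n / 2)), seq(-ceiling(n / 2) + 1, -1)) * fs / n
  w <- weights(abs(f))
  x <- stats::rnorm(n)
  y <- Re(stats::fft(w * stats::fft(x), inverse = TRUE)) / n
  y / sqrt(mean(w^2))
}

band_weights <- function(lo, hi) function(f) as.numeric(f >= lo & f <= hi)
pink_weights <- function(floor_hz = 1) function(f) 1 / sqrt(pmax(f, floor_hz))

# Fraction of a weight profile's variance inside [lo, hi] Hz.
band_fraction <- function(n, fs, weights, lo = 8, hi = 30) {
  f <- abs(c(seq(0, floor(n / 2)), seq(-ceiling(n / 2) + 1, -1)) * fs / n)
  w2 <- weights(f)^2
  sum(w2[f >= lo & f <= hi]) / sum(w2)
}

# Spatial profile: Gaussian bump in montage coordinates around an anchor.
topo_bump <- function(montage, anchor, width = 0.22) {
  pos <- montage$positions
  ctr <- pos[channel_index(montage, anchor), ]
  d2 <- rowSums((pos - matrix(ctr, nrow(pos), 2, byrow = TRUE))^2)
  exp(-d2 / (2 * width^2))
}

trial_seed <- function(seed, class_idx, trial_idx) {
  as.integer((as.double(seed) * 1000003 + class_idx * 10007 +
                trial_idx * 101) %% 2147483647)
}

#' Simulate a labeled motor-imagery EEG session with known ground truth
#'
#' Generates trials under a linear instantaneous mixing model: three
#' band-limited (8-30 Hz) Gaussian task sources with fixed scalp
#' projections peaking near C3, C4 and Cz, superposed on spatially
#' correlated 1/f background noise, sensor noise, and (optionally) a
#' frontal low-frequency ocular component. From the cue onward, each
#' class rescales its task sources' band variance according to the
#' event-related (de)synchronization pattern of the imagined limbs:
#' e.g. left-hand-and-feet imagery lowers power at C4 and Cz and raises
#' it at C3, and mirrored for right-hand-and-feet. Combined commands
#' multiply their component commands' variance factors elementwise.
#' The pre-cue segment is always unmodulated.
#'
#' The output is raw in the sense that the background is broadband; run
#' \code{\link{bandpass_8_30}} (or the full preprocessing chain) before
#' CSP, as with recorded data.
#'
#' @param config a \code{\link{sim_config}}.
#' @return A list with components \code{epochs} (an \code{\link{epochs}}
#'   set of \code{n_trials_per_class * length(classes)} trials) and
#'   \code{truth}, a \code{synthetic_truth} object holding the scaled
#'   mixing columns (channels x 3, columns named C3/C4/Cz), the per-class
#'   source variance factors, and the seed.
#' @examples
#' sess <- simulate_session(sim_config(n_channels = 16, n_trials_per_class = 4))
#' sess$epochs
#' @export
simulate_session <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }

  fs <- config$fs
  ns <- round(config$trial_len_s * fs)
  t0 <- -0.5
  cue_i <- round(-t0 * fs) + 1L     # first post-cue sample
  mon <- make_montage(config$n_channels)
  nch <- config$n_channels

  # structural randomness (background mixing) from the session seed.
  # The background is spatially full rank and smooth: one 1/f source per
  # channel, each projecting as a Gaussian bump at a random scalp
  # location (a crude stand-in for distributed cortical activity under
  # volume conduction), plus independent sensor noise.
  set.seed(config$seed)
  nb <- nch
  pos <- mon$positions
  B <- vapply(seq_len(nb), function(j) {
    r <- sqrt(stats::runif(1)); a <- stats::runif(1, 0, 2 * pi)
    ctr <- c(r * cos(a), r * sin(a))
    d2 <- rowSums((pos - matrix(ctr, nch, 2, byrow = TRUE))^2)
    exp(-d2 / (2 * 0.3^2)) * sample(c(-1, 1), 1)
  }, numeric(nch))
  B <- B / sqrt(mean(rowSums(B^2))) * 10      # mean background RMS 10 uV
  sigma_w <- 1                                # sensor noise RMS, uV

  anchors <- c("C3", "C4", "Cz")
  A <- sapply(anchors, function(a) topo_bump(mon, a))

  # gain per task source: band SNR at the peak channel over the background
  pinkw <- pink_weights()
  frac_bg <- band_fraction(ns, fs, pinkw)
  frac_w <- band_fraction(ns, fs, function(f) rep(1, length(f)))
  gains <- vapply(seq_along(anchors), function(p) {
    peak <- which.max(abs(A[, p]))
    bg_band <- sum(B[peak, ]^2) * frac_bg + sigma_w^2 * frac_w
    sqrt(10^(config$snr_db / 10) * bg_band) / abs(A[peak, p])
  }, 1.0)
  A <- sweep(A, 2, gains, `*`)
  colnames(A) <- anchors

  eog_col <- if (config$eog_amplitude > 0) {
    v <- topo_bump(mon, "FC5") + topo_bump(mon, "FC6")  # frontal spread
    v / max(abs(v)) * config$eog_amplitude
  } else NULL

  classes <- config$classes
  mods <- t(vapply(classes, class_modulation, numeric(3), d = config$erd_depth))
  colnames(mods) <- anchors

  ntr <- config$n_trials_per_class * length(classes)
  dat <- array(0, c(ntr, nch, ns))
  labels <- character(ntr)
  bw <- band_weights(8, 30)
  class_order <- match(classes, c("LH", "RH", "F", "LH&RH", "LH&F", "RH&F"))

  i <- 0L
  for (ci in seq_along(classes)) {
    fac <- sqrt(mods[ci, ])
    for (tr in seq_len(config$n_trials_per_class)) {
      i <- i + 1L
      set.seed(trial_seed(config$seed, class_order[ci], tr))
      S <- vapply(1:3, function(p) shaped_noise(ns, fs, bw), numeric(ns))
      # modulate band variance from the cue onward only
      S[cue_i:ns, ] <- sweep(S[cue_i:ns, , drop = FALSE], 2, fac, `*`)
      Sbg <- vapply(seq_len(nb), function(j) shaped_noise(ns, fs, pinkw),
                    numeric(ns))
      X <- A %*% t(S) + B %*% t(Sbg) +
        matrix(stats::rnorm(nch * ns, sd = sigma_w), nch, ns)
      if (!is.null(eog_col))
        X <- X + eog_col %*% t(shaped_noise(ns, fs, band_weights(0.2, 4)))
      dat[i, , ] <- X
      labels[i] <- classes[ci]
    }
  }

  truth <- structure(
    list(mixing = A,
         class_source_variance = mods,
         seed = config$seed),
    class = "synthetic_truth")
  list(epochs = epochs(dat, labels, fs, mon, t0_offset_s = t0),
       truth = truth)
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat("<synthetic_truth> mixing ", nrow(x$mixing), " x ", ncol(x$mixing),
      ", seed ", x$seed, "\n", sep = "")
  cat("class source variance factors (8-30 Hz):\n")
  print(round(x$class_source_variance, 3))
  invisible(x)
}
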