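# Shared fixtures, generated once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# Small fast session: 16 channels, 250 Hz, band-passed, with truth.
small_session <- function() {
  cached("small", {
    sess <- simulate_session(sim_config(
      n_channels = 16, fs = 250, n_trials_per_class = 12,
      classes = c("LH", "RH", "LH&F", "RH&F"),
      snr_db = 10, erd_depth = 0.6, seed = 42))
    sess$filtered <- bandpass_8_30(sess$epochs)
    sess
  })
}

split_small <- function() {
  sess <- small_session()
  ep <- sess$filtered
  list(source = ep[ep$labels %in% c("LH", "RH")],
       target = ep[ep$labels %in% c("LH&F", "RH&F")],
       truth = sess$truth)
}

# Deterministic toy epochs with hand-set contents (any channel count).
toy_epochs <- function(dat, labels, fs = 100, t0 = 0) {
  nch <- dim(dat)[2L]
  mon <- if (nch >= 8) make_montage(nch) else
    transfercsp:::montage_from_names(paste0("ch", seq_len(nch)))
  epochs(dat, labels, fs, mon, t0_offset_s = t0)
}

# Random SPD covariance pair with unit trace, for eigen-identity checks.
random_cov_pair <- function(n) {
  A <- matrix(stats::rnorm(n * n), n)
  B <- matrix(stats::rnorm(n * n), n)
  R1 <- crossprod(A) + 0.1 * diag(n)
  R2 <- crossprod(B) + 0.1 * diag(n)
  list(R1 = R1 / sum(diag(R1)), R2 = R2 / sum(diag(R2)))
}

# Naive direct-summation Fisher ratio, the independent oracle for Eq-style
# between/within scatter (loops, no vectorization shared with the package).
naive_fisher <- function(x, labels) {
  if (is.vector(x)) x <- matrix(x, ncol = 1)
  labels <- factor(labels)
  n <- nrow(x)
  sapply(seq_len(ncol(x)), function(k) {
    m <- mean(x[, k])
    sb <- 0; sw <- 0
    for (lv in levels(labels)) {
      xi <- x[labels == lv, k]
      sb <- sb + (length(xi) / n) * (mean(xi) - m)^2
      for (v in xi) sw <- sw + (v - mean(xi))^2
    }
    sw <- sw / n
    if (sw > 0) sb / sw else if (sb > 0) Inf else 0
  })
}
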