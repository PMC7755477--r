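make_rec <- function(dat, fs = 250, events = data.frame(sample = integer(),
                                                        label = character())) {
  continuous_record(dat, fs, make_montage(nrow(dat)), events)
}

test_that("linked-mastoid re-referencing subtracts half the right mastoid", {
  mon <- make_montage(8)
  dat <- matrix(0, 8, 10)
  rm_i <- match("RM", mon$channel_names)
  c3_i <- match("C3", mon$channel_names)
  dat[c3_i, ] <- 4
  dat[rm_i, ] <- 2
  out <- rereference_linked_mastoids(make_rec(dat))
  expect_equal(out$data[c3_i, ], rep(3, 10))   # 4 - 2/2
  expect_equal(out$data[rm_i, ], rep(1, 10))   # RM itself becomes RM/2
  expect_equal(out$reference, "LM+RM/2")

  # degenerate: all-zero RM leaves everything unchanged
  dat[rm_i, ] <- 0
  out0 <- rereference_linked_mastoids(make_rec(dat))
  expect_equal(out0$data, dat)

  # not idempotent by design: a second application is refused
  expect_error(rereference_linked_mastoids(out), "LM")
})

test_that("bad channels become the mean of their good neighbours", {
  dat <- matrix(rnorm(8 * 20), 8, 20)
  rec <- make_rec(dat)
  expect_identical(interpolate_bad_channels(rec, character())$data, dat)

  nb <- list(C3 = c("Cz", "FC5"))
  out <- interpolate_bad_channels(rec, "C3", nb)
  c3 <- match("C3", rec$montage$channel_names)
  cz <- match("Cz", rec$montage$channel_names)
  f5 <- match("FC5", rec$montage$channel_names)
  expect_equal(out$data[c3, ], (dat[cz, ] + dat[f5, ]) / 2)
  expect_equal(out$data[-c3, ], dat[-c3, ])

  # constant field: interpolation reproduces the constant
  datc <- dat; datc[cz, ] <- 1; datc[f5, ] <- 1
  outc <- interpolate_bad_channels(make_rec(datc), "C3", nb)
  expect_equal(outc$data[c3, ], rep(1, 20))

  # a bad channel whose neighbourhood is all bad cannot be repaired
  expect_error(
    interpolate_bad_channels(rec, c("C3", "Cz", "FC5"), nb),
    "fewer than 2 good neighbours")
})

test_that("band-pass keeps 15 Hz, rejects 50 Hz, 2 Hz and DC", {
  fs <- 500
  t <- seq(0, 4, by = 1 / fs)[-1]
  tone <- function(f) sin(2 * pi * f * t)
  dat <- rbind(tone(15), tone(50), tone(2), rep(100, length(t)),
               matrix(0, 4, length(t)))
  out <- bandpass_8_30(make_rec(dat, fs = fs))
  mid <- 500:1500  # trim the edges before measuring amplitude
  amp <- function(x) sqrt(2 * mean(x[mid]^2))
  expect_gt(amp(out$data[1, ]), 0.9)          # passband tone preserved
  expect_lt(amp(out$data[2, ]), 1 / 10)       # >= 20 dB down at 50 Hz
  expect_lt(amp(out$data[3, ]), 1 / 10)       # >= 20 dB down at 2 Hz
  expect_lt(abs(mean(out$data[4, mid])), 1e-6)  # DC removed
  expect_error(bandpass_8_30(make_rec(dat[, 1:100], fs = 50)), "headroom")
})

test_that("epoching is half-open with exact sample counts and labels", {
  fs <- 500
  dat <- matrix(rep(seq_len(3000), each = 8), 8, 3000, byrow = FALSE)
  ev <- data.frame(sample = c(500L, 1500L, 1900L),
                   label = c("LH&F", "RH&F", "LH&F"))
  ep <- extract_epochs(make_rec(dat, fs, ev), -0.5, 2.0)
  expect_equal(dim(ep$data), c(3L, 8L, 1250L))  # (2.0 - (-0.5)) * 500
  expect_equal(as.character(ep$labels), ev$label)
  expect_equal(ep$t0_offset_s, -0.5)
  # first sample of trial 1 sits 0.5 s before its cue
  expect_equal(ep$data[1, 1, 1], dat[1, 500 - 250])
  # sample at tmax is excluded
  expect_equal(ep$data[1, 1, 1250], dat[1, 500 + 2 * fs - 1])

  one <- extract_epochs(make_rec(dat, fs, ev), 0, 0.002)
  expect_equal(dim(one$data)[3], 1L)

  ev_bad <- data.frame(sample = c(100L, 1500L), label = c("LH&F", "RH&F"))
  expect_error(extract_epochs(make_rec(dat, fs, ev_bad)), "#1")
})

test_that("baseline correction subtracts the pre-cue mean and is idempotent", {
  dat <- array(5, c(2, 4, 100))
  ep <- toy_epochs(dat, c("a", "b"), fs = 100, t0 = -0.5)
  out <- baseline_correct(ep, c(-0.5, 0))
  expect_true(all(out$data == 0))

  dat2 <- array(0, c(1, 4, 100))
  dat2[1, 2, 1:50] <- 2    # baseline mean 2
  dat2[1, 2, 51:100] <- 7  # post-cue mean 7
  ep2 <- toy_epochs(dat2, "a", fs = 100, t0 = -0.5)
  out2 <- baseline_correct(ep2, c(-0.5, 0))
  expect_equal(mean(out2$data[1, 2, 51:100]), 5)
  expect_equal(baseline_correct(out2, c(-0.5, 0))$data, out2$data)

  expect_error(baseline_correct(ep2, c(-1, 0)), "outside")
})

test_that("the full chain runs in the fixed order and preserves labels", {
  fs <- 250
  set.seed(8)
  dat <- matrix(rnorm(12 * 2500, sd = 10), 12, 2500)
  ev <- data.frame(sample = c(300L, 900L, 1500L, 1900L),
                   label = c("LH", "RH", "LH", "RH"))
  ep <- preprocess(make_rec(dat, fs, ev))
  expect_s3_class(ep, "epochs")
  expect_equal(n_trials(ep), 4L)
  expect_equal(as.character(ep$labels), ev$label)
  expect_equal(dim(ep$data)[2], 12L)
  # re-running on the already re-referenced record must fail loudly
  rec2 <- rereference_linked_mastoids(make_rec(dat, fs, ev))
  expect_error(preprocess(rec2), "LM")
})
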