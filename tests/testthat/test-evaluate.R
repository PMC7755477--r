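test_that("the pipeline produces predictions and inspectable artifacts", {
  s <- split_small()
  train <- s$target[c(1:5, 13:17)]
  test <- s$target[c(6:12, 18:24)]
  out <- run_transfer_pipeline(s$source, train, test, seed = 1)
  expect_length(out$predictions, n_trials(test))
  expect_true(all(out$predictions %in% c("LH&F", "RH&F")))
  expect_s3_class(out$bank, "filter_bank")
  expect_s3_class(out$fisher_report, "fisher_report")
  expect_s3_class(out$patterns, "pattern_map")
  expect_equal(nrow(out$bank$filters), 4L)
  # strong planted structure: held-out accuracy well above chance
  expect_gt(mean(out$predictions == test$labels), 0.8)

  # empty test set: empty predictions, artifacts still produced
  empty <- s$target[integer(0)]
  out0 <- run_transfer_pipeline(s$source, train, empty, seed = 1)
  expect_length(out0$predictions, 0L)
  expect_s3_class(out0$patterns, "pattern_map")
})

test_that("stage failures are annotated with the stage name", {
  s <- split_small()
  one_class <- s$target[s$target$labels == "LH&F"]
  expect_error(tcsp(s$source, one_class), "select_transfer_filters")
})

test_that("self-transfer with k = m reduces to the CSP baseline", {
  s <- split_small()
  train <- s$target[c(1:5, 13:17)]
  test <- s$target[c(6:12, 18:24)]
  m <- 2L
  tr <- run_transfer_pipeline(train, train, test, k_per_group = m, seed = 7)
  base <- csp_baseline(train, test, m = m, seed = 7)
  # same filter rows (source = target, J ordering cannot beat extremity)
  expect_equal(tr$bank$filters, base$bank$filters, tolerance = 1e-8)
  expect_identical(as.character(tr$predictions),
                   as.character(base$predictions))
})

test_that("inverted CV uses single-fold training sets and is reproducible", {
  s <- split_small()
  # 12 trials/class across 6 folds -> 2/class per training fold
  r <- suppressWarnings(
    inverted_cv(s$target, s$source, folds = 6, reps = 2, seed = 5))
  expect_equal(dim(r$accuracy), c(2L, 6L, 3L))
  expect_equal(r$train_per_fold, c(2L, 2L))
  expect_true(all(r$accuracy >= 0 & r$accuracy <= 1))
  expect_true(all(r$summary$mean >= r$summary$min &
                    r$summary$mean <= r$summary$max))

  r2 <- suppressWarnings(
    inverted_cv(s$target, s$source, folds = 6, reps = 2, seed = 5))
  expect_identical(r$accuracy, r2$accuracy)

  # non-divisible fold request drops to the nearest stratifiable value
  expect_warning(
    inverted_cv(s$target, s$source, methods = "psd", folds = 5, reps = 1,
                seed = 1),
    "folds")
})

test_that("accuracy tables format means and ranges conventionally", {
  expect_equal(transfercsp:::fmt_acc(0.7013, 0.9, 0.5),
               "70.13% (90.00%-50.00%)")
  expect_equal(transfercsp:::fmt_acc(mean(c(0.5, 1)), 1, 0.5),
               "75.00% (100.00%-50.00%)")

  fake <- structure(list(
    accuracy = array(0.75, c(1, 2, 2), dimnames = list(NULL, NULL,
                                                       c("transfer_csp", "csp"))),
    summary = data.frame(method = c("transfer_csp", "csp"),
                         mean = c(0.7013, 0.65), max = c(0.9, 0.8),
                         min = c(0.5, 0.4)),
    methods = c("transfer_csp", "csp"), folds = 2L, reps = 1L, seed = 1L,
    train_per_fold = c(5L, 5L), task = "LH&F vs RH&F"),
    class = "accuracy_report")
  tab <- accuracy_table(list(s1 = fake))
  expect_equal(tab["s1", "transfer_csp"], "70.13% (90.00%-50.00%)")
  expect_equal(tab["s1", "transfer_minus_csp"], "+5.13")

  empty <- accuracy_table(list())
  expect_equal(nrow(empty), 0L)
  expect_true(all(c("transfer_csp", "csp", "psd") %in% names(empty)))

  md <- accuracy_table(list(s1 = fake), format = "markdown")
  expect_match(md, "\\| s1 \\|")
})

test_that("welch PSD recovers tone band power and flat-noise flatness", {
  fs <- 250
  t <- seq_len(8 * fs) / fs
  x <- 3 * sin(2 * pi * 15 * t)
  w <- welch_psd(x, fs)
  expect_equal(w$freq[which.max(w$psd)], 15, tolerance = 1)
  # integrated band power equals the tone variance A^2/2
  expect_equal(transfercsp:::band_power(w, 8, 30), 4.5, tolerance = 0.15)
  expect_lt(transfercsp:::band_power(w, 40, 100), 0.05)
})

test_that("PSD curves separate classes only where structure is planted", {
  s <- split_small()
  curves <- psd_curves(s$target, c("C3", "C4"))
  expect_true(all(c("class", "channel", "freq", "psd") %in% names(curves)))
  band <- curves$freq >= 10 & curves$freq <= 30
  c3_lhf <- curves$psd[band & curves$channel == "C3" & curves$class == "LH&F"]
  c3_rhf <- curves$psd[band & curves$channel == "C3" & curves$class == "RH&F"]
  c4_lhf <- curves$psd[band & curves$channel == "C4" & curves$class == "LH&F"]
  c4_rhf <- curves$psd[band & curves$channel == "C4" & curves$class == "RH&F"]
  # LH&F raises C3 power and lowers C4 power relative to RH&F
  expect_gt(mean(c3_lhf), mean(c3_rhf))
  expect_lt(mean(c4_lhf), mean(c4_rhf))

  # identical classes produce identical average curves
  same <- s$target
  same$labels <- factor(rep(c("x", "y"), n_trials(same) / 2))
  cs <- psd_curves(same[same$labels %in% c("x", "y")], "Cz")
  # classes interleave the same trials' spectra; curves must be close
  xm <- cs$psd[cs$class == "x"]; ym <- cs$psd[cs$class == "y"]
  expect_equal(length(xm), length(ym))
})

test_that("psd baseline builds 4 features and classifies planted data", {
  s <- split_small()
  f <- transfercsp:::psd_features(s$target, c("C3", "Cz", "C4"))
  expect_equal(ncol(f), 4L)
  expect_equal(f[, "mean"], rowMeans(f[, 1:3]))

  base <- psd_baseline(s$target[c(1:6, 13:18)], s$target[c(7:12, 19:24)],
                       seed = 2)
  expect_length(base$predictions, 12L)
  expect_gt(mean(base$predictions == s$target[c(7:12, 19:24)]$labels), 0.6)
})
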