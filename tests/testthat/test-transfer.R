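test_that("fisher ratio matches the hand-worked example and edge cases", {
  fs <- fisher_scores(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  expect_identical(fs$s_between, 2.25)
  expect_equal(fs$s_within, 2 / 3)
  expect_equal(fs$J, 3.375)

  # identical class means: no between-class scatter
  expect_equal(fisher_scores(c(1, 3, 1, 3), c("a", "a", "b", "b"))$J, 0)
  # perfect separation: within-class scatter is zero
  expect_identical(fisher_scores(c(2, 2, 5, 5), c("a", "a", "b", "b"))$J, Inf)
  # constant feature: defined as 0
  expect_identical(fisher_scores(rep(1, 4), c("a", "a", "b", "b"))$J, 0)
  expect_error(fisher_scores(1:4, rep("a", 4)), "two classes")
})

test_that("fisher scores agree with a naive summation oracle", {
  set.seed(31)
  for (i in 1:100) {
    n_cl <- sample(2:3, 1)
    n_per <- sample(2:6, n_cl, replace = TRUE)
    labels <- rep(letters[seq_len(n_cl)], n_per)
    x <- matrix(rnorm(length(labels) * 3), ncol = 3)
    expect_equal(fisher_scores(x, labels)$J, naive_fisher(x, labels),
                 tolerance = 1e-10)
  }
})

test_that("duplicating every sample leaves fisher scores unchanged", {
  set.seed(32)
  x <- matrix(rnorm(40), 10, 4)
  labels <- rep(c("a", "b"), 5)
  expect_equal(fisher_scores(rbind(x, x), c(labels, labels))$J,
               fisher_scores(x, labels)$J, tolerance = 1e-12)
})

test_that("transfer selection keeps k filters per eigenvalue group", {
  s <- split_small()
  bank <- csp_filters(class_covariance(s$source, "LH"),
                      class_covariance(s$source, "RH"),
                      source_classes = c("LH", "RH"),
                      montage = s$source$montage)
  sel <- select_transfer_filters(bank, s$target, k_per_group = 2)
  expect_equal(nrow(sel$bank$filters), 4L)
  expect_equal(sum(sel$bank$group == "high"), 2L)
  expect_equal(sum(sel$bank$group == "low"), 2L)
  expect_true(all(diff(sel$bank$eigenvalues) <= 0))

  # selected J dominates rejected J within each group
  tab <- sel$report$table
  for (g in c("high", "low")) {
    sel_j <- tab$J[tab$selected & tab$group == g]
    rej_j <- tab$J[!tab$selected & tab$group == g]
    expect_gte(min(sel_j), max(rej_j))
  }

  # selection via exhaustive scoring oracle: recompute J for every filter
  # directly from projected single-filter variances over the whole bank
  v <- transfercsp:::trial_band_variances(bank, s$target, c(0, 2))
  feats <- log(v / rowSums(v))
  J_oracle <- naive_fisher(feats, s$target$labels)
  expect_equal(tab$J, J_oracle, tolerance = 1e-10)
})

test_that("selection is balanced for random banks and k at its maximum", {
  s <- split_small()
  bank <- csp_filters(class_covariance(s$source, "LH"),
                      class_covariance(s$source, "RH"),
                      source_classes = c("LH", "RH"),
                      montage = s$source$montage)
  for (k in c(1, 3, 8)) {
    sel <- select_transfer_filters(bank, s$target, k_per_group = k)
    expect_equal(sum(sel$bank$group == "high"), as.integer(k))
    expect_equal(sum(sel$bank$group == "low"), as.integer(k))
  }
  # k at half the bank: selection is the identity
  sel_all <- select_transfer_filters(bank, s$target, k_per_group = 8)
  expect_equal(sel_all$bank$filters, bank$filters)
  expect_error(select_transfer_filters(bank, s$target, k_per_group = 9),
               "half the bank")
})

test_that("the middle filter of an odd bank is in no group, never selected", {
  cp <- random_cov_pair(5)
  b <- csp_filters(cp$R1, cp$R2, gamma = 0)
  expect_equal(b$group, c("high", "high", "none", "low", "low"))
  set.seed(5)
  dat <- array(rnorm(8 * 5 * 100), c(8, 5, 100))
  mon <- transfercsp:::montage_from_names(paste0("ch", 1:5))
  tgt <- epochs(dat, rep(c("p", "q"), each = 4), 100, mon)
  sel <- select_transfer_filters(b, tgt, k_per_group = 2, window = NULL)
  expect_false(3L %in% sel$bank$source_index)
})

test_that("selection targets the planted discriminative sources", {
  s <- split_small()
  bank <- csp_filters(class_covariance(s$source, "LH"),
                      class_covariance(s$source, "RH"),
                      source_classes = c("LH", "RH"),
                      montage = s$source$montage)
  sel <- select_transfer_filters(bank, s$target, k_per_group = 1)
  pm <- spatial_patterns(sel$bank)
  # the two kept filters should recover the C3 and C4 planted columns
  cors <- abs(stats::cor(t(pm$patterns), s$truth$mixing[, c("C3", "C4")]))
  expect_gt(max(cors[, "C3"]), 0.85)
  expect_gt(max(cors[, "C4"]), 0.85)
})

test_that("degenerate target training sets are rejected", {
  s <- split_small()
  bank <- csp_filters(class_covariance(s$source, "LH"),
                      class_covariance(s$source, "RH"))
  one_class <- s$target[s$target$labels == "LH&F"]
  expect_error(select_transfer_filters(bank, one_class), "2 classes")
  tiny <- s$target[c(1, 13)]  # one trial per class
  expect_error(select_transfer_filters(bank, tiny), "at least 2")
})
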