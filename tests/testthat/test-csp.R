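test_that("class covariance is the trace-normalized average scatter", {
  # one trial, 2 channels, X = [[1,-1],[0,0]] -> XX' = [[2,0],[0,0]] -> /2
  dat <- array(0, c(1, 2, 2))
  dat[1, 1, ] <- c(1, -1)
  mon <- structure(list(channel_names = c("a", "b"),
                        positions = matrix(0, 2, 2,
                                           dimnames = list(c("a", "b"), NULL)),
                        n_channels = 2L), class = "montage")
  ep <- epochs(dat, "x", 100, mon)
  out <- class_covariance(ep, "x", window = NULL)
  expect_equal(out$cov, matrix(c(1, 0, 0, 0), 2), tolerance = 1e-12)
  expect_equal(out$n, 1L)

  # K identical trials average to the single-trial matrix; trace is 1
  dat5 <- array(rep(dat, 5), c(5, 2, 2))
  for (i in 1:5) dat5[i, , ] <- dat[1, , ]
  ep5 <- epochs(dat5, rep("x", 5), 100, mon)
  out5 <- class_covariance(ep5, "x", window = NULL)
  expect_equal(out5$cov, out$cov)
})

test_that("any covariance has unit trace and zero-variance trials error", {
  sess <- small_session()
  out <- class_covariance(sess$filtered, "LH")
  expect_equal(sum(diag(out$cov)), 1, tolerance = 1e-9)
  expect_equal(out$cov, t(out$cov), tolerance = 1e-10)
  expect_equal(out$n, 12L)
  expect_true(min(eigen(out$cov, symmetric = TRUE)$values) > -1e-10)

  dead <- sess$epochs
  dead$data[3, , ] <- 0
  expect_error(class_covariance(dead, dead$labels[3], window = NULL),
               "trial 3")
})

test_that("the hand-computable diagonal pair gives axis filters", {
  b <- csp_filters(diag(c(0.8, 0.2)), diag(c(0.2, 0.8)))
  expect_equal(b$eigenvalues, c(0.8, 0.2), tolerance = 1e-5)
  expect_equal(abs(b$filters), diag(2), tolerance = 1e-5)
  expect_equal(b$group, c("high", "low"))

  # no discriminative direction when the classes share a covariance
  same <- random_cov_pair(4)$R1
  b2 <- csp_filters(same, same)
  expect_equal(b2$eigenvalues, rep(0.5, 4), tolerance = 1e-5)
})

test_that("whitening and complementary-eigenvalue identities hold", {
  set.seed(20)
  for (i in 1:30) {
    n <- sample(c(4, 8, 16), 1)
    cp <- random_cov_pair(n)
    b <- csp_filters(cp$R1, cp$R2, gamma = 0)
    W <- b$filters
    R <- cp$R1 + cp$R2
    expect_lt(max(abs(W %*% R %*% t(W) - diag(n))), 1e-8)
    l2 <- diag(W %*% cp$R2 %*% t(W))
    expect_lt(max(abs(b$eigenvalues + l2 - 1)), 1e-8)
    # variance-ratio interpretation of the eigenvalues, non-increasing
    ratio <- diag(W %*% cp$R1 %*% t(W)) / diag(W %*% R %*% t(W))
    expect_equal(ratio, b$eigenvalues, tolerance = 1e-8)
    expect_true(all(diff(b$eigenvalues) <= 1e-10))
  }
})

test_that("filters match a generalized-eigenvalue oracle on small problems", {
  set.seed(21)
  for (n in 2:4) {
    cp <- random_cov_pair(n)
    b <- csp_filters(cp$R1, cp$R2, gamma = 0)
    # independent oracle: eigenvalues of R^-1 R1 solve max w R1 w'/ w R w'
    oracle <- sort(Re(eigen(solve(cp$R1 + cp$R2) %*% cp$R1)$values),
                   decreasing = TRUE)
    expect_equal(b$eigenvalues, oracle, tolerance = 1e-8)
  }
})

test_that("the bank is invariant to global scaling of the trials", {
  s <- split_small()
  src <- s$source
  b1 <- csp_filters(class_covariance(src, "LH"), class_covariance(src, "RH"))
  scaled <- src
  scaled$data <- scaled$data * 37.5
  b2 <- csp_filters(class_covariance(scaled, "LH"),
                    class_covariance(scaled, "RH"))
  expect_equal(b1$filters, b2$filters, tolerance = 1e-8)
  expect_equal(b1$eigenvalues, b2$eigenvalues, tolerance = 1e-10)
})

test_that("permuting channels permutes filter columns identically", {
  cp <- random_cov_pair(6)
  p <- c(3, 1, 6, 2, 5, 4)
  b <- csp_filters(cp$R1, cp$R2, gamma = 0)
  bp <- csp_filters(cp$R1[p, p], cp$R2[p, p], gamma = 0)
  expect_equal(bp$filters, b$filters[, p], tolerance = 1e-8)
  expect_equal(bp$eigenvalues, b$eigenvalues, tolerance = 1e-10)
})

test_that("patterns are the forward model paired with the filters", {
  cp <- random_cov_pair(8)
  b <- csp_filters(cp$R1, cp$R2, gamma = 0)
  pm <- spatial_patterns(b)
  expect_lt(max(abs(pm$patterns %*% t(b$filters) - diag(8))), 1e-8)

  # orthonormal filter matrix: patterns equal filters
  q <- qr.Q(qr(matrix(rnorm(25), 5)))
  fake <- structure(list(filters = q, eigenvalues = rep(0.5, 5),
                         group = rep("none", 5), source_classes = c("a", "b"),
                         source_index = 1:5, montage = NULL),
                    class = "filter_bank")
  expect_equal(spatial_patterns(fake)$patterns, q, tolerance = 1e-10)
})

test_that("the top pattern recovers the planted mixing column", {
  s <- split_small()
  b <- csp_filters(class_covariance(s$source, "LH"),
                   class_covariance(s$source, "RH"),
                   source_classes = c("LH", "RH"),
                   montage = s$source$montage)
  pm <- spatial_patterns(b)
  # LH raises the C3 source: the top (lambda max, class-LH) filter's
  # pattern should align with the planted C3 column
  r <- abs(stats::cor(pm$patterns[1, ], s$truth$mixing[, "C3"]))
  expect_gt(r, 0.9)
})

test_that("pattern tables carry montage coordinates for topographic tools", {
  s <- split_small()
  b <- csp_filters(class_covariance(s$source, "LH"),
                   class_covariance(s$source, "RH"),
                   montage = s$source$montage)
  tab <- pattern_table(spatial_patterns(b))
  expect_equal(nrow(tab), 16 * 16)
  expect_true(all(c("filter", "channel", "value", "x", "y") %in% names(tab)))
  path <- withr::local_tempfile(fileext = ".tsv")
  pattern_table(spatial_patterns(b), path)
  expect_true(file.exists(path))
})
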