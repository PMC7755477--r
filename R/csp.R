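#' Class-average normalized spatial covariance
#'
#' For each trial X (channels x samples) of the requested class, the
#' scatter matrix X X' is divided by its own trace, and the K per-trial
#' matrices are averaged. The per-trial trace normalization makes the
#' estimate invariant to global amplitude scaling and gives the average
#' unit trace. By default only the post-cue analysis window \code{[0, 2)} s
#' feeds the estimate, so pre-cue baseline samples never enter the
#' covariance.
#'
#' @param x an \code{\link{epochs}} set.
#' @param class_label the class whose trials to average.
#' @param window cue-relative analysis window in seconds (half-open), or
#'   \code{NULL} for the whole trial.
#' @return A list with \code{cov} (channels x channels, symmetric positive
#'   semidefinite, unit trace) and \code{n} (number of trials averaged).
#' @export
class_covariance <- function(x, class_label, window = c(0, 2)) {
  stopifnot(inherits(x, "epochs"))
  if (!is.null(window)) x <- crop_epochs(x, window)
  idx <- which(x$labels == class_label)
  if (length(idx) < 1L)
    stop("no trials with label '", class_label, "'", call. = FALSE)
  nch <- dim(x$data)[2L]
  acc <- matrix(0, nch, nch)
  for (i in idx) {
    X <- x$data[i, , ]
    S <- tcrossprod(X)
    tr <- sum(diag(S))
    if (tr <= 0)
      stop("trial ", i, " has zero variance; cannot trace-normalize",
           call. = FALSE)
    acc <- acc + S / tr
  }
  R <- acc / length(idx)
  list(cov = (R + t(R)) / 2, n = length(idx))
}

shrink <- function(R, gamma) {
  n <- nrow(R)
  (1 - gamma) * R + gamma * (sum(diag(R)) / n) * diag(n)
}

#' Common spatial pattern filter bank from a covariance pair
#'
#' Implements the classical two-class CSP construction by simultaneous
#' diagonalization. The composite covariance R = R1 + R2 is
#' eigendecomposed as R = U L U'; the whitening transform P = L^(-1/2) U'
#' gives P R P' = I. The whitened class-1 covariance S1 = P R1 P' is then
#' eigendecomposed as S1 = B L1 B' with eigenvalues sorted in decreasing
#' order, and the filter bank is W = B' P (one filter per row). Because
#' S1 + S2 = I, the same B diagonalizes S2 with eigenvalues 1 - L1: a
#' filter with L1 eigenvalue near 1 passes class-1 variance and suppresses
#' class 2, and vice versa near 0. All N rows are retained; truncation to
#' the most discriminative rows is deferred to selection
#' (\code{\link{select_transfer_filters}}) or to the caller.
#'
#' A small shrinkage \code{gamma} toward the scaled identity regularizes
#' near-singular covariances (few trials, rank-deficient montages); it is
#' raised automatically, with a warning, when R is numerically singular.
#' Each filter row is sign-fixed so its largest-magnitude coefficient is
#' positive.
#'
#' @param R1,R2 the two class covariances (channels x channels), e.g. from
#'   \code{\link{class_covariance}}; \code{R1} may also be the list that
#'   function returns.
#' @param source_classes length-2 character, the class labels behind R1
#'   and R2 (bookkeeping only).
#' @param montage optional \code{montage} carried along for pattern export.
#' @param gamma shrinkage weight in [0, 1); default 1e-6.
#' @return An object of class \code{filter_bank}: \code{filters}
#'   (n_filters x channels), \code{eigenvalues} (whitened class-1 variance
#'   per filter, in [0, 1], non-increasing), \code{group}
#'   (\code{"high"}/\code{"low"}, the middle filter of an odd bank is
#'   \code{"none"}), \code{source_classes}, \code{source_index},
#'   \code{montage}.
#' @examples
#' b <- csp_filters(diag(c(0.8, 0.2)) / 1, diag(c(0.2, 0.8)))
#' b$eigenvalues  # 0.8, 0.2
#' @export
csp_filters <- function(R1, R2, source_classes = c("class1", "class2"),
                        montage = NULL, gamma = 1e-6) {
  if (is.list(R1) && !is.null(R1$cov)) R1 <- R1$cov
  if (is.list(R2) && !is.null(R2$cov)) R2 <- R2$cov
  stopifnot(is.matrix(R1), is.matrix(R2), all(dim(R1) == dim(R2)),
            nrow(R1) == ncol(R1))
  n <- nrow(R1)

  g <- gamma
  repeat {
    R1s <- shrink(R1, g); R2s <- shrink(R2, g)
    R <- R1s + R2s
    e <- eigen((R + t(R)) / 2, symmetric = TRUE)
    cond <- e$values[1] / e$values[n]
    if (is.finite(cond) && e$values[n] > 1e-12 * e$values[1]) break
    if (g >= 1e-2)
      stop("composite covariance is rank deficient beyond shrinkage repair ",
           "(condition number ", format(cond, digits = 3), ")", call. = FALSE)
    g <- max(g * 100, 1e-6)
    warning("near-singular composite covariance; shrinkage raised to ", g,
            call. = FALSE)
  }

  P <- diag(1 / sqrt(e$values)) %*% t(e$vectors)
  S1 <- P %*% R1s %*% t(P)
  e1 <- eigen((S1 + t(S1)) / 2, symmetric = TRUE)  # values non-increasing
  W <- t(e1$vectors) %*% P
  lambda <- pmin(pmax(e1$values, 0), 1)

  # eigenvector sign is arbitrary: make the dominant coefficient positive
  for (j in seq_len(n)) {
    k <- which.max(abs(W[j, ]))
    if (W[j, k] < 0) W[j, ] <- -W[j, ]
  }
  if (!is.null(montage)) colnames(W) <- montage$channel_names

  m <- n %/% 2L
  group <- rep("none", n)
  group[seq_len(m)] <- "high"
  group[seq.int(n - m + 1L, n)] <- "low"

  structure(
    list(filters = W, eigenvalues = lambda, group = group,
         source_classes = source_classes, source_index = seq_len(n),
         montage = montage, gamma = g),
    class = "filter_bank")
}

#' @export
print.filter_bank <- function(x, ...) {
  cat("<filter_bank> ", nrow(x$filters), " filters x ", ncol(x$filters),
      " channels (", x$source_classes[1], " vs ", x$source_classes[2],
      ")\n", sep = "")
  cat("eigenvalues: ", paste(sprintf("%.3f", utils::head(x$eigenvalues, 6)),
                             collapse = " "),
      if (length(x$eigenvalues) > 6) " ..." else "", "\n", sep = "")
  invisible(x)
}

#' Subset a filter bank
#' @param x a \code{filter_bank}.
#' @param i filter (row) indices.
#' @export
`[.filter_bank` <- function(x, i, ...) {
  structure(
    list(filters = x$filters[i, , drop = FALSE],
         eigenvalues = x$eigenvalues[i],
         group = x$group[i],
         source_classes = x$source_classes,
         source_index = x$source_index[i],
         montage = x$montage, gamma = x$gamma),
    class = "filter_bank")
}

#' Spatial patterns (forward model) of a filter bank
#'
#' The pattern paired with each spatial filter is the corresponding column
#' of the inverse of the full filter matrix: if Z = W X, then X = A Z with
#' A = W^(-1), and column j of A is the scalp projection of the source
#' that filter j extracts. Patterns, not filters, are what should be
#' inspected physiologically. For a square full-rank bank the patterns are
#' exact; a bank produced by selection carries the patterns inherited from
#' its full parent bank.
#'
#' @param bank a \code{filter_bank}.
#' @return An object of class \code{pattern_map}: \code{patterns}
#'   (n_filters x channels, one pattern per row), plus the bank's
#'   eigenvalues, groups and montage.
#' @export
spatial_patterns <- function(bank) {
  stopifnot(inherits(bank, "filter_bank"))
  W <- bank$filters
  if (!is.null(bank$patterns)) {
    A <- bank$patterns
  } else if (nrow(W) == ncol(W)) {
    Ainv <- tryCatch(solve(W),
                     error = function(e) stop("singular filter matrix: ",
                                              conditionMessage(e), call. = FALSE))
    A <- t(Ainv)
  } else {
    stop("bank is not square and carries no inherited patterns; ",
         "compute patterns on the full bank before selection", call. = FALSE)
  }
  if (!is.null(bank$montage)) colnames(A) <- bank$montage$channel_names
  structure(
    list(patterns = A, eigenvalues = bank$eigenvalues, group = bank$group,
         montage = bank$montage),
    class = "pattern_map")
}

#' @export
print.pattern_map <- function(x, ...) {
  cat("<pattern_map> ", nrow(x$patterns), " patterns x ", ncol(x$patterns),
      " channels\n", sep = "")
  invisible(x)
}

#' Export patterns as a long table
#'
#' One row per (filter, channel) with the pattern value and, when a
#' montage is attached, the 2-D channel coordinates — the layout external
#' topographic plotting tools expect.
#'
#' @param pm a \code{pattern_map}.
#' @param path optional file; when given, written as TSV.
#' @return A data.frame (invisibly when \code{path} is given).
#' @export
pattern_table <- function(pm, path = NULL) {
  stopifnot(inherits(pm, "pattern_map"))
  nf <- nrow(pm$patterns); nc <- ncol(pm$patterns)
  ch <- if (!is.null(pm$montage)) pm$montage$channel_names else
    paste0("ch", seq_len(nc))
  out <- data.frame(
    filter = rep(seq_len(nf), each = nc),
    channel = rep(ch, nf),
    value = as.vector(t(pm$patterns)))
  if (!is.null(pm$montage)) {
    out$x <- rep(pm$montage$positions[, 1], nf)
    out$y <- rep(pm$montage$positions[, 2], nf)
  }
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
    return(invisible(out))
  }
  out
}
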