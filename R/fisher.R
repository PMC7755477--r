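#' Fisher discriminant ratio per feature dimension
#'
#' For every column of \code{x}, the ratio J = S_between / S_within, where
#' S_between is the class-size-weighted variance of the class means around
#' the grand mean, \code{sum_i (n_i/n) (m_i - m)^2}, and S_within is the
#' pooled within-class scatter \code{(1/n) sum_i sum_{x in class i}
#' (x - m_i)^2}. A dimension with zero within-class scatter but distinct
#' class means is perfectly separating and scores \code{Inf}; a constant
#' dimension scores 0. J is invariant to duplicating every sample (both
#' scatters are averages over n).
#'
#' @param x numeric matrix, samples x dimensions (a vector is treated as
#'   one dimension).
#' @param labels per-sample class labels, at least two classes.
#' @return An object of class \code{fisher_scores}: \code{J} (per
#'   dimension), \code{s_between}, \code{s_within}, \code{class_means}
#'   (classes x dimensions), \code{grand_mean}, \code{n_per_class}.
#' @examples
#' fisher_scores(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))$J  # 3.375
#' @export
fisher_scores <- function(x, labels) {
  if (is.vector(x)) x <- matrix(x, ncol = 1L)
  stopifnot(is.matrix(x), nrow(x) == length(labels))
  labels <- factor(labels)
  if (nlevels(labels) < 2L)
    stop("Fisher scoring needs at least two classes, got ",
         nlevels(labels), call. = FALSE)
  n <- nrow(x)
  ni <- as.vector(table(labels))
  cm <- apply(x, 2, function(col) tapply(col, labels, mean))
  cm <- matrix(cm, nrow = nlevels(labels),
               dimnames = list(levels(labels), colnames(x)))
  gm <- colMeans(x)
  s_between <- colSums((ni / n) * sweep(cm, 2, gm, `-`)^2)
  s_within <- colSums((x - cm[as.integer(labels), , drop = FALSE])^2) / n
  J <- ifelse(s_within > 0, s_between / s_within,
              ifelse(s_between > 0, Inf, 0))
  structure(
    list(J = unname(J), s_between = unname(s_between),
         s_within = unname(s_within), class_means = cm,
         grand_mean = unname(gm), n_per_class = ni),
    class = "fisher_scores")
}

# Indices selected from each eigenvalue group by Fisher score.
# Ties broken by eigenvalue extremity |lambda - 0.5| (more extreme wins),
# then by original bank order for full determinism.
fisher_select_idx <- function(J, group, eigenvalues, k_per_group,
                              mode = c("per_group", "overall")) {
  mode <- match.arg(mode)
  extremity <- abs(eigenvalues - 0.5)
  pick <- function(idx, k) {
    ord <- idx[order(-J[idx], -extremity[idx], idx)]
    ord[seq_len(k)]
  }
  if (mode == "per_group") {
    sel <- c(pick(which(group == "high"), k_per_group),
             pick(which(group == "low"), k_per_group))
  } else {
    sel <- pick(which(group != "none"), 2L * k_per_group)
  }
  sort(sel)
}

#' Transfer a source filter bank to a target task by Fisher selection
#'
#' Scores every filter of a source-task bank on a (small) target-task
#' training set and keeps the most discriminative ones, balanced across
#' the bank's two eigenvalue groups. Each target trial is projected
#' through the full bank, normalized log-variance features are computed
#' over the whole bank (the same transform later used for
#' classification), and each feature dimension — i.e. each filter — is
#' scored with \code{\link{fisher_scores}}. The \code{k_per_group}
#' highest-scoring filters in the high-eigenvalue group and likewise in
#' the low group are kept (\code{mode = "overall"} instead keeps the
#' \code{2 k_per_group} best regardless of group), and returned re-sorted
#' by source eigenvalue. The default \code{k_per_group = 2} keeps 4
#' filters, the usual operating point. The middle filter of an odd-sized
#' bank belongs to neither group and is never selected.
#'
#' @param bank a full \code{filter_bank} built from source-task data.
#' @param target_train an \code{\link{epochs}} set with exactly two
#'   classes and at least 2 trials per class (5 per class is the intended
#'   operating point).
#' @param k_per_group filters kept per group; at most half the bank size.
#' @param window analysis window (s, cue-relative) for the scoring
#'   features; \code{NULL} for the whole trial.
#' @param mode \code{"per_group"} (default, balanced) or \code{"overall"}.
#' @return A list with \code{bank} (the transferred \code{filter_bank},
#'   \code{2 k_per_group} rows, patterns inherited from the full bank when
#'   it is square) and \code{report} (a \code{fisher_report}: per-filter
#'   data.frame of group, eigenvalue, J and selection mask, plus the
#'   scoring components).
#' @export
select_transfer_filters <- function(bank, target_train, k_per_group = 2L,
                                    window = c(0, 2),
                                    mode = c("per_group", "overall")) {
  stopifnot(inherits(bank, "filter_bank"), inherits(target_train, "epochs"))
  mode <- match.arg(mode)
  labels <- droplevels(factor(target_train$labels))
  if (nlevels(labels) != 2L)
    stop("target training set must have exactly 2 classes, got ",
         nlevels(labels), call. = FALSE)
  cnt <- table(labels)
  if (any(cnt < 2L))
    stop("need at least 2 target training trials per class (got ",
         paste(cnt, collapse = "/"), "); 5 per class is the intended ",
         "operating point", call. = FALSE)
  nf <- nrow(bank$filters)
  if (k_per_group > nf %/% 2L)
    stop("k_per_group = ", k_per_group, " exceeds half the bank size (",
         nf %/% 2L, ")", call. = FALSE)

  v <- trial_band_variances(bank, target_train, window)
  feats <- log(v / rowSums(v))
  fs <- fisher_scores(feats, labels)
  sel <- fisher_select_idx(fs$J, bank$group, bank$eigenvalues, k_per_group,
                           mode)
  # re-sort by source eigenvalue (descending), i.e. original bank order
  sel <- sel[order(-bank$eigenvalues[sel], sel)]

  sub <- bank[sel]
  if (nrow(bank$filters) == ncol(bank$filters))
    sub$patterns <- spatial_patterns(bank)$patterns[sel, , drop = FALSE]

  report <- structure(
    list(table = data.frame(
           filter_index = seq_len(nf),
           group = bank$group,
           eigenvalue = bank$eigenvalues,
           J = fs$J,
           selected = seq_len(nf) %in% sel),
         scores = fs, k_per_group = as.integer(k_per_group), mode = mode,
         target_classes = levels(labels)),
    class = "fisher_report")
  list(bank = sub, report = report)
}

#' @export
print.fisher_report <- function(x, ...) {
  cat("<fisher_report> ", sum(x$table$selected), " of ", nrow(x$table),
      " filters selected (", x$k_per_group, " per group, mode=", x$mode,
      ") for ", paste(x$target_classes, collapse = " vs "), "\n", sep = "")
  print(utils::head(x$table[order(-x$table$J), ], 8), row.names = FALSE)
  invisible(x)
}

#' Write a Fisher report as TSV
#' @param report a \code{fisher_report}.
#' @param path output file.
#' @export
write_fisher_report <- function(report, path) {
  stopifnot(inherits(report, "fisher_report"))
  utils::write.table(report$table, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
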