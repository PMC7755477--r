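#' Project epochs through a filter bank
#'
#' Applies the linear map Z = W X to each trial: one output row per
#' filter, one column per sample.
#'
#' @param bank a \code{filter_bank}.
#' @param x an \code{\link{epochs}} set with matching channel count.
#' @param window optional cue-relative window (s) to crop first.
#' @return A list of Z matrices (n_filters x samples), one per trial.
#' @export
project_epochs <- function(bank, x, window = NULL) {
  stopifnot(inherits(bank, "filter_bank"), inherits(x, "epochs"))
  if (!is.null(window)) x <- crop_epochs(x, window)
  if (ncol(bank$filters) != dim(x$data)[2L])
    stop("bank expects ", ncol(bank$filters), " channels but epochs have ",
         dim(x$data)[2L], call. = FALSE)
  lapply(seq_len(n_trials(x)), function(i) bank$filters %*% x$data[i, , ])
}

#' Normalized log-variance features of a projected trial
#'
#' For a trial's projection Z (rows = filters), computes
#' f_p = log(var_p / sum_q var_q), where var_p is the population variance
#' (1/G, about the row mean) of row p. The variance shares sum to 1 before
#' the log, so the features are invariant to any global amplitude scaling
#' of the data.
#'
#' @param Z numeric matrix, filters x samples (at least 2 samples).
#' @return Numeric vector of length \code{nrow(Z)}.
#' @examples
#' # two rows with variances 3 and 1 -> log(0.75), log(0.25)
#' @export
logvar_features <- function(Z) {
  stopifnot(is.matrix(Z), ncol(Z) >= 2L)
  v <- rowMeans(Z^2) - rowMeans(Z)^2
  s <- sum(v)
  if (s <= 0)
    stop("all-zero projection: log-variance features undefined", call. = FALSE)
  log(v / s)
}

# Per-trial population variances of the bank projection, via quadratic
# forms on centered per-trial scatter matrices (exactly var(W X) rowwise,
# but O(channels^2) per trial instead of re-projecting).
trial_band_variances <- function(bank, x, window = NULL) {
  if (!is.null(window)) x <- crop_epochs(x, window)
  if (ncol(bank$filters) != dim(x$data)[2L])
    stop("bank expects ", ncol(bank$filters), " channels but epochs have ",
         dim(x$data)[2L], call. = FALSE)
  W <- bank$filters
  G <- dim(x$data)[3L]
  t(vapply(seq_len(n_trials(x)), function(i) {
    X <- x$data[i, , ]
    mu <- rowMeans(X)
    WX <- W %*% X
    rowMeans(WX^2) - (W %*% mu)^2
  }, numeric(nrow(W))))
}

#' Feature table for a bank over an epoch set
#'
#' Convenience wrapper: normalized log-variance features
#' (\code{\link{logvar_features}}) of every trial projected through the
#' bank, with labels.
#'
#' @inheritParams project_epochs
#' @return An object of class \code{feature_table}: \code{features}
#'   (trials x n_filters), \code{labels}, \code{n_filters}.
#' @export
feature_table <- function(bank, x, window = c(0, 2)) {
  v <- trial_band_variances(bank, x, window)
  if (any(rowSums(v) <= 0))
    stop("trial with all-zero projection", call. = FALSE)
  structure(
    list(features = log(v / rowSums(v)),
         labels = droplevels(factor(x$labels)),
         n_filters = nrow(bank$filters)),
    class = "feature_table")
}

#' Write a feature table as TSV
#' @param ft a \code{feature_table}.
#' @param path output file.
#' @export
write_feature_table <- function(ft, path) {
  stopifnot(inherits(ft, "feature_table"))
  df <- data.frame(trial = seq_len(nrow(ft$features)),
                   label = as.character(ft$labels))
  f <- as.data.frame(ft$features)
  names(f) <- paste0("f", seq_len(ncol(f)))
  utils::write.table(cbind(df, f), path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Train the RBF-SVM classifier on log-variance features
#'
#' Features are z-scored by training statistics (log-variance features
#' have very different scales across filters, and the RBF kernel is not
#' scale invariant), then a support vector machine with Gaussian kernel
#' is tuned by stratified cross-validation over a logarithmic grid of the
#' cost C (10^-1 to 10^3) and kernel width gamma (10^-2/d to 10^2/d, d =
#' feature dimension), and refit on all training data with the winning
#' pair. Five folds are used when every class has at least 5 samples;
#' with 2-4 samples per class the tuning degrades to leave-one-out with a
#' warning; a singleton class is an error. Fold assignment is drawn from
#' \code{seed}, so training is deterministic.
#'
#' @param x a \code{feature_table} with labels, or a numeric feature
#'   matrix (then \code{labels} is required).
#' @param labels per-sample labels when \code{x} is a matrix.
#' @param seed integer seed for fold assignment.
#' @return An object of class \code{mi_svm} with a
#'   \code{\link{predict.mi_svm}} method.
#' @export
train_classifier <- function(x, labels = NULL, seed = 1L) {
  if (inherits(x, "feature_table")) {
    labels <- x$labels
    x <- x$features
  }
  stopifnot(is.matrix(x), !is.null(labels), nrow(x) == length(labels))
  labels <- droplevels(factor(labels))
  cnt <- table(labels)
  if (any(cnt < 2L))
    stop("class '", names(cnt)[which.min(cnt)], "' has ", min(cnt),
         " sample(s); at least 2 per class are required", call. = FALSE)

  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  xs <- scale(x, ctr, scl)

  d <- ncol(x)
  costs <- 10^seq(-1, 3)
  gammas <- 10^seq(-2, 2) / d

  k <- if (min(cnt) >= 5L) 5L else {
    warning("only ", min(cnt), " samples in the smallest class; ",
            "hyperparameter tuning degrades to leave-one-out", call. = FALSE)
    0L  # marker for LOOCV
  }
  folds <- make_folds(labels, if (k == 0L) length(labels) else k, seed,
                      loocv = k == 0L)

  best <- c(acc = -1, cost = costs[1], gamma = gammas[1])
  for (co in costs) for (ga in gammas) {
    correct <- 0L
    for (f in seq_len(max(folds))) {
      tr <- folds != f; te <- !tr
      if (length(unique(labels[tr])) < 2L) next
      fit <- e1071::svm(xs[tr, , drop = FALSE], labels[tr], cost = co,
                        gamma = ga, kernel = "radial", scale = FALSE)
      correct <- correct +
        sum(stats::predict(fit, xs[te, , drop = FALSE]) == labels[te])
    }
    acc <- correct / length(labels)
    if (acc > best["acc"] + 1e-12) best <- c(acc = acc, cost = co, gamma = ga)
  }

  fit <- e1071::svm(xs, labels, cost = best[["cost"]], gamma = best[["gamma"]],
                    kernel = "radial", scale = FALSE)
  structure(
    list(svm = fit, center = ctr, scale = scl, levels = levels(labels),
         cost = best[["cost"]], gamma = best[["gamma"]],
         cv_accuracy = best[["acc"]], seed = seed),
    class = "mi_svm")
}

# Stratified fold ids, deterministic in seed; loocv gives one fold/sample.
# Runs in a private RNG scope so the caller's random stream is untouched.
make_folds <- function(labels, k, seed, loocv = FALSE) {
  n <- length(labels)
  if (loocv) return(seq_len(n))
  folds <- integer(n)
  with_seed(seed, {
    for (lv in levels(labels)) {
      idx <- which(labels == lv)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds
}

# Evaluate expr under set.seed(seed), restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) {
    if (exists(".Random.seed", globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr  # lazily evaluated here, in the caller's environment
}

#' @export
print.mi_svm <- function(x, ...) {
  cat("<mi_svm> RBF SVM, C = ", format(x$cost), ", gamma = ",
      format(x$gamma), ", classes: ", paste(x$levels, collapse = " vs "),
      " (tuning accuracy ", sprintf("%.1f%%", 100 * x$cv_accuracy), ")\n",
      sep = "")
  invisible(x)
}

#' Predict class labels from features
#'
#' Applies the stored training standardization, then the SVM decision
#' function. Only labels seen in training can be produced.
#'
#' @param object an \code{mi_svm}.
#' @param newdata a \code{feature_table} or numeric matrix with the
#'   training feature dimension.
#' @param ... unused.
#' @return Factor of predicted labels (empty for an empty table).
#' @export
predict.mi_svm <- function(object, newdata, ...) {
  if (inherits(newdata, "feature_table")) newdata <- newdata$features
  stopifnot(is.matrix(newdata))
  if (ncol(newdata) != length(object$center))
    stop("feature dimension ", ncol(newdata), " != training dimension ",
         length(object$center), call. = FALSE)
  if (nrow(newdata) == 0L) return(factor(character(), levels = object$levels))
  xs <- scale(newdata, object$center, object$scale)
  factor(as.character(stats::predict(object$svm, xs)), levels = object$levels)
}
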