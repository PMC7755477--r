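#' Fit a task-transfer CSP classifier
#'
#' The central estimator of the package. Given an abundant two-class
#' \emph{source}-task session (e.g. left-hand vs right-hand imagery) and a
#' small \emph{target}-task training set (e.g. left-hand-and-feet vs
#' right-hand-and-feet), it
#' \enumerate{
#'   \item estimates the two source class covariances on the analysis
#'     window (\code{\link{class_covariance}}),
#'   \item builds the full CSP filter bank by simultaneous diagonalization
#'     (\code{\link{csp_filters}}),
#'   \item scores every source filter on the target training trials with
#'     the Fisher ratio of its normalized log-variance feature and keeps
#'     \code{k_per_group} filters per eigenvalue group
#'     (\code{\link{select_transfer_filters}}),
#'   \item trains an RBF SVM on the selected filters' features
#'     (\code{\link{train_classifier}}).
#' }
#' The rationale: spatial projections of the sensorimotor rhythms are
#' largely shared between a limb command and combined commands containing
#' that limb, so filters learned where data are plentiful transfer, and
#' the Fisher screening discards the source filters that do not
#' discriminate the new task. Only a handful of target trials per class
#' (five, typically) are then needed for the classifier.
#'
#' @param source \code{\link{epochs}} with exactly two classes, the
#'   source task (after band-pass filtering).
#' @param target_train \code{\link{epochs}} with exactly two classes, the
#'   target task's calibration trials.
#' @param k_per_group filters kept per eigenvalue group (default 2, i.e.
#'   4 transferred filters).
#' @param window cue-relative analysis window in seconds feeding
#'   covariances and features (default \code{c(0, 2)}, the post-cue
#'   segment).
#' @param mode Fisher selection mode, see
#'   \code{\link{select_transfer_filters}}.
#' @param gamma covariance shrinkage, see \code{\link{csp_filters}}.
#' @param seed seed for the SVM tuning folds.
#' @return An object of class \code{tcsp} with methods \code{print},
#'   \code{summary}, \code{coef} (the transferred filter rows),
#'   \code{predict} (labels for new epochs), \code{fitted} and
#'   \code{plot} (topographic maps of the transferred patterns).
#' @examples
#' \donttest{
#' sess <- simulate_session(sim_config(n_channels = 16,
#'   n_trials_per_class = 12, seed = 3))
#' ep <- bandpass_8_30(sess$epochs)
#' src <- ep[ep$labels %in% c("LH", "RH")]
#' tgt <- ep[ep$labels %in% c("LH&F", "RH&F")]
#' fit <- tcsp(src, tgt[c(1:5, 13:17)])
#' mean(predict(fit, tgt[c(6:12, 18:24)]) == tgt[c(6:12, 18:24)]$labels)
#' }
#' @export
tcsp <- function(source, target_train, k_per_group = 2L, window = c(0, 2),
                 mode = c("per_group", "overall"), gamma = 1e-6, seed = 1L) {
  stopifnot(inherits(source, "epochs"), inherits(target_train, "epochs"))
  mode <- match.arg(mode)
  src_classes <- levels(droplevels(factor(source$labels)))
  if (length(src_classes) != 2L)
    stop("source must contain exactly 2 classes, got ",
         length(src_classes), call. = FALSE)

  R1 <- stage("class_covariance",
              class_covariance(source, src_classes[1], window))
  R2 <- stage("class_covariance",
              class_covariance(source, src_classes[2], window))
  bank <- stage("csp_filters",
                csp_filters(R1, R2, source_classes = src_classes,
                            montage = source$montage, gamma = gamma))
  sel <- stage("select_transfer_filters",
               select_transfer_filters(bank, target_train, k_per_group,
                                       window, mode))
  ft <- stage("logvar_features", feature_table(sel$bank, target_train, window))
  model <- stage("train_classifier", train_classifier(ft, seed = seed))

  structure(
    list(source_bank = bank, bank = sel$bank, fisher = sel$report,
         model = model, window = window, k_per_group = as.integer(k_per_group),
         mode = mode, source_classes = src_classes,
         target_classes = levels(ft$labels), training = ft,
         call = match.call()),
    class = "tcsp")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("in stage '", name, "': ", conditionMessage(e), call. = FALSE))
}

#' @export
print.tcsp <- function(x, ...) {
  cat("Task-transfer CSP classifier\n")
  cat("  source: ", paste(x$source_classes, collapse = " vs "),
      " (", nrow(x$source_bank$filters), "-filter bank)\n", sep = "")
  cat("  target: ", paste(x$target_classes, collapse = " vs "),
      " (", length(x$training$labels), " training trials)\n", sep = "")
  cat("  transferred filters: ", nrow(x$bank$filters), " (",
      x$k_per_group, " per group, mode=", x$mode, "), source indices ",
      paste(x$bank$source_index, collapse = ", "), "\n", sep = "")
  cat("  SVM: C = ", format(x$model$cost), ", gamma = ",
      format(x$model$gamma), "\n", sep = "")
  invisible(x)
}

#' @export
summary.tcsp <- function(object, ...) {
  out <- list(fit = object,
              fisher = object$fisher$table,
              training_accuracy =
                mean(fitted(object) == object$training$labels))
  class(out) <- "summary.tcsp"
  out
}

#' @export
print.summary.tcsp <- function(x, ...) {
  print(x$fit)
  cat("  training accuracy: ",
      sprintf("%.1f%%", 100 * x$training_accuracy), "\n\n", sep = "")
  cat("Fisher screening of source filters (top 8 by J):\n")
  tab <- x$fisher[order(-x$fisher$J), ]
  print(utils::head(tab, 8), row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
coef.tcsp <- function(object, ...) object$bank$filters

#' @export
fitted.tcsp <- function(object, ...) {
  predict(object$model, object$training)
}

#' Predict target-task labels for new epochs
#' @param object a fitted \code{\link{tcsp}} model.
#' @param newdata an \code{\link{epochs}} set (same montage/channel count).
#' @param ... unused.
#' @return Factor of predicted class labels, one per trial.
#' @export
predict.tcsp <- function(object, newdata, ...) {
  stopifnot(inherits(newdata, "epochs"))
  if (n_trials(newdata) == 0L)
    return(factor(character(), levels = object$model$levels))
  ft <- feature_table(object$bank, newdata, object$window)
  predict(object$model, ft)
}

#' Topographic plot of spatial patterns
#'
#' Draws each pattern as colored discs at the montage coordinates (red
#' positive, blue negative, area proportional to magnitude) inside a head
#' outline — a dependency-free stand-in for a full topographic
#' interpolation, adequate for judging lateralization.
#'
#' @param x a \code{pattern_map}.
#' @param filters which pattern rows to draw (default up to the first 4).
#' @param ... unused.
#' @export
plot.pattern_map <- function(x, filters = seq_len(min(4L, nrow(x$patterns))),
                             ...) {
  if (is.null(x$montage)) stop("pattern map has no montage", call. = FALSE)
  pos <- x$montage$positions
  old <- graphics::par(mfrow = grDevices::n2mfrow(length(filters)),
                       mar = c(1, 1, 2, 1))
  on.exit(graphics::par(old))
  th <- seq(0, 2 * pi, length.out = 181)
  for (j in filters) {
    v <- x$patterns[j, ]
    graphics::plot(cos(th), sin(th), type = "l", asp = 1, axes = FALSE,
                   xlab = "", ylab = "",
                   main = sprintf("pattern %d (lambda=%.2f)", j,
                                  x$eigenvalues[j]))
    graphics::points(pos[, 1], pos[, 2],
                     cex = 0.3 + 2.5 * abs(v) / max(abs(v)),
                     pch = 19,
                     col = ifelse(v >= 0, "#d62728aa", "#1f77b4aa"))
  }
  invisible(x)
}

#' @export
plot.tcsp <- function(x, ...) {
  plot(spatial_patterns(x$bank), ...)
}
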