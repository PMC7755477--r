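#' Source/target task pairing
#'
#' Records which source-task pair trains the filter bank for a target-task
#' pair. \code{default_source_classes} implements the similarity rule of
#' thumb for combined commands: classify LH&F vs RH&F with LH vs RH as
#' source (the differing limbs), and LH&RH vs RH&F with F vs RH.
#'
#' @param source_classes,target_classes length-2 character vectors.
#' @param rationale free-text note on why this pairing.
#' @return A \code{task_spec} list.
#' @export
task_spec <- function(source_classes, target_classes, rationale = "") {
  stopifnot(length(source_classes) == 2L, length(target_classes) == 2L,
            source_classes[1] != source_classes[2])
  structure(list(source_classes = source_classes,
                 target_classes = target_classes,
                 rationale = rationale),
            class = "task_spec")
}

#' @rdname task_spec
#' @export
default_source_classes <- function(target_classes) {
  key <- paste(sort(target_classes), collapse = "|")
  switch(key,
         "LH&F|RH&F" = c("LH", "RH"),
         "LH&RH|RH&F" = c("F", "RH"),
         "LH&F|LH&RH" = c("F", "RH"),
         NULL)
}

#' Run the full transfer pipeline on explicit splits
#'
#' Convenience orchestration of the whole scheme — covariances, CSP bank,
#' Fisher transfer, features, SVM, prediction — returning the predictions
#' together with every intermediate artifact for inspection. Errors are
#' annotated with the stage that raised them.
#'
#' @param source two-class source \code{\link{epochs}}.
#' @param target_train two-class target calibration \code{\link{epochs}}.
#' @param target_test target \code{\link{epochs}} to label (may be empty).
#' @param ... passed to \code{\link{tcsp}} (\code{k_per_group},
#'   \code{window}, \code{mode}, \code{gamma}, \code{seed}).
#' @return List: \code{predictions}, \code{model} (\code{tcsp}),
#'   \code{bank} (transferred), \code{source_bank}, \code{fisher_report},
#'   \code{patterns} (of the transferred bank).
#' @export
run_transfer_pipeline <- function(source, target_train, target_test, ...) {
  fit <- tcsp(source, target_train, ...)
  preds <- stage("predict", predict(fit, target_test))
  list(predictions = preds, model = fit, bank = fit$bank,
       source_bank = fit$source_bank, fisher_report = fit$fisher,
       patterns = spatial_patterns(fit$bank))
}

#' CSP baseline: filters from the target training data alone
#'
#' Classical small-sample CSP: build the filter bank from the (few)
#' target training trials, keep the \code{m} first and \code{m} last
#' rows, then the same log-variance features and SVM as the transfer
#' pipeline. This is the comparator the transfer method is meant to beat
#' when calibration data are scarce.
#'
#' @param target_train,target_test two-class target \code{\link{epochs}}.
#' @param m filters kept from each end of the eigenvalue spectrum
#'   (default 2, so 4 filters).
#' @param window analysis window (s).
#' @param gamma covariance shrinkage (raised automatically if needed).
#' @param seed SVM tuning seed.
#' @return List: \code{predictions}, \code{bank}, \code{model}.
#' @export
csp_baseline <- function(target_train, target_test, m = 2L,
                         window = c(0, 2), gamma = 1e-6, seed = 1L) {
  classes <- levels(droplevels(factor(target_train$labels)))
  if (length(classes) != 2L)
    stop("target training set must have exactly 2 classes", call. = FALSE)
  R1 <- class_covariance(target_train, classes[1], window)
  R2 <- class_covariance(target_train, classes[2], window)
  bank <- csp_filters(R1, R2, source_classes = classes,
                      montage = target_train$montage, gamma = gamma)
  nf <- nrow(bank$filters)
  if (2L * m > nf) stop("m = ", m, " too large for ", nf, " channels",
                        call. = FALSE)
  keep <- c(seq_len(m), seq.int(nf - m + 1L, nf))
  sub <- bank[keep]
  model <- train_classifier(feature_table(sub, target_train, window),
                            seed = seed)
  preds <- if (n_trials(target_test) == 0L)
    factor(character(), levels = model$levels)
  else predict(model, feature_table(sub, target_test, window))
  list(predictions = preds, bank = sub, model = model)
}

#' PSD baseline: band power at the sensorimotor channels
#'
#' Per trial, Welch PSD at the named channels over the analysis window;
#' features are the log 8-30 Hz band power of each channel plus their
#' across-channel mean (so 4 features for the default C3/Cz/C4), fed to
#' the same SVM regime. No spatial filtering at all — the floor any
#' spatial method should clear.
#'
#' @param target_train,target_test two-class target \code{\link{epochs}}.
#' @param channels channel labels (default C3, Cz, C4).
#' @param window analysis window (s).
#' @param seed SVM tuning seed.
#' @return List: \code{predictions}, \code{model}.
#' @export
psd_baseline <- function(target_train, target_test,
                         channels = c("C3", "Cz", "C4"),
                         window = c(0, 2), seed = 1L) {
  ftr <- psd_features(target_train, channels, window)
  model <- train_classifier(ftr, target_train$labels, seed = seed)
  preds <- if (n_trials(target_test) == 0L)
    factor(character(), levels = model$levels)
  else predict(model, psd_features(target_test, channels, window))
  list(predictions = preds, model = model)
}

#' Inverted cross-validation over a target session
#'
#' The scarce-calibration protocol: the target trials are split into
#' \code{folds} stratified folds, and for each fold the model is trained
#' on that \emph{single} fold (1/12 of the data by default — 5 trials per
#' class for a 60-per-class session) and tested on the remaining 11/12.
#' The whole split is reshuffled \code{reps} times from a seeded stream,
#' giving \code{reps * folds} accuracy values per method.
#'
#' Methods: \code{"transfer_csp"} (source-bank filters + Fisher
#' selection; requires \code{source}), \code{"csp"} (filters from the
#' training fold alone), \code{"psd"} (band-power features). Pass
#' band-pass-filtered epochs; the protocol does no preprocessing itself.
#'
#' @param target two-class target \code{\link{epochs}}.
#' @param source two-class source \code{\link{epochs}} (only needed for
#'   \code{"transfer_csp"}).
#' @param methods subset of \code{c("transfer_csp", "csp", "psd")}.
#' @param folds number of folds (default 12); if the per-class trial
#'   counts are not divisible, the nearest divisor is used with a warning.
#' @param reps independent reshuffles (default 5).
#' @param k_per_group,mode transfer selection parameters.
#' @param m CSP-baseline filters per end.
#' @param channels PSD-baseline channels.
#' @param window analysis window (s).
#' @param gamma covariance shrinkage.
#' @param seed master seed; fold shuffles and SVM tuning derive from it.
#' @return An \code{accuracy_report}: \code{accuracy} (reps x folds x
#'   methods array), per-method \code{summary} (mean/max/min), and the
#'   protocol parameters.
#' @export
inverted_cv <- function(target, source = NULL,
                        methods = c("transfer_csp", "csp", "psd"),
                        folds = 12L, reps = 5L, k_per_group = 2L,
                        mode = c("per_group", "overall"), m = 2L,
                        channels = c("C3", "Cz", "C4"),
                        window = c(0, 2), gamma = 1e-6, seed = 1L) {
  stopifnot(inherits(target, "epochs"))
  mode <- match.arg(mode)
  methods <- match.arg(methods, several.ok = TRUE)
  labels <- droplevels(factor(target$labels))
  if (nlevels(labels) != 2L)
    stop("target must have exactly 2 classes", call. = FALSE)
  cnt <- table(labels)

  f <- as.integer(folds)
  while (f > 1L && any(cnt %% f != 0L)) f <- f - 1L
  if (f != folds)
    warning("per-class counts (", paste(cnt, collapse = "/"),
            ") not divisible into ", folds, " folds; using ", f,
            call. = FALSE)

  # ---- precomputation shared across folds ----
  tgt <- crop_epochs(target, window)
  ntr <- n_trials(tgt)
  nch <- dim(tgt$data)[2L]

  src_bank <- NULL
  vfull <- NULL
  if ("transfer_csp" %in% methods) {
    if (is.null(source)) stop("transfer_csp requires source epochs",
                              call. = FALSE)
    src_classes <- levels(droplevels(factor(source$labels)))
    if (length(src_classes) != 2L)
      stop("source must have exactly 2 classes", call. = FALSE)
    R1 <- class_covariance(source, src_classes[1], window)
    R2 <- class_covariance(source, src_classes[2], window)
    src_bank <- csp_filters(R1, R2, source_classes = src_classes,
                            montage = source$montage, gamma = gamma)
    vfull <- trial_band_variances(src_bank, tgt, NULL)
  }

  scat_raw <- scat_cent <- NULL
  if ("csp" %in% methods) {
    scat_raw <- array(0, c(ntr, nch, nch))
    scat_cent <- array(0, c(ntr, nch, nch))
    G <- dim(tgt$data)[3L]
    for (i in seq_len(ntr)) {
      X <- tgt$data[i, , ]
      S <- tcrossprod(X)
      scat_raw[i, , ] <- S / sum(diag(S))
      mu <- rowMeans(X)
      scat_cent[i, , ] <- S / G - tcrossprod(mu)
    }
  }

  psd_f <- if ("psd" %in% methods) psd_features(target, channels, window)

  acc <- array(NA_real_, c(reps, f, length(methods)),
               dimnames = list(NULL, NULL, methods))
  for (r in seq_len(reps)) {
    fold_id <- make_folds(labels, f,
                          seed = as.integer((seed * 1009 + r) %% 2147483647))
    for (k in seq_len(f)) {
      tr <- fold_id == k
      te <- !tr
      svm_seed <- as.integer((seed * 7919 + r * 101 + k) %% 2147483647)
      truth <- labels[te]

      if ("transfer_csp" %in% methods) {
        feats_full <- log(vfull / rowSums(vfull))
        J <- fisher_scores(feats_full[tr, , drop = FALSE], labels[tr])$J
        sel <- fisher_select_idx(J, src_bank$group, src_bank$eigenvalues,
                                 k_per_group, mode)
        vs <- vfull[, sel, drop = FALSE]
        feats <- log(vs / rowSums(vs))
        mdl <- suppressWarnings(
          train_classifier(feats[tr, , drop = FALSE], labels[tr],
                           seed = svm_seed))
        p <- predict(mdl, feats[te, , drop = FALSE])
        acc[r, k, "transfer_csp"] <- mean(p == truth)
      }

      if ("csp" %in% methods) {
        cls <- levels(labels)
        idx1 <- which(tr & labels == cls[1]); idx2 <- which(tr & labels == cls[2])
        R1 <- apply(scat_raw[idx1, , , drop = FALSE], c(2, 3), mean)
        R2 <- apply(scat_raw[idx2, , , drop = FALSE], c(2, 3), mean)
        bank <- suppressWarnings(
          csp_filters(R1, R2, source_classes = cls,
                      montage = tgt$montage, gamma = gamma))
        nf <- nrow(bank$filters)
        W <- bank$filters[c(seq_len(m), seq.int(nf - m + 1L, nf)), ,
                          drop = FALSE]
        v <- t(vapply(seq_len(ntr), function(i)
          diag(W %*% scat_cent[i, , ] %*% t(W)), numeric(2L * m)))
        feats <- log(v / rowSums(v))
        mdl <- suppressWarnings(
          train_classifier(feats[tr, , drop = FALSE], labels[tr],
                           seed = svm_seed))
        p <- predict(mdl, feats[te, , drop = FALSE])
        acc[r, k, "csp"] <- mean(p == truth)
      }

      if ("psd" %in% methods) {
        mdl <- suppressWarnings(
          train_classifier(psd_f[tr, , drop = FALSE], labels[tr],
                           seed = svm_seed))
        p <- predict(mdl, psd_f[te, , drop = FALSE])
        acc[r, k, "psd"] <- mean(p == truth)
      }
    }
  }

  summ <- data.frame(
    method = methods,
    mean = vapply(methods, function(mm) mean(acc[, , mm]), 1.0),
    max = vapply(methods, function(mm) max(acc[, , mm]), 1.0),
    min = vapply(methods, function(mm) min(acc[, , mm]), 1.0),
    row.names = NULL)

  structure(
    list(accuracy = acc, summary = summ, methods = methods,
         folds = f, reps = reps, seed = seed,
         train_per_fold = as.integer(cnt %/% f),
         task = paste(levels(labels), collapse = " vs ")),
    class = "accuracy_report")
}

fmt_acc <- function(mean, max, min) {
  sprintf("%.2f%% (%.2f%%-%.2f%%)", 100 * mean, 100 * max, 100 * min)
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat("<accuracy_report> ", x$task, ": ", x$reps, " x ", x$folds,
      "-fold inverted CV (train ", paste(x$train_per_fold, collapse = "+"),
      " trials/fold)\n", sep = "")
  for (i in seq_len(nrow(x$summary)))
    cat(sprintf("  %-14s %s\n", x$summary$method[i],
                fmt_acc(x$summary$mean[i], x$summary$max[i],
                        x$summary$min[i])))
  invisible(x)
}

#' Comparison table across sessions
#'
#' Formats one or more \code{accuracy_report}s as the conventional
#' mean (max-min) comparison: one row per session, one column per method
#' with cells \code{"mean\% (max\%-min\%)"}, plus a column of the
#' transfer-minus-CSP mean difference in percentage points when both
#' methods are present. With \code{path}, also written as TSV;
#' \code{format = "markdown"} returns a markdown table string instead.
#'
#' @param reports a single \code{accuracy_report} or a (preferably named)
#'   list of them; an empty list yields a header-only table.
#' @param format \code{"data.frame"} (default) or \code{"markdown"}.
#' @param path optional TSV output path.
#' @export
accuracy_table <- function(reports, format = c("data.frame", "markdown"),
                           path = NULL) {
  format <- match.arg(format)
  if (inherits(reports, "accuracy_report")) reports <- list(reports)
  stopifnot(is.list(reports))
  methods <- if (length(reports)) reports[[1L]]$methods else
    c("transfer_csp", "csp", "psd")
  nm <- names(reports)
  if (is.null(nm) || any(nm == ""))
    nm <- if (length(reports)) paste0("session", seq_along(reports)) else
      character(0)

  rows <- lapply(reports, function(r) {
    cells <- vapply(methods, function(mm) {
      i <- match(mm, r$summary$method)
      if (is.na(i)) return(NA_character_)
      fmt_acc(r$summary$mean[i], r$summary$max[i], r$summary$min[i])
    }, "")
    out <- c(task = r$task, cells)
    if (all(c("transfer_csp", "csp") %in% r$summary$method)) {
      d <- 100 * (r$summary$mean[r$summary$method == "transfer_csp"] -
                    r$summary$mean[r$summary$method == "csp"])
      out <- c(out, transfer_minus_csp = sprintf("%+.2f", d))
    }
    out
  })
  cols <- c("task", methods,
            if (length(rows) && "transfer_minus_csp" %in% names(rows[[1L]]))
              "transfer_minus_csp")
  df <- as.data.frame(matrix(NA_character_, length(rows), length(cols),
                             dimnames = list(nm, cols)),
                      stringsAsFactors = FALSE)
  for (i in seq_along(rows)) df[i, names(rows[[i]])] <- rows[[i]]

  if (!is.null(path))
    utils::write.table(cbind(session = rownames(df), df), path, sep = "\t",
                       row.names = FALSE, quote = FALSE)
  if (format == "markdown") {
    hdr <- paste0("| session | ", paste(cols, collapse = " | "), " |")
    sep <- paste0("|", paste(rep("---", length(cols) + 1L), collapse = "|"),
                  "|")
    body <- vapply(seq_len(nrow(df)), function(i)
      paste0("| ", rownames(df)[i], " | ",
             paste(df[i, ], collapse = " | "), " |"), "")
    return(paste(c(hdr, sep, body), collapse = "\n"))
  }
  df
}
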