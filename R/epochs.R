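#' Epoched EEG trials
#'
#' Container for a set of fixed-length multichannel trials: a
#' trials x channels x samples array in microvolts, one class label per
#' trial, the sampling rate, the montage, and the time of sample 1 relative
#' to the task cue (\code{t0_offset_s}; negative means the trial starts
#' before the cue).
#'
#' @param data numeric array, trials x channels x samples.
#' @param labels per-trial class labels (coerced to factor).
#' @param fs sampling rate in Hz.
#' @param montage a \code{montage} with as many channels as \code{dim(data)[2]}.
#' @param t0_offset_s time (s) of the first sample relative to the cue.
#' @return An object of class \code{epochs}.
#' @export
epochs <- function(data, labels, fs, montage, t0_offset_s = 0) {
  if (length(dim(data)) != 3L)
    stop("data must be a 3-d array (trials x channels x samples)", call. = FALSE)
  if (length(labels) != dim(data)[1L])
    stop("label count (", length(labels), ") != trial count (", dim(data)[1L], ")",
         call. = FALSE)
  if (!is.numeric(fs) || fs <= 0) stop("fs must be > 0", call. = FALSE)
  stopifnot(inherits(montage, "montage"))
  if (montage$n_channels != dim(data)[2L])
    stop("montage has ", montage$n_channels, " channels but data has ",
         dim(data)[2L], call. = FALSE)
  structure(
    list(data = data, labels = factor(labels), fs = fs,
         montage = montage, t0_offset_s = t0_offset_s),
    class = "epochs")
}

#' @export
print.epochs <- function(x, ...) {
  d <- dim(x$data)
  cat("<epochs> ", d[1L], " trials x ", d[2L], " channels x ", d[3L],
      " samples @ ", x$fs, " Hz (t0 = ", x$t0_offset_s, " s)\n", sep = "")
  print(table(x$labels))
  invisible(x)
}

#' @export
`[.epochs` <- function(x, i, ...) {
  epochs(x$data[i, , , drop = FALSE], x$labels[i], x$fs, x$montage, x$t0_offset_s)
}

#' Number of trials in an epoch set
#' @param x an \code{epochs} object.
#' @export
n_trials <- function(x) {
  stopifnot(inherits(x, "epochs"))
  dim(x$data)[1L]
}

#' Restrict epochs to a cue-relative time window
#'
#' Returns the same trials cropped to \code{[window[1], window[2])} seconds
#' relative to the cue (half-open, so the sample at \code{window[2]} is
#' excluded). This is how the analysis sub-window feeding covariance and
#' feature estimation is selected (by default the post-cue segment).
#'
#' @param x an \code{epochs} object.
#' @param window length-2 numeric, seconds relative to the cue.
#' @export
crop_epochs <- function(x, window) {
  stopifnot(inherits(x, "epochs"), length(window) == 2L, window[2] > window[1])
  ns <- dim(x$data)[3L]
  i0 <- round((window[1] - x$t0_offset_s) * x$fs) + 1
  i1 <- round((window[2] - x$t0_offset_s) * x$fs)
  if (i0 < 1 || i1 > ns)
    stop("window [", window[1], ", ", window[2], ") s is outside the trial (",
         x$t0_offset_s, " to ", x$t0_offset_s + ns / x$fs, " s)", call. = FALSE)
  epochs(x$data[, , i0:i1, drop = FALSE], x$labels, x$fs, x$montage,
         t0_offset_s = window[1])
}

#' Concatenate epoch sets
#' @param ... \code{epochs} objects sharing fs, montage and trial length.
#' @export
bind_epochs <- function(...) {
  xs <- list(...)
  stopifnot(length(xs) >= 1L, all(vapply(xs, inherits, TRUE, "epochs")))
  ref <- xs[[1L]]
  for (x in xs[-1L]) {
    stopifnot(identical(dim(x$data)[2:3], dim(ref$data)[2:3]),
              x$fs == ref$fs, x$t0_offset_s == ref$t0_offset_s)
  }
  dat <- do.call(abind3, lapply(xs, `[[`, "data"))
  labs <- unlist(lapply(xs, function(x) as.character(x$labels)))
  epochs(dat, labs, ref$fs, ref$montage, ref$t0_offset_s)
}

# bind 3-d arrays along the first dimension
abind3 <- function(...) {
  xs <- list(...)
  d <- dim(xs[[1L]])
  n <- sum(vapply(xs, function(x) dim(x)[1L], 1L))
  out <- array(0, c(n, d[2L], d[3L]))
  at <- 1L
  for (x in xs) {
    k <- dim(x)[1L]
    out[at:(at + k - 1L), , ] <- x
    at <- at + k
  }
  out
}

#' Continuous multichannel recording
#'
#' A channels x samples matrix with a sampling rate, montage, event table
#' (cue onsets with class labels) and the label of the current reference
#' channel. This mirrors what an EDF export of a raw session holds.
#'
#' @param data channels x samples numeric matrix (microvolts).
#' @param fs sampling rate (Hz).
#' @param montage a \code{montage}.
#' @param events data.frame with columns \code{sample} (1-based cue sample
#'   index) and \code{label}.
#' @param reference label of the reference channel used at acquisition
#'   (default \code{"LM"}, the left mastoid).
#' @return An object of class \code{continuous_record}.
#' @export
continuous_record <- function(data, fs, montage, events, reference = "LM") {
  stopifnot(is.matrix(data), inherits(montage, "montage"), fs > 0)
  if (nrow(data) != montage$n_channels)
    stop("data has ", nrow(data), " rows but montage has ",
         montage$n_channels, " channels", call. = FALSE)
  events <- as.data.frame(events)
  stopifnot(all(c("sample", "label") %in% names(events)))
  if (nrow(events) && (any(events$sample < 1) || any(events$sample > ncol(data))))
    stop("event sample indices fall outside the record", call. = FALSE)
  structure(
    list(data = data, fs = fs, montage = montage,
         events = events, reference = reference),
    class = "continuous_record")
}

#' @export
print.continuous_record <- function(x, ...) {
  cat("<continuous_record> ", nrow(x$data), " channels x ", ncol(x$data),
      " samples @ ", x$fs, " Hz, ", nrow(x$events), " events, reference = ",
      x$reference, "\n", sep = "")
  invisible(x)
}

channel_index <- function(montage, label) {
  i <- match(label, montage$channel_names)
  if (anyNA(i))
    stop("channel(s) not in montage: ",
         paste(label[is.na(i)], collapse = ", "), call. = FALSE)
  i
}
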