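#' Re-reference from the left mastoid to linked mastoids
#'
#' Converts a record referenced at the left mastoid (LM) into the
#' linked-mastoid reference (average of LM and RM): every channel x
#' becomes \code{x - RM/2}, which is the exact algebra of switching the
#' reference from LM to (LM+RM)/2. The operation is not idempotent, so a
#' record whose \code{reference} field is no longer \code{"LM"} is
#' rejected.
#'
#' @param rec a \code{\link{continuous_record}} with \code{reference = "LM"}.
#' @return The re-referenced record, with \code{reference = "LM+RM/2"}.
#' @export
rereference_linked_mastoids <- function(rec) {
  stopifnot(inherits(rec, "continuous_record"))
  if (!identical(rec$reference, "LM"))
    stop("record is referenced to '", rec$reference,
         "', not 'LM'; linked-mastoid re-referencing applies once, ",
         "starting from a left-mastoid reference", call. = FALSE)
  rm_i <- channel_index(rec$montage, "RM")
  rec$data <- sweep(rec$data, 2, rec$data[rm_i, ] / 2, `-`)
  rec$reference <- "LM+RM/2"
  rec
}

#' Interpolate bad channels from their neighbours
#'
#' Replaces each bad channel, samplewise, by the arithmetic mean of its
#' non-bad neighbours; all other channels are untouched. Neighbourhoods
#' default to montage geometry (\code{\link{montage_neighbors}}).
#'
#' @param rec a \code{\link{continuous_record}}.
#' @param bad character vector of bad channel labels (may be empty).
#' @param neighbor_map named list, channel -> neighbour labels; defaults to
#'   the montage's 4-nearest-neighbour map.
#' @export
interpolate_bad_channels <- function(rec, bad, neighbor_map = NULL) {
  stopifnot(inherits(rec, "continuous_record"))
  if (length(bad) == 0L) return(rec)
  channel_index(rec$montage, bad)  # validates labels
  if (is.null(neighbor_map)) neighbor_map <- montage_neighbors(rec$montage)
  out <- rec$data
  for (ch in bad) {
    nb <- setdiff(neighbor_map[[ch]], bad)
    if (length(nb) < 2L)
      stop("cannot interpolate '", ch, "': fewer than 2 good neighbours (",
           length(nb), ")", call. = FALSE)
    out[channel_index(rec$montage, ch), ] <-
      colMeans(rec$data[channel_index(rec$montage, nb), , drop = FALSE])
  }
  rec$data <- out
  rec
}

# zero-phase 4th-order Butterworth band-pass over rows of a matrix
bandpass_matrix <- function(x, fs, lo = 8, hi = 30) {
  bf <- signal::butter(4, c(lo, hi) / (fs / 2), type = "pass")
  t(apply(x, 1, function(ch) signal::filtfilt(bf, ch)))
}

#' Zero-phase 8-30 Hz band-pass
#'
#' Applies a 4th-order Butterworth band-pass (8-30 Hz) forward and backward
#' (zero phase) to every channel. This isolates the mu/alpha (8-12 Hz) and
#' beta (13-30 Hz) sensorimotor rhythms whose event-related
#' (de)synchronization carries the motor-imagery signal. Works on both
#' continuous records and epoch sets (per trial).
#'
#' @param x a \code{\link{continuous_record}} or \code{\link{epochs}}.
#' @return The same type, filtered.
#' @export
bandpass_8_30 <- function(x) {
  UseMethod("bandpass_8_30")
}

#' @export
bandpass_8_30.continuous_record <- function(x) {
  if (x$fs <= 60)
    stop("fs = ", x$fs, " Hz leaves no headroom above the 30 Hz band edge",
         call. = FALSE)
  x$data <- bandpass_matrix(x$data, x$fs)
  x
}

#' @export
bandpass_8_30.epochs <- function(x) {
  if (x$fs <= 60)
    stop("fs = ", x$fs, " Hz leaves no headroom above the 30 Hz band edge",
         call. = FALSE)
  bf <- signal::butter(4, c(8, 30) / (x$fs / 2), type = "pass")
  d <- dim(x$data)
  for (i in seq_len(d[1L]))
    for (ch in seq_len(d[2L]))
      x$data[i, ch, ] <- signal::filtfilt(bf, x$data[i, ch, ])
  x
}

#' Cut cue-aligned epochs out of a continuous record
#'
#' One trial per event, spanning \code{[cue + tmin_s, cue + tmax_s)}
#' seconds (half-open: the sample at \code{tmax_s} is excluded, so each
#' trial has exactly \code{(tmax_s - tmin_s) * fs} samples). The default
#' window, 0.5 s before to 2 s after the cue, matches the usual
#' motor-imagery epoching.
#'
#' @param rec a \code{\link{continuous_record}} with a populated event table.
#' @param tmin_s,tmax_s window edges in seconds relative to the cue.
#' @return An \code{\link{epochs}} set with \code{t0_offset_s = tmin_s}.
#' @export
extract_epochs <- function(rec, tmin_s = -0.5, tmax_s = 2.0) {
  stopifnot(inherits(rec, "continuous_record"), tmax_s > tmin_s)
  fs <- rec$fs
  nspan <- round((tmax_s - tmin_s) * fs)
  i0 <- rec$events$sample + round(tmin_s * fs)
  i1 <- i0 + nspan - 1L
  badev <- which(i0 < 1 | i1 > ncol(rec$data))
  if (length(badev))
    stop("event(s) with truncated epoch window: ",
         paste(sprintf("#%d (sample %d, label %s)", badev,
                       rec$events$sample[badev],
                       rec$events$label[badev]), collapse = "; "),
         call. = FALSE)
  ne <- nrow(rec$events)
  dat <- array(0, c(ne, nrow(rec$data), nspan))
  for (e in seq_len(ne))
    dat[e, , ] <- rec$data[, i0[e]:i1[e]]
  epochs(dat, rec$events$label, fs, rec$montage, t0_offset_s = tmin_s)
}

#' Baseline-correct epochs
#'
#' Subtracts, per trial and channel, the mean over the baseline interval
#' (by default the 500 ms preceding the cue, \code{[-0.5, 0)} s). The
#' operation is idempotent.
#'
#' @param x an \code{\link{epochs}} set.
#' @param interval length-2 numeric, cue-relative seconds, half-open.
#' @export
baseline_correct <- function(x, interval = c(-0.5, 0)) {
  stopifnot(inherits(x, "epochs"), length(interval) == 2L,
            interval[2] > interval[1])
  ns <- dim(x$data)[3L]
  i0 <- round((interval[1] - x$t0_offset_s) * x$fs) + 1
  i1 <- round((interval[2] - x$t0_offset_s) * x$fs)
  if (i0 < 1 || i1 > ns || i1 < i0)
    stop("baseline interval [", interval[1], ", ", interval[2],
         ") s lies outside the trial window", call. = FALSE)
  bl <- apply(x$data[, , i0:i1, drop = FALSE], c(1, 2), mean)
  x$data <- x$data - array(bl, dim(x$data))
  x
}

#' Full preprocessing chain for a continuous record
#'
#' Runs the fixed conditioning order: linked-mastoid re-referencing, bad
#' channel interpolation, zero-phase 8-30 Hz band-pass, cue-aligned
#' epoching, baseline correction. The order is enforced here because the
#' steps do not commute (e.g. baselining must see the filtered signal).
#' Ocular-artifact removal by ICA and manual trial screening are outside
#' this chain and are expected to be done upstream when working with real
#' recordings.
#'
#' @param rec a \code{\link{continuous_record}} referenced at LM.
#' @param bad labels of bad channels (default none).
#' @param neighbor_map optional adjacency for interpolation.
#' @param tmin_s,tmax_s epoch window (s, cue-relative).
#' @param baseline baseline interval (s, cue-relative).
#' @return An \code{\link{epochs}} set.
#' @export
preprocess <- function(rec, bad = character(), neighbor_map = NULL,
                       tmin_s = -0.5, tmax_s = 2.0,
                       baseline = c(-0.5, 0)) {
  rec <- rereference_linked_mastoids(rec)
  rec <- interpolate_bad_channels(rec, bad, neighbor_map)
  rec <- bandpass_8_30(rec)
  ep <- extract_epochs(rec, tmin_s, tmax_s)
  baseline_correct(ep, baseline)
}
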