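#' Write / read an epoch set container
#'
#' Serializes an \code{\link{epochs}} object to a single-file hierarchical
#' container (R serialization of a named list) with the documented layout:
#' \code{/format} (\code{"transfercsp-epochs-v1"}), \code{/data} (trials x
#' channels x samples, microvolts), \code{/labels}, \code{/fs},
#' \code{/montage} (\code{/montage/channel_names},
#' \code{/montage/positions}), \code{/t0_offset_s}. \code{read_epochs}
#' validates every field and raises a format error naming the first field
#' that is missing or malformed, so a truncated or foreign file fails
#' loudly rather than half-loading.
#'
#' @param x an \code{epochs} object.
#' @param path file path.
#' @return \code{write_epochs} returns \code{path} invisibly;
#'   \code{read_epochs} returns the reconstructed \code{epochs} object
#'   (lossless round-trip).
#' @export
write_epochs <- function(x, path) {
  stopifnot(inherits(x, "epochs"))
  obj <- list(format = "transfercsp-epochs-v1",
              data = x$data,
              labels = as.character(x$labels),
              fs = x$fs,
              montage = list(channel_names = x$montage$channel_names,
                             positions = x$montage$positions),
              t0_offset_s = x$t0_offset_s)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  obj <- tryCatch(readRDS(path),
                  error = function(e) stop("not a readable epochs container: ",
                                           path, call. = FALSE))
  if (!is.list(obj) || !identical(obj$format, "transfercsp-epochs-v1"))
    stop("format error: missing or wrong 'format' tag", call. = FALSE)
  for (f in c("data", "labels", "fs", "montage", "t0_offset_s"))
    if (is.null(obj[[f]]))
      stop("format error: container lacks field '", f, "'", call. = FALSE)
  if (length(dim(obj$data)) != 3L)
    stop("format error: field 'data' is not a 3-d array", call. = FALSE)
  for (f in c("channel_names", "positions"))
    if (is.null(obj$montage[[f]]))
      stop("format error: container lacks field 'montage/", f, "'", call. = FALSE)
  mon <- structure(
    list(channel_names = obj$montage$channel_names,
         positions = obj$montage$positions,
         n_channels = length(obj$montage$channel_names)),
    class = "montage")
  epochs(obj$data, obj$labels, obj$fs, mon, obj$t0_offset_s)
}

fixed_str <- function(s, width) {
  s <- substr(paste0(s, strrep(" ", width)), 1, width)
  s
}

#' Export / import a continuous record as EDF
#'
#' Writes a \code{\link{continuous_record}} as a standard EDF file (16-bit
#' samples with per-channel physical scaling, 1 s data records, zero-padded
#' to a whole record; the true sample count and reference channel are kept
#' in the header's recording-identification field) plus a sidecar
#' \code{<path>.events.tsv} with columns \code{sample}, \code{label}.
#' \code{read_edf} reverses this. The round trip is exact up to 16-bit
#' amplitude quantization (relative error below 1e-4 of the channel range).
#'
#' @param rec a \code{continuous_record}; \code{fs} must be an integer.
#' @param path output path (conventionally \code{.edf}).
#' @export
write_edf <- function(rec, path) {
  stopifnot(inherits(rec, "continuous_record"))
  fs <- rec$fs
  if (fs != round(fs)) stop("EDF export requires an integer sampling rate",
                            call. = FALSE)
  nch <- nrow(rec$data)
  nsamp <- ncol(rec$data)
  nrec <- ceiling(nsamp / fs)
  pad <- nrec * fs - nsamp
  dat <- if (pad > 0) cbind(rec$data, matrix(0, nch, pad)) else rec$data

  pmax_ <- apply(abs(dat), 1, max)
  pmax_[pmax_ == 0] <- 1
  dig_max <- 32767
  dig <- round(sweep(dat, 1, pmax_ / dig_max, `/`))

  con <- file(path, "wb")
  on.exit(close(con))
  ws <- function(s, w) writeChar(fixed_str(s, w), con, eos = NULL)
  ws("0", 8)
  ws("X X X X", 80)
  ws(sprintf("nsamples=%d ref=%s", nsamp, rec$reference), 80)
  ws("01.01.00", 8); ws("00.00.00", 8)
  ws(as.character(256 * (nch + 1)), 8)
  ws("", 44)
  ws(as.character(nrec), 8)
  ws("1", 8)
  ws(as.character(nch), 4)
  labs <- rec$montage$channel_names
  for (l in labs) ws(l, 16)
  for (l in labs) ws("EEG electrode", 80)
  for (l in labs) ws("uV", 8)
  for (i in seq_len(nch)) ws(sprintf("%-.7g", -pmax_[i]), 8)
  for (i in seq_len(nch)) ws(sprintf("%-.7g", pmax_[i]), 8)
  for (l in labs) ws("-32767", 8)
  for (l in labs) ws("32767", 8)
  for (l in labs) ws("", 80)
  for (l in labs) ws(as.character(fs), 8)
  for (l in labs) ws("", 32)
  for (r in seq_len(nrec)) {
    cols <- ((r - 1) * fs + 1):(r * fs)
    writeBin(as.integer(t(dig[, cols, drop = FALSE])), con, size = 2,
             endian = "little")
  }
  utils::write.table(rec$events, paste0(path, ".events.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_edf
#' @export
read_edf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  rs <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rs(8); rs(80)
  recid <- rs(80)
  rs(8); rs(8); rs(8); rs(44)
  nrec <- as.integer(rs(8))
  dur <- as.numeric(rs(8))
  nch <- as.integer(rs(4))
  labs <- vapply(seq_len(nch), function(i) rs(16), "")
  for (i in seq_len(nch)) rs(80)
  for (i in seq_len(nch)) rs(8)
  pmin_ <- as.numeric(vapply(seq_len(nch), function(i) rs(8), ""))
  pmax_ <- as.numeric(vapply(seq_len(nch), function(i) rs(8), ""))
  dmin <- as.numeric(vapply(seq_len(nch), function(i) rs(8), ""))
  dmax <- as.numeric(vapply(seq_len(nch), function(i) rs(8), ""))
  for (i in seq_len(nch)) rs(80)
  spr <- as.integer(vapply(seq_len(nch), function(i) rs(8), ""))
  for (i in seq_len(nch)) rs(32)
  if (length(unique(spr)) != 1L)
    stop("format error: per-channel sampling rates differ", call. = FALSE)
  fs <- spr[1L] / dur

  dat <- matrix(0, nch, nrec * spr[1L])
  for (r in seq_len(nrec)) {
    block <- readBin(con, integer(), n = nch * spr[1L], size = 2,
                     endian = "little")
    dat[, ((r - 1) * spr[1L] + 1):(r * spr[1L])] <-
      matrix(block, nch, spr[1L], byrow = TRUE)
  }
  scale_ <- (pmax_ - pmin_) / (dmax - dmin)
  dat <- sweep(sweep(dat, 1, dmin, `-`), 1, scale_, `*`) + pmin_

  nsamp <- ncol(dat)
  reference <- "LM"
  m <- regmatches(recid, regexec("nsamples=(\\d+) ref=(\\S+)", recid))[[1]]
  if (length(m) == 3) {
    nsamp <- as.integer(m[2])
    reference <- m[3]
  }
  dat <- dat[, seq_len(nsamp), drop = FALSE]

  ev_path <- paste0(path, ".events.tsv")
  events <- if (file.exists(ev_path)) {
    utils::read.table(ev_path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
  } else data.frame(sample = integer(), label = character())

  mon <- montage_from_names(labs)
  continuous_record(dat, fs, mon, events, reference = reference)
}

# Montage for an externally named channel set: canonical channels keep
# their canonical spots, everything else takes the ring layout in order.
montage_from_names <- function(names) {
  n <- length(names)
  ref <- make_montage(max(n, 8))
  pos <- matrix(0, n, 2, dimnames = list(names, NULL))
  canon <- intersect(names, ref$channel_names[1:7])
  pos[canon, ] <- ref$positions[canon, ]
  rest <- setdiff(names, canon)
  filler <- ref$positions[-(1:7), , drop = FALSE]
  if (length(rest))
    pos[rest, ] <- filler[seq_along(rest) %% nrow(filler) + 1, , drop = FALSE]
  structure(list(channel_names = names, positions = pos, n_channels = n),
            class = "montage")
}
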