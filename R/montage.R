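#' Build an EEG montage on the unit disc
#'
#' Constructs a montage containing the channels this package relies on by
#' name — the sensorimotor row \code{C3}, \code{Cz}, \code{C4}, the
#' fronto-central pair \code{FC5}, \code{FC6}, and the two mastoids
#' \code{LM}, \code{RM} — plus auto-named filler channels (\code{E8},
#' \code{E9}, ...) laid out on concentric rings so that every channel has a
#' 2-D position inside the unit disc (nose up, left ear at negative x).
#' Positions are schematic: they drive neighbour maps and topographic
#' exports, not forward modelling.
#'
#' @param n_channels total number of channels, at least 8.
#' @return An object of class \code{montage}: a list with
#'   \code{channel_names} (character), \code{positions} (n x 2 matrix with
#'   row names), and \code{n_channels}.
#' @examples
#' mon <- make_montage(64)
#' mon$channel_names[1:7]
#' @export
make_montage <- function(n_channels) {
  if (!is.numeric(n_channels) || length(n_channels) != 1L || n_channels < 8)
    stop("n_channels must be a single integer >= 8 (7 named channels are required)",
         call. = FALSE)
  n_channels <- as.integer(n_channels)

  named <- rbind(
    C3  = c(-0.40,  0.00),
    Cz  = c( 0.00,  0.00),
    C4  = c( 0.40,  0.00),
    FC5 = c(-0.60,  0.25),
    FC6 = c( 0.60,  0.25),
    LM  = c(-0.85, -0.45),
    RM  = c( 0.85, -0.45))

  n_fill <- n_channels - nrow(named)
  fill <- matrix(0, n_fill, 2)
  if (n_fill > 0) {
    # concentric rings, innermost first; ring k holds ~8k channels
    radii <- c(0.2, 0.45, 0.7, 0.88)
    per_ring <- pmax(1L, round(n_fill * radii / sum(radii)))
    while (sum(per_ring) < n_fill) per_ring[length(per_ring)] <- per_ring[length(per_ring)] + 1L
    while (sum(per_ring) > n_fill) {
      i <- which.max(per_ring); per_ring[i] <- per_ring[i] - 1L
    }
    idx <- 1L
    for (k in seq_along(radii)) {
      nk <- per_ring[k]
      if (nk == 0L) next
      ang <- 2 * pi * (seq_len(nk) - 1) / nk + 0.1 * k
      fill[idx:(idx + nk - 1L), ] <- cbind(radii[k] * cos(ang), radii[k] * sin(ang))
      idx <- idx + nk
    }
    rownames(fill) <- paste0("E", seq.int(8L, n_channels))
  }

  positions <- rbind(named, fill)[seq_len(n_channels), , drop = FALSE]
  structure(
    list(channel_names = rownames(positions),
         positions = positions,
         n_channels = n_channels),
    class = "montage")
}

#' @export
print.montage <- function(x, ...) {
  cat("<montage> ", x$n_channels, " channels (",
      paste(utils::head(x$channel_names, 7), collapse = ", "),
      if (x$n_channels > 7) ", ..." else "", ")\n", sep = "")
  invisible(x)
}

#' Neighbour map from montage geometry
#'
#' For each channel, its \code{k} nearest neighbours by Euclidean distance
#' in the 2-D layout. Used as the default adjacency for bad-channel
#' interpolation; a hand-built list can be supplied instead wherever a
#' \code{neighbor_map} argument is accepted.
#'
#' @param montage a \code{montage}.
#' @param k neighbours per channel (default 4).
#' @return Named list: channel name -> character vector of neighbour names.
#' @export
montage_neighbors <- function(montage, k = 4L) {
  stopifnot(inherits(montage, "montage"))
  pos <- montage$positions
  d <- as.matrix(stats::dist(pos))
  out <- lapply(seq_len(nrow(pos)), function(i) {
    ord <- order(d[i, ])
    rownames(pos)[setdiff(ord, i)[seq_len(min(k, nrow(pos) - 1L))]]
  })
  names(out) <- rownames(pos)
  out
}
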