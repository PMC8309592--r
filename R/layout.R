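# Scalp-proximity channel re-ordering: the 32 EEG channels arrive in the
# DEAP (Geneva) order, which interleaves hemispheres; re-ordering columns
# so that physically adjacent electrodes are adjacent in the matrix helps
# 2-D convolutions pick up local spatial structure.

#' DEAP EEG channel names (Geneva order)
#' @return Character vector of the 32 EEG channel labels, recording order.
#' @export
deap_channel_names <- function() {
  c("Fp1", "AF3", "F3", "F7", "FC5", "FC1", "C3", "T7",
    "CP5", "CP1", "P3", "P7", "PO3", "O1", "Oz", "Pz",
    "Fp2", "AF4", "Fz", "F4", "F8", "FC6", "FC2", "Cz",
    "C4", "T8", "CP6", "CP2", "P4", "P8", "PO4", "O2")
}

#' Schematic 2-D scalp coordinates of the 10-20 montage
#'
#' Approximate top-view positions (x: left negative to right positive,
#' y: posterior negative to anterior positive, unit head radius) for the 32
#' DEAP EEG channels. Used to derive and audit proximity orderings; not
#' intended for source analysis.
#'
#' @return Tibble `channel`, `x`, `y` in DEAP recording order.
#' @export
deap_montage_coords <- function() {
  pos <- c(
    Fp1 = c(-0.31,  0.95), AF3 = c(-0.35,  0.78), F3  = c(-0.38,  0.55),
    F7  = c(-0.81,  0.59), FC5 = c(-0.62,  0.30), FC1 = c(-0.22,  0.28),
    C3  = c(-0.50,  0.00), T7  = c(-1.00,  0.00), CP5 = c(-0.62, -0.30),
    CP1 = c(-0.22, -0.28), P3  = c(-0.38, -0.55), P7  = c(-0.81, -0.59),
    PO3 = c(-0.35, -0.78), O1  = c(-0.31, -0.95), Oz  = c( 0.00, -1.00),
    Pz  = c( 0.00, -0.55), Fp2 = c( 0.31,  0.95), AF4 = c( 0.35,  0.78),
    Fz  = c( 0.00,  0.55), F4  = c( 0.38,  0.55), F8  = c( 0.81,  0.59),
    FC6 = c( 0.62,  0.30), FC2 = c( 0.22,  0.28), Cz  = c( 0.00,  0.00),
    C4  = c( 0.50,  0.00), T8  = c( 1.00,  0.00), CP6 = c( 0.62, -0.30),
    CP2 = c( 0.22, -0.28), P4  = c( 0.38, -0.55), P8  = c( 0.81, -0.59),
    PO4 = c( 0.35, -0.78), O2  = c( 0.31, -0.95)
  )
  m <- matrix(pos, ncol = 2, byrow = TRUE)
  tibble::tibble(channel = deap_channel_names(), x = m[, 1], y = m[, 2])
}

#' Proximity-based channel layout
#'
#' Builds the default scalp-proximity ordering as a greedy
#' nearest-neighbour chain over the montage coordinates, starting at the
#' left-frontal pole (Fp1): each next column is the closest electrode not
#' yet placed. Consecutive matrix columns are therefore physical
#' neighbours on the scalp, which is what 2-D convolutions exploit. The
#' result is data, not code: any permutation of 1..32 can be supplied to
#' [spatial_reorder()] instead.
#'
#' @return A `channel_layout`: list with `permutation` (source indices in
#'   their new order), `names`, and `coords`.
#' @export
default_channel_layout <- function() {
  co <- deap_montage_coords()
  xy <- cbind(co$x, co$y)
  d <- as.matrix(stats::dist(xy))
  n <- nrow(co)
  perm <- integer(n)
  perm[1] <- which(co$channel == "Fp1")
  left <- setdiff(seq_len(n), perm[1])
  for (i in 2:n) {
    nxt <- left[which.min(d[perm[i - 1L], left])]
    perm[i] <- nxt
    left <- setdiff(left, nxt)
  }
  structure(list(permutation = perm,
                 names = co$channel[perm],
                 coords = co),
            class = "channel_layout")
}

#' @export
print.channel_layout <- function(x, ...) {
  cat("<channel_layout>", paste(x$names, collapse = " "), "\n")
  invisible(x)
}

#' Mean scalp distance between adjacent matrix columns
#'
#' Audit statistic for a channel ordering: the mean Euclidean scalp
#' distance between consecutive channels under the given permutation.
#'
#' @param permutation Integer permutation of 1..32 (identity = DEAP order).
#' @param coords Coordinate tibble, default [deap_montage_coords()].
#' @return Mean adjacent distance (smaller = more proximity-preserving).
#' @export
mean_adjacent_distance <- function(permutation, coords = deap_montage_coords()) {
  stopifnot(length(permutation) == nrow(coords),
            all(sort(permutation) == seq_len(nrow(coords))))
  xy <- cbind(coords$x, coords$y)[permutation, ]
  mean(sqrt(rowSums(diff(xy)^2)))
}

#' Re-order epoch channels by a layout
#'
#' Permutes the channel columns of an epoch (or every epoch of a set)
#' according to the layout; metadata are untouched.
#'
#' @param e A `time x 32` epoch matrix or an [epoch_set].
#' @param layout A `channel_layout` (default [default_channel_layout()]).
#' @return Object of the same type with permuted channel columns.
#' @export
spatial_reorder <- function(e, layout = default_channel_layout()) {
  stopifnot(inherits(layout, "channel_layout"))
  p <- layout$permutation
  if (inherits(e, "epoch_set")) {
    if (dim(e$data)[2] != length(p)) {
      stopf("epoch set has %d channels, layout expects %d",
            dim(e$data)[2], length(p))
    }
    e$data <- e$data[, p, , drop = FALSE]
    return(e)
  }
  stopifnot(is.matrix(e))
  if (ncol(e) != length(p)) {
    stopf("epoch has %d channels, layout expects %d", ncol(e), length(p))
  }
  e[, p, drop = FALSE]
}
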