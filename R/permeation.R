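#' Permeation reaction coordinate
#'
#' The position of the tracked ion along the pore axis, measured relative to
#' the mass-weighted centre of mass of the four Thr96 reference residues at
#' the base of the selectivity filter. Axis polarity is dataset configuration
#' (the coordinate is a signed difference; no global sign convention is
#' assumed). A side-chain-only reference variant is available via
#' `sidechain_only` for datasets where the reference should exclude backbone
#' atoms.
#'
#' @param frame A `frame`.
#' @param ion_idx Index of the ion atom.
#' @param ref_idx Indices of the reference (Thr96) atoms.
#' @param sidechain_only If `TRUE`, drop backbone atoms (names N, CA, C, O)
#'   from the reference before the centre of mass is taken.
#' @return z in angstrom (ion z minus reference COM z).
#' @export
reaction_coordinate <- function(frame, ion_idx, ref_idx, sidechain_only = FALSE) {
  if (!length(ref_idx)) stop("empty Thr96 reference selection")
  a <- frame$atoms
  if (sidechain_only) {
    ref_idx <- ref_idx[!a$name[ref_idx] %in% c("N", "CA", "C", "O")]
    if (!length(ref_idx)) stop("no side-chain atoms in reference selection")
  }
  m <- atomic_mass(a$element[ref_idx])
  com_z <- sum(a$z[ref_idx] * m) / sum(m)
  a$z[ion_idx] - com_z
}

#' Reaction coordinate across a trajectory
#'
#' @param traj A `trajectory` with `ion_K` and `reference_T96` tags.
#' @inheritParams reaction_coordinate
#' @return Numeric vector, one z per frame.
#' @export
reaction_coordinate_series <- function(traj, sidechain_only = FALSE) {
  ion <- traj$tags$ion_K
  ref <- traj$tags$reference_T96
  if (length(ion) != 1) stop("'ion_K' tag must name exactly one atom")
  if (!length(ref)) stop("trajectory has no 'reference_T96' tag")
  nm <- traj$topology$name[ref]
  if (sidechain_only) ref <- ref[!nm %in% c("N", "CA", "C", "O")]
  m <- atomic_mass(traj$topology$element[ref])
  com_z <- as.vector(m %*% traj$coords[ref, 3, , drop = FALSE][, 1, ]) / sum(m)
  traj$coords[ion, 3, ] - com_z
}

#' Detect ion crossings of a plane with hysteresis
#'
#' A crossing event is recorded when the ion passes from below
#' `plane_z - hysteresis` to above `plane_z + hysteresis` (direction `+z`) or
#' the reverse (`-z`) without first re-entering the band it came from; the
#' two-threshold state machine makes double counting impossible.
#'
#' @param z Numeric vector of per-frame ion positions (angstrom), e.g. from
#'   [reaction_coordinate_series()].
#' @param plane_z Plane position, angstrom.
#' @param hysteresis Half-width of the dead band, angstrom (>= 0).
#' @return Data frame of events: `entry_frame` (last frame in the origin
#'   band), `exit_frame` (first frame in the destination band), `direction`
#'   (`"+z"` or `"-z"`). Frames are 0-indexed.
#' @export
detect_crossings <- function(z, plane_z, hysteresis = 2.0) {
  stopifnot(hysteresis >= 0)
  lo <- plane_z - hysteresis
  hi <- plane_z + hysteresis
  side <- integer(length(z))      # -1 below band, +1 above band, 0 in band
  side[z < lo] <- -1L
  side[z > hi] <- 1L
  events <- list()
  last_side <- 0L
  last_frame <- NA_integer_
  for (i in seq_along(z)) {
    s <- side[i]
    if (s == 0L) next
    if (last_side != 0L && s != last_side) {
      events[[length(events) + 1L]] <- data.frame(
        entry_frame = last_frame - 1L, exit_frame = i - 1L,
        direction = if (s > last_side) "+z" else "-z",
        stringsAsFactors = FALSE)
    }
    last_side <- s
    last_frame <- i
  }
  if (!length(events))
    return(data.frame(entry_frame = integer(0), exit_frame = integer(0),
                      direction = character(0), stringsAsFactors = FALSE))
  do.call(rbind, events)
}

#' Water coordination number of an ion
#'
#' Count of water oxygen atoms within the cutoff of the ion
#' (minimum image when a box is present).
#'
#' @param frame A `frame`.
#' @param ion_idx Index of the ion atom.
#' @param waterO_idx Indices of water oxygen atoms.
#' @param cutoff Cutoff, angstrom (default 3.0).
#' @return Integer count.
#' @export
coordination_number <- function(frame, ion_idx, waterO_idx, cutoff = 3.0) {
  if (!length(waterO_idx)) return(0L)
  xyz <- frame_xyz(frame)
  d <- pair_dists(xyz[ion_idx, , drop = FALSE],
                  xyz[waterO_idx, , drop = FALSE], frame$box)
  sum(d <= cutoff)
}

#' Coordination samples across a trajectory
#'
#' @param traj A `trajectory` with `ion_K`, `water_O` and `reference_T96`
#'   tags.
#' @param cutoff Coordination cutoff, angstrom.
#' @return Data frame with columns `frame`, `z` (reaction coordinate) and
#'   `n_O`.
#' @export
coordination_series <- function(traj, cutoff = 3.0) {
  z <- reaction_coordinate_series(traj)
  ion <- traj$tags$ion_K
  wat <- traj$tags$water_O
  n_O <- vapply(seq_len(n_frames(traj)), function(k) {
    d <- pair_dists(matrix(traj$coords[ion, , k], 1),
                    traj$coords[wat, , k, drop = TRUE], traj$box)
    sum(d <= cutoff)
  }, integer(1))
  data.frame(frame = seq_len(n_frames(traj)) - 1L, z = z, n_O = n_O)
}

#' Column-normalized coordination histogram
#'
#' Joint distribution of hydration number against position along the pore,
#' with each z column expressed as percentages summing to 100.
#'
#' @param samples Data frame with columns `z` and `n_O` (see
#'   [coordination_series()]).
#' @param z_bins Numeric vector of z bin edges (angstrom).
#' @return List with `z_mid`, `n_O` levels, `percent` (matrix, n_O rows by z
#'   columns; each retained column sums to 100), and `empty_bins` (indices of
#'   omitted empty z bins).
#' @export
coordination_histogram <- function(samples, z_bins) {
  stopifnot(length(z_bins) >= 2)
  col <- findInterval(samples$z, z_bins, rightmost.closed = TRUE)
  ok <- col >= 1 & col <= length(z_bins) - 1
  col <- col[ok]
  nO <- samples$n_O[ok]
  levels_n <- 0:max(nO)
  nb <- length(z_bins) - 1
  m <- matrix(0, length(levels_n), nb)
  for (i in seq_along(col)) m[nO[i] + 1L, col[i]] <- m[nO[i] + 1L, col[i]] + 1
  tot <- colSums(m)
  empty <- which(tot == 0)
  pct <- m
  for (j in seq_len(nb)) if (tot[j] > 0) pct[, j] <- 100 * m[, j] / tot[j]
  keep <- tot > 0
  list(z_mid = ((z_bins[-1] + z_bins[-length(z_bins)]) / 2)[keep],
       n_O = levels_n,
       percent = pct[, keep, drop = FALSE],
       empty_bins = empty)
}

#' Frames conditioned on conduction
#'
#' Selects the frames during which an ion is transiting the collar: for each
#' crossing event, the frames between band exit and band entry (the transit
#' itself), optionally widened by a window.
#'
#' @param n_total Total number of frames in the trajectory.
#' @param events Event table from [detect_crossings()].
#' @param window Extra frames added on each side of every transit.
#' @return Sorted integer vector of 0-indexed conducting frames (empty when
#'   there are no events).
#' @export
conduction_conditioned <- function(n_total, events, window = 0L) {
  if (!nrow(events)) return(integer(0))
  frames <- unlist(lapply(seq_len(nrow(events)), function(i) {
    seq(max(0L, events$entry_frame[i] - window),
        min(n_total - 1L, events$exit_frame[i] + window))
  }))
  sort(unique(frames))
}
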