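tail_groups <- function(traj) {
  idx <- traj$tags$tail_terminus
  if (!length(idx)) stop("trajectory has no 'tail_terminus' tag")
  split(idx, traj$topology$resid[idx])
}

#' Lipid tail engagement of the collar in one frame
#'
#' A tail is engaged when the minimum distance from any of its counted atoms
#' (by default the terminal acyl carbon; optionally the distal few carbons)
#' to any collar side-chain atom is at or below the cutoff. Distances use the
#' minimum-image convention when the frame has a box.
#'
#' @param frame A `frame`.
#' @param tail_atoms List of integer vectors, counted atoms per tail.
#' @param collar_idx Integer vector of collar side-chain atom indices.
#' @param cutoff Contact cutoff, angstrom (default 5.0).
#' @return An `engagement_record` list: `frame_index`, `engaged_count`,
#'   `per_tail` (logical), `contact_pairs` (data frame of tail atom index,
#'   collar atom index, distance for every contact at or below cutoff).
#' @export
engaged_tails <- function(frame, tail_atoms, collar_idx, cutoff = 5.0) {
  if (!length(tail_atoms) || !length(collar_idx))
    stop("tail and collar selections must be nonempty")
  xyz <- frame_xyz(frame)
  collar <- xyz[collar_idx, , drop = FALSE]
  per_tail <- logical(length(tail_atoms))
  pairs <- list()
  for (t in seq_along(tail_atoms)) {
    ta <- tail_atoms[[t]]
    d <- pair_dists(xyz[ta, , drop = FALSE], collar, frame$box)
    hit <- which(d <= cutoff, arr.ind = TRUE)
    per_tail[t] <- nrow(hit) > 0
    if (nrow(hit))
      pairs[[length(pairs) + 1L]] <- data.frame(
        tail_atom = ta[hit[, 1]], collar_atom = collar_idx[hit[, 2]],
        distance = d[hit])
  }
  structure(list(frame_index = frame$index,
                 engaged_count = sum(per_tail),
                 per_tail = per_tail,
                 contact_pairs = if (length(pairs)) do.call(rbind, pairs)
                                 else data.frame(tail_atom = integer(0),
                                                 collar_atom = integer(0),
                                                 distance = numeric(0))),
            class = "engagement_record")
}

#' Engagement counts across a trajectory
#'
#' @param traj A `trajectory` with `tail_terminus` and `collar_sidechain`
#'   tags (tails grouped by residue id).
#' @param cutoff Contact cutoff, angstrom.
#' @return Data frame with columns `frame`, `engaged_count`.
#' @export
engagement_series <- function(traj, cutoff = 5.0) {
  tails <- tail_groups(traj)
  collar <- traj$tags$collar_sidechain
  if (!length(collar)) stop("trajectory has no 'collar_sidechain' tag")
  box <- traj$box
  counts <- vapply(seq_len(n_frames(traj)), function(k) {
    xyz <- traj$coords[, , k]
    cxyz <- xyz[collar, , drop = FALSE]
    eng <- 0L
    for (ta in tails) {
      d <- pair_dists(xyz[ta, , drop = FALSE], cxyz, box)
      if (any(d <= cutoff)) eng <- eng + 1L
    }
    eng
  }, integer(1))
  data.frame(frame = seq_len(n_frames(traj)) - 1L, engaged_count = counts)
}

#' Occupancy distribution of engaged tails
#'
#' @param counts Integer vector of per-frame engaged-tail counts, or the data
#'   frame returned by [engagement_series()].
#' @param k_max Largest count to report (defaults to the observed maximum).
#' @return Data frame with columns `k`, `n_frames`, `prob`; probabilities sum
#'   to 1.
#' @export
occupancy_distribution <- function(counts, k_max = NULL) {
  if (is.data.frame(counts)) counts <- counts$engaged_count
  if (!length(counts)) stop("no frames")
  if (is.null(k_max)) k_max <- max(counts)
  k <- 0:k_max
  n <- vapply(k, function(kk) sum(counts == kk), integer(1))
  data.frame(k = k, n_frames = n, prob = n / length(counts))
}

#' Aperture-area density conditioned on engagement count
#'
#' @param series Data frame with columns `engaged_count` and `area` (join of
#'   [engagement_series()] and [collar_series()]).
#' @param k Engagement count to condition on.
#' @param bw Optional kernel bandwidth passed to [stats::density()].
#' @return List with `k`, `n`, `mean_area`, and `density` (a
#'   `stats::density` object, or `NULL` when fewer than 2 frames match).
#' @export
conditional_area_density <- function(series, k, bw = "nrd0") {
  sub <- series$area[series$engaged_count == k]
  if (!length(sub))
    stop("no frames with engaged_count == ", k)
  dens <- if (length(sub) >= 2 && sd(sub) > 0) density(sub, bw = bw) else NULL
  list(k = k, n = length(sub), mean_area = mean(sub), density = dens)
}

#' Head-group contact fraction at the canonical site
#'
#' Among frames in which a given fenestration is occupied by a lipid tail,
#' the fraction whose head group lies within the cutoff of the canonical
#' binding-site atoms (His/Trp/Arg pocket analogues).
#'
#' @param traj A `trajectory` with `headgroup_P`, `site_HRW`,
#'   `tail_terminus` and `collar_sidechain` tags.
#' @param cutoff Contact cutoff, angstrom (default 5.0).
#' @param engage_cutoff Cutoff defining fenestration occupancy, angstrom.
#' @return List with `fraction`, `numerator`, `denominator`.
#' @export
headgroup_contact_fraction <- function(traj, cutoff = 5.0, engage_cutoff = 5.0) {
  tails <- tail_groups(traj)
  heads <- split(traj$tags$headgroup_P, traj$topology$resid[traj$tags$headgroup_P])
  if (!setequal(names(tails), names(heads)))
    stop("tail and head-group tags must cover the same lipid residues")
  heads <- heads[names(tails)]
  site <- traj$tags$site_HRW
  collar <- traj$tags$collar_sidechain
  if (!length(site)) stop("trajectory has no 'site_HRW' tag")
  num <- 0L; den <- 0L
  for (k in seq_len(n_frames(traj))) {
    xyz <- traj$coords[, , k]
    sxyz <- xyz[site, , drop = FALSE]
    cxyz <- xyz[collar, , drop = FALSE]
    for (t in seq_along(tails)) {
      d <- pair_dists(xyz[tails[[t]], , drop = FALSE], cxyz, traj$box)
      if (any(d <= engage_cutoff)) {
        den <- den + 1L
        dh <- pair_dists(xyz[heads[[t]], , drop = FALSE], sxyz, traj$box)
        if (any(dh <= cutoff)) num <- num + 1L
      }
    }
  }
  if (den == 0L) stop("no fenestration-occupied lipid-frames in trajectory")
  list(fraction = num / den, numerator = num, denominator = den)
}

#' Planar head-group number-density map and radial profile
#'
#' Per-leaflet 2-D histogram of head-group positions projected on the
#' membrane plane, normalized per frame and per bin area
#' (count frame^-1 A^-2), plus an azimuthally averaged radial profile about
#' the pore axis.
#'
#' @param traj A `trajectory` with a `headgroup_P` tag.
#' @param leaflet_split_z z of the membrane mid-plane (angstrom); head groups
#'   with z above it belong to the `upper` leaflet.
#' @param bin Bin width, angstrom.
#' @param r_max Extent of the map from the pore axis, angstrom.
#' @param axis_xy xy position of the pore axis (default column means of the
#'   head-group cloud).
#' @return A `density_map` list with per-leaflet `edges`, `density` matrices,
#'   `counts` matrices, `n_frames`, and `radial` (data frame `r`, `density`
#'   per leaflet).
#' @export
headgroup_density_map <- function(traj, leaflet_split_z = 0, bin = 1.0,
                                  r_max = NULL, axis_xy = NULL) {
  stopifnot(bin > 0)
  idx <- traj$tags$headgroup_P
  if (!length(idx)) stop("trajectory has no 'headgroup_P' tag")
  nf <- n_frames(traj)
  xs <- as.vector(traj$coords[idx, 1, ])
  ys <- as.vector(traj$coords[idx, 2, ])
  zs <- as.vector(traj$coords[idx, 3, ])
  if (is.null(axis_xy)) axis_xy <- c(mean(xs), mean(ys))
  if (is.null(r_max)) r_max <- max(abs(c(xs - axis_xy[1], ys - axis_xy[2]))) + bin
  edges <- seq(-r_max, r_max, by = bin)
  nb <- length(edges) - 1
  one_leaflet <- function(keep) {
    cnt <- matrix(0L, nb, nb)
    i <- findInterval(xs[keep] - axis_xy[1], edges, rightmost.closed = TRUE)
    j <- findInterval(ys[keep] - axis_xy[2], edges, rightmost.closed = TRUE)
    ok <- i >= 1 & i <= nb & j >= 1 & j <= nb
    for (k in which(ok)) cnt[i[k], j[k]] <- cnt[i[k], j[k]] + 1L
    list(counts = cnt, density = cnt / (nf * bin^2))
  }
  up <- one_leaflet(zs > leaflet_split_z)
  lo <- one_leaflet(zs <= leaflet_split_z)
  radial_profile <- function(keep) {
    r <- sqrt((xs[keep] - axis_xy[1])^2 + (ys[keep] - axis_xy[2])^2)
    redges <- seq(0, r_max, by = bin)
    ri <- findInterval(r, redges, rightmost.closed = TRUE)
    ri <- ri[ri >= 1 & ri <= length(redges) - 1]
    n <- tabulate(ri, nbins = length(redges) - 1)
    ann <- pi * (redges[-1]^2 - redges[-length(redges)]^2)
    data.frame(r = (redges[-1] + redges[-length(redges)]) / 2,
               density = n / (nf * ann))
  }
  structure(list(edges = edges, axis_xy = axis_xy, n_frames = nf,
                 upper = up, lower = lo,
                 radial = list(upper = radial_profile(zs > leaflet_split_z),
                               lower = radial_profile(zs <= leaflet_split_z))),
            class = "density_map")
}
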