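#' Pore radius profile
#'
#' HOLE-style profile of the largest sphere that fits in the pore at each
#' height z: at a point p in the z-plane the available radius is
#' `min_i (|p - x_i| - vdw_i)` over all wall atoms i, and the pore radius at z
#' is the maximum of that quantity over the plane. The optimizer is a coarse
#' grid (default 0.25 angstrom) followed by Nelder-Mead refinement.
#'
#' @param frame A `frame`.
#' @param z_range Length-2 numeric, z interval to profile (angstrom).
#' @param dz Spacing of the z grid, angstrom.
#' @param exclude Optional `selection` of atoms to drop before profiling
#'   (waters, ions and lipids are typically excluded upstream).
#' @param grid_res Coarse grid resolution in the plane, angstrom.
#' @param cap Maximum reported radius; planes where the optimum escapes the
#'   wall are reported at `cap` and flagged in `capped`.
#' @return A `pore_profile`: data frame with columns `z`, `radius`, `cx`,
#'   `cy`, `capped`.
#' @export
radius_profile <- function(frame, z_range, dz = 0.5, exclude = NULL,
                           grid_res = 0.25, cap = NULL) {
  atoms <- frame$atoms
  if (!is.null(exclude)) {
    drop <- resolve(exclude, frame)
    if (length(drop)) atoms <- atoms[-drop, , drop = FALSE]
  }
  if (nrow(atoms) < 4) stop("fewer than 4 atoms after exclusion")
  if (is.null(cap)) {
    cap <- if (!is.null(frame$box)) sqrt(sum(frame$box^2)) / 2 else
      max(pair_dists(frame_xyz(frame), matrix(colMeans(frame_xyz(frame)), 1))) + 5
  }
  P <- as.matrix(atoms[, c("x", "y", "z")])
  vdw <- atoms$vdw
  zs <- seq(z_range[1], z_range[2], by = dz)
  avail <- function(p, z) {
    dx <- P[, 1] - p[1]; dy <- P[, 2] - p[2]; dzv <- P[, 3] - z
    min(sqrt(dx * dx + dy * dy + dzv * dzv) - vdw)
  }
  out <- lapply(zs, function(z) {
    gx <- seq(min(P[, 1]), max(P[, 1]), by = grid_res)
    gy <- seq(min(P[, 2]), max(P[, 2]), by = grid_res)
    grid <- as.matrix(expand.grid(x = gx, y = gy))
    vals <- apply(grid, 1, avail, z = z)
    best <- grid[which.max(vals), ]
    op <- optim(best, function(p) -avail(p, z), method = "Nelder-Mead",
                control = list(reltol = 1e-10, maxit = 500))
    r <- -op$value
    capped <- r > cap
    data.frame(z = z, radius = min(r, cap), cx = op$par[1], cy = op$par[2],
               capped = capped)
  })
  res <- do.call(rbind, out)
  res$radius <- pmax(res$radius, 0)
  class(res) <- c("pore_profile", "data.frame")
  res
}

#' Collar aperture geometry for one frame
#'
#' The gating collar is a ring of four symmetry-related leucine side chains.
#' Per subunit the collar tip is the point midway between the two delta
#' carbons (Cd1, Cd2); subunits are ordered by azimuth about the pore axis;
#' D1 and D2 are the two diagonal distances between opposite-subunit
#' midpoints, and the aperture area is the shoelace area of the
#' azimuth-ordered midpoints projected on the plane normal to the axis.
#'
#' @param frame A `frame`.
#' @param collar_pairs 4 x 2 integer matrix of (Cd1, Cd2) atom indices, one
#'   row per subunit, or `"auto"` to derive pairs from `resname == "LEU"`
#'   CD1/CD2 atoms grouped by chain.
#' @param vdw_shrink If `TRUE`, each midpoint is pulled radially inward by the
#'   carbon van der Waals radius before the area is computed (alternative
#'   aperture definition; the unshrunk planar area is the default statistic).
#' @return A `collar_geometry` list: `frame_index`, `midpoints` (4 x 3),
#'   `D1`, `D2`, `area`.
#' @export
collar_geometry <- function(frame, collar_pairs = "auto", vdw_shrink = FALSE) {
  if (identical(collar_pairs, "auto")) {
    a <- frame$atoms
    cd1 <- which(a$resname == "LEU" & a$name == "CD1")
    cd2 <- which(a$resname == "LEU" & a$name == "CD2")
    ch1 <- a$chain[cd1]
    cd2 <- cd2[match(ch1, a$chain[cd2])]
    collar_pairs <- cbind(cd1, cd2)
  }
  collar_pairs <- matrix(as.integer(collar_pairs), ncol = 2)
  if (nrow(collar_pairs) != 4) stop("exactly 4 subunit (Cd1, Cd2) pairs required")
  xyz <- frame_xyz(frame)
  mid <- (xyz[collar_pairs[, 1], , drop = FALSE] +
          xyz[collar_pairs[, 2], , drop = FALSE]) / 2
  ctr <- colMeans(mid)
  rel <- sweep(mid[, 1:2, drop = FALSE], 2, ctr[1:2])
  rad <- sqrt(rowSums(rel^2))
  if (any(rad < 1e-9)) stop("degenerate collar geometry: midpoint on axis")
  ord <- order(atan2(rel[, 2], rel[, 1]))
  mid <- mid[ord, , drop = FALSE]
  rel <- rel[ord, , drop = FALSE]
  if (anyDuplicated(round(mid, 6)))
    stop("degenerate collar geometry: duplicate midpoints")
  if (vdw_shrink) {
    r <- sqrt(rowSums(rel^2))
    shrink <- pmax(r - .VDW_TABLE[["C"]], 0) / r
    rel <- rel * shrink
  }
  d1 <- sqrt(sum((mid[1, ] - mid[3, ])^2))
  d2 <- sqrt(sum((mid[2, ] - mid[4, ])^2))
  xs <- rel[, 1]; ys <- rel[, 2]
  j <- c(2, 3, 4, 1)
  area <- abs(sum(xs * ys[j] - xs[j] * ys)) / 2
  structure(list(frame_index = frame$index, midpoints = mid,
                 D1 = d1, D2 = d2, area = area),
            class = "collar_geometry")
}

#' Collar geometry across a trajectory
#'
#' @param traj A `trajectory` whose `collar_sidechain` tag (or explicit
#'   `collar_pairs`) identifies the four Cd1/Cd2 pairs.
#' @inheritParams collar_geometry
#' @return Data frame with columns `frame`, `D1`, `D2`, `area`.
#' @export
collar_series <- function(traj, collar_pairs = "auto", vdw_shrink = FALSE) {
  if (identical(collar_pairs, "auto") && !is.null(traj$tags$collar_sidechain)) {
    idx <- traj$tags$collar_sidechain
    a <- traj$topology[idx, ]
    cd1 <- idx[a$name == "CD1"]
    cd2 <- idx[a$name == "CD2"]
    cd2 <- cd2[match(traj$topology$chain[cd1], traj$topology$chain[cd2])]
    collar_pairs <- cbind(cd1, cd2)
  }
  rows <- lapply(seq_len(n_frames(traj)) - 1L, function(i) {
    g <- collar_geometry(get_frame(traj, i), collar_pairs, vdw_shrink)
    data.frame(frame = i, D1 = g$D1, D2 = g$D2, area = g$area)
  })
  do.call(rbind, rows)
}

#' Symmetrize diagonal couplets
#'
#' The assignment of the two collar diagonals to the labels D1 and D2 is
#' arbitrary, so each observed couplet (D1, D2) is duplicated as (D2, D1);
#' histograms of the symmetrized set are exactly mirror-symmetric about the
#' diagonal.
#'
#' @param couplets Data frame or matrix with columns `D1`, `D2`.
#' @return Data frame with twice the rows, closed under swapping.
#' @export
symmetrize_couplets <- function(couplets) {
  couplets <- as.data.frame(couplets)
  if (!nrow(couplets))
    return(data.frame(D1 = numeric(0), D2 = numeric(0)))
  rbind(data.frame(D1 = couplets$D1, D2 = couplets$D2),
        data.frame(D1 = couplets$D2, D2 = couplets$D1))
}

#' 2-D histogram of diagonal couplets
#'
#' Square binning on a common grid for both axes (binning geometry is a
#' plotting choice; counts are only ever compared within one scheme).
#'
#' @param couplets Data frame with columns `D1`, `D2` (typically already
#'   symmetrized).
#' @param bin_width Bin width, angstrom.
#' @param origin Lower edge of the first bin.
#' @return A `hist2d` list: `edges` (common break vector), `counts` (matrix,
#'   D1 rows x D2 columns), `n` (total count).
#' @export
hist2d <- function(couplets, bin_width = 0.25, origin = 0) {
  stopifnot(bin_width > 0)
  couplets <- as.data.frame(couplets)
  if (!nrow(couplets)) {
    return(structure(list(edges = numeric(0),
                          counts = matrix(0, 0, 0), n = 0L),
                     class = "hist2d"))
  }
  hi <- max(couplets$D1, couplets$D2)
  edges <- seq(origin, origin + bin_width * (ceiling((hi - origin) / bin_width) + 1),
               by = bin_width)
  i <- findInterval(couplets$D1, edges, rightmost.closed = TRUE)
  j <- findInterval(couplets$D2, edges, rightmost.closed = TRUE)
  nb <- length(edges) - 1
  counts <- matrix(0L, nb, nb)
  for (k in seq_along(i)) counts[i[k], j[k]] <- counts[i[k], j[k]] + 1L
  structure(list(edges = edges, counts = counts, n = nrow(couplets)),
            class = "hist2d")
}

#' Least-squares rigid superposition and RMSD
#'
#' Kabsch superposition of matched atoms of two structures. Atoms are put in
#' correspondence by (chain, resid, name); unmatched selected atoms are an
#' error listing the offenders.
#'
#' @param A,B `frame` objects.
#' @param sel A `selection` applied to both structures (default all C-alpha).
#' @return List with `rotation` (3 x 3), `translation` (length 3, applied to B
#'   after rotation), and `rmsd` (angstrom) over the matched atoms.
#' @export
superpose_rmsd <- function(A, B, sel = selection(name == "CA")) {
  ia <- resolve(sel, A)
  ib <- resolve(sel, B)
  key <- function(fr, idx) with(fr$atoms[idx, ], paste(chain, resid, name))
  ka <- key(A, ia); kb <- key(B, ib)
  common <- intersect(ka, kb)
  lost <- c(setdiff(ka, kb), setdiff(kb, ka))
  if (length(lost))
    stop("unmatched atoms in superposition: ", paste(head(lost, 8), collapse = "; "),
         if (length(lost) > 8) " ...")
  if (length(common) < 3) stop("need at least 3 matched atoms")
  Pa <- frame_xyz(A, ia[match(common, ka)])
  Pb <- frame_xyz(B, ib[match(common, kb)])
  ca <- colMeans(Pa); cb <- colMeans(Pb)
  X <- sweep(Pb, 2, cb)   # moving
  Y <- sweep(Pa, 2, ca)   # reference
  H <- t(X) %*% Y
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  fitted <- X %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted - Y)^2)))
  list(rotation = R, translation = as.numeric(ca - R %*% cb), rmsd = rmsd)
}
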