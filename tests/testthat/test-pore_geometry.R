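cylinder_frame <- function(n = 12, R = 5, vdw_el = "C", z_levels = c(-2, 0, 2)) {
  rows <- list()
  k <- 0
  for (z in z_levels) for (i in seq_len(n)) {
    k <- k + 1
    th <- 2 * pi * (i - 1) / n
    rows[[k]] <- data.frame(serial = k, name = "C", resname = "CYL",
                            resid = k, chain = "A", element = vdw_el,
                            x = R * cos(th), y = R * sin(th), z = z,
                            stringsAsFactors = FALSE)
  }
  fr <- new_frame(do.call(rbind, rows))
  fr$atoms$vdw <- 1.5
  fr
}

test_that("radius profile recovers the cylinder closed form", {
  fr <- cylinder_frame(n = 12, R = 5)
  prof <- radius_profile(fr, z_range = c(0, 0), dz = 1)
  expect_equal(prof$radius, 5 - 1.5, tolerance = 0.05)
  expect_lt(sqrt(prof$cx^2 + prof$cy^2), 0.1)
})

test_that("removing a wall atom cannot shrink the pore", {
  fr <- cylinder_frame(n = 12, R = 5)
  prof0 <- radius_profile(fr, z_range = c(-2, 2), dz = 1)
  fr2 <- fr
  fr2$atoms <- fr2$atoms[-5, ]
  prof1 <- radius_profile(fr2, z_range = c(-2, 2), dz = 1)
  expect_true(all(prof1$radius >= prof0$radius - 1e-6))
})

test_that("optimized radius matches an exhaustive fine-grid search", {
  set.seed(42)
  fr <- random_frame(50, seed = 42)
  fr$atoms$vdw <- runif(50, 1.2, 2.0)
  prof <- radius_profile(fr, z_range = c(0, 0), dz = 1, grid_res = 0.25)
  # brute force: 0.05 A grid over the xy bounding box
  P <- as.matrix(fr$atoms[, c("x", "y", "z")])
  gx <- seq(min(P[, 1]), max(P[, 1]), by = 0.05)
  gy <- seq(min(P[, 2]), max(P[, 2]), by = 0.05)
  grid <- as.matrix(expand.grid(gx, gy))
  best <- -Inf
  for (i in seq_len(nrow(grid))) {
    d <- sqrt((P[, 1] - grid[i, 1])^2 + (P[, 2] - grid[i, 2])^2 + P[, 3]^2)
    best <- max(best, min(d - fr$atoms$vdw))
  }
  expect_equal(prof$radius, best, tolerance = 0.05)
})

test_that("collar geometry reproduces square closed forms", {
  fr <- collar_frame(radii = rep(2.5, 4))
  g <- collar_geometry(fr)
  expect_equal(g$D1, 5.0, tolerance = 1e-9)
  expect_equal(g$D2, 5.0, tolerance = 1e-9)
  expect_equal(g$area, 12.5, tolerance = 1e-9)
  # explicit midpoint arithmetic
  a <- data.frame(serial = 1:2, name = c("CD1", "CD2"), resname = "LEU",
                  resid = 124L, chain = "A", element = "C",
                  x = c(1, 3), y = 0, z = 0)
  xyz <- as.matrix(a[, c("x", "y", "z")])
  expect_equal(colMeans(xyz), c(x = 2, y = 0, z = 0))
})

test_that("shoelace area of the diagonal quadrilateral equals D1*D2/2", {
  for (seed in 1:20) {
    set.seed(seed)
    radii <- runif(4, 1.5, 5.5)
    fr <- collar_frame(radii = radii)
    g <- collar_geometry(fr)
    # orthogonal diagonals: area = D1 * D2 / 2 in the planar square layout
    expect_equal(g$area, g$D1 * g$D2 / 2, tolerance = 1e-9)
    # independent shoelace oracle on the projected midpoints
    ctr <- colMeans(g$midpoints[, 1:2])
    expect_equal(g$area, shoelace(sweep(g$midpoints[, 1:2], 2, ctr)),
                 tolerance = 1e-9)
  }
})

test_that("collar metrics are invariant under rigid motion about the axis", {
  fr <- collar_frame(radii = c(2.1, 4.8, 3.3, 2.9))
  g0 <- collar_geometry(fr)
  for (seed in 1:5) {
    set.seed(seed)
    fr2 <- transform_frame(fr, rotation_z(runif(1, 0, 2 * pi)),
                           t = c(runif(2, -20, 20), runif(1, -5, 5)))
    g <- collar_geometry(fr2)
    expect_equal(g$area, g0$area, tolerance = 1e-3)
    expect_equal(sort(c(g$D1, g$D2)), sort(c(g0$D1, g0$D2)), tolerance = 1e-3)
  }
})

test_that("degenerate collar configurations are rejected", {
  fr <- collar_frame(radii = rep(2.5, 4))
  fr$atoms$x <- 0; fr$atoms$y <- 0
  expect_error(collar_geometry(fr), "degenerate")
})

test_that("couplet symmetrization duplicates with swapped labels", {
  out <- symmetrize_couplets(data.frame(D1 = 4, D2 = 6))
  expect_equal(nrow(out), 2)
  expect_setequal(paste(out$D1, out$D2), c("4 6", "6 4"))
  expect_equal(nrow(symmetrize_couplets(data.frame(D1 = numeric(0),
                                                   D2 = numeric(0)))), 0)
})

test_that("2-D histograms conserve counts and gain exact mirror symmetry", {
  set.seed(9)
  for (rep in 1:10) {
    cp <- data.frame(D1 = runif(200, 2, 12), D2 = runif(200, 2, 12))
    sym <- symmetrize_couplets(cp)
    h <- hist2d(sym, bin_width = 0.5)
    expect_equal(h$n, 2 * nrow(cp))
    expect_equal(sum(h$counts), 2 * nrow(cp))
    expect_identical(h$counts, t(h$counts))
  }
  # single couplet lands in one mirrored pair of bins (or one diagonal bin)
  h1 <- hist2d(symmetrize_couplets(data.frame(D1 = 4.1, D2 = 4.2)),
               bin_width = 1)
  expect_equal(sum(h1$counts), 2)
})

test_that("superposition is exact for self and rigidly moved copies", {
  fr <- random_frame(40, seed = 3)
  fr$atoms$name <- "CA"
  expect_equal(superpose_rmsd(fr, fr)$rmsd, 0, tolerance = 1e-9)
  moved <- transform_frame(fr, random_rotation(5), t = c(3, -2, 7))
  expect_equal(superpose_rmsd(fr, moved)$rmsd, 0, tolerance = 1e-6)
})

test_that("superposition rmsd equals the quaternion-method oracle", {
  for (seed in 1:10) {
    fr <- random_frame(10, seed = seed)
    fr$atoms$name <- "CA"
    fr$atoms$resid <- 1:10
    fr$atoms$chain <- "A"
    fr2 <- fr
    set.seed(seed + 100)
    fr2$atoms$x <- fr2$atoms$x + rnorm(10, sd = 0.7)
    fr2$atoms$y <- fr2$atoms$y + rnorm(10, sd = 0.7)
    fr2$atoms$z <- fr2$atoms$z + rnorm(10, sd = 0.7)
    got <- superpose_rmsd(fr, fr2)$rmsd
    oracle <- quaternion_rmsd(as.matrix(fr$atoms[, c("x", "y", "z")]),
                              as.matrix(fr2$atoms[, c("x", "y", "z")]))
    expect_equal(got, oracle, tolerance = 1e-8)
  }
})

test_that("superposition reports unmatched atoms", {
  fr <- random_frame(10, seed = 1)
  fr$atoms$name <- "CA"; fr$atoms$resid <- 1:10; fr$atoms$chain <- "A"
  fr2 <- fr
  fr2$atoms$resid[10] <- 99L
  expect_error(superpose_rmsd(fr, fr2), "unmatched")
})
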