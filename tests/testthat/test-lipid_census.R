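test_that("engagement follows the cutoff definition exactly at the edge", {
  mk <- function(d) {
    atoms <- data.frame(
      serial = 1:2, name = c("C16", "CD1"), resname = c("LIP", "LEU"),
      resid = c(1L, 124L), chain = c("L", "A"), element = "C",
      x = c(d, 0), y = 0, z = 0, stringsAsFactors = FALSE)
    new_frame(atoms)
  }
  near <- engaged_tails(mk(4.9), tail_atoms = list(1L), collar_idx = 2L)
  far <- engaged_tails(mk(5.1), tail_atoms = list(1L), collar_idx = 2L)
  expect_equal(near$engaged_count, 1L)
  expect_equal(far$engaged_count, 0L)
  expect_equal(nrow(near$contact_pairs), 1)
  expect_equal(near$contact_pairs$distance, 4.9)
})

test_that("engagement equals all-pairs brute force on random configurations", {
  for (seed in 1:40) {
    fr <- random_frame(30, seed = seed,
                       box = if (seed %% 2) c(25, 25, 25) else NULL)
    tails <- split(1:8, rep(1:4, each = 2))
    collar <- 9:16
    rec <- engaged_tails(fr, tails, collar, cutoff = 5)
    oracle <- brute_engaged(fr, tails, collar, 5, fr$box)
    expect_identical(rec$per_tail, unname(oracle))
    expect_identical(rec$engaged_count, sum(oracle))
  }
})

test_that("occupancy distribution recounts frames and sums to one", {
  traj <- generate_pore_trajectory(pore_spec(seed = 13), 800)
  eng <- engagement_series(traj)
  occ <- occupancy_distribution(eng)
  expect_equal(sum(occ$prob), 1)
  expect_equal(sum(occ$n_frames), 800)
  # frame-by-frame recount oracle
  truth <- attr(traj, "truth")
  expect_identical(eng$engaged_count, as.integer(truth$engaged_count))
  for (k in occ$k)
    expect_equal(occ$n_frames[occ$k == k], sum(eng$engaged_count == k))
  # all-closed generator puts every frame at zero
  closed <- generate_pore_trajectory(pore_spec(engage_rate_in = 0, seed = 1),
                                     500)
  occ0 <- occupancy_distribution(engagement_series(closed))
  expect_equal(occ0$prob[occ0$k == 0], 1)
})

test_that("conditional area densities partition frames and match groupby", {
  traj <- generate_pore_trajectory(pore_spec(seed = 17), 3000)
  ser <- merge(engagement_series(traj), collar_series(traj), by = "frame")
  ks <- sort(unique(ser$engaged_count))
  n_tot <- 0
  for (k in ks) {
    cd <- conditional_area_density(ser, k)
    n_tot <- n_tot + cd$n
    expect_equal(cd$mean_area, mean(ser$area[ser$engaged_count == k]))
  }
  expect_equal(n_tot, nrow(ser))
  expect_error(conditional_area_density(ser, 99), "no frames")
  # construction: fully engaged frames have larger apertures than closed ones
  if (all(c(0, 4) %in% ks))
    expect_gt(conditional_area_density(ser, 4)$mean_area,
              conditional_area_density(ser, 0)$mean_area)
})

test_that("open-aperture probability increases with engagement count", {
  traj <- generate_pore_trajectory(pore_spec(seed = 19), 12000)
  ser <- merge(engagement_series(traj), collar_series(traj), by = "frame")
  conducting <- 40
  p_open <- vapply(0:3, function(k) {
    sub <- ser$area[ser$engaged_count == k]
    mean(sub >= conducting)
  }, 0)
  expect_true(all(diff(p_open) >= 0))
  expect_gt(p_open[4], p_open[1])
})

test_that("head-group contact fraction matches brute-force recount", {
  traj <- generate_pore_trajectory(pore_spec(seed = 23), 400)
  hf <- headgroup_contact_fraction(traj)
  # recount with explicit loops
  num <- 0L; den <- 0L
  tails <- split(traj$tags$tail_terminus,
                 traj$topology$resid[traj$tags$tail_terminus])
  heads <- split(traj$tags$headgroup_P,
                 traj$topology$resid[traj$tags$headgroup_P])
  for (i in seq_len(n_frames(traj)) - 1L) {
    fr <- get_frame(traj, i)
    xyz <- as.matrix(fr$atoms[, c("x", "y", "z")])
    for (t in seq_along(tails)) {
      dmin <- min(pair_dists(xyz[tails[[t]], , drop = FALSE],
                             xyz[traj$tags$collar_sidechain, , drop = FALSE]))
      if (dmin <= 5) {
        den <- den + 1L
        dh <- min(pair_dists(xyz[heads[[t]], , drop = FALSE],
                             xyz[traj$tags$site_HRW, , drop = FALSE]))
        if (dh <= 5) num <- num + 1L
      }
    }
  }
  expect_identical(hf$numerator, num)
  expect_identical(hf$denominator, den)
  expect_equal(hf$fraction, num / den)
})

test_that("density maps conserve counts and find an annulus peak", {
  # all heads at one point occupy a single bin
  traj <- generate_pore_trajectory(pore_spec(seed = 2), 5)
  traj$coords[traj$tags$headgroup_P, 1, ] <- 3.2
  traj$coords[traj$tags$headgroup_P, 2, ] <- -1.7
  traj$coords[traj$tags$headgroup_P, 3, ] <- 8
  dm <- headgroup_density_map(traj, leaflet_split_z = 0, bin = 1,
                              axis_xy = c(0, 0), r_max = 30)
  expect_equal(sum(dm$upper$counts > 0), 1)
  expect_equal(sum(dm$upper$counts) + sum(dm$lower$counts), 4 * 5)
  # conservation on unmodified generator output
  traj2 <- generate_pore_trajectory(pore_spec(seed = 3), 200)
  dm2 <- headgroup_density_map(traj2, leaflet_split_z = 0, bin = 2,
                               axis_xy = c(0, 0), r_max = 40)
  expect_equal(sum(dm2$upper$counts) + sum(dm2$lower$counts), 4 * 200)
  # never-engaged lipids sit on the annulus: radial peak in the 25-30 A band
  ann <- generate_pore_trajectory(pore_spec(engage_rate_in = 0, seed = 5), 500)
  dm3 <- headgroup_density_map(ann, leaflet_split_z = 0, bin = 1,
                               axis_xy = c(0, 0), r_max = 40)
  peak_r <- dm3$radial$upper$r[which.max(dm3$radial$upper$density)]
  expect_gte(peak_r, 25)
  expect_lte(peak_r, 30)
})
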