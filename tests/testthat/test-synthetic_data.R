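test_that("pore generator limits: never-engaged and always-engaged", {
  closed <- generate_pore_trajectory(
    pore_spec(engage_rate_in = 0, seed = 4), 2000)
  truth <- attr(closed, "truth")
  expect_true(all(truth$engaged_count == 0))
  z <- truth$ion_z + truth$collar_plane_rel
  expect_equal(nrow(detect_crossings(z, truth$collar_plane_rel, 2)), 0)

  open <- generate_pore_trajectory(
    pore_spec(engage_rate_in = 0.5, engage_rate_out = 0, seed = 4), 3000)
  t2 <- attr(open, "truth")
  # all tails engaged from the start (stationary probability 1)
  expect_true(all(t2$engaged_count == 4))
  ser <- collar_series(open)
  # aperture diagonals settle around 2 * r_open
  expect_equal(mean(c(ser$D1, ser$D2)), 2 * 5.2, tolerance = 0.05)
})

test_that("pore generator is bit-reproducible under a fixed seed", {
  a <- generate_pore_trajectory(pore_spec(seed = 11), 50)
  b <- generate_pore_trajectory(pore_spec(seed = 11), 50)
  expect_identical(a$coords, b$coords)
  c2 <- generate_channel_trace(channel_preset("decyl"), 2, 1000, seed = 8)
  c3 <- generate_channel_trace(channel_preset("decyl"), 2, 1000, seed = 8)
  expect_identical(c2$samples, c3$samples)
  w1 <- generate_umbrella_samples(flat_potential(c(-5, 5)), 0, 3000,
                                  n_per_window = 100, seed = 2)
  w2 <- generate_umbrella_samples(flat_potential(c(-5, 5)), 0, 3000,
                                  n_per_window = 100, seed = 2)
  expect_identical(w1[[1]]$samples, w2[[1]]$samples)
  f1 <- generate_flux_curve(noise_sd = 10, seed = 3)
  f2 <- generate_flux_curve(noise_sd = 10, seed = 3)
  expect_identical(f1$F, f2$F)
})

test_that("invalid generator configurations are rejected", {
  expect_error(pore_spec(r_open = 2, r_closed = 3), "r_open > r_closed")
  expect_error(pore_spec(engage_rate_in = -0.1), "rates")
  expect_error(pore_spec(ou_tau = 0), "invalid")
  expect_error(generate_flux_curve(noise_sd = -1), "noise_sd")
  expect_error(generate_flux_curve(k_decay = -0.1), "k_decay")
  P_bad <- matrix(c(0.5, 0.2, 0.3, 0.1, 0.1, 0.1, 0, 0, 1), 3, 3, byrow = TRUE)
  expect_error(channel_scheme(P_bad, c(0, 1, 3), 0.5), "row-stochastic")
})

test_that("umbrella sampler reproduces Gaussian closed-form variances", {
  # flat potential: var = kBT / k_bias
  k_force <- 3000                       # kJ/mol/nm^2 -> 30 kJ/mol/A^2
  w <- generate_umbrella_samples(flat_potential(c(-5, 5)), centers = 0,
                                 k_force = k_force, n_per_window = 50000,
                                 seed = 6)[[1]]
  expect_equal(var(w$samples), kBT(303.15) / 30, tolerance = 0.05)
  # harmonic potential of stiffness k_U: var = kBT / (k_U + k_bias); the
  # slightly wider tolerance absorbs the O(dt) Euler-Maruyama variance bias
  k_U <- 10
  w2 <- generate_umbrella_samples(harmonic_potential(k_U, 0, c(-5, 5)),
                                  centers = 0, k_force = k_force,
                                  n_per_window = 50000, seed = 6)[[1]]
  expect_equal(var(w2$samples), kBT(303.15) / (k_U + 30), tolerance = 0.08)
})

test_that("umbrella window means are monotone across a double well", {
  U <- double_well_potential(c(21.5, 31.5), 12)
  centers <- seq(16.5, 36.5, 0.5)
  wins <- generate_umbrella_samples(U, centers, 3000, n_per_window = 2000,
                                    seed = 9)
  means <- vapply(wins, function(w) mean(w$samples), 0)
  expect_true(all(diff(means) > 0))
  # oracle: quadrature means of the biased Boltzmann densities
  kT <- kBT(303.15)
  zq <- seq(14, 39, 0.01)
  oracle <- vapply(centers, function(c0) {
    wgt <- exp(-(U$fun(zq) + 0.5 * 30 * (zq - c0)^2) / kT)
    sum(zq * wgt) / sum(wgt)
  }, 0)
  expect_equal(means, oracle, tolerance = 0.02)
})

test_that("unstable umbrella integration settings are refused", {
  expect_error(generate_umbrella_samples(flat_potential(c(-5, 5)), 0,
                                         k_force = 3000, friction = 1,
                                         dt = 1, seed = 1),
               "unstable|instability")
})

test_that("channel trace generator honors degenerate schemes", {
  P2 <- matrix(c(0.98, 0.02, 0.05, 0.95), 2, 2, byrow = TRUE)
  sc <- channel_scheme(P2, c(0, 3.5), c(0, 0), classes = c("C", "O"))
  tr <- generate_channel_trace(sc, 2, 1000, seed = 3)
  expect_setequal(unique(tr$samples), c(0, 3.5))
  # absorbing open state: occupancy of O approaches 1
  P_abs <- matrix(c(0.9, 0.1, 0, 1), 2, 2, byrow = TRUE)
  sc2 <- channel_scheme(P_abs, c(0, 3.5), 0.1, classes = c("C", "O"))
  tr2 <- generate_channel_trace(sc2, 20, 1000, seed = 3)
  expect_gt(mean(tr2$hidden == 2), 0.98)
})

test_that("preset schemes have the prescribed stationary open occupancy", {
  # eigen-analysis oracle against the construction targets
  for (nm in c("decyl", "octyl", "hexyl")) {
    sc <- channel_preset(nm)
    pi_st <- stationary_distribution(sc$P)
    target <- c(decyl = 0.69, octyl = 0.41, hexyl = 0.46)[[nm]]
    expect_equal(pi_st[3], target, tolerance = 1e-10)
    expect_equal(rowSums(sc$P), rep(1, 3), tolerance = 1e-12)
  }
})

test_that("flux curve generator matches its closed form", {
  flat <- generate_flux_curve(k_decay = 0, noise_sd = 0, seed = 1)
  expect_true(all(flat$F[flat$t < attr(flat, "t_val")] == flat$F[1]))
  cv <- generate_flux_curve(F0 = 5000, F_inf = 1500, k_decay = 0.1,
                            noise_sd = 0, seed = 1)
  i10 <- which.min(abs(cv$t - 10))
  expect_equal(cv$F[i10], 1500 + 3500 * exp(-1), tolerance = 1e-6)
})

test_that("crossing probability increases with tail engagement", {
  # the generator's central causal structure at toy scale
  traj <- generate_pore_trajectory(pore_spec(seed = 21), 12000)
  truth <- attr(traj, "truth")
  ev <- detect_crossings(truth$ion_z + truth$collar_plane_rel,
                         truth$collar_plane_rel, 2)
  cross <- rep(FALSE, 12000)
  cross[ev$exit_frame + 1] <- TRUE
  k <- truth$engaged_count
  expect_gt(mean(cross[k >= 3]), mean(cross[k < 3]))
})
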