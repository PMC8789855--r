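#' One-dimensional potential for permeation toy models
#'
#' @param fun Function U(z), kJ/mol, finite on the domain.
#' @param grad Analytic gradient dU/dz; when `NULL` a central finite
#'   difference (h = 1e-4 angstrom) is used.
#' @param domain Length-2 numeric, z domain in angstrom.
#' @return A `potential_1d`.
#' @export
potential_1d <- function(fun, grad = NULL, domain) {
  stopifnot(is.function(fun), length(domain) == 2, domain[1] < domain[2])
  if (is.null(grad))
    grad <- function(z) (fun(z + 1e-4) - fun(z - 1e-4)) / 2e-4
  probe <- seq(domain[1], domain[2], length.out = 64)
  if (any(!is.finite(fun(probe)))) stop("potential not finite on domain")
  structure(list(fun = fun, grad = grad, domain = domain),
            class = "potential_1d")
}

#' @rdname potential_1d
#' @export
flat_potential <- function(domain) {
  potential_1d(function(z) rep(0, length(z)), function(z) rep(0, length(z)),
               domain)
}

#' @rdname potential_1d
#' @param k Stiffness, kJ mol^-1 A^-2.
#' @param center Well centre, angstrom.
#' @export
harmonic_potential <- function(k, center, domain) {
  potential_1d(function(z) 0.5 * k * (z - center)^2,
               function(z) k * (z - center), domain)
}

#' Symmetric double-well potential
#'
#' Quartic double well with minima at `wells` (both at U = 0) and a central
#' barrier of height `barrier` kJ/mol.
#'
#' @param wells Length-2 numeric, the two minima positions, angstrom.
#' @param barrier Barrier height at the midpoint, kJ/mol.
#' @param domain z domain (defaults to the wells widened by half their
#'   separation).
#' @export
double_well_potential <- function(wells = c(21.5, 31.5), barrier = 12,
                                  domain = NULL) {
  m <- mean(wells); w <- diff(wells)
  if (is.null(domain)) domain <- c(wells[1] - w / 2, wells[2] + w / 2)
  u <- function(z) 2 * (z - m) / w
  potential_1d(function(z) barrier * (u(z)^2 - 1)^2,
               function(z) (8 * barrier / w) * u(z) * (u(z)^2 - 1),
               domain)
}

# ---- toy pore ----------------------------------------------------------

#' Specification for the synthetic gated-pore generator
#'
#' Defines a four-fold pseudo-pore whose collar aperture opens in response
#' to stochastic lipid-tail engagement. Per fenestration, engagement is a
#' two-state telegraph process; the collar-tip midpoint of that subunit
#' performs a mean-reverting (Ornstein-Uhlenbeck) walk about `r_closed`,
#' retargeted to `r_open` while the tail is engaged. One K+ ion performs
#' overdamped 1-D diffusion along the axis in a Gaussian barrier centred at
#' the collar whose height decreases linearly with the number of engaged
#' tails, `B(k) = max(0, B0 - k * dB)`; defaults put the fully closed barrier
#' far above thermal energy and the fully engaged barrier near it. Water
#' oxygens are placed so the ion's 3-angstrom coordination count is 6-7 in
#' bulk and 4-5 while passing the collar.
#'
#' @param collar_z Collar plane height, angstrom.
#' @param r_closed,r_open Radial positions of the collar-tip midpoints in the
#'   closed and engaged states, angstrom (`r_open > r_closed > 0`).
#' @param ou_tau Relaxation time of the radial walk, frames.
#' @param ou_sigma Stationary fluctuation SD of the radial walk, angstrom.
#' @param n_tails Tails per fenestration.
#' @param engage_rate_in,engage_rate_out Per-frame engage/disengage
#'   probabilities (in \[0, 1)).
#' @param open_threshold Engaged-tail count regarded as full opening (used
#'   for reporting; the barrier decreases continuously with count).
#' @param water_count Total water oxygens placed per frame.
#' @param barrier_B0 Closed-state barrier height, kJ/mol.
#' @param barrier_dB Barrier decrease per engaged tail, kJ/mol.
#' @param ion_D Ion diffusion coefficient, A^2/frame.
#' @param z_wall Reflecting wall position (|z - collar_z|), angstrom.
#' @param head_site_prob Probability that the head group of an engaged lipid
#'   sits within contact range of the canonical His/Trp/Arg site.
#' @param head_annulus_r Radius of the annulus on which non-engaged head
#'   groups are placed, angstrom.
#' @param temperature Temperature (K) setting thermal energy for the ion.
#' @param seed RNG seed (generation is bit-reproducible under it).
#' @return A `pore_spec`.
#' @export
pore_spec <- function(collar_z = 0, r_closed = 2.1, r_open = 5.2,
                      ou_tau = 10, ou_sigma = 0.3, n_tails = 1,
                      engage_rate_in = 0.02, engage_rate_out = 0.02,
                      open_threshold = 3, water_count = 30,
                      barrier_B0 = 25, barrier_dB = 6, ion_D = 1,
                      z_wall = 12, head_site_prob = 0.955,
                      head_annulus_r = 27, temperature = 303.15, seed = 1) {
  if (!(r_open > r_closed && r_closed > 0))
    stop("require r_open > r_closed > 0")
  if (engage_rate_in < 0 || engage_rate_in >= 1 ||
      engage_rate_out < 0 || engage_rate_out >= 1)
    stop("engagement rates must lie in [0, 1)")
  if (ou_tau <= 0 || ou_sigma < 0 || ion_D <= 0 || water_count < 8 ||
      barrier_B0 < 0 || barrier_dB < 0 || n_tails < 1)
    stop("invalid pore spec parameter")
  structure(as.list(environment()), class = "pore_spec")
}

.unit_dirs <- function(n) {
  v <- matrix(rnorm(3 * n), n, 3)
  v / sqrt(rowSums(v^2))
}

#' Generate a synthetic gated-pore trajectory
#'
#' @param spec A [pore_spec()].
#' @param n_frames Number of frames (>= 1).
#' @return A `trajectory` with all role tags populated and an attribute
#'   `truth`: list with the per-frame engaged matrix, ion z, and the collar
#'   plane position on the reaction coordinate (`collar_plane_rel`).
#' @export
generate_pore_trajectory <- function(spec, n_frames) {
  stopifnot(inherits(spec, "pore_spec"), n_frames >= 1)
  set.seed(spec$seed)
  nf <- as.integer(n_frames)
  ns <- 4L
  n_tail <- ns * spec$n_tails
  phi <- (seq_len(ns) - 1) * pi / 2

  # telegraph engagement, one column per tail
  p_st <- if (spec$engage_rate_in + spec$engage_rate_out > 0)
    spec$engage_rate_in / (spec$engage_rate_in + spec$engage_rate_out) else 0
  eng <- matrix(FALSE, nf, n_tail)
  state <- runif(n_tail) < p_st
  u <- matrix(runif(nf * n_tail), nf, n_tail)
  for (t in seq_len(nf)) {
    flip_on <- !state & (u[t, ] < spec$engage_rate_in)
    flip_off <- state & (u[t, ] < spec$engage_rate_out)
    state <- (state | flip_on) & !flip_off
    eng[t, ] <- state
  }
  # a fenestration is open while any of its tails is engaged
  fen <- matrix(FALSE, nf, ns)
  for (s in seq_len(ns))
    fen[, s] <- rowSums(eng[, ((s - 1) * spec$n_tails + 1):(s * spec$n_tails),
                            drop = FALSE]) > 0
  k_eng <- rowSums(eng)

  # OU radial walk per subunit, retargeted by fenestration state
  r <- matrix(NA_real_, nf, ns)
  target0 <- ifelse(fen[1, ], spec$r_open, spec$r_closed)
  cur <- target0
  noise <- matrix(rnorm(nf * ns, sd = spec$ou_sigma * sqrt(2 / spec$ou_tau)),
                  nf, ns)
  for (t in seq_len(nf)) {
    target <- ifelse(fen[t, ], spec$r_open, spec$r_closed)
    cur <- cur + (target - cur) / spec$ou_tau + noise[t, ]
    cur <- pmax(cur, 0.5)
    r[t, ] <- cur
  }

  # overdamped ion diffusion through the count-dependent barrier
  kT <- kBT(spec$temperature)
  B <- pmax(0, spec$barrier_B0 - k_eng * spec$barrier_dB)
  sig_b <- 2.0
  zi <- numeric(nf)
  z <- spec$collar_z - 8
  # substep the Euler-Maruyama integration so the step stays well below the
  # barrier width (otherwise the discretization leaks the closed barrier)
  n_sub <- 5L
  dt_sub <- 1 / n_sub
  step_sd <- sqrt(2 * spec$ion_D * dt_sub)
  gauss_step <- matrix(rnorm(nf * n_sub), n_sub, nf)
  for (t in seq_len(nf)) {
    for (ss in seq_len(n_sub)) {
      dz <- z - spec$collar_z
      gradU <- B[t] * exp(-dz^2 / (2 * sig_b^2)) * (-dz / sig_b^2)
      # reflecting quartic walls
      over <- abs(dz) - spec$z_wall
      if (over > 0) gradU <- gradU + sign(dz) * 20 * over
      z <- z - gradU * spec$ion_D * dt_sub / kT + step_sd * gauss_step[ss, t]
      z <- min(max(z, spec$collar_z - spec$z_wall - 2),
               spec$collar_z + spec$z_wall + 2)
    }
    zi[t] <- z
  }

  # ---- topology --------------------------------------------------------
  chains <- c("A", "B", "C", "D")
  topo <- rbind(
    data.frame(serial = 1:8,
               name = rep(c("CD1", "CD2"), ns),
               resname = "LEU", resid = 124L,
               chain = rep(chains, each = 2), element = "C"),
    data.frame(serial = 9:12, name = "CA", resname = "THR", resid = 96L,
               chain = chains, element = "C"),
    data.frame(serial = 12 + seq_len(n_tail), name = "C16", resname = "LIP",
               resid = as.integer(rep(seq_len(ns), each = spec$n_tails)),
               chain = "L", element = "C"),
    data.frame(serial = 12 + n_tail + 1:4, name = "P", resname = "LIP",
               resid = 1:4, chain = "L", element = "P"),
    data.frame(serial = 12 + n_tail + 4 + 1:12,
               name = "CB",
               resname = rep(c("HIS", "TRP", "ARG"), ns),
               resid = rep(c(37L, 46L, 137L), ns),
               chain = rep(chains, each = 3), element = "C"),
    data.frame(serial = 12 + n_tail + 17, name = "K", resname = "K",
               resid = 500L, chain = "I", element = "K"),
    data.frame(serial = 12 + n_tail + 17 + seq_len(spec$water_count),
               name = "O", resname = "HOH",
               resid = 600L + seq_len(spec$water_count),
               chain = "W", element = "O")
  )
  nat <- nrow(topo)
  coords <- array(0, c(nat, 3, nf))

  tang <- cbind(-sin(phi), cos(phi), 0)
  radial <- cbind(cos(phi), sin(phi), 0)

  # collar Cd1/Cd2 straddle the subunit midpoint tangentially
  for (s in seq_len(ns)) {
    mid <- cbind(r[, s] * radial[s, 1], r[, s] * radial[s, 2], spec$collar_z)
    coords[2 * s - 1, , ] <- t(mid + matrix(0.8 * tang[s, ], nf, 3, byrow = TRUE))
    coords[2 * s, , ] <- t(mid - matrix(0.8 * tang[s, ], nf, 3, byrow = TRUE))
  }
  # Thr96 reference ring, 10 A below the collar plane
  for (s in seq_len(ns)) {
    coords[8 + s, 1, ] <- 6 * radial[s, 1]
    coords[8 + s, 2, ] <- 6 * radial[s, 2]
    coords[8 + s, 3, ] <- spec$collar_z - 10
  }
  # tail termini: engaged -> just outside the collar tip; else far out
  jit <- array(rnorm(n_tail * 3 * nf, sd = 0.25), c(n_tail, 3, nf))
  for (j in seq_len(n_tail)) {
    s <- (j - 1) %/% spec$n_tails + 1
    rt <- ifelse(eng[, j], r[, s] + 2.5, r[, s] + 9)
    coords[12 + j, 1, ] <- rt * radial[s, 1] + jit[j, 1, ]
    coords[12 + j, 2, ] <- rt * radial[s, 2] + jit[j, 2, ]
    coords[12 + j, 3, ] <- spec$collar_z + jit[j, 3, ]
  }
  # canonical site ring (His37/Trp46/Arg137 analogues) at the interface
  site_centroid <- matrix(NA_real_, ns, 3)
  for (s in seq_len(ns)) {
    for (a in 1:3) {
      idx <- 12 + n_tail + 4 + (s - 1) * 3 + a
      ang <- phi[s] + (a - 2) * 0.08
      coords[idx, 1, ] <- 14 * cos(ang)
      coords[idx, 2, ] <- 14 * sin(ang)
      coords[idx, 3, ] <- spec$collar_z + 6 + (a - 2) * 0.5
    }
    site_centroid[s, ] <- c(14 * cos(phi[s]), 14 * sin(phi[s]),
                            spec$collar_z + 6)
  }
  # head groups: engaged lipids mostly dock at the site; otherwise annulus
  at_site <- matrix(runif(nf * ns) < spec$head_site_prob, nf, ns)
  ann_phi <- matrix(runif(nf * ns, 0, 2 * pi), nf, ns)
  ann_r <- matrix(rnorm(nf * ns, spec$head_annulus_r, 1.0), nf, ns)
  hjit <- array(rnorm(ns * 3 * nf, sd = 0.8), c(ns, 3, nf))
  for (s in seq_len(ns)) {
    idx <- 12 + n_tail + s
    dock <- fen[, s] & at_site[, s]
    coords[idx, 1, ] <- ifelse(dock, site_centroid[s, 1] + hjit[s, 1, ],
                               ann_r[, s] * cos(ann_phi[, s]))
    coords[idx, 2, ] <- ifelse(dock, site_centroid[s, 2] + hjit[s, 2, ],
                               ann_r[, s] * sin(ann_phi[, s]))
    coords[idx, 3, ] <- ifelse(dock, site_centroid[s, 3] + hjit[s, 3, ],
                               spec$collar_z + 10)
  }
  # ion
  ion_idx <- 12 + n_tail + 17
  coords[ion_idx, 1, ] <- rnorm(nf, sd = 0.3)
  coords[ion_idx, 2, ] <- rnorm(nf, sd = 0.3)
  coords[ion_idx, 3, ] <- zi
  # waters: first-shell count 6-7 in bulk, 4-5 at the collar
  nw <- spec$water_count
  at_collar <- abs(zi - spec$collar_z) <= 3
  n_shell <- ifelse(at_collar, 4L, 6L) + (runif(nf) < 0.5)
  dirs <- .unit_dirs(nw * nf)
  shell_mask <- outer(seq_len(nw), n_shell, "<=")          # nw x nf
  rad_w <- matrix(runif(nw * nf, 2.3, 2.9), nw, nf)
  rad_w[!shell_mask] <- runif(sum(!shell_mask), 5, 12)
  ion_pos <- coords[ion_idx, , ]                           # 3 x nf
  for (d in 1:3) {
    dm <- matrix(dirs[, d], nw, nf)
    coords[12 + n_tail + 17 + seq_len(nw), d, ] <-
      matrix(ion_pos[d, ], nw, nf, byrow = TRUE) + dm * rad_w
  }

  tags <- list(
    collar_sidechain = 1:8,
    reference_T96 = 9:12,
    tail_terminus = 12 + seq_len(n_tail),
    headgroup_P = 12 + n_tail + 1:4,
    site_HRW = 12 + n_tail + 4 + 1:12,
    ion_K = ion_idx,
    water_O = 12 + n_tail + 17 + seq_len(nw)
  )
  traj <- new_trajectory(topo, coords, box = NULL, dt = 10, tags = tags)
  attr(traj, "truth") <- list(engaged = eng, fenestration = fen,
                              engaged_count = k_eng, ion_z = zi,
                              collar_plane_rel = 10)
  traj
}

# ---- umbrella sampling -------------------------------------------------

#' Generate umbrella-sampling windows by overdamped Langevin dynamics
#'
#' Euler-Maruyama integration of
#' \eqn{dz = -(U'(z) + k (z - z_0)) dt/\gamma + \sqrt{2 k_B T dt/\gamma}\,\xi}
#' per window; the first `burn_in` fraction of samples is discarded.
#'
#' @param U A [potential_1d()].
#' @param centers Window centres, angstrom (within the domain).
#' @param k_force Bias force constant, kJ mol^-1 nm^-2.
#' @param n_per_window Retained samples per window.
#' @param temperature Temperature, K.
#' @param friction Friction coefficient gamma, kJ mol^-1 ps A^-2; the
#'   integration step must satisfy `dt * k / gamma < 0.1` (per-angstrom k),
#'   enforced as a configuration error.
#' @param dt Time step, ps.
#' @param seed RNG seed.
#' @param burn_in Fraction of each window discarded as burn-in.
#' @param thin Keep every `thin`-th integration step, so retained samples
#'   are decorrelated (the integrator's correlation time is roughly
#'   `friction / (k dt)` steps).
#' @return List of `umbrella_window` objects.
#' @export
generate_umbrella_samples <- function(U, centers, k_force = 3000,
                                      n_per_window = 5000,
                                      temperature = 303.15, friction = 50,
                                      dt = 0.1, seed = 1, burn_in = 0.1,
                                      thin = 20) {
  stopifnot(inherits(U, "potential_1d"), k_force > 0)
  if (any(centers < U$domain[1] | centers > U$domain[2]))
    stop("window centers outside potential domain")
  kA <- .k_per_A2(k_force)
  if (dt * kA / friction >= 0.1)
    stop("unstable integration step: require dt * k / friction < 0.1")
  set.seed(seed)
  kT <- kBT(temperature)
  stopifnot(thin >= 1)
  nwin <- length(centers)
  nburn <- ceiling(burn_in * n_per_window) * thin
  ntot <- n_per_window * thin + nburn
  width <- diff(U$domain)
  z <- centers
  noise_sd <- sqrt(2 * kT * dt / friction)
  out <- matrix(NA_real_, n_per_window, nwin)
  for (t in seq_len(ntot)) {
    force <- U$grad(z) + kA * (z - centers)
    step <- -force * dt / friction + rnorm(nwin, sd = noise_sd)
    if (any(abs(step) > width))
      stop("integration instability: step exceeds domain width")
    z <- z + step
    if (t > nburn && (t - nburn) %% thin == 0)
      out[(t - nburn) %/% thin, ] <- z
  }
  lapply(seq_len(nwin), function(i)
    umbrella_window(centers[i], k_force, out[, i], temperature))
}

# ---- channel traces ----------------------------------------------------

#' Three-level channel kinetic scheme
#'
#' @param P Row-stochastic transition matrix (per sample at the recording
#'   rate), states ordered C, S, O.
#' @param level_mean Current level per class, pA, strictly ordered by
#'   magnitude C < S < O.
#' @param level_sd Gaussian noise SD per class, pA (recycled).
#' @param classes Class labels.
#' @return A `channel_scheme`.
#' @export
channel_scheme <- function(P, level_mean, level_sd,
                           classes = c("C", "S", "O")) {
  P <- as.matrix(P)
  if (nrow(P) != ncol(P) || any(P < 0) ||
      max(abs(rowSums(P) - 1)) > 1e-8)
    stop("P must be a row-stochastic square matrix")
  if (length(level_mean) != nrow(P)) stop("one level mean per state required")
  if (any(diff(abs(level_mean)) <= 0))
    stop("level means must be strictly ordered by magnitude (C < S < O)")
  level_sd <- rep(level_sd, length.out = nrow(P))
  structure(list(P = P, level_mean = level_mean, level_sd = level_sd,
                 classes = classes), class = "channel_scheme")
}

#' Stationary distribution of a transition matrix
#'
#' Left eigenvector of `P` for eigenvalue 1, normalized to sum 1.
#'
#' @param P Row-stochastic matrix.
#' @return Numeric probability vector.
#' @export
stationary_distribution <- function(P) {
  e <- eigen(t(P))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  v / sum(v)
}

#' Build a reversible three-state scheme with a target occupancy
#'
#' Constructs a birth-death chain C - S - O satisfying detailed balance with
#' the requested stationary distribution; used to build presets whose
#' open-class occupancy equals a prescribed open probability.
#'
#' @param occupancy Target stationary probabilities (C, S, O), summing to 1.
#' @param a Per-sample C to S transition probability (sets the closed dwell
#'   time scale; the default keeps closed dwells well below typical burst
#'   separation criteria).
#' @param d Per-sample O to S transition probability.
#' @param level_mean,level_sd Emission levels, pA.
#' @return A `channel_scheme` whose stationary distribution equals
#'   `occupancy` (verifiable with [stationary_distribution()]).
#' @export
scheme_from_occupancy <- function(occupancy, a = 0.08, d = 0.03,
                                  level_mean = c(0, 1.4, 3.5),
                                  level_sd = 0.525) {
  stopifnot(length(occupancy) == 3, abs(sum(occupancy) - 1) < 1e-8,
            all(occupancy > 0))
  b <- a * occupancy[1] / occupancy[2]
  cc <- d * occupancy[3] / occupancy[2]
  if (b + cc >= 1 || a >= 1 || d >= 1)
    stop("rates too fast for the requested occupancy")
  P <- rbind(c(1 - a, a, 0),
             c(b, 1 - b - cc, cc),
             c(0, d, 1 - d))
  channel_scheme(P, level_mean, level_sd)
}

#' Packaged kinetic presets
#'
#' Presets named after alkyl-chain derivatised channel constructs; each
#' stores the target stationary occupancies (C, S, O) and emission levels
#' from which [scheme_from_occupancy()] builds the transition matrix. The
#' open-class occupancies equal the burst-wise open probabilities reported
#' for the corresponding constructs (decyl 0.69, octyl 0.41, hexyl 0.46).
#'
#' @param name Preset name (`"decyl"`, `"octyl"`, `"hexyl"`).
#' @return A `channel_scheme`.
#' @export
channel_preset <- function(name) {
  path <- system.file("extdata", "presets.json", package = "lipogate")
  presets <- jsonlite::read_json(path, simplifyVector = TRUE)$channel
  if (!name %in% names(presets))
    stop("unknown channel preset '", name, "'; available: ",
         paste(names(presets), collapse = ", "))
  p <- presets[[name]]
  scheme_from_occupancy(p$occupancy, a = p$a, d = p$d,
                        level_mean = p$level_mean, level_sd = p$level_sd)
}

#' Construct a channel current trace
#'
#' @param samples Current samples, pA.
#' @param fs Sampling rate, Hz.
#' @param voltage Holding potential, mV.
#' @param hidden Optional true class path (from the generator).
#' @param filter_history Character record of applied operations.
#' @return A `channel_trace`.
#' @export
channel_trace <- function(samples, fs, voltage = NA_real_, hidden = NULL,
                          filter_history = character()) {
  stopifnot(fs > 0, all(is.finite(samples)))
  structure(list(samples = as.numeric(samples), fs = fs, voltage = voltage,
                 hidden = hidden, filter_history = filter_history),
            class = "channel_trace")
}

#' Simulate a three-level single-channel current trace
#'
#' Hidden path simulated from the scheme's transition matrix; observation is
#' the class level mean plus Gaussian noise. The true path is retained in
#' the trace for oracle tests.
#'
#' @param scheme A `channel_scheme`.
#' @param duration Record length, s (`duration * fs >= 1000`).
#' @param fs Sampling rate, Hz.
#' @param seed RNG seed.
#' @return A `channel_trace` with `hidden` set.
#' @export
generate_channel_trace <- function(scheme, duration, fs = 1000, seed = 1) {
  stopifnot(inherits(scheme, "channel_scheme"))
  n <- round(duration * fs)
  if (n < 1000) stop("duration * fs must be at least 1000 samples")
  set.seed(seed)
  ns <- nrow(scheme$P)
  cum <- t(apply(scheme$P, 1, cumsum))
  path <- integer(n)
  s <- which.max(stationary_distribution(scheme$P))
  u <- runif(n)
  for (t in seq_len(n)) {
    s <- findInterval(u[t], cum[s, ]) + 1L
    path[t] <- s
  }
  obs <- scheme$level_mean[path] +
    rnorm(n, sd = scheme$level_sd[path])
  channel_trace(obs, fs = fs, voltage = -80, hidden = path)
}

# ---- flux curves -------------------------------------------------------

#' Construct a flux-assay fluorescence curve
#'
#' @param t Time, minutes; protonophore addition defines t = 0.
#' @param F Fluorescence, arbitrary units.
#' @param t_val Time of ionophore (valinomycin) addition, min.
#' @param baseline_window Pre-addition baseline interval, min.
#' @return A `flux_curve` (data frame with attributes).
#' @export
flux_curve <- function(t, F, t_val, baseline_window = c(-3, 0)) {
  stopifnot(all(diff(t) > 0), t_val > 0, length(t) == length(F))
  out <- data.frame(t = t, F = F)
  attr(out, "t_val") <- t_val
  attr(out, "baseline_window") <- baseline_window
  class(out) <- c("flux_curve", "data.frame")
  out
}

#' Simulate an ACMA-style flux-assay fluorescence time course
#'
#' Baseline at `F0` for 3 min before protonophore addition (t = 0);
#' first-order decay toward `F_inf` until valinomycin addition at `t_val`;
#' then a fast relaxation to the valinomycin floor.
#'
#' @param F0 Initial (maximal) fluorescence, a.u.
#' @param F_inf Asymptote of the channel-mediated decay, a.u.
#' @param k_decay First-order rate constant, min^-1 (>= 0).
#' @param t_val Valinomycin addition time, min.
#' @param noise_sd Gaussian noise SD, a.u. (>= 0).
#' @param seed RNG seed.
#' @param dt Sampling interval, min.
#' @param t_end End of record, min.
#' @param vali_floor Post-valinomycin plateau, a.u.
#' @param vali_k Rate of the post-valinomycin relaxation, min^-1.
#' @return A `flux_curve`.
#' @export
generate_flux_curve <- function(F0 = 5000, F_inf = 1500, k_decay = 0.1,
                                t_val = 35, noise_sd = 0, seed = 1,
                                dt = 0.1, t_end = t_val + 20,
                                vali_floor = F_inf, vali_k = 3) {
  if (k_decay < 0) stop("k_decay must be nonnegative")
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  stopifnot(t_val > 0)
  set.seed(seed)
  t <- seq(-3, t_end, by = dt)
  Fv <- numeric(length(t))
  pre <- t < 0
  dec <- t >= 0 & t < t_val
  post <- t >= t_val
  Fv[pre] <- F0
  Fv[dec] <- F_inf + (F0 - F_inf) * exp(-k_decay * t[dec])
  F_at_val <- F_inf + (F0 - F_inf) * exp(-k_decay * t_val)
  Fv[post] <- vali_floor + (F_at_val - vali_floor) *
    exp(-vali_k * (t[post] - t_val))
  if (noise_sd > 0) Fv <- Fv + rnorm(length(t), sd = noise_sd)
  flux_curve(t, Fv, t_val = t_val)
}
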