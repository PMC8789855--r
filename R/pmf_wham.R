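#' Construct an umbrella-sampling window
#'
#' @param center Restraint centre z0, angstrom.
#' @param k_force Harmonic force constant, kJ mol^-1 nm^-2 (the MD engine
#'   convention; converted to per-angstrom internally, once).
#' @param samples Numeric vector of sampled reaction-coordinate values,
#'   angstrom.
#' @param temperature Temperature, K.
#' @return An `umbrella_window`.
#' @export
umbrella_window <- function(center, k_force, samples, temperature = 303.15) {
  stopifnot(k_force >= 0, length(samples) >= 1, all(is.finite(samples)),
            temperature > 0)
  structure(list(center = center, k_force = k_force,
                 samples = as.numeric(samples), temperature = temperature),
            class = "umbrella_window")
}

# kJ mol^-1 nm^-2 -> kJ mol^-1 A^-2
.k_per_A2 <- function(k_force_nm) k_force_nm / 100

.window_overlap_check <- function(occ, bin_width) {
  # occupied-bin connectivity: windows form one component when each window
  # shares at least one occupied bin with the union of its predecessors
  n <- length(occ)
  if (n == 1) return(invisible(TRUE))
  comp <- seq_len(n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (length(intersect(occ[[i]], occ[[j]])))
      comp[comp == comp[j]] <- comp[i]
  }
  if (length(unique(comp)) > 1)
    stop("umbrella windows do not overlap: histograms form ",
         length(unique(comp)), " disconnected groups")
  invisible(TRUE)
}

#' Weighted histogram analysis (WHAM) of umbrella windows
#'
#' Self-consistent unbiasing of harmonically biased samples. With per-window
#' bias \eqn{w_i(z) = k/2 (z - z_i)^2}, the unbiased density and window free
#' energies are iterated to convergence:
#' \deqn{\rho(z_b) = \sum_i n_i(z_b) / \sum_i N_i \exp[(f_i - w_i(z_b))/k_BT]}
#' \deqn{f_i = -k_BT \ln \sum_b \rho(z_b) \exp(-w_i(z_b)/k_BT)}
#' The free-energy profile is \eqn{G = -k_BT \ln \rho}, shifted so its
#' minimum is zero.
#'
#' @param windows List of `umbrella_window` objects.
#' @param bin_width Histogram bin width, angstrom.
#' @param tol Convergence tolerance on max |change in f_i|, kJ/mol.
#' @param max_iter Iteration cap; a non-converged result is returned flagged,
#'   not thrown.
#' @param f_init Optional warm-start window free energies.
#' @return A `pmf_profile` list: `z` (bin centres), `G` (kJ/mol, min 0),
#'   `rho`, `f` (window free energies, first window gauged to 0),
#'   `n_iterations`, `converged`, `temperature`, `bin_width`.
#' @export
wham <- function(windows, bin_width = 0.1, tol = 1e-6, max_iter = 50000,
                 f_init = NULL) {
  stopifnot(length(windows) >= 1, bin_width > 0)
  temperature <- windows[[1]]$temperature
  if (any(vapply(windows, function(w) w$temperature, 0) != temperature))
    stop("windows must share one temperature")
  kT <- kBT(temperature)
  allz <- unlist(lapply(windows, `[[`, "samples"))
  lo <- floor(min(allz) / bin_width) * bin_width
  hi <- ceiling(max(allz) / bin_width) * bin_width
  edges <- seq(lo, hi + bin_width / 2, by = bin_width)
  z <- (edges[-1] + edges[-length(edges)]) / 2
  nb <- length(z)
  nw <- length(windows)
  counts <- matrix(0, nw, nb)
  for (i in seq_len(nw)) {
    b <- findInterval(windows[[i]]$samples, edges, rightmost.closed = TRUE)
    counts[i, ] <- tabulate(b, nbins = nb)
  }
  occ <- lapply(seq_len(nw), function(i) which(counts[i, ] > 0))
  .window_overlap_check(occ, bin_width)
  centers <- vapply(windows, `[[`, 0, "center")
  if (nw > 1) {
    # adjacent windows (by centre) should share at least one occupied bin
    ord <- order(centers)
    for (i in seq_len(nw - 1)) {
      if (!length(intersect(occ[[ord[i]]], occ[[ord[i + 1]]]))) {
        warning("gap between windows centred at ", centers[ord[i]], " and ",
                centers[ord[i + 1]], " exceeds the bin width")
        break
      }
    }
  }
  kA <- vapply(windows, function(w) .k_per_A2(w$k_force), 0)
  W <- t(vapply(seq_len(nw), function(i) 0.5 * kA[i] * (z - centers[i])^2,
                numeric(nb)))
  N <- rowSums(counts)
  nz <- colSums(counts)
  f <- if (!is.null(f_init)) f_init else numeric(nw)
  expW <- exp(-W / kT)                      # nw x nb, bias Boltzmann factors
  converged <- FALSE
  it <- 0L
  repeat {
    it <- it + 1L
    denom <- as.vector(t(N * exp(f / kT)) %*% expW)   # sum_i N_i e^{(f_i-W_ib)/kT}
    rho <- nz / denom
    rho[denom == 0] <- 0
    fnew <- -kT * log(as.vector(expW %*% rho))
    fnew <- fnew - fnew[1]
    delta <- max(abs(fnew - f))
    f <- fnew
    if (delta < tol) { converged <- TRUE; break }
    if (it >= max_iter) break
  }
  G <- -kT * log(rho)
  keep <- is.finite(G)
  G <- G - min(G[keep])
  structure(list(z = z, G = G, rho = rho, f = f,
                 n_iterations = it, converged = converged,
                 temperature = temperature, bin_width = bin_width,
                 counts = counts, centers = centers, k_per_A2 = kA),
            class = "pmf_profile")
}

#' Bayesian-bootstrap confidence band for a WHAM profile
#'
#' Each replicate reweights whole windows with Dirichlet(1, ..., 1) weights
#' (the Bayesian bootstrap; resampling unit = complete window histogram) and
#' re-solves the WHAM equations; the band is the central 95% interval across
#' replicates after aligning every replicate to min zero. A per-sample
#' weighting variant is available via `unit = "sample"`, which draws
#' Dirichlet weights over samples within every window and rebuilds the
#' histograms.
#'
#' @param windows List of `umbrella_window` objects.
#' @param n_boot Number of bootstrap replicates (default 200).
#' @param tol WHAM tolerance per replicate.
#' @param seed RNG seed.
#' @param bin_width Histogram bin width, angstrom.
#' @param level Interval coverage (default 0.95).
#' @param unit `"window"` (default) or `"sample"` resampling unit.
#' @return List with `profile` (full-data `pmf_profile`), `ci_lo`, `ci_hi`
#'   (kJ/mol per bin), `n_boot_used`, `n_dropped` (non-converged replicates,
#'   dropped and counted).
#' @export
bayesian_bootstrap <- function(windows, n_boot = 200, tol = 1e-6, seed = 1,
                               bin_width = 0.1, level = 0.95,
                               unit = c("window", "sample")) {
  unit <- match.arg(unit)
  full <- wham(windows, bin_width = bin_width, tol = tol)
  if (!full$converged) stop("WHAM did not converge on the full data")
  set.seed(seed)
  nw <- length(windows)
  reps <- matrix(NA_real_, n_boot, length(full$z))
  dropped <- 0L
  for (b in seq_len(n_boot)) {
    wts <- rgamma(nw, 1); wts <- wts / sum(wts) * nw
    prof <- if (unit == "window") {
      .wham_weighted(windows, wts, bin_width, tol, f_init = full$f)
    } else {
      ww <- lapply(windows, function(w) {
        sw <- rgamma(length(w$samples), 1)
        attr(w, "sample_weights") <- sw / sum(sw) * length(sw)
        w
      })
      .wham_weighted(ww, rep(1, nw), bin_width, tol, f_init = full$f)
    }
    if (!prof$converged) { dropped <- dropped + 1L; next }
    Gi <- approx(prof$z, prof$G, xout = full$z, rule = 2)$y
    reps[b, ] <- Gi - min(Gi, na.rm = TRUE)
  }
  ok <- !is.na(reps[, 1])
  a <- (1 - level) / 2
  ci <- apply(reps[ok, , drop = FALSE], 2, quantile, probs = c(a, 1 - a),
              na.rm = TRUE)
  list(profile = full, ci_lo = ci[1, ], ci_hi = ci[2, ],
       n_boot_used = sum(ok), n_dropped = dropped)
}

# WHAM with per-window multiplicative weights (Dirichlet bootstrap); shares
# the bin grid construction with wham() but scales counts.
.wham_weighted <- function(windows, wts, bin_width, tol, f_init = NULL,
                           max_iter = 50000) {
  temperature <- windows[[1]]$temperature
  kT <- kBT(temperature)
  allz <- unlist(lapply(windows, `[[`, "samples"))
  lo <- floor(min(allz) / bin_width) * bin_width
  hi <- ceiling(max(allz) / bin_width) * bin_width
  edges <- seq(lo, hi + bin_width / 2, by = bin_width)
  z <- (edges[-1] + edges[-length(edges)]) / 2
  nb <- length(z)
  nw <- length(windows)
  counts <- matrix(0, nw, nb)
  for (i in seq_len(nw)) {
    b <- findInterval(windows[[i]]$samples, edges, rightmost.closed = TRUE)
    sw <- attr(windows[[i]], "sample_weights")
    if (is.null(sw)) counts[i, ] <- tabulate(b, nbins = nb) * wts[i]
    else counts[i, ] <- vapply(seq_len(nb), function(bb) sum(sw[b == bb]),
                               0) * wts[i]
  }
  centers <- vapply(windows, `[[`, 0, "center")
  kA <- vapply(windows, function(w) .k_per_A2(w$k_force), 0)
  W <- t(vapply(seq_len(nw), function(i) 0.5 * kA[i] * (z - centers[i])^2,
                numeric(nb)))
  N <- rowSums(counts)
  nz <- colSums(counts)
  f <- if (!is.null(f_init)) f_init else numeric(nw)
  expW <- exp(-W / kT)
  converged <- FALSE
  it <- 0L
  repeat {
    it <- it + 1L
    denom <- as.vector(t(N * exp(f / kT)) %*% expW)
    rho <- nz / denom
    rho[denom == 0] <- 0
    fnew <- -kT * log(as.vector(expW %*% rho))
    fnew <- fnew - fnew[1]
    delta <- max(abs(fnew - f))
    f <- fnew
    if (delta < tol) { converged <- TRUE; break }
    if (it >= max_iter) break
  }
  G <- -kT * log(rho)
  keep <- is.finite(G)
  G <- G - min(G[keep])
  list(z = z, G = G, f = f, converged = converged)
}

#' Barrier height from a free-energy profile
#'
#' @param profile A `pmf_profile`.
#' @param region Length-2 numeric, z interval containing the barrier.
#' @param ref `"global-min"` (default) or `"left-min"` (minimum left of the
#'   region) as the reference level.
#' @return Barrier height, kJ/mol.
#' @export
barrier_height <- function(profile, region, ref = c("global-min", "left-min")) {
  ref <- match.arg(ref)
  inreg <- profile$z >= region[1] & profile$z <= region[2] & is.finite(profile$G)
  if (!any(inreg)) stop("no profile bins in region [",
                        region[1], ", ", region[2], "]")
  peak <- max(profile$G[inreg])
  base <- if (ref == "global-min") min(profile$G[is.finite(profile$G)])
          else {
            left <- profile$z < region[1] & is.finite(profile$G)
            if (!any(left)) stop("no bins left of region for 'left-min' reference")
            min(profile$G[left])
          }
  peak - base
}

#' Read umbrella windows from per-window files
#'
#' Each window file holds a metadata line `# center k_force temperature`
#' followed by one sample per line; the manifest lists one file path per
#' line (relative paths resolved against the manifest's directory).
#'
#' @param manifest Path to the manifest file.
#' @return List of `umbrella_window` objects.
#' @export
read_umbrella_windows <- function(manifest) {
  paths <- readLines(manifest, warn = FALSE)
  paths <- paths[nzchar(trimws(paths))]
  base <- dirname(manifest)
  lapply(paths, function(p) {
    fp <- if (file.exists(p)) p else file.path(base, p)
    lines <- readLines(fp, warn = FALSE)
    meta <- as.numeric(strsplit(trimws(sub("^#", "", lines[1])), "\\s+")[[1]])
    if (length(meta) < 3 || any(is.na(meta)))
      stop("bad metadata line in window file ", fp)
    umbrella_window(center = meta[1], k_force = meta[2],
                    samples = as.numeric(lines[-1]), temperature = meta[3])
  })
}

#' Write umbrella windows and a manifest
#'
#' @param windows List of `umbrella_window` objects.
#' @param dir Output directory (created if needed).
#' @return Path to the manifest, invisibly.
#' @export
write_umbrella_windows <- function(windows, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(length(windows))
  for (i in seq_along(windows)) {
    w <- windows[[i]]
    files[i] <- sprintf("window_%03d.dat", i)
    writeLines(c(sprintf("# %.6g %.6g %.6g", w$center, w$k_force, w$temperature),
                 format(w$samples, digits = 10)),
               file.path(dir, files[i]))
  }
  manifest <- file.path(dir, "manifest.txt")
  writeLines(files, manifest)
  invisible(manifest)
}
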