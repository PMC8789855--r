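#' Normalize a flux-assay fluorescence curve to the percent scale
#'
#' Affine rescaling sending the fluorescence at protonophore addition
#' (t = 0, maximal fluorescence) to 100% and the post-valinomycin plateau
#' (all liposomes equilibrated) to 0%. The plateau is the mean of the final
#' 5 minutes of the record; a slope test (|slope| < 0.5 %/min over that
#' stretch) flags records where the plateau was not reached. The map is
#' invariant to gain/offset changes of the raw signal and idempotent.
#'
#' @param curve A `flux_curve`.
#' @param plateau_window Length of the terminal plateau stretch, min.
#' @param slope_limit Plateau attainment threshold, %/min.
#' @return A normalized `flux_curve` (percent scale) with attributes
#'   `anchors` (raw F0 and plateau values) and `plateau_reached`.
#' @export
normalize_flux <- function(curve, plateau_window = 5, slope_limit = 0.5) {
  stopifnot(inherits(curve, "flux_curve"))
  t <- curve$t; Fv <- curve$F
  t_val <- attr(curve, "t_val")
  # maximal-fluorescence anchor: the last half minute of baseline up to and
  # including t = 0 (the decay has not started yet)
  near0 <- which(t >= -0.5 & t <= 0)
  if (!length(near0)) near0 <- which.min(abs(t))
  F0 <- mean(Fv[near0])
  tail_idx <- which(t >= max(t) - plateau_window & t > t_val)
  if (length(tail_idx) < 3) stop("no post-valinomycin plateau samples")
  plateau <- mean(Fv[tail_idx])
  if (abs(F0 - plateau) < 1e-12) stop("degenerate curve: F0 equals plateau")
  Fn <- 100 * (Fv - plateau) / (F0 - plateau)
  slope <- coef(lm(Fn[tail_idx] ~ t[tail_idx]))[[2]]
  plateau_reached <- abs(slope) < slope_limit
  if (!plateau_reached)
    warning("post-valinomycin plateau not reached (|slope| = ",
            signif(abs(slope), 3), " %/min)")
  out <- flux_curve(t, Fn, t_val = t_val,
                    baseline_window = attr(curve, "baseline_window"))
  attr(out, "anchors") <- c(F0 = F0, plateau = plateau)
  attr(out, "plateau_reached") <- plateau_reached
  attr(out, "normalized") <- TRUE
  out
}

#' Fit a first-order exponential decay to a normalized flux curve
#'
#' Nonlinear least squares of \eqn{F(t) = F_\infty + (F_0 - F_\infty)
#' e^{-kt}} over the fitting window. Two fluorescence-change summaries are
#' reported: `dF_window`, the fitted decrease over the window (fitted F at
#' window start minus fitted F at window end), and `dF_amplitude`, the
#' fitted total amplitude \eqn{F_0 - F_\infty}.
#'
#' @param curve A normalized `flux_curve` (percent scale).
#' @param window Fitting window, min (default 0 to 35, protonophore to
#'   valinomycin).
#' @return A `decay_fit` list: `F0`, `F_inf`, `k_decay` (min^-1),
#'   `dF_window`, `dF_amplitude`, `rss`, `se_k`, `converged`.
#' @export
fit_decay <- function(curve, window = NULL) {
  stopifnot(inherits(curve, "flux_curve"))
  if (is.null(window)) window <- c(0, attr(curve, "t_val"))
  keep <- curve$t >= window[1] & curve$t <= window[2]
  if (sum(keep) < 5) stop("need at least 5 points in the fitting window")
  t <- curve$t[keep]; Fv <- curve$F[keep]
  f0 <- Fv[which.min(t)]
  finf0 <- min(Fv)
  span <- f0 - finf0
  k0 <- if (span > 1e-9) {
    # log-linear starting value from the early decay
    half_idx <- which(Fv - finf0 <= span / 2)
    if (length(half_idx)) log(2) / max(t[half_idx[1]], diff(range(t)) / 20)
    else 1 / diff(range(t))
  } else 1e-3
  dat <- data.frame(t = t, Fv = Fv)
  fit <- tryCatch(
    nls(Fv ~ Finf + (F0 - Finf) * exp(-k * t), data = dat,
        start = list(F0 = f0, Finf = finf0, k = k0),
        control = list(maxiter = 200, warnOnly = FALSE)),
    error = function(e) NULL)
  if (is.null(fit))
    fit <- tryCatch(
      minpack.lm::nlsLM(Fv ~ Finf + (F0 - Finf) * exp(-k * t), data = dat,
                        start = list(F0 = f0, Finf = finf0, k = abs(k0)),
                        lower = c(-Inf, -Inf, 0),
                        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
  if (is.null(fit)) {
    # grid-refined restart over k
    ks <- 10^seq(-4, 1, length.out = 60)
    rss <- vapply(ks, function(k) {
      ek <- exp(-k * t)
      co <- tryCatch(coef(lm(Fv ~ ek)), error = function(e) c(NA, NA))
      sum((Fv - co[1] - co[2] * ek)^2)
    }, 0)
    kbest <- ks[which.min(rss)]
    ek <- exp(-kbest * t)
    co <- coef(lm(Fv ~ ek))
    pars <- c(F0 = co[[1]] + co[[2]], Finf = co[[1]], k = kbest)
    fitted_fun <- function(tt) pars[["Finf"]] +
      (pars[["F0"]] - pars[["Finf"]]) * exp(-pars[["k"]] * tt)
    return(structure(list(F0 = pars[["F0"]], F_inf = pars[["Finf"]],
                          k_decay = pars[["k"]],
                          dF_window = fitted_fun(window[1]) - fitted_fun(window[2]),
                          dF_amplitude = pars[["F0"]] - pars[["Finf"]],
                          rss = min(rss), se_k = NA_real_, converged = FALSE),
                     class = "decay_fit"))
  }
  co <- coef(fit)
  k <- max(co[["k"]], 0)
  fitted_fun <- function(tt) co[["Finf"]] + (co[["F0"]] - co[["Finf"]]) * exp(-k * tt)
  se_k <- tryCatch(summary(fit)$coefficients["k", "Std. Error"],
                   error = function(e) NA_real_)
  structure(list(F0 = co[["F0"]], F_inf = co[["Finf"]], k_decay = k,
                 dF_window = fitted_fun(window[1]) - fitted_fun(window[2]),
                 dF_amplitude = co[["F0"]] - co[["Finf"]],
                 rss = sum(resid(fit)^2), se_k = se_k, converged = TRUE),
            class = "decay_fit")
}

#' Dunnett many-to-one comparisons of fluorescence changes
#'
#' Two-sided comparisons of each treatment group mean against a shared
#' control, with family-wise adjustment through the equicorrelated
#' multivariate-t distribution of the comparison statistics, whose quantiles
#' and tail probabilities are estimated by seeded Monte Carlo. With a single
#' treatment group the procedure reduces to the plain two-sided pooled
#' t-test.
#'
#' @param groups Named list of numeric vectors (per-replicate fluorescence
#'   changes, % scale), each of length >= 2.
#' @param control Name of the control group.
#' @param alpha Family-wise error rate for the simultaneous intervals.
#' @param mc_draws Monte Carlo sample size.
#' @param seed RNG seed.
#' @return Data frame with one row per treatment group: `estimate`
#'   (treatment minus control), `t`, `p_unadjusted`, `p_adjusted`, `ci_lo`,
#'   `ci_hi` (simultaneous 100(1-alpha)% interval).
#' @export
compare_to_control <- function(groups, control, alpha = 0.05,
                               mc_draws = 2e5, seed = 1) {
  stopifnot(control %in% names(groups))
  if (any(vapply(groups, length, 0L) < 2))
    stop("every group needs at least 2 replicates")
  trt <- setdiff(names(groups), control)
  if (!length(trt)) stop("no treatment groups to compare")
  y0 <- groups[[control]]
  n0 <- length(y0)
  ns <- vapply(groups[trt], length, 0L)
  N <- n0 + sum(ns)
  k <- length(trt)
  # pooled within-group variance
  ss <- sum((y0 - mean(y0))^2) +
    sum(vapply(groups[trt], function(y) sum((y - mean(y))^2), 0))
  nu <- N - (k + 1)
  s2 <- ss / nu
  est <- vapply(groups[trt], mean, 0) - mean(y0)
  se <- sqrt(s2 * (1 / ns + 1 / n0))
  tstat <- est / se
  p_un <- 2 * pt(-abs(tstat), df = nu)
  # one-factor structure of the Dunnett correlation: rho_ij = b_i b_j
  b <- sqrt(ns / (ns + n0))
  set.seed(seed)
  z0 <- rnorm(mc_draws)
  w <- sqrt(rchisq(mc_draws, nu) / nu)
  Tmax <- rep(0, mc_draws)
  Tabs <- matrix(0, mc_draws, k)
  for (i in seq_len(k)) {
    zi <- b[i] * z0 + sqrt(1 - b[i]^2) * rnorm(mc_draws)
    Tabs[, i] <- abs(zi / w)
  }
  Tmax <- apply(Tabs, 1, max)
  p_adj <- vapply(tstat, function(tt) mean(Tmax >= abs(tt)), 0)
  p_adj <- pmax(p_adj, p_un)   # adjusted p never below unadjusted
  crit <- quantile(Tmax, 1 - alpha, names = FALSE)
  data.frame(group = trt, estimate = est, t = tstat,
             p_unadjusted = p_un, p_adjusted = p_adj,
             ci_lo = est - crit * se, ci_hi = est + crit * se,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Read a flux curve from CSV plus JSON metadata
#'
#' @param path CSV with columns `time_min`, `fluorescence`; metadata JSON
#'   alongside (same basename) must provide `t_val`.
#' @param curve A `flux_curve` (for writing).
#' @return `read_flux_curve` returns a `flux_curve`.
#' @export
read_flux_curve <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- read.csv(path)
  meta_path <- sub("\\.csv$", ".json", path)
  if (!file.exists(meta_path)) stop("metadata file not found: ", meta_path)
  meta <- jsonlite::read_json(meta_path)
  flux_curve(tab$time_min, tab$fluorescence, t_val = meta$t_val)
}

#' @rdname read_flux_curve
#' @export
write_flux_curve <- function(curve, path) {
  write.csv(data.frame(time_min = curve$t, fluorescence = curve$F),
            path, row.names = FALSE)
  jsonlite::write_json(list(t_val = attr(curve, "t_val")),
                       sub("\\.csv$", ".json", path), auto_unbox = TRUE)
  invisible(path)
}
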