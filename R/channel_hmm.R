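#' Pre-process a single-channel current trace
#'
#' Zero-phase low-pass filtering (4th-order Butterworth, forward-backward)
#' followed by decimation to the analysis rate, mirroring the conventional
#' re-digitization of patch-clamp records before idealization. The filter
#' step is skipped when the cutoff is at or above the Nyquist frequency of
#' the input.
#'
#' @param trace A `channel_trace`.
#' @param target_fs Analysis sampling rate, Hz (default 1000).
#' @param lp_cutoff Low-pass cutoff, Hz (default 1000).
#' @return A `channel_trace` at `target_fs` with `filter_history` appended;
#'   output length is `ceiling(n * target_fs / fs)`.
#' @export
preprocess <- function(trace, target_fs = 1000, lp_cutoff = 1000) {
  stopifnot(inherits(trace, "channel_trace"))
  if (target_fs > trace$fs)
    stop("target_fs exceeds the trace sampling rate")
  x <- trace$samples
  hist <- trace$filter_history
  if (lp_cutoff < trace$fs / 2) {
    bf <- signal::butter(4, lp_cutoff / (trace$fs / 2), type = "low")
    m <- mean(x)   # demean so edge transients vanish for near-DC signals
    x <- signal::filtfilt(bf, x - m) + m
    hist <- c(hist, sprintf("butterworth4 zero-phase lp %g Hz", lp_cutoff))
  }
  if (target_fs < trace$fs) {
    n_out <- ceiling(length(x) * target_fs / trace$fs)
    ratio <- trace$fs / target_fs
    idx <- 1 + (seq_len(n_out) - 1) * ratio
    x <- if (all(abs(idx - round(idx)) < 1e-9)) x[round(idx)]
         else approx(seq_along(x), x, xout = idx, rule = 2)$y
    hist <- c(hist, sprintf("decimated %g -> %g Hz", trace$fs, target_fs))
  }
  channel_trace(x, fs = target_fs, voltage = trace$voltage,
                hidden = NULL, filter_history = hist)
}

.gauss_B <- function(x, mu, sigma, floor = 1e-300) {
  B <- vapply(seq_along(mu), function(k) dnorm(x, mu[k], sigma[k]),
              numeric(length(x)))
  B[B < floor] <- floor
  B
}

.em_once <- function(x, mu, sigma, P, pi0, tol, max_iter, var_floor) {
  K <- length(mu)
  ll_trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  floored <- FALSE
  for (it in seq_len(max_iter)) {
    B <- .gauss_B(x, mu, sigma)
    fb <- .hmm_fwdbwd(B, pi0, P)
    ll <- fb$loglik
    ll_trace <- c(ll_trace, ll)
    gamma <- fb$gamma
    xi <- fb$xi
    pi0 <- gamma[1, ] / sum(gamma[1, ])
    P <- xi / pmax(rowSums(xi), 1e-300)
    P <- P / rowSums(P)
    gs <- colSums(gamma)
    mu <- as.numeric(t(gamma) %*% x) / gs
    sigma <- sqrt(vapply(seq_len(K), function(k)
      sum(gamma[, k] * (x - mu[k])^2), 0) / gs)
    if (any(sigma < var_floor)) {
      sigma <- pmax(sigma, var_floor)
      floored <- TRUE
    }
    if (is.finite(ll_old) &&
        abs(ll - ll_old) <= tol * abs(ll_old)) { converged <- TRUE; break }
    ll_old <- ll
  }
  list(mu = mu, sigma = sigma, P = P, pi0 = pi0, loglik = ll,
       loglik_trace = ll_trace, n_iterations = length(ll_trace),
       converged = converged, variance_floored = floored)
}

#' Fit a Gaussian-emission hidden Markov model to a current trace
#'
#' Baum-Welch expectation-maximization with Gaussian emissions; the best of
#' `restarts` seeded initializations is kept and the states are relabelled by
#' sorted level magnitude so class 1/2/3 always means closed/substate/open
#' regardless of initialization.
#'
#' @param trace A `channel_trace` (>= 1000 samples).
#' @param n_classes Number of conductance classes (default 3: C, S, O).
#' @param init `"quantile"` (spread means over trace quantiles) or
#'   `"manual"` (supply `mu0`).
#' @param mu0 Initial means when `init = "manual"`.
#' @param tol Relative log-likelihood convergence tolerance.
#' @param max_iter EM iteration cap per restart.
#' @param restarts Number of jittered initializations.
#' @param seed RNG seed for the restarts.
#' @param var_floor Lower bound on emission SDs, pA; collapse onto single
#'   samples is prevented by flooring with a warning.
#' @return An `hmm_fit`: `scheme` (list with `P`, `level_mean`, `level_sd`,
#'   `classes`), `pi0`, `log_likelihood`, `loglik_trace` (non-decreasing),
#'   `n_iterations`, `converged`.
#' @export
fit_hmm <- function(trace, n_classes = 3, init = c("quantile", "manual"),
                    mu0 = NULL, tol = 1e-6, max_iter = 200, restarts = 8,
                    seed = 1, var_floor = 1e-3) {
  stopifnot(inherits(trace, "channel_trace"))
  init <- match.arg(init)
  x <- trace$samples
  if (length(x) < 1000) stop("need at least 1000 samples to fit")
  K <- n_classes
  set.seed(seed)
  base_mu <- if (init == "manual") {
    if (length(mu0) != K) stop("mu0 must have one value per class")
    mu0
  } else {
    # k-means centres seeded from range-spread quantiles; plain occupancy
    # quantiles start two components on top of the dominant level when the
    # class occupancies are skewed
    starts <- quantile(x, probs = seq(0.01, 0.99, length.out = K),
                       names = FALSE)
    starts <- starts + seq_len(K) * 1e-6 * max(diff(range(x)), 1)
    km <- suppressWarnings(
      tryCatch(stats::kmeans(x, centers = starts, iter.max = 100,
                             algorithm = "Lloyd"),
               error = function(e) NULL))
    if (is.null(km)) starts else sort(as.numeric(km$centers))
  }
  spread <- max(sd(x) / K, 10 * var_floor)
  best <- NULL
  for (r in seq_len(restarts)) {
    mu <- if (r == 1) base_mu else sort(base_mu + rnorm(K, sd = spread / 2))
    sigma <- rep(spread, K)
    P <- matrix(0.02 / (K - 1), K, K); diag(P) <- 0.98
    pi0 <- rep(1 / K, K)
    fit <- .em_once(x, mu, sigma, P, pi0, tol, max_iter, var_floor)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  if (best$variance_floored)
    warning("emission variance collapsed and was floored at ", var_floor, " pA")
  ord <- order(abs(best$mu))
  classes <- if (K == 3) c("C", "S", "O") else paste0("L", seq_len(K))
  structure(list(
    scheme = list(P = best$P[ord, ord, drop = FALSE],
                  level_mean = best$mu[ord],
                  level_sd = best$sigma[ord],
                  classes = classes),
    pi0 = best$pi0[ord],
    log_likelihood = best$loglik,
    loglik_trace = best$loglik_trace,
    n_iterations = best$n_iterations,
    converged = best$converged,
    fs = trace$fs, voltage = trace$voltage), class = "hmm_fit")
}

#' Idealize a trace with the Viterbi path
#'
#' Maximum-likelihood class path under a fitted model, plus the dwell table
#' obtained by run-length encoding of that path.
#'
#' @param trace A `channel_trace`.
#' @param fit An `hmm_fit` (converged, or knowingly accepted while flagged).
#' @return An `idealized_path`: `states` (integer per sample), `classes`
#'   (labels), `dwells` (data frame: class, start sample (0-based), duration
#'   in samples and seconds), `fs`, `log_path_likelihood`.
#' @export
idealize <- function(trace, fit) {
  stopifnot(inherits(trace, "channel_trace"), inherits(fit, "hmm_fit"))
  sc <- fit$scheme
  x <- trace$samples
  logB <- log(.gauss_B(x, sc$level_mean, sc$level_sd))
  logP <- log(pmax(sc$P, 1e-300))
  logpi <- log(pmax(fit$pi0, 1e-300))
  states <- .hmm_viterbi(logB, logpi, logP)
  ll_path <- .hmm_path_loglik(states, logB, logpi, logP)
  r <- rle(states)
  start <- cumsum(c(0L, head(r$lengths, -1)))
  dwells <- data.frame(class = sc$classes[r$values],
                       state = r$values,
                       start = start,
                       duration = r$lengths,
                       duration_s = r$lengths / trace$fs,
                       stringsAsFactors = FALSE)
  structure(list(states = states, classes = sc$classes, dwells = dwells,
                 fs = trace$fs, log_path_likelihood = ll_path),
            class = "idealized_path")
}

#' Observed amplitude histogram with the fitted mixture overlay
#'
#' @param trace A `channel_trace`.
#' @param fit An `hmm_fit`.
#' @param bin Histogram bin width, pA.
#' @param path Optional `idealized_path`; computed when absent. Mixture
#'   weights are the idealized class occupancies.
#' @return List with `mid`, `counts`, and `mixture` (expected counts per bin
#'   from the weighted Gaussian mixture; integrates to the sample count).
#' @export
amplitude_histogram <- function(trace, fit, bin = 0.1, path = NULL) {
  x <- trace$samples
  if (is.null(path)) path <- idealize(trace, fit)
  K <- length(fit$scheme$level_mean)
  pi_c <- vapply(seq_len(K), function(k) mean(path$states == k), 0)
  edges <- seq(floor(min(x) / bin) * bin, max(x) + bin, by = bin)
  counts <- tabulate(findInterval(x, edges, rightmost.closed = TRUE),
                     nbins = length(edges) - 1)
  mid <- (edges[-1] + edges[-length(edges)]) / 2
  dens <- rowSums(vapply(seq_len(K), function(k)
    pi_c[k] * dnorm(mid, fit$scheme$level_mean[k], fit$scheme$level_sd[k]),
    numeric(length(mid))))
  list(mid = mid, counts = counts, mixture = dens * length(x) * bin,
       weights = pi_c)
}

#' Burst-wise open and substate probabilities
#'
#' Bursts are separated by closed-class dwells longer than `t_crit`;
#' leading/trailing closed samples are trimmed from each burst. Po is the
#' open-class fraction of total burst time and Ps the substate fraction.
#'
#' @param path An `idealized_path` (3-class labelling C/S/O).
#' @param t_crit Critical closed gap separating bursts, seconds (default
#'   0.1 s = 100 ms).
#' @return List with `Po`, `Ps`, `bursts` (data frame: start, end sample,
#'   duration_s), and `n_bursts`. With no open or substate samples at all the
#'   result is returned empty and flagged (`no_bursts = TRUE`).
#' @export
burst_metrics <- function(path, t_crit = 0.1) {
  stopifnot(inherits(path, "idealized_path"))
  st <- path$states
  closed <- st == 1L
  if (all(closed)) {
    return(list(Po = NA_real_, Ps = NA_real_,
                bursts = data.frame(start = integer(0), end = integer(0),
                                    duration_s = numeric(0)),
                n_bursts = 0L, no_bursts = TRUE))
  }
  gap <- round(t_crit * path$fs)
  r <- rle(closed)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  # separators: closed runs longer than the critical gap (and the record edges)
  sep <- which(r$values & r$lengths > gap)
  cutpoints <- c(0L, ends[sep], length(st))
  bursts <- list()
  for (i in seq_len(length(cutpoints) - 1)) {
    lo <- cutpoints[i] + 1L
    hi <- if (i < length(cutpoints) - 1) starts[sep[i]] - 1L else cutpoints[i + 1]
    if (hi < lo) next
    seg <- lo:hi
    open_in <- seg[!closed[seg]]
    if (!length(open_in)) next
    bursts[[length(bursts) + 1L]] <- c(min(open_in), max(open_in))
  }
  if (!length(bursts)) {
    return(list(Po = NA_real_, Ps = NA_real_,
                bursts = data.frame(start = integer(0), end = integer(0),
                                    duration_s = numeric(0)),
                n_bursts = 0L, no_bursts = TRUE))
  }
  bm <- do.call(rbind, bursts)
  tot <- 0L; t_open <- 0L; t_sub <- 0L
  for (i in seq_len(nrow(bm))) {
    seg <- bm[i, 1]:bm[i, 2]
    tot <- tot + length(seg)
    t_open <- t_open + sum(st[seg] == 3L)
    t_sub <- t_sub + sum(st[seg] == 2L)
  }
  list(Po = t_open / tot, Ps = t_sub / tot,
       bursts = data.frame(start = bm[, 1] - 1L, end = bm[, 2] - 1L,
                           duration_s = (bm[, 2] - bm[, 1] + 1) / path$fs),
       n_bursts = nrow(bm), no_bursts = FALSE)
}

#' Current-voltage summary across recordings
#'
#' @param records List of lists with elements `voltage` (mV) and `fit`
#'   (`hmm_fit`); at least two distinct voltages.
#' @return List with `table` (voltage, open-level mean pA), `conductance_pS`
#'   (slope of the least-squares line), `reversal_mV` (x-intercept).
#' @export
iv_summary <- function(records) {
  v <- vapply(records, function(r) r$voltage, 0)
  if (length(unique(v)) < 2) stop("need recordings at two or more voltages")
  mu_open <- vapply(records, function(r) {
    lm_ <- r$fit$scheme$level_mean
    lm_[length(lm_)]
  }, 0)
  fit <- lm(mu_open ~ v)
  slope <- coef(fit)[["v"]]        # pA/mV = nS
  list(table = data.frame(voltage = v, open_level_pA = mu_open),
       conductance_pS = slope * 1000,
       reversal_mV = -coef(fit)[["(Intercept)"]] / slope)
}

#' Read/write channel traces as two-column CSV with JSON metadata
#'
#' @param path CSV path (`time_s`, `current_pA`); metadata JSON (fs,
#'   voltage) stored alongside with extension `.json`.
#' @param trace A `channel_trace` (for writing).
#' @return `read_channel_trace` returns a `channel_trace`.
#' @export
read_channel_trace <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- read.csv(path)
  meta_path <- sub("\\.csv$", ".json", path)
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path)
          else list(fs = 1 / median(diff(tab$time_s)), voltage = NA)
  channel_trace(tab$current_pA, fs = meta$fs, voltage = meta$voltage)
}

#' @rdname read_channel_trace
#' @export
write_channel_trace <- function(trace, path) {
  tab <- data.frame(time_s = (seq_along(trace$samples) - 1) / trace$fs,
                    current_pA = trace$samples)
  write.csv(tab, path, row.names = FALSE)
  jsonlite::write_json(list(fs = trace$fs, voltage = trace$voltage),
                       sub("\\.csv$", ".json", path), auto_unbox = TRUE)
  invisible(path)
}
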