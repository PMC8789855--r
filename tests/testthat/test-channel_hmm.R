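two_level_trace <- function(n = 4000, period = 200, levels = c(0, 3.5),
                            noise = 0, fs = 1000, seed = 1) {
  set.seed(seed)
  hidden <- rep(rep(1:2, each = period), length.out = n)
  channel_trace(levels[hidden] + rnorm(n, sd = noise), fs = fs,
                hidden = hidden)
}

test_that("preprocessing preserves DC, attenuates tones, sets the length", {
  dc <- channel_trace(rep(2.5, 5000), fs = 50000)
  out <- preprocess(dc, target_fs = 1000, lp_cutoff = 1000)
  expect_equal(out$fs, 1000)
  expect_equal(length(out$samples), ceiling(5000 * 1000 / 50000))
  expect_equal(unique(round(out$samples, 6)), 2.5)
  # a 10 kHz tone sampled at 50 kHz must lose >20 dB through the 1 kHz filter
  t <- seq(0, 0.5, by = 1 / 50000)
  tone <- channel_trace(sin(2 * pi * 10000 * t), fs = 50000)
  filt <- preprocess(tone, target_fs = 50000, lp_cutoff = 1000)
  core <- seq(1000, length(filt$samples) - 1000)  # ignore filter edges
  atten <- 20 * log10(sd(filt$samples[core]) / sd(tone$samples[core]))
  expect_lt(atten, -20)
  expect_error(preprocess(dc, target_fs = 100000), "exceeds")
  expect_match(out$filter_history[2], "decimated")
})

test_that("noiseless two-level traces are recovered exactly", {
  tr <- two_level_trace(noise = 0)
  # the zero-noise limit collapses the emission variance, which is floored
  # with a warning by design
  expect_warning(
    fit <- fit_hmm(tr, n_classes = 2, restarts = 2, seed = 1,
                   var_floor = 1e-4),
    "floored")
  expect_equal(sort(fit$scheme$level_mean), c(0, 3.5), tolerance = 1e-6)
  path <- idealize(tr, fit)
  expect_identical(path$states, tr$hidden)
  # dwell boundaries: all runs have the construction period
  expect_true(all(path$dwells$duration == 200))
})

test_that("EM log-likelihood is non-decreasing at every iteration", {
  tr <- two_level_trace(noise = 0.6, seed = 5)
  fit <- fit_hmm(tr, n_classes = 2, restarts = 3, seed = 2)
  expect_true(all(diff(fit$loglik_trace) >= -1e-6 * abs(fit$loglik_trace[-1])))
  sc3 <- channel_preset("decyl")
  tr3 <- generate_channel_trace(sc3, 5, 1000, seed = 4)
  fit3 <- fit_hmm(tr3, n_classes = 3, restarts = 2, seed = 2)
  expect_true(all(diff(fit3$loglik_trace) >= -1e-6 * abs(fit3$loglik_trace[-1])))
  expect_equal(rowSums(fit3$scheme$P), rep(1, 3), tolerance = 1e-9)
})

test_that("class labels always come out sorted by level magnitude", {
  sc <- channel_preset("octyl")
  tr <- generate_channel_trace(sc, 10, 1000, seed = 6)
  for (s in c(1, 99)) {
    fit <- fit_hmm(tr, n_classes = 3, restarts = 3, seed = s)
    expect_true(all(diff(abs(fit$scheme$level_mean)) > 0))
    expect_equal(fit$scheme$classes, c("C", "S", "O"))
  }
})

test_that("Viterbi path likelihood never exceeds the total likelihood", {
  sc <- channel_preset("decyl")
  tr <- generate_channel_trace(sc, 5, 1000, seed = 7)
  fit <- fit_hmm(tr, n_classes = 3, restarts = 2, seed = 3)
  path <- idealize(tr, fit)
  expect_lte(path$log_path_likelihood, fit$log_likelihood + 1e-6)
  # dwell table partitions the record (run-length-encoding oracle)
  expect_equal(sum(path$dwells$duration), length(tr$samples))
  expect_identical(path$states, rep(path$dwells$state, path$dwells$duration))
})

test_that("amplitude histograms carry three modes and integrate to n", {
  sc <- channel_preset("decyl")
  tr <- generate_channel_trace(sc, 30, 1000, seed = 8)
  fit <- fit_hmm(tr, n_classes = 3, restarts = 2, seed = 3)
  ah <- amplitude_histogram(tr, fit, bin = 0.1)
  expect_equal(sum(ah$counts), length(tr$samples))
  expect_equal(sum(ah$mixture) , length(tr$samples), tolerance = 0.01)
  # the three fitted component means recover the generator levels
  expect_equal(fit$scheme$level_mean, c(0, 1.4, 3.5), tolerance = 0.05)
  # the mixture curve tracks the observed histogram
  expect_gt(cor(ah$counts, ah$mixture), 0.98)
})

test_that("burst metrics follow their defining limits", {
  all_open <- structure(list(states = rep(3L, 2000),
                             classes = c("C", "S", "O"),
                             dwells = NULL, fs = 1000),
                        class = "idealized_path")
  bm <- burst_metrics(all_open)
  expect_equal(bm$Po, 1)
  expect_equal(bm$n_bursts, 1L)
  # t_crit -> infinity: a single burst spanning the active record
  mixed <- structure(list(states = rep(c(3L, 1L, 2L, 1L), c(300, 400, 300, 200)),
                          classes = c("C", "S", "O"), dwells = NULL, fs = 1000),
                     class = "idealized_path")
  bm2 <- burst_metrics(mixed, t_crit = 1e6)
  expect_equal(bm2$n_bursts, 1L)
  # trimmed to the last non-closed sample: trailing closure excluded
  expect_equal(bm2$Po, 300 / 1000)
  expect_equal(bm2$Ps, 300 / 1000)
  # all-closed record: flagged empty result
  closed <- structure(list(states = rep(1L, 1500), classes = c("C", "S", "O"),
                           dwells = NULL, fs = 1000),
                      class = "idealized_path")
  expect_true(burst_metrics(closed)$no_bursts)
})

test_that("burst separation excludes long closures from burst time", {
  # two bursts split by a 300 ms closure at 1 kHz with t_crit = 100 ms
  states <- c(rep(3L, 500), rep(1L, 300), rep(3L, 200))
  path <- structure(list(states = states, classes = c("C", "S", "O"),
                         dwells = NULL, fs = 1000),
                    class = "idealized_path")
  bm <- burst_metrics(path, t_crit = 0.1)
  expect_equal(bm$n_bursts, 2L)
  expect_equal(bm$Po, 1)
  # with a short 50 ms closure the record is one burst including the gap
  states2 <- c(rep(3L, 500), rep(1L, 50), rep(3L, 200))
  path2 <- structure(list(states = states2, classes = c("C", "S", "O"),
                          dwells = NULL, fs = 1000),
                     class = "idealized_path")
  bm2 <- burst_metrics(path2, t_crit = 0.1)
  expect_equal(bm2$n_bursts, 1L)
  expect_equal(bm2$Po, 700 / 750)
})

test_that("ohmic synthetic records give back their conductance", {
  gamma_pS <- 20
  voltages <- c(-80, -40, 40, 80)
  records <- lapply(voltages, function(v) {
    mu_open <- gamma_pS * v / 1000   # pA
    fit <- structure(list(scheme = list(level_mean = c(0, mu_open / 2, mu_open),
                                        level_sd = rep(0.2, 3),
                                        classes = c("C", "S", "O"))),
                     class = "hmm_fit")
    list(voltage = v, fit = fit)
  })
  iv <- iv_summary(records)
  expect_equal(iv$conductance_pS, gamma_pS, tolerance = 1e-9)
  expect_equal(iv$reversal_mV, 0, tolerance = 1e-6)
  expect_error(iv_summary(records[1]), "two or more")
  # least-squares oracle
  mu <- vapply(records, function(r) r$fit$scheme$level_mean[3], 0)
  slope <- cov(mu, voltages) / var(voltages)
  expect_equal(iv$conductance_pS, slope * 1000)
})

test_that("trace CSV round trip preserves samples and metadata", {
  tr <- generate_channel_trace(channel_preset("hexyl"), 2, 1000, seed = 9)
  path <- file.path(withr::local_tempdir(), "trace.csv")
  write_channel_trace(tr, path)
  back <- read_channel_trace(path)
  expect_equal(back$samples, tr$samples, tolerance = 1e-9)
  expect_equal(back$fs, 1000)
  expect_equal(back$voltage, -80)
})
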