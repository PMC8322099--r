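test_that("PSTHs conserve counts and use half-open bins", {
  empty <- compute_psth(list(numeric(0), numeric(0)), 10, c(0, 100))
  expect_true(all(empty$rate == 0))

  # a spike exactly on a bin edge lands in the right bin
  one <- compute_psth(list(10), 10, c(0, 30))
  expect_equal(one$counts, c(0L, 1L, 0L))

  # total count conservation before subtraction
  set.seed(41)
  spikes <- lapply(1:20, function(i) runif(30, -200, 400))
  ps <- compute_psth(spikes, 10, c(-200, 400))
  expect_equal(sum(ps$counts), sum(vapply(spikes, function(s) {
    sum(s >= -200 & s < 400)
  }, numeric(1))))

  # homogeneous Poisson 20 Hz: per-bin rates within 3 SE
  sp <- generate_ephys_session(baseline_rate_hz = 20, duration_ms = 1000,
                               pre_ms = 0, n_trials = 200, seed = 42)
  ph <- compute_psth(sp, 10, c(0, 1000))
  se <- sqrt(20 / (200 * 0.01))
  expect_true(all(abs(ph$rate - 20) < 3.5 * se))
  expect_equal(mean(ph$rate), 20, tolerance = 0.05 * 20)

  # baseline subtraction and display smoothing
  pb <- compute_psth(sp, 10, c(0, 1000), baseline_ms = c(0, 200),
                     smooth_bins = 3)
  expect_equal(mean(pb$rate[pb$mid < 200]), 0, tolerance = 1e-9)
  expect_length(pb$smoothed, length(pb$rate))
})

test_that("evoked responses sum the positive-going PSTH", {
  ps <- structure(list(mid = seq(5, 295, by = 10),
                       rate = rep(-1, 30), bin_ms = 10), class = "psth")
  expect_equal(evoked_response(ps, c(0, 150)), 0)

  ps$rate <- c(5, rep(0, 29))
  expect_equal(evoked_response(ps, c(0, 150)), 5)
  expect_equal(evoked_response(ps, c(0, 150), normalize_to = 10), 0.5)
  expect_true(is.na(evoked_response(ps, c(0, 150), normalize_to = 0)))

  set.seed(43)
  ps$rate <- rnorm(30)
  win <- ps$mid >= 0 & ps$mid < 150
  expect_equal(evoked_response(ps, c(0, 150)),
               sum(ps$rate[win][ps$rate[win] > 0]), tolerance = 1e-12)
})

test_that("suppression kinetics fit the single-exponential model", {
  t_ms <- seq(0.25, 100, by = 0.5)
  # noiseless synthetic exponential: exact recovery
  truth <- ifelse(t_ms < 5, 1, 0.05 + 0.95 * exp(-(t_ms - 5) / 20))
  fit <- suppression_kinetics(t_ms, truth)
  expect_true(fit$ok)
  expect_equal(fit$latency_ms, 5, tolerance = 0.5)
  expect_equal(fit$tau_ms, 20, tolerance = 0.1)
  expect_equal(fit$floor, 0.05, tolerance = 0.01)

  # flat PSTH: failure sentinel
  flat <- suppression_kinetics(t_ms, rep(1, length(t_ms)))
  expect_false(flat$ok)
  expect_true(is.na(flat$tau_ms))

  # Poisson-sampled recovery within 25% at 500 trials
  sp <- generate_ephys_session(baseline_rate_hz = 50, duration_ms = 100,
                               pre_ms = 10, n_trials = 500,
                               suppression = list(latency = 5, tau = 20,
                                                  floor = 0.05),
                               seed = 44)
  ps <- compute_psth(sp, 0.5, c(-10, 100))
  norm <- ps$rate / mean(ps$rate[ps$mid < 0])
  pfit <- suppression_kinetics(ps$mid, norm)
  expect_true(pfit$ok)
  expect_lt(abs(pfit$tau_ms - 20) / 20, 0.25)
  expect_lt(abs(pfit$latency_ms - 5), 5)
})

test_that("suppression-fit error shrinks with trial count", {
  rmse_at <- function(n_trials, seed) {
    sp <- generate_ephys_session(baseline_rate_hz = 50, duration_ms = 100,
                                 pre_ms = 10, n_trials = n_trials,
                                 suppression = list(latency = 5, tau = 20,
                                                    floor = 0.05),
                                 seed = seed)
    ps <- compute_psth(sp, 0.5, c(-10, 100))
    fit <- suppression_kinetics(ps$mid, ps$rate / mean(ps$rate[ps$mid < 0]))
    fit$rmse
  }
  lo <- vapply(1:8, function(s) rmse_at(150, s), numeric(1))
  hi <- vapply(1:8, function(s) rmse_at(600, 100 + s), numeric(1))
  expect_lt(median(hi), median(lo))
})

test_that("d-prime follows the Gaussian quantile arithmetic", {
  expect_equal(dprime(0.7, 0.7), 0)
  expect_equal(dprime(0.99, 0.01, clip = 0.005),
               qnorm(0.99) - qnorm(0.01), tolerance = 1e-12)
  expect_equal(dprime(0.99, 0.01, clip = 0.005), 4.652696, tolerance = 1e-6)
  expect_equal(dprime(0.2, 0.8), -dprime(0.8, 0.2))

  hits <- seq(0.05, 0.95, by = 0.05)
  d <- dprime(hits, 0.2)
  expect_true(all(diff(d) > 0))
  # clipping keeps extreme rates finite
  expect_true(is.finite(dprime(1, 0, clip = 0.01)))
})

test_that("psychometric fits recover planted parameters and trim sessions", {
  # single-session smoke check; the calibrated 90%-of-seeds claim lives in
  # the acceptance suite
  b <- generate_behavior_session(midpoint_ms = 20, slope = 4, n_trials = 250,
                                 led_fraction = 0, seed = 45)
  fit <- fit_psychometric(b)
  expect_true(fit$control$ok)
  expect_lt(abs(fit$control$half_max_delta_ms - 20) / 20, 0.3)

  # step-function behavior: half-max at the step within grid resolution
  bs <- generate_behavior_session(midpoint_ms = 20, slope = 1e6,
                                  n_trials = 400, led_fraction = 0, seed = 46)
  sfit <- fit_psychometric(bs, first_n = Inf)
  expect_true(sfit$control$half_max_delta_ms > 15 &&
                sfit$control$half_max_delta_ms < 30)

  # all-lick degenerate session: failure sentinel
  deg <- data.frame(delta_onset_ms = rep(c(0, -15, -30), 20),
                    lick = TRUE, led = FALSE)
  expect_false(fit_psychometric(deg)$control$ok)

  # unmotivated head of the session is dropped before fitting
  good <- generate_behavior_session(midpoint_ms = 20, slope = 4,
                                    n_trials = 200, led_fraction = 0,
                                    seed = 47)
  head_miss <- data.frame(delta_onset_ms = 0, led = FALSE, lick = FALSE,
                          trial = NA)[rep(1, 12), ]
  both <- rbind(head_miss[names(good)], good)
  tfit <- fit_psychometric(both, first_n = Inf)
  expect_lt(abs(tfit$control$half_max_delta_ms - 20) / 20, 0.3)

  # order invariance of the fit itself
  shuf <- good[sample(nrow(good)), ]
  expect_equal(fit_psychometric(shuf, first_n = Inf)$control$midpoint,
               fit_psychometric(good, first_n = Inf)$control$midpoint,
               tolerance = 1e-9)
})

test_that("optogenetic broadening is measured from the two fitted curves", {
  b <- generate_behavior_session(midpoint_ms = 19.4, led_midpoint_ms = 28.2,
                                 slope = 6, n_trials = 2000, seed = 48)
  fit <- fit_psychometric(b, first_n = Inf)
  expect_true(fit$control$ok && fit$led$ok)
  expect_gt(fit$led$half_max_delta_ms, fit$control$half_max_delta_ms)
  planted <- (28.2 - 19.4) / 19.4 * 100
  expect_equal(fit$broadening_pct, planted, tolerance = 0.35 * planted)
})
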