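test_that("neuropil correction subtracts scaled background with brightness gate", {
  sess <- list(f_cell = matrix(100, 2, 50), f_bg = matrix(0, 2, 50))
  out <- neuropil_correct(sess)
  expect_equal(out$f, sess$f_cell)
  expect_true(all(out$included))

  # equal cell and background at r = 0.9: F = 10 and the ROI is excluded
  sess2 <- list(f_cell = matrix(100, 1, 10), f_bg = matrix(100, 1, 10))
  out2 <- neuropil_correct(sess2, r = 0.9)
  expect_equal(out2$f, matrix(10, 1, 10))
  expect_false(out2$included)

  # r = 0 is the identity
  sess3 <- list(f_cell = matrix(runif(30, 90, 110), 3, 10),
                f_bg = matrix(runif(30, 40, 60), 3, 10))
  expect_equal(neuropil_correct(sess3, r = 0)$f, sess3$f_cell)

  expect_error(neuropil_correct(list(f_cell = matrix(0, 2, 5),
                                     f_bg = matrix(0, 2, 6))))
})

test_that("dF/F follows the offset-guarded ratio", {
  expect_equal(compute_dff(rep(80, 10), 80), rep(0, 10))
  expect_equal(compute_dff(150, 80, offset = 20), 0.7)
  # scale invariance at offset 0
  expect_equal(compute_dff(2 * 150, 2 * 80, offset = 0),
               compute_dff(150, 80, offset = 0))
  expect_error(compute_dff(1, -30, offset = 20), "baseline")
})

test_that("response amplitudes match trapezoidal integration", {
  fr <- 30
  al <- make_aligned(list(rep(0, 61)), frame_rate = fr)
  expect_equal(response_amplitude(al)$trial[1], 0)

  # rectangular pulse (0.5 dF/F over 0.6 s under trapezoidal quadrature)
  pulse <- c(rep(0, 5), rep(0.5, 18), rep(0, 38))
  al2 <- make_aligned(list(pulse), frame_rate = fr)
  got <- response_amplitude(al2)$trial[1]
  expect_equal(got, trapz_oracle(pulse[1:31], 1 / fr), tolerance = 1e-12)
  expect_equal(got, 0.3, tolerance = 1e-12)

  set.seed(3)
  y <- rnorm(61)
  al3 <- make_aligned(list(y), frame_rate = fr)
  expect_equal(response_amplitude(al3)$trial[1],
               trapz_oracle(y[1:31], 1 / fr), tolerance = 1e-9)

  # charge mode integrates sign-flipped negative current
  cur <- -pmin(y, 0)
  expect_equal(response_amplitude(al3, mode = "charge")$trial[1],
               trapz_oracle(cur[1:31], 1 / fr), tolerance = 1e-9)

  expect_error(response_amplitude(make_aligned(list(rep(0, 10)),
                                               frame_rate = fr)),
               "window")
})

test_that("significance needs both the per-trial and mean criteria", {
  fr <- 30
  set.seed(41)
  bn <- 0.01
  plateau <- function(h) c(rep(0, 3), rep(h, 20), rep(0, 38))  # 0.66 s at h

  # all-zero trials are not significant
  zero <- make_aligned(replicate(5, rep(0, 61), simplify = FALSE),
                       frame_rate = fr)
  expect_false(test_significance(zero)$significant)

  # suprathreshold 0.66 s plateau in 4/5 trials and the mean
  good <- make_aligned(c(replicate(4, plateau(1), simplify = FALSE),
                         list(rep(0, 61))), frame_rate = fr,
                       base_noise = bn)
  res <- test_significance(good)
  expect_true(res$significant)
  expect_true(res$criterion1 && res$criterion2)

  # mean passes but only 2/5 trials do: criterion 1 fails
  weak <- make_aligned(c(replicate(2, plateau(1), simplify = FALSE),
                         replicate(3, rep(0, 61), simplify = FALSE)),
                       frame_rate = fr, base_noise = bn)
  res2 <- test_significance(weak)
  expect_false(res2$significant)
  expect_false(res2$criterion1)
  expect_true(res2$criterion2)

  # monotone in threshold: raising k never flips non-significant on
  for (k in c(1, 2, 4, 8, 16)) {
    lo <- test_significance(good, threshold_k = k)$significant
    hi <- test_significance(good, threshold_k = k * 2)$significant
    expect_true(lo || !hi)
  }
})

test_that("ROC calibration returns the 90% true-positive threshold", {
  # perfectly separated classes: gap midpoint, TPR 1
  sep <- calibrate_threshold(c(0, 1, 2, 10, 11, 12),
                             c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE))
  expect_equal(sep$threshold, 6)
  expect_equal(sep$tpr, 1)

  # planted Gaussian classes: threshold near mu_pos - 1.2816 sigma
  set.seed(7)
  v <- c(rnorm(4000, 0), rnorm(4000, 3))
  lab <- rep(c(FALSE, TRUE), each = 4000)
  g <- calibrate_threshold(v, lab)
  expect_equal(g$threshold, 3 - qnorm(0.9), tolerance = 0.1)
  expect_gte(g$tpr, 0.9)

  # shuffled labels: threshold near the 10th percentile of "positives"
  set.seed(8)
  vs <- rnorm(2000)
  labs <- sample(c(TRUE, FALSE), 2000, replace = TRUE)
  s <- calibrate_threshold(vs, labs)
  expect_equal(s$threshold, quantile(vs[labs], 0.1, names = FALSE),
               tolerance = 0.05)
  expect_equal(s$fpr, 0.9, tolerance = 0.05)
})

test_that("CI and LI honor boundaries, clipping, and invariances", {
  expect_equal(coincidence_index(0.4, 0.4), 0)
  expect_equal(coincidence_index(0.4, 0), 1)
  expect_equal(coincidence_index(0, 0.4), -1)
  expect_equal(coincidence_index(0.3, -0.1), 1)  # S clipped to 0
  expect_true(is.na(coincidence_index(0, 0)))
  expect_true(is.na(coincidence_index(-0.2, -0.3)))

  expect_equal(linearity_index(0.45, 0.45), 0)
  expect_equal(linearity_index(0, 0.3), -1)
  expect_equal(linearity_index(0.9, sum(c(0.1, 0.2, 0.15))), 1 / 3)
  expect_true(is.na(linearity_index(-0.1, -0.2)))

  set.seed(9)
  for (i in 1:20) {
    a <- runif(2, 0, 2)
    s <- runif(1, 0.1, 10)
    expect_equal(coincidence_index(a[1], a[2]),
                 coincidence_index(s * a[1], s * a[2]), tolerance = 1e-12)
    expect_equal(coincidence_index(a[1], a[2]),
                 -coincidence_index(a[2], a[1]), tolerance = 1e-12)
    expect_equal(linearity_index(a[1], a[2]),
                 linearity_index(s * a[1], s * a[2]), tolerance = 1e-12)
    expect_true(abs(coincidence_index(a[1], a[2])) <= 1)
  }
})

test_that("tuning metrics follow the CF threshold rule and recover BW70", {
  freqs <- exp(seq(log(4000), log(64000), length.out = 17))
  levels <- c(30, 50, 70)

  # cell responsive only at 70 dB: threshold level 70, CF from that row
  amps <- matrix(0, 17, 3)
  sig <- matrix(FALSE, 17, 3)
  amps[9, 3] <- 1
  sig[9, 3] <- TRUE
  tm <- tuning_metrics(amps, sig, freqs, levels)
  expect_equal(tm$threshold_level, 70)
  expect_equal(tm$cf_hz, freqs[9])

  # no significant response: undefined sentinel
  none <- tuning_metrics(matrix(0, 17, 3), matrix(FALSE, 17, 3),
                         freqs, levels)
  expect_true(is.na(none$cf_hz))

  # Gaussian tuning at 70 dB: BW recovered within 10% of the planted
  # width at the fit threshold (half maximum)
  mu <- log2(16000)
  sigma <- 0.8
  prof <- exp(-(log2(freqs) - mu)^2 / (2 * sigma^2))
  amps2 <- cbind(0, 0, prof)
  sig2 <- cbind(FALSE, FALSE, prof > 0.5)
  tm2 <- tuning_metrics(amps2, sig2, freqs, levels)
  planted_fwhm <- 2 * sqrt(2 * log(2)) * sigma
  expect_equal(tm2$bw70_oct, planted_fwhm, tolerance = 0.1 * planted_fwhm)

  # threshold at the lowest tested level: CF averages the two estimates,
  # landing at the peak for a symmetric profile
  amps3 <- cbind(prof, prof, prof)
  sig3 <- cbind(prof > 0.5, prof > 0.5, prof > 0.5)
  tm3 <- tuning_metrics(amps3, sig3, freqs, levels)
  expect_equal(tm3$threshold_level, 30)
  expect_equal(log2(tm3$cf_hz), mu, tolerance = 0.15)
})
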