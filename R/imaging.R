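# Per-ROI trace processing and per-cell statistics: neuropil correction,
# dF/F, response amplitudes, the two-criterion significance rule, ROC
# threshold calibration, coincidence-preference and linearity indices, and
# pure-tone tuning metrics.

#' Neuropil (background) correction
#'
#' `F(t) = F_cell_measured(t) - r * F_background(t)` per ROI. ROIs are
#' flagged for inclusion only if their mean measured fluorescence is at
#' least `brightness_min` brighter than the background ring (default 3%),
#' which guards against over-subtraction of dim somata.
#'
#' @param session A `roi_session` (or any list with `f_cell` and `f_bg`
#'   cell x frame matrices).
#' @param r Contamination coefficient in `[0, 1]` (default 0.9).
#' @param brightness_min Required fractional brightness margin (default
#'   0.03).
#' @return List with `f` (corrected cell x frame matrix) and `included`
#'   (logical per ROI).
#' @export
neuropil_correct <- function(session, r = 0.9, brightness_min = 0.03) {
  f_cell <- session$f_cell
  f_bg <- session$f_bg
  if (!all(dim(f_cell) == dim(f_bg)))
    stop("cell and background traces must have matching dimensions")
  if (r < 0 || r > 1) stop("r must be in [0, 1]")
  f <- f_cell - r * f_bg
  included <- rowMeans(f_cell) >= (1 + brightness_min) * rowMeans(f_bg)
  list(f = f, included = included)
}

#' Fractional fluorescence change
#'
#' `dF/F = (F - F0) / (F0 + offset)`, with `F0` the per-trial baseline mean.
#' The small offset is added to the denominator only, guarding the division
#' against near-zero baselines.
#'
#' @param f Fluorescence values (vector or matrix).
#' @param f0 Baseline value(s), recycled against `f`.
#' @param offset Denominator guard in a.u. (default 20).
#' @return dF/F values with the shape of `f`.
#' @export
compute_dff <- function(f, f0, offset = 20) {
  if (any(f0 + offset <= 0)) stop("degenerate baseline: F0 + offset <= 0")
  (f - f0) / (f0 + offset)
}

#' Trial-aligned dF/F snippets
#'
#' Cuts per-trial windows `[-pre_s, post_s]` around each sound onset and
#' converts them to dF/F with a per-trial baseline (`baseline_s` before
#' onset).
#'
#' @param f Corrected fluorescence matrix (cells x frames) or vector.
#' @param onset_frames Sound-onset frame per trial.
#' @param frame_rate Frames per second.
#' @param pre_s,post_s Window extent around onset in s.
#' @param baseline_s Baseline window length before onset (default 1).
#' @param offset dF/F denominator guard (default 20).
#' @return A cells x trials x frames array of dF/F with attributes
#'   `onset_index` (frame index of sound onset within the window, 1-based)
#'   and `frame_rate`.
#' @export
align_trials <- function(f, onset_frames, frame_rate, pre_s = 1, post_s = 2,
                         baseline_s = 1, offset = 20) {
  if (is.vector(f)) f <- matrix(f, nrow = 1)
  n_pre <- round(pre_s * frame_rate)
  n_post <- round(post_s * frame_rate)
  n_base <- round(baseline_s * frame_rate)
  if (n_base > n_pre) stop("baseline window must fit before the onset")
  n_win <- n_pre + n_post + 1L
  n_cell <- nrow(f)
  n_trial <- length(onset_frames)
  out <- array(NA_real_, dim = c(n_cell, n_trial, n_win))
  for (tr in seq_len(n_trial)) {
    o <- onset_frames[tr]
    if (o - n_pre < 1 || o + n_post > ncol(f))
      stop("trial window outside trace")
    seg <- f[, (o - n_pre):(o + n_post), drop = FALSE]
    f0 <- rowMeans(f[, (o - n_base):(o - 1L), drop = FALSE])
    out[, tr, ] <- compute_dff(seg, f0, offset = offset)
  }
  attr(out, "onset_index") <- n_pre + 1L
  attr(out, "frame_rate") <- frame_rate
  out
}

# trapezoidal integral of y sampled at spacing dt
.trapz <- function(y, dt) sum((y[-1] + y[-length(y)]) / 2) * dt

#' Response amplitude of trial-aligned traces
#'
#' `auc` mode integrates (trapezoid) the baseline-subtracted dF/F over
#' `window_s` after sound onset, in dF/F·s. `charge` mode integrates the
#' negative-going part of a current trace over the window and flips the
#' sign, for excitatory synaptic charge.
#'
#' @param aligned Trials x frames matrix (one ROI) or the cells x trials x
#'   frames array from [align_trials()].
#' @param frame_rate Frames per second (taken from the attribute when
#'   present).
#' @param onset_index Frame index of sound onset (attribute default).
#' @param window_s Integration window after onset (default 1).
#' @param mode `"auc"` or `"charge"`.
#' @return For a matrix input, a list with `trial` (per-trial amplitudes)
#'   and `mean`; for an array input, a cells x trials matrix of amplitudes.
#' @export
response_amplitude <- function(aligned,
                               frame_rate = attr(aligned, "frame_rate"),
                               onset_index = attr(aligned, "onset_index"),
                               window_s = 1, mode = c("auc", "charge")) {
  mode <- match.arg(mode)
  if (is.null(frame_rate)) stop("frame_rate is required")
  if (is.null(onset_index)) onset_index <- 1L
  nw <- round(window_s * frame_rate)
  one <- function(y) {
    if (onset_index + nw > length(y)) stop("window outside trace")
    seg <- y[onset_index:(onset_index + nw)]
    if (mode == "charge") seg <- -pmin(seg, 0)
    .trapz(seg, 1 / frame_rate)
  }
  if (length(dim(aligned)) == 3) {
    apply(aligned, c(1, 2), one)
  } else {
    amps <- apply(as.matrix(aligned), 1, one)
    list(trial = amps, mean = mean(amps))
  }
}

# length (in samples) of the longest run of TRUE
.max_run <- function(x) {
  r <- rle(x)
  m <- r$lengths[r$values]
  if (length(m) == 0) 0L else max(m)
}

#' Two-criterion response significance test
#'
#' A cell-stimulus pair is significantly excited iff (1) dF/F exceeds
#' `threshold_k` baseline SDs consecutively for at least `min_dur_s` in more
#' than `trial_fraction` of trials, AND (2) the trial-averaged dF/F does so
#' too. The baseline SD is estimated from the pre-onset samples pooled
#' across trials. Default SD multiples by cell type: pyramidal 3.3,
#' SOM 1.6, PV 2.6 (see [calibrate_threshold()]).
#'
#' @param aligned Trials x frames dF/F matrix for one ROI-stimulus pair.
#' @param frame_rate Frames per second.
#' @param onset_index Frame index of sound onset.
#' @param threshold_k Threshold in baseline SD multiples (default 3.3).
#' @param min_dur_s Required consecutive supra-threshold duration
#'   (default 0.5).
#' @param trial_fraction Required fraction of trials, exceeded strictly
#'   (default 0.5).
#' @return List with `significant` plus diagnostics (`criterion1`,
#'   `criterion2`, `frac_trials`, `threshold`).
#' @export
test_significance <- function(aligned,
                              frame_rate = attr(aligned, "frame_rate"),
                              onset_index = attr(aligned, "onset_index"),
                              threshold_k = 3.3, min_dur_s = 0.5,
                              trial_fraction = 0.5) {
  aligned <- as.matrix(aligned)
  if (is.null(onset_index)) stop("onset_index is required")
  base <- aligned[, seq_len(onset_index - 1L), drop = FALSE]
  sd0 <- stats::sd(as.vector(base))
  if (!is.finite(sd0)) stop("cannot estimate baseline SD")
  # a perfectly flat baseline (noiseless input) degenerates to threshold 0:
  # any strictly positive sustained response is then significant, an
  # all-zero response is not
  thr <- threshold_k * sd0
  resp <- aligned[, onset_index:ncol(aligned), drop = FALSE]
  min_run <- round(min_dur_s * frame_rate)
  per_trial <- apply(resp > thr, 1, .max_run) >= min_run
  frac <- mean(per_trial)
  crit1 <- frac > trial_fraction
  crit2 <- .max_run(colMeans(resp) > thr) >= min_run
  list(significant = crit1 && crit2, criterion1 = crit1, criterion2 = crit2,
       frac_trials = frac, threshold = thr)
}

#' Calibrate the significance threshold by ROC analysis
#'
#' Returns the largest threshold whose true-positive rate on labeled
#' responses still meets `target_tpr` (default 90%), i.e. the
#' `(1 - target_tpr)` quantile of the positive class. If the classes are
#' perfectly separated the midpoint of the gap is returned (TPR = 1). If
#' the target is unattainable the boundary threshold is returned with a
#' warning.
#'
#' @param values Numeric response statistic (e.g. peak dF/F in baseline SD
#'   units).
#' @param labels Logical (or 0/1) true-response labels.
#' @param target_tpr Required true-positive rate (default 0.9).
#' @return List with `threshold`, `tpr`, `fpr`.
#' @export
calibrate_threshold <- function(values, labels, target_tpr = 0.9) {
  labels <- as.logical(labels)
  pos <- values[labels]
  neg <- values[!labels]
  if (length(pos) == 0 || length(neg) == 0)
    stop("both label classes are required")
  if (max(neg) < min(pos)) {
    thr <- (max(neg) + min(pos)) / 2
  } else {
    thr <- unname(stats::quantile(pos, probs = 1 - target_tpr, type = 1))
  }
  tpr <- mean(pos >= thr)
  if (tpr < target_tpr) {
    warning("target true-positive rate unattainable; returning boundary")
    thr <- min(pos)
    tpr <- 1
  }
  list(threshold = thr, tpr = tpr, fpr = mean(neg >= thr))
}

#' Coincidence-preference index
#'
#' `CI = (C - S) / (C + S)` for the response to coincident (`C`) versus
#' onset-shifted (`S`) harmonics. Negative amplitudes are clipped to 0
#' first, keeping CI in `[-1, 1]`; if both are 0 after clipping the index
#' is undefined and `NA` is returned (such pairs are dropped from pooling).
#'
#' @param c_amp,s_amp Response amplitudes (vectorized).
#' @return CI in `[-1, 1]` or `NA`.
#' @export
coincidence_index <- function(c_amp, s_amp) {
  c_amp <- pmax(c_amp, 0)
  s_amp <- pmax(s_amp, 0)
  ifelse(c_amp + s_amp == 0, NA_real_, (c_amp - s_amp) / (c_amp + s_amp))
}

#' Linearity index
#'
#' `LI = (H - S) / (H + S)` comparing the multi-tone response `H` with the
#' linear sum `S` of the component-tone responses. Negative amplitudes are
#' clipped to 0 first; 0 means linear summation, negative sublinear,
#' positive supralinear. `NA` when both are 0 after clipping.
#'
#' @param h_amp Multi-tone (harmonic) response amplitude.
#' @param s_linear Linear sum of component responses.
#' @return LI in `[-1, 1]` or `NA`.
#' @export
linearity_index <- function(h_amp, s_linear) {
  h_amp <- pmax(h_amp, 0)
  s_linear <- pmax(s_linear, 0)
  ifelse(h_amp + s_linear == 0, NA_real_,
         (h_amp - s_linear) / (h_amp + s_linear))
}

#' Compute the response table of a session
#'
#' Runs neuropil correction, trial alignment, amplitude integration and the
#' two-criterion significance test for every ROI x stimulus of a
#' `roi_session`.
#'
#' @param session A `roi_session`.
#' @param r,brightness_min See [neuropil_correct()].
#' @param threshold_k,min_dur_s,trial_fraction See [test_significance()].
#' @param window_s Response window in s (default 1).
#' @param baseline_s,offset See [align_trials()].
#' @return A list of class `response_table`: `amplitude` (ROI x stimulus
#'   trial-mean matrix), `significant` (logical matrix), `trial_amps`
#'   (ROI x stimulus x trial array), `included` (brightness mask),
#'   `stim_table`, `coords`.
#' @export
response_table <- function(session, r = 0.9, brightness_min = 0.03,
                           threshold_k = 3.3, min_dur_s = 0.5,
                           trial_fraction = 0.5, window_s = 1,
                           baseline_s = 1, offset = 20) {
  np <- neuropil_correct(session, r = r, brightness_min = brightness_min)
  stim <- session$stim_table
  n_cell <- nrow(np$f)
  n_stim <- nrow(stim)
  n_trial <- max(table(session$trials$stim_id))
  amp_mean <- sig <- matrix(NA_real_, n_cell, n_stim)
  trial_amps <- array(NA_real_, dim = c(n_cell, n_stim, n_trial))
  for (si in seq_len(n_stim)) {
    onsets <- session$trials$onset_frame[session$trials$stim_id ==
                                           stim$stim_id[si]]
    al <- align_trials(np$f, onsets, session$frame_rate,
                       pre_s = baseline_s, post_s = window_s + 1,
                       baseline_s = baseline_s, offset = offset)
    amps <- response_amplitude(al, window_s = window_s)
    trial_amps[, si, seq_len(ncol(amps))] <- amps
    amp_mean[, si] <- rowMeans(amps)
    for (ci in seq_len(n_cell)) {
      sig[ci, si] <- test_significance(
        al[ci, , ], frame_rate = session$frame_rate,
        onset_index = attr(al, "onset_index"), threshold_k = threshold_k,
        min_dur_s = min_dur_s, trial_fraction = trial_fraction)$significant
    }
  }
  structure(list(amplitude = amp_mean, significant = sig == 1,
                 trial_amps = trial_amps, included = np$included,
                 stim_table = stim, coords = session$coords),
            class = "response_table")
}

#' Coincidence indices of a response table
#'
#' CI per ROI-F0-Δonset combination, computed only where a significant
#' excitatory response was evoked by the coincident and/or the shifted
#' stimulus. Shifts of ±15 and ±30 ms are pooled per area by default
#' (±45 ms excluded).
#'
#' @param rt A [response_table()].
#' @param pool_shifts Absolute Δonsets (ms) pooled into the CI sample
#'   (default `c(15, 30)`).
#' @return Data frame `roi`, `f0`, `delta_onset`, `ci` (undefined pairs
#'   dropped).
#' @export
coincidence_indices <- function(rt, pool_shifts = c(15, 30)) {
  stim <- rt$stim_table
  rows <- list()
  for (f0 in unique(stim$f0)) {
    i0 <- which(stim$f0 == f0 & stim$delta_onset == 0)
    if (length(i0) != 1) next
    for (d in setdiff(unique(stim$delta_onset[stim$f0 == f0]), 0)) {
      if (!(abs(d) %in% pool_shifts)) next
      id <- which(stim$f0 == f0 & stim$delta_onset == d)
      eligible <- rt$significant[, i0] | rt$significant[, id]
      ci <- coincidence_index(rt$amplitude[, i0], rt$amplitude[, id])
      keep <- which(eligible & !is.na(ci) & rt$included)
      if (length(keep) > 0) {
        rows[[length(rows) + 1L]] <- data.frame(roi = keep, f0 = f0,
                                                delta_onset = d,
                                                ci = ci[keep])
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(roi = integer(0), f0 = numeric(0),
                      delta_onset = numeric(0), ci = numeric(0)))
  }
  do.call(rbind, rows)
}

#' Pure-tone tuning metrics: CF and BW70
#'
#' The threshold intensity is the lowest level with at least one
#' significant tone response; CF is the frequency of the strongest response
#' at that level. When the threshold sits at (or below) the lowest tested
#' level, CF is the average of two estimates at the lowest level: the
#' strongest-response frequency and the mean of a Gaussian fit over
#' log2-frequency. BW70 is the mean of (a) the octave span of frequencies
#' with significant responses at 70 dB and (b) the span where a Gaussian
#' fit at 70 dB exceeds half its peak.
#'
#' @param amps Frequencies x levels matrix of response amplitudes.
#' @param sig Matching logical significance matrix.
#' @param freqs Tone frequencies (Hz), ascending.
#' @param levels Sound levels (dB), ascending.
#' @return List with `cf_hz`, `bw70_oct`, `threshold_level`; all `NA` when
#'   no tone response is significant.
#' @export
tuning_metrics <- function(amps, sig, freqs, levels) {
  stopifnot(all(dim(amps) == dim(sig)),
            nrow(amps) == length(freqs), ncol(amps) == length(levels))
  any_sig <- apply(sig, 2, any)
  if (!any(any_sig)) {
    return(list(cf_hz = NA_real_, bw70_oct = NA_real_,
                threshold_level = NA_real_))
  }
  li <- which(any_sig)[1]
  thr_level <- levels[li]
  cf_peak <- freqs[which.max(amps[, li])]
  cf <- cf_peak
  if (li == 1) {
    fit <- .gauss_fit_log2(freqs, pmax(amps[, li], 0))
    if (!is.null(fit)) cf <- (cf_peak + 2^fit$mu) / 2
  }
  bw <- NA_real_
  i70 <- which(levels == 70)
  if (length(i70) == 1) {
    emp <- NA_real_
    if (any(sig[, i70])) {
      fr <- range(freqs[sig[, i70]])
      emp <- log2(fr[2] / fr[1])
    }
    fitted_bw <- NA_real_
    fit <- .gauss_fit_log2(freqs, pmax(amps[, i70], 0))
    if (!is.null(fit)) {
      lf <- seq(log2(min(freqs)), log2(max(freqs)), length.out = 512)
      y <- fit$a * exp(-(lf - fit$mu)^2 / (2 * fit$sigma^2))
      above <- lf[y > fit$a / 2]
      if (length(above) > 1) fitted_bw <- max(above) - min(above)
    }
    bw <- mean(c(emp, fitted_bw), na.rm = TRUE)
    if (is.nan(bw)) bw <- NA_real_
  }
  list(cf_hz = cf, bw70_oct = bw, threshold_level = thr_level)
}

# least-squares Gaussian over log2(frequency), positivity-bounded
.gauss_fit_log2 <- function(freqs, y) {
  lf <- log2(freqs)
  if (max(y) <= 0) return(NULL)
  st <- list(a = max(y), mu = lf[which.max(y)],
             sigma = (max(lf) - min(lf)) / 4)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ a * exp(-(lf - mu)^2 / (2 * sigma^2)),
                      start = st,
                      lower = c(a = 0, mu = min(lf) - 2, sigma = 1e-3),
                      upper = c(a = Inf, mu = max(lf) + 2, sigma = 20),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(NULL)
  as.list(stats::coef(fit))
}
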