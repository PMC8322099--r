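# Ground-truthed synthetic inputs for every pipeline stage: calcium imaging
# sessions with planted response archetypes and shared-latent subnetworks,
# harmonic vocal audio, Poisson spike trains with optogenetic suppression,
# and behavioral go/no-go sessions.

#' Archetype tuning weights over onset shifts
#'
#' Default response-profile templates over the Δonset grid for the three
#' response archetypes plus a nonresponsive class. Coincidence cells peak at
#' Δonset = 0; shift archetypes peak at the corresponding sign.
#'
#' @param kind One of `"coincidence"`, `"negative_shift"`, `"positive_shift"`,
#'   `"nonresponsive"`.
#' @param delta_onsets Δonset grid in ms (default -45..45 by 15).
#' @return Numeric weight vector in `[0, 1]`, one entry per Δonset.
#' @export
archetype_weights <- function(kind = c("coincidence", "negative_shift",
                                       "positive_shift", "nonresponsive"),
                              delta_onsets = seq(-45, 45, by = 15)) {
  kind <- match.arg(kind)
  d <- delta_onsets
  w <- switch(kind,
    coincidence = 0.1 + 0.9 * exp(-(d / 12)^2),
    negative_shift = 0.05 + 0.95 * stats::plogis(-d / 10),
    positive_shift = 0.05 + 0.95 * stats::plogis(d / 10),
    nonresponsive = rep(0, length(d)))
  if (kind != "nonresponsive") w <- w / max(w)
  w
}

#' Configuration of a synthetic imaging population
#'
#' @param n_cells Named counts per archetype per F0, e.g.
#'   `c(coincidence = 8, negative_shift = 8, positive_shift = 8,
#'   nonresponsive = 8)`.
#' @param f0s F0 labels (Hz) of the harmonic stimulus families.
#' @param delta_onsets Δonset grid in ms.
#' @param n_trials Trials (blocks) per stimulus (default 5).
#' @param frame_rate Imaging frame rate in Hz (default 30).
#' @param peak_amp Archetype peak response amplitude in dF/F·s (AUC over the
#'   1 s response window).
#' @param trial_noise_cv Multiplicative trial noise (coefficient of
#'   variation on the amplitude).
#' @param amp_noise_sd Additive per-trial amplitude noise SD (dF/F·s).
#' @param latent_sd Shared-latent SD within same-F0 coincidence subnetworks
#'   (dF/F·s); pairwise noise correlation in a subnetwork approaches
#'   `latent_sd^2 / (latent_sd^2 + amp_noise_sd^2)` when the multiplicative
#'   term is off.
#' @param trace_noise_sd Additive white noise on the fluorescence traces
#'   (a.u.).
#' @param base_f Baseline cell fluorescence (a.u.).
#' @param bg_f Baseline background (neuropil ring) fluorescence (a.u.).
#' @param neuropil_r Contamination coefficient mixed into the measured cell
#'   trace (the analysis subtracts `r * F_background`).
#' @param kernel_rise,kernel_decay Calcium kernel time constants in s
#'   (difference of exponentials; GCaMP6s-like defaults 0.05 and 1).
#' @param kernel_support_s Hard truncation of the kernel (s).
#' @param trial_period_s Spacing between consecutive sound onsets (s).
#' @param field_um Imaging field size (µm, square).
#' @param cluster_radius_um SD of the 2-D Gaussian spatial cluster of each
#'   same-F0 coincidence subnetwork.
#' @param seed Integer seed.
#' @return A list of class `population_config`.
#' @export
population_config <- function(n_cells = c(coincidence = 8, negative_shift = 8,
                                          positive_shift = 8,
                                          nonresponsive = 8),
                              f0s = c(2000, 2800, 4000, 5700, 8000),
                              delta_onsets = seq(-45, 45, by = 15),
                              n_trials = 5, frame_rate = 30, peak_amp = 0.5,
                              trial_noise_cv = 0.2, amp_noise_sd = 0.05,
                              latent_sd = 0.033, trace_noise_sd = 1,
                              base_f = 100, bg_f = 50, neuropil_r = 0.9,
                              kernel_rise = 0.05, kernel_decay = 1,
                              kernel_support_s = 4, trial_period_s = 6,
                              field_um = 620, cluster_radius_um = 60,
                              seed = 1) {
  stopifnot(all(n_cells >= 0), n_trials >= 1, frame_rate > 0,
            kernel_decay > kernel_rise, kernel_rise > 0)
  structure(as.list(environment()), class = "population_config")
}

# calcium kernel sampled on the frame grid, normalized so the trapezoidal
# integral of the first `window_s` seconds is 1 (planted amplitudes are
# then recovered exactly by the AUC readout in the noiseless limit)
.calcium_kernel <- function(frame_rate, rise, decay, support_s, window_s = 1) {
  t <- seq(0, support_s, by = 1 / frame_rate)
  k <- exp(-t / decay) - exp(-t / rise)
  nw <- round(window_s * frame_rate)
  auc <- sum(diff(t[1:(nw + 1)]) * (k[1:nw] + k[2:(nw + 1)]) / 2)
  k / auc
}

#' Generate a synthetic imaging population session
#'
#' Per trial, the planted response amplitude of a cell is
#' `weight(Δonset) * peak * (1 + cv * e1) + N(0, amp_noise_sd) + latent`,
#' where the latent term is shared by all cells of the same-F0 coincidence
#' subnetwork on that trial. Amplitudes are rendered onto fluorescence
#' traces with a truncated difference-of-exponentials calcium kernel;
#' background (ring) traces carry independent noise and a fraction of the
#' background is mixed into the measured cell trace so neuropil correction
#' is exercised. Cells of each same-F0 coincidence subnetwork are placed in
#' a 2-D Gaussian spatial cluster; all other cells are uniform in the field.
#'
#' @param config A [population_config()].
#' @param weights Optional list mapping archetype kind to a custom weight
#'   vector over Δonsets (defaults to [archetype_weights()]).
#' @return A list of class `synthetic_session` with elements
#'   `session` (class `roi_session`: `f_cell`, `f_bg` cell x frame matrices,
#'   `coords`, `trials` data frame with `stim_id` and `onset_frame`,
#'   `frame_rate`, `stim_table`) and `truth` (`cells` data frame with
#'   archetype/F0/subnetwork per cell, `amps` cell x stimulus x trial array
#'   of planted amplitudes, `weights`).
#' @export
generate_population <- function(config, weights = NULL) {
  stopifnot(inherits(config, "population_config"))
  cf <- config
  withr::with_seed(as.integer(cf$seed), {
    kinds <- names(cf$n_cells)
    if (is.null(weights)) {
      weights <- lapply(stats::setNames(kinds, kinds), archetype_weights,
                        delta_onsets = cf$delta_onsets)
    }
    cells <- do.call(rbind, lapply(cf$f0s, function(f0) {
      do.call(rbind, lapply(kinds, function(k) {
        if (cf$n_cells[[k]] == 0) return(NULL)
        data.frame(archetype = k, f0 = f0, n = seq_len(cf$n_cells[[k]]))
      }))
    }))
    n_cell <- nrow(cells)
    cells$cell <- seq_len(n_cell)
    cells$subnetwork <- ifelse(cells$archetype == "coincidence",
                               paste0("F", cells$f0), NA_character_)
    # stimulus table: every F0 x Δonset
    stim <- expand.grid(delta_onset = cf$delta_onsets, f0 = cf$f0s)
    stim <- stim[, c("f0", "delta_onset")]
    stim$stim_id <- seq_len(nrow(stim))
    n_stim <- nrow(stim)

    # blocked schedule
    sched <- build_schedule(stim$stim_id, n_blocks = cf$n_trials,
                            seed = sample.int(.Machine$integer.max, 1))
    n_trial_tot <- nrow(sched)
    onset_frames <- round((seq_len(n_trial_tot) * cf$trial_period_s) *
                            cf$frame_rate)
    n_frames <- max(onset_frames) +
      round((cf$kernel_support_s + 2) * cf$frame_rate)

    # planted per-trial amplitudes [cell, stim, block]
    amps <- array(0, dim = c(n_cell, n_stim, cf$n_trials))
    widx <- match(cells$archetype, kinds)
    latent <- array(stats::rnorm(length(cf$f0s) * n_stim * cf$n_trials,
                                 sd = cf$latent_sd),
                    dim = c(length(cf$f0s), n_stim, cf$n_trials))
    for (ci in seq_len(n_cell)) {
      w_cell <- weights[[cells$archetype[ci]]]
      for (si in seq_len(n_stim)) {
        w <- if (stim$f0[si] == cells$f0[ci]) {
          w_cell[match(stim$delta_onset[si], cf$delta_onsets)]
        } else 0
        e1 <- stats::rnorm(cf$n_trials)
        a <- w * cf$peak_amp * (1 + cf$trial_noise_cv * e1) +
          stats::rnorm(cf$n_trials, sd = cf$amp_noise_sd)
        if (!is.na(cells$subnetwork[ci])) {
          a <- a + latent[match(cells$f0[ci], cf$f0s), si, ]
        }
        amps[ci, si, ] <- a
      }
    }

    # render traces
    kern <- .calcium_kernel(cf$frame_rate, cf$kernel_rise, cf$kernel_decay,
                            cf$kernel_support_s)
    lk <- length(kern)
    dff <- matrix(0, n_cell, n_frames)
    block_count <- integer(n_stim)
    trial_rows <- data.frame(trial = seq_len(n_trial_tot),
                             block = sched$block, stim_id = sched$stim_id,
                             onset_frame = onset_frames)
    for (tr in seq_len(n_trial_tot)) {
      si <- sched$stim_id[tr]
      block_count[si] <- block_count[si] + 1L
      f1 <- onset_frames[tr]
      idx <- f1:(f1 + lk - 1L)
      dff[, idx] <- dff[, idx] + outer(amps[, si, block_count[si]], kern)
    }
    f_true <- cf$base_f * (1 + dff)
    f_bg <- matrix(cf$bg_f, n_cell, n_frames) +
      matrix(stats::rnorm(n_cell * n_frames, sd = cf$trace_noise_sd),
             n_cell, n_frames)
    f_cell <- f_true + cf$neuropil_r * f_bg +
      matrix(stats::rnorm(n_cell * n_frames, sd = cf$trace_noise_sd),
             n_cell, n_frames)

    # spatial coordinates
    coords <- matrix(stats::runif(n_cell * 2, 0, cf$field_um), n_cell, 2)
    for (f0 in cf$f0s) {
      mem <- which(!is.na(cells$subnetwork) & cells$f0 == f0)
      if (length(mem) > 0) {
        ctr <- stats::runif(2, cf$field_um * 0.2, cf$field_um * 0.8)
        coords[mem, ] <- cbind(
          stats::rnorm(length(mem), ctr[1], cf$cluster_radius_um),
          stats::rnorm(length(mem), ctr[2], cf$cluster_radius_um))
      }
    }
    coords <- pmin(pmax(coords, 0), cf$field_um)
    colnames(coords) <- c("x_um", "y_um")

    session <- structure(list(f_cell = f_cell, f_bg = f_bg, coords = coords,
                              trials = trial_rows, frame_rate = cf$frame_rate,
                              stim_table = stim, cell_type = "pyr"),
                         class = "roi_session")
    structure(list(session = session,
                   truth = list(cells = cells, amps = amps,
                                weights = weights, config = cf)),
              class = "synthetic_session")
  })
}

#' Generate synthetic vocal audio with planted harmonic syllables
#'
#' Harmonic syllables (equal-amplitude harmonics of each listed F0, with
#' linear ramps) separated by silent gaps, embedded in white noise at the
#' requested SNR. A leading noise-only baseline segment is included so
#' syllable detection can estimate the noise floor.
#'
#' @param f0s Vector of syllable F0s in Hz (empty for a noise-only
#'   recording).
#' @param syllable_dur_ms Syllable duration (default 60).
#' @param n_harmonics Number of harmonics per syllable (default 4).
#' @param snr_db Signal-to-noise ratio in dB (syllable RMS over noise RMS).
#' @param gap_ms Silent gap between syllables (default 60).
#' @param lead_ms Leading noise-only baseline (default 150).
#' @param ramp_ms Linear rise/fall per syllable (default 5).
#' @param sample_rate Sampling rate in Hz (default 192000).
#' @param seed Integer seed.
#' @return Waveform with `sample_rate` attribute and attribute `truth`, a
#'   data frame of planted `onset_s`, `offset_s`, `f0`.
#' @export
generate_vocal_audio <- function(f0s, syllable_dur_ms = 60, n_harmonics = 4,
                                 snr_db = 20, gap_ms = 60, lead_ms = 150,
                                 ramp_ms = 5, sample_rate = 192000,
                                 seed = 1) {
  if (length(f0s) > 0 && any(f0s <= 0)) stop("f0s must be > 0")
  withr::with_seed(as.integer(seed), {
    dur_s <- syllable_dur_ms / 1000
    gap_s <- gap_ms / 1000
    lead_s <- lead_ms / 1000
    total_s <- lead_s + length(f0s) * (dur_s + gap_s) + gap_s
    n <- ceiling(total_s * sample_rate)
    t_all <- (seq_len(n) - 1) / sample_rate
    x <- numeric(n)
    truth <- NULL
    for (i in seq_along(f0s)) {
      onset <- lead_s + (i - 1) * (dur_s + gap_s)
      comps <- do.call(rbind, lapply(seq_len(n_harmonics), function(k) {
        tone_component(k * f0s[i], onset = 0, duration = syllable_dur_ms,
                       ramp = ramp_ms)
      }))
      wav <- synthesize_waveform(stimulus_spec(comps, f0 = f0s[i]),
                                 sample_rate = sample_rate)
      i0 <- round(onset * sample_rate) + 1L
      idx <- i0:(i0 + length(wav) - 1L)
      x[idx] <- x[idx] + wav
      truth <- rbind(truth, data.frame(onset_s = onset,
                                       offset_s = onset + dur_s, f0 = f0s[i]))
    }
    if (length(f0s) > 0 && is.finite(snr_db)) {
      sig_rms <- sqrt(mean(x[x != 0]^2))
      noise_sd <- sig_rms / 10^(snr_db / 20)
    } else {
      noise_sd <- 1e-3
    }
    x <- x + stats::rnorm(n, sd = noise_sd)
    attr(x, "sample_rate") <- sample_rate
    attr(x, "truth") <- truth
    attr(x, "noise_sd") <- noise_sd
    x
  })
}

#' Generate spike trains with optional optogenetic suppression
#'
#' Inhomogeneous Poisson spike trains at a constant baseline rate; on LED
#' trials the rate is multiplied by
#' `floor + (1 - floor) * exp(-(t - latency)/tau)` after `latency` (rate
#' unchanged before), emulating photosuppression of population firing.
#'
#' @param baseline_rate_hz Spontaneous rate in Hz.
#' @param duration_ms Trial duration in ms; time 0 is LED onset for
#'   suppression trials.
#' @param pre_ms Time simulated before 0 (baseline segment), default 20.
#' @param n_trials Number of trials.
#' @param suppression `NULL` for control trials, else
#'   `list(latency = ms, tau = ms, floor = fraction)`.
#' @param seed Integer seed.
#' @return List of numeric vectors of spike times in ms (relative to LED
#'   onset at 0), one per trial.
#' @export
generate_ephys_session <- function(baseline_rate_hz = 50, duration_ms = 200,
                                   pre_ms = 20, n_trials = 100,
                                   suppression = NULL, seed = 1) {
  stopifnot(baseline_rate_hz >= 0)
  withr::with_seed(as.integer(seed), {
    rate_fn <- function(t_ms) {
      r <- rep(baseline_rate_hz, length(t_ms))
      if (!is.null(suppression)) {
        post <- t_ms >= suppression$latency
        r[post] <- baseline_rate_hz *
          (suppression$floor + (1 - suppression$floor) *
             exp(-(t_ms[post] - suppression$latency) / suppression$tau))
      }
      r
    }
    lapply(seq_len(n_trials), function(i) {
      if (baseline_rate_hz == 0) return(numeric(0))
      span <- (duration_ms + pre_ms) / 1000
      n_exp <- stats::rpois(1, baseline_rate_hz * span)
      t <- sort(stats::runif(n_exp, -pre_ms, duration_ms))
      keep <- stats::runif(n_exp) < rate_fn(t) / baseline_rate_hz
      t[keep]
    })
  })
}

#' Generate a behavioral discrimination session
#'
#' Go/no-go trials: the mouse licks for coincident harmonics and withholds
#' for onset-shifted ones. Lick outcomes are Bernoulli draws from a logistic
#' psychometric function of the log-modulus-transformed Δonset,
#' `P(lick) = plogis(slope * (x - x_mid))` with
#' `x = sign(Δ) * log10(1 + |Δ|)`; on LED (photoinactivation) trials the
#' midpoint is shifted to `led_midpoint_ms`.
#'
#' @param midpoint_ms Control half-max Δonset magnitude in ms.
#' @param slope Logistic growth rate on the log-modulus scale.
#' @param n_trials Number of trials.
#' @param delta_grid Δonset values presented (ms), sampled uniformly.
#' @param led_fraction Fraction of randomly interleaved LED trials
#'   (default 0.3).
#' @param led_midpoint_ms Half-max Δonset on LED trials (defaults to the
#'   control midpoint: no optogenetic effect).
#' @param seed Integer seed.
#' @return Data frame `trial`, `delta_onset_ms`, `led`, `lick`.
#' @export
generate_behavior_session <- function(midpoint_ms = 19.4, slope = 4,
                                      n_trials = 250,
                                      delta_grid = seq(-75, 0, by = 15),
                                      led_fraction = 0.3,
                                      led_midpoint_ms = midpoint_ms,
                                      seed = 1) {
  if (length(delta_grid) == 0) stop("delta_grid is empty")
  withr::with_seed(as.integer(seed), {
    delta <- sample(delta_grid, n_trials, replace = TRUE)
    led <- stats::runif(n_trials) < led_fraction
    x <- log_modulus(delta)
    xm <- ifelse(led, -log10(1 + led_midpoint_ms), -log10(1 + midpoint_ms))
    p <- stats::plogis(slope * (x - xm))
    data.frame(trial = seq_len(n_trials), delta_onset_ms = delta, led = led,
               lick = stats::runif(n_trials) < p)
  })
}
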