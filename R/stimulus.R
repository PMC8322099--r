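#' Construct a tone component
#'
#' A single frequency component of a multi-tone stimulus. Times are in ms
#' relative to the stimulus reference (onset of the unshifted group); the
#' component occupies the half-open interval `[onset, onset + duration)`.
#'
#' @param frequency Frequency in Hz (> 0).
#' @param onset Onset in ms relative to the stimulus reference.
#' @param duration Duration in ms (> 0).
#' @param level Nominal level label in dB SPL. Levels are relative labels:
#'   the software reference is a full-scale sine of amplitude 1, there is no
#'   physical calibration.
#' @param ramp Linear rise/fall time in ms (`2 * ramp <= duration`).
#' @return A one-row data frame with columns frequency, onset, duration,
#'   level, ramp.
#' @export
tone_component <- function(frequency, onset = 0, duration = 100, level = 70,
                           ramp = 5) {
  if (frequency <= 0) stop("frequency must be > 0")
  if (duration <= 0) stop("duration must be > 0")
  if (ramp < 0 || 2 * ramp > duration) stop("need 0 <= 2*ramp <= duration")
  data.frame(frequency = frequency, onset = onset, duration = duration,
             level = level, ramp = ramp)
}

#' Construct a stimulus specification
#'
#' @param components Data frame of tone components (see [tone_component()]).
#'   Components are kept sorted by frequency.
#' @param f0 Fundamental frequency in Hz, or `NA` for jittered / pure-tone
#'   stimuli without a defined F0.
#' @param delta_onset Signed onset shift in ms applied to `shift_group`.
#' @param shift_group One of `"none"`, `"lower_half"`, `"fundamental"`.
#' @param jitter_seed Integer seed used to draw frequency jitter, or `NA`.
#' @param total_level Total presented level label in dB SPL.
#' @return An object of class `stimulus_spec`.
#' @export
stimulus_spec <- function(components, f0 = NA_real_, delta_onset = 0,
                          shift_group = c("none", "lower_half", "fundamental"),
                          jitter_seed = NA_integer_, total_level = 70) {
  shift_group <- match.arg(shift_group)
  stopifnot(is.data.frame(components),
            all(c("frequency", "onset", "duration", "level", "ramp") %in%
                  names(components)))
  components <- components[order(components$frequency), , drop = FALSE]
  rownames(components) <- NULL
  structure(list(components = components, f0 = f0, delta_onset = delta_onset,
                 shift_group = shift_group, jitter_seed = jitter_seed,
                 total_level = total_level),
            class = "stimulus_spec")
}

#' @export
print.stimulus_spec <- function(x, ...) {
  cat(sprintf("<stimulus_spec: %d components, F0 = %s Hz, delta_onset = %g ms (%s)>\n",
              nrow(x$components),
              if (is.na(x$f0)) "NA" else format(x$f0), x$delta_onset,
              x$shift_group))
  invisible(x)
}

#' Build a harmonic stack
#'
#' Components at every integer multiple of `f0` up to `fmax`, sharing onset 0
#' and equal per-component level. Frequencies are exact integer multiples
#' (`k * f0`), so a 4 kHz F0 stack up to 40 kHz has ten tones 4, 8, ..., 40 kHz.
#'
#' @param f0 Fundamental frequency in Hz.
#' @param fmax Highest allowed component frequency in Hz (`fmax >= f0`).
#' @param duration Component duration in ms.
#' @param level Per-component level label (dB SPL).
#' @param ramp Linear rise/fall in ms.
#' @param total_level Total level label of the summed stimulus.
#' @return A `stimulus_spec` with `floor(fmax / f0)` components.
#' @export
make_harmonic_stack <- function(f0, fmax = 40000, duration = 100, level = 70,
                                ramp = 5, total_level = 70) {
  if (f0 <= 0) stop("f0 must be > 0")
  if (fmax < f0) stop("fmax must be >= f0")
  k <- seq_len(floor(fmax / f0))
  comps <- data.frame(frequency = k * f0, onset = 0, duration = duration,
                      level = level, ramp = ramp)
  stimulus_spec(comps, f0 = f0, total_level = total_level)
}

#' Shift the onset of one component group
#'
#' Adds `delta` ms to the onsets of the designated group and sets all other
#' components to onset 0 (the stimulus reference). For a fresh stack (all
#' onsets 0) this places the group at `delta`; applying the shift again
#' with `-delta` restores the original onsets. Negative `delta` means the
#' designated group leads. `"lower_half"` shifts the `floor(n/2)`
#' lowest-frequency components; `"fundamental"` shifts only the component
#' at F0.
#'
#' @param spec A `stimulus_spec` with at least two components.
#' @param delta Signed onset shift in ms.
#' @param group `"lower_half"` or `"fundamental"`.
#' @return A `stimulus_spec` with updated onsets and recorded
#'   `delta_onset` / `shift_group` metadata.
#' @export
apply_onset_shift <- function(spec, delta, group = c("lower_half", "fundamental")) {
  group <- match.arg(group)
  stopifnot(inherits(spec, "stimulus_spec"))
  comps <- spec$components
  if (nrow(comps) < 2) stop("spec must have >= 2 components")
  if (group == "fundamental") {
    if (is.na(spec$f0)) stop("fundamental shift requires a spec with F0")
    idx <- which(comps$frequency == spec$f0)
    if (length(idx) == 0) stop("no component at F0")
  } else {
    idx <- order(comps$frequency)[seq_len(floor(nrow(comps) / 2))]
  }
  shifted <- comps$onset[idx] + delta
  comps$onset <- 0
  comps$onset[idx] <- shifted
  spec$components <- comps
  spec$delta_onset <- shifted[1]
  spec$shift_group <- if (all(shifted == 0)) "none" else group
  spec
}

#' Add random frequency jitter to a harmonic stack
#'
#' Each component frequency is perturbed by an independent uniform draw in
#' `[-jitter_halfwidth, +jitter_halfwidth]`. The draw is seeded so the same
#' seed reproduces the same frequency set (jittered sets are held fixed
#' within a presentation block). A perturbed frequency that lands at or
#' below 0 Hz is redrawn by default (preserving the component count) or the
#' jitter is rejected, per `on_nonpositive`.
#'
#' @param spec A harmonic `stimulus_spec`.
#' @param jitter_halfwidth Half width of the uniform jitter in Hz
#'   (conventionally `0.5 * F0`).
#' @param seed Integer seed.
#' @param on_nonpositive `"redraw"` (default) or `"reject"`.
#' @return A `stimulus_spec` with jittered frequencies, `f0 = NA` and the
#'   seed recorded. Attribute `"n_redraws"` counts redraws taken.
#' @export
make_jittered <- function(spec, jitter_halfwidth, seed,
                          on_nonpositive = c("redraw", "reject")) {
  on_nonpositive <- match.arg(on_nonpositive)
  stopifnot(inherits(spec, "stimulus_spec"))
  if (jitter_halfwidth < 0) stop("jitter_halfwidth must be >= 0")
  comps <- spec$components
  draw <- withr::with_seed(as.integer(seed), {
    f <- comps$frequency +
      stats::runif(nrow(comps), -jitter_halfwidth, jitter_halfwidth)
    n_redraws <- 0L
    bad <- which(f <= 0)
    while (length(bad) > 0) {
      if (on_nonpositive == "reject")
        stop("jitter produced non-positive frequency")
      n_redraws <- n_redraws + length(bad)
      f[bad] <- comps$frequency[bad] +
        stats::runif(length(bad), -jitter_halfwidth, jitter_halfwidth)
      bad <- which(f <= 0)
    }
    list(f = f, n_redraws = n_redraws)
  })
  freqs <- draw$f
  n_redraws <- draw$n_redraws
  comps$frequency <- freqs
  out <- stimulus_spec(comps, f0 = NA_real_, delta_onset = spec$delta_onset,
                       shift_group = spec$shift_group,
                       jitter_seed = as.integer(seed),
                       total_level = spec$total_level)
  attr(out, "n_redraws") <- n_redraws
  out
}

#' Build a log-spaced pure-tone set
#'
#' `n_freqs` frequencies uniformly spaced in log frequency between `fmin` and
#' `fmax` (endpoints inclusive), crossed with the requested levels. The
#' standard receptive-field set is 17 frequencies, 4-64 kHz, at 30/50/70 dB.
#'
#' @param fmin,fmax Frequency range in Hz.
#' @param n_freqs Number of frequencies (>= 2).
#' @param levels Numeric vector of levels (dB SPL labels).
#' @param duration Tone duration in ms.
#' @param ramp Rise/fall in ms.
#' @return A list of `stimulus_spec`, one per (frequency, level), ordered
#'   level-major then frequency.
#' @export
make_pure_tone_set <- function(fmin = 4000, fmax = 64000, n_freqs = 17,
                               levels = c(30, 50, 70), duration = 100,
                               ramp = 5) {
  if (fmin <= 0 || fmax <= 0) stop("frequencies must be positive")
  if (fmin >= fmax) stop("fmin must be < fmax")
  if (n_freqs < 2) stop("n_freqs must be >= 2")
  freqs <- exp(seq(log(fmin), log(fmax), length.out = n_freqs))
  out <- list()
  for (lv in levels) for (fr in freqs) {
    comps <- data.frame(frequency = fr, onset = 0, duration = duration,
                        level = lv, ramp = ramp)
    out[[length(out) + 1L]] <- stimulus_spec(comps, f0 = NA_real_,
                                             total_level = lv)
  }
  out
}

# linear rise/fall envelope for one component, sampled at time t (seconds,
# relative to component onset); duration/ramp in seconds
.ramp_envelope <- function(t, duration, ramp) {
  env <- as.numeric(t >= 0 & t < duration)
  if (ramp > 0) {
    rise <- t >= 0 & t < ramp
    fall <- t >= (duration - ramp) & t < duration
    env[rise] <- t[rise] / ramp
    env[fall] <- (duration - t[fall]) / ramp
  }
  env
}

#' Synthesize the waveform of a stimulus
#'
#' Sums sine-phase components with linear on/off ramps. Per-component
#' amplitudes are equal and scaled so the coherent (sine-phase) peak of the
#' summed stimulus equals `peak_amplitude`; level labels are not used for
#' scaling (there is no physical calibration in software). The waveform
#' spans the earliest component onset to the latest offset.
#'
#' @param spec A `stimulus_spec`.
#' @param sample_rate Sampling rate in Hz; must exceed twice the highest
#'   component frequency.
#' @param peak_amplitude Full-scale peak of the summed sine-phase stimulus.
#' @param equal_mode `"amplitude"` (default) gives every component the same
#'   linear amplitude; `"db"` interprets per-component `level` columns as
#'   relative dB and scales the set so the coherent peak still equals
#'   `peak_amplitude`.
#' @return Numeric waveform with attributes `sample_rate` and `t0` (time in
#'   seconds of the first sample relative to the stimulus reference).
#' @export
synthesize_waveform <- function(spec, sample_rate = 192000,
                                peak_amplitude = 1,
                                equal_mode = c("amplitude", "db")) {
  equal_mode <- match.arg(equal_mode)
  stopifnot(inherits(spec, "stimulus_spec"))
  comps <- spec$components
  if (nrow(comps) == 0) {
    out <- numeric(0)
    attr(out, "sample_rate") <- sample_rate
    attr(out, "t0") <- 0
    return(out)
  }
  if (any(comps$frequency >= sample_rate / 2))
    stop("component at or above Nyquist; raise sample_rate")
  w <- if (equal_mode == "amplitude") rep(1, nrow(comps))
       else 10 ^ (comps$level / 20)
  w <- w * (peak_amplitude / sum(w))   # coherent sine-phase peak = sum of amps
  t_start <- min(comps$onset) / 1000
  t_end <- max(comps$onset + comps$duration) / 1000
  n <- ceiling((t_end - t_start) * sample_rate)
  t <- t_start + (seq_len(n) - 1L) / sample_rate
  x <- numeric(n)
  for (i in seq_len(nrow(comps))) {
    tc <- t - comps$onset[i] / 1000
    env <- .ramp_envelope(tc, comps$duration[i] / 1000, comps$ramp[i] / 1000)
    x <- x + w[i] * env * sin(2 * pi * comps$frequency[i] * tc)
  }
  attr(x, "sample_rate") <- sample_rate
  attr(x, "t0") <- t_start
  x
}

#' Build a blocked presentation schedule
#'
#' Each block contains every stimulus id exactly once, in an independent
#' seeded random order; blocks are concatenated.
#'
#' @param stim_ids Vector of stimulus identifiers.
#' @param n_blocks Number of blocks (default 5).
#' @param seed Integer seed.
#' @return A data frame with columns `block`, `trial`, `stim_id`, of class
#'   `presentation_schedule`.
#' @export
build_schedule <- function(stim_ids, n_blocks = 5, seed = 1) {
  if (length(stim_ids) == 0) stop("stimulus list is empty")
  if (n_blocks < 1) stop("n_blocks must be >= 1")
  orders <- withr::with_seed(as.integer(seed), {
    lapply(seq_len(n_blocks), function(b) sample(length(stim_ids)))
  })
  out <- do.call(rbind, lapply(seq_len(n_blocks), function(b) {
    data.frame(block = b, stim_id = stim_ids[orders[[b]]])
  }))
  out$trial <- seq_len(nrow(out))
  out <- out[, c("block", "trial", "stim_id")]
  class(out) <- c("presentation_schedule", "data.frame")
  out
}

#' Write a stimulus table to CSV
#'
#' One row per spec: id, F0, delta onset, shift group, jitter seed and the
#' component frequencies (semicolon-separated Hz).
#'
#' @param specs List of `stimulus_spec`.
#' @param path Output CSV path.
#' @return The table, invisibly.
#' @export
write_stimulus_table <- function(specs, path) {
  tab <- do.call(rbind, lapply(seq_along(specs), function(i) {
    s <- specs[[i]]
    data.frame(stim_id = i, F0_Hz = s$f0, delta_onset_ms = s$delta_onset,
               shift_group = s$shift_group, jitter_seed = s$jitter_seed,
               component_freqs = paste(s$components$frequency, collapse = ";"))
  }))
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(tab)
}
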