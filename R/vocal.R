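# F0 extraction from harmonic vocalizations: syllable detection on the
# amplitude envelope, spectrogram contour tracing, and harmonic template
# matching with the evaluation function
#   EF(F0) = sqrt( (1/n) * sum_i ((k_i * F0 - F_i) / F_i)^2 ),
# k_i = harmonic order of observed component frequency F_i. Segments with
# EF below threshold (default 0.5) are judged harmonic.

#' Detect syllables in a vocalization recording
#'
#' A syllable is emitted wherever the amplitude envelope exceeds
#' `detect_k` standard deviations of the baseline noise; its bounds are
#' extended outward to the `bound_k`-SD crossings, and `margin_ms` of context
#' is kept on both ends. Bursts whose bound-crossing intervals overlap after
#' margin addition are merged. The baseline SD is estimated from a leading
#' segment of the recording assumed free of events.
#'
#' @param audio Numeric waveform.
#' @param sample_rate Sampling rate in Hz (taken from the `sample_rate`
#'   attribute when present).
#' @param detect_k Detection threshold in baseline SD multiples (default 10).
#' @param bound_k Onset/offset threshold in SD multiples (default 5;
#'   must satisfy `detect_k >= bound_k > 0`).
#' @param margin_ms Margin kept around each syllable (default 15).
#' @param baseline_ms Length of the leading baseline segment used for the
#'   noise SD (default 100).
#' @param source_id Recording label carried on each syllable.
#' @return List of `syllable` objects: `onset`/`offset` (s, bound crossings),
#'   `samples` (slice incl. margins), `t0` (time of first sample), `source_id`.
#' @export
detect_syllables <- function(audio, sample_rate = attr(audio, "sample_rate"),
                             detect_k = 10, bound_k = 5, margin_ms = 15,
                             baseline_ms = 100, source_id = "audio") {
  if (length(audio) == 0) stop("audio is empty")
  if (is.null(sample_rate)) stop("sample_rate is required")
  if (!(detect_k >= bound_k && bound_k > 0))
    stop("need detect_k >= bound_k > 0")
  n <- length(audio)
  n_base <- min(n, max(2, round(baseline_ms / 1000 * sample_rate)))
  base_sd <- stats::sd(audio[seq_len(n_base)])
  if (!is.finite(base_sd) || base_sd == 0)
    stop("baseline segment has zero variance; cannot estimate noise SD")

  # envelope: block maxima of |x| at 0.25 ms resolution
  blk <- max(1L, round(sample_rate * 0.00025))
  nb <- ceiling(n / blk)
  absx <- c(abs(audio), rep(0, nb * blk - n))
  env <- apply(matrix(absx, nrow = blk), 2, max)

  above_bound <- env > bound_k * base_sd
  above_detect <- env > detect_k * base_sd
  r <- rle(above_bound)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  ivals <- NULL
  for (i in keep) {
    if (any(above_detect[starts[i]:ends[i]])) {
      ivals <- rbind(ivals, c((starts[i] - 1L) * blk + 1L,
                              min(n, ends[i] * blk)))
    }
  }
  if (is.null(ivals)) return(list())
  margin <- round(margin_ms / 1000 * sample_rate)
  lo <- pmax(1L, ivals[, 1] - margin)
  hi <- pmin(n, ivals[, 2] + margin)
  # merge overlapping margin-extended intervals
  o <- order(lo)
  lo <- lo[o]; hi <- hi[o]; b_lo <- ivals[o, 1]; b_hi <- ivals[o, 2]
  m_lo <- lo[1]; m_hi <- hi[1]; m_blo <- b_lo[1]; m_bhi <- b_hi[1]
  out <- list()
  flush <- function(l, h, bl, bh) {
    structure(list(onset = (bl - 1) / sample_rate,
                   offset = bh / sample_rate,
                   samples = structure(audio[l:h], sample_rate = sample_rate),
                   t0 = (l - 1) / sample_rate,
                   source_id = source_id),
              class = "syllable")
  }
  if (length(lo) > 1) {
    for (i in 2:length(lo)) {
      if (lo[i] <= m_hi) {
        m_hi <- max(m_hi, hi[i]); m_bhi <- max(m_bhi, b_hi[i])
      } else {
        out[[length(out) + 1L]] <- flush(m_lo, m_hi, m_blo, m_bhi)
        m_lo <- lo[i]; m_hi <- hi[i]; m_blo <- b_lo[i]; m_bhi <- b_hi[i]
      }
    }
  }
  out[[length(out) + 1L]] <- flush(m_lo, m_hi, m_blo, m_bhi)
  out
}

# columnwise moving average along rows (frequency axis), edge-truncated
.colwise_ma <- function(m, w) {
  if (w <= 1) return(m)
  w <- as.integer(w)
  if (w %% 2 == 0) w <- w + 1L
  h <- (w - 1L) %/% 2L
  nr <- nrow(m)
  padded <- rbind(m[rep(1L, h), , drop = FALSE], m,
                  m[rep(nr, h), , drop = FALSE])
  cs <- apply(padded, 2, cumsum)
  (cs[(w):(nr + w - 1L), , drop = FALSE] -
     rbind(0, cs[seq_len(nr - 1L), , drop = FALSE])) / w
}

# Hessian-based vesselness (bright ridges) over a small scale range.
# rows/cols are treated isotropically in pixel units; gamma = 2 scale
# normalization and the standard blobness constant beta.
.frangi <- function(m, scales = 1:3, beta = 0.5) {
  best <- matrix(0, nrow(m), ncol(m))
  for (s in scales) {
    g <- as.matrix(EBImage::gblur(m, sigma = s))
    nr <- nrow(g); nc <- ncol(g)
    if (nr < 3 || nc < 3) next
    fxx <- fyy <- fxy <- matrix(0, nr, nc)
    i <- 2:(nr - 1); j <- 2:(nc - 1)
    fxx[i, ] <- g[i + 1, ] - 2 * g[i, ] + g[i - 1, ]
    fyy[, j] <- g[, j + 1] - 2 * g[, j] + g[, j - 1]
    fxy[i, j] <- (g[i + 1, j + 1] - g[i + 1, j - 1] -
                    g[i - 1, j + 1] + g[i - 1, j - 1]) / 4
    fxx <- fxx * s^2; fyy <- fyy * s^2; fxy <- fxy * s^2
    tmp <- sqrt(((fxx - fyy) / 2)^2 + fxy^2)
    e1 <- (fxx + fyy) / 2 + tmp
    e2 <- (fxx + fyy) / 2 - tmp
    lam1 <- ifelse(abs(e1) <= abs(e2), e1, e2)  # smaller magnitude
    lam2 <- ifelse(abs(e1) <= abs(e2), e2, e1)
    s2 <- lam1^2 + lam2^2
    cc <- sqrt(max(s2)) / 2
    if (cc == 0) next
    rb2 <- ifelse(lam2 != 0, (lam1 / lam2)^2, 0)
    v <- exp(-rb2 / (2 * beta^2)) * (1 - exp(-s2 / (2 * cc^2)))
    v[lam2 > 0] <- 0  # dark ridges / background
    best <- pmax(best, v)
  }
  best
}

#' Trace spectral contours of one syllable
#'
#' Pipeline: short-time Fourier spectrogram (Hann window of twice the time
#' bin) -> per-time-bin moving-average subtraction along frequency ->
#' 3x3 median filter -> optional ridge (vesselness) enhancement -> keep
#' pixels above `power_threshold` of the syllable maximum -> flood-fill
#' connected components -> drop components shorter than `min_duration_ms`.
#' Component frequencies are refined per time bin by parabolic interpolation
#' of the log spectrum around the contour peak (set `refine = FALSE` to use
#' raw pixel positions).
#'
#' @param syllable A `syllable` object or a numeric waveform.
#' @param sample_rate Sampling rate in Hz (required for bare waveforms).
#' @param time_resolution_ms Spectrogram time bin in ms (0.5 or 1 typical).
#' @param detrend_window_hz Moving-average window along frequency (Hz).
#' @param power_threshold Fraction of the syllable maximum kept (default 0.05).
#' @param min_duration_ms Minimum component duration (default 7).
#' @param ridge_filter Apply the vesselness enhancement (default TRUE).
#' @param ridge_scales Pixel scales for the vesselness filter.
#' @param refine Parabolic frequency refinement (default TRUE).
#' @return List of `spectro_contour` objects, each with `time_s`, `freq_hz`,
#'   `power` per time bin plus the raw `pixels` and a `duration_ms` field.
#' @export
extract_contours <- function(syllable, sample_rate = NULL,
                             time_resolution_ms = 1, detrend_window_hz = 4000,
                             power_threshold = 0.05, min_duration_ms = 7,
                             ridge_filter = TRUE, ridge_scales = 1:3,
                             refine = TRUE) {
  if (inherits(syllable, "syllable")) {
    x <- syllable$samples
    sample_rate <- attr(x, "sample_rate")
    t0 <- syllable$t0
  } else {
    x <- syllable
    if (is.null(sample_rate)) sample_rate <- attr(x, "sample_rate")
    if (is.null(sample_rate)) stop("sample_rate is required")
    t0 <- 0
  }
  hop <- max(2L, round(time_resolution_ms / 1000 * sample_rate))
  win <- 2L * hop
  if (length(x) < win) return(list())
  sp <- signal::specgram(x, n = win, Fs = sample_rate,
                         window = signal::hanning(win), overlap = win - hop)
  mag <- abs(sp$S)
  pow <- mag^2
  if (max(pow) == 0) return(list())
  df <- sp$f[2] - sp$f[1]
  w_bins <- max(1, round(detrend_window_hz / df))
  det <- pow - .colwise_ma(pow, w_bins)
  det[det < 0] <- 0
  mx <- max(det)
  if (mx == 0) return(list())
  img <- det / mx
  img <- as.matrix(EBImage::medianFilter(img, size = 1))
  mask <- img > power_threshold * max(img)
  if (ridge_filter) {
    # vesselness keeps ridge-like pixels; intersect with the power mask so
    # the scale-space smoothing cannot bridge neighboring harmonics
    proc <- .frangi(img, scales = ridge_scales)
    if (max(proc) > 0) mask <- mask & (proc > power_threshold * max(proc))
  }
  lab <- as.matrix(EBImage::bwlabel(EBImage::Image(mask * 1)))
  out <- list()
  for (k in seq_len(max(lab))) {
    idx <- which(lab == k, arr.ind = TRUE)
    cols <- sort(unique(idx[, 2]))
    dur <- (max(cols) - min(cols) + 1) * time_resolution_ms
    if (dur < min_duration_ms) next
    time_s <- freq <- powr <- numeric(length(cols))
    for (ci in seq_along(cols)) {
      j <- cols[ci]
      rows <- idx[idx[, 2] == j, 1]
      r <- rows[which.max(pow[rows, j])]
      fr <- sp$f[r]
      if (refine && r > 1 && r < nrow(pow)) {
        a <- log(mag[r - 1, j] + 1e-300)
        b <- log(mag[r, j] + 1e-300)
        cc <- log(mag[r + 1, j] + 1e-300)
        den <- a - 2 * b + cc
        p <- if (den < 0) 0.5 * (a - cc) / den else 0
        p <- max(-0.5, min(0.5, p))
        fr <- fr + p * df
      }
      time_s[ci] <- t0 + sp$t[j]
      freq[ci] <- fr
      powr[ci] <- max(pow[rows, j])
    }
    out[[length(out) + 1L]] <- structure(
      list(time_s = time_s, freq_hz = freq, power = powr,
           pixels = data.frame(row = idx[, 1], col = idx[, 2]),
           duration_ms = dur, time_resolution_ms = time_resolution_ms),
      class = "spectro_contour")
  }
  out
}

#' Harmonic template evaluation function
#'
#' `EF(F0) = sqrt(mean(((k * F0 - F) / F)^2))` over observed component
#' frequencies `F`, with harmonic orders `k = max(1, round(F / F0))`.
#' EF is 0 iff every component sits exactly on an integer multiple of F0,
#' and is invariant to a common rescaling of all frequencies and F0.
#'
#' @param freqs Observed component frequencies in Hz (all > 0).
#' @param f0 Candidate fundamental in Hz.
#' @return The EF value (dimensionless, >= 0).
#' @export
ef_harmonic <- function(freqs, f0) {
  k <- pmax(1, round(freqs / f0))
  sqrt(mean(((k * f0 - freqs) / freqs)^2))
}

#' Match observed frequencies against a harmonic template grid
#'
#' Evaluates the harmonic evaluation function at every grid F0 and returns
#' the minimizing F0. Each component is assigned harmonic order
#' `max(1, round(F / F0))`; components mapping to the same order both stay
#' in the sum (the sum runs over observed components, not template orders).
#' Because every divisor of a fundamental reproduces its lattice exactly,
#' EF ties across subharmonics (EF(F0) = EF(F0/2) = ...); ties at the
#' minimum are broken toward the largest F0, which recovers the true
#' fundamental rather than a subharmonic.
#'
#' @param freqs Observed component frequencies in Hz.
#' @param f0_grid Candidate F0s in Hz (default 1-10 kHz in 50 Hz steps).
#' @param threshold Harmonicity threshold on EF (default 0.5).
#' @return List with `best_f0`, `ef`, `orders` (at the best F0),
#'   `is_harmonic` (`ef < threshold`) and `n` (component count).
#' @export
match_harmonic_template <- function(freqs, f0_grid = seq(1000, 10000, by = 50),
                                    threshold = 0.5) {
  if (length(freqs) == 0) stop("empty segment")
  if (any(freqs <= 0)) stop("all frequencies must be > 0")
  if (length(f0_grid) == 0) stop("empty F0 grid")
  efs <- vapply(f0_grid, function(f0) ef_harmonic(freqs, f0), numeric(1))
  emin <- min(efs)
  cand <- which(efs <= emin * (1 + 1e-9) + 1e-15)
  i <- cand[which.max(f0_grid[cand])]
  best <- f0_grid[i]
  list(best_f0 = best, ef = efs[i],
       orders = pmax(1, round(freqs / best)),
       is_harmonic = efs[i] < threshold, n = length(freqs))
}

#' Segment contours and estimate F0 per segment
#'
#' Splits the contours' common time span into segments of
#' `segment_width_ms`, collects the simultaneous contour frequencies in each
#' segment (power-weighted mean per contour), and runs
#' [match_harmonic_template()]. Segments whose EF meets the harmonicity
#' threshold are returned (set `keep_all = TRUE` to keep every matched
#' segment with its `is_harmonic` flag).
#'
#' @param contours List of `spectro_contour`.
#' @param segment_width_ms Segment width in ms (default 1.4).
#' @param f0_grid Candidate F0 grid in Hz.
#' @param ef_threshold Harmonicity threshold (default 0.5).
#' @param keep_all Keep segments failing the threshold too (default FALSE).
#' @return Data frame with `t_center_s`, `n_components`, `best_f0_hz`, `ef`,
#'   `is_harmonic`.
#' @export
segment_and_match <- function(contours, segment_width_ms = 1.4,
                              f0_grid = seq(1000, 10000, by = 50),
                              ef_threshold = 0.5, keep_all = FALSE) {
  empty <- data.frame(t_center_s = numeric(0), n_components = integer(0),
                      best_f0_hz = numeric(0), ef = numeric(0),
                      is_harmonic = logical(0))
  if (length(contours) == 0) return(empty)
  if (segment_width_ms <= 0) stop("segment_width_ms must be > 0")
  all_t <- unlist(lapply(contours, `[[`, "time_s"))
  w <- segment_width_ms / 1000
  edges <- seq(min(all_t), max(all_t) + w, by = w)
  rows <- list()
  for (s in seq_len(length(edges) - 1)) {
    lo <- edges[s]; hi <- edges[s + 1]
    comp <- numeric(0)
    for (ct in contours) {
      sel <- ct$time_s >= lo & ct$time_s < hi
      if (any(sel)) {
        pw <- ct$power[sel]
        comp <- c(comp, sum(ct$freq_hz[sel] * pw) / sum(pw))
      }
    }
    if (length(comp) == 0) next
    m <- match_harmonic_template(comp, f0_grid, threshold = ef_threshold)
    rows[[length(rows) + 1L]] <- data.frame(
      t_center_s = (lo + hi) / 2, n_components = m$n, best_f0_hz = m$best_f0,
      ef = m$ef, is_harmonic = m$is_harmonic)
  }
  if (length(rows) == 0) return(empty)
  out <- do.call(rbind, rows)
  if (!keep_all) out <- out[out$is_harmonic, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summarize F0 usage across harmonic segments
#'
#' Probability-normalized F0 histogram plus the 10th/50th/90th percentiles
#' (the central 80% interval and median of F0 usage).
#'
#' @param segments Data frame from [segment_and_match()] (or a numeric
#'   vector of F0s).
#' @param bin_edges Histogram bin edges in Hz.
#' @return List with `histogram` (data frame `lo`, `hi`, `mid`, `prob`),
#'   `median`, `q10`, `q90`, `n`. With no harmonic segments returns `n = 0`
#'   and `NA` summaries.
#' @export
f0_usage_summary <- function(segments, bin_edges = seq(0, 10000, by = 250)) {
  f0s <- if (is.data.frame(segments)) {
    segments$best_f0_hz[segments$is_harmonic]
  } else as.numeric(segments)
  if (length(f0s) == 0) {
    return(list(histogram = NULL, median = NA_real_, q10 = NA_real_,
                q90 = NA_real_, n = 0L))
  }
  h <- graphics::hist(f0s, breaks = bin_edges, plot = FALSE)
  q <- stats::quantile(f0s, c(0.1, 0.5, 0.9), names = FALSE)
  list(histogram = data.frame(lo = h$breaks[-length(h$breaks)],
                              hi = h$breaks[-1], mid = h$mids,
                              prob = h$counts / sum(h$counts)),
       median = q[2], q10 = q[1], q90 = q[3], n = length(f0s))
}

#' Run the full vocal F0 pipeline on a recording
#'
#' Detects syllables, traces contours in each, and returns all harmonic
#' segments pooled across syllables.
#'
#' @param audio Waveform with a `sample_rate` attribute (or pass
#'   `sample_rate`).
#' @param sample_rate Sampling rate in Hz.
#' @param ... Passed to [extract_contours()] and [segment_and_match()]
#'   (matched by name).
#' @inheritParams detect_syllables
#' @param f0_grid,ef_threshold,segment_width_ms See [segment_and_match()].
#' @return Data frame of harmonic segments (one row per segment) with a
#'   `syllable` index column.
#' @export
analyze_vocalization <- function(audio,
                                 sample_rate = attr(audio, "sample_rate"),
                                 detect_k = 10, bound_k = 5, margin_ms = 15,
                                 baseline_ms = 100,
                                 segment_width_ms = 1.4,
                                 f0_grid = seq(1000, 10000, by = 50),
                                 ef_threshold = 0.5, ...) {
  syls <- detect_syllables(audio, sample_rate, detect_k = detect_k,
                           bound_k = bound_k, margin_ms = margin_ms,
                           baseline_ms = baseline_ms)
  segs <- list()
  for (i in seq_along(syls)) {
    ct <- extract_contours(syls[[i]], ...)
    sg <- segment_and_match(ct, segment_width_ms = segment_width_ms,
                            f0_grid = f0_grid, ef_threshold = ef_threshold)
    if (nrow(sg) > 0) {
      sg$syllable <- i
      segs[[length(segs) + 1L]] <- sg
    }
  }
  if (length(segs) == 0) {
    return(data.frame(t_center_s = numeric(0), n_components = integer(0),
                      best_f0_hz = numeric(0), ef = numeric(0),
                      is_harmonic = logical(0), syllable = integer(0)))
  }
  out <- do.call(rbind, segs)
  rownames(out) <- NULL
  out
}
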