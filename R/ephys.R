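# Spike-train PSTH analysis, optogenetic suppression kinetics, and
# behavioral psychometrics (log-modulus logistic fits, d-prime).

#' Peristimulus time histogram
#'
#' Trial-averaged firing rate per uniform bin (half-open `[lo, hi)`
#' convention), with optional baseline subtraction and an optional centered
#' moving average kept as a separate `smoothed` field (for display only,
#' not used by quantification).
#'
#' @param spikes List of per-trial spike time vectors (ms).
#' @param bin_ms Bin width in ms (default 10).
#' @param range_ms Two-element time range in ms.
#' @param baseline_ms Optional window (e.g. `c(-200, 0)`) whose mean rate
#'   is subtracted.
#' @param smooth_bins Width of the moving average (odd; 0 disables).
#' @return List of class `psth`: `edges`, `mid`, `rate` (Hz, baseline
#'   subtracted if requested), `counts` (raw summed counts), `smoothed`,
#'   `n_trials`, `bin_ms`, `baseline_rate`.
#' @export
compute_psth <- function(spikes, bin_ms = 10, range_ms = c(-200, 400),
                         baseline_ms = NULL, smooth_bins = 0) {
  if (bin_ms <= 0) stop("bin_ms must be > 0")
  edges <- seq(range_ms[1], range_ms[2], by = bin_ms)
  nb <- length(edges) - 1L
  counts <- integer(nb)
  for (tr in spikes) {
    idx <- findInterval(tr, edges, left.open = FALSE)
    idx <- idx[idx >= 1 & idx <= nb & tr < edges[nb + 1L]]
    if (length(idx) > 0) counts <- counts + tabulate(idx, nbins = nb)
  }
  n_trials <- length(spikes)
  rate <- counts / n_trials / (bin_ms / 1000)
  base_rate <- 0
  if (!is.null(baseline_ms)) {
    mid <- edges[-length(edges)] + bin_ms / 2
    in_base <- mid >= baseline_ms[1] & mid < baseline_ms[2]
    base_rate <- mean(rate[in_base])
    rate <- rate - base_rate
  }
  smoothed <- NULL
  if (smooth_bins > 1) {
    smoothed <- as.numeric(stats::filter(rate, rep(1 / smooth_bins,
                                                   smooth_bins),
                                         sides = 2))
  }
  structure(list(edges = edges, mid = edges[-length(edges)] + bin_ms / 2,
                 rate = rate, counts = counts, smoothed = smoothed,
                 n_trials = n_trials, bin_ms = bin_ms,
                 baseline_rate = base_rate),
            class = "psth")
}

#' Evoked response magnitude from a PSTH
#'
#' Sum of the positive-going PSTH bins inside the window (default
#' 0-150 ms after sound onset), optionally normalized to a maximum control
#' response.
#'
#' @param psth A [compute_psth()] result.
#' @param window_ms Two-element window in ms.
#' @param normalize_to Optional normalizer (e.g. maximum control response);
#'   `NA` is returned if it is zero.
#' @return Scalar evoked magnitude.
#' @export
evoked_response <- function(psth, window_ms = c(0, 150),
                            normalize_to = NULL) {
  sel <- psth$mid >= window_ms[1] & psth$mid < window_ms[2]
  if (!any(sel)) stop("window outside PSTH range")
  v <- sum(pmax(psth$rate[sel], 0))
  if (!is.null(normalize_to)) {
    if (normalize_to == 0) return(NA_real_)
    v <- v / normalize_to
  }
  v
}

#' Optogenetic suppression kinetics
#'
#' Fits `r(t) = 1` for `t < latency` and
#' `r(t) = floor + (1 - floor) * exp(-(t - latency)/tau)` for
#' `t >= latency` to a fine-binned PSTH normalized to the pre-LED rate,
#' by least squares with the latency profiled over a grid. Non-decaying
#' input returns a failure sentinel with diagnostics instead of a fit.
#'
#' @param time_ms Bin centers in ms (LED onset at 0).
#' @param norm_rate Normalized rate per bin (pre-LED level 1).
#' @param latency_grid Candidate latencies in ms.
#' @param decay_criterion The fit is declared a failure when the mean
#'   normalized rate late in the window exceeds this (default 0.8).
#' @return List with `ok`, `latency_ms`, `tau_ms`, `floor`, `rmse`. On
#'   failure `ok = FALSE` and the parameters are `NA`.
#' @export
suppression_kinetics <- function(time_ms, norm_rate,
                                 latency_grid = seq(0, 20, by = 0.5),
                                 decay_criterion = 0.8) {
  stopifnot(length(time_ms) == length(norm_rate))
  post <- time_ms > max(time_ms) * 0.6
  fail <- list(ok = FALSE, latency_ms = NA_real_, tau_ms = NA_real_,
               floor = NA_real_, rmse = NA_real_)
  if (mean(norm_rate[post]) > decay_criterion) {
    fail$rmse <- sqrt(mean((norm_rate - 1)^2))
    return(fail)
  }
  best <- NULL
  for (lat in latency_grid) {
    sel <- time_ms >= lat
    if (sum(sel) < 5) next
    tt <- time_ms[sel] - lat
    yy <- norm_rate[sel]
    fit <- tryCatch(
      minpack.lm::nlsLM(yy ~ fl + (1 - fl) * exp(-tt / tau),
                        start = list(fl = max(min(yy), 0.01), tau = 10),
                        lower = c(fl = 0, tau = 0.1),
                        upper = c(fl = 1, tau = max(time_ms) * 10),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    co <- stats::coef(fit)
    pred <- ifelse(time_ms < lat, 1,
                   co["fl"] + (1 - co["fl"]) *
                     exp(-(time_ms - lat) / co["tau"]))
    sse <- sum((norm_rate - pred)^2)
    if (is.null(best) || sse < best$sse) {
      best <- list(lat = lat, fl = unname(co["fl"]),
                   tau = unname(co["tau"]), sse = sse)
    }
  }
  if (is.null(best)) return(fail)
  list(ok = TRUE, latency_ms = best$lat, tau_ms = best$tau,
       floor = best$fl, rmse = sqrt(best$sse / length(norm_rate)))
}

#' Signal-detection d-prime
#'
#' `d' = z(hit) - z(fa)` with `z` the standard normal quantile
#' (equal-variance Gaussian model); rates are clipped into
#' `[clip, 1 - clip]` to keep the quantiles finite.
#'
#' @param hit_rate,fa_rate Hit and false-alarm rates in `[0, 1]`.
#' @param clip Clipping bound in `(0, 0.5)`; the conventional choice is
#'   `1/(2N)` for `N` trials per condition.
#' @return d-prime (vectorized).
#' @export
dprime <- function(hit_rate, fa_rate, clip = 0.005) {
  stopifnot(clip > 0, clip < 0.5)
  h <- pmin(pmax(hit_rate, clip), 1 - clip)
  f <- pmin(pmax(fa_rate, clip), 1 - clip)
  stats::qnorm(h) - stats::qnorm(f)
}

#' Log-modulus transform
#'
#' `sign(x) * log10(1 + |x|)`: symmetric, compresses large magnitudes and
#' keeps 0 at 0. Used to linearize the Δonset axis for psychometric fits.
#'
#' @param x Numeric.
#' @return Transformed values.
#' @export
log_modulus <- function(x) sign(x) * log10(1 + abs(x))

# drop leading/trailing blocks where the animal stopped licking targets:
# any leading (trailing) run of >= miss_run consecutive misses on target
# (delta == 0) trials removes all session trials up to (from) its end
.trim_unmotivated <- function(trials, miss_run = 10) {
  tgt <- which(trials$delta_onset_ms == 0)
  if (length(tgt) == 0) return(trials)
  miss <- !trials$lick[tgt]
  r <- rle(miss)
  keep_lo <- 1L
  keep_hi <- nrow(trials)
  if (r$values[1] && r$lengths[1] >= miss_run) {
    last_missed <- tgt[r$lengths[1]]
    keep_lo <- last_missed + 1L
  }
  if (r$values[length(r$values)] && r$lengths[length(r$values)] >= miss_run) {
    first_missed <- tgt[length(tgt) - r$lengths[length(r$values)] + 1L]
    keep_hi <- first_missed - 1L
  }
  if (keep_lo > keep_hi) return(trials[0, , drop = FALSE])
  trials[keep_lo:keep_hi, , drop = FALSE]
}

#' Fit psychometric functions to a discrimination session
#'
#' Response (lick) rate against Δonset is fit per condition (control and
#' LED) with a logistic on the log-modulus scale,
#' `P(lick) = plogis(slope * (x - midpoint))`, by binomial maximum
#' likelihood. The half-max Δonset (behavioral threshold) is the
#' back-transformed `|Δ|` at 50% response. Sessions are trimmed of leading
#' and trailing unmotivated blocks and capped at the first `first_n`
#' trials.
#'
#' @param trials Data frame with `delta_onset_ms`, `lick`, `led` columns.
#' @param first_n Analyze only the first `first_n` trials after trimming
#'   (default 250; `Inf` keeps all).
#' @param miss_run Consecutive target misses defining an unmotivated block
#'   (default 10).
#' @return List of class `psychometric_fit`: per condition (`control`,
#'   `led` when present) `midpoint` (log-modulus units), `slope`,
#'   `half_max_delta_ms`, `rates` (per-Δonset response rates), `ok`; plus
#'   `broadening_pct` when both conditions are fit
#'   (`(half_led - half_ctrl) / half_ctrl * 100`).
#' @export
fit_psychometric <- function(trials, first_n = 250, miss_run = 10) {
  stopifnot(all(c("delta_onset_ms", "lick") %in% names(trials)))
  if (!"led" %in% names(trials)) trials$led <- FALSE
  trials <- .trim_unmotivated(trials, miss_run = miss_run)
  if (nrow(trials) > first_n) trials <- trials[seq_len(first_n), ]
  fit_one <- function(tt) {
    res <- list(ok = FALSE, midpoint = NA_real_, slope = NA_real_,
                half_max_delta_ms = NA_real_, rates = NULL)
    if (length(unique(tt$delta_onset_ms)) < 2) return(res)
    res$rates <- stats::aggregate(lick ~ delta_onset_ms, tt, mean)
    if (all(tt$lick) || !any(tt$lick)) return(res)
    x <- log_modulus(tt$delta_onset_ms)
    g <- tryCatch(stats::glm(tt$lick ~ x, family = stats::binomial()),
                  warning = function(w)
                    suppressWarnings(stats::glm(tt$lick ~ x,
                                                family = stats::binomial())),
                  error = function(e) NULL)
    if (is.null(g)) return(res)
    b <- stats::coef(g)
    if (!all(is.finite(b)) || b[2] == 0) return(res)
    res$slope <- unname(b[2])
    res$midpoint <- unname(-b[1] / b[2])
    res$half_max_delta_ms <- 10^abs(res$midpoint) - 1
    res$ok <- TRUE
    res
  }
  out <- list(control = fit_one(trials[!trials$led, , drop = FALSE]))
  if (any(trials$led)) out$led <- fit_one(trials[trials$led, , drop = FALSE])
  if (!is.null(out$led) && out$control$ok && out$led$ok) {
    out$broadening_pct <- (out$led$half_max_delta_ms -
                             out$control$half_max_delta_ms) /
      out$control$half_max_delta_ms * 100
  }
  class(out) <- "psychometric_fit"
  out
}
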