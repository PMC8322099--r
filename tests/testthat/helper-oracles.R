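# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Exhaustive EF minimization: for each grid F0 every component is assigned
# the error-minimizing harmonic order by explicit enumeration of orders.
ef_oracle <- function(freqs, f0_grid) {
  per_f0 <- vapply(f0_grid, function(f0) {
    terms <- vapply(freqs, function(fr) {
      ks <- seq_len(ceiling(fr / f0) + 2)
      min(((ks * f0 - fr) / fr)^2)
    }, numeric(1))
    sqrt(mean(terms))
  }, numeric(1))
  min(per_f0)
}

# Trapezoidal integration oracle.
trapz_oracle <- function(y, dt) {
  s <- 0
  for (i in seq_len(length(y) - 1)) s <- s + (y[i] + y[i + 1]) / 2 * dt
  s
}

# Brute-force syllable bounds: first/last sample index with |x| > k * sd.
bounds_oracle <- function(x, k, sd0, from, to) {
  idx <- which(abs(x[from:to]) > k * sd0) + from - 1L
  c(min(idx), max(idx))
}

# Build a trial-aligned dF/F array (trials x frames) with given baseline
# and response segments, for significance-rule tests.
make_aligned <- function(trial_resp, n_base = 30, frame_rate = 30,
                         base_noise = 0) {
  n_tr <- length(trial_resp)
  n_resp <- length(trial_resp[[1]])
  m <- matrix(0, n_tr, n_base + n_resp)
  if (base_noise > 0) {
    m[, seq_len(n_base)] <- stats::rnorm(n_tr * n_base, sd = base_noise)
  }
  for (i in seq_len(n_tr)) m[i, (n_base + 1):(n_base + n_resp)] <- trial_resp[[i]]
  attr(m, "onset_index") <- n_base + 1L
  attr(m, "frame_rate") <- frame_rate
  m
}

# Small helper: build the concatenated population matrix and per-pair truth
# labels from a synthetic session (own-F0 pairs carry the planted archetype,
# cross-F0 pairs are labeled "noise").
pm_with_truth <- function(pop, rt) {
  stim <- rt$stim_table
  cells <- pop$truth$cells
  cols <- list()
  labs <- NULL
  for (f0 in unique(stim$f0)) {
    idx <- which(stim$f0 == f0)
    pm <- build_population_matrix(rt$amplitude[, idx], rt$significant[, idx])
    cols[[as.character(f0)]] <- pm$matrix
    labs <- c(labs, ifelse(cells$f0[pm$included] == f0,
                           cells$archetype[pm$included], "noise"))
  }
  list(matrix = do.call(cbind, cols), labels = labs)
}
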