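# Noise-correlation computation between simultaneously recorded ROIs and
# matched-control pair construction for subnetwork detection.

#' Pairwise noise correlation
#'
#' Per ROI, the per-stimulus mean amplitude is subtracted from each trial
#' amplitude; the residuals are concatenated across stimuli and trials and
#' the Pearson correlation is taken per ROI pair. Adding a per-stimulus
#' constant to one ROI leaves the result unchanged. Pairs involving a
#' zero-variance residual vector get `NA`.
#'
#' @param trial_amps ROIs x stimuli x trials array of response amplitudes
#'   (e.g. `trial_amps` of a [response_table()]).
#' @return ROI x ROI correlation matrix (diagonal 1).
#' @export
noise_correlation <- function(trial_amps) {
  stopifnot(length(dim(trial_amps)) == 3)
  n_cell <- dim(trial_amps)[1]
  res <- apply(trial_amps, 1, function(m) {
    # m: stimuli x trials; subtract per-stimulus mean, concatenate
    as.vector(m - rowMeans(m, na.rm = TRUE))
  })  # observations x cells
  res <- res[stats::complete.cases(res), , drop = FALSE]
  suppressWarnings(stats::cor(res))
}

#' Matched control pairs for noise-correlation comparisons
#'
#' Distance mode: per target pair, `n_controls` random same-field pairs
#' whose spatial distance is within `tol` (fractional) of the target
#' distance; the tolerance doubles (up to `max_widen` times) when too few
#' candidates exist. SD / SNR mode: for each ROI of a target pair the two
#' ROIs with the closest statistic are found, and the controls are the
#' 2 x 2 cross combinations.
#'
#' @param pairs Two-column matrix/data frame of target ROI index pairs.
#' @param coords ROI coordinates (µm), needed for distance mode.
#' @param stat Per-ROI statistic (baseline SD or SNR), needed for sd/snr
#'   mode.
#' @param mode `"distance"`, `"sd"`, or `"snr"`.
#' @param n_controls Controls per target pair in distance mode (default 3).
#' @param tol Initial fractional distance tolerance (default 0.1).
#' @param max_widen Times the tolerance may double (default 2).
#' @param strict Error instead of widening past `max_widen` (default
#'   FALSE: the pair is dropped with a message).
#' @param seed Integer seed for control sampling.
#' @return Data frame `roi_a`, `roi_b`, `target_pair` (index into `pairs`),
#'   `mode`.
#' @export
matched_control_pairs <- function(pairs, coords = NULL, stat = NULL,
                                  mode = c("distance", "sd", "snr"),
                                  n_controls = 3, tol = 0.1, max_widen = 2,
                                  strict = FALSE, seed = 1) {
  mode <- match.arg(mode)
  pairs <- as.matrix(pairs)
  out <- list()
  if (mode == "distance") {
    if (is.null(coords)) stop("coords required for distance matching")
    dmat <- as.matrix(stats::dist(coords))
    n <- nrow(coords)
    cand <- which(upper.tri(dmat), arr.ind = TRUE)
    cand_d <- dmat[cand]
    picks <- withr::with_seed(as.integer(seed), {
      lapply(seq_len(nrow(pairs)), function(i) {
        td <- dmat[pairs[i, 1], pairs[i, 2]]
        tl <- tol
        for (wd in 0:max_widen) {
          ok <- which(abs(cand_d - td) <= tl * td &
                        !(cand[, 1] == min(pairs[i, ]) &
                            cand[, 2] == max(pairs[i, ])))
          if (length(ok) >= n_controls) {
            return(ok[sample.int(length(ok), n_controls)])
          }
          tl <- tl * 2
        }
        if (strict) stop("insufficient distance-matched candidates")
        message("dropping target pair ", i, ": too few matched candidates")
        integer(0)
      })
    })
    for (i in seq_along(picks)) {
      if (length(picks[[i]]) > 0) {
        out[[length(out) + 1L]] <- data.frame(
          roi_a = cand[picks[[i]], 1], roi_b = cand[picks[[i]], 2],
          target_pair = i, mode = mode)
      }
    }
  } else {
    if (is.null(stat)) stop("stat required for sd/snr matching")
    nearest2 <- function(roi, exclude) {
      pool <- setdiff(seq_along(stat), c(roi, exclude))
      pool[order(abs(stat[pool] - stat[roi]))[1:2]]
    }
    for (i in seq_len(nrow(pairs))) {
      a <- pairs[i, 1]; b <- pairs[i, 2]
      ca <- nearest2(a, b)
      cb <- nearest2(b, c(a, ca))  # disjoint sets: 2 x 2 valid combinations
      combos <- expand.grid(roi_a = ca, roi_b = cb)
      combos <- combos[combos$roi_a != combos$roi_b, , drop = FALSE]
      if (nrow(combos) > 0) {
        out[[length(out) + 1L]] <- data.frame(combos, target_pair = i,
                                              mode = mode)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(roi_a = integer(0), roi_b = integer(0),
                      target_pair = integer(0), mode = character(0)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Spatial distance statistics per cell category
#'
#' Pairwise Euclidean distances within each category of cell pairs (e.g.
#' all cells, same-F0 coincidence-preferring, across-F0), with empirical
#' CDFs and rank-sum comparisons against the first category.
#'
#' @param coords ROI coordinates (µm).
#' @param groups Named list of index vectors; each entry defines a
#'   category whose within-group pairwise distances are collected. Entries
#'   may also be two-column matrices of explicit pairs.
#' @return List with `distances` (named list), `ecdf` (named list of
#'   functions), `tests` (rank-sum p-values vs the first category).
#' @export
spatial_distance_stats <- function(coords, groups) {
  dmat <- as.matrix(stats::dist(coords))
  dists <- lapply(groups, function(g) {
    if (is.matrix(g) || is.data.frame(g)) {
      g <- as.matrix(g)
      dmat[cbind(g[, 1], g[, 2])]
    } else {
      if (length(g) < 2) return(NA_real_)
      dmat[g, g][upper.tri(matrix(0, length(g), length(g)))]
    }
  })
  tests <- NULL
  ref <- dists[[1]]
  if (length(dists) > 1) {
    tests <- vapply(dists[-1], function(d) {
      if (all(is.na(d)) || all(is.na(ref))) return(NA_real_)
      suppressWarnings(stats::wilcox.test(d, ref)$p.value)
    }, numeric(1))
  }
  list(distances = dists,
       ecdf = lapply(dists, function(d) {
         if (all(is.na(d))) NULL else stats::ecdf(d)
       }),
       tests = tests)
}
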