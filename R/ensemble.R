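# Population-level geometry and clustering: normalized response matrices,
# PCA of condition ensembles, pairwise distance/correlation across onset
# shifts, NMF clustering of response profiles, and cluster-overlap
# permutation tests.

#' Build a normalized population response matrix
#'
#' Conditions x ROIs matrix of response amplitudes: nonsignificant entries
#' are forced to 0 (de-noising), each ROI is normalized to its maximum
#' across the Δonset conditions, and only ROIs with a significant
#' excitatory response in at least one condition are included. ROIs whose
#' normalizer is zero are excluded and counted.
#'
#' @param amps ROIs x conditions amplitude matrix.
#' @param sig Matching logical significance matrix.
#' @param condition_labels Labels for the conditions (e.g. Δonsets).
#' @param roi_labels Optional data frame of per-ROI labels (area, F0,
#'   mouse), subset to the included ROIs.
#' @return A list of class `population_matrix`: `matrix` (conditions x
#'   included ROIs, entries in `[0, 1]`), `conditions`, `roi_labels`,
#'   `included` (indices into the input ROIs), `n_excluded`.
#' @export
build_population_matrix <- function(amps, sig,
                                    condition_labels = colnames(amps),
                                    roi_labels = NULL) {
  stopifnot(all(dim(amps) == dim(sig)))
  a <- pmax(amps, 0)
  a[!sig] <- 0
  keep <- which(apply(sig, 1, any) & apply(a, 1, max) > 0)
  m <- t(a[keep, , drop = FALSE] / apply(a[keep, , drop = FALSE], 1, max))
  if (!is.null(roi_labels)) roi_labels <- roi_labels[keep, , drop = FALSE]
  structure(list(matrix = m, conditions = condition_labels,
                 roi_labels = roi_labels, included = keep,
                 n_excluded = sum(apply(sig, 1, any)) - length(keep)),
            class = "population_matrix")
}

#' Project condition ensembles onto principal components
#'
#' Conditions are the observations and ROIs the variables; the matrix is
#' mean-centered and the top components returned in variance order. With
#' rank-deficient input, fewer components are returned.
#'
#' @param pm A `population_matrix` (or a plain conditions x ROIs matrix).
#' @param n_components Number of components requested (default 3).
#' @return List with `scores` (conditions x components), `explained`
#'   (variance fractions), `rotation`.
#' @export
pca_project <- function(pm, n_components = 3) {
  m <- if (inherits(pm, "population_matrix")) pm$matrix else pm
  if (nrow(m) < 2) stop("need >= 2 conditions")
  p <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  k <- min(n_components, sum(p$sdev > 1e-12), ncol(p$x))
  k <- max(k, 1L)
  tot <- sum(p$sdev^2)
  expl <- if (tot > 0) (p$sdev^2 / tot)[seq_len(k)] else rep(0, k)
  list(scores = p$x[, seq_len(k), drop = FALSE], explained = expl,
       rotation = p$rotation[, seq_len(k), drop = FALSE])
}

#' Pairwise ensemble geometry across conditions
#'
#' Euclidean distances between condition rows divided by the square root of
#' the ROI count (so distances are comparable across population sizes), and
#' Pearson correlations across ROIs. Per-condition means exclude the
#' diagonal.
#'
#' @param pm A `population_matrix` or conditions x ROIs matrix.
#' @return List with `distance`, `correlation` (condition x condition
#'   matrices), `mean_distance`, `mean_correlation` (per condition,
#'   off-diagonal means).
#' @export
pairwise_geometry <- function(pm) {
  m <- if (inherits(pm, "population_matrix")) pm$matrix else pm
  if (nrow(m) < 2) stop("need >= 2 conditions")
  d <- as.matrix(stats::dist(m)) / sqrt(ncol(m))
  r <- suppressWarnings(stats::cor(t(m)))
  off <- function(x) {
    diag(x) <- NA
    rowMeans(x, na.rm = TRUE)
  }
  list(distance = d, correlation = r, mean_distance = off(d),
       mean_correlation = off(r))
}

# Frobenius NMF by multiplicative updates; returns the factorization with
# the lowest reconstruction error over n_restarts random nonnegative inits
.nmf <- function(x, k, n_restarts = 100, seed = 1, max_iter = 500,
                 tol = 1e-7) {
  if (any(x < 0)) stop("matrix must be nonnegative")
  if (max(x) == 0) stop("matrix is all zero")
  eps <- .Machine$double.eps
  best <- NULL
  seeds <- withr::with_seed(as.integer(seed),
                            sample.int(.Machine$integer.max, n_restarts))
  for (rs in seq_len(n_restarts)) {
    res <- withr::with_seed(seeds[rs], {
      w <- matrix(stats::runif(nrow(x) * k), nrow(x), k)
      h <- matrix(stats::runif(k * ncol(x)), k, ncol(x))
      err_prev <- Inf
      for (it in seq_len(max_iter)) {
        h <- h * (crossprod(w, x)) / (crossprod(w) %*% h + eps)
        w <- w * (x %*% t(h)) / (w %*% tcrossprod(h) + eps)
        if (it %% 10 == 0) {
          err <- sum((x - w %*% h)^2)
          if (err_prev - err < tol * max(err, 1)) break
          err_prev <- err
        }
      }
      list(w = w, h = h, err = sum((x - w %*% h)^2))
    })
    if (is.null(best) || res$err < best$err) best <- res
  }
  best
}

#' Cluster response profiles by non-negative matrix factorization
#'
#' Factorizes the conditions x pairs matrix into `k` nonnegative templates
#' (best of `n_restarts` random restarts by reconstruction error). Each
#' ROI-sound pair is assigned to the cluster of its dominating coefficient;
#' pairs whose dominant coefficient fraction is below 0.5 are labeled
#' `"others"`. Template identities (negative_shift / positive_shift /
#' coincidence) are read off the Δonset location of each template's
#' maximum; ties break toward coincidence.
#'
#' @param pm A `population_matrix` (conditions x pairs) or plain matrix.
#' @param delta_onsets Δonset (ms) of each condition row.
#' @param k Number of clusters (default 3).
#' @param n_restarts NMF restarts (default 100).
#' @param seed Master seed spawning the per-restart seeds.
#' @param others_cutoff Dominant-fraction cutoff (default 0.5).
#' @return List of class `cluster_assignment`: `cluster` (factor per pair),
#'   `dominant_fraction`, `templates` (conditions x k), `template_labels`,
#'   `coefficients` (k x pairs), `recon_error`.
#' @export
nmf_cluster_assign <- function(pm, delta_onsets, k = 3, n_restarts = 100,
                               seed = 1, others_cutoff = 0.5) {
  m <- if (inherits(pm, "population_matrix")) pm$matrix else pm
  stopifnot(length(delta_onsets) == nrow(m))
  fit <- .nmf(m, k, n_restarts = n_restarts, seed = seed)
  # label templates by the Δonset at their maximum
  lab <- character(k)
  for (j in seq_len(k)) {
    peak_idx <- which(fit$w[, j] == max(fit$w[, j]))
    d <- delta_onsets[peak_idx]
    lab[j] <- if (any(d == 0)) "coincidence"
      else if (d[which.max(abs(d))] < 0) "negative_shift"
      else "positive_shift"
  }
  frac <- apply(fit$h, 2, function(co) {
    s <- sum(co)
    if (s == 0) 0 else max(co) / s
  })
  dominant <- apply(fit$h, 2, which.max)
  cluster <- ifelse(frac < others_cutoff, "others", lab[dominant])
  structure(list(cluster = factor(cluster,
                                  levels = c("negative_shift",
                                             "positive_shift", "coincidence",
                                             "others")),
                 dominant_fraction = frac, templates = fit$w,
                 template_labels = lab, coefficients = fit$h,
                 recon_error = fit$err),
            class = "cluster_assignment")
}

#' Fraction of coincidence-preferring pairs per group
#'
#' The denominator is all clustered pairs including `"others"` (the
#' alternative excluding `"others"` is available). With two groups, a
#' chi-square proportion test is run.
#'
#' @param assign A `cluster_assignment` (or factor of cluster labels).
#' @param groups Grouping factor (e.g. cortical area) over the same pairs.
#' @param include_others Count `"others"` in the denominator (default
#'   TRUE).
#' @return List with `fraction` (per group), `counts`, `test` (htest or
#'   NULL).
#' @export
coincidence_fraction <- function(assign, groups, include_others = TRUE) {
  cl <- if (inherits(assign, "cluster_assignment")) assign$cluster
        else as.factor(assign)
  groups <- as.factor(groups)
  stopifnot(length(cl) == length(groups))
  if (!include_others) {
    keep <- cl != "others"
    cl <- cl[keep]; groups <- droplevels(groups[keep])
  }
  tab <- table(groups, coincidence = cl == "coincidence")
  frac <- sapply(levels(groups), function(g) {
    n <- sum(groups == g)
    if (n == 0) NA_real_ else sum(cl[groups == g] == "coincidence") / n
  })
  test <- NULL
  if (nlevels(groups) == 2 && all(rowSums(tab) > 0)) {
    test <- suppressWarnings(stats::chisq.test(tab))
  }
  list(fraction = frac, counts = tab, test = test)
}

#' Permutation test for cluster-membership overlap
#'
#' Observed statistic: number of cells belonging to two or more membership
#' sets (e.g. coincidence-preferring for multiple F0s). Null: each set's
#' labels are reassigned uniformly at random over the cell universe,
#' preserving set sizes (stratified within `strata` when given, e.g. per
#' mouse). `p = (1 + #(null >= observed)) / (1 + n_perm)`.
#'
#' @param sets List of membership vectors (cell ids).
#' @param universe Vector of all candidate cell ids.
#' @param n_perm Number of permutations (default 10000).
#' @param seed Integer seed.
#' @param strata Optional factor over `universe`; shuffles preserve per-set
#'   sizes within each stratum.
#' @return List with `observed`, `null` (counts per permutation), `p`.
#' @export
overlap_permutation_test <- function(sets, universe, n_perm = 10000,
                                     seed = 1, strata = NULL) {
  if (length(universe) == 0) stop("empty cell universe")
  if (length(sets) < 2) stop("need >= 2 membership sets")
  n_univ <- length(universe)
  # work on integer indices into the universe so the null loop can use
  # tabulate() rather than table()
  idx_sets <- lapply(sets, function(s) unique(match(s, universe)))
  if (any(vapply(idx_sets, anyNA, logical(1))))
    stop("set members outside the universe")
  count_overlap <- function(ss) {
    sum(tabulate(unlist(ss), nbins = n_univ) >= 2L)
  }
  observed <- count_overlap(idx_sets)
  if (is.null(strata)) {
    sizes <- lengths(idx_sets)
    null <- withr::with_seed(as.integer(seed), {
      vapply(seq_len(n_perm), function(i) {
        count_overlap(lapply(sizes, function(sz) sample.int(n_univ, sz)))
      }, numeric(1))
    })
  } else {
    strata <- as.factor(strata)
    stopifnot(length(strata) == length(universe))
    sizes <- lapply(idx_sets, function(s) table(strata[s]))
    by_str <- split(seq_len(n_univ), strata)
    null <- withr::with_seed(as.integer(seed), {
      vapply(seq_len(n_perm), function(i) {
        ss <- lapply(sizes, function(sz) {
          unlist(lapply(names(sz), function(g) {
            pool <- by_str[[g]]
            pool[sample.int(length(pool), sz[[g]])]
          }))
        })
        count_overlap(ss)
      }, numeric(1))
    })
  }
  list(observed = observed, null = null,
       p = (1 + sum(null >= observed)) / (1 + n_perm))
}
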