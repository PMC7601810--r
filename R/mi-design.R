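#' k-nearest-neighbor mutual information (KSG variant 1)
#'
#' Nonparametric estimate of the mutual information between two continuous
#' samples from k-th nearest-neighbor distances:
#' `I = psi(k) + psi(N) - <psi(n_x + 1) + psi(n_y + 1)>`, with max-norm
#' neighborhoods in the joint space and marginal counts strictly within the
#' k-th joint distance. Heavily tied or duplicated inputs should be jittered
#' first (see [candidate_mi()]), as the estimator assumes continuous
#' distributions.
#'
#' Mutual information is invariant under monotone marginal transforms, but
#' the kNN estimate is not scale-free: with max-norm joint balls, a
#' marginal whose spread dwarfs the other's dominates every distance and
#' the estimate collapses. Each marginal is therefore standardized
#' (centered, unit variance) before distances are computed, the usual
#' practice for this estimator.
#'
#' @param x,y Numeric vectors or matrices (rows = samples).
#' @param k_neighbors Neighbor order `k` (default 6).
#' @return Estimated mutual information in nats (can be slightly negative
#'   for independent samples; see [candidate_mi()] for the clamped design
#'   path).
#' @examples
#' set.seed(1)
#' x <- rnorm(500); y <- x + rnorm(500)
#' knn_mi(x, y)
#' @export
knn_mi <- function(x, y, k_neighbors = 6) {
  x <- as.matrix(x); y <- as.matrix(y)
  if (nrow(x) != nrow(y)) abort("x and y must have the same sample count")
  if (nrow(x) < k_neighbors + 1)
    abort("need at least k_neighbors + 1 samples")
  standardize <- function(m) {
    apply(m, 2, function(v) {
      s <- stats::sd(v)
      if (s == 0) v else (v - mean(v)) / s
    })
  }
  cpp_ksg_mi(standardize(x), standardize(y), as.integer(k_neighbors))
}

#' Mutual information of candidate scans
#'
#' For each candidate design (a day, and for the two-compartment model a
#' metric), estimates the mutual information between the posterior parameter
#' draws and the corresponding low-fidelity predictions. Since the
#' predictions are a deterministic map of the parameter (the framework
#' assumes no model discrepancy and zero measurement error), a uniform
#' jitter of `jitter` times the sample range is added to both coordinates
#' before the kNN distances to break degenerate ties; negative raw estimates
#' are clamped to zero.
#'
#' @param theta Matrix (or vector) of posterior draws.
#' @param predictions Matrix of low-fidelity predictions,
#'   `n_candidates x n_draws`.
#' @param candidates Tibble describing the candidates (one row per
#'   prediction row); returned with the estimates.
#' @param k_neighbors Neighbor order for the KSG estimator (default 6).
#' @param jitter Relative tie-breaking jitter (default 1e-8).
#' @return `candidates` with an added `mi` column (nats, >= 0).
#' @export
candidate_mi <- function(theta, predictions, candidates,
                         k_neighbors = 6, jitter = 1e-8) {
  theta <- as.matrix(theta)
  predictions <- as.matrix(predictions)
  if (nrow(candidates) == 0) abort("empty candidate set")
  stopifnot(nrow(predictions) == nrow(candidates),
            ncol(predictions) == nrow(theta))
  rng_t <- max(apply(theta, 2, function(v) diff(range(v))), 1e-300)
  xj <- theta + runif(length(theta), -0.5, 0.5) * jitter * rng_t
  mi <- vapply(seq_len(nrow(predictions)), function(i) {
    y <- predictions[i, ]
    rng <- diff(range(y))
    if (rng == 0) return(0)  # prediction pinned: no information
    yj <- y + runif(length(y), -0.5, 0.5) * jitter * rng
    max(0, knn_mi(xj, yj, k_neighbors))
  }, numeric(1))
  out <- candidates
  out$mi <- mi
  out
}

#' Relative mutual information
#'
#' Scales a vector of per-candidate MI estimates by the maximum over the
#' remaining candidates, so the best candidate scores 1 and all values lie
#' in `[0, 1]`.
#'
#' @param mi_table Tibble with an `mi` column (output of [candidate_mi()]).
#' @return The table with an added `r_mi` column.
#' @export
relative_mi <- function(mi_table) {
  stopifnot("mi" %in% names(mi_table), nrow(mi_table) > 0)
  m <- max(mi_table$mi)
  if (m <= 0) {
    warn("all candidate MI estimates are zero; relative MI degenerate")
    mi_table$r_mi <- rep(0, nrow(mi_table))
  } else {
    mi_table$r_mi <- mi_table$mi / m
  }
  mi_table
}

#' Skip-penalized score function
#'
#' Scores each candidate by its relative mutual information minus a penalty
#' proportional to the relative information of every candidate that would be
#' skipped by jumping ahead to it:
#' `S_k(i, r) = R(i, r) - k * sum_{j < i} R(j, r) / sum_all R(l, r)`,
#' where the sums run over candidates between the last chosen scan and `i`
#' (numerator) and over all remaining candidates up to the horizon
#' (denominator). With two metrics, a same-day candidate of the other
#' metric is not "skipped" and does not enter the numerator. `k = 0`
#' recovers pure mutual-information ranking.
#'
#' @param r_table Output of [relative_mi()], ordered or not; must contain
#'   `day` and `r_mi` (and optionally `metric`).
#' @param k Penalty weight in `[0, 1]`.
#' @return The table, sorted by day (tumor before necrotic within a day),
#'   with an added `score` column.
#' @export
score_candidates <- function(r_table, k) {
  stopifnot(k >= 0, k <= 1, all(c("day", "r_mi") %in% names(r_table)))
  tb <- r_table
  if (!"metric" %in% names(tb)) tb$metric <- "tumor"
  tb <- dplyr::arrange(tb, .data$day,
                       factor(.data$metric, levels = c("tumor", "necrotic")))
  denom <- sum(tb$r_mi)
  if (denom == 0) {
    warn("all relative MI values are zero; skip penalty waived")
    tb$score <- tb$r_mi
    return(tb)
  }
  skipped <- vapply(seq_len(nrow(tb)),
                    function(i) sum(tb$r_mi[tb$day < tb$day[i]]),
                    numeric(1))
  tb$score <- tb$r_mi - k * skipped / denom
  tb
}

#' Select the next scan from a score table
#'
#' Argmax of the score, with ties broken by the earliest day and then by
#' tumor volume before necrotic volume.
#'
#' @param scores Output of [score_candidates()].
#' @return The selected row (one-row tibble).
#' @export
select_next <- function(scores) {
  stopifnot(nrow(scores) > 0, "score" %in% names(scores))
  tb <- scores
  if (!"metric" %in% names(tb)) tb$metric <- "tumor"
  ord <- order(-tb$score, tb$day,
               factor(tb$metric, levels = c("tumor", "necrotic")))
  tb[ord[1], , drop = FALSE]
}
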