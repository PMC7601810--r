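# Look up a (day, metric) measurement in a high-fidelity trajectory.
hf_value <- function(ca_data, day, metric) {
  col <- if (metric == "tumor") "tumor_volume" else "necrotic_volume"
  if (!col %in% names(ca_data))
    abort(paste("trajectory has no", col, "column"))
  v <- ca_data[[col]][match(day, ca_data$day)]
  if (anyNA(v)) abort(paste("trajectory has no day", day))
  v
}

new_design_history <- function(steps, final_chain, data, ...) {
  structure(steps, class = c("design_history", class(steps)),
            final_chain = final_chain, data = data, meta = list(...))
}

# Per-step bookkeeping shared by both design loops: posterior summary of
# beta plus the whole-horizon relative error at the posterior median.
step_summary <- function(chain, model, pretreat, alpha, schedule, ca_data) {
  est <- median(chain_draws(chain)[, "beta"])
  iq <- posterior_iqr(chain, "beta")
  days <- ca_data$day
  if (model == "one") {
    fit <- predict_grid_1c(pretreat$A, pretreat$B, alpha, est, schedule,
                           pretreat$V0, days)[, 1]
  } else {
    p2 <- params_two_compartment(pretreat$lambda, pretreat$K, pretreat$eta,
                                 pretreat$zeta)
    fit <- predict_grid_2c(p2, alpha, est, schedule, pretreat$V0,
                           pretreat$N0, days)$tumor[, 1]
  }
  err <- relative_error(ca_data,
                        tibble(day = days, tumor_volume = fit))
  list(beta_median = est, beta_q25 = iq[["q25"]], beta_q75 = iq[["q75"]],
       rel_error = err)
}

# Prediction matrix (n_candidates x n_draws) for a candidate table.
candidate_predictions <- function(model, pretreat, alpha, beta_draws,
                                  schedule, candidates) {
  if (model == "one") {
    predict_grid_1c(pretreat$A, pretreat$B, alpha, beta_draws, schedule,
                    pretreat$V0, candidates$day)
  } else {
    p2 <- params_two_compartment(pretreat$lambda, pretreat$K, pretreat$eta,
                                 pretreat$zeta)
    gr <- predict_grid_2c(p2, alpha, beta_draws, schedule, pretreat$V0,
                          pretreat$N0, candidates$day)
    out <- matrix(NA_real_, nrow(candidates), length(beta_draws))
    for (i in seq_len(nrow(candidates)))
      out[i, ] <- gr[[candidates$metric[i]]][i, ]
    out
  }
}

#' Sequentially design a scan schedule under a budget
#'
#' Runs the full information-theoretic design loop against a high-fidelity
#' trajectory: starting from scans at `initial_days` (pre-treatment scans
#' plus the first treatment day), it repeatedly (1) recalibrates the
#' radiosensitivity parameter `beta` by DRAM on the accumulated scans,
#' (2) estimates the mutual information between the posterior draws and the
#' low-fidelity prediction at every remaining candidate (day, metric),
#' (3) scores candidates with the skip penalty weight `k`, (4) appends the
#' high-fidelity value of the argmax candidate, until the scan budget is
#' exhausted.
#'
#' With `model = "two"` one metric is measured per step, and the other
#' metric of the current day stays available on the next step. With
#' `free_tumor = TRUE` (the practical variant) choosing a necrotic scan
#' automatically appends the same-day tumor volume at no budget cost, since
#' the imaging scan provides both.
#'
#' @param ca_data High-fidelity trajectory tibble covering the horizon
#'   (columns `day`, `tumor_volume`, and `necrotic_volume` for the
#'   two-compartment model).
#' @param model `"one"` or `"two"` compartment low-fidelity model.
#' @param budget Number of scans to add (>= 1).
#' @param k Skip-penalty weight in `[0, 1]`.
#' @param free_tumor Practical-setting variant (two-compartment only).
#' @param alpha Fixed linear LQ coefficient (default 0.14).
#' @param pretreat Fixed pre-treatment parameters (defaults to the packaged
#'   stand-ins for the chosen model).
#' @param schedule Treatment schedule (default [build_schedule()]).
#' @param prior Prior for `beta` (default uniform on `[0, 0.5]`).
#' @param initial_days Days whose tumor volume seeds the data set
#'   (default `c(5, 10, 15)`).
#' @param last_candidate_day Latest candidate day (default 55, the day-6
#'   scan of the final treatment week).
#' @param n_iter DRAM iterations per recalibration (default 10000).
#' @param n_mi Posterior draws used by the MI estimator (default 1000).
#' @param k_neighbors KSG neighbor order (default 6).
#' @param iqr_stop Optional interquartile-width stopping threshold;
#'   `NULL` (default) runs to budget exhaustion.
#' @param seed Optional integer seed covering the whole loop.
#' @return A `design_history`: tibble with one row per added scan (`step`,
#'   `day`, `metric`, `mi`, `r_mi`, `score`, `beta_median`, `beta_q25`,
#'   `beta_q75`, `rel_error`) carrying the final chain, the accumulated
#'   data set and the run settings as attributes.
#' @export
sequential_design <- function(ca_data, model = c("one", "two"), budget, k,
                              free_tumor = FALSE, alpha = 0.14,
                              pretreat = NULL,
                              schedule = build_schedule(),
                              prior = prior_uniform(c(beta = 0), c(beta = 0.5)),
                              initial_days = c(5, 10, 15),
                              last_candidate_day = 55, n_iter = 10000,
                              n_mi = 1000, k_neighbors = 6, iqr_stop = NULL,
                              seed = NULL) {
  model <- match.arg(model)
  stopifnot(budget >= 1, k >= 0, k <= 1)
  if (free_tumor && model != "two")
    abort("free_tumor applies to the two-compartment model only")
  if (max(ca_data$day) < last_candidate_day)
    abort("high-fidelity data does not cover the candidate horizon")
  if (!is.null(seed)) set.seed(seed)

  if (is.null(pretreat))
    pretreat <- if (model == "one") default_pretreatment_1c()
                else default_pretreatment_2c()
  data <- tibble(day = initial_days, metric = "tumor",
                 value = hf_value(ca_data, initial_days, "tumor"))
  metrics <- if (model == "one") "tumor" else c("tumor", "necrotic")
  all_cand <- tidyr::expand_grid(day = seq(min(initial_days) + 1,
                                           last_candidate_day),
                                 metric = metrics)
  all_cand <- all_cand[all_cand$day > max(initial_days) |
                         (all_cand$day == max(initial_days) &
                            all_cand$metric == "necrotic"), ]

  chain <- calibrate_beta(data, model, pretreat, alpha, schedule, prior,
                          n_iter = n_iter)
  steps <- list()
  score_tables <- list()
  last_day <- max(initial_days)
  for (s in seq_len(budget)) {
    cand <- all_cand[all_cand$day > last_day |
                       (all_cand$day == last_day &
                          !paste(all_cand$day, all_cand$metric) %in%
                            paste(data$day, data$metric)), ]
    cand <- cand[cand$day >= last_day, ]
    if (nrow(cand) == 0) {
      warn("candidate set exhausted before the scan budget")
      break
    }
    pp <- posterior_predictive(chain, function(b)
      candidate_predictions(model, pretreat, alpha, b, schedule, cand),
      n_draws = min(n_mi, floor(0.8 * n_iter)))
    mi_tb <- candidate_mi(pp$theta, pp$pred, cand, k_neighbors = k_neighbors)
    sc <- score_candidates(relative_mi(mi_tb), k)
    pick <- select_next(sc)
    score_tables[[s]] <- sc

    new_rows <- tibble(day = pick$day, metric = pick$metric,
                       value = hf_value(ca_data, pick$day, pick$metric))
    if (free_tumor && pick$metric == "necrotic" &&
        !any(data$day == pick$day & data$metric == "tumor")) {
      new_rows <- dplyr::bind_rows(new_rows,
        tibble(day = pick$day, metric = "tumor",
               value = hf_value(ca_data, pick$day, "tumor")))
    }
    data <- dplyr::bind_rows(data, new_rows)
    last_day <- pick$day

    chain <- calibrate_beta(data, model, pretreat, alpha, schedule, prior,
                            n_iter = n_iter,
                            init = c(beta = median(chain_draws(chain)[, "beta"])))
    sm <- step_summary(chain, model, pretreat, alpha, schedule, ca_data)
    steps[[s]] <- tibble(step = s, day = pick$day, metric = pick$metric,
                         mi = pick$mi, r_mi = pick$r_mi, score = pick$score,
                         !!!sm)
    if (!is.null(iqr_stop) &&
        (sm$beta_q75 - sm$beta_q25) < iqr_stop) break
  }
  new_design_history(dplyr::bind_rows(steps), chain, data,
                     model = model, k = k, budget = budget,
                     free_tumor = free_tumor, score_tables = score_tables,
                     design = "sequential")
}

#' Weekly-budget scan design
#'
#' The constrained variant of the design loop: exactly one tumor volume
#' scan per treatment week. For each of treatment weeks 2 through
#' `n_weeks`, the candidates are the seven days of that weekly cycle and
#' the raw mutual-information argmax is selected (no skip penalty applies
#' within a week); the model is recalibrated after each selection.
#'
#' @inheritParams sequential_design
#' @param n_weeks Number of treatment weeks (default 6).
#' @param first_treatment_day First dose day (default 15).
#' @return A `design_history` with one row per week; `cycle_day` gives the
#'   position within the weekly cycle (1 = Monday, the first dose day of
#'   the week).
#' @export
weekly_design <- function(ca_data, alpha = 0.14, pretreat = NULL,
                          schedule = build_schedule(),
                          prior = prior_uniform(c(beta = 0), c(beta = 0.5)),
                          initial_days = c(5, 10, 15), n_weeks = 6,
                          first_treatment_day = 15, n_iter = 10000,
                          n_mi = 1000, k_neighbors = 6, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(pretreat)) pretreat <- default_pretreatment_1c()
  data <- tibble(day = initial_days, metric = "tumor",
                 value = hf_value(ca_data, initial_days, "tumor"))
  chain <- calibrate_beta(data, "one", pretreat, alpha, schedule, prior,
                          n_iter = n_iter)
  steps <- list()
  score_tables <- list()
  for (w in 2:n_weeks) {
    week_start <- first_treatment_day + 7 * (w - 1)
    cand <- tibble(day = week_start + 0:6, metric = "tumor")
    pp <- posterior_predictive(chain, function(b)
      candidate_predictions("one", pretreat, alpha, b, schedule, cand),
      n_draws = min(n_mi, floor(0.8 * n_iter)))
    mi_tb <- relative_mi(candidate_mi(pp$theta, pp$pred, cand,
                                      k_neighbors = k_neighbors))
    mi_tb$score <- mi_tb$r_mi  # raw-MI argmax within the week
    pick <- select_next(mi_tb)
    score_tables[[w - 1]] <- mi_tb

    data <- dplyr::bind_rows(data,
      tibble(day = pick$day, metric = "tumor",
             value = hf_value(ca_data, pick$day, "tumor")))
    chain <- calibrate_beta(data, "one", pretreat, alpha, schedule, prior,
                            n_iter = n_iter,
                            init = c(beta = median(chain_draws(chain)[, "beta"])))
    sm <- step_summary(chain, "one", pretreat, alpha, schedule, ca_data)
    steps[[w - 1]] <- tibble(step = w - 1, week = w, day = pick$day,
                             cycle_day = pick$day - week_start + 1,
                             metric = "tumor", mi = pick$mi,
                             r_mi = pick$r_mi, score = pick$score, !!!sm)
  }
  new_design_history(dplyr::bind_rows(steps), chain, data,
                     model = "one", k = 0, budget = n_weeks - 1,
                     free_tumor = FALSE, score_tables = score_tables,
                     design = "weekly")
}

#' Tidy a design history
#'
#' Returns the per-step table as a plain tibble.
#'
#' @param x A `design_history`.
#' @param ... Unused.
#' @export
tidy.design_history <- function(x, ...) {
  as_tibble(unclass(x)[seq_along(x)])
}

#' One-row summary of a design run
#'
#' Final calibrated `beta` (posterior median and interquartile range),
#' whole-horizon relative error, and the number of scans used.
#'
#' @param x A `design_history`.
#' @param ... Unused.
#' @export
glance.design_history <- function(x, ...) {
  ch <- attr(x, "final_chain")
  iq <- posterior_iqr(ch, "beta")
  tibble(beta_hat = median(chain_draws(ch)[, "beta"]),
         beta_q25 = iq[["q25"]], beta_q75 = iq[["q75"]],
         rel_error = x$rel_error[nrow(x)],
         n_scans = nrow(attr(x, "data")),
         k = attr(x, "meta")$k, model = attr(x, "meta")$model,
         design = attr(x, "meta")$design)
}

#' @export
print.design_history <- function(x, ...) {
  m <- attr(x, "meta")
  cat(sprintf("%s design (%s-compartment, k = %g): %d scan(s) added\n",
              m$design, m$model, m$k, nrow(x)))
  print(tidy(x), ...)
  invisible(x)
}
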