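#' Uniform prior specification
#'
#' Independent uniform priors, one `(lower, upper)` pair per parameter.
#'
#' @param lower,upper Numeric vectors of equal length with
#'   `lower < upper` elementwise; names are taken as parameter names.
#' @return A list of class `prior_spec`.
#' @export
prior_uniform <- function(lower, upper) {
  stopifnot(length(lower) == length(upper))
  if (any(lower >= upper)) abort("each lower bound must be below its upper bound")
  nm <- names(lower)
  if (is.null(nm)) nm <- paste0("theta", seq_along(lower))
  structure(list(lower = setNames(as.numeric(lower), nm),
                 upper = setNames(as.numeric(upper), nm)),
            class = "prior_spec")
}

log_prior <- function(prior, theta) {
  if (any(theta < prior$lower | theta > prior$upper)) return(-Inf)
  -sum(log(prior$upper - prior$lower))
}

#' Build a log-posterior function for Gaussian residuals
#'
#' Independent Gaussian residuals with fixed variance `sigma2` around the
#' predictions of `predict_fn`, plus a uniform prior. Parameter values
#' outside the prior support, or predictions that fail, score `-Inf`.
#'
#' @param observed Numeric vector of observations.
#' @param predict_fn Function mapping a parameter vector to a prediction
#'   vector aligned with `observed`.
#' @param prior A [prior_uniform()] object.
#' @param sigma2 Fixed residual variance (> 0).
#' @return A function `theta -> log posterior` (up to a constant).
#' @export
make_log_posterior <- function(observed, predict_fn, prior, sigma2) {
  stopifnot(sigma2 > 0)
  n <- length(observed)
  function(theta) {
    lp <- log_prior(prior, theta)
    if (!is.finite(lp)) return(-Inf)
    pred <- tryCatch(predict_fn(theta), error = function(e) {
      warn(paste("model evaluation failed:", conditionMessage(e)))
      NULL
    })
    if (is.null(pred) || anyNA(pred)) return(-Inf)
    ss <- sum((observed - pred)^2)
    -n / 2 * log(2 * pi * sigma2) - ss / (2 * sigma2) + lp
  }
}

#' Delayed-rejection adaptive Metropolis sampler
#'
#' Random-walk Metropolis with two standard accelerations: the proposal
#' covariance is adapted from the chain history (scaled by `2.38^2/d` plus a
#' small regularization) at a fixed interval after a warm-up, and each
#' first-stage rejection triggers one delayed-rejection stage with the
#' proposal scaled down by `dr_scale`, accepted with the usual two-stage
#' probability that preserves the target.
#'
#' The target can be supplied either as a black-box `log_posterior`, or as a
#' sum-of-squares function `ss_fun` for Gaussian likelihoods, in which case
#' each residual variance is Gibbs-sampled from its conjugate inverse-gamma
#' full conditional every iteration (one variance per residual block).
#'
#' @param log_posterior Function `theta -> log density` (used when `ss_fun`
#'   is `NULL`).
#' @param init Numeric initial parameter vector (inside the support).
#' @param n_iter Number of iterations (default 10000).
#' @param prior A [prior_uniform()] object (required with `ss_fun`; also
#'   used to bound proposals).
#' @param ss_fun Optional function `theta -> named vector` of residual
#'   sums of squares, one element per data block.
#' @param n_obs Integer vector of observation counts per block (required
#'   with `ss_fun`).
#' @param sigma2_init Initial residual variance guess per block; defaults to
#'   `ss_fun(init)/n_obs`.
#' @param config List of sampler settings: `prop_sd` (initial proposal
#'   standard deviations; default 5% of the prior range), `adapt_start`
#'   (default 200), `adapt_interval` (default 100), `dr_scale`
#'   (default 0.4), `n0` (variance prior weight, default 1).
#' @param seed Optional integer seed.
#' @return An object of class `rtscan_chain`: list with `samples` (matrix,
#'   one row per iteration), `log_post`, `sigma2` (matrix or NULL),
#'   `accept_rate`, `burn_frac` (0.2), and the call settings.
#' @examples
#' target <- function(th) -0.5 * th^2
#' ch <- dram_sample(target, init = 0, n_iter = 2000,
#'                   prior = prior_uniform(-10, 10), seed = 1)
#' glance(ch)
#' @export
dram_sample <- function(log_posterior = NULL, init, n_iter = 10000,
                        prior = NULL, ss_fun = NULL, n_obs = NULL,
                        sigma2_init = NULL, config = list(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  d <- length(init)
  cfg <- utils::modifyList(list(
    prop_sd = NULL, adapt_start = 200L, adapt_interval = 100L,
    dr_scale = 0.4, n0 = 1
  ), config)
  if (is.null(cfg$prop_sd)) {
    if (!is.null(prior)) cfg$prop_sd <- 0.05 * (prior$upper - prior$lower)
    else cfg$prop_sd <- rep(1, d)
  }
  use_ss <- !is.null(ss_fun)
  if (use_ss) {
    if (is.null(prior) || is.null(n_obs))
      abort("ss_fun requires prior and n_obs")
    ss_cur <- ss_fun(init)
    if (anyNA(ss_cur) || any(!is.finite(ss_cur)))
      abort("ss_fun failed at the initial value")
    nb <- length(ss_cur)
    stopifnot(length(n_obs) == nb)
    if (is.null(sigma2_init)) sigma2_init <- pmax(ss_cur / pmax(n_obs, 1), 1e-12)
    if (any(sigma2_init <= 0)) abort("initial residual variance must be positive")
    sigma2 <- sigma2_init
    s02 <- sigma2_init
    loglik <- function(ss) sum(-n_obs / 2 * log(2 * pi * sigma2) - ss / (2 * sigma2))
    lp_cur <- loglik(ss_cur) + log_prior(prior, init)
  } else {
    if (is.null(log_posterior)) abort("supply log_posterior or ss_fun")
    lp_cur <- log_posterior(init)
    if (!is.finite(lp_cur)) abort("init must have finite log posterior")
  }

  chol_prop <- diag(cfg$prop_sd, d)
  samples <- matrix(NA_real_, n_iter, d)
  lps <- numeric(n_iter)
  sig_out <- if (use_ss) matrix(NA_real_, n_iter, length(sigma2)) else NULL
  theta <- as.numeric(init)
  ss_theta <- if (use_ss) ss_cur else NULL
  n_accept <- 0L
  run_mean <- theta
  run_cov <- matrix(0, d, d)

  eval_lp <- function(th) {
    if (use_ss) {
      if (any(th < prior$lower | th > prior$upper))
        return(list(lp = -Inf, ss = NULL))
      ss <- tryCatch(ss_fun(th), error = function(e) NULL)
      if (is.null(ss) || anyNA(ss) || any(!is.finite(ss)))
        return(list(lp = -Inf, ss = NULL))
      list(lp = loglik(ss) + log_prior(prior, th), ss = ss)
    } else {
      lp <- log_posterior(th)
      if (!is.null(prior) && any(th < prior$lower | th > prior$upper)) lp <- -Inf
      list(lp = lp, ss = NULL)
    }
  }
  # log density (up to constant) of the stage-1 proposal N(center, C)
  prop_logq <- function(from, to) {
    z <- backsolve(chol_prop, to - from, transpose = TRUE)
    -0.5 * sum(z^2)
  }

  for (it in seq_len(n_iter)) {
    z <- rnorm(d)
    cand1 <- theta + drop(t(chol_prop) %*% z)
    e1 <- eval_lp(cand1)
    a1 <- min(1, exp(e1$lp - lp_cur))
    if (is.finite(e1$lp) && runif(1) < a1) {
      theta <- cand1; lp_cur <- e1$lp
      if (use_ss) ss_theta <- e1$ss
      n_accept <- n_accept + 1L
    } else {
      # delayed-rejection stage: narrower proposal around the current point
      cand2 <- theta + cfg$dr_scale * drop(t(chol_prop) %*% rnorm(d))
      e2 <- eval_lp(cand2)
      if (is.finite(e2$lp)) {
        a1_rev <- min(1, exp(e1$lp - e2$lp))
        num <- e2$lp + prop_logq(cand2, cand1) + log1p(-a1_rev)
        den <- lp_cur + prop_logq(theta, cand1) + log1p(-a1)
        if (is.finite(num) && runif(1) < exp(num - den)) {
          theta <- cand2; lp_cur <- e2$lp
          if (use_ss) ss_theta <- e2$ss
          n_accept <- n_accept + 1L
        }
      }
    }

    if (use_ss) {
      # conjugate inverse-gamma update of each residual variance
      shape <- (cfg$n0 + n_obs) / 2
      rate <- (cfg$n0 * s02 + ss_theta) / 2
      sigma2 <- 1 / stats::rgamma(length(ss_theta), shape = shape, rate = rate)
      lp_cur <- loglik(ss_theta) + log_prior(prior, theta)
      sig_out[it, ] <- sigma2
    }

    samples[it, ] <- theta
    lps[it] <- lp_cur

    # recursive moments for adaptation
    delta <- theta - run_mean
    run_mean <- run_mean + delta / it
    run_cov <- run_cov + (tcrossprod(delta, theta - run_mean) - run_cov) / it
    if (it >= cfg$adapt_start && it %% cfg$adapt_interval == 0) {
      cov_ad <- 2.38^2 / d * (run_cov + diag(1e-10 * cfg$prop_sd^2, d))
      ch <- tryCatch(chol(cov_ad), error = function(e) NULL)
      if (!is.null(ch)) chol_prop <- ch
    }
  }

  nm <- names(init)
  if (is.null(nm)) nm <- paste0("theta", seq_len(d))
  colnames(samples) <- nm
  structure(list(samples = samples, log_post = lps, sigma2 = sig_out,
                 accept_rate = n_accept / n_iter, burn_frac = 0.2,
                 n_iter = n_iter, config = cfg, seed = seed),
            class = "rtscan_chain")
}

# post-burn-in sample matrix
chain_draws <- function(chain, burn_frac = chain$burn_frac) {
  n <- nrow(chain$samples)
  keep <- seq.int(floor(burn_frac * n) + 1L, n)
  chain$samples[keep, , drop = FALSE]
}

#' Posterior interquartile range
#'
#' 25th to 75th percentile of the post-burn-in samples of one parameter;
#' the shrinkage of this interval across design steps is the working
#' measure of calibration progress.
#'
#' @param chain An `rtscan_chain` from [dram_sample()].
#' @param param Column name or index (default 1).
#' @return Named numeric vector `c(q25, q75)`.
#' @export
posterior_iqr <- function(chain, param = 1) {
  stopifnot(inherits(chain, "rtscan_chain"), nrow(chain$samples) > 4)
  x <- chain_draws(chain)[, param]
  setNames(quantile(x, c(0.25, 0.75), names = FALSE), c("q25", "q75"))
}

#' Posterior draws paired with low-fidelity predictions
#'
#' Thins the post-burn-in chain to `n_draws` parameter vectors and evaluates
#' the low-fidelity prediction at every candidate design. The resulting
#' joint sample of (parameter, prediction) pairs feeds the mutual-
#' information estimator.
#'
#' @param chain An `rtscan_chain`.
#' @param predict_fn Function mapping a vector of parameter draws to a
#'   `n_candidates x n_draws` matrix of predictions (or a named list of such
#'   matrices, one per metric).
#' @param n_draws Number of thinned draws (at most the post-burn-in length).
#' @return List with `theta` (draw matrix) and `pred` (the predictions as
#'   returned by `predict_fn`).
#' @export
posterior_predictive <- function(chain, predict_fn, n_draws = 1000) {
  draws <- chain_draws(chain)
  if (n_draws > nrow(draws))
    abort("n_draws exceeds the post-burn-in chain length")
  idx <- unique(round(seq(1, nrow(draws), length.out = n_draws)))
  th <- draws[idx, , drop = FALSE]
  list(theta = th, pred = predict_fn(th[, 1]))
}

#' @export
print.rtscan_chain <- function(x, ...) {
  cat("DRAM chain:", nrow(x$samples), "iterations,",
      ncol(x$samples), "parameter(s)\n")
  cat(sprintf("acceptance rate %.2f; burn-in fraction %.2f\n",
              x$accept_rate, x$burn_frac))
  print(tidy(x))
  invisible(x)
}

#' Tidy a DRAM chain
#'
#' One row per parameter with the posterior median, mean, standard
#' deviation and quartiles of the post-burn-in samples.
#'
#' @param x An `rtscan_chain`.
#' @param ... Unused.
#' @export
tidy.rtscan_chain <- function(x, ...) {
  draws <- chain_draws(x)
  purrr::map_dfr(colnames(draws), function(nm) {
    v <- draws[, nm]
    tibble(term = nm, estimate = median(v), mean = mean(v),
           std.error = stats::sd(v),
           q25 = quantile(v, 0.25, names = FALSE),
           q75 = quantile(v, 0.75, names = FALSE))
  })
}

#' Chain-level summary of a DRAM run
#'
#' @param x An `rtscan_chain`.
#' @param ... Unused.
#' @export
glance.rtscan_chain <- function(x, ...) {
  tibble(n_iter = x$n_iter, accept_rate = x$accept_rate,
         burn_frac = x$burn_frac, n_params = ncol(x$samples))
}

# Calibrate the radiosensitivity parameter beta against an accumulated scan
# data set. `data` is a tibble (day, metric, value) with metric in
# {"tumor", "necrotic"}; residual blocks are per metric with separate
# Gibbs-sampled variances. Shared glue for the design loops and the CLI.
calibrate_beta <- function(data, model = c("one", "two"),
                           pretreat = NULL, alpha = 0.14,
                           schedule = build_schedule(),
                           prior = prior_uniform(c(beta = 0), c(beta = 0.5)),
                           n_iter = 10000, init = NULL, config = list()) {
  model <- match.arg(model)
  stopifnot(all(data$metric %in% c("tumor", "necrotic")),
            !anyDuplicated(data[c("day", "metric")]))
  if (is.null(pretreat))
    pretreat <- if (model == "one") default_pretreatment_1c()
                else default_pretreatment_2c()
  metrics <- sort(unique(data$metric))
  obs <- split(data, factor(data$metric, levels = metrics))
  n_obs <- vapply(obs, nrow, integer(1))
  if (model == "one") {
    if (!all(data$metric == "tumor"))
      abort("the one-compartment model only fits tumor volume data")
    days <- obs$tumor$day
    p1 <- params_one_compartment(pretreat$A, pretreat$B)
    ss_fun <- function(th) {
      pred <- predict_grid_1c(p1$A, p1$B, alpha, th, schedule,
                              pretreat$V0, days)[, 1]
      c(tumor = sum((obs$tumor$value - pred)^2))
    }
  } else {
    p2 <- params_two_compartment(pretreat$lambda, pretreat$K, pretreat$eta,
                                 pretreat$zeta)
    ss_fun <- function(th) {
      vapply(metrics, function(m) {
        days <- obs[[m]]$day
        pred <- predict_grid_2c(p2, alpha, th, schedule, pretreat$V0,
                                pretreat$N0, days)[[m]][, 1]
        sum((obs[[m]]$value - pred)^2)
      }, numeric(1))
    }
  }
  if (is.null(init)) init <- c(beta = mean(c(prior$lower, prior$upper)))
  dram_sample(init = init, n_iter = n_iter, prior = prior, ss_fun = ss_fun,
              n_obs = n_obs, config = config)
}
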