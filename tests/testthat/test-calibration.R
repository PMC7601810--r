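test_that("log posterior behaves like a Gaussian likelihood with bounds", {
  obs <- c(1, 2, 3)
  predict_fn <- function(th) rep(th, 3)
  prior <- prior_uniform(c(theta = -10), c(theta = 10))
  lp <- make_log_posterior(obs, predict_fn, prior, sigma2 = 0.5)
  expect_equal(lp(100), -Inf)  # outside the prior support
  # perfect fit attains the maximal likelihood value
  lp_perfect <- make_log_posterior(c(2, 2, 2), predict_fn, prior, 0.5)
  expect_equal(lp_perfect(2), -3 / 2 * log(2 * pi * 0.5) - log(20))
  # doubling the residuals lowers the posterior
  expect_gt(lp(2), lp(4))
})

test_that("DRAM recovers a standard normal target", {
  target <- function(th) -0.5 * th^2
  ch <- dram_sample(target, init = c(theta = 0), n_iter = 20000,
                    prior = prior_uniform(c(theta = -10), c(theta = 10)),
                    seed = 42)
  draws <- ch$samples[4001:20000, 1]
  expect_lt(abs(mean(draws)), 0.05)
  expect_lt(abs(var(draws) - 1), 0.1)
  expect_gt(ch$accept_rate, 0.05)
  expect_lt(ch$accept_rate, 0.9)
})

test_that("DRAM agrees with the conjugate linear-Gaussian posterior", {
  set.seed(5)
  sigma <- 0.3
  y <- rnorm(25, mean = 1.7, sd = sigma)
  prior <- prior_uniform(c(mu = -10), c(mu = 10))
  # fixed-variance path: posterior is exactly N(mean(y), sigma^2/n)
  lp <- make_log_posterior(y, function(th) rep(th, 25), prior, sigma^2)
  ch <- dram_sample(lp, init = c(mu = 0), n_iter = 20000, prior = prior,
                    seed = 9)
  draws <- chain_draws <- ch$samples[4001:20000, 1]
  se <- sigma / sqrt(25)
  expect_lt(abs(mean(draws) - mean(y)), 3 * se / sqrt(100))
  expect_lt(abs(sd(draws) - se), 0.25 * se)
  # sampled-variance path: posterior mean still centers on mean(y)
  ch2 <- dram_sample(init = c(mu = 0), n_iter = 10000, prior = prior,
                     ss_fun = function(th) c(y = sum((y - th)^2)),
                     n_obs = 25, seed = 10)
  draws2 <- ch2$samples[2001:10000, 1]
  expect_lt(abs(mean(draws2) - mean(y)), 4 * se / sqrt(50))
})

test_that("chains are reproducible from their seed", {
  target <- function(th) -0.5 * th^2
  prior <- prior_uniform(c(theta = -5), c(theta = 5))
  a <- dram_sample(target, c(theta = 0), 500, prior, seed = 3)
  b <- dram_sample(target, c(theta = 0), 500, prior, seed = 3)
  expect_identical(a$samples, b$samples)
  c <- dram_sample(target, c(theta = 0), 500, prior, seed = 4)
  expect_false(identical(a$samples, c$samples))
})

test_that("posterior summaries follow order statistics", {
  fake_chain <- function(x) {
    structure(list(samples = matrix(x, ncol = 1,
                                    dimnames = list(NULL, "beta")),
                   burn_frac = 0, n_iter = length(x)),
              class = "rtscan_chain")
  }
  const <- fake_chain(rep(2, 100))
  expect_equal(unname(diff(posterior_iqr(const, "beta"))), 0)
  set.seed(1)
  unif <- fake_chain(runif(200000))
  iq <- posterior_iqr(unif, "beta")
  expect_equal(iq[["q25"]], 0.25, tolerance = 0.01)
  expect_equal(iq[["q75"]], 0.75, tolerance = 0.01)
})

test_that("posterior predictive pairs draws with model predictions", {
  x <- seq(0.01, 0.5, length.out = 1000)
  ch <- structure(list(samples = matrix(x, ncol = 1,
                                        dimnames = list(NULL, "beta")),
                       burn_frac = 0.2, n_iter = length(x)),
                  class = "rtscan_chain")
  pre <- default_pretreatment_1c()
  sched <- build_schedule(15, 6, 2)
  cands <- tibble::tibble(day = c(14, 15, 20), metric = "tumor")
  pp <- posterior_predictive(ch, function(b)
    rtscan:::predict_grid_1c(pre$A, pre$B, 0.14, b, sched, pre$V0,
                             cands$day), n_draws = 300)
  expect_equal(dim(pp$pred), c(3, 300))
  expect_equal(nrow(pp$theta), 300)
  # a dose-day scan reports the post-dose volume: day-15 prediction equals
  # the pre-dose value scaled by the survival fraction (up to growth over
  # the remaining fraction of the day)
  b1 <- pp$theta[1, 1]
  sf <- exp(-0.14 * 2 - b1 * 4)
  v_before <- rtscan:::predict_grid_1c(pre$A, pre$B, 0.14, b1, sched,
                                       pre$V0, 15 - 1e-9)[1, 1]
  expect_equal(unname(pp$pred[2, 1]), unname(v_before * sf),
               tolerance = 1e-6)
  # degenerate posterior: all draws identical
  ch0 <- structure(list(samples = matrix(rep(0.1, 100), ncol = 1,
                                         dimnames = list(NULL, "beta")),
                        burn_frac = 0.2, n_iter = 100),
                   class = "rtscan_chain")
  pp0 <- posterior_predictive(ch0, function(b)
    rtscan:::predict_grid_1c(pre$A, pre$B, 0.14, b, sched, pre$V0,
                             cands$day), n_draws = 50)
  expect_equal(max(apply(pp0$pred, 1, function(z) diff(range(z)))), 0)
  expect_error(posterior_predictive(ch0, identity, n_draws = 1000),
               "exceeds")
})

test_that("beta calibration recovers the truth on clean synthetic scans", {
  hf <- fake_hf_1c(beta = 0.14, noise = 0.01, seed = 2)
  days <- 16:45
  data <- tibble::tibble(day = days, metric = "tumor",
                         value = hf$tumor_volume[match(days, hf$day)])
  set.seed(8)
  ch <- rtscan:::calibrate_beta(data, "one", n_iter = 6000)
  est <- median(rtscan:::chain_draws(ch)[, "beta"])
  expect_lt(abs(est - 0.14) / 0.14, 0.1)
  expect_gt(ch$accept_rate, 0.05)
  expect_lt(ch$accept_rate, 0.7)
})

test_that("tidy and glance summarize chains", {
  target <- function(th) -0.5 * th^2
  ch <- dram_sample(target, c(theta = 0), 2000,
                    prior_uniform(c(theta = -5), c(theta = 5)), seed = 1)
  td <- tidy(ch)
  expect_equal(td$term, "theta")
  expect_true(all(c("estimate", "q25", "q75") %in% names(td)))
  gl <- glance(ch)
  expect_equal(gl$n_iter, 2000)
})
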