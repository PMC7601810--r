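test_that("survival fraction follows the linear-quadratic law", {
  expect_equal(lq_survival_fraction(radiosensitivity(0.14, 0.14), 0), 1)
  expect_equal(lq_survival_fraction(radiosensitivity(0.14, 0.14), 2),
               exp(-0.84))
  expect_equal(lq_survival_fraction(radiosensitivity(0.14, 0.0156), 2),
               exp(-0.14 * 2 - 0.0156 * 4))
  expect_error(lq_survival_fraction(radiosensitivity(0.14, 0.14), -1),
               "non-negative")
})

test_that("survival fraction is monotone decreasing in dose, alpha and beta", {
  doses <- seq(0, 10, by = 0.5)
  sf <- lq_survival_fraction(radiosensitivity(0.14, 0.05), doses)
  expect_true(all(diff(sf) < 0))
  alphas <- seq(0, 0.5, by = 0.05)
  sfa <- vapply(alphas,
                function(a) lq_survival_fraction(radiosensitivity(a, 0.05), 2),
                numeric(1))
  expect_true(all(diff(sfa) < 0))
  betas <- seq(0, 0.5, by = 0.05)
  sfb <- vapply(betas,
                function(b) lq_survival_fraction(radiosensitivity(0.14, b), 2),
                numeric(1))
  expect_true(all(diff(sfb) < 0))
})

test_that("schedule builder produces the Mon-Fri fractionation pattern", {
  one_week <- build_schedule(15, 1, 2)
  expect_equal(one_week$day, 15:19)
  expect_equal(unique(one_week$dose), 2)
  expect_equal(nrow(build_schedule(15, 0, 2)), 0)
  six_weeks <- build_schedule(15, 6, 2)
  expect_equal(nrow(six_weeks), 30)
  expect_equal(max(six_weeks$day), 54)
  expect_true(all(diff(six_weeks$day) > 0))
  # weekend gaps: consecutive dose days jump by 3 across weeks
  expect_equal(sort(unique(diff(six_weeks$day))), c(1, 3))
})

test_that("reparameterization maps biological rates to the identifiable form", {
  p <- reparameterize(lambda = 0.3, eta = 0.1, K = 100)
  expect_equal(p$A, 0.2)
  expect_equal(p$B, 0.003)
  degenerate <- reparameterize(lambda = 1, eta = 1, K = 5)
  expect_equal(degenerate$A, 0)
  expect_equal(degenerate$B, 0.2)
  expect_error(reparameterize(0.3, 0.1, 0), "K > 0")
  # algebraic round trip at fixed eta
  eta <- 0.07
  lambda <- p$A + eta
  expect_equal(reparameterize(lambda, eta, lambda / p$B)$B, p$B)
})

test_that("untreated one-compartment solution matches the logistic closed form", {
  p <- params_one_compartment(A = 0.25, B = 0.01)
  r <- radiosensitivity(0, 0)
  days <- 1:60
  tr <- simulate_one_compartment(p, r, build_schedule(n_weeks = 0),
                                 V0 = 0.5, eval_days = days)
  closed <- (p$A / p$B) /
    (1 + (p$A / (p$B * 0.5) - 1) * exp(-p$A * days))
  expect_equal(tr$tumor_volume, closed, tolerance = 1e-8)
  # exponential limit when crowding vanishes
  p0 <- params_one_compartment(A = 0.25, B = 0)
  tr0 <- simulate_one_compartment(p0, r, build_schedule(n_weeks = 0),
                                  V0 = 0.5, eval_days = days)
  expect_equal(tr0$tumor_volume, 0.5 * exp(0.25 * days), tolerance = 1e-8)
})

test_that("treated one-compartment trajectories agree across solvers", {
  p <- params_one_compartment(A = 0.29, B = 0.0137)
  r <- radiosensitivity(0.14, 0.14)
  sched <- build_schedule(15, 6, 2)
  an <- simulate_one_compartment(p, r, sched, 0.05, 1:57)
  od <- simulate_one_compartment(p, r, sched, 0.05, 1:57, method = "ode")
  expect_equal(an$tumor_volume, od$tumor_volume, tolerance = 1e-3)
  # the C++ propagator and the plain-R reference march identically
  ref <- rtscan:::predict_grid_1c_r(p$A, p$B, 0.14, 0.14, sched, 0.05, 1:57)
  expect_equal(an$tumor_volume, ref[, 1], tolerance = 1e-12)
  # zero radiosensitivity with doses equals the untreated trajectory
  null_rt <- simulate_one_compartment(p, radiosensitivity(0, 0), sched,
                                      0.05, 1:57)
  untreated <- simulate_one_compartment(p, r, build_schedule(n_weeks = 0),
                                        0.05, 1:57)
  expect_equal(null_rt$tumor_volume, untreated$tumor_volume)
})

test_that("two-compartment model honors its equilibria and limits", {
  p <- params_two_compartment(lambda = 0.32, K = 24, eta = 0.03, zeta = 0.05)
  r <- radiosensitivity(0, 0)
  no_rt <- build_schedule(n_weeks = 0)
  # eta = 0 keeps the necrotic compartment empty
  p0 <- params_two_compartment(0.32, 24, 0, 0.05)
  tr0 <- simulate_two_compartment(p0, r, no_rt, 1, 0, 1:30)
  expect_equal(tr0$necrotic_volume, rep(0, 30))
  # untreated equilibrium: V* = K(1 - eta/lambda), N* = eta V*/zeta
  tr <- simulate_two_compartment(p, r, no_rt, 1, 0, seq(100, 600, by = 100))
  v_star <- p$K * (1 - p$eta / p$lambda)
  n_star <- p$eta * v_star / p$zeta
  expect_equal(tail(tr$viable_volume, 1), v_star, tolerance = 1e-5)
  expect_equal(tail(tr$necrotic_volume, 1), n_star, tolerance = 1e-5)
})

test_that("fast necrotic decay collapses the two-compartment model onto one", {
  r <- radiosensitivity(0.14, 0.14)
  sched <- build_schedule(15, 3, 2)
  # compare on non-dose days: on a dose day the two-compartment total is
  # conserved across the impulse (the kill only moves volume to the
  # necrotic compartment), so the models differ there by construction
  days <- setdiff(1:35, sched$day)
  one <- simulate_one_compartment(
    params_one_compartment(A = 0.32 - 0.03, B = 0.32 / 24), r, sched,
    V0 = 0.5, eval_days = days)
  zetas <- c(1e3, 1e4)
  hs <- c(2e-3, 2e-4)  # keep the explicit integrator inside its
                       # stability limit as zeta grows
  err <- vapply(1:2, function(i) {
    p2 <- params_two_compartment(0.32, 24, 0.03, zetas[i])
    two <- rtscan:::predict_grid_2c(p2, 0.14, 0.14, sched, 0.5, 0, days,
                                    h = hs[i])
    max(abs(two$tumor[, 1] - one$tumor_volume) / one$tumor_volume)
  }, numeric(1))
  expect_lt(err[1], 0.05)
  expect_lt(err[2], err[1])  # discrepancy shrinks as zeta grows
})

test_that("dose impulses conserve total volume in the two-compartment model", {
  p <- params_two_compartment(0.32, 24, 0.03, 0.05)
  r <- radiosensitivity(0.14, 0.14)
  sched <- build_schedule(15, 1, 2)
  eps <- 1e-6
  tr <- simulate_two_compartment(p, r, sched, 0.5, 0.05,
                                 c(15 - eps, 15, 15 + eps))
  # total is continuous across the impulse while the split is not
  expect_equal(tr$tumor_volume[2], tr$tumor_volume[1], tolerance = 1e-4)
  expect_gt(tr$necrotic_volume[2], tr$necrotic_volume[1])
  expect_lt(tr$viable_volume[2], tr$viable_volume[1])
})

test_that("volumes stay non-negative across parameters and schedules", {
  set.seed(42)
  sched <- build_schedule(5, 4, 2)
  for (i in 1:20) {
    p <- params_one_compartment(A = runif(1, 0.05, 0.6),
                                B = runif(1, 0, 0.05))
    r <- radiosensitivity(runif(1, 0, 0.3), runif(1, 0, 0.3))
    tr <- simulate_one_compartment(p, r, sched, runif(1, 0.01, 2), 1:40)
    expect_true(all(tr$tumor_volume >= 0))
  }
})

test_that("relative error is the normalized L2 distance over shared days", {
  a <- tibble::tibble(day = 1:2, tumor_volume = c(3, 4))
  expect_equal(relative_error(a, a), 0)
  b <- tibble::tibble(day = 1:2, tumor_volume = c(0, 0))
  expect_equal(relative_error(a, b), 1)
  c1 <- tibble::tibble(day = 1:2, tumor_volume = c(1, 1))
  c2 <- tibble::tibble(day = 1:2, tumor_volume = c(1, 0))
  expect_equal(relative_error(c1, c2), 1 / sqrt(2))
  expect_error(relative_error(b, a), "identically zero")
  d <- tibble::tibble(day = 2:3, tumor_volume = c(1, 1))
  expect_error(relative_error(c1, d), "day grid")
})
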