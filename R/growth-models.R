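#' Radiosensitivity parameters of the linear-quadratic model
#'
#' The linear-quadratic (LQ) model summarizes a tissue's response to a single
#' radiation dose `d` through the survival fraction `exp(-alpha*d - beta*d^2)`.
#' `alpha` (1/Gy) captures single-strand DNA breaks, `beta` (1/Gy^2)
#' double-strand breaks; their ratio `alpha/beta` characterizes fractionation
#' sensitivity.
#'
#' @param alpha Linear LQ coefficient (1/Gy), non-negative.
#' @param beta Quadratic LQ coefficient (1/Gy^2), non-negative.
#' @return A list of class `radiosensitivity` with fields `alpha` and `beta`.
#' @examples
#' radiosensitivity(0.14, 0.14)
#' @export
radiosensitivity <- function(alpha, beta) {
  stopifnot(is.numeric(alpha), is.numeric(beta),
            length(alpha) == 1, length(beta) == 1)
  if (alpha < 0 || beta < 0) abort("alpha and beta must be non-negative")
  structure(list(alpha = alpha, beta = beta), class = "radiosensitivity")
}

#' Named radiosensitivity test scenarios
#'
#' Three reference tumors spanning the clinically relevant range of the
#' `alpha/beta` ratio: `"high"` sensitivity (`alpha/beta = 1`), `"medium"`
#' (`alpha/beta = 3`) and `"low"` (`alpha/beta = 9`), all with
#' `alpha = 0.14`/Gy.
#'
#' @param scenario One of `"high"`, `"medium"`, `"low"`.
#' @return A [radiosensitivity()] object.
#' @examples
#' scenario_radiosensitivity("medium")
#' @export
scenario_radiosensitivity <- function(scenario = c("high", "medium", "low")) {
  scenario <- match.arg(scenario)
  beta <- switch(scenario, high = 0.14, medium = 0.0467, low = 0.0156)
  radiosensitivity(alpha = 0.14, beta = beta)
}

#' Linear-quadratic survival fraction
#'
#' Fraction of cells surviving a single radiation dose under the
#' linear-quadratic model, `SF = exp(-alpha*d - beta*d^2)`.
#'
#' @param radio A [radiosensitivity()] object.
#' @param dose Dose in Gy (non-negative; vectorized).
#' @return Survival fraction(s) in `(0, 1]`.
#' @examples
#' lq_survival_fraction(radiosensitivity(0.14, 0.14), 2)
#' @export
lq_survival_fraction <- function(radio, dose) {
  stopifnot(inherits(radio, "radiosensitivity"), is.numeric(dose))
  if (any(dose < 0)) abort("dose must be non-negative")
  exp(-radio$alpha * dose - radio$beta * dose^2)
}

#' Build a Monday-to-Friday fractionation schedule
#'
#' Standard fractionated radiotherapy course: one fraction per day on five
#' consecutive days, followed by a two-day weekend break, repeated for
#' `n_weeks` weeks.
#'
#' @param first_treatment_day Simulation day of the first fraction
#'   (default 15; day 1 is the first simulated day).
#' @param n_weeks Number of treatment weeks (default 6).
#' @param dose Dose per fraction in Gy (default 2).
#' @return A tibble with columns `day` and `dose`, one row per fraction.
#' @examples
#' build_schedule(15, 6, 2)
#' @export
build_schedule <- function(first_treatment_day = 15, n_weeks = 6, dose = 2) {
  stopifnot(n_weeks >= 0, dose >= 0)
  if (n_weeks == 0) return(tibble(day = integer(), dose = numeric()))
  days <- as.integer(outer(0:4, first_treatment_day + 7 * (0:(n_weeks - 1)), `+`))
  tibble(day = sort(days), dose = dose)
}

#' One-compartment growth parameters
#'
#' Identifiable re-parameterization of logistic growth with natural cell
#' death: `dV/dt = A*V*(1 - (B/A)*V)` with net growth rate `A = lambda - eta`
#' (1/day) and crowding coefficient `B = lambda/K` (1/(day mm^3)).
#'
#' @param A Net growth rate (1/day), non-negative (zero marks degenerate
#'   net growth where death balances proliferation).
#' @param B Crowding coefficient (1/(day mm^3)), non-negative.
#' @return A list of class `params_1c`.
#' @export
params_one_compartment <- function(A, B) {
  stopifnot(is.numeric(A), is.numeric(B), length(A) == 1, length(B) == 1)
  if (A < 0) abort("A must be non-negative")
  if (B < 0) abort("B must be non-negative")
  structure(list(A = A, B = B), class = "params_1c")
}

#' Two-compartment (viable/necrotic) growth parameters
#'
#' Viable volume `V` grows logistically (rate `lambda`, capacity `K`) and
#' converts to necrotic volume `N` at rate `eta`; necrotic material decays at
#' rate `zeta`:
#' `dV/dt = lambda*V*(1 - V/K) - eta*V`, `dN/dt = eta*V - zeta*N`.
#'
#' @param lambda Growth rate (1/day), positive.
#' @param K Carrying capacity (mm^3), positive.
#' @param eta Necrosis conversion rate (1/day), non-negative, `eta < lambda`.
#' @param zeta Necrotic decay rate (1/day), non-negative.
#' @return A list of class `params_2c`.
#' @export
params_two_compartment <- function(lambda, K, eta, zeta) {
  stopifnot(is.numeric(lambda), is.numeric(K), is.numeric(eta),
            is.numeric(zeta))
  if (lambda <= 0) abort("lambda must be positive")
  if (K <= 0) abort("K must be positive")
  if (eta < 0 || zeta < 0) abort("eta and zeta must be non-negative")
  if (eta >= lambda) abort("eta must be below lambda for net growth")
  structure(list(lambda = lambda, K = K, eta = eta, zeta = zeta),
            class = "params_2c")
}

#' Map biological rates to the identifiable one-compartment form
#'
#' `A = lambda - eta`, `B = lambda / K`. The pair `(lambda, eta)` is not
#' structurally identifiable from volume data; only their difference enters
#' the identifiable form.
#'
#' @inheritParams params_two_compartment
#' @return A [params_one_compartment()] object.
#' @examples
#' reparameterize(lambda = 0.3, eta = 0.1, K = 100)
#' @export
reparameterize <- function(lambda, eta, K) {
  stopifnot(lambda > 0, eta >= 0, K > 0)
  params_one_compartment(A = lambda - eta, B = lambda / K)
}

# Piecewise-exact logistic propagation: value at time t1 given V(t0) = v0
# under dV/dt = A*V - B*V^2. Vectorized over v0.
logistic_step <- function(v0, A, B, dt) {
  if (dt == 0) return(v0)
  if (A == 0) return(v0 / (1 + B * v0 * dt))
  A * v0 / (B * v0 + (A - B * v0) * exp(-A * dt))
}

# Core propagator shared by simulate_one_compartment(), the calibration
# likelihood and the posterior-predictive grid: marches the exact logistic
# solution between dose impulses, applying V <- SF * V at each fraction.
# `beta` may be a vector (one trajectory per value); returns a
# length(eval_days) x length(beta) matrix of post-dose-convention volumes.
# The numerics live in C++ (cpp_predict_1c); predict_grid_1c_r below is the
# plain-R reference implementation kept for cross-checks.
predict_grid_1c <- function(A, B, alpha, beta, schedule, V0, eval_days,
                            t0 = 0) {
  stopifnot(V0 > 0, all(eval_days >= t0))
  ord <- order(eval_days)
  dose <- if (nrow(schedule)) schedule$dose[1] else 0
  out <- cpp_predict_1c(A, B, alpha, as.numeric(beta),
                        sort(as.numeric(schedule$day)), dose, V0,
                        as.numeric(eval_days)[ord], t0)
  out[order(ord), , drop = FALSE]
}

predict_grid_1c_r <- function(A, B, alpha, beta, schedule, V0, eval_days,
                              t0 = 0) {
  stopifnot(V0 > 0, all(eval_days >= t0))
  eval_days <- as.numeric(eval_days)
  sf <- exp(-alpha * schedule$dose - outer(schedule$dose^2, beta))
  if (nrow(schedule) == 0) sf <- matrix(numeric(), 0, length(beta))
  out <- matrix(NA_real_, length(eval_days), length(beta))
  dose_times <- as.numeric(schedule$day)
  keep <- dose_times > t0 & dose_times <= max(eval_days, t0)
  dose_times <- dose_times[keep]
  sf <- sf[keep, , drop = FALSE]
  v <- rep(V0, length(beta))
  t_cur <- t0
  events <- c(dose_times, Inf)
  i_dose <- 1L
  for (ev in seq_along(events)) {
    t_next <- events[ev]
    in_seg <- which(eval_days >= t_cur & eval_days < t_next)
    if (length(in_seg)) {
      for (ii in in_seg)
        out[ii, ] <- logistic_step(v, A, B, eval_days[ii] - t_cur)
    }
    if (!is.finite(t_next)) break
    v <- logistic_step(v, A, B, t_next - t_cur)
    v <- v * sf[i_dose, ]
    t_cur <- t_next
    # post-dose convention: a scan on a dose day reports V(t+)
    at_dose <- which(eval_days == t_next)
    if (length(at_dose)) out[at_dose, ] <- rep(v, each = length(at_dose))
    i_dose <- i_dose + 1L
  }
  if (anyNA(out) || any(!is.finite(out)))
    abort("one-compartment propagation produced non-finite volumes")
  out
}

#' Simulate the one-compartment model under fractionated radiotherapy
#'
#' Integrates `dV/dt = A*V*(1 - (B/A)*V)` between fractions and applies the
#' instantaneous kill `V(t+) = SF * V(t-)` at each dose time. Scans falling
#' on a dose day report the post-dose volume. The default `"analytic"`
#' method propagates the exact piecewise logistic solution; `"ode"` uses an
#' adaptive integrator (deSolve, rtol 1e-8) restarted at each impulse and is
#' retained as a numerical cross-check.
#'
#' @param params A [params_one_compartment()] object.
#' @param radio A [radiosensitivity()] object.
#' @param schedule A treatment schedule from [build_schedule()].
#' @param V0 Initial tumor volume (mm^3) at `t0`.
#' @param eval_days Days at which to report the volume.
#' @param t0 Time origin of the initial condition (default 0).
#' @param method `"analytic"` (exact, default) or `"ode"`.
#' @return A trajectory tibble with columns `day` and `tumor_volume`.
#' @examples
#' p <- params_one_compartment(A = 0.2, B = 0.2 / 2)
#' simulate_one_compartment(p, radiosensitivity(0.14, 0.14),
#'                          build_schedule(15, 1, 2), V0 = 0.05,
#'                          eval_days = 1:20)
#' @export
simulate_one_compartment <- function(params, radio, schedule, V0, eval_days,
                                     t0 = 0, method = c("analytic", "ode")) {
  method <- match.arg(method)
  stopifnot(inherits(params, "params_1c"), inherits(radio, "radiosensitivity"))
  if (V0 <= 0) abort("V0 must be positive")
  if (method == "analytic") {
    v <- predict_grid_1c(params$A, params$B, radio$alpha, radio$beta,
                         schedule, V0, eval_days, t0)[, 1]
  } else {
    v <- ode_one_compartment(params, radio, schedule, V0, eval_days, t0)
  }
  tibble(day = eval_days, tumor_volume = v)
}

# deSolve path: adaptive lsoda restarted at dose impulses via events.
ode_one_compartment <- function(params, radio, schedule, V0, eval_days, t0) {
  sf <- lq_survival_fraction(radio, if (nrow(schedule)) schedule$dose[1] else 0)
  rhs <- function(t, y, p) list(p$A * y[1] - p$B * y[1]^2)
  dose_times <- schedule$day[schedule$day > t0 & schedule$day <= max(eval_days)]
  times <- sort(unique(c(t0, eval_days, dose_times)))
  ev <- NULL
  if (length(dose_times))
    ev <- list(data = data.frame(var = "V", time = dose_times,
                                 value = sf, method = "multiply"))
  sol <- deSolve::lsoda(c(V = V0), times, rhs, params, rtol = 1e-8,
                        atol = 1e-10, events = ev)
  if (attr(sol, "istate")[1] < 0) abort("ODE solver failed")
  v <- sol[match(eval_days, sol[, "time"]), "V"]
  # deSolve reports the pre-event state at event times; scans on dose days
  # follow the post-dose convention, so apply the kill to those entries
  v[eval_days %in% dose_times] <- v[eval_days %in% dose_times] * sf
  if (anyNA(v) || any(!is.finite(v))) abort("ODE solver returned non-finite volumes")
  v
}

#' Simulate the two-compartment model under fractionated radiotherapy
#'
#' Between fractions integrates the viable/necrotic system
#' `dV/dt = lambda*V*(1 - V/K) - eta*V`, `dN/dt = eta*V - zeta*N`.
#' At each dose time, irradiated viable cells move into the necrotic
#' compartment: `V(t+) = SF*V(t-)`, `N(t+) = N(t-) + (1 - SF)*V(t-)`; the
#' total `V + N` is conserved across the impulse, so radiation shows up
#' immediately in tumor composition but only with delay in total volume.
#'
#' @param params A [params_two_compartment()] object.
#' @inheritParams simulate_one_compartment
#' @param N0 Initial necrotic volume (mm^3), non-negative.
#' @return A trajectory tibble with columns `day`, `tumor_volume` (= V + N),
#'   `necrotic_volume` and `viable_volume`.
#' @export
simulate_two_compartment <- function(params, radio, schedule, V0, N0,
                                     eval_days, t0 = 0) {
  stopifnot(inherits(params, "params_2c"), inherits(radio, "radiosensitivity"))
  if (V0 <= 0) abort("V0 must be positive")
  if (N0 < 0) abort("N0 must be non-negative")
  sf <- lq_survival_fraction(radio, if (nrow(schedule)) schedule$dose[1] else 0)
  rhs <- function(t, y, p) {
    dv <- p$lambda * y[1] * (1 - y[1] / p$K) - p$eta * y[1]
    dn <- p$eta * y[1] - p$zeta * y[2]
    list(c(dv, dn))
  }
  dose_times <- schedule$day[schedule$day > t0 & schedule$day <= max(eval_days)]
  times <- sort(unique(c(t0, eval_days, dose_times)))
  ev <- NULL
  if (length(dose_times)) {
    evfun <- function(t, y, p) c((y[1]) * sf, y[2] + (1 - sf) * y[1])
    ev <- list(func = evfun, time = dose_times)
  }
  sol <- deSolve::lsoda(c(V = V0, N = N0), times, rhs, params, rtol = 1e-8,
                        atol = 1e-10, events = ev)
  if (attr(sol, "istate")[1] < 0) abort("ODE solver failed")
  idx <- match(eval_days, sol[, "time"])
  v <- sol[idx, "V"]; n <- sol[idx, "N"]
  # post-dose convention at dose-day scans (deSolve reports pre-event state;
  # the total V + N is conserved across the impulse, but the split is not)
  at_dose <- eval_days %in% dose_times
  n[at_dose] <- n[at_dose] + (1 - sf) * v[at_dose]
  v[at_dose] <- sf * v[at_dose]
  if (anyNA(v) || any(!is.finite(v)) || any(!is.finite(n)))
    abort("ODE solver returned non-finite volumes")
  tibble(day = eval_days, tumor_volume = v + n, necrotic_volume = n,
         viable_volume = v)
}

# Fixed-step RK4 propagation of the two-compartment system over a vector of
# beta draws (all other parameters shared). Backs the calibration likelihood
# and the posterior-predictive grid in the design loop, where one deSolve
# call per draw would dominate the run time; cross-checked against
# simulate_two_compartment() in the test suite. Returns
# list(tumor, necrotic) of length(eval_days) x length(beta) matrices.
predict_grid_2c <- function(params, alpha, beta, schedule, V0, N0, eval_days,
                            t0 = 0, h = 0.05) {
  stopifnot(V0 > 0, N0 >= 0, all(eval_days >= t0))
  ord <- order(eval_days)
  dose <- if (nrow(schedule)) schedule$dose[1] else 0
  out <- cpp_predict_2c(params$lambda, params$K, params$eta, params$zeta,
                        alpha, as.numeric(beta),
                        sort(as.numeric(schedule$day)), dose, V0, N0,
                        as.numeric(eval_days)[ord], t0, h)
  inv <- order(ord)
  list(tumor = out$tumor[inv, , drop = FALSE],
       necrotic = out$necrotic[inv, , drop = FALSE])
}

predict_grid_2c_r <- function(params, alpha, beta, schedule, V0, N0,
                              eval_days, t0 = 0, h = 0.05) {
  lam <- params$lambda; K <- params$K; eta <- params$eta; zeta <- params$zeta
  nb <- length(beta)
  v <- rep(V0, nb); n <- rep(N0, nb)
  eval_days <- as.numeric(eval_days)
  out_t <- matrix(NA_real_, length(eval_days), nb)
  out_n <- matrix(NA_real_, length(eval_days), nb)
  dose_times <- as.numeric(schedule$day)
  dose_times <- dose_times[dose_times > t0 & dose_times <= max(eval_days)]
  doses <- schedule$dose[match(dose_times, schedule$day)]
  events <- sort(unique(c(dose_times, eval_days)))
  t_cur <- t0
  deriv <- function(v, n) {
    dv <- lam * v * (1 - v / K) - eta * v
    list(dv = dv, dn = eta * v - zeta * n)
  }
  rk4_to <- function(v, n, dt) {
    steps <- max(1L, ceiling(dt / h))
    hh <- dt / steps
    for (s in seq_len(steps)) {
      k1 <- deriv(v, n)
      k2 <- deriv(v + hh / 2 * k1$dv, n + hh / 2 * k1$dn)
      k3 <- deriv(v + hh / 2 * k2$dv, n + hh / 2 * k2$dn)
      k4 <- deriv(v + hh * k3$dv, n + hh * k3$dn)
      v2 <- v + hh / 6 * (k1$dv + 2 * k2$dv + 2 * k3$dv + k4$dv)
      n2 <- n + hh / 6 * (k1$dn + 2 * k2$dn + 2 * k3$dn + k4$dn)
      v <- v2; n <- n2
    }
    list(v = v, n = n)
  }
  for (te in events) {
    if (te > t_cur) {
      st <- rk4_to(v, n, te - t_cur)
      v <- st$v; n <- st$n
      t_cur <- te
    }
    di <- match(te, dose_times)
    if (!is.na(di)) {
      d <- doses[di]
      sf <- exp(-alpha * d - beta * d^2)
      n <- n + (1 - sf) * v
      v <- sf * v
    }
    ii <- which(eval_days == te)
    if (length(ii)) {
      out_t[ii, ] <- rep(v + n, each = length(ii))
      out_n[ii, ] <- rep(n, each = length(ii))
    }
  }
  list(tumor = out_t, necrotic = out_n)
}

#' Relative L2 calibration error between trajectories
#'
#' `||d_h - d_l||_2 / ||d_h||_2` over all shared days, where `d_h` is the
#' high-fidelity series and `d_l` the low-fidelity approximation. Because the
#' error runs over the full horizon (not just calibrated scans) it doubles
#' as a measure of predictive power.
#'
#' @param high,low Trajectory tibbles on the same day grid.
#' @param metric Column to compare (default `"tumor_volume"`).
#' @return Non-negative scalar.
#' @examples
#' a <- tibble::tibble(day = 1:2, tumor_volume = c(1, 1))
#' b <- tibble::tibble(day = 1:2, tumor_volume = c(1, 0))
#' relative_error(a, b)  # 1/sqrt(2)
#' @export
relative_error <- function(high, low, metric = "tumor_volume") {
  stopifnot(metric %in% names(high), metric %in% names(low))
  if (!identical(as.numeric(high$day), as.numeric(low$day)))
    abort("high and low trajectories must share the same day grid")
  dh <- high[[metric]]
  dl <- low[[metric]]
  denom <- sqrt(sum(dh^2))
  if (denom == 0) abort("high-fidelity series is identically zero")
  sqrt(sum((dh - dl)^2)) / denom
}
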