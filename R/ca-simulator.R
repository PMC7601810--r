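#' Cellular-automaton simulator parameters
#'
#' Configuration of the hybrid cellular automaton used as the high-fidelity
#' data generator: a 2-D square cross-section through an in-vitro tumor
#' spheroid, with one lattice site per cell diameter. Oxygen is the single
#' growth-limiting nutrient, solved to quasi-steady state every hour with
#' per-cell consumption; its local level drives the proliferating (P) /
#' quiescent (Q) / necrotic (N) state transitions.
#'
#' Oxygen is non-dimensionalized by the far-field concentration, so the
#' thresholds `c_Q` and `c_N` are fractions of the boundary value. The
#' consumption rates are expressed as the dimensionless per-site sink of the
#' discrete diffusion equation at the reference site size of 18 um, and are
#' rescaled internally by `(dx/18um)^2` so that coarser lattices represent
#' the same physical tumor.
#'
#' @param lattice_n Sites per side (default 100, i.e. 36 um sites — a
#'   coarse-grained two-cell-diameter site at the default domain size).
#'   Note that automaton growth speed is resolution-dependent (the rim
#'   advances about one site per cell cycle), so the packaged growth
#'   calibration is tied to this default resolution.
#' @param domain_cm Physical side length of the square domain in cm
#'   (default 0.36).
#' @param c_inf Far-field oxygen concentration (dimensionless, default 1).
#' @param c_Q Quiescence threshold as a fraction of `c_inf` (default 0.65).
#' @param c_N Necrosis threshold as a fraction of `c_inf` (default 0.45);
#'   must be below `c_Q`.
#' @param p_lysis Lysis probability per necrotic cell per hour (default
#'   0.04, i.e. necrotic material is cleared within about a day, so
#'   radiation kill registers promptly in the measured volume).
#' @param cycle_hours Mean cell-cycle duration in hours (default 56; with
#'   crowding delays this reproduces a tumor volume doubling time of a few
#'   days, and balances the 2 Gy daily kill so that the low-sensitivity
#'   reference tumor barely responds over the course).
#' @param cycle_jitter Relative half-width of the uniform cycle-length
#'   jitter (default 0.2, i.e. 56 h +/- 20%).
#' @param uptake_P Dimensionless oxygen consumption per proliferating cell
#'   per site at the 18 um reference spacing (default 3e-4, placing
#'   quiescence onset near a 0.6 mm spheroid radius and necrosis onset near
#'   0.9 mm).
#' @param uptake_Q Consumption of quiescent cells; fixed at half the
#'   proliferating rate.
#' @param contact_inhibition If `TRUE` (default), the division probability
#'   is scaled by `(8 - occupied Moore neighbors)/8`.
#' @param init_radius_mm Radius of the initial circular seed of
#'   proliferating cells (default 0.2 mm).
#' @param radio A [radiosensitivity()] object used when radiation is applied
#'   (default the high-sensitivity scenario).
#' @param oxygen_tol Convergence tolerance of the oxygen relaxation solver.
#' @param oxygen_max_iter Maximum relaxation sweeps before erroring.
#' @return A list of class `ca_params`.
#' @export
ca_params <- function(lattice_n = 100, domain_cm = 0.36, c_inf = 1,
                      c_Q = 0.65, c_N = 0.45, p_lysis = 0.04,
                      cycle_hours = 56, cycle_jitter = 0.2,
                      uptake_P = 3e-4, uptake_Q = uptake_P / 2,
                      contact_inhibition = TRUE, init_radius_mm = 0.2,
                      radio = scenario_radiosensitivity("high"),
                      oxygen_tol = 1e-7, oxygen_max_iter = 100000) {
  if (lattice_n < 10) abort("lattice_n must be at least 10")
  if (c_N >= c_Q) abort("c_N must be below c_Q")
  if (p_lysis < 0 || p_lysis > 1) abort("p_lysis must be in [0, 1]")
  if (!isTRUE(all.equal(uptake_Q, uptake_P / 2)))
    abort("quiescent cells consume oxygen at half the proliferating rate")
  dx_mm <- domain_cm * 10 / lattice_n
  structure(list(
    lattice_n = lattice_n, domain_cm = domain_cm, dx_mm = dx_mm,
    c_inf = c_inf, c_Q = c_Q * c_inf, c_N = c_N * c_inf,
    p_lysis = p_lysis, cycle_hours = cycle_hours,
    cycle_jitter = cycle_jitter,
    # rescale the per-site sink so physics is invariant to lattice spacing
    uptake_P = uptake_P * (dx_mm / 0.018)^2,
    uptake_Q = uptake_Q * (dx_mm / 0.018)^2,
    contact_inhibition = contact_inhibition,
    init_radius_mm = init_radius_mm, radio = radio,
    oxygen_tol = oxygen_tol, oxygen_max_iter = oxygen_max_iter
  ), class = "ca_params")
}

#' Initialize a spheroid on the lattice
#'
#' Plants a circular seed of proliferating cells at the lattice center with
#' uniformly staggered cycle clocks; oxygen starts at the far-field level
#' everywhere. A radius of zero places a single cell.
#'
#' @param params A [ca_params()] object.
#' @param radius_sites Seed radius in lattice sites; defaults to
#'   `init_radius_mm` converted to sites.
#' @return A CA state: list with integer matrix `grid` (0 = empty,
#'   1 = proliferating, 2 = quiescent, 3 = necrotic), numeric matrices
#'   `oxygen`, `clock`, `cyclen`, and hour counter `t`.
#' @export
init_spheroid <- function(params, radius_sites = NULL) {
  stopifnot(inherits(params, "ca_params"))
  if (is.null(radius_sites))
    radius_sites <- params$init_radius_mm / params$dx_mm
  st <- cpp_init_spheroid(params$lattice_n, radius_sites, params$c_inf,
                          params$cycle_hours, params$cycle_jitter)
  st$t <- 0
  structure(st, class = "ca_state")
}

#' Solve the quasi-steady oxygen field
#'
#' Dirichlet diffusion-consumption solve on the current occupancy:
#' proliferating cells consume at the full rate, quiescent at half, necrotic
#' and empty sites not at all; the domain edge is held at the far-field
#' concentration.
#'
#' @param state A CA state from [init_spheroid()].
#' @param params A [ca_params()] object.
#' @return The state with an updated `oxygen` field.
#' @export
ca_update_oxygen <- function(state, params) {
  state$oxygen <- cpp_solve_oxygen(state$grid, state$oxygen, params$uptake_P,
                                   params$uptake_Q, params$c_inf, params$c_Q,
                                   params$c_N, params$oxygen_tol,
                                   params$oxygen_max_iter)
  state
}

#' Reclassify cell states from the oxygen field
#'
#' Occupied sites become proliferating above `c_Q`, quiescent between the
#' thresholds, and necrotic at or below `c_N`; necrosis is irreversible.
#'
#' @inheritParams ca_update_oxygen
#' @return The state with an updated `grid`.
#' @export
ca_classify <- function(state, params) {
  state$grid <- cpp_classify(state$grid, state$oxygen, params$c_Q, params$c_N)
  state
}

#' Advance the automaton by one time step
#'
#' Proliferating cells accumulate cycle time and divide when their clock
#' completes, subject to contact inhibition; the daughter is placed by
#' shifting a chain of cells outward toward the nearest empty site
#' (cell-cell adhesion). Each necrotic cell lyses with probability
#' `p_lysis * dt`, pulling a boundary chain inward to fill its site.
#'
#' @inheritParams ca_update_oxygen
#' @param dt_h Step length in hours (default 1).
#' @return The updated state.
#' @export
ca_step <- function(state, params, dt_h = 1) {
  out <- cpp_step_cells(state$grid, state$clock, state$cyclen, dt_h,
                        params$p_lysis, params$cycle_hours,
                        params$cycle_jitter, params$contact_inhibition)
  state$grid <- out$grid
  state$clock <- out$clock
  state$cyclen <- out$cyclen
  state$t <- state$t + dt_h
  state
}

#' Apply an impulsive radiation dose to the lattice
#'
#' Every living (P or Q) cell independently converts to a necrotic cell with
#' probability `1 - exp(-alpha*d - beta*d^2)`; necrotic and empty sites are
#' unaffected.
#'
#' @inheritParams ca_update_oxygen
#' @param dose Dose in Gy.
#' @return The updated state.
#' @export
ca_apply_rt <- function(state, dose, params) {
  if (dose < 0) abort("dose must be non-negative")
  sf <- lq_survival_fraction(params$radio, dose)
  state$grid <- cpp_apply_rt(state$grid, sf)
  state
}

#' Measure the tumor cross-section
#'
#' Extracts the occupied extents `h` (horizontal) and `v` (vertical) through
#' the tumor center and converts to an ellipsoid volume
#' `V = 0.5 * h * v^2` (mm^3); the necrotic volume is the total scaled by
#' the necrotic area fraction.
#'
#' @param state A CA state.
#' @param params A [ca_params()] object.
#' @return A one-row tibble with cell counts, extents, areas and volumes.
#' @export
ca_measure <- function(state, params) {
  m <- cpp_measure(state$grid, params$dx_mm)
  as_tibble(m[c("n_p", "n_q", "n_n", "h_mm", "v_mm", "total_area",
                "necrotic_area", "total_volume", "necrotic_volume")])
}

#' Run the cellular automaton through a treatment course
#'
#' Simulates daily tumor growth from day 1 through `horizon` days. On each
#' scheduled dose day the radiation kill is applied at the start of the day;
#' the automaton then advances 24 hourly sub-steps (oxygen solve, state
#' classification, division and lysis) and is measured at the end of the
#' day, so scans on dose days reflect the post-dose state.
#'
#' @param params A [ca_params()] object (its `radio` field sets the
#'   radiosensitivity).
#' @param schedule Treatment schedule from [build_schedule()]; use
#'   `build_schedule(n_weeks = 0)` for untreated growth.
#' @param seed Optional integer seed for reproducibility.
#' @param horizon Last simulated day (default 57, covering the day-6 scan of
#'   treatment week 6 at day 55 with margin).
#' @return A tibble of class `ca_output` with one row per day: `day`,
#'   `tumor_volume`, `necrotic_volume` (mm^3), extents `h_mm`, `v_mm`, and
#'   raw state counts `n_p`, `n_q`, `n_n`.
#' @examples
#' \donttest{
#' traj <- run_ca(ca_params(lattice_n = 60), build_schedule(n_weeks = 0),
#'                seed = 1, horizon = 10)
#' }
#' @export
run_ca <- function(params = ca_params(), schedule = build_schedule(),
                   seed = NULL, horizon = 57) {
  stopifnot(inherits(params, "ca_params"))
  if (!is.null(seed)) set.seed(seed)
  dose <- if (nrow(schedule)) schedule$dose[1] else 0
  sf <- lq_survival_fraction(params$radio, dose)
  out <- cpp_run_ca(params$lattice_n, params$init_radius_mm / params$dx_mm,
                    params$c_inf, params$c_Q, params$c_N, params$uptake_P,
                    params$uptake_Q, params$p_lysis, params$cycle_hours,
                    params$cycle_jitter, params$contact_inhibition,
                    as.integer(schedule$day), sf, horizon, params$dx_mm,
                    params$oxygen_tol, params$oxygen_max_iter)
  res <- tibble(day = out$day, tumor_volume = out$total_volume,
                necrotic_volume = out$necrotic_volume, h_mm = out$h_mm,
                v_mm = out$v_mm, n_p = out$n_p, n_q = out$n_q, n_n = out$n_n)
  class(res) <- c("ca_output", class(res))
  res
}

#' Generate high-fidelity data for a named radiosensitivity scenario
#'
#' Convenience wrapper around [run_ca()] for the three reference tumors
#' (`alpha = 0.14` with `beta` 0.14, 0.0467 or 0.0156) under the standard
#' 2 Gy Monday-to-Friday six-week course.
#'
#' @param scenario One of `"high"`, `"medium"`, `"low"`.
#' @param schedule Treatment schedule (default [build_schedule()]).
#' @param seed Optional integer seed.
#' @param params Base [ca_params()]; its `radio` field is replaced by the
#'   scenario's parameters.
#' @param horizon Last simulated day.
#' @return A `ca_output` tibble (see [run_ca()]).
#' @export
run_scenario <- function(scenario = c("high", "medium", "low"),
                         schedule = build_schedule(), seed = NULL,
                         params = ca_params(), horizon = 57) {
  scenario <- match.arg(scenario)
  params$radio <- scenario_radiosensitivity(scenario)
  run_ca(params, schedule, seed = seed, horizon = horizon)
}
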