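#' Fixed pre-treatment growth parameters (one-compartment)
#'
#' The design loop calibrates only the radiosensitivity parameter `beta`;
#' the pre-treatment growth parameters are assumed to have been identified
#' before the treatment course begins and are held fixed throughout. The
#' packaged values are synthetic-calibration stand-ins: they were fit once,
#' by least squares on log volume, to a set of packaged-simulator runs
#' (untreated trajectories plus treated trajectories of all three
#' radiosensitivity scenarios, sharing one growth parameterization with a
#' free per-scenario beta), and then frozen. Override them to match other
#' data sources.
#'
#' @return Named list with `A` (1/day), `B` (1/(day mm^3)) and the initial
#'   volume `V0` (mm^3) at day 0.
#' @export
default_pretreatment_1c <- function() {
  list(A = 0.17868, B = 0.22990, V0 = 0.00884)
}

#' Fixed pre-treatment growth parameters (two-compartment)
#'
#' See [default_pretreatment_1c()]. The viable-compartment parameters
#' derive from the same untreated-simulator fit (`lambda = A + eta`,
#' `K = lambda/B`); spontaneous necrosis is minor in the simulated
#' spheroids over this horizon, so `eta` is set to a small nominal rate,
#' and the necrotic decay `zeta` matches the simulator's lysis rate
#' (0.04/h, i.e. 0.96/day).
#'
#' @return Named list with `lambda`, `eta`, `zeta` (1/day), `K` (mm^3),
#'   `V0` and `N0` (mm^3) at day 0.
#' @export
default_pretreatment_2c <- function() {
  list(lambda = 0.18368, K = 0.7989, eta = 0.005, zeta = 0.96,
       V0 = 0.00884, N0 = 0)
}
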