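#' Read a trajectory CSV
#'
#' The exchange format for tumor time series: columns `day`, `tumor_volume`
#' and optionally `necrotic_volume` (mm^3). Days must be strictly
#' increasing and volumes non-negative.
#'
#' @param path CSV file path.
#' @return A trajectory tibble.
#' @export
read_trajectory <- function(path) {
  tr <- readr::read_csv(path, show_col_types = FALSE)
  req <- c("day", "tumor_volume")
  missing <- setdiff(req, names(tr))
  if (length(missing))
    abort(paste("trajectory file lacks required column(s):",
                paste(missing, collapse = ", ")))
  if (is.unsorted(tr$day, strictly = TRUE))
    abort("trajectory days must be strictly increasing")
  vols <- intersect(c("tumor_volume", "necrotic_volume"), names(tr))
  for (v in vols)
    if (any(tr[[v]] < 0, na.rm = TRUE)) abort("volumes must be non-negative")
  tr
}

#' Write a trajectory CSV
#'
#' @param traj Trajectory tibble (columns `day`, `tumor_volume`, optionally
#'   `necrotic_volume`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  keep <- intersect(c("day", "tumor_volume", "necrotic_volume"), names(traj))
  readr::write_csv(traj[keep], path)
  invisible(path)
}

#' Read a run configuration file
#'
#' Flat YAML key-value configuration for [run_experiment()]; unknown keys
#' are rejected so every default remains auditable.
#'
#' @param path YAML file path.
#' @return A named list merged over the packaged defaults.
#' @export
read_run_config <- function(path) {
  defaults <- default_run_config()
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown))
    abort(paste("unknown config key(s):", paste(unknown, collapse = ", ")))
  out <- utils::modifyList(defaults, cfg)
  validate_run_config(out)
  out
}

#' Default run configuration
#'
#' @return Named list of every experiment setting with its default.
#' @export
default_run_config <- function() {
  list(
    design = "sequential",       # or "weekly"
    model = "one",               # or "two"
    scenarios = c("high", "medium", "low"),
    k = c(0, 0.2, 0.5, 1),
    budget = 12,
    free_tumor = FALSE,
    seeds = 1,
    lattice_n = 200,
    n_iter = 10000,
    n_mi = 1000,
    k_neighbors = 6,
    horizon = 57,
    first_treatment_day = 15,
    n_weeks = 6,
    dose = 2,
    out_dir = NULL
  )
}

validate_run_config <- function(cfg) {
  if (!cfg$design %in% c("sequential", "weekly"))
    abort("design must be 'sequential' or 'weekly'")
  if (!cfg$model %in% c("one", "two")) abort("model must be 'one' or 'two'")
  if (!all(cfg$scenarios %in% c("high", "medium", "low")))
    abort("scenarios must be among high, medium, low")
  if (any(cfg$k < 0 | cfg$k > 1)) abort("k must lie in [0, 1]")
  if (cfg$budget < 1) abort("budget must be at least 1")
  invisible(cfg)
}

#' Run a full scan-design experiment
#'
#' Generates (or reuses) high-fidelity data for each radiosensitivity
#' scenario and seed, runs the requested design over the `k` grid, and
#' returns per-run design histories plus a summary table of final `beta`
#' estimates and relative errors (rows = radiosensitivity scenario,
#' one row per `k` and seed). When `out_dir` is set, per-run history CSVs
#' and the summary are written there.
#'
#' @param config Named list as from [read_run_config()] or
#'   [default_run_config()]; missing entries take their defaults.
#' @param ca_data Optional named list of pre-generated trajectories (names
#'   = scenario); when absent the cellular automaton is run per scenario
#'   and seed.
#' @return A list of class `experiment_report` with `summary` (tibble) and
#'   `histories` (nested list scenario -> k -> seed).
#' @export
run_experiment <- function(config = list(), ca_data = NULL) {
  cfg <- utils::modifyList(default_run_config(), config)
  validate_run_config(cfg)
  sched <- build_schedule(cfg$first_treatment_day, cfg$n_weeks, cfg$dose)
  histories <- list()
  rows <- list()
  for (sc in cfg$scenarios) {
    for (seed in cfg$seeds) {
      traj <- if (!is.null(ca_data)) ca_data[[sc]]
      else run_scenario(sc, sched, seed = seed,
                        params = ca_params(lattice_n = cfg$lattice_n),
                        horizon = cfg$horizon)
      for (kk in cfg$k) {
        res <- tryCatch({
          if (cfg$design == "weekly")
            weekly_design(traj, schedule = sched, n_weeks = cfg$n_weeks,
                          first_treatment_day = cfg$first_treatment_day,
                          n_iter = cfg$n_iter, n_mi = cfg$n_mi,
                          k_neighbors = cfg$k_neighbors,
                          seed = seed)
          else
            sequential_design(traj, model = cfg$model, budget = cfg$budget,
                              k = kk, free_tumor = cfg$free_tumor,
                              schedule = sched, n_iter = cfg$n_iter,
                              n_mi = cfg$n_mi, k_neighbors = cfg$k_neighbors,
                              seed = seed)
        }, error = function(e) e)
        key <- paste(sc, kk, seed, sep = "_")
        histories[[key]] <- res
        if (inherits(res, "error")) {
          warn(paste("design run failed for", key, ":",
                     conditionMessage(res)))
          rows[[key]] <- tibble(scenario = sc, k = kk, seed = seed,
                                failed = TRUE)
        } else {
          g <- glance(res)
          rows[[key]] <- dplyr::bind_cols(
            tibble(scenario = sc, k = kk, seed = seed, failed = FALSE),
            g[c("beta_hat", "beta_q25", "beta_q75", "rel_error", "n_scans")])
          if (!is.null(cfg$out_dir)) {
            dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
            readr::write_csv(tidy(res),
                             file.path(cfg$out_dir,
                                       paste0("history_", key, ".csv")))
          }
        }
        if (cfg$design == "weekly") break  # weekly ignores the k grid
      }
    }
  }
  summary <- dplyr::bind_rows(rows)
  if (!is.null(cfg$out_dir))
    readr::write_csv(summary, file.path(cfg$out_dir, "summary.csv"))
  structure(list(summary = summary, histories = histories, config = cfg),
            class = "experiment_report")
}

#' @export
print.experiment_report <- function(x, ...) {
  cat("scan-design experiment:", x$config$design, "design,",
      x$config$model, "compartment model\n")
  print(x$summary, ...)
  invisible(x)
}
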