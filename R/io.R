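#' Load a parameter configuration
#'
#' Reads a flat key-value YAML (or JSON, which YAML parses) configuration
#' into an [electrocyte_params()] object.  Keys must be a subset of the
#' `electrocyte_params()` argument names; unknown keys are rejected with
#' an itemized error.  The name `"epm-default"` resolves to the default
#' profile shipped with the package.
#'
#' @param path path to a YAML/JSON file, or the profile name
#'   `"epm-default"`
#' @return an `electrocyte_params` object
#' @export
load_params_config <- function(path) {
  if (identical(path, "epm-default"))
    path <- system.file("extdata", "epm-default.yaml",
                        package = "electrocyte", mustWork = TRUE)
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  allowed <- names(formals(electrocyte_params))
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown))
    stop("unknown configuration keys:\n  - ",
         paste(unknown, collapse = "\n  - "), call. = FALSE)
  do.call(electrocyte_params, cfg)
}

#' Write a parameter set as a YAML profile
#'
#' @param params an [electrocyte_params()] object
#' @param path output path
#' @return `path`, invisibly
#' @export
write_params_config <- function(params, path) {
  stopifnot(inherits(params, "electrocyte_params"))
  yaml::write_yaml(unclass(params), path, precision = 15)
  invisible(path)
}

#' Load a stimulus-regime configuration
#'
#' Reads a YAML regime description with optional keys `background`
#' (steady syn_clamp level), `amplitude` and `frequency` (pulsatile
#' component) and `clamp` (a mapping with `kind`, `amplitude`, `duration`
#' and optional `start`, `width`, `frequency`).
#'
#' @param path path to a YAML file
#' @return a [stimulus_regime()]
#' @export
load_regime_config <- function(path) {
  if (!file.exists(path)) stop("regime file not found: ", path)
  cfg <- yaml::read_yaml(path)
  allowed <- c("background", "amplitude", "frequency", "clamp")
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown))
    stop("unknown regime keys:\n  - ", paste(unknown, collapse = "\n  - "),
         call. = FALSE)
  clamp <- NULL
  if (!is.null(cfg$clamp))
    clamp <- do.call(current_clamp, cfg$clamp)
  stimulus_regime(amplitude = cfg$amplitude %||% 0,
                  frequency = cfg$frequency,
                  background = cfg$background %||% 0,
                  clamp = clamp)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Export a trajectory as CSV
#'
#' Writes the time series with explicitly united column names
#' (`t_ms`, `V_mV`, gating variables, and the current breakdown in nA)
#' preceded by a `#`-prefixed header comment stating the sign convention.
#'
#' @param traj a `membrane_trajectory`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_trajectory_csv <- function(traj, path) {
  df <- data.frame(t_ms = traj$t, V_mV = traj$v, m = traj$m, h = traj$h,
                   n = traj$n, I_NaT_nA = traj$i_na_t,
                   I_NaP_nA = traj$i_na_p, I_K_nA = traj$i_k,
                   I_L_nA = traj$i_leak, I_AChR_Na_nA = traj$i_achr_na,
                   I_AChR_K_nA = traj$i_achr_k, I_clamp_nA = traj$i_clamp)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# membrane trajectory; currents in nA, positive outward;",
    "# I_clamp positive depolarizing; t in ms, V in mV"), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Export a spike train or entry tally as JSON
#'
#' @param x a `spike_train` or `entry_tally`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_result_json <- function(x, path) {
  obj <- if (inherits(x, "entry_tally")) unclass(x)
         else as.list(as.data.frame(x))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Generate reference fixture files
#'
#' Writes, under `dir`: one YAML regime file per cost-table row
#' (`regime-01.yaml` ... `regime-18.yaml`), a staircase scan description
#' (`staircase-scan.yaml`), and short golden trajectory CSVs for the
#' standard 200 Hz and 600 Hz pulsatile runs (`golden-200hz.csv`,
#' `golden-600hz.csv`, 10 ms each).  All content is generated
#' deterministically from the package's own defaults, so repeated calls
#' produce byte-identical files.
#'
#' @param dir output directory (created if needed)
#' @param params an [electrocyte_params()] object
#' @return character vector of the files written, invisibly
#' @export
generate_fixtures <- function(dir, params = electrocyte_params()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  regimes <- cost_table_regimes()
  for (i in seq_len(nrow(regimes))) {
    rg <- regimes[i, ]
    f <- file.path(dir, sprintf("regime-%02d.yaml", rg$row))
    cfg <- list(background = rg$background)
    if (rg$amplitude > 0) {
      cfg$amplitude <- rg$amplitude
      cfg$frequency <- rg$target_hz
    }
    yaml::write_yaml(cfg, f, precision = 15)
    written <- c(written, f)
  }
  f <- file.path(dir, "staircase-scan.yaml")
  yaml::write_yaml(list(background = 0.00736, frequency = 200,
                        amplitude_min = 0, amplitude_max = 0.5,
                        amplitude_step = 0.005), f, precision = 15)
  written <- c(written, f)
  for (spec in list(list(hz = 200, g = 700), list(hz = 600, g = 1126))) {
    p <- params; p$g_na_max <- spec$g
    traj <- simulate_membrane(p, stimulus_regime(amplitude = 1,
                                                 frequency = spec$hz),
                              duration = 10)
    f <- file.path(dir, sprintf("golden-%dhz.csv", spec$hz))
    write_trajectory_csv(traj, f)
    written <- c(written, f)
  }
  invisible(written)
}
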