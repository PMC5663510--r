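#' Scenario presets
#'
#' Named configurations for the standard study scenarios: the
#' high/low-initial-state time series at `theta = 2, mu = 9`
#' (`"fig1a"`/`"fig1b"`), the unique-attractor case at
#' `theta = 0.25, mu = 3.5` (`"fig1c"`), mortality sweeps at `theta = 2`
#' (`"fig2a"`) and `theta = 0.25` (`"fig2b"`), the two-parameter boundary
#' diagram (`"fig3"`) and the life-history case `theta = 1, mu = 8`
#' (`"fig4"`).
#'
#' @param name Preset name.
#' @return A resolved run configuration (see [load_run_config()]).
#' @examples
#' preset_config("fig4")$parameters$theta
#' @export
preset_config <- function(name = c("fig1a", "fig1b", "fig1c", "fig2a",
                                   "fig2b", "fig3", "fig4")) {
  name <- match.arg(name)
  base <- list(
    fig1a = list(parameters = list(theta = 2, mu = 9),
                 initial_state = list(R = 1, J = 0.2, A = 0.2, B = 0)),
    fig1b = list(parameters = list(theta = 2, mu = 9),
                 initial_state = list(R = 1, J = 0.01, A = 0.01, B = 0)),
    fig1c = list(parameters = list(theta = 0.25, mu = 3.5),
                 initial_state = list(R = 1, J = 0.2, A = 0.2, B = 0)),
    fig2a = list(parameters = list(theta = 2, mu = 0.1),
                 grids = list(mu = seq(0.1, 10.5, by = 0.1))),
    fig2b = list(parameters = list(theta = 0.25, mu = 0.1),
                 grids = list(mu = seq(0.1, 5.5, by = 0.1))),
    fig3 = list(parameters = list(theta = 1, mu = 0.1),
                grids = list(theta = c(0.25, 0.5, 0.75, 1, 1.5, 2))),
    fig4 = list(parameters = list(theta = 1, mu = 8),
                grids = list(tm = seq(0, 1, length.out = 401)))
  )[[name]]
  base$scenario <- name
  resolve_run_config(base)
}

config_fields <- list(
  scenario = "character",
  parameters = c("theta", "mu", "rho", "Kr", "Imax", "Q", "sigma", "z"),
  initial_state = c("R", "J", "A", "B"),
  solver = c("rtol", "atol", "method", "n_max", "tol_fix", "ext_tol",
             "conv_run", "tol_eig"),
  grids = c("mu", "theta", "tm"),
  output = c("dir", "formats")
)

# fill defaults and validate a raw config list
resolve_run_config <- function(cfg) {
  bad <- setdiff(names(cfg), names(config_fields))
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  for (sect in c("parameters", "initial_state", "solver", "grids",
                 "output")) {
    extra <- setdiff(names(cfg[[sect]]), config_fields[[sect]])
    if (length(extra))
      stop("unknown key(s) in `", sect, "`: ",
           paste(extra, collapse = ", "), call. = FALSE)
  }
  if (is.null(cfg$parameters$theta) || is.null(cfg$parameters$mu))
    stop("config must set parameters$theta and parameters$mu explicitly",
         call. = FALSE)
  p <- do.call(cr_params, cfg$parameters)
  ctrl_args <- cfg$solver %||% list()
  ctrl <- do.call(cr_control, ctrl_args)
  s0 <- cfg$initial_state %||% list(R = 1, J = 0.2, A = 0.2, B = 0)
  s0 <- do.call(season_state, s0)
  list(scenario = cfg$scenario %||% "custom",
       parameters = p, initial_state = s0, solver = ctrl,
       grids = cfg$grids %||% list(),
       output = cfg$output %||% list(dir = ".", formats = c("csv", "json")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Load a run configuration from a YAML file
#'
#' Reads, validates and resolves a configuration: unknown keys are
#' rejected with field-level messages, unspecified parameters fall back to
#' the model's standard defaults, and `theta`/`mu` must be given
#' explicitly (they are the parameters analyses vary).
#'
#' @param path Path to a YAML file.
#' @return A resolved configuration list: `scenario`, `parameters`
#'   ([cr_params()]), `initial_state`, `solver` ([cr_control()]), `grids`,
#'   `output`.
#' @seealso [write_run_config()] for echoing the resolved configuration
#'   next to results; the two round-trip.
#' @export
load_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  resolve_run_config(cfg)
}

#' Write a resolved run configuration as YAML
#'
#' @param config A resolved configuration from [load_run_config()] or
#'   [preset_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(config, path) {
  out <- list(scenario = config$scenario,
              parameters = unclass(config$parameters),
              initial_state = as.list(config$initial_state),
              solver = unclass(config$solver),
              grids = config$grids,
              output = config$output)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Write result tables and summaries to files
#'
#' Dispatches on the result class and writes CSV tables with a fixed
#' column order plus a JSON summary; identical inputs produce
#' byte-identical CSV bodies (no timestamps, fixed 12-significant-digit
#' serialisation of the JSON summary).
#'
#' @param result A `season_iteration`, `cr_branches`, `cr_boundaries`,
#'   `r0_curve` or `cohort_trajectory` object.
#' @param dir Output directory (created if missing).
#' @param stem File-name stem; defaults to the result class.
#' @return Character vector of the files written, invisibly.
#' @export
write_outputs <- function(result, dir = ".", stem = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cls <- class(result)[1]
  if (is.null(stem)) stem <- cls
  csv <- file.path(dir, paste0(stem, ".csv"))
  json <- file.path(dir, paste0(stem, ".json"))
  summarise <- function(x) lapply(x, function(v)
    if (is.numeric(v)) signif(v, 12) else v)
  if (inherits(result, "season_iteration")) {
    readr::write_csv(result$seasons, csv)
    smry <- list(schema = "pulsecr/1", type = "season_iteration",
                 flag = result$flag,
                 final_state = as.list(result$final_state),
                 n_seasons = nrow(result$seasons))
  } else if (inherits(result, "cr_branches") ||
             inherits(result, "cr_boundaries")) {
    readr::write_csv(tibble::as_tibble(result), csv)
    smry <- list(schema = "pulsecr/1", type = cls, n_rows = nrow(result))
    if (inherits(result, "cr_boundaries"))
      smry$n_bistable <- sum(result$bistable, na.rm = TRUE)
  } else if (inherits(result, "r0_curve")) {
    readr::write_csv(tibble::as_tibble(result), csv)
    smry <- c(list(schema = "pulsecr/1", type = cls,
                   mode = attr(result, "mode")),
              as.list(r0_features(result)))
  } else if (inherits(result, "cohort_trajectory")) {
    readr::write_csv(tibble::as_tibble(result), csv)
    smry <- list(schema = "pulsecr/1", type = cls,
                 mode = attr(result, "mode"),
                 peak_B = attr(result, "peak_B"),
                 juvenile_depletion = attr(result, "juvenile_depletion"))
  } else {
    stop("no output writer for class ", cls, call. = FALSE)
  }
  jsonlite::write_json(summarise(smry), json, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(c(csv, json))
}
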