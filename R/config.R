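#' Default run configuration
#'
#' The full nested configuration with every field at its default: display
#' geometry, condition, truncated-noise parameters, competition-dynamics
#' parameters, pool accounting, and campaign settings.
#'
#' @return Nested list of defaults.
#' @export
default_config <- function() {
  list(
    condition = list(
      experiment = "exp1",
      background = "gray",
      swap_rate = 3.75,
      trial_duration = 70,
      settle_duration = 10
    ),
    geometry = list(
      box_side = 4.5,
      disk_diameter = 1.5,
      annulus_outer_diameter = 1.75,
      disk_center_offsets = c(1.5, -1.5),
      raster_resolution = 40
    ),
    noise = list(sigma = 1, lower = -0.35, upper = 0.35),
    dynamics = list(
      gain = 1.3, gain_bias = 0.55,
      dt = 0.25, adaptation_update = 0.01, base_step = 0.001,
      tau_d = 2.5, tau_r = 1.5,
      switch_rule = "carry", gain_in_store = FALSE
    ),
    accounting = list(background_extent = "full_box_plus_swap",
                      eyes = "both"),
    campaign = list(n_runs = 100, seed = 1),
    verbosity = "info"
  )
}

merge_config <- function(defaults, overrides, path = character(0)) {
  for (key in names(overrides)) {
    here <- paste(c(path, key), collapse = ".")
    if (!key %in% names(defaults)) {
      stop(sprintf("config: unknown key '%s'", here), call. = FALSE)
    }
    if (is.list(defaults[[key]]) && !is.null(names(defaults[[key]]))) {
      if (!is.list(overrides[[key]])) {
        stop(sprintf("config: key '%s' must be a block", here), call. = FALSE)
      }
      defaults[[key]] <- merge_config(defaults[[key]], overrides[[key]],
                                      c(path, key))
    } else {
      defaults[[key]] <- overrides[[key]]
    }
  }
  defaults
}

#' Load and validate a run configuration
#'
#' Reads a JSON configuration file, fills every omitted field with its
#' default, rejects unknown keys (naming the offending key, so typos fail
#' loudly), and validates the result through the parameter constructors. An
#' empty file yields the full default configuration.
#'
#' @param path Path to a JSON configuration file.
#' @return An object of class `run_config`: the merged configuration plus
#'   constructed `noise`, `dynamics`, `accounting` and `condition` objects.
#' @examples
#' f <- tempfile(fileext = ".json")
#' writeLines('{"dynamics": {"tau_r": 1.5}}', f)
#' cfg <- load_config(f)
#' cfg$dynamics$tau_r
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("config: file '%s' does not exist", path), call. = FALSE)
  }
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  overrides <- if (!nzchar(trimws(txt))) {
    list()
  } else {
    tryCatch(jsonlite::fromJSON(txt, simplifyVector = TRUE),
             error = function(e) {
               stop(sprintf("config: cannot parse '%s': %s", path,
                            conditionMessage(e)), call. = FALSE)
             })
  }
  cfg <- merge_config(default_config(), overrides)

  geometry <- do.call(geometry_spec, cfg$geometry)
  condition <- condition_spec(
    experiment = cfg$condition$experiment,
    background = cfg$condition$background,
    swap_rate = cfg$condition$swap_rate,
    trial_duration = cfg$condition$trial_duration,
    settle_duration = cfg$condition$settle_duration,
    geometry = geometry
  )
  out <- list(
    raw = cfg,
    condition = condition,
    noise = do.call(noise_params, cfg$noise),
    dynamics = do.call(dynamics_params, cfg$dynamics),
    accounting = do.call(pool_accounting, cfg$accounting),
    campaign = cfg$campaign,
    verbosity = cfg$verbosity
  )
  class(out) <- "run_config"
  out
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  print(x$condition)
  print(x$noise)
  print(x$dynamics)
  print(x$accounting)
  cat(sprintf("  campaign: n_runs = %d, seed = %d\n",
              as.integer(x$campaign$n_runs), as.integer(x$campaign$seed)))
  invisible(x)
}

format_table <- function(df) {
  out <- df
  for (nm in names(out)) {
    if (is.double(out[[nm]])) out[[nm]] <- signif(out[[nm]], 6)
  }
  out
}

#' Write campaign outputs
#'
#' Writes summary/sweep tables and traces as CSV (numeric columns at six
#' significant digits, so identical inputs give byte-identical files) and a
#' JSON sidecar echoing the effective configuration, seed and package
#' version. Logging goes to standard error, never into the data streams.
#'
#' @param tables Named list of data.frames.
#' @param traces Named list of [run_trial()] traces (optional).
#' @param dir Output directory (created if needed).
#' @param config The effective configuration to echo (a list or
#'   `run_config`); optional.
#' @param seed Campaign seed to echo; optional.
#' @return Invisibly, the paths written.
#' @export
write_outputs <- function(tables = list(), traces = list(), dir,
                          config = NULL, seed = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (nm in names(tables)) {
    p <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(format_table(as.data.frame(tables[[nm]])), p,
                     row.names = FALSE)
    paths <- c(paths, p)
  }
  for (nm in names(traces)) {
    p <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(format_table(as.data.frame(traces[[nm]])), p,
                     row.names = FALSE)
    paths <- c(paths, p)
  }
  sidecar <- list(
    tool = "rivalnorm",
    version = as.character(utils::packageVersion("rivalnorm")),
    seed = seed,
    config = if (inherits(config, "run_config")) config$raw else config
  )
  p <- file.path(dir, "run_metadata.json")
  jsonlite::write_json(sidecar, p, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  paths <- c(paths, p)
  invisible(paths)
}

log_msg <- function(verbosity, level = "info", ...) {
  levels <- c(quiet = 0, info = 1, debug = 2)
  if (levels[[level]] <= levels[[verbosity %||% "info"]]) {
    message(sprintf("[%s] %s", level, paste0(...)))
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
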