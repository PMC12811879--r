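#' Deterministic per-trial seed splitting
#'
#' A campaign seed spawns one private seed per trial via R's RNG, so
#' campaigns with different seeds (or different run counts drawn from
#' different campaign seeds) are independent, and a campaign is exactly
#' reproducible from its seed.
#'
#' @param campaign_seed Integer campaign seed.
#' @param n Number of trial seeds to spawn.
#' @return Integer vector of `n` seeds.
#' @export
spawn_trial_seeds <- function(campaign_seed, n) {
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(campaign_seed))
  sample.int(.Machine$integer.max - 1L, n)
}

run_condition_trials <- function(condition, noise, dynamics, accounting,
                                 seeds) {
  lapply(seeds, function(s) {
    tryCatch(
      run_trial(condition, noise = noise, dynamics = dynamics, seed = s,
                accounting = accounting),
      error = function(e) {
        stop(sprintf("trial failed (%s background, seed %d): %s",
                     condition$background, s, conditionMessage(e)),
             call. = FALSE)
      }
    )
  })
}

#' Simulate the stable-background experiment
#'
#' Runs `n_runs` independent trials for each of the three stable backgrounds
#' (green, gray, red) and summarises the proportion of measured time each
#' disk-color percept was dominant. With default parameters the summary shows
#' the background-dependent staircase: the green percept is rarest on a green
#' background, intermediate on gray, and most common on a red background,
#' mirrored for red percepts.
#'
#' @param noise A [noise_params()].
#' @param dynamics A [dynamics_params()].
#' @param n_runs Trials per background (>= 1).
#' @param seed Campaign seed; spawns per-trial seeds deterministically.
#' @param accounting A [pool_accounting()].
#' @param backgrounds Backgrounds to simulate (default green, gray, red).
#' @return A `summary_table` data.frame with columns `condition`,
#'   `background`, `percept`, `mean_proportion`, `sd_proportion`, `n_runs`,
#'   `seed`.
#' @examples
#' run_experiment1(n_runs = 3, seed = 1)
#' @export
run_experiment1 <- function(noise = noise_params(),
                            dynamics = dynamics_params(),
                            n_runs = 100,
                            seed = 1,
                            accounting = pool_accounting(),
                            backgrounds = c("green", "gray", "red")) {
  stopifnot(n_runs >= 1)
  seeds <- matrix(spawn_trial_seeds(seed, n_runs * length(backgrounds)),
                  nrow = n_runs)
  rows <- list()
  for (b in seq_along(backgrounds)) {
    cond <- condition_spec("exp1", background = backgrounds[b])
    traces <- run_condition_trials(cond, noise, dynamics, accounting,
                                   seeds[, b])
    props <- t(vapply(traces, dominance_proportions,
                      numeric(length(cond$channels))))
    for (ch in cond$channels) {
      rows[[length(rows) + 1L]] <- data.frame(
        condition = paste0(backgrounds[b], "_background"),
        background = backgrounds[b],
        percept = ch,
        mean_proportion = mean(props[, ch]),
        sd_proportion = stats::sd(props[, ch]),
        n_runs = n_runs,
        seed = seed,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("summary_table", "data.frame")
  out
}

#' Simulate the rivalrous-background experiment
#'
#' Builds the symmetric-pool condition (rivalrous red/green backgrounds with
#' patchwork disks), in which each color's pool spans one background and one
#' disk per eye, so the two normalized drives are equal. The competition then
#' runs over the two whole-field color hypotheses, so every sample is a
#' similarity-enhanced (uniform) percept; difference-enhanced outcomes are
#' structurally impossible and are reported with proportion exactly 0.
#'
#' @inheritParams run_experiment1
#' @return A `summary_table` data.frame with percept rows
#'   `similarity_green`, `similarity_red`, and `difference_enhanced`.
#' @examples
#' run_experiment2(n_runs = 3, seed = 1)
#' @export
run_experiment2 <- function(noise = noise_params(),
                            dynamics = dynamics_params(),
                            n_runs = 100,
                            seed = 1,
                            accounting = pool_accounting()) {
  stopifnot(n_runs >= 1)
  cond <- condition_spec("exp2", background = "rivalrous")
  seeds <- spawn_trial_seeds(seed, n_runs)
  traces <- run_condition_trials(cond, noise, dynamics, accounting, seeds)
  props <- t(vapply(traces, dominance_proportions,
                    numeric(length(cond$channels))))
  rows <- lapply(cond$channels, function(ch) {
    data.frame(
      condition = "rivalrous_background",
      background = "rivalrous",
      percept = paste0("similarity_", ch),
      mean_proportion = mean(props[, ch]),
      sd_proportion = stats::sd(props[, ch]),
      n_runs = n_runs, seed = seed,
      stringsAsFactors = FALSE
    )
  })
  rows[[length(rows) + 1L]] <- data.frame(
    condition = "rivalrous_background", background = "rivalrous",
    percept = "difference_enhanced",
    mean_proportion = 0, sd_proportion = 0,
    n_runs = n_runs, seed = seed, stringsAsFactors = FALSE
  )
  out <- do.call(rbind, rows)
  class(out) <- c("summary_table", "data.frame")
  out
}

#' Check the staircase ordering of a summary table
#'
#' @param summary A [run_experiment1()] table covering green, gray and red
#'   backgrounds.
#' @return `TRUE` if the ordinal staircase holds for both percept colors:
#'   green-percept proportion smallest on green background, intermediate on
#'   gray, largest on red, mirrored for red percepts.
#' @export
staircase_holds <- function(summary) {
  get_prop <- function(bg, pc) {
    summary$mean_proportion[summary$background == bg & summary$percept == pc]
  }
  g <- vapply(c("green", "gray", "red"), get_prop, numeric(1), pc = "green")
  r <- vapply(c("green", "gray", "red"), get_prop, numeric(1), pc = "red")
  (g[1] < g[2] && g[2] < g[3]) && (r[1] > r[2] && r[2] > r[3])
}

sweep_parameters <- c("noise_bound", "gain", "gain_bias", "tau_d", "tau_r")

#' Parameter-sensitivity sweep
#'
#' Re-runs the stable-background campaign over a grid of one parameter and
#' reports, per grid point and condition, the percept proportions, mean
#' dominance durations and switch rates. Useful for reproducing the
#' qualitative noise regimes (larger noise bounds produce faster, flicker-like
#' alternation; small bounds suppress switching) and the effect of slow
#' adaptation (staircase preserved, alternation suppressed).
#'
#' @param parameter One of `"noise_bound"` (symmetric truncation bound),
#'   `"gain"`, `"gain_bias"`, `"tau_d"`, `"tau_r"`.
#' @param values Numeric grid of parameter values.
#' @param noise,dynamics Base parameter objects the grid perturbs.
#' @param n_runs Trials per grid point and background.
#' @param seed Campaign seed (per-trial seeds spawned deterministically; the
#'   same trial seeds are reused across grid points so differences are due to
#'   the parameter, not the noise realisation).
#' @param accounting A [pool_accounting()].
#' @param backgrounds Backgrounds to simulate.
#' @return A `sweep_table` data.frame with columns `parameter`, `value`,
#'   `condition`, `percept`, `mean_proportion`, `mean_duration_s`,
#'   `switch_rate_hz`, `n_runs`.
#' @examples
#' sensitivity_sweep("noise_bound", c(0.1, 0.35), n_runs = 2, seed = 1,
#'                   backgrounds = "gray")
#' @export
sensitivity_sweep <- function(parameter, values,
                              noise = noise_params(),
                              dynamics = dynamics_params(),
                              n_runs = 25,
                              seed = 1,
                              accounting = pool_accounting(),
                              backgrounds = c("green", "gray", "red")) {
  parameter <- match.arg(parameter, sweep_parameters)
  if (!is.numeric(values) || !length(values) || anyNA(values)) {
    stop("sensitivity_sweep: values must be a numeric grid", call. = FALSE)
  }
  seeds <- matrix(spawn_trial_seeds(seed, n_runs * length(backgrounds)),
                  nrow = n_runs)
  rows <- list()
  for (v in values) {
    nz <- noise
    dy <- dynamics
    if (parameter == "noise_bound") {
      if (v <= 0) stop("sensitivity_sweep: noise_bound values must be positive",
                       call. = FALSE)
      nz <- noise_params(sigma = noise$sigma, lower = -v, upper = v)
    } else {
      dy[[parameter]] <- v
      dy <- validate_dynamics_params(dy)
    }
    for (b in seq_along(backgrounds)) {
      cond <- condition_spec("exp1", background = backgrounds[b])
      traces <- run_condition_trials(cond, nz, dy, accounting, seeds[, b])
      stats_list <- lapply(traces, trial_stats)
      props <- t(vapply(stats_list, function(s) s$proportions,
                        numeric(length(cond$channels))))
      rates <- vapply(stats_list, function(s) s$switch_rate_hz, numeric(1))
      for (ch in cond$channels) {
        durs <- vapply(stats_list, function(s) s$mean_duration_s[[ch]],
                       numeric(1))
        rows[[length(rows) + 1L]] <- data.frame(
          parameter = parameter, value = v,
          condition = paste0(backgrounds[b], "_background"),
          percept = ch,
          mean_proportion = mean(props[, ch]),
          mean_duration_s = mean(durs, na.rm = TRUE),
          switch_rate_hz = mean(rates),
          n_runs = n_runs,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("sweep_table", "data.frame")
  out
}
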