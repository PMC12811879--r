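#' Synthetic observer parameters
#'
#' Configuration for the synthetic report-stream generator, which emulates
#' the button-press protocol (press and hold while a measured percept is
#' seen; withhold for unresolved/piecemeal percepts) with controlled
#' long-run dominance structure. Dominance durations are gamma distributed
#' (shape about 3 by default), the standard empirical description of rivalry
#' dominance-duration distributions.
#'
#' @param targets Named numeric vector of long-run per-percept dominance
#'   proportions (e.g. `c(green = 0.4, red = 0.5)`).
#' @param mean_duration_s Mean dominance duration, seconds (default 2).
#' @param shape Gamma shape parameter of the duration distribution
#'   (default 3).
#' @param unreported Fraction of trial time without a report (default the
#'   complement of `sum(targets)`); `sum(targets) + unreported` must be 1.
#' @param trial_length_s Trial (measured window) length, seconds (default 60).
#' @param n_days Number of repeat days (default 3).
#' @param n_trials_per_day Trials per day (default 1).
#' @return An object of class `synthetic_observer_params`.
#' @examples
#' synthetic_observer_params(c(green = 0.6, red = 0.4))
#' @export
synthetic_observer_params <- function(targets,
                                      mean_duration_s = 2,
                                      shape = 3,
                                      unreported = NULL,
                                      trial_length_s = 60,
                                      n_days = 3,
                                      n_trials_per_day = 1) {
  if (is.null(names(targets)) || any(!nzchar(names(targets)))) {
    stop("synthetic observer: targets must be a named vector of proportions",
         call. = FALSE)
  }
  if (any(targets < 0)) {
    stop("synthetic observer: target proportions must be nonnegative",
         call. = FALSE)
  }
  if (is.null(unreported)) unreported <- 1 - sum(targets)
  if (unreported < -1e-9 || abs(sum(targets) + unreported - 1) > 1e-9) {
    stop("synthetic observer: target proportions plus unreported fraction must equal 1",
         call. = FALSE)
  }
  if (!(mean_duration_s > 0) || !(shape > 0) || !(trial_length_s > 0)) {
    stop("synthetic observer: durations, shape and trial length must be positive",
         call. = FALSE)
  }
  structure(
    list(targets = targets, mean_duration_s = mean_duration_s, shape = shape,
         unreported = max(0, unreported), trial_length_s = trial_length_s,
         n_days = as.integer(n_days),
         n_trials_per_day = as.integer(n_trials_per_day)),
    class = "synthetic_observer_params"
  )
}

#' Generate a synthetic observer report stream
#'
#' Produces alternating labeled intervals whose durations are i.i.d. gamma
#' draws; percept labels are drawn with probabilities proportional to the
#' target proportions, and the unreported fraction is carved out as gamma
#' gaps between reports, so the long-run recovered proportions converge to
#' the targets. Adjacent same-label reports with no gap are merged, so a
#' single target with proportion 1 yields one interval covering the whole
#' trial. The records satisfy [dominance_summary()]'s input contract and the
#' same seed yields an identical record set.
#'
#' @param params A [synthetic_observer_params()].
#' @param seed Integer seed.
#' @param observer Observer identifier for the emitted records.
#' @return Data.frame of report records (`observer`, `day`, `trial`,
#'   `percept`, `onset_s`, `offset_s`).
#' @examples
#' p <- synthetic_observer_params(c(A = 0.6, B = 0.4))
#' head(generate_report_stream(p, seed = 1))
#' @export
generate_report_stream <- function(params, seed, observer = "synthetic") {
  stopifnot(inherits(params, "synthetic_observer_params"))
  if (missing(seed)) stop("generate_report_stream: a seed is required",
                          call. = FALSE)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))

  reported <- sum(params$targets)
  label_prob <- params$targets / reported
  gap_mean <- if (params$unreported > 0) {
    params$mean_duration_s * params$unreported / reported
  } else 0
  rows <- list()
  for (day in seq_len(params$n_days)) {
    for (trial in seq_len(params$n_trials_per_day)) {
      t <- 0
      labs <- character(0)
      ons <- numeric(0)
      offs <- numeric(0)
      while (t < params$trial_length_s) {
        lab <- names(params$targets)[
          sample.int(length(params$targets), 1, prob = label_prob)]
        dur <- stats::rgamma(1, shape = params$shape,
                             scale = params$mean_duration_s / params$shape)
        end <- min(t + dur, params$trial_length_s)
        n <- length(labs)
        if (n > 0 && labs[n] == lab && abs(offs[n] - t) < 1e-12) {
          offs[n] <- end # merge with the adjacent same-label report
        } else {
          labs <- c(labs, lab)
          ons <- c(ons, t)
          offs <- c(offs, end)
        }
        t <- end
        if (gap_mean > 0 && t < params$trial_length_s) {
          gap <- stats::rgamma(1, shape = params$shape,
                               scale = gap_mean / params$shape)
          t <- min(t + gap, params$trial_length_s)
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        observer = observer, day = day, trial = trial,
        percept = labs, onset_s = ons, offset_s = offs,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

#' Synthesize per-background staircase proportions for one observer
#'
#' Produces the pair of background-proportion triplets (green percept and red
#' percept across green/neutral/red backgrounds) used to exercise the
#' staircase scorer end to end: triplets are jittered around a monotone
#' staircase of the given separation. With `effect = 0` the three values of a
#' triplet are exchangeable, so [staircase_success()] fires at exactly the
#' 1/6 chance level, making the binomial null correct by construction.
#'
#' @param effect Separation between adjacent staircase levels (>= 0).
#' @param noise_sd Standard deviation of the jitter (default 0.1).
#' @param seed Integer seed.
#' @return List with elements `green` and `red`, each a named triplet
#'   (`on_green`, `on_neutral`, `on_red`) clamped to `[0, 1]`.
#' @examples
#' make_staircase_observer(effect = 0.2, seed = 1)
#' @export
make_staircase_observer <- function(effect, noise_sd = 0.1, seed) {
  if (effect < 0) stop("make_staircase_observer: effect must be >= 0",
                       call. = FALSE)
  if (missing(seed)) stop("make_staircase_observer: a seed is required",
                          call. = FALSE)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  clamp <- function(x) pmin(1, pmax(0, x))
  green <- clamp(c(0.5 - effect, 0.5, 0.5 + effect) +
                   stats::rnorm(3, sd = noise_sd))
  red <- clamp(c(0.5 + effect, 0.5, 0.5 - effect) +
                 stats::rnorm(3, sd = noise_sd))
  names(green) <- names(red) <- c("on_green", "on_neutral", "on_red")
  list(green = green, red = red)
}
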