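#' Competition-dynamics parameters
#'
#' The stochastic winner-take-all competition runs on three nested clocks:
#' a 1-ms base timebase (internal bookkeeping), 100-Hz explicit-Euler updates
#' for adaptation of the dominant representation and recovery of the
#' suppressed one, and a 4-Hz sampling clock (`dt`) at which noise is
#' resampled, the multiplicative gain is assigned, and the winner-take-all
#' comparison is made.
#'
#' @param gain Multiplicative gain g applied transiently to one channel's
#'   comparison value each `dt` interval (default 1.3, a 30% amplification).
#'   The gain biases the comparison only; it does not compound into the
#'   stored strengths (see `gain_in_store`).
#' @param gain_bias Probability p that the gain goes to the currently stronger
#'   channel (default 0.55, complement 0.45 to the weaker).
#' @param dt Winner-take-all / gain / noise sampling interval, seconds
#'   (default 0.25, i.e. 4 Hz).
#' @param adaptation_update Euler step for adaptation and recovery, seconds
#'   (default 0.01, i.e. 100 Hz). Must divide `dt`.
#' @param base_step Base integration timebase, seconds (default 0.001). Must
#'   divide `adaptation_update`.
#' @param tau_d Adaptation time constant of the dominant representation,
#'   seconds (default 2.5). `Inf` disables adaptation.
#' @param tau_r Recovery time constant of the suppressed representation,
#'   seconds (default 1.5). `Inf` disables recovery.
#' @param switch_rule `"carry"` (default): after a dominance switch the new
#'   dominant keeps its current strength and the new suppressed recovers from
#'   its current strength toward its ceiling. `"reset"`: each dominance phase
#'   restarts with the winner at its ceiling and the loser fully suppressed
#'   at 0 (the regime in which the zero-noise alternation period is the root
#'   of `g exp(-t/tau_d) = 1 - exp(-t/tau_r)`).
#' @param gain_in_store If `TRUE`, the winner's stored strength incorporates
#'   the transient gain; default `FALSE` (the un-gained value is stored).
#' @return An object of class `dynamics_params`.
#' @examples
#' dynamics_params()
#' @export
dynamics_params <- function(gain = 1.3,
                            gain_bias = 0.55,
                            dt = 0.25,
                            adaptation_update = 0.01,
                            base_step = 0.001,
                            tau_d = 2.5,
                            tau_r = 1.5,
                            switch_rule = c("carry", "reset"),
                            gain_in_store = FALSE) {
  switch_rule <- match.arg(switch_rule)
  p <- structure(
    list(gain = as.numeric(gain), gain_bias = as.numeric(gain_bias),
         dt = as.numeric(dt), adaptation_update = as.numeric(adaptation_update),
         base_step = as.numeric(base_step), tau_d = as.numeric(tau_d),
         tau_r = as.numeric(tau_r), switch_rule = switch_rule,
         gain_in_store = isTRUE(gain_in_store)),
    class = "dynamics_params"
  )
  validate_dynamics_params(p)
}

validate_dynamics_params <- function(p) {
  stopifnot(inherits(p, "dynamics_params"))
  if (!(p$base_step > 0 && p$base_step <= p$adaptation_update &&
        p$adaptation_update <= p$dt)) {
    stop("dynamics: need base_step <= adaptation_update <= dt (all positive)",
         call. = FALSE)
  }
  for (nm in c("tau_d", "tau_r")) {
    if (!(p[[nm]] > 0)) stop(sprintf("dynamics: %s must be positive", nm),
                             call. = FALSE)
  }
  if (p$gain < 1) stop("dynamics: gain must be >= 1", call. = FALSE)
  if (p$gain_bias < 0 || p$gain_bias > 1) {
    stop("dynamics: gain_bias must lie in [0, 1]", call. = FALSE)
  }
  k <- p$dt / p$adaptation_update
  if (abs(k - round(k)) > 1e-9) {
    stop("dynamics: adaptation_update must divide dt", call. = FALSE)
  }
  m <- p$adaptation_update / p$base_step
  if (abs(m - round(m)) > 1e-9) {
    stop("dynamics: base_step must divide adaptation_update", call. = FALSE)
  }
  # Euler stability: one step must not overshoot
  if (p$adaptation_update >= p$tau_d || p$adaptation_update >= p$tau_r) {
    stop("dynamics: adaptation_update must be smaller than both time constants",
         call. = FALSE)
  }
  p
}

#' @export
print.dynamics_params <- function(x, ...) {
  cat("<dynamics_params>\n")
  cat(sprintf("  gain g = %g (bias p = %g to the stronger channel)\n",
              x$gain, x$gain_bias))
  cat(sprintf("  clocks: dt = %g s, adaptation update = %g s, base = %g s\n",
              x$dt, x$adaptation_update, x$base_step))
  cat(sprintf("  tau_d = %g s, tau_r = %g s, switch rule = %s\n",
              x$tau_d, x$tau_r, x$switch_rule))
  invisible(x)
}

#' One explicit-Euler adaptation step for the dominant representation
#'
#' `P <- P - dt * P / tau_d`: exponential decay of the dominant strength
#' toward zero. Noise is handled on the sampling clock, not here.
#'
#' @param p Current strength (nonnegative).
#' @param dt Step size in seconds (the adaptation-update interval).
#' @param tau_d Adaptation time constant in seconds (`Inf` = no decay).
#' @return Updated strength (never negative for `dt < tau_d`).
#' @examples
#' adapt_step(1, 0.01, 2.5) # 0.996, vs exact exp(-0.004) = 0.996008
#' @export
adapt_step <- function(p, dt, tau_d) {
  p * (1 - dt / tau_d)
}

#' One explicit-Euler recovery step for the suppressed representation
#'
#' `P <- P + dt * (P_M - P) / tau_r`: relaxation of the suppressed strength
#' toward its ceiling `P_M`. Under zero noise the strength approaches `P_M`
#' monotonically from below and never overshoots.
#'
#' @param p Current strength.
#' @param p_m Ceiling (maximal) strength.
#' @param dt Step size in seconds.
#' @param tau_r Recovery time constant in seconds (`Inf` = no recovery).
#' @return Updated strength.
#' @examples
#' recover_step(0, 1, 0.01, 1.5) # 0.006667
#' @export
recover_step <- function(p, p_m, dt, tau_r) {
  p + dt * (p_m - p) / tau_r
}

#' Stochastic gain assignment
#'
#' Assigns the multiplicative gain to one of the two channels for the current
#' sampling interval: the currently stronger representation — the incumbent
#' dominant percept, which holds the competitive advantage — receives it with
#' probability `gain_bias`, the suppressed one with the complement. Consumes
#' one uniform draw.
#'
#' @param p Numeric vector of the two channels' current strengths (unused by
#'   the assignment itself; accepted so callers can pass the full state).
#' @param incumbent Index (1 or 2) of the incumbent dominant channel.
#' @param params A [dynamics_params()].
#' @return Index (1 or 2) of the channel that receives the gain.
#' @examples
#' set.seed(1)
#' apply_gain(c(1, 0.069), 1, dynamics_params())
#' @export
apply_gain <- function(p, incumbent, params = dynamics_params()) {
  incumbent <- as.integer(incumbent)
  if (stats::runif(1) < params$gain_bias) incumbent else 3L - incumbent
}

#' Winner-take-all comparison
#'
#' Implements the recursive maxing step: the next dominant value is the
#' maximum of the two noise-perturbed (and gain-modulated) values, and the
#' winner is whichever channel attains it. On an exact tie the incumbent
#' retains dominance (ties have measure zero under noise; the rule buys
#' stability in degenerate noise-free runs).
#'
#' @param p_d,p_s Current dominant and suppressed strengths.
#' @param eta_d,eta_s Additive perturbations (signal-proportional noise, and
#'   any transient gain folded in by the caller).
#' @param incumbent `"dominant"` label owner; returned on ties.
#' @return List with `winner` (`"dominant"` or `"suppressed"`) and `value`,
#'   the updated dominant strength.
#' @examples
#' wta_compare(0.80, 0.85, 0, 0) # previously suppressed wins at 0.85
#' @export
wta_compare <- function(p_d, p_s, eta_d, eta_s, incumbent = "dominant") {
  vd <- p_d + eta_d
  vs <- p_s + eta_s
  if (!is.finite(vd) || !is.finite(vs)) {
    stop("wta_compare: non-finite comparison value", call. = FALSE)
  }
  if (vs > vd) list(winner = "suppressed", value = vs)
  else if (vd > vs) list(winner = "dominant", value = vd)
  else list(winner = incumbent, value = vd)
}

#' Simulate one rivalry trial
#'
#' Runs the full model for one trial of a condition: computes the two
#' channels' normalized drives, initializes both strengths and ceilings at
#' those drives, selects the initial dominant by a first noisy comparison,
#' then alternates 100-Hz adaptation/recovery updates with 4-Hz sampling
#' events (noise resampling, stochastic gain assignment, winner-take-all
#' comparison, role switching). Dominance is recorded on the sampling grid;
#' proportions are computed over the measured window after the settling
#' discard.
#'
#' Random-draw order is fixed and documented: the initial comparison consumes
#' one noise multiplier per channel (in the condition's channel order); every
#' subsequent sampling event consumes one multiplier per channel followed by
#' one uniform for the gain assignment. This makes label relabelling an exact
#' symmetry under a shared seed.
#'
#' @param condition A [condition_spec()].
#' @param noise A [noise_params()].
#' @param dynamics A [dynamics_params()].
#' @param seed Integer seed for the trial's private random stream.
#' @param accounting A [pool_accounting()].
#' @param audit If `TRUE`, the per-event noise draws and gain target are kept
#'   in the trace for reproducibility audits.
#' @return An object of class `percept_trace`: a data.frame with one row per
#'   sampling interval (columns `time_s`, `dominant`, `P_<channel>` for both
#'   channels, plus `xi_<channel>` and `gain_target` when auditing), with the
#'   condition, parameters, drives and seed attached as attributes.
#' @examples
#' tr <- run_trial(condition_spec("exp1", "green"), seed = 1)
#' dominance_proportions(tr)
#' @export
run_trial <- function(condition,
                      noise = noise_params(),
                      dynamics = dynamics_params(),
                      seed,
                      accounting = pool_accounting(),
                      audit = FALSE) {
  validate_condition_spec(condition)
  validate_dynamics_params(dynamics)
  if (missing(seed)) stop("run_trial: a seed is required", call. = FALSE)

  drives <- normalized_drives(condition, accounting = accounting)
  labels <- condition$channels

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))

  p_m <- unname(drives)
  p <- p_m
  k <- round(dynamics$dt / dynamics$adaptation_update)
  decay_d <- (1 - dynamics$adaptation_update / dynamics$tau_d)^k
  decay_r <- (1 - dynamics$adaptation_update / dynamics$tau_r)^k
  n_int <- round(condition$trial_duration / dynamics$dt)

  # initial dominant: first noisy comparison (no gain)
  xi <- sample_noise_multiplier(noise, 2)
  v <- p + channel_noise(p, xi)
  dom <- if (v[1] >= v[2]) 1L else 2L
  p <- v # noise is retained in the stored values
  if (dynamics$switch_rule == "reset") {
    p[dom] <- p_m[dom]
    p[3L - dom] <- 0
  }

  dominant <- integer(n_int)
  p1 <- numeric(n_int)
  p2 <- numeric(n_int)
  if (audit) {
    xi1 <- numeric(n_int)
    xi2 <- numeric(n_int)
    gt <- integer(n_int)
  }

  for (i in seq_len(n_int)) {
    dominant[i] <- dom
    p1[i] <- p[1]
    p2[i] <- p[2]
    # adaptation/recovery over the interval: k explicit-Euler substeps
    sup <- 3L - dom
    p[dom] <- p[dom] * decay_d
    p[sup] <- p_m[sup] - (p_m[sup] - p[sup]) * decay_r
    # sampling event at the end of the interval
    xi <- sample_noise_multiplier(noise, 2)
    p <- p + channel_noise(p, xi)
    gained <- apply_gain(p, dom, dynamics)
    comp <- p
    comp[gained] <- comp[gained] * dynamics$gain
    if (!all(is.finite(comp))) {
      stop(sprintf("run_trial: non-finite state at t = %.3f s", i * dynamics$dt),
           call. = FALSE)
    }
    winner <- if (comp[1] == comp[2]) dom else which.max(comp)
    if (dynamics$gain_in_store) p[winner] <- comp[winner]
    if (winner != dom) {
      if (dynamics$switch_rule == "reset") {
        p[winner] <- p_m[winner]
        p[dom] <- 0
      }
      dom <- winner
    }
    if (audit) {
      xi1[i] <- xi[1]
      xi2[i] <- xi[2]
      gt[i] <- gained
    }
  }

  trace <- data.frame(
    time_s = (seq_len(n_int) - 1L) * dynamics$dt,
    dominant = labels[dominant],
    stringsAsFactors = FALSE
  )
  trace[[paste0("P_", labels[1])]] <- p1
  trace[[paste0("P_", labels[2])]] <- p2
  if (audit) {
    trace[[paste0("xi_", labels[1])]] <- xi1
    trace[[paste0("xi_", labels[2])]] <- xi2
    trace$gain_target <- labels[gt]
  }
  structure(trace,
            class = c("percept_trace", "data.frame"),
            condition = condition,
            noise = noise,
            dynamics = dynamics,
            accounting = accounting,
            drives = drives,
            seed = as.integer(seed))
}

#' @export
print.percept_trace <- function(x, ...) {
  cond <- attr(x, "condition")
  pr <- dominance_proportions(x)
  cat(sprintf("<percept_trace> %s, %s background, seed %d\n",
              cond$experiment, cond$background, attr(x, "seed")))
  cat(sprintf("  drives: %s\n",
              paste(sprintf("%s = %.4g", names(attr(x, "drives")),
                            attr(x, "drives")), collapse = ", ")))
  cat(sprintf("  measured dominance: %s\n",
              paste(sprintf("%s %.3f", names(pr), pr), collapse = ", ")))
  invisible(x)
}

#' Quick-look plot of a trial trace
#'
#' @param x A [run_trial()] trace.
#' @param ... Passed to [graphics::matplot()].
#' @return The trace, invisibly.
#' @export
plot.percept_trace <- function(x, ...) {
  cond <- attr(x, "condition")
  labels <- cond$channels
  cols <- ifelse(labels == "red", "firebrick", "forestgreen")
  graphics::matplot(x$time_s, cbind(x[[paste0("P_", labels[1])]],
                                    x[[paste0("P_", labels[2])]]),
                    type = "l", lty = 1, col = cols,
                    xlab = "time (s)", ylab = "strength P", ...)
  graphics::legend("topright", legend = labels, col = cols, lty = 1, bty = "n")
  invisible(x)
}

#' Dominance proportions over the measured window
#'
#' Fraction of the measured window (after the settling discard) in which each
#' channel was dominant. The binary readout partitions time, so the
#' proportions sum to one.
#'
#' @param trace A [run_trial()] trace.
#' @return Named numeric vector over the condition's channels.
#' @export
dominance_proportions <- function(trace) {
  stopifnot(inherits(trace, "percept_trace"))
  cond <- attr(trace, "condition")
  keep <- trace$time_s >= cond$settle_duration
  labs <- cond$channels
  n <- sum(keep)
  stats::setNames(
    vapply(labs, function(l) sum(trace$dominant[keep] == l) / n, numeric(1)),
    labs
  )
}

#' Per-trial dominance statistics
#'
#' Episode (dominance-phase) durations, mean dominance duration, and switch
#' rate over the measured window of a trace.
#'
#' @param trace A [run_trial()] trace.
#' @return List with `proportions`, `mean_duration_s` (per channel and
#'   overall), `switch_rate_hz`, and `n_switches`.
#' @export
trial_stats <- function(trace) {
  stopifnot(inherits(trace, "percept_trace"))
  cond <- attr(trace, "condition")
  dt <- attr(trace, "dynamics")$dt
  keep <- trace$time_s >= cond$settle_duration
  labs <- trace$dominant[keep]
  window <- sum(keep) * dt
  r <- rle(labs)
  durations <- r$lengths * dt
  n_sw <- length(r$lengths) - 1L
  mean_by <- vapply(cond$channels, function(l) {
    d <- durations[r$values == l]
    if (length(d)) mean(d) else NA_real_
  }, numeric(1))
  list(
    proportions = dominance_proportions(trace),
    mean_duration_s = c(overall = mean(durations), mean_by),
    switch_rate_hz = n_sw / window,
    n_switches = n_sw
  )
}
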