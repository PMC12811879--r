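#' Staircase-ordering success
#'
#' Scores one observer staircase (the dominance proportions of one percept
#' color across the green, neutral and red backgrounds) against the model's
#' ordinal prediction: a green percept should be rarest on a green
#' background, intermediate on neutral, most common on red; a red percept the
#' reverse. Only the strict ordering counts; ties score as failure (ties have
#' zero probability under continuous proportions). Exactly one of the six
#' strict orderings of three distinct proportions is a success, so the chance
#' level is 1/6.
#'
#' @param percept `"green"` or `"red"`.
#' @param on_green,on_neutral,on_red Dominance proportions of that percept on
#'   the three backgrounds.
#' @return Logical: does the strict predicted ordering hold?
#' @examples
#' staircase_success("green", 0.313, 0.459, 0.702) # TRUE
#' staircase_success("red", 0.545, 0.323, 0.182)   # TRUE
#' @export
staircase_success <- function(percept = c("green", "red"),
                              on_green, on_neutral, on_red) {
  percept <- match.arg(percept)
  props <- c(on_green, on_neutral, on_red)
  if (any(!is.finite(props))) {
    stop("staircase_success: proportions must be finite", call. = FALSE)
  }
  if (percept == "green") {
    on_green < on_neutral && on_neutral < on_red
  } else {
    on_green > on_neutral && on_neutral > on_red
  }
}

#' Exact one-tailed binomial tail probability
#'
#' Upper-tail probability `P(X >= k)` for `X ~ Binomial(n, p0)`, the
#' one-tailed (directional, a priori) test used to score how many observed
#' staircases match the predicted ordering against the chance level (1/6 per
#' staircase; 1/36 for both staircases of one observer).
#'
#' @param k Number of successes (0..n).
#' @param n Number of trials.
#' @param p0 Null success probability, in (0, 1).
#' @return `P(X >= k)` computed exactly.
#' @examples
#' binomial_tail(9, 10, 1/6)   # 8.43e-07
#' binomial_tail(4, 5, (1/6)^2) # 2.91e-06
#' @export
binomial_tail <- function(k, n, p0) {
  if (length(k) != 1 || length(n) != 1 || length(p0) != 1 ||
      k != round(k) || n != round(n) || k < 0 || n < 0 || k > n) {
    stop("binomial_tail: need integers 0 <= k <= n", call. = FALSE)
  }
  if (!(p0 > 0 && p0 < 1)) {
    stop("binomial_tail: p0 must lie in (0, 1)", call. = FALSE)
  }
  if (k == 0) return(1)
  stats::pbinom(k - 1, n, p0, lower.tail = FALSE)
}

#' Staircase binomial test result row
#'
#' @param name Label for the test.
#' @param k,n,p0 Passed to [binomial_tail()].
#' @return One-row data.frame: `test`, `k`, `n`, `p0`, `p_value`.
#' @examples
#' staircase_binomial("all_staircases", 9, 10, 1/6)
#' @export
staircase_binomial <- function(name, k, n, p0) {
  data.frame(test = name, k = k, n = n, p0 = p0,
             p_value = binomial_tail(k, n, p0),
             stringsAsFactors = FALSE)
}

#' Dominance summary of observer report streams
#'
#' Aggregates button-press style report records (non-overlapping labeled
#' intervals inside the measured window) into per-percept total dominance
#' proportions and mean dominance durations, with the standard error of the
#' mean computed across repeats (days): each day's proportion is averaged
#' over that day's trials, and the SEM is the standard deviation of the day
#' means divided by the square root of the number of days. Time without a
#' report (withheld presses, e.g. piecemeal percepts) contributes to no
#' percept. With a single repeat the SEM is reported as `NA`.
#'
#' @param records Data.frame with columns `observer`, `day`, `trial`,
#'   `percept`, `onset_s`, `offset_s` (times relative to the start of the
#'   measured window).
#' @param window_s Length of the measured window per trial, seconds
#'   (default 60).
#' @return Data.frame with one row per observer and percept: columns
#'   `observer`, `percept`, `mean_proportion`, `mean_duration_s`, `sem`,
#'   `n_days`.
#' @examples
#' rec <- data.frame(observer = "S1", day = 1, trial = 1, percept = "green",
#'                   onset_s = 0, offset_s = 30)
#' dominance_summary(rec)
#' @export
dominance_summary <- function(records, window_s = 60) {
  needed <- c("observer", "day", "trial", "percept", "onset_s", "offset_s")
  if (!all(needed %in% names(records))) {
    stop(sprintf("dominance_summary: records need columns %s",
                 paste(needed, collapse = ", ")), call. = FALSE)
  }
  if (any(records$offset_s <= records$onset_s)) {
    stop("dominance_summary: every interval needs offset_s > onset_s",
         call. = FALSE)
  }
  # overlap check within one observer/day/trial (across percepts: an observer
  # reports one percept at a time)
  key <- interaction(records$observer, records$day, records$trial, drop = TRUE)
  for (kk in levels(key)) {
    sub <- records[key == kk, , drop = FALSE]
    ord <- order(sub$onset_s)
    if (any(sub$onset_s[ord][-1] < sub$offset_s[ord][-nrow(sub)] - 1e-9)) {
      stop(sprintf("dominance_summary: overlapping intervals in %s", kk),
           call. = FALSE)
    }
  }
  records$duration <- records$offset_s - records$onset_s
  out <- list()
  for (obs in unique(records$observer)) {
    robs <- records[records$observer == obs, , drop = FALSE]
    days <- sort(unique(robs$day))
    for (pc in sort(unique(robs$percept))) {
      day_props <- vapply(days, function(d) {
        rd <- robs[robs$day == d, , drop = FALSE]
        trials <- unique(rd$trial)
        per_trial <- vapply(trials, function(tr) {
          sum(rd$duration[rd$trial == tr & rd$percept == pc]) / window_s
        }, numeric(1))
        mean(per_trial)
      }, numeric(1))
      durs <- robs$duration[robs$percept == pc]
      out[[length(out) + 1L]] <- data.frame(
        observer = obs, percept = pc,
        mean_proportion = mean(day_props),
        mean_duration_s = if (length(durs)) mean(durs) else NA_real_,
        sem = if (length(days) > 1) {
          stats::sd(day_props) / sqrt(length(days))
        } else NA_real_,
        n_days = length(days),
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, out)
}

#' Convert a simulated trace into report records
#'
#' Expresses the measured window of a [run_trial()] trace in the observer
#' report dialect consumed by [dominance_summary()], with onsets relative to
#' the start of the measured window.
#'
#' @param trace A [run_trial()] trace.
#' @param observer,day,trial Identifiers for the emitted records.
#' @return Data.frame of report records.
#' @export
trace_to_reports <- function(trace, observer = "sim", day = 1L, trial = 1L) {
  stopifnot(inherits(trace, "percept_trace"))
  cond <- attr(trace, "condition")
  dt <- attr(trace, "dynamics")$dt
  keep <- trace$time_s >= cond$settle_duration
  labs <- trace$dominant[keep]
  r <- rle(labs)
  ends <- cumsum(r$lengths) * dt
  starts <- c(0, ends[-length(ends)])
  data.frame(observer = observer, day = day, trial = trial,
             percept = r$values, onset_s = starts, offset_s = ends,
             stringsAsFactors = FALSE)
}
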