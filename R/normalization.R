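#' Truncated-normal noise parameters
#'
#' The multiplicative noise draw xi is a zero-mean normal with standard
#' deviation `sigma`, truncated to `[lower, upper]`. With the defaults
#' (sigma 1, bounds +/- 0.35) the post-truncation standard deviation is
#' about 0.2, i.e. perturbations of roughly 20% of the current signal.
#' Setting `sigma = 0` degenerates to noise-free draws (always 0).
#'
#' @param sigma Standard deviation of the untruncated normal (default 1).
#' @param lower,upper Truncation bounds (defaults -0.35, +0.35).
#' @return An object of class `noise_params`.
#' @examples
#' noise_params()
#' truncnorm_sd(noise_params())
#' @export
noise_params <- function(sigma = 1, lower = -0.35, upper = 0.35) {
  if (!(lower < upper)) {
    stop("noise: lower bound must be strictly below upper bound", call. = FALSE)
  }
  if (sigma < 0) {
    stop("noise: sigma must be nonnegative", call. = FALSE)
  }
  structure(list(sigma = as.numeric(sigma),
                 lower = as.numeric(lower),
                 upper = as.numeric(upper)),
            class = "noise_params")
}

#' @export
print.noise_params <- function(x, ...) {
  cat(sprintf("<noise_params> N(0, %g^2) truncated to [%g, %g] (sd %.4f)\n",
              x$sigma, x$lower, x$upper, truncnorm_sd(x)))
  invisible(x)
}

#' Closed-form standard deviation of the truncated noise
#'
#' For a zero-mean normal truncated to `[a, b]`, the variance is
#' `sigma^2 * (1 + (alpha phi(alpha) - beta phi(beta))/Z - ((phi(alpha) -
#' phi(beta))/Z)^2)` with `alpha = a/sigma`, `beta = b/sigma` and
#' `Z = Phi(beta) - Phi(alpha)`. At the defaults this evaluates to 0.2004.
#'
#' @param params A [noise_params()].
#' @return The standard deviation of the truncated distribution.
#' @export
truncnorm_sd <- function(params = noise_params()) {
  stopifnot(inherits(params, "noise_params"))
  if (params$sigma == 0) return(0)
  al <- params$lower / params$sigma
  be <- params$upper / params$sigma
  z <- stats::pnorm(be) - stats::pnorm(al)
  m <- (stats::dnorm(al) - stats::dnorm(be)) / z
  v <- 1 + (al * stats::dnorm(al) - be * stats::dnorm(be)) / z - m^2
  params$sigma * sqrt(v)
}

#' Sample truncated-normal noise multipliers
#'
#' Draws xi from the renormalized truncated density by inverse-CDF sampling
#' (not rejection or clipping), so every draw lies strictly inside the bounds
#' and the post-truncation standard deviation is exact in distribution.
#' Consumes exactly `n` uniforms from R's random stream.
#'
#' @param params A [noise_params()].
#' @param n Number of draws.
#' @return Numeric vector of length `n` in `[lower, upper]`.
#' @examples
#' set.seed(1)
#' range(sample_noise_multiplier(noise_params(), 1000))
#' @export
sample_noise_multiplier <- function(params = noise_params(), n = 1) {
  stopifnot(inherits(params, "noise_params"))
  u <- stats::runif(n)
  if (params$sigma == 0) return(numeric(n))
  plo <- stats::pnorm(params$lower, sd = params$sigma)
  phi <- stats::pnorm(params$upper, sd = params$sigma)
  stats::qnorm(plo + u * (phi - plo), sd = params$sigma)
}

#' Signal-proportional channel noise
#'
#' The additive perturbation applied to a channel is the product of its
#' current strength and a truncated-normal multiplier, so noise scales with
#' signal and vanishes for a silent channel.
#'
#' @param signal Current channel strength (nonnegative).
#' @param xi Noise multiplier(s), e.g. from [sample_noise_multiplier()].
#' @return `signal * xi`.
#' @examples
#' channel_noise(0.069, -0.2)
#' @export
channel_noise <- function(signal, xi) {
  if (any(signal < 0)) {
    stop("channel_noise: negative signal indicates corrupted state",
         call. = FALSE)
  }
  signal * xi
}

#' Normalized chromatic drive
#'
#' The deterministic divisive-normalization ratio for one channel: its masked
#' (rivalrous-region) signal divided by its total pooled signal. The ratio is
#' noise-free; stochastic perturbations are injected downstream in the
#' competition dynamics. A channel whose signal lies entirely inside the
#' rivalrous regions has drive exactly 1.
#'
#' @param sums A [channel_sums()] table.
#' @param channel Chromatic label (`"red"` or `"green"`).
#' @param semisaturation Optional additive constant in the denominator
#'   (default 0), the canonical normalization semisaturation term.
#' @return The drive, a dimensionless multiplier in `(0, 1]` for any channel
#'   present in the rivalrous regions (with `semisaturation = 0`).
#' @examples
#' s <- channel_sums(render_fields(condition_spec("exp1", "green")))
#' normalized_drive(s, "red")   # all red signal is inside the disks -> 1
#' normalized_drive(s, "green") # attenuated by the background pool
#' @export
normalized_drive <- function(sums, channel, semisaturation = 0) {
  stopifnot(inherits(sums, "channel_sums"))
  row <- sums[sums$channel == channel, , drop = FALSE]
  if (nrow(row) != 1) {
    stop(sprintf("normalized_drive: unknown channel '%s'", channel),
         call. = FALSE)
  }
  if (row$total_sum + semisaturation <= 0) {
    stop(sprintf(
      "normalized_drive: channel '%s' is absent from the stimulus (total sum 0)",
      channel), call. = FALSE)
  }
  unname(row$masked_sum / (row$total_sum + semisaturation))
}

#' Normalized drives for both competing channels
#'
#' @param condition A [condition_spec()].
#' @param accounting A [pool_accounting()].
#' @param mode Rendering mode passed to [render_fields()].
#' @param semisaturation Passed to [normalized_drive()].
#' @return Named numeric vector of drives in the condition's channel order.
#' @examples
#' normalized_drives(condition_spec("exp1", "green"))
#' @export
normalized_drives <- function(condition, accounting = pool_accounting(),
                              mode = "analytic", semisaturation = 0) {
  sums <- channel_sums(render_fields(condition, mode = mode),
                       accounting = accounting)
  stats::setNames(
    vapply(condition$channels, function(ch) {
      normalized_drive(sums, ch, semisaturation = semisaturation)
    }, numeric(1)),
    condition$channels
  )
}
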