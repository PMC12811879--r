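# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# upper binomial tail by direct summation
binom_tail_by_summation <- function(k, n, p0) {
  if (k == 0) return(1)
  j <- k:n
  sum(choose(n, j) * p0^j * (1 - p0)^(n - j))
}

# truncated-normal sd by numeric integration of the renormalized density
truncnorm_sd_by_integration <- function(sigma, a, b) {
  z <- stats::pnorm(b, sd = sigma) - stats::pnorm(a, sd = sigma)
  f <- function(x) x^2 * stats::dnorm(x, sd = sigma) / z
  sqrt(stats::integrate(f, a, b, rel.tol = 1e-10)$value)
}

# analytic areas of the default display, written out from the geometry
default_areas <- function() {
  list(disk = pi * 0.75^2,
       hole = pi * 0.875^2,
       box = 4.5^2)
}

default_green_condition <- function() condition_spec("exp1", "green")

quiet_noise <- function() noise_params(sigma = 0)
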