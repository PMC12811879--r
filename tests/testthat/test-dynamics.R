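test_that("Euler adaptation and recovery steps track the exact exponentials", {
  # single 10-ms steps against the closed forms
  expect_equal(adapt_step(1, 0.01, 2.5), 0.996)
  expect_lt(abs(adapt_step(1, 0.01, 2.5) - exp(-0.01 / 2.5)), 1e-5)
  expect_equal(recover_step(0, 1, 0.01, 1.5), 0.01 / 1.5)
  # first-order agreement with the exact relaxation: the gap is O(dt^2/tau^2)
  expect_lt(abs(recover_step(0, 1, 0.01, 1.5) - (1 - exp(-0.01 / 1.5))),
            (0.01 / 1.5)^2)
  # per-step relative error below 0.1% across a range of states
  for (p in c(0.05, 0.3, 1)) {
    expect_lt(abs(adapt_step(p, 0.01, 2.5) - p * exp(-0.004)) / p, 1e-3)
    expect_lt(abs(recover_step(p, 2, 0.01, 1.5) -
                    (2 - (2 - p) * exp(-0.01 / 1.5))) / 2, 1e-3)
  }
  # infinite time constants freeze the state
  expect_identical(adapt_step(0.7, 0.01, Inf), 0.7)
  expect_identical(recover_step(0.3, 1, 0.01, Inf), 0.3)
})

test_that("iterated recovery reaches its ceiling like the closed form", {
  # 3 * tau_r of accumulated 10-ms steps from 0: within ~5% of the ceiling,
  # matching 1 - exp(-3) = 0.9502 to better than 0.1%
  p <- 0
  for (i in seq_len(450)) p <- recover_step(p, 1, 0.01, 1.5)
  expect_lt(abs(p - (1 - exp(-3))) / (1 - exp(-3)), 1e-3)
  expect_gt(p, 1 - 0.051)
  # monotone decay of the dominant under zero noise
  ps <- Reduce(function(x, i) adapt_step(x, 0.01, 2.5), 1:100,
               accumulate = TRUE, init = 1)
  expect_true(all(diff(ps) < 0))
  expect_true(all(ps >= 0))
})

test_that("winner-take-all comparison picks the max and honors ties", {
  r <- wta_compare(0.80, 0.85, 0, 0)
  expect_identical(r$winner, "suppressed")
  expect_identical(r$value, 0.85)
  expect_identical(wta_compare(0.5, 0.5, 0, 0)$winner, "dominant")
  expect_identical(wta_compare(0.5, 0.5, 0, 0, incumbent = "suppressed")$winner,
                   "suppressed")
  expect_identical(wta_compare(0.9, 0.5, 0, 0)$winner, "dominant")
  expect_error(wta_compare(Inf, 0.5, 0, 0), "non-finite")
})

test_that("gain assignment follows the bias probability", {
  # degenerate bias: always the incumbent
  set.seed(1)
  dyn1 <- dynamics_params(gain_bias = 1)
  expect_true(all(replicate(200, apply_gain(c(1, 0.5), 1, dyn1)) == 1L))
  # p = 0.55: empirical frequency within 3 standard errors over 1e5 draws
  set.seed(2)
  n <- 1e5
  hits <- sum(replicate(n, apply_gain(c(1, 0.5), 1L, dynamics_params())) == 1L)
  se <- sqrt(0.55 * 0.45 / n)
  expect_lt(abs(hits / n - 0.55), 3 * se)
})

test_that("unit gain leaves the comparison unchanged", {
  dyn <- dynamics_params(gain = 1, gain_bias = 0.55)
  tr1 <- run_trial(condition_spec("exp1", "gray"), dynamics = dyn, seed = 5)
  dyn2 <- dynamics_params(gain = 1, gain_bias = 0.95)
  tr2 <- run_trial(condition_spec("exp1", "gray"), dynamics = dyn2, seed = 5)
  # with g = 1 the gain target is irrelevant: identical trajectories
  expect_identical(tr1$dominant, tr2$dominant)
  expect_identical(tr1$P_red, tr2$P_red)
})

test_that("dynamics parameter invariants are enforced", {
  expect_error(dynamics_params(dt = 0.005), "base_step")
  expect_error(dynamics_params(adaptation_update = 0.0103), "divide")
  expect_error(dynamics_params(gain = 0.5), "gain")
  expect_error(dynamics_params(gain_bias = 1.2), "gain_bias")
  expect_error(dynamics_params(tau_d = -1), "tau_d")
  expect_error(dynamics_params(tau_r = 0.005), "smaller")
})

test_that("trials are reproducible and partition time between percepts", {
  cond <- condition_spec("exp1", "green")
  tr1 <- run_trial(cond, seed = 9, audit = TRUE)
  tr2 <- run_trial(cond, seed = 9, audit = TRUE)
  expect_identical(as.data.frame(tr1), as.data.frame(tr2))
  expect_equal(sum(dominance_proportions(tr1)), 1)
  expect_true(all(tr1$P_red >= 0 & tr1$P_green >= 0))
  expect_true(all(abs(tr1$xi_red) <= 0.35 & abs(tr1$xi_green) <= 0.35))
  expect_setequal(unique(tr1$dominant), c("red", "green"))
  # trace covers the full trial on the sampling grid
  expect_equal(nrow(tr1), cond$trial_duration / 0.25)
  expect_equal(tr1$time_s[1], 0)
})

test_that("relabeling the channels mirrors the trajectory exactly", {
  c1 <- condition_spec("exp1", "green")
  c2 <- mirror_condition(c1)
  expect_identical(c2$background, "red")
  p1 <- dominance_proportions(run_trial(c1, seed = 77))
  p2 <- dominance_proportions(run_trial(c2, seed = 77))
  expect_identical(unname(p1[["red"]]), unname(p2[["green"]]))
  expect_identical(unname(p1[["green"]]), unname(p2[["red"]]))
})

test_that("switching needs perturbation or adaptation", {
  cond <- condition_spec("exp1", "gray")
  # noise off, g = 1: alternation only through the adaptation crossing
  dyn <- dynamics_params(gain = 1, gain_bias = 0.55)
  tr <- run_trial(cond, noise = quiet_noise(), dynamics = dyn, seed = 3)
  expect_gt(trial_stats(tr)$n_switches, 0)
  # adaptation and recovery off too: the incumbent holds forever
  dyn0 <- dynamics_params(gain = 1, tau_d = Inf, tau_r = Inf)
  tr0 <- run_trial(cond, noise = quiet_noise(), dynamics = dyn0, seed = 3)
  expect_identical(unique(tr0$dominant), tr0$dominant[1])
})

test_that("green-background trials favor the red percept", {
  for (seed in c(1, 23, 456)) {
    pr <- dominance_proportions(run_trial(condition_spec("exp1", "green"),
                                          seed = seed))
    expect_gt(pr[["red"]], pr[["green"]])
  }
})

test_that("zero-noise full-bias alternation has the closed-form period", {
  # with noise off, gain always on the dominant, equal drives and the reset
  # switch rule, each dominance phase decays from the ceiling while the
  # rival recovers from full suppression: the phase length is the crossing
  # of g*exp(-t/tau_d) with 1 - exp(-t/tau_r)
  root <- uniroot(function(t) 1.3 * exp(-t / 2.5) - (1 - exp(-t / 1.5)),
                  c(0.1, 10), tol = 1e-9)$root
  for (dtv in c(0.25, 0.01)) {
    dyn <- dynamics_params(gain_bias = 1, dt = dtv, switch_rule = "reset")
    tr <- run_trial(condition_spec("exp1", "gray"), noise = quiet_noise(),
                    dynamics = dyn, seed = 1)
    durs <- rle(tr$dominant)$lengths * dtv
    steady <- durs[-c(1, length(durs))] # drop the truncated end phases
    expect_identical(length(unique(steady)), 1L) # constant period
    # the sampling clock quantises the switch to the next dt tick
    expect_lte(abs(steady[1] - root), dtv + 0.011)
  }
  # the default carry rule also settles into constant-period alternation
  dyn <- dynamics_params(gain_bias = 1, switch_rule = "carry")
  tr <- run_trial(condition_spec("exp1", "gray"), noise = quiet_noise(),
                  dynamics = dyn, seed = 1)
  durs <- rle(tr$dominant)$lengths
  steady <- durs[10:(length(durs) - 1)]
  expect_identical(length(unique(steady)), 1L)
})

test_that("trial statistics summarise episodes coherently", {
  tr <- run_trial(condition_spec("exp1", "gray"), seed = 12)
  st <- trial_stats(tr)
  expect_equal(sum(st$proportions), 1)
  expect_gte(st$switch_rate_hz, 0)
  expect_gt(st$mean_duration_s[["overall"]], 0)
  # proportions and durations agree through the episode decomposition
  keep <- tr$time_s >= 10
  expect_equal(st$n_switches,
               sum(tr$dominant[keep][-1] != tr$dominant[keep][-sum(keep)]))
})
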