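test_that("staircase success requires the strict predicted ordering", {
  # the published group means satisfy both predicted orderings
  expect_true(staircase_success("green", 0.313, 0.459, 0.702))
  expect_true(staircase_success("red", 0.545, 0.323, 0.182))
  # ties violate strict ordering
  expect_false(staircase_success("green", 0.5, 0.5, 0.6))
  expect_false(staircase_success("red", 0.5, 0.5, 0.4))
  # wrong direction
  expect_false(staircase_success("green", 0.7, 0.5, 0.3))
  expect_error(staircase_success("green", NA, 0.5, 0.6), "finite")
})

test_that("exactly one of the six orderings of distinct values succeeds", {
  vals <- c(0.2, 0.5, 0.8)
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  for (pc in c("green", "red")) {
    wins <- vapply(perms, function(p) {
      staircase_success(pc, vals[p[1]], vals[p[2]], vals[p[3]])
    }, logical(1))
    expect_identical(sum(wins), 1L)
  }
})

test_that("binomial tails are exact against direct summation", {
  cases <- expand.grid(k = c(0, 1, 4, 9), n = c(5, 10, 20),
                       p0 = c(1 / 6, 1 / 36, 0.5))
  cases <- cases[cases$k <= cases$n, ]
  for (i in seq_len(nrow(cases))) {
    with(cases[i, ], {
      expect_equal(binomial_tail(k, n, p0),
                   binom_tail_by_summation(k, n, p0),
                   tolerance = 1e-12)
    })
  }
  # upper and lower tails partition the distribution exactly
  for (i in seq_len(nrow(cases))) {
    with(cases[i, ], {
      if (k >= 1) {
        expect_equal(binomial_tail(k, n, p0) + pbinom(k - 1, n, p0), 1,
                     tolerance = 1e-12)
      }
    })
  }
  expect_identical(binomial_tail(0, 10, 1 / 6), 1)
  expect_error(binomial_tail(11, 10, 1 / 6), "k <= n")
  expect_error(binomial_tail(2, 10, 1.5), "p0")
})

test_that("the published staircase counts clear the 0.001 bound", {
  # 9 of 10 staircases at chance 1/6; 4 of 5 observers at chance 1/36
  p1 <- binomial_tail(9, 10, 1 / 6)
  p2 <- binomial_tail(4, 5, (1 / 6)^2)
  expect_equal(p1, 8.434468e-07, tolerance = 1e-6)
  expect_equal(p2, 2.910718e-06, tolerance = 1e-6)
  expect_lt(p1, 0.001)
  expect_lt(p2, 0.001)
  row <- staircase_binomial("all_staircases", 9, 10, 1 / 6)
  expect_identical(row$p_value, p1)
})

test_that("dominance summaries aggregate reports by day", {
  # three repeats with known proportions: mean 0.5, SEM 0.1/sqrt(3)
  rec <- data.frame(
    observer = "S1", day = rep(1:3, each = 1), trial = 1,
    percept = "green",
    onset_s = 0, offset_s = c(24, 30, 36)
  )
  out <- dominance_summary(rec, window_s = 60)
  expect_equal(out$mean_proportion, 0.5)
  expect_equal(out$sem, 0.1 / sqrt(3))
  expect_identical(out$n_days, 3L)
  # single repeat: SEM reported as absent
  one <- dominance_summary(rec[1, ], window_s = 60)
  expect_equal(one$mean_proportion, 0.4)
  expect_true(is.na(one$sem))
  # full coverage by one percept
  full <- dominance_summary(
    data.frame(observer = "S1", day = 1, trial = 1, percept = "red",
               onset_s = 0, offset_s = 60))
  expect_equal(full$mean_proportion, 1)
  # partial coverage leaves the remainder unassigned
  half <- dominance_summary(
    data.frame(observer = "S1", day = 1, trial = 1, percept = "red",
               onset_s = 10, offset_s = 40))
  expect_equal(half$mean_proportion, 0.5)
})

test_that("summaries are invariant to splitting report intervals", {
  whole <- data.frame(observer = "S1", day = 1:3, trial = 1,
                      percept = "green", onset_s = 0, offset_s = 30)
  split <- do.call(rbind, lapply(1:3, function(d) {
    data.frame(observer = "S1", day = d, trial = 1, percept = "green",
               onset_s = c(0, 12.5), offset_s = c(12.5, 30))
  }))
  expect_equal(dominance_summary(whole)$mean_proportion,
               dominance_summary(split)$mean_proportion)
  expect_equal(dominance_summary(whole)$sem, dominance_summary(split)$sem)
})

test_that("overlapping or malformed reports are rejected", {
  bad <- data.frame(observer = "S1", day = 1, trial = 1,
                    percept = c("green", "red"),
                    onset_s = c(0, 5), offset_s = c(10, 12))
  expect_error(dominance_summary(bad), "overlap")
  expect_error(dominance_summary(data.frame(observer = 1)), "columns")
  rev <- data.frame(observer = "S1", day = 1, trial = 1, percept = "red",
                    onset_s = 10, offset_s = 5)
  expect_error(dominance_summary(rev), "offset_s")
})

test_that("simulated traces round-trip through the report dialect", {
  tr <- run_trial(condition_spec("exp1", "gray"), seed = 8)
  rec <- trace_to_reports(tr)
  out <- dominance_summary(rec, window_s = 60)
  pr <- dominance_proportions(tr)
  for (ch in c("red", "green")) {
    expect_equal(out$mean_proportion[out$percept == ch], unname(pr[[ch]]))
  }
  expect_equal(sum(rec$offset_s - rec$onset_s), 60)
})
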