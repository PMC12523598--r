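test_that("rule construction enforces its invariants", {
  expect_equal(qc_rule("1_2.5s", 1)$label, "1_2.5s N1")
  expect_equal(qc_rule("MR")$n_per_event, 4L)
  expect_setequal(qc_rule("MR")$subrules, c("1_3s", "2_2s", "R_4s", "4_1s"))
  expect_length(qc_rule("1_3s", 2)$subrules, 0)
  expect_error(qc_rule("MR", 2), "requires 4")
  expect_error(qc_rule("1_3s", 3), "1, 2 or 4")
})

test_that("single rules reject iff any observation reaches the limit", {
  expect_false(evaluate_event(qc_rule("1_3s", 1), 2.9)$reject)
  expect_true(evaluate_event(qc_rule("1_3s", 1), -3.0)$reject)  # at the limit
  expect_true(evaluate_event(qc_rule("1_2.5s", 1), 2.5)$reject)
  expect_true(evaluate_event(qc_rule("1_3s", 2), c(0.2, 3.4))$reject)
  expect_error(evaluate_event(qc_rule("1_3s", 2), 1), "expects 2")
})

test_that("multirule subrules fire on their defining patterns", {
  mr <- qc_rule("MR")
  ev <- function(z) evaluate_event(mr, z)
  expect_equal(ev(c(2.1, 2.2, 0.1, -0.3))$triggered, "2_2s")
  expect_equal(ev(c(2.5, -1.6, 0, 0))$triggered, "R_4s")  # range 4.1
  expect_equal(ev(c(1.2, 1.4, 1.1, 2.0))$triggered, "4_1s")
  expect_equal(ev(c(-1.2, -1.4, -1.1, -2.0))$triggered, "4_1s")
  expect_equal(ev(c(3.2, 0, 0, 0))$triggered, "1_3s")
  expect_equal(ev(c(4.2, 0, 0, 0))$triggered, c("1_3s", "R_4s"))
  expect_false(ev(c(1.9, -1.9, 0.5, 0.2))$reject)
  expect_true(ev(c(-2.0, -2.0, 0, 0))$reject)   # same-side at the limit
  # opposite sides never count as 2_2s, but the range picks it up
  expect_equal(ev(c(2.1, -2.1, 0, 0))$triggered, "R_4s")
})

test_that("closed-form rejection probabilities match normal-tail oracles", {
  # oracles: two-sided tail of the standard normal at the limit
  expect_equal(false_rejection_probability(qc_rule("1_3s", 1)),
               2 * (1 - pnorm(3)), tolerance = 1e-12)
  expect_equal(false_rejection_probability(qc_rule("1_3s", 1)), 0.0027,
               tolerance = 1e-2)
  expect_equal(false_rejection_probability(qc_rule("1_2s", 1)), 0.0455,
               tolerance = 1e-3)
  # shifted: Phi(shift - k) + 1 - Phi(shift + k)
  expect_equal(
    as.numeric(rejection_probability(qc_rule("1_2s", 1), 3.35)),
    pnorm(1.35) + (1 - pnorm(5.35)), tolerance = 1e-12)
  expect_equal(
    as.numeric(rejection_probability(qc_rule("1_2s", 1), 3.35)),
    0.9115, tolerance = 1e-4)
  # N controls: complement of all N accepting
  p1 <- pnorm(2 - 3) + pnorm(-3 - 2)
  expect_equal(as.numeric(rejection_probability(qc_rule("1_3s", 4), 2)),
               1 - (1 - p1)^4, tolerance = 1e-12)
  expect_error(rejection_probability(qc_rule("1_3s", 1), -0.5),
               "non-negative")
})

test_that("false rejection anchors the monitor-stage exclusion of 1_2s", {
  expect_gt(false_rejection_probability(qc_rule("1_2s", 1)), 0.04)
  expect_lt(false_rejection_probability(qc_rule("1_3s", 1)), 0.01)
})

test_that("brute-force event simulation agrees with closed forms within 4 SE", {
  set.seed(301)
  reps <- 1e5
  for (spec in list(list(k = 2, n = 1), list(k = 3, n = 2),
                    list(k = 2.5, n = 1))) {
    rule <- qc_rule(paste0("1_", sub("\\.0$", "", format(spec$k)), "s"),
                    spec$n)
    for (shift in c(0, 1.5, 3)) {
      z <- matrix(rnorm(reps * spec$n, mean = shift), ncol = spec$n)
      mc <- mean(rowSums(abs(z) >= spec$k) > 0)
      cf <- as.numeric(rejection_probability(rule, shift))
      se <- sqrt(max(cf * (1 - cf), 1e-12) / reps)
      expect_lt(abs(mc - cf), 4 * se + 1e-9)
    }
  }
})

test_that("critical shift is sigma minus 1.65 and fails at the boundary", {
  expect_equal(critical_shift(5), 3.35)
  expect_equal(critical_shift(6), 4.35)
  expect_error(critical_shift(1.65), "not controllable")
})

test_that("power curves are monotone with Pfr at zero shift", {
  pc <- power_curve(qc_rule("1_3s", 1), shift_grid = 0:4)
  expect_equal(pc$ped[pc$shift == 4], pnorm(1) + pnorm(-7),
               tolerance = 1e-12)
  expect_true(all(diff(pc$ped) >= 0))
  expect_equal(pc$ped[1], false_rejection_probability(qc_rule("1_3s", 1)))
  expect_equal(attr(pc, "pfr"), pc$ped[1])
  expect_error(power_curve(qc_rule("1_3s", 1), c(1, 0.5)), "ascending")

  # detection improves with N for a fixed limit
  pc2 <- power_curve(qc_rule("1_3s", 4), shift_grid = 0:4)
  expect_true(all(pc2$ped >= pc$ped))
})

test_that("the multirule dominates its 1_3s N4 subrule pointwise", {
  grid <- seq(0, 5, by = 0.5)
  mr <- power_curve(qc_rule("MR"), shift_grid = grid, mc_reps = 1e5)
  sub <- power_curve(qc_rule("1_3s", 4), shift_grid = grid)
  expect_true(all(mr$ped + 4 * mr$se_of_ped >= sub$ped))
  # and clearly so away from saturation
  mid <- grid <= 3
  expect_true(all(mr$ped[mid] > sub$ped[mid]))
  # Monte Carlo metadata travels with the curve
  expect_equal(unique(mr$method), "monte_carlo")
  expect_equal(attr(mr, "mc_reps"), 1e5)
})

test_that("multirule Monte Carlo power is reproducible and seed-sensitive", {
  p1 <- rejection_probability(qc_rule("MR"), 2, mc_reps = 2e4, mc_seed = 5)
  p2 <- rejection_probability(qc_rule("MR"), 2, mc_reps = 2e4, mc_seed = 5)
  expect_identical(as.numeric(p1), as.numeric(p2))
  expect_false(isTRUE(all.equal(
    as.numeric(p1),
    as.numeric(rejection_probability(qc_rule("MR"), 2, mc_reps = 2e4,
                                     mc_seed = 6)))))
  # user RNG stream is not disturbed
  set.seed(123); before <- rnorm(1)
  set.seed(123); invisible(rejection_probability(qc_rule("MR"), 1,
                                                 mc_reps = 1e4))
  expect_identical(rnorm(1), before)
})
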