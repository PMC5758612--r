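test_that("the transformed up/down equilibrium follows p^n = 0.5", {
  expect_identical(equilibrium_probability(3, 1), 0.5^(1 / 3))
  expect_identical(equilibrium_probability(1, 1), 0.5)
  expect_equal(equilibrium_probability(2, 1), sqrt(0.5), tolerance = 1e-15)
  expect_error(equilibrium_probability(3, 2), "1-up")
})

test_that("a deterministic step-oracle staircase descends in 3-trial blocks and brackets the edge", {
  res <- run_staircase(function(c_) c_ >= 0.1, staircase_settings())
  expect_identical(res$termination_reason, "reversals_reached")
  expect_identical(length(res$reversal_contrasts), 14L)
  # descent: first 21 trials all correct, one down-step per 3 trials
  expect_true(all(res$trials$correct[1:21]))
  expect_equal(res$trials$contrast[22], 0.5 * 10^(-0.7), tolerance = 1e-9)
  # first reversal at the first contrast below the edge
  expect_lt(res$reversal_contrasts[1], 0.1)
  expect_gt(res$reversal_contrasts[1], 0.1 * 10^(-0.1))
  # thereafter it oscillates between the two levels bracketing 0.1
  last6 <- tail(res$reversal_contrasts, 6)
  expect_equal(sort(unique(round(log10(last6), 6))),
               round(log10(0.5) - 0.1 * c(7, 6), 6))
  # threshold within one 0.1-log step of the edge (log-mean of the bracket)
  expect_lt(abs(log10(res$threshold) - log10(0.1)), 0.1)
  expect_equal(res$threshold, sqrt(prod(unique(last6))), tolerance = 1e-9)
})

test_that("an always-correct oracle runs to the floor with no reversals and an invalid threshold", {
  expect_warning(
    res <- run_staircase(function(c_) TRUE, staircase_settings()),
    "reversal")
  expect_identical(res$termination_reason, "trials_exhausted")
  expect_identical(res$n_trials_run, 120L)
  expect_identical(length(res$reversal_contrasts), 0L)
  expect_true(is.na(res$threshold))
  expect_false(res$valid)
  s <- staircase_settings()
  expect_true(all(res$trials$contrast >= s$contrast_floor - 1e-15))
  expect_true(all(res$trials$contrast <= s$contrast_ceiling + 1e-15))
})

test_that("logged reversals are exactly the sign changes of executed steps", {
  obs <- flat_observer(threshold = 0.2)
  set.seed(3)
  for (i in 1:5) {
    res <- measure_threshold(obs, cond_at())
    steps <- sign(diff(log10(res$trials$contrast)))
    executed <- which(steps != 0)
    dirs <- steps[executed]
    change <- executed[which(diff(dirs) != 0) + 1]   # trial after which dir flipped
    # the step following the final trial is not part of the trial record, so
    # a reversal logged on the terminating trial is compared separately
    logged <- which(res$trials$reversal)
    expect_identical(logged[logged < res$n_trials_run], change)
    expect_lte(length(res$reversal_contrasts), 14L)
    expect_lte(res$n_trials_run, 120L)
  }
})

test_that("settings invariants are enforced", {
  expect_error(staircase_settings(step_log10 = 0), "positive")
  expect_error(staircase_settings(n_reversals_for_threshold = 20), "exceed")
  expect_error(staircase_settings(start_contrast = 2), "ceiling")
  expect_error(staircase_settings(n_up = 2), "1-up")
})

test_that("a single seeded convergence run equals a direct staircase call", {
  obs <- flat_observer(threshold = 0.2)
  rep1 <- convergence_report(obs, cond_at(), n_runs = 1, seed = 5)
  set.seed(5)
  direct <- measure_threshold(obs, cond_at())
  expect_identical(rep1$estimates, direct$threshold)
})

test_that("the reversal-mean estimator recovers the 79.4% point with small bias", {
  obs <- flat_observer(threshold = 0.2, beta = 3, lapse = 0.02)
  rep <- convergence_report(obs, cond_at(), n_runs = 100, seed = 21)
  expect_lt(abs(rep$bias_log10), 0.05)
  expect_identical(rep$n_valid, 100L)
})

test_that("steeper psychometric slopes yield more precise staircase estimates", {
  shallow <- convergence_report(flat_observer(threshold = 0.2, beta = 2),
                                cond_at(), n_runs = 150, seed = 9)
  steep <- convergence_report(flat_observer(threshold = 0.2, beta = 8),
                              cond_at(), n_runs = 150, seed = 9)
  expect_lt(steep$sd_log10_estimate, shallow$sd_log10_estimate)
})
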