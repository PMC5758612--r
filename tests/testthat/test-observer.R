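test_that("2AFC guess rate and lapse-limited asymptote bound the psychometric function", {
  obs <- flat_observer(threshold = 0.01, beta = 3, lapse = 0.02)
  expect_equal(p_correct(obs, cond_at(), 0), 0.5)
  expect_equal(p_correct(obs, cond_at(), 1), 0.98, tolerance = 1e-6)
})

test_that("Weibull evaluates in closed form at its scale parameter", {
  thr <- 0.2
  obs <- flat_observer(threshold = thr, beta = 3, lapse = 0)
  # invert the 79.37% parameterisation to recover alpha independently
  p_star <- 0.5^(1 / 3)
  alpha <- thr / (-log(1 - (p_star - 0.5) / 0.5))^(1 / 3)
  expect_equal(p_correct(obs, cond_at(), alpha), 0.5 + 0.5 * (1 - exp(-1)),
               tolerance = 1e-12)
  # and by construction P(threshold) is the staircase equilibrium
  expect_equal(p_correct(obs, cond_at(), thr), p_star, tolerance = 1e-12)
})

test_that("p_correct is non-decreasing in contrast for assorted parameters", {
  grid <- seq(0, 1, length.out = 200)
  for (beta in c(1, 2, 3, 8)) {
    for (lapse in c(0, 0.05)) {
      obs <- flat_observer(threshold = 0.15, beta = beta, lapse = lapse)
      p <- vapply(grid, function(c_) p_correct(obs, cond_at(), c_), 0)
      expect_true(all(diff(p) >= -1e-12))
    }
  }
})

test_that("collinear threshold equals baseline scaled by 10^TE, exactly", {
  profile <- lateral_profile(c("3" = 0.2, "4" = 0.05, "6" = -0.1, "8" = -0.15))
  obs <- observer_model(c("3" = 0.2, "4" = 0.2, "6" = 0.2, "8" = 0.2), profile)
  expect_equal(true_threshold(obs, cond_at(3, "collinear")), 0.2 * 10^0.2,
               tolerance = 1e-12)
  for (s in c(3, 4, 6, 8)) {
    ratio <- log10(true_threshold(obs, cond_at(s, "collinear")) /
                     true_threshold(obs, cond_at(s, "orthogonal")))
    expect_equal(ratio, unname(profile$te_by_separation[as.character(s)]),
                 tolerance = 1e-12)
  }
  # null profile: collinear and orthogonal coincide
  null_obs <- flat_observer(te = 0)
  expect_equal(true_threshold(null_obs, cond_at(3, "collinear")),
               true_threshold(null_obs, cond_at(3, "orthogonal")))
})

test_that("true_threshold is the unique root of p_correct minus the equilibrium", {
  obs <- flat_observer(threshold = 0.13, beta = 2.5, lapse = 0.03)
  thr <- true_threshold(obs, cond_at())
  root <- uniroot(function(c_) p_correct(obs, cond_at(), c_) - 0.5^(1 / 3),
                  c(1e-6, 1), tol = 1e-12)$root
  expect_equal(thr, root, tolerance = 1e-8)
})

test_that("the lateral profile interpolates and locates the perceptual-field border", {
  prof <- lateral_profile(c("3" = 0.3, "4" = 0.1, "6" = -0.1, "8" = -0.15))
  expect_lt(profile_te(prof, 6), 0)
  expect_gt(profile_te(prof, 3), 0)
  # zero crossing of the piecewise-linear profile between 4 and 6 lambda
  expect_equal(prof$pf_border_lambda, 4 + 2 * 0.1 / 0.2, tolerance = 1e-12)
  expect_equal(profile_te(prof, prof$pf_border_lambda), 0, tolerance = 1e-12)
  # monotone profile with no sign change has no border
  expect_true(is.na(lateral_profile(c("3" = 0.2, "4" = 0.1))$pf_border_lambda))
})

test_that("responses are reproducible under a seed and match binomial sampling", {
  obs <- flat_observer(threshold = 0.2, beta = 3, lapse = 0.02)
  set.seed(42)
  a <- replicate(50, respond(obs, cond_at(), 0.2))
  set.seed(42)
  b <- replicate(50, respond(obs, cond_at(), 0.2))
  expect_identical(a, b)

  set.seed(7)
  draws <- replicate(10000, respond(obs, cond_at(), 0.2))
  p_star <- 0.5^(1 / 3)
  se <- sqrt(p_star * (1 - p_star) / 10000)
  expect_lt(abs(mean(draws) - p_star), 3 * se)
})

test_that("invalid observer parameters are rejected", {
  expect_error(psychometric_params(beta = 0), "positive")
  expect_error(psychometric_params(lapse = 0.2), "0, 0.1")
  expect_error(observer_model(c("3" = 1.5), lateral_profile(c("3" = 0))),
               "\\(0, 1\\]")
  expect_error(observer_model(0.2, lateral_profile(c("3" = 0))), "named")
  obs <- flat_observer()
  expect_error(p_correct(obs, cond_at(4), 0.2), "separation 4")
  expect_error(p_correct(obs, cond_at(), 1.5), "\\[0, 1\\]")
})
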