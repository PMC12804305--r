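test_that("one-phase fit recovers exact data to optimizer tolerance", {
  t_h <- seq(0, 140, length.out = 8)
  a <- 100 * exp(-0.01 * t_h)
  fit <- fit_effective_half_life(t_h, a, model = "one_phase")
  expect_equal(fit$coefficients[["lambda"]], 0.01, tolerance = 1e-6)
  expect_equal(fit$coefficients[["A0"]], 100, tolerance = 1e-6)
  expect_equal(fit$t_half_eff_h, 69.3147, tolerance = 1e-4)
})

test_that("auto model selection collapses a degenerate biexponential", {
  t_h <- seq(0, 100, length.out = 9)
  a <- 50 * exp(-0.02 * t_h)  # two-phase with A2 = 0 is really one-phase
  fit <- fit_effective_half_life(t_h, a, model = "auto")
  expect_identical(fit$model, "one_phase")
})

test_that("two-phase fits separate a genuine biexponential", {
  t_h <- seq(0, 120, length.out = 12)
  a <- 80 * exp(-0.15 * t_h) + 20 * exp(-0.01 * t_h)
  fit <- fit_effective_half_life(t_h, a, model = "two_phase")
  expect_equal(fit$coefficients[["lambda1"]], 0.15, tolerance = 1e-5)
  expect_equal(fit$coefficients[["lambda2"]], 0.01, tolerance = 1e-5)
  expect_gt(fit$coefficients[["lambda1"]], fit$coefficients[["lambda2"]])
  # and auto prefers it on these data
  expect_identical(fit_effective_half_life(t_h, a, model = "auto")$model,
                   "two_phase")
})

test_that("5% multiplicative noise leaves the rate recoverable", {
  errs <- vapply(1:100, function(seed) {
    wb <- generate_wholebody(78.41, 100, n_points = 10, noise_cv = 0.05,
                             seed = seed)
    fit <- fit_effective_half_life(wb$t_h, wb$activity, model = "one_phase")
    abs(fit$coefficients[["lambda"]] - wb$truth$lambda_eff_per_h) /
      wb$truth$lambda_eff_per_h
  }, numeric(1))
  expect_lt(stats::median(errs), 0.05)
})

test_that("fitting preconditions are enforced", {
  expect_error(fit_effective_half_life(c(0, 1), c(2, 1)), "3 points")
  expect_error(fit_effective_half_life(c(0, 1, 2, 3), c(4, 3, 2, 1),
                                       model = "two_phase"), "5 points")
  expect_error(fit_effective_half_life(c(0, 1, 2), c(1, 0, 1)), "positive")
})

test_that("effective half-life of an excreted tracer is below the physical one", {
  for (seed in 1:20) {
    wb <- generate_wholebody(78.41, t_half_bio_h = 60, n_points = 10,
                             noise_cv = 0.05, seed = seed)
    fit <- fit_effective_half_life(wb$t_h, wb$activity,
                                   model = "one_phase", nuclide = "Zr-89")
    expect_lt(fit$t_half_eff_h, 78.41)
    # biological half-life back out of 1/t_eff = 1/t_phys + 1/t_bio
    expect_equal(1 / fit$t_half_biological_h,
                 1 / fit$t_half_eff_h - 1 / 78.41, tolerance = 1e-9)
  }
  # no excretion: the series is pure physical decay
  wb <- generate_wholebody(78.41, Inf, n_points = 8, noise_cv = 0)
  fit <- fit_effective_half_life(wb$t_h, wb$activity, model = "one_phase")
  expect_equal(fit$t_half_eff_h, 78.41, tolerance = 1e-6)
})

test_that("Bateman daughter matches brute-force ODE integration", {
  skip_if_not_installed("deSolve")
  grid <- expand.grid(lm = c(0.001, 0.05, 0.3, 0.999, 0.9999999999),
                      ld = 1.0, t = c(0.5, 2, 10))
  for (i in seq_len(nrow(grid))) {
    p <- grid[i, ]
    analytic <- bateman_daughter(100, p$lm, p$ld, p$t, BR = 0.8)
    numeric <- ode_daughter(100, p$lm, p$ld, p$t, BR = 0.8)
    expect_equal(analytic, numeric, tolerance = 1e-8)
  }
})

test_that("Bateman boundary cases", {
  expect_equal(bateman_daughter(100, 0.1, 1, 0), 0)           # t = 0
  # secular case, BR 1: half the mother activity after one daughter t1/2
  ld <- log(2) / 4.6
  expect_equal(bateman_daughter(100, 0, ld, 4.6, BR = 1), 50,
               tolerance = 1e-12)
  # frozen value from the ODE oracle (A_m0 100, lm 0.1, ld 1, t 2 h)
  expect_equal(bateman_daughter(100, 0.1, 1, 2), 75.9328299823743,
               tolerance = 1e-9)
  # exact rate degeneracy takes the analytic limit lam*t*exp(-lam*t)
  expect_equal(bateman_daughter(100, 1, 1, 2), 100 * 2 * exp(-2),
               tolerance = 1e-12)
})

test_that("secular formula is the lambda_m -> 0 limit of the full Bateman", {
  ld <- log(2) / (45.6 / 60)  # per hour
  t <- c(0.1, 0.5, 1, 2, 5, 10)
  expect_equal(bateman_daughter(100, 1e-12, ld, t, BR = 0.9),
               secular_daughter(100, ld, t, BR = 0.9), tolerance = 1e-9)
  # asymptote A_m0 * BR after ten daughter half-lives
  expect_equal(secular_daughter(100, ld, 10 * 45.6 / 60, BR = 1),
               100 * (1 - 2^-10), tolerance = 1e-9)
})

test_that("equilibrium timing reproduces the five-half-life rule", {
  ld <- log(2) / 1
  expect_equal(time_to_equilibrium(ld, 0.5), 1, tolerance = 1e-12)
  # smallest integer number of half-lives with 1 - 2^-n >= 0.95
  n <- ceiling(time_to_equilibrium(ld, 0.95))
  expect_equal(n, 5)
  # 45.6-min daughter to 99%: ~5 h
  ld_bi <- log(2) / 45.6
  t99_min <- time_to_equilibrium(ld_bi, 0.99)
  expect_equal(t99_min, 302.959842253727, tolerance = 1e-9)
  expect_equal(round(t99_min / 60), 5)
  expect_error(time_to_equilibrium(ld, 1), "fraction")
})

test_that("transient equilibrium ratio and peak time", {
  expect_equal(transient_ratio(0.1, 1.0), 10 / 9, tolerance = 1e-12)
  expect_equal(transient_ratio(1e-9, 1.0, BR = 0.7), 0.7, tolerance = 1e-6)
  expect_error(transient_ratio(1, 1), "lambda_d > lambda_m")
  # the daughter maximum sits where the Bateman curve peaks
  lm <- 0.05; ld <- 0.8
  tmax <- daughter_peak_time(lm, ld)
  tt <- seq(0.01, 20, by = 0.001)
  expect_equal(tt[which.max(bateman_daughter(1, lm, ld, tt))], tmax,
               tolerance = 1e-3)
})

test_that("mother activity inverts from the measured daughter", {
  # equilibrium identity: at secular equilibrium A_m0 = A_d (BR = 1)
  ld <- log(2) / 0.76
  expect_equal(mother_from_daughter(7.3, 40, 0, ld), 7.3, tolerance = 1e-9)
  # round trip through the forward model
  ad <- bateman_daughter(7.3, 0.02, 0.9, 3, BR = 0.85)
  expect_equal(mother_from_daughter(ad, 3, 0.02, 0.9, BR = 0.85), 7.3,
               tolerance = 1e-12)
  # generator breakthrough scenario: mother Ra-224 (3.63 d), daughter
  # Pb-212 (10.6 h), remeasured after 5 days
  lm <- log(2) / (3.63 * 24)
  ld2 <- log(2) / 10.6
  ad5 <- bateman_daughter(4.2, lm, ld2, 5 * 24)
  expect_equal(mother_from_daughter(ad5, 5 * 24, lm, ld2), 4.2,
               tolerance = 1e-9)
  # measuring far too early is ill-conditioned
  expect_error(mother_from_daughter(0.01, 1e-9, lm, ld2),
               "ill-conditioned")
})
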