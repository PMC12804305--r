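test_that("background aggregation follows the configured policy", {
  expect_equal(suppressWarnings(background_cpm(c(30, 32, 28, 30))), 30)
  expect_equal(suppressWarnings(background_cpm(0)), 0)
  expect_error(background_cpm(numeric(0)), "no background")
  expect_warning(background_cpm(c(30, 31)), "fewer than 3")
  expect_equal(background_cpm(c(10, 11, 1000, 12), policy = "median"), 11.5)
})

test_that("standard syringe delivered mass must be positive", {
  expect_equal(standard_mass_delivered(1.0042, 0.9), 0.1042,
               tolerance = 1e-12)
  expect_error(standard_mass_delivered(1.0, 1.0), "no mass")
  expect_error(standard_mass_delivered(0.9, 1.0), "no mass")
})

test_that("aliquot formulation mass is a mass-fraction dilution", {
  expect_equal(aliquot_formulation_mass(1.01042, 0.1042, 10.1042), 0.010420,
               tolerance = 1e-9)
  # the whole stock contains the whole standard
  expect_equal(aliquot_formulation_mass(10.1042, 0.1042, 10.1042), 0.1042)
  expect_error(aliquot_formulation_mass(0, 0.1, 10), "non-positive")
  expect_error(aliquot_formulation_mass(11, 0.1, 10), "exceeds")
})

test_that("the calibration factor recovers CPM per gram of formulation", {
  study <- tiny_study()
  q <- quantify_study(study)
  cal <- q$calibration
  # 4 aliquots, each net 52100 CPM over 0.010420 g formulation
  expect_equal(cal$cf_mass, 5e6, tolerance = 1e-9)
  expect_equal(cal$cv_pct, 0, tolerance = 1e-9)
  expect_equal(cal$background_cpm, 30)
  expect_equal(cal$standard_mass_delivered_g, 0.1042, tolerance = 1e-12)
})

test_that("activity-based factor follows cf_mass * std_mass / A_delivered", {
  # direct substitution: cf 5e6 CPM/g, 0.1042 g delivered, 2.0 MBq
  standards <- data.frame(tube_id = paste0("STD", 1:4),
                          tube_empty_mass_g = 5.2,
                          tube_full_mass_g = 5.2 + 1.01042,
                          cpm = 52130)
  stock <- list(tube_empty_g = 6.8, tube_plus_water_g = 16.8,
                tube_plus_water_plus_standard_g = 16.9042)
  t_ref <- t_base()
  syr <- list(mass_full_g = 1.0042, mass_empty_g = 0.9,
              activity_before_MBq = 2.5,
              t_activity_before = format_timestamp(t_ref),
              activity_after_MBq = 0.5,
              t_activity_after = format_timestamp(t_ref))
  cal <- calibration_factor(standards, stock, syr, background = 30,
                            nuclide = get_nuclide("Zr-89"), t_ref = t_ref)
  expect_equal(cal$A_delivered_MBq, 2.0)
  expect_equal(cal$cf_activity, 2.605e5, tolerance = 1e-9)
})

test_that("a standard tube at background level is an error naming the tube", {
  study <- tiny_study()
  study$samples$cpm[study$samples$tube_id == "STD2"] <- 30
  expect_error(suppressWarnings(quantify_study(study)), "STD2")
})

test_that("calibration is scale-equivariant in CPM", {
  base <- tiny_study()
  scaled <- tiny_study()
  scaled$samples$cpm <- scaled$samples$cpm * 7
  cf1 <- quantify_study(base)$calibration$cf_mass
  cf7 <- quantify_study(scaled)$calibration$cf_mass
  expect_equal(cf7, 7 * cf1, tolerance = 1e-12)
})

test_that("zero-noise synthetic data recover the generator constant exactly", {
  g <- generate_study(synth_config(noise = "none", seed = 5))
  cal <- quantify_study(g$study)$calibration
  expect_equal(cal$cf_mass, g$truth$counts_per_gram_constant,
               tolerance = 1e-10)
})

test_that("dispersed standard aliquots raise the CV warning", {
  study <- tiny_study()
  i <- which(study$samples$role == "standard")
  study$samples$cpm[i] <- c(52130, 62130, 42130, 52130)
  expect_warning(quantify_study(study), "CV")
})

test_that("linearity check flags a disproportionate point", {
  # perfectly proportional: zero deviation
  expected <- c(1, 2, 4, 8)
  lc <- linearity_check(expected, 1000 * expected)
  expect_equal(lc$max_deviation_pct, 0, tolerance = 1e-9)
  expect_true(lc$pass)
  # one point +10%: independent oracle = explicit least-squares arithmetic
  measured <- 1000 * expected
  measured[3] <- measured[3] * 1.10
  slope <- sum(expected * measured) / sum(expected^2)
  oracle_dev <- 100 * max(abs((measured - slope * expected) / (slope * expected)))
  lc <- linearity_check(expected, measured)
  expect_equal(lc$max_deviation_pct, oracle_dev, tolerance = 1e-9)
  expect_gt(lc$max_deviation_pct, 5)
  expect_false(lc$pass)
  expect_equal(which.max(abs(lc$relative_residuals)), 3L)
  expect_error(linearity_check(c(1, 2), c(10, 20)), "3 points")
})
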