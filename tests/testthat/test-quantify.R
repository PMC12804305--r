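test_that("injected activity from injected mass and calibration factor", {
  study <- tiny_study()
  q <- quantify_study(study)
  # 0.1242 g at 5e6 CPM/g
  expect_equal(q$per_animal$injected_cpm, 6.21e5, tolerance = 1e-9)
  expect_equal(q$per_animal$injected_mass_g, 0.1242, tolerance = 1e-12)
})

test_that("a non-positive injected mass is rejected", {
  cal <- quantify_study(tiny_study())$calibration
  expect_error(injected_activity(list(mass_full_g = 3, mass_empty_g = 3),
                                 cal), "non-positive injected mass")
})

test_that("manual override replaces the mass-based activity via cf_activity", {
  cal <- structure(list(cf_mass = 5e6, cf_activity = 2.605e5,
                        background_cpm = 30), class = "calibration_result")
  ia <- injected_activity(list(mass_full_g = 3.1242, mass_empty_g = 3.0),
                          cal, override_MBq = 1.5)
  expect_equal(ia$injected_cpm, 3.9075e5, tolerance = 1e-12)
  expect_identical(ia$source, "override")
  # without an activity factor the override cannot be applied
  cal$cf_activity <- NULL
  expect_error(injected_activity(list(mass_full_g = 3.1242,
                                      mass_empty_g = 3.0),
                                 cal, override_MBq = 1.5),
               "activity calibration factor")
})

test_that("net CPM honours the negative-net policy", {
  expect_equal(net_cpm(1030, 30)$net_cpm, 1000)
  expect_equal(net_cpm(30, 30)$net_cpm, 0)
  r <- net_cpm(10, 30, policy = "flag")
  expect_equal(r$net_cpm, -20)
  expect_identical(r$flags, "negative_net")
  r <- net_cpm(10, 30, policy = "clamp")
  expect_equal(r$net_cpm, 0)
  expect_identical(r$flags, "negative_net")
})

test_that("%ID/g, %ID organ and SUV definitions hold", {
  expect_equal(pct_id_per_gram(12420, 0.1, 6.21e5), 20, tolerance = 1e-12)
  expect_equal(pct_id_per_gram(0, 0.5, 6.21e5), 0)
  # whole-carcass conservation: all injected counts in 1 g -> 100 %ID/g
  expect_equal(pct_id_per_gram(6.21e5, 1, 6.21e5), 100)
  expect_true(is.na(pct_id_per_gram(100, 0, 6.21e5)))  # zero mass undefined
  expect_error(pct_id_per_gram(100, 0.1, 0), "positive")

  expect_equal(suv(20, 20), 4)
  expect_equal(suv(100 / 37, 37), 1)  # uniform distribution fixed point
  expect_equal(suv(0, 25), 0)
  expect_error(suv(20, 0), "positive")
})

test_that("unit coherence: pct_id_organ = pct_id_per_g * mass", {
  g <- generate_study(synth_config(noise = "poisson", seed = 9))
  tis <- quantify_study(g$study)$tissues
  expect_equal(tis$pct_id_organ, tis$pct_id_per_g * tis$mass_g,
               tolerance = 1e-12)
})

test_that("results are invariant under a common CPM rescaling", {
  base <- tiny_study()
  scaled <- tiny_study()
  scaled$samples$cpm <- scaled$samples$cpm * 3.7
  a <- quantify_study(base)$tissues
  b <- quantify_study(scaled)$tissues
  expect_equal(b$pct_id_per_g, a$pct_id_per_g, tolerance = 1e-12)
  expect_equal(b$suv, a$suv, tolerance = 1e-12)
})

test_that("tiny fixture yields the hand-computed tissue panel", {
  q <- quantify_study(tiny_study())
  tis <- q$tissues
  expect_equal(tis$pct_id_per_g[tis$tissue_name == "tumor"], 20,
               tolerance = 1e-9)
  expect_equal(tis$pct_id_per_g[tis$tissue_name == "muscle"], 2,
               tolerance = 1e-9)
  expect_equal(tis$suv[tis$tissue_name == "tumor"], 4, tolerance = 1e-9)
  r <- contrast_ratios(q, "tumor", "muscle")
  expect_equal(r$per_animal$ratio, 10, tolerance = 1e-9)
})

test_that("contrast ratios guard zero backgrounds and missing tissues", {
  q <- quantify_study(tiny_study())
  q$tissues$pct_id_per_g[q$tissues$tissue_name == "muscle"] <- 0
  r <- contrast_ratios(q, "tumor", "muscle")
  expect_true(is.na(r$per_animal$ratio))
  expect_identical(r$per_animal$flag, "undefined_background")
  expect_warning(contrast_ratios(q, "tumor", "liver"), "missing")
})

test_that("group summary uses sample sd and excludes flagged animals", {
  g <- generate_study(synth_config(noise = "poisson", n_animals = 3,
                                   seed = 21))
  q <- quantify_study(g$study)
  # inject known values {1, 2, 3} for one tissue
  i <- q$tissues$tissue_name == "tumor"
  q$tissues$pct_id_per_g[i] <- c(1, 2, 3)
  gs <- group_summary(q)$summary
  row <- gs[gs$tissue_name == "tumor", ]
  expect_equal(row$n, 3)
  expect_equal(row$mean_pct_id_per_g, 2)
  expect_equal(row$sd_pct_id_per_g, 1)
  expect_equal(row$cv_pct_id_per_g, 50)
  # excluding an animal drops it from the summary but keeps its rows
  q$tissues$excluded[q$tissues$animal_id == "M01"] <- TRUE
  gs2 <- group_summary(q)$summary
  expect_equal(gs2$n[gs2$tissue_name == "tumor"], 2)
  expect_true(any(quantify_study(g$study)$tissues$animal_id == "M01"))
  # single animal: sd undefined
  q$tissues$excluded[q$tissues$animal_id %in% c("M01", "M02")] <- TRUE
  gs3 <- group_summary(q)$summary
  expect_equal(gs3$n[gs3$tissue_name == "tumor"], 1)
  expect_true(is.na(gs3$sd_pct_id_per_g[gs3$tissue_name == "tumor"]))
})

test_that("summed %ID above 100% + tolerance triggers the recovery warning", {
  q <- quantify_study(tiny_study())
  q$tissues$pct_id_organ <- c(80, 40)  # 120% total
  expect_warning(group_summary(q), "exceeds 100")
})

test_that("zero-noise synthetic study is an exact fixed point of the analysis", {
  g <- generate_study(synth_config(noise = "none", seed = 13))
  q <- quantify_study(g$study)
  tr <- g$truth$true_pct_id_per_g
  for (i in seq_len(nrow(q$tissues))) {
    truth <- tr[q$tissues$animal_id[i], q$tissues$tissue_name[i]]
    expect_equal(q$tissues$pct_id_per_g[i], truth, tolerance = 1e-9)
    expect_equal(q$tissues$suv[i],
                 truth * q$per_animal$body_weight_g[
                   match(q$tissues$animal_id[i], q$per_animal$animal_id)] /
                   100,
                 tolerance = 1e-9)
  }
  # mass-based and dose-calibrator injected activities agree
  expect_equal(q$per_animal$injected_MBq_mass_based,
               q$per_animal$injected_MBq_calibrator, tolerance = 1e-9)
  expect_equal(q$per_animal$injected_cpm,
               unname(g$truth$true_injected_cpm), tolerance = 1e-9)
})

test_that("Poisson-noise group means land within 3 SE of realized truth", {
  # 200 seeded replicates; tissues with >= 1e4 expected counts
  hits <- 0L; total <- 0L
  for (seed in 1:200) {
    g <- generate_study(synth_config(noise = "poisson", n_animals = 4,
                                     seed = seed))
    q <- quantify_study(g$study)
    tis <- q$tissues
    inj <- g$truth$true_injected_cpm[tis$animal_id]
    expected_counts <- inj * tis$pct_id_per_g * tis$mass_g / 100
    for (tn in unique(tis$tissue_name)) {
      i <- tis$tissue_name == tn
      if (mean(expected_counts[i], na.rm = TRUE) < 1e4) next
      est <- tis$pct_id_per_g[i]
      truth <- g$truth$true_pct_id_per_g[tis$animal_id[i], tn]
      se <- stats::sd(est) / sqrt(length(est))
      total <- total + 1L
      if (abs(mean(est) - mean(truth)) <= 3 * se) hits <- hits + 1L
    }
  }
  expect_gte(hits / total, 0.95)
})
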