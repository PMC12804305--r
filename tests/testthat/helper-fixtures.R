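# Shared fixtures built in code.

t_base <- function() parse_timestamp("2026-02-03T08:00:00")

# Minimal hand-built valid study: 1 animal, 4 backgrounds, 4 standards,
# 2 tissues, with exactly known arithmetic (counts-per-gram 5e6, background
# 30 CPM, no noise).
tiny_study <- function(negative_net_policy = "flag") {
  t_ref <- format_timestamp(t_base() + 6 * 3600)
  ts <- function(h) format_timestamp(t_base() + h * 3600)
  syringes <- data.frame(
    syringe_id = c("S01", "STD"),
    role = c("animal", "standard"),
    mass_full_g = c(3.1242, 3.1042),
    mass_empty_g = c(3.0000, 3.0000),
    t_weigh_full = ts(0), t_weigh_empty = ts(1),
    activity_before_MBq = NA_real_, t_activity_before = NA_character_,
    activity_after_MBq = NA_real_, t_activity_after = NA_character_,
    comment = "", stringsAsFactors = FALSE)
  injections <- data.frame(
    animal_id = "M01", syringe_id = "S01", t_injection = ts(0.5),
    body_weight_g = 20, group = "A", exclusion_flag = FALSE,
    manual_injected_activity_override_MBq = NA_real_, comment = "",
    stringsAsFactors = FALSE)
  # stock: 0.1042 g standard into 10 g water -> stock_total 10.1042 g
  stock <- list(tube_empty_g = 6.8, tube_plus_water_g = 16.8,
                tube_plus_water_plus_standard_g = 16.9042,
                standard_syringe_id = "STD", t_spike = ts(1))
  # each 1.01042 g aliquot holds 0.010420 g formulation (by construction
  # 1.01042 / 10.1042 = 0.1); net 52100 CPM -> cf 5e6 CPM/g
  std <- do.call(rbind, lapply(1:4, function(i) data.frame(
    tube_id = paste0("STD", i), role = "standard",
    tube_empty_mass_g = 5.2, tube_full_mass_g = 5.2 + 1.01042,
    cpm = 52130, t_count_ref = t_ref, animal_id = NA_character_,
    tissue_name = NA_character_, stringsAsFactors = FALSE)))
  bkg <- do.call(rbind, lapply(1:4, function(i) data.frame(
    tube_id = paste0("BKG", i), role = "background",
    tube_empty_mass_g = 5.2, tube_full_mass_g = 5.2,
    cpm = c(30, 32, 28, 30)[i], t_count_ref = t_ref,
    animal_id = NA_character_, tissue_name = NA_character_,
    stringsAsFactors = FALSE)))
  # injected_cpm = 5e6 * 0.1242 = 6.21e5
  # tumor: net 12420 over 0.100 g -> 20 %ID/g; muscle: net 1242 over
  # 0.100 g -> 2 %ID/g
  tis <- data.frame(
    tube_id = c("T1", "T2"), role = "tissue",
    tube_empty_mass_g = 5.2, tube_full_mass_g = 5.3,
    cpm = c(12450, 1272), t_count_ref = t_ref, animal_id = "M01",
    tissue_name = c("tumor", "muscle"), stringsAsFactors = FALSE)
  cfg <- study_config("Zr-89", stock = stock,
                      negative_net_policy = negative_net_policy)
  study <- structure(list(syringes = syringes, injections = injections,
                          samples = rbind(bkg, std, tis), config = cfg),
                     class = "biodist_study")
  study$validation <- validate_study(study)
  study
}

# analytic-vs-ODE comparison helper: daughter activity by numerical
# integration of the mother-daughter activity system (independent of the
# closed form under test)
ode_daughter <- function(A_m0, lambda_m, lambda_d, t_end, BR = 1) {
  rhs <- function(t, y, p) {
    list(c(-p$lm * y[1], p$ld * p$BR * y[1] - p$ld * y[2]))
  }
  out <- deSolve::ode(c(A_m0, 0), c(0, t_end), rhs,
                      list(lm = lambda_m, ld = lambda_d, BR = BR),
                      rtol = 1e-12, atol = 1e-12)
  unname(out[nrow(out), 3])
}
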