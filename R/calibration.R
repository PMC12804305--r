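# Weighed-standard calibration: from the standard-syringe dilution and the
# counted standard aliquots to a calibration factor in CPM per gram of
# formulation (optionally CPM per MBq), plus the background estimate.
#
# The chain: the standard syringe delivers `std_mass` g of formulation into
# a ~10 mL water stock of total mass `stock_total`. Each counted ~1 mL
# aliquot of mass m_i therefore contains std_mass * m_i / stock_total grams
# of formulation. Net CPM over that formulation mass gives CPM per gram of
# the injected formulation at the shared counter reference time.

#' Background CPM estimate from background tubes
#'
#' @param cpm numeric vector of background-tube CPM.
#' @param policy `"mean"` (default) or `"median"`.
#' @return scalar background CPM.
#' @export
background_cpm <- function(cpm, policy = c("mean", "median")) {
  policy <- match.arg(policy)
  if (length(cpm) == 0) stop("no background tubes")
  if (any(cpm < 0)) stop("negative background CPM")
  if (length(cpm) < 3) {
    warning("fewer than 3 background replicates; quadruplicate recommended")
  }
  if (policy == "mean") mean(cpm) else stats::median(cpm)
}

#' Mass of formulation delivered by the standard syringe
#'
#' @param mass_full_g loaded standard-syringe mass, g.
#' @param mass_empty_g emptied standard-syringe mass, g.
#' @return delivered mass, g (> 0).
#' @export
standard_mass_delivered <- function(mass_full_g, mass_empty_g) {
  m <- mass_full_g - mass_empty_g
  if (m <= 0) stop("standard syringe delivered no mass (full <= empty)")
  m
}

#' Formulation mass contained in a stock aliquot
#'
#' Mass-fraction dilution: an aliquot of `aliquot_mass_g` grams taken from a
#' well-mixed stock of `stock_total_g` grams containing `std_mass_g` grams
#' of formulation holds `std_mass_g * aliquot_mass_g / stock_total_g` grams.
#'
#' @param aliquot_mass_g aliquot mass, g (0 < m <= stock_total_g).
#' @param std_mass_g formulation mass in the whole stock, g.
#' @param stock_total_g total stock mass (water + formulation), g.
#' @return formulation mass in the aliquot, g.
#' @export
aliquot_formulation_mass <- function(aliquot_mass_g, std_mass_g,
                                     stock_total_g) {
  if (any(aliquot_mass_g <= 0)) stop("non-positive aliquot mass")
  if (any(aliquot_mass_g > stock_total_g)) {
    stop("aliquot mass exceeds total stock mass")
  }
  if (std_mass_g >= stock_total_g) {
    stop("standard mass must be smaller than the total stock mass")
  }
  std_mass_g * aliquot_mass_g / stock_total_g
}

#' Compute the calibration factor from counted standards
#'
#' Per standard aliquot i, `cf_i = (cpm_i - background) / formulation
#' mass_i`; the reported `cf_mass` is their mean, with the CV across
#' aliquots as a pipetting-quality diagnostic. When dose-calibrator
#' readings for the standard syringe exist, an independent activity-based
#' factor `cf_activity = cf_mass * std_mass / A_delivered(t_ref)` (CPM per
#' MBq) is also computed as a cross-check; it never replaces the mass-based
#' factor.
#'
#' @param standards data.frame of standard tubes with columns
#'   `tube_id`, `tube_empty_mass_g`, `tube_full_mass_g`, `cpm` (already
#'   decay-corrected by the counter to the shared reference time).
#' @param stock list with `tube_empty_g`, `tube_plus_water_g`,
#'   `tube_plus_water_plus_standard_g`.
#' @param std_syringe list/row with `mass_full_g`, `mass_empty_g` and
#'   optionally `activity_before_MBq`, `t_activity_before`,
#'   `activity_after_MBq`, `t_activity_after`.
#' @param background scalar background CPM (see [background_cpm()]).
#' @param nuclide `nuclide` object; needed only for `cf_activity`.
#' @param t_ref shared counter reference time; needed only for
#'   `cf_activity`.
#' @param cv_warn_pct warn when the aliquot CV exceeds this percentage.
#' @return object of class `calibration_result`: `cf_mass` (CPM/g of
#'   formulation at t_ref), `per_standard_cf`, `cv_pct`, `background_cpm`,
#'   `standard_mass_delivered_g`, `stock_total_g`, and optionally
#'   `cf_activity` (CPM/MBq) with `A_delivered_MBq`.
#' @export
calibration_factor <- function(standards, stock, std_syringe, background,
                               nuclide = NULL, t_ref = NULL,
                               cv_warn_pct = 5) {
  if (nrow(standards) == 0) stop("no standard aliquots")
  if (nrow(standards) < 4) {
    warning("fewer than 4 standard aliquots; quadruplicate recommended")
  }
  std_mass <- standard_mass_delivered(std_syringe$mass_full_g,
                                      std_syringe$mass_empty_g)
  stock_total <- stock$tube_plus_water_plus_standard_g - stock$tube_empty_g
  if (stock_total <= 0) stop("non-positive stock total mass")
  aliquot_mass <- tissue_mass(standards$tube_full_mass_g,
                              standards$tube_empty_mass_g)
  form_mass <- aliquot_formulation_mass(aliquot_mass, std_mass, stock_total)
  net <- standards$cpm - background
  if (any(net <= 0)) {
    bad <- standards$tube_id[net <= 0]
    stop("background exceeds standard counts in tube(s): ",
         paste(bad, collapse = ", "))
  }
  per_cf <- net / form_mass
  cf_mass <- mean(per_cf)
  cv <- if (length(per_cf) > 1) 100 * stats::sd(per_cf) / cf_mass else 0
  if (cv > cv_warn_pct) {
    warning(sprintf("standard-aliquot CV %.2f%% exceeds %.1f%%", cv,
                    cv_warn_pct))
  }
  res <- list(
    cf_mass = cf_mass,
    per_standard_cf = per_cf,
    cv_pct = cv,
    background_cpm = background,
    standard_mass_delivered_g = std_mass,
    stock_total_g = stock_total,
    cf_activity = NULL,
    A_delivered_MBq = NULL
  )
  has_act <- !is.null(std_syringe$activity_before_MBq) &&
    !is.na(std_syringe$activity_before_MBq) &&
    !is.null(std_syringe$activity_after_MBq) &&
    !is.na(std_syringe$activity_after_MBq)
  if (has_act && !is.null(nuclide) && !is.null(t_ref)) {
    a_before <- decay_correct(std_syringe$activity_before_MBq,
                              std_syringe$t_activity_before, t_ref, nuclide)
    a_after <- decay_correct(std_syringe$activity_after_MBq,
                             std_syringe$t_activity_after, t_ref, nuclide)
    a_del <- a_before - a_after
    if (a_del > 0) {
      res$A_delivered_MBq <- a_del
      res$cf_activity <- cf_mass * std_mass / a_del
    } else {
      warning("dose-calibrator readings imply non-positive delivered ",
              "activity; cf_activity not computed")
    }
  }
  class(res) <- "calibration_result"
  res
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf("<calibration> cf_mass = %.6g CPM/g (CV %.2f%%, n = %d), background = %.4g CPM\n",
              x$cf_mass, x$cv_pct, length(x$per_standard_cf),
              x$background_cpm))
  if (!is.null(x$cf_activity)) {
    cat(sprintf("  cf_activity = %.6g CPM/MBq (A_delivered = %.4g MBq)\n",
                x$cf_activity, x$A_delivered_MBq))
  }
  invisible(x)
}

#' Gamma-counter linearity check on a dilution series
#'
#' Fits a least-squares line through the origin to measured CPM versus
#' expected relative activity and reports per-point relative residuals.
#' Counter calibration factors can drift, causing non-linearity that
#' underestimates activity in high-count samples; this check flags it.
#'
#' @param expected_relative numeric vector of expected relative activities
#'   (any common scale, e.g. dilution factors).
#' @param measured_cpm measured CPM per point.
#' @param tolerance_pct pass/fail threshold on the maximum relative
#'   deviation (default 5).
#' @return list with `slope`, `relative_residuals`, `max_deviation_pct`,
#'   `pass`.
#' @export
linearity_check <- function(expected_relative, measured_cpm,
                            tolerance_pct = 5) {
  if (length(expected_relative) != length(measured_cpm)) {
    stop("expected and measured vectors differ in length")
  }
  if (length(expected_relative) < 3) {
    stop("need at least 3 points spanning the activity range")
  }
  if (any(expected_relative <= 0)) stop("expected relative activity must be > 0")
  slope <- sum(expected_relative * measured_cpm) / sum(expected_relative^2)
  fitted <- slope * expected_relative
  rel <- (measured_cpm - fitted) / fitted
  maxdev <- 100 * max(abs(rel))
  list(slope = slope,
       relative_residuals = rel,
       max_deviation_pct = maxdev,
       pass = maxdev <= tolerance_pct)
}
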