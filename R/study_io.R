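# Study sheets: data model, readers/writers, validation.
#
# Three UTF-8 CSV sheets mirror the paper forms used at the bench:
#   syringes.csv   - one row per drawn syringe (animal doses + the standard)
#   injections.csv - one row per injected animal
#   samples.csv    - one row per gamma-counted tube (background/standard/tissue)
# plus a JSON study configuration holding the nuclide, the standard-stock
# weighings and processing policies. All masses are grams, recorded to four
# decimals; timestamps are ISO 8601 on one shared clock.

#' Default controlled vocabulary of collected tissues
#' @return character vector of tissue labels.
#' @export
default_tissue_vocabulary <- function() {
  c("blood", "tumor", "gallbladder", "heart", "lung", "liver", "spleen",
    "pancreas", "stomach", "small intestine", "large intestine",
    "adrenal gland", "kidney", "fat", "urine", "muscle", "bone", "brain",
    "tail", "skin")
}

.syringe_cols <- c("syringe_id", "role", "mass_full_g", "mass_empty_g",
                   "t_weigh_full", "t_weigh_empty", "activity_before_MBq",
                   "t_activity_before", "activity_after_MBq",
                   "t_activity_after", "comment")
.injection_cols <- c("animal_id", "syringe_id", "t_injection",
                     "body_weight_g", "group", "exclusion_flag",
                     "manual_injected_activity_override_MBq", "comment")
.sample_cols <- c("tube_id", "role", "tube_empty_mass_g", "tube_full_mass_g",
                  "cpm", "t_count_ref", "animal_id", "tissue_name")

#' Build a study configuration
#'
#' @param nuclide_id radionuclide label, e.g. `"Zr-89"`.
#' @param stock list describing the counting-standard stock dilution:
#'   `tube_empty_g`, `tube_plus_water_g`, `tube_plus_water_plus_standard_g`,
#'   `standard_syringe_id`, `t_spike`.
#' @param t_ref_policy reference-time policy; currently only
#'   `"gamma_protocol_start"` (all counter CPM are already decay-corrected
#'   there by the counter, and syringe activities are corrected to it).
#' @param background_policy `"mean"` or `"median"` aggregation of the
#'   background tubes.
#' @param negative_net_policy `"flag"` keeps negative net CPM (flagged);
#'   `"clamp"` sets them to 0 (flagged).
#' @param tissue_vocabulary controlled vocabulary; unknown tissue labels
#'   warn but are accepted.
#' @param molar_activity_gbq_per_umol optional molar activity.
#' @param counter_ceiling_cpm optional linear-range ceiling; CPM above it
#'   raise a saturation warning (recount recommended).
#' @param cv_warn_pct warn when the calibration-standard CV exceeds this.
#' @param recovery_tolerance_pct warn when an animal's summed %ID exceeds
#'   100 plus this.
#' @return list of class `biodist_config`.
#' @export
study_config <- function(nuclide_id,
                         stock = NULL,
                         t_ref_policy = "gamma_protocol_start",
                         background_policy = c("mean", "median"),
                         negative_net_policy = c("flag", "clamp"),
                         tissue_vocabulary = default_tissue_vocabulary(),
                         molar_activity_gbq_per_umol = NULL,
                         counter_ceiling_cpm = NULL,
                         cv_warn_pct = 5,
                         recovery_tolerance_pct = 5) {
  t_ref_policy <- match.arg(t_ref_policy, "gamma_protocol_start")
  cfg <- list(
    nuclide_id = normalize_nuclide_id(nuclide_id),
    stock = stock,
    t_ref_policy = t_ref_policy,
    background_policy = match.arg(background_policy),
    negative_net_policy = match.arg(negative_net_policy),
    tissue_vocabulary = tissue_vocabulary,
    molar_activity_gbq_per_umol = molar_activity_gbq_per_umol,
    counter_ceiling_cpm = counter_ceiling_cpm,
    cv_warn_pct = cv_warn_pct,
    recovery_tolerance_pct = recovery_tolerance_pct
  )
  class(cfg) <- "biodist_config"
  cfg
}

#' Read a study configuration from JSON
#' @param path JSON file written by [write_config()].
#' @return `biodist_config` list.
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(study_config, raw[intersect(names(raw), names(formals(study_config)))])
}

#' Write a study configuration to JSON
#' @param config `biodist_config`.
#' @param path output path.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Plan the formulation volume for a study
#'
#' A counting standard must be drawn from the same formulation as the animal
#' doses, so at least n + 1 syringes are prepared for n animals.
#'
#' @param n_animals number of animals to inject (>= 1).
#' @param volume_per_dose_ul injected volume per animal, microlitres.
#' @return list with `total_volume_ul` and `n_syringes`.
#' @export
#' @examples
#' plan_formulation(5, 100)  # 600 uL, 6 syringes
plan_formulation <- function(n_animals, volume_per_dose_ul) {
  if (!is.numeric(n_animals) || length(n_animals) != 1L ||
      n_animals < 1 || n_animals != round(n_animals)) {
    stop("n_animals must be a positive integer")
  }
  if (!is.numeric(volume_per_dose_ul) || volume_per_dose_ul <= 0) {
    stop("volume_per_dose_ul must be positive")
  }
  list(total_volume_ul = (n_animals + 1) * volume_per_dose_ul,
       n_syringes = as.integer(n_animals) + 1L)
}

#' Tissue mass from tube weighings
#'
#' The tissue (or standard aliquot) mass is the difference between the
#' filled tube and the pre-weighed empty tube (tube + cap).
#'
#' @param tube_full_mass_g filled tube mass, g.
#' @param tube_empty_mass_g empty tube (+ cap) mass, g.
#' @return mass in g (>= 0); exactly 0 warns of an empty tube.
#' @export
tissue_mass <- function(tube_full_mass_g, tube_empty_mass_g) {
  m <- tube_full_mass_g - tube_empty_mass_g
  if (any(m < 0)) {
    stop("tube_full_mass < tube_empty_mass: weighing mix-up (negative mass)")
  }
  if (any(m == 0)) warning("tube full mass equals empty mass: empty tube?")
  m
}

.new_report <- function() {
  structure(list(errors = character(), warnings = character()),
            class = "biodist_validation")
}

.add_error <- function(rep, ...) {
  rep$errors <- c(rep$errors, paste0(...)); rep
}
.add_warning <- function(rep, ...) {
  rep$warnings <- c(rep$warnings, paste0(...)); rep
}

#' @export
print.biodist_validation <- function(x, ...) {
  cat(sprintf("<validation> %d error(s), %d warning(s)\n",
              length(x$errors), length(x$warnings)))
  for (e in x$errors) cat("  ERROR: ", e, "\n", sep = "")
  for (w in x$warnings) cat("  warning: ", w, "\n", sep = "")
  invisible(x)
}

#' Is a validation report clean?
#' @param report a `biodist_validation` object.
#' @return TRUE when it contains no errors.
#' @export
is_valid <- function(report) length(report$errors) == 0L

.read_sheet <- function(path, cols, sheet) {
  if (!file.exists(path)) stop("missing sheet file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("NA", ""))
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop(sheet, ": missing column(s): ", paste(missing, collapse = ", "))
  }
  df[cols]
}

#' Read and cross-validate the three study sheets
#'
#' Reads `syringes.csv`, `injections.csv` and `samples.csv` from a
#' directory (or explicit paths), cross-links the records and collects
#' every validation failure into a report rather than stopping at the
#' first.
#'
#' @param dir directory containing the three sheets (and optionally
#'   `config.json`).
#' @param config a `biodist_config`; when NULL, `config.json` in `dir` is
#'   read.
#' @param paths optional named list overriding individual sheet paths
#'   (`syringes`, `injections`, `samples`).
#' @return object of class `biodist_study`: list with data.frames
#'   `syringes`, `injections`, `samples`, the `config`, and a `validation`
#'   report.
#' @export
read_sheets <- function(dir = NULL, config = NULL, paths = NULL) {
  p <- list(
    syringes = file.path(dir %||% ".", "syringes.csv"),
    injections = file.path(dir %||% ".", "injections.csv"),
    samples = file.path(dir %||% ".", "samples.csv")
  )
  if (!is.null(paths)) p[names(paths)] <- paths
  if (is.null(config)) {
    cfg_path <- file.path(dir %||% ".", "config.json")
    if (!file.exists(cfg_path)) stop("no config given and no config.json in ", dir)
    config <- read_config(cfg_path)
  }
  syr <- .read_sheet(p$syringes, .syringe_cols, "syringes.csv")
  inj <- .read_sheet(p$injections, .injection_cols, "injections.csv")
  smp <- .read_sheet(p$samples, .sample_cols, "samples.csv")
  inj$exclusion_flag <- as.logical(inj$exclusion_flag)
  # an all-NA override column reads back as logical; keep it numeric
  inj$manual_injected_activity_override_MBq <-
    as.numeric(inj$manual_injected_activity_override_MBq)
  study <- structure(
    list(syringes = syr, injections = inj, samples = smp, config = config),
    class = "biodist_study"
  )
  study$validation <- validate_study(study)
  study
}

#' Validate a study bundle
#'
#' Checks every record-level invariant and cross-link, accumulating all
#' violations (validation is total: nothing is silently accepted or
#' partially reported).
#'
#' @param study a `biodist_study`.
#' @return a `biodist_validation` report.
#' @export
validate_study <- function(study) {
  rep <- .new_report()
  syr <- study$syringes; inj <- study$injections; smp <- study$samples
  cfg <- study$config

  ok_nuc <- tryCatch({get_nuclide(cfg$nuclide_id); TRUE},
                     error = function(e) FALSE)
  if (!ok_nuc) rep <- .add_error(rep, "config: unknown nuclide '", cfg$nuclide_id, "'")

  if (anyDuplicated(syr$syringe_id)) {
    rep <- .add_error(rep, "syringes: duplicate syringe_id ",
                      paste(unique(syr$syringe_id[duplicated(syr$syringe_id)]),
                            collapse = ", "))
  }
  bad_role <- !syr$role %in% c("animal", "standard")
  for (i in which(bad_role)) {
    rep <- .add_error(rep, "syringe ", syr$syringe_id[i],
                      ": invalid role '", syr$role[i], "'")
  }
  for (i in seq_len(nrow(syr))) {
    if (!is.na(syr$mass_full_g[i]) && !is.na(syr$mass_empty_g[i]) &&
        syr$mass_full_g[i] <= syr$mass_empty_g[i]) {
      rep <- .add_error(rep, "syringe ", syr$syringe_id[i],
                        ": mass_full <= mass_empty (",
                        syr$mass_full_g[i], " <= ", syr$mass_empty_g[i], ")")
    }
    for (col in c("activity_before_MBq", "activity_after_MBq")) {
      v <- syr[[col]][i]
      if (!is.na(v) && v < 0) {
        rep <- .add_error(rep, "syringe ", syr$syringe_id[i],
                          ": negative ", col)
      }
    }
  }

  if (anyDuplicated(inj$animal_id)) {
    rep <- .add_error(rep, "injections: duplicate animal_id ",
                      paste(unique(inj$animal_id[duplicated(inj$animal_id)]),
                            collapse = ", "))
  }
  for (i in seq_len(nrow(inj))) {
    j <- match(inj$syringe_id[i], syr$syringe_id)
    if (is.na(j)) {
      rep <- .add_error(rep, "animal ", inj$animal_id[i],
                        ": unresolvable syringe_id '", inj$syringe_id[i], "'")
    } else if (syr$role[j] != "animal") {
      rep <- .add_error(rep, "animal ", inj$animal_id[i], ": syringe ",
                        inj$syringe_id[i], " has role '", syr$role[j],
                        "', expected 'animal'")
    }
    if (!is.na(inj$body_weight_g[i]) && inj$body_weight_g[i] <= 0) {
      rep <- .add_error(rep, "animal ", inj$animal_id[i],
                        ": non-positive body weight")
    }
  }

  if (anyDuplicated(smp$tube_id)) {
    rep <- .add_error(rep, "samples: duplicate tube_id ",
                      paste(unique(smp$tube_id[duplicated(smp$tube_id)]),
                            collapse = ", "))
  }
  bad_role <- !smp$role %in% c("background", "standard", "tissue")
  for (i in which(bad_role)) {
    rep <- .add_error(rep, "tube ", smp$tube_id[i], ": invalid role '",
                      smp$role[i], "'")
  }
  for (i in seq_len(nrow(smp))) {
    if (!is.na(smp$cpm[i]) && smp$cpm[i] < 0) {
      rep <- .add_error(rep, "tube ", smp$tube_id[i], ": negative CPM")
    }
    if (smp$role[i] %in% c("standard", "tissue")) {
      if (!is.na(smp$tube_full_mass_g[i]) && !is.na(smp$tube_empty_mass_g[i]) &&
          smp$tube_full_mass_g[i] < smp$tube_empty_mass_g[i]) {
        rep <- .add_error(rep, "tube ", smp$tube_id[i],
                          ": tube_full_mass < tube_empty_mass")
      }
    }
    if (smp$role[i] == "tissue") {
      if (is.na(smp$animal_id[i])) {
        rep <- .add_error(rep, "tube ", smp$tube_id[i],
                          ": tissue tube without animal_id")
      } else if (!smp$animal_id[i] %in% inj$animal_id) {
        rep <- .add_error(rep, "tube ", smp$tube_id[i], ": animal_id '",
                          smp$animal_id[i], "' not on the injection sheet")
      }
      tn <- smp$tissue_name[i]
      if (is.na(tn)) {
        rep <- .add_error(rep, "tube ", smp$tube_id[i],
                          ": tissue tube without tissue_name")
      } else if (!tn %in% cfg$tissue_vocabulary) {
        rep <- .add_warning(rep, "tube ", smp$tube_id[i],
                            ": tissue '", tn, "' not in vocabulary")
      }
    }
  }
  n_bg <- sum(smp$role == "background")
  n_std <- sum(smp$role == "standard")
  if (n_bg == 0) rep <- .add_error(rep, "samples: no background tubes")
  if (n_std == 0) rep <- .add_error(rep, "samples: no standard tubes")
  if (n_bg > 0 && n_bg < 3) {
    rep <- .add_warning(rep, "samples: only ", n_bg,
                        " background tube(s); quadruplicate recommended")
  }
  if (n_std > 0 && n_std < 4) {
    rep <- .add_warning(rep, "samples: only ", n_std,
                        " standard tube(s); quadruplicate recommended")
  }

  if (is.null(cfg$stock)) {
    rep <- .add_error(rep, "config: no standard-stock block")
  } else {
    st <- cfg$stock
    if (st$tube_plus_water_g <= st$tube_empty_g) {
      rep <- .add_error(rep, "stock: tube_plus_water <= tube_empty")
    }
    if (st$tube_plus_water_plus_standard_g <= st$tube_plus_water_g) {
      rep <- .add_error(rep, "stock: no mass added by the standard syringe")
    }
    if (!st$standard_syringe_id %in% syr$syringe_id[syr$role == "standard"]) {
      rep <- .add_error(rep, "stock: standard_syringe_id '",
                        st$standard_syringe_id,
                        "' does not match a standard-role syringe")
    }
  }

  if (!is.null(cfg$counter_ceiling_cpm)) {
    sat <- which(smp$cpm > cfg$counter_ceiling_cpm)
    for (i in sat) {
      rep <- .add_warning(rep, "tube ", smp$tube_id[i], ": CPM ", smp$cpm[i],
                          " above counter linear-range ceiling; recount later")
    }
  }

  # timestamps must parse and share one clock
  ts_cols <- list(syringes = c("t_weigh_full", "t_weigh_empty",
                               "t_activity_before", "t_activity_after"),
                  injections = "t_injection",
                  samples = "t_count_ref")
  all_ts <- c(unlist(syr[ts_cols$syringes]), inj$t_injection, smp$t_count_ref)
  all_ts <- all_ts[!is.na(all_ts)]
  ok <- tryCatch({parse_timestamp(all_ts); TRUE},
                 error = function(e) {rep <<- .add_error(rep, "timestamps: ",
                                                         conditionMessage(e)); FALSE})
  rep
}

#' @export
print.biodist_study <- function(x, ...) {
  cat(sprintf("<biodist_study> %s: %d syringes, %d injections, %d counted tubes\n",
              x$config$nuclide_id, nrow(x$syringes), nrow(x$injections),
              nrow(x$samples)))
  print(x$validation)
  invisible(x)
}

.fmt_num <- function(x) {
  ifelse(is.na(x), NA, signif(x, 10))
}

#' Write a study bundle back to the three CSV sheets (+ config.json)
#' @param study a `biodist_study`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sheets <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(study$syringes, file.path(dir, "syringes.csv"),
                   row.names = FALSE, na = "")
  utils::write.csv(study$injections, file.path(dir, "injections.csv"),
                   row.names = FALSE, na = "")
  utils::write.csv(study$samples, file.path(dir, "samples.csv"),
                   row.names = FALSE, na = "")
  write_config(study$config, file.path(dir, "config.json"))
  invisible(dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
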