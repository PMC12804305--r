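# Per-animal injected activity, tissue-level %ID/g, %ID per organ, SUV,
# contrast ratios and group summaries.
#
# All CPM entering this module are decay-corrected to the shared counter
# reference time, so the injected activity (in CPM-equivalents at t_ref,
# via the mass-based calibration factor) and the tissue counts are directly
# comparable and %ID is a plain ratio.

#' Injected activity of one animal dose
#'
#' The primary, mass-based estimate is `cf_mass * injected_mass` with
#' `injected_mass = mass_full - mass_empty` of the animal syringe. When
#' dose-calibrator readings exist, the calibrator-based activity
#' `A_inj(t_ref) = decay_correct(A_before) - decay_correct(A_after)` is
#' reported side by side with the relative difference, to reveal e.g.
#' radiotracer sticking to the syringe. A manual override (MBq at t_ref,
#' for failed or sticky injections) replaces the mass-based value via the
#' activity calibration factor.
#'
#' @param syringe list/row with `mass_full_g`, `mass_empty_g` and optional
#'   activity readings (`activity_before_MBq`, `t_activity_before`,
#'   `activity_after_MBq`, `t_activity_after`).
#' @param cf `calibration_result`.
#' @param nuclide `nuclide` object (for decay correction of the calibrator
#'   readings).
#' @param t_ref shared counter reference time.
#' @param override_MBq optional manual injected activity (MBq at t_ref).
#' @return list with `injected_cpm`, `injected_mass_g`, optional
#'   `injected_MBq_calibrator`, `injected_MBq_mass_based`,
#'   `relative_difference`, and `source` (`"mass"`, `"override"`).
#' @export
injected_activity <- function(syringe, cf, nuclide = NULL, t_ref = NULL,
                              override_MBq = NULL) {
  if (!inherits(cf, "calibration_result")) stop("cf must be a calibration_result")
  m_inj <- syringe$mass_full_g - syringe$mass_empty_g
  if (!is.na(m_inj) && m_inj <= 0) {
    stop("non-positive injected mass for syringe")
  }
  out <- list(injected_mass_g = m_inj,
              injected_cpm = cf$cf_mass * m_inj,
              source = "mass")
  if (!is.null(cf$cf_activity)) {
    out$injected_MBq_mass_based <- out$injected_cpm / cf$cf_activity
  }
  has_act <- !is.null(syringe$activity_before_MBq) &&
    !is.na(syringe$activity_before_MBq) &&
    !is.null(syringe$activity_after_MBq) &&
    !is.na(syringe$activity_after_MBq)
  if (has_act && !is.null(nuclide) && !is.null(t_ref)) {
    a_inj <- decay_correct(syringe$activity_before_MBq,
                           syringe$t_activity_before, t_ref, nuclide) -
      decay_correct(syringe$activity_after_MBq,
                    syringe$t_activity_after, t_ref, nuclide)
    out$injected_MBq_calibrator <- a_inj
    if (!is.null(out$injected_MBq_mass_based) && a_inj > 0) {
      out$relative_difference <-
        (out$injected_MBq_mass_based - a_inj) / a_inj
    }
  }
  if (!is.null(override_MBq) && !is.na(override_MBq)) {
    if (is.null(cf$cf_activity)) {
      stop("manual override needs an activity calibration factor ",
           "(dose-calibrator readings for the standard syringe)")
    }
    out$injected_cpm <- override_MBq * cf$cf_activity
    out$source <- "override"
  }
  out
}

#' Net (background-subtracted) CPM of a tissue tube
#'
#' @param cpm measured CPM.
#' @param background background CPM.
#' @param policy `"flag"` (default) keeps a negative net value with a
#'   `negative_net` flag so group means stay unbiased; `"clamp"` returns 0
#'   with the same flag.
#' @return list with `net_cpm` and `flags` (character vector).
#' @export
net_cpm <- function(cpm, background, policy = c("flag", "clamp")) {
  policy <- match.arg(policy)
  net <- cpm - background
  flags <- character()
  if (net < 0) {
    flags <- "negative_net"
    if (policy == "clamp") net <- 0
  }
  list(net_cpm = net, flags = flags)
}

#' Percent injected dose per gram of tissue
#'
#' @param net_cpm background-subtracted tissue CPM (at t_ref).
#' @param mass_g tissue mass, g.
#' @param injected_cpm injected activity in CPM-equivalents (at t_ref).
#' @return %ID per gram; `NA` (with a message attribute dropped) when
#'   `mass_g` is 0 — a zero-mass tissue has no defined concentration.
#' @export
pct_id_per_gram <- function(net_cpm, mass_g, injected_cpm) {
  if (any(injected_cpm <= 0)) stop("injected_cpm must be positive")
  if (any(mass_g < 0)) stop("negative tissue mass")
  ifelse(mass_g == 0, NA_real_, 100 * (net_cpm / injected_cpm) / mass_g)
}

#' Standardized uptake value from %ID/g and body weight
#'
#' SUV by body weight: tissue concentration divided by injected activity
#' per gram of body, i.e. `pct_id_per_g * body_weight / 100`. A tracer
#' distributed uniformly through the body gives SUV 1 in every tissue.
#'
#' @param pct_id_per_g percent injected dose per gram.
#' @param body_weight_g animal body weight, g.
#' @return dimensionless SUV.
#' @export
suv <- function(pct_id_per_g, body_weight_g) {
  if (any(body_weight_g <= 0)) stop("body weight must be positive")
  pct_id_per_g * body_weight_g / 100
}

#' Quantify every tissue tube of a study
#'
#' Runs the full chain: background estimate, calibration factor, per-animal
#' injected activity, then per-tube net CPM, mass, %ID/g, %ID per organ and
#' SUV, with per-tube flags (`negative_net`, `zero_mass`, `saturation`).
#'
#' @param study a validated `biodist_study`.
#' @return list of class `biodist_results`: `calibration`, `per_animal`
#'   (data.frame of injected activities), `tissues` (data.frame, one row
#'   per tissue tube), `config`.
#' @export
quantify_study <- function(study) {
  if (!is_valid(study$validation)) {
    stop("study has validation errors; fix them first:\n",
         paste(study$validation$errors, collapse = "\n"))
  }
  cfg <- study$config
  nuc <- get_nuclide(cfg$nuclide_id)
  smp <- study$samples
  t_ref <- parse_timestamp(smp$t_count_ref[1])
  bg <- background_cpm(smp$cpm[smp$role == "background"],
                       policy = cfg$background_policy)
  std_syr <- as.list(study$syringes[
    study$syringes$syringe_id == cfg$stock$standard_syringe_id, , drop = FALSE])
  stock <- list(
    tube_empty_g = cfg$stock$tube_empty_g,
    tube_plus_water_g = cfg$stock$tube_plus_water_g,
    tube_plus_water_plus_standard_g = cfg$stock$tube_plus_water_plus_standard_g
  )
  cal <- calibration_factor(smp[smp$role == "standard", , drop = FALSE],
                            stock, std_syr, bg, nuclide = nuc, t_ref = t_ref,
                            cv_warn_pct = cfg$cv_warn_pct)

  inj <- study$injections
  per_animal <- do.call(rbind, lapply(seq_len(nrow(inj)), function(i) {
    syr <- as.list(study$syringes[
      study$syringes$syringe_id == inj$syringe_id[i], , drop = FALSE])
    ia <- injected_activity(syr, cal, nuclide = nuc, t_ref = t_ref,
                            override_MBq =
                              inj$manual_injected_activity_override_MBq[i])
    data.frame(animal_id = inj$animal_id[i],
               group = inj$group[i],
               body_weight_g = inj$body_weight_g[i],
               excluded = isTRUE(inj$exclusion_flag[i]),
               injected_mass_g = ia$injected_mass_g,
               injected_cpm = ia$injected_cpm,
               injected_MBq_calibrator = ia$injected_MBq_calibrator %||% NA_real_,
               injected_MBq_mass_based = ia$injected_MBq_mass_based %||% NA_real_,
               relative_difference = ia$relative_difference %||% NA_real_,
               source = ia$source,
               stringsAsFactors = FALSE)
  }))

  tis <- smp[smp$role == "tissue", , drop = FALSE]
  rows <- lapply(seq_len(nrow(tis)), function(i) {
    an <- match(tis$animal_id[i], per_animal$animal_id)
    nc <- net_cpm(tis$cpm[i], bg, policy = cfg$negative_net_policy)
    m <- tis$tube_full_mass_g[i] - tis$tube_empty_mass_g[i]
    flags <- nc$flags
    if (m == 0) flags <- c(flags, "zero_mass")
    if (!is.null(cfg$counter_ceiling_cpm) &&
        tis$cpm[i] > cfg$counter_ceiling_cpm) {
      flags <- c(flags, "saturation")
    }
    inj_cpm <- per_animal$injected_cpm[an]
    pidg <- if (m > 0) pct_id_per_gram(nc$net_cpm, m, inj_cpm) else NA_real_
    data.frame(animal_id = tis$animal_id[i],
               group = per_animal$group[an],
               tissue_name = tis$tissue_name[i],
               tube_id = tis$tube_id[i],
               net_cpm = nc$net_cpm,
               mass_g = m,
               pct_id_per_g = pidg,
               pct_id_organ = 100 * nc$net_cpm / inj_cpm,
               suv = if (is.na(pidg)) NA_real_ else
                 suv(pidg, per_animal$body_weight_g[an]),
               excluded = per_animal$excluded[an],
               flags = paste(flags, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  tissues <- do.call(rbind, rows)
  structure(list(calibration = cal, per_animal = per_animal,
                 tissues = tissues, config = cfg),
            class = "biodist_results")
}

#' @export
print.biodist_results <- function(x, ...) {
  cat(sprintf("<biodist_results> %d animals, %d tissue tubes\n",
              nrow(x$per_animal), nrow(x$tissues)))
  print(x$calibration)
  invisible(x)
}

#' Group summaries of %ID/g and SUV
#'
#' Per group x tissue: n, mean, sample sd (n-1 denominator) and CV of
#' %ID/g and SUV. Animals with the exclusion flag are omitted. Each
#' animal's summed %ID over organs is reported as a recovery diagnostic,
#' warning when it exceeds 100% plus the configured tolerance.
#'
#' @param results a `biodist_results`.
#' @return list with `summary` (data.frame) and `recovery` (data.frame
#'   animal_id, total_pct_id).
#' @export
group_summary <- function(results) {
  tis <- results$tissues[!results$tissues$excluded, , drop = FALSE]
  if (nrow(tis) == 0) stop("no non-excluded animals to summarize")
  key <- interaction(tis$group, tis$tissue_name, drop = TRUE)
  stat <- function(v) {
    v <- v[!is.na(v)]
    n <- length(v)
    m <- if (n) mean(v) else NA_real_
    s <- if (n > 1) stats::sd(v) else NA_real_
    c(n = n, mean = m, sd = s,
      cv = if (!is.na(s) && !is.na(m) && m > 0) 100 * s / m else NA_real_)
  }
  rows <- lapply(split(tis, key), function(d) {
    a <- stat(d$pct_id_per_g); b <- stat(d$suv)
    data.frame(group = d$group[1], tissue_name = d$tissue_name[1],
               n = a[["n"]],
               mean_pct_id_per_g = a[["mean"]], sd_pct_id_per_g = a[["sd"]],
               cv_pct_id_per_g = a[["cv"]],
               mean_suv = b[["mean"]], sd_suv = b[["sd"]], cv_suv = b[["cv"]],
               stringsAsFactors = FALSE)
  })
  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL
  rec <- stats::aggregate(pct_id_organ ~ animal_id, data = tis, FUN = sum)
  names(rec)[2] <- "total_pct_id"
  tol <- results$config$recovery_tolerance_pct %||% 5
  over <- rec$animal_id[rec$total_pct_id > 100 + tol]
  if (length(over)) {
    warning("summed %ID exceeds 100% + tolerance for animal(s): ",
            paste(over, collapse = ", "))
  }
  list(summary = summary, recovery = rec)
}

#' Target-to-background contrast ratios
#'
#' Ratios are formed per animal as `pct_id_per_g(target) /
#' pct_id_per_g(background)` (preserving within-animal pairing), then
#' summarized per group with mean and sample sd. Background values <= 0
#' leave the ratio undefined for that animal (flagged); animals missing
#' either tissue are excluded pairwise with a warning.
#'
#' @param results a `biodist_results`.
#' @param targets character vector of target tissue names.
#' @param backgrounds character vector of background tissue names.
#' @return list with `per_animal` and `summary` data.frames.
#' @export
contrast_ratios <- function(results, targets, backgrounds) {
  tis <- results$tissues[!results$tissues$excluded, , drop = FALSE]
  per <- list()
  for (tg in targets) for (bg in backgrounds) {
    for (an in unique(tis$animal_id)) {
      vt <- tis$pct_id_per_g[tis$animal_id == an & tis$tissue_name == tg]
      vb <- tis$pct_id_per_g[tis$animal_id == an & tis$tissue_name == bg]
      if (!length(vt) || !length(vb)) {
        warning("animal ", an, " missing '",
                if (!length(vt)) tg else bg, "'; excluded from ", tg, "/",
                bg, " ratio")
        next
      }
      g <- tis$group[tis$animal_id == an][1]
      flag <- ""
      ratio <- if (is.na(vb[1]) || vb[1] <= 0) {
        flag <- "undefined_background"
        NA_real_
      } else vt[1] / vb[1]
      per[[length(per) + 1L]] <- data.frame(
        animal_id = an, group = g, target = tg, background = bg,
        ratio = ratio, flag = flag, stringsAsFactors = FALSE)
    }
  }
  per <- if (length(per)) do.call(rbind, per) else
    data.frame(animal_id = character(), group = character(),
               target = character(), background = character(),
               ratio = numeric(), flag = character())
  key <- interaction(per$group, per$target, per$background, drop = TRUE)
  rows <- lapply(split(per, key), function(d) {
    v <- d$ratio[!is.na(d$ratio)]
    data.frame(group = d$group[1], target = d$target[1],
               background = d$background[1], n = length(v),
               mean_ratio = if (length(v)) mean(v) else NA_real_,
               sd_ratio = if (length(v) > 1) stats::sd(v) else NA_real_,
               stringsAsFactors = FALSE)
  })
  summary <- if (length(rows)) do.call(rbind, rows) else
    data.frame(group = character(), target = character(),
               background = character(), n = integer(),
               mean_ratio = numeric(), sd_ratio = numeric())
  rownames(summary) <- NULL
  list(per_animal = per, summary = summary)
}

#' Run the full analysis of a study directory or bundle
#'
#' Convenience wrapper: quantify, summarize, optionally compute contrast
#' ratios, and (optionally) write `results_per_animal.csv`,
#' `group_summary.csv`, `ratios.csv` plus a JSON mirror to an output
#' directory.
#'
#' @param study a `biodist_study` (from [read_sheets()] or
#'   [generate_study()]).
#' @param targets,backgrounds optional tissue lists for contrast ratios.
#' @param out_dir optional output directory.
#' @return list with `results`, `groups`, `ratios` (or NULL).
#' @export
analyze_study <- function(study, targets = NULL, backgrounds = NULL,
                          out_dir = NULL) {
  results <- quantify_study(study)
  groups <- group_summary(results)
  ratios <- if (!is.null(targets) && !is.null(backgrounds)) {
    contrast_ratios(results, targets, backgrounds)
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    w <- function(df, f) utils::write.csv(.round_sig(df),
                                          file.path(out_dir, f),
                                          row.names = FALSE, na = "")
    w(results$tissues, "results_per_animal.csv")
    w(groups$summary, "group_summary.csv")
    if (!is.null(ratios)) w(ratios$summary, "ratios.csv")
    jsonlite::write_json(
      list(calibration = unclass(results$calibration),
           per_animal = results$per_animal,
           tissues = results$tissues,
           group_summary = groups$summary,
           recovery = groups$recovery,
           ratios = if (!is.null(ratios)) ratios$summary),
      file.path(out_dir, "results.json"),
      auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE)
  }
  list(results = results, groups = groups, ratios = ratios)
}

# round numeric columns to 6 significant digits for CSV output
.round_sig <- function(df, digits = 6) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], signif, digits = digits)
  df
}
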