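# Radionuclide constants and decay correction.
#
# The nuclide table ships as plain text under inst/extdata/nuclides.csv.
# Half-lives are stored with their customary unit (s/min/h/d) and converted
# to seconds internally; the decay constant is always derived as
# lambda = ln(2) / half_life, never stored.

.unit_seconds <- c(s = 1, min = 60, h = 3600, d = 86400)

#' Convert a duration to seconds
#'
#' @param value numeric duration value.
#' @param unit one of `"s"`, `"min"`, `"h"`, `"d"`.
#' @return duration in seconds.
#' @keywords internal
duration_seconds <- function(value, unit) {
  unit <- match.arg(unit, names(.unit_seconds))
  value * .unit_seconds[[unit]]
}

# Cache for the parsed nuclide table (filled lazily per session).
.biodistr_env <- new.env(parent = emptyenv())

.parse_pairs <- function(x, value_name) {
  # "a:b;c:d" -> data.frame(key, value); empty string -> zero rows
  if (is.na(x) || !nzchar(x)) {
    out <- data.frame(key = character(), value = numeric())
    names(out) <- c(names(out)[1], value_name)
    return(out)
  }
  parts <- strsplit(strsplit(x, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
  out <- data.frame(
    key = vapply(parts, `[`, character(1), 1L),
    value = as.numeric(vapply(parts, `[`, character(1), 2L))
  )
  names(out)[2] <- value_name
  out
}

#' Load the bundled nuclide table
#'
#' Reads the package's radionuclide data table (or a user-supplied one in
#' the same format) into a data frame. Columns: `id`, `half_life_value`,
#' `half_life_unit`, `emissions` (`energy:intensity;...` in keV and percent),
#' `daughters` (`id:BR;...`).
#'
#' @param path path to a nuclide table; defaults to the bundled table.
#' @return data.frame with one row per nuclide.
#' @export
#' @examples
#' nrow(nuclide_table()) >= 80
nuclide_table <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(.biodistr_env$nuclide_table)) {
      return(.biodistr_env$nuclide_table)
    }
    path <- system.file("extdata", "nuclides.csv", package = "biodistr",
                        mustWork = TRUE)
  }
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c("character", "numeric", "character",
                                        "character", "character"))
  stopifnot(all(c("id", "half_life_value", "half_life_unit") %in% names(tab)))
  if (anyDuplicated(tab$id)) {
    stop("duplicate nuclide ids in table: ",
         paste(unique(tab$id[duplicated(tab$id)]), collapse = ", "))
  }
  if (any(tab$half_life_value <= 0)) stop("non-positive half-life in table")
  if (is.null(.biodistr_env$nuclide_table) &&
      identical(path, system.file("extdata", "nuclides.csv",
                                  package = "biodistr"))) {
    .biodistr_env$nuclide_table <- tab
  }
  tab
}

#' Normalize a nuclide identifier
#'
#' Accepts `"Zr-89"`, `"89Zr"`, `"zr89"`, `"ZR-89"` and similar spellings,
#' returning the canonical `Element-MassNumber` form. A trailing `m` (as in
#' `"Tc-99m"`, `"99mTc"`) marks a metastable state and is preserved.
#'
#' @param id character nuclide label.
#' @return canonical id string.
#' @export
normalize_nuclide_id <- function(id) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  x <- gsub("[^A-Za-z0-9]", "", id)
  # mass-first (89Zr, 99mTc) or element-first (Zr89, Tc99m)
  m <- regmatches(x, regexec("^([0-9]+)(m?)([A-Za-z]+)$", x))[[1]]
  if (length(m)) {
    elem <- m[4]; mass <- m[2]; meta <- m[3]
  } else {
    m <- regmatches(x, regexec("^([A-Za-z]+)([0-9]+)(m?)$", x))[[1]]
    if (!length(m)) stop("cannot parse nuclide id: '", id, "'")
    elem <- m[2]; mass <- m[3]; meta <- m[4]
  }
  elem <- paste0(toupper(substr(elem, 1, 1)), tolower(substr(elem, 2, 3)))
  paste0(elem, "-", mass, tolower(meta))
}

#' Look up a radionuclide
#'
#' @param id nuclide label in any accepted spelling (`"Zr-89"`, `"89Zr"`,
#'   `"zr89"`).
#' @param table optional nuclide table from [nuclide_table()].
#' @return an object of class `nuclide`: list with `id`, `half_life`
#'   (value), `half_life_unit`, `half_life_s`, `lambda_per_s`, `emissions`
#'   (data.frame `energy_kev`, `intensity_pct`), `daughters` (data.frame
#'   `id`, `branching_ratio`).
#' @export
#' @examples
#' get_nuclide("89Zr")$half_life  # 78.41 (hours)
get_nuclide <- function(id, table = nuclide_table()) {
  canon <- normalize_nuclide_id(id)
  i <- match(canon, table$id)
  if (is.na(i)) {
    # name nearest matches to help against typos
    d <- utils::adist(canon, table$id, ignore.case = TRUE)
    near <- table$id[order(d)][seq_len(min(3L, nrow(table)))]
    stop("unknown nuclide '", id, "' (normalized '", canon,
         "'); nearest entries: ", paste(near, collapse = ", "))
  }
  hl_s <- duration_seconds(table$half_life_value[i], table$half_life_unit[i])
  emissions <- .parse_pairs(table$emissions[i], "intensity_pct")
  names(emissions)[1] <- "energy_kev"
  emissions$energy_kev <- as.numeric(emissions$energy_kev)
  daughters <- .parse_pairs(table$daughters[i], "branching_ratio")
  names(daughters)[1] <- "id"
  structure(
    list(
      id = table$id[i],
      half_life = table$half_life_value[i],
      half_life_unit = table$half_life_unit[i],
      half_life_s = hl_s,
      lambda_per_s = log(2) / hl_s,
      emissions = emissions,
      daughters = daughters
    ),
    class = "nuclide"
  )
}

#' @export
print.nuclide <- function(x, ...) {
  cat(sprintf("<nuclide> %s  t1/2 = %g %s  (lambda = %.6g s^-1)\n",
              x$id, x$half_life, x$half_life_unit, x$lambda_per_s))
  if (nrow(x$emissions)) {
    cat("  gamma lines:",
        paste(sprintf("%g keV (%.3g%%)", x$emissions$energy_kev,
                      x$emissions$intensity_pct), collapse = ", "), "\n")
  }
  if (nrow(x$daughters)) {
    cat("  daughters:",
        paste(sprintf("%s (BR %.4g)", x$daughters$id,
                      x$daughters$branching_ratio), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Parse ISO 8601 timestamps on a single study clock
#'
#' Naive timestamps (no UTC offset) are assumed to share one clock, as the
#' protocol requires a single clock for all time measurements; they are
#' interpreted in UTC. Offset-aware stamps (`Z` or `+hh:mm`) are converted
#' to UTC. Mixing naive and offset-aware stamps within one call is an
#' error, since their relative offsets would be undefined.
#'
#' @param x character vector of ISO 8601 timestamps
#'   (`YYYY-MM-DDTHH:MM:SS[Z|+hh:mm]`; a space separator is accepted).
#' @return POSIXct vector (UTC).
#' @export
parse_timestamp <- function(x) {
  if (inherits(x, "POSIXct")) return(x)
  stopifnot(is.character(x))
  x <- trimws(x)
  if (any(!nzchar(x) | is.na(x))) stop("empty or NA timestamp")
  aware <- grepl("(Z|[+-][0-9]{2}:?[0-9]{2})$", x)
  if (any(aware) && !all(aware)) {
    stop("mixing offset-aware and naive timestamps; ",
         "all study timestamps must share one clock")
  }
  y <- sub("Z$", "+0000", x)
  y <- sub("([+-][0-9]{2}):([0-9]{2})$", "\\1\\2", y)
  y <- sub("T", " ", y, fixed = TRUE)
  fmt <- if (all(aware)) "%Y-%m-%d %H:%M:%S %z" else "%Y-%m-%d %H:%M:%S"
  if (all(aware)) y <- sub("([+-][0-9]{4})$", " \\1", y)
  out <- as.POSIXct(y, format = fmt, tz = "UTC")
  if (anyNA(out)) {
    stop("unparseable ISO 8601 timestamp(s): ",
         paste(x[is.na(out)], collapse = ", "))
  }
  out
}

#' Format timestamps back to ISO 8601 (UTC, naive)
#' @param t POSIXct vector.
#' @return character vector `YYYY-MM-DDTHH:MM:SS`.
#' @export
format_timestamp <- function(t) {
  format(t, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
}

#' Decay-correct an activity-like quantity to a reference time
#'
#' Rescales a measurement (MBq, CPM, ...) from its measurement time to a
#' common reference time using exponential decay:
#' `value * exp(-lambda * (t_ref - t_meas))`. Correcting forward in time
#' (t_ref later) shrinks the value; correcting back grows it. The
#' correction is multiplicative and unit-agnostic.
#'
#' @param value non-negative activity-like quantity.
#' @param t_meas measurement time (POSIXct or ISO 8601 string).
#' @param t_ref reference time (same clock).
#' @param nuclide a `nuclide` object, or a nuclide id string.
#' @return corrected value at `t_ref`.
#' @export
#' @examples
#' t0 <- parse_timestamp("2026-01-10T09:00:00")
#' decay_correct(100, t0, t0 + 78.41 * 3600, "Zr-89")  # 50
decay_correct <- function(value, t_meas, t_ref, nuclide) {
  if (is.character(nuclide)) nuclide <- get_nuclide(nuclide)
  stopifnot(inherits(nuclide, "nuclide"), all(value >= 0))
  t_meas <- parse_timestamp(t_meas)
  t_ref <- parse_timestamp(t_ref)
  dt <- as.numeric(difftime(t_ref, t_meas, units = "secs"))
  x <- nuclide$lambda_per_s * dt
  if (any(abs(x) > 700)) {
    stop("decay-correction exponent |lambda*dt| > 700: interval of ",
         "~", format(max(abs(dt)) / nuclide$half_life_s, digits = 3),
         " half-lives would overflow/underflow")
  }
  value * exp(-x)
}
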