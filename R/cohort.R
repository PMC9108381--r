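#' @importFrom rlang .data abort warn %||%
#' @importFrom dplyr mutate filter select summarise group_by ungroup across
#'   bind_rows bind_cols arrange count n if_else case_when pull left_join
#' @importFrom tibble tibble as_tibble
#' @importFrom purrr map map_dbl map_lgl map_chr imap pmap keep
#' @importFrom stats pnorm qnorm qbeta qgamma qlnorm rnorm runif rgamma
#'   setNames uniroot dnorm median sd cor quantile approx
NULL

# -- schema ------------------------------------------------------------------

SEX_LEVELS <- c("male", "female")
ANTITHROMBOTIC_LEVELS <- c("none", "oral_anticoagulant", "heparin",
                           "antiplatelet", "combination")
LOCATION_LEVELS <- c("basal_ganglia", "subcortical", "cortical", "brainstem")
DISCHARGE_LEVELS <- c("home", "rehabilitation", "death")

#' Column names of a patient-level ICH cohort table
#'
#' One row per admitted patient with spontaneous intracerebral hemorrhage:
#' demographics, admission severity scores (GCS, NIHSS), imaging-derived
#' hematoma measurements, resource use (lengths of stay, rescue craniotomy,
#' external ventricular drain) and functional outcomes on the modified
#' Rankin Scale (mRS, 0 = no symptoms to 6 = death).
#'
#' @return Character vector of the canonical column names, in CSV order.
#' @export
cohort_columns <- function() {
  c("patient_id", "age", "sex", "premorbid_mrs", "antithrombotic",
    "gcs", "nihss", "location", "ivh", "onset_to_admission_h",
    "triage_to_image_min", "volume_initial_ml", "volume_control_ml",
    "control_interval_h", "brainstem_dysfunction", "rescue_surgery",
    "evd", "los_icu_d", "los_stroke_unit_d", "los_total_d",
    "discharge_destination", "mrs_discharge", "mrs_midterm", "survived_30d")
}

# Fields where an empty CSV cell (missing value) is legal.
MISSING_OK <- c("volume_control_ml", "control_interval_h",
                "mrs_discharge", "mrs_midterm")

#' Validate a patient-level cohort table
#'
#' Checks every row of a cohort tibble against the record invariants:
#' ranges (age >= 18, GCS 3-15, NIHSS 0-42, mRS 0-6, premorbid mRS 0-5),
#' enumerations for the categorical fields, non-negative volumes, times and
#' stays, `los_icu_d + los_stroke_unit_d <= los_total_d`, agreement between
#' death as discharge destination and mRS 6 at discharge, and the rule that
#' a patient dead within 30 days must have died in hospital. Missing values
#' are only accepted where the schema declares them
#' (`volume_control_ml`, `control_interval_h`, `mrs_discharge`,
#' `mrs_midterm`).
#'
#' @param cohort A data frame with exactly the columns of
#'   [cohort_columns()].
#' @return The validated cohort as a tibble (invisibly usable in a pipe).
#'   Errors name the offending row and field.
#' @export
validate_cohort <- function(cohort) {
  cohort <- as_tibble(cohort)
  extra <- setdiff(names(cohort), cohort_columns())
  missing_cols <- setdiff(cohort_columns(), names(cohort))
  if (length(extra) > 0) {
    abort(paste0("Unknown cohort column(s): ", paste(extra, collapse = ", ")))
  }
  if (length(missing_cols) > 0) {
    abort(paste0("Missing cohort column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  cohort <- cohort[, cohort_columns()]
  problems <- character(0)
  note <- function(rows, field, why) {
    if (any(rows, na.rm = TRUE)) {
      problems <<- c(problems, paste0(
        "row ", paste(which(rows), collapse = ","), ", field '", field,
        "': ", why))
    }
  }

  req_na <- function(field) {
    note(is.na(cohort[[field]]) & !(field %in% MISSING_OK), field,
         "missing value not allowed")
  }
  for (f in setdiff(cohort_columns(), MISSING_OK)) req_na(f)

  int_in <- function(field, lo, hi) {
    x <- cohort[[field]]
    note(!is.na(x) & (x != round(x) | x < lo | x > hi), field,
         paste0("must be an integer in [", lo, ", ", hi, "]"))
  }
  nonneg <- function(field) {
    x <- cohort[[field]]
    note(!is.na(x) & (!is.finite(x) | x < 0), field, "must be >= 0 and finite")
  }
  in_set <- function(field, levels) {
    x <- cohort[[field]]
    note(!is.na(x) & !(x %in% levels), field,
         paste0("must be one of {", paste(levels, collapse = ", "), "}"))
  }
  logical_field <- function(field) {
    if (!is.logical(cohort[[field]])) {
      problems <<- c(problems, paste0("field '", field, "': must be logical"))
    }
  }

  int_in("age", 18, 120)
  int_in("premorbid_mrs", 0, 5)
  int_in("gcs", 3, 15)
  int_in("nihss", 0, 42)
  int_in("mrs_discharge", 0, 6)
  int_in("mrs_midterm", 0, 6)
  in_set("sex", SEX_LEVELS)
  in_set("antithrombotic", ANTITHROMBOTIC_LEVELS)
  in_set("location", LOCATION_LEVELS)
  in_set("discharge_destination", DISCHARGE_LEVELS)
  for (f in c("onset_to_admission_h", "triage_to_image_min",
              "volume_initial_ml", "volume_control_ml", "control_interval_h",
              "los_icu_d", "los_stroke_unit_d", "los_total_d")) nonneg(f)
  for (f in c("ivh", "brainstem_dysfunction", "rescue_surgery", "evd",
              "survived_30d")) logical_field(f)

  if (length(problems) == 0) {
    note(cohort$los_icu_d + cohort$los_stroke_unit_d >
           cohort$los_total_d + 1e-9,
         "los_total_d", "ICU + Stroke-Unit stay exceeds total stay")
    dd <- cohort$discharge_destination
    note(dd == "death" & !is.na(cohort$mrs_discharge) &
           cohort$mrs_discharge != 6,
         "mrs_discharge", "discharge destination is death but mRS != 6")
    note(dd != "death" & !is.na(cohort$mrs_discharge) &
           cohort$mrs_discharge == 6,
         "discharge_destination", "mRS 6 at discharge but destination not death")
    note(dd == "death" & !is.na(cohort$mrs_midterm) & cohort$mrs_midterm != 6,
         "mrs_midterm", "patient dead at discharge but midterm mRS != 6")
    note(!cohort$survived_30d & dd != "death",
         "survived_30d", "death within 30 days requires in-hospital death")
  }

  if (length(problems) > 0) {
    abort(paste0("Invalid cohort:\n  ",
                 paste(problems, collapse = "\n  ")))
  }
  cohort
}

# -- CSV I/O -----------------------------------------------------------------

cohort_col_types <- function() {
  readr::cols(
    patient_id = readr::col_character(),
    age = readr::col_double(),
    sex = readr::col_character(),
    premorbid_mrs = readr::col_double(),
    antithrombotic = readr::col_character(),
    gcs = readr::col_double(),
    nihss = readr::col_double(),
    location = readr::col_character(),
    ivh = readr::col_logical(),
    onset_to_admission_h = readr::col_double(),
    triage_to_image_min = readr::col_double(),
    volume_initial_ml = readr::col_double(),
    volume_control_ml = readr::col_double(),
    control_interval_h = readr::col_double(),
    brainstem_dysfunction = readr::col_logical(),
    rescue_surgery = readr::col_logical(),
    evd = readr::col_logical(),
    los_icu_d = readr::col_double(),
    los_stroke_unit_d = readr::col_double(),
    los_total_d = readr::col_double(),
    discharge_destination = readr::col_character(),
    mrs_discharge = readr::col_double(),
    mrs_midterm = readr::col_double(),
    survived_30d = readr::col_logical()
  )
}

#' Read / write a cohort CSV
#'
#' The on-disk format is one row per patient, header exactly
#' [cohort_columns()], UTF-8, `.` decimal separator, empty string for
#' missing. `read_cohort()` validates every row on ingest;
#' `write_cohort()` refuses to write an invalid table, so
#' write-then-read is the identity on valid cohorts.
#'
#' @param path Path to a cohort CSV file.
#' @param cohort A validated cohort tibble.
#' @return `read_cohort()`: a validated cohort tibble. `write_cohort()`:
#'   the input, invisibly.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) abort(paste0("Cohort file not found: ", path))
  header <- names(readr::read_csv(path, n_max = 0, col_types = readr::cols(),
                                  show_col_types = FALSE))
  extra <- setdiff(header, cohort_columns())
  if (length(extra) > 0) {
    abort(paste0("Unknown cohort column(s) in ", path, ": ",
                 paste(extra, collapse = ", ")))
  }
  cohort <- readr::read_csv(path, col_types = cohort_col_types(),
                            na = "", show_col_types = FALSE)
  validate_cohort(cohort)
}

#' @rdname read_cohort
#' @export
write_cohort <- function(cohort, path) {
  cohort <- validate_cohort(cohort)
  readr::write_csv(cohort, path, na = "")
  invisible(cohort)
}

# -- imaging-derived quantities ----------------------------------------------

#' Hematoma volume by the ABC/2 ellipsoid approximation
#'
#' Estimates intracerebral hematoma volume from the three orthogonal
#' diameters measured on CT/MRI: `a * b * c / 2`, in ml (diameters in cm).
#' Vectorised and symmetric in its three arguments.
#'
#' @param a_cm,b_cm,c_cm Orthogonal hematoma diameters in centimetres;
#'   must be finite and non-negative.
#' @return Hematoma volume(s) in ml.
#' @examples
#' abc2_volume(6, 5, 4) # 60 ml
#' @export
abc2_volume <- function(a_cm, b_cm, c_cm) {
  d <- c(a_cm, b_cm, c_cm)
  if (any(is.na(d)) || any(!is.finite(d)) || any(d < 0)) {
    abort("abc2_volume(): diameters must be finite and >= 0")
  }
  a_cm * b_cm * c_cm / 2
}

#' Hematoma expansion flag
#'
#' A hematoma counts as expanded when the control scan shows an increase of
#' strictly more than 5 ml over the initial scan. A missing control volume
#' yields `NA` (indeterminate), never a silent `FALSE`.
#'
#' @param volume_initial_ml,volume_control_ml Volumes in ml; initial must be
#'   present and non-negative, control may be `NA`.
#' @param threshold_ml Expansion threshold in ml (default 5).
#' @return Logical vector; `NA` where the control volume is missing.
#' @export
expansion_flag <- function(volume_initial_ml, volume_control_ml,
                           threshold_ml = 5) {
  if (any(is.na(volume_initial_ml)) || any(volume_initial_ml < 0)) {
    abort("expansion_flag(): initial volume must be present and >= 0")
  }
  if (any(volume_control_ml < 0, na.rm = TRUE)) {
    abort("expansion_flag(): control volume must be >= 0")
  }
  if_else(is.na(volume_control_ml), NA,
          volume_control_ml - volume_initial_ml > threshold_ml)
}

# -- marginal summary --------------------------------------------------------

#' Marginal summary of a cohort
#'
#' Deterministic per-cohort summary in the layout of a baseline-features
#' table: n, sex fraction, mean (SD) age and hematoma volume, categorical
#' counts, median (range) triage-to-image time, length-of-stay means and
#' outcome fractions. Returned long (one statistic per row) so it pipes into
#' further dplyr verbs.
#'
#' @param cohort A validated cohort tibble with at least one row.
#' @return A tibble with columns `statistic` and `value`.
#' @export
summarize_cohort <- function(cohort) {
  cohort <- validate_cohort(cohort)
  if (nrow(cohort) == 0) abort("summarize_cohort(): empty cohort")
  cat_counts <- function(field, levels) {
    vals <- cohort[[field]]
    setNames(map_dbl(levels, ~ sum(vals == .x, na.rm = TRUE)),
             paste0(field, "_", levels, "_n"))
  }
  exp_flag <- expansion_flag(cohort$volume_initial_ml,
                             cohort$volume_control_ml)
  sd0 <- function(x) if (length(x) < 2) 0 else sd(x)
  stats <- c(
    n = nrow(cohort),
    male_frac = mean(cohort$sex == "male"),
    age_mean = mean(cohort$age),
    age_sd = sd0(cohort$age),
    volume_mean_ml = mean(cohort$volume_initial_ml),
    volume_sd_ml = sd0(cohort$volume_initial_ml),
    nihss_median = median(cohort$nihss),
    nihss_min = min(cohort$nihss),
    nihss_max = max(cohort$nihss),
    triage_to_image_median_min = median(cohort$triage_to_image_min),
    triage_to_image_min_min = min(cohort$triage_to_image_min),
    triage_to_image_max_min = max(cohort$triage_to_image_min),
    ivh_frac = mean(cohort$ivh),
    expansion_frac = mean(exp_flag, na.rm = TRUE),
    control_image_frac = mean(!is.na(cohort$volume_control_ml)),
    rescue_surgery_frac = mean(cohort$rescue_surgery),
    evd_frac = mean(cohort$evd),
    los_icu_mean_d = mean(cohort$los_icu_d),
    los_stroke_unit_mean_d = mean(cohort$los_stroke_unit_d),
    los_total_mean_d = mean(cohort$los_total_d),
    mortality_30d_frac = mean(!cohort$survived_30d),
    mrs_midterm_evaluable_n = sum(!is.na(cohort$mrs_midterm)),
    cat_counts("sex", SEX_LEVELS),
    cat_counts("premorbid_mrs", 0:5),
    cat_counts("location", LOCATION_LEVELS),
    cat_counts("antithrombotic", ANTITHROMBOTIC_LEVELS),
    cat_counts("discharge_destination", DISCHARGE_LEVELS),
    cat_counts("mrs_discharge", 0:6),
    cat_counts("mrs_midterm", 0:6)
  )
  tibble(statistic = names(stats), value = unname(stats))
}
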