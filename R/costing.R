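# Tariff-based costing: every strategy is priced from the same line items
# (operating-room minutes, surgical pack, navigation, procedure-specific
# material, per-diem stays, rehabilitation per-diems).

#' Tariff table of unit costs
#'
#' Default values are the 2020/2021 public-health tariff of the reference
#' institution: 5 EUR per operating-room minute, 1,150 EUR surgical pack,
#' 862 EUR neuronavigation, per-diems of 1,175.9 EUR (ICU), 707.4 EUR
#' (Stroke Unit), 419 EUR (ward) and 97.8 EUR (rehabilitation facility)
#' over a 90-day social-care horizon. Procedure-specific material: 200 EUR
#' for the MISTIE catheter set, 7,000 EUR for endoscopic consumables.
#'
#' @param or_rate_per_min EUR per operating-room minute.
#' @param surgical_pack EUR per intervention for the standard pack.
#' @param navigation EUR per intervention when neuronavigation is used.
#' @param specific_material Named numeric vector mapping material keys to
#'   EUR per intervention.
#' @param icu_per_diem,stroke_unit_per_diem,ward_per_diem,rehab_per_diem
#'   EUR per day.
#' @param rehab_horizon_days Days of rehabilitation/social care charged for
#'   patients discharged to a secondary facility.
#' @return A list of class `tariff`.
#' @export
tariff_table <- function(or_rate_per_min = 5,
                         surgical_pack = 1150,
                         navigation = 862,
                         specific_material = c(mistie_catheter = 200,
                                               endoscope_consumables = 7000),
                         icu_per_diem = 1175.9,
                         stroke_unit_per_diem = 707.4,
                         ward_per_diem = 419,
                         rehab_per_diem = 97.8,
                         rehab_horizon_days = 90) {
  t <- list(or_rate_per_min = or_rate_per_min, surgical_pack = surgical_pack,
            navigation = navigation, specific_material = specific_material,
            icu_per_diem = icu_per_diem,
            stroke_unit_per_diem = stroke_unit_per_diem,
            ward_per_diem = ward_per_diem, rehab_per_diem = rehab_per_diem,
            rehab_horizon_days = rehab_horizon_days)
  bad <- names(t)[map_lgl(t, ~ any(.x < 0))]
  if (length(bad) > 0) {
    abort(paste0("tariff_table(): negative unit cost in ",
                 paste(bad, collapse = ", ")))
  }
  structure(t, class = "tariff")
}

#' Read / write a tariff table as YAML
#'
#' @param path Path to a YAML file with [tariff_table()] fields.
#' @param tariff A `tariff` object.
#' @return `read_tariff()`: a `tariff`; `write_tariff()`: input, invisibly.
#' @export
read_tariff <- function(path) {
  if (!file.exists(path)) abort(paste0("Tariff file not found: ", path))
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$specific_material)) {
    raw$specific_material <- unlist(raw$specific_material)
  }
  do.call(tariff_table, raw)
}

#' @rdname read_tariff
#' @export
write_tariff <- function(tariff, path) {
  stopifnot(inherits(tariff, "tariff"))
  out <- unclass(tariff)
  out$specific_material <- as.list(out$specific_material)
  yaml::write_yaml(out, path)
  invisible(tariff)
}

#' Surgical cost per intervention
#'
#' Operating-room minutes times the per-minute rate, plus the surgical
#' pack, plus navigation when used, plus any procedure-specific material.
#' This is the full operating-room subtotal of one intervention; nothing is
#' double-counted on top of it.
#'
#' @param minutes Operating-room minutes (>= 0).
#' @param tariff A [tariff_table()].
#' @param use_navigation Add the navigation-system charge?
#' @param material_key Key into `tariff$specific_material`, or `NA`/`NULL`
#'   for none. An unknown key is an error.
#' @return Cost in EUR.
#' @examples
#' surgery_subtotal(60, tariff_table(), TRUE, "mistie_catheter") # 2512
#' @export
surgery_subtotal <- function(minutes, tariff = tariff_table(),
                             use_navigation = FALSE, material_key = NULL) {
  if (any(is.na(minutes)) || any(minutes < 0)) {
    abort("surgery_subtotal(): minutes must be present and >= 0")
  }
  material <- 0
  if (!is.null(material_key) && !is.na(material_key)) {
    if (!material_key %in% names(tariff$specific_material)) {
      abort(paste0("Unknown material_key '", material_key, "'. Known: ",
                   paste(names(tariff$specific_material), collapse = ", ")))
    }
    material <- unname(tariff$specific_material[[material_key]])
  }
  nav <- if (isTRUE(use_navigation)) tariff$navigation else 0
  minutes * tariff$or_rate_per_min + tariff$surgical_pack + nav + material
}

#' Ward days from total stay
#'
#' Ordinary-ward days are the remainder of the total stay after the ICU and
#' Stroke-Unit components, floored at zero.
#'
#' @param los_total,los_icu,los_stroke_unit Stays in days (>= 0).
#' @return Ward days (vectorised).
#' @export
ward_days <- function(los_total, los_icu, los_stroke_unit) {
  pmax(0, los_total - los_icu - los_stroke_unit)
}

cost_breakdown_row <- function(arm, surgery_subtotal, surgery_prob,
                               icu_days, stroke_unit_days, wdays,
                               rehab_frac, tariff) {
  surgery_weighted <- surgery_prob * surgery_subtotal
  icu <- icu_days * tariff$icu_per_diem
  su <- stroke_unit_days * tariff$stroke_unit_per_diem
  ward <- wdays * tariff$ward_per_diem
  hospital_total <- surgery_weighted + icu + su + ward
  social <- if (is.na(rehab_frac)) NA_real_ else
    social_cost(rehab_frac, tariff)
  tibble(
    arm = arm,
    surgery_subtotal = surgery_subtotal,
    surgery_weighted = surgery_weighted,
    icu = icu, stroke_unit = su, ward = ward,
    hospital_total = hospital_total,
    social = social,
    total_with_social = hospital_total + social)
}

#' Cost of a conservatively managed arm
#'
#' Conservative management carries no planned operation, but a fraction of
#' patients deteriorate and undergo rescue craniotomy; that probability
#' weights the rescue procedure's surgical subtotal. Stay components are
#' mean days times per-diems.
#'
#' @param summary An [arm_resource_summary()] with `surgery_prob` in
#'   \[0, 1\] (the rescue fraction) and the rescue procedure's
#'   `or_minutes` / navigation / material settings.
#' @param tariff A [tariff_table()].
#' @return A one-row tibble (`cost_breakdown`): surgery subtotal and
#'   weighted surgery cost, ICU / Stroke-Unit / ward components,
#'   `hospital_total`, `social` and `total_with_social` (EUR per patient).
#' @export
conservative_arm_cost <- function(summary, tariff = tariff_table()) {
  stopifnot(inherits(summary, "arm_summary"))
  check_days(summary)
  sub <- surgery_subtotal(summary$or_minutes, tariff,
                          summary$navigation_used,
                          summary$specific_material_cost_key)
  cost_breakdown_row(summary$name, sub, summary$surgery_prob,
                     summary$icu_days, summary$stroke_unit_days,
                     summary$ward_days, summary$rehab_discharge_frac, tariff)
}

#' Cost of a minimally invasive surgical arm
#'
#' Every patient in an interventional arm is operated, so the surgical
#' subtotal enters unweighted; stay components are mean days times
#' per-diems.
#'
#' @inheritParams conservative_arm_cost
#' @return A one-row `cost_breakdown` tibble (see
#'   [conservative_arm_cost()]).
#' @export
mis_arm_cost <- function(summary, tariff = tariff_table()) {
  stopifnot(inherits(summary, "arm_summary"))
  if (!isTRUE(all.equal(summary$surgery_prob, 1))) {
    abort("mis_arm_cost(): interventional arm must have surgery_prob = 1")
  }
  check_days(summary)
  sub <- surgery_subtotal(summary$or_minutes, tariff,
                          summary$navigation_used,
                          summary$specific_material_cost_key)
  cost_breakdown_row(summary$name, sub, 1,
                     summary$icu_days, summary$stroke_unit_days,
                     summary$ward_days, summary$rehab_discharge_frac, tariff)
}

check_days <- function(summary) {
  d <- c(summary$icu_days, summary$stroke_unit_days, summary$ward_days)
  if (any(is.na(d)) || any(d < 0)) {
    abort("arm summary stay days must be present and >= 0")
  }
}

#' Social / rehabilitation cost per patient
#'
#' Patients discharged to a secondary rehabilitation or social facility are
#' charged the rehabilitation per-diem over the social-care horizon; the
#' arm-level cost is that amount weighted by the rehabilitation-discharge
#' fraction.
#'
#' @param rehab_frac Fraction discharged to rehabilitation, in \[0, 1\].
#' @param tariff A [tariff_table()].
#' @return EUR per patient.
#' @export
social_cost <- function(rehab_frac, tariff = tariff_table()) {
  if (any(is.na(rehab_frac)) || any(rehab_frac < 0) || any(rehab_frac > 1)) {
    abort("social_cost(): rehab_frac must lie in [0, 1]")
  }
  rehab_frac * tariff$rehab_per_diem * tariff$rehab_horizon_days
}

#' Per-patient cost breakdown for a cohort
#'
#' Applies the same line-item logic to each patient's own resource use:
#' the rescue-surgery indicator (0/1) replaces the arm-level probability,
#' stays are the patient's own days, and the social term applies to
#' patients discharged to rehabilitation. The mean of these rows over a
#' cohort equals [conservative_arm_cost()] of the cohort's
#' [arm_summary_from_cohort()].
#'
#' @param cohort A validated cohort tibble.
#' @param tariff A [tariff_table()].
#' @param rescue_minutes Operating-room minutes of the rescue craniotomy.
#' @param use_navigation,material_key Rescue-procedure surgical policy.
#' @return A tibble with one `cost_breakdown` row per patient plus
#'   `patient_id`.
#' @export
cost_per_patient <- function(cohort, tariff = tariff_table(),
                             rescue_minutes = 130, use_navigation = FALSE,
                             material_key = NULL) {
  cohort <- validate_cohort(cohort)
  if (any(is.na(cohort$los_icu_d) | is.na(cohort$los_stroke_unit_d) |
            is.na(cohort$los_total_d))) {
    abort("cost_per_patient(): missing length-of-stay fields")
  }
  sub <- surgery_subtotal(rescue_minutes, tariff, use_navigation,
                          material_key)
  wd <- ward_days(cohort$los_total_d, cohort$los_icu_d,
                  cohort$los_stroke_unit_d)
  surgery_weighted <- as.numeric(cohort$rescue_surgery) * sub
  icu <- cohort$los_icu_d * tariff$icu_per_diem
  su <- cohort$los_stroke_unit_d * tariff$stroke_unit_per_diem
  ward <- wd * tariff$ward_per_diem
  hospital_total <- surgery_weighted + icu + su + ward
  social <- as.numeric(cohort$discharge_destination == "rehabilitation") *
    tariff$rehab_per_diem * tariff$rehab_horizon_days
  tibble(
    patient_id = cohort$patient_id,
    surgery_subtotal = sub,
    surgery_weighted = surgery_weighted,
    icu = icu, stroke_unit = su, ward = ward,
    hospital_total = hospital_total,
    social = social,
    total_with_social = hospital_total + social)
}
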