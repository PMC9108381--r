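# Declarative trial-eligibility rule engine. Criteria reference patient
# fields or derived quantities; missing inputs make a criterion
# indeterminate, which by the conservative default policy renders the
# patient ineligible with the reason recorded.

# Derived quantities resolvable by criteria, computed per patient.
DERIVED_FIELDS <- list(
  # >5 ml growth on a control scan at least 6 h after the first image;
  # NA when no control scan exists.
  hematoma_stable = function(p) {
    flag <- expansion_flag(p$volume_initial_ml, p$volume_control_ml)
    if_else(is.na(flag) | is.na(p$control_interval_h), NA,
            !flag & p$control_interval_h >= 6)
  },
  volume_delta_ml = function(p) p$volume_control_ml - p$volume_initial_ml,
  # Clinical severity gate used by the catheter trial: GCS <= 14 or
  # NIHSS >= 6.
  gcs_le14_or_nihss_ge6 = function(p) p$gcs <= 14 | p$nihss >= 6,
  supratentorial = function(p) p$location != "brainstem"
)

CRITERION_OPS <- c("ge", "gt", "le", "lt", "eq", "in_set",
                   "is_true", "is_false", "not_missing")

#' Define a single eligibility criterion
#'
#' @param field A cohort column ([cohort_columns()]) or derived quantity
#'   (`hematoma_stable`, `volume_delta_ml`, `gcs_le14_or_nihss_ge6`,
#'   `supratentorial`).
#' @param op One of `ge`, `gt`, `le`, `lt`, `eq`, `in_set`, `is_true`,
#'   `is_false`, `not_missing`.
#' @param value Threshold or set; ignored for the unary operators.
#' @param label Human-readable rule text (defaults to a compact rendering).
#' @return A list of class `criterion`. Unknown fields or operators error
#'   here, at configuration time, never during evaluation.
#' @export
criterion <- function(field, op, value = NULL, label = NULL) {
  if (!field %in% c(cohort_columns(), names(DERIVED_FIELDS))) {
    abort(paste0("criterion(): unknown field '", field, "'"))
  }
  if (!op %in% CRITERION_OPS) {
    abort(paste0("criterion(): unknown op '", op, "'"))
  }
  if (op %in% c("ge", "gt", "le", "lt", "eq", "in_set") && is.null(value)) {
    abort(paste0("criterion(): op '", op, "' requires a value"))
  }
  label <- label %||% paste(field, op,
                            if (!is.null(value))
                              paste(value, collapse = "/") else "")
  structure(list(field = field, op = op, value = value,
                 label = trimws(label)), class = "criterion")
}

#' Define a trial rule set
#'
#' A patient is eligible when every inclusion criterion holds and no
#' exclusion criterion holds.
#'
#' @param trial Trial identifier.
#' @param inclusion Non-empty list of [criterion()] objects.
#' @param exclusion List of [criterion()] objects (may be empty).
#' @return A list of class `trial_ruleset`.
#' @export
trial_ruleset <- function(trial, inclusion, exclusion = list()) {
  if (length(inclusion) == 0) {
    abort("trial_ruleset(): inclusion list must be non-empty")
  }
  for (cr in c(inclusion, exclusion)) {
    if (!inherits(cr, "criterion")) {
      abort("trial_ruleset(): all rules must be criterion objects")
    }
  }
  structure(list(trial = trial, inclusion = inclusion,
                 exclusion = exclusion), class = "trial_ruleset")
}

#' @export
print.trial_ruleset <- function(x, ...) {
  cat("<trial_ruleset> ", x$trial, "\n  inclusion:\n", sep = "")
  for (cr in x$inclusion) cat("    - ", cr$label, "\n", sep = "")
  if (length(x$exclusion) > 0) {
    cat("  exclusion:\n")
    for (cr in x$exclusion) cat("    - ", cr$label, "\n", sep = "")
  }
  invisible(x)
}

#' Shipped default rule sets of the surgical ICH trials
#'
#' Rule content reconstructed from the trials' published protocols:
#' `study_selection` (supratentorial ICH, admission within 48 h, premorbid
#' mRS <= 3), `mistie3` (volume >= 30 ml, hematoma stability on a repeat
#' scan >= 6 h apart with growth < 5 ml, 72 h window, premorbid mRS <= 1,
#' GCS <= 14 or NIHSS >= 6, no irreversible brainstem dysfunction),
#' `dist` (volume >= 10 ml, 8 h window, premorbid mRS <= 2, NIHSS >= 2,
#' no brainstem dysfunction), `enrich` (lobar or anterior basal-ganglia
#' 30-80 ml, GCS 5-14) and `invest` (deep 20-80 ml, NIHSS >= 6). All
#' defaults are overridable through [trial_ruleset()] configuration files.
#'
#' @param trial One of `"study_selection"`, `"mistie3"`, `"dist"`,
#'   `"enrich"`, `"invest"`.
#' @return A [trial_ruleset()].
#' @export
builtin_ruleset <- function(trial = c("study_selection", "mistie3", "dist",
                                      "enrich", "invest")) {
  trial <- match.arg(trial)
  supra <- criterion("supratentorial", "is_true",
                     label = "supratentorial hematoma")
  no_brainstem <- criterion("brainstem_dysfunction", "is_true",
                            label = "irreversible brainstem dysfunction")
  switch(trial,
    study_selection = trial_ruleset("study_selection", list(
      supra,
      criterion("onset_to_admission_h", "le", 48,
                label = "admission within 48 h of onset"),
      criterion("premorbid_mrs", "le", 3, label = "premorbid mRS <= 3"))),
    mistie3 = trial_ruleset("mistie3", list(
      supra,
      criterion("volume_initial_ml", "ge", 30, label = "volume >= 30 ml"),
      criterion("hematoma_stable", "is_true",
                label = "stable hematoma on repeat imaging (>= 6 h, < 5 ml growth)"),
      criterion("onset_to_admission_h", "le", 72,
                label = "within 72 h window"),
      criterion("premorbid_mrs", "le", 1, label = "premorbid mRS <= 1"),
      criterion("gcs_le14_or_nihss_ge6", "is_true",
                label = "GCS <= 14 or NIHSS >= 6")),
      list(no_brainstem)),
    dist = trial_ruleset("dist", list(
      supra,
      criterion("volume_initial_ml", "ge", 10, label = "volume >= 10 ml"),
      criterion("onset_to_admission_h", "le", 8,
                label = "within 8 h of symptom onset"),
      criterion("premorbid_mrs", "le", 2, label = "premorbid mRS <= 2"),
      criterion("nihss", "ge", 2, label = "NIHSS >= 2")),
      list(no_brainstem)),
    enrich = trial_ruleset("enrich", list(
      criterion("location", "in_set", c("cortical", "basal_ganglia"),
                label = "lobar or anterior basal-ganglia hematoma"),
      criterion("volume_initial_ml", "ge", 30, label = "volume >= 30 ml"),
      criterion("volume_initial_ml", "le", 80, label = "volume <= 80 ml"),
      criterion("gcs", "ge", 5, label = "GCS >= 5"),
      criterion("gcs", "le", 14, label = "GCS <= 14"),
      criterion("onset_to_admission_h", "le", 24,
                label = "within 24 h window")),
      list(no_brainstem)),
    invest = trial_ruleset("invest", list(
      criterion("location", "in_set", c("basal_ganglia", "subcortical"),
                label = "deep hematoma"),
      criterion("volume_initial_ml", "ge", 20, label = "volume >= 20 ml"),
      criterion("volume_initial_ml", "le", 80, label = "volume <= 80 ml"),
      criterion("nihss", "ge", 6, label = "NIHSS >= 6"),
      criterion("onset_to_admission_h", "le", 24,
                label = "within 24 h window")),
      list(no_brainstem)))
}

# Evaluate one criterion against one patient (a one-row tibble).
# Returns TRUE / FALSE / NA (indeterminate).
eval_criterion <- function(cr, patient) {
  x <- if (cr$field %in% names(DERIVED_FIELDS)) {
    DERIVED_FIELDS[[cr$field]](patient)
  } else {
    patient[[cr$field]]
  }
  if (cr$op == "not_missing") return(!is.na(x))
  if (is.na(x)) return(NA)
  switch(cr$op,
    ge = x >= cr$value,
    gt = x > cr$value,
    le = x <= cr$value,
    lt = x < cr$value,
    eq = x == cr$value,
    in_set = x %in% cr$value,
    is_true = isTRUE(as.logical(x)),
    is_false = isFALSE(as.logical(x)))
}

#' Evaluate one patient against a rule set
#'
#' Eligibility requires every inclusion criterion to hold and every
#' exclusion criterion to fail. Criteria that touch missing fields are
#' reported as indeterminate; under the default `"conservative"` policy an
#' indeterminate criterion renders the patient ineligible (with the reason
#' recorded), under `"optimistic"` it is treated as satisfied.
#'
#' @param rules A [trial_ruleset()].
#' @param patient A one-row validated cohort tibble.
#' @param missing_policy `"conservative"` (default) or `"optimistic"`.
#' @return A list: `eligible` (logical), `failed` (labels of violated
#'   criteria), `indeterminate` (labels of criteria touching missing
#'   fields).
#' @export
evaluate_patient <- function(rules, patient,
                             missing_policy = c("conservative",
                                                "optimistic")) {
  missing_policy <- match.arg(missing_policy)
  stopifnot(inherits(rules, "trial_ruleset"))
  failed <- character(0)
  indeterminate <- character(0)
  for (cr in rules$inclusion) {
    v <- eval_criterion(cr, patient)
    if (is.na(v)) indeterminate <- c(indeterminate, cr$label)
    else if (!v) failed <- c(failed, cr$label)
  }
  for (cr in rules$exclusion) {
    v <- eval_criterion(cr, patient)
    if (is.na(v)) indeterminate <- c(indeterminate, cr$label)
    else if (v) failed <- c(failed, cr$label)
  }
  eligible <- length(failed) == 0 &&
    (missing_policy == "optimistic" || length(indeterminate) == 0)
  list(eligible = eligible, failed = failed, indeterminate = indeterminate)
}

#' Screen a cohort against a trial's criteria
#'
#' @param cohort A validated cohort tibble with at least one row.
#' @param rules A [trial_ruleset()].
#' @inheritParams evaluate_patient
#' @return A list of class `screening_result`: `trial`, `n_screened`,
#'   `n_eligible`, `proportion`, and `per_patient`, a tibble with
#'   `patient_id`, `eligible` and list-columns `failed` and
#'   `indeterminate`.
#' @export
screen_cohort <- function(cohort, rules,
                          missing_policy = c("conservative", "optimistic")) {
  missing_policy <- match.arg(missing_policy)
  cohort <- validate_cohort(cohort)
  if (nrow(cohort) == 0) abort("screen_cohort(): empty cohort")
  results <- map(seq_len(nrow(cohort)), function(i) {
    evaluate_patient(rules, cohort[i, ], missing_policy)
  })
  per_patient <- tibble(
    patient_id = cohort$patient_id,
    eligible = map_lgl(results, "eligible"),
    failed = map(results, "failed"),
    indeterminate = map(results, "indeterminate"))
  n_eligible <- sum(per_patient$eligible)
  structure(list(
    trial = rules$trial,
    n_screened = nrow(cohort),
    n_eligible = n_eligible,
    proportion = n_eligible / nrow(cohort),
    per_patient = per_patient), class = "screening_result")
}

#' @export
print.screening_result <- function(x, ...) {
  cat("<screening_result> ", x$trial, ": ", x$n_eligible, "/", x$n_screened,
      " eligible (", sprintf("%.1f%%", 100 * x$proportion), ")\n", sep = "")
  invisible(x)
}

#' Read / write rule sets as YAML
#'
#' One document per trial with fields `trial`, `inclusion`, `exclusion`,
#' each rule a mapping `{field, op, value, label}`.
#'
#' @param path Path to a YAML rule-set file.
#' @param rules A [trial_ruleset()].
#' @return `read_ruleset()`: a `trial_ruleset`; `write_ruleset()`: input,
#'   invisibly.
#' @export
read_ruleset <- function(path) {
  if (!file.exists(path)) abort(paste0("Rule-set file not found: ", path))
  raw <- yaml::read_yaml(path)
  parse_side <- function(side) {
    map(side %||% list(), function(r) {
      criterion(r$field, r$op, value = unlist(r$value), label = r$label)
    })
  }
  trial_ruleset(raw$trial, parse_side(raw$inclusion),
                parse_side(raw$exclusion))
}

#' @rdname read_ruleset
#' @export
write_ruleset <- function(rules, path) {
  stopifnot(inherits(rules, "trial_ruleset"))
  side <- function(rs) map(rs, function(cr) {
    out <- list(field = cr$field, op = cr$op, label = cr$label)
    if (!is.null(cr$value)) out$value <- cr$value
    out
  })
  yaml::write_yaml(list(trial = rules$trial,
                        inclusion = side(rules$inclusion),
                        exclusion = side(rules$exclusion)), path)
  invisible(rules)
}
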