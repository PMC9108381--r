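# mRS -> utility -> QALY over a one-year horizon; death contributes zero.

#' Utility map over modified Rankin Scale states
#'
#' Assigns a health-state utility to each mRS level 0-6. Death (mRS 6) is
#' always worth exactly 0. The shipped preset is `"linear"`,
#' `u(mRS) = (6 - mRS) / 6`; published regression-based maps (e.g. the
#' Whynes EQ-5D model) can be supplied as a custom 7-vector since their
#' coefficients are not part of this package.
#'
#' @param values Numeric vector of 7 utilities for mRS 0-6, each in
#'   \[-1, 1\] with `values[7] == 0`. Overrides `preset`.
#' @param preset `"linear"` (default).
#' @param name Identifier carried on the object.
#' @return A numeric vector of class `utility_map`, named `mrs0`-`mrs6`.
#'   A user map that is not non-increasing in mRS triggers a warning, not
#'   an error.
#' @examples
#' utility_map()["mrs3"] # 0.5
#' @export
utility_map <- function(values = NULL, preset = "linear", name = preset) {
  if (is.null(values)) {
    values <- switch(preset,
      linear = (6 - 0:6) / 6,
      abort(paste0("Unknown utility preset '", preset, "'")))
  }
  if (length(values) != 7) abort("utility_map(): need 7 values (mRS 0-6)")
  if (any(values < -1) || any(values > 1)) {
    abort("utility_map(): utilities must lie in [-1, 1]")
  }
  if (values[7] != 0) abort("utility_map(): u(mRS 6) must be exactly 0")
  if (any(diff(values) > 1e-12)) {
    warn("utility_map(): utilities are not non-increasing in mRS")
  }
  structure(setNames(as.numeric(values), paste0("mrs", 0:6)),
            class = "utility_map", map_name = name)
}

#' Utility attached to an mRS level
#'
#' @param map A [utility_map()].
#' @param mrs Integer mRS value(s) in 0-6.
#' @return Utility value(s); mRS 6 always yields 0.
#' @export
utility_of_mrs <- function(map, mrs) {
  stopifnot(inherits(map, "utility_map"))
  if (any(is.na(mrs)) || any(mrs < 0 | mrs > 6 | mrs != round(mrs))) {
    abort("utility_of_mrs(): mrs must be integers in 0-6")
  }
  unname(unclass(map)[mrs + 1])
}

#' Mean QALY of an arm from its midterm mRS distribution
#'
#' Each evaluable patient contributes `u(mRS) * horizon_years`; deaths
#' contribute zero. The default denominator is the evaluable patients
#' (those with a counted midterm mRS, deaths included); `"enrolled"`
#' divides by `n_enrolled` instead.
#'
#' @param mrs_counts Length-7 vector of midterm mRS 0-6 counts.
#' @param map A [utility_map()].
#' @param horizon_years Survival horizon in years (default 1, no
#'   discounting).
#' @param denominator `"evaluable"` (default) or `"enrolled"`.
#' @param n_enrolled Required when `denominator = "enrolled"`.
#' @return Mean QALY per patient.
#' @examples
#' arm_qaly(c(1, 9, 19, 17, 25, 13, 16), utility_map()) # 0.4017
#' @export
arm_qaly <- function(mrs_counts, map = utility_map(), horizon_years = 1,
                     denominator = c("evaluable", "enrolled"),
                     n_enrolled = NULL) {
  denominator <- match.arg(denominator)
  if (length(mrs_counts) != 7 || any(mrs_counts < 0)) {
    abort("arm_qaly(): mrs_counts must be 7 non-negative counts")
  }
  den <- if (denominator == "evaluable") sum(mrs_counts) else {
    if (is.null(n_enrolled)) {
      abort("arm_qaly(): n_enrolled required for denominator = 'enrolled'")
    }
    n_enrolled
  }
  if (den <= 0) abort("arm_qaly(): zero denominator")
  sum(mrs_counts * utility_of_mrs(map, 0:6)) * horizon_years / den
}

#' Fraction with a good functional outcome
#'
#' Good outcome is mRS at or below the cutoff (default mRS <= 3).
#'
#' @param mrs_counts Length-7 vector of mRS 0-6 counts.
#' @param cutoff Highest mRS still counted as good (default 3).
#' @return Fraction in \[0, 1\].
#' @examples
#' good_outcome_frac(c(1, 9, 19, 17, 25, 13, 16)) # 0.46
#' @export
good_outcome_frac <- function(mrs_counts, cutoff = 3) {
  if (length(mrs_counts) != 7 || any(mrs_counts < 0)) {
    abort("good_outcome_frac(): mrs_counts must be 7 non-negative counts")
  }
  total <- sum(mrs_counts)
  if (total <= 0) abort("good_outcome_frac(): zero total count")
  sum(mrs_counts[seq_len(cutoff + 1)]) / total
}

#' 30-day survival fraction
#'
#' @param deaths_30d Number dead at 30 days (0 <= deaths <= n).
#' @param n Arm size (> 0).
#' @return `1 - deaths_30d / n`.
#' @export
survival_frac_30d <- function(deaths_30d, n) {
  if (n <= 0) abort("survival_frac_30d(): n must be > 0")
  if (deaths_30d < 0 || deaths_30d > n) {
    abort("survival_frac_30d(): deaths must lie in [0, n]")
  }
  1 - deaths_30d / n
}

#' Effectiveness summary of an arm
#'
#' Bundles the arm's mean QALY, good-outcome fraction (mRS <= 3), 30-day
#' survival and evaluable count into one tibble row.
#'
#' @param summary An [arm_resource_summary()].
#' @param map A [utility_map()].
#' @param horizon_years Survival horizon in years.
#' @return A one-row tibble: `arm`, `mean_qaly`, `good_outcome_frac`,
#'   `survival_30d_frac`, `n_evaluable`, `horizon_years`.
#' @export
effect_summary <- function(summary, map = utility_map(), horizon_years = 1) {
  stopifnot(inherits(summary, "arm_summary"))
  counts <- summary$mrs_midterm_counts
  tibble(
    arm = summary$name,
    mean_qaly = arm_qaly(counts, map, horizon_years),
    good_outcome_frac = good_outcome_frac(counts),
    survival_30d_frac = 1 - summary$mortality_30d_frac,
    n_evaluable = sum(counts),
    horizon_years = horizon_years)
}
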