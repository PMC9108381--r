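# Probabilistic sensitivity analysis: replicate (delta cost, delta QALY)
# pairs, cost-utility plane export, acceptability curves.

#' PSA configuration
#'
#' The conventional (cohort) arm is resampled by nonparametric bootstrap of
#' patients, costs and utilities jointly per patient; the literature arm is
#' resampled parametrically: midterm mRS counts from a
#' Dirichlet(counts + 1) posterior, stays from moment-matched gamma
#' distributions, operating-room minutes from a normal truncated at zero.
#'
#' @param n_replicates Number of replicates (default 5,000).
#' @param seed Integer seed; identical configuration and seed give
#'   bit-identical replicates.
#' @param lambda_grid Ascending willingness-to-pay grid in EUR per QALY for
#'   acceptability curves (default 0 to 150,000 by 1,000).
#' @return A list of class `psa_config`.
#' @export
psa_config <- function(n_replicates = 5000, seed = 1L,
                       lambda_grid = seq(0, 150000, by = 1000)) {
  if (n_replicates < 1) abort("psa_config(): n_replicates must be >= 1")
  if (length(lambda_grid) < 1 || is.unsorted(lambda_grid, strictly = TRUE)) {
    abort("psa_config(): lambda_grid must be strictly increasing")
  }
  structure(list(n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed), lambda_grid = lambda_grid),
            class = "psa_config")
}

# Dirichlet(alpha) draw as normalised gammas.
rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

# Gamma draw matched to (mean, sd); degenerate sd yields the mean.
rgamma_moments <- function(mean, sd) {
  if (is.na(sd) || sd <= 0 || mean <= 0) return(mean)
  shape <- (mean / sd)^2
  rgamma(1, shape = shape, rate = shape / mean)
}

rnorm_trunc0 <- function(mean, sd) {
  if (is.na(sd) || sd <= 0) return(mean)
  max(rnorm(1, mean, sd), 0)
}

#' Run the probabilistic sensitivity analysis
#'
#' Produces `config$n_replicates` draws of the incremental cost and
#' incremental QALY of the interventional (literature) arm against the
#' conservative patient-level cohort. Each replicate bootstraps the cohort
#' patients (their line-item costs and their midterm-mRS utilities move
#' together) and redraws the literature arm's parameters as described in
#' [psa_config()]. Costs are hospital totals (no social term) unless
#' `include_social = TRUE`.
#'
#' @param cohort Patient-level conservative arm (validated cohort tibble).
#' @param lit_arm An [arm_resource_summary()] for the interventional arm.
#' @param tariff A [tariff_table()].
#' @param map A [utility_map()].
#' @param config A [psa_config()].
#' @param rescue_minutes,rescue_navigation,rescue_material_key Surgical
#'   policy of the conservative arm's rescue craniotomy.
#' @param horizon_years Survival horizon for QALYs.
#' @param include_social Add social/rehabilitation costs to both arms.
#' @return A tibble of class `psa_result` with columns `replicate`,
#'   `delta_cost`, `delta_qaly`; the deterministic point estimate is
#'   attached as attribute `point_estimate`.
#' @export
run_psa <- function(cohort, lit_arm, tariff = tariff_table(),
                    map = utility_map(), config = psa_config(),
                    rescue_minutes = 130, rescue_navigation = FALSE,
                    rescue_material_key = NULL, horizon_years = 1,
                    include_social = FALSE) {
  cohort <- validate_cohort(cohort)
  if (nrow(cohort) == 0) abort("run_psa(): empty cohort arm")
  stopifnot(inherits(lit_arm, "arm_summary"), inherits(config, "psa_config"))

  per_patient <- cost_per_patient(cohort, tariff, rescue_minutes,
                                  rescue_navigation, rescue_material_key)
  pcost <- if (include_social) per_patient$total_with_social else
    per_patient$hospital_total
  putil <- if_else(is.na(cohort$mrs_midterm), NA_real_,
                   utility_of_mrs(map, dplyr::coalesce(cohort$mrs_midterm, 6)) *
                     horizon_years)
  if (all(is.na(putil))) {
    abort("run_psa(): cohort has no midterm mRS at all; no utility signal")
  }
  n <- nrow(cohort)
  u <- utility_of_mrs(map, 0:6)
  alpha <- lit_arm$mrs_midterm_counts + 1

  mis_cost_draw <- function() {
    minutes <- rnorm_trunc0(lit_arm$or_minutes, lit_arm$or_minutes_sd)
    sub <- surgery_subtotal(minutes, tariff, lit_arm$navigation_used,
                            lit_arm$specific_material_cost_key)
    icu <- rgamma_moments(lit_arm$icu_days, lit_arm$icu_days_sd)
    ward <- rgamma_moments(lit_arm$ward_days, lit_arm$ward_days_sd)
    total <- sub + icu * tariff$icu_per_diem +
      lit_arm$stroke_unit_days * tariff$stroke_unit_per_diem +
      ward * tariff$ward_per_diem
    if (include_social && !is.na(lit_arm$rehab_discharge_frac)) {
      total <- total + social_cost(lit_arm$rehab_discharge_frac, tariff)
    }
    total
  }

  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(config$seed)
  reps <- map(seq_len(config$n_replicates), function(r) {
    idx <- sample.int(n, n, replace = TRUE)
    conv_cost <- mean(pcost[idx])
    conv_util <- putil[idx]
    conv_qaly <- mean(conv_util, na.rm = TRUE)
    w <- rdirichlet1(alpha)
    mis_qaly <- sum(w * u) * horizon_years
    mis_cost <- mis_cost_draw()
    c(delta_cost = mis_cost - conv_cost, delta_qaly = mis_qaly - conv_qaly)
  })
  out <- tibble(
    replicate = seq_len(config$n_replicates),
    delta_cost = map_dbl(reps, "delta_cost"),
    delta_qaly = map_dbl(reps, "delta_qaly"))
  if (any(is.na(out$delta_qaly))) {
    warn("run_psa(): replicates with no evaluable midterm mRS were dropped")
    out <- filter(out, !is.na(.data$delta_qaly))
  }

  det_mis_cost <- {
    sub <- surgery_subtotal(lit_arm$or_minutes, tariff,
                            lit_arm$navigation_used,
                            lit_arm$specific_material_cost_key)
    tot <- sub + lit_arm$icu_days * tariff$icu_per_diem +
      lit_arm$stroke_unit_days * tariff$stroke_unit_per_diem +
      lit_arm$ward_days * tariff$ward_per_diem
    if (include_social && !is.na(lit_arm$rehab_discharge_frac)) {
      tot <- tot + social_cost(lit_arm$rehab_discharge_frac, tariff)
    }
    tot
  }
  point <- c(
    delta_cost = det_mis_cost - mean(pcost),
    delta_qaly = arm_qaly(lit_arm$mrs_midterm_counts, map, horizon_years) -
      mean(putil, na.rm = TRUE))
  structure(out, class = c("psa_result", class(out)),
            point_estimate = point, lambda_grid = config$lambda_grid)
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value, the probability that the
#' intervention is cost-effective: the fraction of replicates with
#' strictly positive net monetary benefit
#' (`lambda * delta_qaly - delta_cost > 0`).
#'
#' @param replicates A [run_psa()] result (or any tibble with `delta_cost`
#'   and `delta_qaly`).
#' @param lambda_grid Ascending willingness-to-pay grid (EUR/QALY).
#' @return A tibble of class `ceac_curve` with columns `lambda` and
#'   `probability`; the replicate count is attached as attribute
#'   `n_replicates`.
#' @export
ceac <- function(replicates, lambda_grid = attr(replicates, "lambda_grid")) {
  if (nrow(replicates) < 1) abort("ceac(): need at least one replicate")
  if (is.null(lambda_grid) || length(lambda_grid) < 1) {
    abort("ceac(): empty lambda grid")
  }
  if (is.unsorted(lambda_grid, strictly = TRUE)) {
    abort("ceac(): lambda_grid must be strictly increasing")
  }
  probs <- map_dbl(lambda_grid, function(l) {
    mean(l * replicates$delta_qaly - replicates$delta_cost > 0)
  })
  structure(tibble(lambda = lambda_grid, probability = probs),
            class = c("ceac_curve", class(tibble())),
            n_replicates = nrow(replicates))
}

#' Willingness-to-pay needed for a target acceptability probability
#'
#' The smallest willingness-to-pay (linearly interpolated between grid
#' points) at which the acceptability curve reaches probability `p`.
#' Returns `NA` with attribute `not_reached = TRUE` when the curve never
#' attains `p` on its grid.
#'
#' @param curve A [ceac()] curve.
#' @param p Target probability in (0, 1).
#' @return EUR per QALY, or `NA` if the probability is not reached.
#' @export
wtp_at_probability <- function(curve, p) {
  if (!all(c("lambda", "probability") %in% names(curve)) ||
      nrow(curve) < 1 || any(is.na(curve$probability))) {
    abort("wtp_at_probability(): malformed curve")
  }
  if (p <= 0 || p >= 1) abort("wtp_at_probability(): p must lie in (0, 1)")
  hit <- which(curve$probability >= p)
  if (length(hit) == 0) {
    return(structure(NA_real_, not_reached = TRUE))
  }
  i <- hit[1]
  if (i == 1) return(curve$lambda[1])
  p0 <- curve$probability[i - 1]; p1 <- curve$probability[i]
  l0 <- curve$lambda[i - 1]; l1 <- curve$lambda[i]
  if (p1 == p0) return(l1)
  l0 + (p - p0) / (p1 - p0) * (l1 - l0)
}

#' Cost-utility plane table
#'
#' One row per replicate with its quadrant and whether it is
#' cost-effective at `lambda` (strictly positive net monetary benefit;
#' a replicate exactly on the threshold is not cost-effective).
#'
#' @param replicates A [run_psa()] result.
#' @param lambda Willingness-to-pay threshold (EUR/QALY).
#' @return A tibble: `replicate`, `delta_qaly`, `delta_cost`, `quadrant`,
#'   `cost_effective`.
#' @export
plane_export <- function(replicates, lambda = 30000) {
  if (nrow(replicates) < 1) abort("plane_export(): no replicates")
  tibble(
    replicate = replicates$replicate %||% seq_len(nrow(replicates)),
    delta_qaly = replicates$delta_qaly,
    delta_cost = replicates$delta_cost,
    quadrant = quadrant(replicates$delta_cost, replicates$delta_qaly),
    cost_effective = lambda * replicates$delta_qaly -
      replicates$delta_cost > 0)
}
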