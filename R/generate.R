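# Synthetic cohort generation: marginals calibrated to the admission-year
# registry of a tertiary stroke centre (n = 137 supratentorial ICH), coupled
# through a single latent severity draw (Gaussian copula).

#' Parameters of the synthetic ICH cohort generator
#'
#' Defaults reproduce the marginal distributions of the reference
#' institutional cohort: age 69 (SD 15.1), 59.1% male, premorbid mRS /
#' GCS-band / location / antithrombotic frequencies, mean hematoma volume
#' 35 ml (SD 42), NIHSS median 12 (range 0-36), hematoma expansion in 33.6%
#' of controlled scans, rescue craniotomy in 13.1%, EVD in 14.6%, and
#' length-of-stay moments (ICU 2 +- 7.8 d, Stroke Unit 2 +- 2.6 d, total
#' 15 +- 20.8 d).
#'
#' @param n Number of patients to generate.
#' @param age_mean,age_sd Age distribution (years); sampled from a normal
#'   truncated to \[18, 100\] whose location is solved so the *truncated*
#'   mean equals `age_mean`.
#' @param male_frac Probability of male sex.
#' @param premorbid_mrs_probs Named or plain probability vector over
#'   premorbid mRS 0-3 (patients with worse premorbid status are outside
#'   the registry's selection window).
#' @param gcs_band_probs Probabilities of the GCS bands 14-15, 5-13, 3-4.
#' @param location_probs Probabilities over basal ganglia, subcortical,
#'   cortical, brainstem locations.
#' @param antithrombotic_probs Probabilities over none, oral anticoagulant,
#'   heparin, antiplatelet, combination.
#' @param mrs_discharge_probs Probabilities over mRS 0-6 at discharge.
#' @param ivh_prob,expansion_prob,rescue_surgery_prob,evd_prob Event
#'   probabilities (intraventricular hemorrhage; >5 ml growth on control
#'   imaging; rescue craniotomy; external ventricular drain).
#' @param control_image_prob Probability that a control scan exists.
#' @param nihss_median,nihss_range NIHSS location and admissible range.
#' @param volume_mean,volume_sd Initial hematoma volume moments (ml);
#'   log-normal re-parameterised to match them.
#' @param los_icu_mean_sd,los_stroke_mean_sd,los_total_mean_sd Two-element
#'   vectors c(mean, sd) in days; gamma matched by moments, with the ward
#'   component built as total - ICU - Stroke Unit so the stay invariant
#'   holds by construction.
#' @param mrs_midterm_missing_prob Probability that a survivor has no
#'   midterm mRS assessment.
#' @param severity_coupling Rank-coupling strength in \[0, 1\] between the
#'   latent severity draw and volume, NIHSS, GCS, stays, rescue surgery and
#'   discharge mRS. 0 = independent marginals, 1 = comonotone.
#' @param seed Integer master seed; every field draws from its own
#'   substream derived from it.
#' @return A validated parameter list of class `cohort_gen_params`.
#' @export
cohort_gen_params <- function(
    n = 137,
    age_mean = 69, age_sd = 15.1,
    male_frac = 0.591,
    premorbid_mrs_probs = c(90, 14, 18, 15) / 137,
    gcs_band_probs = c(76, 47, 14) / 137,
    location_probs = c(basal_ganglia = 73, subcortical = 15,
                       cortical = 46, brainstem = 3) / 137,
    antithrombotic_probs = c(none = 82, oral_anticoagulant = 21, heparin = 3,
                             antiplatelet = 29, combination = 2) / 137,
    mrs_discharge_probs = c(4, 11, 22, 12, 23, 20, 44) / 136,
    ivh_prob = 0.38,
    expansion_prob = 0.336,
    rescue_surgery_prob = 0.131,
    evd_prob = 0.146,
    control_image_prob = 0.679,
    nihss_median = 12, nihss_range = c(0, 36),
    volume_mean = 35, volume_sd = 42,
    los_icu_mean_sd = c(2, 7.8),
    los_stroke_mean_sd = c(2, 2.6),
    los_total_mean_sd = c(15, 20.8),
    mrs_midterm_missing_prob = 0.15,
    severity_coupling = 0.6,
    seed = 1L) {
  p <- as.list(environment())
  check_probs <- function(x, name) {
    if (any(x < 0) || any(x > 1)) {
      abort(paste0(name, ": probabilities must lie in [0, 1]"))
    }
    if (abs(sum(x) - 1) > 1e-9) {
      abort(paste0(name, ": probabilities must sum to 1 (got ",
                   format(sum(x), digits = 12), ")"))
    }
  }
  check_probs(p$premorbid_mrs_probs, "premorbid_mrs_probs")
  check_probs(p$gcs_band_probs, "gcs_band_probs")
  check_probs(p$location_probs, "location_probs")
  check_probs(p$antithrombotic_probs, "antithrombotic_probs")
  check_probs(p$mrs_discharge_probs, "mrs_discharge_probs")
  for (f in c("male_frac", "ivh_prob", "expansion_prob",
              "rescue_surgery_prob", "evd_prob", "control_image_prob",
              "mrs_midterm_missing_prob")) {
    if (p[[f]] < 0 || p[[f]] > 1) abort(paste0(f, " must lie in [0, 1]"))
  }
  if (p$severity_coupling < 0 || p$severity_coupling > 1) {
    abort("severity_coupling must lie in [0, 1]")
  }
  if (p$n < 0 || p$n != round(p$n)) abort("n must be a non-negative integer")
  structure(p, class = "cohort_gen_params")
}

# Substream seed for a named field: fixed per-field offsets keep draws for
# existing fields stable when new fields are added.
FIELD_OFFSETS <- c(
  severity = 1, age = 2, sex = 3, premorbid = 4, antithrombotic = 5,
  gcs = 6, gcs_within = 7, nihss = 8, location = 9, ivh = 10,
  onset = 11, triage = 12, volume = 13, expansion = 14, delta = 15,
  control_present = 16, control_interval = 17, brainstem = 18,
  rescue = 19, evd = 20, los_icu = 21, los_su = 22, los_ward = 23,
  mrs_discharge = 24, home = 25, mrs_shift = 26, midterm_missing = 27,
  death_30d = 28
)

substream <- function(seed, field, n, rfun = runif) {
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed((as.numeric(seed) * 2654435 + FIELD_OFFSETS[[field]] * 40503) %%
             2147483629)
  rfun(n)
}

.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_set <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}

# Couple an independent uniform draw to the latent severity z with strength
# rho; the result is still marginally uniform (Gaussian copula).
couple <- function(z, eps_norm, rho, direction = +1) {
  pnorm(direction * rho * z + sqrt(1 - rho^2) * eps_norm)
}

# Location of a normal truncated to [lo, hi] with scale sd whose truncated
# mean equals target.
truncnorm_location <- function(target, sd, lo, hi) {
  tmean <- function(m) {
    a <- (lo - m) / sd; b <- (hi - m) / sd
    z <- pnorm(b) - pnorm(a)
    m + sd * (dnorm(a) - dnorm(b)) / z
  }
  uniroot(function(m) tmean(m) - target, lower = lo, upper = hi,
          tol = 1e-10)$root
}

qtruncnorm <- function(u, mean, sd, lo, hi) {
  pa <- pnorm(lo, mean, sd); pb <- pnorm(hi, mean, sd)
  qnorm(pa + u * (pb - pa), mean, sd)
}

# Quantile function over a discrete support given cell probabilities.
qdiscrete <- function(u, support, probs) {
  idx <- findInterval(u, cumsum(probs), left.open = TRUE) + 1
  support[pmin(idx, length(support))]
}

# Beta shape b such that the median of Beta(a, b) is approximately m.
beta_b_for_median <- function(m, a = 2) (a - 1 / 3) / m - a + 2 / 3

#' Generate a synthetic ICH cohort
#'
#' Draws `params$n` patient records whose marginals follow
#' [cohort_gen_params()] and whose severity-related fields (hematoma volume,
#' NIHSS, GCS, lengths of stay, rescue surgery, discharge and midterm mRS)
#' are coupled through one standard-normal latent severity per patient
#' pushed through each marginal's quantile function (Gaussian copula with
#' strength `severity_coupling`). Output is bit-identical for identical
#' parameters and seed, and always satisfies the cohort invariants.
#'
#' @param params A [cohort_gen_params()] object.
#' @return A validated cohort tibble with `params$n` rows.
#' @examples
#' cohort <- generate_cohort(cohort_gen_params(n = 50, seed = 7))
#' @export
generate_cohort <- function(params = cohort_gen_params()) {
  if (!inherits(params, "cohort_gen_params")) {
    params <- do.call(cohort_gen_params, params)
  }
  p <- params
  n <- p$n
  if (n == 0) {
    empty <- tibble(
      patient_id = character(), age = numeric(), sex = character(),
      premorbid_mrs = numeric(), antithrombotic = character(),
      gcs = numeric(), nihss = numeric(), location = character(),
      ivh = logical(), onset_to_admission_h = numeric(),
      triage_to_image_min = numeric(), volume_initial_ml = numeric(),
      volume_control_ml = numeric(), control_interval_h = numeric(),
      brainstem_dysfunction = logical(), rescue_surgery = logical(),
      evd = logical(), los_icu_d = numeric(), los_stroke_unit_d = numeric(),
      los_total_d = numeric(), discharge_destination = character(),
      mrs_discharge = numeric(), mrs_midterm = numeric(),
      survived_30d = logical())
    return(empty)
  }
  rho <- p$severity_coupling
  seed <- p$seed
  draw_u <- function(field) substream(seed, field, n, runif)
  draw_z <- function(field) substream(seed, field, n, rnorm)

  z <- draw_z("severity")

  age_loc <- truncnorm_location(p$age_mean, p$age_sd, 18, 100)
  age <- round(qtruncnorm(draw_u("age"), age_loc, p$age_sd, 18, 100))
  sex <- if_else(draw_u("sex") < p$male_frac, "male", "female")
  premorbid <- qdiscrete(draw_u("premorbid"), seq_along(p$premorbid_mrs_probs) - 1,
                         p$premorbid_mrs_probs)
  antithrombotic <- qdiscrete(draw_u("antithrombotic"),
                              ANTITHROMBOTIC_LEVELS,
                              unname(p$antithrombotic_probs))
  location <- qdiscrete(draw_u("location"), LOCATION_LEVELS,
                        unname(p$location_probs))
  ivh <- draw_u("ivh") < p$ivh_prob

  # GCS: band picked by a severity-coupled uniform (higher severity = lower
  # GCS), integer within band uniform.
  per_value_probs <- c(rep(p$gcs_band_probs[3] / 2, 2),   # 3-4
                       rep(p$gcs_band_probs[2] / 9, 9),   # 5-13
                       rep(p$gcs_band_probs[1] / 2, 2))   # 14-15
  u_gcs <- couple(z, draw_z("gcs"), rho, direction = -1)
  gcs <- qdiscrete(u_gcs, 3:15, per_value_probs)

  # NIHSS: scaled beta with median matched; severity-increasing.
  b <- beta_b_for_median(p$nihss_median / 42)
  u_nihss <- couple(z, draw_z("nihss"), rho, direction = +1)
  nihss <- pmin(pmax(round(42 * qbeta(u_nihss, 2, b)), p$nihss_range[1]),
                p$nihss_range[2])

  # Initial hematoma volume: log-normal matched to mean/SD.
  sigma2 <- log(1 + (p$volume_sd / p$volume_mean)^2)
  mu <- log(p$volume_mean) - sigma2 / 2
  u_vol <- couple(z, draw_z("volume"), rho, direction = +1)
  volume <- qlnorm(u_vol, mu, sqrt(sigma2))

  onset <- pmin(qlnorm(draw_u("onset"), log(4), 1), 48)
  triage <- pmin(pmax(qlnorm(draw_u("triage"), log(19), 1.42), 2), 460)

  control_present <- draw_u("control_present") < p$control_image_prob
  expanded <- draw_u("expansion") < p$expansion_prob
  delta <- if_else(expanded,
                   5 + 20 * draw_u("delta"),
                   -4 + 8.9 * draw_u("delta"))  # in (-4, 4.9]: never > 5
  volume_control <- if_else(control_present, pmax(volume + delta, 0), NA_real_)
  control_interval <- if_else(control_present,
                              6 + 18 * draw_u("control_interval"), NA_real_)

  brainstem_dysfunction <- draw_u("brainstem") < 0.08 | gcs <= 4
  rescue <- couple(z, draw_z("rescue"), rho, direction = +1) >
    (1 - p$rescue_surgery_prob)
  evd <- draw_u("evd") < p$evd_prob

  gam_q <- function(u, mean_sd) {
    shape <- (mean_sd[1] / mean_sd[2])^2
    qgamma(u, shape = shape, rate = shape / mean_sd[1])
  }
  u_icu <- couple(z, draw_z("los_icu"), rho, direction = +1)
  u_su <- couple(z, draw_z("los_su"), rho * 0.5, direction = +1)
  los_icu <- gam_q(u_icu, p$los_icu_mean_sd)
  los_su <- gam_q(u_su, p$los_stroke_mean_sd)
  ward_mean <- max(p$los_total_mean_sd[1] - p$los_icu_mean_sd[1] -
                     p$los_stroke_mean_sd[1], 0.5)
  ward_sd <- sqrt(max(p$los_total_mean_sd[2]^2 - p$los_icu_mean_sd[2]^2 -
                        p$los_stroke_mean_sd[2]^2, 1))
  u_ward <- couple(z, draw_z("los_ward"), rho, direction = +1)
  los_ward <- gam_q(u_ward, c(ward_mean, ward_sd))
  los_total <- los_icu + los_su + los_ward

  u_mrs <- couple(z, draw_z("mrs_discharge"), rho, direction = +1)
  mrs_discharge <- qdiscrete(u_mrs, 0:6, unname(p$mrs_discharge_probs))
  dead <- mrs_discharge == 6
  home_frac <- 39 / 93  # home share among survivors in the reference cohort
  destination <- case_when(
    dead ~ "death",
    draw_u("home") < home_frac & mrs_discharge <= 4 ~ "home",
    TRUE ~ "rehabilitation")

  # Midterm mRS: discharge status shifted by -1/0/+1 (recovery more likely),
  # deaths persist; missing for a fraction of survivors.
  shift_u <- draw_u("mrs_shift")
  shift <- case_when(shift_u < 0.45 ~ -1L, shift_u < 0.85 ~ 0L, TRUE ~ 1L)
  mrs_midterm <- if_else(dead, 6, pmin(pmax(mrs_discharge + shift, 0), 6))
  missing_mid <- !dead & draw_u("midterm_missing") < p$mrs_midterm_missing_prob
  mrs_midterm[missing_mid] <- NA_real_

  # Most in-hospital deaths occur within 30 days.
  survived_30d <- !dead | draw_u("death_30d") > 0.8

  cohort <- tibble(
    patient_id = sprintf("P%04d", seq_len(n)),
    age = as.numeric(age), sex = sex,
    premorbid_mrs = as.numeric(premorbid),
    antithrombotic = antithrombotic,
    gcs = as.numeric(gcs), nihss = as.numeric(nihss),
    location = location, ivh = ivh,
    onset_to_admission_h = onset,
    triage_to_image_min = triage,
    volume_initial_ml = volume,
    volume_control_ml = volume_control,
    control_interval_h = control_interval,
    brainstem_dysfunction = brainstem_dysfunction,
    rescue_surgery = rescue, evd = evd,
    los_icu_d = los_icu, los_stroke_unit_d = los_su, los_total_d = los_total,
    discharge_destination = destination,
    mrs_discharge = as.numeric(mrs_discharge),
    mrs_midterm = mrs_midterm,
    survived_30d = survived_30d)
  validate_cohort(cohort)
}

#' Read / write generator parameters as YAML
#'
#' @param path Path to a YAML file holding [cohort_gen_params()] fields.
#' @param params A `cohort_gen_params` object.
#' @return `read_gen_params()`: a validated `cohort_gen_params`;
#'   `write_gen_params()`: the input, invisibly.
#' @export
read_gen_params <- function(path) {
  if (!file.exists(path)) abort(paste0("Parameter file not found: ", path))
  raw <- map(yaml::read_yaml(path),
             ~ if (is.list(.x)) unlist(.x) else .x)
  do.call(cohort_gen_params, raw)
}

#' @rdname read_gen_params
#' @export
write_gen_params <- function(params, path) {
  stopifnot(inherits(params, "cohort_gen_params"))
  # named vectors go out as YAML maps so the names survive the round trip
  out <- map(unclass(params),
             ~ if (is.numeric(.x) && !is.null(names(.x))) as.list(.x) else .x)
  yaml::write_yaml(out, path, precision = 15)
  invisible(params)
}
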