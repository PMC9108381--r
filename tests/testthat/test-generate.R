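test_that("generation is deterministic in the seed and respects n", {
  p <- cohort_gen_params(n = 40, seed = 42)
  a <- generate_cohort(p)
  b <- generate_cohort(p)
  expect_identical(a, b)
  expect_equal(nrow(a), 40)
  expect_equal(nrow(generate_cohort(cohort_gen_params(n = 0))), 0)
  d <- generate_cohort(cohort_gen_params(n = 40, seed = 43))
  expect_false(identical(a, d))
  # every generated cohort satisfies the record invariants by construction
  expect_silent(validate_cohort(a))
})

test_that("generated marginals match the calibration targets at n = 5000", {
  cohort <- generate_cohort(cohort_gen_params(n = 5000, seed = 7))
  n <- nrow(cohort)
  z99 <- qnorm(0.995)
  # binomial marginals within the 99% Monte-Carlo CI of their targets
  bin_ci <- function(p) z99 * sqrt(p * (1 - p) / n)
  expect_lt(abs(mean(cohort$sex == "male") - 0.591), bin_ci(0.591))
  expect_lt(abs(mean(cohort$ivh) - 0.38), bin_ci(0.38))
  expect_lt(abs(mean(cohort$rescue_surgery) - 0.131), bin_ci(0.131))
  expect_lt(abs(mean(cohort$evd) - 0.146), bin_ci(0.146))
  expect_lt(abs(mean(cohort$location == "basal_ganglia") - 73 / 137),
            bin_ci(73 / 137))
  expect_lt(abs(mean(cohort$premorbid_mrs == 0) - 90 / 137),
            bin_ci(90 / 137))
  # continuous marginals: mean volume 35 ml (SD 42), mean age 69
  expect_lt(abs(mean(cohort$volume_initial_ml) - 35), z99 * 42 / sqrt(n))
  expect_lt(abs(mean(cohort$age) - 69), z99 * 15.1 / sqrt(n) + 0.5)
  # expansion among controlled scans
  flag <- expansion_flag(cohort$volume_initial_ml, cohort$volume_control_ml)
  expect_lt(abs(mean(flag, na.rm = TRUE) - 0.336), bin_ci(0.336) * 1.3)
  # NIHSS centred near its target median
  expect_lt(abs(median(cohort$nihss) - 12), 2)
})

test_that("severity coupling controls the volume-NIHSS dependence", {
  indep <- generate_cohort(cohort_gen_params(n = 5000, seed = 3,
                                             severity_coupling = 0))
  r0 <- cor(indep$volume_initial_ml, indep$nihss, method = "spearman")
  expect_lt(abs(r0), 0.05)
  tight <- generate_cohort(cohort_gen_params(n = 5000, seed = 3,
                                             severity_coupling = 1))
  r1 <- cor(tight$volume_initial_ml, tight$nihss, method = "spearman")
  expect_gt(r1, 0.5)
  # coupled fields move together: sicker patients stay longer
  expect_gt(cor(tight$nihss, tight$los_total_d, method = "spearman"), 0.5)
})

test_that("invalid generator parameters are rejected before sampling", {
  expect_error(cohort_gen_params(location_probs = c(0.5, 0.2, 0.2, 0.2)),
               "sum to 1")
  expect_error(cohort_gen_params(male_frac = 1.2), "\\[0, 1\\]")
  expect_error(cohort_gen_params(severity_coupling = 2), "severity_coupling")
  expect_error(cohort_gen_params(n = -1), "non-negative")
})

test_that("generator parameters survive a YAML round trip", {
  p <- cohort_gen_params(n = 25, seed = 9, male_frac = 0.5)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_gen_params(p, path)
  q <- read_gen_params(path)
  expect_equal(unclass(q), unclass(p), tolerance = 1e-12)
  expect_identical(generate_cohort(p), generate_cohort(q))
})

test_that("literature arm fixtures carry the published table values", {
  k <- literature_arm("kellner_intervention")
  expect_equal(k$rehab_discharge_frac, 0.93)
  expect_equal(k$or_minutes, 150)
  expect_equal(k$mrs_midterm_counts, c(1, 9, 19, 17, 25, 13, 16))
  expect_equal(sum(k$mrs_midterm_counts), 100)
  m <- literature_arm("mistie3_intervention")
  expect_equal(m$icu_days, 10)
  expect_equal(m$ward_days, 45)
  expect_equal(m$stroke_unit_days, 0)
  expect_equal(m$mrs_midterm_counts, c(1, 15, 30, 64, 60, 31, 48))
  expect_equal(sum(m$mrs_midterm_counts), 249)
  expect_equal(m$mortality_30d_frac, 24 / 255)
  # Kellner stays: cost-line values by default, stay medians on request
  k2 <- literature_arm("kellner_intervention", use_cost_line_days = FALSE)
  expect_equal(k2$icu_days, 9)
  expect_equal(k2$ward_days, 8)
  expect_equal(k$icu_days, 8.5)
  expect_equal(k$ward_days, 8.5)
  expect_error(literature_arm("nope"), "Available")
})

test_that("cohort aggregation computes the costing inputs", {
  two <- dplyr::bind_rows(make_patient("A", rescue_surgery = TRUE),
                          make_patient("B"))
  s <- arm_summary_from_cohort(two, or_minutes = 130)
  expect_equal(s$surgery_prob, 0.5)
  one <- make_patient("A", los_total_d = 24, los_icu_d = 4,
                      los_stroke_unit_d = 2)
  expect_equal(arm_summary_from_cohort(one)$ward_days, 18)
  nomid <- make_cohort(3, mrs_midterm = NA_real_)
  s2 <- arm_summary_from_cohort(nomid)
  expect_equal(s2$mrs_midterm_counts, rep(0, 7))
  expect_false(s2$mrs_complete)
  expect_error(arm_summary_from_cohort(make_patient()[0, ]), "empty")
})

test_that("synthetic candidate reconstructions match the printed aggregates", {
  cath <- reference_cohort("mistie3")
  expect_equal(nrow(cath), 17)
  expect_equal(mean(cath$rescue_surgery), 5 / 17)
  expect_equal(mean(cath$discharge_destination == "rehabilitation"), 12 / 17)
  s <- arm_summary_from_cohort(cath, or_minutes = 130)
  expect_equal(s$mrs_midterm_counts, c(0, 0, 0, 2, 2, 3, 7))
  expect_equal(s$icu_days, 4)
  expect_equal(s$ward_days, 18)
  endo <- reference_cohort("dist")
  expect_equal(nrow(endo), 59)
  expect_equal(mean(endo$rescue_surgery), 10 / 59)
  s2 <- arm_summary_from_cohort(endo, or_minutes = 136.9)
  expect_equal(s2$mrs_midterm_counts, c(2, 1, 5, 6, 10, 6, 19))
  expect_equal(s2$ward_days, 16)
  expect_equal(mean(endo$discharge_destination == "rehabilitation"), 33 / 59)
})
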