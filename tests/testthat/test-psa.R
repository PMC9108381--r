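psa_fixture <- function(n_replicates = 300, seed = 1, arm = "mistie3") {
  cohort <- reference_cohort(arm)
  lit <- literature_arm(if (arm == "mistie3") "mistie3_intervention"
                        else "kellner_intervention")
  run_psa(cohort, lit, tariff_table(), utility_map(),
          psa_config(n_replicates = n_replicates, seed = seed,
                     lambda_grid = seq(0, 150000, by = 2500)),
          rescue_minutes = if (arm == "mistie3") 130 else 136.9)
}

test_that("PSA replicates are reproducible and sized as configured", {
  a <- psa_fixture(n_replicates = 50, seed = 9)
  b <- psa_fixture(n_replicates = 50, seed = 9)
  expect_identical(as.data.frame(a), as.data.frame(b))
  expect_equal(nrow(a), 50)
  c2 <- psa_fixture(n_replicates = 50, seed = 10)
  expect_false(identical(as.data.frame(a), as.data.frame(c2)))
  expect_error(run_psa(make_patient()[0, ],
                       literature_arm("mistie3_intervention")), "empty")
})

test_that("degenerate inputs give near-degenerate replicates", {
  # single patient duplicated and a point-mass literature arm
  cohort <- dplyr::bind_rows(purrr::map(1:5, function(i) {
    make_patient(sprintf("Z%d", i))
  }))
  lit <- arm_resource_summary("point", n = 100, or_minutes = 60,
                              surgery_prob = 1, icu_days = 10,
                              stroke_unit_days = 0, ward_days = 45,
                              mrs_midterm_counts = c(0, 0, 0, 100, 0, 0, 0),
                              navigation_used = TRUE,
                              specific_material_cost_key = "mistie_catheter",
                              or_minutes_sd = 0, icu_days_sd = 0,
                              ward_days_sd = 0)
  reps <- run_psa(cohort, lit, config = psa_config(n_replicates = 40,
                                                   seed = 2))
  # costs are exactly constant (identical patients, frozen parameters);
  # the only residual spread is the Dirichlet smoothing of the mRS counts
  expect_equal(diff(range(reps$delta_cost)), 0)
  expect_lt(stats::sd(reps$delta_qaly), 0.05)
})

test_that("bootstrap means recover the deterministic point estimate", {
  reps <- psa_fixture(n_replicates = 2000, seed = 4)
  point <- attr(reps, "point_estimate")
  mc_se_cost <- stats::sd(reps$delta_cost) / sqrt(nrow(reps))
  mc_se_qaly <- stats::sd(reps$delta_qaly) / sqrt(nrow(reps))
  expect_lt(abs(mean(reps$delta_cost) - point["delta_cost"]),
            2 * mc_se_cost + 50)  # Dirichlet prior shifts by o(1/n) only
  expect_lt(abs(mean(reps$delta_qaly) - point["delta_qaly"]),
            2 * mc_se_qaly + 0.02)
})

test_that("the acceptability curve equals a brute-force replicate count", {
  reps <- psa_fixture(n_replicates = 200, seed = 5)
  grid <- c(1000, 30000, 80000, 140000)
  curve <- ceac(reps, grid)
  brute <- purrr::map_dbl(grid, function(l) {
    sum(l * reps$delta_qaly - reps$delta_cost > 0) / nrow(reps)
  })
  expect_equal(curve$probability, brute)
  # limits: lambda -> 0+ counts cost savings, lambda -> Inf counts gains
  lo <- ceac(reps, c(1e-9, 1e12))
  expect_equal(lo$probability[1], mean(reps$delta_cost < 0))
  expect_equal(lo$probability[2], mean(reps$delta_qaly > 0))
  # all replicates gaining QALYs makes the curve non-decreasing
  if (all(reps$delta_qaly > 0)) {
    full <- ceac(reps, seq(0, 150000, by = 2500))
    expect_true(all(diff(full$probability) >= -1e-12))
  }
  expect_error(ceac(reps, numeric(0)), "empty")
})

test_that("a point-mass replicate set steps at its own ICER", {
  one <- tibble::tibble(replicate = 1, delta_cost = 10, delta_qaly = 1)
  curve <- ceac(one, c(5, 9.999, 10, 10.001, 20))
  expect_equal(curve$probability, c(0, 0, 0, 1, 1))  # strict NMB > 0
  expect_equal(wtp_at_probability(curve, 0.5), 10, tolerance = 1e-3)
})

test_that("WTP-at-probability interpolates and reports unreachable targets", {
  synth <- tibble::tibble(lambda = c(0, 100), probability = c(0, 1))
  expect_equal(wtp_at_probability(synth, 0.25), 25)
  capped <- tibble::tibble(lambda = c(0, 100), probability = c(0.1, 0.4))
  out <- wtp_at_probability(capped, 0.5)
  expect_true(is.na(out))
  expect_true(attr(out, "not_reached"))
  expect_error(wtp_at_probability(synth, 1.5), "\\(0, 1\\)")
  expect_error(wtp_at_probability(tibble::tibble(x = 1), 0.5), "malformed")
})

test_that("the packaged comparison scenarios land north-east", {
  for (arm in c("mistie3", "dist")) {
    reps <- psa_fixture(n_replicates = 400, seed = 6, arm = arm)
    plane <- plane_export(reps, lambda = 30000)
    expect_gte(mean(plane$quadrant == "NE"), 0.9)
    # flags agree with the net-benefit rule
    expect_equal(plane$cost_effective,
                 30000 * reps$delta_qaly - reps$delta_cost > 0)
  }
  # hand-checked flags at the threshold
  toy <- tibble::tibble(replicate = 1:2, delta_cost = c(10000, 10000),
                        delta_qaly = c(1, 0.1))
  flags <- plane_export(toy, lambda = 30000)$cost_effective
  expect_equal(flags, c(TRUE, FALSE))
})

test_that("the 50% acceptability crossing sits near the deterministic ICER", {
  reps <- psa_fixture(n_replicates = 600, seed = 8)
  curve <- ceac(reps, seq(0, 250000, by = 2500))
  wtp50 <- wtp_at_probability(curve, 0.5)
  expect_false(is.na(wtp50))
  # same order of magnitude as the published 50% crossings (62k-69k EUR)
  expect_gt(wtp50, 2e4)
  expect_lt(wtp50, 2.5e5)
})

test_that("plots build without evaluation errors", {
  reps <- psa_fixture(n_replicates = 60, seed = 12)
  p1 <- autoplot(reps)
  p2 <- autoplot(ceac(reps, seq(0, 150000, 5000)))
  expect_s3_class(p1, "ggplot")
  expect_s3_class(p2, "ggplot")
  built <- ggplot2::ggplot_build(p1)
  expect_equal(nrow(built$data[[4]]), 60)  # one point per replicate
})
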