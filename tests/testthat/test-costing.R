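test_that("surgical subtotals reproduce the published operating-room lines", {
  t <- tariff_table()
  expect_equal(surgery_subtotal(60, t, TRUE, "mistie_catheter"), 2512)
  expect_equal(surgery_subtotal(150, t, TRUE, "endoscope_consumables"), 9762)
  expect_equal(surgery_subtotal(130, t, FALSE), 1800)
  expect_error(surgery_subtotal(60, t, FALSE, "unobtainium"), "Known")
  expect_error(surgery_subtotal(-5, t), ">= 0")
})

test_that("ward days are the stay remainder, floored at zero", {
  expect_equal(ward_days(24, 4, 2), 18)
  expect_equal(ward_days(55, 10, 0), 45)
  expect_equal(ward_days(5, 5, 0), 0)
  expect_equal(ward_days(3, 4, 2), 0)
})

test_that("arm costs rebuild the published per-patient totals", {
  t <- tariff_table()
  conv_c <- conservative_arm_cost(
    literature_arm("mistie3_candidates_conventional"), t)
  expect_equal(conv_c$hospital_total, 14190.06, tolerance = 1e-3)
  mis_c <- mis_arm_cost(literature_arm("mistie3_intervention"), t)
  expect_equal(mis_c$hospital_total, 33127.15, tolerance = 1e-3)
  conv_e <- conservative_arm_cost(
    literature_arm("dist_candidates_conventional"), t)
  expect_equal(conv_e$hospital_total, 13486.53, tolerance = 1e-3)
  mis_e <- mis_arm_cost(literature_arm("kellner_intervention"), t)
  expect_equal(mis_e$hospital_total, 23318.74, tolerance = 1e-3)
  # degenerate arm: no surgery probability, no stays, no cost
  zero <- arm_resource_summary("zero", 10, or_minutes = 130,
                               surgery_prob = 0, icu_days = 0,
                               stroke_unit_days = 0, ward_days = 0,
                               rehab_discharge_frac = 0)
  expect_equal(conservative_arm_cost(zero, t)$hospital_total, 0)
  # interventional costing refuses a non-surgical arm
  expect_error(mis_arm_cost(zero, t), "surgery_prob")
})

test_that("social costs follow the rehabilitation fraction and horizon", {
  t <- tariff_table()
  expect_equal(social_cost(0.706, t), 6216.1, tolerance = 5e-4)
  expect_equal(social_cost(0, t), 0)
  expect_equal(social_cost(1, t), 8802)
  expect_error(social_cost(1.2, t), "\\[0, 1\\]")
})

test_that("cost breakdowns are additive and linear in per-diems", {
  t <- tariff_table()
  rows <- reproduce_reference_costs(t)
  expect_equal(rows$hospital_total,
               rows$surgery_weighted + rows$icu + rows$stroke_unit +
                 rows$ward, tolerance = 1e-9)
  expect_equal(rows$total_with_social, rows$hospital_total + rows$social,
               tolerance = 1e-9)
  double <- tariff_table(icu_per_diem = 2 * t$icu_per_diem,
                         stroke_unit_per_diem = 2 * t$stroke_unit_per_diem,
                         ward_per_diem = 2 * t$ward_per_diem)
  rows2 <- reproduce_reference_costs(double)
  expect_equal(rows2$icu, 2 * rows$icu)
  expect_equal(rows2$stroke_unit, 2 * rows$stroke_unit)
  expect_equal(rows2$ward, 2 * rows$ward)
  expect_equal(rows2$surgery_weighted, rows$surgery_weighted)
})

test_that("per-patient costing matches hand sums and the arm-level oracle", {
  t <- tariff_table()
  ward_only <- make_patient(los_icu_d = 0, los_stroke_unit_d = 0,
                            los_total_d = 10,
                            discharge_destination = "home")
  expect_equal(cost_per_patient(ward_only, t)$hospital_total, 4190)
  op <- make_patient(rescue_surgery = TRUE, los_icu_d = 0,
                     los_stroke_unit_d = 0, los_total_d = 0)
  expect_equal(cost_per_patient(op, t, rescue_minutes = 130)$hospital_total,
               1800)
  zero <- make_patient(los_icu_d = 0, los_stroke_unit_d = 0, los_total_d = 0)
  expect_equal(cost_per_patient(zero, t)$hospital_total, 0)

  # oracle equivalence: mean per-patient cost equals the aggregated arm cost
  cohort <- generate_cohort(cohort_gen_params(n = 400, seed = 23))
  per <- cost_per_patient(cohort, t, rescue_minutes = 130)
  summ <- arm_summary_from_cohort(cohort, or_minutes = 130)
  agg <- conservative_arm_cost(summ, t)
  expect_equal(mean(per$hospital_total), agg$hospital_total,
               tolerance = 1e-9)
  expect_equal(mean(per$total_with_social), agg$total_with_social,
               tolerance = 1e-9)
})

test_that("costs are nondecreasing in every resource-use field", {
  t <- tariff_table()
  base <- make_patient(los_icu_d = 2, los_stroke_unit_d = 1,
                       los_total_d = 10)
  base_cost <- cost_per_patient(base, t)$hospital_total
  more_icu <- cost_per_patient(
    make_patient(los_icu_d = 4, los_stroke_unit_d = 1, los_total_d = 10),
    t)$hospital_total
  longer <- cost_per_patient(
    make_patient(los_icu_d = 2, los_stroke_unit_d = 1, los_total_d = 14),
    t)$hospital_total
  with_surgery <- cost_per_patient(
    make_patient(rescue_surgery = TRUE, los_icu_d = 2,
                 los_stroke_unit_d = 1, los_total_d = 10), t)$hospital_total
  expect_gte(more_icu, base_cost)
  expect_gte(longer, base_cost)
  expect_gte(with_surgery, base_cost)
})

test_that("tariffs reject negatives and survive a YAML round trip", {
  expect_error(tariff_table(icu_per_diem = -1), "negative")
  t <- tariff_table()
  path <- withr::local_tempfile(fileext = ".yaml")
  write_tariff(t, path)
  back <- read_tariff(path)
  expect_equal(unclass(back), unclass(t), tolerance = 1e-12)
})
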