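# A minimal valid patient row; override fields as needed.
make_patient <- function(id = "P1", ...) {
  p <- tibble::tibble(
    patient_id = id, age = 70, sex = "male", premorbid_mrs = 0,
    antithrombotic = "none", gcs = 12, nihss = 8,
    location = "basal_ganglia", ivh = FALSE,
    onset_to_admission_h = 6, triage_to_image_min = 19,
    volume_initial_ml = 12, volume_control_ml = NA_real_,
    control_interval_h = NA_real_, brainstem_dysfunction = FALSE,
    rescue_surgery = FALSE, evd = FALSE,
    los_icu_d = 2, los_stroke_unit_d = 2, los_total_d = 10,
    discharge_destination = "home", mrs_discharge = 2, mrs_midterm = 2,
    survived_30d = TRUE)
  overrides <- list(...)
  for (nm in names(overrides)) p[[nm]] <- overrides[[nm]]
  p
}

make_cohort <- function(n = 3, ...) {
  dplyr::bind_rows(lapply(seq_len(n), function(i) {
    make_patient(id = sprintf("P%03d", i), ...)
  }))
}
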