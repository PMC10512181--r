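# Shared, lazily-built fixtures.  The calibrated healthy heart and the
# compensated simulations are reused across test files; everything is built
# in code from the normative subject.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (is.null(.fixtures[[name]]))
    .fixtures[[name]] <- suppressWarnings(force(expr))
  .fixtures[[name]]
}

healthy_subject <- function() subject_data()

healthy_calibration <- function() {
  fixture("cal", calibrate_heart(healthy_subject()))
}

healthy_circulation <- function(disease = FALSE) {
  derive_circulation_parameters(healthy_subject(), disease = disease)
}

healthy_compensation <- function() {
  fixture("comp_h", find_compensated_tbv(healthy_calibration()$heart,
                                         healthy_circulation()))
}

healthy_sim_46 <- function() {
  fixture("sim46", simulate_heart(healthy_calibration()$heart,
                                  healthy_circulation(), tbv = 4600))
}

# compensated dysfunction cases, keyed like "LVSD-S"
dysfunction_compensation <- function(key) {
  fixture(paste0("comp_", key), {
    parts <- strsplit(key, "-")[[1]]
    target <- substr(parts[1], 1, 2)
    mode <- if (substr(parts[1], 3, 4) == "SD") "systolic" else "diastolic"
    sev <- if (parts[2] == "M") "moderate" else "severe"
    h <- apply_dysfunction(healthy_calibration()$heart,
                           dysfunction_spec(target, mode, sev))
    find_compensated_tbv(h, healthy_circulation(disease = TRUE))
  })
}

# small loading sweeps used for the EDPVR-steepening checks; the fraction
# range stays below the pericardium-dominated regime
loading_sweep_case <- function(key, fractions = c(0.9, 1, 1.1, 1.2, 1.3)) {
  fixture(paste0("sweep_", key), {
    if (key == "H") {
      volume_loading_sweep(healthy_calibration()$heart,
                           healthy_circulation(), fractions = fractions)
    } else {
      parts <- strsplit(key, "-")[[1]]
      target <- substr(parts[1], 1, 2)
      mode <- if (substr(parts[1], 3, 4) == "SD") "systolic" else "diastolic"
      sev <- if (parts[2] == "M") "moderate" else "severe"
      h <- apply_dysfunction(healthy_calibration()$heart,
                             dysfunction_spec(target, mode, sev))
      volume_loading_sweep(h, healthy_circulation(disease = TRUE),
                           fractions = fractions)
    }
  })
}

# slope of the LV end-diastolic locus over its rising-EDV prefix (before
# the pericardial constraint pins and then reverses the end-diastolic
# volume); steeper means apparent or intrinsic diastolic stiffening
edpvr_rising_slope <- function(sweep) {
  lv <- sweep[sweep$ventricle == "LV", ]
  lv <- lv[order(lv$tbv_fraction), ]
  n <- which(diff(lv$EDV) <= 0)[1]
  if (!is.na(n)) lv <- lv[seq_len(n), ]
  if (nrow(lv) < 2) return(NA_real_)
  stats::coef(stats::lm(EDP ~ EDV, data = lv))[["EDV"]]
}
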