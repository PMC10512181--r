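#' Unit conversion between mmHg and kPa
#'
#' Pressures and stresses are carried in mmHg on the hemodynamic side and kPa
#' on the myocardial side; this is the single conversion constant used
#' everywhere in the package (1 mmHg = 0.133322 kPa).
#' @format Length-one numeric.
#' @export
kPa_per_mmHg <- 0.133322

#' Energy of one mmHg * mL of pressure-volume work, in joules
#' @format Length-one numeric.
#' @export
joule_per_mmHg_mL <- 1.33322e-4

#' Subject-level hemodynamic measurements
#'
#' Bundles the normative scalar measurements that parameterize the model for
#' one subject: arterial pressures, ventricular end-systolic/end-diastolic
#' pressures and volumes, total blood volume, and heart rate.  Derived
#' defaults follow the normative conventions: LV end-systolic pressure is
#' 1.05 x systolic arterial pressure (the circulation carries no pulse-wave
#' propagation), and RV end-diastolic pressure is one quarter of the LV value.
#'
#' @param SBP Mean systolic arterial blood pressure (mmHg).
#' @param DBP Mean diastolic arterial blood pressure (mmHg).
#' @param EDP_LV LV end-diastolic pressure (mmHg).
#' @param ESV_LV,EDV_LV LV end-systolic / end-diastolic volumes (mL).
#' @param ESP_RV RV end-systolic pressure (mmHg).
#' @param ESV_RV,EDV_RV RV end-systolic / end-diastolic volumes (mL).
#' @param TBV Total blood volume (mL).
#' @param HR Heart rate (beats per minute).
#' @param ESP_LV LV end-systolic pressure (mmHg); default 1.05 * SBP.
#' @param EDP_RV RV end-diastolic pressure (mmHg); default EDP_LV / 4.
#' @return An object of class `subject_data` (a named list).
#' @examples
#' s <- subject_data()        # normative healthy 70-kg adult
#' s$ESP_LV                   # 126 mmHg
#' @export
subject_data <- function(SBP = 120, DBP = 80, EDP_LV = 5,
                         ESV_LV = 50, EDV_LV = 125,
                         ESP_RV = 25, ESV_RV = ESV_LV, EDV_RV = 125,
                         TBV = 5000, HR = 60,
                         ESP_LV = 1.05 * SBP, EDP_RV = EDP_LV / 4) {
  s <- list(SBP = SBP, DBP = DBP,
            ESP_LV = ESP_LV, EDP_LV = EDP_LV,
            ESP_RV = ESP_RV, EDP_RV = EDP_RV,
            ESV_LV = ESV_LV, EDV_LV = EDV_LV,
            ESV_RV = ESV_RV, EDV_RV = EDV_RV,
            TBV = TBV, HR = HR)
  vals <- unlist(s)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all subject measurements must be positive and finite")
  if (EDV_LV <= ESV_LV || EDV_RV <= ESV_RV)
    stop("end-diastolic volume must exceed end-systolic volume")
  if (SBP <= DBP)
    stop("systolic pressure must exceed diastolic pressure")
  class(s) <- "subject_data"
  s
}

#' @export
print.subject_data <- function(x, ...) {
  cat("Subject hemodynamics:\n")
  cat(sprintf("  arterial %g/%g mmHg, HR %g bpm, TBV %g mL\n",
              x$SBP, x$DBP, x$HR, x$TBV))
  cat(sprintf("  LV: ESP %g, EDP %g mmHg; ESV %g, EDV %g mL\n",
              x$ESP_LV, x$EDP_LV, x$ESV_LV, x$EDV_LV))
  cat(sprintf("  RV: ESP %g, EDP %g mmHg; ESV %g, EDV %g mL\n",
              x$ESP_RV, x$EDP_RV, x$ESV_RV, x$EDV_RV))
  invisible(x)
}
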