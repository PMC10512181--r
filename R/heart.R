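#' Assemble a TriSeg heart model
#'
#' Combines the reference geometry, sarcomere parameters, per-wall passive
#' and active scaling factors, and the pericardial constraint into one model
#' object understood by the wall solver, the calibration routines, and the
#' circulation integrator.
#'
#' @param geometry A [build_reference_geometry()] object.
#' @param sarc A [sarcomere_params()] object.
#' @param k_pas,k_act Length-3 vectors of passive/active stress scaling
#'   factors for (LW, SW, RW); usually set by [calibrate_heart()].
#' @param pericardium_s Pericardial shape parameter (dimensionless).
#' @param pericardium_Vh0 Pericardial reference volume (mL); defaults to
#'   1.25 x (EDV_LV + EDV_RV), i.e. 25% above the total end-diastolic chamber
#'   volume, so the constraint engages outside normal working volumes.
#'   Atria are folded into the venous compartments and do not contribute.
#' @param use_pericardium Logical; `FALSE` for ex vivo (isolated heart) use.
#' @return Object of class `triseg_heart`.
#' @export
triseg_heart <- function(geometry, sarc = sarcomere_params(),
                         k_pas = c(1, 1, 1), k_act = c(1, 1, 1),
                         pericardium_s = 10,
                         pericardium_Vh0 = 1.25 * (geometry$EDV_LV +
                                                     geometry$EDV_RV),
                         use_pericardium = TRUE) {
  stopifnot(length(k_pas) == 3, length(k_act) == 3,
            all(k_pas >= 0), all(k_act >= 0),
            pericardium_s > 0, pericardium_Vh0 > 0)
  h <- list(geometry = geometry, sarc = sarc,
            k_pas = stats::setNames(as.numeric(k_pas), c("LW", "SW", "RW")),
            k_act = stats::setNames(as.numeric(k_act), c("LW", "SW", "RW")),
            pericardium = list(s = pericardium_s, Vh0 = pericardium_Vh0),
            use_pericardium = use_pericardium)
  class(h) <- "triseg_heart"
  h
}

# flat list representation consumed by the C++ core
heart_as_list <- function(heart) {
  list(Vw = unname(heart$geometry$Vw),
       Am_ref = unname(heart$geometry$Am_ref),
       kpas = unname(heart$k_pas), kact = unname(heart$k_act),
       L_ref = heart$sarc$L_ref, L_c0 = heart$sarc$L_c0,
       L_se_iso = heart$sarc$L_se_iso, v_max = heart$sarc$v_max,
       gamma = heart$sarc$gamma,
       peri_s = heart$pericardium$s, peri_Vh0 = heart$pericardium$Vh0,
       use_pericardium = isTRUE(heart$use_pericardium))
}

#' @export
print.triseg_heart <- function(x, ...) {
  cat("TriSeg biventricular heart model\n")
  print(x$geometry)
  cat(sprintf("  gamma %.3g; k_pas %s; k_act %s\n", x$sarc$gamma,
              paste(signif(x$k_pas, 4), collapse = "/"),
              paste(signif(x$k_act, 4), collapse = "/")))
  cat(sprintf("  pericardium: s %g, Vh0 %.0f mL (%s)\n",
              x$pericardium$s, x$pericardium$Vh0,
              if (isTRUE(x$use_pericardium)) "active" else "disabled"))
  invisible(x)
}

#' Modify wall scaling factors of a heart model
#'
#' @param heart A [triseg_heart()] object.
#' @param k_pas,k_act Optional length-3 replacement vectors (LW, SW, RW).
#' @param use_pericardium Optional logical.
#' @return The modified `triseg_heart`.
#' @export
set_wall_properties <- function(heart, k_pas = NULL, k_act = NULL,
                                use_pericardium = NULL) {
  if (!is.null(k_pas)) heart$k_pas[] <- k_pas
  if (!is.null(k_act)) heart$k_act[] <- k_act
  if (!is.null(use_pericardium)) heart$use_pericardium <- use_pericardium
  heart
}
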