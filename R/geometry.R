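#' Inner radius of a spherical chamber
#'
#' @param V Chamber volume (mL).
#' @return Radius (cm) of the sphere enclosing `V`.
#' @examples
#' inner_radius(4 / 3 * pi)  # 1 cm
#' @export
inner_radius <- function(V) {
  if (any(!is.finite(V)) || any(V <= 0))
    stop("chamber volume must be positive")
  (3 * V / (4 * pi))^(1 / 3)
}

#' Spherical-segment reference geometry of the three walls
#'
#' Builds the midwall reference areas and wall volumes of the LV free wall
#' (LW), septum (SW), and RV free wall (RW) from end-diastolic volumes and
#' wall thicknesses.  The LV (LW + SW) is treated as a thick-walled sphere
#' enclosing `EDV_LV`; its wall volume and midwall area are split 2/3 (LW) :
#' 1/3 (SW).  The RW is built from its own sphere enclosing `EDV_RV`.  The
#' midwall is the surface radially halfway through the wall, so the midwall
#' radius is the inner radius plus half the thickness.
#'
#' @param EDV_LV,EDV_RV End-diastolic volumes (mL).
#' @param h_LV LW/septal wall thickness (cm); default 0.8 (8 mm).
#' @param h_RW RV free wall thickness (cm); default 0.4 (4 mm).
#' @return An object of class `triseg_geometry`: named per-wall vectors
#'   `Vw` (wall volumes, mL) and `Am_ref` (midwall reference areas, cm^2),
#'   plus the intermediate radii.
#' @examples
#' g <- build_reference_geometry(125, 125)
#' g$Vw["LW"] / g$Vw["SW"]   # 2
#' @export
build_reference_geometry <- function(EDV_LV, EDV_RV, h_LV = 0.8, h_RW = 0.4) {
  if (EDV_LV <= 0 || EDV_RV <= 0 || h_LV <= 0 || h_RW <= 0)
    stop("volumes and thicknesses must be positive")
  ri_LV <- inner_radius(EDV_LV)
  ri_RW <- inner_radius(EDV_RV)
  if (h_LV >= ri_LV || h_RW >= ri_RW)
    stop("wall thickness must be smaller than the inner chamber radius")
  rm_LV <- ri_LV + h_LV / 2
  rm_RW <- ri_RW + h_RW / 2
  ro_LV <- ri_LV + h_LV
  ro_RW <- ri_RW + h_RW
  Am_LV <- 4 * pi * rm_LV^2
  Am_RW <- 4 * pi * rm_RW^2
  Vw_LV <- 4 / 3 * pi * ro_LV^3 - EDV_LV
  Vw_RW <- 4 / 3 * pi * ro_RW^3 - EDV_RV
  g <- list(
    Vw = c(LW = 2 / 3 * Vw_LV, SW = 1 / 3 * Vw_LV, RW = Vw_RW),
    Am_ref = c(LW = 2 / 3 * Am_LV, SW = 1 / 3 * Am_LV, RW = Am_RW),
    h = c(LW = h_LV, SW = h_LV, RW = h_RW),
    ri = c(LV = ri_LV, RW = ri_RW),
    rm = c(LV = rm_LV, RW = rm_RW),
    ro = c(LV = ro_LV, RW = ro_RW),
    Vw_LV = Vw_LV, Am_ref_LV = Am_LV,
    EDV_LV = EDV_LV, EDV_RV = EDV_RV)
  class(g) <- "triseg_geometry"
  g
}

#' @export
print.triseg_geometry <- function(x, ...) {
  cat("TriSeg reference geometry (from EDVs):\n")
  cat(sprintf("  wall volumes   LW %.1f  SW %.1f  RW %.1f mL\n",
              x$Vw["LW"], x$Vw["SW"], x$Vw["RW"]))
  cat(sprintf("  midwall areas  LW %.1f  SW %.1f  RW %.1f cm^2\n",
              x$Am_ref["LW"], x$Am_ref["SW"], x$Am_ref["RW"]))
  invisible(x)
}
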