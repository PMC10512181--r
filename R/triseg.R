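# Wall kinematics, tensions, and the instantaneous TriSeg configuration.
#
# Sign convention: the x axis points from the LV free wall toward the RV free
# wall.  xm_LW < 0 (bulging left), xm_RW > 0 (bulging right), xm_SW of either
# sign with Cm_SW > 0 meaning the septum bows into the RV.  ym > 0 is the
# radius of the junction circle where the three walls meet.
#
# The R functions here are direct formula implementations used for oracles
# and user-level inspection; the Newton solver and ODE right-hand side run
# the same formulas compiled in src/triseg.cpp.

#' Spherical-cap midwall geometry
#'
#' Midwall area, curvature, and enclosed (signed) cap volume of a wall
#' attached to a junction circle of radius `ym` with axial midwall
#' displacement `xm`.
#'
#' @param xm Axial midwall displacement (cm), signed.
#' @param ym Junction radius (cm), positive.
#' @return List with `Am` (cm^2), `Cm` (1/cm), `Vm` (mL, signed).
#' @examples
#' cap_geometry(1, 1)$Cm  # hemisphere of radius 1: curvature 1
#' @export
cap_geometry <- function(xm, ym) {
  if (any(ym <= 0)) stop("junction radius ym must be positive")
  d <- xm^2 + ym^2
  list(Am = pi * d,
       Cm = 2 * xm / d,
       Vm = (pi / 6) * xm * (xm^2 + 3 * ym^2))
}

#' Wall strain, curvature ratio, and sarcomere length
#'
#' The curvature-thickness ratio is `z = 3 Cm Vw / (2 Am)`; the natural
#' myofiber strain follows the small-curvature expansion
#' `eps_f = ln(Am/Am_ref)/2 - z^2/12 - 0.019 z^4`, and the sarcomere length
#' is `Ls = L_ref exp(eps_f)`.
#'
#' @param Am Midwall area (cm^2).
#' @param Cm Midwall curvature (1/cm).
#' @param Vw Wall volume (mL).
#' @param Am_ref Midwall reference area (cm^2).
#' @param L_ref Reference sarcomere length (um).
#' @return List with `z`, `eps_f`, and `Ls` (um).
#' @export
wall_strain_and_length <- function(Am, Cm, Vw, Am_ref, L_ref = 2) {
  if (any(Am_ref <= 0)) stop("Am_ref must be positive")
  z <- 3 * Cm * Vw / (2 * Am)
  eps_f <- 0.5 * log(Am / Am_ref) - z^2 / 12 - 0.019 * z^4
  list(z = z, eps_f = eps_f, Ls = L_ref * exp(eps_f))
}

#' Midwall tension and its junction components
#'
#' Representative midwall tension `Tm = (sigma Vw / (2 Am)) (1 + z^2/3 +
#' z^4/5)` and its axial/radial components at the junction circle,
#' `Tx = Tm sin(alpha)`, `Ty = Tm cos(alpha)` with `sin(alpha) =
#' 2 xm ym / (xm^2 + ym^2)`.
#'
#' @param sigma Total myofiber stress (kPa).
#' @param Vw Wall volume (mL).
#' @param Am Midwall area (cm^2).
#' @param z Curvature-thickness ratio.
#' @param xm,ym Midwall displacements (cm).
#' @return List with `Tm`, `Tx`, `Ty` (kPa cm).
#' @export
wall_tension <- function(sigma, Vw, Am, z, xm, ym) {
  if (any(Am <= 0)) stop("Am must be positive")
  Tm <- sigma * Vw / (2 * Am) * (1 + z^2 / 3 + z^4 / 5)
  d <- xm^2 + ym^2
  list(Tm = Tm, Tx = Tm * 2 * xm * ym / d, Ty = Tm * (ym^2 - xm^2) / d)
}

#' Junction residuals of a trial wall configuration
#'
#' The four equilibrium conditions of the instantaneous TriSeg problem: the
#' axial and radial tension sums at the shared junction, and the consistency
#' of the two chamber volumes with the midwall cap volumes (the midwall
#' surfaces bisect the wall volumes).  All four vanish at mechanical
#' equilibrium.
#'
#' @param u Numeric length 4: `(xm_LW, xm_SW, xm_RW, ym)`.
#' @param V_LV,V_RV Chamber volumes (mL).
#' @param Lc Length-3 contractile element lengths (um) for (LW, SW, RW).
#' @param Y Activation fraction.
#' @param heart A [triseg_heart()] object.
#' @return Named numeric length 4: `Tx`, `Ty` (kPa cm) and `V_LV`, `V_RV`
#'   (mL) residuals.
#' @export
junction_residual <- function(u, V_LV, V_RV, Lc, Y, heart) {
  ts_residual_cpp(as.numeric(u), V_LV, V_RV, as.numeric(Lc), Y,
                  heart_as_list(heart))
}

#' Solve the instantaneous wall configuration
#'
#' Newton iteration on the four displacement unknowns `(xm_LW, xm_SW,
#' xm_RW, ym)` driving [junction_residual()] to zero at the given chamber
#' volumes, contractile lengths, and activation.  Warm-start from a previous
#' solution when available; otherwise a volume-consistent geometric guess is
#' constructed internally.
#'
#' @inheritParams junction_residual
#' @param guess Optional numeric length 4 initial guess.
#' @param quasi_static_Lc If `TRUE`, replace `Lc` by its isometric
#'   steady-state value `Ls - L_se_iso` (used by the end-systolic
#'   calibration); `Lc` is then ignored.
#' @param tol Relative residual tolerance of the Newton solve.
#' @param maxit Maximum Newton iterations.
#' @return A wall configuration: displacements, per-wall `Am`, `Cm`, `Vm`,
#'   `z`, `Ls`, stresses and tensions, transmural and total chamber
#'   pressures (mmHg), and pericardial pressure.
#' @export
solve_wall_configuration <- function(V_LV, V_RV, Lc = NULL, Y = 0, heart,
                                     guess = NULL, quasi_static_Lc = is.null(Lc),
                                     tol = 1e-9, maxit = 50) {
  hl <- heart_as_list(heart)
  if (is.null(guess)) guess <- ts_guess_cpp(V_LV, V_RV, hl)
  if (is.null(Lc)) Lc <- rep(heart$sarc$L_ref - heart$sarc$L_se_iso, 3)
  cfg <- ts_solve_cpp(V_LV, V_RV, as.numeric(Lc), Y, hl, as.numeric(guess),
                      lc_mode = if (quasi_static_Lc) 1L else 0L,
                      tol = tol, maxit = maxit)
  if (!isTRUE(cfg$converged))
    stop(sprintf("TriSeg wall solve did not converge (residual %.3g)",
                 cfg$residual_norm))
  cfg
}

#' Chamber pressures of a solved configuration
#'
#' Transmural pressures follow from the axial tension balance over each free
#' wall cap (`P = -2 Tx_LW / ym` for the LV, `+2 Tx_RW / ym` for the RV,
#' converted from kPa to mmHg); the pericardial pressure is added to both
#' chambers.
#'
#' @param config A configuration from [solve_wall_configuration()].
#' @return Named numeric: `P_LV`, `P_RV` (mmHg).
#' @export
chamber_pressures <- function(config) {
  c(P_LV = config$P_LV, P_RV = config$P_RV)
}

#' Pericardial pressure
#'
#' `P_peri = exp(s (Vh/Vh0 - 1)) - 1` (mmHg) with `Vh = V_LV + V_RV`; zero
#' at the reference heart volume, bounded below by -1 mmHg, and rising
#' steeply outside normal working volumes.
#'
#' @param V_LV,V_RV Chamber volumes (mL).
#' @param s Shape parameter.
#' @param Vh0 Reference heart volume (mL).
#' @return Pressure (mmHg).
#' @examples
#' pericardial_pressure(150, 150, 10, 300)  # 0 at the reference volume
#' @export
pericardial_pressure <- function(V_LV, V_RV, s = 10, Vh0) {
  if (any(V_LV <= 0) || any(V_RV <= 0)) stop("volumes must be positive")
  exp(s * ((V_LV + V_RV) / Vh0 - 1)) - 1
}
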