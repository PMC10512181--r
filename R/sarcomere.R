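#' Sarcomere-level material parameters
#'
#' Parameters of the myofiber stress laws shared by the three walls.  Lengths
#' are in micrometres; `nu_L` is the 1/um unit-conversion factor in the
#' passive and active laws, so the stress scale is carried entirely by the
#' wall scaling factors `k_pas` and `k_act`.
#'
#' @param L_ref Reference sarcomere length (um), i.e. length at zero strain.
#' @param L_c0 Contractile element length at zero active stress (um).
#' @param L_se_iso Length of the isometrically stressed series elastic
#'   element (um).
#' @param v_max Sarcomere shortening velocity (um/s).
#' @param gamma Steepness of the passive length-tension relationship
#'   (dimensionless); calibrated against Klotz curves by [fit_gamma()].
#' @param nu_L Unit conversion factor (1/um).
#' @return Object of class `sarcomere_params`.
#' @export
sarcomere_params <- function(L_ref = 2, L_c0 = 1.51, L_se_iso = 0.04,
                             v_max = 3.5, gamma = 7.5, nu_L = 1) {
  p <- list(L_ref = L_ref, L_c0 = L_c0, L_se_iso = L_se_iso,
            v_max = v_max, gamma = gamma, nu_L = nu_L)
  if (any(unlist(p) <= 0)) stop("sarcomere parameters must be positive")
  if (L_c0 >= L_ref) stop("slack length L_c0 must be below L_ref")
  class(p) <- "sarcomere_params"
  p
}

#' Activation timing parameters
#'
#' The activation waveform rises over `T_S = k_TS * T` (time to maximal
#' systolic elastance) and falls over `T_R = k_TR * T` (end of isovolumic
#' relaxation), where `T = 60/HR` is the cycle period.
#'
#' @param HR Heart rate (beats per minute).
#' @param k_TS,k_TR Cycle fractions for the rise and fall (dimensionless).
#' @return Object of class `activation_params` with `T`, `T_S`, `T_R`.
#' @export
activation_params <- function(HR = 60, k_TS = 0.2, k_TR = 0.2) {
  if (HR <= 0) stop("heart rate must be positive")
  if (k_TS + k_TR >= 1) stop("k_TS + k_TR must be below 1")
  Tcyc <- 60 / HR
  p <- list(HR = HR, k_TS = k_TS, k_TR = k_TR,
            T = Tcyc, T_S = k_TS * Tcyc, T_R = k_TR * Tcyc)
  class(p) <- "activation_params"
  p
}

#' Mechanical activation waveform
#'
#' Sinusoidal driving function for myocyte contraction: a rising half-cosine
#' from 0 to 1 on `[0, T_S]`, a falling half-cosine on `[T_S, T_S + T_R]`,
#' and zero for the remainder of the cycle.  Time is reduced modulo the cycle
#' period, with beat onset at t = 0 for all three walls.
#'
#' @param t Time (s), any length.
#' @param params An [activation_params()] object.
#' @return Activation fraction in `[0, 1]`, same length as `t`.
#' @examples
#' ap <- activation_params(HR = 60)
#' activation(ap$T_S, ap)  # 1 at maximal systolic elastance
#' @export
activation <- function(t, params) {
  ts_activation_cpp(as.numeric(t), params$T_S, params$T_R, params$T)
}

#' Passive myofiber stress
#'
#' Exponential-type passive law `(nu_L * (L - L_c0))^gamma`, clamped to zero
#' below the slack length (tension cannot be negative).
#'
#' @param L Sarcomere length (um).
#' @param params A [sarcomere_params()] object.
#' @return Unscaled passive stress (kPa before `k_pas` scaling).
#' @export
passive_stress <- function(L, params) {
  dl <- pmax(params$nu_L * (L - params$L_c0), 0)
  dl^params$gamma
}

#' Active myofiber stress
#'
#' `nu_L * (Lc - L_c0) * ((L - Lc)/L_se_iso) * Y`: the contractile element
#' extension times the strain of the isometrically stressed series elastic
#' element, gated by the activation fraction `Y`.
#'
#' @param L Sarcomere length (um).
#' @param Lc Contractile element length (um).
#' @param Y Activation fraction in `[0, 1]`.
#' @param params A [sarcomere_params()] object.
#' @return Unscaled active stress (kPa before `k_act` scaling).
#' @export
active_stress <- function(L, Lc, Y, params) {
  params$nu_L * pmax(Lc - params$L_c0, 0) * ((L - Lc) / params$L_se_iso) * Y
}

#' Rate of change of the contractile element length
#'
#' `dLc/dt = ((L - Lc)/L_se_iso - 1) * v_max`: the contractile element
#' shortens at `v_max` when the series element is unstretched and is in
#' equilibrium when the series element carries its isometric extension.
#'
#' @inheritParams active_stress
#' @return Rate (um/s).
#' @export
contractile_length_rate <- function(L, Lc, params) {
  ((L - Lc) / params$L_se_iso - 1) * params$v_max
}

#' Total scaled wall stress
#'
#' `sigma = k_pas * sigma_pas + k_act * sigma_act` for one wall.
#'
#' @inheritParams active_stress
#' @param k_pas,k_act Passive and active scaling factors for the wall.
#' @return Total myofiber stress (kPa).
#' @export
total_wall_stress <- function(L, Lc, Y, k_pas, k_act, params) {
  k_pas * passive_stress(L, params) + k_act * active_stress(L, Lc, Y, params)
}
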