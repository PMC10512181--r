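# Six-compartment closed-loop circulation: LV -> systemic arteries (SA) ->
# systemic veins (SV) -> RV -> pulmonary arteries (PA) -> pulmonary veins
# (PV) -> LV, with ideal-diode valves and viscoelastic arterial resistances.
# Atria are folded into the venous compartments.

#' Compartment volume fractions and pressure landmarks
#'
#' Reference table of total-blood-volume fractions, unstressed-volume
#' fractions (healthy and disease columns), and maximal/mean/minimal
#' compartment pressures used to derive compliances and resistances.
#' The disease column raises the stressed:unstressed ratio in the vascular
#' compartments to 30%/20%/65%/25% stressed (SA/SV/PA/PV), emulating the
#' venoconstrictive redistribution accompanying heart failure.
#'
#' @return A data.frame with one row per compartment.
#' @export
compartment_fractions <- function() {
  data.frame(
    compartment = c("LV", "SA", "SV", "RV", "PA", "PV"),
    tbv_frac    = c(0.03, 0.20, 0.54, 0.03, 0.05, 0.15),
    vu_healthy  = c(NA, 0.70, 0.90, NA, 0.40, 0.90),
    vu_disease  = c(NA, 0.60, 0.80, NA, 0.35, 0.75),
    P_max       = c(121, 120, 6, 26, 25, 8),
    P_mean      = c(NA, 95, 4, NA, 15, 5),
    P_min       = c(4, 80, 4, 4, 10, 2),
    stringsAsFactors = FALSE)
}

#' Derive circulation parameters from subject data
#'
#' Compartment volumes are fractions of total blood volume; unstressed
#' volumes are fractions of the compartment volume (healthy or disease
#' column); compliances are maximal stressed volume over maximal pressure;
#' systemic and pulmonary resistances are the mean pressure drops over the
#' cardiac output `CO = SV x HR`.  Compliances always use the healthy
#' unstressed column, so the disease switch changes only the stressed
#' volume distribution, not the vessel wall properties.  Ventricular rows
#' seed initial conditions only; ventricular pressures come from the TriSeg
#' walls.
#'
#' @param subject A [subject_data()] object.
#' @param fractions A table in the format of [compartment_fractions()].
#' @param disease If `TRUE`, use the disease unstressed-volume column.
#' @param Rt_SA,Rt_PA Systemic/pulmonary arterial viscoelastic resistance
#'   components (mmHg s/mL).
#' @param R_mv,R_tv Mitral/tricuspid valve resistances (mmHg s/mL).
#' @return Object of class `circulation_params`.
#' @examples
#' cp <- derive_circulation_parameters(subject_data())
#' cp$C_SA  # 2.5 mL/mmHg
#' @export
derive_circulation_parameters <- function(subject,
                                          fractions = compartment_fractions(),
                                          disease = FALSE,
                                          Rt_SA = 0.08, Rt_PA = 0.02,
                                          R_mv = 5e-4, R_tv = 5e-4) {
  f <- fractions
  if (abs(sum(f$tbv_frac) - 1) > 1e-8)
    stop("compartment TBV fractions must sum to 1")
  rownames(f) <- f$compartment
  TBV <- subject$TBV
  vol <- f$tbv_frac * TBV
  names(vol) <- f$compartment
  vu_col <- if (disease) f$vu_disease else f$vu_healthy
  names(vu_col) <- f$compartment
  Vu <- vu_col * vol
  # compliances from the healthy stressed fraction and maximal pressure
  C <- (1 - f$vu_healthy) * vol / f$P_max
  names(C) <- f$compartment
  SV <- subject$EDV_LV - subject$ESV_LV
  CO <- SV * subject$HR / 60   # mL/s
  R_sys <- (f["SA", "P_mean"] - f["SV", "P_mean"]) / CO
  R_pul <- (f["PA", "P_mean"] - f["PV", "P_mean"]) / CO
  p <- list(C_SA = C[["SA"]], C_SV = C[["SV"]], C_PA = C[["PA"]],
            C_PV = C[["PV"]],
            Vu_SA = Vu[["SA"]], Vu_SV = Vu[["SV"]], Vu_PA = Vu[["PA"]],
            Vu_PV = Vu[["PV"]],
            R_sys = R_sys, R_pul = R_pul,
            Rt_SA = Rt_SA, Rt_PA = Rt_PA, R_mv = R_mv, R_tv = R_tv,
            TBV = TBV, init_frac = stats::setNames(f$tbv_frac,
                                                   f$compartment),
            disease = disease)
  class(p) <- "circulation_params"
  p
}

#' Ideal-diode valve flow
#'
#' Forward flow only: `q = max(P_up - P_down, 0) / R`.
#'
#' @param P_up,P_down Upstream/downstream pressures (mmHg).
#' @param R Valve resistance (mmHg s/mL).
#' @return Flow (mL/s).
#' @export
valve_flow <- function(P_up, P_down, R) {
  if (any(R <= 0)) stop("valve resistance must be positive")
  pmax(P_up - P_down, 0) / R
}

#' Vascular compartment pressure
#'
#' Elastic pressure `(V - Vu)/C` plus, for arterial compartments, the
#' viscoelastic component `Rt * q_net` proportional to the net volume inflow
#' rate.  Venous compartments are purely elastic (`Rt = 0`).
#'
#' @param V Compartment volume (mL).
#' @param Vu Unstressed volume (mL).
#' @param C Compliance (mL/mmHg).
#' @param q_net Net inflow rate (mL/s).
#' @param Rt Viscoelastic resistance (mmHg s/mL).
#' @return Pressure (mmHg).
#' @export
compartment_pressure <- function(V, Vu, C, q_net = 0, Rt = 0) {
  if (any(C <= 0)) stop("compliance must be positive")
  (V - Vu) / C + Rt * q_net
}

# activation timing attached to the circulation list for the C++ RHS
circ_as_list <- function(circ, act) {
  c(unclass(circ)[c("C_SA", "C_SV", "C_PA", "C_PV",
                    "Vu_SA", "Vu_SV", "Vu_PA", "Vu_PV",
                    "R_sys", "R_pul", "Rt_SA", "Rt_PA", "R_mv", "R_tv")],
    list(T = act$T, T_S = act$T_S, T_R = act$T_R))
}

#' Full-system time derivative
#'
#' Right-hand side of the nine-state ODE system (six compartment volumes and
#' three contractile lengths).  Solves the TriSeg wall configuration at the
#' current state, evaluates all pressures and flows, and returns the
#' derivative together with the auxiliary records (pressures, flows, septal
#' curvature, displacements).  Exposed mainly for testing and inspection;
#' [simulate_heart()] integrates it.
#'
#' @param t Time (s).
#' @param state Named or ordered numeric of length 9:
#'   `V_LV, V_SA, V_SV, V_RV, V_PA, V_PV, Lc_LW, Lc_SW, Lc_RW`.
#' @param heart A [triseg_heart()] object.
#' @param circ A [derive_circulation_parameters()] object.
#' @param act An [activation_params()] object.
#' @param guess Optional warm-start displacement guess.
#' @return List: `dstate` (length 9), `aux` (named numeric), `u` (solution
#'   displacements).
#' @export
system_rhs <- function(t, state, heart, circ, act, guess = NULL) {
  hl <- heart_as_list(heart)
  if (is.null(guess)) guess <- ts_guess_cpp(state[1], state[4], hl)
  out <- ts_rhs_cpp(t, as.numeric(state), hl, circ_as_list(circ, act),
                    as.numeric(guess))
  names(out) <- c("dstate", "aux", "u")
  out
}

#' Simulate the closed-loop model to periodic steady state
#'
#' Integrates the stiff nine-state system with `deSolve::lsoda` for
#' `n_transient` beats to wash out transients, then `n_record` further beats
#' recorded at dense output for metric extraction.  Initial compartment
#' volumes distribute the circulating volume by the reference fractions;
#' initial contractile lengths come from a passive static solve.
#'
#' @param heart A [triseg_heart()] object.
#' @param circ A [derive_circulation_parameters()] object.
#' @param tbv Circulating total blood volume for this run (mL); defaults to
#'   the parameterization TBV.  Unstressed volumes stay fixed, so volume
#'   loading raises stressed volumes and pressures.
#' @param hr Heart rate (bpm).
#' @param n_transient,n_record Number of transient and recorded beats.
#' @param samples_per_beat Dense-output samples per beat (recorded window).
#' @param rtol,atol Integrator tolerances.
#' @return Object of class `triseg_sim`: `series` (data.frame of the
#'   recorded window), `full` (all beats, coarser), periodicity and volume
#'   conservation diagnostics, and the run parameters.
#' @export
simulate_heart <- function(heart, circ, tbv = circ$TBV, hr = 60,
                           n_transient = 20, n_record = 2,
                           samples_per_beat = 500,
                           rtol = 1e-6, atol = 1e-8) {
  act <- activation_params(HR = hr)
  hl <- heart_as_list(heart)
  cl <- circ_as_list(circ, act)

  v0 <- circ$init_frac * tbv
  # passive static solve for initial contractile lengths and displacements
  cfg0 <- solve_wall_configuration(v0[["LV"]], v0[["RV"]], Y = 0,
                                   heart = heart, quasi_static_Lc = TRUE)
  y0 <- c(V_LV = v0[["LV"]], V_SA = v0[["SA"]], V_SV = v0[["SV"]],
          V_RV = v0[["RV"]], V_PA = v0[["PA"]], V_PV = v0[["PV"]],
          Lc_LW = cfg0$Ls[["LW"]] - heart$sarc$L_se_iso,
          Lc_SW = cfg0$Ls[["SW"]] - heart$sarc$L_se_iso,
          Lc_RW = cfg0$Ls[["RW"]] - heart$sarc$L_se_iso)

  wenv <- new.env(parent = emptyenv())
  wenv$u <- cfg0$u
  rhs <- function(t, y, p) {
    out <- ts_rhs_cpp(t, y, hl, cl, wenv$u)
    wenv$u <- out[["u"]]
    list(out[["dy"]], out[["aux"]])
  }

  t_end <- (n_transient + n_record) * act$T
  t_rec <- n_transient * act$T
  dt <- act$T / samples_per_beat
  times <- c(seq(0, t_rec - dt, by = act$T / 50),
             seq(t_rec, t_end, by = dt))
  sol <- deSolve::lsoda(y0, times, rhs, parms = NULL,
                        rtol = rtol, atol = atol, maxsteps = 50000)
  sol <- as.data.frame(sol)
  names(sol)[1] <- "t"

  vol_cols <- c("V_LV", "V_SA", "V_SV", "V_RV", "V_PA", "V_PV")
  tot <- rowSums(sol[, vol_cols])
  vol_err <- max(abs(tot - tbv)) / tbv

  rec <- sol[sol$t >= t_rec - 1e-9, ]
  # beat-to-beat periodicity: EDV of the two recorded beats
  edv <- vapply(seq_len(n_record), function(b) {
    w <- rec$t >= t_rec + (b - 1) * act$T - 1e-9 &
         rec$t <= t_rec + b * act$T + 1e-9
    max(rec$V_LV[w])
  }, numeric(1))
  periodicity <- if (n_record >= 2)
    abs(edv[n_record] - edv[n_record - 1]) / edv[n_record - 1] else NA_real_
  if (is.finite(periodicity) && periodicity > 1e-3)
    warning(sprintf("beat-to-beat EDV change %.2g%% after transient",
                    100 * periodicity))

  res <- list(series = rec, full = sol,
              t_record = t_rec, T = act$T, hr = hr, tbv = tbv,
              n_transient = n_transient, n_record = n_record,
              vol_conservation = vol_err, periodicity = periodicity,
              heart = heart, circ = circ, activation = act)
  class(res) <- "triseg_sim"
  res
}

#' @export
print.triseg_sim <- function(x, ...) {
  cat(sprintf(
    "TriSeg closed-loop simulation: HR %g bpm, TBV %.0f mL, %d+%d beats\n",
    x$hr, x$tbv, x$n_transient, x$n_record))
  cat(sprintf("  volume conservation %.2g (relative), periodicity %.2g\n",
              x$vol_conservation, x$periodicity))
  m <- cardiac_metrics(x)
  print(m, row.names = FALSE)
  invisible(x)
}

#' Plot pressure-volume loops of a simulation
#'
#' @param x A `triseg_sim` object.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.triseg_sim <- function(x, ...) {
  s <- last_beat(x)
  graphics::plot(s$V_LV, s$P_LV, type = "l", col = "firebrick",
                 xlab = "Volume (mL)", ylab = "Pressure (mmHg)",
                 xlim = range(c(s$V_LV, s$V_RV)),
                 ylim = range(c(s$P_LV, s$P_RV)), ...)
  graphics::lines(s$V_RV, s$P_RV, col = "steelblue")
  graphics::legend("topleft", legend = c("LV", "RV"), bty = "n",
                   col = c("firebrick", "steelblue"), lty = 1)
  invisible(x)
}

#' Final full beat of the recorded window
#'
#' @param sim A [simulate_heart()] result.
#' @return Data.frame of the dense samples spanning the last beat.
#' @export
last_beat <- function(sim) {
  t1 <- max(sim$series$t)
  sim$series[sim$series$t >= t1 - sim$T - 1e-9, ]
}
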