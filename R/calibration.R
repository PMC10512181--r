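# Passive-stiffness calibration against the Klotz single-beat EDPVR, and the
# per-wall passive/active scaling-factor computation.

#' Klotz single-beat EDPVR
#'
#' Constructs the empirical end-diastolic pressure-volume relationship from a
#' single measured (EDP, EDV) pair.  Landmark volumes: `V0 = EDV (0.6 -
#' 0.006 EDP)` (volume near zero pressure) and `V30 = V0 + (EDV - V0) /
#' (EDP/An)^(1/Bn)` (volume at 30 mmHg), with the normalized-template
#' constants `An = 27.78` mmHg, `Bn = 2.76`.  The subject curve is the power
#' law `P = alpha V^beta` through (EDV, EDP) and (V30, 30 mmHg).
#'
#' @param EDP End-diastolic pressure (mmHg), below 30.
#' @param EDV End-diastolic volume (mL).
#' @return Object of class `klotz_curve` with `V0`, `V30`, `alpha`, `beta`,
#'   `An`, `Bn`.
#' @examples
#' kc <- klotz_curve(5, 125)
#' kc$V0                    # 71.25 mL
#' klotz_pressure(kc, 125)  # 5 mmHg by construction
#' @export
klotz_curve <- function(EDP, EDV) {
  if (EDP <= 0 || EDV <= 0) stop("EDP and EDV must be positive")
  if (EDP >= 30)
    warning("EDP at or above 30 mmHg: Klotz landmarks are extrapolated")
  An <- 27.78
  Bn <- 2.76
  V0 <- EDV * (0.6 - 0.006 * EDP)
  V30 <- V0 + (EDV - V0) / (EDP / An)^(1 / Bn)
  beta <- log(EDP / 30) / log(EDV / V30)
  alpha <- 30 / V30^beta
  kc <- list(EDP = EDP, EDV = EDV, V0 = V0, V30 = V30,
             alpha = alpha, beta = beta, An = An, Bn = Bn)
  class(kc) <- "klotz_curve"
  kc
}

#' Evaluate a Klotz curve
#'
#' @param curve A [klotz_curve()] object.
#' @param V Volumes (mL).
#' @return Pressures (mmHg).
#' @export
klotz_pressure <- function(curve, V) {
  curve$alpha * V^curve$beta
}

#' Normalize an EDPVR to Klotz coordinates
#'
#' Maps the volume axis to `Vn = (V - V0)/(V30 - V0)`, under which EDPVRs of
#' hearts of different size collapse onto the common template
#' `P = An Vn^Bn`.
#'
#' @param curve A data.frame with columns `V` and `P`.
#' @param klotz A [klotz_curve()] object supplying `V0` and `V30`.
#' @return The input with an added `Vn` column.
#' @export
normalize_edpvr <- function(curve, klotz) {
  if (klotz$V30 <= klotz$V0) stop("V30 must exceed V0")
  curve$Vn <- (curve$V - klotz$V0) / (klotz$V30 - klotz$V0)
  curve
}

#' Ex vivo passive inflation of the isolated heart
#'
#' Static EDPVR of the model heart with zero activation, no pericardium, and
#' both chambers inflated jointly (the RV volume tracks the LV volume by the
#' end-diastolic volume ratio).  Each point is a static TriSeg solve.
#'
#' @param heart A [triseg_heart()] object.
#' @param volumes LV volume grid (mL).
#' @param rv_ratio RV/LV volume ratio along the inflation (defaults to the
#'   geometry EDV ratio).
#' @return Data.frame with `V_LV`, `V_RV`, `P_LV`, `P_RV` (mmHg, transmural).
#' @export
ex_vivo_edpvr <- function(heart, volumes,
                          rv_ratio = heart$geometry$EDV_RV /
                            heart$geometry$EDV_LV) {
  heart$use_pericardium <- FALSE
  hl <- heart_as_list(heart)
  volumes <- sort(volumes)
  guess <- ts_guess_cpp(volumes[1], volumes[1] * rv_ratio, hl)
  out <- matrix(NA_real_, length(volumes), 4,
                dimnames = list(NULL, c("V_LV", "V_RV", "P_LV", "P_RV")))
  lc <- c(0, 0, 0)  # unused at Y = 0
  for (i in seq_along(volumes)) {
    v <- volumes[i]
    cfg <- ts_solve_cpp(v, v * rv_ratio, lc, 0, hl, guess, lc_mode = 1L)
    if (!isTRUE(cfg$converged))
      stop(sprintf("static inflation failed at V_LV = %g mL", v))
    guess <- cfg$u
    out[i, ] <- c(v, v * rv_ratio, cfg$P_LV, cfg$P_RV)
  }
  as.data.frame(out)
}

# Gamma_i: chamber-pressure-per-unit-fiber-stress factor (dimensionless,
# kPa/kPa) of wall i at a frozen configuration.  LW drives P_LV, RW drives
# P_RV, SW drives the septal transmural pressure P_LV - P_RV.
gamma_factor_walls <- function(cfg, heart) {
  xm <- cfg$xm; ym <- cfg$ym
  d <- xm^2 + ym^2
  sinA <- 2 * xm * ym / d
  shape <- 1 + cfg$z^2 / 3 + cfg$z^4 / 5
  w <- heart$geometry$Vw / (2 * cfg$Am) * shape
  c(LW = -2 * w[["LW"]] * sinA[["LW"]] / ym,
    SW =  2 * w[["SW"]] * sinA[["SW"]] / ym,
    RW =  2 * w[["RW"]] * sinA[["RW"]] / ym)
}

#' Passive stress scaling factors from end-diastolic pressures
#'
#' Computes `k_pas_i = EDP_i / (Gamma_i,d sigma_pas_i,d)` per wall, where
#' `Gamma_i,d` is the chamber pressure produced by unit fiber stress in wall
#' i at the end-diastolic configuration (computed numerically from the
#' frozen geometry) and `sigma_pas_i,d` is the passive stress at the
#' configuration's end-diastolic sarcomere length (approximately the 2 um
#' resting length, since the reference areas are built from the EDVs).  The
#' septal wall is calibrated to the septal transmural pressure
#' `EDP_LV - EDP_RV`.  Configuration and factors are iterated to a fixed
#' point so the calibration is self-consistent.
#'
#' @param heart A [triseg_heart()] object.
#' @param subject A [subject_data()] object supplying EDPs and EDVs.
#' @param max_iter,tol Fixed-point iteration controls.
#' @return The heart with calibrated `k_pas`, with attributes
#'   `ed_config` (the end-diastolic configuration) and `iterations`.
#' @export
compute_kpas <- function(heart, subject, max_iter = 40, tol = 1e-10) {
  targets_kpa <- c(LW = subject$EDP_LV,
                   SW = subject$EDP_LV - subject$EDP_RV,
                   RW = subject$EDP_RV) * kPa_per_mmHg
  if (any(targets_kpa <= 0))
    stop("end-diastolic calibration requires EDP_LV > EDP_RV > 0")
  heart$use_pericardium <- FALSE
  guess <- NULL
  kpas <- heart$k_pas
  for (it in seq_len(max_iter)) {
    cfg <- solve_wall_configuration(subject$EDV_LV, subject$EDV_RV, Y = 0,
                                    heart = heart, guess = guess,
                                    quasi_static_Lc = TRUE)
    guess <- cfg$u
    sig_pas_d <- passive_stress(cfg$Ls, heart$sarc)
    if (any(sig_pas_d <= 0))
      stop("passive stress vanished at end-diastole (slack sarcomeres)")
    Gam <- gamma_factor_walls(cfg, heart)
    kpas_new <- targets_kpa / (Gam * sig_pas_d)
    rel <- max(abs(kpas_new - kpas) / kpas_new)
    heart$k_pas[] <- kpas_new
    kpas <- kpas_new
    if (rel < tol) break
  }
  attr(heart, "ed_config") <- cfg
  attr(heart, "iterations") <- it
  heart
}

#' Active stress scaling factors from end-systolic pressures
#'
#' Computes `k_act_i = ESP_i / (Gamma_i,s sigma_act_i,s)` per wall at the
#' end-systolic configuration built from the end-systolic volumes, assuming
#' 60% activation and the isometric quasi-steady contractile length
#' `Lc = Ls - L_se_iso` (so `sigma_act = (Ls - L_se_iso - L_c0) Y`).  The
#' septal wall is calibrated to `ESP_LV - ESP_RV`.  Iterated to a fixed
#' point jointly with the configuration.
#'
#' @inheritParams compute_kpas
#' @param Y_es Activation fraction assumed at end-systole.
#' @return The heart with calibrated `k_act` (attribute `es_config`).
#' @export
compute_kact <- function(heart, subject, Y_es = 0.6, max_iter = 40,
                         tol = 1e-10) {
  targets_kpa <- c(LW = subject$ESP_LV,
                   SW = subject$ESP_LV - subject$ESP_RV,
                   RW = subject$ESP_RV) * kPa_per_mmHg
  if (any(targets_kpa <= 0))
    stop("end-systolic calibration requires ESP_LV > ESP_RV > 0")
  heart$use_pericardium <- FALSE
  guess <- NULL
  kact <- heart$k_act
  for (it in seq_len(max_iter)) {
    cfg <- solve_wall_configuration(subject$ESV_LV, subject$ESV_RV,
                                    Y = Y_es, heart = heart, guess = guess,
                                    quasi_static_Lc = TRUE)
    guess <- cfg$u
    sig_act_s <- (cfg$Ls - heart$sarc$L_se_iso - heart$sarc$L_c0) * Y_es
    if (any(sig_act_s <= 0))
      stop("active stress vanished at end-systole (contractile slack)")
    Gam <- gamma_factor_walls(cfg, heart)
    kact_new <- targets_kpa / (Gam * sig_act_s)
    rel <- max(abs(kact_new - kact) / kact_new)
    heart$k_act[] <- kact_new
    kact <- kact_new
    if (rel < tol) break
  }
  attr(heart, "es_config") <- cfg
  attr(heart, "iterations") <- it
  heart
}

#' Fit the passive length-tension steepness against Klotz curves
#'
#' For each candidate `gamma`, recalibrates `k_pas` (so the model passes
#' through the subject (EDV, EDP) anchors) and computes the model ex vivo
#' EDPVRs of both ventricles over a volume grid; `gamma` is chosen by
#' nonlinear least squares on the pressure residuals against the LV and RV
#' Klotz curves jointly, with equal weights.
#'
#' @param heart A [triseg_heart()] object.
#' @param subject A [subject_data()] object.
#' @param n_grid Number of volume grid points.
#' @param span Grid span as fractions of EDV.
#' @param interval Search interval for `gamma`.
#' @param reference Optional reference pressures: a list with functions
#'   `P_LV(V)` and `P_RV(V)` (mmHg) replacing the Klotz curves (used e.g.
#'   for parameter-recovery checks against model-generated curves).
#' @return List: `gamma`, recalibrated `heart`, fit diagnostics (`sse`,
#'   `grid`, model and Klotz pressures at the optimum).
#' @export
fit_gamma <- function(heart, subject, n_grid = 40, span = c(0.5, 1.3),
                      interval = c(3, 15), reference = NULL) {
  grid <- seq(span[1] * subject$EDV_LV, span[2] * subject$EDV_LV,
              length.out = n_grid)
  rv_ratio <- subject$EDV_RV / subject$EDV_LV
  if (is.null(reference)) {
    klotz_LV <- klotz_curve(subject$EDP_LV, subject$EDV_LV)
    klotz_RV <- klotz_curve(subject$EDP_RV, subject$EDV_RV)
    ref_LV <- klotz_pressure(klotz_LV, grid)
    ref_RV <- klotz_pressure(klotz_RV, grid * rv_ratio)
  } else {
    ref_LV <- reference$P_LV(grid)
    ref_RV <- reference$P_RV(grid * rv_ratio)
  }

  eval_curve <- function(gam) {
    h <- heart
    h$sarc$gamma <- gam
    h <- compute_kpas(h, subject)
    ex_vivo_edpvr(h, grid, rv_ratio = rv_ratio)
  }
  sse <- function(lg) {
    cur <- eval_curve(exp(lg))
    sum((cur$P_LV - ref_LV)^2) + sum((cur$P_RV - ref_RV)^2)
  }
  opt <- stats::optim(log(7), sse, method = "L-BFGS-B",
                      lower = log(interval[1]), upper = log(interval[2]),
                      control = list(factr = 1e9))
  gam <- exp(opt$par)
  h <- heart
  h$sarc$gamma <- gam
  h <- compute_kpas(h, subject)
  cur <- ex_vivo_edpvr(h, grid, rv_ratio = rv_ratio)
  list(gamma = gam, heart = h, sse = opt$value, grid = grid,
       model_LV = cur$P_LV, model_RV = cur$P_RV,
       klotz_LV = ref_LV, klotz_RV = ref_RV,
       convergence = opt$convergence)
}

#' Calibrate a subject-specific heart model
#'
#' Full calibration pipeline: build the reference geometry from the EDVs,
#' optionally fit `gamma` against the Klotz curves, then compute the
#' passive (`k_pas`, end-diastolic) and active (`k_act`, end-systolic)
#' scaling factors.
#'
#' @param subject A [subject_data()] object.
#' @param h_LV,h_RW Wall thicknesses (cm).
#' @param sarc Sarcomere parameters; its `gamma` is the starting value.
#' @param fit_gamma If `FALSE`, keep `sarc$gamma` and skip the Klotz fit.
#' @param Y_es Activation fraction assumed at end-systole.
#' @return List of class `triseg_calibration`: the calibrated `heart`,
#'   `gamma`, `k_pas`, `k_act`, and fit diagnostics.
#' @examples
#' \donttest{
#' cal <- calibrate_heart(subject_data())
#' round(cal$gamma, 2)
#' }
#' @export
calibrate_heart <- function(subject = subject_data(), h_LV = 0.8,
                            h_RW = 0.4, sarc = sarcomere_params(),
                            fit_gamma = TRUE, Y_es = 0.6) {
  geom <- build_reference_geometry(subject$EDV_LV, subject$EDV_RV,
                                   h_LV = h_LV, h_RW = h_RW)
  heart <- triseg_heart(geom, sarc = sarc)
  fit <- NULL
  if (fit_gamma) {
    fit <- fit_gamma(heart, subject)
    heart <- fit$heart
  } else {
    heart <- compute_kpas(heart, subject)
  }
  heart <- compute_kact(heart, subject, Y_es = Y_es)
  heart$use_pericardium <- TRUE
  out <- list(heart = heart, subject = subject,
              gamma = heart$sarc$gamma,
              k_pas = heart$k_pas, k_act = heart$k_act, fit = fit)
  class(out) <- "triseg_calibration"
  out
}

#' @export
print.triseg_calibration <- function(x, ...) {
  cat("TriSeg calibration report\n")
  cat(sprintf("  gamma = %.3f%s\n", x$gamma,
              if (is.null(x$fit)) " (fixed)" else " (Klotz fit)"))
  cat(sprintf("  k_pas: LW %.4g, SW %.4g, RW %.4g\n",
              x$k_pas[1], x$k_pas[2], x$k_pas[3]))
  cat(sprintf("  k_act: LW %.4g, SW %.4g, RW %.4g\n",
              x$k_act[1], x$k_act[2], x$k_act[3]))
  if (!is.null(x$fit))
    cat(sprintf("  Klotz fit SSE %.4g mmHg^2 over %d points x 2 ventricles\n",
                x$fit$sse, length(x$fit$grid)))
  invisible(x)
}
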