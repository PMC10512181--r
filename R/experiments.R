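# Dysfunction scaling, volume-loading sweeps, compensation search, and
# extraction of per-beat functional metrics.

#' Specify an acute ventricular dysfunction
#'
#' Systolic dysfunction scales the active factors `k_act` of the targeted
#' walls to 60% (moderate) or 40% (severe) of nominal; diastolic dysfunction
#' scales the passive factors `k_pas` by 7 (moderate) or 15 (severe).  For
#' LV dysfunction the septum is considered part of the LV, so LW and SW are
#' scaled jointly; RV dysfunction scales the RV free wall only.
#'
#' @param target `"LV"` or `"RV"`.
#' @param mode `"systolic"` or `"diastolic"`.
#' @param severity `"healthy"`, `"moderate"`, or `"severe"`.
#' @return Object of class `dysfunction_spec`.
#' @export
dysfunction_spec <- function(target = c("LV", "RV"),
                             mode = c("systolic", "diastolic"),
                             severity = c("healthy", "moderate", "severe")) {
  spec <- list(target = match.arg(target), mode = match.arg(mode),
               severity = match.arg(severity))
  class(spec) <- "dysfunction_spec"
  spec
}

#' Apply a dysfunction to a calibrated heart
#'
#' Scaling is acute: the reference geometry is not re-derived (no
#' remodeling).  `severity = "healthy"` is the identity.
#'
#' @param heart A calibrated [triseg_heart()] object.
#' @param spec A [dysfunction_spec()].
#' @return The modified heart.
#' @export
apply_dysfunction <- function(heart, spec) {
  if (spec$severity == "healthy") return(heart)
  walls <- if (spec$target == "LV") c("LW", "SW") else "RW"
  if (spec$mode == "systolic") {
    f <- c(moderate = 0.6, severe = 0.4)[[spec$severity]]
    heart$k_act[walls] <- heart$k_act[walls] * f
  } else {
    f <- c(moderate = 7, severe = 15)[[spec$severity]]
    heart$k_pas[walls] <- heart$k_pas[walls] * f
  }
  heart
}

#' Per-beat functional metrics
#'
#' From the final recorded beat: EDV/ESV as the maximal/minimal chamber
#' volume, EDP/ESP as the pressures at those instants, SV = EDV - ESV,
#' EF = 100 SV/EDV, CO = SV x HR (L/min), and CPO as the pressure-volume
#' loop area times beat frequency (W; 1 mmHg mL = 1.33322e-4 J).
#'
#' @param sim A [simulate_heart()] result.
#' @return Data.frame with one row per ventricle.
#' @export
cardiac_metrics <- function(sim) {
  s <- last_beat(sim)
  one <- function(V, P) {
    i_ed <- which.max(V)
    i_es <- which.min(V)
    EDV <- V[i_ed]; ESV <- V[i_es]
    SV <- EDV - ESV
    area <- pv_loop_area(V, P)
    data.frame(SV = SV, EF = 100 * SV / EDV,
               CO = SV * sim$hr / 1000,
               CPO = area * joule_per_mmHg_mL * sim$hr / 60,
               ESP = P[i_es], EDP = P[i_ed], ESV = ESV, EDV = EDV)
  }
  out <- rbind(cbind(ventricle = "LV", one(s$V_LV, s$P_LV)),
               cbind(ventricle = "RV", one(s$V_RV, s$P_RV)))
  rownames(out) <- NULL
  out
}

# signed area of the (V, P) loop over one beat, closed between last and
# first sample; counterclockwise ejection work is positive
pv_loop_area <- function(V, P) {
  n <- length(V)
  j <- c(seq_len(n)[-1], 1L)
  -sum(0.5 * (P + P[j]) * (V[j] - V))
}

#' Septal curvature time course
#'
#' Septal midwall curvature over the final recorded beat, annotated with the
#' cardiac phase derived from the valve flows (ejection, isovolumic
#' relaxation, filling, isovolumic contraction).  Positive curvature means
#' the septum bows into the RV.
#'
#' @param sim A [simulate_heart()] result.
#' @param flow_tol Flow threshold (mL/s) below which a valve counts closed.
#' @return Data.frame with `t` (s, from beat onset), `Cm_SW` (1/cm), and
#'   `phase`.
#' @export
septal_curvature_timecourse <- function(sim, flow_tol = 0.5) {
  s <- last_beat(sim)
  t0 <- min(s$t)
  eject <- s$q_a > flow_tol
  fill <- s$q_m > flow_tol
  phase <- ifelse(eject, "ejection",
                  ifelse(fill, "filling", "isovolumic"))
  # isovolumic samples after the last ejection sample and before filling
  # resumes belong to relaxation; the rest to contraction
  t_es <- if (any(eject)) max(s$t[eject]) else t0
  phase[phase == "isovolumic" & s$t > t_es] <- "isovolumic_relaxation"
  t_fill <- if (any(fill & s$t > t_es)) min(s$t[fill & s$t > t_es]) else Inf
  phase[phase == "isovolumic_relaxation" & s$t > t_fill] <- "isovolumic"
  phase[phase == "isovolumic"] <- "isovolumic_contraction"
  data.frame(t = s$t - t0, Cm_SW = s$Cm_SW, phase = phase)
}

#' Search the circulating volume achieving a target mean arterial pressure
#'
#' Bisection on total blood volume so the cycle-averaged systemic arterial
#' pressure over the final beat hits the target.  If the target is not
#' reachable within the bracket the nearest bound is returned with
#' `compensated = FALSE` (compensation is physiologically limited in some
#' severe dysfunction cases).
#'
#' @param heart A calibrated [triseg_heart()] object.
#' @param circ A [derive_circulation_parameters()] object.
#' @param target_mean_Psa Target cycle-mean systemic arterial pressure
#'   (mmHg).
#' @param tol Acceptable pressure mismatch (mmHg).
#' @param bracket Search bracket as fractions of the parameterization TBV.
#' @param hr Heart rate (bpm).
#' @param ... Passed to [simulate_heart()].
#' @return List: `tbv` (mL), `mean_Psa` (mmHg), `compensated` (logical),
#'   `sim` (the simulation at the returned volume), `evaluations`.
#' @export
find_compensated_tbv <- function(heart, circ, target_mean_Psa = 95,
                                 tol = 0.5, bracket = c(0.8, 3.5),
                                 hr = 60, ...) {
  evals <- list()
  f <- function(frac) {
    sim <- simulate_heart(heart, circ, tbv = frac * circ$TBV, hr = hr, ...)
    m <- mean_pressure(sim, "P_SA")
    evals[[length(evals) + 1]] <<- c(frac = frac, mean_Psa = m)
    list(err = m - target_mean_Psa, sim = sim, mean = m)
  }
  lo <- bracket[1]; hi <- bracket[2]
  flo <- f(lo)
  if (flo$err >= -tol) {
    return(list(tbv = lo * circ$TBV, mean_Psa = flo$mean,
                compensated = abs(flo$err) <= tol, sim = flo$sim,
                evaluations = do.call(rbind, evals)))
  }
  fhi <- f(hi)
  if (fhi$err <= tol) {
    return(list(tbv = hi * circ$TBV, mean_Psa = fhi$mean,
                compensated = abs(fhi$err) <= tol, sim = fhi$sim,
                evaluations = do.call(rbind, evals)))
  }
  best <- NULL
  for (i in 1:40) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    best <- fm
    if (abs(fm$err) <= tol) break
    if (fm$err < 0) lo <- mid else hi <- mid
    if ((hi - lo) * circ$TBV < 1) break
  }
  list(tbv = mid * circ$TBV, mean_Psa = best$mean,
       compensated = abs(best$err) <= tol, sim = best$sim,
       evaluations = do.call(rbind, evals))
}

#' Cycle-averaged value of a recorded signal over the final beat
#'
#' Trapezoidal time-average, e.g. the cycle-mean systemic arterial pressure
#' used as the compensation criterion.
#'
#' @param sim A [simulate_heart()] result.
#' @param col Column of the recorded series.
#' @return Time-averaged value.
#' @export
mean_pressure <- function(sim, col = "P_SA") {
  s <- last_beat(sim)
  x <- s[[col]]
  t <- s$t
  sum(diff(t) * (x[-1] + x[-length(x)]) / 2) / (max(t) - min(t))
}

#' Volume-loading sweep
#'
#' Runs the model to periodic steady state at each circulating-volume
#' fraction and records per-beat metrics plus the end-systolic and
#' end-diastolic points, from which ESPVR, EDPVR, and Frank-Starling loci
#' are assembled.
#'
#' @param heart A calibrated [triseg_heart()] object.
#' @param circ A [derive_circulation_parameters()] object.
#' @param fractions Circulating volume as fractions of the parameterization
#'   TBV (the loading protocol spans 100%-350%).
#' @param hr Heart rate (bpm).
#' @param target_mean_Psa Compensation target used to flag points (mmHg).
#' @param tol Pressure tolerance for the compensated flag (mmHg).
#' @param ... Passed to [simulate_heart()].
#' @return Data.frame with one row per fraction and ventricle: metrics,
#'   mean systemic arterial pressure, and the compensated flag.
#' @export
volume_loading_sweep <- function(heart, circ, fractions = seq(1, 3.5, 0.1),
                                 hr = 60, target_mean_Psa = 95, tol = 0.5,
                                 ...) {
  rows <- lapply(fractions, function(fr) {
    sim <- tryCatch(
      simulate_heart(heart, circ, tbv = fr * circ$TBV, hr = hr, ...),
      error = function(e) NULL)
    if (is.null(sim)) return(NULL)
    m <- cardiac_metrics(sim)
    m$tbv_fraction <- fr
    m$tbv <- fr * circ$TBV
    m$mean_Psa <- mean_pressure(sim, "P_SA")
    m$compensated <- abs(m$mean_Psa - target_mean_Psa) <= tol
    m
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the full dysfunction study
#'
#' Calibrates the healthy heart, finds its compensated baseline, then for
#' each dysfunction case (LV/RV x systolic/diastolic x moderate/severe)
#' switches to the disease unstressed-volume fractions, volume-loads to the
#' compensated baseline (or flags the 350% bound), and collects the
#' functional metrics, cardiac power outputs, and septal curvature series.
#'
#' @param subject A [subject_data()] object.
#' @param hr Heart rate (bpm).
#' @param cases Character vector among `"LVSD"`, `"LVDD"`, `"RVSD"`,
#'   `"RVDD"`.
#' @param severities Character vector among `"moderate"`, `"severe"`.
#' @param calibration Optional precomputed [calibrate_heart()] result.
#' @param ... Passed to [simulate_heart()].
#' @return List of class `triseg_study`: `metrics` (Table-style data.frame
#'   over all cases and ventricles), `baselines` (compensation results),
#'   `curvature` (septal series per case), `calibration`.
#' @export
run_study <- function(subject = subject_data(), hr = 60,
                      cases = c("LVSD", "LVDD", "RVSD", "RVDD"),
                      severities = c("moderate", "severe"),
                      calibration = NULL, ...) {
  if (is.null(calibration)) calibration <- calibrate_heart(subject)
  heart <- calibration$heart
  circ_h <- derive_circulation_parameters(subject, disease = FALSE)
  circ_d <- derive_circulation_parameters(subject, disease = TRUE)

  case_specs <- list(
    LVSD = dysfunction_spec("LV", "systolic"),
    LVDD = dysfunction_spec("LV", "diastolic"),
    RVSD = dysfunction_spec("RV", "systolic"),
    RVDD = dysfunction_spec("RV", "diastolic"))

  metrics <- list(); baselines <- list(); curvature <- list()
  collect <- function(label, comp) {
    m <- cardiac_metrics(comp$sim)
    m <- cbind(case = label, m, mean_Psa = comp$mean_Psa,
               tbv = comp$tbv, compensated = comp$compensated)
    metrics[[label]] <<- m
    baselines[[label]] <<- comp[c("tbv", "mean_Psa", "compensated")]
    cv <- septal_curvature_timecourse(comp$sim)
    cv$case <- label
    curvature[[label]] <<- cv
  }

  comp_h <- find_compensated_tbv(heart, circ_h, hr = hr, ...)
  collect("Healthy", comp_h)

  for (cs in cases) {
    for (sev in severities) {
      spec <- case_specs[[cs]]
      spec$severity <- sev
      h <- apply_dysfunction(heart, spec)
      label <- paste0(cs, "-", if (sev == "moderate") "M" else "S")
      comp <- tryCatch(find_compensated_tbv(h, circ_d, hr = hr, ...),
                       error = function(e) {
                         warning(sprintf("case %s failed: %s", label,
                                         conditionMessage(e)))
                         NULL
                       })
      if (!is.null(comp)) collect(label, comp)
    }
  }
  out <- list(metrics = do.call(rbind, metrics),
              baselines = baselines,
              curvature = do.call(rbind, curvature),
              calibration = calibration, hr = hr)
  rownames(out$metrics) <- NULL
  class(out) <- "triseg_study"
  out
}

#' @export
print.triseg_study <- function(x, ...) {
  cat(sprintf("TriSeg dysfunction study at HR %g bpm\n", x$hr))
  m <- x$metrics
  num <- vapply(m, is.numeric, logical(1))
  m[num] <- lapply(m[num], signif, 3)
  print(m, row.names = FALSE)
  invisible(x)
}
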