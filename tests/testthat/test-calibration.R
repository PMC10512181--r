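test_that("Klotz single-beat landmarks match the construction", {
  kc <- klotz_curve(5, 125)
  expect_equal(kc$V0, 71.25)
  expect_equal(kc$V30, 171.3006372, tolerance = 1e-8)
  expect_equal(kc$beta, 5.686204847, tolerance = 1e-8)
  expect_equal(klotz_pressure(kc, 125), 5, tolerance = 1e-10)
  expect_equal(klotz_pressure(kc, kc$V30), 30, tolerance = 1e-10)
  expect_lt(klotz_pressure(kc, kc$V0), 0.5)   # near zero at V0
  expect_warning(klotz_curve(31, 125), "30 mmHg")
})

test_that("volume normalization maps the landmarks to 0 and 1", {
  kc <- klotz_curve(5, 125)
  cur <- data.frame(V = c(kc$V0, kc$V30, 125), P = c(0, 30, 5))
  nrm <- normalize_edpvr(cur, kc)
  expect_equal(nrm$Vn[1:2], c(0, 1))
  expect_true(nrm$Vn[3] > 0 && nrm$Vn[3] < 1)
})

test_that("ex vivo inflation is monotone and slack at low volume", {
  heart <- healthy_calibration()$heart
  ev <- ex_vivo_edpvr(heart, seq(40, 160, by = 10))
  expect_true(all(diff(ev$P_LV) > 0))
  expect_true(all(diff(ev$P_RV) > 0))
  expect_lt(ev$P_LV[1], 0.05)                 # near slack
  expect_true(all(ev$P_LV > ev$P_RV))         # stiffer-calibrated LV
})

test_that("passive calibration reproduces the end-diastolic anchors", {
  s <- subject_data()
  h <- compute_kpas(triseg_heart(build_reference_geometry(125, 125)), s)
  ev <- ex_vivo_edpvr(h, 125)
  expect_equal(ev$P_LV, s$EDP_LV, tolerance = 0.05)
  expect_equal(ev$P_RV, s$EDP_RV, tolerance = 0.05)
  # idempotence: recalibrating a calibrated heart changes factors < 1%
  h2 <- compute_kpas(h, s)
  expect_equal(unname(h2$k_pas), unname(h$k_pas), tolerance = 0.01)
})

test_that("active calibration hits its end-systolic identity", {
  s <- subject_data()
  cal <- healthy_calibration()
  h <- cal$heart
  h$use_pericardium <- FALSE
  # at the frozen end-systolic configuration with 60% activation, the
  # calibrated chamber pressures equal the targets
  cfg <- solve_wall_configuration(s$ESV_LV, s$ESV_RV, Y = 0.6, heart = h,
                                  quasi_static_Lc = TRUE)
  expect_equal(cfg$P_LV, s$ESP_LV, tolerance = 0.02)
  expect_equal(cfg$P_RV, s$ESP_RV, tolerance = 0.02)
  h2 <- compute_kact(h, s)
  expect_equal(unname(h2$k_act), unname(h$k_act), tolerance = 0.01)
})

test_that("gamma is recovered from model-generated reference curves", {
  s <- subject_data()
  geom <- build_reference_geometry(125, 125)
  truth <- triseg_heart(geom)
  truth$sarc$gamma <- 6.3
  truth <- compute_kpas(truth, s)
  grid <- seq(62.5, 162.5, length.out = 60)
  ref <- ex_vivo_edpvr(truth, grid)
  fit <- fit_gamma(triseg_heart(geom), s,
                   reference = list(P_LV = stats::approxfun(ref$V_LV,
                                                            ref$P_LV),
                                    P_RV = stats::approxfun(ref$V_RV,
                                                            ref$P_RV)))
  expect_equal(fit$gamma, 6.3, tolerance = 5e-4)   # 3 significant figures
})

test_that("the Klotz fit is robust to grid density", {
  s <- subject_data()
  h <- triseg_heart(build_reference_geometry(125, 125))
  f40 <- fit_gamma(h, s, n_grid = 40)
  f80 <- fit_gamma(h, s, n_grid = 80)
  expect_lt(abs(f80$gamma - f40$gamma) / f40$gamma, 0.01)
})

test_that("normalized model EDPVRs collapse across heart sizes", {
  sizes <- c(62.5, 125, 187.5, 250)
  Vn <- seq(0.2, 1, length.out = 20)
  gam <- healthy_calibration()$gamma
  curves <- lapply(sizes, function(edv) {
    lam <- (edv / 125)^(1 / 3)      # geometric similarity across sizes
    ss <- subject_data(EDV_LV = edv, EDV_RV = edv, ESV_LV = 0.4 * edv)
    hh <- triseg_heart(build_reference_geometry(edv, edv,
                                                h_LV = 0.8 * lam,
                                                h_RW = 0.4 * lam),
                       sarc = sarcomere_params(gamma = gam))
    hh <- compute_kpas(hh, ss)
    kc <- klotz_curve(5, edv)
    ex_vivo_edpvr(hh, kc$V0 + Vn * (kc$V30 - kc$V0))
  })
  P_LV <- sapply(curves, `[[`, "P_LV")
  P_RV <- sapply(curves, `[[`, "P_RV")
  gap <- function(M) max(apply(M, 1, function(r) diff(range(r))))
  expect_lt(gap(P_LV), 0.02 * 30)   # 2% of the 30 mmHg scale
  expect_lt(gap(P_RV), 0.02 * 30)
})
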