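test_that("spherical-cap geometry matches the closed forms", {
  flat <- cap_geometry(0, 2)
  expect_equal(flat$Cm, 0)
  expect_equal(flat$Vm, 0)
  expect_equal(flat$Am, pi * 4)
  hemi <- cap_geometry(1.5, 1.5)          # hemisphere of radius 1.5
  expect_equal(hemi$Am, 2 * pi * 1.5^2)
  expect_equal(hemi$Cm, 1 / 1.5)
  expect_equal(hemi$Vm, 2 / 3 * pi * 1.5^3)
  g <- cap_geometry(1, 2)
  expect_equal(g$Am, 15.70796327, tolerance = 1e-8)
  expect_equal(g$Cm, 0.4)
  expect_equal(g$Vm, 6.806784083, tolerance = 1e-8)
  expect_error(cap_geometry(1, 0), "positive")
})

test_that("strain expansion recovers the stated limits", {
  ref <- wall_strain_and_length(100, 0, 50, 100, L_ref = 2)
  expect_equal(ref$eps_f, 0)
  expect_equal(ref$Ls, 2)
  stretched <- wall_strain_and_length(100 * exp(2), 0, 50, 100, L_ref = 2)
  expect_equal(stretched$Ls, 2 * exp(1), tolerance = 1e-12)
  # z reduces the strain below the pure area term
  curved <- wall_strain_and_length(100, 0.3, 50, 100, L_ref = 2)
  expect_lt(curved$Ls, ref$Ls)
  expect_equal(curved$z, 3 * 0.3 * 50 / 200)
})

test_that("wall tension components satisfy the trigonometric identity", {
  t0 <- wall_tension(0, 80, 100, 0.3, -2, 3)
  expect_equal(t0$Tm, 0); expect_equal(t0$Tx, 0); expect_equal(t0$Ty, 0)
  thin <- wall_tension(10, 80, 100, 0, -2, 3)
  expect_equal(thin$Tm, 10 * 80 / 200)
  for (xm in c(-2.5, 0.5, 3)) {
    tt <- wall_tension(12, 60, 90, 0.25, xm, 2.8)
    expect_equal(tt$Tx^2 + tt$Ty^2, tt$Tm^2, tolerance = 1e-12)
  }
})

test_that("compiled junction residuals agree with the R formula route", {
  heart <- triseg_heart(build_reference_geometry(125, 125),
                        k_pas = c(300, 500, 130), k_act = c(500, 700, 200))
  sp <- heart$sarc
  set.seed(42)
  for (i in 1:8) {
    u <- c(-runif(1, 3, 5), runif(1, 0.5, 2.5), runif(1, 3, 6),
           runif(1, 2.5, 4))
    Lc <- runif(3, 1.7, 2.0)
    Y <- runif(1)
    r_cpp <- junction_residual(u, 120, 130, Lc, Y, heart)
    # independent route through the exported R formulas
    Tx <- Ty <- Vm <- numeric(3)
    for (w in 1:3) {
      cg <- cap_geometry(u[w], u[4])
      st <- wall_strain_and_length(cg$Am, cg$Cm, heart$geometry$Vw[w],
                                   heart$geometry$Am_ref[w], sp$L_ref)
      sig <- total_wall_stress(st$Ls, Lc[w], Y, heart$k_pas[w],
                               heart$k_act[w], sp)
      tn <- wall_tension(sig, heart$geometry$Vw[w], cg$Am, st$z, u[w], u[4])
      Tx[w] <- tn$Tx; Ty[w] <- tn$Ty; Vm[w] <- cg$Vm
    }
    expect_equal(r_cpp[["Tx"]], sum(Tx), tolerance = 1e-10)
    expect_equal(r_cpp[["Ty"]], sum(Ty), tolerance = 1e-10)
    expect_equal(r_cpp[["V_LV"]],
                 (-Vm[1] + Vm[2]) -
                   (120 + 0.5 * sum(heart$geometry$Vw[1:2])),
                 tolerance = 1e-10)
    expect_equal(r_cpp[["V_RV"]],
                 (Vm[3] - Vm[2]) -
                   (130 + 0.5 * sum(heart$geometry$Vw[2:3])),
                 tolerance = 1e-10)
  }
})

test_that("wall solver converges to a physical healthy configuration", {
  heart <- healthy_calibration()$heart
  cfg <- solve_wall_configuration(125, 125, Y = 0, heart = heart,
                                  quasi_static_Lc = TRUE)
  expect_true(cfg$converged)
  expect_gt(cfg$ym, 0)
  expect_lt(cfg$xm[["LW"]], 0)
  expect_gt(cfg$xm[["RW"]], 0)
  expect_gt(cfg$Cm[["SW"]], 0)      # septum bows into the RV
  # residuals at the solution are below tolerance
  r <- junction_residual(cfg$u, 125, 125, cfg$Ls - heart$sarc$L_se_iso, 0,
                         heart)
  expect_lt(max(abs(r[1:2])) / sum(abs(cfg$Tm)), 1e-8)
  expect_lt(max(abs(r[3:4])) / 250, 1e-8)
  # restarting from its own solution is an immediate fixed point
  cfg2 <- solve_wall_configuration(125, 125, Y = 0, heart = heart,
                                   guess = cfg$u, quasi_static_Lc = TRUE)
  expect_lte(cfg2$iterations, 2)
  expect_equal(cfg2$u, cfg$u, tolerance = 1e-7)
})

test_that("solution is insensitive to a 10x tighter tolerance", {
  heart <- healthy_calibration()$heart
  a <- solve_wall_configuration(110, 140, Y = 0.3, heart = heart,
                                quasi_static_Lc = TRUE, tol = 1e-8)
  b <- solve_wall_configuration(110, 140, Y = 0.3, heart = heart,
                                quasi_static_Lc = TRUE, tol = 1e-9)
  expect_equal(a$P_LV, b$P_LV, tolerance = 1e-3)
  expect_equal(a$P_RV, b$P_RV, tolerance = 1e-3)
})

test_that("radial tension sum responds monotonically to ym near equilibrium", {
  heart <- healthy_calibration()$heart
  cfg <- solve_wall_configuration(125, 125, Y = 0, heart = heart,
                                  quasi_static_Lc = TRUE)
  Lc <- cfg$Ls - heart$sarc$L_se_iso
  dy <- 0.02
  up <- cfg$u + c(0, 0, 0, dy)
  dn <- cfg$u - c(0, 0, 0, dy)
  r_up <- junction_residual(up, 125, 125, Lc, 0, heart)[["Ty"]]
  r_dn <- junction_residual(dn, 125, 125, Lc, 0, heart)[["Ty"]]
  expect_true(sign(r_up) != sign(r_dn))
})

test_that("a thin isolated sphere reproduces the Laplace membrane law", {
  # one sphere built from two hemispheric caps and a massless flat septum;
  # the fiber stress sigma_f distributed isotropically in-plane corresponds
  # to an isotropic membrane stress sigma_f/2, so P = 2 (sigma_f/2) h / r
  rm <- 3; h <- 0.2; sig <- 10
  g <- build_reference_geometry(125, 125)
  Vsph <- 4 / 3 * pi * ((rm + h / 2)^3 - (rm - h / 2)^3)
  g$Vw[] <- c(Vsph / 2, 1e-4, Vsph / 2)
  g$Am_ref[] <- c(2 * pi * rm^2, pi * rm^2, 2 * pi * rm^2)
  sphere <- triseg_heart(g, sarc = sarcomere_params(gamma = 1e-8),
                         k_pas = c(sig, 0, sig), k_act = c(0, 0, 0),
                         use_pericardium = FALSE)
  Vhalf <- (4 / 3 * pi * (rm - h / 2)^3) / 2
  cfg <- solve_wall_configuration(Vhalf, Vhalf, Y = 0, heart = sphere,
                                  quasi_static_Lc = TRUE)
  h_eff <- Vsph / (4 * pi * rm^2)
  P_laplace <- 2 * (sig / 2) * h_eff / rm / kPa_per_mmHg
  expect_equal(cfg$P_LV, P_laplace, tolerance = 0.05)
  expect_equal(cfg$P_RV, P_laplace, tolerance = 0.05)
  expect_equal(cfg$xm[["SW"]], 0, tolerance = 1e-6)  # symmetric: flat septum
})

test_that("pericardial pressure has the stated landmarks and monotonicity", {
  expect_equal(pericardial_pressure(150, 150, 10, 300), 0)
  expect_equal(pericardial_pressure(165, 165, 10, 300), exp(1) - 1,
               tolerance = 1e-12)
  v <- seq(100, 250, by = 10)
  p <- pericardial_pressure(v, v, 10, 300)
  expect_true(all(diff(p) > 0))
  expect_true(all(p > -1))          # bounded negative suction
})
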