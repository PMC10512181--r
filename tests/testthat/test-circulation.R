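test_that("circulation parameters follow the derivation recipe", {
  cp <- derive_circulation_parameters(subject_data())
  expect_equal(cp$C_SA, (1000 * 0.30) / 120)     # 2.5 mL/mmHg
  expect_equal(cp$C_SV, (2700 * 0.10) / 6)
  expect_equal(cp$C_PA, (250 * 0.60) / 25)
  expect_equal(cp$C_PV, (750 * 0.10) / 8)
  expect_equal(cp$R_sys, (95 - 4) / 75)          # ~1.213 mmHg s/mL
  expect_equal(cp$R_pul, (15 - 5) / 75)          # ~0.133 mmHg s/mL
  expect_equal(cp$Vu_SA, 700)
  expect_equal(cp$Vu_SV, 2430)
  # disease column lowers unstressed volumes but keeps compliances
  cd <- derive_circulation_parameters(subject_data(), disease = TRUE)
  expect_equal(cd$C_SA, cp$C_SA)
  expect_equal(cd$Vu_SA, 600)
  expect_equal(cd$Vu_PV, 0.75 * 750)
  expect_lt(cd$Vu_SA + cd$Vu_SV + cd$Vu_PA + cd$Vu_PV,
            cp$Vu_SA + cp$Vu_SV + cp$Vu_PA + cp$Vu_PV)
})

test_that("malformed fraction tables are rejected", {
  f <- compartment_fractions()
  f$tbv_frac[2] <- 0.5
  expect_error(derive_circulation_parameters(subject_data(), fractions = f),
               "sum to 1")
})

test_that("diode valve admits forward flow only", {
  expect_equal(valve_flow(10, 20, 5e-4), 0)
  expect_equal(valve_flow(21, 20, 5e-4), 2000)
  expect_equal(valve_flow(20, 20, 5e-4), 0)
  expect_error(valve_flow(1, 0, 0), "positive")
})

test_that("compartment pressure combines elastic and viscoelastic parts", {
  expect_equal(compartment_pressure(700, 700, 2.5), 0)
  expect_equal(compartment_pressure(1000, 700, 2.5), 120)
  expect_equal(compartment_pressure(1000, 700, 2.5, q_net = 100, Rt = 0.08),
               128)
  # venous use ignores Rt by passing the default 0
  expect_equal(compartment_pressure(2500, 2430, 45), 70 / 45)
})

test_that("the closed-loop right-hand side conserves blood volume", {
  cal <- healthy_calibration()
  circ <- healthy_circulation()
  act <- activation_params(HR = 60)
  set.seed(7)
  for (i in 1:5) {
    state <- c(V_LV = runif(1, 60, 180), V_SA = runif(1, 900, 1100),
               V_SV = runif(1, 2400, 2700), V_RV = runif(1, 60, 180),
               V_PA = runif(1, 180, 280), V_PV = runif(1, 650, 800),
               Lc_LW = runif(1, 1.7, 2), Lc_SW = runif(1, 1.7, 2),
               Lc_RW = runif(1, 1.7, 2))
    out <- system_rhs(runif(1, 0, 1), state, cal$heart, circ, act)
    expect_equal(sum(out$dstate[1:6]), 0, tolerance = 1e-10)
    expect_true(all(out$aux[c("q_m", "q_a", "q_t", "q_p")] >= 0))
    # contractile dynamics match the sarcomere law at the solved lengths
    for (w in 1:3) {
      Ls <- out$aux[[c("Ls_LW", "Ls_SW", "Ls_RW")[w]]]
      expect_equal(out$dstate[6 + w],
                   unname(contractile_length_rate(Ls, state[[6 + w]],
                                                  cal$heart$sarc)),
                   tolerance = 1e-8)
    }
  }
})

test_that("healthy simulation is conservative, periodic, and balanced", {
  sim <- healthy_sim_46()
  expect_lt(sim$vol_conservation, 1e-6)
  expect_lt(sim$periodicity, 1e-3)
  s <- last_beat(sim)
  # no reverse flow through any valve at any recorded time
  expect_true(all(s$q_m >= 0 & s$q_a >= 0 & s$q_t >= 0 & s$q_p >= 0))
  m <- cardiac_metrics(sim)
  sv <- m$SV
  expect_lt(abs(sv[1] - sv[2]) / sv[1], 0.01)   # LV vs RV stroke volume
  # per-beat flow balance: systemic throughput matches the stroke volume
  q_sys_beat <- mean_pressure(sim, "q_sys") * sim$T
  expect_lt(abs(q_sys_beat - sv[1]) / sv[1], 0.01)
  # pressure ordering during ejection
  ej <- s$q_a > 1
  expect_true(all(s$P_LV[ej] > s$P_RV[ej]))
  # mitral valve closed while the aortic valve is open
  expect_true(all(s$q_m[ej] < 1e-6))
})
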