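test_that("APP synthesis responds linearly to the hyperacute signal", {
  expect_equal(app_synthesis_rate(10, 1.5, 0), 10)
  expect_equal(app_synthesis_rate(10, 1.5, 1), 25)
  expect_equal(app_synthesis_rate(10, 0, 7), 10)
  rb <- seq(0, 5, by = 0.5)
  expect_true(all(diff(app_synthesis_rate(10, 1.5, rb)) > 0))
  expect_error(app_synthesis_rate(10, 1.5, -0.1), "R_B")
})

test_that("resting steady state solves the system to the stated residual", {
  am <- amyloid_params()
  tr <- transport_params()
  ss <- steady_state_baseline(am, tr)
  resid <- blastkin:::.pbpk_deriv(ss, 0, am, tr)
  expect_lt(max(abs(resid)), 1e-10 * am$k_APP0)
  expect_true(all(ss >= 0))
  # zero synthesis everywhere -> all-zero state
  ss0 <- steady_state_baseline(amyloid_params(k_APP0 = 0), tr)
  expect_equal(max(abs(ss0)), 0)
})

test_that("steady state matches the decoupled closed form", {
  # no flows, no transporters, no exchange: every compartment independent;
  # production f_42 * k_APP0 enters ISF, so ISF = f_42 k_APP0 / k_deg_ISF
  am <- amyloid_params(k_APP0 = 50, f_per = 0.2)
  tr <- transport_params(k_RAGE = 0, k_LRP1 = 0, k_PgP = 0, F_BBB = 0,
                         F_gly = 0, Q_br = 0, Q_per = 0, L_br = 0, L_per = 0)
  ss <- steady_state_baseline(am, tr)
  expect_equal(ss[["APP_br"]], 50 / am$k_BACE1)
  expect_equal(ss[["C99_br"]], 50 / am$k_gS)
  expect_equal(ss[["Ab42_ISF"]], am$f_42 * 50 / tr$k_deg["ISF"][[1]])
  expect_equal(ss[["Ab42_per"]], am$f_42 * 0.2 * 50 / tr$k_deg["per"][[1]])
  expect_equal(ss[["Ab42_plasma"]], 0)
  # two-compartment reduction: efflux ISF -> vasc only, solved analytically
  tr2 <- transport_params(k_RAGE = 0, k_LRP1 = 0.4, k_PgP = 0.2, F_BBB = 0,
                          F_gly = 0, Q_br = 0, Q_per = 0, L_br = 0, L_per = 0)
  ss2 <- steady_state_baseline(am, tr2)
  prod <- am$f_42 * 50
  c_isf <- prod / (0.6 + tr2$k_deg["ISF"][[1]])
  expect_equal(ss2[["Ab42_ISF"]], c_isf)
  expect_equal(ss2[["Ab42_vasc"]],
               0.6 * c_isf * tr2$V["ISF"][[1]] /
                 (tr2$V["vasc"][[1]] * tr2$k_deg["vasc"][[1]]))
})

test_that("a compartment with no outflow is diagnosed by name", {
  tr <- transport_params(L_br = 0, L_per = 0,
                         k_deg = c(ISF = 0.3, vasc = 0.1, peri = 0.1,
                                   plasma = 0.3, per = 0.2, lymph = 0))
  expect_error(steady_state_baseline(amyloid_params(), tr), "Ab42_lymph")
})

test_that("transport-only dynamics conserve total Abeta42 mass", {
  am <- amyloid_params(k_APP0 = 0)
  tr <- transport_params(k_deg = c(ISF = 0, vasc = 0, peri = 0, plasma = 0,
                                   per = 0, lymph = 0))
  sys <- build_ode_system(am, tr)
  y0 <- numeric(12)
  names(y0) <- blastkin:::.pbpk_species()
  y0[7:12] <- c(30, 10, 5, 20, 8, 2)  # arbitrary positive Abeta42 state
  out <- integrate_system(sys, y0, times = seq(0, 100, by = 5),
                          rel_tol = 1e-10, abs_tol = 1e-12)
  colnames(out) <- c("time", names(y0))
  mass <- total_ab42_mass(out[, -1], tr)
  expect_lt(max(abs(mass - mass[1])) / mass[1], 1e-8)
  expect_true(all(out[, -1] >= -1e-9))
})

test_that("with all couplings off, plasma evolves independently", {
  am <- amyloid_params(k_APP0 = 0)
  tr <- transport_params(k_RAGE = 0, k_LRP1 = 0, k_PgP = 0, F_BBB = 0,
                         F_gly = 0, Q_br = 0, Q_per = 0, L_br = 0, L_per = 0,
                         k_deg = c(ISF = 0.3, vasc = 0.1, peri = 0.1,
                                   plasma = 0, per = 0.2, lymph = 0.1))
  sys <- build_ode_system(am, tr)
  y0 <- numeric(12); y0[10] <- 20  # plasma only, no local rates
  out <- integrate_system(sys, y0, times = seq(0, 50, by = 10),
                          rel_tol = 1e-10, abs_tol = 1e-12)
  expect_equal(out[, 11], rep(20, nrow(out)), tolerance = 1e-9)
})

test_that("steady state is linear in the synthesis rate", {
  tr <- transport_params()
  s1 <- steady_state_baseline(amyloid_params(k_APP0 = 10), tr)
  s2 <- steady_state_baseline(amyloid_params(k_APP0 = 20), tr)
  expect_equal(s2, 2 * s1, tolerance = 1e-6)
})

test_that("efflux lowers and influx raises brain ISF Abeta42", {
  am <- amyloid_params(k_APP0 = 10)
  base <- steady_state_baseline(am, transport_params())
  up_efflux <- steady_state_baseline(am, transport_params(k_LRP1 = 0.8))
  up_influx <- steady_state_baseline(am, transport_params(k_RAGE = 0.15))
  expect_lt(up_efflux[["Ab42_ISF"]], base[["Ab42_ISF"]])
  expect_gt(up_influx[["Ab42_ISF"]], base[["Ab42_ISF"]])
  expect_lt(up_influx[["Ab42_vasc"]], base[["Ab42_vasc"]])
})

test_that("the optional Abeta40 mirror shares the C99 flux with fraction 1 - f_42", {
  am <- amyloid_params(k_APP0 = 10, f_42 = 0.1)
  tr <- transport_params()
  ss <- steady_state_baseline(am, tr, include_ab40 = TRUE)
  # identical transport: Abeta40 steady state = (1 - f_42)/f_42 times Abeta42
  ratio <- ss[["Ab40_plasma"]] / ss[["Ab42_plasma"]]
  expect_equal(ratio, (1 - 0.1) / 0.1, tolerance = 1e-8)
})
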