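empty_tl <- exposure_timeline(numeric(0), numeric(0), character(0))

test_that("mechanical damage derivative matches its stated kinetics", {
  p <- damage_params()  # alpha / t_d = 0.2 per h
  expect_equal(rm_rhs(1, lambda = 1, source = 0, p), 0)  # fixed point
  expect_equal(rm_rhs(2, lambda = 0, source = 0, p), -0.4)
  # exponential decay against the closed form
  tr <- simulate_damage(empty_tl, p, t_grid = seq(0, 20, 0.5), y0 = c(2, 0, 0))
  expect_equal(tr$R_M, 2 * exp(-0.2 * tr$time_h), tolerance = 1e-7)
})

test_that("response derivatives vanish at rest and have the stated fixed points", {
  p <- damage_params()
  expect_equal(unname(rb_rhs(0, 0, 0, p)), c(0, 0))
  # sustained R_M = lambda: solve the fixed points analytically
  lam <- 1
  rb1_star <- p$k_in * lam * (lam + p$R_M0) / p$k_out1   # 4
  rb2_star <- p$k_out1 * rb1_star / p$k_out2             # 20
  expect_equal(unname(rb_rhs(lam, rb1_star, rb2_star, p)), c(0, 0))
  # and the integrator converges to them after a supra-threshold blast
  tl <- exposure_timeline(0.5, 8)  # lambda = 1 under defaults
  tr <- simulate_damage(tl, p, t_grid = c(0, seq(0.5, 400, by = 2)))
  last <- tr[nrow(tr), ]
  expect_equal(last$R_M, lam, tolerance = 1e-3)
  expect_equal(last$R_B1, rb1_star, tolerance = 1e-3)
  expect_equal(last$R_B2, rb2_star, tolerance = 1e-3)
})

test_that("a single supra-threshold event peaks ~0.5 s after the event", {
  tl <- exposure_timeline(0.001, 8)
  tr <- simulate_damage(tl, t_grid = c(0, 0.001, 1))
  i <- which.max(tr$R_M)
  t_peak_s <- (tr$time_h[i] - 0.001) * 3600
  expect_gt(t_peak_s, 0.4)
  expect_lt(t_peak_s, 0.6)
  # peak amplitude ~ dose_scale * BOP
  expect_equal(tr$R_M[i], 8, tolerance = 0.01)
})

test_that("sub-threshold exposure recovers fully; supra-threshold leaves residual damage", {
  # BOP 3 < threshold: all states decay below 1e-6 of their peaks
  tl <- exposure_timeline(0.5, 3)
  tr <- simulate_damage(tl, t_grid = c(0, seq(0.5, 250, by = 2.5)))
  peaks <- vapply(tr[c("R_M", "R_B1", "R_B2")], max, 1)
  last <- unlist(tr[nrow(tr), c("R_M", "R_B1", "R_B2")])
  expect_true(all(last < 1e-6 * peaks))
  # BOP 8: R_M relaxes to lambda = 1 within 0.1%
  tl8 <- exposure_timeline(0.5, 8)
  tr8 <- simulate_damage(tl8, t_grid = c(0, seq(0.5, 250, by = 2.5)))
  expect_equal(tr8$R_M[nrow(tr8)], 1, tolerance = 1e-3)
})

test_that("repeat exposure is additive inside the recovery phase and not beyond it", {
  grid <- function(t_end) c(0, seq(0.5, t_end, by = 0.5))
  # within the recovery phase (24 h apart): second peak strictly higher
  tl2 <- exposure_timeline(c(0.5, 24.5), c(8, 8))
  tr2 <- simulate_damage(tl2, t_grid = grid(48))
  p1 <- max(tr2$R_M[tr2$time_h < 24.5])
  p2 <- max(tr2$R_M[tr2$time_h >= 24.5])
  expect_gt(p2, p1)
  # far apart and sub-threshold (full recovery): peaks equal
  tl_far <- exposure_timeline(c(0.5, 300.5), c(3, 3))
  tr_far <- simulate_damage(tl_far, t_grid = grid(500))
  q1 <- max(tr_far$R_M[tr_far$time_h < 300])
  q2 <- max(tr_far$R_M[tr_far$time_h >= 300])
  expect_equal(q1, q2, tolerance = 1e-6)
})

test_that("all damage states stay non-negative over random exposure histories", {
  for (seed in 1:4) {
    set.seed(100 + seed)
    n_ev <- sample(1:4, 1)
    tl <- exposure_timeline(sort(runif(n_ev, 1, 40)) + cumsum(rep(0.1, n_ev)),
                            runif(n_ev, 0, 10))
    tr <- simulate_damage(tl, t_grid = c(0, seq(0.5, 60, by = 0.5)))
    expect_true(all(tr$R_M >= 0))
    expect_true(all(tr$R_B1 >= 0))
    expect_true(all(tr$R_B2 >= 0))
  }
})

test_that("numerically integrated damage matches the closed-form solution", {
  tl <- exposure_timeline(c(1, 20), c(8, 6))
  tr <- simulate_damage(tl, t_grid = c(0, seq(0.5, 48, by = 0.5)))
  rm_fun <- mechanical_damage_analytic(tl)
  expect_equal(tr$R_M, rm_fun(tr$time_h), tolerance = 1e-6)
})

test_that("adaptive integration agrees with fixed-step RK4 on pulse-free dynamics", {
  # start from a displaced state with sustained residual damage; no pulse,
  # so a 1e-3 h fixed step resolves everything
  tl <- exposure_timeline(numeric(0), numeric(0), character(0))
  parms <- list(drive = blastkin:::.event_drive(tl, dose_params()),
                damage = damage_params())
  parms$drive$lambdas <- numeric(0)
  rhs <- blastkin:::.damage_rhs
  y0 <- c(5, 2, 1)
  ada <- integrate_system(rhs, y0, times = seq(0, 48, by = 1), parms = parms,
                          rel_tol = 1e-10, abs_tol = 1e-12)
  rk <- rk4_integrate(rhs, y0, 0, 48, dt = 1e-3, parms = parms)
  rk_at <- rk[seq(1, 48001, by = 1000), ]  # rows at whole hours
  expect_equal(unname(ada[, -1]), unname(rk_at[, -1]), tolerance = 1e-4)
})
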