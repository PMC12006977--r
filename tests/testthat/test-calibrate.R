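test_that("the superposition fast path equals the direct objective", {
  co <- small_cohort()
  cfg <- blastkin_config()
  basis <- calibration_basis(co, cfg)
  spec <- calibration_spec()
  for (x in c(0.7, 1.5, 3)) {
    direct <- calibration_objective(x, co, cfg)
    fast <- local({
      aligned_sse <- 0
      obs <- blastkin:::.normalize_observations(co)
      for (id in names(co$scenarios)) {
        sc <- co$scenarios[[id]]
        o <- obs[obs$subject_id == id & obs$draw_label != sc$sample_labels[1], ]
        p <- blastkin:::.basis_normalized(basis[[id]], x)
        m <- match(o$draw_label, basis[[id]]$labels)
        aligned_sse <- aligned_sse + sum((p[m] - o$observed_normalized)^2)
      }
      aligned_sse
    })
    expect_equal(fast, direct, tolerance = 1e-6)
  }
})

test_that("the objective is zero at the generating value and grows away from it", {
  co <- small_cohort()  # generated at x = 1.5, noise-free
  cfg <- blastkin_config()
  at_truth <- calibration_objective(1.5, co, cfg)
  expect_lt(at_truth, 1e-10)
  for (delta in c(0.1, 0.5, 1.0)) {
    expect_gt(calibration_objective(1.5 + delta, co, cfg), at_truth + 1e-8)
    expect_gt(calibration_objective(1.5 - delta, co, cfg), at_truth + 1e-8)
  }
})

test_that("noise-free calibration recovers the generating amplification", {
  fit <- fit_amplification(test_cohort(), basis = test_basis())
  expect_lt(abs(fit$estimate[["x"]] - 1.5), 0.01)
  expect_true(fit$convergence)
  expect_true(all(abs(fit$residuals$residual) < 1e-5))
})

test_that("a null blast effect is recovered as x ~ 0", {
  cfg <- blastkin_config(); cfg$pbpk$x <- 0
  co <- generate_cohort(cohort_design(n_subjects = 2, seed = 5, noise_cv = 0),
                        cfg)
  fit <- fit_amplification(co, blastkin_config())
  expect_lte(fit$estimate[["x"]], 0.01)
})

test_that("calibration without blast exposure is flagged, not fitted", {
  sched <- training_schedule(1, daily_bop = 0)  # no blast signal at all
  sc <- subject_scenario("N1", sched)
  obs <- data.frame(subject_id = "N1",
                    draw_label = sc$sample_labels,
                    time_h = sc$sample_times,
                    abeta42_pg_ml = c(20, 20))
  co <- make_cohort(list(sc), obs)
  expect_error(fit_amplification(co), "identifiable")
})

test_that("fitting is deterministic for a fixed spec", {
  co <- reobserve_cohort(test_cohort(), 0.05, 99)
  f1 <- fit_amplification(co, basis = test_basis())
  f2 <- fit_amplification(co, basis = test_basis())
  expect_identical(f1$estimate, f2$estimate)
  expect_identical(f1$objective, f2$objective)
})

test_that("recovery is unbiased and tight across noise replicates", {
  # 3 cohort designs x 17 noise draws = 51 replicates at 5% CV; the
  # superposition basis makes each refit closed-form
  errs <- c()
  for (ds in 1:3) {
    co <- generate_cohort(cohort_design(n_subjects = 5, seed = 20 + ds,
                                        noise_cv = 0))
    basis <- calibration_basis(co, blastkin_config())
    for (r in 1:17) {
      cor <- reobserve_cohort(co, 0.05, 1000 * ds + r)
      fit <- fit_amplification(cor, basis = basis)
      errs <- c(errs, fit$estimate[["x"]] - 1.5)
    }
  }
  expect_lt(stats::median(abs(errs)), 0.15)
  q <- stats::quantile(errs, c(0.05, 0.95))
  expect_lt(q[[1]], 0)
  expect_gt(q[[2]], 0)
})
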