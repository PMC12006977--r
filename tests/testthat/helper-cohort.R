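# shared fixtures, built once per test run

# study-scale noise-free cohort (15 subjects, 3 days) at the default
# (calibrated) amplification; memoised because generation runs the full model
test_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_cohort(cohort_design(seed = 11, noise_cv = 0),
                                blastkin_config())
    cache
  }
})

# superposition basis for test_cohort under the default config, memoised
test_basis <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- calibration_basis(test_cohort())
    cache
  }
})

# two-subject slice of test_cohort for checks that re-run full simulations
small_cohort <- function() {
  co <- test_cohort()
  ids <- names(co$scenarios)[1:2]
  obs <- co$observations[co$observations$subject_id %in% ids, ]
  truth <- co$truth[co$truth$subject_id %in% ids, ]
  make_cohort(co$scenarios[ids], obs, truth = truth)
}

# one-subject scenario with a single supra-threshold training day
one_day_scenario <- function(bop = 8) {
  subject_scenario("T1", training_schedule(1, daily_bop = bop))
}

# brute-force exact signed-rank null: enumerate all 2^n sign assignments
# (average ranks for ties, zeros dropped before calling)
enumerate_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Ws <- as.vector(signs %*% r)
  mu <- sum(r) / 2
  mean(abs(Ws - mu) >= abs(W - mu) - 1e-9)
}
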