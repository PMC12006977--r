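test_that("relative percent error follows the over-approximation sign convention", {
  expect_equal(relative_percent_error(1, 1), 0)
  expect_equal(relative_percent_error(1.2, 1.0), 20)
  expect_equal(relative_percent_error(0.883, 1.0), -11.7)
  expect_error(relative_percent_error(1, 0), "observed")
})

toy_table <- function(e) {
  # single-subject table with the same value in all five error slots unless
  # a length-5 vector is given
  if (length(e) == 1) e <- rep(e, 5)
  validation_table(data.frame(subject_id = "t", age = 40, service_years = 10,
                              d1_post = e[1], d2_pre = e[2], d2_post = e[3],
                              d3_pre = e[4], d3_post = e[5]))
}

test_that("error summaries use absolute values and both SD conventions", {
  s <- summarize_errors(toy_table(7))
  expect_equal(s$mean_abs, 7)
  expect_equal(s$sd_abs, 0)
  # symmetric signed entries: mean |e| = a, SD 0
  s2 <- summarize_errors(toy_table(c(3, -3, 3, -3, 3)))
  expect_equal(s2$mean_abs, 3)
  expect_equal(s2$sd_abs, 0)
  # invariant under sign flips
  t1 <- toy_table(c(1, -2, 3, -4, 5))
  t2 <- toy_table(c(-1, 2, -3, 4, -5))
  expect_equal(summarize_errors(t1), summarize_errors(t2))
})

test_that("over-approximation counts strict positivity and partitions to one", {
  tab <- validation_table(data.frame(
    subject_id = c("a", "b"), age = c(40, 41), service_years = c(10, 11),
    d1_post = c(1, 1), d2_pre = c(1, -1), d2_post = c(1, 1),
    d3_pre = c(2, 0), d3_post = c(1, 1)))
  fo <- fraction_overapproximated(tab, "pre")
  expect_equal(fo$fraction, 2 / 4)  # zero counts as not over-approximated
  expect_equal(fo$numerator, 2)
  e <- as.matrix(tab[c("d2_pre", "d3_pre")])
  expect_equal(mean(e > 0) + mean(e < 0) + mean(e == 0), 1)
  all_neg <- toy_table(c(-1, -2, -3, -4, -5))
  expect_equal(fraction_overapproximated(all_neg, "pre")$fraction, 0)
})

test_that("regression diagnostics behave at the extremes", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(regression_r2(x, 2 * x + 1)$r_squared, 1)
  expect_equal(regression_r2(x, rep(4, 5))$r_squared, 0)
  expect_error(regression_r2(rep(2, 5), x), "constant")
  r <- regression_r2(x, c(1.1, 2.3, 2.9, 4.2, 4.8))
  expect_equal(r$pearson_r^2, r$r_squared, tolerance = 1e-12)
})

test_that("the packaged cohort table reproduces its printed summaries", {
  tab <- load_validation_errors()
  expect_equal(nrow(tab), 15)
  rep <- validation_report(tab)
  expect_equal(rep$mean_abs_error_pct, 6.5, tolerance = 0.01)
  expect_equal(rep$sd_abs_error_pct, 5.2, tolerance = 0.01)
  expect_equal(rep$sd_abs_error_pct_sample, 5.2, tolerance = 0.05)
  expect_lt(rep$wilcoxon$p, 0.01)
  expect_equal(rep$frac_pre_overapprox, 0.8)
  expect_lt(rep$r2_age, 0.1)
  expect_lt(rep$r2_service, 0.1)
})

test_that("self-consistent predictions give an all-zero validation table", {
  co <- test_cohort()  # noise-free observations = model truth
  tab <- build_validation_table(co)
  e <- as.matrix(tab[c("d1_post", "d2_pre", "d2_post", "d3_pre", "d3_post")])
  expect_lt(max(abs(e)), 0.01)  # percent units
})

test_that("incomplete tables are rejected with the offending subjects", {
  bad <- data.frame(subject_id = c("a", "b"), age = 1:2, service_years = 1:2,
                    d1_post = c(1, NA), d2_pre = 1:2, d2_post = 1:2,
                    d3_pre = 1:2, d3_post = 1:2)
  expect_error(validation_table(bad), "b")
  expect_error(validation_table(bad[-4]), "d1_post")
})
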