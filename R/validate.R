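#' Signed relative percent error
#'
#' `100 * (predicted - observed) / observed` on normalized serum
#' concentrations. Positive values mean the model over-approximates the
#' measurement.
#'
#' @param predicted,observed Normalized concentrations (`observed > 0`).
#' @return Signed percent error, same length as the inputs.
#' @export
#' @examples
#' relative_percent_error(1.2, 1.0)    # +20
#' relative_percent_error(0.883, 1.0)  # -11.7
relative_percent_error <- function(predicted, observed) {
  if (any(observed <= 0)) stop("'observed' must be > 0", call. = FALSE)
  100 * (predicted - observed) / observed
}

.err_cols <- c("d1_post", "d2_pre", "d2_post", "d3_pre", "d3_post")
.pre_cols <- c("d2_pre", "d3_pre")
.post_cols <- c("d1_post", "d2_post", "d3_post")

#' Per-subject validation error table
#'
#' Columns: `subject_id`, `age`, `service_years`, then one signed relative
#' percent error per non-baseline draw of the three-day design
#' (`d1_post`, `d2_pre`, `d2_post`, `d3_pre`, `d3_post`). The day-one
#' pre-training error is identically zero by normalization and is not
#' tabulated.
#'
#' @param df Data frame with the columns above.
#' @return The validated table, classed `validation_table`.
#' @export
validation_table <- function(df) {
  need <- c("subject_id", "age", "service_years", .err_cols)
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("validation table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  bad <- df$subject_id[!stats::complete.cases(df[.err_cols])]
  if (length(bad))
    stop("missing error entries for subject(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  structure(df[need], class = c("validation_table", "data.frame"))
}

#' Packaged per-subject validation errors
#'
#' Loads the packaged table of relative percent errors of predicted serum
#' Abeta42 for the 15-subject, three-day 0.50-caliber weapons-training
#' cohort (five timepoints per subject plus age and duration of service).
#'
#' @return A `validation_table`.
#' @export
load_validation_errors <- function() {
  path <- system.file("extdata", "validation_errors.csv", package = "blastkin",
                      mustWork = TRUE)
  validation_table(utils::read.csv(path))
}

#' Cohort error summary
#'
#' Mean and standard deviation of the absolute values of all tabulated
#' errors (75 entries for the full cohort). Both the population SD
#' (divisor n, the default summary) and the sample SD (divisor n - 1) are
#' returned.
#'
#' @param table A `validation_table`.
#' @return List `mean_abs`, `sd_abs` (population), `sd_abs_sample`, `n`.
#' @export
summarize_errors <- function(table) {
  table <- validation_table(table)
  e <- abs(as.matrix(table[.err_cols]))
  n <- length(e)
  m <- mean(e)
  list(mean_abs = m,
       sd_abs = sqrt(mean((e - m)^2)),
       sd_abs_sample = stats::sd(e),
       n = n)
}

#' Pre- vs post-training prediction accuracy contrast
#'
#' For each subject, the mean absolute error over the pre-training draws
#' (days 2-3) is paired with the mean absolute error over the
#' post-training draws (days 1-3), and the paired difference is tested
#' with the exact two-sided Wilcoxon signed-rank test.
#'
#' @param table A `validation_table`.
#' @return A `wilcoxon_result` (see [wilcoxon_signed_rank_exact()]) with an
#'   added `pairs` data frame of the per-subject means.
#' @export
pre_post_comparison <- function(table) {
  table <- validation_table(table)
  pre <- rowMeans(abs(table[.pre_cols]))
  post <- rowMeans(abs(table[.post_cols]))
  res <- wilcoxon_signed_rank_exact(pre, post)
  res$pairs <- data.frame(subject_id = table$subject_id,
                          mean_abs_pre = pre, mean_abs_post = post)
  res
}

#' Fraction of over-approximated entries
#'
#' Share of strictly positive signed errors among the selected entries
#' (zero counts as not over-approximated). Pre-training entries are the
#' day-2 and day-3 pre-training columns.
#'
#' @param table A `validation_table`.
#' @param which `"pre"`, `"post"`, or `"all"`.
#' @return List `fraction`, `numerator`, `denominator`.
#' @export
fraction_overapproximated <- function(table, which = c("pre", "post", "all")) {
  which <- match.arg(which)
  table <- validation_table(table)
  cols <- switch(which, pre = .pre_cols, post = .post_cols, all = .err_cols)
  e <- as.matrix(table[cols])
  list(fraction = mean(e > 0), numerator = sum(e > 0), denominator = length(e))
}

#' Coefficient of determination of a simple linear regression
#'
#' OLS of `y` on `x`; returns R-squared along with the slope and Pearson
#' correlation so the strength and direction of the association are both
#' visible.
#'
#' @param x Covariate (one value per subject; must not be constant).
#' @param y Response (e.g., per-subject mean pre-training absolute error).
#' @return List `r_squared`, `slope`, `intercept`, `pearson_r`, `n`.
#' @export
regression_r2 <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3)
    stop("need at least 3 paired values", call. = FALSE)
  if (stats::sd(x) == 0)
    stop("covariate is constant; slope undefined", call. = FALSE)
  if (stats::sd(y) == 0)  # no variance to explain; avoid a 0/0 from lm
    return(list(r_squared = 0, slope = 0, intercept = y[1],
                pearson_r = NA_real_, n = length(x)))
  fit <- stats::lm(y ~ x)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  list(r_squared = 1 - ss_res / ss_tot,
       slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       pearson_r = stats::cor(x, y),
       n = length(x))
}

#' Full validation report
#'
#' All cohort-level validation statistics in one list: error summary,
#' pre/post Wilcoxon contrast, pre-training over-approximation fraction,
#' and regressions of per-subject mean pre-training absolute error on age
#' and on duration of service.
#'
#' @param table A `validation_table`.
#' @return A named list mirroring the JSON report layout.
#' @export
validation_report <- function(table) {
  table <- validation_table(table)
  s <- summarize_errors(table)
  w <- pre_post_comparison(table)
  fo <- fraction_overapproximated(table, "pre")
  pre <- rowMeans(abs(table[.pre_cols]))
  list(
    mean_abs_error_pct = s$mean_abs,
    sd_abs_error_pct = s$sd_abs,
    sd_abs_error_pct_sample = s$sd_abs_sample,
    wilcoxon = list(W = w$statistic, n = w$n_effective, p = w$p_two_sided),
    frac_pre_overapprox = fo$fraction,
    r2_age = regression_r2(table$age, pre)$r_squared,
    r2_service = regression_r2(table$service_years, pre)$r_squared
  )
}

#' Validation table from a cohort and model predictions
#'
#' Runs [predict_serum()] for every subject of a cohort, normalizes the
#' observed draws to each subject's first draw, and tabulates the signed
#' relative percent errors at the five non-baseline draws of the three-day
#' design.
#'
#' @param cohort A `blastkin_cohort` with a three-day (6 draw) design.
#' @param config Model configuration.
#' @return A `validation_table`.
#' @export
build_validation_table <- function(cohort, config = blastkin_config()) {
  stopifnot(inherits(cohort, "blastkin_cohort"))
  obs <- .normalize_observations(cohort)
  rows <- lapply(names(cohort$scenarios), function(id) {
    sc <- cohort$scenarios[[id]]
    pred <- predicted_draws(predict_serum(sc, config, dense = FALSE))
    o <- obs[obs$subject_id == id, , drop = FALSE]
    row <- data.frame(subject_id = id, age = sc$age,
                      service_years = sc$service_years)
    for (lab in .err_cols) {
      p <- pred$serum_normalized[match(lab, pred$sample_label)]
      yv <- o$observed_normalized[match(lab, o$draw_label)]
      if (is.na(p) || is.na(yv))
        stop("subject ", id, " lacks draw '", lab, "'", call. = FALSE)
      row[[lab]] <- relative_percent_error(p, yv)
    }
    row
  })
  validation_table(do.call(rbind, rows))
}
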