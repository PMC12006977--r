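#' Synthetic cohort design
#'
#' Study-design distributions for the synthetic-cohort generator, matching
#' the three-day, 15-subject 0.50-caliber weapons-training layout: 6 h of
#' training per day, pre-training draws 2.1-3.16 h before training start,
#' post-training draws 0.48-2.90 h after training end, 4-50 shots per day,
#' and daily average BOPs spanning 3-8 psi (bracketing the 4-psi injury
#' threshold and the 5-12 psi range over which APP disruption scales with
#' overpressure). Measurement noise is multiplicative lognormal with a 5%
#' CV, a typical immunoassay figure.
#'
#' @param n_subjects,n_days Cohort size and training days.
#' @param bop_range Daily average BOP range, psi (uniform).
#' @param shots_range Shots per day (integer uniform).
#' @param pre_offset_range,post_offset_range Draw-offset ranges, h (uniform,
#'   drawn per day).
#' @param age_range,service_range Demographic ranges, years (integer
#'   uniform, independent of exposure).
#' @param noise_cv Fractional CV of the multiplicative lognormal noise.
#' @param seed Integer seed; the cohort is reproducible from
#'   (design, seed, config).
#' @return A list of class `cohort_design`.
#' @export
cohort_design <- function(n_subjects = 15, n_days = 3, bop_range = c(3, 8),
                          shots_range = c(4, 50),
                          pre_offset_range = c(2.10, 3.16),
                          post_offset_range = c(0.48, 2.90),
                          age_range = c(33, 52), service_range = c(8, 26),
                          noise_cv = 0.05, seed = 1L) {
  stopifnot(n_subjects >= 1, n_days >= 1, noise_cv >= 0,
            diff(bop_range) > 0, diff(shots_range) > 0,
            diff(pre_offset_range) > 0, diff(post_offset_range) > 0,
            diff(age_range) > 0, diff(service_range) > 0)
  structure(list(n_subjects = as.integer(n_subjects),
                 n_days = as.integer(n_days), bop_range = bop_range,
                 shots_range = shots_range,
                 pre_offset_range = pre_offset_range,
                 post_offset_range = post_offset_range,
                 age_range = age_range, service_range = service_range,
                 noise_cv = noise_cv, seed = as.integer(seed)),
            class = "cohort_design")
}

# run fn with a private RNG stream; the caller's RNG state is untouched
.with_seed <- function(seed, fn) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}

#' Draw the study-design variables of a synthetic cohort
#'
#' Draws per-subject daily BOPs, shot counts, per-day draw offsets, and
#' demographics from the design's ranges using a seeded generator, without
#' running the model. Demographics are drawn independently of exposure, so
#' regressions of model error on age or service have a near-zero true
#' R-squared.
#'
#' @param design A [cohort_design()].
#' @param training_start_hour Clock hour training starts.
#' @return Named list of [subject_scenario()] objects.
#' @export
draw_scenarios <- function(design, training_start_hour = 9) {
  stopifnot(inherits(design, "cohort_design"))
  .with_seed(design$seed, function() {
    lapply(stats::setNames(seq_len(design$n_subjects),
                           sprintf("S%02d", seq_len(design$n_subjects))),
           function(i) {
      nd <- design$n_days
      sched <- training_schedule(
        n_days = nd,
        daily_bop = stats::runif(nd, design$bop_range[1], design$bop_range[2]),
        shots_per_day = sample(design$shots_range[1]:design$shots_range[2], nd,
                               replace = TRUE),
        training_start_hour = training_start_hour,
        pre_draw_offset = stats::runif(nd, design$pre_offset_range[1],
                                       design$pre_offset_range[2]),
        post_draw_offset = stats::runif(nd, design$post_offset_range[1],
                                        design$post_offset_range[2])
      )
      subject_scenario(
        subject_id = sprintf("S%02d", i), schedule = sched,
        age = sample(design$age_range[1]:design$age_range[2], 1),
        service_years = sample(design$service_range[1]:design$service_range[2], 1)
      )
    })
  })
}

#' Generate a synthetic cohort with model-based observations
#'
#' Draws the study design ([draw_scenarios()]), computes each subject's
#' noise-free serum trajectory with [predict_serum()], and produces
#' observations as the truth at the draw times multiplied by lognormal
#' noise with CV `noise_cv` and mean 1. With `noise_cv = 0` the
#' observations equal the truth exactly.
#'
#' @param design A [cohort_design()].
#' @param config Model configuration (its `pbpk$x` is the generating
#'   amplification constant).
#' @return A `blastkin_cohort` with `truth` (noise-free draws),
#'   `observations`, `design`, `seed`, and a `provenance` attribute
#'   (design + seed + config fingerprint).
#' @export
generate_cohort <- function(design = cohort_design(),
                            config = blastkin_config()) {
  validate_config(config)
  scenarios <- draw_scenarios(design, config$simulation$training_start_hour)
  truth <- do.call(rbind, lapply(scenarios, function(sc) {
    d <- predicted_draws(predict_serum(sc, config, dense = FALSE))
    data.frame(subject_id = sc$subject_id, draw_label = d$sample_label,
               time_h = d$time_h, abeta42_pg_ml = d$serum_pg_ml,
               abeta42_normalized = d$serum_normalized)
  }))
  rownames(truth) <- NULL
  n <- nrow(truth)
  noise <- if (design$noise_cv > 0) {
    sigma2 <- log(1 + design$noise_cv^2)
    # derive the observation stream from the design seed, offset so it does
    # not replay the design draws
    .with_seed(design$seed + 1000003L,
               function() exp(stats::rnorm(n, -sigma2 / 2, sqrt(sigma2))))
  } else rep(1, n)
  obs <- truth[c("subject_id", "draw_label", "time_h")]
  obs$abeta42_pg_ml <- truth$abeta42_pg_ml * noise
  cohort <- make_cohort(scenarios, obs, truth = truth, design = design,
                        seed = design$seed)
  attr(cohort, "provenance") <- list(
    design = unclass(design), seed = design$seed,
    config_hash = config_hash(config))
  cohort
}

#' Re-draw measurement noise on an existing cohort
#'
#' Produces a new `blastkin_cohort` with identical scenarios and truth but
#' a fresh lognormal observation draw; used for noise-replicate studies of
#' calibration recovery.
#'
#' @param cohort A `blastkin_cohort` with `truth` present.
#' @param noise_cv Fractional CV of the multiplicative lognormal noise.
#' @param seed Integer seed for the new draw.
#' @return A `blastkin_cohort`.
#' @export
reobserve_cohort <- function(cohort, noise_cv, seed) {
  stopifnot(inherits(cohort, "blastkin_cohort"))
  if (is.null(cohort$truth)) stop("cohort has no truth table", call. = FALSE)
  truth <- cohort$truth
  noise <- if (noise_cv > 0) {
    sigma2 <- log(1 + noise_cv^2)
    .with_seed(as.integer(seed),
               function() exp(stats::rnorm(nrow(truth), -sigma2 / 2, sqrt(sigma2))))
  } else rep(1, nrow(truth))
  obs <- truth[c("subject_id", "draw_label", "time_h")]
  obs$abeta42_pg_ml <- truth$abeta42_pg_ml * noise
  make_cohort(cohort$scenarios, obs, truth = truth, design = cohort$design,
              seed = as.integer(seed))
}

#' Export a cohort to CSV files
#'
#' Writes `exposures.csv` and `serum.csv` in the schemas consumed by the
#' reading functions, plus `truth.csv` (when present) and
#' `provenance.json`.
#'
#' @param cohort A `blastkin_cohort`.
#' @param dir Output directory (created if needed).
#' @return Named vector of file paths, invisibly.
#' @export
export_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "blastkin_cohort"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  exp_rows <- do.call(rbind, lapply(cohort$scenarios, function(sc) {
    s <- sc$schedule
    if (s$n_days == 0) return(NULL)
    data.frame(subject_id = sc$subject_id, day = seq_len(s$n_days),
               avg_bop_psi = s$daily_bop, shots = s$shots_per_day,
               training_start = s$training_start_hour,
               training_hours = s$training_duration)
  }))
  if (is.null(exp_rows))
    exp_rows <- data.frame(subject_id = character(0), day = integer(0),
                           avg_bop_psi = numeric(0), shots = integer(0),
                           training_start = numeric(0),
                           training_hours = numeric(0))
  paths <- c(exposures = file.path(dir, "exposures.csv"),
             serum = file.path(dir, "serum.csv"),
             truth = file.path(dir, "truth.csv"),
             provenance = file.path(dir, "provenance.json"))
  utils::write.csv(exp_rows, paths["exposures"], row.names = FALSE)
  utils::write.csv(cohort$observations, paths["serum"], row.names = FALSE)
  if (!is.null(cohort$truth))
    utils::write.csv(cohort$truth, paths["truth"], row.names = FALSE)
  prov <- attr(cohort, "provenance")
  if (is.null(prov)) prov <- list(seed = cohort$seed)
  jsonlite::write_json(prov, paths["provenance"], auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(paths)
}

#' Rebuild a cohort from exported CSV files
#'
#' Reconstructs scenarios from an exposures table and attaches serum
#' observations; draw times are taken from the serum table so the
#' round trip `export_cohort()` -> `cohort_from_files()` reproduces the
#' original draws exactly.
#'
#' @param exposures Exposures data frame (see [read_exposures_csv()]) or a
#'   path to the CSV.
#' @param serum Serum data frame (see [read_serum_csv()]) or a path.
#' @return A `blastkin_cohort`.
#' @export
cohort_from_files <- function(exposures, serum) {
  if (is.character(exposures)) exposures <- read_exposures_csv(exposures)
  if (is.character(serum)) serum <- read_serum_csv(serum)
  scenarios <- lapply(split(exposures, exposures$subject_id), function(e) {
    e <- e[order(e$day), , drop = FALSE]
    s <- serum[serum$subject_id == e$subject_id[1], , drop = FALSE]
    s <- s[order(s$time_h), , drop = FALSE]
    subject_scenario(
      subject_id = e$subject_id[1],
      schedule = training_schedule(
        n_days = nrow(e), daily_bop = e$avg_bop_psi,
        shots_per_day = e$shots,
        training_start_hour = e$training_start[1],
        training_duration = e$training_hours[1]),
      sample_times = s$time_h, sample_labels = s$draw_label)
  })
  make_cohort(scenarios, serum)
}
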