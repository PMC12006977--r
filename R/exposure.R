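#' Dose-conversion parameters
#'
#' Parameters mapping a blast overpressure (BOP, psi) to the drive of the
#' mechanical-damage state: the non-dimensional injury threshold (set to 4,
#' proportional to 4 psi), the residual-damage gain above threshold, the
#' rise time constant of the source pulse, and the amplitude scale
#' (non-dimensional damage per psi).
#'
#' @param threshold Injury threshold (non-dimensional, equal to psi under
#'   the default `dose_scale = 1`).
#' @param lambda_gain Residual damage per psi of exceedance above threshold.
#' @param rise_tau_s First-order rise time constant, seconds. The default
#'   0.0383 s puts the damage peak at ~0.5 s for the default decay rate.
#' @param dose_scale Non-dimensional peak damage per psi.
#' @param mode Default timeline construction mode, see [build_timeline()].
#' @return A list of class `dose_params`.
#' @export
dose_params <- function(threshold = 4, lambda_gain = 0.25, rise_tau_s = 0.0383,
                        dose_scale = 1.0, mode = "daily_aggregate") {
  stopifnot(threshold > 0, lambda_gain >= 0, rise_tau_s > 0, dose_scale > 0)
  mode <- match.arg(mode, c("daily_aggregate", "per_shot"))
  structure(list(threshold = threshold, lambda_gain = lambda_gain,
                 rise_tau_s = rise_tau_s, dose_scale = dose_scale, mode = mode),
            class = "dose_params")
}

#' Residual damage left by a blast
#'
#' The long-time mechanical damage after a single exposure: zero at or below
#' the injury threshold (full recovery), and proportional to the exceedance
#' above it (chronic residual damage, growing with blast magnitude). The map
#' is continuous and piecewise linear in BOP.
#'
#' @param bop Peak blast overpressure, psi (scalar or vector, `>= 0`).
#' @param params A [dose_params()] object.
#' @return Residual damage lambda (non-dimensional), same length as `bop`.
#' @export
#' @examples
#' residual_damage(3, dose_params())  # below threshold: 0
#' residual_damage(8, dose_params())  # (8 - 4) * 0.25 = 1
residual_damage <- function(bop, params = dose_params()) {
  if (!is.numeric(bop) || any(!is.finite(bop)) || any(bop < 0))
    stop("'bop' must be finite and >= 0", call. = FALSE)
  params$lambda_gain * pmax(0, bop * params$dose_scale - params$threshold)
}

#' Weapons-training schedule for one subject
#'
#' Describes an n-day training design: daily average BOP, shots fired, the
#' daily 6-h training window, and blood-draw offsets before training start
#' and after training end. Offsets may be scalars (applied to every day) or
#' per-day vectors.
#'
#' @param n_days Number of training days.
#' @param daily_bop Average BOP per day, psi (length `n_days`).
#' @param shots_per_day Shots fired per day (length `n_days`, default 20).
#' @param training_start_hour Clock hour training starts each day.
#' @param training_duration Training length, h.
#' @param pre_draw_offset Hours before training start of the pre-training
#'   draw (cohort average 2.48 h).
#' @param post_draw_offset Hours after training end of the post-training
#'   draw (cohort average 1.40 h).
#' @return A list of class `training_schedule`.
#' @export
training_schedule <- function(n_days, daily_bop, shots_per_day = NULL,
                              training_start_hour = 9, training_duration = 6,
                              pre_draw_offset = 2.48, post_draw_offset = 1.40) {
  stopifnot(n_days >= 0, training_duration > 0)
  if (n_days == 0) {
    daily_bop <- numeric(0)
    shots_per_day <- integer(0)
  }
  if (is.null(shots_per_day)) shots_per_day <- rep(20L, n_days)
  if (length(daily_bop) != n_days)
    stop("'daily_bop' must have length n_days", call. = FALSE)
  if (length(shots_per_day) != n_days)
    stop("'shots_per_day' must have length n_days", call. = FALSE)
  if (any(shots_per_day < 0)) stop("'shots_per_day' must be >= 0", call. = FALSE)
  if (any(daily_bop < 0)) stop("'daily_bop' must be >= 0", call. = FALSE)
  rep_day <- function(x) if (length(x) == 1) rep(x, max(n_days, 1)) else x
  pre <- rep_day(pre_draw_offset); post <- rep_day(post_draw_offset)
  if (any(pre <= 0) || any(post <= 0))
    stop("draw offsets must be > 0", call. = FALSE)
  structure(list(n_days = as.integer(n_days), daily_bop = daily_bop,
                 shots_per_day = as.integer(shots_per_day),
                 training_start_hour = training_start_hour,
                 training_duration = training_duration,
                 pre_draw_offset = pre, post_draw_offset = post),
            class = "training_schedule")
}

#' Convert a training schedule to an exposure timeline
#'
#' In `daily_aggregate` mode (the default, matching the use of the daily
#' average BOP as the dose input) each training day contributes one blast
#' event at the midpoint of its training window with that day's average BOP.
#' In `per_shot` mode each day contributes `shots_per_day` events uniformly
#' spaced across the window, each at the day's average BOP, for sensitivity
#' studies of within-day repetition.
#'
#' @param schedule A [training_schedule()].
#' @param mode `"daily_aggregate"` or `"per_shot"`.
#' @return A data frame of class `exposure_timeline` with columns `time_h`
#'   (study clock, strictly increasing), `overpressure_psi`, and `label`.
#' @export
build_timeline <- function(schedule, mode = c("daily_aggregate", "per_shot")) {
  mode <- match.arg(mode)
  stopifnot(inherits(schedule, "training_schedule"))
  rows <- vector("list", schedule$n_days)
  for (d in seq_len(schedule$n_days)) {
    day_start <- (d - 1) * 24 + schedule$training_start_hour
    dur <- schedule$training_duration
    if (mode == "daily_aggregate") {
      t_ev <- day_start + dur / 2
    } else {
      n <- schedule$shots_per_day[d]
      if (n == 0) { rows[[d]] <- NULL; next }
      # shots at centres of n equal sub-intervals of the training window
      t_ev <- day_start + dur * (seq_len(n) - 0.5) / n
    }
    rows[[d]] <- data.frame(time_h = t_ev,
                            overpressure_psi = schedule$daily_bop[d],
                            label = sprintf("day%d", d))
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(time_h = numeric(0), overpressure_psi = numeric(0),
                      label = character(0))
  out <- out[order(out$time_h), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("exposure_timeline", "data.frame")
  out
}

#' Assemble an exposure timeline from explicit events
#'
#' @param time_h Event times on the study clock, strictly increasing.
#' @param overpressure_psi Peak BOP per event, psi.
#' @param label Optional event labels.
#' @return An `exposure_timeline` data frame.
#' @export
exposure_timeline <- function(time_h, overpressure_psi,
                              label = sprintf("event%d", seq_along(time_h))) {
  stopifnot(length(time_h) == length(overpressure_psi))
  if (any(!is.finite(time_h))) stop("event times must be finite", call. = FALSE)
  if (any(overpressure_psi < 0)) stop("overpressure must be >= 0", call. = FALSE)
  if (length(time_h) > 1 && any(diff(time_h) <= 0))
    stop("event times must be strictly increasing", call. = FALSE)
  structure(data.frame(time_h = time_h, overpressure_psi = overpressure_psi,
                       label = label),
            class = c("exposure_timeline", "data.frame"))
}
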