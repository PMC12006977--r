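#' Damage and biological-response kinetic parameters
#'
#' Rate constants of the three-state injury model: mechanical damage `R_M`
#' decays at rate `alpha / t_d` toward the residual damage lambda; the
#' hyperacute response `R_B1` is driven by `R_M` at rate `k_in` and cleared
#' at rate `k_out1 / (R_M + R_M0)` (clearance slows while damage persists,
#' prolonging recovery); the acute response `R_B2` integrates `R_B1` at rate
#' `k_out1` and clears at `k_out2`.
#'
#' @param alpha Damage decay coefficient (non-dimensional).
#' @param t_d_h Characteristic impulse-recovery time, h.
#' @param k_in Hyperacute drive rate, 1/h.
#' @param k_out1 Hyperacute clearance / acute drive rate, 1/h.
#' @param k_out2 Acute clearance rate, 1/h.
#' @param R_M0 Basal mechanical repair (non-dimensional, default 1).
#' @return A list of class `damage_params`.
#' @export
damage_params <- function(alpha = 0.2, t_d_h = 1.0, k_in = 1.0, k_out1 = 0.5,
                          k_out2 = 0.1, R_M0 = 1.0) {
  vals <- c(alpha = alpha, t_d_h = t_d_h, k_in = k_in, k_out1 = k_out1,
            k_out2 = k_out2, R_M0 = R_M0)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all damage parameters must be finite and > 0", call. = FALSE)
  structure(as.list(vals), class = "damage_params")
}

#' Mechanical-damage derivative
#'
#' `dR_M/dt = source - (alpha / t_d) * (R_M - lambda)`. With no source and
#' `lambda = 0`, damage decays exponentially to zero (full recovery below
#' the injury threshold); with `lambda > 0` it relaxes to the residual
#' damage, the stable fixed point representing chronic injury.
#'
#' @param R_M Current mechanical damage.
#' @param lambda Residual damage in effect.
#' @param source Instantaneous source term, 1/h (blast rise pulse).
#' @param params A [damage_params()] object.
#' @return dR_M/dt, 1/h.
#' @export
rm_rhs <- function(R_M, lambda = 0, source = 0, params = damage_params()) {
  source - (params$alpha / params$t_d_h) * (R_M - lambda)
}

#' Biological-response derivatives
#'
#' `dR_B1/dt = k_in R_M - k_out1 R_B1 / (R_M + R_M0)` and
#' `dR_B2/dt = k_out1 R_B1 - k_out2 R_B2`. Both responses stay non-negative
#' from non-negative initial states. Under sustained damage `R_M = lambda`
#' the fixed points are `R_B1* = k_in lambda (lambda + R_M0) / k_out1` and
#' `R_B2* = k_out1 R_B1* / k_out2`.
#'
#' @param R_M,R_B1,R_B2 Current states (non-negative).
#' @param params A [damage_params()] object.
#' @return Named vector `c(dR_B1, dR_B2)`, 1/h.
#' @export
rb_rhs <- function(R_M, R_B1, R_B2, params = damage_params()) {
  dB1 <- params$k_in * R_M - params$k_out1 * R_B1 / (R_M + params$R_M0)
  dB2 <- params$k_out1 * R_B1 - params$k_out2 * R_B2
  c(dR_B1 = dB1, dR_B2 = dB2)
}

# Per-event drive terms: amplitudes (non-dimensional), residual damages, and
# the rise time constant in hours. lambda in effect at time t is the maximum
# residual over events that have occurred.
.event_drive <- function(timeline, dose) {
  list(
    times = timeline$time_h,
    amps = dose$dose_scale * timeline$overpressure_psi,
    lambdas = residual_damage(timeline$overpressure_psi, dose),
    tau_h = dose$rise_tau_s / 3600
  )
}

# source(t) = sum_i A_i/tau * exp(-(t - t_i)/tau) over past events; the pulse
# integrates to A_i so the damage peak amplitude is ~A_i (decay is slow on
# the rise timescale)
.blast_source <- function(t, drive) {
  # `on` flags events activated for the current integration segment (set by
  # the segment hook): a pulse starts exactly at its segment boundary and is
  # invisible to the preceding segment, keeping every segment's RHS smooth
  past <- if (!is.null(drive$on)) drive$on else drive$times < t
  if (!any(past)) return(0)
  dt <- pmax(t - drive$times[past], 0) / drive$tau_h
  sum(drive$amps[past] * exp(-pmin(dt, 700))) / drive$tau_h
}

.lambda_at <- function(t, drive) {
  past <- if (!is.null(drive$on)) drive$on else drive$times < t
  if (!any(past)) 0 else max(drive$lambdas[past])
}

# activate the pulses of all events at or before the segment start
.drive_segment_setup <- function(parms, lo) {
  parms$drive$on <- parms$drive$times <= lo + 1e-9
  parms
}

# deSolve RHS for the three damage states
.damage_rhs <- function(t, y, parms) {
  drive <- parms$drive
  p <- parms$damage
  src <- .blast_source(t, drive)
  lam <- .lambda_at(t, drive)
  dRM <- rm_rhs(y[1], lam, src, p)
  dB <- rb_rhs(y[1], y[2], y[3], p)
  list(c(dRM, dB[1], dB[2]))
}

#' Integrate the damage/response system over an exposure timeline
#'
#' Each blast event injects a first-order source pulse (time constant
#' `dose$rise_tau_s`) whose amplitude equals `dose_scale * BOP`, producing a
#' damage peak ~0.5 s after the event; the residual damage in effect is the
#' maximum lambda over events so far. State is continuous across events, so
#' a repeat exposure inside the recovery phase adds onto unresolved damage
#' (additive superposition). The output grid is refined to millisecond
#' resolution around each event so the peaks are resolved.
#'
#' @param timeline An `exposure_timeline` (see [build_timeline()]).
#' @param params A [damage_params()] object.
#' @param dose A [dose_params()] object.
#' @param t_grid Output times, h; must be increasing and cover all events.
#' @param y0 Initial `c(R_M, R_B1, R_B2)` (default rest state).
#' @param rel_tol,abs_tol Integrator tolerances.
#' @param refine_window_s,refine_dt_s Width and spacing of the refined
#'   output grid after each event, seconds.
#' @return A data frame of class `damage_trajectory` with columns `time_h`,
#'   `R_M`, `R_B1`, `R_B2`.
#' @export
simulate_damage <- function(timeline, params = damage_params(),
                            dose = dose_params(),
                            t_grid = seq(0, 48, by = 0.1),
                            y0 = c(0, 0, 0),
                            rel_tol = 1e-8, abs_tol = 1e-10,
                            refine_window_s = 2, refine_dt_s = 0.001) {
  stopifnot(inherits(timeline, "data.frame"))
  if (is.unsorted(t_grid, strictly = TRUE))
    stop("'t_grid' must be strictly increasing", call. = FALSE)
  ev <- timeline$time_h
  if (length(ev) && (min(ev) < min(t_grid) || max(ev) > max(t_grid)))
    stop("all event times must lie within 't_grid'", call. = FALSE)
  drive <- .event_drive(timeline, dose)
  times <- .refine_times(t_grid, ev, refine_window_s, refine_dt_s)
  out <- integrate_system(.damage_rhs, y0, times, event_times = ev,
                          parms = list(drive = drive, damage = params),
                          rel_tol = rel_tol, abs_tol = abs_tol,
                          hini = if (length(ev)) drive$tau_h / 20 else 0,
                          segment_setup = .drive_segment_setup)
  traj <- data.frame(time_h = out[, 1],
                     R_M = .clamp0(out[, 2]),
                     R_B1 = .clamp0(out[, 3]),
                     R_B2 = .clamp0(out[, 4]))
  class(traj) <- c("damage_trajectory", "data.frame")
  traj
}

#' Closed-form mechanical damage over an exposure timeline
#'
#' The damage equation is linear, so its solution is available exactly by
#' superposition: each event contributes a rise-and-decay pulse
#' `A (exp(-k dt) - exp(-dt/tau)) / (1 - k tau)` and the relaxation toward
#' the piecewise-constant residual damage is piecewise exponential. Used to
#' drive the coupled serum simulation (the millisecond rise never enters
#' the numeric integrator) and as an analytic oracle for the numerically
#' integrated damage state.
#'
#' @param timeline An `exposure_timeline`.
#' @param params A [damage_params()] object.
#' @param dose A [dose_params()] object.
#' @return A vectorized function `R_M(t)` of study-clock time in hours.
#' @export
mechanical_damage_analytic <- function(timeline, params = damage_params(),
                                       dose = dose_params()) {
  drive <- .event_drive(timeline, dose)
  k <- params$alpha / params$t_d_h
  tau <- drive$tau_h
  n_ev <- length(drive$times)
  # lambda level in effect after each event, and the relaxation state of the
  # homogeneous part at each event boundary (starts at 0)
  lev <- if (n_ev) cummax(drive$lambdas) else numeric(0)
  rh <- numeric(n_ev)  # homogeneous value just at each event time
  if (n_ev >= 2) {
    for (j in 2:n_ev) {
      dtb <- drive$times[j] - drive$times[j - 1]
      rh[j] <- lev[j - 1] + (rh[j - 1] - lev[j - 1]) * exp(-k * dtb)
    }
  }
  function(t) {
    vapply(t, function(tt) {
      past <- which(drive$times <= tt)
      if (!length(past)) return(0)
      j <- max(past)
      dt <- tt - drive$times[past]
      pulse <- sum(drive$amps[past] *
                     (exp(-k * dt) - exp(-pmin(dt / tau, 700))) / (1 - k * tau))
      hom <- lev[j] + (rh[j] - lev[j]) * exp(-k * (tt - drive$times[j]))
      pulse + hom
    }, numeric(1))
  }
}

# merge a millisecond grid after each event into the output times
.refine_times <- function(t_grid, event_times, window_s, dt_s) {
  extra <- unlist(lapply(event_times, function(te)
    te + seq(0, window_s, by = dt_s) / 3600))
  times <- sort(unique(c(t_grid, event_times, extra)))
  times[times >= min(t_grid) & times <= max(t_grid)]
}

# zero out negative values that are pure integrator noise
.clamp0 <- function(x, tol = 1e-9) {
  x[x < 0 & x > -tol] <- 0
  x
}
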