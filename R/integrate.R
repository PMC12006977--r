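#' Event-aware stiff integration
#'
#' Adaptive integration (`deSolve::lsoda`) performed piecewise between blast
#' event times: the solver is stopped and restarted at every event so the
#' millisecond-scale rise pulse beginning there is never stepped over, while
#' the state itself stays continuous across events. Aborts with the last
#' good time if the state becomes non-finite.
#'
#' @param rhs Derivative function `function(t, y, parms) list(dy)`.
#' @param y0 Initial state vector.
#' @param times Increasing output times; must contain the full span.
#' @param event_times Times at which the solver restarts (may be empty).
#' @param parms Parameter object passed to `rhs`.
#' @param rel_tol,abs_tol Relative and absolute tolerances; `abs_tol` may be
#'   a vector with one entry per state.
#' @param hini Initial step size, h (0 = solver heuristic). Supply the rise
#'   time constant scale when segments start on a source pulse: the
#'   automatic choice can underflow at the pulse discontinuity.
#' @param segment_setup Optional `function(parms, segment_start)` returning
#'   the parameters for the segment beginning at `segment_start`; used to
#'   switch source pulses on exactly at their event boundary so every
#'   segment's right-hand side is smooth.
#' @return A matrix: column 1 time, then one column per state, one row per
#'   entry of `times`.
#' @export
integrate_system <- function(rhs, y0, times, event_times = numeric(0),
                             parms = NULL, rel_tol = 1e-8, abs_tol = 1e-10,
                             hini = 0, segment_setup = NULL) {
  if (is.unsorted(times, strictly = TRUE))
    stop("'times' must be strictly increasing", call. = FALSE)
  ev <- sort(unique(event_times))
  ev <- ev[ev > min(times) & ev < max(times)]
  bounds <- c(min(times), ev, max(times))
  y <- y0
  pieces <- vector("list", length(bounds) - 1)
  for (k in seq_len(length(bounds) - 1)) {
    lo <- bounds[k]; hi <- bounds[k + 1]
    seg <- times[times >= lo & times <= hi]
    seg <- sort(unique(c(lo, seg, hi)))
    p_k <- if (is.null(segment_setup)) parms else segment_setup(parms, lo)
    sol <- deSolve::lsoda(y, seg, rhs, p_k, rtol = rel_tol, atol = abs_tol,
                          maxsteps = 50000, hini = hini)
    if (nrow(sol) < length(seg))
      stop("integration stalled at t = ", signif(sol[nrow(sol), 1], 6),
           " h (step budget exhausted)", call. = FALSE)
    if (any(!is.finite(sol[, -1])))
      stop("integration produced non-finite state; last good time ",
           signif(max(sol[apply(is.finite(sol[, -1, drop = FALSE]), 1, all), 1]), 6),
           " h", call. = FALSE)
    y <- sol[nrow(sol), -1]
    pieces[[k]] <- sol
  }
  out <- do.call(rbind, pieces)
  out <- out[!duplicated(out[, 1]), , drop = FALSE]
  out[out[, 1] %in% times, , drop = FALSE]
}

#' Fixed-step classical Runge-Kutta reference integrator
#'
#' A plain RK4 loop used as an independent cross-check of the adaptive
#' solver on smooth (pulse-free) dynamics. Not intended for production runs.
#'
#' @param rhs Derivative function as in [integrate_system()].
#' @param y0 Initial state.
#' @param t0,t1 Time span, h.
#' @param dt Fixed step, h.
#' @param parms Parameters passed to `rhs`.
#' @return A matrix with columns time and state, rows at every step.
#' @export
rk4_integrate <- function(rhs, y0, t0, t1, dt, parms = NULL) {
  n <- ceiling((t1 - t0) / dt)
  out <- matrix(NA_real_, n + 1, length(y0) + 1)
  t <- t0; y <- y0
  out[1, ] <- c(t, y)
  f <- function(t, y) unlist(rhs(t, y, parms)[[1]])
  for (i in seq_len(n)) {
    h <- min(dt, t1 - t)
    k1 <- f(t, y)
    k2 <- f(t + h / 2, y + h / 2 * k1)
    k3 <- f(t + h / 2, y + h / 2 * k2)
    k4 <- f(t + h, y + h * k3)
    y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    t <- t + h
    out[i + 1, ] <- c(t, y)
  }
  out
}
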