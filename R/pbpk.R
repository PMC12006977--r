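#' Amyloid production parameters
#'
#' Rates of the amyloidogenic cascade: APP synthesis (blast-modulated in
#' brain tissue), BACE1 cleavage (APP -> sAPPbeta + C99), gamma-secretase
#' cleavage (C99 -> Abeta + AICD), the Abeta42 fraction of the product, and
#' the peripheral synthesis fraction (peripheral APP synthesis is 10% of
#' the brain baseline and, by default, not blast-modulated).
#'
#' @param k_APP0 Baseline brain APP synthesis, pg/mL/h.
#' @param x Amplification constant of the synthesis response (calibrated
#'   cohort value 1.5).
#' @param f_per Peripheral synthesis as a fraction of `k_APP0`.
#' @param f_42 Fraction of cleaved Abeta produced as Abeta42.
#' @param k_BACE1,k_gS Cleavage rates, 1/h.
#' @param k_byproduct Elimination rate of inert byproducts (sAPPbeta,
#'   AICD), 1/h.
#' @param modulate_peripheral Apply blast modulation to peripheral
#'   synthesis as well (default off).
#' @return A list of class `amyloid_params`.
#' @export
amyloid_params <- function(k_APP0 = 10, x = 1.5, f_per = 0.10, f_42 = 0.10,
                           k_BACE1 = 0.5, k_gS = 1.0, k_byproduct = 0.5,
                           modulate_peripheral = FALSE) {
  stopifnot(k_APP0 >= 0, x >= 0, f_per >= 0, f_per <= 1, f_42 >= 0, f_42 <= 1,
            k_BACE1 > 0, k_gS > 0, k_byproduct > 0)
  structure(list(k_APP0 = k_APP0, x = x, f_per = f_per, f_42 = f_42,
                 k_BACE1 = k_BACE1, k_gS = k_gS, k_byproduct = k_byproduct,
                 modulate_peripheral = isTRUE(modulate_peripheral)),
            class = "amyloid_params")
}

#' Whole-body transport parameters
#'
#' Transporter rates, fluid fluxes, flows, volumes and degradation rates of
#' the six-compartment Abeta transport system: brain interstitial fluid
#' (ISF), brain vasculature, perivascular/glymphatic space, plasma,
#' peripheral tissue, and lymph. LRP1 and P-gP carry efflux from ISF to
#' vasculature, RAGE carries influx back; `F_BBB` is bidirectional fluid
#' exchange across the blood-brain barrier, `F_gly` the glymphatic flux
#' ISF -> perivascular, `L_br` perivascular -> lymph drainage, `Q_*` the
#' plasma/tissue flows and `L_per` peripheral lymph drainage; lymph returns
#' to plasma.
#'
#' @param k_RAGE,k_LRP1,k_PgP Transporter rates, 1/h.
#' @param F_BBB,F_gly Exchange fluxes, mL/h.
#' @param Q_br,Q_per Plasma-tissue flows, mL/h.
#' @param L_br,L_per Lymph drainage flows, mL/h (`L_per <= Q_per`).
#' @param V Named volumes (mL) for `ISF`, `vasc`, `peri`, `plasma`, `per`,
#'   `lymph`.
#' @param k_deg Named degradation rates (1/h) for the same compartments.
#' @param saturable Use Michaelis saturation of the receptor-mediated
#'   transporters (default off; the linear form is the default model).
#' @param K_m_pg_ml Michaelis constant used when `saturable = TRUE`.
#' @return A list of class `transport_params`.
#' @export
transport_params <- function(k_RAGE = 0.05, k_LRP1 = 0.4, k_PgP = 0.2,
                             F_BBB = 10, F_gly = 20, Q_br = 21000,
                             Q_per = 150000, L_br = 20, L_per = 120,
                             V = c(ISF = 150, vasc = 50, peri = 20,
                                   plasma = 3000, per = 35000, lymph = 2000),
                             k_deg = c(ISF = 0.3, vasc = 0.1, peri = 0.1,
                                       plasma = 0.3, per = 0.2, lymph = 0.1),
                             saturable = FALSE, K_m_pg_ml = 1e4) {
  comp <- c("ISF", "vasc", "peri", "plasma", "per", "lymph")
  stopifnot(all(comp %in% names(V)), all(comp %in% names(k_deg)))
  if (any(V[comp] <= 0)) stop("all compartment volumes must be > 0", call. = FALSE)
  rates <- c(k_RAGE, k_LRP1, k_PgP, F_BBB, F_gly, Q_br, Q_per, L_br, L_per,
             k_deg[comp])
  if (any(rates < 0)) stop("transport rates must be >= 0", call. = FALSE)
  if (L_per > Q_per)
    stop("peripheral lymph drainage L_per cannot exceed tissue flow Q_per",
         call. = FALSE)
  structure(list(k_RAGE = k_RAGE, k_LRP1 = k_LRP1, k_PgP = k_PgP,
                 F_BBB = F_BBB, F_gly = F_gly, Q_br = Q_br, Q_per = Q_per,
                 L_br = L_br, L_per = L_per, V = V[comp], k_deg = k_deg[comp],
                 saturable = isTRUE(saturable), K_m_pg_ml = K_m_pg_ml),
            class = "transport_params")
}

#' Blast-modulated APP synthesis rate
#'
#' `k_APP = k_APP0 * (1 + x * R_B)`: synthesis equals its baseline at rest
#' and increases proportionally to the hyperacute biological response.
#'
#' @param k_APP0 Baseline synthesis, pg/mL/h.
#' @param x Amplification constant.
#' @param R_B Hyperacute response (non-negative).
#' @return Synthesis rate, pg/mL/h.
#' @export
#' @examples
#' app_synthesis_rate(10, 1.5, 1)  # 25
app_synthesis_rate <- function(k_APP0, x, R_B) {
  if (any(R_B < 0)) stop("'R_B' must be >= 0", call. = FALSE)
  k_APP0 * (1 + x * R_B)
}

# state vector layout
.pbpk_species <- function(include_ab40 = FALSE) {
  nm <- c("APP_br", "C99_br", "sAPPb", "AICD", "APP_per", "C99_per",
          paste0("Ab42_", c("ISF", "vasc", "peri", "plasma", "per", "lymph")))
  if (include_ab40)
    nm <- c(nm, paste0("Ab40_", c("ISF", "vasc", "peri", "plasma", "per", "lymph")))
  nm
}

# transport derivative block for one Abeta species; conc = c(ISF, vasc, peri,
# plasma, per, lymph); prod_* in pg/mL/h into ISF / peripheral tissue
.transport_block <- function(conc, prod_br, prod_per, tr) {
  V <- tr$V; kd <- tr$k_deg
  i <- conc[1]; v <- conc[2]; p <- conc[3]; q <- conc[4]; w <- conc[5]; l <- conc[6]
  efflux <- (tr$k_LRP1 + tr$k_PgP) * i
  influx <- tr$k_RAGE * v
  if (tr$saturable) {
    efflux <- efflux / (1 + i / tr$K_m_pg_ml)
    influx <- influx / (1 + v / tr$K_m_pg_ml)
  }
  d_i <- prod_br - efflux - (tr$F_gly / V["ISF"]) * i -
    (tr$F_BBB / V["ISF"]) * (i - v) + influx * V["vasc"] / V["ISF"] -
    kd["ISF"] * i
  d_v <- efflux * V["ISF"] / V["vasc"] + (tr$F_BBB / V["vasc"]) * (i - v) -
    influx + (tr$Q_br / V["vasc"]) * (q - v) - kd["vasc"] * v
  d_p <- (tr$F_gly / V["peri"]) * i - (tr$L_br / V["peri"]) * p - kd["peri"] * p
  d_q <- (tr$Q_br / V["plasma"]) * (v - q) +
    ((tr$Q_per - tr$L_per) / V["plasma"]) * w - (tr$Q_per / V["plasma"]) * q +
    ((tr$L_br + tr$L_per) / V["plasma"]) * l - kd["plasma"] * q
  d_w <- prod_per + (tr$Q_per / V["per"]) * (q - w) - kd["per"] * w
  d_l <- (tr$L_br / V["lymph"]) * p + (tr$L_per / V["lymph"]) * w -
    ((tr$L_br + tr$L_per) / V["lymph"]) * l - kd["lymph"] * l
  unname(c(d_i, d_v, d_p, d_q, d_w, d_l))
}

#' Build the whole-body Abeta ODE right-hand side
#'
#' Assembles the mass-balance derivative over the full state (precursors
#' plus Abeta42 across six compartments, optionally a parallel Abeta40 set
#' sharing the C99 flux with fraction `1 - f_42`), driven by an external
#' hyperacute-response signal. All inter-compartment terms conserve mass:
#' each flux appears with opposite signs scaled by the source and
#' destination volumes.
#'
#' @param amyloid An [amyloid_params()] object.
#' @param transport A [transport_params()] object.
#' @param rb_signal Function of time returning the hyperacute response
#'   `R_B1(t)` (default identically 0).
#' @param include_ab40 Track the parallel Abeta40 species.
#' @return A deSolve-compatible function `function(t, y, parms) list(dy)`
#'   over the state named as in the `species` attribute.
#' @export
build_ode_system <- function(amyloid, transport, rb_signal = function(t) 0,
                             include_ab40 = FALSE) {
  nm <- .pbpk_species(include_ab40)
  force(amyloid); force(transport); force(rb_signal)
  f <- function(t, y, parms = NULL) {
    rb <- rb_signal(t)
    list(.pbpk_deriv(y, rb, amyloid, transport, include_ab40))
  }
  attr(f, "species") <- nm
  f
}

# core derivative given the instantaneous R_B value
.pbpk_deriv <- function(y, rb, am, tr, include_ab40 = FALSE) {
  k_br <- app_synthesis_rate(am$k_APP0, am$x, rb)
  k_pe <- am$f_per * am$k_APP0 *
    (if (am$modulate_peripheral) 1 + am$x * rb else 1)
  APP_br <- y[1]; C99_br <- y[2]; sAPPb <- y[3]; AICD <- y[4]
  APP_per <- y[5]; C99_per <- y[6]
  d <- numeric(length(y))
  d[1] <- k_br - am$k_BACE1 * APP_br
  d[2] <- am$k_BACE1 * APP_br - am$k_gS * C99_br
  d[3] <- am$k_BACE1 * APP_br - am$k_byproduct * sAPPb
  d[4] <- am$k_gS * C99_br - am$k_byproduct * AICD
  d[5] <- k_pe - am$k_BACE1 * APP_per
  d[6] <- am$k_BACE1 * APP_per - am$k_gS * C99_per
  d[7:12] <- .transport_block(y[7:12],
                              prod_br = am$f_42 * am$k_gS * C99_br,
                              prod_per = am$f_42 * am$k_gS * C99_per, tr)
  if (include_ab40)
    d[13:18] <- .transport_block(y[13:18],
                                 prod_br = (1 - am$f_42) * am$k_gS * C99_br,
                                 prod_per = (1 - am$f_42) * am$k_gS * C99_per, tr)
  d
}

#' Resting steady state of the Abeta system
#'
#' Solves the unique non-negative fixed point of the (linear) system with
#' the hyperacute response at zero, used as the pre-exposure initial
#' condition. The linear map is assembled column-by-column from the
#' derivative function and solved directly; with saturable transport
#' enabled the state is obtained by long integration instead.
#'
#' @param amyloid An [amyloid_params()] object.
#' @param transport A [transport_params()] object.
#' @param include_ab40 Track the parallel Abeta40 species.
#' @return Named state vector (pg/mL per compartment).
#' @export
steady_state_baseline <- function(amyloid, transport, include_ab40 = FALSE) {
  nm <- .pbpk_species(include_ab40)
  n <- length(nm)
  if (!transport$saturable) {
    b <- .pbpk_deriv(numeric(n), 0, amyloid, transport, include_ab40)
    A <- matrix(0, n, n)
    for (j in seq_len(n)) {
      e <- numeric(n); e[j] <- 1
      A[, j] <- .pbpk_deriv(e, 0, amyloid, transport, include_ab40) - b
    }
    bad <- nm[diag(A) >= 0]
    if (length(bad))
      stop("degenerate parameter set: no net outflow from compartment(s) ",
           paste(bad, collapse = ", "), call. = FALSE)
    ss <- tryCatch(solve(A, -b), error = function(e)
      stop("steady-state system is singular: ", conditionMessage(e), call. = FALSE))
    if (any(ss < -1e-8 * max(abs(ss), 1)))
      stop("steady state has negative concentrations in: ",
           paste(nm[ss < 0], collapse = ", "), call. = FALSE)
    ss <- pmax(ss, 0)
  } else {
    sys <- build_ode_system(amyloid, transport, include_ab40 = include_ab40)
    out <- integrate_system(sys, numeric(n), times = c(0, 1000, 2000, 4000),
                            rel_tol = 1e-10, abs_tol = 1e-12)
    ss <- out[nrow(out), -1]
  }
  names(ss) <- nm
  resid <- .pbpk_deriv(ss, 0, amyloid, transport, include_ab40)
  scale <- max(amyloid$k_APP0, 1e-300)
  if (max(abs(resid)) > 1e-8 * scale)
    warning("steady-state residual ", signif(max(abs(resid)), 3),
            " exceeds 1e-8 of the synthesis scale")
  ss
}

#' Total Abeta42 mass across transport compartments
#'
#' Volume-weighted sum of the six Abeta42 compartment concentrations;
#' conserved exactly when synthesis and degradation are switched off.
#'
#' @param state Named state vector or matrix of states (rows = times).
#' @param transport A [transport_params()] object.
#' @return Mass in pg (scalar or vector).
#' @export
total_ab42_mass <- function(state, transport) {
  nm <- paste0("Ab42_", c("ISF", "vasc", "peri", "plasma", "per", "lymph"))
  V <- unname(transport$V)
  if (is.matrix(state)) as.vector(state[, nm, drop = FALSE] %*% V)
  else sum(state[nm] * V)
}

# construct typed parameter objects from a config list; k_APP0 = NULL means
# auto-scale so that baseline plasma Abeta42 equals the configured target
.amyloid_from_config <- function(cfg) {
  p <- cfg$pbpk
  amyloid_params(k_APP0 = if (is.null(p$k_APP0)) 1 else p$k_APP0,
                 x = p$x, f_per = p$f_per, f_42 = p$f_42,
                 k_BACE1 = p$k_BACE1, k_gS = p$k_gS,
                 k_byproduct = p$k_byproduct,
                 modulate_peripheral = p$modulate_peripheral)
}

.transport_from_config <- function(cfg) {
  p <- cfg$pbpk
  transport_params(k_RAGE = p$k_RAGE, k_LRP1 = p$k_LRP1, k_PgP = p$k_PgP,
                   F_BBB = p$F_BBB, F_gly = p$F_gly, Q_br = p$Q_br,
                   Q_per = p$Q_per, L_br = p$L_br, L_per = p$L_per,
                   V = c(ISF = p$V_ISF, vasc = p$V_vasc, peri = p$V_peri,
                         plasma = p$V_plasma, per = p$V_per, lymph = p$V_lymph),
                   k_deg = c(ISF = p$k_deg_ISF, vasc = p$k_deg_vasc,
                             peri = p$k_deg_peri, plasma = p$k_deg_plasma,
                             per = p$k_deg_per, lymph = p$k_deg_lymph),
                   saturable = p$saturable_transport, K_m_pg_ml = p$K_m_pg_ml)
}

# amyloid params + baseline state with k_APP0 resolved (auto-scaled to the
# configured baseline plasma concentration when not given explicitly);
# exploits linearity: every steady-state concentration scales with k_APP0
.resolve_baseline <- function(cfg) {
  am <- .amyloid_from_config(cfg)
  tr <- .transport_from_config(cfg)
  ab40 <- cfg$pbpk$include_ab40
  ss <- steady_state_baseline(am, tr, include_ab40 = ab40)
  if (is.null(cfg$pbpk$k_APP0)) {
    target <- cfg$pbpk$baseline_plasma_pg_ml
    p1 <- ss[["Ab42_plasma"]]
    if (p1 <= 0)
      stop("baseline plasma concentration is zero; cannot auto-scale k_APP0",
           call. = FALSE)
    gamma <- target / p1
    am$k_APP0 <- am$k_APP0 * gamma
    ss <- ss * gamma
  }
  list(amyloid = am, transport = tr, state = ss, include_ab40 = ab40)
}
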