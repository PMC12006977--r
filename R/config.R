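#' Default model configuration
#'
#' Returns the full nested configuration consumed by every stage of the
#' pipeline: dose conversion (`dose`), damage/response kinetics (`damage`),
#' amyloid production and whole-body transport (`pbpk`), integrator and
#' sampling settings (`simulation`), and calibration bounds (`calibration`).
#' All rate constants are per hour, volumes in mL, flows in mL/h,
#' concentrations in pg/mL, and the study clock runs in hours from midnight
#' before the first training day.
#'
#' Notable keys:
#' \describe{
#'   \item{dose.threshold}{non-dimensional injury threshold, proportional to
#'     4 psi of blast overpressure; exposures below it leave no residual
#'     damage.}
#'   \item{dose.lambda_gain}{residual damage gained per psi of exceedance
#'     above the threshold.}
#'   \item{dose.rise_tau_s}{time constant (seconds) of the first-order source
#'     pulse; the default 0.0383 s places the mechanical-damage peak at
#'     0.50 s after the event given the default decay rate.}
#'   \item{pbpk.x}{amplification constant coupling the hyperacute response to
#'     APP synthesis; 1.5 is the calibrated value used for the whole cohort.}
#'   \item{pbpk.k_APP0}{baseline brain APP synthesis rate (pg/mL/h). `NULL`
#'     (the default) auto-scales it so baseline plasma Abeta42 equals
#'     `pbpk.baseline_plasma_pg_ml`; normalized outputs are insensitive to
#'     this scale.}
#' }
#'
#' @return A nested named list of class `blastkin_config`.
#' @seealso [load_config()], [validate_config()]
#' @export
#' @examples
#' cfg <- blastkin_config()
#' cfg$dose$threshold
blastkin_config <- function() {
  cfg <- list(
    dose = list(
      threshold = 4,
      lambda_gain = 0.25,
      rise_tau_s = 0.0383,
      dose_scale = 1.0,
      mode = "daily_aggregate"
    ),
    damage = list(
      alpha = 0.2,
      t_d_h = 1.0,
      k_in = 1.0,
      k_out1 = 0.5,
      k_out2 = 0.1,
      R_M0 = 1.0
    ),
    pbpk = list(
      x = 1.5,
      k_APP0 = NULL,
      baseline_plasma_pg_ml = 20,
      f_per = 0.10,
      f_42 = 0.10,
      k_BACE1 = 0.5,
      k_gS = 1.0,
      k_byproduct = 0.5,
      k_RAGE = 0.05,
      k_LRP1 = 0.4,
      k_PgP = 0.2,
      F_BBB = 10,
      F_gly = 20,
      Q_br = 21000,
      Q_per = 150000,
      L_br = 20,
      L_per = 120,
      V_ISF = 150,
      V_vasc = 50,
      V_peri = 20,
      V_plasma = 3000,
      V_per = 35000,
      V_lymph = 2000,
      k_deg_ISF = 0.3,
      k_deg_vasc = 0.1,
      k_deg_peri = 0.1,
      k_deg_plasma = 0.3,
      k_deg_per = 0.2,
      k_deg_lymph = 0.1,
      saturable_transport = FALSE,
      K_m_pg_ml = 1e4,
      include_ab40 = FALSE,
      modulate_peripheral = FALSE
    ),
    simulation = list(
      rel_tol = 1e-8,
      abs_tol = 1e-10,
      grid_dt_h = 0.1,
      refine_window_s = 2,
      refine_dt_s = 0.001,
      training_start_hour = 9,
      followup_h = 12
    ),
    calibration = list(
      lower = 0,
      upper = 10,
      objective = "sse_normalized",
      multistart = 3
    ),
    schema_version = 1
  )
  class(cfg) <- "blastkin_config"
  cfg
}

# keys allowed to be NULL / non-numeric
.cfg_special <- list(
  "dose.mode" = function(v) is.character(v) && length(v) == 1 &&
    v %in% c("daily_aggregate", "per_shot"),
  "pbpk.k_APP0" = function(v) is.null(v) || (is.numeric(v) && v > 0),
  "pbpk.saturable_transport" = function(v) is.logical(v) && length(v) == 1,
  "pbpk.include_ab40" = function(v) is.logical(v) && length(v) == 1,
  "pbpk.modulate_peripheral" = function(v) is.logical(v) && length(v) == 1,
  "calibration.objective" = function(v) is.character(v) && length(v) == 1 &&
    v %in% c("sse_normalized", "sse_log")
)

# keys that may be zero; everything else numeric must be > 0
.cfg_nonneg <- c(
  "dose.lambda_gain", "pbpk.x", "pbpk.f_per", "pbpk.f_42",
  "pbpk.k_RAGE", "pbpk.k_LRP1", "pbpk.k_PgP",
  "pbpk.F_BBB", "pbpk.F_gly", "pbpk.L_br", "pbpk.L_per",
  "pbpk.k_deg_ISF", "pbpk.k_deg_vasc", "pbpk.k_deg_peri",
  "pbpk.k_deg_plasma", "pbpk.k_deg_per", "pbpk.k_deg_lymph",
  "pbpk.k_byproduct", "calibration.lower", "simulation.training_start_hour"
)

#' Validate a model configuration
#'
#' Checks completeness (every key of [blastkin_config()] present), rejects
#' unknown keys, and enforces sign/type constraints, naming the offending key
#' in the error message.
#'
#' @param config A configuration list as returned by [blastkin_config()] or
#'   [load_config()].
#' @return The validated config, invisibly.
#' @export
validate_config <- function(config) {
  ref <- unclass(blastkin_config())
  cfg <- unclass(config)
  .check_keys(cfg, ref, prefix = NULL)
  for (sec in setdiff(names(ref), "schema_version")) {
    for (key in names(ref[[sec]])) {
      full <- paste(sec, key, sep = ".")
      v <- cfg[[sec]][[key]]
      chk <- .cfg_special[[full]]
      if (!is.null(chk)) {
        if (!chk(v)) stop("config key '", full, "' has an invalid value", call. = FALSE)
      } else if (!is.numeric(v) || length(v) != 1 || !is.finite(v)) {
        stop("config key '", full, "' must be a single finite number", call. = FALSE)
      } else if (full %in% .cfg_nonneg) {
        if (v < 0) stop("config key '", full, "' must be >= 0", call. = FALSE)
      } else if (v <= 0) {
        stop("config key '", full, "' must be > 0", call. = FALSE)
      }
    }
  }
  if (cfg$pbpk$f_42 > 1) stop("config key 'pbpk.f_42' must be <= 1", call. = FALSE)
  if (cfg$pbpk$f_per > 1) stop("config key 'pbpk.f_per' must be <= 1", call. = FALSE)
  if (cfg$calibration$lower >= cfg$calibration$upper)
    stop("calibration bounds must satisfy lower < upper", call. = FALSE)
  invisible(config)
}

# reject keys absent from the reference layout (partial configs are fine)
.check_unknown <- function(cfg, ref, prefix) {
  path <- function(k) if (is.null(prefix)) k else paste(prefix, k, sep = ".")
  extra <- setdiff(names(cfg), names(ref))
  if (length(extra))
    stop("unknown config key(s): ", paste(vapply(extra, path, ""), collapse = ", "),
         call. = FALSE)
  for (k in names(cfg)) {
    if (is.list(ref[[k]])) {
      if (!is.list(cfg[[k]]))
        stop("config section '", path(k), "' must be a mapping", call. = FALSE)
      .check_unknown(cfg[[k]], ref[[k]], path(k))
    }
  }
  invisible(NULL)
}

.check_keys <- function(cfg, ref, prefix) {
  path <- function(k) if (is.null(prefix)) k else paste(prefix, k, sep = ".")
  extra <- setdiff(names(cfg), names(ref))
  if (length(extra))
    stop("unknown config key(s): ", paste(vapply(extra, path, ""), collapse = ", "),
         call. = FALSE)
  missing <- setdiff(names(ref), names(cfg))
  # NULL-valued entries (pbpk.k_APP0) vanish from yaml round trips; only
  # treat a key as missing if its reference value is non-NULL
  missing <- missing[!vapply(ref[missing], is.null, TRUE)]
  if (length(missing))
    stop("missing config key(s): ", paste(vapply(missing, path, ""), collapse = ", "),
         call. = FALSE)
  for (k in names(ref)) {
    if (is.list(ref[[k]]) && !is.null(cfg[[k]])) {
      if (!is.list(cfg[[k]])) stop("config section '", path(k), "' must be a mapping",
                                   call. = FALSE)
      .check_keys(cfg[[k]], ref[[k]], path(k))
    }
  }
  invisible(NULL)
}

#' Load a configuration file
#'
#' Reads a YAML file with the section/key layout of [blastkin_config()],
#' fills in defaults for anything not given, rejects unknown keys, and
#' validates the result. An empty file (or `path = NULL`) yields the full
#' default configuration.
#'
#' @param path Path to a YAML configuration file, or `NULL` for defaults.
#' @return A validated `blastkin_config` list.
#' @export
load_config <- function(path = NULL) {
  cfg <- unclass(blastkin_config())
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
    user <- yaml::read_yaml(path)
    if (is.null(user)) user <- list()
    if (!is.list(user)) stop("config file must contain a YAML mapping", call. = FALSE)
    .check_unknown(user, cfg, prefix = NULL)
    for (sec in names(user)) {
      if (is.list(cfg[[sec]])) {
        for (key in names(user[[sec]])) {
          v <- user[[sec]][[key]]
          # a null in the file means "use the default"; assigning NULL with
          # [[<- would delete the key instead
          if (is.null(v)) cfg[[sec]][key] <- list(NULL)
          else cfg[[sec]][[key]] <- v
        }
      } else {
        cfg[[sec]] <- user[[sec]]
      }
    }
  }
  class(cfg) <- "blastkin_config"
  validate_config(cfg)
  cfg
}

#' Write a configuration to YAML
#'
#' The written file round-trips: `load_config(write_config(cfg, f))` is
#' identical to `cfg`.
#'
#' @param config A `blastkin_config` list.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_config <- function(config, path) {
  validate_config(config)
  yaml::write_yaml(unclass(config), path, precision = 15)
  invisible(path)
}

# 32-bit FNV-1a over a string; used only for provenance change detection
.fnv1a <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 2166136261
  for (b in bytes) {
    # xor with an octet touches only the low byte; keep h as a double
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b))
    # 32-bit modular multiply, split to stay within double precision
    h <- (16777619 * (h %% 65536) + (16777619 * (h %/% 65536) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Fingerprint of a configuration
#'
#' Short hash of the canonical YAML serialization; changes whenever any
#' field changes. Used in cohort provenance records.
#'
#' @param config A `blastkin_config` list (or any serializable list).
#' @return An 8-character hex string.
#' @export
config_hash <- function(config) {
  .fnv1a(yaml::as.yaml(unclass(config), precision = 15))
}
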