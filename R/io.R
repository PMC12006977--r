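#' Read an exposures CSV
#'
#' Schema: `subject_id`, `day`, `avg_bop_psi`, `shots`, `training_start`
#' (decimal clock hours), `training_hours`. Header required, UTF-8, decimal
#' point. Malformed numeric fields are reported with their line numbers;
#' duplicated `subject_id` + `day` pairs are an error.
#'
#' @param path CSV path.
#' @return Typed data frame.
#' @export
read_exposures_csv <- function(path) {
  df <- .read_checked_csv(path,
    cols = c("subject_id", "day", "avg_bop_psi", "shots", "training_start",
             "training_hours"),
    numeric_cols = c("day", "avg_bop_psi", "shots", "training_start",
                     "training_hours"))
  key <- paste(df$subject_id, df$day)
  if (anyDuplicated(key))
    stop("duplicated subject_id + day in ", path, ": ",
         paste(unique(key[duplicated(key)]), collapse = ", "), call. = FALSE)
  if (any(df$avg_bop_psi < 0)) stop("avg_bop_psi must be >= 0", call. = FALSE)
  if (any(df$shots < 0)) stop("shots must be >= 0", call. = FALSE)
  df
}

#' Read a serum draws CSV
#'
#' Schema: `subject_id`, `draw_label` (`d<k>_pre` / `d<k>_post` or free
#' labels), `time_h`, `abeta42_pg_ml` (> 0). Duplicated
#' `subject_id` + `draw_label` pairs are an error.
#'
#' @param path CSV path.
#' @return Typed data frame.
#' @export
read_serum_csv <- function(path) {
  df <- .read_checked_csv(path,
    cols = c("subject_id", "draw_label", "time_h", "abeta42_pg_ml"),
    numeric_cols = c("time_h", "abeta42_pg_ml"))
  key <- paste(df$subject_id, df$draw_label)
  if (anyDuplicated(key))
    stop("duplicated subject_id + draw_label in ", path, ": ",
         paste(unique(key[duplicated(key)]), collapse = ", "), call. = FALSE)
  if (any(df$abeta42_pg_ml <= 0))
    stop("abeta42_pg_ml must be > 0 (lines ",
         paste(which(df$abeta42_pg_ml <= 0) + 1L, collapse = ", "), ")",
         call. = FALSE)
  df
}

# read as character, check schema, convert numerics reporting 1-based file
# line numbers (header is line 1) for anything that fails to parse
.read_checked_csv <- function(path, cols, numeric_cols) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop(path, " missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  df <- df[cols]
  for (cc in numeric_cols) {
    v <- suppressWarnings(as.numeric(df[[cc]]))
    bad <- which(is.na(v) & nzchar(df[[cc]]))
    if (length(bad))
      stop(path, ": column '", cc, "' is not numeric on line(s) ",
           paste(bad + 1L, collapse = ", "), call. = FALSE)
    if (anyNA(v))
      stop(path, ": column '", cc, "' has empty value on line(s) ",
           paste(which(is.na(v)) + 1L, collapse = ", "), call. = FALSE)
    df[[cc]] <- v
  }
  df
}

#' Export a damage trajectory or prediction series to CSV
#'
#' @param x A `damage_trajectory` or `prediction_series` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_series_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
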