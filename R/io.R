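# CSV readers/writers with schema validation. Units are encoded in column
# name suffixes (_umol_kg, _s, _g, _min) so they cannot be silently mixed up.

.check_numeric <- function(df, cols, path) {
  for (cl in cols) {
    x <- df[[cl]]
    if (!is.numeric(x)) {
      suppressWarnings(xn <- as.numeric(x))
      bad <- which(is.na(xn) & !is.na(x))
      if (length(bad))
        stop(sprintf("%s: nonnumeric value in column '%s', row %d",
                     path, cl, bad[1]))
      df[[cl]] <- xn
    }
  }
  df
}

#' Read and validate a hot-plate latency CSV
#'
#' Expected columns: `animal_id`, `treatment`, `dose_umol_kg`, `time_min`,
#' `latency_s`, `control_latency_s` and optionally `cutoff_s` (default 35).
#' Row-level invariants (`0 < latency_s <= cutoff_s`,
#' `0 < control_latency_s < cutoff_s`, `dose_umol_kg >= 0`,
#' `time_min >= 0`) are enforced with errors naming the file, row and column.
#'
#' @param path Path to the CSV file.
#' @return Validated data frame of latency records.
#' @export
read_hotplate_csv <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("animal_id", "treatment", "dose_umol_kg", "time_min", "latency_s",
           "control_latency_s")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop(sprintf("%s: missing columns: %s", path, paste(miss, collapse = ", ")))
  if (!("cutoff_s" %in% names(df))) df$cutoff_s <- 35
  df <- .check_numeric(df, c("dose_umol_kg", "time_min", "latency_s",
                             "control_latency_s", "cutoff_s"), path)
  checks <- list(
    list("dose_umol_kg", df$dose_umol_kg < 0, "negative dose"),
    list("time_min", df$time_min < 0, "negative time"),
    list("latency_s", df$latency_s <= 0, "latency must be positive"),
    list("latency_s", df$latency_s > df$cutoff_s, "latency exceeds cutoff"),
    list("control_latency_s", df$control_latency_s <= 0,
         "control latency must be positive"),
    list("control_latency_s", df$control_latency_s >= df$cutoff_s,
         "control latency must be below cutoff")
  )
  for (ck in checks) {
    bad <- which(ck[[2]])
    if (length(bad))
      stop(sprintf("%s: row %d, column '%s': %s", path, bad[1], ck[[1]],
                   ck[[3]]))
  }
  df
}

#' Write a hot-plate latency table to CSV
#'
#' @param records Latency data frame (the [read_hotplate_csv()] layout).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hotplate_csv <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' Read and validate an SNL withdrawal CSV
#'
#' Expected columns: `animal_id`, `group`, `endpoint`, `session`, `value`.
#' Values must be positive numbers; `endpoint` must be `thermal` or
#' `mechanical`.
#'
#' @param path Path to the CSV file.
#' @return Validated data frame.
#' @export
read_snl_csv <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("animal_id", "group", "endpoint", "session", "value")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop(sprintf("%s: missing columns: %s", path, paste(miss, collapse = ", ")))
  df <- .check_numeric(df, "value", path)
  bad <- which(df$value <= 0)
  if (length(bad))
    stop(sprintf("%s: row %d, column 'value': value must be positive",
                 path, bad[1]))
  bad <- which(!(df$endpoint %in% c("thermal", "mechanical")))
  if (length(bad))
    stop(sprintf("%s: row %d, column 'endpoint': must be 'thermal' or 'mechanical'",
                 path, bad[1]))
  df
}

#' Write an SNL withdrawal table to CSV
#' @param records SNL data frame (the [read_snl_csv()] layout).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_snl_csv <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' Serializable report from a dose-response fit
#'
#' @param fit A `dose_response_fit`.
#' @return A plain list (parameters, SEs, covariance, per-dose summaries)
#'   suitable for `jsonlite::write_json()`.
#' @export
fit_report <- function(fit) {
  stopifnot(inherits(fit, "dose_response_fit"))
  list(model = fit$model,
       free = fit$free,
       se = as.list(fit$se),
       se_log10_ed50 = fit$se_log10_ed50,
       covariance = fit$covariance,
       n_total = fit$n_total,
       df = fit$df,
       residual_ss = fit$residual_ss,
       converged = fit$converged,
       time_selection = fit$time_selection,
       dose_summaries = summarize_doses(fit$data))
}
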