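#' Percent maximum possible effect (%MPE) from a hot-plate latency
#'
#' Converts an observed hot-plate response latency to the normalized
#' antinociception scale
#' \deqn{\%MPE = 100 \cdot \frac{observed - control}{cutoff - control}}
#' where \code{control} is the animal's pre-dose baseline latency and
#' \code{cutoff} the maximum permitted exposure (35 s by default, after which
#' the animal is removed and the observation is censored at 100\%).
#'
#' The transformation is affine in the observed latency: it is exactly 0 at the
#' control latency and exactly 100 at the cutoff.  Observed latencies below the
#' baseline give negative \%MPE; these are retained by default because the
#' definition imposes no floor and clamping at 0 biases ED50 estimates upward.
#'
#' @param observed_latency Observed response latency in seconds; must satisfy
#'   \code{0 < observed_latency <= cutoff}.
#' @param control_latency Pre-dose baseline latency in seconds; must satisfy
#'   \code{0 < control_latency < cutoff}.
#' @param cutoff Maximum exposure time in seconds (default 35).
#' @param clamp_negative If \code{TRUE}, negative \%MPE values are clamped to 0.
#'   Default \code{FALSE}.
#' @return \%MPE as a numeric vector (percent). Exactly 100 when
#'   \code{observed_latency == cutoff}.
#' @examples
#' compute_mpe(20, 10)        # 40
#' compute_mpe(35, 10)        # 100 (censored at cutoff)
#' compute_mpe(c(10, 15), 10) # 0, 20
#' @export
compute_mpe <- function(observed_latency, control_latency, cutoff = 35,
                        clamp_negative = FALSE) {
  stopifnot(is.numeric(observed_latency), is.numeric(control_latency),
            is.numeric(cutoff))
  if (any(control_latency >= cutoff))
    stop("invalid baseline: control_latency >= cutoff (denominator <= 0)")
  if (any(control_latency <= 0))
    stop("invalid baseline: control_latency must be positive")
  if (any(observed_latency > cutoff))
    stop("censoring violation: observed_latency exceeds cutoff")
  if (any(observed_latency <= 0))
    stop("observed_latency must be positive")
  mpe <- 100 * (observed_latency - control_latency) / (cutoff - control_latency)
  mpe[observed_latency == cutoff] <- 100
  if (clamp_negative) mpe <- pmax(mpe, 0)
  mpe
}

#' Convert a table of hot-plate latency records to %MPE observations
#'
#' Applies [compute_mpe()] row-wise to a latency table (the `hotplate.csv`
#' layout, see [read_hotplate_csv()]) and flags censored records
#' (latency at cutoff).
#'
#' @param latencies Data frame with columns `animal_id`, `treatment`,
#'   `dose_umol_kg`, `time_min`, `latency_s`, `control_latency_s` and
#'   optionally `cutoff_s` (default 35).
#' @param clamp_negative Passed to [compute_mpe()].
#' @return Data frame with columns `animal_id`, `treatment`, `dose_umol_kg`,
#'   `time_min`, `mpe`, `censored`.
#' @export
latencies_to_mpe <- function(latencies, clamp_negative = FALSE) {
  req <- c("animal_id", "treatment", "dose_umol_kg", "time_min", "latency_s",
           "control_latency_s")
  miss <- setdiff(req, names(latencies))
  if (length(miss))
    stop("missing columns: ", paste(miss, collapse = ", "))
  cutoff <- if ("cutoff_s" %in% names(latencies)) latencies$cutoff_s else 35
  mpe <- compute_mpe(latencies$latency_s, latencies$control_latency_s, cutoff,
                     clamp_negative = clamp_negative)
  data.frame(
    animal_id = latencies$animal_id,
    treatment = latencies$treatment,
    dose_umol_kg = latencies$dose_umol_kg,
    time_min = latencies$time_min,
    mpe = mpe,
    censored = latencies$latency_s == cutoff,
    stringsAsFactors = FALSE
  )
}

#' Collapse a %MPE time course to one value per animal and dose
#'
#' Hot-plate responses are recorded at several times post-dose (5--120 min);
#' dose--response fitting needs a single value per animal x dose.  Two rules
#' are supported: the value at a fixed time (default 15 min, the time at which
#' the study's per-dose means are reported) or the per-animal peak over the
#' time course.
#'
#' @param observations Data frame of \%MPE observations as returned by
#'   [latencies_to_mpe()].
#' @param rule Either `"fixed"` (value at `time`) or `"peak"` (per-animal
#'   maximum over the time course).
#' @param time Fixed selection time in minutes (used when `rule = "fixed"`).
#' @return Data frame with one row per animal x treatment x dose, columns
#'   `animal_id`, `treatment`, `dose_umol_kg`, `time_min`, `mpe`, `censored`,
#'   and attribute `time_selection` recording the rule used.
#' @export
collapse_timecourse <- function(observations, rule = c("fixed", "peak"),
                                time = 15) {
  rule <- match.arg(rule)
  key <- interaction(observations$animal_id, observations$treatment,
                     observations$dose_umol_kg, drop = TRUE)
  pick <- function(idx) {
    sub <- observations[idx, , drop = FALSE]
    if (rule == "fixed") {
      j <- which(sub$time_min == time)
      if (length(j) == 0)
        stop(sprintf("missing timepoint: animal '%s' has no observation at %g min",
                     sub$animal_id[1], time))
      sub[j[1], , drop = FALSE]
    } else {
      sub[which.max(sub$mpe), , drop = FALSE]
    }
  }
  out <- do.call(rbind, lapply(split(seq_len(nrow(observations)), key), pick))
  rownames(out) <- NULL
  attr(out, "time_selection") <-
    if (rule == "fixed") sprintf("fixed@%g", time) else "peak"
  out
}

#' Per-dose summary of %MPE observations
#'
#' Arithmetic mean and standard error of the mean (sample SD / sqrt(n)) per
#' dose, the `mean +/- SEM` convention of behavioral pharmacology reports.
#' SEM is `NA` for singleton doses.
#'
#' @param observations Collapsed \%MPE observations (one row per animal x dose),
#'   with columns `dose_umol_kg` and `mpe` (a `treatment` column, if present,
#'   enters the grouping).
#' @return Data frame with columns `treatment` (if supplied), `dose_umol_kg`,
#'   `n`, `mean_mpe`, `sem_mpe`, sorted by dose.  Empty input gives an empty
#'   data frame.
#' @export
summarize_doses <- function(observations) {
  has_trt <- "treatment" %in% names(observations)
  if (nrow(observations) == 0) {
    out <- data.frame(dose_umol_kg = numeric(), n = integer(),
                      mean_mpe = numeric(), sem_mpe = numeric())
    if (has_trt) out <- cbind(treatment = character(), out)
    return(out)
  }
  key <- if (has_trt)
    interaction(observations$treatment, observations$dose_umol_kg, drop = TRUE)
  else factor(observations$dose_umol_kg)
  rows <- lapply(split(observations, key), function(sub) {
    n <- nrow(sub)
    out <- data.frame(
      dose_umol_kg = sub$dose_umol_kg[1],
      n = n,
      mean_mpe = mean(sub$mpe),
      sem_mpe = if (n > 1) stats::sd(sub$mpe) / sqrt(n) else NA_real_
    )
    if (has_trt) out <- cbind(treatment = sub$treatment[1], out)
    out
  })
  out <- do.call(rbind, rows)
  ord <- if (has_trt) order(out$treatment, out$dose_umol_kg)
         else order(out$dose_umol_kg)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}
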