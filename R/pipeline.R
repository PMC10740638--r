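#' Full isobolographic analysis pipeline
#'
#' Runs the complete chain on a hot-plate latency table containing two
#' single-drug arms and a fixed-ratio mixture arm:
#' \%MPE conversion -> time-course collapse -> per-arm Hill fits ->
#' theoretical additive ED50 with uncertainty -> interaction assessment ->
#' isobologram geometry.  Optionally writes a JSON report (embedding the
#' configuration and seeds) and tidy CSVs of the dose summaries and geometry.
#'
#' @param latencies Latency data frame (the [read_hotplate_csv()] layout) or a
#'   path to such a CSV.
#' @param treatment_a,treatment_b Treatment labels of the two single-drug arms
#'   (A is the isobologram ordinate / formula numerator).
#' @param treatment_mix Treatment label of the mixture arm (default
#'   `"<a>+<b>"`).
#' @param rho_a Molar fraction of component A in the mixture (default 0.5).
#' @param time_rule,time Time-course collapse rule, passed to
#'   [collapse_timecourse()].
#' @param variance_method `"delta"` or `"montecarlo"` for the additive-ED50
#'   uncertainty.
#' @param alpha Significance level for the classification (default 0.05).
#' @param seed Seed used by stochastic variance methods (default 1).
#' @param clamp_negative Clamp negative \%MPE at 0 (default `FALSE`).
#' @param out_dir If non-`NULL`, directory where `report.json`,
#'   `dose_summaries.csv` and `isobologram.csv` are written.
#' @return Object of class `isobole_pipeline`: list with `fits` (named list of
#'   `dose_response_fit`s), `additivity`, `assessment`, `geometry`,
#'   `dose_summaries`, `config`.
#' @export
run_pipeline <- function(latencies, treatment_a, treatment_b,
                         treatment_mix = paste0(treatment_a, "+", treatment_b),
                         rho_a = 0.5, time_rule = c("fixed", "peak"),
                         time = 15, variance_method = c("delta", "montecarlo"),
                         alpha = 0.05, seed = 1L, clamp_negative = FALSE,
                         out_dir = NULL) {
  time_rule <- match.arg(time_rule)
  variance_method <- match.arg(variance_method)
  if (is.character(latencies) && length(latencies) == 1)
    latencies <- read_hotplate_csv(latencies)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  mpe <- stage("mpe", latencies_to_mpe(latencies,
                                       clamp_negative = clamp_negative))
  collapsed <- stage("collapse",
                     collapse_timecourse(mpe, rule = time_rule, time = time))

  arm <- function(label) {
    sub <- collapsed[collapsed$treatment == label, , drop = FALSE]
    if (nrow(sub) == 0) stop("no observations for treatment '", label, "'")
    attr(sub, "time_selection") <- attr(collapsed, "time_selection")
    sub
  }
  fits <- stage("fit", list(
    a = fit_dose_response(arm(treatment_a)),
    b = fit_dose_response(arm(treatment_b)),
    mix = fit_dose_response(arm(treatment_mix))
  ))
  names(fits) <- c(treatment_a, treatment_b, treatment_mix)
  for (nm in names(fits))
    if (!fits[[nm]]$converged)
      stop("pipeline stage 'fit' failed: fit for '", nm, "' did not converge")

  design <- mixture_design(treatment_a, treatment_b, rho_a = rho_a)
  additivity <- stage("additivity",
                      additive_ed50_uncertainty(fits[[treatment_a]],
                                                fits[[treatment_b]], design,
                                                method = variance_method,
                                                seed = seed))
  mixfit <- fits[[treatment_mix]]
  assessment <- stage("assessment",
                      assess_interaction(mixfit$model$ed50,
                                         mixfit$se[["ed50"]], additivity,
                                         alpha = alpha,
                                         df_mix = max(mixfit$df, 1)))
  geometry <- stage("geometry",
                    isobologram_geometry(fits[[treatment_a]],
                                         fits[[treatment_b]],
                                         mixfit$model$ed50,
                                         mixfit$se[["ed50"]], design,
                                         additivity = additivity))
  result <- structure(list(
    fits = fits,
    additivity = additivity,
    assessment = assessment,
    geometry = geometry,
    dose_summaries = summarize_doses(collapsed),
    config = list(treatment_a = treatment_a, treatment_b = treatment_b,
                  treatment_mix = treatment_mix, rho_a = rho_a,
                  time_rule = attr(collapsed, "time_selection"),
                  variance_method = variance_method, alpha = alpha,
                  seed = as.integer(seed), clamp_negative = clamp_negative,
                  package_version = as.character(utils::packageVersion("isobolr")))
  ), class = "isobole_pipeline")

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(pipeline_report(result),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    utils::write.csv(result$dose_summaries,
                     file.path(out_dir, "dose_summaries.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(geometry),
                     file.path(out_dir, "isobologram.csv"), row.names = FALSE)
  }
  result
}

#' Serializable report from a pipeline run
#'
#' @param pipeline An `isobole_pipeline` result.
#' @return A plain list mirroring the result types, suitable for JSON export;
#'   embeds the configuration and all seeds.
#' @export
pipeline_report <- function(pipeline) {
  stopifnot(inherits(pipeline, "isobole_pipeline"))
  a <- pipeline$assessment
  list(
    config = pipeline$config,
    fits = lapply(pipeline$fits, fit_report),
    additivity = list(ed50_add = pipeline$additivity$ed50_add,
                      se_add = pipeline$additivity$se_add,
                      df_add = pipeline$additivity$df_add,
                      potency_ratio = pipeline$additivity$potency_ratio,
                      variance_method = pipeline$additivity$variance_method),
    assessment = list(ed50_mix = a$ed50_mix, se_mix = a$se_mix,
                      ed50_add = a$ed50_add, se_add = a$se_add,
                      interaction_index = a$interaction_index,
                      t_statistic = a$t_statistic, df = a$df,
                      p_value = a$p_value, classification = a$classification,
                      alpha = a$alpha),
    geometry = as.data.frame(pipeline$geometry)
  )
}

#' @export
print.isobole_pipeline <- function(x, ...) {
  cat("Isobolographic analysis pipeline\n")
  for (nm in names(x$fits))
    cat(sprintf("  %-12s ED50 = %.4g +/- %.3g umol/kg\n", nm,
                x$fits[[nm]]$model$ed50, x$fits[[nm]]$se[["ed50"]]))
  print(x$assessment)
  invisible(x)
}
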