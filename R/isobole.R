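#' Fixed-ratio mixture design
#'
#' Describes an equi-effective two-drug mixture by the component labels and
#' their molar fractions.  Fractions must be nonnegative and sum to 1 (to
#' 1e-12); the equimolar design is `rho_a = rho_b = 0.5`.
#'
#' @param component_a,component_b Component labels.  `component_a` is the drug
#'   whose ED50 appears in the numerator of the additive-dose formula (and on
#'   the isobologram ordinate); `component_b`'s ED50 sits on the abscissa.
#' @param rho_a Molar fraction of component A in the mixture (default 0.5).
#' @param rho_b Molar fraction of component B (default `1 - rho_a`).
#' @return Object of class `mixture_design`.
#' @export
mixture_design <- function(component_a, component_b, rho_a = 0.5,
                           rho_b = 1 - rho_a) {
  stopifnot(is.character(component_a), is.character(component_b))
  if (!is.numeric(rho_a) || !is.numeric(rho_b) || rho_a < 0 || rho_b < 0)
    stop("molar fractions must be nonnegative")
  if (abs(rho_a + rho_b - 1) > 1e-12)
    stop("molar fractions must sum to 1 (tolerance 1e-12)")
  structure(list(component_a = component_a, component_b = component_b,
                 rho_a = rho_a, rho_b = rho_b),
            class = "mixture_design")
}

#' Potency ratio of two drugs
#'
#' The potency scale `R = ED50_A / ED50_B`: how many times more drug A than
#' drug B is needed for the half-maximal effect.
#'
#' @param ed50_a,ed50_b Component ED50s (umol/kg, > 0).
#' @return Dimensionless ratio.
#' @export
potency_ratio <- function(ed50_a, ed50_b) {
  if (any(ed50_a <= 0) || any(ed50_b <= 0))
    stop("ED50s must be positive")
  ed50_a / ed50_b
}

#' Theoretical additive ED50 of a fixed-ratio mixture (Loewe additivity)
#'
#' The total mixture dose expected to give the half-maximal effect if the two
#' drugs merely add (the additive theoretical point on the isobologram):
#' \deqn{ED_{50,add} = \frac{ED_{50,A}}{\rho_A + R\,\rho_B},\qquad
#'       R = ED_{50,A}/ED_{50,B}.}
#' The result is invariant under a simultaneous swap of components and
#' fractions, reduces to the single-drug ED50 at `rho = 1`, equals the
#' harmonic mean `2AB/(A+B)` for the equimolar design, and always lies
#' between the two component ED50s.
#'
#' @param ed50_a,ed50_b Component ED50s (umol/kg, > 0); A is the design's
#'   `component_a`.
#' @param design A [mixture_design()].
#' @return ED50_add in umol/kg.
#' @export
additive_ed50 <- function(ed50_a, ed50_b, design) {
  stopifnot(inherits(design, "mixture_design"))
  R <- potency_ratio(ed50_a, ed50_b)
  ed50_a / (design$rho_a + R * design$rho_b)
}

#' Uncertainty of the theoretical additive ED50
#'
#' Propagates the two component ED50 uncertainties into `ED50_add`.
#' Delta method (default): with \eqn{Z = A/(\rho_A + (A/B)\rho_B)},
#' \deqn{Var(Z) = \left(\frac{\rho_A}{D^2}\right)^2 Var(A)
#'             + \left(\frac{\rho_B A^2}{B^2 D^2}\right)^2 Var(B),}
#' where \eqn{D = \rho_A + (A/B)\rho_B}; the components are treated as
#' independent (they come from separate animal cohorts).  Propagation is on
#' the natural dose scale by default, matching natural-scale error bars on
#' the isobologram; `scale = "log"` propagates on log ED50s instead.
#' Monte-Carlo (`method = "montecarlo"`, alias `"bootstrap"`): paired
#' normal draws of the two ED50s pushed through the formula, seed-reproducible.
#'
#' The effective degrees of freedom of the additive ED50 are combined from the
#' two fits by Welch--Satterthwaite.
#'
#' @param fit_a,fit_b Converged [fit_dose_response()] objects for the two
#'   single-drug arms (A = `component_a` of the design).
#' @param design A [mixture_design()].
#' @param method `"delta"`, `"montecarlo"` or `"bootstrap"` (the last two are
#'   synonyms).
#' @param seed Seed for the Monte-Carlo propagation.
#' @param n_draws Monte-Carlo draws (default 5000).
#' @param scale `"natural"` (default) or `"log"` delta-method scale.
#' @return Object of class `additivity_result`: list with `ed50_add`, `se_add`,
#'   `df_add`, `potency_ratio`, `variance_method`, `design`, and the component
#'   estimates.
#' @export
additive_ed50_uncertainty <- function(fit_a, fit_b, design,
                                      method = c("delta", "montecarlo",
                                                 "bootstrap"),
                                      seed = 1L, n_draws = 5000,
                                      scale = c("natural", "log")) {
  stopifnot(inherits(fit_a, "dose_response_fit"),
            inherits(fit_b, "dose_response_fit"),
            inherits(design, "mixture_design"))
  method <- match.arg(method)
  if (method == "bootstrap") method <- "montecarlo"
  scale <- match.arg(scale)
  if (!fit_a$converged || !fit_b$converged)
    stop("refusing a non-converged fit")
  A <- fit_a$model$ed50; B <- fit_b$model$ed50
  seA <- fit_a$se[["ed50"]]; seB <- fit_b$se[["ed50"]]
  if (!is.finite(seA) || !is.finite(seB))
    stop("both fits must carry finite ED50 standard errors")
  rhoA <- design$rho_a; rhoB <- design$rho_b
  Z <- additive_ed50(A, B, design)

  D <- rhoA + (A / B) * rhoB
  gA <- rhoA / D^2
  gB <- rhoB * A^2 / (B^2 * D^2)
  vA <- seA^2; vB <- seB^2
  if (method == "delta") {
    if (scale == "natural") {
      varZ <- gA^2 * vA + gB^2 * vB
    } else {
      # propagate on log ED50s: Var(log X) ~ Var(X)/X^2, then back-transform
      vlA <- vA / A^2; vlB <- vB / B^2
      dlA <- gA * A / Z; dlB <- gB * B / Z   # d log Z / d log A, d log Z / d log B
      varlZ <- dlA^2 * vlA + dlB^2 * vlB
      varZ <- varlZ * Z^2
    }
    se_add <- sqrt(varZ)
  } else {
    draws <- .with_seed(seed, list(a = stats::rnorm(n_draws, A, seA),
                                   b = stats::rnorm(n_draws, B, seB)))
    As <- draws$a
    Bs <- draws$b
    ok <- As > 0 & Bs > 0
    Zs <- As[ok] / (rhoA + (As[ok] / Bs[ok]) * rhoB)
    se_add <- stats::sd(Zs)
  }

  # Welch-Satterthwaite combination of the two variance contributions
  cA <- gA^2 * vA; cB <- gB^2 * vB
  df_add <- if (cA + cB > 0)
    (cA + cB)^2 / (cA^2 / max(fit_a$df, 1) + cB^2 / max(fit_b$df, 1))
  else max(fit_a$df, 1) + max(fit_b$df, 1)

  structure(list(ed50_add = Z, se_add = se_add, df_add = df_add,
                 potency_ratio = potency_ratio(A, B),
                 variance_method = method, scale = scale, design = design,
                 ed50_a = A, se_a = seA, ed50_b = B, se_b = seB),
            class = "additivity_result")
}

#' @export
print.additivity_result <- function(x, ...) {
  cat(sprintf("Loewe additive ED50: %.4g +/- %.3g umol/kg (%s, R = %.3g)\n",
              x$ed50_add, x$se_add, x$variance_method, x$potency_ratio))
  invisible(x)
}

#' Classify a drug-drug interaction against the Loewe additive benchmark
#'
#' Compares the experimentally fitted mixture ED50 with the theoretical
#' additive ED50 by a two-sided t statistic
#' \deqn{t = \frac{ED_{50,add} - ED_{50,mix}}{\sqrt{SE_{add}^2 + SE_{mix}^2}}}
#' and reports the interaction index \eqn{\gamma = ED_{50,mix}/ED_{50,add}}.
#' The mixture is classified synergistic when it sits significantly below the
#' additive point (`ED50_mix < ED50_add` and `p < alpha`), antagonistic when
#' significantly above, and additive otherwise.
#'
#' @param ed50_mix,se_mix Fitted mixture ED50 and its SE (umol/kg).
#' @param additivity An [additive_ed50_uncertainty()] result.
#' @param alpha Significance level (default 0.05).
#' @param df_rule `"welch"` (default): Welch--Satterthwaite degrees of freedom
#'   from the two SEs and their fit degrees of freedom; `"fixed"`: use `df`.
#' @param df Degrees of freedom when `df_rule = "fixed"`.
#' @param df_mix Residual degrees of freedom of the mixture fit (needed for
#'   the Welch rule; defaults to `Inf` with a message if not supplied).
#' @return Object of class `interaction_assessment`: list with `ed50_mix`,
#'   `se_mix`, `ed50_add`, `se_add`, `interaction_index`, `t_statistic`, `df`,
#'   `p_value`, `classification`, `alpha`.
#' @export
assess_interaction <- function(ed50_mix, se_mix, additivity, alpha = 0.05,
                               df_rule = c("welch", "fixed"), df = NULL,
                               df_mix = Inf) {
  stopifnot(inherits(additivity, "additivity_result"))
  df_rule <- match.arg(df_rule)
  if (ed50_mix <= 0) stop("ED50_mix must be positive")
  if (se_mix < 0) stop("se_mix must be nonnegative")
  ed50_add <- additivity$ed50_add
  se_add <- additivity$se_add
  gamma <- ed50_mix / ed50_add

  if (se_mix == 0 && se_add == 0) {
    if (ed50_mix == ed50_add) {
      tstat <- 0; p <- 1; dfree <- NA_real_
    } else {
      warning("degenerate variance: both SEs are zero with unequal ED50s")
      tstat <- sign(ed50_add - ed50_mix) * Inf; p <- 0; dfree <- NA_real_
    }
  } else {
    tstat <- (ed50_add - ed50_mix) / sqrt(se_add^2 + se_mix^2)
    dfree <- if (df_rule == "fixed") {
      if (is.null(df)) stop("df_rule = \"fixed\" requires df")
      df
    } else {
      v1 <- se_add^2; v2 <- se_mix^2
      (v1 + v2)^2 / (v1^2 / max(additivity$df_add, 1) + v2^2 / df_mix)
    }
    p <- 2 * stats::pt(-abs(tstat), df = dfree)
  }

  classification <- if (p < alpha) {
    if (ed50_mix < ed50_add) "synergistic" else "antagonistic"
  } else "additive"

  structure(list(ed50_mix = ed50_mix, se_mix = se_mix,
                 ed50_add = ed50_add, se_add = se_add,
                 interaction_index = gamma,
                 t_statistic = tstat, df = dfree, p_value = p,
                 classification = classification, alpha = alpha),
            class = "interaction_assessment")
}

#' @export
print.interaction_assessment <- function(x, ...) {
  cat("Isobolographic interaction assessment\n")
  cat(sprintf("  ED50,mix = %.4g +/- %.3g, ED50,add = %.4g +/- %.3g umol/kg\n",
              x$ed50_mix, x$se_mix, x$ed50_add, x$se_add))
  cat(sprintf("  interaction index gamma = %.3g, t = %.3f (df %.1f), p = %.3g\n",
              x$interaction_index, x$t_statistic, x$df, x$p_value))
  cat(sprintf("  classification: %s (alpha = %g)\n", x$classification, x$alpha))
  invisible(x)
}

#' Isobologram geometry: additive line, additive point, mixture point
#'
#' Produces plot-ready coordinates for the classical isobologram: the additive
#' line joins the single-drug ED50s (component B on the abscissa, component A
#' on the ordinate); the additive point and the experimental mixture point are
#' each a total dose decomposed into per-component doses by the molar
#' fractions (component dose = total dose x that component's fraction).  The
#' additive point lies exactly on the Loewe line
#' `x / ED50_B + y / ED50_A = 1`.
#'
#' @param fit_a,fit_b Converged single-drug fits (A = ordinate drug).
#' @param ed50_mix,se_mix Mixture ED50 estimate and SE.
#' @param design A [mixture_design()].
#' @param additivity Optional precomputed [additive_ed50_uncertainty()] result;
#'   computed with delta-method defaults when missing.
#' @return Object of class `isobologram_geometry`: list with
#'   `axis_b_intercept`, `axis_a_intercept`, `additive_point`, `mixture_point`
#'   (each `c(dose_b, dose_a)`), `error_bars`, and `as.data.frame()` support
#'   for CSV export.
#' @export
isobologram_geometry <- function(fit_a, fit_b, ed50_mix, se_mix, design,
                                 additivity = NULL) {
  stopifnot(inherits(design, "mixture_design"))
  if (is.null(additivity))
    additivity <- additive_ed50_uncertainty(fit_a, fit_b, design)
  A <- fit_a$model$ed50; B <- fit_b$model$ed50
  Zadd <- additivity$ed50_add
  pt_add <- c(dose_b = design$rho_b * Zadd, dose_a = design$rho_a * Zadd)
  pt_mix <- c(dose_b = design$rho_b * ed50_mix, dose_a = design$rho_a * ed50_mix)
  structure(list(
    axis_b_intercept = B,
    axis_a_intercept = A,
    additive_point = pt_add,
    mixture_point = pt_mix,
    error_bars = list(
      axis_b = fit_b$se[["ed50"]],
      axis_a = fit_a$se[["ed50"]],
      additive = c(dose_b = design$rho_b * additivity$se_add,
                   dose_a = design$rho_a * additivity$se_add),
      mixture = c(dose_b = design$rho_b * se_mix,
                  dose_a = design$rho_a * se_mix)
    ),
    design = design
  ), class = "isobologram_geometry")
}

#' @export
as.data.frame.isobologram_geometry <- function(x, ...) {
  data.frame(
    point = c("axis_b_intercept", "axis_a_intercept", "additive", "mixture"),
    dose_b_umol_kg = c(x$axis_b_intercept, 0,
                       x$additive_point[["dose_b"]],
                       x$mixture_point[["dose_b"]]),
    dose_a_umol_kg = c(0, x$axis_a_intercept,
                       x$additive_point[["dose_a"]],
                       x$mixture_point[["dose_a"]]),
    se = c(x$error_bars$axis_b, x$error_bars$axis_a,
           sqrt(sum(x$error_bars$additive^2)),
           sqrt(sum(x$error_bars$mixture^2))),
    stringsAsFactors = FALSE
  )
}
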