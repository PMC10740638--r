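#' Hill dose-response function on the %MPE scale
#'
#' \deqn{E(D) = e_0 + (e_{max} - e_0) \frac{D^n}{D^n + ED_{50}^n}}
#' with `n` the Hill slope.  `E(0) = e0` and `E(ED50) = (e0 + emax)/2`.
#'
#' @param dose Dose vector (umol/kg, >= 0).
#' @param ed50 Half-maximal dose (> 0).
#' @param hill_slope Hill coefficient (> 0).
#' @param emax Maximal effect (percent, default 100).
#' @param e0 Baseline effect (percent, default 0).
#' @return Predicted effect (percent).
#' @export
hill_effect <- function(dose, ed50, hill_slope, emax = 100, e0 = 0) {
  out <- rep(e0, length(dose))
  pos <- dose > 0
  out[pos] <- e0 + (emax - e0) / (1 + (ed50 / dose[pos])^hill_slope)
  out
}

# Internal: build free-parameter vector / model from internal parameterization.
# theta holds a subset of (lz = log10 ed50, lh = log hill_slope, emax, e0).
.hill_unpack <- function(theta, free, fixed_values) {
  p <- fixed_values
  if ("ed50" %in% free)       p$ed50 <- 10^theta[["lz"]]
  if ("hill_slope" %in% free) p$hill_slope <- exp(theta[["lh"]])
  if ("emax" %in% free)       p$emax <- theta[["emax"]]
  if ("e0" %in% free)         p$e0 <- theta[["e0"]]
  p
}

#' Fit a Hill dose-response model to %MPE observations
#'
#' Least-squares estimation of the Hill model from collapsed \%MPE
#' observations (one per animal x dose).  By default `emax = 100` and `e0 = 0`
#' are held fixed -- \%MPE is already normalized to its ceiling -- and
#' `(ED50, hill_slope)` are free; a fully free 4-parameter fit is available
#' via `fixed = character(0)`.
#'
#' Fitting is performed on the log10-dose scale with a log-parameterized ED50
#' (and log Hill slope) so positivity is enforced without constraints.
#' Optimization uses Nelder-Mead from 5 log-spaced ED50 starting values across
#' the dose range (relative tolerance 1e-8 on the residual sum of squares,
#' at most 500 iterations); the best residual wins, ties broken by the start
#' whose log ED50 is closest to the median log dose.  Standard errors come
#' from the inverse of the approximate information at the optimum
#' (Gauss-Newton: \eqn{\hat\sigma^2 (J'J)^{-1}} with J the Jacobian of the
#' predicted effects in the internal parameterization).
#'
#' Censored observations (latency at cutoff, \%MPE = 100) enter the least
#' squares as 100\%.  The fit is flagged not converged when the optimizer does
#' not converge or the fitted ED50 falls outside
#' `[min(dose)/100, max(dose) * 100]`; downstream isobole operations refuse
#' non-converged fits.
#'
#' @param observations Data frame with columns `dose_umol_kg` and `mpe`
#'   (optionally `animal_id`, kept for bootstrap resampling).  At least 3
#'   distinct positive doses are required; dose-0 (vehicle) records are
#'   excluded from the fit.
#' @param fixed Character vector naming which of `"emax"`, `"e0"`,
#'   `"hill_slope"` are held at their defaults (default: `c("emax","e0")`).
#' @param emax,e0 Values used when the corresponding parameter is fixed, and
#'   starting values otherwise.
#' @param hill_slope Value used when `"hill_slope"` is in `fixed`.
#' @return Object of class `dose_response_fit`: a list with elements
#'   `model` (list `ed50`, `hill_slope`, `emax`, `e0`), `se` (named natural-scale
#'   standard errors), `se_log10_ed50`, `covariance` (internal-scale parameter
#'   covariance), `free`, `n_total`, `df`, `residual_ss`, `sigma2`,
#'   `converged`, `time_selection`, `data` (the observations used).
#' @export
fit_dose_response <- function(observations, fixed = c("emax", "e0"),
                              emax = 100, e0 = 0, hill_slope = 1) {
  stopifnot(all(c("dose_umol_kg", "mpe") %in% names(observations)))
  obs <- observations[observations$dose_umol_kg > 0, , drop = FALSE]
  doses <- obs$dose_umol_kg
  y <- obs$mpe
  if (length(unique(doses)) < 3)
    stop("design error: at least 3 distinct positive doses are required")
  if (length(fixed))
    fixed <- unique(match.arg(fixed, c("emax", "e0", "hill_slope"),
                              several.ok = TRUE))
  free <- c("ed50", setdiff(c("hill_slope", "emax", "e0"), fixed))
  fixed_values <- list(ed50 = NA_real_, hill_slope = hill_slope,
                       emax = emax, e0 = e0)

  ssq <- function(theta) {
    p <- .hill_unpack(theta, free, fixed_values)
    sum((y - hill_effect(doses, p$ed50, p$hill_slope, p$emax, p$e0))^2)
  }

  ld <- log10(range(doses))
  starts_lz <- seq(ld[1], ld[2], length.out = 5)
  start_theta <- function(lz) {
    th <- c(lz = lz)
    if ("hill_slope" %in% free) th <- c(th, lh = 0)
    if ("emax" %in% free) th <- c(th, emax = max(y))
    if ("e0" %in% free) th <- c(th, e0 = min(y))
    th
  }
  runs <- lapply(starts_lz, function(lz) {
    th0 <- start_theta(lz)
    if (length(th0) == 1) {
      r <- stats::optim(th0, ssq, method = "Brent",
                        lower = ld[1] - 3, upper = ld[2] + 3,
                        control = list(reltol = 1e-8, maxit = 500))
      names(r$par) <- names(th0)
      r
    } else {
      stats::optim(th0, ssq, method = "Nelder-Mead",
                   control = list(reltol = 1e-8, maxit = 500))
    }
  })
  vals <- vapply(runs, `[[`, numeric(1), "value")
  best_val <- min(vals)
  cand <- which(vals <= best_val * (1 + 1e-6) + 1e-12)
  med_ld <- stats::median(log10(doses))
  best <- cand[which.min(abs(vapply(runs[cand],
                                    function(r) r$par[["lz"]], numeric(1)) - med_ld))]
  opt <- runs[[best]]
  theta <- opt$par
  p <- .hill_unpack(theta, free, fixed_values)

  n <- length(y)
  np <- length(theta)
  rss <- opt$value
  dfres <- n - np
  sigma2 <- if (dfres > 0) rss / dfres else NA_real_

  # numerical Jacobian of predictions wrt internal parameters
  J <- matrix(NA_real_, n, np, dimnames = list(NULL, names(theta)))
  h <- pmax(1e-6, abs(theta) * 1e-6)
  for (k in seq_len(np)) {
    tp <- theta; tm <- theta
    tp[k] <- tp[k] + h[k]; tm[k] <- tm[k] - h[k]
    pp <- .hill_unpack(tp, free, fixed_values)
    pm <- .hill_unpack(tm, free, fixed_values)
    J[, k] <- (hill_effect(doses, pp$ed50, pp$hill_slope, pp$emax, pp$e0) -
               hill_effect(doses, pm$ed50, pm$hill_slope, pm$emax, pm$e0)) /
      (2 * h[k])
  }
  covmat <- tryCatch(sigma2 * solve(crossprod(J)),
                     error = function(e) matrix(NA_real_, np, np,
                                                dimnames = list(names(theta),
                                                                names(theta))))
  if (!is.null(dim(covmat))) dimnames(covmat) <- list(names(theta), names(theta))

  se_lz <- if ("lz" %in% names(theta) && is.finite(covmat["lz", "lz"]) &&
               covmat["lz", "lz"] >= 0) sqrt(covmat["lz", "lz"]) else NA_real_
  se <- c(
    ed50 = if (!is.na(se_lz)) log(10) * p$ed50 * se_lz else NA_real_,
    hill_slope = if ("lh" %in% names(theta) && is.finite(covmat["lh", "lh"]) &&
                     covmat["lh", "lh"] >= 0)
      p$hill_slope * sqrt(covmat["lh", "lh"]) else NA_real_,
    emax = if ("emax" %in% names(theta)) sqrt(covmat["emax", "emax"]) else NA_real_,
    e0 = if ("e0" %in% names(theta)) sqrt(covmat["e0", "e0"]) else NA_real_
  )

  # a flat response (no variation) or an absurd slope marks an unidentified
  # fit: the optimizer may sit at a degenerate step-function solution
  converged <- opt$convergence == 0 &&
    is.finite(p$ed50) &&
    p$ed50 >= min(doses) / 100 && p$ed50 <= max(doses) * 100 &&
    stats::sd(y) > 0 &&
    p$hill_slope >= 1e-3 && p$hill_slope <= 100

  structure(list(
    model = list(ed50 = p$ed50, hill_slope = p$hill_slope,
                 emax = p$emax, e0 = p$e0),
    free = free,
    se = se,
    se_log10_ed50 = se_lz,
    covariance = covmat,
    n_total = n,
    df = dfres,
    residual_ss = rss,
    sigma2 = sigma2,
    converged = converged,
    time_selection = attr(observations, "time_selection"),
    data = obs
  ), class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat("Hill dose-response fit (%MPE scale)\n")
  cat(sprintf("  ED50       : %.4g umol/kg (SE %.3g)\n",
              x$model$ed50, x$se[["ed50"]]))
  cat(sprintf("  Hill slope : %.4g%s\n", x$model$hill_slope,
              if ("hill_slope" %in% x$free)
                sprintf(" (SE %.3g)", x$se[["hill_slope"]]) else " (fixed)"))
  cat(sprintf("  Emax / E0  : %.4g / %.4g %s\n", x$model$emax, x$model$e0,
              if (any(c("emax", "e0") %in% x$free)) "" else "(fixed)"))
  cat(sprintf("  n = %d, residual SS = %.4g, converged = %s\n",
              x$n_total, x$residual_ss, x$converged))
  invisible(x)
}

#' Predicted %MPE from a fitted dose-response model
#'
#' @param object A `dose_response_fit`.
#' @param dose Doses at which to predict (default: observed doses).
#' @param ... Unused.
#' @return Predicted \%MPE vector.
#' @export
predict.dose_response_fit <- function(object, dose = object$data$dose_umol_kg,
                                      ...) {
  m <- object$model
  hill_effect(dose, m$ed50, m$hill_slope, m$emax, m$e0)
}

#' Standard error and confidence interval for a fitted ED50
#'
#' Delta method: the SE of log10(ED50) is read from the fit covariance and a
#' t-based interval on the log scale is exponentiated (so the interval
#' respects positivity); the natural-scale SE is `ln(10) * ED50 * SE(log10 ED50)`.
#' Bootstrap: animals are case-resampled with replacement within each dose,
#' the model refit per resample, and a percentile interval taken;
#' reproducible given `seed`.
#'
#' @param fit A converged `dose_response_fit`.
#' @param method `"delta"` (default) or `"bootstrap"`.
#' @param level Confidence level (default 0.95).
#' @param n_boot Number of bootstrap resamples (default 1000).
#' @param seed Integer seed for the bootstrap.
#' @return List with `se`, `lower`, `upper` (umol/kg), `level`, `method`, and
#'   for the bootstrap `n_effective` (resamples whose refit converged).
#' @export
ed50_interval <- function(fit, method = c("delta", "bootstrap"), level = 0.95,
                          n_boot = 1000, seed = 1L) {
  stopifnot(inherits(fit, "dose_response_fit"))
  if (!fit$converged)
    stop("refusing a non-converged fit")
  method <- match.arg(method)
  if (method == "delta") {
    se_lz <- fit$se_log10_ed50
    if (!is.finite(se_lz)) stop("no finite SE available for log10(ED50)")
    lz <- log10(fit$model$ed50)
    tq <- stats::qt(1 - (1 - level) / 2, df = max(fit$df, 1))
    list(se = fit$se[["ed50"]],
         lower = 10^(lz - tq * se_lz),
         upper = 10^(lz + tq * se_lz),
         level = level, method = "delta")
  } else {
    obs <- fit$data
    if (!("animal_id" %in% names(obs)))
      stop("bootstrap requires the original observations with animal_id attached")
    by_dose <- split(seq_len(nrow(obs)), obs$dose_umol_kg)
    fixed <- setdiff(c("emax", "e0", "hill_slope"), fit$free)
    boots <- .with_seed(seed, vapply(seq_len(n_boot), function(b) {
      idx <- unlist(lapply(by_dose, function(ii) sample(ii, length(ii),
                                                        replace = TRUE)),
                    use.names = FALSE)
      bf <- tryCatch(fit_dose_response(obs[idx, , drop = FALSE], fixed = fixed,
                                       emax = fit$model$emax, e0 = fit$model$e0,
                                       hill_slope = fit$model$hill_slope),
                     error = function(e) NULL)
      if (is.null(bf) || !bf$converged) NA_real_ else bf$model$ed50
    }, numeric(1)))
    ok <- boots[is.finite(boots)]
    if (length(ok) < 10) stop("too few converged bootstrap refits")
    alpha <- (1 - level) / 2
    qs <- stats::quantile(ok, c(alpha, 1 - alpha), names = FALSE)
    list(se = stats::sd(ok), lower = qs[1], upper = qs[2],
         level = level, method = "bootstrap", n_effective = length(ok))
  }
}
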