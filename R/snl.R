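#' Thermal cutoff for the radiant-heat withdrawal test
#'
#' The maximum exposure to the radiant heat source is three times the animal's
#' baseline (control) latency, to avoid tissue damage; longer measurements are
#' censored at the cutoff.
#'
#' @param baseline_latency Baseline paw-withdrawal latency in seconds (> 0).
#' @return Cutoff in seconds (`3 * baseline_latency`).
#' @export
thermal_cutoff <- function(baseline_latency) {
  if (any(!is.finite(baseline_latency)) || any(baseline_latency <= 0))
    stop("baseline latency must be positive")
  3 * baseline_latency
}

#' Truncate thermal latencies at the 3x-baseline cutoff
#'
#' @param value Measured withdrawal latencies (seconds).
#' @param baseline_latency Per-animal baseline latencies (recycled).
#' @return Data frame with `value` (truncated) and `censored` flag.  Applying
#'   the truncation twice equals applying it once.
#' @export
apply_thermal_cutoff <- function(value, baseline_latency) {
  cut <- thermal_cutoff(baseline_latency)
  data.frame(value = pmin(value, cut), censored = value > cut)
}

#' Group x session summary of SNL withdrawal time courses
#'
#' Mean +/- SEM per group x endpoint x session cell, in tidy long format.
#'
#' @param measurements Data frame with columns `group`, `endpoint`, `session`,
#'   `value` (and anything else, ignored).
#' @return Data frame with columns `group`, `endpoint`, `session`, `n`,
#'   `mean`, `sem` (SEM `NA` for singleton cells).
#' @export
summarize_timecourse <- function(measurements) {
  req <- c("group", "endpoint", "session", "value")
  miss <- setdiff(req, names(measurements))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  key <- interaction(measurements$group, measurements$endpoint,
                     measurements$session, drop = TRUE)
  rows <- lapply(split(measurements, key), function(sub) {
    n <- nrow(sub)
    data.frame(group = sub$group[1], endpoint = sub$endpoint[1],
               session = sub$session[1], n = n, mean = mean(sub$value),
               sem = if (n > 1) stats::sd(sub$value) / sqrt(n) else NA_real_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$endpoint, out$session, out$group), , drop = FALSE]
}

#' Dunnett many-to-one comparisons against a control group
#'
#' One-way ANOVA followed by Dunnett's test: each non-control group is
#' compared with the named control using the pooled residual variance, and the
#' familywise-adjusted two-sided p-values are obtained from the multivariate-t
#' distribution of the comparison statistics (correlation
#' \eqn{\lambda_i\lambda_j}, \eqn{\lambda_i = \sqrt{(1/n_0)/(1/n_i + 1/n_0)}}),
#' evaluated by seeded Genz--Bretz Monte-Carlo integration so results are
#' deterministic given the seed.  Adjusted p-values are forced to be at least
#' the raw p-values and monotone in |t|.
#'
#' With a single comparison the adjustment vanishes and the Dunnett p equals
#' the pooled-variance two-sample t-test p (up to Monte-Carlo tolerance).
#'
#' @param values Numeric response vector.
#' @param groups Group labels (same length as `values`).
#' @param control Label of the control group.
#' @param seed Integer seed for the multivariate-t integration
#'   (default 20231208).
#' @param n_draws Maximum Monte-Carlo integration points (default 1e5).
#' @return Object of class `dunnett_result`: list with `anova`
#'   (`f`, `df1`, `df2`, `p`), `comparisons` (data frame: `group`, `estimate`,
#'   `se`, `t`, `df`, `p_raw`, `p_adj`), `control`, `seed`.
#' @export
dunnett_vs_control <- function(values, groups, control, seed = 20231208L,
                               n_draws = 1e5) {
  groups <- as.character(groups)
  stopifnot(length(values) == length(groups))
  if (!(control %in% groups)) stop("control group not present: ", control)
  glev <- unique(groups)
  if (length(glev) < 2) stop("design error: at least 2 groups are required")
  ns <- vapply(split(values, groups), length, numeric(1))
  if (any(ns < 2)) stop("design error: at least 2 animals per group")

  means <- tapply(values, groups, mean)
  N <- length(values); k <- length(glev)
  ss_within <- sum((values - means[groups])^2)
  df2 <- N - k
  s2 <- ss_within / df2
  if (s2 <= 0)
    stop("degenerate variance: zero within-group variance everywhere")

  gm <- mean(values)
  ss_between <- sum(ns[names(means)] * (means - gm)^2)
  fstat <- (ss_between / (k - 1)) / s2
  p_anova <- stats::pf(fstat, k - 1, df2, lower.tail = FALSE)

  others <- setdiff(glev, control)
  n0 <- ns[[control]]
  est <- means[others] - means[[control]]
  se <- sqrt(s2 * (1 / ns[others] + 1 / n0))
  tstat <- est / se
  p_raw <- 2 * stats::pt(-abs(tstat), df2)

  m <- length(others)
  lam <- sqrt((1 / n0) / (1 / ns[others] + 1 / n0))
  corr <- tcrossprod(lam)
  diag(corr) <- 1
  p_adj <- vapply(seq_len(m), function(i) {
    q <- abs(tstat[i])
    if (!is.finite(q)) return(0)
    .with_seed(seed, {
      pr <- mvtnorm::pmvt(lower = rep(-q, m), upper = rep(q, m), df = df2,
                          corr = corr, sigma = NULL, type = "shifted",
                          algorithm = mvtnorm::GenzBretz(maxpts = n_draws,
                                                         abseps = 1e-4))
      1 - as.numeric(pr)
    })
  }, numeric(1))
  # enforce p_adj >= p_raw and monotonicity in |t|
  p_adj <- pmax(p_adj, p_raw)
  ord <- order(abs(tstat), decreasing = TRUE)
  p_adj[ord] <- cummax(p_adj[ord])
  p_adj <- pmin(p_adj, 1)

  structure(list(
    anova = list(f = fstat, df1 = k - 1, df2 = df2, p = p_anova),
    comparisons = data.frame(group = others, estimate = unname(est),
                             se = unname(se), t = unname(tstat), df = df2,
                             p_raw = unname(p_raw), p_adj = unname(p_adj),
                             stringsAsFactors = FALSE),
    control = control, seed = seed
  ), class = "dunnett_result")
}

#' @export
print.dunnett_result <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.3f, p = %.4g\n",
              x$anova$df1, x$anova$df2, x$anova$f, x$anova$p))
  cat(sprintf("Dunnett comparisons vs '%s':\n", x$control))
  print(x$comparisons, row.names = FALSE)
  invisible(x)
}

#' Paired t-test of a session against baseline
#'
#' Two-sided paired t-test on animal-matched differences (session minus
#' baseline).  Animals present in only one of the two sessions raise a pairing
#' error naming them; constant differences (zero variance) raise a
#' degenerate-variance error.
#'
#' @param session Session values.
#' @param baseline Baseline values.
#' @param animal_id Optional animal identifiers for each vector (lists
#'   `session_id` and `baseline_id`); when given, values are matched by id.
#' @return List with `t`, `df`, `p`, `mean_difference`, `n`.
#' @export
paired_vs_baseline <- function(session, baseline, animal_id = NULL) {
  if (!is.null(animal_id)) {
    sid <- animal_id$session_id; bid <- animal_id$baseline_id
    unmatched <- c(setdiff(sid, bid), setdiff(bid, sid))
    if (length(unmatched))
      stop("pairing error: unmatched animals: ",
           paste(unique(unmatched), collapse = ", "))
    baseline <- baseline[match(sid, bid)]
  }
  if (length(session) != length(baseline))
    stop("pairing error: session and baseline have different lengths")
  if (length(session) < 2) stop("at least 2 matched pairs are required")
  d <- session - baseline
  if (all(d == 0))   # no change whatsoever: t = 0 by convention
    return(list(t = 0, df = length(d) - 1, p = 1, mean_difference = 0,
                n = length(d)))
  if (stats::sd(d) == 0)
    stop("degenerate variance: all paired differences are equal")
  tt <- stats::t.test(session, baseline, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_difference = unname(tt$estimate),
       n = length(d))
}

#' Full SNL time-course report
#'
#' For each endpoint and post-baseline session: one-way ANOVA across groups
#' and Dunnett comparisons against the control group; plus, within each group,
#' a paired t-test of every post-baseline session against that group's
#' baseline.
#'
#' @param measurements Data frame with columns `animal_id`, `group`,
#'   `endpoint`, `session`, `value`.
#' @param control_group Control for the Dunnett family (default
#'   `"Sham+saline"`).
#' @param baseline_session Session label for the within-group comparisons
#'   (default `"baseline"`).
#' @param alpha Significance level recorded in the report (default 0.05).
#' @param seed Seed for the Dunnett multivariate-t integration.
#' @return Object of class `snl_report`: list with `summary`
#'   (from [summarize_timecourse()]), `dunnett` (data frame: endpoint,
#'   session, group, t, p_raw, p_adj, anova_f, anova_p), `paired` (data frame:
#'   endpoint, group, session, t, df, p), `control_group`, `alpha`.
#' @export
snl_report <- function(measurements, control_group = "Sham+saline",
                       baseline_session = "baseline", alpha = 0.05,
                       seed = 20231208L) {
  req <- c("animal_id", "group", "endpoint", "session", "value")
  miss <- setdiff(req, names(measurements))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  sessions <- setdiff(unique(measurements$session), baseline_session)
  endpoints <- unique(measurements$endpoint)

  dun <- list(); prs <- list()
  for (ep in endpoints) {
    epd <- measurements[measurements$endpoint == ep, , drop = FALSE]
    for (ss in sessions) {
      sub <- epd[epd$session == ss, , drop = FALSE]
      if (length(unique(sub$group)) < 2) next
      d <- dunnett_vs_control(sub$value, sub$group, control_group, seed = seed)
      dun[[length(dun) + 1]] <- cbind(
        endpoint = ep, session = ss, d$comparisons[, c("group", "t", "p_raw",
                                                       "p_adj")],
        anova_f = d$anova$f, anova_p = d$anova$p)
    }
    base <- epd[epd$session == baseline_session, , drop = FALSE]
    for (g in unique(epd$group)) {
      bg <- base[base$group == g, , drop = FALSE]
      for (ss in sessions) {
        sg <- epd[epd$session == ss & epd$group == g, , drop = FALSE]
        if (nrow(sg) < 2 || nrow(bg) < 2) next
        pt <- tryCatch(
          paired_vs_baseline(sg$value, bg$value,
                             animal_id = list(session_id = sg$animal_id,
                                              baseline_id = bg$animal_id)),
          error = function(e) NULL)
        if (is.null(pt)) next
        prs[[length(prs) + 1]] <- data.frame(
          endpoint = ep, group = g, session = ss, t = pt$t, df = pt$df,
          p = pt$p, stringsAsFactors = FALSE)
      }
    }
  }
  structure(list(
    summary = summarize_timecourse(measurements),
    dunnett = if (length(dun)) do.call(rbind, dun) else NULL,
    paired = if (length(prs)) do.call(rbind, prs) else NULL,
    control_group = control_group, alpha = alpha, seed = seed
  ), class = "snl_report")
}

#' @export
print.snl_report <- function(x, ...) {
  cat("SNL behavioral time-course report\n")
  cat(sprintf("  Dunnett control group: %s (alpha = %g)\n",
              x$control_group, x$alpha))
  if (!is.null(x$dunnett)) {
    flagged <- x$dunnett[x$dunnett$p_adj < x$alpha, , drop = FALSE]
    cat(sprintf("  %d of %d group x session comparisons flagged (p_adj < alpha)\n",
                nrow(flagged), nrow(x$dunnett)))
  }
  invisible(x)
}
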