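test_that("potency ratio is the plain ED50 ratio and rejects nonpositive input", {
  expect_equal(potency_ratio(7.8, 7.8), 1)
  expect_equal(potency_ratio(10, 5), 2)
  expect_equal(potency_ratio(5, 10), 0.5)
  expect_error(potency_ratio(-1, 5), "positive")
  expect_error(potency_ratio(5, 0), "positive")
})

test_that("additive ED50 obeys the Loewe identities", {
  eq <- mixture_design("A", "B", rho_a = 0.5)
  expect_equal(additive_ed50(10, 5, eq), 20 / 3, tolerance = 1e-9)
  # equimolar case = harmonic mean
  expect_equal(additive_ed50(10, 5, eq), 2 * 10 * 5 / 15)
  # Loewe identity: equal potencies give that potency for any rho
  for (rho in c(0.2, 0.5, 0.9)) {
    d <- mixture_design("A", "B", rho_a = rho)
    expect_equal(additive_ed50(7, 7, d), 7)
  }
  # single-drug limits
  expect_equal(additive_ed50(10, 5, mixture_design("A", "B", rho_a = 1)), 10)
  expect_equal(additive_ed50(10, 5, mixture_design("A", "B", rho_a = 0)), 5)
})

test_that("additive ED50 is swap-symmetric, bounded and monotone in rho", {
  set.seed(3)
  for (i in 1:50) {
    A <- runif(1, 0.1, 50); B <- runif(1, 0.1, 50); rho <- runif(1, 0.01, 0.99)
    zad <- additive_ed50(A, B, mixture_design("A", "B", rho_a = rho))
    swap <- additive_ed50(B, A, mixture_design("B", "A", rho_a = 1 - rho))
    expect_equal(zad, swap, tolerance = 1e-12)
    expect_gte(zad, min(A, B) - 1e-12)
    expect_lte(zad, max(A, B) + 1e-12)
  }
  rhos <- seq(0.05, 0.95, by = 0.05)
  z <- vapply(rhos, function(r)
    additive_ed50(12, 4, mixture_design("A", "B", rho_a = r)), numeric(1))
  expect_true(all(diff(z) > 0))  # more of the weaker drug -> larger total dose
})

test_that("mixture designs validate their molar fractions", {
  expect_error(mixture_design("A", "B", rho_a = 0.5, rho_b = 0.6), "sum to 1")
  expect_error(mixture_design("A", "B", rho_a = -0.1, rho_b = 1.1),
               "nonnegative")
})

make_fit_with <- function(ed50, se_ed50, df = 38) {
  # minimal converged fit object for propagation tests
  f <- list(model = list(ed50 = ed50, hill_slope = 1.5, emax = 100, e0 = 0),
            free = c("ed50", "hill_slope"),
            se = c(ed50 = se_ed50, hill_slope = NA, emax = NA, e0 = NA),
            se_log10_ed50 = se_ed50 / (log(10) * ed50),
            df = df, n_total = df + 2, converged = TRUE)
  class(f) <- "dose_response_fit"
  f
}

test_that("delta propagation of the additive ED50 matches closed forms", {
  eq <- mixture_design("A", "B", rho_a = 0.5)
  # no input variance -> no output variance
  r0 <- additive_ed50_uncertainty(make_fit_with(10, 0), make_fit_with(5, 0), eq)
  expect_equal(r0$se_add, 0)
  # symmetric point: equal ED50s P, equal variances v -> SE = sqrt(v/2)
  v <- 4
  rs <- additive_ed50_uncertainty(make_fit_with(10, sqrt(v)),
                                  make_fit_with(10, sqrt(v)), eq)
  expect_equal(rs$se_add, sqrt(v / 2), tolerance = 1e-12)
})

test_that("delta and Monte-Carlo propagation agree on study-scale inputs", {
  eq <- mixture_design("A", "B", rho_a = 0.5)
  fa <- make_fit_with(10, 1); fb <- make_fit_with(5, 0.8)
  d <- additive_ed50_uncertainty(fa, fb, eq, method = "delta")
  mc <- additive_ed50_uncertainty(fa, fb, eq, method = "montecarlo",
                                  seed = 4, n_draws = 5000)
  expect_equal(mc$se_add / d$se_add, 1, tolerance = 0.1)
  # seed determinism of the Monte-Carlo route
  mc2 <- additive_ed50_uncertainty(fa, fb, eq, method = "montecarlo",
                                   seed = 4, n_draws = 5000)
  expect_identical(mc$se_add, mc2$se_add)
})

test_that("propagation refuses non-converged fits", {
  f <- make_fit_with(10, 1); f$converged <- FALSE
  expect_error(additive_ed50_uncertainty(f, make_fit_with(5, 1),
                                         mixture_design("A", "B")),
               "non-converged")
})

make_additivity <- function(ed50_add, se_add, df_add = 38) {
  structure(list(ed50_add = ed50_add, se_add = se_add, df_add = df_add,
                 potency_ratio = 1, variance_method = "delta",
                 design = mixture_design("A", "B")),
            class = "additivity_result")
}

test_that("interaction assessment reproduces hand-computed t statistics", {
  # null case
  a0 <- assess_interaction(5, 1, make_additivity(5, 1))
  expect_equal(a0$t_statistic, 0)
  expect_equal(a0$p_value, 1)
  expect_equal(a0$classification, "additive")
  expect_equal(a0$interaction_index, 1)

  # strongly synergistic, fixed df = 18
  syn <- assess_interaction(1.07, 0.43, make_additivity(10.7, 2.0),
                            df_rule = "fixed", df = 18)
  expect_equal(syn$t_statistic, 4.707, tolerance = 1e-3)
  expect_equal(syn$p_value, 2 * pt(-4.707429, 18), tolerance = 1e-4)
  expect_equal(syn$classification, "synergistic")
  expect_equal(syn$interaction_index, 0.1)

  # antagonistic
  ant <- assess_interaction(12, 1, make_additivity(6, 1), df_rule = "fixed",
                            df = 18)
  expect_equal(ant$t_statistic, -4.2426, tolerance = 1e-3)
  expect_equal(ant$classification, "antagonistic")
  expect_gt(ant$interaction_index, 1)
})

test_that("degenerate zero-variance assessments warn and report p = 0", {
  expect_warning(a <- assess_interaction(2, 0, make_additivity(10, 0)),
                 "degenerate variance")
  expect_equal(a$p_value, 0)
  expect_equal(a$classification, "synergistic")
})

test_that("isobologram geometry decomposes totals by molar fraction", {
  eq <- mixture_design("A", "B", rho_a = 0.5)
  fa <- make_fit_with(10, 1); fb <- make_fit_with(5, 0.8)
  g <- isobologram_geometry(fa, fb, ed50_mix = 4.8, se_mix = 0.5, eq)
  expect_equal(unname(g$mixture_point), c(2.4, 2.4))
  expect_equal(unname(g$additive_point), c(20 / 6, 20 / 6), tolerance = 1e-9)
  # additive point sits exactly on the Loewe line x/ED50_B + y/ED50_A = 1
  expect_equal(g$additive_point[["dose_b"]] / g$axis_b_intercept +
               g$additive_point[["dose_a"]] / g$axis_a_intercept, 1,
               tolerance = 1e-9)
  df <- as.data.frame(g)
  expect_equal(nrow(df), 4)
  expect_true(all(is.finite(df$dose_b_umol_kg)))
})
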