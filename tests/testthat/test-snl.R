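test_that("thermal cutoff is 3x baseline, truncation flags and is idempotent", {
  expect_equal(thermal_cutoff(10), 30)
  expect_equal(thermal_cutoff(26.1), 78.3)
  expect_error(thermal_cutoff(0), "positive")

  r <- apply_thermal_cutoff(80, 26.1)
  expect_equal(r$value, 78.3)
  expect_true(r$censored)
  r2 <- apply_thermal_cutoff(r$value, 26.1)
  expect_equal(r2$value, r$value)
  expect_false(r2$censored)
})

test_that("time-course summaries give mean +/- SEM per cell", {
  df <- data.frame(group = "SNL+saline", endpoint = "thermal",
                   session = "post_SNL_d7", value = c(14, 15, 16))
  s <- summarize_timecourse(df)
  expect_equal(s$mean, 15)
  expect_equal(s$sem, 0.5774, tolerance = 1e-4)
  one <- df[1, , drop = FALSE]
  expect_true(is.na(summarize_timecourse(one)$sem))
  df$value <- 14
  expect_equal(summarize_timecourse(df)$sem, 0)
})

test_that("Dunnett with one comparison reduces to the pooled t-test", {
  set.seed(42)
  x <- rnorm(8, 10, 2); y <- rnorm(9, 12, 2)
  d <- dunnett_vs_control(c(x, y), rep(c("ctrl", "trt"), c(8, 9)), "ctrl")
  tt <- t.test(y, x, var.equal = TRUE)
  expect_equal(d$comparisons$p_adj, tt$p.value, tolerance = 1e-3)
  expect_equal(d$comparisons$t, unname(tt$statistic), tolerance = 1e-10)
})

test_that("Dunnett p-values dominate Bonferroni and match multcomp", {
  set.seed(7)
  k <- 4; n <- 8
  values <- rnorm(k * n, rep(c(10, 11, 12, 10.5), each = n), 2)
  groups <- rep(paste0("g", 1:k), each = n)
  d <- dunnett_vs_control(values, groups, "g1")
  bonf <- pmin(d$comparisons$p_raw * (k - 1), 1)
  expect_true(all(d$comparisons$p_adj <= bonf + 0.005))
  expect_true(all(d$comparisons$p_adj >= d$comparisons$p_raw - 1e-12))
  # monotone in |t|
  ord <- order(abs(d$comparisons$t), decreasing = TRUE)
  expect_true(all(diff(d$comparisons$p_adj[ord]) >= -1e-12))

  # independent implementation: multcomp's Dunnett contrasts
  df <- data.frame(y = values, g = factor(groups))
  gl <- multcomp::glht(aov(y ~ g, df), linfct = multcomp::mcp(g = "Dunnett"))
  pm <- summary(gl, test = multcomp::adjusted("single-step"))$test$pvalues
  expect_equal(d$comparisons$p_adj, as.numeric(pm), tolerance = 0.005)
})

test_that("Dunnett adjusted p-values match a direct Monte-Carlo simulation", {
  set.seed(19)
  values <- rnorm(30, rep(c(20, 17, 16), each = 10), 3)
  groups <- rep(c("ctrl", "g2", "g3"), each = 10)
  d <- dunnett_vs_control(values, groups, "ctrl")
  p_mc <- mc_dunnett_oracle(d$comparisons$t, ns = c(10, 10), control_n = 10,
                            df = d$comparisons$df[1])
  expect_equal(d$comparisons$p_adj, pmax(p_mc, d$comparisons$p_raw),
               tolerance = 0.005)
})

test_that("Dunnett rejects degenerate designs", {
  expect_error(dunnett_vs_control(1:4, rep("a", 4), "a"), "2 groups")
  expect_error(dunnett_vs_control(c(1, 2), c("a", "b"), "a"), "2 animals")
  expect_error(dunnett_vs_control(rep(5, 8), rep(c("a", "b"), 4), "a"),
               "degenerate variance")
})

test_that("paired baseline comparisons match hand arithmetic", {
  expect_error(paired_vs_baseline(c(1, 2, 3), c(2, 3, 4)),
               "degenerate variance")
  r <- paired_vs_baseline(c(10, 11, 9), c(12, 15, 14))
  expect_equal(r$t, -4.1576, tolerance = 1e-4)
  expect_equal(r$df, 2)
  expect_equal(r$mean_difference, -11 / 3)

  expect_error(
    paired_vs_baseline(c(10, 11), c(12, 15),
                       animal_id = list(session_id = c("a", "b"),
                                        baseline_id = c("a", "c"))),
    "unmatched animals.*b")
})

test_that("identical session and baseline vectors give t = 0, p = 1", {
  x <- c(10, 12, 14, 9)
  r <- paired_vs_baseline(x, x)
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)
  expect_equal(r$mean_difference, 0)
})

test_that("snl_report flags the injury and recovery pattern", {
  sc <- snl_scenario(seed = 33)
  dat <- simulate_snl(sc)
  rep <- snl_report(dat)
  # SNL+saline differs from sham at every post-surgery session, both endpoints
  snl_rows <- rep$dunnett[rep$dunnett$group == "SNL+saline", ]
  expect_true(all(snl_rows$p_adj < 0.05))
  # treated thermal animals recover: day-14 not significantly below their own
  # baseline is not guaranteed at n = 6, but the paired table must exist
  expect_true(all(c("endpoint", "group", "session", "t", "p") %in%
                  names(rep$paired)))
  expect_true(all(rep$dunnett$p_adj >= rep$dunnett$p_raw - 1e-12))
})
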