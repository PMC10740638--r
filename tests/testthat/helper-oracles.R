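# Independent oracles and shared fixtures for the test suite.

# Brute-force grid-search least-squares oracle for the 2-parameter Hill fit
# (emax = 100, e0 = 0 fixed): exhaustive 400 x 400 grid over
# (log10 ED50, Hill slope). Independent of the package fitter.
grid_fit_oracle <- function(doses, mpe, n_grid = 400,
                            lz_range = log10(range(doses)) + c(-2, 2),
                            slope_range = c(0.2, 5)) {
  lz <- seq(lz_range[1], lz_range[2], length.out = n_grid)
  sl <- seq(slope_range[1], slope_range[2], length.out = n_grid)
  best <- list(rss = Inf)
  ld <- log10(doses)
  for (s in sl) {
    # E = 100 / (1 + 10^(s * (lz - log10 d))) for all lz at once
    M <- 100 / (1 + 10^(s * outer(lz, ld, "-")))   # n_grid x n_obs
    rss <- rowSums((M - matrix(mpe, n_grid, length(mpe), byrow = TRUE))^2)
    j <- which.min(rss)
    if (rss[j] < best$rss)
      best <- list(rss = rss[j], ed50 = 10^lz[j], slope = s,
                   lz_step = lz[2] - lz[1])
  }
  best
}

# Crude Monte-Carlo oracle for Dunnett adjusted p-values: simulate the max-|T|
# distribution of the comparison statistics under the null directly.
mc_dunnett_oracle <- function(tstats, ns, control_n, df, n_sim = 2e5,
                              seed = 777) {
  set.seed(seed)
  m <- length(tstats)
  lam <- sqrt((1 / control_n) / (1 / ns + 1 / control_n))
  # T_i = (Z_i - lam_i * Z0) / sqrt(S), with Z ~ N(0,1), S ~ chi2_df / df;
  # equivalently correlated MVN scaled by a shared chi factor.
  Z0 <- rnorm(n_sim)
  S <- sqrt(rchisq(n_sim, df) / df)
  maxT <- rep(0, n_sim)
  for (i in seq_len(m)) {
    Zi <- rnorm(n_sim)
    Ti <- (sqrt(1 - lam[i]^2) * Zi + lam[i] * Z0) / S
    maxT <- pmax(maxT, abs(Ti))
  }
  vapply(abs(tstats), function(q) mean(maxT >= q), numeric(1))
}

# Small noisy single-drug dataset for fitter tests.
make_noisy_arm <- function(seed, ed50 = 8, slope = 1.5,
                           doses = c(3, 5, 10, 30), n_per_dose = 10,
                           noise_sd = 12) {
  sc <- hotplate_scenario(
    drugs = list(drug = list(ed50 = ed50, hill_slope = slope, doses = doses)),
    mixture = NULL, n_per_dose = n_per_dose, times = 15, noise_sd = noise_sd,
    seed = seed)
  lat <- simulate_hot_plate(sc)
  collapse_timecourse(latencies_to_mpe(lat))
}
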