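test_that("hot-plate simulation is deterministic and has the design cardinality", {
  sc <- hotplate_scenario(seed = 99)
  a <- simulate_hot_plate(sc)
  b <- simulate_hot_plate(sc)
  expect_identical(a, b)

  n_arms <- length(sc$drugs) + 1          # two drugs + mixture
  n_doses <- 4
  expect_equal(nrow(a),
               n_arms * n_doses * sc$n_per_dose * length(sc$times))
})

test_that("all simulated latency records satisfy the measurement invariants", {
  sc <- hotplate_scenario(seed = 12)
  lat <- simulate_hot_plate(sc)
  expect_true(all(lat$latency_s > 0))
  expect_true(all(lat$latency_s <= lat$cutoff_s))
  expect_true(all(lat$control_latency_s > 0))
  expect_true(all(lat$control_latency_s < lat$cutoff_s))
  expect_true(all(lat$dose_umol_kg > 0))
  # %MPE conversion accepts everything the generator emits
  expect_silent(latencies_to_mpe(lat))
})

test_that("zero-noise simulation at the true ED50 and peak time gives 50% MPE", {
  sc <- hotplate_scenario(
    drugs = list(d = list(ed50 = 7.8, hill_slope = 1.5, doses = c(3, 7.8, 30))),
    mixture = NULL, noise_sd = 0, n_per_dose = 3, times = c(5, 15, 60),
    seed = 2)
  lat <- simulate_hot_plate(sc)
  m <- latencies_to_mpe(lat)
  at_peak <- m[m$dose_umol_kg == 7.8 & m$time_min == 15, ]
  expect_equal(at_peak$mpe, rep(50, nrow(at_peak)))
})

test_that("mixture truths follow the Loewe formula scaled by gamma", {
  sc <- hotplate_scenario(seed = 1)    # defaults: ED50s 17 and 7.8, gamma 0.1
  tr <- simulate_mixture_truth(sc)
  expect_equal(tr$ed50_add, 10.6935, tolerance = 1e-4)
  expect_equal(tr$ed50_mix, 1.0694, tolerance = 1e-4)

  sc1 <- hotplate_scenario(
    mixture = list(components = c("cris104", "dpz"), rho = c(0.5, 0.5),
                   gamma = 1, hill_slope = 1.5, doses = c(1, 3, 10)),
    seed = 1)
  tr1 <- simulate_mixture_truth(sc1)
  expect_equal(tr1$ed50_mix, tr1$ed50_add)

  # swapping the components leaves the truths unchanged
  scs <- hotplate_scenario(
    mixture = list(components = c("dpz", "cris104"), rho = c(0.5, 0.5),
                   gamma = 0.1, hill_slope = 1.5, doses = c(1, 3, 10)),
    seed = 1)
  trs <- simulate_mixture_truth(scs)
  expect_equal(trs$ed50_add, tr$ed50_add)
  expect_equal(trs$ed50_mix, tr$ed50_mix)
})

test_that("scenario validation names the offending fields", {
  expect_error(hotplate_scenario(noise_sd = -1), "noise_sd")
  expect_error(hotplate_scenario(
    drugs = list(x = list(ed50 = -3, hill_slope = 1, doses = c(1, 3, 10))),
    mixture = NULL), "x\\$ed50")
  expect_error(hotplate_scenario(baseline_mean = 40), "baseline_mean")
})

test_that("SNL simulation is deterministic, truncated and noise-free exact", {
  sc <- snl_scenario(seed = 8)
  a <- simulate_snl(sc)
  expect_identical(a, simulate_snl(sc))
  th <- a[a$endpoint == "thermal", ]
  for (id in unique(th$animal_id)) {
    sub <- th[th$animal_id == id, ]
    base <- sub$value[sub$session == "baseline"]
    expect_true(all(sub$value[sub$session != "baseline"] <=
                    thermal_cutoff(base) + 1e-12))
  }

  sc0 <- snl_scenario(between_sd = c(thermal = 0, mechanical = 0),
                      within_sd = c(thermal = 0, mechanical = 0), seed = 3)
  d0 <- simulate_snl(sc0)
  s0 <- summarize_timecourse(d0)
  snl_th <- s0[s0$group == "SNL+saline" & s0$endpoint == "thermal" &
               s0$session == "post_SNL_d7", ]
  expect_equal(snl_th$mean, 14.7)
  expect_equal(snl_th$sem, 0)
})

test_that("day-7 SNL thermal group means concentrate around the true 14.7 s", {
  # the recovered group mean should fall within twice the reported day-7
  # SEM (14.7 +/- 2.1 s) in nearly all replicates
  hits <- 0L
  n_rep <- 500
  for (r in seq_len(n_rep)) {
    d <- simulate_snl(snl_scenario(seed = 5000 + r))
    sub <- d[d$group == "SNL+saline" & d$endpoint == "thermal" &
             d$session == "post_SNL_d7", ]
    if (abs(mean(sub$value) - 14.7) <= 2 * 2.1) hits <- hits + 1L
  }
  expect_gte(hits / n_rep, 0.95)
})

test_that("malformed SNL trajectories are rejected", {
  bad <- matrix(1, 2, 2)
  expect_error(snl_scenario(thermal_means = bad), "malformed trajectory")
})
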