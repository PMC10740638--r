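#' Hot-plate study scenario
#'
#' Bundles the true parameters of a simulated hot-plate dose-response study:
#' two single-drug arms and an optional fixed-ratio mixture arm whose true
#' ED50 is `gamma x ED50_add` (Loewe-additive truth scaled by the interaction
#' index; `gamma = 1` simulates no interaction, `gamma < 1` synergy).
#'
#' Defaults emulate the study design the package targets: oral dosing ladders
#' of 5--100 and 3--30 umol/kg for the two drugs, an equimolar mixture at
#' 0.6--4.8 umol/kg, n = 10 animals per dose, latencies read at 5--120 min
#' with a smooth effect-time kernel peaking at 15 min, a 35 s hot-plate
#' cutoff, baseline latencies ~10 s, and residual noise of 12 %MPE units.
#' The default true ED50 of the donepezil-like drug is 7.8 umol/kg; the
#' agonist-like drug's 17 umol/kg is a package calibration default (no
#' reference value exists for it).
#'
#' @param drugs Named list of single-drug arms, each a list with `ed50`,
#'   `hill_slope`, `doses`.
#' @param mixture `NULL`, or a list with `components` (two names from
#'   `drugs`), `rho` (molar fractions, sum 1), `gamma` (true interaction
#'   index), `hill_slope`, `doses`.
#' @param n_per_dose Animals per dose (default 10).
#' @param times Measurement times post-dose in minutes.
#' @param kernel_peak,kernel_width Effect-time kernel: a log-normal-shaped
#'   unimodal curve `exp(-(log(t/peak))^2 / (2 width^2))`, equal to 1 at the
#'   peak (default 15 min) and ~0 by 120 min (width 0.6).
#' @param baseline_mean,baseline_sd,baseline_range Truncated-normal baseline
#'   latency distribution in seconds (defaults mean 10, SD 1.5, range (3, 30)).
#' @param noise_sd Residual measurement noise in \%MPE units (default 12).
#' @param cutoff Hot-plate cutoff in seconds (default 35).
#' @param seed Integer seed.
#' @return Object of class `hotplate_scenario`.
#' @export
hotplate_scenario <- function(
    drugs = list(
      cris104 = list(ed50 = 17, hill_slope = 1.5, doses = c(5, 10, 30, 100)),
      dpz = list(ed50 = 7.8, hill_slope = 1.5, doses = c(3, 5, 10, 30))),
    mixture = list(components = c("cris104", "dpz"), rho = c(0.5, 0.5),
                   gamma = 0.1, hill_slope = 1.5,
                   doses = c(0.6, 1.2, 2.4, 4.8)),
    n_per_dose = 10, times = c(5, 15, 30, 60, 120),
    kernel_peak = 15, kernel_width = 0.6,
    baseline_mean = 10, baseline_sd = 1.5, baseline_range = c(3, 30),
    noise_sd = 12, cutoff = 35, seed = 1L) {
  bad <- character(0)
  for (nm in names(drugs)) {
    d <- drugs[[nm]]
    if (!is.numeric(d$ed50) || d$ed50 <= 0) bad <- c(bad, paste0(nm, "$ed50"))
    if (!is.numeric(d$hill_slope) || d$hill_slope <= 0)
      bad <- c(bad, paste0(nm, "$hill_slope"))
    if (!is.numeric(d$doses) || any(d$doses <= 0))
      bad <- c(bad, paste0(nm, "$doses"))
  }
  if (!is.null(mixture)) {
    if (!all(mixture$components %in% names(drugs)))
      bad <- c(bad, "mixture$components")
    if (abs(sum(mixture$rho) - 1) > 1e-12) bad <- c(bad, "mixture$rho")
    if (!is.numeric(mixture$gamma) || mixture$gamma <= 0)
      bad <- c(bad, "mixture$gamma")
  }
  if (n_per_dose < 1) bad <- c(bad, "n_per_dose")
  if (any(times < 0)) bad <- c(bad, "times")
  if (kernel_peak <= 0 || kernel_width <= 0)
    bad <- c(bad, "kernel_peak/kernel_width")
  if (baseline_mean <= 0 || baseline_mean >= cutoff) bad <- c(bad, "baseline_mean")
  if (baseline_sd < 0) bad <- c(bad, "baseline_sd")
  if (noise_sd < 0) bad <- c(bad, "noise_sd")
  if (cutoff <= 0) bad <- c(bad, "cutoff")
  if (length(bad))
    stop("invalid scenario fields: ", paste(bad, collapse = ", "))
  structure(list(drugs = drugs, mixture = mixture, n_per_dose = n_per_dose,
                 times = times, kernel_peak = kernel_peak,
                 kernel_width = kernel_width, baseline_mean = baseline_mean,
                 baseline_sd = baseline_sd, baseline_range = baseline_range,
                 noise_sd = noise_sd, cutoff = cutoff, seed = as.integer(seed)),
            class = "hotplate_scenario")
}

#' Effect-time kernel of a hot-plate scenario
#'
#' Smooth unimodal multiplier on the Hill effect: 1 at the peak time,
#' decaying to ~0 by 120 min with the default width.
#'
#' @param time Minutes post-dose.
#' @param peak Peak time (minutes).
#' @param width Log-scale width.
#' @return Multiplier in (0, 1].
#' @export
effect_time_kernel <- function(time, peak = 15, width = 0.6) {
  k <- numeric(length(time))
  pos <- time > 0
  k[pos] <- exp(-(log(time[pos] / peak))^2 / (2 * width^2))
  k
}

#' True additive and mixture ED50s of a scenario
#'
#' Applies the Loewe additive-dose formula to the scenario's true component
#' ED50s and scales by the true interaction index:
#' `ED50_mix = gamma x ED50_add`.
#'
#' @param scenario A [hotplate_scenario()] with a mixture defined.
#' @return List with `ed50_add`, `ed50_mix`, `gamma`, `design`.
#' @export
simulate_mixture_truth <- function(scenario) {
  stopifnot(inherits(scenario, "hotplate_scenario"))
  mx <- scenario$mixture
  if (is.null(mx)) stop("scenario has no mixture defined")
  design <- mixture_design(mx$components[1], mx$components[2],
                           rho_a = mx$rho[1], rho_b = mx$rho[2])
  edA <- scenario$drugs[[mx$components[1]]]$ed50
  edB <- scenario$drugs[[mx$components[2]]]$ed50
  add <- additive_ed50(edA, edB, design)
  list(ed50_add = add, ed50_mix = mx$gamma * add, gamma = mx$gamma,
       design = design)
}

# truncated-normal draws by rejection (well-conditioned for the defaults)
.rtruncnorm <- function(n, mean, sd, lower, upper) {
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    x <- stats::rnorm(length(need), mean, sd)
    ok <- x > lower & x < upper
    out[need[ok]] <- x[ok]
    need <- need[!ok]
  }
  out
}

#' Simulate a hot-plate latency dataset
#'
#' For every arm (each drug and, if defined, the mixture), dose, animal and
#' time point: a baseline control latency is drawn from a truncated normal on
#' `baseline_range`; the true \%MPE is `kernel(t) x Hill(dose)` using the
#' arm's true parameters (mixture: `ED50_mix = gamma x ED50_add`); the
#' observed latency is
#' `control + (cutoff - control) x (MPE_true + noise)/100`, with noise in
#' \%MPE units, truncated to `(0, cutoff]` (floor 0.5 s, a physical reaction
#' floor) and censored at the cutoff.  Fully reproducible given the scenario
#' seed.
#'
#' @param scenario A [hotplate_scenario()].
#' @return Data frame of latency records with columns `animal_id`,
#'   `treatment`, `dose_umol_kg`, `time_min`, `latency_s`,
#'   `control_latency_s`, `cutoff_s`, plus attribute `provenance` (the
#'   scenario and the true parameter values, including the mixture truths).
#' @export
simulate_hot_plate <- function(scenario) {
  stopifnot(inherits(scenario, "hotplate_scenario"))
  cutoff <- scenario$cutoff

  arms <- lapply(names(scenario$drugs), function(nm) {
    d <- scenario$drugs[[nm]]
    list(name = nm, ed50 = d$ed50, hill_slope = d$hill_slope, doses = d$doses)
  })
  truth <- NULL
  if (!is.null(scenario$mixture)) {
    truth <- simulate_mixture_truth(scenario)
    mx <- scenario$mixture
    arms <- c(arms, list(list(
      name = paste(mx$components, collapse = "+"),
      ed50 = truth$ed50_mix, hill_slope = mx$hill_slope, doses = mx$doses)))
  }

  recs <- list()
  animal_counter <- 0L
  out <- .with_seed(scenario$seed, {
  for (arm in arms) {
    for (dose in arm$doses) {
      ids <- sprintf("%s_d%g_a%02d", arm$name, dose,
                     animal_counter + seq_len(scenario$n_per_dose))
      animal_counter <- animal_counter + scenario$n_per_dose
      control <- .rtruncnorm(scenario$n_per_dose, scenario$baseline_mean,
                             scenario$baseline_sd,
                             scenario$baseline_range[1],
                             min(scenario$baseline_range[2], cutoff))
      for (i in seq_len(scenario$n_per_dose)) {
        mpe_true <- effect_time_kernel(scenario$times, scenario$kernel_peak,
                                       scenario$kernel_width) *
          hill_effect(dose, arm$ed50, arm$hill_slope)
        eps <- if (scenario$noise_sd > 0)
          stats::rnorm(length(scenario$times), 0, scenario$noise_sd) else 0
        lat <- control[i] + (cutoff - control[i]) * (mpe_true + eps) / 100
        lat <- pmin(pmax(lat, 0.5), cutoff)
        recs[[length(recs) + 1]] <- data.frame(
          animal_id = ids[i], treatment = arm$name, dose_umol_kg = dose,
          time_min = scenario$times, latency_s = lat,
          control_latency_s = control[i], cutoff_s = cutoff,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, recs)
  })
  rownames(out) <- NULL
  attr(out, "provenance") <- list(
    scenario = scenario,
    truth = c(lapply(scenario$drugs, `[[`, "ed50"),
              if (!is.null(truth)) list(ed50_add = truth$ed50_add,
                                        ed50_mix = truth$ed50_mix,
                                        gamma = truth$gamma))
  )
  out
}

#' SNL chronic-pain scenario
#'
#' True group x session mean trajectories for the spinal-nerve-ligation time
#' course, for the thermal withdrawal latency (s) and mechanical threshold (g)
#' endpoints, with between-animal and within-animal (measurement) noise.
#'
#' Defaults are calibrated to the endpoint pattern of the study the package
#' targets: thermal latency falls from 26.1 s at baseline to 14.7 s seven days
#' after surgery in ligated animals (mechanical threshold 49.2 -> 25.9 g);
#' saline-treated ligated animals do not recover, while treated animals
#' recover to 22.5 s / 42.2 g by treatment day 14 (intermediate sessions
#' interpolated).  Sham animals stay at baseline.  n = 6 animals per group.
#' Noise SDs are chosen so simulated SEMs at n = 6 match the reported
#' 1.3--3.0 range.
#'
#' @param thermal_means,mechanical_means Matrices (group x session) of true
#'   means; rows `Sham+saline`, `SNL+saline`, `SNL+treatment`; columns
#'   `baseline`, `post_SNL_d7`, `treat_d3`, `treat_d7`, `treat_d10`,
#'   `treat_d14`.
#' @param between_sd,within_sd Named vectors (`thermal`, `mechanical`) of the
#'   between-animal and within-animal SDs.
#' @param n_per_group Animals per group (default 6).
#' @param seed Integer seed.
#' @return Object of class `snl_scenario`.
#' @export
snl_scenario <- function(
    thermal_means = NULL, mechanical_means = NULL,
    between_sd = c(thermal = 3, mechanical = 5),
    within_sd = c(thermal = 2, mechanical = 3),
    n_per_group = 6, seed = 1L) {
  groups <- c("Sham+saline", "SNL+saline", "SNL+treatment")
  sessions <- c("baseline", "post_SNL_d7", "treat_d3", "treat_d7", "treat_d10",
                "treat_d14")
  if (is.null(thermal_means)) {
    thermal_means <- rbind(
      `Sham+saline`   = c(26.1, 26.1, 26.1, 26.1, 26.1, 26.1),
      `SNL+saline`    = c(26.1, 14.7, 14.7, 14.7, 14.7, 14.7),
      `SNL+treatment` = c(26.1, 14.7, 16.5, 18.5, 20.5, 22.5))
    colnames(thermal_means) <- sessions
  }
  if (is.null(mechanical_means)) {
    mechanical_means <- rbind(
      `Sham+saline`   = c(49.2, 49.2, 49.2, 49.2, 49.2, 49.2),
      `SNL+saline`    = c(49.2, 25.9, 25.9, 25.9, 25.9, 25.9),
      `SNL+treatment` = c(49.2, 25.9, 29.0, 33.0, 38.0, 42.2))
    colnames(mechanical_means) <- sessions
  }
  for (m in list(thermal_means, mechanical_means)) {
    if (!is.matrix(m) || !identical(rownames(m), groups) ||
        !identical(colnames(m), sessions) || any(m <= 0))
      stop("malformed trajectory matrix: need positive group x session means ",
           "with rows ", paste(groups, collapse = ", "), " and columns ",
           paste(sessions, collapse = ", "))
  }
  if (any(between_sd < 0) || any(within_sd < 0)) stop("SDs must be >= 0")
  if (n_per_group < 1) stop("n_per_group must be >= 1")
  structure(list(groups = groups, sessions = sessions,
                 thermal_means = thermal_means,
                 mechanical_means = mechanical_means,
                 between_sd = between_sd, within_sd = within_sd,
                 n_per_group = n_per_group, seed = as.integer(seed),
                 treatment_dose = "1.6 + 1.6 umol/kg (equimolar combination)"),
            class = "snl_scenario")
}

#' Simulate an SNL behavioral time course
#'
#' Each value is `true group x session mean + animal offset + measurement
#' noise`; the animal offset is drawn once per animal x endpoint
#' (between-animal SD) and the noise per measurement (within-animal SD).
#' Thermal measurements after baseline are truncated at 3x the animal's
#' measured baseline latency (the radiant-heat cutoff rule); all values are
#' floored at 0.5.  Seed-reproducible.
#'
#' @param scenario An [snl_scenario()].
#' @return Data frame with columns `animal_id`, `group`, `endpoint`,
#'   `session`, `value`, `censored`, plus a `provenance` attribute embedding
#'   the scenario.
#' @export
simulate_snl <- function(scenario) {
  stopifnot(inherits(scenario, "snl_scenario"))
  recs <- list()
  out <- .with_seed(scenario$seed, {
  for (ep in c("thermal", "mechanical")) {
    means <- if (ep == "thermal") scenario$thermal_means
             else scenario$mechanical_means
    bsd <- scenario$between_sd[[ep]]
    wsd <- scenario$within_sd[[ep]]
    for (g in scenario$groups) {
      for (i in seq_len(scenario$n_per_group)) {
        id <- sprintf("%s_a%02d", gsub("[^A-Za-z0-9]+", "", g), i)
        offset <- stats::rnorm(1, 0, bsd)
        vals <- means[g, ] + offset +
          stats::rnorm(length(scenario$sessions), 0, wsd)
        vals <- pmax(vals, 0.5)
        censored <- rep(FALSE, length(vals))
        if (ep == "thermal") {
          cut <- thermal_cutoff(vals[1])
          censored[-1] <- vals[-1] > cut
          vals[-1] <- pmin(vals[-1], cut)
        }
        recs[[length(recs) + 1]] <- data.frame(
          animal_id = id, group = g, endpoint = ep,
          session = scenario$sessions, value = unname(vals),
          censored = censored, stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, recs)
  })
  rownames(out) <- NULL
  attr(out, "provenance") <- list(scenario = scenario)
  out
}
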