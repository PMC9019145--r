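#' Cohort configuration for the synthetic-data generator
#'
#' Builds the parameter set describing a laboratory cohort of fish drawn
#' from warm- and ambient-source populations and acclimated to two
#' temperatures. The generative law for the "true" metabolic rate of a fish
#' of wet mass \eqn{M} (mg) at acclimation temperature \eqn{T} is the
#' mass--temperature model
#' \deqn{\log_{10} R = \log_{10} a + b_T \log_{10} M +
#'   \left[E_a^{(h)}\,(1/kT - 1/kT_0) + \gamma\, h_c t_c\right]/\ln 10 +
#'   u_{pop} + u_{tank} + \varepsilon,}
#' where \eqn{a} is the rate of a 1 mg fish at the reference temperature
#' \eqn{T_0} (25 degrees C), \eqn{b_T = b + \Delta b\, t_c} is the allometric
#' exponent (optionally shifted between acclimation temperatures),
#' \eqn{E_a^{(h)}} is the per-history activation energy in eV (negative for
#' rates that rise with temperature), \eqn{\gamma} an extra
#' history-by-temperature log offset, \eqn{h_c, t_c \in \{-1/2, +1/2\}} code
#' history (warm high) and temperature (30 degrees C high), and
#' \eqn{\varepsilon \sim N(0, \sigma^2)} is fish-level log10 noise shared
#' across traits. Routine and maximum rates are tied to the standard rate by
#' multiplicative gaps that keep SMR <= RMR <= MMR for every noise draw.
#'
#' Defaults emulate the study design this package targets: 8 populations
#' (4 warm-source, 4 ambient-source), 2 tanks per population (one per
#' acclimation temperature, 20 and 30 degrees C), 198 fish total, and
#' activation energies inside the ranges reported for each thermal history.
#'
#' @param n_populations number of source populations.
#' @param histories per-population thermal history, `"warm"` or `"ambient"`.
#' @param n_tanks_per_population tanks per population; tanks cycle through
#'   `acclimation_temps`.
#' @param n_fish_total cohort size, distributed as evenly as possible over
#'   tanks.
#' @param acclimation_temps acclimation temperatures in degrees Celsius.
#' @param mass_range_mg log-uniform wet-mass bounds (mg).
#' @param allometric_a named per-trait intercepts: rate (ug O2/min) of a
#'   1 mg fish at the reference temperature.
#' @param allometric_b named per-trait allometric exponents.
#' @param activation_energy list with components `ambient` and `warm`, each
#'   a named per-trait vector of activation energies (eV, signed).
#' @param mass_by_temperature_interaction shift in the allometric exponent
#'   between acclimation temperatures (value at 30 minus value at 20).
#' @param history_by_temperature_interaction additional natural-log offset
#'   applied as \eqn{\gamma h_c t_c}.
#' @param reference_temp_C anchor temperature for the intercepts.
#' @param trait_noise_sd fish-level log10 SD shared across the three traits.
#' @param ratio_noise_sd natural-log SD of the RMR/SMR and MMR/RMR gap
#'   multipliers.
#' @param population_sd,tank_sd log10 SDs of population and tank random
#'   intercepts on metabolic rate.
#' @param latency_meanlog,latency_history_effect,latency_temp_effect,latency_mass_effect,latency_metab_effect,latency_sdlog,latency_pop_sd,latency_tank_sd
#'   log-normal emergence-latency model: location intercept and effects of
#'   history (\eqn{h_c}), temperature (\eqn{t_c}), centred log10 mass, and
#'   fish-level metabolic residual, plus observation / population / tank SDs.
#' @param latency_limit_s right-censor limit of the boldness assay (s).
#' @param activity_log_mean,activity_history_effect,activity_interaction,activity_mass_effect,activity_metab_effect,activity_olre_sd,activity_pop_sd,activity_tank_sd
#'   Poisson-lognormal activity model: natural-log mean seconds moving and
#'   effects as above; `activity_olre_sd` is the observation-level
#'   (lognormal overdispersion) SD.
#' @param activity_window_s activity observation window (s); counts are
#'   capped here as in the assay.
#' @param seed integer seed; the generator is deterministic given the seed.
#' @return an object of class `cohort_config` (a named list).
#' @seealso [generate_cohort()], [zero_noise()]
#' @export
cohort_config <- function(n_populations = 8,
                          histories = rep(c("ambient", "warm"), each = 4),
                          n_tanks_per_population = 2,
                          n_fish_total = 198,
                          acclimation_temps = c(20, 30),
                          mass_range_mg = c(50, 1500),
                          allometric_a = c(smr = 0.20, rmr = 0.27, mmr = 0.452),
                          allometric_b = c(smr = 0.40, rmr = 0.40, mmr = 0.35),
                          activation_energy = list(
                            ambient = c(smr = -1.33, rmr = -1.30, mmr = -1.20),
                            warm = c(smr = -1.06, rmr = -1.05, mmr = -0.95)
                          ),
                          mass_by_temperature_interaction = -0.15,
                          history_by_temperature_interaction = 0,
                          reference_temp_C = 25,
                          trait_noise_sd = 0.10,
                          ratio_noise_sd = 0.4,
                          population_sd = 0.05,
                          tank_sd = 0.03,
                          latency_meanlog = 6.285,
                          latency_history_effect = -1.55,
                          latency_temp_effect = -0.3,
                          latency_mass_effect = 0.4,
                          latency_metab_effect = -2,
                          latency_sdlog = 1.2,
                          latency_pop_sd = 0.2,
                          latency_tank_sd = 0.1,
                          latency_limit_s = 600,
                          activity_log_mean = log(60),
                          activity_history_effect = -0.2,
                          activity_interaction = 0.4,
                          activity_mass_effect = -0.5,
                          activity_metab_effect = 2,
                          activity_olre_sd = sqrt(0.5),
                          activity_pop_sd = 0.15,
                          activity_tank_sd = 0.1,
                          activity_window_s = 300,
                          seed = NULL) {
  cfg <- mget(names(formals()))
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
  cfg
}

#' Remove all stochastic and group-level variation from a cohort config
#'
#' Convenience for identity tests: sets trait, ratio, population, tank and
#' behaviour noise SDs to zero so the generated cohort lies exactly on the
#' deterministic generative surfaces.
#'
#' @param config a [cohort_config()].
#' @return the modified config.
#' @export
zero_noise <- function(config) {
  for (f in c(
    "trait_noise_sd", "ratio_noise_sd", "population_sd", "tank_sd",
    "latency_pop_sd", "latency_tank_sd", "activity_olre_sd",
    "activity_pop_sd", "activity_tank_sd"
  )) {
    config[[f]] <- 0
  }
  validate_cohort_config(config)
  config
}

validate_cohort_config <- function(cfg) {
  fail <- function(param, why) {
    stop(sprintf("invalid cohort config: `%s` %s", param, why), call. = FALSE)
  }
  if (cfg$n_populations < 1) fail("n_populations", "must be >= 1")
  if (length(cfg$histories) != cfg$n_populations) {
    fail("histories", "must have one entry per population")
  }
  if (!all(cfg$histories %in% c("warm", "ambient"))) {
    fail("histories", "entries must be 'warm' or 'ambient'")
  }
  if (!all(c("warm", "ambient") %in% cfg$histories)) {
    fail("histories", "must represent both 'warm' and 'ambient'")
  }
  if (cfg$n_tanks_per_population < 1) fail("n_tanks_per_population", "must be >= 1")
  n_tanks <- cfg$n_populations * cfg$n_tanks_per_population
  if (cfg$n_fish_total < n_tanks) {
    fail("n_fish_total", "must provide at least one fish per tank")
  }
  if (any(cfg$acclimation_temps <= 0 | cfg$acclimation_temps >= 40)) {
    fail("acclimation_temps", "must lie within (0, 40) degrees C")
  }
  if (length(cfg$mass_range_mg) != 2 || any(cfg$mass_range_mg <= 0) ||
    diff(cfg$mass_range_mg) < 0) {
    fail("mass_range_mg", "must be positive increasing bounds")
  }
  traits <- c("smr", "rmr", "mmr")
  if (!all(traits %in% names(cfg$allometric_a)) || any(cfg$allometric_a <= 0)) {
    fail("allometric_a", "needs positive smr/rmr/mmr entries")
  }
  if (!all(traits %in% names(cfg$allometric_b)) || !all(is.finite(cfg$allometric_b))) {
    fail("allometric_b", "needs finite smr/rmr/mmr entries")
  }
  for (h in c("ambient", "warm")) {
    ea <- cfg$activation_energy[[h]]
    if (is.null(ea) || !all(traits %in% names(ea)) || !all(is.finite(ea))) {
      fail("activation_energy", sprintf("needs finite smr/rmr/mmr entries for '%s'", h))
    }
  }
  for (f in c(
    "trait_noise_sd", "ratio_noise_sd", "population_sd", "tank_sd",
    "latency_sdlog", "latency_pop_sd", "latency_tank_sd",
    "activity_olre_sd", "activity_pop_sd", "activity_tank_sd"
  )) {
    if (cfg[[f]] < 0) fail(f, "must be >= 0")
  }
  # The ordering SMR <= RMR <= MMR must hold on the deterministic surfaces
  # over the whole mass range for every group; the gap construction then
  # guarantees it for all noise draws.
  grid <- expand.grid(
    mass = cfg$mass_range_mg, history = c("ambient", "warm"),
    temp = cfg$acclimation_temps, stringsAsFactors = FALSE
  )
  det <- true_metabolic_rates(grid$mass, grid$history, grid$temp, cfg)
  if (any(det$rmr <= det$smr) || any(det$mmr <= det$rmr)) {
    fail(
      "allometric_a/allometric_b/activation_energy",
      "imply SMR < RMR < MMR is violated somewhere in the mass range"
    )
  }
  invisible(cfg)
}

#' Deterministic true metabolic rates under a cohort configuration
#'
#' Evaluates the generative mass--temperature law (see [cohort_config()])
#' with all random components at zero.
#'
#' @param mass_mg wet mass in mg.
#' @param history `"warm"` or `"ambient"` (recycled).
#' @param temp_C acclimation temperature in degrees Celsius (recycled).
#' @param config a [cohort_config()].
#' @return tibble with columns `smr`, `rmr`, `mmr` in ug O2/min.
#' @export
true_metabolic_rates <- function(mass_mg, history, temp_C, config) {
  n <- max(length(mass_mg), length(history), length(temp_C))
  mass_mg <- rep_len(mass_mg, n)
  history <- rep_len(history, n)
  temp_C <- rep_len(temp_C, n)
  h_c <- ifelse(history == "warm", 0.5, -0.5)
  # temperature contrast centred on the two acclimation temperatures
  temps <- sort(unique(config$acclimation_temps))
  t_c <- ifelse(temp_C >= mean(range(temps)), 0.5, -0.5)
  ikt <- inverse_kT(temp_C) - inverse_kT(config$reference_temp_C)
  out <- lapply(c("smr", "rmr", "mmr"), function(trait) {
    a <- config$allometric_a[[trait]]
    b <- config$allometric_b[[trait]] + config$mass_by_temperature_interaction * t_c
    ea <- ifelse(
      history == "warm",
      config$activation_energy$warm[[trait]],
      config$activation_energy$ambient[[trait]]
    )
    log10r <- log10(a) + b * log10(mass_mg) +
      (ea * ikt + config$history_by_temperature_interaction * h_c * t_c) / log(10)
    10^log10r
  })
  names(out) <- c("smr", "rmr", "mmr")
  tibble::as_tibble(out)
}

#' Generate a synthetic fish cohort with known ground truth
#'
#' Draws a full cohort under the generative model of [cohort_config()]:
#' log-uniform masses, true SMR/RMR/MMR (ordered by construction),
#' right-censored emergence latency, and Poisson-lognormal activity for
#' emergent fish. Columns prefixed `true_` are the hidden ground truth;
#' [write_cohort()] stores them in a separate file that the analysis
#' pipeline never reads.
#'
#' @param config a [cohort_config()].
#' @return a tibble with one row per fish: identifiers (`fish_id`,
#'   `population`, `tank`, `chamber_id`), design (`history`, `accl_temp_C`),
#'   morphometrics (`mass_mg`, `volume_ml`, `sex`), behaviour (`latency_s`,
#'   `latency_censored`, `emerged`, `activity_s`) and ground truth
#'   (`true_smr`, `true_rmr`, `true_mmr`, `true_latency_s`, `true_eps`).
#' @examples
#' cohort <- generate_cohort(cohort_config(seed = 1))
#' nrow(cohort)
#' @export
generate_cohort <- function(config = cohort_config()) {
  validate_cohort_config(config)
  if (!is.null(config$seed)) set.seed(config$seed)

  n_pop <- config$n_populations
  pops <- sprintf("P%02d", seq_len(n_pop))
  temps <- config$acclimation_temps
  tank_tbl <- expand.grid(
    tank_of_pop = seq_len(config$n_tanks_per_population),
    population = pops,
    stringsAsFactors = FALSE
  )
  tank_tbl$accl_temp_C <- temps[((tank_tbl$tank_of_pop - 1) %% length(temps)) + 1]
  tank_tbl$tank <- sprintf("T%02d", seq_len(nrow(tank_tbl)))
  n_tanks <- nrow(tank_tbl)

  # even allocation of the cohort across tanks
  base <- config$n_fish_total %/% n_tanks
  extra <- config$n_fish_total %% n_tanks
  tank_tbl$n_fish <- base + as.integer(seq_len(n_tanks) <= extra)

  fish <- tank_tbl[rep(seq_len(n_tanks), tank_tbl$n_fish), c("population", "tank", "accl_temp_C")]
  rownames(fish) <- NULL
  n <- nrow(fish)
  fish$fish_id <- sprintf("F%03d", seq_len(n))
  hist_of_pop <- setNames(config$histories, pops)
  fish$history <- unname(hist_of_pop[fish$population])
  fish$chamber_id <- sprintf("C%d", ((seq_len(n) - 1) %% 4) + 1)

  lo <- log10(config$mass_range_mg[1])
  hi <- log10(config$mass_range_mg[2])
  fish$mass_mg <- 10^runif(n, lo, hi)
  fish$volume_ml <- fish$mass_mg / 1000 # wet tissue density ~ 1 g/ml
  fish$sex <- sample(c("F", "M"), n, replace = TRUE)

  pop_eff <- setNames(rnorm(n_pop, 0, config$population_sd), pops)
  tank_eff <- setNames(rnorm(n_tanks, 0, config$tank_sd), tank_tbl$tank)
  eps <- rnorm(n, 0, config$trait_noise_sd)

  det <- true_metabolic_rates(fish$mass_mg, fish$history, fish$accl_temp_C, config)
  shared <- 10^(pop_eff[fish$population] + tank_eff[fish$tank] + eps)
  smr <- det$smr * unname(shared)

  s2 <- config$ratio_noise_sd^2
  gap_r <- exp(rnorm(n, 0, config$ratio_noise_sd) - s2 / 2)
  gap_m <- exp(rnorm(n, 0, config$ratio_noise_sd) - s2 / 2)
  rmr <- smr * (1 + (det$rmr / det$smr - 1) * gap_r)
  mmr <- rmr * (1 + (det$mmr / det$rmr - 1) * gap_m)

  h_c <- ifelse(fish$history == "warm", 0.5, -0.5)
  t_c <- ifelse(fish$accl_temp_C >= mean(range(temps)), 0.5, -0.5)
  cmass <- log10(fish$mass_mg) - mean(c(lo, hi))

  pop_b <- setNames(rnorm(n_pop, 0, config$latency_pop_sd), pops)
  tank_b <- setNames(rnorm(n_tanks, 0, config$latency_tank_sd), tank_tbl$tank)
  meanlog <- config$latency_meanlog +
    config$latency_history_effect * h_c +
    config$latency_temp_effect * t_c +
    config$latency_mass_effect * cmass +
    config$latency_metab_effect * eps +
    unname(pop_b[fish$population] + tank_b[fish$tank])
  latent <- exp(meanlog + config$latency_sdlog * rnorm(n))
  censored <- latent >= config$latency_limit_s
  fish$true_latency_s <- latent
  fish$latency_s <- pmin(latent, config$latency_limit_s)
  fish$latency_censored <- censored
  fish$emerged <- !censored

  pop_a <- setNames(rnorm(n_pop, 0, config$activity_pop_sd), pops)
  tank_a <- setNames(rnorm(n_tanks, 0, config$activity_tank_sd), tank_tbl$tank)
  log_lambda <- config$activity_log_mean +
    config$activity_history_effect * h_c +
    config$activity_interaction * h_c * t_c +
    config$activity_mass_effect * cmass +
    config$activity_metab_effect * eps +
    unname(pop_a[fish$population] + tank_a[fish$tank]) +
    rnorm(n, 0, config$activity_olre_sd)
  activity <- rpois(n, exp(log_lambda))
  activity <- pmin(activity, config$activity_window_s)
  fish$activity_s <- ifelse(fish$emerged, activity, NA_integer_)

  fish$true_smr <- smr
  fish$true_rmr <- rmr
  fish$true_mmr <- mmr
  fish$true_eps <- eps

  tibble::as_tibble(fish[, c(
    "fish_id", "population", "tank", "chamber_id", "history", "accl_temp_C",
    "mass_mg", "volume_ml", "sex", "latency_s", "latency_censored", "emerged",
    "activity_s", "true_smr", "true_rmr", "true_mmr", "true_latency_s",
    "true_eps"
  )])
}

#' Write / read a cohort as plain-text tables
#'
#' `write_cohort()` splits a generated cohort into an observable trait table
#' (`<stem>_traits.csv`) and a hidden ground-truth table
#' (`<stem>_truth.csv`); the analysis pipeline only ever reads the former.
#'
#' @param cohort tibble from [generate_cohort()].
#' @param stem file-path stem (without extension).
#' @return invisibly, the two file paths.
#' @export
write_cohort <- function(cohort, stem) {
  truth_cols <- grep("^true_", names(cohort), value = TRUE)
  traits <- cohort[, setdiff(names(cohort), truth_cols)]
  truth <- cohort[, c("fish_id", truth_cols)]
  paths <- c(
    traits = paste0(stem, "_traits.csv"),
    truth = paste0(stem, "_truth.csv")
  )
  write.csv(traits, paths[["traits"]], row.names = FALSE)
  write.csv(truth, paths[["truth"]], row.names = FALSE)
  invisible(paths)
}

#' @rdname write_cohort
#' @param path path to a `_traits.csv` file.
#' @export
read_cohort <- function(path) {
  tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
}
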