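#' Respirometry trace configuration
#'
#' Parameters of the simulated oxygen-logger signal. The chamber is a
#' closed, stirred 40 ml respirometer; during closed phases the oxygen
#' concentration (mg/L, equivalently ug/ml) declines at
#' \eqn{(\dot M O_2^{fish} + \dot M O_2^{blank}) / (V_r - V_f)} per minute,
#' where \eqn{V_r} and \eqn{V_f} are chamber and fish volume in ml and rates
#' are in ug O2/min. Flush phases relax the concentration back toward the
#' supply water concentration with time constant `flush_tau_s`. Background
#' (microbial) consumption drifts linearly in time between
#' `blank_rate_start` and `blank_rate_end` over the trial, mirroring growth
#' in the assay water; spontaneous activity during overnight SMR cycles is a
#' marked Poisson process of bursts that multiply the fish's instantaneous
#' consumption.
#'
#' @param chamber_volume_ml respirometer volume \eqn{V_r} (ml).
#' @param smr_flush_s,smr_wait_s,smr_measure_s intermittent-flow cycle
#'   timing (s): 5 min flush, 30 s wait, 15 min measurement.
#' @param smr_duration_h overnight SMR run length (h).
#' @param rmr_duration_s static RMR measurement length (s).
#' @param mmr_duration_s post-chase MMR measurement length (s).
#' @param blank_measure_s length of the pre- and post-trial blank
#'   measurements (s).
#' @param o2_start_mgL oxygen concentration of the supply water (mg/L).
#' @param sensor_noise_sd Gaussian sensor noise SD (mg/L).
#' @param blank_rate_start,blank_rate_end microbial oxygen consumption
#'   (ug O2/min) at the pre- and post-trial blank measurements.
#' @param burst_rate_per_h activity-burst rate during SMR cycles (events/h).
#' @param burst_multiplier factor (> 1) applied to fish consumption during
#'   a burst.
#' @param burst_duration_s burst length (s).
#' @param flush_tau_s flush relaxation time constant (s).
#' @param sampling_interval_s logger sampling interval (s).
#' @return an object of class `trace_config`.
#' @export
trace_config <- function(chamber_volume_ml = 40,
                         smr_flush_s = 300,
                         smr_wait_s = 30,
                         smr_measure_s = 900,
                         smr_duration_h = 18,
                         rmr_duration_s = 900,
                         mmr_duration_s = 300,
                         blank_measure_s = 900,
                         o2_start_mgL = 8,
                         sensor_noise_sd = 0.01,
                         blank_rate_start = 0.05,
                         blank_rate_end = 0.25,
                         burst_rate_per_h = 2,
                         burst_multiplier = 2.5,
                         burst_duration_s = 90,
                         flush_tau_s = 60,
                         sampling_interval_s = 5,
                         seed = NULL) {
  cfg <- mget(names(formals()))
  class(cfg) <- "trace_config"
  validate_trace_config(cfg)
  cfg
}

#' @param seed integer seed recorded with the config (used by the trace
#'   generators when no explicit seed is passed).
#' @noRd
validate_trace_config <- function(cfg) {
  fail <- function(param, why) {
    stop(sprintf("invalid trace config: `%s` %s", param, why), call. = FALSE)
  }
  if (cfg$chamber_volume_ml <= 0) fail("chamber_volume_ml", "must be > 0")
  for (f in c(
    "smr_flush_s", "smr_wait_s", "smr_measure_s", "smr_duration_h",
    "rmr_duration_s", "mmr_duration_s", "blank_measure_s", "flush_tau_s",
    "sampling_interval_s"
  )) {
    if (cfg[[f]] <= 0) fail(f, "must be > 0")
  }
  if (cfg$blank_rate_start < 0 || cfg$blank_rate_end < 0) {
    fail("blank_rate_start/blank_rate_end", "must be >= 0")
  }
  if (cfg$burst_rate_per_h < 0) fail("burst_rate_per_h", "must be >= 0")
  if (cfg$burst_multiplier <= 1) fail("burst_multiplier", "must be > 1")
  if (cfg$sampling_interval_s >= cfg$smr_measure_s) {
    fail("sampling_interval_s", "must be shorter than the measurement period")
  }
  invisible(cfg)
}

# Phase schedule of a full trial on the trial clock (t = 0 at RMR start).
trial_schedule <- function(config) {
  cyc <- config$smr_flush_s + config$smr_wait_s + config$smr_measure_s
  n_cyc <- max(1L, floor(config$smr_duration_h * 3600 / cyc))
  smr0 <- config$rmr_duration_s + config$smr_flush_s
  rows <- list(
    data.frame(
      kind = "RMR", phase = "measure", cycle = 1L,
      t_start = 0, t_end = config$rmr_duration_s
    ),
    data.frame(
      kind = "SMR", phase = "flush", cycle = 0L,
      t_start = config$rmr_duration_s, t_end = smr0
    )
  )
  for (i in seq_len(n_cyc)) {
    s <- smr0 + (i - 1) * cyc
    rows[[length(rows) + 1]] <- data.frame(
      kind = "SMR",
      phase = c("wait", "measure", "flush"),
      cycle = i,
      t_start = s + c(0, config$smr_wait_s, config$smr_wait_s + config$smr_measure_s),
      t_end = s + c(config$smr_wait_s, config$smr_wait_s + config$smr_measure_s, cyc)
    )
  }
  smr_end <- smr0 + n_cyc * cyc
  mmr0 <- smr_end + 300 # handling: chase to exhaustion outside the chamber
  rows[[length(rows) + 1]] <- data.frame(
    kind = "MMR", phase = "measure", cycle = 1L,
    t_start = mmr0, t_end = mmr0 + config$mmr_duration_s
  )
  out <- do.call(rbind, rows)
  attr(out, "n_smr_cycles") <- n_cyc
  out
}

# Simulate the oxygen signal over a phase schedule. `rate_fun(t_mid)` gives
# the total instantaneous consumption (ug O2/min) during closed phases.
# Integration uses the midpoint rule, which is exact for rates linear in
# time, so linear blank drift stays exactly recoverable downstream.
sim_o2_signal <- function(schedule, rate_fun, effective_volume_ml, config) {
  dt <- config$sampling_interval_s
  o2 <- config$o2_start_mgL
  segs <- vector("list", nrow(schedule))
  for (i in seq_len(nrow(schedule))) {
    seg <- schedule[i, ]
    tt <- seq(seg$t_start, seg$t_end, by = dt)
    if (seg$phase == "flush") {
      path <- config$o2_start_mgL +
        (o2 - config$o2_start_mgL) * exp(-(tt - seg$t_start) / config$flush_tau_s)
    } else {
      mids <- (tt[-length(tt)] + tt[-1]) / 2
      drop <- rate_fun(mids) * dt / 60 / effective_volume_ml
      path <- o2 - c(0, cumsum(drop))
    }
    o2 <- path[length(path)]
    segs[[i]] <- data.frame(
      kind = seg$kind, phase = seg$phase, cycle = seg$cycle,
      t_s = tt, o2_true = path
    )
    # drop the duplicated boundary sample except on the final segment
    if (i < nrow(schedule)) segs[[i]] <- segs[[i]][-nrow(segs[[i]]), ]
  }
  do.call(rbind, segs)
}

# Burst indicator: marked Poisson process over [t_min, t_max] (trial clock).
draw_bursts <- function(t_min, t_max, config) {
  span_h <- (t_max - t_min) / 3600
  n_ev <- rpois(1, config$burst_rate_per_h * span_h)
  if (n_ev == 0) {
    return(data.frame(start = numeric(0), end = numeric(0)))
  }
  start <- sort(runif(n_ev, t_min, t_max))
  data.frame(start = start, end = start + config$burst_duration_s)
}

burst_factor <- function(t, bursts, multiplier) {
  f <- rep(1, length(t))
  for (i in seq_len(nrow(bursts))) {
    f[t >= bursts$start[i] & t < bursts$end[i]] <- multiplier
  }
  f
}

#' Simulate a single respirometry trace
#'
#' Generates the oxygen time series of one trial kind for one fish (or a
#' blank chamber). SMR traces follow the intermittent-flow protocol
#' (flush/wait/measure cycles over ~18 h) with spontaneous activity bursts;
#' RMR and MMR are single static measurements; blank traces contain only
#' the drifting background consumption.
#'
#' @param fish one-row data frame with at least `fish_id`, `chamber_id`,
#'   `volume_ml`, `accl_temp_C` and the true rate for the requested kind
#'   (`true_smr`, `true_rmr` or `true_mmr`). For `kind = "blank"` the fish
#'   volume must be 0 (pass `blank_record()`).
#' @param kind `"SMR"`, `"RMR"`, `"MMR"` or `"blank"`.
#' @param config a [trace_config()].
#' @param seed optional integer seed.
#' @return tibble with columns `chamber_id`, `fish_id`, `kind`, `phase`,
#'   `cycle`, `t_s`, `o2_mgL`, `temp_C`.
#' @export
generate_trace <- function(fish, kind = c("SMR", "RMR", "MMR", "blank"),
                           config = trace_config(), seed = NULL) {
  kind <- match.arg(kind)
  if (!is.null(seed)) set.seed(seed) else if (!is.null(config$seed)) set.seed(config$seed)
  vf <- fish$volume_ml
  if (kind == "blank" && vf != 0) {
    stop("blank traces require a fish volume of 0 (water-only chamber)")
  }
  if (vf >= config$chamber_volume_ml) {
    stop("fish volume must be smaller than the chamber volume")
  }
  dur <- switch(kind,
    SMR = NULL,
    RMR = config$rmr_duration_s,
    MMR = config$mmr_duration_s,
    blank = config$blank_measure_s
  )
  if (kind == "SMR") {
    sched <- trial_schedule(config)
    sched <- sched[sched$kind == "SMR", ]
    sched$t_end <- sched$t_end - sched$t_start[1]
    sched$t_start <- sched$t_start - sched$t_start[1]
  } else {
    sched <- data.frame(
      kind = kind, phase = "measure", cycle = 1L, t_start = 0, t_end = dur
    )
  }
  span <- max(sched$t_end)
  blank_at <- function(t) {
    config$blank_rate_start +
      (config$blank_rate_end - config$blank_rate_start) * t / span
  }
  base <- switch(kind,
    SMR = fish$true_smr, RMR = fish$true_rmr, MMR = fish$true_mmr, blank = 0
  )
  bursts <- if (kind == "SMR" && config$burst_rate_per_h > 0) {
    draw_bursts(0, span, config)
  } else {
    data.frame(start = numeric(0), end = numeric(0))
  }
  rate_fun <- function(t) {
    base * burst_factor(t, bursts, config$burst_multiplier) + blank_at(t)
  }
  sig <- sim_o2_signal(sched, rate_fun, config$chamber_volume_ml - vf, config)
  sig$o2_mgL <- sig$o2_true + rnorm(nrow(sig), 0, config$sensor_noise_sd)
  tibble::tibble(
    chamber_id = fish$chamber_id,
    fish_id = if (kind == "blank") NA_character_ else fish$fish_id,
    kind = kind,
    phase = sig$phase,
    cycle = sig$cycle,
    t_s = sig$t_s,
    o2_mgL = sig$o2_mgL,
    temp_C = fish$accl_temp_C
  )
}

#' A water-only chamber record for blank traces
#'
#' @param chamber_id chamber identifier.
#' @param temp_C water temperature in degrees Celsius.
#' @return one-row data frame usable as the `fish` argument of
#'   [generate_trace()] with `kind = "blank"`.
#' @export
blank_record <- function(chamber_id = "C1", temp_C = 25) {
  data.frame(
    fish_id = NA_character_, chamber_id = chamber_id,
    volume_ml = 0, accl_temp_C = temp_C
  )
}

#' Simulate the full trial timeline for one fish
#'
#' Produces the complete trace set of one trial on a common clock: a
#' pre-trial blank measurement, the RMR measurement (t = 0), a flush, the
#' overnight intermittent-flow SMR run, the post-chase MMR measurement and
#' a post-trial blank. Background consumption drifts linearly between its
#' value at the pre-blank midpoint and its value at the post-blank
#' midpoint, so the linear blank interpolation used by the extraction stage
#' matches the generative law exactly.
#'
#' @param fish one-row cohort entry (see [generate_cohort()]).
#' @param config a [trace_config()].
#' @param seed optional integer seed.
#' @return tibble in the long trace format of [generate_trace()]; blank
#'   rows carry the fish's id in `fish_id` (they bracket that fish's trial)
#'   with `kind = "blank"`.
#' @export
generate_trial_traces <- function(fish, config = trace_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed) else if (!is.null(config$seed)) set.seed(config$seed)
  vf <- fish$volume_ml
  if (vf >= config$chamber_volume_ml) {
    stop("fish volume must be smaller than the chamber volume")
  }
  sched <- trial_schedule(config)
  trial_end <- max(sched$t_end)
  pre <- data.frame(
    kind = "blank", phase = "measure", cycle = 1L,
    t_start = -2 * config$blank_measure_s, t_end = -config$blank_measure_s
  )
  post <- data.frame(
    kind = "blank", phase = "measure", cycle = 2L,
    t_start = trial_end + config$blank_measure_s,
    t_end = trial_end + 2 * config$blank_measure_s
  )
  pre_mid <- mean(c(pre$t_start, pre$t_end))
  post_mid <- mean(c(post$t_start, post$t_end))
  blank_at <- function(t) {
    config$blank_rate_start +
      (config$blank_rate_end - config$blank_rate_start) *
        (t - pre_mid) / (post_mid - pre_mid)
  }
  smr_rows <- sched$kind == "SMR"
  bursts <- if (config$burst_rate_per_h > 0) {
    draw_bursts(min(sched$t_start[smr_rows]), max(sched$t_end[smr_rows]), config)
  } else {
    data.frame(start = numeric(0), end = numeric(0))
  }
  rate_fun <- function(t, kind) {
    base <- switch(kind,
      RMR = fish$true_rmr, MMR = fish$true_mmr, blank = 0,
      SMR = fish$true_smr
    )
    mult <- if (kind == "SMR") burst_factor(t, bursts, config$burst_multiplier) else 1
    base * mult + blank_at(t)
  }

  sim_part <- function(part_sched, vol) {
    # each trial part starts from freshly flushed water
    parts <- split(part_sched, part_sched$kind)[unique(part_sched$kind)]
    do.call(rbind, lapply(parts, function(ps) {
      kind <- ps$kind[1]
      sim_o2_signal(ps, function(t) rate_fun(t, kind), vol, config)
    }))
  }
  fish_sig <- sim_part(sched, config$chamber_volume_ml - vf)
  blank_sig <- rbind(
    sim_o2_signal(pre, function(t) rate_fun(t, "blank"), config$chamber_volume_ml, config),
    sim_o2_signal(post, function(t) rate_fun(t, "blank"), config$chamber_volume_ml, config)
  )
  sig <- rbind(fish_sig, blank_sig)
  sig <- sig[order(sig$t_s), ]
  sig$o2_mgL <- sig$o2_true + rnorm(nrow(sig), 0, config$sensor_noise_sd)
  tibble::tibble(
    chamber_id = fish$chamber_id,
    fish_id = fish$fish_id,
    kind = sig$kind,
    phase = sig$phase,
    cycle = sig$cycle,
    t_s = sig$t_s,
    o2_mgL = sig$o2_mgL,
    temp_C = fish$accl_temp_C
  )
}

#' Simulate trial traces for a whole cohort
#'
#' @param cohort tibble from [generate_cohort()].
#' @param config a [trace_config()].
#' @param seed root seed; fish `i` uses sub-stream `seed + i`.
#' @return long-format tibble of all traces.
#' @export
generate_cohort_traces <- function(cohort, config = trace_config(), seed = 1L) {
  out <- lapply(seq_len(nrow(cohort)), function(i) {
    generate_trial_traces(cohort[i, ], config, seed = seed + i)
  })
  dplyr::bind_rows(out)
}

#' Write / read long-format trace tables
#'
#' @param traces trace tibble.
#' @param path CSV path.
#' @export
write_traces <- function(traces, path) {
  write.csv(traces, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_traces
#' @param column_map optional named character vector remapping non-standard
#'   column names (e.g. a four-channel logger export) onto the standard
#'   schema; names are the standard columns, values the columns present in
#'   the file.
#' @export
read_traces <- function(path, column_map = NULL) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(column_map)) {
    for (std in names(column_map)) {
      if (!column_map[[std]] %in% names(x)) {
        stop(sprintf("column '%s' not found in %s", column_map[[std]], path))
      }
      names(x)[names(x) == column_map[[std]]] <- std
    }
  }
  needed <- c("chamber_id", "fish_id", "kind", "phase", "t_s", "o2_mgL")
  missing <- setdiff(needed, names(x))
  if (length(missing) > 0) {
    stop("trace table is missing columns: ", paste(missing, collapse = ", "))
  }
  tibble::as_tibble(x)
}
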