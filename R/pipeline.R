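#' Pipeline run configuration
#'
#' Bundles everything an end-to-end run needs: input paths (or a synthetic
#' cohort/trace configuration), stage options and the root seed. All
#' randomness flows from the root seed through fixed per-stage offsets, so
#' a config maps deterministically to its outputs.
#'
#' @param out_dir output directory (created if absent).
#' @param seed root integer seed.
#' @param cohort a [cohort_config()] for the synthetic cohort (ignored if
#'   `traits_path` is given).
#' @param trace a [trace_config()] for synthetic traces.
#' @param traits_path optional CSV of an existing per-fish trait table; the
#'   pipeline then starts at the scaling stage (`simulate_traces` is
#'   ignored).
#' @param traces_path optional CSV of existing raw traces.
#' @param simulate_traces simulate and process raw oxygen traces (TRUE) or
#'   work directly from the cohort's trait values (FALSE; faster, skips
#'   the measurement layer).
#' @param outlier_order,trim_leading_s respirometry options (see
#'   [extract_metabolism()]).
#' @param b_mode exponent used for mass normalization (see
#'   [activation_energy_table()]).
#' @param delta_threshold,average model-selection options (see
#'   [rank_and_average()]).
#' @param traits metabolic traits carried through scaling and inference.
#' @param behavior fit the behaviour models.
#' @param dry_run validate configuration and input schemas without
#'   computing.
#' @return a `run_config` list.
#' @export
run_config <- function(out_dir = tempfile("thermetab_run_"),
                       seed = 1L,
                       cohort = cohort_config(),
                       trace = trace_config(),
                       traits_path = NULL,
                       traces_path = NULL,
                       simulate_traces = FALSE,
                       outlier_order = "global",
                       trim_leading_s = 30,
                       b_mode = "group",
                       delta_threshold = 4,
                       average = "conditional",
                       traits = c("smr", "rmr", "mmr", "aerobic_scope"),
                       behavior = TRUE,
                       dry_run = FALSE) {
  cfg <- mget(names(formals()))
  class(cfg) <- "run_config"
  cfg
}

stage_seed <- function(seed, stage) {
  offsets <- c(cohort = 101L, traces = 2020L, models = 30303L)
  seed + offsets[[stage]]
}

#' Run the full measurement-to-inference pipeline
#'
#' Executes the stages simulate -> extract -> scale -> infer -> behaviour
#' in order, writing each stage's outputs as CSV into the configured
#' output directory together with a JSON manifest (seed, options, record
#' counts, md5 hashes of every output) and a plain-text run log with
#' per-stage timings. Any stage failure aborts with an error naming the
#' stage.
#'
#' @param config a [run_config()].
#' @return the manifest, invisibly (a list; also written as
#'   `manifest.json`).
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run.log")
  log_lines <- character(0)
  note <- function(...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(...))
    log_lines <<- c(log_lines, line)
    message(line)
  }
  run_stage <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
        call. = FALSE
      )
    })
    note("stage %-9s done in %.1fs", stage, proc.time()[["elapsed"]] - t0)
    out
  }
  outputs <- character(0)
  emit <- function(x, name) {
    path <- file.path(config$out_dir, name)
    write.csv(x, path, row.names = FALSE)
    outputs <<- c(outputs, path)
    path
  }

  if (config$dry_run) {
    if (!is.null(config$traits_path)) read_cohort(config$traits_path)
    if (!is.null(config$traces_path)) read_traces(config$traces_path)
    validate_cohort_config(config$cohort)
    validate_trace_config(config$trace)
    note("dry run: configuration and input schemas are valid")
    return(invisible(list(dry_run = TRUE, seed = config$seed)))
  }

  # -- simulate / load ------------------------------------------------------
  traces <- NULL
  if (!is.null(config$traits_path)) {
    cohort <- run_stage("load", read_cohort(config$traits_path))
    if (!is.null(config$traces_path)) traces <- read_traces(config$traces_path)
  } else {
    cohort <- run_stage("simulate", {
      cc <- config$cohort
      cc$seed <- stage_seed(config$seed, "cohort")
      ch <- generate_cohort(cc)
      write_cohort(ch, file.path(config$out_dir, "cohort"))
      outputs <- c(outputs, file.path(config$out_dir, "cohort_traits.csv"))
      ch
    })
    outputs <- c(outputs, file.path(config$out_dir, "cohort_traits.csv"))
    if (config$simulate_traces) {
      traces <- run_stage("traces", {
        tr <- generate_cohort_traces(
          cohort, config$trace,
          seed = stage_seed(config$seed, "traces")
        )
        tr
      })
      emit(traces, "traces.csv")
    }
  }

  # -- extract --------------------------------------------------------------
  estimates <- run_stage("extract", {
    if (!is.null(traces)) {
      extract_metabolism(
        traces, cohort,
        chamber_volume_ml = config$trace$chamber_volume_ml,
        trim_leading_s = config$trim_leading_s,
        outlier_order = config$outlier_order
      )
    } else {
      trait_source <- if ("smr" %in% names(cohort)) {
        cohort
      } else {
        dplyr::rename(cohort, smr = "true_smr", rmr = "true_rmr", mmr = "true_mmr")
      }
      dplyr::bind_rows(lapply(seq_len(nrow(trait_source)), function(i) {
        summarize_metabolism(
          trait_source$fish_id[i],
          smr = trait_source$smr[i],
          rmr = trait_source$rmr[i], mmr = trait_source$mmr[i]
        )
      }))
    }
  })
  emit(estimates, "metabolic_estimates.csv")

  meta_cols <- intersect(
    c(
      "fish_id", "population", "tank", "history", "accl_temp_C", "mass_mg",
      "volume_ml", "sex", "latency_s", "latency_censored", "emerged",
      "activity_s"
    ),
    names(cohort)
  )
  combined <- dplyr::inner_join(estimates, cohort[, meta_cols], by = "fish_id")

  # -- scale ----------------------------------------------------------------
  mtraits <- intersect(config$traits, c("smr", "rmr", "mmr"))
  scaling <- run_stage("scale", group_scaling(estimates, cohort, mtraits))
  emit(scaling, "group_scaling.csv")
  ea_hist <- run_stage("arrhenius", activation_energy_table(
    estimates, cohort, mtraits,
    by = "history", b_mode = config$b_mode, scaling = scaling
  ))
  emit(ea_hist, "activation_energy_history.csv")
  ea_pop <- activation_energy_table(
    estimates, cohort, mtraits,
    by = "population", b_mode = config$b_mode, scaling = scaling
  )
  emit(ea_pop, "activation_energy_population.csv")

  # -- infer ----------------------------------------------------------------
  selections <- run_stage("infer", {
    set.seed(stage_seed(config$seed, "models"))
    lapply(setNames(config$traits, config$traits), function(trait) {
      select_metabolic_models(
        combined, trait,
        delta_threshold = config$delta_threshold, average = config$average
      )
    })
  })
  sel_table <- dplyr::bind_rows(lapply(names(selections), function(trait) {
    cbind(trait = trait, selections[[trait]]$table)
  }))
  emit(sel_table, "model_selection.csv")
  coef_table <- dplyr::bind_rows(lapply(names(selections), function(trait) {
    cbind(trait = trait, selections[[trait]]$coefficients)
  }))
  emit(coef_table, "averaged_coefficients.csv")

  # -- behaviour ------------------------------------------------------------
  behavior_rows <- NULL
  if (isTRUE(config$behavior) && "latency_s" %in% names(combined)) {
    behavior_rows <- run_stage("behavior", {
      af <- analysis_frame(combined)
      rows <- list()
      bold <- fit_boldness_binomial(af)
      rows$boldness <- tibble::tibble(
        model = "boldness_binomial", term = names(coef(bold)),
        estimate = unname(coef(bold)),
        note = if (bold$separation) "separation" else ""
      )
      act <- fit_activity_pln(af)
      rows$activity <- tibble::tibble(
        model = "activity_pln", term = names(lme4::fixef(act)),
        estimate = unname(lme4::fixef(act)),
        note = sprintf("olre_var=%.3f", olre_variance(act))
      )
      temps <- sort(unique(af$accl_temp_C))
      for (tc in temps) {
        for (cv in intersect(c("smr", "rmr", "mmr"), names(af))) {
          ft <- fit_latency_censored(af, covariate = cv, accl_temp = tc)
          rows[[paste("lat", tc, cv, sep = "_")]] <- tibble::tibble(
            model = sprintf("latency_tobit_%gC_%s", tc, cv),
            term = names(coef(ft)), estimate = unname(coef(ft)),
            note = sprintf("sigma=%.1f;censored=%d/%d", ft$sigma, ft$n_censored, ft$n)
          )
        }
      }
      dplyr::bind_rows(rows)
    })
    emit(behavior_rows, "behavior_models.csv")
  }

  # -- manifest -------------------------------------------------------------
  outputs <- unique(outputs)
  manifest <- list(
    package = "thermetab",
    version = as.character(packageVersion("thermetab")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    options = list(
      outlier_order = config$outlier_order,
      trim_leading_s = config$trim_leading_s,
      b_mode = config$b_mode,
      delta_threshold = config$delta_threshold,
      average = config$average,
      simulate_traces = config$simulate_traces
    ),
    n_fish = nrow(cohort),
    n_traits = length(config$traits),
    outputs = as.list(tools::md5sum(outputs))
  )
  jsonlite::write_json(
    manifest, file.path(config$out_dir, "manifest.json"),
    auto_unbox = TRUE, pretty = TRUE
  )
  writeLines(log_lines, log_path)
  invisible(manifest)
}

#' Save / load generator and run configurations as YAML
#'
#' Round-trips [cohort_config()] and [trace_config()] objects through
#' plain-text YAML so that a simulation's full parameterization can be
#' archived next to its outputs.
#'
#' @param config a `cohort_config` or `trace_config`.
#' @param path YAML file path.
#' @return `save_config()` returns the path invisibly; `load_config()`
#'   returns the validated config object.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, c("cohort_config", "trace_config")))
  # YAML drops names on atomic vectors; store named vectors as maps
  as_mappable <- function(x) {
    if (is.atomic(x) && !is.null(names(x))) {
      as.list(x)
    } else if (is.list(x)) {
      lapply(x, as_mappable)
    } else {
      x
    }
  }
  payload <- list(type = class(config)[1], fields = lapply(unclass(config), as_mappable))
  yaml::write_yaml(payload, path, precision = 15)
  invisible(path)
}

#' @rdname save_config
#' @export
load_config <- function(path) {
  payload <- yaml::read_yaml(path)
  if (is.null(payload$type) ||
    !payload$type %in% c("cohort_config", "trace_config")) {
    stop("not a saved thermetab configuration: ", path)
  }
  fields <- payload$fields
  # YAML flattens named numeric vectors to lists; restore them
  fields <- lapply(fields, function(x) {
    if (is.list(x) && length(x) > 0 && all(vapply(x, is.numeric, TRUE))) {
      unlist(x)
    } else {
      x
    }
  })
  if (payload$type == "cohort_config") {
    fields$activation_energy <- lapply(fields$activation_energy, unlist)
    do.call(cohort_config, fields)
  } else {
    do.call(trace_config, fields)
  }
}
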