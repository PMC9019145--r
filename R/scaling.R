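#' Allometric scaling fit
#'
#' Least-squares regression of log10 metabolic rate (ug O2/min) on log10
#' wet mass (mg). The slope is the allometric scaling exponent b.
#'
#' @param mass_mg wet masses (mg), all > 0.
#' @param mo2 metabolic rates (ug O2/min), all > 0.
#' @return a `group_scaling` list: `intercept_log10_a`, `exponent_b`,
#'   `se_b`, `r_squared`, `n`.
#' @examples
#' m <- c(50, 100, 200, 400, 800)
#' fit_allometry(m, 0.1 * m^0.35)$exponent_b
#' @export
fit_allometry <- function(mass_mg, mo2) {
  if (length(mass_mg) != length(mo2)) stop("mass_mg and mo2 must have equal length")
  bad <- which(!is.finite(mass_mg) | !is.finite(mo2) | mass_mg <= 0 | mo2 <= 0)
  if (length(bad) > 0) {
    stop(
      "nonpositive or non-finite values at rows: ",
      paste(utils::head(bad, 10), collapse = ", ")
    )
  }
  n <- length(mo2)
  if (n < 3) stop("at least 3 observations are required")
  x <- log10(mass_mg)
  y <- log10(mo2)
  sxx <- sum((x - mean(x))^2)
  if (sxx == 0) stop("degenerate fit: all masses identical")
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  syy <- sum((y - mean(y))^2)
  b <- sxy / sxx
  a0 <- mean(y) - b * mean(x)
  rss <- syy - b * sxy
  rss <- max(rss, 0)
  se_b <- sqrt(rss / (n - 2) / sxx)
  r2 <- if (syy == 0) 1 else 1 - rss / syy
  structure(
    list(
      intercept_log10_a = a0, exponent_b = b, se_b = se_b,
      r_squared = r2, n = n
    ),
    class = "group_scaling"
  )
}

#' Mass-normalize metabolic rates
#'
#' \deqn{R_{norm} = \dot MO_2 \times M^{-b}} in ug O2 min^-1 mg^-b.
#'
#' @param mo2 rates (ug O2/min).
#' @param mass_mg masses (mg).
#' @param b allometric exponent used for normalization.
#' @return normalized rates.
#' @examples
#' mass_normalize(1.9, 100, 0.5) # 0.19
#' @export
mass_normalize <- function(mo2, mass_mg, b) {
  mo2 * mass_mg^(-b)
}

#' Two-point Arrhenius activation energy
#'
#' Activation energy of mass-normalized metabolic rate between exactly two
#' acclimation temperatures:
#' \deqn{E_a = \frac{\ln R_2 - \ln R_1}{1/kT_2 - 1/kT_1}}
#' with temperatures in Kelvin and \eqn{k = 8.62\times10^{-5}} eV/K. The
#' sign is not flipped: rates that increase with temperature give a
#' negative Ea (the 1/kT axis decreases with temperature).
#'
#' @param temp_C the two temperatures (degrees Celsius).
#' @param mean_rate the two group-mean normalized rates, both > 0.
#' @param history,trait optional labels carried through.
#' @return an `activation_energy` list: `Ea_eV`, `history`, `trait`,
#'   `temps_C`, `mean_rates`.
#' @examples
#' fit_activation_energy(c(20, 30), c(1, 2))$Ea_eV # ~ -0.531
#' @export
fit_activation_energy <- function(temp_C, mean_rate, history = NA_character_,
                                  trait = NA_character_) {
  if (length(temp_C) != 2 || length(unique(temp_C)) != 2) {
    stop("exactly two distinct temperatures are required")
  }
  if (length(mean_rate) != 2) stop("exactly two mean rates are required")
  if (any(!is.finite(mean_rate) | mean_rate <= 0)) {
    stop("mean rates must be positive")
  }
  ikt <- inverse_kT(temp_C)
  ea <- (log(mean_rate[2]) - log(mean_rate[1])) / (ikt[2] - ikt[1])
  structure(
    list(
      Ea_eV = ea, history = history, trait = trait,
      temps_C = temp_C, mean_rates = mean_rate
    ),
    class = "activation_energy"
  )
}

# internal: analysis frame joining estimates to fish metadata
join_metabolism <- function(estimates, meta) {
  need <- c("fish_id", "history", "accl_temp_C", "mass_mg")
  missing <- setdiff(need, names(meta))
  if (length(missing) > 0) {
    stop("meta is missing columns: ", paste(missing, collapse = ", "))
  }
  dplyr::inner_join(estimates, meta[, unique(c(need, "population"[
    "population" %in% names(meta)
  ]))], by = "fish_id")
}

#' Per-group allometric scaling table
#'
#' Fits [fit_allometry()] separately for every thermal history x
#' acclimation temperature combination, per metabolic trait.
#'
#' @param estimates per-fish estimate table (columns `fish_id` and the
#'   requested traits, e.g. from [extract_metabolism()]).
#' @param meta per-fish metadata (`fish_id`, `history`, `accl_temp_C`,
#'   `mass_mg`).
#' @param traits traits to fit.
#' @return tidy tibble: `trait`, `history`, `accl_temp_C`,
#'   `intercept_log10_a`, `exponent_b`, `se_b`, `r_squared`, `n`.
#' @export
group_scaling <- function(estimates, meta, traits = c("smr", "rmr", "mmr")) {
  df <- join_metabolism(estimates, meta)
  rows <- list()
  for (trait in traits) {
    if (!trait %in% names(df)) stop("trait column not found: ", trait)
    for (h in unique(df$history)) {
      for (tc in sort(unique(df$accl_temp_C))) {
        sub <- df[df$history == h & df$accl_temp_C == tc &
          !is.na(df[[trait]]), ]
        fit <- fit_allometry(sub$mass_mg, sub[[trait]])
        rows[[length(rows) + 1]] <- tibble::tibble(
          trait = trait, history = h, accl_temp_C = tc,
          intercept_log10_a = fit$intercept_log10_a,
          exponent_b = fit$exponent_b, se_b = fit$se_b,
          r_squared = fit$r_squared, n = fit$n
        )
      }
    }
  }
  dplyr::bind_rows(rows)
}

#' Activation energies of mass-normalized metabolic rates
#'
#' For each thermal history (or each population), normalizes individual
#' rates by M^-b and fits the two-point Arrhenius slope between the two
#' acclimation temperatures. By default b is the group-specific exponent
#' from the matching history x temperature x trait allometric fit
#' (`b_mode = "group"`); `b_mode = "global"` instead uses one exponent per
#' trait fitted across all fish.
#'
#' @inheritParams group_scaling
#' @param by `"history"` or `"population"`.
#' @param b_mode `"group"` or `"global"`.
#' @param scaling optional precomputed [group_scaling()] table.
#' @return tibble: `trait`, grouping column, `Ea_eV`, and the per-
#'   temperature mean normalized rates `rate_20ish`/`rate_30ish` named by
#'   temperature.
#' @export
activation_energy_table <- function(estimates, meta,
                                    traits = c("smr", "rmr", "mmr"),
                                    by = c("history", "population"),
                                    b_mode = c("group", "global"),
                                    scaling = NULL) {
  by <- match.arg(by)
  b_mode <- match.arg(b_mode)
  df <- join_metabolism(estimates, meta)
  if (by == "population" && !"population" %in% names(df)) {
    stop("meta must contain `population` for by = 'population'")
  }
  temps <- sort(unique(df$accl_temp_C))
  if (length(temps) != 2) {
    stop("exactly two acclimation temperatures are required")
  }
  if (is.null(scaling) && b_mode == "group") {
    scaling <- group_scaling(df[, c("fish_id", traits)], meta, traits)
  }
  b_for <- function(trait, h, tc) {
    if (b_mode == "global") {
      keep <- !is.na(df[[trait]])
      return(fit_allometry(df$mass_mg[keep], df[[trait]][keep])$exponent_b)
    }
    row <- scaling[scaling$trait == trait & scaling$history == h &
      scaling$accl_temp_C == tc, ]
    if (nrow(row) != 1) stop("no scaling fit for ", trait, "/", h, "/", tc)
    row$exponent_b
  }
  groups <- unique(df[[by]])
  rows <- list()
  for (trait in traits) {
    for (g in groups) {
      sub <- df[df[[by]] == g & !is.na(df[[trait]]), ]
      h <- sub$history[1]
      means <- vapply(temps, function(tc) {
        s2 <- sub[sub$accl_temp_C == tc, ]
        if (nrow(s2) == 0) {
          return(NA_real_)
        }
        b <- b_for(trait, h, tc)
        mean(mass_normalize(s2[[trait]], s2$mass_mg, b))
      }, 0)
      if (any(is.na(means))) next
      ea <- fit_activation_energy(temps, means, history = h, trait = trait)
      row <- tibble::tibble(trait = trait, Ea_eV = ea$Ea_eV)
      row[[by]] <- g
      row[[paste0("rate_", temps[1], "C")]] <- means[1]
      row[[paste0("rate_", temps[2], "C")]] <- means[2]
      rows[[length(rows) + 1]] <- row
    }
  }
  out <- dplyr::bind_rows(rows)
  out[, c("trait", by, "Ea_eV", setdiff(names(out), c("trait", by, "Ea_eV")))]
}
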