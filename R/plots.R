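#' Log-log allometry scatter with per-group fits
#'
#' @param estimates per-fish estimate table.
#' @param meta per-fish metadata.
#' @param trait trait column to plot.
#' @return a ggplot object.
#' @export
plot_allometry <- function(estimates, meta, trait = "smr") {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_allometry requires the ggplot2 package")
  }
  df <- join_metabolism(estimates, meta)
  df <- df[!is.na(df[[trait]]) & df[[trait]] > 0, ]
  ggplot2::ggplot(
    df,
    ggplot2::aes(
      x = log10(.data$mass_mg), y = log10(.data[[trait]]),
      colour = .data$history, linetype = factor(.data$accl_temp_C)
    )
  ) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE) +
    ggplot2::labs(
      x = "log10 mass (mg)", y = sprintf("log10 %s (ug O2/min)", toupper(trait)),
      colour = "thermal history", linetype = "acclimation (deg C)"
    )
}

#' Arrhenius plot of mass-normalized rates
#'
#' Mean log mass-normalized rate against 1/kT, one line per thermal
#' history; slopes are the activation energies.
#'
#' @param ea_table output of [activation_energy_table()] (by history).
#' @return a ggplot object.
#' @export
plot_arrhenius <- function(ea_table) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_arrhenius requires the ggplot2 package")
  }
  rate_cols <- grep("^rate_", names(ea_table), value = TRUE)
  temps <- as.numeric(sub("^rate_([0-9.]+)C$", "\\1", rate_cols))
  long <- do.call(rbind, lapply(seq_along(rate_cols), function(i) {
    data.frame(
      trait = ea_table$trait, history = ea_table$history,
      inv_kT = inverse_kT(temps[i]), log_rate = log(ea_table[[rate_cols[i]]])
    )
  }))
  ggplot2::ggplot(
    long,
    ggplot2::aes(
      x = .data$inv_kT, y = .data$log_rate,
      colour = .data$history, group = .data$history
    )
  ) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~trait, scales = "free_y") +
    ggplot2::labs(x = "1/kT (1/eV)", y = "ln mass-normalized rate")
}
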