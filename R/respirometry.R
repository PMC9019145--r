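#' Least-squares oxygen slope over one measurement segment
#'
#' Ordinary least-squares slope of oxygen concentration against time over a
#' closed measurement window, in ug ml^-1 min^-1 (mg L^-1 min^-1). The
#' slope is signed: consumption gives a negative slope. An optional leading
#' trim discards the first seconds of the window (mixing transient after
#' the flush/wait).
#'
#' @param t_s sample times in seconds, strictly increasing.
#' @param o2_mgL oxygen concentrations (mg/L).
#' @param trim_leading_s seconds discarded from the start of the window.
#' @return an object of class `measurement_cycle`: a list with
#'   `slope_per_min`, `r_squared`, `n_points`, `t_start`, `t_end`, `t_mid`.
#' @examples
#' tt <- seq(0, 600, by = 5)
#' fit_o2_slope(tt, 8 - 0.05 * tt / 60)
#' @export
fit_o2_slope <- function(t_s, o2_mgL, trim_leading_s = 0) {
  if (length(t_s) != length(o2_mgL)) stop("t_s and o2_mgL must have equal length")
  if (any(diff(t_s) <= 0)) stop("timestamps must be strictly increasing")
  keep <- t_s >= t_s[1] + trim_leading_s
  t_s <- t_s[keep]
  o2_mgL <- o2_mgL[keep]
  n <- length(t_s)
  if (n < 3) stop("segment rejected: fewer than 3 points after trimming")
  # closed-form normal equations; cross-checked against stats::lm in tests
  tbar <- mean(t_s)
  ybar <- mean(o2_mgL)
  sxx <- sum((t_s - tbar)^2)
  sxy <- sum((t_s - tbar) * (o2_mgL - ybar))
  syy <- sum((o2_mgL - ybar)^2)
  slope_s <- sxy / sxx
  r2 <- if (syy == 0) {
    if (abs(slope_s) < .Machine$double.eps) 1 else 0
  } else {
    sxy^2 / (sxx * syy)
  }
  structure(
    list(
      slope_per_min = slope_s * 60,
      r_squared = r2,
      n_points = n,
      t_start = t_s[1],
      t_end = t_s[n],
      t_mid = (t_s[1] + t_s[n]) / 2
    ),
    class = "measurement_cycle"
  )
}

#' Oxygen consumption rate from a fitted slope
#'
#' \deqn{\dot M O_2 = (V_r - V_f) \times (-\mathrm{slope})} with volumes in
#' ml and the slope in ug ml^-1 min^-1, giving ug O2/min. Consumption
#' (negative slope) is reported positive; a rising oxygen signal yields a
#' negative rate, which downstream steps flag rather than clip.
#'
#' @param cycle a `measurement_cycle` from [fit_o2_slope()], or a numeric
#'   slope in ug ml^-1 min^-1.
#' @param Vr respirometer volume (ml).
#' @param Vf fish volume (ml); 0 for blanks.
#' @return oxygen consumption rate in ug O2/min.
#' @examples
#' compute_mo2(-0.05, Vr = 40, Vf = 2) # 1.9
#' @export
compute_mo2 <- function(cycle, Vr, Vf = 0) {
  slope <- if (inherits(cycle, "measurement_cycle")) cycle$slope_per_min else cycle
  if (!is.numeric(slope) || length(slope) != 1) stop("invalid slope")
  if (Vf < 0) stop("fish volume must be >= 0")
  if (Vf >= Vr) stop("fish volume must be smaller than respirometer volume")
  (Vr - Vf) * (-slope)
}

#' Pre/post blank background series
#'
#' Background (microbial) consumption measured in water-only chambers
#' before and after a trial, interpolated linearly in time between the two
#' measurements and clamped to the endpoint values outside their interval.
#'
#' @param pre_time,post_time measurement midpoints (s, trial clock).
#' @param pre_rate,post_rate background rates (ug O2/min); either may be
#'   `NA` (one-sided constant correction, with a warning at correction
#'   time), but not both.
#' @return an object of class `blank_series`.
#' @export
blank_series <- function(pre_time, pre_rate, post_time, post_rate) {
  if (is.na(pre_rate) && is.na(post_rate)) {
    stop("at least one blank measurement is required")
  }
  if (!is.na(pre_rate) && !is.na(post_rate) && post_time <= pre_time) {
    stop("post-trial blank must be measured after the pre-trial blank")
  }
  if ((!is.na(pre_rate) && pre_rate < 0) || (!is.na(post_rate) && post_rate < 0)) {
    stop("blank rates must be >= 0")
  }
  structure(
    list(
      pre_time = pre_time, pre_rate = pre_rate,
      post_time = post_time, post_rate = post_rate
    ),
    class = "blank_series"
  )
}

#' Background-correct an oxygen consumption rate
#'
#' Subtracts the background rate, interpolated linearly in time between the
#' pre- and post-trial blank measurements, from a fish's measured rate.
#' With only one blank available the correction is constant (warned once
#' per call). Corrections larger than the measured rate yield negative
#' values, which are preserved (and flagged downstream) rather than
#' floored, so that cycle-level variability statistics stay unbiased.
#'
#' @param mo2 measured rate (ug O2/min); vectorised.
#' @param t_mid measurement midpoint(s) on the trial clock (s).
#' @param blanks a [blank_series()].
#' @return corrected rate(s), ug O2/min.
#' @examples
#' bs <- blank_series(0, 0.1, 36000, 0.3)
#' blank_correct(2.0, 18000, bs) # 1.8
#' @export
blank_correct <- function(mo2, t_mid, blanks) {
  stopifnot(inherits(blanks, "blank_series"))
  if (is.na(blanks$pre_rate)) {
    warning("pre-trial blank missing; applying constant post-trial correction")
    return(mo2 - blanks$post_rate)
  }
  if (is.na(blanks$post_rate)) {
    warning("post-trial blank missing; applying constant pre-trial correction")
    return(mo2 - blanks$pre_rate)
  }
  frac <- (t_mid - blanks$pre_time) / (blanks$post_time - blanks$pre_time)
  frac <- pmin(pmax(frac, 0), 1)
  mo2 - (blanks$pre_rate + frac * (blanks$post_rate - blanks$pre_rate))
}

#' Standard metabolic rate from cycle-level rates
#'
#' SMR is the mean of the lowest 10% of the per-cycle oxygen consumption
#' rates after excluding outliers beyond two standard deviations of the
#' mean. With `outlier_order = "global"` (default) the +/- 2 SD screen uses
#' the mean and SD of all cycles and is applied before taking the lowest
#' decile; `"subset"` instead takes the lowest decile first and screens
#' within it. The decile count is `ceiling(lowest_frac * n)`, never less
#' than one.
#'
#' @param cycle_mo2 blank-corrected per-cycle rates (ug O2/min).
#' @param outlier_order `"global"` or `"subset"` (see above).
#' @param lowest_frac fraction of cycles averaged (default 0.10).
#' @return list with `smr`, `n_outliers`, `n_used`, `n_cycles`.
#' @examples
#' extract_smr(1:20) # mean of {1, 2} = 1.5
#' @export
extract_smr <- function(cycle_mo2, outlier_order = c("global", "subset"),
                        lowest_frac = 0.10) {
  outlier_order <- match.arg(outlier_order)
  x <- cycle_mo2[!is.na(cycle_mo2)]
  n <- length(x)
  if (n < 2) stop("at least 2 cycle measurements are required")
  screen <- function(v, centre_v) {
    m <- mean(centre_v)
    s <- sd(centre_v)
    if (is.na(s) || s == 0) rep(TRUE, length(v)) else abs(v - m) <= 2 * s
  }
  if (outlier_order == "global") {
    keep <- screen(x, x)
    survivors <- x[keep]
    if (length(survivors) == 0) stop("all cycles excluded as outliers")
    k <- max(1L, ceiling(lowest_frac * length(survivors)))
    low <- sort(survivors)[seq_len(k)]
    n_out <- n - length(survivors)
  } else {
    k <- max(1L, ceiling(lowest_frac * n))
    low0 <- sort(x)[seq_len(k)]
    keep <- screen(low0, low0)
    low <- low0[keep]
    if (length(low) == 0) stop("all cycles excluded as outliers")
    n_out <- k - length(low)
  }
  list(
    smr = mean(low), n_outliers = n_out, n_used = length(low), n_cycles = n
  )
}

#' Assemble a per-fish metabolic estimate
#'
#' Combines SMR, RMR and MMR into the derived scopes: absolute aerobic
#' scope AS = MMR - SMR and factorial aerobic scope FAS = MMR / SMR. A
#' `chase_underestimate` flag is raised when MMR falls below RMR or SMR
#' (the exhaustive-chase protocol can underestimate true maximum rates);
#' non-positive SMR is flagged and FAS withheld.
#'
#' @param fish_id identifier.
#' @param smr,rmr,mmr rates in ug O2/min.
#' @param n_cycles_used,n_outliers_excluded SMR provenance.
#' @return one-row tibble (a `MetabolicEstimate`).
#' @examples
#' summarize_metabolism("F001", smr = 1, rmr = 1.35, mmr = 1.7)
#' @export
summarize_metabolism <- function(fish_id, smr, rmr = NA_real_, mmr = NA_real_,
                                 n_cycles_used = NA_integer_,
                                 n_outliers_excluded = NA_integer_) {
  flags <- character(0)
  if (!is.na(smr) && smr <= 0) flags <- c(flags, "nonpositive_smr")
  if (!is.na(mmr) && !is.na(smr) && mmr <= smr) flags <- c(flags, "chase_underestimate")
  if (!is.na(mmr) && !is.na(rmr) && mmr < rmr) {
    flags <- union(flags, "chase_underestimate")
  }
  as_ <- if (!is.na(mmr) && !is.na(smr)) mmr - smr else NA_real_
  fas <- if (!is.na(mmr) && !is.na(smr) && smr > 0) mmr / smr else NA_real_
  tibble::tibble(
    fish_id = fish_id, smr = smr, rmr = rmr, mmr = mmr,
    aerobic_scope = as_, factorial_scope = fas,
    n_cycles_used = n_cycles_used, n_outliers_excluded = n_outliers_excluded,
    flags = paste(flags, collapse = ";")
  )
}

#' Extract per-fish metabolic estimates from long-format traces
#'
#' Runs the full trace-processing chain for every fish in a trace table:
#' per-cycle oxygen slopes over the SMR measurement windows (with a leading
#' trim), conversion to rates via chamber and fish volumes, linear blank
#' correction anchored on the pre/post blank measurements, lowest-decile
#' SMR extraction, and single-window RMR and MMR rates.
#'
#' @param traces long-format trace tibble (see [generate_trial_traces()] or
#'   [read_traces()]); blank rows must carry the bracketed fish's id.
#' @param meta per-fish metadata with columns `fish_id`, `volume_ml` and
#'   optionally `chamber_volume_ml` (defaults to `chamber_volume_ml`).
#' @param chamber_volume_ml default respirometer volume (ml).
#' @param trim_leading_s leading trim applied to SMR measurement windows
#'   (s); RMR/MMR windows are used in full.
#' @param outlier_order passed to [extract_smr()].
#' @return tibble of [summarize_metabolism()] rows, one per fish.
#' @export
extract_metabolism <- function(traces, meta, chamber_volume_ml = 40,
                               trim_leading_s = 30,
                               outlier_order = c("global", "subset")) {
  outlier_order <- match.arg(outlier_order)
  needed <- c("fish_id", "kind", "phase", "cycle", "t_s", "o2_mgL")
  missing <- setdiff(needed, names(traces))
  if (length(missing) > 0) {
    stop("trace table is missing columns: ", paste(missing, collapse = ", "))
  }
  if (!all(c("fish_id", "volume_ml") %in% names(meta))) {
    stop("meta must contain fish_id and volume_ml")
  }
  meas <- traces[traces$phase == "measure", ]
  out <- lapply(unique(meas$fish_id[!is.na(meas$fish_id)]), function(fid) {
    tr <- meas[meas$fish_id == fid, ]
    mrow <- meta[meta$fish_id == fid, ]
    if (nrow(mrow) != 1) stop("no unique metadata row for fish ", fid)
    vr <- if ("chamber_volume_ml" %in% names(mrow)) {
      mrow$chamber_volume_ml
    } else {
      chamber_volume_ml
    }
    vf <- mrow$volume_ml

    seg_rate <- function(seg, vol_f, trim) {
      cyc <- fit_o2_slope(seg$t_s, seg$o2_mgL, trim_leading_s = trim)
      list(mo2 = compute_mo2(cyc, vr, vol_f), t_mid = cyc$t_mid)
    }

    bl <- tr[tr$kind == "blank", ]
    if (nrow(bl) == 0) stop("no blank measurements found for fish ", fid)
    bl_cycles <- split(bl, bl$cycle)
    bl_fits <- lapply(bl_cycles, seg_rate, vol_f = 0, trim = 0)
    bl_t <- unname(vapply(bl_fits, function(z) z$t_mid, 0))
    bl_r <- unname(pmax(vapply(bl_fits, function(z) z$mo2, 0), 0))
    ord <- order(bl_t)
    if (length(ord) >= 2) {
      blanks <- blank_series(
        bl_t[ord[1]], bl_r[ord[1]],
        bl_t[ord[length(ord)]], bl_r[ord[length(ord)]]
      )
    } else {
      blanks <- blank_series(bl_t[1], bl_r[1], bl_t[1] + 1, NA_real_)
    }

    smr_tr <- tr[tr$kind == "SMR" & tr$cycle > 0, ]
    smr <- NA_real_
    n_used <- NA_integer_
    n_out <- NA_integer_
    if (nrow(smr_tr) > 0) {
      fits <- lapply(split(smr_tr, smr_tr$cycle), seg_rate,
        vol_f = vf, trim = trim_leading_s
      )
      mo2 <- vapply(fits, function(z) z$mo2, 0)
      tmid <- vapply(fits, function(z) z$t_mid, 0)
      corrected <- blank_correct(mo2, tmid, blanks)
      est <- extract_smr(corrected, outlier_order = outlier_order)
      smr <- est$smr
      n_used <- est$n_used
      n_out <- est$n_outliers
    }

    single <- function(kind) {
      seg <- tr[tr$kind == kind, ]
      if (nrow(seg) == 0) {
        return(NA_real_)
      }
      f <- seg_rate(seg, vol_f = vf, trim = 0)
      blank_correct(f$mo2, f$t_mid, blanks)
    }
    summarize_metabolism(
      fid,
      smr = smr, rmr = single("RMR"), mmr = single("MMR"),
      n_cycles_used = n_used, n_outliers_excluded = n_out
    )
  })
  dplyr::bind_rows(out)
}
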