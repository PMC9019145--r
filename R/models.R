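#' The seven-candidate fixed-effect set
#'
#' Candidate fixed-effect structures over mass, thermal history and
#' acclimation temperature used for every metabolic and behavioural trait;
#' model 7 is the mass-only null. All models additionally carry random
#' intercepts for population and tank.
#'
#' @return named character vector of right-hand-side formulas over the
#'   analysis-frame variables `log10_mass`, `history`, `accl_temp`.
#' @export
candidate_models <- function() {
  c(
    m1 = "log10_mass + history + accl_temp",
    m2 = "log10_mass * history * accl_temp",
    m3 = "log10_mass * history + accl_temp",
    m4 = "log10_mass + history * accl_temp",
    m5 = "log10_mass + history + accl_temp + history:accl_temp + log10_mass:accl_temp",
    m6 = "log10_mass + history + accl_temp + log10_mass:accl_temp + history:log10_mass",
    m7 = "log10_mass"
  )
}

#' Build the analysis frame for trait models
#'
#' Joins per-fish metabolic estimates to cohort metadata and constructs the
#' modelling variables: `log10_mass` (log10 mg), `history` (factor, ambient
#' reference), `accl_temp` (factor, colder level reference) and log10 trait
#' responses `log10_smr` etc.
#'
#' @param data per-fish table holding `mass_mg`, `history`, `accl_temp_C`,
#'   `population`, `tank` and trait columns.
#' @param traits trait columns to log-transform (those present are used).
#' @return tibble ready for [fit_lmm()] and the behaviour models.
#' @export
analysis_frame <- function(data, traits = c("smr", "rmr", "mmr", "aerobic_scope")) {
  need <- c("mass_mg", "history", "accl_temp_C", "population", "tank")
  missing <- setdiff(need, names(data))
  if (length(missing) > 0) {
    stop("data is missing columns: ", paste(missing, collapse = ", "))
  }
  out <- tibble::as_tibble(data)
  out$log10_mass <- log10(out$mass_mg)
  out$history <- factor(out$history, levels = c("ambient", "warm"))
  out$accl_temp <- factor(out$accl_temp_C)
  for (trait in intersect(traits, names(out))) {
    v <- out[[trait]]
    out[[paste0("log10_", trait)]] <-
      ifelse(!is.na(v) & v > 0, log10(pmax(v, .Machine$double.xmin)), NA_real_)
  }
  out
}

#' Fit one candidate linear mixed model
#'
#' Linear mixed model of a (log10) trait on a candidate fixed-effect
#' structure with random intercepts for population and tank, fitted by
#' maximum likelihood (`REML = FALSE`) so that likelihoods are comparable
#' across fixed-effect structures for AICc ranking. Random terms whose
#' grouping factor has fewer than two levels are dropped with a warning;
#' with no usable random term the model falls back to ordinary least
#' squares.
#'
#' @param data analysis frame (see [analysis_frame()]).
#' @param response response column name (e.g. `"log10_smr"`).
#' @param fixed right-hand-side fixed-effects string.
#' @param random grouping-factor column names for random intercepts.
#' @param reml fit by REML instead of ML (for reporting variance
#'   components, not for AICc comparison).
#' @return the fitted `lmerMod` (or `lm` fallback).
#' @export
fit_lmm <- function(data, response, fixed, random = c("population", "tank"),
                    reml = FALSE) {
  data <- data[!is.na(data[[response]]), ]
  usable <- random[vapply(
    random,
    function(g) length(unique(data[[g]])) >= 2, TRUE
  )]
  if (length(usable) < length(random)) {
    warning(
      "dropping random term(s) with a single level: ",
      paste(setdiff(random, usable), collapse = ", ")
    )
  }
  if (length(usable) == 0) {
    return(lm(as.formula(paste(response, "~", fixed)), data = data))
  }
  re <- paste(sprintf("(1 | %s)", usable), collapse = " + ")
  f <- as.formula(paste(response, "~", fixed, "+", re))
  lme4::lmer(
    f,
    data = data, REML = reml,
    control = lme4::lmerControl(calc.derivs = FALSE, check.conv.singular = "ignore")
  )
}

#' Second-order Akaike information criterion
#'
#' \deqn{AICc = -2\ell + 2k + \frac{2k(k+1)}{n-k-1}} with k the full
#' parameter count (fixed effects plus variance components) and n the
#' number of observations.
#'
#' @param loglik maximized log-likelihood.
#' @param k parameter count.
#' @param n number of observations; must exceed k + 1.
#' @return the AICc value.
#' @examples
#' aicc(-100, 3, 50) # 206.5217
#' @export
aicc <- function(loglik, k, n) {
  if (n <= k + 1) stop("AICc undefined: n must exceed k + 1")
  -2 * loglik + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

# AICc of a fitted model, using its logLik df as parameter count
aicc_of <- function(fit) {
  ll <- logLik(fit)
  aicc(as.numeric(ll), attr(ll, "df"), nobs(fit))
}

fixef_of <- function(fit) {
  if (inherits(fit, "merMod")) lme4::fixef(fit) else coef(fit)
}

#' Rank candidate models by AICc and average the retained set
#'
#' Computes AICc, delta-AICc and Akaike weights for a candidate set,
#' retains models with delta below a threshold, renormalizes weights over
#' the retained set, and model-averages the fixed-effect coefficients.
#' Averaging is conditional by default (each term averaged over the
#' retained models that contain it, with weights renormalized per term);
#' `average = "full"` substitutes zero where a term is absent. Optionally,
#' retained models containing interaction terms whose Wald |z| falls below
#' 1.96 can be screened out before averaging.
#'
#' @param fits named list of fitted candidate models (each providing
#'   `logLik`, `nobs` and fixed-effect coefficients).
#' @param delta_threshold retention threshold on delta-AICc (default 4).
#' @param average `"conditional"` or `"full"`.
#' @param drop_ns_interactions if `TRUE`, retained non-null models whose
#'   interaction terms are all non-significant are removed before
#'   averaging (off by default).
#' @return a `model_selection` list: `table` (per-model tibble with `k`,
#'   `loglik`, `AICc`, `delta`, `weight`, `retained`) and `coefficients`
#'   (term-level averaged estimates).
#' @export
rank_and_average <- function(fits, delta_threshold = 4,
                             average = c("conditional", "full"),
                             drop_ns_interactions = FALSE) {
  average <- match.arg(average)
  stopifnot(length(fits) >= 1, !is.null(names(fits)))
  lls <- unname(vapply(fits, function(f) as.numeric(logLik(f)), 0))
  ks <- unname(vapply(fits, function(f) attr(logLik(f), "df"), 0))
  ns <- unname(vapply(fits, nobs, 0))
  aiccs <- mapply(aicc, lls, ks, ns)
  delta <- aiccs - min(aiccs)
  retained <- delta < delta_threshold

  if (drop_ns_interactions) {
    for (m in which(retained)) {
      cf <- fixef_of(fits[[m]])
      se <- sqrt(diag(as.matrix(vcov(fits[[m]]))))
      ia <- grepl(":", names(cf))
      if (any(ia) && all(abs(cf[ia] / se[ia]) < qnorm(0.975))) {
        retained[m] <- FALSE
      }
    }
    if (!any(retained)) retained[which.min(delta)] <- TRUE
  }

  w <- exp(-delta / 2) * retained
  w <- w / sum(w)

  coefs <- lapply(fits, fixef_of)
  terms <- unique(unlist(lapply(coefs[retained], names)))
  avg <- vapply(terms, function(term) {
    present <- vapply(coefs, function(cf) term %in% names(cf), TRUE) & retained
    vals <- vapply(which(present), function(i) coefs[[i]][[term]], 0)
    if (average == "conditional") {
      sum(w[present] * vals) / sum(w[present])
    } else {
      sum(w[present] * vals)
    }
  }, 0)
  structure(
    list(
      table = tibble::tibble(
        model = names(fits), k = ks, loglik = lls, AICc = aiccs,
        delta = delta, weight = as.numeric(w), retained = retained
      ),
      coefficients = tibble::tibble(term = terms, estimate = unname(avg)),
      average = average
    ),
    class = "model_selection"
  )
}

#' @export
print.model_selection <- function(x, ...) {
  cat("Model selection (", x$average, " averaging)\n", sep = "")
  print(x$table[order(x$table$delta), ])
  cat("\nAveraged coefficients:\n")
  print(x$coefficients)
  invisible(x)
}

#' Candidate-model selection for one metabolic trait
#'
#' Fits all seven candidate mixed models (ML) for a log10 metabolic trait
#' and ranks/averages them by AICc.
#'
#' @param data per-fish table (see [analysis_frame()]); may already be an
#'   analysis frame.
#' @param trait `"smr"`, `"rmr"`, `"mmr"` or `"aerobic_scope"`.
#' @param delta_threshold,average,drop_ns_interactions passed to
#'   [rank_and_average()].
#' @param log_response model the trait on the log10 scale (default) or raw.
#' @return a `model_selection` object; the fitted models are attached as
#'   attribute `fits`.
#' @export
select_metabolic_models <- function(data, trait = "smr", delta_threshold = 4,
                                    average = c("conditional", "full"),
                                    drop_ns_interactions = FALSE,
                                    log_response = TRUE) {
  average <- match.arg(average)
  df <- if (!"log10_mass" %in% names(data)) analysis_frame(data) else data
  response <- if (log_response) paste0("log10_", trait) else trait
  if (!response %in% names(df)) stop("response column not found: ", response)
  fits <- lapply(candidate_models(), function(rhs) {
    fit_lmm(df, response, rhs)
  })
  res <- rank_and_average(fits, delta_threshold, average, drop_ns_interactions)
  attr(res, "fits") <- fits
  res
}
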