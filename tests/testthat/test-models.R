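# minimal stand-in fit objects so selection arithmetic can be tested exactly
fake_fit <- function(loglik, k, n, coefs) {
  structure(list(ll = loglik, k = k, n = n, cf = coefs), class = "fakefit")
}
registerS3method("logLik", "fakefit",
  function(object, ...) structure(object$ll, df = object$k, class = "logLik"),
  envir = asNamespace("stats")
)
registerS3method("nobs", "fakefit", function(object, ...) object$n,
  envir = asNamespace("stats")
)
registerS3method("coef", "fakefit", function(object, ...) object$cf,
  envir = asNamespace("stats")
)

test_that("AICc matches hand arithmetic and its limits", {
  expect_equal(aicc(-100, 3, 50), 206.5217, tolerance = 1e-4)
  expect_equal(aicc(-100, 3, 50), 206 + 24 / 46, tolerance = 1e-12)
  expect_lt(abs(aicc(-250, 5, 1e6) - (2 * 250 + 10)), 1e-4)
  expect_equal(aicc(-50, 0, 10), 100)
  expect_error(aicc(-10, 5, 6), "undefined")
})

test_that("Akaike weights follow exp(-delta/2) and renormalize over the retained set", {
  f1 <- fake_fit(-100, 3, 50, c(a = 1, b = 2))
  # delta of exactly 2: lower the log-likelihood by 1 at equal k
  f2 <- fake_fit(-101, 3, 50, c(a = 3, d = 4))
  res <- rank_and_average(list(m1 = f1, m2 = f2))
  expect_equal(res$table$delta, c(0, 2))
  expect_equal(round(res$table$weight, 4), c(0.7311, 0.2689))
  expect_equal(sum(res$table$weight), 1)

  # shifting every log-likelihood leaves the weights unchanged
  g1 <- fake_fit(-100 + 7, 3, 50, c(a = 1))
  g2 <- fake_fit(-101 + 7, 3, 50, c(a = 3))
  res2 <- rank_and_average(list(m1 = g1, m2 = g2))
  expect_equal(res2$table$weight, res$table$weight, tolerance = 1e-12)

  # identical models share weight equally
  res3 <- rank_and_average(list(a = f1, b = f1, c = f1))
  expect_equal(res3$table$weight, rep(1 / 3, 3))
})

test_that("model averaging is conditional by default with a full-average option", {
  f1 <- fake_fit(-100, 3, 50, c(`(Intercept)` = 1, x = 2))
  f2 <- fake_fit(-101, 3, 50, c(`(Intercept)` = 3))
  res <- rank_and_average(list(m1 = f1, m2 = f2))
  w <- res$table$weight
  expect_equal(
    res$coefficients$estimate[res$coefficients$term == "(Intercept)"],
    w[1] * 1 + w[2] * 3
  )
  # conditional: x averaged only over models containing it
  expect_equal(res$coefficients$estimate[res$coefficients$term == "x"], 2)
  full <- rank_and_average(list(m1 = f1, m2 = f2), average = "full")
  expect_equal(
    full$coefficients$estimate[full$coefficients$term == "x"],
    w[1] * 2
  )
  # a single retained model returns its coefficients unchanged, weight one
  solo <- rank_and_average(list(
    m1 = f1, m2 = fake_fit(-130, 3, 50, c(`(Intercept)` = 9))
  ))
  expect_equal(solo$table$weight, c(1, 0))
  expect_equal(solo$coefficients$estimate, c(1, 2))
})

test_that("the candidate set has seven members with a mass-only null", {
  cm <- candidate_models()
  expect_length(cm, 7)
  expect_equal(unname(cm["m7"]), "log10_mass")
  expect_match(cm["m5"], "history:accl_temp")
  expect_match(cm["m5"], "log10_mass:accl_temp")
})

test_that("with no group variance the mixed model collapses onto least squares", {
  cfg <- cohort_config(seed = 6)
  cfg$population_sd <- 0
  cfg$tank_sd <- 0
  co <- generate_cohort(cfg)
  df <- analysis_frame(measured_cohort(co))
  rhs <- candidate_models()[["m5"]]
  f1 <- lme4::fixef(fit_lmm(df, "log10_smr", rhs))
  f2 <- coef(lm(as.formula(paste("log10_smr ~", rhs)), df))
  expect_equal(f1, f2[names(f1)], tolerance = 1e-6)
})

test_that("row order does not affect the mixed-model estimates", {
  co <- generate_cohort(cohort_config(seed = 9))
  df <- analysis_frame(measured_cohort(co))
  rhs <- candidate_models()[["m1"]]
  set.seed(1)
  perm <- df[sample(nrow(df)), ]
  expect_equal(
    lme4::fixef(fit_lmm(df, "log10_smr", rhs)),
    lme4::fixef(fit_lmm(perm, "log10_smr", rhs)),
    tolerance = 1e-10
  )
})

test_that("single-level grouping factors are dropped with a warning", {
  co <- generate_cohort(small_cohort_config(seed = 3))
  df <- analysis_frame(measured_cohort(co))
  df$population <- "P01"
  expect_warning(
    fit <- fit_lmm(df, "log10_smr", "log10_mass"),
    "single level"
  )
  expect_s4_class(fit, "lmerMod")
})

test_that("the history-by-temperature interaction is recovered within 2 SE", {
  cfg <- cohort_config(seed = 8)
  co <- generate_cohort(cfg)
  df <- analysis_frame(measured_cohort(co))
  fit <- fit_lmm(df, "log10_smr", candidate_models()[["m5"]])
  cf <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(vcov(fit))))
  # dummy-coded warm:30C effect implied by the per-history activation energies
  truth <- (cfg$activation_energy$warm[["smr"]] -
    cfg$activation_energy$ambient[["smr"]]) *
    (inverse_kT(30) - inverse_kT(20)) / log(10)
  i <- grep("historywarm:accl_temp30", names(cf))
  expect_length(i, 1)
  expect_lt(abs(cf[i] - truth), 2 * se[i])
})

test_that("trait-level selection returns a coherent seven-model table", {
  co <- generate_cohort(cohort_config(seed = 10))
  sel <- select_metabolic_models(measured_cohort(co), "smr")
  expect_s3_class(sel, "model_selection")
  expect_equal(nrow(sel$table), 7)
  expect_equal(min(sel$table$delta), 0)
  expect_equal(sum(sel$table$weight), 1, tolerance = 1e-12)
  expect_true(all(sel$table$weight[!sel$table$retained] == 0))
  # interaction screen option executes and never empties the retained set
  sel2 <- select_metabolic_models(measured_cohort(co), "smr",
    drop_ns_interactions = TRUE
  )
  expect_gte(sum(sel2$table$retained), 1)
})

test_that("breaking the history labels destroys the history effect (negative control)", {
  signs <- vapply(1:60, function(s) {
    co <- generate_cohort(cohort_config(seed = 4000 + s))
    df <- analysis_frame(measured_cohort(co))
    # relabel which populations count as warm, severing the true link
    set.seed(4000 + s)
    fake_warm <- sample(unique(df$population), 4)
    df$history <- factor(
      ifelse(df$population %in% fake_warm, "warm", "ambient"),
      levels = c("ambient", "warm")
    )
    fit <- fit_lmm(df, "log10_smr", candidate_models()[["m1"]])
    sign(lme4::fixef(fit)[["historywarm"]])
  }, 0)
  agreement <- max(mean(signs > 0), mean(signs < 0))
  expect_lte(agreement, 0.68)
})
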