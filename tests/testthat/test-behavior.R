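# numerically integrated censored-likelihood oracle (tail probabilities by
# quadrature rather than pnorm)
integrated_tobit_loglik <- function(beta, sigma, y, X, censored, limit) {
  mu <- drop(X %*% beta)
  ll <- 0
  for (i in seq_along(y)) {
    if (censored[i]) {
      tail <- integrate(function(u) dnorm(u, mu[i], sigma),
        limit, mu[i] + 15 * sigma,
        rel.tol = 1e-13, abs.tol = 0
      )$value
      ll <- ll + log(tail)
    } else {
      ll <- ll + dnorm(y[i], mu[i], sigma, log = TRUE)
    }
  }
  ll
}

test_that("the censored log-likelihood matches a brute-force integrated oracle", {
  y <- c(550, 600, 300, 600, 450)
  X <- cbind(1, 1:5)
  cens <- c(FALSE, TRUE, FALSE, TRUE, FALSE)
  for (par in list(c(400, 20, 100), c(500, 10, 80), c(620, -5, 150))) {
    a <- tobit_loglik(par[1:2], par[3], y, X, cens, 600)
    b <- integrated_tobit_loglik(par[1:2], par[3], y, X, cens, 600)
    expect_equal(a, b, tolerance = 1e-8)
  }
})

test_that("with no censoring the Tobit fit reduces to least squares", {
  set.seed(42)
  n <- 80
  x <- runif(n, 1, 3)
  y <- 100 + 50 * x + rnorm(n, 0, 20)
  ft <- fit_tobit(y, cbind(`(Intercept)` = 1, x = x), rep(FALSE, n), limit = 1e6)
  ols <- lm(y ~ x)
  expect_equal(unname(ft$coefficients), unname(coef(ols)), tolerance = 1e-6)
  # ML scale (divisor n, not n - p)
  expect_equal(ft$sigma, sqrt(sum(resid(ols)^2) / n), tolerance = 1e-6)
  expect_true(ft$converged)
})

test_that("a latent mean near the limit is recovered despite ~16% censoring", {
  set.seed(11)
  n <- 500
  latent <- rnorm(n, 550, 50)
  cens <- latent >= 600
  ft <- fit_tobit(pmin(latent, 600), matrix(1, n, 1), cens, limit = 600)
  expect_lt(abs(ft$coefficients[1] - 550), 10)
  expect_gt(ft$n_censored, 0)
})

test_that("degenerate censoring patterns are rejected", {
  expect_error(
    fit_tobit(rep(600, 10), matrix(1, 10, 1), rep(TRUE, 10), 600),
    "no uncensored"
  )
})

test_that("the Tobit agrees with an independent survival-model implementation", {
  skip_if_not_installed("survival")
  set.seed(3)
  n <- 200
  x <- runif(n, -1, 1)
  latent <- 450 + 80 * x + rnorm(n, 0, 90)
  cens <- latent >= 600
  y <- pmin(latent, 600)
  ft <- fit_tobit(y, cbind(1, x), cens, limit = 600)
  sv <- survival::survreg(survival::Surv(y, !cens) ~ x,
    dist = "gaussian",
    control = survival::survreg.control(rel.tolerance = 1e-12, iter.max = 100)
  )
  expect_equal(unname(ft$coefficients), unname(coef(sv)), tolerance = 1e-3)
  expect_equal(ft$sigma, sv$scale, tolerance = 1e-3)
  # both optimizers sit on the same likelihood value
  ll_sv <- tobit_loglik(coef(sv), sv$scale, y, cbind(1, x), cens, 600)
  expect_equal(ft$loglik, ll_sv, tolerance = 1e-6)
})

test_that("latency models run per acclimation temperature on cohort data", {
  co <- measured_cohort(generate_cohort(cohort_config(seed = 3)))
  ft <- fit_latency_censored(co, "rmr", accl_temp = 30)
  expect_s3_class(ft, "censored_fit")
  expect_equal(ft$limit, 600)
  sub <- co[co$accl_temp_C == 30, ]
  expect_equal(ft$n, nrow(sub))
  expect_equal(ft$n_censored, sum(sub$latency_censored))
  expect_named(ft$coefficients, c("(Intercept)", "log10_mass", "log10_rmr"))
})

test_that("without group variance the boldness model matches plain logistic regression", {
  cfg <- cohort_config(seed = 4)
  cfg$latency_pop_sd <- 0
  cfg$latency_tank_sd <- 0
  co <- generate_cohort(cfg)
  df <- analysis_frame(measured_cohort(co))
  bold <- fit_boldness_binomial(df)
  expect_false(bold$separation)
  ref <- glm(emerged ~ log10_mass + history + accl_temp, binomial, df)
  expect_equal(coef(bold), coef(ref), tolerance = 1e-3)
})

test_that("an all-emerging cohort is flagged as separation with a penalized fallback", {
  cfg <- cohort_config(seed = 5)
  cfg$latency_meanlog <- 2 # everyone leaves the refuge almost immediately
  co <- generate_cohort(cfg)
  expect_true(all(co$emerged))
  df <- analysis_frame(measured_cohort(co))
  expect_warning(bold <- fit_boldness_binomial(df), "separation")
  expect_true(bold$separation)
  expect_equal(bold$method, "firth")
  expect_true(all(is.finite(coef(bold))))
})

test_that("warm-source fish are detected as bolder across simulated cohorts", {
  signs <- vapply(1:40, function(s) {
    co <- generate_cohort(cohort_config(seed = 2000 + s))
    df <- analysis_frame(measured_cohort(co))
    sign(coef(fit_boldness_binomial(df))[["historywarm"]])
  }, 0)
  expect_gte(mean(signs > 0), 0.95)
})

test_that("without overdispersion the activity model matches plain Poisson regression", {
  cfg <- cohort_config(seed = 5)
  for (f in c(
    "activity_olre_sd", "activity_pop_sd", "activity_tank_sd",
    "trait_noise_sd", "activity_interaction", "activity_history_effect"
  )) {
    cfg[[f]] <- 0
  }
  cfg$latency_meanlog <- 3 # near-complete emergence for a full sample
  co <- generate_cohort(cfg)
  df <- analysis_frame(measured_cohort(co))
  fit <- fit_activity_pln(df)
  ref <- glm(
    activity_s ~ log10_mass + history + accl_temp, poisson,
    df[df$emerged & !is.na(df$activity_s), ]
  )
  expect_equal(lme4::fixef(fit), coef(ref), tolerance = 1e-3)
})

test_that("the observation-level variance is recovered near its true value", {
  est <- vapply(1:30, function(s) {
    set.seed(100 + s)
    n <- 150
    d <- data.frame(
      population = factor(rep(1:8, length.out = n)),
      tank = factor(rep(1:16, length.out = n)),
      x = runif(n, -1, 1)
    )
    eta <- log(50) + 0.4 * d$x + rnorm(n, 0, sqrt(0.5))
    d$y <- rpois(n, exp(eta))
    d$.obs <- factor(seq_len(n))
    f <- suppressMessages(lme4::glmer(
      y ~ x + (1 | population) + (1 | tank) + (1 | .obs),
      family = poisson, data = d
    ))
    as.numeric(lme4::VarCorr(f)$.obs[1, 1])
  }, 0)
  expect_lt(abs(median(est) - 0.5), 0.15)
})

test_that("a constant response recovers its log mean with negligible variances", {
  co <- generate_cohort(small_cohort_config(seed = 6, n_fish_total = 60))
  df <- analysis_frame(measured_cohort(co))
  df$emerged <- TRUE
  df$activity_s <- 55L
  expect_message(
    fit <- fit_activity_pln(df, random = c("population", "tank")),
    "constant"
  )
  cf <- coef(fit)
  expect_equal(unname(cf[["(Intercept)"]] +
    cf[["log10_mass"]] * mean(df$log10_mass)), log(55), tolerance = 0.05)
  expect_identical(olre_variance(fit), 0)
})

test_that("activity counts outside the assay window are rejected", {
  co <- generate_cohort(small_cohort_config(seed = 7))
  df <- analysis_frame(measured_cohort(co))
  df$activity_s[which(df$emerged)[1]] <- 301L
  expect_error(fit_activity_pln(df), "window")
  df$activity_s[which(df$emerged)[1]] <- -1L
  expect_error(fit_activity_pln(df), ">= 0")
  df$activity_s[which(df$emerged)[1]] <- 10.5
  expect_error(fit_activity_pln(df), "integer")
})

test_that("activity can be modelled against a metabolic covariate per temperature", {
  co <- measured_cohort(generate_cohort(cohort_config(seed = 12)))
  fit <- suppressWarnings(fit_activity_pln(co, covariate = "rmr", accl_temp = 20))
  expect_true("log10_rmr" %in% names(lme4::fixef(fit)))
})
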