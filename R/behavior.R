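#' Tobit (right-censored Gaussian) log-likelihood
#'
#' Log-likelihood of a linear model with right censoring at a known limit:
#' uncensored observations contribute \eqn{\log\phi((y - x\beta)/\sigma) -
#' \log\sigma}; censored observations contribute
#' \eqn{\log\Phi((x\beta - L)/\sigma)}, the probability that the latent
#' response exceeds the limit \eqn{L}.
#'
#' @param beta coefficient vector (length = ncol(X)).
#' @param sigma residual scale, > 0.
#' @param y observed responses; censored entries are at the limit.
#' @param X design matrix.
#' @param censored logical vector of right-censoring indicators.
#' @param limit censoring limit.
#' @return the log-likelihood.
#' @export
tobit_loglik <- function(beta, sigma, y, X, censored, limit = 600) {
  stopifnot(sigma > 0, nrow(X) == length(y), length(censored) == length(y))
  mu <- drop(X %*% beta)
  obs <- !censored
  sum(dnorm(y[obs], mu[obs], sigma, log = TRUE)) +
    sum(pnorm((mu[censored] - limit) / sigma, log.p = TRUE))
}

# analytic gradient in (beta, log sigma)
tobit_grad <- function(beta, log_sigma, y, X, censored, limit) {
  sigma <- exp(log_sigma)
  mu <- drop(X %*% beta)
  g_beta <- numeric(length(beta))
  g_ls <- 0
  obs <- !censored
  if (any(obs)) {
    r <- (y[obs] - mu[obs]) / sigma
    g_beta <- g_beta + drop(crossprod(X[obs, , drop = FALSE], r / sigma))
    g_ls <- g_ls + sum(r^2 - 1)
  }
  if (any(censored)) {
    z <- (mu[censored] - limit) / sigma
    lambda <- exp(dnorm(z, log = TRUE) - pnorm(z, log.p = TRUE))
    g_beta <- g_beta + drop(crossprod(X[censored, , drop = FALSE], lambda / sigma))
    g_ls <- g_ls - sum(lambda * z)
  }
  c(g_beta, g_ls)
}

#' Fit a right-censored (Tobit) regression
#'
#' Maximum-likelihood Tobit fit with right censoring at a fixed limit.
#' Optimization is BFGS on \eqn{(\beta, \log\sigma)} with an analytic
#' gradient and three deterministic starts (least squares on the
#' uncensored subset, least squares on all observations, and the first
#' start with an inflated scale); standard errors come from the inverse
#' observed information.
#'
#' @param y responses; censored entries sit at `limit`.
#' @param X design matrix (include the intercept column).
#' @param censored logical right-censoring indicators.
#' @param limit censoring limit.
#' @param maxit,reltol optimizer control.
#' @return a `censored_fit` list: `coefficients`, `se`, `sigma`,
#'   `sigma_se`, `loglik`, `n`, `n_censored`, `limit`, `converged`.
#' @export
fit_tobit <- function(y, X, censored, limit = 600, maxit = 500, reltol = 1e-10) {
  X <- as.matrix(X)
  censored <- as.logical(censored)
  keep <- complete.cases(y, X, censored)
  y <- y[keep]
  X <- X[keep, , drop = FALSE]
  censored <- censored[keep]
  if (!any(!censored)) stop("no uncensored observations: Tobit fit impossible")
  if (nrow(X) <= ncol(X)) stop("more parameters than observations")

  ls_fit <- function(rows) {
    qr.coef(qr(X[rows, , drop = FALSE]), y[rows])
  }
  b_obs <- ls_fit(which(!censored))
  b_all <- ls_fit(seq_along(y))
  b_obs[is.na(b_obs)] <- 0
  b_all[is.na(b_all)] <- 0
  s0 <- sd(y[!censored] - drop(X[!censored, , drop = FALSE] %*% b_obs))
  if (!is.finite(s0) || s0 <= 0) s0 <- max(sd(y), 1e-3)
  starts <- list(
    c(b_obs, log(s0)), c(b_all, log(s0)), c(b_obs, log(2 * s0))
  )

  nll <- function(theta) {
    p <- length(theta)
    -tobit_loglik(theta[-p], exp(theta[p]), y, X, censored, limit)
  }
  ngr <- function(theta) {
    p <- length(theta)
    -tobit_grad(theta[-p], theta[p], y, X, censored, limit)
  }
  best <- NULL
  for (st in starts) {
    opt <- tryCatch(
      optim(st, nll, ngr,
        method = "BFGS",
        control = list(maxit = maxit, reltol = reltol)
      ),
      error = function(e) NULL
    )
    if (!is.null(opt) && (is.null(best) || opt$value < best$value)) best <- opt
  }
  if (is.null(best)) stop("Tobit optimization failed from all starts")
  p <- length(best$par)
  sigma <- exp(best$par[p])
  if (sigma < 1e-8) warning("Tobit scale collapsed toward zero; fit unreliable")
  hess <- optimHess(best$par, nll, ngr)
  vc <- tryCatch(solve(hess), error = function(e) matrix(NA_real_, p, p))
  se <- sqrt(pmax(diag(vc), 0))
  beta <- best$par[-p]
  names(beta) <- colnames(X)
  structure(
    list(
      coefficients = beta,
      se = setNames(se[-p], colnames(X)),
      sigma = unname(sigma),
      sigma_se = unname(sigma * se[p]),
      loglik = -best$value,
      n = length(y),
      n_censored = sum(censored),
      limit = limit,
      converged = best$convergence == 0
    ),
    class = "censored_fit"
  )
}

#' @export
coef.censored_fit <- function(object, ...) object$coefficients

#' @export
logLik.censored_fit <- function(object, ...) {
  structure(object$loglik,
    df = length(object$coefficients) + 1,
    nobs = object$n, class = "logLik"
  )
}

#' @export
nobs.censored_fit <- function(object, ...) object$n

#' @export
print.censored_fit <- function(x, ...) {
  cat(sprintf(
    "Right-censored regression (limit %g; %d of %d censored)\n",
    x$limit, x$n_censored, x$n
  ))
  print(data.frame(estimate = x$coefficients, se = x$se))
  cat(sprintf(
    "sigma = %.4g (se %.3g), logLik = %.4f, converged: %s\n",
    x$sigma, x$sigma_se, x$loglik, x$converged
  ))
  invisible(x)
}

#' Censored regression of emergence latency on metabolic rate
#'
#' Latency to leave the refuge (s), right-censored at the assay limit, is
#' regressed on log10 mass and one log10 metabolic covariate, separately
#' per acclimation temperature to avoid confounding metabolic rate with
#' temperature.
#'
#' @param data per-fish table with `latency_s`, `latency_censored`,
#'   `mass_mg` and the metabolic covariate column.
#' @param covariate `"smr"`, `"rmr"` or `"mmr"`.
#' @param accl_temp optional single acclimation temperature (degrees C) to
#'   subset on.
#' @param limit censoring limit (s).
#' @return a `censored_fit`.
#' @export
fit_latency_censored <- function(data, covariate = c("smr", "rmr", "mmr"),
                                 accl_temp = NULL, limit = 600) {
  covariate <- match.arg(covariate)
  if (!is.null(accl_temp)) data <- data[data$accl_temp_C == accl_temp, ]
  need <- c("latency_s", "latency_censored", "mass_mg", covariate)
  missing <- setdiff(need, names(data))
  if (length(missing) > 0) {
    stop("data is missing columns: ", paste(missing, collapse = ", "))
  }
  keep <- complete.cases(data[, need]) & data[[covariate]] > 0
  data <- data[keep, ]
  X <- cbind(
    `(Intercept)` = 1,
    log10_mass = log10(data$mass_mg),
    stats::setNames(data.frame(log10(data[[covariate]])), paste0("log10_", covariate))
  )
  fit_tobit(data$latency_s, as.matrix(X), data$latency_censored, limit = limit)
}

# Firth-penalized logistic regression (fixed effects only); used as the
# fallback when the mixed binomial model shows complete separation.
firth_logit <- function(X, y, maxit = 100, tol = 1e-8) {
  X <- as.matrix(X)
  beta <- rep(0, ncol(X))
  for (i in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    p <- 1 / (1 + exp(-eta))
    W <- p * (1 - p)
    XW <- X * W
    info <- crossprod(X, XW)
    h <- diag(X %*% solve(info, t(XW)))
    U <- crossprod(X, y - p + h * (0.5 - p))
    step <- solve(info, U)
    beta <- beta + drop(step)
    if (max(abs(step)) < tol) break
  }
  list(coefficients = setNames(drop(beta), colnames(X)), iterations = i)
}

#' Mixed-effects binomial model of boldness
#'
#' Logit-link binomial mixed model of refuge emergence (1 = left the
#' refuge within the assay limit) on log10 mass, thermal history and
#' acclimation temperature, with random intercepts for population and
#' tank, estimated by Laplace approximation (lme4::glmer). Complete or
#' quasi-complete separation (a degenerate response or unbounded
#' coefficients) is detected and reported, and a Firth-penalized
#' fixed-effects fit is returned as fallback.
#'
#' @param data per-fish table with `emerged`, `mass_mg`, `history`,
#'   `accl_temp_C`, `population`, `tank`.
#' @param random random-intercept grouping columns.
#' @return a `boldness_fit` list: `fit` (a `glmerMod`, or the Firth
#'   fallback under separation), `separation`, `method`.
#' @export
fit_boldness_binomial <- function(data, random = c("population", "tank")) {
  df <- if (!"log10_mass" %in% names(data)) analysis_frame(data) else data
  df <- df[!is.na(df$emerged), ]
  y <- as.integer(df$emerged)
  degenerate <- length(unique(y)) < 2
  sep <- degenerate
  fit <- NULL
  if (!degenerate) {
    re <- paste(sprintf("(1 | %s)", random), collapse = " + ")
    f <- as.formula(paste("emerged ~ log10_mass + history + accl_temp +", re))
    fit <- suppressMessages(tryCatch(
      lme4::glmer(f, data = df, family = stats::binomial()),
      error = function(e) NULL, warning = function(w) {
        suppressWarnings(lme4::glmer(f, data = df, family = stats::binomial()))
      }
    ))
    if (!is.null(fit) && any(abs(lme4::fixef(fit)) > 10)) sep <- TRUE
    if (is.null(fit)) sep <- TRUE
  }
  if (sep) {
    warning("separation detected in boldness model; returning Firth-penalized fit")
    X <- stats::model.matrix(~ log10_mass + history + accl_temp, df)
    fb <- firth_logit(X, y)
    return(structure(
      list(fit = fb, separation = TRUE, method = "firth"),
      class = "boldness_fit"
    ))
  }
  structure(
    list(fit = fit, separation = FALSE, method = "glmer_laplace"),
    class = "boldness_fit"
  )
}

#' @export
coef.boldness_fit <- function(object, ...) {
  if (object$method == "firth") {
    object$fit$coefficients
  } else {
    lme4::fixef(object$fit)
  }
}

#' @export
print.boldness_fit <- function(x, ...) {
  cat(
    "Boldness (emergence) model, method:", x$method,
    if (x$separation) "[separation]" else "", "\n"
  )
  print(coef(x))
  invisible(x)
}

#' Poisson-lognormal mixed model of activity
#'
#' Activity (integer seconds spent moving within the 5-minute window,
#' emergent fish only) modelled as Poisson with log link, random
#' intercepts for population and tank, and an observation-level normal
#' random effect supplying the lognormal overdispersion. Fixed effects are
#' log10 mass, thermal history and acclimation temperature, or log10 mass
#' plus one log10 metabolic covariate when `covariate` is given (then
#' typically per acclimation temperature).
#'
#' @param data per-fish table with `activity_s` and design columns.
#' @param covariate optional metabolic covariate (`"smr"`, `"rmr"`,
#'   `"mmr"`).
#' @param accl_temp optional single acclimation temperature to subset on.
#' @param random random-intercept grouping columns.
#' @param window_s assay window; counts above it are rejected.
#' @return the fitted `glmerMod`; the observation-level variance is
#'   available via [olre_variance()].
#' @export
fit_activity_pln <- function(data, covariate = NULL, accl_temp = NULL,
                             random = c("population", "tank"),
                             window_s = 300) {
  df <- if (!"log10_mass" %in% names(data)) analysis_frame(data) else data
  if (!is.null(accl_temp)) df <- df[df$accl_temp_C == accl_temp, ]
  if ("emerged" %in% names(df)) df <- df[df$emerged %in% TRUE, ]
  df <- df[!is.na(df$activity_s), ]
  if (any(df$activity_s < 0)) stop("activity counts must be >= 0")
  if (any(df$activity_s > window_s)) {
    stop(sprintf("activity counts above %d s exceed the observation window", window_s))
  }
  if (any(df$activity_s != round(df$activity_s))) {
    stop("activity must be integer seconds")
  }
  df$.obs <- factor(seq_len(nrow(df)))
  fixed <- if (is.null(covariate)) {
    "log10_mass + history + accl_temp"
  } else {
    covariate <- match.arg(covariate, c("smr", "rmr", "mmr"))
    df[[paste0("log10_", covariate)]] <- log10(df[[covariate]])
    paste("log10_mass +", paste0("log10_", covariate))
  }
  if (var(df$activity_s) == 0) {
    # a constant response pins every variance component at zero and defeats
    # the mixed-model inner iterations; the ML fit is the plain Poisson GLM
    message("constant activity response: all variance components are zero; fitting fixed-effects Poisson model")
    fit <- stats::glm(as.formula(paste("activity_s ~", fixed)),
      family = stats::poisson(), data = df
    )
    class(fit) <- c("pln_degenerate", class(fit))
    return(fit)
  }
  re <- paste(sprintf("(1 | %s)", c(random, ".obs")), collapse = " + ")
  f <- as.formula(paste("activity_s ~", fixed, "+", re))
  suppressMessages(lme4::glmer(f, data = df, family = stats::poisson()))
}

#' Observation-level (lognormal overdispersion) variance of a PLN fit
#'
#' @param fit a `glmerMod` from [fit_activity_pln()].
#' @return the `.obs` random-intercept variance.
#' @export
olre_variance <- function(fit) {
  if (inherits(fit, "pln_degenerate")) {
    return(0)
  }
  vc <- lme4::VarCorr(fit)
  if (!".obs" %in% names(vc)) stop("fit has no observation-level random effect")
  as.numeric(vc$.obs[1, 1])
}
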