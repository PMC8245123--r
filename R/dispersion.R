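#' Poisson regression with log link
#'
#' Thin wrapper around base R's iteratively reweighted least squares
#' (`glm.fit`) at a tight relative tolerance, returning the coefficient
#' vector and the fitted means `mu_i = exp(x_i' beta)` needed by the
#' overdispersion test.
#'
#' @param design A [build_design()] result or numeric matrix.
#' @param counts Non-negative integer response vector.
#'
#' @return A list of class `"poisson_glm"` with `coefficients`, `fitted`,
#'   `loglik`, `converged`, `n`, `p`.
#' @export
fit_poisson_glm <- function(design, counts) {
  x <- design_x(design)
  if (nrow(x) < ncol(x)) stop("need n >= p", call. = FALSE)
  if (any(counts < 0) || any(counts != floor(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  if (all(counts == 0)) {
    stop("all counts are zero: the log-link Poisson MLE does not exist",
         call. = FALSE)
  }
  fit <- suppressWarnings(stats::glm.fit(
    x, counts, family = stats::poisson(),
    control = stats::glm.control(epsilon = 1e-10, maxit = 200)))
  coefs <- fit$coefficients
  coefs[is.na(coefs)] <- 0 # aliased columns carry no information
  if (any(!is.finite(coefs)) || anyNA(fit$fitted.values) ||
      any(!is.finite(fit$fitted.values))) {
    stop("Poisson IRLS diverged", call. = FALSE)
  }
  fit$coefficients <- coefs
  if (!fit$converged) {
    warning("Poisson IRLS hit the iteration limit (possible separation: ",
            "some fitted means may sit at the boundary)", call. = FALSE)
  }
  mu <- fit$fitted.values
  structure(list(
    coefficients = stats::setNames(fit$coefficients, colnames(x)),
    fitted = mu,
    loglik = sum(stats::dpois(counts, mu, log = TRUE)),
    converged = fit$converged,
    n = nrow(x), p = ncol(x)
  ), class = "poisson_glm")
}

#' Regression-based overdispersion test for a Poisson GLM
#'
#' The Cameron-Trivedi test of equidispersion against the alternative
#' `Var(y) = mu + alpha * g(mu)`. It runs the auxiliary ordinary least
#' squares regression, without intercept, of
#' `z_i = ((y_i - mu_i)^2 - y_i) / mu_i` on `g(mu_i) / mu_i`, and performs a
#' one-sided t-test of the slope being positive (overdispersion). The
#' canonical quadratic alternative `g(mu) = mu^2` (NB2) is the default; the
#' linear alternative `g(mu) = mu` (NB1) reduces the regressor to a constant
#' and tests the mean of `z`.
#'
#' @param counts Observed counts.
#' @param fitted_means Fitted Poisson means, all positive.
#' @param level One-sided significance level (default 0.01, i.e. a 99%
#'   confidence requirement before declaring overdispersion).
#' @param g Variance-function alternative, `"nb2"` or `"nb1"`.
#'
#' @return A list of class `"ct_test"`: `alpha_hat`, `t_stat`, `p_value`
#'   (one-sided), `reject`, `level`, `g`, `df`.
#' @examples
#' coh <- simulate_cohort(synthetic_config(n = 2000, seed = 3))
#' d <- build_design(coh, model2_terms())
#' pg <- fit_poisson_glm(d, coh$ae_count)
#' ct_test(coh$ae_count, pg$fitted)
#' @export
ct_test <- function(counts, fitted_means, level = 0.01, g = c("nb2", "nb1")) {
  g <- match.arg(g)
  if (any(fitted_means <= 0)) stop("fitted means must be positive",
                                   call. = FALSE)
  z <- ((counts - fitted_means)^2 - counts) / fitted_means
  w <- if (g == "nb2") fitted_means else rep(1, length(counts))
  if (g == "nb2" && stats::var(w) == 0) {
    stop("constant regressor: fitted means are all equal, the auxiliary ",
         "regression is uninformative under the NB2 alternative",
         call. = FALSE)
  }
  ols <- stats::lm(z ~ 0 + w)
  sm <- summary(ols)$coefficients
  t_stat <- sm[1, "t value"]
  df <- ols$df.residual
  p <- stats::pt(t_stat, df = df, lower.tail = FALSE)
  structure(list(
    alpha_hat = unname(sm[1, "Estimate"]),
    t_stat = unname(t_stat),
    p_value = unname(p),
    reject = unname(p < level),
    level = level, g = g, df = df
  ), class = "ct_test")
}

#' @export
print.ct_test <- function(x, ...) {
  cat(sprintf(
    "Overdispersion test (%s alternative): alpha = %.4f, t = %.3f, one-sided p = %.3g\n",
    toupper(x$g), x$alpha_hat, x$t_stat, x$p_value))
  cat(if (x$reject) "Equidispersion rejected" else "Equidispersion not rejected",
      sprintf("at level %.2g\n", x$level))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.ct_test <- function(x, ...) {
  tibble::tibble(alpha_hat = x$alpha_hat, statistic = x$t_stat,
                 p.value = x$p_value, reject = x$reject,
                 level = x$level, alternative = x$g)
}
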