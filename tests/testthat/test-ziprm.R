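# Independent oracle: direct numerical maximisation of the ZIP(RM) likelihood
# on an unconstrained parameterisation (logit weight, log-linear rates).
zip_direct_mle <- function(x, y, start = NULL) {
  p <- ncol(x)
  negll <- function(th) {
    pi1 <- stats::plogis(th[1])
    lam <- exp(drop(x %*% th[-1]))
    lp0 <- log(pi1 + (1 - pi1) * exp(-lam))
    lpy <- log(1 - pi1) + stats::dpois(y, lam, log = TRUE)
    -sum(ifelse(y == 0, lp0, lpy))
  }
  if (is.null(start)) start <- c(0, log(mean(y[y > 0]) + 0.5), rep(0, p - 1))
  opt <- stats::optim(start, negll, method = "BFGS",
                      control = list(maxit = 2000, reltol = 1e-14))
  list(pi1 = stats::plogis(opt$par[1]), beta = opt$par[-1],
       loglik = -opt$value)
}

test_that("the mixture pmf matches hand-evaluated cases and normalises", {
  expect_equal(dzipmix(0, c(0.5, 0.5), log(2)), 0.75)
  expect_equal(dzipmix(1, c(0.5, 0.5), log(2)), 0.25 * log(2),
               tolerance = 1e-12)
  expect_equal(round(dzipmix(1, c(0.5, 0.5), log(2)), 5), 0.17329)

  set.seed(42)
  for (i in 1:20) {
    pars <- random_zipmix_params()
    total <- sum(dzipmix(0:200, pars$pi, pars$lambda))
    expect_lt(abs(total - 1), 1e-10)
  }

  expect_error(dzipmix(-1, c(0.5, 0.5), 1), "non-negative")
  expect_error(dzipmix(0, c(0.5, 0.5), -1), "positive")
  expect_error(dzipmix(0, c(0.5, 0.4), 1), "probability")
})

test_that("the log-likelihood agrees with a brute-force per-record oracle", {
  # degenerate single record: all mass on the structural zero
  x1 <- matrix(1, 1, 1)
  expect_equal(ziprm_loglik(list(pi = c(1, 0),
                                 beta = c("(Intercept)" = 0)), x1, 0L), 0)

  set.seed(7)
  n <- 20
  x <- cbind(1, stats::rnorm(n), stats::rbinom(n, 1, 0.4))
  y <- stats::rpois(n, 1)
  for (K in 2:3) {
    pi <- stats::runif(K, 0.2, 1); pi <- pi / sum(pi)
    betas <- lapply(seq_len(K - 1), function(k) stats::rnorm(3, 0, 0.4))
    # naive evaluation, record by record, straight from the mixture law
    naive <- 0
    for (i in seq_len(n)) {
      dens <- if (y[i] == 0) pi[1] else 0
      for (k in 2:K) {
        dens <- dens + pi[k] * stats::dpois(y[i], exp(sum(x[i, ] * betas[[k - 1]])))
      }
      naive <- naive + log(dens)
    }
    expect_equal(ziprm_loglik(list(pi = pi, beta = betas), x, y), naive,
                 tolerance = 1e-10)
  }
})

test_that("E-step responsibilities are exact where they can be hand-computed", {
  x <- matrix(1, 3, 1)
  y <- c(0L, 0L, 3L)
  params <- list(pi = c(0.5, 0.5), beta = list(c("(Intercept)" = log(log(2)))))
  r <- e_step(params, x, y)
  expect_equal(rowSums(r), rep(1, 3), tolerance = 1e-12)
  expect_equal(r[1, 1], 2 / 3, tolerance = 1e-12) # 0.5 / 0.75
  expect_equal(r[3, 1], 0)                        # positive count
})

test_that("the M-step solves the weighted Poisson subproblems", {
  set.seed(11)
  n <- 200
  x <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  y <- stats::rpois(n, 2)
  r <- cbind(rep(0.3, n), rep(0.7, n))
  params <- m_step(r, x, y)
  # uniform weights: weighted Poisson MLE is the (weighted) mean count
  expect_equal(unname(params$beta[[1]]), log(mean(y)), tolerance = 1e-8)
  expect_equal(params$pi, c(0.3, 0.7), tolerance = 1e-12)

  # everything in component 2: boundary weight is clipped, not zero/one exactly
  hard <- cbind(rep(0, n), rep(1, n))
  ph <- m_step(hard, x, y)
  expect_gt(ph$pi[1], 0)
  expect_lt(ph$pi[2], 1)
})

test_that("an EM cycle never decreases the log-likelihood", {
  set.seed(13)
  for (i in 1:100) {
    n <- 80
    x <- cbind(1, stats::rnorm(n))
    K <- sample(2:3, 1)
    pi_true <- c(0.5, rep(0.5 / (K - 1), K - 1))
    comp <- sample.int(K, n, replace = TRUE, prob = pi_true)
    lam <- exp(0.3 + 0.4 * x[, 2])
    y <- ifelse(comp == 1, 0L, stats::rpois(n, lam))
    pi0 <- stats::runif(K, 0.2, 1); pi0 <- pi0 / sum(pi0)
    params <- list(pi = pi0,
                   beta = lapply(seq_len(K - 1), function(k)
                     stats::rnorm(2, 0, 0.3)))
    ll0 <- ziprm_loglik(params, x, y)
    r <- e_step(params, x, y)
    params1 <- m_step(r, x, y, beta_start = params$beta)
    ll1 <- ziprm_loglik(params1, x, y)
    expect_gte(ll1, ll0 - 1e-8)
  }
})

test_that("K = 2 EM equals the direct ZIP maximum-likelihood oracle", {
  set.seed(19)
  n <- 2000
  x <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  comp <- stats::rbinom(n, 1, 0.4)             # 0 = structural zero
  y <- ifelse(comp == 0, 0L, stats::rpois(n, 2))
  fit <- fit_ziprm(x, y, K = 2, n_starts = 3, seed = 1,
                   tol = 1e-12, max_iter = 5000)
  oracle <- zip_direct_mle(x, y)
  expect_equal(fit$loglik, oracle$loglik, tolerance = 1e-6)
  expect_equal(fit$params$pi[1], oracle$pi1, tolerance = 1e-4)
  expect_equal(unname(fit$params$beta[[1]][1]), oracle$beta[1],
               tolerance = 1e-4)

  # and with one covariate
  x2 <- cbind(`(Intercept)` = 1, z = stats::rbinom(n, 1, 0.5))
  y2 <- ifelse(stats::rbinom(n, 1, 0.3) == 1, 0L,
               stats::rpois(n, exp(0.5 + 0.4 * x2[, 2])))
  fit2 <- fit_ziprm(x2, y2, K = 2, n_starts = 3, seed = 2,
                    tol = 1e-12, max_iter = 5000)
  oracle2 <- zip_direct_mle(x2, y2)
  expect_equal(fit2$loglik, oracle2$loglik, tolerance = 1e-6)
})

test_that("EM recovers the generating parameters within 3 standard errors", {
  set.seed(23)
  n <- 20000
  x <- cbind(`(Intercept)` = 1, z = stats::rnorm(n))
  pi1 <- 0.85
  comp <- stats::rbinom(n, 1, 1 - pi1)
  y <- ifelse(comp == 0, 0L, stats::rpois(n, exp(0.5 + 0.4 * x[, 2])))
  fit <- fit_ziprm(x, y, K = 2, n_starts = 3, seed = 3)
  fit <- ziprm_se(fit, x, y)
  beta_hat <- fit$params$beta[[1]]
  se_b <- fit$se[c("comp2:(Intercept)", "comp2:z")]
  expect_lt(abs(beta_hat[1] - 0.5), 3 * se_b[1])
  expect_lt(abs(beta_hat[2] - 0.4), 3 * se_b[2])
  # mixture weight on its estimation scale, log(pi2 / pi1)
  w_hat <- log(fit$params$pi[2] / fit$params$pi[1])
  w_true <- log((1 - pi1) / pi1)
  se_w <- fit$se["logit_w2"]
  expect_lt(abs(w_hat - w_true) / se_w, 3)
})

test_that("free-parameter counts match the two model specifications at K = 2", {
  coh <- simulate_cohort(synthetic_config(n = 3000, seed = 29))
  f2 <- fit_ziprm(build_design(coh, model2_terms()), coh$ae_count,
                  K = 2, n_starts = 1, seed = 1, max_iter = 30)
  expect_equal(f2$n_free_par, 20)
  f1 <- fit_ziprm(build_design(coh, model1_terms()), coh$ae_count,
                  K = 2, n_starts = 1, seed = 1, max_iter = 30)
  expect_equal(f1$n_free_par, 25)
})

test_that("information criteria follow their definitions", {
  # BIC/AIC arithmetic on a fitted object
  coh <- simulate_cohort(synthetic_config(n = 1500, seed = 37))
  d <- build_design(coh, "multidrug")
  fit <- fit_ziprm(d, coh$ae_count, K = 2, n_starts = 2, seed = 1)
  expect_equal(fit$bic, -2 * fit$loglik + log(fit$n) * fit$n_free_par)
  expect_equal(fit$aic, -2 * fit$loglik + 2 * fit$n_free_par)
  # the formula at the worked numbers: l = -100, n = 100, 5 parameters
  expect_equal(round(-2 * (-100) + log(100) * 5, 4), 223.0259)
  # ICL = BIC + 2 * posterior entropy; hard posteriors leave it at BIC
  ent <- -sum(fit$posterior[fit$posterior > 0] *
                log(fit$posterior[fit$posterior > 0]))
  expect_equal(fit$icl, fit$bic + 2 * ent)
  hard <- fit
  expect_equal(fit$icl - 2 * ent, fit$bic)
})

test_that("BIC selects the true number of components under separation", {
  set.seed(41)
  n <- 6000
  x <- cbind(`(Intercept)` = 1, z = stats::rnorm(n))
  comp <- sample.int(2, n, replace = TRUE, prob = c(0.5, 0.5))
  y <- ifelse(comp == 1, 0L, stats::rpois(n, exp(1.0 + 0.5 * x[, 2])))
  sel <- ziprm_select(x, y, K_range = 1:3, n_starts = 2, seed = 5,
                      max_iter = 200)
  expect_equal(sel$best_K, 2)
  expect_equal(nrow(sel$criteria), 3)
  expect_s3_class(sel$criteria, "tbl_df")
})

test_that("numerical standard errors reduce to closed forms in the Poisson limit", {
  set.seed(43)
  n <- 1000
  x <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  y <- stats::rpois(n, 3)
  fit <- fit_ziprm(x, y, K = 1)
  fit <- ziprm_se(fit, x, y)
  expect_equal(unname(fit$se[1]), 1 / sqrt(sum(y)), tolerance = 1e-4)

  # duplicated covariate -> singular information, reported as collinear
  coh <- simulate_cohort(synthetic_config(n = 1200, seed = 47))
  d <- build_design(coh, "multidrug")
  xdup <- cbind(d$x, multidrug2 = d$x[, "multidrug"])
  fdup <- suppressWarnings(fit_ziprm(xdup, coh$ae_count, K = 2,
                                     n_starts = 1, seed = 1, max_iter = 50))
  expect_error(ziprm_se(fdup, xdup, coh$ae_count), "collinear")
})

test_that("standard errors track the sampling spread of the estimator", {
  set.seed(53)
  n <- 1500
  reps <- 200
  x <- cbind(`(Intercept)` = 1, z = stats::rbinom(n, 1, 0.5))
  b_hat <- matrix(NA_real_, reps, 2)
  se_hat <- matrix(NA_real_, reps, 2)
  for (r in seq_len(reps)) {
    comp <- stats::rbinom(n, 1, 0.5)
    y <- ifelse(comp == 0, 0L, stats::rpois(n, exp(0.8 + 0.5 * x[, 2])))
    fit <- fit_ziprm(x, y, K = 2, n_starts = 1, seed = r, tol = 1e-10)
    fit <- ziprm_se(fit, x, y)
    b_hat[r, ] <- fit$params$beta[[1]]
    se_hat[r, ] <- fit$se[c("comp2:(Intercept)", "comp2:z")]
  }
  for (j in 1:2) {
    expect_lt(abs(stats::sd(b_hat[, j]) - mean(se_hat[, j])) /
                stats::sd(b_hat[, j]), 0.15)
  }
})

test_that("incidence-rate-ratio tables encode the reporting conventions", {
  fit <- structure(list(
    K = 2L, params = list(pi = c(0.8, 0.2),
                          beta = list(c(0, log(1.59), 0.5))),
    term_names = c("(Intercept)", "in_hospital", "z"),
    se = c("logit_w2" = 0.1, "comp2:(Intercept)" = 0.2,
           "comp2:in_hospital" = 0, "comp2:z" = 0.1),
    n = 100L, posterior = matrix(1, 1, 2)
  ), class = "ziprm_fit")
  tab <- irr_table(fit)
  expect_equal(tab$irr[tab$term == "(Intercept)"], 1)
  expect_equal(tab$irr[tab$term == "in_hospital"], 1.59)
  expect_equal(tab$conf.low[tab$term == "in_hospital"], 1.59)  # se = 0
  row <- tab[tab$term == "z", ]
  expect_equal(row$conf.low, exp(0.5 - 1.96 * 0.1))
  expect_equal(row$conf.high, exp(0.5 + 1.96 * 0.1))
  expect_true(all(tab$conf.low <= tab$irr & tab$irr <= tab$conf.high))
})

test_that("MAP classification matches stored latent labels under separation", {
  set.seed(59)
  n <- 8000
  x <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  comp_true <- stats::rbinom(n, 1, 0.3) + 1   # 1 = structural zero
  y <- ifelse(comp_true == 1, 0L, stats::rpois(n, exp(1.3)))
  fit <- fit_ziprm(x, y, K = 2, n_starts = 2, seed = 6)
  cl <- ziprm_classify(fit)
  expect_true(all(cl$component[y > 0] == 2))
  expect_equal(sum(cl$shares$share), 1)
  at_risk <- comp_true == 2
  acc <- mean(cl$component[at_risk] == 2)
  expect_gte(acc, 0.95)
})

test_that("three-component fits are canonicalised by intercept order", {
  set.seed(61)
  n <- 6000
  x <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  comp <- sample.int(3, n, replace = TRUE, prob = c(0.4, 0.3, 0.3))
  y <- ifelse(comp == 1, 0L,
              ifelse(comp == 2, stats::rpois(n, 1), stats::rpois(n, 8)))
  fit <- fit_ziprm(x, y, K = 3, n_starts = 4, seed = 7)
  intercepts <- vapply(fit$params$beta, `[`, numeric(1), 1)
  expect_true(all(diff(intercepts) > 0))
  expect_equal(rowSums(fit$posterior), rep(1, n), tolerance = 1e-9)
})

test_that("an intercept-only concomitant weight model matches constant weights", {
  coh <- simulate_cohort(synthetic_config(n = 2500, seed = 67))
  d <- build_design(coh, "multidrug")
  const <- fit_ziprm(d, coh$ae_count, K = 2, n_starts = 2, seed = 8)
  w1 <- matrix(1, nrow(d$x), 1, dimnames = list(NULL, "(Intercept)"))
  conc <- fit_ziprm(d, coh$ae_count, K = 2, n_starts = 2, seed = 8,
                    concomitant = w1)
  expect_equal(conc$loglik, const$loglik, tolerance = 1e-6)
  expect_equal(conc$params$pi, const$params$pi, tolerance = 1e-4)
  expect_equal(conc$n_free_par, const$n_free_par)
})
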