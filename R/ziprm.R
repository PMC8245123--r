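#' Zero-inflated Poisson mixture probability mass function
#'
#' Probability of observing count `y` under a K-component mixture of a point
#' mass at zero (weight `pi[1]`) and K - 1 Poisson components with rates
#' `lambda`:
#' \deqn{P(Y=0) = \pi_1 + \sum_{k\ge 2} \pi_k e^{-\lambda_k}, \qquad
#'       P(Y=y) = \sum_{k\ge 2} \pi_k e^{-\lambda_k}\lambda_k^y / y!
#'       \ (y > 0).}
#'
#' @param y Vector of non-negative integer counts.
#' @param pi Length-K probability vector; `pi[1]` is the structural-zero mass.
#' @param lambda Positive Poisson rates for components 2..K (length K - 1).
#' @param log Return log probabilities?
#'
#' @return A numeric vector the length of `y`.
#' @examples
#' dzipmix(0, pi = c(0.5, 0.5), lambda = log(2)) # 0.75
#' @export
dzipmix <- function(y, pi, lambda, log = FALSE) {
  if (any(y < 0) || any(y != floor(y))) {
    stop("y must be non-negative integers", call. = FALSE)
  }
  if (any(pi < 0) || abs(sum(pi) - 1) > 1e-8) {
    stop("pi must be a probability vector", call. = FALSE)
  }
  if (length(lambda) != length(pi) - 1 || any(lambda <= 0)) {
    stop("lambda must be positive, one rate per Poisson component",
         call. = FALSE)
  }
  lterms <- vapply(seq_along(lambda), function(k) {
    log(pi[k + 1]) + stats::dpois(y, lambda[k], log = TRUE)
  }, numeric(length(y)))
  lterms <- matrix(lterms, nrow = length(y))
  lzero <- ifelse(y == 0, log(pi[1]), -Inf)
  lp <- row_logsumexp(cbind(lzero, lterms))
  if (log) lp else exp(lp)
}

# log mixture weights per record: constant, or multinomial-logit in the
# concomitant design (baseline = structural-zero component)
ziprm_log_weights <- function(params, n, w_mat = NULL) {
  if (!is.null(params$gamma) && !is.null(w_mat)) {
    eta <- cbind(0, w_mat %*% params$gamma)
    eta - row_logsumexp(eta)
  } else {
    matrix(rep(log(params$pi), each = n), nrow = n)
  }
}

# n x K matrix of log(pi_ik * f_k(y_i)); component 1 is the point mass at zero
ziprm_log_components <- function(params, x, counts, w_mat = NULL) {
  K <- if (!is.null(params$gamma)) ncol(params$gamma) + 1 else length(params$pi)
  n <- length(counts)
  lpi <- ziprm_log_weights(params, n, w_mat)
  lc <- matrix(-Inf, n, K)
  lc[, 1] <- ifelse(counts == 0, lpi[, 1], -Inf)
  for (k in 2:K) {
    beta <- params$beta[[k - 1]]
    eta <- drop(x %*% beta)
    lc[, k] <- lpi[, k] + stats::dpois(counts, exp(eta), log = TRUE)
  }
  lc
}

#' Observed-data log-likelihood of a ZIPRM parameter set
#'
#' Sum over records of the log mixture density, with rates
#' `lambda[i, k] = exp(x_i' beta_k)`, computed with log-sum-exp
#' stabilisation.
#'
#' @param params A list with `pi` (length K) and `beta` (list of K - 1 named
#'   coefficient vectors aligned with the design columns).
#' @param design A [build_design()] result or a plain numeric matrix.
#' @param counts Non-negative integer response vector.
#'
#' @param concomitant Optional concomitant-variable design (matrix or
#'   [build_design()] result) when the mixture weights follow a
#'   multinomial-logit model with coefficients `params$gamma`; `NULL` for
#'   constant weights.
#' @return The scalar log-likelihood.
#' @export
ziprm_loglik <- function(params, design, counts, concomitant = NULL) {
  x <- design_x(design)
  if (nrow(x) != length(counts)) stop("dimension mismatch", call. = FALSE)
  betas <- if (is.list(params$beta)) params$beta else list(params$beta)
  w_mat <- if (is.null(concomitant)) NULL else design_x(concomitant)
  sum(row_logsumexp(ziprm_log_components(
    list(pi = params$pi, beta = betas, gamma = params$gamma),
    x, counts, w_mat)))
}

#' E-step: posterior component responsibilities
#'
#' Computes, in log space, `r[i, k] = pi_k f_k(y_i | x_i) / sum_j pi_j f_j`.
#' Records with a positive count have zero responsibility for the
#' structural-zero component.
#'
#' @inheritParams ziprm_loglik
#' @return An n x K matrix with rows summing to one.
#' @export
e_step <- function(params, design, counts, concomitant = NULL) {
  x <- design_x(design)
  betas <- if (is.list(params$beta)) params$beta else list(params$beta)
  w_mat <- if (is.null(concomitant)) NULL else design_x(concomitant)
  lc <- ziprm_log_components(
    list(pi = params$pi, beta = betas, gamma = params$gamma), x, counts, w_mat)
  lse <- row_logsumexp(lc)
  if (any(!is.finite(lse))) {
    stop("numerical underflow: zero total density at some record",
         call. = FALSE)
  }
  exp(lc - lse)
}

#' M-step: update weights and component coefficients
#'
#' Mixture weights become the column means of the responsibilities (constant
#' weight model), clipped away from the boundary; each Poisson component's
#' coefficients are re-estimated by a responsibility-weighted Poisson
#' regression (iteratively reweighted least squares to convergence).
#'
#' @param resp Responsibility matrix from [e_step()].
#' @inheritParams ziprm_loglik
#' @param beta_start Optional list of warm-start coefficient vectors.
#'
#' @return A params list (`pi`, `beta`) as accepted by [ziprm_loglik()].
#' @export
m_step <- function(resp, design, counts, beta_start = NULL,
                   concomitant = NULL, gamma_start = NULL) {
  x <- design_x(design)
  K <- ncol(resp)
  pi <- clip(colMeans(resp), 1e-10, 1 - 1e-10)
  pi <- pi / sum(pi)
  gamma <- NULL
  if (!is.null(concomitant)) {
    w_mat <- design_x(concomitant)
    gamma <- mnl_newton(w_mat, resp, tol = 1e-8, start = gamma_start)$coef
  }
  betas <- vector("list", K - 1)
  for (k in 2:K) {
    w <- resp[, k]
    if (sum(w) < 1e-8 && !is.null(beta_start)) {
      betas[[k - 1]] <- beta_start[[k - 1]]
      next
    }
    # standard IRLS tolerance; a tighter one makes boundary cells (empty
    # covariate categories, coefficient -> -Inf) spin for the full budget
    wpois <- function(start) {
      suppressWarnings(stats::glm.fit(
        x, counts, weights = w, family = stats::poisson(), start = start,
        control = stats::glm.control(epsilon = 1e-8, maxit = 50)))
    }
    fit <- tryCatch(
      wpois(if (!is.null(beta_start)) beta_start[[k - 1]] else NULL),
      error = function(e) NULL)
    bad <- function(f) {
      is.null(f) || anyNA(f$fitted.values) ||
        any(!is.finite(f$fitted.values)) ||
        any(!is.finite(f$coefficients) & !is.na(f$coefficients))
    }
    if (bad(fit) && !is.null(beta_start)) {
      # a poor warm start can overflow the log link; retry cold
      fit <- tryCatch(wpois(NULL), error = function(e) NULL)
    }
    if (bad(fit)) {
      stop("weighted Poisson IRLS diverged in the M-step", call. = FALSE)
    }
    beta_k <- fit$coefficients
    beta_k[is.na(beta_k)] <- 0 # aliased (all-zero-weight) columns
    betas[[k - 1]] <- stats::setNames(beta_k, colnames(x))
  }
  list(pi = pi, beta = betas, gamma = gamma)
}

ziprm_free_par <- function(K, p, q = NULL) {
  if (K == 1) return(p)
  if (is.null(q)) (K - 1) + (K - 1) * p else (K - 1) * q + (K - 1) * p
}

# starting values: pi1 from the observed zero excess over a Poisson GLM,
# betas from a Poisson GLM on the positive-count records, jittered per start
ziprm_init <- function(x, counts, K, start_index, base_seed) {
  set.seed(base_seed + start_index)
  pois <- suppressWarnings(stats::glm.fit(x, counts, family = stats::poisson()))
  p0_excess <- mean(counts == 0) - mean(exp(-pois$fitted.values))
  pi1 <- clip(p0_excess, 0.05, 0.95)
  rest <- rep((1 - pi1) / (K - 1), K - 1) * stats::runif(K - 1, 0.8, 1.2)
  pi <- c(pi1, rest * (1 - pi1) / sum(rest))
  pos <- counts > 0
  base <- if (sum(pos) >= ncol(x)) {
    suppressWarnings(stats::glm.fit(x[pos, , drop = FALSE], counts[pos],
                                    family = stats::poisson()))$coefficients
  } else {
    c(log(mean(counts) + 1e-6), rep(0, ncol(x) - 1))
  }
  base[!is.finite(base)] <- 0
  base <- clip(base, -8, 8) # a separated positive-count subfit is no anchor
  betas <- lapply(seq_len(K - 1), function(k) {
    stats::setNames(base + stats::rnorm(length(base), 0, 0.1), colnames(x))
  })
  list(pi = pi, beta = betas)
}

# order Poisson components by intercept so fits are permutation-stable
canonicalize_ziprm <- function(params, posterior = NULL) {
  K <- length(params$pi)
  if (K <= 2) return(list(params = params, posterior = posterior))
  ord <- order(vapply(params$beta, `[`, numeric(1), 1))
  params$beta <- params$beta[ord]
  params$pi <- c(params$pi[1], params$pi[-1][ord])
  if (!is.null(params$gamma)) {
    params$gamma <- params$gamma[, ord, drop = FALSE]
  }
  if (!is.null(posterior)) {
    posterior <- cbind(posterior[, 1, drop = FALSE],
                       posterior[, -1, drop = FALSE][, ord, drop = FALSE])
  }
  list(params = params, posterior = posterior)
}

#' Fit a zero-inflated Poisson regression mixture by multi-start EM
#'
#' Maximises the observed-data log-likelihood of a K-component mixture of a
#' point mass at zero and K - 1 Poisson regressions whose log rates are
#' linear in the design columns. Because the mixture log-likelihood is
#' multi-modal, `n_starts` random initialisations are run and the fit with
#' the highest log-likelihood is returned. `K = 1` fits a plain Poisson
#' regression (no zero inflation); `K = 2` is exactly the zero-inflated
#' Poisson (ZIP) regression model.
#'
#' @param design A [build_design()] result or numeric matrix (intercept
#'   first).
#' @param counts Non-negative integer response vector.
#' @param K Number of mixture components (>= 1).
#' @param n_starts Number of random EM initialisations.
#' @param seed Base seed; start `s` uses `seed + s`.
#' @param tol Relative log-likelihood convergence tolerance.
#' @param max_iter Maximum EM iterations per start.
#' @param concomitant Optional concomitant-variable design (matrix or
#'   [build_design()] result, intercept first). When supplied, the mixture
#'   weights follow a multinomial-logit model in these covariates instead of
#'   being constant; the fitted coefficients are returned in `params$gamma`
#'   and `params$pi` holds the average weights. Off (`NULL`) by default: the
#'   constant-weight form is the primary model.
#'
#' @return An object of class `"ziprm_fit"`: `params` (`pi`, `beta`),
#'   `loglik`, `loglik_trace`, `n_iter`, `converged`, `n_free_par`, `bic`,
#'   `aic`, `icl`, `posterior`, `start_index`, plus bookkeeping
#'   (`K`, `term_names`, `n`). Standard errors are added by [ziprm_se()].
#' @examples
#' cfg <- synthetic_config(n = 800, seed = 7)
#' coh <- simulate_cohort(cfg)
#' d <- build_design(coh, c("in_hospital", "duration"))
#' fit <- fit_ziprm(d, coh$ae_count, K = 2, n_starts = 2, seed = 1)
#' glance(fit)
#' @export
fit_ziprm <- function(design, counts, K = 2, n_starts = 5, seed = 1,
                      tol = 1e-8, max_iter = 500, concomitant = NULL) {
  x <- design_x(design)
  w_mat <- if (is.null(concomitant)) NULL else design_x(concomitant)
  n <- nrow(x)
  p <- ncol(x)
  if (n < p) stop("need at least as many records as design columns",
                  call. = FALSE)
  if (K < 1) stop("K must be >= 1", call. = FALSE)

  if (K == 1) {
    fit <- suppressWarnings(stats::glm.fit(
      x, counts, family = stats::poisson(),
      control = stats::glm.control(epsilon = 1e-10, maxit = 100)))
    beta <- fit$coefficients
    beta[is.na(beta)] <- 0 # aliased columns
    beta <- stats::setNames(beta, colnames(x))
    ll <- sum(stats::dpois(counts, exp(drop(x %*% beta)), log = TRUE))
    out <- structure(list(
      params = list(pi = 1, beta = list(beta)), K = 1L,
      loglik = ll, loglik_trace = ll, n_iter = fit$iter,
      converged = fit$converged, n_free_par = p,
      bic = -2 * ll + log(n) * p, aic = -2 * ll + 2 * p,
      icl = -2 * ll + log(n) * p,
      posterior = matrix(1, n, 1), start_index = 1L,
      term_names = colnames(x), n = n
    ), class = "ziprm_fit")
    return(out)
  }

  best <- NULL
  failures <- character(0)
  for (s in seq_len(n_starts)) {
    init <- ziprm_init(x, counts, K, s, seed)
    if (!is.null(w_mat)) {
      gamma <- matrix(0, ncol(w_mat), K - 1)
      gamma[1, ] <- log(init$pi[-1] / init$pi[1])
      init$gamma <- gamma
    }
    res <- tryCatch(
      ziprm_em_one(x, counts, K, init, tol, max_iter, w_mat),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      failures <- c(failures, sprintf("start %d: %s", s, conditionMessage(res)))
      next
    }
    if (is.null(best) || res$loglik > best$loglik) {
      best <- res
      best$start_index <- s
    }
  }
  if (is.null(best)) {
    stop("no EM start converged; diagnostics:\n",
         paste(failures, collapse = "\n"), call. = FALSE)
  }
  if (!is.null(w_mat)) {
    # report average per-record weights alongside the logit coefficients
    best$params$pi <- colMeans(exp(ziprm_log_weights(best$params, n, w_mat)))
  }
  if (any(best$params$pi[-1] < 1e-4)) {
    warning("degenerate mixture component (weight < 1e-4)", call. = FALSE)
  }

  canon <- canonicalize_ziprm(best$params, best$posterior)
  npar <- ziprm_free_par(K, p, q = if (is.null(w_mat)) NULL else ncol(w_mat))
  ent <- entropy_of(canon$posterior)
  ll <- best$loglik
  structure(list(
    params = canon$params, K = as.integer(K),
    loglik = ll, loglik_trace = best$trace, n_iter = best$n_iter,
    converged = best$converged, n_free_par = npar,
    bic = -2 * ll + log(n) * npar,
    aic = -2 * ll + 2 * npar,
    icl = -2 * ll + log(n) * npar + 2 * ent,
    posterior = canon$posterior, start_index = best$start_index,
    term_names = colnames(x), n = n
  ), class = "ziprm_fit")
}

entropy_of <- function(post) {
  q <- post[post > 0]
  -sum(q * log(q))
}

ziprm_em_one <- function(x, counts, K, params, tol, max_iter, w_mat = NULL) {
  ll_old <- -Inf
  trace <- numeric(0)
  converged <- FALSE
  resp <- NULL
  for (it in seq_len(max_iter)) {
    lc <- ziprm_log_components(params, x, counts, w_mat)
    lse <- row_logsumexp(lc)
    ll <- sum(lse)
    trace <- c(trace, ll)
    resp <- exp(lc - lse)
    if (is.finite(ll_old) &&
        abs(ll - ll_old) < tol * (abs(ll_old) + 1e-3)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
    params <- m_step(resp, x, counts, beta_start = params$beta,
                     concomitant = w_mat, gamma_start = params$gamma)
  }
  list(params = params, posterior = resp, loglik = trace[length(trace)],
       trace = trace, n_iter = length(trace), converged = converged)
}

#' @export
print.ziprm_fit <- function(x, ...) {
  cat(sprintf(
    "ZIPRM fit: K = %d, logLik = %.3f, BIC = %.3f (%d free parameters)\n",
    x$K, x$loglik, x$bic, x$n_free_par))
  if (x$K >= 2) {
    cat(sprintf("pi1 (structural zeros) = %.4f; converged: %s after %d iterations\n",
                x$params$pi[1], x$converged, x$n_iter))
  }
  invisible(x)
}

#' Fit ZIPRM models over a range of component numbers and select by BIC
#'
#' Fits the mixture for every K in `K_range` (`K = 1` is the plain Poisson
#' regression) and computes, for each fit,
#' `BIC = -2 l(theta) + log(n) * npar`, `AIC = -2 l(theta) + 2 * npar`, and
#' `ICL = BIC + 2 * entropy(posterior)`. The model with the lowest BIC is
#' selected; ties closer than 1e-6 go to the smaller K (parsimony).
#' Component numbers whose fit fails are recorded and excluded from the
#' selection with a warning.
#'
#' @inheritParams fit_ziprm
#' @param K_range Integer vector of component numbers to try.
#'
#' @return A list of class `"ziprm_selection"`: `fits` (named list), `criteria`
#'   (tibble with K, loglik, n_free_par, bic, aic, icl), `best_K`, and
#'   `best_fit`.
#' @export
ziprm_select <- function(design, counts, K_range = 1:4, n_starts = 5,
                         seed = 1, tol = 1e-8, max_iter = 500) {
  if (length(K_range) == 0) stop("K_range must be non-empty", call. = FALSE)
  fits <- list()
  for (K in K_range) {
    res <- tryCatch(
      fit_ziprm(design, counts, K = K, n_starts = n_starts, seed = seed,
                tol = tol, max_iter = max_iter),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      warning("K = ", K, " failed to fit: ", conditionMessage(res),
              call. = FALSE)
    } else {
      fits[[as.character(K)]] <- res
    }
  }
  if (length(fits) == 0) stop("no component number could be fitted",
                              call. = FALSE)
  criteria <- dplyr::bind_rows(lapply(fits, function(f) {
    tibble::tibble(K = f$K, loglik = f$loglik, n_free_par = f$n_free_par,
                   bic = f$bic, aic = f$aic, icl = f$icl)
  }))
  if (anyNA(criteria$bic)) {
    warning("dropping component numbers with undefined BIC: K = ",
            paste(criteria$K[is.na(criteria$bic)], collapse = ", "),
            call. = FALSE)
    criteria <- criteria[!is.na(criteria$bic), , drop = FALSE]
    if (nrow(criteria) == 0) stop("no valid fit", call. = FALSE)
  }
  bic <- criteria$bic
  best <- which(bic <= min(bic) + 1e-6)
  best_K <- criteria$K[best[which.min(criteria$K[best])]]
  structure(list(fits = fits, criteria = criteria, best_K = best_K,
                 best_fit = fits[[as.character(best_K)]]),
            class = "ziprm_selection")
}

#' @export
print.ziprm_selection <- function(x, ...) {
  cat("ZIPRM component selection (lowest BIC preferred):\n")
  print(x$criteria)
  cat("Selected K =", x$best_K, "\n")
  invisible(x)
}

#' Numerical standard errors for a fitted ZIPRM
#'
#' Standard errors are the square roots of the diagonal of the inverse of the
#' observed information matrix, obtained by numerically differentiating the
#' log-likelihood at the maximum. The mixture weights are differentiated on a
#' multinomial-logit scale (baseline: the structural-zero component) so the
#' parameter space is unconstrained; coefficient standard errors are on the
#' natural (log-rate) scale.
#'
#' @param fit A `"ziprm_fit"`.
#' @inheritParams ziprm_loglik
#'
#' @return The fit with `se` (named vector), `vcov`, and `theta_names` added.
#' @export
ziprm_se <- function(fit, design, counts) {
  if (!is.null(fit$params$gamma)) {
    stop("standard errors are implemented for the constant-weight model only",
         call. = FALSE)
  }
  x <- design_x(design)
  K <- fit$K
  p <- ncol(x)
  if (K == 1) {
    theta <- fit$params$beta[[1]]
    names(theta) <- fit$term_names
    negll <- function(th) {
      -sum(stats::dpois(counts, exp(drop(x %*% th)), log = TRUE))
    }
    nm <- fit$term_names
  } else {
    w <- log(fit$params$pi[-1] / fit$params$pi[1])
    theta <- c(w, unlist(fit$params$beta))
    nm <- c(paste0("logit_w", 2:K),
            unlist(lapply(2:K, function(k) paste0("comp", k, ":", fit$term_names))))
    names(theta) <- nm
    negll <- function(th) {
      wk <- th[seq_len(K - 1)]
      pi <- exp(c(0, wk)) / sum(exp(c(0, wk)))
      betas <- split(th[-seq_len(K - 1)], rep(seq_len(K - 1), each = p))
      -ziprm_loglik(list(pi = pi, beta = betas), x, counts)
    }
  }
  hess <- stats::optimHess(theta, negll)
  cov <- tryCatch(solve(hess), error = function(e) NULL)
  if (is.null(cov) || any(diag(cov) <= 0)) {
    qx <- qr(x)
    collinear <- if (qx$rank < p) {
      paste(colnames(x)[-qx$pivot[seq_len(qx$rank)]], collapse = ", ")
    } else {
      "none detected in the design; the likelihood surface may be flat"
    }
    stop("information matrix is not positive definite; collinear terms: ",
         collinear, call. = FALSE)
  }
  dimnames(cov) <- list(nm, nm)
  fit$se <- stats::setNames(sqrt(diag(cov)), nm)
  fit$vcov <- cov
  fit$theta_names <- nm
  fit
}

#' Incidence-rate-ratio table for the at-risk components
#'
#' Exponentiates the Poisson-component coefficients to incidence rate ratios
#' with 95% Wald confidence intervals, `exp(beta +/- 1.96 se)`.
#'
#' @param fit A `"ziprm_fit"`, with standard errors attached by [ziprm_se()]
#'   (without them the interval columns are `NA`).
#' @param conf_z Normal quantile for the interval (1.96 for 95%).
#'
#' @return A tibble with columns `component`, `term`, `estimate`,
#'   `std.error`, `irr`, `conf.low`, `conf.high`.
#' @export
irr_table <- function(fit, conf_z = 1.96) {
  rows <- list()
  ks <- if (fit$K == 1) 1 else 2:fit$K
  for (k in ks) {
    beta <- fit$params$beta[[if (fit$K == 1) 1 else k - 1]]
    se <- rep(NA_real_, length(beta))
    if (!is.null(fit$se)) {
      nm <- if (fit$K == 1) fit$term_names else
        paste0("comp", k, ":", fit$term_names)
      se <- unname(fit$se[nm])
    }
    rows[[length(rows) + 1]] <- tibble::tibble(
      component = k,
      term = fit$term_names,
      estimate = unname(beta),
      std.error = se,
      irr = exp(unname(beta)),
      conf.low = exp(unname(beta) - conf_z * se),
      conf.high = exp(unname(beta) + conf_z * se)
    )
  }
  dplyr::bind_rows(rows)
}

#' MAP classification of records into mixture components
#'
#' Allocates each record to the component with the largest posterior
#' responsibility (ties to the lower component index) and reports the share
#' of the cohort in each cluster. Component 1 is the no-risk
#' (structural-zero) cluster; records with a positive count can never be
#' allocated to it.
#'
#' @param fit A `"ziprm_fit"`.
#'
#' @return A list with `component` (integer vector) and `shares` (tibble with
#'   `component`, `n`, `share`).
#' @export
ziprm_classify <- function(fit) {
  comp <- max.col(fit$posterior, ties.method = "first")
  tab <- tabulate(comp, nbins = ncol(fit$posterior))
  list(
    component = comp,
    shares = tibble::tibble(
      component = seq_along(tab), n = tab, share = tab / sum(tab))
  )
}

#' @exportS3Method generics::tidy
tidy.ziprm_fit <- function(x, ...) {
  irr_table(x)
}

#' @exportS3Method generics::glance
glance.ziprm_fit <- function(x, ...) {
  tibble::tibble(
    K = x$K, logLik = x$loglik, n_free_par = x$n_free_par,
    BIC = x$bic, AIC = x$aic, ICL = x$icl,
    pi1 = if (x$K >= 2) x$params$pi[1] else NA_real_,
    n_iter = x$n_iter, converged = x$converged, nobs = x$n
  )
}

#' Forest plot of incidence rate ratios
#'
#' @param object A `"ziprm_fit"` with standard errors attached.
#' @param ... Unused.
#' @return A ggplot object (log-scaled x axis, reference line at IRR = 1).
#' @exportS3Method ggplot2::autoplot
autoplot.ziprm_fit <- function(object, ...) {
  tab <- irr_table(object)
  tab <- tab[tab$term != "(Intercept)", , drop = FALSE]
  tab$term <- factor(tab$term, levels = rev(unique(tab$term)))
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$irr, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(
      ggplot2::aes(xmin = .data$conf.low, xmax = .data$conf.high)) +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~component, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "Incidence rate ratio (95% CI)", y = NULL) +
    ggplot2::theme_minimal()
}
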