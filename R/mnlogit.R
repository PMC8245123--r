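#' Expand a cohort into an event-level table for the AE-type model
#'
#' The multinomial logit for the adverse-event type is fitted on one row per
#' event: every recorded AE contributes one row labelled with its category,
#' and every AE-free procedure contributes exactly one row labelled with the
#' no-AE reference. A procedure with several AEs therefore appears several
#' times, which is why the event table can be larger than the cohort. Row
#' order is deterministic: cohort order, then the stored type order within a
#' record.
#'
#' @param cohort A validated cohort tibble.
#'
#' @return A tibble with all cohort covariate columns, a `z` column
#'   (`"none"` or an [ae_types()] category) and a `record` column indexing
#'   the source row.
#' @examples
#' coh <- simulate_cohort(synthetic_config(n = 200, seed = 5))
#' ev <- expand_events(coh)
#' table(ev$z)
#' @export
expand_events <- function(cohort) {
  types <- split_tokens(cohort$ae_types)
  bad <- setdiff(unique(unlist(types)), ae_types())
  if (length(bad) > 0) {
    stop("unknown AE-type label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  n_rows <- pmax(lengths(types), 1L)
  idx <- rep(seq_len(nrow(cohort)), n_rows)
  z <- unlist(lapply(types, function(t) if (length(t) == 0) "none" else t))
  out <- cohort[idx, setdiff(names(cohort), c("ae_types", ".component")),
                drop = FALSE]
  out$z <- z
  out$record <- idx
  tibble::as_tibble(out)
}

# Newton-Raphson for a multinomial logit with (possibly soft) outcome matrix.
# x: n x p design; Y: n x l non-negative weights, column 1 = reference.
mnl_newton <- function(x, Y, ridge = 0, tol = 1e-10, max_iter = 100,
                       start = NULL) {
  n <- nrow(x)
  p <- ncol(x)
  l <- ncol(Y)
  m <- l - 1
  N <- rowSums(Y)
  B <- if (is.null(start)) matrix(0, p, m) else start
  probs <- function(B) {
    eta <- cbind(0, x %*% B)
    e <- exp(eta - apply(eta, 1, max))
    e / rowSums(e)
  }
  llfun <- function(B) {
    P <- probs(B)
    sum(Y * log(pmax(P, 1e-300)))
  }
  ll <- llfun(B)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    P <- probs(B)
    G <- t(x) %*% (Y[, -1, drop = FALSE] - N * P[, -1, drop = FALSE])
    H <- matrix(0, p * m, p * m)
    for (a in seq_len(m)) {
      for (b in a:m) {
        v <- N * (P[, a + 1] * ((a == b) - P[, b + 1]))
        blk <- crossprod(x, x * v)
        ra <- (a - 1) * p + seq_len(p)
        rb <- (b - 1) * p + seq_len(p)
        H[ra, rb] <- blk
        H[rb, ra] <- t(blk)
      }
    }
    if (ridge > 0) H <- H + diag(ridge, p * m)
    delta <- tryCatch(solve(H, as.vector(G)), error = function(e) NULL)
    if (is.null(delta)) {
      stop("singular Hessian in the multinomial Newton step ",
           "(quasi-separation?); retry with ridge = 1e-8", call. = FALSE)
    }
    step <- 1
    repeat {
      B_new <- B + matrix(step * delta, p, m)
      ll_new <- llfun(B_new)
      if (is.finite(ll_new) && ll_new >= ll - 1e-12) break
      step <- step / 2
      if (step < 1e-10) {
        stop("step-halving failed in the multinomial Newton iteration",
             call. = FALSE)
      }
    }
    moved <- abs(ll_new - ll)
    B <- B_new
    ll <- ll_new
    if (moved < tol * (abs(ll) + 1) && max(abs(G)) < 1e-6) {
      converged <- TRUE
      break
    }
  }
  P <- probs(B)
  H <- matrix(0, p * m, p * m)
  for (a in seq_len(m)) {
    for (b in a:m) {
      v <- N * (P[, a + 1] * ((a == b) - P[, b + 1]))
      blk <- crossprod(x, x * v)
      ra <- (a - 1) * p + seq_len(p)
      rb <- (b - 1) * p + seq_len(p)
      H[ra, rb] <- blk
      H[rb, ra] <- t(blk)
    }
  }
  list(coef = B, loglik = ll, info = H, converged = converged, n_iter = it)
}

#' Fit a multinomial logit for the adverse-event type
#'
#' Maximum-likelihood multinomial logistic regression of the event category
#' against the no-AE reference,
#' `log P(Z = z | x) / P(Z = 0 | x) = alpha_z + x' beta_z`, fitted by
#' Newton-Raphson with step-halving. The covariance matrix is the inverse of
#' the observed information at the optimum.
#'
#' @param events An event table from [expand_events()], or any tibble with
#'   the model covariates and a `z` column.
#' @param terms Design terms (see [build_design()]); `character(0)` fits an
#'   intercept-only model.
#' @param reference Reference category (default `"none"`, absence of AEs).
#' @param categories Optional explicit category order (reference first);
#'   defaults to the reference followed by the observed categories in
#'   [ae_types()] order, then any others alphabetically.
#' @param ridge Optional ridge (e.g. `1e-8`) added to the Hessian to
#'   stabilise near-separated fits.
#' @param spec A [cohort_spec()] for the design coding.
#'
#' @return An object of class `"mnlogit_fit"`: `coef` (p x (l-1) matrix,
#'   columns named by category), `alpha` (intercept row), `loglik`, `vcov`,
#'   `se`, `categories`, `reference`, `term_names`, `n`, `converged`.
#' @examples
#' coh <- simulate_cohort(synthetic_config(n = 3000, seed = 11))
#' ev <- expand_events(coh)
#' fit <- fit_mnlogit(ev, terms = character(0))
#' tidy(fit)
#' @export
fit_mnlogit <- function(events, terms = model3_terms(), reference = "none",
                        categories = NULL, ridge = 0, spec = cohort_spec()) {
  z <- as.character(events$z)
  if (is.null(categories)) {
    obs <- unique(z)
    ordered <- c(intersect(ae_types(), obs), sort(setdiff(obs, c(ae_types(), reference))))
    categories <- c(reference, ordered)
  }
  if (!all(z %in% categories)) {
    stop("event categories outside the declared set: ",
         paste(setdiff(unique(z), categories), collapse = ", "), call. = FALSE)
  }
  missing_cat <- setdiff(categories, unique(z))
  if (length(missing_cat) > 0) {
    stop("category never observed: ", paste(missing_cat, collapse = ", "),
         call. = FALSE)
  }
  x <- if (length(terms) == 0) {
    matrix(1, nrow(events), 1, dimnames = list(NULL, "(Intercept)"))
  } else {
    build_design(events, terms, spec)$x
  }
  Y <- outer(z, categories, `==`) * 1
  res <- mnl_newton(x, Y, ridge = ridge)
  if (!res$converged) {
    stop("multinomial Newton iteration did not converge", call. = FALSE)
  }
  p <- ncol(x)
  m <- length(categories) - 1
  cov <- tryCatch(solve(res$info), error = function(e) {
    stop("observed information is singular at the optimum ",
         "(quasi-separation?); retry with ridge = 1e-8", call. = FALSE)
  })
  se <- matrix(sqrt(diag(cov)), p, m)
  dimnames(res$coef) <- dimnames(se) <- list(colnames(x), categories[-1])
  structure(list(
    coef = res$coef, alpha = res$coef[1, ], loglik = res$loglik,
    vcov = cov, se = se, categories = categories, reference = reference,
    term_names = colnames(x), n = nrow(x), converged = res$converged,
    n_iter = res$n_iter
  ), class = "mnlogit_fit")
}

#' Predicted category probabilities from a multinomial logit fit
#'
#' @param fit A `"mnlogit_fit"`.
#' @param x Design matrix with the fit's columns (intercept first).
#' @return An n x l matrix of probabilities (reference category first),
#'   rows summing to one.
#' @export
mnlogit_probs <- function(fit, x) {
  eta <- cbind(0, x %*% fit$coef)
  e <- exp(eta - apply(eta, 1, max))
  p <- e / rowSums(e)
  colnames(p) <- fit$categories
  p
}

#' Odds-ratio table from a multinomial logit fit
#'
#' Exponentiates each non-reference category's coefficients to odds ratios
#' against the no-AE reference, with 95% Wald intervals
#' `exp(beta +/- 1.96 se)`.
#'
#' @param fit A `"mnlogit_fit"`.
#' @param category Optional single category to report; default all.
#' @param conf_z Normal quantile for the interval.
#'
#' @return A tibble with `category`, `term`, `estimate`, `std.error`, `or`,
#'   `conf.low`, `conf.high`.
#' @export
or_table <- function(fit, category = NULL, conf_z = 1.96) {
  cats <- if (is.null(category)) fit$categories[-1] else category
  rows <- lapply(cats, function(cz) {
    b <- fit$coef[, cz]
    s <- fit$se[, cz]
    tibble::tibble(
      category = cz, term = fit$term_names,
      estimate = unname(b), std.error = unname(s),
      or = exp(unname(b)),
      conf.low = exp(unname(b) - conf_z * s),
      conf.high = exp(unname(b) + conf_z * s)
    )
  })
  dplyr::bind_rows(rows)
}

#' @export
print.mnlogit_fit <- function(x, ...) {
  cat(sprintf(
    "Multinomial logit: %d categories vs '%s', logLik = %.3f, n = %d events\n",
    length(x$categories) - 1, x$reference, x$loglik, x$n))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.mnlogit_fit <- function(x, ...) {
  or_table(x)
}

#' @exportS3Method generics::glance
glance.mnlogit_fit <- function(x, ...) {
  tibble::tibble(
    logLik = x$loglik,
    n_categories = length(x$categories) - 1,
    n_par = length(x$coef),
    nobs = x$n, n_iter = x$n_iter, converged = x$converged
  )
}

#' Forest plot of odds ratios for one or all AE categories
#'
#' @param object A `"mnlogit_fit"`.
#' @param category Optional category subset.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.mnlogit_fit <- function(object, category = NULL, ...) {
  tab <- or_table(object, category = category)
  tab <- tab[tab$term != "(Intercept)", , drop = FALSE]
  tab$term <- factor(tab$term, levels = rev(unique(tab$term)))
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$or, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(
      ggplot2::aes(xmin = .data$conf.low, xmax = .data$conf.high)) +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~category) +
    ggplot2::labs(x = "Odds ratio vs no AE (95% CI)", y = NULL) +
    ggplot2::theme_minimal()
}
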