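#' Configuration for the end-to-end analysis pipeline
#'
#' Exactly one input mode must be set: `cohort_path` to load an existing
#' cohort CSV, or `synthetic` (a [synthetic_config()]) to generate one.
#'
#' @param cohort_path Path of a cohort CSV, or `NULL`.
#' @param synthetic A [synthetic_config()], or `NULL`.
#' @param K_range Component numbers tried for the count models.
#' @param n_starts Random EM starts per component number.
#' @param seed Seed governing every stochastic step of the run.
#' @param tol EM convergence tolerance.
#' @param max_iter Maximum EM iterations per start.
#' @param figures Write forest-plot figures (PNG)? Off by default so the
#'   pipeline is headless-safe.
#' @param model3 Covariate terms of the AE-type multinomial logit. The full
#'   [model3_terms()] set suits registry-scale cohorts; smaller cohorts with
#'   only a handful of events per category need a reduced set.
#' @param mnlogit_ridge Ridge passed to [fit_mnlogit()] (0 = plain maximum
#'   likelihood).
#'
#' @return A list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(cohort_path = NULL, synthetic = NULL,
                            K_range = 1:4, n_starts = 3, seed = 1,
                            tol = 1e-8, max_iter = 500, figures = FALSE,
                            model3 = model3_terms(), mnlogit_ridge = 0) {
  if (is.null(cohort_path) == is.null(synthetic)) {
    stop("set exactly one of cohort_path or synthetic", call. = FALSE)
  }
  structure(list(cohort_path = cohort_path, synthetic = synthetic,
                 K_range = K_range, n_starts = n_starts, seed = seed,
                 tol = tol, max_iter = max_iter, figures = figures,
                 model3 = model3, mnlogit_ridge = mnlogit_ridge),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' The YAML mirrors the arguments of [pipeline_config()]; a `synthetic`
#' block is forwarded to [synthetic_config()].
#'
#' @param path YAML file path.
#' @return A `"pipeline_config"`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  syn <- NULL
  if (!is.null(raw$synthetic)) {
    args <- raw$synthetic
    # YAML 1.1 reads a bare `n:` key as the boolean FALSE; map it back
    names(args)[names(args) %in% c("FALSE", "no")] <- "n"
    syn <- do.call(synthetic_config, args)
  }
  pipeline_config(
    cohort_path = raw$cohort_path, synthetic = syn,
    K_range = if (is.null(raw$K_range)) 1:4 else as.integer(raw$K_range),
    n_starts = raw$n_starts %||% 3, seed = raw$seed %||% 1,
    tol = raw$tol %||% 1e-8, max_iter = raw$max_iter %||% 500,
    figures = isTRUE(raw$figures),
    model3 = raw$model3 %||% model3_terms(),
    mnlogit_ridge = raw$mnlogit_ridge %||% 0
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

# empty covariate cells put coefficients at the boundary and make the
# observed information singular; report the fit with NA standard errors
# rather than failing the stage
try_ziprm_se <- function(fit, design, counts) {
  tryCatch(ziprm_se(fit, design, counts), error = function(e) {
    warning("standard errors unavailable: ", conditionMessage(e),
            call. = FALSE)
    fit
  })
}

propofol_subset <- function(cohort) {
  keep <- vapply(split_tokens(cohort$drugs), function(d) "propofol" %in% d,
                 logical(1))
  cohort[keep, , drop = FALSE]
}

#' Run the full adverse-event analysis pipeline
#'
#' Stages, mirroring the structure of the study replica:
#' \enumerate{
#'   \item load or generate the cohort;
#'   \item descriptives: covariate table, AE-count summary (pooled and by
#'     propofol stratum), AE-type tabulation;
#'   \item overdispersion pre-test on the full-covariate Poisson GLM;
#'   \item Model 1: ZIPRM over all records with the six-drug design,
#'     components selected by BIC;
#'   \item Model 2: ZIPRM restricted to propofol-receiving records with the
#'     multidrug contrast;
#'   \item Model 3: multinomial logit for the AE type on the event-expanded
#'     table.
#' }
#' All tables are written as CSV, fits as JSON, and a run log with seeds,
#' tolerances, timings and convergence diagnostics as JSON. Reruns with the
#' same configuration and seed produce identical numbers.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if missing).
#'
#' @return Invisibly, a list with the cohort and every stage result.
#' @export
run_pipeline <- function(config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  log <- list(seed = config$seed, tol = config$tol,
              n_starts = config$n_starts, K_range = config$K_range,
              started = format(t0), stages = list())
  tick <- function(name, start) {
    log$stages[[name]] <<- list(seconds = round(
      as.numeric(difftime(Sys.time(), start, units = "secs")), 2))
  }

  s <- Sys.time()
  cohort <- stage("cohort", {
    if (!is.null(config$cohort_path)) read_cohort(config$cohort_path)
    else simulate_cohort(config$synthetic)
  })
  tick("cohort", s)

  s <- Sys.time()
  descr <- stage("describe", {
    pooled <- summarize_counts(cohort$ae_count)
    prop <- propofol_subset(cohort)
    multi_flag <- vapply(split_tokens(prop$drugs),
                         function(d) any(c("midazolam", "fentanyl") %in% d),
                         logical(1))
    list(
      pooled = pooled,
      by_stratum = list(
        propofol_alone = summarize_counts(prop$ae_count[!multi_flag]),
        propofol_multi = if (any(multi_flag))
          summarize_counts(prop$ae_count[multi_flag]) else NULL
      ),
      events = tabulate_events(cohort)
    )
  })
  readr::write_csv(descr$pooled$freq, file.path(out_dir, "counts_pooled.csv"))
  readr::write_csv(descr$events, file.path(out_dir, "events.csv"))
  tick("describe", s)

  s <- Sys.time()
  design1 <- stage("design", build_design(cohort, model1_terms()))
  disp <- stage("dispersion", {
    pg <- fit_poisson_glm(design1, cohort$ae_count)
    ct_test(cohort$ae_count, pg$fitted)
  })
  jsonlite::write_json(tidy(disp), file.path(out_dir, "dispersion.json"),
                       auto_unbox = TRUE, digits = NA)
  tick("dispersion", s)

  s <- Sys.time()
  model1 <- stage("model1", {
    sel <- ziprm_select(design1, cohort$ae_count, K_range = config$K_range,
                        n_starts = config$n_starts, seed = config$seed,
                        tol = config$tol, max_iter = config$max_iter)
    fit <- sel$best_fit
    if (fit$K >= 2) fit <- try_ziprm_se(fit, design1, cohort$ae_count)
    list(selection = sel, fit = fit)
  })
  write_ziprm_outputs(model1, "model1", out_dir, config$figures)
  tick("model1", s)

  s <- Sys.time()
  model2 <- stage("model2", {
    prop <- propofol_subset(cohort)
    d2 <- build_design(prop, model2_terms())
    sel <- ziprm_select(d2, prop$ae_count, K_range = config$K_range,
                        n_starts = config$n_starts, seed = config$seed,
                        tol = config$tol, max_iter = config$max_iter)
    fit <- sel$best_fit
    if (fit$K >= 2) fit <- try_ziprm_se(fit, d2, prop$ae_count)
    list(selection = sel, fit = fit, n = nrow(prop))
  })
  write_ziprm_outputs(model2, "model2", out_dir, config$figures)
  tick("model2", s)

  s <- Sys.time()
  model3 <- stage("model3", {
    events <- expand_events(cohort)
    fit_mnlogit(events, terms = config$model3, ridge = config$mnlogit_ridge)
  })
  readr::write_csv(or_table(model3), file.path(out_dir, "model3_or.csv"))
  jsonlite::write_json(
    list(loglik = model3$loglik, categories = model3$categories,
         coef = as.data.frame(model3$coef)),
    file.path(out_dir, "model3_fit.json"), auto_unbox = TRUE, digits = NA)
  if (config$figures) {
    ggplot2::ggsave(file.path(out_dir, "model3_forest.png"),
                    autoplot(model3), width = 8, height = 6, dpi = 150)
  }
  tick("model3", s)

  log$finished <- format(Sys.time())
  jsonlite::write_json(log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE)
  invisible(list(cohort = cohort, descriptives = descr, dispersion = disp,
                 model1 = model1, model2 = model2, model3 = model3,
                 log = log))
}

write_ziprm_outputs <- function(model, name, out_dir, figures) {
  fit <- model$fit
  ser <- list(
    K = fit$K, pi = fit$params$pi, beta = lapply(fit$params$beta, as.list),
    loglik = fit$loglik, n_free_par = fit$n_free_par,
    bic = fit$bic, aic = fit$aic, icl = fit$icl,
    converged = fit$converged,
    se = if (!is.null(fit$se)) as.list(fit$se) else NULL,
    criteria = model$selection$criteria
  )
  jsonlite::write_json(ser, file.path(out_dir, paste0(name, "_fit.json")),
                       auto_unbox = TRUE, digits = NA)
  readr::write_csv(irr_table(fit), file.path(out_dir, paste0(name, "_irr.csv")))
  if (figures && fit$K >= 2) {
    ggplot2::ggsave(file.path(out_dir, paste0(name, "_forest.png")),
                    autoplot(fit), width = 8, height = 6, dpi = 150)
  }
  invisible(NULL)
}
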