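#' Build a regression design matrix from a cohort
#'
#' Constructs the numeric design matrix used by the Poisson GLM, the
#' zero-inflated Poisson regression mixture, and the multinomial logit. The
#' first column is an intercept of ones. Categorical covariates are
#' dummy-coded with their declared reference level omitted; `duration` is
#' rescaled from minutes to hours; drug terms are non-exclusive 0/1
#' indicators (a procedure may use several sedatives).
#'
#' Two special terms encode the sedation comparisons of interest:
#' \describe{
#'   \item{`drugs`}{one indicator per sedative in [drug_names()]
#'     (six columns).}
#'   \item{`multidrug`}{a single indicator for propofol given together with
#'     midazolam and/or fentanyl, versus any other drug pattern.}
#' }
#'
#' @param cohort A validated cohort tibble.
#' @param terms Character vector naming the covariates to enter, e.g.
#'   `model2_terms()`. Categorical and continuous names must exist in `spec`.
#' @param spec A [cohort_spec()].
#'
#' @return A list of class `"design_matrix"` with elements `x` (n x p numeric
#'   matrix, intercept first), `terms`, and `coding` (a tibble mapping each
#'   column to its covariate and level).
#' @examples
#' coh <- simulate_cohort(synthetic_config(n = 100, seed = 1))
#' d <- build_design(coh, model2_terms())
#' ncol(d$x) # 19 columns
#' @export
build_design <- function(cohort, terms, spec = cohort_spec()) {
  n <- nrow(cohort)
  cols <- list(`(Intercept)` = rep(1, n))
  coding <- list(tibble::tibble(column = "(Intercept)",
                                covariate = "(Intercept)", level = NA_character_))
  drugs <- NULL
  if (any(terms %in% c("drugs", "multidrug"))) {
    drugs <- split_tokens(cohort$drugs)
  }

  for (term in terms) {
    if (term == "drugs") {
      for (d in drug_names()) {
        nm <- paste0("drug_", d)
        cols[[nm]] <- as.numeric(vapply(drugs, function(x) d %in% x, logical(1)))
        coding[[length(coding) + 1]] <-
          tibble::tibble(column = nm, covariate = "drugs", level = d)
      }
    } else if (term == "multidrug") {
      cols[["multidrug"]] <- as.numeric(vapply(
        drugs,
        function(x) "propofol" %in% x && any(c("midazolam", "fentanyl") %in% x),
        logical(1)
      ))
      coding[[length(coding) + 1]] <-
        tibble::tibble(column = "multidrug", covariate = "multidrug",
                       level = "propofol+midazolam/fentanyl")
    } else if (term %in% c("emergency", "in_hospital")) {
      cols[[term]] <- as.numeric(cohort[[term]])
      coding[[length(coding) + 1]] <-
        tibble::tibble(column = term, covariate = term, level = "TRUE")
    } else if (!is.null(spec[[term]]) && spec[[term]]$kind == "continuous") {
      src <- spec[[term]]$source
      nm <- if (term == "duration") "duration_hr" else term
      cols[[nm]] <- cohort[[src]] * spec[[term]]$scale
      coding[[length(coding) + 1]] <-
        tibble::tibble(column = nm, covariate = term, level = NA_character_)
    } else if (!is.null(spec[[term]]) && spec[[term]]$kind == "categorical") {
      s <- spec[[term]]
      vals <- as.character(cohort[[term]])
      for (lev in setdiff(s$levels, s$reference)) {
        nm <- paste0(term, lev)
        cols[[nm]] <- as.numeric(vals == lev)
        coding[[length(coding) + 1]] <-
          tibble::tibble(column = nm, covariate = term, level = lev)
      }
    } else {
      stop("unknown covariate in model terms: '", term, "'", call. = FALSE)
    }
  }

  x <- do.call(cbind, cols)
  colnames(x) <- names(cols)
  if (n > 0) {
    constant <- apply(x[, -1, drop = FALSE], 2, function(v) length(unique(v)) == 1)
    if (any(constant)) {
      warning("constant design column(s) after coding: ",
              paste(names(constant)[constant], collapse = ", "),
              " (rank deficiency likely)", call. = FALSE)
    }
  }
  structure(list(x = x, terms = terms, coding = dplyr::bind_rows(coding)),
            class = "design_matrix")
}

#' Covariate sets of the two count-model specifications
#'
#' `model1_terms()` is the full-drug specification: demographics, clinical
#' scores, procedure characteristics, and one indicator per sedative drug
#' (24 design columns; 25 free parameters at K = 2 once the mixture weight is
#' counted). `model2_terms()` replaces the six drug indicators with the single
#' `multidrug` flag contrasting propofol + midazolam/fentanyl against propofol
#' alone (19 columns; 20 free parameters at K = 2). `model3_terms()` is the
#' covariate set of the multinomial logit for the AE type.
#'
#' @return A character vector of term names for [build_design()].
#' @export
model1_terms <- function() {
  c("sex", "age_cat", "bmi_cat", "asa", "mallampati", "smoking",
    "emergency", "in_hospital", "duration", "drugs")
}

#' @rdname model1_terms
#' @export
model2_terms <- function() {
  c("sex", "age_cat", "bmi_cat", "asa", "mallampati", "smoking",
    "emergency", "in_hospital", "duration", "multidrug")
}

#' @rdname model1_terms
#' @export
model3_terms <- function() {
  model2_terms()
}

#' @export
print.design_matrix <- function(x, ...) {
  cat(sprintf("Design matrix: %d rows x %d columns\n", nrow(x$x), ncol(x$x)))
  cat("Columns:", paste(colnames(x$x), collapse = ", "), "\n")
  invisible(x)
}

design_x <- function(design) {
  if (inherits(design, "design_matrix")) design$x else as.matrix(design)
}
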