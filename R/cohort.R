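#' @importFrom rlang .data
#' @importFrom stats setNames
NULL

#' Adverse-event categories and sedative drugs recognised by the cohort schema
#'
#' @description
#' `ae_types()` returns the five adverse-event (AE) categories recorded during
#' sedation for gastrointestinal endoscopy: cardiovascular, respiratory,
#' hemorrhagic, other, and suspension of the procedure before accomplishment
#' ("stopped"). `drug_names()` returns the sedative-drug indicators tracked per
#' procedure.
#'
#' @return A character vector.
#' @export
ae_types <- function() {
  c("cardiovascular", "respiratory", "hemorrhagic", "other", "stopped")
}

#' @rdname ae_types
#' @export
drug_names <- function() {
  c("propofol", "midazolam", "fentanyl", "sevoflurane", "curare", "other")
}

#' Covariate specification for a sedation cohort
#'
#' Declares, for every covariate in the cohort schema, its kind (categorical,
#' 0/1 indicator, or continuous), its ordered level set and reference level,
#' and any unit rescaling applied when the design matrix is built.
#'
#' The default reference levels encode the baseline categories of the study
#' design: age < 66 years, BMI < 21, ASA I, Mallampati I, elective procedure,
#' outpatient, current smoker, and male sex. Duration is stored in minutes and
#' rescaled to hours at design-matrix construction so that its coefficient is
#' the log rate ratio per additional hour of endoscopy.
#'
#' @param ... Named elements overriding entries of the default specification.
#'
#' @return A named list of per-covariate descriptors, of class
#'   `"covariate_spec"`. Each descriptor has `kind`, and for categorical
#'   covariates `levels` and `reference`; continuous covariates carry `source`
#'   (the cohort column) and a positive `scale` factor.
#' @examples
#' spec <- cohort_spec()
#' names(spec)
#' spec$smoking$reference
#' @export
cohort_spec <- function(...) {
  spec <- list(
    sex = list(kind = "categorical",
               levels = c("male", "female"), reference = "male"),
    age_cat = list(kind = "categorical",
                   levels = c("<66", "67-75", ">=75"), reference = "<66"),
    bmi_cat = list(kind = "categorical",
                   levels = c("<21", "21-24", "25-27", ">=27"),
                   reference = "<21"),
    asa = list(kind = "categorical",
               levels = c("1", "2", "3", "4"), reference = "1"),
    mallampati = list(kind = "categorical",
                      levels = c("1", "2", "3", "4"), reference = "1"),
    smoking = list(kind = "categorical",
                   levels = c("current", "previous", "non"),
                   reference = "current"),
    emergency = list(kind = "indicator"),
    in_hospital = list(kind = "indicator"),
    duration = list(kind = "continuous", source = "duration_min", scale = 1 / 60)
  )
  override <- list(...)
  for (nm in names(override)) spec[[nm]] <- override[[nm]]
  for (nm in names(spec)) {
    s <- spec[[nm]]
    if (identical(s$kind, "categorical") && !(s$reference %in% s$levels)) {
      stop("reference level of '", nm, "' is not among its levels",
           call. = FALSE)
    }
    if (identical(s$kind, "continuous") && (!is.numeric(s$scale) || s$scale <= 0)) {
      stop("scale of '", nm, "' must be a positive number", call. = FALSE)
    }
  }
  structure(spec, class = "covariate_spec")
}

cohort_columns <- function() {
  c("sex", "age_cat", "bmi_cat", "asa", "mallampati", "smoking",
    "emergency", "in_hospital", "duration_min", "drugs", "ae_count", "ae_types")
}

split_tokens <- function(x) {
  strsplit(ifelse(is.na(x) | x == "", "", x), ";", fixed = TRUE)
}

join_tokens <- function(x) {
  vapply(x, paste, collapse = ";", FUN.VALUE = character(1))
}

#' Validate a cohort table against the schema
#'
#' Checks one-row-per-procedure cohort data: categorical values must belong to
#' their declared level sets (ASA and Mallampati scores 1-4; the registry
#' contains no ASA 5 or 6), AE counts must be non-negative integers, durations
#' non-negative, and the semicolon-joined `drugs` / `ae_types` fields must use
#' recognised tokens. Rows with missing required cells are dropped and counted
#' (mirroring registry curation, where incomplete records are excluded rather
#' than imputed); values that violate a schema invariant raise an error.
#'
#' @param cohort A data frame with the cohort columns (see [read_cohort()]).
#' @param spec A [cohort_spec()].
#'
#' @return A validated tibble with attribute `n_dropped` counting removed
#'   incomplete rows.
#' @export
validate_cohort <- function(cohort, spec = cohort_spec()) {
  required <- cohort_columns()
  missing_cols <- setdiff(required, names(cohort))
  if (length(missing_cols) > 0) {
    stop("cohort is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  cohort <- tibble::as_tibble(cohort)
  cohort$asa <- as.integer(cohort$asa)
  cohort$mallampati <- as.integer(cohort$mallampati)
  cohort$ae_count <- suppressWarnings(as.integer(cohort$ae_count))
  cohort$duration_min <- as.numeric(cohort$duration_min)
  cohort$emergency <- as.logical(cohort$emergency)
  cohort$in_hospital <- as.logical(cohort$in_hospital)
  cohort$drugs <- ifelse(is.na(cohort$drugs), "", as.character(cohort$drugs))
  cohort$ae_types <- ifelse(is.na(cohort$ae_types), "", as.character(cohort$ae_types))

  need <- c("sex", "age_cat", "bmi_cat", "asa", "mallampati", "smoking",
            "emergency", "in_hospital", "duration_min", "ae_count")
  complete <- !Reduce(`|`, lapply(cohort[need], is.na))
  n_dropped <- sum(!complete)
  cohort <- cohort[complete, , drop = FALSE]

  check_levels <- function(col, levels) {
    bad <- !(as.character(cohort[[col]]) %in% levels)
    if (any(bad)) {
      stop("invalid ", col, " value(s): ",
           paste(unique(cohort[[col]][bad]), collapse = ", "), call. = FALSE)
    }
  }
  for (nm in c("sex", "age_cat", "bmi_cat", "asa", "mallampati", "smoking")) {
    check_levels(nm, spec[[nm]]$levels)
  }
  if (any(cohort$ae_count < 0)) {
    stop("ae_count must be a non-negative integer", call. = FALSE)
  }
  if (any(cohort$duration_min < 0)) {
    stop("duration_min must be non-negative", call. = FALSE)
  }
  bad_drug <- setdiff(unique(unlist(split_tokens(cohort$drugs))), drug_names())
  if (length(bad_drug) > 0) {
    stop("unknown drug token(s): ", paste(bad_drug, collapse = ", "),
         call. = FALSE)
  }
  bad_type <- setdiff(unique(unlist(split_tokens(cohort$ae_types))), ae_types())
  if (length(bad_type) > 0) {
    stop("unknown AE-type token(s): ", paste(bad_type, collapse = ", "),
         call. = FALSE)
  }
  n_listed <- lengths(split_tokens(cohort$ae_types))
  if (any(n_listed > 0 & cohort$ae_count == 0)) {
    stop("records with ae_count = 0 cannot carry AE-type labels", call. = FALSE)
  }
  attr(cohort, "n_dropped") <- n_dropped
  cohort
}

#' Read or write a cohort CSV
#'
#' The cohort CSV has one row per sedated procedure with columns `sex`,
#' `age_cat`, `bmi_cat`, `asa`, `mallampati`, `smoking`, `emergency`,
#' `in_hospital`, `duration_min`, `drugs`, `ae_count`, `ae_types`. The `drugs`
#' and `ae_types` fields hold semicolon-joined tokens (a multiset for
#' `ae_types`, since one procedure can record several adverse events). Rows
#' with missing required cells are dropped and counted via the `n_dropped`
#' attribute; schema violations (negative counts, out-of-range scores) are
#' errors.
#'
#' @param path File path of a comma-separated, UTF-8, headered CSV.
#' @param spec A [cohort_spec()] declaring levels and references.
#' @param cohort A validated cohort tibble.
#'
#' @return `read_cohort()` returns a validated cohort tibble;
#'   `write_cohort()` invisibly returns `path`.
#' @export
read_cohort <- function(path, spec = cohort_spec()) {
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(
      sex = readr::col_character(),
      age_cat = readr::col_character(),
      bmi_cat = readr::col_character(),
      asa = readr::col_integer(),
      mallampati = readr::col_integer(),
      smoking = readr::col_character(),
      emergency = readr::col_logical(),
      in_hospital = readr::col_logical(),
      duration_min = readr::col_double(),
      drugs = readr::col_character(),
      ae_count = readr::col_integer(),
      ae_types = readr::col_character(),
      .default = readr::col_guess()
    ),
    comment = "#",
    progress = FALSE,
    show_col_types = FALSE
  )
  validate_cohort(raw, spec)
}

#' @rdname read_cohort
#' @export
write_cohort <- function(cohort, path) {
  out <- cohort[, intersect(cohort_columns(), names(cohort)), drop = FALSE]
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Summarise an adverse-event count distribution
#'
#' Computes the sample mean, the sample variance (denominator `n`, the
#' population form; at registry scale it is indistinguishable from the `n - 1`
#' form), and a frequency table with percentages rounded to two decimals.
#'
#' @param counts A non-empty vector of non-negative integer counts.
#'
#' @return A list of class `"count_summary"` with elements `n`, `mean`,
#'   `variance`, and `freq` (a tibble with columns `count`, `n`, `pct`).
#' @examples
#' summarize_counts(rep(0:3, c(22489, 722, 73, 5)))
#' @export
summarize_counts <- function(counts) {
  if (length(counts) == 0) stop("counts must be non-empty", call. = FALSE)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  n <- length(counts)
  m <- sum(counts) / n
  v <- sum((counts - m)^2) / n
  tab <- table(factor(counts, levels = 0:max(counts)))
  pcts <- round(100 * as.integer(tab) / n, 2)
  freq <- tibble::tibble(
    count = as.integer(names(tab)),
    n = as.integer(tab),
    pct = pcts
  )
  structure(list(n = n, mean = m, variance = v, freq = freq),
            class = "count_summary")
}

#' @export
print.count_summary <- function(x, ...) {
  cat(sprintf("Count summary: n = %d, mean = %.3f, variance = %.3f\n",
              x$n, x$mean, x$variance))
  print(x$freq)
  invisible(x)
}

#' Tabulate adverse events by category
#'
#' Counts, over all procedures in the cohort, how many recorded at least one
#' adverse event of any kind ("any") and how many recorded each AE category
#' at least once. Percentages are over the number of procedures, rounded to
#' two decimals.
#'
#' @param cohort A validated cohort tibble.
#'
#' @return A tibble with columns `event`, `n`, `pct`.
#' @export
tabulate_events <- function(cohort) {
  n_records <- nrow(cohort)
  types <- split_tokens(cohort$ae_types)
  rows <- lapply(ae_types(), function(tp) {
    k <- sum(vapply(types, function(t) tp %in% t, logical(1)))
    tibble::tibble(event = tp, n = k, pct = round(100 * k / n_records, 2))
  })
  k_any <- sum(cohort$ae_count >= 1)
  any_row <- tibble::tibble(
    event = "any", n = k_any, pct = round(100 * k_any / n_records, 2))
  dplyr::bind_rows(any_row, rows)
}
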