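# Shared fixtures, built in code.

# Minimal hand-written cohort rows used by the I/O and validation tests.
tiny_cohort <- function() {
  tibble::tibble(
    sex = c("male", "female", "female"),
    age_cat = c("<66", "67-75", ">=75"),
    bmi_cat = c("<21", "21-24", ">=27"),
    asa = c(1L, 2L, 3L),
    mallampati = c(1L, 2L, 1L),
    smoking = c("non", "current", "previous"),
    emergency = c(FALSE, TRUE, FALSE),
    in_hospital = c(TRUE, TRUE, FALSE),
    duration_min = c(30, 45.5, 60),
    drugs = c("propofol", "propofol;midazolam", "sevoflurane;curare"),
    ae_count = c(0L, 2L, 0L),
    ae_types = c("", "cardiovascular;respiratory", "")
  )
}

# Pooled AE count distribution from the published per-stratum frequency table
# (propofol alone: 19262/519/14/0; propofol + midazolam/fentanyl: 3227/203/59/5).
printed_pooled_counts <- function() {
  rep(0:3, c(19262 + 3227, 519 + 203, 14 + 59, 0 + 5))
}

printed_alone_counts <- function() rep(0:3, c(19262, 519, 14, 0))
printed_multi_counts <- function() rep(0:3, c(3227, 203, 59, 5))

# Cohort of 23,788 records whose any-AE and per-type tallies equal the
# published headline counts (1,797 with >= 1 AE; 776 cardiovascular, 660
# respiratory, 22 hemorrhagic, 95 other, 244 suspensions; one type each).
printed_event_cohort <- function() {
  n <- 23788
  type_counts <- c(cardiovascular = 776, respiratory = 660,
                   hemorrhagic = 22, other = 95, stopped = 244)
  types <- rep(names(type_counts), type_counts)
  cohort <- tibble::tibble(
    sex = rep("male", n), age_cat = "<66", bmi_cat = "<21",
    asa = 1L, mallampati = 1L, smoking = "non",
    emergency = FALSE, in_hospital = FALSE, duration_min = 40,
    drugs = "propofol", ae_count = 0L, ae_types = ""
  )
  idx <- seq_along(types)
  cohort$ae_count[idx] <- 1L
  cohort$ae_types[idx] <- types
  cohort
}

# Random valid mixture parameters for property-style checks.
random_zipmix_params <- function() {
  K <- sample(2:4, 1)
  pi <- stats::runif(K, 0.1, 1)
  pi <- pi / sum(pi)
  lambda <- stats::runif(K - 1, 0.2, 5)
  list(pi = pi, lambda = lambda)
}
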