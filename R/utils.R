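# row-wise log-sum-exp of a matrix of log terms; -Inf rows allowed
row_logsumexp <- function(lx) {
  m <- apply(lx, 1, max)
  m[!is.finite(m)] <- 0
  m + log(rowSums(exp(lx - m)))
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
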