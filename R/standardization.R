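#' Indirectly standardized expected counts
#'
#' Allocates expected case counts to each region in proportion to its
#' population times a pooled incidence rate: `E_ij = n_ij * (sum_i Y_ij /
#' sum_i n_ij)` within each year (`per_year`, the default), or with a single
#' rate pooled over the whole study period (`overall`). Per-year expecteds
#' are calibrated so each year's expected total equals its observed total,
#' which is the calibration the space-time scan statistic assumes
#' (`E[C] = C`).
#'
#' @param panel a [count_panel].
#' @param stratification `"per_year"` or `"overall"`.
#' @return An object of class `expected_matrix`: list with `expected`
#'   (regions x years matrix) and `stratification`.
#' @export
expected_counts <- function(panel, stratification = c("per_year", "overall")) {
  stratification <- match.arg(stratification)
  Y <- panel$observed
  n <- panel$population
  if (stratification == "per_year") {
    rate <- colSums(Y) / colSums(n)
    if (any(colSums(Y) == 0))
      warning("year(s) with zero total cases: expected counts are 0 there")
    E <- sweep(n, 2, rate, `*`)
  } else {
    rate <- sum(Y) / sum(n)
    if (sum(Y) == 0)
      warning("panel has zero total cases: expected counts are all 0")
    E <- n * rate
  }
  dimnames(E) <- dimnames(Y)
  structure(list(expected = E, stratification = stratification),
            class = "expected_matrix")
}

#' Crude standardized incidence ratios
#'
#' `SIR_ij = Y_ij / E_ij`. An SIR above 1 means the region-year saw more
#' cases than expected under the pooled rate. Cells with `E = 0` and `Y > 0`
#' are undefined and returned as `NA` (flagged in the `undefined` attribute),
#' never as infinity; cells with `E = 0` and `Y = 0` are also `NA`.
#'
#' @param panel a [count_panel].
#' @param expected an [expected_counts] result of matching shape.
#' @return Matrix (regions x years) of class `sir_matrix`.
#' @export
crude_sir <- function(panel, expected) {
  E <- expected$expected
  Y <- panel$observed
  if (!all(dim(E) == dim(Y)))
    stop("expected matrix shape does not match the panel")
  sir <- Y / E
  undef <- E == 0
  sir[undef] <- NA_real_
  structure(sir, class = c("sir_matrix", "matrix"),
            undefined = which(undef & Y > 0))
}

#' Long-format SIR table
#'
#' One row per region-year with observed, expected and crude SIR, in
#' canonical region order; the presentation the incidence maps are drawn
#' from.
#'
#' @param panel a [count_panel].
#' @param expected an [expected_counts] result.
#' @param digits round SIR to this many decimals in the table (`NULL` to
#'   keep full precision); the default 2 matches conventional reporting.
#' @return data.frame with columns region, year, observed, expected, sir.
#' @export
sir_table <- function(panel, expected, digits = 2) {
  sir <- crude_sir(panel, expected)
  df <- data.frame(
    region = rep(panel$region_ids, times = length(panel$years)),
    year = rep(panel$years, each = length(panel$region_ids)),
    observed = as.integer(panel$observed),
    expected = as.vector(expected$expected),
    sir = as.vector(unclass(sir)))
  if (!is.null(digits)) df$sir <- round(df$sir, digits)
  df[order(match(df$region, panel$region_ids), df$year), , drop = FALSE]
}
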