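#' Log odds ratio from a 2x2 outcome table
#'
#' Computes the log odds ratio `ln(ad/bc)`, its Woolf (Wald) standard error
#' `sqrt(1/a + 1/b + 1/c + 1/d)` and a normal-theory confidence interval from
#' a 2x2 table of severe/non-severe outcomes in an exposed (comorbidity) and
#' a comparator (monoinfection) arm. All arguments are vectorized.
#'
#' With `correction = "haldane"` the Haldane-Anscombe continuity correction
#' adds 0.5 to all four cells of a table, but only for tables containing at
#' least one zero cell; tables without zeros are left untouched. With
#' `correction = "none"` a zero cell is an error.
#'
#' @param a,b events and non-events in the exposed (comorbidity) group.
#' @param c,d events and non-events in the comparator (monoinfection) group.
#' @param correction `"haldane"` (default) or `"none"`.
#' @param level confidence level for the Wald interval.
#' @return A list with vectors `y`, `sigma`, `ci_low`, `ci_high`.
#' @examples
#' log_odds_ratio(20, 80, 10, 90, correction = "none")  # y = log(2.25)
#' @export
log_odds_ratio <- function(a, b, c, d, correction = c("haldane", "none"),
                           level = 0.95) {
  correction <- match.arg(correction)
  cells <- cbind(a = a, b = b, c = c, d = d)
  if (any(!is.finite(cells)) || any(cells < 0) || any(cells != round(cells)))
    stop("all four counts must be non-negative integers", call. = FALSE)
  if (any(a + b < 1) || any(c + d < 1))
    stop("each arm needs at least one subject", call. = FALSE)
  zero <- rowSums(cells == 0) > 0
  if (correction == "none" && any(zero)) {
    i <- which(zero)[1]
    cell <- c("a", "b", "c", "d")[which(cells[i, ] == 0)[1]]
    stop(sprintf("zero cell '%s' in table %d; use correction = \"haldane\"",
                 cell, i), call. = FALSE)
  }
  adj <- ifelse(zero, 0.5, 0)
  aa <- a + adj; bb <- b + adj; cc <- c + adj; dd <- d + adj
  y <- log(aa) - log(bb) - log(cc) + log(dd)
  sigma <- sqrt(1 / aa + 1 / bb + 1 / cc + 1 / dd)
  z <- qnorm(1 - (1 - level) / 2)
  list(y = y, sigma = sigma, ci_low = y - z * sigma, ci_high = y + z * sigma)
}
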