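## Exact test on a 2x2 contingency table.
##
## The two-sided p-value follows the point-probability rule: with all
## margins fixed, every table in the hypergeometric support whose
## probability does not exceed that of the observed table (up to a 1e-7
## relative tolerance guarding against floating-point ties) contributes to
## p. This is the convention of mainstream exact-test implementations. The
## odds ratio reported is the sample cross-product ratio, not the
## conditional MLE.

#' Build a 2x2 burden contingency table
#'
#' Cell layout: `a` = cohort carriers (or alternate alleles), `b` = cohort
#' non-carriers (or reference alleles), `c` = reference-population carriers,
#' `d` = reference-population non-carriers.
#'
#' @param a,b,c,d Non-negative integer cell counts.
#' @param unit `"individuals"` or `"alleles"`.
#' @return A `burden_table` list.
#' @export
burden_table <- function(a, b, c, d, unit = c("individuals", "alleles")) {
  unit <- match.arg(unit)
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0) || any(cells != round(cells)))
    stop("table cells must be non-negative integers")
  if (a + b == 0 || c + d == 0)
    stop("degenerate table: each row margin must be positive")
  structure(list(a = a, b = b, c = c, d = d, unit = unit),
            class = "burden_table")
}

#' Two-sided Fisher's exact test
#'
#' @param table A [burden_table()].
#' @return An `exact_test` list: `p_two_sided`, `odds_ratio`, `table`.
#' @export
fisher_exact_two_sided <- function(table) {
  stopifnot(inherits(table, "burden_table"))
  a <- table$a; b <- table$b; c <- table$c; d <- table$d
  m <- a + b           # row-1 margin
  n <- c + d           # row-2 margin
  k <- a + c           # column-1 margin
  support <- max(0L, k - n):min(m, k)
  logp <- stats::dhyper(support, m, n, k, log = TRUE)
  logp_obs <- stats::dhyper(a, m, n, k, log = TRUE)
  keep <- logp <= logp_obs + log1p(1e-7)
  p <- min(1, sum(exp(logp[keep])))
  or <- if (b * c == 0) {
    if (a * d == 0) NaN else Inf
  } else (a * d) / (b * c)
  structure(list(p_two_sided = p, odds_ratio = or, table = table),
            class = "exact_test")
}

#' @export
print.exact_test <- function(x, digits = 4, ...) {
  t <- x$table
  cat(sprintf("2x2 exact test (%s): [%d %d; %d %d]\n", t$unit,
              t$a, t$b, t$c, t$d))
  cat(sprintf("  p (two-sided) = %.*g, odds ratio = %.*g\n",
              digits, x$p_two_sided, digits, x$odds_ratio))
  invisible(x)
}
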