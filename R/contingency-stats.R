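#' 2x2 contingency table
#'
#' Cells are row-major: `a`, `b` form the row of interest (event /
#' non-event), `c`, `d` the reference row. Real-valued cells are permitted —
#' the EMR screen's assumed-1000-participant rule rescales observed counts
#' to non-integer effective counts — but the Fisher exact test rejects them.
#'
#' @param a,b,c,d Nonnegative cell values.
#' @return Numeric vector of class `contingency` with names a, b, c, d.
#' @export
contingency <- function(a, b, c, d) {
  x <- c(a = a, b = b, c = c, d = d)
  if (anyNA(x) || any(x < 0)) stop("all cells must be nonnegative")
  if (sum(x) <= 0) stop("table total must be positive")
  structure(x, class = "contingency")
}

as_cells <- function(table) {
  if (inherits(table, "contingency")) return(unclass(table))
  x <- as.numeric(table) # accepts a 2x2 matrix (column-major: a, c, b, d)
  if (length(x) != 4L) stop("need four cells")
  if (is.matrix(table)) x <- c(table[1, 1], table[1, 2], table[2, 1], table[2, 2])
  names(x) <- c("a", "b", "c", "d")
  if (anyNA(x) || any(x < 0)) stop("all cells must be nonnegative")
  if (sum(x) <= 0) stop("table total must be positive")
  x
}

#' Chi-squared test on a 2x2 table
#'
#' Shortcut form of the Pearson statistic with optional Yates continuity
#' correction:
#' \deqn{X^2 = \frac{n(\max(|ad-bc| - n/2, 0))^2}{(a+b)(c+d)(a+c)(b+d)}}
#' with the `n/2` term dropped when `correct = FALSE`. The Yates clamp makes
#' the corrected statistic exactly 0 (p = 1) whenever `|ad-bc| <= n/2`,
#' which matters for tiny cohorts. P-value is the upper tail of the
#' chi-square distribution with 1 degree of freedom. Real-valued cells are
#' accepted; a reported p-value is never exactly 0 (underflow is floored at
#' the smallest positive double).
#'
#' @param table A `contingency`, 2x2 matrix, or numeric vector (a, b, c, d).
#' @param correct Apply the Yates continuity correction (default `TRUE`).
#' @return List with `statistic`, `p.value`, `method` (`"chi2_yates"` or
#'   `"chi2"`).
#' @examples
#' chi_squared(contingency(1, 1487, 10, 990))   # p ~ 1.75e-3
#' @export
chi_squared <- function(table, correct = TRUE) {
  x <- as_cells(table)
  a <- x[["a"]]; b <- x[["b"]]; cc <- x[["c"]]; d <- x[["d"]]
  n <- a + b + cc + d
  margins <- c(a + b, cc + d, a + cc, b + d)
  if (any(margins == 0)) stop("degenerate margin")
  num <- abs(a * d - b * cc)
  if (correct) num <- max(num - n / 2, 0)
  stat <- n * num^2 / prod(margins)
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
  if (p <= 0) {
    p <- .Machine$double.xmin
    message("chi_squared: p-value underflow, floored at double.xmin")
  }
  list(statistic = unname(stat), p.value = unname(p),
       method = if (correct) "chi2_yates" else "chi2")
}

#' Fisher exact test on a 2x2 table
#'
#' Conditional on the observed margins, the first cell follows a
#' hypergeometric distribution. The two-sided p-value sums the
#' probabilities of all tables with the same margins whose probability does
#' not exceed that of the observed table (the convention of
#' [stats::fisher.test()]); `"greater"`/`"less"` give the one-sided tails,
#' with `"greater"` testing overrepresentation of the event in the row of
#' interest. Cells must be integer-valued.
#'
#' @param table A `contingency`, 2x2 matrix, or numeric vector (a, b, c, d).
#' @param alternative One of `"two.sided"`, `"greater"`, `"less"`.
#' @return List with `statistic` (`NA`, kept for interface symmetry),
#'   `p.value`, `method = "fisher"`.
#' @examples
#' fisher_exact(c(0, 2, 2, 0))$p.value  # 1/3
#' @export
fisher_exact <- function(table, alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  x <- as_cells(table)
  if (any(abs(x - round(x)) > 1e-8)) stop("exact test requires integer counts")
  x <- round(x)
  a <- x[["a"]]; r1 <- x[["a"]] + x[["b"]]; r2 <- x[["c"]] + x[["d"]]
  c1 <- x[["a"]] + x[["c"]]
  lo <- max(0, c1 - r2)
  hi <- min(c1, r1)
  support <- lo:hi
  dens <- stats::dhyper(support, r1, r2, c1)
  obs <- dens[a - lo + 1L]
  p <- switch(alternative,
    two.sided = sum(dens[dens <= obs * (1 + 1e-7)]),
    greater   = sum(dens[support >= a]),
    less      = sum(dens[support <= a])
  )
  list(statistic = NA_real_, p.value = min(p, 1), method = "fisher")
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up procedure (via [stats::p.adjust()]): in sorted order,
#' `q(i) = min_{j >= i} p(j) * m / j`, clamped at 1, returned in the input
#' order. Always `q >= p` elementwise.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Numeric vector of q-values, same order as the input.
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0L) stop("empty p-value vector")
  if (anyNA(p) || any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}
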