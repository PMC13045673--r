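#' Round half-up
#'
#' Rounds to `digits` decimal places with ties going away from zero (the
#' convention used when presenting clinical percentages), unlike base
#' [round()], which rounds half to even. A tiny relative fudge guards
#' against binary representation of exact halves.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Numeric vector rounded half-up.
#' @export
#' @examples
#' round_half_up(12.45, 1) # 12.5
round_half_up <- function(x, digits = 1) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5 + 1e-9) / scale
}

#' Percentage with reporting rounding
#'
#' `100 * numerator / denominator`, rounded half-up to one decimal place,
#' the convention used throughout the package's report tables.
#'
#' @param numerator Non-negative count.
#' @param denominator Positive count.
#' @return Percentage rounded to one decimal.
#' @export
#' @examples
#' percent(50, 174) # 28.7
percent <- function(numerator, denominator) {
  stopifnot(is.numeric(numerator), is.numeric(denominator))
  if (any(denominator <= 0)) {
    stop("percent(): denominator must be positive", call. = FALSE)
  }
  if (any(numerator < 0)) {
    stop("percent(): numerator must be non-negative", call. = FALSE)
  }
  round_half_up(100 * numerator / denominator, 1)
}

#' Median and interquartile range
#'
#' Median, first and third quartile by linear interpolation between order
#' statistics (quantile positions `p * (n - 1) + 1`, [stats::quantile()]
#' type 7).
#'
#' @param values Numeric vector; missing values are dropped.
#' @return Named numeric vector `c(median, q1, q3)`.
#' @export
#' @examples
#' median_iqr(c(1, 2, 3, 4)) # 2.5, 1.75, 3.25
median_iqr <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0) {
    stop("median_iqr(): no non-missing values", call. = FALSE)
  }
  q <- stats::quantile(values, probs = c(0.5, 0.25, 0.75), type = 7, names = FALSE)
  c(median = q[1], q1 = q[2], q3 = q[3])
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Computes the two-sided p-value by full enumeration of the
#' hypergeometric distribution over the feasible range of the top-left
#' cell, summing the probabilities of all tables with the observed margins
#' whose probability does not exceed that of the observed table (with
#' relative tolerance 1e-7, the probability-mass convention of mainstream
#' statistical software). Probabilities are accumulated on the log scale
#' so registry-scale counts do not overflow.
#'
#' @param a,b,c,d Non-negative cell counts: rows are treatment strata,
#'   columns criteria met / not met. Alternatively `a` may be a 2x2 matrix
#'   (row-wise `a, b; c, d`) with `b`, `c`, `d` missing.
#' @return An object of class `crs_fisher`: list with `p_two_sided` and
#'   `odds_ratio` (unconditional `a*d / (b*c)`, `NA` if undefined).
#' @export
#' @examples
#' fisher_exact_2x2(3, 1, 1, 3)$p_two_sided # 34/70
fisher_exact_2x2 <- function(a, b, c, d) {
  if (is.matrix(a)) {
    stopifnot(missing(b), all(dim(a) == 2))
    d <- a[2, 2]; c <- a[2, 1]; b <- a[1, 2]; a <- a[1, 1]
  }
  cells <- c(a, b, c, d)
  if (any(is.na(cells)) || any(cells < 0)) {
    stop("fisher_exact_2x2(): cells must be non-negative counts", call. = FALSE)
  }
  if (any(cells != round(cells))) {
    stop("fisher_exact_2x2(): cells must be integers", call. = FALSE)
  }
  if (sum(cells) == 0) {
    stop("fisher_exact_2x2(): at least one margin must be positive", call. = FALSE)
  }
  m <- a + b          # row 1 total
  n2 <- c + d         # row 2 total
  k <- a + c          # column 1 total
  N <- m + n2
  support <- max(0, k - n2):min(k, m)
  logp <- lchoose(m, support) + lchoose(n2, k - support) - lchoose(N, k)
  p_obs <- logp[support == a]
  p <- sum(exp(logp)[logp <= p_obs + log1p(1e-7)])
  or <- if (b * c == 0) NA_real_ else (a * d) / (b * c)
  structure(
    list(p_two_sided = min(p, 1), odds_ratio = or,
         table = matrix(cells, 2, byrow = TRUE)),
    class = "crs_fisher"
  )
}

#' @export
print.crs_fisher <- function(x, ...) {
  cat("Fisher's exact test (two-sided, full enumeration)\n")
  cat(sprintf("  p = %.4g", x$p_two_sided))
  if (!is.na(x$odds_ratio)) cat(sprintf(", odds ratio = %.3g", x$odds_ratio))
  cat("\n")
  invisible(x)
}
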