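# Three-valued (strong Kleene) logic over possibly-missing clinical data.
#
# A TriState is represented as an R logical: TRUE, FALSE, or NA for
# UNKNOWN. Under the partial-information order UNKNOWN is below both
# TRUE and FALSE; all connectives here are monotone in that order, which
# is what makes "filling in a missing field never flips a determinate
# verdict" a theorem rather than a hope.

#' Kleene conjunction
#'
#' Strong-Kleene AND: FALSE if either operand is FALSE (FALSE absorbs
#' through UNKNOWN), TRUE if both are TRUE, UNKNOWN otherwise.
#'
#' @param a,b Logical vectors; `NA` means UNKNOWN.
#' @return Logical vector of the same length.
#' @export
#' @examples
#' kleene_and(FALSE, NA) # FALSE
#' kleene_and(TRUE, NA)  # NA (unknown)
kleene_and <- function(a, b) a & b

#' Kleene disjunction
#'
#' Strong-Kleene OR: TRUE if either operand is TRUE (TRUE absorbs through
#' UNKNOWN), FALSE if both are FALSE, UNKNOWN otherwise.
#'
#' @inheritParams kleene_and
#' @return Logical vector of the same length.
#' @export
kleene_or <- function(a, b) a | b

#' Threshold criterion on a possibly-missing measurement
#'
#' All leaf criteria in the bundled rule sets are at-least comparisons;
#' a missing measurement yields UNKNOWN, never FALSE.
#'
#' @param value Numeric vector, possibly `NA`.
#' @param cutoff Finite numeric scalar.
#' @return Logical vector: `NA` where `value` is missing, else
#'   `value >= cutoff`.
#' @export
#' @examples
#' threshold_test(37, 35) # TRUE
#' threshold_test(NA, 35) # NA
threshold_test <- function(value, cutoff) {
  stopifnot(is.numeric(cutoff), length(cutoff) == 1, is.finite(cutoff))
  value >= cutoff
}

#' At-least-k-of-n over three-valued criteria
#'
#' TRUE when the known TRUEs already reach `k`; FALSE when even counting
#' every UNKNOWN as TRUE cannot reach `k`; UNKNOWN otherwise. This is
#' exactly the three-way summary of evaluating every completion of the
#' UNKNOWNs: TRUE iff all completions reach `k`, FALSE iff none does.
#'
#' @param states Logical vector of component verdicts (`NA` = UNKNOWN).
#' @param k Positive integer, `1 <= k <= length(states)`.
#' @return Single logical value.
#' @export
#' @examples
#' at_least_k(c(TRUE, TRUE, TRUE, NA, NA), 3)    # TRUE
#' at_least_k(c(TRUE, NA, NA, FALSE, FALSE), 3)  # NA
at_least_k <- function(states, k) {
  stopifnot(is.logical(states))
  if (!is.numeric(k) || length(k) != 1 || k != round(k) ||
      k < 1 || k > length(states)) {
    stop("at_least_k(): k must be an integer in [1, length(states)]",
         call. = FALSE)
  }
  n_true <- sum(states, na.rm = TRUE)
  n_unknown <- sum(is.na(states))
  if (n_true >= k) TRUE else if (n_true + n_unknown < k) FALSE else NA
}

# Vectorised at-least-k over a row-per-patient logical matrix.
at_least_k_rows <- function(m, k) {
  stopifnot(k >= 1, k <= ncol(m))
  n_true <- rowSums(m, na.rm = TRUE)
  n_unknown <- rowSums(is.na(m))
  out <- rep(NA, nrow(m))
  out[n_true >= k] <- TRUE
  out[n_true + n_unknown < k] <- FALSE
  out
}

#' Type-2 inflammation criterion
#'
#' Evidence of type-2 inflammation: blood eosinophil count at or above
#' the eosinophil cutoff and/or serum total IgE at or above the IgE
#' cutoff, combined with Kleene disjunction so one sufficient marker
#' decides even when the other is missing.
#'
#' @param bec Blood eosinophil count in cells/uL, possibly `NA`.
#' @param ige Serum total IgE in IU/mL, possibly `NA`.
#' @param bec_min,ige_min Cutoffs (defaults 150 cells/uL, 100 IU/mL).
#' @return Logical vector (`NA` = UNKNOWN).
#' @export
#' @examples
#' eval_type2(200, NA) # TRUE
#' eval_type2(100, NA) # NA
eval_type2 <- function(bec, ige, bec_min = 150, ige_min = 100) {
  kleene_or(threshold_test(bec, bec_min), threshold_test(ige, ige_min))
}

# Human-readable label for a TriState scalar/vector.
tri_label <- function(x) {
  ifelse(is.na(x), "unknown", ifelse(x, "true", "false"))
}
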