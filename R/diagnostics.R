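#' Frobenius asymmetry of a confusion matrix
#'
#' `Asy(M) = ||M - t(M)||_F = sqrt(sum_{i,j} (M_ij - M_ji)^2)`, the sum
#' running over all ordered index pairs, so each unordered pair contributes
#' twice.  Zero exactly for symmetric matrices; scales linearly with a
#' positive scaling of the matrix (unlike the metrics, which are scale
#' invariant).
#'
#' @param cm numeric square matrix.
#' @return a non-negative number, in the units of the counts.
#' @examples
#' asymmetry(matrix(c(1, 2, 2, 1), 2))       # 0
#' asymmetry(matrix(c(1, 5, 1, 1), 2, byrow = TRUE))  # sqrt(2) * 4
#' @export
asymmetry <- function(cm) {
  if (!is.matrix(cm) || nrow(cm) != ncol(cm))
    stop("asymmetry requires a square matrix")
  sqrt(sum((cm - t(cm))^2))
}

#' Shannon entropy of the off-diagonal cells (base 2)
#'
#' Collects the `N^2 - N` off-diagonal entries, normalizes them by their
#' sum, and returns the base-2 Shannon entropy `-sum p_i log2 p_i` with the
#' usual convention `0 * log 0 = 0` (needed when some misclassification
#' cells are exactly zero).  Measures how evenly the misclassifications are
#' spread: the maximum `log2(N^2 - N)` is attained at uniform off-diagonal
#' mass, and a decrease of this entropy to zero along a family of matrices
#' is the regime in which Kappa and MCC move in opposite directions.
#'
#' Invariant under positive scaling.  If every off-diagonal entry is zero
#' there is no misclassification and hence no uncertainty: the value is `0`,
#' with a warning rather than an error.
#'
#' @param cm numeric square matrix with non-negative entries.
#' @return entropy in bits, in `[0, log2(N^2 - N)]`.
#' @examples
#' offdiag_entropy(matrix(c(1, 3, 3, 1), 2))  # 1 bit: uniform over 2 cells
#' @export
offdiag_entropy <- function(cm) {
  if (!is.matrix(cm) || nrow(cm) != ncol(cm))
    stop("off-diagonal entropy requires a square matrix")
  if (any(cm < 0)) stop("entries must be non-negative")
  off <- cm[row(cm) != col(cm)]
  n <- sum(off)
  if (n == 0) {
    warning("all off-diagonal entries are zero: no misclassification, ",
            "entropy is 0")
    return(0)
  }
  p <- off / n
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Structural diagnostics for one confusion matrix
#'
#' @inheritParams asymmetry
#' @return a one-row `data.frame` with columns `asy` (Frobenius asymmetry)
#'   and `ent` (off-diagonal entropy, bits).
#' @export
diagnostic_report <- function(cm) {
  data.frame(asy = asymmetry(cm), ent = offdiag_entropy(cm))
}
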