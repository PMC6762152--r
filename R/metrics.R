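#' Accuracy of a confusion matrix
#'
#' Fraction of correctly classified cases: the trace of the matrix divided
#' by its total.  Invariant under positive scaling of the matrix.
#'
#' @param cm numeric square confusion matrix (rows = actual,
#'   columns = predicted).
#' @return a number in `[0, 1]`.
#' @examples
#' accuracy(matrix(c(3, 0, 0, 3), 2))  # 1
#' @export
accuracy <- function(cm) {
  validate_confusion(cm, require_margins = FALSE)
  sum(diag(cm)) / sum(cm)
}

#' Chance agreement of a confusion matrix
#'
#' The hypothetical probability that actual and predicted class coincide if
#' both were drawn independently from the matrix's marginal distributions:
#' `Pe = sum_i row_i * col_i / S^2`.  This is the quantity Kappa corrects
#' Accuracy by.
#'
#' @inheritParams accuracy
#' @return a number in `(0, 1]`.
#' @export
chance_agreement <- function(cm) {
  validate_confusion(cm, require_margins = FALSE)
  S <- sum(cm)
  sum(rowSums(cm) * colSums(cm)) / S^2
}

#' Cohen's Kappa
#'
#' Chance-corrected agreement `K = (Acc - Pe) / (1 - Pe)`.  Symmetric in the
#' sense `K(t(cm)) = K(cm)` and invariant under positive scaling.  Requires
#' all marginal sums positive and `Pe < 1`: a matrix with all mass in one
#' diagonal cell has `Acc = 1` but also `Pe = 1`, and Kappa is undefined
#' there (0/0), so that case errors rather than returning `NaN`.
#'
#' @inheritParams accuracy
#' @return a real number; `1` for perfect classification.
#' @examples
#' cohen_kappa(matrix(c(40, 10, 5, 45), 2, byrow = TRUE))
#' @export
cohen_kappa <- function(cm) {
  validate_confusion(cm)
  pe <- chance_agreement(cm)
  if (pe >= 1 - 1e-15)
    stop("kappa undefined, Pe=1 (chance agreement is certain)")
  (accuracy(cm) - pe) / (1 - pe)
}

#' Multi-class Matthews Correlation Coefficient (closed form)
#'
#' The generalized correlation between actual and predicted classes.  The
#' numerator is computed as `S * trace(C) - sum_k row_k * col_k` and the
#' denominator as `sqrt(S^2 - sum_k row_k^2) * sqrt(S^2 - sum_k col_k^2)`,
#' an `O(N^2)` simplification of the triple-sum form that is algebraically
#' identical to it.  For `N = 2` this reduces to the familiar
#' `(ad - bc) / sqrt((a+b)(b+d)(a+c)(c+d))`.
#'
#' Both denominator factors must be strictly positive: no row or column sum
#' may equal `0` or the grand total `S` (the binary assumptions
#' `a+b, c+d, a+c, b+d > 0`, generalized).
#'
#' @inheritParams accuracy
#' @return a number in `[-1, 1]`.
#' @seealso [mcc_indicator_oracle()] for the definition-level computation.
#' @examples
#' mcc_multiclass(matrix(c(2, 1, 1, 2), 2, byrow = TRUE))  # 1/3
#' @export
mcc_multiclass <- function(cm) {
  validate_confusion(cm)
  S <- sum(cm)
  rs <- rowSums(cm)
  cs <- colSums(cm)
  den_r <- S^2 - sum(rs^2)
  den_c <- S^2 - sum(cs^2)
  if (den_r <= 0 || den_c <= 0)
    stop("MCC undefined (degenerate marginals): ",
         "a row or column holds all the mass")
  (S * sum(diag(cm)) - sum(rs * cs)) / (sqrt(den_r) * sqrt(den_c))
}

#' MCC via indicator-matrix correlation (independent oracle)
#'
#' Expands an integer confusion matrix into its case-level indicator
#' matrices `X` (actual) and `Y` (predicted), each `S x N` with one `1` per
#' row, and returns the averaged-covariance correlation
#' `rho~(X, Y) = Cov~(X, Y) / sqrt(Cov~(X, X) * Cov~(Y, Y))`, where
#' `Cov~` averages the `N` per-column covariances.  This is the
#' definition the closed form of [mcc_multiclass()] is derived from, so the
#' two must agree to floating-point tolerance; the oracle exists precisely
#' to test that, and deliberately shares no code with the closed form.
#'
#' @inheritParams accuracy
#' @param tol tolerance for deciding that entries are whole numbers.
#' @return a number in `[-1, 1]`.
#' @export
mcc_indicator_oracle <- function(cm, tol = 1e-9) {
  validate_confusion(cm)
  if (max(abs(cm - round(cm))) > tol)
    stop("indicator oracle requires integer counts ",
         "(case-level expansion); scale the matrix first")
  cm <- round(cm)
  n <- nrow(cm)
  S <- sum(cm)
  actual <- rep(rep(seq_len(n), times = n), times = as.vector(t(cm)))
  predicted <- rep(rep(seq_len(n), each = n), times = as.vector(t(cm)))
  X <- matrix(0, S, n)
  Y <- matrix(0, S, n)
  X[cbind(seq_len(S), actual)] <- 1
  Y[cbind(seq_len(S), predicted)] <- 1
  covk <- function(u, v) mean(u * v) - mean(u) * mean(v)
  cxy <- mean(vapply(seq_len(n), function(k) covk(X[, k], Y[, k]), 0))
  cxx <- mean(vapply(seq_len(n), function(k) covk(X[, k], X[, k]), 0))
  cyy <- mean(vapply(seq_len(n), function(k) covk(Y[, k], Y[, k]), 0))
  if (cxx <= 0 || cyy <= 0)
    stop("MCC undefined (degenerate marginals)")
  cxy / sqrt(cxx * cyy)
}

#' The binary one-sided agreement ratios alpha and beta
#'
#' For a 2x2 matrix `[[a, b], [c, d]]`,
#' `alpha = (ad - bc) / ((a+b)(b+d))` and
#' `beta  = (ad - bc) / ((a+c)(c+d))`.
#' Kappa is the harmonic mean of the two and `|MCC|` their geometric mean,
#' which is what forces `0 < K <= MCC` when `ad > bc` and
#' `MCC <= K < 0` when `ad < bc` (both are exactly `0` when `ad = bc`).
#'
#' @param cm a 2x2 confusion matrix with positive marginal sums.
#' @return named numeric vector `c(alpha = , beta = )`.
#' @export
alpha_beta <- function(cm) {
  validate_confusion(cm)
  if (nrow(cm) != 2L)
    stop("alpha/beta are defined for binary (2x2) matrices only")
  a <- cm[1, 1]; b <- cm[1, 2]; c <- cm[2, 1]; d <- cm[2, 2]
  det <- a * d - b * c
  c(alpha = det / ((a + b) * (b + d)),
    beta  = det / ((a + c) * (c + d)))
}

#' Full metric report for one confusion matrix
#'
#' One row with Accuracy, chance agreement, Kappa and MCC; for binary
#' matrices the `alpha`/`beta` decomposition is filled in as well (`NA`
#' otherwise).
#'
#' @inheritParams accuracy
#' @return a one-row `data.frame` with columns `acc`, `pe`, `kappa`, `mcc`,
#'   `alpha`, `beta`.
#' @seealso [diagnostic_report()] for the structural diagnostics,
#'   [audit_confusion()] for the combined report with warning flags.
#' @export
metric_report <- function(cm) {
  validate_confusion(cm)
  ab <- if (nrow(cm) == 2L) alpha_beta(cm) else c(alpha = NA_real_,
                                                  beta = NA_real_)
  data.frame(acc = accuracy(cm),
             pe = chance_agreement(cm),
             kappa = cohen_kappa(cm),
             mcc = mcc_multiclass(cm),
             alpha = unname(ab["alpha"]),
             beta = unname(ab["beta"]))
}
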