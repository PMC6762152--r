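#' Validate a square confusion matrix
#'
#' A confusion matrix here is a plain numeric `N x N` matrix (`N >= 2`) of
#' non-negative, possibly real-valued counts, with the fixed orientation
#' rows = actual class, columns = predicted class.  Real entries are allowed
#' because every statistic in this package is invariant under multiplication
#' of the whole matrix by a positive constant, so a matrix such as
#' `[[0.2, 5], [1, 0.2]]` is simply a convenient representative of its
#' equivalence class.
#'
#' @param cm numeric matrix to validate.
#' @param require_margins if `TRUE` (the default for metric evaluation),
#'   additionally require every row sum and every column sum to be strictly
#'   positive.
#' @return `cm`, invisibly, if valid; otherwise an error is thrown.
#' @examples
#' validate_confusion(matrix(c(3, 0, 0, 3), 2))
#' @export
validate_confusion <- function(cm, require_margins = TRUE) {
  if (!is.matrix(cm) || !is.numeric(cm))
    stop("confusion matrix must be a numeric matrix")
  if (nrow(cm) != ncol(cm))
    stop("confusion matrix must be square, got ", nrow(cm), "x", ncol(cm))
  if (nrow(cm) < 2L)
    stop("confusion matrix needs at least 2 classes")
  if (anyNA(cm))
    stop("confusion matrix contains missing values")
  if (any(cm < 0))
    stop("confusion matrix entries must be non-negative")
  if (sum(cm) <= 0)
    stop("empty matrix: total count must be positive")
  if (require_margins) {
    if (any(rowSums(cm) <= 0))
      stop("degenerate matrix: every row sum must be positive")
    if (any(colSums(cm) <= 0))
      stop("degenerate matrix: every column sum must be positive")
  }
  invisible(cm)
}

#' Read a confusion matrix from a headerless CSV grid
#'
#' The expected dialect is a plain numeric grid: comma-separated, period
#' decimal mark, no header, one matrix row per line.  With `header = TRUE`
#' a leading label row and label column are tolerated and dropped.
#'
#' @param path path to a CSV file.
#' @param header whether the file carries a label row and label column.
#' @return a validated numeric matrix.
#' @seealso [write_confusion()], [audit_confusion()]
#' @export
read_confusion <- function(path, header = FALSE) {
  df <- utils::read.csv(path, header = header, check.names = FALSE,
                        strip.white = TRUE)
  if (header) df <- df[, -1L, drop = FALSE]
  if (!all(vapply(df, is.numeric, logical(1))))
    stop("non-numeric cells in ", path, ": not a confusion matrix grid")
  cm <- as.matrix(df)
  dimnames(cm) <- NULL
  validate_confusion(cm, require_margins = FALSE)
  cm
}

#' Write a confusion matrix as a headerless CSV grid
#'
#' @param cm numeric confusion matrix.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_confusion <- function(cm, path) {
  validate_confusion(cm, require_margins = FALSE)
  utils::write.table(cm, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
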