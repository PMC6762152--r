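#' Recompute the study's numeric tables from scratch
#'
#' * `"table1"`: MCC, Kappa, asymmetry and off-diagonal entropy of `M2(A)`
#'   for `A = 10, 25, 50, 75, 100`, rounded to 4 decimals.
#' * `"table2"`: the same four statistics for `M4(A)`,
#'   `A = 50, 60, ..., 100`, rounded to 4 decimals.
#' * `"table3"`: the agreement/disagreement summary — each implemented
#'   family is swept over its default grid, classified with
#'   [classify_regime()], and reported with its entropy and asymmetry
#'   trends.
#'
#' Every cell is computed at call time from the family generators and the
#' metric/diagnostic functions; nothing is looked up.
#'
#' @param name `"table1"`, `"table2"` or `"table3"`.
#' @param file optional path; when given the table is also written as CSV.
#' @return a `data.frame` (statistics in rows and parameter values in
#'   columns for tables 1-2; one row per family for table 3).
#' @export
reproduce_table <- function(name = c("table1", "table2", "table3"),
                            file = NULL) {
  name <- match.arg(name)
  tab <- switch(name,
    table1 = .metric_table("M2", c(10, 25, 50, 75, 100)),
    table2 = .metric_table("M4", c(50, 60, 70, 80, 90, 100)),
    table3 = .regime_table())
  if (!is.null(file))
    utils::write.csv(tab, file, row.names = FALSE)
  tab
}

.metric_table <- function(family, As) {
  cols <- lapply(As, function(A) {
    cm <- make_example_family(family, A)
    round(c(mcc = mcc_multiclass(cm), kappa = cohen_kappa(cm),
            asy = asymmetry(cm), ent = offdiag_entropy(cm)), 4)
  })
  out <- data.frame(statistic = c("mcc", "kappa", "asy", "ent"),
                    do.call(cbind, cols))
  names(out)[-1] <- paste0("A", As)
  out
}

# The eight families of the summary table, with the fixed parameters used
# throughout the study (binary cases at a = d = 1, Z_A in dimension 3).
.summary_families <- function() {
  list(C0 = family_spec("C0", a = 1, d = 1),
       C1 = family_spec("C1", a = 1, d = 1),
       ZA = family_spec("ZA", N = 3),
       M1 = family_spec("M1"), M2 = family_spec("M2"),
       M3 = family_spec("M3"), M4 = family_spec("M4"),
       M5 = family_spec("M5"))
}

.regime_table <- function() {
  rows <- lapply(.summary_families(), function(sp) {
    rl <- classify_regime(sweep_family(sp))
    data.frame(family = sp$name, label = rl$label,
               entropy_trend = rl$entropy_trend,
               asymmetry_trend = rl$asymmetry_trend)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Audit a user-supplied confusion matrix
#'
#' Reads a confusion matrix (CSV grid or an in-memory matrix), computes the
#' full metric and diagnostic report, and raises an advisory flag when the
#' matrix sits in the regime where Kappa is untrustworthy: off-diagonal
#' entropy below `ent_frac` of its maximum `log2(N^2 - N)` while the
#' matrix is asymmetric.  In that regime the misclassification mass is
#' concentrated in few cells, which is exactly where Kappa can improve as
#' the classification worsens.  The flag never alters the metric values.
#'
#' @param x path to a CSV file, or a numeric square matrix.
#' @param ent_frac warning threshold as a fraction of the maximum
#'   off-diagonal entropy (default 0.25).
#' @param header passed to [read_confusion()] when `x` is a path.
#' @return an object of class `"audit_report"`: list with `matrix`,
#'   `report` (one-row data.frame merging metrics and diagnostics),
#'   `low_entropy_warning` (logical) and `ent_max` (the attainable
#'   maximum).
#' @examples
#' audit_confusion(make_example_family("M1", 10))$low_entropy_warning  # FALSE
#' @export
audit_confusion <- function(x, ent_frac = 0.25, header = FALSE) {
  cm <- if (is.character(x)) read_confusion(x, header = header) else x
  validate_confusion(cm)
  rep <- cbind(metric_report(cm), diagnostic_report(cm))
  ent_max <- log2(nrow(cm)^2 - nrow(cm))
  flag <- rep$ent < ent_frac * ent_max && rep$asy > 0
  structure(list(matrix = cm, report = rep,
                 low_entropy_warning = flag, ent_max = ent_max),
            class = "audit_report")
}

#' @export
print.audit_report <- function(x, digits = 4, ...) {
  cat("<audit_report> ", nrow(x$matrix), " classes, total ",
      format(sum(x$matrix)), "\n", sep = "")
  print(round(x$report, digits))
  if (x$low_entropy_warning)
    cat("WARNING: off-diagonal entropy ", signif(x$report$ent, 3),
        " is low (< 25% of max ", signif(x$ent_max, 3), ") and the ",
        "matrix is asymmetric;\n  Kappa is unreliable here - prefer ",
        "MCC.\n", sep = "")
  invisible(x)
}

#' Serialize an audit report as JSON
#'
#' @param x an [audit_confusion()] result.
#' @return a JSON string (single object, numbers unboxed).
#' @export
audit_json <- function(x) {
  stopifnot(inherits(x, "audit_report"))
  jsonlite::toJSON(c(as.list(x$report),
                     list(low_entropy_warning = x$low_entropy_warning)),
                   auto_unbox = TRUE, digits = NA, na = "null")
}
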