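#' CTCAE grade distribution percentages
#'
#' Recomputes per-grade percentages from a cohort count table: one row per
#' CTCAE grade (0-4), one column per phenotype, entries = number of
#' patients.  Percentages are per column, out of the column total.
#'
#' @param counts data.frame or matrix with a `grade` column/rownames and
#'   integer phenotype columns.
#' @return data.frame of percentages with the same shape (grade column
#'   retained), values in 0-100.
#' @export
grade_percentages <- function(counts) {
  counts <- as.data.frame(counts)
  gcol <- counts[["grade"]]
  num <- counts[, setdiff(names(counts), "grade"), drop = FALSE]
  tot <- colSums(num)
  if (any(tot == 0)) stop("phenotype column with zero total")
  pct <- sweep(num, 2L, tot / 100, `/`)
  cbind(data.frame(grade = gcol), pct)
}

#' Class sizes from a grade count table
#'
#' Collapses per-grade counts into low (grades 0-1), intermediate (2) and
#' high (3-4) class totals per phenotype column.
#'
#' @inheritParams grade_percentages
#' @return data.frame with rows low/intermediate/high.
#' @export
grade_class_sizes <- function(counts) {
  counts <- as.data.frame(counts)
  g <- counts[["grade"]]
  num <- counts[, setdiff(names(counts), "grade"), drop = FALSE]
  cls <- toxicity_class(g)
  out <- rowsum(num, cls)
  out <- out[c("low", "intermediate", "high"), , drop = FALSE]
  cbind(data.frame(class = rownames(out)), out, row.names = NULL)
}
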