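#' Genotype container
#'
#' Bundles a variant table with an additive-dosage matrix (variants x
#' samples; `NA` = missing genotype) and an optional per-genotype read-depth
#' matrix of the same shape.  Only bi-allelic variants are representable:
#' dosages count copies of the single alternate allele.
#'
#' @param variants data.frame with columns `variant_id`, `chrom`, `pos`
#'   (1-based), `ref`, `alt`, `filter`.
#' @param dosage integer matrix, one row per variant in `variants`, one
#'   column per sample; values in `{0, 1, 2, NA}`.
#' @param samples character vector of sample ids (column order of `dosage`).
#' @param depth optional numeric matrix of per-genotype read depths, same
#'   dimensions as `dosage`, or `NULL`.
#' @return An object of class `genotype_data`.
#' @export
genotype_data <- function(variants, dosage, samples, depth = NULL) {
  stopifnot(is.data.frame(variants),
            all(c("variant_id", "chrom", "pos", "ref", "alt") %in% names(variants)))
  if (!"filter" %in% names(variants)) variants$filter <- "PASS"
  dosage <- as.matrix(dosage)
  if (nrow(dosage) != nrow(variants))
    stop("dosage must have one row per variant")
  if (ncol(dosage) != length(samples))
    stop("dosage must have one column per sample")
  bad <- dosage[!is.na(dosage)]
  if (length(bad) && !all(bad %in% 0:2))
    stop("dosages must be 0, 1, 2 or NA")
  if (anyDuplicated(variants$variant_id))
    stop("duplicate variant_id")
  if (any(variants$pos < 1)) stop("pos must be >= 1")
  dimnames(dosage) <- list(variants$variant_id, samples)
  if (!is.null(depth)) {
    depth <- as.matrix(depth)
    stopifnot(all(dim(depth) == dim(dosage)))
    dimnames(depth) <- dimnames(dosage)
  }
  structure(list(variants = variants, dosage = dosage,
                 samples = as.character(samples), depth = depth),
            class = "genotype_data")
}

#' @export
print.genotype_data <- function(x, ...) {
  cat(sprintf("genotype_data: %d variants x %d samples (%s depth)\n",
              nrow(x$variants), length(x$samples),
              if (is.null(x$depth)) "no" else "with"))
  invisible(x)
}

#' @export
dim.genotype_data <- function(x) dim(x$dosage)

#' Subset a genotype container by variant and/or sample
#'
#' @param gd a `genotype_data` object
#' @param variants variant ids or logical/integer index over variants
#' @param samples sample ids or index over samples
#' @return a `genotype_data` restricted to the selection, order preserved
#'   as given.
#' @export
subset_genotypes <- function(gd, variants = NULL, samples = NULL) {
  stopifnot(inherits(gd, "genotype_data"))
  vi <- if (is.null(variants)) seq_len(nrow(gd$variants)) else {
    if (is.character(variants)) {
      miss <- setdiff(variants, gd$variants$variant_id)
      if (length(miss)) stop("unknown variant id(s): ", paste(head(miss, 5), collapse = ", "))
      match(variants, gd$variants$variant_id)
    } else variants
  }
  si <- if (is.null(samples)) seq_along(gd$samples) else {
    if (is.character(samples)) {
      miss <- setdiff(samples, gd$samples)
      if (length(miss)) stop("unknown sample id(s): ", paste(head(miss, 5), collapse = ", "))
      match(samples, gd$samples)
    } else samples
  }
  genotype_data(gd$variants[vi, , drop = FALSE],
                gd$dosage[vi, si, drop = FALSE],
                gd$samples[si],
                if (is.null(gd$depth)) NULL else gd$depth[vi, si, drop = FALSE])
}

#' Map CTCAE grades to toxicity classes
#'
#' Grades 0-1 are the low-toxicity class (controls), grade 2 intermediate
#' (excluded from case/control testing), grades 3-4 high (cases).
#'
#' @param grades integer vector of CTCAE grades in 0..4.
#' @return factor with levels `low`, `intermediate`, `high`.
#' @export
toxicity_class <- function(grades) {
  if (any(!is.na(grades) & (grades < 0 | grades > 4)))
    stop("CTCAE grades must be in 0..4")
  cut(grades, breaks = c(-Inf, 1, 2, Inf),
      labels = c("low", "intermediate", "high"))
}

#' Map toxicity classes to case/control status
#'
#' @param classes factor from [toxicity_class()].
#' @return character vector in `{case, control, excluded}`: high = case,
#'   low = control, intermediate = excluded.
#' @export
case_control <- function(classes) {
  out <- rep("excluded", length(classes))
  out[classes == "high"] <- "case"
  out[classes == "low"] <- "control"
  out
}

#' Read a per-sample CTCAE phenotype table
#'
#' Expects a TSV with header `sample_id`, `grade_neutropenia`,
#' `grade_leukopenia`, `grade_thrombocytopenia`, `grade_maximal`.
#' When all three component grades are present, the maximal grade must be
#' at least their maximum.
#'
#' @param path TSV file (gzip transparent).
#' @return data.frame of grades keyed by `sample_id`.
#' @export
read_phenotypes <- function(path) {
  ph <- as.data.frame(data.table::fread(path))
  need <- c("sample_id", "grade_neutropenia", "grade_leukopenia",
            "grade_thrombocytopenia", "grade_maximal")
  miss <- setdiff(need, names(ph))
  if (length(miss)) stop("phenotype table misses column(s): ",
                         paste(miss, collapse = ", "))
  validate_phenotypes(ph)
  ph
}

validate_phenotypes <- function(ph) {
  gcols <- grep("^grade_", names(ph), value = TRUE)
  for (g in gcols)
    if (any(!is.na(ph[[g]]) & (ph[[g]] < 0 | ph[[g]] > 4)))
      stop("grades in ", g, " outside 0..4")
  comp <- c("grade_neutropenia", "grade_leukopenia", "grade_thrombocytopenia")
  if (all(c(comp, "grade_maximal") %in% names(ph))) {
    cm <- do.call(pmax, c(ph[comp], na.rm = TRUE))
    ok <- is.na(cm) | is.na(ph$grade_maximal) | ph$grade_maximal >= cm
    if (!all(ok)) stop("grade_maximal below a component grade for sample(s): ",
                       paste(head(ph$sample_id[!ok], 5), collapse = ", "))
  }
  invisible(ph)
}
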