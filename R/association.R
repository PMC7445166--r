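#' Allelic Fisher exact test for one variant
#'
#' Builds the 2x2 allele-count table (each called sample contributes two
#' alleles; missing genotypes contribute none), with cases = high-toxicity
#' and controls = low-toxicity samples; intermediates must already be
#' marked `excluded`.  The two-sided p-value is the sum of hypergeometric
#' probabilities of all tables (at fixed margins) no more probable than the
#' observed one — the PLINK `--fisher` convention, no mid-p.  The odds
#' ratio is the cross product `(a*d)/(b*c)`; when any cell is zero the
#' Haldane-Anscombe +0.5 is added to all four cells for reporting only.
#'
#' @param dosages integer vector of alt-allele counts (0/1/2/NA).
#' @param status character vector in `{case, control, excluded}` (see
#'   [case_control()]).
#' @return one-row data.frame: allele counts `a` (case-alt), `b`
#'   (case-ref), `c` (control-alt), `d` (control-ref), `odds_ratio`,
#'   `p_value`, `monomorphic`.
#' @export
allelic_fisher <- function(dosages, status) {
  if (length(dosages) != length(status))
    stop("dosages and status lengths differ")
  use <- status %in% c("case", "control")
  if (!any(use)) stop("all samples excluded")
  d <- dosages[use]; s <- status[use]
  called <- !is.na(d)
  a <- sum(d[called & s == "case"])
  b <- 2L * sum(called & s == "case") - a
  cc <- sum(d[called & s == "control"])
  dd <- 2L * sum(called & s == "control") - cc
  mono <- (a + cc == 0L) || (b + dd == 0L) || (a + b == 0L) || (cc + dd == 0L)
  if (mono) {
    p <- 1; or <- 1
  } else {
    p <- fisher_2x2_p(a, b, cc, dd)
    if (a == 0 || b == 0 || cc == 0 || dd == 0) {
      or <- ((a + 0.5) * (dd + 0.5)) / ((b + 0.5) * (cc + 0.5))
    } else {
      or <- (a * dd) / (b * cc)
    }
  }
  data.frame(a = a, b = b, c = cc, d = dd, odds_ratio = or, p_value = p,
             monomorphic = mono)
}

# two-sided Fisher p for a 2x2 table by summation over the hypergeometric
# support; ties in probability included with a 1e-7 relative tolerance
fisher_2x2_p <- function(a, b, c, d) {
  k_alt <- a + c                 # total alt alleles (white balls)
  n_case <- a + b                # case alleles drawn
  n_tot <- a + b + c + d
  support <- max(0L, k_alt - (c + d)):min(k_alt, n_case)
  pr <- dhyper(support, k_alt, n_tot - k_alt, n_case)
  obs <- dhyper(a, k_alt, n_tot - k_alt, n_case)
  min(1, sum(pr[pr <= obs * (1 + 1e-7)]))
}

#' Per-variant allelic association against one phenotype
#'
#' Applies [allelic_fisher()] to every variant in a genotype container.
#'
#' @param gd a [genotype_data()] object.
#' @param grades integer CTCAE grades (0-4), one per sample, in the
#'   container's sample order; grades 3-4 are cases, 0-1 controls, 2
#'   excluded.
#' @param phenotype label stored in the result (e.g. `"neutropenia"`).
#' @param alpha nominal significance threshold used for the `nominal` flag
#'   (inclusive, default `1e-3`).
#' @return data.frame with one row per variant: id, coordinates, allele
#'   counts, odds ratio, p-value, `monomorphic` and `nominal` flags.
#' @export
association_test <- function(gd, grades, phenotype = "toxicity", alpha = 1e-3) {
  stopifnot(inherits(gd, "genotype_data"))
  if (length(grades) != length(gd$samples))
    stop("grades must match the sample count")
  status <- case_control(toxicity_class(grades))
  res <- do.call(rbind, lapply(seq_len(nrow(gd$dosage)), function(i)
    allelic_fisher(gd$dosage[i, ], status)))
  out <- cbind(gd$variants[, c("variant_id", "chrom", "pos")], res)
  out$phenotype <- phenotype
  out$nominal <- out$p_value <= alpha
  rownames(out) <- NULL
  out
}

#' Filter association results to the nominal subset
#'
#' @param results data.frame from [association_test()].
#' @param alpha inclusive p-value threshold (default `1e-3`).
#' @return the rows with `p_value <= alpha`, order preserved.
#' @export
filter_nominal <- function(results, alpha = 1e-3) {
  results[results$p_value <= alpha, , drop = FALSE]
}

#' Principal component analysis of genotypes
#'
#' Monomorphic variants and variants with more than `max_missing` missing
#' genotypes are dropped; remaining missing dosages are imputed to the
#' variant mean.  Variants are centered and scaled to unit variance before
#' the decomposition.  Component signs are fixed so that the largest-
#' magnitude loading of each component is positive.
#'
#' @param gd a [genotype_data()] object (or a variants x samples dosage
#'   matrix).
#' @param n_components number of components to return.
#' @param max_missing maximum tolerated per-variant missing fraction
#'   (default 0.05).
#' @return list with `scores` (samples x components), `loadings`,
#'   `explained_variance` (per component), `proportion` (of total
#'   variance), and `n_variants_used`.
#' @export
pca_genotypes <- function(gd, n_components = 2, max_missing = 0.05) {
  dos <- if (inherits(gd, "genotype_data")) gd$dosage else as.matrix(gd)
  if (ncol(dos) < 2) stop("need at least 2 samples")
  missfrac <- rowMeans(is.na(dos))
  v <- apply(dos, 1L, var, na.rm = TRUE)
  keep <- missfrac <= max_missing & !is.na(v) & v > 0
  if (sum(keep) < n_components)
    stop("fewer polymorphic variants (", sum(keep), ") than components")
  dos <- dos[keep, , drop = FALSE]
  rm <- rowMeans(dos, na.rm = TRUE)
  idx <- which(is.na(dos), arr.ind = TRUE)
  if (nrow(idx)) dos[idx] <- rm[idx[, 1]]
  x <- scale(t(dos))                       # samples x variants
  pc <- prcomp(x, center = FALSE, scale. = FALSE, rank. = n_components)
  flip <- vapply(seq_len(n_components), function(j) {
    l <- pc$rotation[, j]
    sign(l[which.max(abs(l))]) < 0
  }, logical(1))
  pc$rotation[, flip] <- -pc$rotation[, flip]
  pc$x[, flip] <- -pc$x[, flip]
  ev <- pc$sdev^2
  list(scores = pc$x[, seq_len(n_components), drop = FALSE],
       loadings = pc$rotation,
       explained_variance = ev[seq_len(n_components)],
       proportion = ev[seq_len(n_components)] / sum(ev),
       n_variants_used = sum(keep))
}
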