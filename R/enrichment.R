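#' Two-sided Fisher overlap enrichment of a module against a gene set
#'
#' Both sets are intersected with the universe first; the 2x2 table is
#' in/out module x in/out target.  The p-value is the two-sided Fisher
#' exact sum-of-probabilities; the odds ratio is the cross product with
#' the +0.5 correction applied to all cells only when some cell is zero.
#'
#' @param module_genes character vector.
#' @param target_set character vector.
#' @param universe character vector of all eligible genes (non-empty).
#' @param name label for the result row.
#' @return one-row data.frame: `set_name`, `overlap`, `odds_ratio`,
#'   `p_value`, `universe_size`, set and module sizes (in-universe).
#' @export
overlap_fisher <- function(module_genes, target_set, universe,
                           name = "target") {
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  m <- intersect(unique(module_genes), universe)
  t_ <- intersect(unique(target_set), universe)
  a <- length(intersect(m, t_))
  b <- length(m) - a
  c_ <- length(t_) - a
  d <- length(universe) - a - b - c_
  p <- fisher_2x2_p(a, b, c_, d)
  or <- if (a == 0 || b == 0 || c_ == 0 || d == 0)
    ((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c_ + 0.5)) else (a * d) / (b * c_)
  data.frame(set_name = name, overlap = a, odds_ratio = or, p_value = p,
             module_size = length(m), set_size = length(t_),
             universe_size = length(universe), stringsAsFactors = FALSE)
}

#' Fisher's method for combining p-values
#'
#' `X = -2 * sum(log(p))` referred to a chi-square distribution with `2k`
#' degrees of freedom.
#'
#' @param p_values numeric vector with all values in (0, 1].
#' @return the combined p-value.
#' @export
fisher_method <- function(p_values) {
  if (!length(p_values)) stop("no p-values")
  if (any(p_values <= 0 | p_values > 1)) stop("p-values must be in (0, 1]")
  x <- -2 * sum(log(p_values))
  pchisq(x, df = 2 * length(p_values), lower.tail = FALSE)
}

#' Bonferroni adjustment
#'
#' @param p_values numeric vector.
#' @param m number of tests (default `length(p_values)`; must be at least
#'   that).
#' @return `pmin(1, p * m)`.
#' @export
bonferroni <- function(p_values, m = length(p_values)) {
  if (m < length(p_values)) stop("m must be >= number of p-values")
  pmin(1, p_values * m)
}

#' Transcripts per million
#'
#' `rate_g = count_g / length_g`; `TPM_g = 1e6 * rate_g / sum(rates)`,
#' per sample.  A sample with all-zero counts yields all-zero TPM with a
#' warning.
#'
#' @param counts genes x samples matrix of non-negative counts.
#' @param lengths per-gene lengths in bp (> 0), recycled across samples.
#' @return genes x samples TPM matrix; non-degenerate columns sum to 1e6.
#' @export
tpm <- function(counts, lengths) {
  counts <- as.matrix(counts)
  if (length(lengths) != nrow(counts))
    stop("lengths must match the gene count")
  if (any(lengths <= 0)) stop("gene lengths must be positive")
  if (any(counts < 0)) stop("counts must be non-negative")
  rate <- counts / lengths
  tot <- colSums(rate)
  zero <- tot == 0
  if (any(zero)) {
    warning(sum(zero), " all-zero sample(s): TPM set to zero")
    tot[zero] <- 1
  }
  sweep(rate, 2L, tot / 1e6, `/`)
}

#' Expressed-gene filter
#'
#' Genes with TPM strictly greater than `threshold` in at least
#' `min_samples` samples.
#'
#' @param tpm_matrix genes x samples TPM matrix with rownames.
#' @param threshold strict TPM lower bound (default 1).
#' @param min_samples minimum number of samples exceeding it (default 2).
#' @return character vector of gene ids.
#' @export
expressed_set <- function(tpm_matrix, threshold = 1, min_samples = 2) {
  if (!nrow(tpm_matrix) || !ncol(tpm_matrix)) return(character())
  hits <- rowSums(tpm_matrix > threshold) >= min_samples
  rownames(tpm_matrix)[hits]
}

#' Permutation test for module expression enrichment
#'
#' Draws `|module|` genes from the background without replacement,
#' `n_perm` times, and counts how many fall in the expressed set; the
#' empirical p-value is `(1 + #{permuted count >= observed}) / (n_perm +
#' 1)` (never exactly zero).  Module genes outside the background are
#' dropped with a message.
#'
#' @param module_genes character vector.
#' @param background_genes character vector to draw from (e.g. all genes
#'   with nonzero counts).
#' @param expressed character vector (see [expressed_set()]).
#' @param n_perm number of permutations (default 10000).
#' @param seed RNG seed.
#' @return list with `observed`, `mean_permuted`, `p_value`, `n_perm`,
#'   and the vector of `permuted` counts.
#' @export
expression_permutation <- function(module_genes, background_genes, expressed,
                                   n_perm = 10000, seed = 1) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  background_genes <- unique(background_genes)
  module_genes <- unique(module_genes)
  out <- setdiff(module_genes, background_genes)
  if (length(out)) {
    message(length(out), " module gene(s) outside background dropped")
    module_genes <- intersect(module_genes, background_genes)
  }
  m <- length(module_genes)
  if (length(background_genes) < m) stop("background smaller than module")
  is_expr <- background_genes %in% expressed
  observed <- sum(module_genes %in% expressed)
  set.seed(seed)
  permuted <- vapply(seq_len(n_perm), function(i)
    sum(is_expr[sample.int(length(background_genes), m)]), 0L)
  list(observed = observed, mean_permuted = mean(permuted),
       p_value = (1 + sum(permuted >= observed)) / (n_perm + 1),
       n_perm = n_perm, permuted = permuted)
}

#' Over-representation analysis over a gene-set collection
#'
#' One-sided (greater) Fisher exact test per set, BH-adjusted by default,
#' sorted by adjusted p.
#'
#' @param collection named list of gene sets (see [read_gmt()]).
#' @param module_genes character vector.
#' @param universe character vector.
#' @param fdr_method `p.adjust` method (default `"BH"`).
#' @return data.frame: `set_name`, `overlap`, `set_size`, `p_value`,
#'   `adjusted_p`, `method`.
#' @export
ora <- function(collection, module_genes, universe, fdr_method = "BH") {
  if (!length(collection))
    return(data.frame(set_name = character(), overlap = integer(),
                      set_size = integer(), p_value = numeric(),
                      adjusted_p = numeric(), method = character()))
  universe <- unique(universe)
  m <- intersect(unique(module_genes), universe)
  rows <- lapply(names(collection), function(nmset) {
    t_ <- intersect(unique(collection[[nmset]]), universe)
    k <- length(intersect(m, t_))
    p <- phyper(k - 1, length(t_), length(universe) - length(t_), length(m),
                lower.tail = FALSE)
    data.frame(set_name = nmset, overlap = k, set_size = length(t_),
               p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$adjusted_p <- p.adjust(out$p_value, method = fdr_method)
  out$method <- fdr_method
  out[order(out$adjusted_p, out$p_value, out$set_name), , drop = FALSE]
}
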