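#' Simulation configuration
#'
#' The defaults state the cohort the whole pipeline assumes: 96 samples in
#' a 54/8/34 high/intermediate/low split of maximal toxicity, a few
#' thousand candidate bi-allelic variants with Hardy-Weinberg genotypes at
#' uniform MAFs, a handful of planted causal variants whose genes co-locate
#' in one dense network module, a planted-partition interaction network,
#' and negative-binomial expression counts for 3 cell lines x
#' {untreated, drugA, drugB} x 2 replicates with line-specific treatment
#' effects on module genes.
#'
#' @param n_samples cohort size.
#' @param class_counts named integer vector `c(high=, intermediate=, low=)`
#'   summing to `n_samples`; classes are enforced by rank-thresholding the
#'   liability so the counts are exact.
#' @param n_variants number of candidate variants.
#' @param maf_range uniform sampling range for minor-allele frequencies,
#'   within (0, 0.5].
#' @param n_causal number of planted causal variants, each in a distinct
#'   planted-module gene.
#' @param causal_odds_ratio per-alt-allele odds ratio shared by the causal
#'   variants (1 = null model).
#' @param network list: `n_module_genes`, `n_background_genes`, `p_in`,
#'   `p_out`, `module_score_range`, `background_score_range`.
#' @param expression list: `n_cell_lines`, `n_replicates`, `nb_dispersion`,
#'   `treatment_log2fc`, `n_affected_module_genes`.
#' @param missing_rate per-genotype missingness rate.
#' @param rng_seed master seed; each generator derives its own stream from
#'   it so stages can be regenerated independently.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 96,
                       class_counts = c(high = 54, intermediate = 8, low = 34),
                       n_variants = 3000,
                       maf_range = c(0.05, 0.5),
                       n_causal = 5,
                       causal_odds_ratio = 3,
                       network = list(),
                       expression = list(),
                       missing_rate = 0.01,
                       rng_seed = 1) {
  net <- utils::modifyList(list(n_module_genes = 50, n_background_genes = 450,
                                p_in = 0.8, p_out = 0.02,
                                module_score_range = c(701, 999),
                                background_score_range = c(150, 999)), network)
  expr <- utils::modifyList(list(n_cell_lines = 3, n_replicates = 2,
                                 nb_dispersion = 0.15, treatment_log2fc = 2,
                                 n_affected_module_genes = 18), expression)
  cfg <- list(n_samples = n_samples, class_counts = class_counts,
              n_variants = n_variants, maf_range = maf_range,
              n_causal = n_causal, causal_odds_ratio = causal_odds_ratio,
              network = net, expression = expr,
              missing_rate = missing_rate, rng_seed = rng_seed)
  if (maf_range[1] <= 0 || maf_range[2] > 0.5 || maf_range[1] > maf_range[2])
    stop("maf_range must lie within (0, 0.5]")
  if (net$p_in <= net$p_out) stop("p_in must exceed p_out")
  if (n_causal > n_variants) stop("n_causal exceeds n_variants")
  if (!all(c("high", "intermediate", "low") %in% names(class_counts)))
    stop("class_counts needs names high, intermediate, low")
  if (sum(class_counts) != n_samples)
    stop("class_counts must sum to n_samples")
  if (net$n_module_genes < 3) stop("planted module must have >= 3 genes")
  structure(cfg, class = "sim_config")
}

# independent, reproducible per-stage streams from one master seed
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 104729 + k * 7919) %% 2147483647)
}

all_pairs <- function(n) {
  i <- rep.int(seq_len(n - 1L), (n - 1L):1L)
  j <- sequence((n - 1L):1L) + i
  cbind(i, j)
}

#' Simulate a PPI network with one planted dense module
#'
#' Planted-partition graph: module genes are pairwise connected with
#' probability `p_in` (scores uniform on the module score range, >700 by
#' default so they survive the high-confidence filter); every other pair
#' with probability `p_out` (scores uniform on the background range).
#'
#' @param config a [sim_config()].
#' @param seed RNG seed; defaults to a stream derived from the config seed.
#' @return list with `network` (simple undirected `igraph` with integer
#'   `score` edge attribute) and `truth` (planted module and background
#'   gene ids).
#' @export
simulate_network <- function(config, seed = derive_seed(config$rng_seed, 1L)) {
  stopifnot(inherits(config, "sim_config"))
  net <- config$network
  if (net$n_module_genes < 3) stop("planted module must have >= 3 genes")
  mod_genes <- sprintf("TOXG%03d", seq_len(net$n_module_genes))
  bg_genes <- sprintf("BKG%03d", seq_len(net$n_background_genes))
  genes <- c(mod_genes, bg_genes)
  n <- length(genes)
  set.seed(seed)
  pr <- all_pairs(n)
  in_module <- pr[, 1] <= net$n_module_genes & pr[, 2] <= net$n_module_genes
  p_edge <- ifelse(in_module, net$p_in, net$p_out)
  keep <- runif(nrow(pr)) < p_edge
  pr <- pr[keep, , drop = FALSE]
  in_module <- in_module[keep]
  lo <- ifelse(in_module, net$module_score_range[1], net$background_score_range[1])
  hi <- ifelse(in_module, net$module_score_range[2], net$background_score_range[2])
  score <- round(runif(nrow(pr), lo, hi))
  g <- igraph::graph_from_data_frame(
    data.frame(from = genes[pr[, 1]], to = genes[pr[, 2]], score = score),
    directed = FALSE, vertices = genes)
  truth <- list(module_genes = mod_genes, background_genes = bg_genes,
                causal_variants = NULL, causal_genes = NULL,
                causal_log_or = NULL, affected_genes = NULL)
  list(network = g, truth = truth)
}

#' Simulate gene models for the network genes
#'
#' Genes are laid out round-robin on chromosomes 1-22 with 1 Mb spacing and
#' random lengths/strands, giving every network gene a locus that nearest-
#' gene mapping can hit.
#'
#' @inheritParams simulate_network
#' @param truth truth list from [simulate_network()].
#' @return gene-model data.frame (see [read_gene_models()]).
#' @export
simulate_gene_models <- function(config, truth,
                                 seed = derive_seed(config$rng_seed, 2L)) {
  genes <- c(truth$module_genes, truth$background_genes)
  set.seed(seed)
  chrom <- paste0("chr", rep_len(1:22, length(genes)))
  slot <- stats::ave(seq_along(genes), chrom, FUN = seq_along)
  start <- 1e6L * slot + 1L
  len <- as.integer(round(runif(length(genes), 5e3, 5e4)))
  strand <- sample(c("+", "-"), length(genes), replace = TRUE)
  data.frame(gene_id = genes, chrom = chrom, start = start,
             end = start + len - 1L, strand = strand,
             tss = ifelse(strand == "+", start, start + len - 1L),
             biotype = "protein_coding", stringsAsFactors = FALSE)
}

#' Simulate genotypes and CTCAE phenotypes
#'
#' Genotypes are Hardy-Weinberg draws at per-variant MAFs.  A liability
#' `sum(log(OR) * dosage)` over the planted causal variants plus logistic
#' noise is rank-thresholded so the maximal-toxicity classes hit the
#' configured counts exactly; grades within a class follow the stated
#' cohort's grade distribution.  The three component phenotypes are the
#' maximal grade minus a random decrement, with one phenotype per sample
#' forced to attain the maximum, giving correlated grades that all track
#' the same liability.  Causal variants are placed inside distinct
#' planted-module genes; a small fraction of other variants go to chrX to
#' exercise the autosomal filter, and QC failures (non-PASS labels, low
#' depth, high missingness) are injected at low rates.
#'
#' @inheritParams simulate_gene_models
#' @param gene_models gene models from [simulate_gene_models()].
#' @return list with `genotypes` ([genotype_data()]), `phenotypes`
#'   (data.frame of grades), `truth` (updated with causal variant ids and
#'   effects), and `maf` (per-variant allele frequencies).
#' @export
simulate_genotypes_phenotypes <- function(config, truth, gene_models,
                                          seed = derive_seed(config$rng_seed, 3L)) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  nv <- config$n_variants; ns <- config$n_samples
  maf <- runif(nv, config$maf_range[1], config$maf_range[2])
  # planted causal variants are common (MAF >= 0.2) so a cohort of ~100
  # has allelic power at the nominal threshold; rare planted signal would
  # make every seeded recovery test a coin flip
  maf_lo <- max(config$maf_range[1], min(0.2, config$maf_range[2]))
  maf[seq_len(config$n_causal)] <- runif(config$n_causal, maf_lo,
                                         config$maf_range[2])

  # causal variants in distinct planted-module genes
  if (config$n_causal > length(truth$module_genes))
    stop("n_causal exceeds number of planted module genes")
  causal_genes <- sample(truth$module_genes, config$n_causal)
  gm <- gene_models[match(causal_genes, gene_models$gene_id), ]
  chrom <- character(nv); pos <- integer(nv)
  ci <- seq_len(config$n_causal)
  chrom[ci] <- gm$chrom
  pos[ci] <- as.integer(gm$start + floor(runif(config$n_causal) * (gm$end - gm$start)))
  # the rest: random loci, ~2% on chrX
  rest <- setdiff(seq_len(nv), ci)
  chrom[rest] <- ifelse(runif(length(rest)) < 0.02, "chrX",
                        paste0("chr", sample(1:22, length(rest), replace = TRUE)))
  pos[rest] <- as.integer(round(runif(length(rest), 1, 5e7)))
  ids <- sprintf("var%05d", seq_len(nv))

  dosage <- matrix(rbinom(nv * ns, 2L, rep(maf, ns)), nrow = nv)
  # liability-threshold phenotype model
  eff <- rep(log(config$causal_odds_ratio), config$n_causal)
  liab <- drop(crossprod(dosage[ci, , drop = FALSE], eff)) + rlogis(ns)
  cc <- config$class_counts
  ord <- order(liab, decreasing = TRUE)
  class <- character(ns)
  class[ord[seq_len(cc["high"])]] <- "high"
  class[ord[cc["high"] + seq_len(cc["intermediate"])]] <- "intermediate"
  class[ord[cc["high"] + cc["intermediate"] + seq_len(cc["low"])]] <- "low"
  # within-class grade mix follows the stated cohort (maximal toxicity):
  # grade 4:3 = 39:15 among high, grade 0:1 = 23:11 among low
  gmax <- integer(ns)
  hi <- class == "high"; lo <- class == "low"
  gmax[hi] <- 3L + rbinom(sum(hi), 1L, 39 / 54)
  gmax[class == "intermediate"] <- 2L
  gmax[lo] <- rbinom(sum(lo), 1L, 11 / 34)
  # component grades: maximal minus a 0/1 decrement, one phenotype attains
  # it; a single-grade drop cannot move a high sample into the control
  # class (grade 3 drops to the excluded grade 2), keeping each component
  # phenotype's case/control classes consistent with the liability
  dec <- matrix(rbinom(ns * 3L, 1L, 0.3), ns, 3L)
  dec[cbind(seq_len(ns), sample.int(3L, ns, replace = TRUE))] <- 0L
  grades <- pmax(gmax - dec, 0L)

  # QC blemishes: missingness, non-PASS labels, low-depth cells
  miss <- matrix(runif(nv * ns) < config$missing_rate, nv, ns)
  heavy <- sample(nv, max(1L, round(0.02 * nv)))      # variants w/ poor call rate
  miss[heavy, ] <- miss[heavy, ] | matrix(runif(length(heavy) * ns) < 0.1,
                                          length(heavy), ns)
  dosage[miss] <- NA_integer_
  filt <- rep("PASS", nv)
  filt[sample(nv, max(1L, round(0.02 * nv)))] <- "q10"
  depth <- matrix(rpois(nv * ns, 35), nv, ns)
  lowdp <- sample(setdiff(seq_len(nv), ci), max(1L, round(0.02 * nv)))
  depth[cbind(lowdp, sample.int(ns, length(lowdp), replace = TRUE))] <- 3L

  samples <- sprintf("S%03d", seq_len(ns))
  variants <- data.frame(variant_id = ids, chrom = chrom, pos = pos,
                         ref = "A", alt = "G", filter = filt,
                         stringsAsFactors = FALSE)
  gd <- genotype_data(variants, dosage, samples, depth)
  ph <- data.frame(sample_id = samples,
                   grade_neutropenia = grades[, 1],
                   grade_leukopenia = grades[, 2],
                   grade_thrombocytopenia = grades[, 3],
                   grade_maximal = gmax,
                   stringsAsFactors = FALSE)
  validate_phenotypes(ph)
  truth$causal_variants <- ids[ci]
  truth$causal_genes <- causal_genes
  truth$causal_log_or <- eff
  list(genotypes = gd, phenotypes = ph, truth = truth, maf = maf)
}

#' Simulate an expression count matrix
#'
#' 18 samples by default: `n_cell_lines` lines x {untreated, drugA, drugB}
#' x `n_replicates`.  Counts are negative binomial around gene baselines;
#' `n_affected_module_genes` planted-module genes are shifted by
#' `treatment_log2fc` in a line-specific pattern (drugA acts in line 1,
#' drugB in line `n_cell_lines`), and ~10% of genes are near-silent so the
#' expressed-gene filter has something to remove.
#'
#' @inheritParams simulate_gene_models
#' @return list with `counts` (genes x samples integer matrix),
#'   `gene_length` (bp), `samples` (data.frame: sample, line, treatment,
#'   replicate) and `affected_genes`.
#' @export
simulate_expression <- function(config, truth,
                                seed = derive_seed(config$rng_seed, 4L)) {
  stopifnot(inherits(config, "sim_config"))
  ex <- config$expression
  set.seed(seed)
  genes <- c(truth$module_genes, truth$background_genes)
  ng <- length(genes)
  lines <- sprintf("line%d", seq_len(ex$n_cell_lines))
  design <- expand.grid(replicate = seq_len(ex$n_replicates),
                        treatment = c("untreated", "drugA", "drugB"),
                        line = lines, stringsAsFactors = FALSE)[, 3:1]
  design$sample <- sprintf("%s_%s_r%d", design$line, design$treatment,
                           design$replicate)
  len <- as.integer(round(runif(ng, 500, 10000)))
  base_mu <- stats::rlnorm(ng, meanlog = log(150), sdlog = 1)
  base_mu[runif(ng) < 0.1] <- 0.05                       # near-silent genes
  n_aff <- min(ex$n_affected_module_genes, length(truth$module_genes))
  affected <- sample(truth$module_genes, n_aff)
  fc <- 2^ex$treatment_log2fc
  counts <- matrix(0L, ng, nrow(design), dimnames = list(genes, design$sample))
  for (j in seq_len(nrow(design))) {
    mu <- base_mu * (len / 1000)
    hit <- (design$treatment[j] == "drugA" && design$line[j] == lines[1]) ||
      (design$treatment[j] == "drugB" && design$line[j] == lines[length(lines)])
    if (hit) mu[match(affected, genes)] <- mu[match(affected, genes)] * fc
    counts[, j] <- rnbinom(ng, mu = mu, size = 1 / ex$nb_dispersion)
  }
  truth$affected_genes <- affected
  list(counts = counts, gene_length = setNames(len, genes),
       samples = design, affected_genes = affected, truth = truth)
}

#' Simulate a full synthetic cohort
#'
#' Runs the network, gene-model, genotype/phenotype and expression
#' generators off independent streams derived from `config$rng_seed`.
#'
#' @param config a [sim_config()].
#' @return list with `network`, `gene_models`, `genotypes`, `phenotypes`,
#'   `expression`, `truth`, `maf`, `config`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  net <- simulate_network(config)
  gm <- simulate_gene_models(config, net$truth)
  gp <- simulate_genotypes_phenotypes(config, net$truth, gm)
  ex <- simulate_expression(config, gp$truth)
  list(network = net$network, gene_models = gm, genotypes = gp$genotypes,
       phenotypes = gp$phenotypes, expression = ex,
       truth = ex$truth, maf = gp$maf, config = config)
}

#' Write a simulated cohort to disk
#'
#' Emits `genotypes.vcf`, `phenotypes.tsv`, `network.tsv` (edge list with
#' scores), `gene_models.gff3`, `expression_counts.tsv` (gene, gene_length,
#' then one column per sample) and `truth.tsv` into `dir`.
#'
#' @param cohort result of [simulate_cohort()].
#' @param dir output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_vcf(cohort$genotypes, file.path(dir, "genotypes.vcf"))
  write_table(cohort$phenotypes, file.path(dir, "phenotypes.tsv"))
  ed <- igraph::as_data_frame(cohort$network, what = "edges")
  names(ed) <- c("geneA", "geneB", "combined_score")
  write_table(ed, file.path(dir, "network.tsv"))
  gm <- cohort$gene_models
  gff <- c("##gff-version 3",
           sprintf("%s\ttoxmod\tgene\t%d\t%d\t.\t%s\t.\tID=%s;gene_id=%s;gene_biotype=protein_coding",
                   gm$chrom, gm$start, gm$end, gm$strand, gm$gene_id, gm$gene_id))
  writeLines(gff, file.path(dir, "gene_models.gff3"))
  cx <- data.frame(gene = rownames(cohort$expression$counts),
                   gene_length = unname(cohort$expression$gene_length),
                   cohort$expression$counts, check.names = FALSE)
  write_table(cx, file.path(dir, "expression_counts.tsv"))
  tr <- cohort$truth
  write_table(data.frame(
    item = c(rep("causal_variant", length(tr$causal_variants)),
             rep("module_gene", length(tr$module_genes)),
             rep("affected_gene", length(tr$affected_genes))),
    id = c(tr$causal_variants, tr$module_genes, tr$affected_genes)),
    file.path(dir, "truth.tsv"))
  invisible(dir)
}
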