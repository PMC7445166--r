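# Small in-code fixtures shared across test files.

write_toy_vcf <- function(path, extra_record = NULL) {
  lines <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Depth">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "S1", "S2", "S3"), collapse = "\t"),
    "chr1\t100\trs1\tA\tG\t.\tPASS\t.\tGT:DP\t0/1:20\t1|1:18\t./.:.",
    "chr1\t200\trs2\tC\tT,G\t.\tPASS\t.\tGT:DP\t0/1:15\t0/0:22\t0/0:30",
    "chr2\t300\t.\tG\tA\t.\tq10\t.\tGT:DP\t0/0:12\t0/1:9\t1/1:14",
    extra_record)
  writeLines(lines, path)
  path
}

make_gd <- function(dosage, filter = NULL, depth = NULL,
                    chrom = NULL, pos = NULL) {
  nv <- nrow(dosage)
  variants <- data.frame(
    variant_id = sprintf("v%02d", seq_len(nv)),
    chrom = if (is.null(chrom)) rep("chr1", nv) else chrom,
    pos = if (is.null(pos)) seq_len(nv) * 100L else pos,
    ref = "A", alt = "G",
    filter = if (is.null(filter)) rep("PASS", nv) else filter)
  genotype_data(variants, dosage,
                sprintf("S%02d", seq_len(ncol(dosage))), depth)
}

toy_gene_models <- function() {
  data.frame(
    gene_id = c("geneA", "geneB", "geneC"),
    chrom = c("chr1", "chr1", "chr2"),
    start = c(10000L, 50000L, 10000L),
    end = c(20000L, 60000L, 15000L),
    strand = c("+", "-", "+"),
    tss = c(10000L, 60000L, 10000L),
    biotype = "protein_coding")
}

small_cohort_config <- function(seed = 11, or = 8, n_variants = 600) {
  sim_config(n_variants = n_variants, causal_odds_ratio = or,
             network = list(n_module_genes = 30, n_background_genes = 120),
             rng_seed = seed)
}
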