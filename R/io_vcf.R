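#' Read a VCF into a genotype container
#'
#' Thin wrapper around `VariantAnnotation::readVcf()` that restricts to
#' bi-allelic records, converts GT fields to additive alt-allele dosages
#' (0/1/2, `./.` recorded as `NA`) and carries FORMAT/DP read depths when
#' present.  Multi-allelic records are dropped, not decomposed.
#'
#' @param path VCF 4.x file, plain or gzip/bgzip compressed; GT must be
#'   present.
#' @param sample_subset character vector of sample ids to load, in the
#'   returned column order; `NULL` (default) loads all samples in file
#'   order.  A requested sample absent from the header is an error.
#' @return a [genotype_data()] object.
#' @export
read_vcf <- function(path, sample_subset = NULL) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop("read_vcf requires the VariantAnnotation package")
  hdr <- VariantAnnotation::scanVcfHeader(path)
  all_samples <- VariantAnnotation::samples(hdr)
  if (!is.null(sample_subset) && length(sample_subset)) {
    miss <- setdiff(sample_subset, all_samples)
    if (length(miss))
      stop("sample(s) not in VCF: ", paste(miss, collapse = ", "))
    param <- VariantAnnotation::ScanVcfParam(samples = sample_subset)
    vcf <- VariantAnnotation::readVcf(path, genome = "unknown", param = param)
  } else {
    vcf <- VariantAnnotation::readVcf(path, genome = "unknown")
  }
  alt <- VariantAnnotation::alt(vcf)
  biallelic <- S4Vectors::elementNROWS(alt) == 1L
  vcf <- vcf[biallelic, ]

  rr <- SummarizedExperiment::rowRanges(vcf)
  fx <- VariantAnnotation::fixed(vcf)
  chrom <- as.character(GenomicRanges::seqnames(rr))
  pos <- GenomicRanges::start(rr)
  ref <- as.character(VariantAnnotation::ref(vcf))
  altc <- as.character(unlist(VariantAnnotation::alt(vcf)))
  ids <- names(rr)
  fallback <- paste(chrom, pos, ref, altc, sep = ":")
  # readVcf synthesizes "chrom:pos_ref/alt" names for records with ID ".";
  # normalize those to the package's chrom:pos:ref:alt convention
  synthesized <- paste0(chrom, ":", pos, "_", ref, "/", altc)
  bad_id <- is.na(ids) | ids == "." | ids == "" | ids == synthesized
  ids[bad_id] <- fallback[bad_id]
  filt <- as.character(fx$FILTER)

  gt <- VariantAnnotation::geno(vcf)$GT
  if (is.null(gt)) stop("VCF has no GT field")
  dosage <- gt_to_dosage(gt)
  depth <- NULL
  if ("DP" %in% names(VariantAnnotation::geno(vcf))) {
    depth <- VariantAnnotation::geno(vcf)$DP
    storage.mode(depth) <- "double"
  }
  variants <- data.frame(variant_id = ids, chrom = chrom, pos = pos,
                         ref = ref, alt = altc, filter = filt,
                         stringsAsFactors = FALSE)
  genotype_data(variants, dosage, colnames(gt), depth)
}

# "0/1", "1|1", "./." etc -> 0/1/2/NA alt-allele counts
gt_to_dosage <- function(gt) {
  d <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  clean <- gsub("\\|", "/", gt)
  d[clean %in% c("0/0")] <- 0L
  d[clean %in% c("0/1", "1/0")] <- 1L
  d[clean %in% c("1/1")] <- 2L
  d
}

#' Write a genotype container as VCF 4.2
#'
#' Emits GT (and DP when depths are present) for every sample.  Used by the
#' synthetic-data generator so that the reader can be exercised end to end.
#'
#' @param gd a [genotype_data()] object.
#' @param path output path (`.gz` writes gzip).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gd, path) {
  stopifnot(inherits(gd, "genotype_data"))
  has_dp <- !is.null(gd$depth)
  hdr <- c("##fileformat=VCFv4.2",
           "##source=toxmod",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           if (has_dp) '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", gd$samples), collapse = "\t"))
  gtmap <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  gt <- matrix("./.", nrow(gd$dosage), ncol(gd$dosage))
  called <- !is.na(gd$dosage)
  gt[called] <- gtmap[as.character(gd$dosage[called])]
  if (has_dp) {
    dp <- matrix(".", nrow(gt), ncol(gt))
    ok <- !is.na(gd$depth)
    dp[ok] <- format(gd$depth[ok], trim = TRUE, scientific = FALSE)
    gt <- matrix(paste(gt, dp, sep = ":"), nrow(gt))
  }
  body <- paste(gd$variants$chrom, gd$variants$pos, gd$variants$variant_id,
                gd$variants$ref, gd$variants$alt, ".", gd$variants$filter, ".",
                if (has_dp) "GT:DP" else "GT",
                apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(c(hdr, body), con)
  invisible(path)
}

#' Variant quality-control filter
#'
#' Keeps records that are labeled PASS, have a genotyping rate of at least
#' `min_genotyping_rate`, have no called genotype with read depth below
#' `min_depth`, and have a mean read depth across all samples of at least
#' `min_mean_depth`.  Depth rules are skipped with a warning when the
#' container carries no depths.  The filter is idempotent.
#'
#' @param gd a [genotype_data()] object.
#' @param min_genotyping_rate minimum fraction of called genotypes (default
#'   0.95).
#' @param min_depth minimum per-genotype read depth among called genotypes
#'   (default 5).
#' @param min_mean_depth minimum mean depth across all samples (default 10).
#' @return the filtered `genotype_data`.
#' @export
qc_filter_variants <- function(gd, min_genotyping_rate = 0.95,
                               min_depth = 5, min_mean_depth = 10) {
  stopifnot(inherits(gd, "genotype_data"))
  keep <- gd$variants$filter == "PASS"
  called <- !is.na(gd$dosage)
  keep <- keep & rowMeans(called) >= min_genotyping_rate
  if (is.null(gd$depth)) {
    warning("no depth information: depth-based QC rules skipped")
  } else {
    dp_called <- gd$depth
    dp_called[!called] <- NA        # per-genotype rule looks at called GTs only
    low <- rowSums(dp_called < min_depth, na.rm = TRUE) > 0
    keep <- keep & !low
    keep <- keep & rowMeans(gd$depth, na.rm = TRUE) >= min_mean_depth
  }
  subset_genotypes(gd, variants = which(keep))
}
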