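#' Read a STRING-style weighted edge list into a PPI network
#'
#' Expects a TSV with columns `geneA`, `geneB`, `combined_score` (STRING
#' exports named `protein1`/`protein2`/`combined_score` are accepted too;
#' otherwise the first three columns are used).  Scores are on the STRING
#' 0-999 scale.  Edges are kept only when the score is strictly greater
#' than `min_score`, self-loops are dropped, and duplicate edges (in either
#' orientation) keep the maximum score.
#'
#' @param path edge-list TSV (gzip transparent).
#' @param min_score strict lower bound on the combined score; the default
#'   700 keeps high-confidence interactions only.
#' @return an undirected simple `igraph` graph with edge attribute `score`.
#' @export
read_network <- function(path, min_score = 700) {
  dt <- data.table::fread(path, header = TRUE, colClasses = list(character = 1:2))
  if (ncol(dt) < 3) stop("network file needs >= 3 columns")
  nm <- tolower(names(dt))
  a <- if ("genea" %in% nm) which(nm == "genea") else if ("protein1" %in% nm) which(nm == "protein1") else 1L
  b <- if ("geneb" %in% nm) which(nm == "geneb") else if ("protein2" %in% nm) which(nm == "protein2") else 2L
  s <- if ("combined_score" %in% nm) which(nm == "combined_score") else 3L
  raw_score <- dt[[s]]
  score <- suppressWarnings(as.numeric(raw_score))
  bad <- which(is.na(score) & !is.na(raw_score) & raw_score != "")
  if (length(bad))
    stop(sprintf("non-numeric combined_score at line %d: '%s'",
                 bad[1] + 1L, raw_score[bad[1]]))
  ed <- data.table::data.table(gene_a = dt[[a]], gene_b = dt[[b]], score = score)
  ed <- ed[gene_a != gene_b]
  # canonical orientation, keep max score across duplicates
  swap <- ed$gene_a > ed$gene_b
  tmp <- ed$gene_a[swap]; ed$gene_a[swap] <- ed$gene_b[swap]; ed$gene_b[swap] <- tmp
  ed <- ed[, .(score = max(score)), by = .(gene_a, gene_b)]
  ed <- ed[score > min_score]
  g <- igraph::graph_from_data_frame(ed, directed = FALSE)
  g
}

#' Read a GMT gene-set collection
#'
#' @param path GMT file: one set per line, tab separated, `name`,
#'   `description`, members.  Duplicate genes within a set are removed
#'   (first occurrence kept).
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path) else file(path)
  on.exit(close(con))
  lines <- readLines(con)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 2) stop("malformed GMT line: ", substr(ln, 1, 60))
    out[[f[1]]] <- unique(f[-(1:2)])
  }
  out
}

#' Read gene models from BED or GFF3
#'
#' BED input (0-based half-open) is converted to the package-wide 1-based
#' inclusive convention at this boundary; GFF3 coordinates pass through.
#' When a biotype attribute/column is available only `protein_coding`
#' entries are retained (BED carries no biotype, so everything is kept and
#' labeled `protein_coding`).  The transcription start site is the start
#' coordinate on the + strand and the end coordinate on the - strand;
#' unstranded entries are treated as +.
#'
#' @param path input file (gzip transparent via `rtracklayer`).
#' @param format `"GFF3"` or `"BED"`.
#' @return data.frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`, `tss`, `biotype`.
#' @export
read_gene_models <- function(path, format = c("GFF3", "BED")) {
  format <- toupper(format[1])
  if (!format %in% c("GFF3", "BED")) stop("unknown gene-model format: ", format)
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("read_gene_models requires the rtracklayer package")
  gr <- rtracklayer::import(path, format = if (format == "GFF3") "gff3" else "bed")
  md <- as.data.frame(gr)
  if (format == "GFF3") {
    if ("type" %in% names(md) && any(md$type == "gene"))
      md <- md[md$type == "gene", , drop = FALSE]
    bt_col <- intersect(c("gene_biotype", "biotype", "gene_type"), names(md))[1]
    biotype <- if (!is.na(bt_col)) as.character(md[[bt_col]]) else rep("protein_coding", nrow(md))
    biotype[is.na(biotype)] <- "protein_coding"
    id_col <- intersect(c("gene_id", "ID", "Name"), names(md))[1]
    if (is.na(id_col)) stop("GFF3 gene records carry no usable id attribute")
    gene_id <- as.character(md[[id_col]])
    keep <- biotype == "protein_coding"
    md <- md[keep, , drop = FALSE]; gene_id <- gene_id[keep]; biotype <- biotype[keep]
  } else {
    gene_id <- if ("name" %in% names(md)) as.character(md$name) else
      paste0("gene", seq_len(nrow(md)))
    biotype <- rep("protein_coding", nrow(md))
  }
  strand <- as.character(md$strand)
  strand[!strand %in% c("+", "-")] <- "+"
  out <- data.frame(gene_id = gene_id,
                    chrom = as.character(md$seqnames),
                    start = md$start, end = md$end,
                    strand = strand,
                    tss = ifelse(strand == "+", md$start, md$end),
                    biotype = biotype,
                    stringsAsFactors = FALSE)
  if (any(out$start > out$end)) stop("gene model with start > end")
  out
}

#' Write a TSV with header
#'
#' All pipeline outputs go through this writer: tab separated, no quoting,
#' `NA` spelled literally, so that text and integer columns round-trip
#' bit-identically through [data.table::fread()].
#'
#' @param rows data.frame to write.
#' @param path destination (`.gz` writes gzip).
#' @return `path`, invisibly.
#' @export
write_table <- function(rows, path) {
  data.table::fwrite(rows, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}

#' Read an additive dosage matrix from TSV
#'
#' Column 1 must be `variant_id`; the remaining columns are samples with
#' values in `{0, 1, 2, NA}`.  Ids of the form `chrom:pos:ref:alt` are
#' parsed back into variant coordinates; other ids get `NA` coordinates.
#'
#' @param path TSV file (gzip transparent).
#' @return a [genotype_data()] object without depths.
#' @export
read_dosage_tsv <- function(path) {
  dt <- as.data.frame(data.table::fread(path))
  if (names(dt)[1] != "variant_id") stop("first column must be variant_id")
  ids <- as.character(dt$variant_id)
  dos <- as.matrix(dt[, -1, drop = FALSE])
  parts <- strsplit(ids, ":", fixed = TRUE)
  four <- lengths(parts) == 4L
  chrom <- ifelse(four, vapply(parts, `[`, "", 1L), NA_character_)
  pos <- ifelse(four, suppressWarnings(as.integer(vapply(parts, `[`, "", 2L))), NA_integer_)
  variants <- data.frame(variant_id = ids, chrom = chrom,
                         pos = ifelse(is.na(pos), 1L, pos),
                         ref = ifelse(four, vapply(parts, `[`, "", 3L), "N"),
                         alt = ifelse(four, vapply(parts, `[`, "", 4L), "N"),
                         filter = "PASS", stringsAsFactors = FALSE)
  genotype_data(variants, dos, colnames(dos))
}
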