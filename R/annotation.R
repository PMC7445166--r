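#' Annotate variants by genomic location
#'
#' Assigns each variant exactly one category with priority
#' promoter > exon > intron > distal_intergenic.  A promoter is a
#' strand-aware window around a gene's transcription start site; an intron
#' is a position inside a gene body that overlaps no exon (when no exon
#' models are supplied, the whole gene body outside promoter windows
#' counts as intron).
#'
#' @param variants data.frame with `variant_id`, `chrom`, `pos`.
#' @param gene_models gene models (see [read_gene_models()]).
#' @param promoter_window half-width in bp of the TSS window (default
#'   3000, i.e. TSS +/- 3 kb).
#' @param exon_models optional data.frame with `chrom`, `start`, `end` of
#'   exons (1-based inclusive).
#' @return data.frame `variant_id`, `category`.
#' @export
annotate_variants <- function(variants, gene_models, promoter_window = 3000,
                              exon_models = NULL) {
  cat_one <- function(chrom, pos) {
    g <- gene_models[gene_models$chrom == chrom, , drop = FALSE]
    if (nrow(g)) {
      if (any(abs(pos - g$tss) <= promoter_window)) return("promoter")
      in_body <- pos >= g$start & pos <= g$end
      if (any(in_body)) {
        if (!is.null(exon_models)) {
          e <- exon_models[exon_models$chrom == chrom, , drop = FALSE]
          if (nrow(e) && any(pos >= e$start & pos <= e$end)) return("exon")
        }
        return("intron")
      }
    }
    "distal_intergenic"
  }
  data.frame(variant_id = variants$variant_id,
             category = mapply(cat_one, variants$chrom, variants$pos,
                               USE.NAMES = FALSE),
             stringsAsFactors = FALSE)
}

#' Map variants to their nearest protein-coding gene
#'
#' Distance is 0 when the position falls inside the gene body, otherwise
#' the distance to the nearer gene boundary.  Only genes on the same
#' chromosome within `max_distance` bp qualify; ties are broken by smaller
#' start coordinate, then lexicographic gene id.  The returned distance is
#' signed: negative when the variant lies before the gene start.
#'
#' @param variants data.frame with `variant_id`, `chrom`, `pos`.
#' @param gene_models gene models (see [read_gene_models()]); non
#'   protein-coding entries are ignored if a `biotype` column is present.
#' @param max_distance maximum mapping distance in bp (default 3e6,
#'   i.e. 3000 kb; genes strictly farther are not assigned).
#' @return data.frame `variant_id`, `gene_id` (`NA` when nothing is in
#'   range), `distance` (absolute bp), `signed_distance`.
#' @export
nearest_gene <- function(variants, gene_models, max_distance = 3e6) {
  if ("biotype" %in% names(gene_models))
    gene_models <- gene_models[gene_models$biotype == "protein_coding", , drop = FALSE]
  by_chrom <- split(gene_models, gene_models$chrom)
  one <- function(chrom, pos) {
    g <- by_chrom[[chrom]]
    if (is.null(g) || !nrow(g))
      return(list(NA_character_, NA_real_, NA_real_))
    inside <- pos >= g$start & pos <= g$end
    dist <- ifelse(inside, 0, pmin(abs(pos - g$start), abs(pos - g$end)))
    ok <- dist <= max_distance
    if (!any(ok)) return(list(NA_character_, NA_real_, NA_real_))
    g <- g[ok, , drop = FALSE]; dist <- dist[ok]
    pick <- order(dist, g$start, g$gene_id)[1]
    sgn <- if (dist[pick] == 0) 0 else if (pos < g$start[pick]) -1 else 1
    list(g$gene_id[pick], dist[pick], sgn * dist[pick])
  }
  res <- mapply(one, variants$chrom, variants$pos, SIMPLIFY = FALSE,
                USE.NAMES = FALSE)
  data.frame(variant_id = variants$variant_id,
             gene_id = vapply(res, function(r) r[[1]], ""),
             distance = vapply(res, function(r) r[[2]], 0),
             signed_distance = vapply(res, function(r) r[[3]], 0),
             stringsAsFactors = FALSE)
}

#' Restrict variants to autosomes
#'
#' Sex-chromosome variants are carried through association testing but are
#' excluded before seed-gene mapping and module construction.
#'
#' @param variants data.frame with a `chrom` column.
#' @return the autosomal subset.
#' @export
autosomal <- function(variants) {
  chr <- sub("^chr", "", variants$chrom)
  variants[chr %in% as.character(1:22), , drop = FALSE]
}
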