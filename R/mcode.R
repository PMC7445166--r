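#' MCODE vertex weights
#'
#' For every vertex `v`, take the subgraph induced by its closed
#' neighborhood `N[v]` (v and its neighbors), find the highest k-core of
#' that subgraph, and set `weight(v) = k * density(core)`, with density
#' `2E / (n (n-1))` for `n >= 2` and weight 0 for isolated vertices.
#' Self-loops are ignored (the graph is expected simple).
#'
#' @param network an undirected simple `igraph` graph.
#' @return named numeric vector of weights, one per vertex.
#' @export
mcode_vertex_weights <- function(network) {
  stopifnot(igraph::is_igraph(network))
  n <- igraph::vcount(network)
  w <- numeric(n)
  names(w) <- igraph::V(network)$name
  adj <- igraph::adjacent_vertices(network, igraph::V(network))
  for (v in seq_len(n)) {
    nb <- unique(c(v, as.integer(adj[[v]])))
    if (length(nb) < 2) next
    sub <- igraph::induced_subgraph(network, nb)
    core <- igraph::coreness(sub)
    k <- max(core)
    if (k < 1) next
    cv <- which(core == k)
    csub <- igraph::induced_subgraph(sub, cv)
    m <- length(cv)
    dens <- if (m >= 2) 2 * igraph::ecount(csub) / (m * (m - 1)) else 0
    w[v] <- k * dens
  }
  w
}

#' MCODE molecular-complex detection
#'
#' Greedy complex growth: seed from the highest-weight unvisited vertex
#' (ties broken lexicographically by name), recursively add unvisited
#' neighbors whose weight is at least `(1 - vwp) * seed weight`, and mark
#' added vertices visited so complexes are vertex-disjoint.
#' Post-processing: complexes whose induced subgraph contains no 2-core
#' are discarded (checked before haircut); the optional haircut then
#' iteratively removes degree-1 vertices within each complex.  Complexes
#' are returned sorted by `score = density * size`, descending (ties:
#' larger first, then seed name).
#'
#' @param network undirected simple `igraph` graph.
#' @param weights vertex weights from [mcode_vertex_weights()]; computed
#'   if missing.
#' @param vwp vertex weight percentage in `[0, 1)`; larger values admit
#'   lighter vertices (default 0.5).
#' @param haircut remove singly-connected vertices from each complex
#'   (default `TRUE`).
#' @param fluff not implemented; must stay `FALSE`.
#' @return list of complexes; each is a list with `members` (character),
#'   `seed`, `score`, `density`, `size`.
#' @export
mcode_find_complexes <- function(network, weights = NULL, vwp = 0.5,
                                 haircut = TRUE, fluff = FALSE) {
  if (vwp < 0 || vwp >= 1) stop("vwp must be in [0, 1)")
  if (isTRUE(fluff)) stop("fluff post-processing is not implemented")
  if (igraph::vcount(network) == 0) return(list())
  if (is.null(weights)) weights <- mcode_vertex_weights(network)
  nm <- igraph::V(network)$name
  stopifnot(length(weights) == length(nm))
  weights <- weights[nm]
  adj <- igraph::adjacent_vertices(network, igraph::V(network))
  visited <- rep(FALSE, length(nm))
  order_seeds <- order(-weights, nm)
  complexes <- list()
  for (s in order_seeds) {
    if (visited[s] || weights[s] <= 0) next
    thr <- (1 - vwp) * weights[s]
    members <- s
    visited[s] <- TRUE
    frontier <- s
    while (length(frontier)) {
      cand <- unique(unlist(lapply(frontier, function(v) as.integer(adj[[v]]))))
      cand <- cand[!visited[cand] & weights[cand] >= thr]
      if (!length(cand)) break
      visited[cand] <- TRUE
      members <- c(members, cand)
      frontier <- cand
    }
    if (length(members) < 2) next
    sub <- igraph::induced_subgraph(network, members)
    if (max(igraph::coreness(sub)) < 2) next       # must contain a 2-core
    if (haircut) {
      repeat {
        deg <- igraph::degree(sub)
        drop <- which(deg <= 1)
        if (!length(drop) || length(drop) == igraph::vcount(sub)) break
        sub <- igraph::delete_vertices(sub, drop)
      }
    }
    msize <- igraph::vcount(sub)
    dens <- if (msize >= 2) 2 * igraph::ecount(sub) / (msize * (msize - 1)) else 0
    complexes[[length(complexes) + 1L]] <-
      list(members = sort(igraph::V(sub)$name), seed = nm[s],
           score = dens * msize, density = dens, size = msize)
  }
  ord <- order(-vapply(complexes, `[[`, 0, "score"),
               -vapply(complexes, `[[`, 0, "size"),
               vapply(complexes, `[[`, "", "seed"))
  complexes[ord]
}

#' Build a phenotype module from seed-enriched complexes
#'
#' Each complex is tested for over-representation of the seed genes by a
#' one-sided (greater) Fisher exact test against the network node
#' universe; the module is the union of complexes with `p < enrich_alpha`.
#' Seeds absent from the network are dropped with a message.
#'
#' @param network undirected `igraph` graph (the node universe).
#' @param complexes list from [mcode_find_complexes()].
#' @param seed_genes character vector of seed gene ids.
#' @param enrich_alpha complex inclusion threshold (strict, default 0.05).
#' @return list with `genes` (module members, sorted), `seeds_contained`,
#'   and `complex_table` (per-complex size, seed overlap, p, included).
#' @export
seed_module <- function(network, complexes, seed_genes, enrich_alpha = 0.05) {
  universe <- igraph::V(network)$name
  unknown <- setdiff(seed_genes, universe)
  if (length(unknown))
    message(length(unknown), " seed gene(s) not in network dropped")
  seeds <- intersect(seed_genes, universe)
  n_univ <- length(universe); n_seed <- length(seeds)
  rows <- lapply(seq_along(complexes), function(i) {
    cx <- complexes[[i]]
    k <- length(intersect(cx$members, seeds))
    p <- phyper(k - 1, n_seed, n_univ - n_seed, length(cx$members),
                lower.tail = FALSE)
    data.frame(complex_id = i, size = length(cx$members), n_seeds = k,
               p_value = p, included = p < enrich_alpha)
  })
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(complex_id = integer(), size = integer(), n_seeds = integer(),
               p_value = numeric(), included = logical())
  genes <- sort(unique(unlist(lapply(which(tab$included), function(i)
    complexes[[i]]$members))))
  if (!length(genes)) warning("no complex enriched for seeds: empty module")
  list(genes = genes, seeds_contained = intersect(seeds, genes),
       complex_table = tab)
}

#' Cross-phenotype toxicity module
#'
#' Genes present in at least `min_overlap` of the three per-phenotype
#' modules, with per-gene membership flags.  Optionally attaches the
#' nominal variants that map to module genes.
#'
#' @param modules named list of exactly three character vectors (gene sets
#'   for neutropenia, leukopenia, thrombocytopenia).
#' @param min_overlap 2 (main analysis) or 3 (stricter validation
#'   analysis).
#' @param variant_gene_map optional data.frame with `variant_id`,
#'   `gene_id` linking nominal variants to their mapped gene.
#' @return list with `genes`, `membership` (logical gene x phenotype
#'   matrix) and `member_variants` (subset of `variant_gene_map` mapping
#'   into the module, or `NULL`).
#' @export
toxicity_overlap <- function(modules, min_overlap = 2,
                             variant_gene_map = NULL) {
  if (length(modules) != 3) stop("need exactly 3 phenotype modules")
  if (!min_overlap %in% 2:3) stop("min_overlap must be 2 or 3")
  if (is.null(names(modules)))
    names(modules) <- c("neutropenia", "leukopenia", "thrombocytopenia")
  empty <- !vapply(modules, length, 0L)
  if (any(empty))
    warning("empty phenotype module(s): ", paste(names(modules)[empty],
                                                 collapse = ", "))
  univ <- sort(unique(unlist(modules)))
  membership <- vapply(modules, function(m) univ %in% m,
                       logical(length(univ)))
  if (!is.matrix(membership))
    membership <- matrix(membership, nrow = length(univ),
                         dimnames = list(univ, names(modules)))
  rownames(membership) <- univ
  keep <- rowSums(membership) >= min_overlap
  genes <- univ[keep]
  mv <- NULL
  if (!is.null(variant_gene_map))
    mv <- variant_gene_map[variant_gene_map$gene_id %in% genes, , drop = FALSE]
  list(genes = genes, membership = membership[keep, , drop = FALSE],
       member_variants = mv)
}
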