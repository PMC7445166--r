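test_that("mcode_vertex_weights on canonical fixtures", {
  # K5: every closed neighborhood is K5 itself -> 4-core, density 1
  k5 <- igraph::make_full_graph(5)
  igraph::V(k5)$name <- letters[1:5]
  expect_equal(unname(mcode_vertex_weights(k5)), rep(4, 5))

  # end vertex of a 3-path: closed neighborhood is a single edge -> 1 * 1
  p3 <- igraph::make_graph(~ a - b, b - c)
  w <- mcode_vertex_weights(p3)
  expect_equal(unname(w["a"]), 1)
  expect_equal(unname(w["c"]), 1)

  # isolated vertex -> 0
  iso <- igraph::make_empty_graph(2, directed = FALSE)
  igraph::V(iso)$name <- c("a", "b")
  expect_equal(unname(mcode_vertex_weights(iso)), c(0, 0))
})

test_that("vertex weights match the subset-enumeration oracle", {
  # exhaustive on 4 vertices here; the 5-vertex exhaustive sweep plus the
  # larger random-graph sweep run in test-acceptance
  for (n in 4) {
    pairs <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
    for (code in 0:(2^nrow(pairs) - 1)) {
      adj <- matrix(0L, n, n, dimnames = list(letters[1:n], letters[1:n]))
      on_bits <- which(bitwAnd(code, 2^(seq_len(nrow(pairs)) - 1)) > 0)
      for (b in on_bits) {
        adj[pairs[b, 1], pairs[b, 2]] <- 1L
        adj[pairs[b, 2], pairs[b, 1]] <- 1L
      }
      g <- graph_from_adj(adj)
      w <- mcode_vertex_weights(g)
      for (v in seq_len(n))
        expect_equal(unname(w[v]), oracle_mcode_weight(adj, v),
                     tolerance = 1e-12)
    }
  }
  # random graphs on 6-8 vertices
  set.seed(55)
  for (i in 1:30) {
    n <- sample(6:8, 1)
    adj <- random_adjacency(n, runif(1, 0.2, 0.8))
    g <- graph_from_adj(adj)
    w <- mcode_vertex_weights(g)
    for (v in seq_len(n))
      expect_equal(unname(w[v]), oracle_mcode_weight(adj, v),
                   tolerance = 1e-12)
  }
})

test_that("mcode_find_complexes on K5 plus a disjoint edge", {
  k5 <- igraph::make_full_graph(5)
  igraph::V(k5)$name <- letters[1:5]
  g <- k5 + igraph::make_graph(~ x - y)
  cx <- mcode_find_complexes(g, vwp = 0.5)
  expect_length(cx, 1)                       # the edge has no 2-core
  expect_setequal(cx[[1]]$members, letters[1:5])
  expect_equal(cx[[1]]$score, 5)             # density 1 * size 5
})

test_that("mcode_find_complexes argument validation and degenerate input", {
  g <- igraph::make_full_graph(3)
  igraph::V(g)$name <- letters[1:3]
  expect_error(mcode_find_complexes(g, vwp = 1), "vwp")
  empty <- igraph::make_empty_graph(0, directed = FALSE)
  expect_length(mcode_find_complexes(empty), 0)
})

test_that("vwp = 0 admits only vertices at least as heavy as the seed", {
  # K4 with a pendant triangle: triangle vertices are lighter
  g <- igraph::make_graph(~ a - b, a - c, a - d, b - c, b - d, c - d,
                          d - e, e - f, f - d)
  w <- mcode_vertex_weights(g)
  cx0 <- mcode_find_complexes(g, w, vwp = 0, haircut = FALSE)
  seedw <- w[cx0[[1]]$seed]
  expect_true(all(w[cx0[[1]]$members] >= seedw))
})

test_that("complexes are vertex-disjoint and contain 2-cores", {
  set.seed(77)
  for (i in 1:20) {
    adj <- random_adjacency(8, 0.4)
    g <- graph_from_adj(adj)
    cx <- mcode_find_complexes(g, vwp = 0.6)
    members <- unlist(lapply(cx, `[[`, "members"))
    expect_equal(anyDuplicated(members), 0)
    for (c_ in cx) {
      sub <- igraph::induced_subgraph(g, c_$members)
      expect_true(igraph::is_connected(sub))
      expect_gte(max(igraph::coreness(sub)), 2)
    }
  }
})

test_that("seed_module enrichment matches the hypergeometric oracle", {
  g <- igraph::make_full_graph(10)
  igraph::V(g)$name <- sprintf("g%03d", 1:10)
  # fake complex table route: one complex of 10 genes holding 5 of 20
  # seeds in a 1000-node universe
  big <- igraph::make_empty_graph(990, directed = FALSE)
  igraph::V(big)$name <- sprintf("u%03d", 1:990)
  net <- g + big
  seeds <- c(sprintf("g%03d", 1:5), sprintf("u%03d", 1:15))
  cx <- list(list(members = sprintf("g%03d", 1:10), seed = "g001",
                  score = 10, density = 1, size = 10))
  sm <- seed_module(net, cx, seeds)
  expect_equal(sm$complex_table$p_value,
               oracle_hyper_greater(5, 20, 980, 10), tolerance = 1e-12)
  expect_true(sm$complex_table$included)
  expect_setequal(sm$genes, sprintf("g%03d", 1:10))
  expect_setequal(sm$seeds_contained, sprintf("g%03d", 1:5))
})

test_that("seed_module degenerate cases", {
  g <- igraph::make_full_graph(6)
  igraph::V(g)$name <- letters[1:6]
  cx <- mcode_find_complexes(g)
  # seeds disjoint from every complex -> empty module (p = 1 boundary)
  expect_warning(sm <- seed_module(g, cx, character()), "empty module")
  expect_length(sm$genes, 0)
  # all nodes are seeds: p = 1 for every complex, strict < alpha -> empty
  expect_warning(sm2 <- seed_module(g, cx, letters[1:6]), "empty module")
  expect_length(sm2$genes, 0)
  # unknown seeds are dropped with a message
  expect_message(suppressWarnings(seed_module(g, cx, c("zz", letters[1:3]))),
                 "dropped")
})

test_that("seed_module recovers the planted module from partial seeds", {
  hits <- bg_rates <- numeric(0)
  for (r in 1:8) {
    cfg <- sim_config(rng_seed = 100 + r)
    net <- simulate_network(cfg)
    w <- mcode_vertex_weights(net$network)
    cx <- mcode_find_complexes(net$network, w, vwp = 0.5)
    set.seed(r)
    seeds <- sample(net$truth$module_genes,
                    round(0.6 * length(net$truth$module_genes)))
    sm <- seed_module(net$network, cx, seeds)
    hits <- c(hits, mean(net$truth$module_genes %in% sm$genes))
    bg_rates <- c(bg_rates, mean(net$truth$background_genes %in% sm$genes))
  }
  expect_gte(mean(hits), 0.8)
  expect_lte(mean(bg_rates), 0.05)
})

test_that("toxicity_overlap membership rules", {
  mods <- list(neutropenia = c("A", "B"), leukopenia = c("B", "C"),
               thrombocytopenia = c("C", "D"))
  expect_setequal(toxicity_overlap(mods, 2)$genes, c("B", "C"))
  expect_length(toxicity_overlap(mods, 3)$genes, 0)
  same <- list(n = c("A", "B"), l = c("A", "B"), t = c("A", "B"))
  expect_setequal(toxicity_overlap(same, 3)$genes, c("A", "B"))
  expect_error(toxicity_overlap(mods[1:2], 2), "exactly 3")
  expect_warning(toxicity_overlap(list(a = character(), b = "X", c = "X"), 2),
                 "empty")
})

test_that("min_overlap = 3 module is always nested in min_overlap = 2", {
  set.seed(13)
  for (i in 1:25) {
    pool <- sprintf("g%02d", 1:30)
    mods <- list(a = sample(pool, 12), b = sample(pool, 15),
                 c = sample(pool, 10))
    g2 <- toxicity_overlap(mods, 2)$genes
    g3 <- toxicity_overlap(mods, 3)$genes
    expect_true(all(g3 %in% g2))
  }
})

test_that("toxicity_overlap attaches member variants", {
  mods <- list(n = c("A", "B"), l = c("B", "C"), t = c("B", "D"))
  vmap <- data.frame(variant_id = c("v1", "v2", "v3"),
                     gene_id = c("B", "D", "A"))
  tox <- toxicity_overlap(mods, 2, variant_gene_map = vmap)
  expect_equal(tox$member_variants$variant_id, "v1")
})
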