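test_that("sim_config validates its invariants", {
  expect_error(sim_config(maf_range = c(0, 0.5)), "maf_range")
  expect_error(sim_config(network = list(p_in = 0.1, p_out = 0.2)), "p_in")
  expect_error(sim_config(n_causal = 50, n_variants = 10), "n_causal")
  expect_error(sim_config(class_counts = c(high = 50, intermediate = 8,
                                           low = 34)), "sum")
  expect_error(sim_config(network = list(n_module_genes = 2)), ">= 3")
})

test_that("simulate_network planted-partition limits", {
  # p_in = 1 on a 5-gene module -> module genes form K5
  cfg <- sim_config(network = list(n_module_genes = 5, n_background_genes = 20,
                                   p_in = 1, p_out = 0))
  net <- simulate_network(cfg)
  sub <- igraph::induced_subgraph(net$network, net$truth$module_genes)
  expect_equal(igraph::ecount(sub), 10)
  # p_out = 0 -> no module-background or background-background edges
  expect_equal(igraph::ecount(net$network), 10)
  expect_true(igraph::is_simple(net$network))
  # module edges carry high-confidence scores
  expect_true(all(igraph::E(sub)$score > 700))
})

test_that("simulation is deterministic under a fixed seed", {
  cfg <- small_cohort_config(seed = 5)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  ea <- igraph::as_data_frame(a$network)
  eb <- igraph::as_data_frame(b$network)
  expect_identical(ea, eb)
  expect_identical(a$genotypes$dosage, b$genotypes$dosage)
  expect_identical(a$phenotypes, b$phenotypes)
  expect_identical(a$expression$counts, b$expression$counts)
})

test_that("class counts are enforced exactly and grades are coherent", {
  co <- simulate_cohort(small_cohort_config(seed = 3))
  cls <- table(toxicity_class(co$phenotypes$grade_maximal))
  expect_equal(unname(cls[c("high", "intermediate", "low")]),
               c(54L, 8L, 34L), ignore_attr = TRUE)
  comp <- pmax(co$phenotypes$grade_neutropenia,
               co$phenotypes$grade_leukopenia,
               co$phenotypes$grade_thrombocytopenia)
  expect_equal(comp, co$phenotypes$grade_maximal)  # max attained
  expect_true(all(unlist(co$phenotypes[, -1]) %in% 0:4))
})

test_that("genotype frequencies follow the configured MAF", {
  cfg <- sim_config(n_samples = 10000,
                    class_counts = c(high = 5625, intermediate = 833,
                                     low = 3542),
                    n_variants = 40, maf_range = c(0.3, 0.3), n_causal = 1,
                    rng_seed = 2)
  gp <- simulate_genotypes_phenotypes(cfg, simulate_network(cfg)$truth,
                                      simulate_gene_models(cfg,
                                        simulate_network(cfg)$truth))
  af <- rowMeans(gp$genotypes$dosage, na.rm = TRUE) / 2
  expect_true(all(abs(af - 0.3) < 0.01))
})

test_that("null model carries no genotype-class signal", {
  set.seed(1)
  aucs <- replicate(60, {
    cfg <- sim_config(n_variants = 30, n_causal = 5, causal_odds_ratio = 1,
                      network = list(n_module_genes = 10,
                                     n_background_genes = 20),
                      rng_seed = sample.int(1e6, 1))
    net <- simulate_network(cfg)
    gm <- simulate_gene_models(cfg, net$truth)
    gp <- simulate_genotypes_phenotypes(cfg, net$truth, gm)
    score <- colSums(gp$genotypes$dosage[gp$truth$causal_variants, ],
                     na.rm = TRUE)
    cls <- toxicity_class(gp$phenotypes$grade_maximal)
    keep <- cls != "intermediate"
    roc_auc(score[keep], cls[keep] == "high")$auc
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
})

test_that("causal variants separate classes more than null variants", {
  set.seed(8)
  ok <- replicate(40, {
    cfg <- sim_config(n_variants = 200, n_causal = 5, causal_odds_ratio = 3,
                      network = list(n_module_genes = 10,
                                     n_background_genes = 20),
                      rng_seed = sample.int(1e6, 1))
    net <- simulate_network(cfg)
    gm <- simulate_gene_models(cfg, net$truth)
    gp <- simulate_genotypes_phenotypes(cfg, net$truth, gm)
    cls <- toxicity_class(gp$phenotypes$grade_maximal)
    diffs <- abs(rowMeans(gp$genotypes$dosage[, cls == "high"], na.rm = TRUE) -
                 rowMeans(gp$genotypes$dosage[, cls == "low"], na.rm = TRUE))
    causal <- gp$truth$causal_variants
    null_q <- quantile(diffs[!names(diffs) %in% causal], 0.95)
    mean(diffs[causal]) > null_q
  })
  expect_gte(mean(ok), 0.8)
})

test_that("genotype columns have no hidden order dependence", {
  cfg <- small_cohort_config(seed = 21, n_variants = 100)
  net <- simulate_network(cfg)
  gm <- simulate_gene_models(cfg, net$truth)
  gp <- simulate_genotypes_phenotypes(cfg, net$truth, gm)
  set.seed(99)
  perm <- sample(nrow(gp$genotypes$dosage))
  sub <- subset_genotypes(gp$genotypes, variants = perm)
  expect_identical(sub$dosage[order(perm), ], gp$genotypes$dosage)
})

test_that("expression generator shifts affected genes line-specifically", {
  cfg <- sim_config(expression = list(treatment_log2fc = 3,
                                      n_affected_module_genes = 10),
                    rng_seed = 6)
  net <- simulate_network(cfg)
  ex <- simulate_expression(cfg, net$truth)
  des <- ex$samples
  aff <- ex$affected_genes
  l1_treated <- des$sample[des$line == "line1" & des$treatment == "drugA"]
  l1_ctrl <- des$sample[des$line == "line1" & des$treatment == "untreated"]
  lfc <- log2((rowMeans(ex$counts[aff, l1_treated]) + 1) /
              (rowMeans(ex$counts[aff, l1_ctrl]) + 1))
  expect_gt(median(lfc), 1.5)
  # drugA in the last line leaves affected genes alone
  l3_treated <- des$sample[des$line == "line3" & des$treatment == "drugA"]
  l3_ctrl <- des$sample[des$line == "line3" & des$treatment == "untreated"]
  lfc3 <- log2((rowMeans(ex$counts[aff, l3_treated]) + 1) /
               (rowMeans(ex$counts[aff, l3_ctrl]) + 1))
  expect_lt(abs(median(lfc3)), 1)
  # constant gene length -> TPM proportional to counts within each sample
  cfg2 <- sim_config(rng_seed = 6)
  ex2 <- simulate_expression(cfg2, net$truth)
  lens <- rep(1000, nrow(ex2$counts))
  tp <- tpm(ex2$counts, lens)
  j <- which(colSums(ex2$counts) > 0)[1]
  nz <- ex2$counts[, j] > 0
  ratio <- tp[nz, j] / ex2$counts[nz, j]
  expect_lt(diff(range(ratio)), 1e-9 * mean(ratio))
})

test_that("write_cohort emits readable files", {
  dir <- withr::local_tempdir()
  co <- simulate_cohort(small_cohort_config(seed = 9, n_variants = 80))
  write_cohort(co, dir)
  inputs <- load_cohort_inputs(dir, min_score = 700)
  expect_equal(length(inputs$genotypes$samples), 96)
  expect_equal(nrow(inputs$phenotypes), 96)
  expect_equal(sort(inputs$gene_models$gene_id),
               sort(c(co$truth$module_genes, co$truth$background_genes)))
  # network file keeps every simulated edge; loader applies the cutoff
  ed <- data.table::fread(file.path(dir, "network.tsv"))
  expect_equal(nrow(ed), igraph::ecount(co$network))
  expect_equal(igraph::ecount(inputs$network),
               sum(ed$combined_score > 700))
})
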