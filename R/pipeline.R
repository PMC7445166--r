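#' Pipeline configuration
#'
#' Collects every tunable the end-to-end run needs.  `mode = "main"`
#' associates on all samples, overlaps modules at `min_overlap = 2` and
#' runs MCODE at `vwp = 0.5`; `mode = "validation"` splits first (the
#' association tables see training samples only), requires overlap of all
#' three toxicities (`min_overlap = 3`) and uses `vwp = 0.1` to
#' compensate for the smaller association sample.  Explicit `vwp` /
#' `min_overlap` arguments override the mode defaults.
#'
#' @param mode `"main"` or `"validation"`.
#' @param alpha inclusive nominal association threshold (default 1e-3).
#' @param vwp MCODE vertex weight percentage (mode default if `NULL`).
#' @param min_overlap module overlap requirement (mode default if `NULL`).
#' @param enrich_alpha complex seed-enrichment threshold (default 0.05).
#' @param min_score strict PPI combined-score cutoff (default 700).
#' @param promoter_window promoter half-width in bp (default 3000).
#' @param max_gene_distance nearest-gene radius in bp (default 3e6).
#' @param validation_fraction held-out fraction per stratum (default 0.2).
#' @param n_perm random-LASSO permutations (default 100000; scale down for
#'   tests).
#' @param penalty_sd sd of the random penalty multipliers (default 0.25).
#' @param quantiles candidate quantile grid (default 0.5-0.9 by 0.1).
#' @param cv_folds CV folds (default 10).
#' @param seed master seed for split, selection and refits.
#' @param out_dir output directory, or `NULL` for in-memory results only.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(mode = c("main", "validation"), alpha = 1e-3,
                            vwp = NULL, min_overlap = NULL,
                            enrich_alpha = 0.05, min_score = 700,
                            promoter_window = 3000, max_gene_distance = 3e6,
                            validation_fraction = 0.2, n_perm = 1e5,
                            penalty_sd = 0.25,
                            quantiles = seq(0.5, 0.9, by = 0.1),
                            cv_folds = 10, seed = 1, out_dir = NULL) {
  mode <- match.arg(mode)
  if (is.null(vwp)) vwp <- if (mode == "main") 0.5 else 0.1
  if (is.null(min_overlap)) min_overlap <- if (mode == "main") 2L else 3L
  structure(list(mode = mode, split_first = mode == "validation",
                 alpha = alpha, vwp = vwp, min_overlap = min_overlap,
                 enrich_alpha = enrich_alpha, min_score = min_score,
                 promoter_window = promoter_window,
                 max_gene_distance = max_gene_distance,
                 validation_fraction = validation_fraction,
                 n_perm = n_perm, penalty_sd = penalty_sd,
                 quantiles = quantiles, cv_folds = cv_folds, seed = seed,
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Load pipeline inputs from a cohort directory
#'
#' Reads the files [write_cohort()] emits: `genotypes.vcf`,
#' `phenotypes.tsv`, `network.tsv`, `gene_models.gff3`.
#'
#' @param dir directory path.
#' @param min_score strict combined-score cutoff for the network.
#' @return list with `genotypes`, `phenotypes`, `network`, `gene_models`.
#' @export
load_cohort_inputs <- function(dir, min_score = 700) {
  list(genotypes = read_vcf(file.path(dir, "genotypes.vcf")),
       phenotypes = read_phenotypes(file.path(dir, "phenotypes.tsv")),
       network = read_network(file.path(dir, "network.tsv"),
                              min_score = min_score),
       gene_models = read_gene_models(file.path(dir, "gene_models.gff3"),
                                      format = "GFF3"))
}

stage_msg <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, sprintf(...)))
}

#' Run the full genotype-to-prediction pipeline
#'
#' Stages: variant QC, stratified split, per-phenotype allelic
#' association, nominal filtering, autosomal nearest-gene seed mapping,
#' MCODE module inference per phenotype, cross-phenotype toxicity-module
#' overlap, random-LASSO selection on the module's member variants,
#' quantile-set evaluation with ridge refits, and prediction of every
#' sample (intermediates included, prediction-only).  In validation mode
#' the association stage sees training samples only.  Deterministic given
#' `config$seed`.  When `config$out_dir` is set, all stage tables, a
#' `manifest.json` (config, seeds, per-stage counts, package version) and
#' the model are written there.
#'
#' @param data list with `genotypes` ([genotype_data()]), `phenotypes`,
#'   `network` (igraph), `gene_models` — e.g. [simulate_cohort()] output
#'   or [load_cohort_inputs()].
#' @param config a [pipeline_config()].
#' @return list with the per-stage results (associations, seeds, modules,
#'   toxicity module, selection frequencies, evaluation table, model,
#'   predictions, AUCs, split, counts).
#' @export
run_pipeline <- function(data, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  phenos <- c("neutropenia", "leukopenia", "thrombocytopenia")
  counts <- list()
  fail <- function(stage, msg) stop("stage '", stage, "' failed: ", msg,
                                    call. = FALSE)

  gd <- qc_filter_variants(data$genotypes)
  counts$variants_raw <- nrow(data$genotypes$variants)
  counts$variants_qc <- nrow(gd$variants)
  stage_msg("qc", "%d of %d variants pass QC", counts$variants_qc,
            counts$variants_raw)
  if (!counts$variants_qc) fail("qc", "no variants left")

  ph <- data$phenotypes[match(gd$samples, data$phenotypes$sample_id), ]
  if (anyNA(ph$sample_id)) fail("phenotypes", "samples missing from table")
  split <- stratified_split(ph, config$validation_fraction, config$seed)
  assoc_ids <- if (config$split_first) split$train else ph$sample_id
  stage_msg("split", "%d train / %d validation / %d prediction-only%s",
            length(split$train), length(split$validation),
            length(split$prediction_only),
            if (config$split_first) " (association on training only)" else "")

  gd_assoc <- subset_genotypes(gd, samples = assoc_ids)
  ph_assoc <- ph[match(assoc_ids, ph$sample_id), ]
  associations <- list(); seeds <- list(); maps <- list(); pca <- list()
  for (p in phenos) {
    grades <- ph_assoc[[paste0("grade_", p)]]
    res <- association_test(gd_assoc, grades, phenotype = p,
                            alpha = config$alpha)
    nom <- filter_nominal(res, config$alpha)
    nom_auto <- autosomal(nom)
    mapped <- nearest_gene(nom_auto, data$gene_models,
                           max_distance = config$max_gene_distance)
    mapped <- mapped[!is.na(mapped$gene_id), , drop = FALSE]
    associations[[p]] <- res
    maps[[p]] <- mapped
    seeds[[p]] <- sort(unique(mapped$gene_id))
    counts[[paste0("nominal_", p)]] <- nrow(nom_auto)
    counts[[paste0("seed_genes_", p)]] <- length(seeds[[p]])
    stage_msg("associate", "%s: %d nominal autosomal variants -> %d seed genes",
              p, nrow(nom_auto), length(seeds[[p]]))
    if (nrow(nom_auto) >= 2) {
      pca[[p]] <- tryCatch(
        pca_genotypes(subset_genotypes(gd, variants = nom_auto$variant_id)),
        error = function(e) NULL)
    }
  }

  weights <- mcode_vertex_weights(data$network)
  complexes <- mcode_find_complexes(data$network, weights, vwp = config$vwp)
  stage_msg("module", "%d MCODE complexes (vwp = %.2f)", length(complexes),
            config$vwp)
  modules <- lapply(phenos, function(p)
    seed_module(data$network, complexes, seeds[[p]],
                enrich_alpha = config$enrich_alpha))
  names(modules) <- phenos
  for (p in phenos) {
    counts[[paste0("module_", p)]] <- length(modules[[p]]$genes)
    stage_msg("module", "%s module: %d genes (%d seeds contained)", p,
              length(modules[[p]]$genes), length(modules[[p]]$seeds_contained))
  }

  vmap <- unique(do.call(rbind, lapply(phenos, function(p)
    data.frame(variant_id = maps[[p]]$variant_id,
               gene_id = maps[[p]]$gene_id, stringsAsFactors = FALSE))))
  tox <- toxicity_overlap(lapply(modules, `[[`, "genes"),
                          min_overlap = config$min_overlap,
                          variant_gene_map = vmap)
  counts$toxicity_module_genes <- length(tox$genes)
  member_variants <- sort(unique(tox$member_variants$variant_id))
  counts$member_variants <- length(member_variants)
  stage_msg("overlap", "toxicity module: %d genes, %d member variants",
            length(tox$genes), length(member_variants))
  if (!length(member_variants))
    fail("overlap", "no nominal variants map into the toxicity module")

  x_all <- build_design(gd, member_variants)
  y_all <- setNames(as.integer(toxicity_class(ph$grade_maximal) == "high"),
                    ph$sample_id)
  tr <- split$train
  te <- if (length(split$validation)) split$validation else split$train
  freqs <- random_lasso_frequencies(
    x_all[tr, , drop = FALSE], y_all[tr], n_perm = config$n_perm,
    cv_folds = config$cv_folds, penalty_sd = config$penalty_sd,
    seed = config$seed)
  stage_msg("select", "%d permutations over %d variants", config$n_perm,
            ncol(x_all))
  sets <- quantile_sets(freqs, config$quantiles)
  evaln <- evaluate_quantile_sets(sets, x_all[tr, , drop = FALSE], y_all[tr],
                                  x_all[te, , drop = FALSE], y_all[te],
                                  cv_folds = config$cv_folds,
                                  seed = config$seed)
  stage_msg("evaluate", "chosen set %s (%d variants), train AUC %.3f, test AUC %.3f",
            evaln$chosen, length(evaln$model$variants),
            evaln$table$auc_train[evaln$table$set == evaln$chosen],
            evaln$table$auc_test[evaln$table$set == evaln$chosen])

  probs <- predict_probability(evaln$model, x_all)
  cls <- toxicity_class(ph$grade_maximal)
  predictions <- data.frame(sample_id = ph$sample_id, class = cls,
                            subset = ifelse(ph$sample_id %in% split$validation,
                                            "validation",
                                            ifelse(ph$sample_id %in% tr,
                                                   "train", "prediction_only")),
                            probability = unname(probs[ph$sample_id]))
  roc_train <- roc_auc(probs[tr], y_all[tr])
  roc_test <- roc_auc(probs[te], y_all[te])

  result <- list(config = config, counts = counts, split = split,
                 associations = associations, variant_gene_map = vmap,
                 seeds = seeds, pca = pca, complexes = complexes,
                 modules = modules, toxicity_module = tox,
                 member_variants = member_variants,
                 selection_frequencies = freqs, quantile_sets = sets,
                 evaluation = evaln$table, chosen_set = evaln$chosen,
                 model = evaln$model, predictions = predictions,
                 auc_train = roc_train$auc, auc_test = roc_test$auc,
                 roc_train = roc_train$roc, roc_test = roc_test$roc)
  if (!is.null(config$out_dir)) write_pipeline_outputs(result, config$out_dir)
  result
}

write_pipeline_outputs <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (p in names(result$associations))
    write_table(result$associations[[p]], file.path(dir, paste0("association_", p, ".tsv")))
  for (p in names(result$modules)) {
    mod <- result$modules[[p]]
    write_table(data.frame(gene = mod$genes,
                           is_seed = mod$genes %in% mod$seeds_contained),
                file.path(dir, paste0("module_", p, ".tsv")))
  }
  for (p in names(result$pca)) {
    pc <- result$pca[[p]]
    if (is.null(pc)) next
    write_table(data.frame(sample_id = rownames(pc$scores), pc$scores),
                file.path(dir, paste0("pca_", p, ".tsv")))
  }
  mem <- as.data.frame(result$toxicity_module$membership)
  write_table(cbind(data.frame(gene = result$toxicity_module$genes), mem),
              file.path(dir, "toxicity_module.tsv"))
  write_table(result$toxicity_module$member_variants,
              file.path(dir, "member_variants.tsv"))
  write_table(result$selection_frequencies,
              file.path(dir, "selection_frequencies.tsv"))
  write_table(result$evaluation, file.path(dir, "evaluation.tsv"))
  write_table(data.frame(term = c("(Intercept)", result$model$variants),
                         coefficient = c(result$model$intercept,
                                         unname(result$model$coefficients))),
              file.path(dir, "model.tsv"))
  write_table(result$predictions, file.path(dir, "predictions.tsv"))
  write_table(cbind(subset = "train", result$roc_train),
              file.path(dir, "roc_train.tsv"))
  write_table(cbind(subset = "test", result$roc_test),
              file.path(dir, "roc_test.tsv"))
  cfg <- result$config; class(cfg) <- NULL
  cfg_json <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA)
  tmp <- file.path(dir, "config.json")
  writeLines(cfg_json, tmp)
  manifest <- list(
    package = "toxmod",
    version = as.character(utils::packageVersion("toxmod")),
    r_version = R.version.string,
    config = jsonlite::fromJSON(cfg_json),
    config_md5 = unname(tools::md5sum(tmp)),
    seed = cfg$seed,
    counts = result$counts,
    chosen_set = result$chosen_set,
    auc_train = result$auc_train,
    auc_test = result$auc_test)
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE),
             file.path(dir, "manifest.json"))
  invisible(dir)
}

#' Summarize a pipeline result directory
#'
#' Writes `summary.txt` (per-stage counts, chosen model, AUCs) and
#' `report.pdf` (selection-frequency histogram, predicted-probability
#' strip plot by class, ROC curves, and PCA scatters when available) into
#' the directory.  Missing stage files are reported, not fatal.
#'
#' @param result_dir directory written by [run_pipeline()].
#' @return path of the summary file, invisibly.
#' @export
report <- function(result_dir) {
  mf_path <- file.path(result_dir, "manifest.json")
  lines <- c("toxmod pipeline report", strrep("=", 22))
  mf <- NULL
  if (file.exists(mf_path)) {
    mf <- jsonlite::fromJSON(mf_path)
    lines <- c(lines,
               sprintf("mode: %s   seed: %s", mf$config$mode, mf$seed),
               sprintf("chosen set: %s", mf$chosen_set),
               sprintf("train AUC: %.3f   test AUC: %.3f",
                       mf$auc_train, mf$auc_test),
               "stage counts:",
               sprintf("  %-28s %s", names(mf$counts), unlist(mf$counts)))
  } else {
    lines <- c(lines, "NOTICE: manifest.json missing; partial report")
  }
  tox_path <- file.path(result_dir, "toxicity_module.tsv")
  if (file.exists(tox_path)) {
    n <- nrow(data.table::fread(tox_path))
    lines <- c(lines, sprintf("toxicity module: %d genes%s", n,
                              if (!n) " (EMPTY)" else ""))
  }
  pdf_path <- file.path(result_dir, "report.pdf")
  pdf(pdf_path, width = 7, height = 5)
  on.exit(dev.off())
  fr_path <- file.path(result_dir, "selection_frequencies.tsv")
  if (file.exists(fr_path)) {
    fr <- data.table::fread(fr_path)
    hist(fr$frequency, breaks = 30, main = "Random-LASSO selection frequencies",
         xlab = "selection frequency", col = "grey80")
  }
  pr_path <- file.path(result_dir, "predictions.tsv")
  if (file.exists(pr_path)) {
    pr <- data.table::fread(pr_path)
    stripchart(probability ~ class, data = pr, vertical = TRUE,
               method = "jitter", pch = 16,
               col = c("forestgreen", "orange", "red"),
               main = "Predicted probability of high toxicity",
               ylab = "probability")
  }
  both <- file.path(result_dir, c("roc_train.tsv", "roc_test.tsv"))
  if (all(file.exists(both))) {
    rt <- data.table::fread(both[1]); rv <- data.table::fread(both[2])
    plot(rt$fpr, rt$tpr, type = "s", col = "black", lwd = 2,
         xlab = "false positive rate", ylab = "true positive rate",
         main = "ROC"); abline(0, 1, lty = 3)
    lines(rv$fpr, rv$tpr, type = "s", col = "grey50", lwd = 2)
    legend("bottomright", c("train", "test"), col = c("black", "grey50"),
           lwd = 2, bty = "n")
  }
  for (f in list.files(result_dir, pattern = "^pca_.*\\.tsv$",
                       full.names = TRUE)) {
    pc <- data.table::fread(f)
    if (all(c("PC1", "PC2") %in% names(pc)))
      plot(pc$PC1, pc$PC2, pch = 16, main = basename(f),
           xlab = "PC1", ylab = "PC2")
  }
  out <- file.path(result_dir, "summary.txt")
  writeLines(lines, out)
  invisible(out)
}
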