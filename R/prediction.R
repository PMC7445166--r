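#' Build a design matrix of additive dosages
#'
#' Samples x variants matrix restricted to the requested variants (the
#' nominal variants mapping to toxicity-module genes, in pipeline use).
#' Residual missing dosages are imputed to the per-variant mode (ties go
#' to the smaller dosage), preserving integer dosage semantics.
#'
#' @param gd a [genotype_data()] object.
#' @param variant_ids columns to keep, in order.
#' @param samples optional sample subset/order.
#' @return numeric matrix with sample rownames and variant colnames, no
#'   missing values.
#' @export
build_design <- function(gd, variant_ids, samples = NULL) {
  sub <- subset_genotypes(gd, variants = variant_ids, samples = samples)
  x <- t(sub$dosage)
  for (j in seq_len(ncol(x))) {
    mis <- is.na(x[, j])
    if (any(mis)) {
      tab <- tabulate(x[!mis, j] + 1L, nbins = 3L)
      x[mis, j] <- which.max(tab) - 1L       # ties -> smaller dosage
    }
  }
  storage.mode(x) <- "double"
  x
}

#' Stratified train/validation split
#'
#' Per high/low stratum, `floor(validation_fraction * n)` samples are
#' drawn uniformly (seeded) for validation and the remainder trains.
#' Intermediates never train or validate: they go to a prediction-only
#' pool.  With the stated 54/8/34 cohort and fraction 0.2 this reproduces
#' a 44/10 high, 0/8 intermediate, 28/6 low split.
#'
#' @param phenotypes data.frame with `sample_id` and `grade_maximal`.
#' @param validation_fraction fraction withheld per stratum (default 0.2).
#' @param seed RNG seed.
#' @return list with `train`, `validation`, `prediction_only` sample ids
#'   and a per-stratum `table`.
#' @export
stratified_split <- function(phenotypes, validation_fraction = 0.2, seed = 1) {
  if (validation_fraction < 0 || validation_fraction >= 1)
    stop("validation_fraction must be in [0, 1)")
  cls <- toxicity_class(phenotypes$grade_maximal)
  ids <- as.character(phenotypes$sample_id)
  set.seed(seed)
  pick <- function(stratum) {
    s_ids <- ids[cls == stratum]
    if (length(s_ids) < 2) stop("stratum '", stratum, "' has fewer than 2 samples")
    n_val <- floor(validation_fraction * length(s_ids))
    val <- if (n_val > 0) sample(s_ids, n_val) else character()
    list(train = setdiff(s_ids, val), validation = val)
  }
  hi <- pick("high"); lo <- pick("low")
  inter <- ids[cls == "intermediate"]
  tab <- data.frame(
    stratum = c("high", "intermediate", "low"),
    n_train = c(length(hi$train), 0L, length(lo$train)),
    n_validation = c(length(hi$validation), length(inter), length(lo$validation)))
  list(train = c(hi$train, lo$train),
       validation = c(hi$validation, lo$validation),
       prediction_only = inter, table = tab)
}

# stratified fold ids: classes spread as evenly as possible across folds
stratified_folds <- function(y, k) {
  foldid <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    foldid[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  foldid
}

# one L1 path + k-fold CV; returns indices of variants with nonzero
# coefficient at the deviance-minimizing lambda.  Lean replacement for
# cv.glmnet: same lambda path, same binomial deviance criterion, but no
# per-call bookkeeping, which matters at 1e3-1e5 permutations.
lasso_cv_select <- function(x, y, penalty_factor, foldid, n_lambda, thresh) {
  full <- glmnet::glmnet(x, y, family = "binomial", alpha = 1,
                         nlambda = n_lambda, penalty.factor = penalty_factor,
                         thresh = thresh)
  lam <- full$lambda
  k <- max(foldid)
  dev <- matrix(NA_real_, k, length(lam))
  for (f in seq_len(k)) {
    hold <- foldid == f
    fit <- glmnet::glmnet(x[!hold, , drop = FALSE], y[!hold],
                          family = "binomial", alpha = 1, lambda = lam,
                          penalty.factor = penalty_factor, thresh = thresh)
    eta <- predict(fit, x[hold, , drop = FALSE])
    mu <- pmin(pmax(1 / (1 + exp(-eta)), 1e-10), 1 - 1e-10)
    d <- -2 * (y[hold] * log(mu) + (1 - y[hold]) * log(1 - mu))
    dev[f, seq_len(ncol(eta))] <- colMeans(d)
  }
  cvm <- colMeans(dev, na.rm = TRUE)
  imin <- which.min(cvm)
  which(full$beta[, imin] != 0)
}

#' Random-LASSO selection frequencies
#'
#' Repeats, `n_perm` times: draw per-variant penalty multipliers from
#' `Normal(1, penalty_sd)` truncated below at 0.01, fit an L1-penalized
#' logistic path of `n_lambda` values with `cv_folds`-fold stratified
#' cross-validation, and at the deviance-minimizing penalty (lambda.min)
#' increment the selection count of every variant with a nonzero
#' coefficient.  Observations are never resampled unless `row_subsample`
#' is set; the randomness is the penalty draw plus the fold assignment.
#' A master seed spawns one seed per permutation, so runs are reproducible
#' and could be sharded.
#'
#' @param x complete samples x variants design matrix (see
#'   [build_design()]).
#' @param y binary response, 1 = high toxicity, 0 = low.
#' @param n_perm number of randomized fits (default 100000, matching the
#'   full-scale procedure; tests use far fewer).
#' @param cv_folds folds for the internal CV (default 10).
#' @param n_lambda path length (default 100).
#' @param penalty_sd sd of the random penalty multipliers (default 0.25).
#' @param seed master seed.
#' @param row_subsample optional fraction of rows drawn (without
#'   replacement) per permutation; `NULL` (default) uses all rows.
#' @param thresh glmnet convergence threshold; the slightly relaxed
#'   default (1e-5) halves runtime with no visible effect on selection
#'   counts.
#' @return data.frame of class `selection_frequency`: `variant_id`,
#'   `count`, `n_perm`, `frequency`, sorted by decreasing count.
#' @export
random_lasso_frequencies <- function(x, y, n_perm = 1e5, cv_folds = 10,
                                     n_lambda = 100, penalty_sd = 0.25,
                                     seed = 1, row_subsample = NULL,
                                     thresh = 1e-5) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  y <- as.numeric(y)
  if (length(unique(y)) < 2) stop("y must contain both classes")
  if (anyNA(x)) stop("design matrix contains missing values")
  p <- ncol(x)
  counts <- integer(p)
  set.seed(seed)
  perm_seeds <- sample.int(2147483646L, n_perm)
  for (i in seq_len(n_perm)) {
    set.seed(perm_seeds[i])
    pf <- pmax(rnorm(p, 1, penalty_sd), 0.01)
    xi <- x; yi <- y
    if (!is.null(row_subsample)) {
      take <- sort(sample.int(nrow(x), max(2L, round(row_subsample * nrow(x)))))
      xi <- x[take, , drop = FALSE]; yi <- y[take]
      if (length(unique(yi)) < 2) next
    }
    foldid <- stratified_folds(yi, cv_folds)
    sel <- lasso_cv_select(xi, yi, pf, foldid, n_lambda, thresh)
    counts[sel] <- counts[sel] + 1L
  }
  out <- data.frame(variant_id = colnames(x), count = counts,
                    n_perm = n_perm, frequency = counts / n_perm,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$variant_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("selection_frequency", "data.frame")
  out
}

#' Quantile candidate sets from selection frequencies
#'
#' For each quantile `q`, the set contains every variant whose selection
#' frequency is at least the empirical `q`-quantile of the observed
#' frequencies (ties included), so the sets are nested and decrease with
#' `q`.  With 123 distinct frequencies the 0.5 set has 62 variants; with
#' 104 distinct, 52.
#'
#' @param freq_table data.frame from [random_lasso_frequencies()].
#' @param quantiles numeric vector in (0, 1) (default 0.5 to 0.9 by 0.1).
#' @return named list of character vectors (`"q0.5"`, ...).
#' @export
quantile_sets <- function(freq_table, quantiles = seq(0.5, 0.9, by = 0.1)) {
  if (!nrow(freq_table)) stop("empty frequency table")
  f <- freq_table$frequency
  out <- lapply(quantiles, function(q) {
    thr <- quantile(f, q, type = 7, names = FALSE)
    freq_table$variant_id[f >= thr]
  })
  names(out) <- paste0("q", quantiles)
  out
}

#' Ridge refit of a candidate variant set (no L1 selection)
#'
#' Fits an L2-penalized logistic path (`alpha = 0`) with stratified
#' `cv_folds`-fold cross-validation and keeps the deviance-minimizing
#' penalty, so every requested variant retains a (possibly small) nonzero
#' coefficient and separation cannot blow the coefficients up.
#'
#' @param x samples x variants design matrix restricted to the candidate
#'   set.
#' @param y binary response.
#' @param cv_folds folds (default 10).
#' @param seed RNG seed for fold assignment.
#' @return object of class `toxmod_model`: `variants`, `intercept`,
#'   `coefficients`, `lambda`, `alpha`.
#' @export
refit_no_shrinkage <- function(x, y, cv_folds = 10, seed = 1) {
  if (is.null(dim(x)) || ncol(x) < 1) stop("empty candidate set")
  y <- as.numeric(y)
  if (length(unique(y)) < 2) stop("y must contain both classes")
  pad <- ncol(x) == 1L                     # glmnet needs >= 2 columns
  xx <- if (pad) cbind(x, `.pad.` = 0) else x
  set.seed(seed)
  foldid <- stratified_folds(y, cv_folds)
  cv <- glmnet::cv.glmnet(xx, y, family = "binomial", alpha = 0,
                          nlambda = 100, foldid = foldid,
                          type.measure = "deviance")
  cf <- as.matrix(coef(cv, s = "lambda.min"))[, 1]
  beta <- cf[-1]
  if (pad) beta <- beta[colnames(x)]
  structure(list(variants = colnames(x), intercept = unname(cf[1]),
                 coefficients = setNames(unname(beta), colnames(x)),
                 lambda = cv$lambda.min, alpha = 0),
            class = "toxmod_model")
}

#' @export
print.toxmod_model <- function(x, ...) {
  cat(sprintf("toxmod_model: %d variants, ridge lambda = %.4g\n",
              length(x$variants), x$lambda))
  invisible(x)
}

#' Predicted probability of high toxicity
#'
#' Inverse-logit of the linear predictor.  Intermediates are scored like
#' any other sample.
#'
#' @param model a `toxmod_model` from [refit_no_shrinkage()].
#' @param x_new samples x variants matrix containing every model variant
#'   as a column (extra columns are ignored).
#' @return named numeric vector of probabilities in `[0, 1]`.
#' @export
predict_probability <- function(model, x_new) {
  stopifnot(inherits(model, "toxmod_model"))
  miss <- setdiff(model$variants, colnames(x_new))
  if (length(miss))
    stop("variant(s) missing from new data: ", paste(head(miss, 5), collapse = ", "))
  eta <- model$intercept +
    drop(x_new[, model$variants, drop = FALSE] %*% model$coefficients)
  plogis(setNames(eta, rownames(x_new)))
}

#' ROC curve and AUC
#'
#' AUC is the Mann-Whitney U statistic divided by `n_pos * n_neg`, with
#' tied scores counted 1/2; ROC points are emitted at every distinct
#' threshold.  Intermediates must be excluded before calling.
#'
#' @param scores numeric predictions (higher = more case-like).
#' @param labels binary labels (1/TRUE = case); both classes required.
#' @return list with `auc` and `roc` (data.frame `threshold`, `tpr`,
#'   `fpr`, starting at (0,0) and ending at (1,1)).
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels)) stop("length mismatch")
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) stop("both classes required")
  r <- rank(scores)                        # midranks handle ties
  auc <- (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(labels & scores >= t) / n_pos, 0)
  fpr <- vapply(thr, function(t) sum(!labels & scores >= t) / n_neg, 0)
  roc <- data.frame(threshold = c(Inf, thr), tpr = c(0, tpr), fpr = c(0, fpr))
  list(auc = auc, roc = roc)
}

#' Evaluate quantile candidate sets and choose the best model
#'
#' Each candidate set is ridge-refitted on the training data and scored on
#' training and test data; the chosen set maximizes test AUC, with ties
#' broken by fewer variants, then higher training AUC.
#'
#' @param sets named list from [quantile_sets()].
#' @param x_train,y_train training design and response.
#' @param x_test,y_test held-out design and response.
#' @param cv_folds folds for each refit.
#' @param seed RNG seed.
#' @return list with `table` (per-set sizes and AUCs), `chosen` (set
#'   name) and `model` (the winning `toxmod_model`).
#' @export
evaluate_quantile_sets <- function(sets, x_train, y_train, x_test, y_test,
                                   cv_folds = 10, seed = 1) {
  if (!length(sets)) stop("no candidate sets")
  models <- vector("list", length(sets))
  rows <- vector("list", length(sets))
  for (i in seq_along(sets)) {
    v <- sets[[i]]
    m <- refit_no_shrinkage(x_train[, v, drop = FALSE], y_train,
                            cv_folds = cv_folds, seed = seed + i)
    tr <- roc_auc(predict_probability(m, x_train), y_train)$auc
    te <- roc_auc(predict_probability(m, x_test), y_test)$auc
    models[[i]] <- m
    rows[[i]] <- data.frame(set = names(sets)[i], n_variants = length(v),
                            auc_train = tr, auc_test = te,
                            stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  best <- order(-tab$auc_test, tab$n_variants, -tab$auc_train)[1]
  list(table = tab, chosen = tab$set[best], model = models[[best]])
}
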