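make_pheno <- function(n_high = 54, n_int = 8, n_low = 34) {
  data.frame(sample_id = sprintf("S%03d", seq_len(n_high + n_int + n_low)),
             grade_maximal = rep(c(4L, 2L, 0L), c(n_high, n_int, n_low)))
}

test_that("stratified_split reproduces the 44/10, 0/8, 28/6 design", {
  sp <- stratified_split(make_pheno(), validation_fraction = 0.2, seed = 1)
  expect_equal(sp$table$n_train, c(44L, 0L, 28L))
  expect_equal(sp$table$n_validation, c(10L, 8L, 6L))
  expect_length(intersect(sp$train, sp$validation), 0)
  expect_length(sp$prediction_only, 8)
  # intermediates never train
  expect_false(any(sp$prediction_only %in% sp$train))
})

test_that("stratified_split determinism and edge cases", {
  ph <- make_pheno()
  expect_identical(stratified_split(ph, seed = 42),
                   stratified_split(ph, seed = 42))
  all_train <- stratified_split(ph, validation_fraction = 0, seed = 1)
  expect_length(all_train$validation, 0)
  expect_length(all_train$train, 88)
  expect_error(stratified_split(make_pheno(n_low = 1)), "fewer than 2")
})

test_that("quantile_sets implements the tie-inclusive quantile rule", {
  tab <- data.frame(variant_id = sprintf("v%03d", 1:123),
                    count = 1000 - seq_len(123), n_perm = 1000,
                    frequency = (1000 - seq_len(123)) / 1000)
  sets <- quantile_sets(tab)
  expect_length(sets$q0.5, 62)              # 62 of 123 distinct
  tab104 <- tab[1:104, ]
  expect_length(quantile_sets(tab104)$q0.5, 52)   # 52 of 104 distinct
  # all-equal frequencies: every set is everything
  tab_tie <- transform(tab, frequency = 0.4)
  expect_true(all(lengths(quantile_sets(tab_tie)) == 123))
  # nesting
  for (i in seq_len(length(sets) - 1))
    expect_true(all(sets[[i + 1]] %in% sets[[i]]))
  expect_error(quantile_sets(tab[0, ]), "empty")
})

test_that("random_lasso_frequencies validates inputs and bounds counts", {
  set.seed(5)
  x <- matrix(rbinom(40 * 12, 2, 0.3), 40, 12,
              dimnames = list(NULL, sprintf("v%02d", 1:12)))
  y <- rbinom(40, 1, 0.5)
  expect_error(random_lasso_frequencies(x, rep(1, 40), n_perm = 2),
               "both classes")
  expect_error(random_lasso_frequencies(x, y, n_perm = 0), "n_perm")
  fr <- random_lasso_frequencies(x, y, n_perm = 25, seed = 2)
  expect_true(all(fr$count >= 0 & fr$count <= 25))
  expect_equal(fr$frequency, fr$count / 25)
  expect_setequal(fr$variant_id, colnames(x))
  # reproducible under the master seed
  fr2 <- random_lasso_frequencies(x, y, n_perm = 25, seed = 2)
  expect_identical(fr, fr2)
})

test_that("a strongly associated variant dominates selection frequencies", {
  set.seed(31)
  n <- 96
  x <- matrix(rbinom(n * 51, 2, 0.3), n, 51,
              dimnames = list(NULL, c("planted", sprintf("null%02d", 1:50))))
  eta <- log(5) * x[, "planted"] + rlogis(n)
  y <- as.integer(eta > median(eta))
  fr <- random_lasso_frequencies(x, y, n_perm = 200, seed = 7)
  planted_f <- fr$frequency[fr$variant_id == "planted"]
  null_f <- fr$frequency[fr$variant_id != "planted"]
  expect_gt(planted_f, quantile(null_f, 0.95))
})

test_that("refit_no_shrinkage survives separation and single columns", {
  x <- matrix(c(rep(2, 10), rep(0, 10)), ncol = 1,
              dimnames = list(sprintf("s%d", 1:20), "v1"))
  y <- c(rep(1, 10), rep(0, 10))
  m <- suppressWarnings(refit_no_shrinkage(x, y, seed = 1))  # tiny folds
  expect_true(all(is.finite(c(m$intercept, m$coefficients))))
  p <- predict_probability(m, x)
  expect_true(all(p[1:10] > p[11:20]))
})

test_that("null refit gives chance-level training AUC", {
  set.seed(17)
  aucs <- replicate(10, {
    x <- matrix(rbinom(78 * 10, 2, 0.3), 78, 10,
                dimnames = list(sprintf("s%d", 1:78), sprintf("v%d", 1:10)))
    y <- rbinom(78, 1, 0.5)
    m <- refit_no_shrinkage(x, y, seed = sample.int(1e6, 1))
    roc_auc(predict_probability(m, x), y)$auc
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.15)
})

test_that("ridge treats duplicated columns symmetrically", {
  set.seed(23)
  x <- matrix(rbinom(60 * 3, 2, 0.4), 60, 3,
              dimnames = list(sprintf("s%d", 1:60), c("a", "b", "c")))
  y <- as.integer(x[, 1] + rnorm(60) > 1)
  xd <- cbind(x, a2 = x[, "a"])
  m <- refit_no_shrinkage(xd, y, seed = 4)
  # the two copies share the load equally (up to solver tolerance)
  expect_equal(unname(m$coefficients["a"]), unname(m$coefficients["a2"]),
               tolerance = 1e-3)
  # symmetry oracle at a fixed penalty: duplicating the whole design at
  # lambda equals the original design at lambda / 2
  xdd <- cbind(x, x)
  colnames(xdd) <- c(colnames(x), paste0(colnames(x), "2"))
  lam <- 0.7
  f1 <- glmnet::glmnet(x, y, family = "binomial", alpha = 0,
                       lambda = lam / 2, standardize = FALSE,
                       thresh = 1e-14, maxit = 1e7)
  f2 <- glmnet::glmnet(xdd, y, family = "binomial", alpha = 0,
                       lambda = lam, standardize = FALSE,
                       thresh = 1e-14, maxit = 1e7)
  expect_equal(unname(predict(f1, x)[, 1]), unname(predict(f2, xdd)[, 1]),
               tolerance = 1e-6)
})

test_that("predict_probability closed forms", {
  m <- structure(list(variants = c("v1", "v2"), intercept = 0,
                      coefficients = c(v1 = 0, v2 = 0), lambda = 0.1,
                      alpha = 0), class = "toxmod_model")
  x <- matrix(c(0, 2, 1, 1), 2, 2, dimnames = list(c("s1", "s2"),
                                                   c("v1", "v2")))
  expect_equal(unname(predict_probability(m, x)), c(0.5, 0.5))
  m$coefficients <- c(v1 = 1.2, v2 = -0.4)
  m$intercept <- 0.3
  eta <- 0.3 + x %*% c(1.2, -0.4)
  expect_equal(unname(predict_probability(m, x)), unname(plogis(eta)[, 1]),
               tolerance = 1e-12)
  # monotone in a positive-coefficient variant
  x2 <- cbind(v1 = 0:2, v2 = 1)
  rownames(x2) <- sprintf("r%d", 1:3)
  expect_false(is.unsorted(predict_probability(m, x2)))
  expect_error(predict_probability(m, x[, "v1", drop = FALSE]), "v2")
})

test_that("roc_auc fixtures and symmetry", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))$auc, 1)
  expect_equal(roc_auc(rep(0.5, 6), c(1, 1, 1, 0, 0, 0))$auc, 0.5)
  set.seed(12)
  s <- rnorm(40); l <- rbinom(40, 1, 0.5)
  if (sum(l) %in% c(0, 40)) l[1] <- 1 - l[1]
  expect_equal(roc_auc(s, l)$auc + roc_auc(-s, l)$auc, 1)
  expect_error(roc_auc(s, rep(1, 40)), "both classes")
  # ROC endpoints
  r <- roc_auc(s, l)$roc
  expect_equal(unlist(r[1, c("tpr", "fpr")], use.names = FALSE), c(0, 0))
  expect_equal(unlist(r[nrow(r), c("tpr", "fpr")], use.names = FALSE), c(1, 1))
})

test_that("roc_auc equals the all-pairs oracle on random vectors", {
  set.seed(3)
  for (i in 1:60) {
    n <- sample(5:200, 1)
    ties <- runif(1) < 0.5
    s <- if (ties) sample(1:5, n, replace = TRUE) else rnorm(n)
    l <- rbinom(n, 1, runif(1, 0.2, 0.8))
    if (sum(l) %in% c(0, n)) l[1] <- 1 - l[1]
    expect_equal(roc_auc(s, l)$auc, oracle_auc(s, l), tolerance = 1e-12)
  }
})

test_that("evaluate_quantile_sets chooses sensibly", {
  set.seed(64)
  n <- 88
  x <- matrix(rbinom(n * 20, 2, 0.3), n, 20,
              dimnames = list(sprintf("s%d", 1:n),
                              c(sprintf("sig%d", 1:5), sprintf("nul%d", 1:15))))
  eta <- x[, 1:5] %*% rep(log(8), 5) + rlogis(n)
  y <- as.integer(eta > median(eta))
  tr <- 1:60; te <- 61:88
  sets <- list(signal = colnames(x)[1:5], noise = colnames(x)[6:10])
  ev <- evaluate_quantile_sets(sets, x[tr, ], y[tr], x[te, ], y[te], seed = 2)
  expect_equal(ev$chosen, "signal")
  one <- evaluate_quantile_sets(sets["noise"], x[tr, ], y[tr], x[te, ],
                                y[te], seed = 2)
  expect_equal(one$chosen, "noise")
  expect_error(evaluate_quantile_sets(list(), x[tr, ], y[tr], x[te, ], y[te]),
               "no candidate")
})

test_that("build_design imputes to the per-variant mode", {
  dos <- matrix(c(0L, 0L, 2L, NA,
                  1L, 1L, NA, 1L), 2, 4, byrow = TRUE)
  gd <- make_gd(dos)
  x <- build_design(gd, c("v01", "v02"))
  expect_equal(unname(x[4, "v01"]), 0)      # mode of (0,0,2), tie impossible
  expect_equal(unname(x[3, "v02"]), 1)
  expect_false(anyNA(x))
  # tie between dosages resolves to the smaller one
  dos2 <- matrix(c(0L, 2L, NA), 1, 3)
  x2 <- build_design(make_gd(dos2), "v01")
  expect_equal(unname(x2[3, 1]), 0)
})
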