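test_that("stratified folds balance class proportions and partition all cases", {
  labels <- c(rep(0, 42), rep(1, 36))
  f <- make_stratified_folds(labels, 10, seed = 3)
  expect_length(f, 78)
  expect_setequal(unique(f), 1:10)
  tb <- table(f, labels)
  expect_true(all(tb[, "0"] %in% 4:5))
  expect_true(all(tb[, "1"] %in% 3:4))
  expect_identical(f, make_stratified_folds(labels, 10, seed = 3))
  f2 <- make_stratified_folds(c(0, 0, 1, 1), 2, seed = 1)
  expect_equal(unname(table(f2, c(0, 0, 1, 1))), matrix(1L, 2, 2),
               ignore_attr = TRUE)
  expect_error(make_stratified_folds(c(0, 1), 3, 1), class = "dynrad_fold_error")
  expect_warning(make_stratified_folds(c(0, rep(1, 9)), 5, 1),
                 "fewer members than folds")
})

test_that("AUC equals exhaustive positive/negative pair counting", {
  or_auc <- function(scores, labels) {
    pos <- scores[labels == 1]; neg <- scores[labels == 0]
    tot <- 0
    for (p in pos) for (n in neg)
      tot <- tot + (p > n) + 0.5 * (p == n)
    tot / (length(pos) * length(neg))
  }
  expect_equal(auc_score(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  set.seed(13)
  for (i in 1:20) {
    s <- round(runif(14), 1)  # rounding forces ties
    y <- sample(c(0, 1), 14, replace = TRUE)
    if (length(unique(y)) < 2) next
    expect_equal(auc_score(s, y), or_auc(s, y))
    # monotone transforms leave AUC unchanged
    expect_equal(auc_score(exp(3 * s), y), auc_score(s, y))
    # complement symmetry (ties counted half on both sides)
    expect_equal(auc_score(s, y) + auc_score(-s, y), 1)
  }
  expect_equal(auc_score(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)
  expect_equal(auc_score(rep(2, 6), c(0, 1, 0, 1, 0, 1)), 0.5)
  expect_error(auc_score(1:3, c(1, 1, 1)), class = "dynrad_class_error")
})

test_that("tie-free scores satisfy the complement identity exactly", {
  set.seed(17)
  s <- rnorm(20); y <- rep(0:1, 10)
  expect_equal(auc_score(s, y) + auc_score(-s, y), 1)
})

test_that("a perfectly separating feature yields AUC 1 for LR and SVM", {
  y <- rep(0:1, each = 12)
  x <- cbind(sep = y + 0.01 * seq_along(y), pad = rnorm(24))
  ev <- suppressWarnings(
    evaluate_feature_set(x, y, models = model_registry()[c("LR", "SVM")],
                         cv = cv_config(n_folds = 4, seed = 2)))
  expect_equal(unname(ev$auc["LR"]), 1)
  expect_equal(unname(ev$auc["SVM"]), 1)
})

test_that("the registry holds ten models that all emit continuous scores", {
  reg <- model_registry()
  expect_length(reg, 10)
  expect_setequal(names(reg), c("NB", "LR", "DT", "GBDT", "nn", "KNN", "Ada",
                                "DA", "RF", "SVM"))
  set.seed(23)
  x <- matrix(rnorm(40 * 4), 40); colnames(x) <- paste0("f", 1:4)
  y <- rep(0:1, each = 20)
  x[, 1] <- x[, 1] + y
  ev <- evaluate_feature_set(x, y, cv = cv_config(n_folds = 5, seed = 4))
  expect_true(all(is.finite(ev$auc)))
  expect_length(ev$errors, 0)
  # deterministic given the seed
  ev2 <- evaluate_feature_set(x, y, cv = cv_config(n_folds = 5, seed = 4))
  expect_identical(ev$auc, ev2$auc)
})

test_that("a failing model is recorded without stopping the others", {
  reg <- model_registry()[c("LR", "DT")]
  reg$broken <- list(fit = function(x, y, seed) stop("boom"),
                     score = function(m, x) rep(0, nrow(x)))
  set.seed(2)
  x <- matrix(rnorm(30 * 3), 30); colnames(x) <- paste0("f", 1:3)
  y <- rep(0:1, 15)
  ev <- evaluate_feature_set(x, y, models = reg, cv = cv_config(n_folds = 3, seed = 1))
  expect_true(is.na(ev$auc["broken"]))
  expect_match(ev$errors$broken, "boom")
  expect_false(anyNA(ev$auc[c("LR", "DT")]))
})

test_that("group comparison reports the models-by-groups table", {
  set.seed(29)
  x <- matrix(rnorm(30 * 3), 30); colnames(x) <- paste0("f", 1:3)
  y <- rep(0:1, each = 15)
  x[, 1] <- x[, 1] + 0.8 * y
  groups <- list(A = x, B = x, C = x[, 2:3],
                 empty = matrix(numeric(0), nrow = 30, ncol = 0))
  mods <- model_registry()[c("NB", "LR", "DT")]
  ev <- run_comparison(groups, y, cv_config(n_folds = 3, seed = 5), mods)
  expect_identical(ev$skipped, "empty")
  expect_equal(dim(ev$auc), c(3, 3))
  # identical inputs give identical AUC columns
  expect_identical(ev$auc$A, ev$auc$B)
  expect_equal(nrow(ev$summary), 3)
  expect_true(all(ev$summary$best_auc >= ev$summary$mean_auc))
})

test_that("nested evaluation runs the cascade inside folds on a small cohort", {
  set.seed(35)
  n <- 40
  y <- rep(0:1, each = 20)
  wb <- matrix(rnorm(n * 40), n); colnames(wb) <- paste0("w", 1:40)
  ll <- matrix(rnorm(n * 30), n); colnames(ll) <- paste0("l", 1:30)
  wb[, 1:4] <- wb[, 1:4] + 1.2 * y
  ll[, 1:3] <- ll[, 1:3] + 1.2 * y
  ev <- suppressWarnings(
    nested_evaluate(wb, ll, y, cv_config(n_folds = 4, seed = 6),
                    model_registry()[c("LR", "NB")],
                    lasso_cfg = lasso_config(n_folds = 4, seed = 6)))
  expect_equal(dim(ev$auc), c(2, 4))
  expect_true(all(ev$auc["LR", ] > 0.5, na.rm = TRUE))
})
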