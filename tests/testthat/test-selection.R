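# centered orthonormal design scaled so X'X = M * I and every column is
# orthogonal to the intercept; the lasso solution is then coordinatewise
# soft-thresholding of the centered least-squares coefficients
make_orthonormal_design <- function(M, p, seed) {
  set.seed(seed)
  Q <- qr.Q(qr(cbind(1, matrix(rnorm(M * (M - 1)), M))))[, 2:(p + 1)]
  X <- sqrt(M) * Q
  colnames(X) <- paste0("f", seq_len(p))
  X
}

test_that("lasso on orthonormal designs equals closed-form soft-thresholding", {
  X <- make_orthonormal_design(8, 4, seed = 1)
  y <- as.vector(X %*% c(2, -1, 0.5, 0) + 0.1 * rnorm(8))
  for (lam in c(0.05, 0.3, 0.8)) {
    rep <- lasso_select(X, y, lasso_config(seed = 1), lambda = lam)
    bols <- as.vector(crossprod(X, y - mean(y))) / 8
    soft <- sign(bols) * pmax(abs(bols) - lam, 0)
    full <- numeric(4); names(full) <- colnames(X)
    full[names(rep$coefficients)] <- rep$coefficients
    expect_equal(unname(full), soft, tolerance = 1e-6)
    expect_identical(rep$selected, colnames(X)[soft != 0])
  }
  # support is scale-equivariant: scaling X and lambda together
  rep_a <- lasso_select(X, y, lambda = 0.3)
  rep_b <- lasso_select(2 * X, y, lambda = 0.3 / 2)
  expect_identical(rep_a$selected, rep_b$selected)
})

test_that("penalties above lambda_max give an empty support", {
  X <- make_orthonormal_design(10, 5, seed = 2)
  y <- as.vector(X %*% c(1, 0, 0, -2, 0)) + 0.05 * rnorm(10)
  lam_max <- max(abs(crossprod(X, y - mean(y)))) / 10
  rep <- lasso_select(X, y, lambda = lam_max * 1.05)
  expect_length(rep$selected, 0)
  expect_error(lasso_select(X[, 1, drop = FALSE], y),
               class = "dynrad_config_error")
  expect_error(lasso_select(X, rep(1, 10)), class = "dynrad_class_error")
})

test_that("cross-validated lasso is deterministic given a seed", {
  set.seed(5)
  X <- matrix(rnorm(60 * 40), 60); colnames(X) <- paste0("v", 1:40)
  y <- rep(0:1, each = 30)
  X[, 1:3] <- X[, 1:3] + y
  r1 <- lasso_select(X, y, lasso_config(n_folds = 5, seed = 9))
  r2 <- lasso_select(X, y, lasso_config(n_folds = 5, seed = 9))
  expect_identical(r1$selected, r2$selected)
  expect_identical(r1$lambda, r2$lambda)
  expect_equal(r1$coefficients, r2$coefficients)
})

test_that("region concatenation keeps all columns under qualified names", {
  M <- 10
  a <- matrix(rnorm(M * 44), M); colnames(a) <- paste0("feat", 1:44)
  b <- matrix(rnorm(M * 32), M)
  colnames(b) <- c(paste0("feat", 1), paste0("other", 2:32))  # one shared base name
  comb <- combine_sets(a, b)
  expect_equal(ncol(comb), 76)
  expect_equal(sum(endsWith(colnames(comb), ":feat1")), 2)
  expect_true(all(startsWith(colnames(comb)[1:44], "WB:")))
  prov <- attr(comb, "provenance")
  expect_equal(table(prov$region)[["LL"]], 32)
  # empty second set degenerates to qualified first set
  empty <- matrix(numeric(0), nrow = M, ncol = 0)
  comb2 <- combine_sets(a, empty)
  expect_equal(ncol(comb2), 44)
  expect_identical(colnames(comb2), paste0("WB:", colnames(a)))
  expect_error(combine_sets(a, b[-1, ]), class = "dynrad_alignment_error")
})

test_that("outcome correlations match hand arithmetic and flag constants", {
  pw <- pearson_with_outcome(cbind(f = c(1, 2, 3, 4)), c(0, 0, 1, 1))
  expect_equal(unname(pw$r), 0.8944272, tolerance = 1e-6)
  y <- c(0, 1, 0, 1)
  pw2 <- pearson_with_outcome(cbind(a = y, b = -y, k = rep(2, 4)), y)
  expect_equal(unname(pw2$r[c("a", "b")]), c(1, -1))
  expect_identical(pw2$constant, "k")
  expect_error(pearson_with_outcome(cbind(k = rep(1, 4)), y),
               class = "dynrad_constant_feature_error")
})

test_that("the second lasso pass selects a subset of the combined set", {
  set.seed(6)
  n <- 50
  y <- rep(0:1, each = 25)
  wb <- matrix(rnorm(n * 30), n); colnames(wb) <- paste0("w", 1:30)
  ll <- matrix(rnorm(n * 20), n); colnames(ll) <- paste0("l", 1:20)
  wb[, 1:3] <- wb[, 1:3] + 0.8 * y
  ll[, 1:2] <- ll[, 1:2] + 0.8 * y
  casc <- lasso_cascade(wb, ll, y, lasso_config(n_folds = 5, seed = 3))
  expect_true(all(colnames(casc$lasso_combined) %in% colnames(casc$combined)))
  expect_equal(ncol(casc$combined),
               ncol(casc$lasso_wb) + ncol(casc$lasso_ll))
  expect_true(all(startsWith(colnames(casc$combined),
                             "WB:") | startsWith(colnames(casc$combined), "LL:")))
})
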