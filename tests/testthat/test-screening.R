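test_that("range normalization matches its closed form and flags constants", {
  m <- cbind(a = c(1, 2, 3), b = c(7, 7, 7), c = c(-0.5, 0, 0.5))
  nm <- normalize_matrix(m)
  expect_equal(unname(nm[, "a"]), c(-0.5, 0, 0.5))
  expect_identical(attr(nm, "excluded_constant_columns"), "b")
  # mean-0, range-1 columns are fixed points
  expect_equal(unname(nm[, "c"]), c(-0.5, 0, 0.5))
  expect_lt(max(abs(colMeans(nm))), 1e-12)
  expect_error(normalize_matrix(m[1, , drop = FALSE]),
               class = "dynrad_insufficient_data_error")
  z <- normalize_matrix(m, method = "zscore")
  expect_equal(unname(z[, "a"]), c(-1, 0, 1))
})

test_that("homogeneity and t-test p-values agree with reference implementations", {
  set.seed(21)
  for (i in 1:10) {
    x0 <- rnorm(6 + i, sd = 1 + i / 5); x1 <- rnorm(9, 0.4, 2)
    expect_equal(homogeneity_pvalue(x0, x1),
                 car::leveneTest(c(x0, x1),
                                 factor(rep(0:1, c(length(x0), 9))))$`Pr(>F)`[1],
                 tolerance = 1e-10)
    expect_equal(homogeneity_pvalue(x0, x1, center = "mean"),
                 car::leveneTest(c(x0, x1),
                                 factor(rep(0:1, c(length(x0), 9))),
                                 center = mean)$`Pr(>F)`[1],
                 tolerance = 1e-10)
    expect_equal(two_sample_pvalue(x0, x1, TRUE),
                 t.test(x0, x1, var.equal = TRUE)$p.value, tolerance = 1e-10)
    expect_equal(two_sample_pvalue(x0, x1, FALSE),
                 t.test(x0, x1)$p.value, tolerance = 1e-10)
  }
  # identical groups: no spread difference, no mean difference
  expect_equal(homogeneity_pvalue(c(1, 5, 2), c(1, 5, 2)), 1)
  expect_equal(two_sample_pvalue(c(1, 2, 3), c(1, 2, 3)), 1)
  # pooled example against the closed form
  expect_equal(two_sample_pvalue(1:4, 2:5, TRUE),
               t.test(1:4, 2:5, var.equal = TRUE)$p.value, tolerance = 1e-12)
  # degenerate zero-variance limits
  expect_equal(two_sample_pvalue(c(2, 2), c(2, 2)), 1)
  expect_equal(two_sample_pvalue(c(2, 2), c(3, 3)), 0)
  expect_error(two_sample_pvalue(1, 1:3), class = "dynrad_sample_size_error")
})

test_that("unequal spreads are detected with high power", {
  hits <- 0
  set.seed(31)
  for (r in 1:200) {
    p <- homogeneity_pvalue(rnorm(50), rnorm(50, sd = 5))
    hits <- hits + (p < 0.01)
  }
  expect_gte(hits / 200, 0.95)
})

test_that("screening retains planted effects and is calibrated and monotone", {
  set.seed(41)
  n <- 60
  labels <- rep(0:1, each = n / 2)
  x <- matrix(rnorm(n * 201), n)
  colnames(x) <- c("planted", paste0("null", 1:200))
  x[, "planted"] <- labels + rnorm(n, sd = 0.25)
  rep1 <- screen_significant(x, labels)
  expect_true("planted" %in% rep1$retained)
  null_rate <- mean(rep1$table$retained[-1])
  band <- qbinom(c(0.005, 0.995), 200, 0.05) / 200
  expect_gte(null_rate, band[1])
  expect_lte(null_rate, band[2])
  # monotone in alpha
  rep_small <- screen_significant(x, labels, alpha = 0.01)
  expect_true(all(rep_small$retained %in% rep1$retained))
  expect_length(screen_significant(x, labels, alpha = 0)$retained, 0)
  # p-values are invariant to affine feature rescaling
  x2 <- sweep(sweep(x, 2, runif(201, 1, 4), "*"), 2, rnorm(201), "+")
  rep2 <- screen_significant(x2, labels)
  expect_equal(rep2$table$t_p, rep1$table$t_p, tolerance = 1e-9)
  expect_equal(rep2$table$levene_p, rep1$table$levene_p, tolerance = 1e-9)
  expect_error(screen_significant(x, rep(0, n)), class = "dynrad_class_error")
})

test_that("null p-values are approximately uniform", {
  set.seed(51)
  x <- matrix(rnorm(80 * 1000), 80)
  colnames(x) <- paste0("f", 1:1000)
  rep <- screen_significant(x, rep(0:1, each = 40))
  ks <- suppressWarnings(ks.test(rep$table$t_p, "punif"))
  expect_gt(ks$p.value, 0.001)
  expect_lt(abs(mean(rep$table$retained) - 0.05), 0.025)
})
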