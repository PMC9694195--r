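test_that("the filter bank has exactly 18 canonically named members", {
  expect_length(filter_bank(), 18)
  expect_true(all(c("original", "wavelet-HHL", "log-sigma-3-0-mm-3D",
                    "square", "squareroot", "logarithm", "exponential")
                  %in% filter_bank()))
  set.seed(1)
  v <- array(rnorm(8 * 8 * 8, 100, 10), dim = c(8, 8, 8))
  fb <- derive_filter_bank(v, c(1, 1, 1))
  expect_identical(names(fb), filter_bank())
  expect_identical(fb$original, v)
  expect_error(derive_filter_bank(array(NaN, dim = c(4, 4, 4))),
               class = "dynrad_input_error")
})

test_that("high-pass wavelet sub-bands and interior LoG vanish on constants", {
  const <- array(5, dim = c(8, 8, 8))
  fb <- derive_filter_bank(const, c(1, 1, 1))
  for (band in paste0("wavelet-", c("LLH", "LHL", "LHH", "HLL", "HLH", "HHL", "HHH")))
    expect_lt(max(abs(fb[[band]])), 1e-10)
  for (s in 1:5)
    expect_lt(max(abs(fb[[sprintf("log-sigma-%d-0-mm-3D", s)]][3:6, 3:6, 3:6])), 1e-10)
})

test_that("texture matrices equal exhaustive enumeration on small toys", {
  for (seed in c(2, 7, 13)) {
    dims <- c(4, 4, 4)
    g <- make_toy_gray(dims, ng = 3, seed = seed)
    # carve an irregular mask: zero some voxels out
    set.seed(seed + 100)
    g[sample(length(g), 12)] <- 0L
    ng <- 3L
    gv <- as.integer(g); dm <- as.integer(dims)
    got <- dynrad:::cpp_glcm(gv, dm, ng)
    want <- or_glcm(g, ng)
    for (d in 1:13)
      expect_equal(unclass(got[[d]]), want[[d]], tolerance = 1e-9,
                   ignore_attr = TRUE)
    gotr <- dynrad:::cpp_glrlm(gv, dm, ng)
    wantr <- or_glrlm(g, ng)
    for (d in 1:13)
      expect_equal(unclass(gotr[[d]]), wantr[[d]], tolerance = 1e-9,
                   ignore_attr = TRUE)
    gotn <- dynrad:::cpp_ngtdm(gv, dm, ng)
    expect_equal(unclass(gotn), or_ngtdm(g, ng), tolerance = 1e-9,
                 ignore_attr = TRUE)
    gotd <- dynrad:::cpp_gldm(gv, dm, ng, 0L)
    expect_equal(unclass(gotd), or_gldm(g, ng, 0), tolerance = 1e-9,
                 ignore_attr = TRUE)
    gotz <- dynrad:::cpp_glszm(gv, dm)
    wantz <- or_glszm(g)
    ord <- function(m) m[order(m[, 1], m[, 2]), , drop = FALSE]
    expect_equal(ord(unclass(gotz)), ord(wantz), ignore_attr = TRUE)
  }
})

test_that("GLCM contrast on a two-gray toy matches direct neighbour-pair counting", {
  g <- array(1L, dim = c(3, 3, 3))
  g[2, 2, 2] <- 2L
  g[1, 3, 2] <- 2L
  Ps <- or_glcm(g, 2)
  contrasts <- vapply(Ps, function(P) {
    p <- P / sum(P)
    iv <- matrix(1:2, 2, 2); jv <- t(iv)
    sum((iv - jv)^2 * p)
  }, numeric(1))
  mask <- array(TRUE, dim = c(3, 3, 3))
  vol <- (g - 1) * 25  # two gray levels one bin apart
  f <- extract_timepoint_features(vol, mask, cfg = feature_family_config(bin_width = 25),
                                  filters = "original")
  expect_equal(unname(f["original_glcm_Contrast"]), mean(contrasts),
               tolerance = 1e-9)
})

test_that("the radiomics vector has the exact 1674-feature count structure", {
  set.seed(11)
  v <- array(rnorm(16^2 * 8, 100, 20), dim = c(16, 16, 8))
  mask <- array(FALSE, dim = c(16, 16, 8)); mask[4:13, 4:13, 2:7] <- TRUE
  f <- extract_timepoint_features(v, mask, c(1, 1, 1))
  expect_length(f, 1674)
  expect_true(all(is.finite(f)))
  fam <- parse_drf_names(names(f))$family
  expect_equal(unname(table(fam)[c("firstorder", "glcm", "glrlm", "glszm",
                                   "ngtdm", "gldm")]),
               c(324, 432, 288, 288, 90, 252), ignore_attr = TRUE)
  # deterministic
  expect_identical(f, extract_timepoint_features(v, mask, c(1, 1, 1)))
})

test_that("a constant-intensity ROI has zero variance, entropy and joint entropy", {
  v <- array(42, dim = c(6, 6, 4))
  mask <- array(FALSE, dim = c(6, 6, 4)); mask[2:5, 2:5, 2:3] <- TRUE
  f <- extract_timepoint_features(v, mask, filters = "original")
  expect_equal(unname(f["original_firstorder_Variance"]), 0)
  expect_equal(unname(f["original_firstorder_Entropy"]), 0)
  expect_equal(unname(f["original_glcm_JointEntropy"]), 0)
  expect_error(extract_timepoint_features(v, array(c(TRUE, rep(FALSE, 143)),
                                                   dim = c(6, 6, 4))),
               class = "dynrad_degenerate_roi_error")
})

test_that("discretized texture features are invariant to intensity shifts", {
  set.seed(3)
  v <- array(rnorm(6 * 6 * 4, 100, 30), dim = c(6, 6, 4))
  mask <- array(TRUE, dim = c(6, 6, 4))
  f1 <- extract_timepoint_features(v, mask, filters = "original")
  f2 <- extract_timepoint_features(v + 137.3, mask, filters = "original")
  texture <- !startsWith(names(f1), "original_firstorder")
  expect_equal(f1[texture], f2[texture], tolerance = 1e-9)
})

test_that("features depend only on in-mask voxels (far-field perturbations)", {
  set.seed(8)
  dims <- c(20, 20, 20)
  v <- array(rnorm(prod(dims), 100, 15), dim = dims)
  mask <- array(FALSE, dims); mask[8:12, 8:12, 8:12] <- TRUE
  filt <- c("original", "wavelet-LLL", "wavelet-HHH", "log-sigma-1-0-mm-3D",
            "square", "squareroot", "logarithm", "exponential")
  f1 <- extract_timepoint_features(v, mask, filters = filt)
  v2 <- v
  v2[1, 1, 1] <- v2[1, 1, 1] + 500  # far outside every filter's support
  f2 <- extract_timepoint_features(v2, mask, filters = filt)
  expect_equal(f1, f2, tolerance = 1e-9)
})
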