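#' Normalize a feature matrix column-wise
#'
#' Applies `F* = (F - mean(F)) / (max(F) - min(F))` to every column.
#' Constant columns (zero range) cannot be normalized; they are dropped and
#' listed in the `excluded_constant_columns` attribute.  A z-score variant
#' (`(F - mean) / sd`) is available behind `method`.
#'
#' @param mat Numeric matrix (cases x features) or `drf_matrix`; >= 2 rows.
#' @param method `"range"` (default) or `"zscore"`.
#' @return The normalized matrix, class `normalized_matrix`, with attributes
#'   of the input preserved plus `excluded_constant_columns`.
#' @export
normalize_matrix <- function(mat, method = c("range", "zscore")) {
  method <- match.arg(method)
  if (nrow(mat) < 2)
    dr_stop("need at least 2 rows to normalize", "dynrad_insufficient_data_error")
  m <- unclass(mat)
  mins <- apply(m, 2, min)
  maxs <- apply(m, 2, max)
  rng <- maxs - mins
  keep <- rng > 0
  excluded <- colnames(m)[!keep]
  m <- m[, keep, drop = FALSE]
  mu <- colMeans(m)
  denom <- if (method == "range") rng[keep] else apply(m, 2, sd)
  norm <- sweep(sweep(m, 2, mu), 2, denom, "/")
  structure(norm, labels = attr(mat, "labels"), region = attr(mat, "region"),
            excluded_constant_columns = excluded, method = method,
            class = c("normalized_matrix", "matrix", "array"))
}

# vectorized Brown-Forsythe / Levene p-values for a two-group split.
# x: matrix (cases x features); returns p per column.
dr_levene_p_cols <- function(x, g0, g1, center = "median") {
  cf <- if (center == "median") function(m) apply(m, 2, median) else colMeans
  z0 <- abs(sweep(x[g0, , drop = FALSE], 2, cf(x[g0, , drop = FALSE])))
  z1 <- abs(sweep(x[g1, , drop = FALSE], 2, cf(x[g1, , drop = FALSE])))
  n0 <- length(g0); n1 <- length(g1); n <- n0 + n1
  m0 <- colMeans(z0); m1 <- colMeans(z1)
  mall <- (n0 * m0 + n1 * m1) / n
  ssb <- n0 * (m0 - mall)^2 + n1 * (m1 - mall)^2
  ssw <- colSums(sweep(z0, 2, m0)^2) + colSums(sweep(z1, 2, m1)^2)
  f <- (n - 2) * ssb / pmax(ssw, .dr_eps)
  p <- pf(f, 1, n - 2, lower.tail = FALSE)
  p[ssb <= .dr_eps & ssw <= .dr_eps] <- 1  # identical spreads
  p
}

# vectorized two-sample t-test p-values; pooled when pooled[j] is TRUE,
# Welch (Satterthwaite df) otherwise
dr_ttest_p_cols <- function(x, g0, g1, pooled) {
  n0 <- length(g0); n1 <- length(g1)
  m0 <- colMeans(x[g0, , drop = FALSE]); m1 <- colMeans(x[g1, , drop = FALSE])
  v0 <- colSums(sweep(x[g0, , drop = FALSE], 2, m0)^2) / (n0 - 1)
  v1 <- colSums(sweep(x[g1, , drop = FALSE], 2, m1)^2) / (n1 - 1)
  diff <- m0 - m1
  p <- numeric(ncol(x))
  sp2 <- ((n0 - 1) * v0 + (n1 - 1) * v1) / (n0 + n1 - 2)
  se_p <- sqrt(sp2 * (1 / n0 + 1 / n1))
  df_p <- n0 + n1 - 2
  se_w <- sqrt(v0 / n0 + v1 / n1)
  df_w <- (v0 / n0 + v1 / n1)^2 /
    pmax((v0 / n0)^2 / (n0 - 1) + (v1 / n1)^2 / (n1 - 1), .dr_eps)
  se <- ifelse(pooled, se_p, se_w)
  df <- ifelse(pooled, df_p, df_w)
  ok <- se > 0
  p[ok] <- 2 * pt(abs(diff[ok]) / se[ok], df[ok], lower.tail = FALSE)
  # zero variance in both groups: p = 1 if means equal, else -> 0
  p[!ok] <- ifelse(abs(diff[!ok]) < .dr_eps, 1, 0)
  p
}

#' Levene-family homogeneity-of-variance p-value
#'
#' Brown-Forsythe variant by default (absolute deviations from the group
#' median, one-way ANOVA F on two groups); mean centering gives the classic
#' Levene test.
#'
#' @param x0,x1 Numeric vectors, each with >= 2 values.
#' @param center `"median"` (Brown-Forsythe, default) or `"mean"`.
#' @return Two-sided p-value in `[0, 1]`.
#' @export
homogeneity_pvalue <- function(x0, x1, center = c("median", "mean")) {
  center <- match.arg(center)
  if (length(x0) < 2 || length(x1) < 2)
    dr_stop("each group needs >= 2 values", "dynrad_sample_size_error")
  x <- matrix(c(x0, x1), ncol = 1)
  dr_levene_p_cols(x, seq_along(x0), length(x0) + seq_along(x1), center)[1]
}

#' Two-sample t-test p-value
#'
#' Pooled-variance t-test when `equal_variance` is `TRUE`; Welch's t-test
#' with Satterthwaite degrees of freedom otherwise.
#'
#' @param x0,x1 Numeric vectors, each with >= 2 values.
#' @param equal_variance Logical flag.
#' @return Two-sided p-value.  When both groups have zero variance the
#'   p-value is 1 for equal means and 0 otherwise (degenerate limit).
#' @export
two_sample_pvalue <- function(x0, x1, equal_variance = FALSE) {
  if (length(x0) < 2 || length(x1) < 2)
    dr_stop("each group needs >= 2 values", "dynrad_sample_size_error")
  x <- matrix(c(x0, x1), ncol = 1)
  dr_ttest_p_cols(x, seq_along(x0), length(x0) + seq_along(x1), equal_variance)[1]
}

#' Screen features with a Levene-gated two-sample t-test
#'
#' For every feature column, a Levene (Brown-Forsythe) test at
#' `levene_alpha` decides between the pooled-variance t-test (homogeneous
#' variances) and Welch's t-test; features with `t_p < alpha` are retained.
#' No multiple-testing correction is applied by default, matching the raw
#' `p < 0.05` rule of the screening protocol; set `adjust = "BH"` for a
#' Benjamini-Hochberg variant.
#'
#' @param mat A `normalized_matrix` (or plain matrix) of cases x features.
#' @param labels 0/1 outcome labels (both classes present).
#' @param alpha Retention significance level (default 0.05).
#' @param levene_alpha Gate level for the variance test (default 0.05).
#' @param center Levene centering, `"median"` or `"mean"`.
#' @param adjust `"none"` (default) or `"BH"`.
#' @return A `screen_report` list: data.frame `table` (feature, levene_p,
#'   equal_variance, t_p, retained), character vector `retained`, the alpha
#'   levels, and a per-family summary data.frame `family_summary`.
#' @export
screen_significant <- function(mat, labels = attr(mat, "labels"), alpha = 0.05,
                               levene_alpha = 0.05,
                               center = c("median", "mean"),
                               adjust = c("none", "BH")) {
  center <- match.arg(center); adjust <- match.arg(adjust)
  if (is.null(labels)) dr_stop("labels are required", "dynrad_class_error")
  labels <- as.integer(labels)
  g0 <- which(labels == 0); g1 <- which(labels == 1)
  if (length(g0) < 2 || length(g1) < 2)
    dr_stop("both classes must be present with >= 2 cases", "dynrad_class_error")
  x <- unclass(mat)
  lev_p <- dr_levene_p_cols(x, g0, g1, center)
  equal_var <- lev_p >= levene_alpha
  t_p <- dr_ttest_p_cols(x, g0, g1, equal_var)
  t_p_eff <- if (adjust == "BH") stats::p.adjust(t_p, "BH") else t_p
  retained <- colnames(x)[t_p_eff < alpha]
  tab <- data.frame(feature = colnames(x), levene_p = lev_p,
                    equal_variance = equal_var, t_p = t_p,
                    retained = t_p_eff < alpha, stringsAsFactors = FALSE)
  fam <- parse_drf_names(colnames(x))$family
  fs <- NULL
  if (!all(is.na(fam))) {
    ret <- tab$retained
    fs <- do.call(rbind, lapply(split(seq_len(ncol(x)), fam), function(idx) {
      r <- idx[ret[idx]]
      data.frame(family = fam[idx[1]], n_tested = length(idx),
                 n_retained = length(r),
                 mean_p = if (length(r)) mean(t_p[r]) else NA_real_,
                 sd_p = if (length(r) > 1) sd(t_p[r]) else NA_real_)
    }))
    rownames(fs) <- NULL
  }
  structure(list(table = tab, retained = retained, alpha = alpha,
                 levene_alpha = levene_alpha, family_summary = fs),
            class = "screen_report")
}

#' Write a screen report as CSV (+ JSON summary)
#' @param report A `screen_report`.
#' @param csv_path,json_path Output paths (JSON optional).
#' @return Invisibly, `csv_path`.
#' @export
write_screen_report <- function(report, csv_path, json_path = NULL) {
  data.table::fwrite(report$table, csv_path)
  if (!is.null(json_path)) {
    jsonlite::write_json(list(alpha = report$alpha,
                              n_tested = nrow(report$table),
                              n_retained = length(report$retained),
                              family_summary = report$family_summary),
                         json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(csv_path)
}
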