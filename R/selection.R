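#' Lasso selection configuration
#'
#' @param n_folds Cross-validation folds for the penalty choice (default 10).
#' @param nlambda Number of penalty values on the log-spaced grid.
#' @param lambda_min_ratio Smallest penalty as a fraction of the smallest
#'   penalty with empty support.
#' @param max_iter,tol Coordinate-descent budget and convergence threshold.
#' @param seed Seed for the CV fold assignment.
#' @return An object of class `lasso_config`.
#' @export
lasso_config <- function(n_folds = 10, nlambda = 100, lambda_min_ratio = 1e-4,
                         max_iter = 1e5, tol = 1e-7, seed = 1L) {
  if (n_folds < 2) dr_stop("n_folds must be >= 2", "dynrad_config_error")
  structure(list(n_folds = as.integer(n_folds), nlambda = as.integer(nlambda),
                 lambda_min_ratio = lambda_min_ratio, max_iter = max_iter,
                 tol = tol, seed = as.integer(seed)),
            class = "lasso_config")
}

#' Select outstanding features with a cross-validated Lasso
#'
#' Squared-error Lasso of the outcome coding (good = 0, poor = 1) on the
#' screened feature matrix:
#' `argmin sum_i (y_i - b0 - sum_j b_j x_ij)^2 + lambda * sum_j |b_j|`
#' with an unpenalized intercept.  The penalty grid is 100 log-spaced values
#' from the smallest lambda with empty support down to `lambda_min_ratio`
#' times it; `lambda` is chosen by seeded, label-stratified k-fold CV
#' minimizing mean squared prediction error.  Features with non-zero
#' coefficients at the chosen penalty are selected.
#'
#' @param x Numeric matrix (cases x features), >= 2 features.
#' @param labels 0/1 outcome vector (or numeric coding; both classes must be
#'   present for binary labels).
#' @param cfg A [lasso_config()].
#' @param lambda Optional fixed penalty (in the `(1/2M) RSS + lambda |b|_1`
#'   parameterization used by glmnet); skips cross-validation.
#' @return A `selection_report`: `selected` (names), `coefficients` (named,
#'   non-zero), `intercept`, `lambda`, `lambda_grid`, `cv_mse`.
#' @export
lasso_select <- function(x, labels, cfg = lasso_config(), lambda = NULL) {
  x <- unclass(x)
  if (anyDuplicated(colnames(x)))
    dr_stop("duplicated feature names in selection input", "dynrad_cohort_error")
  if (ncol(x) < 2)
    dr_stop("need >= 2 features for lasso selection", "dynrad_config_error")
  y <- as.numeric(labels)
  if (length(unique(y)) < 2)
    dr_stop("outcome is constant", "dynrad_class_error")
  m <- nrow(x)
  lambda_max <- max(abs(crossprod(x, y - mean(y)))) / m
  grid <- exp(seq(log(lambda_max), log(lambda_max * cfg$lambda_min_ratio),
                  length.out = cfg$nlambda))
  if (is.null(lambda)) {
    foldid <- make_stratified_folds(as.integer(labels), cfg$n_folds, cfg$seed)
    cvfit <- glmnet::cv.glmnet(x, y, family = "gaussian", lambda = grid,
                               standardize = FALSE, foldid = foldid,
                               thresh = cfg$tol, maxit = cfg$max_iter)
    lam <- cvfit$lambda.min
    fit <- cvfit$glmnet.fit
    cv_mse <- cvfit$cvm
  } else {
    fit <- glmnet::glmnet(x, y, family = "gaussian",
                          lambda = sort(unique(c(grid, lambda)), decreasing = TRUE),
                          standardize = FALSE, thresh = cfg$tol,
                          maxit = cfg$max_iter)
    lam <- lambda
    cv_mse <- NULL
  }
  beta <- as.numeric(glmnet::coef.glmnet(fit, s = lam, exact = FALSE))
  nm <- rownames(glmnet::coef.glmnet(fit, s = lam))
  nonzero <- which(beta[-1] != 0)
  structure(list(selected = colnames(x)[nonzero],
                 coefficients = stats::setNames(beta[-1][nonzero], colnames(x)[nonzero]),
                 intercept = beta[1], lambda = lam, lambda_grid = grid,
                 cv_mse = cv_mse, n_input = ncol(x)),
            class = "selection_report")
}

#' Concatenate whole-brain and lesion selected feature sets
#'
#' Column-binds the two region matrices with region-qualified names
#' (`WB:<name>`, `LL:<name>`).  Same-named features from different regions
#' are different measurements and are never merged, so the combined set has
#' exactly `|A| + |B|` columns.
#'
#' @param matA,matB Numeric matrices with identical row (case) order; may
#'   have 0 columns.
#' @param tagA,tagB Region tags used to qualify names.
#' @return A matrix of class `combined_set` with attribute `provenance`
#'   (data.frame: qualified name, region, base name).
#' @export
combine_sets <- function(matA, matB, tagA = "WB", tagB = "LL") {
  if (nrow(matA) != nrow(matB) ||
      (!is.null(rownames(matA)) && !is.null(rownames(matB)) &&
       !identical(rownames(matA), rownames(matB))))
    dr_stop("case order differs between the two region matrices", "dynrad_alignment_error")
  qa <- if (ncol(matA)) paste0(tagA, ":", colnames(matA)) else character(0)
  qb <- if (ncol(matB)) paste0(tagB, ":", colnames(matB)) else character(0)
  out <- cbind(matA, matB)
  colnames(out) <- c(qa, qb)
  prov <- data.frame(name = c(qa, qb),
                     region = c(rep(tagA, ncol(matA)), rep(tagB, ncol(matB))),
                     base = c(colnames(matA), colnames(matB)),
                     stringsAsFactors = FALSE)
  structure(out, provenance = prov, labels = attr(matA, "labels"),
            class = c("combined_set", "matrix", "array"))
}

#' Pearson correlation of each feature with the outcome
#'
#' @param x Numeric matrix (cases x features), >= 3 cases.
#' @param labels Outcome coding.
#' @return A list: `r` (named per-feature correlations), `mean_abs_r`,
#'   `sd_abs_r`, and `constant` (names of excluded constant features).
#' @export
pearson_with_outcome <- function(x, labels) {
  x <- unclass(x)
  if (nrow(x) < 3) dr_stop("need >= 3 cases", "dynrad_sample_size_error")
  y <- as.numeric(labels)
  sds <- apply(x, 2, sd)
  constant <- colnames(x)[sds == 0]
  if (ncol(x) == length(constant))
    dr_stop("all features are constant; correlation undefined", "dynrad_constant_feature_error")
  keep <- sds > 0
  r <- as.vector(cor(x[, keep, drop = FALSE], y))
  names(r) <- colnames(x)[keep]
  list(r = r, mean_abs_r = mean(abs(r)), sd_abs_r = sd(abs(r)),
       constant = constant)
}

#' Run the full two-stage Lasso cascade
#'
#' Produces the four feature groups from screened whole-brain and lesion
#' matrices: `Lasso(WB)`, `Lasso(LL)`, their concatenation
#' (`combined`), and a second Lasso pass on the concatenation
#' (`Lasso(combined)`).
#'
#' @param wb,ll Normalized, screened feature matrices (cases x features) for
#'   the whole-brain and lesion regions, same case order.
#' @param labels 0/1 outcome vector.
#' @param cfg A [lasso_config()].
#' @return A list with the four group matrices (`lasso_wb`, `lasso_ll`,
#'   `combined`, `lasso_combined`) and the three `selection_report`s.
#' @export
lasso_cascade <- function(wb, ll, labels, cfg = lasso_config()) {
  rep_wb <- lasso_select(wb, labels, cfg)
  rep_ll <- lasso_select(ll, labels, cfg)
  m_wb <- unclass(wb)[, rep_wb$selected, drop = FALSE]
  m_ll <- unclass(ll)[, rep_ll$selected, drop = FALSE]
  comb <- combine_sets(m_wb, m_ll)
  rep_comb <- if (ncol(comb) >= 2) lasso_select(unclass(comb), labels, cfg) else
    structure(list(selected = colnames(comb),
                   coefficients = stats::setNames(rep(NA_real_, ncol(comb)), colnames(comb)),
                   intercept = NA_real_, lambda = NA_real_,
                   lambda_grid = numeric(0), cv_mse = NULL, n_input = ncol(comb)),
              class = "selection_report")
  list(lasso_wb = m_wb, lasso_ll = m_ll, combined = unclass(comb),
       lasso_combined = unclass(comb)[, rep_comb$selected, drop = FALSE],
       report_wb = rep_wb, report_ll = rep_ll, report_combined = rep_comb)
}

#' Write a selection report as CSV (+ JSON summary)
#' @param report A `selection_report`.
#' @param csv_path,json_path Output paths (JSON optional).
#' @return Invisibly, `csv_path`.
#' @export
write_selection_report <- function(report, csv_path, json_path = NULL) {
  data.table::fwrite(data.frame(feature = report$selected,
                                coefficient = report$coefficients), csv_path)
  if (!is.null(json_path)) {
    fam <- parse_drf_names(report$selected)$family
    counts <- if (all(is.na(fam))) NULL else as.list(table(fam))
    jsonlite::write_json(list(lambda = report$lambda,
                              n_selected = length(report$selected),
                              n_input = report$n_input,
                              per_family = counts),
                         json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(csv_path)
}
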