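#' Cross-validation configuration
#'
#' @param n_folds Number of folds (default 10).
#' @param seed Seed for fold assignment and model substreams.
#' @param auc_aggregation `"pooled"` (one AUC over the pooled out-of-fold
#'   scores; every case used exactly once) or `"mean_of_folds"`.
#' @param selection_mode `"paper"` (screen/select on the full cohort before
#'   CV, reproducing the original leakage-prone protocol) or `"nested"`
#'   (screening + selection re-run inside each training fold; see
#'   [nested_evaluate()]).
#' @return An object of class `cv_config`.
#' @export
cv_config <- function(n_folds = 10, seed = 1L,
                      auc_aggregation = c("pooled", "mean_of_folds"),
                      selection_mode = c("paper", "nested")) {
  if (n_folds < 2) dr_stop("n_folds must be >= 2", "dynrad_config_error")
  structure(list(n_folds = as.integer(n_folds), seed = as.integer(seed),
                 auc_aggregation = match.arg(auc_aggregation),
                 selection_mode = match.arg(selection_mode)),
            class = "cv_config")
}

#' Stratified fold assignment
#'
#' Partitions cases into `k` folds with per-fold class counts within one
#' case of the global proportions: each class is shuffled by the seed and
#' dealt round-robin.
#'
#' @param labels 0/1 (or factor-like) label vector.
#' @param k Number of folds.
#' @param seed Integer seed.
#' @return Integer vector of fold ids in `1..k`, one per case.
#' @export
make_stratified_folds <- function(labels, k, seed) {
  n <- length(labels)
  if (k > n) dr_stop("more folds than cases", "dynrad_fold_error")
  if (min(table(labels)) < k)
    warning("a class has fewer members than folds; some folds will miss it")
  fold <- integer(n)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv), add = TRUE)
  set.seed(as.integer(seed))
  offset <- 0L
  for (cls in sort(unique(labels))) {
    idx <- which(labels == cls)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- ((seq_along(idx) - 1L + offset) %% k) + 1L
    offset <- offset + length(idx)
  }
  fold
}

#' Area under the ROC curve (Mann-Whitney form)
#'
#' The probability that a randomly chosen positive case outscores a
#' randomly chosen negative one, ties counted 1/2.
#'
#' @param scores Continuous scores for the positive class.
#' @param labels 0/1 labels (both classes present).
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(scores, labels) {
  y <- as.integer(labels)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0)
    dr_stop("AUC undefined: only one class present", "dynrad_class_error")
  r <- rank(scores)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Cross-validated AUC of one feature set across models
#'
#' For each model: train on k-1 folds, score the held-out fold, and
#' aggregate the out-of-fold scores into an AUC.  Deterministic given the
#' `cv_config` seed; a model that fails to train is recorded as `NA` with
#' its error message and the remaining models proceed.
#'
#' @param x Numeric matrix (cases x features).
#' @param labels 0/1 outcome vector, same length as `nrow(x)`.
#' @param models A model registry (default [model_registry()]).
#' @param cv A [cv_config()].
#' @return A list: `auc` (named per-model), `errors` (named list of error
#'   messages), `folds` (fold assignment).
#' @export
evaluate_feature_set <- function(x, labels, models = model_registry(),
                                 cv = cv_config()) {
  x <- unclass(x)
  y <- as.integer(labels)
  if (nrow(x) != length(y))
    dr_stop("labels length does not match matrix rows", "dynrad_alignment_error")
  folds <- make_stratified_folds(y, cv$n_folds, cv$seed)
  auc <- stats::setNames(rep(NA_real_, length(models)), names(models))
  errors <- list()
  for (mi in seq_along(models)) {
    mod <- models[[mi]]
    res <- tryCatch({
      oof <- rep(NA_real_, length(y))
      fold_aucs <- numeric(0)
      for (f in sort(unique(folds))) {
        tr <- folds != f; te <- !tr
        seed_f <- dr_child_seed(cv$seed, mi * 100L + f)
        fit <- mod$fit(x[tr, , drop = FALSE], y[tr], seed_f)
        oof[te] <- mod$score(fit, x[te, , drop = FALSE])
        if (cv$auc_aggregation == "mean_of_folds" && length(unique(y[te])) == 2)
          fold_aucs <- c(fold_aucs, auc_score(oof[te], y[te]))
      }
      if (cv$auc_aggregation == "pooled") auc_score(oof, y) else mean(fold_aucs)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      errors[[names(models)[mi]]] <- conditionMessage(res)
    } else auc[mi] <- res
  }
  list(auc = auc, errors = errors, folds = folds)
}

#' Compare feature groups across the model registry
#'
#' Evaluates each feature group (e.g. `Lasso(WB)`, `Lasso(LL)`, `combined`,
#' `Lasso(combined)`) with every model under the same stratified CV and
#' assembles the models x groups AUC table with per-group mean, SD, and
#' best AUC.  Groups with zero features are skipped and flagged.
#'
#' @param groups Named list of feature matrices with identical case order.
#' @param labels 0/1 outcome vector.
#' @param cv A [cv_config()].
#' @param models A model registry.
#' @return An `evaluation_report`: `auc` (data.frame models x groups),
#'   `summary` (per-group mean/sd/best), `skipped`, `errors`, `config`.
#' @export
run_comparison <- function(groups, labels, cv = cv_config(),
                           models = model_registry()) {
  ns <- vapply(groups, nrow, integer(1))
  if (length(unique(ns)) != 1)
    dr_stop("feature groups disagree on case count", "dynrad_alignment_error")
  skipped <- names(groups)[vapply(groups, ncol, integer(1)) == 0]
  use <- setdiff(names(groups), skipped)
  auc <- matrix(NA_real_, nrow = length(models), ncol = length(use),
                dimnames = list(names(models), use))
  errors <- list()
  for (g in use) {
    ev <- evaluate_feature_set(groups[[g]], labels, models, cv)
    auc[, g] <- ev$auc[rownames(auc)]
    if (length(ev$errors)) errors[[g]] <- ev$errors
  }
  summ <- data.frame(group = use,
                     mean_auc = colMeans(auc, na.rm = TRUE),
                     sd_auc = apply(auc, 2, sd, na.rm = TRUE),
                     best_auc = apply(auc, 2, max, na.rm = TRUE),
                     best_model = rownames(auc)[apply(auc, 2, which.max)],
                     row.names = NULL)
  note <- if (cv$selection_mode == "paper")
    paste("feature selection was performed on the full cohort before",
          "cross-validation; out-of-fold AUCs therefore inherit the",
          "selection optimism of that protocol") else NULL
  structure(list(auc = as.data.frame(auc), summary = summ, skipped = skipped,
                 errors = errors, config = cv, note = note),
            class = "evaluation_report")
}

#' Nested (leakage-free) evaluation of the full cascade
#'
#' Re-runs screening and the Lasso cascade inside every training fold, then
#' scores the held-out fold with models trained on the fold-specific
#' feature groups.  Slower but free of selection leakage; the counterpart
#' of the `"paper"` selection mode.
#'
#' @param wb,ll Normalized whole-brain / lesion feature matrices (all
#'   columns, pre-screening), identical case order.
#' @param labels 0/1 outcome vector.
#' @param cv A [cv_config()].
#' @param models A model registry.
#' @param alpha Screening significance level.
#' @param lasso_cfg A [lasso_config()].
#' @return An `evaluation_report` (pooled AUC only).
#' @export
nested_evaluate <- function(wb, ll, labels, cv = cv_config(),
                            models = model_registry(), alpha = 0.05,
                            lasso_cfg = lasso_config()) {
  y <- as.integer(labels)
  folds <- make_stratified_folds(y, cv$n_folds, cv$seed)
  group_names <- c("lasso_wb", "lasso_ll", "combined", "lasso_combined")
  oof <- array(NA_real_, dim = c(length(y), length(models), length(group_names)),
               dimnames = list(NULL, names(models), group_names))
  for (f in sort(unique(folds))) {
    tr <- folds != f; te <- !tr
    scr_wb <- screen_significant(wb[tr, , drop = FALSE], y[tr], alpha)
    scr_ll <- screen_significant(ll[tr, , drop = FALSE], y[tr], alpha)
    if (length(scr_wb$retained) < 2 || length(scr_ll$retained) < 2) next
    casc <- lasso_cascade(wb[tr, scr_wb$retained, drop = FALSE],
                          ll[tr, scr_ll$retained, drop = FALSE],
                          y[tr], lasso_cfg)
    test_groups <- list(
      lasso_wb = wb[te, colnames(casc$lasso_wb), drop = FALSE],
      lasso_ll = ll[te, colnames(casc$lasso_ll), drop = FALSE],
      combined = cbind(wb[te, colnames(casc$lasso_wb), drop = FALSE],
                       ll[te, colnames(casc$lasso_ll), drop = FALSE]),
      lasso_combined = {
        prov <- attr(combine_sets(casc$lasso_wb, casc$lasso_ll), "provenance")
        sel <- prov[prov$name %in% colnames(casc$lasso_combined), ]
        m <- cbind(wb[te, sel$base[sel$region == "WB"], drop = FALSE],
                   ll[te, sel$base[sel$region == "LL"], drop = FALSE])
        m
      })
    train_groups <- list(lasso_wb = casc$lasso_wb, lasso_ll = casc$lasso_ll,
                         combined = casc$combined,
                         lasso_combined = casc$lasso_combined)
    for (g in group_names) {
      if (ncol(train_groups[[g]]) == 0) next
      for (mi in seq_along(models)) {
        seed_f <- dr_child_seed(cv$seed, mi * 100L + f)
        fit <- try(models[[mi]]$fit(train_groups[[g]], y[tr], seed_f), silent = TRUE)
        if (inherits(fit, "try-error")) next
        xte <- test_groups[[g]]
        colnames(xte) <- colnames(train_groups[[g]])
        oof[te, mi, g] <- models[[mi]]$score(fit, xte)
      }
    }
  }
  auc <- matrix(NA_real_, length(models), length(group_names),
                dimnames = list(names(models), group_names))
  for (g in group_names) for (mi in seq_along(models)) {
    s <- oof[, mi, g]
    if (all(is.finite(s))) auc[mi, g] <- auc_score(s, y)
  }
  summ <- data.frame(group = group_names,
                     mean_auc = colMeans(auc, na.rm = TRUE),
                     sd_auc = apply(auc, 2, sd, na.rm = TRUE),
                     best_auc = suppressWarnings(apply(auc, 2, max, na.rm = TRUE)),
                     row.names = NULL)
  structure(list(auc = as.data.frame(auc), summary = summ, skipped = character(0),
                 errors = list(), config = cv,
                 note = "nested mode: selection re-run inside each training fold"),
            class = "evaluation_report")
}

#' Write an evaluation report as CSV (+ JSON)
#' @param report An `evaluation_report`.
#' @param csv_path,json_path Output paths (JSON optional).
#' @return Invisibly, `csv_path`.
#' @export
write_evaluation_report <- function(report, csv_path, json_path = NULL) {
  tab <- cbind(model = rownames(report$auc), report$auc)
  data.table::fwrite(tab, csv_path)
  if (!is.null(json_path)) {
    jsonlite::write_json(list(summary = report$summary, skipped = report$skipped,
                              errors = report$errors,
                              config = unclass(report$config),
                              note = report$note),
                         json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(csv_path)
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("Cross-validated AUC (models x feature groups)\n")
  print(round(as.matrix(x$auc), 3))
  cat("\nPer-group summary:\n")
  print(x$summary, digits = 3)
  if (!is.null(x$note)) cat("\nNote:", x$note, "\n")
  invisible(x)
}
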