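#' Pipeline configuration
#'
#' Bundles the per-stage configurations of the end-to-end pipeline
#' (simulate -> preprocess -> extract -> screen -> select -> evaluate) into
#' one object that round-trips losslessly through YAML.
#'
#' @param cohort A [cohort_config()].
#' @param smoothing A [smoothing_config()] or `NULL` to skip smoothing.
#' @param features A [feature_family_config()].
#' @param filters Subset of [filter_bank()] to compute.
#' @param alpha,levene_alpha Screening significance levels.
#' @param lasso A [lasso_config()].
#' @param cv A [cv_config()].
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            smoothing = smoothing_config(),
                            features = feature_family_config(),
                            filters = filter_bank(),
                            alpha = 0.05, levene_alpha = 0.05,
                            lasso = lasso_config(),
                            cv = cv_config()) {
  structure(list(cohort = cohort, smoothing = smoothing, features = features,
                 filters = filters, alpha = alpha, levene_alpha = levene_alpha,
                 lasso = lasso, cv = cv),
            class = "pipeline_config")
}

# recursively strip S3 classes so configs serialize as plain lists
dr_plain <- function(x) {
  if (is.list(x)) lapply(unclass(x), dr_plain) else x
}

#' Write / read a pipeline configuration as YAML
#' @param config A `pipeline_config`.
#' @param path YAML file path.
#' @return `write_pipeline_config` returns `path` invisibly;
#'   `read_pipeline_config` returns a `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(dr_plain(config), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  pipeline_config(
    cohort = do.call(cohort_config, c(
      y$cohort[setdiff(names(y$cohort), c("bolus", "lesion", "lesion_effect_delta"))],
      list(bolus = do.call(bolus_model, y$cohort$bolus),
           lesion = do.call(lesion_effect, y$cohort$lesion),
           lesion_effect_delta = y$cohort$lesion_effect_delta))),
    smoothing = do.call(smoothing_config, y$smoothing),
    features = do.call(feature_family_config, y$features),
    filters = y$filters,
    alpha = y$alpha, levene_alpha = y$levene_alpha,
    lasso = do.call(lasso_config, y$lasso),
    cv = do.call(cv_config, y$cv))
}

#' Run the full pipeline into a run directory
#'
#' Executes simulate -> preprocess/extract -> screen -> select -> evaluate,
#' writing per-stage artifacts (`labels.csv`, per-region DRF tables and
#' manifests, screen and selection reports, the evaluation table) and a
#' `manifest.json` listing every output with an md5 checksum.  Completed
#' stages are reused on re-run (stage CSVs are reloaded) unless
#' `overwrite = TRUE`.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Run directory (created if missing).
#' @param overwrite Recompute stages whose artifacts already exist.
#' @param write_nifti Also write per-case NIfTI volumes during simulation.
#' @return Invisibly, a list with the in-memory stage results
#'   (`cohort`, `drf`, `screen`, `cascade`, `evaluation`) and `paths`.
#' @export
run_pipeline <- function(config, out_dir, overwrite = FALSE, write_nifti = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    labels = file.path(out_dir, "labels.csv"),
    drf = c(WB = file.path(out_dir, "drf_WB.csv"),
            LL = file.path(out_dir, "drf_LL.csv")),
    screen = c(WB = file.path(out_dir, "screen_WB.csv"),
               LL = file.path(out_dir, "screen_LL.csv")),
    selection = c(WB = file.path(out_dir, "selection_WB.csv"),
                  LL = file.path(out_dir, "selection_LL.csv"),
                  combined = file.path(out_dir, "selection_combined.csv")),
    evaluation = file.path(out_dir, "evaluation.csv"),
    manifest = file.path(out_dir, "manifest.json"))

  # -- simulate + extract ----------------------------------------------------
  drf <- list()
  if (!overwrite && all(file.exists(paths$drf))) {
    drf$WB <- read_drf_matrix(paths$drf["WB"], "WB")
    drf$LL <- read_drf_matrix(paths$drf["LL"], "LL")
    labels <- attr(drf$WB, "labels")
    cohort <- NULL
  } else {
    cohort <- generate_cohort(config$cohort)
    if (write_nifti) write_cohort(cohort, file.path(out_dir, "nifti"))
    labels <- cohort_labels(cohort)
    utils::write.csv(data.frame(
      case_id = vapply(cohort, function(e) e$study$case_id, character(1)),
      mrs_group = ifelse(labels == 1, "poor", "good")),
      paths$labels, row.names = FALSE)
    for (rg in c("WB", "LL")) {
      drf[[rg]] <- build_drf_matrix(cohort, rg, config$features, config$filters,
                                    config$smoothing)
      write_drf_matrix(drf[[rg]], paths$drf[rg],
                       file.path(out_dir, sprintf("drf_%s_manifest.json", rg)))
    }
  }

  # -- screen ----------------------------------------------------------------
  norm <- lapply(drf, normalize_matrix)
  screen <- list()
  for (rg in c("WB", "LL")) {
    screen[[rg]] <- screen_significant(norm[[rg]], labels, config$alpha,
                                       config$levene_alpha)
    write_screen_report(screen[[rg]], paths$screen[rg],
                        file.path(out_dir, sprintf("screen_%s_summary.json", rg)))
  }

  # -- select ----------------------------------------------------------------
  casc <- lasso_cascade(
    unclass(norm$WB)[, screen$WB$retained, drop = FALSE],
    unclass(norm$LL)[, screen$LL$retained, drop = FALSE],
    labels, config$lasso)
  write_selection_report(casc$report_wb, paths$selection["WB"],
                         file.path(out_dir, "selection_WB_summary.json"))
  write_selection_report(casc$report_ll, paths$selection["LL"],
                         file.path(out_dir, "selection_LL_summary.json"))
  write_selection_report(casc$report_combined, paths$selection["combined"],
                         file.path(out_dir, "selection_combined_summary.json"))

  # -- evaluate --------------------------------------------------------------
  groups <- list(`Lasso(WB)` = casc$lasso_wb, `Lasso(LL)` = casc$lasso_ll,
                 combined = casc$combined, `Lasso(combined)` = casc$lasso_combined)
  evaluation <- run_comparison(groups, labels, config$cv)
  write_evaluation_report(evaluation, paths$evaluation,
                          file.path(out_dir, "evaluation_summary.json"))

  files <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  files <- setdiff(files, paths$manifest)
  manifest <- list(
    package_version = as.character(utils::packageVersion("dynrad")),
    seed = config$cohort$seed,
    config = dr_plain(config),
    files = data.frame(path = basename(files),
                       md5 = unname(tools::md5sum(files))))
  jsonlite::write_json(manifest, paths$manifest, auto_unbox = TRUE, digits = NA)
  invisible(list(cohort = cohort, drf = drf, screen = screen, cascade = casc,
                 evaluation = evaluation, paths = paths))
}
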