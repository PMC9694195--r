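#' Extract the radiomics vector of one 3D volume and mask
#'
#' Computes every configured feature family on every configured derived
#' image.  With the full bank and all six families this yields the
#' 1674-feature vector (93 features x 18 derived images), named
#' `<filter>_<family>_<feature>`.
#'
#' @param volume Finite 3D array.
#' @param mask An `roi_mask` (or logical array) with at least 2 voxels.
#' @param spacing Voxel spacing in mm.
#' @param cfg A [feature_family_config()].
#' @param filters Subset of [filter_bank()] to use.
#' @return Named numeric vector; all values finite.
#' @export
extract_timepoint_features <- function(volume, mask, spacing = c(1, 1, 1),
                                       cfg = feature_family_config(),
                                       filters = filter_bank()) {
  m <- if (inherits(mask, "roi_mask")) mask$mask else array(as.logical(mask), dim = dim(mask))
  if (sum(m) < 2)
    dr_stop("mask has fewer than 2 voxels", "dynrad_degenerate_roi_error")
  if (!identical(dim(m), dim(volume)))
    dr_stop("mask grid does not match the volume", "dynrad_grid_mismatch_error")
  bank <- derive_filter_bank(volume, spacing, mask = m, filters = filters)
  dims <- as.integer(dim(volume))
  voxvol <- prod(spacing)
  midx <- as.vector(m)
  np <- sum(midx)
  out <- numeric(0)
  for (fname in names(bank)) {
    vals <- bank[[fname]][m]
    d <- dr_discretize(vals, cfg$bin_width)
    gvol <- integer(length(midx))
    gvol[midx] <- d$g
    for (fam in cfg$families) {
      feats <- switch(fam,
        firstorder = dr_fo_features(vals, cfg$bin_width, voxvol),
        glcm = dr_glcm_features(cpp_glcm(gvol, dims, d$ng)),
        glrlm = dr_glrlm_features(cpp_glrlm(gvol, dims, d$ng), np),
        glszm = dr_glszm_features(cpp_glszm(gvol, dims), np),
        ngtdm = dr_ngtdm_features(cpp_ngtdm(gvol, dims, d$ng)),
        gldm = dr_gldm_features(cpp_gldm(gvol, dims, d$ng, cfg$gldm_alpha), np))
      names(feats) <- paste(fname, fam, .dr_family_names[[fam]], sep = "_")
      out <- c(out, feats)
    }
  }
  if (any(!is.finite(out)))
    dr_stop(paste("non-finite feature values:",
                  paste(head(names(out)[!is.finite(out)], 5), collapse = ", ")),
            "dynrad_feature_error")
  out
}

#' Extract the dynamic radiomics (DRF) row of a study
#'
#' Concatenates the per-timepoint radiomics vectors in time order; names are
#' suffixed `_t` with 0-based timepoint index, so `<...>_1` is computed on
#' the second 3D volume S(1).
#'
#' @param study A `perfusion_study`.
#' @param mask An `roi_mask` on the study grid.
#' @param cfg A [feature_family_config()].
#' @param filters Subset of [filter_bank()].
#' @return Named numeric vector of length `T * features_per_timepoint`.
#' @export
extract_drf_row <- function(study, mask, cfg = feature_family_config(),
                            filters = filter_bank()) {
  stopifnot(inherits(study, "perfusion_study"))
  T <- dim(study$signal)[4]
  rows <- vector("list", T)
  for (t in seq_len(T)) {
    feats <- tryCatch(
      extract_timepoint_features(study$signal[, , , t, drop = TRUE], mask,
                                 study$spacing, cfg, filters),
      error = function(e) {
        dr_stop(sprintf("timepoint %d: %s", t - 1L, conditionMessage(e)),
                "dynrad_extraction_error")
      })
    names(feats) <- paste0(names(feats), "_", t - 1L)
    rows[[t]] <- feats
  }
  unlist(rows)
}

#' Build the cohort DRF matrix for one region
#'
#' @param cohort A `pwi_cohort` (all studies must share the grid and T).
#' @param region `"WB"` (whole brain) or `"LL"` (local lesion).
#' @param cfg A [feature_family_config()].
#' @param filters Subset of [filter_bank()].
#' @param smoothing Optional [smoothing_config()] applied to every study
#'   before extraction (`NULL` to skip).
#' @return A `drf_matrix`: numeric matrix (cases x DRFs) with attributes
#'   `region`, `labels`, `case_ids`.
#' @export
build_drf_matrix <- function(cohort, region = c("WB", "LL"),
                             cfg = feature_family_config(),
                             filters = filter_bank(),
                             smoothing = smoothing_config()) {
  region <- match.arg(region)
  Ts <- vapply(cohort, function(e) dim(e$study$signal)[4], integer(1))
  if (length(unique(Ts)) != 1)
    dr_stop("inconsistent number of timepoints across cases", "dynrad_cohort_error")
  rows <- vector("list", length(cohort))
  for (i in seq_along(cohort)) {
    e <- cohort[[i]]
    vm <- validate_masks(e$study, e$brain, e$lesion)
    study <- if (is.null(smoothing)) e$study else smooth_time_curves(e$study, smoothing)
    mask <- if (region == "WB") vm$brain else vm$lesion
    rows[[i]] <- extract_drf_row(study, mask, cfg, filters)
  }
  mat <- do.call(rbind, rows)
  rownames(mat) <- vapply(cohort, function(e) e$study$case_id, character(1))
  if (anyDuplicated(colnames(mat)))
    dr_stop("duplicated DRF column names", "dynrad_cohort_error")
  structure(mat, region = region, labels = cohort_labels(cohort),
            class = c("drf_matrix", class(mat)))
}

#' Decompose DRF column names into filter / family / feature / timepoint
#'
#' @param names Character vector of DRF names
#'   (`<filter>_<family>_<feature>_<t>`); the trailing timepoint is optional.
#' @return A data.frame with columns `name`, `filter`, `family`, `feature`,
#'   `timepoint` (NA when absent).
#' @export
parse_drf_names <- function(names) {
  out <- data.frame(name = names, filter = NA_character_,
                    family = NA_character_, feature = NA_character_,
                    timepoint = NA_integer_, stringsAsFactors = FALSE)
  # strip a region qualifier if present ("WB:" / "LL:")
  core <- sub("^(WB|LL):", "", names)
  parts <- strsplit(core, "_", fixed = TRUE)
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    if (length(p) < 3) next
    tp <- suppressWarnings(as.integer(p[length(p)]))
    if (!is.na(tp) && length(p) >= 4) {
      out$timepoint[i] <- tp
      p <- p[-length(p)]
    }
    out$filter[i] <- p[1]
    out$family[i] <- p[2]
    out$feature[i] <- paste(p[-(1:2)], collapse = "_")
  }
  out
}

#' Write a DRF matrix as CSV plus a columns manifest
#'
#' The CSV holds one row per case (first column `case_id`, second `label`);
#' the JSON manifest records the region and the filter/family/feature/
#' timepoint decomposition of every column.  Values are serialized at 10
#' significant digits.
#'
#' @param mat A `drf_matrix`.
#' @param csv_path,manifest_path Output paths (manifest optional).
#' @return Invisibly, `csv_path`.
#' @export
write_drf_matrix <- function(mat, csv_path, manifest_path = NULL) {
  dt <- data.table::data.table(case_id = rownames(mat),
                               label = attr(mat, "labels"))
  vals <- signif(unclass(mat), 10)
  dt <- cbind(dt, data.table::as.data.table(vals))
  data.table::fwrite(dt, csv_path)
  if (!is.null(manifest_path)) {
    man <- list(region = attr(mat, "region"), n_cases = nrow(mat),
                n_columns = ncol(mat), columns = parse_drf_names(colnames(mat)))
    jsonlite::write_json(man, manifest_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(csv_path)
}

#' Read a DRF matrix written by [write_drf_matrix()]
#' @param csv_path Path to the CSV table.
#' @param region Region tag to attach.
#' @return A `drf_matrix`.
#' @export
read_drf_matrix <- function(csv_path, region = "WB") {
  dt <- data.table::fread(csv_path)
  labels <- dt$label
  ids <- dt$case_id
  mat <- as.matrix(dt[, -(1:2)])
  rownames(mat) <- ids
  structure(mat, region = region, labels = labels,
            class = c("drf_matrix", class(mat)))
}
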