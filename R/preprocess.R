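#' Temporal smoothing configuration
#'
#' @param kernel_length Odd moving-average window length (default 3,
#'   i.e. a 1x3 kernel along time).
#' @param edge_policy `"truncate"` averages only the in-range samples at the
#'   series edges; `"replicate"` pads by repeating the edge sample.
#' @return An object of class `smoothing_config`.
#' @export
smoothing_config <- function(kernel_length = 3, edge_policy = c("truncate", "replicate")) {
  edge_policy <- match.arg(edge_policy)
  if (kernel_length < 1 || kernel_length %% 2 == 0)
    dr_stop("kernel_length must be odd and >= 1", "dynrad_config_error")
  structure(list(kernel_length = as.integer(kernel_length), edge_policy = edge_policy),
            class = "smoothing_config")
}

#' Smooth each voxel's time-intensity curve
#'
#' Replaces every voxel's time series by its centered moving average of
#' length `kernel_length` (default 1x3).  Spatial geometry is unchanged.
#' The operation is linear in the input and never increases per-voxel
#' temporal variance.
#'
#' @param study A `perfusion_study`.
#' @param cfg A [smoothing_config()].
#' @return The smoothed `perfusion_study`.
#' @export
smooth_time_curves <- function(study, cfg = smoothing_config()) {
  stopifnot(inherits(study, "perfusion_study"), inherits(cfg, "smoothing_config"))
  dm <- dim(study$signal)
  T <- dm[4]
  if (T < cfg$kernel_length)
    dr_stop("series shorter than smoothing kernel", "dynrad_config_error")
  h <- (cfg$kernel_length - 1L) / 2L
  m <- matrix(study$signal, ncol = T)
  out <- matrix(0, nrow = nrow(m), ncol = T)
  for (t in seq_len(T)) {
    lo <- t - h; hi <- t + h
    if (cfg$edge_policy == "truncate") {
      w <- max(1L, lo):min(T, hi)
      out[, t] <- rowMeans(m[, w, drop = FALSE])
    } else {
      w <- pmin(pmax(lo:hi, 1L), T)
      out[, t] <- rowMeans(m[, w, drop = FALSE])
    }
  }
  study$signal <- array(out, dim = dm)
  study
}

#' Average 3D volume over the bolus-free window
#'
#' Voxelwise mean of the first `n` and last `n` 3D volumes of the series,
#' with denominator `2n`.  With `n = 15` of `N = 50` measurements this
#' excludes the contrast transit and yields a quasi-baseline volume, used
#' for mask quality control.
#'
#' @param study A `perfusion_study` with `N` timepoints.
#' @param n Window size at each end of the series (default 15); requires
#'   `2n <= N`.
#' @return A 3D array.
#' @export
average_volume <- function(study, n = 15) {
  stopifnot(inherits(study, "perfusion_study"))
  dm <- dim(study$signal)
  N <- dm[4]
  if (2 * n > N)
    dr_stop("average window 2n exceeds the number of measurements", "dynrad_window_error")
  m <- matrix(study$signal, ncol = N)
  idx <- c(seq_len(n), seq(N - n + 1L, N))
  array(rowMeans(m[, idx, drop = FALSE]), dim = dm[1:3])
}

#' Validate a whole-brain / lesion mask pair against a study
#'
#' Asserts that both masks live on the study grid, are binary and non-empty,
#' and that the lesion is contained in the brain.  Returns the masks
#' unchanged.
#'
#' @param study A `perfusion_study`.
#' @param brain,lesion `roi_mask` objects (or raw binary arrays).
#' @return `list(brain, lesion)` of validated `roi_mask` objects.
#' @export
validate_masks <- function(study, brain, lesion) {
  stopifnot(inherits(study, "perfusion_study"))
  if (!inherits(brain, "roi_mask")) brain <- roi_mask(brain, "whole_brain")
  if (!inherits(lesion, "roi_mask")) lesion <- roi_mask(lesion, "lesion")
  gdim <- dim(study$signal)[1:3]
  if (!identical(dim(brain$mask), gdim) || !identical(dim(lesion$mask), gdim))
    dr_stop("mask grid does not match the study grid", "dynrad_grid_mismatch_error")
  if (!any(brain$mask) || !any(lesion$mask))
    dr_stop("mask is empty", "dynrad_mask_empty_error")
  if (any(lesion$mask & !brain$mask))
    dr_stop("lesion mask extends outside the brain mask", "dynrad_containment_error")
  list(brain = brain, lesion = lesion)
}
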