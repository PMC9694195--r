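# Coiflets-1 decomposition filter pair (6 taps).  The high-pass filter is
# the quadrature mirror of the low-pass one; it annihilates constants.
.dr_coif1_lo <- c(-0.01565572813546454, -0.07273261951285390,
                  0.38486484686420286,  0.85257202021225542,
                  0.33789766245780922, -0.07273261951285390)
.dr_coif1_hi <- c(-0.07273261951285390, -0.33789766245780922,
                  0.85257202021225542, -0.38486484686420286,
                  -0.07273261951285390, 0.01565572813546454)

.dr_log_sigmas <- 1:5  # mm

#' Canonical derived-image (filter bank) names
#'
#' The 18-member bank: the original image, the 8 sub-bands of a single-level
#' stationary 3D coiflets-1 wavelet transform, Laplacian-of-Gaussian at
#' sigma 1--5 mm, and four monotone intensity remaps (square, square root,
#' logarithm, exponential).
#'
#' @return Character vector of 18 canonical filter names, in fixed order.
#' @export
filter_bank <- function() {
  c("original",
    paste0("wavelet-", c("LLL", "LLH", "LHL", "LHH", "HLL", "HLH", "HHL", "HHH")),
    sprintf("log-sigma-%d-0-mm-3D", .dr_log_sigmas),
    "square", "squareroot", "logarithm", "exponential")
}

dr_conv3 <- function(v, dims, k, axis, mode) {
  cpp_conv_axis(v, dims, k, axis, as.integer((length(k) - 1) %/% 2), mode)
}

# stationary (undecimated) single-level 3D wavelet sub-bands; band letters
# index the (x, y, z) axes in order; periodic boundary handling
dr_wavelet_bands <- function(vol) {
  dims <- as.integer(dim(vol))
  v <- as.double(vol)
  lo <- .dr_coif1_lo; hi <- .dr_coif1_hi
  ax <- function(v, k, axis) cpp_conv_axis(v, dims, k, axis, 2L, 0L)
  Lx <- ax(v, lo, 0L); Hx <- ax(v, hi, 0L)
  out <- list()
  for (bx in c("L", "H")) {
    vx <- if (bx == "L") Lx else Hx
    for (by in c("L", "H")) {
      vxy <- ax(vx, if (by == "L") lo else hi, 1L)
      for (bz in c("L", "H")) {
        band <- paste0("wavelet-", bx, by, bz)
        out[[band]] <- array(ax(vxy, if (bz == "L") lo else hi, 2L), dim = dims)
      }
    }
  }
  # reorder to canonical LLL, LLH, LHL, LHH, HLL, HLH, HHL, HHH
  out[paste0("wavelet-", c("LLL", "LLH", "LHL", "LHH", "HLL", "HLH", "HHL", "HHH"))]
}

# scale-normalized Laplacian of Gaussian at sigma (mm); replicate boundary
dr_log_filter <- function(vol, spacing, sigma_mm) {
  dims <- as.integer(dim(vol))
  v <- as.double(vol)
  for (axis in 0:2) {
    s_vox <- sigma_mm / spacing[axis + 1]
    r <- max(1L, as.integer(ceiling(4 * s_vox)))
    k <- stats::dnorm(seq(-r, r), sd = s_vox)
    k <- k / sum(k)
    v <- cpp_conv_axis(v, dims, k, axis, r, 1L)
  }
  lap <- numeric(length(v))
  for (axis in 0:2) {
    k2 <- c(1, -2, 1) / spacing[axis + 1]^2
    lap <- lap + cpp_conv_axis(v, dims, k2, axis, 1L, 1L)
  }
  array(sigma_mm^2 * lap, dim = dims)
}

#' Derive the 18-member filter bank of a 3D volume
#'
#' Computes all derived images the radiomics features are extracted from.
#' The intensity remaps (square, square root, logarithm, exponential) are
#' monotone and rescaled to the intensity range observed inside `mask`
#' (whole volume if `mask` is `NULL`), so that a fixed discretization bin
#' width remains meaningful on every derived image; their normalization
#' constants depend only on in-mask voxels.
#'
#' @param volume Finite 3D array.
#' @param spacing Voxel spacing in mm (length 3); used by the
#'   Laplacian-of-Gaussian filters.
#' @param mask Optional logical array delimiting the region whose intensity
#'   range anchors the remap filters.
#' @param filters Subset of [filter_bank()] names to compute.
#' @return Named list of 3D arrays, in canonical order.
#' @export
derive_filter_bank <- function(volume, spacing = c(1, 1, 1), mask = NULL,
                               filters = filter_bank()) {
  if (any(!is.finite(volume)))
    dr_stop("volume contains non-finite values", "dynrad_input_error")
  if (any(spacing <= 0))
    dr_stop("voxel spacing must be positive", "dynrad_input_error")
  bad <- setdiff(filters, filter_bank())
  if (length(bad))
    dr_stop(paste("unknown filters:", paste(bad, collapse = ", ")), "dynrad_config_error")
  ref <- if (is.null(mask)) as.vector(volume) else volume[mask]
  mn <- min(ref); mx <- max(ref); rng <- mx - mn
  out <- list()
  if ("original" %in% filters) out$original <- volume
  if (any(startsWith(filters, "wavelet-"))) {
    wb <- dr_wavelet_bands(volume)
    out <- c(out, wb[intersect(names(wb), filters)])
  }
  for (s in .dr_log_sigmas) {
    nm <- sprintf("log-sigma-%d-0-mm-3D", s)
    if (nm %in% filters) out[[nm]] <- dr_log_filter(volume, spacing, s)
  }
  if ("square" %in% filters) {
    M <- max(abs(ref))
    out$square <- if (M > 0) volume^2 / M else volume * 0
  }
  z <- pmax(volume - mn, 0)
  if ("squareroot" %in% filters)
    out$squareroot <- if (rng > 0) sqrt(z * rng) else z * 0
  if ("logarithm" %in% filters)
    out$logarithm <- if (rng > 0) log1p(z) * rng / log1p(rng) else z * 0
  if ("exponential" %in% filters)
    out$exponential <- if (rng > 0) expm1(z / rng * log1p(rng)) else z * 0
  out[intersect(filter_bank(), names(out))]
}
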