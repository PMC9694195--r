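#' Gamma-variate bolus model
#'
#' Parameterizes the contrast-agent transit of a DSC-PWI acquisition as a
#' gamma-variate concentration curve together with the exponential
#' signal-attenuation law `S(t) = S0 * exp(-k * C(t))`.  Defaults place the
#' concentration peak (and hence the signal nadir) at timepoint
#' `t0 + alpha * beta = 19`, inside the 17--22 transit window typical of a
#' 50-measurement acquisition.
#'
#' @param t0 Bolus arrival time (timepoint units).
#' @param alpha Gamma shape parameter (> 0, dimensionless).
#' @param beta Gamma scale parameter (> 0, timepoint units).
#' @param amplitude Peak concentration scale (>= 0, arbitrary units).
#' @param k Signal-attenuation coefficient per concentration unit.
#' @param baseline Pre-bolus signal intensity S0 (> 0).
#' @return An object of class `bolus_model`.
#' @export
#' @examples
#' b <- bolus_model()
#' gamma_variate_concentration(19, b)
bolus_model <- function(t0 = 12, alpha = 3.5, beta = 2, amplitude = 0.18,
                        k = 0.1, baseline = 100) {
  vals <- c(t0, alpha, beta, amplitude, k, baseline)
  if (any(!is.finite(vals)))
    dr_stop("bolus parameters must be finite", "dynrad_parameter_error")
  if (alpha <= 0 || beta <= 0 || amplitude < 0 || baseline <= 0)
    dr_stop("bolus parameters out of range (alpha, beta > 0; amplitude >= 0; baseline > 0)",
            "dynrad_parameter_error")
  structure(list(t0 = t0, alpha = alpha, beta = beta, amplitude = amplitude,
                 k = k, baseline = baseline), class = "bolus_model")
}

#' Evaluate the gamma-variate concentration curve
#'
#' `C(t) = amplitude * (t - t0)^alpha * exp(-(t - t0) / beta)` for `t > t0`
#' and 0 otherwise; the curve is continuous in `t` and peaks at
#' `t0 + alpha * beta`.
#'
#' @param t Time (timepoint units), scalar or vector, `t >= 0`.
#' @param bolus A [bolus_model()].
#' @return Concentration value(s), same length as `t`.
#' @export
gamma_variate_concentration <- function(t, bolus) {
  stopifnot(inherits(bolus, "bolus_model"))
  if (any(!is.finite(t)) || any(t < 0))
    dr_stop("t must be finite and >= 0", "dynrad_parameter_error")
  dt <- t - bolus$t0
  out <- numeric(length(t))
  pos <- dt > 0
  out[pos] <- bolus$amplitude * dt[pos]^bolus$alpha * exp(-dt[pos] / bolus$beta)
  out
}

#' Lesion perfusion effect
#'
#' Describes how the ischemic lesion modifies the bolus transit relative to
#' healthy tissue: an added arrival delay (the simulator's analog of the
#' clinical Tmax > 6 s criterion), an amplitude attenuation, and a spatially
#' correlated heterogeneity field added to the lesion baseline signal.
#'
#' @param delay Added arrival delay inside the lesion (timepoint units, >= 0).
#' @param amplitude_factor Lesion amplitude multiplier in `[0, 1]`.
#' @param texture_sd Standard deviation of the smoothed heterogeneity field
#'   added to the lesion baseline (intensity units, >= 0).
#' @return An object of class `lesion_effect`.
#' @export
lesion_effect <- function(delay = 2, amplitude_factor = 0.7, texture_sd = 5) {
  if (delay < 0 || amplitude_factor < 0 || amplitude_factor > 1 || texture_sd < 0)
    dr_stop("lesion effect out of range (delay >= 0, 0 <= amplitude_factor <= 1, texture_sd >= 0)",
            "dynrad_parameter_error")
  structure(list(delay = delay, amplitude_factor = amplitude_factor,
                 texture_sd = texture_sd), class = "lesion_effect")
}

#' Cohort simulation configuration
#'
#' Defines the full set of study conditions for a synthetic DSC-PWI cohort:
#' group sizes (defaults 42 good / 36 poor outcomes), grid and timing
#' (default 50 measurements), the bolus and lesion models, and the two
#' independently parameterized outcome effects -- a whole-brain transit
#' broadening (`global_effect`, fractional increase of the gamma scale in
#' poor-outcome cases) and a lesion-specific increment
#' (`lesion_effect_delta`) added to the lesion delay, amplitude factor and
#' heterogeneity in poor-outcome cases.
#'
#' @param n_good,n_poor Number of good-/poor-outcome cases.
#' @param grid Integer triple `(X, Y, Z)` of voxel counts.
#' @param n_timepoints Number of measurements T (>= 3).
#' @param voxel_spacing Voxel spacing in mm, length 3.
#' @param noise_sd Additive Gaussian noise SD (intensity units); the signal
#'   is truncated at 0 after noise.
#' @param bolus A [bolus_model()].
#' @param lesion A [lesion_effect()].
#' @param global_effect Fractional broadening of the bolus gamma scale in
#'   poor-outcome cases (whole-brain effect).
#' @param lesion_effect_delta Named list with `delay`, `amplitude_factor`,
#'   `texture_sd` increments applied to the lesion effect in poor-outcome
#'   cases (amplitude factor is clamped to `[0, 1]`).
#' @param baseline_texture_sd SD of the smoothed whole-brain baseline
#'   heterogeneity field (intensity units); gives healthy tissue a texture.
#' @param texture_kernel_vox Gaussian kernel SD (voxels) used to spatially
#'   correlate the heterogeneity fields.
#' @param seed RNG seed for the cohort.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_good = 42, n_poor = 36, grid = c(48, 48, 12),
                          n_timepoints = 50, voxel_spacing = c(4, 4, 6),
                          noise_sd = 2, bolus = bolus_model(),
                          lesion = lesion_effect(), global_effect = 0.15,
                          lesion_effect_delta = list(delay = 2,
                                                     amplitude_factor = -0.15,
                                                     texture_sd = 4),
                          baseline_texture_sd = 5, texture_kernel_vox = 1.5,
                          seed = 1L) {
  if (n_good < 0 || n_poor < 0)
    dr_stop("group sizes must be >= 0", "dynrad_parameter_error")
  if (n_timepoints < 3)
    dr_stop("need at least 3 timepoints", "dynrad_parameter_error")
  if (length(grid) != 3 || any(grid < 4))
    dr_stop("grid must be an (X, Y, Z) triple with all dims >= 4", "dynrad_parameter_error")
  structure(list(n_good = as.integer(n_good), n_poor = as.integer(n_poor),
                 grid = as.integer(grid), n_timepoints = as.integer(n_timepoints),
                 voxel_spacing = as.numeric(voxel_spacing), noise_sd = noise_sd,
                 bolus = bolus, lesion = lesion, global_effect = global_effect,
                 lesion_effect_delta = lesion_effect_delta,
                 baseline_texture_sd = baseline_texture_sd,
                 texture_kernel_vox = texture_kernel_vox,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' Construct a region-of-interest mask
#'
#' @param mask Logical (or 0/1) 3D array on the study grid.
#' @param region Region tag, `"whole_brain"` or `"lesion"`.
#' @return An object of class `roi_mask`.
#' @export
roi_mask <- function(mask, region = c("whole_brain", "lesion")) {
  region <- match.arg(region)
  vals <- unique(as.vector(mask))
  if (!all(vals %in% c(0, 1, TRUE, FALSE)))
    dr_stop("mask must be binary", "dynrad_mask_binarity_error")
  m <- array(as.logical(mask), dim = dim(mask))
  if (!any(m)) dr_stop("mask is empty", "dynrad_mask_empty_error")
  structure(list(mask = m, region = region), class = "roi_mask")
}

# smoothed standard-normal field on the grid: Gaussian blur of iid noise,
# rescaled so the pointwise SD is 1 (uses the exact kernel-energy factor)
dr_smooth_field <- function(grid, kernel_sd) {
  noise <- array(stats::rnorm(prod(grid)), dim = grid)
  if (kernel_sd <= 0) return(noise)
  r <- max(1L, ceiling(3 * kernel_sd))
  k <- stats::dnorm(seq(-r, r), sd = kernel_sd)
  k <- k / sum(k)
  v <- as.double(noise)
  for (ax in 0:2) v <- cpp_conv_axis(v, as.integer(grid), k, ax, r, 1L)
  # after three separable passes the variance shrinks by (sum k^2)^3
  array(v / sqrt(sum(k^2))^3, dim = grid)
}

# ellipsoidal masks for brain and lesion; lesion strictly inside the brain
dr_default_masks <- function(grid) {
  X <- grid[1]; Y <- grid[2]; Z <- grid[3]
  cx <- (X + 1) / 2; cy <- (Y + 1) / 2; cz <- (Z + 1) / 2
  rx <- 0.42 * X; ry <- 0.42 * Y; rz <- 0.40 * Z
  xs <- seq_len(X); ys <- seq_len(Y); zs <- seq_len(Z)
  d2 <- outer(outer(((xs - cx) / rx)^2, ((ys - cy) / ry)^2, `+`),
              ((zs - cz) / rz)^2, `+`)
  brain <- d2 <= 1
  lx <- cx + 0.18 * X
  lrx <- 0.12 * X; lry <- 0.12 * Y; lrz <- 0.22 * Z
  l2 <- outer(outer(((xs - lx) / lrx)^2, ((ys - cy) / lry)^2, `+`),
              ((zs - cz) / lrz)^2, `+`)
  lesion <- l2 <= 1
  if (any(lesion & !brain))
    dr_stop("lesion placement falls outside the brain mask", "dynrad_construction_error")
  if (!any(lesion))
    dr_stop("grid too small to place a lesion", "dynrad_construction_error")
  list(brain = brain, lesion = lesion)
}

#' Simulate one DSC-PWI study
#'
#' Builds a single 4D perfusion study with whole-brain and lesion masks.
#' Each brain voxel follows `S(t) = B(v) * exp(-k * C(t)) + noise`, where
#' `B(v)` is the baseline plus smoothed heterogeneity, and `C(t)` is the
#' gamma-variate concentration of the voxel's compartment (lesion voxels use
#' a delayed, attenuated bolus).  For poor-outcome cases the gamma scale is
#' broadened by `global_effect` and the lesion effect is shifted by
#' `lesion_effect_delta`.  Deterministic for a fixed `seed`.
#'
#' @param config A [cohort_config()].
#' @param label Outcome label: 0 = good, 1 = poor.
#' @param seed Integer seed for this study's RNG substream.
#' @param case_id Case identifier string.
#' @return A list with elements `study` (class `perfusion_study`), `brain`
#'   and `lesion` (class `roi_mask`).
#' @export
simulate_study <- function(config, label, seed, case_id = "case") {
  stopifnot(inherits(config, "cohort_config"), label %in% c(0, 1))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv), add = TRUE)
  set.seed(as.integer(seed))

  grid <- config$grid; T <- config$n_timepoints
  b <- config$bolus; les <- config$lesion
  beta <- b$beta
  delay <- les$delay; af <- les$amplitude_factor; tsd <- les$texture_sd
  if (label == 1) {
    beta <- beta * (1 + config$global_effect)
    d <- config$lesion_effect_delta
    delay <- delay + d$delay
    af <- min(1, max(0, af + d$amplitude_factor))
    tsd <- max(0, tsd + d$texture_sd)
  }
  tt <- seq_len(T) - 1
  bol <- bolus_model(t0 = b$t0, alpha = b$alpha, beta = beta,
                     amplitude = b$amplitude, k = b$k, baseline = b$baseline)
  c_tissue <- gamma_variate_concentration(tt, bol)
  bol_les <- bolus_model(t0 = b$t0 + delay, alpha = b$alpha, beta = beta,
                         amplitude = b$amplitude * af, k = b$k, baseline = b$baseline)
  c_lesion <- gamma_variate_concentration(tt, bol_les)

  masks <- dr_default_masks(grid)
  nvox <- prod(grid)
  base_field <- config$bolus$baseline +
    config$baseline_texture_sd * dr_smooth_field(grid, config$texture_kernel_vox)
  if (tsd > 0) {
    lf <- dr_smooth_field(grid, config$texture_kernel_vox)
    base_field[masks$lesion] <- base_field[masks$lesion] + tsd * lf[masks$lesion]
  }

  sig <- matrix(0, nrow = nvox, ncol = T)
  idx_les <- which(as.vector(masks$lesion))
  idx_tis <- which(as.vector(masks$brain) & !as.vector(masks$lesion))
  bvec <- as.vector(base_field)
  sig[idx_tis, ] <- outer(bvec[idx_tis], exp(-b$k * c_tissue))
  sig[idx_les, ] <- outer(bvec[idx_les], exp(-b$k * c_lesion))
  if (config$noise_sd > 0)
    sig <- sig + matrix(stats::rnorm(nvox * T, sd = config$noise_sd), nvox, T)
  sig <- pmax(sig, 0)

  study <- structure(list(signal = array(sig, dim = c(grid, T)),
                          spacing = config$voxel_spacing,
                          case_id = case_id, label = as.integer(label)),
                     class = "perfusion_study")
  list(study = study,
       brain = roi_mask(masks$brain, "whole_brain"),
       lesion = roi_mask(masks$lesion, "lesion"))
}

#' Generate a full synthetic cohort
#'
#' Draws `n_good + n_poor` studies with labels shuffled by the cohort seed;
#' each study receives an independent RNG substream so the cohort is
#' reproducible case-by-case.
#'
#' @param config A [cohort_config()].
#' @return A list of class `pwi_cohort`; each element has `study`, `brain`,
#'   `lesion`.  The configuration is attached as attribute `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n_good + config$n_poor
  if (n == 0) dr_stop("cohort has zero cases", "dynrad_empty_cohort_error")
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv), add = TRUE)
  set.seed(config$seed)
  labels <- c(rep(0L, config$n_good), rep(1L, config$n_poor))
  labels <- labels[sample.int(n)]
  seeds <- vapply(seq_len(n), function(i) dr_child_seed(config$seed, i), integer(1))
  cohort <- vector("list", n)
  for (i in seq_len(n)) {
    cohort[[i]] <- simulate_study(config, labels[i], seeds[i],
                                  case_id = sprintf("case_%03d", i))
  }
  structure(cohort, class = "pwi_cohort", config = config)
}

#' Extract the label vector of a cohort
#' @param cohort A `pwi_cohort`.
#' @return Integer vector of 0/1 outcome labels in cohort order.
#' @export
cohort_labels <- function(cohort) {
  vapply(cohort, function(e) e$study$label, integer(1))
}

#' Write a cohort to disk as NIfTI volumes plus a labels table
#'
#' Writes `case_<id>_pwi.nii.gz` (4D), `case_<id>_brain.nii.gz` and
#' `case_<id>_lesion.nii.gz` per case, and a `labels.csv` with columns
#' `case_id` and `mrs_group` (`good`/`poor`).
#'
#' @param cohort A `pwi_cohort`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the path to `labels.csv`.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ids <- character(length(cohort))
  for (i in seq_along(cohort)) {
    e <- cohort[[i]]
    id <- e$study$case_id
    ids[i] <- id
    sp <- e$study$spacing
    img <- RNifti::asNifti(e$study$signal, pixdim = c(sp, 1))
    RNifti::writeNifti(img, file.path(dir, sprintf("%s_pwi.nii.gz", id)))
    RNifti::writeNifti(RNifti::asNifti(e$brain$mask * 1L, pixdim = sp),
                       file.path(dir, sprintf("%s_brain.nii.gz", id)))
    RNifti::writeNifti(RNifti::asNifti(e$lesion$mask * 1L, pixdim = sp),
                       file.path(dir, sprintf("%s_lesion.nii.gz", id)))
  }
  labels <- data.frame(case_id = ids,
                       mrs_group = ifelse(cohort_labels(cohort) == 1, "poor", "good"))
  path <- file.path(dir, "labels.csv")
  utils::write.csv(labels, path, row.names = FALSE)
  invisible(path)
}

#' Read one study and its masks from NIfTI files
#'
#' @param pwi,brain,lesion Paths to the 4D signal and the two binary masks.
#' @param case_id Case identifier.
#' @param label Outcome label (0/1) or NA if unknown.
#' @return As [simulate_study()]: list with `study`, `brain`, `lesion`.
#' @export
read_study <- function(pwi, brain, lesion, case_id = basename(pwi), label = NA_integer_) {
  img <- RNifti::readNifti(pwi)
  sp <- attr(img, "pixdim")[1:3]
  if (is.null(sp) || any(!is.finite(sp)) || any(sp <= 0)) sp <- c(1, 1, 1)
  arr <- array(as.numeric(img), dim = dim(img))
  study <- structure(list(signal = arr, spacing = sp, case_id = case_id,
                          label = as.integer(label)),
                     class = "perfusion_study")
  list(study = study,
       brain = roi_mask(array(as.numeric(RNifti::readNifti(brain)) > 0.5,
                              dim = dim(img)[1:3]), "whole_brain"),
       lesion = roi_mask(array(as.numeric(RNifti::readNifti(lesion)) > 0.5,
                               dim = dim(img)[1:3]), "lesion"))
}
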