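# Canonical feature names per family.  Cardinalities are part of the
# package contract: 18 + 24 + 16 + 16 + 5 + 14 = 93 per derived image.
.dr_fo_names <- c("Energy", "TotalEnergy", "Entropy", "Minimum", "10Percentile",
                  "90Percentile", "Maximum", "Mean", "Median",
                  "InterquartileRange", "Range", "MeanAbsoluteDeviation",
                  "RobustMeanAbsoluteDeviation", "RootMeanSquared", "Skewness",
                  "Kurtosis", "Variance", "Uniformity")
.dr_glcm_names <- c("Autocorrelation", "ClusterProminence", "ClusterShade",
                    "ClusterTendency", "Contrast", "Correlation",
                    "DifferenceAverage", "DifferenceEntropy",
                    "DifferenceVariance", "Id", "Idm", "Idmn", "Idn", "Imc1",
                    "Imc2", "InverseVariance", "JointAverage", "JointEnergy",
                    "JointEntropy", "MaximumProbability", "MCC", "SumAverage",
                    "SumEntropy", "SumSquares")
.dr_glrlm_names <- c("GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
                     "GrayLevelVariance", "HighGrayLevelRunEmphasis",
                     "LongRunEmphasis", "LongRunHighGrayLevelEmphasis",
                     "LongRunLowGrayLevelEmphasis", "LowGrayLevelRunEmphasis",
                     "RunEntropy", "RunLengthNonUniformity",
                     "RunLengthNonUniformityNormalized", "RunPercentage",
                     "RunVariance", "ShortRunEmphasis",
                     "ShortRunHighGrayLevelEmphasis", "ShortRunLowGrayLevelEmphasis")
.dr_glszm_names <- c("GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
                     "GrayLevelVariance", "HighGrayLevelZoneEmphasis",
                     "LargeAreaEmphasis", "LargeAreaHighGrayLevelEmphasis",
                     "LargeAreaLowGrayLevelEmphasis", "LowGrayLevelZoneEmphasis",
                     "SizeZoneNonUniformity", "SizeZoneNonUniformityNormalized",
                     "SmallAreaEmphasis", "SmallAreaHighGrayLevelEmphasis",
                     "SmallAreaLowGrayLevelEmphasis", "ZoneEntropy",
                     "ZonePercentage", "ZoneVariance")
.dr_ngtdm_names <- c("Busyness", "Coarseness", "Complexity", "Contrast", "Strength")
.dr_gldm_names <- c("DependenceEntropy", "DependenceNonUniformity",
                    "DependenceNonUniformityNormalized", "DependenceVariance",
                    "GrayLevelNonUniformity", "GrayLevelVariance",
                    "HighGrayLevelEmphasis", "LargeDependenceEmphasis",
                    "LargeDependenceHighGrayLevelEmphasis",
                    "LargeDependenceLowGrayLevelEmphasis", "LowGrayLevelEmphasis",
                    "SmallDependenceEmphasis", "SmallDependenceHighGrayLevelEmphasis",
                    "SmallDependenceLowGrayLevelEmphasis")

.dr_family_names <- list(firstorder = .dr_fo_names, glcm = .dr_glcm_names,
                         glrlm = .dr_glrlm_names, glszm = .dr_glszm_names,
                         ngtdm = .dr_ngtdm_names, gldm = .dr_gldm_names)

#' Feature family configuration
#'
#' @param bin_width Fixed intensity bin width used to discretize in-mask
#'   values before texture-matrix computation (and for the first-order
#'   entropy/uniformity histogram).  Bins are anchored at the in-mask
#'   minimum, making all discretized features invariant to intensity shifts.
#' @param families Which of the six families to compute.
#' @param gldm_alpha Gray-level difference tolerance of the dependence
#'   matrix (default 0: neighbours must match exactly).
#' @return An object of class `feature_family_config`.
#' @export
feature_family_config <- function(bin_width = 25,
                                  families = names(.dr_family_names),
                                  gldm_alpha = 0) {
  if (bin_width <= 0) dr_stop("bin_width must be > 0", "dynrad_config_error")
  bad <- setdiff(families, names(.dr_family_names))
  if (length(bad))
    dr_stop(paste("unknown families:", paste(bad, collapse = ", ")), "dynrad_config_error")
  structure(list(bin_width = bin_width,
                 families = intersect(names(.dr_family_names), families),
                 gldm_alpha = as.integer(gldm_alpha)),
            class = "feature_family_config")
}

#' Feature-name catalogue
#' @return Named list of canonical feature names per family.
#' @export
feature_families <- function() .dr_family_names

# discretize in-mask values with a fixed bin width anchored at the minimum;
# returns gray levels 1..Ng
dr_discretize <- function(vals, bin_width) {
  g <- as.integer(floor((vals - min(vals)) / bin_width)) + 1L
  list(g = g, ng = max(g))
}

.dr_eps <- 2.220446e-16

dr_fo_features <- function(vals, bin_width, voxel_volume) {
  n <- length(vals)
  d <- dr_discretize(vals, bin_width)
  p <- tabulate(d$g, d$ng) / n
  p <- p[p > 0]
  mu <- mean(vals)
  m2 <- mean((vals - mu)^2)
  q <- quantile(vals, c(0.10, 0.25, 0.50, 0.75, 0.90), names = FALSE, type = 7)
  rob <- vals[vals >= q[1] & vals <= q[5]]
  c(Energy = sum(vals^2),
    TotalEnergy = voxel_volume * sum(vals^2),
    Entropy = -sum(p * log2(p)),
    Minimum = min(vals),
    `10Percentile` = q[1],
    `90Percentile` = q[5],
    Maximum = max(vals),
    Mean = mu,
    Median = q[3],
    InterquartileRange = q[4] - q[2],
    Range = max(vals) - min(vals),
    MeanAbsoluteDeviation = mean(abs(vals - mu)),
    RobustMeanAbsoluteDeviation = if (length(rob)) mean(abs(rob - mean(rob))) else 0,
    RootMeanSquared = sqrt(mean(vals^2)),
    Skewness = if (m2 > 0) mean((vals - mu)^3) / m2^1.5 else 0,
    Kurtosis = if (m2 > 0) mean((vals - mu)^4) / m2^2 else 0,
    Variance = m2,
    Uniformity = sum(p^2))
}

dr_glcm_one <- function(P) {
  s <- sum(P)
  ng <- nrow(P)
  p <- P / s
  iv <- matrix(seq_len(ng), ng, ng)
  jv <- t(iv)
  px <- rowSums(p)              # == colSums(p) by symmetry
  mu <- sum(iv * p)
  sigma2 <- sum((iv - mu)^2 * p)
  ks <- as.vector(iv + jv)
  pxy <- rowsum(as.vector(p), ks)            # p_{x+y}, k = 2..2Ng
  kvals <- as.numeric(rownames(pxy))
  dd <- as.vector(abs(iv - jv))
  pxmy <- rowsum(as.vector(p), dd)           # p_{x-y}, k = 0..Ng-1
  dvals <- as.numeric(rownames(pxmy))
  da <- sum(dvals * pxmy)
  nz <- p > 0
  hxy <- -sum(p[nz] * log2(p[nz]))
  pipj <- outer(px, px)
  hxy1 <- -sum(p[nz] * log2(pipj[nz] + .dr_eps))
  nz2 <- pipj > 0
  hxy2 <- -sum(pipj[nz2] * log2(pipj[nz2]))
  hx <- { q <- px[px > 0]; -sum(q * log2(q)) }
  imc1 <- if (hx > 0) (hxy - hxy1) / hx else 0
  imc2 <- sqrt(pmax(0, 1 - exp(-2 * (hxy2 - hxy))))
  offd <- iv != jv
  # MCC: second-largest eigenvalue magnitude of the gray-level transition
  # kernel, restricted to occupied levels
  occ <- which(px > 0)
  mcc <- if (length(occ) < 2) 1 else {
    psub <- p[occ, occ, drop = FALSE]
    pxs <- px[occ]
    A <- sweep(psub, 2, pxs, "/")        # A[i, k] = p(i, k) / py(k)
    Q <- (psub / pxs) %*% t(A)           # Q[i, j] = sum_k p(i,k) p(j,k) / (px(i) py(k))
    ev <- sort(Mod(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    sqrt(pmax(0, min(ev[2], 1)))
  }
  pxypos <- pxy[pxy > 0]; pxmypos <- pxmy[pxmy > 0]
  c(Autocorrelation = sum(iv * jv * p),
    ClusterProminence = sum((iv + jv - 2 * mu)^4 * p),
    ClusterShade = sum((iv + jv - 2 * mu)^3 * p),
    ClusterTendency = sum((iv + jv - 2 * mu)^2 * p),
    Contrast = sum((iv - jv)^2 * p),
    Correlation = if (sigma2 > 0) (sum(iv * jv * p) - mu^2) / sigma2 else 1,
    DifferenceAverage = da,
    DifferenceEntropy = -sum(pxmypos * log2(pxmypos)),
    DifferenceVariance = sum((dvals - da)^2 * pxmy),
    Id = sum(p / (1 + abs(iv - jv))),
    Idm = sum(p / (1 + (iv - jv)^2)),
    Idmn = sum(p / (1 + (iv - jv)^2 / ng^2)),
    Idn = sum(p / (1 + abs(iv - jv) / ng)),
    Imc1 = imc1,
    Imc2 = imc2,
    InverseVariance = sum(p[offd] / (iv[offd] - jv[offd])^2),
    JointAverage = mu,
    JointEnergy = sum(p^2),
    JointEntropy = hxy,
    MaximumProbability = max(p),
    MCC = mcc,
    SumAverage = sum(kvals * pxy),
    SumEntropy = -sum(pxypos * log2(pxypos)),
    SumSquares = sigma2)
}

dr_glcm_features <- function(Plist) {
  mats <- Filter(function(P) sum(P) > 0, Plist)
  if (!length(mats)) return(stats::setNames(numeric(24), .dr_glcm_names))
  rowMeans(vapply(mats, dr_glcm_one, numeric(24)))
}

dr_rlm_one <- function(P, np) {
  nr <- sum(P)
  p <- P / nr
  ng <- nrow(P)
  iv <- matrix(seq_len(ng), ng, ncol(P))
  rv <- matrix(seq_len(ncol(P)), ng, ncol(P), byrow = TRUE)
  pg <- rowSums(P)   # runs per gray level
  pr <- colSums(P)   # runs per length
  mu_g <- sum(iv * p)
  mu_r <- sum(rv * p)
  ppos <- p[p > 0]
  c(GrayLevelNonUniformity = sum(pg^2) / nr,
    GrayLevelNonUniformityNormalized = sum(pg^2) / nr^2,
    GrayLevelVariance = sum((iv - mu_g)^2 * p),
    HighGrayLevelRunEmphasis = sum(iv^2 * p),
    LongRunEmphasis = sum(rv^2 * p),
    LongRunHighGrayLevelEmphasis = sum(iv^2 * rv^2 * p),
    LongRunLowGrayLevelEmphasis = sum(rv^2 / iv^2 * p),
    LowGrayLevelRunEmphasis = sum(p / iv^2),
    RunEntropy = -sum(ppos * log2(ppos)),
    RunLengthNonUniformity = sum(pr^2) / nr,
    RunLengthNonUniformityNormalized = sum(pr^2) / nr^2,
    RunPercentage = nr / np,
    RunVariance = sum((rv - mu_r)^2 * p),
    ShortRunEmphasis = sum(p / rv^2),
    ShortRunHighGrayLevelEmphasis = sum(iv^2 / rv^2 * p),
    ShortRunLowGrayLevelEmphasis = sum(p / (iv^2 * rv^2)))
}

dr_glrlm_features <- function(Plist, np) {
  mats <- Filter(function(P) sum(P) > 0, Plist)
  if (!length(mats)) return(stats::setNames(numeric(16), .dr_glrlm_names))
  rowMeans(vapply(mats, dr_rlm_one, numeric(16), np = np))
}

dr_glszm_features <- function(zones, np) {
  nz <- nrow(zones)
  if (nz == 0) return(stats::setNames(numeric(16), .dr_glszm_names))
  g <- zones[, 1]; s <- zones[, 2]
  w <- 1 / nz
  mu_g <- mean(g); mu_s <- mean(s)
  cg <- table(g); cs <- table(s)
  joint <- table(paste(g, s)) / nz
  c(GrayLevelNonUniformity = sum(cg^2) / nz,
    GrayLevelNonUniformityNormalized = sum(cg^2) / nz^2,
    GrayLevelVariance = mean((g - mu_g)^2),
    HighGrayLevelZoneEmphasis = mean(g^2),
    LargeAreaEmphasis = mean(s^2),
    LargeAreaHighGrayLevelEmphasis = mean(s^2 * g^2),
    LargeAreaLowGrayLevelEmphasis = mean(s^2 / g^2),
    LowGrayLevelZoneEmphasis = mean(1 / g^2),
    SizeZoneNonUniformity = sum(cs^2) / nz,
    SizeZoneNonUniformityNormalized = sum(cs^2) / nz^2,
    SmallAreaEmphasis = mean(1 / s^2),
    SmallAreaHighGrayLevelEmphasis = mean(g^2 / s^2),
    SmallAreaLowGrayLevelEmphasis = mean(1 / (g^2 * s^2)),
    ZoneEntropy = -sum(joint * log2(joint)),
    ZonePercentage = nz / np,
    ZoneVariance = mean((s - mu_s)^2))
}

dr_ngtdm_features <- function(mat) {
  n_i <- mat[, 1]; s_i <- mat[, 2]
  nvp <- sum(n_i)
  if (nvp == 0) return(stats::setNames(numeric(5), .dr_ngtdm_names))
  p_i <- n_i / nvp
  lev <- seq_len(nrow(mat))
  occ <- p_i > 0
  ngp <- sum(occ)
  pi_o <- p_i[occ]; si_o <- s_i[occ]; li_o <- lev[occ]
  dif <- outer(li_o, li_o, `-`)
  coarse_den <- sum(pi_o * si_o)
  contrast <- if (ngp > 1)
    sum(outer(pi_o, pi_o) * dif^2) / (ngp * (ngp - 1)) * sum(si_o) / nvp else 0
  busy_den <- sum(abs(outer(li_o * pi_o, li_o * pi_o, `-`)))
  complexity <- sum(abs(dif) * (outer(pi_o * si_o, pi_o * si_o, `+`)) /
                      outer(pi_o, pi_o, `+`)) / nvp
  strength <- if (sum(si_o) > 0)
    sum(outer(pi_o, pi_o, `+`) * dif^2) / sum(si_o) else 0
  c(Busyness = if (ngp > 1 && busy_den > 0) coarse_den / busy_den else 0,
    Coarseness = if (coarse_den > 0) min(1 / coarse_den, 1e6) else 1e6,
    Complexity = complexity,
    Contrast = contrast,
    Strength = strength)
}

dr_gldm_features <- function(P, np) {
  nz <- sum(P)
  if (nz == 0) return(stats::setNames(numeric(14), .dr_gldm_names))
  p <- P / nz
  ng <- nrow(P)
  iv <- matrix(seq_len(ng), ng, ncol(P))
  jv <- matrix(seq_len(ncol(P)), ng, ncol(P), byrow = TRUE)
  pg <- rowSums(P); pd <- colSums(P)
  mu_j <- sum(jv * p)
  mu_g <- sum(iv * p)
  ppos <- p[p > 0]
  c(DependenceEntropy = -sum(ppos * log2(ppos)),
    DependenceNonUniformity = sum(pd^2) / nz,
    DependenceNonUniformityNormalized = sum(pd^2) / nz^2,
    DependenceVariance = sum((jv - mu_j)^2 * p),
    GrayLevelNonUniformity = sum(pg^2) / nz,
    GrayLevelVariance = sum((iv - mu_g)^2 * p),
    HighGrayLevelEmphasis = sum(iv^2 * p),
    LargeDependenceEmphasis = sum(jv^2 * p),
    LargeDependenceHighGrayLevelEmphasis = sum(iv^2 * jv^2 * p),
    LargeDependenceLowGrayLevelEmphasis = sum(jv^2 / iv^2 * p),
    LowGrayLevelEmphasis = sum(p / iv^2),
    SmallDependenceEmphasis = sum(p / jv^2),
    SmallDependenceHighGrayLevelEmphasis = sum(iv^2 / jv^2 * p),
    SmallDependenceLowGrayLevelEmphasis = sum(p / (iv^2 * jv^2)))
}
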