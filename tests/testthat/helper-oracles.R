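# Brute-force enumeration oracles for the texture matrices, written
# independently of the package's C++ accumulation path, plus small fixture
# builders shared across test files.

or_dirs <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
                 c(1, 1, 0), c(1, -1, 0), c(1, 0, 1), c(1, 0, -1),
                 c(0, 1, 1), c(0, 1, -1),
                 c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1))

or_all_neighbors <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
or_all_neighbors <- or_all_neighbors[rowSums(abs(or_all_neighbors)) > 0, ]

or_inside <- function(p, dm) all(p >= 1) && all(p <= dm)

# symmetric co-occurrence matrices by exhaustive voxel-pair enumeration
or_glcm <- function(g, ng) {
  dm <- dim(g)
  w <- which(g > 0, arr.ind = TRUE)
  lapply(seq_len(nrow(or_dirs)), function(d) {
    P <- matrix(0L, ng, ng)
    for (r in seq_len(nrow(w))) {
      p <- w[r, ]; q <- p + or_dirs[d, ]
      if (!or_inside(q, dm)) next
      gj <- g[q[1], q[2], q[3]]
      if (gj == 0) next
      gi <- g[p[1], p[2], p[3]]
      P[gi, gj] <- P[gi, gj] + 1L
      P[gj, gi] <- P[gj, gi] + 1L
    }
    P
  })
}

# run-length matrices via line extraction + rle
or_glrlm <- function(g, ng) {
  dm <- dim(g)
  lmax <- sum(dm)
  lapply(seq_len(nrow(or_dirs)), function(d) {
    dir <- or_dirs[d, ]
    P <- matrix(0L, ng, lmax)
    for (z in seq_len(dm[3])) for (y in seq_len(dm[2])) for (x in seq_len(dm[1])) {
      p <- c(x, y, z)
      if (or_inside(p - dir, dm)) next  # not a line start
      seqv <- integer(0)
      q <- p
      while (or_inside(q, dm)) {
        seqv <- c(seqv, g[q[1], q[2], q[3]])
        q <- q + dir
      }
      r <- rle(seqv)
      for (k in seq_along(r$values)) {
        if (r$values[k] > 0)
          P[r$values[k], r$lengths[k]] <- P[r$values[k], r$lengths[k]] + 1L
      }
    }
    P
  })
}

# connected zones of equal gray level (26-connectivity), breadth-first in R
or_glszm <- function(g) {
  dm <- dim(g)
  seen <- array(FALSE, dm)
  zones <- NULL
  idx <- which(g > 0, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    p0 <- idx[r, ]
    if (seen[p0[1], p0[2], p0[3]]) next
    gl <- g[p0[1], p0[2], p0[3]]
    frontier <- matrix(p0, ncol = 3)
    seen[p0[1], p0[2], p0[3]] <- TRUE
    size <- 0L
    while (nrow(frontier) > 0) {
      nxt <- NULL
      size <- size + nrow(frontier)
      for (f in seq_len(nrow(frontier))) {
        for (nb in seq_len(nrow(or_all_neighbors))) {
          q <- frontier[f, ] + or_all_neighbors[nb, ]
          if (!or_inside(q, dm)) next
          if (seen[q[1], q[2], q[3]]) next
          if (g[q[1], q[2], q[3]] != gl) next
          seen[q[1], q[2], q[3]] <- TRUE
          nxt <- rbind(nxt, q)
        }
      }
      frontier <- if (is.null(nxt)) matrix(numeric(0), ncol = 3) else nxt
    }
    zones <- rbind(zones, c(gl, size))
  }
  zones
}

or_ngtdm <- function(g, ng) {
  dm <- dim(g)
  out <- matrix(0, ng, 2)
  idx <- which(g > 0, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    p <- idx[r, ]
    nb <- numeric(0)
    for (k in seq_len(nrow(or_all_neighbors))) {
      q <- p + or_all_neighbors[k, ]
      if (!or_inside(q, dm)) next
      v <- g[q[1], q[2], q[3]]
      if (v > 0) nb <- c(nb, v)
    }
    if (!length(nb)) next
    gi <- g[p[1], p[2], p[3]]
    out[gi, 1] <- out[gi, 1] + 1
    out[gi, 2] <- out[gi, 2] + abs(gi - mean(nb))
  }
  out
}

or_gldm <- function(g, ng, alpha = 0) {
  dm <- dim(g)
  P <- matrix(0L, ng, 27)
  idx <- which(g > 0, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    p <- idx[r, ]
    gi <- g[p[1], p[2], p[3]]
    dep <- 0L
    for (k in seq_len(nrow(or_all_neighbors))) {
      q <- p + or_all_neighbors[k, ]
      if (!or_inside(q, dm)) next
      v <- g[q[1], q[2], q[3]]
      if (v > 0 && abs(v - gi) <= alpha) dep <- dep + 1L
    }
    P[gi, dep + 1L] <- P[gi, dep + 1L] + 1L
  }
  P
}

# ---- fixtures --------------------------------------------------------------

# wrap a per-voxel-constant time series into a perfusion_study
make_series_study <- function(series, grid = c(2, 2, 2)) {
  arr <- array(rep(series, each = prod(grid)), dim = c(grid, length(series)))
  structure(list(signal = arr, spacing = c(1, 1, 1), case_id = "toy", label = 0L),
            class = "perfusion_study")
}

# random small integer-leveled toy volume + full mask, for oracle tests
make_toy_gray <- function(dims, ng, seed) {
  set.seed(seed)
  array(sample.int(ng, prod(dims), replace = TRUE), dim = dims)
}

# study conditions compressed in time by a factor of 2 relative to the
# package defaults (t0 and beta halved, amplitude rescaled by 2^alpha so the
# concentration curve is an exact time compression, lesion delays halved),
# on a desk-scale grid; used by the multi-seed stochastic tests
reduced_cohort_config <- function(n_good, n_poor, seed, grid = c(12, 12, 6),
                                  n_timepoints = 12, null_effects = FALSE) {
  cohort_config(
    n_good = n_good, n_poor = n_poor, grid = grid,
    n_timepoints = n_timepoints,
    bolus = bolus_model(t0 = 6, alpha = 3.5, beta = 1,
                        amplitude = 0.18 * 2^3.5),
    lesion = lesion_effect(delay = 1, amplitude_factor = 0.7, texture_sd = 5),
    global_effect = if (null_effects) 0 else 0.15,
    lesion_effect_delta = if (null_effects)
      list(delay = 0, amplitude_factor = 0, texture_sd = 0) else
      list(delay = 1, amplitude_factor = -0.15, texture_sd = 4),
    seed = seed)
}

# small derived-image subset used by cohort-scale stochastic tests
reduced_filters <- c("original", "log-sigma-2-0-mm-3D")

# run screening + cascade on a cohort, returning the four feature groups
run_cascade_on_cohort <- function(cohort, filters, lasso_folds = 5) {
  labels <- cohort_labels(cohort)
  wb <- normalize_matrix(build_drf_matrix(cohort, "WB", filters = filters))
  ll <- normalize_matrix(build_drf_matrix(cohort, "LL", filters = filters))
  swb <- screen_significant(wb, labels)
  sll <- screen_significant(ll, labels)
  casc <- lasso_cascade(unclass(wb)[, swb$retained, drop = FALSE],
                        unclass(ll)[, sll$retained, drop = FALSE],
                        labels,
                        lasso_config(n_folds = lasso_folds,
                                     seed = attr(cohort, "config")$seed))
  list(labels = labels, cascade = casc, screen = list(WB = swb, LL = sll))
}
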