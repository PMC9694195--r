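test_that("gamma-variate curve matches its closed form and peaks at t0 + alpha*beta", {
  b <- bolus_model(t0 = 15, alpha = 2, beta = 2, amplitude = 1)
  expect_identical(gamma_variate_concentration(15, b), 0)
  expect_identical(gamma_variate_concentration(10, b), 0)
  expect_equal(gamma_variate_concentration(19, b), 16 * exp(-2), tolerance = 1e-12)
  tt <- seq(0, 40, by = 0.001)
  cc <- gamma_variate_concentration(tt, b)
  expect_equal(tt[which.max(cc)], 15 + 2 * 2, tolerance = 2e-3)
  # continuity at arrival
  expect_lt(gamma_variate_concentration(15 + 1e-9, b), 1e-6)
  expect_error(bolus_model(alpha = -1), class = "dynrad_parameter_error")
  expect_error(bolus_model(t0 = NaN), class = "dynrad_parameter_error")
})

test_that("simulated studies place the signal nadir in the bolus transit window", {
  cfg <- cohort_config(n_good = 1, n_poor = 0, grid = c(16, 16, 8),
                       n_timepoints = 50, noise_sd = 0, seed = 5)
  st <- simulate_study(cfg, 0, 101)
  mb <- apply(st$study$signal, 4, function(v) mean(v[st$brain$mask]))
  nadir <- which.min(mb) - 1
  expect_gte(nadir, 17)
  expect_lte(nadir, 22)
  expect_equal(sum(mb == min(mb)), 1)  # unique minimum without noise
})

test_that("a null lesion effect leaves lesion voxel curves identical to tissue", {
  cfg <- cohort_config(n_good = 1, n_poor = 0, grid = c(12, 12, 6),
                       n_timepoints = 20, noise_sd = 0,
                       lesion = lesion_effect(delay = 0, amplitude_factor = 1,
                                              texture_sd = 0),
                       baseline_texture_sd = 0, seed = 2)
  st <- simulate_study(cfg, 0, 7)
  sig <- matrix(st$study$signal, ncol = 20)
  les <- which(as.vector(st$lesion$mask))
  tis <- which(as.vector(st$brain$mask) & !as.vector(st$lesion$mask))
  expect_equal(sig[les[1], ], sig[tis[1], ], tolerance = 1e-12)
  expect_equal(max(abs(sweep(sig[les, ], 2, sig[tis[1], ]))), 0, tolerance = 1e-12)
})

test_that("cohort generation is seed-reproducible with correct label counts and containment", {
  cfg <- cohort_config(n_good = 42, n_poor = 36, grid = c(10, 10, 6),
                       n_timepoints = 5, seed = 9)
  coh1 <- generate_cohort(cfg)
  coh2 <- generate_cohort(cfg)
  expect_length(coh1, 78)
  expect_equal(sum(cohort_labels(coh1) == 0), 42)
  expect_equal(sum(cohort_labels(coh1) == 1), 36)
  expect_identical(coh1[[5]]$study$signal, coh2[[5]]$study$signal)
  expect_identical(cohort_labels(coh1), cohort_labels(coh2))
  for (e in coh1[1:5])
    expect_false(any(e$lesion$mask & !e$brain$mask))
  # labels are shuffled, not blocked
  expect_false(all(cohort_labels(coh1) == c(rep(0, 42), rep(1, 36))))
  one <- generate_cohort(cohort_config(n_good = 1, n_poor = 0, grid = c(10, 10, 6),
                                       n_timepoints = 5, seed = 1))
  expect_length(one, 1)
  expect_identical(cohort_labels(one), 0L)
  expect_error(generate_cohort(cohort_config(n_good = 0, n_poor = 0,
                                             grid = c(10, 10, 6),
                                             n_timepoints = 5)),
               class = "dynrad_empty_cohort_error")
})

test_that("cohort NIfTI round trip preserves signal, masks and labels", {
  dir <- withr::local_tempdir()
  cfg <- cohort_config(n_good = 1, n_poor = 1, grid = c(10, 10, 6),
                       n_timepoints = 4, seed = 3)
  coh <- generate_cohort(cfg)
  write_cohort(coh, dir)
  labs <- read.csv(file.path(dir, "labels.csv"))
  expect_setequal(labs$mrs_group, c("good", "poor"))
  id <- coh[[1]]$study$case_id
  back <- read_study(file.path(dir, sprintf("%s_pwi.nii.gz", id)),
                     file.path(dir, sprintf("%s_brain.nii.gz", id)),
                     file.path(dir, sprintf("%s_lesion.nii.gz", id)))
  expect_equal(dim(back$study$signal), dim(coh[[1]]$study$signal))
  expect_equal(back$study$signal, coh[[1]]$study$signal, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_identical(back$brain$mask, coh[[1]]$brain$mask)
  expect_identical(back$lesion$mask, coh[[1]]$lesion$mask)
})
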