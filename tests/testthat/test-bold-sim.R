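test_that("zero-noise, zero-amplitude runs equal baseline plus drift exactly", {
  s <- simulate_subject(1, seed = 50)
  np <- neuro_params(grid_shape = c(5L, 4L, 3L), noise_sd = 0,
                     regions = list())
  bold <- simulate_bold(s$seq, s$outcomes, np, seed = 1)
  fwd <- forward_model(s$seq, s$outcomes, np, bold$drift_coef)
  expect_lt(max(abs(matrix(bold$data, prod(np$grid_shape)) - fwd)), 1e-8)
  # every voxel carries the same baseline + drift series
  expect_equal(bold$data[1, 1, 1, ], bold$data[5, 4, 3, ])
})

test_that("noiseless planted amplitude is recovered by an independent regression", {
  s <- simulate_subject(1, seed = 51)
  reg <- list(mask = cbind(1L, 1L, 0L), amp_aware = 1, amp_unaware = 0,
              amp_correct = 0)
  np <- neuro_params(grid_shape = c(4L, 3L, 2L), noise_sd = 0,
                     regions = list(reg))
  bold <- simulate_bold(s$seq, s$outcomes, np, seed = 1)
  y <- bold$data[2, 2, 1, ]  # voxel (1,1,0) in 0-based coordinates

  # oracle regressor built here from first principles: binned aware train
  # convolved with the true HRF, amplitude-normalized to 1 percent area
  n_vol <- length(y)
  ons <- event_onsets_by_class(s$seq, s$outcomes)$aware_error
  train <- numeric(n_vol)
  train[floor(ons / 2.46 + 0.5) + 1] <- 1
  kern <- hrf_eval(gamma_hrf(), (0:7) * 2.46)
  x <- numeric(n_vol)
  for (i in seq_len(n_vol))
    for (k in seq_along(kern))
      if (i - k + 1 >= 1) x[i] <- x[i] + kern[k] * train[i - k + 1]
  x <- x * (100 * 19.68 / 100) / gamma_auc(gamma_hrf())
  tt <- seq_len(n_vol) / n_vol * 2 - 1
  fit <- stats::lm(y ~ x + tt + I(1.5 * tt^2 - 0.5))
  expect_equal(unname(coef(fit)["x"]), 1, tolerance = 1e-6)
})

test_that("noise smoothness propagates to the residual-based estimate", {
  s <- simulate_subject(1, seed = 52)
  np <- neuro_params(grid_shape = c(16L, 16L, 12L), noise_sd = 1,
                     smooth_fwhm_mm = 6, regions = list())
  bold <- simulate_bold(s$seq, s$outcomes, np, seed = 2)
  sl <- subject_level_analysis(s$seq, s$outcomes, bold,
                               conditions = "aware_error")
  expect_equal(sl$fwhm$geometric_mean, 6, tolerance = 0.15 * 6)
})

test_that("BOLD generation is reproducible and guards its mask invariants", {
  s <- simulate_subject(1, seed = 53)
  np <- neuro_params(grid_shape = c(5L, 4L, 3L), regions = list())
  a <- simulate_bold(s$seq, s$outcomes, np, seed = 9)
  b <- simulate_bold(s$seq, s$outcomes, np, seed = 9)
  expect_identical(a$data, b$data)

  expect_error(neuro_params(grid_shape = c(4L, 4L, 3L),
                            regions = list(list(mask = cbind(4L, 1L, 1L),
                                                amp_aware = 1,
                                                amp_unaware = 0,
                                                amp_correct = 0))),
               "outside grid")
  overlapping <- list(
    list(mask = cbind(1L, 1L, 1L), amp_aware = 1, amp_unaware = 0,
         amp_correct = 0),
    list(mask = cbind(1L, 1L, 1L), amp_aware = 1, amp_unaware = 0,
         amp_correct = 0))
  expect_error(neuro_params(grid_shape = c(4L, 4L, 3L),
                            regions = overlapping), "disjoint")
  expect_error(neuro_params(ar1_rho = 1), "ar1_rho")
})

test_that("cohort simulation writes a loadable, seed-stable directory", {
  dir1 <- tempfile("cohort1-"); dir2 <- tempfile("cohort2-")
  np <- neuro_params(grid_shape = c(6L, 6L, 4L),
                     regions = default_regions(c(6L, 6L, 4L)))
  for (d in c(dir1, dir2))
    simulate_cohort(2, d, neuro = np, seed = 7)

  expect_true(all(file.exists(file.path(dir1, c("sub-01", "sub-02")))))
  ev <- read_events_tsv(file.path(dir1, "sub-01", "events.tsv"))
  expect_identical(nrow(ev), 1050L)
  b <- read_bold_nifti(file.path(dir1, "sub-01", "bold.nii.gz"),
                       expect_grid = c(6, 6, 4))
  expect_equal(b$tr_s, 2.46)
  tm <- read_traits_tsv(file.path(dir1, "traits.tsv"))
  expect_identical(dim(tm), c(2L, 22L))

  # same seed twice: byte-identical ground truth
  expect_identical(readLines(file.path(dir1, "ground_truth.json")),
                   readLines(file.path(dir2, "ground_truth.json")))
})
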