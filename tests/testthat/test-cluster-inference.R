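test_that("paired t-map matches the closed-form one-sample t on differences", {
  gs <- c(2L, 2L, 1L)
  d <- c(1, 2, 3, 4, 5)
  aware <- array(0, c(gs, 5)); unaware <- array(0, c(gs, 5))
  aware[1, 1, 1, ] <- d
  tm <- paired_t_map(aware, unaware, voxel_mm = 3)
  expect_equal(tm$t[1, 1, 1], mean(d) / (sd(d) / sqrt(5)))
  expect_identical(tm$df, 4L)

  # identical conditions: t is zero, not masked
  expect_equal(tm$t[2, 2, 1], 0)

  # sign flip negates the map exactly
  tm2 <- paired_t_map(unaware, aware, voxel_mm = 3)
  expect_equal(tm2$t, -tm$t)

  # nonzero mean with zero variance is masked
  aware[2, 1, 1, ] <- 1
  tm3 <- paired_t_map(aware, unaware, voxel_mm = 3)
  expect_true(is.na(tm3$t[2, 1, 1]))
  expect_identical(tm3$n_masked, 1L)
})

test_that("connected-component labeling agrees with a flood-fill oracle", {
  set.seed(21)
  for (conn in c(6L, 18L, 26L)) {
    for (rep in 1:6) {
      mask <- array(runif(8 * 8 * 6) < 0.3, c(8, 8, 6))
      ours <- canon_components(eatfmri:::label_components(mask, conn))
      oracle <- canon_components(flood_fill_components(mask, conn))
      expect_identical(ours, oracle)
    }
  }
})

test_that("L-shaped blobs and diagonal pairs cluster per connectivity", {
  mask <- array(FALSE, c(5, 5, 3))
  mask[cbind(c(1, 2, 3, 3, 3), c(1, 1, 1, 2, 3), 1)] <- TRUE  # L shape
  comps <- eatfmri:::label_components(mask, 6L)
  expect_length(comps, 1)
  expect_length(comps[[1]], 5)

  diagm <- array(FALSE, c(4, 4, 2))
  diagm[1, 1, 1] <- TRUE; diagm[2, 2, 1] <- TRUE
  expect_length(eatfmri:::label_components(diagm, 6L), 2)   # faces only
  expect_length(eatfmri:::label_components(diagm, 26L), 1)  # corners join
})

test_that("cluster extraction applies the volume floor and reports geometry", {
  gs <- c(10L, 10L, 6L)
  tvals <- array(0, gs)
  tvals[5, 5, 3] <- 10                          # isolated voxel: 27 uL
  tvals[2:3, 2:4, 2:3] <- 8                     # 12 voxels: 324 uL
  tm <- list(t = tvals, df = 29L, n_subjects = 30L, voxel_mm = 3,
             n_masked = 0L)
  class(tm) <- "eat_tmap"

  tab <- extract_clusters(tm, t_threshold = 6, min_volume_uL = 250)
  expect_identical(nrow(tab), 1L)
  expect_equal(tab$volume_uL, 12 * 27)
  expect_equal(tab$peak_t, 8)
  # center of mass: uniform weights over a symmetric block
  origin <- -(gs - 1) / 2 * 3
  expect_equal(tab$x, origin[1] + mean(c(1, 2)) * 3)
  expect_equal(tab$y, origin[2] + mean(c(1, 2, 3)) * 3)
  expect_equal(tab$z, origin[3] + mean(c(1, 2)) * 3)
  expect_identical(tab$hemisphere, "L")

  # empty table below threshold; volumes invariant to sign flips
  expect_identical(nrow(extract_clusters(tm, t_threshold = 20,
                                         min_volume_uL = 250)), 0L)
  tm_neg <- tm; tm_neg$t <- -tm_neg$t
  tab_neg <- extract_clusters(tm_neg, 6, 250)
  expect_equal(tab_neg$volume_uL, tab$volume_uL)
  expect_equal(tab_neg$peak_t, -8)
})

test_that("null-cluster simulation handles degenerate settings", {
  # voxel p so strict that nothing survives
  d <- simulate_null_clusters(grid = c(8L, 8L, 6L), fwhm_mm = 0,
                              voxel_p = 1e-12, n_iter = 150, seed = 1)
  expect_identical(d$threshold_voxels, 1L)
  expect_true(all(d$max_sizes == 0L))

  expect_error(simulate_null_clusters(n_iter = 50), "n_iter")
  expect_error(simulate_null_clusters(n_iter = 200, alpha = 0.001,
                                      grid = c(8L, 8L, 6L)),
               "Monte Carlo resolution")
})

test_that("unsmoothed null maps match the binomial suprathreshold oracle", {
  # with fwhm 0 the 16^3 standardized field is iid: P(any voxel above the
  # two-tailed 0.001 threshold) = 1 - (1 - p)^N
  d <- simulate_null_clusters(grid = c(16L, 16L, 16L), fwhm_mm = 0,
                              voxel_p = 0.001, n_iter = 600, seed = 3,
                              alpha = 0.01)
  p_any <- mean(d$max_sizes >= 1)
  oracle <- 1 - (1 - 0.001)^(16^3)
  se <- sqrt(oracle * (1 - oracle) / 600)
  expect_lt(abs(p_any - oracle), 4 * se + 0.01)
})

test_that("the selected threshold is the smallest size meeting alpha", {
  d <- simulate_null_clusters(grid = c(12L, 12L, 8L), fwhm_mm = 6,
                              voxel_p = 0.01, n_iter = 400, seed = 5,
                              alpha = 0.05)
  s <- d$threshold_voxels
  expect_lte(mean(d$max_sizes >= s), 0.05)
  if (s > 1) expect_gt(mean(d$max_sizes >= s - 1), 0.05)
  expect_equal(d$threshold_uL, s * 27)
})
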