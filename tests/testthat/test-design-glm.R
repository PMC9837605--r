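test_that("a single event produces a shifted-identity FIR block", {
  sq <- toy_sequence(c("nogo", rep("go", 39)))  # event at t = 0
  # classify: make the lone No-Go an aware error (right press)
  resp <- toy_responses(c("right", rep("left", 39)))
  out <- classify_trials(sq, resp)
  suppressWarnings(
    des <- build_design_matrix(sq, out, n_volumes = 24, tr_s = 2.46,
                               fir_window_s = 8 * 2.46, drift_order = 1))
  cols <- des$condition_cols$aware_error
  M <- unname(des$X[, cols])
  expect_equal(M[1:8, ], diag(8))
  expect_true(all(M[9:24, ] == 0))
})

test_that("event classes with no events are dropped with a warning", {
  sq <- toy_sequence(c("nogo", rep("go", 39)))
  resp <- toy_responses(c("none", rep("left", 39)))  # only correct inhibition
  out <- classify_trials(sq, resp)
  w <- capture_warnings(
    des <- build_design_matrix(sq, out, 24, 2.46, drift_order = 1))
  expect_true(any(grepl("aware_error", w)))
  expect_true(any(grepl("unaware_error", w)))
  expect_null(des$condition_cols$aware_error)
  expect_false(is.null(des$condition_cols$correct_inhibition))
})

test_that("overlapping events sum their lagged indicators (convolution oracle)", {
  types <- rep("go", 40); types[c(5, 9)] <- "nogo"
  sq <- toy_sequence(types)
  resp <- toy_responses(ifelse(seq_along(types) %in% c(5, 9), "none", "left"))
  out <- classify_trials(sq, resp)
  suppressWarnings(
    des <- build_design_matrix(sq, out, 24, 2.46, drift_order = 1))
  cols <- des$condition_cols$correct_inhibition
  # oracle: direct convolution of the binned event train with lag sticks
  train <- numeric(24)
  vols <- floor(sq$trials$onset_s[c(5, 9)] / 2.46 + 0.5) + 1
  train[vols] <- 1
  for (lag in 0:7) {
    expected <- c(rep(0, lag), train)[1:24]
    expect_equal(unname(des$X[, cols[lag + 1]]), expected)
  }
})

test_that("rank-deficient designs fail loudly", {
  # Legendre columns beyond the number of volumes are linearly dependent
  sq <- toy_sequence(c("nogo", rep("go", 39)))
  resp <- toy_responses(c("right", rep("left", 39)))
  out <- classify_trials(sq, resp)
  expect_error(
    suppressWarnings(build_design_matrix(sq, out, n_volumes = 24,
                                         tr_s = 2.46, drift_order = 30)),
    "rank deficient")
})

test_that("noiseless forward-simulated data is recovered to solver precision", {
  s <- simulate_subject(1, seed = 14)
  np <- neuro_params(grid_shape = c(6L, 6L, 4L), noise_sd = 0,
                     regions = list(list(
                       mask = cbind(2:3, 2L, 1L),
                       amp_aware = 1, amp_unaware = 0.4, amp_correct = 0.2)))
  bold <- simulate_bold(s$seq, s$outcomes, np, seed = 1)
  des <- build_design_matrix(s$seq, s$outcomes, dim(bold$data)[4], 2.46)
  fit <- fit_glm(bold, des)

  # FIR estimates must equal amp * scale * hrf samples exactly
  kern <- hrf_eval(gamma_hrf(), (0:7) * 2.46)
  scale <- (100 * 19.68 / 100) / gamma_auc(gamma_hrf())
  li <- region_linear_idx(np$regions[[1]], np$grid_shape)
  for (cl in c("aware_error", "unaware_error", "correct_inhibition")) {
    amp <- c(aware_error = 1, unaware_error = 0.4,
             correct_inhibition = 0.2)[[cl]]
    irf <- irf_estimates(fit, cl)[, li[1]]
    expect_equal(unname(irf), amp * scale * kern, tolerance = 1e-6)
  }
  expect_equal(unname(fit$beta0[li[1]]), 100, tolerance = 1e-8)

  # residuals orthogonal to the design
  xr <- crossprod(des$X, fit$residuals[, li[1]])
  expect_lt(max(abs(xr)) / nrow(des$X), 1e-6)

  # percent-area maps reproduce the planted amplitudes
  maps <- activation_maps(fit)
  expect_equal(mean(maps$aware_error[li]), 1, tolerance = 0.01)
  expect_equal(mean(maps$unaware_error[li]), 0.4, tolerance = 0.01)
  expect_equal(mean(maps$correct_inhibition[li]), 0.2, tolerance = 0.01)
  off <- setdiff(seq_len(prod(np$grid_shape)), li)
  expect_lt(max(abs(maps$aware_error[off])), 1e-8)
})

test_that("an intercept-only model returns the time-series mean", {
  y <- matrix(rnorm(50, mean = 7), 1, 50)  # one voxel, 50 volumes
  des <- list(X = matrix(1, 50, 1), labels = "drift0",
              condition_cols = list(), intercept_col = 1L, n_lags = 0L,
              tr_s = 2.46, fir_window_s = 0)
  class(des) <- "eat_design"
  fit <- fit_glm(y, des)
  expect_equal(unname(fit$beta0[1]), mean(y), tolerance = 1e-12)
})

test_that("volume mismatches are rejected", {
  s <- simulate_subject(1, seed = 14)
  np <- neuro_params(grid_shape = c(4L, 4L, 3L), noise_sd = 0,
                     regions = list())
  bold <- simulate_bold(s$seq, s$outcomes, np, seed = 1)
  des <- build_design_matrix(s$seq, s$outcomes, dim(bold$data)[4], 2.46)
  bold$data <- bold$data[, , , 1:100]
  expect_error(fit_glm(bold, des), "mismatch")
})
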