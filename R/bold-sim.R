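#' Neuroimaging generating parameters for synthetic BOLD runs
#'
#' Describes the synthetic acquisition grid and generative signal/noise
#' model: a baseline of 100 arbitrary units (so percent signal is directly
#' interpretable), per-region event-related responses built by convolving
#' condition event trains with a ground-truth gamma-variate HRF, a low-order
#' polynomial drift, and AR(1) Gaussian noise spatially smoothed to a target
#' FWHM. Region amplitudes are expressed in percent-of-baseline-area units
#' over the response window `window_s`, so downstream percent-area estimates
#' are directly comparable to the planted values.
#'
#' @param grid_shape Integer length-3 voxel grid dimensions.
#' @param voxel_mm Isotropic voxel size (mm).
#' @param tr_s Repetition time (s).
#' @param hrf_true Ground-truth [gamma_hrf()] used for generation.
#' @param regions List of regions; each a list with `mask` (integer matrix of
#'   0-based voxel coordinates, one row per voxel) and amplitudes
#'   `amp_aware`, `amp_unaware`, `amp_correct` (percent-area units).
#' @param noise_sd Temporal SD of the Gaussian noise (signal units; baseline
#'   is 100).
#' @param ar1_rho AR(1) temporal autocorrelation of the noise.
#' @param drift_amp Amplitude of the low-order polynomial drift.
#' @param smooth_fwhm_mm Spatial smoothness applied to the noise field (mm).
#' @param window_s Response window over which amplitudes are defined (s).
#' @param baseline Baseline signal level.
#' @return Object of class `eat_neuro_params`.
#' @export
neuro_params <- function(grid_shape = c(24L, 24L, 18L), voxel_mm = 3,
                         tr_s = 2.46, hrf_true = gamma_hrf(),
                         regions = default_regions(grid_shape),
                         noise_sd = 1, ar1_rho = 0.3, drift_amp = 2,
                         smooth_fwhm_mm = 6, window_s = 8 * 2.46,
                         baseline = 100) {
  stopifnot(tr_s > 0, abs(ar1_rho) < 1, length(grid_shape) == 3L)
  seen <- integer(0)
  for (reg in regions) {
    m <- reg$mask
    if (any(m < 0) || any(t(m) >= grid_shape))
      stop("region mask outside grid")
    li <- mask_linear_idx(m, as.integer(grid_shape))
    if (any(li %in% seen)) stop("region masks must be disjoint")
    seen <- c(seen, li)
  }
  out <- list(grid_shape = as.integer(grid_shape), voxel_mm = voxel_mm,
              tr_s = tr_s, hrf_true = hrf_true, regions = regions,
              noise_sd = noise_sd, ar1_rho = ar1_rho, drift_amp = drift_amp,
              smooth_fwhm_mm = smooth_fwhm_mm, window_s = window_s,
              baseline = baseline)
  class(out) <- "eat_neuro_params"
  out
}

#' Default planted regions for synthetic cohorts
#'
#' Two cuboid regions centered in the grid: an "awareness" region with a
#' planted aware-minus-unaware percent-area difference of 0.5, and a control
#' region active for both error types with no awareness difference (it should
#' never appear in an aware-vs-unaware contrast).
#'
#' @param grid_shape Grid dimensions.
#' @return List of region specifications (see [neuro_params()]).
#' @export
default_regions <- function(grid_shape = c(24L, 24L, 18L)) {
  cuboid <- function(center, half) {
    rng <- lapply(1:3, function(a)
      seq.int(max(0L, center[a] - half[a]),
              min(grid_shape[a] - 1L, center[a] + half[a])))
    as.matrix(expand.grid(x = rng[[1]], y = rng[[2]], z = rng[[3]]))
  }
  c1 <- pmax(round(grid_shape * 0.3), 2L)
  c2 <- pmin(round(grid_shape * 0.7), grid_shape - 3L)
  m1 <- cuboid(c1, c(2L, 2L, 1L))
  m2 <- cuboid(c2, c(2L, 2L, 1L))
  # on very small grids the cuboids can meet: keep them disjoint
  k1 <- apply(m1, 1, paste, collapse = ",")
  m2 <- m2[!apply(m2, 1, paste, collapse = ",") %in% k1, , drop = FALSE]
  list(
    awareness = list(mask = m1,
                     amp_aware = 1.0, amp_unaware = 0.5, amp_correct = 0.5),
    control = list(mask = m2,
                   amp_aware = 0.8, amp_unaware = 0.8, amp_correct = 0.4))
}

mask_linear_idx <- function(mask, grid_shape) {
  1L + mask[, 1] + grid_shape[1] * (mask[, 2] + grid_shape[2] * mask[, 3])
}

# condition event train at TR resolution convolved with the HRF, scaled so a
# unit amplitude yields unit percent-area over window_s
condition_signal <- function(onsets, n_vol, params) {
  train <- numeric(n_vol)
  if (length(onsets)) {
    vols <- floor(onsets / params$tr_s + 0.5) + 1L
    vols <- vols[vols >= 1L & vols <= n_vol]
    for (v in vols) train[v] <- train[v] + 1
  }
  h <- params$hrf_true
  lags <- seq(0, params$window_s - params$tr_s, by = params$tr_s)
  kern <- hrf_eval(h, lags)
  scale <- (params$baseline * params$window_s / 100) / gamma_auc(h)
  sig <- numeric(n_vol)
  for (k in seq_along(kern)) {
    if (kern[k] == 0) next
    idx <- seq_len(n_vol - k + 1L)
    sig[idx + k - 1L] <- sig[idx + k - 1L] + kern[k] * train[idx]
  }
  sig * scale
}

#' Simulate a 4D BOLD run for one subject
#'
#' Voxel time series are `baseline + sum_condition amp * (event train
#' convolved with hrf_true) + drift + AR(1) noise`, with the noise field
#' spatially smoothed to `smooth_fwhm_mm`. The smoothing is applied to the
#' noise only, so planted region amplitudes are exact: signal is confined to
#' the region masks and a unit amplitude corresponds to exactly 1 percent of
#' the baseline area over the response window. The AR(1) innovation scale is
#' chosen so the marginal temporal SD equals `noise_sd`, and the smoothed
#' field is rescaled to preserve that marginal SD.
#'
#' @param seq An `eat_sequence`.
#' @param outcomes An `eat_outcomes` for the subject.
#' @param params An [neuro_params()].
#' @param seed Integer seed.
#' @return List of class `eat_bold`: `data` (4D array x,y,z,t), `tr_s`,
#'   `voxel_mm`, plus the generating `params` and ground-truth drift
#'   coefficients.
#' @export
simulate_bold <- function(seq, outcomes, params = neuro_params(), seed = 1L) {
  old <- get_rng_state(); on.exit(restore_rng_state(old), add = TRUE)
  set.seed(seed)

  geom <- run_geometry(seq$config, params$tr_s)
  n_vol <- geom$n_volumes
  gs <- params$grid_shape
  n_vox <- prod(gs)

  onsets <- event_onsets_by_class(seq, outcomes)
  sig_by_cond <- list(
    aware = condition_signal(onsets$aware_error, n_vol, params),
    unaware = condition_signal(onsets$unaware_error, n_vol, params),
    correct = condition_signal(onsets$correct_inhibition, n_vol, params))

  # voxels x time matrix
  dat <- matrix(params$baseline, n_vox, n_vol)

  tt <- seq_len(n_vol) / n_vol * 2 - 1
  drift_coef <- stats::runif(2, -1, 1) * params$drift_amp
  drift <- drift_coef[1] * tt + drift_coef[2] * (1.5 * tt^2 - 0.5)
  dat <- dat + matrix(drift, n_vox, n_vol, byrow = TRUE)

  for (reg in params$regions) {
    li <- mask_linear_idx(reg$mask, gs)
    reg_sig <- reg$amp_aware * sig_by_cond$aware +
      reg$amp_unaware * sig_by_cond$unaware +
      reg$amp_correct * sig_by_cond$correct
    dat[li, ] <- dat[li, ] + matrix(reg_sig, length(li), n_vol, byrow = TRUE)
  }

  if (params$noise_sd > 0) {
    innov_sd <- params$noise_sd * sqrt(1 - params$ar1_rho^2)
    eps <- array(stats::rnorm(n_vox * n_vol, sd = innov_sd), c(gs, n_vol))
    if (params$smooth_fwhm_mm > 0) {
      eps <- smooth_volume(eps, params$smooth_fwhm_mm, params$voxel_mm)
      # restore the marginal SD the smoothing shrank (interior scale)
      eps <- eps * (innov_sd / stats::sd(eps))
    }
    dim(eps) <- c(n_vox, n_vol)
    if (params$ar1_rho != 0)
      for (v in 2:n_vol)
        eps[, v] <- eps[, v] + params$ar1_rho * eps[, v - 1L]
    dat <- dat + eps
  }

  out <- list(data = array(dat, c(gs, n_vol)), tr_s = params$tr_s,
              voxel_mm = params$voxel_mm, n_volumes = n_vol,
              params = params, drift_coef = drift_coef)
  class(out) <- "eat_bold"
  out
}

#' @export
print.eat_bold <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("synthetic BOLD run: %d x %d x %d voxels (%g mm), %d volumes (TR %g s)\n",
              d[1], d[2], d[3], x$voxel_mm, d[4], x$tr_s))
  invisible(x)
}

#' Noise-free forward model of a simulated BOLD run
#'
#' Re-evaluates baseline + planted signal + drift from recorded ground truth;
#' used to verify that generation is exactly reproducible.
#'
#' @param seq,outcomes,params As in [simulate_bold()].
#' @param drift_coef Drift coefficients recorded by [simulate_bold()].
#' @return Voxels-by-time matrix.
#' @export
forward_model <- function(seq, outcomes, params, drift_coef) {
  geom <- run_geometry(seq$config, params$tr_s)
  n_vol <- geom$n_volumes
  gs <- params$grid_shape
  onsets <- event_onsets_by_class(seq, outcomes)
  dat <- matrix(params$baseline, prod(gs), n_vol)
  tt <- seq_len(n_vol) / n_vol * 2 - 1
  drift <- drift_coef[1] * tt + drift_coef[2] * (1.5 * tt^2 - 0.5)
  dat <- dat + matrix(drift, prod(gs), n_vol, byrow = TRUE)
  sig <- list(aware = condition_signal(onsets$aware_error, n_vol, params),
              unaware = condition_signal(onsets$unaware_error, n_vol, params),
              correct = condition_signal(onsets$correct_inhibition, n_vol,
                                         params))
  for (reg in params$regions) {
    li <- mask_linear_idx(reg$mask, gs)
    reg_sig <- reg$amp_aware * sig$aware + reg$amp_unaware * sig$unaware +
      reg$amp_correct * sig$correct
    dat[li, ] <- dat[li, ] + matrix(reg_sig, length(li), n_vol, byrow = TRUE)
  }
  dat
}
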