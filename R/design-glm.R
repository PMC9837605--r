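#' Build the subject-level deconvolution design matrix
#'
#' FIR (finite impulse response) deconvolution design: each No-Go outcome
#' class (aware errors, unaware errors, correct inhibitions) contributes `L`
#' lagged indicator columns (`L = fir_window_s / tr_s`), giving an
#' unconstrained impulse-response estimate at TR resolution. Go-omission
#' events and inter-block rest periods enter as regressors of no interest
#' (an HRF-convolved stick train and a rest boxcar respectively), and
#' Legendre polynomial drift columns up to `drift_order` complete the
#' baseline model. Events are binned to the nearest TR. A rank check is
#' performed after construction; all-zero event classes are dropped with a
#' warning.
#'
#' @param seq An `eat_sequence`.
#' @param outcomes An `eat_outcomes`.
#' @param n_volumes Number of acquired volumes.
#' @param tr_s Repetition time (s).
#' @param fir_window_s FIR window length (s); must be a multiple of `tr_s`.
#' @param drift_order Highest Legendre polynomial order (0 = intercept only).
#' @return Object of class `eat_design`: list with matrix `X` (volumes x
#'   columns), `labels`, `condition_cols` (named list of column indices per
#'   FIR class), `intercept_col`, `n_lags`, `tr_s`.
#' @export
build_design_matrix <- function(seq, outcomes, n_volumes, tr_s = 2.46,
                                fir_window_s = 8 * 2.46, drift_order = 3L) {
  L <- fir_window_s / tr_s
  if (abs(L - round(L)) > 1e-9)
    stop("fir_window_s must be a multiple of tr_s")
  L <- as.integer(round(L))
  onsets <- event_onsets_by_class(seq, outcomes)
  max_onset <- max(seq$trials$onset_s)
  if (max_onset > n_volumes * tr_s)
    stop("event onsets extend beyond the acquired run")

  fir_block <- function(ons) {
    M <- matrix(0, n_volumes, L)
    vols <- floor(ons / tr_s + 0.5) + 1L
    vols <- vols[vols >= 1L & vols <= n_volumes]
    for (v in vols) {
      lag_rows <- v + seq_len(L) - 1L
      keep <- lag_rows <= n_volumes
      M[cbind(lag_rows[keep], which(keep))] <-
        M[cbind(lag_rows[keep], which(keep))] + 1
    }
    M
  }

  classes <- c("aware_error", "unaware_error", "correct_inhibition")
  X_parts <- list(); labels <- character(0); cond_cols <- list()
  col <- 0L
  for (cl in classes) {
    ons <- onsets[[cl]]
    if (!length(ons)) {
      warning("no events of class '", cl, "': FIR columns dropped")
      next
    }
    M <- fir_block(ons)
    X_parts[[length(X_parts) + 1L]] <- M
    labels <- c(labels, paste0(cl, "#lag", seq_len(L) - 1L))
    cond_cols[[cl]] <- col + seq_len(L)
    col <- col + L
  }

  # omission regressor of no interest: stick train convolved with a
  # canonical gamma-variate shape
  if (length(onsets$omission)) {
    train <- numeric(n_volumes)
    vols <- floor(onsets$omission / tr_s + 0.5) + 1L
    vols <- vols[vols >= 1L & vols <= n_volumes]
    for (v in vols) train[v] <- train[v] + 1
    kern <- hrf_eval(gamma_hrf(), seq(0, fir_window_s - tr_s, by = tr_s))
    om <- numeric(n_volumes)
    for (k in seq_along(kern)) {
      if (kern[k] == 0) next
      idx <- seq_len(n_volumes - k + 1L)
      om[idx + k - 1L] <- om[idx + k - 1L] + kern[k] * train[idx]
    }
    om <- om / max(abs(om))
    X_parts[[length(X_parts) + 1L]] <- matrix(om, ncol = 1)
    labels <- c(labels, "omission")
    col <- col + 1L
  }

  # rest boxcar over inter-block gaps
  cfg <- seq$config
  if (cfg$n_blocks > 1L && cfg$interblock_rest_s > 0) {
    starts <- block_starts_s(cfg)
    block_len <- cfg$trials_per_block * trial_dur_s(cfg)
    times <- (seq_len(n_volumes) - 1L) * tr_s
    rest <- numeric(n_volumes)
    for (b in seq_len(cfg$n_blocks - 1L)) {
      t0 <- starts[b] + block_len
      rest[times >= t0 & times < t0 + cfg$interblock_rest_s] <- 1
    }
    X_parts[[length(X_parts) + 1L]] <- matrix(rest, ncol = 1)
    labels <- c(labels, "rest")
    col <- col + 1L
  }

  # Legendre drift columns on [-1, 1]
  tt <- seq_len(n_volumes) / n_volumes * 2 - 1
  P <- legendre_basis(tt, drift_order)
  X_parts[[length(X_parts) + 1L]] <- P
  labels <- c(labels, paste0("drift", 0:drift_order))
  intercept_col <- col + 1L

  X <- do.call(cbind, X_parts)
  colnames(X) <- labels
  qr_X <- qr(X)
  if (qr_X$rank < ncol(X)) {
    dropped <- labels[qr_X$pivot[(qr_X$rank + 1L):ncol(X)]]
    stop("design matrix rank deficient; collinear columns: ",
         paste(dropped, collapse = ", "))
  }
  out <- list(X = X, labels = labels, condition_cols = cond_cols,
              intercept_col = intercept_col, n_lags = L, tr_s = tr_s,
              fir_window_s = fir_window_s)
  class(out) <- "eat_design"
  out
}

legendre_basis <- function(tt, order) {
  P <- matrix(0, length(tt), order + 1L)
  P[, 1] <- 1
  if (order >= 1) P[, 2] <- tt
  if (order >= 2) for (k in 2:order)
    P[, k + 1L] <- ((2 * k - 1) * tt * P[, k] - (k - 1) * P[, k - 1L]) / k
  P
}

#' @export
print.eat_design <- function(x, ...) {
  cat("FIR deconvolution design:", nrow(x$X), "volumes x", ncol(x$X),
      "columns;", length(x$condition_cols), "event classes x", x$n_lags,
      "lags\n")
  invisible(x)
}

#' Ordinary least-squares GLM fit of a BOLD run
#'
#' Per-voxel OLS against the deconvolution design. Voxels with non-finite
#' data are masked out and reported. Returns the coefficient matrix, the
#' baseline level (intercept coefficient), and residuals for smoothness
#' estimation.
#'
#' @param bold An `eat_bold` (or a voxels-by-time matrix with attributes
#'   supplied via `...` arguments `grid_shape`).
#' @param design An `eat_design`.
#' @return Object of class `eat_glm`: list with `coef` (columns x voxels),
#'   `beta0` (per-voxel baseline), `residuals` (volumes x voxels),
#'   `mask` (logical per voxel), `design`, `grid_shape`, `voxel_mm`.
#' @export
fit_glm <- function(bold, design) {
  if (inherits(bold, "eat_bold")) {
    gs <- dim(bold$data)[1:3]
    Y <- t(matrix(bold$data, prod(gs), dim(bold$data)[4]))
    voxel_mm <- bold$voxel_mm
  } else {
    Y <- t(bold); gs <- c(nrow(bold), 1L, 1L); voxel_mm <- NA_real_
  }
  X <- design$X
  if (nrow(Y) != nrow(X))
    stop("volume count mismatch: data has ", nrow(Y), " volumes, design ",
         nrow(X))
  mask <- if (all(is.finite(Y))) rep(TRUE, ncol(Y))
  else colSums(!is.finite(Y)) == 0L
  if (!all(mask))
    warning(sum(!mask), " voxels with non-finite data masked out")
  qr_X <- qr(X)
  coef <- matrix(NA_real_, ncol(X), ncol(Y))
  coef[, mask] <- qr.coef(qr_X, Y[, mask, drop = FALSE])
  res <- matrix(NA_real_, nrow(Y), ncol(Y))
  res[, mask] <- qr.resid(qr_X, Y[, mask, drop = FALSE])
  out <- list(coef = coef, beta0 = coef[design$intercept_col, ],
              residuals = res, mask = mask, design = design,
              grid_shape = gs, voxel_mm = voxel_mm)
  class(out) <- "eat_glm"
  out
}

#' @export
print.eat_glm <- function(x, ...) {
  cat("subject-level GLM fit:", sum(x$mask), "voxels,",
      nrow(x$coef), "regressors\n")
  invisible(x)
}

#' Extract per-condition IRF estimates from a GLM fit
#'
#' @param glm_fit An `eat_glm`.
#' @param condition One of the FIR class names in the design.
#' @return Matrix lags x voxels of FIR coefficients.
#' @export
irf_estimates <- function(glm_fit, condition) {
  cols <- glm_fit$design$condition_cols[[condition]]
  if (is.null(cols)) stop("no FIR columns for condition '", condition, "'")
  glm_fit$coef[cols, , drop = FALSE]
}

#' Per-voxel percent-area activation maps for every condition
#'
#' For each modeled condition, fits a gamma variate to every voxel's IRF (by
#' the vectorized profiled-amplitude grid search) and converts the fitted
#' area under the curve into percent of the baseline area over the FIR
#' window.
#'
#' @param glm_fit An `eat_glm`.
#' @param conditions Conditions to map (default: all modeled FIR classes).
#' @return Named list (one element per condition) of 3D percent-area arrays;
#'   gamma parameters are attached as attributes `A`, `r`, `b` (vectors over
#'   voxels).
#' @export
activation_maps <- function(glm_fit,
                            conditions = names(glm_fit$design$condition_cols)) {
  gs <- glm_fit$grid_shape
  window_s <- glm_fit$design$fir_window_s
  out <- list()
  for (cl in conditions) {
    irf <- irf_estimates(glm_fit, cl)
    if (!all(glm_fit$mask)) irf[!is.finite(irf)] <- 0
    fit <- fit_gamma_grid(irf, glm_fit$design$tr_s)
    pct <- percent_signal(fit$auc, glm_fit$beta0, window_s)
    m <- array(pct, gs)
    attr(m, "A") <- fit$A; attr(m, "r") <- fit$r; attr(m, "b") <- fit$b
    out[[cl]] <- m
  }
  out
}
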