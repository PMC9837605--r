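#' Z-score standardization
#'
#' Centers and scales each column to mean 0, SD 1 (denominator `n - 1`).
#' All variables entering the lasso models -- predictors and outcomes -- are
#' standardized this way.
#'
#' @param x Numeric vector or matrix.
#' @return Standardized copy with attributes `center` and `scale`.
#' @export
standardize_z <- function(x) {
  if (is.vector(x)) {
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) stop("constant input cannot be standardized")
    out <- (x - mean(x)) / s
    attr(out, "center") <- mean(x); attr(out, "scale") <- s
    return(out)
  }
  x <- as.matrix(x)
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  bad <- !is.finite(scl) | scl == 0
  if (any(bad))
    stop("constant column(s): ",
         paste(colnames(x)[bad] %||% which(bad), collapse = ", "))
  out <- sweep(sweep(x, 2, ctr), 2, scl, "/")
  attr(out, "center") <- ctr; attr(out, "scale") <- scl
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

lambda_max <- function(X, y) max(abs(crossprod(X, y - mean(y)))) / nrow(X)

default_lambda_grid <- function(X, y, n = 100L, ratio = 1e-3) {
  lmax <- lambda_max(X, y)
  exp(seq(log(lmax), log(lmax * ratio), length.out = n))
}

#' Lasso fit at a fixed penalty
#'
#' Minimizes `(1/(2n)) * sum((y - b0 - X beta)^2) + lambda * sum(|beta|)`
#' (glmnet's Gaussian objective; fitting is delegated to glmnet at high
#' precision with standardization disabled -- inputs are expected to be
#' z-scored already). The Karush-Kuhn-Tucker optimality conditions of the
#' returned fit can be checked with [verify_kkt()].
#'
#' @param X Standardized predictor matrix.
#' @param y Standardized response.
#' @param lambda Penalty (>= 0).
#' @return Object of class `lasso_fit`: `coefficients` (named), `intercept`,
#'   `lambda`, `objective`.
#' @export
fit_lasso <- function(X, y, lambda) {
  X <- as.matrix(X)
  if (!all(is.finite(X)) || !all(is.finite(y)))
    stop("non-finite values in lasso inputs")
  stopifnot(lambda >= 0, nrow(X) == length(y))
  n <- nrow(X)
  lmax <- lambda_max(X, y)
  path <- sort(unique(c(exp(seq(log(max(lmax, lambda * 1.01, 1e-12)),
                                log(max(lambda, 1e-12)), length.out = 30L)),
                        lambda)), decreasing = TRUE)
  g <- glmnet::glmnet(X, y, family = "gaussian", lambda = path,
                      standardize = FALSE, intercept = TRUE, thresh = 1e-14,
                      maxit = 10^6)
  cf <- withCallingHandlers(
    as.numeric(glmnet::coef.glmnet(g, s = lambda, exact = TRUE, x = X,
                                   y = y, thresh = 1e-14, maxit = 10^6)),
    # near-duplicate points on the refit path trigger a harmless
    # interpolation note inside predict()
    warning = function(w) {
      if (grepl("collapsing to unique", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  beta <- cf[-1]; names(beta) <- colnames(X)
  obj <- sum((y - cf[1] - X %*% beta)^2) / (2 * n) + lambda * sum(abs(beta))
  out <- list(coefficients = beta, intercept = cf[1], lambda = lambda,
              objective = obj)
  class(out) <- "lasso_fit"
  out
}

#' @export
print.lasso_fit <- function(x, ...) {
  cat(sprintf("lasso fit: lambda = %.4g, %d of %d coefficients nonzero\n",
              x$lambda, sum(x$coefficients != 0), length(x$coefficients)))
  invisible(x)
}

#' Verify Karush-Kuhn-Tucker conditions of a lasso fit
#'
#' For the objective `(1/(2n))||y - b0 - X beta||^2 + lambda ||beta||_1`:
#' the gradient condition requires `|x_j'(y - yhat)| / n <= lambda` for
#' `beta_j = 0` and `x_j'(y - yhat) / n = lambda * sign(beta_j)` otherwise.
#'
#' @param fit A `lasso_fit`.
#' @param X,y The data it was fitted to.
#' @param tol Tolerance.
#' @return `TRUE` invisibly; stops with the worst violation otherwise.
#' @export
verify_kkt <- function(fit, X, y, tol = 1e-6) {
  X <- as.matrix(X)
  n <- nrow(X)
  r <- y - fit$intercept - X %*% fit$coefficients
  g <- as.numeric(crossprod(X, r)) / n
  beta <- fit$coefficients
  viol <- ifelse(beta == 0, pmax(abs(g) - fit$lambda, 0),
                 abs(g - fit$lambda * sign(beta)))
  if (max(viol) > tol)
    stop("KKT violation ", format(max(viol)), " exceeds tolerance ", tol)
  invisible(TRUE)
}

#' Select the lasso penalty by 10-fold cross-validation
#'
#' Log-spaced penalty grid from `lambda_max` down (100 points, ratio 1e-3 by
#' default); fold assignment is seeded and recorded; the returned penalty
#' minimizes mean held-out squared error (minimum-CV rule).
#'
#' @param X Standardized predictors.
#' @param y Standardized response.
#' @param n_folds Number of CV folds.
#' @param lambda_grid Optional penalty grid (decreasing).
#' @param seed Integer seed for fold assignment.
#' @return List with `lambda`, `cv_curve` (data.frame `lambda`, `cvm`,
#'   `cvsd`), `foldid`.
#' @export
cv_select_lambda <- function(X, y, n_folds = 10L, lambda_grid = NULL,
                             seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < n_folds) stop("fewer observations than folds")
  if (is.null(lambda_grid)) lambda_grid <- default_lambda_grid(X, y)
  old <- get_rng_state(); on.exit(restore_rng_state(old), add = TRUE)
  set.seed(seed)
  foldid <- sample(rep(seq_len(n_folds), length.out = n))
  cv <- glmnet::cv.glmnet(X, y, family = "gaussian", lambda = lambda_grid,
                          foldid = foldid, standardize = FALSE,
                          intercept = TRUE, thresh = 1e-10)
  list(lambda = cv$lambda.min,
       cv_curve = data.frame(lambda = cv$lambda, cvm = cv$cvm,
                             cvsd = cv$cvsd),
       foldid = foldid)
}

#' Bootstrap stability selection for the lasso
#'
#' Re-runs the full cross-validated lasso on bootstrap resamples (drawn with
#' replacement, size n) and reports, per predictor, the percentage of
#' resamples in which its coefficient is nonzero, alongside the coefficients
#' of the full-sample fit at its CV-optimal penalty. Rows with missing
#' values are excluded before fitting and the excluded count reported. By
#' default the penalty is re-selected by CV within every resample (full
#' procedural bootstrap); set `refit_lambda = FALSE` to freeze the
#' full-sample penalty instead.
#'
#' @param X Predictor matrix (will be standardized; rows with any NA
#'   dropped).
#' @param y Response vector (standardized internally).
#' @param n_boot Number of bootstrap resamples.
#' @param seed Integer seed.
#' @param n_folds CV folds.
#' @param refit_lambda Re-select lambda within each resample?
#' @return Object of class `lasso_stability`: data.frame with `predictor`,
#'   `coefficient`, `pct_nonzero`; attributes `lambda`, `n_used`,
#'   `n_excluded`, `n_boot`.
#' @export
bootstrap_stability <- function(X, y, n_boot = 500L, seed = 1L,
                                n_folds = 10L, refit_lambda = TRUE) {
  X <- as.matrix(X)
  ok <- stats::complete.cases(X, y)
  n_excluded <- sum(!ok)
  X <- X[ok, , drop = FALSE]; y <- y[ok]
  Xs <- standardize_z(X); ys <- standardize_z(y)

  sel <- cv_select_lambda(Xs, ys, n_folds = n_folds,
                          seed = derive_seed(seed, "cv-full"))
  full <- fit_lasso(Xs, ys, sel$lambda)

  old <- get_rng_state(); on.exit(restore_rng_state(old), add = TRUE)
  set.seed(derive_seed(seed, "bootstrap"))
  n <- nrow(Xs)
  nonzero <- matrix(FALSE, n_boot, ncol(Xs))
  for (b in seq_len(n_boot)) {
    i <- sample.int(n, n, replace = TRUE)
    Xb <- X[i, , drop = FALSE]; yb <- y[i]
    if (any(apply(Xb, 2, stats::sd) == 0) || stats::sd(yb) == 0) next
    Xbs <- standardize_z(Xb); ybs <- standardize_z(yb)
    lam <- if (refit_lambda)
      cv_select_lambda(Xbs, ybs, n_folds = n_folds,
                       seed = derive_seed(seed, "cv-boot", b))$lambda
    else sel$lambda
    fb <- fit_lasso(Xbs, ybs, lam)
    nonzero[b, ] <- fb$coefficients != 0
  }
  out <- data.frame(predictor = colnames(X) %||% paste0("x", seq_len(ncol(X))),
                    coefficient = unname(full$coefficients),
                    pct_nonzero = 100 * colMeans(nonzero),
                    stringsAsFactors = FALSE)
  attr(out, "lambda") <- sel$lambda
  attr(out, "n_used") <- n
  attr(out, "n_excluded") <- n_excluded
  attr(out, "n_boot") <- n_boot
  class(out) <- c("lasso_stability", class(out))
  out
}

#' @export
print.lasso_stability <- function(x, ...) {
  cat(sprintf("lasso stability selection: n = %d (%d excluded), %d bootstraps, lambda = %.4g\n",
              attr(x, "n_used"), attr(x, "n_excluded"), attr(x, "n_boot"),
              attr(x, "lambda")))
  df <- as.data.frame(x)
  df$coefficient <- ifelse(df$coefficient == 0, "-",
                           sprintf("%.3f", df$coefficient))
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}
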