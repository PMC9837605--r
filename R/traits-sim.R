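#' The 22 questionnaire subscale names used as lasso predictors
#'
#' Subscales of the BIS-11 (impulsiveness), AQ (autistic traits), BIS/BAS
#' (behavioral inhibition/activation), HADS (anxiety/depression) and CAARS
#' (adult ADHD) batteries.
#'
#' @return Character vector of 22 column names.
#' @export
trait_subscales <- function() c(
  "BIS-11—attentional", "BIS-11—motor", "BIS-11—nonplanning",
  "AQ—social skill", "AQ—attention switching", "AQ—attention to detail",
  "AQ—communication", "AQ—imagination",
  "BIS/BAS—BAS drive", "BIS/BAS—BAS fun", "BIS/BAS—BAS reward",
  "BIS/BIS—BIS score",
  "HADS—anxiety", "HADS—depression",
  "CAARS—attention", "CAARS—hyperactivity", "CAARS—impulsivity",
  "CAARS—self-concept", "CAARS—DSM attention", "CAARS—DSM hyperactivity",
  "CAARS—DSM ADHD", "CAARS—index")

# instrument membership used for the default block correlation structure
trait_instruments <- function() {
  s <- trait_subscales()
  sub("—.*$", "", sub("/BIS", "/BAS", s))
}

#' Trait-generating parameters
#'
#' Latent structure for the 22 questionnaire subscales: a block correlation
#' matrix (subscales of the same instrument correlate at `rho_within`, others
#' at `rho_between`), target correlations between selected predictors and a
#' supplied outcome (`true_effects`), and an MCAR missingness rate. The
#' default missingness rate matches a cohort in which 20 of 402 subjects lack
#' questionnaire data.
#'
#' @param rho_within,rho_between Within/between-instrument latent
#'   correlations.
#' @param correlation Optional explicit 22x22 correlation matrix (overrides
#'   the block structure); must be positive semidefinite.
#' @param true_effects Named numeric vector (names from [trait_subscales()]):
#'   target correlation of each named predictor with the outcome.
#' @param mcar_rate Probability that a subject's questionnaire row is missing
#'   completely at random.
#' @return Object of class `eat_trait_params`.
#' @export
trait_params <- function(rho_within = 0.4, rho_between = 0.1,
                         correlation = NULL, true_effects = numeric(0),
                         mcar_rate = 20 / 402) {
  p <- length(trait_subscales())
  if (is.null(correlation)) {
    inst <- trait_instruments()
    correlation <- outer(inst, inst, function(a, b)
      ifelse(a == b, rho_within, rho_between))
    diag(correlation) <- 1
  }
  ev <- eigen(correlation, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop("trait correlation matrix is not positive semidefinite")
  if (length(true_effects) &&
      !all(names(true_effects) %in% trait_subscales()))
    stop("true_effects names must be questionnaire subscales")
  stopifnot(mcar_rate >= 0, mcar_rate < 1)
  out <- list(correlation = correlation, true_effects = true_effects,
              mcar_rate = mcar_rate)
  class(out) <- "eat_trait_params"
  out
}

#' Simulate questionnaire trait matrices
#'
#' Draws subjects-by-subscales trait scores from a multivariate normal with
#' the configured latent correlation; predictors named in `true_effects` are
#' mixed with the standardized `neural_outcome` so that their population
#' correlation with the outcome equals the stated effect. An MCAR mask blanks
#' whole questionnaire rows at the configured rate.
#'
#' @param n_subjects Number of subjects.
#' @param params An [trait_params()].
#' @param neural_outcome Numeric vector of length `n_subjects` the planted
#'   effects couple to (any outcome: awareness rate, a cluster mean, ...).
#' @param seed Integer seed.
#' @return Matrix `n_subjects` x 22 with subscale column names and a logical
#'   attribute `missing` marking MCAR rows (rows are `NA` in the matrix).
#' @export
simulate_traits <- function(n_subjects, params = trait_params(),
                            neural_outcome = NULL, seed = 1L) {
  p <- length(trait_subscales())
  old <- get_rng_state(); on.exit(restore_rng_state(old), add = TRUE)
  set.seed(seed)
  L <- chol_psd(params$correlation)
  Z <- matrix(stats::rnorm(n_subjects * p), n_subjects, p) %*% L
  colnames(Z) <- trait_subscales()

  if (length(params$true_effects)) {
    if (is.null(neural_outcome) || length(neural_outcome) != n_subjects)
      stop("neural_outcome of length n_subjects required for planted effects")
    o <- as.vector(scale(neural_outcome))
    for (nm in names(params$true_effects)) {
      beta <- params$true_effects[[nm]]
      if (abs(beta) >= 1) stop("true effect magnitudes must be < 1")
      Z[, nm] <- sqrt(1 - beta^2) * Z[, nm] + beta * o
    }
  }

  miss <- stats::runif(n_subjects) < params$mcar_rate
  Z[miss, ] <- NA_real_
  attr(Z, "missing") <- miss
  Z
}

# upper-triangular Cholesky tolerant of a PSD (rank-deficient) input
chol_psd <- function(S) {
  out <- tryCatch(chol(S), error = function(e) NULL)
  if (!is.null(out)) return(out)
  e <- eigen(S, symmetric = TRUE)
  v <- pmax(e$values, 0)
  t(e$vectors %*% diag(sqrt(v)) %*% t(e$vectors))
}
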