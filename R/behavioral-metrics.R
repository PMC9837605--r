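#' Behavioral summary of a classified EAT subject
#'
#' Computes the standard performance indices: inhibition accuracy (% of No-Go
#' trials correctly withheld), total commission errors, error awareness (% of
#' commission errors signaled), mean reaction times for correct Go responses
#' and for aware/unaware error presses, and the post-No-Go reaction-time
#' adjustment for each No-Go outcome class. Awareness is reported as missing
#' when the subject made no commission errors. Go RT means exclude omissions,
#' anomalous right presses and awareness presses.
#'
#' @param outcomes An `eat_outcomes`.
#' @param responses The matching `eat_responses`.
#' @param seq The `eat_sequence` the subject performed (needed for the
#'   post-No-Go adjustment windows).
#' @return A one-row data.frame with columns `inhibition_pct`, `total_errors`,
#'   `awareness_pct`, `rt_go_ms`, `rt_aware_ms`, `rt_unaware_ms`,
#'   `postnogo_adjust_aware_ms`, `postnogo_adjust_unaware_ms`,
#'   `postnogo_adjust_correct_ms`.
#' @export
summarize_behavior <- function(outcomes, responses, seq = NULL) {
  ct <- attr(outcomes, "counts")
  n_nogo <- sum(outcomes$trial_type == "nogo")
  n_err <- ct[["aware_error"]] + ct[["unaware_error"]]
  inhibition <- 100 * ct[["correct_inhibition"]] / n_nogo
  awareness <- if (n_err > 0) 100 * ct[["aware_error"]] / n_err else NA_real_

  is_go <- outcomes$trial_type == "go"
  valid_go <- is_go & responses$button == "left" & !outcomes$anomalous
  rt_go <- mean(responses$rt_ms[valid_go])

  rt_cls <- function(cl) {
    i <- which(!is.na(outcomes$class) & outcomes$class == cl &
                 responses$button != "none")
    if (length(i)) mean(responses$rt_ms[i]) else NA_real_
  }

  adj <- if (!is.null(seq)) {
    vapply(c("aware_error", "unaware_error", "correct_inhibition"),
           function(cl) post_nogo_adjustment(seq, outcomes, responses,
                                             cl)$mean_ms,
           numeric(1))
  } else rep(NA_real_, 3)

  data.frame(inhibition_pct = inhibition,
             total_errors = n_err,
             awareness_pct = awareness,
             rt_go_ms = rt_go,
             rt_aware_ms = rt_cls("aware_error"),
             rt_unaware_ms = rt_cls("unaware_error"),
             postnogo_adjust_aware_ms = adj[1],
             postnogo_adjust_unaware_ms = adj[2],
             postnogo_adjust_correct_ms = adj[3])
}

#' Post-No-Go reaction-time adjustment
#'
#' For each No-Go event of a given outcome class, the adjustment is the RT of
#' the third Go trial after the No-Go trial minus the RT of the Go trial
#' immediately preceding it (the first two post-error trials are contaminated
#' by the awareness press and are not used). Events are dropped when the
#' pre-trial or third post-trial lacks a valid left-press RT (omission,
#' anomalous press), when another No-Go trial falls inside the three-trial
#' window, or when the window crosses a block boundary.
#'
#' @param seq An `eat_sequence`.
#' @param outcomes An `eat_outcomes`.
#' @param responses An `eat_responses`.
#' @param nogo_class One of `"aware_error"`, `"unaware_error"`,
#'   `"correct_inhibition"`.
#' @return List with `events` (data.frame of retained events with
#'   `trial_index`, `pre_rt_ms`, `post3_rt_ms`, `adjust_ms`) and `mean_ms`
#'   (subject mean, `NA` when no events are retained).
#' @export
post_nogo_adjustment <- function(seq, outcomes, responses, nogo_class) {
  stopifnot(nogo_class %in% c("aware_error", "unaware_error",
                              "correct_inhibition"))
  tr <- seq$trials
  n <- nrow(tr)
  idx <- which(!is.na(outcomes$class) & outcomes$class == nogo_class)

  valid_left <- responses$button == "left" & tr$trial_type == "go" &
    !outcomes$anomalous

  keep <- logical(length(idx))
  pre_rt <- post_rt <- rep(NA_real_, length(idx))
  for (k in seq_along(idx)) {
    i <- idx[k]
    if (i - 1L < 1L || i + 3L > n) next
    if (tr$block[i - 1L] != tr$block[i] || tr$block[i + 3L] != tr$block[i])
      next
    if (any(tr$trial_type[(i + 1L):(i + 3L)] == "nogo")) next
    if (!valid_left[i - 1L] || !valid_left[i + 3L]) next
    keep[k] <- TRUE
    pre_rt[k] <- responses$rt_ms[i - 1L]
    post_rt[k] <- responses$rt_ms[i + 3L]
  }
  ev <- data.frame(trial_index = tr$trial_index[idx[keep]],
                   pre_rt_ms = pre_rt[keep], post3_rt_ms = post_rt[keep],
                   adjust_ms = post_rt[keep] - pre_rt[keep])
  list(events = ev,
       mean_ms = if (nrow(ev)) mean(ev$adjust_ms) else NA_real_)
}

#' One-way repeated-measures ANOVA with Greenhouse-Geisser correction
#'
#' Classical within-subject F test for a subjects-by-conditions matrix, with
#' the Greenhouse-Geisser sphericity correction: epsilon is computed from the
#' double-centered condition covariance matrix and applied to both degrees of
#' freedom; the corrected p-value is reported alongside the uncorrected one.
#'
#' @param y Numeric matrix, subjects in rows, conditions in columns (complete
#'   cases required).
#' @return List with `F`, `df` (uncorrected, length 2), `gg_epsilon`,
#'   `df_gg`, `p_uncorrected`, `p_gg`.
#' @export
rm_anova_gg <- function(y) {
  y <- as.matrix(y)
  if (anyNA(y)) stop("complete subjects-by-conditions matrix required")
  n <- nrow(y); k <- ncol(y)
  if (k < 2L || n < 2L) stop("need at least 2 subjects and 2 conditions")

  grand <- mean(y)
  cond_means <- colMeans(y)
  subj_means <- rowMeans(y)
  ss_cond <- n * sum((cond_means - grand)^2)
  ss_subj <- k * sum((subj_means - grand)^2)
  ss_tot <- sum((y - grand)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  df1 <- k - 1L
  df2 <- (k - 1L) * (n - 1L)
  Fstat <- if (ss_cond == 0) 0 else (ss_cond / df1) / (ss_err / df2)

  # Greenhouse-Geisser epsilon from the double-centered covariance
  S <- stats::cov(y)
  C <- diag(k) - matrix(1 / k, k, k)
  Sc <- C %*% S %*% C
  ev <- sum(diag(Sc))
  eps <- if (ev == 0) 1 else ev^2 / (df1 * sum(Sc^2))
  eps <- min(1, max(1 / df1, eps))

  list(F = Fstat, df = c(df1, df2), gg_epsilon = eps,
       df_gg = eps * c(df1, df2),
       p_uncorrected = stats::pf(Fstat, df1, df2, lower.tail = FALSE),
       p_gg = stats::pf(Fstat, eps * df1, eps * df2, lower.tail = FALSE))
}

#' Spearman rank correlation
#'
#' Midrank-based Spearman correlation (Pearson correlation of ranks, ties as
#' midranks) with the asymptotic t approximation for the p-value, as used for
#' all brain-behavior association tests in this pipeline.
#'
#' @param x,y Paired numeric vectors (pairs with missing values dropped).
#' @return List with `rho`, `p`, `n`.
#' @export
spearman_rho <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("Spearman correlation undefined for constant input")
  rho <- stats::cor(rank(x), rank(y))
  p <- if (abs(rho) >= 1) 0
  else 2 * stats::pt(abs(rho) * sqrt((n - 2) / (1 - rho^2)), n - 2,
                     lower.tail = FALSE)
  list(rho = rho, p = p, n = n)
}

#' Holm step-down p-value adjustment
#'
#' @param p Vector of raw p-values in `[0, 1]`.
#' @return Adjusted p-values (same order as input).
#' @export
holm_adjust <- function(p) {
  if (any(!is.finite(p) | p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "holm")
}
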