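#' Behavioral generating parameters for a simulated EAT subject
#'
#' Defaults target the published cohort profile: inhibition accuracy near
#' 53.6% of No-Go trials, awareness signaling of 86.5% of commission errors,
#' Go reaction times near mean 518 ms / SD 81 ms, commission-error presses
#' slightly faster than Go presses (aware more so than unaware), and a planted
#' +19 ms slowing on the third Go trial after an unaware error.
#'
#' Reaction times are lognormal (positive, right-skewed), parameterized here
#' by their arithmetic mean and SD in milliseconds.
#'
#' @param p_inhibit Probability of a correct withhold on a No-Go trial.
#' @param p_aware Probability that a commission error is signaled with a right
#'   button press on the following Go trial.
#' @param go_rt_mean_ms,go_rt_sd_ms Mean and SD of the Go RT distribution.
#' @param aware_rt_shift_ms Additive RT shift for commission presses on errors
#'   that will be signaled.
#' @param unaware_rt_shift_ms Additive RT shift for unsignaled error presses.
#' @param p_omission Probability that a Go trial receives no response.
#' @param post_unaware_slow_ms Slowing planted on the third Go trial after an
#'   unaware error (the post-No-Go adjustment measure).
#' @param awareness_rt_shift_ms Additive shift for the awareness (right) press
#'   itself; awareness presses are typically fast.
#' @return An object of class `eat_behavior_params`.
#' @export
behavior_params <- function(p_inhibit = 0.536, p_aware = 0.865,
                            go_rt_mean_ms = 518, go_rt_sd_ms = 81,
                            aware_rt_shift_ms = -29,
                            unaware_rt_shift_ms = -10,
                            p_omission = 0.02,
                            post_unaware_slow_ms = 19,
                            awareness_rt_shift_ms = -150) {
  stopifnot(p_inhibit >= 0, p_inhibit <= 1, p_aware >= 0, p_aware <= 1,
            p_omission >= 0, p_omission <= 1,
            go_rt_mean_ms > 0, go_rt_sd_ms > 0)
  out <- as.list(environment())
  class(out) <- "eat_behavior_params"
  out
}

# lognormal (meanlog, sdlog) matching a target arithmetic mean/sd
lognormal_pars <- function(mean, sd) {
  s2 <- log(1 + (sd / mean)^2)
  c(meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

draw_rt <- function(n, params, shift_ms = 0, max_ms) {
  lp <- lognormal_pars(params$go_rt_mean_ms, params$go_rt_sd_ms)
  rt <- stats::rlnorm(n, lp["meanlog"], lp["sdlog"]) + shift_ms
  pmin(pmax(rt, 120), max_ms - 1)
}

#' Simulate a subject's responses to an EAT sequence
#'
#' Go trials receive a left button press with lognormal RT (or an omission
#' with probability `p_omission`). Each No-Go trial is withheld with
#' probability `p_inhibit`; otherwise the subject commits an error with a left
#' press. With probability `p_aware` the error is signaled: the response on
#' the next Go trial is replaced by a right (awareness) button press.
#' Unsignaled errors are followed by an ordinary left press on the next Go
#' trial. A planted `post_unaware_slow_ms` is added to the RT of the third
#' trial after each unsignaled error, when that trial is a Go trial with a
#' left press (the measurement window of the post-No-Go adjustment
#' statistic).
#'
#' @param seq An [generate_sequence()] result.
#' @param params A [behavior_params()] object.
#' @param seed Integer seed.
#' @param subject_id Identifier stored with the responses.
#' @return An object of class `eat_responses`: data.frame with one row per
#'   trial, columns `button` (`"none"`, `"left"`, `"right"`) and `rt_ms`
#'   (`NA` when no press).
#' @export
simulate_responses <- function(seq, params = behavior_params(), seed = 1L,
                               subject_id = "sub-01") {
  tr <- seq$trials
  n <- nrow(tr)
  max_ms <- seq$config$stim_ms + seq$config$isi_ms
  old <- get_rng_state(); on.exit(restore_rng_state(old), add = TRUE)
  set.seed(seed)

  button <- rep("none", n)
  rt <- rep(NA_real_, n)

  is_go <- tr$trial_type == "go"
  go_idx <- which(is_go)
  press <- stats::runif(length(go_idx)) >= params$p_omission
  button[go_idx[press]] <- "left"
  rt[go_idx[press]] <- draw_rt(sum(press), params, 0, max_ms)

  nogo_idx <- which(!is_go)
  committed <- stats::runif(length(nogo_idx)) >= params$p_inhibit
  err_idx <- nogo_idx[committed]
  signaled <- stats::runif(length(err_idx)) < params$p_aware
  button[err_idx] <- "left"
  rt[err_idx] <- draw_rt(length(err_idx), params,
                         ifelse(signaled, params$aware_rt_shift_ms,
                                params$unaware_rt_shift_ms), max_ms)

  # awareness press replaces the response on the next trial (a Go trial by
  # design, except when the error falls on the final trial of the run)
  sig_next <- err_idx[signaled] + 1L
  sig_next <- sig_next[sig_next <= n]
  button[sig_next] <- "right"
  rt[sig_next] <- draw_rt(length(sig_next), params,
                          params$awareness_rt_shift_ms, max_ms)

  # planted post-error slowing: third trial after each unsignaled error
  slow_idx <- err_idx[!signaled] + 3L
  slow_idx <- slow_idx[slow_idx <= n & button[pmin(slow_idx, n)] == "left" &
                         is_go[pmin(slow_idx, n)]]
  rt[slow_idx] <- pmin(rt[slow_idx] + params$post_unaware_slow_ms, max_ms - 1)

  out <- data.frame(trial_index = tr$trial_index, button = button,
                    rt_ms = rt, stringsAsFactors = FALSE)
  attr(out, "subject_id") <- subject_id
  attr(out, "params") <- params
  class(out) <- c("eat_responses", class(out))
  out
}

#' @export
print.eat_responses <- function(x, ...) {
  cat("EAT responses for", attr(x, "subject_id"), ":", nrow(x), "trials,",
      sum(x$button != "none"), "presses (",
      sum(x$button == "right"), "right )\n")
  invisible(x)
}
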