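#' Classify No-Go trials into aware errors, unaware errors and correct
#' inhibitions
#'
#' Implements the deterministic Error Awareness Task classification rule. A
#' No-Go trial with no press is a correct inhibition. A commission error
#' (press on a No-Go trial) is an *unaware* error only when the subject
#' pressed the left button on the No-Go trial and again on the following Go
#' trial; any deviation from that pattern (a right press on the No-Go trial,
#' a right press or no press on the following trial) is an *aware* error. Go
#' trials with no press are flagged as omissions; a right press on a Go trial
#' not preceded by a commission error is recorded as anomalous and excluded
#' from reaction-time summaries downstream.
#'
#' A commission error on the final trial of the run (no following trial) is
#' classified aware only if the error press itself was a right press,
#' otherwise unaware; this edge rule is configurable via `final_trial_aware`.
#'
#' @param seq An `eat_sequence`.
#' @param resp An `eat_responses` aligned to `seq`.
#' @param final_trial_aware If `TRUE`, a last-trial commission error with a
#'   left press is classified aware rather than unaware.
#' @return An object of class `eat_outcomes`: data.frame with one row per
#'   trial, columns `trial_index`, `trial_type`, `onset_s`, `class`
#'   (`"correct_inhibition"`, `"aware_error"`, `"unaware_error"` for No-Go
#'   trials, `NA` otherwise), `omission`, `anomalous`; summary counts in
#'   attribute `counts`.
#' @export
classify_trials <- function(seq, resp, final_trial_aware = FALSE) {
  tr <- seq$trials
  if (nrow(tr) != nrow(resp))
    stop("alignment error: sequence has ", nrow(tr), " trials but responses ",
         "have ", nrow(resp), " rows")
  n <- nrow(tr)
  is_nogo <- tr$trial_type == "nogo"
  btn <- resp$button

  cls <- rep(NA_character_, n)
  nogo_idx <- which(is_nogo)
  next_btn <- c(btn[-1L], NA_character_)[nogo_idx]
  this_btn <- btn[nogo_idx]

  cls_nogo <- ifelse(this_btn == "none", "correct_inhibition",
              ifelse(this_btn == "left" & !is.na(next_btn) &
                       next_btn == "left", "unaware_error", "aware_error"))
  # final-trial edge: no following trial exists
  last_nogo <- nogo_idx == n
  if (any(last_nogo) && !final_trial_aware) {
    i <- which(last_nogo)
    cls_nogo[i] <- ifelse(this_btn[i] == "none", "correct_inhibition",
                          ifelse(this_btn[i] == "left", "unaware_error",
                                 "aware_error"))
  }
  cls[nogo_idx] <- cls_nogo

  omission <- tr$trial_type == "go" & btn == "none"
  # right press on a Go trial is the awareness signal when the preceding
  # trial was a commission error; otherwise it is anomalous
  prev_error <- c(FALSE, (is_nogo & btn != "none")[-n])
  anomalous <- tr$trial_type == "go" & btn == "right" & !prev_error

  out <- data.frame(trial_index = tr$trial_index,
                    trial_type = tr$trial_type,
                    onset_s = tr$onset_s,
                    class = cls, omission = omission, anomalous = anomalous,
                    stringsAsFactors = FALSE)
  counts <- c(correct_inhibition = sum(cls == "correct_inhibition", na.rm = TRUE),
              aware_error = sum(cls == "aware_error", na.rm = TRUE),
              unaware_error = sum(cls == "unaware_error", na.rm = TRUE),
              omission = sum(omission), anomalous = sum(anomalous))
  attr(out, "counts") <- counts
  attr(out, "subject_id") <- attr(resp, "subject_id")
  class(out) <- c("eat_outcomes", class(out))
  out
}

#' @export
print.eat_outcomes <- function(x, ...) {
  ct <- attr(x, "counts")
  cat("EAT outcomes:", ct["correct_inhibition"], "correct inhibitions,",
      ct["aware_error"], "aware /", ct["unaware_error"], "unaware errors,",
      ct["omission"], "Go omissions\n")
  invisible(x)
}

#' Event onsets grouped by outcome class
#'
#' Partitions No-Go onsets by classified outcome and lists Go-omission onsets
#' separately, for design-matrix construction.
#'
#' @param seq An `eat_sequence` (unused beyond alignment checks; onsets are
#'   carried in `outcomes`).
#' @param outcomes An `eat_outcomes`.
#' @return Named list of onset vectors (seconds): `aware_error`,
#'   `unaware_error`, `correct_inhibition`, `omission`.
#' @export
event_onsets_by_class <- function(seq, outcomes) {
  stopifnot(nrow(seq$trials) == nrow(outcomes))
  nogo <- outcomes[outcomes$trial_type == "nogo", ]
  list(aware_error = nogo$onset_s[nogo$class == "aware_error"],
       unaware_error = nogo$onset_s[nogo$class == "unaware_error"],
       correct_inhibition = nogo$onset_s[nogo$class == "correct_inhibition"],
       omission = outcomes$onset_s[outcomes$omission])
}
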