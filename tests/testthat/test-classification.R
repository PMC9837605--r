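test_that("classification matches the exhaustive 9-case truth table", {
  # oracle: unaware iff (left on No-Go, left on next); none -> correct;
  # any other commission pattern -> aware
  oracle <- function(nogo_btn, next_btn) {
    if (nogo_btn == "none") return("correct_inhibition")
    if (nogo_btn == "left" && next_btn == "left") return("unaware_error")
    "aware_error"
  }
  sq <- toy_sequence(c("go", "nogo", "go", "go"))
  for (nb in c("none", "left", "right"))
    for (xb in c("none", "left", "right")) {
      resp <- toy_responses(c("left", nb, xb, "left"))
      out <- classify_trials(sq, resp)
      expect_identical(out$class[2], oracle(nb, xb),
                       label = paste("nogo:", nb, "next:", xb))
    }
})

test_that("final-trial commission errors follow the documented edge rule", {
  sq <- toy_sequence(c("go", "go", "nogo"))
  left <- classify_trials(sq, toy_responses(c("left", "left", "left")))
  expect_identical(left$class[3], "unaware_error")
  right <- classify_trials(sq, toy_responses(c("left", "left", "right")))
  expect_identical(right$class[3], "aware_error")
  flip <- classify_trials(sq, toy_responses(c("left", "left", "left")),
                          final_trial_aware = TRUE)
  expect_identical(flip$class[3], "aware_error")
})

test_that("omission and anomalous flags are set correctly", {
  sq <- toy_sequence(c("go", "go", "nogo", "go", "go"))
  resp <- toy_responses(c("none", "left", "left", "right", "right"))
  out <- classify_trials(sq, resp)
  expect_true(out$omission[1])
  expect_false(any(out$omission[-1]))
  expect_false(out$anomalous[4])  # awareness press after commission error
  expect_true(out$anomalous[5])   # right press with no preceding error
  expect_identical(out$class[3], "aware_error")
})

test_that("boundary generating parameters produce the expected patterns", {
  sq <- generate_sequence(eat_task_config(rng_seed = 2))
  r1 <- simulate_responses(sq, behavior_params(p_inhibit = 1), seed = 1)
  o1 <- classify_trials(sq, r1)
  ct <- attr(o1, "counts")
  expect_identical(unname(ct["aware_error"] + ct["unaware_error"]), 0L)
  expect_identical(sum(r1$button == "right"), 0L)

  r2 <- simulate_responses(sq, behavior_params(p_inhibit = 0, p_aware = 0,
                                               p_omission = 0), seed = 1)
  nogo_idx <- which(sq$trials$trial_type == "nogo")
  nxt <- nogo_idx + 1L
  expect_true(all(r2$button[nxt[nxt <= nrow(r2)]] == "left"))
})

test_that("outcome classes partition the No-Go trials for simulated subjects", {
  for (seed in c(3, 17)) {
    s <- simulate_subject(1, seed = seed)
    ct <- attr(s$outcomes, "counts")
    expect_identical(unname(ct[["correct_inhibition"]] + ct[["aware_error"]] +
                              ct[["unaware_error"]]),
                     sum(s$seq$trials$trial_type == "nogo"))
    ons <- event_onsets_by_class(s$seq, s$outcomes)
    nogo_onsets <- s$seq$trials$onset_s[s$seq$trials$trial_type == "nogo"]
    expect_setequal(c(ons$aware_error, ons$unaware_error,
                      ons$correct_inhibition), nogo_onsets)
  }
})

test_that("toy onsets land in the right class lists", {
  sq <- toy_sequence(c("go", "nogo", "go", "go", "nogo", "go", "go"))
  resp <- toy_responses(c("left", "left", "right", "left", "left", "left",
                          "none"))
  out <- classify_trials(sq, resp)
  ons <- event_onsets_by_class(sq, out)
  expect_equal(ons$aware_error, sq$trials$onset_s[2])     # signaled error
  expect_equal(ons$unaware_error, sq$trials$onset_s[5])   # left-left pattern
  expect_length(ons$correct_inhibition, 0)
  expect_equal(ons$omission, sq$trials$onset_s[7])
})

test_that("misaligned responses raise an alignment error", {
  sq <- toy_sequence(c("go", "nogo", "go"))
  expect_error(classify_trials(sq, toy_responses(c("left", "left"))),
               "alignment")
})

test_that("cohort awareness rate tracks the generating probability", {
  hits <- 0; total <- 0
  for (i in 1:40) {
    s <- simulate_subject(i, seed = 60)
    ct <- attr(s$outcomes, "counts")
    hits <- hits + ct[["aware_error"]]
    total <- total + ct[["aware_error"]] + ct[["unaware_error"]]
  }
  # classification can only upgrade unsignaled errors followed by an
  # omission to aware, so allow the small upward shift
  se <- sqrt(0.865 * 0.135 / total)
  expect_lt(abs(hits / total - 0.865), 3 * se + 0.005)
})
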