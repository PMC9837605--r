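test_that("behavioral summary arithmetic matches hand counts on a toy subject", {
  # 4 No-Go: 2 withheld, 2 errors of which 1 signaled
  sq <- toy_sequence(c("go", "nogo", "go", "go", "nogo", "go", "go",
                       "nogo", "go", "go", "nogo", "go"))
  resp <- toy_responses(c("left", "none", "left", "left",
                          "left", "right", "left",
                          "left", "left", "left",
                          "none", "left"))
  out <- classify_trials(sq, resp)
  s <- summarize_behavior(out, resp, sq)
  expect_equal(s$inhibition_pct, 50)
  expect_equal(s$total_errors, 2)
  expect_equal(s$awareness_pct, 50)
})

test_that("awareness is missing for an error-free subject", {
  sq <- toy_sequence(c("go", "nogo", "go"))
  resp <- toy_responses(c("left", "none", "left"))
  out <- classify_trials(sq, resp)
  s <- summarize_behavior(out, resp, sq)
  expect_equal(s$inhibition_pct, 100)
  expect_true(is.na(s$awareness_pct))
})

test_that("post-No-Go adjustment equals third-post minus pre RT", {
  sq <- toy_sequence(c("go", "nogo", "go", "go", "go", "go"))
  resp <- toy_responses(c("left", "left", "left", "left", "left", "left"),
                        rts = c(480, 400, 430, 440, 520, 510))
  out <- classify_trials(sq, resp)
  adj <- post_nogo_adjustment(sq, out, resp, "unaware_error")
  expect_equal(adj$events$adjust_ms, 520 - 480)
  expect_equal(adj$mean_ms, 40)

  # constant RTs give exactly zero for every class
  resp0 <- toy_responses(c("left", "none", "left", "left", "left", "left"),
                         rts = rep(500, 6))
  out0 <- classify_trials(sq, resp0)
  expect_equal(post_nogo_adjustment(sq, out0, resp0,
                                    "correct_inhibition")$mean_ms, 0)
})

test_that("adjustment events with broken windows are dropped, not zeroed", {
  # omission on the third post trial
  sq <- toy_sequence(c("go", "nogo", "go", "go", "go", "go"))
  resp <- toy_responses(c("left", "left", "left", "left", "none", "left"))
  out <- classify_trials(sq, resp)
  adj <- post_nogo_adjustment(sq, out, resp, "unaware_error")
  expect_identical(nrow(adj$events), 0L)
  expect_true(is.na(adj$mean_ms))

  # another No-Go inside the 3-trial window
  sq2 <- toy_sequence(c("go", "nogo", "go", "nogo", "go", "go", "go", "go"))
  resp2 <- toy_responses(rep("left", 8))
  out2 <- classify_trials(sq2, resp2)
  adj2 <- post_nogo_adjustment(sq2, out2, resp2, "unaware_error")
  expect_identical(adj2$events$trial_index, 3L)  # only the second event kept

  # window crossing a block boundary
  sq3 <- toy_sequence(c("go", "nogo", "go", "go", "go", "go", "go", "go"),
                      trials_per_block = 4)
  resp3 <- toy_responses(rep("left", 8))
  out3 <- classify_trials(sq3, resp3)
  adj3 <- post_nogo_adjustment(sq3, out3, resp3, "unaware_error")
  expect_identical(nrow(adj3$events), 0L)
})

test_that("repeated-measures ANOVA matches an independent implementation", {
  skip_if_not_installed("car")
  set.seed(10)
  y <- matrix(rnorm(5 * 3, mean = rep(c(0, 0.5, 1), each = 5)), 5, 3)
  ours <- rm_anova_gg(y)

  idata <- data.frame(cond = factor(1:3))
  fit <- stats::lm(y ~ 1)
  av <- car::Anova(fit, idata = idata, idesign = ~cond, type = 3)
  s <- summary(av, multivariate = FALSE)
  expect_equal(ours$F, unname(s$univariate.tests["cond", "F value"]),
               tolerance = 1e-8)
  expect_equal(ours$gg_epsilon, unname(s$pval.adjustments["cond", "GG eps"]),
               tolerance = 1e-8)
  expect_equal(ours$p_gg, unname(s$pval.adjustments["cond", "Pr(>F[GG])"]),
               tolerance = 1e-8)
})

test_that("repeated-measures ANOVA limiting cases hold", {
  y_id <- matrix(rep(c(1, 5, 3, 2), 3), 4, 3)     # identical conditions
  expect_equal(rm_anova_gg(y_id)$F, 0)

  set.seed(2)
  y2 <- matrix(rnorm(12), 6, 2)                   # k = 2: F = t^2
  tt <- stats::t.test(y2[, 1], y2[, 2], paired = TRUE)
  expect_equal(rm_anova_gg(y2)$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(rm_anova_gg(y2)$gg_epsilon, 1)     # epsilon is 1 for k = 2

  set.seed(3)
  eps <- rm_anova_gg(matrix(rnorm(30), 10, 3))$gg_epsilon
  expect_gte(eps, 0.5)  # lower bound 1/(k-1)
  expect_lte(eps, 1)

  expect_error(rm_anova_gg(matrix(1:3, 3, 1)), "at least 2")
})

test_that("Spearman correlation uses midranks and matches cor.test", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(spearman_rho(x, x)$rho, 1)
  expect_equal(spearman_rho(x, -x)$rho, -1)

  xt <- c(1, 2, 2, 3, 5, 5, 5, 9)   # ties handled by midranks
  yt <- c(2, 1, 4, 4, 6, 9, 7, 8)
  ours <- spearman_rho(xt, yt)
  ref <- suppressWarnings(stats::cor.test(xt, yt, method = "spearman"))
  expect_equal(ours$rho, unname(ref$estimate), tolerance = 1e-12)

  expect_error(spearman_rho(rep(1, 5), 1:5), "constant")
})

test_that("Holm adjustment matches the hand-computed step-down procedure", {
  expect_equal(holm_adjust(0.03), 0.03)
  expect_equal(holm_adjust(c(0.01, 0.04)), c(0.02, 0.04))
  set.seed(4)
  p <- runif(12)
  adj <- holm_adjust(p)
  expect_true(all(adj >= p))
  expect_true(all(adj <= 1))
  expect_true(all(diff(adj[order(p)]) >= -1e-15))  # monotone in raw order
  expect_error(holm_adjust(c(0.2, 1.4)), "\\[0, 1\\]")
})

test_that("planted post-unaware slowing is recovered on a small cohort", {
  vals <- vapply(1:60, function(i) {
    s <- simulate_subject(i, seed = 77)
    post_nogo_adjustment(s$seq, s$outcomes, s$responses,
                         "unaware_error")$mean_ms
  }, numeric(1))
  se <- stats::sd(vals, na.rm = TRUE) / sqrt(sum(!is.na(vals)))
  expect_lt(abs(mean(vals, na.rm = TRUE) - 19), 3 * se)
})
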