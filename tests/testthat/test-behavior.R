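test_that("psychometric function saturates, sits at chance at zero tilt, and favors valid cues", {
  obs0 <- observer_model(lapse_rate = 0)
  expect_equal(p_correct(obs0, 1e6), 1)
  expect_equal(p_correct(obs0, 0), 0.5)
  expect_equal(p_correct(obs0, 0, "invalid"), 0.5)
  obs <- observer_model(validity_effect = 0.6, lapse_rate = 0.02)
  # Monte-Carlo accuracy difference matches the closed-form psychometric gap
  s <- generate_session("endogenous", n_runs = 13, trials_per_run = 40,
                        seed = 31)  # 520 trials; ~390 valid, ~130 invalid
  s <- simulate_responses(s, obs, tilt = 1.5, exclusion_rate = 0, seed = 32)
  st <- s$trials[s$trials$trial_type %in% c("pre_cue", "post_cue"), ]
  acc <- tapply(st$correct, st$validity, mean)
  gap_mc <- acc[["valid"]] - acc[["invalid"]]
  gap_cf <- p_correct(obs, 1.5, "valid") - p_correct(obs, 1.5, "invalid")
  expect_gt(gap_mc, 0)
  expect_lt(abs(gap_mc - gap_cf), 0.08)
  expect_error(simulate_responses(s, obs, tilt = -1, seed = 1), "non-negative")
})

test_that("cue-only and blank trials are third-key responses, always correct", {
  s <- small_session(seed = 41)
  nostim <- s$trials[s$trials$trial_type %in% c("cue_only", "blank"), ]
  expect_true(all(nostim$correct))
  expect_true(all(is.na(nostim$target_cw)))
})

test_that("exclusion flags appear at the configured rate, independent of trial type", {
  s <- generate_session("exogenous", 14, 40, seed = 51)
  s <- simulate_responses(s, observer_model(), tilt = 2,
                          exclusion_rate = 0.13, seed = 52)
  rate <- mean(s$trials$excluded)
  expect_lt(abs(rate - 0.13), 0.05)
})

test_that("staircase converges near the analytically inverted 79.4% threshold", {
  obs <- observer_model(sigma = 1.5, lapse_rate = 0.01)
  target_tilt <- tilt_for_accuracy(obs, 0.794)
  tilts <- vapply(1:5, function(s) quiet(run_staircase(obs, seed = s))$tilt,
                  numeric(1))
  expect_lt(abs(mean(tilts) - target_tilt) / target_tilt, 0.10)
})

test_that("staircase estimate is invariant to the starting tilt", {
  obs <- observer_model(sigma = 1.5, lapse_rate = 0.01)
  lo <- quiet(run_staircase(obs, seed = 7, start_tilt = 0.5))$tilt
  hi <- quiet(run_staircase(obs, seed = 7, start_tilt = 6))$tilt
  expect_lt(abs(lo - hi), 0.5)
})

test_that("an unreachable target is reported as non-convergence, not accepted", {
  # the tilt ceiling caps accuracy below the 79.4% target
  obs <- observer_model(sigma = 50, lapse_rate = 0.01)
  expect_warning(sc <- run_staircase(obs, seed = 3, max_tilt = 5),
                 "did not converge")
  expect_false(sc$converged)
  expect_error(run_staircase(obs, n_trials = 50, seed = 1), ">= 100")
})

test_that("d-prime follows the inverse-normal convention with extreme-rate protection", {
  expect_equal(dprime(50, 100, 50, 100), 0)
  # z(0.9) - z(0.3), frozen from inverse-normal arithmetic
  expect_equal(dprime(90, 100, 30, 100), 1.8059521, tolerance = 1e-6)
  expect_true(is.finite(dprime(100, 100, 0, 100)))
  # antisymmetric under swapping hits and false alarms
  expect_equal(dprime(80, 100, 20, 100), -dprime(20, 100, 80, 100))
})

test_that("behavioral summaries compute per-cell d-prime and median RT after exclusions", {
  sessions <- list(P1 = small_session("endogenous", n_runs = 2, seed = 61),
                   P1 = simulate_responses(
                     generate_session("exogenous", 2, 40, seed = 62),
                     observer_model(), 2, exclusion_rate = 0, seed = 63),
                   P2 = small_session("endogenous", n_runs = 2, seed = 64),
                   P2 = simulate_responses(
                     generate_session("exogenous", 2, 40, seed = 65),
                     observer_model(), 2, exclusion_rate = 0, seed = 66))
  bs <- summarize_behavior(sessions)
  pp <- bs$per_participant
  expect_equal(nrow(pp), 2 * 2 * 2 * 2)  # participant x attention x epoch x validity
  expect_true(all(pp$n_trials > 0))
  expect_true(all(is.finite(pp$d_prime)))
  expect_true(all(pp$median_rt_s > 0))
})

test_that("the valid-invalid d-prime gap shrinks monotonically as the validity effect approaches 1", {
  # noiseless expectation: accuracy -> expected d' via the inverse normal
  gap <- vapply(c(0.5, 0.7, 0.9, 1), function(ve) {
    obs <- observer_model(validity_effect = ve, lapse_rate = 0)
    pv <- p_correct(obs, 1.5, "valid"); pi <- p_correct(obs, 1.5, "invalid")
    2 * qnorm(pv) - 2 * qnorm(pi)   # symmetric 2-AFC: d' = 2 z(pc)
  }, numeric(1))
  expect_true(all(diff(gap) < 0))
  expect_equal(gap[4], 0)
})

test_that("the three-way repeated-measures ANOVA isolates a pure validity effect", {
  set.seed(71)
  cells <- expand.grid(participant = paste0("P", 1:5),
                       attention_type = c("endogenous", "exogenous"),
                       cue_epoch = c("pre", "post"),
                       validity = c("valid", "invalid"),
                       stringsAsFactors = FALSE)
  cells$d_prime <- 1 + 0.5 * (cells$validity == "valid") +
    rnorm(nrow(cells), 0, 1e-6)
  res <- rm_anova(cells, "d_prime",
                  c("attention_type", "validity", "cue_epoch"))
  expect_lt(res$p_value[res$effect == "validity"], 1e-10)
  others <- res[res$effect != "validity", ]
  expect_true(all(others$p_value > 0.01))
  expect_true(all(res$df1 == 1 & res$df2 == 4))
})

test_that("the repeated-measures ANOVA is calibrated under the null", {
  set.seed(72)
  n_rep <- 300
  p_validity <- vapply(seq_len(n_rep), function(i) {
    cells <- expand.grid(participant = paste0("P", 1:5),
                         attention_type = c("a", "b"),
                         cue_epoch = c("pre", "post"),
                         validity = c("valid", "invalid"),
                         stringsAsFactors = FALSE)
    cells$d_prime <- rnorm(nrow(cells))
    res <- rm_anova(cells, "d_prime",
                    c("attention_type", "validity", "cue_epoch"))
    res$p_value[res$effect == "validity"]
  }, numeric(1))
  # rejection rate at 5% within Monte-Carlo error (3 binomial SDs)
  expect_lt(abs(mean(p_validity < 0.05) - 0.05), 3 * sqrt(0.05 * 0.95 / n_rep))
})

test_that("incomplete or single-participant designs are rejected with the cell named", {
  cells <- expand.grid(participant = paste0("P", 1:3),
                       validity = c("valid", "invalid"),
                       stringsAsFactors = FALSE)
  cells$d_prime <- rnorm(nrow(cells))
  expect_error(rm_anova(cells[-1, ], "d_prime", "validity"), "P1")
  one <- cells[cells$participant == "P1", ]
  expect_error(rm_anova(one, "d_prime", "validity"), "at least 2")
})
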