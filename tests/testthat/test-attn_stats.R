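test_that("AMI is 1 for equal amplitudes and matches direct arithmetic", {
  for (const in c(0, 0.1, 0.2, 0.4))
    expect_equal(compute_ami(0.5, 0.5, 0.5, 0.5, constant = const), 1)
  expect_equal(compute_ami(0.3, 0.1, 0.1, 0.1, constant = 0.2), 0.5 / 0.35)
  # scale invariance at zero constant
  expect_equal(compute_ami(0.3, 0.1, 0.2, 0.15, constant = 0),
               compute_ami(3, 1, 2, 1.5, constant = 0))
  expect_error(compute_ami(-1, -1, -1, -1, constant = 0.2), "raise 'constant'")
})

test_that("the four numerator-choice AMIs sum to 4 for any amplitudes and constant", {
  set.seed(201)
  for (i in 1:200) {
    a <- runif(4, -0.3, 1)
    const <- runif(1, 0.5, 2)
    s <- sum(vapply(c("Vc", "Ic", "Vi", "Ii"), function(n)
      compute_ami(a[1], a[2], a[3], a[4], const, n), numeric(1)))
    expect_lt(abs(s - 4), 1e-12)
  }
})

test_that("AMI approaches 1 monotonically as the constant grows", {
  consts <- c(0.2, 0.5, 1, 5, 50)
  amis <- vapply(consts, function(k) compute_ami(0.4, 0.1, 0.2, 0.1, k),
                 numeric(1))
  expect_true(all(diff(abs(amis - 1)) < 0))
  expect_lt(abs(amis[length(amis)] - 1), 0.01)
})

test_that("AMI records carry epoch-specific contralateral and pooled ipsilateral terms", {
  # contralateral valid pre = 0.6, all other stimulus cells 0.2
  tab <- amp_table_from_means(function(r)
    if (r$laterality == "contralateral" && r$validity == "valid" &&
        r$cue_epoch == "pre") 0.6 else 0.2)
  recs <- ami_table(tab, constant = 0.2)
  pre_valid <- recs$ami[recs$cue_epoch == "pre" &
                          recs$numerator_condition == "valid"]
  post_valid <- recs$ami[recs$cue_epoch == "post" &
                           recs$numerator_condition == "valid"]
  # oracle: pre denominator mean((0.8, 0.4, 0.4, 0.4)) = 0.5 -> 1.6;
  # post cells are all 0.4 after the offset -> AMI exactly 1
  expect_equal(unique(pre_valid), 0.8 / 0.5)
  expect_equal(unique(post_valid), 1)
  # fully epoch-specific variant changes nothing here (ipsi equal across epochs)
  recs2 <- ami_table(tab, ipsi_epoch_specific = TRUE)
  expect_equal(recs$ami, recs2$ami)
})

test_that("the AMI-vs-1 test matches the closed-form one-sample formulas", {
  means <- c(1.1, 1.2, 1.15, 1.25, 1.3)
  tab <- amp_table_from_means(function(r) {
    i <- as.integer(sub("P", "", r$participant))
    # shift only the valid-contralateral amplitude per participant
    if (r$laterality == "contralateral" && r$validity == "valid") {
      0.2 + (means[i] - 1) * 0.4
    } else 0.2
  })
  recs <- ami_table(tab, constant = 0.2)
  res <- ami_vs_one_test(recs)
  # independent oracle: the Vc bump also raises the denominator, so compute
  # the implied AMIs and the one-sample t by hand
  implied <- vapply(means, function(mu) {
    vc <- 0.2 + (mu - 1) * 0.4 + 0.2
    d <- mean(c(vc, 0.4, 0.4, 0.4))
    vc / d
  }, numeric(1))
  t_or <- mean(implied - 1) / (sd(implied) / sqrt(5))
  expect_equal(res$t, t_or, tolerance = 1e-10)
  expect_equal(res$df, 4)
  expect_equal(res$cohens_d, (mean(implied) - 1) / sd(implied),
               tolerance = 1e-10)
  expect_equal(res$p_value, 2 * pt(-abs(t_or), 4), tolerance = 1e-10)
})

test_that("degenerate zero-variance AMI means are reported, not tested", {
  tab <- amp_table_from_means(function(r) 0.3)
  recs <- ami_table(tab)
  res <- ami_vs_one_test(recs)
  expect_true(res$degenerate)
  expect_true(is.na(res$t))
  expect_equal(res$mean, 1)
})

test_that("per-ROI one-tailed tests sit at p = 0.5 when valid equals invalid", {
  tab <- amp_table_from_means(function(r) 0.25)
  recs <- ami_table(tab)
  res <- per_roi_validity_tests(recs)
  expect_equal(nrow(res), 6 * 2 * 2)
  expect_true(all(res$p_value == 0.5))
  expect_true(all(res$t == 0))
})

test_that("per-ROI tests are one-tailed for valid > invalid with optional Holm correction", {
  set.seed(211)
  bump <- rnorm(5, 0.25, 0.02)
  tab <- amp_table_from_means(function(r) {
    i <- as.integer(sub("P", "", r$participant))
    base <- 0.2
    if (r$laterality == "contralateral" && r$validity == "valid" &&
        r$attention_type == "endogenous") base + bump[i] else base
  })
  recs <- ami_table(tab)
  res <- per_roi_validity_tests(recs)
  endo <- res[res$attention_type == "endogenous", ]
  exo <- res[res$attention_type == "exogenous", ]
  expect_true(all(endo$p_value < 0.05))
  expect_true(all(exo$p_value == 0.5))
  resh <- per_roi_validity_tests(recs, correction = "holm")
  expect_true(all(resh$p_value >= res$p_value))
})

test_that("hierarchy regression matches the closed-form least-squares oracle", {
  d <- c(0.01, 0.02, 0.03, 0.05, 0.06, 0.08)
  res <- hierarchy_regression(d, 1:6)
  # independent oracle: hand-derived simple-regression formulas
  # Sxx = 17.5, Sxy = 0.245 -> slope 0.014; R2 = 0.00343/0.0034833
  expect_equal(res$slope, 0.014, tolerance = 1e-12)
  expect_equal(res$intercept, 0.25 / 6 - 0.014 * 3.5, tolerance = 1e-12)
  expect_equal(res$r_squared, 0.00343 / (0.0139 - 0.25^2 / 6),
               tolerance = 1e-10)
  expect_equal(res$df2, 4)
  expect_equal(res$F, 0.00343 / ((0.0139 - 0.25^2 / 6 - 0.00343) / 4),
               tolerance = 1e-8)
  expect_error(hierarchy_regression(d[1:2], 1:2), "at least 3")
})

test_that("hierarchy regression handles exact and constant patterns", {
  lin <- hierarchy_regression(0.02 * (1:6), 1:6)
  expect_equal(lin$r_squared, 1)
  expect_equal(lin$p_value, 0)
  flat <- hierarchy_regression(rep(0.1, 6), 1:6)
  expect_equal(flat$slope, 0)
  expect_equal(flat$r_squared, 0)
})

test_that("the laterality ANOVA detects a contralateral boost and stays flat without one", {
  set.seed(221)
  tab <- amp_table_from_means(function(r) {
    0.3 + 0.3 * (r$laterality == "contralateral") + rnorm(1, 0, 0.01)
  })
  res <- laterality_anova(tab, "endogenous")
  lat <- res[res$effect == "laterality", ]
  expect_lt(lat$p_value, 1e-4)
  int <- res[res$effect == "laterality:validity", ]
  expect_gt(int$p_value, 0.05)  # the boost is validity-independent
})

test_that("the laterality ANOVA holds its nominal type-I rate under the null", {
  set.seed(222)
  n_rep <- 150
  p <- vapply(seq_len(n_rep), function(i) {
    tab <- amp_table_from_means(function(r) rnorm(1, 0.3, 0.1),
                                attention_types = "endogenous")
    res <- laterality_anova(tab, "endogenous")
    res$p_value[res$effect == "laterality"]
  }, numeric(1))
  expect_lt(abs(mean(p < 0.05) - 0.05), 3 * sqrt(0.05 * 0.95 / n_rep))
})

test_that("AMI sensitivity reports a constant-invariant pattern for a real hierarchy effect", {
  tab <- amp_table_from_means(function(r) {
    d <- 0.08 * r$rank
    base <- 0.3
    if (r$laterality == "contralateral" && r$cue_epoch == "pre") {
      base + if (r$validity == "valid") d / 2 else -d / 2
    } else base
  })
  sens <- ami_sensitivity(tab, constants = c(0.1, 0.2, 0.4))
  expect_true(sens$pattern_invariant)
  pre <- sens$regressions[sens$regressions$cue_epoch == "pre", ]
  expect_true(all(pre$slope > 0))
})

test_that("the mixed model reproduces the closed-form fixed effects when variance is zero", {
  # noiseless construction: endogenous slope 0.02/rank, exogenous 0.005/rank + offset
  tab <- amp_table_from_means(function(r) {
    base <- 0.3
    if (r$laterality != "contralateral" || r$cue_epoch != "pre") return(base)
    slope <- if (r$attention_type == "endogenous") 0.02 else 0.005
    off <- if (r$attention_type == "endogenous") 0 else 0.05
    base + off + if (r$validity == "valid") slope * r$rank / 2 else
      -slope * r$rank / 2
  })
  recs <- ami_table(tab, constant = 0.2)
  fit <- fit_attention_lmm(recs, "pre")
  # oracle: ordinary least squares on the same data (random variance is 0)
  d <- fit$data
  ols <- lm(diff ~ rank * att, data = d)
  expect_equal(fit$fixed$estimate, unname(coef(ols)), tolerance = 1e-5)
  # under +/-1/2 coding the interaction equals the full slope difference
  slope_by_att <- vapply(c(0.5, -0.5), function(a) {
    unname(coef(lm(diff ~ rank, data = d[d$att == a, ]))[2])
  }, numeric(1))
  expect_equal(fit$fixed$estimate[fit$fixed$term == "rank:att"],
               slope_by_att[1] - slope_by_att[2], tolerance = 1e-5)
  expect_true(all(fit$fixed$df == 56))
  expect_true(fit$singular)   # zero variance is reported, not hidden
})

test_that("the mixed model detects a rank x attention interaction at study-scale effects", {
  set.seed(231)
  detected <- vapply(1:10, function(i) {
    tab <- amp_table_from_means(function(r) {
      base <- 0.3
      if (r$laterality != "contralateral" || r$cue_epoch != "pre")
        return(base + rnorm(1, 0, 0.02))
      slope <- if (r$attention_type == "endogenous") 0.05 else 0
      flat <- if (r$attention_type == "endogenous") 0 else 0.15
      eff <- slope * r$rank + flat
      base + rnorm(1, 0, 0.02) +
        if (r$validity == "valid") eff / 2 else -eff / 2
    })
    recs <- ami_table(tab)
    fit <- fit_attention_lmm(recs, "pre")
    fit$fixed$p_lrt[fit$fixed$term == "rank:att"] < 0.05
  }, logical(1))
  expect_gte(mean(detected), 0.8)
})

test_that("the post-cue regime shows intercept/attention structure without a rank effect", {
  set.seed(241)
  tab <- amp_table_from_means(function(r) {
    base <- 0.3
    if (r$laterality != "contralateral" || r$cue_epoch != "post")
      return(base + rnorm(1, 0, 0.02))
    eff <- if (r$attention_type == "endogenous") 0.2 else 0
    base + rnorm(1, 0, 0.02) + if (r$validity == "valid") eff / 2 else -eff / 2
  })
  recs <- ami_table(tab)
  fit <- fit_attention_lmm(recs, "post")
  fx <- fit$fixed
  expect_lt(fx$p_lrt[fx$term == "(Intercept)"], 0.05)
  expect_lt(fx$p_lrt[fx$term == "att"], 0.05)
  expect_gt(fx$p_lrt[fx$term == "rank"], 0.05)
})
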