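test_that("preprocessing removes ramps, drops leading volumes, and attenuates slow drifts", {
  vx <- voxel_grid(2, 1, rois = "V1")
  n <- 160; tr <- 1.75
  tt <- (seq_len(n) - 1) * tr
  ramp <- structure(list(data = matrix(rep(100 + 0.05 * tt, each = 4), 4,
                                       byrow = FALSE),
                         tr = tr, run_id = "ramp", n_discard = 8L,
                         voxel_meta = vx, run_duration_s = n * tr),
                    class = "voxel_ts")
  out <- preprocess_run(ramp)
  expect_equal(ncol(out$data), 152L)
  expect_lt(max(abs(out$data)), 1e-8)

  # a 0.001 Hz sinusoid (amplitude 1 raw unit = 1 percent of baseline)
  # loses at least 90% of its variance to the 0.01 Hz high-pass
  slow <- ramp
  slow$data <- matrix(rep(100 + sin(2 * pi * 0.001 * tt), each = 4), 4)
  outs <- preprocess_run(slow)
  post <- tt[-(1:8)]
  var_in <- var(sin(2 * pi * 0.001 * post))
  expect_lt(var(outs$data[1, ]), 0.1 * var_in)

  short <- ramp; short$data <- short$data[, 1:20]
  expect_error(preprocess_run(short), "too short")
})

test_that("ROI averaging is the unweighted mean over selected voxels", {
  vx <- voxel_grid(3, 1, rois = c("V1", "V2"))
  dat <- matrix(rnorm(12 * 10), 12, 10)
  ts <- structure(list(data = dat, tr = 1.75, run_id = "x", n_discard = 0L,
                       voxel_meta = vx, run_duration_s = 17.5),
                  class = "voxel_ts")
  # identical voxels: mean equals any single voxel
  ts$data[vx$roi == "V1" & vx$hemisphere == "left", ] <-
    matrix(rep(dat[1, ], each = 3), 3)
  expect_equal(average_roi_timecourse(ts, NULL, "V1", "left"), dat[1, ])
  # opposite-sign pair cancels
  i2 <- which(vx$roi == "V2" & vx$hemisphere == "right")[1:2]
  ts$data[i2[1], ] <- 1:10; ts$data[i2[2], ] <- -(1:10)
  fits <- data.frame(voxel = vx$voxel, amplitude = 1, phase = 1, coherence = 1)
  fits$selected <- vx$voxel %in% i2
  sel <- list(fits = fits); class(sel) <- "voxel_selection"
  expect_equal(unname(average_roi_timecourse(ts, sel, "V2", "right")),
               rep(0, 10))
  expect_error(average_roi_timecourse(ts, NULL, "LO1", "left"), "absent")
  # empty selection falls back to all ROI voxels with a warning
  fits$selected <- FALSE
  sel2 <- list(fits = fits); class(sel2) <- "voxel_selection"
  expect_warning(avg <- average_roi_timecourse(ts, sel2, "V1", "left"),
                 "falling back")
  expect_equal(avg, dat[1, ])
})

test_that("restricting to responsive voxels raises the contrast-to-noise of the ROI mean", {
  s <- small_session(seed = 101)
  gt <- ground_truth_effects("endogenous")
  vx <- voxel_grid(20, 0.5)
  err_for <- function(use_selection) {
    errs <- vapply(1:6, function(r) {
      run <- simulate_attention_run(s, 1, gt, voxels = vx, seed = 500 + r,
                                    noise = noise_params(1.2, 0.3, 0.5, 0.05))
      run <- preprocess_run(run, baseline = 100)
      sel <- if (use_selection) {
        fits <- data.frame(voxel = vx$voxel, amplitude = 1, phase = 1,
                           coherence = 1, selected = vx$responsive)
        structure(list(fits = fits), class = "voxel_selection")
      } else NULL
      amp <- quiet(condition_amplitudes(list(run), s, sel,
                                        correct_only = FALSE,
                                        rois = "LO1"))
      chk <- merge(amp, gt$amps, by = c("roi", "hemisphere", "condition"))
      mean((chk$beta_psc - chk$amplitude)^2)
    }, numeric(1))
    mean(errs)
  }
  # the unselected average dilutes signal with silent voxels -> larger error
  expect_lt(err_for(TRUE), err_for(FALSE))
})

test_that("the design matrix has the twelve named regressors and flags absent conditions", {
  s <- small_session(seed = 111)
  d <- quiet(build_design_matrix(s$trials, tr = 1.75, n_vols_per_run = 160L))
  expect_length(d$task_cols, 12)
  expect_setequal(d$task_cols,
                  c(paste(rep(c("pre", "post"), each = 4),
                          rep(rep(c("valid", "invalid"), each = 2), 2),
                          rep(c("left", "right"), 4), sep = "_"),
                    "cue_only_left", "cue_only_right", "blank",
                    "eye_movement"))
  # no excluded trials -> eye-movement column exists, is all zero, flagged
  expect_true("eye_movement" %in% d$empty_cols)
  expect_true(all(d$X[, "eye_movement"] == 0))
  # excluded trials load only on the eye-movement regressor
  s2 <- s; s2$trials$excluded[1:5] <- TRUE
  d2 <- quiet(build_design_matrix(s2$trials, 1.75, 160L))
  expect_false("eye_movement" %in% d2$empty_cols)
  expect_gt(max(d2$X[, "eye_movement"]), 0)
})

test_that("incorrect trials are diverted to a nuisance column under correct-only estimation", {
  s <- small_session(seed = 121, tilt = 0.3)  # hard tilt -> many errors
  d <- quiet(build_design_matrix(s$trials, 1.75, 160L, correct_only = TRUE))
  expect_true("incorrect" %in% colnames(d$X))
  d0 <- quiet(build_design_matrix(s$trials, 1.75, 160L, correct_only = FALSE))
  expect_false("incorrect" %in% colnames(d0$X))
  # the condition regressors then carry only correct trials: column sums shrink
  expect_lt(sum(d$X[, "pre_valid_left"]), sum(d0$X[, "pre_valid_left"]))
})

test_that("noiseless GLM recovery is exact and doubles with doubled amplitudes", {
  s <- small_session(seed = 131)
  gt1 <- ground_truth_effects("endogenous", base_contra = 0.4,
                              base_ipsi = 0.25, slope_per_rank = 0.03,
                              flat_effect = 0.1)
  gt2 <- ground_truth_effects("endogenous", base_contra = 0.8,
                              base_ipsi = 0.5, slope_per_rank = 0.06,
                              flat_effect = 0.2, cue_amp_contra = 0.6,
                              cue_amp_ipsi = 0.3, blank_amp = 0.2)
  fit_for <- function(gt) {
    run <- noiseless_run(s, gt)
    run <- preprocess_run(run, baseline = 100)
    quiet(condition_amplitudes(list(run), s, NULL, correct_only = FALSE))
  }
  a1 <- fit_for(gt1)
  chk <- merge(a1, gt1$amps, by = c("roi", "hemisphere", "condition"))
  expect_lt(max(abs(chk$beta_psc - chk$amplitude)), 1e-6)
  # stimulus-condition amplitudes in gt2 are exactly double gt1's
  a2 <- fit_for(gt2)
  m <- merge(a1, a2, by = c("roi", "hemisphere", "condition"))
  expect_equal(m$beta_psc.y, 2 * m$beta_psc.x, tolerance = 1e-6)
})

test_that("under white noise the beta distribution matches the closed-form OLS covariance", {
  s <- small_session(seed = 141)
  run0 <- noiseless_run(s, ground_truth_effects("endogenous"), n_per_roi = 1)
  pr0 <- preprocess_run(run0, baseline = 100)
  design <- build_design_matrix(
    s$trials, 1.75, ncol(pr0$data), correct_only = FALSE,
    nuisance_q = list(pr0$nuisance_q))
  X <- design$X[, setdiff(colnames(design$X), design$empty_cols)]
  sigma <- 0.5
  xtx_inv <- solve(crossprod(X))
  set.seed(142)
  B <- t(vapply(seq_len(400), function(i) {
    y <- rnorm(nrow(X), 0, sigma)
    fit <- estimate_amplitudes(y, design)
    fit$coefficients$beta
  }, numeric(ncol(X))))
  emp_mean <- colMeans(B)
  emp_var <- apply(B, 2, var)
  theo_var <- diag(xtx_inv) * sigma^2
  expect_lt(max(abs(emp_mean)), 4 * sqrt(max(theo_var) / 400) + 0.05)
  expect_lt(max(abs(emp_var / theo_var - 1)), 0.35)
})

test_that("rank-deficient designs are rejected with the offending column named", {
  s <- small_session(seed = 151)
  d <- quiet(build_design_matrix(s$trials, 1.75, 160L, correct_only = FALSE))
  d$X <- cbind(d$X, dup = d$X[, "blank"])
  expect_error(estimate_amplitudes(rnorm(nrow(d$X)), d), "dup|blank")
  d2 <- quiet(build_design_matrix(s$trials, 1.75, 160L, correct_only = FALSE))
  expect_error(estimate_amplitudes(rnorm(10), d2), "does not match")
})

test_that("betas are invariant to the order of run concatenation", {
  s <- small_session(seed = 161, n_runs = 2)
  gt <- ground_truth_effects("endogenous")
  vx <- voxel_grid(2, 1)
  runs <- lapply(1:2, function(r)
    simulate_attention_run(s, r, gt, voxels = vx, seed = 170 + r,
                           noise = noise_params(0.3, 0.3, 0.5, 0)))
  runs <- lapply(runs, preprocess_run, baseline = 100)
  amp12 <- quiet(condition_amplitudes(runs, s, NULL, correct_only = FALSE))
  # relabel runs 1<->2 and feed them in the swapped order
  s2 <- s
  s2$trials$run <- 3L - s2$trials$run
  s2$trials <- s2$trials[order(s2$trials$run, s2$trials$trial_index), ]
  amp21 <- quiet(condition_amplitudes(rev(runs), s2, NULL,
                                      correct_only = FALSE))
  m <- merge(amp12, amp21, by = c("roi", "hemisphere", "condition"))
  expect_equal(m$beta_psc.x, m$beta_psc.y, tolerance = 1e-10)
})

test_that("laterality recoding is a pure relabeling and inverts exactly", {
  h <- c("left", "right", "left", "right")
  cs <- c("left", "left", "right", "right")
  lat <- hemisphere_to_laterality(h, cs)
  expect_equal(lat, c("ipsilateral", "contralateral", "contralateral",
                      "ipsilateral"))
  expect_equal(laterality_to_hemisphere(lat, cs), h)
})
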