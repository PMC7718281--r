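#' Canonical double-gamma hemodynamic response function
#'
#' The kernel linking neural events to BOLD signal: a gamma density peaking
#' at `peak_time` minus a scaled gamma undershoot peaking at
#' `undershoot_time`, normalized so the peak equals 1 (betas estimated
#' against this kernel are therefore peak amplitudes in the data's units,
#' here percent signal change). The kernel is causal: it is exactly zero at
#' t = 0 and its argmax lies in 4-6 s under the default parameterization.
#'
#' @param t Non-negative time grid in seconds.
#' @param peak_time Mode of the positive lobe, seconds.
#' @param undershoot_time Mode of the undershoot lobe, seconds.
#' @param undershoot_ratio Relative amplitude of the undershoot.
#' @return Numeric vector of kernel values on `t`.
#' @export
hrf <- function(t, peak_time = 5, undershoot_time = 15,
                undershoot_ratio = 1 / 6) {
  if (any(t < 0)) stop("hrf is causal: negative times are not allowed")
  stopifnot(peak_time > 0, undershoot_time > peak_time, undershoot_ratio >= 0)
  raw <- function(tt) {
    # unit-rate gammas with modes at the requested times (mode = shape - 1)
    stats::dgamma(tt, shape = peak_time + 1, rate = 1) -
      undershoot_ratio * stats::dgamma(tt, shape = undershoot_time + 1, rate = 1)
  }
  grid <- seq(0, undershoot_time * 2.5, by = 0.01)
  raw(t) / max(raw(grid))
}

# kernel evaluated at (possibly negative) lags, zero before the event
.hrf_lag <- function(dt, ...) {
  out <- numeric(length(dt))
  pos <- dt >= 0
  out[pos] <- hrf(dt[pos], ...)
  out
}

# exact HRF regressor: sum of kernels shifted to each event onset,
# sampled at the volume acquisition times
event_regressor <- function(onsets, times, ...) {
  if (length(onsets) == 0) return(numeric(length(times)))
  rowSums(vapply(onsets, function(o) .hrf_lag(times - o, ...),
                 numeric(length(times))))
}

#' Noise parameters for synthetic BOLD runs
#'
#' @param white_sd Innovation SD of the AR(1) noise, percent signal change.
#' @param ar1 AR(1) coefficient of the temporal noise.
#' @param drift_amp Maximum magnitude of the per-voxel linear drift over a
#'   run (slope drawn uniformly in +/- `drift_amp`), percent signal change.
#' @param voxel_amp_sd SD of per-voxel response amplitudes around the ROI
#'   ground-truth mean, percent signal change.
#' @return A `noise_params` list.
#' @export
noise_params <- function(white_sd = 0.3, ar1 = 0.3, drift_amp = 0.5,
                         voxel_amp_sd = 0.05) {
  stopifnot(white_sd >= 0, abs(ar1) < 1, drift_amp >= 0, voxel_amp_sd >= 0)
  structure(list(white_sd = white_sd, ar1 = ar1, drift_amp = drift_amp,
                 voxel_amp_sd = voxel_amp_sd), class = "noise_params")
}

#' Ground-truth condition amplitudes along the visual hierarchy
#'
#' Defines the true percent-signal-change response amplitude of every ROI x
#' hemisphere x condition cell for one attention type. The contralateral
#' valid-invalid difference follows a `modulation_profile` per cue epoch:
#' `"increasing"` (difference grows linearly with hierarchy rank, slope
#' `slope_per_rank`), `"flat"` (constant positive difference
#' `flat_effect`) or `"null"` (no difference). Ipsilateral (distractor)
#' responses carry no validity effect and a lower baseline, giving the
#' contralateral > ipsilateral laterality effect.
#'
#' @param attention_type `"endogenous"` or `"exogenous"`.
#' @param profiles Named character vector: modulation profile for `pre`
#'   and `post` cue epochs.
#' @param base_contra,base_ipsi Baseline stimulus response amplitudes
#'   (percent signal change) for contralateral/ipsilateral ROIs.
#' @param slope_per_rank Valid-invalid difference added per hierarchy rank
#'   under the `"increasing"` profile.
#' @param flat_effect Constant valid-invalid difference under `"flat"`.
#' @param cue_amp_contra,cue_amp_ipsi Cue-only response amplitudes.
#' @param blank_amp Response-cue-evoked amplitude on blank trials.
#' @param rois Named integer vector of hierarchy ranks.
#' @return A `ground_truth` object with an `amps` data frame (`roi`,
#'   `rank`, `hemisphere`, `condition`, `amplitude`) and the profile
#'   parameters.
#' @export
ground_truth_effects <- function(attention_type = c("endogenous", "exogenous"),
                                 profiles = c(pre = "increasing", post = "flat"),
                                 base_contra = 0.8, base_ipsi = 0.5,
                                 slope_per_rank = 0.05, flat_effect = 0.15,
                                 cue_amp_contra = 0.3, cue_amp_ipsi = 0.15,
                                 blank_amp = 0.1, rois = roi_hierarchy) {
  attention_type <- match.arg(attention_type)
  stopifnot(all(names(profiles) %in% c("pre", "post")),
            all(profiles %in% c("increasing", "flat", "null")))
  diff_for <- function(profile, rank) {
    switch(profile,
           increasing = slope_per_rank * rank,
           flat = flat_effect,
           null = 0)
  }
  rows <- list()
  for (roi in names(rois)) {
    rank <- rois[[roi]]
    for (hemi in .hemis()) {
      contra_cue_side <- if (hemi == "left") "right" else "left"
      for (epoch in c("pre", "post")) {
        d <- diff_for(profiles[[epoch]], rank)
        for (validity in c("valid", "invalid")) {
          for (cue_side in c("left", "right")) {
            contra <- cue_side == contra_cue_side
            amp <- if (contra) {
              base_contra + if (validity == "valid") d / 2 else -d / 2
            } else base_ipsi
            rows[[length(rows) + 1L]] <-
              data.frame(roi = roi, rank = rank, hemisphere = hemi,
                         condition = paste(epoch, validity, cue_side, sep = "_"),
                         amplitude = amp, stringsAsFactors = FALSE)
          }
        }
      }
      for (cue_side in c("left", "right")) {
        rows[[length(rows) + 1L]] <-
          data.frame(roi = roi, rank = rank, hemisphere = hemi,
                     condition = paste0("cue_only_", cue_side),
                     amplitude = if (cue_side == contra_cue_side)
                       cue_amp_contra else cue_amp_ipsi,
                     stringsAsFactors = FALSE)
      }
      rows[[length(rows) + 1L]] <-
        data.frame(roi = roi, rank = rank, hemisphere = hemi,
                   condition = "blank", amplitude = blank_amp,
                   stringsAsFactors = FALSE)
    }
  }
  amps <- do.call(rbind, rows)
  structure(list(attention_type = attention_type, profiles = profiles,
                 amps = amps,
                 params = list(base_contra = base_contra, base_ipsi = base_ipsi,
                               slope_per_rank = slope_per_rank,
                               flat_effect = flat_effect,
                               cue_amp_contra = cue_amp_contra,
                               cue_amp_ipsi = cue_amp_ipsi,
                               blank_amp = blank_amp, rois = rois)),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("Ground-truth effects (", x$attention_type, "): pre = ",
      x$profiles[["pre"]], ", post = ", x$profiles[["post"]], "\n", sep = "")
  invisible(x)
}

# rescale the valid-invalid effects of a ground truth by a factor
# (used for per-participant effect-size variability)
scale_ground_truth <- function(gt, factor) {
  gt2 <- ground_truth_effects(
    attention_type = gt$attention_type, profiles = gt$profiles,
    base_contra = gt$params$base_contra, base_ipsi = gt$params$base_ipsi,
    slope_per_rank = gt$params$slope_per_rank * factor,
    flat_effect = gt$params$flat_effect * factor,
    cue_amp_contra = gt$params$cue_amp_contra,
    cue_amp_ipsi = gt$params$cue_amp_ipsi,
    blank_amp = gt$params$blank_amp, rois = gt$params$rois)
  gt2
}

#' Define the simulated voxel grid
#'
#' @param n_per_roi Voxels per ROI per hemisphere.
#' @param prop_responsive Proportion of each ROI's voxels that respond to
#'   the stimulus (the localizer's ground-truth target set).
#' @param n_background Additional unlabeled (non-cortical) voxels.
#' @param rois ROI labels.
#' @return Data frame `voxel`, `roi`, `hemisphere`, `responsive`.
#' @export
voxel_grid <- function(n_per_roi = 100L, prop_responsive = 0.8,
                       n_background = 0L, rois = .rois()) {
  stopifnot(n_per_roi >= 1, prop_responsive >= 0, prop_responsive <= 1)
  n_resp <- round(n_per_roi * prop_responsive)
  meta <- expand.grid(i = seq_len(n_per_roi), hemisphere = .hemis(),
                      roi = rois, stringsAsFactors = FALSE)
  meta$responsive <- meta$i <= n_resp
  if (n_background > 0)
    meta <- rbind(meta,
                  data.frame(i = seq_len(n_background), hemisphere = "none",
                             roi = "background", responsive = FALSE))
  meta$voxel <- seq_len(nrow(meta))
  meta[, c("voxel", "roi", "hemisphere", "responsive")]
}

# condition key of each trial row (NA for none)
condition_key <- function(trials) {
  epoch <- ifelse(trials$trial_type == "pre_cue", "pre",
                  ifelse(trials$trial_type == "post_cue", "post", NA))
  ifelse(trials$trial_type %in% c("pre_cue", "post_cue"),
         paste(epoch, trials$validity, trials$cue_side, sep = "_"),
         ifelse(trials$trial_type == "cue_only",
                paste0("cue_only_", trials$cue_side), "blank"))
}

# neural event anchor: stimulus onset for stimulus trials, cue onset for
# cue-only trials, response-cue onset for blank trials
event_anchor <- function(trials) {
  ifelse(trials$trial_type %in% c("pre_cue", "post_cue"), trials$stim_on,
         ifelse(trials$trial_type == "cue_only", trials$cue_on,
                trials$response_cue_on))
}

#' Simulate one event-related attention run
#'
#' Each stimulus-responsive voxel's series is baseline (100) plus the sum
#' over trials of its condition amplitude times the HRF shifted to the
#' event onset, plus a linear drift and AR(1) noise, all in percent signal
#' change about the baseline. Contralateral assignment follows cue side
#' (a left cue drives right-hemisphere voxels); per-voxel amplitudes are
#' drawn around the ROI's ground-truth mean (SD `noise$voxel_amp_sd`).
#'
#' @param session A `session_design`.
#' @param run Run number within the session.
#' @param ground_truth A [ground_truth_effects()] object for the session's
#'   attention type.
#' @param noise A [noise_params()] list.
#' @param voxels A [voxel_grid()] data frame.
#' @param seed Integer seed (required).
#' @return A `voxel_ts` object: list with `data` (voxel x timepoint
#'   matrix), `tr`, `run_id`, `n_discard`, `voxel_meta`, `run_duration_s`.
#' @export
simulate_attention_run <- function(session, run, ground_truth,
                                   noise = noise_params(),
                                   voxels = voxel_grid(), seed) {
  stopifnot(inherits(session, "session_design"),
            inherits(ground_truth, "ground_truth"))
  if (!identical(ground_truth$attention_type, session$attention_type))
    stop("ground truth is for ", ground_truth$attention_type,
         " but the session is ", session$attention_type)
  if (missing(seed) || is.null(seed)) stop("'seed' is required")
  set.seed(seed)
  trials <- session$trials[session$trials$run == run, , drop = FALSE]
  if (nrow(trials) == 0) stop("run ", run, " is not part of this session")
  tr <- session$timing$tr
  run_dur <- session$timing$run_duration_s
  n_vols <- round(run_dur / tr)
  times <- (seq_len(n_vols) - 1) * tr

  keys <- condition_key(trials)
  anchors <- event_anchor(trials)
  if (any(anchors > run_dur))
    stop("trial events extend past the run duration; design and run length mismatch")
  conds <- unique(keys)
  R <- t(vapply(conds, function(k) event_regressor(anchors[keys == k], times),
                numeric(n_vols)))   # condition x time

  amp_lookup <- setNames(ground_truth$amps$amplitude,
                         paste(ground_truth$amps$roi, ground_truth$amps$hemisphere,
                               ground_truth$amps$condition))
  nv <- nrow(voxels)
  A <- matrix(0, nv, length(conds))  # voxel x condition amplitudes
  for (j in seq_along(conds)) {
    key <- paste(voxels$roi, voxels$hemisphere, conds[j])
    mu <- amp_lookup[key]
    mu[is.na(mu)] <- 0
    a <- mu + rnorm(nv, 0, noise$voxel_amp_sd)
    a[!voxels$responsive] <- 0
    A[, j] <- a
  }
  signal <- A %*% R

  drift <- if (noise$drift_amp > 0) {
    slopes <- runif(nv, -noise$drift_amp, noise$drift_amp)
    outer(slopes, (times - mean(times)) / (run_dur / 2))
  } else matrix(0, nv, n_vols)
  eps <- if (noise$white_sd > 0) {
    w <- matrix(rnorm(nv * n_vols, 0, noise$white_sd), nv, n_vols)
    t(apply(w, 1, function(x) as.numeric(stats::filter(x, noise$ar1,
                                                       method = "recursive"))))
  } else matrix(0, nv, n_vols)

  structure(list(data = 100 + signal + drift + eps, tr = tr,
                 run_id = paste0(session$attention_type, "_run", run),
                 n_discard = 8L, voxel_meta = voxels,
                 run_duration_s = run_dur),
            class = "voxel_ts")
}

#' Simulate one block-design localizer run
#'
#' 16 cycles of 17.5 s (8.75 s stimulus on / 8.75 s off), 280 s per run,
#' 160 volumes at TR 1.75 s. Stimulus-responsive voxels carry an
#' HRF-convolved boxcar at the cycle frequency (1/17.5 Hz) plus drift and
#' AR(1) noise; non-responsive voxels carry noise only.
#'
#' @param voxels A [voxel_grid()] data frame.
#' @param amp Response amplitude of responsive voxels (percent signal
#'   change at the plateau of the convolved boxcar).
#' @param n_cycles,cycle_s,tr Block protocol parameters.
#' @param noise A [noise_params()] list.
#' @param seed Integer seed (required).
#' @param run_id Run identifier.
#' @return A `voxel_ts` object (with `n_discard = 0`: localizer analysis
#'   operates on the full cycle structure).
#' @export
simulate_localizer_run <- function(voxels = voxel_grid(), amp = 1.5,
                                   n_cycles = 16L, cycle_s = 17.5, tr = 1.75,
                                   noise = noise_params(), seed,
                                   run_id = "localizer") {
  if (missing(seed) || is.null(seed)) stop("'seed' is required")
  set.seed(seed)
  run_dur <- n_cycles * cycle_s
  n_vols <- round(run_dur / tr)
  times <- (seq_len(n_vols) - 1) * tr
  # HRF-convolved boxcar on a fine grid, sampled at volume times
  dt <- tr / 16
  fine <- seq(0, run_dur, by = dt)
  box <- as.numeric((fine %% cycle_s) < cycle_s / 2)
  kern <- hrf(seq(0, 32, by = dt))
  conv <- convolve(box, rev(kern), type = "open")[seq_along(fine)] * dt
  conv <- conv / max(conv)
  reg <- conv[round(times / dt) + 1L]

  nv <- nrow(voxels)
  amps <- (amp + rnorm(nv, 0, noise$voxel_amp_sd)) * voxels$responsive
  signal <- outer(amps, reg)
  drift <- if (noise$drift_amp > 0) {
    slopes <- runif(nv, -noise$drift_amp, noise$drift_amp)
    outer(slopes, (times - mean(times)) / (run_dur / 2))
  } else matrix(0, nv, n_vols)
  eps <- if (noise$white_sd > 0) {
    w <- matrix(rnorm(nv * n_vols, 0, noise$white_sd), nv, n_vols)
    t(apply(w, 1, function(x) as.numeric(stats::filter(x, noise$ar1,
                                                       method = "recursive"))))
  } else matrix(0, nv, n_vols)

  structure(list(data = 100 + signal + drift + eps, tr = tr, run_id = run_id,
                 n_discard = 0L, voxel_meta = voxels,
                 run_duration_s = run_dur),
            class = "voxel_ts")
}

#' @export
print.voxel_ts <- function(x, ...) {
  cat(sprintf("BOLD run '%s': %d voxels x %d volumes (TR %.3g s, %g s)\n",
              x$run_id, nrow(x$data), ncol(x$data), x$tr, x$run_duration_s))
  invisible(x)
}

#' Average several runs voxel-wise
#'
#' Used to average the localizer runs before the sinusoid fit. Runs must
#' share voxel grid, TR and length.
#'
#' @param runs List of `voxel_ts` objects.
#' @return A `voxel_ts` with the element-wise mean data.
#' @export
average_runs <- function(runs) {
  stopifnot(length(runs) >= 1, all(vapply(runs, inherits, TRUE, "voxel_ts")))
  dims <- vapply(runs, function(r) dim(r$data), numeric(2))
  if (any(dims != dims[, 1])) stop("runs differ in voxel/volume counts")
  out <- runs[[1]]
  out$data <- Reduce(`+`, lapply(runs, `[[`, "data")) / length(runs)
  out$run_id <- paste0("avg_of_", length(runs))
  out
}

#' Convert a raw BOLD matrix to percent signal change and back
#'
#' Percent signal change is expressed about the per-voxel temporal mean:
#' `psc = 100 * (x - mean) / mean`. `psc_to_raw` inverts the mapping given
#' the stored baselines; the round trip is the identity to numerical
#' precision.
#'
#' @param x Voxel x time matrix of raw signal.
#' @return For `raw_to_psc`: list with `psc` matrix and `baseline` vector.
#' @export
raw_to_psc <- function(x) {
  baseline <- rowMeans(x)
  if (any(baseline == 0)) stop("zero-mean voxel: percent signal change undefined")
  list(psc = 100 * sweep(x, 1, baseline) / baseline, baseline = baseline)
}

#' @rdname raw_to_psc
#' @param psc Percent-signal-change matrix.
#' @param baseline Per-voxel baseline returned by `raw_to_psc`.
#' @export
psc_to_raw <- function(psc, baseline) {
  sweep(psc * baseline / 100, 1, baseline, `+`)
}
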