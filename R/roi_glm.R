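#' Preprocess one BOLD run
#'
#' Standard event-related preprocessing: discard the first `n_discard`
#' volumes (longitudinal magnetization reaching steady state), remove each
#' voxel's linear trend, apply a temporal high-pass filter (discrete-cosine
#' basis projection, cutoff `highpass_hz`, default 0.01 Hz) and convert to
#' percent signal change about the voxel mean.
#'
#' @param ts A `voxel_ts` object.
#' @param highpass_hz High-pass cutoff in Hz; DCT components below this
#'   frequency are projected out. `0` disables the filter.
#' @param n_discard Number of leading volumes to discard (default the
#'   run's own `n_discard`, typically 8).
#' @param baseline Baseline for the percent-signal-change conversion:
#'   `NULL` (default) uses each voxel's temporal mean; a scalar or
#'   per-voxel vector (e.g. the nominal simulated baseline of 100) makes
#'   the conversion exactly linear, which noiseless recovery checks rely
#'   on.
#' @param min_volumes Minimum remaining volumes required.
#' @return The `voxel_ts` with `data` replaced by percent-signal-change
#'   values, `n_discard` set to 0, a `preprocessed` flag, and the
#'   orthonormal nuisance basis in `nuisance_q` (the GLM projects its
#'   design through the same basis so filtering does not bias the betas).
#' @export
preprocess_run <- function(ts, highpass_hz = 0.01, n_discard = NULL,
                           baseline = NULL, min_volumes = 16L) {
  stopifnot(inherits(ts, "voxel_ts"))
  if (is.null(n_discard)) n_discard <- ts$n_discard
  n_total <- ncol(ts$data)
  if (n_total - n_discard < min_volumes)
    stop("run too short: ", n_total, " volumes with ", n_discard,
         " discarded leaves fewer than ", min_volumes)
  x <- ts$data[, (n_discard + 1L):n_total, drop = FALSE]
  n <- ncol(x)
  if (is.null(baseline)) baseline <- rowMeans(x)
  if (length(baseline) == 1L) baseline <- rep(baseline, nrow(x))
  if (any(baseline <= 0)) stop("non-positive baseline: cannot form percent signal change")

  # nuisance basis: intercept, linear trend, low-frequency DCT components
  tt <- seq_len(n)
  basis <- cbind(1, tt - mean(tt))
  if (highpass_hz > 0) {
    k_max <- floor(2 * n * ts$tr * highpass_hz)
    if (k_max >= 1) {
      dct <- sapply(seq_len(k_max),
                    function(k) cos(pi * k * (tt - 0.5) / n))
      basis <- cbind(basis, dct)
    }
  }
  # project the nuisance space out of each voxel's series
  qb <- qr.Q(qr(basis))
  resid <- x - (x %*% qb) %*% t(qb)
  ts$data <- 100 * resid / baseline
  ts$n_discard <- 0L
  ts$n_discarded <- as.integer(n_discard)
  ts$baseline <- baseline
  ts$nuisance_q <- qb
  ts$preprocessed <- TRUE
  ts
}

#' Average the time course across an ROI's selected voxels
#'
#' Unweighted mean over the stimulus-responsive (localizer-selected)
#' voxels of one ROI in one hemisphere. If no voxel of the ROI survives
#' selection, a warning is raised and all ROI voxels are used.
#'
#' @param ts A (preprocessed) `voxel_ts`.
#' @param selection A `voxel_selection` (or `NULL` to use all ROI voxels).
#' @param roi,hemisphere ROI label and hemisphere.
#' @return Numeric vector: the ROI-mean time course.
#' @export
average_roi_timecourse <- function(ts, selection, roi, hemisphere) {
  stopifnot(inherits(ts, "voxel_ts"))
  meta <- ts$voxel_meta
  in_roi <- meta$roi == roi & meta$hemisphere == hemisphere
  if (!any(in_roi))
    stop("ROI ", roi, " (", hemisphere, ") is absent from the voxel metadata")
  idx <- meta$voxel[in_roi]
  if (!is.null(selection)) {
    sel <- selection$fits$voxel[selection$fits$selected]
    keep <- intersect(idx, sel)
    if (length(keep) == 0) {
      warning("no selected voxels in ", roi, " (", hemisphere,
              "); falling back to all ", length(idx), " ROI voxels")
    } else idx <- keep
  }
  colMeans(ts$data[match(idx, meta$voxel), , drop = FALSE])
}

#' Build the twelve-regressor event-related design matrix
#'
#' One HRF-convolved regressor per condition: the 8 combinations of cue
#' side (left/right) x validity (valid/invalid) x cue epoch (pre/post),
#' left and right cue-only, blank, and eye-movement (fixation-break
#' trials, which load only on that regressor regardless of their nominal
#' condition). With `correct_only = TRUE` (the default), incorrect
#' non-excluded stimulus trials load on a separate `incorrect` nuisance
#' column so the 8 condition betas reflect correct trials only. Per-run
#' intercept columns are appended. Regressors are exact sums of HRF
#' kernels shifted to the event anchors (stimulus onset for stimulus
#' trials, cue onset for cue-only, response-cue onset for blank trials),
#' sampled at the post-discard volume times.
#'
#' @param trials Trial data frame (concatenated across runs) with the
#'   columns written by [generate_session()] plus `correct`/`excluded`.
#' @param tr Repetition time, seconds.
#' @param n_vols_per_run Named or ordered vector: post-discard volume
#'   count of each run, in concatenation order.
#' @param n_discard Leading volumes discarded from each run (onsets are
#'   counted from acquisition start).
#' @param correct_only Model incorrect trials as a separate nuisance
#'   regressor.
#' @param nuisance_q Optional list (one per run, in order) of orthonormal
#'   nuisance bases from [preprocess_run()]; each run's regressor block is
#'   projected through the same basis as the data, so temporal filtering
#'   does not bias the condition betas. When supplied, per-run intercepts
#'   are omitted (the projection annihilates them).
#' @return A `design_matrix`: list with `X` (timepoint x regressor),
#'   `task_cols` (the 12 condition regressor names), `empty_cols`
#'   (flagged all-zero task columns), `run_index`, `tr`.
#' @export
build_design_matrix <- function(trials, tr, n_vols_per_run, n_discard = 8L,
                                correct_only = TRUE, nuisance_q = NULL) {
  runs <- sort(unique(trials$run))
  if (length(n_vols_per_run) == 1L)
    n_vols_per_run <- rep(n_vols_per_run, length(runs))
  stopifnot(length(n_vols_per_run) == length(runs))

  # canonical order: epoch_validity_side
  task_cols <- c(paste(rep(c("pre", "post"), each = 4),
                       rep(rep(c("valid", "invalid"), each = 2), 2),
                       rep(c("left", "right"), 4), sep = "_"),
                 "cue_only_left", "cue_only_right", "blank", "eye_movement")

  trials$condition <- condition_key(trials)
  trials$anchor <- event_anchor(trials)
  is_stim <- trials$trial_type %in% c("pre_cue", "post_cue")
  if (correct_only && any(is_stim & !trials$excluded & is.na(trials$correct)))
    stop("correct_only = TRUE but some stimulus trials have no correctness; ",
         "simulate or supply responses first")

  reg_of <- rep(NA_character_, nrow(trials))
  reg_of[!trials$excluded] <- trials$condition[!trials$excluded]
  reg_of[trials$excluded] <- "eye_movement"
  incorrect <- correct_only & is_stim & !trials$excluded &
    !is.na(trials$correct) & !trials$correct
  reg_of[incorrect] <- "incorrect"
  all_cols <- c(task_cols, if (any(incorrect)) "incorrect")

  blocks <- list()
  for (i in seq_along(runs)) {
    r <- runs[i]
    n <- n_vols_per_run[i]
    times <- (n_discard + seq_len(n) - 1L) * tr
    rt <- trials[trials$run == r, , drop = FALSE]
    Xr <- matrix(0, n, length(all_cols), dimnames = list(NULL, all_cols))
    for (cc in unique(reg_of[trials$run == r])) {
      on <- rt$anchor[reg_of[trials$run == r] == cc]
      if (anyDuplicated(on)) {
        warning("overlapping events at identical onsets in regressor '", cc,
                "' (run ", r, "); merging")
        on <- unique(on)
      }
      Xr[, cc] <- event_regressor(on, times)
    }
    if (!is.null(nuisance_q)) {
      q <- nuisance_q[[i]]
      if (nrow(q) != n) stop("nuisance basis of run ", r,
                             " does not match its volume count")
      Xr <- Xr - q %*% (t(q) %*% Xr)
    }
    blocks[[i]] <- Xr
  }
  X <- do.call(rbind, blocks)
  run_index <- rep(runs, n_vols_per_run)
  if (is.null(nuisance_q)) {
    for (r in runs) {
      col <- paste0("run_", r)
      X <- cbind(X, as.numeric(run_index == r))
      colnames(X)[ncol(X)] <- col
    }
  }
  empty <- task_cols[colSums(abs(X[, task_cols, drop = FALSE])) == 0]
  if (length(empty) > 0)
    message("design matrix: condition(s) absent from the session, ",
            "all-zero column(s) flagged: ", paste(empty, collapse = ", "))
  structure(list(X = X, task_cols = task_cols, empty_cols = empty,
                 run_index = run_index, tr = tr, n_discard = n_discard),
            class = "design_matrix")
}

#' @export
print.design_matrix <- function(x, ...) {
  cat(sprintf("Design matrix: %d timepoints x %d regressors (%d task)\n",
              nrow(x$X), ncol(x$X), length(x$task_cols)))
  if (length(x$empty_cols)) cat("  empty task columns:",
                                paste(x$empty_cols, collapse = ", "), "\n")
  invisible(x)
}

#' Estimate condition response amplitudes by OLS
#'
#' Ordinary least-squares fit of an ROI time course (percent signal
#' change) against the event-related design matrix. Flagged all-zero
#' columns are dropped before fitting; any remaining rank deficiency is an
#' error naming the offending columns.
#'
#' @param y Numeric vector: ROI time course (concatenated runs, percent
#'   signal change).
#' @param design A `design_matrix`.
#' @return A `glm_fit`: list with `coefficients` data frame (`regressor`,
#'   `beta`, `se`), `sigma`, `df_residual`, `dropped` columns.
#' @export
estimate_amplitudes <- function(y, design) {
  stopifnot(inherits(design, "design_matrix"))
  X <- design$X
  if (length(y) != nrow(X))
    stop("time course length (", length(y), ") does not match the design (",
         nrow(X), " timepoints)")
  keep <- setdiff(colnames(X), design$empty_cols)
  X <- X[, keep, drop = FALSE]
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    stop("design matrix is rank deficient; offending column(s): ",
         paste(bad, collapse = ", "))
  }
  beta <- qr.coef(qx, y)
  res <- y - as.numeric(X %*% beta)
  dfr <- length(y) - ncol(X)
  sigma2 <- sum(res^2) / dfr
  xtx_inv <- chol2inv(qr.R(qx))[order(qx$pivot), order(qx$pivot), drop = FALSE]
  se <- sqrt(diag(xtx_inv) * sigma2)
  structure(list(coefficients = data.frame(regressor = colnames(X),
                                           beta = as.numeric(beta),
                                           se = se, row.names = NULL),
                 sigma = sqrt(sigma2), df_residual = dfr,
                 dropped = design$empty_cols),
            class = "glm_fit")
}

#' @export
print.glm_fit <- function(x, ...) {
  cat("Event-related GLM fit (percent signal change):\n")
  print(head(x$coefficients, 12), digits = 3)
  cat(sprintf("  residual SD %.3g on %d df\n", x$sigma, x$df_residual))
  invisible(x)
}

#' Recode hemispheres as contralateral/ipsilateral to the cue
#'
#' A pure relabeling: a left cue makes the right hemisphere contralateral
#' and vice versa. `laterality_to_hemisphere` is the exact inverse; the
#' composition restores the hemisphere labels.
#'
#' @param hemisphere,cue_side Character vectors (`"left"`/`"right"`).
#' @return Character vector (`"contralateral"`/`"ipsilateral"` or
#'   hemisphere labels).
#' @export
hemisphere_to_laterality <- function(hemisphere, cue_side) {
  ifelse(hemisphere != cue_side, "contralateral", "ipsilateral")
}

#' @rdname hemisphere_to_laterality
#' @param laterality `"contralateral"` or `"ipsilateral"`.
#' @export
laterality_to_hemisphere <- function(laterality, cue_side) {
  other <- ifelse(cue_side == "left", "right", "left")
  ifelse(laterality == "contralateral", other, cue_side)
}

#' Assemble the condition-amplitude table for one participant
#'
#' Runs the GLM for every ROI x hemisphere of one session and returns one
#' row per condition beta, recoded contralateral/ipsilateral relative to
#' the cue side.
#'
#' @param runs List of preprocessed `voxel_ts` runs of one session.
#' @param session The `session_design` the runs realize (with responses).
#' @param selection A `voxel_selection` (or `NULL`).
#' @param participant Participant identifier.
#' @param rois ROI labels to analyse.
#' @param correct_only Passed to [build_design_matrix()].
#' @return Data frame: `participant`, `attention_type`, `roi`,
#'   `hemisphere`, `laterality`, `cue_side`, `cue_epoch`, `validity`,
#'   `condition`, `beta_psc`, `se`.
#' @export
condition_amplitudes <- function(runs, session, selection = NULL,
                                 participant = "P1", rois = .rois(),
                                 correct_only = TRUE) {
  stopifnot(inherits(session, "session_design"))
  n_vols <- vapply(runs, function(r) ncol(r$data), integer(1))
  qs <- lapply(runs, `[[`, "nuisance_q")
  if (any(vapply(qs, is.null, TRUE))) qs <- NULL
  nd <- runs[[1]]$n_discarded
  if (is.null(nd)) nd <- runs[[1]]$n_discard
  design <- build_design_matrix(session$trials, tr = session$timing$tr,
                                n_vols_per_run = n_vols,
                                n_discard = nd, correct_only = correct_only,
                                nuisance_q = qs)
  out <- list()
  for (roi in rois) for (hemi in .hemis()) {
    y <- unlist(lapply(runs, average_roi_timecourse, selection = selection,
                       roi = roi, hemisphere = hemi))
    fit <- estimate_amplitudes(y, design)
    co <- fit$coefficients
    stim <- co[grepl("^(pre|post)_", co$regressor), , drop = FALSE]
    parts <- do.call(rbind, strsplit(stim$regressor, "_"))
    out[[length(out) + 1L]] <- data.frame(
      participant = participant, attention_type = session$attention_type,
      roi = roi, hemisphere = hemi,
      laterality = hemisphere_to_laterality(hemi, parts[, 3]),
      cue_side = parts[, 3], cue_epoch = parts[, 1], validity = parts[, 2],
      condition = stim$regressor, beta_psc = stim$beta, se = stim$se,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
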