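#' Fit a sinusoid at the stimulus alternation frequency
#'
#' Least-squares fit of each voxel's time series to
#' \eqn{A\cos(2\pi f t - \phi)} at the block alternation frequency, which
#' for a frequency that is a whole number of cycles per run is exactly the
#' discrete Fourier component. Returns the amplitude, the phase of the
#' best-fit cosine measured from run start and wrapped to [0, 2pi), and
#' the coherence: the spectral amplitude at the stimulus frequency divided
#' by the root-sum-square of amplitudes over all non-DC frequencies (the
#' traveling-wave convention; 1 for a pure single-frequency signal).
#'
#' @param ts A `voxel_ts` object or a voxel x time numeric matrix (a bare
#'   vector is treated as one voxel).
#' @param stimulus_frequency Stimulus alternation frequency in Hz; must be
#'   an integer number of cycles over the run.
#' @param tr Repetition time in seconds (taken from `ts` when it is a
#'   `voxel_ts`).
#' @param detrend Remove a per-voxel linear trend (in addition to the
#'   mean) before fitting. Off by default: preprocessing normally handles
#'   trends.
#' @param reference_phase Cosine-phase of the stimulus fundamental at run
#'   start, subtracted from the fitted phase so that the reported phase is
#'   the response lag behind the stimulus. `0` (default) reports the raw
#'   best-fit cosine phase; for a block protocol whose on-block starts at
#'   t = 0 the fundamental is sine-like, so pass `pi / 2` — the
#'   hemodynamic delay then places stimulus-driven responses in (0, pi).
#' @return Data frame with one row per voxel: `voxel`, `amplitude`,
#'   `phase`, `coherence`.
#' @export
fit_sinusoid <- function(ts, stimulus_frequency, tr = NULL, detrend = FALSE,
                         reference_phase = 0) {
  if (inherits(ts, "voxel_ts")) {
    if (is.null(tr)) tr <- ts$tr
    x <- ts$data
  } else x <- ts
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (is.null(tr)) stop("'tr' is required when 'ts' is a bare matrix")
  n <- ncol(x)
  k <- stimulus_frequency * n * tr   # cycles per run
  if (abs(k - round(k)) > 1e-8)
    stop("stimulus_frequency (", stimulus_frequency, " Hz) is not a whole ",
         "number of cycles over the ", n * tr, " s run")
  k <- as.integer(round(k))
  if (k < 1 || k > floor(n / 2))
    stop("stimulus frequency not resolvable by a series of length ", n)

  x <- sweep(x, 1, rowMeans(x))
  if (detrend) {
    tt <- seq_len(n) - (n + 1) / 2
    slope <- (x %*% tt) / sum(tt^2)
    x <- x - outer(as.numeric(slope), tt)
  }
  ff <- t(stats::mvfft(t(x)))            # voxel x frequency bins
  half <- 2:(floor(n / 2) + 1L)          # non-DC bins up to Nyquist
  mods <- Mod(ff[, half, drop = FALSE])
  amplitude <- 2 * mods[, k] / n
  denom <- sqrt(rowSums(mods^2))
  coherence <- ifelse(denom > 0, mods[, k] / denom, 0)
  phase <- (-Arg(ff[, k + 1L]) - reference_phase) %% (2 * pi)
  data.frame(voxel = seq_len(nrow(x)), amplitude = amplitude,
             phase = phase, coherence = coherence)
}

#' Select stimulus-responsive voxels from localizer fits
#'
#' Restricts each ROI to voxels whose best-fit sinusoid has phase inside
#' `phase_window` (default the open interval (0, pi): responses whose
#' hemodynamic delay places them in the stimulus-on half cycle) and
#' coherence strictly greater than `coherence_min` (default 0.2). Both
#' thresholds are strict inequalities.
#'
#' @param fits Data frame from [fit_sinusoid()], computed on the
#'   across-run average localizer series.
#' @param voxel_meta Voxel metadata (`voxel`, `roi`, `hemisphere`) as from
#'   [voxel_grid()]; optional — without it no per-ROI report is produced.
#' @param phase_window Open interval of acceptable phases, radians.
#' @param coherence_min Minimum coherence (strict).
#' @return A `voxel_selection`: list with `fits` (fit columns plus
#'   `selected`), `thresholds`, and `roi_report` (per ROI/hemisphere:
#'   total, selected and median coherence), or `NULL` report if no
#'   metadata. ROIs with an empty selection are reported with a warning
#'   naming the ROI (analysis proceeds).
#' @export
select_voxels <- function(fits, voxel_meta = NULL,
                          phase_window = c(0, pi), coherence_min = 0.2) {
  stopifnot(all(c("phase", "coherence") %in% names(fits)),
            length(phase_window) == 2, phase_window[1] < phase_window[2])
  fits$selected <- fits$phase > phase_window[1] &
    fits$phase < phase_window[2] &
    fits$coherence > coherence_min
  roi_report <- NULL
  if (!is.null(voxel_meta)) {
    m <- merge(fits, voxel_meta, by = "voxel")
    m <- m[m$roi != "background", , drop = FALSE]
    roi_report <- do.call(rbind, lapply(
      split(m, list(m$roi, m$hemisphere), drop = TRUE), function(g) {
        data.frame(roi = g$roi[1], hemisphere = g$hemisphere[1],
                   n_voxels_total = nrow(g), n_selected = sum(g$selected),
                   median_coherence = median(g$coherence),
                   stringsAsFactors = FALSE)
      }))
    rownames(roi_report) <- NULL
    empty <- roi_report[roi_report$n_selected == 0, , drop = FALSE]
    if (nrow(empty) > 0)
      warning("no voxels selected for: ",
              paste(empty$roi, empty$hemisphere, collapse = ", "),
              " (falling back to all ROI voxels downstream)")
  }
  structure(list(fits = fits,
                 thresholds = list(phase_window = phase_window,
                                   coherence_min = coherence_min),
                 roi_report = roi_report),
            class = "voxel_selection")
}

#' @export
print.voxel_selection <- function(x, ...) {
  cat(sprintf("Voxel selection: %d / %d voxels (coherence > %g, phase in (%g, %g))\n",
              sum(x$fits$selected), nrow(x$fits), x$thresholds$coherence_min,
              x$thresholds$phase_window[1], x$thresholds$phase_window[2]))
  if (!is.null(x$roi_report)) print(x$roi_report, digits = 3)
  invisible(x)
}

#' Write the per-ROI selection report as CSV
#'
#' @param selection A `voxel_selection`.
#' @param path Output CSV path.
#' @export
write_selection_report <- function(selection, path) {
  stopifnot(inherits(selection, "voxel_selection"))
  if (is.null(selection$roi_report))
    stop("selection has no ROI report (no voxel metadata was supplied)")
  write.csv(selection$roi_report, path, row.names = FALSE)
  invisible(path)
}
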