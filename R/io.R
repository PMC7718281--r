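#' Write / read a BOLD run as 4-D NIfTI
#'
#' Voxels are laid out along the first spatial axis (the synthetic grid
#' has no spatial structure); the repetition time is stored in the fourth
#' pixdim slot. Voxel metadata travels in the ROI atlas (see
#' [write_roi_atlas()]), not the 4-D file.
#'
#' @param ts A `voxel_ts`.
#' @param path Output `.nii` path.
#' @return Invisibly, `path`.
#' @export
write_bold_nifti <- function(ts, path) {
  stopifnot(inherits(ts, "voxel_ts"))
  arr <- array(ts$data, dim = c(nrow(ts$data), 1L, 1L, ncol(ts$data)))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(1, 1, 1, ts$tr)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_bold_nifti
#' @param voxel_meta Voxel metadata data frame to attach (e.g. from
#'   [read_roi_atlas()]).
#' @param n_discard Leading-volume count to flag on the returned object.
#' @export
read_bold_nifti <- function(path, voxel_meta = NULL, n_discard = 8L) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  tr <- RNifti::pixdim(img)[4]
  data <- matrix(img, nrow = prod(d[1:3]), ncol = d[4])
  structure(list(data = data, tr = tr, run_id = basename(path),
                 n_discard = as.integer(n_discard), voxel_meta = voxel_meta,
                 run_duration_s = d[4] * tr),
            class = "voxel_ts")
}

#' Write / read the integer ROI-label atlas
#'
#' Labels encode ROI and hemisphere: `rank` for left-hemisphere,
#' `rank + n_rois` for right-hemisphere voxels, 0 for background.
#'
#' @param voxel_meta Voxel metadata from [voxel_grid()].
#' @param path Output `.nii` path.
#' @param rois Named integer vector of hierarchy ranks.
#' @export
write_roi_atlas <- function(voxel_meta, path, rois = roi_hierarchy) {
  lab <- integer(nrow(voxel_meta))
  known <- voxel_meta$roi %in% names(rois)
  lab[known] <- rois[voxel_meta$roi[known]] +
    length(rois) * (voxel_meta$hemisphere[known] == "right")
  img <- RNifti::asNifti(array(lab, dim = c(length(lab), 1L, 1L)))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_roi_atlas
#' @export
read_roi_atlas <- function(path, rois = roi_hierarchy) {
  img <- RNifti::readNifti(path)
  lab <- as.integer(img)
  n <- length(rois)
  roi <- rep("background", length(lab))
  hemi <- rep("none", length(lab))
  nz <- lab > 0
  hemi[nz] <- ifelse(lab[nz] > n, "right", "left")
  idx <- ifelse(lab[nz] > n, lab[nz] - n, lab[nz])
  roi[nz] <- names(rois)[idx]
  data.frame(voxel = seq_along(lab), roi = roi, hemisphere = hemi,
             stringsAsFactors = FALSE)
}

#' Write a selection mask as NIfTI
#'
#' @param selection A `voxel_selection`.
#' @param path Output `.nii` path.
#' @export
write_selection_nifti <- function(selection, path) {
  stopifnot(inherits(selection, "voxel_selection"))
  m <- as.integer(selection$fits$selected)
  img <- RNifti::asNifti(array(m, dim = c(length(m), 1L, 1L)))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Import an externally supplied condition-amplitude table
#'
#' Reads a CSV with one row per participant/ROI/condition cell (such as a
#' study's deposited per-condition amplitude data), renames columns via
#' `column_mapping`, recodes hemisphere labels to contralateral/
#' ipsilateral via the cue-side rule when needed, and validates
#' completeness: every participant x ROI x attention type x cue epoch x
#' validity x laterality cell must be present.
#'
#' @param path CSV path (lines starting with `#` are ignored).
#' @param column_mapping Named character vector mapping target column
#'   names (names) to source column names (values), e.g.
#'   `c(beta_psc = "amplitude")`.
#' @param rois ROI labels that must all be present.
#' @return Validated amplitude table (same layout as
#'   [condition_amplitudes()]).
#' @export
import_amplitude_table <- function(path, column_mapping = NULL,
                                   rois = .rois()) {
  df <- read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  if (!is.null(column_mapping)) {
    for (target in names(column_mapping)) {
      src <- column_mapping[[target]]
      if (!src %in% names(df))
        stop("mapped source column '", src, "' not found in ", path)
      names(df)[names(df) == src] <- target
    }
  }
  need <- c("participant", "roi", "attention_type", "cue_epoch", "validity",
            "beta_psc")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0)
    stop("amplitude table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  if (!"laterality" %in% names(df)) {
    if (!all(c("hemisphere", "cue_side") %in% names(df)))
      stop("need either a 'laterality' column or both 'hemisphere' and ",
           "'cue_side' to recode laterality")
    df$laterality <- hemisphere_to_laterality(df$hemisphere, df$cue_side)
  }
  missing_rois <- setdiff(rois, unique(df$roi))
  if (length(missing_rois) > 0)
    stop("amplitude table is missing ROI(s): ",
         paste(missing_rois, collapse = ", "))
  cells <- expand.grid(participant = unique(df$participant), roi = rois,
                       attention_type = unique(df$attention_type),
                       cue_epoch = c("pre", "post"),
                       validity = c("valid", "invalid"),
                       laterality = c("contralateral", "ipsilateral"),
                       stringsAsFactors = FALSE)
  key <- function(d) do.call(paste, d[, names(cells)])
  absent <- !(key(cells) %in% key(df))
  if (any(absent))
    stop("amplitude table is missing ", sum(absent), " cell(s), e.g.: ",
         paste(utils::head(key(cells)[absent], 3), collapse = "; "))
  df
}

# md5 of an R object via its serialization (for provenance records)
config_hash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}
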