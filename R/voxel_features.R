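#' Detect the first contrast-enhanced frame
#'
#' Scans frames in order; frame `i` qualifies when the mean in-mask signal
#' exceeds the mean of all earlier (baseline) frames by more than twice the
#' baseline SD of those frame means. The first qualifying frame is returned.
#'
#' @param dce 4-D DCE series.
#' @param mask binary breast mask.
#' @param min_baseline smallest number of baseline frames (default 2).
#' @return 1-based frame index.
#' @export
detect_enhancement_start <- function(dce, mask, min_baseline = 2L) {
  n <- dim(dce)[4]
  inb <- which(mask > 0)
  means <- vapply(seq_len(n), function(i) mean(frame_of(dce, i)[inb]), numeric(1))
  for (i in (min_baseline + 1L):n) {
    base <- means[seq_len(i - 1L)]
    if (means[i] > mean(base) + 2 * sd(base)) return(i)
  }
  stop("no frame exceeds the baseline enhancement criterion", call. = FALSE)
}

voxel_feature_names <- function() {
  c(sprintf("dce_%02d", 1:26), sprintf("ddce_%02d", 1:25), "nsumdce",
    "mri_pre", "mri_peak", "mri_post",
    "dmri_post_pre", "dmri_peak_pre", "dmri_post_peak",
    "dwi_b0", "dwi_b850", "adc", "pet")
}

voxel_feature_groups <- function() {
  setNames(c(rep("DCE", 26), rep("dDCE", 25), "DCE",
             rep("MRI", 3), rep("dMRI", 3), rep("DWI", 3), "PET"),
           voxel_feature_names())
}

#' Per-voxel 62-feature matrix for segmentation
#'
#' For every voxel inside the breast mask: 26 consecutive DCE frame
#' intensities from the enhancement-onset frame `j`; 25 time-normalised
#' two-frame forward differences `(I(x, i+2) - I(x, i)) / (t_{i+2} - t_i)`
#' for `i = j..j+24` (the window start is moved back when the series ends one
#' frame early); the summed 26-frame enhancement normalised by its in-mask
#' maximum; the three high-resolution intensities and their three pairwise
#' differences; DWI b0/b850 and ADC; and PET. The DCE frame and high-res
#' intensity features use the standardised volumes; the normalised sum is
#' computed on the raw (positive) signal so it stays in [0, 1] with in-mask
#' maximum exactly 1; DWI and PET are consumed raw.
#'
#' @param study an [mp_study()] with raw intensities; standardisation is
#'   applied internally.
#' @return A data.frame of class `voxel_features`: columns `x`, `y`, `z`,
#'   `voxel` (linear index) and the 62 named features, one row per in-mask
#'   voxel; attribute `groups` maps feature names to modality groups.
#' @export
voxel_feature_matrix <- function(study) {
  raw_dce <- study$dce
  study <- standardise_study(study)
  j <- study$enhancement_onset
  n <- dim(study$dce)[4]
  if (j + 25L > n)
    stop(sprintf("DCE series too short: need %d frames for a 26-frame window from %d",
                 j + 25L, j), call. = FALSE)
  inb <- which(study$breast_mask > 0)
  coord <- arrayInd(inb, dim(study$breast_mask))
  nvox3 <- prod(dim(study$breast_mask))
  dcem <- matrix(study$dce, nrow = nvox3, ncol = n)[inb, , drop = FALSE]

  f_dce <- dcem[, j:(j + 25L), drop = FALSE]
  # delta window: i = j..j+24 needs frame j+26; shift back if one frame short
  istart <- if (j + 26L <= n) j else j - 1L
  if (istart < 1L) stop("DCE series too short for the 25 forward differences",
                        call. = FALSE)
  ii <- istart:(istart + 24L)
  dt <- study$times[ii + 2L] - study$times[ii]
  f_ddce <- sweep(dcem[, ii + 2L, drop = FALSE] - dcem[, ii, drop = FALSE],
                  2L, dt, "/")
  raw_m <- matrix(raw_dce, nrow = nvox3, ncol = n)[inb, , drop = FALSE]
  sumdce <- pmax(rowSums(raw_m[, j:(j + 25L), drop = FALSE]), 0)
  f_nsumdce <- sumdce / max(sumdce)

  fm <- cbind(f_dce, f_ddce, f_nsumdce,
              study$dce_pre[inb], study$dce_peak[inb], study$dce_post[inb],
              study$dce_post[inb] - study$dce_pre[inb],
              study$dce_peak[inb] - study$dce_pre[inb],
              study$dce_post[inb] - study$dce_peak[inb],
              study$dwi_b0[inb], study$dwi_b850[inb], study$adc[inb],
              study$pet[inb])
  colnames(fm) <- voxel_feature_names()
  out <- data.frame(x = coord[, 1], y = coord[, 2], z = coord[, 3],
                    voxel = inb, fm, check.names = FALSE)
  attr(out, "groups") <- voxel_feature_groups()
  class(out) <- c("voxel_features", class(out))
  out
}

#' Drop modality feature groups from a voxel feature matrix
#'
#' @param features a `voxel_features` data.frame.
#' @param drop subset of `c("DWI", "PET")`.
#' @return The matrix without the dropped modality columns.
#' @export
feature_subset <- function(features, drop = character(0)) {
  if (length(drop) == 0L) return(features)
  bad <- setdiff(drop, c("DWI", "PET"))
  if (length(bad)) stop("unknown modality: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  groups <- attr(features, "groups")
  rm_cols <- names(groups)[groups %in% drop]
  out <- features[, !(names(features) %in% rm_cols), drop = FALSE]
  attr(out, "groups") <- groups[setdiff(names(groups), rm_cols)]
  class(out) <- class(features)
  out
}

# Feature column names of a voxel_features table (excludes coordinates).
feature_columns <- function(features) {
  setdiff(names(features), c("x", "y", "z", "voxel"))
}
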