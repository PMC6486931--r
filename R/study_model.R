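#' A co-registered multiparametric study
#'
#' Container for one patient's volumes, all on a single voxel grid (the
#' co-registration contract): the DCE-MRI 4-D series with per-frame
#' acquisition times, the high-resolution pre/peak/post contrast volumes,
#' DWI b0/b850 and the ADC map, FDG-PET, the breast mask, and the lesion
#' annotation (label volume) with per-lesion benign/malignant labels.
#'
#' @param dce 4-D array (x, y, z, frame).
#' @param times per-frame acquisition times in seconds, strictly increasing.
#' @param dce_pre,dce_peak,dce_post,dwi_b0,dwi_b850,adc,pet 3-D arrays.
#' @param breast_mask binary 3-D array.
#' @param annotation integer label 3-D array (0 = background); must lie inside
#'   the breast mask.
#' @param lesion_labels named character vector, `"benign"`/`"malignant"` per
#'   lesion id.
#' @param enhancement_onset 1-based index of the first contrast-enhanced
#'   frame; a 26-frame window from it must exist.
#' @param voxel_size length-3 voxel spacing in mm.
#' @param patient_id character identifier.
#' @return An `mp_study` list.
#' @export
mp_study <- function(dce, times, dce_pre, dce_peak, dce_post,
                     dwi_b0, dwi_b850, adc, pet, breast_mask, annotation,
                     lesion_labels, enhancement_onset, voxel_size = c(1, 1, 1),
                     patient_id = "unknown") {
  study <- structure(list(dce = dce, times = times, dce_pre = dce_pre,
                          dce_peak = dce_peak, dce_post = dce_post,
                          dwi_b0 = dwi_b0, dwi_b850 = dwi_b850, adc = adc,
                          pet = pet, breast_mask = breast_mask,
                          annotation = annotation, lesion_labels = lesion_labels,
                          enhancement_onset = as.integer(enhancement_onset),
                          voxel_size = voxel_size, patient_id = patient_id),
                     class = "mp_study")
  validate_mp_study(study)
}

study_volume_roles <- c("dce_pre", "dce_peak", "dce_post", "dwi_b0", "dwi_b850",
                        "adc", "pet", "breast_mask", "annotation")

validate_mp_study <- function(study) {
  if (length(dim(study$dce)) != 4L)
    stop("dce must be a 4-D array (x, y, z, frame)", call. = FALSE)
  ref <- dim(study$dce)[1:3]
  for (role in study_volume_roles) {
    v <- study[[role]]
    if (is.null(v)) stop(sprintf("missing volume '%s'", role), call. = FALSE)
    if (!identical(dim(v), as.integer(ref)) && !identical(dim(v), ref))
      stop(sprintf("volume '%s' is not on the reference grid (%s vs %s)", role,
                   paste(dim(v), collapse = "x"), paste(ref, collapse = "x")),
           call. = FALSE)
  }
  n_frames <- dim(study$dce)[4]
  if (length(study$times) != n_frames)
    stop("times must have one entry per DCE frame", call. = FALSE)
  if (any(diff(study$times) <= 0))
    stop("acquisition times must be strictly increasing", call. = FALSE)
  j <- study$enhancement_onset
  if (is.na(j) || j < 1L || j + 25L > n_frames)
    stop(sprintf("enhancement onset %d leaves no 26-frame window in %d frames",
                 j, n_frames), call. = FALSE)
  if (any(study$annotation > 0 & study$breast_mask == 0))
    stop("annotation must lie inside the breast mask", call. = FALSE)
  ids <- sort(unique(study$annotation[study$annotation > 0]))
  if (length(ids) && !all(as.character(ids) %in% names(study$lesion_labels)))
    stop("every annotated lesion id needs a class label", call. = FALSE)
  study
}

#' @export
print.mp_study <- function(x, ...) {
  d <- dim(x$dce)
  cat(sprintf("mp_study '%s': grid %dx%dx%d, %d DCE frames (onset %d)\n",
              x$patient_id, d[1], d[2], d[3], d[4], x$enhancement_onset))
  n_les <- length(unique(x$annotation[x$annotation > 0]))
  cat(sprintf("  %d lesion(s); breast mask %d voxels\n", n_les, sum(x$breast_mask)))
  invisible(x)
}

#' Write a study as NIfTI volumes plus a JSON manifest
#'
#' @param study an [mp_study()].
#' @param dir output directory (created if needed); one `.nii.gz` per volume
#'   role, DCE as a 4-D NIfTI, and `manifest.json` holding times, onset,
#'   lesion labels and voxel size.
#' @return The manifest path, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pd <- study$voxel_size
  paths <- list()
  write_vol <- function(arr, role) {
    p <- file.path(dir, paste0(role, ".nii.gz"))
    img <- RNifti::asNifti(arr, pixdim = if (length(dim(arr)) == 4L)
      c(pd, diff(study$times[1:2])) else pd)
    RNifti::writeNifti(img, p)
    paths[[role]] <<- basename(p)
  }
  write_vol(study$dce, "dce")
  for (role in study_volume_roles) write_vol(study[[role]], role)
  manifest <- list(patient_id = study$patient_id, times = study$times,
                   enhancement_onset = study$enhancement_onset,
                   voxel_size = study$voxel_size,
                   lesion_labels = as.list(study$lesion_labels),
                   volumes = paths)
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(mp)
}

#' Read a study written by [write_study()]
#'
#' @param dir directory containing `manifest.json` and the NIfTI volumes.
#' @return A validated [mp_study()]. Missing files or mismatched grids raise
#'   errors naming the offending volume.
#' @export
read_study <- function(dir) {
  mp <- file.path(dir, "manifest.json")
  if (!file.exists(mp)) stop("manifest.json not found in ", dir, call. = FALSE)
  man <- jsonlite::read_json(mp, simplifyVector = TRUE)
  vols <- man$volumes
  need <- c("dce", study_volume_roles)
  missing <- setdiff(need, names(vols))
  if (length(missing))
    stop("manifest is missing volume(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  read_vol <- function(role) {
    p <- file.path(dir, vols[[role]])
    if (!file.exists(p)) stop(sprintf("volume file for '%s' not found: %s", role, p),
                              call. = FALSE)
    arr <- as.array(RNifti::readNifti(p))
    attributes(arr) <- list(dim = dim(arr))
    arr
  }
  dce <- read_vol("dce")
  args <- lapply(study_volume_roles, read_vol)
  names(args) <- study_volume_roles
  args$annotation <- array(as.integer(round(args$annotation)), dim(args$annotation))
  args$breast_mask <- array(as.integer(round(args$breast_mask)), dim(args$breast_mask))
  labels <- unlist(man$lesion_labels)
  do.call(mp_study, c(list(dce = dce, times = as.numeric(man$times)), args,
                      list(lesion_labels = labels,
                           enhancement_onset = man$enhancement_onset,
                           voxel_size = as.numeric(man$voxel_size),
                           patient_id = man$patient_id)))
}

#' Resample a volume onto a reference grid
#'
#' Maps reference voxel centres into the source grid's physical space (axis-
#' aligned grids: spacing plus origin) and interpolates. Linear interpolation
#' reproduces constants exactly; points outside the source grid take the
#' nearest edge value.
#'
#' @param volume 3-D array.
#' @param spacing,origin source voxel spacing (mm) and origin of voxel
#'   (1,1,1)'s centre.
#' @param ref_dim,ref_spacing,ref_origin reference grid specification.
#' @param order `"linear"` (trilinear) or `"nearest"`.
#' @return 3-D array of shape `ref_dim`.
#' @export
resample_to_reference <- function(volume, spacing, ref_dim, ref_spacing,
                                  origin = c(0, 0, 0), ref_origin = c(0, 0, 0),
                                  order = c("linear", "nearest")) {
  order <- match.arg(order)
  if (any(spacing <= 0) || any(ref_spacing <= 0))
    stop("spacings must be positive (non-singular grid transform)", call. = FALSE)
  d <- dim(volume)
  # continuous source index (1-based) of each reference voxel centre, per axis
  ax_idx <- lapply(1:3, function(a) {
    phys <- ref_origin[a] + (seq_len(ref_dim[a]) - 1) * ref_spacing[a]
    (phys - origin[a]) / spacing[a] + 1
  })
  cx <- rep(ax_idx[[1]], times = ref_dim[2] * ref_dim[3])
  cy <- rep(rep(ax_idx[[2]], each = ref_dim[1]), times = ref_dim[3])
  cz <- rep(ax_idx[[3]], each = ref_dim[1] * ref_dim[2])
  clamp <- function(v, n) pmin(pmax(v, 1), n)
  if (order == "nearest") {
    ix <- clamp(round(cx), d[1]); iy <- clamp(round(cy), d[2]); iz <- clamp(round(cz), d[3])
    out <- volume[cbind(ix, iy, iz)]
  } else {
    x0 <- clamp(floor(cx), d[1]); y0 <- clamp(floor(cy), d[2]); z0 <- clamp(floor(cz), d[3])
    x1 <- clamp(x0 + 1, d[1]); y1 <- clamp(y0 + 1, d[2]); z1 <- clamp(z0 + 1, d[3])
    fx <- clamp(cx, d[1]) - x0; fy <- clamp(cy, d[2]) - y0; fz <- clamp(cz, d[3]) - z0
    v <- function(i, j, k) volume[cbind(i, j, k)]
    out <- (1 - fx) * (1 - fy) * (1 - fz) * v(x0, y0, z0) +
      fx * (1 - fy) * (1 - fz) * v(x1, y0, z0) +
      (1 - fx) * fy * (1 - fz) * v(x0, y1, z0) +
      fx * fy * (1 - fz) * v(x1, y1, z0) +
      (1 - fx) * (1 - fy) * fz * v(x0, y0, z1) +
      fx * (1 - fy) * fz * v(x1, y0, z1) +
      (1 - fx) * fy * fz * v(x0, y1, z1) +
      fx * fy * fz * v(x1, y1, z1)
  }
  array(out, ref_dim)
}

#' Segment the breast by intensity-based region growing
#'
#' Thresholds the pre-contrast volume (Otsu's criterion on its intensity
#' histogram), seeds at the largest above-threshold 6-connected component and
#' grows it; the result is a single connected region excluding background air.
#'
#' @param pre 3-D pre-contrast volume.
#' @return A binary 3-D array of class `breast_mask`.
#' @export
grow_breast_mask <- function(pre) {
  if (any(!is.finite(pre))) stop("pre-contrast volume must be finite", call. = FALSE)
  thr <- otsu_threshold(pre)
  fg <- array(as.integer(pre > thr), dim(pre))
  if (sum(fg) == 0L)
    stop("no above-threshold voxels; supply a manual breast mask", call. = FALSE)
  lab <- label_components_6(fg)
  mask <- array(as.integer(lab == 1L), dim(pre))
  structure(mask, class = c("breast_mask", class(mask)))
}

# Otsu's threshold on a 256-bin histogram.
otsu_threshold <- function(x) {
  r <- range(x)
  if (diff(r) == 0) return(r[1])
  h <- graphics::hist(as.numeric(x), breaks = seq(r[1], r[2], length.out = 257),
                      plot = FALSE)
  p <- h$counts / sum(h$counts)
  mids <- h$mids
  w0 <- cumsum(p); mu <- cumsum(p * mids); mu_t <- mu[length(mu)]
  w1 <- 1 - w0
  between <- (mu_t * w0 - mu)^2 / (w0 * w1)
  between[!is.finite(between)] <- 0
  mids[which.max(between)]
}

#' Standardise a volume to zero mean, unit SD over a mask
#'
#' The affine map `(x - m) / s`, with `m`, `s` estimated from the in-mask
#' voxels, is applied to the whole volume, so out-of-mask intensities stay on
#' the same scale as in-mask ones.
#'
#' @param volume 3-D array.
#' @param mask binary 3-D array with at least two voxels and nonzero variance.
#' @return The standardised volume.
#' @export
standardise <- function(volume, mask) {
  inb <- volume[mask > 0]
  if (length(inb) < 2L) stop("mask must contain at least 2 voxels", call. = FALSE)
  s <- sd(inb)
  if (s == 0) stop("zero variance inside mask", call. = FALSE)
  (volume - mean(inb)) / s
}

#' Standardise all MRI volumes of a study
#'
#' Per-volume statistics for the pre/peak/post high-resolution volumes; for
#' the 4-D DCE series the statistics come from the pre-contrast frames only
#' (frames before `enhancement_onset`) and one affine map is applied to every
#' frame, preserving inter-frame contrast. DWI and PET are left raw.
#'
#' @param study an [mp_study()].
#' @return The study with standardised `dce`, `dce_pre`, `dce_peak`, `dce_post`.
#' @export
standardise_study <- function(study) {
  m <- study$breast_mask
  for (f in c("dce_pre", "dce_peak", "dce_post"))
    study[[f]] <- standardise(study[[f]], m)
  j <- study$enhancement_onset
  pre_frames <- seq_len(max(j - 1L, 1L))
  vals <- unlist(lapply(pre_frames, function(i) frame_of(study$dce, i)[m > 0]))
  s <- sd(vals)
  if (s == 0) stop("zero variance in pre-contrast DCE frames", call. = FALSE)
  study$dce <- (study$dce - mean(vals)) / s
  study
}
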