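#' Segmentation configuration
#'
#' @param n_per_class training voxels sampled per class per patient.
#' @param ntree random-forest size.
#' @param theta_grid probability thresholds scanned when maximising training
#'   DSC (ties broken toward the smallest threshold).
#' @param drop modality groups to exclude (`"DWI"`, `"PET"`).
#' @param seed integer seed for sampling and forest growth.
#' @return A `seg_config` list.
#' @export
seg_config <- function(n_per_class = 1000L, ntree = 100L,
                       theta_grid = seq(0, 1, by = 0.01),
                       drop = character(0), seed = 1L) {
  structure(list(n_per_class = as.integer(n_per_class), ntree = as.integer(ntree),
                 theta_grid = theta_grid, drop = drop, seed = as.integer(seed)),
            class = "seg_config")
}

as_study_list <- function(cohort) {
  lapply(cohort, function(e) if (inherits(e, "mp_study")) e else e$study)
}

#' Sample training voxels per class
#'
#' Draws up to `n_per_class` lesion and `n_per_class` background row indices
#' from a voxel feature table, without replacement, reproducibly under `seed`.
#'
#' @param features a `voxel_features` table.
#' @param annotation the study's lesion label volume.
#' @param n_per_class samples per class (default 1000).
#' @param seed integer seed.
#' @return List with integer row-index vectors `lesion` and `background`.
#' @export
sample_training_voxels <- function(features, annotation, n_per_class = 1000L,
                                   seed = 1L) {
  is_lesion <- annotation[features$voxel] > 0
  les <- which(is_lesion); bg <- which(!is_lesion)
  if (length(les) == 0L) stop("study has no lesion voxels in the mask", call. = FALSE)
  if (length(bg) == 0L) stop("study has no background voxels in the mask", call. = FALSE)
  with_seed(seed, {
    list(lesion = sort(sample(les, min(n_per_class, length(les)))),
         background = sort(sample(bg, min(n_per_class, length(bg)))))
  })
}

#' Train the voxel-wise random-forest segmenter
#'
#' Fits a random forest on pooled sampled voxels (up to 1000 per class per
#' patient) and selects the probability threshold that maximises the mean
#' training-set DSC over a grid, ties broken toward the smallest threshold.
#'
#' @param cohort list of [mp_study()] objects (or `$study`/`$truth` pairs).
#' @param config a [seg_config()].
#' @param features_list optional precomputed `voxel_features` tables (one per
#'   study) to avoid recomputation across cross-validation folds.
#' @return A `seg_model` list: `forest`, `theta`, `features` (column names),
#'   `manifest`.
#' @export
train_segmenter <- function(cohort, config = seg_config(), features_list = NULL) {
  studies <- as_study_list(cohort)
  if (length(studies) < 1L) stop("need at least one training study", call. = FALSE)
  if (length(studies) == 1L)
    warning("training on a single study; threshold selection may overfit")
  if (is.null(features_list))
    features_list <- lapply(studies, voxel_feature_matrix)
  features_list <- lapply(features_list, feature_subset, drop = config$drop)
  cols <- feature_columns(features_list[[1L]])

  xs <- list(); ys <- list()
  for (i in seq_along(studies)) {
    idx <- sample_training_voxels(features_list[[i]], studies[[i]]$annotation,
                                  config$n_per_class,
                                  seed = child_seed(config$seed, i))
    fm <- features_list[[i]]
    xs[[i]] <- as.matrix(fm[c(idx$lesion, idx$background), cols, drop = FALSE])
    ys[[i]] <- rep(c("lesion", "background"),
                   c(length(idx$lesion), length(idx$background)))
  }
  x <- do.call(rbind, xs)
  y <- factor(unlist(ys), levels = c("background", "lesion"))
  if (length(unique(y)) < 2L) stop("degenerate labels: both classes required",
                                   call. = FALSE)
  forest <- with_seed(child_seed(config$seed, 0L),
                      randomForest::randomForest(x = x, y = y, ntree = config$ntree))

  # threshold maximising mean training DSC (raw thresholded masks)
  dsc_by_theta <- rep(0, length(config$theta_grid))
  for (i in seq_along(studies)) {
    prob <- predict(forest, as.matrix(features_list[[i]][, cols, drop = FALSE]),
                    type = "prob")[, "lesion"]
    truth <- studies[[i]]$annotation[features_list[[i]]$voxel] > 0
    nt <- sum(truth)
    for (ti in seq_along(config$theta_grid)) {
      pred <- prob >= config$theta_grid[ti]
      dsc_by_theta[ti] <- dsc_by_theta[ti] +
        if (nt + sum(pred) == 0) 0 else 2 * sum(pred & truth) / (nt + sum(pred))
    }
  }
  theta <- config$theta_grid[which.max(dsc_by_theta)]  # first max = smallest theta
  structure(list(forest = forest, theta = theta, features = cols,
                 manifest = list(n_studies = length(studies),
                                 n_per_class = config$n_per_class,
                                 ntree = config$ntree, seed = config$seed,
                                 drop = config$drop)),
            class = "seg_model")
}

#' @export
print.seg_model <- function(x, ...) {
  cat(sprintf("Voxel segmenter: %d trees, %d features, theta = %.2f (trained on %d studies)\n",
              x$manifest$ntree, length(x$features), x$theta, x$manifest$n_studies))
  invisible(x)
}

#' Predict a lesion probability map and segmentation for a study
#'
#' @param model a `seg_model`.
#' @param study an [mp_study()].
#' @param features optional precomputed `voxel_features` table for the study.
#' @return A `seg_result` list: `prob` (3-D map, 0 outside the breast mask),
#'   `mask` (binary, `prob >= theta` within the breast mask), `theta`.
#' @export
predict_segmentation <- function(model, study, features = NULL) {
  if (is.null(features)) features <- voxel_feature_matrix(study)
  missing <- setdiff(model$features, names(features))
  if (length(missing))
    stop("study features are missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  prob_in <- predict(model$forest,
                     as.matrix(features[, model$features, drop = FALSE]),
                     type = "prob")[, "lesion"]
  prob <- array(0, dim(study$breast_mask))
  prob[features$voxel] <- prob_in
  mask <- array(as.integer(prob >= model$theta & study$breast_mask > 0),
                dim(prob))
  structure(list(prob = prob, mask = mask, theta = model$theta), class = "seg_result")
}

#' Post-process a binary segmentation into labelled blobs
#'
#' Labels 6-connected components. In evaluation mode (an annotation is given)
#' components with zero overlap with the annotation are removed, mimicking a
#' radiologist selecting the suspicious region; without an annotation all
#' components are kept.
#'
#' @param mask binary 3-D array.
#' @param annotation optional label volume.
#' @return Integer label array of surviving blobs (relabelled 1..k).
#' @export
postprocess_blobs <- function(mask, annotation = NULL) {
  lab <- label_components_6(mask)
  if (is.null(annotation) || max(lab) == 0L) return(lab)
  keep <- sort(unique(lab[lab > 0 & annotation > 0]))
  out <- array(0L, dim(lab))
  for (i in seq_along(keep)) out[lab == keep[i]] <- i
  out
}

#' Dice similarity coefficient
#'
#' `2|A∩B| / (|A|+|B|)`; defined as 0 when both masks are empty.
#'
#' @param a,b binary arrays of identical shape.
#' @return DSC in [0, 1].
#' @export
dice <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("masks must share a shape", call. = FALSE)
  sa <- sum(a > 0); sb <- sum(b > 0)
  if (sa + sb == 0) return(0)
  2 * sum(a > 0 & b > 0) / (sa + sb)
}

# Voxel-level true-positive rate of pred against truth.
voxel_sensitivity <- function(pred, truth) {
  nt <- sum(truth > 0)
  if (nt == 0) return(NA_real_)
  sum(pred > 0 & truth > 0) / nt
}

#' Leave-one-out cross-validated segmentation evaluation
#'
#' Each study is held out once; the segmenter (including its DSC-maximising
#' threshold) is trained on the rest and applied to the held-out study.
#' Predicted masks are post-processed (6-connected components, annotation-
#' overlap filter). DSC is reported per lesion (blobs overlapping that lesion
#' against the lesion mask) and per patient; a lesion counts as detected when
#' at least one predicted blob overlaps it.
#'
#' @param cohort a list of studies or an `mp_cohort`.
#' @param config a [seg_config()].
#' @param features_list optional precomputed feature tables.
#' @return A `seg_eval` list: data.frames `per_lesion` and `per_patient`, and
#'   `summary` (mean/median lesion DSC, mean patient DSC, sensitivity,
#'   detection rate).
#' @export
loocv_segmentation <- function(cohort, config = seg_config(), features_list = NULL) {
  studies <- as_study_list(cohort)
  n <- length(studies)
  if (n < 3L) stop("LOOCV needs at least 3 studies", call. = FALSE)
  if (is.null(features_list))
    features_list <- lapply(studies, voxel_feature_matrix)
  per_lesion <- list(); per_patient <- list()
  for (held in seq_len(n)) {
    cfg <- config; cfg$seed <- child_seed(config$seed, 1000L + held)
    model <- train_segmenter(studies[-held], cfg, features_list[-held])
    res <- predict_segmentation(model, studies[[held]],
                                feature_subset(features_list[[held]], config$drop))
    study <- studies[[held]]
    blobs <- postprocess_blobs(res$mask, study$annotation)
    pred <- blobs > 0
    per_patient[[held]] <- data.frame(
      patient = study$patient_id,
      dsc = dice(pred, study$annotation > 0),
      sensitivity = voxel_sensitivity(pred, study$annotation),
      theta = model$theta)
    ids <- sort(unique(study$annotation[study$annotation > 0]))
    per_lesion[[held]] <- do.call(rbind, lapply(ids, function(l) {
      lmask <- study$annotation == l
      touching <- unique(blobs[blobs > 0 & lmask])
      pl <- array(blobs %in% touching & blobs > 0, dim(blobs))
      data.frame(patient = study$patient_id, lesion = l,
                 class = unname(study$lesion_labels[as.character(l)]),
                 dsc = dice(pl, lmask), detected = length(touching) > 0,
                 sensitivity = voxel_sensitivity(pred, lmask))
    }))
  }
  per_lesion <- do.call(rbind, per_lesion)
  per_patient <- do.call(rbind, per_patient)
  structure(list(
    per_lesion = per_lesion, per_patient = per_patient,
    summary = c(mean_dsc_lesion = mean(per_lesion$dsc),
                median_dsc_lesion = stats::median(per_lesion$dsc),
                mean_dsc_patient = mean(per_patient$dsc),
                mean_sensitivity = mean(per_lesion$sensitivity),
                detection_rate = mean(per_lesion$detected))),
    class = "seg_eval")
}

#' @export
print.seg_eval <- function(x, ...) {
  cat("LOOCV segmentation evaluation\n")
  print(round(x$summary, 4))
  invisible(x)
}
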