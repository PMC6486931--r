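test_that("dice agrees with set arithmetic", {
  a <- array(0L, c(4, 4, 2)); b <- array(0L, c(4, 4, 2))
  a[1:2, 1:2, 1] <- 1L; b[1:2, 1:2, 1] <- 1L
  expect_equal(dice(a, b), 1)
  b[] <- 0L; b[3:4, 3:4, 2] <- 1L
  expect_equal(dice(a, b), 0)
  a[] <- 0L; b[] <- 0L
  a[1:4, 1, 1] <- 1L                 # |a| = 4
  b[2:4, 1, 1] <- 1L; b[1:3, 2, 1] <- 1L  # |b| = 6, overlap 3
  expect_equal(dice(a, b), 0.6)
  expect_equal(dice(array(0L, c(2, 2, 2)), array(0L, c(2, 2, 2))), 0)
  expect_error(dice(a, array(0L, c(2, 2, 2))), "shape")
  # random masks vs brute-force set arithmetic
  set.seed(8)
  for (i in 1:10) {
    x <- array(as.integer(runif(60) > 0.6), c(5, 4, 3))
    y <- array(as.integer(runif(60) > 0.6), c(5, 4, 3))
    inter <- sum(x == 1 & y == 1)
    expected <- if (sum(x) + sum(y) == 0) 0 else 2 * inter / (sum(x) + sum(y))
    expect_equal(dice(x, y), expected)
  }
})

test_that("6-connected labelling matches a flood-fill oracle", {
  # face-touching voxels connect; corner-touching do not
  m <- array(0L, c(3, 3, 3)); m[1, 1, 1] <- 1L; m[2, 1, 1] <- 1L
  expect_equal(max(label_components_6(m)), 1)
  m <- array(0L, c(3, 3, 3)); m[1, 1, 1] <- 1L; m[2, 2, 2] <- 1L
  expect_equal(max(label_components_6(m)), 2)
  m <- array(0L, c(3, 3, 1)); m[1, 1, 1] <- 1L
  expect_equal(max(label_components_6(m)), 1)
  set.seed(14)
  for (i in 1:8) {
    m <- array(as.integer(runif(4 * 4 * 4) > 0.55), c(4, 4, 4))
    got <- label_components_6(m)
    want <- bf_components6(m)
    expect_equal(max(got), max(want))
    # identical partition up to label permutation
    if (max(want) > 0)
      expect_equal(length(unique(paste(got[m > 0], want[m > 0]))), max(want))
  }
})

test_that("post-processing keeps only annotation-overlapping blobs", {
  m <- array(0L, c(8, 8, 4))
  m[1:2, 1:2, 1:2] <- 1L; m[6:7, 6:7, 3:4] <- 1L
  ann <- array(0L, c(8, 8, 4)); ann[2, 2, 1] <- 1L
  kept <- postprocess_blobs(m, ann)
  expect_equal(max(kept), 1)
  expect_true(all(kept[6:7, 6:7, 3:4] == 0))
  # deployment mode keeps everything
  expect_equal(max(postprocess_blobs(m)), 2)
})

test_that("training voxel sampling is capped, exhaustive and reproducible", {
  s <- tiny_cohort()[[1]]$study
  vf <- voxel_feature_matrix(s)
  n_les <- sum(s$annotation[vf$voxel] > 0)
  idx <- sample_training_voxels(vf, s$annotation, n_per_class = 1000, seed = 2)
  expect_length(idx$lesion, min(1000, n_les))
  expect_length(idx$background, 1000)
  expect_true(all(s$annotation[vf$voxel[idx$lesion]] > 0))
  expect_true(all(s$annotation[vf$voxel[idx$background]] == 0))
  small <- sample_training_voxels(vf, s$annotation, n_per_class = 1e6, seed = 2)
  expect_length(small$lesion, n_les)      # cannot exceed the population
  idx2 <- sample_training_voxels(vf, s$annotation, n_per_class = 1000, seed = 2)
  expect_identical(idx, idx2)
})

test_that("segmentation probabilities live on the breast mask", {
  coh <- tiny_cohort()
  studies <- lapply(coh, function(e) e$study)
  model <- suppressWarnings(train_segmenter(studies, seg_config(seed = 5)))
  expect_true(model$theta >= 0 && model$theta <= 1)
  res <- predict_segmentation(model, studies[[1]])
  expect_true(all(res$prob >= 0 & res$prob <= 1))
  expect_true(all(res$prob[studies[[1]]$breast_mask == 0] == 0))
  expect_true(all(res$mask[studies[[1]]$breast_mask == 0] == 0))
  # noise-free well-separated lesion: every lesion voxel above threshold
  expect_true(all(res$mask[studies[[1]]$annotation > 0] == 1))
})

test_that("single-study training warns; missing features error", {
  coh <- tiny_cohort()
  expect_warning(train_segmenter(coh[1], seg_config(seed = 5)), "single")
  model <- suppressWarnings(train_segmenter(coh[1], seg_config(seed = 5)))
  vf <- feature_subset(voxel_feature_matrix(coh[[1]]$study), "PET")
  expect_error(predict_segmentation(model, coh[[1]]$study, vf), "pet")
})

test_that("LOOCV covers every study and a perfect predictor scores DSC 1", {
  coh <- tiny_cohort()
  cfg <- phantom_config(n_patients = 4, grid_shape = c(24, 24, 16), noise_sd = 0.05,
                        vessel_count = 1, lesion_radius_range = c(5, 7), seed = 6)
  small <- make_cohort(cfg)
  ev <- loocv_segmentation(small, seg_config(seed = 8))
  expect_equal(nrow(ev$per_patient), 4)
  expect_true(all(ev$per_lesion$dsc >= 0 & ev$per_lesion$dsc <= 1))
  expect_true(all(ev$per_lesion$sensitivity >= 0 & ev$per_lesion$sensitivity <= 1))
  # a probability map equal to the annotation thresholds to a perfect mask
  s <- coh[[1]]$study
  perfect <- list(prob = array(as.numeric(s$annotation > 0), dim(s$annotation)),
                  mask = array(as.integer(s$annotation > 0), dim(s$annotation)))
  blobs <- postprocess_blobs(perfect$mask, s$annotation)
  expect_equal(dice(blobs > 0, s$annotation > 0), 1)
})

test_that("removing vessel distractors never lowers segmentation DSC", {
  base <- list(n_patients = 4, grid_shape = c(24, 24, 16), noise_sd = 0,
               lesion_radius_range = c(5, 7), seed = 17)
  with_v <- make_cohort(do.call(phantom_config, c(base, vessel_count = 2)))
  no_v <- make_cohort(do.call(phantom_config, c(base, vessel_count = 0)))
  ev_v <- loocv_segmentation(with_v, seg_config(seed = 3))
  ev_n <- loocv_segmentation(no_v, seg_config(seed = 3))
  expect_gte(ev_n$summary[["mean_dsc_lesion"]] + 1e-9,
             ev_v$summary[["mean_dsc_lesion"]])
})
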