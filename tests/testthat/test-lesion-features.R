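test_that("fuzzy c-means separates distant clouds and is seeded", {
  set.seed(3)
  x <- rbind(matrix(rnorm(60, 0, 0.2), ncol = 2),
             matrix(rnorm(60, 8, 0.2), ncol = 2))
  f <- fuzzy_c_means(x, c = 2, seed = 4)
  ctr <- f$centres[order(f$centres[, 1]), ]
  expect_equal(unname(ctr[1, ]), c(0, 0), tolerance = 0.15)
  expect_equal(unname(ctr[2, ]), c(8, 8), tolerance = 0.15)
  expect_equal(rowSums(f$memberships), rep(1, 60), tolerance = 1e-9)
  f2 <- fuzzy_c_means(x, c = 2, seed = 4)
  expect_identical(f, f2)
  expect_error(fuzzy_c_means(matrix(1:4, 2), c = 5), "distinct")
})

test_that("fuzzy c-means agrees with the e1071 reference implementation", {
  skip_if_not_installed("e1071")
  set.seed(9)
  x <- matrix(rnorm(900), 300, 3)
  got <- fuzzy_c_means(x, c = 3, seed = 2)
  ux <- unique(x)
  ctr0 <- mpcad:::with_seed(2, ux[sample.int(nrow(ux), 3), , drop = FALSE])
  ref <- e1071::cmeans(x, centers = ctr0, m = 2, iter.max = 200)
  ord_g <- order(got$centres[, 1]); ord_r <- order(ref$centers[, 1])
  expect_equal(got$centres[ord_g, ], unname(ref$centers[ord_r, ]),
               tolerance = 0.02)
})

test_that("the characteristic kinetic curve tracks the fast subpopulation", {
  # hand-built lesion: 80% slow benign-like voxels, 20% fast malignant-like
  grid <- c(8, 8, 4); n_frames <- 34; j <- 7
  times <- (seq_len(n_frames) - 1) * 13.2
  t_enh <- (seq_len(n_frames) - j + 1) * 13.2
  slow <- enhancement_curve(t_enh, G = 1, alpha = 1, tau = 50, t_half = 200)
  fast <- enhancement_curve(t_enh, G = 2, alpha = 1, tau = 15, t_half = 70,
                            beta = -5e-4, k = 1)
  dce <- array(1, c(grid, n_frames))
  mask <- array(0L, grid); mask[2:6, 2:6, 2:3] <- 1L
  vox <- which(mask == 1)
  set.seed(11)
  fast_vox <- sample(vox, round(0.2 * length(vox)))
  slow_vox <- setdiff(vox, fast_vox)
  for (i in j:n_frames) {
    fr <- array(1, grid)
    fr[slow_vox] <- 1 + slow[i] * (1 + 0.02 * seq_along(slow_vox) / length(slow_vox))
    fr[fast_vox] <- 1 + fast[i] * (1 + 0.02 * seq_along(fast_vox) / length(fast_vox))
    dce[, , , i] <- fr
  }
  ckc <- characteristic_kinetic_curve(dce, mask, j, times, seed = 2)
  expect_length(ckc$intensity, 25)
  expect_length(ckc$deltas, 21)
  expect_false(ckc$fallback)
  # the chosen centre matches the fast curve, not the slow or the pooled mean
  err_fast <- sqrt(mean((ckc$intensity - fast[j:(j + 24)])^2))
  err_slow <- sqrt(mean((ckc$intensity - slow[j:(j + 24)])^2))
  expect_lt(err_fast, 0.1)
  expect_gt(err_slow, 5 * err_fast)
})

test_that("homogeneous lesions fall back to their common curve", {
  s <- tiny_cohort()[[1]]$study
  grid <- dim(s$breast_mask)
  dce <- s$dce
  mask <- array(0L, grid); mask[2:4, 2:4, 2:3] <- 1L
  # make every in-mask curve identical
  for (i in seq_len(dim(dce)[4])) { fr <- mpcad:::frame_of(dce, i); fr[mask > 0] <- 1 + i / 10; dce[, , , i] <- fr }
  expect_warning(ckc <- characteristic_kinetic_curve(dce, mask, s$enhancement_onset,
                                                     s$times, seed = 1), "mean curve")
  j <- s$enhancement_onset
  expect_equal(ckc$intensity, (1 + (j:(j + 24)) / 10) - mean(1 + (1:(j - 1)) / 10),
               tolerance = 1e-9)
})

test_that("spatial GLCM matches exhaustive pair enumeration", {
  # 3x3x1 two-level toy volume
  vol <- array(c(0, 0, 1, 1, 0, 1, 0, 1, 1), c(3, 3, 1))
  mask <- array(1L, c(3, 3, 1))
  g <- glcm_3d(vol, mask, bins = 2)
  want <- bf_glcm_spatial(vol, mask, 2)
  want <- (want + t(want)) / 2; want <- want / sum(want)
  expect_equal(unclass(g), want, ignore_attr = TRUE)
  # random volumes up to 5x5x5 with random masks
  set.seed(21)
  for (i in 1:6) {
    d <- sample(2:5, 3, replace = TRUE)
    vol <- array(runif(prod(d)), d)
    mask <- array(as.integer(runif(prod(d)) > 0.3), d)
    if (sum(mask) < 2) next
    g <- glcm_3d(vol, mask, bins = 8)
    want <- bf_glcm_spatial(vol, mask, 8)
    want <- (want + t(want)) / 2; want <- want / sum(want)
    expect_equal(unclass(g), want, ignore_attr = TRUE, tolerance = 1e-12)
  }
  expect_equal(sum(g), 1)
  expect_equal(unclass(g), t(unclass(g)), ignore_attr = TRUE)
})

test_that("constant volumes give a single-entry GLCM", {
  g <- glcm_3d(array(5, c(3, 3, 2)), array(1L, c(3, 3, 2)), bins = 128)
  expect_equal(sum(g > 0), 1)
  expect_equal(g[1, 1], 1)
  expect_error(glcm_3d(array(1, c(2, 2, 2)), array(0L, c(2, 2, 2))), "mask")
})

test_that("temporal GLCM pairs co-located voxels across time points", {
  d <- c(4, 4, 3)
  mask <- array(as.integer(runif(prod(d), 0, 1) > 0.4), d)
  set.seed(31)
  va <- array(runif(prod(d)), d); vb <- array(runif(prod(d)), d)
  g <- temporal_glcm(va, vb, mask, bins = 6)
  expect_equal(attr(g, "n_pairs"), sum(mask))
  want <- bf_glcm_temporal(va, vb, mask, 6)
  want <- (want + t(want)) / 2; want <- want / sum(want)
  expect_equal(unclass(g), want, ignore_attr = TRUE, tolerance = 1e-12)
  # identical volumes co-occur strictly on the diagonal
  gd <- temporal_glcm(va, va, mask, bins = 6)
  expect_true(all(gd[row(gd) != col(gd)] == 0))
  # uniform uptake has higher energy than heterogeneous uptake
  uni <- array(1, d); uni2 <- array(2, d)
  e_uni <- haralick13(temporal_glcm(uni, uni2, array(1L, d), bins = 8))[["energy"]]
  e_het <- haralick13(temporal_glcm(va, vb, array(1L, d), bins = 8))[["energy"]]
  expect_gt(e_uni, e_het)
})

test_that("Haralick statistics match a textbook recomputation", {
  g <- matrix(0, 4, 4); g[1, 1] <- 1
  h <- haralick13(g)
  expect_equal(h[["energy"]], 1)
  expect_equal(h[["entropy"]], 0)
  k <- 5
  gu <- matrix(1 / k^2, k, k)
  hu <- haralick13(gu)
  expect_equal(hu[["energy"]], 1 / k^2)
  expect_equal(hu[["entropy"]], log(k^2))
  set.seed(41)
  for (i in 1:5) {
    m <- matrix(runif(36), 6, 6); m <- (m + t(m)) / 2; m <- m / sum(m)
    expect_equal(as.numeric(haralick13(m)), as.numeric(bf_haralick(m)),
                 tolerance = 1e-10)
  }
})

test_that("Haralick features are invariant to affine intensity rescaling", {
  set.seed(51)
  d <- c(5, 5, 4)
  vol <- array(runif(prod(d)), d)
  mask <- array(1L, d)
  h1 <- haralick13(glcm_3d(vol, mask, bins = 16))
  h2 <- haralick13(glcm_3d(vol * 37 - 11, mask, bins = 16))
  expect_equal(h1, h2, tolerance = 1e-12)
})

test_that("extreme cluster centres find the low-ADC and high-PET levels", {
  d <- c(5, 5, 5)
  vol <- array(rep(1:5, each = 25), d)
  mask <- array(1L, d)
  lo <- cluster_extreme_intensity(vol, mask, "lowest", seed = 2)
  hi <- cluster_extreme_intensity(vol, mask, "highest", seed = 2)
  expect_equal(as.numeric(lo), 1, tolerance = 0.2)
  expect_equal(as.numeric(hi), 5, tolerance = 0.2)
  expect_lte(as.numeric(lo), as.numeric(hi))
  cst <- cluster_extreme_intensity(array(3, d), mask, "lowest")
  expect_equal(as.numeric(cst), 3)
  expect_true(attr(cst, "fallback"))
})

test_that("shape descriptors recover analytic ball and box geometry", {
  ball <- ball_mask(10)
  sh <- shape_descriptors(ball, spacing = c(1, 1, 1))
  expect_equal(sh[["compactness"]], 1, tolerance = 0.1)
  expect_equal(sh[["sphericity"]], 1, tolerance = 0.05)
  expect_equal(sh[["radius_mean"]], 10, tolerance = 0.5)
  expect_equal(sh[["convexity"]], 1, tolerance = 0.05)
  # doubling the spacing multiplies volume by 8
  sh2 <- shape_descriptors(ball, spacing = c(2, 2, 2))
  expect_equal(sh2[["volume"]], 8 * sh[["volume"]])
  # axis-aligned 20x5x5 box: principal-axis ratio = 4
  box <- array(0L, c(26, 11, 11)); box[4:23, 4:8, 4:8] <- 1L
  shb <- shape_descriptors(box, spacing = c(1, 1, 1))
  expect_equal(shb[["elongation"]], 4, tolerance = 0.05)
  two <- array(0L, c(6, 6, 6)); two[1, 1, 1] <- 1L; two[6, 6, 6] <- 1L
  expect_error(shape_descriptors(two), "per lesion")
})

test_that("the lesion feature vector is canonical and class-separating", {
  coh <- tiny_cohort()
  s <- coh[[1]]$study
  fv <- lesion_feature_vector(s, lesion_id = 1, seed = 3)
  expect_length(fv, 143)
  tags <- attr(fv, "groups")
  expect_equal(unname(table(tags)[c("DCE", "DWI", "PET", "MORPH")]),
               c(133L, 1L, 1L, 8L), ignore_attr = TRUE)
  # "DCE only" filter removes exactly the ADC and PET features
  dce_only <- fv[tags %in% c("DCE", "MORPH")]
  expect_setdiff <- setdiff(names(fv), names(dce_only))
  expect_equal(sort(expect_setdiff), c("adc_low", "pet_high"))
  fv2 <- lesion_feature_vector(s, lesion_id = 1, seed = 3)
  expect_identical(fv, fv2)
})

test_that("malignant phantom lesions show faster kinetics and lower ADC", {
  tab <- cls_table()
  mal <- tab$class == "malignant"
  expect_lt(mean(tab$kin_thalf[mal]), mean(tab$kin_thalf[!mal]))
  expect_lt(mean(tab$adc_low[mal]), mean(tab$adc_low[!mal]))
  expect_gt(mean(tab$pet_high[mal]), mean(tab$pet_high[!mal]))
})
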