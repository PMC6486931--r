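test_that("rank-based AUC equals exhaustive pair counting", {
  expect_equal(roc_auc(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE)), 1)
  expect_equal(roc_auc(c(4, 3, 2, 1), c(FALSE, FALSE, TRUE, TRUE)), 0)
  expect_equal(roc_auc(c(1, 1, 2, 2), c(FALSE, TRUE, FALSE, TRUE)), 0.5)
  set.seed(7)
  for (i in 1:10) {
    n <- sample(4:20, 1)
    scores <- sample(1:6, n, replace = TRUE)   # plenty of ties
    labels <- runif(n) > 0.5
    if (!any(labels) || all(labels)) next
    expect_equal(roc_auc(scores, labels), bf_auc(scores, labels))
  }
  expect_error(roc_auc(1:3, c(TRUE, TRUE, TRUE)), "both classes")
})

test_that("Gini importance ranks the informative feature first and co-ranks duplicates", {
  set.seed(12)
  n <- 200
  y <- factor(rep(c("benign", "malignant"), each = n / 2),
              levels = c("benign", "malignant"))
  signal <- ifelse(y == "malignant", 1, 0) + rnorm(n, sd = 0.1)
  x <- cbind(signal = signal, dup = signal + rnorm(n, sd = 0.01),
             noise1 = rnorm(n), noise2 = rnorm(n), noise3 = rnorm(n))
  rk <- gini_ranking(x, y, cls_config(seed = 5))
  expect_true(all(rk$scores >= 0))
  expect_equal(sum(rk$scores), 1, tolerance = 1e-9)
  # both redundant copies land in the top ranks
  expect_setequal(rk$features[1:2], c("signal", "dup"))
  # the noise features collect little importance
  expect_lt(sum(rk$scores[rk$features %in% c("noise1", "noise2", "noise3")]), 0.2)
})

test_that("mRMR demotes an exact duplicate below a weaker independent feature", {
  set.seed(13)
  n <- 200
  y <- rep(c(0, 1), each = n / 2)
  strong <- y + rnorm(n, sd = 0.3)
  weak <- y + rnorm(n, sd = 1.0)
  x <- cbind(strong = strong, dup = strong, weak = weak, noise = rnorm(n))
  rk <- mrmr_ranking(x, factor(y))
  expect_equal(rk$features[1], "strong")
  # the duplicate carries full redundancy and must fall behind 'weak'
  expect_lt(which(rk$features == "weak"), which(rk$features == "dup"))
  # K = feature count returns a permutation of all features
  expect_setequal(rk$features, colnames(x))
  expect_error(mrmr_ranking(x, factor(y), K = 10), "exceeds")
})

test_that("the first mRMR pick maximises mutual information with the label", {
  set.seed(23)
  for (i in 1:3) {
    n <- 150
    y <- factor(runif(n) > 0.5)
    x <- matrix(rnorm(n * 6), n, 6, dimnames = list(NULL, paste0("f", 1:6)))
    x[, 3] <- as.numeric(y) + rnorm(n, sd = 1.2)
    rk <- mrmr_ranking(x, y)
    disc <- apply(x, 2, mpcad:::discretise_ef, bins = 3L)
    mis <- apply(disc, 2, bf_mi, b = as.integer(y))
    expect_equal(rk$features[1], names(which.max(mis)))
    expect_equal(rk$scores[1], max(mis), tolerance = 1e-12)
  }
})

test_that("the greedy mRMR path matches a brute-force reimplementation", {
  set.seed(29)
  n <- 120
  x <- matrix(rnorm(n * 6), n, 6, dimnames = list(NULL, paste0("f", 1:6)))
  y <- factor(x[, 2] + 0.5 * x[, 5] + rnorm(n, sd = 0.8) > 0)
  rk <- mrmr_ranking(x, y)
  disc <- apply(x, 2, mpcad:::discretise_ef, bins = 3L)
  yv <- as.integer(y)
  rel <- apply(disc, 2, bf_mi, b = yv)
  sel <- integer(0); rem <- 1:6
  for (step in 1:6) {
    crit <- sapply(rem, function(f) {
      if (!length(sel)) rel[f]
      else rel[f] - mean(sapply(sel, function(s) bf_mi(disc[, f], disc[, s])))
    })
    pick <- rem[which.max(crit)]
    sel <- c(sel, pick); rem <- setdiff(rem, pick)
  }
  expect_equal(rk$features, colnames(x)[sel])
})

test_that("classifier training maximises F1 with the smallest tied threshold", {
  set.seed(31)
  n <- 60
  y <- factor(rep(c("benign", "malignant"), each = n / 2),
              levels = c("benign", "malignant"))
  x <- cbind(f = ifelse(y == "malignant", 2, -2) + rnorm(n, sd = 0.2),
             g = rnorm(n))
  model <- train_lesion_classifier(x, y, cls_config(seed = 4))
  prob <- model$forest$votes[, "malignant"]   # thresholds come from OOB votes
  expect_equal(mpcad:::f1_score(prob >= model$theta, y == "malignant"), 1)
  # tie-break: no smaller grid threshold achieves the same F1
  grid <- cls_config()$theta_grid
  f1s <- vapply(grid, function(th) mpcad:::f1_score(prob >= th, y == "malignant"),
                numeric(1))
  expect_equal(model$theta, grid[which.max(f1s)])
  expect_error(train_lesion_classifier(x, factor(rep("malignant", n),
                                                 levels = levels(y))),
               "both classes")
})

test_that("LOOCV classification reports repeat spread and leaks nothing", {
  tab <- cls_table()
  ev1 <- loocv_classification(tab, cls_config(repeats = 1, seed = 2))
  expect_equal(ev1$auc_sd, 0)
  expect_true(ev1$auc_mean >= 0 && ev1$auc_mean <= 1)
  # sens/spec agree with the confusion matrix of the thresholded scores
  expect_true(ev1$sensitivity >= 0 && ev1$sensitivity <= 1)
  expect_true(ev1$specificity >= 0 && ev1$specificity <= 1)
  # flipping a held-out label cannot change its own fold's prediction
  xy <- mpcad:::lesion_xy(tab)
  p1 <- mpcad:::loocv_pass(xy$x, xy$y, cls_config(seed = 2), n_features = 10,
                           ranking = "mrmr")
  yflip <- xy$y
  yflip[1] <- if (yflip[1] == "malignant") "benign" else "malignant"
  p2 <- mpcad:::loocv_pass(xy$x, yflip, cls_config(seed = 2), n_features = 10,
                           ranking = "mrmr")
  expect_equal(p1$scores[1], p2$scores[1])
})

test_that("incremental top-k curves are valid and start at one feature", {
  tab <- cls_table()
  curve <- incremental_evaluation(tab, method = "mrmr", K = 3,
                                  config = cls_config(repeats = 1, seed = 3))
  expect_equal(curve$k, 1:3)
  expect_true(all(curve$auc >= 0 & curve$auc <= 1))
  one <- incremental_evaluation(tab, method = "gi", K = 1,
                                config = cls_config(repeats = 1, seed = 3))
  expect_equal(nrow(one), 1)
})

test_that("automatic-segmentation classification falls back when undetected", {
  coh <- tiny_cohort()
  studies <- lapply(coh, function(e) e$study)
  perfect <- lapply(studies, function(s)
    list(prob = array(as.numeric(s$annotation > 0), dim(s$annotation)),
         mask = array(as.integer(s$annotation > 0), dim(s$annotation)),
         theta = 0.5))
  # needs >= 3 lesions for LOOCV: duplicate the cohort
  studies4 <- c(studies, studies)
  perfect4 <- c(perfect, perfect)
  res <- classify_from_segmentation(studies4, perfect4,
                                    cls_config(repeats = 1, seed = 5))
  expect_false(any(res$fallback))
  # blank out one prediction: exactly one fallback flag
  perfect4[[1]]$mask[] <- 0L
  res2 <- classify_from_segmentation(studies4, perfect4,
                                     cls_config(repeats = 1, seed = 5))
  expect_equal(sum(res2$fallback), 1)
})
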