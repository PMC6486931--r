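#' Lesion classification configuration
#'
#' @param ntree random-forest size.
#' @param theta_grid thresholds scanned when maximising training F1 (ties to
#'   the smallest threshold).
#' @param repeats number of repetitions of the LOOCV experiment; repeats
#'   differ only in the forest/clustering seeds.
#' @param ranking `NULL` (use all features), `"gi"` or `"mrmr"`; recomputed
#'   inside each training fold.
#' @param n_features top-k features kept when `ranking` is set.
#' @param drop modality groups to exclude (`"DWI"`, `"PET"`).
#' @param seed integer base seed.
#' @return A `cls_config` list.
#' @export
cls_config <- function(ntree = 100L, theta_grid = seq(0, 1, by = 0.01),
                       repeats = 20L, ranking = NULL, n_features = NULL,
                       drop = character(0), seed = 1L) {
  structure(list(ntree = as.integer(ntree), theta_grid = theta_grid,
                 repeats = as.integer(repeats), ranking = ranking,
                 n_features = n_features, drop = drop, seed = as.integer(seed)),
            class = "cls_config")
}

lesion_xy <- function(table, drop = character(0)) {
  groups <- attr(table, "groups")
  cols <- setdiff(names(table), c("patient", "lesion", "class"))
  if (length(drop)) {
    bad <- setdiff(drop, c("DWI", "PET"))
    if (length(bad)) stop("unknown modality: ", paste(bad, collapse = ", "),
                          call. = FALSE)
    cols <- cols[!(groups[cols] %in% drop)]
  }
  x <- as.matrix(table[, cols, drop = FALSE])
  y <- factor(table$class, levels = c("benign", "malignant"))
  list(x = x, y = y)
}

#' Train the benign/malignant lesion classifier
#'
#' Random forest plus a decision threshold maximising the training-set F1
#' score (harmonic mean of precision and sensitivity for the malignant class)
#' over a probability grid, ties broken toward the smallest threshold. The
#' threshold is selected on the forest's out-of-bag class votes: in-bag
#' probabilities are overfit to near 0/1 and would drive the smallest-tie
#' threshold to the bottom of the grid.
#'
#' @param x feature matrix (rows = lesions).
#' @param y factor with levels benign/malignant.
#' @param config a [cls_config()].
#' @return A `lesion_classifier` list: `forest`, `theta`, `features`.
#' @export
train_lesion_classifier <- function(x, y, config = cls_config()) {
  if (nlevels(droplevels(y)) < 2L)
    stop("both classes must be present in training", call. = FALSE)
  x <- impute_nonfinite(x)
  forest <- with_seed(config$seed,
                      randomForest::randomForest(x = x, y = y, ntree = config$ntree))
  prob <- forest$votes[, "malignant"]
  bad <- !is.finite(prob)          # samples never out-of-bag (tiny forests)
  if (any(bad)) prob[bad] <- predict(forest, x[bad, , drop = FALSE],
                                     type = "prob")[, "malignant"]
  f1s <- vapply(config$theta_grid, function(th)
    f1_score(prob >= th, y == "malignant"), numeric(1))
  theta <- config$theta_grid[which.max(f1s)]
  structure(list(forest = forest, theta = theta, features = colnames(x)),
            class = "lesion_classifier")
}

f1_score <- function(pred, truth) {
  tp <- sum(pred & truth)
  prec <- if (sum(pred) == 0) 0 else tp / sum(pred)
  sens <- if (sum(truth) == 0) 0 else tp / sum(truth)
  if (prec + sens == 0) 0 else 2 * prec * sens / (prec + sens)
}

# Replace non-finite entries by the column median (flagged fits etc.).
impute_nonfinite <- function(x, stats = NULL) {
  if (is.null(stats))
    stats <- apply(x, 2L, function(col) {
      md <- stats::median(col[is.finite(col)])
      if (is.finite(md)) md else 0
    })
  for (k in seq_len(ncol(x))) {
    bad <- !is.finite(x[, k])
    if (any(bad)) x[bad, k] <- stats[k]
  }
  attr(x, "impute_stats") <- stats
  x
}

#' Rank-based ROC AUC
#'
#' Mann-Whitney formulation with midrank tie handling: the probability that a
#' randomly chosen positive scores above a randomly chosen negative (ties
#' count half).
#'
#' @param scores numeric scores, larger = more positive.
#' @param labels logical (or coercible) positive-class indicator.
#' @return AUC in [0, 1].
#' @export
roc_auc <- function(scores, labels) {
  pos <- as.logical(labels)
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) stop("both classes required for AUC", call. = FALSE)
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Gini-importance feature ranking
#'
#' Mean decrease in Gini impurity across the forest's splits, normalised to
#' sum 1. Redundant but informative features are all ranked highly.
#'
#' @param x feature matrix.
#' @param y class factor.
#' @param config a [cls_config()] (forest size and seed).
#' @return A `ranking_result`: `features` (ordered names), `scores`, `method`.
#' @export
gini_ranking <- function(x, y, config = cls_config()) {
  x <- impute_nonfinite(x)
  forest <- with_seed(config$seed,
                      randomForest::randomForest(x = x, y = y, ntree = config$ntree,
                                                 importance = FALSE))
  imp <- forest$importance[, "MeanDecreaseGini"]
  if (sum(imp) > 0) imp <- imp / sum(imp)
  ord <- order(-imp)
  structure(list(features = colnames(x)[ord], scores = unname(imp[ord]),
                 method = "gi"), class = "ranking_result")
}

# Equal-frequency discretisation into `bins` levels.
discretise_ef <- function(v, bins = 3L) {
  fin <- is.finite(v)
  out <- rep(1L, length(v))
  if (length(unique(v[fin])) <= 1L) return(out)
  br <- unique(quantile(v[fin], probs = seq(0, 1, length.out = bins + 1L)))
  if (length(br) < 2L) return(out)
  out[fin] <- as.integer(cut(v[fin], breaks = br, include.lowest = TRUE))
  out
}

# Mutual information (nats) between two discrete vectors.
mutual_information <- function(a, b) {
  tab <- table(a, b)
  p <- tab / sum(tab)
  px <- rowSums(p); py <- colSums(p)
  e <- outer(px, py)
  sum(ifelse(p > 0, p * log(p / e), 0))
}

#' Minimum-redundancy-maximum-relevance feature ranking
#'
#' Greedy mRMR in the MID (mutual-information difference) form on
#' equal-frequency 3-bin discretised features: the first feature maximises
#' `I(f; y)`; each next feature maximises relevance minus the mean mutual
#' information with the already-selected set. Deterministic given the
#' discretisation; ties break toward the earlier column.
#'
#' @param x feature matrix.
#' @param y class factor (or discrete vector).
#' @param K number of features to rank (default all).
#' @param bins discretisation bins (default 3).
#' @return A `ranking_result` with the greedy selection order and the
#'   criterion value at each step.
#' @export
mrmr_ranking <- function(x, y, K = ncol(x), bins = 3L) {
  if (K > ncol(x)) stop("K exceeds the feature count", call. = FALSE)
  disc <- apply(x, 2L, discretise_ef, bins = bins)
  yv <- as.integer(factor(y))
  rel <- apply(disc, 2L, mutual_information, b = yv)
  selected <- integer(0); scores <- numeric(0)
  red <- matrix(NA_real_, ncol(x), ncol(x))
  remaining <- seq_len(ncol(x))
  for (step in seq_len(K)) {
    crit <- if (length(selected) == 0L) rel[remaining] else {
      vapply(remaining, function(f) {
        for (s in selected) if (is.na(red[f, s])) {
          red[f, s] <<- red[s, f] <<- mutual_information(disc[, f], disc[, s])
        }
        rel[f] - mean(red[f, selected])
      }, numeric(1))
    }
    best <- remaining[which.max(crit)]
    selected <- c(selected, best)
    scores <- c(scores, max(crit))
    remaining <- setdiff(remaining, best)
  }
  structure(list(features = colnames(x)[selected], scores = scores,
                 method = "mrmr"), class = "ranking_result")
}

#' @export
print.ranking_result <- function(x, ...) {
  cat(sprintf("%s feature ranking (%d features)\n", toupper(x$method),
              length(x$features)))
  print(head(data.frame(feature = x$features, score = round(x$scores, 5)), 10))
  invisible(x)
}

rank_features <- function(x, y, method, config) {
  switch(method,
         gi = gini_ranking(x, y, config),
         mrmr = mrmr_ranking(x, y),
         stop("unknown ranking method: ", method, call. = FALSE))
}

# One LOOCV pass over the lesion table; returns held-out scores and the
# per-fold thresholded prediction.
loocv_pass <- function(x, y, config, n_features = NULL, ranking = NULL,
                       fixed_ranking = NULL) {
  n <- nrow(x)
  scores <- numeric(n); pred <- logical(n)
  for (held in seq_len(n)) {
    xt <- x[-held, , drop = FALSE]; yt <- droplevels(y[-held])
    if (nlevels(yt) < 2L) stop("a training fold lost one class", call. = FALSE)
    cols <- colnames(x)
    if (!is.null(fixed_ranking)) {
      cols <- head(fixed_ranking$features, n_features %||% length(fixed_ranking$features))
    } else if (!is.null(ranking)) {
      rk <- rank_features(xt, y[-held], ranking, config)
      cols <- head(rk$features, n_features %||% length(rk$features))
    }
    cfg <- config; cfg$seed <- child_seed(config$seed, held)
    model <- train_lesion_classifier(xt[, cols, drop = FALSE], y[-held], cfg)
    xtr <- impute_nonfinite(xt[, cols, drop = FALSE])
    xi <- impute_nonfinite(x[held, cols, drop = FALSE],
                           stats = attr(xtr, "impute_stats"))
    p <- predict(model$forest, xi, type = "prob")[, "malignant"]
    scores[held] <- p
    pred[held] <- p >= model$theta
  }
  list(scores = scores, pred = pred)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Leave-one-out cross-validated lesion classification
#'
#' The LOOCV unit is the lesion. Feature ranking (when requested) and the
#' F1-maximising threshold are recomputed inside every training fold, so no
#' information from the held-out lesion leaks into model selection. The whole
#' experiment is repeated `repeats` times varying only the seeds; AUC is
#' reported as mean +/- SD over repeats, sensitivity/specificity as means of
#' the per-repeat confusion at the fold thresholds.
#'
#' @param table a lesion feature table from [cohort_lesion_table()].
#' @param config a [cls_config()].
#' @return An `eval_result`: `auc_mean`, `auc_sd`, `sensitivity`,
#'   `specificity`, `per_repeat` data.frame, `scores` (last repeat).
#' @export
loocv_classification <- function(table, config = cls_config()) {
  xy <- lesion_xy(table, config$drop)
  if (nrow(xy$x) < 3L) stop("LOOCV needs at least 3 lesions", call. = FALSE)
  per <- data.frame(repeat_i = seq_len(config$repeats), auc = NA_real_,
                    sensitivity = NA_real_, specificity = NA_real_)
  last_scores <- NULL
  for (r in seq_len(config$repeats)) {
    cfg <- config
    cfg$seed <- child_seed(config$seed, 100000L + r)
    pass <- loocv_pass(xy$x, xy$y, cfg, n_features = config$n_features,
                       ranking = config$ranking)
    truth <- xy$y == "malignant"
    per$auc[r] <- roc_auc(pass$scores, truth)
    per$sensitivity[r] <- if (sum(truth)) sum(pass$pred & truth) / sum(truth) else NA
    per$specificity[r] <- if (sum(!truth)) sum(!pass$pred & !truth) / sum(!truth) else NA
    last_scores <- pass$scores
  }
  structure(list(auc_mean = mean(per$auc),
                 auc_sd = if (config$repeats > 1L) sd(per$auc) else 0,
                 sensitivity = mean(per$sensitivity),
                 specificity = mean(per$specificity),
                 per_repeat = per, scores = last_scores,
                 labels = xy$y), class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("LOOCV classification: AUC %.3f +/- %.3f; sens %.3f, spec %.3f (%d repeats)\n",
              x$auc_mean, x$auc_sd, x$sensitivity, x$specificity,
              nrow(x$per_repeat)))
  invisible(x)
}

#' Incremental top-k evaluation of a feature ranking
#'
#' For k = 1..K, runs a LOOCV classification restricted to the top-k features
#' and records the AUC, tracing how performance grows as ranked features are
#' added. By default the ranking is recomputed inside each training fold with
#' `method`; passing `fixed_ranking` evaluates a frozen ranking instead.
#'
#' @param table lesion feature table.
#' @param method `"gi"` or `"mrmr"`.
#' @param K largest k (default 10).
#' @param config a [cls_config()]; `repeats` is forced to 1 per k.
#' @param fixed_ranking optional `ranking_result` to use as-is.
#' @return Data.frame with columns `k` and `auc`.
#' @export
incremental_evaluation <- function(table, method = "mrmr", K = 10L,
                                   config = cls_config(), fixed_ranking = NULL) {
  xy <- lesion_xy(table, config$drop)
  K <- min(K, ncol(xy$x))
  out <- data.frame(k = seq_len(K), auc = NA_real_)
  truth <- xy$y == "malignant"
  for (k in seq_len(K)) {
    pass <- if (is.null(fixed_ranking))
      loocv_pass(xy$x, xy$y, config, n_features = k, ranking = method)
    else loocv_pass(xy$x, xy$y, config, n_features = k,
                    fixed_ranking = fixed_ranking)
    out$auc[k] <- roc_auc(pass$scores, truth)
  }
  out
}

#' Classification from automatic segmentations with manual fallback
#'
#' Extracts lesion features from the predicted, post-processed blobs of each
#' study's segmentation; annotated lesions with no overlapping predicted blob
#' fall back to the manual annotation mask and are flagged. The resulting
#' table is evaluated with [loocv_classification()].
#'
#' @param cohort list of studies.
#' @param seg_results list of `seg_result` objects, one per study.
#' @param config a [cls_config()].
#' @param seed seed for feature extraction.
#' @return List: `eval` (an `eval_result`), `table`, `fallback` (logical per
#'   lesion row).
#' @export
classify_from_segmentation <- function(cohort, seg_results, config = cls_config(),
                                       seed = 1L) {
  studies <- as_study_list(cohort)
  stopifnot(length(studies) == length(seg_results))
  rows <- list(); fallback <- logical(0)
  for (i in seq_along(studies)) {
    s <- studies[[i]]
    std <- standardise_study(s)
    blobs <- postprocess_blobs(seg_results[[i]]$mask, s$annotation)
    ids <- sort(unique(s$annotation[s$annotation > 0]))
    for (l in ids) {
      lmask <- s$annotation == l
      touching <- setdiff(unique(blobs[blobs > 0 & lmask]), 0L)
      fb <- length(touching) == 0L
      mask <- if (fb) array(as.integer(lmask), dim(lmask)) else {
        bm <- array(as.integer(blobs %in% touching), dim(blobs))
        # keep a single 6-connected component for the shape descriptors
        lb <- label_components_6(bm)
        array(as.integer(lb == 1L), dim(bm))
      }
      fv <- lesion_feature_vector(s, mask = mask, seed = seed, std_study = std)
      row <- data.frame(patient = s$patient_id, lesion = l,
                        class = unname(s$lesion_labels[as.character(l)]),
                        t(as.numeric(fv)), check.names = FALSE)
      names(row)[-(1:3)] <- names(fv)
      rows[[length(rows) + 1L]] <- row
      fallback <- c(fallback, fb)
    }
  }
  tab <- do.call(rbind, rows)
  attr(tab, "groups") <- lesion_feature_group_tags()
  list(eval = loocv_classification(tab, config), table = tab, fallback = fallback)
}
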