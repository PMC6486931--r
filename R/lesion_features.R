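#' Fuzzy c-means clustering with seeded initialisation
#'
#' Standard FCM: alternating membership and centre updates with fuzziness
#' exponent `m`, iterated to a membership-change tolerance. Initial centres
#' are drawn reproducibly from distinct data rows and every update is plain
#' deterministic arithmetic, so the same seed yields a bit-identical result.
#'
#' @param x numeric matrix (rows = samples) or vector.
#' @param c number of clusters (>= 2).
#' @param m fuzziness exponent (> 1, default 2).
#' @param seed integer seed for centre initialisation.
#' @param iter_max maximum iterations.
#' @param tol convergence tolerance on the membership matrix.
#' @return List with `centres` (c x d matrix) and `memberships` (n x c,
#'   rows summing to 1).
#' @export
fuzzy_c_means <- function(x, c = 5L, m = 2, seed = 1L, iter_max = 200L,
                          tol = 1e-9) {
  if (is.vector(x)) x <- matrix(x, ncol = 1)
  if (c < 2L) stop("c must be at least 2", call. = FALSE)
  if (m <= 1) stop("fuzziness m must exceed 1", call. = FALSE)
  ux <- unique(x)
  if (nrow(ux) < c) stop("need at least c distinct samples", call. = FALSE)
  centres <- with_seed(seed, ux[sample.int(nrow(ux), c), , drop = FALSE])
  n <- nrow(x)
  memberships <- function(ctr) {
    d2 <- outer(rowSums(x^2), rep(1, c)) - 2 * x %*% t(ctr) +
      outer(rep(1, n), rowSums(ctr^2))
    d2 <- pmax(d2, 0)
    u <- matrix(0, n, c)
    zero <- d2 < 1e-300
    any_zero <- rowSums(zero) > 0
    w <- d2^(-1 / (m - 1))
    u[!any_zero, ] <- w[!any_zero, , drop = FALSE] /
      rowSums(w[!any_zero, , drop = FALSE])
    if (any(any_zero))
      u[any_zero, ] <- zero[any_zero, , drop = FALSE] /
        rowSums(zero[any_zero, , drop = FALSE])
    u
  }
  u <- memberships(centres)
  for (it in seq_len(iter_max)) {
    um <- u^m
    centres <- (t(um) %*% x) / colSums(um)
    u_new <- memberships(centres)
    delta <- max(abs(u_new - u))
    u <- u_new
    if (delta < tol) break
  }
  list(centres = unname(centres), memberships = unname(u))
}

#' Characteristic kinetic curve of a lesion
#'
#' Clusters the in-lesion relative-enhancement signal-time curves by fuzzy
#' c-means and returns the cluster-centre curve with the highest contrast
#' enhancement rate, `(max(curve) - curve[1]) / (t_max - t_1)`. Curves use the
#' 25 time points beginning with contrast enhancement; the time axis starts
#' one frame interval after contrast arrival. Relative enhancement is the raw
#' DCE signal minus the voxel's pre-onset baseline mean.
#'
#' @param dce raw 4-D DCE series.
#' @param lesion_mask binary 3-D array.
#' @param j enhancement-onset frame (1-based).
#' @param times per-frame acquisition times (seconds).
#' @param c,m,seed fuzzy c-means settings (defaults c = 5, m = 2).
#' @return A `ckc` object: `intensity` (25), `times` (25, from onset),
#'   `deltas` (21 four-frame forward differences per second), `delta_times`,
#'   `fallback` (TRUE when the mean curve was used).
#' @export
characteristic_kinetic_curve <- function(dce, lesion_mask, j, times,
                                         c = 5L, m = 2, seed = 1L) {
  inb <- which(lesion_mask > 0)
  if (length(inb) == 0L) stop("empty lesion mask", call. = FALSE)
  n <- dim(dce)[4]
  if (j + 24L > n) stop("DCE series too short for a 25-point curve", call. = FALSE)
  nvox3 <- prod(dim(dce)[1:3])
  dcem <- matrix(dce, nrow = nvox3, ncol = n)[inb, , drop = FALSE]
  base <- if (j > 1L) rowMeans(dcem[, seq_len(j - 1L), drop = FALSE]) else 0
  curves <- dcem[, j:(j + 24L), drop = FALSE] - base
  dt1 <- if (j > 1L) times[j] - times[j - 1L] else mean(diff(times))
  t_ckc <- times[j:(j + 24L)] - times[j] + dt1

  fallback <- FALSE
  centre <- tryCatch({
    if (nrow(curves) < c) stop("lesion too small")
    fcm <- fuzzy_c_means(curves, c = c, m = m, seed = seed)
    rate <- apply(fcm$centres, 1L, function(cv) {
      im <- which.max(cv)
      if (im == 1L) return(-Inf)
      (cv[im] - cv[1L]) / (t_ckc[im] - t_ckc[1L])
    })
    fcm$centres[which.max(rate), ]
  }, error = function(e) {
    fallback <<- TRUE
    colMeans(curves)
  })
  if (fallback) warning("lesion too small or homogeneous; using mean curve",
                        call. = FALSE)
  ii <- 1:21
  deltas <- (centre[ii + 4L] - centre[ii]) / (t_ckc[ii + 4L] - t_ckc[ii])
  structure(list(intensity = as.numeric(centre), times = t_ckc,
                 deltas = as.numeric(deltas), delta_times = t_ckc[ii],
                 fallback = fallback), class = "ckc")
}

#' Extreme fuzzy-cluster centre of in-mask intensities
#'
#' Partitions the in-mask scalar intensities into `c` fuzzy clusters and
#' returns the lowest (ADC) or highest (PET uptake) cluster centre. With
#' fewer than `c` in-mask voxels or fewer than `c` distinct values the
#' in-mask min/max is returned and flagged.
#'
#' @param volume 3-D array.
#' @param mask binary array.
#' @param mode `"lowest"` or `"highest"`.
#' @param c cluster count (default 5).
#' @param seed integer seed.
#' @return Scalar with attribute `fallback`.
#' @export
cluster_extreme_intensity <- function(volume, mask, mode = c("lowest", "highest"),
                                      c = 5L, seed = 1L) {
  mode <- match.arg(mode)
  vals <- volume[mask > 0]
  if (length(vals) == 0L) stop("empty mask", call. = FALSE)
  pick <- function(v) if (mode == "lowest") min(v) else max(v)
  if (length(vals) < c || length(unique(vals)) < c) {
    out <- pick(vals); attr(out, "fallback") <- TRUE; return(out)
  }
  fcm <- fuzzy_c_means(vals, c = c, seed = seed)
  out <- pick(fcm$centres[, 1L])
  attr(out, "fallback") <- FALSE
  out
}

# Separable Gaussian smoothing of a 3-D array (sigma per axis, in voxels).
gaussian_smooth3 <- function(arr, sigma) {
  for (ax in 1:3) {
    s <- sigma[ax]
    if (s <= 0) next
    r <- max(1L, ceiling(3 * s))
    k <- exp(-(seq(-r, r))^2 / (2 * s^2)); k <- k / sum(k)
    d <- dim(arr)
    perm <- c(ax, setdiff(1:3, ax))
    m <- matrix(aperm(arr, perm), nrow = d[ax])
    n <- d[ax]
    cm <- matrix(0, n, n)
    for (o in -r:r) {
      rows <- seq_len(n) + o
      ok <- rows >= 1 & rows <= n
      cm[cbind(rows[ok], seq_len(n)[ok])] <- cm[cbind(rows[ok], seq_len(n)[ok])] +
        k[o + r + 1]
    }
    m <- cm %*% m
    arr <- aperm(array(m, dim(arr)[perm]), order(perm))
  }
  arr
}

#' Shape descriptors of a single 6-connected lesion mask
#'
#' Spacing-aware descriptors: volume (mm^3), surface area (mm^2, estimated as
#' the integral of the gradient magnitude of the Gaussian-smoothed indicator
#' function), compactness `36 pi V^2 / S^3` (1 for a ball), sphericity (its
#' cube root), mean and SD of surface-voxel-to-centroid radii (mm),
#' elongation (ratio of largest to smallest principal axis SD) and convexity
#' `V / V_hull` with the convex-hull volume approximated slice-wise
#' (2-D hulls stacked along z) — an approximation, as is the whole set.
#'
#' @param mask binary 3-D array, one 6-connected component.
#' @param spacing voxel spacing in mm (length 3).
#' @return Named numeric vector of 8 descriptors.
#' @export
shape_descriptors <- function(mask, spacing = c(1, 1, 1)) {
  idx <- which(mask > 0)
  if (length(idx) == 0L) stop("empty mask", call. = FALSE)
  lab <- label_components_6(array(as.integer(mask > 0), dim(mask)))
  if (max(lab) > 1L)
    stop("mask has multiple components; call per lesion", call. = FALSE)
  d <- dim(mask)
  voxvol <- prod(spacing)
  volume <- length(idx) * voxvol

  # surface via |grad| of the smoothed indicator, padded to avoid clipping
  pad <- 6L
  pd <- d + 2L * pad
  ind <- array(0, pd)
  ind[(pad + 1):(pad + d[1]), (pad + 1):(pad + d[2]), (pad + 1):(pad + d[3])] <-
    as.numeric(mask > 0)
  sig_mm <- 0.8 * min(spacing)
  sm <- gaussian_smooth3(ind, sigma = sig_mm / spacing)
  gx <- (sm[c(2:pd[1], pd[1]), , ] - sm[c(1, 1:(pd[1] - 1)), , ]) / (2 * spacing[1])
  gy <- (sm[, c(2:pd[2], pd[2]), ] - sm[, c(1, 1:(pd[2] - 1)), ]) / (2 * spacing[2])
  gz <- (sm[, , c(2:pd[3], pd[3])] - sm[, , c(1, 1:(pd[3] - 1))]) / (2 * spacing[3])
  surface <- sum(sqrt(gx^2 + gy^2 + gz^2)) * voxvol

  compactness <- 36 * pi * volume^2 / surface^3
  sphericity <- compactness^(1 / 3)

  coord <- sweep(arrayInd(idx, d), 2L, spacing, "*")
  centroid <- colMeans(coord)
  # surface voxels: at least one of the 6 face neighbours outside the mask
  inside <- array(FALSE, d); inside[idx] <- TRUE
  offs <- neighbour_offsets_6()
  co_i <- arrayInd(idx, d)
  is_surf <- rep(FALSE, length(idx))
  for (o in seq_len(nrow(offs))) {
    nb <- sweep(co_i, 2L, offs[o, ], "+")
    out <- nb[, 1] < 1 | nb[, 1] > d[1] | nb[, 2] < 1 | nb[, 2] > d[2] |
      nb[, 3] < 1 | nb[, 3] > d[3]
    innb <- !out
    val <- rep(FALSE, length(idx))
    val[innb] <- inside[nb[innb, , drop = FALSE]]
    is_surf <- is_surf | out | !val
  }
  radii <- sqrt(rowSums(sweep(coord[is_surf, , drop = FALSE], 2L, centroid, "-")^2))
  ev <- eigen(stats::cov(coord), symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 1e-12)
  elongation <- sqrt(ev[1] / ev[3])

  # slice-wise convex-hull volume
  co <- arrayInd(idx, d)
  hull_vol <- 0
  for (z in unique(co[, 3])) {
    sl <- co[co[, 3] == z, 1:2, drop = FALSE]
    n_sl <- nrow(sl)
    if (n_sl < 3L) { hull_vol <- hull_vol + n_sl * voxvol; next }
    pts <- sweep(sl, 2L, spacing[1:2], "*")
    h <- grDevices::chull(pts)
    hp <- pts[h, , drop = FALSE]
    a <- abs(sum(hp[, 1] * hp[c(2:nrow(hp), 1), 2] -
                   hp[c(2:nrow(hp), 1), 1] * hp[, 2])) / 2
    hull_vol <- hull_vol + max(a, n_sl * spacing[1] * spacing[2]) * spacing[3]
  }
  convexity <- min(1, volume / hull_vol)

  c(volume = volume, surface = surface, compactness = compactness,
    sphericity = sphericity, radius_mean = mean(radii), radius_sd = sd(radii),
    elongation = elongation, convexity = convexity)
}

lesion_feature_group_tags <- function() {
  c(setNames(rep("DCE", 25), sprintf("ckc_%02d", 1:25)),
    setNames(rep("DCE", 21), sprintf("dckc_%02d", 1:21)),
    setNames(rep("DCE", 4), c("kin_alpha", "kin_tau", "kin_beta", "kin_k")),
    setNames(rep("DCE", 5), c("kin_auc", "kin_cmax", "kin_tmax", "kin_thalf",
                              "kin_mder")),
    setNames(rep("DCE", 78),
             as.vector(t(outer(c("tex_pre", "tex_peak", "tex_post",
                                 "tex_peak_pre", "tex_post_pre", "tex_post_peak"),
                               haralick_names, paste, sep = "_")))),
    setNames("DWI", "adc_low"), setNames("PET", "pet_high"),
    setNames(rep("MORPH", 8), c("morph_volume", "morph_surface",
                                "morph_compactness", "morph_sphericity",
                                "morph_radius_mean", "morph_radius_sd",
                                "morph_elongation", "morph_convexity")))
}

#' Full lesion-level feature vector
#'
#' Canonical concatenation of the characteristic kinetic curve (25 points),
#' its 21 four-frame forward differences, the fitted kinetic parameters
#' (alpha, tau, beta, k), the five 7-minute curve summaries, six 13-feature
#' Haralick blocks (spatial texture on the standardised pre/peak/post volumes
#' and temporal texture on the (pre,peak), (pre,post), (peak,post) pairs),
#' the lowest-ADC and highest-PET fuzzy-cluster centres, and eight shape
#' descriptors — 143 named features with modality group tags (`DCE`, `DWI`,
#' `PET`, `MORPH`) retained for ablations and group rankings.
#'
#' @param study an [mp_study()] (raw; standardisation is applied internally
#'   where needed).
#' @param lesion_id lesion label in the annotation (ignored when `mask` given).
#' @param mask optional binary lesion mask overriding the annotation (e.g. a
#'   predicted blob).
#' @param seed integer seed for the fuzzy clustering steps.
#' @param std_study optional pre-standardised copy of `study` (cache).
#' @return Named numeric vector (length 143) with attributes `groups` and
#'   `flags` (kinetic-fit convergence, clustering fallbacks).
#' @export
lesion_feature_vector <- function(study, lesion_id = NULL, mask = NULL,
                                  seed = 1L, std_study = NULL) {
  if (is.null(mask)) {
    if (is.null(lesion_id)) stop("give lesion_id or mask", call. = FALSE)
    mask <- array(as.integer(study$annotation == lesion_id), dim(study$annotation))
  }
  if (sum(mask) == 0L) stop("empty lesion mask", call. = FALSE)
  if (is.null(std_study)) std_study <- standardise_study(study)
  j <- study$enhancement_onset

  ckc <- suppressWarnings(
    characteristic_kinetic_curve(study$dce, mask, j, study$times, seed = seed))
  fit <- fit_kinetic(ckc, seed = seed)
  tex <- c(haralick13(glcm_3d(std_study$dce_pre, mask)),
           haralick13(glcm_3d(std_study$dce_peak, mask)),
           haralick13(glcm_3d(std_study$dce_post, mask)),
           haralick13(temporal_glcm(std_study$dce_pre, std_study$dce_peak, mask)),
           haralick13(temporal_glcm(std_study$dce_pre, std_study$dce_post, mask)),
           haralick13(temporal_glcm(std_study$dce_peak, std_study$dce_post, mask)))
  adc_low <- cluster_extreme_intensity(study$adc, mask, "lowest", seed = seed)
  pet_high <- cluster_extreme_intensity(study$pet, mask, "highest", seed = seed)
  morph <- shape_descriptors(mask, study$voxel_size)

  out <- c(ckc$intensity, ckc$deltas,
           fit$par[c("alpha", "tau", "beta", "k")], fit$summaries,
           as.numeric(tex), as.numeric(adc_low), as.numeric(pet_high), morph)
  tags <- lesion_feature_group_tags()
  names(out) <- names(tags)
  attr(out, "groups") <- tags
  attr(out, "flags") <- c(fit_converged = fit$converged,
                          ckc_fallback = ckc$fallback,
                          adc_fallback = isTRUE(attr(adc_low, "fallback")),
                          pet_fallback = isTRUE(attr(pet_high, "fallback")))
  out
}

#' Lesion feature table for a cohort
#'
#' @param cohort an `mp_cohort` or list of studies.
#' @param seed integer seed passed to the clustering steps.
#' @return Data.frame: `patient`, `lesion`, `class`, then the 143 features;
#'   attribute `groups` maps feature names to modality groups.
#' @export
cohort_lesion_table <- function(cohort, seed = 1L) {
  studies <- as_study_list(cohort)
  rows <- list()
  for (s in studies) {
    std <- standardise_study(s)
    ids <- sort(unique(s$annotation[s$annotation > 0]))
    for (l in ids) {
      fv <- lesion_feature_vector(s, lesion_id = l, seed = seed, std_study = std)
      rows[[length(rows) + 1L]] <- data.frame(
        patient = s$patient_id, lesion = l,
        class = unname(s$lesion_labels[as.character(l)]),
        t(as.numeric(fv)), check.names = FALSE)
      names(rows[[length(rows)]])[-(1:3)] <- names(fv)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "groups") <- lesion_feature_group_tags()
  out
}
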