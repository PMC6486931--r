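#' Configuration for the synthetic multiparametric phantom cohort
#'
#' The generator emulates co-registered breast PET/MRI studies: a DCE-MRI time
#' series whose lesion voxels follow class-specific enhancement kinetics
#' (malignant: fast wash-in then washout; benign: slow persistent
#' enhancement), high-resolution pre/peak/post contrast volumes, DWI b0/b850
#' derived from a ground-truth ADC map by mono-exponential decay
#' `S(b) = S0 exp(-b ADC)`, an FDG-PET volume with elevated lesion uptake,
#' enhancing vessel-like distractor tubes, and additive Gaussian noise.
#'
#' @param n_patients number of studies to generate.
#' @param grid_shape integer length-3 voxel grid.
#' @param voxel_size isotropic voxel edge in mm.
#' @param n_frames DCE frame count; must allow a 26-frame window from onset.
#' @param frame_interval seconds per DCE acquisition (default 13.2).
#' @param enhancement_onset_frame 1-based index of the first enhancing frame.
#' @param lesion_radius_range lesion radius range in mm.
#' @param lesions_per_patient lesions per study.
#' @param class_mix fraction of lesions that are malignant.
#' @param kinetic_priors per-class uniform ranges for (G, alpha, tau, t_half,
#'   beta, k); see defaults.
#' @param hetero_sd per-class SD of the multiplicative intra-lesion
#'   enhancement-scale field (malignant lesions enhance more heterogeneously).
#' @param adc_levels mean ADC (mm^2/s) for malignant/benign lesion and breast
#'   background.
#' @param pet_levels mean FDG uptake (arbitrary units) per class and background.
#' @param vessel_count distractor tubes per breast.
#' @param noise_sd additive Gaussian noise SD, as a fraction of each
#'   modality's tissue-scale signal.
#' @param seed integer seed; the cohort is a pure function of the config.
#' @return A `phantom_config` list.
#' @export
phantom_config <- function(n_patients = 8L,
                           grid_shape = c(40L, 40L, 24L),
                           voxel_size = 2,
                           n_frames = 34L,
                           frame_interval = 13.2,
                           enhancement_onset_frame = 7L,
                           lesion_radius_range = c(6, 12),
                           lesions_per_patient = 1L,
                           class_mix = 2 / 3,
                           kinetic_priors = list(
                             malignant = list(G = c(1.8, 2.6), alpha = c(1, 2),
                                              tau = c(10, 25), t_half = c(50, 90),
                                              beta = c(-7e-4, -3e-4), k = c(1, 1)),
                             benign = list(G = c(0.8, 1.4), alpha = c(1, 2),
                                           tau = c(40, 70), t_half = c(160, 240),
                                           beta = c(-1.5e-4, -0.5e-4), k = c(1, 1))),
                           hetero_sd = c(malignant = 0.25, benign = 0.08),
                           adc_levels = c(malignant = 0.9e-3, benign = 1.6e-3,
                                          background = 2.0e-3),
                           pet_levels = c(malignant = 5, benign = 2, background = 1),
                           vessel_count = 2L,
                           noise_sd = 0.05,
                           seed = 1L) {
  cfg <- list(n_patients = as.integer(n_patients), grid_shape = as.integer(grid_shape),
              voxel_size = voxel_size, n_frames = as.integer(n_frames),
              frame_interval = frame_interval,
              enhancement_onset_frame = as.integer(enhancement_onset_frame),
              lesion_radius_range = lesion_radius_range,
              lesions_per_patient = as.integer(lesions_per_patient),
              class_mix = class_mix, kinetic_priors = kinetic_priors,
              hetero_sd = hetero_sd, adc_levels = adc_levels,
              pet_levels = pet_levels, vessel_count = as.integer(vessel_count),
              noise_sd = noise_sd, seed = as.integer(seed))
  validate_phantom_config(cfg)
  structure(cfg, class = "phantom_config")
}

validate_phantom_config <- function(cfg) {
  if (cfg$n_frames < cfg$enhancement_onset_frame + 25L)
    stop("n_frames must cover a 26-frame window from enhancement onset", call. = FALSE)
  if (cfg$class_mix < 0 || cfg$class_mix > 1) stop("class_mix must be in [0,1]", call. = FALSE)
  if (any(cfg$lesion_radius_range <= 0)) stop("lesion radii must be positive", call. = FALSE)
  if (cfg$noise_sd < 0) stop("noise_sd must be non-negative", call. = FALSE)
  if (length(cfg$grid_shape) != 3L || any(cfg$grid_shape < 8L))
    stop("grid_shape must be three axes of at least 8 voxels", call. = FALSE)
  invisible(cfg)
}

draw_kinetic_params <- function(prior) {
  p <- vapply(prior, function(rg) runif(1, rg[1], rg[2]), numeric(1))
  p[c("G", "alpha", "tau", "t_half", "beta", "k")]
}

# Ellipsoidal breast volume centred in the grid.
breast_ellipsoid <- function(grid_shape) {
  ax <- (grid_shape - 1) / 2
  semi <- 0.45 * grid_shape
  g <- expand.grid(x = seq_len(grid_shape[1]), y = seq_len(grid_shape[2]),
                   z = seq_len(grid_shape[3]))
  d <- ((g$x - 1 - ax[1]) / semi[1])^2 + ((g$y - 1 - ax[2]) / semi[2])^2 +
    ((g$z - 1 - ax[3]) / semi[3])^2
  array(as.integer(d <= 1), grid_shape)
}

# Voxel indices of a digital ball: centres within radius r (voxels) of c.
ball_voxels <- function(centre, r, grid_shape) {
  lo <- pmax(1L, floor(centre - r)); hi <- pmin(grid_shape, ceiling(centre + r))
  g <- expand.grid(x = lo[1]:hi[1], y = lo[2]:hi[2], z = lo[3]:hi[3])
  d2 <- (g$x - centre[1])^2 + (g$y - centre[2])^2 + (g$z - centre[3])^2
  g <- g[d2 <= r^2, , drop = FALSE]
  (g$x) + (g$y - 1L) * grid_shape[1] + (g$z - 1L) * grid_shape[1] * grid_shape[2]
}

# Voxel indices within radius r of the segment p1-p2 (all in voxel units).
tube_voxels <- function(p1, p2, r, grid_shape) {
  g <- expand.grid(x = seq_len(grid_shape[1]), y = seq_len(grid_shape[2]),
                   z = seq_len(grid_shape[3]))
  v <- p2 - p1
  len2 <- sum(v^2)
  w <- cbind(g$x - p1[1], g$y - p1[2], g$z - p1[3])
  tt <- pmin(1, pmax(0, (w %*% v) / len2))
  d2 <- (w[, 1] - tt * v[1])^2 + (w[, 2] - tt * v[2])^2 + (w[, 3] - tt * v[3])^2
  which(d2 <= r^2)
}

#' Generate a seeded synthetic multiparametric cohort
#'
#' Produces one [mp_study()] per patient plus its ground truth (lesion label
#' volume, per-lesion class and the true kinetic parameters). Identical
#' config (including seed) yields a bit-identical cohort.
#'
#' @param config a [phantom_config()].
#' @return A list of class `mp_cohort`; each element has `$study` and `$truth`.
#' @export
make_cohort <- function(config) {
  validate_phantom_config(config)
  if (config$n_patients == 0L) return(structure(list(), class = "mp_cohort"))
  cohort <- with_seed(config$seed, {
    lapply(seq_len(config$n_patients), function(p) {
      make_phantom_study(config, patient_id = sprintf("phantom%02d", p))
    })
  })
  structure(cohort, class = "mp_cohort")
}

# Build one study; assumes RNG state is already seeded by the caller.
make_phantom_study <- function(config, patient_id) {
  gs <- config$grid_shape
  r_vox_max <- max(config$lesion_radius_range) / config$voxel_size
  if (2 * r_vox_max + 2 > min(gs))
    stop("grid too small for the requested lesion radius", call. = FALSE)

  mask <- breast_ellipsoid(gs)
  nvox <- prod(gs)
  annotation <- array(0L, gs)
  n_frames <- config$n_frames
  j <- config$enhancement_onset_frame
  times <- (seq_len(n_frames) - 1) * config$frame_interval
  # enhancement clock: contrast arrives one interval before frame j
  t_enh <- ifelse(seq_len(n_frames) >= j,
                  (seq_len(n_frames) - j + 1) * config$frame_interval, NA_real_)

  n_les <- config$lesions_per_patient
  classes <- character(0); kinetics <- list()
  centres <- list(); radii <- numeric(0)
  gain <- numeric(nvox)           # per-voxel enhancement scale field
  curve_of <- list()              # per-lesion kinetic parameter vector
  for (l in seq_len(n_les)) {
    cls <- if (runif(1) < config$class_mix) "malignant" else "benign"
    r_mm <- runif(1, config$lesion_radius_range[1], config$lesion_radius_range[2])
    r_vox <- r_mm / config$voxel_size
    placed <- FALSE
    for (try in 1:200) {
      centre <- vapply(gs, function(d) runif(1, 1 + r_vox + 1, d - r_vox - 1), numeric(1))
      vox <- ball_voxels(centre, r_vox, gs)
      if (all(mask[vox] == 1L) && all(annotation[vox] == 0L)) { placed <- TRUE; break }
    }
    if (!placed) stop("could not place lesion inside breast mask", call. = FALSE)
    annotation[vox] <- l
    classes[l] <- cls
    centres[[l]] <- centre; radii[l] <- r_vox
    kin <- draw_kinetic_params(config$kinetic_priors[[cls]])
    kinetics[[l]] <- kin
    gain[vox] <- pmax(0.2, 1 + config$hetero_sd[[cls]] * rnorm(length(vox)))
    curve_of[[l]] <- kin
  }
  names(kinetics) <- seq_len(n_les)

  inb <- which(mask == 1L)
  # smooth fibroglandular-like anatomy so pre-contrast tissue has texture
  anat <- gaussian_smooth3(array(rnorm(nvox), gs), sigma = c(2, 2, 2))
  anat <- anat / sd(anat) * 0.12
  baseline <- array(0.05, gs)
  baseline[inb] <- pmax(0.4, 1 + anat[inb])

  # enhancement per lesion voxel per frame
  enhance_at <- function(t) {            # 3-D enhancement field at elapsed time t
    e <- numeric(nvox)
    for (l in seq_along(curve_of)) {
      vox <- which(annotation == l)
      kin <- curve_of[[l]]
      e[vox] <- gain[vox] * enhancement_curve(t, kin[["G"]], kin[["alpha"]],
                                              kin[["tau"]], kin[["t_half"]],
                                              kin[["beta"]], kin[["k"]])
    }
    array(e, gs)
  }

  dce <- array(0, c(gs, n_frames))
  for (i in seq_len(n_frames)) {
    fr <- baseline
    if (i >= j) fr <- fr + enhance_at(t_enh[i])
    dce[, , , i] <- fr
  }

  # pre/peak/post high-resolution volumes from the same kinetic model
  peak_t <- if (length(curve_of)) {
    stats::median(vapply(curve_of, function(k) kinetic_summaries(k)[["tmax"]], numeric(1)))
  } else 150
  end_t <- t_enh[n_frames]
  dce_pre <- baseline
  dce_peak <- baseline + enhance_at(peak_t)
  dce_post <- baseline + enhance_at(end_t)

  adc <- array(0, gs); adc[inb] <- config$adc_levels[["background"]]
  pet <- array(0.1, gs); pet[inb] <- config$pet_levels[["background"]]
  for (l in seq_len(n_les)) {
    vox <- which(annotation == l)
    adc[vox] <- config$adc_levels[[classes[l]]]
    pet[vox] <- config$pet_levels[[classes[l]]]
  }
  dwi_b0 <- array(0.02, gs); dwi_b0[inb] <- pmax(0.4, 1 + anat[inb])
  dwi_b850 <- dwi_b0 * exp(-850 * adc)

  study <- mp_study(dce = dce, times = times,
                    dce_pre = dce_pre, dce_peak = dce_peak, dce_post = dce_post,
                    dwi_b0 = dwi_b0, dwi_b850 = dwi_b850, adc = adc, pet = pet,
                    breast_mask = mask, annotation = annotation,
                    lesion_labels = setNames(classes, seq_len(n_les)),
                    enhancement_onset = j, voxel_size = rep(config$voxel_size, 3),
                    patient_id = patient_id)
  study <- embed_vessels(study, config)
  study <- add_phantom_noise(study, config)
  truth <- list(lesion_masks = annotation, classes = setNames(classes, seq_len(n_les)),
                kinetics = kinetics, peak_time = peak_t,
                centres = centres, radii_vox = radii)
  list(study = study, truth = truth)
}

#' Add enhancing vessel-like distractor tubes to a study
#'
#' Tubes enhance in the DCE series and the peak/post volumes with fast,
#' vascular kinetics but keep background-level ADC, DWI and PET, and are
#' excluded from the lesion annotation — they exist so that false-positive
#' removal in post-processing is exercised.
#'
#' @param study an [mp_study()].
#' @param config a [phantom_config()]; `vessel_count` tubes are added.
#' @return The modified study (unchanged when `vessel_count` is 0).
#' @export
embed_vessels <- function(study, config) {
  if (config$vessel_count == 0L) return(study)
  gs <- dim(study$breast_mask)
  if (sum(study$breast_mask) == 0L) stop("breast mask is empty", call. = FALSE)
  j <- study$enhancement_onset
  n_frames <- dim(study$dce)[4]
  t_enh <- (seq_len(n_frames) - j + 1) * diff(study$times[1:2])
  kin <- c(G = 1.6, alpha = 1, tau = 8, t_half = 40, beta = -8e-4, k = 1)
  inb <- which(study$breast_mask == 1L & study$annotation == 0L)
  coord <- arrayInd(inb, gs)
  for (v in seq_len(config$vessel_count)) {
    repeat {
      p1 <- coord[sample.int(nrow(coord), 1L), ]
      p2 <- coord[sample.int(nrow(coord), 1L), ]
      if (sqrt(sum((p1 - p2)^2)) > min(gs) / 2) break
    }
    vox <- tube_voxels(p1, p2, r = 1.2, grid_shape = gs)
    vox <- vox[study$breast_mask[vox] == 1L & study$annotation[vox] == 0L]
    if (length(vox) == 0L) next
    for (i in seq_len(n_frames)) {
      if (i < j) next
      e <- enhancement_curve(t_enh[i], kin[["G"]], kin[["alpha"]], kin[["tau"]],
                             kin[["t_half"]], kin[["beta"]], kin[["k"]])
      fr <- frame_of(study$dce, i); fr[vox] <- fr[vox] + e
      study$dce[, , , i] <- fr
    }
    peak_e <- kinetic_summaries(kin)[["cmax"]]
    study$dce_peak[vox] <- study$dce_peak[vox] + peak_e
    study$dce_post[vox] <- study$dce_post[vox] +
      enhancement_curve(t_enh[n_frames], kin[["G"]], kin[["alpha"]], kin[["tau"]],
                        kin[["t_half"]], kin[["beta"]], kin[["k"]])
  }
  study
}

# Additive Gaussian noise, scaled per modality to its tissue-level signal.
add_phantom_noise <- function(study, config) {
  s <- config$noise_sd
  if (s == 0) return(study)
  n <- length(study$dce)
  study$dce <- study$dce + array(rnorm(n, sd = s), dim(study$dce))
  for (f in c("dce_pre", "dce_peak", "dce_post", "dwi_b0", "dwi_b850"))
    study[[f]] <- study[[f]] + array(rnorm(length(study[[f]]), sd = s), dim(study[[f]]))
  study$adc <- pmax(study$adc + array(rnorm(length(study$adc), sd = s * 2e-4),
                                      dim(study$adc)), 1e-5)
  study$pet <- study$pet + array(rnorm(length(study$pet),
                                       sd = s * config$pet_levels[["background"]]),
                                 dim(study$pet))
  study
}

#' @export
print.mp_cohort <- function(x, ...) {
  cat(sprintf("Synthetic multiparametric cohort: %d studies\n", length(x)))
  if (length(x)) {
    cls <- unlist(lapply(x, function(e) unname(e$truth$classes)))
    cat(sprintf("  lesions: %d (%d malignant, %d benign)\n", length(cls),
                sum(cls == "malignant"), sum(cls == "benign")))
    cat(sprintf("  grid %s, %d DCE frames\n",
                paste(dim(x[[1]]$study$breast_mask), collapse = "x"),
                dim(x[[1]]$study$dce)[4]))
  }
  invisible(x)
}
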