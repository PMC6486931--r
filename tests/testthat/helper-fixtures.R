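# Shared fixtures, generated once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, expr, envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# Small noise-free cohort for fast structural tests.
tiny_cohort <- function() cached("tiny", make_cohort(
  phantom_config(n_patients = 2, grid_shape = c(24, 24, 16), noise_sd = 0,
                 vessel_count = 1, lesion_radius_range = c(5, 7), seed = 21)))

# Moderate noisy cohort used by the end-to-end segmentation evaluation.
seg_cohort <- function() cached("seg", make_cohort(phantom_config(n_patients = 8,
                                                                  seed = 11)))

# 30-lesion cohort and its lesion feature table for classification runs.
cls_cohort <- function() cached("cls", make_cohort(phantom_config(n_patients = 30,
                                                                  seed = 7)))
cls_table <- function() cached("cls_tab", cohort_lesion_table(cls_cohort(), seed = 5))

# Hand-built minimal study: constant-in-time DCE, flat anatomy, one cubic
# lesion; useful for exact-value feature tests.
manual_study <- function(n_frames = 34, onset = 7, grid = c(10, 10, 6)) {
  mask <- array(1L, grid)
  dce <- array(rep(seq_len(prod(grid)) / prod(grid), n_frames), c(grid, n_frames))
  vol <- array(seq_len(prod(grid)) / prod(grid), grid)
  ann <- array(0L, grid); ann[4:6, 4:6, 3:4] <- 1L
  mp_study(dce = dce, times = (seq_len(n_frames) - 1) * 13.2,
           dce_pre = vol, dce_peak = vol * 2, dce_post = vol * 1.5,
           dwi_b0 = vol, dwi_b850 = vol * 0.5, adc = vol * 1e-3, pet = vol,
           breast_mask = mask, annotation = ann,
           lesion_labels = c("1" = "malignant"), enhancement_onset = onset,
           voxel_size = c(1, 1, 1), patient_id = "manual")
}

# Digital ball mask of radius r voxels centred in its own padded grid.
ball_mask <- function(r, pad = 3) {
  n <- 2 * ceiling(r) + 1 + 2 * pad
  c0 <- (n + 1) / 2
  g <- expand.grid(x = 1:n, y = 1:n, z = 1:n)
  array(as.integer((g$x - c0)^2 + (g$y - c0)^2 + (g$z - c0)^2 <= r^2), c(n, n, n))
}
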