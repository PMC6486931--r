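#' Quantise in-mask intensities to equal-width grey-level bins
#'
#' @param volume 3-D array.
#' @param mask binary array.
#' @param bins number of grey-value bins (default 128).
#' @param range optional pooled range (used by [temporal_glcm()] so both
#'   volumes share bins); default the in-mask range of `volume`.
#' @return Integer array: bin 1..bins inside the mask, 0 outside.
#' @export
quantise_greylevels <- function(volume, mask, bins = 128L, range = NULL) {
  if (sum(mask > 0) == 0L) stop("empty mask", call. = FALSE)
  vals <- volume[mask > 0]
  if (any(!is.finite(vals))) stop("volume must be finite inside the mask", call. = FALSE)
  if (is.null(range)) range <- c(min(vals), max(vals))
  q <- array(0L, dim(volume))
  if (diff(range) == 0) { q[mask > 0] <- 1L; return(q) }
  b <- floor((volume[mask > 0] - range[1]) / diff(range) * bins) + 1L
  q[mask > 0] <- pmin(as.integer(b), as.integer(bins))
  q
}

# Accumulate pair counts (a_i, b_i) into a bins x bins matrix.
accumulate_pairs <- function(a, b, bins) {
  counts <- tabulate(a + (b - 1L) * bins, nbins = bins * bins)
  matrix(counts, bins, bins)
}

finalise_glcm <- function(counts, bins, n_pairs) {
  counts <- (counts + t(counts)) / 2
  if (sum(counts) == 0) stop("no co-occurring voxel pairs in mask", call. = FALSE)
  p <- counts / sum(counts)
  structure(p, class = c("cooc_matrix", class(p)), bins = bins, n_pairs = n_pairs)
}

#' 3-D grey-level co-occurrence matrix over the 26-neighbourhood
#'
#' In-mask intensities are quantised to `bins` equal-width grey levels over
#' the in-mask range; co-occurrences are accumulated over all 26 unit offsets
#' for voxel pairs that both lie in the mask, symmetrised and normalised to
#' sum 1. Equal-width binning over the in-mask range makes the downstream
#' Haralick features invariant to affine intensity rescaling.
#'
#' @param volume 3-D array.
#' @param mask binary array (the lesion).
#' @param bins grey-level count (default 128).
#' @return A `cooc_matrix`: `bins x bins` matrix summing to 1.
#' @export
glcm_3d <- function(volume, mask, bins = 128L) {
  q <- quantise_greylevels(volume, mask, bins)
  d <- dim(q)
  counts <- matrix(0, bins, bins)
  n_pairs <- 0L
  offs <- neighbour_offsets_26()
  for (o in seq_len(nrow(offs))) {
    dx <- offs[o, 1]; dy <- offs[o, 2]; dz <- offs[o, 3]
    if (any(pmax(1, 1 + c(dx, dy, dz)) > pmin(d, d + c(dx, dy, dz)))) next
    xr <- max(1, 1 + dx):min(d[1], d[1] + dx)
    yr <- max(1, 1 + dy):min(d[2], d[2] + dy)
    zr <- max(1, 1 + dz):min(d[3], d[3] + dz)
    a <- q[xr, yr, zr, drop = FALSE]
    b <- q[xr - dx, yr - dy, zr - dz, drop = FALSE]
    ok <- a > 0L & b > 0L
    if (!any(ok)) next
    counts <- counts + accumulate_pairs(a[ok], b[ok], as.integer(bins))
    n_pairs <- n_pairs + sum(ok)
  }
  finalise_glcm(counts, as.integer(bins), n_pairs)
}

#' Spatio-temporal co-occurrence matrix of two time points
#'
#' One co-occurrence per in-mask voxel: the pair of quantised intensities of
#' the same spatial position in `vol_a` and `vol_b` (e.g. peak and post
#' contrast), capturing the homogeneity of contrast uptake over time. Both
#' volumes share equal-width bins over their pooled in-mask range.
#'
#' @param vol_a,vol_b 3-D arrays on the same grid.
#' @param mask binary array.
#' @param bins grey-level count (default 128).
#' @return A `cooc_matrix` with attribute `n_pairs` equal to the mask size.
#' @export
temporal_glcm <- function(vol_a, vol_b, mask, bins = 128L) {
  if (!identical(dim(vol_a), dim(vol_b))) stop("volumes must share a grid", call. = FALSE)
  inb <- which(mask > 0)
  if (length(inb) == 0L) stop("empty mask", call. = FALSE)
  pooled <- range(c(vol_a[inb], vol_b[inb]))
  qa <- quantise_greylevels(vol_a, mask, bins, range = pooled)
  qb <- quantise_greylevels(vol_b, mask, bins, range = pooled)
  counts <- accumulate_pairs(qa[inb], qb[inb], as.integer(bins))
  finalise_glcm(counts, as.integer(bins), length(inb))
}

haralick_names <- c("energy", "contrast", "correlation", "variance",
                    "homogeneity", "sum_average", "sum_variance", "sum_entropy",
                    "entropy", "difference_variance", "difference_entropy",
                    "imc1", "imc2")

xlogx <- function(p) ifelse(p > 0, p * log(p), 0)

#' The 13 Haralick second-order statistics of a normalised GLCM
#'
#' Energy (angular second moment), contrast, correlation, variance (sum of
#' squares), homogeneity (inverse difference moment), sum average, sum
#' variance, sum entropy, entropy, difference variance, difference entropy and
#' the two information measures of correlation. Natural logarithms are used;
#' `0 log 0` is taken as 0. With degenerate marginals (zero variance) the
#' correlation-type statistics are defined as 0 and flagged via the
#' `degenerate` attribute.
#'
#' @param glcm a `cooc_matrix` (or any normalised symmetric matrix).
#' @return Named numeric vector of length 13.
#' @export
haralick13 <- function(glcm) {
  p <- unclass(glcm)
  ng <- nrow(p)
  if (abs(sum(p) - 1) > 1e-8) stop("GLCM must be normalised to sum 1", call. = FALSE)
  i <- row(p); j <- col(p)
  px <- rowSums(p); py <- colSums(p)
  mu_x <- sum(seq_len(ng) * px); mu_y <- sum(seq_len(ng) * py)
  sd_x <- sqrt(sum((seq_len(ng) - mu_x)^2 * px))
  sd_y <- sqrt(sum((seq_len(ng) - mu_y)^2 * py))
  degenerate <- sd_x == 0 || sd_y == 0

  energy <- sum(p^2)
  contrast <- sum((i - j)^2 * p)
  correlation <- if (degenerate) 0 else sum((i - mu_x) * (j - mu_y) * p) / (sd_x * sd_y)
  variance <- sum((i - mu_x)^2 * p)
  homogeneity <- sum(p / (1 + (i - j)^2))

  # distributions of i + j (2..2Ng) and |i - j| (0..Ng-1)
  psum <- vapply(2:(2 * ng), function(k) sum(p[i + j == k]), numeric(1))
  pdif <- vapply(0:(ng - 1), function(k) sum(p[abs(i - j) == k]), numeric(1))
  ks <- 2:(2 * ng); kd <- 0:(ng - 1)
  sum_average <- sum(ks * psum)
  sum_variance <- sum((ks - sum_average)^2 * psum)
  sum_entropy <- -sum(xlogx(psum))
  entropy <- -sum(xlogx(p))
  dif_average <- sum(kd * pdif)
  difference_variance <- sum((kd - dif_average)^2 * pdif)
  difference_entropy <- -sum(xlogx(pdif))

  hx <- -sum(xlogx(px)); hy <- -sum(xlogx(py))
  pxy <- outer(px, py)
  hxy1 <- -sum(ifelse(pxy > 0, p * log(pxy), 0))
  hxy2 <- -sum(xlogx(pxy))
  imc1 <- if (max(hx, hy) == 0) 0 else (entropy - hxy1) / max(hx, hy)
  imc2 <- sqrt(pmax(0, 1 - exp(-2 * (hxy2 - entropy))))

  out <- c(energy, contrast, correlation, variance, homogeneity, sum_average,
           sum_variance, sum_entropy, entropy, difference_variance,
           difference_entropy, imc1, imc2)
  names(out) <- haralick_names
  attr(out, "degenerate") <- degenerate
  out
}
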