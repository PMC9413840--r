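# Amplitude of low-frequency fluctuations, z-normalisation, Gaussian
# smoothing of volumes, and spherical small-volume masks.

#' Amplitude of low-frequency fluctuations
#'
#' FFT of the series, square root of the power spectrum (scaled to
#' one-sided amplitude, 2/T |FFT|), averaged over frequency bins inside
#' the band; the DC bin is always excluded and bin inclusion is
#' \code{low <= f <= high}.
#'
#' @param y numeric time series (length >= 16)
#' @param tr_seconds sampling interval
#' @param band two-element numeric, band edges in Hz (default 0.01-0.08)
#' @return non-negative scalar ALFF
#' @export
compute_alff <- function(y, tr_seconds, band = c(0.01, 0.08)) {
  T_n <- length(y)
  if (T_n < 16) stop_invalid("need at least 16 time points")
  nyq <- 1 / (2 * tr_seconds)
  if (band[1] <= 0 || band[2] > nyq || band[1] >= band[2])
    stop_invalid("band must satisfy 0 < low < high <= Nyquist")
  freqs <- (seq_len(T_n) - 1) / (T_n * tr_seconds)
  half <- 2:floor(T_n / 2 + 1)          # positive frequencies, DC excluded
  amp <- 2 / T_n * Mod(stats::fft(y))
  in_band <- half[freqs[half] >= band[1] & freqs[half] <= band[2]]
  if (!length(in_band))
    stop_invalid("no frequency bins inside the band; resolution is ",
                 signif(1 / (T_n * tr_seconds), 4), " Hz")
  mean(amp[in_band])
}

#' z-score a map of values
#'
#' Centred and scaled with the sample (n - 1) standard deviation over all
#' included units.
#'
#' @param values numeric vector (ROI or voxel values), length >= 2
#' @return z-scored vector (mean 0, SD 1)
#' @export
zscore_map <- function(values) {
  if (length(values) < 2) stop_invalid("need at least 2 units")
  s <- stats::sd(values)
  if (s == 0) stop_invalid("zero variance: map cannot be z-scored")
  (values - mean(values)) / s
}

# 1-D discrete Gaussian kernel for a given sigma in voxels.
gaussian_kernel_1d <- function(sigma_vox) {
  if (sigma_vox == 0) return(1)
  r <- max(1L, ceiling(4 * sigma_vox))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma_vox^2))
  k / sum(k)
}

# Reflective 1-D convolution along one margin of a 3D array.
convolve_reflect_1d <- function(v, kernel) {
  r <- (length(kernel) - 1L) / 2L
  if (r == 0) return(v)
  n <- length(v)
  if (r > n) stop_invalid("kernel radius exceeds volume extent")
  # half-sample symmetric padding: ..v3,v2,v1 | v1..vn | vn,vn-1,..
  idx <- c(rev(seq_len(r)), seq_len(n), n + 1L - seq_len(r))
  ext <- v[idx]
  out <- stats::filter(ext, kernel, sides = 2)
  as.numeric(out[(r + 1L):(r + n)])
}

#' Separable Gaussian smoothing of a 3D volume
#'
#' Applies a 1-D Gaussian along each axis with
#' sigma = FWHM / (2 sqrt(2 ln 2)) / voxel size. Boundaries are handled by
#' reflection, so constant volumes (and the global mean) are preserved.
#'
#' @param volume 3D numeric array
#' @param fwhm_mm full width at half maximum in mm (0 = identity)
#' @param voxel_size_mm per-axis voxel size in mm (length 1 or 3)
#' @return smoothed array, same dimensions
#' @export
gaussian_smooth <- function(volume, fwhm_mm, voxel_size_mm) {
  stopifnot(length(dim(volume)) == 3)
  if (fwhm_mm < 0) stop_invalid("fwhm must be non-negative")
  voxel_size_mm <- rep(voxel_size_mm, length.out = 3)
  if (any(voxel_size_mm <= 0)) stop_invalid("voxel sizes must be positive")
  if (fwhm_mm == 0) return(volume)
  sigma_vox <- fwhm_mm / (2 * sqrt(2 * log(2))) / voxel_size_mm
  out <- volume
  for (axis in 1:3) {
    k <- gaussian_kernel_1d(sigma_vox[axis])
    out <- apply(out, setdiff(1:3, axis), convolve_reflect_1d, kernel = k)
    # apply() returns the convolved axis first; rotate back into place
    out <- aperm(out, order(c(axis, setdiff(1:3, axis))))
  }
  out
}

#' Packaged small-volume sphere centres
#'
#' The five MNI peak coordinates (mm) used for small-volume correction,
#' available under the preset name \code{"paper_svc_spheres"}: precuneus,
#' superior frontal gyrus/SMA, superior temporal/frontal orbital,
#' superior temporal/insula, and right superior temporal area.
#'
#' @return 5 x 3 numeric matrix of MNI mm coordinates
#' @export
svc_sphere_centers <- function() {
  m <- rbind(c(3, -48, 69), c(12, -3, 75), c(36, 21, -21),
             c(-45, 9, -15), c(60, -21, 15))
  rownames(m) <- c("precuneus", "SFG_SMA", "STG_orbitofrontal",
                   "STG_insula", "right_STG")
  colnames(m) <- c("x", "y", "z")
  m
}

#' Build a spherical small-volume mask
#'
#' A voxel is included when its centre lies within \code{radius_mm} of any
#' sphere centre (Euclidean distance in mm).
#'
#' @param centers matrix of MNI mm coordinates (one row per sphere), or
#'   the preset name \code{"paper_svc_spheres"}
#' @param radius_mm sphere radius (default 5)
#' @param grid list describing the voxel lattice: \code{dim} (3 integers),
#'   \code{voxel_size_mm} (length 1 or 3), \code{origin_mm} (mm coordinate
#'   of voxel [1,1,1], default c(0,0,0))
#' @return list of class \code{sphere_mask}: \code{mask} (logical 3D
#'   array), \code{included_voxels} (index matrix), \code{centers},
#'   \code{radius_mm}, \code{grid}
#' @export
build_sphere_mask <- function(centers, radius_mm = 5, grid) {
  if (is.character(centers)) {
    if (centers != "paper_svc_spheres")
      stop_invalid("unknown mask preset: ", centers)
    centers <- svc_sphere_centers()
  }
  centers <- as.matrix(centers)
  vs <- rep(grid$voxel_size_mm, length.out = 3)
  origin <- if (is.null(grid$origin_mm)) c(0, 0, 0) else grid$origin_mm
  dims <- grid$dim
  co <- lapply(1:3, function(a) origin[a] + (seq_len(dims[a]) - 1) * vs[a])
  mask <- array(FALSE, dim = dims)
  for (s in seq_len(nrow(centers))) {
    d2 <- outer(outer((co[[1]] - centers[s, 1])^2,
                      (co[[2]] - centers[s, 2])^2, `+`),
                (co[[3]] - centers[s, 3])^2, `+`)
    mask <- mask | (d2 <= radius_mm^2)
  }
  structure(list(mask = mask, included_voxels = which(mask, arr.ind = TRUE),
                 centers = centers, radius_mm = radius_mm, grid = grid),
            class = "sphere_mask")
}

#' ROI-level ALFF table
#'
#' Computes ALFF for every ROI of a (typically nuisance-regressed,
#' unfiltered) time-series object and z-scores the map across ROIs.
#'
#' @param roi_ts a \code{\link{roi_timeseries}}
#' @param band ALFF band in Hz
#' @return data frame: \code{roi}, \code{alff}, \code{alff_z}
#' @export
alff_by_roi <- function(roi_ts, band = c(0.01, 0.08)) {
  vals <- apply(roi_ts$values, 1, compute_alff,
                tr_seconds = roi_ts$tr_seconds, band = band)
  data.frame(roi = roi_ts$roi_labels, alff = vals,
             alff_z = zscore_map(vals), row.names = NULL)
}
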