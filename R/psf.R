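# Gaussian blur operators built as symmetric banded matrices. Symmetry makes
# every blur self-adjoint, which keeps the OSEM forward/back projector pair
# exactly matched. Kernels are normalized to unit sum; rows near the volume
# boundary lose mass (no renormalization -- renormalizing would break
# symmetry).

blur_matrix_1d <- function(n, sigma_vox) {
  if (sigma_vox <= 1e-8) return(diag(n))
  K <- ceiling(4 * sigma_vox)
  off <- -K:K
  k <- exp(-off^2 / (2 * sigma_vox^2))
  k <- k / sum(k)
  B <- matrix(0, n, n)
  idx <- abs(outer(seq_len(n), seq_len(n), "-"))
  sel <- idx <= K
  B[sel] <- k[idx[sel] + K + 1L]
  B
}

# cache of expensive deterministic operators (rotation matrices, PSF stacks)
.vq_cache <- new.env(parent = emptyenv())

cache_get <- function(key, builder) {
  if (!exists(key, envir = .vq_cache, inherits = FALSE)) {
    assign(key, builder(), envir = .vq_cache)
  }
  get(key, envir = .vq_cache, inherits = FALSE)
}

# distance-dependent collimator+intrinsic response:
# FWHM(d) = sqrt(fwhm_intrinsic^2 + (a*d + b)^2), d = source-to-collimator
# distance in mm
psf_fwhm_mm <- function(psf, distance_mm) {
  sqrt(psf$fwhm_intrinsic_mm^2 + (psf$a * distance_mm + psf$b_mm)^2)
}

# per-depth blur matrix stacks for the in-plane (u) and axial (v) detector
# axes; depth index d runs along the rotated y axis, detector beyond d = ny
psf_matrix_stack <- function(grid, cfg) {
  psf <- cfg$psf
  key <- paste("psf", paste(grid$shape, collapse = ","),
               paste(signif(grid$voxel_size_mm, 8), collapse = ","),
               psf$fwhm_intrinsic_mm, psf$a, psf$b_mm,
               cfg$orbit_radius_cm, sep = "|")
  cache_get(key, function() {
    ny <- grid$shape[2]
    vy <- grid$voxel_size_mm[2]
    cy <- (ny + 1) / 2
    lapply(seq_len(ny), function(d) {
      dist_mm <- cfg$orbit_radius_cm * 10 - (d - cy) * vy
      fw <- psf_fwhm_mm(psf, max(dist_mm, 0))
      sig <- fwhm_to_sigma(fw)
      list(Bu = blur_matrix_1d(grid$shape[1], sig / grid$voxel_size_mm[1]),
           Bv = blur_matrix_1d(grid$shape[3], sig / grid$voxel_size_mm[3]))
    })
  })
}

# separable 3-D Gaussian blur of a volume, sigma given in mm per axis
gaussian_blur_volume <- function(vol, grid, sigma_mm) {
  d <- dim(vol)
  if (length(sigma_mm) == 1L) sigma_mm <- rep(sigma_mm, 3)
  # axis 1
  B <- blur_matrix_1d(d[1], sigma_mm[1] / grid$voxel_size_mm[1])
  vol <- array(B %*% matrix(vol, d[1], d[2] * d[3]), d)
  # axis 2
  B <- blur_matrix_1d(d[2], sigma_mm[2] / grid$voxel_size_mm[2])
  m <- matrix(aperm(vol, c(2, 1, 3)), d[2], d[1] * d[3])
  vol <- aperm(array(B %*% m, c(d[2], d[1], d[3])), c(2, 1, 3))
  # axis 3
  B <- blur_matrix_1d(d[3], sigma_mm[3] / grid$voxel_size_mm[3])
  m <- matrix(aperm(vol, c(3, 1, 2)), d[3], d[1] * d[2])
  aperm(array(B %*% m, c(d[3], d[1], d[2])), c(2, 3, 1))
}

# 2-D Gaussian blur of a detector image (u along rows, v along columns)
gaussian_blur_image <- function(img, pitch_mm, fwhm_mm) {
  if (fwhm_mm <= 0) return(img)
  sig <- fwhm_to_sigma(fwhm_mm)
  Bu <- blur_matrix_1d(nrow(img), sig / pitch_mm[1])
  Bv <- blur_matrix_1d(ncol(img), sig / pitch_mm[2])
  Bu %*% img %*% Bv
}
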