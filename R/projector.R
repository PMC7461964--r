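# Parallel-beam projector pair for a rotating gamma camera.
#
# Geometry: the camera rotates in the (x, y) plane about the z axis. For a
# projection at angle theta the volume is resampled onto a rotated frame by
# a sparse bilinear-interpolation operator R; the rotated y index is the
# depth toward the detector (detector beyond d = ny). Attenuation is a
# diagonal factor exp(-integral of mu along the exit path), the
# distance-dependent PSF a symmetric per-depth blur. Because R is an
# explicit sparse matrix, the backprojector uses t(R) and the pair is
# exactly matched (adjoint), which OSEM/MLEM monotonicity relies on.

# sparse in-plane rotation operator (bilinear sampling), cached per
# (nx, ny, angle); maps a vectorized (nx x ny) slice to the rotated slice
rotation_operator <- function(nx, ny, angle_deg) {
  key <- paste("rot", nx, ny, round(angle_deg %% 360, 8), sep = "|")
  cache_get(key, function() {
    th <- angle_deg * pi / 180
    cu <- (nx + 1) / 2; cd <- (ny + 1) / 2
    u <- rep(seq_len(nx), times = ny)
    d <- rep(seq_len(ny), each = nx)
    # source coordinates in the unrotated frame
    sx <- cu + cos(th) * (u - cu) - sin(th) * (d - cd)
    sy <- cd + sin(th) * (u - cu) + cos(th) * (d - cd)
    x0 <- floor(sx); y0 <- floor(sy)
    fx <- sx - x0; fy <- sy - y0
    row <- seq_len(nx * ny)
    ii <- integer(0); jj <- integer(0); ww <- numeric(0)
    for (corner in 1:4) {
      xo <- if (corner %in% c(2, 4)) 1L else 0L
      yo <- if (corner %in% c(3, 4)) 1L else 0L
      xs <- x0 + xo; ys <- y0 + yo
      w <- (if (xo == 1L) fx else 1 - fx) * (if (yo == 1L) fy else 1 - fy)
      ok <- xs >= 1 & xs <= nx & ys >= 1 & ys <= ny & w > 0
      ii <- c(ii, row[ok])
      jj <- c(jj, xs[ok] + nx * (ys[ok] - 1L))
      ww <- c(ww, w[ok])
    }
    Matrix::sparseMatrix(i = ii, j = jj, x = ww, dims = c(nx * ny, nx * ny))
  })
}

# conservative rotation for extensive quantities (activity): each source
# voxel splats its content into the rotated frame with bilinear weights --
# the transpose of the gather operator for the inverse angle. Column sums
# are exactly 1 away from the volume edge, so total activity is conserved;
# the gather form is kept for intensive quantities (mu).
rotation_splat_operator <- function(nx, ny, angle_deg) {
  key <- paste("rotT", nx, ny, round(angle_deg %% 360, 8), sep = "|")
  cache_get(key, function() Matrix::t(rotation_operator(nx, ny, -angle_deg)))
}

rotate_volume <- function(vol, R) {
  d <- dim(vol)
  array(as.numeric(R %*% matrix(vol, d[1] * d[2], d[3])), d)
}

# exclusive path integral toward the detector (d = ny side):
# out[u,d,v] = sum_{d' > d} mu[u,d',v] * dy_cm ; attenuation = exp(-out)
attenuation_factors <- function(mu_rot, dy_cm) {
  d <- dim(mu_rot)
  m <- matrix(aperm(mu_rot, c(2, 1, 3)), d[2], d[1] * d[3])
  cs <- apply(m, 2, cumsum)                 # inclusive cumsum along depth
  tot <- rep(cs[d[2], ], each = d[2])
  path <- (tot - cs) * dy_cm                # exclusive sum beyond the voxel
  att <- exp(-array(path, c(d[2], d[1], d[3])))
  aperm(att, c(2, 1, 3))
}

# forward projection of one angle: volume values (any units) -> detector
# image (nu x nv), without count scaling. `S` is the conservative splat
# rotation operator for the angle.
forward_one <- function(vals, grid, angle_deg, att_rot = NULL, psf_stack = NULL,
                        S = NULL) {
  d <- grid$shape
  if (is.null(S)) S <- rotation_splat_operator(d[1], d[2], angle_deg)
  W <- rotate_volume(vals, S)
  if (!is.null(att_rot)) W <- W * att_rot
  if (is.null(psf_stack)) {
    m <- aperm(W, c(2, 1, 3))
    P <- matrix(colSums(matrix(m, d[2], d[1] * d[3])), d[1], d[3])
  } else {
    P <- matrix(0, d[1], d[3])
    for (dep in seq_len(d[2])) {
      P <- P + psf_stack[[dep]]$Bu %*% W[, dep, ] %*% psf_stack[[dep]]$Bv
    }
    P <- as.matrix(P)
  }
  P
}

# matched adjoint of forward_one: detector image -> volume (uses the
# literal transpose of the same splat operator)
backproject_one <- function(img, grid, angle_deg, att_rot = NULL,
                            psf_stack = NULL, S = NULL) {
  d <- grid$shape
  if (is.null(S)) S <- rotation_splat_operator(d[1], d[2], angle_deg)
  X <- array(0, d)
  if (is.null(psf_stack)) {
    for (dep in seq_len(d[2])) X[, dep, ] <- img
  } else {
    for (dep in seq_len(d[2])) {
      X[, dep, ] <- as.matrix(psf_stack[[dep]]$Bu %*% img %*% psf_stack[[dep]]$Bv)
    }
  }
  if (!is.null(att_rot)) X <- X * att_rot
  array(as.numeric(Matrix::crossprod(S, matrix(X, d[1] * d[2], d[3]))), d)
}

# counts per (kBq/mL voxel value): voxel volume (mL) x abundance x dwell
# time (s) x system sensitivity (counts per kBq*s)
count_scale <- function(isotope, grid, cfg) {
  voxel_volume_ml(grid) * isotope$abundance * cfg$time_per_projection_s *
    cfg$sensitivity_cps_per_kbq
}

#' Project an activity map through the attenuating medium at one angle
#'
#' Analytic primary-photon forward model: parallel-beam line integrals of
#' activity times exp(-path integral of mu along the exit path), with a
#' depth-dependent Gaussian detector response applied per depth layer
#' (FWHM(d) = sqrt(FWHM_int^2 + (a d + b)^2)), scaled by photon abundance,
#' dwell time and system sensitivity. In-plane voxels must be square.
#'
#' @param src a \code{vq_activity} (kBq/mL).
#' @param mu a \code{vq_mu} attenuation map on the same grid, or NULL for
#'   an unattenuated projection.
#' @param cfg an \code{\link{acquisition_config}}.
#' @param angle_deg camera angle in degrees.
#' @param psf logical; apply the distance-dependent response (default:
#'   taken from \code{cfg$psf$enabled}).
#' @return nu x nv matrix of expected counts (real-valued, no noise).
#' @export
project_primary <- function(src, mu, cfg, angle_deg, psf = cfg$psf$enabled) {
  grid <- src$grid
  if (abs(grid$voxel_size_mm[1] - grid$voxel_size_mm[2]) > 1e-9)
    stop("project_primary(): in-plane voxels must be square (x pitch == y pitch)")
  att_rot <- NULL
  if (!is.null(mu)) {
    stop_if_grid_mismatch(grid, mu$grid, "activity and mu maps")
    G <- rotation_operator(grid$shape[1], grid$shape[2], angle_deg)
    att_rot <- attenuation_factors(rotate_volume(mu$values, G),
                                   grid$voxel_size_mm[2] / 10)
  }
  stack <- if (isTRUE(psf)) psf_matrix_stack(grid, cfg) else NULL
  S <- rotation_splat_operator(grid$shape[1], grid$shape[2], angle_deg)
  P <- forward_one(src$values, grid, angle_deg, att_rot, stack, S)
  P * count_scale(src$isotope, grid, cfg)
}
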