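#' Voxel grid geometry
#'
#' Defines the sampling grid shared by phantoms, activity maps, attenuation
#' maps and reconstructions. The axis convention is fixed throughout the
#' package: x runs right-to-left, y anterior-to-posterior, z
#' caudal-to-cranial. Coronal planes are slabs of constant y-index ranges,
#' with the anterior-most plane at the lowest y index.
#'
#' @param shape integer triple (nx, ny, nz); every dimension must be >= 8.
#' @param voxel_size_mm positive real triple, voxel pitch in mm per axis.
#' @return An object of class \code{vq_grid}.
#' @examples
#' voxel_grid(c(128, 128, 108), c(3.92, 3.92, 3.59))
#' @export
voxel_grid <- function(shape, voxel_size_mm) {
  shape <- as.integer(shape)
  voxel_size_mm <- as.numeric(voxel_size_mm)
  if (length(shape) != 3L || any(!is.finite(shape)))
    stop("voxel_grid(): 'shape' must be an integer triple")
  if (any(shape < 8L))
    stop("voxel_grid(): all grid dimensions must be >= 8 (got ",
         paste(shape, collapse = "x"), ")")
  if (length(voxel_size_mm) != 3L || any(!is.finite(voxel_size_mm)) ||
      any(voxel_size_mm <= 0))
    stop("voxel_grid(): 'voxel_size_mm' must be three positive reals")
  structure(
    list(shape = shape, voxel_size_mm = voxel_size_mm,
         axes = c(x = "right->left", y = "anterior->posterior",
                  z = "caudal->cranial")),
    class = "vq_grid")
}

#' @exportS3Method base::print
print.vq_grid <- function(x, ...) {
  cat(sprintf("<vq_grid> %d x %d x %d voxels, %.4g x %.4g x %.4g mm\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$voxel_size_mm[1], x$voxel_size_mm[2], x$voxel_size_mm[3]))
  cat("  axes: x right->left, y anterior->posterior, z caudal->cranial\n")
  invisible(x)
}

#' @exportS3Method base::format
format.vq_grid <- function(x, ...) {
  sprintf("%s @ %s mm", paste(x$shape, collapse = "x"),
          paste(signif(x$voxel_size_mm, 4), collapse = "x"))
}

grids_equal <- function(a, b, tol = 1e-9) {
  identical(a$shape, b$shape) &&
    all(abs(a$voxel_size_mm - b$voxel_size_mm) < tol)
}

stop_if_grid_mismatch <- function(a, b, what = "volumes") {
  if (!grids_equal(a, b))
    stop("grid mismatch between ", what, ": ",
         format(a), " vs ", format(b))
  invisible(TRUE)
}

# voxel volume in mL (mm^3 / 1000)
voxel_volume_ml <- function(grid) prod(grid$voxel_size_mm) / 1000

# physical coordinates (mm) of voxel centers, centered on the volume middle
grid_coords <- function(grid) {
  cc <- function(n, v) (seq_len(n) - (n + 1) / 2) * v
  list(x = cc(grid$shape[1], grid$voxel_size_mm[1]),
       y = cc(grid$shape[2], grid$voxel_size_mm[2]),
       z = cc(grid$shape[3], grid$voxel_size_mm[3]))
}

check_volume_on_grid <- function(vol, grid, what = "volume") {
  if (!is.array(vol) || length(dim(vol)) != 3L)
    stop(what, " must be a 3-D array")
  if (!identical(as.integer(dim(vol)), grid$shape))
    stop(what, " dimensions ", paste(dim(vol), collapse = "x"),
         " do not match grid ", paste(grid$shape, collapse = "x"))
  invisible(TRUE)
}
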