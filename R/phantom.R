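#' Tissue-coded digital phantom
#'
#' A Zubal-style voxel phantom: an 8-bit tissue-code volume on a
#' \code{\link{voxel_grid}}, a \code{\link{tissue_table}} mapping codes to
#' density and attenuation, and lung / airway masks derived from the codes.
#'
#' @param grid a \code{vq_grid}.
#' @param codes integer 3-D array of tissue codes on \code{grid}.
#' @param table a \code{vq_tissue_table} covering every code present.
#' @return An object of class \code{vq_phantom}.
#' @export
tissue_phantom <- function(grid, codes, table = default_tissue_table()) {
  check_volume_on_grid(codes, grid, "codes")
  codes <- array(as.integer(codes), dim(codes))
  present <- sort(unique(as.vector(codes)))
  unknown <- setdiff(present, table$code)
  if (length(unknown))
    stop("tissue_phantom(): codes not in tissue table: ",
         paste(unknown, collapse = ", "))
  if (any(present < 0L | present > 255L))
    stop("tissue_phantom(): codes must be representable in 8 bits")
  lung_mask <- codes == TISSUE_LUNG
  airway_mask <- codes == TISSUE_BRONCHI
  structure(list(grid = grid, codes = codes, table = table,
                 lung_mask = lung_mask, airway_mask = airway_mask),
            class = "vq_phantom")
}

#' @exportS3Method base::print
print.vq_phantom <- function(x, ...) {
  cat("<vq_phantom>", format(x$grid), "\n")
  tab <- table(factor(as.vector(x$codes), levels = x$table$code,
                      labels = x$table$name))
  for (nm in names(tab)) if (tab[[nm]] > 0)
    cat(sprintf("  %-12s %d voxels\n", nm, tab[[nm]]))
  invisible(x)
}

#' Segment a CT Hounsfield-unit volume into a tissue phantom
#'
#' Voxels are classified by HU interval into air, lung, fat, soft tissue
#' and bone. Air voxels are then split into outside air vs intrathoracic
#' airways (bronchi) by 6-connected component labeling against the volume
#' border: border-connected air is outside, enclosed air is airway.
#'
#' @param hu finite numeric 3-D array of Hounsfield units.
#' @param grid the \code{vq_grid} the volume lives on.
#' @param thresholds strictly increasing HU cutpoints
#'   (air | lung | fat | soft | bone); see \code{\link{default_hu_thresholds}}.
#' @param table tissue table for the resulting phantom.
#' @return A \code{vq_phantom}.
#' @export
segment_hu_volume <- function(hu, grid,
                              thresholds = default_hu_thresholds(),
                              table = default_tissue_table()) {
  check_volume_on_grid(hu, grid, "hu")
  nbad <- sum(!is.finite(hu))
  if (nbad > 0)
    stop("segment_hu_volume(): ", nbad, " non-finite HU voxel(s)")
  thresholds <- as.numeric(thresholds)
  if (length(thresholds) != 4L || any(diff(thresholds) <= 0))
    stop("segment_hu_volume(): thresholds must be 4 strictly increasing cutpoints")

  codes <- array(TISSUE_BONE, dim(hu))
  codes[hu < thresholds[4]] <- TISSUE_SOFT
  codes[hu < thresholds[3]] <- TISSUE_FAT
  codes[hu < thresholds[2]] <- TISSUE_LUNG
  air <- hu < thresholds[1]

  # outside air = air reachable from the volume border; the rest is airway
  outside <- flood_fill6(air, border_mask(dim(hu)))
  codes[air] <- TISSUE_BRONCHI
  codes[outside] <- TISSUE_OUTSIDE

  ph <- tissue_phantom(grid, codes, table)
  if (!any(ph$lung_mask))
    stop("segment_hu_volume(): empty lung mask after segmentation; ",
         "phantom unusable (check HU calibration / thresholds)")
  ph
}

#' Generate a parametric synthetic thorax
#'
#' Produces a CT-like HU volume plus the exact tissue-code phantom used to
#' paint it, for fully offline testing of segmentation, the coronal
#' perfusion gradient and lung-ROI erosion. The geometry is an elliptical
#' soft-tissue body with a fat shell, a spine and sternum, two lung
#' ellipsoids (slightly posterior of center, as in a supine patient) and
#' an enclosed bronchial-tree stub (trachea plus main bronchi) that does
#' not reach the volume border. Per-tissue Gaussian HU noise is drawn with
#' the given seed; the returned ground-truth phantom is noise-free.
#'
#' @param grid simulation grid; default 64^3 voxels at 6 mm pitch.
#' @param body_axes_mm semi-axes (x, y) of the elliptical body cross-section.
#' @param fat_thickness_mm thickness of the subcutaneous fat shell.
#' @param lung_axes_mm semi-axes (x, y, z) of each lung ellipsoid.
#' @param lung_center_x_mm distance of each lung center from the midline.
#' @param lung_center_y_mm posterior shift of the lung centers.
#' @param spine_radius_mm,sternum_radius_mm bone cylinder radii.
#' @param bronchus_radius_mm radius of the airway tubes.
#' @param hu_noise_scale multiplier on the per-tissue HU noise SDs
#'   (0 disables noise).
#' @param table tissue table supplying per-tissue HU mean/SD.
#' @param seed integer seed for the HU noise.
#' @return list with \code{hu} (numeric array), \code{phantom} (ground-truth
#'   \code{vq_phantom}) and \code{params}.
#' @export
make_synthetic_thorax <- function(grid = voxel_grid(c(64, 64, 64), c(6, 6, 6)),
                                  body_axes_mm = c(150, 110),
                                  fat_thickness_mm = 9,
                                  lung_axes_mm = c(55, 80, 100),
                                  lung_center_x_mm = 65,
                                  lung_center_y_mm = 10,
                                  spine_radius_mm = 14,
                                  sternum_radius_mm = 8,
                                  bronchus_radius_mm = 6,
                                  hu_noise_scale = 1,
                                  table = default_tissue_table(),
                                  seed = 1L) {
  co <- grid_coords(grid)
  half <- grid$shape * grid$voxel_size_mm / 2
  checks <- c(body_x = body_axes_mm[1], body_y = body_axes_mm[2],
              lung_x = lung_center_x_mm + lung_axes_mm[1],
              lung_y = lung_center_y_mm + lung_axes_mm[2],
              lung_z = lung_axes_mm[3])
  lims <- c(half[1], half[2], half[1], half[2], half[3])
  bad <- which(checks >= lims)
  if (length(bad))
    stop("make_synthetic_thorax(): geometry exceeds grid along axis '",
         names(checks)[bad[1]], "' (", checks[bad[1]], " mm >= ",
         lims[bad[1]], " mm half-extent)")

  nx <- grid$shape[1]; ny <- grid$shape[2]; nz <- grid$shape[3]
  X <- array(rep(co$x, times = ny * nz), c(nx, ny, nz))
  Y <- array(rep(rep(co$y, each = nx), times = nz), c(nx, ny, nz))
  Z <- array(rep(co$z, each = nx * ny), c(nx, ny, nz))

  codes <- array(TISSUE_OUTSIDE, grid$shape)
  ell2 <- function(x, y, a, b) (x / a)^2 + (y / b)^2
  body <- ell2(X, Y, body_axes_mm[1], body_axes_mm[2]) <= 1
  inner <- ell2(X, Y, body_axes_mm[1] - fat_thickness_mm,
                body_axes_mm[2] - fat_thickness_mm) <= 1
  codes[body] <- TISSUE_FAT
  codes[inner] <- TISSUE_SOFT

  spine_y <- body_axes_mm[2] - fat_thickness_mm - spine_radius_mm - 12
  spine <- (X^2 + (Y - spine_y)^2) <= spine_radius_mm^2
  sternum_y <- -(body_axes_mm[2] - fat_thickness_mm - sternum_radius_mm - 6)
  sternum <- (X^2 + (Y - sternum_y)^2) <= sternum_radius_mm^2
  codes[(spine | sternum) & inner] <- TISSUE_BONE

  lungs <- (ell2(X - lung_center_x_mm, Y - lung_center_y_mm,
                 lung_axes_mm[1], lung_axes_mm[2]) + (Z / lung_axes_mm[3])^2 <= 1) |
           (ell2(X + lung_center_x_mm, Y - lung_center_y_mm,
                 lung_axes_mm[1], lung_axes_mm[2]) + (Z / lung_axes_mm[3])^2 <= 1)
  lungs <- lungs & inner & !spine & !sternum
  codes[lungs] <- TISSUE_LUNG

  # bronchial stub: vertical trachea segment + two straight main bronchi,
  # rendered as capsules; stays strictly inside the body so it is enclosed air
  seg_dist <- function(px, py, pz, a, b) {
    vx <- b[1] - a[1]; vy <- b[2] - a[2]; vz <- b[3] - a[3]
    L2 <- vx^2 + vy^2 + vz^2
    t <- ((px - a[1]) * vx + (py - a[2]) * vy + (pz - a[3]) * vz) / L2
    t <- pmin(pmax(t, 0), 1)
    sqrt((px - (a[1] + t * vx))^2 + (py - (a[2] + t * vy))^2 +
         (pz - (a[3] + t * vz))^2)
  }
  carina <- c(0, lung_center_y_mm, 0.35 * lung_axes_mm[3])
  trachea_top <- c(0, lung_center_y_mm, min(0.9 * lung_axes_mm[3], half[3] - 2 * grid$voxel_size_mm[3]))
  air_tube <- seg_dist(X, Y, Z, carina, trachea_top) <= bronchus_radius_mm
  for (s in c(-1, 1)) {
    tip <- c(s * lung_center_x_mm * 0.7, lung_center_y_mm, 0)
    air_tube <- air_tube | (seg_dist(X, Y, Z, carina, tip) <= bronchus_radius_mm)
  }
  codes[air_tube & inner] <- TISSUE_BRONCHI

  phantom <- tissue_phantom(grid, codes, table)

  if (!all(c("hu_mean", "hu_sd") %in% names(table)))
    stop("make_synthetic_thorax(): tissue table lacks hu_mean/hu_sd columns")
  hu_mean <- table$hu_mean[match(as.vector(codes), table$code)]
  hu_sd <- table$hu_sd[match(as.vector(codes), table$code)] * hu_noise_scale
  hu <- with_seed(seed, hu_mean + stats::rnorm(length(hu_mean), 0, pmax(hu_sd, 0)))
  hu <- array(hu, grid$shape)

  list(hu = hu, phantom = phantom,
       params = list(grid = grid, body_axes_mm = body_axes_mm,
                     fat_thickness_mm = fat_thickness_mm,
                     lung_axes_mm = lung_axes_mm,
                     lung_center_x_mm = lung_center_x_mm,
                     lung_center_y_mm = lung_center_y_mm,
                     hu_noise_scale = hu_noise_scale, seed = seed))
}

#' Resample a phantom to a coarser simulation grid
#'
#' Tissue codes are resampled by per-target-voxel majority vote (mode) --
#' codes are categorical and are never numerically interpolated. Both grids
#' are aligned on their physical volume centers; every source voxel votes
#' into the target voxel containing its center. Only downsampling (target
#' pitch >= source pitch) is allowed. Ties break to the smallest code.
#'
#' @param phantom a \code{vq_phantom}.
#' @param target the target \code{vq_grid}
#'   (e.g. \code{voxel_grid(c(128,128,108), c(3.92,3.92,3.59))}).
#' @return A \code{vq_phantom} on \code{target}.
#' @export
resample_to_simulation_grid <- function(phantom, target) {
  src <- phantom$grid
  if (grids_equal(src, target)) return(phantom)
  if (any(target$voxel_size_mm < src$voxel_size_mm - 1e-9))
    stop("resample_to_simulation_grid(): target pitch ",
         paste(signif(target$voxel_size_mm, 4), collapse = "x"),
         " mm is finer than source ",
         paste(signif(src$voxel_size_mm, 4), collapse = "x"),
         " mm; upsampling codes is not allowed")

  sco <- grid_coords(src)
  # target voxel index per source center coordinate (volume centers aligned)
  tidx <- function(coord, ax) {
    i <- floor(coord / target$voxel_size_mm[ax] + target$shape[ax] / 2) + 1
    as.integer(pmin(pmax(i, 1L), target$shape[ax]))
  }
  ix <- tidx(sco$x, 1); iy <- tidx(sco$y, 2); iz <- tidx(sco$z, 3)

  nxt <- target$shape[1]; nyt <- target$shape[2]; nzt <- target$shape[3]
  nt <- nxt * nyt * nzt
  flat_t <- rep(ix, times = src$shape[2] * src$shape[3]) +
    nxt * (rep(rep(iy - 1L, each = src$shape[1]), times = src$shape[3])) +
    nxt * nyt * rep(iz - 1L, each = src$shape[1] * src$shape[2])

  codes_v <- as.vector(phantom$codes)
  levels <- sort(unique(codes_v))
  counts <- matrix(0L, nt, length(levels))
  for (k in seq_along(levels)) {
    sel <- codes_v == levels[k]
    counts[, k] <- tabulate(flat_t[sel], nbins = nt)
  }
  win <- max.col(counts, ties.method = "first")  # first = smallest code on ties
  out_codes <- levels[win]
  # target voxels receiving no vote (possible when extents differ): outside air
  out_codes[rowSums(counts) == 0L] <- TISSUE_OUTSIDE
  out_codes <- array(out_codes, target$shape)
  tissue_phantom(target, out_codes, phantom$table)
}
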