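#' Isotope specification
#'
#' @param name isotope label.
#' @param photon_energy_keV photopeak emission energy.
#' @param abundance photon abundance per decay, in (0, 1].
#' @return A \code{vq_isotope}.
#' @export
isotope_spec <- function(name, photon_energy_keV, abundance) {
  stopifnot(photon_energy_keV > 0, abundance > 0, abundance <= 1)
  structure(list(name = name, photon_energy_keV = photon_energy_keV,
                 abundance = abundance), class = "vq_isotope")
}

#' @describeIn isotope_spec Tc-99m preset: 140 keV, 88.5% abundance.
#' @export
isotope_tc99m <- function() isotope_spec("Tc-99m", 140, 0.885)

#' @describeIn isotope_spec Kr-81m preset: 190 keV, 100% abundance.
#'   Kr-81m is modeled as a stationary homogeneous gas with no decay during
#'   the acquisition (13 s half-life, continuously replenished by breathing).
#' @export
isotope_kr81m <- function() isotope_spec("Kr-81m", 190, 1.0)

#' Radioactivity concentration map
#'
#' @param grid a \code{vq_grid}.
#' @param values non-negative numeric 3-D array, kBq/mL.
#' @param isotope a \code{vq_isotope}.
#' @return A \code{vq_activity}.
#' @export
activity_map <- function(grid, values, isotope) {
  check_volume_on_grid(values, grid, "activity values")
  if (any(values < 0)) stop("activity_map(): negative activity values")
  stopifnot(inherits(isotope, "vq_isotope"))
  structure(list(grid = grid, values = values, isotope = isotope),
            class = "vq_activity")
}

#' Anterior-to-posterior perfusion gradient specification
#'
#' The lungs are divided into \code{n_planes} coronal slabs; each slab gets
#' one concentration. The default linear profile interpolates between the
#' anterior-most (\code{c_first}) and posterior-most (\code{c_last}) plane
#' concentrations; a full per-plane vector may be supplied instead.
#'
#' @param n_planes number of coronal planes (default 16).
#' @param c_first concentration in the anterior-most plane, kBq/mL (default 43).
#' @param c_last concentration in the posterior-most plane, kBq/mL (default 65).
#' @param profile optional length-\code{n_planes} vector of absolute per-plane
#'   concentrations (kBq/mL), must be positive and non-decreasing; overrides
#'   the linear default.
#' @return A \code{vq_gradient}.
#' @export
gradient_spec <- function(n_planes = 16L, c_first = 43, c_last = 65,
                          profile = NULL) {
  n_planes <- as.integer(n_planes)
  if (n_planes < 2L) stop("gradient_spec(): n_planes must be >= 2")
  if (is.null(profile)) {
    profile <- c_first + (seq_len(n_planes) - 1) * (c_last - c_first) / (n_planes - 1)
  } else {
    if (length(profile) != n_planes)
      stop("gradient_spec(): profile length must equal n_planes")
    c_first <- profile[1]; c_last <- profile[n_planes]
  }
  if (any(profile <= 0)) stop("gradient_spec(): all per-plane values must be > 0")
  if (any(diff(profile) < 0))
    stop("gradient_spec(): profile must be non-decreasing anterior->posterior")
  structure(list(n_planes = n_planes, c_first = c_first, c_last = c_last,
                 profile = profile), class = "vq_gradient")
}

#' Perfusion defect specification
#'
#' @param mask logical 3-D array; the defect zone, must lie within the lungs.
#' @param relative_concentration remaining activity fraction in the zone,
#'   in [0, 1); the worked example uses 0.5 (a 50% segmental defect).
#' @return A \code{vq_defect}.
#' @export
defect_spec <- function(mask, relative_concentration = 0.5) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3L)
  if (!(relative_concentration >= 0 && relative_concentration < 1))
    stop("defect_spec(): relative_concentration must be in [0, 1)")
  structure(list(mask = mask, relative_concentration = relative_concentration),
            class = "vq_defect")
}

#' Build the Kr-81m ventilation source map
#'
#' Uniform concentration over lungs and airways (the inhaled gas fills
#' both), zero elsewhere.
#'
#' @param phantom a \code{vq_phantom} with a non-empty lung mask.
#' @param concentration_kbq_ml activity concentration (default 55 kBq/mL).
#' @return A \code{vq_activity} with the Kr-81m isotope preset.
#' @export
build_ventilation_source <- function(phantom, concentration_kbq_ml = 55) {
  if (concentration_kbq_ml <= 0)
    stop("build_ventilation_source(): concentration must be > 0")
  if (!any(phantom$lung_mask))
    stop("build_ventilation_source(): phantom has an empty lung mask")
  vals <- array(0, phantom$grid$shape)
  vals[phantom$lung_mask | phantom$airway_mask] <- concentration_kbq_ml
  activity_map(phantom$grid, vals, isotope_kr81m())
}

# contiguous y-slab partition of [y0, y1] into n near-equal slabs;
# remainder voxels are assigned to the posterior-most slabs
slab_partition <- function(y0, y1, n) {
  L <- y1 - y0 + 1L
  base <- L %/% n
  extra <- L %% n
  thick <- rep(base, n)
  if (extra > 0) thick[(n - extra + 1L):n] <- base + 1L
  ends <- y0 - 1L + cumsum(thick)
  starts <- c(y0, utils::head(ends, -1L) + 1L)
  cbind(start = starts, end = ends)
}

#' Build the Tc-99m-MAA perfusion source map
#'
#' Models the gravity-driven anterior-to-posterior gradient of pulmonary
#' blood flow in a supine patient: the lung bounding box along y (one
#' joint partition for both lungs -- a single gravity axis) is split into
#' \code{grad$n_planes} contiguous coronal slabs of near-equal thickness,
#' and every lung voxel in slab k receives the slab's concentration.
#' Airways get zero (MAA is intravascular), as does everything outside the
#' lungs.
#'
#' @param phantom a \code{vq_phantom}.
#' @param grad a \code{\link{gradient_spec}}.
#' @return A \code{vq_activity} with the Tc-99m isotope preset.
#' @export
build_perfusion_source <- function(phantom, grad = gradient_spec()) {
  stopifnot(inherits(grad, "vq_gradient"))
  if (!any(phantom$lung_mask))
    stop("build_perfusion_source(): phantom has an empty lung mask")
  ys <- which(apply(phantom$lung_mask, 2, any))
  y0 <- min(ys); y1 <- max(ys)
  extent <- y1 - y0 + 1L
  if (extent < grad$n_planes)
    stop("build_perfusion_source(): lung y-extent (", extent,
         " voxels) is thinner than n_planes = ", grad$n_planes)
  slabs <- slab_partition(y0, y1, grad$n_planes)
  vals <- array(0, phantom$grid$shape)
  for (k in seq_len(grad$n_planes)) {
    sel <- phantom$lung_mask
    keep <- logical(phantom$grid$shape[2])
    keep[slabs[k, "start"]:slabs[k, "end"]] <- TRUE
    sel <- sel & rep(rep(keep, each = phantom$grid$shape[1]),
                     times = phantom$grid$shape[3])
    vals[sel] <- grad$profile[k]
  }
  activity_map(phantom$grid, vals, isotope_tc99m())
}

#' Insert a perfusion defect into a source map
#'
#' Multiplies the activity by the defect's relative concentration inside
#' its mask and leaves every other voxel bit-identical. Returns a new map;
#' the input is not modified.
#'
#' @param src a \code{vq_activity}.
#' @param defect a \code{\link{defect_spec}}; its mask must lie inside
#'   voxels where defects are meaningful (the lung mask).
#' @param lung_mask logical array used to validate the defect location.
#' @return A new \code{vq_activity}.
#' @export
insert_defect <- function(src, defect, lung_mask) {
  stopifnot(inherits(src, "vq_activity"), inherits(defect, "vq_defect"))
  check_volume_on_grid(defect$mask, src$grid, "defect mask")
  n_out <- sum(defect$mask & !lung_mask)
  if (n_out > 0)
    stop("insert_defect(): ", n_out, " defect voxel(s) outside the lung mask")
  vals <- src$values
  vals[defect$mask] <- vals[defect$mask] * defect$relative_concentration
  activity_map(src$grid, vals, src$isotope)
}

#' Parametric segmental wedge defect mask
#'
#' Stand-in for a manually delineated segmental area: the set of lung
#' voxels of one lung inside a cone with apex near the hilum. Defaults
#' place the apex at the medial edge of the right lung and aim the cone
#' laterally, downward and posteriorly, approximating a posterobasal
#' segment. Deterministic for fixed parameters.
#'
#' @param phantom a \code{vq_phantom}.
#' @param apex_mm physical (x, y, z) apex coordinates in mm (volume-centered
#'   frame); default: medial-inferior point of the right lung.
#' @param direction cone axis (need not be normalized); default
#'   lateral/posterior/caudal into the right lung.
#' @param half_angle_deg angular half-width of the cone (default 25, which
#'   yields a realistic segment-sized fraction of one lung).
#' @param side "right" or "left": which lung component the wedge is cut from.
#' @return A \code{vq_defect}-ready logical mask (largest connected piece of
#'   cone-intersect-lung).
#' @export
make_segmental_wedge <- function(phantom, apex_mm = NULL, direction = NULL,
                                 half_angle_deg = 25,
                                 side = c("right", "left")) {
  side <- match.arg(side)
  sgn <- if (side == "right") -1 else 1   # x axis runs right -> left
  co <- grid_coords(phantom$grid)
  lungs <- phantom$lung_mask
  if (!any(lungs)) stop("make_segmental_wedge(): empty lung mask")

  lab <- label_components6(lungs, max_components = 8L)
  # centroid x of each component decides the side
  comp_ids <- setdiff(sort(unique(as.vector(lab))), 0L)
  cx <- vapply(comp_ids, function(i) {
    idx <- which(lab == i, arr.ind = TRUE)
    mean(co$x[idx[, 1]])
  }, numeric(1))
  pick <- if (sgn < 0) comp_ids[which.min(cx)] else comp_ids[which.max(cx)]
  lung <- lab == pick

  idx <- which(lung, arr.ind = TRUE)
  px <- co$x[idx[, 1]]; py <- co$y[idx[, 2]]; pz <- co$z[idx[, 3]]
  if (is.null(apex_mm)) {
    # hilum-like point: medial edge of the chosen lung, mid-height
    apex_mm <- c(if (sgn < 0) max(px) else min(px), stats::median(py),
                 stats::quantile(pz, 0.35, names = FALSE))
  }
  if (is.null(direction)) direction <- c(sgn, 0.5, -0.7)  # lateral, posterior, caudal
  direction <- direction / sqrt(sum(direction^2))
  if (any(apex_mm < c(min(px), min(py), min(pz)) - phantom$grid$voxel_size_mm) ||
      any(apex_mm > c(max(px), max(py), max(pz)) + phantom$grid$voxel_size_mm))
    stop("make_segmental_wedge(): apex outside the lung bounding box")

  dx <- px - apex_mm[1]; dy <- py - apex_mm[2]; dz <- pz - apex_mm[3]
  r <- sqrt(dx^2 + dy^2 + dz^2)
  cosang <- (dx * direction[1] + dy * direction[2] + dz * direction[3]) /
    pmax(r, 1e-9)
  inside <- cosang >= cos(half_angle_deg * pi / 180) | r < 1e-9

  mask <- array(FALSE, phantom$grid$shape)
  mask[lung] <- inside
  if (!any(mask))
    stop("make_segmental_wedge(): empty wedge (cone misses the lung)")
  # keep the largest connected piece so the defect is one territory
  wl <- label_components6(mask, max_components = 16L)
  mask <- wl == 1L
  mask
}

#' Ground-truth pulmonary vascular obstruction index (PVOI)
#'
#' Activity-weighted perfusion loss fraction over the lung mask:
#' \code{1 - sum(defect activity) / sum(normal activity)}. This is the
#' exact ground truth that delineation methods can be benchmarked against.
#'
#' @param src_normal,src_defect perfusion \code{vq_activity} maps on the
#'   same grid (defect map typically from \code{\link{insert_defect}}).
#' @param lung_mask logical array restricting the sums to the lungs.
#' @return Fraction in [0, 1).
#' @export
ground_truth_pvoi <- function(src_normal, src_defect, lung_mask) {
  stop_if_grid_mismatch(src_normal$grid, src_defect$grid, "activity maps")
  check_volume_on_grid(lung_mask, src_normal$grid, "lung mask")
  tot <- sum(src_normal$values[lung_mask])
  if (tot <= 0)
    stop("ground_truth_pvoi(): zero total normal perfusion; PVOI undefined")
  1 - sum(src_defect$values[lung_mask]) / tot
}
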