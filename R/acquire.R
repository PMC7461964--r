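#' Energy window presets for dual-isotope V/Q acquisition
#'
#' The four windows of the dual-isotope protocol: Tc-99m scatter
#' [109.9, 129.5] keV, Tc-99m photopeak [129.5, 150.5] keV, Kr-81m scatter
#' [150.7, 177.6] keV, Kr-81m photopeak [177.6, 206.4] keV.
#'
#' @return Named list of windows, each with \code{lo_keV}, \code{hi_keV}.
#' @export
default_energy_windows <- function() {
  list(
    tc_scatter   = list(label = "tc_scatter",   lo_keV = 109.9, hi_keV = 129.5),
    tc_photopeak = list(label = "tc_photopeak", lo_keV = 129.5, hi_keV = 150.5),
    kr_scatter   = list(label = "kr_scatter",   lo_keV = 150.7, hi_keV = 177.6),
    kr_photopeak = list(label = "kr_photopeak", lo_keV = 177.6, hi_keV = 206.4)
  )
}

window_width_keV <- function(w) w$hi_keV - w$lo_keV

#' Default per-window photon transfer model
#'
#' For each energy window: the geometric (unscattered primary) fraction,
#' the in-window scatter fraction applied to a broad-Gaussian-blurred copy
#' of the primary, and the downscatter fractions contributed by the other
#' isotope. Kr-81m (190 keV) downscatters into BOTH Tc windows; Tc-99m
#' contributes nothing above its photopeak. These fractions are plausible
#' stand-ins producing realistic window ratios, not fitted constants.
#'
#' @return Named list keyed by window label.
#' @export
default_window_model <- function() {
  list(
    tc_photopeak = list(primary = "tc", geometric_fraction = 1.0,
                        scatter_fraction = 0.30, kernel_fwhm_mm = 60,
                        downscatter = list(kr = 0.15)),
    tc_scatter   = list(primary = "tc", geometric_fraction = 0.0,
                        scatter_fraction = 0.45, kernel_fwhm_mm = 60,
                        downscatter = list(kr = 0.30)),
    kr_photopeak = list(primary = "kr", geometric_fraction = 1.0,
                        scatter_fraction = 0.30, kernel_fwhm_mm = 60,
                        downscatter = list()),
    kr_scatter   = list(primary = "kr", geometric_fraction = 0.0,
                        scatter_fraction = 0.50, kernel_fwhm_mm = 60,
                        downscatter = list())
  )
}

#' Acquisition configuration
#'
#' Defaults mirror a clinical dual-isotope lung protocol on a MELP
#' (medium-energy low-penetration) collimator camera: 128 projections,
#' 10 s per projection, step-and-shoot, circular orbit of 30 cm radius
#' (the non-circular clinical orbit is simplified to circular; per-angle
#' radii are not modeled). The distance-dependent response defaults give
#' about a 7.5 mm system FWHM at 10 cm. Sensitivity is a single scalar;
#' absolute sensitivity is irrelevant when projections are rescaled to a
#' target count level before adding Poisson noise.
#'
#' @param n_projections number of angles over 360 degrees (default 128).
#' @param time_per_projection_s dwell time per angle (default 10).
#' @param orbit_radius_cm camera rotation radius (default 30).
#' @param detector_pixel_mm nominal detector pixel pitch, metadata only:
#'   projections are sampled on the simulation grid's in-plane pitch.
#' @param psf list(enabled, fwhm_intrinsic_mm, a, b_mm): FWHM(d) =
#'   sqrt(fwhm_intrinsic^2 + (a d + b)^2), d in mm.
#' @param window_model per-window transfer model, see
#'   \code{\link{default_window_model}}.
#' @param windows energy window definitions.
#' @param sensitivity_cps_per_kbq system sensitivity, counts per kBq s.
#' @return A \code{vq_acq_config}.
#' @export
acquisition_config <- function(n_projections = 128L,
                               time_per_projection_s = 10,
                               orbit_radius_cm = 30,
                               detector_pixel_mm = 4.7,
                               psf = list(enabled = TRUE,
                                          fwhm_intrinsic_mm = 3.8,
                                          a = 0.055, b_mm = 1.0),
                               window_model = default_window_model(),
                               windows = default_energy_windows(),
                               sensitivity_cps_per_kbq = 1.0) {
  n_projections <- as.integer(n_projections)
  stopifnot(n_projections >= 1L, time_per_projection_s > 0,
            orbit_radius_cm > 0, sensitivity_cps_per_kbq > 0)
  for (nm in names(window_model)) {
    wm <- window_model[[nm]]
    fr <- c(wm$geometric_fraction, wm$scatter_fraction,
            unlist(wm$downscatter, use.names = FALSE))
    if (any(fr < 0 | fr > 1))
      stop("acquisition_config(): fractions for window '", nm,
           "' must be in [0, 1]")
  }
  structure(list(n_projections = n_projections,
                 time_per_projection_s = time_per_projection_s,
                 orbit_radius_cm = orbit_radius_cm,
                 detector_pixel_mm = detector_pixel_mm,
                 psf = psf, window_model = window_model, windows = windows,
                 sensitivity_cps_per_kbq = sensitivity_cps_per_kbq),
            class = "vq_acq_config")
}

projection_angles <- function(cfg) {
  seq(0, 360, length.out = cfg$n_projections + 1L)[seq_len(cfg$n_projections)]
}

#' Linear attenuation map from a tissue phantom
#'
#' Voxelwise lookup of the tissue table's attenuation column at the
#' requested photon energy (140 or 190 keV with the default table).
#'
#' @param phantom a \code{vq_phantom}.
#' @param energy_keV photon energy; a column \code{mu_<energy>} must exist
#'   in the tissue table.
#' @return A \code{vq_mu} (grid + mu values in 1/cm + energy).
#' @export
make_mu_map <- function(phantom, energy_keV) {
  col <- paste0("mu_", format(energy_keV))
  if (!col %in% names(phantom$table))
    stop("make_mu_map(): no attenuation column for ", energy_keV,
         " keV in the tissue table (have: ",
         paste(grep("^mu_", names(phantom$table), value = TRUE),
               collapse = ", "), ")")
  mu <- phantom$table[[col]][match(as.vector(phantom$codes), phantom$table$code)]
  structure(list(grid = phantom$grid,
                 values = array(mu, phantom$grid$shape),
                 energy_keV = energy_keV),
            class = "vq_mu")
}

#' Simulate the dual-isotope energy-window acquisition
#'
#' Runs the Tc-99m perfusion chain (attenuation at 140 keV) and the Kr-81m
#' ventilation chain (attenuation at 190 keV) separately -- the two source
#' maps are physically never imaged simultaneously by the model. Per
#' window, expected counts are
#' \code{geometric_fraction * primary + scatter_fraction * blur(primary)},
#' and the Kr chain's downscatter is added into both Tc windows according
#' to the window model. Poisson noise is applied last with the given seed;
#' the noiseless expectation is kept alongside.
#'
#' @param vent Kr-81m \code{vq_activity} (may be NULL to skip the chain).
#' @param perf Tc-99m \code{vq_activity} (may be NULL).
#' @param phantom the \code{vq_phantom} providing the attenuation medium.
#' @param cfg an \code{\link{acquisition_config}}.
#' @param seed integer seed for the Poisson draws.
#' @param noise logical; FALSE returns expectation-valued "counts".
#' @return A \code{vq_projections}: angles, per-window noisy count stacks
#'   (\code{$windows}), noiseless expectations (\code{$expected}), config
#'   echo and seed.
#' @export
simulate_acquisition <- function(vent, perf, phantom, cfg = acquisition_config(),
                                 seed = 1L, noise = TRUE) {
  grid <- phantom$grid
  if (!is.null(perf)) stop_if_grid_mismatch(grid, perf$grid, "phantom/perfusion")
  if (!is.null(vent)) stop_if_grid_mismatch(grid, vent$grid, "phantom/ventilation")
  angles <- projection_angles(cfg)
  nu <- grid$shape[1]; nv <- grid$shape[3]
  pitch <- grid$voxel_size_mm[c(1, 3)]

  # primary chains per isotope
  prim <- list()
  chains <- list(tc = perf, kr = vent)
  energies <- c(tc = 140, kr = 190)
  for (iso in names(chains)) {
    src <- chains[[iso]]
    if (is.null(src)) next
    mu <- make_mu_map(phantom, energies[[iso]])
    stack <- array(0, c(nu, nv, length(angles)))
    for (a in seq_along(angles)) {
      stack[, , a] <- project_primary(src, mu, cfg, angles[a])
    }
    prim[[iso]] <- stack
  }

  needed <- names(cfg$windows)
  expected <- list()
  for (wn in needed) {
    wm <- cfg$window_model[[wn]]
    if (is.null(wm))
      stop("simulate_acquisition(): window_model lacks an entry for ('",
           if (wn %in% c("tc_scatter", "tc_photopeak")) "tc" else "kr",
           "', '", wn, "')")
    out <- array(0, c(nu, nv, length(angles)))
    p <- prim[[wm$primary]]
    if (!is.null(p)) {
      for (a in seq_along(angles)) {
        out[, , a] <- wm$geometric_fraction * p[, , a] +
          wm$scatter_fraction *
            gaussian_blur_image(p[, , a], pitch, wm$kernel_fwhm_mm)
      }
    }
    for (iso in names(wm$downscatter)) {
      q <- prim[[iso]]
      if (is.null(q)) next
      f <- wm$downscatter[[iso]]
      for (a in seq_along(angles)) {
        out[, , a] <- out[, , a] +
          f * gaussian_blur_image(q[, , a], pitch, wm$kernel_fwhm_mm)
      }
    }
    expected[[wn]] <- out
  }

  windows <- expected
  if (isTRUE(noise)) {
    windows <- with_seed(seed, lapply(expected, function(e) {
      array(stats::rpois(length(e), as.vector(e)), dim(e))
    }))
  }
  structure(list(angles = angles, windows = windows, expected = expected,
                 grid = grid, config = cfg, seed = seed, noise = noise),
            class = "vq_projections")
}

#' Rescale projections to a target total count and draw Poisson noise
#'
#' Simulated expectations are in arbitrary sensitivity units; clinical
#' realism is imposed by scaling the grand total to a target count level
#' before adding Poisson noise. When a named list of windows is given the
#' single scale factor is shared across windows (their ratios are physics
#' and must survive the rescaling).
#'
#' @param expectation non-negative array, or named list of arrays.
#' @param target_total_counts desired grand total over everything passed in.
#' @param seed integer seed.
#' @return Same shape as the input, with integer Poisson counts; the common
#'   scale factor is attached as attribute \code{"scale_factor"}.
#' @export
scale_and_poisson <- function(expectation, target_total_counts, seed = 1L) {
  if (target_total_counts <= 0)
    stop("scale_and_poisson(): target_total_counts must be > 0")
  is_list <- is.list(expectation)
  parts <- if (is_list) expectation else list(expectation)
  tot <- sum(vapply(parts, sum, numeric(1)))
  if (tot <= 0)
    stop("scale_and_poisson(): all-zero expectation cannot be scaled")
  if (any(vapply(parts, function(p) any(p < 0), logical(1))))
    stop("scale_and_poisson(): expectation must be non-negative")
  f <- target_total_counts / tot
  out <- with_seed(seed, lapply(parts, function(p) {
    array(stats::rpois(length(p), as.vector(p) * f), dim(p))
  }))
  res <- if (is_list) out else out[[1]]
  attr(res, "scale_factor") <- f
  res
}
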