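#' Eroded lung ROI
#'
#' Morphological erosion of the lung mask by a physical margin, used to
#' keep Z-score statistics away from partial-volume artifacts at the lung
#' boundary. The per-axis erosion radius is the margin divided by the
#' voxel pitch, rounded to the nearest integer with a minimum of one voxel
#' for any positive margin -- so the conventional 0.5 cm margin equals a
#' 1-voxel erosion at ~4-6 mm pitch.
#'
#' @param phantom a \code{vq_phantom} with a non-empty lung mask.
#' @param margin_cm erosion margin (default 0.5).
#' @return Logical array (strict subset of the lung mask for margin > 0).
#' @export
eroded_lung_roi <- function(phantom, margin_cm = 0.5) {
  if (!any(phantom$lung_mask)) stop("eroded_lung_roi(): empty lung mask")
  if (margin_cm < 0) stop("eroded_lung_roi(): margin must be >= 0")
  if (margin_cm == 0) return(phantom$lung_mask)
  r <- pmax(round(margin_cm * 10 / phantom$grid$voxel_size_mm), 1L)
  out <- erode_mask(phantom$lung_mask, r)
  if (!any(out))
    stop("eroded_lung_roi(): erosion by margin ", margin_cm, " cm (",
         paste(r, collapse = "/"), " voxels) emptied the lung mask of ",
         sum(phantom$lung_mask), " voxels")
  out
}

#' Normalize a reconstruction to its in-ROI mean
#'
#' Divides every voxel by the mean value inside the ROI, so the in-ROI
#' mean of the output is exactly 1. Mean-normalization removes the
#' arbitrary count scale before database comparison and makes the result
#' invariant to any positive rescaling of the input.
#'
#' @param vol a \code{vq_volume} (or plain array).
#' @param roi non-empty logical array on the same grid.
#' @return Same type as the input.
#' @export
normalize_to_mean <- function(vol, roi) {
  v <- if (inherits(vol, "vq_volume")) vol$values else vol
  if (!any(roi)) stop("normalize_to_mean(): empty ROI")
  m <- mean(v[roi])
  if (!is.finite(m) || m <= 0)
    stop("normalize_to_mean(): non-positive in-ROI mean (", m, ")")
  out <- v / m
  if (inherits(vol, "vq_volume")) recon_volume(vol$grid, out, vol$provenance)
  else out
}

#' Normal database container
#'
#' Voxelwise MEAN and SD maps built from mean-normalized reconstructions
#' of n co-registered normal cases, plus the normalization ROI.
#'
#' @param grid a \code{vq_grid}.
#' @param mean_map,sd_map numeric arrays on \code{grid}; \code{sd_map >= 0}.
#' @param n_subjects integer >= 2.
#' @param roi the normalization/analysis ROI used to build the database.
#' @param settings list echoing the generative settings (for manifests).
#' @return A \code{vq_normal_db}.
#' @export
normal_database <- function(grid, mean_map, sd_map, n_subjects, roi,
                            settings = list()) {
  check_volume_on_grid(mean_map, grid, "mean_map")
  check_volume_on_grid(sd_map, grid, "sd_map")
  if (any(sd_map < 0)) stop("normal_database(): sd_map must be >= 0")
  if (n_subjects < 2) stop("normal_database(): n_subjects must be >= 2")
  structure(list(grid = grid, mean_map = mean_map, sd_map = sd_map,
                 n_subjects = as.integer(n_subjects), roi = roi,
                 settings = settings),
            class = "vq_normal_db")
}

# SD floor: voxels whose SD is below 1e-3 x the in-ROI mean of MEANmap are
# treated as undefined (degenerate synthetic databases would otherwise
# blow up the division)
db_sd_floor <- function(db) 1e-3 * mean(db$mean_map[db$roi])

#' Voxelwise Z-score map against a normal database
#'
#' z(x,y,z) = (value - MEANmap) / SDmap wherever the SD map is above the
#' database's SD floor; undefined (NA) elsewhere. The input volume must be
#' mean-normalized with the same ROI convention used to build the database.
#'
#' @param vol a mean-normalized \code{vq_volume} (or plain array).
#' @param db a \code{vq_normal_db} on the same grid.
#' @return A \code{vq_zscore_map}: \code{$z} (array, NA where undefined)
#'   and \code{$defined} (logical array).
#' @export
zscore_map <- function(vol, db) {
  v <- if (inherits(vol, "vq_volume")) vol$values else vol
  if (inherits(vol, "vq_volume")) stop_if_grid_mismatch(vol$grid, db$grid)
  check_volume_on_grid(v, db$grid, "volume")
  defined <- db$sd_map > db_sd_floor(db)
  z <- array(NA_real_, db$grid$shape)
  z[defined] <- (v[defined] - db$mean_map[defined]) / db$sd_map[defined]
  structure(list(grid = db$grid, z = z, defined = defined),
            class = "vq_zscore_map")
}

#' Z-score distribution statistics within an ROI
#'
#' Mean, population SD, and the percentage of voxels beyond +1 / -1,
#' computed over the ROI voxels where the Z-score is defined.
#'
#' @param zmap a \code{vq_zscore_map}.
#' @param roi logical array; must intersect the defined region.
#' @return List: \code{mean_z}, \code{sd_z}, \code{pct_above_1},
#'   \code{pct_below_minus1} (in percent), \code{n_roi}.
#' @export
zscore_stats <- function(zmap, roi) {
  check_volume_on_grid(roi, zmap$grid, "roi")
  sel <- roi & zmap$defined
  n <- sum(sel)
  if (n == 0) stop("zscore_stats(): empty ROI (no defined Z-score voxels)")
  z <- zmap$z[sel]
  list(mean_z = mean(z),
       sd_z = sqrt(mean((z - mean(z))^2)),   # population SD
       pct_above_1 = 100 * mean(z > 1),
       pct_below_minus1 = 100 * mean(z < -1),
       n_roi = n)
}

# smooth multiplicative inter-subject field: blurred white noise rescaled
# to the requested SD, centered at 1
smooth_field <- function(grid, sd, corr_mm) {
  if (sd <= 0) return(array(1, grid$shape))
  w <- array(stats::rnorm(prod(grid$shape)), grid$shape)
  f <- gaussian_blur_volume(w, grid, rep(fwhm_to_sigma(corr_mm * 2), 3))
  f <- f / stats::sd(as.vector(f)) * sd
  pmax(1 + f, 0.1)
}

#' Build a seeded synthetic normal database
#'
#' Stands in for a co-registered database of real normal cases: simulates
#' \code{n_subjects} perturbed normal studies end to end (source map ->
#' energy-window projections -> count scaling + Poisson noise -> OSEM
#' reconstruction -> mean-normalization in the eroded lung ROI) and
#' accumulates the voxelwise mean and population SD. Inter-subject
#' variability has three components: a global log-normal activity scale, a
#' jitter of the two gradient endpoint concentrations, and a smooth
#' multiplicative field (dominant axis of real variability being the
#' anterior-to-posterior gradient, which the endpoint jitter perturbs).
#'
#' @param phantom the common anatomy (real databases are co-registered).
#' @param n_subjects number of cases (>= 2; 20 is a reasonable desk-scale
#'   stand-in for a large clinical database).
#' @param study "perfusion" (Tc photopeak) or "ventilation" (Kr photopeak).
#' @param acq_cfg,recon_cfg acquisition / reconstruction configuration.
#' @param grad base perfusion gradient (perturbed per subject).
#' @param vent_kbq_ml base ventilation concentration.
#' @param variability list: \code{log_scale_sd} (default 0.1),
#'   \code{endpoint_jitter_sd} (kBq/mL, default 3), \code{field_sd}
#'   (default 0.05), \code{field_corr_mm} (default 30).
#' @param target_counts total counts over the photopeak+scatter window pair
#'   per study (default 2e6).
#' @param margin_cm erosion margin for the normalization ROI.
#' @param include_downscatter simulate the other isotope's chain too, so Tc
#'   windows contain Kr downscatter (default TRUE).
#' @param poisson apply Poisson count noise (default TRUE; FALSE gives the
#'   degenerate noiseless database used to exercise the SD floor).
#' @param seed root seed; every subject's randomness derives from it.
#' @return A \code{vq_normal_db}.
#' @export
build_synthetic_normal_db <- function(phantom, n_subjects = 20L,
                                      study = c("perfusion", "ventilation"),
                                      acq_cfg = acquisition_config(),
                                      recon_cfg = recon_config(),
                                      grad = gradient_spec(),
                                      vent_kbq_ml = 55,
                                      variability = list(),
                                      target_counts = 2e6,
                                      margin_cm = 0.5,
                                      include_downscatter = TRUE,
                                      poisson = TRUE,
                                      seed = 1L) {
  study <- match.arg(study)
  n_subjects <- as.integer(n_subjects)
  if (n_subjects < 2L)
    stop("build_synthetic_normal_db(): n_subjects must be >= 2")
  vb <- utils::modifyList(list(log_scale_sd = 0.1, endpoint_jitter_sd = 3,
                               field_sd = 0.05, field_corr_mm = 30),
                          variability)
  roi <- eroded_lung_roi(phantom, margin_cm)
  seeds <- derive_seeds(seed, 2L * n_subjects)

  s1 <- array(0, phantom$grid$shape)
  s2 <- array(0, phantom$grid$shape)
  for (i in seq_len(n_subjects)) {
    vol <- tryCatch(
      simulate_normal_case(phantom, study, acq_cfg, recon_cfg, grad,
                           vent_kbq_ml, vb, target_counts, roi,
                           include_downscatter, poisson = poisson,
                           param_seed = seeds[2L * i - 1L],
                           noise_seed = seeds[2L * i]),
      error = function(e) stop("build_synthetic_normal_db(): subject ", i,
                               " failed: ", conditionMessage(e)))
    s1 <- s1 + vol
    s2 <- s2 + vol^2
  }
  mean_map <- s1 / n_subjects
  sd_map <- sqrt(pmax(s2 / n_subjects - mean_map^2, 0))  # population SD
  normal_database(phantom$grid, mean_map, sd_map, n_subjects, roi,
                  settings = c(vb, list(study = study, seed = seed,
                                        n_subjects = n_subjects,
                                        target_counts = target_counts,
                                        margin_cm = margin_cm)))
}

#' Simulate one perturbed normal case end to end
#'
#' The single-subject kernel of \code{\link{build_synthetic_normal_db}};
#' also the way to produce held-out normal realizations (or defect cases,
#' via \code{defect}) for scoring against a database.
#'
#' @inheritParams build_synthetic_normal_db
#' @param variability resolved variability list (all four components).
#' @param roi normalization ROI.
#' @param poisson apply Poisson count noise (FALSE reconstructs scaled
#'   noiseless expectations).
#' @param param_seed,noise_seed seeds for the subject's source perturbation
#'   and for count noise.
#' @param defect optional \code{vq_defect} inserted into the study's source.
#' @return Mean-normalized reconstruction values (plain array).
#' @export
simulate_normal_case <- function(phantom, study, acq_cfg, recon_cfg, grad,
                                 vent_kbq_ml, variability, target_counts,
                                 roi, include_downscatter = TRUE,
                                 poisson = TRUE,
                                 param_seed = 1L, noise_seed = 2L,
                                 defect = NULL) {
  pars <- with_seed(param_seed, {
    list(scale = exp(stats::rnorm(1, 0, variability$log_scale_sd)),
         jit = stats::rnorm(2, 0, variability$endpoint_jitter_sd),
         field = smooth_field(phantom$grid, variability$field_sd,
                              variability$field_corr_mm))
  })
  c_first <- max(grad$c_first + pars$jit[1], 1)
  c_last <- max(grad$c_last + pars$jit[2], c_first + 0.5)
  g <- gradient_spec(grad$n_planes, c_first, c_last)

  perf <- build_perfusion_source(phantom, g)
  perf$values <- perf$values * pars$scale * pars$field
  vent <- build_ventilation_source(phantom, vent_kbq_ml)
  vent$values <- vent$values * pars$scale * pars$field

  if (!is.null(defect)) {
    tgt <- if (study == "perfusion") "perf" else "vent"
    if (tgt == "perf") perf <- insert_defect(perf, defect, phantom$lung_mask)
    else vent <- insert_defect(vent, defect, phantom$lung_mask)
  }

  if (!include_downscatter) {
    if (study == "perfusion") vent <- NULL else perf <- NULL
  }
  proj <- simulate_acquisition(vent, perf, phantom, acq_cfg,
                               seed = noise_seed, noise = FALSE)
  iso <- if (study == "perfusion") "tc" else "kr"
  pk <- paste0(iso, "_photopeak"); sc <- paste0(iso, "_scatter")
  if (isTRUE(poisson)) {
    noisy <- scale_and_poisson(proj$expected[c(pk, sc)], target_counts,
                               seed = noise_seed)
    f <- attr(noisy, "scale_factor")
  } else {
    tot <- sum(proj$expected[[pk]]) + sum(proj$expected[[sc]])
    f <- target_counts / tot
    noisy <- lapply(proj$expected[c(pk, sc)], function(e) e * f)
  }
  proj$windows[[pk]] <- noisy[[pk]]
  proj$windows[[sc]] <- noisy[[sc]]
  # the shared rescale also applies to the model expectation the OSEM
  # forward projector should match
  acq2 <- proj$config
  acq2$sensitivity_cps_per_kbq <- acq2$sensitivity_cps_per_kbq * f
  proj$config <- acq2

  vol <- osem_reconstruct(proj, pk, phantom, recon_cfg)
  normalize_to_mean(vol, roi)$values
}
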