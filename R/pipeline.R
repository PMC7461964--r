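# End-to-end pipeline: phantom -> sources -> acquisition -> reconstruction
# -> normal database -> Z-score statistics, with a run manifest. All
# randomness derives from the single root seed via documented sub-seeding.

pipeline_schema <- function() {
  list(
    seed = "integer",
    grid = list(shape = "integer[3]", voxel_mm = "numeric[3]"),
    phantom = list(type = "synthetic|ct", ct_path = "path",
                   hu_noise_scale = "numeric", seed_offset = "integer"),
    ventilation = list(kbq_ml = "numeric"),
    gradient = list(c_first = "numeric", c_last = "numeric",
                    n_planes = "integer"),
    defect = list(enabled = "logical", half_angle_deg = "numeric",
                  relative_concentration = "numeric", side = "right|left"),
    acquisition = list(n_projections = "integer",
                       time_per_projection_s = "numeric",
                       orbit_radius_cm = "numeric",
                       target_total_counts = "numeric"),
    recon = list(iterations = "integer", subsets = "integer",
                 attenuation_correction = "logical",
                 scatter_correction = "logical",
                 postfilter_fwhm_mm = "numeric"),
    database = list(n_subjects = "integer", log_scale_sd = "numeric",
                    endpoint_jitter_sd = "numeric", field_sd = "numeric",
                    field_corr_mm = "numeric"),
    zscore = list(margin_cm = "numeric", study = "perfusion|ventilation")
  )
}

validate_pipeline_config <- function(config) {
  schema <- pipeline_schema()
  check_keys <- function(cfg, sch, prefix = "") {
    unknown <- setdiff(names(cfg), names(sch))
    if (length(unknown))
      stop("pipeline config: unknown key '", prefix, unknown[1], "'")
    for (nm in names(cfg)) {
      if (is.list(sch[[nm]]) && !is.null(names(sch[[nm]]))) {
        if (!is.list(cfg[[nm]]))
          stop("pipeline config: '", prefix, nm, "' must be a block")
        check_keys(cfg[[nm]], sch[[nm]], paste0(prefix, nm, "."))
      }
    }
  }
  check_keys(config, schema)
  for (req in c("seed", "gradient")) {
    if (is.null(config[[req]]))
      stop("pipeline config: missing required key '", req, "'")
  }
  invisible(TRUE)
}

#' Run the full V/Q simulation pipeline
#'
#' Executes phantom construction, source painting (with optional wedge
#' defect), dual-isotope acquisition, OSEM reconstruction, synthetic
#' normal-database construction and Z-score scoring, writing every
#' intermediate volume plus machine-readable statistics and a run
#' manifest under \code{out_dir}. A single root seed governs all
#' stochastic stages (sub-seeds are derived deterministically from it), so
#' the same config + seed reproduces every artifact.
#'
#' @param config path to a JSON config file, or an equivalent named list.
#'   Unknown keys are rejected (typo protection for physics parameters);
#'   \code{seed} and \code{gradient} are required.
#' @param out_dir output directory (created if absent).
#' @return Invisibly, a list with the \code{stats}, the \code{manifest}
#'   and the database/reconstruction objects.
#' @export
run_pipeline <- function(config, out_dir = tempfile("vqrun")) {
  if (is.character(config)) {
    config <- jsonlite::fromJSON(config, simplifyVector = TRUE)
  }
  validate_pipeline_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed)
  sub <- derive_seeds(seed, 8L)
  manifest <- list(package_version = as.character(utils::packageVersion("vqspect")),
                   started = format(Sys.time(), tz = "UTC"),
                   seed = seed, config = config, stages = character(0))
  stage <- function(name) manifest$stages <<- c(manifest$stages, name)
  fail <- function(name, e) {
    manifest$failed_stage <- name
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, force = TRUE)
    stop("run_pipeline(): stage '", name, "' failed: ", conditionMessage(e))
  }

  # -- phantom ---------------------------------------------------------
  res <- tryCatch({
    gshape <- config$grid$shape %||% c(64L, 64L, 64L)
    gvox <- config$grid$voxel_mm %||% c(6, 6, 6)
    grid <- voxel_grid(gshape, gvox)
    ptype <- config$phantom$type %||% "synthetic"
    if (ptype == "synthetic") {
      syn <- make_synthetic_thorax(
        grid, hu_noise_scale = config$phantom$hu_noise_scale %||% 1,
        seed = sub[1])
      phantom <- segment_hu_volume(syn$hu, grid)
    } else {
      v <- read_volume(config$phantom$ct_path)
      phantom <- segment_hu_volume(v$values, v$grid)
      phantom <- resample_to_simulation_grid(phantom, grid)
    }
    write_volume(phantom, file.path(out_dir, "phantom_codes.mhd"))
    phantom
  }, error = function(e) fail("phantom", e))
  phantom <- res; stage("phantom")

  # -- sources ---------------------------------------------------------
  res <- tryCatch({
    grad <- gradient_spec(config$gradient$n_planes %||% 16L,
                          config$gradient$c_first %||% 43,
                          config$gradient$c_last %||% 65)
    vent <- build_ventilation_source(phantom,
                                     config$ventilation$kbq_ml %||% 55)
    perf <- build_perfusion_source(phantom, grad)
    defect <- NULL; pvoi <- NULL
    if (isTRUE(config$defect$enabled)) {
      mask <- make_segmental_wedge(
        phantom, half_angle_deg = config$defect$half_angle_deg %||% 25,
        side = config$defect$side %||% "right")
      defect <- defect_spec(mask,
                            config$defect$relative_concentration %||% 0.5)
      perf_d <- insert_defect(perf, defect, phantom$lung_mask)
      pvoi <- ground_truth_pvoi(perf, perf_d, phantom$lung_mask)
      write_volume(array(as.integer(mask), dim(mask)),
                   file.path(out_dir, "defect_mask.mhd"), grid = phantom$grid)
      perf <- perf_d
    }
    write_volume(vent, file.path(out_dir, "source_ventilation.mhd"))
    write_volume(perf, file.path(out_dir, "source_perfusion.mhd"))
    list(vent = vent, perf = perf, grad = grad, defect = defect, pvoi = pvoi)
  }, error = function(e) fail("sources", e))
  stage("sources")
  vent <- res$vent; perf <- res$perf; grad <- res$grad
  defect <- res$defect; pvoi <- res$pvoi

  acq_cfg <- acquisition_config(
    n_projections = config$acquisition$n_projections %||% 32L,
    time_per_projection_s = config$acquisition$time_per_projection_s %||% 10,
    orbit_radius_cm = config$acquisition$orbit_radius_cm %||% 30)
  rc <- recon_config(
    iterations = config$recon$iterations %||% 4L,
    subsets = config$recon$subsets %||% 8L,
    attenuation_correction = config$recon$attenuation_correction %||% TRUE,
    scatter_correction = config$recon$scatter_correction %||% TRUE,
    postfilter_fwhm_mm = config$recon$postfilter_fwhm_mm %||% 8.4)
  target <- config$acquisition$target_total_counts %||% 2e6
  study <- config$zscore$study %||% "perfusion"
  margin <- config$zscore$margin_cm %||% 0.5
  vb <- list(log_scale_sd = config$database$log_scale_sd %||% 0.1,
             endpoint_jitter_sd = config$database$endpoint_jitter_sd %||% 3,
             field_sd = config$database$field_sd %||% 0.05,
             field_corr_mm = config$database$field_corr_mm %||% 30)

  # -- database --------------------------------------------------------
  db <- tryCatch({
    db <- build_synthetic_normal_db(
      phantom, n_subjects = config$database$n_subjects %||% 5L,
      study = study, acq_cfg = acq_cfg, recon_cfg = rc, grad = grad,
      variability = vb, target_counts = target, margin_cm = margin,
      seed = sub[2])
    write_volume(db$mean_map, file.path(out_dir, "db_mean.mhd"),
                 grid = phantom$grid)
    write_volume(db$sd_map, file.path(out_dir, "db_sd.mhd"),
                 grid = phantom$grid)
    db
  }, error = function(e) fail("database", e))
  stage("database")

  # -- test case: simulate, reconstruct, score -------------------------
  stats <- tryCatch({
    roi <- db$roi
    vol <- simulate_normal_case(phantom, study, acq_cfg, rc, grad,
                                config$ventilation$kbq_ml %||% 55,
                                vb, target, roi,
                                param_seed = sub[3], noise_seed = sub[4],
                                defect = defect)
    write_volume(vol, file.path(out_dir, "recon_normalized.mhd"),
                 grid = phantom$grid)
    zm <- zscore_map(vol, db)
    st <- zscore_stats(zm, roi)
    if (!is.null(pvoi)) st$ground_truth_pvoi <- pvoi
    jsonlite::write_json(st, file.path(out_dir, "stats.json"),
                         auto_unbox = TRUE, digits = NA)
    st
  }, error = function(e) fail("zscore", e))
  stage("zscore")

  manifest$finished <- format(Sys.time(), tz = "UTC")
  manifest$outputs <- list.files(out_dir)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  invisible(list(stats = stats, manifest = manifest, db = db,
                 phantom = phantom, out_dir = out_dir))
}
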