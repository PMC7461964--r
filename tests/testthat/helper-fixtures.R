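# Shared fixtures, built once per test run (generation is seeded and cheap;
# the heavier simulated objects are cached in this environment).

.fx <- new.env(parent = emptyenv())

# default 64^3 synthetic thorax + its HU segmentation
fx_thorax <- function() {
  if (is.null(.fx$thorax)) {
    syn <- make_synthetic_thorax(seed = 7)
    .fx$thorax <- list(syn = syn,
                       phantom = segment_hu_volume(syn$hu, syn$params$grid))
  }
  .fx$thorax
}

# all-air phantom on a small grid (projector physics tests)
fx_air_phantom <- function(shape = c(32, 32, 32), voxel = c(8, 8, 8)) {
  g <- voxel_grid(shape, voxel)
  tissue_phantom(g, array(0L, shape))
}

# acquisition config with scatter and downscatter switched off (pure
# primary-photon chain) -- the physics oracles need the geometric term alone
fx_clean_acq <- function(n_projections = 16L, psf = FALSE,
                         orbit_radius_cm = 30) {
  wm <- default_window_model()
  for (nm in names(wm)) {
    wm[[nm]]$scatter_fraction <- 0
    wm[[nm]]$downscatter <- list()
  }
  acquisition_config(n_projections = n_projections,
                     orbit_radius_cm = orbit_radius_cm,
                     psf = list(enabled = psf, fwhm_intrinsic_mm = 3.8,
                                a = 0.055, b_mm = 1.0),
                     window_model = wm)
}

# uniform water-like cylinder phantom + matching uniform emission source
fx_cylinder <- function(shape = c(48, 48, 16), voxel = c(8, 8, 8),
                        radius_mm = 120, conc = 10) {
  g <- voxel_grid(shape, voxel)
  co <- vqspect:::grid_coords(g)
  X <- array(rep(co$x, shape[2] * shape[3]), shape)
  Y <- array(rep(rep(co$y, each = shape[1]), shape[3]), shape)
  cyl <- (X^2 + Y^2) <= radius_mm^2
  codes <- array(0L, shape)
  codes[cyl] <- 4L      # soft tissue (water-like)
  vals <- array(0, shape)
  vals[cyl] <- conc
  list(phantom = tissue_phantom(g, codes), mask = cyl,
       src = activity_map(g, vals, isotope_tc99m()), X = X, Y = Y, grid = g)
}

# shared 20-subject perfusion normal database at desk scale (64^3 thorax,
# 32 projections) -- reused by the Z-score consistency and defect tests
fx_normal_db <- function() {
  if (is.null(.fx$db)) {
    th <- fx_thorax()
    acq <- acquisition_config(n_projections = 32L)
    .fx$db <- build_synthetic_normal_db(th$phantom, 20L, "perfusion",
                                        acq_cfg = acq, seed = 101L)
    .fx$db_acq <- acq
  }
  list(db = .fx$db, acq = .fx$db_acq)
}

fx_default_variability <- function() {
  list(log_scale_sd = 0.1, endpoint_jitter_sd = 3, field_sd = 0.05,
       field_corr_mm = 30)
}
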