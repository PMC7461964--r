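test_that("mu maps are table lookups with the physical energy ordering", {
  ph <- fx_thorax()$phantom
  mu140 <- make_mu_map(ph, 140)
  mu190 <- make_mu_map(ph, 190)
  # voxelwise ordering propagates from the tissue table
  expect_true(all(mu190$values <= mu140$values))
  # direct lookup: a soft-tissue voxel carries exactly the table entry
  soft <- which(ph$codes == 4L)[1]
  tt <- ph$table
  expect_equal(mu140$values[soft], tt$mu_140[tt$code == 4L])
  # air phantom is (near) transparent
  air <- fx_air_phantom()
  expect_lt(max(make_mu_map(air, 140)$values), 1e-3)
  # energies without a table column are rejected
  expect_error(make_mu_map(ph, 250), "250")
})

test_that("projection conserves counts without attenuation and PSF", {
  grid <- voxel_grid(c(32, 32, 32), c(8, 8, 8))
  cfg <- fx_clean_acq()
  vals <- array(0, grid$shape)
  vals[10:22, 12:20, 8:24] <- 1 + (outer(1:13, 1:9) %o% rep(1, 17)) / 50
  src <- activity_map(grid, vals, isotope_tc99m())
  expected <- sum(vals) * vqspect:::voxel_volume_ml(grid) * 0.885 *
    cfg$time_per_projection_s * cfg$sensitivity_cps_per_kbq
  for (a in c(0, 30, 45, 123, 270)) {
    P <- project_primary(src, NULL, cfg, a, psf = FALSE)
    expect_lt(abs(sum(P) - expected) / expected, 0.005)
  }
})

test_that("a ln(2) attenuating slab halves the counts exactly", {
  grid <- voxel_grid(c(32, 32, 32), c(4, 4, 4))
  cfg <- fx_clean_acq()
  vals <- array(0, grid$shape); vals[16, 16, 16] <- 10
  src <- activity_map(grid, vals, isotope_tc99m())
  mu_vals <- array(0, grid$shape)
  mu_vals[, 20:24, ] <- log(2) / (5 * 0.4)   # 5 voxels x 0.4 cm, integral ln 2
  mu <- structure(list(grid = grid, values = mu_vals, energy_keV = 140),
                  class = "vq_mu")
  P0 <- project_primary(src, NULL, cfg, 0, psf = FALSE)
  P1 <- project_primary(src, mu, cfg, 0, psf = FALSE)
  expect_lt(abs(sum(P1) / sum(P0) - 0.5), 0.001)
  # attenuated counts never exceed unattenuated, any pixel, any angle
  for (a in c(0, 60, 200)) {
    expect_true(all(project_primary(src, mu, cfg, a, psf = FALSE) <=
                    project_primary(src, NULL, cfg, a, psf = FALSE) + 1e-12))
  }
})

test_that("point-source blur follows the closed-form distance-dependent PSF", {
  grid <- voxel_grid(c(64, 64, 16), c(2, 2, 2))
  vals <- array(0, grid$shape); vals[32, 32, 8] <- 100
  src <- activity_map(grid, vals, isotope_tc99m())
  for (radius in c(20, 30)) {
    cfg <- acquisition_config(n_projections = 8, orbit_radius_cm = radius)
    P <- project_primary(src, NULL, cfg, 0)
    fw <- measure_fwhm(P[, 8], 2)
    d <- radius * 10 - (32 - 32.5) * 2       # source depth to collimator, mm
    fw_true <- sqrt(3.8^2 + (0.055 * d + 1)^2)
    expect_lt(abs(fw - fw_true) / fw_true, 0.05)
  }
  # resolution degrades with orbit radius per the PSF law
  f20 <- measure_fwhm(project_primary(
    src, NULL, acquisition_config(n_projections = 8, orbit_radius_cm = 20),
    0)[, 8], 2)
  f30 <- measure_fwhm(project_primary(
    src, NULL, acquisition_config(n_projections = 8, orbit_radius_cm = 30),
    0)[, 8], 2)
  expect_gt(f30, f20)
})

test_that("dual-isotope windows separate sources and add downscatter linearly", {
  ph <- fx_thorax()$phantom
  acq <- acquisition_config(n_projections = 8)
  vent <- build_ventilation_source(ph)
  perf <- build_perfusion_source(ph)

  # no perfusion and no downscatter: Tc windows exactly zero before noise
  wm0 <- acq$window_model
  wm0$tc_photopeak$downscatter <- list()
  wm0$tc_scatter$downscatter <- list()
  acq0 <- acquisition_config(n_projections = 8, window_model = wm0)
  p0 <- simulate_acquisition(vent, NULL, ph, acq0, noise = FALSE)
  expect_true(all(p0$expected$tc_photopeak == 0))
  expect_true(all(p0$expected$tc_scatter == 0))
  expect_gt(sum(p0$expected$kr_photopeak), 0)

  # with downscatter: Tc windows of a perfusion-free acquisition hold the
  # pure-Kr contribution, and window additivity is exact (noiseless)
  p_full <- simulate_acquisition(vent, perf, ph, acq, noise = FALSE)
  p_off <- simulate_acquisition(vent, perf, ph, acq0, noise = FALSE)
  p_kr <- simulate_acquisition(vent, NULL, ph, acq, noise = FALSE)
  expect_gt(sum(p_kr$expected$tc_photopeak), 0)
  expect_equal(p_full$expected$tc_photopeak,
               p_off$expected$tc_photopeak + p_kr$expected$tc_photopeak)

  # seeded determinism of the noisy realization
  s1 <- simulate_acquisition(vent, perf, ph, acq, seed = 9)
  s2 <- simulate_acquisition(vent, perf, ph, acq, seed = 9)
  expect_identical(s1$windows, s2$windows)
  expect_true(all(vapply(s1$windows,
                         function(w) all(w == round(w) & w >= 0), logical(1))))

  # missing window model entries are named
  wm_bad <- acq$window_model; wm_bad$tc_photopeak <- NULL
  acq_bad <- acquisition_config(n_projections = 8, window_model = wm_bad)
  expect_error(simulate_acquisition(vent, perf, ph, acq_bad, noise = FALSE),
               "tc_photopeak")
})

test_that("Poisson realizations agree with the noiseless expectation", {
  # 200 seeded draws: per-pixel means within 3 SE for >= 95% of pixels and
  # within 5 SE always, no systematic bias, empirical variance ~ lambda
  grid <- voxel_grid(c(16, 16, 8), c(12, 12, 12))
  ph <- tissue_phantom(grid, array(0L, grid$shape))
  vals <- array(0, grid$shape); vals[6:11, 6:11, 3:6] <- 20
  src <- activity_map(grid, vals, isotope_tc99m())
  cfg <- fx_clean_acq(n_projections = 4)
  base <- simulate_acquisition(NULL, src, ph, cfg, noise = FALSE)
  e <- base$expected$tc_photopeak
  n_draws <- 200L
  acc <- array(0, dim(e)); acc2 <- array(0, dim(e))
  for (s in seq_len(n_draws)) {
    w <- simulate_acquisition(NULL, src, ph, cfg, seed = s)$windows$tc_photopeak
    acc <- acc + w; acc2 <- acc2 + w^2
  }
  m <- acc / n_draws
  sel <- e > 0.5
  z <- (m[sel] - e[sel]) / sqrt(e[sel] / n_draws)
  expect_gte(mean(abs(z) <= 3), 0.95)
  expect_lt(max(abs(z)), 5)
  expect_lt(abs(mean(z)), 3 / sqrt(sum(sel)))          # no bias
  v_emp <- (acc2 / n_draws - m^2)[sel]
  expect_lt(abs(mean(v_emp / e[sel]) - 1), 0.1)        # Poisson variance
})

test_that("count rescaling hits its target and follows the sqrt(N) law", {
  grid <- voxel_grid(c(16, 16, 8), c(12, 12, 12))
  e <- vqspect:::with_seed(4, array(stats::runif(16 * 16 * 4) + 0.5, c(16, 16, 4)))

  out <- scale_and_poisson(e, 1e6, seed = 5)
  expect_lt(abs(sum(out) - 1e6), 4 * sqrt(1e6))
  expect_identical(out, scale_and_poisson(e, 1e6, seed = 5))

  # named lists share one scale factor across windows
  lst <- scale_and_poisson(list(a = e, b = 2 * e), 3e5, seed = 1)
  expect_lt(abs(sum(lst$a) + sum(lst$b) - 3e5), 4 * sqrt(3e5))

  # quadrupling the count target halves the per-pixel relative noise
  rel_noise <- function(target) {
    draws <- vapply(1:40, function(s)
      as.vector(scale_and_poisson(e, target, seed = s)), numeric(length(e)))
    mean(apply(draws, 1, stats::sd) / rowMeans(draws))
  }
  r1 <- rel_noise(2e5); r4 <- rel_noise(8e5)
  expect_lt(abs(r4 / r1 - 0.5), 0.08)

  expect_error(scale_and_poisson(array(0, c(4, 4, 2)), 100), "all-zero")
  expect_error(scale_and_poisson(e, 0), "> 0")
})
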