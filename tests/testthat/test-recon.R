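test_that("DEW subtraction scales by the window-width ratio and clips at zero", {
  p <- matrix(10, 4, 4); s <- matrix(1, 4, 4)
  # scatter window empty: identity
  expect_identical(dew_correct(p, matrix(0, 4, 4)), p)
  # Tc presets: width ratio 21.0 / 19.6
  out <- dew_correct(p, s, k = 0.5)
  expect_equal(out[1, 1], 10 - 0.5 * (21.0 / 19.6))
  # over-subtraction clips pixelwise at zero
  s2 <- s; s2[2, 2] <- 100
  out2 <- dew_correct(p, s2, k = 1)
  expect_equal(out2[2, 2], 0)
  expect_gt(out2[1, 1], 0)
  expect_error(dew_correct(p, matrix(0, 3, 3)), "shape mismatch")
})

test_that("MLEM localizes a noiseless point source to sub-voxel accuracy", {
  grid <- voxel_grid(c(32, 32, 32), c(8, 8, 8))
  ph <- tissue_phantom(grid, array(0L, grid$shape))
  cfg <- fx_clean_acq(n_projections = 16)
  vals <- array(0, grid$shape); vals[14, 18, 16] <- 50
  src <- activity_map(grid, vals, isotope_tc99m())
  proj <- simulate_acquisition(NULL, src, ph, cfg, noise = FALSE)
  rc <- recon_config(iterations = 20, subsets = 1,
                     attenuation_correction = FALSE,
                     scatter_correction = FALSE, postfilter_fwhm_mm = 0,
                     model_psf_in_recon = FALSE)
  rec <- osem_reconstruct(proj, "tc_photopeak", ph, rc, use_expected = TRUE)
  expect_true(all(rec$values >= 0))
  w <- rec$values / sum(rec$values)
  idx <- which(w > 0, arr.ind = TRUE)
  cen <- colSums(idx * w[w > 0])
  expect_lt(max(abs(cen - c(14, 18, 16))), 0.5)
})

test_that("one OSEM iteration with one subset is a classic MLEM step", {
  grid <- voxel_grid(c(16, 16, 8), c(12, 12, 12))
  ph <- tissue_phantom(grid, array(0L, grid$shape))
  cfg <- fx_clean_acq(n_projections = 8)
  vals <- array(0, grid$shape); vals[6:10, 7:11, 3:6] <- 5
  src <- activity_map(grid, vals, isotope_tc99m())
  proj <- simulate_acquisition(NULL, src, ph, cfg, noise = FALSE)
  rc <- recon_config(iterations = 1, subsets = 1,
                     attenuation_correction = FALSE,
                     scatter_correction = FALSE, postfilter_fwhm_mm = 0,
                     model_psf_in_recon = FALSE)
  rec <- osem_reconstruct(proj, "tc_photopeak", ph, rc, use_expected = TRUE)

  # hand-rolled single MLEM update with the same projector pair
  scale <- vqspect:::count_scale(isotope_tc99m(), grid, cfg)
  ones <- matrix(1, grid$shape[1], grid$shape[3])
  sens <- array(0, grid$shape)
  upd <- array(0, grid$shape)
  x0 <- array(0, grid$shape)
  for (a in proj$angles) {
    sens <- sens + vqspect:::backproject_one(ones, grid, a) * scale
  }
  x0[sens > 1e-12] <- 1
  for (i in seq_along(proj$angles)) {
    yh <- vqspect:::forward_one(x0, grid, proj$angles[i]) * scale
    r <- proj$expected$tc_photopeak[, , i] / pmax(yh, 1e-12)
    upd <- upd + vqspect:::backproject_one(r, grid, proj$angles[i]) * scale
  }
  x1 <- x0 * upd / pmax(sens, 1e-12)
  x1[sens <= 1e-12] <- 0
  expect_equal(rec$values, x1, tolerance = 1e-12)
})

test_that("MLEM Poisson log-likelihood is non-decreasing over iterations", {
  grid <- voxel_grid(c(16, 16, 8), c(12, 12, 12))
  ph <- tissue_phantom(grid, array(0L, grid$shape))
  cfg <- fx_clean_acq(n_projections = 8)
  vals <- array(0, grid$shape); vals[5:12, 6:11, 2:7] <- 8
  src <- activity_map(grid, vals, isotope_tc99m())
  proj <- simulate_acquisition(NULL, src, ph, cfg, seed = 3)  # noisy data
  scale <- vqspect:::count_scale(isotope_tc99m(), grid, cfg)
  loglik <- function(x) {
    s <- 0
    for (i in seq_along(proj$angles)) {
      yh <- vqspect:::forward_one(x, grid, proj$angles[i]) * scale
      y <- proj$windows$tc_photopeak[, , i]
      ok <- yh > 0
      s <- s + sum(y[ok] * log(yh[ok]) - yh[ok])
    }
    s
  }
  lls <- vapply(1:5, function(k) {
    rc <- recon_config(iterations = k, subsets = 1,
                       attenuation_correction = FALSE,
                       scatter_correction = FALSE, postfilter_fwhm_mm = 0,
                       model_psf_in_recon = FALSE)
    loglik(osem_reconstruct(proj, "tc_photopeak", ph, rc)$values)
  }, numeric(1))
  expect_true(all(diff(lls) >= -1e-8 * abs(lls[-length(lls)])))
})

test_that("attenuation correction restores uniformity in a water cylinder", {
  fx <- fx_cylinder()
  cfg <- fx_clean_acq(n_projections = 32)
  proj <- simulate_acquisition(NULL, fx$src, fx$phantom, cfg, noise = FALSE)
  mkrc <- function(ac) recon_config(iterations = 4, subsets = 8,
                                    attenuation_correction = ac,
                                    scatter_correction = FALSE,
                                    postfilter_fwhm_mm = 0,
                                    model_psf_in_recon = FALSE)
  rac <- osem_reconstruct(proj, "tc_photopeak", fx$phantom, mkrc(TRUE),
                          use_expected = TRUE)
  rno <- osem_reconstruct(proj, "tc_photopeak", fx$phantom, mkrc(FALSE),
                          use_expected = TRUE)
  expect_true(all(rac$values >= 0) && all(rno$values >= 0))

  r2 <- fx$X^2 + fx$Y^2
  center <- r2 <= 40^2
  edge <- fx$mask & r2 >= 90^2
  zsel <- array(FALSE, dim(fx$mask)); zsel[, , 4:13] <- TRUE
  bias <- function(r) abs(mean(r$values[center & zsel]) /
                          mean(r$values[edge & zsel]) - 1)
  # noAC shows the classic center depression; AC removes >= half of it
  expect_gt(bias(rno), 0.2)
  expect_lt(bias(rac), 0.5 * bias(rno))
})

test_that("noiseless uniform cylinder reconstructs flat under the default chain", {
  fx <- fx_cylinder()
  # scatter on in simulation and DEW on in reconstruction (the default
  # clinical chain), PSF modeled, default 4 it / 8 subsets + post-filter
  acq <- acquisition_config(n_projections = 32)
  proj <- simulate_acquisition(NULL, fx$src, fx$phantom, acq, noise = FALSE)
  rec <- osem_reconstruct(proj, "tc_photopeak", fx$phantom, recon_config(),
                          use_expected = TRUE)
  r2 <- fx$X^2 + fx$Y^2
  roi <- (r2 <= 80^2) & fx$mask
  roi[, , c(1:3, 14:16)] <- FALSE
  cov <- stats::sd(rec$values[roi]) / mean(rec$values[roi])
  expect_lt(cov, 0.05)
})

test_that("the Gaussian post-filter has the nominal impulse response", {
  g <- voxel_grid(c(64, 64, 64), c(1, 1, 1))
  imp <- array(0, g$shape); imp[32, 32, 32] <- 1

  # fwhm 0 is the identity
  expect_identical(gaussian_postfilter(imp, 0, grid = g), imp)

  sm <- gaussian_postfilter(imp, 8.4, grid = g)
  for (ax in 1:3) {
    expect_lt(abs(measure_fwhm(sm, 1, axis = ax) - 8.4), 0.5)
  }
  # interior blur conserves total intensity
  expect_lt(abs(sum(sm) - 1), 1e-3)
  # sigma closed form
  expect_equal(vqspect:::fwhm_to_sigma(8.4), 8.4 / 2.35482, tolerance = 1e-5)
  expect_error(gaussian_postfilter(imp, -1, grid = g), ">= 0")
})

test_that("reconstruction guards its preconditions", {
  grid <- voxel_grid(c(16, 16, 8), c(12, 12, 12))
  ph <- tissue_phantom(grid, array(0L, grid$shape))
  cfg <- fx_clean_acq(n_projections = 8)
  vals <- array(0, grid$shape); vals[8, 8, 4] <- 5
  src <- activity_map(grid, vals, isotope_tc99m())
  proj <- simulate_acquisition(NULL, src, ph, cfg, noise = FALSE)
  expect_error(osem_reconstruct(proj, "tc_photopeak", ph,
                                recon_config(subsets = 3)), "divide")
  expect_error(osem_reconstruct(proj, "tc_scatter", ph, recon_config()),
               "scatter window itself")
})
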