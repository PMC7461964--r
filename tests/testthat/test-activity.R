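test_that("ventilation source is uniform over lungs and airways", {
  ph <- fx_thorax()$phantom
  vent <- build_ventilation_source(ph)
  inside <- ph$lung_mask | ph$airway_mask
  expect_true(all(vent$values[inside] == 55))
  expect_true(all(vent$values[!inside] == 0))
  expect_equal(vent$isotope$photon_energy_keV, 190)
  expect_equal(vent$isotope$abundance, 1.0)

  # total activity = concentration x lung+airway volume (mL)
  vol_ml <- sum(inside) * vqspect:::voxel_volume_ml(ph$grid)
  expect_equal(sum(vent$values) * vqspect:::voxel_volume_ml(ph$grid),
               55 * vol_ml)

  expect_error(build_ventilation_source(ph, 0), "> 0")
})

test_that("perfusion gradient spans 16 coronal slabs from 43 to 65 kBq/mL", {
  ph <- fx_thorax()$phantom
  perf <- build_perfusion_source(ph)
  expect_equal(perf$isotope$photon_energy_keV, 140)
  expect_equal(perf$isotope$abundance, 0.885)
  expect_true(all(perf$values[ph$airway_mask] == 0))   # MAA is vascular
  expect_true(all(perf$values[!ph$lung_mask] == 0))

  # per-y-plane lung concentrations: monotone, endpoints exact, 16 levels
  ny <- ph$grid$shape[2]
  plane_mean <- vapply(seq_len(ny), function(j) {
    sel <- ph$lung_mask[, j, ]
    if (!any(sel)) NA_real_ else mean(perf$values[, j, ][sel])
  }, numeric(1))
  occupied <- which(!is.na(plane_mean))
  prof <- plane_mean[occupied]
  expect_equal(prof[1], 43)                     # anterior-most plane
  expect_equal(prof[length(prof)], 65)          # posterior-most plane
  expect_true(all(diff(prof) >= 0))
  levels <- sort(unique(as.vector(perf$values[ph$lung_mask])))
  expect_length(levels, 16L)
  # linear profile closed form: slab k = 43 + (k-1) * 22/15
  expect_equal(levels, 43 + (0:15) * (65 - 43) / 15)
  expect_equal(levels[8], 53 + 4 / 15)          # 53.2666... kBq/mL

  # lungs thinner than n_planes are rejected with the measured extent
  expect_error(build_perfusion_source(ph, gradient_spec(n_planes = 64L)),
               "thinner")
})

test_that("gradient_spec validates its profile", {
  expect_error(gradient_spec(n_planes = 1L), ">= 2")
  expect_error(gradient_spec(profile = c(5, 4, 3), n_planes = 3L),
               "non-decreasing")
  expect_error(gradient_spec(profile = c(0, 1, 2), n_planes = 3L), "> 0")
  g <- gradient_spec(profile = c(40, 50, 70), n_planes = 3L)
  expect_equal(g$c_first, 40)
  expect_equal(g$c_last, 70)
})

test_that("defect insertion is local, multiplicative and returns a new map", {
  ph <- fx_thorax()$phantom
  perf <- build_perfusion_source(ph)
  mask <- make_segmental_wedge(ph)
  def <- defect_spec(mask, 0.5)
  out <- insert_defect(perf, def, ph$lung_mask)

  expect_identical(out$values[!mask], perf$values[!mask])  # bit-identical
  expect_equal(out$values[mask], perf$values[mask] * 0.5)
  expect_false(identical(out$values, perf$values))

  # empty mask is the identity
  empty <- defect_spec(array(FALSE, ph$grid$shape), 0.5)
  expect_identical(insert_defect(perf, empty, ph$lung_mask)$values,
                   perf$values)

  # relative concentration 0 annihilates in-mask activity, and the total
  # drops by exactly the mask's pre-defect share
  zero <- defect_spec(mask, 0)
  out0 <- insert_defect(perf, zero, ph$lung_mask)
  expect_true(all(out0$values[mask] == 0))
  expect_equal(sum(out0$values), sum(perf$values) - sum(perf$values[mask]))

  # masks outside the lungs are rejected with the violating count
  bad_mask <- array(FALSE, ph$grid$shape)
  bad_mask[1, 1, 1] <- TRUE
  expect_error(insert_defect(perf, defect_spec(bad_mask, 0.5), ph$lung_mask),
               "1 defect voxel")
  expect_error(defect_spec(mask, 1), "\\[0, 1\\)")
})

test_that("segmental wedge is deterministic, connected and segment-sized", {
  ph <- fx_thorax()$phantom
  m1 <- make_segmental_wedge(ph)
  m2 <- make_segmental_wedge(ph)
  expect_identical(m1, m2)

  # regression fixture: fraction of lung volume from the fixed default
  # geometry (computed once from the generator's analytic shape)
  expect_equal(sum(m1), 858L)
  frac <- sum(m1) / sum(ph$lung_mask)
  expect_gt(frac, 0.03); expect_lt(frac, 0.10)   # one segment of ~19

  # half-width 180 degrees covers the entire ipsilateral lung
  m180 <- make_segmental_wedge(ph, half_angle_deg = 180)
  lab <- vqspect:::label_components6(ph$lung_mask, 8L)
  side <- unique(lab[m180])
  expect_length(side, 1L)
  expect_equal(sum(m180), sum(lab == side))
})

test_that("ground-truth PVOI matches its arithmetic definition", {
  ph <- fx_thorax()$phantom
  perf <- build_perfusion_source(ph)

  # identical maps give zero
  expect_equal(ground_truth_pvoi(perf, perf, ph$lung_mask), 0)

  # a 50% defect in a region carrying share s of total perfusion: PVOI = s/2
  mask <- make_segmental_wedge(ph)
  share <- sum(perf$values[mask]) / sum(perf$values[ph$lung_mask])
  out <- insert_defect(perf, defect_spec(mask, 0.5), ph$lung_mask)
  expect_equal(ground_truth_pvoi(perf, out, ph$lung_mask), share / 2)

  # near-total obstruction approaches the PVOI = 1 limit
  whole <- defect_spec(ph$lung_mask, 0.001)
  expect_equal(ground_truth_pvoi(perf, insert_defect(perf, whole, ph$lung_mask),
                                 ph$lung_mask), 0.999)

  # additivity: disjoint defects inserted sequentially sum exactly
  m_l <- make_segmental_wedge(ph, side = "left")
  expect_false(any(mask & m_l))
  both <- insert_defect(insert_defect(perf, defect_spec(mask, 0.5),
                                      ph$lung_mask),
                        defect_spec(m_l, 0.3), ph$lung_mask)
  p1 <- ground_truth_pvoi(perf, insert_defect(perf, defect_spec(mask, 0.5),
                                              ph$lung_mask), ph$lung_mask)
  p2 <- ground_truth_pvoi(perf, insert_defect(perf, defect_spec(m_l, 0.3),
                                              ph$lung_mask), ph$lung_mask)
  expect_equal(ground_truth_pvoi(perf, both, ph$lung_mask), p1 + p2)

  # zero normal activity is undefined
  zero <- activity_map(ph$grid, array(0, ph$grid$shape), isotope_tc99m())
  expect_error(ground_truth_pvoi(zero, zero, ph$lung_mask), "undefined")
})
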