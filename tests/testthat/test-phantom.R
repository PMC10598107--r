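test_that("a defect-free noise-free phantom is grade I with zero defect volume", {
  ph <- cached("nodefect", generate_phantom(small_phantom_spec()))
  expect_identical(as.integer(ph$truth$grade), 1L)
  expect_true(all(ph$truth$zone_volumes$v_defect == 0))
  # every voxel gets exactly one known label
  expect_identical(sum(label_counts(ph$truth$labels)),
                   as.integer(prod(dim(ph$truth$labels))))
})

test_that("the seed feeds only the noise: noise-free phantoms are seed-invariant", {
  spec1 <- small_phantom_spec(seed = 1L)
  spec2 <- small_phantom_spec(seed = 999L)
  expect_identical(unclass(generate_phantom(spec1)$ct),
                   unclass(generate_phantom(spec2)$ct))
  # and noisy generation is reproducible for a fixed seed
  specn <- small_phantom_spec(noise_sd_hu = 30, seed = 7L)
  expect_identical(unclass(generate_phantom(specn)$ct),
                   unclass(generate_phantom(specn)$ct))
})

test_that("noise-free HU values lie strictly inside their class intervals", {
  ph <- small_phantom()
  hu <- unclass(ph$ct); lab <- unclass(ph$truth$labels)
  expect_true(all(hu[lab == label_codes[["defect"]]] < 200))
  expect_true(all(hu[lab == label_codes[["bone_tibia"]]] > 200 &
                    hu[lab == label_codes[["bone_tibia"]]] < 1800))
  expect_true(all(hu[lab == label_codes[["cement"]]] > 300 &
                    hu[lab == label_codes[["cement"]]] < 1400))
  expect_true(all(hu[lab == label_codes[["implant"]]] > 2000 &
                    hu[lab == label_codes[["implant"]]] <= 3071))
})

test_that("ellipsoidal defect volume is recovered within 2% at 0.625 mm spacing", {
  spec <- phantom_spec(grid_shape = c(176L, 112L, 176L),
                       spacing_mm = rep(0.625, 3),
                       defects = list(defect_spec("metaphysis", "medial",
                                                  semi_axes_mm = c(6, 5.5, 8),
                                                  target_volume_cm3 = 1.1)))
  ph <- cached("iso625", generate_phantom(spec))
  v_true <- ph$truth$zone_volumes$v_defect[ph$truth$zone_volumes$scope == "total"]
  expect_lt(abs(v_true - 1.1) / 1.1, 0.02)
  # a medial defect distal to the fibular-tip plane grades IIa
  expect_identical(as.integer(ph$truth$grade), 2L)
})

test_that("invalid phantom specs are rejected", {
  expect_error(phantom_spec(spacing_mm = c(0.7, 0.7, 5)), "tray thinner")
  expect_error(phantom_spec(total_length_mm = -5), "positive")
  # a defect poking out of the bone envelope
  bad <- phantom_spec(defects = list(
    defect_spec(centre_mm = c(5, 39, 60), semi_axes_mm = c(10, 10, 10))))
  expect_error(generate_phantom(bad), "outside the bone envelope")
})

test_that("ground-truth zone volumes are consistent with voxel counts", {
  ph <- small_phantom()
  rep <- ph$truth$zone_volumes
  v <- voxel_cm3(ph$truth$labels)
  cnt <- label_counts(ph$truth$labels,
                      c(ph$truth$landmarks$tibial_cut_z,
                        ph$truth$landmarks$distal_end_z))
  tot <- rep[rep$scope == "total", ]
  expect_equal(tot$v_bone, cnt[["bone_tibia"]] * v, tolerance = 1e-12)
  expect_equal(tot$v_defect, cnt[["defect"]] * v, tolerance = 1e-12)
  zones <- rep[rep$scope != "total", ]
  vol_cols <- grep("^v_", names(rep), value = TRUE)
  expect_equal(colSums(zones[, vol_cols]), unlist(tot[, vol_cols]),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("identity confusion matrices reproduce the intraoperative grades", {
  cs <- cohort_spec(500, ct_confusion = diag(4), xray_confusion = diag(4),
                    seed = 3L)
  coh <- simulate_cohort(cs)
  expect_identical(coh$ct, coh$intraop)
  expect_identical(coh$xray, coh$intraop)
})

test_that("simulated confusion frequencies converge to the specified rows", {
  cs <- cohort_spec(40000, seed = 5L)
  coh <- simulate_cohort(cs)
  emp <- prop.table(table(factor(coh$intraop, 1:4), factor(coh$ct, 1:4)), 1)
  for (g in 1:4) {
    n_row <- sum(coh$intraop == g)
    p <- cs$ct_confusion[g, ]
    bound <- 3 * sqrt(pmax(p * (1 - p), 1e-12) / n_row) + 1e-9
    expect_true(all(abs(emp[g, ] - p) <= pmax(bound, 3 / n_row)))
  }
})

test_that("cohort simulation is reproducible and seed-sensitive", {
  a <- simulate_cohort(cohort_spec(200, seed = 10L))
  b <- simulate_cohort(cohort_spec(200, seed = 10L))
  c <- simulate_cohort(cohort_spec(200, seed = 11L))
  expect_identical(a, b)
  expect_false(identical(a$ct, c$ct))
})
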