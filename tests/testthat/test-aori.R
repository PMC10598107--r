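# Toy label maps: 1 mm isotropic, so 500 voxels = 0.5 cm^3; the involvement
# threshold default is 0.5 cm^3. Planes: fibular tip z0 = 20, tubercle z0 = 40,
# midline x0 = 19.5 (medial = R index <= 20).

test_that("grading follows the plane rules in order", {
  lm <- toy_landmarks()
  # no defect -> I
  expect_identical(as.integer(grade_defect(toy_labels(), lm)), 1L)
  # defect proximal to the fibular tip plane -> I, however large
  prox <- toy_labels(list(list(x = 11:20, y = 11:20, z = zr(6, 18), code = 5L)))
  expect_identical(as.integer(grade_defect(prox, lm)), 1L)
  # medial-only defect crossing the tip plane, none below tubercle -> IIa
  med <- toy_labels(list(list(x = 11:18, y = 11:20, z = zr(25, 35), code = 5L)))
  expect_identical(as.integer(grade_defect(med, lm)), 2L)
  # matching lateral defect too -> IIb
  bic <- toy_labels(list(list(x = 11:18, y = 11:20, z = zr(25, 35), code = 5L),
                         list(x = 22:29, y = 11:20, z = zr(25, 35), code = 5L)))
  expect_identical(as.integer(grade_defect(bic, lm)), 3L)
  # any supra-threshold defect below the tubercle -> III regardless of sides
  deep <- toy_labels(list(list(x = 11:18, y = 11:20, z = zr(45, 54), code = 5L)))
  expect_identical(as.integer(grade_defect(deep, lm)), 4L)
})

test_that("sub-threshold involvement does not raise the grade", {
  lm <- toy_landmarks()
  # 384 voxels = 0.384 cm^3 < 0.5 crossing the tip plane
  tiny <- toy_labels(list(list(x = 11:18, y = 11:16, z = zr(25, 32), code = 5L)))
  expect_identical(as.integer(grade_defect(tiny, lm)), 1L)
  expect_identical(as.integer(grade_defect(tiny, lm, min_involvement_cm3 = 0.1)), 2L)
})

test_that("adding defect voxels never decreases the grade", {
  lm <- toy_landmarks()
  fills <- list(
    list(x = 11:18, y = 11:20, z = zr(25, 35), code = 5L),   # medial II
    list(x = 22:29, y = 11:20, z = zr(25, 35), code = 5L),   # + lateral
    list(x = 14:26, y = 11:20, z = zr(45, 54), code = 5L))   # + below tubercle
  prev <- 1L
  for (k in seq_along(fills)) {
    g <- as.integer(grade_defect(toy_labels(fills[seq_len(k)]), lm))
    expect_gte(g, prev)
    prev <- g
  }
})

test_that("mediolateral mirroring preserves the grade value", {
  lm <- toy_landmarks()
  med <- toy_labels(list(list(x = 11:18, y = 11:20, z = zr(25, 35), code = 5L)))
  arr <- unclass(med)[rev(seq_len(dim(med)[1])), , ]  # mirror across midline
  mir <- label_map(arr, spacing_mm(med))
  expect_identical(as.integer(grade_defect(med, lm)),
                   as.integer(grade_defect(mir, lm)))
})

test_that("missing plane landmarks are errors", {
  lab <- toy_labels(list(list(x = 11:18, y = 11:20, z = zr(25, 35), code = 5L)))
  lm_no_tub <- toy_landmarks(); lm_no_tub$tubercle_z <- NA_real_
  expect_error(grade_defect(lab, lm_no_tub), "tubercle")
  lm_no_tip <- toy_landmarks(); lm_no_tip$fibular_tip_z <- NA_real_
  expect_error(grade_defect(lab, lm_no_tip), "fibular_tip")
})

test_that("grade_cohort is element-wise and order-preserving", {
  lm <- toy_landmarks()
  med <- toy_labels(list(list(x = 11:18, y = 11:20, z = zr(25, 35), code = 5L)))
  deep <- toy_labels(list(list(x = 11:18, y = 11:20, z = zr(45, 54), code = 5L)))
  none <- toy_labels()
  g <- grade_cohort(list(none, med, deep), list(lm, lm, lm))
  expect_identical(g, c(1L, 2L, 4L))
  g2 <- grade_cohort(list(deep, none, med), list(lm, lm, lm))
  expect_identical(g2, c(4L, 1L, 2L))
  expect_identical(grade_cohort(list(), list()), integer(0))
  expect_error(grade_cohort(list(a = none), list(lm_bad = NULL)), "Knee")
})
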