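test_that("tibial cut detection follows the tray, then bone, then errors", {
  arr <- array(0L, c(10, 10, 20))
  arr[3:7, 3:7, 11:20] <- 1L
  arr[3:7, 3:7, 11:12] <- 4L       # tray top at 0-based slice 10
  expect_identical(detect_tibial_cut(label_map(arr, 1)), 10L)
  arr[arr == 4L] <- 1L
  arr2 <- array(0L, c(10, 10, 20)); arr2[3:7, 3:7, 5:20] <- 1L
  expect_identical(detect_tibial_cut(label_map(arr2, 1)), 4L)
  arr3 <- array(0L, c(6, 6, 6)); arr3[2, 2, ] <- 4L  # implant on every slice
  expect_identical(detect_tibial_cut(label_map(arr3, 1)), 0L)
  expect_error(detect_tibial_cut(label_map(array(0L, c(4, 4, 4)), 1)), "Empty")
})

test_that("fibular landmarks: tip, widest, and tie rules", {
  arr <- array(0L, c(30, 20, 30))
  # fibula widening then narrowing; widest (9 voxels) at slices 12 and 15 (0-based)
  widths <- c(3, 5, 7, 9, 7, 9, 5)
  for (i in seq_along(widths)) {
    w <- widths[i]
    arr[20 + seq_len(w) - 1, 8:12, 10 + i] <- 2L
  }
  lm <- detect_fibular_landmarks(label_map(arr, 1))
  expect_identical(lm$fibular_tip_z, 10L)
  expect_identical(lm$fibular_widest_z, 13L)   # proximal of the two ties
  # single-slice fibula: tip == widest
  arr1 <- array(0L, c(10, 10, 10)); arr1[4:6, 4:6, 5] <- 2L
  lm1 <- detect_fibular_landmarks(label_map(arr1, 1))
  expect_identical(lm1$fibular_tip_z, lm1$fibular_widest_z)
  expect_error(detect_fibular_landmarks(label_map(array(0L, c(4, 4, 4)), 1)),
               "supply")
})

test_that("epiphyseal width equals the cylinder diameter and is translation-invariant", {
  arr <- array(0L, c(40, 40, 20))
  arr[11:25, 11:25, 3:18] <- 1L   # 15-voxel wide block
  lab <- label_map(arr, c(0.7, 0.7, 1))
  w <- measure_epiphysis_width(lab, 2, 10)
  expect_equal(w, 15 * 0.7, tolerance = 1e-12)
  arr2 <- array(0L, c(40, 40, 20)); arr2[16:30, 11:25, 3:18] <- 1L
  expect_equal(measure_epiphysis_width(label_map(arr2, c(0.7, 0.7, 1)), 2, 10), w)
  expect_error(measure_epiphysis_width(lab, 5, 5), "Empty")
})

test_that("the rule of the square partitions the ROI exactly", {
  lm <- tibial_landmarks(tibial_cut_z = 10, fibular_tip_z = 45,
                         fibular_widest_z = 50, tubercle_z = 90,
                         midline_x = 50, distal_end_z = 300)
  p <- partition_zones(lm, width_mm = 80, spacing = c(1, 1, 0.625))
  expect_identical(p$epiphysis, c(10, 50))
  expect_identical(p$metaphysis, c(50, 138))    # 10 + 80 / 0.625
  expect_identical(p$diaphysis, c(138, 300))
  # contiguous exact cover
  expect_identical(p$epiphysis[2], p$metaphysis[1])
  expect_identical(p$metaphysis[2], p$diaphysis[1])
  # doubling W doubles the square depth
  p2 <- partition_zones(lm, 160, c(1, 1, 0.625))
  expect_identical(p2$metaphysis[2] - p2$epiphysis[1],
                   2L * (p$metaphysis[2] - p$epiphysis[1]))
  # clamping to a short volume empties the diaphysis
  lm2 <- tibial_landmarks(10, 45, 50, 90, 50, 100)
  p3 <- partition_zones(lm2, 80, c(1, 1, 0.625))
  expect_identical(p3$diaphysis, c(100, 100))
  # square shorter than the epiphysis warns and empties the metaphysis
  expect_warning(p4 <- partition_zones(lm, 20, c(1, 1, 0.625)), "metaphysis")
  expect_identical(p4$metaphysis[1], p4$metaphysis[2])
})

test_that("detected landmarks match phantom ground truth within one slice", {
  ph <- small_phantom()
  seg <- split_tibia_fibula(segment_hu(ph$ct))
  lt <- ph$truth$landmarks
  lm <- detect_landmarks(seg, tubercle_z = lt$tubercle_z)
  for (nm in c("tibial_cut_z", "fibular_tip_z", "fibular_widest_z",
               "distal_end_z")) {
    expect_lte(abs(lm[[nm]] - lt[[nm]]), 1)
  }
  expect_lt(abs(lm$midline_x - lt$midline_x), 1)
})

test_that("landmark ordering is validated", {
  expect_error(tibial_landmarks(50, 20, 30, 60, 10, 40), "ordered")
  expect_error(tibial_landmarks(10, 35, 30, 60, 10, 40), "distal")
})
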