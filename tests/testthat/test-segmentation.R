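test_that("uniform implant-range volume is labelled implant throughout", {
  ct <- ct_volume(array(2500L, c(8, 8, 8)), 1)
  lab <- suppressWarnings(segment_hu(ct))
  expect_true(all(unclass(lab) == label_codes[["implant"]]))
})

test_that("cement-range HU far from any implant is bone, not cement", {
  hu <- array(-1000L, c(30, 30, 12))
  hu[3:6, 3:6, 3:10] <- 2500L      # implant block
  hu[24:27, 24:27, 3:10] <- 850L   # cement-range HU ~25 mm away
  lab <- segment_hu(ct_volume(hu, 1), cement_adjacency_mm = 3)
  expect_true(all(unclass(lab)[24:27, 24:27, 3:10] == label_codes[["bone_tibia"]]))
  # the same voxels become cement when the adjacency reaches them
  lab2 <- segment_hu(ct_volume(hu, 1), cement_adjacency_mm = 40)
  expect_true(all(unclass(lab2)[24:27, 24:27, 3:10] == label_codes[["cement"]]))
})

test_that("enlarging the cement adjacency never shrinks the cement class", {
  ph <- small_phantom()
  l1 <- segment_hu(ph$ct, cement_adjacency_mm = 2)
  l2 <- segment_hu(ph$ct, cement_adjacency_mm = 4)
  c1 <- unclass(l1) == label_codes[["cement"]]
  c2 <- unclass(l2) == label_codes[["cement"]]
  expect_true(all(c2[c1]))
})

test_that("every voxel receives exactly one label (conservation)", {
  ph <- small_phantom()
  lab <- split_tibia_fibula(segment_hu(ph$ct))
  expect_identical(sum(label_counts(lab)), as.integer(prod(dim(lab))))
})

test_that("a noise-free phantom re-segments to truth outside a one-voxel shell", {
  ph <- small_phantom()
  seg <- split_tibia_fibula(segment_hu(ph$ct))
  tr <- unclass(ph$truth$labels)
  sg <- unclass(seg)
  mis <- which(tr != sg)
  if (length(mis) > 0) {
    # every mismatched voxel must touch a truth class boundary (26-shell)
    nb <- array(FALSE, dim(tr))
    for (s in list(c(1,0,0), c(-1,0,0), c(0,1,0), c(0,-1,0), c(0,0,1), c(0,0,-1))) {
      ix <- pmin(pmax(seq_len(dim(tr)[1]) + s[1], 1), dim(tr)[1])
      iy <- pmin(pmax(seq_len(dim(tr)[2]) + s[2], 1), dim(tr)[2])
      iz <- pmin(pmax(seq_len(dim(tr)[3]) + s[3], 1), dim(tr)[3])
      nb <- nb | (tr != tr[ix, iy, iz])
    }
    d_boundary <- distance_to(nb, c(1, 1, 1))
    expect_lte(max(d_boundary[mis]), sqrt(3) + 1e-9)
  } else {
    succeed()
  }
})

test_that("segmentation of class-midpoint HU is idempotent up to the boundary shell", {
  ph <- small_phantom()
  seg1 <- split_tibia_fibula(segment_hu(ph$ct))
  hu_lut <- c(-1000L, 1000L, 1000L, 850L, 2500L, -400L)
  hu2 <- array(hu_lut[unclass(seg1) + 1L], dim(seg1))
  seg2 <- split_tibia_fibula(segment_hu(ct_volume(hu2, spacing_mm(ph$ct))))
  agree <- mean(unclass(seg1) == unclass(seg2))
  expect_gt(agree, 0.999)
})

test_that("tibia/fibula split matches ground truth and handles absent fibula", {
  ph <- small_phantom()
  seg <- split_tibia_fibula(segment_hu(ph$ct))
  expect_identical(label_counts(seg)[["bone_fibula"]],
                   label_counts(ph$truth$labels)[["bone_fibula"]])
  nofib <- cached("nofib", generate_phantom(small_phantom_spec(fibula = NULL)))
  seg2 <- split_tibia_fibula(segment_hu(nofib$ct))
  expect_identical(label_counts(seg2)[["bone_fibula"]], 0L)
})

test_that("an all-air volume is rejected and HU 200 goes to bone", {
  expect_error(suppressWarnings(segment_hu(ct_volume(array(-1000L, c(5, 5, 5)), 1))),
               "No foreground")
  hu <- array(-1000L, c(10, 10, 10))
  hu[4:7, 4:7, 4:7] <- 200L
  expect_warning(lab <- segment_hu(ct_volume(hu, 1)), "Empty implant")
  expect_true(all(unclass(lab)[4:7, 4:7, 4:7] == label_codes[["bone_tibia"]]))
})
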