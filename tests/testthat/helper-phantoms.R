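# Shared phantom fixtures, generated once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# coarser grid for unit tests: same anatomy, ~8x fewer voxels
small_phantom_spec <- function(...) {
  phantom_spec(grid_shape = c(112L, 80L, 96L), spacing_mm = c(1, 1, 1.25), ...)
}

small_phantom <- function() {
  cached("small", generate_phantom(
    small_phantom_spec(defects = list(defect_spec("metaphysis", "medial")))))
}

default_phantom <- function() {
  cached("default", generate_phantom(
    phantom_spec(defects = list(defect_spec("metaphysis", "medial")))))
}

# hand-built label map + landmarks for fast grading tests (1 mm isotropic,
# 1 voxel = 1 mm^3); geometry chosen so plane positions are unambiguous
toy_labels <- function(fill = list()) {
  arr <- array(0L, c(40L, 40L, 60L))
  arr[10:30, 10:30, 5:55] <- 1L     # a block of tibial bone
  for (f in fill) arr[f$x, f$y, f$z] <- f$code
  label_map(arr, c(1, 1, 1))
}

toy_landmarks <- function() {
  tibial_landmarks(tibial_cut_z = 4, fibular_tip_z = 20, fibular_widest_z = 25,
                   tubercle_z = 40, midline_x = 19.5, distal_end_z = 55)
}

# 1-based index ranges for carving defects into toy_labels (0-based slices
# z0 map to R index z0 + 1)
zr <- function(z0_from, z0_to) (z0_from + 1):(z0_to + 1)
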