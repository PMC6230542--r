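test_that("phantom generation is a pure function of spec and index", {
  sp <- tiny_phantom_spec(seed = 9L)
  a <- generate_phantom(sp, 7L)
  b <- generate_phantom(sp, 7L)
  expect_identical(a$ct$voxels, b$ct$voxels)
  expect_identical(a$activity$voxels, b$activity$voxels)
  c <- generate_phantom(sp, 8L)
  expect_false(identical(a$ct$voxels, c$ct$voxels))
})

test_that("bone shell is closed when no air cavities are requested", {
  sp <- tiny_phantom_spec(seed = 4L, n_air_cavities_range = c(0L, 0L))
  ph <- generate_phantom(sp, 0L)
  mid <- ceiling(sp$n_slices / 2)
  tis <- ph$ct$tissue[, , mid]
  # oracle: flood from the border through everything that is not bone;
  # a closed shell means no brain-interior pixel is reachable
  reach <- flood_reachable(tis != 2L)
  brain <- ph$activity$label_map[, , mid] > 0
  expect_gt(sum(brain), 0)
  expect_false(any(reach & brain))
})

test_that("a skull defect removes bone relative to the same-seed phantom", {
  sp0 <- tiny_phantom_spec(seed = 6L)
  sp1 <- tiny_phantom_spec(seed = 6L, abnormality = "skull_defect")
  n0 <- sum(generate_phantom(sp0, 2L)$ct$tissue == 2L)
  n1 <- sum(generate_phantom(sp1, 2L)$ct$tissue == 2L)
  expect_lt(n1, n0)
})

test_that("a hot lesion adds a high-uptake ROI", {
  sp <- tiny_phantom_spec(seed = 6L, abnormality = "hot_lesion")
  ph <- generate_phantom(sp, 1L)
  lesion <- ph$activity$label_map == 7L
  expect_gt(sum(lesion), 0)
  expect_true(all(ph$activity$voxels[lesion] ==
                    sp$activity_levels[["lesion"]]))
})

test_that("impossible skull geometry is rejected", {
  sp <- tiny_phantom_spec(head_axes_range = c(20, 20),
                          skull_thickness_range = c(25, 25))
  expect_error(generate_phantom(sp, 0L), "skull thickness")
})

test_that("thresholding the CT recovers the internal tissue labels exactly", {
  sp <- tiny_phantom_spec(seed = 13L)
  for (i in 0:3) {
    ph <- generate_phantom(sp, i)
    expect_true(all(unclass(discretize_ct(ph$ct)) == ph$ct$tissue))
  }
})

test_that("phantom composition invariants hold across draws", {
  sp <- tiny_phantom_spec(seed = 21L)
  for (i in 0:3) {
    ph <- generate_phantom(sp, i)
    head <- head_mask_from_tissue(ph$ct$tissue)
    bone_frac <- sum(ph$ct$tissue == 2L) / sum(head)
    expect_gt(bone_frac, 0)
    expect_lt(bone_frac, 0.5)
    # no uptake outside the body
    outside_air <- ph$ct$tissue == 0L & !head
    expect_true(all(ph$activity$voxels[outside_air] == 0))
    # uptake present throughout the soft tissue
    expect_true(all(ph$activity$voxels[ph$ct$tissue == 1L] > 0))
    ids <- sort(unique(as.vector(ph$activity$label_map)))
    expect_identical(ids, seq(0L, max(ids)))
    expect_gte(max(ids), 4L)
  }
})

test_that("make_dataset writes disjoint splits and is reproducible", {
  sp <- phantom_spec(grid_size = 24L, n_slices = 2L, pixel_size = 9,
                     slice_spacing = 9, seed = 3L)
  d1 <- file.path(tempdir(), "ds1"); d2 <- file.path(tempdir(), "ds2")
  unlink(c(d1, d2), recursive = TRUE)
  m1 <- make_dataset(sp, n_train = 4, n_test = 2, out_dir = d1)
  expect_equal(nrow(m1), 6)
  expect_length(intersect(m1$id[m1$split == "train"],
                          m1$id[m1$split == "test"]), 0)
  m2 <- make_dataset(sp, n_train = 4, n_test = 2, out_dir = d2)
  f1 <- file.path(d1, "manifest.tsv"); f2 <- file.path(d2, "manifest.tsv")
  t1 <- readLines(f1); t2 <- readLines(f2)
  expect_identical(gsub(d1, "", t1, fixed = TRUE),
                   gsub(d2, "", t2, fixed = TRUE))
  expect_error(make_dataset(sp, 4, 2, out_dir = d1), "overwrite")
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("the train/evaluate cohort sizing follows the requested split", {
  sp <- phantom_spec(grid_size = 16L, n_slices = 1L, pixel_size = 14,
                     slice_spacing = 10, scalp_thickness = 4,
                     skull_thickness_range = c(8, 10),
                     n_air_cavities_range = c(0L, 0L), seed = 8L)
  d <- file.path(tempdir(), "ds128")
  unlink(d, recursive = TRUE)
  m <- make_dataset(sp, n_train = 100, n_test = 28, out_dir = d)
  expect_equal(nrow(m), 128)
  expect_equal(sum(m$split == "test"), 28)
  unlink(d, recursive = TRUE)
})
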