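test_that("intensity normalizations follow the stated scalings", {
  cfg <- preprocess_config()
  expect_equal(normalize_pet(array(c(0, 3000, 6000), c(3, 1, 1)), cfg),
               array(c(0, 0.5, 1), c(3, 1, 1)))
  expect_error(normalize_pet(array(-1, c(1, 1, 1)), cfg), "non-negative")
  expect_equal(normalize_ct(array(c(-1000, 0, 1000), c(3, 1, 1)), cfg),
               array(c(0, 0.5, 1), c(3, 1, 1)))
  expect_equal(rescale_to_hu(normalize_ct(317.2, cfg), cfg), 317.2,
               tolerance = 1e-9)
})

test_that("Softsign and its inverse are exact on the open unit range", {
  expect_equal(softsign(0), 0)
  expect_equal(softsign(1), 0.5)
  expect_equal(softsign(-1), -0.5)
  set.seed(7)
  x <- array(rnorm(1000, 0, 3), c(10, 10, 10))
  expect_lt(max(abs(inverse_softsign(softsign(x)) - x)), 1e-9)
  expect_true(all(abs(softsign(x)) < 1))
  expect_error(inverse_softsign(c(0.2, 1)), "range")
})

test_that("the bounding box tightly encloses the thresholded object", {
  v <- array(0, c(40, 30, 3))
  v[11:21, 6:16, ] <- 5     # rows 10..20, cols 5..15 in 0-based coords
  cfg <- preprocess_config(crop_margin = 0L)
  got <- crop_bounding_box(v, cfg)
  # brute-force oracle over every voxel
  fg <- which(v > cfg$crop_threshold * max(v), arr.ind = TRUE)
  expect_equal(got$crop_box,
               c(min(fg[, 1]) - 1L, min(fg[, 2]) - 1L,
                 max(fg[, 1]), max(fg[, 2])))
  expect_equal(got$crop_box, c(10L, 5L, 21L, 16L))
  expect_equal(dim(got$cropped), c(11, 11, 3))

  # all pixels above threshold -> the full image
  flat <- array(1, c(8, 9, 2))
  expect_equal(crop_bounding_box(flat, cfg)$crop_box, c(0L, 0L, 8L, 9L))

  # margins clip at the volume bounds
  edge <- array(0, c(10, 10, 1)); edge[1:4, 7:10, 1] <- 1
  got2 <- crop_bounding_box(edge, preprocess_config(crop_margin = 2L))
  expect_equal(got2$crop_box, c(0L, 4L, 6L, 10L))

  expect_error(crop_bounding_box(array(0, c(5, 5, 1)), cfg), "threshold")
})

test_that("bilinear resampling is exact on identity and constants", {
  set.seed(1)
  sl <- matrix(rnorm(35 * 20), 35, 20)
  expect_identical(resample_bilinear(sl, c(35, 20)), sl)
  expect_equal(resample_bilinear(matrix(3.2, 9, 7), c(21, 13)),
               matrix(3.2, 21, 13))
  # band-limited round trip: upsample then downsample back
  g <- outer(seq(0, pi, length.out = 24), seq(0, pi, length.out = 24),
             function(a, b) sin(a) * cos(b))
  up <- resample_bilinear(g, c(96, 96))
  back <- resample_bilinear(up, c(24, 24))
  expect_lt(max(abs(back - g)), 0.01 * diff(range(g)))
})

test_that("restore_to_source embeds predictions in an air canvas", {
  pred <- matrix(100, 6, 6)
  out <- restore_to_source(pred, crop_box = c(2L, 3L, 8L, 9L),
                           source_shape = c(12L, 14L))
  expect_equal(dim(out), c(12, 14))
  expect_equal(out[3:8, 4:9], matrix(100, 6, 6))
  expect_true(all(out[1:2, ] == -1000))
  expect_true(all(out[, 11:14] == -1000))
})

test_that("slice pairs share one crop box and live inside the Softsign range", {
  ph <- generate_phantom(tiny_phantom_spec(seed = 31L), 0)
  nac <- structure(list(voxels = ph$activity$voxels, spacing = ph$ct$spacing,
                        provenance = "NAC"), class = "pet_image")
  cfg <- preprocess_config(target_matrix = c(32L, 32L))
  pairs <- build_slice_pairs(nac, ph$ct, cfg)
  expect_length(pairs, dim(ph$ct$voxels)[3])
  boxes <- unique(lapply(pairs, `[[`, "crop_box"))
  expect_length(boxes, 1)
  for (p in pairs) {
    expect_equal(dim(p$input), c(32, 32))
    expect_equal(dim(p$target), c(32, 32))
    expect_true(all(abs(p$input) < 1) && all(abs(p$target) < 1))
  }
  expect_error(build_slice_pairs(nac, new_ct_volume(array(0, c(10, 10, 2)),
                                                    c(1, 1, 1))),
               "grid")
})

test_that("the forward chain inverts to the cropped CT within 1 HU", {
  ph <- generate_phantom(tiny_phantom_spec(seed = 8L), 2)
  nac <- structure(list(voxels = ph$activity$voxels, spacing = ph$ct$spacing,
                        provenance = "NAC"), class = "pet_image")
  # first pass just to learn the crop-box size, then match the target
  # matrix to it so resampling is the identity
  box <- crop_bounding_box(normalize_pet(nac$voxels),
                           preprocess_config())$crop_box
  cfg <- preprocess_config(target_matrix = c(box[3] - box[1],
                                             box[4] - box[2]))
  pairs <- build_slice_pairs(nac, ph$ct, cfg)
  preds <- lapply(pairs, `[[`, "target")   # a perfect network
  pseudo <- pseudo_ct_from_predictions(preds, box, dim(ph$ct$voxels)[1:2],
                                       ph$ct$spacing, cfg)
  ct_crop <- ph$ct$voxels[(box[1] + 1):box[3], (box[2] + 1):box[4], ]
  ps_crop <- pseudo$voxels[(box[1] + 1):box[3], (box[2] + 1):box[4], ]
  expect_lt(max(abs(ps_crop - ct_crop)), 1)
})

test_that("slice datasets round-trip through disk", {
  ph <- generate_phantom(tiny_phantom_spec(seed = 14L), 0)
  nac <- structure(list(voxels = ph$activity$voxels, spacing = ph$ct$spacing,
                        provenance = "NAC"), class = "pet_image")
  cfg <- preprocess_config(target_matrix = c(16L, 16L))
  pairs <- build_slice_pairs(nac, ph$ct, cfg, source_id = "ph0")
  path <- file.path(tempdir(), "pairs")
  write_slice_dataset(pairs, path)
  back <- read_slice_dataset(path)
  expect_length(back, length(pairs))
  expect_equal(back[[2]]$input, pairs[[2]]$input, tolerance = 1e-6)
  expect_equal(back[[2]]$target, pairs[[2]]$target, tolerance = 1e-6)
  expect_equal(back[[2]]$crop_box, pairs[[2]]$crop_box)
  expect_equal(back[[2]]$source_id, "ph0")
})
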