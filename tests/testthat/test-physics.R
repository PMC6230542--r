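test_that("HU to attenuation conversion hits the defining points", {
  mu <- ct_to_mu(array(c(-1000, 0), c(2, 1, 1)))
  expect_equal(mu$voxels[1, 1, 1], 0)
  expect_equal(mu$voxels[2, 1, 1], 0.096)
  seq_mu <- ct_to_mu(array(c(-500, 0, 500, 1500), c(4, 1, 1)))$voxels
  expect_true(all(diff(as.vector(seq_mu)) > 0))
  expect_equal(seq_mu[1], 0.096 * 0.5)
  expect_equal(seq_mu[3], 0.096 + 2.2e-5 * 500)
  expect_error(ct_to_mu(array(c(0, NaN), c(1, 1, 2))), "slice")
})

test_that("HU to attenuation conversion is monotone", {
  set.seed(5)
  hu <- array(runif(600, -1200, 2800), c(10, 10, 6))
  mu <- ct_to_mu(hu)$voxels
  ord <- order(hu)
  expect_true(all(diff(mu[ord]) >= 0))
})

test_that("forward projection follows the attenuated line-integral model", {
  g <- 40
  act <- new_activity_map(array(0, c(g, g, 1)), c(5, 5, 5))
  act$voxels[20, 15, 1] <- 800          # a = 800 Bq/ml
  mu <- ct_to_mu(array(-1000, c(g, g, 1)))
  mu$voxels[5:14, , 1] <- 0.1           # slab: 10 rows x 0.5 cm = 5 cm
  geom <- scan_geometry(n_angles = 2, n_bins = 61, bin_width = 5)
  sino <- forward_project(act, mu, geom, count_scale = 1)
  # angle 0 rays run along image rows (x = const): the source ray crosses
  # the full slab; hand oracle: a * l * exp(-mu t), l = 0.5 cm, t = 5 cm
  expected <- 800 * 0.5 * exp(-0.1 * 5)
  expect_equal(sum(sino$counts[1, , 1]), expected, tolerance = 0.01)
  # the perpendicular view misses the slab at the source row
  expect_gt(sum(sino$counts[2, , 1]), expected)
})

test_that("zero activity and zero attenuation behave as identities", {
  g <- 24
  zero <- new_activity_map(array(0, c(g, g, 2)), c(4, 4, 4))
  geom <- scan_geometry(n_angles = 12)
  expect_true(all(forward_project(zero, NULL, geom)$counts == 0))
  act <- new_activity_map(array(runif(g * g * 2), c(g, g, 2)), c(4, 4, 4))
  mu0 <- ct_to_mu(array(-1000, c(g, g, 2)))
  s1 <- forward_project(act, mu0, geom, count_scale = 2)
  s2 <- forward_project(act, NULL, geom, count_scale = 2)
  expect_equal(s1$counts, s2$counts)
})

test_that("forward projection is linear in activity", {
  set.seed(11)
  g <- 24
  geom <- scan_geometry(n_angles = 10)
  mu <- ct_to_mu(array(runif(g * g, -1000, 500), c(g, g, 1)))
  a1 <- new_activity_map(array(runif(g * g), c(g, g, 1)), c(4, 4, 4))
  a2 <- new_activity_map(array(runif(g * g), c(g, g, 1)), c(4, 4, 4))
  sum12 <- new_activity_map(a1$voxels + a2$voxels, c(4, 4, 4))
  f <- function(a) forward_project(a, mu, geom, count_scale = 3)$counts
  expect_equal(f(sum12), f(a1) + f(a2), tolerance = 1e-12)
})

test_that("a too-narrow detector is rejected", {
  g <- 32
  act <- new_activity_map(array(1, c(g, g, 1)), c(4, 4, 4))
  expect_error(forward_project(act, NULL, scan_geometry(10, n_bins = 8)),
               "cover")
})

test_that("Poisson realization is seeded and integer-valued", {
  act <- generate_phantom(tiny_phantom_spec(), 0)$activity
  geom <- scan_geometry(n_angles = 20)
  s1 <- forward_project(act, NULL, geom, count_scale = 1e-3, seed = 4)
  s2 <- forward_project(act, NULL, geom, count_scale = 1e-3, seed = 4)
  expect_identical(s1$counts, s2$counts)
  expect_true(all(s1$counts == round(s1$counts)))
  expect_true(s1$noise_realized)
})

test_that("MLEM reconstructs the defining oracles", {
  g <- 32
  geom <- scan_geometry(n_angles = 40)
  # all-zero sinogram -> all-zero image after one update
  zero <- new_activity_map(array(0, c(g, g, 1)), c(4, 4, 4))
  sz <- forward_project(zero, NULL, geom)
  rz <- reconstruct_osem(sz, NULL, recon_config(1, 1, 0, use_attenuation = FALSE))
  expect_true(all(rz$voxels == 0))
  # noiseless centered point source localizes exactly
  pt <- new_activity_map(array(0, c(g, g, 1)), c(4, 4, 4))
  pt$voxels[17, 17, 1] <- 100
  sp <- forward_project(pt, NULL, geom, count_scale = 1)
  rp <- reconstruct_osem(sp, NULL, recon_config(50, 1, 0, use_attenuation = FALSE))
  expect_equal(which.max(rp$voxels[, , 1]),
               which.max(pt$voxels[, , 1]))
})

test_that("MLEM matches total counts on a noiseless uniform disc", {
  g <- 32
  xy <- expand.grid(1:g, 1:g)
  disc <- array(0, c(g, g, 1))
  disc[as.matrix(xy[(xy[, 1] - 16.5)^2 + (xy[, 2] - 16.5)^2 < 100, ])] <- 50
  act <- new_activity_map(disc, c(4, 4, 4))
  geom <- scan_geometry(n_angles = 40)
  sino <- forward_project(act, NULL, geom, count_scale = 1)
  rec <- reconstruct_osem(sino, NULL,
                          recon_config(60, 1, 0, use_attenuation = FALSE))
  refit <- forward_project(new_activity_map(rec$voxels, c(4, 4, 4)), NULL,
                           geom, count_scale = 1)
  expect_equal(sum(refit$counts), sum(sino$counts), tolerance = 1e-3)
})

test_that("the Poisson log-likelihood is non-decreasing over MLEM iterations", {
  ph <- generate_phantom(tiny_phantom_spec(seed = 2L), 0)
  act <- new_activity_map(ph$activity$voxels[, , 2, drop = FALSE],
                          ph$activity$spacing)
  mu <- ct_to_mu(ph$ct$voxels[, , 2, drop = FALSE])
  sino <- forward_project(act, mu, scan_geometry(n_angles = 30),
                          count_scale = 2e-3)
  rec <- reconstruct_osem(sino, mu, recon_config(25, 1, 0),
                          track_loglik = TRUE)
  ll <- attr(rec, "loglik")
  expect_true(all(diff(ll) > -1e-6 * abs(ll[-length(ll)])))
})

test_that("reconstruction converges towards the true activity", {
  ph <- generate_phantom(tiny_phantom_spec(seed = 3L), 1)
  act <- new_activity_map(ph$activity$voxels[, , 2, drop = FALSE],
                          ph$activity$spacing)
  mu <- ct_to_mu(ph$ct$voxels[, , 2, drop = FALSE])
  sino <- forward_project(act, mu, scan_geometry(n_angles = 60),
                          count_scale = 2e-3)
  nrmse <- function(n_it) {
    r <- reconstruct_osem(sino, mu, recon_config(n_it, 1, 0))
    sqrt(mean((r$voxels - act$voxels)^2)) / max(act$voxels)
  }
  e_early <- nrmse(3); e_late <- nrmse(40)
  expect_lt(e_late, e_early)
  expect_lt(e_late, 0.12)
})

test_that("the Gaussian post filter preserves mass and location", {
  img <- structure(list(voxels = array(0, c(31, 31, 1)),
                        spacing = c(1, 1, 1), provenance = "truth"),
                   class = "pet_image")
  img$voxels[16, 16, 1] <- 10
  expect_identical(apply_post_filter(img, 0)$voxels, img$voxels)
  f <- apply_post_filter(img, 4)
  expect_equal(sum(f$voxels), 10, tolerance = 1e-6)
  expect_equal(which.max(f$voxels), which.max(img$voxels))
  expect_lt(max(f$voxels), 10)
})
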