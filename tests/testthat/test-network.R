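test_that("output shape mirrors the input shape for valid sizes", {
  for (shape in list(c(16, 16), c(32, 16), c(64, 64))) {
    net <- tiny_network(input_shape = shape)
    x <- matrix(rnorm(prod(shape)), shape[1], shape[2])
    y <- predict_slices(net, x)
    expect_equal(dim(y), shape)
  }
})

test_that("invalid input shapes are rejected with guidance", {
  expect_error(build_network(network_spec(list(c(1, 4), c(1, 8))), c(30, 16)),
               "divisible")
  expect_error(build_network(network_spec(list(c(1, 4), c(1, 8))), c(30, 16)),
               "32")
})

test_that("inference pads non-divisible slices and crops the output back", {
  net <- tiny_network(input_shape = c(32, 32))
  x <- matrix(rnorm(33 * 18), 33, 18)
  y <- predict_slices(net, x)
  expect_equal(dim(y), c(33, 18))
})

test_that("the parameter count matches the closed-form oracle", {
  spec <- network_spec(list(c(1, 8), c(1, 16)))
  net <- build_network(spec, c(32, 32))
  # hand count: conv k*k*cin*cout + cout biases, batch norm 2*cout,
  # encoder 1->8, 8->16; decoder 16->16, 16->8; output conv 8->1
  conv <- function(ci, co) 9 * ci * co + co
  bn <- function(co) 2 * co
  expected <- conv(1, 8) + bn(8) + conv(8, 16) + bn(16) +
    conv(16, 16) + bn(16) + conv(16, 8) + bn(8) + conv(8, 1)
  expect_equal(count_parameters(net), expected)
})

test_that("shortcut connections are parameter-free", {
  with_sc <- build_network(network_spec(list(c(1, 8), c(1, 16)),
                                        shortcut_stages = 1L), c(32, 32))
  no_sc <- build_network(network_spec(list(c(1, 8), c(1, 16)),
                                      shortcut_stages = integer(0)),
                         c(32, 32))
  expect_equal(count_parameters(with_sc), count_parameters(no_sc))
})

test_that("zeroed output convolution with the input shortcut is the identity", {
  net <- tiny_network(seed = 5L, input_shape = c(32, 32))
  net$params[["out.w"]][] <- 0
  net$params[["out.b"]][] <- 0
  x <- matrix(rnorm(32 * 32), 32, 32)
  expect_identical(predict_slices(net, x), x)
})

test_that("weight initialization is seeded and follows the fan-in scale", {
  spec <- network_spec(list(c(2, 64)))
  a <- initialize_weights(build_network(spec, c(16, 16)), seed = 11L)
  b <- initialize_weights(build_network(spec, c(16, 16)), seed = 11L)
  expect_identical(a$params, b$params)
  d <- initialize_weights(build_network(spec, c(16, 16)), seed = 12L)
  expect_false(identical(a$params, d$params))
  # a 3x3x64-input kernel: sample sd of its draws near sqrt(2/576)
  w <- a$params[["enc1_2.w"]]
  expect_equal(dim(w), c(3, 3, 64, 64))
  expect_lt(abs(sd(w) - sqrt(2 / 576)) / sqrt(2 / 576), 0.2)
  # batch-norm shifts start at exactly zero, scales at one
  expect_true(all(a$params[["enc1_1.beta"]] == 0))
  expect_true(all(a$params[["enc1_1.gamma"]] == 1))
})

test_that("inference is deterministic and batch-consistent", {
  net <- tiny_network(seed = 2L, input_shape = c(16, 16))
  x3 <- array(rnorm(16 * 16 * 3), c(16, 16, 3))
  y1 <- predict_slices(net, x3)
  y2 <- predict_slices(net, x3)
  expect_identical(y1, y2)
  singles <- sapply(1:3, function(i) predict_slices(net, x3[, , i]),
                    simplify = "array")
  expect_equal(y1, singles, tolerance = 1e-6)
})

test_that("feature maps halve per stage through the encoder", {
  net <- tiny_network(seed = 1L, stages = list(c(1, 4), c(1, 8), c(1, 8)),
                      input_shape = c(32, 32))
  x <- array(rnorm(32 * 32), c(32, 32, 1, 1))
  fw <- petac:::net_forward(net, x, training = FALSE, backprop = TRUE)
  pool_dims <- lapply(Filter(function(i)
    net$layers[[i]]$type == "pool", seq_along(net$layers)),
    function(i) fw$caches[[i]]$in_dim[1:2])
  expect_equal(pool_dims, list(c(32, 32), c(16, 16), c(8, 8)))
})

test_that("gradients reach the first convolution at initialization", {
  net <- tiny_network(seed = 4L, stages = list(c(1, 4), c(1, 8), c(1, 8)),
                      input_shape = c(32, 32))
  set.seed(1)
  x <- array(rnorm(32 * 32 * 2), c(32, 32, 1, 2))
  tg <- array(rnorm(32 * 32 * 2), c(32, 32, 1, 2))
  r <- net_loss_grads(net, x, tg)
  expect_gt(max(abs(r$grads[["enc1_1.w"]])), 0)
  expect_gt(max(abs(r$grads[["enc1_1.b"]])), 0)
})

test_that("analytic gradients agree with finite differences", {
  net <- tiny_network(seed = 6L, input_shape = c(16, 16))
  set.seed(2)
  x <- array(rnorm(16 * 16 * 2), c(16, 16, 1, 2))
  tg <- array(rnorm(16 * 16 * 2), c(16, 16, 1, 2))
  base <- net_loss_grads(net, x, tg)
  eps <- 1e-3
  for (nm in c("enc1_1.w", "dec2_1.w", "dec1_1.gamma", "enc2_1.beta")) {
    i <- min(3, length(net$params[[nm]]))
    up <- net; up$params[[nm]][i] <- up$params[[nm]][i] + eps
    dn <- net; dn$params[[nm]][i] <- dn$params[[nm]][i] - eps
    fd <- (net_loss_grads(up, x, tg)$loss -
             net_loss_grads(dn, x, tg)$loss) / (2 * eps)
    # single-precision convolutions: finite differences agree to ~1%
    expect_equal(base$grads[[nm]][i], fd, tolerance = 0.01)
  }
})

test_that("checkpoints round-trip through disk", {
  net <- tiny_network(seed = 9L)
  path <- file.path(tempdir(), "ck.rds")
  save_checkpoint(net, path)
  back <- load_checkpoint(path)
  expect_identical(back$params, net$params)
  x <- matrix(rnorm(256), 16, 16)
  expect_identical(predict_slices(back, x), predict_slices(net, x))
  expect_error(load_checkpoint(file.path(tempdir(), "nope.rds")), "missing")
})

test_that("network specs round-trip through YAML", {
  spec <- network_spec(list(c(1, 16), c(1, 32), c(2, 64)),
                       shortcut_stages = c(1L, 2L))
  path <- file.path(tempdir(), "net.yaml")
  save_network_spec(spec, path)
  back <- load_network_spec(path)
  expect_equal(back$stages, lapply(spec$stages, as.integer))
  expect_identical(back$shortcut_stages, spec$shortcut_stages)
  expect_identical(back$input_output_shortcut, spec$input_output_shortcut)
  net_a <- build_network(spec, c(64, 64))
  net_b <- build_network(back, c(64, 64))
  expect_equal(count_parameters(net_a), count_parameters(net_b))
})
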