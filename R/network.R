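#' Convolutional encoder-decoder specification
#'
#' Declarative description of the network topology: a VGG-style encoder of
#' unit layers (3x3 convolution, batch normalization, ReLU) with 2x2/stride-2
#' max pooling after each stage, a mirrored decoder whose un-pooling is
#' bilinear upsampling, a final single-filter convolution synthesizing the
#' output image, symmetric parameter-free shortcut connections that add each
#' encoder stage's pre-pool feature map into the mirrored decoder stage
#' (inserted before that unit layer's batch norm and activation — the full
#' pre-activation residual insertion), and an input-to-output shortcut adding
#' the network input to the single-channel output.
#'
#' @param stages list of \code{c(n_conv_layers, n_filters)} per encoder stage
#' @param kernel_size convolution kernel size in pixels (odd)
#' @param shortcut_stages encoder stages whose pre-pool features are added
#'   into the mirrored decoder stage; default: every inter-stage boundary
#'   (all stages but the deepest)
#' @param input_output_shortcut add the input image to the output
#' @param init weight initialization scheme
#' @return object of class \code{network_spec}
#' @export
network_spec <- function(stages = list(c(1, 16), c(1, 32), c(2, 64)),
                         kernel_size = 3L, shortcut_stages = NULL,
                         input_output_shortcut = TRUE,
                         init = c("he_normal")) {
  init <- match.arg(init)
  S <- length(stages)
  if (is.null(shortcut_stages)) shortcut_stages <- seq_len(max(S - 1, 0))
  filters <- vapply(stages, function(s) s[2], numeric(1))
  if (any(diff(filters) < 0)) stop("filters must be non-decreasing over stages")
  stopifnot(kernel_size %% 2 == 1)
  structure(list(stages = stages, kernel_size = as.integer(kernel_size),
                 shortcut_stages = as.integer(shortcut_stages),
                 input_output_shortcut = input_output_shortcut, init = init),
            class = "network_spec")
}

#' The full-size (13 convolution layer) encoder-decoder specification
#'
#' VGG16-configuration encoder — stages (2,64), (2,128), (3,256), (3,512),
#' (3,512), 13 unit layers in total, filters growing from 64 to 512 — with
#' four symmetric shortcut connections and the input-to-output shortcut.
#' @export
full_network_spec <- function() {
  spec <- network_spec(stages = list(c(2, 64), c(2, 128), c(3, 256),
                                     c(3, 512), c(3, 512)),
                       shortcut_stages = 1:4)
  stopifnot(sum(vapply(spec$stages, `[`, numeric(1), 1)) == 13,
            spec$stages[[1]][2] == 64,
            max(vapply(spec$stages, `[`, numeric(1), 2)) == 512,
            length(spec$shortcut_stages) == 4)
  spec
}

#' Build an encoder-decoder network
#'
#' Lays out the layer graph for a given input shape and allocates (zeroed)
#' parameters; call \code{\link{initialize_weights}} before use. The input
#' shape must be divisible by \code{2^n_stages} so pooling and un-pooling
#' round-trip exactly; \code{\link{predict_slices}} pads other sizes
#' automatically.
#'
#' @param spec a \code{\link{network_spec}}
#' @param input_shape integer pair (rows, cols)
#' @return object of class \code{ced_network}
#' @export
build_network <- function(spec, input_shape) {
  S <- length(spec$stages)
  div <- 2^S
  if (any(input_shape %% div != 0)) {
    valid <- pmax(div * ceiling(input_shape / div), div)
    stop("input_shape (", paste(input_shape, collapse = "x"),
         ") must be divisible by 2^", S, " = ", div,
         "; nearest valid size: ", paste(valid, collapse = "x"))
  }
  k <- spec$kernel_size
  filters <- vapply(spec$stages, function(s) as.integer(s[2]), integer(1))
  nconv <- vapply(spec$stages, function(s) as.integer(s[1]), integer(1))
  layers <- list()
  params <- list()
  state <- list()
  add_unit <- function(name, cin, cout, shortcut_from = NULL) {
    layers[[length(layers) + 1]] <<- list(type = "conv", name = name,
                                          cin = cin, cout = cout,
                                          shortcut_from = shortcut_from)
    params[[paste0(name, ".w")]] <<- array(0, c(k, k, cin, cout))
    params[[paste0(name, ".b")]] <<- numeric(cout)
    layers[[length(layers) + 1]] <<- list(type = "bn", name = name, c = cout)
    params[[paste0(name, ".gamma")]] <<- rep(1, cout)
    params[[paste0(name, ".beta")]] <<- numeric(cout)
    state[[paste0(name, ".rmean")]] <<- numeric(cout)
    state[[paste0(name, ".rvar")]] <<- rep(1, cout)
    layers[[length(layers) + 1]] <<- list(type = "relu")
  }
  cin <- 1L
  for (s in seq_len(S)) {
    for (l in seq_len(nconv[s])) {
      add_unit(sprintf("enc%d_%d", s, l), cin, filters[s])
      cin <- filters[s]
    }
    layers[[length(layers) + 1]] <- list(type = "pool",
                                         tag = sprintf("P%d", s))
  }
  for (s in rev(seq_len(S))) {
    layers[[length(layers) + 1]] <- list(type = "upsample")
    for (l in seq_len(nconv[s])) {
      sc <- if (l == 1 && s %in% spec$shortcut_stages) sprintf("P%d", s)
      add_unit(sprintf("dec%d_%d", s, l), cin, filters[s], shortcut_from = sc)
      cin <- filters[s]
    }
  }
  layers[[length(layers) + 1]] <- list(type = "conv", name = "out",
                                       cin = cin, cout = 1L,
                                       shortcut_from = NULL)
  params[["out.w"]] <- array(0, c(k, k, cin, 1L))
  params[["out.b"]] <- numeric(1)
  structure(list(spec = spec, input_shape = as.integer(input_shape),
                 layers = layers, params = params, state = state,
                 bn_momentum = 0.99, bn_eps = 1e-5),
            class = "ced_network")
}

#' Initialize network weights
#'
#' Convolution kernels are drawn from a zero-centered normal whose standard
#' deviation scales with the inverse square root of the fan-in
#' (\eqn{\sqrt{2 / (k^2 C_{in})}}, the rectifier-aware scheme); biases are 0,
#' batch-norm scales 1 and shifts 0. Deterministic given the seed.
#'
#' @param net a \code{ced_network}
#' @param seed integer seed
#' @export
initialize_weights <- function(net, seed = 0L) {
  with_seed(seed, {
    for (nm in names(net$params)) {
      p <- net$params[[nm]]
      if (endsWith(nm, ".w")) {
        d <- dim(p)
        fan_in <- d[1] * d[2] * d[3]
        net$params[[nm]] <- array(stats::rnorm(length(p), 0,
                                               sqrt(2 / fan_in)), d)
      } else if (endsWith(nm, ".b") || endsWith(nm, ".beta")) {
        net$params[[nm]] <- numeric(length(p))
      } else if (endsWith(nm, ".gamma")) {
        net$params[[nm]] <- rep(1, length(p))
      }
    }
    for (nm in names(net$state)) {
      net$state[[nm]] <- if (endsWith(nm, ".rvar")) rep(1, length(net$state[[nm]]))
      else numeric(length(net$state[[nm]]))
    }
  })
  net
}

#' Total number of trainable parameters
#' @param net a \code{ced_network}
#' @export
count_parameters <- function(net) {
  sum(vapply(net$params, length, numeric(1)))
}

# Forward pass. Returns list(out, cache) when backprop = TRUE, else the
# output array. x: (H, W, 1, N) in the Softsign domain.
net_forward <- function(net, x, training = FALSE, backprop = training) {
  stopifnot(length(dim(x)) == 4)
  caches <- if (backprop) vector("list", length(net$layers))
  feats <- list()
  input <- x
  for (li in seq_along(net$layers)) {
    L <- net$layers[[li]]
    if (L$type == "conv") {
      w <- net$params[[paste0(L$name, ".w")]]
      b <- net$params[[paste0(L$name, ".b")]]
      y <- cpp_conv2d_forward(x, w, b)
      if (!is.null(L$shortcut_from)) y <- y + feats[[L$shortcut_from]]
      if (backprop) caches[[li]] <- list(x = x)
      x <- y
    } else if (L$type == "bn") {
      g <- net$params[[paste0(L$name, ".gamma")]]
      be <- net$params[[paste0(L$name, ".beta")]]
      if (training) {
        st <- cpp_bn_stats(x)
        sdv <- sqrt(st$var + net$bn_eps)
        mom <- net$bn_momentum
        net$state[[paste0(L$name, ".rmean")]] <-
          mom * net$state[[paste0(L$name, ".rmean")]] + (1 - mom) * st$mean
        net$state[[paste0(L$name, ".rvar")]] <-
          mom * net$state[[paste0(L$name, ".rvar")]] + (1 - mom) * st$var
        m <- st$mean
      } else {
        m <- net$state[[paste0(L$name, ".rmean")]]
        sdv <- sqrt(net$state[[paste0(L$name, ".rvar")]] + net$bn_eps)
      }
      y <- cpp_bn_forward(x, m, sdv, g, be)
      if (backprop) caches[[li]] <- list(x = x, m = m, sdv = sdv, g = g)
      x <- y
    } else if (L$type == "relu") {
      x <- cpp_relu_forward(x)
      if (backprop) caches[[li]] <- list(y = x)
    } else if (L$type == "pool") {
      feats[[L$tag]] <- x
      r <- cpp_maxpool2_forward(x)
      if (backprop) caches[[li]] <- list(idx = r$idx, in_dim = dim(x))
      x <- r$y
    } else if (L$type == "upsample") {
      if (backprop) caches[[li]] <- list(in_dim = dim(x))
      x <- cpp_upsample2_forward(x)
    }
  }
  if (net$spec$input_output_shortcut) x <- x + input
  if (backprop) list(out = x, caches = caches, net = net) else x
}

# Backward pass through a cached forward. Returns the parameter gradients.
net_backward <- function(net, caches, dy) {
  grads <- list()
  sc_grads <- list()
  for (li in rev(seq_along(net$layers))) {
    L <- net$layers[[li]]
    if (L$type == "conv") {
      cc <- caches[[li]]
      if (!is.null(L$shortcut_from)) {
        tag <- L$shortcut_from
        sc_grads[[tag]] <- if (is.null(sc_grads[[tag]])) dy
        else sc_grads[[tag]] + dy
      }
      g <- cpp_conv2d_backward(cc$x, net$params[[paste0(L$name, ".w")]], dy,
                               need_dx = li > 1)
      grads[[paste0(L$name, ".w")]] <- g$dw
      grads[[paste0(L$name, ".b")]] <- g$db
      dy <- g$dx
    } else if (L$type == "bn") {
      cc <- caches[[li]]
      g <- cpp_bn_backward(cc$x, dy, cc$m, cc$sdv, cc$g)
      grads[[paste0(L$name, ".beta")]] <- g$dbeta
      grads[[paste0(L$name, ".gamma")]] <- g$dgamma
      dy <- g$dx
    } else if (L$type == "relu") {
      dy <- cpp_relu_backward(dy, caches[[li]]$y)
    } else if (L$type == "pool") {
      cc <- caches[[li]]
      dx <- numeric(prod(cc$in_dim))
      dx[as.vector(cc$idx)] <- as.vector(dy)
      dx <- array(dx, cc$in_dim)
      tag <- L$tag
      if (!is.null(sc_grads[[tag]])) dx <- dx + sc_grads[[tag]]
      dy <- dx
    } else if (L$type == "upsample") {
      dy <- cpp_upsample2_backward(dy)
    }
  }
  grads
}

#' Loss and gradients on one mini-batch
#'
#' Mean squared error in the Softsign domain, averaged over all pixels of
#' the batch, and its gradients with respect to every trainable parameter.
#' Exposed for diagnostics (e.g. gradient-flow checks); the training loop
#' uses it internally.
#' @param net a \code{ced_network}
#' @param x input batch (H, W, 1, N)
#' @param target target batch of the same shape
#' @return list(loss, grads, net) — \code{net} carries updated batch-norm
#'   running statistics
#' @export
net_loss_grads <- function(net, x, target) {
  fw <- net_forward(net, x, training = TRUE, backprop = TRUE)
  diff <- fw$out - target
  loss <- mean(diff^2)
  dy <- 2 * diff / length(diff)
  grads <- net_backward(fw$net, fw$caches, dy)
  list(loss = loss, grads = grads, net = fw$net)
}

pad_to_valid <- function(slice, div, value = 0) {
  d <- dim(slice)
  target <- as.integer(ceiling(d / div) * div)
  if (all(target == d)) return(list(x = slice, orig = d))
  out <- matrix(value, target[1], target[2])
  out[seq_len(d[1]), seq_len(d[2])] <- slice
  list(x = out, orig = d)
}

#' Run inference on one or more slices
#'
#' Deterministic: batch normalization uses its running statistics. Slices
#' whose shape is not divisible by \code{2^n_stages} are zero-padded (zero is
#' the normalized-air value in the Softsign domain) and the output cropped
#' back, so e.g. a 200x180 matrix is processed at 224x192.
#'
#' @param net an initialized/trained \code{ced_network}
#' @param slices a 2D array, or a 3D array (H, W, N) of slices
#' @return predictions with the same shape as the input
#' @export
predict_slices <- function(net, slices) {
  one <- length(dim(slices) %||% c(1, 1)) == 2 || is.null(dim(slices))
  if (is.matrix(slices)) slices <- array(slices, c(dim(slices), 1))
  d <- dim(slices)
  div <- 2^length(net$spec$stages)
  padded <- lapply(seq_len(d[3]), function(i) pad_to_valid(slices[, , i], div))
  pd <- dim(padded[[1]]$x)
  x <- array(0, c(pd[1], pd[2], 1, d[3]))
  for (i in seq_len(d[3])) x[, , 1, i] <- padded[[i]]$x
  y <- net_forward(net, x, training = FALSE, backprop = FALSE)
  out <- array(0, d)
  for (i in seq_len(d[3])) out[, , i] <- y[seq_len(d[1]), seq_len(d[2]), 1, i]
  if (one && d[3] == 1) out[, , 1] else out
}

#' Save / load a network checkpoint
#'
#' A single self-describing file: the network spec, input shape, parameters
#' and batch-norm state together.
#' @param net a \code{ced_network}
#' @param path checkpoint file path
#' @export
save_checkpoint <- function(net, path) {
  saveRDS(list(spec = net$spec, input_shape = net$input_shape,
               params = net$params, state = net$state), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop("missing checkpoint file: ", path)
  ck <- readRDS(path)
  net <- build_network(ck$spec, ck$input_shape)
  net$params <- ck$params
  net$state <- ck$state
  net
}

#' Round-trip a network spec through YAML
#'
#' @param spec a \code{\link{network_spec}}
#' @param path YAML file path
#' @export
save_network_spec <- function(spec, path) {
  yaml::write_yaml(list(stages = lapply(spec$stages, as.integer),
                        kernel_size = spec$kernel_size,
                        shortcut_stages = as.integer(spec$shortcut_stages),
                        input_output_shortcut = spec$input_output_shortcut,
                        init = spec$init), path)
  invisible(path)
}

#' @rdname save_network_spec
#' @export
load_network_spec <- function(path) {
  l <- yaml::read_yaml(path)
  network_spec(stages = lapply(l$stages, unlist),
               kernel_size = l$kernel_size,
               shortcut_stages = unlist(l$shortcut_stages),
               input_output_shortcut = l$input_output_shortcut,
               init = l$init)
}
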