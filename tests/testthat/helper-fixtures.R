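# Small shared fixtures; everything is generated in code.

tiny_phantom_spec <- function(seed = 42L, ...) {
  phantom_spec(grid_size = 48L, n_slices = 4L, pixel_size = 4.5,
               slice_spacing = 4.5, seed = seed, ...)
}

tiny_network <- function(seed = 3L, stages = list(c(1, 4), c(1, 8)),
                         input_shape = c(16, 16)) {
  initialize_weights(build_network(network_spec(stages), input_shape),
                     seed = seed)
}

# Independent flood fill used as a geometry oracle: grows a reachable set
# from the volume border through "passable" pixels by repeated dilation.
flood_reachable <- function(passable) {
  d <- dim(passable)
  reach <- matrix(FALSE, d[1], d[2])
  reach[1, ] <- passable[1, ]; reach[d[1], ] <- passable[d[1], ]
  reach[, 1] <- reach[, 1] | passable[, 1]
  reach[, d[2]] <- reach[, d[2]] | passable[, d[2]]
  repeat {
    nxt <- reach
    nxt[-1, ] <- nxt[-1, ] | reach[-d[1], ]
    nxt[-d[1], ] <- nxt[-d[1], ] | reach[-1, ]
    nxt[, -1] <- nxt[, -1] | reach[, -d[2]]
    nxt[, -d[2]] <- nxt[, -d[2]] | reach[, -1]
    nxt <- nxt & passable
    if (identical(nxt, reach)) return(reach)
    reach <- nxt
  }
}
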