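#' Training configuration
#'
#' ADAM at a fixed learning rate with a mean-squared-error image loss
#' computed per mini-batch; defaults follow the reference recipe
#' (lr 0.001, batch 12, 50 epochs).
#'
#' @param learning_rate fixed ADAM step size
#' @param batch_size images per mini-batch
#' @param n_epochs training epochs
#' @param loss image loss ("mse")
#' @param optimizer "adam"
#' @param seed integer seed driving the epoch shuffles
#' @export
train_config <- function(learning_rate = 0.001, batch_size = 12L,
                         n_epochs = 50L, loss = c("mse"),
                         optimizer = c("adam"), seed = 0L) {
  loss <- match.arg(loss); optimizer <- match.arg(optimizer)
  stopifnot(learning_rate > 0, batch_size >= 1, n_epochs >= 1)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 n_epochs = as.integer(n_epochs), loss = loss,
                 optimizer = optimizer, seed = as.integer(seed)),
            class = "train_config")
}

#' Iterations implied by a dataset size and epoch count
#'
#' One iteration = one mini-batch update; an epoch runs
#' \code{ceiling(n_slices / batch_size)} iterations. (4,800 slices at batch
#' 12 for 50 epochs gives exactly 20,000 iterations.)
#' @param n_slices dataset size
#' @param batch_size mini-batch size
#' @param n_epochs epochs
#' @export
iterations_for <- function(n_slices, batch_size, n_epochs) {
  n_epochs * ceiling(n_slices / batch_size)
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0)
}

adam_step <- function(params, grads, st, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  st$t <- st$t + 1
  bc1 <- 1 - beta1^st$t
  bc2 <- 1 - beta2^st$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * g
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (st$m[[nm]] / bc1) / (sqrt(st$v[[nm]] / bc2) + eps)
  }
  list(params = params, st = st)
}

#' Train an encoder-decoder on slice pairs
#'
#' Shuffled mini-batch ADAM updates on the Softsign-domain MSE; one
#' parameter checkpoint per epoch; the returned network is the checkpoint at
#' the epoch with the least training loss (ties broken by the earliest
#' epoch). Aborts on a non-finite loss, naming the offending batch.
#'
#' @param net an initialized \code{ced_network}
#' @param pairs list of slice pairs from \code{\link{build_slice_pairs}}
#' @param cfg a \code{\link{train_config}}
#' @param checkpoint_dir optional directory for on-disk epoch checkpoints
#' @param verbose print a per-epoch loss line
#' @return list with \code{network} (best epoch), \code{curve} (a
#'   \code{loss_curve}: per-epoch mean MSE and \code{best_epoch}) and
#'   \code{checkpoints} (in-memory per-epoch parameter sets)
#' @export
train_network <- function(net, pairs, cfg = train_config(),
                          checkpoint_dir = NULL, verbose = FALSE) {
  stopifnot(length(pairs) >= 1)
  d <- dim(pairs[[1]]$input)
  n <- length(pairs)
  X <- array(0, c(d, 1, n)); Tg <- array(0, c(d, 1, n))
  for (i in seq_len(n)) {
    X[, , 1, i] <- pairs[[i]]$input
    Tg[, , 1, i] <- pairs[[i]]$target
  }
  st <- adam_init(net$params)
  losses <- numeric(cfg$n_epochs)
  checkpoints <- vector("list", cfg$n_epochs)
  with_seed(substream_seed(cfg$seed, "shuffle"), {
    for (ep in seq_len(cfg$n_epochs)) {
      ord <- sample(n)
      starts <- seq(1, n, by = cfg$batch_size)
      batch_losses <- numeric(length(starts))
      for (bi in seq_along(starts)) {
        ix <- ord[starts[bi]:min(starts[bi] + cfg$batch_size - 1, n)]
        r <- net_loss_grads(net, X[, , , ix, drop = FALSE],
                            Tg[, , , ix, drop = FALSE])
        if (!is.finite(r$loss))
          stop("non-finite training loss at epoch ", ep, ", batch ", bi,
               " (slices ", paste(ix, collapse = ","), ")")
        net <- r$net
        upd <- adam_step(net$params, r$grads, st, cfg$learning_rate)
        net$params <- upd$params
        st <- upd$st
        batch_losses[bi] <- r$loss
      }
      losses[ep] <- mean(batch_losses)
      checkpoints[[ep]] <- list(params = net$params, state = net$state)
      if (!is.null(checkpoint_dir)) {
        dir.create(checkpoint_dir, recursive = TRUE, showWarnings = FALSE)
        save_checkpoint(net, file.path(checkpoint_dir,
                                       sprintf("epoch_%03d.rds", ep)))
      }
      if (verbose) message(sprintf("epoch %d/%d  loss %.6g", ep,
                                   cfg$n_epochs, losses[ep]))
    }
  })
  curve <- structure(list(loss = losses, best_epoch = which.min(losses)),
                     class = "loss_curve")
  list(network = select_model(curve, checkpoints, net),
       curve = curve, checkpoints = checkpoints)
}

#' Select the least-loss checkpoint
#'
#' Returns the network at \code{best_epoch} (the argmin of the loss curve;
#' ties resolve to the earliest epoch).
#' @param curve a \code{loss_curve}
#' @param checkpoints per-epoch parameter sets (from \code{train_network})
#'   or a directory of epoch checkpoint files
#' @param net a network template providing the layer graph
#' @export
select_model <- function(curve, checkpoints, net = NULL) {
  stopifnot(length(curve$loss) >= 1)
  best <- which.min(curve$loss)
  if (is.character(checkpoints)) {
    return(load_checkpoint(file.path(checkpoints,
                                     sprintf("epoch_%03d.rds", best))))
  }
  stopifnot(!is.null(net))
  ck <- checkpoints[[best]]
  if (is.null(ck)) stop("missing checkpoint for epoch ", best)
  net$params <- ck$params
  net$state <- ck$state
  net
}
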