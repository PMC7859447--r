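# Unsupervised training: population mode over a set of volumes (all
# ordered pairs, shuffled per epoch) and instance mode on a single pair.
# Optimizer is Adam; the population learning rate follows a stepped
# schedule (2e-4 halved every 10 epochs).

#' Stepped learning-rate schedule
#'
#' `lr(epoch) = lr0 * 0.5^(epoch %/% 10)`: the initial rate is halved
#' after every 10 epochs.
#'
#' @param epoch 0-based epoch index (vectorized).
#' @param lr0 initial learning rate.
#' @export
lr_schedule <- function(epoch, lr0 = 2e-4) {
  lr0 * 0.5^(epoch %/% 10L)
}

adam_state <- function(leaves) {
  list(m = lapply(leaves, function(x) x * 0),
       v = lapply(leaves, function(x) x * 0),
       t = 0L)
}

adam_step <- function(leaves, grads, st, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  st$t <- st$t + 1L
  bc1 <- 1 - beta1^st$t
  bc2 <- 1 - beta2^st$t
  for (k in seq_along(leaves)) {
    g <- grads[[k]]
    st$m[[k]] <- beta1 * st$m[[k]] + (1 - beta1) * g
    st$v[[k]] <- beta2 * st$v[[k]] + (1 - beta2) * g * g
    leaves[[k]] <- leaves[[k]] -
      lr * (st$m[[k]] / bc1) / (sqrt(st$v[[k]] / bc2) + eps)
  }
  list(leaves = leaves, state = st)
}

# one optimization step on a wrapped parameter set; returns grads + loss
epreg_step <- function(params, wrapped, leaves, fixed, moving,
                       cache = NULL) {
  fw <- epreg_forward(params, fixed, moving, wrapped = wrapped,
                      cache = cache)
  lo <- total_loss_node(fixed, moving, fw$grids, fw$full_grid,
                        params$config, cache = cache)
  if (!is.finite(lo$node$value)) {
    bd <- lo$breakdown
    bad <- c(paste0("sim", 1:4)[!is.finite(bd$sim)],
             if (!is.finite(bd$smooth)) "smooth")
    stop("non-finite training loss (offending term: ",
         paste(bad, collapse = ", "), ")")
  }
  ad_backward(lo$node)
  grads <- lapply(leaves, function(nd) {
    if (is.null(nd$grad)) nd$value * 0 else nd$grad
  })
  list(grads = grads, breakdown = lo$breakdown)
}

wrap_with_leaves <- function(params) {
  col <- new.env()
  col$leaves <- list()
  wrapped <- wrap_params(params, col)
  list(wrapped = wrapped, leaves = col$leaves)
}

#' Optimize the registration objective on a single pair
#'
#' Desk-scale counterpart of population training: starting from a fresh
#' (identity) network, Adam minimizes the same multi-scale objective on
#' one volume pair. The identity initialization means the iteration-0
#' loss is exactly the unwarped similarity, so training can only improve
#' or match it.
#'
#' @param fixed,moving preprocessed 3D arrays in \[0, 1\], 16-divisible
#'   shape.
#' @param cfg an [epreg_config()].
#' @param iters number of Adam steps.
#' @param lr constant learning rate (instance mode does not use the
#'   population epoch schedule).
#' @param seed seed for parameter initialization.
#' @param verbose print the loss every 25 iterations.
#' @return List with `params` (trained), `log` (data.frame of per-step
#'   loss terms) and `result` (final [register_pair()] output).
#' @export
instance_optimize <- function(fixed, moving, cfg = epreg_config(),
                              iters = 200L, lr = 1e-3, seed = 1L,
                              verbose = FALSE) {
  fixed <- vol_data(fixed)
  moving <- vol_data(moving)
  params <- epreg_params(cfg, seed = seed)
  leaves <- param_leaves(params)
  st <- adam_state(leaves)
  cache <- new.env(parent = emptyenv())
  log <- vector("list", iters)
  for (it in seq_len(iters)) {
    ww <- wrap_with_leaves(params)
    stp <- epreg_step(params, ww$wrapped, ww$leaves, fixed, moving,
                      cache = cache)
    upd <- adam_step(lapply(ww$leaves, function(n) n$value), stp$grads,
                     st, lr)
    st <- upd$state
    params <- set_param_leaves(params, upd$leaves)
    bd <- stp$breakdown
    log[[it]] <- data.frame(step = it, total = bd$total,
                            sim1 = bd$sim[1], sim2 = bd$sim[2],
                            sim3 = bd$sim[3], sim4 = bd$sim[4],
                            smooth = bd$smooth, lr = lr)
    if (verbose && it %% 25L == 0L) {
      message(sprintf("iter %4d  total %.3f  smooth %.4f", it,
                      bd$total, bd$smooth))
    }
  }
  list(params = params, log = do.call(rbind, log),
       result = register_pair(fixed, moving, params))
}

#' Register a pair with a trained network (one forward pass)
#'
#' @param fixed,moving preprocessed 3D arrays.
#' @param params trained [epreg_params()].
#' @param moving_labels optional integer label map to warp
#'   (nearest-neighbour) with the predicted grid.
#' @return List with `warped` (3D array), `full_grid`, `agg_field`
#'   (full-resolution displacement, normalized coordinates), `grids` and
#'   `phis` (numeric arrays per level), `affine12`, and `warped_labels`
#'   when labels were given.
#' @export
register_pair <- function(fixed, moving, params, moving_labels = NULL) {
  fixed <- vol_data(fixed)
  moving <- vol_data(moving)
  fw <- epreg_forward(params, fixed, moving)
  full_grid <- fw$full_grid$value
  out <- list(
    warped = array(fw$warped$value, dim(fixed)),
    full_grid = full_grid,
    agg_field = full_grid - identity_grid(dim(fixed)),
    grids = lapply(fw$grids, ad_value),
    phis = lapply(fw$phis, ad_value),
    affine12 = fw$affine12$value
  )
  if (!is.null(moving_labels)) {
    out$warped_labels <- warp_labels_nn(moving_labels, full_grid)
  }
  out
}

#' Train on a population of volumes
#'
#' All ordered pairs of distinct volumes form the training set; pairs are
#' reshuffled every epoch with the run seed. The learning rate follows
#' [lr_schedule()] (2e-4 halved every 10 epochs by default) and the
#' objective is the same multi-scale loss as in instance mode.
#'
#' @param volumes list of preprocessed same-shape 3D arrays (>= 2).
#' @param cfg an [epreg_config()].
#' @param epochs number of epochs.
#' @param lr0 initial learning rate.
#' @param seed run seed (initialization and pair shuffling).
#' @param checkpoint_path optional path; the best-loss checkpoint is
#'   saved there after every epoch.
#' @param verbose print per-epoch mean loss.
#' @return List with `params` (best epoch-mean loss), `final_params`,
#'   and `log` (per-step data.frame).
#' @export
train_epreg <- function(volumes, cfg = epreg_config(), epochs = 3L,
                        lr0 = 2e-4, seed = 1L, checkpoint_path = NULL,
                        verbose = FALSE) {
  stopifnot(length(volumes) >= 2L)
  volumes <- lapply(volumes, vol_data)
  shp <- dim(volumes[[1]])
  for (v in volumes) stopifnot(identical(dim(v), shp))
  params <- epreg_params(cfg, seed = seed)
  leaves <- param_leaves(params)
  st <- adam_state(leaves)
  pairs <- expand.grid(f = seq_along(volumes), m = seq_along(volumes))
  pairs <- pairs[pairs$f != pairs$m, ]
  caches <- lapply(seq_len(nrow(pairs)),
                   function(i) new.env(parent = emptyenv()))
  best <- list(loss = Inf, params = params)
  log <- list()
  for (ep in seq_len(epochs) - 1L) {
    lr <- lr_schedule(ep, lr0)
    set.seed(seed + ep)
    ord <- sample(nrow(pairs))
    ep_losses <- numeric(0)
    for (r in ord) {
      ww <- wrap_with_leaves(params)
      stp <- epreg_step(params, ww$wrapped, ww$leaves,
                        volumes[[pairs$f[r]]], volumes[[pairs$m[r]]],
                        cache = caches[[r]])
      upd <- adam_step(lapply(ww$leaves, function(n) n$value),
                       stp$grads, st, lr)
      st <- upd$state
      params <- set_param_leaves(params, upd$leaves)
      bd <- stp$breakdown
      ep_losses <- c(ep_losses, bd$total)
      log[[length(log) + 1L]] <-
        data.frame(epoch = ep, pair = r, total = bd$total,
                   smooth = bd$smooth, lr = lr)
    }
    mloss <- mean(ep_losses)
    if (verbose) message(sprintf("epoch %3d  lr %.2e  mean loss %.3f",
                                 ep, lr, mloss))
    if (mloss < best$loss) best <- list(loss = mloss, params = params)
    if (!is.null(checkpoint_path)) save_checkpoint(best$params,
                                                   checkpoint_path)
  }
  list(params = best$params, final_params = params,
       log = do.call(rbind, log))
}

#' Save / load a self-describing checkpoint
#'
#' The checkpoint carries the parameters together with their
#' configuration, so a loaded file reconstructs the exact architecture.
#'
#' @param params an [epreg_params()].
#' @param path file path.
#' @export
save_checkpoint <- function(params, path) {
  saveRDS(list(params = params, package_version = "0.1.0"), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  stopifnot(inherits(ck$params, "epreg_params"))
  ck$params
}
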