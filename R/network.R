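# The registration network: a shared dual-stream encoder produces
# four-level feature pyramids from the (intensity, edge) dual input of the
# fixed and the moving volume; an affine block regresses 12 degrees of
# freedom from the coarsest paired features; three deformable blocks then
# estimate residual displacement fields coarse-to-fine, each grid being
# the 2x-upsampled previous grid plus the new residual. One forward pass
# yields phi_4..phi_1, G_4..G_1 and the warped moving volume.

#' Network configuration
#'
#' @param widths encoder channel widths per pyramid level (level 1..4).
#'   These are not fixed by the architecture description; the defaults are
#'   sized for CPU-scale experiments and are recorded in checkpoints.
#' @param aspp_rates dilation rates of the atrous spatial pyramid pooling
#'   branches at the coarsest level.
#' @param use_edges if `FALSE`, the Sobel edge channel is dropped and the
#'   encoder takes a single intensity channel (the "PReg" ablation).
#' @param norm_eps epsilon of the per-channel feature normalization.
#' @param lambda smoothness weight of the training objective.
#' @param window local cross-correlation window edge length (odd voxels).
#' @return A list of class `epreg_config`.
#' @export
epreg_config <- function(widths = c(16L, 32L, 32L, 64L),
                         aspp_rates = c(1L, 2L, 4L),
                         use_edges = TRUE,
                         norm_eps = 1e-5,
                         lambda = 1000,
                         window = 9L) {
  stopifnot(length(widths) == 4L, all(widths >= 1L),
            window %% 2L == 1L, window >= 3L, lambda >= 0)
  structure(list(widths = as.integer(widths),
                 aspp_rates = as.integer(aspp_rates),
                 use_edges = isTRUE(use_edges),
                 norm_eps = norm_eps,
                 lambda = lambda,
                 window = as.integer(window)),
            class = "epreg_config")
}

# ---- parameter construction --------------------------------------------

new_conv <- function(cin, cout, zero = FALSE) {
  k <- 27L * cin
  w <- if (zero) matrix(0, k, cout)
       else matrix(rnorm(k * cout, sd = sqrt(2 / k)), k, cout)
  list(w = w, b = numeric(cout))
}

new_pointwise <- function(cin, cout, zero = FALSE) {
  w <- if (zero) matrix(0, cin, cout)
       else matrix(rnorm(cin * cout, sd = sqrt(2 / cin)), cin, cout)
  list(w = w, b = numeric(cout))
}

new_norm <- function(c) list(g = rep(1, c), b = numeric(c))

# residual block; a projection shortcut is added when cin != cout
new_res_block <- function(cin, cout) {
  p <- list(conv1 = new_conv(cin, cout), n1 = new_norm(cout),
            conv2 = new_conv(cout, cout), n2 = new_norm(cout))
  if (cin != cout) p$proj <- new_pointwise(cin, cout)
  p
}

#' Initialize network parameters
#'
#' Encoder weights are He-initialized; the final 1x1x1 convolutions of the
#' affine and deformable heads are zero-initialized so that the untrained
#' network is exactly the identity map (a stable anchor for unsupervised
#' training). The encoder is a single parameter set literally shared by
#' the fixed and moving streams.
#'
#' @param cfg an [epreg_config()].
#' @param seed optional integer seed for reproducible initialization.
#' @return Nested list of parameter arrays of class `epreg_params`.
#' @export
epreg_params <- function(cfg = epreg_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  w <- cfg$widths
  in_ch <- if (cfg$use_edges) 2L else 1L
  enc <- list(
    b1 = list(conv = new_conv(in_ch, w[1]), n = new_norm(w[1])),
    b2 = list(conv = new_conv(w[1], w[2]), n = new_norm(w[2]),
              res1 = new_res_block(w[2], w[2]),
              res2 = new_res_block(w[2], w[2])),
    b3 = list(conv = new_conv(w[2], w[3]), n = new_norm(w[3]),
              res1 = new_res_block(w[3], w[3]),
              res2 = new_res_block(w[3], w[3])),
    b4 = list(conv = new_conv(w[3], w[4]), n = new_norm(w[4]),
              aspp = list(branches = lapply(cfg$aspp_rates,
                                            function(r) new_conv(w[4], w[4])),
                          fuse = new_pointwise(w[4] * length(cfg$aspp_rates),
                                               w[4]),
                          n = new_norm(w[4])))
  )
  aff <- list(res = new_res_block(2L * w[4], 2L * w[4]),
              out = new_pointwise(2L * w[4], 12L, zero = TRUE))
  def_head <- function(ci, cn) {
    cin <- 2L * ci + 2L * cn + 3L
    list(res1 = new_res_block(cin, ci),
         res2 = new_res_block(ci, ci),
         out = new_pointwise(ci, 3L, zero = TRUE))
  }
  structure(list(enc = enc, aff = aff,
                 def3 = def_head(w[3], w[4]),
                 def2 = def_head(w[2], w[3]),
                 def1 = def_head(w[1], w[2]),
                 config = cfg),
            class = "epreg_params")
}

# wrap every numeric leaf in an ad_param node; `leaves` collects them in a
# stable order so gradients can be read back after ad_backward()
wrap_params <- function(params, collector) {
  wrap <- function(x) {
    if (is.list(x)) return(lapply(x, wrap))
    if (is.numeric(x)) {
      nd <- ad_param(x)
      collector$leaves[[length(collector$leaves) + 1L]] <- nd
      return(nd)
    }
    x
  }
  wrap(params[setdiff(names(params), "config")])
}

param_leaves <- function(params) {
  out <- list()
  walk <- function(x) {
    if (is.list(x)) {
      for (e in x) walk(e)
    } else if (is.numeric(x)) {
      out[[length(out) + 1L]] <<- x
    }
  }
  walk(params[setdiff(names(params), "config")])
  out
}

set_param_leaves <- function(params, values) {
  i <- 0L
  walk <- function(x) {
    if (is.list(x)) return(lapply(x, walk))
    if (is.numeric(x)) {
      i <<- i + 1L
      return(values[[i]])
    }
    x
  }
  out <- walk(params[setdiff(names(params), "config")])
  out$config <- params$config
  class(out) <- class(params)
  out
}

# ---- layers -------------------------------------------------------------

res_block_fw <- function(x, pp, eps) {
  h <- ad_relu(ad_norm(ad_conv3d(x, pp$conv1$w, pp$conv1$b),
                       pp$n1$g, pp$n1$b, eps))
  h <- ad_norm(ad_conv3d(h, pp$conv2$w, pp$conv2$b), pp$n2$g, pp$n2$b, eps)
  sc <- if (!is.null(pp$proj)) ad_pointwise(x, pp$proj$w, pp$proj$b) else x
  ad_relu(ad_add(h, sc))
}

down_block_fw <- function(x, pp, eps) {
  ad_relu(ad_norm(ad_conv3d(x, pp$conv$w, pp$conv$b, stride = 2L),
                  pp$n$g, pp$n$b, eps))
}

aspp_fw <- function(x, pp, rates, eps) {
  branches <- lapply(seq_along(rates), function(k) {
    ad_conv3d(x, pp$branches[[k]]$w, pp$branches[[k]]$b,
              dilation = rates[k])
  })
  h <- ad_pointwise(ad_concat(branches), pp$fuse$w, pp$fuse$b)
  ad_relu(ad_norm(h, pp$n$g, pp$n$b, eps))
}

# shared encoder: dual input -> feature pyramid F1..F4 (strides 2..16)
encode_fw <- function(x, enc, cfg) {
  eps <- cfg$norm_eps
  f1 <- down_block_fw(x, enc$b1, eps)
  f2 <- down_block_fw(f1, enc$b2, eps)
  f2 <- res_block_fw(res_block_fw(f2, enc$b2$res1, eps), enc$b2$res2, eps)
  f3 <- down_block_fw(f2, enc$b3, eps)
  f3 <- res_block_fw(res_block_fw(f3, enc$b3$res1, eps), enc$b3$res2, eps)
  f4 <- down_block_fw(f3, enc$b4, eps)
  f4 <- aspp_fw(f4, enc$b4$aspp, cfg$aspp_rates, eps)
  list(f1, f2, f3, f4)
}

affine_head_fw <- function(F4, M4, aff, eps) {
  h <- res_block_fw(ad_concat(list(F4, M4)), aff$res, eps)
  ad_gap(ad_pointwise(h, aff$out$w, aff$out$b))  # 12 values
}

deformable_head_fw <- function(Fi, Mi, Fn, Mn, G_next, phi_next_dense,
                               head, eps) {
  sp <- dim(Fi$value)[1:3]
  G_up <- ad_resize(G_next, sp)
  Mi_w <- ad_grid_sample(Mi, G_up)
  Mn_w <- ad_grid_sample(Mn, G_next)
  inp <- ad_concat(list(Fi, Mi_w, ad_resize(Fn, sp), ad_resize(Mn_w, sp),
                        ad_resize(phi_next_dense, sp)))
  h <- res_block_fw(res_block_fw(inp, head$res1, eps), head$res2, eps)
  phi <- ad_pointwise(h, head$out$w, head$out$b)
  list(phi = phi, grid = ad_add(G_up, phi))
}

#' One forward pass of the registration network
#'
#' Computes Sobel edge maps, encodes both dual inputs with the shared
#' encoder, regresses the affine grid at the coarsest level and refines it
#' through the three deformable blocks; the moving volume is finally
#' warped by the level-1 grid upsampled to full resolution.
#'
#' This builds the autodiff tape; pass the returned nodes to
#' [total_loss()] / `ad_backward()` for training, or read plain arrays
#' from the `$...` values for inference (see [register_pair()]).
#'
#' @param params an [epreg_params()] object (or the same structure with
#'   `ad_param` leaves from an ongoing training step).
#' @param fixed,moving preprocessed 3D arrays in \[0, 1\] with identical,
#'   16-divisible shapes.
#' @param wrapped internal: pass pre-wrapped parameters.
#' @param cache internal: environment reusing per-pair constants (edge
#'   maps / dual inputs) across the iterations of an optimization run.
#' @return List with `phis` (residual fields, level 4 = dense affine
#'   residual), `grids` (G_4..G_1, named by level), `full_grid` (level-1
#'   grid upsampled to full resolution), `warped` (moving volume warped to
#'   full resolution) and `affine12` (the 12 regressed values); all as
#'   autodiff nodes.
#' @export
epreg_forward <- function(params, fixed, moving, wrapped = NULL,
                          cache = NULL) {
  cfg <- params$config
  fixed <- vol_data(fixed)
  moving <- vol_data(moving)
  if (!identical(dim(fixed), dim(moving))) {
    stop("fixed and moving shapes differ: ",
         paste(dim(fixed), collapse = "x"), " vs ",
         paste(dim(moving), collapse = "x"))
  }
  sp <- dim(fixed)
  if (any(sp %% 16L != 0L)) {
    stop("input shape must be divisible by 16; got ",
         paste(sp, collapse = "x"))
  }
  p <- if (is.null(wrapped)) {
    col <- new.env()
    col$leaves <- list()
    wrap_params(params, col)
  } else wrapped

  cc <- if (is.null(cache)) new.env(parent = emptyenv()) else cache
  if (is.null(cc$dual_f)) {
    mk <- function(x) {
      if (cfg$use_edges) make_dual_input(x, sobel_edge_map(x))
      else array(x, c(sp, 1L))
    }
    cc$dual_f <- mk(fixed)
    cc$dual_m <- mk(moving)
  }
  Ff <- encode_fw(ad_const(cc$dual_f), p$enc, cfg)
  Fm <- encode_fw(ad_const(cc$dual_m), p$enc, cfg)

  eps <- cfg$norm_eps
  t12 <- affine_head_fw(Ff[[4]], Fm[[4]], p$aff, eps)
  sp4 <- dim(Ff[[4]]$value)[1:3]
  G4 <- ad_affine_grid_op(t12, sp4)
  phi4 <- ad_sub(G4, ad_const(identity_grid(sp4)))

  heads <- list(p$def3, p$def2, p$def1)
  grids <- list(`4` = G4)
  phis <- list(`4` = phi4)
  G <- G4
  phi_dense <- phi4
  for (i in 3:1) {
    r <- deformable_head_fw(Ff[[i]], Fm[[i]], Ff[[i + 1]], Fm[[i + 1]],
                            G, phi_dense, heads[[4L - i]], eps)
    G <- r$grid
    phi_dense <- r$phi
    grids[[as.character(i)]] <- G
    phis[[as.character(i)]] <- r$phi
  }
  full_grid <- ad_resize(G, sp)
  warped <- ad_grid_sample(ad_const(array(moving, c(sp, 1L))), full_grid)

  list(phis = phis, grids = grids, full_grid = full_grid,
       warped = warped, affine12 = t12,
       pyramids = list(fixed = Ff, moving = Fm))
}
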