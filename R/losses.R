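# The unsupervised objective: patch-based local normalized
# cross-correlation summed over four pyramid scales, plus a diffusion
# regularizer on the aggregated full-resolution displacement field.
#
# Window sums are computed by separable box filtering with replicate
# padding (voxels whose window exits the volume reuse edge values). The
# local-NCC denominator uses the standard squared-sum form; a small
# epsilon keeps locally constant patches (0/0) finite.

lncc_parts_const <- function(x, v) {
  n <- v^3
  s <- boxsum3(x, v)
  ss <- boxsum3(x * x, v)
  list(s = s, var = pmax(ss - s * s / n, 0))
}

# autodiff local-NCC of a constant fixed volume against a warped node;
# `fx` carries the precomputed fixed-side window statistics
lncc_node <- function(fixed, warped, v, eps, fx = lncc_parts_const(fixed, v)) {
  n <- v^3
  Sw <- ad_boxsum(warped, v)
  Sww <- ad_boxsum(ad_sq(warped), v)
  Sfw <- ad_boxsum(ad_mul_const(warped, fixed), v)
  cross <- ad_sub(Sfw, ad_mul_const(Sw, fx$s / n))
  varw <- ad_sub(Sww, ad_scale(ad_sq(Sw), 1 / n))
  cc <- ad_div(ad_sq(cross), ad_add_const(ad_mul_const(varw, fx$var), eps))
  ad_neg(ad_sum(cc))
}

#' Local normalized cross-correlation loss
#'
#' For every voxel p the correlation of the two images over the v^3
#' window centred at p is squared and normalized by the windowed
#' variances; the loss is the negative sum over all voxels, so a perfect
#' match of a non-constant pair approaches `-prod(dim)`. Lower is better.
#' Symmetric in its arguments and invariant to positive affine intensity
#' rescaling of either image.
#'
#' @param a,b same-shape 3D arrays (or `epreg_volume`s).
#' @param window odd window edge length in voxels (default 9).
#' @param eps denominator stabilizer for locally constant patches.
#' @return Scalar in \[-prod(dim), 0\].
#' @export
lncc_loss <- function(a, b, window = 9L, eps = 1e-5) {
  a <- vol_data(a)
  b <- vol_data(b)
  if (!identical(dim(a), dim(b))) {
    stop("lncc_loss inputs differ in shape: ",
         paste(dim(a), collapse = "x"), " vs ", paste(dim(b), collapse = "x"))
  }
  stopifnot(window %% 2L == 1L, window >= 3L)
  n <- window^3
  sa <- boxsum3(a, window)
  sb <- boxsum3(b, window)
  sab <- boxsum3(a * b, window)
  saa <- boxsum3(a * a, window)
  sbb <- boxsum3(b * b, window)
  cross <- sab - sa * sb / n
  vara <- saa - sa * sa / n
  varb <- sbb - sb * sb / n
  -sum(cross * cross / (vara * varb + eps))
}

#' Diffusion regularizer of a displacement field
#'
#' Sum over all voxels and components of squared forward finite
#' differences; boundary sites without a forward neighbour are excluded.
#' The field is taken in its stored normalized-coordinate units.
#'
#' @param phi (D, H, W, 3) displacement field (typically the
#'   full-resolution aggregate, see [aggregate_field()]).
#' @return Non-negative scalar.
#' @export
smoothness_loss <- function(phi) {
  stopifnot(is.array(phi), length(dim(phi)) == 4L)
  ad_smoothness_op(ad_const(phi))$value
}

# autodiff total loss; grids is the list returned by epreg_forward.
# An optional cache environment holds the per-pair constants (image
# pyramids, fixed-side window statistics, identity grid) across the
# iterations of an optimization run.
total_loss_node <- function(fixed, moving, grids, full_grid, cfg,
                            cache = NULL) {
  sp <- dim(fixed)
  cc <- if (is.null(cache)) new.env(parent = emptyenv()) else cache
  if (is.null(cc$levels)) {
    cc$levels <- lapply(1:4, function(i) {
      spi <- sp %/% (2L^i)
      f_i <- array(resize_trilinear(fixed, spi), c(spi, 1L))
      list(f = f_i,
           fx = lncc_parts_const(f_i, cfg$window),
           m = ad_const(array(resize_trilinear(moving, spi), c(spi, 1L))))
    })
    cc$id_full <- ad_const(identity_grid(sp))
  }
  sim <- numeric(4L)
  total <- NULL
  for (i in 1:4) {
    lv <- cc$levels[[i]]
    w_i <- ad_grid_sample(lv$m, grids[[as.character(i)]])
    term <- lncc_node(lv$f, w_i, cfg$window, 1e-5, fx = lv$fx)
    sim[i] <- term$value
    total <- if (is.null(total)) term else ad_add(total, term)
  }
  phi_agg <- ad_sub(full_grid, cc$id_full)
  sm <- ad_smoothness_op(phi_agg)
  total <- ad_add(total, ad_scale(sm, cfg$lambda))
  list(node = total, breakdown = list(sim = sim, smooth = sm$value,
                                      lambda = cfg$lambda,
                                      total = total$value))
}

#' Multi-scale registration loss
#'
#' `L = sum_{i=1..4} LNCC(down_{2^i}(I_f), down_{2^i}(I_m) o G_i)
#'  + lambda * smoothness(phi)`, where phi is the full-resolution
#' aggregate displacement (the full grid minus the identity).
#' Downsampling is trilinear.
#'
#' @param fixed,moving preprocessed 3D arrays.
#' @param grids list of deformation grids named `"4".."1"` (numeric
#'   arrays), e.g. extracted from a forward pass.
#' @param full_grid full-resolution grid (level-1 grid upsampled 2x).
#' @param cfg an [epreg_config()] supplying `lambda` and `window`.
#' @return List with `total` and a per-term `breakdown` (four similarity
#'   terms and the weighted smoothness term sum exactly to the total).
#' @export
total_loss <- function(fixed, moving, grids, full_grid,
                       cfg = epreg_config()) {
  fixed <- vol_data(fixed)
  moving <- vol_data(moving)
  gnodes <- lapply(grids, function(g) {
    if (inherits(g, "ad_node")) g else ad_const(g)
  })
  fg <- if (inherits(full_grid, "ad_node")) full_grid else ad_const(full_grid)
  r <- total_loss_node(fixed, moving, gnodes, fg, cfg)
  list(total = r$node$value, breakdown = r$breakdown)
}

# finite-difference vs autodiff gradient check utility (used in tests)
loss_from_fields <- function(fixed, moving, phi_levels, cfg) {
  sp <- dim(fixed)
  nodes <- lapply(phi_levels, ad_param)
  G <- ad_add(nodes[[4]], ad_const(identity_grid(sp %/% 16L)))
  grids <- list(`4` = G)
  for (i in 3:1) {
    G <- ad_add(ad_resize(G, sp %/% (2L^i)), nodes[[i]])
    grids[[as.character(i)]] <- G
  }
  full_grid <- ad_resize(G, sp)
  r <- total_loss_node(fixed, moving, grids, full_grid, cfg)
  list(loss = r$node, phi_nodes = nodes, breakdown = r$breakdown)
}
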