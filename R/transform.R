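# Deformation grids, displacement fields and warping.
#
# Coordinate convention: every grid/field value lives in the normalized
# [-1, 1] span of its axis with align-corners semantics (index j of an
# n-voxel axis sits at -1 + 2*(j-1)/(n-1)). Under this convention a 2x
# trilinear upsampling of a grid or field needs no magnitude rescaling,
# which is what makes the coarse-to-fine additive composition of the
# pyramid well defined at every level. Grids hold absolute sampling
# coordinates; fields hold displacements (grid minus identity).

normalized_axis <- function(n) {
  if (n == 1L) 0 else seq(-1, 1, length.out = n)
}

#' Identity deformation grid
#'
#' @param shape integer (D, H, W).
#' @return (D, H, W, 3) array whose value at voxel p is p's own normalized
#'   coordinate; warping with it is the identity.
#' @export
identity_grid <- function(shape) {
  shape <- as.integer(rep(shape, length.out = 3L))
  g <- array(0, c(shape, 3L))
  g[, , , 1] <- normalized_axis(shape[1])
  g[, , , 2] <- rep(normalized_axis(shape[2]), each = shape[1])
  g[, , , 3] <- rep(normalized_axis(shape[3]), each = shape[1] * shape[2])
  g
}

# Nvox x 4 homogeneous normalized coordinates, voxel order matching the
# column-major array layout (axis 1 fastest)
homogeneous_coords <- function(shape) {
  cbind(matrix(identity_grid(shape), ncol = 3L), 1)
}

#' Dense grid of a 12-parameter affine transform
#'
#' @param mat 3x4 matrix `[A | t]` acting on homogeneous normalized
#'   coordinates (rotation/scale/shear plus translation; 12 degrees of
#'   freedom).
#' @param shape integer (D, H, W).
#' @return (D, H, W, 3) deformation grid.
#' @export
affine_grid <- function(mat, shape) {
  stopifnot(is.matrix(mat), all(dim(mat) == c(3L, 4L)), all(is.finite(mat)))
  shape <- as.integer(rep(shape, length.out = 3L))
  G <- homogeneous_coords(shape) %*% t(mat)
  array(G, c(shape, 3L))
}

#' Warp a volume or feature grid with a deformation grid
#'
#' Trilinear (spatial-transformer style) resampling: `out(p) = x(g(p))`,
#' with out-of-domain samples clamped to the border. The output spatial
#' shape is the grid's shape.
#'
#' @param x 3D array / `epreg_volume`, or (D, H, W, C) feature array.
#' @param grid (Do, Ho, Wo, 3) deformation grid in normalized coordinates.
#' @return Warped array with spatial shape (Do, Ho, Wo).
#' @export
warp_volume <- function(x, grid) {
  x <- vol_data_any(x)
  stopifnot(length(dim(grid)) == 4L)
  if (dim(grid)[4L] != 3L) stop("grid must have 3 vector components")
  was3d <- length(dim(x)) == 3L
  if (was3d) dim(x) <- c(dim(x), 1L)
  out <- cpp_grid_sample_fw(x, grid)
  if (was3d) dim(out) <- dim(out)[1:3]
  out
}

# like vol_data but passes 4D feature arrays through
vol_data_any <- function(x) {
  if (inherits(x, "epreg_volume")) return(x$data)
  stopifnot(is.array(x), length(dim(x)) %in% c(3L, 4L))
  x
}

#' Warp an integer label map with nearest-neighbour sampling
#'
#' @param labels 3D integer array.
#' @param grid (Do, Ho, Wo, 3) deformation grid.
#' @return Integer array of the grid's spatial shape.
#' @export
warp_labels_nn <- function(labels, grid) {
  d <- dim(labels)
  gd <- dim(grid)[1:3]
  n <- prod(gd)
  idx <- integer(0)
  co <- vector("list", 3L)
  for (k in 1:3) {
    t <- grid[, , , k]
    pos <- (t + 1) / 2 * (d[k] - 1)
    co[[k]] <- pmin(pmax(as.integer(round(pos)), 0L), d[k] - 1L)
  }
  lin <- 1L + co[[1]] + d[1] * (co[[2]] + d[2] * co[[3]])
  array(labels[lin], gd)
}

#' Trilinear align-corners resize
#'
#' Shared resampling primitive: used for input preprocessing, for the 2x
#' grid/field upsampling between pyramid levels and for the multi-scale
#' image downsampling inside the loss.
#'
#' @param x 3D or (D, H, W, C) array.
#' @param out_shape target spatial shape (D, H, W).
#' @return Resized array (same number of channels).
#' @export
resize_trilinear <- function(x, out_shape) {
  x <- vol_data_any(x)
  out_shape <- as.integer(rep(out_shape, length.out = 3L))
  was3d <- length(dim(x)) == 3L
  if (was3d) dim(x) <- c(dim(x), 1L)
  out <- cpp_resize3(x, out_shape)
  if (was3d) dim(out) <- dim(out)[1:3]
  out
}

#' Upsample a grid or displacement field to a finer pyramid level
#'
#' Trilinear upsampling of each component. In normalized align-corners
#' coordinates the values need no rescaling: an identity grid upsamples to
#' the identity grid of the finer level exactly.
#'
#' @param g (D, H, W, 3) grid or field.
#' @param factor integer upsampling factor (2 between adjacent levels).
#' @export
upsample_grid <- function(g, factor = 2L) {
  stopifnot(length(dim(g)) == 4L, dim(g)[4L] == 3L)
  resize_trilinear(g, dim(g)[1:3] * as.integer(factor))
}

#' Compose a coarse grid with a finer-level residual displacement
#'
#' `G_i = upsample2(G_{i+1}) + phi_i`: the additive coarse-to-fine
#' combination used throughout the pyramid. `method = "resample"`
#' offers functional composition instead (the upsampled coarse grid
#' resampled at the residual-displaced positions,
#' `G_i(p) = up(G_{i+1})(p + phi_i(p))`), for experimentation; the
#' network itself always composes additively.
#'
#' @param g_coarse grid at level i+1.
#' @param phi residual displacement field at level i (twice the spatial
#'   extent of `g_coarse`).
#' @param method `"additive"` (default) or `"resample"`.
#' @export
compose_grid <- function(g_coarse, phi,
                         method = c("additive", "resample")) {
  method <- match.arg(method)
  up <- upsample_grid(g_coarse, 2L)
  if (!identical(dim(up), dim(phi))) {
    stop("upsampled grid and residual field shapes differ: ",
         paste(dim(up), collapse = "x"), " vs ",
         paste(dim(phi), collapse = "x"))
  }
  if (method == "additive") {
    up + phi
  } else {
    warp_volume(up, identity_grid(dim(phi)[1:3]) + phi)
  }
}

#' Aggregate multi-scale residual fields to full resolution
#'
#' `phi = sum_i upsample_{2^i}(phi_i)`. The level-4 entry is the affine
#' level's dense residual (its grid minus the identity grid).
#'
#' @param phis list of residual fields, element i at 1/2^i resolution
#'   (i = 1..4).
#' @param full_shape full-resolution spatial shape (D, H, W).
#' @return (D, H, W, 3) displacement field in normalized coordinates.
#' @export
aggregate_field <- function(phis, full_shape) {
  stopifnot(length(phis) == 4L)
  full_shape <- as.integer(rep(full_shape, length.out = 3L))
  out <- array(0, c(full_shape, 3L))
  for (i in seq_along(phis)) {
    out <- out + resize_trilinear(phis[[i]], full_shape)
  }
  out
}

#' Convert a normalized-coordinate field to voxel units
#'
#' Component k is scaled by (n_k - 1)/2 of its own grid shape.
#'
#' @param phi (D, H, W, 3) field in normalized coordinates.
#' @return Field in voxel units.
#' @export
field_to_voxel <- function(phi) {
  d <- dim(phi)[1:3]
  for (k in 1:3) phi[, , , k] <- phi[, , , k] * (d[k] - 1) / 2
  phi
}

#' Convert a voxel-unit field to normalized coordinates
#'
#' @param phi (D, H, W, 3) field in voxel units.
#' @export
field_to_normalized <- function(phi) {
  d <- dim(phi)[1:3]
  for (k in 1:3) phi[, , , k] <- phi[, , , k] * 2 / (d[k] - 1)
  phi
}
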