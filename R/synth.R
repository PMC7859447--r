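# Synthetic fixtures: labelled smooth phantoms plus ground-truth affine
# and smooth non-rigid deformations, so every pipeline stage (training,
# registration, evaluation) runs with no external data. Phantoms stand in
# for skull-stripped T1 MRI: a smooth textured background with a handful
# of blob-shaped ROIs of distinct intensity. All generators are pure
# functions of their seed.

# separable Gaussian smoothing via per-axis banded weight matrices with
# renormalized (replicate-like) boundaries
smooth_axis <- function(x, axis, sigma) {
  n <- dim(x)[axis]
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  w <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  M <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- pmax(1L, pmin(n, i + seq(-r, r)))
    for (k in seq_along(j)) M[i, j[k]] <- M[i, j[k]] + w[k]
  }
  M <- M / rowSums(M)
  d <- dim(x)
  if (axis == 1L) {
    array(M %*% matrix(x, nrow = n), d)
  } else {
    perm <- seq_along(d)
    perm[c(1L, axis)] <- perm[c(axis, 1L)]
    y <- aperm(x, perm)
    dy <- dim(y)
    y <- array(M %*% matrix(y, nrow = n), dy)
    aperm(y, perm)
  }
}

smooth_gauss3 <- function(x, sigma) {
  if (sigma <= 0) return(x)
  for (ax in 1:3) x <- smooth_axis(x, ax, sigma)
  x
}

#' Generate a labelled 3D phantom
#'
#' A smooth random background texture plus `n_rois` blob-shaped regions
#' (thresholded smoothed Gaussian fields around random centres) with
#' distinct intensity levels and matching integer labels. Intensities lie
#' in \[0, 1\]; the result is deterministic given `seed`.
#'
#' @param shape integer (D, H, W) (scalars are recycled).
#' @param n_rois number of labelled regions (>= 1).
#' @param sigma_tex texture smoothness in voxels.
#' @param seed integer seed.
#' @return List with `volume` (3D array in \[0, 1\]) and `labels`
#'   (3D integer array, 0 = background, labels `1..n_rois` all present).
#' @export
make_phantom <- function(shape = 48L, n_rois = 4L, sigma_tex = 2,
                         seed = 1L) {
  shape <- as.integer(rep(shape, length.out = 3L))
  if (any(shape < 8L)) stop("phantom shape too small: ",
                            paste(shape, collapse = "x"))
  stopifnot(n_rois >= 1L)
  set.seed(seed)
  bg <- smooth_gauss3(array(runif(prod(shape)), shape), sigma_tex)
  bg <- (bg - min(bg)) / max(1e-12, diff(range(bg)))
  vol <- 0.15 + 0.25 * bg
  labels <- array(0L, shape)
  strength <- array(-Inf, shape)
  ax <- lapply(1:3, function(k) seq_len(shape[k]))
  for (roi in seq_len(n_rois)) {
    centre <- sapply(shape, function(n) runif(1, 0.3 * n, 0.7 * n))
    radius <- runif(1, 0.10, 0.16) * min(shape)
    d2 <- outer(outer((ax[[1]] - centre[1])^2, (ax[[2]] - centre[2])^2, "+"),
                (ax[[3]] - centre[3])^2, "+")
    bump <- exp(-d2 / (2 * radius^2)) +
      0.15 * smooth_gauss3(array(rnorm(prod(shape)), shape), sigma_tex + 2)
    mask <- bump > 0.55
    if (!any(mask)) {
      ci <- pmin(pmax(round(centre), 1), shape)
      mask[ci[1], ci[2], ci[3]] <- TRUE
    }
    take <- mask & (bump > strength)
    labels[take] <- roi
    strength[take] <- bump[take]
    level <- 0.5 + 0.45 * roi / n_rois
    vol[take] <- level + 0.2 * (bg[take] - mean(bg))
  }
  vol <- pmin(pmax(vol, 0), 1)
  list(volume = vol, labels = labels)
}

#' Generate a random ground-truth deformation
#'
#' An affine transform sampled within the stated magnitudes plus a
#' non-rigid part built from Gaussian-smoothed white noise, rescaled so
#' its maximum displacement norm equals `amplitude` voxels, then
#' converted to normalized coordinates. Zero magnitudes give the exact
#' identity.
#'
#' @param shape volume shape (D, H, W).
#' @param rot_deg maximum rotation per axis in degrees.
#' @param scale_dev maximum |scale - 1| per axis.
#' @param trans_frac maximum translation as a fraction of the extent.
#' @param amplitude maximum non-rigid displacement norm in voxels.
#' @param sigma_f smoothness of the non-rigid field in voxels (>= 1).
#' @param seed integer seed.
#' @return List with `affine` (3x4 matrix on normalized coordinates),
#'   `field` (full-resolution non-rigid (D,H,W,3) field, normalized
#'   coordinates) and `grid` (the composed ground-truth deformation grid).
#' @export
make_deformation <- function(shape = 48L, rot_deg = 3, scale_dev = 0.03,
                             trans_frac = 0.02, amplitude = 4,
                             sigma_f = 6, seed = 1L) {
  shape <- as.integer(rep(shape, length.out = 3L))
  stopifnot(sigma_f >= 1)
  set.seed(seed)
  ang <- runif(3, -1, 1) * rot_deg * pi / 180
  rot1 <- matrix(c(1, 0, 0, 0, cos(ang[1]), sin(ang[1]),
                   0, -sin(ang[1]), cos(ang[1])), 3, 3)
  rot2 <- matrix(c(cos(ang[2]), 0, -sin(ang[2]), 0, 1, 0,
                   sin(ang[2]), 0, cos(ang[2])), 3, 3)
  rot3 <- matrix(c(cos(ang[3]), sin(ang[3]), 0,
                   -sin(ang[3]), cos(ang[3]), 0, 0, 0, 1), 3, 3)
  scl <- diag(1 + runif(3, -1, 1) * scale_dev)
  tr <- runif(3, -1, 1) * trans_frac * 2  # extent is 2 normalized units
  affine <- unname(cbind(rot3 %*% rot2 %*% rot1 %*% scl, tr))

  field <- array(0, c(shape, 3L))
  if (amplitude > 0) {
    noise <- array(rnorm(prod(shape) * 3), c(shape, 3L))
    for (k in 1:3) noise[, , , k] <- smooth_gauss3(noise[, , , k], sigma_f)
    nrm <- sqrt(noise[, , , 1]^2 + noise[, , , 2]^2 + noise[, , , 3]^2)
    noise <- noise * (amplitude / max(nrm))  # voxel units, max norm = a
    field <- field_to_normalized(noise)
  }
  grid <- affine_grid(affine, shape) + field
  list(affine = affine, field = field, grid = grid)
}

#' Generate a registration test pair with known correspondence
#'
#' The fixed image is a phantom; the moving image is the fixed image
#' warped by a known ground-truth grid (labels warped nearest-neighbour),
#' so recovery of the deformation can be scored against the truth.
#'
#' @param shape volume shape.
#' @param n_rois number of labelled regions.
#' @param sigma_tex phantom texture smoothness (voxels).
#' @param seed integer seed (drives both phantom and deformation).
#' @param ... deformation magnitudes passed to [make_deformation()].
#' @return List with `fixed`, `moving` (3D arrays), `labels_f`,
#'   `labels_m` (integer arrays), `gt_grid` (the ground-truth grid with
#'   `moving = warp(fixed, gt_grid)`) and `gt_field` (gt displacement,
#'   normalized coordinates).
#' @export
make_pair <- function(shape = 48L, n_rois = 4L, sigma_tex = 2,
                      seed = 1L, ...) {
  ph <- make_phantom(shape, n_rois, sigma_tex, seed = seed)
  def <- make_deformation(shape = dim(ph$volume), seed = seed + 1000L, ...)
  moving <- warp_volume(ph$volume, def$grid)
  labels_m <- warp_labels_nn(ph$labels, def$grid)
  list(fixed = ph$volume, moving = moving,
       labels_f = ph$labels, labels_m = labels_m,
       gt_grid = def$grid,
       gt_field = def$grid - identity_grid(dim(ph$volume)),
       gt_affine = def$affine)
}
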