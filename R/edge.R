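# 3D Sobel edge enhancement: the edge map that forms the second input
# channel of each encoder stream.

#' The three 3x3x3 Sobel kernels
#'
#' Each kernel differentiates along one array axis and smooths (weights
#' 1-2-1, centre 4) across the two others: the slice at offset -1 is
#' `[[1,2,1],[2,4,2],[1,2,1]]`, the centre slice is zero and the slice at
#' offset +1 is its negation. `Sx`/`Sy`/`Sz` differentiate along array
#' axes 1/2/3 respectively. All weights sum to zero.
#'
#' @return Named list of three 3x3x3 integer arrays `Sx`, `Sy`, `Sz`.
#' @export
sobel_kernels <- function() {
  smooth <- c(1, 2, 1)
  deriv <- c(1, 0, -1)  # + at offset -1, - at offset +1
  k <- function(axis) {
    w <- switch(axis,
                outer(deriv, outer(smooth, smooth)),
                outer(smooth, outer(deriv, smooth)),
                outer(smooth, outer(smooth, deriv)))
    array(as.integer(w), c(3L, 3L, 3L))
  }
  list(Sx = k(1L), Sy = k(2L), Sz = k(3L))
}

# cross-correlate a replicate-padded volume with one 3x3x3 kernel;
# correlation and convolution give identical edge magnitudes here because
# Eq-style gradient kernels only flip sign under reflection
correlate3 <- function(x, kern) {
  d <- dim(x)
  # replicate padding by one voxel via clamped index vectors
  id <- c(1L, seq_len(d[1]), d[1])
  ih <- c(1L, seq_len(d[2]), d[2])
  iw <- c(1L, seq_len(d[3]), d[3])
  xp <- x[id, ih, iw]
  out <- array(0, d)
  for (k in 1:3) for (j in 1:3) for (i in 1:3) {
    w <- kern[i, j, k]
    if (w == 0) next
    out <- out + w * xp[i:(i + d[1] - 1L), j:(j + d[2] - 1L),
                        k:(k + d[3] - 1L)]
  }
  out
}

#' Sobel edge map of a volume
#'
#' `E = sqrt((Sx*I)^2 + (Sy*I)^2 + (Sz*I)^2)` with same-shape output;
#' borders are handled by replicate padding, so a flat border produces no
#' spurious edge response.
#'
#' @param v an `epreg_volume` or 3D array (each axis >= 3).
#' @return 3D non-negative array, same shape as the input.
#' @export
sobel_edge_map <- function(v) {
  x <- vol_data(v)
  if (any(dim(x) < 3L)) {
    stop("sobel_edge_map needs every axis >= 3; got ",
         paste(dim(x), collapse = "x"))
  }
  ks <- sobel_kernels()
  gx <- correlate3(x, ks$Sx)
  gy <- correlate3(x, ks$Sy)
  gz <- correlate3(x, ks$Sz)
  sqrt(gx * gx + gy * gy + gz * gz)
}

#' Stack intensity and edge channels into the network's dual input
#'
#' Channel 1 is the intensity volume (expected already normalized to
#' \[0, 1\], see [preprocess_volume()]); channel 2 is the edge map rescaled
#' to \[0, 1\] so both channels enter the encoder on comparable scales.
#'
#' @param v intensity volume (`epreg_volume` or 3D array).
#' @param e edge map of the same shape, e.g. from [sobel_edge_map()].
#' @return (D, H, W, 2) array.
#' @export
make_dual_input <- function(v, e) {
  x <- vol_data(v)
  e <- vol_data(e)
  if (!identical(dim(x), dim(e))) {
    stop("volume and edge map shapes differ: ",
         paste(dim(x), collapse = "x"), " vs ", paste(dim(e), collapse = "x"))
  }
  emax <- max(e)
  if (emax > 0) e <- e / emax
  array(c(x, e), c(dim(x), 2L))
}
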