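# NIfTI input/output and input-shape preprocessing.
#
# Volumes are carried as lightweight S3 objects wrapping a dense 3D double
# array plus voxel spacing and the NIfTI header (kept only so that world
# metadata survives a read/write round trip; registration math never uses
# it). Most package functions also accept a bare 3D array.

#' Construct a volume object
#'
#' @param data 3D numeric array of intensities, axis order (D, H, W).
#' @param spacing voxel spacing in mm per axis (length 3).
#' @param header optional NIfTI header carried through unchanged.
#' @return An object of class `epreg_volume`.
#' @export
new_volume <- function(data, spacing = c(1, 1, 1), header = NULL) {
  stopifnot(is.array(data), length(dim(data)) == 3L)
  if (!all(is.finite(data))) stop("volume contains non-finite intensities")
  structure(list(data = array(as.double(data), dim(data)),
                 spacing = as.double(spacing), header = header),
            class = "epreg_volume")
}

#' @export
print.epreg_volume <- function(x, ...) {
  cat("<epreg_volume ", paste(dim(x$data), collapse = "x"),
      ", spacing ", paste(signif(x$spacing, 3), collapse = "x"),
      " mm, range [", signif(min(x$data), 4), ", ",
      signif(max(x$data), 4), "]>\n", sep = "")
  invisible(x)
}

# accept either an epreg_volume or a bare array
vol_data <- function(v) {
  if (inherits(v, "epreg_volume")) v$data
  else if (is.array(v)) v
  else stop("expected an epreg_volume or a numeric array")
}

#' Read a 3D volume from a NIfTI file
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return An `epreg_volume`; intensities are cast to double.
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("unreadable NIfTI file ", path,
                                           ": ", conditionMessage(e)))
  d <- dim(img)
  if (length(d) == 4L && d[4L] == 1L) {
    img <- img[, , , 1L]
    d <- dim(img)
  }
  if (length(d) != 3L) {
    stop("expected 3D volume in ", path, " but found ",
         length(d), "D image")
  }
  new_volume(array(as.double(img), d),
             spacing = RNifti::pixdim(img)[1:3],
             header = RNifti::niftiHeader(img))
}

#' Write a volume to a NIfTI file
#'
#' @param v an `epreg_volume` or 3D array.
#' @param path output path (`.nii` or `.nii.gz`).
#' @export
write_volume <- function(v, path) {
  hdr <- if (inherits(v, "epreg_volume")) v$header else NULL
  x <- vol_data(v)
  img <- if (is.null(hdr)) RNifti::asNifti(x)
         else RNifti::asNifti(x, reference = hdr)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read an integer ROI label map
#'
#' @param path path to a NIfTI file with non-negative integer labels
#'   (0 = background).
#' @return A 3D integer array with attribute `label_ids` (nonzero labels
#'   present).
#' @export
read_label_map <- function(path) {
  v <- read_volume(path)
  x <- v$data
  if (any(x < 0) || max(abs(x - round(x))) > 1e-6) {
    stop("label map ", path, " is not a non-negative integer volume")
  }
  lab <- array(as.integer(round(x)), dim(x))
  attr(lab, "label_ids") <- sort(unique(lab[lab > 0L]))
  lab
}

#' Resample a volume to the network input shape and normalize intensities
#'
#' Trilinear (align-corners) resampling to `target_shape`, followed by
#' per-volume min-max normalization to \[0, 1\]. A constant volume maps to
#' all zeros. Each target axis must be divisible by 16 so that four
#' stride-2 halvings stay aligned.
#'
#' @param v an `epreg_volume` or 3D array.
#' @param target_shape integer (D, H, W), each divisible by 16.
#' @return A 3D array in \[0, 1\] with exactly `target_shape`.
#' @export
preprocess_volume <- function(v, target_shape) {
  target_shape <- as.integer(rep(target_shape, length.out = 3L))
  if (any(target_shape < 16L) || any(target_shape %% 16L != 0L)) {
    stop("target_shape axes must be >= 16 and divisible by 16 ",
         "(four stride-2 pyramid levels); got ",
         paste(target_shape, collapse = "x"))
  }
  x <- vol_data(v)
  if (!all(is.finite(x))) stop("volume contains non-finite intensities")
  y <- resize_trilinear(x, target_shape)
  rng <- range(y)
  if (rng[2] > rng[1]) (y - rng[1]) / (rng[2] - rng[1]) else array(0, dim(y))
}

#' Write a displacement field as a 4D NIfTI
#'
#' The trailing dimension holds the 3 vector components, stored in the
#' package's normalized \[-1, 1\] align-corners coordinate convention (see
#' [field_to_voxel()] to convert to voxel units).
#'
#' @param phi (D, H, W, 3) array.
#' @param path output path.
#' @export
write_field <- function(phi, path) {
  stopifnot(is.array(phi), length(dim(phi)) == 4L, dim(phi)[4L] == 3L)
  if (!all(is.finite(phi))) stop("refusing to write non-finite field")
  img <- RNifti::asNifti(phi)
  img$intent_code <- 1007L  # NIFTI_INTENT_VECTOR
  img$descrip <- "displacement in normalized [-1,1] align-corners coords"
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a displacement field written by [write_field()]
#'
#' @param path path to a 4D NIfTI with trailing vector dimension 3.
#' @return (D, H, W, 3) array.
#' @export
read_field <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) == 5L && d[4L] == 1L) {  # NIfTI vector-in-5th-dim layout
    img <- img[, , , 1L, ]
    d <- dim(img)
  }
  if (length(d) != 4L || d[4L] != 3L) {
    stop("expected 4D field with trailing vector dimension 3 in ", path)
  }
  array(as.double(img), d)
}
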