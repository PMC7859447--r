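# 3D evaluation metrics: Dice index, Hausdorff distance and average
# symmetric surface distance, computed on the voxel lattice in voxel
# units (volumes are assumed resampled to a common isotropic cube).

binarize_label <- function(x, label) {
  stopifnot(is.array(x), length(dim(x)) == 3L)
  x == label
}

# 6-connectivity boundary: region voxels with at least one face
# neighbour outside the region (voxels beyond the array count as outside)
boundary_voxels <- function(mask) {
  d <- dim(mask)
  pad <- array(FALSE, d + 2L)
  pad[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- mask
  core <- pad[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)]
  inside6 <- pad[1:d[1], 2:(d[2] + 1L), 2:(d[3] + 1L)] &
    pad[3:(d[1] + 2L), 2:(d[2] + 1L), 2:(d[3] + 1L)] &
    pad[2:(d[1] + 1L), 1:d[2], 2:(d[3] + 1L)] &
    pad[2:(d[1] + 1L), 3:(d[2] + 2L), 2:(d[3] + 1L)] &
    pad[2:(d[1] + 1L), 2:(d[2] + 1L), 1:d[3]] &
    pad[2:(d[1] + 1L), 2:(d[2] + 1L), 3:(d[3] + 2L)]
  which(core & !inside6, arr.ind = TRUE)
}

check_same_shape <- function(a, b) {
  if (!identical(dim(a), dim(b))) {
    stop("label maps differ in shape: ", paste(dim(a), collapse = "x"),
         " vs ", paste(dim(b), collapse = "x"))
  }
}

#' Dice similarity coefficient of one label
#'
#' `2 |A n B| / (|A| + |B|)` for the binarized label. When the label is
#' absent from both maps the overlap is vacuously perfect and 1 is
#' returned with a warning (`strict = TRUE` raises an error instead).
#'
#' @param a,b same-shape 3D integer label maps.
#' @param label integer ROI label to compare.
#' @param strict error on label absent from both maps.
#' @return Scalar in \[0, 1\].
#' @export
dsc <- function(a, b, label = 1L, strict = FALSE) {
  check_same_shape(a, b)
  ma <- binarize_label(a, label)
  mb <- binarize_label(b, label)
  na <- sum(ma)
  nb <- sum(mb)
  if (na + nb == 0L) {
    if (strict) stop("label ", label, " absent from both maps")
    warning("label ", label, " absent from both maps; DSC defined as 1")
    return(1)
  }
  2 * sum(ma & mb) / (na + nb)
}

#' Hausdorff distance between two labelled regions
#'
#' The longest over both directions of the shortest Euclidean
#' surface-to-surface distances (100th percentile, not HD95), in voxel
#' units. Equivalent to the Hausdorff distance between the solid regions.
#'
#' @inheritParams dsc
#' @return Non-negative scalar (voxels).
#' @export
hausdorff <- function(a, b, label = 1L) {
  check_same_shape(a, b)
  ma <- binarize_label(a, label)
  mb <- binarize_label(b, label)
  if (!any(ma) || !any(mb)) {
    stop("hausdorff undefined: label ", label, " empty in at least one map")
  }
  ba <- boundary_voxels(ma)
  bb <- boundary_voxels(mb)
  # max-min distances are attained on boundaries, but each direction must
  # ignore points interior to the other region (distance 0 there)
  da <- cpp_nn_min_dist(ba * 1.0, bb * 1.0)
  db <- cpp_nn_min_dist(bb * 1.0, ba * 1.0)
  inb <- mb[ba[, 1] + dim(ma)[1] * (ba[, 2] - 1L) +
              dim(ma)[1] * dim(ma)[2] * (ba[, 3] - 1L)]
  ina <- ma[bb[, 1] + dim(ma)[1] * (bb[, 2] - 1L) +
              dim(ma)[1] * dim(ma)[2] * (bb[, 3] - 1L)]
  da[inb] <- 0
  db[ina] <- 0
  max(max(da), max(db))
}

#' Average symmetric surface distance
#'
#' `(sum_{x in B_a} d(x, B_b) + sum_{y in B_b} d(y, B_a)) /
#'  (|B_a| + |B_b|)` over the 6-connectivity boundary voxel sets, in
#' voxel units.
#'
#' @inheritParams dsc
#' @return Non-negative scalar (voxels).
#' @export
assd <- function(a, b, label = 1L) {
  check_same_shape(a, b)
  ma <- binarize_label(a, label)
  mb <- binarize_label(b, label)
  if (!any(ma) || !any(mb)) {
    stop("assd undefined: label ", label, " empty in at least one map")
  }
  ba <- boundary_voxels(ma)
  bb <- boundary_voxels(mb)
  da <- cpp_nn_min_dist(ba * 1.0, bb * 1.0)
  db <- cpp_nn_min_dist(bb * 1.0, ba * 1.0)
  (sum(da) + sum(db)) / (nrow(ba) + nrow(bb))
}

#' Per-label registration metrics for a pair of label maps
#'
#' Computes DSC, Hausdorff distance and ASSD for every label shared by
#' the two maps, plus mean and SD summary rows. The warped map should
#' come from nearest-neighbour warping ([warp_labels_nn()]).
#'
#' @param fixed_labels,warped_labels same-shape 3D integer label maps.
#' @return `data.frame` with columns `label`, `dsc`, `hd`, `assd`; the
#'   final two rows (`label` = "mean", "sd") summarize the per-label rows.
#' @export
evaluate_pair <- function(fixed_labels, warped_labels) {
  check_same_shape(fixed_labels, warped_labels)
  shared <- intersect(unique(fixed_labels[fixed_labels > 0L]),
                      unique(warped_labels[warped_labels > 0L]))
  if (length(shared) == 0L) stop("label maps share no nonzero labels")
  shared <- sort(shared)
  rows <- lapply(shared, function(l) {
    data.frame(label = as.character(l),
               dsc = dsc(fixed_labels, warped_labels, l),
               hd = hausdorff(fixed_labels, warped_labels, l),
               assd = assd(fixed_labels, warped_labels, l))
  })
  tab <- do.call(rbind, rows)
  num <- tab[, c("dsc", "hd", "assd")]
  summ <- data.frame(label = c("mean", "sd"),
                     dsc = c(mean(num$dsc), sd(num$dsc)),
                     hd = c(mean(num$hd), sd(num$hd)),
                     assd = c(mean(num$assd), sd(num$assd)))
  rbind(tab, summ)
}
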