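cube_map <- function(shape, from, to, label = 1L) {
  x <- array(0L, shape)
  x[from[1]:to[1], from[2]:to[2], from[3]:to[3]] <- label
  x
}

test_that("Dice handles identity, disjoint and half-overlapping regions", {
  sp <- c(20L, 20L, 20L)
  a <- cube_map(sp, c(3, 3, 3), c(12, 12, 12))
  expect_equal(dsc(a, a), 1)

  b <- cube_map(sp, c(14, 14, 14), c(18, 18, 18))
  expect_equal(dsc(a, b), 0)

  # two 10^3 cubes overlapping in a 10x10x5 slab: 2*500/(1000+1000)
  c1 <- cube_map(sp, c(1, 1, 1), c(10, 10, 10))
  c2 <- cube_map(sp, c(1, 1, 6), c(10, 10, 15))
  expect_equal(dsc(c1, c2), 0.5)

  expect_warning(v <- dsc(a * 0L, a * 0L), "absent")
  expect_equal(v, 1)
  expect_error(dsc(a * 0L, a * 0L, strict = TRUE), "absent")
})

test_that("Hausdorff distance equals the shift for shifted cubes and is symmetric", {
  sp <- c(24L, 24L, 24L)
  a <- cube_map(sp, c(3, 3, 3), c(8, 8, 8))
  expect_equal(hausdorff(a, a), 0)

  for (k in c(7L, 10L)) {  # non-overlapping shifts along axis 1
    b <- cube_map(sp, c(3 + k, 3, 3), c(8 + k, 8, 8))
    expect_equal(hausdorff(a, b), k)
    expect_equal(hausdorff(b, a), k)
  }

  # exhaustive pairwise-distance oracle on small random blobs
  set.seed(61)
  m1 <- array(as.integer(rand_vol(c(9, 9, 9), 62) > 0.7), c(9, 9, 9))
  m2 <- array(as.integer(rand_vol(c(9, 9, 9), 63) > 0.7), c(9, 9, 9))
  solid1 <- which(m1 == 1L, arr.ind = TRUE)
  solid2 <- which(m2 == 1L, arr.ind = TRUE)
  dmat <- as.matrix(dist(rbind(solid1, solid2)))
  n1 <- nrow(solid1)
  cross <- dmat[seq_len(n1), n1 + seq_len(nrow(solid2)), drop = FALSE]
  want <- max(max(apply(cross, 1, min)), max(apply(cross, 2, min)))
  expect_equal(hausdorff(m1, m2), want)

  expect_error(hausdorff(a, a * 0L), "empty")
})

test_that("ASSD equals the gap between parallel plates and is symmetric", {
  sp <- c(16L, 16L, 16L)
  for (k in c(4L, 9L)) {
    p1 <- cube_map(sp, c(2, 1, 1), c(2, 16, 16))
    p2 <- cube_map(sp, c(2 + k, 1, 1), c(2 + k, 16, 16))
    expect_equal(assd(p1, p2), k)
    expect_equal(assd(p2, p1), k)
  }
  a <- cube_map(sp, c(3, 3, 3), c(8, 8, 8))
  expect_equal(assd(a, a), 0)
  expect_error(assd(a, a * 0L), "empty")
})

test_that("pair evaluation reports per-label rows plus summary and perfect identity scores", {
  ph <- make_phantom(shape = 24L, n_rois = 3L, seed = 64L)
  tab <- evaluate_pair(ph$labels, ph$labels)
  labs <- sort(unique(ph$labels[ph$labels > 0]))
  expect_equal(nrow(tab), length(labs) + 2L)
  expect_equal(tab$label, c(as.character(labs), "mean", "sd"))
  per <- tab[seq_along(labs), ]
  expect_true(all(per$dsc == 1))
  expect_true(all(per$hd == 0))
  expect_true(all(per$assd == 0))

  # warped under a known 2-voxel shift: hand-computable per-ROI values
  sp <- c(16L, 16L, 16L)
  one <- cube_map(sp, c(4, 4, 4), c(9, 9, 9))
  g <- identity_grid(sp)
  g[, , , 1] <- g[, , , 1] + 2 * 2 / (sp[1] - 1)
  shifted <- warp_labels_nn(one, g)
  tab2 <- evaluate_pair(one, shifted)
  # 6x6x6 cube shifted by 2: overlap 4*6*6
  expect_equal(tab2$dsc[1], 2 * 4 * 36 / (216 + 216))
  expect_equal(tab2$hd[1], 2)

  expect_error(evaluate_pair(one, one * 0L), "no nonzero labels")
})
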