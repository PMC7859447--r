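test_that("identity grid follows the align-corners convention and warps as identity", {
  g <- identity_grid(c(2, 2, 2))
  expect_equal(sort(unique(as.vector(g))), c(-1, 1))
  g8 <- identity_grid(c(8, 8, 8))
  x <- rand_vol(c(8, 8, 8), seed = 31)
  expect_equal(warp_volume(x, g8), x, tolerance = 1e-12)
  expect_equal(g8 - g8, array(0, c(8, 8, 8, 3)))
})

test_that("affine grids reproduce translation, identity and centred scaling", {
  sp <- c(5, 6, 7)
  idm <- cbind(diag(3), c(0, 0, 0))
  expect_equal(affine_grid(idm, sp), identity_grid(sp))

  tr <- cbind(diag(3), c(0.1, -0.2, 0.3))
  g <- affine_grid(tr, sp)
  idg <- identity_grid(sp)
  for (k in 1:3) expect_equal(g[, , , k], idg[, , , k] + tr[k, 4])

  half <- affine_grid(cbind(diag(0.5, 3), c(0, 0, 0)), sp)
  expect_equal(half, idg * 0.5)

  # per-voxel matrix-multiply oracle on a random affine
  set.seed(32)
  M <- cbind(diag(3) + matrix(rnorm(9, sd = 0.05), 3), rnorm(3, sd = 0.1))
  g <- affine_grid(M, c(4, 4, 4))
  for (i in 1:4) for (j in 1:4) for (k in 1:4) {
    idv <- identity_grid(c(4, 4, 4))[i, j, k, ]
    expect_equal(g[i, j, k, ], as.vector(M %*% c(idv, 1)), tolerance = 1e-12)
  }
})

test_that("warping matches the brute-force trilinear oracle and is linear", {
  x <- rand_vol(c(8, 8, 8), seed = 33)
  set.seed(34)
  grid <- identity_grid(c(8, 8, 8)) +
    array(rnorm(8^3 * 3, sd = 0.15), c(8, 8, 8, 3))
  expect_equal(warp_volume(x, grid), oracle_trilinear(x, grid),
               tolerance = 1e-5)

  # a +1 voxel shift along axis 3 applied to the ramp I = z
  r <- ramp_vol(8)
  gs <- identity_grid(c(8, 8, 8))
  gs[, , , 3] <- gs[, , , 3] + 2 / 7
  w <- warp_volume(r, gs)
  expect_equal(w[3:6, 3:6, 3:6], r[3:6, 3:6, 3:6] + 1, tolerance = 1e-9)

  # nodal exactness: sampling a voxel's exact location returns its value
  g1 <- array(identity_grid(c(8, 8, 8))[3, 5, 2, ], c(1, 1, 1, 3))
  expect_equal(as.vector(warp_volume(x, g1)), x[3, 5, 2])

  # linearity in the image argument
  y <- rand_vol(c(8, 8, 8), seed = 35)
  expect_equal(warp_volume(2 * x - 3 * y, grid),
               2 * warp_volume(x, grid) - 3 * warp_volume(y, grid),
               tolerance = 1e-10)

  expect_error(warp_volume(x, grid[, , , 1:2]), "3 vector components")
})

test_that("grid upsampling is exact on identity/linear fields and rescales nothing", {
  expect_equal(upsample_grid(identity_grid(c(4, 4, 4)), 2L),
               identity_grid(c(8, 8, 8)), tolerance = 1e-12)
  z <- array(0, c(4, 4, 4, 3))
  expect_equal(upsample_grid(z, 2L), array(0, c(8, 8, 8, 3)))

  # a field linear in normalized position keeps its slope
  lin <- identity_grid(c(4, 4, 4)) * 0.25
  up <- upsample_grid(lin, 2L)
  expect_equal(up, identity_grid(c(8, 8, 8)) * 0.25, tolerance = 1e-12)
})

test_that("grid composition is additive and telescopes as expected", {
  g4 <- identity_grid(c(4, 4, 4))
  phi <- array(0, c(8, 8, 8, 3))
  expect_equal(compose_grid(g4, phi), identity_grid(c(8, 8, 8)),
               tolerance = 1e-12)

  const <- array(0.07, c(8, 8, 8, 3))
  expect_equal(compose_grid(g4, const),
               identity_grid(c(8, 8, 8)) + 0.07, tolerance = 1e-12)

  # two successive compositions: identity + up(phi_a) + phi_b
  set.seed(36)
  phi_a <- array(rnorm(8^3 * 3, sd = 0.05), c(8, 8, 8, 3))
  phi_b <- array(rnorm(16^3 * 3, sd = 0.05), c(16, 16, 16, 3))
  got <- compose_grid(compose_grid(g4, phi_a), phi_b)
  want <- identity_grid(c(16, 16, 16)) + upsample_grid(phi_a, 2L) + phi_b
  expect_equal(got, want, tolerance = 1e-12)

  expect_error(compose_grid(g4, array(0, c(6, 6, 6, 3))), "differ")

  # resampling composition agrees with addition for zero residuals and
  # for constant shifts of an identity coarse grid (linearity)
  expect_equal(compose_grid(g4, phi * 0, method = "resample"),
               compose_grid(g4, phi * 0), tolerance = 1e-12)
  expect_equal(compose_grid(g4, const, method = "resample")[2:7, 2:7, 2:7, ],
               compose_grid(g4, const)[2:7, 2:7, 2:7, ], tolerance = 1e-9)
})

test_that("field aggregation equals the independent sum of upsampled fields", {
  set.seed(37)
  shapes <- list(c(8, 8, 8), c(4, 4, 4), c(2, 2, 2), c(1, 1, 1))
  phis <- lapply(shapes, function(s) array(rnorm(prod(s) * 3, sd = 0.05),
                                           c(s, 3L)))
  agg <- aggregate_field(phis, c(16, 16, 16))
  want <- array(0, c(16, 16, 16, 3))
  for (p in phis) want <- want + resize_trilinear(p, c(16, 16, 16))
  expect_equal(agg, want, tolerance = 1e-12)

  # all-zero residuals and identity affine aggregate to zero
  zs <- lapply(shapes, function(s) array(0, c(s, 3L)))
  expect_equal(aggregate_field(zs, c(16, 16, 16)),
               array(0, c(16, 16, 16, 3)))
})

test_that("voxel/normalized field unit conversions invert each other", {
  set.seed(38)
  phi <- array(rnorm(5 * 6 * 7 * 3), c(5, 6, 7, 3))
  expect_equal(field_to_normalized(field_to_voxel(phi)), phi,
               tolerance = 1e-12)
  vox <- field_to_voxel(phi)
  expect_equal(vox[, , , 1], phi[, , , 1] * 2)  # (5-1)/2
})
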