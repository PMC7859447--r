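test_that("local NCC matches the direct-summation oracle", {
  a <- rand_vol(c(12, 12, 12), seed = 41)
  b <- rand_vol(c(12, 12, 12), seed = 42, smooth = 1)
  expect_equal(lncc_loss(a, b, window = 3L), oracle_lncc(a, b, 3L),
               tolerance = 1e-4)
})

test_that("local NCC of an identical non-constant pair approaches -|Omega|", {
  a <- rand_vol(c(12, 12, 12), seed = 43)
  n <- 12^3
  expect_lt(abs(lncc_loss(a, a, window = 3L) + n) / n, 0.02)
  expect_lt(abs(lncc_loss(a, a, window = 9L) + n) / n, 0.02)
})

test_that("local NCC is symmetric and intensity-affine invariant", {
  a <- rand_vol(c(10, 10, 10), seed = 44)
  b <- rand_vol(c(10, 10, 10), seed = 45)
  expect_equal(lncc_loss(a, b), lncc_loss(b, a), tolerance = 1e-9)
  expect_equal(lncc_loss(a, 2.3 * b + 0.7, window = 5L),
               lncc_loss(a, b, window = 5L), tolerance = 1e-3)
  expect_error(lncc_loss(a, b[1:5, , ]), "shape")
})

test_that("diffusion regularizer counts squared forward differences exactly", {
  expect_equal(smoothness_loss(array(0.4, c(5, 5, 5, 3))), 0)

  # slope-s single-component linear field: s^2 per interior difference site
  n <- 6L
  s <- 0.3
  phi <- array(0, c(n, n, n, 3))
  for (k in seq_len(n)) phi[, , k, 1] <- s * k
  expect_equal(smoothness_loss(phi), s^2 * n * n * (n - 1))

  set.seed(46)
  psi <- array(rnorm(4^3 * 3), c(4, 4, 4, 3))
  expect_equal(smoothness_loss(2 * psi), 4 * smoothness_loss(psi),
               tolerance = 1e-9)
})

test_that("total loss breakdown sums to the total and lambda scales as stated", {
  pair <- make_pair(shape = 32L, seed = 47, amplitude = 3)
  params <- epreg_params(tiny_config(), seed = 47)
  fw <- epreg_forward(params, pair$fixed, pair$moving)
  grids <- lapply(fw$grids, epreg:::ad_value)
  fg <- fw$full_grid$value

  cfg <- params$config
  tl <- total_loss(pair$fixed, pair$moving, grids, fg, cfg)
  bd <- tl$breakdown
  expect_equal(sum(bd$sim) + bd$lambda * bd$smooth, tl$total,
               tolerance = 1e-9)

  cfg0 <- epreg_config(widths = cfg$widths, lambda = 0)
  tl0 <- total_loss(pair$fixed, pair$moving, grids, fg, cfg0)
  expect_equal(tl0$total, sum(tl0$breakdown$sim), tolerance = 1e-9)

  # identity cascade on an identical pair: similarity near its floor,
  # smoothness exactly zero
  idp <- epreg_params(tiny_config(), seed = 48)
  fwi <- epreg_forward(idp, pair$fixed, pair$fixed)
  tli <- total_loss(pair$fixed, pair$fixed,
                    lapply(fwi$grids, epreg:::ad_value),
                    fwi$full_grid$value, cfg)
  expect_equal(tli$breakdown$smooth, 0, tolerance = 1e-12)
  sims_direct <- sapply(1:4, function(i) {
    fi <- resize_trilinear(pair$fixed, dim(pair$fixed) %/% (2L^i))
    lncc_loss(fi, fi, window = cfg$window)
  })
  expect_equal(tli$breakdown$sim, sims_direct, tolerance = 1e-8)
})

test_that("autodiff gradients of the total loss match finite differences", {
  f <- rand_vol(c(16, 16, 16), seed = 49, smooth = 1)
  m <- rand_vol(c(16, 16, 16), seed = 50, smooth = 1)
  cfg <- epreg_config(window = 3L, lambda = 1000)
  set.seed(51)
  shapes <- list(c(8, 8, 8), c(4, 4, 4), c(2, 2, 2), c(1, 1, 1))
  phis <- lapply(shapes, function(s) array(rnorm(prod(s) * 3, sd = 0.02),
                                           c(s, 3L)))
  lf <- epreg:::loss_from_fields(f, m, phis, cfg)
  epreg:::ad_backward(lf$loss)
  idx <- rbind(c(3, 4, 5, 1), c(1, 8, 2, 3), c(6, 2, 7, 2))
  h <- 1e-5
  for (r in seq_len(nrow(idx))) {
    i <- idx[r, ]
    pp <- phis
    pp[[1]][i[1], i[2], i[3], i[4]] <- pp[[1]][i[1], i[2], i[3], i[4]] + h
    lp <- epreg:::loss_from_fields(f, m, pp, cfg)$loss$value
    pp[[1]][i[1], i[2], i[3], i[4]] <- pp[[1]][i[1], i[2], i[3], i[4]] - 2 * h
    lm <- epreg:::loss_from_fields(f, m, pp, cfg)$loss$value
    fd <- (lp - lm) / (2 * h)
    ad <- lf$phi_nodes[[1]]$grad[i[1], i[2], i[3], i[4]]
    expect_lt(abs(ad - fd) / max(abs(fd), 1e-6), 1e-3)
  }
})
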