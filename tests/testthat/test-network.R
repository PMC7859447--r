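test_that("encoder yields a four-level pyramid at strides 2..16 with shared weights", {
  params <- epreg_params(tiny_config(), seed = 71)
  x <- rand_vol(c(64, 64, 64), seed = 71, smooth = 1)
  fw <- epreg_forward(params, x, x)
  spat <- lapply(fw$pyramids$fixed, function(f) dim(f$value)[1:3])
  expect_equal(spat, list(c(32L, 32L, 32L), c(16L, 16L, 16L),
                          c(8L, 8L, 8L), c(4L, 4L, 4L)))
  widths <- sapply(fw$pyramids$fixed, function(f) dim(f$value)[4])
  expect_equal(widths, tiny_config()$widths)
  # same data through both streams: identical pyramids (shared encoder)
  for (i in 1:4) {
    expect_identical(fw$pyramids$fixed[[i]]$value,
                     fw$pyramids$moving[[i]]$value)
  }
  expect_true(all(sapply(fw$pyramids$fixed,
                         function(f) all(is.finite(f$value)))))
})

test_that("a freshly initialized network is exactly the identity map", {
  params <- epreg_params(tiny_config(), seed = 72)
  pair <- make_pair(shape = 32L, seed = 72, amplitude = 3)
  fw <- epreg_forward(params, pair$fixed, pair$moving)

  # zero-initialized heads: 12 affine values all zero, all residuals zero
  expect_length(fw$affine12$value, 12L)
  expect_equal(fw$affine12$value, numeric(12L))
  for (i in c("3", "2", "1")) {
    expect_equal(max(abs(fw$phis[[i]]$value)), 0)
  }
  expect_equal(array(fw$warped$value, dim(pair$moving)), pair$moving,
               tolerance = 1e-12)
})

test_that("every level's grid is the upsampled coarser grid plus its residual", {
  params <- epreg_params(tiny_config(), seed = 73)
  # give the heads non-trivial output so the relation is not 0 = 0
  params$aff$out$w <- matrix(rnorm(length(params$aff$out$w), sd = 0.02),
                             nrow(params$aff$out$w))
  for (h in c("def3", "def2", "def1")) {
    params[[h]]$out$w <- matrix(rnorm(length(params[[h]]$out$w), sd = 0.02),
                                nrow(params[[h]]$out$w))
  }
  pair <- make_pair(shape = 32L, seed = 73, amplitude = 3)
  fw <- epreg_forward(params, pair$fixed, pair$moving)
  for (i in 3:1) {
    up <- upsample_grid(fw$grids[[as.character(i + 1)]]$value, 2L)
    expect_equal(fw$grids[[as.character(i)]]$value,
                 up + fw$phis[[as.character(i)]]$value, tolerance = 1e-12)
  }
  # grids live at strides 16, 8, 4, 2
  expect_equal(dim(fw$grids[["4"]]$value)[1:3], c(2L, 2L, 2L))
  expect_equal(dim(fw$grids[["1"]]$value)[1:3], c(16L, 16L, 16L))
  expect_true(max(abs(fw$phis[["1"]]$value)) > 0)
})

test_that("forward passes are deterministic and validate their inputs", {
  params <- epreg_params(tiny_config(), seed = 74)
  pair <- make_pair(shape = 32L, seed = 74)
  f1 <- epreg_forward(params, pair$fixed, pair$moving)
  f2 <- epreg_forward(params, pair$fixed, pair$moving)
  expect_identical(f1$warped$value, f2$warped$value)
  expect_identical(f1$full_grid$value, f2$full_grid$value)

  expect_error(epreg_forward(params, pair$fixed,
                             pair$moving[1:16, , ]), "differ")
  x24 <- rand_vol(c(24, 24, 24), seed = 75)
  expect_error(epreg_forward(params, x24, x24), "divisible by 16")
})

test_that("the intensity-only configuration drops the edge channel", {
  cfg <- tiny_config(use_edges = FALSE)
  params <- epreg_params(cfg, seed = 76)
  expect_equal(nrow(params$enc$b1$conv$w), 27L)  # 1 input channel
  pair <- make_pair(shape = 32L, seed = 76)
  fw <- epreg_forward(params, pair$fixed, pair$moving)
  expect_equal(array(fw$warped$value, dim(pair$moving)), pair$moving,
               tolerance = 1e-12)
})
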