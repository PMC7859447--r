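# fraction of a field's spectral energy above a quarter of the
# full-resolution Nyquist band, measured on the field's native grid
# (frequencies are in cycles per volume, so levels are band-limited to
# their own grid and no interpolation artifacts are counted)
hf_fraction <- function(phi, full_shape) {
  d <- dim(phi)[1:3]
  cutoff <- full_shape[1] / 8  # Nyquist of the full grid is n/2 cycles
  fr <- lapply(d, function(n) {
    f <- seq_len(n) - 1L
    pmin(f, n - f)
  })
  high <- outer(outer(fr[[1]] > cutoff, fr[[2]] > cutoff, "|"),
                fr[[3]] > cutoff, "|")
  tot <- 0
  hi <- 0
  for (k in 1:3) {
    sp <- Mod(fft(phi[, , , k]))^2
    tot <- tot + sum(sp)
    hi <- hi + sum(sp[high])
  }
  hi / max(tot, 1e-12)
}

test_that("the learning rate halves every ten epochs from 2e-4", {
  expect_identical(lr_schedule(0), 2e-4)
  expect_identical(lr_schedule(10), 1e-4)
  expect_identical(lr_schedule(25), 5e-5)
  ep <- c(0:12, 99)
  expect_equal(lr_schedule(ep), 2e-4 * 0.5^(ep %/% 10))
})

test_that("an identical pair sits at the similarity floor from iteration zero", {
  ph <- make_phantom(shape = 32L, seed = 91L)
  fit <- instance_optimize(ph$volume, ph$volume, cfg = tiny_config(),
                           iters = 8L, seed = 91L)
  floor0 <- sum(sapply(1:4, function(i) {
    fi <- resize_trilinear(ph$volume, dim(ph$volume) %/% (2L^i))
    lncc_loss(fi, fi)
  }))
  expect_equal(fit$log$total[1], floor0, tolerance = 1e-8)
  # training cannot improve on a perfect match by much, nor break it
  expect_lt(abs(fit$log$total[8] - floor0) / abs(floor0), 0.02)
  # the affine head stays near the identity
  expect_lt(max(abs(fit$result$affine12)), 0.05)
})

test_that("instance optimization reduces the loss on a misaligned pair", {
  pair <- make_pair(shape = 32L, seed = 92L, amplitude = 3)
  fit <- instance_optimize(pair$moving, pair$fixed, cfg = tiny_config(),
                           iters = 40L, seed = 92L)
  expect_true(all(is.finite(fit$log$total)))
  expect_lt(fit$log$total[40], fit$log$total[1])
  # similarity improves on a trailing moving average
  sim <- rowSums(fit$log[, c("sim1", "sim2", "sim3", "sim4")])
  expect_lt(mean(sim[31:40]), mean(sim[1:5]))
})

test_that("an overwhelming smoothness weight suppresses the non-uniform field", {
  pair <- make_pair(shape = 32L, seed = 93L, amplitude = 3)
  fits <- lapply(c(1000, 1e9), function(lam) {
    instance_optimize(pair$moving, pair$fixed,
                      cfg = tiny_config(lambda = lam),
                      iters = 60L, seed = 93L)
  })
  # in the regularizer-dominated limit the diffusion term is driven far
  # below its value under the default weight, and keeps shrinking
  s_ref <- fits[[1]]$log$smooth[60]
  s_big <- fits[[2]]$log$smooth[60]
  expect_lt(s_big, s_ref / 50)
  expect_lt(s_big, fits[[2]]$log$smooth[25])
})

test_that("population training over ordered pairs lowers the epoch-mean loss", {
  vols <- lapply(94:96, function(s) make_phantom(shape = 32L, seed = s)$volume)
  fit <- train_epreg(vols, cfg = tiny_config(), epochs = 3L, lr0 = 1e-3,
                     seed = 94L)
  expect_equal(nrow(fit$log), 3L * 6L)  # 3 volumes -> 6 ordered pairs
  m0 <- mean(fit$log$total[fit$log$epoch == 0])
  m2 <- mean(fit$log$total[fit$log$epoch == 2])
  expect_lt(m2, m0)
  expect_true(all(is.finite(fit$log$total)))
})

test_that("registration is deterministic and checkpoints are self-describing", {
  dir <- withr::local_tempdir()
  pair <- make_pair(shape = 32L, seed = 97L, amplitude = 3)
  fit <- instance_optimize(pair$moving, pair$fixed, cfg = tiny_config(),
                           iters = 10L, seed = 97L)
  r1 <- register_pair(pair$moving, pair$fixed, fit$params,
                      moving_labels = pair$labels_f)
  r2 <- register_pair(pair$moving, pair$fixed, fit$params,
                      moving_labels = pair$labels_f)
  expect_identical(r1$warped, r2$warped)
  expect_identical(r1$warped_labels, r2$warped_labels)

  ck <- file.path(dir, "net.rds")
  save_checkpoint(fit$params, ck)
  params2 <- load_checkpoint(ck)
  expect_equal(params2$config$widths, tiny_config()$widths)
  r3 <- register_pair(pair$moving, pair$fixed, params2)
  expect_identical(r3$warped, r1$warped)
})

test_that("finer levels carry progressively more similarity and detail", {
  sims <- matrix(0, 0, 4)
  hfs <- matrix(0, 0, 2)
  for (s in 101:105) {
    pair <- make_pair(shape = 32L, seed = s, amplitude = 3)
    fit <- instance_optimize(pair$moving, pair$fixed, cfg = tiny_config(),
                             iters = 30L, seed = s)
    reg <- fit$result
    sp1 <- dim(pair$fixed) %/% 2L
    f1 <- resize_trilinear(pair$moving, sp1)
    m1 <- resize_trilinear(pair$fixed, sp1)
    sims <- rbind(sims, sapply(c("4", "3", "2", "1"), function(i) {
      g <- resize_trilinear(reg$grids[[i]], sp1)
      lncc_loss(f1, warp_volume(m1, g))
    }))
    hfs <- rbind(hfs, c(hf_fraction(reg$phis[["1"]], dim(pair$fixed)),
                        hf_fraction(reg$phis[["3"]], dim(pair$fixed))))
  }
  # statistical tendency over seeds, not a per-seed hard assertion:
  # the finest grid matches at least as well as the coarsest on average,
  # and the finest residual field holds more high-frequency energy
  expect_lt(mean(sims[, 4]), mean(sims[, 1]))
  expect_gt(mean(hfs[, 1]), mean(hfs[, 2]))
})
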