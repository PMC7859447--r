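# Independent brute-force oracles used to pin the fast implementations.
# All are deliberately naive triple-loop computations.

# trilinear interpolation of `vol` at normalized align-corners grid coords
oracle_trilinear <- function(vol, grid) {
  d <- dim(vol)
  gd <- dim(grid)[1:3]
  out <- array(0, gd)
  for (k in seq_len(gd[3])) for (j in seq_len(gd[2])) for (i in seq_len(gd[1])) {
    pos <- (grid[i, j, k, ] + 1) / 2 * (d - 1)
    pos <- pmin(pmax(pos, 0), d - 1)
    i0 <- pmax(pmin(floor(pos), d - 2), 0)
    f <- pos - i0
    acc <- 0
    for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
      w <- (if (dx) f[1] else 1 - f[1]) *
        (if (dy) f[2] else 1 - f[2]) *
        (if (dz) f[3] else 1 - f[3])
      acc <- acc + w * vol[i0[1] + dx + 1, i0[2] + dy + 1, i0[3] + dz + 1]
    }
    out[i, j, k] <- acc
  }
  out
}

# direct cross-correlation of a replicate-padded volume with a 3x3x3 kernel
oracle_correlate <- function(x, kern) {
  d <- dim(x)
  cl <- function(v, n) pmin(pmax(v, 1L), n)
  out <- array(0, d)
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    acc <- 0
    for (c in -1:1) for (b in -1:1) for (a in -1:1) {
      acc <- acc + kern[a + 2, b + 2, c + 2] *
        x[cl(i + a, d[1]), cl(j + b, d[2]), cl(k + c, d[3])]
    }
    out[i, j, k] <- acc
  }
  out
}

oracle_sobel <- function(x) {
  ks <- sobel_kernels()
  sqrt(oracle_correlate(x, ks$Sx)^2 + oracle_correlate(x, ks$Sy)^2 +
         oracle_correlate(x, ks$Sz)^2)
}

# direct per-voxel windowed local NCC with replicate padding
oracle_lncc <- function(a, b, v, eps = 1e-5) {
  r <- (v - 1L) / 2L
  d <- dim(a)
  cl <- function(idx, n) pmin(pmax(idx, 1L), n)
  tot <- 0
  for (k in seq_len(d[3])) for (j in seq_len(d[2])) for (i in seq_len(d[1])) {
    pa <- a[cl(i + (-r:r), d[1]), cl(j + (-r:r), d[2]), cl(k + (-r:r), d[3])]
    pb <- b[cl(i + (-r:r), d[1]), cl(j + (-r:r), d[2]), cl(k + (-r:r), d[3])]
    ca <- pa - mean(pa)
    cb <- pb - mean(pb)
    tot <- tot + sum(ca * cb)^2 / (sum(ca * ca) * sum(cb * cb) + eps)
  }
  -tot
}

# seeded test volumes
rand_vol <- function(shape, seed, smooth = 0) {
  set.seed(seed)
  x <- array(runif(prod(shape)), shape)
  if (smooth > 0) x <- epreg:::smooth_gauss3(x, smooth)
  x
}

# axis-3 unit ramp I(x,y,z) = z
ramp_vol <- function(n, axis = 3L) {
  x <- array(0, rep(n, 3L))
  idx <- slice.index(x, axis)
  array(as.double(idx), dim(x))
}

# small config used throughout network-level tests to keep runtimes low
tiny_config <- function(...) {
  epreg_config(widths = c(4L, 8L, 8L, 16L), ...)
}
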