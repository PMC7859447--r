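# Minimal reverse-mode autodiff over dense R arrays.
#
# A node is an environment holding `value`, the accumulated `grad`, its
# `parents` and one vector-Jacobian-product closure per parent. The graph
# is a DAG built eagerly during the forward pass; ad_backward() runs a
# non-recursive topological sort restricted to the gradient-requiring
# subgraph and accumulates gradients root-first. This is deliberately the
# smallest engine that supports the registration network: no broadcasting
# rules, no higher-order gradients, arrays only.

.ad <- new.env(parent = emptyenv())
.ad$run <- 0L

ad_node <- function(value, parents = list(), vjps = list(),
                    req = length(parents) > 0L &&
                      any(vapply(parents, function(p) p$req, FALSE))) {
  e <- new.env(parent = emptyenv())
  e$value <- value
  e$parents <- parents
  e$vjps <- vjps
  e$req <- req
  e$grad <- NULL
  class(e) <- "ad_node"
  e
}

#' @export
print.ad_node <- function(x, ...) {
  d <- dim(x$value)
  cat("<ad_node", if (is.null(d)) paste0("len ", length(x$value))
      else paste(d, collapse = "x"),
      if (x$req) "(grad)" else "(const)", ">\n")
  invisible(x)
}

ad_const <- function(value) ad_node(value, req = FALSE)
ad_param <- function(value) ad_node(value, req = TRUE)

ad_value <- function(x) if (inherits(x, "ad_node")) x$value else x

# Backpropagate from a scalar root; afterwards every reachable
# gradient-requiring node carries its gradient in $grad.
ad_backward <- function(root) {
  stopifnot(inherits(root, "ad_node"), length(root$value) == 1L)
  rid <- .ad$run <- .ad$run + 1L
  stack <- list(list(n = root, expanded = FALSE))
  topo <- vector("list", 0L)
  while (length(stack)) {
    top <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    n <- top$n
    if (top$expanded) {
      topo[[length(topo) + 1L]] <- n
      next
    }
    if (identical(n$.seen, rid) || !n$req) next
    n$.seen <- rid
    stack[[length(stack) + 1L]] <- list(n = n, expanded = TRUE)
    for (p in n$parents) {
      if (p$req && !identical(p$.seen, rid)) {
        stack[[length(stack) + 1L]] <- list(n = p, expanded = FALSE)
      }
    }
  }
  for (n in topo) n$grad <- NULL
  root$grad <- 1
  for (n in rev(topo)) {
    g <- n$grad
    if (is.null(g)) next
    for (k in seq_along(n$parents)) {
      p <- n$parents[[k]]
      if (!p$req) next
      contrib <- n$vjps[[k]](g)
      p$grad <- if (is.null(p$grad)) contrib else p$grad + contrib
    }
  }
  invisible(root)
}

# ---- elementwise primitives --------------------------------------------

ad_add <- function(x, y) {
  ad_node(x$value + y$value, list(x, y),
          list(function(g) g, function(g) g))
}

ad_sub <- function(x, y) {
  ad_node(x$value - y$value, list(x, y),
          list(function(g) g, function(g) -g))
}

ad_mul <- function(x, y) {
  xv <- x$value; yv <- y$value
  ad_node(xv * yv, list(x, y),
          list(function(g) g * yv, function(g) g * xv))
}

ad_div <- function(x, y) {
  xv <- x$value; yv <- y$value
  ad_node(xv / yv, list(x, y),
          list(function(g) g / yv, function(g) -g * xv / (yv * yv)))
}

ad_sq <- function(x) {
  xv <- x$value
  ad_node(xv * xv, list(x), list(function(g) 2 * g * xv))
}

ad_neg <- function(x) ad_node(-x$value, list(x), list(function(g) -g))

ad_scale <- function(x, a) ad_node(a * x$value, list(x), list(function(g) a * g))

# elementwise multiply / add with a constant array
ad_mul_const <- function(x, k) ad_node(x$value * k, list(x), list(function(g) g * k))
ad_add_const <- function(x, k) ad_node(x$value + k, list(x), list(function(g) g))

ad_sum <- function(x) {
  dm <- dim(x$value)
  ad_node(sum(x$value), list(x),
          list(function(g) array(g, if (is.null(dm)) length(x$value) else dm)))
}

ad_relu <- function(x) {
  mask <- x$value > 0
  ad_node(x$value * mask, list(x), list(function(g) g * mask))
}

# ---- structural ops -----------------------------------------------------

# concatenate feature maps along the trailing (channel) axis
ad_concat <- function(nodes) {
  vals <- lapply(nodes, ad_value)
  sp <- dim(vals[[1L]])[1:3]
  chans <- vapply(vals, function(v) dim(v)[4L], 0)
  out <- array(unlist(vals, use.names = FALSE), dim = c(sp, sum(chans)))
  offs <- cumsum(c(0, chans))
  nvox <- prod(sp)
  vjps <- lapply(seq_along(nodes), function(k) {
    force(k)
    function(g) array(g[nvox * offs[k] + seq_len(nvox * chans[k])],
                      dim = c(sp, chans[k]))
  })
  ad_node(out, nodes, vjps)
}

# 1x1x1 convolution: per-voxel linear map across channels
ad_pointwise <- function(x, w, b) {
  xv <- x$value
  dm <- dim(xv)
  cin <- dm[4L]
  xm <- matrix(xv, ncol = cin)
  om <- xm %*% w$value
  om <- sweep(om, 2L, b$value, "+")
  cout <- ncol(om)
  ad_node(array(om, c(dm[1:3], cout)), list(x, w, b), list(
    function(g) array(matrix(g, ncol = cout) %*% t(w$value), dm),
    function(g) crossprod(xm, matrix(g, ncol = cout)),
    function(g) colSums(matrix(g, ncol = cout))
  ))
}

# per-channel spatial normalization with learnable scale/shift
ad_norm <- function(x, gamma, beta, eps = 1e-5) {
  xv <- x$value
  dm <- dim(xv)
  C <- dm[4L]
  xm <- matrix(xv, ncol = C)
  mu <- colMeans(xm)
  xc <- sweep(xm, 2L, mu)
  va <- colMeans(xc * xc)
  s <- 1 / sqrt(va + eps)
  xhat <- sweep(xc, 2L, s, "*")
  om <- sweep(sweep(xhat, 2L, gamma$value, "*"), 2L, beta$value, "+")
  ad_node(array(om, dm), list(x, gamma, beta), list(
    function(g) {
      gm <- matrix(g, ncol = C)
      dxh <- sweep(gm, 2L, gamma$value, "*")
      m1 <- colMeans(dxh)
      m2 <- colMeans(dxh * xhat)
      dx <- sweep(dxh, 2L, m1) - sweep(xhat, 2L, m2, "*")
      array(sweep(dx, 2L, s, "*"), dm)
    },
    function(g) colSums(matrix(g, ncol = C) * xhat),
    function(g) colSums(matrix(g, ncol = C))
  ))
}

# global average pooling: (D,H,W,C) -> length-C vector
ad_gap <- function(x) {
  dm <- dim(x$value)
  n <- prod(dm[1:3])
  ad_node(colMeans(matrix(x$value, ncol = dm[4L])), list(x),
          list(function(g) array(rep(g / n, each = n), dm)))
}

# ---- kernels with C++ forward/adjoint ----------------------------------

# 3x3x3 convolution, zero padding = dilation, so stride 1 preserves shape
# and stride 2 halves even extents. Weights are (27*Cin) x Cout matrices
# with row order kd, kh, kw (fastest first), then input channel.
ad_conv3d <- function(x, w, b, stride = 1L, dilation = 1L) {
  xv <- x$value; wv <- w$value; bv <- b$value
  out <- cpp_conv3d_fw(xv, wv, bv, as.integer(stride), as.integer(dilation))
  cache <- NULL
  getc <- function(g) {
    if (is.null(cache)) {
      cache <<- cpp_conv3d_bw(xv, wv, g, as.integer(stride),
                              as.integer(dilation), x$req)
    }
    cache
  }
  ad_node(out, list(x, w, b), list(
    function(g) getc(g)$gx,
    function(g) getc(g)$gw,
    function(g) getc(g)$gb
  ))
}

# trilinear align-corners resize of a (D,H,W,C) array to out_shape
ad_resize <- function(x, out_shape) {
  isp <- dim(x$value)[1:3]
  ad_node(cpp_resize3(x$value, as.integer(out_shape)), list(x),
          list(function(g) cpp_resize3_adj(g, as.integer(isp))))
}

# trilinear sampling of x at grid (both differentiable)
ad_grid_sample <- function(x, grid) {
  xv <- x$value; gv <- grid$value
  out <- cpp_grid_sample_fw(xv, gv)
  cache <- NULL
  getc <- function(g) {
    if (is.null(cache)) cache <<- cpp_grid_sample_bw(xv, gv, g, x$req)
    cache
  }
  ad_node(out, list(x, grid), list(
    function(g) getc(g)$gx,
    function(g) getc(g)$ggrid
  ))
}

# separable v^3 box-window sum with replicate padding
boxsum3 <- function(a, v) {
  for (ax in 1:3) a <- cpp_box_axis(a, ax, as.integer(v), FALSE)
  a
}

boxsum3_adj <- function(g, v) {
  for (ax in 3:1) g <- cpp_box_axis(g, ax, as.integer(v), TRUE)
  g
}

ad_boxsum <- function(x, v) {
  ad_node(boxsum3(x$value, v), list(x),
          list(function(g) boxsum3_adj(g, v)))
}

# dense grid from a 12-parameter offset from the identity affine transform
# (t is a length-12 node; matrix(t, 3, 4) is added to [I | 0])
ad_affine_grid_op <- function(t, shape) {
  hom <- homogeneous_coords(shape)          # Nvox x 4 constant
  M <- diag(1, 3, 4) + matrix(t$value, 3, 4)
  G <- hom %*% t(M)
  ad_node(array(G, c(shape, 3L)), list(t), list(
    function(g) as.vector(t(matrix(g, ncol = 3L)) %*% hom)
  ))
}

# sum of squared forward finite differences over all three axes of a
# (D,H,W,3) field; boundary sites without a forward neighbour are excluded
ad_smoothness_op <- function(phi) {
  pv <- phi$value
  dm <- dim(pv)
  d1 <- pv[-1, , , , drop = FALSE] - pv[-dm[1], , , , drop = FALSE]
  d2 <- pv[, -1, , , drop = FALSE] - pv[, -dm[2], , , drop = FALSE]
  d3 <- pv[, , -1, , drop = FALSE] - pv[, , -dm[3], , drop = FALSE]
  val <- sum(d1 * d1) + sum(d2 * d2) + sum(d3 * d3)
  ad_node(val, list(phi), list(function(g) {
    gp <- array(0, dm)
    gp[-1, , , ] <- gp[-1, , , , drop = FALSE] + 2 * g * d1
    gp[-dm[1], , , ] <- gp[-dm[1], , , , drop = FALSE] - 2 * g * d1
    gp[, -1, , ] <- gp[, -1, , , drop = FALSE] + 2 * g * d2
    gp[, -dm[2], , ] <- gp[, -dm[2], , , drop = FALSE] - 2 * g * d2
    gp[, , -1, ] <- gp[, , -1, , drop = FALSE] + 2 * g * d3
    gp[, , -dm[3], ] <- gp[, , -dm[3], , drop = FALSE] - 2 * g * d3
    gp
  }))
}
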