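# Tape-based reverse-mode automatic differentiation over dense R arrays.
#
# A "tensor" is an environment with fields:
#   v  : the value (numeric array / matrix / scalar)
#   g  : accumulated gradient (NULL until backward touches it)
#   parents, backfn : recorded only while a tape is active
# Network parameters are persistent leaf tensors (created by ad_param); they
# additionally carry an optimizer velocity slot. Activations are recorded on
# the tape only while recording is on, so evaluation-mode forward passes pay
# no graph overhead.

.ad <- new.env(parent = emptyenv())
.ad$tape <- NULL
.ad$count_cache <- list()

ad_recording <- function() !is.null(.ad$tape)

ad_start <- function() {
  .ad$tape <- new.env(parent = emptyenv())
  .ad$tape$nodes <- vector("list", 1024L)
  .ad$tape$n <- 0L
  invisible(NULL)
}

ad_stop <- function() {
  .ad$tape <- NULL
  invisible(NULL)
}

is_ad <- function(x) is.environment(x)

#' @noRd
vv <- function(x) if (is.environment(x)) x$v else x

ad_param <- function(value) {
  n <- new.env(parent = emptyenv())
  n$v <- value
  n$g <- NULL
  n$vel <- NULL
  n$leaf <- TRUE
  n
}

ad_const <- function(value) value  # plain arrays are constants

# Record a computed node. parents: list possibly mixing tensors and plain
# values; backfn(g) must return a list of gradients aligned with parents
# (NULL entries for constants).
ad_node <- function(value, parents, backfn) {
  if (!ad_recording()) return(value)
  if (!any(vapply(parents, is.environment, logical(1)))) return(value)
  n <- new.env(parent = emptyenv())
  n$v <- value
  n$g <- NULL
  n$parents <- parents
  n$backfn <- backfn
  t <- .ad$tape
  t$n <- t$n + 1L
  if (t$n > length(t$nodes)) t$nodes <- c(t$nodes, vector("list", length(t$nodes)))
  t$nodes[[t$n]] <- n
  n
}

ad_backward <- function(loss) {
  stopifnot(is.environment(loss))
  t <- .ad$tape
  loss$g <- 1
  for (i in seq(t$n, 1L)) {
    n <- t$nodes[[i]]
    if (is.null(n$g) || is.null(n$backfn)) next
    gs <- n$backfn(n$g)
    ps <- n$parents
    for (j in seq_along(ps)) {
      p <- ps[[j]]
      if (is.environment(p) && !is.null(gs[[j]])) {
        p$g <- if (is.null(p$g)) gs[[j]] else p$g + gs[[j]]
      }
    }
    n$g <- NULL  # free memory as we go
  }
  invisible(NULL)
}

ad_zero_grad <- function(params) {
  for (p in params) p$g <- NULL
  invisible(NULL)
}

ad_detach <- function(x) vv(x)

# ---- elementwise / scalar ops -------------------------------------------

ad_add <- function(a, b) {
  ad_node(vv(a) + vv(b), list(a, b), function(g) list(g, g))
}

ad_sub <- function(a, b) {
  ad_node(vv(a) - vv(b), list(a, b), function(g) list(g, -g))
}

ad_mul <- function(a, b) {
  av <- vv(a); bv <- vv(b)
  ad_node(av * bv, list(a, b), function(g) list(g * bv, g * av))
}

ad_div <- function(a, b) {
  av <- vv(a); bv <- vv(b)
  ad_node(av / bv, list(a, b),
          function(g) list(g / bv, -g * av / (bv * bv)))
}

ad_scale <- function(a, s) {  # s plain scalar
  ad_node(vv(a) * s, list(a), function(g) list(g * s))
}

ad_square <- function(a) {
  av <- vv(a)
  ad_node(av * av, list(a), function(g) list(2 * g * av))
}

ad_log <- function(a) {
  av <- vv(a)
  ad_node(log(av), list(a), function(g) list(g / av))
}

ad_clamp <- function(a, lo, hi) {
  av <- vv(a)
  out <- pmin(pmax(av, lo), hi)
  pass <- (av > lo & av < hi)
  ad_node(out, list(a), function(g) list(g * pass))
}

ad_sigmoid <- function(a) {
  s <- 1 / (1 + exp(-vv(a)))
  ad_node(s, list(a), function(g) list(g * s * (1 - s)))
}

ad_relu <- function(a) {
  av <- vv(a)
  pos <- av > 0
  ad_node(av * pos, list(a), function(g) list(g * pos))
}

ad_lrelu <- function(a, slope = 0.2) {
  av <- vv(a)
  fac <- (av > 0) * (1 - slope) + slope
  ad_node(av * fac, list(a), function(g) list(g * fac))
}

# PReLU with a single learnable slope per layer.
ad_prelu <- function(a, slope) {
  av <- vv(a); sv <- as.numeric(vv(slope))
  pos <- av > 0
  neg <- av * !pos
  ad_node(av * pos + sv * neg, list(a, slope),
          function(g) list(g * (pos + sv * !pos), sum(g * neg)))
}

ad_sum <- function(a) {
  av <- vv(a)
  dm <- dim(av); n <- length(av)
  ad_node(sum(av), list(a), function(g) {
    gr <- array(as.numeric(g), dim = if (is.null(dm)) n else dm)
    list(gr)
  })
}

ad_mean <- function(a) {
  av <- vv(a)
  dm <- dim(av); n <- length(av)
  ad_node(mean(av), list(a), function(g) {
    gr <- array(as.numeric(g) / n, dim = if (is.null(dm)) n else dm)
    list(gr)
  })
}

# ---- linear algebra ------------------------------------------------------

ad_matmul <- function(a, b) {
  av <- vv(a); bv <- vv(b)
  ad_node(av %*% bv, list(a, b), function(g)
    list(g %*% t(bv), crossprod(av, g)))
}

# x: (d_in x N) matrix of columns; W: (d_out x d_in); b: length d_out
ad_linear <- function(x, W, b = NULL) {
  xv <- vv(x); Wv <- vv(W)
  out <- Wv %*% xv
  if (!is.null(b)) out <- out + vv(b)
  need_x <- is.environment(x)
  ad_node(out, list(x, W, b), function(g) {
    list(if (need_x) crossprod(Wv, g), tcrossprod(g, xv),
         if (is.null(b)) NULL else rowSums(g))
  })
}

# ---- shape utilities -----------------------------------------------------

ad_reshape <- function(a, dm) {
  av <- vv(a)
  old <- dim(av)
  out <- av
  dim(out) <- dm
  ad_node(out, list(a), function(g) { dim(g) <- old; list(g) })
}

# Channel concatenation of (C,Z,Y,X) tensors.
ad_concat_ch <- function(xs) {
  vals <- lapply(xs, vv)
  Cs <- vapply(vals, function(v) dim(v)[1], integer(1))
  sp <- dim(vals[[1]])[-1]
  mats <- lapply(vals, function(v) { dim(v) <- c(dim(v)[1], prod(sp)); v })
  out <- do.call(rbind, mats)
  dim(out) <- c(sum(Cs), sp)
  ends <- cumsum(Cs); starts <- ends - Cs + 1
  ad_node(out, xs, function(g) {
    dim(g) <- c(sum(Cs), prod(sp))
    lapply(seq_along(xs), function(i) {
      gi <- g[starts[i]:ends[i], , drop = FALSE]
      dim(gi) <- c(Cs[i], sp)
      gi
    })
  })
}

# Channel slice of a (C,Z,Y,X) tensor.
ad_channel <- function(x, i) {
  xv <- vv(x)
  dm <- dim(xv)
  out <- xv[i, , , , drop = FALSE]
  dim(out) <- dm[-1]
  ad_node(out, list(x), function(g) {
    gx <- array(0, dm)
    gx[i, , , ] <- g
    list(gx)
  })
}

# ---- convolution & friends ----------------------------------------------

# 3D convolution with direct compiled kernels (no unfolded buffer).
# x: (C,Z,Y,X); W: (Cout x C*prod(k)); b: length Cout. "Same" padding is
# pad = (k-1)/2 when stride 1. The input gradient is only computed when the
# input is itself a tracked tensor.
ad_conv3d <- function(x, W, b, k, stride = c(1L, 1L, 1L), pad = NULL) {
  xv <- vv(x); Wv <- vv(W)
  dm <- dim(xv)
  if (is.null(pad)) pad <- (k - 1L) %/% 2L
  k <- as.integer(k); stride <- as.integer(stride); pad <- as.integer(pad)
  out <- cpp_conv3d_fwd(xv, dm, Wv, k, stride, pad) + vv(b)
  Zo <- (dm[2] + 2 * pad[1] - k[1]) %/% stride[1] + 1L
  Yo <- (dm[3] + 2 * pad[2] - k[2]) %/% stride[2] + 1L
  Xo <- (dm[4] + 2 * pad[3] - k[3]) %/% stride[3] + 1L
  dim(out) <- c(nrow(Wv), Zo, Yo, Xo)
  need_x <- is.environment(x)
  ad_node(out, list(x, W, b), function(g) {
    dim(g) <- c(nrow(Wv), Zo * Yo * Xo)
    gx <- NULL
    if (need_x) {
      gx <- cpp_conv3d_gx(dm, Wv, g, k, stride, pad)
      dim(gx) <- dm
    }
    list(gx, cpp_conv3d_gw(xv, dm, g, nrow(Wv), k, stride, pad), rowSums(g))
  })
}

# Pointwise (1x1x1) convolution as a pure GEMM.
ad_conv1x1 <- function(x, W, b = NULL) {
  xv <- vv(x); Wv <- vv(W)
  dm <- dim(xv)
  xm <- xv; dim(xm) <- c(dm[1], prod(dm[-1]))
  out <- Wv %*% xm
  if (!is.null(b)) out <- out + vv(b)
  dim(out) <- c(nrow(Wv), dm[-1])
  need_x <- is.environment(x)
  ad_node(out, list(x, W, b), function(g) {
    dim(g) <- c(nrow(Wv), prod(dm[-1]))
    gx <- NULL
    if (need_x) {
      gx <- crossprod(Wv, g)
      dim(gx) <- dm
    }
    list(gx, tcrossprod(g, xm), if (is.null(b)) NULL else rowSums(g))
  })
}

# Stride-1 "same" average pooling with valid-count divisor (a constant field
# pools to itself, including at borders).
ad_avgpool_same <- function(x, k) {
  xv <- vv(x)
  dm <- dim(xv)
  cnt <- pool_counts(dm, k)
  out <- cpp_winsum3d(xv, dm, as.integer(k)) / cnt
  dim(out) <- dm
  ad_node(out, list(x), function(g) {
    gx <- cpp_winsum3d(g / cnt, dm, as.integer(k))
    dim(gx) <- dm
    list(gx)
  })
}

# Number of in-bounds window elements at each voxel, as a (C,Z,Y,X) array.
# Cached per (shape, kernel) signature: the same shapes recur every
# iteration during training.
pool_counts <- function(dm, k) {
  key <- paste(c(dm, k), collapse = ",")
  hit <- .ad$count_cache[[key]]
  if (!is.null(hit)) return(hit)
  axis_counts <- function(n, kk) {
    h <- kk %/% 2
    i <- seq_len(n) - 1
    pmin(i + h, n - 1) - pmax(i - h, 0) + 1
  }
  cz <- axis_counts(dm[2], k[1])
  cy <- axis_counts(dm[3], k[2])
  cx <- axis_counts(dm[4], k[3])
  cnt <- outer(outer(cz, cy), cx)
  out <- aperm(array(cnt, dim = c(dm[2], dm[3], dm[4], dm[1])), c(4, 1, 2, 3))
  .ad$count_cache[[key]] <- out
  out
}

# Non-overlapping average-pool downsampling by integer factors f.
ad_pool_down <- function(x, f) {
  xv <- vv(x)
  dm <- dim(xv)
  out <- cpp_pool_down(xv, dm, as.integer(f))
  dim(out) <- c(dm[1], dm[2] %/% f[1], dm[3] %/% f[2], dm[4] %/% f[3])
  ad_node(out, list(x), function(g) {
    gx <- cpp_pool_down_grad(g, dm, as.integer(f))
    dim(gx) <- dm
    list(gx)
  })
}

# Transpose convolution with kernel == stride == f (non-overlapping blocks).
# W: (Cout*prod(f)) x Cin; output spatial dims multiply by f.
ad_upconv <- function(x, W, b, f, Cout) {
  xv <- vv(x); Wv <- vv(W)
  dm <- dim(xv)
  xm <- xv; dim(xm) <- c(dm[1], prod(dm[-1]))
  y <- Wv %*% xm + vv(b)
  out <- cpp_block_scatter(y, as.integer(Cout), as.integer(f),
                           as.integer(dm[2:4]))
  dim(out) <- c(Cout, dm[2] * f[1], dm[3] * f[2], dm[4] * f[3])
  need_x <- is.environment(x)
  ad_node(out, list(x, W, b), function(g) {
    gy <- cpp_block_gather(g, as.integer(Cout), as.integer(f),
                           as.integer(dm[2:4]))
    gx <- NULL
    if (need_x) {
      gx <- crossprod(Wv, gy)
      dim(gx) <- dm
    }
    list(gx, tcrossprod(gy, xm), rowSums(gy))
  })
}

ad_resize_trilinear <- function(x, odims) {
  xv <- vv(x)
  dm <- dim(xv)
  out <- cpp_resize_trilinear(xv, dm, as.integer(odims))
  dim(out) <- c(dm[1], odims)
  ad_node(out, list(x), function(g) {
    gx <- cpp_resize_trilinear_grad(g, dm, as.integer(odims))
    dim(gx) <- dm
    list(gx)
  })
}

# ---- normalization -------------------------------------------------------

# Group normalization over a (C,Z,Y,X) tensor; gamma/beta length C.
# Implemented on a (C x P) matrix view with column-recycled per-channel
# vectors (groups are contiguous channel blocks).
ad_groupnorm <- function(x, gamma, beta, groups, eps = 1e-5) {
  xv <- vv(x)
  dm <- dim(xv)
  C <- dm[1]; P <- prod(dm[2:4])
  gs <- C %/% groups
  ng <- gs * P
  xm <- xv; dim(xm) <- c(C, P)
  group_mean <- function(m) colSums(matrix(rowSums(m), gs, groups)) / ng
  mu <- group_mean(xm)
  xc <- xm - rep(mu, each = gs)
  va <- group_mean(xc * xc)
  inv_g <- 1 / sqrt(va + eps)
  inv <- rep(inv_g, each = gs)
  xhat <- xc * inv
  gv <- as.numeric(vv(gamma)); bv <- as.numeric(vv(beta))
  out <- xhat * gv + bv
  dim(out) <- dm
  ad_node(out, list(x, gamma, beta), function(g) {
    dim(g) <- c(C, P)
    ggamma <- rowSums(g * xhat)
    gbeta <- rowSums(g)
    gxh <- g * gv
    m1 <- rep(group_mean(gxh), each = gs)
    m2 <- rep(group_mean(gxh * xhat), each = gs)
    gx <- (gxh - m1 - xhat * m2) * inv
    dim(gx) <- dm
    list(gx, ggamma, gbeta)
  })
}

# Layer normalization over the rows of a (d x N) matrix (per column/token).
ad_layernorm <- function(x, gamma, beta, eps = 1e-5) {
  xv <- vv(x)
  d <- nrow(xv)
  mu <- colMeans(xv)
  xc <- sweep(xv, 2, mu, "-")
  va <- colMeans(xc * xc)
  inv <- 1 / sqrt(va + eps)
  xhat <- sweep(xc, 2, inv, "*")
  gv <- as.numeric(vv(gamma)); bv <- as.numeric(vv(beta))
  out <- xhat * gv + bv
  ad_node(out, list(x, gamma, beta), function(g) {
    ggamma <- rowSums(g * xhat)
    gbeta <- rowSums(g)
    gxh <- g * gv
    m1 <- colMeans(gxh)
    m2 <- colMeans(gxh * xhat)
    gx <- sweep(sweep(gxh, 2, m1, "-") - sweep(xhat, 2, m2, "*"), 2, inv, "*")
    list(gx, ggamma, gbeta)
  })
}

# Softmax over the rows of a matrix (one distribution per column).
ad_softmax_cols <- function(x) {
  xv <- vv(x)
  xv <- sweep(xv, 2, apply(xv, 2, max), "-")
  e <- exp(xv)
  s <- sweep(e, 2, colSums(e), "/")
  ad_node(s, list(x), function(g) {
    dot <- colSums(g * s)
    list(s * sweep(g, 2, dot, "-"))
  })
}

# ---- channel attention helpers ------------------------------------------

# Global average over spatial dims: (C,Z,Y,X) -> length-C vector.
ad_global_mean <- function(x) {
  xv <- vv(x)
  dm <- dim(xv)
  xm <- xv; dim(xm) <- c(dm[1], prod(dm[-1]))
  out <- rowMeans(xm)
  ad_node(out, list(x), function(g) {
    gx <- matrix(g, dm[1], prod(dm[-1])) / prod(dm[-1])
    dim(gx) <- dm
    list(gx)
  })
}

# Per-channel scaling of a (C,Z,Y,X) tensor by a length-C gate.
ad_scale_channels <- function(x, s) {
  xv <- vv(x); sv <- as.numeric(vv(s))
  dm <- dim(xv)
  out <- sweep(xv, 1, sv, "*")
  ad_node(out, list(x, s), function(g) {
    gx <- sweep(g, 1, sv, "*")
    gsm <- g * xv; dim(gsm) <- c(dm[1], prod(dm[-1]))
    list(gx, rowSums(gsm))
  })
}

# ---- deformable attention sampling --------------------------------------

# vals: list of L (d,Z,Y,X) tensors; loc: (3,K,L,H,N); w: (K,L,H,N).
ad_msdmsa_sample <- function(vals, loc, w, H, N, K) {
  vvals <- lapply(vals, vv)
  ldims <- do.call(rbind, lapply(vvals, dim))
  locv <- vv(loc); wv <- vv(w)
  out <- cpp_msdmsa_fwd(vvals, ldims, as.numeric(locv), as.numeric(wv),
                        as.integer(H), as.integer(N), as.integer(K))
  ad_node(out, c(vals, list(loc, w)), function(g) {
    bw <- cpp_msdmsa_bwd(vvals, ldims, as.numeric(locv), as.numeric(wv),
                         as.integer(H), as.integer(N), as.integer(K), g)
    gvals <- lapply(seq_along(vals), function(l) {
      gv <- bw$gvals[[l]]; dim(gv) <- ldims[l, ]; gv
    })
    gl <- bw$gloc; dim(gl) <- dim(locv)
    gw <- bw$gw; dim(gw) <- dim(wv)
    c(gvals, list(gl, gw))
  })
}

# Column-wise concatenation of (d x N_i) matrices.
ad_cbind <- function(xs) {
  vals <- lapply(xs, vv)
  ns <- vapply(vals, ncol, integer(1))
  out <- do.call(cbind, vals)
  ends <- cumsum(ns); starts <- ends - ns + 1
  ad_node(out, xs, function(g) {
    lapply(seq_along(xs), function(i) g[, starts[i]:ends[i], drop = FALSE])
  })
}

# Column slice of a matrix.
ad_cols <- function(x, from, to) {
  xv <- vv(x)
  dm <- dim(xv)
  out <- xv[, from:to, drop = FALSE]
  ad_node(out, list(x), function(g) {
    gx <- matrix(0, dm[1], dm[2])
    gx[, from:to] <- g
    list(gx)
  })
}

# Add a column vector (length d) to every column of a (d x N) matrix.
ad_add_col <- function(x, b) {
  xv <- vv(x); bv <- as.numeric(vv(b))
  ad_node(xv + bv, list(x, b), function(g) list(g, rowSums(g)))
}
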