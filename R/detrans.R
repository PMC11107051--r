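# Deformable transformer context encoder (DeTrans).
#
# The four pyramid levels are projected to a shared embedding, flattened to
# one token sequence with 3D sinusoidal positional encoding plus a learnable
# level embedding, and passed through N DeTrans layers. Each layer is a
# multi-scale deformable self-attention (MS-DMSA) step — every query attends
# to a small set of learned sampling points on every level, with attention
# weights softmaxed jointly over points and levels — followed by a
# feed-forward network, each with a residual connection and layer
# normalization. The output sequence is reshaped back to the per-level grids
# and projected to the original channel counts with a residual connection.

# 3D sinusoidal positional encoding for a (Z,Y,X) grid: d rows split across
# the three axes, sine/cosine pairs with transformer-style frequencies.
sinusoidal_pos3d <- function(d, dims) {
  Z <- dims[1]; Y <- dims[2]; X <- dims[3]
  N <- Z * Y * X
  m_yx <- d %/% 3
  m_z <- d - 2 * m_yx
  zc <- rep_len(seq_len(Z) - 1, N)
  yc <- rep_len(rep(seq_len(Y) - 1, each = Z), N)
  xc <- rep(seq_len(X) - 1, each = Z * Y)
  axis_block <- function(t, m) {
    if (m == 0) return(NULL)
    out <- matrix(0, m, N)
    for (r in seq_len(m)) {
      j <- (r - 1) %/% 2
      ang <- t / (10000^(2 * j / m))
      out[r, ] <- if ((r - 1) %% 2 == 0) sin(ang) else cos(ang)
    }
    out
  }
  rbind(axis_block(zc, m_z), axis_block(yc, m_yx), axis_block(xc, m_yx))
}

# Normalized (z,y,x) in [0,1] reference coordinates for every token of a
# level, columns in the same z-fastest order as the flattened grid.
reference_points <- function(dims) {
  Z <- dims[1]; Y <- dims[2]; X <- dims[3]
  N <- Z * Y * X
  nrm <- function(i, n) if (n > 1) i / (n - 1) else rep(0.5, length(i))
  rbind(nrm(rep_len(seq_len(Z) - 1, N), Z),
        nrm(rep_len(rep(seq_len(Y) - 1, each = Z), N), Y),
        nrm(rep(seq_len(X) - 1, each = Z * Y), X))
}

mod_detrans <- function(cfg) {
  dt <- cfg$detrans
  d <- dt$embed; H <- dt$heads; K <- dt$points; L <- 4L
  stopifnot(d %% H == 0)
  lch <- rev(cfg$channels)  # channels per level l=1 (lowest res) .. 4
  layers <- lapply(seq_len(dt$layers), function(i) {
    list(Wv = ad_param(init_linear_w(d, d)),
         bv = ad_param(numeric(d)),
         Woff = ad_param(matrix(0, 3 * K * L * H, d)),
         boff = ad_param(stats::rnorm(3 * K * L * H, sd = 0.2)),
         Ww = ad_param(matrix(0, K * L * H, d)),
         bw = ad_param(numeric(K * L * H)),
         Wo = ad_param(init_linear_w(d, d)),
         bo = ad_param(numeric(d)),
         ln1g = ad_param(rep(1, d)), ln1b = ad_param(numeric(d)),
         W1 = ad_param(init_linear_w(dt$ffn, d, sd = sqrt(2 / d))),
         b1 = ad_param(numeric(dt$ffn)),
         W2 = ad_param(init_linear_w(d, dt$ffn)),
         b2 = ad_param(numeric(d)),
         ln2g = ad_param(rep(1, d)), ln2b = ad_param(numeric(d)))
  })
  p <- list(in_proj = lapply(lch, function(C) mod_conv3d(C, d, c(1L, 1L, 1L))),
            out_proj = lapply(lch, function(C) mod_conv3d(d, C, c(1L, 1L, 1L))),
            level_embed = lapply(seq_len(L), function(l)
              ad_param(stats::rnorm(d, sd = 0.02))),
            layers = layers)
  m <- new_module(p, NULL, "detrans")
  m$opt$cache <- new.env(parent = emptyenv())
  m$fw <- function(levels) {
    dims_l <- lapply(levels, function(x) dim(vv(x))[-1])
    Ns <- vapply(dims_l, prod, numeric(1))
    N <- as.integer(sum(Ns))
    ends <- cumsum(Ns); starts <- ends - Ns + 1
    key <- paste(unlist(dims_l), collapse = "x")
    cache <- m$opt$cache
    if (is.null(cache[[key]])) {
      pos <- lapply(dims_l, function(dm) sinusoidal_pos3d(d, dm))
      ref <- do.call(cbind, lapply(dims_l, reference_points))  # 3 x N
      refexp <- aperm(array(ref, c(3, N, K, L, H)), c(1, 3, 4, 5, 2))
      base3L <- vapply(dims_l, function(dm) pmax(dm - 1, 0), numeric(3))
      scale <- aperm(array(base3L, c(3, L, K, H, N)), c(1, 3, 2, 4, 5))
      cache[[key]] <- list(pos = pos, refexp = refexp, scale = scale)
    }
    cc <- cache[[key]]
    toks <- lapply(1:4, function(l)
      ad_reshape(p$in_proj[[l]]$fw(levels[[l]]), c(d, Ns[l])))
    x <- ad_cbind(toks)
    pos_node <- ad_cbind(lapply(1:4, function(l)
      ad_add_col(cc$pos[[l]], p$level_embed[[l]])))
    for (ly in p$layers) {
      q <- ad_add(x, pos_node)
      if (isTRUE(m$opt$skip_attn)) {
        x <- ad_layernorm(x, ly$ln1g, ly$ln1b)
      } else {
        off <- ad_reshape(ad_linear(q, ly$Woff, ly$boff), c(3L, K, L, H, N))
        loc <- ad_mul(ad_add(off, cc$refexp), cc$scale)
        aw <- ad_reshape(ad_linear(q, ly$Ww, ly$bw), c(K * L, H * N))
        aw <- ad_reshape(ad_softmax_cols(aw), c(K, L, H, N))
        m$opt$last_attention <- vv(aw)
        v <- ad_linear(x, ly$Wv, ly$bv)
        vals <- lapply(1:4, function(l)
          ad_reshape(ad_cols(v, starts[l], ends[l]), c(d, dims_l[[l]])))
        att <- ad_msdmsa_sample(vals, loc, aw, H, N, K)
        x <- ad_layernorm(ad_add(x, ad_linear(att, ly$Wo, ly$bo)),
                          ly$ln1g, ly$ln1b)
      }
      ff <- ad_linear(ad_relu(ad_linear(x, ly$W1, ly$b1)), ly$W2, ly$b2)
      x <- ad_layernorm(ad_add(x, ff), ly$ln2g, ly$ln2b)
    }
    lapply(1:4, function(l) {
      tok <- ad_reshape(ad_cols(x, starts[l], ends[l]), c(d, dims_l[[l]]))
      ad_add(levels[[l]], p$out_proj[[l]]$fw(tok))
    })
  }
  m
}
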