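# Network building blocks: Conv-GN-PReLU, anisotropic convolution (AsBlock),
# squeeze-and-excitation residual (SE-Res), pyramid boundary-aware (PBA)
# blocks, and the U-Net domain discriminator.
#
# A module is a list(params = <nested named list of ad_param tensors /
# sub-modules>, fw = <forward closure>, opt = <mutable option environment>),
# class "hc_module". Parameters are initialized from the current R RNG
# stream, so building a network after set.seed() is fully reproducible.

new_module <- function(params, fw, type = "module") {
  structure(list(params = params, fw = fw, opt = new.env(parent = emptyenv()),
                 type = type),
            class = "hc_module")
}

is_module <- function(x) inherits(x, "hc_module")

# Flatten all parameter tensors of a module tree into a named list.
module_params <- function(m, prefix = "") {
  out <- list()
  walk <- function(x, pre) {
    if (is.environment(x)) {
      out[[pre]] <<- x
    } else if (is_module(x)) {
      walk(x$params, pre)
    } else if (is.list(x)) {
      nm <- names(x)
      for (i in seq_along(x)) {
        key <- if (!is.null(nm) && nzchar(nm[i])) nm[i] else as.character(i)
        walk(x[[i]], paste0(pre, if (nzchar(pre)) "." else "", key))
      }
    }
  }
  walk(m, prefix)
  out
}

#' Per-parameter size table for a module or network
#'
#' @param m a network or module object.
#' @return A data.frame with columns `name` (dotted parameter path) and `n`
#'   (number of scalar parameters).
#' @export
module_param_table <- function(m) {
  ps <- module_params(m)
  data.frame(name = names(ps),
             n = vapply(ps, function(p) length(p$v), numeric(1)),
             row.names = NULL)
}

#' Total number of trainable parameters
#' @param m a network or module object.
#' @return Integer count of scalar parameters.
#' @export
module_param_count <- function(m) sum(module_param_table(m)$n)

# ---- parameter initializers ---------------------------------------------

init_conv_w <- function(Cout, Cin, k) {
  K <- Cin * prod(k)
  matrix(stats::rnorm(Cout * K, sd = sqrt(2 / K)), Cout, K)
}

init_linear_w <- function(dout, din, sd = sqrt(1 / din)) {
  matrix(stats::rnorm(dout * din, sd = sd), dout, din)
}

# Largest divisor of C not exceeding the requested group count.
gn_group_count <- function(C, groups) {
  g <- min(groups, C)
  while (C %% g != 0) g <- g - 1
  g
}

# ---- elementary blocks ---------------------------------------------------

mod_conv3d <- function(Cin, Cout, k = c(3L, 3L, 3L), stride = c(1L, 1L, 1L)) {
  k <- as.integer(k); stride <- as.integer(stride)
  p <- list(W = ad_param(init_conv_w(Cout, Cin, k)),
            b = ad_param(numeric(Cout)))
  new_module(p, function(x) ad_conv3d(x, p$W, p$b, k, stride), "conv3d")
}

mod_conv_gn_prelu <- function(Cin, Cout, k = c(3L, 3L, 3L),
                              stride = c(1L, 1L, 1L), groups = 8L) {
  k <- as.integer(k); stride <- as.integer(stride)
  g <- gn_group_count(Cout, groups)
  p <- list(W = ad_param(init_conv_w(Cout, Cin, k)),
            b = ad_param(numeric(Cout)),
            gamma = ad_param(rep(1, Cout)),
            beta = ad_param(numeric(Cout)),
            slope = ad_param(0.25))
  new_module(p, function(x) {
    ad_prelu(ad_groupnorm(ad_conv3d(x, p$W, p$b, k, stride),
                          p$gamma, p$beta, g), p$slope)
  }, "conv_gn_prelu")
}

# Anisotropic convolution block: parallel in-plane (1x3x3) and through-plane
# (3x1x1) convolutions, concatenated with a 1x1x1-projected copy of the
# input, then projected back to Cout channels.
mod_as_block <- function(Cin, Cout, groups = 8L) {
  p <- list(plane = mod_conv_gn_prelu(Cin, Cout, c(1L, 3L, 3L), groups = groups),
            axial = mod_conv_gn_prelu(Cin, Cout, c(3L, 1L, 1L), groups = groups),
            proj_in = mod_conv3d(Cin, Cout, c(1L, 1L, 1L)),
            proj_out = mod_conv_gn_prelu(3L * Cout, Cout, c(1L, 1L, 1L),
                                         groups = groups))
  new_module(p, function(x) {
    p$proj_out$fw(ad_concat_ch(list(p$plane$fw(x), p$axial$fw(x),
                                    p$proj_in$fw(x))))
  }, "as_block")
}

# Squeeze-and-excitation residual block. The residual sum has no post-add
# activation, so with zeroed convolutions the block is an exact identity
# regardless of the gate.
mod_se_res <- function(Cin, Cout, stride = c(1L, 1L, 1L), reduction = 4L,
                       groups = 8L) {
  stride <- as.integer(stride)
  r <- gn_group_count(Cout, reduction)  # largest divisor <= reduction
  identity_skip <- Cin == Cout && all(stride == 1L)
  g2 <- gn_group_count(Cout, groups)
  p <- list(conv1 = mod_conv_gn_prelu(Cin, Cout, stride = stride, groups = groups),
            conv2 = mod_conv3d(Cout, Cout),
            gamma2 = ad_param(rep(1, Cout)),
            beta2 = ad_param(numeric(Cout)),
            fc1 = ad_param(init_linear_w(Cout %/% r, Cout, sd = sqrt(2 / Cout))),
            fb1 = ad_param(numeric(Cout %/% r)),
            fc2 = ad_param(init_linear_w(Cout, Cout %/% r)),
            fb2 = ad_param(numeric(Cout)))
  if (!identity_skip) p$skip <- mod_conv3d(Cin, Cout, c(1L, 1L, 1L), stride)
  m <- new_module(p, NULL, "se_res")
  m$fw <- function(x) {
    h <- ad_groupnorm(p$conv2$fw(p$conv1$fw(x)), p$gamma2, p$beta2, g2)
    gate <- m$opt$gate_override
    if (is.null(gate)) {
      s <- ad_global_mean(h)
      s <- ad_relu(ad_add(ad_matmul(p$fc1, ad_reshape(s, c(length(vv(s)), 1))),
                          ad_reshape(p$fb1, c(length(vv(p$fb1)), 1))))
      s <- ad_sigmoid(ad_add(ad_matmul(p$fc2, s),
                             ad_reshape(p$fb2, c(length(vv(p$fb2)), 1))))
      gate <- ad_reshape(s, length(vv(s)))
    }
    gated <- ad_scale_channels(h, gate)
    sk <- if (identity_skip) x else p$skip$fw(x)
    ad_add(gated, sk)
  }
  m
}

#' Pyramid boundary-aware branch responses
#'
#' For each pooling kernel `k` the feature grid is average-pooled with a
#' stride-1 "same" window, the pooled grid is subtracted from the original,
#' passed through a sigmoid, and used as a soft gate on the feature:
#' `sigmoid(F - avgpool_k(F)) * F`. These multi-granularity boundary
#' responses are what the PBA block concatenates and projects.
#'
#' @param x numeric array of shape (C, Z, Y, X).
#' @param kernels integer vector of odd pooling kernel edge lengths (>= 3).
#' @return List of arrays, one per kernel, each the same shape as `x`.
#' @export
pba_branches <- function(x, kernels) {
  stopifnot(all(kernels %% 2 == 1), all(kernels >= 3))
  lapply(kernels, function(k) {
    pk <- ad_avgpool_same(x, c(k, k, k))
    vv(ad_mul(ad_sigmoid(ad_sub(x, pk)), x))
  })
}

# PBA block module: branch responses concatenated over channels, then a
# 1x1x1 convolution restores the channel count.
mod_pba <- function(C, kernels, groups = 8L) {
  kernels <- as.integer(kernels)
  p <- list(proj = mod_conv3d(length(kernels) * C, C, c(1L, 1L, 1L)))
  new_module(p, function(x) {
    branches <- lapply(kernels, function(k) {
      pk <- ad_avgpool_same(x, c(k, k, k))
      ad_mul(ad_sigmoid(ad_sub(x, pk)), x)
    })
    p$proj$fw(ad_concat_ch(branches))
  }, "pba")
}

mod_upconv <- function(Cin, Cout, f) {
  f <- as.integer(f)
  p <- list(W = ad_param(init_conv_w(Cout * prod(f), Cin, c(1L, 1L, 1L))),
            b = ad_param(numeric(Cout * prod(f))))
  new_module(p, function(x) ad_upconv(x, p$W, p$b, f, Cout), "upconv")
}

# ---- U-Net domain discriminator -----------------------------------------

# Per-level domain discriminator: a 1x1x1 channel projection at feature
# resolution, trilinear upsampling to the patch grid, then a 3-level U-Net
# with leaky-ReLU activations and a linear (unbounded) 1-channel head, as
# required by least-squares adversarial targets of +/-1.
mod_discriminator <- function(Cin, base = c(16L, 32L, 64L)) {
  b1 <- base[1]; b2 <- base[2]; b3 <- base[3]
  p <- list(proj = mod_conv3d(Cin, b1, c(1L, 1L, 1L)),
            e1 = mod_conv3d(b1, b1),
            e2 = mod_conv3d(b1, b2),
            bott = mod_conv3d(b2, b3),
            up2 = mod_upconv(b3, b2, c(2L, 2L, 2L)),
            d2 = mod_conv3d(b2, b2),
            up1 = mod_upconv(b2, b1, c(2L, 2L, 2L)),
            d1 = mod_conv3d(b1, b1),
            head = mod_conv3d(b1, 1L, c(1L, 1L, 1L)))
  new_module(p, function(feat, patch_shape) {
    x <- ad_resize_trilinear(p$proj$fw(feat), patch_shape)
    e1 <- ad_lrelu(p$e1$fw(x))
    x <- ad_pool_down(e1, c(2L, 2L, 2L))
    e2 <- ad_lrelu(p$e2$fw(x))
    x <- ad_pool_down(e2, c(2L, 2L, 2L))
    x <- ad_lrelu(p$bott$fw(x))
    x <- ad_lrelu(p$d2$fw(ad_add(p$up2$fw(x), e2)))
    x <- ad_lrelu(p$d1$fw(ad_add(p$up1$fw(x), e1)))
    p$head$fw(x)
  }, "discriminator")
}
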