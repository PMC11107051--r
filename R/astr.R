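# AsTr: anisotropic CNN-transformer segmentation backbone.
#
# Encoder: Conv-GN-PReLU stem, two in-plane (1x2x2) average-pooling
# downsamplings interleaved with two stages of AsBlocks, then two stages of
# SE-Res blocks whose first block downsamples isotropically (2x2x2) by
# strided convolution. This yields a 4-level feature pyramid; level l = 1 is
# the lowest resolution. The pyramid is passed through the DeTrans context
# encoder and decoded with transpose convolutions, mirrored AsBlock/SE-Res
# stages and one pyramid boundary-aware (PBA) block per level. The head
# produces 2-channel voxel logits at full patch resolution; the four
# post-PBA feature grids are returned for domain alignment.

#' AsTr network configuration
#'
#' @param base_channels channel widths of the four encoder stages, highest
#'   resolution first.
#' @param width_mult multiplier applied to `base_channels` (and to the
#'   discriminator widths); lets the same architecture run at desk scale.
#' @param as_blocks number of AsBlocks in the two anisotropic encoder stages.
#' @param se_res number of SE-Res blocks in the two isotropic encoder stages.
#' @param detrans_layers,detrans_heads,detrans_points,detrans_embed,detrans_ffn
#'   DeTrans depth, attention heads, sampling points per head and level,
#'   token embedding width, and feed-forward width.
#' @param pba_kernels list of 4 integer vectors: average-pooling kernel edge
#'   lengths of the PBA block at levels 1..4 (lowest to highest resolution).
#' @param down list of 4 per-stage downsampling factors (z,y,x); the first
#'   two are in-plane only to respect anisotropic voxel spacing.
#' @param gn_groups requested group-normalization group count (reduced to a
#'   divisor of the channel count where needed).
#' @param use_pba logical; `FALSE` disables the PBA blocks (ablation), in
#'   which case the returned alignment features are the pre-PBA features.
#' @param num_classes number of output classes (2: background, tumor).
#' @param disc_channels U-Net domain-discriminator channel widths.
#' @return An object of class `astr_config`.
#' @export
network_config <- function(base_channels = c(16, 32, 64, 128),
                           width_mult = 1,
                           as_blocks = c(2L, 3L),
                           se_res = c(3L, 2L),
                           detrans_layers = 4L,
                           detrans_heads = 6L,
                           detrans_points = 4L,
                           detrans_embed = 126L,
                           detrans_ffn = 2L * detrans_embed,
                           pba_kernels = list(c(3L, 5L), c(3L, 5L),
                                              c(5L, 7L), c(5L, 7L)),
                           down = list(c(1L, 2L, 2L), c(1L, 2L, 2L),
                                       c(2L, 2L, 2L), c(2L, 2L, 2L)),
                           gn_groups = 8L,
                           use_pba = TRUE,
                           num_classes = 2L,
                           disc_channels = c(16, 32, 64)) {
  stopifnot(length(base_channels) == 4, length(pba_kernels) == 4,
            length(down) == 4, detrans_embed %% detrans_heads == 0)
  ch <- pmax(2L, as.integer(round(base_channels * width_mult)))
  dc <- pmax(2L, as.integer(round(disc_channels * width_mult)))
  structure(list(channels = ch, as_blocks = as.integer(as_blocks),
                 se_res = as.integer(se_res),
                 detrans = list(layers = as.integer(detrans_layers),
                                heads = as.integer(detrans_heads),
                                points = as.integer(detrans_points),
                                embed = as.integer(detrans_embed),
                                ffn = as.integer(detrans_ffn)),
                 pba_kernels = lapply(pba_kernels, as.integer),
                 down = lapply(down, as.integer),
                 gn_groups = as.integer(gn_groups),
                 use_pba = isTRUE(use_pba),
                 num_classes = as.integer(num_classes),
                 disc_channels = dc),
            class = "astr_config")
}

#' Desk-scale network configuration
#'
#' A reduced-width profile of the same architecture that trains in minutes
#' on one CPU core: quarter channel widths and a small DeTrans (2 layers,
#' 2 heads, 2 sampling points, 32-dim embedding).
#'
#' @param ... overrides passed on to [network_config()].
#' @return An `astr_config` object.
#' @export
desk_network_config <- function(...) {
  args <- list(width_mult = 0.25, detrans_layers = 2L, detrans_heads = 2L,
               detrans_points = 2L, detrans_embed = 32L, detrans_ffn = 64L)
  override <- list(...)
  args[names(override)] <- override
  do.call(network_config, args)
}

mod_encoder <- function(cfg) {
  ch <- cfg$channels; g <- cfg$gn_groups
  stage_blocks <- function(n, Cin, Cout, maker, stride1 = NULL) {
    lapply(seq_len(n), function(i) {
      if (i == 1) {
        if (is.null(stride1)) maker(Cin, Cout) else maker(Cin, Cout, stride1)
      } else maker(Cout, Cout)
    })
  }
  p <- list(
    stem = mod_conv_gn_prelu(1L, ch[1], groups = g),
    stage1 = stage_blocks(cfg$as_blocks[1], ch[1], ch[1],
                          function(a, b) mod_as_block(a, b, g)),
    stage2 = stage_blocks(cfg$as_blocks[2], ch[1], ch[2],
                          function(a, b) mod_as_block(a, b, g)),
    stage3 = stage_blocks(cfg$se_res[1], ch[2], ch[3],
                          function(a, b, s = c(1L, 1L, 1L))
                            mod_se_res(a, b, s, groups = g),
                          stride1 = cfg$down[[3]]),
    stage4 = stage_blocks(cfg$se_res[2], ch[3], ch[4],
                          function(a, b, s = c(1L, 1L, 1L))
                            mod_se_res(a, b, s, groups = g),
                          stride1 = cfg$down[[4]]))
  run <- function(blocks, x) { for (b in blocks) x <- b$fw(x); x }
  new_module(p, function(x) {
    x <- p$stem$fw(x)
    x <- ad_pool_down(x, cfg$down[[1]])
    l4 <- run(p$stage1, x)
    l3 <- run(p$stage2, ad_pool_down(l4, cfg$down[[2]]))
    l2 <- run(p$stage3, l3)
    l1 <- run(p$stage4, l2)
    list(l1, l2, l3, l4)  # level 1 = lowest resolution
  }, "encoder")
}

mod_decoder <- function(cfg) {
  ch <- cfg$channels; g <- cfg$gn_groups
  p <- list(
    se1 = mod_se_res(ch[4], ch[4], groups = g),
    pba1 = mod_pba(ch[4], cfg$pba_kernels[[1]], g),
    up1 = mod_upconv(ch[4], ch[3], cfg$down[[4]]),
    se2 = mod_se_res(ch[3], ch[3], groups = g),
    pba2 = mod_pba(ch[3], cfg$pba_kernels[[2]], g),
    up2 = mod_upconv(ch[3], ch[2], cfg$down[[3]]),
    as3 = mod_as_block(ch[2], ch[2], g),
    pba3 = mod_pba(ch[2], cfg$pba_kernels[[3]], g),
    up3 = mod_upconv(ch[2], ch[1], cfg$down[[2]]),
    as4 = mod_as_block(ch[1], ch[1], g),
    pba4 = mod_pba(ch[1], cfg$pba_kernels[[4]], g),
    up4 = mod_upconv(ch[1], ch[1], cfg$down[[1]]),
    head = mod_conv_gn_prelu(ch[1], ch[1], groups = g),
    classifier = mod_conv3d(ch[1], cfg$num_classes, c(1L, 1L, 1L)))
  new_module(p, function(pyr, skip) {
    feats <- vector("list", 4L)
    blockset <- list(list(p$se1, p$pba1, p$up1), list(p$se2, p$pba2, p$up2),
                     list(p$as3, p$pba3, p$up3), list(p$as4, p$pba4, p$up4))
    x <- NULL
    for (l in 1:4) {
      inp <- ad_add(pyr[[l]], skip[[l]])
      x <- if (l == 1) inp else ad_add(x, inp)
      x <- blockset[[l]][[1]]$fw(x)
      if (cfg$use_pba) x <- blockset[[l]][[2]]$fw(x)
      feats[[l]] <- x
      x <- blockset[[l]][[3]]$fw(x)
    }
    logits <- p$classifier$fw(p$head$fw(x))
    list(logits = logits, pba_feats = feats)
  }, "decoder")
}

#' Build an AsTr segmentation network
#'
#' Parameters are drawn from the current R random-number stream, so calling
#' `set.seed()` beforehand makes network construction reproducible.
#'
#' @param cfg an [network_config()] object.
#' @return An object of class `astr_network`.
#' @export
astr_network <- function(cfg = network_config()) {
  stopifnot(inherits(cfg, "astr_config"))
  p <- list(enc = mod_encoder(cfg), det = mod_detrans(cfg),
            dec = mod_decoder(cfg))
  m <- new_module(p, NULL, "astr")
  m$cfg <- cfg
  m$fw <- function(x) {
    levels <- p$enc$fw(x)
    pyr <- p$det$fw(levels)
    p$dec$fw(pyr, levels)
  }
  class(m) <- c("astr_network", class(m))
  m
}

# Total downsampling factor of the pyramid per axis.
total_downsample <- function(cfg) {
  Reduce(`*`, cfg$down)
}

check_patch_shape <- function(cfg, shape) {
  td <- total_downsample(cfg)
  if (any(shape %% td != 0))
    stop("patch shape (", paste(shape, collapse = "x"),
         ") must be divisible by the cumulative downsampling factors (",
         paste(td, collapse = "x"), ")")
  invisible(TRUE)
}

# Coerce a (Z,Y,X) patch array to the (1,Z,Y,X) tensor layout.
as_input_tensor <- function(patch) {
  if (length(dim(patch)) == 3) dim(patch) <- c(1L, dim(patch))
  patch
}

#' Run the AsTr network on a patch
#'
#' @param net an [astr_network()] object.
#' @param patch numeric array of shape (Z,Y,X) or (1,Z,Y,X); dimensions must
#'   be divisible by the cumulative downsampling factors (4, 16, 16 by
#'   default).
#' @return A list with `logits` (num_classes, Z, Y, X) and `pba_feats`
#'   (list of 4 feature arrays, level 1 = lowest resolution). In evaluation
#'   mode (outside training) the forward pass is deterministic.
#' @export
astr_forward <- function(net, patch) {
  x <- as_input_tensor(patch)
  check_patch_shape(net$cfg, dim(x)[-1])
  out <- net$fw(x)
  if (!ad_recording())
    out <- list(logits = vv(out$logits), pba_feats = lapply(out$pba_feats, vv))
  out
}

#' Encode a patch into the 4-level feature pyramid
#'
#' @inheritParams astr_forward
#' @return List of 4 feature arrays, level 1 = lowest resolution.
#' @export
astr_encode <- function(net, patch) {
  x <- as_input_tensor(patch)
  check_patch_shape(net$cfg, dim(x)[-1])
  out <- net$params$enc$fw(x)
  if (!ad_recording()) out <- lapply(out, vv)
  out
}

#' Per-layer parameter summary of a network
#'
#' @param net a network or module object.
#' @return A data.frame of per-parameter sizes with attribute `total`;
#'   printed totals match `module_param_count()`.
#' @export
network_summary <- function(net) {
  tab <- module_param_table(net)
  attr(tab, "total") <- sum(tab$n)
  tab
}
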