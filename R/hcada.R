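# Hierarchical class-aware domain alignment (HCADA): the voxel-wise class
# attention map, one independent U-Net domain discriminator per pyramid
# level, and the CADA combination of the two.

#' Voxel-wise class attention map
#'
#' Softmax of the segmentation logits over the class channel at every
#' spatial position. The resulting per-voxel class probabilities weight the
#' adversarial alignment toward voxels with class evidence.
#'
#' @param logits numeric array (num_classes, Z, Y, X).
#' @return Array of the same shape; channel values sum to 1 at every voxel.
#' @export
class_attention <- function(logits) {
  logits <- vv(logits)
  stopifnot(length(dim(logits)) == 4)
  mx <- apply(logits, 2:4, max)
  e <- exp(sweep(logits, 2:4, mx, "-"))
  sweep(e, 2:4, apply(e, 2:4, sum), "/")
}

#' Build the per-level domain discriminators
#'
#' One independent 3-level U-Net discriminator per pyramid level (no shared
#' parameters). Each takes the post-PBA feature grid of its level, projects
#' the channels, upsamples to patch resolution by trilinear interpolation
#' and emits an unbounded per-voxel domain score map suitable for
#' least-squares adversarial targets of +1 (source) and -1 (target).
#'
#' @param cfg an [network_config()] object (feature channel counts and
#'   discriminator widths are read from it).
#' @return List of 4 discriminator modules, level 1 = lowest resolution.
#' @export
domain_discriminators <- function(cfg) {
  lch <- rev(cfg$channels)
  lapply(1:4, function(l) mod_discriminator(lch[l], cfg$disc_channels))
}

#' Apply a level's domain discriminator
#'
#' @param discs list from [domain_discriminators()].
#' @param level pyramid level in 1..4.
#' @param feat feature array (C, z, y, x) for that level.
#' @param patch_shape integer (Z, Y, X) of the full-resolution patch.
#' @return Domain score map of shape (1, Z, Y, X) (plain array outside
#'   training).
#' @export
discriminate <- function(discs, level, feat, patch_shape) {
  if (!(level %in% seq_along(discs))) stop("unknown discriminator level: ", level)
  out <- discs[[level]]$fw(feat, as.integer(patch_shape))
  if (!ad_recording()) vv(out) else out
}

#' Class-aware domain probability map
#'
#' Element-wise product of a discriminator score map with the tumor-channel
#' class attention, focusing alignment pressure on voxels with tumor
#' evidence.
#'
#' @param dmap domain score map, shape (Z,Y,X) or (1,Z,Y,X).
#' @param att tumor-class attention, same spatial shape (a full attention
#'   array (2,Z,Y,X) is accepted; its tumor channel is used).
#' @return Array of the same spatial shape as `dmap`.
#' @export
cada_map <- function(dmap, att) {
  dmap <- drop_lead(vv(dmap))
  att <- vv(att)
  if (length(dim(att)) == 4) att <- tumor_channel(att)
  att <- drop_lead(att)
  if (!identical(dim(dmap), dim(att)))
    stop("shape mismatch between domain map and attention map")
  dmap * att
}

tumor_channel <- function(att) {
  dm <- dim(att)
  out <- att[dm[1], , , , drop = FALSE]
  dim(out) <- dm[-1]
  out
}

drop_lead <- function(x) {
  dm <- dim(x)
  if (length(dm) == 4 && dm[1] == 1) dim(x) <- dm[-1]
  x
}
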