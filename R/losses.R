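# Training objectives: Dice + binary cross-entropy segmentation loss,
# least-squares adversarial discrimination/adaptation losses, and their
# hierarchical (per-level weighted) sums.
#
# The user-facing functions operate on plain arrays and return numbers; the
# ad_* counterparts build the same quantities on the autodiff tape and are
# used by the trainers.

#' Soft Dice loss
#'
#' `1 - 2*sum(p*g) / (sum(p^2) + sum(g^2))` over all voxels. When both
#' prediction and ground truth are entirely empty the loss is defined as 0.
#'
#' @param p predicted tumor probabilities in `[0,1]`.
#' @param g binary ground-truth mask, same shape.
#' @return A single number in `[0, 1]`.
#' @export
dice_loss <- function(p, g) {
  p <- as.numeric(vv(p)); g <- as.numeric(vv(g))
  stopifnot(length(p) == length(g))
  den <- sum(p * p) + sum(g * g)
  if (den == 0) return(0)
  1 - 2 * sum(p * g) / den
}

#' Binary cross-entropy loss
#'
#' Standard negative-log binary cross-entropy, averaged over voxels, with
#' probabilities clamped to `[eps, 1-eps]`.
#'
#' @inheritParams dice_loss
#' @param eps clamping constant.
#' @return A single nonnegative number.
#' @export
bce_loss <- function(p, g, eps = 1e-7) {
  p <- pmin(pmax(as.numeric(vv(p)), eps), 1 - eps)
  g <- as.numeric(vv(g))
  -mean(g * log(p) + (1 - g) * log(1 - p))
}

#' Segmentation loss: Dice + BCE
#' @inheritParams dice_loss
#' @return `dice_loss(p, g) + bce_loss(p, g)`.
#' @export
seg_loss <- function(p, g) dice_loss(p, g) + bce_loss(p, g)

#' Single-level least-squares discrimination loss
#'
#' Mean squared distance of the source score map to +1 plus mean squared
#' distance of the target score map to -1.
#'
#' @param d_src,d_tgt discriminator score maps (any shape).
#' @return A single nonnegative number.
#' @export
dis_loss_level <- function(d_src, d_tgt) {
  mean((as.numeric(vv(d_src)) - 1)^2) + mean((as.numeric(vv(d_tgt)) + 1)^2)
}

#' Single-level class-aware adversarial adaptation loss
#'
#' Mean over voxels of `att * (d_tgt - 1)^2`: drives target-domain features
#' toward the discriminator's source label, weighted by tumor-class
#' attention.
#'
#' @param d_tgt discriminator score map on target features.
#' @param att tumor-class attention map, same number of voxels.
#' @return A single nonnegative number.
#' @export
da_loss_level <- function(d_tgt, att) {
  d <- as.numeric(vv(d_tgt)); a <- as.numeric(vv(att))
  stopifnot(length(d) == length(a))
  mean(a * (d - 1)^2)
}

#' Hierarchical (per-level weighted) loss
#'
#' `sum_l lambda[l] * losses[l]`. The default weights halve with every
#' resolution halving, level 1 (lowest resolution) getting the smallest.
#'
#' @param losses numeric vector of 4 per-level losses (level 1 first).
#' @param lambda numeric vector of 4 weights.
#' @return A single number.
#' @export
hierarchical_loss <- function(losses, lambda = c(1 / 8, 1 / 4, 1 / 2, 1)) {
  stopifnot(length(losses) == length(lambda))
  sum(lambda * losses)
}

# ---- autodiff versions ---------------------------------------------------

# Tumor probability from 2-channel logits: softmax over 2 classes reduces to
# a sigmoid of the logit difference.
ad_tumor_prob <- function(logits) {
  ad_sigmoid(ad_sub(ad_channel(logits, 2L), ad_channel(logits, 1L)))
}

ad_dice_loss <- function(p, g) {
  gv <- vv(g)
  num <- ad_scale(ad_sum(ad_mul(p, gv)), 2)
  den <- ad_add(ad_sum(ad_square(p)), sum(gv * gv))
  ad_sub(1, ad_div(num, den))
}

ad_bce_loss <- function(p, g, eps = 1e-7) {
  gv <- vv(g)
  pc <- ad_clamp(p, eps, 1 - eps)
  ll <- ad_add(ad_mul(ad_log(pc), gv), ad_mul(ad_log(ad_sub(1, pc)), 1 - gv))
  ad_scale(ad_sum(ll), -1 / length(gv))
}

ad_seg_loss <- function(logits, g) {
  p <- ad_tumor_prob(logits)
  ad_add(ad_dice_loss(p, g), ad_bce_loss(p, g))
}

ad_dis_loss_level <- function(d_src, d_tgt) {
  ad_add(ad_mean(ad_square(ad_sub(d_src, 1))),
         ad_mean(ad_square(ad_add(d_tgt, 1))))
}

ad_da_loss_level <- function(d_tgt, att) {
  ad_mean(ad_mul(ad_square(ad_sub(d_tgt, 1)), att))
}
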