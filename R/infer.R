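# Full-volume inference: sliding-window patch prediction with overlap
# averaging of logits, followed by argmax to a binary mask.

window_starts <- function(size, patch, stride) {
  if (size <= patch) return(0L)
  s <- seq(0L, size - patch, by = stride)
  if (s[length(s)] != size - patch) s <- c(s, size - patch)
  as.integer(s)
}

# fwfun(patch_zyx_array) -> logits (C, dz, dy, dx)
sliding_window_logits <- function(fwfun, volarr, patch_shape, overlap = 0.5) {
  dm <- dim(volarr)
  pad <- pmax(patch_shape - dm, 0)
  if (any(pad > 0)) {
    padded <- array(0, pmax(dm, patch_shape))
    padded[seq_len(dm[1]), seq_len(dm[2]), seq_len(dm[3])] <- volarr
    volarr <- padded
  }
  vdm <- dim(volarr)
  stride <- pmax(1L, as.integer(round(patch_shape * (1 - overlap))))
  acc <- NULL
  cnt <- array(0, vdm)
  for (z0 in window_starts(vdm[1], patch_shape[1], stride[1]))
    for (y0 in window_starts(vdm[2], patch_shape[2], stride[2]))
      for (x0 in window_starts(vdm[3], patch_shape[3], stride[3])) {
        zi <- z0 + seq_len(patch_shape[1])
        yi <- y0 + seq_len(patch_shape[2])
        xi <- x0 + seq_len(patch_shape[3])
        lg <- fwfun(volarr[zi, yi, xi, drop = FALSE])
        if (is.null(acc)) acc <- array(0, c(dim(lg)[1], vdm))
        acc[, zi, yi, xi] <- acc[, zi, yi, xi] + lg
        cnt[zi, yi, xi] <- cnt[zi, yi, xi] + 1
      }
  acc <- sweep(acc, 2:4, cnt, "/")
  acc[, seq_len(dm[1]), seq_len(dm[2]), seq_len(dm[3]), drop = FALSE]
}

logits_to_mask <- function(logits, spacing) {
  pred <- logits[2, , , ] > logits[1, , , ]
  seg_mask(array(as.integer(pred), dim(logits)[-1]), spacing)
}

#' Evaluate a checkpoint on labeled cases
#'
#' Each case is resampled to the checkpoint's target spacing, normalized
#' with the checkpoint's cohort statistics, segmented by sliding-window
#' inference (50% overlap, logit averaging, argmax), and scored against the
#' identically resampled ground truth.
#'
#' @param ckpt an `hcadan_checkpoint`.
#' @param data list of labeled cases `list(volume, mask)`.
#' @param predict_fn optional override: a function mapping a (Z,Y,X) patch
#'   array to a (2,Z,Y,X) logits array (used for oracle/baseline probes).
#' @param patch_shape inference window shape; defaults to the training patch
#'   shape. A window covering the whole volume gives single-pass inference
#'   (the network is fully convolutional).
#' @param ids optional case identifiers.
#' @return A [metrics_report()] data.frame; predictions are attached as
#'   attribute `"predictions"`. Cases with an empty prediction or ground
#'   truth have `NA` surface metrics and `distance_defined = FALSE`.
#' @export
evaluate_checkpoint <- function(ckpt, data, predict_fn = NULL,
                                patch_shape = NULL, ids = NULL) {
  stopifnot(inherits(ckpt, "hcadan_checkpoint"))
  cfg <- ckpt$cfg
  if (is.null(patch_shape)) patch_shape <- cfg$preprocess$patch_shape
  check_patch_shape(cfg$network, patch_shape)
  prep <- prepare_cases(data, cfg, stats = ckpt$stats)
  if (is.null(predict_fn)) {
    net <- restore_network(ckpt)
    predict_fn <- function(patch) vv(net$fw(as_input_tensor(patch))$logits)
  }
  sp <- cfg$preprocess$target_spacing
  preds <- lapply(prep$cases, function(cs) {
    lg <- sliding_window_logits(predict_fn, cs$volume$data, patch_shape)
    logits_to_mask(lg, sp)
  })
  gts <- lapply(prep$cases, `[[`, "mask")
  rep <- metrics_report(preds, gts, sp, ids = ids)
  attr(rep, "predictions") <- preds
  rep
}
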