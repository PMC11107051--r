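# Supervised and adversarial (HCA-DAN) training.
#
# Supervised training minimizes the Dice+BCE segmentation loss over
# augmented tumor-centered patches with SGD (momentum 0.99, polynomial
# learning-rate decay). Adversarial adaptation alternates, per iteration,
# a segmentor step minimizing L_seg + w_da * L_da^h (the class-attention-
# gated least-squares adaptation loss summed over active pyramid levels)
# and a discriminator step minimizing L_dis^h on the same features.

#' Training configuration
#'
#' Defaults follow the full-scale training recipe: SGD with momentum 0.99,
#' initial learning rate 1e-3, batch size 2, 500 epochs of 250 iterations.
#' All values can be overridden; [desk_train_config()] gives a profile that
#' runs in minutes on one CPU.
#'
#' @param network an [network_config()].
#' @param preprocess a [preprocess_config()].
#' @param lr,momentum segmentor SGD settings.
#' @param batch_size patches per segmentor step (per domain, for
#'   adaptation).
#' @param epochs,iters_per_epoch,iterations training length; `iterations`
#'   defaults to `epochs * iters_per_epoch` and takes precedence when given.
#' @param seed RNG seed fixed before any sampling or initialization.
#' @param align_mode `"hcada"` (all 4 levels, class-aware), `"m1"` (only the
#'   highest-resolution CADA block), `"m2"` (class-agnostic: attention
#'   replaced by 1), or `"off"` (no alignment; supervised on source only).
#' @param lambda per-level weights of the hierarchical losses, level 1
#'   (lowest resolution) first; halves with each resolution halving.
#' @param w_da adversarial weight on the segmentor.
#' @param disc_lr discriminator SGD learning rate.
#' @param augment logical; apply online augmentation to training patches.
#' @param lr_poly polynomial decay exponent (`lr * (1 - t/T)^lr_poly`).
#' @param fg_patch_prob probability of drawing a tumor-centered patch (the
#'   remainder are uniform-random patches, so background-only windows are
#'   seen in training).
#' @param grad_clip global gradient-norm clip applied before each update
#'   (`Inf` disables); guards the segmentor against occasional large
#'   adversarial gradients.
#' @param da_ramp logical; ramp the adversarial weight from 0 to `w_da`
#'   over training with the standard domain-adversarial schedule
#'   `2/(1+exp(-10 p)) - 1` (p = training progress), so alignment pressure
#'   arrives only once the segmenter has stabilized. Without it the
#'   adversarial term can collapse the (small) tumor class early in short
#'   schedules.
#' @return An object of class `train_config`.
#' @export
train_config <- function(network = network_config(),
                         preprocess = preprocess_config(),
                         lr = 1e-3, momentum = 0.99, batch_size = 2L,
                         epochs = 500L, iters_per_epoch = 250L,
                         iterations = NULL, seed = 1L,
                         align_mode = c("hcada", "m1", "m2", "off"),
                         lambda = c(1 / 8, 1 / 4, 1 / 2, 1),
                         w_da = 0.01, disc_lr = 1e-4,
                         augment = TRUE, lr_poly = 0.9,
                         fg_patch_prob = 0.5, grad_clip = 12,
                         da_ramp = TRUE) {
  align_mode <- match.arg(align_mode)
  if (is.null(iterations)) iterations <- epochs * iters_per_epoch
  stopifnot(lr > 0, batch_size >= 1, iterations >= 0, length(lambda) == 4)
  structure(list(network = network, preprocess = preprocess, lr = lr,
                 momentum = momentum, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 iters_per_epoch = as.integer(iters_per_epoch),
                 iterations = as.integer(iterations), seed = as.integer(seed),
                 align_mode = align_mode, lambda = lambda, w_da = w_da,
                 disc_lr = disc_lr, augment = isTRUE(augment),
                 lr_poly = lr_poly, fg_patch_prob = fg_patch_prob,
                 grad_clip = grad_clip, da_ramp = isTRUE(da_ramp)),
            class = "train_config")
}

#' Desk-scale training configuration
#'
#' Quarter-width network, 16 x 32 x 32 patches, batch 1, 60 iterations:
#' small enough to train on one CPU core in about a minute while exercising
#' every component. The optimizer is rescaled for this regime — lr 0.01 with
#' momentum 0.9 keeps the effective step of the full-scale recipe
#' (lr/(1-momentum) = 0.1) but converges reliably within short schedules,
#' where momentum 0.99 is unstable; the discriminator rate is scaled
#' accordingly.
#'
#' @param iterations,... overrides passed to [train_config()].
#' @return A `train_config`.
#' @export
desk_train_config <- function(iterations = 60L, ...) {
  args <- list(network = desk_network_config(),
               preprocess = preprocess_config(patch_shape = c(16L, 32L, 32L)),
               batch_size = 1L, iterations = iterations,
               lr = 0.01, momentum = 0.9, disc_lr = 1e-3)
  override <- list(...)
  args[names(override)] <- override
  do.call(train_config, args)
}

# Global gradient-norm clipping across a parameter set.
clip_gradients <- function(params, max_norm) {
  if (!is.finite(max_norm)) return(invisible(NULL))
  total <- sqrt(sum(vapply(params, function(p)
    if (is.null(p$g)) 0 else sum(p$g * p$g), numeric(1))))
  if (total > max_norm) {
    sc <- max_norm / total
    for (p in params) if (!is.null(p$g)) p$g <- p$g * sc
  }
  invisible(NULL)
}

# SGD with classical momentum.
sgd_update <- function(params, lr, momentum) {
  for (p in params) {
    if (is.null(p$g)) next
    if (is.null(p$vel)) p$vel <- 0 * p$g
    p$vel <- momentum * p$vel - lr * p$g
    p$v <- p$v + p$vel
  }
  invisible(NULL)
}

poly_lr <- function(lr0, it, total, power) {
  if (total <= 1) return(lr0)
  lr0 * (1 - (it - 1) / total)^power
}

# Resample cases to the target grid and normalize with cohort statistics
# computed on the labeled volumes (or with the supplied `stats`).
prepare_cases <- function(cases, cfg, stats = NULL) {
  pp <- cfg$preprocess
  res <- lapply(cases, function(cs) {
    v <- resample(cs$volume, pp$target_spacing, pp$interp_order_image)
    m <- if (!is.null(cs$mask))
      resample(cs$mask, pp$target_spacing, pp$interp_order_mask)
    list(volume = v, mask = m)
  })
  if (is.null(stats)) {
    labeled <- Filter(function(cs) !is.null(cs$mask), res)
    if (length(labeled) == 0) stop("no labeled cases to compute statistics")
    stats <- cohort_norm_stats(lapply(labeled, `[[`, "volume"),
                               lapply(labeled, `[[`, "mask"),
                               pp$clip_low_pct, pp$clip_high_pct)
  }
  list(cases = lapply(res, function(cs)
    list(volume = apply_norm_stats(cs$volume, stats),
         mask = cache_centroid(cs$mask))),
    stats = stats)
}

# Draw one augmented labeled patch: tumor-centered with probability
# cfg$fg_patch_prob, else uniform-random, so that inference also behaves on
# background-only windows.
sample_labeled_patch <- function(prep_cases, cfg) {
  cs <- prep_cases[[sample.int(length(prep_cases), 1)]]
  pt <- if (stats::runif(1) < cfg$fg_patch_prob) {
    extract_patch(cs$volume, cs$mask, cfg$preprocess, draw_seed())
  } else {
    sd <- draw_seed()
    shape <- cfg$preprocess$patch_shape
    v <- extract_patch_random(cs$volume, shape, sd)
    dm <- dim(cs$volume$data)
    start <- with_seed(sd, vapply(pmax(dm - shape, 0), function(r)
      if (r > 0) sample(0:r, 1) else 0L, numeric(1)))
    mk <- crop_with_pad(mask_array(cs$mask), start, shape)
    list(volume = v, mask = seg_mask(array(as.integer(mk), shape),
                                     cs$volume$spacing))
  }
  if (cfg$augment)
    pt <- augment(pt$volume, pt$mask, cfg$preprocess, draw_seed())
  list(x = as_input_tensor(pt$volume$data), g = mask_array(pt$mask))
}

sample_unlabeled_patch <- function(prep_cases, cfg) {
  cs <- prep_cases[[sample.int(length(prep_cases), 1)]]
  v <- extract_patch_random(cs$volume, cfg$preprocess$patch_shape, draw_seed())
  as_input_tensor(v$data)
}

new_checkpoint <- function(net, cfg, stats, losses, discs = NULL) {
  structure(list(values = lapply(module_params(net), vv),
                 disc_values = if (!is.null(discs))
                   lapply(discs, function(d) lapply(module_params(d), vv)),
                 cfg = cfg, stats = stats, losses = losses),
            class = "hcadan_checkpoint")
}

#' Save / load a training checkpoint
#'
#' Checkpoints store the network weights, the full configuration (including
#' the seed) and the cohort normalization statistics.
#'
#' @param ckpt an `hcadan_checkpoint`.
#' @param path file path.
#' @return `load_checkpoint()` returns the checkpoint object.
#' @export
save_checkpoint <- function(ckpt, path) {
  stopifnot(inherits(ckpt, "hcadan_checkpoint"))
  saveRDS(ckpt, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  ckpt <- readRDS(path)
  stopifnot(inherits(ckpt, "hcadan_checkpoint"))
  ckpt
}

# Rebuild the network of a checkpoint and load its weights.
restore_network <- function(ckpt) {
  net <- astr_network(ckpt$cfg$network)
  ps <- module_params(net)
  stopifnot(identical(sort(names(ps)), sort(names(ckpt$values))))
  for (nm in names(ps)) ps[[nm]]$v <- ckpt$values[[nm]]
  net
}

check_loss_finite <- function(value, it, what = "loss") {
  if (!is.finite(value))
    stop("non-finite ", what, " (", value, ") at iteration ", it,
         "; try a lower learning rate", call. = FALSE)
}

#' Supervised training of the AsTr segmentor
#'
#' Minimizes the Dice+BCE segmentation loss over seeded augmented
#' tumor-centered patches. Fully deterministic for a given seed, data and
#' configuration.
#'
#' @param cfg a [train_config()].
#' @param data list of labeled cases `list(volume, mask)`.
#' @param verbose print the running loss every 25 iterations.
#' @return An `hcadan_checkpoint` with a `losses` data.frame attached.
#' @export
train_supervised <- function(cfg, data, verbose = FALSE) {
  stopifnot(inherits(cfg, "train_config"), length(data) >= 1)
  set.seed(cfg$seed)
  prep <- prepare_cases(data, cfg)
  net <- astr_network(cfg$network)
  check_patch_shape(cfg$network, cfg$preprocess$patch_shape)
  params <- module_params(net)
  losses <- numeric(cfg$iterations)
  for (it in seq_len(cfg$iterations)) {
    lr_t <- poly_lr(cfg$lr, it, cfg$iterations, cfg$lr_poly)
    ad_start()
    total <- NULL
    for (b in seq_len(cfg$batch_size)) {
      pt <- sample_labeled_patch(prep$cases, cfg)
      out <- net$fw(pt$x)
      li <- ad_seg_loss(out$logits, pt$g)
      total <- if (is.null(total)) li else ad_add(total, li)
    }
    total <- ad_scale(total, 1 / cfg$batch_size)
    losses[it] <- vv(total)
    check_loss_finite(losses[it], it, "segmentation loss")
    ad_backward(total)
    clip_gradients(params, cfg$grad_clip)
    sgd_update(params, lr_t, cfg$momentum)
    ad_zero_grad(params)
    ad_stop()
    if (verbose && it %% 25 == 0)
      message(sprintf("iter %4d  L_seg %.4f", it, losses[it]))
  }
  ck <- new_checkpoint(net, cfg, prep$stats,
                       data.frame(iter = seq_len(cfg$iterations),
                                  L_seg = losses))
  ck
}

#' Strip masks from a case list (unlabeled target-domain loader)
#'
#' The adaptation trainer only ever accepts target data in this mask-free
#' form; supplying masks is rejected as a contract violation.
#'
#' @param cases list of cases (`list(volume, mask)` or `volume3d`).
#' @return List of `list(volume)` entries.
#' @export
unlabeled_set <- function(cases) {
  lapply(cases, function(cs) {
    v <- if (inherits(cs, "volume3d")) cs else cs$volume
    list(volume = v)
  })
}

check_unlabeled <- function(target) {
  for (cs in target) {
    bad <- (is.list(cs) && !inherits(cs, "volume3d") && !is.null(cs$mask))
    if (bad)
      stop("target-domain cases must not carry masks during adaptation; ",
           "strip them with unlabeled_set()", call. = FALSE)
  }
  invisible(TRUE)
}

# One discriminator update on fixed (plain-array) feature sets; returns the
# hierarchical discrimination loss before the update.
disc_step <- function(discs, fs, ft, cfg, levels, patch_shape, lr) {
  dparams <- unlist(lapply(discs, module_params), recursive = FALSE)
  ad_start()
  l_dis <- NULL
  for (l in levels) {
    d_s <- discs[[l]]$fw(fs[[l]], patch_shape)
    d_t <- discs[[l]]$fw(ft[[l]], patch_shape)
    term <- ad_scale(ad_dis_loss_level(d_s, d_t), cfg$lambda[l])
    l_dis <- if (is.null(l_dis)) term else ad_add(l_dis, term)
  }
  val <- vv(l_dis)
  ad_backward(l_dis)
  clip_gradients(dparams, cfg$grad_clip)
  sgd_update(dparams, lr, cfg$momentum)
  ad_zero_grad(dparams)
  ad_stop()
  val
}

#' Adversarial domain-adaptive training (HCA-DAN)
#'
#' Alternates, per iteration, (a) a segmentor step minimizing
#' `L_seg + w_da * L_da^h` — the class-attention-gated least-squares
#' adaptation loss pushes target-domain features toward the discriminators'
#' source label — and (b) a discriminator step minimizing `L_dis^h` on the
#' same features. The attention map is treated as a constant inside the
#' adaptation loss. Target masks are never read; passing them is an error.
#'
#' `align_mode` gates the levels: `"hcada"` aligns all four, `"m1"` only the
#' highest-resolution level, `"m2"` aligns all four with attention replaced
#' by 1 (class-agnostic), `"off"` reduces exactly to
#' [train_supervised()] on the source set.
#'
#' @param cfg a [train_config()].
#' @param source list of labeled source cases `list(volume, mask)`.
#' @param target list of unlabeled target cases (see [unlabeled_set()]).
#' @param verbose print running losses every 25 iterations.
#' @return An `hcadan_checkpoint` (segmentor + discriminator weights) with
#'   per-iteration `L_seg`, `L_da`, `L_dis` in `$losses`.
#' @export
train_hcada <- function(cfg, source, target, verbose = FALSE) {
  stopifnot(inherits(cfg, "train_config"))
  if (cfg$align_mode == "off") return(train_supervised(cfg, source, verbose))
  check_unlabeled(target)
  set.seed(cfg$seed)
  prep_s <- prepare_cases(source, cfg)
  prep_t <- prepare_cases(target, cfg, stats = prep_s$stats)
  net <- astr_network(cfg$network)
  discs <- domain_discriminators(cfg$network)
  check_patch_shape(cfg$network, cfg$preprocess$patch_shape)
  params <- module_params(net)
  dparams <- unlist(lapply(discs, module_params), recursive = FALSE)
  levels <- if (cfg$align_mode == "m1") 4L else 1:4
  patch_shape <- cfg$preprocess$patch_shape
  log <- matrix(0, cfg$iterations, 3,
                dimnames = list(NULL, c("L_seg", "L_da", "L_dis")))
  for (it in seq_len(cfg$iterations)) {
    lr_t <- poly_lr(cfg$lr, it, cfg$iterations, cfg$lr_poly)
    dlr_t <- poly_lr(cfg$disc_lr, it, cfg$iterations, cfg$lr_poly)
    w_da_t <- if (cfg$da_ramp) {
      cfg$w_da * (2 / (1 + exp(-10 * (it - 1) / cfg$iterations)) - 1)
    } else cfg$w_da
    # -- segmentor step -------------------------------------------------
    ad_start()
    l_seg <- NULL; l_da <- NULL
    fs <- vector("list", 4); ft <- vector("list", 4)
    for (b in seq_len(cfg$batch_size)) {
      pt <- sample_labeled_patch(prep_s$cases, cfg)
      out_s <- net$fw(pt$x)
      li <- ad_seg_loss(out_s$logits, pt$g)
      l_seg <- if (is.null(l_seg)) li else ad_add(l_seg, li)
      xt <- sample_unlabeled_patch(prep_t$cases, cfg)
      out_t <- net$fw(xt)
      att <- if (cfg$align_mode == "m2") 1 else {
        a <- class_attention(vv(out_t$logits))  # detached by construction
        tc <- tumor_channel(a); dim(tc) <- c(1L, dim(tc))
        tc
      }
      for (l in levels) {
        d_t <- discs[[l]]$fw(out_t$pba_feats[[l]], patch_shape)
        term <- ad_scale(ad_da_loss_level(d_t, att), cfg$lambda[l])
        l_da <- if (is.null(l_da)) term else ad_add(l_da, term)
      }
      for (l in 1:4) {
        fs[[l]] <- c(fs[[l]], list(vv(out_s$pba_feats[[l]])))
        ft[[l]] <- c(ft[[l]], list(vv(out_t$pba_feats[[l]])))
      }
    }
    l_seg <- ad_scale(l_seg, 1 / cfg$batch_size)
    l_da <- ad_scale(l_da, 1 / cfg$batch_size)
    total <- ad_add(l_seg, ad_scale(l_da, w_da_t))
    log[it, "L_seg"] <- vv(l_seg); log[it, "L_da"] <- vv(l_da)
    check_loss_finite(vv(total), it)
    ad_backward(total)
    clip_gradients(params, cfg$grad_clip)
    sgd_update(params, lr_t, cfg$momentum)
    ad_zero_grad(params); ad_zero_grad(dparams)
    ad_stop()
    # -- discriminator step on the same features ------------------------
    l_dis <- 0
    for (b in seq_len(cfg$batch_size))
      l_dis <- l_dis + disc_step(discs, lapply(fs, `[[`, b),
                                 lapply(ft, `[[`, b), cfg, levels,
                                 patch_shape, dlr_t)
    log[it, "L_dis"] <- l_dis / cfg$batch_size
    check_loss_finite(log[it, "L_dis"], it, "discrimination loss")
    if (verbose && it %% 25 == 0)
      message(sprintf("iter %4d  L_seg %.4f  L_da %.4f  L_dis %.4f",
                      it, log[it, 1], log[it, 2], log[it, 3]))
  }
  new_checkpoint(net, cfg, prep_s$stats,
                 as.data.frame(cbind(iter = seq_len(cfg$iterations), log)),
                 discs = discs)
}
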