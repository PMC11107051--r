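ns <- asNamespace("hcadan")

zero_params <- function(mod) {
  for (p in ns$module_params(mod)) p$v <- 0 * p$v
  invisible(mod)
}

test_that("AsBlock preserves shape, is linear in its weights, and its
           convolution parameter count matches the closed form", {
  set.seed(31)
  blk <- ns$mod_as_block(3L, 5L, groups = 8L)
  x <- array(rnorm(3 * 4 * 6 * 6), c(3, 4, 6, 6))
  out <- ns$vv(blk$fw(x))
  expect_equal(dim(out), c(5, 4, 6, 6))
  zero_params(blk)
  expect_true(all(ns$vv(blk$fw(x)) == 0))
  # 4 conv layers: 1x3x3 and 3x1x1 branches, input and output projections
  tab <- module_param_table(blk)
  conv_n <- sum(tab$n[grepl("\\.(W|b)$", tab$name)])
  Cin <- 3; Cout <- 5
  expect_equal(conv_n,
               (Cout * Cin * 9 + Cout) + (Cout * Cin * 3 + Cout) +
                 (Cout * Cin + Cout) + (Cout * 3 * Cout + Cout))
})

test_that("SE-Res block honors its residual and gating contracts", {
  set.seed(32)
  blk <- ns$mod_se_res(4L, 4L, groups = 4L)
  x <- array(rnorm(4 * 4 * 6 * 6), c(4, 4, 6, 6))
  expect_equal(dim(ns$vv(blk$fw(x))), dim(x))
  # zeroed convolutions: gate at 1 or 0, the block is an exact identity
  zero_params(blk)
  blk$opt$gate_override <- 1
  expect_equal(ns$vv(blk$fw(x)), x, tolerance = 1e-12)
  blk$opt$gate_override <- 0
  expect_equal(ns$vv(blk$fw(x)), x, tolerance = 1e-12)
  # with real weights the sigmoid gate lies strictly inside (0, 1)
  set.seed(33)
  blk2 <- ns$mod_se_res(4L, 4L, groups = 4L)
  h <- ns$vv(blk2$params$conv2$fw(blk2$params$conv1$fw(x)))
  # direct sigmoid evaluation of the squeeze-excitation path
  s <- rowMeans(matrix(ns$vv(ns$ad_groupnorm(h, blk2$params$gamma2,
                                             blk2$params$beta2, 4L)),
                       4))
  z1 <- pmax(blk2$params$fc1$v %*% s + blk2$params$fb1$v, 0)
  gate <- 1 / (1 + exp(-(blk2$params$fc2$v %*% z1 + blk2$params$fb2$v)))
  expect_true(all(gate > 0 & gate < 1))
})

test_that("PBA branches match hand-computed sigmoid gating", {
  # single branch spanning the whole 1x2x2 grid
  f <- array(c(1, 2, 3, 4), c(1, 1, 2, 2))
  br <- pba_branches(f, 3L)[[1]]
  expect_equal(as.vector(br),
               1 / (1 + exp(-(c(1, 2, 3, 4) - 2.5))) * c(1, 2, 3, 4),
               tolerance = 1e-6)
  # constant field: every pooled map equals c, each branch is 0.5 * c
  for (kern in list(c(3L, 5L), c(5L, 7L))) {
    cf <- array(2.4, c(2, 6, 8, 8))
    for (b in pba_branches(cf, kern))
      expect_equal(b, 0.5 * cf, tolerance = 1e-12)
  }
  expect_error(pba_branches(cf, 4L))
})

test_that("the encoder produces the documented anisotropic pyramid", {
  set.seed(34)
  cfg <- desk_network_config()
  expect_equal(cfg$as_blocks, c(2L, 3L))
  expect_equal(cfg$se_res, c(3L, 2L))
  expect_equal(cfg$pba_kernels,
               list(c(3L, 5L), c(3L, 5L), c(5L, 7L), c(5L, 7L)))
  net <- astr_network(cfg)
  expect_length(net$params$enc$params$stage1, 2)
  expect_length(net$params$enc$params$stage2, 3)
  expect_length(net$params$enc$params$stage3, 3)
  expect_length(net$params$enc$params$stage4, 2)
  x <- array(rnorm(16 * 64 * 64), c(16, 64, 64))
  pyr <- astr_encode(net, x)
  expect_equal(dim(pyr[[4]]), c(cfg$channels[1], 16, 32, 32))
  expect_equal(dim(pyr[[3]]), c(cfg$channels[2], 16, 16, 16))
  expect_equal(dim(pyr[[2]]), c(cfg$channels[3], 8, 8, 8))
  expect_equal(dim(pyr[[1]]), c(cfg$channels[4], 4, 4, 4))
  # pyramid monotonicity: spatial volume strictly increases with level
  vols <- sapply(pyr, function(f) prod(dim(f)[-1]))
  expect_true(all(diff(vols) > 0))
  expect_error(astr_forward(net, array(0, c(15, 64, 64))), "divisible")
})

test_that("the DeTrans context encoder preserves shapes and its attention
           weights form distributions over points and levels", {
  set.seed(35)
  cfg <- desk_network_config()
  det <- ns$mod_detrans(cfg)
  lch <- rev(cfg$channels)
  dims <- list(c(2, 2, 2), c(4, 4, 4), c(4, 8, 8), c(4, 16, 16))
  levels <- lapply(1:4, function(l)
    array(rnorm(lch[l] * prod(dims[[l]])), c(lch[l], dims[[l]])))
  out <- det$fw(levels)
  for (l in 1:4) expect_equal(dim(ns$vv(out[[l]])), dim(levels[[l]]))
  aw <- det$opt$last_attention  # (K, L, H, N)
  sums <- apply(aw, 3:4, sum)
  expect_equal(as.vector(sums), rep(1, length(sums)), tolerance = 1e-9)

  # zeroed offset/weight/output projections: attention contributes nothing,
  # so the output equals the feed-forward-only path
  for (ly in det$params$layers)
    for (nm in c("Woff", "boff", "Ww", "bw", "Wo", "bo"))
      ly[[nm]]$v <- 0 * ly[[nm]]$v
  with_attn <- det$fw(levels)
  det$opt$skip_attn <- TRUE
  without_attn <- det$fw(levels)
  det$opt$skip_attn <- NULL
  for (l in 1:4)
    expect_equal(ns$vv(with_attn[[l]]), ns$vv(without_attn[[l]]),
                 tolerance = 1e-10)
})

test_that("forward yields full-resolution logits plus pyramid-shaped
           alignment features, deterministically", {
  set.seed(36)
  cfg <- desk_network_config()
  net <- astr_network(cfg)
  x <- array(rnorm(16 * 64 * 64), c(16, 64, 64))
  out <- astr_forward(net, x)
  expect_equal(dim(out$logits), c(2, 16, 64, 64))
  expect_equal(dim(out$pba_feats[[4]]), c(cfg$channels[1], 16, 32, 32))
  expect_equal(dim(out$pba_feats[[1]]), c(cfg$channels[4], 4, 4, 4))
  out2 <- astr_forward(net, x)
  expect_identical(out$logits, out2$logits)

  # PBA ablation: identical weights elsewhere, still runs, features change
  set.seed(36)
  net0 <- astr_network(desk_network_config(use_pba = FALSE))
  out0 <- astr_forward(net0, x)
  expect_equal(dim(out0$logits), c(2, 16, 64, 64))
  expect_false(identical(out0$pba_feats[[4]], out$pba_feats[[4]]))

  tab <- network_summary(net)
  expect_equal(attr(tab, "total"), sum(tab$n))
  expect_equal(module_param_count(net), sum(tab$n))
})

test_that("every decoder parameter receives gradient from the
           segmentation loss", {
  set.seed(37)
  cfg <- desk_network_config()
  net <- astr_network(cfg)
  x <- array(rnorm(16 * 32 * 32), c(16, 32, 32))
  g <- array(rbinom(16 * 32 * 32, 1, 0.1), c(16, 32, 32))
  params <- ns$module_params(net)
  ns$ad_start()
  loss <- ns$ad_seg_loss(net$fw(ns$as_input_tensor(x))$logits, g)
  ns$ad_backward(loss)
  ns$ad_stop()
  dec <- params[grepl("^dec\\.", names(params))]
  got <- vapply(dec, function(p) !is.null(p$g) && any(p$g != 0), logical(1))
  expect_true(all(got))
  ns$ad_zero_grad(params)
})
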