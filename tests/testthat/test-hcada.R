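ns <- asNamespace("hcadan")

test_that("class attention is an exact per-voxel softmax", {
  eq <- array(0.7, c(2, 2, 3, 3))
  expect_equal(class_attention(eq),
               array(0.5, c(2, 2, 3, 3)), tolerance = 1e-12)
  big <- array(0, c(2, 1, 1, 1)); big[2, 1, 1, 1] <- 20
  expect_gt(class_attention(big)[2, 1, 1, 1], 1 - 1e-8)
  lg <- array(c(0, log(3)), c(2, 1, 1, 1))
  expect_equal(as.vector(class_attention(lg)), c(0.25, 0.75),
               tolerance = 1e-12)
  set.seed(41)
  att <- class_attention(array(rnorm(2 * 3 * 4 * 4), c(2, 3, 4, 4)))
  expect_equal(as.vector(apply(att, 2:4, sum)), rep(1, 48), tolerance = 1e-12)
  expect_true(all(att >= 0 & att <= 1))
})

test_that("per-level discriminators emit full-resolution score maps and
           share no parameters", {
  set.seed(42)
  cfg <- desk_network_config()
  discs <- domain_discriminators(cfg)
  expect_length(discs, 4)
  patch <- c(8L, 16L, 16L)
  feat <- array(rnorm(cfg$channels[4] * 2 * 2 * 2), c(cfg$channels[4], 2, 2, 2))
  out <- discriminate(discs, 1, feat, patch)
  expect_equal(dim(out), c(1, patch))
  expect_true(all(is.finite(out)))
  expect_error(discriminate(discs, 5, feat, patch), "unknown")
  # parameter tensors are pairwise distinct objects across levels
  plists <- lapply(discs, ns$module_params)
  for (i in 1:3) for (j in (i + 1):4)
    for (pi in plists[[i]]) for (pj in plists[[j]])
      expect_false(identical(pi, pj))
  # perturbing one discriminator leaves the others untouched
  before <- ns$vv(discriminate(discs, 2,
                               array(0.3, c(cfg$channels[3], 4, 4, 4)), patch))
  for (p in ns$module_params(discs[[1]])) p$v <- p$v + 1
  after <- ns$vv(discriminate(discs, 2,
                              array(0.3, c(cfg$channels[3], 4, 4, 4)), patch))
  expect_identical(before, after)
})

test_that("trilinear upsampling of a constant feature grid is constant", {
  cf <- array(1.7, c(3, 2, 4, 4))
  up <- ns$vv(ns$ad_resize_trilinear(cf, c(8L, 16L, 16L)))
  expect_equal(up, array(1.7, c(3, 8, 16, 16)), tolerance = 1e-12)
})

test_that("cada_map is the element-wise attention-gated score map", {
  dmap <- array(c(2, -1, 0, 4), c(1, 2, 2))
  att <- array(c(0.5, 0.5, 1, 0.25), c(1, 2, 2))
  expect_equal(cada_map(dmap, att), array(c(1, -0.5, 0, 1), c(1, 2, 2)))
  expect_equal(cada_map(dmap, array(0, c(1, 2, 2))), array(0, c(1, 2, 2)))
  expect_equal(cada_map(dmap, array(1, c(1, 2, 2))), dmap)
  expect_error(cada_map(dmap, array(1, c(2, 2, 2))), "mismatch")
  # a full 2-channel attention array is reduced to its tumor channel
  logits <- array(0, c(2, 1, 2, 2))
  att2 <- class_attention(logits)  # 0.5 everywhere
  expect_equal(cada_map(dmap, att2), 0.5 * dmap)
})
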