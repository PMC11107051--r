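ns <- asNamespace("hcadan")

make_tiny_cases <- function(n, seed0 = 500) {
  spec <- tiny_phantom_spec()
  lapply(seq_len(n), function(i) generate_phantom(spec, seed0 + i))
}

test_that("zero-iteration training returns the seeded initialization", {
  cases <- make_tiny_cases(2)
  cfg <- tiny_train_config(iterations = 0L, seed = 17L)
  ck <- train_supervised(cfg, cases)
  set.seed(17L)
  ns$prepare_cases(cases, cfg)  # consumes no RNG, mirrors the trainer
  ref <- astr_network(cfg$network)
  expect_identical(ck$values, lapply(ns$module_params(ref), ns$vv))
})

test_that("training trajectories are reproducible per seed", {
  cases <- make_tiny_cases(3)
  cfg <- tiny_train_config(iterations = 6L, seed = 21L)
  a <- train_supervised(cfg, cases)
  b <- train_supervised(cfg, cases)
  expect_identical(a$losses, b$losses)
  expect_identical(a$values, b$values)
  c2 <- train_supervised(tiny_train_config(iterations = 6L, seed = 22L), cases)
  expect_false(identical(a$losses$L_seg, c2$losses$L_seg))
})

test_that("alignment mode off reduces exactly to supervised training", {
  cases <- make_tiny_cases(2)
  tgt <- unlabeled_set(make_tiny_cases(2, seed0 = 900))
  cfg <- tiny_train_config(iterations = 4L, seed = 5L, align_mode = "off")
  a <- train_hcada(cfg, cases, tgt)
  b <- train_supervised(cfg, cases)
  expect_identical(a$values, b$values)
  expect_identical(a$losses, b$losses)
})

test_that("adaptation refuses target cases that carry masks", {
  cases <- make_tiny_cases(2)
  cfg <- tiny_train_config(iterations = 2L, seed = 5L)
  expect_error(train_hcada(cfg, cases, make_tiny_cases(2, seed0 = 900)),
               "must not carry masks")
})

test_that("m1/m2 gate only the alignment term, never the first-step L_seg", {
  cases <- make_tiny_cases(2)
  tgt <- unlabeled_set(make_tiny_cases(2, seed0 = 900))
  first_lseg <- sapply(c("hcada", "m1", "m2"), function(mode) {
    cfg <- tiny_train_config(iterations = 1L, seed = 9L, align_mode = mode)
    train_hcada(cfg, cases, tgt)$losses$L_seg[1]
  })
  expect_equal(first_lseg[["m1"]], first_lseg[["hcada"]])
  expect_equal(first_lseg[["m2"]], first_lseg[["hcada"]])
})

test_that("one discriminator step does not increase L_dis on a fixed batch", {
  set.seed(55)
  cfg <- tiny_train_config(seed = 1L)
  discs <- domain_discriminators(cfg$network)
  lch <- rev(cfg$network$channels)
  dims <- list(c(2, 2, 2), c(4, 4, 4), c(4, 8, 8), c(4, 16, 16))
  fs <- lapply(1:4, function(l) array(rnorm(lch[l] * prod(dims[[l]])),
                                      c(lch[l], dims[[l]])))
  ft <- lapply(1:4, function(l) array(rnorm(lch[l] * prod(dims[[l]])),
                                      c(lch[l], dims[[l]])))
  ps <- c(8L, 16L, 16L)
  l0 <- ns$disc_step(discs, fs, ft, cfg, 1:4, ps, lr = cfg$disc_lr)
  l1 <- ns$disc_step(discs, fs, ft, cfg, 1:4, ps, lr = cfg$disc_lr)
  expect_lte(l1, l0 + 1e-10)
})

test_that("checkpoints round-trip through disk with bitwise-identical
           evaluation", {
  cases <- make_tiny_cases(2)
  cfg <- tiny_train_config(iterations = 3L, seed = 31L)
  ck <- train_supervised(cfg, cases)
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(ck, path)
  ck2 <- load_checkpoint(path)
  r1 <- evaluate_checkpoint(ck, cases)
  r2 <- evaluate_checkpoint(ck2, cases)
  expect_identical(attr(r1, "predictions"), attr(r2, "predictions"))
  expect_equal(r1$DSC, r2$DSC)
})

test_that("evaluation scores an oracle predictor perfectly and flags
           all-background predictions", {
  cases <- make_tiny_cases(2)
  cfg <- tiny_train_config(iterations = 0L, seed = 2L)
  ck <- train_supervised(cfg, cases)
  oracle <- local({
    prep <- ns$prepare_cases(cases, cfg)
    masks <- lapply(prep$cases, function(cs) ns$mask_array(cs$mask))
    k <- 0
    function(patch) {
      k <<- k + 1
      m <- masks[[k]]
      lg <- array(0, c(2, dim(m)))
      lg[1, , , ] <- ifelse(m == 1, -10, 10)
      lg[2, , , ] <- ifelse(m == 1, 10, -10)
      lg
    }
  })
  # patch shape equals the tiny volume shape: one window per case
  rep <- evaluate_checkpoint(ck, cases, predict_fn = oracle)
  expect_equal(rep$DSC, c(100, 100))
  expect_equal(rep$ASD, c(0, 0))
  allbg <- function(patch) {
    lg <- array(0, c(2, dim(patch))); lg[1, , , ] <- 10; lg[2, , , ] <- -10
    lg
  }
  rep0 <- evaluate_checkpoint(ck, cases, predict_fn = allbg)
  expect_equal(rep0$DSC, c(0, 0))
  expect_false(any(rep0$distance_defined))
  expect_true(all(is.na(rep0$ASD)))
})

test_that("overlap-averaged windows equal a single window when the patch
           covers the volume", {
  fw <- function(patch) {
    lg <- array(0, c(2, dim(patch)))
    lg[1, , , ] <- -patch; lg[2, , , ] <- patch
    lg
  }
  v <- array(rnorm(6 * 10 * 12), c(6, 10, 12))
  out <- ns$sliding_window_logits(fw, v, c(8L, 16L, 16L))
  padded <- array(0, c(8, 16, 16))
  padded[1:6, 1:10, 1:12] <- v
  direct <- fw(padded)[, 1:6, 1:10, 1:12, drop = FALSE]
  expect_equal(out, direct, tolerance = 1e-12)
})

test_that("split plans partition cases exactly once and LOCO never leaks
           the target center", {
  # two volumes per case: group cross-validation keeps them together
  ids <- rep(sprintf("case%02d", 1:10), each = 2)
  centers <- rep(rep(c("A", "B"), each = 5), each = 2)
  plan <- split_plan(ids, centers, "in_center_5fold", n_folds = 5, seed = 3)
  expect_equal(sort(unique(plan$fold)), 1:5)
  for (id in unique(ids))
    expect_length(unique(plan$fold[plan$id == id]), 1)
  # every case lands in exactly one test fold, all folds nonempty
  expect_true(all(!is.na(plan$fold)))
  expect_true(all(table(plan$fold[!duplicated(plan$id)]) >= 1))

  centers4 <- rep(c("A", "B", "C", "D"), times = c(3, 2, 3, 2))
  plan2 <- split_plan(sprintf("c%02d", 1:10), centers4, "cross_center_loco")
  expect_equal(sort(unique(plan2$fold)), c("A", "B", "C", "D"))
  for (f in unique(plan2$fold)) {
    src_centers <- plan2$center[plan2$fold != f]
    expect_false(f %in% src_centers)
  }
  expect_error(split_plan(1:3, rep("A", 3), "cross_center_loco"), "2 centers")
})

test_that("run_protocol executes the splits and aggregates per-case metrics", {
  cases <- make_tiny_cases(4)
  ids <- sprintf("p%d", 1:4)
  plan <- split_plan(ids, rep(c("A", "B"), 2), "in_center_5fold",
                     n_folds = 2, seed = 1)
  cfg <- tiny_train_config(iterations = 2L, seed = 3L)
  res <- run_protocol(plan, cfg, cases)
  expect_length(res, 2)
  tested <- unlist(lapply(res, function(r) r$report$id))
  expect_setequal(tested, ids)
  rep1 <- res[[1]]$report
  expect_equal(summary(rep1)["DSC", "mean"], mean(rep1$DSC))
})
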