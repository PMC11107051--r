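test_that("dice, bce and segmentation losses match their closed forms", {
  expect_equal(dice_loss(c(1, 1, 0, 0), c(1, 1, 0, 0)), 0)
  expect_equal(dice_loss(c(1, 1, 0, 0), c(0, 0, 1, 1)), 1)
  expect_equal(dice_loss(c(1, 1, 0, 0), c(1, 0, 1, 0)), 0.5)
  expect_equal(dice_loss(numeric(4), numeric(4)), 0)  # 0/0 guard

  g <- c(1, 0, 1, 1, 0)
  expect_lt(bce_loss(g, g), 2 * 1e-7 * abs(log(1e-7)) + 1e-12)
  expect_equal(bce_loss(rep(0.5, 8), rbinom(8, 1, .5)), log(2))
  set.seed(1)
  p <- runif(8); gg <- rbinom(8, 1, .5)
  oracle <- -mean(gg * log(p) + (1 - gg) * log(1 - p))
  expect_equal(bce_loss(p, gg), oracle, tolerance = 1e-9)
  expect_equal(seg_loss(p, gg), dice_loss(p, gg) + bce_loss(p, gg))
  expect_equal(seg_loss(c(1, 1, 0, 0), c(1, 0, 1, 0)),
               0.5 + bce_loss(c(1, 1, 0, 0), c(1, 0, 1, 0)))
})

test_that("least-squares adversarial losses match direct evaluation", {
  expect_equal(dis_loss_level(1, -1), 0)
  expect_equal(dis_loss_level(0, 0), 2)
  set.seed(2)
  ds <- matrix(rnorm(4), 2); dt <- matrix(rnorm(4), 2)
  expect_equal(dis_loss_level(ds, dt),
               mean((ds - 1)^2) + mean((dt + 1)^2), tolerance = 1e-9)

  expect_equal(da_loss_level(rep(1, 4), runif(4)), 0)
  expect_equal(da_loss_level(rnorm(4), rep(0, 4)), 0)
  expect_equal(da_loss_level(c(0, 2), c(0.5, 1)), mean(c(0.5 * 1, 1 * 1)))
})

test_that("hierarchical loss weighting is linear with the default lambda", {
  expect_equal(hierarchical_loss(c(1, 1, 1, 1)), 1.875)
  expect_equal(hierarchical_loss(c(0, 0, 3, 0)), 0.5 * 3)
  lv <- c(0.3, 1.2, 0.7, 2)
  lam <- c(1 / 8, 1 / 4, 1 / 2, 1)
  expect_equal(hierarchical_loss(lv, 3 * lam), 3 * hierarchical_loss(lv, lam))
})

test_that("overlap metrics match set-count oracles and identities", {
  dm <- c(4, 5, 5)
  a <- array(0L, dm); b <- array(0L, dm)
  a[1, 1:2, 1:2] <- 1L               # |P| = 4
  b[1, 1:2, 1] <- 1L; b[1, 3:4, 2] <- 1L  # |G| = 4, 2 shared
  expect_equal(dsc(a, b), 50)
  expect_equal(jaccard(a, b), 100 / 3)
  expect_equal(dsc(a, a), 100)
  expect_equal(jaccard(a, a), 100)
  expect_equal(dsc(array(0L, dm), array(0L, dm)), 100)
  disj <- array(0L, dm); disj[4, 5, 5] <- 1L
  expect_equal(dsc(a, disj), 0)
  set.seed(5)
  for (i in 1:10) {
    p <- random_mask(c(8, 8, 8)); g <- random_mask(c(8, 8, 8))
    ji <- jaccard(p, g)
    expect_equal(dsc(p, g), 200 * ji / (100 + ji), tolerance = 1e-9)
    expect_equal(dsc(p, g), dsc(g, p))
    # binary consistency with the Dice loss
    expect_equal(dice_loss(as.numeric(p), as.numeric(g)),
                 1 - dsc(p, g) / 100, tolerance = 1e-9)
  }
})

test_that("surface metrics agree with a single-pair distance oracle", {
  dm <- c(8, 10, 10)
  sp <- c(5, 0.741, 0.741)
  a <- array(0L, dm); b <- array(0L, dm)
  a[4, 3, 6] <- 1L
  b[4, 6, 6] <- 1L  # 3 voxels apart along y
  expect_equal(asd(a, b, sp), 3 * 0.741, tolerance = 1e-9)
  expect_equal(hd95(a, b, sp), 3 * 0.741, tolerance = 1e-9)
  expect_equal(asd(a, a, sp), 0)
  expect_equal(hd95(a, a, sp), 0)
  expect_error(asd(a, array(0L, dm), sp), "empty")
})

test_that("surface metrics match exhaustive brute force on random masks", {
  set.seed(6)
  for (i in 1:15) {
    dm <- sample(5:12, 3, replace = TRUE)
    sp <- c(runif(1, 2, 8), runif(1, 0.5, 1), runif(1, 0.5, 1))
    p <- random_mask(dm); g <- random_mask(dm)
    if (sum(p) == 0 || sum(g) == 0) next
    ref <- r_surface_metrics(p, g, sp)
    expect_equal(asd(p, g, sp), ref$asd, tolerance = 1e-6)
    expect_equal(hd95(p, g, sp), ref$hd95, tolerance = 1e-6)
    expect_lte(hd95(p, g, sp), ref$hd + 1e-9)
    expect_equal(asd(p, g, sp), asd(g, p, sp), tolerance = 1e-9)
    expect_equal(hd95(p, g, sp), hd95(g, p, sp), tolerance = 1e-9)
  }
})

test_that("metrics reports aggregate per-case rows into mean +/- SD", {
  set.seed(7)
  preds <- list(random_mask(c(6, 8, 8)), random_mask(c(6, 8, 8)),
                array(0L, c(6, 8, 8)))
  gts <- list(random_mask(c(6, 8, 8)), random_mask(c(6, 8, 8)),
              random_mask(c(6, 8, 8)))
  rep <- metrics_report(preds, gts, c(5, 1, 1))
  expect_s3_class(rep, "metrics_report")
  expect_equal(nrow(rep), 3)
  expect_false(rep$distance_defined[3])
  expect_true(is.na(rep$ASD[3]))
  s <- summary(rep)
  expect_equal(s["DSC", "mean"], mean(rep$DSC))
  expect_equal(s["ASD", "mean"], mean(rep$ASD, na.rm = TRUE))
})
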