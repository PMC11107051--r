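test_that("phantom generation is deterministic and geometrically sound", {
  spec <- phantom_spec()
  a <- generate_phantom(spec, seed = 11)
  b <- generate_phantom(spec, seed = 11)
  expect_identical(a$volume$data, b$volume$data)
  expect_identical(a$mask$data, b$mask$data)
  expect_false(identical(a$volume$data,
                         generate_phantom(spec, seed = 12)$volume$data))

  # fixed semi-axes, no rotation: voxel count close to the analytic volume
  spec46 <- phantom_spec(shape = c(24L, 32L, 32L), semi_axes = c(4, 6, 6))
  ph <- generate_phantom(spec46, seed = 2)
  expect_lt(abs(sum(ph$mask$data) - 4 / 3 * pi * 4 * 6 * 6) /
              (4 / 3 * pi * 4 * 6 * 6), 0.10)

  # masks are nonempty and strictly inside the grid
  for (s in 1:10) {
    m <- generate_phantom(spec, seed = s)$mask$data
    dm <- dim(m)
    expect_gt(sum(m), 0)
    expect_equal(sum(m[c(1, dm[1]), , ]) + sum(m[, c(1, dm[2]), ]) +
                   sum(m[, , c(1, dm[3])]), 0)
  }
})

test_that("noiseless hard-boundary phantoms take exactly two values", {
  spec <- phantom_spec(texture_amp = 0, noise_sd = 0, soft_boundary = FALSE)
  ph <- generate_phantom(spec, seed = 5)
  expect_setequal(unique(as.vector(ph$volume$data)),
                  c(spec$mu_bg, spec$mu_bg + spec$delta_t))
  # the soft boundary instead inserts partial-volume intermediate values
  specs <- phantom_spec(texture_amp = 0, noise_sd = 0, soft_boundary = TRUE)
  phs <- generate_phantom(specs, seed = 5)
  expect_gt(length(unique(as.vector(phs$volume$data))), 2)
})

test_that("tumor volume fraction spans at least 4x across a generated set", {
  # a cohort-sized set (the clinical centers hold 39-74 cases each)
  spec <- phantom_spec()
  fr <- vapply(1:40, function(s)
    mean(generate_phantom(spec, seed = 1000 + s)$mask$data), numeric(1))
  expect_gte(max(fr) / min(fr), 4)
})

test_that("domain pairs realize the requested shift", {
  spec <- phantom_spec()
  # null shift: target generation parameters are unchanged
  null <- generate_domain_pair(spec, spec, domain_shift_spec(), n = 4, seed = 1)
  expect_equal(dim(null$target[[1]]$volume$data), spec$shape,
               ignore_attr = TRUE)
  expect_equal(null$target[[1]]$volume$spacing, spec$spacing)
  ms <- mean(sapply(null$source, function(p) mean(p$volume$data)))
  mt <- mean(sapply(null$target, function(p) mean(p$volume$data)))
  expect_lt(abs(ms - mt), 3 * phantom_background_sd(spec))

  # delta-mu = 50: background mean difference ~= 50 within 3 SE over n = 20
  pr <- generate_domain_pair(spec, spec, domain_shift_spec(delta_mu = 50),
                             n = 20, seed = 7)
  bg_mean <- function(p) mean(p$volume$data[p$mask$data == 0])
  d <- sapply(pr$target, bg_mean) - sapply(pr$source, bg_mean)
  se <- sd(d) / sqrt(length(d))
  expect_lt(abs(mean(d) - 50), 3 * se)

  # slice-spacing pair (5, 8): target z extent = round(z_mm / 8)
  pr2 <- generate_domain_pair(spec, spec,
                              domain_shift_spec(spacing_pair = c(5, 8)),
                              n = 2, seed = 3)
  z_mm <- spec$shape[1] * spec$spacing[1]
  expect_equal(dim(pr2$target[[1]]$volume$data)[1], round(z_mm / 8))
  expect_equal(pr2$target[[1]]$volume$spacing[1], 8)
  expect_equal(dim(pr2$source[[1]]$volume$data)[1], spec$shape[1])
})

test_that("phantom sets write NIfTI pairs with a manifest", {
  dir <- withr::local_tempdir()
  spec <- tiny_phantom_spec()
  phs <- lapply(1:2, function(s) generate_phantom(spec, s))
  man <- write_phantom_set(dir, phs, domain = "A")
  expect_equal(nrow(man), 2)
  expect_true(all(file.exists(man$path)))
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  rb <- read_volume(man$path[1], man$mask[1])
  expect_equal(rb$volume$data, phs[[1]]$volume$data, tolerance = 1e-7,
               ignore_attr = TRUE)
  expect_equal(sum(rb$mask$data), sum(phs[[1]]$mask$data))
})
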