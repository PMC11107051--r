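# Synthetic anisotropic CT-like phantoms: ellipsoidal "tumors" on a textured
# background with Gaussian noise, plus controllable inter-domain shifts
# (intensity offset, contrast scale, noise ratio, slice spacing). These
# emulate the variability of multi-center anisotropic abdominal CT — highly
# variable tumor size/shape/intensity and inter-center heterogeneity — so
# that preprocessing, the network, and the adaptation scheme are all
# testable without any external data.

#' Phantom specification
#'
#' @param shape grid shape (Z, Y, X) in voxels.
#' @param spacing voxel spacing (sz, sy, sx) in mm.
#' @param semi_axes fixed ellipsoid semi-axes (a_z, b_y, c_x) in voxels, or
#'   `NULL` to draw them per phantom from `semi_axes_range`.
#' @param semi_axes_range list of per-axis ranges the semi-axes are drawn
#'   from (uniform); the defaults span a >4-fold range of tumor volume.
#' @param delta_t tumor intensity offset added inside the mask.
#' @param mu_bg background mean intensity.
#' @param texture_amp total amplitude of the low-frequency background
#'   texture (sum of 3 seeded cosine fields).
#' @param noise_sd Gaussian noise SD (>= 0).
#' @param soft_boundary logical; if `TRUE` the tumor edge gets a ~1-voxel
#'   partial-volume ramp, if `FALSE` the edge is hard (the noiseless,
#'   texture-free image then takes exactly two values).
#' @param domain free-text domain tag.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape = c(16L, 64L, 64L),
                         spacing = c(5, 0.741, 0.741),
                         semi_axes = NULL,
                         semi_axes_range = list(z = c(2, 4), y = c(5, 12),
                                                x = c(5, 12)),
                         delta_t = 30, mu_bg = 100, texture_amp = 10,
                         noise_sd = 10, soft_boundary = TRUE,
                         domain = "A") {
  stopifnot(length(shape) == 3, all(shape >= 4), all(spacing > 0),
            noise_sd >= 0)
  max_semi <- if (is.null(semi_axes)) {
    vapply(semi_axes_range, max, numeric(1))
  } else semi_axes
  if (any(2 * ceiling(max_semi) + 4 > shape))
    stop("ellipsoid semi-axes do not fit inside the grid")
  structure(list(shape = as.integer(shape), spacing = as.numeric(spacing),
                 semi_axes = semi_axes, semi_axes_range = semi_axes_range,
                 delta_t = delta_t, mu_bg = mu_bg, texture_amp = texture_amp,
                 noise_sd = noise_sd, soft_boundary = isTRUE(soft_boundary),
                 domain = domain),
            class = "phantom_spec")
}

#' Analytic background intensity SD of a phantom specification
#'
#' SD of texture plus noise: the three cosine fields carry amplitudes
#' (0.5, 0.3, 0.2) x `texture_amp`, each contributing amp^2/2 of variance.
#'
#' @param spec a [phantom_spec()].
#' @return The background SD (intensity units).
#' @export
phantom_background_sd <- function(spec) {
  amps <- spec$texture_amp * c(0.5, 0.3, 0.2)
  sqrt(sum(amps^2) / 2 + spec$noise_sd^2)
}

#' Generate one phantom
#'
#' The mask is a discretized ellipsoid with seeded random center, in-plane
#' orientation and (optionally) semi-axes; the image is background texture
#' plus `delta_t` inside the tumor plus Gaussian noise. Deterministic per
#' seed.
#'
#' @param spec a [phantom_spec()].
#' @param seed integer seed.
#' @return `list(volume, mask)`: a `volume3d` and its `seg_mask`.
#' @export
generate_phantom <- function(spec, seed = 0L) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_seed(seed, {
    dm <- spec$shape
    semi <- if (is.null(spec$semi_axes)) {
      r <- spec$semi_axes_range
      c(stats::runif(1, r$z[1], r$z[2]), stats::runif(1, r$y[1], r$y[2]),
        stats::runif(1, r$x[1], r$x[2]))
    } else as.numeric(spec$semi_axes)
    margin <- ceiling(c(semi[1], max(semi[2:3]), max(semi[2:3]))) + 1
    if (any(2 * margin >= dm))
      stop("ellipsoid semi-axes do not fit inside the grid")
    ctr <- vapply(1:3, function(a)
      stats::runif(1, margin[a], dm[a] - 1 - margin[a]), numeric(1))
    theta <- if (is.null(spec$semi_axes)) stats::runif(1, 0, pi) else 0
    zc <- (seq_len(dm[1]) - 1) - ctr[1]
    yc <- (seq_len(dm[2]) - 1) - ctr[2]
    xc <- (seq_len(dm[3]) - 1) - ctr[3]
    dz <- array(zc, dm)
    dy <- array(rep(yc, each = dm[1]), dm)
    dx <- array(rep(xc, each = dm[1] * dm[2]), dm)
    u <- cos(theta) * dy + sin(theta) * dx
    w <- -sin(theta) * dy + cos(theta) * dx
    e <- sqrt((dz / semi[1])^2 + (u / semi[2])^2 + (w / semi[3])^2)
    mask <- array(as.integer(e <= 1), dm)
    tumor_w <- if (spec$soft_boundary) {
      ramp <- 1 / mean(semi)  # ~1 voxel in normalized ellipsoid units
      pmin(pmax((1 + ramp / 2 - e) / ramp, 0), 1)
    } else as.numeric(e <= 1)
    tex <- array(0, dm)
    if (spec$texture_amp > 0) {
      amps <- spec$texture_amp * c(0.5, 0.3, 0.2)
      for (j in 1:3) {
        fr <- stats::runif(3, 0.5, 1.5)
        ph <- stats::runif(1, 0, 2 * pi)
        tex <- tex + amps[j] *
          cos(2 * pi * (fr[1] * dz / dm[1] + fr[2] * dy / dm[2] +
                          fr[3] * dx / dm[3]) + ph)
      }
    }
    img <- spec$mu_bg + tex + spec$delta_t * tumor_w
    if (spec$noise_sd > 0)
      img <- img + array(stats::rnorm(prod(dm), sd = spec$noise_sd), dm)
    list(volume = volume3d(img, spec$spacing),
         mask = seg_mask(mask, spec$spacing))
  })
}

#' Inter-domain shift specification
#'
#' @param delta_mu additive intensity shift applied to target images.
#' @param gamma contrast scale about the background mean (> 0).
#' @param noise_ratio multiplier on the target noise SD.
#' @param spacing_pair slice spacings (source_sz, target_sz) in mm; the
#'   target grid keeps the physical z extent, so its z size becomes
#'   `round(z_mm / target_sz)`.
#' @return An object of class `domain_shift_spec`.
#' @export
domain_shift_spec <- function(delta_mu = 0, gamma = 1, noise_ratio = 1,
                              spacing_pair = c(5, 5)) {
  stopifnot(gamma > 0, noise_ratio >= 0, length(spacing_pair) == 2,
            all(spacing_pair > 0))
  structure(list(delta_mu = delta_mu, gamma = gamma,
                 noise_ratio = noise_ratio,
                 spacing_pair = as.numeric(spacing_pair)),
            class = "domain_shift_spec")
}

#' Generate a paired source/target phantom set
#'
#' Draws `n` phantoms per domain. The target domain spec is modified by the
#' shift: its slice spacing becomes `shift$spacing_pair[2]` (same physical z
#' extent, semi-axes rescaled accordingly), its noise SD is multiplied by
#' `shift$noise_ratio`, and each target image is transformed as
#' `mu_bg + gamma * (img - mu_bg) + delta_mu`. Target masks are returned for
#' evaluation only; unsupervised adaptation must not read them.
#'
#' @param specA,specB [phantom_spec()] objects for source and target.
#' @param shift a [domain_shift_spec()].
#' @param n phantoms per domain (>= 1).
#' @param seed integer seed.
#' @return `list(source, target, shift)`; `source` and `target` are lists of
#'   `list(volume, mask)`.
#' @export
generate_domain_pair <- function(specA, specB, shift = domain_shift_spec(),
                                 n = 20L, seed = 0L) {
  stopifnot(n >= 1)
  sz_src <- shift$spacing_pair[1]; sz_tgt <- shift$spacing_pair[2]
  specA$spacing[1] <- sz_src
  z_mm <- specB$shape[1] * specB$spacing[1]
  tgt <- specB
  tgt$spacing[1] <- sz_tgt
  tgt$shape[1] <- max(4L, as.integer(round(z_mm / sz_tgt)))
  zscale <- specB$spacing[1] / sz_tgt
  if (!is.null(tgt$semi_axes)) {
    tgt$semi_axes[1] <- tgt$semi_axes[1] * zscale
  } else {
    tgt$semi_axes_range$z <- tgt$semi_axes_range$z * zscale
  }
  tgt$noise_sd <- tgt$noise_sd * shift$noise_ratio
  seeds <- with_seed(seed, draw_seed(2 * n))
  source <- lapply(seq_len(n), function(i) generate_phantom(specA, seeds[i]))
  target <- lapply(seq_len(n), function(i) {
    ph <- generate_phantom(tgt, seeds[n + i])
    img <- tgt$mu_bg + shift$gamma * (ph$volume$data - tgt$mu_bg) +
      shift$delta_mu
    ph$volume <- volume3d(img, ph$volume$spacing)
    ph
  })
  list(source = source, target = target, shift = shift)
}

#' Write a phantom set to disk as NIfTI pairs with a manifest
#'
#' @param dir output directory (created if needed).
#' @param phantoms list of `list(volume, mask)` as produced by
#'   [generate_phantom()] / [generate_domain_pair()].
#' @param domain domain tag recorded in the manifest.
#' @return The manifest data.frame (also written as `manifest.csv`).
#' @export
write_phantom_set <- function(dir, phantoms, domain = "A") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(seq_along(phantoms), function(i) {
    img <- file.path(dir, sprintf("%s_%03d.nii.gz", domain, i))
    msk <- file.path(dir, sprintf("%s_%03d_mask.nii.gz", domain, i))
    write_volume(phantoms[[i]]$volume, img)
    write_volume(phantoms[[i]]$mask, msk)
    data.frame(path = img, mask = msk, domain = domain,
               sz = phantoms[[i]]$volume$spacing[1],
               sy = phantoms[[i]]$volume$spacing[2],
               sx = phantoms[[i]]$volume$spacing[3])
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  manifest
}
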