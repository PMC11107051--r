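# Preprocessing: foreground-percentile intensity clipping with z-score
# normalization, per-axis spline resampling to a target voxel grid,
# tumor-centered anisotropic patch extraction, and seeded online
# augmentation (flips, in-plane 90-degree rotations, integer translations).

#' Preprocessing configuration
#'
#' @param clip_low_pct,clip_high_pct foreground-intensity percentiles used
#'   as clipping bounds (defaults 0.5 and 99.5).
#' @param target_spacing resampling target (sz, sy, sx) in mm.
#' @param patch_shape training patch shape (Dz, Dy, Dx) in voxels, each
#'   >= 8.
#' @param jitter patch-center jitter as a fraction of the patch extent per
#'   axis (uniform, integer voxels).
#' @param p_flip,p_rot per-axis flip probability and in-plane 90-degree
#'   rotation probability of the augmentation sampler.
#' @param max_shift maximum in-plane integer translation in voxels.
#' @param interp_order_image,interp_order_mask spline interpolation orders
#'   (3 = cubic spline for images, 0 = nearest for masks).
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(clip_low_pct = 0.5, clip_high_pct = 99.5,
                              target_spacing = c(5, 0.741, 0.741),
                              patch_shape = c(28L, 256L, 256L),
                              jitter = 0.25,
                              p_flip = 0.5, p_rot = 0.25, max_shift = 5L,
                              interp_order_image = 3L,
                              interp_order_mask = 0L) {
  stopifnot(clip_low_pct >= 0, clip_low_pct < clip_high_pct,
            clip_high_pct <= 100, all(patch_shape >= 8),
            all(target_spacing > 0))
  structure(list(clip_low_pct = clip_low_pct, clip_high_pct = clip_high_pct,
                 target_spacing = as.numeric(target_spacing),
                 patch_shape = as.integer(patch_shape), jitter = jitter,
                 p_flip = p_flip, p_rot = p_rot,
                 max_shift = as.integer(max_shift),
                 interp_order_image = as.integer(interp_order_image),
                 interp_order_mask = as.integer(interp_order_mask)),
            class = "preprocess_config")
}

#' Read or write a preprocessing configuration as YAML
#' @param path YAML file path.
#' @return `read_preprocess_config()` returns a `preprocess_config`.
#' @export
read_preprocess_config <- function(path) {
  do.call(preprocess_config, yaml::read_yaml(path))
}

#' @rdname read_preprocess_config
#' @param cfg a `preprocess_config`.
#' @export
write_preprocess_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Clip to foreground percentiles and z-score
#'
#' Intensities are clamped to the low/high percentiles of the foreground
#' voxels (linear interpolation between order statistics), then z-scored by
#' the mean and SD of the clamped foreground. A zero-variance foreground
#' yields an all-zero volume.
#'
#' @param vol a `volume3d`.
#' @param fg a `seg_mask` marking foreground voxels (>= 1 voxel set).
#' @param low,high clipping percentiles.
#' @return A normalized `volume3d` on the same grid.
#' @export
clip_normalize <- function(vol, fg, low = 0.5, high = 99.5) {
  stopifnot(inherits(vol, "volume3d"))
  m <- mask_array(fg)
  check_same_shape(vol$data, m)
  if (sum(m) == 0) stop("empty foreground mask")
  st <- norm_stats_from_values(vol$data[m == 1], low, high)
  apply_norm_stats(vol, st)
}

norm_stats_from_values <- function(vals, low = 0.5, high = 99.5) {
  b <- stats::quantile(vals, c(low, high) / 100, type = 7, names = FALSE)
  cl <- pmin(pmax(vals, b[1]), b[2])
  list(lo = b[1], hi = b[2], mean = mean(cl), sd = stats::sd(cl))
}

#' Cohort normalization statistics
#'
#' Pools the foreground intensities of a set of labeled volumes and returns
#' the clipping bounds and z-score statistics computed on the pooled sample.
#' Applying one set of cohort statistics to every volume (source and target
#' alike) preserves genuine inter-domain intensity shifts, which per-volume
#' normalization would erase.
#'
#' @param vols list of `volume3d`.
#' @param masks list of matching `seg_mask` foreground masks.
#' @param low,high clipping percentiles.
#' @return A list with `lo`, `hi`, `mean`, `sd`.
#' @export
cohort_norm_stats <- function(vols, masks, low = 0.5, high = 99.5) {
  vals <- unlist(lapply(seq_along(vols), function(i) {
    m <- mask_array(masks[[i]])
    vols[[i]]$data[m == 1]
  }))
  if (length(vals) == 0) stop("empty foreground mask")
  norm_stats_from_values(vals, low, high)
}

#' @rdname cohort_norm_stats
#' @param vol a `volume3d` to normalize with precomputed statistics `st`.
#' @param st statistics from `cohort_norm_stats()`.
#' @export
apply_norm_stats <- function(vol, st) {
  x <- pmin(pmax(vol$data, st$lo), st$hi)
  x <- if (is.na(st$sd) || st$sd == 0) array(0, dim(x)) else (x - st$mean) / st$sd
  volume3d(x, vol$spacing, vol$origin)
}

# 1D interpolation of all lines of `a` along `axis` at fractional input
# coordinates `xout` (0-based voxel units). Interpolation is linear in the
# data, so the per-axis operator is built once (by interpolating the unit
# basis) and applied to every line as a single matrix product.
interp_axis <- function(a, axis, xout, order) {
  dm <- dim(a)
  n <- dm[axis]
  perm <- c(axis, setdiff(1:3, axis))
  ap <- aperm(a, perm)
  dim(ap) <- c(n, prod(dm[-axis]))
  out <- if (order == 0) {
    idx <- pmin(pmax(round(xout), 0), n - 1) + 1
    ap[idx, , drop = FALSE]
  } else if (n == 1) {
    ap[rep(1, length(xout)), , drop = FALSE]
  } else {
    S <- interp_operator(n, xout, order)
    S %*% ap
  }
  dim(out) <- c(length(xout), dm[-axis])
  aperm(out, order(perm))
}

interp_operator <- function(n, xout, order) {
  xi <- seq_len(n) - 1
  xc <- pmin(pmax(xout, 0), n - 1)
  basis <- diag(n)
  cols <- lapply(seq_len(n), function(j) {
    if (order == 1 || n < 4) {
      stats::approx(xi, basis[, j], xout = xc, rule = 2)$y
    } else {
      stats::spline(xi, basis[, j], xout = xc, method = "fmm")$y
    }
  })
  do.call(cbind, cols)
}

#' Resample a volume to a target voxel spacing
#'
#' Separable per-axis interpolation on a node-centered grid: cubic splines
#' (order 3) for images, linear (order 1), or nearest neighbor (order 0,
#' which preserves \{0,1\} masks). The output shape per axis is
#' `round(shape * spacing / target_spacing)`.
#'
#' @param vol a `volume3d` or `seg_mask`.
#' @param target_spacing (sz, sy, sx) in mm, all positive.
#' @param order interpolation order, one of 0, 1, 3.
#' @return The resampled volume on the target grid.
#' @export
resample <- function(vol, target_spacing, order = 3L) {
  stopifnot(inherits(vol, "volume3d"), order %in% c(0L, 1L, 3L))
  if (any(!is.finite(target_spacing)) || any(target_spacing <= 0))
    stop("target spacing must be positive")
  dm <- dim(vol$data)
  out_shape <- pmax(1L, as.integer(round(dm * vol$spacing / target_spacing)))
  if (all(out_shape == dm) && all(vol$spacing == target_spacing)) {
    out <- vol$data
  } else {
    out <- vol$data
    for (axis in 1:3) {
      xout <- (seq_len(out_shape[axis]) - 1) * target_spacing[axis] / vol$spacing[axis]
      out <- interp_axis(out, axis, xout, order)
    }
  }
  if (inherits(vol, "seg_mask")) {
    seg_mask(array(as.integer(out > 0.5), dim(out)), target_spacing, vol$origin)
  } else {
    volume3d(out, target_spacing, vol$origin)
  }
}

mask_centroid <- function(mask) {
  ctr <- attr(mask, "centroid")
  if (!is.null(ctr)) return(ctr)
  m <- mask_array(mask)
  idx <- which(m == 1, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("empty mask")
  round(colMeans(idx)) - 1  # 0-based
}

# Precompute and attach the centroid (drawn on every patch otherwise).
cache_centroid <- function(mask) {
  if (is.null(mask) || sum(mask_array(mask)) == 0) return(mask)
  attr(mask, "centroid") <- mask_centroid(mask)
  mask
}

# Crop with zero padding; start is 0-based. Clamped into the volume where
# the patch fits, padded where it does not.
crop_with_pad <- function(arr, start, shape) {
  dm <- dim(arr)
  start <- pmin(pmax(start, 0), pmax(dm - shape, 0))
  out <- array(0, shape)
  lo_in <- pmax(start, 0) + 1
  hi_in <- pmin(start + shape, dm)
  lo_out <- lo_in - start
  hi_out <- hi_in - start
  out[lo_out[1]:hi_out[1], lo_out[2]:hi_out[2], lo_out[3]:hi_out[3]] <-
    arr[lo_in[1]:hi_in[1], lo_in[2]:hi_in[2], lo_in[3]:hi_in[3]]
  out
}

#' Extract a tumor-centered training patch
#'
#' The patch is centered on the tumor centroid plus a seeded uniform integer
#' jitter of at most `cfg$jitter` times the patch extent per axis. The patch
#' is clamped into the volume where it fits and zero-padded where the volume
#' is smaller than the patch; the mask is cropped identically.
#'
#' @param vol a `volume3d`.
#' @param mask its `seg_mask` (nonempty).
#' @param cfg a [preprocess_config()].
#' @param seed integer seed making the jitter reproducible.
#' @return `list(volume, mask)` of shape `cfg$patch_shape`.
#' @export
extract_patch <- function(vol, mask, cfg, seed = 0L) {
  ctr <- mask_centroid(mask)  # errors on empty mask
  shape <- cfg$patch_shape
  jit <- with_seed(seed, {
    jmax <- floor(cfg$jitter * shape)
    vapply(jmax, function(j) if (j > 0) sample(seq(-j, j), 1) else 0L, numeric(1))
  })
  start <- ctr - shape %/% 2 + jit
  list(volume = volume3d(crop_with_pad(vol$data, start, shape), vol$spacing),
       mask = seg_mask(array(as.integer(
         crop_with_pad(mask_array(mask), start, shape)), shape), vol$spacing))
}

# Uniform random patch for unlabeled volumes (no centroid available).
extract_patch_random <- function(vol, patch_shape, seed = 0L) {
  dm <- dim(vol$data)
  start <- with_seed(seed, vapply(pmax(dm - patch_shape, 0), function(r)
    if (r > 0) sample(0:r, 1) else 0L, numeric(1)))
  volume3d(crop_with_pad(vol$data, start, patch_shape), vol$spacing)
}

#' Apply a deterministic spatial transform
#'
#' Flips, an in-plane (y,x) rotation by multiples of 90 degrees, and an
#' integer in-plane translation with zero fill, in that order. Used by
#' [augment()]; exposed so individual transforms can be applied directly.
#'
#' @param arr 3D array (z, y, x).
#' @param flips logical length-3 vector: flip each axis.
#' @param rot_k in-plane quarter-turns (0-3); 90/270 require a square y-x
#'   plane.
#' @param shift integer (dy, dx) translation.
#' @return The transformed array (same shape).
#' @export
spatial_transform <- function(arr, flips = c(FALSE, FALSE, FALSE), rot_k = 0L,
                              shift = c(0L, 0L)) {
  dm <- dim(arr)
  if (flips[1]) arr <- arr[dm[1]:1, , , drop = FALSE]
  if (flips[2]) arr <- arr[, dm[2]:1, , drop = FALSE]
  if (flips[3]) arr <- arr[, , dm[3]:1, drop = FALSE]
  rot_k <- rot_k %% 4L
  if (rot_k > 0) {
    if (dm[2] != dm[3] && rot_k %% 2 == 1)
      stop("90-degree in-plane rotation requires a square y-x plane")
    for (i in seq_len(rot_k)) {
      arr <- aperm(arr, c(1, 3, 2))       # transpose (y,x)
      arr <- arr[, dim(arr)[2]:1, , drop = FALSE]  # then flip y: 90 deg
    }
  }
  if (any(shift != 0)) {
    out <- array(0, dim(arr))
    src_y <- intersect(seq_len(dm[2]) - shift[1], seq_len(dm[2]))
    src_x <- intersect(seq_len(dm[3]) - shift[2], seq_len(dm[3]))
    out[, src_y + shift[1], src_x + shift[2]] <- arr[, src_y, src_x]
    arr <- out
  }
  arr
}

#' Seeded online augmentation
#'
#' Samples one spatial transform (per-axis flips with probability
#' `cfg$p_flip`, an in-plane 90-degree rotation with probability
#' `cfg$p_rot`, and integer in-plane translations up to `cfg$max_shift`
#' voxels) and applies it identically to image and mask. Deterministic per
#' seed; the mask stays binary.
#'
#' @param img a `volume3d` patch.
#' @param mask its `seg_mask` (same shape).
#' @param cfg a [preprocess_config()].
#' @param seed integer seed.
#' @return `list(volume, mask, transform)`.
#' @export
augment <- function(img, mask, cfg, seed = 0L) {
  check_same_shape(img$data, mask$data)
  dm <- dim(img$data)
  tf <- with_seed(seed, {
    flips <- stats::runif(3) < cfg$p_flip
    rot_ok <- dm[2] == dm[3]
    rot_k <- if (stats::runif(1) < cfg$p_rot)
      sample(if (rot_ok) 1:3 else 2L, 1) else 0L
    shift <- if (cfg$max_shift > 0)
      c(sample(seq(-cfg$max_shift, cfg$max_shift), 1),
        sample(seq(-cfg$max_shift, cfg$max_shift), 1)) else c(0L, 0L)
    list(flips = flips, rot_k = rot_k, shift = shift)
  })
  av <- spatial_transform(img$data, tf$flips, tf$rot_k, tf$shift)
  am <- spatial_transform(mask_array(mask), tf$flips, tf$rot_k, tf$shift)
  list(volume = volume3d(av, img$spacing),
       mask = seg_mask(array(as.integer(am), dm), img$spacing),
       transform = tf)
}
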