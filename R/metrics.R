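# Segmentation evaluation metrics: volume-overlap (Dice, Jaccard) and
# physical surface-distance (average surface distance, 95th-percentile
# Hausdorff) metrics with anisotropic voxel spacing.

mask_array <- function(m) {
  a <- if (inherits(m, "seg_mask") || inherits(m, "volume3d")) m$data else m
  storage.mode(a) <- "integer"
  a
}

check_same_shape <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop("prediction and ground truth have different shapes")
}

#' Dice similarity coefficient (percent)
#'
#' `200 * |P & G| / (|P| + |G|)`. Two empty masks score 100 by convention.
#'
#' @param pred,gt binary arrays (or `seg_mask` objects) of equal shape.
#' @return DSC in percent, in `[0, 100]`.
#' @export
dsc <- function(pred, gt) {
  p <- mask_array(pred); g <- mask_array(gt)
  check_same_shape(p, g)
  den <- sum(p) + sum(g)
  if (den == 0) return(100)
  200 * sum(p & g) / den
}

#' Jaccard index (percent)
#'
#' `100 * |P & G| / |P | G|`. Two empty masks score 100 by convention.
#'
#' @inheritParams dsc
#' @return JI in percent, in `[0, 100]`.
#' @export
jaccard <- function(pred, gt) {
  p <- mask_array(pred); g <- mask_array(gt)
  check_same_shape(p, g)
  un <- sum(p | g)
  if (un == 0) return(100)
  100 * sum(p & g) / un
}

# Physical-coordinate surface point sets of a mask. Surface voxels are
# foreground voxels with a face-adjacent background voxel (the outside of
# the grid counts as background).
surface_coords <- function(mask, spacing) {
  m <- mask_array(mask)
  pts <- cpp_surface_points(as.integer(m), dim(m))
  sweep(matrix(as.numeric(pts), nrow(pts), 3), 2, spacing, "*")
}

directed_surface_dists <- function(pred, gt, spacing) {
  p <- mask_array(pred); g <- mask_array(gt)
  check_same_shape(p, g)
  if (sum(p) == 0 || sum(g) == 0)
    stop("surface-distance metrics are undefined for an empty mask",
         call. = FALSE)
  A <- surface_coords(p, spacing)
  B <- surface_coords(g, spacing)
  list(ab = cpp_min_dists(A, B), ba = cpp_min_dists(B, A))
}

#' Average surface distance (mm)
#'
#' Half the sum of the two directed mean surface distances: the mean nearest
#' distance from prediction-surface points to the ground-truth surface, and
#' vice versa, in physical (spacing-scaled) coordinates.
#'
#' @inheritParams dsc
#' @param spacing voxel spacing (sz, sy, sx) in mm.
#' @return ASD in mm; errors if either mask is empty.
#' @export
asd <- function(pred, gt, spacing) {
  d <- directed_surface_dists(pred, gt, spacing)
  0.5 * (mean(d$ab) + mean(d$ba))
}

#' 95th-percentile Hausdorff distance (mm)
#'
#' Maximum of the two directed 95th-percentile surface distances
#' (percentiles by linear interpolation between order statistics).
#'
#' @inheritParams asd
#' @return HD95 in mm; errors if either mask is empty.
#' @export
hd95 <- function(pred, gt, spacing) {
  d <- directed_surface_dists(pred, gt, spacing)
  max(stats::quantile(d$ab, 0.95, type = 7, names = FALSE),
      stats::quantile(d$ba, 0.95, type = 7, names = FALSE))
}

#' Per-case metrics report with mean +/- SD summary
#'
#' @param preds,gts lists of binary masks (equal shapes pairwise).
#' @param spacing voxel spacing (sz, sy, sx) in mm, or a list of per-case
#'   spacings.
#' @param ids optional case identifiers.
#' @return A data.frame of class `metrics_report` with one row per case
#'   (columns `id, DSC, JI, ASD, HD95, distance_defined`); surface metrics
#'   are `NA` where either mask is empty. Summary rows are available via
#'   `summary()`.
#' @export
metrics_report <- function(preds, gts, spacing, ids = NULL) {
  stopifnot(length(preds) == length(gts))
  n <- length(preds)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  sp <- if (is.list(spacing)) spacing else rep(list(spacing), n)
  rows <- lapply(seq_len(n), function(i) {
    p <- preds[[i]]; g <- gts[[i]]
    ok <- sum(mask_array(p)) > 0 && sum(mask_array(g)) > 0
    data.frame(id = ids[i],
               DSC = dsc(p, g),
               JI = jaccard(p, g),
               ASD = if (ok) asd(p, g, sp[[i]]) else NA_real_,
               HD95 = if (ok) hd95(p, g, sp[[i]]) else NA_real_,
               distance_defined = ok)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("metrics_report", class(out))
  out
}

#' @export
summary.metrics_report <- function(object, ...) {
  agg <- function(v) c(mean = mean(v, na.rm = TRUE), sd = stats::sd(v, na.rm = TRUE))
  out <- rbind(DSC = agg(object$DSC), JI = agg(object$JI),
               ASD = agg(object$ASD), HD95 = agg(object$HD95))
  as.data.frame(out)
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("Segmentation metrics (", nrow(x), " cases)\n", sep = "")
  print.data.frame(x, digits = 4, row.names = FALSE)
  s <- summary(x)
  cat("\nmean ± SD:\n")
  for (m in rownames(s))
    cat(sprintf("  %-5s %7.2f ± %.2f\n", m, s[m, "mean"], s[m, "sd"]))
  invisible(x)
}
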