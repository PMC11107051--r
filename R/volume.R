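# Volume containers and NIfTI input/output.
#
# A volume3d is a list(data, spacing, origin): `data` is a numeric array
# indexed (z, y, x), `spacing` the per-axis voxel size (sz, sy, sx) in mm,
# `origin` a physical offset in mm. A seg_mask is the same on a {0,1} grid,
# sharing the lattice of its paired volume.

#' Construct a 3D volume
#'
#' @param data numeric 3D array indexed (z, y, x).
#' @param spacing voxel spacing (sz, sy, sx) in mm, all positive and finite.
#' @param origin physical offset in mm.
#' @return An object of class `volume3d`.
#' @export
volume3d <- function(data, spacing, origin = c(0, 0, 0)) {
  stopifnot(is.array(data), length(dim(data)) == 3,
            length(spacing) == 3, all(is.finite(spacing)), all(spacing > 0),
            length(origin) == 3)
  structure(list(data = data, spacing = as.numeric(spacing),
                 origin = as.numeric(origin)),
            class = "volume3d")
}

#' Construct a binary segmentation mask
#'
#' @param data array with values in \{0, 1\} indexed (z, y, x).
#' @inheritParams volume3d
#' @return An object of class `seg_mask` (also a `volume3d`).
#' @export
seg_mask <- function(data, spacing, origin = c(0, 0, 0)) {
  stopifnot(all(data %in% c(0, 1)))
  storage.mode(data) <- "integer"
  out <- volume3d(data, spacing, origin)
  class(out) <- c("seg_mask", class(out))
  out
}

#' @export
print.volume3d <- function(x, ...) {
  cat(if (inherits(x, "seg_mask")) "seg_mask" else "volume3d",
      paste(dim(x$data), collapse = " x "),
      "voxels, spacing", paste(signif(x$spacing, 4), collapse = " x "), "mm\n")
  if (inherits(x, "seg_mask"))
    cat("  foreground voxels:", sum(x$data), "\n")
  invisible(x)
}

#' Read a NIfTI volume (and optional mask)
#'
#' Axes are reordered to (z, y, x) and the spacing is taken from the header.
#' A mask, if given, is binarized (any value > 0 becomes 1) and must match
#' the image grid.
#'
#' @param path path to a NIfTI image (.nii or .nii.gz).
#' @param mask_path optional path to a NIfTI label volume.
#' @return A `volume3d`, or `list(volume, mask)` when `mask_path` is given.
#' @export
read_volume <- function(path, mask_path = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) == 4 && dim(arr)[4] == 1) dim(arr) <- dim(arr)[1:3]
  if (length(dim(arr)) != 3) stop("expected a 3D image: ", path)
  sp <- RNifti::pixdim(img)[1:3]          # (sx, sy, sz)
  vol <- volume3d(aperm(arr, c(3, 2, 1)), rev(sp))
  if (is.null(mask_path)) return(vol)
  if (!file.exists(mask_path)) stop("file not found: ", mask_path)
  mimg <- RNifti::readNifti(mask_path)
  marr <- as.array(mimg)
  if (length(dim(marr)) == 4 && dim(marr)[4] == 1) dim(marr) <- dim(marr)[1:3]
  if (length(dim(marr)) != 3) stop("expected a 3D mask: ", mask_path)
  if (!identical(dim(marr), dim(arr)))
    stop("mask shape (", paste(dim(marr), collapse = "x"),
         ") does not match image shape (", paste(dim(arr), collapse = "x"), ")")
  m <- aperm(marr, c(3, 2, 1))
  mask <- seg_mask(array(as.integer(m > 0), dim(m)), rev(sp))
  list(volume = vol, mask = mask)
}

#' Write a volume or mask to NIfTI
#'
#' @param vol a `volume3d` or `seg_mask`.
#' @param path output path (.nii or .nii.gz).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "volume3d"))
  arr <- aperm(vol$data, c(3, 2, 1))
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- rev(vol$spacing)
  RNifti::writeNifti(img, path)
  invisible(path)
}
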