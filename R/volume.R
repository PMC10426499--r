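#' Construct a volume-with-mask object
#'
#' The basic image container of the pipeline: a 3D intensity volume in
#' Hounsfield units, its voxel spacing in millimetres, and an aligned binary
#' region-of-interest mask of the same shape.
#'
#' @param intensities 3D numeric array of HU values.
#' @param spacing numeric length-3, mm per voxel along each axis (all > 0).
#' @param mask 3D logical (or 0/1) array, same shape as `intensities`, with at
#'   least one foreground voxel.
#' @return An object of class `volume_with_mask` with elements `intensities`,
#'   `spacing`, `mask`.
#' @export
volume_with_mask <- function(intensities, spacing, mask) {
  if (length(dim(intensities)) != 3L)
    stop("intensities must be a 3D array")
  spacing <- as.numeric(spacing)
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("spacing must be 3 positive numbers (mm)")
  if (!identical(dim(mask), dim(intensities)))
    stop("mask and intensities must have identical dimensions")
  m <- array(as.logical(mask), dim = dim(mask))
  if (anyNA(m)) stop("mask must be binary with no missing values")
  if (!any(m)) stop("mask must contain at least one foreground voxel")
  structure(list(intensities = intensities, spacing = spacing, mask = m),
            class = "volume_with_mask")
}

#' @exportS3Method base::print
print.volume_with_mask <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf("<volume_with_mask> %d x %d x %d voxels, spacing %s mm, %d ROI voxels\n",
              d[1], d[2], d[3], paste(format(x$spacing), collapse = " x "),
              sum(x$mask)))
  invisible(x)
}

# Bounding box of the mask: list(min, max, nvox) of 1-based voxel indices
# per axis.
mask_bbox <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  mn <- apply(idx, 2, min)
  mx <- apply(idx, 2, max)
  list(min = mn, max = mx, nvox = mx - mn + 1L)
}

# Margin (voxels) between the mask bounding box and the volume boundary,
# per axis and side. Phantoms guarantee >= 35% of the bbox length so that
# maximal (30%) translations never clip.
mask_margins <- function(v) {
  bb <- mask_bbox(v$mask)
  d <- dim(v$mask)
  cbind(low = bb$min - 1L, high = d - bb$max)
}
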