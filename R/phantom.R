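#' Phantom cohort configuration
#'
#' Describes a synthetic two-class cohort of hollow-shell ROIs (mimicking a
#' left-ventricular wall) over textured volumes. Each class draws its shell
#' intensities from a smoothed Gaussian random field with a class-specific
#' mean (HU), standard deviation (HU) and texture correlation length (mm);
#' texture is generated by filtering white noise with a Gaussian kernel of the
#' configured correlation length, giving one-knob control of textural feature
#' values.
#'
#' Defaults emulate the study setting this package targets: a balanced
#' 15 + 15 cohort of contrast-enhanced myocardium-like shells (about 140 HU,
#' SD 25 HU) where the two phenotypes differ in texture scale only (coarser
#' texture for the positive class), so that textural features drive the
#' classification. Shape differences between classes are available through
#' `inner_scale` but are off by default.
#'
#' @param n_per_class subjects per class (>= 2).
#' @param grid_shape voxels per axis of the generated volume.
#' @param voxel_spacing mm per voxel (length 1 or 3).
#' @param outer,inner outer/inner ellipsoid semi-axes in mm; the ROI is the
#'   shell between them, so `inner` must be strictly smaller than `outer`.
#' @param class_params named list with entries `CA` (label 1, positive class)
#'   and `AS` (label 0); each a list with `mean`, `sd`, `corr_len` (mm) and
#'   optional `inner_scale` (multiplies the inner semi-axes, changing wall
#'   thickness; default 1).
#' @param background list with `mean` and `sd` (HU) of the tissue outside the
#'   shell.
#' @param fill `"shell"` (default): the textured field exists only inside the
#'   ROI, with plain background noise outside — translated ROIs sample the
#'   background. `"full"`: the class's stationary field fills the whole
#'   volume, so translated ROIs sample statistically identical texture; this
#'   is the setting for translation-robustness experiments.
#' @param seed integer RNG seed; identical seeds give bit-identical cohorts.
#' @return A `phantom_config` object.
#' @export
phantom_config <- function(n_per_class = 15L,
                           grid_shape = c(72L, 72L, 92L),
                           voxel_spacing = c(1, 1, 1),
                           outer = c(20, 20, 26),
                           inner = c(13, 13, 19),
                           class_params = list(
                             CA = list(mean = 140, sd = 25, corr_len = 5),
                             AS = list(mean = 140, sd = 25, corr_len = 2.5)),
                           background = list(mean = 40, sd = 10),
                           fill = c("shell", "full"),
                           seed = 1L) {
  fill <- match.arg(fill)
  voxel_spacing <- as.numeric(voxel_spacing)
  if (length(voxel_spacing) == 1L) voxel_spacing <- rep(voxel_spacing, 3L)
  stopifnot(n_per_class >= 2L, length(grid_shape) == 3L,
            length(outer) == 3L, length(inner) == 3L,
            all(voxel_spacing > 0))
  if (!all(inner < outer))
    stop("inner semi-axes must be strictly smaller than outer semi-axes")
  if (!all(c("CA", "AS") %in% names(class_params)))
    stop("class_params must have entries 'CA' and 'AS'")
  for (nm in c("CA", "AS")) {
    cp <- class_params[[nm]]
    stopifnot(all(c("mean", "sd", "corr_len") %in% names(cp)))
    if (is.null(cp$inner_scale)) class_params[[nm]]$inner_scale <- 1
  }
  structure(list(n_per_class = as.integer(n_per_class),
                 grid_shape = as.integer(grid_shape),
                 voxel_spacing = voxel_spacing,
                 outer = as.numeric(outer), inner = as.numeric(inner),
                 class_params = class_params, background = background,
                 fill = fill, seed = as.integer(seed)),
            class = "phantom_config")
}

# Ellipsoid-shell mask on the voxel grid, centred on the volume centre.
shell_mask <- function(grid_shape, spacing, outer, inner) {
  ctr <- (grid_shape + 1) / 2
  ax <- lapply(1:3, function(a) ((seq_len(grid_shape[a]) - ctr[a]) * spacing[a]))
  X2o <- outer(outer((ax[[1]] / outer[1])^2, (ax[[2]] / outer[2])^2, "+"),
               (ax[[3]] / outer[3])^2, "+")
  X2i <- outer(outer((ax[[1]] / inner[1])^2, (ax[[2]] / inner[2])^2, "+"),
               (ax[[3]] / inner[3])^2, "+")
  X2o <= 1 & X2i > 1
}

# Analytic shell volume in mm^3 (difference of ellipsoid volumes).
shell_volume_analytic <- function(outer, inner) {
  4 / 3 * pi * (prod(outer) - prod(inner))
}

#' Generate a synthetic phantom cohort
#'
#' Draws `2 * n_per_class` subjects. Each subject is a volume of background
#' noise with an ellipsoid-shell ROI whose interior is a stationary Gaussian
#' random field: white noise filtered by a Gaussian kernel with the class's
#' correlation length, renormalised to the class SD and shifted to the class
#' mean. The mask bounding box is guaranteed to keep a margin of at least 35%
#' of its own length to the volume boundary on every axis, so maximal (30%)
#' ROI translations stay in bounds.
#'
#' @param config a [phantom_config()].
#' @return list of subjects; each a list with `id`, `volume`
#'   (a [volume_with_mask()]) and `label` (1 = CA, 0 = AS).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(config$seed)
  gs <- config$grid_shape
  sp <- config$voxel_spacing
  n <- prod(gs)
  subjects <- list()
  k <- 0L
  for (cls in c("CA", "AS")) {
    cp <- config$class_params[[cls]]
    msk <- shell_mask(gs, sp, config$outer, config$inner * cp$inner_scale)
    if (!any(msk)) stop("geometry yields an empty shell for class ", cls)
    bb <- mask_bbox(msk)
    marg <- cbind(bb$min - 1L, gs - bb$max)
    need <- ceiling(0.35 * bb$nvox)
    if (any(marg < need))
      stop("phantom grid too small: mask margin below 35% of the bounding box")
    sig_vox <- cp$corr_len / sp
    rad <- pmax(1L, as.integer(ceiling(3 * sig_vox)))
    for (i in seq_len(config$n_per_class)) {
      k <- k + 1L
      field <- .cpp_gaussian_smooth(array(rnorm(n), dim = gs), gs,
                                    sig_vox, rad)
      field <- field / sd(field)
      if (config$fill == "full") {
        vol <- cp$mean + cp$sd * field
      } else {
        vol <- config$background$mean + config$background$sd * rnorm(n)
        dim(vol) <- gs
        vol[msk] <- cp$mean + cp$sd * field[msk]
      }
      subjects[[k]] <- list(
        id = sprintf("S%02d", k),
        volume = volume_with_mask(vol, sp, msk),
        label = if (cls == "CA") 1L else 0L)
    }
  }
  subjects
}
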