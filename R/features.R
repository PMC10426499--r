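#' Feature-extraction configuration
#'
#' @param bin_width fixed histogram bin width in HU (> 0, default 0.5) used to
#'   discretize intensities before first-order entropy/uniformity and all
#'   texture matrices.
#' @export
extraction_config <- function(bin_width = 0.5) {
  stopifnot(is.numeric(bin_width), length(bin_width) == 1L, bin_width > 0)
  structure(list(bin_width = bin_width), class = "extraction_config")
}

#' Read the pinned extraction configuration
#'
#' Loads the extraction-parameter file shipped with the package (or a
#' user-supplied YAML file with a `bin_width` field). The shipped file pins
#' the exact settings used throughout: 0.5 HU fixed bin width, all feature
#' classes enabled, distance-1 full-3D texture neighbourhoods.
#'
#' @param path YAML parameter file; defaults to the in-package file.
#' @export
read_extraction_config <- function(path = system.file("extdata",
                                                      "extraction.yaml",
                                                      package = "radiostab")) {
  prm <- yaml::read_yaml(path)
  extraction_config(bin_width = prm$bin_width)
}

# Fixed-bin-width discretization: bin 1 holds the minimum's bin, levels are
# consecutive integers from there (gaps allowed for unoccupied bins).
discretize_fbw <- function(x, bin_width) {
  as.integer(floor(x / bin_width) - floor(min(x) / bin_width) + 1)
}

feature_class_of_family <- c(shape = "shape-size", firstorder = "first-order",
                             glcm = "textural", glrlm = "textural",
                             glszm = "textural", gldm = "textural",
                             ngtdm = "textural")

# Namespaced feature name: <class>/<family>/<name>.
feat_names <- function(family, names) {
  paste(feature_class_of_family[[family]], family, names, sep = "/")
}

#' Feature class of each feature name
#'
#' @param feature_names character vector of namespaced feature names.
#' @return character vector of classes
#'   (`shape-size`, `first-order`, `textural`).
#' @export
feature_classes <- function(feature_names) {
  vapply(strsplit(feature_names, "/", fixed = TRUE), `[[`, "", 1L)
}

#' Extract the 107 radiomic features from a volume
#'
#' Computes the standard 107-feature set: 14 shape-size, 18 first-order, and
#' 75 textural features (24 GLCM, 16 GLRLM, 16 GLSZM, 14 GLDM, 5 NGTDM),
#' following the IBSI-style definitions used by the common 3D extractors.
#' GLCM and GLRLM are accumulated over the 13 unique 3D directions at
#' distance 1 and feature values averaged over directions; GLSZM zones use
#' 26-connectivity; GLDM uses distance 1 with equal-level dependence
#' (the dependence size counts the centre voxel, so it starts at 1); NGTDM
#' uses the 26-neighbourhood. Gray levels are the fixed-bin-width bins of
#' [extraction_config()].
#'
#' @param v a preprocessed [volume_with_mask()] with at least 2 ROI voxels.
#' @param cfg an [extraction_config()].
#' @return named numeric vector of length 107 with attribute `class_of`
#'   (named character vector of feature classes).
#' @export
extract_features <- function(v, cfg = extraction_config()) {
  stopifnot(inherits(v, "volume_with_mask"))
  if (sum(v$mask) < 2L)
    stop("mask must contain at least 2 voxels (texture undefined)")
  x <- v$intensities[v$mask]
  sp <- v$spacing
  vox_vol <- prod(sp)

  shape <- shape_features(v$mask, sp)
  fo <- firstorder_features(x, vox_vol, cfg$bin_width)

  # discretized, cropped integer image (0 outside mask) for texture matrices
  bb <- mask_bbox(v$mask)
  sub_m <- v$mask[bb$min[1]:bb$max[1], bb$min[2]:bb$max[2], bb$min[3]:bb$max[3],
                  drop = FALSE]
  sub_i <- v$intensities[bb$min[1]:bb$max[1], bb$min[2]:bb$max[2],
                         bb$min[3]:bb$max[3], drop = FALSE]
  g <- array(0L, dim = dim(sub_m))
  g[sub_m] <- discretize_fbw(sub_i[sub_m], cfg$bin_width)
  ng <- max(g)
  dims <- dim(g)

  tex <- c(glcm_features(g, dims, ng),
           glrlm_features(g, dims, ng, np = sum(sub_m)),
           glszm_features(g, dims, np = sum(sub_m)),
           gldm_features(g, dims, ng),
           ngtdm_features(g, dims, ng))

  out <- c(shape, fo, tex)
  if (any(!is.finite(out)))
    out[!is.finite(out)] <- 0  # degenerate ROIs: report 0, never NaN/Inf
  attr(out, "class_of") <- setNames(feature_classes(names(out)), names(out))
  out
}

# ---- shape-size (14) ------------------------------------------------------

shape_features <- function(mask, sp) {
  d <- dim(mask)
  n <- sum(mask)
  vox_vol <- prod(sp)
  V <- n * vox_vol
  surf <- .cpp_surface(mask, d)
  faces <- surf$faces  # exposed faces orthogonal to x, y, z
  A <- faces[1] * sp[2] * sp[3] + faces[2] * sp[1] * sp[3] +
       faces[3] * sp[1] * sp[2]
  idx <- which(mask, arr.ind = TRUE)
  phys <- sweep(idx, 2, sp, "*")
  if (n >= 2) {
    ev <- sort(eigen(stats::cov(phys), symmetric = TRUE,
                     only.values = TRUE)$values, decreasing = TRUE)
    ev <- pmax(ev, 0)
  } else ev <- c(0, 0, 0)
  spts <- sweep(surf$coords + 1, 2, sp, "*")
  max3d <- .cpp_max_pairwise_dist(spts, integer(0))
  d2_slice <- .cpp_max_pairwise_dist(spts, surf$coords[, 3])
  d2_col <- .cpp_max_pairwise_dist(spts, surf$coords[, 1])
  d2_row <- .cpp_max_pairwise_dist(spts, surf$coords[, 2])
  vals <- c(
    MeshVolume = V,           # voxel-based approximation of the mesh volume
    VoxelVolume = V,
    SurfaceArea = A,
    SurfaceVolumeRatio = A / V,
    Sphericity = (36 * pi * V^2)^(1 / 3) / A,
    Maximum3DDiameter = max3d,
    Maximum2DDiameterSlice = d2_slice,
    Maximum2DDiameterColumn = d2_col,
    Maximum2DDiameterRow = d2_row,
    MajorAxisLength = 4 * sqrt(ev[1]),
    MinorAxisLength = 4 * sqrt(ev[2]),
    LeastAxisLength = 4 * sqrt(ev[3]),
    Elongation = if (ev[1] > 0) sqrt(ev[2] / ev[1]) else 0,
    Flatness = if (ev[1] > 0) sqrt(ev[3] / ev[1]) else 0)
  setNames(vals, feat_names("shape", names(vals)))
}

# ---- first-order (18) -----------------------------------------------------

firstorder_features <- function(x, vox_vol, bin_width) {
  n <- length(x)
  g <- discretize_fbw(x, bin_width)
  p <- tabulate(g) / n
  p <- p[p > 0]
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  m3 <- mean((x - mu)^3)
  m4 <- mean((x - mu)^4)
  qs <- quantile(x, c(0.10, 0.25, 0.5, 0.75, 0.90), names = FALSE)
  mid <- x[x >= qs[1] & x <= qs[5]]
  vals <- c(
    Energy = sum(x^2),
    TotalEnergy = vox_vol * sum(x^2),
    Entropy = -sum(p * log2(p)),
    Minimum = min(x),
    `10Percentile` = qs[1],
    `90Percentile` = qs[5],
    Maximum = max(x),
    Mean = mu,
    Median = qs[3],
    InterquartileRange = qs[4] - qs[2],
    Range = max(x) - min(x),
    MeanAbsoluteDeviation = mean(abs(x - mu)),
    RobustMeanAbsoluteDeviation = mean(abs(mid - mean(mid))),
    RootMeanSquared = sqrt(mean(x^2)),
    Skewness = if (m2 > 0) m3 / m2^1.5 else 0,
    Kurtosis = if (m2 > 0) m4 / m2^2 else 0,
    Variance = m2,
    Uniformity = sum(p^2))
  setNames(vals, feat_names("firstorder", names(vals)))
}

# ---- GLCM (24) ------------------------------------------------------------

glcm_features_one <- function(P, iv, ng) {
  eps <- 2.2e-16
  px <- rowSums(P)
  py <- colSums(P)
  mux <- sum(iv * px); muy <- sum(iv * py)
  sgx <- sqrt(sum((iv - mux)^2 * px)); sgy <- sqrt(sum((iv - muy)^2 * py))
  I <- matrix(iv, length(iv), length(iv))
  J <- t(I)
  D <- I - J
  S <- I + J
  # distributions of i+j and |i-j|
  ps <- rowsum(as.vector(P), as.vector(S))
  ks <- as.numeric(rownames(ps)); ps <- as.vector(ps)
  pd <- rowsum(as.vector(P), as.vector(abs(D)))
  kd <- as.numeric(rownames(pd)); pd <- as.vector(pd)
  HX <- -sum(px[px > 0] * log2(px[px > 0]))
  HY <- -sum(py[py > 0] * log2(py[py > 0]))
  HXY <- -sum(P[P > 0] * log2(P[P > 0]))
  PXPY <- outer(px, py)
  HXY1 <- -sum(P * log2(PXPY + eps))
  HXY2 <- -sum(PXPY[PXPY > 0] * log2(PXPY[PXPY > 0]))
  da <- sum(kd * pd)
  corr <- if (sgx > 0 && sgy > 0) (sum(I * J * P) - mux * muy) / (sgx * sgy) else 1
  # MCC: second largest eigenvalue of Q
  mcc <- 1
  if (length(iv) > 1) {
    Q <- sweep(P, 1, pmax(px, eps), "/") %*% sweep(t(P), 1, pmax(py, eps), "/")
    evq <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
    mcc <- sqrt(max(evq[2], 0))
  }
  offd <- D != 0
  c(Autocorrelation = sum(I * J * P),
    JointAverage = mux,
    ClusterProminence = sum((S - mux - muy)^4 * P),
    ClusterShade = sum((S - mux - muy)^3 * P),
    ClusterTendency = sum((S - mux - muy)^2 * P),
    Contrast = sum(D^2 * P),
    Correlation = corr,
    DifferenceAverage = da,
    DifferenceEntropy = -sum(pd[pd > 0] * log2(pd[pd > 0])),
    DifferenceVariance = sum((kd - da)^2 * pd),
    JointEnergy = sum(P^2),
    JointEntropy = HXY,
    Imc1 = if (max(HX, HY) > 0) (HXY - HXY1) / max(HX, HY) else 0,
    Imc2 = sqrt(pmax(1 - exp(-2 * (HXY2 - HXY)), 0)),
    Idm = sum(P / (1 + D^2)),
    Idmn = sum(P / (1 + D^2 / ng^2)),
    Id = sum(P / (1 + abs(D))),
    Idn = sum(P / (1 + abs(D) / ng)),
    InverseVariance = sum(P[offd] / D[offd]^2),
    MaximumProbability = max(P),
    SumAverage = sum(ks * ps),
    SumEntropy = -sum(ps[ps > 0] * log2(ps[ps > 0])),
    SumSquares = sum((I - mux)^2 * P),
    MCC = mcc)
}

glcm_features <- function(g, dims, ng) {
  M <- .cpp_glcm(g, dims, ng)
  acc <- NULL
  nd <- 0L
  for (d in 1:13) {
    Pd <- matrix(M[, , d], ng, ng)
    tot <- sum(Pd)
    if (tot == 0) next
    occ <- which(rowSums(Pd) + colSums(Pd) > 0)
    f <- glcm_features_one(Pd[occ, occ, drop = FALSE] / tot, occ, ng)
    acc <- if (is.null(acc)) f else acc + f
    nd <- nd + 1L
  }
  if (nd == 0L) acc <- setNames(numeric(24), names(glcm_features_one(matrix(1), 1, 1)))
  else acc <- acc / nd
  setNames(acc, feat_names("glcm", names(acc)))
}

# ---- GLRLM (16) -----------------------------------------------------------

glrlm_features_one <- function(R, np) {
  nr <- sum(R)
  p <- R / nr
  iv <- as.numeric(rownames(R))
  jv <- as.numeric(colnames(R))
  pi_ <- rowSums(p); pj <- colSums(p)
  mu_i <- sum(iv * pi_); mu_j <- sum(jv * pj)
  c(ShortRunEmphasis = sum(pj / jv^2),
    LongRunEmphasis = sum(pj * jv^2),
    GrayLevelNonUniformity = sum(rowSums(R)^2) / nr,
    GrayLevelNonUniformityNormalized = sum(rowSums(R)^2) / nr^2,
    RunLengthNonUniformity = sum(colSums(R)^2) / nr,
    RunLengthNonUniformityNormalized = sum(colSums(R)^2) / nr^2,
    RunPercentage = nr / np,
    GrayLevelVariance = sum(pi_ * (iv - mu_i)^2),
    RunVariance = sum(pj * (jv - mu_j)^2),
    RunEntropy = -sum(p[p > 0] * log2(p[p > 0])),
    LowGrayLevelRunEmphasis = sum(pi_ / iv^2),
    HighGrayLevelRunEmphasis = sum(pi_ * iv^2),
    ShortRunLowGrayLevelEmphasis = sum(p / outer(iv^2, jv^2)),
    ShortRunHighGrayLevelEmphasis = sum(p * outer(iv^2, 1 / jv^2)),
    LongRunLowGrayLevelEmphasis = sum(p * outer(1 / iv^2, jv^2)),
    LongRunHighGrayLevelEmphasis = sum(p * outer(iv^2, jv^2)))
}

glrlm_features <- function(g, dims, ng, np) {
  M <- .cpp_glrlm(g, dims, ng)
  acc <- NULL
  nd <- 0L
  for (d in 1:13) {
    Rd <- matrix(M[, , d], nrow = ng)
    if (sum(Rd) == 0) next
    ro <- which(rowSums(Rd) > 0)
    co <- which(colSums(Rd) > 0)
    Rs <- Rd[ro, co, drop = FALSE]
    rownames(Rs) <- ro; colnames(Rs) <- co
    f <- glrlm_features_one(Rs, np)
    acc <- if (is.null(acc)) f else acc + f
    nd <- nd + 1L
  }
  acc <- acc / max(nd, 1L)
  setNames(acc, feat_names("glrlm", names(acc)))
}

# ---- GLSZM (16) -----------------------------------------------------------

glszm_features <- function(g, dims, np) {
  z <- .cpp_glszm_zones(g, dims)
  lev <- z[, 1]; sz <- z[, 2]
  nz <- length(lev)
  ni <- table(lev); nj <- table(sz)
  p_cell <- table(paste(lev, sz)) / nz
  mu_i <- mean(lev); mu_j <- mean(sz)
  vals <- c(
    SmallAreaEmphasis = mean(1 / sz^2),
    LargeAreaEmphasis = mean(sz^2),
    GrayLevelNonUniformity = sum(ni^2) / nz,
    GrayLevelNonUniformityNormalized = sum(ni^2) / nz^2,
    SizeZoneNonUniformity = sum(nj^2) / nz,
    SizeZoneNonUniformityNormalized = sum(nj^2) / nz^2,
    ZonePercentage = nz / np,
    GrayLevelVariance = mean((lev - mu_i)^2),
    ZoneVariance = mean((sz - mu_j)^2),
    ZoneEntropy = -sum(p_cell * log2(p_cell)),
    LowGrayLevelZoneEmphasis = mean(1 / lev^2),
    HighGrayLevelZoneEmphasis = mean(lev^2),
    SmallAreaLowGrayLevelEmphasis = mean(1 / (lev^2 * sz^2)),
    SmallAreaHighGrayLevelEmphasis = mean(lev^2 / sz^2),
    LargeAreaLowGrayLevelEmphasis = mean(sz^2 / lev^2),
    LargeAreaHighGrayLevelEmphasis = mean(lev^2 * sz^2))
  setNames(vals, feat_names("glszm", names(vals)))
}

# ---- GLDM (14) ------------------------------------------------------------

gldm_features <- function(g, dims, ng) {
  Dm <- .cpp_gldm(g, dims, ng)
  ro <- which(rowSums(Dm) > 0)
  co <- which(colSums(Dm) > 0)
  R <- Dm[ro, co, drop = FALSE]
  iv <- ro; jv <- co
  nz <- sum(R)
  p <- R / nz
  pi_ <- rowSums(p); pj <- colSums(p)
  mu_i <- sum(iv * pi_); mu_j <- sum(jv * pj)
  vals <- c(
    SmallDependenceEmphasis = sum(pj / jv^2),
    LargeDependenceEmphasis = sum(pj * jv^2),
    GrayLevelNonUniformity = sum(rowSums(R)^2) / nz,
    DependenceNonUniformity = sum(colSums(R)^2) / nz,
    DependenceNonUniformityNormalized = sum(colSums(R)^2) / nz^2,
    GrayLevelVariance = sum(pi_ * (iv - mu_i)^2),
    DependenceVariance = sum(pj * (jv - mu_j)^2),
    DependenceEntropy = -sum(p[p > 0] * log2(p[p > 0])),
    LowGrayLevelEmphasis = sum(pi_ / iv^2),
    HighGrayLevelEmphasis = sum(pi_ * iv^2),
    SmallDependenceLowGrayLevelEmphasis = sum(p / outer(iv^2, jv^2)),
    SmallDependenceHighGrayLevelEmphasis = sum(p * outer(iv^2, 1 / jv^2)),
    LargeDependenceLowGrayLevelEmphasis = sum(p * outer(1 / iv^2, jv^2)),
    LargeDependenceHighGrayLevelEmphasis = sum(p * outer(iv^2, jv^2)))
  setNames(vals, feat_names("gldm", names(vals)))
}

# ---- NGTDM (5) ------------------------------------------------------------

ngtdm_features <- function(g, dims, ng) {
  M <- .cpp_ngtdm(g, dims, ng)
  occ <- which(M[, 1] > 0)
  iv <- occ
  n_i <- M[occ, 1]
  s_i <- M[occ, 2]
  nvp <- sum(n_i)
  p_i <- n_i / nvp
  ngp <- length(occ)
  coarse_den <- sum(p_i * s_i)
  contrast <- if (ngp > 1) {
    (sum(outer(p_i, p_i) * outer(iv, iv, "-")^2) / (ngp * (ngp - 1))) *
      (sum(s_i) / nvp)
  } else 0
  busy_den <- sum(abs(outer(iv * p_i, iv * p_i, "-")))
  PSi <- outer(p_i * s_i, p_i * s_i, "+")
  Psum <- outer(p_i, p_i, "+")
  complexity <- sum(abs(outer(iv, iv, "-")) * PSi / Psum) / nvp
  strength <- if (coarse_den > 0 && sum(s_i) > 0)
    sum(Psum * outer(iv, iv, "-")^2) / sum(s_i) else 0
  vals <- c(
    Coarseness = if (coarse_den > 0) 1 / coarse_den else 1e6,
    Contrast = contrast,
    Busyness = if (busy_den > 0) coarse_den / busy_den else 0,
    Complexity = complexity,
    Strength = strength)
  setNames(vals, feat_names("ngtdm", names(vals)))
}
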