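#' Translation specification for ROI perturbation
#'
#' A rigid in-plane translation of the ROI mask by a signed fraction of its
#' bounding-box length along one axis. The screening protocol uses the
#' minimal entity (+/- 0.5%) to emulate manual-delineation error and the
#' maximal entity (+/- 30%) to probe discrimination; only the x
#' (medial-lateral) and y (antero-posterior) axes are translated.
#'
#' @param fraction signed fraction of the bounding-box length (|fraction|
#'   <= 0.5; the protocol uses 0.005 and 0.30).
#' @param axis `"x"` or `"y"`.
#' @export
translation_spec <- function(fraction, axis = c("x", "y")) {
  axis <- match.arg(axis)
  stopifnot(is.numeric(fraction), length(fraction) == 1L,
            abs(fraction) <= 0.5)
  structure(list(fraction = fraction, axis = axis), class = "translation_spec")
}

# The 8 protocol translations: +/-0.005 and +/-0.30 along x and y.
protocol_translations <- function() {
  specs <- list()
  for (f in c(0.005, 0.30))
    for (s in c(1, -1))
      for (ax in c("x", "y"))
        specs[[length(specs) + 1L]] <- translation_spec(s * f, ax)
  names(specs) <- vapply(specs, function(sp)
    sprintf("%s%s_%s", if (sp$fraction > 0) "+" else "-",
            format(abs(sp$fraction)), sp$axis), "")
  specs
}

#' Translate the ROI mask of a volume
#'
#' Shifts the mask rigidly by `fraction` times the bounding-box length along
#' the chosen axis. The commanded shift is rounded to the nearest whole voxel
#' with a floor of one voxel (so the minimal entity is never a no-op);
#' `fraction = 0` returns the volume unchanged. Intensities are untouched and
#' the foreground voxel count is preserved; a shift that would clip the mask
#' at the volume boundary is an error.
#'
#' @param v a [volume_with_mask()].
#' @param spec a [translation_spec()].
#' @param subject optional subject id used in error messages.
#' @export
translate_mask <- function(v, spec, subject = "?") {
  stopifnot(inherits(v, "volume_with_mask"), inherits(spec, "translation_spec"))
  if (spec$fraction == 0) return(v)
  ax <- match(spec$axis, c("x", "y"))
  bb <- mask_bbox(v$mask)
  len <- bb$nvox[ax]
  shift <- sign(spec$fraction) * max(1L, as.integer(round(abs(spec$fraction) * len)))
  d <- dim(v$mask)
  if (bb$min[ax] + shift < 1L || bb$max[ax] + shift > d[ax])
    stop(sprintf(
      "translation clips the mask at the boundary (subject %s, %+g along %s)",
      subject, spec$fraction, spec$axis))
  new_mask <- array(FALSE, dim = d)
  src <- lapply(seq_len(3), function(a) seq_len(d[a]))
  dst <- src
  if (shift > 0) {
    src[[ax]] <- 1:(d[ax] - shift)
    dst[[ax]] <- (1 + shift):d[ax]
  } else {
    src[[ax]] <- (1 - shift):d[ax]
    dst[[ax]] <- 1:(d[ax] + shift)
  }
  new_mask[dst[[1]], dst[[2]], dst[[3]]] <- v$mask[src[[1]], src[[2]], src[[3]]]
  volume_with_mask(v$intensities, v$spacing, new_mask)
}

#' Percentage of the original ROI covered by a translated ROI
#'
#' @param original,translated binary 3D masks on the same grid.
#' @return `100 * |original AND translated| / |original|`.
#' @export
overlap_fraction <- function(original, translated) {
  if (inherits(original, "volume_with_mask")) original <- original$mask
  if (inherits(translated, "volume_with_mask")) translated <- translated$mask
  stopifnot(identical(dim(original), dim(translated)))
  n0 <- sum(original)
  if (n0 == 0) stop("empty original mask")
  100 * sum(original & translated) / n0
}

#' Intraclass correlation coefficient, two-way absolute agreement, single
#' measure (ICC(A,1))
#'
#' Agreement between feature values computed on the original (`a`) and a
#' translated (`b`) ROI across subjects, under a two-way model with absolute
#' agreement: unlike consistency-type ICCs it penalises systematic offsets.
#' The reported value is clipped to `[-1, 1]`.
#'
#' If both vectors have zero variance the coefficient is degenerate: it is
#' defined as 1 when `a` and `b` are identical, and an error is raised
#' otherwise.
#'
#' @param a,b equal-length (>= 3) numeric vectors of per-subject values.
#' @export
icc <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 3,
            all(is.finite(a)), all(is.finite(b)))
  n <- length(a)
  k <- 2
  if (var(a) == 0 && var(b) == 0) {
    if (isTRUE(all.equal(a, b))) return(1)
    stop("degenerate ICC: zero variance in both vectors and a != b")
  }
  grand <- mean(c(a, b))
  Si <- (a + b) / 2
  Rj <- c(mean(a), mean(b))
  SSR <- k * sum((Si - grand)^2)
  SSC <- n * sum((Rj - grand)^2)
  SST <- sum((a - grand)^2) + sum((b - grand)^2)
  SSE <- SST - SSR - SSC
  MSR <- SSR / (n - 1)
  MSC <- SSC / (k - 1)
  MSE <- SSE / ((n - 1) * (k - 1))
  val <- (MSR - MSE) / (MSR + (k - 1) * MSE + k / n * (MSC - MSE))
  min(1, max(-1, val))
}

#' Screen features for translation robustness
#'
#' For every non-shape feature, features are extracted from the original ROI
#' and from the 4 minimal-entity (+/-0.5% of the bounding box, x and y) and
#' 4 maximal-entity (+/-30%) translated ROIs of every subject; each
#' translation direction yields one ICC between original and translated
#' values across subjects. A feature is *stable* if its minimal-entity mean
#' ICC exceeds 0.75, *discriminative* if its maximal-entity mean ICC is below
#' 0.5, and *robust* if both hold. Shape-size features do not change under a
#' rigid ROI translation, so they bypass the screen and are always retained.
#'
#' Features with zero variance across subjects in both the original and a
#' translated extraction are flagged degenerate and excluded, with the reason
#' recorded in the report.
#'
#' @param cohort list of (preprocessed) subjects (`id`, `volume`, `label`);
#'   at least 3 subjects.
#' @param cfg an [extraction_config()].
#' @param extract_fn extraction function `(volume, cfg) -> named vector`;
#'   injectable for testing, defaults to [extract_features()].
#' @return a `robustness_report`: a data frame with per-feature ICCs
#'   (`icc_min_1..4`, `icc_min_mean`, `icc_max_1..4`, `icc_max_mean`) and
#'   flags (`stable`, `discriminative`, `degenerate`, `robust`), with
#'   attributes `retained` (shape features plus robust features) and
#'   `overlap` (mean overlap percentage per translation).
#' @export
robustness_screen <- function(cohort, cfg = extraction_config(),
                              extract_fn = extract_features) {
  if (length(cohort) < 3) stop("robustness screening needs >= 3 subjects")
  specs <- protocol_translations()
  f0 <- lapply(cohort, function(s) extract_fn(s$volume, cfg))
  nms <- names(f0[[1]])
  cls <- feature_classes(nms)
  nonshape <- nms[cls != "shape-size"]
  F0 <- do.call(rbind, lapply(f0, function(f) as.numeric(f[nonshape])))
  colnames(F0) <- nonshape

  Ft <- list()
  ovl <- numeric(length(specs))
  for (si in seq_along(specs)) {
    sp <- specs[[si]]
    rows <- lapply(cohort, function(s) {
      tv <- translate_mask(s$volume, sp, subject = s$id)
      list(f = extract_fn(tv, cfg)[nonshape],
           o = overlap_fraction(s$volume$mask, tv$mask))
    })
    Ft[[si]] <- do.call(rbind, lapply(rows, function(r) as.numeric(r$f)))
    colnames(Ft[[si]]) <- nonshape
    ovl[si] <- mean(vapply(rows, `[[`, 0, "o"))
  }
  names(ovl) <- names(specs)

  is_min <- vapply(specs, function(sp) abs(sp$fraction) < 0.1, TRUE)
  icc_mat <- matrix(NA_real_, length(nonshape), length(specs),
                    dimnames = list(nonshape, names(specs)))
  degen <- setNames(rep(FALSE, length(nonshape)), nonshape)
  for (fe in nonshape) {
    for (si in seq_along(specs)) {
      a <- F0[, fe]
      b <- Ft[[si]][, fe]
      if (var(a) == 0 && var(b) == 0) {
        degen[fe] <- TRUE
        icc_mat[fe, si] <- if (isTRUE(all.equal(a, b))) 1 else NA_real_
      } else {
        icc_mat[fe, si] <- icc(a, b)
      }
    }
  }
  mins <- icc_mat[, is_min, drop = FALSE]
  maxs <- icc_mat[, !is_min, drop = FALSE]
  rep_df <- data.frame(feature = nonshape, stringsAsFactors = FALSE)
  for (j in 1:4) rep_df[[paste0("icc_min_", j)]] <- mins[, j]
  rep_df$icc_min_mean <- rowMeans(mins)
  for (j in 1:4) rep_df[[paste0("icc_max_", j)]] <- maxs[, j]
  rep_df$icc_max_mean <- rowMeans(maxs)
  rep_df$stable <- !is.na(rep_df$icc_min_mean) & rep_df$icc_min_mean > 0.75
  rep_df$discriminative <- !is.na(rep_df$icc_max_mean) & rep_df$icc_max_mean < 0.5
  rep_df$degenerate <- unname(degen)
  rep_df$robust <- rep_df$stable & rep_df$discriminative & !rep_df$degenerate
  if (any(degen))
    message("robustness_screen: ", sum(degen),
            " degenerate feature(s) (zero variance) excluded: ",
            paste(head(nonshape[degen], 5), collapse = ", "))
  retained <- c(nms[cls == "shape-size"], rep_df$feature[rep_df$robust])
  structure(rep_df, class = c("robustness_report", "data.frame"),
            retained = retained, overlap = ovl)
}

#' Retained features of a robustness report
#' @param report a `robustness_report`.
#' @export
robust_features <- function(report) attr(report, "retained")

#' Write a robustness report to CSV
#' @param report a `robustness_report`. @param path output CSV path.
#' @export
write_robustness_report <- function(report, path) {
  df <- as.data.frame(report)
  num <- vapply(df, is.numeric, TRUE)
  for (j in which(num)) df[[j]] <- sprintf("%.17g", df[[j]])
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a robustness report written by [write_robustness_report()]
#' @param path CSV path.
#' @export
read_robustness_report <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  for (j in grep("^icc_", names(df))) df[[j]] <- as.numeric(df[[j]])
  class(df) <- c("robustness_report", "data.frame")
  attr(df, "retained") <- c()  # retained set is derivable; not serialized
  df
}
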