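#' Build a feature table from a cohort
#'
#' Runs [extract_features()] on every subject and assembles the
#' subjects-by-features matrix with labels and feature-class annotations.
#'
#' @param cohort non-empty list of subjects (`id`, `volume`, `label`); volumes
#'   are expected to be preprocessed already.
#' @param cfg an [extraction_config()].
#' @param extract_fn extraction function `(volume, cfg) -> named vector`;
#'   injectable for testing, defaults to [extract_features()].
#' @return a `feature_table` object.
#' @export
build_feature_table <- function(cohort, cfg = extraction_config(),
                                extract_fn = extract_features) {
  if (!length(cohort)) stop("empty cohort")
  fv <- lapply(cohort, function(s) extract_fn(s$volume, cfg))
  nms <- names(fv[[1]])
  for (f in fv)
    if (!identical(names(f), nms))
      stop("inconsistent feature names across subjects")
  X <- do.call(rbind, lapply(fv, as.numeric))
  colnames(X) <- nms
  rownames(X) <- vapply(cohort, `[[`, "", "id")
  feature_table(X, vapply(cohort, function(s) as.integer(s$label), 0L),
                attr(fv[[1]], "class_of"))
}

#' Construct a feature table
#'
#' @param features numeric matrix, subjects x named features.
#' @param labels integer vector of binary labels (1 = CA positive class,
#'   0 = AS), one per subject.
#' @param class_of named character vector mapping feature names to classes;
#'   derived from the namespaced names when omitted.
#' @export
feature_table <- function(features, labels,
                          class_of = setNames(feature_classes(colnames(features)),
                                              colnames(features))) {
  features <- as.matrix(features)
  if (is.null(colnames(features))) stop("features must have column names")
  labels <- as.integer(labels)
  if (length(labels) != nrow(features)) stop("one label per subject required")
  if (!all(labels %in% c(0L, 1L))) stop("labels must be binary 0/1")
  if (is.null(rownames(features)))
    rownames(features) <- sprintf("S%02d", seq_len(nrow(features)))
  structure(list(features = features, labels = labels,
                 class_of = class_of[colnames(features)],
                 subject_ids = rownames(features)),
            class = "feature_table")
}

#' @exportS3Method base::print
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d subjects x %d features (%s)\n",
              nrow(x$features), ncol(x$features),
              paste(sprintf("%s: %d", names(table(x$class_of)),
                            as.integer(table(x$class_of))), collapse = ", ")))
  cat(sprintf("  labels: %d positive (CA) / %d negative (AS)\n",
              sum(x$labels == 1), sum(x$labels == 0)))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$features)

#' Subset a feature table by subjects and/or features
#'
#' @param x a `feature_table`.
#' @param i subject index. @param j feature index or names.
#' @param ... ignored. @param drop ignored (never drops).
#' @export
`[.feature_table` <- function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nrow(x$features))
  if (missing(j)) j <- seq_len(ncol(x$features))
  feature_table(x$features[i, j, drop = FALSE], x$labels[i],
                x$class_of)
}

#' Write a feature table to CSV (with a sidecar JSON class map)
#'
#' Values are written with 17 significant digits so the write/read round trip
#' is lossless for doubles.
#'
#' @param table a `feature_table`.
#' @param path CSV path; the class map goes to `<path>.classes.json`.
#' @export
write_feature_table <- function(table, path) {
  X <- table$features
  df <- data.frame(subject_id = rownames(X), label = table$labels,
                   check.names = FALSE)
  for (j in seq_len(ncol(X))) df[[colnames(X)[j]]] <- sprintf("%.17g", X[, j])
  write.csv(df, path, row.names = FALSE, quote = TRUE)
  jsonlite::write_json(as.list(table$class_of),
                       paste0(path, ".classes.json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#'
#' @param path CSV path.
#' @export
read_feature_table <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  X <- as.matrix(df[, -(1:2), drop = FALSE])
  storage.mode(X) <- "double"
  rownames(X) <- df$subject_id
  cls_path <- paste0(path, ".classes.json")
  cls <- if (file.exists(cls_path)) {
    unlist(jsonlite::read_json(cls_path))
  } else setNames(feature_classes(colnames(X)), colnames(X))
  feature_table(X, df$label, cls)
}

# ---- z-scoring (fit on training data, apply elsewhere) --------------------

#' Fit a z-score transform on training data
#'
#' Per-feature mean/SD estimated on the training rows only; constant features
#' get SD 1 so they map to all-zero columns instead of NaN.
#'
#' @param X numeric matrix (training subjects x features).
#' @return an object usable with [zscore_apply()].
#' @export
zscore_fit <- function(X) {
  mu <- colMeans(X)
  s <- apply(X, 2, sd)
  s[!is.finite(s) | s == 0] <- 1
  structure(list(mean = mu, sd = s), class = "zscore_transform")
}

#' Apply a fitted z-score transform
#'
#' @param fit a `zscore_transform` from [zscore_fit()].
#' @param X matrix with the same columns as the training data.
#' @export
zscore_apply <- function(fit, X) {
  sweep(sweep(X, 2, fit$mean, "-"), 2, fit$sd, "/")
}
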