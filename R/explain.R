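#' Exact Shapley-value explanation of a model
#'
#' Model-agnostic Shapley attributions of a real-valued decision score over
#' the model's input columns (principal components for the reference
#' pipeline). Absent features are marginalised over a background set: the
#' value of a coalition S is the mean model score with the instance's values
#' on S and background values elsewhere. With up to `max_exact` inputs all
#' coalitions are enumerated, so the attributions are exact Shapley values
#' and satisfy additivity exactly: per instance,
#' `base + sum(phi) = mean score of the instance over the background rows`.
#' A positive attribution pushes the score toward the CA class (label 1).
#'
#' @param object a `final_model`, a `radiostab_model`, or a function
#'   `matrix -> numeric` returning the decision score.
#' @param background matrix of background samples (for a `final_model`, the
#'   SMOTE-augmented training scores by default). Subsampled evenly to at
#'   most `max_background` rows.
#' @param instances matrix of instances to explain (for a `final_model`, the
#'   original cohort by default).
#' @param max_exact maximum input dimension for exact enumeration.
#' @param max_background background-size cap (deterministic even subsample).
#' @return a `shap_report`: list with `shap` (instances x inputs signed
#'   attributions), `base` (expected score), `mean_abs` (per-input mean
#'   absolute attribution, the importance ranking), `score` (per-instance
#'   model score reproduced by `base + rowSums(shap)`).
#' @export
shap_explain <- function(object, background = NULL, instances = NULL,
                         max_exact = 12L, max_background = 32L) {
  if (inherits(object, "final_model")) {
    f <- function(X) predict(object$model, X, type = "score")
    if (is.null(background)) background <- object$aug$features
    if (is.null(instances))
      instances <- final_transform(object, object$table$features)
  } else if (inherits(object, "radiostab_model")) {
    f <- function(X) predict(object, X, type = "score")
  } else if (is.function(object)) {
    f <- object
  } else stop("object must be a model or a score function")
  background <- as.matrix(background)
  instances <- as.matrix(instances)
  if (ncol(background) != ncol(instances))
    stop("feature-dimension mismatch between background and instances")
  M <- ncol(instances)
  if (M > max_exact)
    stop("exact Shapley enumeration limited to ", max_exact,
         " inputs; reduce the dimension or raise max_exact")
  if (nrow(background) > max_background) {
    keep <- unique(round(seq(1, nrow(background), length.out = max_background)))
    background <- background[keep, , drop = FALSE]
  }
  B <- nrow(background)
  n_coal <- 2^M
  masks <- lapply(0:(n_coal - 1), function(s) which(bitwAnd(s, 2^(0:(M - 1))) > 0))
  # Shapley weights w(s) = s! (M-1-s)! / M!
  lw <- lfactorial(0:M)
  wgt <- exp(lw[1:M] + lw[M:1] - lw[M + 1])  # index s+1, s = 0..M-1

  phi <- matrix(0, nrow(instances), M,
                dimnames = list(rownames(instances), colnames(instances)))
  score <- numeric(nrow(instances))
  base <- mean(f(background))
  for (r in seq_len(nrow(instances))) {
    x <- instances[r, ]
    big <- background[rep(seq_len(B), n_coal), , drop = FALSE]
    for (s in seq_len(n_coal)) {
      cols <- masks[[s]]
      if (length(cols))
        big[((s - 1) * B + 1):(s * B), cols] <-
          matrix(x[cols], B, length(cols), byrow = TRUE)
    }
    v <- colMeans(matrix(f(big), nrow = B))  # v[s + 1] = value of coalition s
    for (m in seq_len(M)) {
      bit <- 2^(m - 1)
      no_m <- which(bitwAnd(0:(n_coal - 1), bit) == 0) - 1L  # 0-based coalitions
      sizes <- vapply(masks[no_m + 1L], length, 0L)
      phi[r, m] <- sum(wgt[sizes + 1] * (v[no_m + bit + 1L] - v[no_m + 1L]))
    }
    score[r] <- v[n_coal]
  }
  structure(list(shap = phi, base = base,
                 mean_abs = colMeans(abs(phi)), score = score),
            class = "shap_report")
}

#' @exportS3Method base::print
print.shap_report <- function(x, ...) {
  cat("<shap_report> mean |SHAP| per input (ranked):\n")
  print(sort(x$mean_abs, decreasing = TRUE))
  invisible(x)
}

#' Attribute principal components to radiomic feature classes
#'
#' Per principal component, loadings are squared; squared values higher than
#' half of the component's maximum squared loading are kept and summed by
#' feature class (shape-size, first-order, textural). The class with the
#' largest sum is flagged dominant. The half-max rule always keeps at least
#' the maximum loading itself, and the sums are invariant to feature
#' ordering.
#'
#' @param loadings features x components loading matrix with feature row
#'   names (e.g. `projection$rotation[, 1:k]` of a fitted PCA selector).
#' @param class_of named character vector mapping features to classes.
#' @return data frame: `pc`, one column per class with the squared-loading
#'   sums, and `dominant`.
#' @export
pc_class_attribution <- function(loadings, class_of) {
  loadings <- as.matrix(loadings)
  if (!nrow(loadings)) stop("empty loading matrix")
  if (is.null(rownames(loadings))) stop("loadings must have feature row names")
  classes <- c("shape-size", "first-order", "textural")
  fc <- class_of[rownames(loadings)]
  if (anyNA(fc)) stop("unknown feature class for some loadings")
  rows <- lapply(seq_len(ncol(loadings)), function(j) {
    sq <- loadings[, j]^2
    keep <- sq > 0.5 * max(sq)
    sums <- vapply(classes, function(cl) sum(sq[keep & fc == cl]), 0)
    data.frame(pc = j, `shape-size` = sums[1], `first-order` = sums[2],
               textural = sums[3],
               dominant = classes[which.max(sums)],
               check.names = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Full explanation report for a final model
#'
#' Combines the Shapley analysis of the final model with the
#' principal-component class attribution (PCA-type selectors only).
#'
#' @param final a `final_model` fitted with a PCA-type selector.
#' @param ... passed to [shap_explain()].
#' @return list with `shap` (a `shap_report`) and `attribution` (the
#'   class-attribution table), class `explain_report`.
#' @export
explain_report <- function(final, ...) {
  stopifnot(inherits(final, "final_model"))
  sh <- shap_explain(final, ...)
  attribution <- NULL
  pr <- final$selector_result$projection
  if (!is.null(pr))
    attribution <- pc_class_attribution(pr$rotation[, seq_len(pr$k), drop = FALSE],
                                        final$table$class_of)
  structure(list(shap = sh, attribution = attribution),
            class = "explain_report")
}

#' Write an explanation report to JSON
#'
#' @param report an `explain_report`. @param path output path.
#' @export
write_explain_report <- function(report, path) {
  out <- list(base = report$shap$base,
              mean_abs_shap = as.list(report$shap$mean_abs),
              shap = report$shap$shap,
              attribution = report$attribution)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
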