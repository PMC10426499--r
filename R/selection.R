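# Relevance selection: six methods, each fitted on training subjects only and
# applicable to held-out subjects through `apply_selector()`.

#' @rdname apply_selector
#' @export
selector_result <- function(method, retained = NULL, projection = NULL,
                            fitted_on = NULL) {
  structure(list(method = method, retained = retained, projection = projection,
                 fitted_on = fitted_on),
            class = "selector_result")
}

#' @exportS3Method base::print
print.selector_result <- function(x, ...) {
  if (is.null(x$projection))
    cat(sprintf("<selector_result> %s: %d feature(s) retained\n", x$method,
                length(x$retained)))
  else
    cat(sprintf("<selector_result> %s: %d principal component(s)\n", x$method,
                x$projection$k))
  invisible(x)
}

#' Apply a fitted selector to new subjects
#'
#' Filter-type selectors subset columns; PCA-type selectors project onto the
#' training loadings after centring with the training means. The transform is
#' a pure function of the training subjects it was fitted on.
#'
#' @param result a `selector_result`.
#' @param X numeric matrix with the training feature columns.
#' @return numeric matrix (selected features or PC scores).
#' @export
apply_selector <- function(result, X) {
  X <- as.matrix(X)
  if (!is.null(result$projection)) {
    pr <- result$projection
    Xs <- X[, rownames(pr$rotation), drop = FALSE]
    sweep(Xs, 2, pr$center, "-") %*% pr$rotation[, seq_len(pr$k), drop = FALSE]
  } else {
    X[, result$retained, drop = FALSE]
  }
}

#' Rank-sum (p-value) feature selection
#'
#' Wilcoxon rank-sum test per feature between the two unpaired groups;
#' features with `p < alpha` are retained.
#'
#' @param X training matrix (subjects x features).
#' @param y binary labels; both classes must be present.
#' @param alpha significance level (default 0.05).
#' @export
select_pvalue <- function(X, y, alpha = 0.05) {
  X <- as.matrix(X)
  if (length(unique(y)) < 2) stop("single-class training set")
  p <- apply(X, 2, function(v) {
    if (var(v) == 0) return(1)
    suppressWarnings(wilcox.test(v[y == 1], v[y == 0])$p.value)
  })
  selector_result("p-value", retained = colnames(X)[p < alpha],
                  fitted_on = rownames(X))
}

# deterministic stratified fold assignment (no RNG, no test leakage)
stratified_folds <- function(y, nfolds) {
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    fold[idx] <- rep_len(seq_len(nfolds), length(idx))
  }
  fold
}

#' LASSO feature selection
#'
#' L1-penalised logistic regression; features with a nonzero coefficient at
#' the internally cross-validated lambda (`lambda.min` of a stratified CV on
#' the training fold) are retained.
#'
#' @inheritParams select_pvalue
#' @param nfolds internal CV folds (default 5, stratified, deterministic).
#' @export
select_lasso <- function(X, y, nfolds = 5) {
  X <- as.matrix(X)
  if (length(unique(y)) < 2) stop("degenerate (all-equal) labels")
  if (ncol(X) < 2)  # glmnet needs >= 2 columns; nothing to shrink anyway
    return(selector_result("LASSO", retained = colnames(X),
                           fitted_on = rownames(X)))
  nf <- min(nfolds, min(table(y)))
  if (nf >= 3) {
    cv <- suppressWarnings(
      glmnet::cv.glmnet(X, y, family = "binomial", alpha = 1,
                        foldid = stratified_folds(y, nf),
                        standardize = FALSE))
    cf <- as.matrix(coef(cv, s = "lambda.min"))[-1, 1]
  } else {
    # folds too small for internal CV: pick lambda by BIC along the path
    # (deterministic, training-only)
    fit <- suppressWarnings(glmnet::glmnet(X, y, family = "binomial",
                                           alpha = 1, standardize = FALSE))
    n <- length(y)
    dev <- (1 - fit$dev.ratio) * fit$nulldev
    bic <- dev + log(n) * fit$df
    cf <- as.matrix(coef(fit, s = fit$lambda[which.min(bic)]))[-1, 1]
  }
  selector_result("LASSO", retained = names(cf)[cf != 0],
                  fitted_on = rownames(X))
}

#' Semi-supervised LASSO: p-value screening then LASSO
#'
#' The statistically significant features (rank-sum `p < alpha`) are the
#' input to LASSO, so the retained set is always a subset of the p-value
#' survivors. An empty p-value stage yields an empty selection with a
#' warning.
#'
#' @inheritParams select_lasso
#' @param alpha significance level for the screening stage.
#' @export
select_sslasso <- function(X, y, alpha = 0.05, nfolds = 5) {
  pv <- select_pvalue(X, y, alpha)
  if (!length(pv$retained)) {
    warning("ssLASSO: no significant features; empty selection")
    return(selector_result("ssLASSO", retained = character(0),
                           fitted_on = rownames(X)))
  }
  ls <- select_lasso(as.matrix(X)[, pv$retained, drop = FALSE], y, nfolds)
  selector_result("ssLASSO", retained = ls$retained, fitted_on = rownames(X))
}

#' Principal-component selection
#'
#' PCA of the (z-scored) training features; the number of components is the
#' smallest k whose cumulative explained variance reaches `variance_target`
#' (default 95%). Held-out subjects are projected with the training mean and
#' loadings via [apply_selector()].
#'
#' @inheritParams select_pvalue
#' @param variance_target cumulative explained-variance target in (0, 1].
#' @export
fit_pca <- function(X, y = NULL, variance_target = 0.95) {
  X <- as.matrix(X)
  if (nrow(X) < 2) stop("PCA needs >= 2 training subjects")
  if (all(apply(X, 2, var) == 0)) stop("zero-variance table")
  pr <- prcomp(X, center = TRUE, scale. = FALSE)
  ev <- pr$sdev^2
  cum <- cumsum(ev) / sum(ev)
  k <- which(cum >= variance_target - 1e-12)[1]
  selector_result("PCA",
                  projection = list(center = pr$center, rotation = pr$rotation,
                                    sdev = pr$sdev, k = k),
                  fitted_on = rownames(X))
}

#' @rdname fit_pca
#' @param result a PCA-type `selector_result`.
#' @export
apply_pca <- function(result, X) apply_selector(result, X)

#' Semi-supervised PCA: p-value screening then PCA
#'
#' @inheritParams select_sslasso
#' @param variance_target cumulative explained-variance target.
#' @export
select_sspca <- function(X, y, alpha = 0.05, variance_target = 0.95) {
  pv <- select_pvalue(X, y, alpha)
  if (!length(pv$retained)) {
    warning("ssPCA: no significant features; empty selection")
    return(selector_result("ssPCA", retained = character(0),
                           fitted_on = rownames(X)))
  }
  pc <- fit_pca(as.matrix(X)[, pv$retained, drop = FALSE],
                variance_target = variance_target)
  selector_result("ssPCA", projection = pc$projection,
                  fitted_on = rownames(X))
}

#' Sequential forward selection
#'
#' Greedy forward selection scored by internal stratified cross-validated
#' accuracy of the supplied classifier. The first feature is always added;
#' afterwards the best single-feature addition is accepted only while it
#' improves the score by at least `improvement_threshold` (default 0.02) —
#' the stopping rule reads "stop when the improvement falls below the
#' threshold".
#'
#' @inheritParams select_pvalue
#' @param classifier classifier name for [fit_classifier()].
#' @param improvement_threshold minimum CV-accuracy improvement to continue.
#' @param params classifier hyperparameters.
#' @param nfolds internal CV folds.
#' @export
select_sfs <- function(X, y, classifier = "SVM", improvement_threshold = 0.02,
                       params = list(), nfolds = 5) {
  X <- as.matrix(X)
  if (length(unique(y)) < 2) stop("single-class training set")
  foldid <- stratified_folds(y, min(nfolds, min(table(y))))
  cv_acc <- function(cols) {
    preds <- integer(length(y))
    for (f in unique(foldid)) {
      tr <- foldid != f
      if (length(unique(y[tr])) < 2) return(NA_real_)
      m <- fit_classifier(X[tr, cols, drop = FALSE], y[tr], classifier, params)
      preds[!tr] <- predict(m, X[!tr, cols, drop = FALSE])
    }
    mean(preds == y)
  }
  selected <- character(0)
  score <- -Inf
  candidates <- colnames(X)
  repeat {
    rest <- setdiff(candidates, selected)
    if (!length(rest)) break
    scores <- vapply(rest, function(f) cv_acc(c(selected, f)), 0)
    best <- which.max(scores)  # deterministic: first max in column order
    if (length(selected) == 0L || scores[best] - score >= improvement_threshold) {
      selected <- c(selected, rest[best])
      score <- scores[best]
    } else break
  }
  selector_result("SFS", retained = selected, fitted_on = rownames(X))
}

# dispatch table used by the evaluation harness
fit_selector <- function(method, X, y, alpha = 0.05, variance_target = 0.95,
                         classifier = "SVM", params = list()) {
  switch(method,
    "p-value" = select_pvalue(X, y, alpha),
    "LASSO" = select_lasso(X, y),
    "ssLASSO" = select_sslasso(X, y, alpha),
    "PCA" = fit_pca(X, variance_target = variance_target),
    "ssPCA" = select_sspca(X, y, alpha, variance_target),
    "SFS" = select_sfs(X, y, classifier, params = params),
    stop("unknown selector: ", method))
}

# number of retained features / components of a fitted selector
selector_size <- function(result) {
  if (!is.null(result$projection)) result$projection$k
  else length(result$retained)
}
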