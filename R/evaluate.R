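#' Evaluation-grid configuration
#'
#' @param thresholds subset of the correlation thresholds
#'   `c(0.80, 0.85, 0.90, 0.95, 1)`.
#' @param selectors subset of
#'   `c("p-value", "LASSO", "ssLASSO", "PCA", "ssPCA", "SFS")`.
#' @param classifiers subset of `c("kNN", "SVM", "DT", "LR", "GB")`.
#' @param classifier_params named list (per classifier) of hyperparameters,
#'   see [fit_classifier()].
#' @param alpha rank-sum significance level for p-value-based selectors.
#' @param variance_target PCA cumulative explained-variance target.
#' @param q_neighbors SMOTE neighbour count.
#' @param seed master seed; all stochastic steps (SMOTE) derive per-fold
#'   seeds from it, never from the held-out subject.
#' @export
run_config <- function(thresholds = c(0.80, 0.85, 0.90, 0.95, 1),
                       selectors = c("p-value", "LASSO", "ssLASSO",
                                     "PCA", "ssPCA", "SFS"),
                       classifiers = c("kNN", "SVM", "DT", "LR", "GB"),
                       classifier_params = list(),
                       alpha = 0.05, variance_target = 0.95,
                       q_neighbors = 5L, seed = 1L) {
  stopifnot(length(thresholds) > 0, length(selectors) > 0,
            length(classifiers) > 0)
  structure(list(thresholds = thresholds, selectors = selectors,
                 classifiers = classifiers,
                 classifier_params = classifier_params,
                 alpha = alpha, variance_target = variance_target,
                 q_neighbors = as.integer(q_neighbors),
                 seed = as.integer(seed)),
            class = "run_config")
}

fold_seed <- function(seed, fold, ti, si, ci = 0L) {
  as.integer((as.double(seed) * 97 + fold * 131071 + ti * 8191 +
                si * 127 + ci * 31) %% 2147483647)
}

# Fit the full per-fold pipeline (z-score -> correlation filter -> selector
# -> SMOTE -> classifier) on the training rows of `table`, strictly inside
# the fold. Returns every fitted component; used by loo_run, fit_final and
# the leakage tests.
#' Fit one pipeline cell on a training split
#'
#' All fitting (z-scoring, redundancy filter, selector, SMOTE, classifier)
#' uses only the rows in `train_idx`; held-out subjects never influence any
#' fitted component.
#'
#' @param table a `feature_table`.
#' @param train_idx integer indices of the training subjects.
#' @param threshold correlation threshold.
#' @param selector selector name.
#' @param classifier classifier name.
#' @param cfg a [run_config()].
#' @param smote_seed seed for the SMOTE stage.
#' @return list with `zfit`, `retained`, `selector_result`, `model`, `aug`
#'   (augmented training scores and labels).
#' @export
fit_fold <- function(table, train_idx, threshold, selector, classifier,
                     cfg = run_config(), smote_seed = cfg$seed) {
  Xtr <- table$features[train_idx, , drop = FALSE]
  ytr <- table$labels[train_idx]
  zfit <- zscore_fit(Xtr)
  Ztr <- zscore_apply(zfit, Xtr)
  retained <- correlation_filter(Ztr, threshold)
  sel <- fit_selector(selector, Ztr[, retained, drop = FALSE], ytr,
                      alpha = cfg$alpha, variance_target = cfg$variance_target,
                      classifier = classifier,
                      params = cfg$classifier_params[[classifier]])
  if (selector_size(sel) == 0)
    return(list(zfit = zfit, retained = retained, selector_result = sel,
                model = NULL, aug = NULL))
  Str <- apply_selector(sel, Ztr[, retained, drop = FALSE])
  # SMOTE needs >= 2 members per class to interpolate; tiny smoke cohorts
  # fall back to the unaugmented training set
  aug <- if (min(table(ytr)) >= 2) {
    smote_augment(Str, ytr, smote_config(cfg$q_neighbors, seed = smote_seed))
  } else list(features = Str, labels = ytr)
  model <- fit_classifier(aug$features, aug$labels, classifier,
                          cfg$classifier_params[[classifier]] %||% list())
  list(zfit = zfit, retained = retained, selector_result = sel,
       model = model, aug = aug)
}

# transform + predict a held-out block with a fitted fold
predict_fold <- function(fold_fit, table, test_idx, type = "label") {
  Zte <- zscore_apply(fold_fit$zfit,
                      table$features[test_idx, , drop = FALSE])
  Ste <- apply_selector(fold_fit$selector_result,
                        Zte[, fold_fit$retained, drop = FALSE])
  predict(fold_fit$model, Ste, type = type)
}

#' Leave-one-out evaluation over the (threshold x selector x classifier) grid
#'
#' Each subject is held out once; per fold, z-scoring, the Spearman
#' redundancy filter, the selector, SMOTE and the classifier are all fitted
#' on the remaining subjects only. Performance per cell is computed from the
#' pooled LOO confusion matrix (CA, label 1, is the positive class). Cells
#' whose selector returns zero features in some fold have those folds marked
#' failed and excluded from the pooled summary.
#'
#' For selectors other than SFS the fitted selector and the SMOTE-augmented
#' training set are shared across classifiers within a fold; SFS is refit per
#' classifier because its internal score is the downstream classifier's
#' cross-validated accuracy.
#'
#' @param table a `feature_table` with at least 4 subjects, both classes
#'   present.
#' @param cfg a [run_config()].
#' @return a `grid_result`: list with `grid` (per-cell accuracy, sensitivity,
#'   specificity), `predictions` (per fold), `counts` (mean and SD of the
#'   number of selected features per threshold x selector, the Table-2-style
#'   summary), and `config`.
#' @export
loo_run <- function(table, cfg = run_config()) {
  N <- nrow(table$features)
  if (N < 4) stop("leave-one-out evaluation needs >= 4 subjects")
  if (length(unique(table$labels)) < 2) stop("both classes must be present")
  preds <- list()
  counts <- list()
  for (fold in seq_len(N)) {
    tr <- setdiff(seq_len(N), fold)
    for (ti in seq_along(cfg$thresholds)) {
      thr <- cfg$thresholds[ti]
      for (si in seq_along(cfg$selectors)) {
        sel_name <- cfg$selectors[si]
        per_clf <- if (sel_name == "SFS") cfg$classifiers else cfg$classifiers[1]
        for (ci in seq_along(per_clf)) {
          seed_ci <- if (sel_name == "SFS") ci else 0L
          ff <- fit_fold(table, tr, thr, sel_name, per_clf[ci], cfg,
                         smote_seed = fold_seed(cfg$seed, fold, ti, si, seed_ci))
          clfs <- if (sel_name == "SFS") per_clf[ci] else cfg$classifiers
          counts[[length(counts) + 1L]] <- data.frame(
            fold = fold, threshold = thr, selector = sel_name,
            n_selected = selector_size(ff$selector_result))
          for (clf in clfs) {
            failed <- is.null(ff$model)
            model <- ff$model
            if (!failed && clf != per_clf[ci]) {
              model <- fit_classifier(ff$aug$features, ff$aug$labels, clf,
                                      cfg$classifier_params[[clf]] %||% list())
            }
            sc <- if (failed) NA_real_ else {
              ffc <- ff; ffc$model <- model
              predict_fold(ffc, table, fold, type = "score")
            }
            preds[[length(preds) + 1L]] <- data.frame(
              fold = fold, subject = table$subject_ids[fold],
              threshold = thr, selector = sel_name, classifier = clf,
              truth = table$labels[fold],
              pred = if (failed) NA_integer_ else as.integer(sc > 0),
              score = sc, failed = failed)
          }
        }
      }
    }
  }
  predictions <- do.call(rbind, preds)
  counts <- do.call(rbind, counts)
  grid <- aggregate_grid(predictions)
  counts_sum <- aggregate(counts$n_selected,
                          by = list(threshold = counts$threshold,
                                    selector = counts$selector),
                          FUN = function(v) c(mean = mean(v), sd = sd(v)))
  counts_sum <- data.frame(threshold = counts_sum$threshold,
                           selector = counts_sum$selector,
                           mean_n = counts_sum$x[, "mean"],
                           sd_n = counts_sum$x[, "sd"])
  structure(list(grid = grid, predictions = predictions,
                 counts = counts_sum, config = cfg),
            class = "grid_result")
}

# pooled confusion per cell -> metrics
aggregate_grid <- function(predictions) {
  cells <- unique(predictions[, c("threshold", "selector", "classifier")])
  rows <- lapply(seq_len(nrow(cells)), function(r) {
    sub <- predictions[predictions$threshold == cells$threshold[r] &
                       predictions$selector == cells$selector[r] &
                       predictions$classifier == cells$classifier[r], ]
    ok <- !sub$failed
    tp <- sum(sub$pred[ok] == 1 & sub$truth[ok] == 1)
    tn <- sum(sub$pred[ok] == 0 & sub$truth[ok] == 0)
    fp <- sum(sub$pred[ok] == 1 & sub$truth[ok] == 0)
    fn <- sum(sub$pred[ok] == 0 & sub$truth[ok] == 1)
    m <- if (tp + tn + fp + fn > 0) metrics(tp, tn, fp, fn)
         else c(accuracy = NA, sensitivity = NA, specificity = NA)
    data.frame(cells[r, , drop = FALSE], t(m), n_failed_folds = sum(!ok),
               row.names = NULL)
  })
  do.call(rbind, rows)
}

#' Classification metrics from a confusion matrix
#'
#' Standard definitions with CA (label 1) as the positive class. Ratios with
#' a zero denominator are reported as `NA`, not 0.
#'
#' @param tp,tn,fp,fn non-negative confusion counts, sum > 0.
#' @return named vector `accuracy`, `sensitivity`, `specificity`.
#' @export
metrics <- function(tp, tn, fp, fn) {
  stopifnot(tp >= 0, tn >= 0, fp >= 0, fn >= 0)
  n <- tp + tn + fp + fn
  if (n == 0) stop("all-zero confusion counts")
  c(accuracy = (tp + tn) / n,
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_)
}

#' @exportS3Method base::print
print.grid_result <- function(x, ...) {
  cat(sprintf("<grid_result> %d cell(s), %d LOO fold(s)\n",
              nrow(x$grid), max(x$predictions$fold)))
  print(x$grid, row.names = FALSE)
  invisible(x)
}

#' Fit the final model on the whole cohort
#'
#' Reuses the fold-fitting code path with the full cohort as training set
#' (including SMOTE doubling), as done after model selection.
#'
#' @param table a `feature_table`.
#' @param threshold,selector,classifier the selected pipeline cell (defaults:
#'   the best-performing combination, SVM with PCA at threshold 0.95).
#' @param cfg a [run_config()].
#' @return a `final_model`: the fitted fold plus the cohort transforms.
#' @export
fit_final <- function(table, threshold = 0.95, selector = "PCA",
                      classifier = "SVM", cfg = run_config()) {
  ff <- fit_fold(table, seq_len(nrow(table$features)), threshold, selector,
                 classifier, cfg, smote_seed = cfg$seed)
  if (is.null(ff$model)) stop("final selector returned zero features")
  ff$table <- table
  ff$cell <- list(threshold = threshold, selector = selector,
                  classifier = classifier)
  class(ff) <- "final_model"
  ff
}

#' Transform subjects into the final model's input space
#'
#' @param final a `final_model`. @param X raw feature matrix (107 columns).
#' @export
final_transform <- function(final, X) {
  Z <- zscore_apply(final$zfit, X)
  apply_selector(final$selector_result, Z[, final$retained, drop = FALSE])
}

#' @export
predict.final_model <- function(object, newdata, type = "label", ...) {
  S <- final_transform(object, as.matrix(newdata))
  predict(object$model, S, type = type)
}
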