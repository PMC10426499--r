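test_that("metrics implements the standard definitions", {
  expect_equal(unname(metrics(14, 14, 1, 1)["accuracy"]), 28 / 30)
  expect_equal(unname(metrics(5, 5, 5, 5)), c(0.5, 0.5, 0.5))
  m <- metrics(0, 7, 3, 0)
  expect_true(is.na(m["sensitivity"]))  # no positives -> missing, not 0
  expect_equal(unname(m["specificity"]), 0.7)
  expect_error(metrics(0, 0, 0, 0), "all-zero")
  expect_error(metrics(-1, 2, 0, 0))
})

test_that("a 4-subject smoke cohort produces 4 folds that add up", {
  tab <- random_table(n = 4, d = 5, seed = 21,
                      labels = c(0L, 0L, 1L, 1L))
  cfg <- run_config(thresholds = 1, selectors = "p-value",
                    classifiers = "kNN", alpha = 1, seed = 1)
  gr <- suppressWarnings(loo_run(tab, cfg))
  expect_equal(nrow(gr$predictions), 4L)
  expect_equal(sort(unique(gr$predictions$fold)), 1:4)
  # confusion counts pool to N
  p <- gr$predictions
  expect_equal(sum(p$pred == 1 & p$truth == 1) + sum(p$pred == 0 & p$truth == 0) +
               sum(p$pred == 1 & p$truth == 0) + sum(p$pred == 0 & p$truth == 1),
               4L)
  expect_error(loo_run(tab[1:3, ], cfg), ">= 4 subjects")
})

test_that("stored aggregates match a recomputation from the predictions", {
  set.seed(22)
  tab <- random_table(n = 14, d = 8, seed = 22)
  tab$features[tab$labels == 1, 1:2] <- tab$features[tab$labels == 1, 1:2] + 2
  cfg <- run_config(thresholds = c(0.9, 1), selectors = c("p-value", "PCA"),
                    classifiers = c("LR", "kNN"), seed = 2)
  gr <- suppressWarnings(loo_run(tab, cfg))
  expect_equal(nrow(gr$grid), 8L)
  for (r in seq_len(nrow(gr$grid))) {
    sub <- gr$predictions[gr$predictions$threshold == gr$grid$threshold[r] &
                          gr$predictions$selector == gr$grid$selector[r] &
                          gr$predictions$classifier == gr$grid$classifier[r] &
                          !gr$predictions$failed, ]
    expect_equal(gr$grid$accuracy[r], mean(sub$pred == sub$truth))
  }
  # counts table covers every threshold x selector combination
  expect_equal(nrow(gr$counts), 4L)
  expect_true(all(gr$counts$mean_n > 0))
})

test_that("no information flows from the held-out subject into the fit", {
  tab <- random_table(n = 12, d = 10, seed = 23)
  tab$features[tab$labels == 1, 1:3] <- tab$features[tab$labels == 1, 1:3] + 2
  cfg <- run_config(seed = 7)
  tr <- 2:12
  for (sel in c("p-value", "PCA", "LASSO")) {
    f1 <- suppressWarnings(fit_fold(tab, tr, 0.95, sel, "SVM", cfg,
                                    smote_seed = 99L))
    corrupted <- tab
    corrupted$features[1, ] <- 1e6  # arbitrary values in the held-out row
    f2 <- suppressWarnings(fit_fold(corrupted, tr, 0.95, sel, "SVM", cfg,
                                    smote_seed = 99L))
    expect_identical(f1$zfit, f2$zfit)
    expect_identical(f1$retained, f2$retained)
    expect_identical(f1$selector_result, f2$selector_result)
    expect_identical(f1$aug, f2$aug)
    expect_identical(f1$model, f2$model)
  }
})

test_that("all five classifiers learn an easy separation", {
  set.seed(24)
  n <- 40
  mk <- function(m) {
    X <- cbind(sig = c(rnorm(m / 2, 0), rnorm(m / 2, 4)),
               n1 = rnorm(m), n2 = rnorm(m))
    list(X = X, y = rep(0:1, each = m / 2))
  }
  tr <- mk(n); X <- tr$X; y <- tr$y
  te <- mk(20); Xte <- te$X; yte <- te$y
  for (clf in c("kNN", "SVM", "DT", "LR", "GB")) {
    m <- fit_classifier(X, y, clf)
    expect_gte(mean(predict(m, Xte) == yte), 0.9)
    s <- predict(m, Xte, type = "score")
    expect_equal(as.integer(s > 0), predict(m, Xte))
  }
  expect_error(fit_classifier(X, rep(1, n), "SVM"), "degenerate")
  m <- fit_classifier(X, y, "SVM")
  expect_error(predict(m, Xte[, 1:2]), "dimension mismatch")
})

test_that("the final model reuses the fold path and predicts the cohort", {
  tab <- random_table(n = 16, d = 10, seed = 25)
  tab$features[tab$labels == 1, 1:3] <- tab$features[tab$labels == 1, 1:3] + 2.5
  fin <- fit_final(tab, threshold = 0.95, selector = "PCA",
                   classifier = "SVM", cfg = run_config(seed = 3))
  expect_s3_class(fin, "final_model")
  expect_equal(nrow(fin$aug$features), 32L)  # SMOTE doubled the cohort
  pr <- predict(fin, tab$features)
  expect_length(pr, 16L)
  expect_gte(mean(pr == tab$labels), 0.8)
})
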