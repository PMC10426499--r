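test_that("exact Shapley attributions satisfy the SHAP axioms", {
  set.seed(31)
  B <- matrix(rnorm(20 * 4), 20, 4, dimnames = list(NULL, paste0("PC", 1:4)))
  inst <- matrix(rnorm(3 * 4), 3, 4, dimnames = list(NULL, paste0("PC", 1:4)))

  # linear model with a provably ignored input (zero weight on PC3)
  w <- c(2, -1, 0, 0.5)
  f <- function(X) as.vector(X %*% w)
  rep <- shap_explain(f, B, inst)

  # additivity: base + sum(phi) = model score, exactly
  expect_equal(rep$base + rowSums(rep$shap), f(inst), tolerance = 1e-10)
  expect_equal(rep$score, f(inst), tolerance = 1e-10)
  # dummy axiom
  expect_equal(unname(rep$shap[, "PC3"]), rep(0, 3), tolerance = 1e-10)
  # for a linear model with independent marginalisation,
  # phi_m = w_m * (x_m - mean(background_m))
  expect_equal(rep$shap[1, ],
               w * (inst[1, ] - colMeans(B)), tolerance = 1e-10)

  # symmetry: duplicated columns share the attribution equally
  B2 <- cbind(B[, 1], B[, 1], B[, 3:4])
  colnames(B2) <- paste0("PC", 1:4)
  i2 <- cbind(inst[, 1], inst[, 1], inst[, 3:4])
  colnames(i2) <- paste0("PC", 1:4)
  fsym <- function(X) as.vector(X %*% c(1, 1, 0.3, -0.2))
  rsym <- shap_explain(fsym, B2, i2)
  expect_equal(rsym$shap[, 1], rsym$shap[, 2], tolerance = 1e-10)

  expect_error(shap_explain(f, B, inst[, 1:3]), "dimension mismatch")
})

test_that("Shapley explanation works on a fitted pipeline model", {
  tab <- random_table(n = 16, d = 8, seed = 32)
  tab$features[tab$labels == 1, 1:3] <- tab$features[tab$labels == 1, 1:3] + 2.5
  fin <- fit_final(tab, 0.95, "PCA", "SVM", run_config(seed = 4))
  rep <- shap_explain(fin)
  k <- fin$selector_result$projection$k
  expect_equal(ncol(rep$shap), k)
  expect_equal(nrow(rep$shap), 16L)
  # additivity against the actual SVM decision score
  sc <- predict(fin, tab$features, type = "score")
  expect_equal(unname(rep$base + rowSums(rep$shap)), unname(sc), tolerance = 1e-8)
  expect_true(all(rep$mean_abs >= 0))
})

test_that("pc_class_attribution applies the half-max squared-loading rule", {
  cls <- c(a = "textural", b = "shape-size", c = "shape-size")
  # identity loadings -> each PC fully attributed to its feature's class
  L <- diag(3); dimnames(L) <- list(c("a", "b", "c"), NULL)
  att <- pc_class_attribution(L, cls)
  expect_equal(att$dominant, c("textural", "shape-size", "shape-size"))
  expect_equal(att$textural[1], 1)
  expect_equal(att$`shape-size`[2], 1)

  # hand-computed case: loadings (0.9, 0.1, 0.1); only 0.81 survives half-max
  L2 <- matrix(c(0.9, 0.1, 0.1), 3, 1, dimnames = list(c("a", "b", "c"), NULL))
  att2 <- pc_class_attribution(L2, cls)
  expect_equal(att2$textural, 0.81)
  expect_equal(att2$`shape-size`, 0)
  expect_equal(att2$dominant, "textural")

  # invariant to feature ordering; half-max always keeps >= 1 loading
  set.seed(33)
  L3 <- matrix(rnorm(12), 4, 3,
               dimnames = list(c("a", "b", "c", "d"), NULL))
  cls3 <- c(a = "textural", b = "first-order", c = "shape-size",
            d = "textural")
  att3 <- pc_class_attribution(L3, cls3)
  p <- c(3, 1, 4, 2)
  att3p <- pc_class_attribution(L3[p, ], cls3)
  expect_equal(att3[, 1:4], att3p[, 1:4])
  expect_true(all(rowSums(att3[, 2:4]) > 0))
  expect_error(pc_class_attribution(L3[0, , drop = FALSE], cls3), "empty")
})

test_that("explanation report serialises to JSON", {
  tab <- random_table(n = 12, d = 6, seed = 34)
  tab$features[tab$labels == 1, 1] <- tab$features[tab$labels == 1, 1] + 3
  fin <- fit_final(tab, 1, "PCA", "LR", run_config(seed = 5))
  er <- explain_report(fin)
  expect_s3_class(er, "explain_report")
  expect_equal(nrow(er$attribution), fin$selector_result$projection$k)
  path <- file.path(withr::local_tempdir(), "report.json")
  write_explain_report(er, path)
  back <- jsonlite::read_json(path)
  expect_equal(back$base, er$shap$base, tolerance = 1e-12)
  expect_length(back$attribution, nrow(er$attribution))
})
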