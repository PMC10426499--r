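test_that("translate_mask applies the whole-voxel rounding rule", {
  v <- box_volume(dims = c(70L, 70L, 20L), box = c(40L, 10L, 6L))
  n0 <- sum(v$mask)

  expect_identical(translate_mask(v, translation_spec(0, "x")), v)

  # 40-voxel box, +30% along x -> 12 voxels
  t30 <- translate_mask(v, translation_spec(0.30, "x"))
  expect_equal(sum(t30$mask), n0)  # voxel count preserved
  expect_equal(unname(radiostab:::mask_bbox(t30$mask)$min[1] -
                        radiostab:::mask_bbox(v$mask)$min[1]), 12)
  expect_identical(t30$intensities, v$intensities)

  # 0.5% of 40 voxels = 0.2 -> floor of one voxel, never a no-op
  tmin <- translate_mask(v, translation_spec(0.005, "x"))
  expect_equal(unname(radiostab:::mask_bbox(tmin$mask)$min[1] -
                        radiostab:::mask_bbox(v$mask)$min[1]), 1)

  # negative fractions go the other way
  tneg <- translate_mask(v, translation_spec(-0.30, "y"))
  expect_equal(unname(radiostab:::mask_bbox(tneg$mask)$min[2] -
                        radiostab:::mask_bbox(v$mask)$min[2]), -3)

  # clipping at the boundary errors with subject and spec named
  vs <- box_volume(dims = c(12L, 12L, 12L), box = c(10L, 4L, 4L))
  expect_error(translate_mask(vs, translation_spec(0.30, "x"), subject = "S07"),
               "clips the mask.*S07")
})

test_that("overlap_fraction counts intersection voxels", {
  v <- box_volume(dims = c(40L, 40L, 12L), box = c(10L, 10L, 4L))
  expect_equal(overlap_fraction(v$mask, v$mask), 100)
  # shifted by half its width -> 50%
  t5 <- translate_mask(v, translation_spec(0.5, "x"))
  expect_equal(overlap_fraction(v$mask, t5$mask), 50)
  # disjoint
  m2 <- array(FALSE, dim(v$mask)); m2[1:2, 1:2, 1] <- TRUE
  expect_equal(overlap_fraction(v$mask, m2), 0)
  expect_error(overlap_fraction(array(FALSE, dim(v$mask)), m2),
               "empty original")
})

test_that("icc matches an independent ANOVA oracle and has its invariants", {
  a <- c(1, 2, 3, 4, 5, 6)
  b <- a + 100
  expect_equal(icc(a, b), icc_a1_oracle(a, b), tolerance = 1e-9)
  expect_lt(icc(a, b), 0.01)  # absolute agreement penalises the offset
  expect_equal(icc(a, a), 1)

  set.seed(31)
  for (i in 1:5) {
    x <- rnorm(8); y <- rnorm(8, mean = x, sd = 0.5)
    expect_equal(icc(x, y), icc_a1_oracle(x, y), tolerance = 1e-9)
    expect_equal(icc(x, y), icc(y, x), tolerance = 1e-12)          # symmetry
    expect_equal(icc(2 * x + 3, 2 * y + 3), icc(x, y), tolerance = 1e-9)
  }
  set.seed(32)
  expect_lt(abs(icc(rnorm(1000), rnorm(1000))), 0.1)
  expect_equal(icc(rep(2, 5), rep(2, 5)), 1)
  expect_error(icc(rep(1, 5), rep(2, 5)), "degenerate")
  expect_error(icc(1:2, 1:2))
})

test_that("robustness screen flags noise, keeps shape, logs degenerates", {
  coh <- small_cohort(n_per_class = 2, seed = 21, fill = "full")
  # inject: one fresh-noise feature (must fail stability), one constant
  # feature (must be flagged degenerate and excluded)
  inj <- function(v, cfg) {
    f <- extract_features(v, cfg)
    extra <- c("textural/fake/Noise" = rnorm(1), "textural/fake/Const" = 7)
    out <- c(f, extra)
    attr(out, "class_of") <- setNames(feature_classes(names(out)), names(out))
    out
  }
  set.seed(77)
  rep <- suppressMessages(robustness_screen(coh, extract_fn = inj))
  expect_s3_class(rep, "robustness_report")
  expect_false(rep$stable[rep$feature == "textural/fake/Noise"])
  expect_true(rep$degenerate[rep$feature == "textural/fake/Const"])
  expect_false(rep$robust[rep$feature == "textural/fake/Const"])
  # shape-size features bypass the screen entirely
  expect_false(any(grepl("^shape-size/", rep$feature)))
  ret <- robust_features(rep)
  expect_length(grep("^shape-size/", ret), 14L)
  # screen output is a subset of its input
  expect_true(all(setdiff(ret, grep("^shape-size/", ret, value = TRUE))
                  %in% rep$feature))
  # overlap percentages: minimal translations overlap far more than maximal
  ov <- attr(rep, "overlap")
  expect_true(all(ov[grepl("0.005", names(ov))] >
                    ov[grepl("0.3", names(ov))]))
  expect_error(robustness_screen(coh[1:2]), ">= 3 subjects")
})

test_that("robustness report round-trips through CSV", {
  coh <- small_cohort(n_per_class = 2, seed = 21, fill = "full")
  rep <- suppressMessages(robustness_screen(coh))
  path <- file.path(withr::local_tempdir(), "report.csv")
  write_robustness_report(rep, path)
  back <- read_robustness_report(path)
  expect_equal(as.data.frame(back), as.data.frame(rep), tolerance = 1e-15,
               ignore_attr = TRUE)
})
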