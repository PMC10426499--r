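test_that("cohort generation is deterministic and correctly sized", {
  cfg <- small_phantom_cfg(n_per_class = 2, seed = 11)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  expect_length(a, 4L)
  expect_setequal(vapply(a, `[[`, 0L, "label"), c(1L, 0L))
  # different seed changes the data
  c2 <- generate_cohort(small_phantom_cfg(n_per_class = 2, seed = 12))
  expect_false(identical(a[[1]]$volume$intensities, c2[[1]]$volume$intensities))
})

test_that("shell voxel count matches the analytic ellipsoid-shell volume", {
  cfg <- small_phantom_cfg(n_per_class = 2, seed = 1)
  coh <- generate_cohort(cfg)
  v <- coh[[1]]$volume  # 1 mm spacing
  analytic <- 4 / 3 * pi * (prod(cfg$outer) - prod(cfg$inner))
  expect_lt(abs(sum(v$mask) * prod(v$spacing) - analytic) / analytic, 0.10)
})

test_that("ROI intensities have the configured mean and SD", {
  coh <- generate_cohort(small_phantom_cfg(n_per_class = 5, seed = 3))
  m <- vapply(coh, function(s) mean(s$volume$intensities[s$volume$mask]), 0)
  # cohort-level check: smoothing correlates voxels, so the SE of the mean is
  # estimated from the spread of per-subject ROI means
  expect_lt(abs(mean(m) - 140), 3 * sd(m) / sqrt(length(m)) + 1e-9)
  # within-ROI SD is biased low when the correlation length is comparable to
  # the wall thickness (deviations are measured about the local shell mean),
  # so the check is loose at this small test geometry
  s <- vapply(coh, function(s) sd(s$volume$intensities[s$volume$mask]), 0)
  expect_lt(abs(mean(s) - 25) / 25, 0.35)
})

test_that("mask keeps a >= 35% bounding-box margin and bad geometry errors", {
  coh <- generate_cohort(small_phantom_cfg(n_per_class = 2, seed = 1))
  v <- coh[[1]]$volume
  bb <- radiostab:::mask_bbox(v$mask)
  marg <- radiostab:::mask_margins(v)
  expect_true(all(marg >= ceiling(0.35 * bb$nvox)))
  # a shell thinner than a voxel is empty
  expect_error(generate_cohort(
    phantom_config(grid_shape = c(30L, 30L, 30L), outer = c(2, 2, 2),
                   inner = c(1.9, 1.9, 1.9))), "empty shell")
  # a grid too small for the translation margin is rejected
  expect_error(generate_cohort(
    phantom_config(grid_shape = c(44L, 44L, 56L))), "margin")
  expect_error(phantom_config(inner = c(25, 25, 30)), "strictly smaller")
})

test_that("a large class mean gap separates ROI means with zero overlap", {
  cfg <- small_phantom_cfg(
    n_per_class = 4, seed = 5,
    class_params = list(CA = list(mean = 350, sd = 20, corr_len = 3),
                        AS = list(mean = 150, sd = 20, corr_len = 3)))
  coh <- generate_cohort(cfg)
  m <- vapply(coh, function(s) mean(s$volume$intensities[s$volume$mask]), 0)
  y <- vapply(coh, `[[`, 0L, "label")
  expect_gt(min(m[y == 1]), max(m[y == 0]))
})

test_that("identical class parameters give chance-level classification", {
  # downstream control: with no class difference, pooled LOO accuracy over
  # 5 seeds stays inside the 95% binomial interval around 0.5
  hits <- 0L; total <- 0L
  for (seed in 1:5) {
    cfg <- small_phantom_cfg(
      n_per_class = 3, seed = seed,
      class_params = list(CA = list(mean = 200, sd = 20, corr_len = 3),
                          AS = list(mean = 200, sd = 20, corr_len = 3)))
    tab <- suppressMessages(build_feature_table(
      preprocess_cohort(generate_cohort(cfg))))
    gr <- suppressWarnings(suppressMessages(loo_run(
      tab, run_config(thresholds = 1, selectors = "PCA",
                      classifiers = "kNN", seed = seed))))
    ok <- !gr$predictions$failed
    hits <- hits + sum(gr$predictions$pred[ok] == gr$predictions$truth[ok])
    total <- total + sum(ok)
  }
  lo <- qbinom(0.025, total, 0.5)
  hi <- qbinom(0.975, total, 0.5)
  expect_gte(hits, lo)
  expect_lte(hits, hi)
})

test_that("cohorts round-trip through NRRD + labels.csv", {
  coh <- generate_cohort(small_phantom_cfg(n_per_class = 2, seed = 2))
  dir <- withr::local_tempdir()
  write_cohort(coh, dir)
  expect_true(file.exists(file.path(dir, "labels.csv")))
  back <- read_cohort(dir)
  expect_equal(length(back), length(coh))
  expect_equal(back[[1]]$volume$intensities, coh[[1]]$volume$intensities)
  expect_identical(back[[1]]$volume$mask, coh[[1]]$volume$mask)
  expect_equal(vapply(back, `[[`, 0L, "label"),
               vapply(coh, `[[`, 0L, "label"))
})
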