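# Shared fixtures. Phantom geometry here is scaled down from the package
# defaults to keep unit tests fast; the acceptance tests use the defaults.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, .fixture_cache)) assign(key, force(expr), .fixture_cache)
  get(key, .fixture_cache)
}

# small phantom: ~500 ROI voxels after 2 mm resampling
small_phantom_cfg <- function(n_per_class = 3L, seed = 1L, ...) {
  phantom_config(n_per_class = n_per_class,
                 grid_shape = c(40L, 40L, 48L),
                 outer = c(10, 10, 12), inner = c(6, 6, 7.5),
                 seed = seed, ...)
}

# preprocessed small cohort + feature table, cached per (n, seed, fill)
small_table <- function(n_per_class = 3L, seed = 1L, fill = "shell") {
  key <- sprintf("tab_%d_%d_%s", n_per_class, seed, fill)
  cached(key, {
    coh <- preprocess_cohort(
      generate_cohort(small_phantom_cfg(n_per_class, seed, fill = fill)))
    suppressMessages(build_feature_table(coh))
  })
}

small_cohort <- function(n_per_class = 3L, seed = 1L, fill = "shell") {
  key <- sprintf("coh_%d_%d_%s", n_per_class, seed, fill)
  cached(key, preprocess_cohort(
    generate_cohort(small_phantom_cfg(n_per_class, seed, fill = fill))))
}

# box-shaped volume with a centred cuboid mask
box_volume <- function(dims = c(20L, 20L, 20L), box = c(8L, 8L, 8L),
                       value = 100, spacing = c(1, 1, 1)) {
  arr <- array(value, dim = dims)
  msk <- array(FALSE, dim = dims)
  lo <- (dims - box) %/% 2 + 1L
  hi <- lo + box - 1L
  msk[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- TRUE
  volume_with_mask(arr, spacing, msk)
}

# synthetic gaussian feature table (no imaging), named f01..fNN
random_table <- function(n = 20, d = 10, seed = 1, labels = NULL) {
  set.seed(seed)
  X <- matrix(rnorm(n * d), n, d,
              dimnames = list(NULL, sprintf("f%02d", seq_len(d))))
  if (is.null(labels)) labels <- rep(0:1, length.out = n)
  feature_table(X, labels, setNames(rep("textural", d), colnames(X)))
}

# independent ICC(A,1) oracle via ANOVA mean squares (long-format model),
# kept free of the package's closed-form implementation
icc_a1_oracle <- function(a, b) {
  n <- length(a)
  df <- data.frame(y = c(a, b),
                   subj = factor(rep(seq_len(n), 2)),
                   rater = factor(rep(1:2, each = n)))
  ms <- suppressWarnings(anova(stats::lm(y ~ subj + rater,
                                         data = df)))[["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  (msr - mse) / (msr + mse + 2 / n * (msc - mse))
}
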