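#' SMOTE configuration
#'
#' @param q_neighbors number of same-class nearest neighbours considered when
#'   interpolating (default 5); reduced with a warning when a class has too
#'   few members.
#' @param seed integer RNG seed for neighbour choice and interpolation.
#' @export
smote_config <- function(q_neighbors = 5L, seed = 1L) {
  stopifnot(q_neighbors >= 1)
  structure(list(q_neighbors = as.integer(q_neighbors),
                 seed = as.integer(seed)),
            class = "smote_config")
}

#' Per-class duplicate-by-SMOTE augmentation
#'
#' Doubles a balanced training set: for each class with `n_c` members,
#' exactly `n_c` synthetic samples are generated — one per original sample,
#' placed uniformly at random on the segment connecting the sample to one of
#' its `q` nearest same-class neighbours (Euclidean metric; the neighbour is
#' drawn uniformly among the q nearest). The output is the originals followed
#' by the synthetics, so the size is exactly `2 * (n_A + n_B)` and the class
#' ratio is preserved. Synthetic labels equal their parents'; no synthetic
#' ever crosses classes. A fixed seed reproduces the synthetic set exactly.
#'
#' @param x a `feature_table` or numeric matrix (samples x features).
#' @param y binary labels (ignored when `x` is a `feature_table`).
#' @param cfg a [smote_config()].
#' @return same shape of object as `x`: an augmented `feature_table`, or a
#'   list with `features` and `labels` for matrix input.
#' @export
smote_augment <- function(x, y = NULL, cfg = smote_config()) {
  is_ft <- inherits(x, "feature_table")
  X <- if (is_ft) x$features else as.matrix(x)
  y <- if (is_ft) x$labels else as.integer(y)
  stopifnot(length(y) == nrow(X))
  if (length(unique(y)) < 2) stop("both classes must be present")

  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(cfg$seed)

  synth <- list()
  synth_y <- integer(0)
  for (cl in c(1L, 0L)) {
    idx <- which(y == cl)
    n_c <- length(idx)
    if (n_c < 2) stop("class ", cl, " has fewer than 2 members")
    q <- cfg$q_neighbors
    if (n_c - 1 < q) {
      q <- n_c - 1
      warning("smote_augment: q reduced to ", q, " for class ", cl)
    }
    Xc <- X[idx, , drop = FALSE]
    D2 <- as.matrix(dist(Xc))^2
    diag(D2) <- Inf
    for (i in seq_len(n_c)) {
      nb <- order(D2[i, ])[seq_len(q)]
      pick <- nb[sample.int(q, 1)]
      u <- runif(1)
      synth[[length(synth) + 1L]] <- Xc[i, ] + u * (Xc[pick, ] - Xc[i, ])
      synth_y <- c(synth_y, cl)
    }
  }
  Xs <- do.call(rbind, synth)
  rownames(Xs) <- sprintf("synth%03d", seq_len(nrow(Xs)))
  out_X <- rbind(X, Xs)
  out_y <- c(y, synth_y)
  if (is_ft) feature_table(out_X, out_y, x$class_of)
  else list(features = out_X, labels = out_y)
}
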