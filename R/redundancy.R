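#' Remove internally redundant features by absolute Spearman correlation
#'
#' Whenever a pair of features has `|Spearman rho| > threshold`, only one of
#' the two is kept: the one with the lower mean absolute correlation against
#' the remaining features. The procedure is greedy and deterministic: the
#' currently highest-correlated offending pair is resolved first, mean
#' correlations are recomputed over the surviving set, and the process
#' repeats; ties in the keep rule are broken by lexicographic feature name.
#' A threshold of 1 removes nothing.
#'
#' Constant features have undefined Spearman correlation; they are treated as
#' having correlation 0 with everything (and are therefore never removed
#' here), with a message.
#'
#' @param table a `feature_table` or numeric matrix (subjects x features).
#' @param threshold correlation threshold in (0, 1]; the benchmark grid uses
#'   0.80, 0.85, 0.90, 0.95 and 1.
#' @return character vector of retained feature names.
#' @export
correlation_filter <- function(table, threshold) {
  stopifnot(is.numeric(threshold), length(threshold) == 1L,
            threshold > 0, threshold <= 1)
  X <- if (inherits(table, "feature_table")) table$features else as.matrix(table)
  if (nrow(X) < 2) stop("correlation filter needs >= 2 subjects")
  nms <- colnames(X)
  if (is.null(nms)) stop("features must be named")
  const <- apply(X, 2, function(v) var(v) == 0 || !is.finite(var(v)))
  if (any(const))
    message("correlation_filter: ", sum(const),
            " constant feature(s) treated as correlation 0")
  C <- suppressWarnings(abs(cor(X, method = "spearman")))
  C[is.na(C)] <- 0
  C[const, ] <- 0
  C[, const] <- 0
  diag(C) <- 0

  keep <- nms
  Cw <- C
  repeat {
    mx <- max(Cw)
    if (mx <= threshold) break
    # highest offending pair; ties resolved by lexicographic pair order
    cand <- which(Cw == mx, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    pair_names <- cbind(keep[cand[, 1]], keep[cand[, 2]])
    ord <- order(pair_names[, 1], pair_names[, 2])
    i <- cand[ord[1], 1]
    j <- cand[ord[1], 2]
    others <- setdiff(seq_along(keep), c(i, j))
    mi <- if (length(others)) mean(Cw[i, others]) else 0
    mj <- if (length(others)) mean(Cw[j, others]) else 0
    drop_idx <- if (mi > mj) i
      else if (mj > mi) j
      else if (keep[i] <= keep[j]) j else i  # tie: keep lexicographic smaller
    keep <- keep[-drop_idx]
    Cw <- Cw[-drop_idx, -drop_idx, drop = FALSE]
  }
  keep
}
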