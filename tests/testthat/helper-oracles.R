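# Independent oracles used by unit and acceptance tests. These deliberately
# re-derive the rules from their definitions with plain loops, sharing no
# code with the package implementation.

# Does synthetic point s lie on a segment between two rows of `originals`
# (convex combination with one shared coefficient across coordinates)?
on_segment <- function(s, originals, tol = 1e-8) {
  for (i in seq_len(nrow(originals))) {
    for (j in seq_len(nrow(originals))) {
      if (i == j) next
      d <- originals[j, ] - originals[i, ]
      r <- s - originals[i, ]
      nz <- abs(d) > tol
      if (!any(nz)) next
      u <- r[nz][1] / d[nz][1]
      if (u >= -tol && u <= 1 + tol && max(abs(r - u * d)) < 1e-6) return(TRUE)
    }
  }
  FALSE
}

# Brute-force redundancy-filter oracle: highest offending pair first, drop
# the member with the higher mean absolute Spearman correlation to the rest,
# lexicographic tie-break.
filter_oracle <- function(X, threshold) {
  keep <- colnames(X)
  repeat {
    C <- suppressWarnings(abs(cor(X[, keep, drop = FALSE],
                                  method = "spearman")))
    C[is.na(C)] <- 0
    diag(C) <- 0
    best <- c(NA, NA); best_v <- threshold
    for (i in seq_along(keep))
      for (j in seq_along(keep))
        if (i < j && C[i, j] > best_v) {
          best_v <- C[i, j]; best <- c(i, j)
        } else if (i < j && !is.na(best[1]) && C[i, j] == best_v) {
          if (keep[i] < keep[best[1]] ||
              (keep[i] == keep[best[1]] && keep[j] < keep[best[2]]))
            best <- c(i, j)
        }
    if (is.na(best[1])) break
    i <- best[1]; j <- best[2]
    others <- setdiff(seq_along(keep), best)
    mi <- if (length(others)) mean(C[i, others]) else 0
    mj <- if (length(others)) mean(C[j, others]) else 0
    drop <- if (mi > mj) i else if (mj > mi) j
            else if (keep[i] <= keep[j]) j else i
    keep <- keep[-drop]
  }
  keep
}
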