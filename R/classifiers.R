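# In-package classifiers. The evaluation harness needs five model families
# (kNN, SVM, DT, LR, GB) with a common fit/predict interface and a real-valued
# decision score (used by the Shapley explainer). All fits are deterministic
# given the data.

#' Fit a classifier
#'
#' @param X numeric matrix (samples x features).
#' @param y binary labels (1 = positive/CA).
#' @param method one of `"kNN"`, `"SVM"`, `"DT"`, `"LR"`, `"GB"`.
#' @param params named list of hyperparameters overriding the defaults:
#'   kNN: `k` (5); SVM: `C` (1), `gamma` (`1 / (d * mean var)`, the common
#'   "scale" heuristic); DT: `max_depth` (3), `min_split` (5);
#'   GB: `n_trees` (100), `learning_rate` (0.1), `max_depth` (2); LR: none.
#' @return a `radiostab_model`.
#' @export
fit_classifier <- function(X, y, method = c("kNN", "SVM", "DT", "LR", "GB"),
                           params = list()) {
  method <- match.arg(method)
  X <- as.matrix(X)
  y <- as.integer(y)
  stopifnot(nrow(X) == length(y), all(y %in% 0:1))
  if (length(unique(y)) < 2) stop("training labels are degenerate (one class)")
  fit <- switch(method,
    kNN = fit_knn(X, y, params),
    SVM = fit_svm(X, y, params),
    DT = fit_cart(X, y, params),
    LR = fit_lr(X, y, params),
    GB = fit_gb(X, y, params))
  structure(list(method = method, fit = fit, d = ncol(X)),
            class = "radiostab_model")
}

#' Predict with a fitted classifier
#'
#' @param object a `radiostab_model`. @param newdata matrix of samples.
#' @param type `"label"` (0/1) or `"score"` (real; positive favours class 1).
#' @param ... unused.
#' @export
predict.radiostab_model <- function(object, newdata, type = c("label", "score"),
                                    ...) {
  type <- match.arg(type)
  X <- as.matrix(newdata)
  if (ncol(X) != object$d) stop("feature-dimension mismatch")
  s <- switch(object$method,
    kNN = score_knn(object$fit, X),
    SVM = score_svm(object$fit, X),
    DT = score_cart(object$fit, X),
    LR = score_lr(object$fit, X),
    GB = score_gb(object$fit, X))
  if (type == "score") s else as.integer(s > 0)
}

# ---- kNN ------------------------------------------------------------------

fit_knn <- function(X, y, params) {
  k <- params$k %||% 5L
  list(X = X, y = y, k = min(k, nrow(X)))
}

score_knn <- function(fit, X) {
  apply(X, 1, function(p) {
    d2 <- colSums((t(fit$X) - p)^2)
    nb <- order(d2)[seq_len(fit$k)]  # order() is deterministic on ties
    mean(fit$y[nb]) - 0.5
  })
}

# ---- SVM (RBF kernel, soft margin, SMO solver) ---------------------------

rbf_kernel <- function(A, B, gamma) {
  an <- rowSums(A^2)
  bn <- rowSums(B^2)
  exp(-gamma * (outer(an, bn, "+") - 2 * A %*% t(B)))
}

fit_svm <- function(X, y, params) {
  C <- params$C %||% 1
  v <- mean(apply(X, 2, var))
  gamma <- params$gamma %||% (1 / (ncol(X) * max(v, 1e-12)))
  yy <- ifelse(y == 1, 1, -1)
  n <- nrow(X)
  K <- rbf_kernel(X, X, gamma)
  alpha <- numeric(n)
  b <- 0
  tol <- 1e-4
  # SMO with deterministic working-pair selection (most violating pair).
  fcache <- rep(0, n)  # decision values without b
  for (iter in seq_len(300 * n)) {
    E <- fcache + b - yy
    # KKT violation measure per sample
    viol <- numeric(n)
    up <- (yy * E < -tol & alpha < C - 1e-12)
    dn <- (yy * E > tol & alpha > 1e-12)
    viol[up] <- abs(E[up])
    viol[dn] <- pmax(viol[dn], abs(E[dn]))
    if (max(viol) < tol) break
    i <- which.max(viol)
    j <- which.max(abs(E - E[i]) * (seq_len(n) != i))
    # bounds
    if (yy[i] != yy[j]) {
      L <- max(0, alpha[j] - alpha[i]); H <- min(C, C + alpha[j] - alpha[i])
    } else {
      L <- max(0, alpha[i] + alpha[j] - C); H <- min(C, alpha[i] + alpha[j])
    }
    if (H - L < 1e-12) { fcache <- K %*% (alpha * yy); next }
    eta <- K[i, i] + K[j, j] - 2 * K[i, j]
    if (eta <= 1e-12) { fcache <- K %*% (alpha * yy); next }
    aj_new <- min(H, max(L, alpha[j] + yy[j] * (E[i] - E[j]) / eta))
    if (abs(aj_new - alpha[j]) < 1e-12) break
    ai_new <- alpha[i] + yy[i] * yy[j] * (alpha[j] - aj_new)
    dai <- ai_new - alpha[i]; daj <- aj_new - alpha[j]
    fcache <- fcache + K[, i] * yy[i] * dai + K[, j] * yy[j] * daj
    # update b from the new errors at i and j (standard SMO rule)
    b1 <- b - E[i] - yy[i] * dai * K[i, i] - yy[j] * daj * K[i, j]
    b2 <- b - E[j] - yy[i] * dai * K[i, j] - yy[j] * daj * K[j, j]
    alpha[i] <- ai_new; alpha[j] <- aj_new
    b <- if (alpha[i] > 1e-12 && alpha[i] < C - 1e-12) b1
         else if (alpha[j] > 1e-12 && alpha[j] < C - 1e-12) b2
         else (b1 + b2) / 2
  }
  sv <- which(alpha > 1e-8)
  list(X = X[sv, , drop = FALSE], coef = (alpha * yy)[sv], b = b, gamma = gamma)
}

score_svm <- function(fit, X) {
  if (!nrow(fit$X)) return(rep(fit$b, nrow(X)))
  as.vector(rbf_kernel(X, fit$X, fit$gamma) %*% fit$coef + fit$b)
}

# ---- decision tree (CART, Gini) ------------------------------------------

fit_cart <- function(X, y, params) {
  max_depth <- params$max_depth %||% 3L
  min_split <- params$min_split %||% 5L
  grow <- function(idx, depth) {
    ys <- y[idx]
    p1 <- mean(ys)
    node <- list(leaf = TRUE, score = p1 - 0.5)
    if (depth >= max_depth || length(idx) < min_split ||
        p1 == 0 || p1 == 1) return(node)
    best <- list(gain = 0)
    g0 <- 2 * p1 * (1 - p1)
    for (j in seq_len(ncol(X))) {
      xv <- X[idx, j]
      cuts <- sort(unique(xv))
      if (length(cuts) < 2) next
      mids <- (cuts[-1] + cuts[-length(cuts)]) / 2
      for (cut in mids) {
        l <- xv <= cut
        nl <- sum(l); nr <- length(xv) - nl
        if (nl == 0 || nr == 0) next
        pl <- mean(ys[l]); pr <- mean(ys[!l])
        gini <- (nl * 2 * pl * (1 - pl) + nr * 2 * pr * (1 - pr)) / length(xv)
        gain <- g0 - gini
        if (gain > best$gain + 1e-12) best <- list(gain = gain, j = j, cut = cut)
      }
    }
    if (best$gain <= 1e-12) return(node)
    l <- X[idx, best$j] <= best$cut
    list(leaf = FALSE, j = best$j, cut = best$cut,
         left = grow(idx[l], depth + 1), right = grow(idx[!l], depth + 1))
  }
  grow(seq_along(y), 0L)
}

score_cart_one <- function(node, x) {
  while (!node$leaf)
    node <- if (x[node$j] <= node$cut) node$left else node$right
  node$score
}

score_cart <- function(fit, X) apply(X, 1, function(x) score_cart_one(fit, x))

# ---- logistic regression --------------------------------------------------

fit_lr <- function(X, y, params) {
  fit <- suppressWarnings(glm.fit(cbind(1, X), y, family = binomial()))
  cf <- coef(fit)
  cf[!is.finite(cf)] <- 0
  list(coef = cf)
}

score_lr <- function(fit, X) as.vector(cbind(1, X) %*% fit$coef)

# ---- gradient boosting (logistic loss, shallow CART on residuals) ---------

fit_gb <- function(X, y, params) {
  M <- params$n_trees %||% 100L
  lr <- params$learning_rate %||% 0.1
  max_depth <- params$max_depth %||% 2L
  n <- nrow(X)
  p0 <- mean(y)
  F0 <- log(p0 / (1 - p0))
  Fv <- rep(F0, n)
  trees <- vector("list", M)
  for (m in seq_len(M)) {
    p <- 1 / (1 + exp(-Fv))
    r <- y - p
    w <- pmax(p * (1 - p), 1e-6)
    tree <- gb_tree(X, r, w, seq_len(n), 0L, max_depth)
    trees[[m]] <- tree
    Fv <- Fv + lr * apply(X, 1, function(x) score_cart_one(tree, x))
  }
  list(F0 = F0, lr = lr, trees = trees)
}

# regression tree on gradient residuals with Newton leaf values
gb_tree <- function(X, r, w, idx, depth, max_depth) {
  leaf_val <- sum(r[idx]) / sum(w[idx])
  node <- list(leaf = TRUE, score = leaf_val)
  if (depth >= max_depth || length(idx) < 5) return(node)
  best <- list(gain = 0)
  sse0 <- sum((r[idx] - mean(r[idx]))^2)
  for (j in seq_len(ncol(X))) {
    xv <- X[idx, j]
    cuts <- sort(unique(xv))
    if (length(cuts) < 2) next
    mids <- (cuts[-1] + cuts[-length(cuts)]) / 2
    for (cut in mids) {
      l <- xv <= cut
      if (!any(l) || all(l)) next
      sse <- sum((r[idx][l] - mean(r[idx][l]))^2) +
             sum((r[idx][!l] - mean(r[idx][!l]))^2)
      gain <- sse0 - sse
      if (gain > best$gain + 1e-12) best <- list(gain = gain, j = j, cut = cut)
    }
  }
  if (best$gain <= 1e-12) return(node)
  l <- X[idx, best$j] <= best$cut
  list(leaf = FALSE, j = best$j, cut = best$cut,
       left = gb_tree(X, r, w, idx[l], depth + 1, max_depth),
       right = gb_tree(X, r, w, idx[!l], depth + 1, max_depth))
}

score_gb <- function(fit, X) {
  s <- rep(fit$F0, nrow(X))
  for (tree in fit$trees)
    s <- s + fit$lr * apply(X, 1, function(x) score_cart_one(tree, x))
  s
}

`%||%` <- function(a, b) if (is.null(a)) b else a
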