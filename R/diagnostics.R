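# Per-gene diagnostics for small two-group designs: exact rank-sum tests by
# complete enumeration, ROC/AUC via the Mann-Whitney identity, and a
# minimal linear soft-margin SVM trained by sequential minimal optimization
# with leave-one-out scoring. With 4-vs-4 groups the smallest achievable
# exact two-sided rank-sum p is 2/70 ~ 0.0286, so "p < 0.05" flags are
# attainable at that design size but "p < 0.01" is not.

#' Exact two-sample Wilcoxon rank-sum test
#'
#' The statistic `W` is the midrank sum of the first sample. For combined
#' sizes up to 20 the two-sided p is exact: all `choose(n1+n2, n1)` group
#' assignments of the (mid)ranks are enumerated and
#' `p = min(1, 2 * min(P[W' <= W], P[W' >= W]))`. Larger inputs use the
#' normal approximation with tie correction and continuity correction,
#' flagged via `method`.
#'
#' @param x,y Numeric vectors (both non-empty).
#' @return List with `W`, `p`, `method` (`"exact"` or `"normal_approx"`).
#' @export
wilcoxon_exact <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) stop("both groups must be non-empty")
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  r <- rank(c(x, y))
  W <- sum(r[seq_len(n1)])
  if (N <= 20) {
    sums <- utils::combn(N, n1, FUN = function(idx) sum(r[idx]))
    p_le <- mean(sums <= W + 1e-9)
    p_ge <- mean(sums >= W - 1e-9)
    list(W = W, p = min(1, 2 * min(p_le, p_ge)), method = "exact")
  } else {
    mu <- n1 * (N + 1) / 2
    ties <- table(r)
    sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    if (sigma2 <= 0) return(list(W = W, p = 1, method = "normal_approx"))
    z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sigma2)
    list(W = W, p = min(1, 2 * stats::pnorm(-abs(z))),
         method = "normal_approx")
  }
}

#' ROC curve and AUC
#'
#' AUC is computed by the Mann-Whitney identity
#' (concordant pairs + 0.5 * tied pairs) / (n_case * n_control); the curve
#' is a descending-score threshold sweep with tied scores grouped (so ties
#' appear as diagonal segments, consistent with the 0.5 pair credit). The
#' orientation is NOT forced above 0.5: the AUC of the raw score is
#' reported as-is, and `auc_direction_free = max(auc, 1 - auc)` is supplied
#' alongside for markers that decrease in cases.
#'
#' @param scores Numeric vector of scores (e.g. one gene's expression).
#' @param labels Logical or 0/1 vector; `TRUE`/1 marks cases.
#' @return List with `auc`, `auc_direction_free`, and `curve` (data.frame
#'   `fpr`, `tpr` from (0,0) to (1,1)).
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)
  auc <- (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- c(0, cumsum(vapply(thr, function(t0)
    sum(labels & scores == t0), 0)) / n1)
  fpr <- c(0, cumsum(vapply(thr, function(t0)
    sum(!labels & scores == t0), 0)) / n0)
  list(auc = auc, auc_direction_free = max(auc, 1 - auc),
       curve = data.frame(fpr = fpr, tpr = tpr))
}

svm_standardize <- function(X) {
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  list(X = sweep(sweep(X, 2, ctr), 2, scl, "/"), center = ctr, scale = scl)
}

#' Train a linear soft-margin SVM by sequential minimal optimization
#'
#' Solves the dual of the C-SVM with a linear kernel; features are
#' standardized internally on the training data (zero-variance columns are
#' left unscaled). The working pair is chosen deterministically (the second
#' index maximizes |E_i - E_j|), so training is reproducible. A sweep in
#' which no multiplier moves terminates the optimization; if `max_passes`
#' sweeps elapse without that happening, the best iterate is returned with
#' a warning and `converged = FALSE`.
#'
#' @param features Numeric matrix, samples in rows.
#' @param labels Logical or 0/1 vector (`TRUE`/1 = positive class).
#' @param C Box constraint (default 1).
#' @param tol KKT violation tolerance (default 1e-3).
#' @param max_passes Maximum number of full sweeps (default 50).
#' @return List of class `SvmModel` with `weights`, `bias`, `alpha`, `C`,
#'   `converged`, and the standardization (`center`, `scale`).
#' @export
svm_train <- function(features, labels, C = 1, tol = 1e-3, max_passes = 50) {
  X <- as.matrix(features)
  y <- ifelse(as.logical(labels), 1, -1)
  if (length(unique(y)) < 2) stop("need >= 1 sample per class")
  if (any(!is.finite(X))) stop("features must be finite")
  n <- nrow(X)
  std <- svm_standardize(X)
  Xs <- std$X
  K <- Xs %*% t(Xs)
  alpha <- numeric(n)
  b <- 0
  fcache <- function() as.numeric(K %*% (alpha * y)) + b
  converged <- FALSE
  for (sweep_i in seq_len(max_passes)) {
    changed <- 0L
    for (i in seq_len(n)) {
      f <- fcache()
      Ei <- f[i] - y[i]
      if (!((y[i] * Ei < -tol && alpha[i] < C) ||
            (y[i] * Ei > tol && alpha[i] > 0))) next
      E <- f - y
      js <- setdiff(seq_len(n), i)
      j <- js[which.max(abs(Ei - E[js]))]
      ai_old <- alpha[i]; aj_old <- alpha[j]
      if (y[i] != y[j]) {
        L <- max(0, aj_old - ai_old); H <- min(C, C + aj_old - ai_old)
      } else {
        L <- max(0, ai_old + aj_old - C); H <- min(C, ai_old + aj_old)
      }
      if (L >= H) next
      eta <- 2 * K[i, j] - K[i, i] - K[j, j]
      if (eta >= 0) next
      aj <- aj_old - y[j] * (Ei - E[j]) / eta
      aj <- min(H, max(L, aj))
      if (abs(aj - aj_old) < 1e-12) next
      ai <- ai_old + y[i] * y[j] * (aj_old - aj)
      b1 <- b - Ei - y[i] * (ai - ai_old) * K[i, i] -
        y[j] * (aj - aj_old) * K[i, j]
      b2 <- b - (E[j]) - y[i] * (ai - ai_old) * K[i, j] -
        y[j] * (aj - aj_old) * K[j, j]
      alpha[i] <- ai; alpha[j] <- aj
      b <- if (ai > 0 && ai < C) b1
           else if (aj > 0 && aj < C) b2
           else (b1 + b2) / 2
      changed <- changed + 1L
    }
    if (changed == 0L) { converged <- TRUE; break }
  }
  if (!converged)
    warning("SMO did not converge within max_passes sweeps; ",
            "returning the best iterate")
  w <- as.numeric(t(Xs) %*% (alpha * y))
  structure(list(weights = w, bias = b, alpha = alpha, C = C,
                 converged = converged,
                 center = std$center, scale = std$scale),
            class = "SvmModel")
}

#' Decision scores of a linear SVM
#'
#' @param model An `SvmModel` from [svm_train()].
#' @param features Numeric matrix, samples in rows.
#' @return Numeric vector of decision values `w . x + b`.
#' @export
svm_decision <- function(model, features) {
  X <- as.matrix(features)
  Xs <- sweep(sweep(X, 2, model$center), 2, model$scale, "/")
  as.numeric(Xs %*% model$weights) + model$bias
}

#' Leave-one-out SVM decision scores
#'
#' For each sample, an SVM is trained on the remaining samples and the
#' held-out decision score is recorded; the scores are suitable input for
#' [roc_auc()].
#'
#' @inheritParams svm_train
#' @return Numeric vector of held-out decision scores (one per sample).
#' @export
loocv_scores <- function(features, labels, C = 1) {
  X <- as.matrix(features)
  n <- nrow(X)
  if (n < 3) stop("need >= 3 samples for leave-one-out scoring")
  labels <- as.logical(labels)
  vapply(seq_len(n), function(i) {
    m <- suppressWarnings(svm_train(X[-i, , drop = FALSE], labels[-i], C = C))
    svm_decision(m, X[i, , drop = FALSE])
  }, 0)
}
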