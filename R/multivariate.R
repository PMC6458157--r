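# Unit-variance scaling, NIPALS PCA and PLS-DA, and seven-round
# cross-validated Q2Y, following the SIMCA conventions for omics profiles.

#' Unit-variance (UV) scaling
#'
#' Centres each variable and divides it by its standard deviation so that
#' every variable carries equal weight in the latent-variable models.
#' Constant variables (zero standard deviation) are dropped with a warning.
#'
#' @param x numeric matrix, samples in rows and variables in columns, or a
#'   \linkS4class{MirnaExperiment} (transposed internally).
#' @return list with the scaled matrix \code{x} and \code{params}
#'   (\code{mean}, \code{sd}, \code{dropped}).
#' @export
uvScale <- function(x) {
  if (is(x, "MirnaExperiment")) x <- t(assay(x))
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("at least 2 samples are required for scaling")
  mu <- colMeans(x)
  sk <- apply(x, 2L, stats::sd)
  dropped <- colnames(x)[sk == 0]
  if (length(dropped))
    warning("dropping constant variable(s): ",
            paste(dropped, collapse = ", "))
  keep <- sk > 0
  scaled <- sweep(sweep(x[, keep, drop = FALSE], 2L, mu[keep], "-"),
                  2L, sk[keep], "/")
  list(x = scaled, params = list(mean = mu[keep], sd = sk[keep],
                                 dropped = dropped))
}

# One NIPALS principal component of a centred matrix.
nipalsComponent <- function(X, tol = 1e-10, maxIter = 5000L) {
  t <- X[, which.max(apply(X, 2L, stats::var))]
  for (it in seq_len(maxIter)) {
    p <- crossprod(X, t) / sum(t^2)
    p <- p / sqrt(sum(p^2))
    tNew <- X %*% p
    if (sum((tNew - t)^2) / sum(tNew^2) < tol^2)
      return(list(t = as.vector(tNew), p = as.vector(p)))
    t <- tNew
  }
  NULL
}

#' NIPALS principal component analysis
#'
#' Iterative (NIPALS) extraction of principal components from a scaled
#' matrix. Scores and loadings agree with the singular value decomposition
#' of the matrix up to sign.
#'
#' @param x numeric matrix (samples x variables), already centred/scaled
#'   (see [uvScale()]).
#' @param nComponents number of components, at most
#'   \code{min(nrow - 1, ncol)}.
#' @param tol relative convergence tolerance of the score vector.
#' @param maxIter iteration cap per component.
#' @return a \linkS4class{LatentModel} with per-component R2X.
#' @export
pcaNipals <- function(x, nComponents = 2L, tol = 1e-10, maxIter = 5000L) {
  x <- as.matrix(x)
  if (nComponents > min(nrow(x) - 1L, ncol(x)))
    stop("nComponents must be <= min(samples - 1, variables)")
  ssTot <- sum(x^2)
  T <- matrix(0, nrow(x), nComponents,
              dimnames = list(rownames(x), paste0("PC", seq_len(nComponents))))
  P <- matrix(0, ncol(x), nComponents,
              dimnames = list(colnames(x), colnames(T)))
  r2x <- numeric(nComponents)
  E <- x
  for (a in seq_len(nComponents)) {
    comp <- nipalsComponent(E, tol = tol, maxIter = maxIter)
    if (is.null(comp))
      stop("NIPALS failed to converge for component ", a)
    T[, a] <- comp$t
    P[, a] <- comp$p
    E <- E - tcrossprod(comp$t, comp$p)
    r2x[a] <- sum(comp$t^2) / ssTot
  }
  new("LatentModel", method = "PCA", scores = T, loadings = P,
      weights = matrix(numeric(0), 0, 0), r2x = r2x, r2y = numeric(0),
      q2y = numeric(0))
}

# PLS1 via NIPALS on a centred response; returns scores, weights, loadings,
# response loadings and the regression coefficients for prediction.
pls1Fit <- function(X, y, nComponents) {
  n <- nrow(X)
  T <- matrix(0, n, nComponents)
  W <- matrix(0, ncol(X), nComponents)
  P <- matrix(0, ncol(X), nComponents)
  q <- numeric(nComponents)
  E <- X; f <- y
  for (a in seq_len(nComponents)) {
    w <- crossprod(E, f)
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) { nComponents <- a - 1L; break }
    w <- w / nw
    t <- E %*% w
    p <- crossprod(E, t) / sum(t^2)
    qa <- sum(f * t) / sum(t^2)
    E <- E - tcrossprod(t, p)
    f <- f - qa * t
    T[, a] <- t; W[, a] <- w; P[, a] <- p; q[a] <- qa
  }
  idx <- seq_len(nComponents)
  list(T = T[, idx, drop = FALSE], W = W[, idx, drop = FALSE],
       P = P[, idx, drop = FALSE], q = q[idx], nComponents = nComponents)
}

# Predicted response for new (identically scaled) data from a pls1Fit.
pls1Predict <- function(fit, Xnew) {
  yhat <- rep(0, nrow(Xnew))
  E <- Xnew
  for (a in seq_len(fit$nComponents)) {
    t <- E %*% fit$W[, a]
    yhat <- yhat + fit$q[a] * t
    E <- E - tcrossprod(t, fit$P[, a])
  }
  as.vector(yhat)
}

#' Partial least squares discriminant analysis (PLS-DA)
#'
#' PLS1 regression (NIPALS) of a centred 0/1 class response on the scaled
#' data matrix. Cumulative R2Y is the fraction of response variance
#' explained in training after each component.
#'
#' @param x scaled matrix (samples x variables).
#' @param labels two-class vector (factor, character or logical).
#' @param nComponents number of latent components (default 2).
#' @param caseClass optional label treated as class 1.
#' @return a \linkS4class{LatentModel} with scores, loadings, weights,
#'   per-component R2X and cumulative R2Y.
#' @export
plsda <- function(x, labels, nComponents = 2L, caseClass = NULL) {
  x <- as.matrix(x)
  isCase <- isCaseVector(labels, caseClass)
  if (length(unique(isCase)) < 2L) stop("both classes must be present")
  y <- as.numeric(isCase)
  yc <- y - mean(y)
  fit <- pls1Fit(x, yc, nComponents)
  if (fit$nComponents < 1L) stop("no PLS component could be extracted")
  ssX <- sum(x^2); ssY <- sum(yc^2)
  r2x <- vapply(seq_len(fit$nComponents), function(a)
    sum((fit$T[, a] %o% fit$P[, a])^2) / ssX, numeric(1))
  r2y <- vapply(seq_len(fit$nComponents), function(a) {
    sub <- list(T = fit$T[, seq_len(a), drop = FALSE],
                W = fit$W[, seq_len(a), drop = FALSE],
                P = fit$P[, seq_len(a), drop = FALSE],
                q = fit$q[seq_len(a)], nComponents = a)
    1 - sum((yc - pls1Predict(sub, x))^2) / ssY
  }, numeric(1))
  dimnames(fit$T) <- list(rownames(x),
                          paste0("LV", seq_len(fit$nComponents)))
  dimnames(fit$P) <- list(colnames(x), colnames(fit$T))
  dimnames(fit$W) <- dimnames(fit$P)
  new("LatentModel", method = "PLS-DA", scores = fit$T, loadings = fit$P,
      weights = fit$W, r2x = r2x, r2y = r2y, q2y = numeric(0))
}

#' Seven-round cross-validated Q2Y for PLS-DA
#'
#' Samples are assigned to seven folds and, for each fold, a PLS-DA model is
#' fitted on the remaining samples and used to predict the held-out centred
#' responses. Cumulative Q2Y after each component is 1 - PRESS/TSS. Fold
#' assignment is round-robin over a seed-shuffled sample order by default;
#' deterministic venetian-blind assignment (round-robin in the given order)
#' is also offered.
#'
#' @inheritParams plsda
#' @param folds number of cross-validation rounds (default 7).
#' @param assignment \code{"round_robin"} (seeded shuffle, default) or
#'   \code{"venetian"} (input order).
#' @param seed seed for the shuffled assignment.
#' @return numeric vector of cumulative Q2Y per component.
#' @export
q2yCrossval <- function(x, labels, nComponents = 2L, folds = 7L,
                        assignment = c("round_robin", "venetian"),
                        seed = 1L, caseClass = NULL) {
  x <- as.matrix(x)
  assignment <- match.arg(assignment)
  n <- nrow(x)
  if (n < folds) stop("need at least ", folds, " samples, got ", n)
  isCase <- isCaseVector(labels, caseClass)
  y <- as.numeric(isCase)
  ord <- if (assignment == "round_robin") {
    withSeed(seed, sample(n))
  } else seq_len(n)
  foldId <- integer(n)
  foldId[ord] <- rep_len(seq_len(folds), n)

  press <- numeric(nComponents)
  tss <- 0
  for (f in seq_len(folds)) {
    test <- foldId == f
    yTrain <- y[!test]
    yc <- y - mean(yTrain)
    fit <- pls1Fit(x[!test, , drop = FALSE], yc[!test], nComponents)
    for (a in seq_len(fit$nComponents)) {
      sub <- list(T = fit$T[, seq_len(a), drop = FALSE],
                  W = fit$W[, seq_len(a), drop = FALSE],
                  P = fit$P[, seq_len(a), drop = FALSE],
                  q = fit$q[seq_len(a)], nComponents = a)
      pred <- pls1Predict(sub, x[test, , drop = FALSE])
      press[a] <- press[a] + sum((yc[test] - pred)^2)
    }
    if (fit$nComponents < nComponents)
      press[seq(fit$nComponents + 1L, nComponents)] <- NA_real_
    tss <- tss + sum((yc[test])^2)
  }
  1 - press / tss
}
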