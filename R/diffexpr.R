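# Univariate and longitudinal differential-expression statistics with
# FDR control.

#' D'Agostino-Pearson omnibus normality test
#'
#' Combines the standardized sample skewness and kurtosis into the omnibus
#' statistic K2 = Z1(skewness)^2 + Z2(kurtosis)^2, referred to a chi-square
#' distribution with 2 degrees of freedom. Z1 uses the Johnson SU
#' approximation to the null distribution of skewness and Z2 the
#' Anscombe-Glynn transformation for kurtosis.
#'
#' @param x numeric vector, n >= 8, non-constant.
#' @return an object of class \code{htest} with the K2 statistic and p-value.
#' @export
dagostinoPearson <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 8L)
    stop("D'Agostino-Pearson test requires n >= 8, got ", n)
  if (stats::sd(x) == 0)
    stop("input is constant; normality test undefined")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  m3 <- mean((x - m)^3)
  m4 <- mean((x - m)^4)

  # skewness Z (Johnson SU transform of g1)
  g1 <- m3 / m2^1.5
  y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  W2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(0.5 * log(W2))
  alpha <- sqrt(2 / (W2 - 1))
  zSkew <- delta * log(y / alpha + sqrt((y / alpha)^2 + 1))

  # kurtosis Z (Anscombe-Glynn)
  b2 <- m4 / m2^2
  eB2 <- 3 * (n - 1) / (n + 1)
  varB2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (b2 - eB2) / sqrt(varB2)
  sqrtBeta1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  A <- 6 + 8 / sqrtBeta1 *
    (2 / sqrtBeta1 + sqrt(1 + 4 / sqrtBeta1^2))
  term <- (1 - 2 / A) / (1 + xk * sqrt(2 / (A - 4)))
  zKurt <- (1 - 2 / (9 * A) - sign(term) * abs(term)^(1 / 3)) /
    sqrt(2 / (9 * A))

  k2 <- zSkew^2 + zKurt^2
  p <- stats::pchisq(k2, df = 2, lower.tail = FALSE)
  structure(list(statistic = c(K2 = k2), parameter = c(df = 2),
                 p.value = p, method = "D'Agostino-Pearson omnibus test",
                 data.name = deparse(substitute(x))),
            class = "htest")
}

#' Compare two clinical groups, choosing the test by normality
#'
#' Runs the D'Agostino-Pearson normality test on each group; when both pass
#' at \code{alpha}, the groups are compared with Student's unpaired two-sided
#' t-test, otherwise with the two-sided Mann-Whitney test (exact for small
#' untied samples, normal approximation with tie correction otherwise). With
#' fewer than 8 observations in either group the normality test is undefined
#' and the Mann-Whitney branch is taken.
#'
#' @param x,y numeric vectors (each of length >= 2).
#' @param alpha significance level of the normality gate.
#' @return list with \code{testUsed} ("T_TEST" or "MANN_WHITNEY"),
#'   \code{statistic}, \code{p.value}, and the two normality p-values (NA
#'   when the gate was skipped).
#' @export
groupCompare <- function(x, y, alpha = 0.05) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 2L || length(y) < 2L)
    stop("both groups must have at least 2 observations")
  normP <- c(NA_real_, NA_real_)
  gaussian <- FALSE
  if (length(x) >= 8L && length(y) >= 8L &&
      stats::sd(x) > 0 && stats::sd(y) > 0) {
    normP <- c(dagostinoPearson(x)$p.value, dagostinoPearson(y)$p.value)
    gaussian <- all(normP > alpha)
  }
  if (gaussian) {
    ht <- stats::t.test(x, y, var.equal = TRUE)
    test <- "T_TEST"
  } else {
    ht <- suppressWarnings(stats::wilcox.test(x, y, exact = NULL,
                                              correct = TRUE))
    test <- "MANN_WHITNEY"
  }
  list(testUsed = test, statistic = unname(ht$statistic),
       p.value = ht$p.value, normalityP = normP)
}

#' Welch test on log-transformed counts (geometric-mean comparison)
#'
#' Comparison of log-transformed geometric means of expression counts
#' assuming unequal variances: a two-sided Welch t-test on
#' \code{log2(count + offset)}. The offset accommodates the zeros produced by
#' background subtraction.
#'
#' @param x,y non-negative count vectors.
#' @param offset pseudo-count added before the log (default 1).
#' @return list with \code{testUsed = "WELCH_LOG_GEOMEAN"},
#'   \code{statistic}, \code{p.value} and \code{log2Ratio} (difference of
#'   mean logs, i.e. the log2 geometric-mean ratio).
#' @export
welchLogGeomeanTest <- function(x, y, offset = 1) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (any(x < 0) || any(y < 0)) stop("counts must be non-negative")
  if (all(x == 0) || all(y == 0))
    stop("a group with all-zero counts cannot be log-compared")
  lx <- log2(x + offset); ly <- log2(y + offset)
  ht <- stats::t.test(lx, ly, var.equal = FALSE)
  list(testUsed = "WELCH_LOG_GEOMEAN", statistic = unname(ht$statistic),
       p.value = ht$p.value, log2Ratio = mean(lx) - mean(ly))
}

# Exact permutation p-value of the Friedman statistic for k = 3 untied
# repeated measures: under the null every subject's rank triple is an
# independent uniform permutation of (1,2,3). The joint distribution of the
# first two column rank sums is built by dynamic programming over subjects;
# the third sum is determined. Returns P(Q >= observed Q).
exactFriedmanP <- function(rankSums, n) {
  k <- 3L
  perms <- rbind(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                 c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  # joint probability of (R1, R2) built subject by subject; cell (i, j)
  # holds P(R1 = i - 1, R2 = j - 1); R3 is determined by the total
  cur <- matrix(0, 1L, 1L); cur[1L, 1L] <- 1
  for (i in seq_len(n)) {
    nxt <- matrix(0, nrow(cur) + 3L, ncol(cur) + 3L)
    for (p in seq_len(nrow(perms))) {
      r1 <- perms[p, 1L]; r2 <- perms[p, 2L]
      nxt[seq_len(nrow(cur)) + r1, seq_len(ncol(cur)) + r2] <-
        nxt[seq_len(nrow(cur)) + r1, seq_len(ncol(cur)) + r2] + cur / 6
    }
    cur <- nxt
  }
  qObs <- 12 / (n * k * (k + 1)) * sum(rankSums^2) - 3 * n * (k + 1)
  pTot <- 0
  for (i in seq_len(nrow(cur))) {
    for (j in seq_len(ncol(cur))) {
      if (cur[i, j] == 0) next
      r1 <- i - 1L; r2 <- j - 1L; r3 <- n * k * (k + 1) / 2 - r1 - r2
      q <- 12 / (n * k * (k + 1)) * (r1^2 + r2^2 + r3^2) - 3 * n * (k + 1)
      if (q >= qObs - 1e-9) pTot <- pTot + cur[i, j]
    }
  }
  pTot
}

# Greenhouse-Geisser epsilon from the sample covariance of the k repeated
# measures; bounded in [1/(k-1), 1], 1 under compound symmetry.
ggEpsilon <- function(S) {
  k <- nrow(S)
  sBar <- mean(S)
  dBar <- mean(diag(S))
  rowBar <- rowMeans(S)
  num <- (k * (dBar - sBar))^2
  den <- (k - 1) * (sum(S^2) - 2 * k * sum(rowBar^2) + k^2 * sBar^2)
  eps <- num / den
  min(max(eps, 1 / (k - 1)), 1)
}

#' Longitudinal test across gestational time points
#'
#' For complete subject-by-time-point profiles (3 time points), applies
#' repeated-measures ANOVA with the Greenhouse-Geisser sphericity correction
#' followed by a two-sided post test for linear trend when every time point
#' passes the D'Agostino-Pearson normality test at \code{alpha}; otherwise a
#' Friedman test followed by Dunn's pairwise comparisons with Bonferroni
#' adjustment over the three time-point pairs. The trend post test evaluates
#' the per-subject linear contrast (-1, 0, +1) against zero on the
#' within-subject error.
#'
#' @param values numeric matrix, subjects in rows, the 3 time points in
#'   columns. Subjects with missing values are dropped with a warning.
#' @param alpha significance level of the normality gate.
#' @return list with \code{testUsed} ("RM_ANOVA_GG" or "FRIEDMAN"),
#'   \code{statistic}, \code{p.value}, and either \code{epsilon} +
#'   \code{trendP} (Gaussian branch) or \code{dunn} (data.frame of pairwise
#'   Bonferroni-adjusted p-values).
#' @export
longitudinalTest <- function(values, alpha = 0.05) {
  values <- as.matrix(values)
  k <- ncol(values)
  complete <- stats::complete.cases(values)
  if (any(!complete)) {
    warning("dropping ", sum(!complete), " subject(s) with missing ",
            "time points")
    values <- values[complete, , drop = FALSE]
  }
  n <- nrow(values)
  if (n < 3L) stop("at least 3 complete subjects are required, got ", n)

  gaussian <- n >= 8L &&
    all(apply(values, 2L, function(v)
      stats::sd(v) > 0 && dagostinoPearson(v)$p.value > alpha))

  if (gaussian) {
    grand <- mean(values)
    timeMeans <- colMeans(values)
    subjMeans <- rowMeans(values)
    ssTime <- n * sum((timeMeans - grand)^2)
    ssSubj <- k * sum((subjMeans - grand)^2)
    ssTot <- sum((values - grand)^2)
    ssErr <- ssTot - ssTime - ssSubj
    dfTime <- k - 1
    dfErr <- (n - 1) * (k - 1)
    f <- (ssTime / dfTime) / (ssErr / dfErr)
    eps <- ggEpsilon(stats::cov(values))
    p <- stats::pf(f, eps * dfTime, eps * dfErr, lower.tail = FALSE)
    contrast <- values %*% c(-1, 0, 1)
    trendP <- stats::t.test(contrast)$p.value
    list(testUsed = "RM_ANOVA_GG", statistic = f, p.value = p,
         epsilon = eps, trendP = trendP, n = n)
  } else {
    ranks <- t(apply(values, 1L, rank))
    # all subjects internally tied: no evidence of a time effect, and the
    # tie-corrected statistic is 0/0
    noTies <- all(apply(values, 1L, function(v) !anyDuplicated(v)))
    if (all(abs(ranks - (k + 1) / 2) < .Machine$double.eps^0.5)) {
      ft <- list(statistic = 0, p.value = 1)
    } else if (k == 3L && n <= 12L && noTies) {
      # small samples without ties: exact permutation null of the Friedman
      # statistic instead of the chi-square approximation
      stat <- 12 / (n * k * (k + 1)) * sum(colSums(ranks)^2) -
        3 * n * (k + 1)
      ft <- list(statistic = stat,
                 p.value = exactFriedmanP(colSums(ranks), n))
    } else {
      ft <- stats::friedman.test(values)
    }
    meanRank <- colMeans(ranks)
    se <- sqrt(k * (k + 1) / (6 * n))
    pairs <- utils::combn(k, 2L)
    dunn <- data.frame(
      pair = apply(pairs, 2L, function(ij)
        paste(colnames(values)[ij] %||% ij, collapse = " vs ")),
      z = apply(pairs, 2L, function(ij)
        (meanRank[ij[1L]] - meanRank[ij[2L]]) / se))
    dunn$p.adj <- pmin(1, ncol(pairs) * 2 * stats::pnorm(-abs(dunn$z)))
    list(testUsed = "FRIEDMAN", statistic = unname(ft$statistic),
         p.value = ft$p.value, dunn = dunn, n = n)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up false-discovery-rate adjustment; q-values are monotone, clipped at
#' 1, and returned in input order.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return numeric vector of q-values.
#' @export
bhFdr <- function(p) {
  p <- as.numeric(p)
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1] with no missing values")
  stats::p.adjust(p, method = "BH")
}
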