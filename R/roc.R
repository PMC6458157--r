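# ROC construction, AUC, screen-positive thresholds at 100% detection rate
# with exact binomial intervals, and multi-marker combination.

orientScores <- function(scores, isCase, direction) {
  if (direction == "AUTO") {
    conc <- concordance(scores, isCase)
    direction <- if (conc >= 0.5) "UP_IN_CASES" else "DOWN_IN_CASES"
  }
  list(scores = if (direction == "DOWN_IN_CASES") -scores else scores,
       direction = direction)
}

# Mann-Whitney concordance probability, ties counted 1/2.
concordance <- function(scores, isCase) {
  cs <- scores[isCase]; ct <- scores[!isCase]
  cmp <- outer(cs, ct, ">") + 0.5 * outer(cs, ct, "==")
  mean(cmp)
}

#' Receiver operating characteristic curve
#'
#' Sweeps thresholds over the unique score values (a sample is test-positive
#' when its oriented score is at or above the threshold) and records the
#' operating points (false positive rate, detection rate) from (0,0) to
#' (1,1). The trapezoidal area under the curve equals the Mann-Whitney
#' concordance probability with ties counted one half. \code{AUTO}
#' orientation picks the direction giving AUC >= 0.5.
#'
#' @param scores numeric marker values, one per sample.
#' @param labels two-class labels; see \code{caseClass}.
#' @param direction \code{"AUTO"}, \code{"UP_IN_CASES"} or
#'   \code{"DOWN_IN_CASES"}.
#' @param caseClass label identifying cases (for logical labels, TRUE is the
#'   case).
#' @return a \linkS4class{RocCurve}.
#' @examples
#' rocCurve(c(3, 4, 1, 2), c(TRUE, TRUE, FALSE, FALSE),
#'          direction = "UP_IN_CASES")  # AUC 1
#' @export
rocCurve <- function(scores, labels, direction = "AUTO", caseClass = NULL) {
  scores <- as.numeric(scores)
  isCase <- isCaseVector(labels, caseClass)
  if (!any(isCase) || all(isCase)) stop("both classes must be present")
  ori <- orientScores(scores, isCase, direction)
  s <- ori$scores
  thr <- c(Inf, sort(unique(s), decreasing = TRUE))
  nCase <- sum(isCase); nCtrl <- sum(!isCase)
  dr <- vapply(thr, function(t) sum(s[isCase] >= t) / nCase, numeric(1))
  fpr <- vapply(thr, function(t) sum(s[!isCase] >= t) / nCtrl, numeric(1))
  aucVal <- sum(diff(fpr) * (utils::head(dr, -1) + utils::tail(dr, -1)) / 2)
  outThr <- if (ori$direction == "DOWN_IN_CASES") -thr else thr
  new("RocCurve", thresholds = outThr, fpr = fpr, dr = dr, auc = aucVal,
      caseN = as.integer(nCase), controlN = as.integer(nCtrl),
      direction = ori$direction)
}

#' Mann-Whitney p-value that a marker's AUC differs from 0.5
#'
#' Two-sided Mann-Whitney test of the case-vs-control score distributions,
#' whose statistic is equivalent to the AUC.
#' @inheritParams rocCurve
#' @return p-value.
#' @export
aucPValue <- function(scores, labels, caseClass = NULL) {
  isCase <- isCaseVector(labels, caseClass)
  suppressWarnings(stats::wilcox.test(scores[isCase],
                                      scores[!isCase])$p.value)
}

#' Exact Clopper-Pearson binomial confidence interval
#'
#' @param k number of successes.
#' @param n number of trials.
#' @param conf confidence level (default 0.95).
#' @return numeric vector \code{c(lower, upper)} of proportions.
#' @examples
#' clopperPearson(54, 84)  # 0.5308 to 0.7445
#' @export
clopperPearson <- function(k, n, conf = 0.95) {
  a <- (1 - conf) / 2
  lower <- if (k == 0) 0 else stats::qbeta(a, k, n - k + 1)
  upper <- if (k == n) 1 else stats::qbeta(1 - a, k + 1, n - k)
  c(lower = lower, upper = upper)
}

#' Screening threshold with 100% detection rate
#'
#' Finds the most stringent threshold that still classifies every case as
#' screen-positive (for \code{UP_IN_CASES}, the minimum case score, with
#' test-positivity at or above it; a control exactly at the threshold counts
#' as screen-positive). Reports the specificity achieved there -- the
#' proportion of controls strictly on the negative side -- with its exact
#' Clopper-Pearson 95% interval.
#'
#' @inheritParams rocCurve
#' @return a \linkS4class{ScreenThreshold}.
#' @examples
#' # controls 1..5, cases 3.5 and 6: threshold 3.5, specificity 3/5
#' specificityAtFullSensitivity(c(1:5, 3.5, 6),
#'                              c(rep(FALSE, 5), TRUE, TRUE),
#'                              direction = "UP_IN_CASES")
#' @export
specificityAtFullSensitivity <- function(scores, labels, direction = "AUTO",
                                         caseClass = NULL) {
  scores <- as.numeric(scores)
  isCase <- isCaseVector(labels, caseClass)
  if (!any(isCase) || all(isCase)) stop("both classes must be present")
  ori <- orientScores(scores, isCase, direction)
  s <- ori$scores
  thr <- min(s[isCase])
  nCtrl <- sum(!isCase)
  k <- sum(s[!isCase] < thr)
  ci <- clopperPearson(k, nCtrl)
  new("ScreenThreshold",
      threshold = if (ori$direction == "DOWN_IN_CASES") -thr else thr,
      specificity = k / nCtrl, ciLow = unname(ci[1L]),
      ciHigh = unname(ci[2L]), caseN = as.integer(sum(isCase)),
      controlN = as.integer(nCtrl), direction = ori$direction)
}

#' Combine a marker panel into a single ROC score
#'
#' Fits a two-class logistic model to the panel values (maximum likelihood)
#' and evaluates the fitted linear predictor as the combined score, with the
#' ROC computed in-sample on the fitting cohort. Under perfect separation
#' the maximum-likelihood fit diverges; an L2-ridge-penalised logistic fit is
#' then substituted with a warning. A model-free alternative combines the
#' markers as the mean of their per-marker ranks.
#'
#' @param panel numeric matrix, samples in rows and panel markers in columns
#'   (typically log2 relative expression).
#' @param labels two-class labels.
#' @param method \code{"logistic"} (default) or \code{"ranksum"}.
#' @param caseClass label identifying cases.
#' @param ridgeLambda L2 penalty used by the separation fallback.
#' @return list with \code{score} (per sample), \code{coefficients},
#'   \code{roc} (a \linkS4class{RocCurve}), \code{method} and
#'   \code{separationFallback}.
#' @export
combineMarkers <- function(panel, labels, method = c("logistic", "ranksum"),
                           caseClass = NULL, ridgeLambda = 0.01) {
  panel <- as.matrix(panel)
  if (ncol(panel) < 1L) stop("panel must contain at least one marker")
  method <- match.arg(method)
  isCase <- isCaseVector(labels, caseClass)
  fallback <- FALSE
  if (method == "logistic") {
    y <- as.numeric(isCase)
    dat <- data.frame(y = y, panel, check.names = TRUE)
    sep <- FALSE
    fit <- withCallingHandlers(
      stats::glm(y ~ ., family = stats::binomial(), data = dat),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1",
                  conditionMessage(w))) {
          sep <<- TRUE
          invokeRestart("muffleWarning")
        }
      })
    if (sep || !fit$converged) {
      warning("perfect separation in logistic combination; ",
              "using L2-ridge-penalised fit")
      fallback <- TRUE
      if (ncol(panel) >= 2L) {
        gfit <- glmnet::glmnet(panel, y, family = "binomial", alpha = 0,
                               lambda = ridgeLambda, standardize = TRUE)
        coefs <- as.numeric(stats::coef(gfit))
        score <- as.vector(cbind(1, panel) %*% coefs)
        names(coefs) <- c("(Intercept)", colnames(panel))
      } else {
        # a separating single marker is its own optimal score
        coefs <- c("(Intercept)" = 0, setNames(1, colnames(panel)))
        score <- as.vector(panel[, 1L])
      }
    } else {
      coefs <- stats::coef(fit)
      score <- as.vector(stats::predict(fit, type = "link"))
    }
  } else {
    ranks <- apply(panel, 2L, rank)
    score <- rowMeans(ranks)
    coefs <- setNames(rep(1 / ncol(panel), ncol(panel)), colnames(panel))
  }
  names(score) <- rownames(panel)
  dirn <- if (method == "logistic") "UP_IN_CASES" else "AUTO"
  list(score = score, coefficients = coefs,
       roc = rocCurve(score, isCase, direction = dirn),
       method = method, separationFallback = fallback)
}
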