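# End-to-end orchestration: the discovery phase (count QC, background
# subtraction, normalization, prevalence filtering, per-time-point group
# comparisons with FDR control, candidate panel selection) and the
# validation phase (Ct normalization, fold changes, per-marker ROC screening
# and multi-marker combination).

#' Run the discovery phase on a digital-count cohort
#'
#' Executes haemolysis QC (flagged samples removed), per-sample background
#' subtraction, top-100 normalization and the cross-group prevalence filter;
#' then compares each retained marker between the control group and each
#' experimental group at every gestational time point with [groupCompare()],
#' and applies Benjamini-Hochberg adjustment within each (comparison, time
#' point) family of markers. The candidate panel contains the markers
#' significant (q below \code{fdr}, or raw p below \code{alpha} when
#' \code{useFdr = FALSE}) in at least one time point of either comparison.
#'
#' @param x raw-count \linkS4class{MirnaExperiment}.
#' @param meta sample metadata data.frame (\code{sampleId},
#'   \code{patientId}, \code{timePoint}, \code{outcome}); defaults to the
#'   object's colData.
#' @param alpha significance level for the normality gate and (optionally)
#'   raw-p candidate selection.
#' @param fdr q-value cut-off for the candidate panel.
#' @param zCut haemolysis robust-z cut-off.
#' @param controlGroup reference outcome group.
#' @param comparisons experimental outcome groups compared to the control.
#' @param useFdr select candidates on q (default) rather than raw p.
#' @param nTop reference-set size for normalization.
#' @return object of class \code{mirDiscovery}: a list with \code{qc},
#'   \code{removedSamples}, \code{normalized}, \code{retained}, \code{de}
#'   (per marker/time point/comparison results), \code{panel} and
#'   \code{params}.
#' @export
runDiscovery <- function(x, meta = NULL, alpha = 0.05, fdr = 0.05,
                         zCut = 3, controlGroup = "TERM",
                         comparisons = c("PRETERM", "SHORT"),
                         useFdr = TRUE, nTop = 100) {
  stopifnot(is(x, "MirnaExperiment"))
  if (is.null(meta)) meta <- as.data.frame(colData(x))
  need <- c("sampleId", "timePoint", "outcome")
  if (!all(need %in% colnames(meta)))
    stop("metadata must provide columns ", paste(need, collapse = ", "))
  meta <- meta[match(colnames(x), meta$sampleId), , drop = FALSE]
  if (anyNA(meta$sampleId))
    stop("metadata is missing sample(s) present in the count matrix")

  qc <- haemolysisQC(x, zCut = zCut)
  removed <- flaggedSamples(qc)
  keep <- !colnames(x) %in% removed
  x <- x[, keep]; meta <- meta[keep, , drop = FALSE]

  bg <- subtractBackground(x)
  norm <- top100Normalize(bg, nTop = nTop)
  retained <- prevalenceFilter(bg, meta$outcome)

  vals <- assay(norm)[retained, , drop = FALSE]
  de <- list()
  for (cmp in comparisons) {
    for (tp in sort(unique(meta$timePoint))) {
      inTp <- meta$timePoint == tp
      ctrlIdx <- inTp & meta$outcome == controlGroup
      expIdx <- inTp & meta$outcome == cmp
      if (!any(ctrlIdx) || !any(expIdx))
        stop("empty group in comparison ", cmp, " at time point ", tp)
      res <- lapply(retained, function(mk)
        groupCompare(vals[mk, expIdx], vals[mk, ctrlIdx], alpha = alpha))
      d <- data.frame(marker = retained, timePoint = tp, comparison = cmp,
                      testUsed = vapply(res, `[[`, "", "testUsed"),
                      statistic = vapply(res, `[[`, 0, "statistic"),
                      p = vapply(res, `[[`, 0, "p.value"),
                      stringsAsFactors = FALSE)
      de[[paste(cmp, tp, sep = ".")]] <- d
    }
  }
  de <- do.call(rbind, de)
  rownames(de) <- NULL
  # one BH family over the whole discovery test set, so that a complete-null
  # cohort yields an empty candidate panel with probability >= 1 - fdr
  de$q <- bhFdr(de$p)
  sig <- if (useFdr) de$q < fdr else de$p < alpha
  panel <- sort(unique(de$marker[sig]))

  structure(list(qc = qc, removedSamples = removed, normalized = norm,
                 retained = retained, de = de, panel = panel,
                 meta = meta,
                 params = list(alpha = alpha, fdr = fdr, zCut = zCut,
                               controlGroup = controlGroup,
                               comparisons = comparisons, useFdr = useFdr,
                               nTop = nTop)),
            class = "mirDiscovery")
}

#' @export
print.mirDiscovery <- function(x, ...) {
  cat("Discovery run\n")
  cat(sprintf("  samples removed by haemolysis QC: %d (%s)\n",
              length(x$removedSamples),
              paste(x$removedSamples, collapse = ", ")))
  cat(sprintf("  markers above background/prevalence: %d\n",
              length(x$retained)))
  cat(sprintf("  candidate panel (%s): %d marker(s)\n",
              if (x$params$useFdr) sprintf("q < %g", x$params$fdr)
              else sprintf("p < %g", x$params$alpha),
              length(x$panel)))
  if (length(x$panel)) cat("   ", paste(x$panel, collapse = ", "), "\n")
  invisible(x)
}

#' Run the validation phase on a qPCR cohort
#'
#' Collapses technical replicates, applies the two-step median
#' normalization, then per panel marker, comparison group and time point
#' computes the 2^-dG fold change with group mean relative expression and a
#' group-comparison p-value, plus a ROC analysis (AUC with Mann-Whitney
#' p-value, and specificity at 100% detection rate with its exact binomial
#' interval). Panels of the best-performing markers (by single-marker AUC)
#' are combined with a logistic score and evaluated in-sample.
#'
#' @param ct a \linkS4class{CtSet}.
#' @param meta sample metadata data.frame.
#' @param panel marker ids to validate; all must be assayed in \code{ct}.
#' @param controlGroup,comparisons,alpha as in [runDiscovery()].
#' @param timePoints gestational time points analysed (default A and C).
#' @param comboSizes sizes of the best-marker combinations (default 3 and 7,
#'   truncated to the panel size).
#' @return object of class \code{mirValidation}: \code{normalizedCt},
#'   \code{foldChanges} (Table-3-shaped data.frame), \code{rocTable}
#'   (Table-4-shaped data.frame), \code{screens}, \code{combos}.
#' @export
runValidation <- function(ct, meta, panel, controlGroup = "TERM",
                          comparisons = c("PRETERM", "SHORT"),
                          alpha = 0.05, timePoints = c("A", "C"),
                          comboSizes = c(3, 7)) {
  stopifnot(is(ct, "CtSet"))
  if (length(panel) == 0L) stop("panel must be non-empty")
  collapsed <- collapseReplicates(ct)
  norm <- medianNormalizeCt(collapsed)
  missing <- setdiff(panel, rownames(norm))
  if (length(missing))
    stop("panel marker(s) missing from the Ct table: ",
         paste(missing, collapse = ", "))
  meta <- meta[match(colnames(norm), meta$sampleId), , drop = FALSE]
  if (anyNA(meta$sampleId))
    stop("metadata is missing sample(s) present in the Ct table")

  fcRows <- list(); rocRows <- list(); screens <- list()
  for (tp in timePoints) {
    inTp <- which(meta$timePoint == tp)
    sub <- norm[, inTp]
    grp <- meta$outcome[inTp]
    for (cmp in comparisons) {
      use <- grp %in% c(controlGroup, cmp)
      for (mk in panel) {
        fc <- foldChange(sub[, use], grp[use], mk,
                         experimentalGroup = cmp,
                         controlGroup = controlGroup)
        ctVals <- assay(sub)[mk, use]
        ok <- !is.na(ctVals)
        gc <- groupCompare(-ctVals[ok & grp[use] == cmp],
                           -ctVals[ok & grp[use] == controlGroup],
                           alpha = alpha)
        fcRows[[length(fcRows) + 1L]] <- data.frame(
          marker = mk, comparison = cmp, timePoint = tp,
          meanRelExpr = unname(fc@groupMean[cmp]),
          sem = unname(fc@groupSem[cmp]), dg = fc@dg, fold = fc@fold,
          testUsed = gc$testUsed, p = gc$p.value, stringsAsFactors = FALSE)
        # lower Ct means more template: score on -Ct so cases score high
        score <- -ctVals[ok]
        lab <- grp[use][ok] == cmp
        roc <- rocCurve(score, lab, direction = "AUTO")
        scr <- specificityAtFullSensitivity(score, lab, direction = "AUTO")
        screens[[paste(mk, cmp, tp, sep = ".")]] <- scr
        rocRows[[length(rocRows) + 1L]] <- data.frame(
          marker = mk, comparison = cmp, timePoint = tp, auc = auc(roc),
          p = aucPValue(score, lab),
          specificity = scr@specificity, ciLow = scr@ciLow,
          ciHigh = scr@ciHigh, stringsAsFactors = FALSE)
      }
    }
  }
  foldChanges <- do.call(rbind, fcRows)
  rocTable <- do.call(rbind, rocRows)

  combos <- list()
  tpA <- timePoints[1L]
  for (cmp in comparisons) {
    inTp <- which(meta$timePoint == tpA)
    grp <- meta$outcome[inTp]
    use <- grp %in% c(controlGroup, cmp)
    sub <- assay(norm)[panel, inTp[use], drop = FALSE]
    ok <- colSums(is.na(sub)) == 0
    ranked <- rocTable[rocTable$comparison == cmp &
                         rocTable$timePoint == tpA, ]
    ranked <- ranked$marker[order(ranked$auc, decreasing = TRUE)]
    for (sz in unique(pmin(comboSizes, length(panel)))) {
      top <- ranked[seq_len(sz)]
      # log2 relative expression = -(normalized Ct) up to a constant
      cmb <- combineMarkers(t(-sub[top, ok, drop = FALSE]),
                            grp[use][ok] == cmp)
      combos[[paste(cmp, tpA, sz, sep = ".")]] <-
        list(markers = top, auc = auc(cmb$roc), fit = cmb)
    }
  }

  structure(list(normalizedCt = norm, foldChanges = foldChanges,
                 rocTable = rocTable, screens = screens, combos = combos,
                 params = list(controlGroup = controlGroup,
                               comparisons = comparisons, alpha = alpha,
                               timePoints = timePoints,
                               comboSizes = comboSizes)),
            class = "mirValidation")
}

#' @export
print.mirValidation <- function(x, ...) {
  cat("Validation run\n")
  cat(sprintf("  markers: %d | comparisons: %s | time points: %s\n",
              length(unique(x$rocTable$marker)),
              paste(x$params$comparisons, collapse = ", "),
              paste(x$params$timePoints, collapse = ", ")))
  best <- x$rocTable[which.max(x$rocTable$auc), ]
  cat(sprintf("  best single marker: %s (%s, %s) AUC %.4f, spec@100%%DR %.1f%%\n",
              best$marker, best$comparison, best$timePoint, best$auc,
              100 * best$specificity))
  for (nm in names(x$combos))
    cat(sprintf("  combination %s: AUC %.4f [%s]\n", nm, x$combos[[nm]]$auc,
                paste(x$combos[[nm]]$markers, collapse = ", ")))
  invisible(x)
}
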