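#' @rdname MirnaExperiment-class
#' @export
setMethod("expressionScale", "MirnaExperiment", function(x) x@expressionScale)

#' @rdname MirnaExperiment-class
#' @export
setMethod("probeClass", "MirnaExperiment",
          function(x) setNames(as.character(rowData(x)$probeClass),
                               rownames(x)))

#' @rdname MirnaExperiment-class
#' @export
setMethod("show", "MirnaExperiment", function(object) {
  cat(sprintf("MirnaExperiment (%s): %d probes x %d samples\n",
              object@expressionScale, nrow(object), ncol(object)))
  tab <- table(rowData(object)$probeClass)
  cat("  probe classes:",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  callNextMethod()
})

#' @rdname CtSet-class
#' @export
setMethod("ctRecords", "CtSet", function(x) x@records)

#' @rdname CtSet-class
#' @export
setMethod("calibratorAssay", "CtSet", function(x) x@calibratorAssay)

#' @rdname CtSet-class
#' @export
setMethod("spikeInAssays", "CtSet", function(x) x@spikeInAssays)

#' @rdname CtSet-class
#' @export
setMethod("show", "CtSet", function(object) {
  r <- object@records
  cat(sprintf(
    "CtSet: %d records, %d samples, %d assays, %d plates%s\n",
    nrow(r), length(unique(r$sampleId)), length(unique(r$assayId)),
    length(unique(r$plateId)),
    if (object@collapsed) " (replicates collapsed)" else ""))
  cat("  calibrator:", object@calibratorAssay,
      "| spike-ins:", paste(object@spikeInAssays, collapse = ", "), "\n")
})

#' @rdname RocCurve-class
#' @export
setMethod("auc", "RocCurve", function(x) x@auc)

#' @rdname RocCurve-class
#' @export
setMethod("rocPoints", "RocCurve",
          function(x) data.frame(threshold = x@thresholds, fpr = x@fpr,
                                 dr = x@dr))

#' @rdname RocCurve-class
#' @export
setMethod("show", "RocCurve", function(object) {
  cat(sprintf(
    "RocCurve: AUC = %.4f (%d cases vs %d controls, %s, %d points)\n",
    object@auc, object@caseN, object@controlN, object@direction,
    length(object@fpr)))
})

#' @rdname ScreenThreshold-class
#' @export
setMethod("specificity", "ScreenThreshold", function(x) x@specificity)

#' @rdname ScreenThreshold-class
#' @export
setMethod("show", "ScreenThreshold", function(object) {
  cat(sprintf(
    paste0("ScreenThreshold: cut-off %.4g gives 100%% detection rate with\n",
           "  specificity %.2f%% (95%% CI %.2f%% to %.2f%%; %d controls)\n"),
    object@threshold, 100 * object@specificity, 100 * object@ciLow,
    100 * object@ciHigh, object@controlN))
})

#' @rdname LatentModel-class
#' @export
setMethod("scores", "LatentModel", function(x) x@scores)

#' @rdname LatentModel-class
#' @export
setMethod("loadings", "LatentModel", function(x) x@loadings)

#' @rdname LatentModel-class
#' @export
setMethod("r2x", "LatentModel", function(x) x@r2x)

#' @rdname LatentModel-class
#' @export
setMethod("r2y", "LatentModel", function(x) x@r2y)

#' @rdname LatentModel-class
#' @export
setMethod("q2y", "LatentModel", function(x) x@q2y)

#' @rdname LatentModel-class
#' @export
setMethod("show", "LatentModel", function(object) {
  cat(sprintf("LatentModel (%s): %d components, %d samples, %d variables\n",
              object@method, ncol(object@scores), nrow(object@scores),
              nrow(object@loadings)))
  cat("  R2X:", paste(sprintf("%.3f", object@r2x), collapse = " "), "\n")
  if (length(object@r2y))
    cat("  R2Y(cum):", paste(sprintf("%.3f", object@r2y), collapse = " "),
        "\n")
  if (length(object@q2y))
    cat("  Q2Y(cum):", paste(sprintf("%.3f", object@q2y), collapse = " "),
        "\n")
})

#' @rdname FoldChangeResult-class
#' @export
setMethod("show", "FoldChangeResult", function(object) {
  cat(sprintf(
    "FoldChangeResult: %s, %s vs %s\n  dG = %.3f cycles, fold = %.3g\n",
    object@markerId, object@experimentalGroup, object@controlGroup,
    object@dg, object@fold))
  cat(sprintf("  mean relative expression: %s = %.3g, %s = %.3g\n",
              object@controlGroup, object@groupMean[object@controlGroup],
              object@experimentalGroup,
              object@groupMean[object@experimentalGroup]))
})

#' @rdname QcReport-class
#' @export
setMethod("flaggedSamples", "QcReport",
          function(x) unique(x@flagged$sampleId))

#' @rdname QcReport-class
#' @export
setMethod("show", "QcReport", function(object) {
  cat(sprintf("QcReport: %d of %d samples flagged (robust |z| > %.3g on %s)\n",
              length(unique(object@flagged$sampleId)), nrow(object@scores),
              object@zCut, paste(object@markerIds, collapse = ", ")))
  if (nrow(object@flagged)) print(object@flagged)
})
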