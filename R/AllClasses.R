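#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom stats setNames
#' @importFrom glmnet glmnet
NULL

#' Probe classes recognised on the digital-count platform
#'
#' Endogenous miRNA probes carry the biological signal; negative-control
#' probes (no target present in plasma) define the background noise floor;
#' positive-control and spike-in probes are technical controls.
#' @keywords internal
PROBE_CLASSES <- c("ENDOGENOUS", "NEG_CONTROL", "POS_CONTROL", "SPIKE_IN")

#' Expression scales carried by a MirnaExperiment
#' @keywords internal
EXPRESSION_SCALES <- c("RAW_COUNT", "NORMALIZED_COUNT", "RELATIVE_EXPRESSION",
                       "NORMALIZED_CT")

#' Haemolysis-associated plasma miRNAs
#'
#' Red-blood-cell derived miRNAs whose elevation in a plasma sample marks
#' blood-cell contamination (haemolysis). Samples with very high levels of
#' these markers are flagged and excluded from biomarker analysis.
#' @export
HAEMOLYSIS_MARKERS <- c("hsa-miR-16-5p", "hsa-miR-25-3p", "hsa-miR-93-5p")

#' Container for probe-level miRNA expression data
#'
#' A thin extension of \linkS4class{SummarizedExperiment} holding one assay of
#' probe-by-sample expression values together with the scale those values are
#' on. Rows are probes with a mandatory \code{probeClass} column in
#' \code{rowData} (one of \code{ENDOGENOUS}, \code{NEG_CONTROL},
#' \code{POS_CONTROL}, \code{SPIKE_IN}); columns are samples, with clinical
#' annotation (patient, gestational time point, outcome group, cervical
#' lengths) in \code{colData} when available.
#'
#' @slot expressionScale one of \code{RAW_COUNT}, \code{NORMALIZED_COUNT},
#'   \code{RELATIVE_EXPRESSION}, \code{NORMALIZED_CT}.
#' @export
setClass("MirnaExperiment",
         contains = "SummarizedExperiment",
         representation(expressionScale = "character"),
         prototype(expressionScale = "RAW_COUNT"))

setValidity("MirnaExperiment", function(object) {
  msg <- character()
  if (length(object@expressionScale) != 1L ||
      !object@expressionScale %in% EXPRESSION_SCALES)
    msg <- c(msg, sprintf("expressionScale must be one of %s",
                          paste(EXPRESSION_SCALES, collapse = ", ")))
  if (!"probeClass" %in% colnames(rowData(object)))
    msg <- c(msg, "rowData must contain a 'probeClass' column")
  else if (!all(rowData(object)$probeClass %in% PROBE_CLASSES))
    msg <- c(msg, "probeClass values must be valid probe classes")
  a <- assay(object)
  # undetected qPCR cells stay NA on the Ct scale; count scales are complete
  if (anyNA(a) && object@expressionScale != "NORMALIZED_CT")
    msg <- c(msg, "expression values must not contain missing cells")
  if (object@expressionScale %in% c("RAW_COUNT", "NORMALIZED_COUNT") &&
      any(a < 0, na.rm = TRUE))
    msg <- c(msg, "counts must be non-negative")
  if (object@expressionScale == "RELATIVE_EXPRESSION" &&
      any(a <= 0, na.rm = TRUE))
    msg <- c(msg, "relative expression values must be positive")
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "probe ids must be unique")
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "sample ids must be unique")
  if (length(msg)) msg else TRUE
})

#' Construct a MirnaExperiment
#'
#' @param values numeric matrix, probes in rows and samples in columns. A
#'   samples-by-probes matrix is accepted anywhere in the package by
#'   transposing before the call.
#' @param probeClass character vector, one class per row of \code{values}.
#' @param sampleData optional \code{data.frame}/\code{DataFrame} of per-sample
#'   annotation (row order matching columns of \code{values}).
#' @param scale the expression scale of \code{values}.
#' @return a \linkS4class{MirnaExperiment}.
#' @examples
#' m <- matrix(rpois(6, 50), nrow = 3,
#'             dimnames = list(paste0("p", 1:3), c("s1", "s2")))
#' MirnaExperiment(m, probeClass = c("ENDOGENOUS", "ENDOGENOUS", "NEG_CONTROL"))
#' @export
MirnaExperiment <- function(values, probeClass,
                            sampleData = NULL, scale = "RAW_COUNT") {
  values <- as.matrix(values)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have probe ids as rownames and sample ids as colnames")
  probeClass <- rep_len(as.character(probeClass), nrow(values))
  rd <- DataFrame(probeClass = probeClass, row.names = rownames(values))
  cd <- if (is.null(sampleData)) {
    DataFrame(row.names = colnames(values))
  } else {
    DataFrame(sampleData, row.names = colnames(values))
  }
  se <- SummarizedExperiment(assays = list(exprs = values),
                             rowData = rd, colData = cd)
  new("MirnaExperiment", se, expressionScale = scale)
}

#' Replicate-level qPCR cycle-threshold records
#'
#' Long-format Ct measurements with plate and assay structure. Each record is
#' one PCR reaction: a (sample, assay, plate, replicate) cell with its Ct
#' value, \code{NA} meaning the reaction did not cross threshold
#' ("undetected"). The inter-plate calibrator assay must be present on every
#' plate and each spike-in assay (extraction and reverse-transcription
#' controls) must be present for every sample, so that the two-step median
#' normalization chain is applicable.
#'
#' @slot records data.frame with columns \code{sampleId}, \code{assayId},
#'   \code{plateId}, \code{replicate}, \code{ct} (and, after replicate
#'   collapsing, \code{cv} and \code{cvFlag}).
#' @slot calibratorAssay id of the inter-plate calibrator assay.
#' @slot spikeInAssays ids of the spike-in control assays.
#' @slot collapsed TRUE once technical replicates have been averaged.
#' @export
setClass("CtSet",
         representation(records = "data.frame",
                        calibratorAssay = "character",
                        spikeInAssays = "character",
                        collapsed = "logical"),
         prototype(collapsed = FALSE))

setValidity("CtSet", function(object) {
  r <- object@records
  msg <- character()
  need <- c("sampleId", "assayId", "plateId", "replicate", "ct")
  if (!all(need %in% colnames(r)))
    return(sprintf("records must contain columns %s",
                   paste(need, collapse = ", ")))
  if (length(object@calibratorAssay) != 1L)
    msg <- c(msg, "exactly one calibrator assay id is required")
  bad <- !is.na(r$ct) & r$ct <= 0
  if (any(bad))
    msg <- c(msg, "detected Ct values must be positive and finite")
  plates <- unique(r$plateId)
  calPlates <- unique(r$plateId[r$assayId == object@calibratorAssay])
  missingCal <- setdiff(plates, calPlates)
  if (length(missingCal))
    msg <- c(msg, sprintf("plate(s) missing the calibrator assay: %s",
                          paste(missingCal, collapse = ", ")))
  samples <- unique(r$sampleId[!r$assayId %in%
                                 c(object@calibratorAssay,
                                   object@spikeInAssays)])
  for (sp in object@spikeInAssays) {
    have <- unique(r$sampleId[r$assayId == sp])
    missingSp <- setdiff(samples, have)
    if (length(missingSp))
      msg <- c(msg, sprintf("sample(s) missing spike-in '%s': %s", sp,
                            paste(missingSp, collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' Construct a CtSet
#'
#' @param records data.frame of replicate-level Ct measurements with columns
#'   \code{sampleId}, \code{assayId}, \code{plateId}, \code{replicate},
#'   \code{ct} (NA for undetected reactions).
#' @param calibratorAssay id of the inter-plate calibrator assay.
#' @param spikeInAssays character vector of spike-in assay ids.
#' @return a \linkS4class{CtSet}.
#' @export
CtSet <- function(records, calibratorAssay = "UniSp3_IPC",
                  spikeInAssays = c("cel-254", "UniSp6")) {
  records <- as.data.frame(records)
  records$replicate <- as.integer(records$replicate)
  records$ct <- as.numeric(records$ct)
  new("CtSet", records = records, calibratorAssay = calibratorAssay,
      spikeInAssays = spikeInAssays)
}

#' Per-sample background model for digital counts
#'
#' The background of a digital-count sample is estimated from its
#' negative-control probes as mean + 2 standard deviations (sample sd, n-1
#' denominator).
#' @slot negMean arithmetic mean of negative-control counts.
#' @slot negSd sample standard deviation of negative-control counts.
#' @slot threshold \code{negMean + 2 * negSd}.
#' @export
setClass("BackgroundModel",
         representation(negMean = "numeric", negSd = "numeric",
                        threshold = "numeric"))

#' Receiver operating characteristic curve
#'
#' Ordered operating points (false positive rate, detection rate) from (0,0)
#' to (1,1) with the trapezoidal area under the curve, which equals the
#' Mann-Whitney concordance probability (ties counted 1/2).
#' @slot thresholds score thresholds, in sweep order (one per operating point,
#'   the first being +/- Inf).
#' @slot fpr,dr false positive rate and detection rate (sensitivity) at each
#'   threshold.
#' @slot auc area under the curve.
#' @slot caseN,controlN group sizes.
#' @slot direction \code{"UP_IN_CASES"} or \code{"DOWN_IN_CASES"}.
#' @export
setClass("RocCurve",
         representation(thresholds = "numeric", fpr = "numeric",
                        dr = "numeric", auc = "numeric",
                        caseN = "integer", controlN = "integer",
                        direction = "character"))

setValidity("RocCurve", function(object) {
  msg <- character()
  if (is.unsorted(object@fpr) || is.unsorted(object@dr))
    msg <- c(msg, "FPR and DR must be non-decreasing along the curve")
  if (object@auc < 0 || object@auc > 1)
    msg <- c(msg, "auc must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Screen-positive threshold at 100% detection rate
#'
#' The most stringent threshold that still classifies every case as
#' screen-positive, with the specificity achieved there and its exact
#' Clopper-Pearson 95% binomial confidence interval.
#' @slot threshold the score cut-off.
#' @slot specificity proportion of controls screen-negative at the threshold.
#' @slot ciLow,ciHigh exact binomial 95% confidence bounds on specificity.
#' @slot caseN,controlN group sizes.
#' @slot direction orientation used.
#' @export
setClass("ScreenThreshold",
         representation(threshold = "numeric", specificity = "numeric",
                        ciLow = "numeric", ciHigh = "numeric",
                        caseN = "integer", controlN = "integer",
                        direction = "character"))

#' Latent-variable model (PCA or PLS-DA)
#'
#' Scores and loadings from NIPALS principal component analysis or partial
#' least squares discriminant analysis on unit-variance-scaled data, with the
#' per-component fraction of X-variance explained (R2X) and, for PLS-DA, the
#' cumulative fraction of response variance explained in training (R2Y) and
#' in cross-validation (Q2Y).
#' @slot method "PCA" or "PLS-DA".
#' @slot scores samples-by-components score matrix.
#' @slot loadings variables-by-components loading matrix.
#' @slot weights variables-by-components weight matrix (PLS only).
#' @slot r2x per-component R2X.
#' @slot r2y cumulative R2Y per component (PLS only).
#' @slot q2y cumulative Q2Y per component (empty until cross-validated).
#' @export
setClass("LatentModel",
         representation(method = "character", scores = "matrix",
                        loadings = "matrix", weights = "matrix",
                        r2x = "numeric", r2y = "numeric", q2y = "numeric"))

#' Fold change between clinical groups from normalized Ct values
#'
#' Group fold change on the 2^-deltaCt scale: \code{dg} is the difference in
#' mean normalized Ct (experimental minus control) and \code{fold = 2^-dg}.
#' Per-sample relative expression is scaled so the control-group mean is
#' exactly 1.
#' @slot markerId the assayed miRNA.
#' @slot experimentalGroup,controlGroup the compared groups.
#' @slot dg mean Ct difference in cycles.
#' @slot fold linear fold change, \code{2^-dg}.
#' @slot relExpr data.frame of per-sample relative expression
#'   (\code{sampleId}, \code{group}, \code{relExpr}).
#' @slot groupMean,groupSem named group means and standard errors of the
#'   relative expression.
#' @export
setClass("FoldChangeResult",
         representation(markerId = "character",
                        experimentalGroup = "character",
                        controlGroup = "character",
                        dg = "numeric", fold = "numeric",
                        relExpr = "data.frame",
                        groupMean = "numeric", groupSem = "numeric"))

#' Haemolysis quality-control report
#'
#' Robust z-scores of log2 counts of the haemolysis-associated miRNAs across
#' samples, and the samples flagged as contaminated.
#' @slot flagged data.frame (\code{sampleId}, \code{markerId}, \code{z}) of
#'   flag-triggering scores, one row per (sample, marker) exceeding the
#'   cut-off.
#' @slot scores samples-by-markers matrix of robust z-scores.
#' @slot markerIds markers used.
#' @slot zCut the flagging cut-off applied.
#' @export
setClass("QcReport",
         representation(flagged = "data.frame", scores = "matrix",
                        markerIds = "character", zCut = "numeric"))
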