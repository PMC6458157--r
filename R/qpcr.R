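# RT-qPCR Ct processing: replicate collapsing with CV QC, the two-step
# median-normalization chain (inter-plate calibrator, then extraction/RT
# spike-ins), relative expression and 2^-deltaCt fold change.

#' Collapse technical replicates of a CtSet
#'
#' Averages replicate Ct values per (sample, assay, plate) cell and computes
#' the intra-assay coefficient of variation (sd/mean, percent) where at least
#' two detected replicates exist. Cells at or above the 2% CV quality bound
#' are flagged but retained. Undetected replicates are excluded from the
#' mean; a cell is undetected only when all its replicates are.
#'
#' @param x a \linkS4class{CtSet}.
#' @param cvLimit flagging bound on the percent CV (default 2).
#' @return a collapsed \linkS4class{CtSet} whose records carry one row per
#'   cell with columns \code{ct}, \code{cv} and \code{cvFlag}.
#' @export
collapseReplicates <- function(x, cvLimit = 2) {
  stopifnot(is(x, "CtSet"))
  r <- ctRecords(x)
  key <- interaction(r$sampleId, r$assayId, r$plateId, drop = TRUE)
  agg <- lapply(split(r, key), function(d) {
    ok <- !is.na(d$ct)
    m <- if (any(ok)) mean(d$ct[ok]) else NA_real_
    cv <- if (sum(ok) >= 2L) 100 * stats::sd(d$ct[ok]) / m else NA_real_
    data.frame(sampleId = d$sampleId[1L], assayId = d$assayId[1L],
               plateId = d$plateId[1L], replicate = 1L, ct = m, cv = cv,
               cvFlag = !is.na(cv) && cv >= cvLimit,
               stringsAsFactors = FALSE)
  })
  rec <- do.call(rbind, agg)
  rec <- rec[order(rec$plateId, rec$sampleId, rec$assayId), , drop = FALSE]
  rownames(rec) <- NULL
  new("CtSet", records = rec, calibratorAssay = calibratorAssay(x),
      spikeInAssays = spikeInAssays(x), collapsed = TRUE)
}

#' Two-step median normalization of Ct values
#'
#' Step 1 removes plate-to-plate shifts: each plate's offset is its
#' calibrator Ct minus the median calibrator Ct over plates, and is
#' subtracted from every Ct on the plate. Step 2 removes per-sample technical
#' variation captured by the extraction and reverse-transcription spike-ins:
#' a sample's offset is the median, over spike-in assays, of that sample's
#' spike Ct minus the cross-sample median of the spike's Ct (with two
#' spike-ins this is their midpoint), and is subtracted from all of the
#' sample's target Cts.
#'
#' @param x a \linkS4class{CtSet}; replicates are collapsed first if needed.
#' @return a \linkS4class{MirnaExperiment} of normalized target Cts (markers
#'   in rows, samples in columns) on the \code{NORMALIZED_CT} scale.
#'   Undetected cells remain \code{NA}... callers exclude them explicitly.
#' @export
medianNormalizeCt <- function(x) {
  stopifnot(is(x, "CtSet"))
  if (!x@collapsed) x <- collapseReplicates(x)
  r <- ctRecords(x)
  cal <- calibratorAssay(x)
  spikes <- spikeInAssays(x)

  # step 1: inter-plate calibrator
  calCt <- r[r$assayId == cal, c("plateId", "ct")]
  calByPlate <- tapply(calCt$ct, calCt$plateId, stats::median, na.rm = TRUE)
  calByPlate <- setNames(as.numeric(calByPlate), names(calByPlate))
  plateOffset <- calByPlate - stats::median(calByPlate, na.rm = TRUE)
  r$ct <- r$ct - plateOffset[r$plateId]

  # step 2: spike-in sample offsets (on plate-corrected Cts)
  spikeOffsets <- sapply(spikes, function(sp) {
    d <- r[r$assayId == sp, ]
    v <- tapply(d$ct, d$sampleId, mean, na.rm = TRUE)
    v - stats::median(v, na.rm = TRUE)
  })
  if (is.null(dim(spikeOffsets)))
    spikeOffsets <- matrix(spikeOffsets, ncol = length(spikes),
                           dimnames = list(names(spikeOffsets), spikes))
  sampleOffset <- apply(spikeOffsets, 1L, stats::median, na.rm = TRUE)

  targets <- r[!r$assayId %in% c(cal, spikes), , drop = FALSE]
  targets$ct <- targets$ct - sampleOffset[targets$sampleId]
  mat <- tapply(targets$ct, list(targets$assayId, targets$sampleId),
                mean, na.rm = TRUE)
  mat <- matrix(mat, nrow = nrow(mat), dimnames = dimnames(mat))
  res <- SummarizedExperiment(
    assays = list(exprs = mat),
    rowData = DataFrame(probeClass = rep("ENDOGENOUS", nrow(mat)),
                        row.names = rownames(mat)))
  res <- new("MirnaExperiment", res, expressionScale = "NORMALIZED_CT")
  metadata(res)$plateOffset <- plateOffset
  metadata(res)$sampleOffset <- sampleOffset
  res
}

#' Per-sample relative expression against a control group
#'
#' Converts normalized Ct values of one marker to relative expression on the
#' 2^-deltaCt scale, anchored so the control-group mean is exactly 1: each
#' sample's raw relative value \code{2^-(Ct - mean control Ct)} is divided by
#' the control group's mean raw value.
#'
#' @param x a \code{NORMALIZED_CT} \linkS4class{MirnaExperiment} from
#'   [medianNormalizeCt()].
#' @param groups group label per sample (named by sample or in column order).
#' @param marker marker (assay) id.
#' @param controlGroup label of the reference group.
#' @return data.frame with \code{sampleId}, \code{group}, \code{relExpr};
#'   group means/SEMs in attributes \code{groupMean} and \code{groupSem}.
#' @export
relativeExpression <- function(x, groups, marker, controlGroup = "TERM") {
  stopifnot(is(x, "MirnaExperiment"),
            expressionScale(x) == "NORMALIZED_CT")
  if (!marker %in% rownames(x)) stop("marker '", marker, "' not measured")
  ct <- assay(x)[marker, ]
  groups <- as.character(groups)
  if (!is.null(names(ct)) && length(groups) != length(ct))
    stop("'groups' must have one label per sample")
  keep <- !is.na(ct)
  if (any(!keep))
    warning("excluding ", sum(!keep),
            " sample(s) with undetected Ct for marker '", marker, "'")
  ct <- ct[keep]; groups <- groups[keep]
  if (!controlGroup %in% groups)
    stop("control group '", controlGroup, "' has no detected samples")
  ctrlMean <- mean(ct[groups == controlGroup])
  r <- 2^(-(ct - ctrlMean))
  r <- r / mean(r[groups == controlGroup])
  out <- data.frame(sampleId = names(ct), group = groups, relExpr = unname(r),
                    stringsAsFactors = FALSE)
  gm <- tapply(out$relExpr, out$group, mean)
  gs <- tapply(out$relExpr, out$group, sem)
  attr(out, "groupMean") <- setNames(as.numeric(gm), names(gm))
  attr(out, "groupSem") <- setNames(as.numeric(gs), names(gs))
  out
}

#' Fold change between two clinical groups (2^-dG)
#'
#' \code{dG} is the difference in mean normalized Ct between the experimental
#' and the control group; the fold change is \code{2^-dG} (one PCR cycle is a
#' doubling). Per-sample relative expression scaled to a control mean of 1 is
#' carried along.
#'
#' @inheritParams relativeExpression
#' @param experimentalGroup label of the experimental group.
#' @return a \linkS4class{FoldChangeResult}.
#' @examples
#' # mean Ct 24 in cases vs 26 in controls: dG = -2, fold = 4
#' @export
foldChange <- function(x, groups, marker, experimentalGroup,
                       controlGroup = "TERM") {
  rel <- relativeExpression(x, groups, marker, controlGroup)
  ct <- assay(x)[marker, ]
  groups <- as.character(groups)
  keep <- !is.na(ct)
  ct <- ct[keep]; grp <- groups[keep]
  for (g in c(experimentalGroup, controlGroup))
    if (!any(grp == g)) stop("group '", g, "' is empty for marker '",
                             marker, "'")
  dg <- mean(ct[grp == experimentalGroup]) - mean(ct[grp == controlGroup])
  new("FoldChangeResult", markerId = marker,
      experimentalGroup = experimentalGroup, controlGroup = controlGroup,
      dg = dg, fold = 2^(-dg), relExpr = rel,
      groupMean = attr(rel, "groupMean"), groupSem = attr(rel, "groupSem"))
}
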