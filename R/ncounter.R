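# Digital-count QC, background handling, normalization and prevalence
# filtering for nCounter-style plasma miRNA profiles.

#' Background threshold from negative-control probes
#'
#' The background of a digital-count assay is defined as two standard
#' deviations above the mean of the negative-control probes (sample standard
#' deviation, n-1 denominator).
#'
#' @param negCounts numeric vector of negative-control counts (at least 3).
#' @return a \linkS4class{BackgroundModel}.
#' @examples
#' backgroundThreshold(c(0, 2, 4))  # mean 2, sd 2, threshold 6
#' @export
backgroundThreshold <- function(negCounts) {
  negCounts <- as.numeric(negCounts)
  if (length(negCounts) < 3L)
    stop("at least 3 negative-control values are required, got ",
         length(negCounts))
  m <- mean(negCounts)
  s <- stats::sd(negCounts)
  new("BackgroundModel", negMean = m, negSd = s, threshold = m + 2 * s)
}

#' Subtract per-sample background from endogenous counts
#'
#' For every sample, the threshold estimated from that sample's own
#' negative-control probes (see [backgroundThreshold()]) is subtracted from
#' its endogenous counts, flooring at zero; zero therefore means "not above
#' background" downstream. Control probes are dropped from the output.
#' Pooling negative controls across the whole cohort is available as an
#' alternative.
#'
#' @param x a \linkS4class{MirnaExperiment} with raw counts containing
#'   \code{NEG_CONTROL} probes.
#' @param perSample use each sample's own negative controls (default); if
#'   \code{FALSE}, a single pooled threshold from all negative-control counts
#'   is applied to every sample.
#' @return a \linkS4class{MirnaExperiment} of background-subtracted
#'   endogenous counts, with the per-sample thresholds in
#'   \code{metadata(x)$backgroundThreshold}.
#' @export
subtractBackground <- function(x, perSample = TRUE) {
  stopifnot(is(x, "MirnaExperiment"))
  # already-subtracted matrices have no control probes left; a second pass
  # is the identity
  if (isTRUE(metadata(x)$backgroundSubtracted)) return(x)
  cls <- probeClass(x)
  negIdx <- which(cls == "NEG_CONTROL")
  endoIdx <- which(cls == "ENDOGENOUS")
  if (length(negIdx) == 0L)
    stop("no NEG_CONTROL probes present; cannot estimate background")
  counts <- assay(x)
  thr <- if (perSample) {
    vapply(seq_len(ncol(counts)), function(j) {
      bg <- tryCatch(backgroundThreshold(counts[negIdx, j]),
                     error = function(e)
                       stop("sample '", colnames(counts)[j], "': ",
                            conditionMessage(e), call. = FALSE))
      bg@threshold
    }, numeric(1))
  } else {
    rep(backgroundThreshold(as.vector(counts[negIdx, ]))@threshold,
        ncol(counts))
  }
  names(thr) <- colnames(counts)
  out <- pmax(sweep(counts[endoIdx, , drop = FALSE], 2L, thr, "-"), 0)
  res <- MirnaExperiment(out, probeClass = cls[endoIdx],
                         sampleData = colData(x), scale = "RAW_COUNT")
  metadata(res)$backgroundThreshold <- thr
  metadata(res)$backgroundSubtracted <- TRUE
  res
}

#' Haemolysis quality control
#'
#' Flags plasma samples contaminated by red-blood-cell lysis via the three
#' haemolysis-associated miRNAs. Per marker, a robust z-score of log2(count +
#' 1) is computed across samples (median/MAD with the 1.4826 consistency
#' factor); a sample is flagged when any marker's z exceeds the cut-off.
#'
#' @param x a \linkS4class{MirnaExperiment} of counts.
#' @param markers haemolysis marker probe ids.
#' @param zCut robust z cut-off above which a sample is flagged (default 3;
#'   the field reports "very high expression" without a numeric rule, so the
#'   cut-off is explicit and configurable).
#' @return a \linkS4class{QcReport}.
#' @export
haemolysisQC <- function(x, markers = HAEMOLYSIS_MARKERS, zCut = 3) {
  stopifnot(is(x, "MirnaExperiment"))
  present <- intersect(markers, rownames(x))
  if (length(present) == 0L)
    stop("none of the haemolysis markers (",
         paste(markers, collapse = ", "), ") are present")
  absent <- setdiff(markers, present)
  if (length(absent))
    warning("haemolysis marker(s) absent, QC computed on those present: ",
            paste(absent, collapse = ", "))
  lg <- log2(assay(x)[present, , drop = FALSE] + 1)
  z <- t(apply(lg, 1L, function(v) {
    md <- stats::median(v)
    sc <- stats::mad(v)               # 1.4826 * median absolute deviation
    if (sc == 0) rep(0, length(v)) else (v - md) / sc
  }))
  dimnames(z) <- dimnames(lg)
  hits <- which(z > zCut, arr.ind = TRUE)
  flagged <- data.frame(
    sampleId = colnames(z)[hits[, 2L]],
    markerId = rownames(z)[hits[, 1L]],
    z = z[hits], stringsAsFactors = FALSE)
  flagged <- flagged[order(flagged$sampleId, flagged$markerId), ,
                     drop = FALSE]
  rownames(flagged) <- NULL
  new("QcReport", flagged = flagged, scores = t(z), markerIds = present,
      zCut = zCut)
}

#' Normalize counts to the mean of the top-100 expressed miRNAs
#'
#' The reference set is the 100 endogenous probes with the highest mean count
#' across all samples (all probes when fewer than 100). Each sample is scaled
#' by the grand mean of the reference set divided by that sample's
#' reference-set mean, so every sample's reference-set mean equals the grand
#' mean after normalization.
#'
#' @param x a background-subtracted \linkS4class{MirnaExperiment}.
#' @param nTop reference-set size (default 100).
#' @param referenceSet \code{"global"} (default): one reference set chosen by
#'   cohort-wide mean count, keeping scale factors comparable across samples;
#'   \code{"per_sample"}: each sample normalized by the mean of its own top
#'   \code{nTop} probes.
#' @return a \linkS4class{MirnaExperiment} on the \code{NORMALIZED_COUNT}
#'   scale, with the scale factors in \code{metadata()$normFactor}.
#' @export
top100Normalize <- function(x, nTop = 100,
                            referenceSet = c("global", "per_sample")) {
  stopifnot(is(x, "MirnaExperiment"))
  referenceSet <- match.arg(referenceSet)
  counts <- assay(x)[probeClass(x) == "ENDOGENOUS", , drop = FALSE]
  nTop <- min(nTop, nrow(counts))
  if (referenceSet == "global") {
    ref <- names(sort(rowMeans(counts), decreasing = TRUE))[seq_len(nTop)]
    sampleMeans <- colMeans(counts[ref, , drop = FALSE])
  } else {
    sampleMeans <- apply(counts, 2L, function(v)
      mean(sort(v, decreasing = TRUE)[seq_len(nTop)]))
  }
  if (any(sampleMeans == 0))
    stop("reference-set mean is 0 for sample(s): ",
         paste(colnames(counts)[sampleMeans == 0], collapse = ", "))
  factors <- mean(sampleMeans) / sampleMeans
  out <- sweep(assay(x), 2L, factors, "*")
  res <- MirnaExperiment(out, probeClass = probeClass(x),
                         sampleData = colData(x),
                         scale = "NORMALIZED_COUNT")
  metadata(res) <- metadata(x)
  metadata(res)$normFactor <- factors
  res
}

#' Prevalence filter across clinical groups
#'
#' Retains a marker when, in at least one clinical group, it is expressed
#' above background (value strictly greater than 0 after background
#' subtraction) in strictly more than half of that group's samples. Markers
#' failing the rule in every group are removed.
#'
#' @param x a background-subtracted \linkS4class{MirnaExperiment} (or
#'   normalized counts derived from one: zero still means "not above
#'   background").
#' @param groups factor/character of group membership, one per sample.
#' @return character vector of retained marker ids.
#' @export
prevalenceFilter <- function(x, groups) {
  stopifnot(is(x, "MirnaExperiment"))
  groups <- as.factor(groups)
  if (length(groups) != ncol(x))
    stop("'groups' must have one entry per sample")
  sizes <- table(groups)
  if (any(sizes == 0L))
    stop("empty group(s): ",
         paste(names(sizes)[sizes == 0L], collapse = ", "))
  vals <- assay(x)[probeClass(x) == "ENDOGENOUS", , drop = FALSE]
  keep <- vapply(rownames(vals), function(p) {
    detected <- tapply(vals[p, ] > 0, groups, sum)
    any(detected > sizes / 2)
  }, logical(1))
  names(keep)[keep]
}
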