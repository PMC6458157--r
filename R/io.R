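# Readers and writers for the delimited-text formats the pipeline touches.
# All formats are comma-separated with a mandatory header; a tab dialect is
# auto-detected. Native instrument files (RCC/XML) are out of scope: export
# to CSV from the instrument software first.

#' Read a probe-level count matrix with probe-class annotation
#'
#' The count file holds one digital count per (sample, probe) cell.
#' Orientation is auto-detected from the header: a first column named
#' \code{probe_id} means probes are in rows, a first column named
#' \code{sample_id} means samples are in rows. The annotation file maps every
#' probe id to its class (\code{ENDOGENOUS}, \code{NEG_CONTROL},
#' \code{POS_CONTROL}, \code{SPIKE_IN}).
#'
#' @param path count file (CSV or TSV, auto-detected).
#' @param annotationPath probe annotation file with columns \code{probe_id}
#'   and \code{class}.
#' @return a \linkS4class{MirnaExperiment} on the \code{RAW_COUNT} scale.
#' @seealso [writeCountMatrix()]
#' @export
readCountMatrix <- function(path, annotationPath) {
  tab <- readDelimAuto(path)
  first <- colnames(tab)[1L]
  if (!first %in% c("probe_id", "sample_id"))
    stop("count file header must start with 'probe_id' or 'sample_id', got '",
         first, "'")
  ids <- as.character(tab[[1L]])
  mat <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- ids
  if (first == "sample_id") mat <- t(mat)   # orient to probes x samples
  if (anyDuplicated(colnames(mat)))
    stop("duplicate sample_id: ",
         paste(unique(colnames(mat)[duplicated(colnames(mat))]),
               collapse = ", "))
  if (anyDuplicated(rownames(mat)))
    stop("duplicate probe_id: ",
         paste(unique(rownames(mat)[duplicated(rownames(mat))]),
               collapse = ", "))
  if (anyNA(mat)) stop("count matrix contains missing cells")
  neg <- which(mat < 0, arr.ind = TRUE)
  if (nrow(neg))
    stop(sprintf("negative count at probe '%s', sample '%s'",
                 rownames(mat)[neg[1L, 1L]], colnames(mat)[neg[1L, 2L]]))

  ann <- readDelimAuto(annotationPath)
  if (!all(c("probe_id", "class") %in% colnames(ann)))
    stop("annotation file must have columns 'probe_id' and 'class'")
  cls <- setNames(as.character(ann$class), as.character(ann$probe_id))
  missing <- setdiff(rownames(mat), names(cls))
  if (length(missing))
    stop("probe(s) without annotation: ", paste(missing, collapse = ", "))
  bad <- setdiff(unique(unname(cls[rownames(mat)])), PROBE_CLASSES)
  if (length(bad))
    stop("unknown probe class: ", paste(bad, collapse = ", "))
  MirnaExperiment(mat, probeClass = cls[rownames(mat)], scale = "RAW_COUNT")
}

#' Write a count matrix and its probe annotation
#'
#' Writes the samples-by-probes orientation with a leading \code{sample_id}
#' column; [readCountMatrix()] on the written pair returns an identical
#' object.
#'
#' @param x a \linkS4class{MirnaExperiment}.
#' @param path,annotationPath output CSV paths.
#' @export
writeCountMatrix <- function(x, path, annotationPath) {
  mat <- t(assay(x))
  out <- data.frame(sample_id = rownames(mat), mat, check.names = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  ann <- data.frame(probe_id = rownames(x),
                    class = as.character(rowData(x)$probeClass))
  utils::write.csv(ann, annotationPath, row.names = FALSE, quote = FALSE)
  invisible(c(path, annotationPath))
}

#' Read replicate-level qPCR Ct records
#'
#' Expects columns \code{sample}, \code{assay}, \code{plate},
#' \code{replicate}, \code{ct}. The undetected sentinels \code{Undetermined},
#' \code{NA} and the empty string are mapped to an undetected flag (stored as
#' \code{NA}). Presence of the inter-plate calibrator on every plate and of
#' every spike-in for every sample is enforced.
#'
#' @param path Ct file (CSV or TSV).
#' @param calibratorAssay inter-plate calibrator assay id.
#' @param spikeInAssays spike-in control assay ids.
#' @return a \linkS4class{CtSet}.
#' @export
readCtTable <- function(path, calibratorAssay = "UniSp3_IPC",
                        spikeInAssays = c("cel-254", "UniSp6")) {
  tab <- readDelimAuto(path)
  need <- c("sample", "assay", "plate", "replicate", "ct")
  if (!all(need %in% colnames(tab)))
    stop("Ct file must have columns ", paste(need, collapse = ", "))
  ctRaw <- trimws(as.character(tab$ct))
  undet <- ctRaw %in% c("Undetermined", "NA", "")
  ct <- suppressWarnings(as.numeric(ctRaw))
  ct[undet] <- NA_real_
  if (anyNA(ct[!undet]))
    stop("unparseable ct value: ",
         paste(unique(ctRaw[!undet & is.na(ct)]), collapse = ", "))
  rec <- data.frame(sampleId = as.character(tab$sample),
                    assayId = as.character(tab$assay),
                    plateId = as.character(tab$plate),
                    replicate = as.integer(tab$replicate),
                    ct = ct, stringsAsFactors = FALSE)
  CtSet(rec, calibratorAssay = calibratorAssay,
        spikeInAssays = spikeInAssays)
}

#' Write a CtSet back to CSV
#'
#' Undetected cells are written as \code{Undetermined};
#' [readCtTable()] on the result round-trips.
#' @param x a \linkS4class{CtSet}.
#' @param path output CSV path.
#' @export
writeCtTable <- function(x, path) {
  r <- ctRecords(x)
  ct <- ifelse(is.na(r$ct), "Undetermined", format(r$ct, digits = 15))
  out <- data.frame(sample = r$sampleId, assay = r$assayId,
                    plate = r$plateId, replicate = r$replicate, ct = ct)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read per-sample clinical metadata
#'
#' Expects columns \code{sample_id}, \code{patient_id}, \code{time_point}
#' (A/B/C) and optionally \code{outcome} (TERM/PRETERM/SHORT) and cervical
#' lengths \code{cl_a}, \code{cl_b}, \code{cl_c} in millimetres.
#'
#' When the outcome column is absent it is derived from the cervical-length
#' rule for premature cervical shortening: \code{SHORT} when the length at
#' time point A exceeds 25 mm and the length at B or C falls strictly below
#' 25 mm; otherwise \code{TERM}. A length of exactly 25 mm triggers neither
#' side of the rule, and a patient whose time-point-A length is at or below
#' 25 mm is ineligible for the derivation; both conditions raise a warning
#' and leave the patient \code{TERM}. \code{PRETERM} cannot be derived from
#' cervical lengths and requires an explicit outcome column.
#'
#' @param path metadata file (CSV or TSV).
#' @return data.frame with columns \code{sampleId}, \code{patientId},
#'   \code{timePoint}, \code{outcome}, and \code{clA}, \code{clB}, \code{clC}
#'   when present in the input.
#' @export
readSampleMetadata <- function(path) {
  tab <- readDelimAuto(path)
  need <- c("sample_id", "patient_id", "time_point")
  if (!all(need %in% colnames(tab)))
    stop("metadata file must have columns ", paste(need, collapse = ", "))
  meta <- data.frame(sampleId = as.character(tab$sample_id),
                     patientId = as.character(tab$patient_id),
                     timePoint = as.character(tab$time_point),
                     stringsAsFactors = FALSE)
  badTp <- setdiff(unique(meta$timePoint), c("A", "B", "C"))
  if (length(badTp))
    stop("unknown time point: ", paste(badTp, collapse = ", "))
  clCols <- character(0)
  for (cl in c("cl_a", "cl_b", "cl_c"))
    if (cl %in% colnames(tab)) {
      nm <- c(cl_a = "clA", cl_b = "clB", cl_c = "clC")[[cl]]
      meta[[nm]] <- as.numeric(tab[[cl]])
      clCols <- c(clCols, nm)
    }

  if ("outcome" %in% colnames(tab)) {
    meta$outcome <- as.character(tab$outcome)
    badOut <- setdiff(unique(meta$outcome), c("TERM", "PRETERM", "SHORT"))
    if (length(badOut))
      stop("unknown outcome: ", paste(badOut, collapse = ", "))
  } else {
    if (!all(c("clA", "clB", "clC") %in% colnames(meta)))
      stop("metadata needs either an outcome column or cl_a/cl_b/cl_c ",
           "columns to derive one")
    meta$outcome <- deriveShortOutcome(meta$clA, meta$clB, meta$clC,
                                       meta$patientId)
  }
  if (anyDuplicated(meta[c("patientId", "timePoint")]))
    stop("duplicate (patient_id, time_point) pair in metadata")
  split_out <- split(meta$outcome, meta$patientId)
  bad <- names(split_out)[vapply(split_out,
                                 function(o) length(unique(o)) > 1L,
                                 logical(1))]
  if (length(bad))
    stop("inconsistent outcome across samples of patient(s): ",
         paste(bad, collapse = ", "))
  meta[c("sampleId", "patientId", "timePoint", "outcome", clCols)]
}

# Cervical-shortening derivation; strict inequalities on both sides of the
# 25 mm threshold, exactly 25 mm triggers neither side.
deriveShortOutcome <- function(clA, clB, clC, patientId) {
  minBC <- pmin(clB, clC)
  short <- clA > 25 & minBC < 25
  boundary <- clA == 25 | clB == 25 | clC == 25
  if (any(boundary, na.rm = TRUE))
    warning("cervical length exactly 25 mm for patient(s) ",
            paste(unique(patientId[which(boundary)]), collapse = ", "),
            ": the 25 mm rule uses strict inequalities and was not triggered")
  ineligible <- clA < 25 & minBC < 25
  if (any(ineligible, na.rm = TRUE))
    warning("patient(s) ",
            paste(unique(patientId[which(ineligible)]), collapse = ", "),
            " have short cervix at B/C but time-point-A length not above ",
            "25 mm: ineligible for SHORT derivation, left TERM")
  ifelse(!is.na(short) & short, "SHORT", "TERM")
}

#' Write sample metadata to CSV
#' @param meta data.frame as returned by [readSampleMetadata()].
#' @param path output CSV path.
#' @export
writeSampleMetadata <- function(meta, path) {
  out <- data.frame(sample_id = meta$sampleId, patient_id = meta$patientId,
                    time_point = meta$timePoint, outcome = meta$outcome)
  for (cl in c("clA", "clB", "clC"))
    if (cl %in% colnames(meta))
      out[[c(clA = "cl_a", clB = "cl_b", clC = "cl_c")[[cl]]]] <- meta[[cl]]
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
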