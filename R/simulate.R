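# Synthetic cohort generator. Emulates the statistical structure of a
# first-trimester plasma miRNA study: ~800 endogenous probes of which only a
# few dozen are consistently expressed, negative-control noise probes,
# group-specific fold-change effects rising across three gestational time
# points, a dominant patient-level random effect, occasional
# haemolysis-contaminated samples, and a qPCR layer with inter-plate
# calibrators, extraction/RT spike-ins and duplicate technical replicates.

#' Default group fold effects for the nine-marker panel
#'
#' Per-marker fold changes relative to the TERM group at time points A, B, C
#' for the PRETERM and SHORT outcome groups, on the 4-24x scale reported for
#' first-trimester plasma miRNA biomarkers of preterm birth.
#' @return named list: marker -> list(PRETERM = c(A,B,C), SHORT = c(A,B,C)).
#' @export
defaultFoldEffects <- function() {
  list(
    "hsa-miR-150-5p"  = list(PRETERM = c(6.2, 8.8, 15.4),
                             SHORT   = c(4.5, 6.2, 9.3)),
    "hsa-miR-374a-5p" = list(PRETERM = c(6.2, 8.2, 11.4),
                             SHORT   = c(5.8, 9.5, 8.6)),
    "hsa-miR-19b-3p"  = list(PRETERM = c(4.1, 4.5, 8.0),
                             SHORT   = c(6.1, 5.7, 6.2)),
    "hsa-miR-185-5p"  = list(PRETERM = c(6.2, 4.5, 8.8),
                             SHORT   = c(4.9, 6.8, 5.6)),
    "hsa-miR-15b-5p"  = list(PRETERM = c(11.3, 8.1, 17.4),
                             SHORT   = c(7.5, 8.0, 11.4)),
    "hsa-miR-191-5p"  = list(PRETERM = c(5.5, 7.0, 6.6),
                             SHORT   = c(4.0, 9.2, 10.7)),
    "hsa-miR-93-5p"   = list(PRETERM = c(4.5, 5.3, 6.6),
                             SHORT   = c(3.9, 5.1, 5.1)),
    "hsa-let-7a-5p"   = list(PRETERM = c(6.8, 10.5, 24.2),
                             SHORT   = c(5.4, 8.6, 14.3)),
    "hsa-miR-23a-3p"  = list(PRETERM = c(14.1, 6.5, 21.2),
                             SHORT   = c(8.8, 8.0, 12.8)))
}

#' Simulation configuration
#'
#' Defaults mirror the discovery-cohort design: 16 TERM, 13 PRETERM and 24
#' SHORT patients sampled at three gestational time points, ~800 endogenous
#' probes of which 55 are consistently expressed, 6 negative-control probes,
#' and the nine-marker fold-effect panel of [defaultFoldEffects()]. The
#' patient-level random effect (log2-scale sd 1) dominates other noise
#' sources, matching the patient-specific clustering such cohorts show.
#'
#' @param nPerGroup named integer vector of patients per outcome group.
#' @param nProbes total endogenous probes.
#' @param nExpressed consistently expressed endogenous probes (the rest sit
#'   at or below the background noise floor).
#' @param nNegControls negative-control probes.
#' @param foldEffects named list marker -> list(group -> folds at A, B, C).
#' @param patientSd sd (log2 scale) of the per-patient, per-probe random
#'   effect, constant across time points within a patient.
#' @param countDispersion negative-binomial overdispersion (1/size).
#' @param haemolysisFraction proportion of samples contaminated by
#'   haemolysis (20x spike on the haemolysis-associated markers).
#' @param qpcrNoiseSd replicate-level Ct noise, cycles.
#' @param plateCount qPCR plates.
#' @param seed master seed; all sub-streams derive from it.
#' @return validated config list of class \code{SimConfig}.
#' @export
simConfig <- function(nPerGroup = c(TERM = 16, PRETERM = 13, SHORT = 24),
                      nProbes = 800, nExpressed = 55, nNegControls = 6,
                      foldEffects = defaultFoldEffects(),
                      patientSd = 1, countDispersion = 0.1,
                      haemolysisFraction = 0.05, qpcrNoiseSd = 0.15,
                      plateCount = 4, seed = 1L) {
  stopifnot(all(c("TERM", "PRETERM", "SHORT") %in% names(nPerGroup)))
  if (any(nPerGroup < 1) || nProbes < 1 || nExpressed < 1 ||
      nNegControls < 1 || plateCount < 1)
    stop("all sizes must be >= 1")
  if (nExpressed > nProbes)
    stop("nExpressed (", nExpressed, ") exceeds nProbes (", nProbes, ")")
  folds <- unlist(foldEffects)
  if (length(folds) && any(folds <= 0)) stop("fold effects must be > 0")
  if (haemolysisFraction < 0 || haemolysisFraction > 1)
    stop("haemolysisFraction must lie in [0, 1]")
  if (patientSd < 0 || countDispersion <= 0 || qpcrNoiseSd < 0)
    stop("invalid noise parameters")
  structure(list(nPerGroup = nPerGroup, nProbes = nProbes,
                 nExpressed = nExpressed, nNegControls = nNegControls,
                 foldEffects = foldEffects, patientSd = patientSd,
                 countDispersion = countDispersion,
                 haemolysisFraction = haemolysisFraction,
                 qpcrNoiseSd = qpcrNoiseSd, plateCount = plateCount,
                 seed = as.integer(seed)),
            class = "SimConfig")
}

#' Simulate a digital-count cohort with known ground truth
#'
#' Counts are negative-binomial around per-probe baselines multiplied by the
#' group/time-point fold effect and a log-normal per-patient, per-probe
#' random effect. Negative-control probes are low-mean noise independent of
#' group; non-expressed endogenous probes sit at the negative-control level.
#' A fixed fraction of samples receives a 20x haemolysis spike on the
#' haemolysis-associated markers. Identical seeds give identical output.
#'
#' @param config a [simConfig()].
#' @return list with \code{experiment} (a \linkS4class{MirnaExperiment} with
#'   clinical colData), \code{meta} (data.frame of sample metadata),
#'   \code{truth} (marker ids with any fold effect different from 1),
#'   \code{haemolysedSamples}, and \code{log2Expr} (the latent noise-free
#'   log2 expected expression of the expressed probes, used by
#'   [simulateQpcr()]).
#' @export
simulateCohort <- function(config) {
  stopifnot(inherits(config, "SimConfig"))
  set.seed(subSeed(config$seed, 0L))

  markerIds <- names(config$foldEffects)
  named <- unique(c(markerIds, HAEMOLYSIS_MARKERS))
  if (length(named) > config$nExpressed)
    stop("nExpressed too small for the named markers (need >= ",
         length(named), ")")
  nFillerExpr <- config$nExpressed - length(named)
  nUnexpr <- config$nProbes - config$nExpressed
  probeIds <- c(named,
                sprintf("sim-mir-%04d", seq_len(nFillerExpr + nUnexpr)))
  expressed <- probeIds[seq_len(config$nExpressed)]
  negIds <- paste0("NEG_", seq_len(config$nNegControls))

  # patients and samples, three time points each
  groups <- rep(names(config$nPerGroup), config$nPerGroup)
  nPat <- length(groups)
  patientId <- sprintf("PT%03d", seq_len(nPat))
  meta <- expand.grid(timePoint = c("A", "B", "C"),
                      patientIdx = seq_len(nPat),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  meta <- data.frame(patientId = patientId[meta$patientIdx],
                     timePoint = meta$timePoint,
                     outcome = groups[meta$patientIdx],
                     stringsAsFactors = FALSE)
  meta$sampleId <- paste(meta$patientId, meta$timePoint, sep = "_")
  meta <- meta[order(meta$patientId, meta$timePoint),
               c("sampleId", "patientId", "timePoint", "outcome")]
  rownames(meta) <- NULL
  nSamp <- nrow(meta)

  # cervical lengths consistent with the outcome definitions: shortening
  # groups start above 25 mm at A and fall strictly below 25 mm by B/C
  clA <- round(stats::rnorm(nPat, 32, 2.5), 1)
  clA <- pmax(clA, 26.5)
  clB <- clC <- numeric(nPat)
  term <- groups == "TERM"
  clB[term] <- pmax(round(clA[term] - stats::rnorm(sum(term), 1, 0.8), 1),
                    26)
  clC[term] <- pmax(round(clB[term] - stats::rnorm(sum(term), 1, 0.8), 1),
                    25.5)
  clB[!term] <- round(stats::rnorm(sum(!term), 25.5, 1.5), 1)
  clB[!term][clB[!term] == 25] <- 25.1
  clC[!term] <- pmin(round(stats::rnorm(sum(!term), 21, 1.8), 1), 24.5)
  names(clA) <- names(clB) <- names(clC) <- patientId
  meta$clA <- clA[meta$patientId]
  meta$clB <- clB[meta$patientId]
  meta$clC <- clC[meta$patientId]

  # per-probe baselines; the differential markers sit in a modest-abundance
  # stratum so the top-expressed reference set that drives normalization is
  # carried by stable high-abundance species, as in real plasma profiles
  # specific-signal baselines; every endogenous probe additionally carries a
  # nonspecific-binding floor at the negative-control level, so non-expressed
  # probes sit at background and background subtraction is centred
  baseline <- setNames(numeric(config$nProbes), probeIds)
  baseline[expressed] <-
    exp(stats::rnorm(config$nExpressed, log(300), 1.3)) + 30
  baseline[markerIds] <-
    exp(stats::rnorm(length(markerIds), log(60), 0.4)) + 20
  baseline[setdiff(probeIds, expressed)] <- 0
  negMean <- 5

  # per-patient per-probe random effect on expressed probes (log-normal,
  # log2-scale sd patientSd), constant across the patient's time points
  patEff <- matrix(2^stats::rnorm(nPat * config$nExpressed, 0,
                                  config$patientSd),
                   nrow = config$nExpressed,
                   dimnames = list(expressed, patientId))

  # expected expression per (probe, sample)
  tpIdx <- c(A = 1L, B = 2L, C = 3L)
  mu <- matrix(rep(baseline, nSamp), nrow = config$nProbes,
               dimnames = list(probeIds, meta$sampleId))
  for (j in seq_len(nSamp)) {
    pat <- meta$patientId[j]; grp <- meta$outcome[j]
    tp <- tpIdx[[meta$timePoint[j]]]
    mu[expressed, j] <- mu[expressed, j] * patEff[, pat]
    if (grp != "TERM") {
      for (mk in markerIds) {
        f <- config$foldEffects[[mk]][[grp]]
        if (!is.null(f)) mu[mk, j] <- mu[mk, j] * f[tp]
      }
    }
  }

  size <- 1 / config$countDispersion
  counts <- matrix(stats::rnbinom(length(mu), mu = mu + negMean,
                                  size = size),
                   nrow = nrow(mu), dimnames = dimnames(mu))
  negCounts <- matrix(stats::rnbinom(config$nNegControls * nSamp,
                                     mu = negMean, size = size),
                      nrow = config$nNegControls,
                      dimnames = list(negIds, meta$sampleId))

  nContam <- round(config$haemolysisFraction * nSamp)
  haemolysed <- sort(sample(meta$sampleId, nContam))
  if (nContam > 0)
    counts[HAEMOLYSIS_MARKERS, haemolysed] <-
      counts[HAEMOLYSIS_MARKERS, haemolysed] * 20

  full <- rbind(counts, negCounts)
  experiment <- MirnaExperiment(
    full,
    probeClass = c(rep("ENDOGENOUS", config$nProbes),
                   rep("NEG_CONTROL", config$nNegControls)),
    sampleData = meta, scale = "RAW_COUNT")

  truth <- markerIds[vapply(config$foldEffects, function(fe)
    any(unlist(fe) != 1), logical(1))]
  list(experiment = experiment, meta = meta, truth = truth,
       haemolysedSamples = haemolysed,
       log2Expr = log2(mu[expressed, , drop = FALSE]))
}

#' Simulate a validation qPCR run for a cohort
#'
#' Generates replicate-level Ct records for the requested markers:
#' \code{Ct = ctRef - log2(expression) + plate offset + sample offset +
#' replicate noise}. The inter-plate calibrator is constant per plate up to
#' its offset and noise, and the two spike-in assays (extraction and
#' reverse-transcription controls) carry the per-sample technical offset so
#' that the median-normalization chain can remove it exactly in the
#' noiseless limit.
#'
#' @param config a [simConfig()].
#' @param cohort output of [simulateCohort()].
#' @param markers marker ids to assay (default: the ground-truth panel).
#' @param plateOffsets optional numeric vector (length \code{plateCount}) of
#'   injected plate offsets; drawn N(0, 0.5) by default.
#' @param sampleOffsets optional named per-sample technical offsets; drawn
#'   N(0, 0.3) by default.
#' @param noiseSd replicate Ct noise (cycles); 0 gives the noiseless limit.
#' @param nReplicates technical replicates per reaction (default 2).
#' @return a \linkS4class{CtSet}.
#' @export
simulateQpcr <- function(config, cohort, markers = cohort$truth,
                         plateOffsets = NULL, sampleOffsets = NULL,
                         noiseSd = config$qpcrNoiseSd, nReplicates = 2L) {
  stopifnot(inherits(config, "SimConfig"))
  set.seed(subSeed(config$seed, 77L))
  samples <- cohort$meta$sampleId
  nSamp <- length(samples)
  missing <- setdiff(markers, rownames(cohort$log2Expr))
  if (length(missing))
    stop("marker(s) not in the simulated cohort: ",
         paste(missing, collapse = ", "))

  plates <- sprintf("P%02d", rep_len(seq_len(config$plateCount), nSamp))
  names(plates) <- samples
  if (is.null(plateOffsets))
    plateOffsets <- stats::rnorm(config$plateCount, 0, 0.5)
  names(plateOffsets) <- sprintf("P%02d", seq_len(config$plateCount))
  if (is.null(sampleOffsets))
    sampleOffsets <- stats::rnorm(nSamp, 0, 0.3)
  sampleOffsets <- setNames(rep_len(sampleOffsets, nSamp), samples)

  ctRef <- 30
  calCt <- 20; spikeCt <- c("cel-254" = 18, "UniSp6" = 21)
  rows <- list()
  rep_ids <- seq_len(nReplicates)
  for (s in samples) {
    pl <- plates[[s]]
    for (mk in markers) {
      base <- ctRef - cohort$log2Expr[mk, s] + plateOffsets[[pl]] +
        sampleOffsets[[s]]
      rows[[length(rows) + 1L]] <- data.frame(
        sample = s, assay = mk, plate = pl, replicate = rep_ids,
        ct = base + stats::rnorm(nReplicates, 0, noiseSd))
    }
    for (sp in names(spikeCt)) {
      base <- spikeCt[[sp]] + plateOffsets[[pl]] + sampleOffsets[[s]]
      rows[[length(rows) + 1L]] <- data.frame(
        sample = s, assay = sp, plate = pl, replicate = rep_ids,
        ct = base + stats::rnorm(nReplicates, 0, noiseSd))
    }
  }
  for (pl in unique(plates)) {
    rows[[length(rows) + 1L]] <- data.frame(
      sample = "IPC", assay = "UniSp3_IPC", plate = pl,
      replicate = rep_ids,
      ct = calCt + plateOffsets[[pl]] + stats::rnorm(nReplicates, 0,
                                                     noiseSd))
  }
  rec <- do.call(rbind, rows)
  CtSet(data.frame(sampleId = rec$sample, assayId = rec$assay,
                   plateId = rec$plate, replicate = rec$replicate,
                   ct = rec$ct),
        calibratorAssay = "UniSp3_IPC",
        spikeInAssays = names(spikeCt))
}

#' Write a simulated cohort to the three CSV formats
#'
#' Convenience wrapper producing the counts, probe-annotation and metadata
#' files accepted by [readCountMatrix()] and [readSampleMetadata()].
#' @param cohort output of [simulateCohort()].
#' @param dir output directory (created if needed).
#' @return paths of the written files, invisibly.
#' @export
writeCohortCsv <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  counts <- file.path(dir, "counts.csv")
  probes <- file.path(dir, "probes.csv")
  metaP <- file.path(dir, "metadata.csv")
  writeCountMatrix(cohort$experiment, counts, probes)
  writeSampleMetadata(cohort$meta, metaP)
  invisible(c(counts = counts, probes = probes, metadata = metaP))
}
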