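test_that("simulation is deterministic under a fixed seed", {
  a <- simulateCohort(smallConfig(seed = 7))
  b <- simulateCohort(smallConfig(seed = 7))
  expect_identical(assay(a$experiment), assay(b$experiment))
  expect_identical(a$meta, b$meta)
  expect_identical(a$haemolysedSamples, b$haemolysedSamples)
  qa <- simulateQpcr(smallConfig(seed = 7), a)
  qb <- simulateQpcr(smallConfig(seed = 7), b)
  expect_identical(ctRecords(qa), ctRecords(qb))

  c <- simulateCohort(smallConfig(seed = 8))
  expect_false(identical(assay(a$experiment), assay(c$experiment)))
})

test_that("cohort structure matches the configured design", {
  cfg <- smallConfig(seed = 3)
  co <- simulateCohort(cfg)
  x <- co$experiment
  expect_equal(sum(probeClass(x) == "ENDOGENOUS"), cfg$nProbes)
  expect_equal(sum(probeClass(x) == "NEG_CONTROL"), cfg$nNegControls)
  expect_equal(ncol(x), sum(cfg$nPerGroup) * 3)
  tab <- table(co$meta$patientId)
  expect_true(all(tab == 3))
  byPat <- tapply(co$meta$outcome, co$meta$patientId,
                  function(o) length(unique(o)))
  expect_true(all(byPat == 1))
  # the cervical-length rule is satisfiable on the generated metadata
  short <- co$meta$outcome != "TERM"
  expect_true(all(co$meta$clA[short] > 25))
  expect_true(all(pmin(co$meta$clB, co$meta$clC)[short] < 25))
})

test_that("ground truth is the set of markers with non-unit folds", {
  co <- simulateCohort(smallConfig())
  expect_setequal(co$truth, names(defaultFoldEffects()))

  nullFe <- lapply(defaultFoldEffects(), function(fe)
    list(PRETERM = c(1, 1, 1), SHORT = c(1, 1, 1)))
  co0 <- simulateCohort(smallConfig(foldEffects = nullFe))
  expect_length(co0$truth, 0)
})

test_that("configuration validation rejects impossible designs", {
  expect_error(simConfig(nExpressed = 900), "exceeds nProbes")
  expect_error(simConfig(haemolysisFraction = 1.5), "\\[0, 1\\]")
  expect_error(simConfig(foldEffects = list(x = list(PRETERM = c(-1, 1, 1)))),
               "fold effects")
  expect_error(simulateCohort(simConfig(nExpressed = 5)),
               "nExpressed too small")
})

test_that("haemolysis spike is visible and confined to flagged samples", {
  cfg <- simConfig(nPerGroup = c(TERM = 10, PRETERM = 10, SHORT = 10),
                   haemolysisFraction = 0.04, seed = 11)
  co <- simulateCohort(cfg)
  expect_length(co$haemolysedSamples, round(0.04 * ncol(co$experiment)))
  counts <- assay(co$experiment)[HAEMOLYSIS_MARKERS, ]
  contaminated <- colnames(counts) %in% co$haemolysedSamples
  expect_gt(min(colMeans(log2(counts[, contaminated] + 1))),
            max(colMeans(log2(counts[, !contaminated] + 1))))
})

test_that("qPCR simulation carries the designed technical structure", {
  cfg <- smallConfig(seed = 5, plateCount = 2)
  co <- simulateCohort(cfg)
  ct <- simulateQpcr(cfg, co)
  r <- ctRecords(ct)
  expect_setequal(unique(r$replicate), 1:2)
  # calibrator on every plate, spike-ins for every cohort sample
  expect_setequal(unique(r$plateId[r$assayId == "UniSp3_IPC"]),
                  unique(r$plateId))
  for (sp in c("cel-254", "UniSp6"))
    expect_setequal(unique(r$sampleId[r$assayId == sp]), co$meta$sampleId)

  # a 4-fold expression difference is 2 Ct cycles in the noiseless limit
  fe <- list("hsa-miR-150-5p" = list(PRETERM = c(4, 1, 1)))
  cfg2 <- simConfig(nPerGroup = c(TERM = 6, PRETERM = 6, SHORT = 1),
                    foldEffects = fe, patientSd = 0, seed = 5)
  co2 <- simulateCohort(cfg2)
  ct2 <- simulateQpcr(cfg2, co2, plateOffsets = rep(0, 4),
                      sampleOffsets = rep(0, nrow(co2$meta)), noiseSd = 0)
  r2 <- ctRecords(collapseReplicates(ct2))
  r2 <- r2[r2$assayId == "hsa-miR-150-5p", ]
  m <- merge(r2, co2$meta, by = "sampleId")
  mA <- m[m$timePoint == "A", ]
  expect_equal(mean(mA$ct[mA$outcome == "TERM"]) -
                 mean(mA$ct[mA$outcome == "PRETERM"]), 2)
})

test_that("count-level fold estimate recovers an injected 4-fold effect", {
  # single marker, fold 4 at time point A; pipeline estimate from
  # normalized counts should land in [3.2, 4.8] in nearly all cohorts
  fe <- list("hsa-miR-150-5p" = list(PRETERM = c(4, 1, 1)))
  est <- vapply(1:25, function(s) {
    cfg <- simConfig(nPerGroup = c(TERM = 50, PRETERM = 50, SHORT = 1),
                     foldEffects = fe, patientSd = 0.25,
                     haemolysisFraction = 0, seed = s)
    co <- simulateCohort(cfg)
    norm <- top100Normalize(subtractBackground(co$experiment))
    v <- assay(norm)["hsa-miR-150-5p", ]
    iA <- co$meta$timePoint == "A"
    mean(v[iA & co$meta$outcome == "PRETERM"]) /
      mean(v[iA & co$meta$outcome == "TERM"])
  }, numeric(1))
  expect_gte(mean(est >= 3.2 & est <= 4.8), 0.9)
})

test_that("discovery power decreases as patient variability grows", {
  fe <- lapply(defaultFoldEffects(), function(x)
    list(PRETERM = c(2.2, 2.2, 2.2), SHORT = c(2.2, 2.2, 2.2)))
  power <- vapply(c(0.5, 1.25, 2.5), function(psd) {
    hits <- vapply(1:8, function(s) {
      cfg <- simConfig(nPerGroup = c(TERM = 12, PRETERM = 12, SHORT = 12),
                       foldEffects = fe, patientSd = psd,
                       haemolysisFraction = 0, seed = 300 + s)
      co <- simulateCohort(cfg)
      d <- suppressWarnings(runDiscovery(co$experiment, co$meta))
      length(intersect(d$panel, co$truth))
    }, numeric(1))
    mean(hits) / 9
  }, numeric(1))
  expect_true(power[1] >= power[2] && power[2] >= power[3])
})

test_that("simulated cohorts round-trip through the CSV writers", {
  co <- simulateCohort(smallConfig(seed = 21))
  dir <- withr::local_tempdir()
  paths <- writeCohortCsv(co, dir)
  x <- readCountMatrix(paths["counts"], paths["probes"])
  expect_equal(assay(x), assay(co$experiment))
  expect_equal(readSampleMetadata(paths["metadata"]), co$meta)
})
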