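test_that("replicate collapsing averages, computes CV, and flags >= 2%", {
  rec <- data.frame(
    sampleId = c("s1", "s1", "s2", "s2", "s3"),
    assayId = "mir-x", plateId = "P1",
    replicate = c(1, 2, 1, 2, 1),
    ct = c(24.0, 24.2, 20, 22, 25))
  rec <- rbind(rec,
    data.frame(sampleId = "IPC", assayId = "CAL", plateId = "P1",
               replicate = 1, ct = 20),
    expand.grid(sampleId = c("s1", "s2", "s3"),
                assayId = c("cel-254", "UniSp6"), plateId = "P1",
                replicate = 1, ct = 18, stringsAsFactors = FALSE))
  ct <- collapseReplicates(CtSet(rec, "CAL", c("cel-254", "UniSp6")))
  r <- ctRecords(ct)
  r <- r[r$assayId == "mir-x", ]
  r <- r[order(r$sampleId), ]
  expect_equal(r$ct, c(24.1, 21, 25))
  expect_equal(r$cv, c(100 * sd(c(24, 24.2)) / 24.1,
                       100 * sd(c(20, 22)) / 21, NA))
  expect_equal(r$cvFlag, c(FALSE, TRUE, FALSE))
})

test_that("undetected replicates are excluded; all-undetected stays flagged", {
  rec <- toyCtRecords()
  rec$ct[rec$sampleId == "s1" & rec$assayId == "mir-x"] <- c(25, NA)
  rec$ct[rec$sampleId == "s2" & rec$assayId == "mir-x"] <- c(NA, NA)
  ct <- collapseReplicates(CtSet(rec, "CAL", c("cel-254", "UniSp6")))
  r <- ctRecords(ct)
  expect_equal(r$ct[r$sampleId == "s1" & r$assayId == "mir-x"], 25)
  expect_true(is.na(r$ct[r$sampleId == "s2" & r$assayId == "mir-x"]))
})

test_that("median normalization removes plate then sample offsets", {
  # calibrator Cts 20 and 22: plate medians 21, offsets -1 and +1;
  # a raw Ct of 25 on plate 2 becomes 24 after step 1. The sample on
  # plate 2 also carries a +1 spike-in offset (both spikes 18 -> 19
  # against a two-sample median of 18.5... constructed so the target
  # lands exactly where hand arithmetic says.
  rec <- rbind(
    data.frame(sampleId = "s1", assayId = "mir-x", plateId = "P1",
               replicate = 1, ct = 25),
    data.frame(sampleId = "s2", assayId = "mir-x", plateId = "P2",
               replicate = 1, ct = 25),
    data.frame(sampleId = c("s1", "s2"), assayId = "cel-254",
               plateId = c("P1", "P2"), replicate = 1, ct = c(17, 19)),
    data.frame(sampleId = c("s1", "s2"), assayId = "UniSp6",
               plateId = c("P1", "P2"), replicate = 1, ct = c(21, 23)),
    data.frame(sampleId = "IPC", assayId = "CAL", plateId = c("P1", "P2"),
               replicate = 1, ct = c(20, 22)))
  norm <- medianNormalizeCt(CtSet(rec, "CAL", c("cel-254", "UniSp6")))
  # step 1: s1 Ct 25 -> 26 (offset -1), s2 25 -> 24 (offset +1)
  # step 2: plate-corrected spikes are 18/22 for s1 and 18/22 for s2,
  # so sample offsets are 0 and the step-1 values stand
  expect_equal(as.vector(assay(norm)[, c("s1", "s2")]), c(26, 24))
  expect_equal(unname(metadata(norm)$plateOffset[c("P1", "P2")]), c(-1, 1))

  # spike-in-only offset: single plate, one sample's spikes 1 cycle high
  rec2 <- rbind(
    data.frame(sampleId = c("s1", "s2", "s3"), assayId = "mir-x",
               plateId = "P1", replicate = 1, ct = c(30, 30, 30)),
    data.frame(sampleId = c("s1", "s2", "s3"), assayId = "cel-254",
               plateId = "P1", replicate = 1, ct = c(18, 18, 19)),
    data.frame(sampleId = c("s1", "s2", "s3"), assayId = "UniSp6",
               plateId = "P1", replicate = 1, ct = c(21, 21, 22)),
    data.frame(sampleId = "IPC", assayId = "CAL", plateId = "P1",
               replicate = 1, ct = 20))
  norm2 <- medianNormalizeCt(CtSet(rec2, "CAL", c("cel-254", "UniSp6")))
  expect_equal(as.vector(assay(norm2)[, c("s1", "s2", "s3")]),
               c(30, 30, 29))

  # single plate, identical spikes across samples: identity
  ct3 <- toyCtSet()
  norm3 <- medianNormalizeCt(ct3)
  expect_equal(as.vector(assay(norm3)[, c("s1", "s2")]), c(25, 26))
})

test_that("normalization chain exactly inverts injected offsets", {
  cfg <- simConfig(seed = 3, plateCount = 2,
                   nPerGroup = c(TERM = 3, PRETERM = 3, SHORT = 3),
                   haemolysisFraction = 0)
  co <- simulateCohort(cfg)
  ct <- simulateQpcr(cfg, co, plateOffsets = c(-1, 1),
                     sampleOffsets = rep(0, nrow(co$meta)), noiseSd = 0)
  norm <- medianNormalizeCt(ct)
  truth <- 30 - co$log2Expr[rownames(norm), colnames(norm)]
  expect_equal(assay(norm), truth, tolerance = 1e-12)

  # sample offsets with zero median are also removed exactly
  off <- rep_len(c(-0.5, 0, 0.5), nrow(co$meta))
  ct2 <- simulateQpcr(cfg, co, plateOffsets = c(-1, 1),
                      sampleOffsets = off, noiseSd = 0)
  norm2 <- medianNormalizeCt(ct2)
  expect_equal(assay(norm2), truth, tolerance = 1e-12)
})

test_that("relative expression anchors the control-group mean at 1", {
  m <- matrix(c(25, 27), nrow = 1, dimnames = list("mk", c("a", "b")))
  re <- relativeExpression(ctMatrix(m), c("TERM", "TERM"), "mk")
  expect_equal(re$relExpr, c(1.6, 0.4))
  expect_equal(unname(attr(re, "groupMean")["TERM"]), 1)

  # experimental group identical to control: mean relative expression 1
  m2 <- matrix(c(25, 27, 25, 27), nrow = 1,
               dimnames = list("mk", paste0("s", 1:4)))
  re2 <- relativeExpression(ctMatrix(m2),
                            c("TERM", "TERM", "PRETERM", "PRETERM"), "mk")
  expect_equal(unname(attr(re2, "groupMean")), c(1, 1))

  # undetected samples are excluded with a warning
  m3 <- m2; m3[1, 4] <- NA
  expect_warning(re3 <- relativeExpression(ctMatrix(m3),
                   c("TERM", "TERM", "PRETERM", "PRETERM"), "mk"),
                 "undetected")
  expect_equal(nrow(re3), 3)
})

test_that("fold change is 2^-dG and antisymmetric", {
  m <- matrix(c(24, 24, 26, 26), nrow = 1,
              dimnames = list("mk", paste0("s", 1:4)))
  g <- c("PRETERM", "PRETERM", "TERM", "TERM")
  fc <- foldChange(ctMatrix(m), g, "mk", "PRETERM", "TERM")
  expect_equal(fc@dg, -2)
  expect_equal(fc@fold, 4)

  mEq <- matrix(rep(25, 4), nrow = 1,
                dimnames = list("mk", paste0("s", 1:4)))
  expect_equal(foldChange(ctMatrix(mEq), g, "mk", "PRETERM", "TERM")@fold, 1)

  mDown <- matrix(c(28, 28, 26, 26), nrow = 1,
                  dimnames = list("mk", paste0("s", 1:4)))
  expect_equal(foldChange(ctMatrix(mDown), g, "mk", "PRETERM", "TERM")@fold,
               0.25)

  set.seed(31)
  for (i in 1:20) {
    mr <- matrix(rnorm(12, 25, 2), nrow = 1,
                 dimnames = list("mk", paste0("s", 1:12)))
    gr <- rep(c("TERM", "PRETERM"), 6)
    f1 <- foldChange(ctMatrix(mr), gr, "mk", "PRETERM", "TERM")@fold
    f2 <- foldChange(ctMatrix(mr), gr, "mk", "TERM", "PRETERM")@fold
    expect_equal(f1 * f2, 1, tolerance = 1e-12)
  }

  expect_error(foldChange(ctMatrix(m), g, "mk", "SHORT", "TERM"),
               "empty")
})

test_that("fold change equals the geometric-mean ratio of relative expression", {
  set.seed(8)
  mr <- matrix(rnorm(16, 25, 1.5), nrow = 1,
               dimnames = list("mk", paste0("s", 1:16)))
  gr <- rep(c("TERM", "PRETERM"), each = 8)
  fc <- foldChange(ctMatrix(mr), gr, "mk", "PRETERM", "TERM")
  re <- fc@relExpr
  geo <- function(v) exp(mean(log(v)))
  expect_equal(geo(re$relExpr[re$group == "PRETERM"]) /
                 geo(re$relExpr[re$group == "TERM"]),
               fc@fold, tolerance = 1e-12)
})
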