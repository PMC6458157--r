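# Small in-code fixtures shared across test files.

toyCounts <- function() {
  m <- matrix(c(10, 20, 5, 40, 80, 6), nrow = 3,
              dimnames = list(c("mir-a", "mir-b", "NEG_1"),
                              c("s1", "s2")))
  MirnaExperiment(m, probeClass = c("ENDOGENOUS", "ENDOGENOUS",
                                    "NEG_CONTROL"))
}

# a complete tiny CtSet: one or two plates, duplicate replicates,
# calibrator and both spike-ins present
toyCtRecords <- function(samples = c("s1", "s2"), plates = c("P1", "P1"),
                         targetCt = c(25, 26), calCt = c(P1 = 20),
                         spikeCt = c(18, 18)) {
  rec <- data.frame()
  for (i in seq_along(samples)) {
    rec <- rbind(rec,
      data.frame(sampleId = samples[i], assayId = "mir-x",
                 plateId = plates[i], replicate = 1:2,
                 ct = targetCt[i] + c(0, 0)),
      data.frame(sampleId = samples[i],
                 assayId = rep(c("cel-254", "UniSp6"), each = 2),
                 plateId = plates[i], replicate = rep(1:2, 2),
                 ct = rep(spikeCt[i], 4)))
  }
  for (pl in names(calCt))
    rec <- rbind(rec, data.frame(sampleId = "IPC", assayId = "CAL",
                                 plateId = pl, replicate = 1:2,
                                 ct = calCt[[pl]]))
  rec
}

toyCtSet <- function(...) {
  CtSet(toyCtRecords(...), calibratorAssay = "CAL",
        spikeInAssays = c("cel-254", "UniSp6"))
}

# normalized-Ct MirnaExperiment from a plain matrix
ctMatrix <- function(m) {
  MirnaExperiment(m, probeClass = rep("ENDOGENOUS", nrow(m)),
                  scale = "NORMALIZED_CT")
}

smallConfig <- function(seed = 1, ...) {
  simConfig(nPerGroup = c(TERM = 4, PRETERM = 4, SHORT = 4), nProbes = 60,
            nExpressed = 20, seed = seed, ...)
}

# brute-force Mann-Whitney two-sided exact p by label enumeration
enumMannWhitneyP <- function(x, y) {
  n <- length(x); m <- length(y)
  pooled <- c(x, y)
  idx <- utils::combn(n + m, n)
  uStat <- function(xs, ys) sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  obs <- uStat(x, y)
  us <- apply(idx, 2L, function(ii) uStat(pooled[ii], pooled[-ii]))
  mu <- n * m / 2
  mean(abs(us - mu) >= abs(obs - mu) - 1e-9)
}

# hand step-up BH oracle
stepUpBH <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}
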