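test_that("D'Agostino-Pearson matches independent reference values", {
  # expected values frozen from an independent implementation of the
  # omnibus K2 test on deterministic vectors
  r1 <- dagostinoPearson(sin(1:20))
  expect_equal(unname(r1$statistic), 8.828599767037225, tolerance = 1e-10)
  expect_equal(r1$p.value, 0.012103024686599694, tolerance = 1e-10)

  r2 <- dagostinoPearson((1:30)^2)
  expect_equal(unname(r2$statistic), 3.8582005415682414, tolerance = 1e-10)
  expect_equal(r2$p.value, 0.14527885132570745, tolerance = 1e-10)

  r3 <- dagostinoPearson(qnorm((1:50 - 0.5) / 50))
  expect_equal(unname(r3$statistic), 0.005590930844153561, tolerance = 1e-9)

  # strongly non-normal input is rejected
  r4 <- dagostinoPearson(qexp((1:100 - 0.5) / 100))
  expect_equal(unname(r4$statistic), 45.67117163222572, tolerance = 1e-8)
  expect_lt(r4$p.value, 0.05)

  expect_error(dagostinoPearson(1:7), "n >= 8")
  expect_error(dagostinoPearson(rep(2, 12)), "constant")
})

test_that("normality test holds its size on Gaussian samples", {
  set.seed(1234)
  rej <- mean(vapply(1:800, function(i)
    dagostinoPearson(rnorm(200))$p.value < 0.05, logical(1)))
  expect_gt(rej, 0.02)
  expect_lt(rej, 0.08)
})

test_that("group comparison gates on normality and matches exact Mann-Whitney", {
  gc <- groupCompare(c(1, 2, 3), c(4, 5, 6))
  expect_equal(gc$testUsed, "MANN_WHITNEY")  # n < 8: nonparametric branch
  expect_equal(gc$p.value, 0.1)              # 2/20 by enumeration

  # identical samples give p = 1
  expect_equal(groupCompare(c(1, 2, 3), c(1, 2, 3))$p.value, 1)

  # Gaussian-looking large samples take the t branch
  set.seed(2)
  gcT <- groupCompare(rnorm(40), rnorm(40))
  expect_equal(gcT$testUsed, "T_TEST")
  expect_false(anyNA(gcT$normalityP))

  # exponential samples are routed to Mann-Whitney
  gcM <- groupCompare(qexp((1:20 - 0.5) / 20), qexp((1:20 - 0.5) / 20) + 1)
  expect_equal(gcM$testUsed, "MANN_WHITNEY")

  expect_error(groupCompare(1, c(1, 2)), "at least 2")
})

test_that("exact Mann-Whitney p equals label-enumeration brute force", {
  set.seed(77)
  for (i in 1:25) {
    n <- sample(2:5, 1); m <- sample(2:5, 1)
    x <- round(rnorm(n), 3); y <- round(rnorm(m, 0.5), 3)
    if (anyDuplicated(c(x, y))) next
    gc <- groupCompare(x, y)
    expect_equal(gc$p.value, enumMannWhitneyP(x, y), tolerance = 1e-12,
                 label = sprintf("instance %d", i))
  }
})

test_that("Welch log-geometric-mean test sees exact log2 shifts", {
  x <- c(8, 16, 32)
  w <- welchLogGeomeanTest(4 * x, x, offset = 0)
  expect_equal(w$log2Ratio, 2)

  expect_equal(welchLogGeomeanTest(x, x)$p.value, 1)

  # equals a Welch t-test on the logs
  set.seed(3)
  a <- rpois(15, 40); b <- rpois(12, 60)
  w2 <- welchLogGeomeanTest(a, b)
  oracle <- t.test(log2(a + 1), log2(b + 1), var.equal = FALSE)
  expect_equal(w2$p.value, oracle$p.value)
  expect_equal(w2$statistic, unname(oracle$statistic))

  expect_error(welchLogGeomeanTest(c(0, 0), c(1, 2)), "all-zero")
  expect_error(welchLogGeomeanTest(c(-1, 2), c(1, 2)), "non-negative")
})

test_that("group tests hold their size under the null", {
  set.seed(555)
  rejGc <- mean(vapply(1:600, function(i)
    groupCompare(rnorm(50), rnorm(50))$p.value < 0.05, logical(1)))
  expect_gt(rejGc, 0.03); expect_lt(rejGc, 0.075)
  rejW <- mean(vapply(1:600, function(i)
    welchLogGeomeanTest(rpois(30, 50), rpois(30, 50))$p.value < 0.05,
    logical(1)))
  expect_gt(rejW, 0.03); expect_lt(rejW, 0.075)
})

test_that("group comparison power grows with effect size", {
  set.seed(42)
  power <- vapply(c(0, 0.5, 1.2), function(d)
    mean(vapply(1:150, function(i)
      groupCompare(rnorm(15), rnorm(15, d))$p.value < 0.05, logical(1))),
    numeric(1))
  expect_true(all(diff(power) > 0))
})

test_that("longitudinal test handles degenerate, Gaussian and skewed designs", {
  # every subject constant: Friedman statistic 0, p 1
  flat <- suppressWarnings(
    longitudinalTest(matrix(rep(1:6, 3), ncol = 3)))
  expect_equal(flat$testUsed, "FRIEDMAN")
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p.value, 1)

  # Gaussian branch: epsilon within its analytic bounds, trend detected
  set.seed(10)
  base <- rnorm(20, 10)
  vals <- cbind(A = base + rnorm(20, 0, 0.5),
                B = base + 1 + rnorm(20, 0, 0.5),
                C = base + 2 + rnorm(20, 0, 0.5))
  g <- longitudinalTest(vals)
  expect_equal(g$testUsed, "RM_ANOVA_GG")
  expect_gte(g$epsilon, 0.5)
  expect_lte(g$epsilon, 1)
  expect_lt(g$p.value, 0.01)
  expect_lt(g$trendP, 0.01)

  # non-Gaussian branch at larger n matches stats::friedman.test
  set.seed(11)
  sk <- matrix(rexp(60), ncol = 3)
  sk[, 3] <- sk[, 3] + 2
  f <- longitudinalTest(sk)
  expect_equal(f$testUsed, "FRIEDMAN")
  expect_equal(f$p.value, friedman.test(sk)$p.value)
  expect_true(all(f$dunn$p.adj <= 1))
  expect_lt(f$dunn$p.adj[f$dunn$pair == "1 vs 3"], 0.05)

  # missing time points are dropped with a warning; too few subjects error
  miss <- rbind(vals[1:3, ], c(NA, 1, 2))
  expect_warning(longitudinalTest(miss), "dropping 1 subject")
  expect_error(suppressWarnings(
    longitudinalTest(rbind(vals[1:2, ], c(NA, 1, 2)))), "at least 3")
})

test_that("small-sample Friedman p is the exact permutation probability", {
  # strictly increasing profiles in all 6 subjects: the most extreme
  # configuration, whose exact tail is 3!/6^6
  set.seed(12)
  vals <- matrix(rep(c(1, 2, 3), each = 6), ncol = 3) +
    matrix(runif(18, 0, 0.01), ncol = 3)
  lt <- longitudinalTest(vals)
  expect_equal(lt$statistic, 12)
  expect_equal(lt$p.value, 6 / 6^6, tolerance = 1e-12)

  # brute-force enumeration oracle on a non-extreme 5-subject design
  set.seed(13)
  v5 <- matrix(rnorm(15), ncol = 3)
  lt5 <- longitudinalTest(v5)
  ranks <- t(apply(v5, 1, rank))
  perms <- rbind(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1))
  grid <- as.matrix(expand.grid(rep(list(1:6), 5)))
  qOf <- function(R) 12 / (5 * 3 * 4) * sum(R^2) - 3 * 5 * 4
  qs <- apply(grid, 1, function(idx) qOf(colSums(perms[idx, , drop = FALSE])))
  expect_equal(lt5$p.value, mean(qs >= qOf(colSums(ranks)) - 1e-9),
               tolerance = 1e-12)
})

test_that("Greenhouse-Geisser epsilon is 1 under compound symmetry", {
  S <- diag(3) * 2 + 0.5
  expect_equal(mirScreen:::ggEpsilon(S), 1)
  # maximally non-spherical: variance concentrated in one contrast
  v <- c(1, -2, 1)
  S2 <- tcrossprod(v) + diag(3) * 1e-9
  expect_equal(mirScreen:::ggEpsilon(S2), 0.5, tolerance = 1e-6)
})

test_that("BH adjustment matches the hand step-up construction", {
  expect_equal(bhFdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bhFdr(c(0.005, 0.5)), c(0.01, 0.5))
  expect_equal(bhFdr(0.3), 0.3)
  expect_error(bhFdr(c(0.1, 1.2)), "\\[0, 1\\]")

  set.seed(20)
  for (i in 1:20) {
    p <- runif(sample(3:40, 1))
    expect_equal(bhFdr(p), stepUpBH(p), tolerance = 1e-12)
  }

  # raising any single p never lowers any q
  p <- c(0.01, 0.2, 0.04, 0.8)
  q0 <- bhFdr(p)
  p2 <- p; p2[3] <- 0.5
  expect_true(all(bhFdr(p2) >= q0 - 1e-12))

  # order invariance
  perm <- c(3, 1, 4, 2)
  expect_equal(bhFdr(p[perm]), q0[perm])
})
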