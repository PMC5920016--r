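# AUC, rank-sum, dichotomization, KM/log-rank, NPV, joint risk, full report

test_that("AUC matches hand cases and the all-pairs brute-force oracle", {
  expect_equal(computeAUC(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(computeAUC(c(0.1, 0.2, 0.8, 0.9), c(1, 1, 0, 0)), 0)
  expect_equal(computeAUC(c(1, 1, 1, 1), c(1, 1, 0, 0)), 0.5)
  expect_equal(computeAUC(c(3, 1, 2), c(1, 0, 0)), 1)
  set.seed(81)
  for (i in 1:5) {
    s <- sample(rnorm(20))
    s[sample(20, 4)] <- s[1]              # inject ties
    y <- rbinom(20, 1, 0.5)
    if (sum(y) %in% c(0, 20)) next
    expect_equal(computeAUC(s, y), aucBruteForce(s, y))
  }
  # factor labels behave like 0/1
  f <- factor(c("pCR", "pCR", "RD", "RD"), levels = c("RD", "pCR"))
  expect_equal(computeAUC(c(4, 3, 2, 1), f), 1)
  expect_error(computeAUC(1:4, c(1, 1, 1, 1)), "both classes")
})

test_that("exact rank-sum branch reproduces the full-enumeration oracle", {
  res <- ranksumTest(c(1, 2, 3, 4, 5, 6), c(0, 0, 0, 1, 1, 1))
  expect_true(res$exact)
  expect_equal(res$p.value, 0.1)          # 2 * 1/C(6,3)... = 2/20
  set.seed(82)
  for (i in 1:4) {
    s <- rnorm(12)
    y <- c(rep(1, 5), rep(0, 7))
    res <- ranksumTest(s, y)
    expect_true(res$exact)
    expect_equal(res$p.value, ranksumEnumOracle(s[y == 1], s[y == 0]))
  }
})

test_that("normal-approximation branch agrees with the exact branch near the boundary", {
  set.seed(83)
  s <- rnorm(19)                          # n = 19: exact
  y <- c(rep(1, 9), rep(0, 10))
  pexact <- ranksumTest(s, y)$p.value
  # force the approximation by adding a tie between two RD subjects only;
  # the pCR/RD rank configuration is unchanged
  papprox <- suppressWarnings(stats::wilcox.test(
    s[y == 1], s[y == 0], exact = FALSE, correct = TRUE))$p.value
  expect_lt(abs(pexact - papprox), 0.02)
  # ties at small n choose the approximation branch
  res <- ranksumTest(c(1, 1, 2, 3), c(1, 0, 1, 0))
  expect_false(res$exact)
})

test_that("dichotomization keeps an exact top fraction with deterministic ties", {
  s <- setNames(c(10, 9, 8, 1, 2, 3, 4, 5, 6, 7), paste0("p", 1:10))
  pos <- dichotomizeTopFraction(s, 0.30)
  expect_identical(sum(pos), 3L)
  expect_true(all(pos[c("p1", "p2", "p3")]))
  # boundary tie: two samples share the 3rd-best score
  s2 <- setNames(c(10, 9, 8, 8, 2, 3, 4, 5, 6, 7), paste0("p", 1:10))
  expect_warning(pos2 <- dichotomizeTopFraction(s2, 0.30), "ties")
  expect_identical(sum(pos2), 3L)
  expect_true(pos2[["p3"]]); expect_false(pos2[["p4"]])  # ID order wins
  # non-multiple fraction rounds up
  expect_identical(sum(dichotomizeTopFraction(setNames(1:7, paste0("q", 1:7)),
                                              0.30)), 3L)
  expect_error(dichotomizeTopFraction(s, 0), "fraction")
})

test_that("KM estimator matches the hand-computed product-limit curve", {
  km <- kmEstimate(c(1, 2, 3, 4), c(1, 1, 1, 1))
  expect_equal(km$curves$survival, c(0.75, 0.5, 0.25, 0))
  expect_equal(unname(km$median), 2)
  expect_equal(km$maxFollowUp, 4)
  # censoring: events at 1 and 3, censored at 2 -> S = 3/4, then 3/8
  km2 <- kmEstimate(c(1, 2, 3, 4), c(1, 0, 1, 1))
  ev <- km2$curves[km2$curves$nEvent > 0, ]
  expect_equal(ev$survival[ev$time == 1], 0.75)
  expect_equal(ev$survival[ev$time == 3], 0.75 * 0.5)
  # all censored: survival never drops, median undefined
  km3 <- kmEstimate(c(5, 6, 7), c(0, 0, 0))
  expect_true(is.na(km3$median))
  expect_equal(km3$maxFollowUp, 7)
  expect_error(kmEstimate(c(-1, 2), c(1, 1)), "negative")
  expect_error(kmEstimate(c(1, 2), c(1, 2)), "0/1")
})

test_that("log-rank matches the hypergeometric oracle and its invariances", {
  tt <- c(1, 2, 3, 4); ev <- c(1, 1, 1, 1); gr <- c("A", "A", "B", "B")
  res <- logrankTest(tt, ev, gr)
  expect_equal(res$statistic, 49 / 17, tolerance = 1e-12)
  orc <- logrankOracle(tt, ev, gr)
  expect_equal(res$statistic, orc$statistic, tolerance = 1e-12)
  expect_equal(res$p.value, orc$p.value, tolerance = 1e-12)
  # group-label swap and patient reordering leave the statistic unchanged
  expect_equal(logrankTest(tt, ev, rev(gr))$statistic,
               logrankTest(rev(tt), rev(ev), gr)$statistic, tolerance = 1e-12)
  set.seed(84)
  n <- 40
  tt2 <- rexp(n); ev2 <- rbinom(n, 1, 0.7); gr2 <- rep(c("A", "B"), 20)
  perm <- sample(n)
  expect_equal(logrankTest(tt2, ev2, gr2)$statistic,
               logrankTest(tt2[perm], ev2[perm], gr2[perm])$statistic,
               tolerance = 1e-12)
  orc2 <- logrankOracle(tt2, ev2, gr2)
  expect_equal(logrankTest(tt2, ev2, gr2)$statistic, orc2$statistic,
               tolerance = 1e-8)
  expect_error(logrankTest(tt, ev, rep("A", 4)), "two non-empty groups")
})

test_that("NPV and joint false-negative risk follow their definitions", {
  pos <- c(TRUE, TRUE, FALSE, FALSE, FALSE)
  y <- c(1, 0, 0, 0, 1)                   # one responder slips to negative
  res <- npv(pos, y)
  expect_equal(res$npv, 2 / 3)
  expect_equal(res$falseNegativeRisk, 1 / 3)
  expect_identical(res$nNegative, 3L)
  expect_error(npv(rep(TRUE, 3), c(1, 0, 1)), "no predicted-negative")

  expect_equal(as.numeric(jointFalseNegativeRisk(c(0.3, 0.3))), 0.09)
  expect_equal(as.numeric(jointFalseNegativeRisk(c(0.5, 0.2, 0.1))), 0.01)
  expect_error(jointFalseNegativeRisk(c(0.3, 1.2)), "validation error")
})

test_that("evaluatePredictor composes its parts and is order-invariant", {
  cfg <- tinyConfig(seed = 85, nGenes = 60, nPatients = 80, nDrugs = 1)
  sim <- simulateCellLinePanel(cfg)
  pat <- simulatePatientCohort(cfg, sim$truth)
  co <- pat$cohort
  set.seed(86)
  sc <- setNames(rnorm(80), sampleIds(co))
  rep1 <- evaluatePredictor(sc, co, predictorTag = "x", cohortTag = "c")
  expect_s4_class(rep1, "EvaluationReport")
  # parts recomputed independently
  resp <- responseLabels(co)
  expect_equal(rep1@auc, computeAUC(sc, resp))
  expect_equal(rep1@ranksumP, ranksumTest(sc, resp)$p.value)
  expect_identical(unname(rep1@groupSizes["positive"]),
                   as.integer(ceiling(0.30 * 80)))
  pos <- dichotomizeTopFraction(sc, 0.30, sampleIds(co))
  expect_equal(rep1@npv, npv(pos, resp)$npv)
  # shuffling the score vector's storage order changes nothing
  rep2 <- evaluatePredictor(sample(sc), co, predictorTag = "x",
                            cohortTag = "c")
  expect_equal(rep1@auc, rep2@auc)
  expect_equal(rep1@logrankP, rep2@logrankP)
  expect_equal(rep1@medianSurvival, rep2@medianSurvival)
  # subtype filter: er_neg is all-TRUE by design, so filtering is a no-op
  rep3 <- evaluatePredictor(sc, co, subtype = "er_neg",
                            predictorTag = "x", cohortTag = "c")
  expect_equal(rep1@auc, rep3@auc)
  # tn filter restricts to the triple-negative subset
  rep4 <- evaluatePredictor(sc, co, subtype = "tn",
                            predictorTag = "x", cohortTag = "c")
  tn <- subtypeFlags(co, "tn")
  expect_equal(rep4@auc, computeAUC(sc[sampleIds(co)][tn], resp[tn]))
  expect_error(evaluatePredictor(sc, co, subtype = "nope"), "unknown subtype")
  expect_error(evaluatePredictor(unname(sc), co), "named")
})

test_that("a strongly informative score yields the expected report signs", {
  cfg <- tinyConfig(seed = 87, nGenes = 60, nPatients = 150, nDrugs = 1,
                    responseSlope = 3, hazardLogRatio = 1)
  sim <- simulateCellLinePanel(cfg)
  pat <- simulatePatientCohort(cfg, sim$truth)
  sc <- setNames(trueScores(pat$truth), sampleIds(pat$cohort))
  repT <- evaluatePredictor(sc, pat$cohort, predictorTag = "truth",
                            cohortTag = "sim")
  expect_gt(repT@auc, 0.7)
  expect_lt(repT@ranksumP, 1e-3)
  expect_lt(repT@logrankP, 0.05)
})
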