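# PC-regression drug models, rank percentiles, and the combination predictor

test_that("a rank-1 panel with activity along the factor is fit exactly", {
  set.seed(61)
  n <- 20
  f <- rnorm(n)
  load <- runif(8, 0.5, 1)
  m <- outer(load, f)                      # rank-1 genes x samples
  dimnames(m) <- list(paste0("g", 1:8), paste0("s", 1:n))
  panel <- ExpressionPanel(m)
  act <- setNames(2 * f + 1, paste0("s", 1:n))
  prof <- DrugActivityProfile("T", act)
  model <- fitDrugModel(panel, prof, paste0("g", 1:8))
  expect_identical(model@nComponents, 1L)
  pred <- scoreCohort(model, panel, standardize = "training")
  expect_equal(unname(pred), unname(act), tolerance = 1e-8)
})

test_that("full-component PC regression equals ordinary least squares", {
  set.seed(62)
  n <- 30; p <- 5
  m <- matrix(rnorm(p * n), p, n,
              dimnames = list(paste0("g", 1:p), paste0("s", 1:n)))
  act <- setNames(rnorm(n), paste0("s", 1:n))
  panel <- ExpressionPanel(m)
  prof <- DrugActivityProfile("T", act)
  model <- fitDrugModel(panel, prof, paste0("g", 1:p), nComponents = p)
  pred <- scoreCohort(model, panel, standardize = "training")
  z <- t(scale(t(m)))                      # standardized genes
  ols <- lm(act ~ t(z))
  expect_equal(unname(pred), unname(fitted(ols)), tolerance = 1e-8)
})

test_that("requesting more components than the rank warns and truncates", {
  set.seed(63)
  m <- matrix(rnorm(4 * 10), 4, 10,
              dimnames = list(paste0("g", 1:4), paste0("s", 1:10)))
  panel <- ExpressionPanel(m)
  prof <- DrugActivityProfile("T", setNames(rnorm(10), paste0("s", 1:10)))
  expect_warning(model <- fitDrugModel(panel, prof, paste0("g", 1:4),
                                       nComponents = 9),
                 "rank bound")
  expect_identical(model@nComponents, 4L)
  expect_error(fitDrugModel(panel, prof, c("g1", "nope")), "missing")
})

test_that("the default component rule matches a re-derived variance cumsum", {
  set.seed(64)
  cfg <- tinyConfig(seed = 64, nGenes = 60, nCellLines = 40, nDrugs = 1,
                    nSignatureGenesPerDrug = 8)
  sim <- simulateCellLinePanel(cfg)
  genes <- geneIds(sim$panel)[1:15]
  model <- fitDrugModel(sim$panel, sim$profiles[[1]], genes,
                        varianceThreshold = 0.8, maxComponents = 10)
  z <- t(scale(t(exprValues(sim$panel)[genes, sampleIds(sim$profiles[[1]])])))
  ev <- prcomp(t(z), center = FALSE)$sdev^2
  kExp <- min(min(which(cumsum(ev) / sum(ev) >= 0.8)), 10L)
  expect_identical(model@nComponents, as.integer(kExp))
})

test_that("training-standardized scoring is invariant to per-gene affine maps of the cohort only under cohort standardization", {
  set.seed(65)
  m <- matrix(rnorm(6 * 25), 6, 25,
              dimnames = list(paste0("g", 1:6), paste0("s", 1:25)))
  panel <- ExpressionPanel(m)
  prof <- DrugActivityProfile("T", setNames(rnorm(25), paste0("s", 1:25)))
  model <- fitDrugModel(panel, prof, paste0("g", 1:6))

  shifted <- ExpressionPanel(m * 2 + 5)    # per-cohort affine remap
  a <- scoreCohort(model, panel, standardize = "cohort")
  b <- scoreCohort(model, shifted, standardize = "cohort")
  expect_equal(a, b, tolerance = 1e-10)
  # training standardization is NOT invariant to such remapping
  d <- scoreCohort(model, shifted, standardize = "training")
  expect_false(isTRUE(all.equal(a, d, tolerance = 1e-6)))
})

test_that("held-out cohort scores track the planted true score", {
  cfg <- tinyConfig(seed = 66, nGenes = 150, nCellLines = 60, nPatients = 150,
                    nDrugs = 1, nSignatureGenesPerDrug = 15,
                    concordantFraction = 1)
  sim <- simulateCellLinePanel(cfg)
  pat <- simulatePatientCohort(cfg, sim$truth)
  genes <- signatureGenes(sim$truth)[[1]]
  model <- fitDrugModel(sim$panel, sim$profiles[[1]], genes)
  sc <- scoreCohort(model, pat$cohort)
  expect_gt(abs(cor(sc, trueScores(pat$truth))), 0.5)
})

test_that("rank percentile matches worked examples and invariants", {
  expect_equal(unname(toRankPercentile(c(5, 1, 3))), c(1, 0, 0.5))
  expect_equal(unname(toRankPercentile(c(2, 2, 4))), c(0.25, 0.25, 1))
  set.seed(67)
  x <- rnorm(50)
  p <- toRankPercentile(x)
  expect_equal(min(p), 0); expect_equal(max(p), 1)
  expect_equal(toRankPercentile(exp(x)), p)          # monotone invariance
  expect_equal(unname(sort(p)), (0:49) / 49)
  expect_warning(pt2 <- toRankPercentile(c(3, 3, 3)), "tied")
  expect_equal(unname(pt2), rep(0.5, 3))
  expect_error(toRankPercentile(1), "at least 2")
})

test_that("logistic combination reproduces glm and its formula at random settings", {
  set.seed(68)
  n <- 120
  m <- cbind(T = runif(n), A = runif(n))
  rownames(m) <- paste0("p", 1:n)
  y <- rbinom(n, 1, plogis(-1 + 1.5 * m[, "T"] + 0.5 * m[, "A"]))
  model <- fitCombination(m, y, mode = "logistic")
  expect_identical(model@mode, "logistic")
  ref <- glm(y ~ m[, "T"] + m[, "A"], family = binomial())
  expect_equal(model@intercept, unname(coef(ref)[1]), tolerance = 1e-8)
  expect_equal(unname(model@coefficients), unname(coef(ref)[-1]),
               tolerance = 1e-8)
  # direct formula check at 5 random points
  pred <- predictCombination(model, m)
  for (i in sample(n, 5)) {
    expect_equal(unname(pred[i]),
                 plogis(model@intercept +
                          sum(model@coefficients * m[i, names(model@coefficients)])),
                 tolerance = 1e-12)
  }
})

test_that("prediction is invariant to drug-column order and checks for missing drugs", {
  set.seed(69)
  m <- cbind(T = runif(40), A = runif(40))
  rownames(m) <- paste0("p", 1:40)
  y <- rbinom(40, 1, 0.4)
  model <- fitCombination(m, y, mode = "logistic")
  expect_equal(predictCombination(model, m),
               predictCombination(model, m[, c("A", "T")]))
  expect_error(predictCombination(model, m[, "T", drop = FALSE]),
               "missing drug")
})

test_that("equal-weight mode averages percentiles without touching labels", {
  m <- cbind(T = c(0, 0.5, 1), A = c(1, 0.5, 0))
  rownames(m) <- paste0("p", 1:3)
  model <- fitCombination(m, mode = "equal_weight")
  expect_equal(unname(predictCombination(model, m)), c(0.5, 0.5, 0.5))
})

test_that("complete separation triggers the equal-weight fallback", {
  m <- cbind(T = c(0.1, 0.2, 0.3, 0.7, 0.8, 0.9),
             A = c(0.2, 0.1, 0.3, 0.9, 0.8, 0.7))
  rownames(m) <- paste0("p", 1:6)
  y <- c(0, 0, 0, 1, 1, 1)                 # perfectly separated at 0.5
  expect_warning(model <- fitCombination(m, y, mode = "logistic"),
                 "separation")
  expect_identical(model@mode, "equal_weight")
  expect_equal(unname(predictCombination(model, m)), rowMeans(m),
               ignore_attr = TRUE)
  expect_error(fitCombination(m, rep(0, 6), mode = "logistic"),
               "both response classes")
})

test_that("drug models survive a JSON round-trip bit-exactly for scoring", {
  cfg <- tinyConfig(seed = 70, nGenes = 80, nCellLines = 40, nDrugs = 1,
                    nSignatureGenesPerDrug = 8)
  sim <- simulateCellLinePanel(cfg)
  genes <- signatureGenes(sim$truth)[[1]]
  model <- fitDrugModel(sim$panel, sim$profiles[[1]], genes)
  path <- tempfile(fileext = ".json")
  writeDrugModel(model, path)
  back <- readDrugModel(path)
  expect_identical(back@genes, model@genes)
  expect_identical(back@nComponents, model@nComponents)
  a <- scoreCohort(model, sim$panel)
  b <- scoreCohort(back, sim$panel)
  expect_equal(a, b, tolerance = 1e-10)
})
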