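# the five association statistics and the candidate ranking

test_that("pearson association matches exact and brute-force cases", {
  expect_equal(pearsonAssociation(c(1, 2, 3, 4), c(2, 4, 6, 8))@statistic, 1)
  expect_equal(pearsonAssociation(c(1, 2, 3, 4), c(8, 6, 4, 2))@statistic, -1)

  x <- c(1, 2, 3, 4, 5); y <- c(1, 3, 2, 5, 4)
  # direct covariance-formula oracle
  n <- 5
  rExp <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  tExp <- rExp * sqrt((n - 2) / (1 - rExp^2))
  pExp <- 2 * pt(-abs(tExp), n - 2)
  res <- pearsonAssociation(x, y)
  expect_equal(res@statistic, rExp)
  expect_equal(res@pValue, pExp)
  expect_equal(res@direction, sign(rExp))

  expect_error(pearsonAssociation(rep(1, 5), 1:5), "degenerate")
  expect_error(pearsonAssociation(1:4, 1:5), "alignment")
})

test_that("spearman uses midranks and reduces to pearson on tieless ranks", {
  expect_equal(spearmanAssociation(c(1, 5, 9), c(2, 3, 10))@statistic, 1)
  expect_equal(spearmanAssociation(c(1, 2, 3), c(3, 1, 2))@statistic, -0.5)

  # midrank oracle for ties: (1,1,2,3) -> (1.5, 1.5, 3, 4)
  x <- c(1, 1, 2, 3); y <- c(1, 2, 3, 4)
  rx <- c(1.5, 1.5, 3, 4); ry <- c(1, 2, 3, 4)
  rExp <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  expect_equal(spearmanAssociation(x, y)@statistic, rExp)

  # on data that already are tieless ranks the two statistics coincide
  set.seed(1)
  for (i in 1:5) {
    a <- sample(1:12); b <- sample(1:12)
    expect_identical(pearsonAssociation(a, b)@statistic,
                     spearmanAssociation(a, b)@statistic)
    expect_identical(pearsonAssociation(a, b)@pValue,
                     spearmanAssociation(a, b)@pValue)
  }
})

test_that("welch t matches the hand-evaluated formula and boundary rules", {
  # identical expression in both groups
  res <- welchTAssociation(c(5, 5, 5, 5), c(1, 2, 9, 10))
  expect_equal(res@statistic, 0)
  expect_equal(res@pValue, 1)

  # groups {1,2} vs {9,10} after the median-5.5 split
  x <- c(1, 2, 9, 10); a <- c(1, 2, 9, 10)
  m1 <- mean(c(9, 10)); m0 <- mean(c(1, 2))
  v1 <- var(c(9, 10)); v0 <- var(c(1, 2))
  tExp <- (m1 - m0) / sqrt(v1 / 2 + v0 / 2)
  dfExp <- (v1 / 2 + v0 / 2)^2 / ((v1 / 2)^2 / 1 + (v0 / 2)^2 / 1)
  res <- welchTAssociation(x, a)
  expect_equal(res@statistic, tExp)
  expect_equal(res@pValue, 2 * pt(-abs(tExp), dfExp))

  # odd n: the median-valued sample goes to the resistant group
  a5 <- c(1, 2, 3, 4, 5)  # median 3 -> sensitive {4,5}, resistant {1,2,3}
  x5 <- c(0, 0, 1, 10, 10)
  tt <- t.test(x5[a5 > 3], x5[a5 <= 3])
  expect_equal(welchTAssociation(x5, a5)@statistic, unname(tt$statistic))

  expect_error(welchTAssociation(1:4, rep(2, 4)), "degenerate split")
})

test_that("ancova recovers a noiseless slope exactly and handles collinearity", {
  set.seed(2)
  tissue <- factor(rep(c("a", "b", "c"), each = 8))
  x <- rnorm(24)
  offs <- c(a = 0, b = 2, c = -1)
  act <- 2 * x + offs[tissue]
  res <- ancovaAssociation(x, act, tissue)
  expect_equal(res@estimate, 2, tolerance = 1e-10)
  expect_lt(res@pValue, 1e-10)

  # expression equal to a tissue indicator is rank-deficient
  xcol <- as.numeric(tissue == "a")
  expect_error(ancovaAssociation(xcol, act, tissue), "collinearity")
})

test_that("single-tissue ancova reproduces simple-regression (pearson) inference", {
  set.seed(3)
  x <- rnorm(40); act <- 0.5 * x + rnorm(40)
  one <- factor(rep("t", 40))
  res <- ancovaAssociation(x, act, one)
  pear <- pearsonAssociation(x, act)
  expect_equal(res@pValue, pear@pValue, tolerance = 1e-10)
  fit <- lm(act ~ x)
  expect_equal(res@statistic, summary(fit)$coefficients["x", "t value"],
               tolerance = 1e-10)
})

test_that("rank ancova beats raw ancova on monotone nonlinear signal", {
  set.seed(4)
  x <- rnorm(30)
  act <- exp(2 * x)  # strictly monotone, very non-linear
  one <- factor(rep("t", 30))
  raw <- ancovaAssociation(x, act, one)
  rk <- rankAncovaAssociation(x, act, one)
  expect_gte(abs(rk@statistic), abs(raw@statistic))
  # linear noiseless case at n = 30
  lin <- rankAncovaAssociation(x, 3 * x, one)
  expect_gt(lin@statistic, 0)
  expect_lt(lin@pValue, 1e-3)
  expect_error(rankAncovaAssociation(x, rep(1, 30), one), "tied")
})

test_that("ancova slope is null-calibrated when only tissues shift activity", {
  set.seed(5)
  pvals <- replicate(400, {
    tissue <- factor(rep(c("a", "b"), each = 10))
    x <- rnorm(20)
    act <- ifelse(tissue == "a", 0, 3) + rnorm(20)
    ancovaAssociation(x, act, tissue)@pValue
  })
  expect_gt(ks.test(pvals, "punif")$p.value, 0.01)
  expect_lt(abs(mean(pvals < 0.05) - 0.05), 0.03)
})

test_that("rankCandidates finds dominant signal, breaks ties deterministically, and is order-invariant", {
  set.seed(6)
  n <- 30
  act <- rnorm(n)
  m <- matrix(rnorm(20 * n), 20, n,
              dimnames = list(sprintf("g%02d", 1:20), paste0("s", 1:n)))
  m["g07", ] <- act                    # noiseless copy of activity
  m["g15", ] <- m["g03", ]             # exact duplicate pair
  panel <- ExpressionPanel(m)
  prof <- DrugActivityProfile("T", setNames(act, paste0("s", 1:n)))
  res <- rankCandidates(panel, prof, "pearson", topK = 20)
  expect_identical(res$gene[1], "g07")
  i3 <- which(res$gene == "g03"); i15 <- which(res$gene == "g15")
  expect_equal(abs(i3 - i15), 1L)
  expect_lt(i3, i15)  # gene-ID tie-breaker

  # permuting gene rows does not change the ranking
  perm <- sample(nrow(m))
  res2 <- rankCandidates(ExpressionPanel(m[perm, ]), prof, "pearson",
                         topK = 20)
  expect_identical(as.data.frame(res), as.data.frame(res2))
})

test_that("rankCandidates skips degenerate and mostly-missing genes with a warning", {
  set.seed(7)
  n <- 20
  act <- rnorm(n)
  m <- matrix(rnorm(10 * n), 10, n,
              dimnames = list(sprintf("g%02d", 1:10), paste0("s", 1:n)))
  m["g02", ] <- 7                       # zero variance
  m["g05", 1:10] <- NA                  # only 50% present, below the 80% rule
  panel <- ExpressionPanel(m)
  prof <- DrugActivityProfile("T", setNames(act, paste0("s", 1:n)))
  expect_warning(res <- rankCandidates(panel, prof, "pearson", topK = 8),
                 "skipped")
  expect_false(any(c("g02", "g05") %in% res$gene))
  expect_error(rankCandidates(panel, prof, "pearson", topK = 0), "positive")
  expect_error(rankCandidates(panel, prof, "not_a_method"))
})

test_that("planted signature genes are recovered near the top of the ranking", {
  hits <- vapply(1:3, function(s) {
    cfg <- tinyConfig(seed = s, nGenes = 200, nCellLines = 60, nDrugs = 1,
                      nSignatureGenesPerDrug = 10, signatureEffect = 0.6)
    sim <- simulateCellLinePanel(cfg)
    res <- rankCandidates(sim$panel, sim$profiles[[1]], "pearson",
                          tissue = sim$tissue, topK = 40)
    mean(signatureGenes(sim$truth)[[1]] %in% res$gene)
  }, numeric(1))
  expect_gte(mean(hits), 0.8)
})

test_that("all five methods hold their size on an iid null panel", {
  # iid genes so the 2000 tests are independent: under H0 the rejection
  # rate at alpha = 0.05 has SE ~ 0.005, so [0.03, 0.07] is a 4-SE band
  rej <- sapply(c("pearson", "spearman", "welch_t", "ancova", "rank_ancova"),
                function(meth) {
    ps <- unlist(lapply(1:5, function(s) {
      panel <- randomPanel(400, 60, seed = 100 + s)
      set.seed(500 + s)
      act <- rnorm(60)
      names(act) <- sampleIds(panel)
      tis <- factor(rep(c("a", "b", "c"), each = 20))
      names(tis) <- sampleIds(panel)
      prof <- DrugActivityProfile("T", act)
      rankCandidates(panel, prof, meth, tissue = tis, topK = 400)$pValue
    }))
    mean(ps < 0.05)
  })
  expect_true(all(rej > 0.03 & rej < 0.07))
})
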