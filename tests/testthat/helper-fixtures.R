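# shared fixtures, all generated in code

# a desk-scale configuration for module tests (not the study defaults)
tinyConfig <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(nGenes = 60, nCellLines = 30, nPatients = 50,
         nSignatureGenesPerDrug = 5, nDrugs = 2, seed = seed),
    list(...))
  do.call(simulationConfig, args)
}

# iid standard-normal panel (no coexpression structure)
randomPanel <- function(nGenes, nSamples, seed, prefix = "s") {
  set.seed(seed)
  m <- matrix(rnorm(nGenes * nSamples), nGenes, nSamples,
              dimnames = list(sprintf("g%03d", seq_len(nGenes)),
                              paste0(prefix, seq_len(nSamples))))
  ExpressionPanel(m)
}

# independent all-pairs AUC oracle
aucBruteForce <- function(scores, labels01) {
  sp <- scores[labels01 == 1]; sn <- scores[labels01 == 0]
  tot <- 0
  for (a in sp) for (b in sn) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(sp) * length(sn))
}

# independent exact rank-sum oracle: full enumeration of group assignments,
# two-sided p mirroring 2 * min(P(U <= u), P(U >= u)) capped at 1
ranksumEnumOracle <- function(x, y) {
  s <- c(x, y); n1 <- length(x); n <- length(s)
  r <- rank(s)
  uObs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combos <- utils::combn(n, n1)
  us <- apply(combos, 2L, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  pLow <- mean(us <= uObs); pHigh <- mean(us >= uObs)
  min(1, 2 * min(pLow, pHigh))
}

# independent two-group log-rank oracle: O - E over distinct event times with
# hypergeometric variance
logrankOracle <- function(times, events, groups) {
  groups <- as.factor(groups)
  lv <- levels(groups)
  ts <- sort(unique(times[events == 1]))
  oe <- 0; v <- 0; o <- 0
  for (t in ts) {
    atRisk <- times >= t
    n <- sum(atRisk)
    n1 <- sum(atRisk & groups == lv[1])
    d <- sum(times == t & events == 1)
    d1 <- sum(times == t & events == 1 & groups == lv[1])
    o <- o + d1
    oe <- oe + d1 - d * n1 / n
    if (n > 1) v <- v + d * (n - d) * n1 * (n - n1) / (n^2 * (n - 1))
  }
  chisq <- oe^2 / v
  list(statistic = chisq, p.value = pchisq(chisq, 1, lower.tail = FALSE))
}
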