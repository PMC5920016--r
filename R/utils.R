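# internal helpers

# midranks (average ranks for ties), NA kept
.midrank <- function(x) rank(x, ties.method = "average", na.last = "keep")

# derive a child RNG seed from the master seed; stays below 2^31 - 1
.deriveSeed <- function(seed, offset) {
  as.integer((as.numeric(seed) + 7919 * as.numeric(offset)) %% 2147483647)
}

# row-standardize a matrix to sample mean 0 / sd 1; errors on zero-variance rows
.standardizeRows <- function(m) {
  mu <- rowMeans(m)
  s <- sqrt(rowSums((m - mu)^2) / (ncol(m) - 1L))
  if (any(s == 0))
    stop("zero-variance rows: ", paste(utils::head(rownames(m)[s == 0], 5),
                                       collapse = ", "))
  (m - mu) / s
}

# two-sided p for a Pearson r via the t transform; exact under the fixed-design
# normal null
.pearsonCore <- function(x, y) {
  n <- length(x)
  if (n < 3L) stop("need at least 3 aligned observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero-variance input")
  r <- stats::cor(x, y)
  r <- max(min(r, 1), -1)
  if (abs(r) >= 1 - 1e-15) {
    tstat <- sign(r) * Inf
    p <- 0
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(r = r, t = tstat, p = p, n = n)
}

# align a profile's samples onto a panel's columns; returns column indices
.alignSamples <- function(panel, profile) {
  idx <- match(sampleIds(profile), sampleIds(panel))
  if (anyNA(idx))
    stop("alignment error: profile samples absent from panel: ",
         paste(utils::head(sampleIds(profile)[is.na(idx)], 5), collapse = ", "))
  idx
}

`%||%` <- function(a, b) if (is.null(a)) b else a
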