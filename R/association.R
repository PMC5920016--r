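# Gene-by-gene association between expression and drug activity.
#
# Five alternative statistics, mirroring the screening toolbox compared on
# the cell-line panels: Pearson, Spearman, Welch t on a median-GI50
# sensitive/resistant split, ANCOVA with histology as covariate, and
# rank-based ANCOVA.

.assocMethods <- c("pearson", "spearman", "welch_t", "ancova", "rank_ancova")

#' Single-gene association result
#'
#' @slot gene gene ID.
#' @slot method one of `pearson`, `spearman`, `welch_t`, `ancova`,
#'   `rank_ancova`.
#' @slot statistic correlation r, Welch t, or ANCOVA slope t.
#' @slot pValue two-sided p-value.
#' @slot estimate effect estimate on the method's native scale: the
#'   correlation for `pearson`/`spearman`, the sensitive-minus-resistant mean
#'   difference for `welch_t`, the expression slope for the ANCOVA methods.
#' @slot direction sign of the association.
#' @export
setClass("GeneAssociation",
         representation(gene = "character", method = "character",
                        statistic = "numeric", pValue = "numeric",
                        estimate = "numeric", direction = "numeric"))

setValidity("GeneAssociation", function(object) {
  msg <- character()
  if (!object@method %in% .assocMethods)
    msg <- c(msg, "unknown method")
  if (!is.na(object@pValue) && (object@pValue < 0 || object@pValue > 1))
    msg <- c(msg, "p-value must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

setMethod("show", "GeneAssociation", function(object) {
  cat(sprintf("GeneAssociation [%s] %s: statistic=%.4g p=%.4g\n",
              object@method, object@gene, object@statistic, object@pValue))
})

.newAssoc <- function(gene, method, statistic, pValue, estimate = statistic) {
  methods::new("GeneAssociation", gene = as.character(gene), method = method,
               statistic = statistic, pValue = pValue, estimate = estimate,
               direction = sign(statistic))
}

.checkAligned <- function(expression, activity, gene) {
  if (length(expression) != length(activity))
    stop("alignment error for gene ", gene,
         ": expression and activity lengths differ")
}

#' Pearson correlation association
#'
#' Statistic is the sample Pearson r; the two-sided p-value comes from the
#' t transform `r * sqrt((n - 2) / (1 - r^2))` on `n - 2` df.
#'
#' @param expression,activity aligned numeric vectors (length >= 3, nonzero
#'   variance).
#' @param gene gene ID used in the result and error messages.
#' @return A [GeneAssociation-class].
#' @examples
#' pearsonAssociation(c(1, 2, 3, 4), c(2, 4, 6, 8))
#' @export
pearsonAssociation <- function(expression, activity, gene = "gene") {
  .checkAligned(expression, activity, gene)
  res <- tryCatch(.pearsonCore(expression, activity), error = function(e)
    stop("degenerate input for gene ", gene, ": ", conditionMessage(e)))
  .newAssoc(gene, "pearson", res$r, res$p)
}

#' Spearman rank correlation association
#'
#' Pearson machinery applied to midranks (average ranks for ties).
#'
#' @inheritParams pearsonAssociation
#' @return A [GeneAssociation-class].
#' @export
spearmanAssociation <- function(expression, activity, gene = "gene") {
  .checkAligned(expression, activity, gene)
  rx <- .midrank(expression); ry <- .midrank(activity)
  res <- tryCatch(.pearsonCore(rx, ry), error = function(e)
    stop("degenerate input for gene ", gene, ": ", conditionMessage(e)))
  .newAssoc(gene, "spearman", res$r, res$p)
}

#' Welch two-sample t association on the median-activity split
#'
#' Cell lines with activity strictly above the median form the sensitive
#' group; the rest (including median-valued lines) are resistant. The Welch
#' t statistic (unequal variances, Welch-Satterthwaite df) compares gene
#' expression between the groups; its sign is sensitive minus resistant.
#'
#' @inheritParams pearsonAssociation
#' @return A [GeneAssociation-class].
#' @export
welchTAssociation <- function(expression, activity, gene = "gene") {
  .checkAligned(expression, activity, gene)
  if (length(activity) < 4L) stop("need at least 4 observations")
  sens <- activity > stats::median(activity)
  if (!any(sens) || all(sens))
    stop("degenerate split for gene ", gene,
         ": one group empty at the median cutoff")
  xs <- expression[sens]; xr <- expression[!sens]
  diff <- mean(xs) - mean(xr)
  if (stats::var(xs) == 0 && stats::var(xr) == 0) {
    if (diff == 0) return(.newAssoc(gene, "welch_t", 0, 1, 0))
    return(.newAssoc(gene, "welch_t", sign(diff) * Inf, 0, diff))
  }
  tt <- stats::t.test(xs, xr, var.equal = FALSE)
  .newAssoc(gene, "welch_t", unname(tt$statistic), tt$p.value, diff)
}

.ancovaFit <- function(expression, activity, tissue, gene, method) {
  tissue <- droplevels(as.factor(tissue))
  if (nlevels(tissue) > 1L) {
    tab <- table(tissue)
    if (any(tab < 2L))
      stop("each tissue level needs at least 2 samples (gene ", gene, ")")
    if (length(activity) <= nlevels(tissue) + 2L)
      stop("too few samples for the ANCOVA design (gene ", gene, ")")
    mm <- stats::model.matrix(~ expression + tissue)
  } else {
    mm <- stats::model.matrix(~ expression)
  }
  if (qr(mm)$rank < ncol(mm))
    stop("collinearity error: expression collinear with tissue indicators ",
         "(gene ", gene, ")")
  fit <- stats::lm.fit(mm, activity)
  rdf <- fit$df.residual
  if (rdf < 1L) stop("no residual degrees of freedom (gene ", gene, ")")
  sigma2 <- sum(fit$residuals^2) / rdf
  xtxInv <- chol2inv(qr.R(fit$qr))
  pos <- which(fit$qr$pivot == 2L)  # the expression column
  seBeta <- sqrt(sigma2 * xtxInv[pos, pos])
  beta <- fit$coefficients[["expression"]]
  if (seBeta == 0) {
    tstat <- sign(beta) * Inf
    p <- if (beta == 0) 1 else 0
  } else {
    tstat <- beta / seBeta
    p <- 2 * stats::pt(-abs(tstat), rdf)
  }
  .newAssoc(gene, method, tstat, p, beta)
}

#' ANCOVA association with tissue covariate
#'
#' Least-squares fit of activity on gene expression plus tissue-level
#' offsets; the statistic is the t of the expression slope, accounting for
#' histology differences in overall drug activity. With a single tissue level
#' this reduces to the simple-regression slope test.
#'
#' @inheritParams pearsonAssociation
#' @param tissue factor of histology labels aligned with the samples.
#' @return A [GeneAssociation-class].
#' @export
ancovaAssociation <- function(expression, activity, tissue, gene = "gene") {
  .checkAligned(expression, activity, gene)
  if (length(tissue) != length(activity))
    stop("alignment error: tissue labels must match samples")
  if (stats::sd(expression) == 0)
    stop("degenerate input for gene ", gene, ": zero-variance expression")
  .ancovaFit(expression, activity, tissue, gene, "ancova")
}

#' Rank-based ANCOVA association
#'
#' Identical to [ancovaAssociation()] after replacing expression and activity
#' each by their midranks across samples; robust to monotone nonlinearity.
#'
#' @inheritParams ancovaAssociation
#' @return A [GeneAssociation-class].
#' @export
rankAncovaAssociation <- function(expression, activity, tissue,
                                  gene = "gene") {
  .checkAligned(expression, activity, gene)
  rx <- .midrank(expression); ry <- .midrank(activity)
  if (stats::sd(rx) == 0)
    stop("degenerate input for gene ", gene, ": zero-variance expression ranks")
  if (stats::sd(ry) == 0)
    stop("degenerate input for gene ", gene, ": all activity values tied")
  .ancovaFit(rx, ry, tissue, gene, "rank_ancova")
}

#' Rank candidate genes by association with drug activity
#'
#' Applies the chosen statistic to every gene of the panel against the
#' aligned activity profile, then sorts ascending by p-value with descending
#' |statistic| and finally gene ID as deterministic tie-breakers. Genes with
#' fewer than 80 percent non-missing samples, or raising degenerate-input errors,
#' are skipped with a consolidated warning. Ranking is by raw p-value (no
#' multiplicity correction): downstream selection is by rank, not threshold.
#'
#' @param panel an [ExpressionPanel].
#' @param profile a [DrugActivityProfile] whose samples are a subset of the
#'   panel's.
#' @param method one of `"pearson"`, `"spearman"`, `"welch_t"`, `"ancova"`,
#'   `"rank_ancova"`.
#' @param tissue optional histology factor named by (or aligned with) the
#'   profile samples; required by the ANCOVA methods.
#' @param topK number of top genes to return (default 500).
#' @return A [S4Vectors::DataFrame] with columns `gene`, `method`,
#'   `statistic`, `pValue`, `direction`, `rank`; metadata records the drug,
#'   the method and the skipped-gene count.
#' @examples
#' sim <- simulateCellLinePanel(simulationConfig(nGenes = 60, seed = 3))
#' head(rankCandidates(sim$panel, sim$profiles[[1]], "pearson", topK = 10))
#' @export
rankCandidates <- function(panel, profile, method = "pearson", tissue = NULL,
                           topK = 500L) {
  method <- match.arg(method, .assocMethods)
  topK <- as.integer(topK)
  if (topK <= 0L) stop("topK must be positive")
  idx <- .alignSamples(panel, profile)
  x <- exprValues(panel)[, idx, drop = FALSE]
  act <- activityValues(profile)
  if (!is.null(tissue)) {
    if (!is.null(names(tissue))) tissue <- tissue[sampleIds(profile)]
    if (length(tissue) != length(act))
      stop("tissue labels must align with the profile samples")
    tissue <- droplevels(as.factor(tissue))
  } else if (method %in% c("ancova", "rank_ancova")) {
    tissue <- factor(rep("all", length(act)))
  }
  genes <- rownames(x)
  if (topK > length(genes)) stop("topK exceeds the number of genes")

  resGene <- character(); resStat <- numeric(); resP <- numeric()
  nSkipped <- 0L
  for (i in seq_along(genes)) {
    xi <- x[i, ]
    keep <- !is.na(xi)
    if (mean(keep) < 0.8) { nSkipped <- nSkipped + 1L; next }
    a <- act[keep]; xi <- xi[keep]
    ti <- if (!is.null(tissue)) droplevels(tissue[keep]) else NULL
    r <- tryCatch(switch(method,
      pearson = pearsonAssociation(xi, a, genes[i]),
      spearman = spearmanAssociation(xi, a, genes[i]),
      welch_t = welchTAssociation(xi, a, genes[i]),
      ancova = ancovaAssociation(xi, a, ti, genes[i]),
      rank_ancova = rankAncovaAssociation(xi, a, ti, genes[i])),
      error = function(e) NULL)
    if (is.null(r)) { nSkipped <- nSkipped + 1L; next }
    resGene <- c(resGene, r@gene)
    resStat <- c(resStat, r@statistic)
    resP <- c(resP, r@pValue)
  }
  if (nSkipped > 0L)
    warning(nSkipped, " gene(s) skipped (missingness or degenerate input)")
  if (length(resGene) < topK)
    stop("fewer testable genes (", length(resGene), ") than topK")
  ord <- order(resP, -abs(resStat), resGene)
  sel <- ord[seq_len(topK)]
  out <- S4Vectors::DataFrame(gene = resGene[sel], method = method,
                              statistic = resStat[sel], pValue = resP[sel],
                              direction = sign(resStat[sel]),
                              rank = seq_len(topK))
  S4Vectors::metadata(out) <- list(drug = drugName(profile), method = method,
                                   nTested = length(resGene),
                                   nSkipped = nSkipped)
  out
}
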