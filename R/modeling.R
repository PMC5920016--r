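# Per-drug principal-component regression chemosensitivity models, trained
# strictly in vitro, plus rank-percentile conversion and the combination
# predictor over per-drug percentile scores.

#' Fit a per-drug principal-component regression model
#'
#' Biomarker genes are standardized on the training cell lines, PCA is run on
#' the standardized genes x samples submatrix, and activity is regressed by
#' least squares on the leading components. The default component rule keeps
#' the smallest number of PCs explaining at least `varianceThreshold` of the
#' biomarker-set variance, capped at `maxComponents`; an explicit
#' `nComponents` overrides it (reduced with a warning if it exceeds the
#' rank). The fit never sees patient data: the signature takes only a
#' cell-line panel and activity profile.
#'
#' @param panel training [ExpressionPanel] (cell lines).
#' @param profile [DrugActivityProfile] aligned to the panel.
#' @param biomarkers a [BiomarkerSet-class] (or character vector of genes).
#' @param nComponents optional explicit number of components.
#' @param varianceThreshold cumulative variance target for the default rule
#'   (default 0.8).
#' @param maxComponents cap for the default rule (default 10).
#' @return A self-contained [DrugModel-class].
#' @examples
#' sim <- simulateCellLinePanel(simulationConfig(nGenes = 60, seed = 6))
#' genes <- signatureGenes(sim$truth)[[1]]
#' fitDrugModel(sim$panel, sim$profiles[[1]], genes)
#' @export
fitDrugModel <- function(panel, profile, biomarkers, nComponents = NULL,
                         varianceThreshold = 0.8, maxComponents = 10L) {
  genes <- if (methods::is(biomarkers, "BiomarkerSet"))
    biomarkerGenes(biomarkers) else as.character(biomarkers)
  methodTag <- if (methods::is(biomarkers, "BiomarkerSet"))
    biomarkers@metadata$method %||% "unknown" else "unknown"
  drug <- if (methods::is(biomarkers, "BiomarkerSet")) drugName(biomarkers)
  else drugName(profile)
  missing <- setdiff(genes, geneIds(panel))
  if (length(missing))
    stop("fit error: biomarker genes missing from panel: ",
         paste(utils::head(missing, 10), collapse = ", "))
  idx <- .alignSamples(panel, profile)
  x <- exprValues(panel)[genes, idx, drop = FALSE]
  act <- unname(activityValues(profile))
  n <- ncol(x)
  mu <- rowMeans(x)
  sdv <- sqrt(rowSums((x - mu)^2) / (n - 1L))
  if (any(sdv == 0))
    stop("fit error: zero-variance biomarker genes: ",
         paste(genes[sdv == 0], collapse = ", "))
  z <- (x - mu) / sdv

  pc <- stats::prcomp(t(z), center = FALSE)
  effRank <- sum(pc$sdev > max(pc$sdev) * 1e-8)
  maxK <- min(length(genes), n - 1L, effRank)
  if (is.null(nComponents)) {
    varExp <- cumsum(pc$sdev^2) / sum(pc$sdev^2)
    k <- min(which(varExp >= varianceThreshold))
    k <- min(k, as.integer(maxComponents), maxK)
  } else {
    k <- as.integer(nComponents)
    if (k > maxK) {
      warning("nComponents reduced from ", k, " to the rank bound ", maxK)
      k <- maxK
    }
  }
  k <- max(k, 1L)
  scores <- pc$x[, seq_len(k), drop = FALSE]
  fit <- stats::lm(act ~ scores)
  beta <- stats::coef(fit)
  methods::new("DrugModel", drug = drug, genes = genes,
               center = unname(mu), scale = unname(sdv),
               loadings = unname(pc$rotation[, seq_len(k), drop = FALSE]),
               nComponents = k, intercept = unname(beta[1L]),
               coefficients = unname(beta[-1L]),
               trainingTag = paste0("cells_n", n), methodTag = methodTag)
}

#' Score a cohort with a trained drug model
#'
#' The raw prediction score is a fixed linear combination of standardized
#' biomarker expression projected on the model's PC loadings. By default the
#' genes are re-standardized within the scored cohort (cell lines and tumors
#' are different systems with incomparable location/scale); `"training"`
#' applies the stored training means/sds instead. Up to 10 percent of model genes
#' may be absent from the cohort; they are mean-imputed (zero after
#' standardization) with a warning.
#'
#' @param model a [DrugModel-class].
#' @param panel cohort [ExpressionPanel] (or [PatientCohort]).
#' @param standardize `"cohort"` (default) or `"training"`.
#' @return Named numeric vector of raw scores (one per cohort sample);
#'   higher = predicted more sensitive.
#' @export
scoreCohort <- function(model, panel, standardize = c("cohort", "training")) {
  standardize <- match.arg(standardize)
  genes <- model@genes
  present <- genes %in% geneIds(panel)
  fracMissing <- mean(!present)
  if (fracMissing > 0.10)
    stop("scoring error: ", sum(!present), " of ", length(genes),
         " model genes missing from cohort (> 10%)")
  if (fracMissing > 0)
    warning(sum(!present), " model gene(s) missing from cohort; ",
            "mean-imputed (zero after standardization)")
  x <- exprValues(panel)[genes[present], , drop = FALSE]
  if (standardize == "cohort") {
    mu <- rowMeans(x)
    sdv <- sqrt(rowSums((x - mu)^2) / (ncol(x) - 1L))
    if (any(sdv == 0)) {
      warning("zero-variance cohort gene(s) set to 0 after standardization: ",
              paste(rownames(x)[sdv == 0], collapse = ", "))
      sdv[sdv == 0] <- 1
    }
    z <- (x - mu) / sdv
  } else {
    z <- (x - model@center[present]) / model@scale[present]
  }
  load <- model@loadings[present, , drop = FALSE]
  raw <- drop(model@intercept + t(z) %*% load %*% model@coefficients)
  setNames(raw, sampleIds(panel))
}

#' Convert raw scores to rank percentiles in [0, 1]
#'
#' `percentile = (rank - 1) / (n - 1)` with midranks for ties: the minimum
#' maps to 0 and the maximum to 1, and the output is invariant under any
#' strictly monotone transform of the input. If every value is tied the
#' percentiles are all 0.5 (with a warning).
#'
#' @param raw numeric vector of raw scores, length >= 2.
#' @return Numeric vector of percentiles, names preserved.
#' @examples
#' toRankPercentile(c(5, 1, 3))   # 1.0 0.0 0.5
#' toRankPercentile(c(2, 2, 4))   # 0.25 0.25 1.00
#' @export
toRankPercentile <- function(raw) {
  n <- length(raw)
  if (n < 2L) stop("need at least 2 scores")
  if (length(unique(raw)) == 1L) {
    warning("all raw scores tied; percentiles set to 0.5")
    return(setNames(rep(0.5, n), names(raw)))
  }
  setNames((.midrank(raw) - 1) / (n - 1), names(raw))
}

.asPercentileMatrix <- function(percentiles) {
  if (is.list(percentiles) && !is.data.frame(percentiles)) {
    lens <- lengths(percentiles)
    if (length(unique(lens)) != 1L)
      stop("per-drug percentile vectors have unequal lengths")
    percentiles <- do.call(cbind, percentiles)
  }
  m <- as.matrix(percentiles)
  if (is.null(colnames(m))) stop("percentile columns must be named by drug")
  storage.mode(m) <- "double"
  m
}

#' Fit a combination-chemotherapy predictor
#'
#' Logistic mode runs a maximum-likelihood logistic regression of pCR on the
#' per-drug percentile scores, main effects only (drug-drug interaction terms
#' are deliberately excluded). Equal-weight mode does no fitting: the
#' combined score is the mean percentile, reflecting the
#' independent-compound assumption with no response labels needed. On
#' complete separation the logistic fit falls back to equal weights with a
#' warning.
#'
#' @param percentiles samples x drugs matrix (or named list of per-drug
#'   percentile vectors).
#' @param response binary response: a factor with levels `RD`/`pCR`, logical,
#'   or 0/1 (1 = pCR). Required in logistic mode.
#' @param mode `"logistic"` (default) or `"equal_weight"`.
#' @param cohortTag provenance string stored in the model.
#' @return A [CombinationModel-class].
#' @export
fitCombination <- function(percentiles, response = NULL,
                           mode = c("logistic", "equal_weight"),
                           cohortTag = "unspecified") {
  mode <- match.arg(mode)
  m <- .asPercentileMatrix(percentiles)
  drugs <- colnames(m)
  if (mode == "equal_weight")
    return(methods::new("CombinationModel", drugs = drugs,
                        mode = "equal_weight", intercept = numeric(),
                        coefficients = numeric(), cohortTag = cohortTag))
  if (is.null(response)) stop("logistic mode requires response labels")
  y <- if (is.factor(response)) as.integer(response == "pCR")
  else as.integer(as.logical(as.numeric(response)))
  keep <- !is.na(y)
  if (any(!keep))
    message(sum(!keep), " patients with missing response dropped from the fit")
  y <- y[keep]; mm <- m[keep, , drop = FALSE]
  if (length(unique(y)) < 2L)
    stop("fit error: both response classes must be present")
  separated <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ mm, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        separated <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (separated || !fit$converged || max(abs(stats::coef(fit))) > 1e3) {
    warning("complete separation in the logistic fit; ",
            "falling back to equal weights")
    return(methods::new("CombinationModel", drugs = drugs,
                        mode = "equal_weight", intercept = numeric(),
                        coefficients = numeric(), cohortTag = cohortTag))
  }
  beta <- stats::coef(fit)
  methods::new("CombinationModel", drugs = drugs, mode = "logistic",
               intercept = unname(beta[1L]),
               coefficients = setNames(unname(beta[-1L]), drugs),
               cohortTag = cohortTag)
}

#' Predict combined scores for new patients
#'
#' Logistic mode returns fitted pCR probabilities; equal-weight mode returns
#' the mean percentile. Either way the output lies in `[0, 1]`, with higher
#' values meaning predicted more sensitive, and is invariant to the ordering
#' of the drug columns supplied.
#'
#' @param model a [CombinationModel-class].
#' @param percentiles samples x drugs matrix or named list; must contain
#'   every model drug.
#' @return Numeric vector of combined scores.
#' @export
predictCombination <- function(model, percentiles) {
  m <- .asPercentileMatrix(percentiles)
  missing <- setdiff(model@drugs, colnames(m))
  if (length(missing))
    stop("prediction error: missing drug percentile(s): ",
         paste(missing, collapse = ", "))
  m <- m[, model@drugs, drop = FALSE]
  out <- if (model@mode == "logistic")
    stats::plogis(model@intercept + drop(m %*% model@coefficients))
  else rowMeans(m)
  setNames(out, rownames(m))
}
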