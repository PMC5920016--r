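#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

# ---------------------------------------------------------------------------
# ExpressionPanel
# ---------------------------------------------------------------------------

#' Gene-by-sample expression panel
#'
#' Thin wrapper around [SummarizedExperiment::SummarizedExperiment] holding a
#' single `exprs` assay of log-scale expression values. Gene and sample IDs
#' must be unique; values must be finite or `NA`.
#'
#' @export
setClass("ExpressionPanel", contains = "SummarizedExperiment")

setValidity("ExpressionPanel", function(object) {
  msg <- character()
  if (!"exprs" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "panel must carry an 'exprs' assay")
  g <- rownames(object); s <- colnames(object)
  if (is.null(g) || anyDuplicated(g))
    msg <- c(msg, "gene IDs must be present and unique")
  if (is.null(s) || anyDuplicated(s))
    msg <- c(msg, "sample IDs must be present and unique")
  if (length(msg) == 0L) {
    v <- SummarizedExperiment::assay(object, "exprs")
    if (!is.numeric(v)) msg <- c(msg, "expression values must be numeric")
    else if (any(!is.finite(v) & !is.na(v)))
      msg <- c(msg, "expression values must be finite or NA")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an ExpressionPanel
#'
#' @param values numeric genes x samples matrix.
#' @param geneIds,sampleIds character vectors; default to the matrix dimnames.
#' @return An [ExpressionPanel].
#' @examples
#' m <- matrix(rnorm(6), 3, 2, dimnames = list(paste0("g", 1:3), c("s1", "s2")))
#' ExpressionPanel(m)
#' @export
ExpressionPanel <- function(values, geneIds = rownames(values),
                            sampleIds = colnames(values)) {
  values <- as.matrix(values)
  if (is.null(geneIds) || is.null(sampleIds))
    stop("gene and sample IDs are required")
  dimnames(values) <- list(as.character(geneIds), as.character(sampleIds))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = values))
  methods::new("ExpressionPanel", se)
}

#' @describeIn ExpressionPanel gene IDs
#' @param x an `ExpressionPanel`
#' @export
setMethod("geneIds", "ExpressionPanel", function(x) rownames(x))

#' @describeIn ExpressionPanel sample IDs
#' @export
setMethod("sampleIds", "ExpressionPanel", function(x) colnames(x))

#' @describeIn ExpressionPanel the expression matrix
#' @export
setMethod("exprValues", "ExpressionPanel",
          function(x) SummarizedExperiment::assay(x, "exprs"))

# ---------------------------------------------------------------------------
# DrugActivityProfile
# ---------------------------------------------------------------------------

#' Per-cell-line drug activity (transformed GI50)
#'
#' Activity is on the "higher = more sensitive" scale (the role of
#' -log10(GI50)). Sample IDs are expected to be a subset of some panel's
#' samples and must align one-to-one with the activity vector.
#'
#' @slot drug drug name.
#' @slot sampleIds cell-line identifiers.
#' @slot activity numeric activity values, no missing entries.
#' @slot transform free-text tag for the GI50 transform applied upstream.
#' @export
setClass("DrugActivityProfile",
         representation(drug = "character", sampleIds = "character",
                        activity = "numeric", transform = "character"))

setValidity("DrugActivityProfile", function(object) {
  msg <- character()
  if (length(object@drug) != 1L) msg <- c(msg, "drug must be length one")
  if (length(object@sampleIds) != length(object@activity))
    msg <- c(msg, "sampleIds and activity lengths differ")
  if (anyDuplicated(object@sampleIds))
    msg <- c(msg, "duplicate sample IDs")
  if (anyNA(object@activity) || any(!is.finite(object@activity)))
    msg <- c(msg, "activity must be finite with no missing values")
  if (length(msg)) msg else TRUE
})

#' Construct a DrugActivityProfile
#'
#' @param drug drug name.
#' @param activity named numeric vector, or unnamed with `sampleIds` given.
#' @param sampleIds sample identifiers.
#' @param transform tag describing the GI50 transform (default
#'   `"neg_log10_gi50"`).
#' @return A [DrugActivityProfile].
#' @export
DrugActivityProfile <- function(drug, activity,
                                sampleIds = names(activity),
                                transform = "neg_log10_gi50") {
  methods::new("DrugActivityProfile", drug = as.character(drug),
               sampleIds = as.character(sampleIds),
               activity = unname(as.numeric(activity)),
               transform = transform)
}

#' @describeIn DrugActivityProfile the drug name
#' @param x a `DrugActivityProfile`
#' @export
setMethod("drugName", "DrugActivityProfile", function(x) x@drug)

#' @describeIn DrugActivityProfile named activity vector
#' @export
setMethod("activityValues", "DrugActivityProfile",
          function(x) setNames(x@activity, x@sampleIds))

#' @describeIn DrugActivityProfile sample IDs
#' @export
setMethod("sampleIds", "DrugActivityProfile", function(x) x@sampleIds)

setMethod("show", "DrugActivityProfile", function(object) {
  cat("DrugActivityProfile for", object@drug, "-", length(object@activity),
      "cell lines (", object@transform, ")\n")
})

# ---------------------------------------------------------------------------
# PatientCohort
# ---------------------------------------------------------------------------

#' Patient cohort: expression plus clinical channels
#'
#' An [ExpressionPanel] whose `colData` carries a `response` factor
#' (`pCR`/`RD`, `NA` = missing/other), optional `time` (months) and `event`
#' (0/1) survival columns, and optional logical subtype flags (e.g. `er_neg`,
#' `tn`). Where both flags are declared, `tn` must be nested inside `er_neg`.
#'
#' @export
setClass("PatientCohort", contains = "ExpressionPanel")

setValidity("PatientCohort", function(object) {
  cd <- SummarizedExperiment::colData(object)
  msg <- character()
  if (!"response" %in% colnames(cd))
    msg <- c(msg, "colData must contain 'response'")
  if ("time" %in% colnames(cd)) {
    if (!"event" %in% colnames(cd))
      msg <- c(msg, "'event' must accompany 'time'")
    else {
      tt <- cd$time
      if (any(tt < 0, na.rm = TRUE)) msg <- c(msg, "survival times must be >= 0")
      if (!all(cd$event %in% c(0L, 1L, NA)))
        msg <- c(msg, "event flags must be 0/1")
    }
  } else if ("event" %in% colnames(cd)) {
    msg <- c(msg, "'time' must accompany 'event'")
  }
  if (all(c("er_neg", "tn") %in% colnames(cd))) {
    bad <- which(cd$tn & !cd$er_neg)
    if (length(bad))
      msg <- c(msg, "triple-negative flag set outside the ER- subset")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a PatientCohort
#'
#' @param panel an [ExpressionPanel] (or genes x samples matrix).
#' @param response character/factor of `"pCR"`/`"RD"` per sample; anything else
#'   becomes `NA` (excluded from response metrics).
#' @param time,event optional numeric survival months and 0/1 event flags.
#' @param subtypes optional named list/data.frame of logical per-sample flags
#'   (e.g. `er_neg`, `tn`).
#' @return A [PatientCohort].
#' @export
PatientCohort <- function(panel, response, time = NULL, event = NULL,
                          subtypes = NULL) {
  if (!methods::is(panel, "ExpressionPanel")) panel <- ExpressionPanel(panel)
  n <- ncol(panel)
  response <- as.character(response)
  if (length(response) != n) stop("response length must match sample count")
  nOther <- sum(!is.na(response) & !response %in% c("pCR", "RD"))
  if (nOther > 0)
    message(nOther, " samples with response categories other than pCR/RD ",
            "set to missing")
  response[!response %in% c("pCR", "RD")] <- NA
  cd <- S4Vectors::DataFrame(response = factor(response,
                                               levels = c("RD", "pCR")))
  if (!is.null(time)) {
    if (is.null(event)) stop("'event' must accompany 'time'")
    if (length(time) != n || length(event) != n)
      stop("survival vectors must match sample count")
    cd$time <- as.numeric(time)
    cd$event <- as.integer(event)
  }
  if (!is.null(subtypes)) {
    for (nm in names(subtypes)) cd[[nm]] <- as.logical(subtypes[[nm]])
  }
  rownames(cd) <- colnames(panel)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(exprs = exprValues(panel)), colData = cd)
  methods::new("PatientCohort", methods::new("ExpressionPanel", se))
}

#' @describeIn PatientCohort pCR/RD labels
#' @param x a `PatientCohort`
#' @export
setMethod("responseLabels", "PatientCohort", function(x)
  setNames(SummarizedExperiment::colData(x)$response, colnames(x)))

#' @describeIn PatientCohort observed survival months (or NULL)
#' @export
setMethod("survivalTimes", "PatientCohort", function(x) {
  cd <- SummarizedExperiment::colData(x)
  if (!"time" %in% colnames(cd)) return(NULL)
  setNames(cd$time, colnames(x))
})

#' @describeIn PatientCohort event flags (or NULL)
#' @export
setMethod("eventFlags", "PatientCohort", function(x) {
  cd <- SummarizedExperiment::colData(x)
  if (!"event" %in% colnames(cd)) return(NULL)
  setNames(cd$event, colnames(x))
})

#' Subtype flag of a cohort
#'
#' @param cohort a [PatientCohort].
#' @param name flag column name (e.g. `"er_neg"`, `"tn"`).
#' @return Named logical vector, or `NULL` when the flag is absent.
#' @export
subtypeFlags <- function(cohort, name) {
  cd <- SummarizedExperiment::colData(cohort)
  if (!name %in% colnames(cd)) return(NULL)
  setNames(cd[[name]], colnames(cohort))
}

setMethod("show", "PatientCohort", function(object) {
  cd <- SummarizedExperiment::colData(object)
  cat("PatientCohort:", nrow(object), "genes x", ncol(object), "patients\n")
  r <- table(cd$response, useNA = "ifany")
  cat("  response:", paste(names(r), r, sep = "=", collapse = " "), "\n")
  cat("  survival channel:",
      if ("time" %in% colnames(cd)) "present" else "absent", "\n")
})

# ---------------------------------------------------------------------------
# BiomarkerSet
# ---------------------------------------------------------------------------

#' COXEN-selected biomarker gene set for one drug
#'
#' @slot drug drug name.
#' @slot genes ordered gene IDs (unique).
#' @slot scores `DataFrame` with one row per selected gene: `gene`,
#'   `coxenScore`, `candidateRank`.
#' @slot metadata list: discovery method, candidate-set size, reference tag.
#' @export
setClass("BiomarkerSet",
         representation(drug = "character", genes = "character",
                        scores = "DataFrame", metadata = "list"))

setValidity("BiomarkerSet", function(object) {
  msg <- character()
  if (anyDuplicated(object@genes)) msg <- c(msg, "duplicate biomarker genes")
  if (nrow(object@scores) != length(object@genes))
    msg <- c(msg, "scores table must have one row per gene")
  if (length(msg)) msg else TRUE
})

#' @describeIn BiomarkerSet selected genes, in score order
#' @param x a `BiomarkerSet`
#' @export
setMethod("biomarkerGenes", "BiomarkerSet", function(x) x@genes)

#' @describeIn BiomarkerSet drug name
#' @export
setMethod("drugName", "BiomarkerSet", function(x) x@drug)

#' COXEN score table of a biomarker set
#' @param x a [BiomarkerSet].
#' @return `DataFrame` of gene, coxenScore, candidateRank.
#' @export
coxenScores <- function(x) x@scores

setMethod("show", "BiomarkerSet", function(object) {
  cat("BiomarkerSet:", length(object@genes), "genes for drug", object@drug,
      "\n  COXEN score range:",
      sprintf("%.3f .. %.3f", min(object@scores$coxenScore),
              max(object@scores$coxenScore)), "\n")
})

# ---------------------------------------------------------------------------
# DrugModel
# ---------------------------------------------------------------------------

#' Trained per-drug principal-component regression model
#'
#' Self-contained: stores the biomarker genes, their training means/sds, the
#' PC loadings (genes x components, orthonormal), and the regression
#' intercept/coefficients, so cohorts can be scored without the training data.
#'
#' @slot drug drug name.
#' @slot genes ordered biomarker gene IDs.
#' @slot center,scale per-gene training mean and sd (sd > 0).
#' @slot loadings genes x components orthonormal loading matrix.
#' @slot nComponents number of retained components.
#' @slot intercept,coefficients regression intercept and per-PC coefficients.
#' @slot trainingTag,methodTag provenance strings.
#' @export
setClass("DrugModel",
         representation(drug = "character", genes = "character",
                        center = "numeric", scale = "numeric",
                        loadings = "matrix", nComponents = "integer",
                        intercept = "numeric", coefficients = "numeric",
                        trainingTag = "character", methodTag = "character"))

setValidity("DrugModel", function(object) {
  msg <- character()
  p <- length(object@genes)
  if (length(object@center) != p || length(object@scale) != p)
    msg <- c(msg, "center/scale must match gene count")
  if (any(object@scale <= 0)) msg <- c(msg, "scale entries must be > 0")
  if (nrow(object@loadings) != p ||
      ncol(object@loadings) != object@nComponents)
    msg <- c(msg, "loadings must be genes x nComponents")
  if (length(object@coefficients) != object@nComponents)
    msg <- c(msg, "one coefficient per component required")
  if (object@nComponents >= 1L) {
    ortho <- crossprod(object@loadings)
    if (max(abs(ortho - diag(ncol(ortho)))) > 1e-6)
      msg <- c(msg, "loading columns must be orthonormal")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn DrugModel biomarker genes
#' @param x a `DrugModel`
#' @export
setMethod("biomarkerGenes", "DrugModel", function(x) x@genes)

#' @describeIn DrugModel drug name
#' @export
setMethod("drugName", "DrugModel", function(x) x@drug)

setMethod("show", "DrugModel", function(object) {
  cat("DrugModel for", object@drug, "-", length(object@genes), "genes,",
      object@nComponents, "principal components\n")
  cat("  discovery:", object@methodTag, "| training:", object@trainingTag, "\n")
})

# ---------------------------------------------------------------------------
# CombinationModel
# ---------------------------------------------------------------------------

#' Combination-chemotherapy predictor over per-drug percentile scores
#'
#' Either a fitted multivariate logistic regression (main effects only, no
#' drug-drug interactions) or the unfitted equal-weight mean of percentiles.
#'
#' @slot drugs drug names entering the combination.
#' @slot mode `"logistic"` or `"equal_weight"`.
#' @slot intercept,coefficients logistic parameters (empty in equal-weight
#'   mode); coefficients are named by drug.
#' @slot cohortTag tag of the cohort the logistic fit used.
#' @export
setClass("CombinationModel",
         representation(drugs = "character", mode = "character",
                        intercept = "numeric", coefficients = "numeric",
                        cohortTag = "character"))

setValidity("CombinationModel", function(object) {
  msg <- character()
  if (length(object@drugs) == 0L || anyDuplicated(object@drugs))
    msg <- c(msg, "drug list must be nonempty without duplicates")
  if (!object@mode %in% c("logistic", "equal_weight"))
    msg <- c(msg, "mode must be 'logistic' or 'equal_weight'")
  if (object@mode == "logistic") {
    if (length(object@intercept) != 1L ||
        length(object@coefficients) != length(object@drugs))
      msg <- c(msg, "logistic mode requires intercept and one coefficient per drug")
  } else if (length(object@coefficients) != 0L) {
    msg <- c(msg, "equal-weight mode carries no coefficients")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "CombinationModel", function(object) {
  cat("CombinationModel (", object@mode, ") over drugs:",
      paste(object@drugs, collapse = ", "), "\n")
  if (object@mode == "logistic") {
    cat("  intercept:", sprintf("%.4f", object@intercept), "\n")
    cat("  coefficients:",
        paste(names(object@coefficients),
              sprintf("%.4f", object@coefficients), sep = "=",
              collapse = " "), "\n")
  }
})

# ---------------------------------------------------------------------------
# EvaluationReport
# ---------------------------------------------------------------------------

#' Evaluation of one predictor on one cohort
#'
#' @slot predictorTag,cohortTag identifying strings.
#' @slot nPCR,nRD class counts among response-evaluable patients.
#' @slot auc rank-sum (Mann-Whitney) AUC.
#' @slot ranksumP two-sided Wilcoxon rank-sum p-value.
#' @slot cutoffFraction top fraction called COXEN-positive.
#' @slot groupSizes named counts (positive/negative).
#' @slot medianSurvival per-group median survival months (`NA` = the curve
#'   never reaches 0.5, i.e. "> max follow-up").
#' @slot maxFollowUp last follow-up time in months.
#' @slot logrankStat,logrankP two-group log-rank chi-square and p (NA without
#'   survival data).
#' @slot npv negative predictive value of the COXEN-negative group.
#' @slot falseNegativeRisk 1 - NPV.
#' @export
setClass("EvaluationReport",
         representation(predictorTag = "character", cohortTag = "character",
                        nPCR = "integer", nRD = "integer", auc = "numeric",
                        ranksumP = "numeric", cutoffFraction = "numeric",
                        groupSizes = "integer", medianSurvival = "numeric",
                        maxFollowUp = "numeric", logrankStat = "numeric",
                        logrankP = "numeric", npv = "numeric",
                        falseNegativeRisk = "numeric"))

setMethod("show", "EvaluationReport", function(object) {
  cat("EvaluationReport:", object@predictorTag, "on", object@cohortTag, "\n")
  cat(sprintf("  n: pCR=%d RD=%d | AUC=%.3f rank-sum P=%.4g\n",
              object@nPCR, object@nRD, object@auc, object@ranksumP))
  cat(sprintf("  top %.0f%% dichotomy: positive=%d negative=%d | NPV=%.3f\n",
              100 * object@cutoffFraction, object@groupSizes[["positive"]],
              object@groupSizes[["negative"]], object@npv))
  if (!is.na(object@logrankP)) {
    ms <- vapply(object@medianSurvival, function(m)
      if (is.na(m)) sprintf(">%.4g", object@maxFollowUp)
      else sprintf("%.4g", m), character(1))
    cat(sprintf("  median survival: %s | log-rank chi2=%.3f P=%.4g\n",
                paste(names(ms), ms, sep = "=", collapse = " vs "),
                object@logrankStat, object@logrankP))
  }
})
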