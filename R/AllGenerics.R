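#' @import methods
#' @importFrom stats cor lm glm median pchisq pt plogis rbinom rexp rnorm runif
#'   sd setNames var prcomp quantile binomial coef model.matrix t.test
#'   wilcox.test complete.cases ks.test
#' @importFrom tools md5sum
#' @importFrom utils head count.fields read.table write.table
NULL

#' Gene identifiers of an object
#'
#' @param x an object with a gene dimension.
#' @return Character vector of gene IDs.
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' Sample identifiers of an object
#'
#' @param x an object with a sample dimension.
#' @return Character vector of sample IDs.
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' Expression matrix of a panel
#'
#' @param x an [ExpressionPanel] or [PatientCohort].
#' @return Numeric genes x samples matrix.
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))

#' Drug name carried by an object
#'
#' @param x a [DrugActivityProfile], [BiomarkerSet] or [DrugModel].
#' @return Length-one character.
#' @export
setGeneric("drugName", function(x) standardGeneric("drugName"))

#' Drug activity values
#'
#' @param x a [DrugActivityProfile].
#' @return Named numeric vector of transformed GI50 activities
#'   (higher = more sensitive).
#' @export
setGeneric("activityValues", function(x) standardGeneric("activityValues"))

#' Response labels of a patient cohort
#'
#' @param x a [PatientCohort].
#' @return Factor with levels `pCR`, `RD` (missing responses are `NA`).
#' @export
setGeneric("responseLabels", function(x) standardGeneric("responseLabels"))

#' Observed survival times (months)
#'
#' @param x a [PatientCohort].
#' @return Numeric vector, or `NULL` when the cohort has no survival channel.
#' @export
setGeneric("survivalTimes", function(x) standardGeneric("survivalTimes"))

#' Event indicators (1 = progression/relapse observed)
#'
#' @param x a [PatientCohort].
#' @return Integer 0/1 vector, or `NULL` without a survival channel.
#' @export
setGeneric("eventFlags", function(x) standardGeneric("eventFlags"))

#' Genes of a biomarker set or fitted model
#'
#' @param x a [BiomarkerSet] or [DrugModel].
#' @return Ordered character vector of gene IDs.
#' @export
setGeneric("biomarkerGenes", function(x) standardGeneric("biomarkerGenes"))
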