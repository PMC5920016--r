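# Delimited-text readers/writers and JSON model serialization.
# Tab-delimited is the default dialect; comma is auto-detected. Gene IDs are
# plain strings and cross-panel joins are exact-string intersections.

.detectSep <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header)) "\t" else ","
}

#' Read a gene x sample expression matrix
#'
#' Expects a header row of sample IDs and a first column of gene IDs;
#' tab-delimited by default with comma auto-detected. Ragged rows, duplicate
#' gene IDs and non-numeric cells are rejected with the offending line
#' number; `NA` and empty cells are read as missing.
#'
#' @param path file path.
#' @param sep optional field separator (default: auto-detect).
#' @return An [ExpressionPanel].
#' @export
readExpressionMatrix <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) sep <- .detectSep(path)
  nf <- utils::count.fields(path, sep = sep, quote = "\"")
  if (length(unique(nf)) != 1L) {
    bad <- which(nf != nf[1L])[1L]
    stop("parse error: ragged row at line ", bad, " (", nf[bad],
         " fields, expected ", nf[1L], ")")
  }
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, colClasses = "character",
                          quote = "\"", comment.char = "")
  if (ncol(df) < 2L) stop("parse error: need a gene column plus samples")
  genes <- df[[1L]]
  dup <- genes[duplicated(genes)]
  if (length(dup))
    stop("parse error: duplicated gene ID(s): ",
         paste(unique(utils::head(dup, 5)), collapse = ", "))
  vals <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals)))
  badCell <- which(is.na(num) & !is.na(vals) & !(vals %in% c("NA", "")),
                   arr.ind = TRUE)
  if (nrow(badCell) > 0L)
    stop("parse error: non-numeric cell at line ", badCell[1L, 1L] + 1L,
         ", column ", badCell[1L, 2L] + 1L, " ('",
         vals[badCell[1L, , drop = FALSE]], "')")
  dimnames(num) <- list(genes, colnames(df)[-1L])
  ExpressionPanel(num)
}

#' Write an expression panel as delimited text
#'
#' Inverse of [readExpressionMatrix()]: header of sample IDs, first column
#' `gene_id`.
#'
#' @param panel an [ExpressionPanel].
#' @param path output path.
#' @param sep field separator (default tab).
#' @export
writeExpressionMatrix <- function(panel, path, sep = "\t") {
  m <- exprValues(panel)
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

.readSideTable <- function(path, required) {
  sep <- .detectSep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          quote = "\"", comment.char = "")
  missing <- setdiff(required, colnames(df))
  if (length(missing))
    stop("parse error in ", basename(path), ": missing column(s) ",
         paste(missing, collapse = ", "))
  df
}

#' Assemble a patient cohort from delimited tables
#'
#' Side-table sample IDs must be a subset of the expression samples;
#' unmatched IDs abort assembly with a report. Response values other than
#' `pCR`/`RD` are kept as missing (excluded later from response metrics);
#' the TN-within-ER- nesting is enforced when both flags are provided.
#'
#' @param exprPath expression matrix path (see [readExpressionMatrix()]).
#' @param responsePath optional table with columns `sample_id`, `response`.
#' @param survivalPath optional table with columns `sample_id`, `time`,
#'   `event`.
#' @param subtypePath optional table with `sample_id` plus logical/0-1 flag
#'   columns (e.g. `er_neg`, `tn`).
#' @return A [PatientCohort].
#' @export
readCohortTables <- function(exprPath, responsePath = NULL,
                             survivalPath = NULL, subtypePath = NULL) {
  panel <- readExpressionMatrix(exprPath)
  ids <- sampleIds(panel)
  pull <- function(df, col, default = NA) {
    unknown <- setdiff(df$sample_id, ids)
    if (length(unknown))
      stop("assembly error: sample IDs absent from expression matrix: ",
           paste(utils::head(unknown, 5), collapse = ", "))
    out <- rep(default, length(ids))
    out[match(df$sample_id, ids)] <- df[[col]]
    out
  }
  response <- rep(NA_character_, length(ids))
  if (!is.null(responsePath)) {
    rdf <- .readSideTable(responsePath, c("sample_id", "response"))
    response <- as.character(pull(rdf, "response", NA_character_))
  }
  time <- NULL; event <- NULL
  if (!is.null(survivalPath)) {
    sdf <- .readSideTable(survivalPath, c("sample_id", "time", "event"))
    time <- as.numeric(pull(sdf, "time", NA_real_))
    event <- as.integer(pull(sdf, "event", NA_integer_))
  }
  subtypes <- NULL
  if (!is.null(subtypePath)) {
    ydf <- .readSideTable(subtypePath, "sample_id")
    flags <- setdiff(colnames(ydf), "sample_id")
    subtypes <- lapply(flags, function(f)
      as.logical(as.numeric(pull(ydf, f, NA_real_))))
    names(subtypes) <- flags
  }
  PatientCohort(panel, response = response, time = time, event = event,
                subtypes = subtypes)
}

#' Serialize a drug model to JSON
#'
#' Full provenance round-trip: genes, training means/sds, PC loadings,
#' regression coefficients and tags, at full numeric precision, so a
#' deserialized model scores identically.
#'
#' @param model a [DrugModel-class].
#' @param path output path.
#' @export
writeDrugModel <- function(model, path) {
  obj <- list(drug = model@drug, genes = model@genes,
              center = model@center, scale = model@scale,
              loadings = model@loadings, nComponents = model@nComponents,
              intercept = model@intercept,
              coefficients = model@coefficients,
              trainingTag = model@trainingTag, methodTag = model@methodTag)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Deserialize a drug model from JSON
#'
#' @param path path written by [writeDrugModel()].
#' @return A [DrugModel-class].
#' @export
readDrugModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  methods::new("DrugModel", drug = obj$drug, genes = obj$genes,
               center = as.numeric(obj$center),
               scale = as.numeric(obj$scale),
               loadings = matrix(as.numeric(obj$loadings),
                                 nrow = length(obj$genes)),
               nComponents = as.integer(obj$nComponents),
               intercept = as.numeric(obj$intercept),
               coefficients = as.numeric(obj$coefficients),
               trainingTag = obj$trainingTag, methodTag = obj$methodTag)
}

#' Serialize a biomarker set to JSON
#'
#' @param set a [BiomarkerSet-class].
#' @param path output path.
#' @export
writeBiomarkerSet <- function(set, path) {
  obj <- list(drug = set@drug, genes = set@genes,
              coxenScore = set@scores$coxenScore,
              candidateRank = set@scores$candidateRank,
              method = set@metadata$method %||% "unknown",
              candidateSize = set@metadata$candidateSize %||% NA)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Deserialize a biomarker set from JSON
#'
#' @param path path written by [writeBiomarkerSet()].
#' @return A [BiomarkerSet-class].
#' @export
readBiomarkerSet <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  methods::new("BiomarkerSet", drug = obj$drug, genes = obj$genes,
               scores = S4Vectors::DataFrame(
                 gene = obj$genes,
                 coxenScore = as.numeric(obj$coxenScore),
                 candidateRank = as.integer(obj$candidateRank)),
               metadata = list(method = obj$method,
                               candidateSize = obj$candidateSize))
}

# EvaluationReport -> plain list (for JSON reports)
.reportAsList <- function(r) {
  list(predictor = r@predictorTag, cohort = r@cohortTag,
       n_pcr = r@nPCR, n_rd = r@nRD, auc = r@auc, ranksum_p = r@ranksumP,
       cutoff_fraction = r@cutoffFraction,
       group_sizes = as.list(r@groupSizes),
       median_survival = as.list(r@medianSurvival),
       max_follow_up = r@maxFollowUp,
       logrank_statistic = r@logrankStat, logrank_p = r@logrankP,
       npv = r@npv, false_negative_risk = r@falseNegativeRisk)
}
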