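# End-to-end orchestration: discover -> COXEN -> train per drug, then
# predict -> combine -> evaluate per validation cohort. All randomness flows
# from the single configuration seed; identical configurations reproduce
# identical artifacts.

.defaultNSelect <- c(T = 33L, F = 56L, A = 27L, C = 68L)

#' Run the full pipeline on a freshly simulated study
#'
#' Generates a cell-line training panel with drug activities, three
#' independent patient cohorts from the same generative truth (a COXEN
#' reference used only for concordant-gene selection, a combination-fit
#' cohort, and a held-out validation cohort), then runs per-drug discovery,
#' COXEN selection, in-vitro PC-regression training, cohort scoring,
#' rank-percentile conversion, combination fitting and held-out evaluation.
#' The COXEN reference is never evaluated on, mirroring its
#' selection-only role.
#'
#' @param config a [SimulationConfig-class]; its seed drives every stage.
#' @param method discovery statistic, one per drug (recycled).
#' @param topK candidate-list size per drug (default 500, bounded by the
#'   gene count).
#' @param nSelect named per-drug COXEN set sizes; defaults to the reported
#'   optimal sizes T=33, F=56, A=27, C=68.
#' @param combinationMode `"logistic"` or `"equal_weight"`.
#' @param cutoffFraction top fraction called COXEN-positive (default 0.30).
#' @return A list: `models` (per-drug [DrugModel-class]), `biomarkers`
#'   (per-drug [BiomarkerSet-class]), `percentiles` (per-cohort samples x
#'   drugs matrices), `combination` ([CombinationModel-class]), `combined`
#'   (held-out combined scores), `report` ([EvaluationReport-class] on the
#'   validation cohort), `cohorts`, and `truth` objects for oracle checks.
#' @examples
#' \donttest{
#' res <- runSyntheticStudy(simulationConfig(nGenes = 200, seed = 1),
#'                          topK = 100, nSelect = c(T = 15, F = 15))
#' res$report
#' }
#' @export
runSyntheticStudy <- function(config, method = "pearson", topK = 500L,
                              nSelect = .defaultNSelect,
                              combinationMode = "logistic",
                              cutoffFraction = 0.30) {
  sim <- simulateCellLinePanel(config)
  drugs <- names(sim$profiles)
  method <- rep_len(method, length(drugs))
  names(method) <- drugs
  topK <- min(as.integer(topK), config@nGenes)

  ref <- simulatePatientCohort(config, sim$truth, cohortIndex = 1L)
  fitC <- simulatePatientCohort(config, sim$truth, cohortIndex = 2L)
  val <- simulatePatientCohort(config, sim$truth, cohortIndex = 3L)

  models <- list(); biomarkers <- list(); candidates <- list()
  pctFit <- list(); pctVal <- list()
  for (d in drugs) {
    cand <- suppressWarnings(
      rankCandidates(sim$panel, sim$profiles[[d]], method[[d]],
                     tissue = sim$tissue, topK = topK))
    ns <- if (d %in% names(nSelect)) as.integer(nSelect[[d]]) else
      as.integer(nSelect[[1L]])
    ns <- min(ns, topK)
    bm <- selectCoxenGenes(cand, sim$panel, ref$cohort, nSelect = ns)
    model <- fitDrugModel(sim$panel, sim$profiles[[d]], bm)
    candidates[[d]] <- cand
    biomarkers[[d]] <- bm
    models[[d]] <- model
    pctFit[[d]] <- toRankPercentile(scoreCohort(model, fitC$cohort))
    pctVal[[d]] <- toRankPercentile(scoreCohort(model, val$cohort))
  }
  pctFitM <- do.call(cbind, pctFit)
  pctValM <- do.call(cbind, pctVal)
  colnames(pctFitM) <- drugs; colnames(pctValM) <- drugs

  comb <- fitCombination(pctFitM, responseLabels(fitC$cohort),
                         mode = combinationMode, cohortTag = "fit_cohort")
  combined <- predictCombination(comb, pctValM)
  report <- evaluatePredictor(combined, val$cohort,
                              cutoffFraction = cutoffFraction,
                              predictorTag = paste0("combined_",
                                                    paste(drugs, collapse = "")),
                              cohortTag = "validation_cohort")
  list(models = models, biomarkers = biomarkers, candidates = candidates,
       percentiles = list(fit = pctFitM, validation = pctValM),
       combination = comb, combined = combined, report = report,
       cohorts = list(coxenReference = ref$cohort, fit = fitC$cohort,
                      validation = val$cohort),
       truth = list(cellLine = sim$truth, fit = fitC$truth,
                    validation = val$truth),
       tissue = sim$tissue, panel = sim$panel, profiles = sim$profiles)
}

#' Write a simulated study to delimited files
#'
#' Materializes the `simulate` outputs for the file-based pipeline: the
#' cell-line expression matrix, per-drug activity tables and tissue labels;
#' per-cohort expression/response/survival/subtype tables; the ground-truth
#' manifest as JSON; and the configuration as YAML.
#'
#' @param config a [SimulationConfig-class].
#' @param dir output directory (created if needed).
#' @return Invisibly, the list of written paths.
#' @export
simulateToFiles <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sim <- simulateCellLinePanel(config)
  paths <- list()
  p <- function(...) file.path(dir, paste0(...))
  writeExpressionMatrix(sim$panel, paths$expression <- p("cell_lines.tsv"))
  for (d in names(sim$profiles)) {
    av <- activityValues(sim$profiles[[d]])
    utils::write.table(
      data.frame(sample_id = names(av), activity = unname(av)),
      paths[[paste0("activity_", d)]] <- p("activity_", d, ".tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  utils::write.table(
    data.frame(sample_id = names(sim$tissue), tissue = as.character(sim$tissue)),
    paths$tissue <- p("tissue.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  roles <- c(coxen_reference = 1L, combination_fit = 2L, validation = 3L)
  for (role in names(roles)) {
    pc <- simulatePatientCohort(config, sim$truth, cohortIndex = roles[[role]])
    co <- pc$cohort
    writeExpressionMatrix(co, paths[[paste0(role, "_expr")]] <-
                            p(role, "_expression.tsv"))
    rl <- responseLabels(co)
    utils::write.table(
      data.frame(sample_id = names(rl), response = as.character(rl)),
      paths[[paste0(role, "_response")]] <- p(role, "_response.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(sample_id = sampleIds(co), time = unname(survivalTimes(co)),
                 event = unname(eventFlags(co))),
      paths[[paste0(role, "_survival")]] <- p(role, "_survival.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(sample_id = sampleIds(co),
                 er_neg = as.integer(subtypeFlags(co, "er_neg")),
                 tn = as.integer(subtypeFlags(co, "tn"))),
      paths[[paste0(role, "_subtype")]] <- p(role, "_subtype.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  truth <- sim$truth
  jsonlite::write_json(
    list(signature_genes = truth@signatureGenes,
         concordant = as.list(truth@concordant),
         config_digest = truth@configDigest),
    paths$truth <- p("ground_truth.json"), digits = NA, auto_unbox = TRUE)
  cfg <- sapply(methods::slotNames(config), function(s)
    methods::slot(config, s), simplify = FALSE)
  yaml::write_yaml(cfg, paths$config <- p("config.yaml"))
  invisible(paths)
}

.hashConfig <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(yaml::as.yaml(config), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the file-based pipeline from a configuration
#'
#' Reads the configuration (YAML path or an equivalent list), refuses any
#' configuration whose COXEN reference cohort doubles as a validation cohort,
#' then executes discover -> COXEN -> train per drug and predict -> combine
#' -> evaluate per validation cohort, writing model JSONs, percentile score
#' tables, report JSONs and a stage log under the output directory. Every
#' artifact directory is stamped with the configuration hash and seed;
#' re-running an identical configuration reproduces identical outputs.
#'
#' Expected configuration keys: `seed`, `output_dir`, `cutoff_fraction`,
#' `combination_mode`, `training: {expression, tissue}`, `drugs:` (list of
#' `{name, activity, method, top_k, n_select, n_components}`) and `cohorts:
#' {coxen_reference: {name, expression}, combination_fit: {name, expression,
#' response}, validation: [{name, expression, response, survival, subtype}]}`.
#'
#' @param config YAML file path or a list with the structure above.
#' @return Invisibly, a list with the fitted models, the combination model
#'   and per-cohort [EvaluationReport-class]s.
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- as.integer(config$seed %||% 1L)
  outDir <- config$output_dir %||% stop("config must name an output_dir")
  cutoff <- as.numeric(config$cutoff_fraction %||% 0.30)
  mode <- config$combination_mode %||% "logistic"

  valNames <- vapply(config$cohorts$validation, function(v)
    v$name %||% v$expression, character(1))
  refName <- config$cohorts$coxen_reference$name %||%
    config$cohorts$coxen_reference$expression
  refPath <- config$cohorts$coxen_reference$expression
  valPaths <- vapply(config$cohorts$validation, function(v) v$expression,
                     character(1))
  if (refName %in% valNames || refPath %in% valPaths)
    stop("config error: the COXEN reference cohort cannot also be a ",
         "validation cohort")

  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  for (sub in c("models", "biomarkers", "scores", "reports"))
    dir.create(file.path(outDir, sub), showWarnings = FALSE)
  logPath <- file.path(outDir, "pipeline.log")
  logCon <- file(logPath, open = "wt")
  on.exit(close(logCon), add = TRUE)
  say <- function(...) writeLines(paste0(...), logCon)
  say("config_hash: ", .hashConfig(config))
  say("seed: ", seed)
  set.seed(seed)

  stage <- function(name, what, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed for ", what, ": ",
           conditionMessage(e), call. = FALSE))
  }

  trainPanel <- stage("read", "training panel",
                      readExpressionMatrix(config$training$expression))
  tissue <- NULL
  if (!is.null(config$training$tissue)) {
    tdf <- .readSideTable(config$training$tissue, c("sample_id", "tissue"))
    tissue <- setNames(factor(tdf$tissue), tdf$sample_id)
  }
  refPanel <- stage("read", "COXEN reference cohort",
                    readExpressionMatrix(refPath))

  models <- list()
  for (dcfg in config$drugs) {
    d <- dcfg$name
    prof <- stage("read", paste("activity of", d), {
      adf <- .readSideTable(dcfg$activity, c("sample_id", "activity"))
      DrugActivityProfile(d, setNames(adf$activity, adf$sample_id))
    })
    cand <- stage("discover", d, suppressWarnings(
      rankCandidates(trainPanel, prof, dcfg$method %||% "pearson",
                     tissue = tissue,
                     topK = dcfg$top_k %||% 500L)))
    say("discover ", d, ": tested=", S4Vectors::metadata(cand)$nTested,
        " skipped=", S4Vectors::metadata(cand)$nSkipped)
    nsDefault <- if (d %in% names(.defaultNSelect)) .defaultNSelect[[d]] else 30L
    bm <- stage("coxen", d, selectCoxenGenes(
      cand, trainPanel, refPanel,
      nSelect = dcfg$n_select %||% nsDefault))
    writeBiomarkerSet(bm, file.path(outDir, "biomarkers",
                                    paste0(d, ".json")))
    model <- stage("train", d, fitDrugModel(
      trainPanel, prof, bm, nComponents = dcfg$n_components))
    writeDrugModel(model, file.path(outDir, "models", paste0(d, ".json")))
    say("train ", d, ": genes=", length(biomarkerGenes(model)),
        " components=", model@nComponents)
    models[[d]] <- model
  }

  loadCohort <- function(ccfg) readCohortTables(
    ccfg$expression, ccfg$response, ccfg$survival, ccfg$subtype)
  scoreTable <- function(cohort, tag) {
    pct <- vapply(models, function(mo)
      toRankPercentile(scoreCohort(mo, cohort)),
      numeric(ncol(cohort)))
    colnames(pct) <- names(models)
    df <- data.frame(sample_id = sampleIds(cohort), pct,
                     check.names = FALSE)
    utils::write.table(format(df, digits = 15), file.path(
      outDir, "scores", paste0(tag, "_percentiles.tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
    pct
  }

  fitCfg <- config$cohorts$combination_fit
  fitCohort <- stage("read", "combination-fit cohort", loadCohort(fitCfg))
  fitPct <- scoreTable(fitCohort, fitCfg$name %||% "combination_fit")
  comb <- stage("combine", "combination model",
                fitCombination(fitPct, responseLabels(fitCohort),
                               mode = mode,
                               cohortTag = fitCfg$name %||% "combination_fit"))
  jsonlite::write_json(
    list(drugs = comb@drugs, mode = comb@mode,
         intercept = comb@intercept, coefficients = as.list(comb@coefficients),
         cohort = comb@cohortTag),
    file.path(outDir, "combination_model.json"), digits = NA,
    auto_unbox = TRUE)

  reports <- list()
  for (vcfg in config$cohorts$validation) {
    vname <- vcfg$name %||% basename(vcfg$expression)
    cohort <- stage("read", vname, loadCohort(vcfg))
    pct <- scoreTable(cohort, vname)
    combined <- predictCombination(comb, pct)
    rep <- stage("evaluate", vname, evaluatePredictor(
      combined, cohort, cutoffFraction = cutoff,
      predictorTag = paste0("combined_", paste(names(models), collapse = "")),
      cohortTag = vname))
    jsonlite::write_json(.reportAsList(rep),
                         file.path(outDir, "reports", paste0(vname, ".json")),
                         digits = NA, auto_unbox = TRUE)
    say("evaluate ", vname, ": auc=", format(rep@auc, digits = 6),
        " ranksum_p=", format(rep@ranksumP, digits = 6))
    reports[[vname]] <- rep
  }
  invisible(list(models = models, combination = comb, reports = reports))
}
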