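# Latent-factor synthetic-data generator.
#
# Emulates the structural features the pipeline assumes: a cell-line panel
# with a continuous drug-activity phenotype per drug and a tissue-type
# confounder, plus patient cohorts sharing the gene universe whose gene-gene
# coexpression is only partially concordant with the cell lines, and whose
# binary response and censored survival are driven by the planted signature
# genes. Everything is seeded and byte-reproducible.

.kBackgroundFactors <- 5L
.bgNoiseSd <- 0.7
.drugUniverse <- c("T", "F", "A", "C")

#' Simulation configuration
#'
#' Holds every knob of the paired cell-line/patient generator. See
#' [simulationConfig()] for defaults and units.
#'
#' @export
setClass("SimulationConfig",
         representation(nCellLines = "integer", nPatients = "integer",
                        nGenes = "integer", nSignatureGenesPerDrug = "integer",
                        nDrugs = "integer", signatureEffect = "numeric",
                        concordantFraction = "numeric", nTissues = "integer",
                        tissueShift = "numeric", responseIntercept = "numeric",
                        responseSlope = "numeric", baselineHazard = "numeric",
                        hazardLogRatio = "numeric", censorRate = "numeric",
                        seed = "integer"))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  chk <- function(cond, text) if (!cond) msg <<- c(msg, text)
  chk(object@nCellLines >= 1L, "nCellLines must be >= 1")
  chk(object@nPatients >= 1L, "nPatients must be >= 1")
  chk(object@nGenes >= 1L, "nGenes must be >= 1")
  chk(object@nSignatureGenesPerDrug >= 0L,
      "nSignatureGenesPerDrug must be >= 0")
  chk(object@nDrugs >= 1L && object@nDrugs <= 4L,
      "nDrugs must be between 1 and 4")
  chk(object@nSignatureGenesPerDrug * object@nDrugs <= object@nGenes,
      "nSignatureGenesPerDrug x nDrugs must not exceed nGenes")
  chk(object@concordantFraction >= 0 && object@concordantFraction <= 1,
      "concordantFraction must lie in [0, 1]")
  chk(object@nTissues >= 1L, "nTissues must be >= 1")
  chk(object@baselineHazard > 0, "baselineHazard must be > 0")
  chk(object@censorRate >= 0, "censorRate must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Build a simulation configuration
#'
#' Defaults describe the study conditions the pipeline is exercised under: a
#' 60-line training panel (the NCI-60 scale), 200-patient cohorts, two drugs
#' (the two-drug taxane/anthracycline setting validated for survival), 20
#' planted signature genes per drug with standardized slope 0.6 on activity,
#' half of them coexpression-concordant with the patient panel, three
#' histology groups shifting mean activity by 0.5 per group, a logistic
#' response link giving a ~27 percent pCR rate at the average score, and exponential
#' survival on the month scale (mean 60 months at score 0, light censoring).
#'
#' @param nCellLines,nPatients,nGenes panel dimensions.
#' @param nSignatureGenesPerDrug planted signature genes per drug.
#' @param nDrugs 1-4 drugs, named from T, F, A, C.
#' @param signatureEffect per-gene standardized slope of expression on
#'   activity.
#' @param concordantFraction fraction of signature genes whose coexpression
#'   loadings are preserved in the patient panel.
#' @param nTissues histology groups on the cell-line panel.
#' @param tissueShift per-tissue mean offset added to activity.
#' @param responseIntercept,responseSlope logistic link from true combined
#'   score to pCR probability.
#' @param baselineHazard event hazard per month at score 0.
#' @param hazardLogRatio log-hazard decrease per unit of true score.
#' @param censorRate censoring hazard per month (0 = no censoring).
#' @param seed master RNG seed; every derived dataset is a pure function of it.
#' @return A validated [SimulationConfig-class] object.
#' @examples
#' cfg <- simulationConfig(nGenes = 100, seed = 7)
#' @export
simulationConfig <- function(nCellLines = 60, nPatients = 200, nGenes = 1000,
                             nSignatureGenesPerDrug = 20, nDrugs = 2,
                             signatureEffect = 0.6, concordantFraction = 0.5,
                             nTissues = 3, tissueShift = 0.5,
                             responseIntercept = -1, responseSlope = 2,
                             baselineHazard = 1 / 60, hazardLogRatio = 0.5,
                             censorRate = 1 / 120, seed = 1) {
  obj <- methods::new("SimulationConfig",
                      nCellLines = as.integer(nCellLines),
                      nPatients = as.integer(nPatients),
                      nGenes = as.integer(nGenes),
                      nSignatureGenesPerDrug = as.integer(nSignatureGenesPerDrug),
                      nDrugs = as.integer(nDrugs),
                      signatureEffect = as.numeric(signatureEffect),
                      concordantFraction = as.numeric(concordantFraction),
                      nTissues = as.integer(nTissues),
                      tissueShift = as.numeric(tissueShift),
                      responseIntercept = as.numeric(responseIntercept),
                      responseSlope = as.numeric(responseSlope),
                      baselineHazard = as.numeric(baselineHazard),
                      hazardLogRatio = as.numeric(hazardLogRatio),
                      censorRate = as.numeric(censorRate),
                      seed = as.integer(seed))
  obj
}

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig:", object@nGenes, "genes,", object@nCellLines,
      "cell lines,", object@nPatients, "patients,", object@nDrugs,
      "drug(s)\n")
  cat(sprintf("  signatureEffect=%.3g concordantFraction=%.3g seed=%d\n",
              object@signatureEffect, object@concordantFraction, object@seed))
})

.configDigest <- function(config) {
  paste(vapply(methods::slotNames(config), function(s)
    paste(format(methods::slot(config, s), digits = 15), collapse = ","),
    character(1)), collapse = "|")
}

#' Ground-truth manifest of a simulated study
#'
#' The oracle for parameter-recovery tests: which genes were planted for which
#' drug, which of them keep their coexpression loadings in the patient panel,
#' and (after [simulatePatientCohort()]) each patient's true combined score
#' and response probability.
#'
#' @slot signatureGenes named list (per drug) of planted gene IDs, disjoint
#'   across drugs.
#' @slot concordant named logical over all genes: `TRUE` for the signature
#'   genes whose latent-factor loadings are preserved in the patient system;
#'   all other genes follow the patient panel's own background structure.
#' @slot trueScore,trueResponseProb per-patient values of the most recently
#'   generated cohort (empty before [simulatePatientCohort()]).
#' @slot generator internal loading matrices tying the two panels together.
#' @slot configDigest fingerprint of the generating configuration.
#' @export
setClass("GroundTruth",
         representation(signatureGenes = "list", concordant = "logical",
                        trueScore = "numeric", trueResponseProb = "numeric",
                        generator = "list", configDigest = "character"))

setValidity("GroundTruth", function(object) {
  msg <- character()
  sig <- unlist(object@signatureGenes, use.names = FALSE)
  if (anyDuplicated(sig))
    msg <- c(msg, "signature genes must be disjoint across drugs")
  if (!all(sig %in% names(object@concordant)))
    msg <- c(msg, "signature genes must belong to the gene universe")
  if (length(msg)) msg else TRUE
})

#' @describeIn GroundTruth per-drug planted signature genes
#' @param truth a `GroundTruth`
#' @export
signatureGenes <- function(truth) truth@signatureGenes

#' @describeIn GroundTruth named logical concordance flags
#' @export
concordantFlags <- function(truth) truth@concordant

#' @describeIn GroundTruth per-patient true combined scores of the last cohort
#' @export
trueScores <- function(truth) truth@trueScore

setMethod("show", "GroundTruth", function(object) {
  cat("GroundTruth:", length(object@signatureGenes), "drug signature(s) of",
      paste(lengths(object@signatureGenes), collapse = "/"), "genes;",
      sum(object@concordant[unlist(object@signatureGenes)]),
      "concordant signature genes\n")
})

#' Simulate the cell-line training panel
#'
#' Expression follows a latent-factor Gaussian model: background genes load on
#' a small set of shared factors (giving the coexpression structure COXEN
#' relies on) while each drug's signature genes load on a drug-specific
#' factor. Genes are standardized to sample mean 0 / sd 1 before export. Drug
#' activity (the role of -log10 GI50, higher = more sensitive) is the sum of
#' `signatureEffect` times each signature gene's standardized expression, plus
#' a centered per-tissue offset of `tissueShift` per histology step, plus unit
#' Gaussian noise; non-signature genes are independent of activity given
#' tissue.
#'
#' @param config a [SimulationConfig-class] from [simulationConfig()].
#' @return A list with elements `panel` ([ExpressionPanel]), `profiles`
#'   (named list of [DrugActivityProfile], one per drug), `tissue` (named
#'   factor of histology labels) and `truth` ([GroundTruth-class]).
#' @examples
#' sim <- simulateCellLinePanel(simulationConfig(nGenes = 50, seed = 1))
#' dim(exprValues(sim$panel))
#' @export
simulateCellLinePanel <- function(config) {
  methods::validObject(config)
  set.seed(config@seed)
  nG <- config@nGenes; nS <- config@nCellLines
  m <- config@nSignatureGenesPerDrug
  drugs <- .drugUniverse[seq_len(config@nDrugs)]
  genes <- sprintf("g%0*d", max(4L, nchar(nG)), seq_len(nG))
  samples <- sprintf("cl%03d", seq_len(nS))

  sigList <- setNames(vector("list", length(drugs)), drugs)
  if (m > 0L) {
    sigAll <- sample(genes, m * length(drugs))
    for (i in seq_along(drugs))
      sigList[[i]] <- sigAll[((i - 1L) * m + 1L):(i * m)]
  } else {
    sigAll <- character()
    for (i in seq_along(drugs)) sigList[[i]] <- character()
  }
  drugOfGene <- setNames(rep(NA_character_, nG), genes)
  for (d in drugs) drugOfGene[sigList[[d]]] <- d

  tissue <- factor(sample(rep_len(seq_len(config@nTissues), nS)),
                   levels = seq_len(config@nTissues),
                   labels = paste0("tissue", seq_len(config@nTissues)))
  names(tissue) <- samples

  kBg <- .kBackgroundFactors
  bgLoad <- matrix(rnorm(nG * kBg, sd = 1 / sqrt(kBg)), nG, kBg,
                   dimnames = list(genes, NULL))
  sigLoad <- setNames(runif(length(sigAll), 0.5, 0.9), sigAll)

  # concordance: which genes keep their loadings in the patient system.
  # The patient panel has its own background structure (drawn once below and
  # shared by every cohort), so only the concordant fraction of each drug's
  # signature genes is preserved across systems.
  concordant <- setNames(rep(FALSE, nG), genes)
  if (m > 0L) {
    for (d in drugs) {
      nConc <- round(config@concordantFraction * m)
      if (nConc > 0L)
        concordant[sample(sigList[[d]], nConc)] <- TRUE
    }
  }
  patientBgLoad <- matrix(rnorm(nG * kBg, sd = 1 / sqrt(kBg)), nG, kBg,
                          dimnames = list(genes, NULL))

  fBg <- matrix(rnorm(kBg * nS), kBg, nS)
  fSig <- matrix(rnorm(length(drugs) * nS), length(drugs), nS,
                 dimnames = list(drugs, NULL))
  eps <- matrix(rnorm(nG * nS), nG, nS, dimnames = list(genes, NULL))

  x <- bgLoad %*% fBg + .bgNoiseSd * eps
  if (length(sigAll)) {
    for (g in sigAll) {
      l <- sigLoad[[g]]
      x[g, ] <- l * fSig[drugOfGene[[g]], ] + sqrt(1 - l^2) * eps[g, ]
    }
  }
  z <- .standardizeRows(x)
  dimnames(z) <- list(genes, samples)
  panel <- ExpressionPanel(z)

  offsets <- config@tissueShift *
    (seq_len(config@nTissues) - (config@nTissues + 1) / 2)
  profiles <- setNames(vector("list", length(drugs)), drugs)
  for (d in drugs) {
    signal <- if (length(sigList[[d]]))
      config@signatureEffect * colSums(z[sigList[[d]], , drop = FALSE])
    else rep(0, nS)
    act <- signal + offsets[as.integer(tissue)] + rnorm(nS)
    profiles[[d]] <- DrugActivityProfile(d, setNames(act, samples),
                                         transform = "simulated_neg_log10_gi50")
  }

  truth <- methods::new("GroundTruth", signatureGenes = sigList,
                        concordant = concordant,
                        trueScore = numeric(), trueResponseProb = numeric(),
                        generator = list(genes = genes, bgLoad = bgLoad,
                                         patientBgLoad = patientBgLoad,
                                         sigLoad = sigLoad,
                                         drugOfGene = drugOfGene, kBg = kBg),
                        configDigest = .configDigest(config))
  list(panel = panel, profiles = profiles, tissue = tissue, truth = truth)
}

#' Simulate a patient cohort tied to a cell-line ground truth
#'
#' Concordant signature genes keep the cell-line loadings on their drug's
#' (patient-side) signature factor; every other gene, including discordant
#' signature genes, follows the patient system's own background loadings,
#' which are drawn once per study (all cohorts share them) and independently
#' of the cell-line structure. The per-patient true combined
#' score is the mean over drugs of the standardized planted-signature
#' projection; pCR is Bernoulli(logistic(intercept + slope x score)); survival
#' is exponential with hazard `baselineHazard * exp(-hazardLogRatio x score)`
#' under independent exponential censoring.
#'
#' @param config the same [SimulationConfig-class] that produced `truth`.
#' @param truth the [GroundTruth-class] from [simulateCellLinePanel()].
#' @param cohortIndex integer tag; different indices give independent cohorts
#'   from the same generative truth (COXEN reference, combination-fit,
#'   validation, ...).
#' @return A list with `cohort` ([PatientCohort]) and `truth` (the input
#'   [GroundTruth-class] with per-patient `trueScore` and `trueResponseProb`
#'   filled in for this cohort).
#' @examples
#' cfg <- simulationConfig(nGenes = 60, nPatients = 40, seed = 2)
#' sim <- simulateCellLinePanel(cfg)
#' pc <- simulatePatientCohort(cfg, sim$truth)
#' table(responseLabels(pc$cohort))
#' @export
simulatePatientCohort <- function(config, truth, cohortIndex = 1L) {
  methods::validObject(config)
  if (!identical(truth@configDigest, .configDigest(config)))
    stop("validation error: ground truth was not generated by this ",
         "configuration (mismatched gene universe or parameters)")
  gen <- truth@generator
  genes <- gen$genes
  if (length(genes) != config@nGenes)
    stop("validation error: mismatched gene universe")
  set.seed(.deriveSeed(config@seed, 1000L + as.integer(cohortIndex)))
  nG <- length(genes); nP <- config@nPatients
  drugs <- names(truth@signatureGenes)
  samples <- sprintf("p%d_%03d", as.integer(cohortIndex), seq_len(nP))

  kBg <- gen$kBg
  fBg <- matrix(rnorm(kBg * nP), kBg, nP)
  fSig <- matrix(rnorm(length(drugs) * nP), length(drugs), nP,
                 dimnames = list(drugs, NULL))
  eps <- matrix(rnorm(nG * nP), nG, nP, dimnames = list(genes, NULL))

  # the patient system's own background structure (fixed in the truth, so all
  # cohorts from one study share it); concordant signature genes keep their
  # cell-line loadings on the patient-side signature factors instead
  x <- gen$patientBgLoad %*% fBg + .bgNoiseSd * eps
  sigAll <- unlist(truth@signatureGenes, use.names = FALSE)
  for (g in sigAll[truth@concordant[sigAll]]) {
    l <- gen$sigLoad[[g]]
    x[g, ] <- l * fSig[gen$drugOfGene[[g]], ] + sqrt(1 - l^2) * eps[g, ]
  }
  z <- .standardizeRows(x)
  dimnames(z) <- list(genes, samples)

  perDrug <- vapply(drugs, function(d) {
    sg <- truth@signatureGenes[[d]]
    proj <- if (length(sg)) colSums(z[sg, , drop = FALSE]) else rep(0, nP)
    s <- stats::sd(proj)
    if (s == 0) rep(0, nP) else (proj - mean(proj)) / s
  }, numeric(nP))
  score <- if (length(drugs)) rowMeans(matrix(perDrug, nrow = nP)) else
    rep(0, nP)

  pPcr <- stats::plogis(config@responseIntercept +
                          config@responseSlope * score)
  response <- ifelse(rbinom(nP, 1L, pPcr) == 1L, "pCR", "RD")

  rate <- config@baselineHazard * exp(-config@hazardLogRatio * score)
  tEvent <- rexp(nP, rate)
  tCens <- if (config@censorRate > 0) rexp(nP, config@censorRate) else
    rep(Inf, nP)
  time <- pmin(tEvent, tCens)
  event <- as.integer(tEvent <= tCens)

  tn <- runif(nP) < 0.6  # synthetic TN subset of an all-ER- cohort
  cohort <- PatientCohort(ExpressionPanel(z), response = response,
                          time = time, event = event,
                          subtypes = list(er_neg = rep(TRUE, nP), tn = tn))
  truth@trueScore <- setNames(score, samples)
  truth@trueResponseProb <- setNames(pPcr, samples)
  list(cohort = cohort, truth = truth)
}
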