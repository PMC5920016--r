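# Evaluation of single-drug and combined predictors against pathological
# response and censored survival: rank-sum AUC, Wilcoxon test, top-fraction
# dichotomization, Kaplan-Meier curves, log-rank test, NPV and the
# multi-drug joint false-negative risk.

#' @importFrom survival Surv survfit survdiff
NULL

.asResponse01 <- function(labels) {
  if (is.factor(labels) || is.character(labels))
    ifelse(is.na(labels), NA_integer_, as.integer(labels == "pCR"))
  else as.integer(as.logical(as.numeric(labels)))
}

#' Rank-sum (Mann-Whitney) AUC
#'
#' The probability that a random responder outscores a random non-responder,
#' counting ties as 1/2: the Mann-Whitney U normalization.
#'
#' @param scores numeric prediction scores.
#' @param labels binary labels (factor `pCR`/`RD`, logical, or 0/1 with
#'   1 = pCR); missing labels are excluded.
#' @return AUC in `[0, 1]`.
#' @examples
#' computeAUC(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))  # 1
#' @export
computeAUC <- function(scores, labels) {
  y <- .asResponse01(labels)
  keep <- !is.na(y) & !is.na(scores)
  y <- y[keep]; s <- scores[keep]
  nPos <- sum(y == 1L); nNeg <- sum(y == 0L)
  if (nPos == 0L || nNeg == 0L)
    stop("undefined AUC: both classes must be present")
  r <- rank(s, ties.method = "average")
  u <- sum(r[y == 1L]) - nPos * (nPos + 1) / 2
  u / (nPos * nNeg)
}

#' Wilcoxon rank-sum test of scores between pCR and RD
#'
#' Two-sided by default. With combined n below 20 and no ties, the exact
#' permutation distribution is used; otherwise the normal approximation with
#' midrank ties and continuity correction. (With ties at small n the exact
#' permutation null is unavailable; the approximation branch is used.)
#'
#' @inheritParams computeAUC
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`.
#' @return List with `statistic` (Mann-Whitney U for the pCR group),
#'   `p.value`, and `exact` (logical branch flag).
#' @export
ranksumTest <- function(scores, labels, alternative = "two.sided") {
  y <- .asResponse01(labels)
  keep <- !is.na(y) & !is.na(scores)
  y <- y[keep]; s <- scores[keep]
  if (sum(y == 1L) == 0L || sum(y == 0L) == 0L)
    stop("test error: both classes must be present")
  n <- length(y)
  ties <- anyDuplicated(s) > 0L
  exact <- n < 20L && !ties
  wt <- suppressWarnings(stats::wilcox.test(
    s[y == 1L], s[y == 0L], alternative = alternative,
    exact = exact, correct = TRUE))
  list(statistic = unname(wt$statistic), p.value = wt$p.value, exact = exact)
}

#' Dichotomize patients at a top score fraction
#'
#' The `ceiling(fraction * n)` highest-scoring patients are called
#' COXEN-positive (predicted responders) and the rest COXEN-negative.
#' Boundary ties are resolved by deterministic sample-ID ordering so the
#' positive group always has exactly `ceiling(fraction * n)` members; a
#' warning notes when ties were broken this way.
#'
#' @param scores numeric scores, named by sample (or `sampleIds` given).
#' @param fraction top fraction in (0, 1); 0.30 is the conventional cutoff.
#' @param sampleIds sample identifiers (default `names(scores)`).
#' @return Named logical vector, `TRUE` = COXEN-positive.
#' @export
dichotomizeTopFraction <- function(scores, fraction = 0.30,
                                   sampleIds = names(scores)) {
  if (!(fraction > 0 && fraction < 1))
    stop("fraction must lie strictly between 0 and 1")
  n <- length(scores)
  if (is.null(sampleIds)) sampleIds <- as.character(seq_len(n))
  k <- ceiling(fraction * n)
  ord <- order(-scores, sampleIds)
  pos <- logical(n)
  pos[ord[seq_len(k)]] <- TRUE
  boundary <- scores[ord[k]]
  if (k < n && any(scores[!pos] == boundary))
    warning("ties at the cutoff boundary broken by sample-ID order")
  setNames(pos, sampleIds)
}

#' Kaplan-Meier estimate with per-group median survival
#'
#' Product-limit estimator per group. The median is the earliest time at
#' which the estimated survival drops to 0.5 or below; when a curve never
#' reaches 0.5 the median is `NA` and should be read as "> max follow-up"
#' (reported alongside).
#'
#' @param times non-negative survival times (months).
#' @param events 0/1 event indicators (1 = progression/relapse observed).
#' @param groups group labels (any vector; coerced to factor).
#' @return List with `curves` (a [S4Vectors::DataFrame] of group, time,
#'   nRisk, nEvent, nCensor, survival), `median` (named numeric, `NA` =
#'   undefined) and `maxFollowUp`.
#' @export
kmEstimate <- function(times, events, groups = rep("all", length(times))) {
  if (any(times < 0, na.rm = TRUE))
    stop("validation error: negative survival times")
  if (!all(events %in% c(0, 1)))
    stop("validation error: events must be 0/1")
  groups <- droplevels(as.factor(groups))
  fit <- survival::survfit(survival::Surv(times, events) ~ groups)
  if (nlevels(groups) > 1L) {
    strata <- rep(sub("^groups=", "", names(fit$strata)), fit$strata)
  } else {
    strata <- rep(levels(groups), length(fit$time))
  }
  curves <- S4Vectors::DataFrame(group = strata, time = fit$time,
                                 nRisk = fit$n.risk, nEvent = fit$n.event,
                                 nCensor = fit$n.censor,
                                 survival = fit$surv)
  med <- vapply(levels(groups), function(g) {
    cg <- curves[curves$group == g, ]
    hit <- which(cg$survival <= 0.5 + 1e-12)
    if (length(hit)) cg$time[min(hit)] else NA_real_
  }, numeric(1))
  list(curves = curves, median = med, maxFollowUp = max(times))
}

#' Two-group log-rank test
#'
#' Standard log-rank chi-square: observed minus expected events summed over
#' distinct event times with hypergeometric variance; p from chi-square with
#' 1 df. Exactly two groups are required.
#'
#' @inheritParams kmEstimate
#' @return List with `statistic`, `p.value`, `observed`, `expected` (per
#'   group).
#' @export
logrankTest <- function(times, events, groups) {
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) != 2L)
    stop("test error: exactly two non-empty groups required (got ",
         nlevels(groups), ")")
  if (any(times < 0, na.rm = TRUE))
    stop("validation error: negative survival times")
  sd <- survival::survdiff(survival::Surv(times, events) ~ groups)
  list(statistic = unname(sd$chisq),
       p.value = stats::pchisq(sd$chisq, df = 1L, lower.tail = FALSE),
       observed = setNames(as.numeric(sd$obs), levels(groups)),
       expected = setNames(as.numeric(sd$exp), levels(groups)))
}

#' Negative predictive value of the predicted-negative group
#'
#' NPV = fraction of COXEN-negative patients whose response is RD; `1 - NPV`
#' is the per-drug false-negative risk (responders the model would exclude).
#'
#' @param predictedPositive logical vector, `TRUE` = COXEN-positive.
#' @param labels response labels as in [computeAUC()]; missing excluded.
#' @return List with `npv`, `falseNegativeRisk` and `nNegative`.
#' @export
npv <- function(predictedPositive, labels) {
  y <- .asResponse01(labels)
  keep <- !is.na(y)
  neg <- !predictedPositive[keep]
  if (!any(neg)) stop("undefined NPV: no predicted-negative patients")
  val <- mean(y[keep][neg] == 0L)
  list(npv = val, falseNegativeRisk = 1 - val, nNegative = sum(neg))
}

#' Joint false-negative risk of independent predictors
#'
#' Under the documented independence assumption, the probability of falsely
#' predicting negatively for every one of several effective drugs is the
#' product of the per-drug false-negative probabilities (each `1 - NPV`):
#' two drugs at 0.30 each give 0.09.
#'
#' @param risks numeric per-drug false-negative probabilities in `[0, 1]`.
#' @return The product, with an `assumption` attribute.
#' @examples
#' jointFalseNegativeRisk(c(0.3, 0.3))  # 0.09
#' @export
jointFalseNegativeRisk <- function(risks) {
  if (any(risks < 0 | risks > 1))
    stop("validation error: probabilities must lie in [0, 1]")
  structure(prod(risks), assumption = "independent drug effects")
}

#' Evaluate one predictor on one cohort
#'
#' Applies an optional subtype filter, computes AUC and the rank-sum p on
#' pCR vs RD (patients with missing response excluded), dichotomizes at the
#' top cutoff fraction, runs Kaplan-Meier and log-rank when the cohort has a
#' survival channel (patients without response are retained there), and
#' reports the NPV of the COXEN-negative group. Fully deterministic and
#' invariant to patient ordering.
#'
#' @param scores numeric scores named by cohort sample IDs.
#' @param cohort a [PatientCohort].
#' @param subtype optional subtype flag name (e.g. `"er_neg"`, `"tn"`).
#' @param cutoffFraction top fraction called COXEN-positive (default 0.30).
#' @param predictorTag,cohortTag identifying strings for the report.
#' @return An [EvaluationReport-class].
#' @export
evaluatePredictor <- function(scores, cohort, subtype = NULL,
                              cutoffFraction = 0.30,
                              predictorTag = "predictor",
                              cohortTag = "cohort") {
  ids <- sampleIds(cohort)
  if (is.null(names(scores)))
    stop("scores must be named by cohort sample IDs")
  if (!all(ids %in% names(scores)))
    stop("misaligned IDs: scores missing for some cohort samples")
  scores <- scores[ids]
  keep <- rep(TRUE, length(ids))
  if (!is.null(subtype)) {
    flag <- subtypeFlags(cohort, subtype)
    if (is.null(flag)) stop("unknown subtype flag: ", subtype)
    keep <- flag
  }
  if (!any(keep)) stop("empty filtered cohort")
  ids <- ids[keep]
  s <- scores[ids]
  resp <- responseLabels(cohort)[ids]
  y <- .asResponse01(resp)

  aucVal <- computeAUC(s, resp)
  rsP <- ranksumTest(s, resp)$p.value
  pos <- dichotomizeTopFraction(s, cutoffFraction, ids)
  np <- npv(pos, resp)

  lrStat <- NA_real_; lrP <- NA_real_
  med <- c(positive = NA_real_, negative = NA_real_)
  maxFU <- NA_real_
  tm <- survivalTimes(cohort)
  if (!is.null(tm)) {
    tt <- tm[ids]; ev <- eventFlags(cohort)[ids]
    okS <- !is.na(tt) & !is.na(ev)
    grp <- factor(ifelse(pos, "positive", "negative"),
                  levels = c("negative", "positive"))
    km <- kmEstimate(tt[okS], ev[okS], grp[okS])
    med <- km$median[c("positive", "negative")]
    names(med) <- c("positive", "negative")
    maxFU <- km$maxFollowUp
    if (nlevels(droplevels(grp[okS])) == 2L) {
      lr <- logrankTest(tt[okS], ev[okS], grp[okS])
      lrStat <- lr$statistic; lrP <- lr$p.value
    }
  }

  methods::new("EvaluationReport", predictorTag = predictorTag,
               cohortTag = cohortTag,
               nPCR = sum(y == 1L, na.rm = TRUE),
               nRD = sum(y == 0L, na.rm = TRUE),
               auc = aucVal, ranksumP = rsP,
               cutoffFraction = cutoffFraction,
               groupSizes = c(positive = sum(pos),
                              negative = sum(!pos)),
               medianSurvival = med, maxFollowUp = maxFU,
               logrankStat = lrStat, logrankP = lrP,
               npv = np$npv, falseNegativeRisk = np$falseNegativeRisk)
}
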