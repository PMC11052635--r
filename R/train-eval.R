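# Repeated stratified cross-validation with pooled AUC, plus the
# omics-combination ablation harness.

#' Rank-based AUC with tie correction
#'
#' Mann-Whitney AUC: probability that a random positive outranks a random
#' negative, counting ties as 1/2 (midranks). Invariant under strictly
#' increasing transforms of the scores.
#'
#' @param scores numeric scores (higher = more positive).
#' @param labels binary labels (1 = positive class).
#' @return AUC in \[0, 1\].
#' @export
computeAUC <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Median split of risk scores into high/low-risk groups
#'
#' Group 1 (high risk) when the score is strictly greater than the median,
#' else group 0; with an odd sample count the median element goes to the low
#' group. All-equal scores produce a single (low) group with a warning.
#'
#' @param scores per-sample risk scores.
#' @param sampleIds optional ids to attach.
#' @return data.frame with sample_id (if given), score, group.
#' @export
stratifyRisk <- function(scores, sampleIds = NULL) {
  if (length(scores) < 2) stop("need >= 2 samples")
  grp <- as.integer(scores > median(scores))
  if (all(grp == 0L)) warning("all scores equal; single low-risk group")
  out <- data.frame(score = scores, group = grp)
  if (!is.null(sampleIds)) out <- cbind(sample_id = sampleIds, out)
  out
}

stratifiedFolds <- function(y, nFolds, seed) {
  withSeed(seed, {
    fold <- integer(length(y))
    for (cls in unique(y)) {
      ix <- sample(which(y == cls))
      fold[ix] <- rep_len(seq_len(nFolds), length(ix))
    }
    fold
  })
}

assertFoldIsolation <- function(usedIds, testIds, what) {
  leaked <- intersect(usedIds, testIds)
  if (length(leaked))
    stop("fold-isolation violation: ", what, " touched ", length(leaked),
         " test sample(s), e.g. ", leaked[1])
  invisible(TRUE)
}

# fit one fold: selection, graph, model, training -- all on trainIdx only.
# `leak` (internal, negative-control) widens the selection sample set to the
# full cohort so the isolation assertion must trip.
fitFold <- function(cohort, network, pathways, config, trainIdx, testIds,
                    omics, seed, leak = FALSE, selCache = NULL) {
  selIdx <- if (leak) seq_along(cohortLabels(cohort)) else trainIdx
  key <- paste0(seed, ":", paste(selIdx, collapse = ","))
  sel <- if (!is.null(selCache) && !is.null(selCache[[key]])) selCache[[key]]
  else selectFeatures(cohort, selIdx, k = config$mi_k %||% 3L,
                      jitterSeed = seed)
  if (!is.null(selCache)) selCache[[key]] <- sel
  assertFoldIsolation(attr(sel, "samples_used"), testIds, "MI feature selection")
  keptLists <- sel$kept[intersect(omics, names(sel$kept))]
  graph <- buildGuidanceGraph(network, keptLists)
  cfg <- config
  cfg$mi_k <- NULL
  model <- buildModel(graph, cohort, pathways, sel, cfg,
                      trainIdx = trainIdx, seed = deriveSeed(seed, 23L))
  assertFoldIsolation(attr(model, "samples_used"), testIds,
                      "PCA initializers / pathway order / age standardization")
  model <- trainModel(model, cohort, trainIdx, seed = deriveSeed(seed, 29L))
  assertFoldIsolation(attr(model, "samples_used"), testIds, "model training")
  model
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Repeated stratified k-fold cross-validation with pooled AUC
#'
#' Per repeat, samples are split into stratified folds; for each fold the
#' mutual-information feature selection, guidance graph, PCA initializers,
#' pathway ordering and age standardization are fitted on the training folds
#' only, the model is trained, and the held-out fold is scored with the
#' probability of the non-LTS (high-risk) class. Test scores are pooled
#' across the folds of a repeat before computing the AUC, and the mean and sd
#' over repeats are reported.
#'
#' @param cohort labeled [MultiOmicsCohort-class].
#' @param network RegulatoryNetwork (raw scores; normalized internally).
#' @param pathways a [PathwayMap-class].
#' @param config model configuration list (may also carry `mi_k`).
#' @param nFolds folds per repeat (default 5).
#' @param nRepeats number of repeats (the reference protocol uses 30).
#' @param seed master seed; per-repeat seeds are derived deterministically.
#' @param omics omics layers to use; must include "mRNA".
#' @param leak internal negative control: fit feature selection on all
#'   samples so the fold-isolation assertion trips.
#' @param selCache optional environment memoizing per-fold feature
#'   selections across calls that share folds (used by the ablation harness,
#'   where the per-omics MI does not depend on the combination).
#' @return object of class "CVResult": list with `auc` (per-repeat pooled
#'   AUC), `mean`, `sd`, and `scores` (per repeat, pooled sample scores and
#'   labels).
#' @export
crossValidate <- function(cohort, network, pathways, config = list(),
                          nFolds = 5L, nRepeats = 5L, seed = 1L,
                          omics = names(cohort@assays), leak = FALSE,
                          selCache = NULL) {
  if (!"mRNA" %in% omics) stop("omics must include mRNA")
  if (nFolds < 2) stop("nFolds must be >= 2")
  y <- cohortLabels(cohort)
  if (length(unique(y)) < 2) stop("both classes must be present")
  network <- normalizeTFWeights(network)
  sids <- sampleIds(cohort)
  aucs <- numeric(nRepeats)
  scoreTabs <- vector("list", nRepeats)
  for (rep in seq_len(nRepeats)) {
    rseed <- deriveSeed(seed, rep)
    fold <- stratifiedFolds(y, nFolds, rseed)
    scores <- numeric(length(y))
    for (f in seq_len(nFolds)) {
      testIdx <- which(fold == f)
      trainIdx <- which(fold != f)
      if (length(unique(y[trainIdx])) < 2 || length(unique(y[testIdx])) < 1)
        stop("fold lacking a class; use stratified folds with more samples")
      model <- fitFold(cohort, network, pathways, mergeConfigCV(config),
                       trainIdx, sids[testIdx], omics,
                       seed = deriveSeed(rseed, 1000L + f), leak = leak,
                       selCache = selCache)
      pr <- predictRisk(model, cohort, testIdx)
      scores[testIdx] <- pr$score
    }
    aucs[rep] <- computeAUC(scores, 1L - y)  # positive class: non-LTS
    scoreTabs[[rep]] <- data.frame(repeat_ = rep, sample_id = sids,
                                   score = scores, label = y)
  }
  out <- list(auc = aucs, mean = mean(aucs), sd = stats::sd(aucs),
              nFolds = nFolds, nRepeats = nRepeats,
              scores = do.call(rbind, scoreTabs))
  class(out) <- "CVResult"
  out
}

# config may carry mi_k on top of model config keys
mergeConfigCV <- function(config) {
  mi_k <- config$mi_k
  config$mi_k <- NULL
  cfg <- mergeConfig(config)
  cfg$mi_k <- mi_k %||% 3L
  cfg
}

#' @export
print.CVResult <- function(x, ...) {
  cat(sprintf("CVResult: %d x %d-fold CV, pooled AUC %.3f +/- %.3f\n",
              x$nRepeats, x$nFolds, x$mean, x$sd))
  invisible(x)
}

#' Omics-combination ablation
#'
#' Re-runs the full cross-validation for each omics combination. mRNA must be
#' present in every combination (it is the bridge layer of the guidance
#' graph): a combination without it is an error. The guidance graph of a
#' combination keeps only nodes/edges among the included omics; mutual
#' information selections are shared across combinations within a fold since
#' they are computed per omics independently.
#'
#' @param cohort labeled [MultiOmicsCohort-class].
#' @param network RegulatoryNetwork.
#' @param pathways a [PathwayMap-class].
#' @param config model configuration.
#' @param combos list of character vectors of omics names.
#' @param nFolds,nRepeats,seed as in [crossValidate()].
#' @return data.frame with one row per combination: combo, mean_auc, sd_auc.
#'   Per-combination CVResult objects in attribute `results`.
#' @export
runOmicsAblation <- function(cohort, network, pathways, config = list(),
                             combos = list("mRNA", c("mRNA", "CNV"),
                                           c("mRNA", "MT"),
                                           c("mRNA", "CNV", "MT")),
                             nFolds = 5L, nRepeats = 5L, seed = 1L) {
  for (cb in combos)
    if (!"mRNA" %in% cb) stop("every omics combination must include mRNA")
  selCache <- new.env(parent = emptyenv())
  results <- lapply(combos, function(cb)
    crossValidate(cohort, network, pathways, config, nFolds = nFolds,
                  nRepeats = nRepeats, seed = seed, omics = cb,
                  selCache = selCache))
  tab <- data.frame(
    combo = vapply(combos, paste, "", collapse = "+"),
    mean_auc = vapply(results, `[[`, 0, "mean"),
    sd_auc = vapply(results, `[[`, 0, "sd"))
  attr(tab, "results") <- results
  tab
}
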