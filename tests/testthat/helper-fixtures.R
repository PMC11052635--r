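# Shared fixtures, built in code and memoized for the test run.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

# small planted cohort: fast to select/build/train, still end-to-end
smallSpec <- function(seed = 3, effect = 3) {
  syntheticSpec(n_samples = 60, n_genes = 80, n_tfs = 6, n_pathways = 8,
                pathway_size = c(6L, 15L), n_informative = 15, n_drivers = 3,
                effect_size = effect, seed = seed)
}

smallSim <- function() memo("smallSim", generateCohort(smallSpec()))

smallCohort <- function() memo("smallCohort", labelCohort(smallSim()$cohort, 2))

smallSelection <- function() memo("smallSelection", {
  selectFeatures(smallCohort(), k = 3)
})

smallGraph <- function() memo("smallGraph", {
  buildGuidanceGraph(normalizeTFWeights(smallSim()$network), smallSelection()$kept)
})

smallConfig <- function() list(D = 4L, M_dims = 2L, hidden = 8L, epochs = 25L,
                               batch_size = 16L)

smallModel <- function() memo("smallModel", {
  buildModel(smallGraph(), smallCohort(), smallSim()$pathways,
             smallSelection(), smallConfig(), seed = 7)
})

# trained on all small-cohort samples (checkpoint used by explainer tests)
smallTrained <- function() memo("smallTrained", {
  trainModel(smallModel(), smallCohort(), seed = 5)
})

# smaller trained checkpoint (D = 2): few ReLU units, so the midpoint-rule
# path integral of the attribution is nearly exact
tinyTrained <- function() memo("tinyTrained", {
  m <- buildModel(smallGraph(), smallCohort(), smallSim()$pathways,
                  smallSelection(),
                  list(D = 2L, M_dims = 1L, hidden = 4L, epochs = 15L,
                       batch_size = 16L), seed = 7)
  trainModel(m, smallCohort(), seed = 5)
})

# tiny hand-written guidance graph: path graph over mRNA nodes
pathGraphFixture <- function(nGenes = 6) {
  genes <- paste0("G", seq_len(nGenes))
  net <- data.frame(tf = genes[-nGenes], target = genes[-1],
                    score = rep(1, nGenes - 1))
  class(net) <- c("RegulatoryNetwork", "data.frame")
  attr(net, "normalized") <- TRUE
  buildGuidanceGraph(net, list(mRNA = genes))
}

# exhaustive pairwise AUC oracle (ties count 1/2)
bruteForceAUC <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# chain objective of a pathway ordering: sum of similarities of neighbors
chainObjective <- function(ord, S) {
  sum(S[cbind(ord[-length(ord)], ord[-1])])
}

# all permutations of a small vector
permsOf <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v))
    for (p in permsOf(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
  out
}
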