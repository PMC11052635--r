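test_that("rank-based AUC matches its oracles and conventions", {
  expect_equal(computeAUC(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1)), 1)
  expect_equal(computeAUC(rep(0.5, 6), c(0, 1, 0, 1, 0, 1)), 0.5)
  expect_error(computeAUC(1:4, rep(1, 4)), "both classes")
  # 6-point toy set with ties vs exhaustive pair counting
  s <- c(0.3, 0.3, 0.7, 0.1, 0.7, 0.5)
  l <- c(0, 1, 1, 0, 0, 1)
  expect_equal(computeAUC(s, l), bruteForceAUC(s, l))
})

test_that("AUC equals exhaustive pair counting on random tied sets", {
  withr::local_seed(21)
  for (i in 1:50) {
    n <- sample(4:8, 1)
    l <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    s <- sample(seq(0, 1, 0.25), n, replace = TRUE)  # heavy ties
    expect_equal(computeAUC(s, l), bruteForceAUC(s, l))
  }
})

test_that("AUC is invariant under strictly increasing transforms", {
  withr::local_seed(22)
  s <- rnorm(40); l <- rbinom(40, 1, 0.4)
  a <- computeAUC(s, l)
  expect_identical(computeAUC(exp(s), l), a)
  expect_identical(computeAUC(3 * s + 10, l), a)
})

test_that("median risk split follows the strict-greater convention", {
  expect_identical(stratifyRisk(c(0.1, 0.4, 0.6, 0.9))$group, c(0L, 0L, 1L, 1L))
  # odd n: the median element goes to the low group
  expect_identical(stratifyRisk(c(0.2, 0.5, 0.8))$group, c(0L, 0L, 1L))
  expect_warning(g <- stratifyRisk(rep(0.5, 4)), "all scores equal")
  expect_identical(g$group, rep(0L, 4))
  expect_error(stratifyRisk(0.5), ">= 2")
})

test_that("stratified folds partition every sample exactly once per repeat", {
  y <- rep(c(0L, 1L), c(30, 12))
  fold <- mlgnn:::stratifiedFolds(y, 5, seed = 3)
  expect_identical(sort(unique(fold)), 1:5)
  expect_identical(length(fold), length(y))
  for (f in 1:5) expect_true(all(table(y[fold == f]) >= 2))
  # every sample in exactly one fold is implied by fold being a total labeling
  expect_false(anyNA(fold))
})

test_that("cross-validation pools every sample once and is reproducible", {
  sim <- smallSim()
  coh <- smallCohort()
  cfg <- c(smallConfig(), list(epochs = 6L))
  cv <- crossValidate(coh, sim$network, sim$pathways, cfg,
                      nFolds = 3, nRepeats = 2, seed = 31)
  expect_s3_class(cv, "CVResult")
  expect_length(cv$auc, 2)
  expect_true(all(cv$auc >= 0 & cv$auc <= 1))
  sc <- cv$scores
  expect_identical(nrow(sc), 2L * length(cohortLabels(coh)))
  expect_identical(sort(unique(sc$sample_id)), sort(sampleIds(coh)))
  # bit-reproducible under the same master seed
  cv2 <- crossValidate(coh, sim$network, sim$pathways, cfg,
                       nFolds = 3, nRepeats = 2, seed = 31)
  expect_identical(cv$auc, cv2$auc)
  expect_identical(cv$scores$score, cv2$scores$score)
  # mean/sd are over per-repeat pooled AUCs
  expect_equal(cv$mean, mean(cv$auc))
  expect_equal(cv$sd, sd(cv$auc))
})

test_that("an intentionally leaky run trips the fold-isolation assertion", {
  sim <- smallSim()
  coh <- smallCohort()
  cfg <- c(smallConfig(), list(epochs = 2L))
  expect_error(
    crossValidate(coh, sim$network, sim$pathways, cfg,
                  nFolds = 3, nRepeats = 1, seed = 32, leak = TRUE),
    "fold-isolation violation.*feature selection")
})

test_that("omics ablation requires mRNA and reports one row per combination", {
  sim <- smallSim()
  coh <- smallCohort()
  expect_error(
    runOmicsAblation(coh, sim$network, sim$pathways, combos = list(c("CNV", "MT"))),
    "must include mRNA")
  cfg <- c(smallConfig(), list(epochs = 4L))
  tab <- runOmicsAblation(coh, sim$network, sim$pathways, cfg,
                          combos = list("mRNA", c("mRNA", "CNV")),
                          nFolds = 3, nRepeats = 1, seed = 33)
  expect_identical(tab$combo, c("mRNA", "mRNA+CNV"))
  expect_true(all(tab$mean_auc >= 0 & tab$mean_auc <= 1))
})

test_that("single-omics guidance graphs contain only mRNA nodes and edges", {
  sim <- smallSim()
  sel <- smallSelection()
  net <- normalizeTFWeights(sim$network)
  g1 <- buildGuidanceGraph(net, sel$kept["mRNA"])
  expect_true(all(graphNodes(g1)$omics == "mRNA"))
  expect_true(all(graphEdges(g1)$type == "mRNA"))
  g2 <- buildGuidanceGraph(net, sel$kept[c("mRNA", "CNV")])
  expect_identical(sum(graphNodes(g2)$omics == "MT"), 0L)
  expect_identical(sum(graphEdges(g2)$type == "MM"), 0L)
})
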