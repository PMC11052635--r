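test_that("the generator is bit-reproducible per seed", {
  s1 <- generateCohort(smallSpec(seed = 17))
  s2 <- generateCohort(smallSpec(seed = 17))
  expect_identical(s1$cohort@assays, s2$cohort@assays)
  expect_identical(s1$network, s2$network)
  expect_identical(s1$truth, s2$truth)
  s3 <- generateCohort(smallSpec(seed = 18))
  expect_false(identical(s1$cohort@assays$mRNA, s3$cohort@assays$mRNA))
  # written artifacts are byte-identical too
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  writeCohort(s1, d1); writeCohort(s2, d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
})

test_that("spec validation rejects infeasible settings", {
  expect_error(syntheticSpec(n_genes = 30, n_informative = 5, n_tfs = 5,
                             pathway_size = c(10, 40)), "infeasible")
  expect_error(syntheticSpec(n_informative = 50, n_genes = 40), "n_informative")
  expect_error(syntheticSpec(effect_size = -1), "effect_size")
})

test_that("methylation is anticorrelated and CNV correlated with expression", {
  sim <- smallSim()
  a <- sim$cohort@assays
  corMT <- vapply(seq_len(ncol(a$mRNA)), function(j)
    cor(a$mRNA[, j], a$MT[, j]), 0)
  corCNV <- vapply(seq_len(ncol(a$mRNA)), function(j)
    cor(a$mRNA[, j], a$CNV[, j]), 0)
  expect_lt(mean(corMT), -0.3)
  expect_gt(mean(corCNV), 0.3)
})

test_that("survival labels give the intended class balance within binomial noise", {
  sim <- generateCohort(syntheticSpec(n_samples = 400, seed = 23))
  lab <- makeLabels(sim$clinical, 2)
  frac <- mean(lab$label)
  # construction centers the median survival at the threshold
  expect_gt(frac, 0.5 - 3 * sqrt(0.25 / length(lab$label)) - 0.05)
  expect_lt(frac, 0.5 + 3 * sqrt(0.25 / length(lab$label)) + 0.05)
  # censor rate roughly as configured
  expect_lt(mean(1 - sim$clinical$event), 0.25)
})

test_that("informative genes are clustered inside the driver pathways", {
  sim <- smallSim()
  pg <- pathwayGenes(sim$pathways)
  inDrivers <- unlist(pg[sim$truth$drivers])
  expect_true(all(sim$truth$informative_all %in% inDrivers))
})

test_that("the written cohort round-trips through the readers", {
  sim <- smallSim()
  d <- withr::local_tempdir()
  writeCohort(sim, d)
  back <- readCohortDir(d)
  expect_equal(unclass(back$cohort@assays$mRNA), sim$cohort@assays$mRNA,
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_identical(pathwayIds(back$pathways), pathwayIds(sim$pathways))
  expect_equal(back$network$score, sim$network$score, tolerance = 1e-12)
})

test_that("stronger planted effects raise the informative genes' MI", {
  # needs a few hundred samples: the kNN estimator's noise at n ~ 60 is
  # larger than the MI differences between adjacent effect levels
  miOf <- function(effect) {
    sim <- generateCohort(syntheticSpec(
      n_samples = 240, n_genes = 60, n_tfs = 5, n_pathways = 6,
      pathway_size = c(5L, 12L), n_informative = 15, n_drivers = 3,
      effect_size = effect, seed = 29))
    coh <- labelCohort(sim$cohort, 2)
    y <- cohortLabels(coh)
    inf <- sim$truth$informative$mRNA
    mean(vapply(inf, function(g)
      as.numeric(miDiscreteContinuous(omicsAssays(coh, "mRNA")[, g], y, 3)), 0))
  }
  m0 <- miOf(0); m1 <- miOf(1.5); m2 <- miOf(4)
  expect_lt(m0, m1)
  expect_lt(m1, m2)
})

test_that("recovery metrics are bounded and match trivial oracles", {
  sim <- smallSim()
  sel <- smallSelection()
  # perfect identification -> recall 1
  perfect <- list(kept = sim$truth$informative)
  rep1 <- recoveryReport(sim$truth, selection = perfect)
  expect_equal(unname(rep1$mi_recall_mean), 1)
  rep2 <- recoveryReport(sim$truth, selection = sel)
  expect_true(all(unlist(rep2) >= 0 & unlist(rep2) <= 1))
  # random importance: top-decile recall near the 10% chance level
  withr::local_seed(31)
  genes <- colnames(sim$cohort@assays$mRNA)
  hits <- replicate(60, {
    fake <- data.frame(gene = genes, omics = "mRNA",
                       importance = rnorm(length(genes)))
    fake$rank <- rank(-fake$importance)
    r <- recoveryReport(sim$truth, geneImp = fake)
    r$explainer_top_decile_recall[["mRNA"]]
  })
  expect_lt(abs(mean(hits) - 0.1), 0.1)
  # mismatched truth errors
  fake <- data.frame(gene = c("zz1", "zz2"), omics = "mRNA",
                     importance = c(1, 2), rank = c(1, 2))
  expect_error(recoveryReport(sim$truth, geneImp = fake), "mismatch")
})
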