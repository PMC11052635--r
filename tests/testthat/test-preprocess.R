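test_that("long-term-survivor labels follow the threshold and censoring rules", {
  yr <- 365.25
  cl <- data.frame(sample_id = c("a", "b", "c", "d"),
                   survival_time = c(3 * yr, 1 * yr, 1.5 * yr, 2.5 * yr),
                   event = c(0L, 1L, 0L, 1L))
  lab <- makeLabels(cl, 2)
  expect_identical(lab$sample_id, c("a", "b", "d"))
  expect_identical(lab$label, c(1L, 0L, 1L))       # survivor past threshold is LTS
  expect_identical(lab$excluded, "c")              # short censored follow-up dropped
  expect_error(makeLabels(cl[3, ], 2), "no samples")
})

test_that("labelCohort subsets assays and clinical consistently", {
  coh <- smallCohort()
  expect_identical(length(cohortLabels(coh)), nrow(omicsAssays(coh, "mRNA")))
  expect_identical(clinicalTable(coh)$sample_id, sampleIds(coh))
  expect_true(all(cohortLabels(coh) %in% 0:1))
})

test_that("the kNN MI estimator matches its closed-form oracles", {
  withr::local_seed(1)
  n <- 800
  y <- rep(0:1, each = n / 2)
  # independent: MI = 0
  x <- rnorm(n)
  expect_lt(abs(attr(miDiscreteContinuous(x, y, 3), "raw")), 0.06)
  # disjoint supports: MI = label entropy = ln 2
  x2 <- ifelse(y == 0, runif(n), 10 + runif(n))
  expect_equal(as.numeric(miDiscreteContinuous(x2, y, 3)), log(2),
               tolerance = 0.06)
  # preconditions
  expect_error(miDiscreteContinuous(rnorm(3), c(0, 1, 1), 3), "more than k")
  expect_error(miDiscreteContinuous(rnorm(10), c(0, rep(1, 9)), 3),
               "class '0' has <= k")
})

test_that("MI is invariant to strictly monotone transforms and clipped at 0", {
  withr::local_seed(2)
  n <- 1000
  y <- rep(0:1, each = n / 2)
  x <- rnorm(n) + 0.8 * y
  m1 <- as.numeric(miDiscreteContinuous(x, y, 3))
  m2 <- as.numeric(miDiscreteContinuous(exp(x), y, 3))
  expect_lt(abs(m1 - m2), 0.05)
  # independence: clipped estimate >= 0, raw value possibly slightly negative
  for (s in 1:5) {
    withr::local_seed(s)
    mi <- miDiscreteContinuous(rnorm(300), rep(0:1, 150), 3)
    expect_gte(as.numeric(mi), 0)
    expect_gt(attr(mi, "raw"), -0.1)
  }
})

test_that("feature selection applies the strict mean-MI rule per omics", {
  coh <- smallCohort()
  sel <- smallSelection()
  for (om in names(sel$tables)) {
    tab <- sel$tables[[om]]
    expect_identical(tab$kept, tab$mi > mean(tab$mi))
    expect_gt(sum(tab$kept), 0)
    expect_identical(sel$kept[[om]], tab$gene[tab$kept])
  }
  expect_identical(attr(sel, "samples_used"), sampleIds(coh))
})

test_that("planted informative genes are retained above the background rate", {
  sim <- smallSim()
  sel <- smallSelection()
  for (om in names(sim$truth$informative)) {
    inf <- sim$truth$informative[[om]]
    bg <- setdiff(sel$tables[[om]]$gene, inf)
    rateInf <- mean(inf %in% sel$kept[[om]])
    rateBg <- mean(bg %in% sel$kept[[om]])
    expect_gt(rateInf, rateBg)
  }
})

test_that("selection on permuted labels keeps roughly the chance fraction", {
  sim <- smallSim()
  coh <- smallCohort()
  permuted <- coh
  permuted@labels <- withr::with_seed(99, sample(coh@labels))
  sel <- selectFeatures(permuted, k = 3)
  # no informative enrichment: informative recall comparable to overall rate
  om <- "mRNA"
  overall <- mean(sel$tables[[om]]$kept)
  inf <- sim$truth$informative[[om]]
  recall <- mean(inf %in% sel$kept[[om]])
  expect_lt(abs(recall - overall), 0.45)
})

test_that("all-equal MI values give an empty selection error", {
  coh <- smallCohort()
  const <- coh
  # constant matrices: every MI is 0, strict mean rule keeps nothing
  const@assays <- lapply(coh@assays, function(a) { a[] <- 1; a })
  expect_error(selectFeatures(const, k = 3), "retained no genes")
})

test_that("selection serializes to an auditable TSV", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeFeatureSelection(smallSelection(), f)
  tab <- read.delim(f)
  expect_identical(names(tab), c("omics", "gene", "mi", "kept"))
  expect_setequal(unique(tab$omics), c("mRNA", "CNV", "MT"))
})
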