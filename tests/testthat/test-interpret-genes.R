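test_that("explainer loss at mask init matches the hand-computed penalty", {
  V <- 10L; B <- 2L
  sig <- matrix(0.5, V, B)  # raw mask 0 -> sigma = 0.5 everywhere
  probs <- matrix(0.5, 2, B)
  cfg <- explainerConfig(alpha = 0, beta = 0.02, gamma = 0)
  expect_equal(mlgnn:::explainerLoss(probs, c(0L, 1L), sig, cfg),
               0.02 * 0.5 * V * B)
  # entropy penalty is maximal at sigma = 0.5 and shrinks toward binary masks
  cfgH <- explainerConfig(alpha = 0, beta = 0, gamma = 1)
  lHalf <- mlgnn:::explainerLoss(probs, c(0L, 1L), sig, cfgH)
  lBin <- mlgnn:::explainerLoss(probs, c(0L, 1L),
                                matrix(c(0.98, 0.02), V, B), cfgH)
  expect_gt(lHalf, lBin)
  expect_equal(lHalf, log(2) * V * B, tolerance = 1e-12)
})

test_that("explainer config validates its coefficients", {
  expect_error(explainerConfig(alpha = -1), "alpha")
  expect_error(explainerConfig(steps = 0), "steps")
})

test_that("mask optimization reduces the prediction term on the explained class", {
  model <- smallTrained()
  coh <- smallCohort()
  cfg <- explainerConfig(beta = 0, gamma = 0, steps = 40, lr = 0.05)
  masks <- optimizeNodeMask(model, coh, 1:8, cfg)
  tr <- attr(masks, "lossTrace")
  expect_lt(tr[length(tr)], tr[1] + 1e-8)
  expect_true(all(masks > 0 & masks < 1))
})

test_that("masks recover nodes the planted signal flows through", {
  model <- smallTrained()
  coh <- smallCohort()
  sim <- smallSim()
  masks <- optimizeNodeMask(model, coh, seq_along(cohortLabels(coh)),
                            explainerConfig(steps = 120, lr = 0.05))
  imp <- geneImportance(masks, model@graph)
  # planted genes rank above the median background gene in their omics
  for (om in names(sim$truth$informative)) {
    d <- imp[imp$omics == om, ]
    inf <- intersect(sim$truth$informative[[om]], d$gene)
    skip_if(length(inf) == 0)
    expect_lt(mean(d$rank[d$gene %in% inf]), median(d$rank))
  }
})

test_that("explanations are class-conditional", {
  model <- smallTrained()
  coh <- smallCohort()
  cfg <- explainerConfig(steps = 25, lr = 0.05)
  m0 <- optimizeNodeMask(model, coh, 1:4, cfg, target = rep(0L, 4))
  m1 <- optimizeNodeMask(model, coh, 1:4, cfg, target = rep(1L, 4))
  expect_gt(max(abs(m0 - m1)), 1e-4)
})

test_that("gene importance is the across-sample mean of within-omics z-scores", {
  g <- smallGraph()
  V <- nrow(graphNodes(g))
  withr::local_seed(41)
  onemask <- matrix(runif(V), V, 1)
  masks <- cbind(onemask, onemask)  # two identical samples
  imp <- geneImportance(masks, g)
  z <- attr(imp, "zPerSample")
  nodes <- graphNodes(g)
  for (om in unique(nodes$omics)) {
    sel <- nodes$omics == om
    expect_equal(mean(z[sel, 1]), 0, tolerance = 1e-10)
    expect_equal(sd(z[sel, 1]), 1, tolerance = 1e-6)
  }
  # identical samples: importance equals the single z-scored mask, per node
  key <- paste(nodes$gene, nodes$omics)
  expect_equal(imp$importance,
               z[match(paste(imp$gene, imp$omics), key), 1],
               tolerance = 1e-12)
  # degenerate sample: constant mask -> z = 0 with a warning
  masks2 <- masks
  masks2[, 2] <- 0.5
  w <- capture_warnings(imp2 <- geneImportance(masks2, g))
  expect_true(any(grepl("zero mask variance", w)))
  expect_true(all(is.finite(imp2$importance)))
})

test_that("mean-importance split behaves per convention", {
  sp <- importanceGroupSplit(c(1, 2, 3, 4), c("a", "b", "c", "d"))
  expect_identical(sp$group, c(0L, 0L, 1L, 1L))
  expect_identical(importanceGroupSplit(c(1, 2, 3, 4))$group,
                   importanceGroupSplit(c(1, 2, 3, 4) + 100)$group)
  expect_warning(importanceGroupSplit(rep(2, 3)), "degenerate")
  expect_error(importanceGroupSplit(1), ">= 2")
})

test_that("gene importance export carries the expected schema", {
  model <- smallTrained()
  coh <- smallCohort()
  masks <- optimizeNodeMask(model, coh, 1:6, explainerConfig(steps = 5))
  imp <- geneImportance(masks, model@graph)
  f <- withr::local_tempfile(fileext = ".tsv")
  writeGeneImportance(imp, f, top = 3)
  tab <- read.delim(f)
  expect_identical(names(tab),
                   c("gene", "omics", "importance", "rank", "p_value",
                     "adjusted_p_value"))
  expect_true(all(table(tab$omics) <= 3))
})
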