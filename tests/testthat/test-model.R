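test_that("embedding initialization is seeded and validated", {
  g <- smallGraph()
  e1 <- initEmbeddings(g, 4, seed = 10)
  e2 <- initEmbeddings(g, 4, seed = 10)
  e3 <- initEmbeddings(g, 4, seed = 11)
  expect_identical(e1, e2)
  expect_false(identical(e1, e3))
  expect_identical(dim(e1), c(nrow(graphNodes(g)), 4L))
  expect_error(initEmbeddings(g, 0), "D must be >= 1")
})

test_that("PCA initializer reproduces an independent eigendecomposition", {
  withr::local_seed(4)
  X <- matrix(rnorm(30 * 6), 30, 6)
  pca <- fitPCAInitializer(X, 2)
  # oracle: eigendecomposition of the covariance matrix
  Xc <- scale(X, center = TRUE, scale = FALSE)
  ev <- eigen(cov(Xc))
  for (j in 1:2) {
    v <- ev$vectors[, j]
    scoresOracle <- Xc %*% v
    agree <- min(max(abs(pca$scores[, j] - scoresOracle)),
                 max(abs(pca$scores[, j] + scoresOracle)))  # up to sign
    expect_lt(agree, 1e-6)
  }
  # p_origin = P (X - center) reproduces the scores
  rep <- t(pca$P %*% t(Xc))
  expect_equal(unname(rep), unname(pca$scores), tolerance = 1e-9)
})

test_that("rank-1 data yields the single singular direction and full variance", {
  withr::local_seed(5)
  u <- rnorm(20); v <- rnorm(4)
  X <- outer(u, v)
  pca <- fitPCAInitializer(X, 1)
  projVar <- var(pca$scores[, 1])
  totVar <- sum(apply(X, 2, var))
  expect_equal(projVar, totVar, tolerance = 1e-8)
  expect_error(fitPCAInitializer(X, 5), "mDims")
  expect_error(fitPCAInitializer(X[, integer(0), drop = FALSE], 1), "no genes")
})

test_that("cosine independence penalty follows the |cos| pair convention", {
  expect_equal(cosineIndependenceLoss(rbind(c(1, 0), c(0, 1))), 0)
  expect_equal(cosineIndependenceLoss(rbind(c(1, 0), c(1, 0))), 1)
  expect_equal(cosineIndependenceLoss(rbind(c(1, 0), c(-1, 0))), 1)
  # zero row: its pairs contribute 0
  expect_equal(cosineIndependenceLoss(rbind(c(0, 0), c(1, 0))), 0)
  expect_error(cosineIndependenceLoss(matrix(1, 1, 3)), ">= 2 rows")
  # three rows: sum over the 3 unordered pairs
  W <- rbind(c(1, 0), c(1, 1), c(0, 1))
  expect_equal(cosineIndependenceLoss(W), 2 / sqrt(2))
})

test_that("analytic gradients match finite differences on a jittered model", {
  model <- smallModel()
  coh <- smallCohort()
  withr::local_seed(8)
  params <- lapply(model@params, function(p) p + rnorm(length(p), sd = 1e-3))
  X <- makeNodeInputs(model@graph, coh, 1:6)
  kop <- mlgnn:::kronOp(graphOperator(model@graph), 6)
  ageStd <- (clinicalTable(coh)$age[1:6] - model@ageStats["mean"]) /
    model@ageStats["sd"]
  y <- cohortLabels(coh)[1:6]
  lg <- mlgnn:::lossAndGrads(model, params, kop, X, ageStd, y)
  lossAt <- function(p) mlgnn:::lossAndGrads(model, p, kop, X, ageStd, y)$loss
  eps <- 1e-6
  for (nm in c("E", "W1", "b2", "V1", "V2",
               grep("^(Wp|U1|U2|c1)", names(params), value = TRUE)[c(1, 5, 9, 13)])) {
    p0 <- params[[nm]]
    idx <- if (length(p0) > 4) round(seq(1, length(p0), length.out = 4)) else seq_along(p0)
    for (i in idx) {
      pp <- params; pp[[nm]][i] <- pp[[nm]][i] + eps
      pm <- params; pm[[nm]][i] <- pm[[nm]][i] - eps
      num <- (lossAt(pp) - lossAt(pm)) / (2 * eps)
      expect_equal(lg$grads[[nm]][i], num, tolerance = 1e-3,
                   label = paste("grad", nm, i))
    }
  }
})

test_that("gradients flow to every parameter group", {
  model <- smallModel()
  coh <- smallCohort()
  X <- makeNodeInputs(model@graph, coh, 1:10)
  kop <- mlgnn:::kronOp(graphOperator(model@graph), 10)
  ageStd <- rep(0, 10)
  lg <- mlgnn:::lossAndGrads(model, model@params, kop, X, ageStd,
                             cohortLabels(coh)[1:10])
  norms <- vapply(lg$grads, function(g) sqrt(sum(g^2)), 0)
  for (grp in c("E", "W1", "W2", "V1", "V2"))
    expect_gt(norms[[grp]], 0)
  expect_gt(sum(norms[grep("^Wp", names(norms))]), 0)
  expect_gt(sum(norms[grep("^U1", names(norms))]), 0)
})

test_that("encoder is local: zero input gives zero features, isolated nodes see nothing", {
  g <- pathGraphFixture(6)
  V <- nrow(graphNodes(g))
  emb <- initEmbeddings(g, 3, seed = 2)
  x <- rnorm(V)
  x[2] <- 0
  enc <- geneEncode(g, x, emb, seed = 3)
  expect_equal(enc$S[2, , 1], rep(0, 3))
  # an isolated extra node: only its own input matters
  gi <- buildGuidanceGraph(structure(data.frame(tf = "G1", target = "G2", score = 1),
                                     class = c("RegulatoryNetwork", "data.frame"),
                                     normalized = TRUE),
                           list(mRNA = c("G1", "G2", "LONER")))
  embi <- initEmbeddings(gi, 3, seed = 2)
  xa <- c(1, 2, 3); xb <- c(5, -4, 3)  # loner input unchanged
  za <- geneEncode(gi, xa, embi, seed = 3)$Z
  zb <- geneEncode(gi, xb, embi, seed = 3)$Z
  expect_equal(za[3, , 1], zb[3, , 1])
})

test_that("two encoder layers have an exactly 2-hop receptive field", {
  g <- pathGraphFixture(6)  # chain G1 - G2 - ... - G6
  emb <- initEmbeddings(g, 3, seed = 2)
  x1 <- rnorm(6)
  x2 <- x1; x2[6] <- x2[6] + 5   # perturb a node 3+ hops from G1/G2
  z1 <- geneEncode(g, x1, emb, seed = 3)$Z
  z2 <- geneEncode(g, x2, emb, seed = 3)$Z
  expect_equal(z1[1, , 1], z2[1, , 1])      # 5 hops away: unchanged
  expect_equal(z1[2, , 1], z2[2, , 1])      # 4 hops
  expect_equal(z1[3, , 1], z2[3, , 1])      # 3 hops
  expect_false(isTRUE(all.equal(z1[5, , 1], z2[5, , 1])))  # 1 hop: changed
})

test_that("pathway aggregation is the stated contraction of reweighted encodings", {
  model <- smallModel()
  coh <- smallCohort()
  X <- makeNodeInputs(model@graph, coh, 1:4)
  kop <- mlgnn:::kronOp(graphOperator(model@graph), 4)
  ec <- mlgnn:::encoderForward(model@params, kop, X)
  bc <- mlgnn:::blocksForward(model, model@params, ec$XZ3)
  D <- model@config$D
  k <- which(vapply(model@blocks, function(b) length(b$idx) >= 2, TRUE))[1]
  b <- model@blocks[[k]]
  params <- model@params
  # one-hot row selecting gene 2 of the block: PF row = x_g * z_g
  Wp <- params[[sprintf("Wp.%04d", k)]] * 0
  Wp[1, 2] <- 1
  params[[sprintf("Wp.%04d", k)]] <- Wp
  bc2 <- mlgnn:::blocksForward(model, params, ec$XZ3)
  v <- b$idx[2]
  Z3 <- mlgnn:::tallToArr(ec$Zt, nrow(X), D, 4)
  for (s in 1:4) {
    got <- array(bc2[[k]]$PF, c(b$Me, D, 4))[1, , s]
    expect_equal(got, X[v, s] * Z3[v, , s], tolerance = 1e-12)
  }
  # dense oracle: PF = Wp %*% (x * z) stacked over genes
  WpR <- params[[sprintf("Wp.%04d", k)]]
  for (s in 1:2) {
    XZ <- X[b$idx, s] * Z3[b$idx, , s, drop = TRUE]
    expect_equal(array(bc2[[k]]$PF, c(b$Me, D, 4))[, , s],
                 WpR %*% XZ, tolerance = 1e-9, ignore_attr = TRUE)
  }
  # all-zero inputs give zero pathway features before the FC layers
  X0 <- X * 0
  ec0 <- mlgnn:::encoderForward(model@params, kop, X0)
  bc0 <- mlgnn:::blocksForward(model, model@params, ec0$XZ3)
  expect_true(all(abs(bc0[[k]]$PF) < 1e-12))
})

test_that("the prediction head outputs a softmax and respects max pooling", {
  model <- smallTrained()
  coh <- smallCohort()
  pr <- predictRisk(model, coh, 1:12)
  expect_true(all(pr$p_nonLTS >= 0 & pr$p_LTS >= 0))
  expect_equal(pr$p_nonLTS + pr$p_LTS, rep(1, 12), tolerance = 1e-6)
  # determinism of the forward pass
  pr2 <- predictRisk(model, coh, 1:12)
  expect_identical(pr, pr2)
  # doubling a pooled-away (non-maximal) entry changes nothing
  X <- makeNodeInputs(model@graph, coh, 1:3)
  kop <- mlgnn:::kronOp(graphOperator(model@graph), 3)
  ageStd <- (clinicalTable(coh)$age[1:3] - model@ageStats["mean"]) /
    model@ageStats["sd"]
  fw <- mlgnn:::mlForward(model, model@params, kop, X, ageStd)
  hc <- fw$hc
  w <- hc$windows[[1]]
  arg <- hc$argp[1, 1, 1, 1]
  loser <- setdiff(seq_len(nrow(w$cells)), arg)[1]
  skip_if(is.na(loser))
  Mp2 <- hc$Mp
  cell <- w$cells[loser, ]
  if (Mp2[1, cell[1], cell[2], 1] < hc$pooled[1, 1, 1, 1]) {
    Mp2[1, cell[1], cell[2], 1] <- Mp2[1, cell[1], cell[2], 1] +
      0.5 * (hc$pooled[1, 1, 1, 1] - Mp2[1, cell[1], cell[2], 1])
    # re-pool manually: maximum of the window is unchanged
    vals <- vapply(seq_len(nrow(w$cells)), function(t)
      Mp2[1, w$cells[t, 1], w$cells[t, 2], 1], 0)
    expect_equal(max(vals), hc$pooled[1, 1, 1, 1])
  }
})

test_that("predicting with age on an age-less cohort errors", {
  model <- smallTrained()
  coh <- smallCohort()
  coh@clinical$age <- NULL
  expect_error(predictRisk(model, coh, 1:5), "no age column")
})

test_that("severing inter-omics edges isolates mRNA encodings from CNV/MT inputs", {
  sim <- smallSim()
  sel <- smallSelection()
  graph <- smallGraph()
  coh <- smallCohort()
  cut <- graph
  cut@edges <- cut@edges[cut@edges$type == "mRNA", , drop = FALSE]
  emb <- initEmbeddings(cut, 3, seed = 4)
  X1 <- makeNodeInputs(cut, coh, 1:2)
  X2 <- X1
  nonM <- graphNodes(cut)$omics != "mRNA"
  X2[nonM, ] <- X2[nonM, ] + 3
  z1 <- geneEncode(cut, X1, emb, seed = 6)$Z
  z2 <- geneEncode(cut, X2, emb, seed = 6)$Z
  mr <- which(!nonM)
  expect_equal(z1[mr, , ], z2[mr, , ])
})

test_that("the independence penalty vanishes at the PCA initialization", {
  model <- smallModel()
  linds <- vapply(seq_along(model@blocks), function(k) {
    Wp <- model@params[[sprintf("Wp.%04d", k)]]
    if (nrow(Wp) < 2) 0 else cosineIndependenceLoss(Wp)
  }, 0)
  expect_lt(max(linds), 1e-6)
})
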