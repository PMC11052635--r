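# Model construction: embedding init, PCA-initialized pathway aggregators,
# cosine independence penalty, Pearson-similarity pathway ordering.

defaultModelConfig <- function() {
  list(D = 8L, M_dims = 2L, lambda_ind = 0.01, hidden = 32L,
       lr = 1e-3, epochs = 30L, batch_size = 32L, weight_decay = 0,
       val_frac = 0.15, patience = 5L, use_age = TRUE,
       pool_kernel = c(2L, 2L), mask_steps = 300L, mask_lr = 0.01,
       alpha = 1, beta = 0.005, gamma = 0.1, ig_steps = 128L,
       verbose = FALSE)
}

mergeConfig <- function(config = list()) {
  base <- defaultModelConfig()
  unknown <- setdiff(names(config), names(base))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  base[names(config)] <- config
  base
}

#' Initialize random node embeddings
#'
#' Each guidance-graph node receives a trainable D-dimensional embedding,
#' drawn from a seeded normal with sd 1/sqrt(D).
#'
#' @param graph a [GuidanceGraph-class].
#' @param D embedding width (>= 1).
#' @param seed integer seed.
#' @return numeric matrix (nodes x D).
#' @export
initEmbeddings <- function(graph, D, seed = 1L) {
  if (D < 1) stop("D must be >= 1")
  V <- nrow(graph@nodes)
  withSeed(seed, matrix(rnorm(V * D, sd = 1 / sqrt(D)), V, D))
}

#' Fit the PCA initializer of a pathway-omics aggregation block
#'
#' Rows of the returned loading matrix are the top `mDims` principal-component
#' loadings of the (column-centered) training submatrix, so that
#' `scores = sweep(X, 2, center) %*% t(P)` reproduces the PCA scores.
#'
#' @param X training submatrix (samples x genes) for one (pathway, omics).
#' @param mDims number of components; must satisfy
#'   `mDims <= min(nrow(X) - 1, ncol(X))`.
#' @return list with `P` (mDims x genes loadings), `center` (gene means),
#'   `scores` (samples x mDims).
#' @export
fitPCAInitializer <- function(X, mDims) {
  if (ncol(X) < 1) stop("pathway-omics block has no genes")
  if (mDims > ncol(X) || mDims > nrow(X) - 1)
    stop("mDims must be <= min(n_samples - 1, n_genes)")
  pr <- prcomp(X, center = TRUE, scale. = FALSE)
  P <- t(pr$rotation[, seq_len(mDims), drop = FALSE])
  list(P = P, center = pr$center,
       scores = pr$x[, seq_len(mDims), drop = FALSE])
}

#' Cosine independence penalty of an aggregation matrix
#'
#' Sum over unordered row pairs (m < n) of the absolute cosine similarity
#' between rows. Zero at an orthogonal initializer (PCA loadings are
#' orthonormal); pairs involving a zero row contribute 0.
#'
#' @param W numeric matrix with >= 2 rows.
#' @return scalar penalty.
#' @export
cosineIndependenceLoss <- function(W) {
  if (nrow(W) < 2) stop("need >= 2 rows")
  nrm <- sqrt(rowSums(W^2))
  ok <- nrm > 0
  U <- W
  U[ok, ] <- W[ok, , drop = FALSE] / nrm[ok]
  U[!ok, ] <- 0
  C <- tcrossprod(U)
  sum(abs(C[upper.tri(C)]))
}

# gradient of cosineIndependenceLoss wrt W (zero rows get zero gradient)
gradCosineIndependence <- function(W) {
  nrm <- sqrt(rowSums(W^2))
  ok <- nrm > 0
  U <- W * 0
  U[ok, ] <- W[ok, , drop = FALSE] / nrm[ok]
  C <- tcrossprod(U)
  S <- sign(C)
  # dead zone: at (numerically) exact orthogonality the subgradient of |cos|
  # is 0, not sign(1e-17)
  S[abs(C) < 1e-8] <- 0
  diag(S) <- 0
  G <- (S %*% U - rowSums(S * C) * U)
  G[ok, ] <- G[ok, , drop = FALSE] / nrm[ok]
  G[!ok, ] <- 0
  G
}

#' Greedy Pearson-similarity pathway ordering
#'
#' Computes pairwise Pearson correlations between pathway feature vectors
#' (initial PCA pathway features concatenated across omics and training
#' samples). The most similar pair occupies positions 1-2 (smaller index
#' first); thereafter the unused pathway most similar to the last placed one
#' is appended. Ties break toward the smaller pathway index; a constant
#' pathway vector has all its correlations defined as 0.
#'
#' @param features numeric matrix (pathways x feature length). Ignored when
#'   `similarity` is supplied.
#' @param similarity optional precomputed symmetric similarity matrix.
#' @return integer permutation of pathway indices.
#' @export
reorderPathways <- function(features = NULL, similarity = NULL) {
  if (is.null(similarity)) {
    if (is.null(features)) stop("supply features or similarity")
    if (nrow(features) < 2) stop("need >= 2 pathways")
    similarity <- suppressWarnings(cor(t(features)))
    similarity[!is.finite(similarity)] <- 0
  }
  N <- nrow(similarity)
  if (N < 2) stop("need >= 2 pathways")
  S <- similarity
  diag(S) <- -Inf
  # highest-similarity pair, ties to smallest (i, j)
  best <- -Inf; bi <- 1L; bj <- 2L
  for (i in seq_len(N - 1)) for (j in (i + 1):N)
    if (S[i, j] > best) { best <- S[i, j]; bi <- i; bj <- j }
  ord <- c(bi, bj)
  used <- logical(N); used[ord] <- TRUE
  while (length(ord) < N) {
    last <- ord[length(ord)]
    cand <- which(!used)
    nxt <- cand[which.max(S[last, cand])]
    ord <- c(ord, nxt)
    used[nxt] <- TRUE
  }
  as.integer(ord)
}

#' Assemble an (untrained) multilevel GNN
#'
#' Builds the per-(pathway, omics) aggregation blocks over the guidance
#' graph, fits their PCA initializers and the pathway ordering on the
#' training samples only, standardizes age on the training samples, and
#' initializes all remaining parameters from a seeded random source.
#'
#' @param graph a [GuidanceGraph-class] built on the selected genes.
#' @param cohort labeled [MultiOmicsCohort-class].
#' @param pathways a [PathwayMap-class].
#' @param selection a "FeatureSelection" from [selectFeatures()].
#' @param config named list of hyperparameters (see package vignette);
#'   unknown keys are rejected.
#' @param trainIdx integer indices of training samples (PCA, ordering and
#'   age statistics are fitted on these only).
#' @param seed integer seed for parameter initialization.
#' @return a [MultilevelGNN-class] (untrained parameters).
#' @export
buildModel <- function(graph, cohort, pathways, selection, config = list(),
                       trainIdx = seq_along(cohortLabels(cohort)), seed = 1L) {
  cfg <- mergeConfig(config)
  D <- as.integer(cfg$D); Md <- as.integer(cfg$M_dims)
  omics <- intersect(OMICS_LEVELS, unique(graph@nodes$omics))
  nodes <- graph@nodes
  nodeKey <- paste(nodes$gene, nodes$omics)
  nTrain <- length(trainIdx)
  N <- length(pathways@ids)
  if (N < 2) stop("need >= 2 pathways")

  blocks <- list(); porigin <- vector("list", N)
  for (pi in seq_len(N)) {
    chunks <- list()
    for (oj in seq_along(omics)) {
      om <- omics[oj]
      genes <- intersect(pathways@genes[[pi]], selection$kept[[om]])
      genes <- genes[paste(genes, om) %in% nodeKey]
      chunk <- matrix(0, Md, nTrain)
      if (length(genes) >= 1) {
        Me <- min(Md, length(genes), nTrain - 1)
        Xblk <- cohort@assays[[om]][trainIdx, genes, drop = FALSE]
        pca <- fitPCAInitializer(Xblk, Me)
        blocks[[length(blocks) + 1L]] <- list(
          pathway = pathways@ids[pi], pi = pi, omics = om, oj = oj,
          genes = genes, idx = match(paste(genes, om), nodeKey),
          Me = Me, center = pca$center, P = pca$P)
        chunk[seq_len(Me), ] <- t(pca$scores)
      }
      chunks[[oj]] <- chunk
    }
    porigin[[pi]] <- as.numeric(do.call(rbind, chunks))
  }
  if (!length(blocks)) stop("no pathway-omics block has any gene after selection")
  pfeat <- do.call(rbind, porigin)
  pathwayOrder <- reorderPathways(pfeat)

  useAge <- isTRUE(cfg$use_age) && "age" %in% names(cohort@clinical) &&
    !anyNA(cohort@clinical$age)
  ageStats <- if (useAge) {
    a <- cohort@clinical$age[trainIdx]
    c(mean = mean(a), sd = max(sd(a), 1e-8))
  } else c(mean = NA_real_, sd = NA_real_)
  cfg$use_age <- useAge

  V <- nrow(nodes)
  Np <- ceiling(N / cfg$pool_kernel[1])
  Mp <- ceiling(length(omics) / cfg$pool_kernel[2])
  L <- D * Np * Mp + as.integer(useAge)
  H <- as.integer(cfg$hidden)

  params <- withSeed(seed, {
    p <- list(
      E  = matrix(rnorm(V * D, sd = 1 / sqrt(D)), V, D),
      W1 = matrix(rnorm(2 * D * D, sd = sqrt(2 / (3 * D))), 2 * D, D),
      b1 = numeric(D),
      W2 = matrix(rnorm(2 * D * D, sd = sqrt(2 / (3 * D))), 2 * D, D),
      b2 = numeric(D))
    for (k in seq_along(blocks)) {
      b <- blocks[[k]]
      p[[sprintf("Wp.%04d", k)]] <- b$P
      p[[sprintf("U1.%04d", k)]] <-
        matrix(rnorm(D * b$Me * D, sd = sqrt(2 / (b$Me * D + D))), D, b$Me * D)
      p[[sprintf("c1.%04d", k)]] <- numeric(D)
      p[[sprintf("U2.%04d", k)]] <-
        matrix(rnorm(D * D, sd = sqrt(1 / D)), D, D)
      p[[sprintf("c2.%04d", k)]] <- numeric(D)
    }
    p$V1 <- matrix(rnorm(H * L, sd = sqrt(2 / (L + H))), H, L)
    p$d1 <- numeric(H)
    p$V2 <- matrix(rnorm(2 * H, sd = sqrt(2 / (H + 2))), 2, H)
    p$d2 <- numeric(2)
    p
  })

  sel <- unclass(selection)
  m <- new("MultilevelGNN", graph = graph, blocks = blocks, params = params,
           pathwayOrder = pathwayOrder, pathwayIds = pathways@ids,
           omics = omics, selection = sel,
           ageStats = ageStats, config = cfg)
  attr(m, "samples_used") <- sampleIds(cohort)[trainIdx]
  m
}

#' Node input matrix for a guidance graph
#'
#' Collects, for every (gene, omics) node, that gene's value in the matching
#' omics assay, giving the per-sample node inputs of the encoder.
#'
#' @param graph a [GuidanceGraph-class].
#' @param cohort a [MultiOmicsCohort-class].
#' @param sampleIdx samples to include (default all).
#' @return numeric matrix (nodes x samples).
#' @export
makeNodeInputs <- function(graph, cohort, sampleIdx = seq_len(nrow(cohort@assays[[1]]))) {
  nodes <- graph@nodes
  V <- nrow(nodes); B <- length(sampleIdx)
  X <- matrix(0, V, B)
  for (om in unique(nodes$omics)) {
    sel <- which(nodes$omics == om)
    A <- cohort@assays[[om]]
    j <- match(nodes$gene[sel], colnames(A))
    if (anyNA(j)) stop("graph node gene absent from assay ", om)
    X[sel, ] <- t(A[sampleIdx, j, drop = FALSE])
  }
  dimnames(X) <- list(paste(nodes$gene, nodes$omics, sep = "|"),
                      rownames(cohort@assays[[1]])[sampleIdx])
  X
}
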