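# Node-mask gene explanation (modified GNN-Explainer): a per-node continuous
# mask sigma(M) in (0,1) multiplies each node's input features; the raw mask
# is optimized so the masked graph keeps the model's prediction while using
# few nodes (L1 penalty) with near-binary mask values (entropy penalty).

#' Explainer configuration
#'
#' @param alpha weight of the prediction (negative log-likelihood) term.
#' @param beta weight of the L1 mask-size penalty.
#' @param gamma weight of the elementwise binary-entropy penalty.
#' @param steps number of optimization steps.
#' @param lr learning rate.
#' @param maskInit raw-mask initial value (0 gives sigma = 0.5).
#' @return list of class "ExplainerConfig".
#' @export
explainerConfig <- function(alpha = 1, beta = 0.005, gamma = 0.1,
                            steps = 300L, lr = 0.01, maskInit = 0) {
  stopifnot(alpha >= 0, beta >= 0, gamma >= 0, steps >= 1)
  structure(list(alpha = alpha, beta = beta, gamma = gamma,
                 steps = as.integer(steps), lr = lr, maskInit = maskInit),
            class = "ExplainerConfig")
}

# explainer loss for current sigma-mask and class probabilities
explainerLoss <- function(probs, target, sig, cfg) {
  nll <- -log(pmax(probs[cbind(target + 1L, seq_len(ncol(probs)))], 1e-12))
  cfg$alpha * sum(nll) + cfg$beta * sum(sig) + cfg$gamma * sum(binaryEntropy(sig))
}

#' Optimize per-node input masks (gene explainer)
#'
#' For each sample, a raw mask vector M over guidance-graph nodes is
#' optimized (Adam on the raw mask) to minimize
#' `alpha * NLL(predicted class) + beta * ||sigma(M)||_1 +
#' gamma * sum_v H(sigma(M_v))`, with the mask applied multiplicatively to
#' the node inputs (`s_v <- sigma(M_v) * x_v * e_v`). The model is frozen;
#' masks for different samples are independent and optimized jointly as a
#' batch.
#'
#' @param model trained [MultilevelGNN-class].
#' @param cohort labeled cohort containing the samples to explain.
#' @param sampleIdx samples to explain (default all).
#' @param cfg an [explainerConfig()].
#' @param target optional per-sample class to explain (0 = non-LTS,
#'   1 = LTS); defaults to the model's own prediction.
#' @return matrix of activated masks sigma(M) (nodes x samples), with the
#'   optimization loss trace in attribute `lossTrace`.
#' @export
optimizeNodeMask <- function(model, cohort, sampleIdx = seq_len(nrow(cohort@assays[[1]])),
                             cfg = explainerConfig(), target = NULL) {
  X <- makeNodeInputs(model@graph, cohort, sampleIdx)
  V <- nrow(X); B <- ncol(X)
  kop <- kronOp(graphOperator(model@graph), B)
  ageStd <- if (model@config$use_age)
    (cohort@clinical$age[sampleIdx] - model@ageStats["mean"]) / model@ageStats["sd"]
  else NULL
  params <- model@params
  if (is.null(target)) {
    fw0 <- mlForward(model, params, kop, X, ageStd)
    target <- as.integer(fw0$probs[2, ] > fw0$probs[1, ])
  }
  stopifnot(length(target) == B, all(target %in% c(0L, 1L)))

  M <- matrix(cfg$maskInit, V, B)
  mAdam <- list(m = M * 0, v = M * 0, t = 0L)
  trace <- numeric(cfg$steps)
  for (s in seq_len(cfg$steps)) {
    sig <- sigmoid(M)
    fw <- mlForward(model, params, kop, X, ageStd, mask = sig)
    probs <- fw$probs
    loss <- explainerLoss(probs, target, sig, cfg)
    if (!is.finite(loss))
      stop("non-finite explainer loss at step ", s)
    trace[s] <- loss
    # d(alpha * NLL_b)/dlogits, per sample (no batch averaging)
    Yt <- rbind(as.numeric(target == 0L), as.numeric(target == 1L))
    dlogits <- cfg$alpha * (probs - Yt)
    grads <- mlBackward(model, params, kop, X, sig, fw, dlogits,
                        wantMask = TRUE, paramGrads = FALSE)
    dsig <- attr(grads, "dmask") +
      cfg$beta + cfg$gamma * log((1 - pmin(pmax(sig, 1e-12), 1 - 1e-12)) /
                                   pmin(pmax(sig, 1e-12), 1 - 1e-12))
    dM <- dsig * sig * (1 - sig)
    mAdam$t <- mAdam$t + 1L
    mAdam$m <- 0.9 * mAdam$m + 0.1 * dM
    mAdam$v <- 0.999 * mAdam$v + 0.001 * dM * dM
    M <- M - cfg$lr * (mAdam$m / (1 - 0.9^mAdam$t)) /
      (sqrt(mAdam$v / (1 - 0.999^mAdam$t)) + 1e-8)
  }
  out <- sigmoid(M)
  dimnames(out) <- dimnames(X)
  attr(out, "lossTrace") <- trace
  attr(out, "target") <- target
  out
}

#' Aggregate node masks into per-gene importance scores
#'
#' Per sample, mask values are z-scored across genes within each omics; the
#' z-scores are then averaged across samples, giving one importance score per
#' (gene, omics), ranked within omics. A sample with zero mask variance in an
#' omics contributes zeros (with a warning).
#'
#' @param masks nodes x samples matrix from [optimizeNodeMask()].
#' @param graph the model's [GuidanceGraph-class] (node order must match).
#' @return data.frame (gene, omics, importance, rank) ordered by omics and
#'   decreasing importance; per-sample z-scores in attribute `zPerSample`.
#' @export
geneImportance <- function(masks, graph) {
  if (ncol(masks) < 2) stop("need >= 2 samples")
  nodes <- graph@nodes
  stopifnot(nrow(masks) == nrow(nodes))
  Zs <- masks * 0
  for (om in unique(nodes$omics)) {
    sel <- which(nodes$omics == om)
    if (length(sel) < 2) stop("need >= 2 genes per omics")
    sub <- masks[sel, , drop = FALSE]
    mu <- colMeans(sub)
    sdv <- apply(sub, 2, sd)
    zero <- sdv == 0
    if (any(zero)) {
      warning("zero mask variance across genes in ", sum(zero),
              " sample(s) for omics ", om, "; z set to 0")
      sdv[zero] <- 1
    }
    z <- sweep(sweep(sub, 2, mu), 2, sdv, "/")
    z[, zero] <- 0
    Zs[sel, ] <- z
  }
  imp <- rowMeans(Zs)
  out <- data.frame(gene = nodes$gene, omics = nodes$omics, importance = imp,
                    stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(split(out, out$omics), function(d) {
    d <- d[order(-d$importance, d$gene), ]
    d$rank <- seq_len(nrow(d))
    d
  }))
  rownames(out) <- NULL
  attr(out, "zPerSample") <- Zs
  out
}

#' Split samples by mean importance of one gene
#'
#' High-importance group when a sample's importance for the gene exceeds the
#' across-sample mean; exported with sample ids for external survival
#' analysis. Invariant to adding a constant to all importances.
#'
#' @param importance per-sample importance values for one gene.
#' @param sampleIds optional sample ids.
#' @return data.frame with group (1 = high importance) per sample.
#' @export
importanceGroupSplit <- function(importance, sampleIds = NULL) {
  if (length(importance) < 2) stop("need >= 2 samples")
  grp <- as.integer(importance > mean(importance))
  if (all(grp == 0L) || all(grp == 1L))
    warning("degenerate split: one group is empty")
  out <- data.frame(importance = importance, group = grp)
  if (!is.null(sampleIds)) out <- cbind(sample_id = sampleIds, out)
  out
}

#' Export a gene-importance table (TSV)
#'
#' Columns gene, omics, importance score, plus placeholder p-value columns
#' to be filled by external survival tests.
#'
#' @param imp result of [geneImportance()].
#' @param path output path.
#' @param top keep the top `top` genes per omics (default all).
#' @return `path`, invisibly.
#' @export
writeGeneImportance <- function(imp, path, top = Inf) {
  df <- do.call(rbind, lapply(split(imp, imp$omics), function(d)
    head(d[order(d$rank), ], n = min(nrow(d), top))))
  df$p_value <- NA_real_
  df$adjusted_p_value <- NA_real_
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
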