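# Forward pass of the multilevel GNN. Node-feature batches are carried as
# "tall" matrices of shape (nodes*samples) x features, rows grouped by
# sample, so feature-linear layers are single BLAS calls and neighborhood
# aggregation is one sparse product with a block-diagonal operator.

# block-diagonal expansion of the graph operator over B samples
kronOp <- function(Ahat, B) {
  K <- Matrix::bdiag(rep(list(Ahat), B))
  list(K = K, Kt = Matrix::t(K), B = as.integer(B))
}

# (V*B) x D tall matrix -> V x D x B array
tallToArr <- function(M, V, D, B) aperm(array(M, c(V, B, D)), c(1, 3, 2))
# inverse
arrToTall <- function(A) {
  d <- dim(A)
  matrix(aperm(A, c(1, 3, 2)), d[1] * d[3], d[2])
}

softmaxCols <- function(logits) {
  z <- sweep(logits, 2, apply(logits, 2, max))
  e <- exp(z)
  sweep(e, 2, colSums(e), "/")
}

# ---- encoder ----

encoderForward <- function(params, kop, X, mask = NULL) {
  V <- nrow(X); B <- ncol(X); D <- ncol(params$E)
  xv <- as.vector(X)
  S0 <- params$E[rep.int(seq_len(V), B), , drop = FALSE] * xv
  S <- if (is.null(mask)) S0 else S0 * as.vector(mask)
  A1 <- as.matrix(kop$K %*% S)
  C1 <- cbind(S, A1, 1)   # ones column folds the bias into the matmul
  P1 <- C1 %*% rbind(params$W1, params$b1)
  H1 <- pmax(P1, 0)
  A2 <- as.matrix(kop$K %*% H1)
  C2 <- cbind(H1, A2, 1)
  P2 <- C2 %*% rbind(params$W2, params$b2)
  Zt <- pmax(P2, 0)
  XZ3 <- tallToArr(Zt * xv, V, D, B)  # expression-reweighted encodings x_v * z_v
  list(S0 = S0, C1 = C1, P1 = P1, C2 = C2, P2 = P2, Zt = Zt, XZ3 = XZ3,
       V = V, B = B)
}

encoderBackward <- function(params, kop, X, mask, ecache, dZt,
                            wantMask = FALSE, paramGrads = TRUE) {
  D <- ncol(params$E); V <- ecache$V; B <- ecache$B
  dP2 <- dZt * (ecache$P2 > 0)
  out <- list()
  if (paramGrads) {
    g2 <- crossprod(ecache$C2, dP2)     # last row is the bias gradient
    out$W2 <- g2[seq_len(2 * D), , drop = FALSE]
    out$b2 <- g2[2 * D + 1, ]
  }
  dC2 <- tcrossprod(dP2, params$W2)
  dH1 <- dC2[, seq_len(D), drop = FALSE] +
    as.matrix(kop$Kt %*% dC2[, D + seq_len(D), drop = FALSE])
  dP1 <- dH1 * (ecache$P1 > 0)
  if (paramGrads) {
    g1 <- crossprod(ecache$C1, dP1)
    out$W1 <- g1[seq_len(2 * D), , drop = FALSE]
    out$b1 <- g1[2 * D + 1, ]
  }
  dC1 <- tcrossprod(dP1, params$W1)
  dS <- dC1[, seq_len(D), drop = FALSE] +
    as.matrix(kop$Kt %*% dC1[, D + seq_len(D), drop = FALSE])
  if (paramGrads) {
    xm <- if (is.null(mask)) as.vector(X) else as.vector(X * mask)
    # dE[v, d] = sum_b dS[(b-1)V + v, d] * x[v, b] (* mask)
    out$E <- rowsum(dS * xm, rep.int(seq_len(V), B), reorder = FALSE)
  }
  if (wantMask) out$dmask <- matrix(rowSums(dS * ecache$S0), V, B)
  out
}

# ---- pathway aggregation blocks ----

blocksForward <- function(model, params, XZ3) {
  D <- dim(XZ3)[2]; B <- dim(XZ3)[3]
  lapply(seq_along(model@blocks), function(k) {
    b <- model@blocks[[k]]
    Rmat <- matrix(XZ3[b$idx, , , drop = FALSE], length(b$idx), D * B)
    list(Rmat = Rmat, PF = params[[sprintf("Wp.%04d", k)]] %*% Rmat)
  })
}

# gradients wrt Wp and the expression-reweighted encodings XZ
blocksBackward <- function(model, params, bcache, dPF, V, D, B,
                           paramGrads = TRUE) {
  dXZ3 <- array(0, c(V, D, B))
  grads <- list()
  for (k in seq_along(model@blocks)) {
    b <- model@blocks[[k]]
    Wp <- params[[sprintf("Wp.%04d", k)]]
    if (paramGrads)
      grads[[sprintf("Wp.%04d", k)]] <- tcrossprod(dPF[[k]], bcache[[k]]$Rmat)
    dXZ3[b$idx, , ] <- dXZ3[b$idx, , , drop = FALSE] +
      array(crossprod(Wp, dPF[[k]]), c(length(b$idx), D, B))
  }
  list(grads = grads, dXZ3 = dXZ3)
}

# ---- prediction head (from pathway features PF onward) ----

headForward <- function(model, params, PFlist, ageStd = NULL, B) {
  cfg <- model@config
  D <- cfg$D; N <- length(model@pathwayIds); M <- length(model@omics)
  kr <- cfg$pool_kernel[1]; kc <- cfg$pool_kernel[2]
  pos <- match(seq_len(N), model@pathwayOrder)
  ucache <- vector("list", length(model@blocks))
  Mp <- array(0, c(D, N, M, B))
  for (k in seq_along(model@blocks)) {
    b <- model@blocks[[k]]
    u <- matrix(PFlist[[k]], b$Me * D, B)
    preh <- params[[sprintf("U1.%04d", k)]] %*% u + params[[sprintf("c1.%04d", k)]]
    h <- pmax(preh, 0)
    p <- params[[sprintf("U2.%04d", k)]] %*% h + params[[sprintf("c2.%04d", k)]]
    ucache[[k]] <- list(u = u, preh = preh, h = h)
    Mp[, pos[b$pi], b$oj, ] <- p
  }
  Npool <- ceiling(N / kr); Mpool <- ceiling(M / kc)
  pooled <- array(-Inf, c(D, Npool, Mpool, B))
  argp <- array(1L, c(D, Npool, Mpool, B))
  windows <- vector("list", Npool * Mpool)
  w <- 0L
  for (a in seq_len(Npool)) for (cc in seq_len(Mpool)) {
    w <- w + 1L
    ni <- ((a - 1) * kr + 1):min(a * kr, N)
    mi <- ((cc - 1) * kc + 1):min(cc * kc, M)
    cells <- as.matrix(expand.grid(ni = ni, mi = mi))
    windows[[w]] <- list(a = a, cc = cc, cells = cells)
    cur <- matrix(Mp[, cells[1, 1], cells[1, 2], ], D, B)
    arg <- matrix(1L, D, B)
    if (nrow(cells) > 1) for (t in 2:nrow(cells)) {
      cand <- matrix(Mp[, cells[t, 1], cells[t, 2], ], D, B)
      upd <- cand > cur
      arg[upd] <- t
      cur[upd] <- cand[upd]
    }
    pooled[, a, cc, ] <- cur
    argp[, a, cc, ] <- arg
  }
  q <- matrix(pooled, D * Npool * Mpool, B)
  qa <- if (cfg$use_age) {
    if (is.null(ageStd)) stop("model uses age but no age vector supplied")
    rbind(q, matrix(ageStd, 1, B))
  } else q
  preHH <- params$V1 %*% qa + params$d1
  hh <- pmax(preHH, 0)
  logits <- params$V2 %*% hh + params$d2
  list(ucache = ucache, Mp = Mp, pooled = pooled, argp = argp,
       windows = windows, qa = qa, preHH = preHH, hh = hh,
       logits = logits, probs = softmaxCols(logits))
}

headBackward <- function(model, params, hcache, dlogits, paramGrads = TRUE) {
  cfg <- model@config
  D <- cfg$D; N <- length(model@pathwayIds); M <- length(model@omics)
  B <- ncol(dlogits)
  pos <- match(seq_len(N), model@pathwayOrder)
  grads <- list()
  if (paramGrads) {
    grads$V2 <- tcrossprod(dlogits, hcache$hh)
    grads$d2 <- rowSums(dlogits)
  }
  dhh <- crossprod(params$V2, dlogits)
  dpreHH <- dhh * (hcache$preHH > 0)
  if (paramGrads) {
    grads$V1 <- tcrossprod(dpreHH, hcache$qa)
    grads$d1 <- rowSums(dpreHH)
  }
  dqa <- crossprod(params$V1, dpreHH)
  Npool <- dim(hcache$pooled)[2]; Mpool <- dim(hcache$pooled)[3]
  dq <- dqa[seq_len(D * Npool * Mpool), , drop = FALSE]
  dpooled <- array(dq, c(D, Npool, Mpool, B))
  dMp <- array(0, c(D, N, M, B))
  for (wdef in hcache$windows) {
    arg <- matrix(hcache$argp[, wdef$a, wdef$cc, ], D, B)
    dval <- matrix(dpooled[, wdef$a, wdef$cc, ], D, B)
    for (t in seq_len(nrow(wdef$cells))) {
      contrib <- dval * (arg == t)
      dMp[, wdef$cells[t, 1], wdef$cells[t, 2], ] <-
        matrix(dMp[, wdef$cells[t, 1], wdef$cells[t, 2], ], D, B) + contrib
    }
  }
  dPF <- vector("list", length(model@blocks))
  for (k in seq_along(model@blocks)) {
    b <- model@blocks[[k]]
    uc <- hcache$ucache[[k]]
    dp <- matrix(dMp[, pos[b$pi], b$oj, ], D, B)
    dh <- crossprod(params[[sprintf("U2.%04d", k)]], dp)
    dpreh <- dh * (uc$preh > 0)
    if (paramGrads) {
      grads[[sprintf("U2.%04d", k)]] <- tcrossprod(dp, uc$h)
      grads[[sprintf("c2.%04d", k)]] <- rowSums(dp)
      grads[[sprintf("U1.%04d", k)]] <- tcrossprod(dpreh, uc$u)
      grads[[sprintf("c1.%04d", k)]] <- rowSums(dpreh)
    }
    du <- crossprod(params[[sprintf("U1.%04d", k)]], dpreh)
    dPF[[k]] <- matrix(du, b$Me, D * B)
  }
  list(grads = grads, dPF = dPF)
}

# ---- full model ----

mlForward <- function(model, params, kop, X, ageStd = NULL, mask = NULL) {
  B <- ncol(X)
  ec <- encoderForward(params, kop, X, mask)
  bc <- blocksForward(model, params, ec$XZ3)
  hc <- headForward(model, params, lapply(bc, `[[`, "PF"), ageStd, B)
  list(ec = ec, bc = bc, hc = hc, probs = hc$probs, logits = hc$logits)
}

mlBackward <- function(model, params, kop, X, mask, fw, dlogits,
                       wantMask = FALSE, paramGrads = TRUE) {
  V <- nrow(X); B <- ncol(X); D <- model@config$D
  hb <- headBackward(model, params, fw$hc, dlogits, paramGrads = paramGrads)
  bb <- blocksBackward(model, params, fw$bc, hb$dPF, V, D, B,
                       paramGrads = paramGrads)
  dZt <- arrToTall(bb$dXZ3) * as.vector(X)
  eb <- encoderBackward(params, kop, X, mask, fw$ec, dZt,
                        wantMask = wantMask, paramGrads = paramGrads)
  grads <- c(eb[intersect(c("E", "W1", "b1", "W2", "b2"), names(eb))],
             bb$grads, hb$grads)
  if (wantMask) attr(grads, "dmask") <- eb$dmask
  grads
}

#' Encode gene-level features over a guidance graph
#'
#' Standalone access to the encoder: node inputs are scaled embeddings
#' (`s_v = x_v * e_v`, so a node with zero input contributes a zero vector),
#' followed by two rounds of signed weighted-mean neighborhood aggregation,
#' each concatenated with the self representation and passed through a
#' learned linear map with ReLU (GraphSAGE convention). With two layers a
#' node's encoding depends only on its 2-hop neighborhood.
#'
#' @param graph a [GuidanceGraph-class].
#' @param X node input matrix (nodes x samples) or vector (one sample).
#' @param embeddings node embedding matrix from [initEmbeddings()].
#' @param weights optional list with W1, b1, W2, b2; random (seeded) when
#'   omitted.
#' @param seed seed for default weights.
#' @return list with `S` (input features) and `Z` (encodings), both
#'   nodes x D x samples arrays.
#' @export
geneEncode <- function(graph, X, embeddings, weights = NULL, seed = 1L) {
  if (is.null(dim(X))) X <- matrix(X, ncol = 1)
  V <- nrow(graph@nodes); D <- ncol(embeddings)
  if (nrow(X) != V) stop("dimension mismatch: X rows must equal node count")
  if (nrow(embeddings) != V) stop("dimension mismatch: embeddings rows must equal node count")
  if (is.null(weights))
    weights <- withSeed(seed, list(
      W1 = matrix(rnorm(2 * D * D, sd = sqrt(2 / (3 * D))), 2 * D, D),
      b1 = numeric(D),
      W2 = matrix(rnorm(2 * D * D, sd = sqrt(2 / (3 * D))), 2 * D, D),
      b2 = numeric(D)))
  params <- c(list(E = embeddings), weights)
  B <- ncol(X)
  ec <- encoderForward(params, kronOp(graphOperator(graph), B), X)
  list(S = tallToArr(ec$S0, V, D, B), Z = tallToArr(ec$Zt, V, D, B))
}

#' Predict class probabilities for cohort samples
#'
#' Runs the trained model forward and returns the two-class probabilities.
#' The risk score used throughout the package is the probability of the
#' non-long-term-survivor (high-risk) class.
#'
#' @param model a trained [MultilevelGNN-class].
#' @param cohort a labeled [MultiOmicsCohort-class] containing the model's
#'   selected genes.
#' @param sampleIdx samples to score (default all).
#' @return data.frame with sample_id, p_nonLTS, p_LTS, score (= p_nonLTS).
#' @export
predictRisk <- function(model, cohort, sampleIdx = seq_len(nrow(cohort@assays[[1]]))) {
  X <- makeNodeInputs(model@graph, cohort, sampleIdx)
  ageStd <- NULL
  if (model@config$use_age) {
    if (!"age" %in% names(cohort@clinical))
      stop("model uses age but the cohort has no age column")
    ageStd <- (cohort@clinical$age[sampleIdx] - model@ageStats["mean"]) /
      model@ageStats["sd"]
  }
  fw <- mlForward(model, model@params, kronOp(graphOperator(model@graph), ncol(X)),
                  X, ageStd)
  data.frame(sample_id = sampleIds(cohort)[sampleIdx],
             p_nonLTS = fw$probs[1, ], p_LTS = fw$probs[2, ],
             score = fw$probs[1, ], stringsAsFactors = FALSE)
}
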