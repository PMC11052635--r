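# Training loop: cross-entropy + lambda_ind * mean cosine independence
# penalty, Adam updates, early stopping on a stratified validation split of
# the training samples.

adamInit <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adamStep <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8, weightDecay = 0) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    step <- lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
    # decoupled weight decay on weight matrices (biases are exempt)
    if (weightDecay > 0 && !grepl("^(b|c|d)", nm))
      step <- step + lr * weightDecay * params[[nm]]
    params[[nm]] <- params[[nm]] - step
  }
  list(params = params, state = state)
}

# total loss and gradient on a batch; y is 0/1 (1 = LTS)
lossAndGrads <- function(model, params, kop, X, ageStd, y) {
  B <- ncol(X)
  fw <- mlForward(model, params, kop, X, ageStd)
  probs <- pmax(fw$probs, 1e-12)
  Y <- rbind(as.numeric(y == 0L), as.numeric(y == 1L))
  ce <- -mean(log(probs[cbind(y + 1L, seq_len(B))]))
  dlogits <- (fw$probs - Y) / B
  grads <- mlBackward(model, params, kop, X, NULL, fw, dlogits)
  lam <- model@config$lambda_ind
  lind <- 0
  if (lam > 0) {
    nb <- length(model@blocks)
    for (k in seq_len(nb)) {
      nm <- sprintf("Wp.%04d", k)
      Wp <- params[[nm]]
      if (nrow(Wp) >= 2) {
        lind <- lind + cosineIndependenceLoss(Wp)
        grads[[nm]] <- grads[[nm]] + (lam / nb) * gradCosineIndependence(Wp)
      }
    }
    lind <- lind / nb
  }
  list(loss = ce + lam * lind, ce = ce, lind = lind, grads = grads)
}

evalLoss <- function(model, params, kop, X, ageStd, y) {
  fw <- mlForward(model, params, kop, X, ageStd)
  probs <- pmax(fw$probs, 1e-12)
  -mean(log(probs[cbind(y + 1L, seq_along(y))]))
}

#' Train a multilevel GNN
#'
#' Minimizes cross-entropy plus `lambda_ind` times the mean cosine
#' independence penalty over aggregation blocks, with Adam, mini-batches
#' over samples, and early stopping on a stratified validation split carved
#' from the training samples. Deterministic for a fixed seed.
#'
#' @param model an untrained [MultilevelGNN-class] from [buildModel()].
#' @param cohort labeled [MultiOmicsCohort-class].
#' @param trainIdx integer indices of training samples.
#' @param seed integer seed for batching and the validation split.
#' @return the model with trained parameters; training history in
#'   attribute `history`.
#' @export
trainModel <- function(model, cohort, trainIdx = seq_along(cohortLabels(cohort)),
                       seed = 1L) {
  cfg <- model@config
  y <- cohortLabels(cohort)[trainIdx]
  X <- makeNodeInputs(model@graph, cohort, trainIdx)
  ageStd <- if (cfg$use_age)
    (cohort@clinical$age[trainIdx] - model@ageStats["mean"]) / model@ageStats["sd"]
  else NULL
  Ahat <- graphOperator(model@graph)
  n <- length(trainIdx)
  kops <- new.env(parent = emptyenv())
  getKop <- function(B) {
    key <- as.character(B)
    if (is.null(kops[[key]])) kops[[key]] <- kronOp(Ahat, B)
    kops[[key]]
  }

  # stratified validation split
  vi <- integer()
  if (cfg$val_frac > 0 && n >= 20) {
    vi <- withSeed(deriveSeed(seed, 11L), {
      unlist(lapply(split(seq_len(n), y), function(ix)
        sample(ix, max(1L, round(length(ix) * cfg$val_frac)))))
    })
  }
  ti <- setdiff(seq_len(n), vi)
  params <- model@params
  state <- adamInit(params)
  best <- list(loss = Inf, params = params)
  bad <- 0L
  hist <- data.frame(epoch = integer(), train_loss = numeric(), val_loss = numeric())

  for (epoch in seq_len(cfg$epochs)) {
    ord <- withSeed(deriveSeed(seed, 100L + epoch), sample(ti))
    nb <- ceiling(length(ord) / cfg$batch_size)
    eloss <- 0
    for (bi in seq_len(nb)) {
      sel <- ord[((bi - 1) * cfg$batch_size + 1):min(bi * cfg$batch_size, length(ord))]
      lg <- lossAndGrads(model, params, getKop(length(sel)),
                         X[, sel, drop = FALSE], ageStd[sel], y[sel])
      up <- adamStep(params, lg$grads, state, cfg$lr,
                     weightDecay = cfg$weight_decay)
      params <- up$params; state <- up$state
      eloss <- eloss + lg$loss * length(sel)
    }
    eloss <- eloss / length(ord)
    vloss <- if (length(vi))
      evalLoss(model, params, getKop(length(vi)), X[, vi, drop = FALSE],
               ageStd[vi], y[vi])
    else eloss
    hist <- rbind(hist, data.frame(epoch = epoch, train_loss = eloss, val_loss = vloss))
    if (vloss < best$loss - 1e-6) {
      best <- list(loss = vloss, params = params)
      bad <- 0L
    } else {
      bad <- bad + 1L
      if (bad >= cfg$patience) break
    }
    logMsg(sprintf("epoch %d: train %.4f val %.4f", epoch, eloss, vloss),
           verbose = cfg$verbose)
  }
  model@params <- best$params
  attr(model, "history") <- hist
  attr(model, "samples_used") <- sampleIds(cohort)[trainIdx]
  model
}
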