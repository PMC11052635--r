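# Integrated-Gradients pathway attribution: IG over the pre-FC pathway
# features (the output of the learnable compression matrices), attributed
# through the rest of the network to the non-LTS logit; mean |IG| per
# (pathway, omics, sample), median across samples, z within omics, key at
# z > 1.96.

#' Integrated Gradients along a straight path
#'
#' Midpoint-rule Riemann approximation of
#' `IG_i = (S_i - S'_i) * integral_0^1 df/dS_i (S' + t (S - S')) dt`.
#' Exact for linear `f` at any step count; satisfies the completeness axiom
#' `sum_i IG_i = f(S) - f(S')` as steps grow.
#'
#' @param f scalar-valued function of a numeric vector.
#' @param x input vector S.
#' @param baseline baseline vector S' (default zeros).
#' @param steps number of midpoint evaluation points (>= 1).
#' @param grad optional gradient function of `f`; when omitted a central
#'   finite difference is used.
#' @return numeric vector of per-feature attributions.
#' @export
integratedGradients <- function(f, x, baseline = numeric(length(x)),
                                steps = 128L, grad = NULL) {
  stopifnot(steps >= 1, length(baseline) == length(x))
  if (is.null(grad)) {
    eps <- 1e-5
    grad <- function(v) vapply(seq_along(v), function(i) {
      e <- numeric(length(v)); e[i] <- eps
      (f(v + e) - f(v - e)) / (2 * eps)
    }, 0)
  }
  diffv <- x - baseline
  acc <- numeric(length(x))
  for (l in seq_len(steps)) {
    t <- (l - 0.5) / steps
    g <- grad(baseline + t * diffv)
    if (any(!is.finite(g)))
      stop("non-finite gradient on the path at interpolation t = ", t)
    acc <- acc + g
  }
  diffv * acc / steps
}

# analytic gradient of the non-LTS logit wrt the PF features of all blocks,
# batched over "virtual samples" (columns). PFlist: per block Me x (D*B).
headLogitGradPF <- function(model, params, PFlist, ageStd, B) {
  hc <- headForward(model, params, PFlist, ageStd, B)
  dlogits <- rbind(rep(1, B), rep(0, B))  # d(logit_nonLTS)/dlogits
  hb <- headBackward(model, params, hc, dlogits)
  list(logit = hc$logits[1, ], dPF = hb$dPF)
}

#' Integrated-Gradients scores of pathway features for cohort samples
#'
#' For each sample, the attributed function is the non-LTS logit of the
#' prediction head viewed as a function of the compressed pathway features
#' (all blocks' PF), with age held at the sample's value. The baseline is the
#' all-zeros feature vector (or the training-mean features). The midpoint
#' rule with `steps` points discretizes the path integral; gradients are
#' analytic.
#'
#' @param model trained [MultilevelGNN-class].
#' @param cohort labeled cohort.
#' @param sampleIdx samples to attribute (default all).
#' @param steps integration points.
#' @param baseline "zeros" (default) or "mean" (training-mean PF features,
#'   estimated over the attributed samples).
#' @param refine re-integrate intervals containing gradient discontinuities
#'   (ReLU / max-pool boundary crossings) on a 16x finer midpoint grid;
#'   tightens the completeness gap at extra cost. Pathway rankings are
#'   virtually unaffected, so large screening runs may disable it.
#' @return list with `meanAbsIG`: samples x blocks matrix of mean |IG| over
#'   each block's feature dims; `blocks`: block descriptors (pathway, omics);
#'   `completeness`: per-sample |sum IG - (f(S) - f(S'))|.
#' @export
pathwayIG <- function(model, cohort, sampleIdx = seq_len(nrow(cohort@assays[[1]])),
                      steps = model@config$ig_steps, baseline = c("zeros", "mean"),
                      refine = TRUE) {
  baseline <- match.arg(baseline)
  X <- makeNodeInputs(model@graph, cohort, sampleIdx)
  B <- ncol(X); D <- model@config$D

  params <- model@params
  ageStd <- if (model@config$use_age)
    (cohort@clinical$age[sampleIdx] - model@ageStats["mean"]) / model@ageStats["sd"]
  else NULL
  ec <- encoderForward(params, kronOp(graphOperator(model@graph), B), X)
  bc <- blocksForward(model, params, ec$XZ3)
  nb <- length(model@blocks)
  # per-sample PF columns: block k, sample b -> columns (b-1)*D + 1..D
  PFbase <- lapply(seq_len(nb), function(k) {
    if (baseline == "zeros") bc[[k]]$PF * 0
    else {
      Me <- model@blocks[[k]]$Me
      mu <- rowMeans(array(bc[[k]]$PF, c(Me, D, B)), dims = 2)
      matrix(array(mu, c(Me, D, B)), Me, D * B)
    }
  })
  meanAbs <- matrix(0, B, nb)
  completeness <- numeric(B)
  ts <- (seq_len(steps) - 0.5) / steps
  # interpolation points of several samples are batched as virtual samples;
  # chunk size keeps the virtual batch around 4k columns
  chunkSize <- max(1L, 4096L %/% steps)
  starts <- seq(1L, B, by = chunkSize)
  for (st in starts) {
    ch <- st:min(st + chunkSize - 1L, B)
    nc <- length(ch)
    cols <- as.vector(outer(seq_len(D), (ch - 1) * D, "+"))
    dArrs <- vector("list", nb); PF0Arrs <- vector("list", nb)
    PFpath <- vector("list", nb)
    for (k in seq_len(nb)) {
      Me <- model@blocks[[k]]$Me
      PFb <- bc[[k]]$PF[, cols, drop = FALSE]
      PF0 <- PFbase[[k]][, cols, drop = FALSE]
      dArrs[[k]] <- array(PFb - PF0, c(Me, D, nc))
      PF0Arrs[[k]] <- array(PF0, c(Me, D, nc))
      # virtual-sample column order: feature dim fastest, then step, then
      # sample (matrix() flattening of the Me x D x steps x nc array)
      pa <- array(0, c(Me, D, steps, nc))
      for (l in seq_len(steps))
        pa[, , l, ] <- PF0Arrs[[k]] + ts[l] * dArrs[[k]]
      PFpath[[k]] <- matrix(pa, Me, D * steps * nc)
    }
    agev <- if (is.null(ageStd)) NULL else rep(ageStd[ch], each = steps)
    gr <- headLogitGradPF(model, params, PFpath, agev, steps * nc)
    for (k in seq_len(nb))
      if (any(!is.finite(gr$dPF[[k]])))
        stop("non-finite gradient on the integration path (samples ",
             ch[1], "-", ch[nc], ")")
    gArrs <- lapply(seq_len(nb), function(k)
      array(gr$dPF[[k]], c(model@blocks[[k]]$Me, D, steps, nc)))

    # adaptive refinement: the prediction head is piecewise linear, so the
    # path gradient is piecewise constant; a change between two adjacent
    # midpoints pinpoints a ReLU / max-pool boundary crossing. Flagged
    # intervals are re-integrated on a `subSteps`-times finer midpoint grid.
    gMeans <- lapply(gArrs, function(a) colMeans(aperm(a, c(3, 1, 2, 4))))
    if (refine && steps >= 2) {
      ddmax <- matrix(0, steps - 1, nc)
      for (k in seq_len(nb)) {
        a <- gArrs[[k]]
        dg <- abs(a[, , -1, , drop = FALSE] - a[, , -steps, , drop = FALSE])
        m <- matrix(dg, prod(dim(dg)[1:2]), (steps - 1) * nc)
        cm <- m[1, ]
        for (r in seq_len(nrow(m))[-1]) cm <- pmax(cm, m[r, ])
        ddmax <- pmax(ddmax, matrix(cm, steps - 1, nc))
      }
      # refine only jumps large enough to matter: an unrefined interval
      # contributes at most jump/(2*steps) to the completeness gap, so jumps
      # below 1e-6 * steps keep the total residual well under 1e-3
      kink <- ddmax > 1e-6 * steps           # (steps-1) x nc
      pad <- matrix(FALSE, 1, nc)
      flag <- rbind(kink, pad) | rbind(pad, kink)
      fi <- which(flag, arr.ind = TRUE)      # columns: interval l, sample j
      subSteps <- 16L
      if (nrow(fi)) {
        for (fs in seq(1L, nrow(fi), by = max(1L, 4096L %/% subSteps))) {
          fe <- min(fs + max(1L, 4096L %/% subSteps) - 1L, nrow(fi))
          sel <- fi[fs:fe, , drop = FALSE]
          nF <- nrow(sel)
          PFr <- lapply(seq_len(nb), function(k) {
            Me <- model@blocks[[k]]$Me
            p0 <- PF0Arrs[[k]][, , sel[, 2], drop = FALSE]
            dd <- dArrs[[k]][, , sel[, 2], drop = FALSE]
            pa <- array(0, c(Me, D, subSteps, nF))
            for (m in seq_len(subSteps)) {
              tm <- (sel[, 1] - 1 + (m - 0.5) / subSteps) / steps
              pa[, , m, ] <- p0 + dd * rep(tm, each = Me * D)
            }
            matrix(pa, Me, D * subSteps * nF)
          })
          ager <- if (is.null(ageStd)) NULL
          else rep(ageStd[ch[sel[, 2]]], each = subSteps)
          grr <- headLogitGradPF(model, params, PFr, ager, subSteps * nF)
          for (k in seq_len(nb)) {
            Me <- model@blocks[[k]]$Me
            g2 <- array(grr$dPF[[k]], c(Me, D, subSteps, nF))
            gRef <- matrix(colMeans(aperm(g2, c(3, 1, 2, 4))), Me * D, nF)
            # gather the coarse midpoint gradients of the flagged intervals
            base <- matrix(gArrs[[k]],  Me * D, steps * nc)
            gBase <- base[, sel[, 1] + (sel[, 2] - 1) * steps, drop = FALSE]
            delta <- rowsum(t(gRef - gBase) / steps, group = sel[, 2])
            js <- as.integer(rownames(delta))
            gMeans[[k]][, , js] <- gMeans[[k]][, , js, drop = FALSE] +
              array(t(delta), c(Me, D, length(js)))
          }
        }
      }
    }

    igSum <- numeric(nc)
    for (k in seq_len(nb)) {
      ig <- dArrs[[k]] * gMeans[[k]]                      # Me x D x nc
      meanAbs[ch, k] <- apply(abs(ig), 3, mean)
      igSum <- igSum + apply(ig, 3, sum)
    }
    fS <- headLogitGradPF(model, params,
                          lapply(seq_len(nb), function(k) bc[[k]]$PF[, cols, drop = FALSE]),
                          if (is.null(ageStd)) NULL else ageStd[ch], nc)$logit
    fS0 <- headLogitGradPF(model, params,
                           lapply(seq_len(nb), function(k) PFbase[[k]][, cols, drop = FALSE]),
                           if (is.null(ageStd)) NULL else ageStd[ch], nc)$logit
    completeness[ch] <- abs(igSum - (fS - fS0))
  }
  blocks <- data.frame(
    pathway = vapply(model@blocks, `[[`, "", "pathway"),
    omics = vapply(model@blocks, `[[`, "", "omics"), stringsAsFactors = FALSE)
  list(meanAbsIG = meanAbs, blocks = blocks, completeness = completeness)
}

#' Pathway importance table from IG scores
#'
#' Per (pathway, omics): the across-sample median of the per-sample mean |IG|
#' is z-scored within each omics across pathways; pathways with z > 1.96 are
#' flagged as key pathways.
#'
#' A single trained network can under-use one of several genuinely
#' informative pathways (the optimizer settles on a sufficient subset), so
#' `ig` may also be a list of [pathwayIG()] results from models trained with
#' different seeds on the same data; their median scores are averaged before
#' z-scoring, which stabilizes the key-pathway calls.
#'
#' @param ig result of [pathwayIG()], or a list of such results from an
#'   ensemble of trainings.
#' @return data.frame (pathway, omics, score, z, key), ordered by omics and
#'   decreasing z.
#' @export
pathwayImportance <- function(ig) {
  if (!is.null(ig$meanAbsIG)) ig <- list(ig)
  med <- rowMeans(matrix(vapply(ig, function(g) apply(g$meanAbsIG, 2, median),
                                numeric(ncol(ig[[1]]$meanAbsIG))),
                         ncol = length(ig)))
  df <- cbind(ig[[1]]$blocks, score = med)
  out <- do.call(rbind, lapply(split(df, df$omics), function(d) {
    if (nrow(d) < 2)
      stop("z-score undefined: a single pathway in omics ", d$omics[1])
    s <- sd(d$score)
    if (s == 0)
      stop("z-score undefined: zero variance of pathway scores in omics ",
           d$omics[1])
    d$z <- (d$score - mean(d$score)) / s
    d$key <- d$z > 1.96
    d[order(-d$z), ]
  }))
  rownames(out) <- NULL
  out
}

#' Median split of samples by per-sample pathway importance
#'
#' @param scores per-sample importance scores of one (pathway, omics) block
#'   (a column of `pathwayIG()$meanAbsIG`).
#' @param sampleIds optional ids.
#' @return data.frame with group (1 = high score) per sample.
#' @export
pathwayGroupSplit <- function(scores, sampleIds = NULL) {
  if (length(scores) < 2) stop("need >= 2 samples")
  grp <- as.integer(scores > median(scores))
  if (all(grp == 0L)) warning("degenerate split: constant scores")
  out <- data.frame(score = scores, group = grp)
  if (!is.null(sampleIds)) out <- cbind(sample_id = sampleIds, out)
  out
}

#' Export a pathway-importance table (TSV)
#' @param imp result of [pathwayImportance()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writePathwayImportance <- function(imp, path) {
  write.table(imp, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
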