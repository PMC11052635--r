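# Label construction and k-nearest-neighbor mutual-information feature
# selection (computed on training folds only).

#' Derive binary long-term-survivor labels
#'
#' Samples surviving longer than `thresholdYears` are long-term survivors
#' (label 1). Samples with an observed death at or before the threshold are
#' non-LTS (label 0). Censored samples whose follow-up ends at or before the
#' threshold cannot be labeled either way and are excluded.
#'
#' @param clinical clinical data.frame (survival_time in days, event 0/1).
#' @param thresholdYears positive class threshold in years (e.g. 2 for
#'   glioblastoma, 3 for lower-grade glioma / renal clear-cell cohorts).
#' @return list with `sample_id` (retained ids), `label` (0/1 integer),
#'   `excluded` (ids dropped as unlabelable).
#' @export
makeLabels <- function(clinical, thresholdYears) {
  stopifnot(thresholdYears > 0)
  years <- clinical$survival_time / DAYS_PER_YEAR
  lts <- years > thresholdYears
  keep <- lts | clinical$event == 1L
  if (!any(keep)) stop("no samples can be labeled at this threshold")
  list(sample_id = clinical$sample_id[keep],
       label = as.integer(lts[keep]),
       excluded = clinical$sample_id[!keep])
}

#' Attach LTS labels to a cohort
#'
#' Applies [makeLabels()] and subsets the cohort to labelable samples.
#'
#' @param cohort a [MultiOmicsCohort-class].
#' @param thresholdYears survival threshold in years.
#' @return the cohort with `labels` and `thresholdYears` filled in.
#' @export
labelCohort <- function(cohort, thresholdYears = 2) {
  lab <- makeLabels(cohort@clinical, thresholdYears)
  idx <- match(lab$sample_id, sampleIds(cohort))
  assays <- lapply(cohort@assays, function(a) a[idx, , drop = FALSE])
  clin <- cohort@clinical[idx, , drop = FALSE]
  rownames(clin) <- NULL
  new("MultiOmicsCohort", assays = assays, clinical = clin,
      labels = lab$label, thresholdYears = thresholdYears)
}

#' k-nearest-neighbor mutual information between a continuous variable and a
#' discrete label
#'
#' Ross-style estimator for mixed discrete/continuous pairs:
#' `MI = psi(N) - <psi(N_x)> + psi(k) - <psi(m)>`, where for each point
#' `N_x` is the size of its class, the search radius is the distance to its
#' k-th nearest neighbor within the same class, and `m` counts all points
#' (any class, excluding the point itself) within that radius. The estimate
#' is clipped at 0 from below; the raw value is kept in attribute `raw`.
#'
#' @param x numeric vector.
#' @param y class labels (any discrete vector), same length as `x`.
#' @param k neighbor count (default 3).
#' @return non-negative MI estimate in nats, with attribute `raw`.
#' @export
miDiscreteContinuous <- function(x, y, k = 3L) {
  N <- length(x)
  stopifnot(length(y) == N, k >= 1L)
  if (N <= k) stop("need more than k samples")
  tab <- table(y)
  small <- names(tab)[tab <= k]
  if (length(small))
    stop("class '", small[1], "' has <= k members (", tab[small[1]], " <= ", k, ")")
  d <- numeric(N)
  Nx <- numeric(N)
  for (cl in names(tab)) {
    sel <- which(y == cl)
    xo <- x[sel]
    o <- order(xo)
    xs <- xo[o]
    n <- length(xs)
    cand <- matrix(Inf, n, 2L * k)
    for (j in seq_len(k)) {
      if (n > j) {
        cand[(j + 1):n, j] <- xs[(j + 1):n] - xs[1:(n - j)]
        cand[1:(n - j), k + j] <- xs[(1 + j):n] - xs[1:(n - j)]
      }
    }
    # k-th smallest per row via the order(row, value) trick
    srt <- matrix(cand[order(row(cand), cand)], n, 2L * k, byrow = TRUE)
    dk <- srt[, k]
    d[sel[o]] <- dk
    Nx[sel] <- n
  }
  xsAll <- sort(x)
  tol <- d * 1e-9 + 1e-15
  m <- findInterval(x + d + tol, xsAll) - findInterval(x - d - tol, xsAll) - 1L
  raw <- digamma(N) - mean(digamma(Nx)) + digamma(k) - mean(digamma(pmax(m, 1L)))
  out <- max(0, raw)
  attr(out, "raw") <- raw
  out
}

#' Mean-MI feature selection on a labeled cohort
#'
#' For each omics layer, estimates the mutual information between every gene
#' and the LTS label with [miDiscreteContinuous()], then retains genes whose
#' MI is strictly greater than that layer's mean MI. Near-discrete CNV values
#' are jittered with uniform noise of amplitude 1e-10 to break ties before
#' the neighbor search. Selection must be computed on training samples only;
#' the sample ids used are recorded for fold-isolation auditing.
#'
#' @param cohort labeled [MultiOmicsCohort-class].
#' @param sampleIdx integer indices of the training samples to use (default:
#'   all samples).
#' @param k MI neighbor count.
#' @param jitterSeed seed for the CNV tie-breaking jitter.
#' @return object of class "FeatureSelection": list with per-omics
#'   data.frame (gene, mi, kept), `threshold` per omics, `kept` gene lists,
#'   and attribute `samples_used`.
#' @export
selectFeatures <- function(cohort, sampleIdx = seq_along(cohortLabels(cohort)),
                           k = 3L, jitterSeed = 1L) {
  y <- cohortLabels(cohort)
  if (!length(y)) stop("cohort has no labels; call labelCohort() first")
  y <- y[sampleIdx]
  tables <- list(); thresholds <- numeric(); kept <- list()
  for (om in names(cohort@assays)) {
    Xm <- cohort@assays[[om]][sampleIdx, , drop = FALSE]
    if (om == "CNV")
      Xm <- Xm + withSeed(deriveSeed(jitterSeed, 7L),
                          matrix(runif(length(Xm), -1e-10, 1e-10), nrow(Xm)))
    mi <- vapply(seq_len(ncol(Xm)), function(j)
      as.numeric(miDiscreteContinuous(Xm[, j], y, k = k)), 0)
    thr <- mean(mi)
    keep <- mi > thr
    if (!any(keep))
      stop("feature selection retained no genes in omics ", om,
           " (all MI values equal?)")
    tables[[om]] <- data.frame(gene = colnames(Xm), mi = mi, kept = keep,
                               stringsAsFactors = FALSE)
    thresholds[om] <- thr
    kept[[om]] <- colnames(Xm)[keep]
  }
  out <- list(tables = tables, threshold = thresholds, kept = kept, k = k)
  attr(out, "samples_used") <- rownames(cohort@assays[[1]])[sampleIdx]
  class(out) <- "FeatureSelection"
  out
}

#' @export
print.FeatureSelection <- function(x, ...) {
  cat("FeatureSelection (k =", x$k, "):\n")
  for (om in names(x$tables))
    cat(sprintf("  %-4s: %d / %d genes kept (mean MI threshold %.4f)\n",
                om, sum(x$tables[[om]]$kept), nrow(x$tables[[om]]),
                x$threshold[om]))
  invisible(x)
}

#' Serialize a feature selection to TSV (omics, gene, mi, kept)
#' @param sel a "FeatureSelection".
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeFeatureSelection <- function(sel, path) {
  df <- do.call(rbind, lapply(names(sel$tables), function(om)
    cbind(omics = om, sel$tables[[om]])))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
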