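# Guidance-graph construction: per-TF weight normalization and assembly of
# the signed multi-omics graph.

#' Normalize TF out-edge scores into \[0, 1\]
#'
#' Regulatory importance scores are normalized per transcription factor over
#' that TF's out-edges. `mode = "max"` (default) divides by the TF's maximum
#' score, keeping every edge non-zero; `mode = "minmax"` maps each TF's range
#' onto \[0, 1\] (its weakest edge becomes 0). A TF with a single out-edge
#' (or with all scores equal under minmax) gets weight 1.
#'
#' @param network RegulatoryNetwork data.frame (tf, target, score).
#' @param mode "max" or "minmax".
#' @return the network with `score` replaced by normalized weights.
#' @export
normalizeTFWeights <- function(network, mode = c("max", "minmax")) {
  mode <- match.arg(mode)
  if (!nrow(network)) stop("empty regulatory network")
  if (any(network$score <= 0)) stop("scores must be positive before normalization")
  s <- split(seq_len(nrow(network)), network$tf)
  out <- network$score
  for (idx in s) {
    v <- network$score[idx]
    if (mode == "max") {
      out[idx] <- v / max(v)
    } else {
      rng <- max(v) - min(v)
      out[idx] <- if (rng == 0) 1 else (v - min(v)) / rng
    }
  }
  network$score <- out
  attr(network, "normalized") <- TRUE
  network
}

#' Build the signed multi-omics guidance graph
#'
#' Nodes are the union of (gene, omics) pairs over `geneLists`. Edges:
#' regulatory TF -> target edges among the retained mRNA genes carry their
#' normalized weights; every gene present in both the CNV and mRNA lists
#' contributes a +1 CNV-mRNA edge; every gene in both the MT and mRNA lists a
#' -1 MT-mRNA edge. Regulatory edges with a filtered-out endpoint are
#' dropped. Empty intersections simply produce isolated nodes.
#'
#' @param network normalized RegulatoryNetwork (see [normalizeTFWeights()]).
#' @param geneLists named list of gene id vectors; names among mRNA, CNV, MT.
#'   "mRNA" must be present.
#' @return a [GuidanceGraph-class].
#' @export
buildGuidanceGraph <- function(network, geneLists) {
  checkOmicsName(names(geneLists))
  if (!"mRNA" %in% names(geneLists)) stop("geneLists must include mRNA")
  if (!isTRUE(attr(network, "normalized")) && nrow(network) &&
      any(network$score > 1))
    stop("network scores exceed 1; normalize with normalizeTFWeights() first")
  present <- intersect(OMICS_LEVELS, names(geneLists))
  nodes <- do.call(rbind, lapply(present, function(om)
    data.frame(gene = unique(geneLists[[om]]), omics = om, stringsAsFactors = FALSE)))
  rownames(nodes) <- NULL
  key <- paste(nodes$gene, nodes$omics)
  idxOf <- function(gene, om) match(paste(gene, om), key)

  edges <- list()
  mr <- geneLists[["mRNA"]]
  keep <- network$tf %in% mr & network$target %in% mr & network$tf != network$target
  if (any(keep)) {
    nk <- network[keep, , drop = FALSE]
    edges$mRNA <- data.frame(src = idxOf(nk$tf, "mRNA"), dst = idxOf(nk$target, "mRNA"),
                             weight = nk$score, type = "mRNA", stringsAsFactors = FALSE)
  }
  if ("CNV" %in% present) {
    shared <- intersect(geneLists[["CNV"]], mr)
    if (length(shared))
      edges$CM <- data.frame(src = idxOf(shared, "CNV"), dst = idxOf(shared, "mRNA"),
                             weight = 1, type = "CM", stringsAsFactors = FALSE)
  }
  if ("MT" %in% present) {
    shared <- intersect(geneLists[["MT"]], mr)
    if (length(shared))
      edges$MM <- data.frame(src = idxOf(shared, "MT"), dst = idxOf(shared, "mRNA"),
                             weight = -1, type = "MM", stringsAsFactors = FALSE)
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(src = integer(), dst = integer(), weight = numeric(), type = character())
  rownames(edges) <- NULL
  new("GuidanceGraph", nodes = nodes, edges = edges)
}

#' Row-normalized signed adjacency operator of a guidance graph
#'
#' Expands stored (directed) edges symmetrically, then divides each row by
#' the sum of absolute incident weights, so message passing computes a
#' weighted mean of neighbor features in which methylation edges contribute
#' subtractively. Isolated nodes get a zero row.
#'
#' @param graph a [GuidanceGraph-class].
#' @return a sparse `dgCMatrix` (nodes x nodes).
#' @export
graphOperator <- function(graph) {
  V <- nrow(graph@nodes); e <- graph@edges
  if (!nrow(e))
    return(Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                                dims = c(V, V)))
  i <- c(e$src, e$dst); j <- c(e$dst, e$src); x <- c(e$weight, e$weight)
  A <- Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(V, V),
                            use.last.ij = FALSE)
  Aabs <- Matrix::sparseMatrix(i = i, j = j, x = abs(x), dims = c(V, V))
  rs <- Matrix::rowSums(Aabs)
  rs[rs == 0] <- 1
  Matrix::Diagonal(x = 1 / rs) %*% A
}
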