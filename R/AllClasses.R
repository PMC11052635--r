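#' PathwayMap: ordered pathway -> member gene lists
#'
#' Thin container for KEGG-style gene-set membership as read from a GMT
#' file. Pathway order is preserved from the source; gene lists are
#' de-duplicated and non-empty.
#'
#' @slot ids character vector of pathway identifiers (unique, ordered).
#' @slot genes list of character vectors, one per pathway.
#' @slot description character vector of free-text descriptions.
#' @export
setClass("PathwayMap",
  representation(ids = "character", genes = "list", description = "character"),
  validity = function(object) {
    msg <- character()
    if (length(object@ids) != length(object@genes))
      msg <- c(msg, "ids and genes lengths differ")
    if (anyDuplicated(object@ids))
      msg <- c(msg, "duplicate pathway ids")
    if (length(object@genes) && any(vapply(object@genes, length, 1L) == 0L))
      msg <- c(msg, "empty pathway gene list")
    if (length(object@genes) && any(vapply(object@genes, anyDuplicated, 1L) > 0L))
      msg <- c(msg, "duplicated gene within a pathway")
    if (length(msg)) msg else TRUE
  })

#' MultiOmicsCohort: aligned per-omics matrices plus clinical covariates
#'
#' Holds up to three sample x gene matrices (mRNA expression, copy-number
#' variation, DNA methylation) over a common, ordered sample set, the
#' clinical table, and optionally binary long-term-survivor labels.
#'
#' @slot assays named list of numeric matrices (samples x genes), names a
#'   subset of mRNA/CNV/MT; row names are sample ids in common order.
#' @slot clinical data.frame with sample_id, survival_time (days), event,
#'   and optionally age.
#' @slot labels integer vector (1 = long-term survivor, 0 = non-LTS) aligned
#'   to samples, or length 0 before labeling.
#' @slot thresholdYears numeric scalar used to derive labels (NA before
#'   labeling).
#' @export
setClass("MultiOmicsCohort",
  representation(assays = "list", clinical = "data.frame",
                 labels = "integer", thresholdYears = "numeric"),
  prototype(labels = integer(), thresholdYears = NA_real_),
  validity = function(object) {
    msg <- character()
    if (!length(object@assays)) msg <- c(msg, "no assays")
    nm <- names(object@assays)
    if (is.null(nm) || !all(nm %in% OMICS_LEVELS))
      msg <- c(msg, "assay names must be among mRNA, CNV, MT")
    sids <- rownames(object@assays[[1]])
    for (a in object@assays) {
      if (!is.matrix(a) || !is.numeric(a)) msg <- c(msg, "assays must be numeric matrices")
      else {
        if (!identical(rownames(a), sids)) msg <- c(msg, "sample order differs across assays")
        if (anyDuplicated(colnames(a))) msg <- c(msg, "duplicate gene ids in an assay")
        if (anyNA(a)) msg <- c(msg, "missing values in an assay")
      }
    }
    if (length(object@labels) && length(object@labels) != length(sids))
      msg <- c(msg, "labels length differs from sample count")
    if (length(object@labels) && !all(object@labels %in% c(0L, 1L)))
      msg <- c(msg, "labels must be 0/1")
    if (length(msg)) msg else TRUE
  })

#' GuidanceGraph: signed, weighted, typed-node multi-omics graph
#'
#' Nodes are (gene, omics) pairs over the union of the per-omics gene lists.
#' mRNA-mRNA edges carry per-TF-normalized regulatory weights in \[0, 1\];
#' CNV-mRNA edges have weight +1 and methylation-mRNA edges weight -1,
#' reflecting the typical direction of association with expression. CNV and
#' MT nodes are never connected to each other.
#'
#' @slot nodes data.frame with columns gene, omics; row order defines the
#'   node index.
#' @slot edges data.frame with columns src, dst (integer node indices),
#'   weight, type (one of mRNA, CM, MM). Regulatory edges are stored
#'   directed TF -> target; message passing treats them as undirected.
#' @export
setClass("GuidanceGraph",
  representation(nodes = "data.frame", edges = "data.frame"),
  validity = function(object) {
    msg <- character()
    n <- object@nodes; e <- object@edges
    if (!all(c("gene", "omics") %in% names(n))) msg <- c(msg, "nodes need gene, omics")
    if (!all(n$omics %in% OMICS_LEVELS)) msg <- c(msg, "bad omics tag in nodes")
    if (anyDuplicated(paste(n$gene, n$omics))) msg <- c(msg, "duplicate (gene, omics) node")
    if (nrow(e)) {
      if (!all(c("src", "dst", "weight", "type") %in% names(e)))
        msg <- c(msg, "edges need src, dst, weight, type")
      else {
        if (any(e$src < 1L | e$src > nrow(n) | e$dst < 1L | e$dst > nrow(n)))
          msg <- c(msg, "edge endpoint out of range")
        so <- n$omics[e$src]; do <- n$omics[e$dst]
        if (any((so == "CNV" & do == "MT") | (so == "MT" & do == "CNV")))
          msg <- c(msg, "CNV-MT edge not allowed")
        mm <- e$type == "mRNA"
        if (any(mm & (e$weight < 0 | e$weight > 1)))
          msg <- c(msg, "mRNA-mRNA edge weight outside [0, 1]")
        if (any(e$type == "CM" & e$weight != 1)) msg <- c(msg, "CNV-mRNA weight must be +1")
        if (any(e$type == "MM" & e$weight != -1)) msg <- c(msg, "MT-mRNA weight must be -1")
      }
    }
    if (length(msg)) msg else TRUE
  })

#' MultilevelGNN: trained multilevel graph neural network
#'
#' Bundles the guidance graph, per-(pathway, omics) aggregation blocks,
#' all trainable parameters, the pathway ordering, feature selection and
#' the configuration used to fit the model.
#'
#' @slot graph the [GuidanceGraph-class] the model was built on.
#' @slot blocks list of pathway-aggregation block descriptors.
#' @slot params named list of parameter matrices/vectors.
#' @slot pathwayOrder integer permutation of pathways used by the head.
#' @slot pathwayIds character vector of pathway ids (unordered reference).
#' @slot omics character vector of omics layers in the model (column order
#'   of the pathway feature tensor).
#' @slot selection the per-omics feature selection ("FeatureSelection").
#' @slot ageStats numeric length-2 (mean, sd) for age standardization, or
#'   NULL-like NA pair when age is unused.
#' @slot config named list of hyperparameters.
#' @export
setClass("MultilevelGNN",
  representation(graph = "GuidanceGraph", blocks = "list", params = "list",
                 pathwayOrder = "integer", pathwayIds = "character",
                 omics = "character", selection = "list",
                 ageStats = "numeric", config = "list"))

#' @describeIn PathwayMap number of pathways
#' @param x a PathwayMap.
#' @export
setMethod("length", "PathwayMap", function(x) length(x@ids))

setMethod("show", "PathwayMap", function(object) {
  cat("PathwayMap with", length(object@ids), "pathways;",
      "gene-set sizes", if (length(object@ids))
        paste(range(vapply(object@genes, length, 1L)), collapse = "-") else "-", "\n")
})

setMethod("show", "MultiOmicsCohort", function(object) {
  cat("MultiOmicsCohort:", nrow(object@assays[[1]]), "samples\n")
  for (nm in names(object@assays))
    cat("  ", nm, ": ", ncol(object@assays[[nm]]), " genes\n", sep = "")
  if (length(object@labels))
    cat("  labels: ", sum(object@labels == 1L), " LTS / ",
        sum(object@labels == 0L), " non-LTS (threshold ",
        object@thresholdYears, " y)\n", sep = "")
  if ("age" %in% names(object@clinical)) cat("  age available\n")
})

setMethod("show", "GuidanceGraph", function(object) {
  cat("GuidanceGraph:", nrow(object@nodes), "nodes (",
      paste(names(table(object@nodes$omics)), table(object@nodes$omics),
            collapse = ", "), "),",
      nrow(object@edges), "edges (",
      paste(names(table(object@edges$type)), table(object@edges$type),
            collapse = ", "), ")\n")
})

setMethod("show", "MultilevelGNN", function(object) {
  cat("MultilevelGNN: D =", object@config$D,
      "| nodes =", nrow(object@graph@nodes),
      "| blocks =", length(object@blocks),
      "| pathways =", length(object@pathwayIds),
      "| omics =", paste(object@omics, collapse = "+"), "\n")
})

# ---- accessors ----

#' Accessors for mlgnn S4 objects
#'
#' @param x object.
#' @param omics optional omics name to extract a single assay.
#' @return `omicsAssays` returns the named list of matrices (or one matrix);
#'   `clinicalTable` the clinical data.frame; `cohortLabels` the 0/1 label
#'   vector; `pathwayIds`/`pathwayGenes` the id vector and gene-set list;
#'   `graphNodes`/`graphEdges` the node and edge tables.
#' @name accessors
NULL

#' @rdname accessors
#' @export
omicsAssays <- function(x, omics = NULL) {
  stopifnot(is(x, "MultiOmicsCohort"))
  if (is.null(omics)) x@assays else x@assays[[checkOmicsName(omics)]]
}

#' @rdname accessors
#' @export
clinicalTable <- function(x) { stopifnot(is(x, "MultiOmicsCohort")); x@clinical }

#' @rdname accessors
#' @export
cohortLabels <- function(x) { stopifnot(is(x, "MultiOmicsCohort")); x@labels }

#' @rdname accessors
#' @export
sampleIds <- function(x) { stopifnot(is(x, "MultiOmicsCohort")); rownames(x@assays[[1]]) }

#' @rdname accessors
#' @export
pathwayIds <- function(x) { stopifnot(is(x, "PathwayMap")); x@ids }

#' @rdname accessors
#' @export
pathwayGenes <- function(x) { stopifnot(is(x, "PathwayMap")); stats::setNames(x@genes, x@ids) }

#' @rdname accessors
#' @export
graphNodes <- function(x) { stopifnot(is(x, "GuidanceGraph")); x@nodes }

#' @rdname accessors
#' @export
graphEdges <- function(x) { stopifnot(is(x, "GuidanceGraph")); x@edges }

#' Construct a MultiOmicsCohort from matrices and a clinical table
#'
#' @param assays named list of numeric sample x gene matrices (names among
#'   mRNA, CNV, MT) sharing the same ordered sample set.
#' @param clinical clinical data.frame as returned by [readClinical()].
#' @return a [MultiOmicsCohort-class].
#' @export
MultiOmicsCohort <- function(assays, clinical) {
  sids <- rownames(assays[[1]])
  clinical <- clinical[match(sids, clinical$sample_id), , drop = FALSE]
  if (anyNA(clinical$sample_id))
    stop("clinical table is missing some assay samples")
  rownames(clinical) <- NULL
  new("MultiOmicsCohort", assays = assays, clinical = clinical)
}
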