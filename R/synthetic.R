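# Synthetic multi-omics cohort generator: a fully in-silico cohort with a
# planted regulatory network, pathway structure and survival-risk signal, so
# that every pipeline stage (selection, encoding, aggregation, CV,
# explanation) has a checkable ground truth.

#' Specification of a synthetic cohort
#'
#' Defaults are the package's reference desk-scale study conditions: 300
#' samples, 600 genes (20 of them TFs), 30 pathways of 10-40 genes of which
#' 3 are risk-driver pathways, and 30 risk-informative genes (10 per omics
#' layer) clustered inside the driver pathways. `effect_size = 3` plants a
#' strong, recoverable signal; 0 gives a pure-noise null cohort.
#'
#' @param n_samples,n_genes,n_tfs,n_pathways cohort dimensions.
#' @param pathway_size length-2 integer range of pathway sizes.
#' @param n_informative number of risk-informative genes (split evenly
#'   across omics layers).
#' @param n_drivers number of driver pathways hosting the informative genes.
#' @param effect_size per-gene risk effect added to the routed omics layer.
#' @param noise_sd sd of the per-gene measurement noise.
#' @param censor_rate approximate fraction of samples with censored
#'   follow-up (exponential censoring).
#' @param seed integer seed; the generator is bit-reproducible per seed.
#' @return list of class "SyntheticSpec".
#' @export
syntheticSpec <- function(n_samples = 300L, n_genes = 600L, n_tfs = 20L,
                          n_pathways = 30L, pathway_size = c(10L, 40L),
                          n_informative = 30L, n_drivers = 3L,
                          effect_size = 3.0, noise_sd = 1.0,
                          censor_rate = 0.1, seed = 1L) {
  spec <- list(n_samples = as.integer(n_samples), n_genes = as.integer(n_genes),
               n_tfs = as.integer(n_tfs), n_pathways = as.integer(n_pathways),
               pathway_size = as.integer(pathway_size),
               n_informative = as.integer(n_informative),
               n_drivers = as.integer(n_drivers),
               effect_size = effect_size, noise_sd = noise_sd,
               censor_rate = censor_rate, seed = as.integer(seed))
  if (spec$n_informative > spec$n_genes) stop("n_informative > n_genes")
  if (spec$n_drivers > spec$n_pathways) stop("n_drivers > n_pathways")
  if (spec$effect_size < 0) stop("effect_size must be >= 0")
  if (max(spec$pathway_size) > spec$n_genes)
    stop("infeasible spec: pathway sizes exceed gene count")
  class(spec) <- "SyntheticSpec"
  spec
}

#' Generate a synthetic multi-omics cohort
#'
#' Construction: genes receive a latent expression baseline with mild
#' TF -> target co-expression along the planted regulatory network; CNV is
#' positively and methylation negatively coupled to expression for every
#' gene (matching the +1 / -1 guidance-graph edge semantics). A latent
#' per-sample risk r ~ N(0,1) is added (scaled by `effect_size`) to the
#' routed omics layer of each informative gene; survival time is log-linear
#' in -r with exponential censoring, so long-term survivors are the
#' low-risk samples. The risk is the normalized sum of one independent
#' component per driver pathway, and each driver's informative genes carry
#' only that driver's component, so the drivers are mutually non-redundant
#' and gene- and pathway-level explanations have distinct, checkable ground
#' truths.
#'
#' @param spec a [syntheticSpec()].
#' @return list with `cohort` ([MultiOmicsCohort-class]), `network`
#'   (RegulatoryNetwork), `pathways` ([PathwayMap-class]), `clinical`
#'   (data.frame), and `truth` (informative genes per omics, driver pathway
#'   ids, true edges, latent risk).
#' @export
generateCohort <- function(spec = syntheticSpec()) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  withSeed(spec$seed, {
    G <- spec$n_genes; n <- spec$n_samples
    genes <- sprintf("g%04d", seq_len(G))
    tfs <- genes[seq_len(spec$n_tfs)]

    # regulatory network: each TF regulates 8-20 random non-TF targets
    edges <- do.call(rbind, lapply(tfs, function(tf) {
      nt <- sample(8:20, 1)
      data.frame(tf = tf, target = sample(setdiff(genes, tf), nt),
                 score = rgamma(nt, shape = 2, rate = 0.5),
                 stringsAsFactors = FALSE)
    }))
    network <- validateNetwork(edges)

    # informative genes: non-TF genes, routed per omics, clustered in drivers
    nInf <- spec$n_informative
    informative <- sample(setdiff(genes, tfs), nInf)
    # omics routing in blocks, driver assignment cyclic: every driver hosts
    # genes from all omics layers (no aliasing between the two assignments)
    route <- rep(OMICS_LEVELS, each = ceiling(nInf / 3))[seq_len(nInf)]
    drv <- rep_len(seq_len(spec$n_drivers), nInf)

    # pathways: informative genes appear only inside the driver pathways, so
    # pathway-level explanations have a clean ground truth
    sizes <- sample(spec$pathway_size[1]:spec$pathway_size[2],
                    spec$n_pathways, replace = TRUE)
    background <- setdiff(genes, informative)
    pwGenes <- vector("list", spec$n_pathways)
    for (p in seq_len(spec$n_pathways)) {
      if (p <= spec$n_drivers) {
        core <- informative[drv == p]
        sizes[p] <- max(sizes[p], length(core))
        filler <- sample(background, sizes[p] - length(core))
        pwGenes[[p]] <- sample(c(core, filler))
      } else {
        pwGenes[[p]] <- sample(background, sizes[p])
      }
    }
    pwIds <- sprintf("PW%03d", seq_len(spec$n_pathways))
    pathways <- new("PathwayMap", ids = pwIds, genes = pwGenes,
                    description = ifelse(seq_len(spec$n_pathways) <= spec$n_drivers,
                                         "driver", "background"))

    # latent risk: one independent component per driver pathway, so each
    # driver carries its own (non-redundant) share of the total risk and a
    # correct model must rely on all of them
    rk <- matrix(rnorm(n * spec$n_drivers), n, spec$n_drivers)
    r <- rowSums(rk) / sqrt(spec$n_drivers)
    expr <- matrix(rnorm(n * G, sd = spec$noise_sd), n, G,
                   dimnames = list(sprintf("s%04d", seq_len(n)), genes))
    # mild TF -> target co-expression so the regulatory graph is real signal
    wmax <- tapply(network$score, network$tf, max)
    for (e in seq_len(nrow(network))) {
      w <- network$score[e] / wmax[network$tf[e]]
      expr[, network$target[e]] <- expr[, network$target[e]] +
        0.4 * w * expr[, network$tf[e]]
    }
    cnv <- 0.6 * expr + matrix(rnorm(n * G, sd = 0.8 * spec$noise_sd), n, G)
    mt <- -0.6 * expr + matrix(rnorm(n * G, sd = 0.8 * spec$noise_sd), n, G)
    dimnames(cnv) <- dimnames(mt) <- dimnames(expr)

    layers <- list(mRNA = expr, CNV = cnv, MT = mt)
    for (i in seq_len(nInf))
      layers[[route[i]]][, informative[i]] <-
        layers[[route[i]]][, informative[i]] + spec$effect_size * rk[, drv[i]]

    # survival: log-linear in -r, exponential censoring; age mildly
    # risk-associated
    medianDays <- 2 * DAYS_PER_YEAR
    Tdays <- exp(log(medianDays) - r + rnorm(n, sd = 0.4))
    Cdays <- rexp(n, rate = spec$censor_rate / medianDays)
    clinical <- data.frame(
      sample_id = rownames(expr),
      survival_time = pmin(Tdays, Cdays),
      event = as.integer(Tdays <= Cdays),
      age = round(55 + (spec$effect_size > 0) * 2 * r + rnorm(n, sd = 8), 1),
      stringsAsFactors = FALSE)

    cohort <- MultiOmicsCohort(layers, clinical)
    truth <- list(
      informative = split(informative, route)[intersect(OMICS_LEVELS, unique(route))],
      informative_all = informative,
      drivers = pwIds[seq_len(spec$n_drivers)],
      edges = network[, c("tf", "target")],
      risk = stats::setNames(r, rownames(expr)),
      risk_components = rk,
      n_genes = G)
    list(cohort = cohort, network = network, pathways = pathways,
         clinical = clinical, truth = truth, spec = spec)
  })
}

#' Write a synthetic cohort in the package's file dialects
#'
#' Emits per-omics matrices, the edge list, the GMT pathway file, the
#' clinical table and a ground-truth JSON into `dir`.
#'
#' @param sim result of [generateCohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeCohort <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (om in names(sim$cohort@assays))
    writeOmicsMatrix(sim$cohort@assays[[om]], file.path(dir, paste0(om, ".tsv")))
  writeEdgeList(sim$network, file.path(dir, "network.tsv"))
  writeGMT(sim$pathways, file.path(dir, "pathways.gmt"))
  writeClinical(sim$clinical, file.path(dir, "clinical.tsv"))
  jsonlite::write_json(
    list(informative = sim$truth$informative, drivers = sim$truth$drivers),
    file.path(dir, "truth.json"), auto_unbox = FALSE, pretty = TRUE)
  invisible(dir)
}

#' Read a cohort directory written by [writeCohort()]
#' @param dir directory containing mRNA.tsv, CNV.tsv, MT.tsv, network.tsv,
#'   pathways.gmt, clinical.tsv.
#' @param omics omics layers to load.
#' @return list(cohort, network, pathways, clinical).
#' @export
readCohortDir <- function(dir, omics = c("mRNA", "CNV", "MT")) {
  assays <- lapply(stats::setNames(omics, omics), function(om)
    readOmicsMatrix(file.path(dir, paste0(om, ".tsv")), om))
  clinical <- readClinical(file.path(dir, "clinical.tsv"))
  list(cohort = MultiOmicsCohort(assays, clinical),
       network = readEdgeList(file.path(dir, "network.tsv")),
       pathways = readGMT(file.path(dir, "pathways.gmt")),
       clinical = clinical)
}

#' Recovery metrics of a pipeline run against the planted ground truth
#'
#' Reports, for whichever inputs are supplied: the MI-selection recall of
#' informative genes (per omics), the top-decile recall of planted genes in
#' the gene-explainer ranking, precision/recall of key-pathway calls against
#' the driver pathways, and the CV AUC.
#'
#' @param truth ground truth from [generateCohort()].
#' @param selection optional "FeatureSelection".
#' @param geneImp optional [geneImportance()] table.
#' @param pathImp optional [pathwayImportance()] table.
#' @param cv optional "CVResult".
#' @return named list of metrics, all in \[0, 1\] (AUC included).
#' @export
recoveryReport <- function(truth, selection = NULL, geneImp = NULL,
                           pathImp = NULL, cv = NULL) {
  out <- list()
  if (!is.null(selection)) {
    rec <- vapply(names(truth$informative), function(om) {
      inf <- truth$informative[[om]]
      if (!om %in% names(selection$kept)) return(NA_real_)
      mean(inf %in% selection$kept[[om]])
    }, 0)
    out$mi_recall <- rec
    out$mi_recall_mean <- mean(rec, na.rm = TRUE)
  }
  if (!is.null(geneImp)) {
    if (!any(truth$informative_all %in% geneImp$gene) &&
        !any(geneImp$gene %in% unlist(truth$edges)))
      stop("cohort/truth mismatch: no ground-truth gene appears in the importance table")
    rec <- vapply(names(truth$informative), function(om) {
      d <- geneImp[geneImp$omics == om, ]
      if (!nrow(d)) return(NA_real_)
      # decile of the omics' gene universe; genes dropped by selection rank
      # below every ranked gene
      universe <- if (!is.null(truth$n_genes)) truth$n_genes else nrow(d)
      topN <- max(1L, ceiling(universe / 10))
      top <- d$gene[d$rank <= topN]
      inf <- truth$informative[[om]]
      if (!any(inf %in% d$gene)) return(NA_real_)
      mean(inf %in% top)
    }, 0)
    out$explainer_top_decile_recall <- rec
    out$explainer_top_decile_recall_mean <- mean(rec, na.rm = TRUE)
  }
  if (!is.null(pathImp)) {
    keyPw <- unique(pathImp$pathway[pathImp$key])
    out$key_pathway_recall <- mean(truth$drivers %in% keyPw)
    out$key_pathway_precision <-
      if (length(keyPw)) mean(keyPw %in% truth$drivers) else NA_real_
  }
  if (!is.null(cv)) out$cv_auc <- cv$mean
  stopifnot(all(unlist(out) >= 0 | is.na(unlist(out))),
            all(unlist(out) <= 1 | is.na(unlist(out))))
  out
}
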