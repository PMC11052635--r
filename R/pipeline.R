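# Pipeline entry point: strict config validation, deterministic seeding,
# run-directory artifacts with a self-describing manifest.

defaultRunConfig <- function() {
  list(
    data_dir = NULL,
    out_dir = "mlgnn_run",
    seed = 1L,
    threshold_years = 2,
    omics = c("mRNA", "CNV", "MT"),
    folds = 5L,
    repeats = 5L,
    mi_k = 3L,
    model = defaultModelConfig()[c("D", "M_dims", "lambda_ind", "hidden", "lr",
                                   "epochs", "batch_size", "val_frac",
                                   "patience", "use_age", "pool_kernel")],
    explainer = list(alpha = 1, beta = 0.005, gamma = 0.1, steps = 300L,
                     lr = 0.01),
    ig = list(steps = 128L, baseline = "zeros"),
    simulate = list()
  )
}

#' Validate a pipeline configuration
#'
#' Fills defaults and rejects unknown keys (including unknown nested keys
#' under `model`, `explainer`, `ig` and `simulate`) before any compute.
#'
#' @param config named list (e.g. parsed from YAML/JSON).
#' @return the merged, validated configuration.
#' @export
validateRunConfig <- function(config = list()) {
  base <- defaultRunConfig()
  unknown <- setdiff(names(config), names(base))
  if (length(unknown))
    stop("invalid config: unknown key(s): ", paste(unknown, collapse = ", "))
  nestedOK <- list(
    model = names(base$model),
    explainer = names(base$explainer),
    ig = names(base$ig),
    simulate = setdiff(names(formals(syntheticSpec)), "seed"))
  for (nm in names(nestedOK)) {
    bad <- setdiff(names(config[[nm]]), nestedOK[[nm]])
    if (length(bad))
      stop("invalid config: unknown key(s) under '", nm, "': ",
           paste(bad, collapse = ", "))
  }
  for (nm in names(config)) {
    if (nm %in% names(nestedOK)) base[[nm]][names(config[[nm]])] <- config[[nm]]
    else base[[nm]] <- config[[nm]]
  }
  if (!"mRNA" %in% base$omics) stop("invalid config: omics must include mRNA")
  base$seed <- as.integer(base$seed)
  base
}

#' Read a pipeline configuration from YAML or JSON
#' @param path file ending in .yaml/.yml or .json.
#' @return validated config list.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  validateRunConfig(as.list(raw))
}

# stable 32-bit FNV-1a hash of the deparsed config, for the run manifest
configHash <- function(config) {
  s <- paste(deparse(config[order(names(config))]), collapse = "")
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

writeManifest <- function(config, command, outDir) {
  jsonlite::write_json(
    list(command = command, seed = config$seed,
         config_hash = configHash(config),
         package_version = as.character(utils::packageVersion("mlgnn")),
         config = config),
    file.path(outDir, "manifest.json"), auto_unbox = TRUE, pretty = TRUE,
    null = "null")
}

loadRunData <- function(config) {
  if (is.null(config$data_dir)) stop("config needs data_dir")
  dat <- readCohortDir(config$data_dir, config$omics)
  dat$cohort <- labelCohort(dat$cohort, config$threshold_years)
  dat
}

modelConfigOf <- function(config) c(config$model, list(mi_k = config$mi_k))

#' Run a pipeline stage
#'
#' Commands: `simulate` (write a synthetic cohort into the run directory),
#' `train` (cross-validate, then fit a final model on all samples and write a
#' checkpoint plus risk groups), `explain-genes` (node-mask gene importance
#' from the checkpoint), `explain-pathways` (Integrated-Gradients pathway
#' importance from the checkpoint), `ablate` (omics-combination ablation).
#' Every command writes a manifest (config hash, seed, package version) into
#' the run directory; identical config + seed reproduce identical artifacts.
#'
#' @param config validated configuration (see [validateRunConfig()]).
#' @param command one of simulate, train, explain-genes, explain-pathways,
#'   ablate.
#' @return invisibly, a list of the artifacts written.
#' @export
runPipeline <- function(config, command = c("simulate", "train",
                                            "explain-genes",
                                            "explain-pathways", "ablate")) {
  command <- match.arg(command)
  config <- validateRunConfig(config)
  outDir <- config$out_dir
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  arts <- list()

  if (command == "simulate") {
    spec <- do.call(syntheticSpec, c(config$simulate, list(seed = config$seed)))
    sim <- generateCohort(spec)
    dataDir <- config$data_dir %||% file.path(outDir, "data")
    writeCohort(sim, dataDir)
    arts$data_dir <- dataDir
  } else if (command == "train") {
    dat <- loadRunData(config)
    cv <- crossValidate(dat$cohort, dat$network, dat$pathways,
                        modelConfigOf(config), nFolds = config$folds,
                        nRepeats = config$repeats, seed = config$seed,
                        omics = config$omics)
    resTab <- data.frame(repeat_ = seq_along(cv$auc), pooled_auc = cv$auc)
    write.table(resTab, file.path(outDir, "cv_results.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    jsonlite::write_json(list(mean_auc = cv$mean, sd_auc = cv$sd,
                              folds = config$folds, repeats = config$repeats),
                         file.path(outDir, "cv_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    # final model on all labeled samples, for explanation stages
    net <- normalizeTFWeights(dat$network)
    sel <- selectFeatures(dat$cohort, k = config$mi_k,
                          jitterSeed = config$seed)
    graph <- buildGuidanceGraph(net, sel$kept[intersect(config$omics, names(sel$kept))])
    model <- buildModel(graph, dat$cohort, dat$pathways, sel,
                        config$model, seed = deriveSeed(config$seed, 5L))
    model <- trainModel(model, dat$cohort, seed = deriveSeed(config$seed, 6L))
    saveRDS(model, file.path(outDir, "checkpoint.rds"))
    pr <- predictRisk(model, dat$cohort)
    write.table(stratifyRisk(pr$score, pr$sample_id),
                file.path(outDir, "risk_groups.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    arts$cv <- cv
    arts$checkpoint <- file.path(outDir, "checkpoint.rds")
  } else if (command == "explain-genes") {
    dat <- loadRunData(config)
    model <- readRDS(file.path(outDir, "checkpoint.rds"))
    cfg <- do.call(explainerConfig, config$explainer)
    masks <- optimizeNodeMask(model, dat$cohort, cfg = cfg)
    imp <- geneImportance(masks, model@graph)
    writeGeneImportance(imp, file.path(outDir, "gene_importance.tsv"))
    arts$gene_importance <- imp
  } else if (command == "explain-pathways") {
    dat <- loadRunData(config)
    model <- readRDS(file.path(outDir, "checkpoint.rds"))
    ig <- pathwayIG(model, dat$cohort, steps = config$ig$steps,
                    baseline = config$ig$baseline)
    imp <- pathwayImportance(ig)
    writePathwayImportance(imp, file.path(outDir, "pathway_importance.tsv"))
    arts$pathway_importance <- imp
  } else if (command == "ablate") {
    dat <- loadRunData(config)
    combos <- list("mRNA")
    if ("CNV" %in% config$omics) combos <- c(combos, list(c("mRNA", "CNV")))
    if ("MT" %in% config$omics) combos <- c(combos, list(c("mRNA", "MT")))
    if (all(c("CNV", "MT") %in% config$omics))
      combos <- c(combos, list(c("mRNA", "CNV", "MT")))
    tab <- runOmicsAblation(dat$cohort, dat$network, dat$pathways,
                            modelConfigOf(config), combos = combos,
                            nFolds = config$folds, nRepeats = config$repeats,
                            seed = config$seed)
    write.table(tab, file.path(outDir, "ablation.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    arts$ablation <- tab
  }
  writeManifest(config, command, outDir)
  invisible(arts)
}
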