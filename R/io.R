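# Readers/writers for all external artifacts. Dialect: tab-separated, "."
# decimal point; gzip accepted transparently (connection dispatch). Every
# reader validates its schema and is a left inverse of the matching writer.

# writers need an explicit gzfile() to compress; readers pass the path
# directly (R file connections decompress gzip transparently)
openMaybeGz <- function(path, mode = "r") {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

#' Read a sample x gene omics matrix
#'
#' Expects tab-separated text: first row gene ids, first column sample ids.
#' Duplicate ids are rejected; non-numeric cells are reported with their
#' coordinates. Missing values are rejected unless `impute = TRUE`, in which
#' case per-gene medians are substituted.
#'
#' @param path file path (optionally .gz).
#' @param omics one of "mRNA", "CNV", "MT"; stored as an attribute.
#' @param impute replace NAs by the per-gene median instead of failing.
#' @return numeric matrix (samples x genes) with attribute `omics`.
#' @export
readOmicsMatrix <- function(path, omics, impute = FALSE) {
  checkOmicsName(omics)
  df <- read.table(path, header = TRUE, sep = "\t",
                   check.names = FALSE, colClasses = "character",
                   row.names = NULL, quote = "")
  sample_ids <- df[[1]]
  genes <- colnames(df)[-1]
  if (anyDuplicated(sample_ids))
    stop("schema error: duplicated sample id(s): ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (anyDuplicated(genes))
    stop("schema error: duplicated gene id(s): ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  raw <- as.matrix(df[, -1, drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(raw), nrow = nrow(raw)))
  bad <- which(is.na(num) & !(is.na(raw) | raw %in% c("NA", "")), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("parse error: non-numeric cell at row %d (sample %s), column %d (gene %s): '%s'",
                 bad[1, 1], sample_ids[bad[1, 1]], bad[1, 2], genes[bad[1, 2]],
                 raw[bad[1, 1], bad[1, 2]]))
  dimnames(num) <- list(sample_ids, genes)
  if (anyNA(num)) {
    if (!impute)
      stop("missing values present; rerun with impute = TRUE for per-gene median imputation")
    for (j in which(colSums(is.na(num)) > 0)) {
      med <- median(num[, j], na.rm = TRUE)
      if (is.na(med)) stop("gene ", genes[j], " is entirely missing")
      num[is.na(num[, j]), j] <- med
    }
  }
  attr(num, "omics") <- omics
  num
}

#' Write a sample x gene omics matrix
#'
#' @param mat numeric matrix with sample row names and gene column names.
#' @param path output path (optionally .gz).
#' @return `path`, invisibly.
#' @export
writeOmicsMatrix <- function(mat, path) {
  con <- openMaybeGz(path, "w")
  on.exit(close(con))
  writeLines(paste(c("sample_id", colnames(mat)), collapse = "\t"), con)
  body <- cbind(rownames(mat), format(mat, digits = 17, trim = TRUE, scientific = FALSE))
  writeLines(apply(body, 1L, paste, collapse = "\t"), con)
  invisible(path)
}

#' Read pathway gene sets from a GMT file
#'
#' Standard GMT: pathway name, description, then tab-separated gene ids.
#' File order is preserved; duplicate genes within a line are dropped with a
#' warning.
#'
#' @param path GMT file path (optionally .gz).
#' @return a [PathwayMap-class].
#' @export
readGMT <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  ids <- character(); desc <- character(); genes <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      stop("parse error: GMT line ", i, " has fewer than 3 fields")
    g <- f[-(1:2)]
    g <- g[nzchar(g)]
    if (anyDuplicated(g)) {
      warning("duplicate gene(s) within pathway ", f[1], "; deduplicated")
      g <- unique(g)
    }
    ids <- c(ids, f[1]); desc <- c(desc, f[2]); genes <- c(genes, list(g))
  }
  new("PathwayMap", ids = ids, genes = genes, description = desc)
}

#' Write a PathwayMap to GMT
#' @param pm a [PathwayMap-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGMT <- function(pm, path) {
  con <- openMaybeGz(path, "w")
  on.exit(close(con))
  for (i in seq_along(pm@ids))
    writeLines(paste(c(pm@ids[i], pm@description[i], pm@genes[[i]]), collapse = "\t"), con)
  invisible(path)
}

#' Read a TF -> target regulatory edge list
#'
#' Three tab-separated columns: tf, target, score (positive real; SCENIC-style
#' importance). Repeated (tf, target) pairs keep the maximum score with a
#' warning; non-positive scores are rejected.
#'
#' @param path file path (optionally .gz).
#' @return data.frame with columns tf, target, score (class
#'   "RegulatoryNetwork" prepended).
#' @export
readEdgeList <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   colClasses = c("character", "character", "numeric"), quote = "")
  names(df) <- c("tf", "target", "score")
  validateNetwork(df)
}

validateNetwork <- function(df) {
  if (any(!is.finite(df$score)) || any(df$score <= 0))
    stop("validation error: regulatory scores must be positive reals")
  key <- paste(df$tf, df$target, sep = "\r")
  if (anyDuplicated(key)) {
    warning("repeated (tf, target) pair(s); keeping the maximum score")
    o <- order(key, -df$score)
    df <- df[o, , drop = FALSE]
    df <- df[!duplicated(key[o]), , drop = FALSE]
    df <- df[order(as.integer(factor(paste(df$tf, df$target), levels = unique(paste(df$tf, df$target))))), ]
  }
  rownames(df) <- NULL
  class(df) <- c("RegulatoryNetwork", "data.frame")
  df
}

#' Write a regulatory edge list
#' @param network RegulatoryNetwork data.frame (tf, target, score).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeEdgeList <- function(network, path) {
  con <- openMaybeGz(path, "w")
  on.exit(close(con))
  writeLines("tf\ttarget\tscore", con)
  writeLines(paste(network$tf, network$target,
                   format(network$score, digits = 17, trim = TRUE, scientific = FALSE),
                   sep = "\t"), con)
  invisible(path)
}

#' Read a clinical table
#'
#' Required columns: sample_id, survival_time (days, >= 0), event (0/1);
#' optional: age (years). Additional columns are carried through untouched.
#'
#' @param path file path (optionally .gz).
#' @return data.frame with attribute `age_available`.
#' @export
readClinical <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   check.names = FALSE, quote = "")
  req <- c("sample_id", "survival_time", "event")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("schema error: missing required clinical column(s): ",
         paste(miss, collapse = ", "))
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id)) stop("schema error: duplicated sample id")
  if (any(!is.finite(df$survival_time)) || any(df$survival_time < 0))
    stop("validation error: survival_time must be >= 0")
  if (!all(df$event %in% c(0, 1)))
    stop("validation error: event must be 0/1")
  df$event <- as.integer(df$event)
  attr(df, "age_available") <- "age" %in% names(df)
  df
}

#' Write a clinical table
#' @param clinical clinical data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeClinical <- function(clinical, path) {
  con <- openMaybeGz(path, "w")
  on.exit(close(con))
  cols <- intersect(c("sample_id", "survival_time", "event", "age"), names(clinical))
  writeLines(paste(cols, collapse = "\t"), con)
  fmt <- vapply(seq_len(nrow(clinical)), function(i)
    paste(vapply(cols, function(cn) {
      v <- clinical[[cn]][i]
      if (is.numeric(v)) format(v, digits = 17, trim = TRUE, scientific = FALSE) else as.character(v)
    }, ""), collapse = "\t"), "")
  writeLines(fmt, con)
  invisible(path)
}

#' Serialize a GuidanceGraph to TSV
#'
#' Columns: src_gene, src_omics, dst_gene, dst_omics, weight, type. Loadable
#' back bit-exactly with [readGuidanceGraph()].
#'
#' @param graph a [GuidanceGraph-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeGuidanceGraph <- function(graph, path) {
  con <- openMaybeGz(path, "w")
  on.exit(close(con))
  n <- graph@nodes; e <- graph@edges
  writeLines("# nodes", con)
  writeLines("gene\tomics", con)
  writeLines(paste(n$gene, n$omics, sep = "\t"), con)
  writeLines("# edges", con)
  writeLines("src_gene\tsrc_omics\tdst_gene\tdst_omics\tweight\ttype", con)
  if (nrow(e))
    writeLines(paste(n$gene[e$src], n$omics[e$src], n$gene[e$dst], n$omics[e$dst],
                     format(e$weight, digits = 17, trim = TRUE, scientific = FALSE),
                     e$type, sep = "\t"), con)
  invisible(path)
}

#' Read a serialized GuidanceGraph
#' @param path file written by [writeGuidanceGraph()].
#' @return a [GuidanceGraph-class].
#' @export
readGuidanceGraph <- function(path) {
  lines <- readLines(path)
  iN <- which(lines == "# nodes"); iE <- which(lines == "# edges")
  if (length(iN) != 1 || length(iE) != 1) stop("parse error: malformed guidance-graph file")
  nodeLines <- lines[(iN + 2):(iE - 1)]
  nf <- do.call(rbind, strsplit(nodeLines, "\t", fixed = TRUE))
  nodes <- data.frame(gene = nf[, 1], omics = nf[, 2], stringsAsFactors = FALSE)
  key <- paste(nodes$gene, nodes$omics)
  edgeLines <- if (iE + 2 <= length(lines)) lines[(iE + 2):length(lines)] else character()
  if (length(edgeLines)) {
    ef <- do.call(rbind, strsplit(edgeLines, "\t", fixed = TRUE))
    edges <- data.frame(
      src = match(paste(ef[, 1], ef[, 2]), key),
      dst = match(paste(ef[, 3], ef[, 4]), key),
      weight = as.numeric(ef[, 5]), type = ef[, 6], stringsAsFactors = FALSE)
  } else {
    edges <- data.frame(src = integer(), dst = integer(),
                        weight = numeric(), type = character())
  }
  new("GuidanceGraph", nodes = nodes, edges = edges)
}
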