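#' @import methods
#' @importFrom stats prcomp cor median rnorm runif rbinom rexp rgamma sd quantile
#' @importFrom utils read.table write.table head
NULL

DAYS_PER_YEAR <- 365.25

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the global RNG state so seeded internals do not
#' perturb the caller's random stream.
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a child seed from a master seed
#'
#' Deterministic fan-out so each pipeline stage (simulation, fold splits,
#' parameter init, explainers) draws from its own stream while the whole run
#' is governed by one master seed. Result is kept inside 32-bit integer range.
#'
#' @param master integer master seed.
#' @param offset integer stage/repeat offset.
#' @return integer seed.
#' @export
deriveSeed <- function(master, offset) {
  m <- as.numeric(master) %% 1000003
  as.integer((m * 1009 + as.numeric(offset) * 97 + 1) %% 2147483647)
}

OMICS_LEVELS <- c("mRNA", "CNV", "MT")

checkOmicsName <- function(omics) {
  if (!all(omics %in% OMICS_LEVELS))
    stop("unknown omics name(s): ", paste(setdiff(omics, OMICS_LEVELS), collapse = ", "),
         " (expected mRNA, CNV, MT)")
  invisible(omics)
}

# sigmoid and binary entropy used by the node-mask explainer
sigmoid <- function(x) 1 / (1 + exp(-x))

binaryEntropy <- function(p) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -p * log(p) - (1 - p) * log(1 - p)
}

#' @keywords internal
logMsg <- function(..., verbose = TRUE) {
  if (isTRUE(verbose)) message("[mlgnn] ", ...)
  invisible(NULL)
}
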