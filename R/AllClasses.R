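#' @import methods
NULL

#' ModuleSet: a co-expression module decomposition
#'
#' Holds the gene-to-module assignment produced by [detectModules()] together
#' with per-module eigengenes (first principal components of the module
#' submatrices), per-gene singular-vector loadings, and the fraction of
#' module variance each eigengene explains. Module labels are integers
#' ordered by decreasing module size; label 0 is the unassigned ("grey")
#' set.
#'
#' @slot labels named integer vector, gene -> module label (0 = unassigned).
#' @slot eigengenes numeric matrix, modules x samples; rownames `"M1"`, ...
#' @slot varianceExplained named numeric vector, one entry per module.
#' @slot loadings named list; per module, the named gene weight vector of the
#'   first left singular vector (used for projection into external cohorts).
#' @slot params list of the parameters the modules were computed under.
#'
#' @seealso [detectModules()], [moduleEigengenes()], [moduleLabels()],
#'   [eigengenes()]
#' @exportClass ModuleSet
setClass("ModuleSet",
  slots = c(labels = "integer", eigengenes = "matrix",
            varianceExplained = "numeric", loadings = "list",
            params = "list"))

setValidity("ModuleSet", function(object) {
  msg <- character(0)
  if (is.null(names(object@labels))) msg <- c(msg, "labels must be named by gene")
  if (any(object@labels < 0L)) msg <- c(msg, "module labels must be >= 0")
  k <- length(setdiff(unique(object@labels), 0L))
  if (nrow(object@eigengenes) && nrow(object@eigengenes) != k)
    msg <- c(msg, "eigengene rows must match the number of non-grey modules")
  if (length(object@varianceExplained) &&
      length(object@varianceExplained) != nrow(object@eigengenes))
    msg <- c(msg, "varianceExplained length must match eigengene rows")
  if (length(msg)) msg else TRUE
})

#' BayesNetFit: a (model-averaged) Bayesian network structure
#'
#' A directed acyclic graph over a set of variables, together with the arc
#' frequency table accumulated across hill-climbing restarts. Produced by
#' [learnAveragedNetwork()]; single [hillClimb()] fits are wrapped with all
#' arc frequencies equal to 1.
#'
#' @slot nodes character vector of variable names.
#' @slot arcs two-column character matrix (`from`, `to`); acyclic.
#' @slot strength data.frame with columns `from`, `to`, `frequency`: the
#'   fraction of learned networks containing each directed arc.
#' @slot nRestarts integer, number of networks averaged.
#' @slot params list (score, threshold, seeds, ...).
#'
#' @seealso [learnAveragedNetwork()], [markovBlanket()], [prioritizeModules()]
#' @exportClass BayesNetFit
setClass("BayesNetFit",
  slots = c(nodes = "character", arcs = "matrix", strength = "data.frame",
            nRestarts = "integer", params = "list"))

setValidity("BayesNetFit", function(object) {
  msg <- character(0)
  if (ncol(object@arcs) != 2L) msg <- c(msg, "arcs must have two columns")
  if (nrow(object@arcs)) {
    if (any(object@arcs[, 1L] == object@arcs[, 2L]))
      msg <- c(msg, "self-loops are not allowed")
    if (!all(object@arcs %in% object@nodes))
      msg <- c(msg, "arc endpoints must be nodes")
    amat <- .arcsToAmat(object@arcs, object@nodes)
    if (!.isAcyclic(amat)) msg <- c(msg, "arc set must be acyclic")
  }
  if (nrow(object@strength) &&
      !all(c("from", "to", "frequency") %in% names(object@strength)))
    msg <- c(msg, "strength must have columns from, to, frequency")
  if (nrow(object@strength) &&
      (any(object@strength$frequency < 0) || any(object@strength$frequency > 1)))
    msg <- c(msg, "arc frequencies must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' EPCScores: edge-percolated-component centrality scores
#'
#' Per-node expected number of other nodes reachable after independent random
#' edge removal (each edge kept with probability `p`). Monte Carlo scores
#' ([epcScore()]) carry a standard error; exact scores ([epcExact()]) have
#' `se = 0` and `exact = TRUE`.
#'
#' @slot table data.frame with columns `gene`, `epc`, `se`, `degree`.
#' @slot p edge retention probability.
#' @slot nSamples number of Monte Carlo realizations (1 for exact scores).
#' @slot seed RNG seed used (NA for exact scores).
#' @slot exact logical flag.
#'
#' @seealso [epcScore()], [epcExact()], [selectHubs()]
#' @exportClass EPCScores
setClass("EPCScores",
  slots = c(table = "data.frame", p = "numeric", nSamples = "integer",
            seed = "integer", exact = "logical"))

setValidity("EPCScores", function(object) {
  msg <- character(0)
  if (!all(c("gene", "epc", "se", "degree") %in% names(object@table)))
    msg <- c(msg, "table must have columns gene, epc, se, degree")
  if (object@p <= 0 || object@p >= 1) msg <- c(msg, "p must lie in (0, 1)")
  n <- nrow(object@table)
  if (n && (any(object@table$epc < 0) || any(object@table$epc > n - 1 + 1e-9)))
    msg <- c(msg, "EPC scores must lie in [0, n - 1]")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ModuleSet", function(object) {
  k <- nrow(object@eigengenes)
  sz <- moduleSizes(object)
  cat("ModuleSet with", k, "modules over", length(object@labels), "genes\n")
  if (k) {
    cat("  sizes:", paste(sz[names(sz) != "0"], collapse = ", "), "\n")
    cat("  unassigned (grey):", sum(object@labels == 0L), "genes\n")
    cat("  variance explained:",
        paste(sprintf("%.2f", object@varianceExplained), collapse = ", "), "\n")
  }
  invisible(object)
})

setMethod("show", "BayesNetFit", function(object) {
  cat("BayesNetFit:", length(object@nodes), "nodes,", nrow(object@arcs),
      "arcs (averaged over", object@nRestarts, "networks)\n")
  if (nrow(object@arcs)) {
    head <- utils::head(apply(object@arcs, 1L, paste, collapse = " -> "), 8L)
    cat(" ", paste(head, collapse = "; "))
    if (nrow(object@arcs) > 8L) cat(" ...")
    cat("\n")
  }
  invisible(object)
})

setMethod("show", "EPCScores", function(object) {
  cat(if (object@exact) "Exact" else "Monte Carlo",
      "EPC scores for", nrow(object@table), "nodes (p =", object@p)
  if (!object@exact) cat(",", object@nSamples, "realizations")
  cat(")\n")
  top <- utils::head(object@table[order(-object@table$epc), ], 6L)
  print(top, row.names = FALSE)
  invisible(object)
})
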