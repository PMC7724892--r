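#' Accessors for module, network and centrality objects
#'
#' Small accessor generics so downstream code never touches slots directly:
#' `moduleLabels()` returns the named gene -> module assignment,
#' `moduleSizes()` a size table (including the grey label 0), `eigengenes()`
#' the module x sample eigengene matrix, `varianceExplained()` the fraction
#' of module variance captured by each eigengene, `moduleLoadings()` the
#' per-module gene weight vectors, `arcs()` the two-column arc matrix of a
#' fitted network, `arcStrength()` its arc frequency table, and `epcTable()`
#' the per-gene centrality table.
#'
#' @param object a [ModuleSet-class], [BayesNetFit-class] or
#'   [EPCScores-class] object.
#' @return See each generic's description.
#' @name accessors
#' @examples
#' x <- matrix(rnorm(200), 20, 10,
#'             dimnames = list(paste0("G", 1:20), paste0("S", 1:10)))
#' ms <- moduleEigengenes(x, setNames(rep(1:2, each = 10L), rownames(x)))
#' moduleSizes(ms)
#' dim(eigengenes(ms))
NULL

#' @rdname accessors
#' @export
setGeneric("moduleLabels", function(object) standardGeneric("moduleLabels"))
#' @rdname accessors
#' @export
setGeneric("moduleSizes", function(object) standardGeneric("moduleSizes"))
#' @rdname accessors
#' @export
setGeneric("eigengenes", function(object) standardGeneric("eigengenes"))
#' @rdname accessors
#' @export
setGeneric("varianceExplained",
           function(object) standardGeneric("varianceExplained"))
#' @rdname accessors
#' @export
setGeneric("moduleLoadings", function(object) standardGeneric("moduleLoadings"))
#' @rdname accessors
#' @export
setGeneric("arcs", function(object) standardGeneric("arcs"))
#' @rdname accessors
#' @export
setGeneric("arcStrength", function(object) standardGeneric("arcStrength"))
#' @rdname accessors
#' @export
setGeneric("epcTable", function(object) standardGeneric("epcTable"))

#' @rdname accessors
setMethod("moduleLabels", "ModuleSet", function(object) object@labels)

#' @rdname accessors
setMethod("moduleSizes", "ModuleSet", function(object) {
  tab <- table(object@labels)
  stats::setNames(as.integer(tab), names(tab))
})

#' @rdname accessors
setMethod("eigengenes", "ModuleSet", function(object) object@eigengenes)

#' @rdname accessors
setMethod("varianceExplained", "ModuleSet",
          function(object) object@varianceExplained)

#' @rdname accessors
setMethod("moduleLoadings", "ModuleSet", function(object) object@loadings)

#' @rdname accessors
setMethod("arcs", "BayesNetFit", function(object) object@arcs)

#' @rdname accessors
setMethod("arcStrength", "BayesNetFit", function(object) object@strength)

#' @rdname accessors
setMethod("epcTable", "EPCScores", function(object) object@table)
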