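# Within-module gene network construction and edge-percolated-component
# (EPC) centrality. EPC(v) is the expected number of other nodes still
# reachable from v after each edge is independently removed with probability
# 1 - p: a global measure of how strongly a gene ties the module network
# together, robust to the loss of single interactions.

#' Learn a within-module gene network
#'
#' Learns a model-averaged gene-level Bayesian network on the submatrix of
#' a module's genes (delegating to [learnAveragedNetwork()]), optionally
#' restricted to a caller-supplied keep list (e.g. a literature-based
#' filter), drops isolated genes, and returns the undirected skeleton as an
#' `igraph` graph. Percolation-based centrality is an undirected notion, so
#' edge direction is discarded here.
#'
#' @param x genes x samples matrix or `SummarizedExperiment` (z-scored
#'   rows recommended).
#' @param moduleGenes character vector of the module's gene ids.
#' @param keepGenes optional character vector restricting the analysis.
#' @param nRestarts hill-climbing restarts (default 100).
#' @param arcThreshold averaged-network arc threshold (default 0.5).
#' @param seed random seed.
#' @param dropIsolated drop genes with no skeleton edge (default TRUE).
#' @param initProb per-arc probability of the random initial DAGs; the
#'   default scales as `min(0.1, 2 / (nGenes - 1))` so the expected
#'   initial arc count stays near the gene count and every restart can
#'   converge.
#' @param maxIter maximum accepted moves per climb (default
#'   `max(200, 10 * nGenes)`).
#' @return An undirected `igraph` graph; attribute `fit` carries the
#'   underlying [BayesNetFit-class].
#' @export
buildGeneNetwork <- function(x, moduleGenes, keepGenes = NULL,
                             nRestarts = 100L, arcThreshold = 0.5, seed = 1,
                             dropIsolated = TRUE, initProb = NULL,
                             maxIter = NULL) {
  m <- .exprsMatrix(x)
  missing <- setdiff(moduleGenes, rownames(m))
  if (length(missing))
    stop("module genes absent from the matrix: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  genes <- moduleGenes
  if (!is.null(keepGenes)) genes <- intersect(genes, keepGenes)
  if (length(genes) < 3L) stop("fewer than 3 genes to model")
  if (is.null(initProb)) initProb <- min(0.1, 2 / (length(genes) - 1))
  if (is.null(maxIter)) maxIter <- max(200L, 10L * length(genes))
  d <- as.data.frame(t(m[genes, , drop = FALSE]))
  fit <- learnAveragedNetwork(d, nRestarts = nRestarts,
                              arcThreshold = arcThreshold, seed = seed,
                              initProb = initProb, maxIter = maxIter)
  g <- igraph::make_empty_graph(n = length(genes), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = genes)
  if (nrow(fit@arcs))
    g <- igraph::add_edges(g, t(fit@arcs))
  g <- igraph::simplify(g)
  if (dropIsolated) {
    iso <- igraph::V(g)[igraph::degree(g) == 0]
    g <- igraph::delete_vertices(g, iso)
  }
  attr(g, "fit") <- fit
  g
}

.epcGraph <- function(net) {
  if (!igraph::is_igraph(net))
    stop("net must be an igraph graph (see buildGeneNetwork)")
  g <- igraph::as_undirected(igraph::simplify(net))
  if (is.null(igraph::V(g)$name))
    g <- igraph::set_vertex_attr(g, "name",
                                 value = as.character(seq_len(igraph::vcount(g))))
  g
}

# component sizes per vertex for a given kept-edge subset
.componentSizes <- function(g, keptEdges) {
  sub <- igraph::subgraph_from_edges(g, keptEdges, delete.vertices = FALSE)
  comp <- igraph::components(sub)
  comp$csize[comp$membership]
}

#' Monte Carlo edge-percolated-component centrality
#'
#' For each of `nSamples` realizations, keeps each edge independently with
#' probability `p` and counts, for every node, the other nodes left in its
#' connected component; the EPC score is the mean count across
#' realizations, with a Monte Carlo standard error. Deterministic given
#' `seed`.
#'
#' @param net an undirected `igraph` graph (directed input is flattened).
#' @param p edge retention probability, in (0, 1) (default 0.5).
#' @param nSamples number of realizations (default 1000).
#' @param seed random seed.
#' @return An [EPCScores-class] object.
#' @examples
#' tri <- igraph::make_ring(3)
#' epcTable(epcScore(tri, p = 0.5, nSamples = 2000, seed = 1))  # epc ~ 1.25
#' @export
epcScore <- function(net, p = 0.5, nSamples = 1000L, seed = 1) {
  if (p <= 0 || p >= 1) stop("p must lie in (0, 1)")
  if (nSamples < 1L) stop("nSamples must be >= 1")
  g <- .epcGraph(net)
  nV <- igraph::vcount(g)
  nE <- igraph::ecount(g)
  if (nV == 0L) stop("empty graph")
  if (nE == 0L) {
    warning("graph has no edges; all EPC scores are 0")
    tab <- data.frame(gene = igraph::V(g)$name, epc = 0, se = 0,
                      degree = 0L)
    return(methods::new("EPCScores", table = tab, p = p,
                        nSamples = as.integer(nSamples),
                        seed = as.integer(seed), exact = FALSE))
  }
  sums <- numeric(nV)
  sq <- numeric(nV)
  .withSeed(seed, {
    for (s in seq_len(nSamples)) {
      kept <- which(stats::runif(nE) < p)
      reach <- .componentSizes(g, kept) - 1
      sums <- sums + reach
      sq <- sq + reach^2
    }
  })
  epc <- sums / nSamples
  se <- if (nSamples > 1L)
    sqrt(pmax(sq / nSamples - epc^2, 0) / (nSamples - 1L)) else rep(NA_real_, nV)
  tab <- data.frame(gene = igraph::V(g)$name, epc = epc, se = se,
                    degree = igraph::degree(g))
  rownames(tab) <- NULL
  methods::new("EPCScores", table = tab, p = p,
               nSamples = as.integer(nSamples), seed = as.integer(seed),
               exact = FALSE)
}

#' Exact edge-percolated-component centrality
#'
#' Exact expectation of the percolated reachable-node count by enumerating
#' all 2^E kept-edge subsets, each weighted `p^kept * (1-p)^removed`. Only
#' feasible for small graphs (at most 20 edges); serves as the auditable
#' oracle for [epcScore()].
#'
#' @param net an undirected `igraph` graph with at most 20 edges.
#' @param p edge retention probability in (0, 1).
#' @return An [EPCScores-class] with `exact = TRUE` and `se = 0`.
#' @examples
#' epcTable(epcExact(igraph::make_ring(3), 0.5))$epc  # exactly 1.25
#' @export
epcExact <- function(net, p = 0.5) {
  if (p <= 0 || p >= 1) stop("p must lie in (0, 1)")
  g <- .epcGraph(net)
  nV <- igraph::vcount(g)
  nE <- igraph::ecount(g)
  if (nV == 0L) stop("empty graph")
  if (nE > 20L) stop("exact enumeration limited to 20 edges (got ", nE, ")")
  epc <- numeric(nV)
  for (mask in 0:(2^nE - 1)) {
    kept <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(nE) - 1L)) != 0L)
    w <- p^length(kept) * (1 - p)^(nE - length(kept))
    epc <- epc + w * (.componentSizes(g, kept) - 1)
  }
  tab <- data.frame(gene = igraph::V(g)$name, epc = epc, se = 0,
                    degree = igraph::degree(g))
  rownames(tab) <- NULL
  methods::new("EPCScores", table = tab, p = p, nSamples = 1L,
               seed = NA_integer_, exact = TRUE)
}

#' Select hub genes and their subnetwork
#'
#' Takes the top-`k` nodes by EPC score (ties broken by degree, then node
#' id) as hub genes and returns the subnetwork induced by the hubs plus all
#' their directly connected neighbors, annotated by EPC rank.
#'
#' @param scores an [EPCScores-class] from [epcScore()] or [epcExact()].
#' @param net the `igraph` graph the scores were computed on.
#' @param k number of hubs (default 6).
#' @return list with `hubs` (character vector of length `k`), `ranking`
#'   (full ranked score table with `rank`), and `subnetwork` (`igraph`
#'   graph of hubs + neighbors, vertex attributes `epc`, `rank`,
#'   `isHub`).
#' @export
selectHubs <- function(scores, net, k = 6L) {
  stopifnot(methods::is(scores, "EPCScores"))
  if (k <= 0) stop("k must be positive")
  tab <- scores@table
  if (k > nrow(tab)) stop("k exceeds the number of scored nodes")
  ord <- order(-tab$epc, -tab$degree, tab$gene)
  tab <- tab[ord, ]
  tab$rank <- seq_len(nrow(tab))
  rownames(tab) <- NULL
  hubs <- tab$gene[seq_len(k)]
  g <- .epcGraph(net)
  nb <- unique(unlist(lapply(hubs, function(h)
    igraph::V(g)$name[as.integer(igraph::neighbors(g, h))])))
  keep <- union(hubs, nb)
  sub <- igraph::induced_subgraph(g, keep)
  idx <- match(igraph::V(sub)$name, tab$gene)
  sub <- igraph::set_vertex_attr(sub, "epc", value = tab$epc[idx])
  sub <- igraph::set_vertex_attr(sub, "rank", value = tab$rank[idx])
  sub <- igraph::set_vertex_attr(sub, "isHub",
                                 value = igraph::V(sub)$name %in% hubs)
  list(hubs = hubs, ranking = tab, subnetwork = sub)
}
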