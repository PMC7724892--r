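# Score-based Gaussian Bayesian-network structure learning. The score is the
# decomposable Gaussian BIC: per node, the ML Gaussian log-likelihood of the
# node regressed on its parents minus (log n / 2) * (|parents| + 2), counting
# intercept, coefficients and residual variance. Local scores are computed
# from the centered cross-product matrix and cached by (node, parent set), so
# hill-climbing restarts on the same data share one cache.

.scoreContext <- function(data) {
  m <- as.matrix(data)
  if (!is.numeric(m)) stop("data must be numeric")
  n <- nrow(m)
  C <- crossprod(scale(m, center = TRUE, scale = FALSE))
  list(C = C, n = n, nodes = colnames(m), cache = new.env(parent = emptyenv()))
}

# BIC local score from a residual sum of squares; sigma^2 is floored so a
# (near-)perfect fit stays finite and comparisons remain deterministic.
.bicFromRSS <- function(rss, nPar, n) {
  sigma2 <- pmax(rss, 1e-12) / n
  -n / 2 * (log(2 * pi * sigma2) + 1) - log(n) / 2 * (nPar + 2)
}

.localScore <- function(ctx, j, pa) {
  key <- paste0(j, "|", paste(sort(pa), collapse = "."))
  hit <- ctx$cache[[key]]
  if (!is.null(hit)) return(hit)
  C <- ctx$C; n <- ctx$n
  rss <- if (length(pa)) {
    sol <- tryCatch(solve(C[pa, pa, drop = FALSE], C[pa, j]),
                    error = function(e) NULL)
    if (is.null(sol)) NA_real_
    else C[j, j] - sum(C[j, pa] * sol)
  } else C[j, j]
  val <- if (is.na(rss)) {
    -Inf  # singular parent design; the configuration is never selected
  } else {
    .bicFromRSS(rss, length(pa), n)
  }
  ctx$cache[[key]] <- val
  val
}

#' Gaussian BIC network score
#'
#' Decomposable score of a DAG on multivariate data: the sum over nodes of
#' the maximum-likelihood Gaussian log-likelihood of each node given its
#' parents, penalized by `log(n)/2 * (|parents| + 2)` per node (intercept,
#' regression coefficients, residual variance). Higher is better. An empty
#' graph scores the sum of per-node marginal Gaussian BICs.
#'
#' @param data numeric data.frame or matrix (samples x variables).
#' @param arcs two-column arc matrix / data.frame (may be empty) over the
#'   data columns.
#' @return A single numeric score.
#' @examples
#' d <- simulateDAGData(cbind("A", "B"), 2, n = 100, seed = 1)
#' bicGaussianScore(d, cbind("A", "B")) > bicGaussianScore(d, NULL)
#' @export
bicGaussianScore <- function(data, arcs = NULL) {
  ctx <- .scoreContext(data)
  amat <- .arcsToAmat(if (is.null(arcs)) character(0) else arcs, ctx$nodes)
  if (!.isAcyclic(amat)) stop("arc set is cyclic; a DAG is required")
  total <- 0
  for (j in seq_along(ctx$nodes)) {
    s <- .localScore(ctx, j, which(amat[, j] == 1L))
    if (!is.finite(s)) stop("singular parent design matrix for node '",
                            ctx$nodes[j], "'")
    total <- total + s
  }
  total
}

# Core greedy search, delegated to the compiled implementation
# (src/hillclimb.cpp): cached single-arc score deltas from Schur-complement
# updates of the parent-block inverse, cycle-creating moves masked with a
# reachability matrix, deterministic scan-order tie-breaks.
.hillClimbCore <- function(ctx, initAmat, maxIter = 200L) {
  res <- .hcCoreCpp(ctx$C, ctx$n, initAmat, as.integer(maxIter))
  amat <- matrix(as.integer(res$amat), nrow(initAmat),
                 dimnames = dimnames(initAmat))
  list(amat = amat, score = res$score, trajectory = res$trajectory,
       converged = res$converged)
}

# Random DAG via a random topological order: arcs allowed only from earlier
# to later nodes, included independently with probability `prob`.
.randomDagAmat <- function(nodes, prob) {
  p <- length(nodes)
  amat <- .emptyAmat(nodes)
  ord <- sample.int(p)
  for (a in seq_len(p - 1L)) {
    later <- ord[(a + 1L):p]
    inc <- later[stats::runif(length(later)) < prob]
    amat[ord[a], inc] <- 1L
  }
  amat
}

#' Greedy hill-climbing structure search
#'
#' Repeatedly applies the single-arc operation (add, delete or reverse)
#' that most improves the Gaussian BIC score while preserving acyclicity,
#' until no operation improves the score (a local optimum) or `maxIter`
#' sweeps are exhausted. Ties between equally good moves are broken by a
#' fixed scan order over (from, to) cells and operations, so the search is
#' deterministic given its starting graph.
#'
#' @param data numeric data.frame or matrix (samples x variables).
#' @param init starting DAG as a two-column arc matrix (`NULL` = empty
#'   graph), or `"random"` for a random initial DAG.
#' @param seed seed used only when `init = "random"`.
#' @param maxIter maximum number of accepted moves (default 200).
#' @param initProb per-arc inclusion probability for random starts.
#' @return A [BayesNetFit-class] with attributes in `@params`: `score`,
#'   `trajectory` (strictly increasing accepted-move scores) and
#'   `converged`.
#' @examples
#' d <- simulateDAGData(rbind(c("A", "B"), c("B", "C")), c(1.5, 1.5),
#'                      n = 2000, seed = 1)
#' fit <- hillClimb(d)
#' arcs(fit)
#' @export
hillClimb <- function(data, init = NULL, seed = 1, maxIter = 200L,
                      initProb = 0.1) {
  ctx <- .scoreContext(data)
  initAmat <- if (is.null(init)) {
    .emptyAmat(ctx$nodes)
  } else if (identical(init, "random")) {
    .withSeed(seed, .randomDagAmat(ctx$nodes, initProb))
  } else {
    amat <- .arcsToAmat(init, ctx$nodes)
    if (!.isAcyclic(amat)) stop("initial graph is cyclic")
    amat
  }
  res <- .hillClimbCore(ctx, initAmat, maxIter = maxIter)
  arcsOut <- .amatToArcs(res$amat)
  strength <- if (nrow(arcsOut))
    data.frame(from = arcsOut[, 1L], to = arcsOut[, 2L], frequency = 1)
  else data.frame(from = character(0), to = character(0),
                  frequency = numeric(0))
  methods::new("BayesNetFit", nodes = ctx$nodes, arcs = arcsOut,
               strength = strength, nRestarts = 1L,
               params = list(score = res$score, trajectory = res$trajectory,
                             converged = res$converged))
}

#' Model-averaged Bayesian network over random restarts
#'
#' Runs [hillClimb()] from `nRestarts` random initial DAGs (stochastic
#' initialization avoids being trapped in a single local optimum), tallies
#' how often each directed arc appears across the learned networks, and
#' builds the averaged network: undirected pairs whose total frequency
#' reaches `arcThreshold` are kept and directed by majority vote. Any cycle
#' induced by the voting is resolved by removing the lowest-frequency arc
#' on the cycle until the graph is acyclic. Deterministic given `seed`.
#'
#' @param data numeric data.frame or matrix (samples x variables).
#' @param nRestarts number of random restarts (default 200).
#' @param arcThreshold minimum total (both-direction) arc frequency to keep
#'   a pair (default 0.5).
#' @param seed random seed.
#' @param initProb per-arc inclusion probability of the random initial
#'   DAGs (default 0.1).
#' @param maxIter maximum accepted moves per climb.
#' @return A [BayesNetFit-class]; `arcStrength()` holds the full directed
#'   frequency table over all `nRestarts` networks.
#' @export
learnAveragedNetwork <- function(data, nRestarts = 200L, arcThreshold = 0.5,
                                 seed = 1, initProb = 0.1, maxIter = 200L) {
  if (nRestarts < 1L) stop("nRestarts must be >= 1")
  ctx <- .scoreContext(data)
  p <- length(ctx$nodes)
  counts <- matrix(0, p, p, dimnames = list(ctx$nodes, ctx$nodes))
  .withSeed(seed, {
    for (r in seq_len(nRestarts)) {
      initAmat <- .randomDagAmat(ctx$nodes, initProb)
      res <- .hillClimbCore(ctx, initAmat, maxIter = maxIter)
      counts <- counts + res$amat
    }
  })
  freq <- counts / nRestarts

  avg <- .emptyAmat(ctx$nodes)
  for (a in seq_len(p - 1L)) {
    for (b in (a + 1L):p) {
      total <- freq[a, b] + freq[b, a]
      if (total >= arcThreshold) {
        if (freq[a, b] >= freq[b, a]) avg[a, b] <- 1L else avg[b, a] <- 1L
      }
    }
  }
  repeat {
    cyc <- .findCycle(avg)
    if (is.null(cyc)) break
    arcsInCycle <- cbind(cyc[-length(cyc)], cyc[-1L])
    fr <- freq[arcsInCycle]
    drop <- arcsInCycle[which.min(fr), , drop = FALSE]
    avg[drop] <- 0L
  }
  idx <- which(freq > 0, arr.ind = TRUE)
  strength <- data.frame(from = ctx$nodes[idx[, 1L]],
                         to = ctx$nodes[idx[, 2L]],
                         frequency = freq[idx])
  strength <- strength[order(-strength$frequency, strength$from,
                             strength$to), ]
  rownames(strength) <- NULL
  methods::new("BayesNetFit", nodes = ctx$nodes, arcs = .amatToArcs(avg),
               strength = strength, nRestarts = as.integer(nRestarts),
               params = list(arcThreshold = arcThreshold, seed = seed,
                             initProb = initProb))
}

#' Markov blanket of a node
#'
#' The Markov blanket of a node in a DAG is the union of its parents, its
#' children, and the other parents of its children (its "co-parents"); it
#' renders the node conditionally independent of every other variable in
#' the network.
#'
#' @param x a [BayesNetFit-class] or a two-column arc matrix.
#' @param node node name.
#' @param nodes full node set (only needed when `x` is an arc matrix and
#'   has isolated nodes).
#' @return Character vector of blanket node names (possibly empty).
#' @examples
#' markovBlanket(rbind(c("A", "B"), c("B", "C")), "B")  # A, C
#' @export
markovBlanket <- function(x, node, nodes = NULL) {
  if (methods::is(x, "BayesNetFit")) {
    arcsM <- x@arcs; nodes <- x@nodes
  } else {
    arcsM <- .asArcMatrix(x)
    if (is.null(nodes)) nodes <- unique(as.vector(arcsM))
  }
  if (!node %in% nodes) stop("unknown node: ", node)
  parents <- arcsM[arcsM[, 2L] == node, 1L]
  children <- arcsM[arcsM[, 1L] == node, 2L]
  coparents <- arcsM[arcsM[, 2L] %in% children, 1L]
  sort(setdiff(unique(c(parents, children, coparents)), node))
}

#' d-separation in a DAG
#'
#' Tests whether `x` and `y` are d-separated given conditioning set `z`,
#' via the moralized-ancestral-graph criterion: restrict the DAG to the
#' ancestors of `x`, `y` and `z`, marry all co-parents, drop arrowheads,
#' remove `z`, and check whether `x` and `y` are disconnected. Used as an
#' independent audit of [markovBlanket()] (every non-blanket node must be
#' d-separated from the node given its blanket).
#'
#' @param arcs two-column arc matrix (or [BayesNetFit-class]).
#' @param x,y node names.
#' @param z character vector of conditioning nodes (may be empty).
#' @param nodes full node set (for isolated nodes).
#' @return `TRUE` if `x` and `y` are d-separated given `z`.
#' @export
dSeparated <- function(arcs, x, y, z = character(0), nodes = NULL) {
  if (methods::is(arcs, "BayesNetFit")) {
    nodes <- arcs@nodes; arcs <- arcs@arcs
  } else {
    arcs <- .asArcMatrix(arcs)
    if (is.null(nodes)) nodes <- unique(as.vector(arcs))
  }
  stopifnot(x %in% nodes, y %in% nodes, all(z %in% nodes))
  amat <- .arcsToAmat(arcs, nodes)
  # ancestral closure of {x, y} U z
  anc <- unique(c(x, y, z))
  repeat {
    idx <- match(anc, nodes)
    pa <- nodes[which(rowSums(amat[, idx, drop = FALSE]) > 0)]
    new <- setdiff(pa, anc)
    if (!length(new)) break
    anc <- c(anc, new)
  }
  idx <- match(anc, nodes)
  sub <- amat[idx, idx, drop = FALSE]
  moral <- pmax(sub, t(sub))
  # marry parents sharing a child
  for (j in seq_along(anc)) {
    par <- which(sub[, j] == 1L)
    if (length(par) > 1L)
      for (a in seq_len(length(par) - 1L))
        for (b in (a + 1L):length(par)) {
          moral[par[a], par[b]] <- 1L
          moral[par[b], par[a]] <- 1L
        }
  }
  keep <- !(anc %in% z)
  moral <- moral[keep, keep, drop = FALSE]
  kept <- anc[keep]
  g <- igraph::graph_from_adjacency_matrix(moral, mode = "undirected")
  comp <- igraph::components(g)$membership
  comp[match(x, kept)] != comp[match(y, kept)]
}

#' Rank modules by phenotype association in the learned network
#'
#' Implements the module-prioritization rule of the module-to-phenotype
#' network: a module is the more strongly tied to reserve and cognition
#' the more phenotype nodes its Markov blanket contains, and direct
#' parenthood of the reserve and MMSE nodes is the strongest evidence.
#' Modules are ranked lexicographically by (i) reserve in the blanket,
#' (ii) reserve a child of the module, (iii) number of phenotype nodes in
#' the blanket, (iv) MMSE a child of the module; remaining ties are broken
#' by the summed arc frequency between the module and the phenotype nodes.
#'
#' @param fit a [BayesNetFit-class] over module and phenotype nodes.
#' @param phenotypeNodes names of the phenotype nodes (default
#'   `c("reserve", "mmse", "braak", "nft")`).
#' @param moduleNodes names of the module nodes (default: all non-phenotype
#'   nodes).
#' @return data.frame, one row per module in rank order, with the ranking
#'   keys (`reserveInMB`, `reserveChild`, `nPhenoInMB`, `mmseChild`,
#'   `strengthSum`) and `rank`.
#' @export
prioritizeModules <- function(fit,
                              phenotypeNodes = c("reserve", "mmse",
                                                 "braak", "nft"),
                              moduleNodes = NULL) {
  stopifnot(methods::is(fit, "BayesNetFit"))
  missing <- setdiff(phenotypeNodes, fit@nodes)
  if (length(missing))
    stop("phenotype node(s) not in the network: ",
         paste(missing, collapse = ", "))
  if (is.null(moduleNodes)) moduleNodes <- setdiff(fit@nodes, phenotypeNodes)
  arcsM <- fit@arcs
  st <- fit@strength
  reserveNode <- phenotypeNodes[1L]
  mmseNode <- if (length(phenotypeNodes) >= 2L) phenotypeNodes[2L] else NA
  rows <- lapply(moduleNodes, function(mod) {
    mb <- markovBlanket(fit, mod)
    children <- arcsM[arcsM[, 1L] == mod, 2L]
    sSum <- if (nrow(st)) sum(st$frequency[(st$from == mod &
                                            st$to %in% phenotypeNodes) |
                                           (st$to == mod &
                                            st$from %in% phenotypeNodes)])
            else 0
    data.frame(module = mod,
               reserveInMB = reserveNode %in% mb,
               reserveChild = reserveNode %in% children,
               nPhenoInMB = sum(phenotypeNodes %in% mb),
               mmseChild = !is.na(mmseNode) && mmseNode %in% children,
               strengthSum = sSum)
  })
  out <- do.call(rbind, rows)
  ord <- order(-out$reserveInMB, -out$reserveChild, -out$nPhenoInMB,
               -out$mmseChild, -out$strengthSum, out$module)
  out <- out[ord, ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Assemble the module-phenotype data table for network learning
#'
#' Binds module eigengenes (one column per module) with the phenotype
#' variables (reserve coded 1/0 with non-evaluable samples coded 0, MMSE,
#' Braak, NFT) and standardizes every column, producing the input table
#' for [learnAveragedNetwork()].
#'
#' @param moduleSet a [ModuleSet-class].
#' @param phenotypes aligned phenotype data.frame with columns
#'   `reserve_label`, `mmse`, `braak`, `nft`.
#' @return data.frame (samples x (modules + 4)) of standardized columns.
#' @export
mpnData <- function(moduleSet, phenotypes) {
  ph <- .phenoTable(phenotypes)
  E <- eigengenes(moduleSet)
  if (ncol(E) != nrow(ph))
    stop("eigengene samples and phenotype rows are not aligned")
  need <- c("reserve_label", "mmse", "braak", "nft")
  miss <- setdiff(need, names(ph))
  if (length(miss)) stop("phenotype table lacks: ", paste(miss, collapse = ", "))
  reserve <- as.numeric(ph$reserve_label == "reserve")
  d <- cbind(as.data.frame(t(E)),
             reserve = reserve, mmse = as.numeric(ph$mmse),
             braak = as.numeric(ph$braak), nft = as.numeric(ph$nft))
  z <- scale(as.matrix(d))
  const <- apply(is.nan(z) | is.na(z), 2L, any)
  if (any(const)) {
    message("constant variable(s) carried as zeros: ",
            paste(colnames(z)[const], collapse = ", "))
    z[, const] <- 0
  }
  as.data.frame(z)
}
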