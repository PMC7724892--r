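# Internal helpers: reproducible RNG scoping and plain adjacency-matrix DAG
# operations used by the structure-learning code. DAGs are passed around as
# 0/1 adjacency matrices (amat[i, j] == 1 means arc i -> j) with node names on
# both dimensions; user-facing objects convert to two-column arc matrices.

# Evaluate `expr` under `seed` without disturbing the caller's RNG stream.
.withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("'seed' must be a single integer", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# One global seed expanded into per-stage child seeds (counter scheme), so a
# stage's stream does not depend on how many draws earlier stages consumed.
.childSeed <- function(seed, stage) {
  offsets <- c(simulate = 101L, preprocess = 211L, coexpression = 307L,
               bayesnet = 401L, hubgenes = 503L, stats = 601L, misc = 701L)
  if (!stage %in% names(offsets)) stop("unknown pipeline stage: ", stage)
  (abs(as.integer(seed)) %% 2000000L) * 1000L + offsets[[stage]]
}

.emptyAmat <- function(nodes) {
  p <- length(nodes)
  matrix(0L, p, p, dimnames = list(nodes, nodes))
}

.arcsToAmat <- function(arcs, nodes) {
  amat <- .emptyAmat(nodes)
  if (length(arcs)) {
    arcs <- .asArcMatrix(arcs)
    bad <- !(arcs %in% nodes)
    if (any(bad))
      stop("arc endpoints not in node set: ",
           paste(unique(arcs[bad]), collapse = ", "))
    amat[arcs] <- 1L
  }
  amat
}

.amatToArcs <- function(amat) {
  idx <- which(amat == 1L, arr.ind = TRUE)
  arcs <- cbind(from = rownames(amat)[idx[, 1L]],
                to   = colnames(amat)[idx[, 2L]])
  arcs[order(arcs[, 1L], arcs[, 2L]), , drop = FALSE]
}

.asArcMatrix <- function(arcs) {
  if (is.data.frame(arcs)) arcs <- as.matrix(arcs[, 1:2])
  if (is.null(dim(arcs))) arcs <- matrix(arcs, ncol = 2L, byrow = TRUE)
  arcs <- arcs[, 1:2, drop = FALSE]
  storage.mode(arcs) <- "character"
  colnames(arcs) <- c("from", "to")
  arcs
}

# Kahn's algorithm; returns the topological order or NULL if cyclic.
.topoSort <- function(amat) {
  p <- nrow(amat)
  indeg <- colSums(amat)
  order <- integer(0)
  queue <- which(indeg == 0L)
  indeg[queue] <- NA_real_
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    order <- c(order, v)
    kids <- which(amat[v, ] == 1L)
    for (k in kids) {
      indeg[k] <- indeg[k] - 1L
      if (!is.na(indeg[k]) && indeg[k] == 0L) {
        queue <- c(queue, k)
        indeg[k] <- NA_real_
      }
    }
  }
  if (length(order) < p) NULL else order
}

.isAcyclic <- function(amat) !is.null(.topoSort(amat))

# Is there a directed path from `from` to `to`? (BFS over the amat.)
.hasPath <- function(amat, from, to) {
  if (from == to) return(TRUE)
  seen <- logical(nrow(amat))
  queue <- from
  seen[from] <- TRUE
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    kids <- which(amat[v, ] == 1L & !seen)
    if (to %in% kids) return(TRUE)
    seen[kids] <- TRUE
    queue <- c(queue, kids)
  }
  FALSE
}

# Transitive closure (descendant reachability) by repeated boolean squaring:
# D[a, b] == 1 iff a directed path a -> ... -> b exists.
.reachability <- function(amat) {
  p <- nrow(amat)
  M <- amat + diag(p)
  repeat {
    M2 <- (M %*% M > 0) + 0L
    if (identical(M2, M)) break
    M <- M2
  }
  diag(M) <- 0L
  M
}

# First directed cycle found by DFS, as an amat index path c(v1, ..., vk, v1);
# NULL when acyclic.
.findCycle <- function(amat) {
  p <- nrow(amat)
  state <- integer(p)         # 0 unseen, 1 on stack, 2 done
  parent <- integer(p)
  cycle <- NULL
  dfs <- function(v) {
    state[v] <<- 1L
    for (w in which(amat[v, ] == 1L)) {
      if (!is.null(cycle)) return()
      if (state[w] == 1L) {
        path <- v
        u <- v
        while (u != w) { u <- parent[u]; path <- c(u, path) }
        cycle <<- c(path, w)
        return()
      }
      if (state[w] == 0L) { parent[w] <<- v; dfs(w) }
    }
    state[v] <<- 2L
  }
  for (v in seq_len(p)) {
    if (state[v] == 0L) dfs(v)
    if (!is.null(cycle)) break
  }
  cycle
}

# Bonferroni with an explicit family size; adjusted p-values are only
# interpretable with m, so m is always carried alongside the result.
.bonferroni <- function(p, m) pmin(1, m * p)

# Extract a genes x samples numeric matrix from a matrix or a
# SummarizedExperiment (first assay).
.exprsMatrix <- function(x) {
  if (methods::is(x, "SummarizedExperiment"))
    return(as.matrix(SummarizedExperiment::assay(x, 1L)))
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.matrix(x) || !is.numeric(x))
    stop("expected a numeric matrix or SummarizedExperiment")
  x
}

.phenoTable <- function(x) {
  if (methods::is(x, "SummarizedExperiment"))
    return(as.data.frame(SummarizedExperiment::colData(x)))
  as.data.frame(x)
}

# Full-precision numeric formatting for deterministic TSV round trips.
.fmtNum <- function(x) format(x, digits = 17, trim = TRUE, scientific = FALSE)
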