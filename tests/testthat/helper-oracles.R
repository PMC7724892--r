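# Independent test oracles: small brute-force computations kept deliberately
# separate from the package's own algorithms.

# all DAGs over a labelled node set, enumerated by brute force over the
# 3^(p choose 2) orientation assignments with an independent cycle check
oracle_all_dags <- function(nodes) {
  pairs <- t(utils::combn(nodes, 2L))
  states <- expand.grid(rep(list(0:2), nrow(pairs)))
  acyclic <- function(arcs, nodes) {
    # repeatedly strip sink nodes
    remaining <- nodes
    repeat {
      if (!nrow(arcs)) return(TRUE)
      sinks <- setdiff(remaining, arcs[, 1L])
      if (!length(sinks)) return(FALSE)
      remaining <- setdiff(remaining, sinks)
      arcs <- arcs[!(arcs[, 2L] %in% sinks), , drop = FALSE]
    }
  }
  out <- list()
  for (r in seq_len(nrow(states))) {
    arcs <- matrix(character(0), 0L, 2L)
    for (k in seq_len(nrow(pairs))) {
      s <- states[r, k]
      if (s == 1) arcs <- rbind(arcs, pairs[k, ])
      if (s == 2) arcs <- rbind(arcs, rev(pairs[k, ]))
    }
    if (acyclic(arcs, nodes)) out[[length(out) + 1L]] <- arcs
  }
  out
}

# Gaussian BIC of a DAG computed through lm()/logLik(): an independent route
# to the package score (logLik uses the ML variance estimate)
oracle_bic <- function(data, arcs) {
  nodes <- colnames(data)
  n <- nrow(data)
  total <- 0
  for (v in nodes) {
    pa <- if (length(arcs)) arcs[arcs[, 2L] == v, 1L] else character(0)
    fml <- if (length(pa))
      stats::as.formula(paste(v, "~", paste(pa, collapse = "+")))
    else stats::as.formula(paste(v, "~ 1"))
    fit <- stats::lm(fml, data = data)
    total <- total + as.numeric(stats::logLik(fit)) -
      log(n) / 2 * (length(pa) + 2)
  }
  total
}

# random DAG over LETTERS[1:nV] by random topological order (independent of
# the package's generator)
oracle_random_dag <- function(nV, prob = 0.3) {
  nodes <- LETTERS[seq_len(nV)]
  ord <- sample(nodes)
  arcs <- matrix(character(0), 0L, 2L)
  for (a in seq_len(nV - 1L))
    for (b in (a + 1L):nV)
      if (stats::runif(1) < prob) arcs <- rbind(arcs, c(ord[a], ord[b]))
  list(nodes = nodes, arcs = arcs)
}

# Welch two-sample t statistic and two-sided p by the closed-form formulas
oracle_welch <- function(x, y) {
  vx <- stats::var(x) / length(x)
  vy <- stats::var(y) / length(y)
  tstat <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  list(t = tstat, p = 2 * stats::pt(-abs(tstat), df))
}

# small standardized synthetic cohort used by several suites
small_cohort <- function(seed = 1, nSamples = 60, nGenes = 400) {
  simulateCohort(nSamples = nSamples, nGenes = nGenes, seed = seed)
}
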