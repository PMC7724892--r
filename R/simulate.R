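#' Simulate a transcriptomic cohort with planted modules and AD phenotypes
#'
#' Generates an expression matrix with a single-latent-factor-per-module
#' linear structure plus module-driven clinical phenotypes, so every stage
#' of the module-to-phenotype pipeline can be tested against known ground
#' truth. Each module m has a latent factor f_m ~ N(0, 1) per sample; a
#' gene in module m is `loading * f_m + noise` with the loading drawn
#' uniformly from `loadingRange`; unassigned genes are pure noise. One
#' designated "hub" gene in the causal module is the module's driver: it
#' receives `hubLoading` (the maximal loading) and half the residual noise
#' of ordinary genes, so it tracks the latent factor more tightly than any
#' other member and is an unambiguous recovery target for centrality
#' ranking.
#'
#' Phenotypes: a pathology latent `P = -rho * f_c + sqrt(1 - rho^2) * eps`
#' is negatively coupled (strength `pathologyCoupling`) to the causal
#' factor f_c. Braak stage is P thresholded into 7 equal-probability
#' ordinal levels; NFT counts are nonnegative and increase with Braak;
#' MMSE is `round(mmseBaseline + 4 * (gammaMMSE * f_c - pathologyWeight * P + e))`
#' truncated to the instrument range 0-30, so higher causal-module
#' expression maintains cognition while pathology erodes it. Age, sex and
#' PMI are independent of all factors. Diagnosis groups and reserve labels
#' are derived by applying [severityGroups()] and [classifyReserve()] to
#' the generated MMSE/Braak, so the labels always satisfy the
#' classification rules.
#'
#' Defaults emulate a small hippocampal microarray cohort: 31 samples,
#' 3000 retained genes in 11 modules spanning 38-853 members, the smallest
#' (last) module causal. Output is deterministic given `seed`.
#'
#' @param nSamples number of samples (>= 4; default 31).
#' @param nGenes number of genes (default 3000).
#' @param moduleSizes integer vector of module sizes (each >= 2, sum <=
#'   `nGenes`). Default: 11 sizes spanning 38-853, scaled to `nGenes`.
#' @param causalModule index of the phenotype-driving module (default: the
#'   last, i.e. smallest, module).
#' @param loadingRange range of per-gene factor loadings (default
#'   `c(0.4, 0.9)`).
#' @param gammaMMSE effect of the causal factor on MMSE in standardized
#'   units (default 0.7).
#' @param pathologyCoupling correlation-scale coupling rho between the
#'   causal factor and the pathology latent (default 0.7).
#' @param pathologyWeight effect of the pathology latent on MMSE (default
#'   0.4).
#' @param mmseBaseline center of the MMSE distribution before the factor,
#'   pathology and noise contributions (default 24, calibrated so that the
#'   reserve prevalence approaches the emulated cohort's).
#' @param noiseSd residual per-gene noise standard deviation (default 0.5).
#' @param hubLoading loading of the designated hub gene (default
#'   `max(loadingRange)`).
#' @param seed random seed; fixes all randomness end-to-end.
#' @return A `SummarizedExperiment`: assay `"exprs"` (genes x samples),
#'   `colData` with mmse, braak, nft, age, sex, pmi, diagnosis_group,
#'   reserve_label, and `metadata(se)$truth`, a list with
#'   `moduleAssignment` (named integer, 0 = unassigned), `causalModule`,
#'   `hubGene`, `factorValues` (samples x modules), `pathology`, and
#'   `phenotypeCoefficients`.
#' @examples
#' se <- simulateCohort(nSamples = 40, nGenes = 300, seed = 1)
#' dim(se)
#' S4Vectors::metadata(se)$truth$hubGene
#' @seealso [simulateDAGData()] for linear-Gaussian DAG fixtures.
#' @export
simulateCohort <- function(nSamples = 31, nGenes = 3000, moduleSizes = NULL,
                           causalModule = NULL, loadingRange = c(0.4, 0.9),
                           gammaMMSE = 0.7, pathologyCoupling = 0.7,
                           pathologyWeight = 0.4, mmseBaseline = 24,
                           noiseSd = 0.5,
                           hubLoading = max(loadingRange), seed = 1) {
  if (!is.numeric(nSamples) || nSamples < 4)
    stop("invalid configuration: nSamples must be >= 4")
  if (!is.numeric(nGenes) || nGenes < 2)
    stop("invalid configuration: nGenes must be >= 2")
  nSamples <- as.integer(nSamples); nGenes <- as.integer(nGenes)
  if (is.null(moduleSizes)) {
    base <- c(853, 600, 430, 310, 225, 165, 120, 90, 68, 50, 38)
    moduleSizes <- pmax(2L, as.integer(round(base * nGenes / 3000)))
    while (sum(moduleSizes) > nGenes && length(moduleSizes) > 1L)
      moduleSizes <- moduleSizes[-1L]
  }
  moduleSizes <- as.integer(moduleSizes)
  if (any(moduleSizes < 2L))
    stop("invalid configuration: moduleSizes must all be >= 2")
  if (sum(moduleSizes) > nGenes)
    stop("invalid configuration: sum(moduleSizes) exceeds nGenes")
  nMod <- length(moduleSizes)
  if (is.null(causalModule)) causalModule <- nMod
  causalModule <- as.integer(causalModule)
  if (causalModule < 1L || causalModule > nMod)
    stop("invalid configuration: causalModule out of range")
  if (length(loadingRange) != 2L || any(loadingRange <= 0) ||
      diff(loadingRange) < 0)
    stop("invalid configuration: loadingRange must be an increasing ",
         "positive interval")
  if (!is.numeric(noiseSd) || noiseSd <= 0)
    stop("invalid configuration: noiseSd must be > 0")
  if (abs(pathologyCoupling) > 1)
    stop("invalid configuration: pathologyCoupling must lie in [-1, 1]")

  .withSeed(seed, {
    geneIds <- sprintf("G%05d", seq_len(nGenes))
    sampleIds <- sprintf("S%03d", seq_len(nSamples))
    assignment <- stats::setNames(rep.int(0L, nGenes), geneIds)
    assignment[seq_len(sum(moduleSizes))] <-
      rep.int(seq_len(nMod), moduleSizes)

    F <- matrix(stats::rnorm(nSamples * nMod), nSamples, nMod,
                dimnames = list(sampleIds, paste0("M", seq_len(nMod))))
    loadings <- stats::setNames(
      stats::runif(nGenes, loadingRange[1L], loadingRange[2L]), geneIds)
    hubGene <- geneIds[which(assignment == causalModule)[1L]]
    loadings[hubGene] <- hubLoading

    expr <- matrix(stats::rnorm(nGenes * nSamples, sd = noiseSd),
                   nGenes, nSamples, dimnames = list(geneIds, sampleIds))
    for (m in seq_len(nMod)) {
      idx <- which(assignment == m)
      expr[idx, ] <- expr[idx, ] + tcrossprod(loadings[idx], F[, m])
    }
    # the hub is the module's driver: maximal loading and half the residual
    # noise, so it is unambiguously the best single-gene proxy of the factor
    expr[hubGene, ] <- hubLoading * F[, causalModule] +
      stats::rnorm(nSamples, sd = noiseSd / 2)
    loadings[assignment == 0L] <- 0

    fC <- F[, causalModule]
    rho <- pathologyCoupling
    pathology <- -rho * fC + sqrt(1 - rho^2) * stats::rnorm(nSamples)
    braak <- findInterval(pathology, stats::qnorm(seq_len(6) / 7))
    nft <- pmax(0, round(4 * braak + stats::rnorm(nSamples, sd = 2)))
    latent <- gammaMMSE * fC - pathologyWeight * pathology +
      stats::rnorm(nSamples)
    mmse <- pmin(30, pmax(0, round(mmseBaseline + 4 * latent)))

    pheno <- data.frame(
      mmse = mmse, braak = braak, nft = nft,
      age = round(stats::rnorm(nSamples, 80, 7)),
      sex = sample(c("male", "female"), nSamples, replace = TRUE),
      pmi = round(stats::rlnorm(nSamples, log(6), 0.4), 1),
      row.names = sampleIds)
    pheno <- severityGroups(pheno)
    pheno <- suppressMessages(classifyReserve(pheno))

    truth <- list(
      moduleAssignment = assignment, causalModule = causalModule,
      hubGene = hubGene, factorValues = F, pathology = pathology,
      loadings = loadings,
      phenotypeCoefficients = list(gammaMMSE = gammaMMSE,
                                   pathologyCoupling = pathologyCoupling,
                                   pathologyWeight = pathologyWeight),
      moduleSizes = moduleSizes, noiseSd = noiseSd, seed = seed)
    SummarizedExperiment::SummarizedExperiment(
      assays = list(exprs = expr),
      colData = S4Vectors::DataFrame(pheno),
      metadata = list(truth = truth))
  })
}

#' Simulate data from a known linear-Gaussian DAG
#'
#' Samples each node, in topological order, as the coefficient-weighted sum
#' of its parents plus Gaussian noise. Used as ground-truth input for
#' structure-learning tests: e.g. a single arc A -> B with coefficient c and
#' unit noise implies cor(A, B) = c / sqrt(c^2 + 1).
#'
#' @param arcs two-column character matrix or data.frame (`from`, `to`);
#'   may have zero rows.
#' @param coefficients numeric vector, one per arc (same order as `arcs`).
#' @param nodes character vector of all node names (defaults to the arc
#'   endpoints); isolated nodes must be listed explicitly.
#' @param noiseSd noise standard deviation (scalar or per node, named).
#' @param n number of samples.
#' @param seed random seed.
#' @return data.frame with `n` rows and one column per node.
#' @examples
#' d <- simulateDAGData(cbind("A", "B"), 2, noiseSd = 1, n = 5000, seed = 1)
#' cor(d$A, d$B)  # ~ 2 / sqrt(5) = 0.894
#' @export
simulateDAGData <- function(arcs, coefficients = numeric(0), nodes = NULL,
                            noiseSd = 1, n = 100, seed = 1) {
  arcs <- if (length(arcs)) .asArcMatrix(arcs) else
    matrix(character(0), 0L, 2L, dimnames = list(NULL, c("from", "to")))
  if (nrow(arcs) != length(coefficients))
    stop("need exactly one coefficient per arc")
  if (is.null(nodes)) nodes <- unique(as.vector(t(arcs)))
  nodes <- unique(c(nodes, as.vector(arcs)))
  if (!length(nodes)) stop("no nodes given")
  amat <- .arcsToAmat(arcs, nodes)
  ord <- .topoSort(amat)
  if (is.null(ord)) stop("arc set is cyclic; a DAG is required")
  if (length(noiseSd) == 1L)
    noiseSd <- stats::setNames(rep(noiseSd, length(nodes)), nodes)
  .withSeed(seed, {
    out <- matrix(0, n, length(nodes), dimnames = list(NULL, nodes))
    for (v in ord) {
      node <- nodes[v]
      val <- stats::rnorm(n, sd = noiseSd[[node]])
      pa <- which(amat[, v] == 1L)
      for (u in pa) {
        k <- which(arcs[, 1L] == nodes[u] & arcs[, 2L] == node)
        val <- val + coefficients[k] * out[, u]
      }
      out[, v] <- val
    }
    as.data.frame(out)
  })
}
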