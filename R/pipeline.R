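# End-to-end pipeline driver: preprocess -> co-expression modules ->
# module-phenotype Bayesian network -> module prioritization -> hub genes ->
# downstream statistics, with TSV/GraphML outputs and a JSON run manifest.

.configDefaults <- function() list(
  expression = NULL, phenotypes = NULL, outDir = NULL,
  keepFraction = 0.25, keepCount = NULL, dropConstant = TRUE,
  power = 6, powers = 1:20, r2Cutoff = 0.9,
  cutHeight = 0.99, minModuleSize = 30,
  covariates = c("age", "sex", "pmi"),
  moduleRestarts = 200L, arcThreshold = 0.5, initProb = 0.1,
  geneRestarts = 100L, geneArcThreshold = 0.5, keepGenesPath = NULL,
  geneMax = 150L,
  epcP = 0.5, epcSamples = 1000L, kHubs = 6L,
  familySize = NULL, seed = 1L)

#' Build a pipeline configuration
#'
#' Collects all pipeline parameters with validated defaults. Unknown keys
#' are rejected. A JSON file with the same keys can override the defaults.
#'
#' @param ... named parameters overriding the defaults (see
#'   [runPipeline()] for their meaning).
#' @param configFile optional path to a JSON configuration; its entries are
#'   applied before `...`.
#' @return A named list with class `"mpnPipelineConfig"`.
#' @examples
#' cfg <- pipelineConfig(seed = 7, kHubs = 6)
#' cfg$seed
#' @export
pipelineConfig <- function(..., configFile = NULL) {
  cfg <- .configDefaults()
  apply_over <- function(cfg, over, src) {
    unknown <- setdiff(names(over), names(cfg))
    if (length(unknown))
      stop("unknown configuration key(s) in ", src, ": ",
           paste(unknown, collapse = ", "))
    for (k in names(over)) cfg[[k]] <- over[[k]]
    cfg
  }
  if (!is.null(configFile))
    cfg <- apply_over(cfg, jsonlite::read_json(configFile, simplifyVector = TRUE),
                      configFile)
  cfg <- apply_over(cfg, list(...), "arguments")
  if (!is.null(cfg$keepFraction) &&
      (cfg$keepFraction <= 0 || cfg$keepFraction > 1))
    stop("keepFraction must lie in (0, 1]")
  if (!identical(cfg$power, "auto") && (!is.numeric(cfg$power) || cfg$power < 1))
    stop("power must be >= 1 or \"auto\"")
  for (k in c("moduleRestarts", "geneRestarts", "epcSamples", "kHubs"))
    if (cfg[[k]] < 1) stop(k, " must be >= 1")
  if (cfg$epcP <= 0 || cfg$epcP >= 1) stop("epcP must lie in (0, 1)")
  structure(cfg, class = "mpnPipelineConfig")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the module-to-phenotype pipeline
#'
#' Executes, in order: z-score normalization and variance filtering;
#' similarity / soft-thresholded adjacency / topological overlap / module
#' detection / eigengenes / covariate-adjusted module-trait correlations;
#' model-averaged Bayesian-network learning over module eigengenes plus
#' the reserve, MMSE, Braak and NFT phenotype nodes; Markov-blanket module
#' prioritization; within-module gene-network learning and
#' edge-percolated-component hub selection for the top-ranked module; and
#' reserve / severity group contrasts of the top module's eigengene.
#'
#' When `outDir` is set, writes: module assignment and eigengene TSVs, the
#' module-trait table, module- and gene-level edge lists (TSV and
#' GraphML), EPC scores, the hub subnetwork (GraphML), a statistics TSV,
#' and `manifest.json` recording the package version, all parameters, the
#' derived per-stage seeds, and md5 digests of inputs and outputs.
#' Identical configuration and seed reproduce all outputs byte for byte.
#'
#' @param config an `"mpnPipelineConfig"` from [pipelineConfig()].
#' @param expression genes x samples matrix or `SummarizedExperiment`
#'   (overrides `config$expression` path).
#' @param phenotypes phenotype data.frame (overrides `config$phenotypes`
#'   path; taken from the `SummarizedExperiment` colData if present).
#' @return list with `topModule` (label), `priority` (ranking table),
#'   `hubs`, `moduleSet`, `moduleTrait`, `mpnFit`, `geneNetwork`,
#'   `epc`, `stats`, `selectedPower`, `manifest`, and `files`.
#' @export
runPipeline <- function(config = pipelineConfig(), expression = NULL,
                        phenotypes = NULL) {
  stopifnot(inherits(config, "mpnPipelineConfig"))
  seed <- as.integer(config$seed)
  inputDigests <- list()

  if (is.null(expression)) {
    if (is.null(config$expression))
      stop("no expression input: pass `expression` or set config$expression")
    inputDigests$expression <- unname(tools::md5sum(config$expression))
    expression <- readExpression(config$expression)
  }
  if (is.null(phenotypes)) {
    if (methods::is(expression, "SummarizedExperiment")) {
      phenotypes <- .phenoTable(expression)
    } else if (!is.null(config$phenotypes)) {
      inputDigests$phenotypes <- unname(tools::md5sum(config$phenotypes))
      phenotypes <- readPhenotypes(config$phenotypes)
    } else stop("no phenotype input")
  }
  phenotypes <- .phenoTable(phenotypes)
  expr <- .exprsMatrix(expression)
  if (ncol(expr) != nrow(phenotypes))
    stop("expression samples and phenotype rows are not aligned")

  z <- .stage("preprocess", {
    z <- zscoreGenes(expr, dropConstant = isTRUE(config$dropConstant))
    filterByVariance(z, keepFraction = config$keepFraction,
                     keepCount = config$keepCount)
  })
  phenotypes <- .stage("preprocess", {
    ph <- phenotypes
    if (is.null(ph$diagnosis_group)) ph <- severityGroups(ph)
    if (is.null(ph$reserve_label)) ph <- classifyReserve(ph)
    ph
  })

  co <- .stage("coexpression", {
    sim <- pearsonSimilarity(z)
    power <- config$power
    fitTab <- NULL
    if (identical(power, "auto")) {
      pick <- pickSoftThreshold(sim, powers = config$powers,
                                r2Cutoff = config$r2Cutoff)
      power <- pick$power
      fitTab <- pick$fitTable
    }
    adj <- adjacencyFromSimilarity(sim, beta = power)
    tomMat <- tomSimilarity(adj)
    labels <- detectModules(tomMat, minModuleSize = config$minModuleSize,
                            cutHeight = config$cutHeight)
    if (!any(labels > 0L)) stop("no modules detected")
    ms <- moduleEigengenes(z, labels)
    mt <- moduleTraitCorrelation(ms, phenotypes,
                                 covariates = config$covariates)
    list(moduleSet = ms, moduleTrait = mt, power = power, fitTable = fitTab)
  })
  ms <- co$moduleSet

  mpn <- .stage("bayesnet", {
    d <- mpnData(ms, phenotypes)
    learnAveragedNetwork(d, nRestarts = config$moduleRestarts,
                         arcThreshold = config$arcThreshold,
                         seed = .childSeed(seed, "bayesnet"),
                         initProb = config$initProb)
  })
  priority <- .stage("bayesnet", prioritizeModules(mpn))
  topModule <- priority$module[1L]

  hub <- .stage("hubgenes", {
    labels <- moduleLabels(ms)
    topLabel <- as.integer(sub("^M", "", topModule))
    genes <- names(labels)[labels == topLabel]
    if (length(genes) > config$geneMax) {
      # reduce a large module to its most coherent members (highest
      # absolute module membership), keeping the gene network tractable
      mm <- abs(stats::cor(t(z[genes, , drop = FALSE]),
                           eigengenes(ms)[topModule, ]))
      genes <- genes[order(-mm)[seq_len(config$geneMax)]]
    }
    keepGenes <- if (!is.null(config$keepGenesPath))
      readLines(config$keepGenesPath) else NULL
    net <- buildGeneNetwork(z, genes, keepGenes = keepGenes,
                            nRestarts = config$geneRestarts,
                            arcThreshold = config$geneArcThreshold,
                            seed = .childSeed(seed, "hubgenes"))
    if (igraph::vcount(net) < 2L)
      stop("gene network for module ", topModule, " is empty")
    sc <- epcScore(net, p = config$epcP, nSamples = config$epcSamples,
                   seed = .childSeed(seed, "hubgenes") + 1L)
    k <- min(config$kHubs, nrow(epcTable(sc)))
    hubs <- selectHubs(sc, net, k = k)
    list(network = net, scores = sc, hubs = hubs)
  })

  statsTab <- .stage("stats", {
    eg <- eigengenes(ms)[topModule, ]
    tests <- list()
    lab <- phenotypes$reserve_label
    ev <- lab %in% c("reserve", "loss_reserve")
    if (length(unique(lab[ev])) == 2L &&
        all(table(droplevels(factor(lab[ev]))) >= 2L))
      tests$reserve <- groupCompare(eg[ev], droplevels(factor(lab[ev])),
                                    familySize = 1L)
    grp <- droplevels(factor(phenotypes$diagnosis_group))
    if (nlevels(grp) >= 2L && all(table(grp) >= 2L))
      tests$severity <- groupCompare(eg, grp, familySize = 1L)
    m <- if (is.null(config$familySize)) length(tests) else config$familySize
    out <- do.call(rbind, tests)
    if (!is.null(out)) {
      out$m <- m
      out$adjusted_p <- .bonferroni(out$raw_p, m)
      out <- cbind(contrast = names(tests), out)
      rownames(out) <- NULL
    }
    out
  })

  files <- list()
  manifest <- list(
    package = "mpnet",
    version = as.character(utils::packageVersion("mpnet")),
    seed = seed,
    childSeeds = list(bayesnet = .childSeed(seed, "bayesnet"),
                      hubgenes = .childSeed(seed, "hubgenes")),
    parameters = unclass(config)[setdiff(names(config),
                                         c("expression", "phenotypes",
                                           "outDir"))],
    selectedPower = co$power,
    inputDigests = inputDigests,
    topModule = topModule,
    hubs = hub$hubs$hubs)

  if (!is.null(config$outDir)) {
    dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
    fp <- function(name) file.path(config$outDir, name)
    labels <- moduleLabels(ms)
    utils::write.table(
      data.frame(gene_id = names(labels), module = labels),
      files$modules <- fp("module_assignment.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    writeExpression(eigengenes(ms), files$eigengenes <- fp("eigengenes.tsv"))
    mt <- co$moduleTrait
    mtTab <- data.frame(module = rownames(mt$correlation),
                        trait = rep(colnames(mt$correlation),
                                    each = nrow(mt$correlation)),
                        correlation = .fmtNum(as.vector(mt$correlation)),
                        p = .fmtNum(as.vector(mt$p)),
                        padj = .fmtNum(as.vector(mt$padj)))
    utils::write.table(mtTab, files$moduleTrait <- fp("module_trait.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeEdgeList(mpn, files$mpnEdges <- fp("mpn_edges.tsv"))
    writeNetworkGraphML(mpn, files$mpnGraphML <- fp("mpn_network.graphml"))
    utils::write.table(priority, files$priority <- fp("module_priority.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeEdgeList(hub$network, files$geneEdges <- fp("gene_edges.tsv"))
    writeNetworkGraphML(hub$network,
                        files$geneGraphML <- fp("gene_network.graphml"))
    epcTab <- hub$hubs$ranking
    epcTab$epc <- .fmtNum(epcTab$epc)
    epcTab$se <- .fmtNum(epcTab$se)
    utils::write.table(epcTab, files$epc <- fp("epc_scores.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeNetworkGraphML(hub$hubs$subnetwork,
                        files$hubGraphML <- fp("hub_subnetwork.graphml"))
    if (!is.null(statsTab))
      utils::write.table(statsTab, files$stats <- fp("stats.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$outputDigests <- lapply(files, function(f)
      unname(tools::md5sum(f)))
    jsonlite::write_json(manifest, fp("manifest.json"), auto_unbox = TRUE,
                         pretty = TRUE, digits = NA, null = "null")
    files$manifest <- fp("manifest.json")
  }

  list(topModule = topModule, priority = priority, hubs = hub$hubs$hubs,
       moduleSet = ms, moduleTrait = co$moduleTrait, mpnFit = mpn,
       geneNetwork = hub$network, epc = hub$scores, stats = statsTab,
       selectedPower = co$power, manifest = manifest, files = files)
}
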