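#' Pearson similarity between gene expression profiles
#'
#' @param x genes x samples matrix or `SummarizedExperiment` with at least
#'   3 samples and no constant rows.
#' @return Symmetric genes x genes correlation matrix with unit diagonal.
#' @examples
#' m <- matrix(rnorm(30), 3, 10, dimnames = list(c("a", "b", "c"), NULL))
#' pearsonSimilarity(m)
#' @export
pearsonSimilarity <- function(x) {
  m <- .exprsMatrix(x)
  if (ncol(m) < 3L) stop("need at least 3 samples")
  sds <- apply(m, 1L, stats::sd)
  if (any(sds < .Machine$double.eps^0.5))
    stop("constant gene row(s) present; drop them before computing ",
         "similarity: ", paste(utils::head(rownames(m)[sds < 1e-8], 5L),
                               collapse = ", "))
  s <- stats::cor(t(m))
  diag(s) <- 1
  s
}

#' Scale-free topology fit of a connectivity distribution
#'
#' Bins connectivities into `nBins` equal-width bins and regresses
#' log10(bin frequency) on log10(mean bin connectivity); a power-law
#' degree distribution makes this relation linear. The returned R^2 is
#' signed by the slope: scale-free topology requires a negative slope, so
#' a positive slope yields a negative fit index. (Equal-count bins would
#' make the frequencies constant by construction and the fit degenerate,
#' so width-based binning is the only meaningful discretization here.)
#'
#' @param k numeric vector of node connectivities (k_i = sum_j a_ij).
#' @param nBins number of equal-width bins (default 10).
#' @return list with `r2` (signed), `slope`, and `table` (per-bin mean k
#'   and log frequency).
#' @export
scaleFreeFit <- function(k, nBins = 10) {
  k <- k[k > 0]
  if (length(unique(k)) < 3L) stop("fewer than 3 nonempty connectivity bins")
  breaks <- seq(min(k), max(k), length.out = nBins + 1L)
  bin <- cut(k, breaks = breaks, include.lowest = TRUE)
  counts <- tabulate(bin, nbins = nlevels(bin))
  meanK <- tapply(k, bin, mean)
  keep <- counts > 0 & !is.na(meanK)
  if (sum(keep) < 3L) stop("fewer than 3 nonempty connectivity bins")
  df <- data.frame(logK = log10(meanK[keep]),
                   logP = log10(counts[keep] / sum(counts)))
  fit <- stats::lm(logP ~ logK, data = df)
  slope <- unname(stats::coef(fit)[2L])
  r2 <- summary(fit)$r.squared
  list(r2 = if (slope < 0) r2 else -r2, slope = slope, table = df)
}

#' Select the soft-thresholding power by scale-free fit
#'
#' For each candidate power, raises the absolute correlation matrix to that
#' power, computes node connectivities and the signed scale-free fit R^2
#' ([scaleFreeFit()]), and returns the smallest power whose R^2 reaches
#' `r2Cutoff`. If no power reaches the cutoff, the power maximizing R^2 is
#' returned with `warning = TRUE`.
#'
#' @param sim similarity matrix from [pearsonSimilarity()].
#' @param powers candidate integer powers (default 1:20).
#' @param r2Cutoff required signed R^2 (default 0.9).
#' @param nBins connectivity bins for the fit (default 10).
#' @return list with `power`, `warning` (logical), and `fitTable`
#'   (power, r2, slope, meanK).
#' @export
pickSoftThreshold <- function(sim, powers = 1:20, r2Cutoff = 0.9, nBins = 10) {
  if (!length(powers)) stop("candidate power list is empty")
  rows <- lapply(powers, function(b) {
    a <- abs(sim)^b
    diag(a) <- 0
    k <- rowSums(a)
    f <- scaleFreeFit(k, nBins)
    data.frame(power = b, r2 = f$r2, slope = f$slope, meanK = mean(k))
  })
  tab <- do.call(rbind, rows)
  ok <- which(tab$r2 >= r2Cutoff)
  if (length(ok)) {
    list(power = tab$power[ok[1L]], warning = FALSE, fitTable = tab)
  } else {
    list(power = tab$power[which.max(tab$r2)], warning = TRUE, fitTable = tab)
  }
}

#' Soft-thresholded (unsigned) adjacency
#'
#' `a_ij = |cor_ij|^beta`; the diagonal is set to 0 so that row sums are
#' node connectivities. The unsigned network is used throughout; the power
#' emphasises strong correlations and suppresses weak ones, pushing the
#' degree distribution toward scale-free.
#'
#' @param sim similarity matrix.
#' @param beta integer power >= 1 (default 6).
#' @return Adjacency matrix in \[0, 1\] with attribute `beta`.
#' @export
adjacencyFromSimilarity <- function(sim, beta = 6) {
  if (!is.numeric(beta) || beta < 1) stop("beta must be >= 1")
  a <- abs(sim)^beta
  diag(a) <- 0
  attr(a, "beta") <- beta
  a
}

#' Topological overlap matrix
#'
#' `TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` for i != j, with
#' `l_ij = sum_u a_iu a_uj` the shared-neighbor sum and `k_i = sum_u a_iu`
#' the connectivity; `TOM_ii = 1` by convention. Two genes have high
#' topological overlap when they are strongly connected to each other and
#' to the same neighbors, which makes 1 - TOM a robust clustering
#' dissimilarity.
#'
#' @param adj adjacency matrix from [adjacencyFromSimilarity()] (zero
#'   diagonal).
#' @return Symmetric TOM matrix with entries in \[0, 1\] and unit diagonal.
#' @export
tomSimilarity <- function(adj) {
  a <- unclass(adj)
  diag(a) <- 0
  k <- rowSums(a)
  l <- a %*% a
  denom <- outer(k, k, pmin) + 1 - a
  tomMat <- (l + a) / denom
  diag(tomMat) <- 1
  # guard against tiny negative / >1 values from floating error
  tomMat[tomMat < 0] <- 0
  tomMat[tomMat > 1] <- 1
  out <- (tomMat + t(tomMat)) / 2
  attr(out, "beta") <- NULL
  out
}

#' Detect co-expression modules by tree cutting
#'
#' Average-linkage hierarchical clustering on the dissimilarity 1 - TOM,
#' cut at a fixed dendrogram height; clusters smaller than
#' `minModuleSize` are merged into the unassigned (grey) label 0. Labels
#' are renumbered 1, 2, ... by decreasing module size.
#'
#' @param tomMat TOM matrix from [tomSimilarity()].
#' @param minModuleSize smallest admissible module (default 30).
#' @param cutHeight dendrogram cut height on the 1 - TOM scale
#'   (default 0.99).
#' @return Named integer vector: gene -> module label (0 = unassigned).
#' @export
detectModules <- function(tomMat, minModuleSize = 30, cutHeight = 0.99) {
  if (minModuleSize < 2) stop("minModuleSize must be >= 2")
  d <- stats::as.dist(1 - tomMat)
  if (max(d) - min(d) < 1e-12)
    message("degenerate TOM (all dissimilarities equal); ",
            "module structure is not identifiable")
  h <- stats::hclust(d, method = "average")
  raw <- stats::cutree(h, h = cutHeight)
  sizes <- table(raw)
  big <- names(sizes)[sizes >= minModuleSize]
  labels <- rep.int(0L, length(raw))
  if (length(big)) {
    ord <- big[order(-sizes[big], as.integer(big))]
    for (i in seq_along(ord)) labels[raw == as.integer(ord[i])] <- i
  }
  stats::setNames(as.integer(labels), rownames(tomMat))
}

#' Module eigengenes and gene loadings
#'
#' The eigengene of a module is the first right singular vector (over
#' samples) of the row-standardized module submatrix: a unit-norm
#' per-sample summary profile of the module. Its sign is aligned so that
#' its correlation with the module's mean expression profile is
#' nonnegative. The fraction of module variance explained by the eigengene
#' and the per-gene first-singular-vector loadings (used to project the
#' module into external cohorts) are recorded.
#'
#' @param x genes x samples matrix or `SummarizedExperiment` (rows should
#'   be z-scored; they are re-standardized defensively).
#' @param labels named integer module assignment from [detectModules()],
#'   or a [ModuleSet-class] whose labels are reused.
#' @return A [ModuleSet-class] object.
#' @export
moduleEigengenes <- function(x, labels) {
  m <- .exprsMatrix(x)
  if (methods::is(labels, "ModuleSet")) labels <- moduleLabels(labels)
  if (is.null(names(labels)))
    stop("module labels must be named by gene")
  common <- intersect(rownames(m), names(labels))
  if (!length(common)) stop("no overlap between matrix genes and labels")
  labels <- labels[common]
  mods <- sort(setdiff(unique(labels), 0L))
  eig <- matrix(NA_real_, length(mods), ncol(m),
                dimnames = list(paste0("M", seq_along(mods)), colnames(m)))
  ve <- stats::setNames(numeric(length(mods)), rownames(eig))
  loads <- stats::setNames(vector("list", length(mods)), rownames(eig))
  for (i in seq_along(mods)) {
    genes <- names(labels)[labels == mods[i]]
    sub <- m[genes, , drop = FALSE]
    sub <- t(scale(t(sub)))
    if (length(genes) == 1L) {
      warning("module ", mods[i], " has a single gene; ",
              "its eigengene is that gene's profile")
      v <- sub[1L, ] / sqrt(sum(sub[1L, ]^2))
      eig[i, ] <- v; ve[i] <- 1
      loads[[i]] <- stats::setNames(1, genes)
      next
    }
    sv <- svd(sub)
    v <- sv$v[, 1L]
    u <- sv$u[, 1L]
    if (stats::cor(v, colMeans(sub)) < 0) { v <- -v; u <- -u }
    eig[i, ] <- v
    ve[i] <- sv$d[1L]^2 / sum(sv$d^2)
    loads[[i]] <- stats::setNames(u, genes)
  }
  methods::new("ModuleSet", labels = labels, eigengenes = eig,
               varianceExplained = ve, loadings = loads,
               params = list(nSamples = ncol(m)))
}

# Encode a phenotype column numerically for correlation: factors are coded
# ordinally in level order; reserve labels 1/0 with not_evaluable -> NA;
# sex male = 0 / female = 1.
.encodeTrait <- function(v, name) {
  if (is.numeric(v)) return(as.numeric(v))
  v <- as.character(v)
  if (name == "reserve_label")
    return(ifelse(v == "reserve", 1,
           ifelse(v == "loss_reserve", 0, NA_real_)))
  if (name == "sex") return(ifelse(tolower(v) %in% c("male", "m"), 0, 1))
  if (name == "diagnosis_group") {
    lev <- c("control", "incipient", "moderate", "severe",
             "NCI", "MCI", "AD")
    code <- c(0, 1, 2, 3, 0, 1, 2)
    return(code[match(v, lev)])
  }
  as.numeric(factor(v)) - 1
}

#' Module-trait correlations with covariate adjustment
#'
#' Partial Pearson correlation between each module eigengene and each
#' phenotype, controlling for a covariate list (age, sex, PMI by default):
#' both sides are residualized on the covariates by least squares and the
#' residuals correlated. Two-sided p-values use the t transform with
#' n - 2 - q degrees of freedom (q covariates); Bonferroni adjustment is
#' applied across the whole module x trait grid.
#'
#' Categorical traits are encoded numerically: diagnosis groups ordinally
#' (control = 0 ... severe = 3, or NCI/MCI/AD = 0/1/2), reserve 1 /
#' loss-reserve 0 (not_evaluable samples are dropped for that trait), sex
#' 0/1.
#'
#' @param eig [ModuleSet-class] or modules x samples eigengene matrix.
#' @param phenotypes data.frame aligned with the eigengene samples.
#' @param traits character vector of phenotype columns to correlate
#'   (default: the intersection of
#'   `c("diagnosis_group", "reserve_label", "mmse", "braak", "nft")` with
#'   available columns).
#' @param covariates character vector of covariate columns (default
#'   `c("age", "sex", "pmi")`, intersected with available columns).
#' @return list with matrices `correlation`, `p`, `padj` (modules x
#'   traits), the family size `m`, and per-trait sample sizes `n`.
#' @export
moduleTraitCorrelation <- function(eig, phenotypes, traits = NULL,
                                   covariates = c("age", "sex", "pmi")) {
  E <- if (methods::is(eig, "ModuleSet")) eigengenes(eig) else as.matrix(eig)
  ph <- .phenoTable(phenotypes)
  if (ncol(E) != nrow(ph))
    stop("eigengene samples and phenotype rows are not aligned")
  if (is.null(traits))
    traits <- intersect(c("diagnosis_group", "reserve_label", "mmse",
                          "braak", "nft"), names(ph))
  covariates <- intersect(covariates, names(ph))
  bad <- intersect(traits, covariates)
  if (length(bad))
    stop("trait and covariate lists overlap (", paste(bad, collapse = ", "),
         "); a trait cannot be its own covariate")
  q <- length(covariates)
  X <- if (q) {
    cv <- vapply(covariates, function(cn) .encodeTrait(ph[[cn]], cn),
                 numeric(nrow(ph)))
    cbind(1, cv)
  } else matrix(1, nrow(ph), 1L)

  corMat <- pMat <- matrix(NA_real_, nrow(E), length(traits),
                           dimnames = list(rownames(E), traits))
  nVec <- stats::setNames(integer(length(traits)), traits)
  for (tr in traits) {
    y <- .encodeTrait(ph[[tr]], tr)
    ok <- !is.na(y) & stats::complete.cases(X)
    n <- sum(ok)
    nVec[tr] <- n
    if (n < q + 4L) stop("too few complete samples for trait '", tr, "'")
    if (stats::sd(y[ok]) < 1e-10) {
      message("trait '", tr, "' is constant; correlations set to NA")
      next
    }
    Xo <- X[ok, , drop = FALSE]
    qrX <- qr(Xo)
    ry <- stats::setNames(qr.resid(qrX, y[ok]), NULL)
    if (stats::sd(ry) < 1e-10)
      stop("trait '", tr, "' is collinear with the covariates (",
           paste(covariates, collapse = ", "), ")")
    for (mi in rownames(E)) {
      re <- qr.resid(qrX, E[mi, ok])
      if (stats::sd(re) < 1e-12) {
        corMat[mi, tr] <- NA_real_
        next
      }
      r <- stats::cor(re, ry)
      df <- n - 2L - q
      tt <- r * sqrt(df / max(1 - r^2, .Machine$double.eps))
      corMat[mi, tr] <- r
      pMat[mi, tr] <- 2 * stats::pt(-abs(tt), df)
    }
  }
  m <- sum(!is.na(pMat))
  list(correlation = corMat, p = pMat, padj = .bonferroni(pMat, m),
       m = m, n = nVec, covariates = covariates)
}

#' Gene significance and module membership
#'
#' Gene significance `GS_g = |cor(expr_g, trait)|` measures a gene's
#' marginal association with a phenotype; module membership
#' `MM_{g,m} = cor(expr_g, ME_m)` measures how well a gene conforms to a
#' module's eigengene. In a biologically coherent, trait-relevant module,
#' MM and GS are positively correlated across member genes.
#'
#' @param x genes x samples matrix or `SummarizedExperiment`.
#' @param moduleSet a [ModuleSet-class].
#' @param trait numeric vector aligned with samples (or a phenotype column
#'   name present in a `SummarizedExperiment` `x`).
#' @return list with `table` (gene, module, GS, MM of its own module),
#'   `MM` (genes x modules matrix), and `summary` (per module:
#'   cor(MM, GS) with its p-value).
#' @export
geneSignificance <- function(x, moduleSet, trait) {
  m <- .exprsMatrix(x)
  if (is.character(trait) && length(trait) == 1L)
    trait <- .encodeTrait(.phenoTable(x)[[trait]], trait)
  trait <- as.numeric(trait)
  if (length(trait) != ncol(m)) stop("trait vector not aligned with samples")
  E <- eigengenes(moduleSet)
  labels <- moduleLabels(moduleSet)
  genes <- intersect(rownames(m), names(labels))
  gs <- abs(as.vector(stats::cor(t(m[genes, , drop = FALSE]), trait)))
  mm <- stats::cor(t(m[genes, , drop = FALSE]), t(E))
  ownLab <- labels[genes]
  ownMM <- rep(NA_real_, length(genes))
  inMod <- ownLab > 0L
  ownMM[inMod] <- mm[cbind(which(inMod), ownLab[inMod])]
  tab <- data.frame(gene = genes, module = ownLab, GS = gs, MM = ownMM,
                    row.names = NULL)
  mods <- sort(setdiff(unique(ownLab), 0L))
  summ <- do.call(rbind, lapply(mods, function(mod) {
    sel <- ownLab == mod
    if (sum(sel) < 3L)
      return(data.frame(module = mod, corMMGS = NA_real_, p = NA_real_))
    ct <- stats::cor.test(abs(mm[sel, mod]), gs[sel])
    data.frame(module = mod, corMMGS = unname(ct$estimate), p = ct$p.value)
  }))
  list(table = tab, MM = mm, summary = summ)
}
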