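test_that("Pearson similarity matches a brute-force pairwise oracle", {
  set.seed(5)
  m <- matrix(rnorm(18), 3, 6, dimnames = list(c("a", "b", "c"), NULL))
  s <- pearsonSimilarity(m)
  expect_equal(diag(s), c(a = 1, b = 1, c = 1))
  for (i in 1:3) for (j in 1:3)
    expect_equal(s[i, j], stats::cor(m[i, ], m[j, ]), tolerance = 1e-12)
  # antisymmetry: gene vs its negation
  m2 <- rbind(x = m[1, ], y = -m[1, ])
  expect_equal(pearsonSimilarity(m2)["x", "y"], -1)
  expect_error(pearsonSimilarity(m[, 1:2]), "3 samples")
  expect_error(pearsonSimilarity(rbind(m, flat = rep(1, 6))), "constant")
})

test_that("adjacency applies the unsigned power transform", {
  s <- matrix(c(1, 0.5, 0, 0.5, 1, -1, 0, -1, 1), 3, 3,
              dimnames = list(letters[1:3], letters[1:3]))
  a <- adjacencyFromSimilarity(s, beta = 6)
  expect_equal(a["a", "b"], 0.5^6)        # 0.015625 exactly
  expect_equal(a["a", "c"], 0)
  expect_equal(a["b", "c"], 1)            # |cor| = 1
  expect_equal(diag(a), c(a = 0, b = 0, c = 0))
  a1 <- adjacencyFromSimilarity(s, beta = 1)
  expect_equal(a1["b", "c"], 1)
  expect_equal(a1["a", "b"], 0.5)
  expect_error(adjacencyFromSimilarity(s, beta = 0), "beta")
})

test_that("TOM matches the hand-evaluated 3-node fixture", {
  # all pairwise adjacencies 0.5: k = 1, l_ij = 0.25,
  # TOM_ij = (0.25 + 0.5) / (min(1,1) + 1 - 0.5) = 0.5
  a <- matrix(0.5, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  diag(a) <- 0
  tm <- tomSimilarity(a)
  expect_equal(tm[1, 2], 0.5, tolerance = 1e-12)
  expect_equal(diag(tm), c(a = 1, b = 1, c = 1))
  # unconnected pair with no shared neighbors has TOM 0
  a2 <- matrix(0, 3, 3); a2[1, 2] <- a2[2, 1] <- 0.8
  dimnames(a2) <- list(letters[1:3], letters[1:3])
  expect_equal(tomSimilarity(a2)["a", "c"], 0)
  # bounds and symmetry on random adjacencies
  set.seed(6)
  r <- matrix(runif(100), 10, 10); r <- (r + t(r)) / 2; diag(r) <- 0
  tr <- tomSimilarity(r)
  expect_true(all(tr >= 0 & tr <= 1))
  expect_equal(tr, t(tr))
  # monotonicity: increasing one adjacency never decreases that pair's TOM
  r2 <- r; r2[1, 2] <- r2[2, 1] <- min(1, r[1, 2] + 0.2)
  expect_gte(tomSimilarity(r2)[1, 2], tr[1, 2])
})

test_that("scale-free fit recognizes an exact power law", {
  # degree sequence with p(k) ~ k^-2 by construction
  ks <- 1:20
  k <- rep(ks, times = round(5000 * ks^-2))
  fit <- suppressWarnings(scaleFreeFit(k, nBins = 10))
  expect_gte(fit$r2, 0.9)
  expect_lt(fit$slope, 0)
  # a flat (uniform) degree distribution is not scale-free
  flat <- suppressWarnings(scaleFreeFit(rep(1:100, each = 20), nBins = 10))
  expect_lt(flat$r2, 0.9)
})

test_that("soft threshold selection returns cutoff or argmax fallback", {
  se <- small_cohort(seed = 2)
  z <- zscoreGenes(SummarizedExperiment::assay(se))
  s <- pearsonSimilarity(z)
  pick <- pickSoftThreshold(s, powers = 1:10, r2Cutoff = 0.9)
  expect_true(pick$power %in% 1:10)
  expect_equal(nrow(pick$fitTable), 10L)
  # impossible cutoff forces the argmax fallback with a warning flag
  pick2 <- pickSoftThreshold(s, powers = 1:6, r2Cutoff = 0.999999)
  expect_true(pick2$warning)
  expect_equal(pick2$power,
               pick2$fitTable$power[which.max(pick2$fitTable$r2)])
  # smallest power reaching an attainable cutoff is selected
  attainable <- max(pick$fitTable$r2) - 1e-6
  pick3 <- pickSoftThreshold(s, powers = 1:10, r2Cutoff = attainable)
  expect_false(pick3$warning)
  expect_equal(pick3$power,
               min(pick3$fitTable$power[pick3$fitTable$r2 >= attainable]))
})

test_that("two planted blocks are recovered exactly", {
  set.seed(7)
  n <- 100
  f1 <- rnorm(n); f2 <- rnorm(n)
  x <- rbind(matrix(rep(f1, each = 40), 40) + matrix(rnorm(40 * n, sd = 0.3), 40),
             matrix(rep(f2, each = 40), 40) + matrix(rnorm(40 * n, sd = 0.3), 40))
  rownames(x) <- paste0("g", 1:80)
  tm <- tomSimilarity(adjacencyFromSimilarity(pearsonSimilarity(x), 6))
  lab <- detectModules(tm, minModuleSize = 30)
  expect_equal(sort(unique(lab)), c(1L, 2L))
  expect_equal(length(unique(lab[1:40])), 1L)
  expect_equal(length(unique(lab[41:80])), 1L)
  expect_false(lab[1] == lab[41])
})

test_that("uncorrelated genes all land in the grey module", {
  set.seed(8)
  x <- matrix(rnorm(60 * 50), 60, 50, dimnames = list(paste0("g", 1:60), NULL))
  tm <- tomSimilarity(adjacencyFromSimilarity(pearsonSimilarity(x), 6))
  lab <- detectModules(tm, minModuleSize = 30)
  expect_true(all(lab == 0L))
  # degenerate TOM is reported
  flat <- matrix(0.5, 10, 10, dimnames = list(paste0("g", 1:10), paste0("g", 1:10)))
  diag(flat) <- 1
  expect_message(detectModules(flat, minModuleSize = 2), "degenerate")
})

test_that("module detection recovers planted modules on synthetic cohorts", {
  skip_if_not_installed("mclust")
  hits <- vapply(1:8, function(i) {
    se <- simulateCohort(nSamples = 100, nGenes = 1000, seed = 7000 + i)
    truth <- S4Vectors::metadata(se)$truth
    z <- zscoreGenes(SummarizedExperiment::assay(se))
    tm <- tomSimilarity(adjacencyFromSimilarity(pearsonSimilarity(z), 6))
    lab <- detectModules(tm)
    planted <- truth$moduleAssignment[names(lab)]
    keep <- planted > 0
    mclust::adjustedRandIndex(planted[keep], lab[keep]) >= 0.8
  }, logical(1L))
  expect_gte(mean(hits), 7 / 8)
})

test_that("permuting gene order permutes all outputs consistently", {
  se <- small_cohort(seed = 9, nGenes = 200)
  z <- zscoreGenes(SummarizedExperiment::assay(se))
  perm <- sample(nrow(z))
  tm1 <- tomSimilarity(adjacencyFromSimilarity(pearsonSimilarity(z), 6))
  tm2 <- tomSimilarity(adjacencyFromSimilarity(pearsonSimilarity(z[perm, ]), 6))
  expect_equal(tm2, tm1[perm, perm])
  lab1 <- detectModules(tm1)
  lab2 <- detectModules(tm2)
  # same partition up to label names
  expect_equal(mpnet:::.adjustedRandIndex(lab1[rownames(z)[perm]], lab2), 1)
})

test_that("eigengenes follow the rank-1 and sign conventions", {
  # identical profiles: eigengene correlates 1 with every member
  set.seed(10)
  prof <- rnorm(40)
  x <- matrix(rep(prof, each = 5), 5, 40,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:40)))
  x <- x + matrix(rnorm(200, sd = 1e-6), 5, 40)
  ms <- moduleEigengenes(x, setNames(rep(1L, 5), rownames(x)))
  eg <- eigengenes(ms)[1, ]
  for (g in rownames(x)) expect_gt(abs(cor(eg, x[g, ])), 0.999)
  expect_gt(cor(eg, colMeans(t(scale(t(x))))), 0)
  expect_gt(varianceExplained(ms)[1], 0.999)
  # rank-1 module reproduces the generating factor at n >= 30
  f <- rnorm(60)
  y <- tcrossprod(runif(20, 0.4, 0.9), f) + matrix(rnorm(20 * 60, sd = 0.5), 20)
  dimnames(y) <- list(paste0("g", 1:20), paste0("s", 1:60))
  ms2 <- moduleEigengenes(y, setNames(rep(1L, 20), rownames(y)))
  expect_gt(abs(cor(eigengenes(ms2)[1, ], f)), 0.95)
  # sign convention holds across random modules
  for (i in 1:5) {
    r <- matrix(rnorm(10 * 30), 10, 30,
                dimnames = list(paste0("g", 1:10), NULL))
    msr <- moduleEigengenes(r, setNames(rep(1L, 10), rownames(r)))
    expect_gte(cor(eigengenes(msr)[1, ], colMeans(t(scale(t(r))))), 0)
  }
  # variance explained equals an independent spectral computation
  zy <- t(scale(t(y)))
  d <- svd(zy)$d
  expect_equal(unname(varianceExplained(ms2)[1]), d[1]^2 / sum(d^2),
               tolerance = 1e-10)
  # single-gene module warns and uses the gene profile
  expect_warning(ms3 <- moduleEigengenes(y, setNames(c(1L, rep(0L, 19)),
                                                     rownames(y))),
                 "single gene")
  expect_equal(abs(cor(eigengenes(ms3)[1, ], y[1, ])), 1, tolerance = 1e-10)
})

test_that("module-trait partial correlation matches a brute-force oracle", {
  se <- small_cohort(seed = 12)
  z <- zscoreGenes(SummarizedExperiment::assay(se))
  truth <- S4Vectors::metadata(se)$truth
  lab <- setNames(truth$moduleAssignment[rownames(z)], rownames(z))
  ms <- moduleEigengenes(z, lab)
  ph <- as.data.frame(SummarizedExperiment::colData(se))
  res <- moduleTraitCorrelation(ms, ph, traits = c("mmse", "braak"),
                                covariates = c("age", "sex", "pmi"))
  # independent residualize-then-correlate oracle via lm()
  sex01 <- ifelse(ph$sex == "male", 0, 1)
  for (tr in c("mmse", "braak")) {
    for (mi in rownames(eigengenes(ms))) {
      ry <- resid(lm(ph[[tr]] ~ ph$age + sex01 + ph$pmi))
      re <- resid(lm(eigengenes(ms)[mi, ] ~ ph$age + sex01 + ph$pmi))
      expect_equal(res$correlation[mi, tr], cor(re, ry), tolerance = 1e-10)
    }
  }
  # Bonferroni bookkeeping
  expect_equal(res$m, sum(!is.na(res$p)))
  expect_true(all(res$padj >= res$p, na.rm = TRUE))
  expect_true(all(res$padj <= 1, na.rm = TRUE))
  # trait identical to an eigengene: correlation 1 at the numerical floor
  ph$fake <- eigengenes(ms)[1, ]
  r2 <- moduleTraitCorrelation(ms, ph, traits = "fake", covariates = NULL)
  expect_equal(unname(r2$correlation[1, "fake"]), 1, tolerance = 1e-10)
  expect_lt(r2$p[1, "fake"], 1e-30)
  # trait equal to a covariate is collinear
  ph$agecopy <- ph$age
  expect_error(moduleTraitCorrelation(ms, ph, traits = "agecopy",
                                      covariates = c("age", "sex", "pmi")),
               "collinear")
  expect_error(moduleTraitCorrelation(ms, ph, traits = "age",
                                      covariates = "age"), "covariate")
})

test_that("gene significance and module membership behave as defined", {
  se <- small_cohort(seed = 13)
  z <- zscoreGenes(SummarizedExperiment::assay(se))
  truth <- S4Vectors::metadata(se)$truth
  ms <- moduleEigengenes(z, truth$moduleAssignment[rownames(z)])
  ph <- as.data.frame(SummarizedExperiment::colData(se))
  # a gene equal to the trait has GS = 1
  z2 <- rbind(z, trait_gene = as.numeric(scale(ph$mmse)))
  lab2 <- c(truth$moduleAssignment[rownames(z)], trait_gene = 0L)
  gs <- geneSignificance(z2, moduleEigengenes(z2, lab2), ph$mmse)
  expect_equal(gs$table$GS[gs$table$gene == "trait_gene"], 1,
               tolerance = 1e-10)
  # causal module shows stronger MM-GS coupling than a null module
  gs2 <- geneSignificance(z, ms, ph$mmse)
  causal <- truth$causalModule
  # labels in ModuleSet are renumbered by size: map by shared genes
  labs <- moduleLabels(ms)
  causalLabel <- unique(labs[names(truth$moduleAssignment)[
    truth$moduleAssignment == causal][1]])
  row <- gs2$summary[gs2$summary$module == causalLabel, ]
  expect_gt(row$corMMGS, 0)
  expect_lt(row$p, 0.05)
})
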