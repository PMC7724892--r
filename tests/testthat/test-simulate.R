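test_that("identical config and seed give bitwise-identical output", {
  a <- simulateCohort(nSamples = 20, nGenes = 100, seed = 7)
  b <- simulateCohort(nSamples = 20, nGenes = 100, seed = 7)
  expect_identical(SummarizedExperiment::assay(a),
                   SummarizedExperiment::assay(b))
  expect_identical(as.data.frame(SummarizedExperiment::colData(a)),
                   as.data.frame(SummarizedExperiment::colData(b)))
  c <- simulateCohort(nSamples = 20, nGenes = 100, seed = 8)
  expect_false(identical(SummarizedExperiment::assay(a),
                         SummarizedExperiment::assay(c)))
})

test_that("invalid configurations raise errors naming the field", {
  expect_error(simulateCohort(nSamples = 3), "nSamples")
  expect_error(simulateCohort(nGenes = 50, moduleSizes = c(30, 30)),
               "moduleSizes")
  expect_error(simulateCohort(moduleSizes = c(10, 1)), "moduleSizes")
  expect_error(simulateCohort(causalModule = 99), "causalModule")
  expect_error(simulateCohort(noiseSd = 0), "noiseSd")
})

test_that("cohort structure matches the declared truth", {
  se <- simulateCohort(nSamples = 30, nGenes = 500, seed = 3)
  truth <- S4Vectors::metadata(se)$truth
  expect_equal(dim(se), c(500L, 30L))
  expect_equal(sum(truth$moduleSizes), sum(truth$moduleAssignment > 0))
  # hub gene belongs to the causal module
  expect_equal(unname(truth$moduleAssignment[truth$hubGene]),
               truth$causalModule)
  # one factor column per module
  expect_equal(ncol(truth$factorValues), length(truth$moduleSizes))
  # reserve labels always satisfy the classification rule
  ph <- as.data.frame(SummarizedExperiment::colData(se))
  relab <- suppressMessages(classifyReserve(
    ph[, c("mmse", "braak")]))$reserve_label
  expect_identical(ph$reserve_label, relab)
  # severity bins satisfy the binning rule
  expect_identical(ph$diagnosis_group,
                   severityGroups(ph[, "mmse", drop = FALSE])$diagnosis_group)
  expect_true(all(ph$mmse >= 0 & ph$mmse <= 30))
  expect_true(all(ph$braak %in% 0:6))
  expect_true(all(ph$nft >= 0))
})

test_that("marginal gene variances and correlations match the model", {
  # single module of 4 genes with known loadings at large n
  se <- simulateCohort(nSamples = 5000, nGenes = 6, moduleSizes = 4L,
                       causalModule = 1, noiseSd = 0.5, seed = 11)
  truth <- S4Vectors::metadata(se)$truth
  x <- SummarizedExperiment::assay(se)
  lo <- truth$loadings
  # ordinary genes; the designated hub carries reduced residual noise and
  # is checked separately
  ordinary <- setdiff(names(lo)[truth$moduleAssignment == 1L],
                      truth$hubGene)
  for (g in ordinary) {
    expect_equal(stats::var(x[g, ]), lo[[g]]^2 + 0.25, tolerance = 0.05)
  }
  expect_equal(stats::var(x[truth$hubGene, ]),
               lo[[truth$hubGene]]^2 + 0.25 / 4, tolerance = 0.05)
  # same-module correlation: l_i l_j / sqrt((l_i^2+s2)(l_j^2+s2))
  gs <- ordinary
  for (i in 1:2) for (j in (i + 1):3) {
    expected <- lo[[gs[i]]] * lo[[gs[j]]] /
      sqrt((lo[[gs[i]]]^2 + 0.25) * (lo[[gs[j]]]^2 + 0.25))
    expect_equal(stats::cor(x[gs[i], ], x[gs[j], ]), expected,
                 tolerance = 0.05)
  }
  # unassigned genes uncorrelated with module genes
  noise <- names(lo)[truth$moduleAssignment == 0L]
  expect_lt(max(abs(stats::cor(t(x[noise, ]), t(x[gs, ])))), 0.05)
})

test_that("no planted effect means no eigengene-MMSE association", {
  hits <- vapply(1:40, function(i) {
    se <- simulateCohort(nSamples = 100, nGenes = 300, gammaMMSE = 0,
                         pathologyCoupling = 0, seed = 4000 + i)
    truth <- S4Vectors::metadata(se)$truth
    genes <- names(truth$moduleAssignment)[
      truth$moduleAssignment == truth$causalModule]
    z <- t(scale(t(SummarizedExperiment::assay(se)[genes, ])))
    v <- svd(z)$v[, 1L]
    abs(stats::cor(v, SummarizedExperiment::colData(se)$mmse)) < 0.4
  }, logical(1L))
  expect_gte(mean(hits), 0.95)
})

test_that("planted effect reproduces the oracle correlation interval", {
  # interval frozen from a 200-seed Monte Carlo of the generative
  # equations (direct simulation, independent of this implementation):
  # single-seed correlations in [0.47, 0.78], mean 0.67
  cors <- vapply(1:10, function(i) {
    se <- simulateCohort(nSamples = 100, gammaMMSE = 0.7, seed = 6000 + i)
    truth <- S4Vectors::metadata(se)$truth
    genes <- names(truth$moduleAssignment)[
      truth$moduleAssignment == truth$causalModule]
    z <- t(scale(t(SummarizedExperiment::assay(se)[genes, ])))
    sv <- svd(z)
    v <- sv$v[, 1L]
    if (stats::cor(v, colMeans(z)) < 0) v <- -v
    stats::cor(v, SummarizedExperiment::colData(se)$mmse)
  }, numeric(1L))
  expect_true(all(cors > 0.42 & cors < 0.82))
  expect_gt(mean(cors), 0.60)
  expect_lt(mean(cors), 0.73)
})

test_that("DAG data generator matches closed-form correlations", {
  # empty DAG: independence
  d0 <- simulateDAGData(NULL, nodes = c("A", "B", "C"), n = 5000, seed = 2)
  expect_lt(max(abs(stats::cor(d0)[upper.tri(diag(3))])), 0.05)
  # single arc, coefficient 2, unit noise: cor = 2/sqrt(5)
  d1 <- simulateDAGData(cbind("A", "B"), 2, noiseSd = 1, n = 5000, seed = 3)
  expect_equal(stats::cor(d1$A, d1$B), 2 / sqrt(5), tolerance = 0.02)
  # determinism
  expect_identical(d1, simulateDAGData(cbind("A", "B"), 2, noiseSd = 1,
                                       n = 5000, seed = 3))
  # cyclic input rejected
  expect_error(simulateDAGData(rbind(c("A", "B"), c("B", "A")), c(1, 1),
                               n = 10), "cyclic")
  expect_error(simulateDAGData(cbind("A", "B"), numeric(0), n = 10),
               "coefficient")
})
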