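# mpnet — module-to-phenotype networks for transcriptomic cohorts

`mpnet` links gene co-expression modules to clinical phenotypes through a
directed probabilistic network, for studies of cognitive reserve in
Alzheimer's disease (AD): given a brain expression matrix and per-sample
traits (MMSE, Braak stage, neurofibrillary-tangle counts, a reserve label),
it asks *which* expression module is directly tied to reserve and cognition
— conditioned on all other modules and traits, not just marginally
correlated — and *which* genes inside that module hold its network
together.

The pipeline, in the field's standard notation:

1. **Co-expression modules.** Genes are z-scored and (optionally)
   variance-filtered; Pearson similarity is soft-thresholded into an
   unsigned adjacency `a_ij = |cor_ij|^β` (β chosen by the signed
   scale-free fit R² ≥ 0.9, or fixed at the canonical 6) and converted to
   topological overlap `TOM_ij = (l_ij + a_ij) / (min(k_i,k_j) + 1 −
   a_ij)`. Average-linkage clustering of `1 − TOM` with a fixed-height cut
   yields modules; each is summarized by its eigengene (first principal
   component) and tested against traits by covariate-adjusted partial
   correlation (age, sex, PMI) with explicit Bonferroni families.
2. **Module-phenotype network (MPN).** A Gaussian-BIC Bayesian network is
   learned over the module eigengenes plus reserve, MMSE, Braak and NFT by
   hill climbing with 200 random restarts and model averaging (arcs kept
   at total frequency ≥ 0.5, majority direction). Modules are prioritized
   by Markov-blanket content: reserve in the blanket, reserve as a child,
   number of phenotypes in the blanket, MMSE as a child, then summed arc
   strength.
3. **Hub genes.** Inside the top module a gene-level averaged network is
   learned and reduced to its skeleton; genes are ranked by
   edge-percolated-component (EPC) centrality — the expected number of
   other genes still reachable when each edge survives independently with
   probability p = 0.5 — estimated by Monte Carlo and auditable against
   exact subset enumeration. The top six genes and their neighbor
   subnetwork are reported.
4. **Validation statistics.** Welch t / one-way ANOVA group contrasts with
   Bonferroni adjustment, the quartile-split MMSE-decline contrast, and
   projection of module eigengenes into external cohorts via the stored
   gene loadings.

A synthetic-cohort generator (`simulateCohort()`) plants known modules, a
causal module driving the phenotypes, and a designated hub gene, so every
stage is testable against ground truth without any data download.

## Worked example

```r
library(mpnet)

se  <- simulateCohort(nSamples = 100, seed = 42)   # planted 11-module cohort
cfg <- pipelineConfig(keepFraction = 1, power = 6, seed = 42)
res <- runPipeline(cfg, expression = se)

res$moduleSet
#> ModuleSet with 11 modules over 3000 genes
#>   sizes: 854, 600, 430, 310, 225, 165, 120, 90, 68, 50, 38
#>   unassigned (grey): 50 genes

round(res$moduleTrait$correlation["M11", ], 2)
#> diagnosis_group  reserve_label  mmse  braak   nft
#>           -0.65           0.32  0.71  -0.69 -0.66

head(res$priority, 3)
#>   module reserveInMB reserveChild nPhenoInMB mmseChild strengthSum rank
#> 1    M11       FALSE        FALSE          2     FALSE       2.150    1
#> 2     M6       FALSE        FALSE          2     FALSE       1.655    2
#> 3     M3       FALSE        FALSE          2     FALSE       0.970    3

res$hubs
#> [1] "G02912" "G02917" "G02915" "G02940" "G02947" "G02949"
S4Vectors::metadata(se)$truth$hubGene
#> [1] "G02912"

res$stats[, c("contrast", "statistic", "adjusted_p")]
#>   contrast statistic   adjusted_p
#> 1  reserve  3.140389 8.971253e-03
#> 2 severity 21.455204 2.038885e-10
```

The detected module M11 recovers the planted causal module exactly: its
eigengene correlates +0.71 with MMSE and −0.66 to −0.69 with the pathology
measures (maintaining cognition, tracking pathology inversely), it is
top-ranked in the MPN with two phenotypes in its Markov blanket, the
planted hub gene `G02912` heads the EPC ranking, and its eigengene
separates reserve from loss-reserve subjects (Welch t, adjusted p = 0.009)
and the four severity groups (ANOVA, adjusted p = 2e-10). With
`outDir` set in the config, all tables (TSV), networks (TSV + GraphML) and
a reproducibility manifest (JSON, with seeds and output digests) are
written to disk; identical config + seed reproduces every file byte for
byte.

A thin command-line wrapper is included at `inst/scripts/mpn`
(subcommands `simulate`, `preprocess`, `run-all`).

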