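# cortexMS

Expression-analysis pipeline for case-control microarray studies of the
multiple sclerosis motor cortex, built around five statistical stages:

1. **Random-variance moderated t-tests** for class comparison. Gene-wise
   inverse variances are modelled as Gamma(a, b); the pooled variance then
   satisfies `s² · a·b ~ F(d, 2a)` across genes, the shrunken variance is
   `σ̃² = (d·s² + 2aτ)/(d + 2a)` with `τ = 1/(ab)`, and the moderated
   statistic is referred to a t distribution with `d + 2a` degrees of
   freedom. Genes are called differentially expressed at `p < 0.01` and
   fold change ±1.5.
2. **Balanced-permutation FDR** with a stringency scan: arrays are split
   into two pseudo-groups each holding half of the cases and half of the
   controls; `FDR% = 100 · median(null DEG counts over 10 permutations) /
   experimental DEG count`, evaluated over a `p ∈ {0.05, 0.01} ×
   FC ∈ {1.5, 2}` grid with shared splits.
3. **Gene-set analysis** with the LS (`mean(−ln p)`) and KS
   (`max_i(i/k − p_(i))`) statistics under a random-set null, the
   Efron–Tibshirani maxmean statistic under a restandardized
   sample-permutation null, and a 2-of-3 consensus rule at α = 0.05.
4. **TNF pathway balance**: pro-death (RIPK1, RIPK3, MLKL, …, TNFR1)
   versus pro-survival (TNFR2, CASP8, …, XIAP) panel summaries, a balance
   index (difference of panel mean log2 fold changes), and heatmap row
   ordering by average-linkage clustering with the uncentered Pearson
   metric.
5. **qPCR verification**: delta-Ct quantification against GAPDH
   (`relative expression = 2^−ΔCt`), group fold changes on the Ct scale,
   and exact Mann–Whitney comparisons.

A synthetic-data generator (`simulateDataset()`) emulates the 5-group,
50-array design — 10 controls plus 10 follicle-positive and 10
follicle-negative SPMS cases, each contributing one grey-matter-lesion
(GML) and one normal-appearing-grey-matter (NAGM) array — with
gene-specific variances drawn from the hierarchical variance model,
configurable planted effects, and ground-truth tables, so the whole
pipeline is testable without any download. The intended audience is
analysts reproducing or stress-testing this class of microarray study
design, and method developers needing a calibrated reference
implementation of the random-variance / permutation-FDR / LS-KS-maxmean
stack.

## Worked example

```r
library(cortexMS)

# a 2000-gene dataset with the TNF death panel up-regulated (log2FC = 1)
# in F+ lesions plus 100 planted DEGs at |log2FC| = 1.2
p <- tnfPanels()
eff <- rbind(
  data.frame(gene = p$gene[p$panel == "death"], condition = "FPOS_GML",
             log2fc = 1),
  data.frame(gene = sprintf("G%05d", 1:100), condition = "FPOS_GML",
             log2fc = rep(c(1.2, -1.2), 50)))
sim <- simulateDataset(simulationConfig(nGenes = 2000, nDecoySets = 10,
                                        effects = eff), seed = 42)

spec  <- ComparisonSpec("FPOS_GML", "CTRL")   # p < 0.01, |FC| >= 1.5
stats <- rvmTTest(sim$se, spec)
attr(stats, "fit")
#> RvmFit: a = 3.465, b = 0.7406 (d = 18, moderated df = 24.93)
#>   logLik = -318.97 over 2000 genes; converged: TRUE

callDegs(stats)
#> DegSet FPOS_GML_vs_CTRL: 108 genes (55 up, 53 down)

permutationFdr(sim$se, spec, nPerm = 10, seed = 42)
#> StringencyCell (p < 0.01, |FC| >= 1.5): experimental = 108,
#> median null = 20, FDR% = 18.52

gsa <- geneSetAnalysis(sim$se, spec, sim$geneSets,
                       nNull = 2000, nPerm = 500, seed = 42)
head(gsa[order(gsa$maxmeanP), c("set", "k", "lsP", "ksP", "maxmeanP",
                                "consensus")], 3)
#>          set  k    lsP    ksP maxmeanP consensus
#> 1  TNF_DEATH 11 0.0005 0.0005    0.002      TRUE
#> 3  DECOY_001 20 0.6447 0.4283    0.637     FALSE
#> 10 DECOY_008 20 0.6347 0.5517    0.681     FALSE

computeBalance(stats)
#> BalanceReport [FPOS_GML_vs_CTRL]
#>   mean log2FC death = 0.877, survival = -0.032, index = 0.909
#>   verdict: death-shifted
```

Reading the output: the variance-model fit recovers hyperparameters close
to the generator's truth (a = 3, b = 1 — the fit here sees only 2000
genes); 108 of the 111 planted genes reach the study thresholds while the
balanced permutations put the empirical FDR of that call set at 18.5%;
the planted TNF death panel is the only consensus gene set (all three
tests significant, decoys flat); and the balance index of +0.91 log2
units classifies the F+ lesion profile as death-shifted, matching the
planted truth.

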