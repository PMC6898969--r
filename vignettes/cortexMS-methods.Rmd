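---
title: "Statistical methods behind cortexMS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Statistical methods behind cortexMS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cortexMS)
```

# The study design the package models

cortexMS analyses case-control microarray studies of the multiple
sclerosis motor cortex with a five-group structure: 10 non-neurological
control arrays, and 10 follicle-positive (F+) plus 10 follicle-negative
(F−) secondary progressive MS cases, each case contributing one grey
matter lesion (GML) and one normal-appearing grey matter (NAGM) array —
50 arrays in total. The group vocabulary is fixed (`msGroups()`), the
expression input is an already normalised log2 intensity matrix, and
every comparison is one MS condition versus the controls.

Row identifiers are treated as opaque: whether they are probe-level or
gene-collapsed makes no difference to any statistic here, so the package
never attempts annotation.

# The random-variance moderated t-test

Per-gene two-sample t-tests at n = 10 per group are noisy because each
gene's variance is estimated from 18 residual degrees of freedom. The
random-variance model shares variance information across genes: the
gene-specific inverse variances are assumed gamma-distributed with shape
$a$ and scale $b$. Under this prior the observed pooled variance obeys

$$ s_g^2 \, a b \sim F(d,\, 2a), $$

with $d = n_A + n_B - 2$, and the posterior-mean precision yields the
shrunken variance

$$ \tilde\sigma_g^2 = \frac{d\, s_g^2 + 2a\tau}{d + 2a},
   \qquad \tau = \frac{1}{ab}, $$

so the moderated statistic
$t_g = (\bar x_{gA} - \bar x_{gB}) / \sqrt{\tilde\sigma_g^2 (1/n_A + 1/n_B)}$
is referred to a t distribution with $d + 2a$ degrees of freedom.
`fitRVM()` estimates $(a, b)$ by maximising the F-distribution
likelihood over all genes (Nelder–Mead on the log scale, relative
tolerance 1e-12, start $a_0 = 2$, $b_0 = 1/\bar s^2$).

The contract we verify by simulation, rather than by appeal to any
particular derivation, is calibration: on model-generated null data the
moderated p-values at $\alpha = 0.01$ must land inside the 99% binomial
band, and $(a, b) = (3, 1)$ must be recovered from 20000 genes. Both
checks run in the test suite at those sizes.

Numerical edge cases: zero variances are floored at the 1st percentile
of the positive variances before fitting (keeps the log-likelihood
finite; configurable by pre-filtering). A degenerate variance
distribution (all values equal) drives $a \to \infty$; this errors by
default, or returns a capped fit ($a = 10^6$, prior mean variance equal
to the common value) with `cap = TRUE`. In the capped limit the
moderated statistic equals the pooled t statistic exactly and its
reference distribution approaches the normal, so agreement with the
pooled t-test's p-values is asymptotic in $d$.

Fold changes use the microarray sign convention: `fc = 2^log2fc` for
up-regulation and `-2^(-log2fc)` for down-regulation, with the
significance rule `p < 0.01` and `|fc| >= 1.5` applied to the magnitude.
The fold-change estimator is the difference of group means of log2
values (a geometric mean ratio); whether published fold changes are
means or medians of per-sample ratios is generally unstated, so this is
a documented convention, not an inference. Comparisons are unpaired;
the case pairing between a donor's GML and NAGM arrays is carried in
the sample sheet but deliberately unused by the tests, matching the
class-comparison design. No gene-level multiplicity adjustment is
applied — error control is delegated to the permutation FDR below.

# Balanced-permutation FDR and the stringency scan

`permutationFdr()` estimates the false discovery rate of a threshold
pair empirically: the arrays of the two compared groups are split into
two pseudo-groups, each containing exactly half of the cases and half
of the controls, so genuine group differences cancel and the DEG count
of the pseudo-comparison estimates the null count. With the default
`nPerm = 10` distinct balanced splits,

$$ \mathrm{FDR\%} = 100 \cdot
   \frac{\mathrm{median}(\text{null counts})}{\text{experimental count}}. $$

Distinctness of splits is enforced by rejection sampling; the variance
model is refitted inside every permutation by default (an honest null;
`refit = FALSE` freezes the observed fit for comparison). Odd group
sizes error by default — the 10+10 design never produces them — with an
opt-in policy that assigns the extra sample to alternating sides per
permutation. A zero experimental count yields `FDR% = NA` with a
warning rather than a division by zero.

`stringencyScan()` evaluates a grid of conditions (default
$p \in \{0.05, 0.01\} \times \mathrm{FC} \in \{1.5, 2\}$) while sharing
the same splits across cells, so the scan varies thresholds, not
labelings, and null counts are monotone in stringency within each
permutation. `pooledFdr()` additionally pools cells across the four
condition-vs-control comparisons as the ratio of summed medians to
summed experimental counts, since a single study-wide figure can be
defined either per comparison or pooled; both are available.

# Gene-set testing and the 2-of-3 consensus

Three set-level tests are computed per gene set:

* **LS**: mean of $-\ln p$ over member genes. The natural log is used;
  any base is monotone-equivalent under the permutation null, so the
  choice only fixes the reported statistic's scale.
* **KS**: with sorted member p-values $p_{(1)} \le \dots \le p_{(k)}$,
  $\max_i (i/k - p_{(i)})$ — the maximal departure of the set's
  p-values below the uniform line.
* **maxmean**: the larger of the mean positive part and mean negative
  part of the member genes' moderated t scores, detecting coordinated
  one-sided shifts and reporting the attaining side as the direction.

LS and KS are referred to a random-set null: `nNull` sets of matched
size drawn uniformly without replacement from all genes. maxmean is
referred to a sample-label permutation null (uniform over assignments
preserving group sizes) with restandardization: the per-gene scores of
the observed data and of each permutation are centered and scaled by
their own across-gene mean and SD before the set score is taken, which
protects against genome-wide shifts. Whether the original tooling's
LS/KS null permutes labels or samples gene sets is ambiguous; the
random-set null is adopted here as a documented semantic choice, and
the test suite verifies its calibration (decoy-set empirical p-values
uniform by a KS check over 500 replicates).

All empirical p-values use the add-one rule
$p = (1 + \#\{\text{null} \ge \text{obs}\})/(n + 1)$, so zero never
occurs and the attainable minimum is $1/(n+1)$. Inside the maxmean
permutation loop the variance-model hyperparameters are frozen at the
observed fit: the fit is label-invariant to first order and refitting
inside each of ~1000 permutations would dominate the runtime without
changing the null in any way our calibration checks can detect.

A set is a consensus hit when at least 2 of the 3 p-values fall
strictly below $\alpha = 0.05$. Strict inequality mirrors the
gene-level "p < 0.01" convention; values exactly at the threshold do
not count. Sets with fewer than `minSetSize = 3` resolved members are
skipped and reported, not failed; unresolvable members are counted and
logged, never silently dropped.

# TNF pathway balance

The TNF signalling dichotomy contrasts a pro-death panel (RIPK1, RIPK3,
MLKL, RNF11, CYLD, LOX, HSP70, TNFAIP3, CASP3, CASP7, TNFR1 — the
necroptotic/apoptotic arm) with a pro-survival panel (TNFR2, CASP8,
TRADD, FADD, CFLAR, IKK-B, NFKB, RELA, AKT, XIAP — the NF-kB survival
arm). The symbols are informal pathway names kept in a user-editable
mapping file (`inst/extdata/tnf_panels.tsv`); the package does not
guess official identifiers for ambiguous ones (HSP70, AKT, NFKB,
IKK-B, LOX, TNFR1/2).

`computeBalance()` summarises a comparison by
$\text{index} = \overline{\log_2\mathrm{FC}}_{\text{death}} -
\overline{\log_2\mathrm{FC}}_{\text{survival}}$, with equal gene
weights and a verdict dead-band of $\delta = 0.2$ log2 units
(death-shifted / survival-shifted / balanced). The index is a
descriptive formalisation of a heatmap dichotomy — an artifact
construct, not a significance test — and is antisymmetric under panel
swap by construction. `panelHeatmapOrder()` orders panel genes for
display by the within-panel dendrogram leaf order, death panel first.

Clustering uses the uncentered Pearson distance
$1 - \sum x_i y_i / \sqrt{\sum x_i^2 \sum y_i^2}$ with unweighted
average linkage, the classic expression-heatmap combination. The
agglomeration is implemented directly because the required metric and
the deterministic tie-break (lowest-index pair first) are part of the
contract; it is validated against an $O(n^3)$ brute-force oracle that
recomputes every pairwise mean distance at every merge, and against
`stats::hclust` heights on tie-free fixtures. Average linkage is
reducible, so heights never invert. The implementation updates a full
distance matrix per merge and is intended for the hundreds-to-low-
thousands of rows of a significant-transcript heatmap, not for
whole-genome clustering.

# qPCR quantification

Relative expression against the GAPDH reference uses the factor-2 rule:
$\Delta C_t = C_t^{\text{target}} - C_t^{\text{ref}}$ and relative
expression $2^{-\Delta C_t}$, with PCR efficiency fixed at perfect
doubling. Group fold changes default to the $\Delta C_t$-of-means
convention $2^{-(\overline{\Delta C_t}_A - \overline{\Delta C_t}_B)}$
(a geometric mean of per-sample ratios, consistent with working on the
cycle scale); the arithmetic ratio-of-means alternative is available
behind a flag since published fold values rarely state which was used.
Group comparisons use the Mann–Whitney test via `stats::wilcox.test`:
exact two-sided p for combined n ≤ 20 without ties, normal
approximation with tie correction otherwise; the exact path is verified
against full enumeration of group assignments in the tests.

# The synthetic-data generator

`simulateDataset()` is the package's test surface. For gene $g$ and
sample $s$:

$$ x_{gs} = \mu_g + \beta_{g,\text{group}(s)} + c_{g,\text{case}(s)}
            + \varepsilon_{gs}, \qquad
   \varepsilon_{gs} \sim N(0, \sigma_g^2), $$

with $\mu_g \sim N(8, 1)$ on the log2 scale (the typical microarray
intensity range), $\sigma_g^2$ drawn from the hierarchical variance
model with $(a, b) = (3, 1)$ — mean precision 3, mean variance 0.5 —
planted effects $\beta$ from a user table, and a case-level random
effect with SD 0.2 shared between a case's GML and NAGM arrays. The
case effect is drawn per gene and case rather than as one scalar per
case: the stated purpose (correlating a donor's two arrays) is
preserved, while a scalar array-level effect would correlate all genes
within an array and make genome-wide rejection counts substantially
over-dispersed relative to the binomial calibration the generator is
required to satisfy.

The generator names its first 21 genes after the TNF panels so that
panel analyses resolve out of the box, builds a gene-set collection
containing the two panels plus decoy sets sampled uniformly from
non-planted genes (a calibrated null for the set tests), and returns a
ground-truth table that mirrors the planted effects exactly. Identical
configuration and seed give identical output.

What the generator does **not** emulate: probe-level intensity
structure, chip or batch artefacts, intensity-dependent variance
(variance is independent of $\mu_g$ here), correlated gene blocks
beyond the planted sets, and annotation ambiguity. Passing tests
therefore demonstrate that the statistical machinery is correct and
calibrated under its own model assumptions — not that any biological
conclusion from a particular real dataset is reproduced. Real-data
effect-size distributions are unknown; the defaults used in tests
(|log2FC| between 0.58 and 2) are configuration, not claims.

The qPCR generator produces Ct values as
$C_t = \text{baseline} - \log_2(\text{expression}) + \text{noise}$,
with a per-sample loading factor affecting target and reference equally
(it cancels in $\Delta C_t$), measurement noise of 0.3 cycles, and
group ratios from a truth table, so the quantification round-trips.

# Problem sizes and runtime choices

The test suite exercises the pipeline at the design scale where the
property is about the design (8000 genes × 50 arrays for calibration
and FDR; 20000 genes for hyperparameter recovery; 20 seeds for FDR
replication) and at reduced sizes where the property is scale-free
(1000–2000 genes and 100–200 permutations for gene-set power and
calibration; 50 seeds for maxmean power). These sizes were chosen so
the whole suite completes in a few minutes on a single CPU while every
band and threshold retains its stated statistical meaning. The
permutation defaults exposed to users (`nPerm = 10` for FDR, 1000 for
maxmean, 10000 random sets for LS/KS) are the analysis-scale defaults.

# Known limitations

* The LS/KS random-set null is one of two defensible readings of the
  original tooling; switching to a label-permutation null would change
  set p-values on correlated data.
* The balance index weights genes equally and ignores significance; it
  is a display-level summary.
* The clustering implementation is quadratic in memory and cubic in
  time in the worst case; it is not meant for >10k rows.
* The generator's independence assumptions make permutation nulls
  behave slightly better than they would on strongly co-expressed real
  data; FDR% estimates on real arrays are correspondingly noisier.
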