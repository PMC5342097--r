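---
title: "Methods: paired multi-omics analysis and the stoichiometric influence model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: paired multi-omics analysis and the stoichiometric influence model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stoichmir)
options(stoichmir.verbose = FALSE)
```

## The problem

Case-control omics screens with small cohorts and large feature sets are
dominated by the "small n, big p" regime: thousands of features are tested
on a handful of patients, and single-layer hit lists carry many false
positives. Two design ideas mitigate this. First, a *paired* design — one
tumor and one matched normal biopsy per patient — removes inter-individual
baselines, so statistics operate on within-patient differences. Second,
*integration across layers*: a miRNA screen, a transcriptome and a proteome
measured on the very same tissue samples constrain each other, because
miRNAs repress their target mRNAs and mRNA abundance partly drives protein
abundance. `stoichmir` implements this pipeline end to end for a cohort of
matched tumor/control pairs (18 by default, mirroring a typical paired
lung-cancer study design).

## Paired differential statistics

Each layer is quantile normalized separately (`quantile_normalize()`;
every sample's distribution is forced to the across-sample mean of sorted
columns, ties receiving the mean of the quantiles they span). All tests in
`test_differential()` run on `log2(x + 1)`:

* paired t-test on per-patient log2 differences; effect size reported as
  $t/\sqrt{n}$ with $n$ the number of pairs;
* two-sample Wilcoxon–Mann–Whitney with a tie-corrected normal
  approximation (the test is deliberately the *two-sample* rank-sum test,
  kept as a robustness check against the t-test rather than as a paired
  test);
* AUC, the probability that a random tumor value exceeds a random control
  value (ties count 1/2), algebraically equal to $U/(n_1 n_2)$;
* Shapiro–Wilk on the paired differences, to gauge how reasonable the
  parametric test is per feature.

Raw t-test p-values are adjusted by both Benjamini–Hochberg and
Bonferroni. Direction is the sign of the mean paired log2 fold change; AUC
is retained as a secondary direction measure (AUC $> 0.5 \iff$ up).

Numerical choices: intensities are nonnegative, so a pseudocount of 1
stabilizes the log transform near zero. Zero-variance difference vectors
leave the t-statistic undefined; such features are flagged and given
$p = 1$ rather than dropped, keeping feature counts stable across layers.
Fewer than three pairs is an error.

## Genomic proximity scan

`linearize()` concatenates chromosomes 1..22, X, Y (about $3\times10^9$
bases with the bundled lengths) and places each feature at its interval
midpoint. `scan_windows()` slides a 1-Mb window along this axis — the step
defaults to 500 kb, and setting `step = window_size` gives non-overlapping
tiling — counting significant features (adjusted $p < 0.05$; Bonferroni by
default, consistent with the pipeline's headline significance calls) per
omics kind in each half-open window. `select_regions()` keeps windows with
at least one significant miRNA, mRNA *and* protein and more than ten
significant features in total, merges overlapping or adjacent qualifying
windows, and splits merged spans at chromosome boundaries (a region that
straddles two chromosomes is biologically meaningless even though the
linearized axis is continuous); each piece must still meet both criteria
on its own. `manhattan_table()` emits the plot-ready
$-\log_{10}(p_\text{adj})$ table, clamping $p = 0$ to the smallest
positive double.

## Ab-initio correlation network

`correlation_edges()` computes Pearson correlations between every
unordered pair of features across all pooled samples on the log2 scale,
with $p$ from the $t$ transform with $n - 2$ degrees of freedom, evaluated
blockwise so the full pairs matrix (nearly $10^9$ pairs at genome scale)
is never materialized. The default per-test threshold is the Bonferroni
family alpha `family_alpha(n)` $= \alpha / \binom{n}{2}$ over the features
actually tested — constant features are excluded first, since their
correlation is undefined. At the scale of a full tri-omics screen
(43,419 features) this threshold is $\approx 5\times10^{-11}$.
`pair_type_summary()` contrasts the observed mix of edge types
(miRNA–mRNA, mRNA–protein, ...) with the combinatorial expectation
$n_A n_B / \binom{N}{2}$.

## The stoichiometric influence model

The core algorithm models the *joint* influence of all miRNAs on each
target gene through a bipartite miRNA–gene graph built from a curated
interaction table (a miRTarBase-style input; either all interactions or
only the functionally validated subset). The key idea is stoichiometric
competition: a miRNA's influence on one target is diluted by the abundance
of its competing targets. For miRNA $m_i$ with target set of size $l$,

$$w_{ij} = \frac{e(g_j)}{\sum_{k=1}^{l} e(g_k)}$$

where $e(\cdot)$ is mean expression over *control* samples on the linear
scale. Weights are shares, so $\sum_j w_{ij} = 1$ per miRNA. The joint
influence on gene $g_j$ targeted by $z$ miRNAs is

$$s(g_j) = \sum_{k=1}^{z} w_{kj}\, e(m_k).$$

With weights fixed from controls, $s$ is evaluated with control miRNA
means ($s^N$) and cancer miRNA means ($s^C$). A gene whose joint influence
*rises* in cancer ($s^C - s^N > 0$) is predicted *down*, and vice versa.
`evaluate_by_degree()` scores these calls against the measured directions
of significantly deregulated genes, stratified by minimum degree $z$, with
a one-sided exact binomial p-value against chance (0.5).

Model-facing choices:

* Expression enters on the **linear** scale: the weights are abundance
  shares, and a log transform would destroy the stoichiometric reading.
  Condition summaries are arithmetic means.
* If all of a miRNA's targets have zero control mean, weights fall back to
  uniform $1/l$ with a warning.
* $\Delta s = 0$ yields `no_call`, excluded from accuracy denominators
  (exact zeros arise only in degenerate inputs).
* Degree $z$ is counted after filtering to measured features and the
  chosen support level — unmeasured miRNAs cannot contribute to $s$.
* The evaluation set defaults to Bonferroni-adjusted $p < 0.05$,
  matching the pipeline's headline significance accounting; BH and raw
  thresholds are selectable.
* The binomial p-value is exact and one-sided; 12 correct calls out of 13
  give $p \approx 0.0017$.

## Gene–protein concordance

`build_concordance_pairs()` expands a protein-to-gene mapping into pairs
where both members have raw t-test $p < 0.05$, and
`concordance_stats()` reports the Pearson correlation of gene vs protein
AUC values plus the percentage of pairs deregulated in the same direction
(both AUCs on the same side of 0.5). An AUC of exactly 0.5 carries no
direction and leaves the concordance denominator.

## The synthetic cohort generator

Real multi-omics matrices of this kind are rarely redistributable, so the
generator (`sim_config()` / `generate_cohort()`) produces paired cohorts
that are statistically shaped like the study and carry full ground truth.
Defaults: 18 patients; 100 miRNAs, 800 genes, 300 proteins (a scaled-down
screen, keeping test runtimes in seconds); mean 4 targets per miRNA
(shifted Poisson); 20% of miRNAs intrinsically deregulated with a
1 log2-unit shift, signs drawn 50/50 since no prior direction is assumed.

Log-abundance of each measurement is
$\mu_f + \beta_p + \delta_f \cdot 1[\text{tumor}] + \varepsilon$, with a
shared patient baseline $\beta_p \sim N(0, 0.3^2)$ and feature noise
$\varepsilon \sim N(0, 0.3^2)$ (natural-log scale); abundances are
$\exp(\cdot)$, hence strictly positive. Baselines are
$\mu \sim N(\log 200, 1)$ for miRNAs and $N(\log 500, 1)$ for genes —
arbitrary but realistic intensity scales. Genes targeted in the network
carry no intrinsic shift; instead their tumor abundance responds to the
miRNA layer through the influence model itself, computed from the true
noise-free condition means: the multiplier is
$\exp(-\kappa\,(s^C - s^N)/\max(s^N, 10^{-6}))$. The relative (rather
than absolute) influence change keeps genes with near-zero baseline
influence from blowing up, and the floor $10^{-6}$ guards the division;
the model in the analysis direction is descriptive, so this generative
inversion is the package's own construction. Proteins copy their mapped
gene's log-abundance plus a protein-specific offset and noise
(default SD 0.5, reflecting the notoriously weak mRNA–protein coupling).
Coordinates tile the chromosomes evenly (~2.7 Mb spacing at default
sizes); an opt-in hotspot packs deregulated features of all three layers
into the central 40% of one 1-Mb window — the packing guarantees that a
sliding window of that size covers all of them, so planted-region
recovery is deterministic.

What the generator does *not* emulate: microarray probe effects,
mass-spectrometry missingness, batch effects, correlated co-regulation
beyond the miRNA coupling, or realistic gene-length/GC structure in the
coordinates. Passing tests therefore demonstrate correctness of the
computations and recoverability under the stated generative model, not
performance on real tissue data.

## Validation strategy and problem sizes

The test suite checks every statistic against an independent oracle:
hand-computed worked examples (paired t on differences (1,2,3,4); the
two-miRNA/two-gene influence toy; the 13-gene high-degree evaluation
giving 92.3%), brute-force re-implementations (BH step-up, naive window
recounts on 100 random layouts, all-pairs `cor.test` at 300 features, AUC
vs the rank-sum identity on 1,000 splits), and Monte-Carlo calibration
(null cohorts of 2,000 features give a raw paired-t rejection rate within
three binomial standard errors of 5%). Parameter recovery uses cohorts at
the default scale with strong coupling ($\kappa = 5$, feature noise 0.1):
direction accuracy at minimum degree 1 exceeds 90%, and mean accuracy is
non-decreasing across $\kappa \in \{0, 1, 5\}$, with an empty evaluation
set (at $\kappa = 0$ nothing is truly deregulated) scored at the 50%
chance baseline. The recovery analyses feed the generator's matrices to
the model without quantile normalization: simulated layers are already
distribution-matched across samples, and forcing identical distributions
when a large fraction of genes genuinely shifts would distort the very
signal being recovered — on real data, where sample distributions differ
for technical reasons, normalization remains the default first step.

## Known limitations

* The influence model is linear and static: no binding-site kinetics, no
  transcription-factor co-regulation, no epigenetics. Accuracy is expected
  to improve with target degree, as the joint score then averages over
  more regulators.
* The WMW test is two-sample by construction here; on a paired design a
  signed-rank test would be the more powerful nonparametric choice.
* Window-scan results depend on the chosen step; the default 500-kb
  sliding step reports each locus in up to two windows, which the region
  merge step collapses.
* Bonferroni control across ~$10^9$ correlation tests is extremely
  conservative; the package reports the threshold actually used and the
  number of tested pairs so users can substitute FDR-based control.
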