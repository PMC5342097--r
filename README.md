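# stoichmir

Integrative analysis of **paired tumor/control multi-omics cohorts** —
miRNA, mRNA and protein abundances measured on the same tissue biopsies —
for researchers studying post-transcriptional regulation in cancer. The
package covers the whole path from raw abundance tables to an annotated
regulatory network: per-layer paired differential statistics, a
genomic-proximity window scan, an ab-initio all-pairs correlation network,
gene–protein concordance, and its centerpiece, a **stoichiometric model of
the joint influence of miRNAs on their target genes**.

## The model

Most miRNAs regulate many "competing" target genes, and most genes are
regulated by several miRNAs. On a bipartite miRNA–gene graph built from
curated interactions, the influence of miRNA $m_i$ on target $g_j$ is the
share of that gene in the total expression of the miRNA's $l$ targets,

$$w_{ij} = \frac{e(g_j)}{\sum_{k=1}^{l} e(g_k)},$$

with $e(\cdot)$ the mean control-sample expression (linear scale). The
joint influence on a gene targeted by $z$ miRNAs is

$$s(g_j) = \sum_{k=1}^{z} w_{kj}\,e(m_k).$$

Weights are inferred once from control samples; evaluating $s$ with
control and with cancer miRNA abundances gives $s^N$ and $s^C$. A gene
whose joint influence rises in cancer ($s^C - s^N > 0$) is predicted to be
**down**-regulated there, and vice versa. Predictions are scored against
measured directions of significantly deregulated genes, stratified by
degree $z$, with exact binomial p-values.

Around the model, the package provides quantile normalization, paired
t / Wilcoxon–Mann–Whitney / AUC statistics with BH and Bonferroni
adjustment, PCA and hierarchical clustering, a 1-Mb sliding-window scan
over linearized chromosomes for regions co-enriched in significant
features of all three layers, a blockwise Pearson correlation network
under family-wise error control, and a synthetic paired-cohort generator
with known ground truth (see the methods vignette in `vignettes/`).

## Worked example

Simulate a cohort of 18 matched pairs in which 20% of miRNAs are
deregulated and target genes respond through the influence model
(coupling strength 5), then recover the gene directions:

```r
library(stoichmir)
cfg <- sim_config(coupling_strength = 5, feature_noise_sd = 0.1,
                  fraction_deregulated = c(miRNA = 0.2, mRNA = 0,
                                           protein = 0),
                  seed = 11)
cohort <- generate_cohort(cfg)

res <- test_differential(cohort$layers$mRNA, cohort$design)
ctl <- cohort$design$sample_id[cohort$design$condition == "control"]
tum <- cohort$design$sample_id[cohort$design$condition == "tumor"]
net <- filter_network(cohort$network, "all",
                      rownames(cohort$layers$miRNA),
                      rownames(cohort$layers$mRNA))
w <- compute_edge_weights(net, rowMeans(cohort$layers$mRNA[, ctl]))
scores <- predict_directions(joint_influence_scores(
  w, rowMeans(cohort$layers$miRNA[, ctl]),
  rowMeans(cohort$layers$miRNA[, tum])))
head(scores, 3)
#>     gene_id degree s_control  s_cancer      delta predicted_direction
#> 1 gene00001      1 185.40250 186.54603   1.143526                down
#> 2 gene00004      1 124.81129 128.06929   3.258005                down
#> 3 gene00006      2  53.84042  35.10387 -18.736544                  up

evaluate_by_degree(scores, res, min_degrees = 1:3)
#>   min_degree n_evaluated n_correct accuracy_pct      p_value
#> 1          1          65        65          100 2.710505e-20
#> 2          2          23        23          100 1.192093e-07
#> 3          3           2         2          100 2.500000e-01
```

Of the 65 genes significantly deregulated after Bonferroni adjustment, the
model calls every direction correctly under this strong, low-noise
coupling; the `delta` column is the change in joint influence whose sign
drives each call (positive ⇒ stronger repression in tumor ⇒ "down").
On real data, accuracy rises with the number of targeting miRNAs, since
the joint score then averages over more regulators.

A command-line front end over the same functions is included:

```sh
Rscript inst/scripts/stoichmir-cli.R run-all --seed 4 --out results/
```

with subcommands `simulate`, `normalize`, `diff`, `scan`, `corrnet`,
`influence`, `concordance` and `run-all` (inputs as TSV/BED, networks
exported as SIF and GraphML for Cytoscape).

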