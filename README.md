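# comorbidome

Transcriptomic, network, and pharmacological comorbidity analysis between
disease pairs — built for the question of why neurodegenerative disorders
(Alzheimer's and Parkinson's disease) show *inverse* comorbidity with many
site-specific cancers (reduced cancer risk) and *direct* comorbidity with a
few others. The package quantifies such relationships at the molecular level
from case/control expression cohorts, disease-gene lists, an interactome, and
drug perturbation signatures, and ships a synthetic-data module that plants
every ground truth so the whole pipeline is testable without any downloads.

It is written tidyverse-style: functions take data frames (or lists of typed
objects) and return tibbles, results have `tidy()` / `glance()` /
`autoplot()` methods, and everything chains with the pipe.

## What it computes

**Random-effects differential-expression meta-analysis.** Per study, each
gene's case/control difference is summarized as Hedges' g,

    d = J * (m_case - m_control) / s_pooled,    J = 1 - 3 / (4(n1 + n2) - 9),
    var(d) = (n1 + n2) / (n1 * n2) + d^2 / (2(n1 + n2)),

and the k study effects are combined with the DerSimonian–Laird estimator:
fixed weights `w_i = 1/var_i` give Cochran's `Q`; the between-study variance
is `tau^2 = max(0, (Q - (k-1)) / (sum(w) - sum(w^2)/sum(w)))`; random-effect
weights `1/(var_i + tau^2)` yield the combined effect `mu_hat`, its standard
error, `z = mu_hat/se`, a two-sided normal p, and BH-adjusted q per gene.
Study-level QC (leave-one-out discordance scores) and sample-level outlier
removal (correlation/MAD) are included.

**Four-quadrant comorbidity classification.** For two disease signatures the
genes at the four intersections of up/down-regulated sets are counted over
the shared universe and tested with one-sided Fisher (upper-tail
hypergeometric) tests. After FDR adjustment, a pair is labeled **SDDC**
(same-direction deregulated: up/up and down/down both significant), **ODDC**
(opposite-direction: up/down and down/up both significant), mixed, or none;
the Pearson correlation of the full `mu_hat` profiles accompanies the label.

**Enrichment.** Overrepresentation analysis (hypergeometric, BH), module
overlap tests, and preranked GSEA on the meta-analytic z-scores with the
weighted running-sum enrichment score, gene-label permutations, sign-matched
NES normalization, and +1-smoothed permutation p-values.

**Interactome disease-module statistics.** Localization of a gene set as the
largest connected induced subgraph `S` and the mean nearest-member distance
`d_aa`; pairwise separation `s_AB = d_AB - (d_AA + d_BB)/2` (negative values
indicate overlapping modules); significance from degree-preserving null
models (log2 degree bins, sampling without replacement).

**Drug-signature matching.** Replicate perturbation profiles are combined
into a MODZ-style consensus (weights from inter-replicate Spearman
correlation, floored and normalized) and matched against disease `mu_hat`
profiles by Spearman correlation; `rho < -0.2` flags a *reversal* candidate
(the drug pushes expression against the disease), `rho > 0.2` a *mimic*.

## Worked example

Simulate a disease pair planted with opposite-direction deregulation (60% of
the first disease's 100 up- and 100 down-regulated genes flipped in the
second), meta-analyze both cohorts, and classify the pair:

```r
library(comorbidome)

cfg_a <- cohort_config(n_studies = 6, n_cases = 20, n_controls = 20,
                       n_genes = 2000, n_up = 100, n_down = 100,
                       effect_mu = 1.5, tau = 0.1, seed = 1)
cfg_b <- cohort_config(n_studies = 6, n_cases = 20, n_controls = 20,
                       n_genes = 2000, n_up = 100, n_down = 100,
                       effect_mu = 1.5, tau = 0.1, seed = 2)
pair <- sim_disease_pair(pair_config(cfg_a, cfg_b, shared_fraction = 0.6,
                                     direction = "opposite"))

ndg    <- meta_analyze(pair$studies_a, disease_id = "NDG")
cancer <- meta_analyze(pair$studies_b, disease_id = "CANCER")
glance(ndg)
#>   disease n_studies n_genes n_analyzed  n_up n_down mean_Q mean_tau alpha
#> 1 NDG             6    2000       2000   100    102   4.96   0.0937  0.05

compare_all(list(NDG = ndg$signature), list(CANCER = cancer$signature)) |>
  dplyr::select(ndg, cancer, label, n_uu, n_dd, n_ud, n_du, q_ud, q_du, r)
#>   ndg   cancer label  n_uu  n_dd  n_ud  n_du     q_ud     q_du      r
#> 1 NDG   CANCER ODDC      0     0    60    60 3.34e-59 4.03e-59 -0.563
```

Reading the output: the meta-analysis recovers the planted signature (100 up,
102 down at q < 0.05; `mean_Q` near k − 1 = 5 and `mean_tau` near the planted
0.1 confirm the heterogeneity calibration). The pair lands exactly 60 genes
in each cross quadrant and none in the same-direction quadrants, both cross
tests are overwhelmingly significant, so the pair is labeled ODDC with a
negative profile correlation — the transcriptomic fingerprint of inverse
comorbidity.

`autoplot(ndg)` draws the volcano plot, `autoplot()` of the `compare_all()`
result the quadrant heatmap, and `run_pipeline(demo_run_config(seed = 1),
"out")` executes the full simulate → meta → compare → enrich → network →
drugs chain deterministically, writing flat TSV/JSON outputs and a run
report.

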