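---
title: "Methods: models, defaults, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, defaults, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette records how each statistic in `comorbidome` is defined, which
defaults were chosen where the methodological literature leaves room, and
what the synthetic-data generator does and does not emulate. It states no
empirical result that the test suite and `scripts/acceptance.R` do not
themselves compute.

## The meta-analytic model

Each study contributes, per gene, a standardized mean difference between
cases and controls. We use Hedges' g with the common approximate small-sample
correction $J = 1 - 3/(4(n_1+n_2)-9)$ and the standard large-sample variance
$\mathrm{var}(d) = \tfrac{n_1+n_2}{n_1 n_2} + \tfrac{d^2}{2(n_1+n_2)}$.
Positive $d$ means higher expression in cases — "upregulated in disease"
throughout the package. The exact gamma-function correction differs from $J$
only in the third decimal at the sample sizes involved; the test suite
cross-checks our estimator against `metafor`'s exact-corrected one at a
correspondingly loose tolerance, and against a literal evaluation of the
formulas at $10^{-12}$.

Study effects are combined per gene with the DerSimonian–Laird moment
estimator. Two conventions worth stating explicitly:

* $\hat\tau^2$ is truncated at zero (the DL convention). Under a homogeneous
  null this truncation makes the random-effects standard error weakly
  conservative, which is why a 2,000-gene null cohort yields zero
  BH-discoveries in the large majority of runs.
* $p$-values come from the normal approximation $z=\hat\mu/se$. With the
  default six studies of 20+20 samples this is accurate enough that the
  per-gene $Q$ statistics average to $k-1$ within a few percent (checked at
  5,000 genes), and BH across genes controls the FDR empirically.

Genes present in fewer than `min_k = 2` studies are kept in the output table
but flagged and excluded from FDR adjustment and from the disease signature;
their count is reported. For real array data, probe-level collapsing is out
of scope — the readers consume gene-level matrices, and externally produced
DE tables can enter directly through `as_disease_signature()`.

### Study- and sample-level QC

The study-level discordance score is defined *here* (the upstream literature
uses a score whose exact formula is not public): for study $i$, the mean over
genes of $|d_{gi} - \hat\mu_{g(-i)}| / \sqrt{\mathrm{var}(d_{gi})}$, where
$\hat\mu_{g(-i)}$ is the leave-one-out meta-analytic effect. A concordant
study scores near $E|N(0,1)| \approx 0.8$; a label-scrambled or
effect-inverted study scores the highest of its cohort. The exclusion
threshold defaults to 7 so that only gross outliers are dropped; both the
score and the threshold are configurable arguments, not constants.

Sample-level outliers are samples whose mean correlation with the rest of
their study falls more than `mad_k = 5` MADs below the study median; one
removal pass is performed, and removal that would leave fewer than two cases
or two controls is an error rather than a silent degradation.

## Pair classification

The four intersections of up/down sets are counted over the *shared tested
universe only* (a configurable floor of 100 genes guards against vacuous
comparisons). Each quadrant is tested one-sided — enrichment beyond chance —
as the upper tail of the hypergeometric distribution; the odds ratio reported
is the sample cross-product ratio. Three genuinely open choices and how we
fixed them:

* **Adjustment family.** BH across all quadrant tests of one
  neurodegeneration-side disease against all cancers (4 × n cancer p-values
  per family). This matches how a screen of one disorder against a cancer
  panel is naturally read; `per_pair` and `global` families are available.
* **Labels are total.** SDDC and ODDC per the decision rule (both
  same-direction quadrants significant without both cross quadrants, and
  vice versa); `mixed` (all four) and `none` complete the partition so every
  pair gets a label.
* **Correlation on the full profiles.** The reported $r$ is computed on the
  complete shared $\hat\mu$ vectors, not only significant genes, with Pearson
  as the default for disease–disease comparisons (Spearman available).

## Enrichment conventions

ORA and the module-overlap test are the same upper-tail hypergeometric as the
quadrant tests (one internal implementation, cross-checked against
`fisher.test` and exhaustive enumeration).

Preranked GSEA uses the weighted Kolmogorov–Smirnov-style running sum: hits
increment by $|s|^{p}$ normalized by the in-set total (default `weight_p =
1`), misses decrement by $1/(N-N_{hits})$. Because the input is a preranked
list, the null is gene-label permutation — sample permutation is impossible
after meta-analysis. NES divides ES by the mean $|ES^\ast|$ of the
matching-sign permutations, and the p-value is the matching-sign tail
frequency with +1 smoothing, so $p \ge 1/(n_{perm}+1)$ and sets whose
matching-sign permutation mean is zero report `NES = NA` rather than a
division artifact. Ranking ties are broken by gene identifier, making the
ranking — and with the seed, the whole analysis — deterministic. Defaults
`min_size = 15`, `max_size = 500`, `n_perm = 1000`.

## Interactome statistics

All distances are unweighted hop counts on the interactome, and analyses are
restricted to the graph's largest connected component; unmapped genes and
members unreachable from every other member are dropped with counts reported
(an alternative would impute diameter + 1 — we prefer reporting to
imputation). Localization is measured as the largest connected induced
subgraph size $S$ and the mean nearest-member distance $d_{aa}$; separation
of two sets is $s_{AB} = d_{AB} - (d_{AA}+d_{BB})/2$ with shared genes
contributing zero to $d_{AB}$, so $s_{AB} < 0$ with a significant z-score
indicates overlapping modules.

The null model preserves degree structure: nodes are binned by
$\lfloor\log_2 \deg\rfloor$, bins merged upward until each holds at least
`bin_min = 25` nodes, and random sets drawn without replacement matching the
reference set's bin composition. On a regular graph this null degenerates to
uniform sampling, which the tests exploit as a calibration check (null-drawn
sets score $|z|$ near zero, z-scores of null sets are standard-normal-like).

## Drug consensus and matching

Replicate perturbation signatures are combined by a correlation-weighted
average in the spirit of the MODZ procedure used for level-5 perturbation
data: weights proportional to each replicate's mean Spearman correlation with
the others, floored at 0.01 before normalization so discordant replicates are
down-weighted but never silently discarded, then normalized to sum to one. A
plain-mean aggregator is available for sensitivity analysis. Matching uses
Spearman correlation over the genes shared by the consensus and the disease
profile (at least 10 required), with the reversal/mimic threshold at
$|\rho| = 0.2$ — the conventional screening cut-off for connectivity-style
analyses. Drugs listed in the indications table without signatures are
reported as untested rather than failing the screen.

## What the generator emulates — and what it does not

`sim_expression_cohort()` draws, per gene and study, an effect
$\delta_{gs} \sim N(\mu, \tau^2)$ applied to case means on the log2 scale
(negated for the down set), which is exactly the random-effects model the
meta-analysis estimates; per-gene baselines are shared across studies so
samples correlate as on a real platform, and the planted shift is scaled by
`noise_sd` so `effect_mu` stays a standardized effect regardless of the noise
level. Defaults — six studies of 20 cases and 20 controls, 2,000 genes, 100
up- and 100 down-regulated genes, $\mu = 1.5$, $\tau = 0.1$ — mirror the
scale of post-mortem brain cohorts (order 5–10 studies, tens of samples
each) at desk size. `sim_disease_pair()` plants SDDC/ODDC structure by
sharing a fixed fraction of the first disease's sets with matched or flipped
sign; `sim_interactome()` uses preferential attachment because the
degree-preserving nulls need a heavy-tailed degree distribution;
`sim_disease_module()` grows modules with a locality parameter interpolating
between connected subgraphs and uniform node sets; `sim_drug_signatures()`
adds independent Gaussian noise to a true signal across synthetic cell
contexts.

Not simulated: platform/batch effects, probe-level structure, RNA-seq count
distributions, correlated gene-gene co-expression beyond the shared planted
sets, dose–response structure in perturbations, and literature interactomes.
Passing tests therefore demonstrate the *statistical machinery* — estimator
calibration, error control, recovery under the assumed generative model —
not robustness to the full messiness of repository data.

## Problem sizes and determinism

The test suite and the acceptance script run at deliberately desk-sized
configurations chosen once: 20 replicate seeds for every stochastic claim,
2,000-gene cohorts for recovery and null control, 800-gene pairs for
classification, 2,000-node interactomes with 200 null draws for module
detection, and 1,000 permutations for GSEA detection. Every generator and
permutation routine takes an explicit integer seed and restores the caller's
RNG state, so the demo pipeline is byte-identical across runs given the same
configuration — the run report echoes the configuration and its digest, which
is sufficient to reproduce any output table.

## Known limitations

* The normal approximation for $z=\hat\mu/se$ is slightly optimistic for
  very small study counts (k ≤ 3); the DL truncation partly compensates.
  Likewise the large-sample variance formula for Hedges' g is a few percent
  biased below ~15 samples per group, which shifts the mean of the per-gene
  $Q$ statistics accordingly.
* The hypergeometric quadrant test treats the two signatures' set sizes as
  fixed margins; it does not model the correlation induced when two cohorts
  share control samples.
* Permutation GSEA p-values are bounded below by $1/(n_{perm}+1)$, so BH
  significance of a single set among many requires enough permutations.
* The degree-binned null is the standard first-order correction; it does not
  preserve higher-order structure (clustering, communities).
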