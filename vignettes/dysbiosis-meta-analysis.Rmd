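---
title: "Defining dysbiosis across chronic diseases: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Defining dysbiosis across chronic diseases: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dysbiome)
```

## The problem

Gut dysbiosis -- an imbalance of the intestinal microbiota -- is implicated
in a cluster of chronic diseases (cardiovascular disease, obesity, diabetes,
kidney disease, urinary stone disease). Two regimes are distinguished:
*loss-of-function* dysbiosis, the depletion of health-associated taxa, and
*gain-of-function* dysbiosis, the enrichment of disease-associated taxa.
`dysbiome` implements a meta-analytic pipeline that quantifies which regime
dominates in 16S rRNA OTU count data: it tests whether disease cohorts lose
more OTUs than they gain relative to healthy controls, whether that signal
exceeds a stochastic-labelling null, which genera carry it, and whether any
genus is dysbiotic beyond what its OTU richness alone predicts. It also
quantifies the association between chronic disease and antibiotic use, and
between antibiotic use and community composition.

Because the original cohorts are raw-read archives, the package ships a
synthetic cohort generator with known ground truth; every stage is validated
by recovery and calibration tests on generated data rather than by
re-processing sequence reads.

## Pipeline overview

1. **Preprocessing** (`read_otu_table`, `filter_low_count`,
   `reduce_to_genus`): OTUs with fewer than 10 counts across the loaded
   dataset are dropped; genus-level summaries exclude OTUs unclassified at
   genus rank.
2. **Population design** (`assign_random_numbers`, `subdivide`,
   `make_stochastic_groups`, `enumerate_comparisons`): each health status is
   split into independent populations by assigning uniform random numbers
   and cutting the ranks into blocks (lowest, middle, highest 100 by
   default). Three healthy against three disease subsets give nine pairwise
   comparisons; a disease with only one subset gives three. Stochastic
   groups 1 and 2 are built the same way from fresh random numbers,
   *ignoring all real metadata* -- they are the empirical null for every
   downstream dysbiosis metric.
3. **Differential abundance** (`nb_wald_test`): a negative-binomial Wald
   test per OTU between the two groups of each comparison.
4. **Dysbiosis summaries** (`fold_difference`, `test_fold_bias`,
   `genus_presence`, `cluster_with_support`): the fold difference in
   enriched-OTU counts per comparison, one-sample t-tests against 1,
   genus-level presence-proportion heatmap matrices, and hierarchical
   clustering of diseases with multiscale-bootstrap support.
5. **Diversity adjustment** (`genus_diversity_records`,
   `spearman_diversity_corr`, `three_sigma_flags`): does dysbiosis track
   genus OTU-richness, and which genera exceed that expectation by more
   than three residual standard deviations?
6. **Antibiotics** (`antibiotic_association`, `weighted_unifrac`, `pcoa`,
   `permanova`): relative risk of antibiotic use in disease with post-hoc
   Fisher's exact tests (Holm-corrected), and a weighted UniFrac /
   PERMANOVA test of antibiotic use against community composition.

`run_pipeline` executes all stages from one configuration, writing
inspectable files plus a checksum manifest; a fixed set of seeds makes the
whole run byte-reproducible.

## The differential-abundance model

Counts for OTU $i$ in sample $j$ are modelled as negative binomial with
mean $\mu_{ij} = s_j q_{i,g(j)}$ and variance $\mu + \alpha_i \mu^2$, where
$s_j$ is a per-sample size factor and $g(j)$ the sample's group. The
statistics reported per OTU are the log2 fold change
$\beta_i = \log_2 (q_{i2}/q_{i1})$, its standard error (lfcse), the Wald
statistic $\beta_i/\mathrm{se}$, the two-sided normal p-value, and the
Benjamini-Hochberg adjusted p-value.

* **Size factors** are median-of-ratios: the median over reference OTUs of
  $k_{ij}/(\prod_j k_{ij})^{1/n}$, rescaled to geometric mean 1. The
  reference set is the OTUs observed in every sample; if none qualifies the
  geometric means are taken over positive counts only.
* **Dispersions** are per-OTU method-of-moments estimates on normalised
  counts, $\hat\alpha_i = \max(10^{-8}, (s^2-\bar m)/\bar m^2)$. An
  optional flag shrinks them halfway (log scale) toward a mean-dispersion
  trend for small designs.
* **Fitting**: with the dispersion fixed and the group factor the only
  covariate, the NB log-link GLM separates per group, so each (OTU, group)
  pair is a one-dimensional Fisher-scoring problem, solved vectorised
  across OTUs (step clamp $\pm 5$, tolerance $10^{-8}$, at most 100
  iterations). The Wald SE $\sqrt{1/I_1 + 1/I_2}/\ln 2$ is identical to
  the two-parameter GLM's, which the test suite verifies against a
  fixed-dispersion `glm` fit.

This is a deliberate simplification of the DESeq2 machinery it emulates:
no dispersion shrinkage to a fitted trend, no outlier replacement, no
independent filtering, no LFC shrinkage. The package establishes validity
by calibration instead: under simulated nulls the raw p-values reject at
the nominal rate and the BH-adjusted discovery fraction stays below 0.05,
while planted 4-fold effects at 50 samples/group are recovered with
sensitivity above 0.8. OTUs with all-zero counts, or unobserved in an
entire group (unbounded fold change), carry `NA` statistics and are logged,
never fatal.

The significance threshold for "differentially abundant" defaults to
adjusted $p < 0.05$ and is configurable everywhere; regularisation is fit
per pairwise comparison (each comparison estimates its own size factors and
dispersions), which keeps comparisons independent.

## Fold difference and the stochastic null

For each comparison, `fold_difference` takes $n_1$ = OTUs enriched in the
healthy (group 1) direction and $n_2$ = enriched in disease, and reports
$n_1/n_2$. Values below 1 are inverted and negated *only for plotting*;
the one-sample t-test against 1 runs on the raw ratios (a log-scale variant
is available). A zero denominator is substituted with $\max(n_2,1)$ and
flagged (configurable to exclusion); a comparison with no discoveries at
all is undefined and always excluded. Per disease the ratios are tested
two-sided against 1 and Holm-corrected across the diseases in the run. A
mean ratio significantly above 1 is the signature of loss-of-function
dysbiosis. The same statistic computed on stochastic groups 1 vs 2 should
be -- and in the test suite is -- non-significant.

## Genus matrices and multiscale-bootstrap cluster support

For each disease and genus, `genus_presence` reports the fraction of that
disease's comparisons in which the genus had at least one significant OTU,
separately for the healthy side ("potentially beneficial") and the disease
side ("potentially pathogenic"). The two sides are clustered separately
(rows = diseases; Euclidean distance, complete linkage by default,
correlation distance and average linkage available).

Node support uses the multiscale bootstrap: for each scale
$r \in \{0.5, 0.6, \ldots, 1.4\}$ the genus columns are resampled with
replacement to size $\lceil r m \rceil$, 1000 times by default, and
$\mathrm{bp}(r)$ is the fraction of replicate trees containing the node's
leaf set. The approximately unbiased value comes from the weighted
least-squares fit $\Phi^{-1}(1-\mathrm{bp}(r)) = v\sqrt r + c/\sqrt r$
with binomial-variance weights, evaluated as
$\mathrm{AU} = 1 - \Phi(v - c)$; BP is reported at scale 1. Scales with
unanimous bp (exactly 0 or 1) carry no probit information and are excluded
from the fit; a node unanimous at (nearly) every scale is degenerate and
its AU is the mean bp, so a node present in every replicate gets AU = 1.
Elsewhere bp is clamped to $[1/(B+1), B/(B+1)]$ before the probit.
AU > 0.95 is stored as a significance flag, never used as a filter.
Leaf sets are encoded as sorted label strings, making support invariant to
input row order.

## Diversity adjustment and the three-sigma rule

Genera with more constituent OTUs have more opportunities to contain
dysbiotic ones, and a Spearman rank correlation (large-sample t
approximation) quantifies that relationship. "Expected" dysbiosis given
diversity is modelled as an ordinary least-squares line of dysbiotic-OTU
count on total-OTU count -- the minimal reading of an expectation from the
plotted relationship; zero-intercept and median-based robust variants are
configurable. The residual SD uses $n-2$ degrees of freedom, and a genus is
flagged only when its residual exceeds $+3$ SD (one-sided: genera far
*below* the line are never flagged). Dysbiotic OTUs are counted uniquely
(significant in at least one comparison, both sides pooled) by default;
comparison-weighted and per-side counting are options.

## Antibiotics and beta diversity

The disease-antibiotic association uses the relative risk
$[a/(a+b)]/[c/(c+d)]$ with a log-normal 95% CI, a post-hoc two-sided
Fisher's exact test under the probability-mass rule (no tail doubling, no
continuity correction), and Holm correction across all diseases analysed in
one run; samples with missing antibiotic metadata are excluded listwise.

Weighted UniFrac is computed from per-edge abundance proportions
accumulated in a single postorder pass: raw distance
$\sum_i b_i |p_i(A) - p_i(B)|$, normalised variant divided by
$\sum_i b_i (p_i(A) + p_i(B))$ (bounded in $[0,1]$). Proportions default to
per-sample relative abundance for boundedness; size-factor-normalised input
is a flag. PCoA is classical scaling (negative eigenvalues dropped with a
warning), and PERMANOVA uses the pseudo-F from the Gower-centred squared
distances with free label permutation (999 by default) through vegan's
permutation engine under an explicit seed.

## The synthetic cohort generator

`simulate_cohort` emulates the statistical structure the analysis assumes:

| parameter | default | meaning |
|---|---|---|
| `n_samples_per_group` | 300 | samples per health status (100-sample subsets, three per status) |
| `n_otus` | 800 | OTUs after preprocessing |
| `n_genera`, `genus_size_exponent` | 120, 1.5 | power-law genus sizes |
| `frac_unclassified_genus` | 0.05 | OTUs with no genus rank |
| `depth_log_mean`, `depth_log_sd` | log 20000, 0.6 | lognormal library sizes |
| `nb_dispersion` | 0.3 | NB dispersion alpha |
| `frac_depleted_in_disease` | 0.15 | OTUs depleted in disease |
| `frac_enriched_in_disease` | 0.05 | OTUs enriched in disease |
| `effect_log2fc` | 2 | planted effect (4-fold) |
| `antibiotic_effect_log2fc`, `frac_abx_affected` | 1, 0.2 | antibiotic composition shift |
| `antibiotic_prevalence_healthy` / `_disease` | 0.25 / 0.45 | antibiotic use in last year |

Baseline relative abundances are Dirichlet draws with lognormal
concentrations (realistic rank-abundance curves); counts are NB with mean
`rel * depth * 2^(disease * lfc + abx * abx_lfc)`; the tree is a random
coalescent over OTU tips. The 3:1 depletion:enrichment default encodes the
loss-of-function regime the pipeline is designed to detect; antibiotic
prevalences are higher in disease, mirroring the association the
antibiotic stage tests. `planted_excess_genus = TRUE` concentrates depleted
OTUs into the largest genus, planting a known three-sigma positive for the
diversity-adjustment stage.

What the generator does *not* emulate: compositional closure effects
beyond depth scaling, phylogenetic signal in which OTUs are affected
(effects are assigned independently of the tree), batch/study effects, and
taxonomy misassignment. Passing recovery tests therefore demonstrate the
statistical machinery is correct and calibrated under the assumed model,
not that real cohorts satisfy the model.

## Numerical choices and degenerate inputs

* Random-number collisions during subdivision are re-drawn, so rank blocks
  are always strict; stochastic groups mirror the disease design's subset
  size (the design is silent on it).
* Fisher scoring: tolerance $10^{-8}$ on the step, 100 iterations, step
  clamp $\pm 5$; non-convergence yields `NA` statistics, logged.
* Fold-difference t-tests: all values exactly 1 gives $t = 0, p = 1$; zero
  variance away from 1 is degenerate and flagged with $p = 0$.
* Cluster support on identical columns degenerates to unanimous support of
  the forced topology.
* Three-sigma with zero residual variance flags nothing and warns.
* In `run_pipeline`, diseases with fewer than two usable fold-difference
  records, or degenerate diversity records, produce `NA` summary rows
  rather than halting; the strict errors remain when the functions are
  called directly.

## Problem sizes in the shipped tests

The test-suite and acceptance-script simulations use scaled-down cohorts
chosen to keep the full suite fast while leaving comfortable statistical
margins: null calibration at 100 OTUs and 30 samples/group (200
replicates), planted-effect recovery at 50 samples/group, loss-of-function
recovery at 150 OTUs with three 20-sample subsets per status (50 seeds),
and beta-diversity power at 100 samples/group over 50 seeds. These sizes
are the package's own validation design; the generator defaults above
remain the cohort-scale conditions.

## Known limitations

* Two-group designs only; no covariate adjustment in the DA model.
* The DA engine's simplifications relative to DESeq2 (above) trade a
  little small-sample shrinkage efficiency for transparency; dispersion
  shrinkage is available behind a flag but defaults off.
* The NB likelihood absorbs depth through offsets, so rescaling a single
  sample's counts is compensated exactly by its size factor only in the
  Poisson limit; the effect on Wald statistics is negligible but not zero.
* AU values are asymptotic approximations; with few genus columns the
  multiscale fit is noisy, which is why BP is reported alongside.
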