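---
title: "Methods: case-control GWAS classification with hybrid selection and wide-and-deep networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: case-control GWAS classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Overview

`gwaswd` implements a complete case-control genome-wide association
classification workflow: PLINK 1 binary input/output, a quality-control
cascade, a per-SNP logistic association screen, one-hot genotype encoding,
a hybrid feature-selection stage (principal-component loadings intersected
with Boruta), neighbour-SNP expansion, and four classifiers — random
forest, a wide neural network, a deep neural network, and a wide-and-deep
network — evaluated with a stratified 70/30 hold-out and 5-fold
cross-validation, plus decision-rule extraction from the best forest tree.

Because real dementia GWAS cohorts are access-controlled, the package
ships a first-class synthetic cohort generator with known ground truth;
every claim the test-suite makes is made against cohorts it generates.

## The synthetic cohort generator

`simulate_cohort()` draws two haplotypes per subject. Along the variant
map each haplotype carries a latent uniform that is retained from the
previous SNP with probability `ld_rho` and redrawn otherwise (restarting
at every chromosome start); the allele is the latent uniform thresholded
at the SNP's drawn allele frequency. Two properties motivated this
construction over the more obvious "copy the neighbouring allele"
Markov chain:

* every SNP's marginal allele frequency equals its drawn frequency
  exactly (an allele-copying chain drags each marginal toward its
  neighbours' frequencies), and
* adjacent alleles correlate with coefficient `ld_rho` when their
  frequencies agree, decaying geometrically with map distance — a crude
  but serviceable stand-in for local linkage disequilibrium.

Disease status follows an additive logistic model over the planted causal
SNPs, `logit P(case) = alpha + sum_j beta_j g_j`, with `alpha` solved by
Monte Carlo so the population prevalence matches `target_prevalence`
(default 0.15, a realistic figure for dementia in an elderly study
population). Subjects are drawn in batches and accepted by rejection
sampling until the exact case and control quotas are met, mirroring
fixed-quota clinical recruitment. On the X chromosome males carry a
single haplotype stored as homozygous diploid codes, the PLINK
convention, which is what makes the X-homozygosity sex check behave.

Defect classes for exercising QC are injected after sampling, in this
order: duplicated samples (a genotype copy with 1% of sites redrawn from
the marginal), heterozygote-excess SNPs (genotypes redrawn with
inbreeding coefficient F = -0.5; their frequencies are re-drawn in
[0.35, 0.5], the range where that genotype law is non-negative),
sex-label flips (the recorded sex changes, the X genotypes do not),
planted high-missingness SNPs and samples (5% and 25% per-call missing
rates, sitting clearly above the 2% / 20% QC thresholds), and finally a
global missing-completely-at-random rate (default 0.2%).

What the generator does *not* emulate: population structure and
admixture, coalescent-accurate LD (no long-range structure, no allele
frequency spectrum from demography), genotyping batch effects, and
chip-specific missingness patterns. Tests passing on these cohorts
demonstrate that the pipeline's machinery is correct and calibrated on
clean, exchangeable genotypes; they do not certify behaviour under
population stratification, which the ethnicity-metadata filter only
crudely addresses.

The canonical study conditions used by the test-suite and the acceptance
script are frozen in `planted_cohort_config()` — 174 cases, 214 controls,
5,000 autosomal SNPs over chromosomes 1-22, allele frequencies uniform on
[0.05, 0.5], `ld_rho = 0.4`, and ten causal SNPs of odds ratio 2.5 spaced
evenly along the map — and `defect_cohort_config()`, the same cohort with
500 X SNPs and every defect class planted. Ten causal SNPs at OR 2.5 give
a liability spread (about 1.9 logits) strong enough that recovery is
possible at n = 388 yet weak enough per-SNP that the screen is not
trivial. The 500-SNP X panel is the smallest at which the female
homozygosity statistic F is tight enough (roughly ±0.15 at this LD level)
for the 0.2/0.8 inference bounds to separate the sexes reliably.

## Quality control

`run_qc()` applies, in a fixed order: SNP missingness (> 2% removed),
sample missingness (> 20%), the X-homozygosity sex check (F > 0.8 male,
F < 0.2 female; discrepant samples removed by default), restriction to
autosomes, the minor-allele-frequency floor (MAF >= 0.05 retained, the
PLINK `--maf` boundary convention), Hardy-Weinberg tests, relatedness,
and optionally an ethnicity-metadata filter. The sex check deliberately
precedes the autosome filter because it needs the X variants.

Hardy-Weinberg testing uses the exact conditional test — enumerating all
heterozygote counts compatible with the observed allele counts and
summing the probabilities of configurations no more probable than the
observed one — rather than the asymptotic chi-square. At thresholds of
1e-6 (controls) and 1e-10 (cases, applied second) the chi-square
approximation is meaningless in the far tail at a few hundred samples;
the exact tail is the only defensible object there. The two-pass
controls-then-cases order matters: a SNP out of equilibrium only in cases
at p = 1e-8 survives, because the case threshold is the looser 1e-10 —
in case-control data a case-only deviation may be signal, not artefact.

Relatedness uses the method-of-moments identity-by-descent estimate:
observed identity-by-state counts for a sample pair are converted to
estimated IBD-state probabilities using cohort allele frequencies,
clipped to the probability simplex, and summarised as
pi-hat = P(IBD=1)/2 + P(IBD=2). Founders only are screened; for each
pair above pi-hat 0.2 the member with the lower call rate is removed
(ties break toward the lexicographically larger id, so the outcome is
deterministic). The all-pairs screen computes IBS counts by indicator
matrix products and scales the frequency-sum expectations by each pair's
non-missing overlap; `estimate_pi_hat()` for a single pair restricts all
sums to exactly the overlapping calls. A practical note: the estimator's
null spread shrinks like the inverse square root of the panel size, so
the 0.2 threshold needs a few thousand autosomal SNPs to keep false
positives negligible; at a few hundred SNPs the null tail crosses 0.2.

## Association screen

Each SNP is tested with a two-parameter logistic regression on additive
dosage (IRLS, log-likelihood tolerance 1e-8, at most 50 iterations; Wald
p-values; missing genotypes dropped listwise per SNP). Complete
separation is flagged at |beta| > 15 and the likelihood-ratio p-value is
reported instead, because the Wald statistic collapses under separation.
Degenerate (monomorphic) SNPs yield flagged rows rather than aborting
the scan. No covariates are included by default.

The screen keeps the 1,000 smallest p-values (ties broken by map
position) regardless of the genome-wide 5e-8 line, which is only drawn
as a reference in the Manhattan output — at a few hundred samples a
rank-based screen is the pragmatic choice. The genomic inflation factor
is the median association chi-square over `qchisq(0.5, 1)` (0.4549...);
QQ expected quantiles are `(i - 0.5) / m`.

## Feature encoding and hybrid selection

Screened SNPs are expanded to three binary indicators each, named
`<snp>_<genotype>` with genotypes spelled from the bim alleles (the
heterozygote is always written A1A2). A missing call leaves all three
indicators zero — missingness is treated as absence of evidence, keeping
the feature count at exactly three per SNP. Selection operates at the
feature (genotype) level, not the SNP level, so a single genotype of a
SNP can be selected on its own.

Two rankers are computed:

* **PCA loadings**: features are centred, the principal-component
  rotation computed, and each feature scored by the sum of absolute
  rotation entries over the components retained up to 95% cumulative
  explained variance. The cutoff and the (un)weighting are genuinely
  open choices; 95%/unweighted is the default and both are exposed
  (`var_explained`, `weight_by_variance`). Components get a
  deterministic sign convention, though the absolute sum is invariant
  to it.
* **Boruta**: the classic shadow-feature scheme — each iteration appends
  a row-shuffled copy of every active column, fits a random forest
  (300 trees, impurity importance, single-threaded and seeded), and
  credits a hit to every real feature beating the best shadow; two-sided
  binomial tests against Binomial(iterations, 1/2), Bonferroni-corrected
  over the original feature count at alpha 0.05, confirm or reject
  features, and rejected features leave the forest. Features undecided
  at the iteration cap stay `tentative` and are treated as rejected
  downstream. With a Bonferroni family of a few thousand features the
  earliest possible decision arrives after roughly 18 iterations, which
  is why iteration budgets below ~20 cannot reject anything.

The hybrid set is the intersection of the two rankings' top quartiles
(`ceiling(0.25 m)` each), ordered by mean rank. An honest caveat
documented here because it shapes expectations: the PCA ranking is
unsupervised and variance-driven, so on a panel of SNPs that all passed
the p-value screen its top quartile hits any given feature at roughly
the base rate, and the intersection behaves like the Boruta quartile
thinned by that rate. The intersection's value is aggressive
dimensionality reduction (a quarter of a quarter), not enrichment of
causal features beyond what Boruta alone provides; the acceptance script
reports the measured causal coverage of each stage so this can be seen
directly.

Neighbour expansion takes, for every unique parent SNP of the selection,
up to `k = 6` map-adjacent SNPs on each side within the same chromosome
(truncated at chromosome ends), unions the windows, and one-hot encodes
the union as the deep feature space. Windows are defined by map order —
bim row adjacency after QC — not base-pair distance.

## Classifiers

* **Random forest**: bagged CART trees with a random feature subset per
  split, majority vote, probability = case-vote fraction. A 50/50 vote
  tie is called control — the conservative direction for a diagnosis.
* **Wide network (WNN)**: one hidden ReLU layer, default width 256.
* **Deep network (DNN)**: ReLU stack, default 64-32-16.
* **Wide-and-deep (WDNN)**: the deep stack consumes the neighbour
  features; the curated wide features are concatenated with the last
  hidden representation immediately before the sigmoid output, so the
  output unit sees `last deep width + wide count` inputs. Concatenation
  before the output unit (rather than before the last hidden layer) was
  chosen so the wide features influence the decision directly as a
  linear path; the alternative is one flag away in `mlp_train()`.

All networks train with mini-batch Adam (learning rate 1e-3, batch 32,
up to 200 epochs) on binary cross-entropy, with a 15% validation split
and early stopping at patience 20, restoring the best-validation
weights. Training is single-threaded and fully deterministic given the
seed. These defaults are deliberately modest: with a few hundred
samples, capacity and schedule matter less than early stopping.

## Evaluation protocol

Samples are split 70/30 with stratification (class proportions preserved
within one sample). Model assessment combines 5-fold cross-validation
inside the training partition with a single final fit evaluated once on
the 30% hold-out; both sets of numbers are reported and labelled, since
they answer different questions. Metrics: accuracy, precision, recall,
F1 (harmonic mean), with zero-denominator ratios reported as 0 and
flagged; ROC curves with trapezoidal area; precision-recall curves with
step-interpolated (average-precision) area. Cases are the positive
class.

Two leakage regimes are explicit. The default, `fold-safe`, fits the
association screen and all feature selection on the training partition
only, so the hold-out estimate is honest. `paper-protocol` performs
selection on the full cohort before splitting — the workflow many
published GWAS-classification studies describe — and is provided for
comparability; its hold-out numbers are optimistically biased because
the selection stage has seen the test labels, and the gap between the
two regimes on the same cohort is itself informative (the acceptance
script's experiment metrics are computed under `paper-protocol` for
comparability with published figures).

## Rule extraction

From a trained forest, the tree with the highest validation accuracy
(ties: fewer leaves, then lower index) is unrolled into one rule per
root-to-leaf path. Splits on one-hot indicators are rendered as genotype
statements (`rs... = AA` / `rs... != AA`). The rule list partitions the
feature space by construction, so exactly one rule fires per sample and
the rule-set predictions reproduce the source tree's predictions
exactly; support and confidence are counted on a caller-chosen dataset.

## Numerical and degenerate-input choices

* Exact HWE p-values compare configuration probabilities with a
  relative guard of 1e-12 to avoid float ties; monomorphic tables give
  p = 1 (a single attainable configuration).
* Missingness thresholds compare with a 1e-12 absolute guard so that a
  rate exactly at the boundary is retained.
* Logistic separation falls back to the likelihood-ratio p rather than
  reporting a Wald p of a divergent estimate.
* All rankings break score ties by feature name; top-k SNP selection
  breaks p-value ties by (chromosome, position). Every ordering in the
  package is total, so repeated runs are identical.
* The MAF boundary keeps variants at exactly the threshold.

## Problem sizes

The shipped tests run the full pipeline at the frozen study conditions
(388 samples by 5,000 SNPs, five generator seeds for the selection-stage
replication) and smaller cohorts elsewhere; the whole suite completes in
a few minutes on one core, and `scripts/acceptance.R` recomputes the
headline quantities in about a minute. These sizes are the package's
chosen benchmark conditions: large enough for the relatedness and
sex-check statistics to concentrate, small enough to iterate on.

## Known limitations

* The generator's LD is local and geometric; no panel-realistic
  haplotype structure, so neighbour-SNP expansion is tested under milder
  LD than real data would provide.
* PCA-loading importance does not enrich for class-informative features
  (see above); the hybrid intersection should be read as a compression
  stage.
* The pi-hat screen is uncorrected method-of-moments; with fewer than a
  few thousand SNPs its null tail widens and the 0.2 threshold will
  produce false positives.
* No covariate adjustment, no mixed models, no imputation: single-locus
  tests on called genotypes only.
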