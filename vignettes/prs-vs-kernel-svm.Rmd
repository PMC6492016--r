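---
title: "Polygenic scores versus kernel SVMs: models, simulator design, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Polygenic scores versus kernel SVMs: models, simulator design, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prsvm)
```

## The scientific question

Polygenic risk scores (PRS) summarize a person's genetic liability to a
complex disease as a weighted sum of risk-allele counts, with weights taken
from univariable per-SNP effect estimates. Multivariate classifiers —
multivariate logistic regression, or soft-margin support vector machines
(SVMs) with a linear kernel — instead estimate all SNP weights jointly, and
nonlinear kernels (the radial basis function, RBF) can additionally exploit
SNP-by-SNP interactions. Empirically, on schizophrenia case–control
genotype panels, the humble PRS classifies cases from controls at least as
well as either SVM. `prsvm` packages the machinery needed to study why:

1. a synthetic case–control cohort generator with known additive and
   epistatic (XOR) architectures;
2. the standard genotype QC stack;
3. a PRS engine and an SVM engine under a shared repeated-split protocol;
4. a two-SNP simulation study isolating the mechanism — retrospective
   case–control ascertainment induces positive correlation between
   independent risk loci, which the aggregated score exploits and a
   multivariate model pays degrees of freedom to re-estimate.

## The disease model

Disease status is generated from a logistic (log-odds additive) liability:

$$\Pr(Y=1 \mid g) = \operatorname{logit}^{-1}\!\Big(\beta_0 +
\sum_j \beta_j g_j + \sum_{(a,b)} \theta_{ab}\,
\mathrm{XOR}(c_a, c_b)\Big),$$

where $g_j \in \{0,1,2\}$ counts the effect allele at SNP $j$ (drawn under
Hardy–Weinberg proportions, loci mutually independent — the simulator
emulates an LD-pruned panel), $\beta_j$ is the per-allele log odds ratio,
and the interaction term uses dominant carrier indicators
$c_a = \mathbf{1}[g_a \ge 1]$. A logistic rather than liability-threshold
model is used because effect sizes throughout are stated as odds ratios.

The intercept $\beta_0$ is solved by `solve_intercept()` so that the
*population* prevalence equals the target $K$: the expectation of the
penetrance over the genotype distribution is computed by exact enumeration
of the $3^k$ genotype cells when at most three loci carry effects
(tolerance $10^{-8}$, Brent root-finding with tolerance $10^{-12}$), and by
a 200,000-draw Monte-Carlo estimate with a fixed internal seed otherwise,
which keeps the solved intercept deterministic for a given architecture.

Cohorts are ascertained retrospectively (`sample_case_control()`): the
generator draws individuals from the population model and retains them
until the case and control quotas are filled exactly, then shuffles row
order. This enrichment of cases relative to $K$ is not a nuisance — it is
the object of study (see below).

### The XOR architecture and the marginal-nulling MAF

The XOR model gives elevated risk exactly when one, but not both, of a
locus pair carries the risk allele. With carrier probability $1/2$ at both
loci the single-locus marginal effects cancel exactly, which is the defining
property of this interaction class: association scans see nothing while the
joint genotype carries signal. Under Hardy–Weinberg proportions the carrier
probability is $1-(1-f)^2$, so the nulling allele frequency is
$f = 1-\sqrt{1/2} \approx 0.293$ (`xor_null_maf()`). At any other
frequency the marginals are nonzero; the generator permits this and the
behaviour is documented rather than forbidden.

### Why the default prevalence is 0.01

The generator's default population prevalence is $K = 0.01$, the
approximate lifetime prevalence of schizophrenia, the disease the package's
study conditions emulate. The choice matters for more than realism. Under a
logistic model, conditioning on case status makes independent risk loci
*negatively* dependent (a collider effect) to a degree that grows with the
saturation of the penetrance curve. Exact 9-cell enumeration shows that at
$K = 0.1$, two loci with OR = 4 and MAF 0.3 have within-case correlation
$r \approx -0.13$ — larger in magnitude than the positive combined-sample
correlation the study is about, and contrary to the observed phenomenon
that within-group correlations are approximately zero. At $K = 0.01$ the
penetrance stays in the near-exponential regime, within-group correlations
stay below 0.025 in magnitude across the whole OR $\in [1,4]$ grid, and the
combined-sample correlation at OR = 4 exceeds the largest within-group
correlation several-fold. A rare disease is therefore a *requirement* of
the phenomenon, not an incidental setting. $K$ remains configurable
everywhere.

## The QC stack

`qc_pipeline()` applies, in order: per-SNP missingness filter (remove at
$\ge 2\%$), minor-allele-frequency filter (remove below 10%, boundary
kept), a 1-df chi-square Hardy–Weinberg goodness-of-fit filter (remove at
$p < 10^{-4}$), fixed region exclusion (default: the extended MHC,
chr6:25–34 Mb, closed interval, 1-based), association-aware LD pruning,
and multinomial imputation of remaining missing genotypes. Hard-calling
from genotype-probability triples (`hard_call()`, strict threshold $>0.9$)
precedes the stack when dosage-style input is used.

Choices a reader should know:

- **HWE in controls only** (default): ascertained cases legitimately
  deviate from HWE at true risk loci; testing in controls is standard GWAS
  practice. `hwe_scope = "all"` is available.
- **LD pruning is association-aware**: SNPs are visited in ascending
  association p-value order, and each retained SNP removes
  not-yet-retained SNPs within ±500 kb on the same chromosome whose
  genotype $r^2$ with it exceeds 0.1. Ties are broken deterministically by
  (p, chromosome, position, id). Monomorphic partners have undefined $r$
  and are treated as not in LD (they are the MAF filter's job).
- **Multinomial imputation**: each SNP's observed genotype class
  frequencies define a 3-class multinomial; missing entries are replaced
  by independent draws. Observed entries are never altered; a SNP with no
  observed entries is a hard error. The stack is idempotent on its own
  output.

## The SVM protocol

Features are allele counts standardized to mean 0, variance 1 with
parameters fitted **on the training side only** (`standardize_features()`);
zero-variance training columns are dropped everywhere. The solver behind
`train_svm()` is libsvm (C-classification, via e1071); decision scores are
the continuous margin values, oriented so larger means more case-like, and
AUC is always computed from these scores, never from hard class labels.

Hyperparameters are chosen by Monte-Carlo random search
(`mc_hyperparameter_search()`): candidates drawn as
$C \sim \mathrm{Exp}(\text{scale}=1)$ and, for RBF,
$\gamma \sim \mathrm{Exp}(\text{scale}=0.01)$, each scored by stratified
4-fold cross-validated AUC on a fold assignment held fixed across
candidates, ties broken toward smaller $C$ then smaller $\gamma$. The
exponential parameter is read as the **scale (mean)**, not the rate: the
protocol's selected values ($C=1$ linear; $C=0.5$, $\gamma=0.02$ RBF) are
typical draws under the scale reading and essentially impossible under a
rate-100 reading of the $\gamma$ prior; `param_as = "rate"` is available.
`tune_svm()` wraps the search in the two-phase design: a stratified 10%
holdout is reserved, the search runs on the remaining 90%, and the holdout
AUC of the winner is reported. Tuned values are then **reused** across the
repeated evaluation splits (re-tuning per split is possible but not the
default, matching the protocol's description).

## The comparison experiment

`run_split()` makes one stratified 75%/25% split shared by every method:
PRS weights (per-SNP univariable logistic log-ORs) are estimated on the
75%, the score is evaluated on the 25%; SVMs are trained on the same 75%
with training-side standardization. `run_experiment()` repeats this over
`n_reps` splits (replicate $r$ uses `base_seed + r`, recorded in a seed
ledger) and summarizes each method's AUC distribution by median, quartiles
and extremes. `compare_methods()` applies a Welch two-sample t-test to
replicate AUC vectors (the unequal-variance form is the safer default; a
Student or paired variant is a flag away), and `compare_sample_sizes()`
applies the same test to one method across cohorts of different size.

## The two-SNP study

`simulate_two_snp_cohort()` draws two (or `n_snps`) independent equal-effect
risk loci, assigns status by the logistic model, and ascertains a balanced
retrospective sample (defaults: 10,000 individuals, 50% cases, $K=0.01$).
`run_correlation_grid()` averages the Pearson correlation between the loci
— overall, in cases only, and in controls only — across simulations per
(OR, MAF) cell. The headline behaviour: within-group correlations hover
near zero while the combined-sample correlation is positive and grows with
OR and MAF, because cases are enriched for risk alleles at *both* loci
simultaneously.

`pvalue_comparison()` turns the same cohorts into the power comparison: the
1-df Wald test of the single aggregated score predictor (with equal true
effects, the unweighted allele sum — the score coefficient's p-value is
invariant to the scale of the weights) against the $k$-df likelihood-ratio
test of the joint model with every SNP as a separate predictor. The
"multivariate" p-value is defined as the LRT because no specific test is
canonical for the joint model; per-coefficient Wald minima would additionally
need multiplicity handling. The score test concentrates the same signal in
one degree of freedom and wins systematically; the advantage grows with the
number of aggregated loci.

## Numerical and degenerate-input conventions

- AUC uses the midrank (Mann–Whitney) convention: ties count one half. It
  is exactly the all-pairs statistic, computed in $O(n\log n)$ via ranks.
- Per-SNP logistic fits that (nearly) separate are capped at $|\beta|=15$
  and flagged `"separation"` rather than returned as unbounded estimates.
- Constant score vectors evaluate to AUC 0.5 with a flagged, undefined
  logistic coefficient — not an error, since null simulations legitimately
  produce them.
- A correlation over a zero-variance subset is reported as `NA` and
  flagged, never silently as 0.
- All randomness flows from user-visible integer seeds through a
  deterministic sub-stream derivation, so every cohort, fold assignment,
  and grid is reproducible bit for bit; CLI stages rerun with the same
  seed write byte-identical files.

## What the simulator does and does not emulate

It emulates: retrospective case–control ascertainment with exact quotas,
Hardy–Weinberg genotype draws at configurable MAFs, additive polygenic and
XOR-epistatic architectures with a solved intercept, and MCAR missingness.
It does **not** emulate LD structure between SNPs (the studied panels are
LD-pruned by design), haplotypes, sex chromosomes, covariates, ancestry
structure or batch effects. Passing tests on these cohorts therefore
demonstrates correctness of the statistical machinery and reproduction of
the ascertainment-correlation mechanism — not performance claims about any
real genotype panel, where LD, stratification and batch artefacts all bite.

## Problem sizes used by the test suite

The packaged checks run cohorts of 4,000 individuals with 20–24 SNPs for
the method comparisons (20 repeated splits), two-SNP grids of 10,000
individuals with 200 simulations per cell, and 100 replicates for effect
recovery — sizes chosen so the full suite exercises every study condition
at meaningful Monte-Carlo precision on a single CPU. All of them scale up
by changing the corresponding config fields.

## Known limitations

- The RBF detectability experiments use small SNP panels; with thousands
  of features the kernel bandwidth regime changes and $\gamma$ priors
  should be rescaled accordingly.
- The per-SNP scan uses Wald p-values (cheap at scale); likelihood-ratio
  p-values differ in small samples.
- The LD pruner is greedy; it matches the stated protocol but is not a
  globally optimal independent-set solver.
- `solve_intercept()`'s Monte-Carlo path (more than three effect loci) is
  accurate to roughly $10^{-3}$ in prevalence, not the $10^{-8}$ of the
  enumeration path.
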