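---
title: "Methods: isoform-level transcriptome-wide association analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: isoform-level transcriptome-wide association analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(twasiso)
```

This vignette documents the statistical models behind each stage of the
package, the tunable parameters and their defaults, what the synthetic
data generator does and does not emulate, and the numerical decisions a
maintainer should know about.

## 1. The association model

For a feature (gene or transcript isoform) with cis SNP weights $w$,
GWAS marginal z-scores $z$, and reference LD correlation matrix $V$, the
weighted burden statistic is

$$Z = \frac{w^\top z}{\sqrt{w^\top V w}},$$

standard normal under the null that the genetically predicted expression
of the feature is unrelated to the trait. `burden_test()` evaluates it on
the intersection of model, GWAS, and LD SNPs, after `harmonize_gwas()`
aligns alleles (sign flips for swapped alleles; strand-ambiguous A/T and
C/G SNPs dropped by default). The statistic is invariant to positive
rescaling of $w$, so weights may be stored on any consistent scale; this
package stores them on the standardized-genotype scale, matching how the
models are trained. Quadratic forms below `1e-12` raise a
degenerate-model error rather than returning an unstable ratio.

### Weight training

`train_feature_model()` fits, per feature, each requested model family on
the same deterministic 10-fold split:

- `enet`: univariate elastic net, mixing parameter 0.5, penalty chosen by
  an inner 5-fold cross-validation inside each training fold (so no
  information from the held-out fold reaches the penalty choice);
- `multi`: a multi-response elastic net over all isoforms of a gene
  (`glmnet` `family = "mgaussian"`), whose group penalty imposes shared
  row sparsity — isoforms of one gene borrow strength about *which* SNPs
  are regulatory while keeping their own effect sizes.

The cross-validation score `cv_r2` is the squared Pearson correlation
between out-of-fold predictions and observations, chosen over
$1 - SSE/SST$ for robustness to scale. Negative out-of-fold correlations
are truncated to zero: an anti-correlated predictor has no predictive
value, and without truncation near-null models inherit a spurious
positive $R^2$ from the systematic negative coupling between
leave-fold-out means and held-out fold means. The best family per
response is the one with the highest `cv_r2`, ties broken by fewest
nonzero weights; the winning family is refit on all samples for the
reported weights. Features are retained iff `cv_r2 > 0.01`, strictly.
Fold assignment is deterministic given the seed, which is recorded in the
model, so gene- and isoform-level models can reproducibly share or not
share folds.

### Two-stage testing and permutation filtering

Isoform tests within a gene are dependent and numerous, so significance
is controlled in two stages (`two_stage_adjust()`):

1. **Gene screen.** Each gene's isoform p-values are combined with the
   equal-weight Cauchy combination (ACAT),
   $p_{gene} = P\{\mathrm{Cauchy} > \tfrac1k\sum_i \tan((0.5-p_i)\pi)\}$,
   and Benjamini–Hochberg adjusted *across genes*. ACAT is exact for one
   input and robust to dependence in its small-p regime, which is where
   decisions are made. Inputs are clamped to $[10^{-300}, 1-10^{-16}]$.
2. **Within-gene FWER.** Isoforms of screened genes are Bonferroni
   adjusted within their gene.

A feature is transcriptome-wide significant iff both adjusted values fall
below $\alpha = 0.05$. Bonferroni was chosen for stage 2 over Shaffer-type
refinements: it is simple, conservative, and the stage-1 screen already
absorbs most of the multiplicity.

Significant features then pass through `permutation_test()`: the weight
*values* are randomly re-assigned to SNP positions (z and LD held fixed),
the burden statistic recomputed $B = 10{,}000$ times, and
$p_{perm} = (1 + \#\{|Z_b| \ge |Z_{obs}|\})/(B+1)$ — the add-one estimator
that cannot return zero. This asks whether the *specific arrangement* of
weights adds information beyond the local GWAS signal; it is deliberately
conservative in high LD. With fewer than 3 SNPs all $m!$ arrangements are
enumerated.

### Effective sample size

Because a noncentral $\chi^2$ mean is linear in the GWAS sample size,
`effective_sample_increase()` compares methods by
$100\,[(\bar\chi^2_{iso}-1)/(\bar\chi^2_{gene}-1) - 1]$ over gene pairs
passing the $\chi^2 > 1$ filter. The filter's wording is ambiguous between
union and per-arm application; the union rule (keep a pair if either arm
exceeds 1) is the default and the per-arm variant is one flag away.
Uncertainty is a leave-one-gene-out jackknife (chosen over a block
jackknife for determinism), reported as a Wald 95% CI.

## 2. Fine-mapping

Within 1 Mb-overlapping groups of significant features (single-linkage,
`group_overlapping()`), predicted-expression correlations are
$\Omega_{ab} = w_a^\top V w_b / \sqrt{(w_a^\top V w_a)(w_b^\top V w_b)}$.
Given association z-scores $z$ and a causal configuration $c$,

$$z \mid c \sim \mathcal N\!\left(0,\; \Omega + \sigma^2_{prior}\,
\Omega_{\cdot c}\Omega_{c\cdot}\right),$$

with independent Bernoulli priors per feature. `compute_pips()`
enumerates configurations up to `max_causal` plus the null configuration
(so PIPs stay calibrated under no signal) and reports per-feature
marginal posteriors. Defaults follow the non-informative convention:
prior probability $1/k$, prior variance of a causal feature's z-score
fixed at 40, `max_causal = 1` (enumeration supports more; at
`max_causal = 1` the Bayes factor provably depends only on each feature's
own z, by the matrix determinant lemma, so correlation enters through the
data rather than the likelihood). The 90% credible set is the smallest
PIP-sorted prefix whose cumulative mass, normalized by the non-null
posterior mass, reaches the level — ties broken lexicographically; if the
raw PIP mass cannot reach the level, all features are returned flagged.

## 3. QTL mapping and colocalization

`map_cis_qtl()` regresses expression on allelic dosage (0/1/2) jointly
with covariates for every SNP within 1 Mb of the TSS — note the two
distinct windows in this package: gene-body ± 1 Mb for weight training,
TSS ± 1 Mb for QTL mapping. Computation is by covariate projection, which
is identical to the joint fit by Frisch–Waugh and is unit-tested against
`lm()`; the residual degrees of freedom count the projected-out columns.

`snp_causal_posterior()` applies the same enumeration machinery at the
SNP level (`max_causal = 2`, per-SNP prior $1/m$, prior z-variance
$5.2^2$, the conventional non-centrality scale). Loci are capped at 100
SNPs, with greedy pruning of near-duplicates ($|r| > 0.99$, keeping the
larger $|z|$; pruned SNPs inherit their proxy's posterior). The
colocalization posterior probability is
$\mathrm{CLPP} = \sum_j P(\text{SNP } j \text{ causal} \mid \text{GWAS})
\cdot P(\text{SNP } j \text{ causal} \mid \text{QTL})$, and a feature is
called colocalized only if all three strict conditions hold: GWAS
$P < 5\times10^{-8}$, QTL $P < 10^{-6}$, $\mathrm{CLPP} > 0.01$.

## 4. Expression-mediated heritability

With per-SNP LD scores $\ell_j = \sum_i r^2_{ij}$ and expression scores
$s_j = \sum_f \sum_i r^2_{ij}\beta^2_{i(f)}$ built from sparse (LASSO)
cis-eQTL effect estimates, the regression

$$E[\chi^2_j] = 1 + n\,\sigma^2_\alpha s_j + n\,\sigma^2_\delta \ell_j$$

identifies the mediated component $h^2_{med} = \sigma^2_\alpha \sum_f
\beta_f^\top V \beta_f$ and the non-mediated component
$\sigma^2_\delta M$. `mesc_fit()` uses two-step weighted least squares
with weights $1/(2\,\hat\mu_j^2)$ (the large-sample $\chi^2$ variance at
fitted mean $\hat\mu_j$, floored at 0.5), a delete-one block jackknife
over 20 contiguous SNP blocks for the SE of $h^2_{med}/h^2$, and a Wald
test of ratio = 0. A negative fitted total heritability flags the
estimate and suppresses the ratio. Multi-tissue analysis is reduced in
scope to element-wise averaging of per-tissue score vectors
(`meta_expression_scores()`).

## 5. The synthetic-data generator

The generator produces data with exactly the structure the analysis
assumes, plus ground truth for recovery tests. What it emulates:

- **Genotypes**: two haplotypes per individual, each from a latent
  Gaussian first-order Markov chain within LD blocks, thresholded at the
  allele-frequency quantile. The latent correlation is calibrated as
  $\sin(\pi\rho/2)$ so the realized allele-level adjacent correlation
  equals the requested $\rho$ at MAF 0.5 (tetrachoric inversion);
  correlation between SNPs of unequal MAF is attenuated, as in real
  panels, which is why LD-calibration checks use matched-MAF settings.
  $\rho \ge 1$ is rejected. Dosages are hard calls, and QC
  (`filter_variants()`) applies the MAF ≥ 5% filter, the exact
  conditional HWE test at $P \ge 10^{-5}$ (exact chosen over $\chi^2$
  because only a threshold is specified and the exact test is
  well-defined at any count), and an optional external-panel MAF ≥ 1%
  filter.
- **Expression**: isoform $k$ is $y_k = X\beta_k + \varepsilon_k$ with
  causal SNPs drawn from the gene-body ± 1 Mb window, effects rescaled to
  the target cis-$h^2$, and exchangeably correlated residuals within a
  gene. Gene expression is the unweighted sum of its isoform columns on
  the normalized scale — a stand-in for counts-level aggregation that
  preserves the opposing-isoform cancellation central to the method
  comparison. Covariates are emitted as generic standard-normal columns
  (default 5, a stand-in for principal components/expression factors;
  the real covariate count is not reproduced) with zero loading by
  default, so expression is residual-ready.
- **GWAS**: the standardized joint SNP effect is
  $b = \sum_k \alpha_k \beta_k + \delta$, trait variance normalized to 1.
  Analytic mode draws $z \sim \mathcal N(\sqrt n\,Vb,\ V)$; individual
  mode simulates a fresh cohort from the recorded genotype recipe and
  computes marginal z-scores by regression. The two agree in
  distribution (cross-mode test). Ground truth records $\beta_k$,
  $\alpha$, $h^2$, and $h^2_{med}$ computed against the panel LD.

What it does **not** emulate: read-level quantification uncertainty,
normalization artifacts, population structure or relatedness, real
haplotype panels, and multi-tissue correlation structure. Passing tests
therefore demonstrate statistical correctness of the machinery under the
assumed model, not robustness to those real-data complications.

### Study conditions

The default end-to-end configuration (`pipeline_config()`) is one
deliberately small but fully featured study: a 400-sample reference panel
(a realistic single-tissue eQTL panel size), 400 SNPs spanning 20 Mb in
10-SNP LD blocks at $\rho = 0.6$, MAF 0.05–0.5, 8 genes × 2 isoforms with
cis-$h^2 = 0.35$ and 2 causal SNPs per isoform, and a 50,000-sample GWAS.
Three genes are mediated through opposing isoforms with
$|\alpha| = 0.22$ — large enough that the isoform arm has power at this
panel size while the gene-level arm cancels. Test and acceptance runs use
reduced replicate counts and SNP panels (e.g. 2,000-replicate null
calibrations, 500-replicate recovery runs, 1,000–5,000-SNP mediation
studies with 100–150 features) chosen as the smallest sizes at which the
checked quantities are statistically stable.

## 6. Numerical decisions

- PSD repairs: Cholesky with an escalating diagonal ridge (from `1e-8`)
  for simulated covariances; a fixed `1e-4` ridge, recorded in the
  result, when a supplied correlation matrix fails factorization.
- ACAT inputs and outputs clamped to machine-safe bounds; the
  permutation p uses the add-one estimator; ties in permutation
  statistics count as exceedances (tolerance `1e-12`), making $p = 1$
  exact for invariant weight vectors.
- Monomorphic SNPs are skipped (QTL mapping) or rejected (LD
  computation) rather than silently producing NaNs; zero-variance
  expression yields an `NA` `cv_r2` sentinel that is never retained.
- Credible-set ties break on feature id; locus ids are assigned in
  genomic order, so all outputs are reproducible byte-for-byte given a
  seed.
- All randomness flows through explicit seed arguments; `run_pipeline()`
  derives stage seeds by fixed offsets from the single configured seed
  and records it in the run manifest.

## 7. Known limitations

- Fine-mapping uses the non-informative prior; with many isoforms
  sharing exons and tight LD, credible sets can be large and horizontal
  pleiotropy of SNP–isoform effects is not modeled.
- The permutation filter is conservative by construction; rank
  concordance with the analytic p-value holds under exchangeability but
  power is deliberately sacrificed in high LD.
- The mediation regression inherits LD-score-regression assumptions
  (random effects, polygenicity); at small SNP counts the jackknife SE
  of the ratio is wide, and estimates are only meaningful when the
  fitted total heritability is positive.
- The enumeration-based posteriors are exact but exponential in
  `max_causal`; guards cap loci at 100 SNPs / 30 features.
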