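---
title: "Two-stage SKAT-Lancaster pathway analysis: models, nulls, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage SKAT-Lancaster pathway analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lancpath)
```

## The problem

Sequencing association studies test millions of variants against a trait, and
single-marker tests lose essentially all power after multiple-testing
adjustment, especially for rare variants. `lancpath` aggregates evidence at
two levels. Stage I summarises all variants of a gene into one p-value with
the sequence kernel association test (SKAT), a variance-component score test.
Stage II combines the gene-level p-values of each pathway (gene set) into one
pathway p-value with the Lancaster procedure, a weighted generalisation of
Fisher's method, correcting for the correlation among genes induced by
linkage disequilibrium and shared subjects.

The package also implements the surrounding theory and tooling: exact
independent-case nulls for the main weighted combined p-value methods
(Fisher, regular and weighted Z, Good, Lancaster), Bahadur efficiency slope
calculators that quantify why the Lancaster procedure is the efficient
choice, a competitive (gene-shuffling) permutation variant, and a synthetic
data engine for calibration and power studies.

## Stage I: the SKAT score test

For gene $i$ with dosage matrix $G_i$ (entries 0/1/2) and variant weights
$W_i = \mathrm{diag}(w_{i1}, \dots)$, the model is
$y = X\alpha + G_i\beta_i + \varepsilon$ with $\beta_{ij} \sim (0, w_{ij}
\tau_i)$. Testing $\tau_i = 0$ gives the score statistic

$$Q_i = (y - \hat\mu)^t G_i W_i G_i^t (y - \hat\mu),$$

with $\hat\mu$ the covariate-only least-squares fit. Under the null, $Q_i$
is distributed as $\sum_k \lambda_k \chi^2_{1,k}$ where the $\lambda_k$ are
the eigenvalues of $\hat\sigma^2 \, W_i^{1/2} G_i^t (I - H) G_i W_i^{1/2}$
($H$ the hat matrix of $X$). `mixture_chisq_sf()` evaluates this survival
function by numerical inversion of the characteristic function (Imhof's
formula). The inversion integrand oscillates at frequency $q/2$ while
decaying only as $u^{-(J/2+1)}$, which defeats generic adaptive quadrature
on $(0,\infty)$ for genes with few variants; the implementation integrates
the head adaptively (relative tolerance `1e-9`) up to the first phase
crossing and sums the oscillatory tail over phase-tracked half-period
Gauss-Legendre blocks with Euler acceleration (absolute accuracy around
`1e-9`; the test suite checks it against closed forms and Monte-Carlo). A
one-eigenvalue spectrum is an exact scaled $\chi^2_1$ and is returned in
closed form. If the inversion fails or the result falls below `1e-13`, a
three-moment scaled noncentral chi-square approximation is used instead and
flagged.

Defaults and options:

* **Variant weights** default to the Beta(1, 25) density at the variant's
  MAF, the standard rare-variant up-weighting; `"flat"` and
  `"invvar"` ($1/(\mathrm{MAF}(1-\mathrm{MAF}))$) are available, or any
  numeric vector. The weight function is a modelling choice, not part of the test itself, so
  it is a configuration knob rather than a constant.
* **Continuous traits only.** Binary-trait SKAT needs a different null
  variance model and is out of scope.
* **Common variants as fixed effects**: move the relevant columns of $G$
  into $X$; the MAF split point is the caller's choice, not hard-coded.

## Stage II: the correlated Lancaster procedure

Given gene p-values $P_1, \dots, P_m$ in a pathway and degrees-of-freedom
weights $w_i > 0$, the Lancaster statistic is

$$T = \sum_{i=1}^m F_i^{-1}(1 - P_i), \qquad F_i = \text{CDF of } \chi^2_{w_i}.$$

With $w_i \equiv 2$ this is exactly Fisher's $-2\sum\log P_i$ (the package
uses the closed form at $w = 2$, so the identity is bit-for-bit). Under
independence $T \sim \chi^2_{\sum w_i}$. Genetic data are correlated, and
ignoring that inflates type I error severely (the naive null more than
doubles the nominal 5% rate in the exchangeable-copula checks in the test
suite). The corrected null matches the first two moments,

$$E(T) = \sum_i w_i, \qquad
\mathrm{var}(T) = 2\sum_i w_i + 2\sum_{i<j}\rho_{ij},$$

with $\rho_{ij} = \mathrm{cov}(F_i^{-1}(1-P_i), F_j^{-1}(1-P_j))$ under the
null, to a scaled chi-square $c\chi^2_v$ by the Satterthwaite method:
$c = \mathrm{var}(T)/(2E(T))$, $v = 2E(T)^2/\mathrm{var}(T)$.

**Estimating $\rho_{ij}$.** The covariance of the transformed statistics
has no closed form under realistic LD. The default here is
phenotype-permutation resampling
(`estimate_lancaster_covariance()`, default $B = 1000$): rerun the
gene-level tests on permuted (or redrawn null) phenotypes, transform each
resampled p-vector by $F_i^{-1}(1-\cdot)$, and take the sample covariance.
Permutation preserves the genotype LD architecture that generates the
correlation. An analytic-zero covariance (independence) and a user-supplied
matrix are accepted alternatives.

**Numerical guards.** A noisy covariance estimate can make the implied
variance non-positive; the off-diagonal sum is then shrunk toward zero by the
minimal factor restoring positivity (with a warning). Combined p-values below
`1e-300` are clamped, with the informative value carried as `log10.p`;
chi-square survival functions are computed in log space. For the weighted
Z-test, boundary p-values are clamped to `[1e-300, 1 - 1e-15]` so the normal
quantile stays finite; ordering is preserved.

**Degenerate duplication behaves sensibly**: if all $m$ p-values are copies
of one test, the estimated covariance drives $v$ down to the single-test
$w$, and the combined p-value approaches the single-test p-value under its
own transform.

## Good's test and its null

Good's statistic $-\log Q = -\sum w_i \log P_i$ has, for pairwise-distinct
weights, the closed-form null CDF
$\Pr(Q < q) = \sum_i \Lambda_i q^{1/w_i}$ with
$\Lambda_i = w_i^{m-1}/\prod_{j\neq i}(w_i - w_j)$. Two practical notes:

* **All-equal weights** are handled exactly: $-\log Q = (w/2)\,T_{Fisher}$,
  so the null is a scaled $\chi^2_{2m}$ and Good's test coincides with
  Fisher's, as it must.
* **Tied (but not all equal) weights** make the $\Lambda_i$ undefined, and
  *nearly* tied weights make them numerically explosive (catastrophic
  cancellation). The closed form errors on ties and a seeded Monte-Carlo
  null (default $10^6$ draws) is used instead.

## The competitive test

The self-contained null is "this pathway has no effect"; the competitive
null is "this pathway is no more associated than a random gene set of the
same size". `run_competitive()` computes the real pathway's Lancaster
p-value, draws $L$ same-size gene sets from the universe ("shuffling genes
among pathways"; exact size matching is the strictest reading of
size-resemblance and removes a tuning knob), and reports the fraction of
permuted sets at least as significant. Design points:

* Gene weights travel with the gene — weights are gene properties (size,
  MAF summaries), so a shuffled gene keeps its own weight.
* Permuted sets are drawn independently per pathway, avoiding induced
  dependence between pathway results beyond genuine gene sharing.
* The plain estimator can return 0; an add-one correction
  $(1+\text{count})/(1+L)$ is available but off by default, matching the
  plain indicator-fraction estimator.
* Whether the covariance correction is applied inside permuted sets is
  configurable (`correct_permuted`, default the same test as the real
  pathway).

## Bahadur efficiency

The Bahadur slope $c(\theta)$ of a test sequence is the almost-sure limit of
$-2\log P_n / n$ under the alternative; the ratio of two slopes is the
limiting inverse ratio of sample sizes needed to reach the same vanishing
significance level. For per-test slopes $c_i(\theta)$ and sample-size
fractions $\lambda_i$:

| method | slope |
|---|---|
| Lancaster (any weights) / Fisher | $\sum_i \lambda_i c_i$ |
| weighted Z | $\left(\sum_i w_i\sqrt{\lambda_i c_i}\right)^2 / \sum_i w_i^2$ |
| regular Z | $\left(\sum_i \sqrt{\lambda_i c_i}\right)^2 / m$ |
| Good | $\sum_i w_i\lambda_i c_i / \max_i w_i$ |

By Cauchy-Schwarz the weighted-Z slope never exceeds the Lancaster slope
(equality iff all $\lambda_i c_i / w_i^2$ are equal), and term-wise
$w_i/\max w \le 1$ bounds Good's slope (equality iff all weights equal).
The Z-test slopes follow from the derivation: under the alternative
$T/\sqrt n \to \sum_i w_i \sqrt{\lambda_i c_i} / \sqrt{\sum_i w_i^2}$, and
the slope is the square of that limit (the radicals matter — dropping them
breaks both the equal-weight reduction and the Cauchy-Schwarz bound, which
the property tests verify). Correlated (approximate) slopes multiply by a
penalty $\frac{\sum w_i}{\sum w_i + 2\sum\rho_{ij}}$ (Lancaster),
$\frac{m}{m + 2\sum\tilde\rho_{ij}}$ (Fisher) or
$\frac{\sum w_i}{\sum w_i^2 + 2\sum\tilde\rho_{ij}}$ (Good), where
$\tilde\rho_{ij}$ is the covariance of the log p-values. Note the
approximate Good penalty does not reduce to the independent
$\max_i w_i$ form at zero correlation; the two forms come from different
approximation routes and no reconciliation is attempted — `slope_good()`
gives the independent slope, `slope_correlated("good", ...)` the stated
approximation.

$\theta$ never appears as a numeric input: the theory is parameter-free once
the $c_i(\theta)$ are supplied. `empirical_slope()` is a verification
harness: it regresses $-2\log P_n$ on $n$ through the origin, using only the
top half of the sample-size grid because the limit is linear in $n$ and
small $n$ carries pre-asymptotic bias.

## The synthetic-data engine

`sim_scenario()` encodes the full study design; its defaults are the
settings of a whole-exome pathway study: 353 pathways of 10-100 genes over
3304 genes, 822 subjects, one central causal pathway with 50% causal genes,
70% causal variants within causal genes, 80%/20% detrimental/protective
signs at both gene and variant level, whole-genome heritability
$h^2 = 20\%$, and Bonferroni level $0.05/353 = 1.4164\times 10^{-4}$.
Scenario 1 sets all effects to zero (type I error); Scenario 2 draws effect
magnitudes $\propto |\log_{10} \mathrm{MAF}|$; Scenario 3 uses the standard
inverse-standard-deviation law $1/\sqrt{\mathrm{MAF}(1-\mathrm{MAF})}$
(the convention that makes per-variant explained variance roughly
MAF-independent); the harsher literal inverse-variance law
$1/(\mathrm{MAF}(1-\mathrm{MAF}))$ is available as
`effect_law = "inv_var_maf"`.

What the generator emulates, and what it does not:

* **MAF spectrum**: 80% of variants rare (MAF uniform on (0.001, 0.03)),
  the rest uniform on (0.03, 0.5) — rare-variant-heavy like exome data. The
  real 1000 Genomes spectrum is not shipped; the spectrum is configuration.
* **LD**: a blockwise Gaussian-threshold copula (default blocks of 10
  variants, within-block latent correlation 0.5) — haplotype-block-like
  correlation, but no long-range LD, no recombination-rate variation, and a
  single homogeneous population (principal-component adjustment is
  supported but off by default since there is no stratification to remove).
* **Pathway structure**: sizes uniform on 10-100; the gene universe is
  partitioned into cores and pathways borrow genes from other cores (the
  `pathway_overlap` fraction, default 0.1, plus whatever the gene budget
  forces), reproducing overlapping gene sets. Real pathway databases have
  heavier-tailed overlap.
* **Effects and heritability**: the hierarchical model above;
  `scale_noise_to_heritability()` sets
  $\sigma^2 = \mathrm{Var}(X\beta)(1-h^2)/h^2$ so realized heritability
  matches $h^2$ in expectation (verified to within one percentage point at
  $n = 1000$ over 100 replicates).

Consequently, passing calibration and power checks on this generator shows
the statistical machinery is sound under realistic rare-variant
architectures; it does not certify behaviour under population structure,
long-range LD, or real pathway-database topology.

## Scenario evaluation and its numerical choices

`run_scenario()` draws the genotypes and pathway structure once per call and
redraws effects/phenotypes per replicate (fresh phenotypes on fixed
genotypes; resampling subjects is a different, unstated design). The
gene-gene covariance is estimated once per call from `cov_B` (default 200)
null-phenotype resamples on the same genotypes.

* **Fast SKAT nulls**: each gene's eigen-spectrum is fixed, so its null
  survival function is precomputed by exact Imhof inversion on a ~48-point
  quantile grid spanning p down to $10^{-12}$ and interpolated monotonically
  in log p (Hyman spline), with linear log-tail extrapolation beyond the
  grid. Interpolation error is far below Monte-Carlo noise. Single tests via
  `skat_test()` always use the exact inversion.
* **Stringent vs lenient power**: stringent is the fraction of replicates in
  which the central causal pathway is significant; lenient counts replicates
  in which any pathway sharing at least one causal gene with the central one
  (including itself) is significant — the minimal reading of "overlapping
  causal pathways".
* **Information-criterion weights** (`aic`, `bic`): the per-gene criterion
  improvement of the multi-SNP regression over the covariate-only null,
  floored at 0.1 and normalised to median 2 (`gene_ic_delta()` +
  `gene_weights()`). Information-criterion weighting admits several concrete definitions, so this one is an explicit design choice — with one hard
  constraint discovered during calibration: Lancaster weights must be
  independent of the phenotype used for testing. Weights computed from the
  observed $y$ co-vary with the gene p-values, $E(T) = \sum w_i$ fails, and
  the null inflates (a chance-significant gene is simultaneously
  up-weighted, so its extreme transform contribution is amplified).
  `run_scenario()` therefore uses the *expected* floored criterion
  improvement across the null permutation archive — a phenotype-independent
  summary of how much variation each gene's multi-SNP regression captures
  given its size and LD — and the standard Satterthwaite machinery then
  applies unchanged. Users supplying observed-data AIC/BIC weights to
  `pathway_test()` should prefer weights derived from data independent of
  the tested trait for the same reason.
* **Problem sizes**: the calibration suite runs the null scenario at a
  reduced scale (500 subjects, 40 pathways, 300 genes, 500 replicates,
  `cov_B = 200`) chosen so the whole analysis is a desk-scale computation;
  the same code runs the full 353-pathway design by changing the scenario
  object.

## Known limitations

* The Satterthwaite null matches two (or, for IC weights, three) moments;
  extreme tail accuracy beyond roughly $10^{-6}$ is not guaranteed under
  strong correlation (the exact correlated null has no closed form).
* Good's closed-form CDF degrades numerically as weights approach ties;
  use the Monte-Carlo null there.
* Binary traits, burden/SKAT-O gene tests, kinship adjustment, and
  rotation/sample-permutation competitive schemes are out of scope.
* The competitive estimator is granular at $1/L$; choose $L$ accordingly
  (the case-study convention is $L = 10^5$).

## A worked example

```{r example}
set.seed(1)
pw <- build_pathways(n_genes = 60, n_pathways = 6, size_range = c(10, 10),
                     overlap = 0, variants_per_gene_mean = 5, seed = 2)
geno <- simulate_genotypes(300, nrow(pw$variant_map), seed = 3)
eff <- assign_effects(pw$db, pw$variant_map, geno$maf,
                      effect_law = "log10maf", central_pathway = "PW0001",
                      seed = 4)
gv <- as.vector(geno$G %*% eff$beta)
y <- gv + rnorm(300, sd = sqrt(scale_noise_to_heritability(gv, 0.2)))

res <- pathway_test(pw$db, y = y, G = geno$G, variant_map = pw$variant_map,
                    cov_policy = "permutation", cov_B = 200, seed = 5)
res
```

The causal pathway should surface at the top of the table; with only 300
subjects and ten genes per pathway the others stay near-uniform.
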