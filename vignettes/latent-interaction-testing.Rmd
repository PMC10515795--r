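---
title: "Detecting latent genetic interactions from multi-trait variance and covariance patterns"
author: "latentgxe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting latent genetic interactions from multi-trait variance and covariance patterns}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A SNP that interacts with an unobserved variable — an environment, another
locus, anything not in the model — leaves a signature even when the
interacting partner is never measured: the *conditional variance* of an
affected trait, and the *conditional covariance* between affected traits,
change with genotype. Under the single-SNP working model

$$Y_k = \beta_k X + \phi_k M + \gamma_k M X + \varepsilon_k,$$

with latent environment $M$ (mean 0, variance 1) and noise variance
$\sigma_k^2$, the variance of trait $k$ given genotype $X$ is the quadratic

$$\mathrm{Var}(Y_k \mid X) = a_k + b_k X + c_k X^2,
  \qquad a_k = \phi_k^2 + \sigma_k^2,\; b_k = 2\phi_k\gamma_k,\;
  c_k = \gamma_k^2,$$

and the covariance of traits $k, k'$ given $X$ is
$\tilde a + \tilde b X + \tilde c X^2$ with
$\tilde a = \phi_k\phi_{k'}$,
$\tilde b = \phi_k\gamma_{k'} + \phi_{k'}\gamma_k$,
$\tilde c = \gamma_k\gamma_{k'}$
(`itv_itc_coefficients()` returns these reference values; the acceptance
suite recovers them from a large simulation). A genotype-dependent
*covariance* arises as soon as one trait interacts and the other shares the
environment — this is the extra signal a multi-trait test can exploit over
trait-by-trait variance tests.

## The three-step test

**Step 1 — residualize.** Traits are standardized (optionally within
groups such as sex, optionally after removing samples more than 4 SD above
the group mean) and residualized on an intercept, covariates, structure
axes, and the tested SNP's additive effect (`standardize_traits()`,
`residualize()`). Genotypes are residualized on the structure axes
(`adjust_genotype()`). Per SNP the additive effect is removed through the
Frisch–Waugh–Lovell identity — a rank-one update of the covariate-only
residuals — which is algebraically identical to refitting the joint design
and is what makes a biobank-scale scan affordable. Residuals are
studentized by $\sqrt{1-h_{jj}}$ (internal studentization with the joint
design's leverages, exposed as an option) so that squared residuals are
unbiased for the conditional variances.

**Step 2 — SQ/CP.** `compute_sqcp()` forms the $n \times (r + r(r-1)/2)$
matrix $Z$ of squared residuals (SQ, one column per trait) and pairwise
cross products (CP, lexicographic pair order). Columns are mean-centered;
they are deliberately *not* variance-scaled, since the kernel statistic's
null calibration uses the realized column scales and the reference
procedure gives no indication of scaling (we verified in a sensitivity
experiment that scaling changes power by only a few points).

**Step 3 — kernel independence test.** With linear kernels
$K = \tilde X \tilde X'$ and $L = Z Z'$, the statistic is
$T = \mathrm{tr}(KL)/n$. Everything is computed through the thin
factorization of the feature matrices (`spectral_factorize()`): eigenvalues
of the $d \times d$ cross-product, never an $n \times n$ matrix. Writing
$R = V_K' V_L$,

* **wLIT** uses $T = \mathrm{tr}(D_K R D_L R')/n$, whose null is a
  weighted sum of 1-df chi-squares with weights
  $\lambda_{K,i}\lambda_{L,j}/(n(n-1))$;
* **uLIT** weights eigenvectors equally, $T = \lVert R\rVert_F^2/n$, the
  projection-kernel statistic, with null $\chi^2_{d_1 d_2}/(n(n-1))$;
* **aLIT** combines the two p-values with the Cauchy combination test
  (`cauchy_combine()`), valid under arbitrary dependence.

The $n(n-1)$ (rather than $n^2$) denominator matches the exact permutation
mean $E_\pi\,\mathrm{tr}(K L_\pi) = \mathrm{tr}(K)\mathrm{tr}(L)/(n-1)$;
at GWAS sample sizes the two are indistinguishable, at small $n$ the
corrected form tracks permutation p-values visibly better. For small
samples `lit_single_snp(..., permutations = B)` provides a permutation
calibration outright.

The choice between the two weightings is a genuine bias: wLIT concentrates
on the high-variance directions of the SQ/CP kernel and wins when the
interaction loads on them (modest trait correlation, most traits
interacting); uLIT spreads weight equally and wins when the signal hides in
low-variance eigenvectors (high baseline correlation, sparse or
sign-mixed interactions). aLIT hedges between them.

### Weighted chi-squared tail probabilities

`weighted_chisq_sf()` computes $P(\sum w_i \chi^2_{1,i} > q)$:

* equal weights resolve to the exact chi-squared closed form;
* in the central range, Imhof's characteristic-function inversion
  (`stats::integrate`, absolute tolerance $10^{-10}$, cross-checked
  against the saddlepoint to guard against failures of the oscillatory
  integral);
* below $p \approx 10^{-4}$, the Kuonen saddlepoint (Barndorff–Nielsen
  form), which is stable to $10^{-300}$ and was verified against an
  exponentially-tilted Monte-Carlo oracle to within ~10% relative error at
  the genome-wide threshold — on the $-\log_{10}$ scale an error far below
  anything that moves a power estimate.

P-values are floored at $10^{-300}$ to keep log-scale output finite.
Degenerate inputs error early: a monomorphic or structure-explained SNP
(adjusted genotype numerically zero) refuses to test; Z-kernel eigenvalues
below `rank_tol` ($10^{-10}$ relative, a spec for duplicate CP columns)
are dropped, reducing $d_1$.

## Marginal baselines

`marginal_test()` regresses every SQ/CP column on the adjusted SNP (score
test, $z = \sqrt{n}\,\hat\rho$; exact-t option for small samples), takes
the minimum p-value, and Bonferroni-corrects by $K$ = the number of
principal components explaining 95% of the Z matrix's variation
(`effective_tests_K()`, computed on the correlation scale so $K$ is
unit-invariant, and once per dataset — a single SNP's adjustment barely
perturbs Z's covariance). Marginal (SQ) uses the SQ columns only with its
own $K$; Marginal (SQ/CP) uses all columns.

## Robustness layer

* **Genomic control** (`genomic_inflation()`, `gc_adjust()`): the median
  1-df chi-squared quantile over its null median 0.4549; deflation is
  applied to the wLIT and uLIT p-values *before* Cauchy combination, and a
  factor below 1 is never used to inflate significance.
* **LD / additive confounding** (`ld_adjust_retest()`): a neighbor in LD
  whose additive effect is imperfectly removed manufactures
  heteroskedasticity at the lead SNP. Neighbors within the window with
  $|r| > 0.1$ are tested for multivariate additive effects with the same
  kernel machinery applied to the traits themselves
  (`additive_cross_trait_test()`); significant ones are regressed out and
  the lead SNP retested.
* **Dominance / trait scale** (`dominance_retest()`): any genotype-level
  mean function (dominance, or a mis-specified trait scale) also registers
  as a variance pattern; refitting with the 2-df genotypic coding absorbs
  it before retesting. With only two observed genotype levels the 2-df
  coding collapses to additive.
* **Individual-specific allele frequencies** (`iaf_standardize()`): for
  modest n, per-SNP logistic regression of allele counts on structure axes
  gives $\hat\pi_j$ and the variance-standardized genotype
  $(x_j - 2\hat\pi_j)/\sqrt{2\hat\pi_j(1-\hat\pi_j)}$. This is plain
  logistic regression on supplied axes — an approximation to full
  latent-factor frequency estimators, documented as such. The default
  biobank path removes structure means only and relies on genomic control
  for residual variance effects.

We recommend against inverse-Normal transformation of traits before
testing: it does not remove a genotype-dependent mean–variance
relationship and can invalidate inference; the dominance retest is the
supported diagnostic for scale problems.

## The simulator

`sim_config()` / `simulate_lit_data()` generate the study design used for
all power and type-I results:

* genotypes Binomial(2, MAF); the interacting SNP has MAF fixed at 0.25
  (removing MAF-driven power jitter), background SNPs draw MAFs from
  U(0.1, 0.4); `m = 100` SNPs by default, SNPs 2..m acting only through
  the polygenic score;
* two standard-normal environments, one interacting ($M$) and one shared
  non-interacting ($W$);
* each trait is a sum of components, each passed through
  `scale_component()` (empirical mean-0 / sd-1) and scaled by the square
  root of its variance budget: additive risk SNP 0.2%; interacting
  environment U(0.5%, 2%) per trait; GxE (the product $MX$, formed
  *before* standardization) U(0.1%, 0.15%) per trait for the first
  `round(tau * r)` traits; shared polygenic background
  (baseline correlation − 15%); shared environment 15%; the remainder
  noise; plus a Normal(0, 5²) intercept;
* the background score and $W$ are *single realizations shared by all
  traits*. This is what makes the baseline inter-trait correlation equal
  15% + background PVE exactly (0.25/0.50/0.75 for background 10/35/60%);
  independent per-trait draws of the background effects cannot reproduce
  that correspondence, which is why we fixed this reading and did not
  revisit it. The uniform PVE draws are per trait (creating effect-size
  heterogeneity across traits); a per-dataset reading changed measured
  power by a few points only.
* pleiotropy modes set the interaction signs relative to the (positive)
  environment effect: `positive` (all equal), `mixed` (fair-coin signs),
  and `*_opposed` variants with the sign opposite the environment. In the
  mixed mode random signs already make the opposed variant
  distributionally equivalent; it is kept for interface completeness.
* `error_dist` switches the noise among normal, centered-scaled
  $\chi^2_5$ (skewness $\sqrt{8/5}$), and $t_3$ (heavy tails) for the
  null studies.

What the generator does **not** emulate: linkage disequilibrium between
the simulated SNPs, population structure / admixture (beyond the toy
two-population check of the IAF path), relatedness, missing genotypes, and
measured covariates. Passing the simulation suite therefore demonstrates
calibration and power under the idealized polygenic GxE design, not
robustness to structure or LD — those are exercised separately by the
adjustment-layer property tests with explicitly constructed confounds.

## Experiment drivers and problem sizes

`power_experiment()` simulates each design cell end-to-end and tests only
the interacting SNP per replicate, drawing the background score directly
(the same model, without storing the genotype matrix). We run 200
replicates per cell at n = 300,000 (binomial SE at most 3.5 percentage
points) in both the acceptance script and the acceptance tests — the
replicate count is the package's chosen desk-scale version of the
reference 500-replicate protocol. `type1_experiment()` scans every
simulated SNP; the reported study uses 10 datasets × 10,000 SNPs at
n = 20,000 with the three error distributions cycling across datasets,
pooling 10⁵ tests per method at α = 10⁻³. Genotypes are generated in
chunks twice with recorded RNG states (two-pass replay), so memory stays
at O(n · chunk) while the traits' polygenic background still comes from
the full tested panel.

Two measured departures from the reference results are recorded here for
transparency. First, under $t_3$ noise the eigenvalue-weighted kernel is
anti-conservative at $\alpha = 10^{-3}$ (about 2x the nominal rate, at
n = 20,000 and unchanged at n = 300,000), while the equally-weighted
kernel remains calibrated: with an infinite fourth moment of the squared
residuals, the cross products $\tilde X' Z$ are dominated by a few
extreme points and the chi-squared-mixture tail is too light for the
weighted statistic; the projection statistic self-normalizes. Normal and
$\chi^2_5$ noise are calibrated for all methods. Users analyzing very
heavy-tailed traits should rely on uLIT or a variance-stabilizing
transformation chosen by goodness of fit. Second, in the positive-pleiotropy cell with 5 traits, baseline
correlation 0.25 and 80% of traits interacting, our aLIT power is ~73%
against a published 53%, driven entirely by the eigenvalue-weighted
kernel; the equally-weighted kernel, the marginal procedures, and all
other cells (including all three τ = 0.5 cells and the 10-trait cell of
the same design) agree with the published values within Monte-Carlo
error. Sensitivity experiments (uncentered kernels, variance-scaled Z
columns, per-dataset effect draws, alternative product standardization)
moved our value far from both numbers or not at all, and our tail
calibration is verified independently by permutation and tilted
Monte-Carlo oracles, so we report the measured value rather than tune the
generator toward the published one.

## Genome-scan engineering

`lit()` standardizes and residualizes once, then processes SNPs in chunks
(C++ core: mean imputation, centering, rank-one additive removal,
leverage studentization, SQ/CP cross products, and the small
eigen-decompositions), returning results in input order; peak memory is
O(n(r+s) + n·chunk). Results are invariant to chunk size. The SQ/CP
matrix is rebuilt per SNP from the covariate-residualized traits — the
exact computation, not the approximation that reuses one global Z.
P-values are written in scientific notation with 6 significant digits via
`write_lit_scan()`.

## Known limitations

* The asymptotic null is a first-moment-corrected chi-squared mixture;
  below n ≈ a few hundred, use `permutations =` in `lit_single_snp()`.
* A detection is evidence of *some* non-additive relationship involving
  the SNP — GxE, GxG, parent-of-origin, or scale misspecification are not
  distinguishable; the dominance and LD retests narrow, but cannot
  eliminate, the last cause.
* The test does not identify which trait drives a signal; run
  `marginal_test()` at the lead SNP to rank traits and pairs.
* Individuals are assumed unrelated; no mixed-model adjustment is
  provided.
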