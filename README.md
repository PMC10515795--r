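# latentgxe

Kernel-based detection of **latent genetic interactions** — gene–environment
or gene–gene effects whose interacting partner is never observed — from
multiple correlated traits in GWAS-scale data.

## The idea

A SNP `X` that interacts with an unobserved variable `M` leaves a
fingerprint on the *second moments* of the traits. Under

```
Y_k = beta_k X + phi_k M + gamma_k M X + eps_k
```

the variance of trait `k` given genotype is the quadratic
`Var(Y_k | X) = (phi_k^2 + sigma_k^2) + 2 phi_k gamma_k X + gamma_k^2 X^2`,
and the covariance of two traits given genotype is
`phi_k phi_k' + (phi_k gamma_k' + phi_k' gamma_k) X + gamma_k gamma_k' X^2`.
So after removing additive effects, the **squared residuals** (SQ,
individual-specific trait variances) and **pairwise residual cross
products** (CP, individual-specific covariances) carry the interaction
signal — without ever specifying or measuring `M`.

The package tests independence between the `n x (r + r(r-1)/2)` SQ/CP
matrix `Z` and the adjusted genotype with a Hilbert–Schmidt
independence-criterion statistic `T = tr(K L) / n` built from linear
kernels, computed through thin spectral factorizations (never an `n x n`
matrix):

* **wLIT** — eigenvalue-weighted form `tr(D_K R D_L R') / n`,
  `R = V_K' V_L`; null: weighted sum of 1-df chi-squares
  (Imhof inversion + saddlepoint tail);
* **uLIT** — equally-weighted (projection-kernel) form `||R||_F^2 / n`;
  null: chi-squared with `d1 d2` df;
* **aLIT** — Cauchy combination of the two p-values (neither weighting
  dominates across genetic architectures; the combination hedges).

Baselines (`marginal_test()`: minimum-p over SQ/CP columns with a
principal-component Bonferroni correction), robustness adjustments
(genomic control, LD/additive retest, 2-df dominance/scale retest, IAF
genotype standardization), a PLINK 1 reader/writer and chunked genome-scan
driver (`lit()`), and the polygenic GxE simulator used for the power and
type-I studies are all included.

## Worked example

```r
library(latentgxe)
set.seed(1)
n <- 5000
x <- rbinom(n, 2, 0.3)           # tested SNP
M <- rnorm(n)                    # latent environment (never observed)
traits <- cbind(
  bmi = 0.20 * x + 0.3 * M + 0.15 * M * x + rnorm(n),
  whr = 0.10 * x + 0.3 * M + 0.12 * M * x + rnorm(n),
  bfp =            0.3 * M +                rnorm(n))

ys  <- standardize_traits(traits)
res <- studentize_residuals(residualize(ys, genotype = x))
Z   <- compute_sqcp(res)         # 3 SQ + 3 CP columns
lit_single_snp(Z, adjust_genotype(x), snp_id = "rs_demo")
#> Latent-interaction kernel test (n = 5000 , d1 = 6 , d2 = 1 )
#>   snp_id T_wlit    p_wlit   T_ulit    p_ulit    p_alit d1 d2 n_used
#>  rs_demo   22.9 3.609e-05 1.05e-06 0.0002006 6.118e-05  6  1   5000
```

Two traits interact with the latent environment; both kernels detect the
genotype-dependent variance/covariance pattern (`p_wlit`, `p_ulit`), and
`p_alit = 6.1e-5` is their Cauchy combination. The marginal baseline sees
the same signal concentrated in the bmi–whr cross product, but pays a
6-fold multiplicity price:

```r
marginal_test(Z, adjust_genotype(x), alpha = 5e-8)
#> Marginal SQ/CP association test (6 columns, n = 5000)
#>   min p = 3.773e-05 at CP:bmi.whr
#>   K = 6, alpha' = 8.333e-09 -> not significant
```

A genome scan takes traits plus a dosage matrix or a PLINK 1 fileset and
returns one row per SNP (`p_wlit`, `p_ulit`, `p_alit`, ranks, MAF), with
QQ plots via `plot()` and genomic-control adjustment via
`gc_correct = TRUE`:

```r
d  <- simulate_lit_data(sim_config(n = 2000, r = 4, m = 50,
                                   baseline_corr = 0.25, tau = 0.5))
sc <- lit(d$traits, d$genotypes)
summary(sc)
```

A thin CLI over the same functions lives at `inst/cli/latentgxe`
(subcommands `scan`, `simulate`, `typeI`, `power`, `inflation`).

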