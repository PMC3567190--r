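# bslmm — Bayesian Sparse Linear Mixed Models for Polygenic Modeling

`bslmm` fits the Bayesian sparse linear mixed model (BSLMM) to
quantitative (and 1/0-coded binary) traits for two polygenic-modeling
tasks in genome-wide association data:

1. **PVE estimation** ("chip heritability"): the proportion of phenotypic
   variance explained jointly by all genotyped markers, together with PGE,
   the share of that genetic variance attributable to large sparse
   effects.
2. **Phenotype prediction** (breeding-value prediction) for individuals
   not used in training.

## The model

For phenotypes $y$ on $n$ individuals and a centered $n \times p$ dosage
matrix $X$,

$$
y = 1\mu + X\beta + u + \epsilon,\qquad
u \sim \mathcal N\!\big(0,\ \sigma_b^2 \tau^{-1} K\big),\qquad
\epsilon \sim \mathcal N\!\big(0,\ \tau^{-1} I\big),
$$

$$
\beta_j \sim \pi\,\mathcal N\!\big(0,\ \sigma_a^2 \tau^{-1}\big)
          + (1-\pi)\,\delta_0 ,
$$

where $K = XX^\top/p$ is the genomic relatedness matrix. The point-normal
("spike and slab") prior on the sparse effects $\beta$ combined with the
polygenic random effect $u$ bridges two standard models: at $\rho = 0$ the
model is the linear mixed model (ridge regression / BLUP), at $\rho = 1$
it is Bayesian variable selection regression (BVSR). Here $(h, \rho)$ are
the hyper-parameters that approximate the expected PVE and PGE; they and
$\log\pi$ carry uniform priors ($\log\pi$ over $[\log(1/p), 0]$), and
$\mu, \tau$ carry the standard improper priors, which makes all inferences
invariant to shifting and rescaling of the phenotype.

Per posterior draw the package reports

$$
\mathrm{PVE} = \frac{V(X\beta + u)}{V(X\beta + u) + 1/\tau},\qquad
\mathrm{PGE} = \frac{V(X\beta)}{V(X\beta + u)},\qquad
V(x) = \tfrac1n \sum_i (x_i - \bar x)^2 ,
$$

plus per-marker posterior inclusion probabilities and posterior mean
effects.

Inference is Metropolis–Hastings over $(\gamma, h, \rho, \log\pi)$, where
$\gamma$ is the set of markers with nonzero sparse effect: $\beta_\gamma$,
$\mu$, $\tau$ and $u$ are integrated out analytically, and a single
eigendecomposition of $K$ makes every likelihood evaluation linear in $n$.
Additions to $\gamma$ use a rank-based proposal concentrating on markers
with strong marginal associations. The per-iteration work is implemented
in C++ (RcppArmadillo).

## Worked example

Everything below is synthetic, generated by the package's own simulator
(10 causal SNPs out of 1,000; the residual noise is rescaled so the
realized PVE is exactly 0.6):

```r
library(bslmm)
set.seed(42)
geno <- simulate_genotypes(n = 300, p = 1000, maf_range = c(0.05, 0.5))
geno <- impute_and_center(geno)
sim  <- simulate_scenario1(geno, S = 10, target_pve = 0.6)
kin  <- compute_kinship(geno)

fit <- run_mcmc(geno, sim$phenotype, kin,
                chain = chain_config(n_iter = 2e4, burn_in = 5e3,
                                     thin = 10, seed = 7))
print(fit)
#> bslmm_fit (mode bslmm): n = 300, p = 1000, 2000 kept draws
#>   PVE 0.661 (0.058)   PGE 0.882 (0.086)   mean |gamma| 10.2
```

The posterior mean PVE 0.661 (posterior sd 0.058) brackets the true value
0.6; PGE near 0.9 and a posterior median of rho of 0.87 correctly identify
a sparse architecture; the mean model size (10.2) matches the 10 simulated
causal SNPs. The five markers with the highest posterior inclusion
probability are all truly causal:

```r
top <- order(fit$pip, decreasing = TRUE)[1:5]
data.frame(marker = geno$marker_ids[top], pip = round(fit$pip[top], 3),
           beta = round(fit$beta_mean[top], 3),
           causal = top %in% sim$truth$causal_ids)
#>   marker   pip   beta causal
#> 1 snp526 1.000  1.885   TRUE
#> 2 snp672 1.000  1.453   TRUE
#> 3 snp826 1.000  1.494   TRUE
#> 4 snp921 1.000  1.971   TRUE
#> 5 snp833 0.879 -1.455   TRUE
```

For comparison, the pure mixed model overestimates PVE on this sparse
architecture (a known behavior — its estimate is far more variable when
few SNPs carry the signal):

```r
rem <- reml_lmm(transform_data(sim$phenotype$values, kin))
#> REML LMM: pve_hat = 0.819 (se 0.109)
```

Prediction for held-out individuals uses `predict(fit, g_test, kin_cross)`
(posterior-mean sparse part plus BLUP transfer of the random part) and is
evaluated with `rmse()`, `correlation()`, `rpg()` (relative predictive
gain: 0 = mean predictor, 1 = best achievable), and for binary traits
`auc()`/`brier()` with `liability_correction()` for observed-scale PVE.

A command-line interface covers the same pipeline:

```sh
Rscript inst/cli/bslmm.R simulate --n 500 --p 2000 --pve 0.6 --out sim
Rscript inst/cli/bslmm.R fit --geno sim.geno.txt --pheno sim.pheno.txt --out fit
Rscript inst/cli/bslmm.R predict --train-geno ... --test-geno ... --param fit.param.txt --hyp fit.hyp.txt --out pred
Rscript inst/cli/bslmm.R evaluate --pred pred.pred.txt --pheno test.pheno.txt --out eval
```

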