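---
title: "Methods: the Bayesian sparse linear mixed model in bslmm"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the Bayesian sparse linear mixed model in bslmm}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model and its assumptions

`bslmm` models a quantitative trait $y$ ($n$ individuals) against a
centered dosage matrix $X$ ($n \times p$, dosages 0/1/2, columns centered
but deliberately **not** standardized) as

$$
y = 1\mu + X\beta + u + \epsilon,\qquad
u \sim \mathcal N(0, \sigma_b^2 \tau^{-1} K),\qquad
\epsilon \sim \mathcal N(0, \tau^{-1} I),
$$

with a point-normal prior on each sparse effect,
$\beta_j \sim \pi \mathcal N(0, \sigma_a^2 \tau^{-1}) + (1 - \pi)\delta_0$,
and $K = XX^\top / p$ the genomic relatedness matrix (mean diagonal
$s_b$). With this choice of $K$ the model is equivalent to giving every
marker a normal "background" effect plus, for a proportion $\pi$ of
markers, an additional large effect: the random term is the polygenic
component, the sparse term the large effects above it. Setting the
mixture entirely on one side recovers the two standard polygenic models —
the linear mixed model (LMM/ridge/BLUP; every marker a small effect) and
Bayesian variable selection regression (BVSR; few markers, larger
effects). Which regime fits a given trait is usually unknown; the point of
the hybrid is that the data decide.

Binary 1/0 traits are handled by fitting them as quantitative; predicted
values are interpreted as case probabilities (clamped to $[0,1]$ for the
Brier score), and `liability_correction()` maps observed-scale PVE to the
liability scale given prevalence and sample case fraction.

## Hyper-parameters and priors

Raw variances $(\sigma_a^2, \sigma_b^2)$ are hard to set priors for
because their effect depends on $p$, $\pi$ and the genotype scale. The
model is therefore re-parameterized through the expected (relative)
genetic variances $A = p \pi s_a \sigma_a^2$ (sparse; $s_a$ = average
per-marker genotype variance) and $B = s_b \sigma_b^2$ (random):

$$
h = \frac{A + B}{1 + A + B}, \qquad \rho = \frac{A}{A + B},
$$

so $h$ approximates the expected PVE and $\rho$ the expected PGE — ratios
of expectations rather than expectations of ratios. Priors:

* $h \sim U(0, 1)$, $\rho \sim U(0, 1)$ — roughly uniform induced priors
  on PVE and PGE, a neutral default;
* $\log \pi \sim U(\log(1/p), 0)$ — the expected number of included
  markers spans 1 to $p$ uniformly on the log scale, reflecting
  order-of-magnitude uncertainty ($\pi$ is stored and proposed on the log
  scale throughout for this reason);
* $\mu$ flat and $p(\tau) \propto 1/\tau$ (the improper shape/rate
  $\to 0$ Gamma limit). These make the posterior over
  $(\gamma, h, \rho, \pi)$ exactly invariant to shifting or rescaling the
  phenotype (a property the test suite asserts), and they contribute no
  density terms of their own.

PVE and PGE are *estimated* from their realized-variance definitions, not
from $(h, \rho)$: each kept draw samples $(\tau, \mu, \beta_\gamma, u)$
from their exact joint conditional and evaluates
$\mathrm{PVE} = V(X\beta + u)/(V(X\beta + u) + 1/\tau)$,
$\mathrm{PGE} = V(X\beta)/V(X\beta + u)$ with $V$ the divisor-$n$
variance. Note that per realization $V(X\beta)/V(X\beta+u)$ can
marginally exceed 1 when $u$ is anticorrelated with $X\beta$; only in
expectation is PGE bounded. Recorded draws are clamped to $[0, 1]$, and
PGE is defined as 0 on the measure-zero event $V(X\beta + u) = 0$.

# The marginal likelihood in the eigenbasis

The key computation is $P(y \mid \gamma, h, \rho, \pi)$ with
$\beta_\gamma$, $\mu$, $\tau$ and $u$ integrated out. One
eigendecomposition $K = U \,\mathrm{diag}(\delta)\, U^\top$ at the start
turns the covariance $\tau^{-1}(\sigma_b^2 K + I)$ diagonal in the rotated
coordinates $\tilde y = U^\top y$, with weights
$d_i = 1/(\sigma_b^2 \delta_i + 1)$. Writing $\langle a, b\rangle_d$ for
the $d$-weighted inner product of transformed vectors,
$s_{11} = \langle 1, 1\rangle_d$, and projecting the $q = |\gamma|$
included columns orthogonally to the intercept in that metric,

$$
\log P(y \mid \gamma, \cdot) = c_0
  + \tfrac12 \textstyle\sum_i \log d_i
  - \tfrac12 \log s_{11}
  - \tfrac12 \log \det A
  - \tfrac{q}{2} \log \sigma_a^2
  - \tfrac{n-1}{2} \log S,
$$

where $A = G_c + \sigma_a^{-2} I$ with $G_c$ the projected weighted Gram
matrix of the $\gamma$ columns, $S$ the generalized-least-squares residual
sum of squares, and
$c_0 = -\frac{n-1}{2}\log 2\pi + \log\Gamma(\frac{n-1}{2}) +
\frac{n-1}{2}\log 2$. The expression is kept fully normalized (with
respect to the improper priors), which costs nothing and lets the test
suite compare absolute values against brute-force quadrature over
$(\mu, \beta, \log\tau)$ on tiny instances (to $10^{-3}$ log units) and
against dense-matrix evaluation with explicit inverses and determinants
(to $10^{-8}$). One evaluation costs $O(nq + q^3)$; no $n \times n$
operation recurs after the initial eigendecomposition, keeping the
per-iteration burden linear in $n$. The $q \le n - 2$ bound is enforced
because the flat-$\mu$ and $\tau$ integrals need residual degrees of
freedom.

The intercept is handled inside the GLS projection rather than by
pre-centering $y$: $U^\top 1$ is not a constant vector, so the flat-$\mu$
integral has to be done in the transformed basis.

Conditional draws of $(\tau, \mu, \beta_\gamma, u)$ reuse the same
quantities: $\tau$ from its Gamma conditional, $(\mu, \beta_\gamma)$ from
the Gaussian conditional around the GLS solution, and $u$ coordinatewise
in the eigenbasis with mean $\sigma_b^2 \delta_i d_i r_i$ and variance
$\sigma_b^2 \delta_i d_i / \tau$ given the residual $r$. $V(\cdot)$ for
PVE/PGE is computed without rotating back (orthonormality preserves norms
and $1^\top x = (U^\top 1)^\top (U^\top x)$).

# The sampler

Metropolis–Hastings over $(\gamma, h, \rho, \log\pi)$. Each iteration
proposes either (probability `hyper_move_prob`, default 0.3) a
hyper-parameter move or a $\gamma$ move.

**$\gamma$ moves.** Single moves are add / remove / swap with default mix
0.4/0.4/0.2 (renormalized when a type is unavailable), plus a 5% chance of
a compound move chaining 2–5 elementary moves. Additions use a rank-based
kernel: markers are ranked once by squared marginal correlation with the
phenotype, and the proposal weight of the excluded marker of rank $r$ is
proportional to $\kappa^r$ (`geometric_rank_param`, default 0.3), mixed
with a uniform component of weight `unif_mix` (default 0.3). The uniform
floor keeps every marker reachable — a pure geometric kernel with
$\kappa = 0.3$ underflows past rank $\sim 650$ and would make
high-rank markers unreachable in finite chains. Removals are uniform over
included markers; swaps compose both. The exact forward and reverse
densities (including the state-dependent move-type renormalization and,
for compound moves, every intermediate state) enter the acceptance ratio;
a detailed-balance test verifies the returned log ratio against
independently computed densities for all single moves, and the
enumeration test (below) exercises the compound bookkeeping.

**Hyper moves.** Symmetric uniform random-walk steps reflected into the
support: half-widths 0.02 for $h$ and $\rho$ and $0.1\log p$ for
$\log\pi$. One third of hyper moves update $\log\pi$ alone: such moves
leave $\sigma_b^2$ — and therefore the weights $d_i$ and the cached
weighted Gram matrix — untouched, so they cost $O(q)$ instead of
$O(nq^2)$, and they decorrelate $\pi$ from the expensive coordinates.
Proposal-mix values were chosen to land in the 20–40% acceptance range on
simulated defaults and are all exposed in `proposal_config()`.

**Model size cap.** $q$ is softly capped at $\min(n - 2, 300)$; proposals
beyond the cap are auto-rejected (and counted). This preserves the
stationary distribution restricted to the valid region and bounds the
per-iteration cost.

**Modes.** `bvsr` pins $\rho = 1$ ($\sigma_b^2 = 0$); `lmm_bayes` pins
$\gamma = \emptyset$, $\rho = 0$, $\pi$ at its lower bound and samples
only $h$; `bslmm_eb` first runs `reml_lmm()` on the null model, pins
$\sigma_b^2$ at the REML estimate, and treats $\rho$ as the coordinate
derived from $h$ under that constraint (proposals whose derived $\rho$
leaves $[0,1]$ are rejected). The `fix` argument pins arbitrary subsets,
which is how the special-case consistency tests compare `bslmm` with
$\rho$ forced to 0 or 1 against `lmm_bayes` and `bvsr`.

**Initialization.** $\gamma$ starts as the top-ranked
$\max(1, \min(10, \lceil p e^{E[\log\pi]} \rceil))$ markers, $h = \rho =
0.5$, $\log \pi$ at the middle of its range; a non-finite likelihood at
initialization triggers up to 10 jittered re-initializations.

**Determinism.** A single seeded generator (R's stream, consumed by the
C++ core through the R API) drives every stochastic operation; identical
seed and configuration give bit-identical output, which the suite
asserts.

**REML.** `reml_lmm()` maximizes the $\gamma = \emptyset$ marginal
likelihood — which under the improper $\mu, \tau$ priors is the
restricted likelihood — over $\log \sigma_b^2$ by Brent-style 1-D
optimization on $[10^{-5}, 10^5]$ (the usual variance-ratio bracket in
LMM software). $\widehat{\mathrm{PVE}} = s_b\hat\lambda/(s_b\hat\lambda +
1)$; its standard error comes from the observed information on the log
scale by the delta method. A flat likelihood (e.g. $K = 0$) or an optimum
at the bracket returns a boundary flag instead of an error.

# The synthetic-data generator

The generator is the package's stated world for testing, mirroring the
benchmark designs used for this model class (which were run on real
genotypes unavailable here):

* **Genotypes**: per-marker MAF uniform on $[0.05, 0.5]$ by default;
  dosages are sums of two Bernoulli(MAF) haplotype alleles. Optional local
  LD: within blocks of `ld_block` consecutive markers each haplotype
  allele is copied from the block's first marker with probability 0.7.
  There is no population structure, no relatedness beyond chance sharing,
  no MAF–effect-size coupling, and no genotyping error.
* **Scenario I**: $S$ causal SNPs drawn uniformly, effects standard
  normal. Spans sparse ($S = 10$) through fully polygenic ($S = p$)
  architectures.
* **Scenario II**: a small moderate-effect group plus a large
  polygenic group, both standard normal, with the moderate group rescaled
  so its realized share of genetic variance equals `pge_target` exactly
  (a quadratic accounting for the realized covariance between group
  contributions). The variance split between groups is a free parameter
  (default 0.3) since the benchmark designs do not pin it.
* **Exact realized PVE**: residual noise is rescaled per replicate so
  that $V(g)/(V(g) + V(e))$ equals the target exactly (to $10^{-12}$),
  rather than only in expectation. Each simulated dataset therefore has a
  single well-defined "true PVE" to recover, which is what the recovery
  tests compare against.

A green recovery test therefore establishes that the sampler recovers PVE
and identifies architecture *under this idealized world at reduced
scale*; it says nothing about confounding by population structure,
ascertainment, LD with untyped causal variants, or real minor-allele
spectra.

# Numerical choices

* Eigenvalues of $K$ below $10^{-8}\lambda_{\max}$ (including round-off
  negatives; $K$ has rank $\le \min(n-1, p)$ by construction) are clamped
  to exactly 0.
* Missing dosages are mean-imputed per marker before centering (common
  LMM practice); a fully missing marker is an error naming the marker.
* Kinship files are symmetrized as $(K + K^\top)/2$ when the asymmetry is
  within $10^{-6}$, rejected otherwise.
* Individuals with missing phenotypes are dropped from the training
  arrays *after* kinship construction, so the train/test cross-blocks
  needed for prediction exist; the training kinship submatrix is
  re-eigendecomposed.
* $\sigma_a^2 = 0$ (reachable at $\rho = 0$) short-circuits to the
  $q = 0$ likelihood path instead of dividing by zero; the $\sigma_a^2
  \to 0$ limit is continuous, which a test asserts.
* The weighted Gram matrix is updated incrementally across $\gamma$ moves
  (each entry computed exactly once under the current weights, so there is
  no error accumulation) and rebuilt from the cached transformed columns
  whenever an accepted hyper move changes $\sigma_b^2$.
* Test dosages are centered with *training* column means; prediction
  never sees the test distribution.
* Ties in the marker ranking break deterministically by marker index;
  ties in AUC scores get half credit.

# Design choices where the design was open

* The elementary-move mix, geometric decay, uniform floor and compound
  scheme of the $\gamma$ kernel are implementation choices (the published
  description of the rank-based proposal leaves them open); they are
  validated by exactness tests (enumeration, detailed balance) rather
  than by reference to a fixed specification, and every constant is a
  visible `proposal_config()` field.
* `n_iter` counts post-burn-in iterations, with `burn_in` separate —
  matching the "burn-in plus sampling" way chain lengths are quoted.
* Draw-averaged prediction (averaging the full BLUP expression over kept
  draws) is available alongside the default posterior-mean plug-in, but
  each draw costs a dense solve, so it subsamples kept draws
  (`ndraws`, default 100) and requires the fit to retain effect draws and
  the training design.
* The liability-scale correction uses the standard
  prevalence/ascertainment factor
  $K^2(1-K)^2 / (z^2 P(1-P))$ and is validated against a
  liability-threshold simulation oracle.
* No modification of the kinship diagonal is applied (some LMM software
  slightly adjusts it; we keep the plain $XX^\top/p$).
* The prior range for $\pi$ is exactly $[1/p, 1]$.

# Known limitations

* Likelihood evaluations keep the full $U^\top X$ matrix in memory
  ($8np$ bytes); at the package's design scale ($n \sim 10^3$–$10^4$,
  $p \sim 10^4$–$10^5$) this is the practical bound.
* The sampler is a single chain; convergence diagnostics beyond
  acceptance rates and the recorded traces are out of scope.
* Binary traits use the quantitative-trait likelihood (no probit link);
  this is the deliberately simple strategy the model class is usually run
  with, and the liability correction applies only to the PVE scale, not
  to individual predictions.
* `h` mixes by reflected random walk; posteriors tightly concentrated
  near a boundary mix slowly at the default step size (the consistency
  tests widen the steps for exactly this reason).
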