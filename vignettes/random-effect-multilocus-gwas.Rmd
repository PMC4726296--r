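---
title: "Random-SNP-effect mixed linear models for multi-locus GWAS: methods and design"
author: "rmlmgwas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Random-SNP-effect mixed linear models for multi-locus GWAS: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rmlmgwas)
```

## The model

For a quantitative trait measured on $n$ individuals genotyped at $m$
biallelic markers coded $z \in \{1, 0, -1\}$ (one homozygote, the
heterozygote, the other homozygote), the per-marker model is

$$ y = X\beta + z_k \gamma_k + u + \varepsilon, \qquad
   \gamma_k \sim N(0, \sigma_k^2), \quad
   u \sim MVN(0, \sigma_g^2 K), \quad
   \varepsilon \sim N(0, \sigma^2 I). $$

Unlike the common fixed-SNP-effect mixed linear model, the tested SNP
effect $\gamma_k$ is itself a random variable with its own variance
$\sigma_k^2$. Writing $\lambda = \sigma_g^2/\sigma^2$ and
$\lambda_k = \sigma_k^2/\sigma^2$,

$$ \mathrm{Var}(y) = \sigma^2\,(\lambda_k z_k z_k' + \lambda K + I). $$

Because the predicted (BLUP) effects are shrunken toward zero, the scan can
use a *modified* Bonferroni correction based on the effective number of
independent markers $m_e \le m$ rather than the raw marker count — the
practical payoff of the random-effect treatment.

### Whitening and P3D

With the eigen-decomposition $K = U D U'$, rotating everything by $U'$
turns the polygenic covariance into the diagonal $\lambda D + I$. The
ratio $\lambda$ is estimated **once**, by REML under the pure polygenic
null model (Brent search on $\log_{10}\lambda \in [-5, 5]$), and then held
fixed for every marker — the "population parameters previously defined"
(P3D) device. A degenerate spectrum (e.g. $K = I$), under which $\lambda$
is unidentifiable, yields $\hat\lambda = 0$ with a warning.

### The per-marker profile and its closed form

Given $R = \hat\lambda D + 1$, each marker's covariance is the rank-one
update $\Sigma(\lambda_k) = \lambda_k z^* z^{*\prime} + \mathrm{diag}(R)$
(stars denote rotated quantities). The Woodbury identities make
$\Sigma^{-1}v$ and $\log|\Sigma|$ O(n). Three scalars per marker,

$$ a = z^{*\prime} P z^*, \qquad t_0 = z^{*\prime} P y^*, \qquad
   r_0 = y^{*\prime} P y^*, $$

with $P$ the REML projection under $R$ alone, determine the whole profiled
restricted likelihood:

$$ \ell_R(\lambda_k) = \mathrm{const} - \tfrac12\Big[\log(1+\lambda_k a)
   + (n-q)\,\log\Big(r_0 - \frac{\lambda_k t_0^2}{1+\lambda_k a}\Big)\Big]. $$

Its score has a single interior root: in $u = \lambda_k a/(1+\lambda_k a)$,

$$ u^\ast = \frac{(n-q)\,b - r_0}{(n-q-1)\,b}, \qquad b = t_0^2/a, $$

valid when $(n-q)b > r_0$ (otherwise the boundary $\hat\lambda_k = 0$
applies). The Newton iteration on the analytic first and second
derivatives, with step-halving and a grid-plus-Brent fallback
(`newton_optimize_lambda_k()`), converges to this point; the vectorised
genome scan evaluates the same algebra for all markers at once, which is
why a 2 000-marker scan takes a fraction of a second. The BLUP and its
conditional variance follow as
$\hat\gamma_k = u\,t_0/a$ and
$\mathrm{Var} = \hat\sigma^2 u/a$, giving the Wald statistic
$W = \hat\gamma_k^2/\mathrm{Var}$, referred to $\chi^2_1$, and
$\mathrm{LOD} = W/(2\ln 10)$.

### Thresholds

* Random-effect scan: $p \le \alpha/m_e$ with $m_e$ the Li–Ji-style sum of
  $\mathbb{1}(\lambda_i \ge 1) + (\lambda_i - \lfloor\lambda_i\rfloor)$
  over eigenvalues of the marker correlation matrix, evaluated in
  consecutive within-chromosome blocks of 133 markers (linkage
  disequilibrium is local; the block estimator is exposed as a pluggable
  strategy).
* Fixed-effect (EMMA-style) baseline: plain Bonferroni $\alpha/m$ — the
  familiar 5e-8 at one million markers — with exact GLS F p-values.

## The multi-locus second stage

1. **Preselection.** All markers with scan $p < 0.01$ survive; walking
   them in ascending $p$, any further marker within the pruning window
   (±1 kb for simulated data, ±20 kb for real data; closed intervals) of
   a kept marker is eliminated to control collinearity.
2. **Classification.** Survivors that also pass $\alpha/m_e$ receive a
   single-marker ML likelihood ratio test; LOD > 1.5 makes the marker a
   *fixed* effect in the joint model, otherwise it stays *random*.
3. **Joint fit.** All survivors enter one model, fitted by EM empirical
   Bayes: each random effect has its own variance with a scaled
   inverse-chi-square prior $(\tau, \omega) = (-2, 0)$ — a flat prior, so
   the M-step is simply $\sigma_k^2 = E(\gamma_k^2 \mid y)$. The polygenic
   background is retained through the whitening weights (a switch
   disables it). The marginal likelihood is non-decreasing across
   iterations; because a vanishing effect variance decays only like
   1/iteration under EM, a boundary-polish step periodically zeroes any
   variance whose removal does not lower the marginal likelihood.
4. **Per-marker LRT.** Each marker is removed (variance to zero, or column
   out of the design), all remaining parameters re-converged from a warm
   start, and $\mathrm{LRT} = 2(\ell_{\mathrm{full}} - \ell_{\mathrm{red}})$
   referred to $\chi^2_1$. If a reduced fit ever dominates the full fit
   (an EM convergence artefact), the full fit is re-converged from the
   reduced solution, which the full model nests, restoring
   $\mathrm{LRT} \ge 0$.
5. **Declaration.** QTNs are markers with LOD ≥ 3 (inclusive), i.e.
   $p \le 0.0002$ under $\chi^2_1$ — slightly stricter than 0.05 because
   stage 1 already selected, but with no further multiplicity correction
   thanks to the multi-locus shrinkage. Calls report
   $r^2 = \mathrm{var}(z_k\hat\gamma_k)/\mathrm{var}(y)$, and the called
   set's fit is summarised by an ordinary-regression BIC
   ($-2\ell + k\ln n$, $k$ counting coefficients plus the residual
   variance, with a $10^{-8}\mathrm{var}(y)$ floor for degenerate perfect
   fits).

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `alpha` | 0.05 | genome-wide level for scan thresholds |
| `p_select` | 0.01 | stage-1 preselection threshold |
| `window_bp` | 1 000 (simulated) / 20 000 (real) | positional pruning half-window, bp |
| `lod_threshold` | 3.0 | final QTN criterion (= p 0.0002) |
| LOD fixed/random | 1.5 | classification cutoff in stage 2 |
| `me_block` | 133 | markers per correlation block for $m_e$ |
| `(tau, omega)` | (-2, 0) | effect-variance prior; flat by default |
| EM `tol`, `max_iter` | 1e-6, 1000 | parameter-change and likelihood-gain stopping |

The EM iteration cap is higher than the few hundred iterations typically
needed because correlated selected markers can converge slowly; iterations
are O(t³) in the handful of selected markers and essentially free.

## The synthetic data generator

The generator reproduces the evaluation designs as stated: n = 199
individuals (also 149 and 99), six additive QTNs at allele frequency 0.30
with heritabilities (0.10, 0.05, 0.05, 0.15, 0.05, 0.05), phenotypic mean
10.0, residual variance 10.0; optionally an additive polygenic component
explaining 0.092 of the phenotypic variance (drawn MVN with the
marker-inferred kinship) and three epistatic pairs each explaining 0.05,
encoded as the elementwise product of the two coded QTN columns and
spanning chromosome pairs (4,2), (2,3), (3,1). True effect sizes are
back-solved from the heritabilities: with total variance
$V_p = \sigma^2/(1-\sum h^2)$, QTN $i$ gets
$a_i = \sqrt{h_i^2 V_p / 2pq}$; epistatic effects are back-solved the same
way from the Hardy–Weinberg variance of the product column,
$(2pq + (p-q)^2)^2 - (p-q)^4$, so that every true effect is a fixed design
constant across replicates (the realized fractions then fluctuate
symmetrically around their targets, exactly as for the additive terms).

Genotypes are drawn as 2n haplotypes from a Gaussian-copula AR(1) process
(adjacent-marker latent correlation 0.7 by default) over five chromosomes
at 500 bp spacing; non-QTN allele frequencies are uniform on [0.05, 0.5],
QTN columns are drawn at exactly 0.30. The marker count defaults to
m = 2 000, the package's desk-scale stand-in for the genomic sub-regions
the original evaluation subset from a real *Arabidopsis thaliana* panel.
What the generator does **not** emulate: real LD block structure and
allele-frequency spectra, population stratification, genotyping error and
missingness patterns. Passing tests therefore certify the estimator
algebra and the designed operating characteristics, not performance on any
particular real data set.

For variance-fraction audits (`sim_variance_audit()`), the realized
fraction is estimated two ways: the mean of per-replicate ratios
var(component)/var(y) (reported by the reproduction script), and the
ratio of means with a delta-method Monte Carlo SE (used by the tests).
The per-replicate-ratio mean carries a small Jensen bias of order
cv²(var y) ≈ 1% because the finite-sample var(y) sits in the denominator;
the ratio of means is first-order unbiased, which is why the tests assert
with it.

## Numerical choices and degenerate inputs

* Eigenvalues of $K$ below $-10^{-8}\,\|K\|$ are an error; tiny negatives
  are clipped to zero.
* Markers that are monomorphic, or with MAF < 1/(2n) after imputation, are
  reported with NA statistics and excluded from thresholds.
* `wald_test(0, 0)` returns $W = 0$, $p = 1$ (full shrinkage at the
  boundary); a zero variance with a nonzero effect is an error.
* Preselection ties are broken by position, then marker id, making the
  pipeline byte-deterministic for fixed inputs and seed.
* Missing genotypes default to per-marker mean imputation
  (major-genotype fill available); the allele sorting first
  lexicographically codes +1, so orientation is deterministic and flips
  only change effect signs.

## Statistical behaviour worth knowing

* **Shrinkage.** For every marker, $|\hat\gamma_k^{\mathrm{random}}| =
  u\,|\hat\gamma_k^{\mathrm{fixed}}|$ with $u \in [0, 1)$: the random-effect
  BLUP never exceeds the fixed-effect estimate in magnitude.
* **Conservative null behaviour.** Under the null, the random-effect Wald
  statistic is a deterministic transform of an $F(1, n-q-1)$ variable with
  the shrinkage factor $u$ inside; its $\chi^2_1$ p-values are
  *conservative* (empirical tail mass ≈ 0.6–0.7 of nominal at
  $\alpha = 10^{-2}$–$10^{-3}$). This is intrinsic to testing a shrunken,
  boundary-constrained predictor and is the flip side of the method's low
  false-positive rate; the fixed-effect baseline with exact F p-values is
  calibrated. Empirically the fixed scan also runs a few percent
  conservative when the kinship is estimated from the scanned markers
  themselves (proximal contamination).
* **Information bound for $\lambda$.** With a trace-normalised kinship,
  the REML information for $\lambda$ at n = 100 caps near 6, so
  $\hat\lambda$ has sd ≳ 0.4 even under the most informative realistic
  structure; null-model estimates at small n should be read accordingly.

## Problem sizes used by the test-suite experiments

The packaged Monte Carlo checks run at the design sample size n = 199 with
m = 2 000 markers and 500 replicates for generator audits and null
calibration, and 200 replicates for the sample-size comparison
(199 → 149 → 99, realised as nested subsamples of each replicate so the
comparison is paired). Smaller unit tests use n ≤ 150 and m ≤ 300.

## Known limitations

* Single trait, additive coding only; no dominance or epistatic terms in
  the fitted models (epistasis exists only in the generator).
* P3D fixes $\lambda$ at the null estimate; per-marker re-estimation of
  the polygenic ratio is out of scope.
* The second stage assumes the preselected set is small relative to n;
  preselection plus pruning enforces this in practice.
* VCF/PLINK binary formats are not parsed; inputs are delimited text.

## A worked run

```{r example, eval = FALSE}
set.seed(1)
cfg <- sim_experiment(2, n = 199)     # polygenic background design
sim <- simulate_genotypes(cfg)
K   <- kinship(sim$geno)
ph  <- simulate_phenotypes(sim, cfg, K = K)
fit <- mrmlm(ph$y, sim$geno, K = K)   # scan + multi-locus refinement
summary(fit)
plot(fit$scan)                        # Manhattan view of stage 1
```
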