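# rmlmgwas

Genome-wide association mapping for quantitative traits with a
**random-SNP-effect mixed linear model** and its **multi-locus** two-stage
refinement, for geneticists mapping quantitative trait nucleotides (QTNs)
in structured populations (plant and animal panels, inbred-line
collections) where the usual fixed-effect single-marker scan with a raw
Bonferroni correction is too conservative.

## The model

For phenotype *y* on *n* individuals and marker *k* coded
z ∈ {1, 0, −1} (homozygote / heterozygote / other homozygote):

    y = Xβ + z_k γ_k + u + ε,
    γ_k ~ N(0, σ_k²),  u ~ MVN(0, σ_g² K),  ε ~ N(0, σ² I)

so Var(y) = σ²(λ_k z_k z_k′ + λ K + I) with λ = σ_g²/σ² and
λ_k = σ_k²/σ². The polygenic ratio λ is estimated once by REML under the
null model and then fixed (P3D). Rotating by the eigenvectors of the
marker-inferred kinship K diagonalises the background, and Woodbury
rank-one identities reduce each marker's profiled restricted likelihood —
a function of the single ratio λ_k — to O(n); its maximiser has a closed
form that the Newton iteration reaches in a step. Each marker reports a
shrunken BLUP effect, a Wald statistic referred to χ²₁, and a LOD score.
Shrinkage justifies a **modified Bonferroni** threshold α/mₑ with mₑ the
effective number of independent markers (eigenvalues of the marker
correlation matrix).

The second stage (`mrmlm()`) preselects markers with scan p < 0.01,
prunes them positionally (±1 kb simulated / ±20 kb real data), classifies
each as fixed (single-marker LRT LOD > 1.5 among those passing α/mₑ) or
random, fits all survivors jointly by **EM empirical Bayes** — every
random effect with its own variance, the M-step σ_k² = E(γ_k²|y) — and
declares QTNs by per-marker likelihood ratio tests at **LOD ≥ 3**
(p ≤ 0.0002), with no further multiplicity correction. A fixed-effect
EMMA-style scan (`emma_scan()`, plain Bonferroni α/m, i.e. 5e-8 at one
million markers) serves as the baseline, and a simulation harness scores
methods by power, MSE, Type 1 error and ROC curves.

## Worked example

Simulate the polygenic-background evaluation design (n = 199, m = 2000,
six QTNs with heritabilities 0.10/0.05/0.05/0.15/0.05/0.05 at MAF 0.30,
mean 10, residual variance 10, polygenic fraction 0.092) and run the
two-stage analysis:

```r
library(rmlmgwas)
set.seed(11)
cfg <- sim_experiment(2, n = 199)
sim <- simulate_genotypes(cfg)
K   <- kinship(sim$geno)
ph  <- simulate_phenotypes(sim, cfg, K = K)

sc <- rmlm(ph$y, sim$geno, K = K)      # stage 1: random-effect scan
sc
#> Random-SNP-effect mixed linear model scan
#>   markers tested: 2000 of 2000; lambda (polygenic) = 0.3941
#>   effective markers m_e = 1437.00; threshold p = 3.48e-05 (alpha = 0.05)
#>   significant markers: 3

fit <- mrmlm(ph$y, sim$geno, K = K, scan = sc)   # stage 2
summary(fit)
#> Multi-locus fit: 10 selected markers, 5 declared QTNs
#> Declared QTNs:
#>        marker chrom    pos treated_as effect   lrt   lod         p      r2
#>  snp_4_100000     4 100000      fixed  2.715 43.96 9.545 3.358e-11 0.11523
#>   snp_1_50000     1  50000      fixed  2.471 41.12 8.929 1.431e-10 0.10603
#>  snp_3_100000     3 100000      fixed  2.017 28.54 6.197 9.180e-08 0.07243
#>  snp_2_100000     2 100000     random  1.692 15.04 3.266 1.053e-04 0.04150
#>  snp_1_150000     1 150000     random  1.530 16.97 3.686 3.791e-05 0.04599
#> BIC of the called set: 1100.24
```

Reading the output: the single-locus scan alone clears its genome-wide
threshold for only 3 markers, while the multi-locus stage declares 5 of
the 6 simulated QTNs, each within 0 bp of a true position — the simulated
truth here is effects (2.280, 1.612, 1.612, 2.792, 1.612, 1.612) at
chr1:50000, chr2:100000, chr3:100000, chr4:100000, chr5:100000 and
chr1:150000 (the chr5 QTN is missed on this draw). `effect` is in trait
units per coded allele unit, `r2` the fraction of phenotypic variance the
call explains, and the BIC summarises an ordinary regression of the trait
on the called set. `plot(sc)` draws the Manhattan view.

File-based workflows use `read_genotypes()` (coded CSV or HapMap-like
calls), `read_phenotypes()`, `read_kinship()`, `write_results()`; a thin
command-line wrapper with `scan`, `mrmlm` and `simulate` subcommands lives
in `inst/cli/rmlmgwas.R`.

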