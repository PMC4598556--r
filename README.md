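# cladediv

Comparative tools for asking whether an ecological trait — here, feeding
on living vascular-plant tissue (herbivory) — accelerates the
diversification of the clades that have it. The intended users are
evolutionary biologists with (i) a time-calibrated phylogeny whose tips
are higher taxa (orders, families, subfamilies), and (ii) a table of
described species richness, stem ages and trait states per clade, who
want to run the standard clade-level analysis battery without stitching
it together by hand.

## What it computes

**Net diversification rates.** For a clade with `n` described species and
stem age `t` (Myr), the method-of-moments stem-age estimator under an
assumed relative extinction fraction `ε = μ/λ` is

    r̂ = ln[ n (1 − ε) + ε ] / t        (lineages / Myr)

computed across the canonical grid ε ∈ {0, 0.5, 0.9} (`mom_stem_rate()`,
`rate_table()`). Stem ages are used rather than crown ages, so incomplete
sampling inside a clade cannot inflate the estimate.

**Phylogenetic generalized least squares.** Rates (or log richness) are
regressed on trait predictors with residual covariance
`σ² V(λ)`, where `V` is the Brownian shared-path-length matrix of the
clade tree and Pagel's λ scales its off-diagonals; λ is estimated by
maximum likelihood on [0, 1] (`pgls()`, `profile_lambda_ml()`). Each fit
reports coefficients with t-tests, r², an F-test model P, and an AIC whose
parameter count includes σ² and the estimated λ; `model_compare()` ranks
model batteries by AIC (`run_order_analysis()` drives the full
tree × ε × model grid).

**Sister-clade comparisons.** `extract_sister_pairs()` finds
non-overlapping, least-inclusive sister pairs in which herbivory is
present in one clade (any proportion) and absent in the other; because
sister clades share a stem age, the richer member is the faster
diversifier. `sign_test(k, n)` gives the exact one-tailed binomial
probability `Σᵢ₌ₖⁿ C(n,i)/2ⁿ`.

**Synthetic data with known truth.** `simulate_dataset()` generates clade
trees (early-burst node ages, like ancient insect radiations), U-shaped
herbivory proportions, true rates `a + b·herbivory + Brownian(σ², λ)
noise`, and richness from the birth–death distribution conditioned on
survival — so every stage above can be validated against ground truth.

## Worked example

```r
library(cladediv)
sim <- simulate_dataset(sim_config())          # 31 clades, seed 1
d   <- transform(sim$data,
                 rate = mom_stem_rate(richness, stem_age_myr, 0.9))
pgls(rate ~ herbivory_prop, d, sim$tree)
```

```
Phylogenetic GLS fit: rate ~ herbivory_prop
  n = 31  lambda = 1 (ML)  sigma2 = 1.404e-07
  logLik = 109.913  AIC = -211.826  r2 = 0.09443  model P = 0.09264
           term estimate       se     t       p
    (Intercept) 0.010250 0.003794 2.702 0.01140
 herbivory_prop 0.006852 0.003940 1.739 0.09264
```

In this particular draw the herbivory effect is positive (+0.0069
lineages/Myr going from 0% to 100% herbivorous, on a baseline of 0.0103)
but not significant at n = 31 (P = 0.093) — with 31 clades and a true
effect of this size, the analysis detects it in roughly 85% of replicate
datasets, so occasional non-significant draws are expected. λ is
estimated at 1 (full Brownian signal), and `r2 = 0.094` is the fraction
of rate variation explained in the whitened space. An exact sign test at
five-of-five informative sister pairs:

```r
sign_test(5, 5)
#> [1] 0.03125
```

The numbered scripts under `analysis/` run the whole workflow on the
synthetic dataset — generation, rate tables, the PGLS model battery
across ε, sister-clade comparisons, and richness-response robustness
checks — writing tables under `results/`.

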