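# raopart

`raopart` partitions the diversity of presence–absence communities — taxonomic
(TD), phylogenetic (PD) and functional (FD) — into the contributions of
environment and space. It is aimed at community ecologists who have a site ×
species occurrence table, site coordinates with environmental variables, a
species trait table and a rooted phylogeny, and who want to know how much of
the variation in within-site (alpha) and between-site (beta) diversity is
explained by environmental filtering, by spatial structure, by their overlap,
and by neither.

## The statistics at the core

**Rao quadratic entropy.** For a community *k* with *S* species and a species
distance matrix *d*, alpha diversity is

> Q(k) = Σᵢ Σⱼ pᵢ pⱼ dᵢⱼ,  pᵢ = 1/S,

the expected distance between two randomly drawn individuals of the
community. With taxonomic distances (dᵢⱼ = 1 for i ≠ j) this is (S−1)/S; with
unit-scaled cophenetic or trait-space distances it becomes PD or FD in the
same mathematical frame. Jost's correction converts Q to an equivalent
number, Q_eq = 1/(1−Q), so that corrected taxonomic alpha equals species
richness exactly and beta diversity can be quantified independently of alpha.
Pairwise beta between communities *k* and *l* is

> β(k,l) = (γ_eq − ᾱ_eq) / γ_eq,

with γ computed on the pooled pair and both terms Jost-corrected.

**Environment vs space.** Spatial predictors are PCNM eigenfunctions
(principal coordinates of neighbour matrices): the positive-eigenvalue axes
of a PCoA of the inter-site distance matrix truncated at the largest
minimum-spanning-tree edge, orthogonal waves running from broad to fine
scale. Environmental and spatial predictor sets are each reduced by forward
selection (permutation tests with Blanchet's double stopping), then
redundancy analysis (RDA) partitions the adjusted R² of each diversity
response into pure environment [a], spatially structured environment [b],
pure space [c] and residual [d]:

> a = R²ₐ(E∪S) − R²ₐ(S), b = R²ₐ(E) + R²ₐ(S) − R²ₐ(E∪S), c = R²ₐ(E∪S) − R²ₐ(E), d = 1 − R²ₐ(E∪S),

with R²ₐ the Ezekiel-adjusted R² and permutation tests for the testable
fractions. Beta matrices enter the RDA through the scores of their
significant PCoA axes. Spatial autocorrelation diagnostics (Moran's I and
Mantel correlograms) and Pagel's λ phylogenetic-signal tests for each trait
round out the workflow.

## Worked example

Everything runs from a synthetic bundle with known structure, so the example
is fully reproducible:

```r
library(raopart)

scn    <- scenario("mixed", n_sites = 120, n_species = 60, seed = 42)
bundle <- simulate_scenario(scn)
report <- run_pipeline(bundle, n_perm_select = 199, n_perm_test = 499, seed = 42)

dplyr::filter(tidy(report), facet == "TD", scale == "beta")
#> # A tibble: 4 × 5
#>   facet scale fraction adj_r2 p_value
#>   <chr> <chr> <chr>     <dbl>   <dbl>
#> 1 TD    beta  a         0.103   0.002
#> 2 TD    beta  b         0.544  NA
#> 3 TD    beta  c         0.142   0.002
#> 4 TD    beta  d         0.210  NA
```

Read: for taxonomic beta diversity, 10.3% of composition-turnover variance is
purely environmental ([a], significant), 54.4% is environment that is itself
spatially structured ([b]), 14.2% is purely spatial ([c], significant —
dispersal-limitation-like structure), and 21.0% is unexplained. Under this
`mixed` scenario both niche filtering and a spatial dispersal field truly
act, and both signals are recovered. `report$lambda` lists Pagel's λ per
trait (the generating values here are 1, 1, 0.5, 0, 1):

```r
report$lambda
#> # A tibble: 5 × 6
#>   trait  lambda loglik   lrt  p_value signif
#>   <chr>   <dbl>  <dbl> <dbl>    <dbl> <chr>
#> 1 trait1  1      -11.5 109.  1.59e-25 "***"
#> 2 trait2  0.992  -15.6 134.  4.53e-31 "***"
#> 3 trait3  0.591  -63.4  11.3 7.76e- 4 "***"
#> 4 trait4  0      -80.9   0   1   e+ 0 ""
#> 5 bin1    0.670  -24.9  37.3 9.98e-10 "***"
```

`autoplot(report)` draws the fraction bars per facet and scale;
`autoplot(report$pcnm)` shows the spatial eigenfunction spectrum.

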