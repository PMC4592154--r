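---
title: "Partitioning taxonomic, phylogenetic and functional diversity between environment and space"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioning taxonomic, phylogenetic and functional diversity between environment and space}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`raopart` asks a classic question of metacommunity ecology: how much of the
variation in community diversity — counted as species (TD), as branches of
the phylogeny (PD), or as spread in trait space (FD) — is due to
environmental filtering, how much to spatial processes such as dispersal
limitation, how much to environment that is itself spatially structured, and
how much remains unexplained? This vignette explains the statistical
machinery, the choices the package makes where the methodology is genuinely
open, and what the synthetic-data generator does and does not establish
about real data.

## 1. Rao quadratic entropy and the Jost correction

All three diversity facets share one statistic. Given a unit-scaled species
distance matrix $d$ and a community $k$ holding $S$ species, alpha diversity
is the quadratic entropy with uniform presence weights $p_i = 1/S$:

$$Q_k = \sum_{i=1}^{S}\sum_{j=1}^{S} p_i\, p_j\, d_{ij}.$$

Interpreted as the expected distance between two random individuals of the
community, $Q$ turns into TD, PD or FD as $d$ is taxonomic ($d_{ij}=1$ for
$i\neq j$), cophenetic, or trait-based. A note on weights: the
presence–absence form is sometimes written as a bare double sum over
$d_{ij}$; we use the uniform-weight form throughout because the bare sum
grows as $S^2$ and has no equivalent-number transform — with uniform weights
the taxonomic case gives $Q = (S-1)/S$, whose Jost equivalent number

$$Q_{eq} = \frac{1}{1-Q}$$

is exactly the species richness $S$ — the identity that anchors the whole
framework (and one of the package's exact tests). An unweighted
`literal_sum` option exists for comparison only.

Pairwise beta between communities $k$ and $l$ applies the correction before
anything else: $\gamma_{eq}$ is the equivalent number of the pooled pair,
$\bar\alpha_{eq}$ the mean of the two corrected alphas (correction first,
averaging second — the order that keeps beta independent of alpha), and

$$\beta_{k,l} = \frac{\gamma_{eq} - \bar\alpha_{eq}}{\gamma_{eq}} \in [0, 1].$$

Identical communities give 0; disjoint equal-sized communities with
taxonomic distances give exactly $1/2$. A multi-community additive
decomposition is exposed as a utility (`rao_decompose()`) but the pipeline
uses only the pairwise form.

## 2. The three distance matrices

**Taxonomic** distances are the 0/1 metric, already unit-scaled.

**Functional** distances standardize each trait column (mean 0, SD 1),
rotate by PCA, and take Euclidean distances over the axes. All axes are
retained by default, which makes the rotation purely a decorrelation: the
distances equal Euclidean distances on the standardized traits exactly
(asserted to 1e-10 in tests), so nothing is lost while correlated trait
blocks stop dominating through double counting. An `axes` argument allows
truncation when a user wants it, and fuzzy-coded trait groups can optionally
be downweighted by $1/\sqrt{\text{group size}}$ (off by default — column-wise
standardization is the documented default treatment). Zero-variance traits
are dropped with a warning; missing trait values are an error, never
imputed.

**Phylogenetic** distances are cophenetic distances on a prepared tree:
binary, ultrametric, root at height 1. Preparation assigns each node the
Grafen height $((t_v-1)/(t_{root}-1))^\rho$ from its descendant tip count
($\rho = 1$ by default; the transform's standard choice, exposed as a
parameter). Polytomies are resolved at random (seeded) into zero-length
branches. Order matters here, and the package is deliberate about it:
heights are computed on the *original* topology and the resolution inserts
genuinely zero-length branches, so the cophenetic matrix is invariant to the
random resolution — resolving first and then assigning Grafen heights would
give the inserted nodes their own tip-count heights and make species
distances depend on an arbitrary coin flip, which is statistically
indefensible for a seeded pipeline. For binary trees the orders coincide.
All matrices are divided by their maximum off-diagonal value so the most
distant pair sits at 1, making facets comparable.

## 3. Spatial eigenfunctions (PCNM)

Spatial predictors are built from the inter-site distance matrix (Euclidean
for projected coordinates, great-circle for lon/lat — both supported because
coordinate systems vary across studies): distances beyond a truncation
threshold $t$ are replaced by $4t$, and a PCoA of the truncated matrix
yields eigenfunctions ordered from broad to fine scale. $t$ defaults to the
largest edge of the minimum spanning tree — the smallest threshold keeping
the site graph connected (verified as such by a graph-connectivity test).
On a regular transect the leading eigenfunction is exactly the broadest sine
wave the design admits, $\sin(2\pi i/(n+1))$; the full basis reproduces a
dense eigendecomposition oracle to 1e-8. Only positive-eigenvalue
eigenfunctions are kept, scaled by $\sqrt{\lambda}$; because "spatial
structure" in this framework means positive autocorrelation, the pipeline
uses the subset with Moran's I above the null expectation $-1/(n-1)$
(`pcnm_scores(basis, positive_moran = TRUE)`); the full set remains
available on the basis object.

## 4. RDA, adjusted R², forward selection, partitioning

The statistical engine is ordinary multivariate least squares. RDA regresses
a centred response table on centred predictors; $R^2$ is the fitted share
of total variance and is adjusted with Ezekiel's formula
$1-(1-R^2)(n-1)/(n-p-1)$, using the *rank* of the predictor matrix (aliased
columns are dropped with a warning, which keeps the partition identities
true on rank-deficient inputs). Significance uses the pseudo-F statistic
under row permutations, $p = (\#\{F^* \ge F\}+1)/(n_{perm}+1)$; partial
models permute the residuals of the reduced model, the standard scheme for
testing one fraction while conditioning on the other set.

Forward selection follows the double-stopping rule: at each step the
candidate adding the most adjusted $R^2$ is tested by a marginal permutation
test conditioned on the current set (999 permutations, $\alpha = 0.05$ by
default) and retained if significant; selection stops when the best
candidate fails the test, when the cumulative adjusted $R^2$ reaches the
adjusted $R^2$ of the all-candidates model (further additions would only
overfit — note the variable that crosses the threshold *is* retained and
only subsequent additions stop; rejecting it instead would make the
procedure unable to select a single strong predictor whose lone-model
adjusted $R^2$ exceeds that of the noise-diluted global model), or when
candidates run out. A global gate first tests the all-candidates model and
selects nothing if it is not significant; simulations in the test suite put
the family-wise false-selection rate of the gated procedure near the nominal
5% and first-choice power at essentially 1 for a strong single predictor.

Variation partitioning combines three fits (environment, space, both) into
the adjusted-$R^2$ fractions $a$ (pure environment), $b$ (spatially
structured environment), $c$ (pure space) and $d$ (residual), which sum to 1
by construction; $[a]$ and $[c]$ are testable by partial-RDA permutation
(9,999 permutations by default in the pipeline). Beta matrices enter as the
site scores of their "significant" PCoA axes. Which axes are significant is
a genuinely open choice; the default is the broken-stick rule on positive
eigenvalues (the standard dimensionality criterion in this literature), with
`all_positive` and fixed-count options. Negative eigenvalues are reported,
not corrected, by default — Jost-corrected Rao beta matrices are
near-Euclidean in practice; a Lingoes correction is available by flag and
the package logs a note whenever negative eigenvalues exceed 5% of the
positive sum.

## 5. Phylogenetic signal

Each trait is tested for phylogenetic signal with Pagel's $\lambda$: the
off-diagonal entries of the Brownian-motion covariance matrix are scaled by
$\lambda \in [0,1]$ (tip heights preserved, so 1 is the upper bound on
ultrametric trees), the root state and rate are profiled analytically by
GLS, and $\lambda$ is found by bounded scalar optimization (tolerance 1e-8;
the optimizer is checked against a 101-point grid scan and both boundaries).
Significance is a likelihood-ratio test against $\lambda = 0$ on
$\chi^2_1$, as is conventional — with the caveat, stated in the
documentation, that the null sits on the boundary of the parameter space,
making the test conservative; a 50:50 mixture option is provided but off by
default. Binary and fuzzy-coded traits are treated as continuous values
under the Gaussian model — a deliberate, documented coercion (the
alternative, a threshold model, is out of scope), and each fuzzy column is
tested separately. Zero-length terminal branches from polytomy resolution
get a diagonal jitter of 1e-8 times tree height before inversion.

## 6. The synthetic-data generator

Because the framework's observable claims are about *recovery* — does the
pipeline attribute variation to the process that generated it? — the package
ships a generator whose defaults emulate the scale of a regional survey:
300 sites placed uniformly in a unit square, 150 species on a Yule tree
(Grafen-prepared), four quantitative traits evolved as multivariate normals
with true $\lambda$ of 1, 1, 0.5 and 0 plus one thresholded binary trait,
and six environmental variables (four climate-like Gaussian-process fields
with exponential covariance $e^{-d/0.25}$ — a quarter of the domain,
regional-scale gradients — plus a Simpson land-use diversity and a
disturbance proportion built from transformed fields, all standardized).

Occurrence follows a quadratic-niche logistic model:

$$P(\text{species } s \text{ at site } i) = \text{logit}^{-1}\!\big(0.5 - 1\cdot(e_i - o_s)^2 + \delta_{is}\big),$$

where $e_i$ is the first environmental variable, the optimum $o_s$ is the
species' first (heritable, $\lambda = 1$) trait, and $\delta_{is}$ is a
species-specific Gaussian field (range 0.15, SD 2) standing in for dispersal
limitation. The intercept 0.5 and unit niche slope give prevalences around
0.2–0.4 — a realistic occupancy for regional presence–absence surveys — and
filtering through a heritable trait couples TD, PD and FD the way real
assemblages couple them. Presets switch terms off: `pure_env` removes the
dispersal field, `pure_space` the niche term, `neutral` both. One master
seed fixes the tree, traits, landscape and occurrences; empty sites are
re-drawn (logged) so validators always pass.

What passing recovery tests shows: that the pipeline attributes
composition variance to the correct side of the partition when the
generating process is known, at realistic size and noise. What it does not
show: robustness to abundance structure (the generator is
presence–absence only, as is the method), to non-Gaussian trait evolution,
to sampling error in species detection, or to environmental drivers acting
on unmeasured traits. Conclusions about real data inherit those caveats.

## 7. Numerical conventions and problem sizes

Permutation p-values are always $(\text{count} \ge \text{obs}+1)/(n_{perm}+1)$,
so they live in $[1/(n_{perm}+1), 1]$. Correlogram distance classes are
equal-width (Sturges' rule on the pair count by default); empty classes
merge rightward with a warning; Moran's I tests are two-sided around the
null expectation, Mantel tests one-sided; a progressive Bonferroni
correction is deliberately not applied by default (plain $p < 0.05$ per
class is reported). Every stochastic operation takes an explicit seed and
the pipeline derives per-stage seeds from one master seed, so reports are
bit-reproducible.

The shipped verification suite runs its heavier simulations at sizes chosen
to make the statistical claims testable at desk scale while staying quick:
recovery replicates use 120 sites and 60 species (50 replicates per
preset), forward-selection operating characteristics use 1,000 null
replicates at $n = 50$ with 5 candidates and 999 permutations, and Pagel's
$\lambda$ recovery uses 100 replicates on 128-tip trees. The acceptance
script runs the full pipeline once at the generator's native 300 × 150
scale.

## 8. Known limitations

* Beta diversity enters the RDA through PCoA scores; information in axes
  discarded by the broken-stick rule is lost to the partition (mitigate
  with `axes_criterion = "all_positive"`).
* The sign attached to a retained variable in the report follows the
  correlation between the predictor and the first canonical axis of the
  selected model — a convention for multivariate responses, not a canonical
  definition.
* Pagel's $\lambda$ on 0/1 traits uses a Gaussian working model; its
  $\lambda$ is interpretable as signal strength but the likelihood is
  misspecified for truly discrete evolution.
* Abundance-weighted Rao, null-model standardized effect sizes and
  Hill-number generalizations beyond the $q = 2$ equivalent number are out
  of scope.
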