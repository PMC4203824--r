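---
title: "Partitioning community trait variation: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioning community trait variation: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(traitshift)
```

## The model

A community's mean trait value can change along an environmental gradient
for two reasons: the species present change (*species turnover*), or the
individuals of the species present change (*intraspecific trait
variation*, ITV). `traitshift` separates the two with three
community-weighted means (CWMs) per site $j$ and trait:

$$\mathrm{CWM}^{total}_j = \sum_i \tilde p_{ij}\, x_{ij}, \qquad
  \mathrm{CWM}^{inter}_j = \sum_i \tilde p_{ij}\, \bar x_i, \qquad
  \mathrm{CWM}^{intra}_j = \mathrm{CWM}^{total}_j - \mathrm{CWM}^{inter}_j,$$

where $x_{ij}$ is the mean trait of species $i$ measured *in* site $j$,
$\bar x_i$ its mean across the sites where it was measured, and
$\tilde p_{ij}$ relative cover renormalized over the trait-sampled
species of the site. The total CWM responds to turnover *and* ITV, the
interspecific ("fixed") CWM to turnover only, and their difference to ITV
only.

Among-site variation is then partitioned through centered sums of
squares:

$$SS_{total} = SS_{turnover} + SS_{intra} + SS_{cov}, \qquad
  SS_{cov} = 2 \sum_j (\mathrm{inter}_j - \overline{\mathrm{inter}})
                      (\mathrm{intra}_j - \overline{\mathrm{intra}}).$$

Positive covariation means turnover and ITV push site means the same
way; negative covariation means they oppose. The same partition applies
to the variance *explained* by an environmental model (each CWM series
regressed on the same predictors, components = regression SS), and to
each site *pair* (squared differences), which is the basis of the
distance-decay analysis.

## Numerical and design choices

**Covariation as a remainder.** $SS_{cov}$ is always computed as
$SS_{total} - SS_{turnover} - SS_{intra}$, never independently, so the
additivity identity holds by construction; the cross-product formula is
used only as an independent test oracle. For explained variation the
remainder can be negative (the inter and intra fits can overlap); it is
reported as-is.

**Raw centered SS.** No denominator is applied: only ratios (the reported
percentages) matter, and any common divisor cancels.

**Global species means.** "Mean across the sites where a species is
measured" is ambiguous between pooling individuals and averaging site
means. The default averages site means (one site, one vote), which makes
the fixed CWM insensitive to unequal per-site sampling effort; pooling is
available as `method = "pooled"`. The site-mean path deliberately uses
`mean()`'s long-double accumulation so that a species with identical site
means gets exactly that value back — this keeps the no-ITV limit *exact*
(the pure-turnover test asserts identical zeros, not near-zeros).

**Missing cells.** A species with cover but no trait measurement in a
site contributes nothing to that site's CWMs; cover is renormalized over
the measured species (field protocols measure species down to ~80% of
cover, so CWMs are implicitly over that subset). An optional
`gap_fill = TRUE` substitutes the species' global mean; it is off by
default because a gap-filled species contributes zero ITV by
construction, deflating the intraspecific component.

**Saturated models.** `decompose_explained_variation()` refuses
`length(predictors) >= n_sites - 1`. The full site-indicator basis (which
reproduces the total-variation decomposition, a useful identity check)
is therefore only reachable with `allow_saturated = TRUE`.

**Pairwise log-ratios.** The relative importance of turnover vs. ITV per
site pair is $\ln(d_{turnover}/d_{intra})$. A zero component produces a
$\pm\infty$ sentinel; no epsilon is added (an epsilon would manufacture
signal from exact ties), and correlation/binning functions drop
non-finite pairs with a count.

**Mantel tests.** Pearson correlation of lower triangles; the null is
simultaneous row/column permutation of the second matrix;
$p = (\#\{|r^*| \ge |r|\} + 1)/(B + 1)$. The partial test residualizes
both matrices on the controlled one and permutes the matrix of residuals
(residual-permutation method: standard, stable, and exactly "controlling
for the other"). Defaults — 9999 permutations, two-tailed — are package
choices, documented rather than inherited from any particular study.
Permutations are reproducible bit-exactly under a fixed seed.

**Geographic distance.** Haversine on a sphere of radius 6371.0088 km
(IUGG mean). Environmental distance is Euclidean on variables z-scored
after any log transforms flagged at table construction.

**Equal-count bins.** Pairs sorted by distance (ties broken by index)
are split into equal-count bins; when the pair count is not divisible,
the extra pairs go to the *nearest*-distance bins, so 231 pairs in 4
bins give 58/58/58/57. Bin means get percentile bootstrap CIs.

**AICc.** $AICc = n\ln(RSS/n) + 2k + 2k(k+1)/(n-k-1)$ with
$k$ = coefficients + 1 (the error variance counts as a parameter); the
Gaussian constant is dropped since it cancels in every comparison.
Stepwise search is greedy single-term add/drop, both directions from the
full candidate set by default, ties broken toward the smaller model.

A caveat worth stating plainly: at $n = 22$ with a handful of noise
candidates, AICc stepwise retains at least one spurious predictor in
roughly a third of replicates — the null spurious-inclusion probability
is ~10% per candidate and is independent of how strong the true effects
are. We verified with an exhaustive all-subsets search that this is a
property of AICc selection, not of the greedy algorithm (the two agree
on ~98% of replicates). Strong true predictors are essentially never
*dropped*; exact-subset recovery is what suffers.

**Predictor screening.** `predictor_correlation_screen()` reports pairs
with $|r|$ at or above a threshold (default 0.5) but drops nothing:
which member of a correlated pair to keep is a scientific judgement the
package does not make.

## What the synthetic generator emulates

The generator stands in for a broad-extent field survey whose raw data
are not available. Its stated world:

* 22 sites on a ~1100 km latitudinal transect; one latent climatic axis
  $g$ (z-scaled latitude) and one latent edaphic axis
  $e = \rho\, g + \sqrt{1-\rho^2}\,\varepsilon$. The coupling is built
  in because it is exactly the confound such surveys face. The default
  $\rho = 0.85$ is set at the latent level so the realized correlation
  between geographic and environmental *distance matrices* — which
  attenuates through per-variable noise — lands near 0.70 (measured:
  mean 0.71, range 0.60–0.81 across seeds).
* Eight observable variables (MAT, MAP on $g$; CEC, pH, P, N, OM, sand
  on $e$) with means and spreads matching a temperate old-field survey
  (e.g. MAT 11.95 ± 3.0 °C, MAP 1132 ± 99 mm), fertility increasing and
  sand decreasing northward.
* A 60-species pool with Gaussian abundance responses along $g$
  (breadth 0.4 ± 0.1 z-units), Dirichlet noise around expected covers,
  and a 0.005 detection threshold. Calibrated (parameter sweep, then
  frozen) to a mean pairwise Bray-Curtis dissimilarity of ~0.76 at a
  mean richness of ~21 species per site.
* Individual traits $x = \beta_{0i} + b_{g,i}\, g_j + b_{e,i}\, e_j +
  N(0, \sigma_{ind}^2)$, with per-species slopes of heterogeneous
  magnitude and (optionally mixed) sign — the "idiosyncratic" ITV of
  real multi-species data. `optimum_coupling` correlates $\beta_{0i}$
  with the niche optimum $\mu_i$: without it turnover produces no
  spatial trait structure and distance decay of the turnover component
  has no power; with it the generator expresses trait-mediated
  environmental filtering.
* The survey protocol itself: species trait-sampled in decreasing cover
  order down to 80% of cover, 5 individuals per species per site,
  non-positive values truncated (rate monitored, < 1%).

**Ground truth is the estimand, not the generator coefficients.** The
stored truth applies the pipeline's own definitions to noise-free
quantities (expected covers, noise-free trait values, the cover-threshold
sampling rule, site means over measured sites). Defined instead over all
sites and species, the "truth" ITV share is ~10 points higher than any
finite survey can estimate — not because the estimator is wrong but
because a species' global mean computed over its occupied sites tracks
its local environment. This estimand property is worth remembering when
comparing ITV shares across studies with different occupancy structures.

**What a green test does not establish.** The generator has linear ITV,
a single compositional gradient, no phylogenetic structure, no
dispersal limitation, and site-independent Dirichlet noise. Green
recovery tests establish that the pipeline measures what the model
world defines — not that real communities satisfy the model.

## Scenario ladder used by the tests

| scenario | truth | expected estimate |
|---|---|---|
| `scenario_pure_turnover()` | no ITV, $\sigma_{ind}=0$ | ITV share exactly 0 |
| `scenario_pure_itv()` | equal baselines, broad niches | turnover share < 5% |
| `scenario_mixed()` | ITV share ≈ 25% | within ±10 points |
| `scenario_itv_edaphic()` | ITV responds to $e$ only | ITV share of explained variance larger under edaphic than climatic predictors |
| `scenario_turnover_gradient()` | filtering, unstructured ITV | turnover component decays with distance; ITV component does not |

## Known limitations

* The decomposition is descriptive: covariation is a remainder and has
  no standard error here; no inferential machinery is attached to the
  percentages.
* Explained-variation components use raw regression SS; with many
  predictors at small $n$ they are optimistic (deliberately, to keep
  additivity; adjusted quantities do not add).
* AICc stepwise at small $n$ over-selects (see above); treat retained
  marginal predictors with suspicion.
* The generator's Dirichlet concentration is a single global knob; real
  surveys have site-dependent sampling effort.
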