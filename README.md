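# traitshift

Partitioning community-weighted mean (CWM) trait variation into **species
turnover**, **intraspecific trait variation (ITV)**, and their
**covariation**.

## The problem

Plant communities shift their mean trait values along environmental
gradients in two ways: the species present change (turnover), and the
individuals of those species change (ITV). Which process dominates — and
whether the answer differs between edaphic and climatic gradients, or with
the spatial distance between communities — is a core question of
trait-based community ecology, and answering it requires trait
measurements of each species *in each site*, not just one mean per
species.

`traitshift` implements the standard sum-of-squares machinery for this
question. Three CWMs are computed per site *j* and trait:

- **total** ("specific"): `sum_i p_ij * x_ij` — site-specific species
  means `x_ij`, responds to turnover and ITV;
- **interspecific** ("fixed"): `sum_i p_ij * x_i` — one global mean per
  species, responds to turnover only;
- **intraspecific**: total − inter, responds to ITV only;

and among-site variation is partitioned as

```
SS_total = SS_turnover + SS_intra + SS_cov
```

with covariation as the remainder (positive when turnover and ITV
reinforce each other). The same partition is applied to the variance
explained by environmental regression models (with AICc stepwise
selection), and to every site pair, giving distance-decay analyses of the
turnover and ITV components with Mantel / partial Mantel permutation
tests.

Because studies of this kind rarely deposit raw data, the package ships a
**synthetic metacommunity generator** with known ground truth: a
latitudinal climate gradient coupled to edaphic axes, Gaussian species
niches, per-species linear ITV of heterogeneous sign, and the field
protocol itself (80%-of-cover trait sampling, 5 individuals per species
per site). Every pipeline stage is validated against what the generator
is known to contain.

## Worked example

```r
library(traitshift)

mc  <- generate_metacommunity(generator_config(seed = 42))
ssm <- site_species_means(mc$traits)
tri <- compute_cwms(mc$cover, ssm)

decompose_total_variation(tri, trait = "height")
#> CWM decomposition (total_variation) -- trait: height, 22 sites
#>   SS  turnover 2251.97  intraspecific 155.26  covariation 373.621  total 2780.85
#>   %   turnover 81.0  intraspecific 5.6  covariation 13.4
```

81% of among-site variance in CWM height is attributable to species
turnover, 5.6% to ITV, and 13.4% to positive covariation (sites whose
species composition favors tall species also hold taller-than-average
individuals). The generator's own (noise-free) ITV share for this seed is
2.7%, inside the sampling noise of the estimate.

```r
decompose_explained_variation(tri, mc$env,
                              c("sand", "pH", "CEC", "OM", "N", "P"),
                              trait = "height")
#> CWM decomposition (explained_variation) -- trait: height, 22 sites
#>   SS  turnover 1222.32  intraspecific 93.1512  covariation 631.231  total 1946.7
#>   %   turnover 62.8  intraspecific 4.8  covariation 32.4
#>   R2  total 0.700  inter 0.543  intra 0.600
```

The edaphic model explains 70% of total-CWM variance; the partition says
most of that response is turnover plus turnover–ITV covariation.

```r
pw <- pairwise_decomposition(tri, "height")
gd <- great_circle_distance(mc$coords)
mantel_test(pw$d_turnover, gd, n_permutations = 999, seed = 1)
#> Mantel test (two-tailed): r = 0.7189, p = 0.001 (999 permutations, 231 pairs)
```

The turnover component of pairwise trait dissimilarity increases strongly
with geographic distance. Mean pairwise Bray-Curtis dissimilarity of the
simulated covers is 0.744 — the high-turnover regime the generator is
calibrated to.

## Command line

A thin CLI over the same functions is installed at
`system.file("cli", "traitshift.R", package = "traitshift")`:

```sh
CLI=$(Rscript -e 'cat(system.file("cli","traitshift.R",package="traitshift"))')
Rscript $CLI simulate --seed 7 --outdir data/
Rscript $CLI validate  --traits data/traits.csv --cover data/cover.csv
Rscript $CLI decompose --traits data/traits.csv --cover data/cover.csv \
        --env data/env.csv --predictors MAT,MAP --out results.csv
Rscript $CLI models --traits data/traits.csv --cover data/cover.csv \
        --env data/env.csv edaphic=sand,pH,CEC,OM,N,P climatic=MAT,MAP \
        --out models.csv
Rscript $CLI distance-decay --traits data/traits.csv --cover data/cover.csv \
        --coords data/coords.csv --env data/env.csv --perms 9999 --seed 1 \
        --out decay.csv
```

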