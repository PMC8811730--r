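---
title: "Reference phenotypes from fermentation time series: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference phenotypes from fermentation time series: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenoclust)
```

## The model

A culture's behavior at one moment is summarized as a *phenotype vector*

\[
a_{j,p} = (\mu,\; r_2,\; \ldots,\; r_m)'
\]

anchored at sampling time $t_j$ of cultivation $p$: the specific growth
rate $\mu$ (1/h) plus one biomass-specific rate $r_D$ (mmol g$^{-1}$
h$^{-1}$, consumption negative) per measured compound. The package's
built-in registry covers eleven dimensions for *Clostridium
pasteurianum*-type fermentations: biomass, the substrates glucose and
glycerol, and the products 1,3-propanediol, ethanol, butanol, lactate,
formate, acetate, butyrate and 2-oxobutyrate, each with molar mass, carbon
count and ATP stoichiometry of substrate-level phosphorylation.

Pooled across many cultivations, these vectors are clustered; each
cluster's *reference phenotype* $\zeta$ is the per-dimension **median of
the raw vectors** assigned to it (medians resist the heavy-tailed rate
errors that arise at low biomass). Downstream analyses treat the
references as abstracted modes of cellular behavior.

## From concentrations to rates

1. **Interpolation.** Each compound's sampled concentrations are
   interpolated with a shape-preserving piecewise cubic Hermite polynomial
   (PCHIP, Fritsch–Carlson slopes, via `pracma::pchip`). PCHIP passes
   through every knot and never overshoots, so non-negative, monotone data
   stay that way — important because the derivative is what we are after.
2. **Slope.** At every interior sampling time the concentration slope is a
   centered finite difference of the interpolant over $\pm$ `grid_step`
   (default 0.1 h). The first and last sampling times are dropped — a
   centered stencil is undefined there, and one vector per retained
   sampling point keeps the observation count interpretable.
3. **Growth rate.** $\mu$ is the OLS slope of $\ln c_1$ versus time over
   the window spanning the two neighboring sampling points (an exponential
   fit). Raw biomass points are used, not interpolated ones: the fit is
   already a local smoother, and stacking it on an interpolant would
   correlate its errors. Non-positive biomass makes the vector undefined;
   it is dropped with a log message.
4. **Fed-batch columns.** A column flagged cumulative records the
   accumulated amount consumed; its slope is a consumption magnitude and
   is negated into the consumption-negative convention. Its
   "concentration" is not a medium concentration, so such points are
   excluded from concentration-based conditionality.
5. **Trimming.** Per dimension, the 3rd and 97th percentiles (linear
   interpolation between order statistics, R quantile type 7) are computed
   over the pooled vectors; a vector falling strictly outside the band in
   *any* dimension is removed. The any-violation rule is the strictest
   reading and best suppresses the low-biomass blow-ups that otherwise
   distort k-means centroids. DBSCAN runs are typically done without
   trimming since noise handling is built into the algorithm. Note that
   with eleven dimensions the union of per-dimension tails can remove a
   third or more of a small dataset; the bands are configurable.

## Clustering

Vectors are z-scored per dimension (sample standard deviation, $n-1$) so
that scale does not weight the metric. Two dissimilarities are supported:
squared Euclidean distance (SED), which groups vectors of similar
magnitude and direction, and cosine distance (CD, $1-\cos\theta$), which
groups by direction only — appropriate when the *pattern* of metabolism
matters more than its intensity.

k-means uses k-means++ initialization and Lloyd iterations, best of
`replicates` restarts (default 20), deterministic given a seed. Under CD
the vectors are unit-normalized and the centroid update is the
renormalized mean of assigned unit vectors (spherical k-means); on the
unit sphere $1-\cos\theta = \lVert\hat u - \hat v\rVert^2/2$, so this
coincides with SED k-means on normalized vectors. Ties go to the lowest
cluster index; an emptied cluster is reseeded with the point farthest from
its centroid. Zero-norm vectors (all dimensions exactly at the mean) are
rejected before CD clustering.

The number of clusters is chosen by scanning $k$ up to `k_max` (default
30) with a *single* k-means++ run per candidate — replication during the
scan is deliberately omitted, matching how such sweeps are usually done,
while the final model at the chosen $k$ is replicated for stability.
Criteria: mean silhouette and the gap statistic (either metric;
the gap reference is B = 50 uniform draws over the per-dimension data
range, one-standard-error rule), plus Davies–Bouldin and
Calinski–Harabasz (SED only, their native geometry).

DBSCAN is provided as the density-based alternative; the default minimum
neighbor count follows the twice-the-dimensionality rule of thumb (22 for
11 dimensions), and `sweep_dbscan()` tabulates, per neighborhood radius
$\varepsilon$: clusters found, fraction of points assigned, and fraction
of assigned points in the first cluster — the diagnostics used to judge
whether a radius yields informative structure.

## Conditionality

Whether a cluster is enriched under a condition not used for clustering
(a tag such as vessel type or BES, or a binned concentration) is measured
by the log deviation of proportions

\[
\delta^{CL}_{cond} = \log_{10}
  \frac{n^{cond}_{CL} / n_{CL}}{n^{cond} / n},
\]

positive for over-representation. Concentrations are pooled into
left-closed bins anchored at zero (canonical metabolite steps 1, 5, 10,
20, 50, 100 mmol/L; biomass uses analogous g/L steps, 0.05 by default —
the appropriate biomass step is dataset-dependent and configurable).
Flooring rather than rounding makes the bin boundary rule explicit. Any
zero count leaves $\delta$ undefined; it is reported as such, never
silently dropped. The statistic is descriptive — no significance
machinery is attached, and enrichment is not causation: the input dataset
is typically biased by design choices.

## Carbon and ATP balancing

For each reference phenotype the carbon recovery is

\[
R_C = 100 \cdot \frac{n_C^{BM}\,\zeta_\mu \cdot 1000/M_{BM}
      + \sum_{D \in products} n_C^D \zeta_D + r_{CO_2}}
     {\sum_{D \in substrates} n_C^D \lvert\zeta_D\rvert},
\]

with the biomass monomer C$_4$H$_7$O$_2$N ($M = 101.1$ g/mol); the
$1000/M_{BM}$ factor converts the growth rate (g biomass per g per h) to
mmol carbon monomer. The theoretical CO$_2$ rate counts pyruvate
decarboxylations: one per ethanol and acetate, two per butanol, and — by
default — two per butyrate, since butyrate condenses from two
acetyl-CoA, each from a decarboxylation. A coefficient of one per
butyrate is selectable (`buac_co2 = 1`) and recorded in the run manifest;
stoichiometric reasoning favors two, but both conventions appear in
practice. Formate enters negatively: it is the C1 unit not released as
CO$_2$. A substrate with net production is ignored in the denominator
(with a warning); no consumed substrate at all makes $R_C$ not
computable.

Assuming ATP formation solely by substrate-level phosphorylation, every
reference phenotype obeys

\[
q_{ATP} = \sum_D s_{ATP/D}\,\zeta_D = \frac{1000}{Y_{BM/ATP}}\,\mu + q^m_{ATP},
\]

with $q_{ATP}$ in mmol g$^{-1}$ h$^{-1}$ and the yield $Y_{BM/ATP}$ in
g/mol — the factor 1000 keeps the units consistent. Clusters whose
carbon recovery deviates from 100 % by more than 19 percentage points (or
is not computable) are excluded, and an unweighted OLS line of $q_{ATP}$
on $\mu$ over the rest yields $1/Y$ (slope) and the maintenance demand
$q^m_{ATP}$ (intercept). The yield's standard error comes from the delta
method on $1000/\hat\beta$; the reported band is a pointwise OLS
confidence band (not a prediction band). A non-positive slope is flagged
as not physical rather than inverted blindly.

## Superposition decomposition

A query phenotype is described as a non-negative mixture of the reference
phenotypes: per dimension, centroids and query are affinely rescaled to
$[0, 1]$ (by default the min/max pool centroids *and* query, so both live
on the same scale; centroid-only scaling is available, in which case the
query may leave $[0,1]$ and is not clipped), then
$\min_x \lVert A x - a\rVert^2,\ x \ge 0$ is solved by the Lawson–Hanson
active-set method (`pracma::lsqnonneg`) and the coefficients are rendered
as percentages. An all-zero solution leaves the proportions undefined.
Duplicated (or collinear) centroids make the split between them
arbitrary; only their summed proportion is meaningful.

For a time course, each point is rescaled and decomposed individually and
the proportion traces are then smoothed by a Gaussian-weighted moving
average over a centered five-point window ($\sigma = 0.8$ window-index
units, the usual convention for a 5-point Gaussian window; edge weights
renormalized) and renormalized to sum to 100 %. Smoothing acts on the
proportions, not the raw coefficients, so the displayed quantity is the
smoothed one.

## The synthetic generator: what it emulates and what it does not

`generate_dataset()` plants known phenotypes so the whole pipeline can be
validated closed-loop. An archetype is a phenotype vector held
biomass-specific and piecewise-constant; experiments integrate
$\dot c_1 = \mu c_1$, $\dot c_D = r_D c_1$ (RK4, step 0.01 h) under a
schedule of archetypes (with optional cross-fades), sample 4–15 times
over 10–24 h, and multiply each measurement by lognormal noise
($\sigma = 0.02$ by default, the scale of HPLC/OD errors; multiplicative,
because instrument error is scale-proportional and concentrations stay
non-negative). Substrate exhaustion zeroes all rates from that moment.
Media follow the Biebl-type design: 300–600 mM glycerol, sized to be
substantially depleted over a batch, and glucose (100–250 mM) only in
experiments scheduled to co-ferment it. Tags are planted with known
structure — the butanol-dominant archetype occurs only under `BES = yes`
— so conditionality has a known positive control.

The five default archetypes (solventogenic, acidogenic, PDO
co-fermenting, ethanologenic, near-dormant) are constructed, not tuned:
the product slate is scaled so each archetype lies exactly on the ATP
line with $Y = 10$ g/mol and $q^m = 2.5$ mmol g$^{-1}$ h$^{-1}$ (the
range reported for 1,3-propanediol fermentations), and the substrate
uptake is then solved from exact carbon closure. Every archetype
therefore has $R_C = 100\,\%$ and the cluster-level ATP regression has a
known ground truth.

What passing these tests does *not* show: real data have pH, product
inhibition and gas-phase dynamics, uneven measurement panels, and
phenotypes that drift rather than switch; none of that is simulated. One
instructive artifact does carry over: the near-dormant archetype consumes
glycerol so slowly (~1 mM/h volumetric) that 2 % noise on a several
hundred mM pool swamps its slope, and its cluster's carbon recovery comes
out wildly wrong (several hundred percent) — the same pathology that real
low-activity phases produce, and precisely what the 19 % recovery
exclusion absorbs: the ATP regression still recovers the planted
$(Y, q^m)$ from the remaining clusters.

## Numerical choices and degenerate inputs

* Percentiles: R quantile type 7 (linear interpolation), stated so
  results reproduce bit-for-bit.
* Two interpolation knots degenerate to the secant line.
* Zero-spread dimensions: rejected by `zscore_fit()` (error naming the
  dimension), dropped with a warning by `rescale_01()`.
* k-means asserts a non-increasing objective at every Lloyd iteration.
* All stochastic operations take an explicit integer seed; stage runners
  write it to the run manifest.
* Test problem sizes: unit tests run on handfuls of points; end-to-end
  checks use 20 simulated experiments (~150–250 phenotype vectors), small
  enough for interactive runs while still exercising every stage.

## Known limitations

* Rate accuracy is bounded by sampling density and measurement noise: a
  centered difference on an interpolant cannot beat the
  noise-to-consumption ratio of an interval. On the default synthetic
  conditions the noise-free median relative error is ~0.4 %; with 2 %
  measurement noise it is ~5 %, concentrated in slowly-moving dimensions.
* The ATP balance ignores electron/redox bookkeeping, inhibition and
  energy spilling; it is a screening regression, not a metabolic model.
* Cluster identity is only as good as the dataset's coverage; the
  conditionality statistic inherits every sampling bias of the inputs.
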