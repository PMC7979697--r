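---
title: "Modelling secondary-forest regrowth, its drivers and its carbon sink"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling secondary-forest regrowth, its drivers and its carbon sink}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regrowr)
```

## The problem

Tropical secondary forests — forests regrowing on land that was cleared and
used — take up carbon far faster than old-growth forest, but how fast depends
strongly on where they grow and what happened to them.  `regrowr` implements
a space-for-time analysis of that regrowth for an Amazon-like setting: it
reconstructs the age and disturbance history of every pixel from a stack of
annual forest/anthropic maps, attaches a single-date aboveground-carbon (AGC)
map to stands of different ages, fits saturating growth curves per climate
region and disturbance class, ranks the drivers of AGC, and converts the
fitted curves into carbon-stock accounts, a no-disturbance counterfactual and
forward preservation scenarios.

Because the full satellite products are tens of gigabytes, the package ships
a synthetic-landscape generator with known ground truth.  Every stage is
exercised and validated against that truth; the generator is a first-class,
tested module, not a fixture.

## Forest history from annual maps

A pixel's annual series of forest (1) / anthropic (0) values determines its
state in the final year:

* forest in **every** year: old-growth;
* anthropic in the final year: anthropic (any earlier regrowth is discarded —
  the clock restarts only at the next 0→1 conversion);
* otherwise: secondary forest, with **age** the length of the uninterrupted
  forest run ending at the final layer (1–32 for a 33-layer stack), and a
  **deforestation count** equal to the number of 1→0 transitions before that
  run.  The count is floored at 1: land that entered the window already
  cleared still experienced its original conversion.  A pixel whose series
  contains a gap is `nodata`; age is undefined across gaps, and the real
  products are gap-free, so this is conservative.

Secondary pixels are grouped into polygons by 8-neighbour connected
components (4-neighbour available).  Components are split by final-year age
*and* disturbance flags, and optionally at climate-region boundaries, so each
polygon is a coherent analysis unit: one age, one disturbance class, one
regional model.  We found during development that allowing polygons to span
ages or classes mixes different growth curves inside one polygon and visibly
corrupts the chronosequence, so coherence is the default; contiguous
mixed-age labelling remains available (`group_by_age = FALSE`) with modal
aggregation (ties toward the smaller value).  Polygons smaller than 9000 m²
(ten 30-m pixels, under an inclusive ≥ rule) are dropped — the minimum
mapping unit of the coarse biomass product.

## The chronosequence and the growth model

Instead of following one stand through time, the analysis reads the
final-year cross-section of stand ages as a trajectory (space-for-time).  For
each group (driver category, or region × disturbance class):

1. each polygon contributes its **modal** AGC (AGB/2 under the 2:1
   biomass:carbon ratio).  Biomass rasters are near-continuous, so the mode
   is taken on 1 Mg C ha⁻¹ bins (configurable), ties toward the smaller
   value;
2. polygon values are aggregated to the **median AGC per age**;
3. a **bias correction** subtracts the smallest median from all medians so
   the youngest stands start at or near zero.

The corrected medians are fitted with the Chapman–Richards curve

$$Y(t) = A\,(1 - e^{-kt})^{c}, \qquad A, k, c > 0,$$

with the asymptote $A$ **fixed** at the group's bias-corrected old-growth
median AGC, and $(k, c)$ estimated by least squares
(Levenberg–Marquardt with positivity bounds, started at $k_0 = 0.1$,
$c_0 = 1$ and restarted on a 4 × 4 grid of $k \in \{0.01, 0.05, 0.1, 0.3\}$,
$c \in \{0.5, 1, 2, 4\}$; the best converged solution by residual sum of
squares is kept — the fitted optimum is checked against a dense grid scan in
the tests).  Fits are unweighted across ages (one median point per age,
matching the aggregation), with per-age-n weighting available.

Two numerical caveats worth knowing:

* **Bias correction is not curve-preserving.**  Subtracting
  $\min_a \mathrm{median}(Y_a) \approx Y(1) > 0$ from both the data and the
  asymptote leaves a function that is no longer exactly Chapman–Richards, so
  even noise-free data returns $(k, c)$ shifted by order $Y(1)/A$.  The
  package's exactness test therefore disables the correction
  (`bias_correct = FALSE`) and recovers the generator's parameters to
  $10^{-4}$; the corrected path is tested at the tolerance its distortion
  permits.
* **Increments are not monotone for $c > 1$.**  The curve inflects at
  $t^\ast = \ln(c)/k$; annual increments rise until $t^\ast$ and shrink
  afterwards.  Only for $c \le 1$ do they shrink from the start.  Projection
  code and tests use the correct condition.

Derived statistics: `predict_agc()` evaluates the curve; the mean
accumulation rate over the first $n$ years is $Y(n)/n$ (the conventional
"first 20 years" rate uses $n = 20$); `time_to_fraction()` inverts the curve
in closed form, $t = -\ln(1 - f^{1/c})/k$, and reports the first integer year
reaching the fraction.  The curve never attains $A$, so "reaching old-growth
carbon" needs a threshold; the default is 90% of the asymptote,
configurable.

Uncertainty: 95% intervals come from the asymptotic curvature (t-based) or a
seeded nonparametric bootstrap of age-row residuals (default 1000 draws,
which downstream stages reuse to propagate bands).  On the short tables the
desk-scale landscapes produce (10–15 age rows), we measured the residual
bootstrap to under-cover badly, so the replicate-recovery experiment uses the
asymptotic intervals; both are available on every fit.

## Drivers, binning and regionalization

Six drivers are attached per polygon as zonal means: shortwave radiation
(W m⁻²), annual precipitation (mm yr⁻¹), maximum cumulative water deficit
(MCWD, mm yr⁻¹), soil cation concentration (cmol(+) kg⁻¹), burned-area
exposure and the repeated-deforestation count.  MCWD runs the standard
deficit recursion with fixed evapotranspiration of 100 mm month⁻¹:
$\mathrm{CWD}_n = \min(0, \mathrm{CWD}_{n-1} + P_n - 100)$, reset each
window; the yearly MCWD is the most negative value and years are averaged.
Calendar-year windows are the default; the window anchor is configurable
because the source method leaves it open.  Coarse driver rasters are brought
to the 30-m grid by nearest-neighbour resampling (values replicated, never
smoothed).  Continuous drivers are binned at the 25/50/75th percentiles of
polygon-level values (half-open intervals, linear-interpolation quantiles) or
at explicit thresholds.

Climate regions come from K-means on z-scored (MCWD, radiation,
precipitation) pixel vectors — z-scoring because the units are incomparable —
with $k = 4$, 10 seeded restarts, clustered on the secondary-forest pixels
(whole-domain clustering optional) and every pixel then assigned to its
nearest centroid so old-growth pixels also carry a region.  Cluster labels
are canonicalised by ascending mean radiation, making "region 1" reproducibly
the wettest, least-irradiated (north-west-like) cluster.

Driver importance uses a deliberately stable protocol: 30 iterations, each
drawing a stratified subsample of 2500 records (strata default to the region
label), splitting 80/20, growing 500 regression trees on the training part
(via `ranger`) and measuring each predictor's **marginal permutation
importance** on the held-out 20% (MSE increase when that column is permuted).
Importances are converted to within-iteration ranks (1 = least, 7 = most
important; ties broken alphabetically for determinism) and averaged with a
t-based 95% interval — only the ranking is comparable across runs, not raw
importances, and the per-iteration raw values are kept for audit.  This is a
marginal variant, not the conditional permutation importance of
`party::cforest`; under strongly correlated predictors marginal importance
can share credit across the correlated set, which is why the contract is the
rank aggregation and the audit trail, not the absolute numbers.

## Carbon accounting, counterfactual and scenarios

Accounting is per pixel: every secondary pixel is scored with its (region,
disturbance class) curve at its own age, times 0.09 ha.  We use the pixel's
own flags and region rather than a polygon lookup because pixels outside
retained ≥9000 m² polygons still carry carbon and must be counted.  The
annual ledger between consecutive years books growth of persisting pixels
($Y(a{+}1) - Y(a)$), recruitment at $Y(1)$ (a one-year-old stand has one year
of growth), and losses as the model-predicted stock of deforested pixels
(an observed-AGC option exists).  Persisting pixels are scored with their
end-year class in both years so the identity
$\text{stock}_{end} = \text{stock}_{start} + \text{gains} - \text{losses}$
holds to machine precision even when a pixel burns between the two years.
The no-disturbance counterfactual rescores every secondary pixel with its
region's single-deforestation, unburnt curve at the observed age — it does
not rewind the clearing history, a conservative choice.  Components can be
aggregated to coarse reporting cells by exact summation (partition, no pixel
dropped or double-counted).

Preservation scenarios age the standing forest forward (no new clearing, no
recruitment): preserve all forests, or only those at least 5/10/15/20 years
old in the base year; non-preserved pixels are excluded at the base year
(optionally booked as an emission).  The headline "annual accumulation until
2030" is the mean over 2017–2030 — a single number summarising a declining
series, with the per-year path also reported.  Pledged-emission arithmetic
converts a reduction fraction of the 2.1 GtCO₂e yr⁻¹ baseline to
Tg C yr⁻¹ via $\times 1000 \times 12/44$, and the sink's contribution is the
plain percentage of that target.

## What the generator emulates — and what it does not

The generator is built to have recoverable ground truth:

* **Land use** is a blockwise Markov chain (default 5 × 5-pixel "fields"):
  old-growth clears at 0.02 yr⁻¹, anthropic land is abandoned to secondary
  forest at 0.10 yr⁻¹, secondary forest is re-cleared at 0.05 yr⁻¹ — the
  5–10-year clear/abandon cycling regime — and 10% of blocks start the
  window already cleared, which populates age 32 and exercises the
  original-conversion floor.  Fires strike standing secondary forest at
  0.02 yr⁻¹ from 2001.  Block-level drawing gives events the spatial
  coherence real fields have; within a block the chain is exactly per-pixel.
  A truth ledger records every event, so tests can replay any pixel
  independently.
* **Drivers** are planted as four quadrant regions whose means are the
  regional climates reported for Amazonia (radiation 163.6–188 W m⁻²,
  precipitation 1913–2100 mm yr⁻¹, MCWD −64.4 to −328.5 mm yr⁻¹), plus
  smooth within-region gradients centred so the anchors are exactly the
  regional means.  The monthly precipitation is a 12-month climatology with
  a six-month dry season whose depth encodes the target MCWD exactly
  ($\mathrm{MCWD} = 6\,(P_{dry} - 100)$); identical years make the
  multi-year mean equal the single-year value.  Soil cations are a smooth
  ramp deliberately unrelated to growth.
* **Carbon** is written from 16 known Chapman–Richards models (4 regions × 4
  disturbance classes).  Asymptotes (112–135.5 Mg C ha⁻¹) and
  no-disturbance 20-year rates (3.0 / 2.8 / 1.8 / 1.3 Mg C ha⁻¹ yr⁻¹ from
  wettest to driest) follow the published regional anchors, with disturbance
  multipliers spanning the reported 8–55% reductions; shape parameters
  are 1.3–1.5 and each $k$ is solved from $Y(20)$.  Secondary pixels carry
  $2\,(Y(\text{age}) + \varepsilon)$, $\varepsilon \sim N(0, 8)$ Mg C ha⁻¹,
  floored at zero; old-growth pixels carry twice the regional asymptote plus
  noise; anthropic pixels carry Uniform(0, 10) Mg ha⁻¹ background biomass.

It does **not** emulate: real Amazon geography or the biome's areal
proportions (the synthetic landscape is far denser in secondary forest than
the real ~4% of the biome, which *helps* the chronosequence); spatially
correlated product error; cloud or sensor artefacts; sub-annual dynamics;
plantation misclassification (exclusion masks are exercised with synthetic
points instead).  Passing tests therefore demonstrate the correctness of the
procedure and its estimators under known truth — not the accuracy of any
real-data product.

## Problem sizes and what the validation shows

The default landscape is 100 × 100 pixels (3 km × 3 km at 30 m) over
1985–2017; the replicate-recovery experiment runs 100 such landscapes, the
conservation property 100 seeded 20 × 20 landscapes, the importance check 30
iterations of 500 trees on 2500-record subsamples, and the history oracle
10⁴ random series — sizes chosen so the whole suite validates every stage in
a few minutes on one core.

Two honest findings from the validation are worth stating.  First,
arithmetic and structural properties (history reconstruction, MCWD,
ledger conservation, gridding, scenario dominance, the published-component
arithmetic) hold exactly.  Second, *statistical* recovery of $(k, c)$ from a
single desk-scale landscape is noise-limited: a 3 km landscape yields only
~15 no-disturbance polygons per region covering ~a third of the 32 ages, the
polygon-level modal AGC has a sampling sd of ~5 Mg C ha⁻¹ at pixel noise of
8, the zero floor censors the youngest ages, and in the driest region the
curve spans only a third of its fixed asymptote in 32 years so $(k, c)$
trade off along a ridge.  The acceptance experiment reports the resulting
median relative errors and interval coverage as measured; matched-noise
experiments on full 32-age tables recover parameters several times more
precisely, confirming the estimator (not the fitter) is data-limited at this
scale.  At the data volumes of the real products (millions of polygons per
age) this limitation vanishes.

## Limitations

Beyond the generator's idealisations: ages before the window opening are
unobservable (old-growth is "no clearing since 1985"); the fixed asymptote
transfers old-growth heterogeneity into fit error by design; losses are
instantaneous stock removals (no decay, no below-ground carbon); the
counterfactual keeps observed ages; and the importance module's marginal
permutation scheme shares credit under collinearity.  All thresholds that
embody a judgement call — the 9000 m² unit, connectivity, the mode bin
width and tie direction, percentile breaks, the 90% "old-growth level"
fraction, K-means $k$, the preservation thresholds — are exposed as
arguments with the defaults documented above.
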