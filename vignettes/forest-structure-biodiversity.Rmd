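---
title: "Linking radar and lidar forest structure to multi-taxon biodiversity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking radar and lidar forest structure to multi-taxon biodiversity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(forestdiv)
```

## The scientific problem

Forest biodiversity — which species assemble where, how many of them, and
how phylogenetically dispersed they are — is strongly structured by stand
structure: canopy cover and height reflect stand maturity, while vertical
and horizontal variability of the canopy reflect structural heterogeneity.
Airborne laser scanning (ALS) measures that structure in three dimensions
but is expensive to fly; space-borne C-band radar (dual-polarisation VV/VH
backscatter at 10 m pixel spacing) is freely and globally available but
only indirectly sensitive to canopy structure. `forestdiv` implements the
full analysis chain needed to ask how much biodiversity signal each sensor
carries:

1. **Structural metrics.** Thirteen ALS metrics per 1-ha plot (height
   distribution, layer penetration ratios, foliage height diversity,
   canopy gaps, canopy-surface statistics) and thirty-four radar metrics
   (seasonal median composites, seasonal and polarisation
   differences/ratios, focal statistics and grey-level co-occurrence
   textures).
2. **Biodiversity responses.** Assemblage composition by non-metric
   multidimensional scaling (NMDS) of Bray–Curtis dissimilarities, log
   species richness, the standardised effect size of mean pairwise
   phylogenetic distance (SES-MPD) against regional-pool null models, and
   Chao–Jost sample coverage.
3. **Sensor comparison and prediction.** Canonical correlation analysis
   between the two metric tables, and component-wise gradient-boosted
   additive models with region-stratified cross-validation and external
   validation.
4. **A synthetic landscape generator** that stands in for field data, so
   the entire chain is testable at desk scale against known latent
   gradients.

## The synthetic landscape: what it emulates

Field campaigns of this kind observe a few hundred 1-ha plots spread over
several regions, spanning long gradients of stand maturity and structural
heterogeneity. The generator reproduces that design: each plot carries a
latent maturity $M \in [0,1]$ and heterogeneity $H \in [0,1]$ (uniform,
with optional region-level shifts) plus a conifer fraction. The default
benchmark uses 250 plots in 5 regions with 60 species — large enough for
stable ordinations and cross-validation, small enough to run in minutes
on one core.

**Point clouds.** Returns are scattered over 1-m cells at a default
density of 5 pulses/m² (the emulated surveys range roughly 8–40 /m²; the
default sits just below that band to keep the benchmark light; density is
a parameter). Canopy top height follows $5 + 30M$ m, so the maturity
gradient spans 5–35 m stands. A fraction $0.4(1-M)$ of cells is gap
(ground-only returns); vegetated cells draw vegetation heights from a
Beta profile concentrated near the local top, with cell-to-cell relief,
within-canopy spread and understory occupancy all increasing in $H$.
These couplings make the 13 ALS metrics respond the way their field
counterparts do: penetration ratios and heights track maturity, height
variability and gap edges track heterogeneity.

**Backscatter.** Gamma-naught is simulated in dB on the 10-m grid. Mean
backscatter *decreases* with maturity, most strongly in winter (the
empirically observed direction for temperate forest C-band composites); a
static spatial field with standard deviation proportional to $H$ supplies
horizontal structure; the seasonal cycle has amplitude proportional to
the broadleaf fraction; speckle is additive Gaussian noise in dB
(multiplicative in linear power — the first-order SAR noise model; no
spatial correlation of speckle is simulated). Season windows default to
summer = June–August and winter = December–February and are configurable.

**Communities.** Species maturity optima evolve by Brownian motion on a
pure-birth phylogeny and are mapped to $[0,1]$ through the normal
distribution function, giving phylogenetic niche conservatism — related
species prefer similar successional stages, so SES-MPD responds to
maturity. Occurrence probability is a Gaussian response curve in maturity
(niche width 0.15, i.e. strong turnover) times a richness multiplier
rising linearly with heterogeneity from 0.4 to 1; abundance is
$1+\text{Poisson}$ given presence, so `occurrence == (abundance > 0)`
holds exactly. When simulating an *external* set of plots, pass the
training `optima` so species keep their niches.

What the generator does **not** emulate: radiative transfer, topography,
geolocation error, correlated speckle, observer effects, or taxon-specific
detection. Passing tests therefore demonstrate the correctness and
internal consistency of the estimators, not field-data performance.

## Metric definitions and numerical choices

**Penetration ratios** divide the returns captured by a layer by those
that reached it: canopy $n(h>5)/n$, understory $n(2<h\le5)/n(h\le5)$,
regeneration $n(0<h\le2)/n(h\le2)$ with ground returns in the
denominator, and canopy cover $n(h>2)/n$. Layer bounds are half-open
$(\text{lower}, \text{upper}]$; an empty denominator yields 0. Foliage
height diversity is the Shannon entropy of vegetation-return proportions
over the three layers, hence bounded by $\ln 3$.

**Gaps.** Cells (1 m default) with canopy-cover penetration below 0.2
form the gap mask; 8-connected components are gap features; features
smaller than 50 m² or with perimeter–area ratio below 1.5 /m are
excluded, and the surviving total area and exposed rook-edge length are
square-root transformed. The perimeter–area-ratio filter is applied
literally — *exclude if below the threshold* — although that reading
removes all large compact gaps (the ratio of a square gap shrinks with
its size). Because the intended units and direction are ambiguous, the
complementary reading (exclude *elongated* features above the threshold)
is available via `invert_par_rule = TRUE`; no intent is guessed, and both
paths are tested against a brute-force flood-fill oracle.

**Canopy surface model.** Highest return per 1-m cell, empty cells
filled from the nearest non-empty cell — a deliberately simple surface
(no pit-free interpolation), which slightly roughens sparse-return CHMs.
The surface ratio triangulates the cell-centre lattice (two triangles per
cell) and divides the 3-d area by the flat lattice area, so a plane of
slope $s$ gives exactly $\sqrt{1+s^2}$.

**Radar composites** are per-pixel medians over the dates of each window
(year, summer, winter), computed in dB. Seasonal differences stay in dB;
the VV/VH "ratio" is computed on the linear power scale $10^{\mathrm{dB}/10}$
so that difference and ratio remain distinct quantities (a dB ratio would
duplicate the dB difference). Whether to summarise in linear power before
conversion is unresolved in practice; dB is the default, and composites
accept either by transforming the stack first.

**Texture.** Grey-level co-occurrence matrices are accumulated per
moving window (9×9 default, truncated at edges, no padding) after
min–max quantisation to 32 levels *within the window*; counts are
symmetric and the four offsets (0,1), (1,0), (1,1), (1,−1) are averaged.
Dissimilarity is $\sum p_{ij}|i-j|$ (contrast group) and entropy
$-\sum p_{ij}\log p_{ij}$ (orderliness group). Per-window quantisation
makes both statistics invariant to adding a constant in dB, which is the
behaviour wanted from a heterogeneity index; global quantisation is the
main alternative and would couple texture to the absolute level.

## Ordination, diversity and their numerics

Bray–Curtis on presence–absence is $1 - 2a/(S_A+S_B)$ with $a$ the
shared species count. NMDS minimises Kruskal stress-1 with a
best-of-30-random-starts strategy (plus a metric-scaling start); the
winning configuration is centred and rotated to principal axes so NMDS1
carries maximal variance. Dimensionality follows the "smallest $k$ with
stress < 0.2" rule; to keep the reported stress sequence non-increasing
each dimension also restarts from the previous winner padded with a tiny
extra axis. The underlying stress minimiser is `vegan::monoMDS`
(isotonic-regression NMDS); tests check its solutions against an
independent direct minimisation of stress-1.

SES-MPD compares the observed mean pairwise patristic distance with 999
richness-matched random assemblages drawn without replacement from the
plot's regional species pool: $(\mathrm{MPD}_{obs} -
\overline{\mathrm{MPD}}_{null})/\mathrm{sd}(\mathrm{MPD}_{null})$. Plots
with fewer than two species and degenerate nulls (e.g. star phylogenies)
are flagged rather than dropped silently. Under its own null the
statistic is approximately standard normal, which the tests verify by
simulation. Richness is natural-log transformed. Sample coverage uses
the Chao–Jost estimator
$1-(f_1/n)\,[(n-1)f_1/((n-1)f_1+2f_2)]$ with a helper to subset plots
above 0.9/0.8/0.7 coverage.

## Canonical correlation and the boosted models

Both metric tables are standardised; canonical directions come from the
singular value decomposition of the whitened cross-covariance. A ridge of
$10^{-10}$ on the within-set covariances (recorded in the fit) guards
against near-singular covariances while leaving exact-duplication cases
at canonical correlation 1 to within $10^{-8}$. Axis signs are fixed by
making each axis's largest-magnitude structure correlation positive.
Sequential Wilks' $\Lambda_k = \prod_{i\ge k}(1-r_i^2)$ tests use Rao's
F-approximation; its type-I rate is verified by simulation. The
redundancy index per axis is the RDA-style mean squared structure
correlation times $r^2$ — the precise "RDA-adjusted $R^2$" convention in
use elsewhere is not standardised, so the implemented formula is named
and replaceable.

The boosted additive models use component-wise $L_2$ boosting: offset =
mean response; per iteration every base learner is fit to the residuals
by penalised least squares and only the best (smallest residual sum of
squares; ties to the earlier learner) is updated with step length
$\nu = 0.1$. P-spline learners use 20 interior knots, cubic B-splines, a
second-order difference penalty and 4 effective degrees of freedom
(penalty solved by matching the trace of the smoother); the region
"random factor" is a penalised categorical ridge learner with one
effective df per spare level — the standard random-intercept surrogate in
component-wise boosting. The stopping iteration is tuned on a 10–500
grid (step 10; finer steps change little and cost linearly) by 25
bootstrap resamples scored out-of-bag, independently within each
cross-validation fold. Prediction clamps spline inputs to the training
range (constant extrapolation) and gives unseen factor levels zero
contribution. The in-sample risk path is provably non-increasing, a
single linear learner converges to the ordinary least-squares fit, and
variable importance aggregates per-learner risk reductions.

## Evaluation design

Cross-validation is five-fold and region-stratified: plots are dealt into
folds within each region, so every fold spans all regions. $R^2$ on the
held-out fold is $1-\mathrm{SSE}/\mathrm{SST}$ about the test-set mean
(primary; the squared observed–predicted correlation is reported
alongside, as the two definitions are often conflated). Mixed-variant
models are fit with the region learner but scored with
fixed-effects-only predictions, which isolates the variance explained by
region: on data whose variance is pure region offsets the fixed-only
score collapses to ~0 while the full-model training risk goes to ~0.

External validation ordinates training and external communities jointly
(default), trains on the training plots only and predicts the external
plots' NMDS1; a dissimilarity-weighted projection onto the training
ordination is available as the alternative strategy because the
projection method used with real campaigns is generally unstated.

## The benchmark and what it shows

`run_pipeline(default_benchmark_config(seed))` executes
simulate → metrics → responses → canonical correlation → cross-validated
models and writes a report with one row per response × sensor × model,
plus a seed-complete manifest; reruns are byte-identical.
`scripts/acceptance.R` runs the same benchmark plus the SES-MPD null
calibration and the external validation, and writes the headline numbers
as JSON. On the default conditions the first canonical axes recover
latent maturity almost perfectly (|r| > 0.99), the NMDS1 models clearly
outperform the richness models for both sensors, and an unseen region
simulated with the same species niches is predicted well — the same
qualitative pattern reported from field campaigns, though cleaner,
because the generator omits most real-world noise sources.

Problem sizes used throughout (250 plots, 60 species, 5 pulses/m²,
monthly acquisitions, 999 null draws, 25 bootstrap resamples) were
chosen once as a desk-scale emulation of a multi-region campaign.

## Known limitations

* The gap perimeter–area-ratio filter has two defensible readings (see
  above); results for gap metrics depend on the flag chosen.
* The CHM is a nearest-neighbour-filled maximum surface; pit artefacts
  are not removed.
* The generator's structure–backscatter couplings are plausibility
  devices with the right signs and monotonicity, not calibrated physics;
  absolute dB levels and model $R^2$ on synthetic data should not be
  read as field predictions.
* Ordination is joint across all plots; per-region ordinations are not
  implemented.
* Only Gaussian-loss boosting with P-spline/linear/ridge learners is
  provided (no tree learners, no stability selection).
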