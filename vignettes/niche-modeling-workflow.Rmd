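---
title: "Methods: presence-only niche modeling, area dynamics and niche differentiation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: presence-only niche modeling, area dynamics and niche differentiation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(enmdyn)
```

This vignette is the package's account of its models and of the design
choices that were genuinely open. It is written for a reader who wants to
know exactly what is computed, under which assumptions, and what the passing
test suite does and does not demonstrate about real data.

## The modeling problem

The pipeline estimates, for a species known only from presence records, the
set of climatic conditions under which it can occur; projects that estimate
onto climate layers for other periods or emission scenarios; converts the
thresholded projections into regional areas; and, separately, asks which
climatic variables statistically separate the realized niches of two or more
species. Occurrence data of this kind (museum collections, sequence
databases, citizen-science portals, literature) carry strong spatial
collection bias, which the pipeline addresses twice: by distance-based
thinning of the records and by sampling modeling background from a
kernel-density estimate of collection effort, so that the model contrasts
presences against effort-matched availability rather than raw geography.

## The maximum-entropy model

### Objective

With presences $x_1,\dots,x_m$ and background cells $z_1,\dots,z_N$ described
by derived features $f_j$, the model is the Gibbs distribution over
background cells $P_\lambda(z) \propto e^{\eta(z)}$,
$\eta = \sum_j \lambda_j f_j$, and the coefficients maximize the penalized
presence log-likelihood

$$\frac{1}{m}\sum_{i=1}^m \eta(x_i) \;-\; \log\sum_{k=1}^N e^{\eta(z_k)}
  \;-\; \sum_j \beta_j\,|\lambda_j|.$$

This objective is concave; the solver (`fit_maxent()`) is an accelerated
proximal-gradient (FISTA) iteration with backtracking line search and
adaptive restart, written in C++ (RcppArmadillo). Convergence is declared
when the relative objective change falls below $10^{-7}$ (iteration cap
5000); a generic split-variable L-BFGS-B solver serves as an independent
oracle in the tests and agrees to $10^{-4}$ in the coefficients.

### Features and penalties

Variables are min–max scaled to $[0,1]$ by their background range. Feature
classes: linear (the scaled variable), quadratic (its square), product (all
pairwise products), hinge (forward and reverse ramps at knots) and threshold
(step indicators at knots). Knots default to 50 per variable, evenly spaced
strictly inside the scaled range. The per-feature penalty is
$\beta_j = rm \cdot \mathrm{base}(\text{class}, m) \cdot s_j$ with $s_j$ the
feature's standard deviation over the presences (floored at $10^{-3}$), $rm$
the user-facing regularization multiplier, and $\mathrm{base}$ the published
MaxEnt default table (linear/quadratic/product interpolated in $m$; hinge
0.5; threshold interpolated from 2 at $m=0$ to 1 at $m\ge100$).

### Output scales

`predict_raw()` returns $e^{\eta - \log Z}$, a distribution over the training
background (sums to one); `predict_cloglog()` returns
$1 - \exp(-e^{H}\,\mathrm{raw})$, where $H$ is the entropy of the fitted raw
distribution. The all-zero-coefficient model therefore scores
$1 - e^{-1} \approx 0.632$ everywhere — a useful analytic anchor that the
tests assert exactly. Projection onto a layer stack clamps scaled features to
the training $[0,1]$ range by default, the conventional guard against
extrapolated responses; disable with `clamp = FALSE`.

### Variable importance

Percent contribution allocates $|\lambda_j| \cdot sd_j(\text{background})$
to each variable (product features split evenly between their two variables)
and normalizes to 100. This is a deliberate deviation from the
optimizer-path-accounting used by the original MaxEnt implementation, whose
result depends on the optimization trajectory and is therefore not
reproducible across solvers; the $|\lambda|\times sd$ allocation measures the
same thing — how much of the linear predictor's variation a variable carries
— and is solver-independent. Permutation importance is the normalized drop in
training AUC after permuting one variable across the pooled presence +
background rows, with a fixed seed.

## Tuning, evaluation and model choice

* `tune()` fits every combination of the six feature-class sets (L, LQ, LQH,
  H, LQHP, LQHPT) with multipliers 1–6 and ranks them by AICc, with the raw
  distribution renormalized over the full study grid (the established
  convention for presence-only AICc) and $k$ = the number of nonzero
  coefficients; combinations with $k \ge n-1$ are invalid. Fits are
  warm-started across multipliers within a class set.
* `make_replicates()` implements bootstrap replicates: a random 25% of
  presences held out for testing, the remaining 75% resampled with
  replacement to its own size. The replicate type named "bootstrap" in the
  original tool is under-documented; this reading matches both the name and
  the stated test percentage.
* `evaluate_candidate()` reports per-replicate train/test AUC (Mann–Whitney
  with midranks), the maxSSS threshold (candidates are the union of observed
  scores; ties break toward the smallest threshold, which makes the choice
  reproducible), the test omission rate with an overfitting flag above 0.1,
  and the partial ROC.
* `choose_model()` is lexicographic: lowest mean test omission, then smallest
  mean |train − test| AUC gap, then highest test AUC — omission first,
  because for widespread species a lower-AUC model with low omission is
  usually the more faithful one.
* `select_variables()` optionally precedes tuning: variables with percent
  contribution below a floor are dropped, and of each background-correlation
  pair above 0.9 the lower-contribution member is dropped, to a fixed point.
  The per-iteration contribution fit uses LQ features at $rm = 1$; the final
  tuning then runs on the retained subset.

### A caveat on the partial ROC p-value

The partial ROC test resamples the test presences (default: half, with
replacement, 500 iterations), restricts the sensitivity-versus-area curve to
the region with omission $\le E = 0.05$, and reports the mean ratio of the
model's partial AUC to the chance-line partial AUC plus the proportion of
ratios $\le 1$ as a p-value — the construction used by the field's standard
tools. Users should know that this p-value is not a calibrated frequentist
p-value: because the omission region is selected from the observed presence
scores, the restricted AUC ratio is biased slightly above 1 under the null
(about +0.01 to +0.05 depending on test-set size), so null p-values
concentrate below 0.5 instead of being uniform. The mean ratio itself is
well centered (the tests verify $1 \pm 0.05$ under the null and a clear
separation on planted signal); treat the p-value as a heuristic strength
measure, not an error rate.

## Thresholds, areas and regions

Projections are averaged over the bootstrap replicates, thresholded at the
maxSSS cloglog value, and converted to km² analytically on the 6371-km
sphere: a cell in a row bounded by latitudes $\phi_b, \phi_t$ has area
$R^2\,\Delta\lambda\,(\sin\phi_t - \sin\phi_b)$, identical along the row.
The analytic route (rather than an equal-area reprojection) is exactly
specified, testable against the $4\pi R^2$ identity, and free of resampling
artifacts. Cells are assigned to Europe iff their center longitude is west of
60°E (the Ural line; a center exactly on the meridian counts as Asia) and to
the polar belt iff their center latitude is at or above 66.562°N, so
Europe + Asia = total holds exactly. Climatic-variable ranges are the
min/max of each layer over the suitable cells.

## Niche differentiation

PCA runs on the correlation matrix (standardized variables) because the
inputs mix °C and mm; component count is chosen by the broken-stick rule
($b_k = \frac{1}{p}\sum_{i=k}^p 1/i$; retain the leading run of components
whose variance share exceeds $b_k$), and each retained component's scores go
through one-way ANOVA and Tukey HSD with significance declared at
$p < 0.001$. Components whose ANOVA is not significant are reported but
flagged rather than dropped silently.

For each species pair, multicollinearity is handled by exhaustive subset
search: for every subset size the subset minimizing the condition number
(computed as $\sqrt{\lambda_{max}/\lambda_{min}}$ of the subset correlation
matrix, which equals the singular-value ratio of the standardized columns) is
kept, and the final set is the largest size whose VIFs (diagonal of the
inverse subset correlation matrix) all stay $\le 10$. The search is exact and
feasible to $p = 19$ ($2^{19}-1$ subsets) because each evaluation is an
eigendecomposition of a small matrix.

Discrimination uses L2-penalized logistic regression: features standardized
on the training split only (stratified 80/20), penalty strength chosen from
100 linearly spaced values in $[0.001, 0.5]$ by 5-fold cross-validated
ROC-AUC, the final fit minimizing mean log-loss
$+\ \lambda_{pen}\lVert\beta\rVert^2$ (intercept unpenalized) by BFGS with an
analytic gradient. The penalty grid is interpreted as penalty *strength*
(larger = more shrinkage), linearly spaced; both choices are configurable
because conventions differ between implementations. For a linear model with
the reference at the training feature means, Shapley attributions have the
closed form $\phi_{ij} = \beta_j (z_{ij} - \bar z_j)$ on the linear-predictor
scale, which the tests verify against exhaustive coalition enumeration;
partial-dependence curves average the predicted probability over the data
with one variable overwritten.

## The synthetic study system

`make_climate_stack()` builds each variable as a planar
latitudinal/longitudinal gradient plus smoothed Gaussian noise: white noise
is smoothed by a separable moving average (correlation length 5 cells),
empirically whitened, and mixed through the Cholesky factor of a target
correlation matrix, so the noise components' empirical correlations equal the
target essentially exactly; nonzero gradients then shift the total
correlations, as shared large-scale structure does in real bioclimatic
layers. Defaults: a 100 × 100 grid of 0.25° cells over 10–35°E, 30–55°N;
variables `bio1`–`bio11` temperature-like (south-west value 24 °C, −23 °C
across the latitude span, noise sd 2.5 °C), `bio12`–`bio19`
precipitation-like (500 mm, −400 mm across the longitude span — a
continentality-style drying —, +200 mm northward, noise sd 120 mm); noise
correlation target $0.5^{|i-j|}$ between variable indices.

`virtual_species()` uses a bell-shaped response per driver with an optional
optimal plateau: suitability 1 within $|z-\mu| \le w$, Gaussian shoulders of
sd $\sigma$ beyond, multiplied across drivers. The pure Gaussian bell is the
special case $w = 0$. The plateau matters for recovery testing: when
presences are drawn proportional to suitability, the maxSSS threshold settles
near the grid-mean suitability, and for a spatially Gaussian bell the area
above that threshold is a multiple (2–5×) of the area above a fixed mid-scale
cutoff — no thresholding rule can then match a cutoff-defined "true area".
With a flat-topped response the suitability surface is close to binary, the
two areas coincide, and area recovery becomes a meaningful test. The default
species (optimum 12 °C / 500 mm, plateaus 3.5 °C / 90 mm, shoulders 0.35 °C /
10 mm, truth cutoff 0.5) occupies roughly a tenth of the default grid.

`sample_presences()` draws cells with probability proportional to
suitability × collection bias and jitters coordinates within the cell;
`make_scenario()` applies additive offsets (e.g. +2 °C to the temperature
block) as period variants; `two_species_scenario()` shifts a second species'
optimum by a stated multiple of the first species' realized spread and
returns the labeled feature table with its ground truth.

What the generator does *not* emulate: non-climatic range limits (dispersal,
biotic interactions, land/sea masks), non-additive climate change,
observation error in coordinates beyond sub-cell jitter, temporal
autocorrelation of sampling, and the heavy-tailed, regionally structured bias
of real collections. Passing recovery tests therefore demonstrate that the
implementation is correct and that the workflow can recover a knowable truth
under its own assumptions — not that any particular real-data model is
right.

## Numerical choices and degenerate inputs

* Thinning is greedy in year-descending order (unknown years last, stable
  within ties), keeping a record iff it is >50 km (great-circle, R = 6371 km)
  from every kept record: deterministic, idempotent, and honoring the
  recency preference. Printed retained counts from any specific dataset are
  order-sensitive where years tie, which is why small count differences are
  tolerated when comparing against published numbers.
* The bias-surface KDE uses the normal-reference bandwidth
  $4 \times 1.06\,\min(sd, IQR/1.34)\,n^{-1/5}$ per axis with kernel sd
  $h/4$ (`MASS::kde2d` convention), on unprojected degrees; records at a
  single unique coordinate are an error directing the caller to jitter or
  use a uniform surface.
* Point-in-cell assignment is half-open ($[w, e) \times [s, n)$), so edge
  points are assigned uniquely; cropping keeps cells whose centers fall in
  the half-open box.
* maxSSS threshold ties (including floating-point ties at $10^{-9}$) break
  toward the smallest candidate.
* Constant variables keep only their linear feature (with a warning);
  constant columns are an error in PCA; exactly collinear subsets are
  reported with infinite condition number and excluded.
* The logistic CV grid keeps the first maximum on ties, making the chosen
  penalty deterministic.

## Problem sizes in the tests and the acceptance script

The test suite exercises the full pipeline at reduced sizes (30–60 cell
grids, 3–12 variables, 50–200 presences) and the complete default scenario
(100 × 100 grid, 19 variables, 200 presences, 2000 background, all 36
class/multiplier combinations) across 10 generator seeds for the recovery
check; the acceptance script reports medians over 3 such worlds plus the
differentiation track at full size. These sizes are the package's choice of
desk-scale defaults: large enough that AUC and area estimates stabilize,
small enough that the whole suite runs in minutes on one CPU.

## Known limitations

* Percent contribution is defined via $|\lambda| \times sd$, not the
  original tool's path accounting; numbers are comparable in meaning but not
  digit-for-digit with MaxEnt output files.
* The partial ROC p-value is heuristic (see above).
* Hinge/threshold knots are evenly spaced, not data-quantile placed.
* The active-set size of the L1 fit is not guaranteed monotone in the
  regularization multiplier (only the weighted penalty norm is); model-size
  comparisons across multipliers should use AICc, not raw counts.
* Categorical variables, replicate-averaged response curves, and
  niche-overlap indices (e.g. Schoener's D) are out of scope.
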