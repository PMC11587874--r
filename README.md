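# enmdyn

Presence-only climatic niche modeling, suitable-area dynamics across climate
periods, and between-species niche differentiation — as one tested, scriptable
R pipeline.

The package is aimed at ecologists who model where a species' climate is
suitable from presence-only occurrence records (museum collections, sequence
databases, citizen-science portals, literature) plus gridded bioclimatic
layers (`bio1`–`bio19`), and who then ask two questions: how does the area of
suitable climate change across past, current and future climate layers, and
which climatic variables separate the niches of related, co-occurring
species?

## What it computes

**Presence–background maximum-entropy model.** Given presence cells and a
background sample, the model is the Gibbs distribution over background cells

```
raw(x) = exp(eta(x) - log Z),    eta(x) = sum_j lambda_j f_j(x),
```

with features `f_j` drawn from the classes L (linear), Q (quadratic),
H (hinge), P (product) and T (threshold) on variables min–max scaled by their
background range. The coefficients maximize the L1-penalized presence
log-likelihood

```
(1/m) sum_presence eta(x)  -  log sum_background exp(eta(x))  -  sum_j beta_j |lambda_j|,
```

where `beta_j = rm * base(class, m) * sd_j` follows the standard MaxEnt
default regularization scaled by the regularization multiplier `rm`. The
working output scale is cloglog, `1 - exp(-e^H raw(x))`, with `H` the entropy
of the fitted distribution. Feature classes and `rm` are tuned by the
small-sample corrected AIC (`AICc = 2k - 2 lnL + 2k(k+1)/(n-k-1)`, `k` =
nonzero coefficients, likelihood renormalized over the study grid), and
candidate models are evaluated with bootstrap replicates (train/test AUC,
maximum-sensitivity-plus-specificity thresholds, omission rates, partial
ROC), prioritizing low omission.

**Area dynamics.** Cloglog projections onto per-period layer stacks are
thresholded at the maxSSS value and converted to km² with exact spherical
cell areas, split into Europe/Asia at 60°E and a polar share at 66.562°N.

**Niche differentiation.** Standardized PCA with broken-stick retention and
ANOVA + Tukey HSD on the retained scores; exhaustive condition-number/VIF
variable-subset selection; stratified 80/20 split; L2-penalized logistic
discrimination with the penalty chosen by 5-fold cross-validated ROC-AUC over
100 values in [0.001, 0.5]; test metrics (ROC-AUC, precision, recall, F1) and
exact linear Shapley attributions with partial-dependence curves.

**Synthetic data.** A generator produces correlated climate raster stacks
(gradients + smoothed, correlation-mixed noise), period variants by additive
offsets, virtual species with known bell-shaped niches, and biased
presence-only samples — so every stage of the pipeline runs and is tested at
desk scale without external downloads. Real layers in ESRI ASCII format and
delimited occurrence tables plug into the same functions.

## Worked example

```r
library(enmdyn)

# a synthetic Palearctic-like study system with known truth
spec  <- synthetic_climate_spec(seed = 42)
stack <- make_climate_stack(spec)
species <- virtual_species(stack)          # temperate virtual species
occ <- sample_presences(species, 200, seed = 42, label = "virtual")

# presence/background samples-with-data tables
pres <- extract_swd(stack, occ, "virtual")
bg   <- extract_swd(stack,
                    sample_background(uniform_bias_surface(stack$spec),
                                      2000, seed = 43),
                    "background")

# AICc tuning over 6 feature-class sets x multipliers 1..6
tuning <- tune(pres, bg, stack)
print(tuning)
#> tuning_result: 36 combinations; best LQHPT, rm = 2 (AICc 2989.31)

# threshold the projection and compare with the species' true range
model <- tuning$best_model
t_sss <- max_sss_threshold(predict_cloglog(model, pres),
                           predict_cloglog(model, bg))
suit  <- project_model(model, stack)
areas <- regional_areas(threshold_map(suit, t_sss))
cat(sprintf("maxSSS threshold: %.3f\n", t_sss))
#> maxSSS threshold: 0.647
cat(sprintf("estimated suitable area: %.2f mln km2 (truth: %.2f mln km2)\n",
            areas$total / 1e6, species$true_area_km2 / 1e6))
#> estimated suitable area: 0.88 mln km2 (truth: 0.84 mln km2)
```

The tuning table says hinge-rich features with a multiplier of 2 minimize
AICc for this species; the thresholded projection recovers the species' true
occupied area to within about 5% here. `run_enm()` chains the full
per-species workflow (thinning → bias surface → background → tuning →
replicate evaluation → projections → regional areas → variable ranges), and
`run_differentiation()` runs the PCA/ANOVA and per-pair logistic
discrimination track; see the methods vignette
(`vignettes/niche-modeling-workflow.Rmd`) for the modeling details and design
choices.

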