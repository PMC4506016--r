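---
title: "Ensemble SDMs with AIC multimodel averaging: models, design and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble SDMs with AIC multimodel averaging: models, design and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ensdm)
```

This vignette is the package's own account of its science: the statistical
models and the assumptions behind them, the parameters that matter and why
their defaults are what they are, what the synthetic-data generator does
and does not emulate, and the numerical choices made where the design was
genuinely open.

## The modelling frame

The unit of analysis is the cell-season-year stratum. Sightings are
assigned to the square grid cell containing their position; cells are
half-open intervals $[x, x+c) \times [y, y+c)$, so a record on an interior
edge belongs deterministically to the higher-index cell. Seasons follow the
austral coastal quarters (summer Jan–Mar, autumn Apr–Jun, winter Jul–Sep,
spring Oct–Dec). Each stratum carries three ecological measurements —
presence/absence, number of sightings, summed individuals — and the survey
effort (km of track) accumulated in it. Strata under 1 km of effort are
excluded to avoid small-sample bias; the threshold is inclusive (exactly
1 km is retained), reading "a minimum of 1 km" at face value. Pooling
within a stratum happens before the filter.

## Candidate models

Presence is binomial with logit link. Both count responses are negative
binomial with log link and `offset(log(effort_km))`; the offset applies to
the summed group-size response as well as sightings, since both are
accumulated over the same uneven effort. The NB dispersion $\theta$ is
estimated by maximum likelihood per candidate (via `MASS::glm.nb`) and is
counted as an estimated parameter in the $k$ of $AIC = -2\ell + 2k$. The
choice of NB over Poisson is diagnosable with `check_overdispersion()`,
the Pearson $\chi^2/df$ of the null Poisson model with offset; ratios
above 1.5 recommend NB.

"GAM" candidates use natural cubic spline bases (`splines::ns`) with a
fixed 3 degrees of freedom per term instead of penalized smoothers. This
makes the cap of 3 df per smooth *exact* rather than an upper bound on
effective df, keeps every candidate a plain ML fit (so AIC's $k$ is
unambiguous), and makes all-subsets enumeration over $2^k$ models cheap
and fully reproducible. The cost is that smoothness is not data-adaptive
within a term; with at most 3 df the difference from a penalized fit
capped at the same complexity is small, and the linear-limit behaviour is
verified in the test suite (a spline fit on linear truth reproduces the
GLM fit).

Predictors are z-standardized (mean 0, sample SD 1) before fitting.
Centering/scaling parameters are estimated on training data only and
re-applied verbatim to test and prediction data — never re-estimated —
so coefficients remain comparable and prediction is honest.

## Collinearity screening

Pairs with Spearman $|r_s| \ge 0.7$ (inclusive, midranks for ties) are
resolved by fitting one univariate model per member — with the family and
offset of the response at hand — and keeping the lower-AIC member. Open
design points resolved here: pairs are processed in descending $|r_s|$,
and pairs involving an already-removed variable are skipped, which makes
chained collinearity ($A \sim B$, $B \sim C$) deterministic; AIC ties
break alphabetically; screening is per response (the same variable can
survive for one response and not another), with the removal log reporting
each decision.

## Multimodel inference

All $2^k$ subsets of the retained predictors (including the null model)
are fitted per technique; a guard refuses $k > 15$. Akaike weights are
computed with the $\Delta$-subtraction for numerical stability, and the
95% confidence set is the minimal weight-ranked prefix with cumulative
weight $> 0.95$ (a $10^{-9}$ tolerance keeps exact-boundary cumulative
sums, e.g. uniform weights, from being tipped by floating-point error).
Candidates that fail to converge are dropped from the ranking with a log
entry rather than aborting the run.

Averaging operates on *response-scale predictions* with weights
renormalized within the confidence set: this is a convex combination, so
averaged probabilities stay in $[0,1]$ and averaged counts stay
non-negative, and it sidesteps the full-versus-conditional ambiguity of
coefficient averaging. Full-average coefficients (absent terms counted as
zero) are available from `coef()` for interpretation only. Averaging is
always over the confidence set, even when the top model's weight exceeds
0.9 — in that regime the average is dominated by the best model anyway.
GLM and GAM candidate sets are ranked and averaged separately, never mixed
in one average.

## Evaluation and diagnostics

Cross-validation is temporal: the early years train, the final year
tests, mirroring how such models are used for forecasting. Discrimination
is the concordance index over all pairs with unequal observed outcomes
(ties in predictions count one half); it applies unchanged to binary and
count outcomes and equals ROC AUC in the binary case. Because survey data
arrive in seasonal blocks, the C-index is computed per season-year stratum
and summarized as a mean and SD across strata; strata with constant
outcomes are skipped.

Residual spatial autocorrelation is checked on the deviance residuals of
the lowest-AIC candidate, averaged per cell, with Moran's I under binary
distance-band weights (default band 0–2 km: the eight neighbours of a
1 km cell). The correlogram computes per-band Moran's I with a two-sided
randomization test, $p = (1 + \#\{|I_{perm}| \ge |I_{obs}|\})/(1 + B)$ —
the observed statistic counts itself, so $p \ge 1/(B+1)$ and the test is
valid at finite $B$. Empty distance bands are reported as undefined, not
fatal. No spatial random effects are fitted: the intended workflow is to
*verify* the absence of residual structure, as the test suite does on the
generator's spatially-smooth-but-model-captured fields.

## Ensemble consensus

The two averaged surfaces per response combine per cell as
$WA_i = \sum_j C_j m_{ji} / \sum_j C_j$ with $C_j$ the technique's mean
training C-index (a global mean, not per-season — the per-season
alternative adds noise to weights that differ by a few hundredths). The
result is again convex and invariant to rescaling all $C_j$.

## Habitat classification and protected-area overlap

Ensemble surfaces over the training strata stack into per-cell mean and
sample-SD maps; thresholds are the averages of each map over categorizable
cells. Classification: SD above the SD threshold is *occasional*
(inter-annual variability takes precedence, so a cell with high mean and
high SD is occasional); otherwise mean above the mean threshold is
*recurrent*; otherwise *unfavourable*. Ties at either threshold fall to
the low side (strict inequalities). Cells missing any layer are
*uncategorized* and excluded from the threshold computation. The
classification is invariant under a common affine rescaling of both maps.

Abundance is the literal cell-wise product of the sightings and
group-size ensemble surfaces, summed over categorizable cells. Because the
group-size response is a per-cell *sum* of individuals, the product's
units are best read as a relative abundance index at the chosen reference
effort rather than a head count; `abundance_surface(..., per_sighting =
TRUE)` records the alternative convention when the second surface is a
mean group size per sighting.

Protected-area membership is center-in-polygon (even-odd ray casting, no
partial-cell weighting). The assessment reports each category's
percentage inside/outside, the key-area (recurrent + occasional) capture,
and Welch unequal-variance two-sided t tests of per-cell mean predictions,
ordered outside minus inside so preference for the protected area gives a
negative t. Exact p-values are always reported; no significance verdict is
hard-coded.

## The synthetic study system

The generator emulates the statistical structure the models consume, not
the oceanography behind it:

* **Field layers** (depth, slope, chlorophyll and its variability, SST and
  its variability) are Gaussian-smoothed white noise rescaled min–max to
  realistic printed ranges (e.g. depth 0.12–102.12 m, SST
  25.43–29.95 °C). Dynamic layers are redrawn per season-year stratum and
  blended (60/40) with a seasonal base level, so e.g. summer SST runs
  warmer than winter while staying in range.
* **Distance layers** (to coast, reef, 100 m isobath, front) are raw
  Euclidean distances from randomly placed polylines; fronts are redrawn
  per stratum. Distances are kept unscaled so they verify exactly against
  a brute-force minimum-distance oracle.
* **Effort** emulates non-systematic vessel surveys: each cell is surveyed
  with a probability calibrated so the *expected* fraction of cells
  receiving at least 1 km equals the target coverage (default 0.69, the
  study system's quarterly coverage), with gamma-distributed effort
  (shape 2, mean 4 km) in surveyed cells — so some surveyed cells fall
  under the 1 km filter and that stage is genuinely exercised.
* **The virtual species** has two layers, the standard device in SDM
  benchmarking: latent suitability $Z \sim Bern(\text{logit}^{-1}(\eta_{occ}))$
  and raw encounters $N_{raw} \sim NB(\mu = e \cdot e^{\eta_{sgt}}, \theta)$,
  with realized sightings $N = Z \cdot N_{raw}$. This decomposition is
  deliberate: it keeps the expected count exactly linear in effort
  (offset contract) and gives parameter-recovery tests direct access to
  each channel's known coefficients. The single coupled draw that would
  make derived presence exactly Bernoulli-logistic *and* counts
  offset-linear does not exist. Default truth coefficients put the
  strongest (negative) effects on distance to the 100 m isobath and to
  fronts, with reef distance and SST secondary — the qualitative pattern
  of the motivating system. $\theta$ defaults to 1; group sizes per
  sighting are zero-truncated NB with mean 23.26 and dispersion 0.2,
  reproducing a heavy-tailed delphinid group-size distribution (SD about
  twice the mean).
* **Reproducibility**: one master seed; every layer and stage derives its
  own child stream from it deterministically, so regenerating any part of
  a scenario is bit-identical.

What the generator does **not** emulate: satellite-derived covariance
between layers (fields are mutually independent up to chance), tidal or
diurnal structure, animal movement and the resulting serial correlation of
sightings, detection-probability variation with sea state, and coastline
geometry (the grid is a full rectangle). Passing tests therefore
demonstrate that the *inference machinery* is correct and well calibrated
under known truth — not that any particular real dataset meets the
models' assumptions.

## Problem sizes and numerical choices

The packaged checks run at the scale of the motivating study: a 14×14 grid
(196 cells) with 14 season-year strata (three full years and one two-season
year training, the final year testing), about 1,900 modelling strata;
parameter recovery uses 100 replicates of 2,000 strata; ensemble
discrimination uses 50 replicates; correlogram calibration uses 200
replicates of 999 permutations on a 7×7 grid. These sizes make the whole
suite complete in a few minutes while keeping Monte-Carlo error well inside
the asserted margins. Other numerical conventions collected here: the
minimum-effort threshold and the Spearman threshold are inclusive;
confidence-set membership uses the $10^{-9}$ boundary tolerance; AIC ties
in screening break alphabetically; non-converged candidates are dropped and
logged; the no-data value in exported rasters is −9999.

## Known limitations

* Plain AIC is used, not AICc; at ~500+ training strata per response the
  difference is negligible, but for much smaller datasets a small-sample
  correction would be preferable.
* Averaged *coefficients* are reported for GLM sets only; spline bases
  differ in meaning across subsets, so coefficient averaging over GAM
  candidates is not offered.
* The abundance product inherits the units caveat above.
* Center-in-polygon membership can misattribute boundary cells relative
  to an area-weighted overlay when the protected area's edge runs through
  many cells.
* The screening stage resolves pairs greedily; with strong chained
  collinearity a different processing order could retain a different (but
  equally defensible) set. The order used — descending $|r_s|$ — is fixed
  and reported in the log.
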