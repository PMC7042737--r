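---
title: "Modelling breeding-success habitat suitability from LiDAR understory density"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling breeding-success habitat suitability from LiDAR understory density}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(understoryHSM)
```

## The problem and the model

Habitat suitability models are usually built from occurrence records. This
package implements the alternative: a suitability model anchored in a
demographic rate — the probability that a nesting attempt of an open-nesting
boreal forest bird (the Siberian jay is the motivating species) fledges at
least one offspring. Two environmental drivers interact:

* **Understory density**, measured from airborne LiDAR as the percentage of
  returns between 0.5 and 5 m height relative to all returns in a 12.5 m
  grid cell. Dense understory conceals nests from visually hunting corvid
  predators but carries a thermoregulatory cost (colder microclimate).
* **Distance to the nearest human settlement**, a proxy for corvid nest
  predator pressure: the predators overwinter at feeders and concentrate
  around settlements.

Breeding success $y_i \in \{0, 1\}$ is modelled with a binomial GLMM
(logit link):

$$
\operatorname{logit} P(y_i = 1) =
  \beta_0 + \beta_a \,\mathrm{I}(\text{unmanaged}_i)
  + \beta_c \,\mathrm{I}(d_i < D)
  + \beta_u \ln(u_i)
  + \beta_{cu}\, \mathrm{I}(d_i < D) \ln(u_i)
  + a_{\text{year}(i)} + b_{\text{F}(i)} + c_{\text{M}(i)}
$$

with crossed random intercepts for breeding year and the identities of both
breeders, study area (managed/unmanaged) as a two-level fixed effect, $u_i$
the understory density (percent) around the nest and $d_i$ the distance to
the nearest settlement. The close/far breakpoint $D$ is not assumed: it is
selected by refitting the model over a candidate grid and minimizing AICc
(`breakpoint_scan()`), and the choice of the density transform (log, linear,
quadratic) is likewise an AICc comparison (`transform_selection()`).

The nest predator proxy itself is a logistic regression of predator
presence/absence near nests on settlement distance (`fit_occurrence()`); the
distance at which the fitted occurrence crosses probability 0.5 is the
*switch distance* $d^\* = -\alpha_0/\alpha_1$, with a delta-method standard
error (`switch_distance()`).

## Key quantities and defaults

| Parameter | Default | Meaning |
|---|---|---|
| `grid_cell_size` | 12.5 m | raster resolution (forestry-map standard) |
| `understory_low`, `understory_high` | 0.5, 5 m | height stratum; half-open `[0.5, 5)` |
| `nest_radius` | 15 m | nest-level summary radius (GPS uncertainty) |
| `territory_radius` | 460 m | largest nest-centred radius |
| `nodata_fraction_max` | 0.05 | tolerated share of management no-data cells per radius |
| `breakpoint_grid` | 500–3500 m by 50 m | breakpoint candidates, clipped to the 10th–90th distance percentiles |
| `log_floor` | 0.1 % | floor applied before `log(density)`; zero densities are possible in open cells and the floor keeps the transform finite. Configurable, and applied identically across compared models |

The 101-radius schedule for the scale analysis keeps both canonical
endpoints (15 m nest radius, 460 m territory border). A schedule defined as
"1–100% of the 460 ha territory area" is inconsistent with a 460 m border
(a 460 m disc is about 66 ha), so the default schedule spaces radii
so consecutive discs add equal area, $r_k = 460\sqrt{k/100}$; a linear
schedule is available via `run_config(radius_spacing = "linear")`.

Boundary conventions that the data do not dictate are fixed and logged:
*close* means strictly less than the breakpoint; the density stratum is
half-open at the top; cells with zero LiDAR returns are no-data rather than
0% (zero evidence is not evidence of zero understory); the >5% no-data rule
counts management-affected cells over forest member cells; clear-cuts
disqualify a pixel only when they predate the LiDAR acquisition, thinning at
any recorded date.

## Mixed-model machinery

`fit_glmm()` maximizes the Laplace-approximated marginal likelihood through
`lme4::glmer`. Tests hold this to two contracts: on a single-factor toy the
Laplace log-likelihood must agree with an independent adaptive-quadrature
evaluation of the marginal likelihood to within 0.05, and the generating
coefficients of synthetic cohorts must be recovered within Wald error at
large n with near-nominal interval coverage at small n.

Model scans that refit the same structure dozens of times
(`breakpoint_scan()`, `breakpoint_sensitivity()`, `scale_profile()`) default
to the penalized-least-squares approximation (`nAGQ = 0`), the standard
screening shortcut for binomial mixed models; the reported final fit is
always the Laplace one (`method = "laplace"`). AICc uses
$-2\ell + 2k + 2k(k+1)/(n-k-1)$ with $k$ counting fixed effects plus
variance components — inert for rankings, since compared models share the
random structure. Variance explained follows the variance-partitioning
$R^2$ for GLMMs with the logit distribution-specific variance $\pi^2/3$;
multicollinearity is checked with design-matrix VIFs.

`fit_glmm` treats the optimizer's exit status as the convergence criterion
and carries lme4's post-hoc gradient diagnostics as messages; prediction
from a fit with such diagnostics warns rather than stops, since these checks
flag benign cases frequently at binary-response sample sizes.

Covariates are not standardized by default (raw-scale coefficient magnitudes
are the interface); this matters when comparing fitted coefficients across
studies that report per-metre or per-log-percent slopes.

## The synthetic-scene generator

All statistical claims in the test suite are made against synthetic scenes
with known truth (`generate_landscape()`, `generate_point_cloud()`,
`generate_nests()`, `generate_jay_observations()`,
`generate_occurrence_raster()`). The generator emulates:

* a spatially autocorrelated understory field (smoothed Gaussian noise,
  default correlation range 100 m, mean 13% and SD 6% — matching the
  descriptive density level of boreal study landscapes), clipped to 0–100;
* settlements as a homogeneous Poisson process (intensity per km²);
* LiDAR returns per cell as Poisson counts at a chosen pulse density with
  stratum membership drawn from the field (heights uniform within strata —
  only stratum membership matters to the metric);
* breeding events on fixed territories observed across years, with breeder
  identities persisting year-to-year with a given probability (geometric
  persistence induces the crossed repeated-measures structure; divorce and
  re-pairing are not modelled), success Bernoulli from the model above with
  default truth: fixed effects (0.24, −0.52, 1.04, 0.40, −1.57), breakpoint
  1450 m, and variance components 0.5 per random factor (the magnitude of
  the year/breeder components is not pinned by published tables; 0.5 is a
  moderate value and configurable);
* an independent coarse occurrence map as block means of the true
  suitability plus noise and an optional regional bias field.

Every generator draws from a stream derived from the seed and the stage
name, so stages can be regenerated independently. What the generator does
*not* emulate: real LiDAR artefacts (scan-angle effects, canopy occlusion),
non-stationary settlement patterns, climate gradients (these enter only as
an optional bias on the occurrence map), and floater/non-breeder dynamics.
Green tests therefore demonstrate internal statistical correctness of the
pipeline, not field validity.

## Scale-of-effect analysis

`scale_profile()` refits the breeding model once per radius with the mean
density within that radius (plus forest cover within the radius as a fixed
effect, included at every radius — also the nest radius — for
comparability), on the subset of nests with valid summaries at *all* radii
so that n is constant. Reported alongside the marginal $R^2$ is the
correlation between radius-level and nest-level density, because on an
autocorrelated landscape large-radius models can look informative purely
through that correlation. `effective_band()` makes the usual visual
judgement explicit: the band starting at the nest radius where marginal
$R^2$ stays at or above a retention fraction (default 0.9) of its maximum,
with radii whose density correlates below 0.5 with the nest-level density
excluded regardless.

Two design notes from the simulation work behind the tests. First, when
breeding success is generated from the density within a *disc* of radius
80 m, the marginal-$R^2$ profile does not peak at 80 m: nested disc means
gain variance ratio with radius and the profile keeps rising well past the
generating radius. A scale-of-effect band in the sense of a declining
profile arises when the effect acts at the nest scale and the field
decorrelates with distance — the construction used in the recovery test
(nest-scale log-density effect, field correlation range 80 m), whose
profile declines in parallel with the density correlation. Second, the
marginal $R^2$ of near-duplicate models is noisy at cohort sizes of a few
hundred (both the fixed-effect variance and the variance components jitter),
so the recovery experiment uses 2500 events over 6 seasons; at realistic
cohort sizes (~200) the band edge should be read as indicative, not sharp.

## Landscape prediction and validation

`predict_suitability()` evaluates the fixed effects only (random intercepts
at zero — population-level prediction; study-area term at the managed
reference level, configurable), converts to probability, and masks to zero
all non-forest pixels and pixels whose density falls outside the
proximity-class-specific range observed at actual nests
(`nesting_ranges()`): sites never chosen for nesting cannot produce a
fledged brood. Predictions aggregate to a coarse validation grid by block
means (`aggregate_to_coarse()`), both maps are min-max normalized, and
`compare_maps()` reports the difference map (occurrence − prediction, so
negative values mean breeding success is over-predicted), the Pearson
correlation of the *non-normalized* maps, and per-region quantiles of the
difference. On the 5 × 5 km synthetic end-to-end scene the validation grid
is 500 m rather than the 2 km used with national survey maps — 2 km cells
would leave only a handful of coarse cells on a desk-scale scene; the cell
size is a parameter throughout.

## Problem sizes used in the test suite

The suite regenerates everything from seeds at sizes chosen to give the
statistical checks adequate power while staying desk-scale: coefficient
recovery on one cohort of 5000 events; interval coverage over 200 cohorts of
500; breakpoint recovery over 50 cohorts of 2000 (scan fits use the
screening approximation); scale-band recovery over 20 scenes with 2500
events each; one full pipeline run on a 5 × 5 km scene at 0.5 returns/m².

## Known limitations

* No reprojection: all inputs must share one projected metric CRS.
* Rasters are read and written as ESRI ASCII grids; point clouds as XYZ
  text. Binary LAS/LAZ and GeoTIFF require external conversion.
* No spatial autocorrelation term in the GLMM and no random slopes.
* The predator proxy is distance-to-settlement only; regional gradients in
  predator abundance (e.g., climate-driven) appear as structured bias in the
  difference map rather than being modelled.
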