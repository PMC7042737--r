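# understoryHSM

Habitat suitability modelling from demographic data for open-nesting boreal
forest birds. Instead of relating environmental layers to occurrence records,
the pipeline models **breeding success** — whether a nesting attempt fledges
at least one offspring — as a function of a LiDAR-derived **understory
density** metric and the **distance to the nearest human settlement**, a
proxy for corvid nest-predator pressure, and then extrapolates the fitted
model to landscape rasters that are validated against independent occurrence
maps. The motivating system is the Siberian jay in managed boreal forest,
but every constant is configurable.

The core model is a binomial GLMM (logit link) with crossed random
intercepts for year and both breeder identities:

```
logit P(success) = β0 + βa·I(unmanaged) + βc·I(d < D)
                 + βu·ln(ud) + βcu·I(d < D)·ln(ud)
                 + u_year + u_female + u_male
```

where `ud` is the percentage of LiDAR returns between 0.5 and 5 m height
relative to all returns (12.5 m grid), `d` the settlement distance, and the
close/far breakpoint `D` is selected by AICc over a candidate grid. The
package covers the whole workflow:

* `read_point_cloud()`, `read_raster()`, `read_nest_table()`,
  `read_points()` — XYZ text, ESRI ASCII grid, CSV and GeoJSON I/O;
* `normalize_heights()`, `understory_density_raster()`, `radius_series()` —
  the density metric with the field's no-data rules, at the nest (15 m) and
  100 radii up to the territory border (460 m);
* `filter_cohort()`, `distance_to_settlements()`, `classify_proximity()` —
  cohort filters (renesting attempts, experimentally treated breeders) and
  per-nest covariates;
* `fit_occurrence()`, `switch_distance()`, `variance_explained()` — the
  predator occurrence proxy;
* `fit_glmm()`, `aicc()`, `r2_glmm()`, `vif_design()`,
  `transform_selection()`, `breakpoint_scan()`, `breakpoint_sensitivity()` —
  the mixed model and its model-selection machinery (`lme4` backend);
* `scale_profile()`, `effective_band()` — at which radius around the nest
  understory density explains breeding success;
* `predict_suitability()`, `aggregate_to_coarse()`, `compare_maps()` —
  landscape prediction, masking to observed nesting ranges, and validation
  against a coarse occurrence raster;
* `generate_landscape()` and friends — a synthetic-scene generator with
  known ground truth that makes the whole pipeline testable end to end.

## Worked example

A synthetic 2.5 × 2.5 km scene with one settlement, a simulated LiDAR
cloud at 0.75 returns/m², a 251-event breeding cohort with the usual
exclusions, and the full model fit on the LiDAR-measured density:

```r
library(understoryHSM)
cfg   <- run_config()
scene <- generate_landscape(extent = c(2500, 2500), config = cfg, seed = 42,
                            settlement_intensity = 1)
scene$settlements <- data.frame(x = 0, y = 0)

pts <- generate_point_cloud(scene, pulse_density = 0.75, seed = 42)
dr  <- understory_density_raster(pts, scene$ud, forest_mask = scene$forest)

nests <- generate_nests(scene, n_nests = 251, n_years = 10, seed = 42,
                        n_renest = 5, n_treated = 11)
kept  <- filter_cohort(nests)$kept          # 235 of 251 kept
prof  <- extract_profiles(dr, kept, cfg, radii = cfg$nest_radius)
kept$ud_lidar <- prof$mean_ud[match(kept$id, prof$id)]

fit <- fit_glmm(kept, breakpoint = 1450, ud_col = "ud_lidar")
fit
#> <glmm_fit> binomial(logit), laplace, n = 235, k = 8
#>                 term estimate    se      z      p
#> 1        (Intercept)   1.2197 1.079  1.130 0.2584
#> 2      areaunmanaged  -0.6958 0.485 -1.433 0.1517
#> 3     proximityclose   2.4775 2.783  0.890 0.3733
#> 4                lud   0.0881 0.394  0.224 0.8230
#> 5 proximityclose:lud  -2.4081 1.164 -2.069 0.0385
#> variance components: breeder_m = 0.000, breeder_f = 0.707, year = 0.384
#> logLik = -125.88, AICc = 268.39, R2m = 0.302, R2c = 0.476
```

The negative `proximityclose:lud` interaction is the central result pattern:
close to settlements, breeding success rises with understory density (cover
against predators), while far from settlements open forest does as well or
better. The predator proxy behind the breakpoint:

```r
jays <- generate_jay_observations(scene, nests = kept, n_obs = 400, seed = 42)
sw   <- switch_distance(fit_occurrence(jays))
#> predator occurrence switch distance: 1311 m (SE 66)
```

i.e. the fitted occurrence curve crosses probability 0.5 about 1.3 km from
settlements, consistent with the 1450 m close/far breakpoint that the AICc
scan selects on larger cohorts.

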