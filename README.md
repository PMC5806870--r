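# sedscape

Long-term annual sediment budgeting for small rural watersheds, aimed at
questions of the form *"where should scarce restoration effort go: along the
river banks, or on the steepest slopes?"*. The package is written for
landscape ecologists and ecosystem-services modellers who need a transparent,
fully testable erosion–routing–calibration–scenario pipeline without
depending on external GIS data.

## The model

Per-pixel soil loss follows the Universal Soil Loss Equation,

```
A = R · K · LS · C · P        [Mg ha⁻¹ y⁻¹]
```

with rainfall erosivity `R` built from multi-gauge daily precipitation
(monthly climatology, Cressman interpolation, and the monthly-ratio
erosivity relationship `R = 68.730 Σₜ (pₜ²/P)^0.841`), erodibility `K` from
a per-soil-class table (min/mean/max options), `LS` from D8 contributing
area (two-dimensional slope-length with the McCool steepness factor and an
`l_max = 122 m` slope-length cap), and per-land-use `C` and `P`.

Eroded mass is routed down the D8 flowpath. Each strictly downstream
hillslope cell `i` traps a fraction `Eᵢ` (its sediment retention
efficiency, SRE) of the mass passing through it and passes on
`Gᵢ = 1 − Eᵢ`; mass reaching a stream cell (or the grid edge) is exported:

```
Oₙ = A₁G₂G₃…Gₙ + A₂G₃…Gₙ + … + Aₙ
```

For a homogeneous buffer of width `l` at pixel size `r` this gives the
whole-buffer trapping efficiency `Te = 1 − (1 − SRE)^{l/r}`, which is how
per-pixel SRE values are tied to published filter-strip experiments.

Observed sediment export at the outlet comes from a twice-daily gauge
series through piecewise rating curves (stage → discharge → turbidity →
suspended sediment) and the unit conversion `SE = 31.536 · Q · SS / DA`.
A 24-member ensemble (3 K options × 2 forest SRE options × 2 initial
pasture C options × 2 C-linkage directions) is calibrated against that
observation by trial-and-error search of pasture SRE and C with a 10%
error tolerance; members that cannot reach the tolerance are discarded.
Calibrated members then drive gradual restoration scenarios — riparian
buffers, steepest slopes, and their combination — compared on mean soil
loss and outlet sediment export.

Everything runs on synthetic watersheds generated by the package itself
(valley DEM, soils, land use, rain gauges, outlet series with a known
"truth" parameter set), so the whole pipeline is testable offline.

## Worked example

```r
library(sedscape)

bundle <- make_reference_watershed(seed = 1)   # 64 x 64 cells at 5 m
obs <- sediment_export_observed(bundle$outlet_series,
                                area_ha = raster_area_ha(bundle$dem))
ens <- run_ensemble(bundle, obs$mean_se)

base <- anthropized(bundle$landuse)            # counterfactual: no forest
scen <- c(list(base),
          scenario_series("riparian", base, bundle$dist, bundle$slope, 25),
          scenario_series("steepest", base, bundle$dist, bundle$slope, 25),
          scenario_series("two_way",  base, bundle$dist, bundle$slope, 25))
cal <- ens$results[ens$results$status == "calibrated", ]
compare_strategies(bundle, scen, cal)
```

prints (seed 1):

```
observed mean sediment export: 48.07 Mg ha-1 y-1
calibration: 14 calibrated, 10 discarded
  soil loss 199.1 ± 58.1, export 46.3 ± 1.9 Mg ha-1 y-1

                   scenario    strategy forest_pct soil_loss_red_pct se_red_pct
1               anthropized anthropized        0.0               0.0        0.0
2         riparian_14.1421m    riparian       24.5              12.3       64.8
3         steepest_33.3354%    steepest       25.0              22.1       31.0
4 two_way_7.07107m_39.5181%     two_way       25.0              18.0       59.0
```

Read it as: all members that can reproduce the observed export agree
closely on export (small spread) but not on soil loss, which was never
calibrated. At 25% forest, riparian restoration cuts sediment export most
(it traps what arrives from upslope), steepest-slope restoration cuts soil
loss most (it removes the strongest sources), and the combined strategy
sits between the two on both axes — the motivation for treating the two
strategies as complementary. Absolute magnitudes belong to the small, steep
synthetic watershed; the orderings, not the magnitudes, are the result.

## Layout

- `R/` — raster container and ASCII-grid I/O, terrain (fill, D8, slope,
  LS, distances), erosivity, gauging/rating curves, the routing model,
  buffer trapping theory, ensemble calibration, restoration scenarios,
  synthetic watershed generator, pipeline driver.
- `tests/testthat/` — unit and property tests with independent brute-force
  oracles, plus `test-acceptance.R` (conservation, oracle equivalence,
  closed forms, parameter recovery, mechanism ordering).
- `vignettes/sediment-budgeting.Rmd` — model description, assumptions,
  parameter choices, and known limitations.
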