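---
title: "Sediment budgeting, ensemble calibration, and restoration scenarios"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sediment budgeting, ensemble calibration, and restoration scenarios}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sedscape)
```

## The model and its assumptions

`sedscape` estimates a long-term annual sediment budget on a regular grid.
Three processes are chained:

1. **Detachment.** Per-pixel sheet-and-rill soil loss by the USLE,
   `A = R·K·LS·C·P` in Mg ha⁻¹ y⁻¹. This is a long-term average: no
   event dynamics, no gullying, no landslides, no channel erosion.
2. **Delivery.** The eroded mass of each pixel (A times cell area) travels
   a single D8 flowpath. Every strictly downstream hillslope pixel traps a
   fraction E of what passes through it — its sediment retention
   efficiency (SRE), a per-land-use parameter — and passes on `1 − E`. A
   pixel's own E never acts on its own erosion. Stream pixels are
   absorbing: whatever reaches them (or the grid edge) is exported. There
   is no transport-capacity limit and no remobilization of deposits.
3. **Observation.** The "observed" export that anchors calibration comes
   from a twice-daily outlet series converted through rating curves:
   stage→discharge (power law), discharge→turbidity (piecewise: two power
   segments below 0.95 m³ s⁻¹, linear above), turbidity→suspended
   sediment (linear), and `SE = 31.536·Q·SS/DA`, averaged per
   hydrological year (Oct–Sep) and then over years.

The delivery rule gives a closed form for a homogeneous buffer: a strip of
width `l` at pixel size `r` traps `Te = 1 − (1 − SRE)^{l/r}` of the
incoming mass, assuming no erosion inside the strip. The package uses this
relation in both directions (`trapping_from_sre()`, `sre_from_trapping()`)
to tie the per-pixel SRE parameter to published filter-strip trapping
data, and `fit_sre_band()` selects a band of SRE values whose curves
bracket a cloud of width–trapping points (bracketing at least 80% of
points, minimum total squared deviation; the published analogue was a
visual fit, so the criterion here is a documented package choice).

## Parameters that matter

| Parameter | Units | Default | Why |
|---|---|---|---|
| erodibility K per soil class | Mg h MJ⁻¹ mm⁻¹ | min/mean/max table | regional measurements vary widely; the three options are ensemble axes |
| pasture C | – | calibrated in [0.05, 0.22] | dominant land use, most leverage on export |
| forest / eucalyptus C | – | linked to pasture C over [0.02, 0.09] / [0.12, 0.30] | literature ranges; increasing and decreasing linear linkages are ensemble axes |
| roads / water / micro-dams C | – | 1 / 0 / 0 | prescribed conventions |
| growing-forest C | – | mean of pasture and forest C | young plantings behave between the two |
| forest SRE | fraction | 0.45 or 0.65 | band that brackets published buffer trapping; ensemble axis |
| pasture SRE | fraction | calibrated in [0.05, 0.40] | no regional observations exist |
| eucalyptus SRE | fraction | mean of pasture and forest SRE | stated convention |
| growing-forest SRE | fraction | mean of pasture and forest SRE | not stated anywhere; mirrors the C rule and the eucalyptus rule (configurable) |
| micro-dam SRE | fraction | 1 | built to trap everything that enters |
| support practice P | – | 1 everywhere | no support practices modelled; configurable |
| stream threshold | upstream cells | 2000 (full), 100 (mini) | full-scale value from network comparison; the mini grid scales it down to keep a comparable drainage density |
| LS slope-length cap `l_max` | m | 122 | conventional bound beyond which overland flow channelizes; without it, high-accumulation pixels near channels dominate the soil-loss map |
| Cressman radius | m | 1.5 × max nearest-gauge spacing | not stated by any source; covers every cell while keeping locality |
| calibration tolerance | relative | 0.10 | stated acceptance threshold |

## Numerical and procedural choices

- **Depression filling** is iterative Planchon–Darboux with an epsilon
  gradient (1e-4 m per cell step), so filled surfaces drain strictly and
  no flats survive on drained paths. Interior cells that still lack a
  descending neighbour are reported by index as errors.
- **D8 ties** are broken in the fixed neighbour order E, SE, S, SW, W,
  NW, N, NE for reproducibility. Accumulation counts strictly upstream
  cells (self excluded); the stream threshold refers to that convention.
- **Slope** is Horn's 8-neighbour stencil with edge replication (one-sided
  differences at borders). **LS** combines the contributing-area
  slope-length generalization with the McCool piecewise steepness factor;
  at zero slope and zero contributing area it degenerates to 0.03.
- **Hillslope-only erosion.** Channel cells produce no USLE soil loss
  (`erode_streams = FALSE`): the USLE describes sheet-and-rill processes,
  and in-channel erosion is out of scope. They still absorb and export
  everything that reaches them.
- **Observed export integration.** The instantaneous product
  `31.536·Q·SS/DA` is averaged, rather than multiplying annual means:
  sediment flux is dominated by discharge peaks, and the product of means
  would discard exactly that covariance.
- **Climatology order.** Monthly totals are averaged into a 12-month
  climatology per gauge, each month is interpolated (single-pass Cressman,
  weight `(R²−d²)/(R²+d²)`), and the erosivity formula is applied per
  cell. Cells outside every gauge radius fall back to inverse-distance
  weighting with a warning. Days missing from a gauge record count as
  zero precipitation with a warning: conservative and explicit.
- **Calibration search.** Stage 1 bisects pasture SRE over [0.05, 0.40]
  (export is monotone decreasing in it), with a deterministic 0.005-grid
  fallback; stage 2 bisects pasture C (rounded to 0.001) with the SRE
  search nested inside, after first checking reachability at the parameter
  bounds so hopeless members are discarded cheaply. Ties prefer the
  smaller error, then the smaller SRE. The reference procedure was manual
  trial and error; this is its deterministic counterpart.
- **Riparian buffers** are Euclidean distance to the nearest stream cell
  (exact two-pass distance transform), per side; the channel line itself
  (distance 0) is never planted. Because distances are quantized on a
  grid, scenario widths are chosen from the achievable step values — on
  the mini watershed the steps are coarse (a one-ring increment moves the
  forest fraction by several points), which is why scenario tests allow a
  few points of slack around their targets.
- **Two-way scenarios** pick the width/threshold pair so each mechanism
  alone would convert the same number of cells (integer bisection on that
  count); where overlap makes the exact split infeasible the nearest
  feasible pair is used with a warning.

## What the synthetic watershed emulates — and what it does not

`make_reference_watershed()` generates a steep valley DEM (down-valley
tilt, meandering axis, sides steepening toward the ridges, smoothed random
roughness), five soil classes as contiguous patches with valley-bottom
alluvium near streams, a land-use map hitting the stated current-scenario
fractions (pasture ≈ 71%, forest 25% on riparian and steep cells, roads
2% as connected polylines, eucalyptus 2% as one stand, micro-dams 0.1%
adjacent to roads), five rain gauges with seasonal, summer-dominant
daily precipitation near 1500 mm y⁻¹, and a twice-daily outlet series
scaled so its implied export matches the forward model under a known
"truth" parameter set (default: maximum-K option, pasture C 0.135,
pasture SRE 0.05, forest SRE 0.65, increasing linkage — a parameter
corner that reproduces the reference calibration structure, where
lowest-K members cannot reach the observation and are discarded).

Two sizes ship: `mini` (64×64 cells, ≈10 ha) for tests and `full`
(693×693, ≈1200 ha). The mini watershed is much smaller and steeper than
any real basin of interest: flowpaths are short, the channel network is a
large share of the area, and absolute soil-loss and export magnitudes are
correspondingly high. A green test therefore establishes the *structure*
of the results — conservation, monotonicity, calibration recovery,
the riparian/steepest/two-way ordering — not field-scale magnitudes, and
no synthetic result should be read as a site prediction. Storm
hyetographs, rainfall–runoff dynamics, and gauge measurement error beyond
lognormal turbidity noise are not emulated.

## Known limitations

- Single-direction (D8) routing; no multiple-flow-direction option.
- No trapping saturation: buffer efficiency is independent of load and
  time, so export reductions from wide riparian buffers are upper bounds.
- No road-condition effects, landslip risk, channel processes, or
  economic valuation.
- GeoTIFF I/O is not provided; rasters are read and written as ESRI
  ASCII grids (plain text). Run configurations are plain lists/JSON.
- The linear C linkage reproduces most, but not all, decodable
  calibrated-value pairs of the reference table; the exceptions are
  documented in the tests rather than resolved.
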