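---
title: "Methods: quantifying the overlap of carbon export and fishing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying the overlap of carbon export and fishing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fishsink)
```

## The problem

The biological carbon pump — the gravitational flux of dead plankton,
faecal pellets and aggregates out of the sunlit ocean — and commercial
fisheries both rest on phytoplankton primary production, so regions of
high particulate organic carbon (POC) export and intense fishing tend to
coincide. Wherever they do, fishing-driven ecosystem change (trophic
cascades, removal of pellet-producing small pelagics, seabed disturbance)
can perturb the carbon sink. `fishsink` quantifies that spatial coincidence
at two scales: a uniform latitude–longitude grid, and FAO-style major
fishing areas.

## Grid geometry and area weighting

All fields live on a cell-edge-registered uniform grid (latitude ascending
from −90°, longitude from −180°, half-open cell membership with the final
edge closed). Cell areas use the exact spherical form
$A = R^2\,\Delta\lambda\,(\sin\phi_2 - \sin\phi_1)$ with $R = 6371$ km;
spherical geometry is sufficient because every reported statistic is a
ratio or an area-weighted mean, where geodetic refinements cancel at far
below the uncertainties of the inputs. Regridding is restricted to exact
nesting (target resolution an integer multiple of the source) with
area-weighted means of valid source cells: this conserves the area
integral of intensive quantities to machine precision and keeps results
bit-reproducible, at the price of refusing non-nesting grids rather than
interpolating.

Missing-data semantics are asymmetric by design. Export is *invalid* where
satellite-driven products fail (ice and cloud at high latitudes), whereas
fishing intensity inside the ocean is *zero* where vessel tracking records
no activity — absence of effort is a true observation, not a gap. The
overlap analysis therefore takes its domain from the export field's
validity and treats fishing zeros as data.

## Export-ratio ensemble

POC export is the product of net primary production (NPP) and an export
ratio (e-ratio). Because no single parameterization is authoritative, the
package carries a registry of algorithms and reports the ensemble mean and
the per-member range:

* an SST-only exponential decay, $0.23\,e^{-0.08\,SST}$;
* an SST/NPP form, $0.04756\,(0.78 - 0.43\,SST/30)\,NPP^{0.307}$, clipped
  at 0 where the polynomial would go negative (near 54 °C, unreachable but
  guarded);
* an SST and $\ln(NPP/Z_{eu})$ form, $-0.0101\,SST + 0.0582\ln(NPP/Z_{eu})
  + 0.419$, clipped to $[0.04, 0.72]$; at $NPP = 0$ the logarithm is
  undefined, the ratio takes the lower clip and the export member is 0 —
  zero production means zero export regardless of the ratio;
* a model-derived export field passed through unchanged, standing for an
  ecosystem-model product consumed as data.

The coefficients are registry entries, not hard-coded logic, because the
scientific claim rests on the ensemble mean rather than any single member;
users can register alternatives. The ensemble mean is taken cell-wise over
*valid* members (a cell with fewer members than the full set is still
averaged, and the member count is recorded), so one algorithm's mask does
not erase another's coverage. Global totals integrate
$E \cdot A \cdot 365$ from mg C m⁻² day⁻¹ to Gt C yr⁻¹, and the
sequestration helper scales a total by the fraction of exported carbon
locked away on centennial timescales (central 15%, temperature-dependent
range 5%–50%).

## The dual upper-quartile overlap

The headline statistic intersects the upper quartiles of the two services.
Two deliberate choices need stating because either could plausibly go the
other way:

* **Thresholds are unweighted over cells; fractions are area-weighted.**
  The quantile treats each valid cell as one observation (the pixel
  reading of "upper quartile"), while the reported shares of "ocean
  surface area", export and effort must weight by spherical cell area.
  An area-weighted threshold variant is exposed
  (`weighted_thresholds = TRUE`) for sensitivity analysis, and the grid
  resolution is a free parameter, since reasonable readings differ.
* **Strict inequality at the threshold.** Ties are excluded from the mask;
  this is deterministic and conservative.

Under these rules the mask is invariant to any strictly increasing
transform of either field, shrinks monotonically as the quantile rises,
and for two independent continuous fields covers an expected
$(1-q)^2 = 6.25\%$ of an equal-area domain at $q = 0.75$ — the null
calibration the tests check by Monte Carlo.

## Regional statistics

Both services are aggregated to regions by area-weighted means. Regions
are ranked descending (ties share the minimum rank of the block — real
data rarely tie, synthetic data can). Fishing intensity then passes an
outlier screen: a region is excluded when it exceeds the across-region
mean by more than $k = 2$ sample standard deviations ($n-1$ denominator —
the convention that reproduces the published per-area statistics, where
the population form does not). With 19 areas the rule flags exactly the
Mediterranean, whose enclosed geography concentrates effort. The Pearson
correlation between per-area export and fishing is computed on the
retained pairs, with a two-sided p-value from the t transform
$t = r\sqrt{n-2}/\sqrt{1-r^2}$; the correlation is computed on
untransformed annual means. The across-area mean export of the packaged
table is reported as the plain arithmetic mean (≈63.4 mg C m⁻² day⁻¹);
an area-weighted version can be had by supplying gridded inputs.

## Catch composition

Per region, catch tonnage shares are computed per gear type and per fished
group, and the "dominant" set is the shortest descending-share prefix
whose cumulative share reaches 50%. Selection uses exact fractions;
rounding to integer percent happens only in the report layer, so a
49.6%/50.4% split cannot flip the selection. Ties are broken by category
code. Unknown-gear and unknown-group codes are ordinary categories — they
compete for dominance like any other. The dominant set is presented in
descending share order, and it is the *set*, not the ordering, that is the
tested contract.

## The synthetic world

The generator exists so that the full pipeline runs, and its statistical
assumptions can be probed, without external data. It emulates: positive,
spatially autocorrelated fields (white noise convolved with a Gaussian
kernel truncated at ±3σ — chosen over spectral synthesis for simplicity
and platform-stable determinism); log-normal NPP and fishing; a tunable
log-space cross-correlation built as
$\rho Z + \sqrt{1-\rho^2}\,W$ against the standardized productivity
driver $Z$; irregular coastlines from thresholded smooth noise; a
multiplicative coastal enhancement of both services within one correlation
length (Chebyshev distance in cells) of land; ice-analogue export
invalidity poleward of a latitude line; true fishing zeros below a
detection floor; and a nearest-seed-point partition of the ocean into
contiguous regions.

Defaults, fixed once as a plausible 2° annual-mean world: 30% land; 6°
correlation length (gyre-scale structure of annual climatologies);
ρ = 0.6 (both services share the productivity driver but fishing adds
economic noise); coastal boost ×2 (production and effort are highest near
coasts); ice line 70°; 19 regions; SST 14 ± 9 °C with a cosine-latitude
gradient; log-NPP mean log(400), SD 0.7; log-fishing mean log(0.3), SD
1.2; fishing floor 0.01 h km⁻² yr⁻¹.

What the generator does **not** emulate: seasonality, bathymetry,
vessel-level tracks, exclusive economic zones, or the observed joint
distribution of real SST/NPP/effort. Passing tests on synthetic worlds
therefore demonstrate that the *pipeline* measures what it claims to
measure (calibrated null, monotone response to the configured coupling,
coastal concentration), not that real-ocean fractions take any particular
value — the real-data overlap fractions require the external gridded
climatology and vessel-tracking products, which are consumed as inputs,
never re-derived.

A note on verifying the coupling: a 2° world has ~10⁴ ocean cells but, at
a 6° correlation length, only ~10² effectively independent patches, so a
single field's empirical correlation scatters around ρ with SD ≈ 0.04–0.1.
The recovery checks therefore compare the Monte-Carlo mean across seeds to
the configured ρ, which is the estimand the construction fixes.

## Problem sizes and numerical choices

Stochastic checks run at 2° resolution (90 × 180): 200 seeds for the null
calibration, 50 seeds per ρ for the monotonicity sweep, 15–20 seeds for
recovery means — a few seconds each on one CPU, with every seed fixed so
reruns are identical. Tolerances: machine-precision identities (area
conservation, regrid conservation, affine invariances) at 10⁻¹²–10⁻⁹
relative; the stochastic null within ±0.01 of 6.25%; recovery means
within ±0.05 of ρ. Degenerate inputs are guarded explicitly: zero-variance
fields in the log-z transform return zeros; all-invalid fields,
zero-total catches and sub-3 sample outlier screens are errors naming the
offending input.

## Known limitations

* Exact-nesting regridding only; arbitrary-grid interpolation is out of
  scope.
* Region masks are gridded id layers; official FAO polygons must be
  rasterized by the user.
* Gridded I/O is the CSV grid-dump dialect (`lat_center, lon_center,
  value`); fields are reconstructed from cell centers on uniform global
  grids.
* The pipeline analyses annual climatologies; there is no time axis.
* The overlap statistic is the quartile intersection only — no spatial
  autocorrelation testing or local hotspot statistics.
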