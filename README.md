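# fishsink

Where the ocean's biological carbon sink and commercial fishing collide.

Plankton-driven export of particulate organic carbon (POC) out of the
surface ocean — the biological carbon pump — and commercial fisheries both
depend on phytoplankton primary production, so the two ecosystem services
overlap in space. `fishsink` maps and quantifies that overlap: it computes
gridded POC export from an ensemble of empirical export-ratio (e-ratio)
algorithms, intersects the upper quartiles of export and fishing intensity,
and reports how much ocean area, carbon export and fishing effort fall
inside the joint-hotspot zone, together with FAO-area regional statistics
and catch-composition summaries. A Gaussian-random-field synthetic world
generator lets every stage run and be tested without external downloads.

## The statistic at the core

Given an export field *E* (mg C m⁻² day⁻¹) and a fishing-intensity field
*F* (h km⁻² yr⁻¹) on a shared latitude–longitude grid, with analysis domain
Ω = cells where *E* is valid (fishing zeros are genuine observations):

1. **Thresholds.** `q_E = Q₀.₇₅(E | Ω)` and `q_F = Q₀.₇₅(F | Ω)`,
   linear-interpolation quantiles with each valid cell one observation.
2. **Overlap mask.** `M = {E > q_E} ∩ {F > q_F}` (strict inequalities).
3. **Fractions** (area-weighted, spherical cell areas
   `A = R² Δλ (sin φ₂ − sin φ₁)`):
   - area: `Σ_M A / Σ_Ω A`
   - export: `Σ_M E·A / Σ_Ω E·A`
   - effort: `Σ_M F·A / Σ_Ω F·A`

Per-algorithm sensitivity ranges come from recomputing the mask with each
ensemble member. Export members are `e-ratio × NPP` with the registered
parameterizations (SST-decay, SST/NPP polynomial, SST + log(NPP/Z_eu) with
clips) plus an optional model-derived export field passed through.

At the regional scale, both services are aggregated to FAO-style areas by
area-weighted means; regions more than 2 sample standard deviations above
the across-region mean fishing intensity are excluded as outliers before a
Pearson correlation between the two services.

## Worked example

```r
library(fishsink)

## regional analysis of the packaged 19-area FAO summary table
tab <- fao_area_summary()
summ <- region_summary(data.frame(code = tab$area, name = tab$name,
                                  mean_export = tab$poc_export,
                                  mean_fishing = tab$fishing))
summ
#> region_summary: 19 regions; fishing mean 0.66, SD 0.69 h km-2
#>   excluded: 37; Pearson r = 0.68 (p = 0.00175, n = 18)
```

Fishing intensity averages 0.66 h km⁻² across the 19 areas (SD 0.69); the
Mediterranean (area 37, 2.75 h km⁻²) exceeds the mean + 2 SD rule and is
excluded, after which export and fishing correlate at r = 0.68 across the
remaining 18 areas — the shared dependence of both services on primary
production, not a causal link.

```r
## full gridded pipeline on a synthetic world
res <- run_pipeline(synth_config(seed = 1), out_dir = "out")
round(unlist(res$overlap[c("area_fraction", "export_fraction",
                           "effort_fraction")]), 3)
#>   area_fraction export_fraction effort_fraction
#>           0.145           0.338           0.472
```

With the default coupling (ρ = 0.6) and coastal enhancement, 14% of the
synthetic ocean's area concentrates 34% of its carbon export and 47% of its
fishing effort — the qualitative concentration pattern the overlap
statistic is designed to expose. `out/` receives the overlap mask (CSV grid
dump), a fractions CSV with per-algorithm ranges, the per-region report,
global export totals with the sequestered fraction (~15%, range 5%–50%),
and a JSON manifest of every threshold and exclusion decision.

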