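# levelcut

Photogeometric synthesis and measurement of level-cut shading stimuli,
for researchers in visual psychophysics studying how sharp bounding
contours determine the perception of shading, 3D shape, and optical
focus.

When a smooth Lambertian surface is lit by a collimated source,
shading intensity next to a smooth self-occluding rim falls off as a
cosine of contour orientation: in observer-centric spherical
coordinates (tilt θ<sub>s</sub>, slant φ<sub>s</sub>; light azimuth
θ<sub>i</sub>, elevation φ<sub>i</sub>),

    L = max(0, r·i·[cos φs·cos φi + sin φs·sin φi·cos(θs − θi)])

and at a rim (φ<sub>s</sub> → 90°) this collapses to
`L = max(0, B·cos(θ_rim − C))`.  The same *orientation–intensity
covariation* arises along **level cuts** — contours made by slicing a
relief surface with a fronto-parallel plane — and is a candidate cue
the visual system uses to identify focused, attached shading.
`levelcut` provides the full pipeline around this statistic:

- **terrain** — seeded band-limited height fields; level-cut masks at
  target visibility fractions (convex/bistable polarity, 180° rotation
  controls); clipped-and-smoothed variants
- **shading** — Lambertian rendering under collimated light, gray-mask
  compositing, layered thin-lens defocus simulation
- **contours** — gradient-side contour extraction, 9×9 local-PCA
  tangents, border-ownership disambiguation into 360° into-mask
  normals, adjacent-intensity sampling
- **covariation** — per-azimuth Pearson correlations, the 16-azimuth
  max rule (score ρ), cosine fits
- **ribbons** — 2-px linearly shaded ribbon stimuli
  (`L = 0.8 − 0.6·Δ(θ,90°)/180°`), spectrum-matched noise, parametric
  mixing over 13 noise proportions
- **psychophysics** — paired-comparison tallies, correlation binning,
  selection-slope regression, Bradley–Terry latent scores,
  gauge-figure relief reconstruction
- **synthetic observer** — a lapse-logistic latent-score choice model
  so every analysis stage is testable without human data

## Worked example

Regenerate the 12-stimulus level-cut battery (3 visibility fractions ×
{convex, bistable} × {level cut, rotated}), measure ρ in every image,
and push the measurements through the synthetic observer and the
paired-comparison analysis:

```r
library(levelcut)

b <- level_cut_battery(seed = 2, size = 128)
b[, c("condition", "visibility", "rho", "best_azimuth")]
#>           condition visibility    rho best_azimuth
#> 1            convex       0.25 0.8470           90
#> 3          bistable       0.25 0.8653          270
#> 2    rotated_convex       0.25 0.1531          112
#> 4  rotated_bistable       0.25 0.0381          135
#> ...
```

Level-cut contours measure high covariation (ρ ≈ 0.85–0.89) peaking at
the top-lit 90° azimuth (convex) or its 180° phase-shifted counterpart
(bistable), while the rotated controls collapse to ρ ≈ 0.04–0.19:
rotation preserves contour shape but destroys the photogeometric link
to the shading.

```r
s  <- focus_score_model(b$rho, b$convex_fraction)
om <- observer_model(setNames(s, paste0(b$condition, "_", b$visibility)), tau = 0.5)
tally <- tally_choices(simulate_choices(om, trials_per_pair = 20, seed = 3))
round(tapply(tally, b$condition, mean), 1)
#>         bistable           convex rotated_bistable   rotated_convex
#>             66.4             87.9             21.1             24.7
```

The simulated percent-chosen tallies reproduce the designed ordering:
convex level cuts are selected as most focused, bistable level cuts
next, rotated masks least.

Ribbon stimuli isolate the covariation cue; mixing in spectrum-matched
noise degrades the measured score:

```r
ribbon_stimulus(seed = 3, size = 128, noise_proportion = 0.5)
#> <ribbon_stimulus> seed 3, w = 0.50, 1942 path pixels, measured rho = 0.892 at 90 deg
```

A noiseless ribbon (`noise_proportion = 0`) measures ρ = 0.996 at 90°;
pure noise (`1.0`) measures ρ = 0.156 at an arbitrary azimuth.

## Documentation

The methods vignette (`vignettes/levelcut-methods.Rmd`) describes the
shading model and its conventions, the terrain and ribbon generators,
the covariation statistic, the defocus approximation, the analysis
layer, all tunable parameters with their defaults and rationale, and
the limits of what the synthetic-observer validation shows.
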