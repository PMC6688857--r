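---
title: "Photogeometry of level-cut contours: models, conventions and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Photogeometry of level-cut contours: models, conventions and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(levelcut)
```

## The scientific problem

When a smooth matte surface is lit by a distant collimated source, its
image contains only low-spatial-frequency shading gradients, and human
observers often misattribute those gradients to optical defocus: a
fully focused rendering of shallow terrain relief looks blurred.  A key
image property that disambiguates the two sources is the behavior of
shading next to sharp bounding contours.  Along a smooth self-occluding
rim, surface slant approaches 90° and surface tilt equals the contour
normal direction, so Lambertian shading intensity falls off as a cosine
of contour orientation.  The same *orientation–intensity covariation*
arises, approximately, along *level cuts* — contours made by slicing a
relief surface with a fronto-parallel plane.  `levelcut` implements the
full synthesis and measurement machinery needed to study this
covariation: terrain synthesis, Lambertian rendering, level-cut masks,
contour orientation estimation with border-ownership disambiguation,
the covariation statistic, linearly shaded ribbon stimuli with
spectrum-matched noise, a thin-lens defocus simulation, and a
paired-comparison analysis layer exercised by a synthetic observer.

## The shading model

In observer-centric spherical coordinates — surface tilt $\theta_s$
(image direction of the projected normal, 90° = up on screen), slant
$\phi_s$ (angle from the viewing axis), illumination azimuth
$\theta_i$ and elevation $\phi_i$ — Lambert's law is the spherical law
of cosines:

$$L = \max\!\big(0,\; r\,i\,[\cos\phi_s \cos\phi_i +
\sin\phi_s \sin\phi_i \cos(\theta_s - \theta_i)]\big).$$

With the light fixed across the image this is
$L = \max(0, A\cos\phi_s + B\sin\phi_s\cos(\theta_s - C))$: a cosine of
tilt with phase $C = \theta_i$, whose offset and amplitude vary with
slant.  At a self-occluding rim $\phi_s \to 90^\circ$, the offset
vanishes and $L = \max(0, B\cos(\theta_{\mathrm{rim}} - C))$
(`rim_luminance()`).  The default stimulus parameters are albedo
$r = 0.3$, light strength $i = 5$, azimuth 90° (top-lit) and elevation
45°; rendering divides by $r\,i$ (the `"fixed"` normalization), so a
fronto-parallel plane maps to $\cos 45^\circ \approx 0.707$ and nothing
clips.

## Angle and indexing conventions

All angle math uses the *display* convention: 0° points right, 90°
points up in the displayed image.  Matrices are stored with origin
top-left and the row axis pointing down, so every angular computation
flips the row axis.  Positions are 1-based (`x` = column, `y` = row),
the natural indexing in R.  Contour orientations live in the full
$[0°, 360°)$ circle: the orientation of a contour pixel is the
direction of the unit normal pointing *from the shading gradients into
the mask*, which corresponds to surface tilt at a convex level cut.
Tilt is everywhere the direction of the image-projected surface normal,
i.e. the downhill direction $-\nabla h$.  One consequence worth
flagging: gauge-figure reconstruction (`reconstruct_profile()`) uses
the along-line height gradient $-\tan(\phi_s)\cos(\theta_s - d)$, the
sign that makes reconstruction from exact downhill-convention normals
reproduce an analytic ridge; a convention with tilt as the *uphill*
direction would flip it.

## Terrain and masks

`generate_terrain()` builds relief as seeded Gaussian white noise low-pass filtered in the frequency
domain with a hard isotropic cutoff (default 8 cycles/image), then
scaled to unit height standard deviation.  Procedural modelling tools
reach the same kind of surface through warped-noise displacement plus
subdivision smoothing, but the perceptual construction only needs a
smooth, isotropic, band-limited relief, and the spectral
parameterization makes the band limit an explicit, testable contract
(≥ 99% of spectral energy below the cutoff).  Heights increase toward
the viewer, so a fronto-parallel cut plane is a height threshold:
convex-polarity masks occlude everything behind the plane (leaving the
shaded peaks), bistable masks occlude everything in front (leaving the
valleys), and the two are exact logical complements at the same depth.
Cut depths for target visible fractions (25/50/75%) come from the exact
empirical quantile of the sorted heights with ties broken toward the
smaller depth, so the achieved fraction is within $1/\mathrm{size}^2$
of the request.  The clipped-terrain variant (`clip_and_smooth()`)
raises everything below a height quantile to that value and smooths
with a truncated Gaussian — the floor quantile is the explicit,
portable replacement for the internal noise-contrast dial of
procedural texture generators, whose mapping to a clipping level is
tool-specific.

`apply_mask()` fills masked pixels with the mean of the whole input
image (the construction used for the gray masks) and leaves visible
pixels bit-identical.  Note that filling with the *global* mean
preserves the image mean exactly only when the masked region's mean
equals the global mean; the tests therefore assert the fill value and
the bit-identity of visible pixels, not global mean preservation.

## Contour measurement

Contour pixels are defined on the gradient side: non-mask pixels with a
mask pixel among their 8 neighbors.  This guarantees that intensity
sampling at inset 1 never reads mask gray: generic edge operators do
not fix which side of a boundary they return, so the package picks the
side that makes the sample well-defined.  Orientation estimation is
two-stage: the principal axis of contour coordinates in a centered 9×9
window gives an undirected tangent (pixels with fewer than 3 contour
neighbors are flagged invalid rather than erroring), and a probe 2 px
along each tangent perpendicular decides which side is the mask — 1 px
probes fail on single-pixel mask necks, so ambiguous pixels (both or
neither probe in the mask) are flagged invalid.  On smooth terrains at
50% visibility the estimator agrees with the analytic gradient oracle
to a circular MAE of ~3–5° with under 5% invalid pixels.

## The covariation statistic

For a candidate azimuth $a$, each pixel's orientation is converted to
its angular separation from $a$ and correlated (Pearson) with sampled
intensity; the sign is flipped so that shading-like falloff scores +1.
The final score $\rho$ is the maximum over 16 azimuths (0° to 337.5°
in 22.5° steps; ties to the smallest), which guards against incidental
correlations consistent with other light directions.  The statistic is
invariant to positive affine intensity transforms and equivariant under
rotations of the stimulus by grid multiples.  The attached cosine fit
linearizes $L \sim A + u\cos\theta + v\sin\theta$; its p-value uses the
t approximation with $n-2$ degrees of freedom and ignores the spatial
autocorrelation of neighboring contour pixels — it is descriptive, not
inferential.

A fixed reference constant: the Pearson correlation between a cosine
and a linear falloff over separations in $[0°, 90°]$ is **0.979**
(`cosine_linear_correlation(90)`); over the full $[0°, 180°]$ range it
is 0.993.  The quarter-range value is the one that justifies shading ribbons
linearly: level-cut normals that ever face the light sit within 90° of
the illumination azimuth, so the quarter range is the separation range
that matters, and it is implemented as the definition.

## Ribbon stimuli

Ribbons isolate the covariation cue: a level-cut contour path (50%
visibility cut of a fresh seeded terrain) is drawn two pixels wide
(path pixel plus its neighbor along the into-mask normal — the
thickening direction is otherwise unconstrained) on an exact 0.5
background, shaded by the linear rule

$$L = 0.8 - 0.6\,\Delta(\theta, 90°)/180°,$$

which decreases from 0.8 at 90° through 0.5 at vertical segments to 0.2
at 270° — the unique linear-in-separation form through those three
anchor values.  Covariation is
weakened by mixing with noise whose radial amplitude spectrum matches
the average spectrum of rendered terrain images
(`spectrum_matched_noise()`: target amplitudes, random phases from a
seeded white-noise transform, conjugate-symmetric by construction); a
packaged default spectrum averaged over 16 seeded terrains
(`default_ribbon_spectrum()`) means no rendering step is needed.
Noise samples along the path are rescaled to the shading gamut
[0.2, 0.8] before mixing — this
choice keeps fully noisy ribbons in the same luminance range as
noiseless ones; downstream analyses rely only on the ordinal mapping
from noise proportion to measured $\rho$.  The 13 canonical mixing proportions
(`ribbon_noise_levels()`) are spaced non-uniformly so that measured
correlations spread approximately uniformly between 1 and 0.

The generate–measure round trip is the key validation: noiseless
ribbons measure $\rho \ge 0.99$ at azimuth 90° by design, and mean
measured $\rho$ decreases strictly across noise proportions
{0, 0.5, 1} (100 seeds at 128², about a minute of compute; the properties are
resolution-invariant well above the band limit, so full 1024² stimuli
behave identically).

## Defocus

Blur is a layered thin-lens approximation, not a lens trace: per-pixel
blur $\sigma(z) = g\,|z - z_f|/N_f$ pixels, with the depth map split
into ≥ 8 layers, each blurred by its representative $\sigma$ and
composited far-to-near with blurred coverage masks.  Only the optical
relations are honored quantitatively: halving the f-number
(2.8 → 1.4) exactly doubles $\sigma$ at every depth, the in-focus plane
and the pinhole limit are identities within $10^{-3}$, and kernels are
normalized so mean luminance is preserved to the same tolerance.  The
absolute pixel scale of lens blur depends on sensor and lens internals
that a thin-lens summary leaves open, so the gain $g$ defaults to 18.7 px per (length
unit/f-number), which puts the strong condition near $\sigma = 8$ px
at a plane 0.6 length units from focus on a 1024² image.  The default
depth-of-field geometry (camera at 20 length units, cut plane at 19.9,
bump peaks near 19.3) is the fixture behind `depth_from_height()`.

## Psychophysics layer and the synthetic observer

The analysis surface is deliberately descriptive: percent-chosen
tallies over complete round-robin paired-comparison designs (mean
exactly 50% for balanced designs), correlation binning with a closed
[0.9, 1.0] top bin, 0.1-wide bins down to [0.4, 0.5) and a catch-all
below 0.4 (empty bins are *missing*, not zero), and an OLS selection
slope per percentile of added noise.  Inferential statistics on human data (variance analyses, contrasts)
are deliberately out of scope — they are routine once the descriptive
layer exists and cannot be validated without subjects.

Because no human data ship with the package, every analysis stage is
validated against a synthetic observer.  Its latent focus score is
linear: $s = \alpha\rho + \beta c - \gamma b$ with covariation $\rho$,
design convexity $c$ (1 convex level cut, 0.5 bistable, 0.25 rotated)
and ordinal blur $b$; the defaults $\alpha = 3, \beta = 2, \gamma = 1$
are fixtures chosen to separate conditions cleanly, *not* estimates of
human parameters.  Choices follow a Bradley–Terry rule with lapse,
$P(i \succ j) = (1 - 2\lambda)\,\mathrm{logistic}((s_i - s_j)/\tau) +
\lambda$; the logistic link (rather than a Thurstone probit) was chosen
for its closed-form two-item solution (75/25 split ⇒ score difference
$\log 3$), and the two links are interchangeable for every qualitative
check here.  `fit_latent_scores()` is the matching
minorization–maximization maximum-likelihood fitter, identified by the
zero-sum (geometric-mean) constraint and iterated to $10^{-8}$; it
errors on disconnected comparison graphs and all-one-sided records.
Gauge-figure settings integrate to relief profiles by trapezoidal
cumulative integration of along-line gradients; repeats are averaged at
the *gradient* stage, which equals averaging profiles (integration is
linear) while tolerating missing repeats.  Observer profiles are
normalized multiplicatively to the grand mean height — gauge profiles
are anchored at zero, so multiplicative scaling preserves that anchor
where an additive shift would not; a zero-mean profile cannot be scaled
and errors (an offset-shift fallback would be the degenerate-case
alternative, and is intentionally not silently applied).  The probe
line direction defaults to 0° (rightward), matching a horizontal probe
row across a vertical ridge.

```{r end-to-end, eval = FALSE}
# End-to-end: stimuli -> measurement -> observer -> analysis
b <- level_cut_battery(seed = 2, size = 128)
s <- focus_score_model(b$rho, b$convex_fraction)
om <- observer_model(setNames(s, rownames(b)), tau = 0.5)
d <- simulate_choices(om, trials_per_pair = 20, seed = 3)
tally <- tally_choices(d)
tapply(tally, b$condition, mean)  # convex > bistable > rotated
```

## Problem sizes, numerics, and limits

Default test and validation sizes are 128²–512² pixels; every property checked — band limits, quantile
accuracy, orientation MAE, round-trip monotonicity — is resolution
robust at and above 128² for a band limit of 8 cycles/image, and the
package scales to 1024² when needed.  Monte-Carlo suites use 100 seeds.
Degenerate inputs raise errors rather than returning silently: constant
height fields (no valid cut), uniform masks (no contour), zero-variance
intensities (undefined correlation), 90° slants (unbounded gradient),
disconnected designs (non-identifiable scores).  Orientation ties in
the azimuth argmax break toward the smallest azimuth; the PCA tangent
of a perfectly isotropic window returns 0°, deterministically.

What the synthetic data do *not* emulate: natural light fields,
specular reflectance, cast shadows, interreflections, perspective
projection, tone mapping, or human decision processes beyond a
lapse-logistic link.  Passing tests therefore certify the stimulus
construction and measurement pipeline, and the internal consistency of
the analysis layer — not any claim about human perception.
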