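---
title: "Seasonal and circadian structural rhythms from TLS point clouds: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Seasonal and circadian structural rhythms from TLS point clouds: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tlsrhythm)
```

## The problem

Terrestrial laser scanning (TLS) produces dense 3D point clouds of crops in
the field. Scanned repeatedly — across a growing season, or every two hours
through a day and a night — those clouds carry two kinds of structural
rhythm: a *seasonal* trajectory (traits grow through the vegetative stages
and plateau at maturity) and a *circadian* cycle (leaves move over the
24 h day, entrained by light, temperature and humidity). `tlsrhythm`
implements the full workflow for quantifying both in maize: cloud
preprocessing, nine plant-level and nine leaf-level structural traits, and
the rhythm statistics (Tukey multiple comparisons across stages, linear
de-trending of circadian series, spline interpolation of half-hourly
weather records, Pearson environment–trait correlation).

Field campaigns of this kind rarely deposit their scans. The package
therefore ships a *parametric synthetic maize generator* whose ground
truth is known in closed form, so that every downstream stage is testable
by parameter recovery: if the method cannot re-measure what the generator
wrote into the cloud, it cannot be trusted on a real scan either.

## The synthetic world

A plant is a vertical stem cylinder plus 8–14 alternate leaves. A leaf is
a ruled surface around a midrib: a base-to-tip chord of length $L$ at
elevation $\varphi$ (inclination) and clockwise-from-north azimuth
$\theta$, with a parabolic downward deflection ("droop", zero at both
ends, $d\,L$ at mid-span), and a sine-arch width profile
$w(s) = W \sin(\pi s)$, $s \in [0,1]$ along the chord. This is the
simplest shape for which the true arc length (closed form via the
$\int\sqrt{a^2+u^2}$ primitive), surface area, apex height, inclination
and azimuth are all available exactly. Droop is capped at $0.5$ so the
midrib stays monotone along its horizontal chord, which is what makes
principal-axis slicing valid; strongly recurved leaves are out of scope.

Sampling emulates the scanner: point counts are Poisson with mean
(density × area), points are uniform on the surface, and isotropic
Gaussian noise of 2 mm reproduces the instrument's stated resolution. The
defaults are the study's stated world where one exists — planting on a
0.6 m grid, stage days 67/78/98/112 after planting, the 16- and 14-moment
circadian schedules, half-hourly environmental records — and a field
scientist's plausible choice where none does:

* mature stem height 2 m with a 5 % plant-to-plant size CV; leaf chords
  0.35–0.55 m (capped so neighbours on the 0.6 m grid do not overlap),
  maximum widths 5–9 cm, inclinations 20–60°, droop 0.05–0.25;
* logistic growth factor $1/(1+e^{-r(t-t_{\rm mid})})$ with
  $r = 0.12$/day and $t_{\rm mid} = 68$ days for the stem (leaves slightly
  earlier), so growth is strong across the first three stages and has
  plateaued by day 112;
* circadian modulation as an additive 24 h sinusoid per trait family
  (2 cm on heights, 3° on inclination, 1° on azimuth, peaking early
  afternoon). The model is *additive in trait units* for all governed
  fields; the mean over a uniformly sampled cycle is exactly the base
  value, which is what the de-trending recovery tests rely on;
* a clear-June-day environment: half-sine PAR (peak
  1500 µmol m⁻² s⁻¹) between sunrise 04:46 and sunset 19:46, temperature
  18–30 °C peaking at 14:00, relative humidity anti-phase to temperature
  between 40 and 80 %.

What the generator does **not** emulate: occlusion and self-shadowing,
wind, tassels and ears, leaf serration or curl, registration error between
stations, and realistic beam-footprint effects. A green test therefore
establishes that the *estimators* are correct on clean geometry of
realistic size, density and noise — not that they are robust to every
field artefact.

## Preprocessing

The chain mirrors standard TLS practice, in the canonical order: box
clipping to the plot, statistical outlier removal (mean distance to the
k = 20 nearest neighbours, rejection beyond mean + 3 sd — parameters that
field software rarely documents, so they are config-exposed), height
normalization against a digital terrain model (per-cell minimum z on a
0.25 m grid, nearest-neighbour infill, 3 × 3 mean smoothing, bilinear
evaluation), and a planting-grid nearest-center clustering that stands in
for instance segmentation (the real campaign used a learned segmenter;
synthetic clouds carry ground-truth labels instead). The cluster radius
defaults to half the planting interval, so distal leaf points of long
leaves are left unassigned by design; the preservation guarantee (≥ 95 %
of plant points) applies to the destructive stages.

One practical note found during development: the soil must be sampled at
the same areal density as the foliage. A sparse synthetic ground plane is
exactly what the outlier filter removes, after which the "terrain" model
is built from plant bottoms and heights are nonsense.

## Plant traits

Maximum/mean height and quantiles use linear interpolation between order
statistics (the common default; config-exposed). Crown size is the
diameter of the 2D convex hull of the horizontal projection. Plant azimuth
is the principal eigenvector of the horizontal covariance, reported modulo
180° because eigenvectors are sign-ambiguous, with an instability flag
when the projection is nearly isotropic (eigenvalue ratio < 1.05).
Projected leaf area uses grid occupancy (5 mm cells, about twice the
sensor resolution) rather than a hull, to respect leaf concavity; note
that occupancy is only accurate when the expected points per cell is well
above 1 — at sparse desk-scale densities it undercounts, which is why the
accuracy oracles sample densely. Volume is the 3D convex hull (an exact
incremental construction in C++; no qhull binding exists in this
environment). The projected area index divides the summed per-leaf
projected areas (overlap counts multiply) by the footprint hull area. The
3D profile index voxelizes the cloud and returns
$\sum_i n_i / (L \max_i n_i)$ over horizontal layers — 1 for a vertically
uniform profile, small for a single dominant layer; this is a declared
substitute for an index whose original formula is not public. Stem points
are excluded from the leaf-area numerators and included in
heights/crown/volume.

## Leaf traits and the midrib estimators

A leaf is sliced into 30 equal-width bins along its first principal
eigenvector; the midrib is the polyline of slice centroids, and the trait
definitions follow from it: length = arc length, widths from the lateral
extent per slice, inclination/azimuth from the base-to-tip chord (base =
the end nearer the stem axis), projected leaf length from the horizontal
projection of the midrib, leaf height = apex point height (attachment
height is available by flag).

At realistic per-leaf point counts (a 0.45 m leaf at 5 × 10⁴ points/m²
carries only ≈ 1000 points, ~30 per slice) naive versions of these
estimators fail their own error budgets, and most of the package's
numerical design lives here:

* **Arc length.** A raw centroid polyline zigzags with centroid sampling
  noise and *overestimates* length by up to 15 % on short wide leaves. The
  midrib is therefore a count-weighted smoothing spline per coordinate
  with low fixed degrees of freedom (df ≈ 8; generalized cross-validation
  was tried and under-smooths badly here). A midrib is a gentle curve; the
  approximation error of df 8 is negligible against the noise it removes.
* **Blade ends.** A tapering blade is never sampled all the way to its
  tip: the expected gap beyond the last sampled point is
  $\approx (2/\pi)/\sqrt{n}$ of the blade, i.e. 2–3 % *per end*. The
  curve is extended to the zero-width intercept of a line fit through the
  end width profile, clamped to 1.2 slices beyond the data; a
  non-tapering profile (e.g. a rectangle) triggers no extension.
* **Slice widths.** The lateral spread is uniform, so
  $\sqrt{12}\,\mathrm{sd}$ is the minimum-variance scale estimate; the
  sensor-noise variance is deconvolved first, estimated from the blade's
  own out-of-plane scatter, and the $O(1/k)$ Jensen bias of the sample sd
  is corrected analytically.
* **Maximum width.** The maximum over 30 noisy slices is biased upward by
  several percent; a single slice is too noisy. The maximum is instead
  read from a coarser width profile (≥ ~60 points per slice) through a
  count-weighted quadratic peak fit, with the within-bin concavity bias
  ($-c_2 h^2/24$) removed.

With these corrections, 50 random in-world leaves at 2 mm noise and
5 × 10⁴ points/m² are recovered with ≈ 2.5 % RMS error in length and
maximum width and < 0.7° RMS in inclination and azimuth (the recovery
tolerances — 3 % and 2° RMS over the 50-leaf sample — are the package's
acceptance criteria). A hard limit remains: leaves that are non-monotone
along their principal axis (extreme droop at high inclination) violate
the slicing precondition and are excluded from the generator's world.

## Rhythm statistics

* **Seasonal comparisons.** One-way ANOVA context; pairwise Tukey HSD
  p-values computed directly from the group means, pooled MSE and the
  studentized range distribution (verified against `stats::TukeyHSD` in
  the tests; the direct form makes 2000-rep Monte-Carlo calibration
  cheap). The compact letter display assigns one letter per maximal run of
  mutually non-significant groups in descending mean order ('a' = highest
  mean); with a common HSD threshold non-significance is an interval graph
  in mean order, so the letters encode the pairwise matrix exactly —
  a property the tests check by brute force. Zero mean difference is
  never significant, so all-identical data shares one letter even with
  zero residual variance.
* **De-trending.** Circadian series mix day-scale movement with seasonal
  growth. The hourly rate is the mean difference between two anchor
  stages divided by the elapsed hours (anchors default to days 78 and
  112; the cold-stress experiment has no seasonal anchors and uses rate
  0), and `corrected(t) = raw(t) − rate · hours(t − t0)` with `t0` at the
  first observation moment (the anchor is not stated by the source
  workflow; it is config-exposed). De-trend then re-trend is exact.
* **Environment interpolation.** Natural cubic spline (zero end second
  derivatives — the boundary condition is unstated upstream, natural is
  the conservative choice) through the half-hourly records; exact at
  knots, ~10⁻⁷ absolute error on a 24 h sine at quarter-hour queries;
  extrapolation is refused rather than guessed.
* **Correlation.** Sample Pearson r with a two-sided t-test on n − 2
  degrees of freedom and reporting tiers at 0.05/0.01/0.001. Aggregation
  before correlation is the arithmetic mean over samples per moment. No
  multiple-testing correction is applied across the trait × factor
  matrix, matching the reporting convention the workflow reproduces.

## Pipeline and reproducibility

`run_pipeline()` ties the stages together for three experiment modes
(seasonal; circadian under standard conditions with the 16-moment
schedule; circadian under cold stress with the 14-moment schedule and
rate 0). Every run writes CSV outputs plus a JSON manifest carrying the
seed, the configuration echo, its MD5 hash and per-file checksums; reruns
with the same configuration are bit-identical. Desk-scale runs use
2–5 × 10⁴ points/m² rather than the instrument's 10⁶ — trait *accuracy*
at that density is reduced (especially occupancy-based areas), but the
rhythm statistics operate on per-plant means and are insensitive to it.

## Known limitations

* Grid-occupancy projected areas undercount at sparse densities and
  overcount by ~perimeter × cell/2 at saturation; choose `cell_size` so
  that density × cell² ≫ 1.
* The planting-grid clustering truncates leaves that cross into a
  neighbour's Voronoi cell; leaf-level traits from the full pipeline are
  biased short for the longest leaves (single-leaf recovery, which is
  what the acceptance measures, is unaffected).
* LAS input is read-only and minimal (XYZ, point formats 0–3).
* The Tukey/CLD machinery assumes the interval structure that a common
  HSD threshold provides; with severely unbalanced group sizes the letter
  display may need more letters than runs (not exercised by this
  workflow, which is balanced).
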