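---
title: "Location-adaptive threshold segmentation: models, phantom and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Location-adaptive threshold segmentation: models, phantom and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(latmseg)
```

## The problem

Quantifying coronary lumen and plaque from contrast-enhanced CT requires,
for every cross-sectional plane along the vessel centerline, a lumen
boundary and an outer vessel-wall boundary. A fixed Hounsfield-unit
threshold fails because intraluminal contrast attenuation varies between
patients, along a vessel, and especially across stenoses. The
location-adaptive threshold method implemented here derives its attenuation
limits per plane from the local *inner point* (the attenuation at the
centerline seed), with a global *calibration factor* as a guard against
implausible inner points. Segmentation quality is assessed the way
method-comparison studies do it: per-plane areas and per-segment volumes
against a fine-interval reference (clinically, intravascular ultrasound;
here, a digital phantom's analytic ground truth), summarized with
Bland-Altman limits of agreement, Pearson correlation, and intraclass
correlation.

## Boundary model

For a plane at arclength $s$, let $I$ be the inner-point attenuation, the
mean HU over a 0.3 mm disc at the centerline point (a neighborhood mean
rather than a single voxel, to stabilize against noise; configurable via
`inner_disc_radius`). With calibration attenuation $C > 0$, the *effective
base* is

$$B = \begin{cases} C, & I > 1.45\,C \text{ or } I < 0.5\,C \\ I, & \text{otherwise,} \end{cases}$$

and the limits are $L = 0.5\,B$ (lower) and $U = 1.45\,B$ (upper). The
override replaces the base for *both* limits. The 0.5 factor is in the
spirit of full width at half maximum; the 1.45 factor marks calcification.

Along each of `n_rays` (default 64) equally spaced rays from the plane
center, attenuation is sampled at `radial_step` (default 0.05 mm) by
bilinear interpolation, optionally Gaussian-smoothed
(`profile_smoothing_sigma`, default 0.1 mm). Then:

* **Lumen boundary** — the first outward crossing below $L$, located to
  sub-step precision by linear interpolation between the bracketing
  samples. A first crossing above $U$ (calcification onset) caps the radius
  earlier if it occurs earlier; if both events fall within one step window,
  the one with the larger attenuation change between its bracketing samples
  wins, ties resolved toward the smaller radius. First crossing (rather
  than a global gradient argmax) prevents jumping across a thin wall into
  the background. If no event occurs, the ray is `"capped"` at
  `max_radius`.
* **Outer wall** — searching outward from the lumen radius, candidate
  spots are local maxima of $|\mathrm{d}HU/\mathrm{d}r|$ (central
  differences; plateaus resolve to the smaller radius). The selected spot
  is the candidate of largest gradient magnitude whose attenuation lies
  below $0.5\,B$ — calcified or still-enhanced samples are ineligible as
  wall spots. The position is refined by a parabolic fit of the gradient
  peak. With no qualifying candidate the wall collapses onto the lumen
  boundary (flag `"no-outer"`), a deliberate zero-plaque fallback rather
  than a guess.

Per-ray radii pass through a circular window-3 median filter (on by
default) to suppress single-ray outliers, and are assembled into closed
polygons. Plaque area is vessel area minus lumen area; plaque burden is
plaque area over vessel area. A plane on which every ray is capped raises a
plane-level segmentation failure; failed planes are logged and excluded,
and a segment fails outright when more than half its planes do — mirroring
how clinical platforms exclude segmentation failures rather than emitting
silent nonsense.

## Curved planar reformation

Centerlines are ordered world-coordinate polylines (mm) with cumulative
arclength and unit tangents. Planes are spanned by rotation-minimizing
frames: the double-reflection construction when points are available,
minimal-rotation (Rodrigues) transport when only tangents are. Frenet
frames were rejected because their normal is undefined on straight runs,
which coronary centerlines contain. Cross-sections are sampled from the
volume by trilinear interpolation on a square grid (default 10 mm field of
view at 0.1 mm — finer than CT voxels so that boundary localization is not
grid-limited); out-of-volume samples are filled with −1024 HU and flagged,
and flagged pixels never participate in boundary searches. One convention
holds everywhere: world coordinates in mm, 0-based voxel indices, voxel
$(i,j,k)$ at `origin + c(i,j,k) * spacing`; NIfTI affines must be
axis-aligned (anisotropy is fine, shears and rotations are rejected on
read).

## Volumes, burden, and profile matching

Two integration conventions coexist deliberately, because the two sides of
a clinical comparison use them: the *test* side (CT software convention)
sums per-plane areas times the plane interval; the *reference* side
(pullback convention) integrates by composite Simpson's rule, with a
trapezoid on the trailing panel when the plane count is even. On identical
profiles the two differ by the half-plane overhang at the segment ends —
visible as a small systematic volume offset in self-comparisons, which is a
property of the conventions, not a defect.

Reference profiles at fine interval (0.001 mm class) are matched to test
planes by linear interpolation of the lumen and vessel area channels;
plaque area and burden are *recomputed* from the interpolated areas so the
identity `plaque = vessel − lumen` survives resampling. Alignment is a
signed scalar arclength offset (landmark-style matching); sub-interval
registration is out of scope. The stenotic subgroup keeps planes whose
reference burden strictly exceeds 0.6 — a burden of exactly 0.6 is
excluded.

## Agreement statistics

* Bland-Altman: differences $d = \text{test} − \text{reference}$, sample SD
  with $n-1$ denominator, limits of agreement $\bar d \pm 1.96\,s_d$, CI of
  the mean difference $\bar d \pm 1.96\,s_d/\sqrt n$.
* Pearson $r$ with Fisher-transform CI
  $\tanh(\operatorname{atanh} r \pm z_{0.975}/\sqrt{n-3})$ and the
  $t$-based two-sided p-value (verified against `cor.test` in the tests).
* ICC(2,1): two-way random effects, single measurement, absolute
  agreement,
  $\mathrm{ICC} = (MS_R - MS_E) / \left(MS_R + (k-1)MS_E + \tfrac{k}{n}(MS_C - MS_E)\right)$,
  with the F-based absolute-agreement confidence interval (McGraw-Wong
  style, Satterthwaite degrees of freedom) and $F = MS_R/MS_E$ for the
  p-value. The mean squares are computed directly; `stats::aov` serves as
  an independent oracle in the test suite only.
* Fisher r-to-Z for independent groups:
  $z = (\operatorname{atanh} r_1 - \operatorname{atanh} r_2)\big/\sqrt{1/(n_1-3) + 1/(n_2-3)}$.
  Where ICC values are compared across platforms the same transform is
  reused and the report flags the method as `"fisher-z-on-icc"` —
  statistically debatable, but it is the convention of the comparison
  design this package mirrors, so it is reproduced and labelled rather
  than silently replaced.

`evaluate_platform()` accepts single profiles or per-segment lists; the
per-segment volume block needs a cohort (n ≥ 2 for Bland-Altman, ≥ 4 for
Pearson, ≥ 5 for ICC) and carries `NULL` statistics below those sizes. Note
that pooling planes across segments treats planes as independent; no
clustered-data correction is applied, a documented limitation of the
mirrored design.

## The digital vessel phantom

The phantom stands in for the clinical pair of CT volume and pullback
reference. It emulates: a contrast-enhanced lumen (400 HU) inside a soft
plaque wall (60 HU) against an epicardial-fat-like background (−50 HU); a
focal stenosis as a cosine-taper lumen-radius reduction (vessel radius
unchanged, so plaque thickens at the throat); optionally a dense calcium
arc (800 HU, an angular sector of the wall between two arclengths) and an
adjacent high-attenuation chamber cylinder; partial-volume blur as an
isotropic Gaussian (0.25 mm); and i.i.d. Gaussian noise in HU (20 HU)
added after the blur — the standard simulation order that keeps the ground
truth analytic. Rasterization is anti-aliased by 4-per-axis supersampling.
Straight and helical centerlines are supported; helical pitch should keep
the curvature radius well above the vessel radius so planes do not
intersect.

Default geometry is a realistic proximal target segment: 25 mm long, 2 mm
lumen radius, 3 mm vessel radius, 50% stenosis over 8 mm at mid-segment on
isotropic 0.4 mm voxels. These defaults make the plaque-burden profile
cross the 0.6 stenotic threshold (≈0.56 at baseline, ≈0.89 at the throat),
so both the stenotic and non-stenotic regimes are exercised. Ground truth
(areas, burden, volumes) derives from the unblurred geometry only — it is
invariant to voxel size, blur and noise — and the fine-interval reference
profile samples it at 0.001 mm-class spacing, emulating a pullback. With a
fixed seed the phantom is bit-reproducible, and the generator restores the
caller's RNG state.

What the phantom does **not** emulate: cardiac anatomy and motion, beam
hardening and calcium blooming beyond a plain dense arc, eccentric or
lipid-gradient plaque, HU texture, bifurcations. Passing tests therefore
demonstrate correctness of the geometry, the detection rules and the
statistics under controlled contrast — not clinical performance.

## Accuracy characteristics and numerical choices

Two intrinsic accuracy limits of the threshold model under the default
phantom contrast are worth understanding, because the test suite measures
them honestly rather than hiding them:

* **Threshold-offset bias of the lumen boundary.** The 50%-of-inner lower
  limit is 200 HU, but the blurred lumen/plaque edge passes through its
  *midpoint* (230 HU) at the true boundary. A first crossing of 200 HU
  therefore sits outside the edge by about
  $\sigma_\mathrm{eff}\,\Phi^{-1}$-scaled distance (≈ 0.22 σ for this
  contrast), where $\sigma_\mathrm{eff}$ combines the phantom blur with
  raster and interpolation smoothing (≈ 0.35–0.4 mm here). At a 2 mm
  radius this is a systematic lumen-area overestimate of several percent.
  It is a property of the half-maximum rule whenever the wall attenuation
  is not negligible compared to the lumen; the acceptance script reports
  the measured per-plane error.
* **Resolution limit of the outer wall.** The outer wall produces a
  gradient peak only if it is separated from the lumen edge by more than
  the smoothing scale. With a 1 mm wall and
  $\sigma_\mathrm{eff} \approx 0.38$ mm, the lumen-edge gradient tail and
  the wall edge merge into a monotone gradient on most rays — the
  continuum $|\mathrm{d}HU/\mathrm{d}r|$ has no local maximum at the wall,
  and the detector takes its documented `"no-outer"` fallback. Plaque
  quantification at baseline wall thickness is therefore
  resolution-limited on this voxel grid; at the stenosis, where the wall
  is thicker, the wall resolves and plaque accuracy recovers.

Other numerical decisions: blur before noise; supersampling factor 4
recorded as a constant of the rasterizer; radii search capped at 4 mm;
sub-step positions by linear interpolation (lumen) and parabolic gradient
refinement clamped to ±half a step (wall); circular median filter window 3;
strict inequalities at every threshold (an inner point exactly at
$1.45\,C$ does not trigger the override; a burden of exactly 0.6 is not
stenotic); degenerate statistical inputs raise errors rather than NaNs
(zero variance, n below the minimum, |r| = 1 in the Fisher transform), and
the perfect-agreement ICC interval collapses onto the point estimate.

Problem sizes used throughout validation: the full-scale segment is 25 mm
at a 0.25 mm plane interval (101 planes); the agreement cohort is eight
segments of 20–25 mm with severities 0.30–0.65 and lumen radii 1.8–2.2 mm;
reference profiles use 0.001 mm sampling; the Fisher null calibration uses
100,000 simulated pairs at n = 30. Unit tests use an 8 mm variant of the
same phantom.

## Known limitations

The polar boundary model assumes a star-convex lumen about the centerline
point — adequate for the phantom and typical coronary cross-sections,
wrong for extreme eccentricity. Calibration is a scalar input, not
estimated from images. Only axis-aligned NIfTI volumes are read. Per-plane
pooling ignores within-segment correlation. The interaction of the 145%
ceiling with calcium encountered while searching for the *outer* boundary
is handled by making high-attenuation samples ineligible as wall spots;
whether that matches any particular clinical implementation is unknown,
and it is stated here rather than guessed at silently.
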