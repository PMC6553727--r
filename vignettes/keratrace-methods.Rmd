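---
title: "Corneal power after SMILE: the keratrace model and its assumptions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Corneal power after SMILE: the keratrace model and its assumptions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(keratrace)
```

## The optical model

`keratrace` represents a cornea as two coaxial, rotationally symmetric
conicoid surfaces in a right-handed frame with +z pointing from air into the
eye and the origin at the anterior apex. A conicoid with apical radius $R$
(mm) and asphericity $Q$ has sag

$$z(r) = \frac{r^2}{R\left(1 + \sqrt{1 - (1+Q)\,r^2/R^2}\right)},$$

so $Q = 0$ is a sphere, $Q < 0$ a prolate ellipsoid (the physiologic
cornea), $Q > 0$ oblate (the typical shape after myopic ablation). The
posterior apex sits at $z = $ central thickness. All lengths are mm; powers
are diopters, computed after converting lengths to meters. A single fixed
sign convention (surface normals oriented toward the incoming light,
ray directions with positive z) keeps the Snell refraction free of
case analysis.

Refractive indices are air 1.0, stroma 1.376, aqueous 1.336, plus the
fictitious keratometric index 1.3375 used only by SimK-style formulas.

### Ray-traced power

Total corneal refractive power (TCRP) traces an axis-parallel ray entering
at height $h$, refracts it at both surfaces with the vector form of
Snell's law, and converts the exit direction to a power

$$P(h) = \frac{n_{aq}\,\sin U'}{h},$$

with $U'$ the exit angle against the axis and $h$ in meters. This
definition was chosen because it reduces exactly to the Gaussian thick-lens
equivalent power

$$P = P_1 + P_2 - \frac{d}{n_c} P_1 P_2$$

as $h \to 0$, which gives the tracer an independent closed-form oracle; it
also avoids any principal-plane bookkeeping at finite aperture. The
instrument's actual focal-length-to-power conversion is proprietary, so an
alternative definition ($n_{aq}$ divided by the axial crossing distance
from the anterior apex plane) is available behind
`power_definition = "axial"` for sensitivity analysis. The two agree
paraxially and drift apart by a few diopters at 4 mm height; none of the
package's conclusions depend on the choice.

```{r oracle}
m <- corneal_model(conic_surface(7.7, -0.25), conic_surface(6.4, -0.20), 0.54)
c(gauss = gaussian_equivalent_power(m), trace = trace_power_at(m, 0.005))
```

Ray-surface intersections are solved as a quadratic in the path length; the
degenerate paraboloid case ($Q = -1$, axis-parallel rays) makes the
quadratic exactly linear and is solved directly rather than iteratively.
Intersections select the first positive root on the conicoid's front sheet.

### Ring and zone aggregation, centration

Power maps sample $P(r, \theta)$ on a polar grid (defaults: 0.05 mm radial
step, 256 meridians, 4 mm outer radius — quadrature error on smooth maps is
below $10^{-4}$ D and halving the grid changes ring values by less than
$10^{-6}$ D on symmetric corneas). Aggregation follows the instrument's
two geometries and two centrations:

* **ring** — the unweighted meridian mean at a single diameter, with linear
  radial interpolation between grid radii (a circle, not an annulus);
* **zone** — the area-weighted mean over the filled disc, each sample
  weighted by its exact clipped annulus area, so the zone value tends to
  the central power as the diameter tends to zero;
* **apex vs pupil** — the grid origin is the corneal apex or the apex
  shifted by the pupil-offset vector. Rays stay parallel to the common
  optical axis while sample radii are measured from the chosen center,
  mimicking instrument-axis acquisition with off-axis aggregation. With a
  zero offset the four variants coincide exactly, which is the package's
  sharp version of the observation that centration has little impact.

Ring and zone statistics refuse to answer when more than 10 % of their
samples (ring) or area (zone) is untraceable, rather than silently
extrapolating peripheral diameters.

## Keratometric formulas

SimK, TNP and EKR are evaluated from the model's apical radii: a
rotationally symmetric cornea makes device meridian selection moot, and the
imported-data pathway takes instrument-exported values instead. This
isolates the one step of the device pipeline (the 3 mm SimK meridian pick)
that cannot be replicated from geometry. The printed EKR formula has no
diameter dependence, so the 4.0 mm and 4.5 mm names evaluate identically on
synthetic data and differ only for imported device exports — declared
rather than hidden.

The clinical history method converts spherical equivalents from the
spectacle to the corneal plane with $SE_c = SE / (1 - SE\,vd/1000)$ before
differencing. The vertex distance is not printed in the source material;
12 mm, the conventional refraction-lane distance, is the default and the
conversion is configurable. At the cohort means, using the spectacle plane
instead would change CHM by about 0.3 D, which is why the corneal-plane
reading is stated explicitly.

## The synthetic cohort generator

The generator's defaults are the study conditions: preoperative Km
42.52 ± 1.30 D on [39.80, 44.50], preoperative SE −4.91 ± 2.01 D on
[−9.50, −1.50], recorded postoperative SE 0.20 ± 0.40 D on [−0.62, 1.12],
optical zones {6.0, 6.5} mm, posterior/anterior radius ratio 0.822, central
thickness 540 ± 30 µm. Independence of preoperative Km and SE is assumed
(no per-eye covariance is published). Two calibration choices matter:

* **Truncated-normal moments.** The printed mean/SD describe the cohort —
  i.e. the *truncated* distribution. Naively truncating
  $N(42.52, 1.30^2)$ to the printed range would shift the mean by
  ~0.11 D, so the sampler solves for the underlying normal whose truncated
  mean and SD equal the configured values (closed-form truncated moments,
  Nelder–Mead) and then samples by rejection.
* **Noise decomposition.** The recorded postoperative SE is drawn from the
  configured distribution, and the cornea is reshaped to deliver that value
  minus an independent N(0, 0.25 D) refraction-measurement noise; surface
  radii used for "measured" keratometry carry independent N(0, 0.01 mm)
  noise. Setting both SDs to zero yields a noise-free pipeline in which
  CHM equals the reshaped anterior SimK exactly — the package's internal
  consistency check.

The lenticule model is invented, because the source describes the surgery,
not a shape equation: anterior keratometric power drops by exactly the
corneal-plane correction, central thickness drops by a Munnerlyn-style
paraxial lenticule $\Delta SE \cdot OZ^2/3$ µm plus a 15 µm base cut, and
the anterior $Q$ shifts oblate-ward by 0.08 per diopter so the ray-traced
power rises from the mid-periphery outward, as observed after myopic
surgery. The posterior surface and the pupil offset are untouched. Default
preoperative asphericities ($Q_{ant} = -0.25$, $Q_{post} = -0.20$) are
representative physiologic prolateness; no published value exists for this
cohort, so all results are functions of the configuration.

What the generator does **not** emulate: astigmatism (only spherical
equivalents are modeled; surfaces are untilted and non-toric), epithelial
remodeling and biomechanical response, decentered ablations, and the
device's proprietary ring/zone weighting and focal-length conversion.
Passing tests therefore demonstrate internal consistency and directional
fidelity (ordering of method means, center-to-periphery power shape), not
per-eye agreement with device measurements.

## Statistical battery

Bland–Altman bias, the SD of paired differences (n−1 denominator) and
95 % limits of agreement bias ± 1.96·SD are computed directly; the LOA
identity is asserted for every report row. Pearson correlation and its
two-sided p come from the t transform with n−2 df. The omnibus comparison
is a within-subject one-way repeated-measures ANOVA (subject as the error
stratum); pairwise contrasts against CHM are paired t tests multiplied by
the Bonferroni family size m and capped at 1. The replication layout
compares 20 methods against CHM (18 regular + 2 modified TCRP), so m = 20;
m is recorded in the report metadata because no published value of m
exists. Degenerate contrasts get documented conventions: a zero
between-method sum of squares reports F = 0, p = 1; a zero-variance
nonzero-mean paired difference reports the epsilon floor p = 1e−15; exact
method-equals-reference correlations are reported as missing with a
`degenerate` flag, never as 1. Sphericity corrections (Greenhouse–Geisser)
and bootstrap LOA intervals are out of scope.

## Problem sizes and determinism

Every stochastic routine takes an explicit seed and cohorts are
byte-identical under a repeated seed. The package's own validation uses
100 randomized corneas for the paraxial-oracle sweep, 1 000 random
incidences for the Snell invariant, n = 5000 (geometry only) for moment
recovery and n = 40 — the study's size — for the full ray-traced pipeline;
a 40-eye cohort with four power maps per eye traces in roughly ten seconds
on one core at the default grid.

## Known limitations

* Scalar powers only: astigmatic/vector keratometry is out of scope.
* The CHM-vs-TCRP bias magnitude in synthetic cohorts depends on the
  invented lenticule Q-shift; only directions are claimed.
* The EKR 4.0/4.5 mm distinction and the device's EKR distribution report
  are not modeled beyond the printed simplified formula.
* XLSX import is a thin convenience over a column mapping; the canonical
  interchange format is CSV.
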