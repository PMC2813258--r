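---
title: "Analytic maps of the V1–V2–V3 complex: models, estimators, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analytic maps of the V1-V2-V3 complex}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foveamap)
```

## The model family

Primate early visual cortex contains mirrored retinotopic maps of the
visual hemifield in areas V1, V2 and V3, whose foveal representations
meet at the foveal confluence.  `foveamap` implements the classical
analytic description of this projection.  Writing a visual-field
location as the complex number \(z = E e^{i\theta}\) (eccentricity
\(E\) in degrees, polar angle \(\theta\) in radians, 0 on the
horizontal meridian, positive in the upper field), the map for a single
area is

\[
w_{\text{mono}}(z) = k \log (z + a), \qquad
w_{\text{di}}(z) = k \log \frac{z + a}{z + b},
\]

with a scale \(k\) (mm per log-unit; typical human fits range over
15–26 mm), a foveal pole \(a\) (default 1.05°) that caps the foveal
singularity, and for the dipole a peripheral pole \(b\) (default 90°)
that makes cortex taper peripherally as it does in reality.  Both maps
are conformal: locally isotropic everywhere, with linear magnification
\(\approx k/E\) for \(a \ll E \ll b\).  Note that this classical
"inverse eccentricity law" is a statement of proportionality: at the
default poles the dipole's magnitude is uniformly about \(0.8\,k/E\)
over 5–15°, while \(E \cdot M(E)\) is constant there to within a few
percent.  The package's tests assert the proportional form.

The full complex is built in two stages (`hemifield_to_pacman()`,
then the map).  The hemifield quadrants are reflected about the
vertical meridian to append V2, and again about the resulting border to
append V3, with angular compressions \(\alpha_1 = 1\), \(\alpha_2\),
\(\alpha_3\) per area.  The result is an intermediate "pacman" space
spanning \(\pm \tfrac{\pi}{2}(\alpha_1+\alpha_2+\alpha_3)\); V1/V2
borders carry the vertical meridian and V2/V3 borders the horizontal
meridian, so the composed cortical map is seamless across areas (this
is tested exactly).  Only \(\alpha_1\) and \(\alpha_3\) are pinned by
the quantitative claims the package reproduces (1 and 0.4); the V2
compression defaults to \(\alpha_2 = 0.5\), between its neighbours, and
is configurable.

## The sheared ("double-sech") variants

Conformality has a price: because \(|z + a|\) is smaller on the
vertical meridian than on the horizontal meridian at the same
eccentricity, the conformal wedge inflates areal magnification
\(M_a\) with polar angle — most dramatically around \(E \approx a\),
where the V3 representation balloons to many times the V1
representation of the same visual region.  Measured maps show the
opposite: \(M_a\) is essentially independent of polar angle within an
area, and V1:V2:V3 surface ratios are constant across eccentricity.

The sheared variants restore this property by compressing the polar
angle before the log map.  We implement the compression exactly from
its defining requirement.  For a single pole \(p\), demanding that
\(M_a(E, \theta)\) not depend on \(\theta\) while leaving the
horizontal meridian unchanged gives the ordinary differential equation

\[
\frac{dg}{d\theta}
  = \prod_{p \in \{a\}\ \text{or}\ \{a, b\}}
    \frac{E^2 + p^2 + 2 p E \cos g}{(E + p)^2},
\qquad g(0) = 0,
\]

whose solution \(g(\theta, E)\) replaces \(\theta\) inside the log.
Each pole contributes one factor that equals 1 on the horizontal
meridian and dips towards the vertical meridian, most strongly at
eccentricities near that pole — a foveal and a peripheral angular
"notch", which is why we keep the traditional *double-sech* name for
the dipole version.  The compression is odd, satisfies
\(|g| \le |\theta|\) (hence the sheared V1 outline is narrower than the
conformal one), and adds **no free parameters**.  Consequences, all
verified numerically in the tests:

* within V1 the meridional anisotropy is 1 to better than 0.1%;
* across areas \(M_a\) at fixed eccentricity scales exactly with
  \(\alpha_i\): V3 has meridional anisotropy \(\alpha_3 = 0.4\), V2
  \(\alpha_2\);
* the V3:V1 integrated surface ratio over any eccentricity band equals
  \(\alpha_3 : \alpha_1\) (0.4 : 1) to the resolution of the surface
  integration;
* the map is no longer conformal: local anisotropy becomes complex and
  strongest near the foveal V3 projection.

The ODE is integrated by fixed-step 4th-order Runge–Kutta (64 steps
over \(|\theta|\), integrated on the absolute angle and sign-restored
so mirror symmetry holds to the last bit).  The integration error,
\(O((\pi/64)^4)\), is orders of magnitude below every tolerance used in
the package.

## Foveal banding

Both wedge models collapse the foveal representation of V2 and V3 to
the single confluence point, whereas measured foveal maps show V2 and
V3 forming bands around the tip of V1.  The banded variant reproduces
this by shifting the intermediate space towards negative x by a graded
amount before the log map:

\[
s(\theta') = \lambda \left(1 + \tfrac{2}{\pi}
  \max\!\bigl(0,\ |\theta'| - \tfrac{\pi}{2}\alpha_1\bigr)\right),
\]

i.e. the whole of V1 translates rigidly by \(\lambda\) (default 0.4°),
and beyond the V1 span the shift grows linearly so that the V2/V3 apex
(zero radius) is drawn out into a line and the wedges become
trapezoids.  Only the boundary behaviour of the grading is dictated by
the geometry (constant over V1, graded beyond, apex to line); the
linear form and its rate \(2/\pi\) per radian are this package's
choice, the simplest grading that extends the apex uniformly.  The
shift is expressed in Cartesian coordinates of the intermediate space
and the result re-polarised (`banding_shift()`).

Two implementation points matter:

* **Stage order.**  For the sheared variants the shift is applied *in
  the sheared frame* (mirror → shear → shift → log), with the shift
  magnitude still a function of the pre-shear pacman angle.  Applying
  the angular shear after the shift would be ill-defined: the shifted
  sub-\(\lambda\) part of V1 wraps past \(\pm\pi\), where any odd
  angular map is discontinuous, and the cortical map would tear along
  the foveal horizontal meridian.  With shift-after-shear the map is
  continuous everywhere (tested to \(10^{-8}\) mm across the seam
  region); for the conformal variants the two orders coincide.
* **Output frame.**  All projections are translated so that the
  *unbanded* V1 foveal image sits at the origin.  With this anchor the
  banded and unbanded maps agree in the periphery (displacement of
  order \(\lambda k / E\)) and banding is visibly a foveal
  modification; the banded V1 tip extends roughly
  \(k \log\{a/(a-\lambda)\} \approx 9.5\) mm beyond the origin, which
  is simply the cortical cost of a 0.4° shift under foveal
  magnification.  Setting \(\lambda = 0\) reproduces the unbanded map
  bit for bit.

With the defaults, banding raises foveal V2/V3 areal magnification
above V1 below about 0.75° and strongly reduces foveal local
anisotropy relative to the unbanded sheared wedge (the tests assert a
halving of the median log anisotropy in foveal V3).  Exactly *on* the
apex line the tangential magnification diverges — a point is mapped to
a line — so local anisotropy necessarily tends to 0 as \(E \to 0\)
inside V2/V3; "local isotropy at the foveal centre" is a statement
about the bulk of central nodes, not the line itself.

## Estimators

All estimators mimic the numerical procedure of projecting a finely
meshed grid of visual-field squares (`grid_spec()`: 64 log-spaced
eccentricities over 0.05–24°, 181 polar samples spanning the pacman
arc, square half-side 1% of the local eccentricity).  Squares are
aligned with the iso-polar and iso-eccentricity directions and have
equal sides in visual degrees.

* **Local anisotropy** (`local_anisotropy_field()`): ratio of the
  projected side lengths, reported as \(M_p / M_e\).  The two
  conventions in circulation differ by inversion; we report the one
  under which the conformal wedge gives \(1/\alpha_3 = 2.5\) in V3 and
  an isotropic map gives 1.
* **Meridional anisotropy** (`meridional_anisotropy_field()`): areal
  magnification of the projected square divided by the areal
  magnification on the V1 horizontal meridian at the same eccentricity
  (computed directly, not from a nearest node).  Squares straddling a
  singularity are flagged, not aggregated.
* **Areal magnification** (`areal_magnification_curve()`): narrow
  iso-eccentricity bands are projected, quadrilaterals triangulated,
  shoelace areas summed, and \(M(E) = \sqrt{A_{\text{cortex}} /
  A_{\text{visual}}}\) reported in mm/deg.  An optional polar window
  restricts the band; a narrow window about the horizontal meridian is
  what the closed-form dipole derivative
  \(k \lvert 1/(E+a) - 1/(E+b) \rvert\) is compared against, since for
  the conformal variants the full-band average sits several percent
  above the horizontal-meridian value (the ballooning again).

The two anisotropy estimators are genuinely different quantities: the
conformal wedge is locally isotropic everywhere yet meridionally very
anisotropic near \(E = a\); the sheared wedge is the converse.  A
consistency test verifies that the finite-square areal estimate
converges (as the square shrinks) to the determinant of the
finite-difference Jacobian (`local_jacobian()`, central differences,
relative step \(10^{-5} \max(E, a/10)\) — the floor keeps the step
stable near the fovea).

`numeric_inverse()` inverts the projection by damped Gauss–Newton from
the best node of a coarse per-area grid; areas are tried in
foveal-to-peripheral order so shared borders resolve to the lower-index
area, and points no area explains are reported unmapped rather than
forced.

## Fitting

`fit_retinomap()` minimises summed squared cortical-position residuals.
Because the map is linear in \(k\) (the anchor translation included),
\(k\) is profiled out in closed form whenever free; remaining free
parameters are optimised by bounded quasi-Newton (`nlminb`) from a
3-per-parameter multi-start grid spanning the bounds
(\(k \in [5, 50]\) mm, \(a \in (0, 5]\)°, \(b \in [40, 180]\)°,
\(\lambda \in [0, 2]\)°), making fits deterministic given the data.
The recommended use keeps \(a\), \(b\), \(\lambda\) fixed at the
defaults and frees only \(k\), which captures most inter-individual
variability; note that \(\lambda\) is only identifiable from banded
models and \(b\) only from peripheral data.  `fit_magnification_curve()`
fits curves in *log* magnification — magnification spans two orders of
magnitude from fovea to periphery, and a log loss weights the foveal
and peripheral ends evenly, which is also why \(k\) can again be
profiled (it is additive in log).  Requests with fewer than three curve
points per free parameter are refused as under-determined and returned
flagged rather than fitted.

The synthetic generator (`generate_synthetic_retinotopy()`, also
available as `simulate()`) draws locations uniformly in
log-eccentricity over 0.2–12° — matching the eccentricity range the
model family is validated on — and uniformly in polar angle per area,
then adds isotropic Gaussian noise in mm.  Parameter-recovery results
on these data show estimator correctness, not robustness to the ways
real fMRI retinotopy deviates from the model (correlated noise, visual
coordinate error, parcellation error, cortical folding and
flattening distortion).

## Problem sizes and reproducibility

The test-suite defaults are sized for interactive use: estimator fields
on grids of roughly \(14 \times 41\) to \(64 \times 181\) nodes,
surface integrals at \(96 \times 48\) cells, and recovery studies with
20 replicate fits at 100 samples per area; all quantitative claims are
insensitive to refining these further (the field estimators change by
well under the asserted tolerances when the grid or the square size is
halved).  Every stochastic step takes an explicit seed; there is no
hidden random state.  `scripts/acceptance.R` recomputes the four
headline quantities (V3 local anisotropy of the conformal wedge, V3
meridional anisotropy and V3:V1 surface ratio of the sheared wedge,
and the peak foveal V3 meridional anisotropy of the conformal wedge)
from scratch.

## Known limitations

* Strictly planar geometry: no cortical curvature or folding, no
  hemisphere stitching across the vertical meridian, nothing beyond V3.
* The grading of the banding shift beyond the V1 span is constrained
  only at its boundaries; other monotone gradings would satisfy the
  same qualitative claims with slightly different foveal band widths.
* The apex line makes V2/V3 local anisotropy degenerate exactly at
  \(E = 0\) (see above).
* Magnification comparisons against \(k/E\) hold as proportionality,
  not equality, at the default poles.
* The CLI figure subcommands render model panels only; no empirical
  overlays are produced.
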