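---
title: "Radial quantification of acetabular bone loss: model and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Radial quantification of acetabular bone loss}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trabl)
```

## The measurement model

The package measures *total radial* bone loss: for every direction from
the reconstructed hip joint center, is there still bone, and if so, how
far beyond where it ought to be? The model has four stages.

**1. Geometry fitting.** The joint center is the center of a least-squares
sphere through the user-outlined acetabular surface of the reconstructed
mesh. We use an algebraic (linear) fit — exact for noise-free data — as
the initializer of a geometric Gauss–Newton refinement of
$\sum_i (\lVert p_i - c\rVert - r)^2$, iterated to a step tolerance of
$10^{-9}$ mm. The geometric criterion matters with anisotropic outlining
noise, where algebraic fits are biased toward smaller radii. A
total-least-squares plane (smallest principal component of the centered
points) is fitted to the rim outline; the acetabular axis $\vec n$ is its
normal, signed to point laterally. "Lateral" needs an orientation rule the
inputs do not supply directly; we use the direction from the ASIS midpoint
(a midline proxy always present in the landmark set) to the sphere center,
projected on the plane normal. The anteroposterior axis is the anterior
axis of the ISB pelvic frame — $Z$ from left to right ASIS, anterior $X$
orthogonal to $Z$ in the plane of both ASIS and the pubis point, superior
$Y = Z \times X$ — projected into the rim plane. The superior in-plane
reference is $\vec n \times \vec{ap}$ with its sign chosen to agree with
ISB superior, which absorbs left/right handedness so a single sector table
serves both sides.

**2. Ray grid.** Directions are sampled on a unit sphere ($r_u = 1$ mm)
with the polar angle $\varphi \in [0, \pi]$ measured from $-\vec n$ (so
$\varphi = 0$ points into the cup) and azimuth $\theta \in [-\pi, \pi)$:
$d(\varphi, \theta) = -\cos\varphi\,\vec n + \sin\varphi\,(\cos\theta\,
\vec{ap} + \sin\theta\,\vec{sup})$. $\varphi$ is sampled closed (the poles
are genuine directions), $\theta$ half-open to avoid a duplicated seam
column. The default grid is $100 \times 100$; it is deliberately *fixed*,
because inter-patient comparability of maps and ratios requires a common
sampling, and it is coarse enough that a case runs in seconds.

**3. Deviation map.** Each ray takes its first entry point ($t > 10^{-6}$
mm, guarding self-origin hits) into each mesh, irrespective of surface
orientation; intersections duplicated across shared edges collapse to the
minimum $t$. The per-ray deviation is $|t_{def} - t_{rec}|$ when both
meshes are hit and $\infty$ otherwise — an uncontained defect has no
radial support, which the color graph shows as grey. Bone found *beyond*
the reconstruction (rim pushed outward by a migrated cup) is kept with its
absolute deviation, and deficient-only hits count toward $A_{def}$; the
ratio is not clamped, so pathological overgrowth can legitimately produce
a negative regional ratio, flagged with a warning. If more than 1% of rays
meet a surface within $10^{-6}$ mm of the origin the case is flagged: the
center then lies *on* a mesh and the frame is suspect. The caster is
Möller–Trumbore behind a median-split AABB BVH (compiled); a separately
written exhaustive-loop caster must agree exactly and a third, pure-R
implementation checks both on small meshes in the tests.

**4. Projection and ratio.** The grid unfolds by azimuthal equidistant
projection, $r = r_u \varphi$, $x = r\cos\theta$, $y = r\sin\theta$, and
the two hit surfaces are compared by area *in the projected plane*:
$\mathrm{ratio} = (1 - A_{def}/A_{rec}) \cdot 100\%$. The planar metric
distorts (a lateral cell covers more planar area than a medial one at
equal solid angle); we keep it as the defining convention, with true
spherical areas available via `metric = "spherical"` for sensitivity
checks — for ratios of similar regions the two differ little.

## Area accounting on a discrete grid

Area on a discrete grid needs a rule. Cells are the quadrilaterals of four
index-adjacent grid points (wrapping in azimuth, so the disk closes);
each contributes its shoelace area weighted by $k/4$ where $k$ of its
corners pass the mask. This fractional rule converges to the continuous
area from both sides and is symmetric; the strict all-corner alternative
(`cell_rule = "all"`) is kept for sensitivity analysis and is what the
independent oracle uses.

Region accounting needs more care than point labels provide. Three
discretization traps surfaced during development, all at boundaries that
coincide with grid structure:

* a sector boundary that falls exactly on a grid column shifts by half a
  cell under any per-corner rule (the boundary column's corners are
  claimed entirely by one side);
* the medial circle $\varphi = \pi/6$ falls exactly mid-cell at the
  default resolutions, so whole-cell region assignment quantizes the Med
  radius by half a cell either way;
* azimuths that round to $360^\circ$ must wrap to sector one, and grid
  columns exactly on a $72^\circ$ boundary need a tie tolerance
  ($10^{-7}$ degrees) to land on their inclusive side.

The final rule therefore integrates the *bilinear interpolant* of the
corner mask over each region's exact share of the cell rectangle: in
$(\varphi, \theta)$ cell coordinates the Med boundary is a horizontal
line and sector boundaries are vertical lines, so the integrals are
closed-form and cheap. Inside a region this reduces exactly to $k/4$, and
summed over regions it reproduces the global masked area exactly — region
areas partition by construction. Residual error is the irreducible one: a
defect edge crossing a cell interior can only be located to within that
cell, i.e. roughly $\pm$half a cell, which at $100\times100$ is about
$\pm 2$ ratio points for a $72^\circ$ sector. That is the resolution
limit a fixed $100\times100$ map carries, and the scale against which the
oracle-agreement checks are set.

## The phantom: what it emulates, what it does not

`make_phantom()` builds a hemispherical cup shell — inner (cavity) radius
25 mm and 4 mm shell thickness, plausible adult acetabular dimensions —
capped by a flat rim annulus, with landmarks placed so the truth axes are
coordinate-aligned, plus an optional rigid motion into a general frame.
Tessellation is a structured polar grid rather than an icosphere: the rim
is then an exact circle and wedge/cap defects deleted by face centroid
have analytically known extents, so expected ratios are closed-form.
Two details of the tessellation are deliberate: mesh meridians sit half a
facet off the ray-grid columns (a ray through a mesh vertex is a
degenerate intersection, numerically fragile under rigid motion), and
quad diagonals alternate, so ragged defect edges after face deletion
carry no directional bias. Defects are implemented by face deletion (cut
walls absent, matching the radial-ray expectation exactly) and radial
vertex displacement for erosions. Presets: `identity`, `wedge25`,
`perforation` (medial hole coinciding with the Med cap), `erosion3`,
`needlehead` (a detached strip beyond the rim emulating rays slipping
through the obturator foramen onto the pubic ramus), `combined`.

What passing the phantom suite does **not** show: real CT meshes have
hundreds of thousands of faces, segmentation noise, metal scatter
artifacts near failed implants, and anatomically irregular rims; the
reconstruction itself carries millimeter-scale uncertainty in center and
radius. Phantom validation establishes that the geometry pipeline
computes the defined quantity correctly, not that the quantity is robust
to those upstream errors; the fitted sphere RMS residual and run-log
warnings are the per-case diagnostics for that.

## The independent oracle

`oracle_ratio()` recomputes ratios along a path sharing no code with the
pipeline: directions built inline from the phantom truth frame (not the
fitted one), the exhaustive-loop caster, strict all-corner cell
membership on per-point labels, its own shoelace summation, at
$400 \times 400$. Agreement within 2 ratio points, globally and per
region, over all six presets is asserted in the acceptance tests. The two
estimators are *different* discretizations — fractional/bilinear at
$100\times100$ against all-corner at $400\times400$ — so their gap also
bounds the discretization error a user should attribute to reported
ratios.

## Parameters that matter

| parameter | default | unit | rationale |
|---|---|---|---|
| `grid_size` | 100 × 100 | — | fixed sampling for comparability; maps and ratios are defined on it |
| `color_max` | 10 | mm | deviations at/above clamp to dark red; fixed range keeps graphs comparable |
| vertex merge tol | 1e-6 | mm | STL stores triangles independently; rebuilds connectivity |
| zero-area threshold | 1e-12 | mm² | drops degenerate facets |
| ray ε | 1e-6 | mm | minimum accepted hit distance; origin-on-surface guard |
| `sector_offset` | 0 | deg | anterior direction on the AntSup/AntInf boundary; configurable since the sector phase is a convention |
| `cell_rule` | fractional | — | converging area estimator; `all` for sensitivity |
| `metric` | planar | — | ratio defined on the projected plane; `spherical` opt-in |

Med membership is boundary-inclusive ($\sin\varphi \le 0.5$ within
$10^{-9}$) and restricted to the medial side $\varphi \le \pi/2$; the
lateral cap keeps sector labels, and the lateral pole, where the in-plane
projection vanishes, falls in the $\psi = 0$ sector by convention
(measure zero either way).

## Degenerate inputs and failure modes

Fewer than 4 non-coplanar sphere points, fewer than 3 non-collinear rim
points, missing or coincident landmarks, and an anterior axis within 1°
of the acetabular axis are hard errors. A region with $A_{rec} = 0$ is
reported not-assessable (`NA`) without affecting the others;
$A_{rec} = 0$ globally is an error. A deficient mesh may validly contain
zero faces (total loss; the ratio is then 100% by computation, not by a
special case).

## Problem sizes used in the checks

Unit tests run phantoms at tessellation level 2 (~2,300 faces) on grids
up to $100\times100$; acceptance checks use the default level 3 (~9,400
faces), the fixed $100\times100$ pipeline grid, $400\times400$ for the
dense oracle and the projection/region convergence laws, and 500-point
noisy sphere fits. These sizes were chosen so the full suite exercises
every law at resolutions where the analytic limits are already tight.

## Known limitations

Radial first-hit distances are not signed and are not closest-point
distances; volumetric loss is out of scope. Multiple shell crossings
(e.g. a ray re-entering through the obturator foramen) keep only the
first hit per mesh, which is what produces the needle-head strip rather
than an error. The user-outlined rim drives both the axis and the
subregion layout, so outlining variability propagates into regional
ratios; automating rim and landmark detection is outside this package.
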