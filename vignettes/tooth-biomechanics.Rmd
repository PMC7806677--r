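---
title: "Methods: plane-strain finite element biomechanics of tooth outlines"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: plane-strain finite element biomechanics of tooth outlines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the model, its assumptions, the numerical choices
made in the implementation, and its limitations. Code chunks are shown but
not evaluated; the README contains an executed worked example, and
`scripts/acceptance.R` recomputes the headline results end to end.

## The mechanical model

Teeth are modelled as two-dimensional labial-view profiles under
**plane-strain linear elasticity**. The out-of-plane strain is zero, so the
out-of-plane stress is recovered as
$\sigma_{zz} = \nu(\sigma_{xx} + \sigma_{yy})$, and the plane-strain
constitutive matrix

$$
D = \frac{E}{(1+\nu)(1-2\nu)}
\begin{pmatrix} 1-\nu & \nu & 0\\ \nu & 1-\nu & 0\\ 0 & 0 & \tfrac{1-2\nu}{2}\end{pmatrix}
$$

is used throughout. Elements are three-node (constant-strain) triangles;
each element stiffness is $K_e = A\,t\,B^{\mathsf T} D B$ with area $A$,
section thickness $t$ and the standard constant $B$ matrix. The global
sparse system is solved with a Cholesky factorization (`Matrix`/CHOLMOD)
after eliminating the constrained degrees of freedom.

**Units.** Geometry is in mm, forces in N; Young's modulus is supplied in Pa
and held internally in MPa (N/mm^2), so all stresses come out in MPa.

**Material defaults** (`material()`): osteodentine with $E = 28.44$ GPa,
$\nu = 0.3$, and a unit section thickness $t = 1$ mm. These are the study
conditions; they are arguments, not constants.

**Boundary conditions.** The root node set (every node at or below the
crown/root boundary $y$) is fixed in both translations. `fe_solve()` also
accepts per-direction constraints (`list(ux = ..., uy = ...)`), which the
benchmark suite uses for symmetry conditions.

**Failure/comparison metric.** Von Mises equivalent stress
$\sigma_{vM} = \sqrt{\tfrac12[(\sigma_{xx}-\sigma_{yy})^2 +
(\sigma_{yy}-\sigma_{zz})^2 + (\sigma_{zz}-\sigma_{xx})^2] + 3\sigma_{xy}^2}$,
summarised across a model by the mesh-weighted arithmetic mean
$\mathrm{MWAM} = \sum_i \sigma_i A_i / \sum_i A_i$, which is insensitive to
non-uniform element sizes.

## Loading scenarios

Two load cases (`build_load_case()`):

- **Puncture**: the total force at the single apex node, direction
  $(0, -1)$ (apicobasal).
- **Draw**: a horizontal force distributed over the nodes of one crown
  cutting edge. The default edge is the **distal** one with pull direction
  $(-1, 0)$; `edge = "mesial"` switches to the opposite edge and direction.
  The draw direction is a design choice: a unidirectional draw engages one
  edge at a time, and with the package's orientation convention (mesial at
  small $x$, distal at large $x$, apex offset towards distal in recurved
  crowns) the distal edge is the natural default for recurved laterals.
  Both options are exposed.

Force magnitudes come from two regimes:

- **Life-size**: the allometry $F = F_{\mathrm{ref}} (M / 240\,
  \mathrm{kg})^{0.67}$, anchored at 1602 N (anterior) / 3131 N (posterior)
  for a 240 kg reference macropredator; the lateral position takes the mean
  of the two (third-class lever: bite force rises towards the jaw joint).
- **Surface-area-scaled**: $F = F_{\mathrm{ref}} \cdot A / A_{\mathrm{ref}}$,
  holding the force-to-surface-area ratio constant across models
  (references: 49,051 N puncture, 500 N draw on the reference anterior
  tooth), so stress differences reflect shape only.

```{r load-case-example}
lc <- build_load_case("draw", mesh, 500, edge = "distal")
```

By default the total force is divided equally over the loaded nodes;
`distribution = "consistent"` instead weights each node by the half-lengths
of its incident boundary segments — the work-equivalent loading of a uniform
edge traction, which the analytic benchmarks (patch test, cantilever) need.

## Synthetic geometry: what the generator emulates

`generate_outline()` builds a closed, counter-clockwise, simple polygon from
a `tooth_spec()`: crown height and basal width, apex offset fraction
(0.5 = symmetric, smaller values shift the apex distally, i.e. recurved),
quadratic inward edge curvature, optional lateral cusplets (height/width as
crown fractions), and a rectangular root block of given depth and width.
Landmarked vertex spans (mesial/distal edges, cusplets) and the apex index
are carried on the object, and the crown/root boundary sits at $y = 0$.

The shipped presets (`otodontid_species()`, `otodontid_tooth_presets()`)
are **illustrative**: they emulate the otodontid morphological gradient
(older species: tall, narrow, cuspleted crowns; younger: broad triangular
cusplet-free crowns; recurvature increasing towards lateral/posterior
positions, gigantism through time) but are *not* digitized fossil outlines,
and the body masses and stratigraphic ranges are round configuration
values. Real outlines can be supplied via `read_outline_xy()` (CSV of x, y
vertices plus the crown/root $y$), which normalizes orientation, drops an
explicit closing vertex, and rejects self-intersecting input.

## Meshing and numerical choices

`triangulate()` is a from-scratch constrained Delaunay triangulator (C++):

- **Element-count targeting** uses the Euler relation $T = 2I + B - 2$
  (T triangles, I interior points, B boundary points) to choose a lattice
  spacing, iterating once or twice; counts land within a few percent of the
  target (tests allow 15%).
- **Boundary resampling keeps every original vertex**, only inserting
  subdivision points, so the polygon (and its area) is preserved exactly;
  the summed element area equals the shoelace polygon area to relative
  1e-9 or better.
- **Interior points** come from a hexagonal lattice, jittered by a
  deterministic coordinate-hash (no RNG anywhere in meshing: identical
  inputs give identical meshes, which makes convergence numbers exactly
  reproducible), with a clearance band of 0.62 lattice spacings from the
  boundary to avoid slivers.
- **Floating-point predicates** (orientation, in-circle) use relative-error
  filters; degenerate (zero or negative area) triangles are repaired during
  incremental insertion, and the acceptance of a mesh requires all element
  areas strictly positive.
- **Tie-breaks** are deterministic: the apex node is the boundary node of
  maximum $y$, ties broken towards larger $x$ (the distal side). Node-set
  membership on edges uses a distance-to-polyline tolerance of 1e-6 mm; the
  root set uses $y \le y_{\mathrm{root}} + 10^{-9}$.

**The apex point load is singular.** A point force on a linear-elastic
continuum produces unbounded stress as the mesh refines, so the *maximum*
von Mises stress under puncture is mesh-dependent and is only meaningful at
a stated resolution (the study uses ~35,000 elements; element counts are
recorded alongside every maximum). The MWAM, by contrast, is
mesh-converged: `convergence_study()` shows relative changes below 2%
between ~16,000 and ~32,000 elements for the draw case used in the
comparative analysis.

## Problem sizes

- Comparative study: 15 models (5 chronospecies × 3 positions) at a 35,000
  element target (~18,000 nodes each), three load cases per model.
- Verification: patch test at a few hundred elements (exact regardless of
  resolution), Timoshenko cantilever at 20,000 elements (within 5% of the
  shear-corrected beam deflection), MWAM convergence at 16,000/32,000.
- Trend tests: 10,000 age-resampled Pearson correlations per
  (position × scaled scenario); ages drawn uniformly within each species'
  chronostratigraphic interval under an isolated, seeded RNG stream
  (the global `.Random.seed` is saved and restored).

## Statistical design choices

Pearson's $r$ between MWAM and resampled age is converted to a two-sided
$p$ via the $t$ transform with $n - 2$ degrees of freedom; perfectly
collinear draws return $p = 0$. Because ages are in Mya, "stress increasing
towards the present" is $r < 0$. Zero-width stratigraphic ranges are
honoured (the replicate distribution collapses to a point), and fully
overlapping ranges give exchangeable ages, hence $E[r] = 0$ — both regimes
are asserted in the test suite.

Edge-band versus central-band element classification (for the qualitative
stress-pattern checks in `crown_bands()`) selects crown elements whose
centroids fall in a mid-crown height window (default fractions 0.25–0.70,
between cusplets and apex) and splits them by distance-to-cutting-edge
quantiles (edge ≤ 0.25 quantile, central ≥ 0.55). These constants are
arguments; the qualitative results (draw loads the edges, puncture peaks at
the apex) are insensitive to moderate changes.

## Limitations

- 2D plane strain captures labial-view shape only; labiolingual curvature,
  out-of-plane loading and tooth oscillation are not modelled.
- Homogeneous, isotropic, linear material: no enameloid layer, no tissue
  heterogeneity, no damage or fracture mechanics.
- Serrations are far below the mesh scale and are not represented.
- The shipped presets are illustrative morphologies, so comparative numbers
  shipped with the package characterize the *method* on those shapes, not
  fossil taxa; supply digitized outlines for empirical work.
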