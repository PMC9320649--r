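---
title: "Phase-field optimal control for membrane force estimation: models, numerics and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase-field optimal control for membrane force estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(cellforce)
```

# The model

`cellforce` treats whole-cell tracking as a PDE-constrained inverse problem.
A migrating cell is described by a phase field $\phi(\bar x,\bar t)$ on the
unit square: $\phi\approx +1$ in the cell bulk, $-1$ in the extracellular
matrix, and the zero level set is the membrane, smeared over a diffuse
interface of width $\sim\bar\epsilon$. The forward model is the forced,
volume-constrained Allen–Cahn equation

$$\bar\epsilon\bar\tau\,\partial_{\bar t}\phi
 = \bar\delta\bar\epsilon\,\Delta\phi
 - \frac{\bar\delta}{\bar\epsilon}\,G'(\phi)
 + \bar\eta(\bar x,\bar t) + \lambda(\bar t),$$

with homogeneous Neumann boundary conditions and the quartic double well
$G(\phi)=\frac14(1-\phi^2)^2$. Its sharp-interface limit is forced mean
curvature flow: the membrane moves with normal velocity
$\bar\tau V = -\bar\delta\kappa + \bar\eta + \lambda$. The terms have direct
mechanical readings: $\bar\delta$ penalises membrane length (surface
tension), $\bar\tau$ is friction against the substrate/matrix, $\bar\eta$
is the force line-density the cell generates at its membrane (positive =
protrusion, negative = retraction), and $\lambda(\bar t)$ is a spatially
constant multiplier that pins the mass $\int\phi$ to a prescribed schedule.
The mass schedule interpolates the *observed* cell areas of the bounding
frames linearly, so it is a data-tracking constraint, not conservation —
segmented areas genuinely change from frame to frame.

Assumptions worth keeping in mind: forces act only in a thin band around the
membrane (the actin cortex); the cell is effectively two-dimensional with a
nominal constant height of 0.1 µm; traction forces transmitted through the
substrate are not modelled; and $\delta$, $\tau$, $\epsilon$ are fixed
inputs, not fitted.

## Units and scaling

Dimensional parameters (Table-style configuration) map onto the unit model
through the characteristic length $L$ (domain side, µm), time $T$ (duration
of the tracked stretch, s) and force $F$ (pN):

$$\bar\epsilon=\epsilon/L,\quad \bar\delta=\delta/F,\quad
  \bar\tau=\tau L^2/(F\,T),\quad \bar\eta=\eta\,L/F .$$

Defaults are $\delta = F = 10$ pN (so $\bar\delta=1$, the top of the
plausible 1–10 pN surface-tension range) and $\tau=2.62$ pN s/µm².
The *numerical* interfacial width $\bar\epsilon$ is a per-dataset
configuration value and deliberately overrides the physical ratio
$\epsilon/L$: resolving a 1 µm membrane inside a 220 µm field of view would
need an extreme grid, and the estimated forces live on the interface, not in
its physical thickness. A fitted $\bar\eta$ converts back to pN/µm as
$\eta = \bar\eta F/L$ (`redimensionalizeForce()`), and a line integral of
$\eta$ along the membrane (µm) yields pN.

# The objective and its exact discrete gradient

For observation fields $\phi_{obs,i}$ at times $\bar t_i$ the control
problem minimises

$$J(\eta;\phi)=\frac{\theta}{2}\int_0^1\!\!\int_{\bar\Omega}\bar\eta^2
 + \frac12\sum_i\int_{\bar\Omega}(\phi(\bar t_i)-\phi_{obs,i})^2 ,$$

with $\theta>0$ a regularisation weight required for well-posedness.
The package follows a strict **discretise-then-optimise** policy: the
gradient is the adjoint of the *actual discrete forward map*, including the
transposed mean-projection of the volume constraint. The payoff is
testability — the adjoint gradient agrees with central finite differences of
the discrete objective to relative error $\sim 10^{-9}$, and that check is
the central correctness oracle of the test suite. An optimise-then-
discretise adjoint would be equally consistent as $h\to 0$ but cannot be
verified to machine precision at finite $h$.

First-order optimality reads $\theta\bar\eta + p = 0$ on the force band,
where $p$ is the (rescaled) adjoint state; `solveAdjoint()` returns exactly
that $p$, and `controlGradient()` assembles $g=\theta\bar\eta+p$ restricted
to the band.

## Optimiser

Projected gradient descent with Armijo backtracking, started from
$\bar\eta=0$:

* control parameterisation: piecewise constant over the `RTS` reconstructed
  time steps of a frame pair, nodal in space;
* band: $\{|\phi^n|<0.95\}$ of the *current* trajectory, recomputed every
  outer iteration — forces are only ever placed near the membrane;
* defaults: $\theta=10^{-3}$, `max_iter = 200`, Armijo constant $10^{-4}$,
  shrink 0.5, initial step 1, relative-decrease tolerance $10^{-6}$; all
  exposed;
* the accepted objective history is non-increasing by construction; a failed
  line search returns the best iterate flagged `converged = FALSE`.

Frame pairs are chained: the fitted final state of pair $i$ is the initial
state of pair $i{+}1$, so segmentation noise does not restart the shape and
the reconstruction stays a single continuous trajectory through the video.
$N$ frames yield $N{-}1$ pair results; the first frame only seeds the
initial condition.

# Discretisation

* **Grid.** Uniform, vertex-centred $n\times n$ nodes on $[0,1]^2$, spacing
  $h=1/(n-1)$, $\bar y$ increasing upward. A uniform serial grid keeps the
  adjoint exact and the implementation transparent; adaptive or multigrid
  solvers are out of scope.
* **Laplacian.** Five-point stencil with mirror ghost nodes, so constants
  are annihilated exactly on the boundary (compatible with the Neumann
  condition) and the stencil is exact on quadratics in the interior.
* **Time stepping.** Semi-implicit IMEX: the stiff Laplacian is implicit,
  $G'$ and $\bar\eta$ explicit. The implicit operator $I-\alpha\Delta_h$ is
  symmetrised by the trapezoid quadrature weights and factorised once per
  (grid, $\mathrm{d}t$) by sparse Cholesky (`Matrix`), cached; every step is
  then a pair of triangular solves.
* **Stability.** The explicit reaction limits the step to
  $\mathrm{d}t \lesssim \bar\epsilon^2\bar\tau/\bar\delta$. Each frame
  interval is divided into `RTS` reconstructed steps, each subdivided into
  `substeps` solver steps with $\mathrm{d}t = \mathrm{TI}/(T\cdot
  \mathrm{RTS}\cdot\mathrm{substeps})$. By default `substeps` is chosen
  automatically as the smallest integer satisfying a quarter of the bound
  (`substeps = NA`); dataset-scale configurations violate the bound badly at
  `substeps = 1`, so an automatic default is the safe choice. Benchmarks
  that need higher temporal accuracy (the shrinking circle below) use
  $\mathrm{d}t=\bar\epsilon^2/16$, since the splitting error in the
  interface velocity scales like $\mathrm{d}t\,\bar\delta/(\bar\epsilon^2
  \bar\tau)$.
* **Volume constraint.** $\lambda^n$ is applied as a post-step projection:
  after the implicit solve, the spatial constant that sets the quadrature
  mean of $\phi^{n+1}$ to the prescribed mass *exactly* (constants lie in
  the kernel of the Neumann Laplacian, so this is the exact discrete
  Lagrange multiplier). Mass tracking therefore holds to round-off
  ($<10^{-10}$) at every step, by construction.
* **Quadrature.** Trapezoidal nodal weights ($h\cdot(\frac12,1,\dots,1,
  \frac12)$ tensorised) for all spatial integrals: they integrate the unit
  square to exactly 1 (the unit-offset objective example evaluates to
  exactly $\frac12$) and make the projection/adjoint algebra exact. In
  time, a step sum times $\mathrm{d}t$.
* **Degenerate inputs.** An all-$(-1)$ field (no cell) is accepted and is a
  fixed point of the unforced dynamics; single-sign fields yield empty
  contours, an empty segmentation raises a structured "no cell" error naming
  the frame.

# Geometry outputs

**Contours and length.** The membrane is extracted by marching squares on
the bilinear interpolant (`grDevices::contourLines` at level 0); polylines
that do not touch the domain boundary are closed. Lengths converge at first
order in $h$ on tanh disks; a radius-0.25 circle is recovered to <1% at
$n=256$.

**Force summaries.** Per reconstructed step, $\bar\eta^n$ is sampled at the
segment midpoints of the contour of $\phi^n$ and its positive/negative parts
are integrated along the membrane; the dimensional total per pair is
$\sum_n \bar\eta\,F\,\ell$ (pN), summed over the pair's `RTS` steps, with
percentages computed on arclength (not node counts) and averaged uniformly
over steps. This accumulation is a package decision: it is dimensionally
consistent (pN/µm × µm) and puts totals for realistically sized cells in
the tens of nanonewtons. $\lambda$ is a global constant constraint force and
is deliberately excluded from the totals. Absolute magnitudes scale with
$1/\theta$ in the small-$\theta$ limit, so cross-dataset comparisons should
hold $\theta$ fixed.

**Euler number.** The topology of $\{\phi>0\}$ (number of cells = components
minus holes) is measured by a band integral of the curvature density,

$$N=\frac{1}{4\pi c}\int_{\{|\phi|<c\}}
 -\Delta\phi+\frac{\nabla|\nabla\phi|^2\cdot\nabla\phi}{2|\nabla\phi|^2}
 \,\mathrm{d}\bar x .$$

The normalisation follows from Gauss–Bonnet: on a radial tanh profile
$\psi(d)$ the integrand reduces to $\psi'(d)\,\kappa$, and integrating
$\psi'$ across the band $|\phi|<c$ gives total variation $2c$ per membrane
crossing, hence $2\pi\cdot 2c$ per boundary component; dividing by $4\pi c$
yields the Euler characteristic (a disk gives 1, an annulus 0). Derivatives
are central differences with mirror ghosts; nodes with
$|\nabla\phi|^2<10^{-12}\max|\nabla\phi|^2$ are excluded. The default band
level $c=0.8$ keeps the integration region inside the tanh transition at all
dataset interfacial widths while leaving enough nodes in the band; it is
exposed in the configuration. Rounded changes of the per-step trace flag
division/fusion events.

# Imaging front end

Segmentation combines Otsu thresholding with edge detection, all through
`EBImage`: Gaussian presmooth ($\sigma=1$ px), Otsu threshold (polarity
configurable), Sobel gradient magnitude thresholded at its 90th percentile
and morphologically closed with a 3 px disc, hole filling, and removal of
components below 50 px. The closed edge map is used to *close boundary gaps
before hole filling*; only its interior is kept, so the edge band itself
does not inflate the Otsu boundary (on clean synthetic disks the mask is
pixel-exact). These parameter values are package defaults, exposed in the
configuration. Multi-cell frames keep all surviving components in one phase
field; an optional crop box restricts the field of view.

Masks become phase fields via the signed Euclidean distance (half-pixel
corrected, positive inside), rescaled to dimensionless units, bilinearly
resampled to the solver grid and passed through the equilibrium profile
$\phi=\tanh(d/(\sqrt2\,\bar\epsilon))$. Image row 1 is the top of the image;
ingestion flips rows exactly once so that $\bar y$ increases upward in all
fields and plots.

# Synthetic data: what it emulates and what it does not

The generators produce segmented-movie stand-ins with exact ground truth:

* `makeTranslatingDiskMovie()` — a rigidly translating cell, rendered
  bright-on-dark (foreground 0.8, background 0.2, Gaussian noise sd 0.05,
  8-bit quantisation — levels Otsu separates robustly). Displacements are
  snapped to the pixel lattice so all masks are exact translates.
* `makeDivisionMovie()` — two disks whose centres separate linearly,
  pinching one blob into two; the first disjoint frame is recorded. The
  default schedule (radius 0.12, separations 0.06→0.54 over 5 frames) jumps
  across tangency so no frame sits in the topologically ambiguous
  near-touching regime.
* `makeInverseCrimeDataset()` — observations generated by the package's own
  forward solver under a known forcing ("inverse crime"), the standard
  fixture on which the optimiser must reduce the misfit by orders of
  magnitude; `makeTranslationControl()` supplies a leading-edge/rear
  cosine-profile forcing with the sharp-interface amplitude
  $\bar\tau|v|$.

All generators are pure functions of (parameters, seed). What they do *not*
emulate: optical blur, uneven illumination, shot noise, textured cytoplasm,
deforming or touching cells. Passing tests on these fixtures therefore
validates the solver, the adjoint, the optimiser and the geometry pipeline —
not segmentation robustness on difficult real microscopy.

# Problem sizes used in validation

Chosen to exercise each property at meaningful resolution: the gradient
check runs on a $32^2$ grid with 5 steps and 10 random probes; the
shrinking-circle oracle ($R^2(\bar t)=R_0^2-2(\bar\delta/\bar\tau)\bar t$,
matched within 2% while $R>3\bar\epsilon$) on $256^2$ with
$\bar\epsilon=0.015$; inverse-crime recovery on $64^2$ with `RTS = 10`
(misfit reduced >100×, final centroid within one grid cell); Euler-number
checks on $256^2$ against a pixel-labelling components-minus-holes oracle on
20 seeded blob fields (blob radii 0.08–0.14, annuli only when the inner
circle stays ≥4$\bar\epsilon$, shapes separated by ≥6$\bar\epsilon$ — the
regime where a band integral can be expected to resolve topology).

# Known limitations

* Absolute force magnitudes depend on $\theta$; only relative spatial and
  temporal patterns are $\theta$-robust.
* The serial uniform-grid solver limits practical resolution to a few
  hundred nodes per side.
* One phase field for all cells: cell identities are not tracked through
  contact, and touching cells merge in the representation.
* Substrate traction is not modelled; reported forces are membrane forces
  under this model, not total cell–substrate forces.
* 2D only; the formulation extends to 3D but this implementation does not.
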