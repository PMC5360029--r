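---
title: "Methods: image-based computational hemodynamics for murine vessels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: image-based computational hemodynamics for murine vessels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## Scope and model

`avflow` reconstructs the lumen of a small vessel — the motivating geometry
is the murine arteriovenous fistula (AVF), a side(artery)-to-end(vein)
carotid–jugular anastomosis — from black-blood image stacks, and solves
pulsatile incompressible laminar Newtonian flow in it:

$$\rho\left(\frac{\partial \mathbf u}{\partial t}
  + \mathbf u\cdot\nabla\mathbf u\right)
  = -\nabla p + \mu\nabla^2\mathbf u,\qquad \nabla\cdot\mathbf u = 0,$$

with blood density $\rho = 1050\ \mathrm{kg/m^3}$, dynamic viscosity
$\mu = 0.0035\ \mathrm{Pa\,s}$, rigid immobile walls with no slip, a
prescribed pulsatile cross-section-averaged velocity at the inflow artery
(and optionally at prescribed outlets), and one traction-free (zero-stress)
outlet that absorbs the flow imbalance. Reynolds numbers in this regime are
3–60, so the laminar assumption holds; the 100 mmHg reference pressure is a
gauge offset only. From the solved fields the package computes wall shear
stress (WSS, $|\boldsymbol\tau_w|$), its spatial gradient
$\mathrm{WSSg} = \sqrt{(\partial_x\tau_{w,x})^2 + (\partial_y\tau_{w,y})^2
+ (\partial_z\tau_{w,z})^2}$, the oscillatory shear index
$\mathrm{OSI} = \tfrac12\left(1 - |\int\boldsymbol\tau_w\,dt| /
\int|\boldsymbol\tau_w|\,dt\right)$, vorticity
$\boldsymbol\Omega=\nabla\times\mathbf u$, helicity density
$\mathbf u\cdot\boldsymbol\Omega$ (with its volume integral), and the
Q-criterion $Q=\tfrac12(\lVert W\rVert_F^2-\lVert S\rVert_F^2)$.

Three definitional choices deserve emphasis because the conventions in the
field vary:

* **WSS** is the Euclidean magnitude of the wall shear vector (the formula),
  not a root-mean-square in time.
* **WSSg** uses only the three *diagonal*, axis-aligned derivative terms, as
  the defining formula is printed; this differs from the full
  surface-gradient tensor used elsewhere in the WSS-gradient literature, and
  each derivative is evaluated in the local tangent plane of the wall.
* **Q** uses squared Frobenius norms of the antisymmetric/symmetric velocity
  gradient parts (the standard Hunt criterion), which makes simple shear
  give exactly $Q = 0$: a vortex is rotation exceeding strain. The helicity
  figure convention is the *density* in $\mathrm{cm/s^2}$; the volume
  integral (in $\mathrm{cm^4/s^2}$) is reported alongside because the
  integral and the density have different units and the display convention
  matches the density.

Units: geometry in mm, solver in SI, reporting in cm/s, dyne/cm²
(= 0.1 Pa), dyne/cm³, 1/s, cm/s², 1/s².

## Synthetic phantoms: what they emulate, what they do not

No deposited in vivo images exist for this problem, so the package's inputs
are synthetic black-blood stacks of analytic vessel phantoms
(`generate_phantom_image()`): dark lumen (mean 20), bright tissue (mean
100), additive Gaussian noise, default 0.1 mm in-plane and 0.5 mm slice
spacing. Defaults of `avf_phantom_spec()` encode the study conditions:
control artery and vein radii sized so that the lumen areas are
0.29 mm² and 1.55 mm² (the control-vessel calibration used for the area
pipeline), a 90° anastomosis, a venous bulge of amplitude 1.5 peaking 1 mm
downstream of the anastomosis (venous dilation is largest about 1 mm from
the junction and is heterogeneous), and a side branch taking off 4.5 mm
downstream — which is also why segment averages use the first 4 mm. The
image grid is deliberately offset from the phantom symmetry axes by a fixed
sub-voxel shift: scanner lattices are never aligned with the vessel, and
exact alignment is a degenerate worst case for quantization.

The phantoms emulate intensity separation, partial-volume-free binary
contrast and anisotropic voxels. They do **not** emulate intensity
inhomogeneity, motion or flow artifacts, wall signal variation, or partial
volume averaging — so passing tests demonstrate correctness of the
reconstruction and flow machinery, not robustness to real scanner
artifacts.

## Geometry pipeline

Segmentation is seeded intensity thresholding: the 26-connected component
of voxels at or below the threshold containing the seed — the deterministic,
scriptable equivalent of interactive region-grow thresholding. Surfaces are
extracted by marching tetrahedra (each grid cube split into the six Kuhn
tetrahedra, which is conforming and therefore watertight by construction) on
the signed Euclidean distance field of the mask, whose zero level sits
midway between inside and outside voxel centers; a few passes of
low-shrinkage (Taubin) vertex relaxation remove the lattice ripple (volume
drift well under 1%; `relax_iterations = 0` returns the raw staircase
isosurface). `smooth_surface()` exposes the same two-step $\lambda/\mu$
relaxation with a 2% volume-drift contract — the interactive smoothing it
replaces publishes no parameters, so the volume bound is this package's own
contract.

Volume meshes are the hexahedral-voxel dialect: the watertight surface is
rasterized at a chosen cubic edge length and every cell whose center lies
inside becomes a fluid cell; boundary faces inherit opening labels from the
surface's cap patches (stored as a JSON sidecar next to STL files, which
carry no labels themselves) and everything else is `wall`. A tetrahedral
dialect was deliberately not implemented: no tetrahedral mesher is available
in the supporting stack, and a structured voxel mesh admits a much faster
matrix-free solver; the discretization family is recorded in the mesh
metadata. Reference meshes at scanner scale run to millions of cells;
desk-scale meshes here use $10^3$–$10^5$ cells, with adequacy established by
the <5% independence protocol rather than any absolute count. Graded
boundary-layer meshing is likewise replaced by the independence study: on a
voxel lattice the near-wall resolution is set by the edge length, and the
wall-shear evaluation (below) recovers the near-wall profile by fitting
rather than by sub-layer cells.

Centerlines follow the maximal-inscribed-sphere idea: an interior
distance-to-wall field is computed on a voxelization of the lumen, a
shortest path between opening centroids is found under an edge cost
$\ell / d_{\mathrm{wall}}^2$ (so the path hugs the deep interior), and the
polyline is smoothed, resampled at 0.1 mm arclength, and refined twice by
moving each sample to the centroid of its perpendicular cross-section. The
anastomosis anchor ($s = 0$) is the common branch point of the
junction paths; on single-branch geometries it is the first opening.
Cross-sectional areas are polygon areas of the connected plane–surface
intersection loop containing the centerline point (a winding-number test in
the cutting plane selects the right loop when the plane also cuts other
branches); samples whose plane yields no enclosing loop — typically at the
open ends — are dropped and counted. Areas are reported in both µm² and mm².

## Waveforms and boundary conditions

Waveforms hold per-cardiac-frame cross-section-averaged velocities (default
8 frames at 16 ms) and are resampled by periodic cubic splines. The native
period of the default acquisition is 8 × 16 = 128 ms while the murine
cardiac cycle is nearer 120 ms; both statements are honored by keeping the
frame-derived period as the default and providing a `period_ms` override
(120 ms at a 0.1 ms step reproduces the canonical ~1200 steps per cycle).
The inlet profile shape is parabolic by default — at Womersley number
$\alpha\approx2$ quasi-steady profiles are a reasonable assumption, and the
source protocol does not state a shape — with `plug` available for
sensitivity checks. Prescribed per-face velocities are renormalized so the
discrete flux equals the mean velocity times the (projected) patch area to
machine precision. Because velocities are prescribed at the inlet *and*
possibly two outlets, the configuration is validated up front: prescribed
outlet fluxes must stay strictly below the inlet flux at every instant,
otherwise the zero-stress outlet would have to supply flow and the
incompressible problem is over-prescribed.

## Flow solver

Cell-centered collocated finite volumes on the voxel mesh with Rhie–Chow
momentum interpolation and SIMPLE pressure–velocity coupling; convection is
second-order upwind via deferred correction over a first-order upwind
matrix, diffusion is second-order central, and time integration is implicit
BDF2 (backward Euler for the first step, with a linear predictor as the
initial guess thereafter). Implementation choices that matter:

* Momentum systems are solved matrix-free (Jacobi-preconditioned BiCGSTAB
  on the 7-point stencil). The pressure-correction matrix is constant in
  time by construction and factorized once per run with a sparse Cholesky.
* Transient stepping uses SIMPLEC-consistent correction coefficients
  $d = V/(a_P - \sum a_N)$ — for the time-dominated diagonal these reduce to
  the constant $\Delta t/(1.5\rho)$ plus boundary terms — with relaxation
  1.0 (velocity) / 0.8 (pressure). Steady solves use classic SIMPLE
  under-relaxation 0.7 / 0.3 (the conventional defaults; the source
  protocol does not state its factors).
* The Rhie–Chow face dissipation uses the transient-consistent pair
  $d_{rc} = V/a_P$ with memory coefficient $\beta$ equal to the time-term
  fraction of $a_P$, so the *effective* steady dissipation
  $d_{rc}/(1-\beta)$ is the diffusion-based, time-step-independent value.
  Without this the periodic solution inherits an $O(\Delta t)$ dependence
  through the face dissipation and the observed temporal order degrades to
  one; with it the solver shows second-order behavior in $\Delta t$ and its
  pulsatile steady limit coincides with the steady solver's solution.
* Convergence per step: scaled x-, y-, z-momentum residuals and the
  continuity residual must fall below $10^{-5}$ (both tolerances
  configurable), with at most 50 inner iterations; non-converged steps are
  flagged. Residual scales include a momentum-flux floor so quiescent
  cross-stream components are not judged by a noise-dominated ratio.
* Initial condition: zero velocity at gauge pressure; three cardiac cycles
  are run and results reported from the third, the first two acting as
  washout (the cycle-3 versus cycle-2 velocity difference is logged and is
  below 1% on all phantom cases, machine-level for the tube benchmarks).

Validation oracles: steady Poiseuille flow (centerline velocity $2U$,
wall shear $4\mu U/R = 28\ \mathrm{dyne/cm^2}$ for $R = 0.5$ mm and
$U = 0.1$ m/s, both within 5%), and the analytic Womersley solution for
oscillatory tube flow at $\alpha \approx 1.98$ (RMS profile error below 5%
at mid-tube on a 2,400-cell desk mesh; the complex Bessel functions are
evaluated by power series, ample for the murine $\alpha$ range).

## Wall metrics on a voxel boundary

A naive evaluation of wall shear on staircase faces is biased low by a
factor approaching $\pi/4$ on a circular cross-section, because axis-aligned
face normals misrepresent the true wall direction. The package therefore
computes, per wall face, a smooth outward normal from the gradient of the
signed distance field of the fluid region, and fits — over the nearby fluid
cells, using their wall distances $s$ from the same field — the constrained
quadratic $u(s) = a s + b s^2$ per velocity component. The wall shear vector
is $\mu$ times the tangential part of $a$; for fully developed tube flow the
fit is exact, and the steady benchmark reproduces $4\mu U/R$ within a
fraction of a percent. With `assume_noslip = FALSE` the traction is instead
evaluated from the full symmetric gradient at the adjacent cell (exact for
linear fields; rigid-body rotation yields zero shear). Cell gradients for
the volumetric metrics use a per-axis quadratic-through-origin least-squares
reconstruction over first and second neighbors: exact for fields quadratic
along each axis (hence pointwise-exact Poiseuille vorticity) and a fortiori
for linear fields.

OSI integrates the stored shear series with trapezoid weights over exactly
one cycle and is clamped to $[0, 0.5]$; faces with identically zero shear
get OSI 0. Systole and diastole are operationalized as the argmax/argmin of
the resampled inlet waveform — the source material does not define the
timing operationally. Segment averages are area-weighted over wall faces
whose projection onto the chosen centerline branch falls within the 4-mm
window anchored at the anastomosis.

## Independence protocols

`mesh_independence_study()` and `timestep_independence_study()` run at
least three levels (edge factors 2/1/0.5, or dt factors 1/0.5/0.25),
monitor the 4-mm segment-averaged cycle-averaged WSS and the domain peak
velocity — the headline outputs; the protocol's source does not name its
monitored scalar — and report symmetric relative differences
$|a-b|/\big((|a|+|b|)/2\big)$ in percent. Results are independent when the
finest consecutive pair differs by less than 5%, and the accepted
configuration is the coarser member of that pair. The desk-scale ladders
reproduce the protocol, not the absolute scanner-scale level values.

## Problem sizes and numerical parameters

Default desk-scale benchmarks: tube phantoms of radius 0.5–0.7 mm and
length 2–5 mm; meshes of roughly 500–4,000 cells (up to ~19,000 in the
finest checks); 0.25–1 ms time steps over 120 ms cycles, three cycles. Key
tolerances: residuals $10^{-5}$; inner linear solves to $10^{-7}$ relative;
smoothing volume drift ≤ 2%; marching-tetrahedra vertex weld at $10^{-7}$
of the domain extent. Degenerate inputs are handled explicitly: empty
segmentations, masks touching the grid boundary (pad first), surfaces
without labeled openings, isosurface levels never crossed (empty surface)
or everywhere equal to the field (flagged), averaging windows outside the
profile extent, and over-prescribed outlet fluxes are all typed errors or
warnings rather than crashes.

## Known limitations

Rigid walls, Newtonian rheology and laminar flow by design. The voxel
discretization resolves curved walls to first order in the edge length, so
very coarse meshes (fewer than ~3 cells per radius) are below the useful
range; the pressure field is validated only through its role in the
velocity solution. Image phantoms lack realistic artifact models. The
centerline is defined for tree-like (non-looping) lumens. The CLI under
`inst/cli/avflow.R` is a thin wrapper over the documented functions —
the package API is the primary interface.
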