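---
title: "Simulating transcranial current stimulation on layered-sphere head phantoms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating transcranial current stimulation on layered-sphere head phantoms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The physical model

Transcranial direct current stimulation (tDCS) drives a weak current
(typically 1 mA) between two saline-soaked scalp patches. At these
frequencies capacitive and inductive effects are negligible, so the
quasistatic approximation of Maxwell's equations reduces the problem to a
generalized Laplace equation for the electric potential $\Phi$ in the head
volume $\Omega$:

$$\nabla \cdot (\sigma \nabla \Phi) = 0 \quad \text{in } \Omega,$$

with inhomogeneous Neumann boundary conditions on the surface: the normal
current density equals the injected density on the anode patch, its
negative on the cathode patch, and zero elsewhere. $\sigma$ is the 3×3
conductivity tensor field. The current density follows as
$J = -\sigma \nabla \Phi$ (we use the physically signed form, so current
flows from anode to cathode; magnitudes are unaffected by the sign
convention), and the electric field as $E = J/\sigma$, reported in uV/mm
(1 V/m = 1000 uV/mm). At the gray-matter conductivity of 0.24 S/m a
current density of 0.1 A/m² corresponds to 417 uV/mm.

Because the problem is linear in the injected current, doubling the total
current exactly doubles $\Phi$ and $J$ everywhere, and swapping anode and
cathode negates both. A sinusoidal stimulation current (tACS) simply
rescales the DC field at every instant, flipping its direction by 180°
each half-wave; `tacs_waveform_view()` implements exactly this.

## The head phantom

Individual MRI-derived head models are subject-specific and not generally
available, so the package generates voxelized layered-sphere phantoms with
the six standard tissue compartments. The default shells (outer radii in
mm) are: white matter 64, gray matter 71, CSF 74, skull compacta 76,
skull spongiosa 79, skull compacta 81, skin 86. This realizes the
three-layer skull sandwich (compacta–spongiosa–compacta) and a CSF layer
between skull and brain, the two features that dominate current routing.
The skull-layer thicknesses are a modeling choice; the literature we
follow does not state them, and all radii are configurable.

Conductivities (S/m) follow the standard literature values: skin 0.43,
skull compacta 0.007, skull spongiosa 0.025, CSF 1.79, and electrode
saline 1.4. Gray and white matter default to 0.24 and 0.19 S/m, which are
also the targets of the anisotropic effective-medium calibration below.

Two optional features emulate anatomy that matters for the field pattern:

* **Gyral ridges** — meridional sectors in which CSF is replaced by gray
  matter, so GM locally protrudes through the CSF shell (default 8
  ridges, 6° half-width, full CSF thickness). Real gyri that protrude
  into well-conducting CSF receive the strongest cortical current
  densities, and the ridges reproduce that mechanism. A ridge azimuth
  window (e.g. `azim_range = c(135, 225)`) restricts ridges to, say, the
  occipital midline, emulating the gyri adjacent to the interhemispheric
  cleft. Note that on the *plain* concentric phantom an antipodal midline
  montage (FPz/Oz analog) is exactly mirror-symmetric, so the frontal and
  occipital peaks tie to solver precision; a front–back asymmetry such as
  posterior ridges is required before one side can genuinely dominate.
* **White-matter anisotropy** — a diffusion-like SPD tensor per WM voxel
  with a prescribed longitudinal:transverse eigenvalue ratio and a radial
  or tangential principal direction. Tensor magnitudes are arbitrary by
  construction, because conductivity scaling renormalizes them (below).

Electrode patches (default 7 cm × 5 cm × 4 mm, 1.4 S/m) are placed as
geodesic rectangles centred on 10–20-analog positions, long axis along
the local azimuthal direction, occupying background voxels radially above
the skin staircase surface. The supported positions put the vertex Cz at
inclination 0° and the outer ring (FPz, Oz, F7, F8, P7, P8) at 90°, with
azimuths from the nasion at equal-arc spacing (FPz 0°, Oz 180°, F7/F8
∓54°, P7/P8 ∓126°).

## Meshing and conductivity assignment

Each non-background voxel becomes one trilinear hexahedral element
(shared nodes, coordinates in meters, deterministic ordering). A single
geometry-adaptation pass then shifts every node that touches a material
interface or the outer boundary toward the centroid of its incident
inter-label face centres, clamped to `shift_factor` × voxel size
(default 0.33, a conventional safe bound against element inversion).
This softens the voxel staircase while provably keeping all Jacobians
positive — the package validates every element at all 2×2×2 Gauss points
and reports offenders by element index. One pass conserves bulk volume to
well under 5 % and preserves mesh connectivity.

Isotropic tissues receive $\sigma = \sigma_{\text{tissue}} I$. Where a
tensor field is supplied, each element's diffusion-like tensor $D$ is
converted by the volume-normalized effective-medium rule: the
conductivity tensor shares the eigenvectors of $D$ and scales all its
eigenvalues by the single factor that makes
$(\det \sigma)^{1/3} = \sigma_{\text{iso,target}}$. Two properties follow
exactly: the anisotropy ratio of $D$ is preserved, and every WM element
satisfies the 0.19 S/m volume constraint to machine precision (the
package asserts $10^{-12}$). We chose the volume-normalized variant over
a linear scaling because the tissue-mean conductivities (0.24/0.19 S/m
for GM/WM) are then model properties rather than empirical outcomes.
With ratio 1 the anisotropic pipeline is numerically identical to the
isotropic one. GM anisotropy is off by default (the phantom supplies WM
tensors only) but the assignment honors any voxel set a tensor field
covers.

## Assembly and solution

The stiffness matrix is assembled isoparametrically with trilinear shape
functions and 2×2×2 Gauss quadrature — exact for trilinear elements with
constant per-element $\sigma$ — in deterministic element order. The
electrode load applies a uniform normal current density over each
patch's exposed boundary faces, lumped to nodes by quarter-face areas and
normalized so anode loads sum to $+I$ and cathode loads to $-I$; the
saline patch volume then distributes the current onto the scalp, as in a
volumetric electrode model. The pure-Neumann operator is singular with
the constant vector as null space, so the load's zero sum is a
compatibility condition (checked to $10^{-12}$ relative) and the
potential is reported in the zero-mean gauge, which treats both
electrodes symmetrically.

Two solvers are provided:

* `"cg"` (default): conjugate gradients with a Jacobi preconditioner,
  run directly on the consistent semidefinite system, with the constant
  mode projected out periodically. Default relative residual tolerance
  $10^{-9}$, iteration cap 10 000. On the 2 mm default phantom
  (~3.4 × 10⁵ unknowns) convergence takes a few hundred iterations and a
  few seconds; the diagonal scaling absorbs most of the 1.79 : 0.007
  tissue contrast.
* `"direct"`: CHOLMOD supernodal Cholesky of the system grounded by
  adding a conductance at one node — because the load sums to zero, the
  grounded system's solution is exactly a solution of the singular one —
  followed by re-gauging. Useful when many loads share one matrix.

The two paths agree to ~10⁻¹² on test problems and both report
`solver_info` (iterations, final relative residual, unknown count).
$J = -\sigma \nabla \Phi$ is evaluated at element centroids from the
isoparametric gradients; trilinear elements reproduce linear potentials
exactly, which the Ohm's-law bar test exploits at $10^{-8}$ tolerance.

Discrete conservation is checked with `flux_through_surface()`, which sums
face-averaged $J \cdot n$ over the boundary of any element set. Two
complementary checks follow from the divergence theorem: a closed
mid-skull sphere encloses neither electrode and must carry zero net flux
(measured ~10⁻¹⁵ A), while any surface separating the anode from the
cathode — e.g. the mid-plane between an antipodal pair — must carry the
full injected current (measured within 0.1 % of 1 mA at 2 mm).

## The analytic oracle

Correctness of the solver chain is measured against an independent
analytic solution: the zonal-harmonic series for a point current source
and sink on the outer surface of concentric conductive layers. Per degree
$n$ the radial profile in layer $k$ is
$A_k (r/R)^n + B_k (R/r)^{n+1}$, with coefficients propagated outward by
2×2 interface conditions (continuity of $\Phi$ and of
$\sigma\, r\, \partial\Phi/\partial r$) and normalized by the outer
Neumann condition. The innermost $B$ vanishes, and the implementation
skips that term rather than evaluating the overflowing negative power.
Default series length is 200 terms with a tail-magnitude diagnostic; the
series matches the homogeneous-sphere closed form to ~10⁻¹⁵ and
self-converges below 10⁻⁸ away from the electrodes.

FE-vs-oracle comparisons sample a mid-depth shell and exclude a 20° polar
cap around each electrode, where the point-source oracle and the
patch-electrode FE model legitimately differ; both fields are re-gauged
to zero mean over the sample before the relative L2 error is formed. On a
3-layer isotropic sphere with small (1 cm) patches the 2 mm mesh achieves
~2.5 % relative L2 potential error and the 4 mm mesh ~4.3 %, the
expected monotone convergence under refinement. Anisotropy has no
analytic counterpart here; it is validated through the exact
isotropy-limit equivalence instead.

## Post-processing and montage comparison

Tissue statistics are element-volume-weighted (adapted elements differ
slightly in volume): peak, mean, and 50/95/99.9 percentiles of $|J|$ per
tissue. The 99.9th percentile accompanies the raw peak because elements
at patch edges carry discretization singularities. Skin and CSF are
flagged `masked_for_visualization` — they dominate so strongly that
intracranial patterns are invisible unless they are hidden — but their
numbers are always reported.

Focality is the GM volume fraction carrying $|J| \ge 50\,\%$ of the GM
peak (half-max volume; smaller = more focal). ROIs are schematic angular
sectors on the sphere: frontal (|azimuth| < 60°, inclination < 100°),
occipital-medial (|azimuth − 180°| < 30°), occipital-lateral
(30°–75° from the occipital pole). All thresholds and sectors are
configurable.

`run_pipeline()` chains phantom → electrodes → mesh → adaptation →
conductivity → solve → statistics for each named montage and emits a
TSV/JSON comparison table, NIfTI $|J|$ volumes and RDS solution bundles.
On the 2 mm default phantom at 1 mA the four standard montages reproduce
the expected qualitative physics: the strongest currents appear in skin,
then CSF, then cortex (shunting); the lateral-frontal F7/F8 montage
yields a higher frontal-ROI mean and a much smaller focality fraction
than the diffuse midline FPz/Oz montage; P7/P8 reaches lateral occipital
cortex better than Cz/Oz; and GM ridges protruding into CSF carry a
higher mean $|J|$ than equally deep non-protruding GM.

## Problem sizes, numerics, and limitations

The default phantom resolution is 2 mm (~3.3 × 10⁵ elements), chosen so
that a full four-montage comparison completes in minutes on one core;
1 mm is available through configuration when finer staircase control is
worth the ~8× cost. The test suite runs its unit checks at 4–8 mm and
its end-to-end checks at 2 mm.

Numerical choices worth knowing: assembly, meshing and the pipeline are
fully deterministic (bit-identical reruns); quadrature is 2×2×2 Gauss;
degenerate inputs (all-zero radii, empty montages, incompatible loads,
labels missing from the conductivity table, non-SPD tensors, off-surface
patches, overlapping footprints) raise early, specific errors; peak-element
ties break to the lowest element index.

What the phantom does *not* emulate: realistic cortical folding (ridges
are schematic sectors), skull holes and sutures, anisotropy estimated
from real diffusion data, inter-subject variability, and the true scalp
geometry that makes real 10–20 positions non-antipodal. Passing tests
therefore demonstrate correctness of the solver and the qualitative
physics of shunting, focality and gyral hot-spots — not numerical
agreement with any individual head. Tissue-specific absolute values
(e.g. skin or CSF peaks) depend strongly on geometry and should be read
as phantom properties.
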