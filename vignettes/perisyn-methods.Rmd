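---
title: "Measuring perisynaptic astrocyte engagement: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring perisynaptic astrocyte engagement: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(perisyn)
```

## The measurement problem

Astrocytic processes cradle excitatory synapses and clear glutamate and
potassium from the synaptic cleft, so the three-dimensional arrangement of
astrocytic membrane around an individual synapse is functionally meaningful
down to tens of nanometers. Serial block-face electron microscopy yields
labeled segmentations of single synapses — dendritic spine, postsynaptic
density (PSD), astrocytic process, axon terminal — on strongly anisotropic
voxel grids (here, 6–7 nm in-plane and 40 nm section thickness are typical
acquisition values). `perisyn` turns such label volumes into comparable
per-synapse numbers.

Everything is anchored on the PSD, the disc-like electron-dense structure
on the spine head: it is flat, consistently segmentable, and marks the
synaptic cleft, so PSD-relative measurements are comparable across synapses
of different sizes and orientations. Two complementary summaries are
computed.

**Torus scalar metrics.** A PSD frame is fit first: the barycenter
(volume-weighted centroid of PSD voxel centers), `r_max` (half the PSD's
longest axis, i.e. half the maximum pairwise distance between voxel
centers, computed on boundary voxels), and the disc normal (least-variance
principal direction of the voxel cloud). The analysis region is a
cylindrical annulus about the frame — radial bounds $0.75\,r_{max}$ to
$1.5\,r_{max}$, total depth 300 nm centered on the barycenter plane. Within
it we report the PSD volume, the minimum distance from the PSD edge to the
astrocyte edge (between boundary-voxel centers, under the anisotropic
metric), and the astrocyte volume. ROIs whose minimum distance exceeds
100 nm (inclusive threshold, configurable) are excluded from analysis, and
the included/excluded accounting is reported.

**Relational shape curves.** For dilation radii $r$ up to 1000 nm, the
$r$-parallel set $Y^r$ of the PSD is the sublevel set of the exact
anisotropic Euclidean distance field from the PSD. Against the observed
object $X$ (astrocyte, or spine for class validation) four Hausdorff-type
measures are recorded as functions of $r$: the cumulative volume
$V(r) = |X \cap Y^r|$; the surface area $S(r)$ of $X$'s boundary within
$Y^r$; the cut area $A_\perp(r)$ of the dilated isosurface
$\partial Y^r$ restricted to $X$; and the contour $C(r)$, the length of
the intersection curve $\partial X \cap \partial Y^r$. Together these form
a cross-K-style relational summary of how astrocytic material is arranged
around the synapse. Analysis concentrates on the 25–175 nm window, the
perisynaptic interval most relevant to receptor activation and transmitter
escape.

**Normalization.** Cumulative measures inflate with $r$ simply because the
dilated domain grows. Each measure is therefore also reported as
proportional coverage: $V(r)$ divided by the volume of the dilated shell
$Y^r \setminus Y$; $S(r)$ and $A_\perp(r)$ divided by the area of
$\partial Y^r$; $C(r)$ divided by $2\pi(r_{eq} + r)$ with $r_{eq}$ the
PSD's volume-equivalent sphere radius. The volume normalization follows
the method's definition; the area and circumference denominators are this
package's dimensional analogs (the method defines normalization explicitly
only for volume). Denominators are computed on the same voxel grid as the
numerators, so truncation by the volume boundary cancels in the ratios;
the truncated fraction of $\partial Y^r$ is nevertheless recorded per
radius and a warning is raised beyond 10%.

**Group comparison.** Curves are compared by a Monte Carlo permutation
test: the distance $t'$ between two group mean curves is the trapezoidal
integral of the absolute difference over the window (absolute area between
curves; the alternative $|\int(\bar m_A - \bar m_B)|$ is available as
`mode = "net"`). Pooled curves are re-split uniformly at random into groups
of the original sizes $n_{perm}$ times and
$p = (1 + \#\{t_i \ge t'\}) / (n_{perm} + 1)$, which is positive, exact
under exchangeability, and invariant to joint monotone rescaling of the
curves. Scalar metrics are compared with Welch's two-tailed $t$ test,
annotated (never switched) by an $F$ test of variance equality. No
multiple-testing correction is applied across measures; all comparisons
are listed. Default $n_{perm}$ is 10,000.

## Numerical choices

* **Distance transform.** Exact squared Euclidean distance via the
  separable lower-envelope algorithm, with per-axis weights for anisotropic
  spacing; distances are between voxel centers
  (voxel $(i,j,k)$, 0-based, has center $((i{+}0.5)dz,(j{+}0.5)dy,(k{+}0.5)dx)$),
  and all geometry is in nm, never voxels.
* **Surfaces are meshes, not voxel faces.** Face counting overestimates
  smooth areas by a direction-dependent factor (up to $\sqrt{3}$), which
  would defeat 5%-level area checks. Isosurfaces are triangulated by
  marching tetrahedra (each cell split into 6 tetrahedra sharing the main
  diagonal; level crossings linearly interpolated). On a 10 nm grid this
  reproduces a 300 nm sphere's area to ~1%. $S(r)$ keeps boundary-mesh
  triangles whose centroid's field value is $\le r$; $A_\perp(r)$ keeps
  dilated-isosurface triangles whose centroid lies in $X$ (nearest voxel);
  $C(r)$ is extracted as the level-set polyline of the distance field
  interpolated on the boundary mesh of $X$.
* **Volume by voxel counting.** $V(r)$ is an exact count
  (`field <= r` within $X$), reproducible against brute-force enumeration;
  measures are taken over $Y^r \setminus Y$, which equals $Y^r$ on disjoint
  labels but keeps normalization denominators well defined at small $r$.
* **Degenerate inputs.** Empty PSD masks are errors; a single-voxel PSD
  yields a degenerate frame (warning, `r_max = 0`) which cannot anchor a
  torus; an empty observed object yields all-zero curves; an astrocyte
  absent from the torus yields an infinite minimum distance and exclusion
  by the apposition filter. Radii exactly at a voxel's distance value are
  included (`<=`); the 100 nm filter is likewise inclusive.
* **`r_max` convention.** The torus bounds treat `r_max` as half the PSD's
  longest axis, the only reading under which $1.5\,r_{max}$ is a radius
  commensurate with the PSD disc; both factors are configurable so the
  full-axis convention is also expressible.
* **Torus depth** is centered on the barycenter plane (150 nm each side),
  the symmetric default; the offset is not otherwise specified by the
  method.
* **Determinism.** All randomness flows from explicit integer seeds; the
  pipeline derives stage seeds from one master seed, and re-running an
  identical configuration reproduces every output byte for byte. Each
  output is stamped with an MD5 hash of the canonical configuration text,
  and the defaults reproduce the method's printed constants (0.75/1.5
  torus factors, 300 nm depth, radii to 1000 nm, 25–175 nm window, 100 nm
  filter) so an empty override runs the reference parameterization.

## The synthetic phantom generator

Real EM segmentations of this kind are not redistributable at package
scale, so every stage is validated on voxelized tripartite-synapse
phantoms with analytic ground truth:

* a spherical spine head of radius $R$;
* the PSD as a spherical cap of half-angle $\alpha$ on the head surface,
  thickened radially inward (so the head surface is the PSD's outer face);
  its chord radius $R\sin\alpha$ is the ground-truth `r_max` analog and
  its barycenter has the closed form used in the recovery tests;
* the astrocyte as a partial spherical shell at standoff `astro_gap` from
  the head surface, of thickness `astro_thickness`, covering a solid-angle
  fraction `astro_coverage` as a polar cap centered on the PSD pole axis —
  so coverage concentrates at the synaptic periphery, which is what the
  measures probe; `astro_gap` is exactly the true minimum PSD–astrocyte
  distance;
* a presynaptic bouton apposed across a 20 nm cleft, included for
  segmentation-schema completeness and never measured.

Labels are disjoint by construction (priority PSD, spine, astrocyte,
axon). Optional Gaussian jitter of the implicit surface threshold adds
boundary roughness; its default is 0 so the analytic oracles hold exactly.
Cohorts draw head radius, coverage and gap from per-group truncated normal
distributions; spine class follows a declared synthetic convention (heads
under 250 nm are "thin", else "mushroom") — the field's thin/mushroom
criteria are not part of the phantom. Defaults (head 250 ± 50 nm, coverage
0.6 ± 0.15, gap 60 ± 15 nm, 10 nm isotropic voxels; a (40, 7, 7) nm preset
mirrors the anisotropic acquisition) represent a plausible adult striatal
spine population; two-group effects are expressed as shifts of these
means.

What the phantoms do **not** emulate: imaging physics (noise, staining
contrast, point-spread), segmentation error, irregular branched astrocyte
morphology, or multi-synapse neuropil crowding. Passing phantom tests
therefore demonstrates that the geometry and statistics are computed
correctly, not that segmentation of real tissue is accurate.

## Problem sizes and study regimes

Validation studies use phantom scales chosen for the property each one
probes:

* **Oracle checks** (sphere shell, half-space, torus, disc) run at 5–20 nm
  isotropic spacing on boxes of roughly $70^3$–$140^3$ voxels, where the
  discretization error of each estimator is measured directly against
  closed forms and shown to shrink with spacing.
* **Gap recovery** sweeps standoffs of 20–150 nm on a display-scale head
  (300 nm) at 10 nm voxels; recovered minimum distances stay within one
  voxel diagonal of truth.
* **Coverage recovery and the permutation studies** run on a thin-spine
  scale phantom (head 70 nm, gap 12 nm, shell 22 nm): with this geometry
  the farthest shell point lies ~168 nm from the PSD cap edge
  ($\sqrt{R^2 + S^2 + 2RS\cos\alpha} < 175$ for outer shell radius $S$),
  i.e. the entire shell sits inside the 25–175 nm analysis window, and
  solid-angle coverage maps linearly onto the normalized volume curve.
  That is the regime in which monotone coverage recovery and the power of
  the group comparison are well-posed properties of the measurement; at
  larger spine scales the measure correctly saturates once additional
  coverage accrues beyond the analysis window — a property of the window,
  not an estimator error — which would confound a sweep spanning coverage
  0.1–1.0. Type-I error is estimated from 200 null cohorts (8 ROIs per
  group) and power from 100 cohorts of 25 ROIs per group with a 40%
  coverage reduction, 500 permutations each.

## Known limitations

* Boundary-voxel minimum distances are accurate to about one voxel pitch;
  at 40 nm section thickness the axial quantization dominates. Sub-voxel
  distances would require surface meshes, which the torus metrics
  deliberately avoid.
* The normal of a nearly isotropic (non-disc-like) PSD is ill-conditioned;
  the frame fit assumes the PSD is flat, as it is for asymmetric synapses.
* $S(r)$ uses the full boundary of the observed object within $Y^r$, not
  only its outward-facing sheet; on binary masks the mesh lies mid-voxel,
  so staircase bias (a few percent on smooth objects) is inherited by
  $S$ — the normalized curves divide much of it out.
* The contour estimator degrades when $\partial X$ and $\partial Y^r$ are
  nearly tangent (the intersection polyline becomes grazing); phantom
  checks place it within 5% on transverse intersections.
* Curve confidence bands in plots are pointwise 95% percentile bootstrap
  over ROIs — a labeled package convention, not part of the permutation
  inference.

## A minimal run

```{r example, eval = FALSE}
cfg <- run_config(
  mode = "simulate",
  cohort = cohort_spec(
    n_per_group = 10,
    groups = list("WT" = list(),
                  "R6/2" = list(astro_coverage = c(0.36, 0.15))),
    seed = 1),
  seed = 1, out_dir = "run1")
report <- run_pipeline(cfg)
report$comparisons[["WT_vs_R6/2.volume"]]
```
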