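---
title: "Multispectral point-cloud enrichment and divisive material segmentation: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multispectral point-cloud enrichment and divisive material segmentation: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the models implemented in `cloudspectra`, the
assumptions behind them, the parameters that matter, and the design
decisions taken where several readings were defensible. It states no
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## 1. Radiometric model

Raw multispectral pixel values depend on illumination, shutter, gain and
optics; material comparison requires surface reflectance. The package uses
a three-part model.

The *incident* solar flux comes from a sunshine sensor sampled with each
capture:
$$\Phi_{ei} = \frac{\nu}{g\,\tau},$$
with raw count $\nu$, relative gain $g$ and exposure $\tau$ (seconds). The
*reflected* flux of a pixel with raw intensity $\rho$ is
$$\Phi_{er} = \frac{f^2(\rho - B)}{A\,\gamma\,\varepsilon} + C,$$
with f-number $f$, ISO $\gamma$, exposure $\varepsilon$ and per-camera
production coefficients $A, B, C$. A reflectance panel of known reflectance
$R_i$ ties the two scales together through a per-band coefficient
$K = \operatorname{mean}(R_i\,\Phi_{ei}/\Phi_{er})$ over valid shots, and
surface reflectance is
$$R = K\,\frac{\Phi_{er}}{\Phi_{ei}\cos\theta},$$
where $\theta$ is the sun/sensor angle. The chain is exactly invertible
(`reflectance_to_pixel()`), which is what the synthetic renderer and the
round-trip tests exploit.

Design choices:

* **Symbol consistency.** One published description of the reflected-flux
  formula confuses the f-number with the gain symbol in its prose; the
  formula body itself is unambiguous and is what we implement
  ($f$ = f-number, $\rho$ = pixel, $\gamma$ = ISO, $\varepsilon$ =
  exposure).
* **Panel protocol.** The panel ratio $K_i = R_i\Phi_{ei}/\Phi_{er}$
  carries no $\cos\theta$ term, while scene reflectance does. The two are
  mutually consistent only if panel shots are taken with the sunshine
  sensor aligned to the sun ($\theta = 0$); the panel simulator therefore
  emits $\theta = 0$ readings. With a misaligned panel, every recovered K
  would be biased by $1/\cos\theta$.
* **Aggregation and saturation.** K is the arithmetic mean over the shots
  of a session protocol (three exposure levels, start and end of
  acquisition); shots whose panel region exceeds 98% of the dynamic range,
  or with non-positive reflected flux, are excluded.
* **Clipping.** Reflectance above `r_max` (default 2.0, dimensionless) is
  clipped, not rejected — specular highlights occur in field data — and the
  clip count is reported. NDVI at $\mathrm{NIR}+\mathrm{Red}=0$ is defined
  as 0 so no non-finite value can reach the clustering stage.

## 2. Fisheye projection

Wide-angle multispectral lenses are modelled by a normalized-angle
polynomial: for a camera-frame point $(X, Y, Z)$,
$$\theta = \frac{2}{\pi}\arctan\!\frac{\sqrt{X^2+Y^2}}{Z}, \qquad
  \rho = \theta + p_2\theta^2 + p_3\theta^3 + p_4\theta^4,$$
followed by an affine map (entries C, D, E, F, which include the focal
scaling) and the principal point. The $2/\pi$ normalization is the only
reading under which $\theta$ spans $[0, 1]$ over the forward hemisphere, as
the model requires. Projection is a total function: points with $Z \le 0$
or $\theta$ beyond `theta_max` report "not projectable" rather than error.
The numeric inverse (`fisheye_unproject()`) solves the quartic by 1-D root
bracketing on $[0, 1]$; project–unproject consistency is part of the test
suite and the acceptance script.

View reliability is classified from the angle between the point normal and
the point-to-camera direction: perpendicular $[0°, 25°)$, oblique
$[25°, 60°]$, indirect $(60°, 180°]$. The two interval boundaries are
assigned to the oblique class for determinism. The default per-class
aggregation weights 1.0 / 0.5 / 0.0 are flat within each class — the three
ranges are given, a weighting law is not — monotone in reliability, and
exposed in configuration (`class_weights`); continuous cosine weighting can
be substituted by passing per-sample weights to `aggregate_point()`.

## 3. Visibility with occlusion rejection

Mapping must not sample a pixel that actually images a nearer surface. The
test walks all in-frustum points from nearest to farthest; each processed
point registers a *minimal triangulated surface patch* — a triangle fan
spanned by the point and its radius neighbours, the neighbours filtered by
normal compatibility (`normal_angle_max`, default 60°) — and a candidate is
occluded exactly when its camera ray crosses an already-registered patch
strictly nearer than the candidate.

Two realizations were evaluated. Oriented surfel *disks* are simple, but a
disk is a tangent-plane extrapolation: at a curved silhouette it overhangs
the true surface, and the resulting false occlusions grow with disk radius
relative to the curvature radius — on a sampled sphere they affected several
percent of points, irrespective of the depth bias. Triangle *fans*
interpolate between actual surface samples: on a convex surface the chords
lie inside the body, so a ray to a visible point cannot cross them, and
false occlusions vanish by construction. The fan realization is the one
shipped.

Parameters, with rationale:

* `neighbor_radius` (scene units) — default $5\times$ the mean
  nearest-neighbour spacing. Fans only seal a Poisson-sampled surface when
  each point's neighbourhood surrounds it; at $3\times$ the spacing,
  one-sided neighbourhoods at sampling voids leave holes that let rays
  through, which the two-plane reference scene makes visible immediately.
* `depth_bias` — default $0.1 \times$ `neighbor_radius`. Patches
  interpolate the surface they were built from, so hits within the bias of
  the candidate's own depth are ignored; the bias must exceed the chord sag
  of the local triangulation (which scales as radius²/curvature) but stay
  small enough not to blind the test to shallow occlusions. Agreement with
  ray casting is insensitive across $[0.05, 0.15]\times$ the radius.
* Patches are registered for *every* processed point, including occluded
  ones: occluded points are real surface samples, and dropping them would
  truncate the registered surface short of silhouettes.
* Lookup is accelerated by binning projected patch footprints on the image
  plane; the brute-force equivalent is kept in the tests as the oracle.

Visibility alone does not make sampling safe: a background point just
*outside* a foreground silhouette is genuinely visible, yet its bilinear
support pixels may be owned by the foreground surface, and a max-based
statistic downstream (the cluster diameter of Section 5) is sensitive to
even a handful of such contaminated points. `enrich_cloud()` therefore
applies the standard depth test of texture mapping: per camera, a depth
buffer is built from the visible points themselves, and a sample is
rejected when the sampling point lies more than `depth_tol` (default
$2\times$ `neighbor_radius`) behind the nearest visible point projecting
into any of its four support pixels. The tolerance must absorb legitimate
within-pixel depth variation on slanted surfaces while rejecting
cross-silhouette reads, whose depth gaps are object-scale.

The reference check casts rays against the *exact triangulation of the
sampled surface* (for the sphere fixture, a structured latitude–longitude
grid whose triangulation is known). An analytic-surface oracle would
instead measure the sampling density — no method that only sees the samples
can know the surface continues a half-spacing beyond the outermost ones.

## 4. Registration

When multispectral poses are not in the RGB cloud's frame, point-to-point
ICP aligns the two clouds. Correspondences are nearest neighbours gated by
distance and normal compatibility, weighted by
$w = e^{-d^2/d_{\max}^2}\max(0, \cos\alpha)$ with $\alpha$ the normal
angle — the two factors (distance, normal compatibility) are given by the
method's description, the functional form is ours. The per-iteration fit is
the closed-form weighted orthogonal Procrustes solution with reflection
correction, so every returned rotation is proper. Iterations that fail to
decrease the mean squared residual are rejected, making the objective
sequence non-increasing; convergence is declared when the decrease falls
below `tol` (default 1e-12, squared scene units). Alignment quality is the
root mean squared nearest-neighbour distance from every aligned point into
the reference cloud — the reference is the RGB cloud because it is the
denser, more precise model. No global initialization is attempted: in the
field the coarse alignment comes from georeferencing; the API accepts an
optional initial transform instead.

## 5. Divisive segmentation

Each admitted point carries 11 attributes: position (m), colour in
$[0, 1]$, four band reflectances and NDVI. These live on incompatible
scales, so all dimensions are z-scored (per-dimension mean 0, sd 1) before
the Euclidean metric is applied; optional per-dimension weights multiply the
standardized columns and default to 1 — the 11 attributes enter equally.
Note the flip side, demonstrated in the test suite: when most dimensions are
uninformative noise (an isotropic Gaussian mixture with a few signal
dimensions), global z-scoring *shrinks* the informative axes relative to the
noise ones; standardization is the right default for heterogeneous physical
units, not a universally safe transform.

The hierarchy is built top-down. Every heterogeneous cluster is bisected by
2-means with k-means++ seeding and `n_init = 10` restarts (best
within-cluster sum of squares kept; Lloyd iterations via `stats::kmeans`).
A child produced by a split with sibling-centroid distance $D$ is recursed
into only while

* its diameter (maximum intra-cluster pairwise distance) is at least $D$,
* it holds at least `min_size` points (default 10), and
* the depth guard `max_depth` (default 32) is not exceeded.

The diameter-vs-distance rule admits one other literal reading — comparing
the *parent's* diameter against its children's centroid distance — but the
children's centroids always lie inside the parent, so that variant can
never stop; it was rejected on that ground. Diameters are exact up to
`exact_threshold = 2000` members and otherwise computed on a deterministic
farthest-point subsample of that size, which never overestimates and is at
least half the true diameter; tests restore exactness by lowering the
threshold. All randomness passes through one seed, giving bitwise
reproducible hierarchies.

**Operating regime.** The stop rule compares two absolute lengths, so a
cluster is only recognised as final when its diameter falls below its
distance to its sibling. A 5,000-point isotropic Gaussian component in 11
dimensions has a diameter near $10\sigma$; components must therefore sit
comfortably farther apart than that, or the rule keeps splitting them. The
packaged mixture generator (`simulate_mixture()`) places component centres
on a regular simplex — every pair equally separated — with a default edge of
$16\sigma$, inside the rule's valid regime. Conversely, a single spatially
extended material (a long wall, an unbroken ground plane spanning the whole
scene) has a large spatial diameter and will be oversegmented spatially;
this is a property of the method, not of this implementation, and is the
main caveat when transferring it to scenes whose materials are not compact.

## 6. The synthetic scene generator

`default_reference_scene()` emulates a small controlled natural plot: six
compact material objects — a ground disc (radius 1 m), a rock box, a trunk
cylinder, and leaf/plant/flower canopy spheres — arranged around a 2.2 m
ring, observed by eight fisheye cameras on a 5.5 m ring at 4 m height.
Material signatures are invented but encode the ordinal spectral facts of
natural surfaces: vegetation reflects strongly in red-edge/NIR and weakly in
the visible (leaf-signature NDVI above 0.6), rocks and ground are spectrally
flat (NDVI below 0.2), flowers pair high red-edge/NIR with a distinctive
visible colour. Within-material variability is Gaussian: colour sd 0.01
(absolute) and reflectance sd 1% of each band's mean — reflectance scatter
in nature grows with brightness, and a relative sd keeps dark bands (red on
vegetation, ~0.05) meaningfully tight.

Rendering is point-splat: every point that survives an analytic
ray-casting check against the primitive surfaces deposits its true
reflectance into its projected pixel, nearest point per pixel; pixels are
converted to raw counts by the exact radiometric inverse under configured
true coefficients $K$, and multiplicative Gaussian noise (default sd 1% of
the signal) is added. Image resolution (96×96 at a 80 px affine scale) is
matched to the splat density so that bilinear sampling has support; panel
shots for the calibration stage are synthesized under the same radiometry.

What the generator does *not* emulate — and hence what green tests do not
establish about field data: cast shadows and indirect illumination,
BRDF/specular directionality beyond the view-angle weighting, vignetting
and per-pixel sensor response, reconstruction noise in positions and
normals (positions are exact surface samples), and volumetric canopies. A
`blob` primitive (Gaussian scatter) exists and is unit-tested, but the
default scene uses surface primitives only: a scatter cloud has no surface,
so surface-based visibility and the point-splat renderer systematically
disagree on it.

Scene layout and signatures were designed, and iterated during development,
so that the stop rule of Section 5 operates in its valid regime — compact
material objects whose spatial and spectral gaps both exceed their internal
spread — and then frozen; they are the package's reference conditions, not
free parameters of any test.

## 7. Problem sizes and runtime envelope

The shipped checks use: 1,000 random radiometry draws; 1,000 projection
round-trips; two 2,000-point occlusion scenes; 200 ICP recoveries on a
5,000-point scene (rotations to 10°, translations to 20% of the bounding
box); 50 Gaussian mixtures with $n = 5{,}000$, $k \in 2..8$, $d = 11$; and
an end-to-end run on the 10,000-point, 8-camera reference scene at 1% image
noise. These sizes exercise every code path at scales where the asymptotic
behaviour (kd-tree lookups, farthest-point diameter approximation, binned
patch lookup) is active, while keeping a complete run in the minutes range
on one CPU.

## 8. Known limitations

* LAS I/O is not provided; PLY (ASCII and binary little-endian) and XYZ
  are. PLY list properties (meshes) are out of scope — the pipeline is
  deliberately mesh-free.
* ICP is point-to-point and local; with no initial transform it converges
  from moderate perturbations (the regime tested) but is not a global
  registration method.
* The visibility test assumes meaningful normals; on scatter geometry
  (volumetric vegetation) occlusion is ill-defined at the sampling scale.
* The stop rule oversegments spatially extended homogeneous materials, as
  discussed in Section 5; merging such leaves back is interpretation and
  is intentionally not performed.
* Radiometric correction covers the global chain only: no vignetting,
  dark-current or flat-field terms.
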