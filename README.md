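# cloudspectra

Unsupervised segmentation of natural materials in photogrammetric point
clouds, driven by calibrated multispectral reflectance.

Consumer RGB photogrammetry produces dense, geometrically precise point
clouds of natural scenes, but leaves, bark, rocks and soil often look alike
in the visible range. `cloudspectra` fuses a high-resolution RGB cloud with
narrow-band multispectral imagery (green, red, red-edge, near-infrared) from
a wide-angle multispectral sensor, then partitions the enriched cloud into
material clusters without knowing how many materials the scene contains. It
is aimed at remote-sensing and computer-vision practitioners who work with
close-range photogrammetry of vegetation, and at anyone who needs a fully
synthetic, ground-truthed test bed for such pipelines.

## The method

The pipeline has three stages.

**1. Radiometric calibration.** A sunshine sensor measures the incident
solar flux Φ<sub>ei</sub> = ν / (g·τ) from its raw count ν, gain g and
exposure τ. Each raw image pixel ρ is converted to reflected flux
Φ<sub>er</sub> = f²·(ρ − B)/(A·γ·ε) + C from the aperture f-number f, ISO γ,
exposure ε and the per-camera production coefficients A, B, C. Shots of a
panel of known reflectance R<sub>i</sub> fix a per-band calibration
coefficient K = mean(R<sub>i</sub>·Φ<sub>ei</sub>/Φ<sub>er</sub>), after
which surface reflectance is

&nbsp;&nbsp;&nbsp;&nbsp;R = K · Φ<sub>er</sub> / (Φ<sub>ei</sub> · cos θ),

with θ the sun/sensor angle. NDVI = (NIR − Red)/(NIR + Red) completes the
spectral attributes.

**2. Mapping onto the cloud.** Every 3-D point is projected into each
multispectral image through a polynomial fisheye model: the normalized
off-axis angle θ = (2/π)·arctan(√(X²+Y²)/Z) ∈ [0, 1] enters the quartic
ρ = θ + p₂θ² + p₃θ³ + p₄θ⁴, and an affine matrix (C, D, E, F) plus the
principal point (c<sub>x</sub>, c<sub>y</sub>) yields pixel coordinates.
Self-occlusion is resolved by a nearest-to-farthest visibility sweep that
registers a minimal triangulated surface patch at every processed point and
discards points whose camera ray crosses a strictly nearer patch. Samples
from multiple cameras are combined with view-angle reliability weights
(perpendicular 0–25°: 1.0, oblique 25–60°: 0.5, indirect >60°: discarded).
If the multispectral poses live in a different frame, an ICP variant with
distance- and normal-compatibility-weighted correspondences aligns the two
clouds first, with quality reported as nearest-neighbour RMSE.

**3. Divisive segmentation.** Each fully enriched point carries 11
attributes (X, Y, Z, R, G, B, red, green, REG, NIR, NDVI), z-scored into a
common Euclidean metric. Starting from one all-points cluster, 2-means
(k-means++, restarted) recursively bisects every heterogeneous cluster; a
child is split further only while its diameter (maximum intra-cluster
distance) is at least the distance between the two sibling centroids of the
split that created it. The leaves are the discovered materials — the number
of clusters is an output, not an input.

A first-class synthetic-scene generator builds labelled six-material scenes
(ground, rocks, trunk wood, leaves, low plants, flowers), renders physically
consistent raw multispectral captures by inverting the radiometric chain,
and synthesizes calibration-panel shots — so the whole pipeline is testable
end to end with exact ground truth.

## Worked example

```r
library(cloudspectra)

cfg   <- default_reference_scene(seed = 1, points_per_material = 500)
scene <- generate_scene(cfg)                      # labelled 3,000-point cloud

captures <- render_views(scene)                   # 8 cameras x 4 raw bands
K <- lapply(simulate_panel_shots(cfg), panel_calibration)
vapply(K, function(k) k$K, 0)
#> green   red   reg   nir
#>   1.4   1.6   1.3   1.2        # the generator's true K, recovered exactly

captures <- calibrate_captures(captures, K)       # raw counts -> reflectance
enriched <- enrich_cloud(scene$cloud, captures)   # visibility + sampling
round(attr(enriched, "coverage"), 3)
#>    green      red      reg      nir complete
#>    0.762    0.762    0.762    0.762    0.762

seg <- segment_cloud(enriched, seed = 1)
seg$clustering
#> divisive_clustering: 2286 points, 6 material clusters, 11 tree nodes
#>   leaf sizes: 368, 298, 335, 489, 478, 318

mclust::adjustedRandIndex(seg$clustering$labels,
                          enriched$attributes$material[seg$ids])
#> [1] 1
```

The panel calibration recovers each band's true coefficient; about 76% of
points are seen well enough (all four bands, non-indirect views) to enter
clustering — the rest are undersides and self-occluded backs; and the
divisive hierarchy stops at exactly six leaves that match the generating
materials perfectly (adjusted Rand index 1).

The same workflow is available from the shell:

```sh
Rscript exec/cloudspectra simulate,calibrate,map,segment --config config.yaml --seed 1
```

which writes the scene, raw TIFF bands with YAML sidecars, the enriched and
labelled PLY clouds, a JSON cluster-tree report and per-stage run reports.

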