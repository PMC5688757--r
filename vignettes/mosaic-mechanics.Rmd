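---
title: "Quantifying the cone lattice mosaic and planar retinal mechanics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying the cone lattice mosaic and planar retinal mechanics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(mosaicmech)
library(dplyr)
```

## The system and the questions

The adult teleost retina packs its cone photoreceptors into a crystalline
lattice mosaic: single-cell-width columns in which Red cones alternate with
either one Blue cone or a Green–UV–Green triplet, while rows perpendicular to
the columns alternate UV and Blue cones. All quantitative work happens at the
outer limiting membrane (OLM), the apical junctional plane where every
photoreceptor and Müller glial process presents a small polygonal profile.
`mosaicmech` implements the computations needed to study two linked
questions on this system:

1. **Pattern** — does the observed arrangement of reporter-positive profiles
   at the OLM match the counts the lattice rules predict (e.g. the ratio of
   Red-cone-reporter-positive to negative profiles, with or without rods at
   the UV-cone corners)?
2. **Mechanics** — do Müller glial processes carry anisotropic tension in
   the epithelial plane, as revealed by the recoil of photoreceptor
   positions after laser ablation of single glia, and do the glial bands
   align with the cone columns?

Because no public imaging data accompany these experiments, the package
ships a first-class synthetic-data generator that renders confocal-like
z-stacks, glial-band images and recoil experiments with known ground truth.
Every analysis stage is exercised end-to-end against that generator.

## The lattice model

`generate_mosaic_lattice()` constructs the ideal mosaic from the 6-cone
repeat motif `RED, BLUE, RED, GREEN, UV, GREEN` along each column, with
adjacent columns phase-shifted by half a repeat unit (three sites) so UV and
Blue cones alternate along rows. The shift is realized as a motif-index
offset rather than a coordinate translation, which keeps all columns flush:
border cells then have the same size as interior cells, which matters when
mean intensities are measured per profile.

Two geometric choices were genuinely open:

* **Inter-column spacing.** We default the column gap to `sqrt(3)` times the
  in-column spacing. With that ratio the six Red cones surrounding each
  interior UV cone are exactly equidistant — the "Red-cone hexagons" of the
  adult mosaic — and `validate_lattice()` checks precisely this property
  (plus the column motif and the four rods per UV cone). Note that the Red
  sites themselves cannot form a triangular lattice: they occur in pairs
  within each column (two per repeat unit), so a Red site has three, not
  six, equidistant nearest Red neighbors. The hexagon centered on UV is the
  correct formalization of the mosaic's hexagonal appearance.
* **Rod placement.** Rods sit at the four diagonal midpoints between a UV
  cone and its nearest cross-column Red neighbors
  (`rod_offset_factor = 0.5`), the corner geometry seen in flat-mount
  preparations.

`expected_profile_ratio()` counts subtypes in one generated repeat unit
rather than hard-coding numbers: 2 Red vs 4 other cones (1:2), or 2 Red vs
4 cones + 4 rods (1:4).

```{r lattice, eval = FALSE}
lat <- generate_mosaic_lattice(4, 4, include_rods = TRUE)
validate_lattice(lat)
expected_profile_ratio(include_rods = TRUE)
ggplot2::autoplot(lat)
```

## What the synthetic renders emulate — and what they do not

`render_zstack()` produces multi-channel stacks with anisotropic voxels
(defaults dz = 1.8 µm, dx = dy = 0.2 µm, matching typical two-photon
acquisition of these preparations). The apical signal is confined to a
surface z(x, y) — flat, tilted plane, or spherical cap (a flat-mounted
retina is a curved cap) — with a Gaussian axial profile
(`psf_sigma_um = 0.9`). Each optical section integrates that profile over
its 1.8 µm slab (an erf difference) rather than point-sampling it; real
detectors integrate, and point-sampling a Gaussian that is narrow relative
to the z-step would alias into a depth-periodic bias of the reconstructed
surface.

Channel styles: *membrane* puts intensity on the boundaries between cell
profiles (ridges of the site Voronoi diagram, emulating a ZO1 junction
label); *soma* puts Gaussian blobs at emitting sites (reporter expression);
*glia* fills thin lamellae around every profile plus thicker bright bands on
the inter-column midlines. Intensity noise is additive Gaussian clipped at
zero; positional jitter on lattice sites is isotropic Gaussian.

Not emulated: realistic PSF physics beyond Gaussian blur, photobleaching,
depth-dependent attenuation, the RPE layer, segmentation-relevant shape
irregularity of glial profiles, and biological variability in cell size.
Passing tests on these renders therefore demonstrate the correctness of the
computations, not robustness to every artifact of real confocal data; the
noise and masking tests probe the failure modes we judged most relevant
(low signal, masked radial fibers, tracking noise).

The recoil simulator (`simulate_ablation_recoil()`) deforms cone positions
about the ablation hole by `M = R(rotation) diag(lambda_x, lambda_y)` with
an exponential saturation in time, `f(t) = (1 - e^(-t/tau)) /
(1 - e^(-t_max/tau))`, tau = 20 min by default. The literature reports
recoil developing over tens of minutes but no functional form or
displacement magnitudes; the saturating exponential is the package's
choice, normalized so the last timepoint carries the full deformation
(which gives exact round-trip tests). CONTROL experiments apply the
identity plus noise.

## Surface projection

`reconstruct_olm_surface()` smooths each pixel's z-profile with a Gaussian
kernel in z (`z_kernel_sigma_um = 1.8`, one z-step — wide enough to bridge
the undersampled axial profile, narrow enough not to merge distinct
structures) and takes the depth of the smoothed maximum. The argmax, rather
than a weighted centroid, locates the OLM robustly in the presence of basal
background; the centroid variant is available via `method = "centroid"`.
Sub-voxel depth comes from a log-parabola through the peak and its two
neighbors — exact for a Gaussian axial profile even when undersampled,
whereas a plain parabola on the raw intensities is biased toward slice
centers (we observed that bias directly as a sawtooth in reconstructed
tilted planes before switching).

Confidence is the smoothed peak prominence normalized to [0, 1]; pixels
below `confidence_floor = 0.1`, and any manually masked pixels, are filled
by normalized convolution (Gaussian-weighted averaging of confident
neighbors, widening the kernel until coverage), then the height field is
smoothed laterally (`xy_smooth_sigma_um = 0.6`). All lateral smoothing uses
zero-padded normalized convolution so constants survive image borders
exactly; because a *ramp* is still biased near borders, `estimate_tilt()`
trims a border of twice the smoothing support before fitting its
confidence-weighted least-squares plane.

`project_at_surface()` reduces (max or mean) the slices within
±`band_halfwidth_um` (default 2 µm, about one z-step) of the surface;
pixels whose band contains no slice center fall back to the nearest slice.

## Segmentation and classification

`segment_profiles()` mirrors the manual workflow: seeds are an input (one
per cell; an auto-seeder exists for convenience but analyses pass explicit
seeds), and regions grow from the seeds over the boundary-intensity
landscape until they meet at the bright walls (EBImage's seeded
propagation, the Bioconductor implementation of seeded watershed-style
region growing). Glial exclusion is an input mask, as in the manual
procedure; masked area is reported as one EXCLUDED profile and seeds
falling inside it are dropped with a warning.

Classification of per-profile mean reporter intensities uses two clusters
with the higher-centroid cluster POSITIVE. The default solver is the exact
1D two-cluster optimum (enumeration over thresholds of the sorted
intensities) — deterministic and globally optimal, with
`stats::kmeans(nstart = 10)` under a fixed seed available as an
alternative. `compute_ratio()` is plain count arithmetic, excluding
EXCLUDED profiles.

## Ridge analysis of glial bands

`steerable_ridge_filter()` implements an even-order steerable
Gaussian-derivative ridge template (order 4, width 8 px by default — the
thickness of inter-column glial bands at 0.2 µm pixels; the width maps to
the Gaussian scale sigma = width / (2 sqrt 2) so the ridge-response FWHM is
near the nominal width). Directional derivatives are steered analytically
from separable basis convolutions, and the per-pixel orientation search is
exact up to a 1° sampling. For orders >= 4 the template is
`sigma^N D^N - 3 sigma^2 D^2` across the candidate ridge: the bare 4th
derivative has positive secondary lobes (~12% of peak) that detect phantom
ridges flanking a real one, and the second-derivative term cancels them to
below 1%, in the tradition of optimized steerable ridge detectors. Scores
are defined only up to a positive scale, so every downstream threshold is
quantile-based and renderer-independent.

`refine_ridges()` then (i) thins the score map to one-pixel centerlines by
non-maximum suppression across the local ridge direction, (ii) applies the
quantile threshold and removes isolated survivors, (iii) thins to a
unit-width skeleton (Zhang–Suen) and splits at true branch points —
pixels whose 8-neighborhood crossing number is >= 3; staircase corners of
diagonal lines are *not* junctions, which a naive degree rule gets wrong —
and (iv) links 8-connected components into lines ordered along their
principal axis. Pixels within the kernel support of the image border are
excluded: boundary-extension artifacts otherwise mimic ridges along the
frame.

`estimate_column_direction()` takes the 2D power spectrum with DC and a
small low-frequency disc removed; the dominant spectral direction (refined
by a local power-weighted centroid, restricted to one half-plane because of
conjugate symmetry) is perpendicular to the columns. A peak-to-median power
ratio below 50 flags a near-isotropic image as low-confidence (white noise
lands near 15; rendered band images in the thousands).

`filter_ridges()` applies the two published rules: angular deviation from
the column direction at most 30° (180°-periodic circular distance) and
length at least 20 px. The package reproduces the negative control built
into the method: running the same filter with the column direction rotated
by 90° leaves almost no surviving lines on a band image.

## Strain mechanics

`fit_affine()` solves the least-squares affine correspondence
`rf ≈ M r0 + b` in closed form on mean-centered coordinates (the centering
conditions the normal equations; `b` is recovered from the centroids), and
refuses nearly collinear configurations. `polar_decompose()` computes
`P = (M'M)^(1/2)` from the eigendecomposition and `U = M P^(-1)` (SVD-based
completion when singular); tests verify it against an independent SVD
oracle. Strains are the eigenvalues of `P` (> 1 stretch, < 1 compression);
`strain_axes()` assigns the eigenvalue whose eigenvector is closer
(mod 180°) to the column direction as the y-strain (parallel to columns)
and the other as the x-strain, reporting the angular deviation and flagging
isotropic `P` as axis-indeterminate.

`residual_fraction()` divides the RMS residual of the affine fit by a
typical neighboring cell distance. RMS (not mean) matches the least-squares
objective being minimized; "typical neighboring cell distance" is defined
here as the median nearest-neighbor distance (`typical_neighbor_distance()`),
since the experimental literature leaves it unspecified.

Group comparison pools all post-ablation timepoints within each group
(`compare_strain_groups()`): Welch's unequal-variance t test per axis
(via `stats::t.test`) and an unequal-covariance two-sample Hotelling
T-squared on the (x, y) strain pairs, `T2 = d' (S1/n1 + S2/n2)^(-1) d`,
with a Yao-type moment-matched F approximation for the null — no installed
package provides this test, so it is implemented here and validated against
a permutation oracle in the test suite.

## Numerical choices and problem sizes

* Angles are degrees, counterclockwise from +x, orientations mod 180°;
  positions are µm; image rows index y, columns x, with pixel centers at
  half-integer multiples of the pixel size. Serialized files state units in
  their sidecars.
* Tie-breaks: the orientation search takes the first maximal angle; the
  1D two-cluster solver takes the first minimal-WSS split; `max.col` ties
  resolve to the first index.
* Degenerate inputs are errors with typed conditions (sizing, geometry,
  rank, format, validation), not silent results; an empty ridge survivor
  set is a valid empty result, not an error.
* The test suite and worked examples run on lattices of 2–6 columns and
  2–4 repeat units (roughly 100–400 px wide renders, 10–20 slices),
  Monte-Carlo batches of 50–100 seeds, and permutation oracles of 10^4–10^5
  resamples — sizes chosen so the whole suite completes in well under a
  minute on one core while leaving every statistical check comfortably
  powered.

## Known limitations

* The affine model is fitted globally around the lesion; spatially varying
  deformation fields are out of scope (the residual fraction quantifies how
  much the affine assumption misses).
* Ridge detection is single-scale; the filter order and width are exposed
  but no multi-scale combination is attempted.
* The classifier only separates reporter-positive from negative profiles;
  cone spectral subtypes are not called from morphology.
* Synthetic realism is deliberately minimal (see above); parameter defaults
  are calibrated to the geometry of the system, not fitted to real images.
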