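---
title: "ranvier3d: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ranvier3d: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Nodes of Ranvier are the short unmyelinated axon segments where saltatory
conduction regenerates the action potential. Each node is flanked by two
paranodes — the regions where the myelin sheath anchors to the axon, labeled
by CASPR immunostaining — and their geometry (paranode length, node width,
total nodal region length) tunes conduction velocity. In gray matter the
axons run at arbitrary angles to the imaging plane, so measuring these
sub-micrometre structures from confocal z-stacks is a genuinely
three-dimensional problem: a 2D maximum-projection measurement of a paranode
tilted by an angle θ out of the plane foreshortens its length roughly by
cos θ, which at typical gray-matter orientations is a distortion far larger
than the effects under study (single-digit percent differences between
experimental groups).

`ranvier3d` implements the full chain: per-node cropped multi-channel
z-stacks in, 3D segmentation of paranodes, sub-voxel length measurement
along the principal axis, pairing of flanking paranodes into nodes,
axon-label (mCherry+/−) classification, and nested mixed-effects group
comparison. A synthetic-stack simulator with complete ground truth makes
every stage testable by parameter recovery, which is how the test suite and
the acceptance script validate the package.

## The synthetic cohort generator

The generator draws a hierarchical cohort — groups, mice within groups,
nodes within mice, two paranodes per node — and renders one confocal field
per node, emulating the acquisition protocol in which a region around each
node is cropped and imaged as its own z-stack.

Geometry. For a node of mouse $m$ in group $g$, each paranode length is

$$L = (\mu + b_m + u_n)\,\rho_g\,(\lambda_g\ \text{if on a labeled axon}) + \varepsilon,$$

with $\mu$ the control mean, $b_m \sim N(0, \sigma_\text{mouse})$ a mouse
intercept, $u_n \sim N(0, \sigma_\text{node})$ a node intercept shared by
the node's two paranodes (zero by default), $\rho_g$ a multiplicative group
effect, $\lambda_g$ a labeled-axon-only multiplier (the DREADD design), and
$\varepsilon \sim N(0, \sigma_\text{par})$, truncated below at 0.2 µm. The
node gap is drawn analogously. Both paranodes are collinear with a node axis
drawn uniformly on the sphere (gray matter) or within a tilt band from the
imaging plane (tract-like geometry). Mice are assigned to staining batches
round-robin; batches act as intensity multipliers at render time and never
touch geometry, mirroring the fact that staining affects brightness, not
anatomy.

Defaults (all exposed in `sim_config()`): control paranode mean 1.6 µm
(SD 0.25), gap 0.9 µm (SD 0.15), capsule radius 0.35 µm, mouse SD 0.05 µm —
the anatomical scales are literature-typical values for small-caliber CNS
axons, since absolute lengths are not printed in the source experiments.
Between-mouse gap SD defaults to 0.02 µm (≈2 % CV, a plausible
between-animal variation; nothing in the source fixes it). Two staining
batches at factors 1.0/1.15.

Rendering. A paranode is a capsule — a cylinder with hemispherical caps —
whose end-to-end extent *including caps* is the ground-truth length; the
morphometry module targets the same convention. The optional node channel is
an ellipsoidal blob in the gap (the Nav1.6 marker), the axon channel a thin
(0.10 µm) cylinder through both capsules. Channels are convolved with an
anisotropic Gaussian PSF (default σ = 0.08, 0.08, 0.20 µm), scaled by
`photon_scale` (default 50 photons at peak, SNR ≈ 7) and the batch factor
over a 2-photon background, then corrupted by Poisson shot noise followed by
Gaussian read noise (SD 2 counts) — in that order, matching the physics of
photon detection before camera readout. Voxels are 0.04 × 0.04 × 0.10 µm,
the acquisition resolution of the emulated protocol, so the z-sampling is
2.5× coarser than xy — the anisotropy that motivates the package. Setting
`photon_scale = Inf` renders the noiseless expectation, used by the
calibration tests.

What the simulator does *not* emulate: optical aberrations, depth-dependent
attenuation, bleaching, tissue autofluorescence structure, curved paranodes,
juxtaparanodal structures (no Kv channel was imaged in the emulated
antibody panel), or segmentation distractors such as debris. Passing the
recovery suite therefore demonstrates correctness of the geometry and
statistics chain under realistic sampling, blur and noise — not robustness
to every real-tissue artifact.

## Segmentation

Per field: Gaussian smoothing (default σ = 0.06, 0.06, 0.12 µm, converted to
voxel units per axis), background subtraction at the field's lower-quartile
intensity, Otsu threshold computed *per cropped field* — per-node crops have
near-bimodal histograms, and staining-batch intensity differences make any
global threshold incomparable across fields — then connected components at
26-connectivity, a volume filter (0.15–10 µm³), and an elongation filter.

The elongation filter deserves its footnote. Principal extents of the
thresholded voxel cloud are inflated by the PSF, and because the axial blur
(σ ≈ 0.2 µm) is much wider than lateral, the inflation depends on
orientation: a 0.7 µm-diameter capsule's second principal extent measures
anywhere from ~0.78 to ~0.97 µm depending on tilt. A ratio cut on raw
extents therefore censors genuinely short paranodes at specific
orientations; worse, a short paranode is nearly indistinguishable in shape
from a round blob, so *any* elongation cut censors the short tail of the
length distribution — group-differentially whenever one group's lengths are
shorter, biasing recovered group differences (we measured ~1–2 percentage
points of attenuation at cuts of 1.2–1.3). The default is therefore 1.0
(disabled): in per-node cropped fields the volume filter alone removes noise
specks. For acquisitions contaminated by round debris the cut can be raised,
and is then applied to deblurred lateral extents (blur full-width subtracted
in quadrature; the long axis is left alone, since a blurred flat edge does
not stretch), which makes the cut act on the structure rather than on the
PSF-fattened mask. The cut, like the volume bounds, is an operator setting
exposed in `segmentation_params()`, tuned on the simulator.

Touching capsules (fused end-to-end nodes) can be split by a seeded
watershed on the anisotropic Euclidean distance transform, triggered for
components longer than `split_min_extent_um`; the two seeds are the distance
maxima of the component's axial halves, so the split lands at the distance
saddle between the capsules. This is off by default — in per-node crops,
over-long components are rare and genuinely long paranodes should not be
shredded.

## Length measurement

All geometry is computed in physical micrometres; voxel indices are
converted exactly once, when components are extracted. Per component, the
voxel cloud's principal axis is taken from the SVD of the centered µm
coordinates, and the intensity profile along the axis is built from voxels
within a 2-voxel-radius tube, binned at a width that adapts to the axial
sampling density (near-axial orientations see the 0.10 µm z-spacing, not the
0.04 µm xy-spacing). The two endpoints are placed where the profile falls to
half its plateau value, scanning from outside in with linear interpolation —
a sub-voxel, threshold-independent definition used consistently for length
*and* width, so that paranode lengths and node width tile the total region.
If no half-maximum crossing exists (degraded profiles), the measurement
falls back to the projected voxel extent plus one mean voxel and is flagged.

Half-maximum endpoints are exactly correct for a blurred *flat* edge, but a
capsule tip is convex: blur erodes it, pulling the crossing inward by an
orientation-dependent amount (up to ~0.07 µm per end at these blur scales).
When the user supplies the total blur sigma and the nominal cap radius,
`paranode_length()` corrects this by phantom calibration: a noiseless
capsule of that radius is rendered at the component's (quantized) tilt on
the same voxel grid, pushed through the identical profile measurement, and
its half-max deficit — which captures blur, tube discretization and binning
effects by construction — is applied as the outward endpoint shift. Phantom
results are memoised, so a cohort with one PSF costs a few dozen phantom
renders. On noiseless capsules this leaves residual errors below ~0.03 µm
with no tilt trend; the suite's orientation-invariance test quantifies the
same at working SNR.

The 2D comparator `project2d_length()` implements the naive measure the 3D
method replaces: the extent of the xy max-projection footprint along its 2D
principal axis. For a capsule at tilt θ its analytic value is
$(L - 2r)\cosθ + 2r$ — the cos θ foreshortening, offset by the cap radius —
and the suite verifies both the foreshortening law and that the 3D measure
is free of it.

## Pairing, node width, total region

Candidate pairs are components whose facing endpoints lie within 3 µm and
whose axes each make ≤ 30° with the inter-endpoint vector; candidates are
scored by the equally-weighted sum of normalized gap and angle and accepted
greedily in ascending score, each component used at most once, ties broken
by smaller gap then smaller label. Greedy matching is used rather than a
global optimum because per-node crops contain few components; the suite
checks greedy–optimal equivalence against an exhaustive oracle on a
thousand random fields. Node-marker (Nav1.6) centroids can be required as
pairing evidence (`require_marker`) but never enter the width measurement:
node width is defined as the distance between the two flanking paranodes'
inner half-maximum endpoints (edge-to-edge, not center-to-center — the
definition that makes width, lengths and total region geometrically
consistent), and total nodal region length as the outer-endpoint distance.
Unpaired components stay available for paranode-length statistics (a
config switch excludes them), since per-figure counts in this literature
show roughly twice as many paranodes as nodes — isolated paranodes are
evidently retained.

## Axon-label classification

The mCherry fill marks the axon core that the CASPR sleeve wraps, so
volumetric overlap between the paranode mask and the axon mask understates
co-axiality. Classification therefore samples the component's *axis line*
at one-voxel steps and asks what fraction of samples lie within 0.2 µm of an
axon-positive voxel; the paranode is labeled when that fraction reaches 0.5,
with ties counting as labeled (a documented rule). The axon channel is
thresholded robustly (median + 4 robust SDs by default) rather than by Otsu,
because an axon-free field has a unimodal noise histogram that Otsu would
split, flooding the dilated line with false positives. The 0.5 line-overlap
criterion is this package's own operational definition of "paranode on a
labeled axon"; the source experiments state no explicit criterion.

## Group statistics

The model is the nested mixed-effects design of the emulated analysis:
`value ~ group + batch` with random intercepts for mouse and — for
paranode-level measures, where two paranodes originate from the same node —
for node nested within mouse, fitted by REML (`lmerTest`). Boundary (zero)
variance estimates are allowed; a batch factor aliased with group is an
error naming the aliased columns; singleton batches warn. Pairwise group
contrasts use Satterthwaite degrees of freedom (the approximate-df method
consistent with fractional df in the emulated reports; it needs only the
fitted covariance, unlike Kenward–Roger) and are reported unadjusted by
default — matching raw pairwise reporting — with Holm available. Group
effects are summarized as percent differences of batch-adjusted estimated
marginal means (raw means available as an option). The axon-specific design
fits `value ~ group * axon_type (+ batch)` with the same random effects; the
labeled-vs-labeled contrast carries the manipulation-specific effect and the
non-labeled contrast is its negative control.

A note on what parameter recovery can and cannot show. The percent
difference between two simulated groups of 6 mice is itself a random
quantity: with a 0.05 µm between-mouse SD its realized value has an SD of
about 1.8 percentage points around the injected effect, before any imaging.
The recovery suite therefore distinguishes pipeline fidelity — measured
versus the cohort's *realized* ground truth, which the implementation
controls — from agreement with the injected population value, which any
single cohort matches only up to mouse-sampling noise. Type-I calibration
of the pairwise contrasts is checked over repeated null cohorts.

## Numerical choices and problem sizes

Deterministic seeding throughout: a cohort seed fans out to per-field child
seeds, so any field can be re-rendered in isolation and identical
configurations give bit-identical outputs. Component principal axes get a
deterministic sign convention. Otsu falls back gracefully on flat fields
(no components, QC-flagged). OME-TIFF stacks store intensities as 32-bit
float scaled by a power of two recorded in the metadata, making write/read
round trips exact after the single initial quantization. Rendered fields
are auto-sized to the structure plus a 3σ PSF margin.

The test suite exercises the pipeline at sizes chosen to probe each claim
with useful power while remaining desk-scale: 500 single-paranode fields
for orientation invariance, 1000 random fields for the pairing oracle, 120
nodes for additivity, 200 null cohorts for type-I calibration, and full
6-mice × 50-node (or 35-node DREADD) cohorts for effect recovery. The
acceptance script regenerates all five recovery cohorts from scratch at
those same sizes.

## Known limitations

Curved paranodes are measured along a straight principal axis; at 1–2 µm
lengths the curvature error is far below the voxel error, but strongly bent
sleeves would be underestimated. No deconvolution is applied; inputs are
assumed to be already-processed intensities. No machine-learned
segmentation, no multi-node axon tracing, no proprietary microscope
formats. The simulator contains no debris, so the shape filters' real-data
selectivity is not validated here. Real acquisitions with PSFs far from
Gaussian would need the blur sigma treated as an effective parameter.
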