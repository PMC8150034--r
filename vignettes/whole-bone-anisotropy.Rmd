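---
title: "Whole-bone trabecular anisotropy and midshaft compactness: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Whole-bone trabecular anisotropy and midshaft compactness: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(osteofabric)
```

## The scientific problem

Bone remodels in response to habitual mechanical load. In taxa that
support their weight on land, gravity and ground reaction forces impose
directed, repeatable stresses, and the internal strut network
(trabecular bone) of a limb bone tends to align with them; in habitually
aquatic taxa the loading regime is weaker and less directional and the
trabecular fabric stays closer to isotropic. Two microanatomical
signals capture this contrast in a single long bone:

1. **The midshaft compactness profile.** A transverse section at the
   narrowest point of the shaft shows, in terrestrial bones, a distinct
   open medullary cavity surrounded by a compact cortex — compactness
   jumps from ~0 at the centre to ~1 at the wall. Aquatic and many
   semi-aquatic bones instead carry trabecular bone throughout the
   cavity, so compactness at the centre is non-zero.
2. **Whole-bone trabecular anisotropy.** Sampling the degree of fabric
   anisotropy (DA) everywhere in the element, rather than in one
   hand-picked cubic volume, yields a frequency distribution whose mode
   separates the two habits: predominantly aligned (modal DA above
   ~0.4) in terrestrial femora versus predominantly isotropic (modal DA
   below ~0.4) in semi-aquatic ones.

`osteofabric` implements both analyses for 3D µCT scans, plus the
segmentation and morphometry they depend on, a synthetic long-bone
phantom generator with exact ground truth, and a correlation-matrix PCA
over the combined variable table.

## Pipeline overview

```
read_volume -> resample_isotropic -> preprocess_volume ->
segment_volume -> { morphometry_table,
                    find_midshaft -> analyse_midshaft,
                    build_lattice -> map_anisotropy ->
                        da_histogram / filter_high / coherence } ->
assemble_features -> pca_correlation
```

All geometry assumes isotropic voxels; `resample_isotropic()` is applied
once, up front, to the smallest input spacing (trilinear). Coordinates
follow a voxel-centre convention: voxel `(i, j, k)` (0-based) sits at
`origin + c(i, j, k) * spacing`, with the third array axis the slice
(proximo-distal) axis after alignment.

## Preprocessing

The conditioning chain is: median filter (kernel 3), intensity-domain
mean-shift smoothing (window 5), third-degree polynomial bias
flattening, and an unnormalized difference-of-Gaussians band-pass
(sigmas 0.75 and 3.0 voxels — the midpoints of the 0.5–1.0 and 2.0–4.0
ranges). Everything computes in double precision whatever the input
dtype. Two interpretations deserve a note:

* **"Mean shift of 5"** is implemented as intensity-domain mean-shift
  smoothing with a 5-voxel spatial window; the range bandwidth defaults
  to half the Otsu inter-class gap, iterated to 1e-3 of the intensity
  range or 10 iterations. A single number cannot pin down both window
  and bandwidth; the window reading preserves step edges, which is what
  the subsequent segmentation needs. On scans where the struts are only
  2 voxels across this smoother can erase them — it belongs to
  resolutions where trabeculae span several voxels.
* **Background overwriting** is handled non-destructively: thresholding
  produces a mask and downstream stages carry it; intensities are never
  mutated.

`threshold_bone()` implements Otsu's criterion exactly (exhaustive
maximization of between-class variance over a 256-bin full-range
histogram), and the test-suite checks it against an independent
brute-force oracle.

## Segmentation

The periosteal envelope ("whole bone") is the morphological closing of
the bone mask (Euclidean ball, default radius 5 voxels) with internal
cavities filled — both in 3D and per transverse slice, so that
fragments cut by the scan boundary still close. Grids are padded with
air before the closing: a structure touching the array face must not
weld to it.

For the cortical/trabecular split we initially implemented a second,
endosteal closing (absorbing struts into the cavity and calling the
bone inside it trabecular). On rod phantoms this is structurally
fragile: one radius must simultaneously absorb multi-strut clusters
(wanting a large radius) and avoid carving pockets into the cortical
wall where struts attach (wanting a small one); no setting satisfies
both. The released rule is instead **depth-based**: a depth map from
the exterior air is compared against a per-slice estimate of the
cortical wall thickness (median local thickness of the bone voxels at
the periosteal surface, running-median smoothed along the shaft, with a
quarter-voxel margin — the thickness estimate itself overshoots the
wall by about half a voxel at the periosteal surface). Bone deeper than the local wall
is trabecular; everything else stays cortical; non-bone voxels inside
the envelope are internal space. Cortical and trabecular labels always
partition the input bone mask exactly. A fixed wall thickness can be
supplied via `segmentation_config(cortical_thickness_um = )` when the
estimate is unreliable (e.g. heavily remodelled or pathological
cortices).

Small trabecular components below `min_component` voxels (default 27)
are reassigned to internal space (`denoise_trabecular()`), mirroring
multi-ROI noise removal. The midshaft is the slice of maximal cortical
area within the contiguous window of slices whose periosteal perimeter
(Crofton estimator, four line families) lies within 2% of the minimum;
the search is confined to the central 25–75% of the occupied extent so
that epiphyses and end caps cannot capture the minimum.

## Morphometry

Areas and volumes are voxel counts scaled by spacing² / spacing³
(reported in mm² / mm³). Local thickness is the
largest-inscribed-sphere definition, computed by sphere painting over
the Euclidean distance transform; the sphere radius at a voxel is its
centre-to-centre distance to the nearest background voxel (the classic
convention), which reads an axis-aligned slab exactly, a digital rod
within half a voxel, and an isolated voxel as two voxels (the sphere
touches the neighbouring background centres). The suite checks equality
with a brute-force maximal-sphere search under the same convention. BV/TV is emitted for both
references — whole bone (TV = labels 1–3) and trabecular compartment
(TV = labels 2–3) — because either convention is defensible; column
`BV/TV` is the whole-bone value and `BV/TV.trab` the compartmental one.
"Average" areas are means over the central 25–75% of the
proximo-distal extent, with midshaft-only values alongside.

## Midshaft compactness profile

The binarized midshaft section (largest component, holes left open) is
divided into 60 angular sectors and 51 radial bins about a centre;
radial distance is normalized per sector to that sector's outermost
bone pixel, so radial coordinate 1 is the periosteal boundary in every
direction. Compactness per cell is the occupied fraction. The profile
is summarized by the four-parameter sigmoid

\[ C(d) = \mathrm{Min} + \frac{\mathrm{Max} - \mathrm{Min}}
          {1 + e^{(P - d)/S}} \]

whose slope at the transition point \(P\) is \((\mathrm{Max} -
\mathrm{Min})/(4S)\): \(S\) is the reciprocal-slope spread. Fits use
bounded Levenberg–Marquardt with five fixed starts (best RSS wins);
per-sector fits report the across-sector mean, SD, and median of each
parameter (the angular variables Rmin, Rmax, P ang, S ang; the mean is
primary). Profiles whose compactness range is below 0.05 are flagged
degenerate and returned as flat.

Three centres are computed: the **section centre** (centroid of the
filled section), the **medullary centre** (centroid of interior
non-bone pixels, falling back to the section centre for solid
sections), and the **ontogenetic centre**. The original tool's
ontogenetic-centre optimization is not published; here it is defined as
the interior point minimizing the total per-sector sigmoid RSS, found
by 1-pixel coordinate descent from the section centre over a coarse
12-sector objective — an interpretation, flagged as such.

The aquatic/terrestrial call is a linear discriminant on Rmin (the
variable that dominates the contrast), with a score of zero resolved to
aquatic. Published coefficient sets can be supplied as a file; because
the source coefficients are not printed anywhere we can cite,
`fit_lifestyle_coefficients()` refits a logistic discriminant on
labelled data (e.g. open- vs filled-cavity phantoms) instead of
shipping invented constants.

## Whole-bone fabric mapping

The sampling lattice is a cubic grid of spherical neighbourhoods with
sample spacing \(s\) = 500 µm, or \(3 \times\) the mean trabecular
width when that width exceeds 167 µm (the changeover where the two
branches meet), and radius of influence \(r = s\), so adjacent
neighbourhoods overlap by exactly half their diameter:
\((2r - s)/(2r) = 1/2\). Centres start at the trabecular bounding-box
minimum corner plus \(s/2\) and stay inside the box; only centres whose
ball touches the trabecular ROI are kept.

Within each ball, surface normals are collected as the normalized
gradient of the Gaussian-smoothed (σ = 1 voxel) trabecular mask at
surface voxels (bone voxels with a 6-connected background neighbour).
The orientation tensor is the trace-normalized mean outer product of
the normals; the **degree of anisotropy** is

\[ \mathrm{DA} = 1 - \lambda_{\min} / \lambda_{\max} \in [0, 1], \]

and the principal material axis is the eigenvector of the smallest
eigenvalue — the direction the normals avoid, i.e. the strut long axis
— reported sign-free with a non-negative slice-axis component. Balls
with fewer than 50 normals are undefined and carry the scalar-map
sentinel value 0; the frequency histogram (bin width 0.05) discards
zeros before binning, and `Ani.M` is the centre of the modal bin (ties
to the lower bin). Plate-like fabrics where the two smallest
eigenvalues nearly coincide set a degeneracy flag rather than receive
an arbitrary axis. High-anisotropy subsets use an inclusive threshold
(default 0.65), and a per-region **coherence** statistic
\((3\eta_1 - 1)/2\) (largest eigenvalue of the mean axis outer-product
tensor; 0 = random axes, 1 = parallel) quantifies "aligned regions of
high anisotropy" along proximal/mid/distal thirds.

The exact anisotropy scalar of the original closed-source
implementation is unpublished, so a second, classical estimator is
included as an in-package oracle: **mean intercept length** fabric over
128 quasi-uniform directions (Fibonacci hemisphere), with the MIL
ellipsoid fitted by least squares on \(1/\mathrm{MIL}^2\) and
\(\mathrm{DA}_{\mathrm{MIL}} = 1 - \mathrm{MIL}_{\min} /
\mathrm{MIL}_{\max}\). The two estimators are required to agree on the
principal axis within 15° and to rank specimens consistently (Spearman
≥ 0.9) across phantoms spanning the DA range; their absolute scales
differ by construction, so histogram comparisons against other software
are qualitative in shape and quantitative only within this package's
definition.

## The phantom generator

`make_long_bone()` builds a tubular cortex (constant or sinusoidal
outer radius) closed by solid end caps, with an air margin beyond both
ends as in a real scan, and fills the medullary cavity with a rod
network: axes drawn from a von Mises–Fisher distribution with angular
scatter σ about the long axis ("terrestrial-like") or uniformly on the
sphere ("semi-aquatic/aquatic-like"), placed until a target fill
fraction is reached within 0.02. Parallel-plate fills exercise the
degenerate-fabric flag; `cavity_fill_extent = "open_midshaft"` leaves
the middle third open. Ground truth carries exact labels, a per-voxel
strut orientation field, the true fill and strut width, and the
analytic radial compactness of the midshaft. Imaging degradation is
Gaussian blur, additive Gaussian noise (SD as a fraction of the
bone/background contrast; SNR = contrast/SD), then a ±10% multiplicative
polynomial bias field; everything is deterministic given the seed.

Default conditions, chosen once as the study conditions: voxel spacing
25 µm (inside the 21.9–32.2 µm range typical of the scans this
emulates), strut radius 60 µm (Tb.Th 120 µm — comfortably inside the
default 500 µm lattice branch, and 4.8 voxels across, i.e. resolved),
fill 0.3, bone 200 / background 50, SNR 5 (noise SD = 0.2 × contrast).
Segmentation-recovery tests use 80 µm struts (6.4 voxels) so that they
measure the segmentation method rather than strut resolvability.

What the phantoms do **not** emulate: plate-rod mixtures and realistic
trabecular curvature, diagenetic infill of fossil pore space, density
gradients within bone, ring or beam-hardening artifacts beyond a smooth
polynomial, and partial-volume physics beyond Gaussian blur. Passing
phantom tests therefore demonstrates correct geometry and estimator
behaviour, not field performance on any particular fossil.

## Numerical choices and degenerate inputs

* Morphology uses exact Euclidean distance transforms (ball structuring
  elements); closings pad the grid with background first.
* The long-axis alignment falls back to the identity (with a flag) when
  the two leading inertia eigenvalues differ by < 2%.
* Sigmoid fit bounds: Min, Max, P in [0, 1]; S in [1e-3, 2]. Min/Max
  are swapped if the optimizer converges inverted.
* DA of an exactly isotropic tensor is 0 by construction; λ₃ is clamped
  at 0 against round-off.
* Problem sizes in the test-suite: phantoms of ~104×104×256 voxels
  (defaults) down to ~70×70×150 for repeated-seed loops; fabric
  estimator comparisons run on 48³ rod cubes. The dedicated
  repeated-seed segmentation check runs 5 + 3 seeds.
* The pipeline's cache is a single configuration hash per run
  directory: outputs are regenerated whenever the hash or any expected
  artifact is missing or stale.

## Known limitations

* The wall-thickness estimate behind the cortical/trabecular split
  assumes the cortex is the dominant structure at the periosteal
  surface in every slice; highly porous or fenestrated cortices may
  need the `cortical_thickness_um` override.
* The trabecular-width lattice rule uses the mean local thickness of
  the trabecular label, which carries the half-voxel discrete bias; at
  the 167 µm changeover this can select 500 µm where 3×Tb.Th was
  intended (both are defensible at the boundary).
* Mean-shift smoothing erases structures ≤ 2 voxels across; on such
  scans run the chain without it (the driver exposes each stage
  separately).
* The MIL estimator drops directions without crossings; on very sparse
  masks fewer than 9 usable directions is an error, not a guess.
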