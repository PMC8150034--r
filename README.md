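# osteofabric

Whole-bone trabecular anisotropy mapping and midshaft compactness
profiles for µCT scans of long bones, in R.

## What it is for

Bone remodels under habitual mechanical load (bone functional
adaptation). In limb bones of terrestrial tetrapods the trabecular
network aligns with the directed stresses of weight support, and the
midshaft shows an open medullary cavity; in habitually aquatic taxa the
fabric stays near-isotropic and the cavity is typically filled with
trabecular bone. `osteofabric` extracts both signals from a 3D µCT
scan, for workers in vertebrate palaeontology and comparative skeletal
biology who want to infer locomotor habit from internal bone
architecture:

* **Whole-bone fabric mapping.** The trabecular compartment is sampled
  on a cubic lattice of overlapping spherical neighbourhoods (sample
  spacing *s* = 500 µm, or 3 × Tb.Th when the mean trabecular width
  exceeds 167 µm; radius of influence *r* = *s*, giving 50% overlap).
  Each neighbourhood yields an orientation tensor **C** = ⟨**n n**ᵀ⟩
  over the bone-surface normals, a degree of anisotropy
  DA = 1 − λ_min/λ_max ∈ [0, 1], and a principal (strut) axis. Outputs
  are vector/scalar maps, the zero-excluded DA frequency histogram and
  its mode (Ani.M), a high-anisotropy subset (DA ≥ 0.65), and a
  per-region axis-coherence summary. A classical mean-intercept-length
  estimator is included as an independent cross-check.
* **Midshaft compactness profile.** At the narrowest shaft section, the
  radial bone-occupancy profile per angular sector is fitted with the
  sigmoid C(d) = Min + (Max − Min)/(1 + exp((P − d)/S)); the angular
  means of (Rmin, Rmax, P, S), the observed global compactness Cg, and
  a binary aquatic/terrestrial discriminant on Rmin summarize the
  section.
* **Supporting stages.** Volume IO (NRRD, MHD+RAW, TIFF stacks),
  the preprocessing chain (median 3, mean-shift 5, third-degree
  polynomial flattening, unnormalized DoG), automatic
  cortical/trabecular/cavity segmentation, standard morphometry (BV,
  TV, BV/TV, Tt.Ar, Ct.Ar, Ma.Ar, Ct.Ar/Tt.Ar, Ct.Th, Tb.Th, P–D,
  R/t), a parametric long-bone phantom generator with exact ground
  truth, and a correlation-matrix PCA over the combined variable table.

## Worked example

No scan at hand is needed — the phantom generator stands in for one:

```r
library(osteofabric)

# a terrestrial-like femur phantom: rods aligned with the long axis
spec  <- phantom_spec(trabecular_model = "aligned_rods",
                      scatter_deg = 7, seed = 7)
ph    <- make_long_bone(spec)
seg   <- segment_volume(median_filter(ph$volume, 3))
lab   <- seg$label

tb    <- local_thickness(lab$labels == 2L, lab$spacing[1])$mean_um
lat   <- build_lattice(lab, tb)
field <- map_anisotropy(lab, lat)
hist  <- da_histogram(field)

print(field)
#> <anisotropy_field> 99 samples (99 defined), lattice s = r = 500 µm
hist$mode
#> [1] 0.925
median(field$samples$da[field$samples$defined])
#> [1] 0.906
```

A modal DA of 0.93 with nearly all sample axes along the shaft is the
aligned, "terrestrial-like" signature. The same run on an
`isotropic_rods` phantom gives a modal DA of about 0.3 — the
isotropic, "semi-aquatic-like" signature — so the two fabrics sit on
opposite sides of the 0.4 line that separates the habits. The midshaft
of a filled-cavity section keeps a non-zero compactness floor:

```r
cs <- make_cross_section(fill = 0.5, seed = 3)
an <- analyse_midshaft(cs$section, cs$spacing_um)
round(an$angular$mean, 3)
#>   min   max     p     s
#> 0.487 1.000 0.725 0.009
```

`Rmin` ≈ 0.49 ≈ the true cavity fill, and `P` ≈ 0.73 matches the
endosteal radius of the section. An end-to-end run over several
specimens — segmentation, morphometry, compactness, fabric, PCA, with
caching and a run log — goes through `run_all()` (see
`?run_config`), or the `inst/cli/osteofabric` script from a shell.

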