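# cortexCT

Semi-automated quantification of cortical-bone degradation in murine
metatarsals from micro-CT image stacks.

In murine arthritis models, bone erosion starts at the metatarsophalangeal
joint and progresses along the shaft, so the informative quantity is not an
average thickness but the **cortical thickness profile**: wall thickness as a
function of the longitudinal distance ξ above the joint. cortexCT extracts
this profile from an isotropic micro-CT stack plus two manual annotations per
bone (a point inside the bone on one slice, and the joint's slice index), and
summarises it with two dimensionless scalars:

* **CTG** (cortical thickness gradient): the slope *k* of a least-squares
  line through the angularly averaged thickness Ψ̄(ξ) ≈ *k*·ξ + *m*.
  Thinning near the joint — the arthritic pattern — gives *k* > 0.
* **CTI** (cortical thickness index): wall thickness relative to the outer
  radius, (r_out − r_in)/r_out, averaged over all measurement rays.

The pipeline:

1. **Texture segmentation** — each slice is convolved with a bank of 36
   Gabor + 4 difference-of-Gaussians filters and pixels are split into
   bone/background by 2-cluster k-means (k-means++ initialization). Unlike
   global thresholding, this separates adjacent bones bridged by
   intermediate-intensity soft tissue, and it is invariant to affine
   intensity rescaling.
2. **Bone isolation** — from the seed point, the bone's 8-connected region
   is tracked slice-to-slice (successor = overlapping region with the most
   similar area), yielding the bone's centerline.
3. **Orthogonal resampling** — cross-sections are re-sampled orthogonal to
   the local bone axis, so thickness does not depend on how the paw lay in
   the scanner.
4. **Cortical metrics** — 25 rays per cross-section locate the inner/outer
   perimeter with sub-pixel precision; by default the final crossings are
   located on the resampled *grayscale* at half-max intensity levels
   (unbiased under a symmetric scanner PSF), with the segmentation mask
   providing tracking and reference levels.

A synthetic **phantom generator** with analytic ground truth (tubes with
linear radius profiles; tilted, curved, tapered and bridged-pair presets)
validates every stage without scan data.

## Worked example

Generate an "arthritic" phantom (cortex thinning toward the joint with true
CTG = 0.010), segment it, and measure it end to end:

```r
library(cortexCT)

p  <- phantom_suite("tapered_ctg10e-3")[[1]]   # spec + seed + range
ph <- generate_phantom(p$spec)
print(ph$stack)
#> ct_stack: 72 x 72 px, 146 slices, voxel 14.599 um
#>   intensity range [-24.8, 274]

bank <- filter_bank()
print(bank)
#> Texture filter bank: 40 filters (36 Gabor, 4 DoG)
#>   kernel supports: 11-37 px

mask <- segment_stack(ph$stack, bank)          # ~40 s for 146 slices
dice(mask, ph$truth$mask)
#> [1] 0.9467

m <- measure_bone(mask, p$seed,
                  voxel_size_um = p$spec$voxel_size_um,
                  range_mm = p$range_mm,
                  stack = ph$stack)            # grayscale-refined measurement
print(m)
#> Cortical profile of bone 'bone'
#>   CTG (slope k)  : +0.0096
#>   intercept m    : 0.1214 mm
#>   average CTI    : 0.448
#>   positions used : 82 (xi 0.76-1.94 mm), fit RMS 0.0004 mm
```

Ground truth for this phantom is CTG = 0.010 and CTI = 0.445 over the
measured range, so the full pipeline recovers the taper to within 0.0004 and
the thickness index to within 0.7%. `plot(m)` shows Ψ̄(ξ) with the fitted
line; `m$profile` holds the full Ψ(ξ, θ) field.

For real scans, use `read_stack("scan.tif", voxel_size_um = 14.599)`,
`read_seeds("seeds.csv")` and either `run_pipeline()` or the CLI installed
under `inst/cli/`:

```sh
cortexCT run --stack scan.tif --seeds seeds.csv --config run.yaml --out results/
cortexCT phantom --preset adjacent_bones_bridged --out phantom_out/
```

All tunables live in one YAML config (see `default_run_config()`); outputs
include per-bone profile CSVs, a combined `metrics.csv`, and a metadata file
with the configuration hash and seeds. Reruns with identical inputs produce
byte-identical CSVs.

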