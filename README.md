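# gsdiff

Gaussian-prompted diffusion segmentation of multimodal tumor volumes in R.

## What problem this addresses

Radiotherapy planning for nasopharyngeal carcinoma requires delineating the
gross tumor volume (GTV: the primary tumor GTVp and involved nodes GTVnd)
from several co-registered volumes — CT, contrast-enhanced T1 MRI (T1-ce)
and T2 MRI — each showing a different partial view of the tumor. Naive
multimodal fusion drowns the tumor signal in redundant background. This
package implements a two-stage alternative for researchers in medical image
analysis:

1. **Clinical-prior-guided Gaussian feature extraction.** Each modality is
   distilled into an *intensity-valued 3D Gaussian field*: a set of points
   with mean μ, SPD covariance Σ = R diag(s²) Rᵀ (unit-quaternion R) and
   intensity *i*, with field value

   G(x) = i · exp(−½ (x−μ)ᵀ Σ⁻¹ (x−μ)),

   fitted by gradient optimization so that its additive rendering
   reconstructs a prior-defined regional image: the thresholded enhanced
   (cancer+vessel) region on T1-ce, the vessel region (enhanced ∖ GTV) on
   T2, and the bone-destruction region (GTV ∩ bone) on CT.

2. **Prompt-conditioned diffusion segmentation.** A DDPM with a
   relation-encoding denoiser (CT-conditioned U-Net) is pretrained to
   generate two-channel GTV masks from noise given the CT. At sampling
   time each fitted field is marginalized along z into a 2D Gaussian splat
   and injected into the per-step noise over a windowed, coarse-to-fine
   modality schedule — reverse steps 1–350 (T1-ce), 351–700 (T2),
   701–1000 (CT) at T = 1000, scaled proportionally for other T — so the
   trajectory is steered first to a coarse cancer range, then away from
   vessels, then into bone-destruction territory.

Because the clinical data for this problem are confidential, the package
ships a seeded multimodal head-phantom generator that encodes exactly the
modality contrasts above, plus preprocessing (HU clipping to ±1000, [0,1]
scaling, isotropic resampling), segmentation metrics (DSC, ASSD, HD95 with
explicit surface conventions), and an end-to-end seeded pipeline.

## Worked example

```r
library(gsdiff)

# one synthetic case with all three modality contrasts
b <- generate_case(phantom_config(seed = 1))
print(b)
#> <case_bundle> 64x64x16, seed 1: GTVp 581 vox, GTVnd 127 vox, vessels 388 vox, bone 1464 vox

# clinical-prior targets (auto Otsu threshold on T1-ce, 0.65 on CT)
tg <- prior_targets(b)
print(tg)
#> <prior_targets>
#>   enhanced_t1ce        969 voxels
#>   vessel_t2            388 voxels
#>   bone                 1464 voxels
#>   bone_destruction_ct  164 voxels
#>   thresholds: t1ce 0.5156, bone 0.65

# fit a 256-point Gaussian field to the enhanced region
fit <- gs_fit(locate_region(b$t1ce, tg$enhanced_t1ce),
              n_points = 256, iterations = 400, seed = 1)
print(fit)
#> <gsfit T1CE> 256 points, 400 iterations
#>   loss (L2): 1.09946 -> 0.000863971 (0.1% of initial)
```

The fitted rendering correlates with its target region at r ≈ 0.967, and
`splat_2d(fit$field)` gives the 2D prompt image used during sampling. The
numbers above are what the code prints at these seeds: the fit reduces the
reconstruction loss to a fraction of a percent of its initial value, and
the prior masks recover the phantom's ground-truth regions (Jaccard ≈ 1).

A desk-scale end-to-end run (phantoms → priors → field fits → DDPM
training → prompted sampling → metrics) is one call:

```r
man <- run_pipeline(pipeline_config(global_seed = 1, n_cases = 5))
```

which writes NIfTI volumes, fields, the model, predictions, a metric table
and a manifest with per-stage seeds and file hashes under the output root.

## Layout

- `R/`, `src/` — implementation (R interface, C++ rendering and conv3d kernels)
- `tests/testthat/` — unit, property and acceptance tests
- `vignettes/gaussian-prompted-diffusion.Rmd` — the methods vignette:
  model, parameter choices, numerical decisions, phantom design, limits
- `inst/cli/gsdiff` — thin command-line front end (phantom / priors /
  evaluate / run)
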