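# isgtomo

Mesoscale modelling of insulin secretory granules (ISGs) and simulation
of soft X-ray tomograms, in R.

Pancreatic beta cells store insulin in dense-core vesicles that mature
from proinsulin-filled granules into granules dominated by a single
insulin crystal. Soft X-ray tomography (SXT) images whole beta cells at
50–60 nm resolution and measures the linear attenuation coefficient
(LAC, µm⁻¹) of every voxel — an absolute density-like quantity in the
water window (517 eV). `isgtomo` closes the loop between proteomics and
SXT:

1. **Proteome reconciliation** — score every candidate ISG protein by
   its localisation evidence. For each annotation keyword,
   `LocScore(loc) = fracPositives − fracNegatives` against a curated
   positive set; a protein's confidence is
   `N_proteome · (W_loc Σ LocScore + W_intloc Σ IntLocScore)`,
   min–max normalised to [0, 1], with the weight pair (12, 1) selected
   by a ROC-AUC sweep (`sweep_weights()`).
2. **Copy-number recipes** — NSAF molar fractions → mass fractions →
   absolute copy numbers for a vesicle of given geometry, anchored by
   the insulin crystal: a 200 nm crystal of the rhombohedral hexamer
   lattice at volume occupancy ≈ 0.686 holds ~3.6×10⁵ monomers; the
   crystal carries mass fraction 0.8, all other proteins 0.2.
3. **3D model building** — procedural crystal lattice, stochastic grid
   packing of the lumen and cytoplasm, membrane proteins and a
   two-leaflet DOPC lipid tiling, soft-overlap relaxation, six discrete
   maturation states, and a 3,456-entry model library
   (16 diameters × 6 crystal sizes × 6 steps × 6 cytoplasm
   concentrations).
4. **Tomogram simulation** — voxelise the model into a LAC volume via
   the mixture rule (mass-fraction-weighted mass attenuation
   coefficients), project, blur (60 nm PSF), add Poisson shot noise and
   alignment jitter, reconstruct by filtered back-projection, and
   average 10 replicates.
5. **Feature interpretation** — multi-scale Laplacian-of-Gaussian blob
   detection with tuned thresholds, radial profiles, and R² fitting
   against the simulated library to classify each feature as an
   immature, transitional or mature vesicle.

## Worked example

Simulate the idealised mature and immature granules (320 nm vesicle,
200 nm crystal capacity, 0.2 g ml⁻¹ cytoplasm) and profile them:

```r
library(isgtomo)

op  <- projection_operator(replicates = 3)   # use 10 for the full protocol
mat <- study_vesicle_peak(step = 6, op = op, seed = 1)
imm <- study_vesicle_peak(step = 1, op = op, seed = 1)

round(c(mature = mat$peak, immature = imm$peak,
        cytoplasm = mat$cytoplasm_mean), 3)
#>    mature  immature cytoplasm
#>     0.767     0.479     0.279
```

The mature granule's insulin crystal dominates its radial-profile peak
(0.767 µm⁻¹ here, vs 0.479 for the proinsulin-filled immature granule
and 0.279 for surrounding cytoplasm — all absolute LACs, µm⁻¹ at
517 eV). Applying the segmentation
protocol to a simulated tomogram containing both granules:

```r
det <- study_detection_asymmetry(op = projection_operator(replicates = 3),
                                 train_op = projection_operator(replicates = 2),
                                 seed = 3)
det$mature_detected        #> TRUE
det$immature_detected      #> FALSE
round(det$contour_diameter_nm)  #> 191
```

The detector threshold, tuned on confidently visible (mature) training
vesicles, sits above the immature granule's contrast: a pool of immature
granules can be invisible to this kind of segmentation, while the mature
granule is recovered with a contour diameter close to its crystal size.

A command-line wrapper for the pipeline stages
(`score`, `recipe`, `build`, `simulate`, `fit`, `fixtures`) is installed
at `inst/scripts/isgtomo`.

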