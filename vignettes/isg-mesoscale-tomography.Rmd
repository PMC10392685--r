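---
title: "Mesoscale models of insulin secretory granules and simulated soft X-ray tomograms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mesoscale models of insulin secretory granules and simulated soft X-ray tomograms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(isgtomo)
```

## The problem

Insulin secretory granules (ISGs) are the dense-core vesicles in which
pancreatic beta cells store insulin. Immature granules are filled with
proinsulin; during maturation, proteases cleave proinsulin to insulin and
C-peptide, and insulin condenses into a single crystal that fills most of
the granule. Soft X-ray tomography (SXT) images whole cells in near-native
conditions at 50--60 nm resolution and measures an absolute physical
quantity per voxel: the linear attenuation coefficient (LAC, units
µm^-1^), which in the "water window" (here 517 eV) is roughly proportional
to organic density. `isgtomo` builds quantitative coarse-grained 3D models
of ISGs from proteomics data and simulates the SXT image formation, so
that features detected in experimental tomograms can be interpreted in
molecular terms: which vesicle size, crystal size, maturation state and
cytoplasm density best explain each observed blob.

## Reconciling proteomes: the confidence score

Published ISG proteomes disagree; contaminant organelles (mitochondria,
nuclei, lysosomes) leak into every isolation protocol. The package scores
each candidate protein by its localisation evidence. A curated set of
true positives and the remaining proteins as trial negatives define, for
every location keyword,

```
LocScore(loc) = fracPositives(loc) - fracNegatives(loc)
```

so that vesicle-associated keywords score towards +1 and contaminant
keywords towards -1. An analogous table (`IntLocScore`) is built from the
keywords of each protein's interactors, on the assumption that
interaction partners share a compartment; each interactor contributes its
keyword set once, and a protein's interactor evidence is the multiset sum
over its interactors. The confidence of protein *p* is

```
raw(p) = N_proteome(p) * ( W_loc * sum LocScore + W_intloc * sum IntLocScore )
```

min--max normalised to [0, 1] over the scored roster. Two representational
choices deserve comment. The difference-of-fractions form is used (rather
than a ratio or log-odds) because negative-evidence keywords must be able
to pull scores down, and because the per-keyword positive/negative
fractions are the natural published summary of the training tables. The
min--max normalisation is per-dataset: reported confidences (for example
a midrange 0.21 or 0.76) are comparable within one scored roster, not
across rosters. The weight pair defaults to `(12, 1)`, the value selected
by a ROC-AUC sweep; `sweep_weights()` re-runs that sweep on any catalog,
with midrank (Mann--Whitney) tie handling and deterministic tie-breaking
towards smaller weights. No cross-validation is performed -- the curated
set is small -- so the high scores of training positives partly reflect
training bias; ranked outputs are intended as a review queue
(`rank_and_flag()` flags confidence > 0.333 or presence in two or more
proteomes), not as final assignments.

## From abundances to a buildable recipe

Per study, raw abundance metrics are length-normalised and scaled to sum
to one (NSAF, a molar-fraction estimate), multiplied by molecular weight
and renormalised into mass fractions. A protein observed in several
proteomes receives the mean of its per-study mass fractions; the pooling
rule is not dictated by the data and the mean is the neutral choice.
Manual exception hooks reproduce the documented curation steps: IAPP is
set to 1% of insulin copies, multi-subunit complexes (vATPase) get the
mean of stoichiometry-normalised subunit counts, and implausible
single-study values can be excluded before pooling. Curated proteins
missing from all proteomes receive a configurable floor fraction
(default 10^-4^ of the non-insulin mass).

Absolute numbers come from the insulin crystal. The most common hexameric
insulin crystal form is a rhombohedral lattice (hexagonal setting,
three hexamers per cell); its volume occupancy is

```
occupancy = z * asym_mw / (N_A * rho_protein * V_cell),   rho_protein = 1.22 g/cm^3
```

which evaluates to 0.685 for the bundled rhombohedral metadata. A 200 nm
crystal at that occupancy holds ~3.6x10^5^ insulin monomers (5,808 Da),
inside the literature range of 2x10^5^--10^6^ per granule. Non-insulin
protein is scaled so the crystal carries mass fraction 0.8 and everything
else 0.2. The bundled crystal-form table marks each row as either a
transcription of the public database entry or an approximate stand-in
(`verified` column); the monoclinic row is approximate.

## Building the model

Compartments are signed distance fields (spheres and boolean
combinations). The crystal is placed procedurally: hexamer positions on
the rhombohedral lattice, carved by a spherical boundary, all with one
orientation (a coherent crystal; no randomness). Everything else is
packed stochastically: space is partitioned into cells matched to each
ingredient's bounding sphere, fitting cells are sampled without
replacement, positions are jittered within cells and orientations are
uniform random quaternions; a random-close-packing guard (64% of free
volume) rejects infeasible requests. Proteins are represented by K-means
bead models (17 Å beads; bead count = molecular weight / ~15.1 kDa, the
mass a 17 Å sphere holds at 1.22 g/cm^3^), with per-bead mass shares that
sum exactly to the molecular weight. Structures can be read from PDB or
mmCIF files; deposited structures usually lack hydrogens, so H counts are
inferred from per-residue templates (they matter for soft X-ray
attenuation). When no structure is available, a synthetic globule of
matching mass and mean protein composition
(H:C:N:O:S = 0.498:0.320:0.085:0.095:0.002 by atom count) stands in.

Overlaps are relieved by soft-potential relaxation: beads repel with
force proportional to overlap depth (zero beyond contact), instances
translate along the summed force, membrane-anchored instances keep their
radial distance, and out-of-boundary instances are reflected back. Full
Langevin rigid-body dynamics is deliberately not reproduced: for
tomogram simulation at 37 nm voxels, relaxed and unrelaxed models give
nearly identical radial profiles, so model building defaults to no
relaxation and `relax()` is available where contact-level realism
matters.

The membrane is two lipid leaflets on Fibonacci lattices at the
mid-bilayer radius ± a quarter bilayer. The per-lipid area comes from the
molecular volume (1,150 Å^3^, DOPC) divided by the leaflet thickness
(2.5 nm for the default 5 nm bilayer), i.e. 46 Å^2^ -- equivalent to a
5 nm shell of full-density DOPC, the upper end of physically sensible
lipid loading.

Maturation is discretised in six steps. The cleaved fraction grows
linearly from step 1 (all proinsulin) to step 6 (all insulin); of the
cleaved insulin, the crystallised fraction grows quadratically, so
transitional states hold free monomer in the lumen. Every cleavage also
releases a C-peptide (3,020 Da), which stays in the lumen -- mature
granules are therefore modelled with a C-peptide-rich lumen around the
crystal. Proinsulin is 9,390 Da, so an immature granule holds ~1.6x the
insulin-core protein mass in its lumen, which is what makes it visibly
denser than cytoplasm in the simulations. The fitting library enumerates
16 vesicle diameters (geometric spacing, 130--473 nm), six crystal sizes
(0.2--0.7 of the diameter, capped by geometry), six maturation steps and
six cytoplasm concentrations (0.06--0.2 g/ml): 3,456 entries, with
soluble and membrane protein counts scaled linearly with each entry's
insulin content. Geometric diameter spacing and proportional crystal
sizes are package choices; the published grid states only the ranges and
counts.

## X-ray attenuation

Elemental photoabsorption is tabulated in
`inst/extdata/photoabsorption_f2.tsv`: imaginary scattering factors f2
computed with the relativistic Cromer--Liberman method (via the gemmi
crystallographic library) on an energy grid covering the water window,
linearly interpolated; MAC = 2 r_e λ N_A f2 / A. Composite materials use
the mixture rule (mass-fraction-weighted MACs). Protein attenuation is
always computed from atomic composition. For the two reference materials
the simulator uses published benchmark constants at 517 eV -- water
1,114.279 cm^-1^ at unit density and DOPC 9,264.835 cm^-1^ at bilayer
density -- because these are the values established for water-window
imaging. The bundled element table reproduces DOPC within ~2% but water
only within ~6%: isolated-atom Cromer--Liberman coefficients
underestimate oxygen's sub-edge absorption relative to the empirical
tabulations behind the benchmarks. This ~5% scale uncertainty on
oxygen-dominated materials is a known limitation and is inherited by all
simulated LAC values.

Voxelisation deposits bead masses trilinearly onto the grid
(37.42 nm voxels by default, matching the experimental pixel size),
weights deposited mass by each ingredient's MAC, and fills the remaining
voxel volume with water. Total solute mass is conserved exactly.

## Simulating the tomogram

Image formation follows the experimental chain: parallel-beam projection
around the vertical axis (120 angles over 180°), Gaussian optical PSF of
FWHM 60 nm (the instrument resolution; the true PSF is not published),
uniform sub-pixel jitter of ±0.5 voxel per projection (alignment error),
Poisson shot noise at 5,000 photons/pixel (a typical water-window
exposure; not published), filtered back-projection with a Ram--Lak
filter, and averaging of 10 independent reconstructions. PSF width,
angles, photon budget, jitter and replicate count are all parameters of
`projection_operator()`. The projector uses a detector wide enough to
cover the grid diagonal so no mass is lost at any tilt angle, which keeps
the reconstruction on the absolute LAC scale (a uniform 0.3 µm^-1^ block
reconstructs to within ~2% away from edges).

Radial profiles are means over concentric annuli, one voxel (37.42 nm)
per bin, in the x--z slice through the feature -- so "six radial points"
spans ~225 nm, the vesicle scale, and 15 points include surrounding
cytoplasm. Whether published profiles were taken on a slice or a
projection is not stated; the central slice is used here because
profile values then remain absolute LACs. Profile centers default to the
brightest voxel (first-index tie-break; in `classify_map()` ties resolve
towards the detected blob center, which matters for idealised phantoms
with uniform crystal cores).

With the bundled tabulation, the simulated idealised granules
(320 nm vesicle, 200 nm crystal capacity, 0.8/0.2 mass split,
0.2 g/ml cytoplasm) give central-slice peaks of ~0.77 µm^-1^ (mature,
the crystal core at occupancy density) and ~0.48 µm^-1^ (immature) and
a reconstructed cytoplasm level of ~0.28 µm^-1^. Published values for
the same idealised pair (0.538 and 0.437) are better matched by the
immature granule than the mature one; the mature peak is the quantity
most sensitive to whether profiles are taken on a slice or a
thickness-averaged projection, and to the absolute protein attenuation
scale discussed above.

### The membrane share

`membrane_contribution()` simulates the same model with and without its
lipids under a shared seed. Three statistics are available. The default,
`"contrast"`, reports the membrane's share of the feature's signal above
the measured cytoplasm background, area-weighted over the blob footprint
-- this is the quantity the blob detector itself responds to, and the
natural reading of "share of the observed absorbance of a feature" for
features that are observed as excess absorbance. It evaluates to ~20--25%
for the idealised granules. The `"mean"` statistic (share of the absolute
footprint mean) evaluates to ~6%: with a 5 nm full-density bilayer the
membrane cannot reach 10% of the absolute absorbance, because the
footprint is dominated by lumen/crystal protein and water. The `"peak"`
statistic is near zero for crystal-cored vesicles (the rim does not touch
the central voxel). The spread of these three readings brackets the
published 10--20% and is reported deliberately rather than collapsed.

## Detecting and classifying features

Blob detection is scale-normalised Laplacian-of-Gaussian over a ladder of
scales, with local maxima over space and scale, parabolic interpolation
in log-scale, overlap suppression on sphere IoU (> 0.3 keeps the stronger
response) and a response threshold. Detected radius is σ√3 (the 3D
scale-selection identity); when the optical PSF is known, the detected
scale is deconvolved (σ_obj² = σ² − σ_PSF²) so sizes refer to the object,
not its blurred image. The threshold is tuned on labelled responses --
planted, confidently visible mature vesicles (250--470 nm) as positives
and random cytoplasm sites as negatives -- maximising accuracy with ties
broken towards the higher threshold. The high tie-break is what creates
the documented detection asymmetry: the tuned threshold sits just below
the weakest confident positive, and the immature granule's
contrast (~0.17 µm^-1^ above cytoplasm vs ~0.5 for mature) falls below
it (the immature granule sits ~0.2 µm^-1 above cytoplasm, the mature
one ~0.5). On the simulated two-vesicle scene the mature granule is
detected with a PSF-corrected contour diameter of ~190-196 nm and the
immature one is missed.

Each detected blob is profiled and fitted against the library by R²
(1 − SS_res/SS_tot) over the first 6 bins (vesicle) and 15 bins (vesicle
plus cytoplasm); the best entry maximises the 6-bin score with ties
broken by the 15-bin score, then entry id. Maturity classes: step 1 =
immature, steps 2--5 = transitional, step 6 = mature. A constant
experimental profile makes R² undefined and is reported per blob as an
error, not silently scored.

## Synthetic data: what it does and does not show

`generate_catalog()` emulates the *structure* of curated localisation
evidence -- class-conditional Bernoulli keywords with configurable
enrichment odds, interactor multisets with Poisson interactor counts and
optional class purity, and proteome memberships -- not the vocabulary or
correlation structure of real annotation databases. Keywords are drawn
independently, whereas real annotations are strongly correlated
(ontology structure, annotation propagation), so passing recovery tests
here shows the scoring machinery is correct, not that real proteomes
will separate this cleanly. For weight-recovery studies the generator's
`interactor_purity` and keyword tables control the injected
informativeness ratio of location vs interactor evidence; the
calibration uses presence-level keyword statistics because the score
tables operate on keyword presence, not draw counts.

`generate_phantom()` builds idealised spherical granules via the full
model pipeline and also returns the closed-form concentric-shell LAC
volume for oracle comparisons. The shell phantom is exactly uniform in
its cytoplasm; the molecular model shows ~2.5% voxel-level CV from
molecular counting statistics (≈100 proteins of ~40 kDa per 37 nm voxel
at 0.2 g/ml), which is physical granularity, not an artefact. Real
granules are neither perfectly spherical nor single-crystal-centred;
size and shape dispersion are outside the idealised study conditions.

## Problem sizes and numerical choices

The test suite runs the simulation studies at reduced budgets (3
replicate reconstructions, 2 for training scenes, 60--120 tilt angles,
65-voxel embeddings) so the whole suite completes in minutes; the
reproduction script `scripts/acceptance.R` uses the full 10-replicate
protocol for the profile studies. Reconstructions are clipped at zero
(LACs are nonnegative); the clip is inactive wherever there is cytoplasm
background. FFT filtering zero-pads to the next power of two. All
randomness flows from one master seed through the documented splitter
`split_seed()` (stream-indexed linear congruence below 2^31), so every
stage can be re-run independently and the full build is bit-reproducible
under a fixed seed.

## Known limitations

- The elemental photoabsorption tabulation is theoretical
  (Cromer--Liberman); oxygen-dominated absolute LACs carry ~5%
  uncertainty (see above), proteins (carbon/nitrogen-dominated) less.
- The monoclinic crystal-form metadata row is an approximate stand-in,
  flagged as unverified in the bundled table.
- Lipid tiling is a uniform two-leaflet lattice, not patch-wise cuts
  from equilibrated bilayers; membrane proteins are anchored at the
  mid-bilayer radius without explicit transmembrane geometry.
- The reconstruction chain is a generic parallel-beam FBP; beamline
  optics, missing-wedge effects and capillary absorption are not
  modelled.
- Confidence scores are trained without cross-validation on a small
  curated set and inherit its bias.
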