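Package: isgtomo
Title: Mesoscale Modelling of Insulin Secretory Granules and Simulation of
    Soft X-Ray Tomograms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An integrative pipeline for mesoscale modelling of insulin
    secretory granules (ISGs) in pancreatic beta cells. Reconciles multiple
    ISG proteomes into a confidence-ranked component list using localisation
    annotation scoring, converts abundance metrics into copy-number recipes,
    constructs coarse-grained 3D vesicle models (immature through mature)
    with a procedural insulin crystal, stochastic compartment packing,
    soft-overlap relaxation and lipid membrane tiling, simulates soft X-ray
    tomograms of the models via the linear attenuation coefficient mixture
    rule and filtered back-projection with realistic noise, and fits
    simulated radial profiles to blob features detected in tomographic
    volumes to classify vesicle maturation state.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    bio3d,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
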