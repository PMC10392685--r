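# Shared fixtures for the test suite.  Everything is built in code.

# six proteins, two keywords, hand-countable memberships
tiny_catalog <- function() {
  locations <- list(
    p1 = c("vesicle"), p2 = c("vesicle", "nucleus"), p3 = c("vesicle"),
    n1 = c("nucleus"), n2 = c("nucleus"), n3 = character(0)
  )
  interactor_locations <- list(
    p1 = c("vesicle", "vesicle"), p2 = c("vesicle"), p3 = character(0),
    n1 = c("nucleus"), n2 = c("nucleus"), n3 = character(0)
  )
  proteomes <- list(
    p1 = c("P1", "P2", "P3"), p2 = c("P1", "P2"), p3 = "P1",
    n1 = c("P1", "P2"), n2 = "P2", n3 = "P3"
  )
  annotation_catalog(locations, interactor_locations, proteomes)
}

tiny_labels <- function(catalog = tiny_catalog()) {
  labelled_set(c("p1", "p2", "p3"), c("n1", "n2", "n3"), catalog)
}

# deterministic small operator for fast simulations
fast_op <- function(replicates = 1, photons = Inf, jitter = 0, psf = 0,
                    n_angles = 60) {
  projection_operator(psf_fwhm_nm = psf, n_angles = n_angles,
                      photons = photons, jitter_voxels = jitter,
                      replicates = replicates)
}

# minimal synthetic single-residue glycine PDB file
write_glycine_pdb <- function(path) {
  lines <- c(
    "ATOM      1  N   GLY A   1       0.000   0.000   0.000  1.00  0.00           N",
    "ATOM      2  CA  GLY A   1       1.458   0.000   0.000  1.00  0.00           C",
    "ATOM      3  C   GLY A   1       2.009   1.420   0.000  1.00  0.00           C",
    "ATOM      4  O   GLY A   1       1.251   2.390   0.000  1.00  0.00           O",
    "ATOM      5  OXT GLY A   1       3.260   1.530   0.000  1.00  0.00           O",
    "END")
  writeLines(lines, path)
  path
}
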