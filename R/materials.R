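# X-ray absorption of biological materials in the water window.
#
# Linear attenuation coefficients (LAC, micrometre^-1) are obtained from
# mass attenuation coefficients (MAC, cm^2 g^-1) via the mixture rule:
# the MAC of a composite is the mass-fraction-weighted mean of the MACs
# of its components, and LAC = MAC * density.

# 2 * r_e * N_A * hc, with r_e in cm, hc in eV*cm.  Dividing by the photon
# energy (eV) and the atomic mass (g/mol) converts the imaginary scattering
# factor f2 to a photoabsorption MAC: mu/rho = 2 r_e lambda N_A f2 / A.
.MAC_PREFACTOR <- 2 * 2.8179403e-13 * 6.02214076e23 * 1.23984198e-4

.AVOGADRO <- 6.02214076e23

# Standard atomic masses (g/mol) for the elements in the bundled table.
.ATOMIC_MASS <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, Na = 22.98977,
  Mg = 24.305, P = 30.973762, S = 32.06, Cl = 35.45, K = 39.0983,
  Ca = 40.078, Fe = 55.845, Zn = 65.38
)

# Mean atomic composition of globular protein, as atom-count fractions.
# Hydrogen is included; it contributes ~7% of the mass and essentially no
# photoabsorption at water-window energies.
PROTEIN_ATOM_FRACTIONS <- c(H = 0.498, C = 0.320, N = 0.085, O = 0.095, S = 0.002)

#' Physical reference constants for the simulation materials
#'
#' Densities, molecular formulas and published water-window benchmarks used
#' throughout the tomogram simulator.  The water and DOPC linear attenuation
#' coefficients at 517 eV are literature benchmark values (1,114.279 cm^-1
#' for water at unit density; 9,264.835 cm^-1 for a DOPC bilayer with
#' 1,150 A^3 per lipid); protein attenuation is always computed from atomic
#' composition via [material_mac()].
#'
#' @return Named list with elements `protein_density` (g cm^-3),
#'   `water_lac_cm` and `dopc_lac_cm` (cm^-1 at 517 eV), `dopc_formula`,
#'   `dopc_volume_A3`, `dopc_mw`, `dopc_density`, `insulin_mw`,
#'   `proinsulin_mw`, `cpeptide_mw` (Da).
#' @export
material_constants <- function() {
  dopc_formula <- c(C = 40, H = 80, N = 1, O = 8, P = 1)
  dopc_mw <- sum(.ATOMIC_MASS[names(dopc_formula)] * dopc_formula)
  dopc_volume <- 1150.0                      # A^3 per lipid
  dopc_density <- dopc_mw / (.AVOGADRO * dopc_volume * 1e-24)
  list(
    protein_density = 1.22,                  # g cm^-3
    water_lac_cm    = 1114.279,              # cm^-1, 517 eV, rho = 1
    dopc_lac_cm     = 9264.835,              # cm^-1, 517 eV, bilayer density
    dopc_formula    = dopc_formula,
    dopc_volume_A3  = dopc_volume,
    dopc_mw         = dopc_mw,
    dopc_density    = dopc_density,
    insulin_mw      = 5808,                  # Da, mature monomer
    proinsulin_mw   = 9390,                  # Da
    cpeptide_mw     = 3020                   # Da, connecting peptide
  )
}

# Cached photoabsorption table (element, z, energy_ev, f2), bundled as a
# plain-text tabulation computed with the relativistic Cromer-Liberman
# method; linear interpolation in energy.  Hydrogen photoabsorption is
# below f2 = 1e-3 throughout the water window and is tabulated as zero.
.f2_env <- new.env(parent = emptyenv())

.f2_table <- function() {
  if (is.null(.f2_env$tab)) {
    path <- system.file("extdata", "photoabsorption_f2.tsv", package = "isgtomo")
    .f2_env$tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  }
  .f2_env$tab
}

#' Elemental mass attenuation coefficient
#'
#' Photoabsorption MAC of a single element at the given photon energy,
#' interpolated from the bundled scattering-factor tabulation.
#'
#' @param element Element symbol (e.g. `"C"`).
#' @param energy_ev Photon energy in eV (default 517, water window).
#' @return MAC in cm^2 g^-1.
#' @export
element_mac <- function(element, energy_ev = 517) {
  tab <- .f2_table()
  rows <- tab[tab$element == element, ]
  if (nrow(rows) == 0L) {
    stop("no photoabsorption data for element '", element, "'")
  }
  if (energy_ev < min(rows$energy_ev) || energy_ev > max(rows$energy_ev)) {
    stop("energy ", energy_ev, " eV outside tabulated range for ", element)
  }
  f2 <- stats::approx(rows$energy_ev, rows$f2, xout = energy_ev)$y
  .MAC_PREFACTOR * f2 / (energy_ev * .ATOMIC_MASS[[element]])
}

#' Mass attenuation coefficient of a compound
#'
#' Applies the mixture rule over the atoms of a molecular formula: the MAC
#' is the mass-fraction-weighted mean of the elemental MACs.
#'
#' @param formula Named numeric vector of atom counts, e.g.
#'   `c(H = 2, O = 1)`.  Counts may be fractional (mean compositions).
#' @param energy_ev Photon energy in eV.
#' @return List with `mac` (cm^2 g^-1), `mw` (g/mol of the formula unit),
#'   `mass_fractions` and `energy_ev`.
#' @export
material_mac <- function(formula, energy_ev = 517) {
  stopifnot(is.numeric(formula), length(formula) >= 1, !is.null(names(formula)))
  if (any(formula < 0)) stop("negative atom counts")
  unknown <- setdiff(names(formula), names(.ATOMIC_MASS))
  if (length(unknown)) stop("unknown element(s): ", paste(unknown, collapse = ", "))
  masses <- .ATOMIC_MASS[names(formula)] * formula
  mw <- sum(masses)
  w <- masses / mw
  macs <- vapply(names(formula), element_mac, numeric(1), energy_ev = energy_ev)
  list(mac = sum(w * macs), mw = mw, mass_fractions = w, energy_ev = energy_ev)
}

#' Average-protein mass attenuation coefficient
#'
#' MAC of the mean globular-protein composition (see
#' [PROTEIN_ATOM_FRACTIONS]), used for ingredients without an explicit
#' atomic composition.
#'
#' @param energy_ev Photon energy in eV.
#' @return MAC in cm^2 g^-1.
#' @export
protein_mac <- function(energy_ev = 517) {
  material_mac(PROTEIN_ATOM_FRACTIONS, energy_ev)$mac
}

#' Linear attenuation coefficient of a protein/lipid/water mixture
#'
#' The mixture rule for a voxel: `LAC = rho * sum(W_i * MAC_i)` where `W_i`
#' are mass fractions and `rho` the total mass density in the voxel.
#'
#' @param fractions Named numeric vector of mass fractions (must sum to 1
#'   within 1e-9), names matching `macs`.
#' @param macs Named numeric vector of component MACs in cm^2 g^-1.
#' @param density Total mass density in the voxel, g cm^-3.
#' @return LAC in micrometre^-1.
#' @export
mixture_lac <- function(fractions, macs, density) {
  stopifnot(length(fractions) >= 1, !is.null(names(fractions)))
  if (any(fractions < -1e-12)) stop("negative mass fraction")
  if (abs(sum(fractions) - 1) > 1e-9) stop("mass fractions must sum to 1")
  if (density < 0) stop("negative density")
  macs <- macs[names(fractions)]
  if (anyNA(macs)) stop("missing MAC for some components")
  # cm^-1 -> um^-1
  density * sum(fractions * macs) * 1e-4
}

#' Linear attenuation coefficient of cytoplasm at a protein concentration
#'
#' Protein at `concentration` g ml^-1 computed from mean protein
#' composition; water (benchmark LAC) fills the remaining volume.
#'
#' @param concentration Protein mass concentration in g ml^-1.
#' @param energy_ev Photon energy in eV.
#' @return LAC in micrometre^-1.
#' @export
cytoplasm_lac <- function(concentration, energy_ev = 517) {
  mc <- material_constants()
  stopifnot(concentration >= 0, concentration < mc$protein_density)
  water_vol <- 1 - concentration / mc$protein_density
  lac_cm <- concentration * protein_mac(energy_ev) + water_vol * mc$water_lac_cm
  lac_cm * 1e-4
}
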