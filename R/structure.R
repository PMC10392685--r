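# Atomic structures reduced to coarse bead models, plus per-protein
# elemental composition for mass and X-ray attenuation calculations.

# Elemental formulas of the free amino acids (hydrogens included).  Chain
# composition = sum of free-residue formulas minus one H2O per peptide
# bond; deposited structures usually lack hydrogens, so H counts are
# inferred from these templates.
.AA_FORMULA <- list(
  GLY = c(C = 2, H = 5, N = 1, O = 2),  ALA = c(C = 3, H = 7, N = 1, O = 2),
  SER = c(C = 3, H = 7, N = 1, O = 3),  PRO = c(C = 5, H = 9, N = 1, O = 2),
  VAL = c(C = 5, H = 11, N = 1, O = 2), THR = c(C = 4, H = 9, N = 1, O = 3),
  CYS = c(C = 3, H = 7, N = 1, O = 2, S = 1), LEU = c(C = 6, H = 13, N = 1, O = 2),
  ILE = c(C = 6, H = 13, N = 1, O = 2), ASN = c(C = 4, H = 8, N = 2, O = 3),
  ASP = c(C = 4, H = 7, N = 1, O = 4),  GLN = c(C = 5, H = 10, N = 2, O = 3),
  LYS = c(C = 6, H = 14, N = 2, O = 2), GLU = c(C = 5, H = 9, N = 1, O = 4),
  MET = c(C = 5, H = 11, N = 1, O = 2, S = 1), HIS = c(C = 6, H = 9, N = 3, O = 2),
  PHE = c(C = 9, H = 11, N = 1, O = 2), ARG = c(C = 6, H = 14, N = 4, O = 2),
  TYR = c(C = 9, H = 11, N = 1, O = 3), TRP = c(C = 11, H = 12, N = 2, O = 2)
)

.add_formula <- function(a, b) {
  els <- union(names(a), names(b))
  out <- stats::setNames(numeric(length(els)), els)
  out[names(a)] <- out[names(a)] + a
  out[names(b)] <- out[names(b)] + b
  out
}

#' Read an atomic structure
#'
#' Parses a PDB or mmCIF file into coordinates, element symbols and an
#' elemental composition.  Deposited files usually omit hydrogens; H counts
#' are inferred from per-residue amino-acid templates (one H2O removed per
#' peptide bond) and added to the composition, which matters for soft X-ray
#' attenuation of protein.
#'
#' @param path File path.
#' @param format `"pdb"` or `"cif"`; guessed from the extension by default.
#' @return Object of class `structure_record`: `id`, `xyz` (n x 3 matrix,
#'   Angstrom), `elements`, `chain`, `composition` (element -> count,
#'   hydrogens included), `mw` (Da).
#' @export
read_structure <- function(path, format = c("auto", "pdb", "cif")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.cif$", path, ignore.case = TRUE)) "cif" else "pdb"
  }
  if (!requireNamespace("bio3d", quietly = TRUE)) {
    stop("reading structures requires the 'bio3d' package")
  }
  pdb <- tryCatch(
    if (format == "pdb") bio3d::read.pdb(path, verbose = FALSE)
    else bio3d::read.cif(path, verbose = FALSE),
    error = function(e) stop("unreadable structure file '", path, "': ",
                             conditionMessage(e))
  )
  atoms <- pdb$atom
  if (is.null(atoms) || nrow(atoms) == 0) stop("structure '", path, "' has no atoms")
  elem <- toupper(trimws(atoms$elesy))
  noel <- is.na(elem) | elem == ""
  elem[noel] <- substr(gsub("[^A-Za-z].*", "", toupper(trimws(atoms$elety[noel]))), 1, 1)
  elem[elem %in% c("ZN", "FE", "NA", "MG", "CL")] <-
    c(ZN = "Zn", FE = "Fe", `NA` = "Na", MG = "Mg", CL = "Cl")[
      elem[elem %in% c("ZN", "FE", "NA", "MG", "CL")]]
  xyz <- cbind(atoms$x, atoms$y, atoms$z)
  comp <- table(elem)
  comp <- stats::setNames(as.numeric(comp), names(comp))
  # infer hydrogens per peptide chain when the file carries none
  if (!"H" %in% names(comp) || comp[["H"]] == 0) {
    res <- unique(atoms[atoms$resid %in% names(.AA_FORMULA),
                        c("chain", "resno", "resid")])
    if (nrow(res) > 0) {
      h_free <- sum(vapply(res$resid, function(r) .AA_FORMULA[[r]][["H"]], numeric(1)))
      bonds <- sum(pmax(table(res$chain) - 1, 0))
      comp <- .add_formula(comp, c(H = h_free - 2 * bonds))
    }
  }
  known <- intersect(names(comp), names(.ATOMIC_MASS))
  mw <- sum(.ATOMIC_MASS[known] * comp[known])
  structure(
    list(id = sub("\\.[^.]+$", "", basename(path)), xyz = xyz, elements = elem,
         chain = atoms$chain, composition = comp, mw = mw),
    class = "structure_record"
  )
}

#' @export
print.structure_record <- function(x, ...) {
  cat("structure_record", x$id, ":", nrow(x$xyz), "atoms, MW",
      round(x$mw), "Da\n")
  invisible(x)
}

#' Default bead count for a protein
#'
#' Deterministic stand-in for manual bead-count tuning: one bead per
#' `m_per_bead` daltons, where the default is the mass held by a 17 A bead
#' at protein density 1.22 g cm^-3 (~15.1 kDa).
#'
#' @param mw Molecular weight, Da.
#' @param m_per_bead Mass per bead, Da.
#' @return Integer bead count (>= 1).
#' @export
default_bead_count <- function(mw, m_per_bead = 15120) {
  max(1L, as.integer(ceiling(mw / m_per_bead)))
}

#' Coarse-grained bead model of a structure
#'
#' K-means clustering of the atom coordinates; bead centers are the
#' cluster centroids and each bead carries a mass share proportional to
#' the atomic mass assigned to it (shares sum exactly to the structure
#' weight, inferred hydrogens included).
#'
#' @param structure A `structure_record` (or any list with `xyz`,
#'   `elements`, `mw`).
#' @param n_beads Number of beads (1..n_atoms); default from
#'   [default_bead_count()].
#' @param seed RNG seed for the k-means++ style initialisation.
#' @param bead_radius Bead radius in Angstrom (default 17).
#' @return Object of class `bead_model`: `centers` (k x 3, Angstrom),
#'   `masses` (Da), `radius`.
#' @export
bead_model <- function(structure, n_beads = NULL, seed = 1, bead_radius = 17.0) {
  xyz <- structure$xyz
  n_atoms <- nrow(xyz)
  if (is.null(n_beads)) n_beads <- min(default_bead_count(structure$mw), n_atoms)
  if (n_beads < 1) stop("n_beads must be >= 1")
  if (n_beads > n_atoms) stop("n_beads exceeds atom count")
  amass <- .ATOMIC_MASS[structure$elements]
  amass[is.na(amass)] <- mean(.ATOMIC_MASS[c("C", "N", "O")])
  if (n_beads == 1L) {
    centers <- matrix(colMeans(xyz), 1, 3)
    cl <- rep(1L, n_atoms)
  } else if (n_beads == n_atoms) {
    centers <- xyz
    cl <- seq_len(n_atoms)
  } else {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    km <- stats::kmeans(xyz, centers = n_beads, nstart = 3, iter.max = 100)
    centers <- km$centers
    cl <- km$cluster
  }
  heavy <- as.vector(tapply(amass, factor(cl, levels = seq_len(n_beads)), sum))
  heavy[is.na(heavy)] <- 0
  masses <- heavy / sum(heavy) * structure$mw
  structure(list(centers = unname(centers), masses = masses, radius = bead_radius),
            class = "bead_model")
}

#' Synthetic globular decoy structure
#'
#' Pseudo-atoms uniformly packed in a sphere whose volume matches the
#' requested mass at protein density 1.22 g cm^-3, with mean globular
#' protein composition ([PROTEIN_ATOM_FRACTIONS]).  Used wherever a real
#' deposited structure is not available.
#'
#' @param mw Molecular weight, Da.
#' @param seed RNG seed.
#' @return A `structure_record`.
#' @export
synthetic_globule <- function(mw, seed = 1) {
  stopifnot(mw > 0)
  mean_atom_mass <- sum(PROTEIN_ATOM_FRACTIONS * .ATOMIC_MASS[names(PROTEIN_ATOM_FRACTIONS)])
  n_atoms <- max(1L, as.integer(round(mw / mean_atom_mass)))
  vol_A3 <- mw / (.AVOGADRO * 1.22) * 1e24
  radius <- (3 * vol_A3 / (4 * pi))^(1 / 3)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  u <- stats::runif(n_atoms)^(1 / 3) * radius
  dir <- matrix(stats::rnorm(3 * n_atoms), ncol = 3)
  dir <- dir / sqrt(rowSums(dir^2))
  xyz <- dir * u
  # largest-remainder assignment of elements to match the composition
  target <- PROTEIN_ATOM_FRACTIONS * n_atoms
  base <- floor(target)
  rem <- n_atoms - sum(base)
  extra <- order(target - base, decreasing = TRUE)[seq_len(rem)]
  counts <- base
  counts[extra] <- counts[extra] + 1
  elements <- rep(names(counts), counts)
  comp <- counts[counts > 0]
  structure(
    list(id = sprintf("globule_%d", round(mw)), xyz = xyz, elements = elements,
         chain = rep("A", n_atoms), composition = comp,
         mw = sum(.ATOMIC_MASS[names(comp)] * comp), radius = radius),
    class = "structure_record"
  )
}
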