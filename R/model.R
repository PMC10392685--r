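# Assembly of complete vesicle models: crystal lattice, lumen packing,
# membrane proteins and lipids, surrounding cytoplasm.  The result is a
# model_instance_set: a placement table plus per-ingredient bead models
# and compositions.

#' Define a model ingredient
#'
#' Bundles everything the builder and the voxeliser need to know about one
#' molecular species: mass, coarse bead model and compartment.
#'
#' @param id Ingredient id.
#' @param mw Molecular weight, Da.
#' @param compartment One of `"crystal"`, `"lumen"`, `"membrane"`,
#'   `"cytoplasm"`, `"lipid"`.
#' @param bead_offsets k x 3 matrix of bead offsets from the instance
#'   origin, nm; default a single bead at the origin.
#' @param bead_masses Per-bead masses, Da (sum to `mw`).
#' @param bead_radius Bead radius, nm (default 1.7).
#' @param mac Mass attenuation coefficient, cm^2 g^-1; default the mean
#'   globular-protein MAC at 517 eV.
#' @return Ingredient definition (list).
#' @export
model_ingredient <- function(id, mw, compartment,
                             bead_offsets = NULL, bead_masses = NULL,
                             bead_radius = 1.7, mac = NULL) {
  if (is.null(bead_offsets)) bead_offsets <- matrix(0, 1, 3)
  if (is.null(bead_masses)) {
    bead_masses <- rep(mw / nrow(bead_offsets), nrow(bead_offsets))
  }
  stopifnot(nrow(bead_offsets) == length(bead_masses),
            abs(sum(bead_masses) - mw) < 1e-6 * mw + 1e-9)
  if (is.null(mac)) mac <- protein_mac()
  list(id = id, mw = mw, compartment = compartment,
       bead_offsets = bead_offsets, bead_masses = bead_masses,
       bead_radius = bead_radius, mac = mac)
}

# ingredient from a structure: bead model in nm, centred
.ingredient_from_structure <- function(id, struct, compartment, n_beads = NULL,
                                       seed = 1) {
  bm <- bead_model(struct, n_beads = n_beads, seed = seed)
  off <- sweep(bm$centers, 2, colMeans(bm$centers)) / 10   # A -> nm
  mac <- material_mac(struct$composition)$mac
  model_ingredient(id, struct$mw, compartment, bead_offsets = off,
                   bead_masses = bm$masses, bead_radius = bm$radius / 10,
                   mac = mac)
}

#' Default non-insulin vesicle proteome
#'
#' A compact representative set of the major non-insulin ISG components
#' (granins, processing enzymes, membrane transporters and fusion
#' machinery) with molecular weights and compartments, plus relative mass
#' weights used to apportion the non-insulin mass budget.  Stands in for a
#' full curated recipe when none is supplied.
#'
#' @return Data frame: `protein_id`, `mw`, `compartment`, `rel_mass`.
#' @export
default_vesicle_proteome <- function() {
  data.frame(
    protein_id = c("ChgA", "ChgB", "Scg2", "Scg3", "Cpe", "Pcsk1", "Pcsk2",
                   "Iapp", "Vgf", "Ptprn", "Ptprn2", "Slc30a8", "Vamp2",
                   "Syt5", "Rab3a", "Rab27a"),
    mw = c(48000, 76000, 70000, 53000, 53000, 84000, 71000,
           3900, 68000, 106000, 111000, 41000, 13000,
           43000, 25000, 25000),
    compartment = c("lumen", "lumen", "lumen", "lumen", "lumen", "lumen",
                    "lumen", "lumen", "lumen", "membrane", "membrane",
                    "membrane", "membrane", "membrane", "membrane", "membrane"),
    rel_mass = c(0.22, 0.13, 0.10, 0.05, 0.08, 0.04, 0.05,
                 0.01, 0.04, 0.07, 0.05, 0.04, 0.03, 0.04, 0.025, 0.025),
    stringsAsFactors = FALSE
  )
}

#' Build a coarse-grained vesicle model
#'
#' Constructs one idealised ISG in cytoplasm: a procedurally placed
#' insulin crystal (rhombohedral hexamer lattice) sized by the maturation
#' state, proinsulin / cleaved monomer / C-peptide and soluble proteins
#' packed into the lumen, membrane proteins on the bilayer shell, lipids
#' tiling both leaflets, and a surrounding cytoplasm of the requested
#' concentration filling the bounding box.
#'
#' @param geometry A [vesicle_geometry()].
#' @param step Maturation step 1..6 (6 = mature).
#' @param cyto_concentration Cytoplasm protein concentration, g ml^-1
#'   (default 0.2).
#' @param seed RNG seed; the whole build is reproducible given the seed.
#' @param box_nm Bounding box edge, nm (default 636, i.e. 17 voxels of
#'   37.42 nm).
#' @param include_lipids Tile the membrane with lipids (default TRUE).
#' @param include_cytoplasm Pack explicit cytoplasm proteins (default TRUE).
#' @param proteome Non-insulin proteome table as in
#'   [default_vesicle_proteome()].
#' @param protein_scale Scale factor applied to all non-insulin copy
#'   numbers (library axis; default 1 at the reference geometry).
#' @param form Insulin [crystal_form()]; default bundled rhombohedral form.
#' @param relax_iterations Soft-overlap relaxation iterations (default 0;
#'   relaxation barely changes simulated tomograms and is expensive).
#' @return Object of class `model_instance_set`.
#' @export
build_vesicle_model <- function(geometry = vesicle_geometry(), step = 6,
                                cyto_concentration = 0.2, seed = 1,
                                box_nm = 636, include_lipids = TRUE,
                                include_cytoplasm = TRUE,
                                proteome = default_vesicle_proteome(),
                                protein_scale = NULL, form = NULL,
                                relax_iterations = 0) {
  mc <- material_constants()
  if (is.null(form)) form <- bundled_crystal_forms()[["1trz"]]
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  R_out <- geometry$vesicle_diameter / 2
  mem <- geometry$membrane_thickness
  R_in <- R_out - mem
  n_total <- insulin_copies(geometry, form, mc$insulin_mw)
  counts <- partition_maturation(n_total, maturation_state(step))

  # crystal radius holding the crystal-partitioned monomers
  vol_A3 <- counts[["crystal"]] * mc$insulin_mw /
    (.AVOGADRO * form$protein_density * form$occupancy) * 1e24
  r_cryst <- if (counts[["crystal"]] > 0) (3 * vol_A3 / (4 * pi))^(1 / 3) / 10 else 0
  r_cryst <- min(r_cryst, R_in - 1)

  crystal_sdf <- sdf_sphere(radius = r_cryst, role = "crystal-boundary")
  lumen_sdf <- if (r_cryst > 0) {
    sdf_difference(sdf_sphere(radius = R_in), sdf_sphere(radius = r_cryst + 1.5))
  } else sdf_sphere(radius = R_in)

  placements <- list()
  ingredients <- list()

  ## insulin crystal: coherent hexamer lattice
  hex_mw <- 6 * mc$insulin_mw
  ingredients$insulin_hexamer <- model_ingredient(
    "insulin_hexamer", hex_mw, "crystal",
    bead_offsets = rbind(c(-1.6, 0, 0), c(1.6, 0, 0), c(0, 1.6, 0)),
    bead_masses = rep(hex_mw / 3, 3), bead_radius = 1.7)
  cry <- place_crystal(lattice_spec(), crystal_sdf)
  # keep at most floor(n/6) hexamers (innermost sites first, deterministic);
  # monomers not absorbed by whole hexamers go to the lumen as free monomer
  max_hex <- counts[["crystal"]] %/% 6
  if (nrow(cry) > max_hex) {
    ord <- order(cry$x^2 + cry$y^2 + cry$z^2)
    cry <- cry[ord[seq_len(max_hex)], , drop = FALSE]
  }
  monomer_extra <- counts[["crystal"]] - 6 * nrow(cry)
  n_monomer <- counts[["monomer"]] + monomer_extra
  placements$crystal <- cry

  ## lumen insulin species; C-peptide accompanies every cleaved monomer
  n_cpep <- n_total - counts[["proinsulin"]]
  lumen_species <- data.frame(
    protein_id = c("proinsulin", "insulin_monomer", "c_peptide"),
    mw = c(mc$proinsulin_mw, mc$insulin_mw, mc$cpeptide_mw),
    count = c(counts[["proinsulin"]], n_monomer, n_cpep),
    stringsAsFactors = FALSE
  )

  ## non-insulin proteins: mass budget = 0.2/0.8 of total insulin mass
  scale <- protein_scale %||% 1
  ins_mass <- n_total * mc$insulin_mw / .AVOGADRO
  non_mass <- ins_mass * 0.2 / 0.8 * scale
  prot <- proteome
  prot$mass <- non_mass * prot$rel_mass / sum(prot$rel_mass)
  prot$count <- pmax(1L, as.integer(round(prot$mass * .AVOGADRO / prot$mw)))

  for (i in seq_len(nrow(lumen_species))) {
    sp <- lumen_species[i, ]
    if (sp$count == 0) next
    ingredients[[sp$protein_id]] <- model_ingredient(sp$protein_id, sp$mw, "lumen")
    r_b <- .bound_radius_nm(sp$mw)
    placements[[sp$protein_id]] <- pack_compartment(
      sp$protein_id, sp$count, r_b, lumen_sdf,
      region_min = rep(-R_in, 3), region_max = rep(R_in, 3))
  }
  for (i in seq_len(nrow(prot))) {
    p <- prot[i, ]
    r_b <- .bound_radius_nm(p$mw)
    nb <- default_bead_count(p$mw)
    off <- if (nb == 1) matrix(0, 1, 3) else
      fibonacci_sphere(nb, radius = max(r_b - 1.7, 0.1))
    ingredients[[p$protein_id]] <- model_ingredient(
      p$protein_id, p$mw, p$compartment, bead_offsets = off,
      bead_masses = rep(p$mw / nb, nb))
    if (p$compartment == "lumen") {
      placements[[p$protein_id]] <- pack_compartment(
        p$protein_id, p$count, r_b, lumen_sdf,
        region_min = rep(-R_in, 3), region_max = rep(R_in, 3))
    } else {
      # membrane-anchored: random points on the bilayer mid-sphere
      u <- matrix(stats::rnorm(3 * p$count), ncol = 3)
      u <- u / sqrt(rowSums(u^2))
      pos <- u * (R_out - mem / 2)
      q <- .random_quaternions(p$count)
      placements[[p$protein_id]] <- data.frame(
        ingredient = rep(p$protein_id, p$count),
        x = pos[, 1], y = pos[, 2], z = pos[, 3],
        qw = q[, 1], qx = q[, 2], qy = q[, 3], qz = q[, 4],
        stringsAsFactors = FALSE)
    }
  }

  ## lipids
  if (include_lipids && mem > 0) {
    ingredients$DOPC <- model_ingredient("DOPC", mc$dopc_mw, "lipid",
                                         bead_radius = 0.5,
                                         mac = mc$dopc_lac_cm / mc$dopc_density)
    placements$DOPC <- tile_membrane(R_out - mem / 2,
                                     lipid_volume_A3 = mc$dopc_volume_A3,
                                     bilayer_thickness_nm = mem)
  }

  ## cytoplasm: explicit proteins in the box outside the vesicle
  if (include_cytoplasm && cyto_concentration > 0) {
    cyto <- .default_cytoplasm_proteome()
    # pack with overhang beyond the box so edge voxels are filled at the
    # nominal concentration; the voxeliser clips mass outside the grid
    pack_nm <- box_nm + 80
    box_vol_cm3 <- (pack_nm * 1e-7)^3
    ves_vol_cm3 <- 4 / 3 * pi * (R_out * 1e-7)^3
    cyto_mass <- cyto_concentration * (box_vol_cm3 - ves_vol_cm3)
    cyto$mass <- cyto_mass * cyto$rel_mass / sum(cyto$rel_mass)
    cyto$count <- pmax(0L, as.integer(round(cyto$mass * .AVOGADRO / cyto$mw)))
    half <- pack_nm / 2
    outside <- sdf_complement(sdf_sphere(radius = R_out + 1))
    for (i in seq_len(nrow(cyto))) {
      p <- cyto[i, ]
      if (p$count == 0) next
      ingredients[[p$protein_id]] <- model_ingredient(p$protein_id, p$mw, "cytoplasm")
      placements[[p$protein_id]] <- pack_compartment(
        p$protein_id, p$count, .bound_radius_nm(p$mw), outside,
        region_min = rep(-half, 3), region_max = rep(half, 3))
    }
  }

  pl <- do.call(rbind, placements)
  rownames(pl) <- NULL
  structure(
    list(placements = pl, ingredients = ingredients, geometry = geometry,
         maturation_step = as.integer(step), box_nm = box_nm,
         cyto_concentration = cyto_concentration, center = c(0, 0, 0),
         boundary_sdf = sdf_sphere(radius = R_in),
         insulin_total = n_total, crystal_radius_nm = r_cryst, seed = seed),
    class = "model_instance_set"
  ) -> model
  if (relax_iterations > 0) model <- relax(model, relax_iterations)
  model
}

# bounding radius of a globular protein of given mass at density 1.22
.bound_radius_nm <- function(mw) {
  vol_nm3 <- mw / (.AVOGADRO * 1.22) * 1e21
  max((3 * vol_nm3 / (4 * pi))^(1 / 3), 0.5)
}

# compact surrogate for the 50 most abundant cytoplasmic proteins:
# glycolytic enzymes, chaperones, translation factors etc. binned into
# representative size classes
.default_cytoplasm_proteome <- function() {
  data.frame(
    protein_id = c("cyto_s", "cyto_m", "cyto_l", "cyto_xl"),
    mw = c(20000, 35000, 60000, 100000),
    rel_mass = c(0.30, 0.40, 0.20, 0.10),
    stringsAsFactors = FALSE
  )
}

#' @export
print.model_instance_set <- function(x, ...) {
  cat("model_instance_set: step", x$maturation_step, "|",
      nrow(x$placements), "instances |",
      length(x$ingredients), "ingredient types | vesicle",
      x$geometry$vesicle_diameter, "nm, crystal",
      round(2 * x$crystal_radius_nm), "nm\n")
  invisible(x)
}

#' Per-ingredient instance counts of a model
#'
#' @param model A `model_instance_set`.
#' @return Named integer vector.
#' @export
instance_counts <- function(model) {
  tab <- table(model$placements$ingredient)
  stats::setNames(as.integer(tab), names(tab))
}

#' Export model placements
#'
#' Writes the instance table (ingredient, position in nm, orientation
#' quaternion) as TSV or JSON.
#'
#' @param model A `model_instance_set`.
#' @param path Output path; format chosen by extension (`.tsv` / `.json`).
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  if (grepl("\\.json$", path)) {
    obj <- list(
      geometry = unclass(model$geometry),
      maturation_step = model$maturation_step,
      box_nm = model$box_nm,
      cyto_concentration = model$cyto_concentration,
      placements = model$placements
    )
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.table(model$placements, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Import model placements
#'
#' Reads a placement table written by [write_model()].  Bead models are
#' not serialised; re-attach ingredients if voxelisation is needed.
#'
#' @param path `.tsv` or `.json` file.
#' @return For JSON, a list with `geometry` and `placements`; for TSV, the
#'   placements data frame.
#' @export
read_model <- function(path) {
  if (grepl("\\.json$", path)) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    obj$placements <- as.data.frame(obj$placements, stringsAsFactors = FALSE)
    obj
  } else {
    utils::read.delim(path, stringsAsFactors = FALSE)
  }
}
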