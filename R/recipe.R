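# From proteome abundance metrics to a buildable vesicle recipe:
# NSAF molar fractions, mass fractions, the 0.8/0.2 crystal/non-crystal
# mass split, absolute copy numbers for a given vesicle geometry, and the
# surrounding cytoplasm recipe.

#' Normalised spectral abundance factors
#'
#' Divides each raw abundance by the protein length, then by the sum over
#' all entries; approximates the molar fraction of each protein.
#'
#' @param entries Data frame with columns `protein_id`, `raw_abundance`
#'   (nonnegative), `length` (amino acids, > 0).
#' @return Named numeric vector of molar fractions summing to 1.
#' @export
nsaf <- function(entries) {
  stopifnot(all(c("protein_id", "raw_abundance", "length") %in% names(entries)))
  if (any(entries$length <= 0)) stop("protein lengths must be positive")
  if (any(entries$raw_abundance < 0)) stop("negative abundances")
  v <- entries$raw_abundance / entries$length
  tot <- sum(v)
  if (tot == 0) stop("all abundances are zero")
  stats::setNames(v / tot, entries$protein_id)
}

#' Mass fractions from molar fractions
#'
#' Multiplies each molar fraction by the protein's molecular weight and
#' renormalises.
#'
#' @param nsaf_map Named numeric vector of molar fractions.
#' @param mw_map Named numeric vector of molecular weights (Da) covering
#'   every protein in `nsaf_map`.
#' @return Named numeric vector of mass fractions summing to 1.
#' @export
mass_fractions <- function(nsaf_map, mw_map) {
  miss <- setdiff(names(nsaf_map), names(mw_map))
  if (length(miss)) stop("missing molecular weight for: ", paste(miss, collapse = ", "))
  w <- nsaf_map * mw_map[names(nsaf_map)]
  w / sum(w)
}

#' Pool per-proteome mass fractions
#'
#' Cross-proteome consensus: a protein observed in k proteomes receives the
#' mean of its per-proteome mass fractions (fractions are computed within
#' each proteome first).  Proteins added by curation but absent from all
#' proteomes receive a small floor fraction.
#'
#' @param fraction_list List of named mass-fraction vectors, one per proteome.
#' @param curated_ids Optional protein ids to force-include with the floor.
#' @param floor_fraction Fraction of total mass assigned to each curated
#'   absent protein (default 1e-4).
#' @return Named numeric vector of pooled mass fractions summing to 1.
#' @export
pool_mass_fractions <- function(fraction_list, curated_ids = character(0),
                                floor_fraction = 1e-4) {
  ids <- unique(c(unlist(lapply(fraction_list, names)), curated_ids))
  m <- vapply(ids, function(id) {
    vals <- unlist(lapply(fraction_list, function(f)
      if (id %in% names(f)) f[[id]] else NULL))
    if (length(vals) == 0) NA_real_ else mean(vals)
  }, numeric(1))
  m[is.na(m)] <- floor_fraction * sum(m, na.rm = TRUE)
  m / sum(m)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Split mass between the insulin crystal and everything else
#'
#' Rescales non-insulin mass fractions so they total 0.2, assigning the
#' remaining 0.8 to the insulin crystal.
#'
#' @param fractions Named mass-fraction vector (sums to 1).
#' @param insulin_ids Ids of the insulin entries (crystal-forming).
#' @param noninsulin_total Target total for the non-insulin proteins
#'   (default 0.2).
#' @return Named vector: insulin entries share `1 - noninsulin_total`
#'   proportionally to their input fractions; the rest sum to
#'   `noninsulin_total`.
#' @export
scale_noninsulin <- function(fractions, insulin_ids, noninsulin_total = 0.2) {
  ins <- names(fractions) %in% insulin_ids
  if (!any(ins)) stop("no insulin entries found")
  if (all(ins)) stop("no non-insulin proteins to scale")
  out <- fractions
  out[!ins] <- fractions[!ins] * (noninsulin_total / sum(fractions[!ins]))
  out[ins] <- fractions[ins] * ((1 - noninsulin_total) / sum(fractions[ins]))
  out
}

#' Crystal-form metadata
#'
#' Describes one insulin crystal form; the volume occupancy (protein volume
#' fraction of the unit cell) is derived as
#' `z * asym_mw / (N_A * protein_density * cell_volume)`.
#'
#' @param pdb_id Entry identifier.
#' @param space_group Space-group symbol (e.g. `"H3"`, `"P21"`).
#' @param asym_mw Asymmetric-unit molecular weight, Da.
#' @param z Asymmetric units per cell.
#' @param cell_volume Unit-cell volume, A^3.
#' @param protein_density Protein mass density, g cm^-3 (default 1.22).
#' @return Object of class `crystal_form` with an `occupancy` field.
#' @export
crystal_form <- function(pdb_id, space_group, asym_mw, z, cell_volume,
                         protein_density = 1.22) {
  stopifnot(asym_mw > 0, z > 0, cell_volume > 0, protein_density > 0)
  form <- structure(
    list(pdb_id = pdb_id, space_group = space_group, asym_mw = asym_mw,
         z = z, cell_volume = cell_volume, protein_density = protein_density),
    class = "crystal_form"
  )
  form$occupancy <- crystal_occupancy(form)
  form
}

#' Crystal volume occupancy
#'
#' Fraction of the unit-cell volume occupied by protein at the reference
#' protein density: `z * asym_mw / (N_A * rho * V_cell)` with the cell
#' volume in A^3 converted to cm^3.
#'
#' @param form A [crystal_form()] (the `occupancy` field is recomputed).
#' @return Occupancy in `(0, 1]`.
#' @export
crystal_occupancy <- function(form) {
  occ <- form$z * form$asym_mw /
    (.AVOGADRO * form$protein_density * form$cell_volume * 1e-24)
  if (occ > 1 + 1e-9) {
    stop("inconsistent crystal metadata: occupancy ", signif(occ, 4), " > 1")
  }
  occ
}

#' Bundled insulin crystal-form metadata
#'
#' Reads `inst/extdata/crystal_forms.tsv`, a transcription of unit-cell
#' constants and asymmetric-unit weights for the two most common hexameric
#' insulin crystal forms (rhombohedral H3 as in PDB entry 1trz; monoclinic
#' P21 as in 1ev6).  The `verified` column records whether the row is an
#' exact transcription of the public database entry or an approximate
#' literature-based stand-in.
#'
#' @return Named list of [crystal_form()] objects with a `verified`
#'   attribute each.
#' @export
bundled_crystal_forms <- function() {
  path <- system.file("extdata", "crystal_forms.tsv", package = "isgtomo")
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(df)), function(i) {
    f <- crystal_form(df$pdb_id[i], df$space_group[i], df$asym_mw[i],
                      df$z[i], df$cell_volume[i])
    attr(f, "verified") <- as.logical(df$verified[i])
    f
  })
  stats::setNames(out, df$pdb_id)
}

#' Vesicle geometry
#'
#' @param vesicle_diameter Outer vesicle diameter, nm (default 320).
#' @param crystal_diameter Insulin crystal diameter, nm (default 200).
#' @param membrane_thickness Bilayer thickness, nm (default 5).
#' @return Object of class `vesicle_geometry`.
#' @export
vesicle_geometry <- function(vesicle_diameter = 320, crystal_diameter = 200,
                             membrane_thickness = 5) {
  stopifnot(vesicle_diameter > 0, crystal_diameter >= 0, membrane_thickness >= 0)
  if (crystal_diameter + 2 * membrane_thickness > vesicle_diameter) {
    stop("crystal plus membrane exceeds the vesicle diameter")
  }
  structure(list(vesicle_diameter = vesicle_diameter,
                 crystal_diameter = crystal_diameter,
                 membrane_thickness = membrane_thickness),
            class = "vesicle_geometry")
}

#' Insulin copies in a crystal of given diameter
#'
#' Number of insulin monomers in a spherical crystal: crystal volume times
#' occupancy times protein density, divided by the monomer mass.
#'
#' @param geometry A [vesicle_geometry()].
#' @param form A [crystal_form()] providing occupancy and density.
#' @param monomer_mw Insulin monomer weight, Da (default 5808).
#' @return Integer count.
#' @export
insulin_copies <- function(geometry, form, monomer_mw = 5808) {
  r_cm <- geometry$crystal_diameter / 2 * 1e-7
  vol <- 4 / 3 * pi * r_cm^3
  mass <- vol * form$occupancy * form$protein_density
  round(mass / (monomer_mw / .AVOGADRO))
}

#' Absolute copy numbers from mass fractions
#'
#' `count_i = round(w_i * M_total / (mw_i / N_A))`, with manual exception
#' hooks applied afterwards:
#' \itemize{
#'   \item `iapp_hook`: islet amyloid polypeptide is assigned 1% of the
#'     insulin copy number (its proteomic signal is unreliable).
#'   \item `complex_hook`: a multi-subunit complex (e.g. vATPase) receives
#'     the mean of its subunits' stoichiometry-normalised counts.
#'   \item `exclusions`: named list protein -> proteome ids whose values are
#'     dropped before pooling (handled upstream in [pool_mass_fractions()]
#'     by filtering `fraction_list`); retained here for per-protein count
#'     overrides of the form protein -> count.
#' }
#'
#' @param fractions Named mass-fraction vector (sums to 1).
#' @param mw_map Named molecular weights (Da).
#' @param total_mass Total protein mass in grams.
#' @param iapp_hook `NULL`, or list `(iapp_id=, insulin_count=, ratio=0.01)`.
#' @param complex_hook `NULL`, or list `(complex_id=, subunit_ids=,
#'   stoichiometry=)`; subunit counts are divided by their stoichiometry and
#'   averaged to give the complex count, and subunit rows are removed.
#' @param overrides Named numeric vector of manual count overrides.
#' @param must_include Ids whose count is floored at 1.
#' @return Named integer vector of copy numbers.
#' @export
copy_numbers <- function(fractions, mw_map, total_mass,
                         iapp_hook = NULL, complex_hook = NULL,
                         overrides = NULL, must_include = character(0)) {
  if (!all(is.finite(fractions)) || any(fractions < 0) || !is.finite(total_mass) ||
      total_mass < 0) {
    stop("fractions and total mass must be finite and nonnegative")
  }
  miss <- setdiff(names(fractions), names(mw_map))
  if (length(miss)) stop("missing molecular weight for: ", paste(miss, collapse = ", "))
  counts <- round(fractions * total_mass / (mw_map[names(fractions)] / .AVOGADRO))
  if (!is.null(iapp_hook)) {
    counts[iapp_hook$iapp_id] <- round((iapp_hook$ratio %||% 0.01) * iapp_hook$insulin_count)
  }
  if (!is.null(complex_hook)) {
    sub <- complex_hook$subunit_ids
    st <- complex_hook$stoichiometry
    stopifnot(length(sub) == length(st), all(st > 0))
    have <- sub %in% names(counts)
    if (!any(have)) stop("no complex subunits present in counts")
    counts[complex_hook$complex_id] <- round(mean(counts[sub[have]] / st[have]))
    counts <- counts[!names(counts) %in% sub]
  }
  if (!is.null(overrides)) counts[names(overrides)] <- round(overrides)
  low <- names(counts) %in% must_include & counts < 1
  counts[low] <- 1
  storage.mode(counts) <- "integer"
  counts
}

#' Cytoplasm recipe fragment
#'
#' Takes the `top_n` most abundant cytoplasmic proteins and scales their
#' concentrations so the total protein mass concentration equals
#' `target_concentration`.
#'
#' @param entries Data frame with `protein_id`, `raw_abundance`, `mw`.
#' @param target_concentration Total concentration, g ml^-1 (default 0.2).
#' @param top_n Number of proteins kept (default 50).
#' @return Data frame `protein_id`, `mw`, `concentration` (g ml^-1) with
#'   `sum(concentration) == target_concentration`.
#' @export
cytoplasm_recipe <- function(entries, target_concentration = 0.2, top_n = 50) {
  stopifnot(all(c("protein_id", "raw_abundance", "mw") %in% names(entries)))
  if (nrow(entries) < top_n) {
    warning("fewer than ", top_n, " cytoplasmic entries; using all ", nrow(entries))
    top_n <- nrow(entries)
  }
  ord <- order(-entries$raw_abundance, entries$protein_id)
  top <- entries[ord[seq_len(top_n)], , drop = FALSE]
  conc <- top$raw_abundance / sum(top$raw_abundance) * target_concentration
  data.frame(protein_id = top$protein_id, mw = top$mw, concentration = conc,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Assemble a vesicle recipe
#'
#' Combines pooled mass fractions, the 0.8/0.2 split, geometry and crystal
#' form into the buildable ingredient list for one vesicle.
#'
#' @param fractions Pooled mass fractions (sum to 1) including insulin.
#' @param mw_map Named molecular weights (Da).
#' @param compartments Named character vector protein -> one of `"lumen"`,
#'   `"membrane"`; insulin entries are assigned `"crystal"`.
#' @param insulin_ids Insulin entry ids.
#' @param geometry A [vesicle_geometry()].
#' @param form A [crystal_form()].
#' @param monomer_mw Insulin monomer weight, Da.
#' @param must_include Ids floored at one copy.
#' @param ... Passed to [copy_numbers()] (exception hooks).
#' @return Object of class `isg_recipe`: data frame of entries plus
#'   geometry/form/insulin metadata in attributes.
#' @export
build_recipe <- function(fractions, mw_map, compartments, insulin_ids,
                         geometry = vesicle_geometry(), form,
                         monomer_mw = 5808, must_include = character(0), ...) {
  split <- scale_noninsulin(fractions, insulin_ids)
  n_ins <- insulin_copies(geometry, form, monomer_mw)
  ins_mass <- n_ins * monomer_mw / .AVOGADRO        # grams, = 0.8 of total
  total_mass <- ins_mass / sum(split[names(split) %in% insulin_ids])
  non <- split[!names(split) %in% insulin_ids]
  counts <- copy_numbers(non, mw_map, total_mass, must_include = must_include, ...)
  comp <- compartments[names(counts)]
  comp[is.na(comp)] <- "lumen"
  entries <- data.frame(
    protein_id = c(insulin_ids[1], names(counts)),
    compartment = c("crystal", unname(comp)),
    copy_number = c(n_ins, unname(counts)),
    mass_fraction = c(sum(split[names(split) %in% insulin_ids]),
                      unname(split[names(counts)])),
    mw = c(monomer_mw, unname(mw_map[names(counts)])),
    structure_ref = NA_character_,
    stringsAsFactors = FALSE
  )
  structure(entries, class = c("isg_recipe", "data.frame"),
            geometry = geometry, form = form, insulin_ids = insulin_ids,
            total_mass = total_mass)
}

#' Write a recipe as JSON
#'
#' cellPACK-style ingredient list: name, compartment, count, molecular
#' weight, mass fraction, structure reference, plus the geometry block.
#'
#' @param recipe An `isg_recipe` (or plain entry data frame).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_recipe_json <- function(recipe, path) {
  geom <- attr(recipe, "geometry")
  obj <- list(
    geometry = if (is.null(geom)) NULL else unclass(geom),
    ingredients = as.data.frame(recipe)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a recipe from JSON
#'
#' @param path Path written by [write_recipe_json()].
#' @return An `isg_recipe`.
#' @export
read_recipe_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  entries <- as.data.frame(obj$ingredients, stringsAsFactors = FALSE)
  geom <- obj$geometry
  structure(entries, class = c("isg_recipe", "data.frame"),
            geometry = if (is.null(geom)) NULL else do.call(vesicle_geometry, geom))
}
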