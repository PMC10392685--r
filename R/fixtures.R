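# Synthetic-data generators: annotation catalogs emulating the structure
# of curated localisation evidence, proteome abundance tables, and vesicle
# phantoms with closed-form attenuation volumes for oracle comparisons.
# Every generator is reproducible under a fixed seed.

#' Derive a per-stream seed from a master seed
#'
#' Deterministic splitting so each pipeline stage has an independent,
#' re-runnable RNG stream: `(master * 1000003 + stream * 7919) mod
#' (2^31 - 1)`.
#'
#' @param master Master seed (integer).
#' @param stream Stream index (integer).
#' @return Integer seed in `[1, 2^31 - 2]`.
#' @export
split_seed <- function(master, stream) {
  as.integer((as.numeric(master) * 1000003 + as.numeric(stream) * 7919) %%
               2147483646 + 1)
}

#' Specification for a synthetic annotation catalog
#'
#' Keyword presence is Bernoulli with class-conditional rates derived from
#' a baseline rate and an enrichment odds ratio (positives : negatives).
#'
#' @param n_positives,n_negatives Numbers of proteins per class.
#' @param loc_keywords Data frame `keyword`, `base_rate`, `odds` for the
#'   proteins' own location annotations.
#' @param intloc_keywords Same, for interactor-contributed annotations.
#' @param interactor_lambda Mean number of interactors per protein
#'   (Poisson).
#' @param interactor_purity Probability that an interactor shares its
#'   owner's class (default 1).  Values near 0.5 dilute the interactor
#'   evidence: with the same per-draw keyword statistics on both flavours,
#'   the asymptotically optimal weight ratio `w_loc / w_intloc` is
#'   approximately `1 / (2 * purity - 1)` -- the injected informativeness
#'   ratio for parameter-recovery studies.
#' @param p_extra_proteome Probability per additional proteome that a
#'   protein is also observed there (positives and negatives alike).
#' @param seed RNG seed.
#' @return Object of class `synthetic_catalog_spec`.
#' @export
synthetic_catalog_spec <- function(n_positives = 30, n_negatives = 240,
                                   loc_keywords = NULL, intloc_keywords = NULL,
                                   interactor_lambda = 4,
                                   interactor_purity = 1,
                                   p_extra_proteome = 0.25, seed = 1) {
  if (is.null(loc_keywords)) {
    loc_keywords <- data.frame(
      keyword = c("secretory_vesicle", "cytoplasmic_vesicle", "secreted",
                  "mitochondrion", "nucleus", "cytoplasm"),
      base_rate = c(0.08, 0.10, 0.08, 0.25, 0.30, 0.50),
      odds = c(20, 12, 8, 0.1, 0.15, 1),
      stringsAsFactors = FALSE)
  }
  if (is.null(intloc_keywords)) {
    intloc_keywords <- data.frame(
      keyword = c("int_vesicle", "int_membrane", "int_nucleus", "int_cytoplasm"),
      base_rate = c(0.10, 0.20, 0.30, 0.50),
      odds = c(6, 2, 0.3, 1),
      stringsAsFactors = FALSE)
  }
  stopifnot(all(loc_keywords$odds > 0), all(intloc_keywords$odds > 0),
            all(loc_keywords$base_rate >= 0 & loc_keywords$base_rate <= 1))
  stopifnot(interactor_purity >= 0, interactor_purity <= 1)
  structure(list(n_positives = n_positives, n_negatives = n_negatives,
                 loc_keywords = loc_keywords, intloc_keywords = intloc_keywords,
                 interactor_lambda = interactor_lambda,
                 interactor_purity = interactor_purity,
                 p_extra_proteome = p_extra_proteome, seed = seed),
            class = "synthetic_catalog_spec")
}

.rate_from_odds <- function(base, odds) {
  # positive-class rate p+ such that odds(p+) = odds * odds(base)
  o <- odds * base / (1 - base)
  o / (1 + o)
}

#' Generate a synthetic annotation catalog
#'
#' Draws per-protein location keywords at class-conditional rates, builds
#' interactor keyword multisets (each interactor contributes one keyword
#' draw per interactor-level keyword), and assigns proteome memberships.
#'
#' @param spec A [synthetic_catalog_spec()].
#' @return List with `catalog` (an [annotation_catalog()]) and `labels`
#'   (a [labelled_set()]).
#' @export
generate_catalog <- function(spec) {
  stopifnot(inherits(spec, "synthetic_catalog_spec"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)
  n <- spec$n_positives + spec$n_negatives
  ids <- sprintf("prot%04d", seq_len(n))
  is_pos <- c(rep(TRUE, spec$n_positives), rep(FALSE, spec$n_negatives))
  draw_keywords <- function(tbl, positive) {
    rates <- ifelse(rep(positive, nrow(tbl)),
                    .rate_from_odds(tbl$base_rate, tbl$odds), tbl$base_rate)
    tbl$keyword[stats::runif(nrow(tbl)) < rates]
  }
  locations <- lapply(seq_len(n), function(i)
    draw_keywords(spec$loc_keywords, is_pos[i]))
  purity <- spec$interactor_purity %||% 1
  interactor_locations <- lapply(seq_len(n), function(i) {
    k <- stats::rpois(1, spec$interactor_lambda)
    if (k == 0) return(character(0))
    unlist(lapply(seq_len(k), function(j) {
      same <- stats::runif(1) < purity
      draw_keywords(spec$intloc_keywords, if (same) is_pos[i] else !is_pos[i])
    }))
  })
  proteomes <- lapply(seq_len(n), function(i) {
    first <- sample(c("P1", "P2", "P3"), 1)
    extra <- setdiff(c("P1", "P2", "P3"), first)
    c(first, extra[stats::runif(2) < spec$p_extra_proteome])
  })
  names(locations) <- names(interactor_locations) <- names(proteomes) <- ids
  catalog <- annotation_catalog(locations, interactor_locations, proteomes)
  labels <- labelled_set(ids[is_pos], ids[!is_pos], catalog)
  list(catalog = catalog, labels = labels)
}

#' Generate synthetic proteome abundance tables
#'
#' Log-normal raw abundances with study-specific scales, for a roster of
#' proteins with log-normal molecular weights; one table per proteome.
#'
#' @param n_proteins Roster size.
#' @param n_proteomes Number of studies (default 3).
#' @param detection_p Probability a protein is detected in a given study.
#' @param seed RNG seed.
#' @return List with `tables` (list of data frames `protein_id`,
#'   `raw_abundance`, `length`, `mw`, `proteome_id`) and `mw_map`.
#' @export
generate_proteome_tables <- function(n_proteins = 60, n_proteomes = 3,
                                     detection_p = 0.7, seed = 1) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  ids <- sprintf("prot%03d", seq_len(n_proteins))
  mw <- round(stats::rlnorm(n_proteins, log(45000), 0.5))
  len <- pmax(50L, as.integer(round(mw / 110)))
  base <- stats::rlnorm(n_proteins, 0, 1)
  tables <- lapply(seq_len(n_proteomes), function(p) {
    det <- stats::runif(n_proteins) < detection_p
    scale <- stats::rlnorm(1, log(100), 0.3)
    data.frame(protein_id = ids[det],
               raw_abundance = base[det] * scale *
                 stats::rlnorm(sum(det), 0, 0.3),
               length = len[det], mw = mw[det],
               proteome_id = sprintf("P%d", p), stringsAsFactors = FALSE)
  })
  list(tables = tables, mw_map = stats::setNames(mw, ids))
}

#' Phantom specification
#'
#' One idealised vesicle in cytoplasm, described by the quantities scanned
#' in the model library.
#'
#' @param vesicle_diameter,crystal_diameter nm.
#' @param step Maturation step 1..6.
#' @param cyto_concentration Cytoplasm concentration, g ml^-1 (0.06-0.2).
#' @param voxel_nm Voxel width (default 37.42).
#' @param box_nm Model bounding box (default 636 nm = 17 voxels).
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(vesicle_diameter = 320, crystal_diameter = 200,
                         step = 6, cyto_concentration = 0.2,
                         voxel_nm = 37.42, box_nm = 636) {
  geom <- vesicle_geometry(vesicle_diameter, crystal_diameter)
  structure(list(geometry = geom, step = step,
                 cyto_concentration = cyto_concentration,
                 voxel_nm = voxel_nm, box_nm = box_nm),
            class = "phantom_spec")
}

#' Generate a vesicle phantom
#'
#' Builds the coarse-grained model via the full pipeline and also returns
#' the closed-form concentric-shell attenuation volume (crystal core,
#' lumen, lipid shell, cytoplasm) evaluated by sub-voxel supersampling,
#' for oracle comparisons against the voxelised model.
#'
#' @param spec A [phantom_spec()].
#' @param seed RNG seed.
#' @param supersample Sub-voxel sampling factor per axis for the analytic
#'   volume (default 3).
#' @return List with `model` (a `model_instance_set`), `volume` (voxelised
#'   [lac_volume()]) and `analytic` (shell-model [lac_volume()]).
#' @export
generate_phantom <- function(spec, seed = 1, supersample = 3) {
  stopifnot(inherits(spec, "phantom_spec"))
  model <- build_vesicle_model(spec$geometry, spec$step,
                               spec$cyto_concentration, seed = seed,
                               box_nm = spec$box_nm)
  volume <- voxelize(model, voxel_nm = spec$voxel_nm)
  analytic <- .analytic_shell_volume(spec, model, supersample)
  list(model = model, volume = volume, analytic = analytic)
}

# closed-form concentric-shell LAC model of the same phantom
.analytic_shell_volume <- function(spec, model, supersample = 3) {
  mc <- material_constants()
  geom <- spec$geometry
  R_out <- geom$vesicle_diameter / 2
  mem <- geom$membrane_thickness
  R_in <- R_out - mem
  r_c <- model$crystal_radius_nm
  form <- bundled_crystal_forms()[["1trz"]]
  mac_p <- protein_mac()
  # crystal: occupancy * protein density of protein, water in the gaps
  rho_cryst <- form$occupancy * form$protein_density
  lac_of <- function(rho_prot, rho_lip = 0) {
    water <- pmax(1 - rho_prot / mc$protein_density - rho_lip / mc$dopc_density, 0)
    (rho_prot * mac_p + rho_lip * mc$dopc_lac_cm / mc$dopc_density +
        water * mc$water_lac_cm) * 1e-4
  }
  # lumen: lumen-assigned protein mass spread over the lumen volume
  counts <- instance_counts(model)
  lumen_ids <- names(model$ingredients)[vapply(model$ingredients, function(i)
    identical(i$compartment, "lumen"), logical(1))]
  lumen_mass <- sum(vapply(lumen_ids, function(id)
    .count0(counts, id) * model$ingredients[[id]]$mw, numeric(1))) / .AVOGADRO
  vol_lumen <- 4 / 3 * pi * ((R_in * 1e-7)^3 - (r_c * 1e-7)^3)
  rho_lumen <- if (vol_lumen > 0) lumen_mass / vol_lumen else 0
  # membrane shell: lipid mass over the shell, plus membrane protein mass
  mem_ids <- names(model$ingredients)[vapply(model$ingredients, function(i)
    identical(i$compartment, "membrane"), logical(1))]
  mem_prot_mass <- sum(vapply(mem_ids, function(id)
    .count0(counts, id) * model$ingredients[[id]]$mw, numeric(1))) / .AVOGADRO
  lip_mass <- .count0(counts, "DOPC") * mc$dopc_mw / .AVOGADRO
  vol_shell <- 4 / 3 * pi * ((R_out * 1e-7)^3 - (R_in * 1e-7)^3)
  rho_lip_shell <- if (vol_shell > 0) lip_mass / vol_shell else 0
  rho_prot_shell <- if (vol_shell > 0) mem_prot_mass / vol_shell else 0
  lac_cyto <- cytoplasm_lac(spec$cyto_concentration)
  lac_r <- function(r) {
    out <- numeric(length(r))
    out[r >= R_out] <- lac_cyto
    out[r >= R_in & r < R_out] <- lac_of(rho_prot_shell, rho_lip_shell)
    out[r >= r_c & r < R_in] <- lac_of(rho_lumen)
    out[r < r_c] <- lac_of(rho_cryst)
    out
  }
  n <- max(3L, round(spec$box_nm / spec$voxel_nm))
  s <- supersample
  sub <- (seq_len(s) - (s + 1) / 2) / s * spec$voxel_nm
  centers <- (seq_len(n) - (n + 1) / 2) * spec$voxel_nm
  fine <- as.vector(outer(sub, centers, "+"))
  g <- expand.grid(x = fine, y = fine, z = fine)
  vals <- lac_r(sqrt(g$x^2 + g$y^2 + g$z^2))
  arr_fine <- array(vals, dim = rep(n * s, 3))
  # average s^3 blocks
  arr <- array(0, dim = rep(n, 3))
  for (i in seq_len(s)) for (j in seq_len(s)) for (k in seq_len(s)) {
    arr <- arr + arr_fine[seq(i, n * s, by = s), seq(j, n * s, by = s),
                          seq(k, n * s, by = s)]
  }
  lac_volume(arr / s^3, spec$voxel_nm)
}

# named-count lookup that yields 0 for absent ingredients
.count0 <- function(counts, id) if (id %in% names(counts)) counts[[id]] else 0

#' Generate a multi-vesicle training scene
#'
#' Builds one phantom per spec, composes them into a cytoplasm-filled
#' scene on a horizontal grid, and returns the scene volume together with
#' the planted centers (ground truth for detector-threshold tuning).
#'
#' @param specs List of [phantom_spec()]s (one per planted vesicle).
#' @param dims Scene grid dimensions (default sized to fit the blocks on a
#'   square grid in x-z at the central y).
#' @param cyto_concentration Background concentration, g ml^-1.
#' @param seed Master seed; per-phantom seeds come from [split_seed()].
#' @param keep_models Keep the built instance models in the result
#'   (default FALSE: a full model holds millions of placements, and only
#'   the voxelised blocks are needed for scene assembly).
#' @return List with `volume` (a [lac_volume()]), `centers_vox` (n x 3)
#'   and `models` (NULL unless `keep_models`).
#' @export
generate_scene <- function(specs, dims = NULL, cyto_concentration = 0.2,
                           seed = 1, keep_models = FALSE) {
  n <- length(specs)
  stopifnot(n >= 1)
  models <- vector("list", n)
  vols <- lapply(seq_len(n), function(i) {
    m <- build_vesicle_model(specs[[i]]$geometry, specs[[i]]$step,
                             cyto_concentration, seed = split_seed(seed, i),
                             box_nm = specs[[i]]$box_nm)
    v <- voxelize(m, voxel_nm = specs[[i]]$voxel_nm)
    if (keep_models) models[[i]] <<- m
    rm(m); gc(FALSE)
    v
  })
  block <- max(vapply(vols, function(v) dim(v$data)[1], integer(1)))
  ncol_grid <- ceiling(sqrt(n))
  nrow_grid <- ceiling(n / ncol_grid)
  pitch <- block + 8
  if (is.null(dims)) {
    side <- max(ncol_grid, nrow_grid) * pitch + 8   # square x-z (tilt slices)
    dims <- c(side, dim(vols[[1]]$data)[2], side)
  }
  off_x <- (dims[1] - ncol_grid * pitch) %/% 2
  off_z <- (dims[3] - nrow_grid * pitch) %/% 2
  centers <- t(vapply(seq_len(n), function(i) {
    gx <- (i - 1) %% ncol_grid
    gz <- (i - 1) %/% ncol_grid
    c(off_x + pitch * gx + pitch %/% 2, (dims[2] + 1) %/% 2,
      off_z + pitch * gz + pitch %/% 2)
  }, numeric(3)))
  vol <- compose_volumes(vols, centers, dims, cyto_concentration)
  list(volume = vol, centers_vox = centers,
       models = if (keep_models) models else NULL)
}

#' Check that the package file formats round-trip losslessly
#'
#' Writes and re-reads a volume (MRC), a model placement table (TSV and
#' JSON) and a recipe (JSON) in a scratch directory and verifies the
#' reread objects agree with the originals to 1e-6 relative on floats.
#'
#' @param dir Directory for the scratch files (default `tempdir()`).
#' @param seed Seed for the small fixtures.
#' @return `TRUE` invisibly; stops with a message naming the first
#'   mismatching format otherwise.
#' @export
check_roundtrips <- function(dir = tempdir(), seed = 1) {
  ok <- function(a, b, what) {
    if (!isTRUE(all.equal(a, b, tolerance = 1e-6))) {
      stop("round-trip mismatch for ", what)
    }
  }
  vol <- lac_volume(array(stats::runif(5^3, 0, 1), c(5, 5, 5)), 37.42)
  p <- file.path(dir, "rt.mrc")
  write_mrc(vol, p)
  ok(read_mrc(p)$data, vol$data, "MRC volume")
  m <- build_vesicle_model(vesicle_geometry(120, 60), step = 6, seed = seed,
                           box_nm = 300, include_cytoplasm = FALSE,
                           include_lipids = FALSE)
  pt <- file.path(dir, "rt.tsv"); pj <- file.path(dir, "rt.json")
  write_model(m, pt); write_model(m, pj)
  ok(read_model(pt)$x, m$placements$x, "model TSV")
  ok(read_model(pj)$placements$x, m$placements$x, "model JSON")
  fr <- c(ins = 0.7, a = 0.2, b = 0.1)
  rec <- build_recipe(fr, c(a = 5e4, b = 2e4), c(a = "lumen", b = "membrane"),
                      insulin_ids = "ins",
                      form = bundled_crystal_forms()[["1trz"]])
  pr <- file.path(dir, "rt_recipe.json")
  write_recipe_json(rec, pr)
  ok(read_recipe_json(pr)$copy_number, rec$copy_number, "recipe JSON")
  invisible(TRUE)
}
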