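# Construction of coarse-grained 3D vesicle models: stochastic grid
# packing of compartments, soft-overlap relaxation, lipid tiling of the
# membrane, maturation-state partitioning of insulin, and the model
# library grid used for tomogram fitting.

.EMPTY_PLACEMENTS <- function() {
  data.frame(ingredient = character(0), x = numeric(0), y = numeric(0),
             z = numeric(0), qw = numeric(0), qx = numeric(0), qy = numeric(0),
             qz = numeric(0), stringsAsFactors = FALSE)
}

.random_quaternions <- function(n) {
  q <- matrix(stats::rnorm(4 * n), ncol = 4)
  q / sqrt(rowSums(q^2))
}

# rotate rows of `v` (n x 3) by per-row unit quaternions `q` (n x 4, w x y z)
.quat_rotate <- function(v, q) {
  w <- q[, 1]; u <- q[, 2:4, drop = FALSE]
  uv <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
              u[, 3] * v[, 1] - u[, 1] * v[, 3],
              u[, 1] * v[, 2] - u[, 2] * v[, 1])
  uuv <- cbind(u[, 2] * uv[, 3] - u[, 3] * uv[, 2],
               u[, 3] * uv[, 1] - u[, 1] * uv[, 3],
               u[, 1] * uv[, 2] - u[, 2] * uv[, 1])
  v + 2 * (w * uv + uuv)
}

#' Stochastic grid packing of one ingredient into a compartment
#'
#' Partitions space into a grid of cells sized to the ingredient's bounding
#' sphere, keeps the cells that fit entirely inside the compartment
#' (`sdf <= -margin`), samples cells without replacement and jitters each
#' placement uniformly within its cell.  Orientations are uniform random
#' quaternions.
#'
#' @param ingredient Ingredient id (string).
#' @param n_copies Number of copies requested.
#' @param bound_radius_nm Bounding-sphere radius of the ingredient, nm.
#' @param sdf Compartment [sdf_sphere()]/boolean combination.
#' @param region_min,region_max Length-3 bounds (nm) of the packing region.
#' @param max_occupancy Random-close-packing guard: requested bounding
#'   volume may not exceed this fraction of the free compartment volume
#'   (default 0.64).
#' @return Placements data frame; attribute `shortfall` gives the number of
#'   copies that could not be placed (0 normally; a warning is raised).
#' @export
pack_compartment <- function(ingredient, n_copies, bound_radius_nm, sdf,
                             region_min, region_max, max_occupancy = 0.64) {
  stopifnot(n_copies >= 0, bound_radius_nm > 0)
  if (n_copies == 0) {
    out <- .EMPTY_PLACEMENTS(); attr(out, "shortfall") <- 0L; return(out)
  }
  cell <- 2 * bound_radius_nm
  span <- region_max - region_min
  ncell <- pmax(1L, as.integer(floor(span / cell)))
  # estimate free volume and the fraction of cells that fit
  margin <- bound_radius_nm * (1 + sqrt(3) / 2) # center jitter stays inside
  probe_n <- 20000L
  probe_idx <- cbind(sample.int(ncell[1], probe_n, replace = TRUE),
                     sample.int(ncell[2], probe_n, replace = TRUE),
                     sample.int(ncell[3], probe_n, replace = TRUE))
  probe_pts <- sweep((probe_idx - 0.5) * cell, 2, region_min, "+")
  d <- sdf_eval(sdf, probe_pts)
  free_frac <- mean(d <= 0)
  fit_frac <- mean(d <= -margin)
  free_vol <- free_frac * prod(ncell) * cell^3
  req_vol <- n_copies * 4 / 3 * pi * bound_radius_nm^3
  if (free_vol <= 0 || req_vol > max_occupancy * free_vol) {
    stop("infeasible packing density for '", ingredient, "': requested ",
         signif(req_vol, 3), " nm^3 in ", signif(free_vol, 3),
         " nm^3 free volume (guard ", max_occupancy, ")")
  }
  total_cells <- prod(as.numeric(ncell))
  est_fit <- max(fit_frac * total_cells, 1)
  placed <- matrix(numeric(0), ncol = 3)
  if (total_cells <= 4e6 || est_fit < 2 * n_copies) {
    # exhaustive enumeration of fitting cells
    grid <- as.matrix(expand.grid(i = seq_len(ncell[1]), j = seq_len(ncell[2]),
                                  k = seq_len(ncell[3])))
    ctr <- sweep((grid - 0.5) * cell, 2, region_min, "+")
    ok <- which(sdf_eval(sdf, ctr) <= -margin)
    take <- min(n_copies, length(ok))
    pick <- if (length(ok)) ok[sample.int(length(ok), take)] else integer(0)
    placed <- ctr[pick, , drop = FALSE]
  } else {
    # lazy sampling of distinct cell indices, filtered by the sdf
    want <- n_copies
    tried <- sample.int(total_cells,
                        size = min(total_cells, ceiling(want / max(fit_frac, 1e-3) * 1.3)))
    i <- (tried - 1) %% ncell[1] + 1
    j <- ((tried - 1) %/% ncell[1]) %% ncell[2] + 1
    k <- (tried - 1) %/% (ncell[1] * ncell[2]) + 1
    ctr <- sweep((cbind(i, j, k) - 0.5) * cell, 2, region_min, "+")
    ok <- which(sdf_eval(sdf, ctr) <= -margin)
    take <- min(want, length(ok))
    placed <- ctr[ok[seq_len(take)], , drop = FALSE]
  }
  shortfall <- n_copies - nrow(placed)
  if (shortfall > 0) {
    warning("pack_compartment('", ingredient, "'): shortfall of ", shortfall,
            " of ", n_copies, " copies")
  }
  # jitter within the cell, bounded so the margin above keeps beads inside
  jit <- (matrix(stats::runif(3 * nrow(placed)), ncol = 3) - 0.5) * cell / 2
  pos <- placed + jit
  q <- .random_quaternions(nrow(pos))
  out <- data.frame(ingredient = rep(ingredient, nrow(pos)),
                    x = pos[, 1], y = pos[, 2], z = pos[, 3],
                    qw = q[, 1], qx = q[, 2], qy = q[, 3], qz = q[, 4],
                    stringsAsFactors = FALSE)
  attr(out, "shortfall") <- as.integer(shortfall)
  out
}

#' Evenly distributed points on a sphere (Fibonacci lattice)
#'
#' @param n Number of points.
#' @param radius Sphere radius, nm.
#' @param center Sphere center, nm.
#' @return n x 3 matrix.
#' @export
fibonacci_sphere <- function(n, radius, center = c(0, 0, 0)) {
  if (n == 0) return(matrix(numeric(0), ncol = 3))
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  pts <- radius * cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
  sweep(pts, 2, center, "+")
}

#' Tile the vesicle membrane with lipids
#'
#' Two leaflets of lipids on Fibonacci lattices.  The per-lipid area comes
#' from the lipid molecular volume divided by the leaflet thickness
#' (half the bilayer); the count is `2 * round(4 pi r^2 / a_lipid)` with
#' `r` the mid-bilayer radius, and the leaflets are offset by a quarter
#' bilayer on either side.
#'
#' @param radius_nm Mid-bilayer sphere radius, nm.
#' @param lipid_volume_A3 Molecular volume per lipid, A^3 (default 1150,
#'   DOPC).
#' @param bilayer_thickness_nm Bilayer thickness, nm (default 5).
#' @param center Sphere center, nm.
#' @return Placements data frame (`ingredient = "DOPC"`) with attribute
#'   `lipid_count`.
#' @export
tile_membrane <- function(radius_nm, lipid_volume_A3 = 1150,
                          bilayer_thickness_nm = 5, center = c(0, 0, 0)) {
  if (radius_nm <= 0) {
    out <- .EMPTY_PLACEMENTS(); attr(out, "lipid_count") <- 0L; return(out)
  }
  leaflet_nm <- bilayer_thickness_nm / 2
  a_lipid_nm2 <- lipid_volume_A3 * 1e-3 / leaflet_nm   # A^3 -> nm^3
  per_leaflet <- round(4 * pi * radius_nm^2 / a_lipid_nm2)
  pts <- rbind(
    fibonacci_sphere(per_leaflet, radius_nm + bilayer_thickness_nm / 4, center),
    fibonacci_sphere(per_leaflet, radius_nm - bilayer_thickness_nm / 4, center)
  )
  out <- data.frame(ingredient = rep("DOPC", nrow(pts)),
                    x = pts[, 1], y = pts[, 2], z = pts[, 3],
                    qw = 1, qx = 0, qy = 0, qz = 0, stringsAsFactors = FALSE)
  attr(out, "lipid_count") <- as.integer(2 * per_leaflet)
  out
}

#' Maturation state of a vesicle
#'
#' Six discrete steps from immature (step 1: all insulin as proinsulin) to
#' mature (step 6: all insulin in the crystal).  The cleaved fraction grows
#' linearly with the step; crystallisation follows cleavage quadratically,
#' so transitional steps hold free cleaved monomer in the lumen.
#'
#' @param step Integer 1..6.
#' @return Object of class `maturation_state` with fields `step` and
#'   `fractions` (crystal, proinsulin, monomer; sum to 1).
#' @export
maturation_state <- function(step) {
  stopifnot(step %in% 1:6)
  m <- (step - 1) / 5                 # cleaved fraction
  crystal <- m^2
  monomer <- m - crystal
  structure(list(step = as.integer(step),
                 fractions = c(crystal = crystal, proinsulin = 1 - m,
                               monomer = monomer)),
            class = "maturation_state")
}

#' Partition insulin among crystal, proinsulin and free monomer
#'
#' Largest-remainder rounding of the maturation fractions to integer
#' counts summing exactly to `total_insulin`.
#'
#' @param total_insulin Total insulin copy number.
#' @param state A [maturation_state()] (or fractions vector summing to 1).
#' @return Named integer vector (crystal, proinsulin, monomer).
#' @export
partition_maturation <- function(total_insulin, state) {
  f <- if (inherits(state, "maturation_state")) state$fractions else state
  stopifnot(abs(sum(f) - 1) < 1e-9, all(f >= 0))
  exact <- f * total_insulin
  base <- floor(exact)
  rem <- as.integer(round(total_insulin - sum(base)))
  if (rem > 0) {
    extra <- order(exact - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  stats::setNames(as.integer(base), names(f))
}

#' Soft-overlap relaxation of placed instances
#'
#' Iterative rigid-body translation along the summed soft repulsion between
#' beads: overlapping bead pairs push their instances apart with force
#' proportional to overlap depth (zero beyond contact).  Instances are
#' reflected back inside their compartment boundary, and membrane-anchored
#' ingredients keep their radial distance (displacement projected onto the
#' sphere tangent).  The total overlap energy is nonincreasing up to
#' tolerance.
#'
#' @param model A `model_instance_set` (see [build_vesicle_model()]).
#' @param iterations Number of iterations (default 150).
#' @param step_scale Displacement per unit overlap depth (default 0.3).
#' @return The model with updated placements; attribute `energy_trace`
#'   records the per-iteration overlap energy.
#' @export
relax <- function(model, iterations = 150, step_scale = 0.3) {
  pl <- model$placements
  n <- nrow(pl)
  if (n == 0 || iterations == 0) { attr(model, "energy_trace") <- numeric(0); return(model) }
  ing <- model$ingredients
  radius_of <- vapply(ing, function(i) i$bead_radius, numeric(1))
  # expand beads: instance index, offsets rotated once per iteration
  energy_trace <- numeric(iterations)
  membrane <- pl$ingredient %in% names(ing)[vapply(ing, function(i)
    isTRUE(i$compartment == "membrane"), logical(1))]
  bound <- model$boundary_sdf
  for (it in seq_len(iterations)) {
    beads <- .expand_beads(pl, ing)
    r <- radius_of[beads$ingredient]
    cut <- 2 * max(r)
    pairs <- .neighbor_pairs(cbind(beads$x, beads$y, beads$z), cut)
    force <- matrix(0, n, 3)
    energy <- 0
    if (nrow(pairs)) {
      p1 <- pairs[, 1]; p2 <- pairs[, 2]
      dx <- beads$x[p1] - beads$x[p2]
      dy <- beads$y[p1] - beads$y[p2]
      dz <- beads$z[p1] - beads$z[p2]
      d <- sqrt(dx^2 + dy^2 + dz^2)
      contact <- r[p1] + r[p2]
      inst1 <- beads$instance[p1]; inst2 <- beads$instance[p2]
      ov <- contact - d
      sel <- which(ov > 0 & d > 1e-9 & inst1 != inst2)
      if (length(sel)) {
        ovs <- ov[sel]; ds <- d[sel]
        fx <- ovs * dx[sel] / ds; fy <- ovs * dy[sel] / ds; fz <- ovs * dz[sel] / ds
        i1 <- inst1[sel]; i2 <- inst2[sel]
        force[, 1] <- force[, 1] + .accum(i1, fx, n) - .accum(i2, fx, n)
        force[, 2] <- force[, 2] + .accum(i1, fy, n) - .accum(i2, fy, n)
        force[, 3] <- force[, 3] + .accum(i1, fz, n) - .accum(i2, fz, n)
        energy <- sum(ovs^2)
      }
    }
    energy_trace[it] <- energy
    if (energy == 0) { energy_trace <- energy_trace[seq_len(it)]; break }
    nb <- tabulate(beads$instance, n)
    disp <- step_scale * force / pmax(nb, 1)
    if (any(membrane)) {
      # project out the radial component for membrane-anchored instances
      ctr <- model$center %||% c(0, 0, 0)
      pos <- cbind(pl$x, pl$y, pl$z)[membrane, , drop = FALSE]
      rel <- sweep(pos, 2, ctr)
      rn <- sqrt(rowSums(rel^2)); rn[rn == 0] <- 1
      u <- rel / rn
      rad <- rowSums(disp[membrane, , drop = FALSE] * u)
      disp[membrane, ] <- disp[membrane, , drop = FALSE] - u * rad
    }
    pl$x <- pl$x + disp[, 1]; pl$y <- pl$y + disp[, 2]; pl$z <- pl$z + disp[, 3]
    if (!is.null(bound)) {
      pos <- cbind(pl$x, pl$y, pl$z)
      d <- sdf_eval(bound, pos)
      out <- which(!membrane & d > 0)
      if (length(out)) {
        # reflect back inside the boundary sphere
        ctr <- model$center %||% c(0, 0, 0)
        rel <- sweep(pos[out, , drop = FALSE], 2, ctr)
        rn <- sqrt(rowSums(rel^2)); rn[rn == 0] <- 1
        scale <- (rn - 2 * d[out]) / rn
        newp <- sweep(rel * scale, 2, ctr, "+")
        pl$x[out] <- newp[, 1]; pl$y[out] <- newp[, 2]; pl$z[out] <- newp[, 3]
      }
    }
  }
  model$placements <- pl
  attr(model, "energy_trace") <- energy_trace
  model
}

.accum <- function(idx, val, n) {
  out <- numeric(n)
  s <- rowsum(val, idx)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}

# bead expansion: one row per bead with instance index
.expand_beads <- function(pl, ingredients) {
  parts <- lapply(split(seq_len(nrow(pl)), pl$ingredient), function(rows) {
    ing <- ingredients[[pl$ingredient[rows[1]]]]
    off <- ing$bead_offsets
    k <- nrow(off)
    if (k == 1 && all(off == 0)) {
      data.frame(instance = rows, ingredient = pl$ingredient[rows],
                 x = pl$x[rows], y = pl$y[rows], z = pl$z[rows],
                 mass = ing$bead_masses[1], stringsAsFactors = FALSE)
    } else {
      q <- as.matrix(pl[rows, c("qw", "qx", "qy", "qz")])
      idx <- rep(seq_along(rows), each = k)
      offs <- off[rep(seq_len(k), length(rows)), , drop = FALSE]
      rot <- .quat_rotate(offs, q[idx, , drop = FALSE])
      data.frame(instance = rows[idx], ingredient = pl$ingredient[rows[1]],
                 x = pl$x[rows][idx] + rot[, 1], y = pl$y[rows][idx] + rot[, 2],
                 z = pl$z[rows][idx] + rot[, 3],
                 mass = rep(ing$bead_masses, length(rows)),
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

# all pairs of points closer than `cut`, via cell binning
.neighbor_pairs <- function(pts, cut) {
  n <- nrow(pts)
  if (n < 2) return(matrix(integer(0), ncol = 2))
  cell <- floor(sweep(pts, 2, apply(pts, 2, min)) / cut)
  key <- cell[, 1] + 100000 * (cell[, 2] + 100000 * cell[, 3])
  groups <- split(seq_len(n), key)
  # candidate pairs: same cell or neighbouring cells
  offs <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  offs <- offs[seq_len(13), , drop = FALSE]  # half the neighbours (avoid double count)
  pair_list <- list()
  for (g in groups) {
    if (length(g) > 1) {
      cmb <- utils::combn(g, 2)
      pair_list[[length(pair_list) + 1]] <- t(cmb)
    }
  }
  keymap <- new.env(hash = TRUE, parent = emptyenv())
  for (nm in names(groups)) assign(nm, groups[[nm]], envir = keymap)
  for (o in seq_len(nrow(offs))) {
    nk <- (cell[, 1] + offs[o, 1]) + 100000 * ((cell[, 2] + offs[o, 2]) +
                                                 100000 * (cell[, 3] + offs[o, 3]))
    nk_chr <- as.character(nk)
    has <- vapply(nk_chr, function(k) !is.null(keymap[[k]]), logical(1))
    if (any(has)) {
      src <- which(has)
      pl <- lapply(src, function(i) {
        others <- keymap[[nk_chr[i]]]
        cbind(i, others)
      })
      pair_list[[length(pair_list) + 1]] <- do.call(rbind, pl)
    }
  }
  if (!length(pair_list)) return(matrix(integer(0), ncol = 2))
  pairs <- do.call(rbind, pair_list)
  d2 <- rowSums((pts[pairs[, 1], , drop = FALSE] - pts[pairs[, 2], , drop = FALSE])^2)
  pairs[d2 < cut^2, , drop = FALSE]
}

#' Model library grid
#'
#' The sampling grid for the fitting library: vesicle diameters
#' (geometric interpolation, default 16 values from 130 to 473 nm),
#' relative crystal sizes (default 6), the six maturation steps and
#' cytoplasm concentrations (default 6 values, 0.06 to 0.2 g ml^-1).
#'
#' @param n_diameters,diameter_range Diameter axis.
#' @param crystal_ratios Crystal diameter as a fraction of the vesicle
#'   diameter (capped by the geometry).
#' @param steps Maturation steps.
#' @param concentrations Cytoplasm concentrations, g ml^-1.
#' @return Object of class `library_grid`.
#' @export
library_grid <- function(n_diameters = 16, diameter_range = c(130, 473),
                         crystal_ratios = seq(0.2, 0.7, by = 0.1),
                         steps = 1:6,
                         concentrations = seq(0.06, 0.2, length.out = 6)) {
  diameters <- exp(seq(log(diameter_range[1]), log(diameter_range[2]),
                       length.out = n_diameters))
  structure(list(diameters = diameters, crystal_ratios = crystal_ratios,
                 steps = steps, concentrations = concentrations),
            class = "library_grid")
}

#' Enumerate the model library
#'
#' Cartesian product of the four grid axes.  For each entry the total
#' insulin content is set by the entry's crystal capacity and the numbers
#' of soluble and membrane proteins scale linearly with it.
#'
#' @param grid A [library_grid()].
#' @param form A [crystal_form()] (default bundled rhombohedral form).
#' @param membrane_thickness_nm Membrane thickness, nm.
#' @param monomer_mw Insulin monomer weight, Da.
#' @return Data frame of model specs with one row per library entry:
#'   diameter, crystal ratio and diameter, step, concentration, insulin
#'   copy number and the protein scale factor.
#' @export
build_library <- function(grid, form = NULL, membrane_thickness_nm = 5,
                          monomer_mw = 5808) {
  stopifnot(inherits(grid, "library_grid"))
  if (is.null(form)) form <- bundled_crystal_forms()[["1trz"]]
  specs <- expand.grid(diameter = grid$diameters, crystal_ratio = grid$crystal_ratios,
                       step = grid$steps, concentration = grid$concentrations,
                       KEEP.OUT.ATTRS = FALSE)
  specs$crystal_diameter <- pmin(specs$crystal_ratio * specs$diameter,
                                 specs$diameter - 2 * membrane_thickness_nm)
  ref <- vesicle_geometry(320, 200, membrane_thickness_nm)
  n_ref <- insulin_copies(ref, form, monomer_mw)
  specs$insulin_total <- vapply(seq_len(nrow(specs)), function(i) {
    g <- vesicle_geometry(specs$diameter[i], specs$crystal_diameter[i],
                          membrane_thickness_nm)
    insulin_copies(g, form, monomer_mw)
  }, numeric(1))
  specs$protein_scale <- specs$insulin_total / n_ref
  specs$entry_id <- sprintf("d%03.0f_c%03.0f_s%d_g%.2f", specs$diameter,
                            specs$crystal_diameter, specs$step, specs$concentration)
  specs
}
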