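# Crystal lattice placement, packing, relaxation, membrane tiling,
# maturation partitioning and the library grid.

test_that("crystal placement is deterministic, coherent and lattice-like", {
  lat <- lattice_spec()
  b <- sdf_sphere(radius = 30, role = "crystal-boundary")
  p1 <- place_crystal(lat, b)
  p2 <- place_crystal(lat, b)
  expect_identical(p1, p2)                      # no RNG
  expect_true(all(p1$qw == 1 & p1$qx == 0))     # single coherent orientation
  # all sites inside the boundary
  expect_true(all(sqrt(p1$x^2 + p1$y^2 + p1$z^2) <= 30 + 1e-9))
  # tiny boundary still contains the origin site
  p0 <- place_crystal(lat, sdf_sphere(radius = 1, role = "crystal-boundary"))
  expect_gte(nrow(p0), 1)
  # pairwise distances drawn from the finite set of lattice vector lengths
  d <- as.matrix(stats::dist(cbind(p1$x, p1$y, p1$z)))
  nn <- sort(unique(round(d[d > 1e-9], 6)))
  expect_lt(length(nn), nrow(p1) * (nrow(p1) - 1) / 2)
})

test_that("crystal site density approaches 3 per cell volume for large spheres", {
  lat <- lattice_spec()
  r <- 90
  p <- place_crystal(lat, sdf_sphere(radius = r, role = "crystal-boundary"))
  expected <- 4 / 3 * pi * r^3 / (lat$cell_volume_A3 * 1e-3) * 3
  expect_equal(nrow(p) / expected, 1, tolerance = 0.05)
})

test_that("degenerate lattice cells are rejected", {
  lat <- lattice_spec()
  lat$basis[2, ] <- lat$basis[1, ]
  expect_error(place_crystal(lat, sdf_sphere(radius = 10,
                                             role = "crystal-boundary")),
               "degenerate")
})

test_that("packing fills a compartment inside the boundary and guards density", {
  sdf <- sdf_sphere(radius = 50)
  set.seed(1)
  out <- pack_compartment("x", 200, 2, sdf, rep(-50, 3), rep(50, 3))
  expect_equal(nrow(out), 200)
  expect_equal(attr(out, "shortfall"), 0L)
  expect_true(all(sqrt(out$x^2 + out$y^2 + out$z^2) <= 50 - 2 + 1e-9))
  expect_equal(pack_compartment("x", 0, 2, sdf, rep(-50, 3), rep(50, 3)) |> nrow(), 0)
  # quaternions are unit norm
  expect_equal(out$qw^2 + out$qx^2 + out$qy^2 + out$qz^2, rep(1, 200),
               tolerance = 1e-9)
  # requested occupancy ~0.9 trips the random-close-packing guard
  expect_error(pack_compartment("x", 14000, 2, sdf, rep(-50, 3), rep(50, 3)),
               "infeasible")
})

test_that("single placements are uniform over octants", {
  sdf <- sdf_sphere(radius = 60)
  set.seed(99)
  oct <- replicate(1000, {
    p <- pack_compartment("x", 1, 1.5, sdf, rep(-60, 3), rep(60, 3))
    1 + (p$x > 0) + 2 * (p$y > 0) + 4 * (p$z > 0)
  })
  tab <- tabulate(oct, 8)
  p <- stats::chisq.test(tab)$p.value
  expect_gt(p, 0.001)
})

test_that("relaxation separates overlaps and never increases energy", {
  # two single-bead instances at overlap depth d: one step must separate them
  ing <- list(a = model_ingredient("a", 15000, "lumen", bead_radius = 1.7))
  pl <- data.frame(ingredient = c("a", "a"), x = c(-1, 1), y = 0, z = 0,
                   qw = 1, qx = 0, qy = 0, qz = 0)
  model <- structure(list(placements = pl, ingredients = ing,
                          center = c(0, 0, 0), boundary_sdf = NULL),
                     class = "model_instance_set")
  r1 <- relax(model, iterations = 1)
  expect_gt(abs(diff(r1$placements$x)), 2)
  # no overlaps -> identity
  pl2 <- pl; pl2$x <- c(-5, 5)
  model2 <- structure(list(placements = pl2, ingredients = ing,
                           center = c(0, 0, 0), boundary_sdf = NULL),
                      class = "model_instance_set")
  r2 <- relax(model2, iterations = 3)
  expect_identical(r2$placements$x, pl2$x)
  # 200-bead overlap soup: energy nonincreasing, final overlaps small
  set.seed(8)
  n <- 200
  soup <- data.frame(ingredient = "a",
                     x = stats::runif(n, -12, 12), y = stats::runif(n, -12, 12),
                     z = stats::runif(n, -12, 12), qw = 1, qx = 0, qy = 0, qz = 0)
  model3 <- structure(list(placements = soup, ingredients = ing,
                           center = c(0, 0, 0), boundary_sdf = NULL),
                      class = "model_instance_set")
  r3 <- relax(model3, iterations = 150, step_scale = 0.3)
  tr <- attr(r3, "energy_trace")
  expect_true(all(diff(tr) <= max(tr) * 0.02))
  pts <- cbind(r3$placements$x, r3$placements$y, r3$placements$z)
  dmin <- as.matrix(stats::dist(pts)); diag(dmin) <- Inf
  worst_overlap <- max(0, 3.4 - min(dmin))
  expect_lte(worst_overlap, 0.1 * 1.7)
})

test_that("membrane tiling scales with area and respects geometry", {
  t1 <- tile_membrane(100)
  t2 <- tile_membrane(200)
  expect_equal(attr(t2, "lipid_count") / attr(t1, "lipid_count"), 4,
               tolerance = 0.01)
  expect_equal(attr(tile_membrane(0), "lipid_count"), 0L)
  # total lipid volume matches the bilayer shell volume within 5%
  mc <- material_constants()
  r <- 157.5
  tl <- tile_membrane(r, bilayer_thickness_nm = 5)
  shell_vol_nm3 <- 4 / 3 * pi * ((r + 2.5)^3 - (r - 2.5)^3)
  lipid_vol_nm3 <- attr(tl, "lipid_count") * mc$dopc_volume_A3 * 1e-3
  expect_equal(lipid_vol_nm3 / shell_vol_nm3, 1, tolerance = 0.05)
  # two leaflet radii present
  rr <- round(sqrt(tl$x^2 + tl$y^2 + tl$z^2), 6)
  expect_equal(sort(unique(rr)), c(r - 1.25, r + 1.25), tolerance = 1e-6)
})

test_that("maturation partitioning uses largest-remainder integer counts", {
  expect_equal(unname(partition_maturation(1000, maturation_state(6))),
               c(1000L, 0L, 0L))
  expect_equal(unname(partition_maturation(1000, maturation_state(1))),
               c(0L, 1000L, 0L))
  out <- partition_maturation(10, c(crystal = 0.5, proinsulin = 0.3,
                                    monomer = 0.2))
  expect_equal(unname(out), c(5L, 3L, 2L))
  for (s in 1:6) {
    p <- partition_maturation(12345, maturation_state(s))
    expect_equal(sum(p), 12345)
    expect_true(all(p >= 0))
  }
  # transitional steps hold free monomer
  expect_gt(partition_maturation(1e5, maturation_state(3))[["monomer"]], 0)
})

test_that("the default library grid enumerates 3456 specs", {
  lib <- build_library(library_grid())
  expect_equal(nrow(lib), 3456)
  expect_equal(nrow(build_library(library_grid(
    n_diameters = 1, diameter_range = c(200, 200), crystal_ratios = 0.5,
    steps = 3, concentrations = 0.1))), 1)
  g <- library_grid(n_diameters = 3, crystal_ratios = c(0.3, 0.5), steps = 1:2,
                    concentrations = c(0.1, 0.2))
  expect_equal(nrow(build_library(g)), 3 * 2 * 2 * 2)
  # protein counts scale linearly with the entry's insulin content
  expect_equal(lib$protein_scale,
               lib$insulin_total / lib$insulin_total[
                 which.min(abs(lib$diameter - 320) + abs(lib$crystal_diameter - 200))],
               tolerance = 0.05)
})

test_that("built models match requested counts and stay inside the vesicle", {
  geom <- vesicle_geometry(240, 150)
  m <- build_vesicle_model(geom, step = 4, seed = 21, box_nm = 500,
                           include_cytoplasm = FALSE)
  counts <- instance_counts(m)
  part <- partition_maturation(m$insulin_total, maturation_state(4))
  # all insulin accounted for: hexamers*6 + free monomers + proinsulin
  expect_equal(unname(6 * counts[["insulin_hexamer"]] +
                        counts[["insulin_monomer"]] + counts[["proinsulin"]]),
               m$insulin_total)
  expect_equal(unname(counts[["proinsulin"]]), unname(part[["proinsulin"]]))
  # no lumen bead outside the vesicle (tolerance: 5% of a bead radius)
  lum <- names(m$ingredients)[vapply(m$ingredients, function(i)
    i$compartment %in% c("lumen", "crystal"), logical(1))]
  pl <- m$placements[m$placements$ingredient %in% lum, ]
  r <- sqrt(pl$x^2 + pl$y^2 + pl$z^2)
  expect_true(all(r <= (240 / 2 - 5) + 1.7 * 0.05))
  # bit-for-bit reproducibility under the seed
  m2 <- build_vesicle_model(geom, step = 4, seed = 21, box_nm = 500,
                            include_cytoplasm = FALSE)
  expect_identical(m$placements, m2$placements)
})

test_that("model placements survive TSV and JSON round-trips", {
  m <- build_vesicle_model(vesicle_geometry(180, 100), step = 6, seed = 2,
                           box_nm = 400, include_cytoplasm = FALSE,
                           include_lipids = FALSE)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  js <- withr::local_tempfile(fileext = ".json")
  write_model(m, tsv); write_model(m, js)
  back_tsv <- read_model(tsv)
  back_js <- read_model(js)
  expect_equal(nrow(back_tsv), nrow(m$placements))
  expect_equal(back_tsv$x, m$placements$x, tolerance = 1e-6)
  expect_equal(back_js$placements$x, m$placements$x, tolerance = 1e-6)
  expect_equal(back_js$geometry$vesicle_diameter, 180)
})
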