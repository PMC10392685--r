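# Material attenuation, the mixture rule, voxelisation and the tomogram
# simulator.

test_that("single-element materials reproduce the tabulated value", {
  mac_c <- element_mac("C")
  m <- material_mac(c(C = 1))
  expect_equal(m$mac, mac_c)
  expect_equal(m$mw, 12.011)
  expect_error(element_mac("Xx"), "no photoabsorption data")
  expect_error(material_mac(c(C = -1)), "negative")
})

test_that("the mixture rule is a mass-fraction-weighted sum", {
  macs <- c(protein = 8000, water = 1100, lipid = 9000)
  # three-component fixture against a brute-force sum
  w <- c(protein = 0.3, water = 0.55, lipid = 0.15)
  rho <- 1.05
  expect_equal(mixture_lac(w, macs, rho),
               rho * sum(w * macs) * 1e-4, tolerance = 1e-12)
  # pure water recovers the water value
  expect_equal(mixture_lac(c(water = 1), macs, 1), 1100e-4)
  # 50/50 at fixed density is the arithmetic mean of the MACs
  expect_equal(mixture_lac(c(protein = .5, water = .5), macs, 1),
               mean(macs[c("protein", "water")]) * 1e-4)
  expect_error(mixture_lac(c(water = 0.9), macs, 1), "sum to 1")
  expect_error(mixture_lac(c(water = 1), macs, -1), "negative")
  # mixture LAC bounded by component LACs at matched density
  lo <- mixture_lac(c(water = 1), macs, rho)
  hi <- mixture_lac(c(lipid = 1), macs, rho)
  expect_gte(mixture_lac(w, macs, rho), lo * min(w["water"], 1))
  expect_lte(mixture_lac(w, macs, rho), hi)
})

test_that("an empty model voxelises to uniform water", {
  empty <- structure(list(placements = NULL, ingredients = list(),
                          geometry = NULL, box_nm = 300),
                     class = "model_instance_set")
  v <- voxelize(empty, voxel_nm = 50)
  water <- material_constants()$water_lac_cm * 1e-4
  expect_true(all(abs(v$data - water) < 1e-12))
})

test_that("a bead at a voxel center deposits its whole mass there", {
  ing <- list(a = model_ingredient("a", 3e6, "lumen"))
  # voxel centers for a 5^3 grid at 40 nm sit at -80, -40, 0, 40, 80
  pl <- data.frame(ingredient = "a", x = 0, y = 0, z = 0,
                   qw = 1, qx = 0, qy = 0, qz = 0)
  m <- structure(list(placements = pl, ingredients = ing, geometry = NULL,
                      box_nm = 200), class = "model_instance_set")
  v <- voxelize(m, voxel_nm = 40)
  mc <- material_constants()
  vox_cm3 <- (40e-7)^3
  mass <- 3e6 / 6.02214076e23
  water_vol <- vox_cm3 - mass / 1.22
  oracle <- (mass * protein_mac() + water_vol * mc$water_lac_cm) / vox_cm3 * 1e-4
  expect_equal(v$data[3, 3, 3], oracle, tolerance = 1e-9)
  expect_equal(attr(v, "protein_mass_g"), mass, tolerance = 1e-20)
})

test_that("voxelisation conserves deposited mass for a built vesicle", {
  m <- build_vesicle_model(vesicle_geometry(240, 150), step = 6, seed = 3,
                           box_nm = 480, include_cytoplasm = FALSE)
  v <- voxelize(m, dims = c(15, 15, 15))
  beads_mass <- sum(.expand_beads(m$placements, m$ingredients)$mass) /
    6.02214076e23
  expect_equal(attr(v, "protein_mass_g") + attr(v, "lipid_mass_g"),
               beads_mass, tolerance = 1e-9)
})

test_that("mature crystal voxels match the closed-form shell model", {
  spec <- phantom_spec(vesicle_diameter = 320, crystal_diameter = 200,
                       step = 6)
  ph <- generate_phantom(spec, seed = 5)
  ctr <- (dim(ph$volume$data) + 1) %/% 2
  core <- ph$volume$data[(ctr[1] - 1):(ctr[1] + 1), (ctr[2] - 1):(ctr[2] + 1),
                         (ctr[3] - 1):(ctr[3] + 1)]
  acore <- ph$analytic$data[(ctr[1] - 1):(ctr[1] + 1),
                            (ctr[2] - 1):(ctr[2] + 1),
                            (ctr[3] - 1):(ctr[3] + 1)]
  expect_equal(mean(core) / mean(acore), 1, tolerance = 0.05)
})

test_that("FBP reconstructs a noiseless phantom within 5%", {
  n <- 49
  arr <- array(0.1, c(n, 3, n))
  c0 <- (n + 1) / 2
  for (i in 1:n) for (k in 1:n) {
    if ((i - c0)^2 + (k - c0)^2 < 8^2) arr[i, , k] <- 0.5
  }
  rec <- simulate_tomogram(lac_volume(arr, 37.42), fast_op(n_angles = 120),
                           seed = 1)
  inside <- (outer((1:n - c0)^2, (1:n - c0)^2, "+") < 6^2)
  rel_l2 <- sqrt(mean((rec$data[, 2, ][inside] - 0.5)^2)) / 0.5
  expect_lt(rel_l2, 0.05)
})

test_that("shot noise is unbiased and replicate averaging shrinks it", {
  n <- 25
  u <- lac_volume(array(0.3, c(n, 3, n)), 37.42)
  r1 <- simulate_tomogram(u, fast_op(replicates = 1, photons = 2000), seed = 2)
  r10 <- simulate_tomogram(u, fast_op(replicates = 10, photons = 2000), seed = 3)
  inner <- function(x) x$data[8:18, 2, 8:18]
  ref <- simulate_tomogram(u, fast_op(), seed = 1)   # noise-free reference
  s1 <- stats::sd(inner(r1) - inner(ref))
  s10 <- stats::sd(inner(r10) - inner(ref))
  # unbiased: means agree within the averaged noise
  expect_lt(abs(mean(inner(r10)) - mean(inner(ref))), 3 * s10)
  # averaging 10 replicates cuts sigma by ~sqrt(10)
  expect_equal(s1 / s10, sqrt(10), tolerance = 0.35)
})

test_that("projection and reconstruction are linear in the input", {
  # a positive background keeps the zero-clipping inactive so the
  # operator chain is exactly linear: f(A+B+bg) = f(A+bg) + f(B+bg) - f(bg)
  n <- 33
  bg <- array(0.2, c(n, 3, n))
  a <- bg; a[10:14, , 10:14] <- 0.6
  b <- bg; b[20:26, , 18:24] <- 0.45
  ab <- a + b - bg
  op <- fast_op(n_angles = 60)
  ra <- simulate_tomogram(lac_volume(a, 37.42), op, seed = 1)
  rb <- simulate_tomogram(lac_volume(b, 37.42), op, seed = 1)
  rbg <- simulate_tomogram(lac_volume(bg, 37.42), op, seed = 1)
  rab <- simulate_tomogram(lac_volume(ab, 37.42), op, seed = 1)
  expect_equal(rab$data, ra$data + rb$data - rbg$data, tolerance = 1e-6)
})

test_that("radial profiles are flat on uniform images and symmetric", {
  img <- matrix(0.25, 41, 41)
  p <- radial_profile(img, center = c(21, 21), n_bins = 10)
  expect_true(all(abs(p$value - 0.25) < 1e-12))
  expect_true(all(diff(p$radius_nm) > 0))
  # rotation by 90 degrees leaves the profile unchanged
  set.seed(4)
  img2 <- matrix(stats::runif(41 * 41), 41, 41)
  img2 <- (img2 + t(img2)) / 2
  p1 <- radial_profile(img2, center = c(21, 21), n_bins = 12)
  p2 <- radial_profile(t(img2)[, rev(seq_len(41))][, ], center = c(21, 21),
                       n_bins = 12)
  expect_equal(p1$value, p2$value, tolerance = 1e-9)
})

test_that("the projected analytic sphere matches the Abel-type closed form", {
  # sphere radius R, LAC mu0, in vacuum; projection along y has
  # profile(r) = 2 mu0 sqrt(R^2 - r^2)
  n <- 65; vox <- 37.42; R <- 12 * vox; mu0 <- 0.5
  c0 <- (n + 1) / 2
  ss <- 4
  sub <- (seq_len(ss) - (ss + 1) / 2) / ss
  centers <- seq_len(n) - c0
  fine <- as.vector(outer(sub, centers, "+")) * vox
  arr_fine <- array(0, rep(n * ss, 3))
  rr2 <- outer(fine^2, fine^2, "+")
  for (iy in seq_len(n * ss)) {
    arr_fine[, iy, ] <- mu0 * ((rr2 + fine[iy]^2) <= R^2)
  }
  # block-average to voxels
  arr <- array(0, rep(n, 3))
  for (i in seq_len(ss)) for (j in seq_len(ss)) for (k in seq_len(ss)) {
    arr <- arr + arr_fine[seq(i, n * ss, ss), seq(j, n * ss, ss),
                          seq(k, n * ss, ss)]
  }
  arr <- arr / ss^3
  proj <- apply(arr, c(1, 3), sum) * vox * 1e-3      # um^-1 * um
  prof <- radial_profile(proj, center = c(c0, c0), n_bins = 12,
                         voxel_nm = vox)
  keep <- prof$radius_nm <= 0.8 * R
  closed <- 2 * mu0 * sqrt(R^2 - prof$radius_nm[keep]^2) * 1e-3
  expect_equal(prof$value[keep], closed, tolerance = 0.02)
})

test_that("brightest-voxel centring uses the first-index tie break", {
  arr <- array(0.1, c(9, 3, 9))
  arr[3, 2, 4] <- 0.9
  arr[7, 2, 6] <- 0.9
  p <- radial_profile(lac_volume(arr, 37.42), n_bins = 3)
  expect_equal(unname(attr(p, "center")[1]), 3)
  expect_error(radial_profile(lac_volume(arr, 37.42), center = c(99, 1, 1)),
               "outside")
})

test_that("photon budget must be positive and volumes finite", {
  expect_error(projection_operator(photons = 0), "positive")
  bad <- lac_volume(array(0.1, c(5, 3, 5)), 10)
  bad$data[1] <- NA
  expect_error(simulate_tomogram(bad, fast_op(), 1), "finite")
})
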