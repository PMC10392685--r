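# NSAF, mass fractions, the crystal mass split, occupancy and copy numbers.

test_that("nsaf normalises length-corrected abundances", {
  e <- data.frame(protein_id = c("a", "b"), raw_abundance = c(10, 20),
                  length = c(100, 200))
  expect_equal(unname(nsaf(e)), c(0.5, 0.5))
  one <- data.frame(protein_id = "x", raw_abundance = 3, length = 70)
  expect_equal(unname(nsaf(one)), 1)
  # 5-entry fixture vs direct recomputation
  e5 <- data.frame(protein_id = letters[1:5],
                   raw_abundance = c(5, 0, 12, 7, 1),
                   length = c(50, 80, 300, 120, 60))
  v <- e5$raw_abundance / e5$length
  expect_equal(unname(nsaf(e5)), v / sum(v))
  expect_equal(sum(nsaf(e5)), 1, tolerance = 1e-12)
  e0 <- data.frame(protein_id = "a", raw_abundance = 0, length = 10)
  expect_error(nsaf(e0), "zero")
})

test_that("mass fractions weight molar fractions by molecular weight", {
  ns <- c(a = 0.5, b = 0.5)
  expect_equal(unname(mass_fractions(ns, c(a = 2e4, b = 1e4))),
               c(2 / 3, 1 / 3))
  expect_equal(unname(mass_fractions(c(x = 1), c(x = 5e4))), 1)
  ns5 <- c(a = .1, b = .2, c = .3, d = .25, e = .15)
  mw5 <- c(a = 1e4, b = 5e4, c = 2e4, d = 8e4, e = 3e4)
  w <- ns5 * mw5
  expect_equal(mass_fractions(ns5, mw5), w / sum(w))
  expect_error(mass_fractions(ns, c(a = 2e4)), "missing molecular weight.*b")
})

test_that("non-insulin scaling yields the 0.8/0.2 split exactly", {
  f <- c(ins1 = 0.5, g1 = 0.3, g2 = 0.2)
  out <- scale_noninsulin(f, "ins1")
  expect_equal(unname(out["ins1"]), 0.8)
  expect_equal(sum(out[c("g1", "g2")]), 0.2, tolerance = 1e-12)
  expect_equal(unname(out["g1"] / out["g2"]), 1.5)  # proportions kept
  expect_equal(sum(out), 1, tolerance = 1e-12)
  # pre-scale non-insulin total 0.5 -> each multiplied by 0.4
  expect_equal(unname(out["g1"]), 0.3 * 0.4)
  expect_error(scale_noninsulin(c(a = 1), "a"), "non-insulin")
  expect_error(scale_noninsulin(c(a = 1), "b"), "no insulin")
})

test_that("crystal occupancy follows the cell-volume formula", {
  # synthetic form built so z*mw/(N_A*rho) equals the cell volume -> 1.0
  rho <- 1.22
  vol_A3 <- 2e5
  mw <- vol_A3 * 1e-24 * 6.02214076e23 * rho / 9
  f <- crystal_form("syn", "H3", asym_mw = mw, z = 9, cell_volume = vol_A3)
  expect_equal(f$occupancy, 1, tolerance = 1e-12)
  # linear in asym_mw, inverse in cell volume
  f2 <- crystal_form("syn", "H3", asym_mw = mw / 2, z = 9, cell_volume = vol_A3)
  f3 <- crystal_form("syn", "H3", asym_mw = mw / 2, z = 9,
                     cell_volume = vol_A3 * 2)
  expect_equal(f2$occupancy, 0.5, tolerance = 1e-12)
  expect_equal(f3$occupancy, 0.25, tolerance = 1e-12)
  expect_error(crystal_form("bad", "H3", asym_mw = 2 * mw, z = 9,
                            cell_volume = vol_A3), "occupancy")
})

test_that("insulin copy number matches a dimensional-analysis oracle", {
  form <- crystal_form("syn", "H3", asym_mw = 11920, z = 9,
                       cell_volume = 213078)
  g <- vesicle_geometry(320, 200)
  n <- insulin_copies(g, form)
  # independent unit conversion: V[cm^3] * occ * rho / (mw/N_A)
  v_cm3 <- 4 / 3 * pi * (100e-7)^3
  oracle <- round(v_cm3 * form$occupancy * 1.22 / (5808 / 6.02214076e23))
  expect_equal(n, oracle)
  # literature range for a 200 nm crystal: 2e5 to 1e6 monomers
  expect_gt(n, 2e5); expect_lt(n, 1e6)
  expect_equal(insulin_copies(vesicle_geometry(320, 0), form), 0)
  n2 <- insulin_copies(vesicle_geometry(900, 400), form)
  expect_equal(n2 / insulin_copies(vesicle_geometry(900, 200), form), 8,
               tolerance = 1e-3)
})

test_that("copy numbers apply rounding and the manual exception hooks", {
  fr <- c(a = 0.5, b = 0.3, c = 0.2)
  mw <- c(a = 5e4, b = 2.5e4, c = 1e4, iapp = 3900, cplx = 9e5,
          s1 = 1e5, s2 = 5e4, s3 = 3e4)
  m <- 1e-15
  cn <- copy_numbers(fr, mw, m)
  oracle <- round(fr * m / (mw[names(fr)] / 6.02214076e23))
  expect_equal(cn, stats::setNames(as.integer(oracle), names(fr)))
  # IAPP hook: 1% of insulin count
  cn2 <- copy_numbers(c(fr, iapp = 0), mw, m,
                      iapp_hook = list(iapp_id = "iapp", insulin_count = 1e6))
  expect_equal(unname(cn2["iapp"]), 10000L)
  # complex hook: mean of stoichiometry-normalised subunit counts
  cn3 <- copy_numbers(c(s1 = 0.2, s2 = 0.3, s3 = 0.5), mw, m,
                      complex_hook = list(complex_id = "cplx",
                                          subunit_ids = c("s1", "s2", "s3"),
                                          stoichiometry = c(1, 2, 3)))
  sub <- round(c(0.2, 0.3, 0.5) * m / (mw[c("s1", "s2", "s3")] / 6.02214076e23))
  expect_equal(unname(cn3["cplx"]), as.integer(round(mean(sub / c(1, 2, 3)))))
  expect_false(any(c("s1", "s2", "s3") %in% names(cn3)))
  expect_error(copy_numbers(c(a = NA_real_), mw, m), "finite")
})

test_that("complex hook reproduces the enumerated example", {
  # subunit counts (30, 60, 90) with stoichiometry (1, 2, 3) -> 30
  mw <- c(s1 = 1, s2 = 1, s3 = 1, v = 1)
  m <- c(30, 60, 90)
  fr <- stats::setNames(m / sum(m), c("s1", "s2", "s3"))
  total <- sum(m) / 6.02214076e23
  cn <- copy_numbers(fr, mw, total,
                     complex_hook = list(complex_id = "v",
                                         subunit_ids = c("s1", "s2", "s3"),
                                         stoichiometry = c(1, 2, 3)))
  expect_equal(unname(cn["v"]), 30L)
})

test_that("per-proteome pooling averages within-study mass fractions", {
  f1 <- c(a = 0.6, b = 0.4)
  f2 <- c(a = 0.2, b = 0.5, c = 0.3)
  pooled <- pool_mass_fractions(list(f1, f2))
  raw <- c(a = mean(c(0.6, 0.2)), b = mean(c(0.4, 0.5)), c = 0.3)
  expect_equal(pooled, raw / sum(raw))
  # an excluded study value changes the mean (exclusion applied upstream)
  pooled_ex <- pool_mass_fractions(list(f1, f2[c("b", "c")]))
  expect_equal(unname(pooled_ex["a"]),
               unname(0.6 / sum(c(0.6, mean(c(0.4, 0.5)), 0.3))))
  # curated protein absent everywhere gets the floor fraction
  with_floor <- pool_mass_fractions(list(f1), curated_ids = "z",
                                    floor_fraction = 1e-4)
  expect_equal(unname(with_floor["z"]), 1e-4 / (1 + 1e-4), tolerance = 1e-12)
})

test_that("cytoplasm recipe keeps the top-n set and the target concentration", {
  set.seed(3)
  e <- data.frame(protein_id = sprintf("c%02d", 1:60),
                  raw_abundance = stats::rlnorm(60), mw = 5e4)
  out <- cytoplasm_recipe(e)
  expect_equal(nrow(out), 50)
  oracle <- e$protein_id[order(-e$raw_abundance, e$protein_id)][1:50]
  expect_setequal(out$protein_id, oracle)
  expect_equal(sum(out$concentration), 0.2, tolerance = 1e-9)
  one <- cytoplasm_recipe(e, top_n = 1)
  expect_equal(one$concentration, 0.2)
  expect_warning(cytoplasm_recipe(e[1:10, ]), "fewer than")
})

test_that("recipes survive a JSON round-trip", {
  form <- bundled_crystal_forms()[["1trz"]]
  fr <- c(ins = 0.7, ChgA = 0.2, Cpe = 0.1)
  rec <- build_recipe(fr, c(ChgA = 48000, Cpe = 53000),
                      c(ChgA = "lumen", Cpe = "lumen"),
                      insulin_ids = "ins", form = form)
  expect_true(all(rec$copy_number >= 0))
  path <- withr::local_tempfile(fileext = ".json")
  write_recipe_json(rec, path)
  back <- read_recipe_json(path)
  expect_equal(back$protein_id, rec$protein_id)
  expect_equal(back$copy_number, rec$copy_number)
  expect_equal(back$mass_fraction, rec$mass_fraction, tolerance = 1e-12)
  expect_equal(attr(back, "geometry")$vesicle_diameter, 320)
})
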