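# LoG blob detection, threshold tuning, R^2 profile fitting and map
# classification.

make_gauss_volume <- function(n = 41, centers, sigmas_vox, amps, voxel = 37.42,
                              bg = 0) {
  arr <- array(bg, c(n, n, n))
  g <- seq_len(n)
  for (b in seq_along(amps)) {
    dx2 <- outer(outer((g - centers[[b]][1])^2, (g - centers[[b]][2])^2, "+"),
                 (g - centers[[b]][3])^2, "+")
    arr <- arr + amps[b] * exp(-dx2 / (2 * sigmas_vox[b]^2))
  }
  lac_volume(arr, voxel)
}

test_that("uniform volumes produce no blobs and empty masks error", {
  u <- lac_volume(array(0.3, c(15, 15, 15)), 37.42)
  out <- detect_blobs(u, scales_nm = c(50, 75, 112))
  expect_equal(nrow(out), 0)
  expect_error(detect_blobs(u, 50, mask = array(FALSE, c(15, 15, 15))),
               "empty mask")
  expect_error(detect_blobs(u, 50, mask = array(TRUE, c(3, 3, 3))), "shape")
})

test_that("a synthetic Gaussian blob is located and sized by scale selection", {
  sb <- 3                        # blob sigma in voxels
  v <- make_gauss_volume(centers = list(c(21, 21, 21)), sigmas_vox = sb,
                         amps = 1)
  scales <- exp(seq(log(40), log(250), length.out = 12))
  out <- detect_blobs(v, scales, threshold = 1e-4)
  expect_gte(nrow(out), 1)
  top <- out[which.max(out$response), ]
  expect_true(all(abs(c(top$x, top$y, top$z) - 21) <= 1))
  expect_equal(top$radius_nm, sqrt(3) * sb * 37.42, tolerance = 0.2)
})

test_that("separated blobs give two detections, coincident blobs one", {
  v2 <- make_gauss_volume(centers = list(c(13, 21, 13), c(31, 21, 31)),
                          sigmas_vox = c(3, 3), amps = c(1, 0.8))
  scales <- exp(seq(log(60), log(250), length.out = 8))
  out2 <- detect_blobs(v2, scales, threshold = 0.05)
  expect_equal(nrow(out2), 2)
  v1 <- make_gauss_volume(centers = list(c(21, 21, 21), c(21, 21, 21)),
                          sigmas_vox = c(3, 3), amps = c(1, 0.8))
  out1 <- detect_blobs(v1, scales, threshold = 0.05)
  expect_equal(nrow(out1), 1)
})

test_that("detection is deterministic given identical inputs", {
  v <- make_gauss_volume(centers = list(c(15, 21, 25)), sigmas_vox = 2.5,
                         amps = 0.7)
  scales <- c(60, 90, 135)
  expect_identical(detect_blobs(v, scales, threshold = 0.01),
                   detect_blobs(v, scales, threshold = 0.01))
})

test_that("threshold tuning maximises accuracy with the high tie-break", {
  # separable: returns the upper edge of the optimal interval
  r <- c(0.1, 0.2, 0.3, 0.8, 0.9, 1.0)
  l <- c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE)
  thr <- tune_threshold(r, l)
  expect_equal(as.numeric(thr), 0.8)
  expect_equal(attr(thr, "accuracy"), 1)
  # all-equal responses: accuracy 0.5, threshold is that value
  thr2 <- tune_threshold(rep(0.4, 10), rep(c(TRUE, FALSE), 5))
  expect_equal(as.numeric(thr2), 0.4)
  expect_equal(attr(thr2, "accuracy"), 0.5)
  expect_error(tune_threshold(1:3, c(TRUE, TRUE, TRUE)), "both classes")
})

test_that("tuned threshold agrees with an exhaustive scan on a 60-item set", {
  set.seed(12)
  r <- c(stats::rnorm(30, 1, 0.4), stats::rnorm(30, 0, 0.4))
  l <- rep(c(TRUE, FALSE), each = 30)
  thr <- tune_threshold(r, l)
  accs <- vapply(sort(unique(r)), function(t) mean((r >= t) == l), numeric(1))
  expect_equal(attr(thr, "accuracy"), max(accs))
  best <- sort(unique(r))[accs == max(accs)]
  expect_equal(as.numeric(thr), max(best))
})

test_that("R^2 fitting selects the generating entry and handles degeneracy", {
  radii <- (seq_len(15) - 0.5) * 37.42
  base <- 0.3 + 0.25 * exp(-(radii / 150)^2)
  prof <- structure(data.frame(radius_nm = radii, value = base),
                    class = c("radial_profile", "data.frame"))
  lib <- list(
    list(id = "self", step = 6, profile = data.frame(radius_nm = radii,
                                                     value = base)),
    list(id = "off", step = 1, profile = data.frame(radius_nm = radii,
                                                    value = base * 0.8)))
  fit <- fit_blob(prof, lib)
  expect_equal(fit$entry_id, "self")
  expect_equal(fit$r2_short, 1)
  expect_equal(fit$r2_long, 1)
  expect_equal(fit$maturity, "mature")
  # hand-computed R^2 on a 5-entry fixture
  sim <- base + c(0.01, -0.02, 0.015, 0, 0.005, rep(0, 10))
  lib5 <- list(list(id = "e1", step = 3,
                    profile = data.frame(radius_nm = radii, value = sim)))
  f5 <- fit_blob(prof, lib5)
  y <- base[1:6]; yh <- sim[1:6]
  expect_equal(f5$r2_short, 1 - sum((y - yh)^2) / sum((y - mean(y))^2),
               tolerance = 1e-12)
  expect_equal(f5$maturity, "transitional")
  # constant experimental profile is a reported error
  flat <- structure(data.frame(radius_nm = radii, value = rep(0.3, 15)),
                    class = c("radial_profile", "data.frame"))
  expect_error(fit_blob(flat, lib), "degenerate")
  expect_error(fit_blob(prof, list()), "empty library")
})

test_that("classify_map recovers planted maturation classes", {
  # three planted analytic phantoms (steps 1, 3, 6) classified against a
  # library of their own embedded radial profiles
  steps <- c(1, 3, 6)
  phs <- lapply(steps, function(s)
    generate_phantom(phantom_spec(step = s), seed = 40 + s))
  vols <- lapply(phs, function(p) p$analytic)
  scene <- compose_volumes(vols, rbind(c(13, 13, 13), c(13, 13, 38),
                                       c(38, 13, 25)),
                           dims = c(50, 25, 50))
  lib <- lapply(seq_along(steps), function(i) {
    emb <- embed_volume(vols[[i]], c(33, 25, 33), 0.2)
    ctr <- (dim(emb$data) + 1) %/% 2
    list(id = sprintf("step%d", steps[i]), step = steps[i],
         profile = radial_profile(emb, center = ctr))
  })
  res <- classify_map(scene, lib, scales_nm = c(70, 90, 120),
                      threshold = 0.02)
  expect_gte(nrow(res$fits), 3)
  top3 <- res$fits[order(-res$fits$response), ][1:3, ]
  got <- top3$maturity[order(top3$z + 100 * (top3$x > 25))]
  expect_setequal(top3$maturity, c("immature", "transitional", "mature"))
  expect_equal(sum(res$counts), nrow(res$fits))
  # empty detection is an empty result, not a crash
  u <- lac_volume(array(0.2, c(15, 15, 15)), 37.42)
  res0 <- classify_map(u, lib, scales_nm = c(70, 90), threshold = 0.05)
  expect_equal(nrow(res0$fits), 0)
  expect_equal(unname(res0$counts), c(0L, 0L, 0L))
})

test_that("cylinder masks exclude the capillary margin", {
  m <- cylinder_mask(c(21, 9, 21), axis_point = c(1, 5, 11),
                     axis_dir = c(1, 0, 0), radius_voxels = 2,
                     margin_voxels = 5)
  expect_false(m[11, 5, 11])    # on the axis
  expect_true(m[11, 5, 21])     # 10 voxels off-axis: beyond radius + margin
  expect_false(m[11, 5, 17])    # 6 voxels off-axis: inside the margin
})
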