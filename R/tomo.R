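# Soft X-ray tomogram simulation: parallel-beam projection of a LAC
# volume around the vertical (y) tilt axis, Gaussian optical PSF, Poisson
# shot noise at a finite photon budget, sub-pixel alignment jitter, and
# filtered back-projection reconstruction, replicated and averaged.

#' Projection and reconstruction operator
#'
#' @param psf_fwhm_nm Gaussian PSF full width at half maximum, nm (default
#'   60, matching the 50-60 nm resolution of water-window microscopes).
#' @param n_angles Number of tilt angles over 180 degrees (default 120).
#' @param photons Photon budget per detector pixel (default 5000);
#'   `Inf` disables shot noise.
#' @param jitter_voxels Uniform sub-pixel translation amplitude applied to
#'   each projection, voxels (default 0.5; 0 disables).
#' @param replicates Number of simulated reconstructions averaged
#'   (default 10).
#' @return Object of class `projection_operator`.
#' @export
projection_operator <- function(psf_fwhm_nm = 60, n_angles = 120,
                                photons = 5000, jitter_voxels = 0.5,
                                replicates = 10) {
  stopifnot(psf_fwhm_nm >= 0, n_angles >= 1, jitter_voxels >= 0, replicates >= 1)
  if (photons <= 0) stop("photon budget must be positive")
  structure(list(psf_fwhm_nm = psf_fwhm_nm, n_angles = n_angles,
                 photons = photons, jitter_voxels = jitter_voxels,
                 replicates = replicates),
            class = "projection_operator")
}

# parallel-beam projection of a square slice onto a detector of width
# n_det >= the slice diagonal, so no mass is lost at any tilt angle.
# Detector coordinate t = -x sin(theta) + z cos(theta) (centered).
.project_slice <- function(img, theta, n_det) {
  n <- nrow(img)
  c_img <- (n + 1) / 2
  c_det <- (n_det + 1) / 2
  g1 <- matrix(rep(seq_len(n_det) - c_det, n_det), n_det, n_det)  # along-ray
  g2 <- t(g1)                                                     # detector
  ct <- cos(theta); st <- sin(theta)
  xs <- ct * g1 - st * g2 + c_img
  zs <- st * g1 + ct * g2 + c_img
  x0 <- floor(xs); z0 <- floor(zs); fx <- xs - x0; fz <- zs - z0
  ok <- x0 >= 1 & x0 < n & z0 >= 1 & z0 < n
  v <- numeric(n_det * n_det)
  i00 <- (z0 - 1) * n + x0
  idx <- which(ok)
  v[idx] <- img[i00[idx]] * ((1 - fx) * (1 - fz))[idx] +
    img[i00[idx] + 1] * (fx * (1 - fz))[idx] +
    img[i00[idx] + n] * ((1 - fx) * fz)[idx] +
    img[i00[idx] + n + 1] * (fx * fz)[idx]
  colSums(matrix(v, n_det, n_det))
}

# 1D Gaussian kernel, sigma in pixels
.gauss_kernel <- function(sigma) {
  if (sigma <= 0) return(1)
  hw <- max(1L, ceiling(3 * sigma))
  k <- exp(-(-hw:hw)^2 / (2 * sigma^2))
  k / sum(k)
}

# separable 2D Gaussian blur with replicate-edge padding
.blur2d <- function(img, sigma1, sigma2 = sigma1) {
  k1 <- .gauss_kernel(sigma1); k2 <- .gauss_kernel(sigma2)
  conv1 <- function(m, k) {
    if (length(k) == 1) return(m)
    hw <- (length(k) - 1) / 2
    n <- nrow(m)
    pad <- rbind(m[rep(1, hw), , drop = FALSE], m, m[rep(n, hw), , drop = FALSE])
    out <- matrix(0, n, ncol(m))
    for (i in seq_along(k)) out <- out + k[i] * pad[i:(i + n - 1), , drop = FALSE]
    out
  }
  t(conv1(t(conv1(img, k1)), k2))
}

# shift a matrix by (d1, d2) pixels with bilinear interpolation
.shift_bilinear <- function(img, d1, d2) {
  n1 <- nrow(img); n2 <- ncol(img)
  i1 <- seq_len(n1) - d1; i2 <- seq_len(n2) - d2
  f1 <- pmin(pmax(floor(i1), 1), n1 - 1); f2 <- pmin(pmax(floor(i2), 1), n2 - 1)
  a1 <- pmin(pmax(i1 - f1, 0), 1); a2 <- pmin(pmax(i2 - f2, 0), 1)
  m00 <- img[f1, f2, drop = FALSE]; m10 <- img[f1 + 1, f2, drop = FALSE]
  m01 <- img[f1, f2 + 1, drop = FALSE]; m11 <- img[f1 + 1, f2 + 1, drop = FALSE]
  outer(1 - a1, 1 - a2) * m00 + outer(a1, 1 - a2) * m10 +
    outer(1 - a1, a2) * m01 + outer(a1, a2) * m11
}

# filtered back-projection of one sinogram (n_det x n_angles) onto an
# n_out x n_out slice; detector coordinate t = -x sin + z cos (centered)
.fbp_slice <- function(sino, angles, n_out) {
  n_det <- nrow(sino)
  np <- 2^ceiling(log2(2 * n_det))
  fr <- c(seq(0, np / 2), seq(np / 2 - 1, 1)) / np    # Ram-Lak |f|
  c_out <- (n_out + 1) / 2
  c_det <- (n_det + 1) / 2
  gx <- matrix(rep(seq_len(n_out) - c_out, n_out), n_out, n_out)
  gz <- t(gx)
  recon <- matrix(0, n_out, n_out)
  for (k in seq_along(angles)) {
    p <- c(sino[, k], rep(0, np - n_det))
    pf <- Re(stats::fft(stats::fft(p) * fr, inverse = TRUE)) / np
    pf <- pf[seq_len(n_det)]
    tt <- -gx * sin(angles[k]) + gz * cos(angles[k]) + c_det
    t0 <- pmin(pmax(floor(tt), 1), n_det - 1)
    ft <- pmin(pmax(tt - t0, 0), 1)
    recon <- recon + pf[t0] * (1 - ft) + pf[t0 + 1] * ft
  }
  recon * pi / length(angles)
}

#' Simulate a tomographic reconstruction of a LAC volume
#'
#' Projects the volume around the y (tilt) axis at `n_angles` angles over
#' 180 degrees, blurs each projection with the optical PSF, applies random
#' sub-pixel translations (alignment error), draws Poisson photon counts
#' from the attenuated beam, reconstructs each x-z slice by filtered
#' back-projection (Ram-Lak), and averages over `replicates` independent
#' noise realisations.  The reconstruction preserves the LAC scale
#' (micrometre^-1).
#'
#' @param volume A [lac_volume()].
#' @param op A [projection_operator()].
#' @param seed RNG seed.
#' @return A [lac_volume()] of the same dimensions (negative reconstruction
#'   values are clipped to zero).
#' @export
simulate_tomogram <- function(volume, op = projection_operator(), seed = 1) {
  stopifnot(inherits(volume, "lac_volume"), inherits(op, "projection_operator"))
  vol <- volume$data
  if (!all(is.finite(vol))) stop("volume contains non-finite values")
  d <- dim(vol)
  if (d[1] != d[3]) stop("x and z extents must match (square tilt slices)")
  n <- d[1]; ny <- d[2]
  ds_um <- volume$voxel_nm * 1e-3
  angles <- seq(0, pi, length.out = op$n_angles + 1)[seq_len(op$n_angles)]
  sigma_vox <- op$psf_fwhm_nm / 2.354820 / volume$voxel_nm
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  n_det <- ceiling(n * sqrt(2)) + 4L   # detector spans the slice diagonal
  acc <- array(0, dim = d)
  for (rep_i in seq_len(op$replicates)) {
    sinos <- array(0, dim = c(n_det, ny, op$n_angles))
    for (k in seq_along(angles)) {
      # projection image: line integrals for every slice y at this angle
      proj <- vapply(seq_len(ny), function(iy) {
        .project_slice(vol[, iy, ], angles[k], n_det) * ds_um
      }, numeric(n_det))                 # n_det x ny
      proj <- .blur2d(proj, sigma_vox, sigma_vox)
      if (op$jitter_voxels > 0) {
        dj <- stats::runif(2, -op$jitter_voxels, op$jitter_voxels)
        proj <- .shift_bilinear(proj, dj[1], dj[2])
      }
      if (is.finite(op$photons)) {
        counts <- stats::rpois(length(proj), op$photons * exp(-proj))
        proj <- -log(pmax(counts, 0.5) / op$photons)
        dim(proj) <- c(n_det, ny)
      }
      sinos[, , k] <- proj
    }
    for (iy in seq_len(ny)) {
      acc[, iy, ] <- acc[, iy, ] + .fbp_slice(sinos[, iy, ], angles, n) / ds_um
    }
  }
  out <- pmax(acc / op$replicates, 0)
  lac_volume(out, volume$voxel_nm, volume$origin_nm)
}

#' Radial profile of a reconstructed volume or slice
#'
#' Mean value per concentric annulus in the x-z plane.  For a 3D volume
#' the x-z slice through the center is used (the slice through the
#' brightest voxel when no center is given); this mirrors how features are
#' profiled in experimental tomograms.
#'
#' @param volume A [lac_volume()] or a 2D matrix.
#' @param center Voxel index (length 3 for a volume, 2 for a matrix) of the
#'   profile center; default the brightest voxel (ties: first index).
#' @param n_bins Number of radial bins (default 15); bin width is one
#'   voxel.
#' @param voxel_nm Voxel width for matrices (default 37.42; taken from the
#'   volume otherwise).
#' @return Object of class `radial_profile`: data frame `radius_nm`,
#'   `value` plus attributes `center` and `voxel_nm`.
#' @export
radial_profile <- function(volume, center = NULL, n_bins = 15, voxel_nm = 37.42) {
  if (inherits(volume, "lac_volume")) {
    voxel_nm <- volume$voxel_nm
    arr <- volume$data
    if (is.null(center)) {
      center <- which(arr == max(arr), arr.ind = TRUE)[1, ]
    }
    stopifnot(length(center) == 3)
    if (any(center < 1 | center > dim(arr))) stop("center outside the grid")
    slice <- arr[, center[2], ]
    c2 <- center[c(1, 3)]
  } else {
    slice <- volume
    if (is.null(center)) {
      center <- which(slice == max(slice), arr.ind = TRUE)[1, ]
    }
    c2 <- center[seq_len(2)]
    if (any(c2 < 1 | c2 > dim(slice))) stop("center outside the grid")
  }
  n1 <- nrow(slice); n2 <- ncol(slice)
  r <- sqrt(outer((seq_len(n1) - c2[1])^2, (seq_len(n2) - c2[2])^2, "+"))
  bin <- floor(r) + 1
  keep <- bin <= n_bins
  means <- tapply(slice[keep], bin[keep], mean)
  radii <- (as.integer(names(means)) - 0.5) * voxel_nm
  out <- data.frame(radius_nm = radii, value = as.numeric(means))
  out <- out[order(out$radius_nm), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "center") <- center
  attr(out, "voxel_nm") <- voxel_nm
  class(out) <- c("radial_profile", class(out))
  out
}

#' Peak value of a radial profile
#'
#' @param profile A [radial_profile()].
#' @param within_nm Restrict to radii below this value (optional).
#' @return Maximum profile value, micrometre^-1.
#' @export
profile_peak <- function(profile, within_nm = NULL) {
  v <- profile$value
  if (!is.null(within_nm)) v <- v[profile$radius_nm <= within_nm]
  max(v)
}

#' Membrane contribution to a vesicle's observed absorbance
#'
#' Builds the paired model without lipids, simulates both tomograms under
#' a shared seed, and returns `1 - without / with` for the chosen profile
#' statistic.  The default statistic is the mean profile value over the
#' vesicle footprint (the membrane is a thin shell: it contributes to the
#' feature's absorbance as a whole far more than to the single central
#' voxel).
#'
#' @param model A `model_instance_set` built with lipids.
#' @param op A [projection_operator()].
#' @param seed Shared RNG seed for the paired simulations.
#' @param embed_dims Embedding grid (default 65 x ny x 65).
#' @param statistic `"contrast"` (default): share of the feature's signal
#'   above the cytoplasm background, `(with - without) / (with - bg)`,
#'   with the background measured from the same reconstruction -- features
#'   in a tomogram are observed as excess absorbance over their
#'   surroundings.  `"mean"`: share of the absolute footprint mean.
#'   `"peak"`: share of the radial-profile peak.
#' @return Fraction; attributes `with`, `without` and `background` carry
#'   the underlying statistics.
#' @export
membrane_contribution <- function(model, op = projection_operator(), seed = 1,
                                  embed_dims = NULL,
                                  statistic = c("contrast", "mean", "peak")) {
  statistic <- match.arg(statistic)
  model_nolip <- model
  model_nolip$placements <-
    model$placements[model$placements$ingredient != "DOPC", , drop = FALSE]
  vw <- voxelize(model)
  vn <- voxelize(model_nolip)
  if (is.null(embed_dims)) {
    d <- dim(vw$data); embed_dims <- c(65, d[2], 65)
  }
  conc <- model$cyto_concentration
  tw <- simulate_tomogram(embed_volume(vw, embed_dims, conc), op, seed)
  tn <- simulate_tomogram(embed_volume(vn, embed_dims, conc), op, seed)
  ctr <- (dim(tw$data) + 1) %/% 2
  R <- model$geometry$vesicle_diameter / 2
  footprint <- function(t) {
    # area-weighted mean over the blob footprint in the central slice,
    # padded by two voxels so the optically blurred rim is included
    sl <- t$data[, ctr[2], ]
    n1 <- nrow(sl); n2 <- ncol(sl)
    r <- sqrt(outer((seq_len(n1) - ctr[1])^2, (seq_len(n2) - ctr[3])^2, "+")) *
      t$voxel_nm
    c(mean(sl[r <= R + 2 * t$voxel_nm]),
      mean(sl[r >= R + 6 * t$voxel_nm]))
  }
  if (statistic == "peak") {
    sw <- profile_peak(radial_profile(tw, center = ctr))
    sn <- profile_peak(radial_profile(tn, center = ctr))
    bg <- NA_real_
    out <- 1 - sn / sw
  } else {
    fw <- footprint(tw); fn <- footprint(tn)
    sw <- fw[1]; sn <- fn[1]; bg <- fw[2]
    out <- if (statistic == "mean") 1 - sn / sw else (sw - sn) / (sw - bg)
  }
  attr(out, "with") <- sw
  attr(out, "without") <- sn
  attr(out, "background") <- bg
  out
}

#' Write a radial profile as two-column TSV
#'
#' @param profile A [radial_profile()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(profile, path) {
  utils::write.table(profile[, c("radius_nm", "value")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a radial profile from TSV
#'
#' @param path Path written by [write_profile_tsv()].
#' @return A [radial_profile()] data frame.
#' @export
read_profile_tsv <- function(path) {
  df <- utils::read.delim(path)
  stopifnot(all(c("radius_nm", "value") %in% names(df)))
  class(df) <- c("radial_profile", class(df))
  df
}
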