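# Detection of vesicle-like blobs in tomographic volumes and maturity
# classification by matching radial profiles against a simulated model
# library.

# separable 3D Gaussian blur (replicate padding), sigma in voxels
.blur3d <- function(arr, sigma) {
  k <- .gauss_kernel(sigma)
  if (length(k) == 1) return(arr)
  d <- dim(arr)
  conv_axis <- function(a, axis) {
    perm <- switch(axis, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
    ap <- aperm(a, perm)
    dp <- dim(ap)
    m <- matrix(ap, nrow = dp[1])
    hw <- (length(k) - 1) / 2
    n <- nrow(m)
    pad <- rbind(m[rep(1, hw), , drop = FALSE], m, m[rep(n, hw), , drop = FALSE])
    out <- matrix(0, n, ncol(m))
    for (i in seq_along(k)) out <- out + k[i] * pad[i:(i + n - 1), , drop = FALSE]
    aperm(array(out, dp), order(perm))
  }
  for (ax in 1:3) arr <- conv_axis(arr, ax)
  arr
}

# discrete 6-neighbour Laplacian with replicate edges
.laplacian3d <- function(arr) {
  d <- dim(arr)
  shift <- function(a, axis, by) {
    idx <- lapply(d, seq_len)
    i <- pmin(pmax(seq_len(d[axis]) + by, 1), d[axis])
    idx[[axis]] <- i
    do.call(`[`, c(list(a), idx))
  }
  (shift(arr, 1, 1) + shift(arr, 1, -1) + shift(arr, 2, 1) + shift(arr, 2, -1) +
     shift(arr, 3, 1) + shift(arr, 3, -1) - 6 * arr)
}

#' Multi-scale Laplacian-of-Gaussian blob detection
#'
#' Computes the scale-normalised negative LoG response at each scale,
#' locates local maxima over space and scale within the mask, discards
#' responses below `threshold`, and suppresses overlapping detections
#' (sphere IoU > `overlap`; the stronger response wins).  Detected radius
#' is `sigma * sqrt(3)` (the 3D LoG scale-selection identity).
#'
#' @param volume A [lac_volume()].
#' @param scales_nm Blob scales (Gaussian sigma) in nm.
#' @param threshold Minimum response (same units as the volume values).
#' @param mask Logical array of the volume's shape (`TRUE` = search here),
#'   or `NULL` for everywhere.
#' @param overlap Sphere intersection-over-union above which the weaker of
#'   two detections is discarded (default 0.3).
#' @param psf_fwhm_nm Known optical PSF width; when positive, the detected
#'   scale is deconvolved (`sigma_obj^2 = sigma^2 - sigma_psf^2`) before
#'   the radius is reported, so blob sizes refer to the underlying object
#'   rather than its blurred image (default 0: no correction).
#' @return Data frame of class `blob_set`: `x`, `y`, `z` (voxel indices),
#'   `sigma_nm`, `radius_nm`, `response`.
#' @export
detect_blobs <- function(volume, scales_nm, threshold = 0, mask = NULL,
                         overlap = 0.3, psf_fwhm_nm = 0) {
  stopifnot(inherits(volume, "lac_volume"), length(scales_nm) >= 1)
  arr <- volume$data
  d <- dim(arr)
  if (!is.null(mask)) {
    if (!identical(dim(mask), d)) stop("mask shape must match the volume")
    if (!any(mask)) stop("empty mask")
  }
  scales_nm <- sort(scales_nm)
  resp <- lapply(scales_nm, function(s_nm) {
    s <- s_nm / volume$voxel_nm
    -s^2 * .laplacian3d(.blur3d(arr, s))
  })
  cand <- list()
  for (si in seq_along(resp)) {
    r <- resp[[si]]
    lo <- if (si > 1) resp[[si - 1]] else NULL
    hi <- if (si < length(resp)) resp[[si + 1]] else NULL
    ismax <- array(TRUE, d)
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      sh <- .shift3(r, dx, dy, dz)
      ismax <- ismax & (r >= sh)
    }
    if (!is.null(lo)) ismax <- ismax & (r >= lo)
    if (!is.null(hi)) ismax <- ismax & (r >= hi)
    # strict positivity with a floor at numerical noise level: a uniform
    # volume has zero response everywhere and must yield no blobs
    ismax <- ismax & (r >= threshold) & (r > 1e-9 * max(abs(arr)))
    if (!is.null(mask)) ismax <- ismax & mask
    idx <- which(ismax, arr.ind = TRUE)
    if (nrow(idx)) {
      # parabolic refinement of the scale in log-sigma (standard
      # scale-space sub-grid localisation); skipped at ladder edges
      sig <- rep(scales_nm[si], nrow(idx))
      if (!is.null(lo) && !is.null(hi) && length(scales_nm) >= 3) {
        flat <- which(ismax)
        rl <- lo[flat]; rc <- r[flat]; rh <- hi[flat]
        denom <- rl - 2 * rc + rh
        delta <- ifelse(abs(denom) > 1e-12, 0.5 * (rl - rh) / denom, 0)
        delta <- pmin(pmax(delta, -1), 1)
        dlog <- log(scales_nm[si] / scales_nm[si - 1])
        sig <- scales_nm[si] * exp(delta * dlog)
      }
      sig_obj <- if (psf_fwhm_nm > 0) {
        s_psf <- psf_fwhm_nm / 2.354820
        sqrt(pmax(sig^2 - s_psf^2, (0.3 * sig)^2))
      } else sig
      cand[[length(cand) + 1]] <- data.frame(
        x = idx[, 1], y = idx[, 2], z = idx[, 3],
        sigma_nm = sig, radius_nm = sig_obj * sqrt(3),
        response = r[ismax])
    }
  }
  if (!length(cand)) {
    out <- data.frame(x = integer(0), y = integer(0), z = integer(0),
                      sigma_nm = numeric(0), radius_nm = numeric(0),
                      response = numeric(0))
    class(out) <- c("blob_set", class(out))
    return(out)
  }
  blobs <- do.call(rbind, cand)
  blobs <- blobs[order(-blobs$response), , drop = FALSE]
  # greedy overlap suppression on sphere IoU
  keep <- logical(nrow(blobs))
  vw <- volume$voxel_nm
  for (i in seq_len(nrow(blobs))) {
    ok <- TRUE
    if (any(keep)) {
      prev <- blobs[keep, , drop = FALSE]
      dist <- sqrt((prev$x - blobs$x[i])^2 + (prev$y - blobs$y[i])^2 +
                     (prev$z - blobs$z[i])^2) * vw
      iou <- mapply(.sphere_iou, dist, prev$radius_nm,
                    MoreArgs = list(r2 = blobs$radius_nm[i]))
      if (any(iou > overlap)) ok <- FALSE
    }
    keep[i] <- ok
  }
  out <- blobs[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("blob_set", class(out))
  out
}

.shift3 <- function(a, dx, dy, dz) {
  d <- dim(a)
  ix <- pmin(pmax(seq_len(d[1]) + dx, 1), d[1])
  iy <- pmin(pmax(seq_len(d[2]) + dy, 1), d[2])
  iz <- pmin(pmax(seq_len(d[3]) + dz, 1), d[3])
  a[ix, iy, iz]
}

# intersection-over-union of two spheres with center distance d
.sphere_iou <- function(d, r1, r2 = r1) {
  if (d >= r1 + r2) return(0)
  if (d <= abs(r1 - r2)) {
    vi <- 4 / 3 * pi * min(r1, r2)^3
  } else {
    vi <- pi * (r1 + r2 - d)^2 *
      (d^2 + 2 * d * (r1 + r2) - 3 * (r1 - r2)^2) / (12 * d)
  }
  vu <- 4 / 3 * pi * (r1^3 + r2^3) - vi
  vi / vu
}

#' Cylindrical exclusion mask
#'
#' Parametric mask for excluding voxels near the sample capillary: voxels
#' within `radius_voxels + margin_voxels` of a cylinder axis are masked
#' out (`FALSE`).
#'
#' @param dims Volume dimensions (length 3).
#' @param axis_point Point on the cylinder axis (voxel coordinates).
#' @param axis_dir Axis direction (length 3).
#' @param radius_voxels Cylinder radius in voxels.
#' @param margin_voxels Additional margin (default 8, middle of the 7-10
#'   range used for capillary exclusion).
#' @return Logical array: `TRUE` where detection is allowed.
#' @export
cylinder_mask <- function(dims, axis_point, axis_dir, radius_voxels,
                          margin_voxels = 8) {
  dims <- as.integer(dims)
  u <- axis_dir / sqrt(sum(axis_dir^2))
  g <- as.matrix(expand.grid(x = seq_len(dims[1]), y = seq_len(dims[2]),
                             z = seq_len(dims[3])))
  rel <- sweep(g, 2, axis_point)
  along <- rel %*% u
  perp2 <- rowSums(rel^2) - along^2
  keep <- perp2 > (radius_voxels + margin_voxels)^2
  array(keep, dim = dims)
}

#' Tune the blob-score threshold on a labelled set
#'
#' Scans all observed response values and returns the threshold (detection
#' rule `response >= threshold`) that maximises classification accuracy on
#' the labelled positives and negatives; ties are broken towards the
#' higher threshold.
#'
#' @param responses Numeric detector responses.
#' @param labels Logical: `TRUE` for positives.
#' @return Threshold value; attribute `accuracy` gives the achieved
#'   accuracy.
#' @export
tune_threshold <- function(responses, labels) {
  labels <- as.logical(labels)
  stopifnot(length(responses) == length(labels))
  if (!any(labels) || all(labels)) stop("both classes must be present")
  cand <- sort(unique(responses))
  acc <- vapply(cand, function(t) mean((responses >= t) == labels), numeric(1))
  best <- max(acc)
  thr <- max(cand[acc == best])
  attr(thr, "accuracy") <- best
  thr
}

#' Fit a blob's radial profile against a model library
#'
#' Computes the coefficient of determination between the experimental and
#' each simulated profile over the first `n_short` radial bins (the
#' vesicle itself) and the first `n_long` bins (vesicle plus surrounding
#' cytoplasm).  The best entry maximises the short-range R^2 (ties: long
#' R^2, then entry id); maturity follows the entry's maturation step
#' (1 = immature, 6 = mature, otherwise transitional).
#'
#' @param profile A [radial_profile()] of the detected blob.
#' @param library List of entries, each a list with `id`, `step` and
#'   `profile` (a [radial_profile()] or data frame on the same bins).
#' @param n_short,n_long Numbers of bins for the two scores (defaults 6
#'   and 15).
#' @return Object of class `fit_result`: `entry_id`, `step`, `r2_short`,
#'   `r2_long`, `maturity`.
#' @export
fit_blob <- function(profile, library, n_short = 6, n_long = 15) {
  if (!length(library)) stop("empty library")
  r2_at <- function(sim, k) {
    k <- min(k, nrow(profile), nrow(sim))
    y <- profile$value[seq_len(k)]
    yhat <- sim$value[seq_len(k)]
    if (length(y) != length(yhat)) stop("profile length mismatch after resampling")
    ss_tot <- sum((y - mean(y))^2)
    if (ss_tot == 0) stop("degenerate (constant) experimental profile")
    1 - sum((y - yhat)^2) / ss_tot
  }
  r2s <- vapply(library, function(e) r2_at(e$profile, n_short), numeric(1))
  r2l <- vapply(library, function(e) r2_at(e$profile, n_long), numeric(1))
  ids <- vapply(library, function(e) as.character(e$id), character(1))
  ord <- order(-r2s, -r2l, ids)
  best <- ord[1]
  step <- library[[best]]$step
  structure(list(entry_id = ids[best], step = step,
                 r2_short = r2s[best], r2_long = r2l[best],
                 maturity = .maturity_class(step)),
            class = "fit_result")
}

.maturity_class <- function(step) {
  if (step <= 1) "immature" else if (step >= 6) "mature" else "transitional"
}

#' Detect, profile and classify all blobs in a volume
#'
#' Runs [detect_blobs()], extracts a radial profile for every blob
#' (centred on the brightest voxel within the blob radius), fits each
#' against the library with [fit_blob()] and tabulates maturity classes.
#'
#' @param volume A [lac_volume()].
#' @param library Model library as in [fit_blob()].
#' @param scales_nm,threshold,mask,overlap Passed to [detect_blobs()].
#' @param n_bins Profile length in bins (default 15).
#' @return List with `fits` (data frame: blob position, radius, entry,
#'   R^2 scores, maturity), `counts` (immature/transitional/mature) and
#'   `r2_summary` (mean and sd of the short-range R^2).
#' @export
classify_map <- function(volume, library, scales_nm, threshold = 0,
                         mask = NULL, overlap = 0.3, n_bins = 15) {
  blobs <- detect_blobs(volume, scales_nm, threshold, mask, overlap)
  if (nrow(blobs) == 0) {
    return(list(fits = data.frame(), counts = c(immature = 0L,
                                                transitional = 0L, mature = 0L),
                r2_summary = c(mean = NA_real_, sd = NA_real_)))
  }
  arr <- volume$data
  d <- dim(arr)
  rows <- lapply(seq_len(nrow(blobs)), function(i) {
    b <- blobs[i, ]
    rad_vox <- ceiling(b$radius_nm / volume$voxel_nm)
    lo <- pmax(c(b$x, b$y, b$z) - rad_vox, 1)
    hi <- pmin(c(b$x, b$y, b$z) + rad_vox, d)
    sub <- arr[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
    # brightest voxel in the blob; among ties, nearest the detected center
    cand <- which(sub == max(sub), arr.ind = TRUE)
    cand <- sweep(cand, 2, lo - 1L, "+")
    d2 <- (cand[, 1] - b$x)^2 + (cand[, 2] - b$y)^2 + (cand[, 3] - b$z)^2
    ctr <- cand[which.min(d2), ]
    prof <- radial_profile(volume, center = ctr, n_bins = n_bins)
    fit <- tryCatch(fit_blob(prof, library), error = function(e) NULL)
    if (is.null(fit)) return(NULL)
    data.frame(x = b$x, y = b$y, z = b$z, radius_nm = b$radius_nm,
               response = b$response, entry_id = fit$entry_id,
               step = fit$step, r2_short = fit$r2_short,
               r2_long = fit$r2_long, maturity = fit$maturity,
               stringsAsFactors = FALSE)
  })
  fits <- do.call(rbind, rows)
  counts <- c(immature = sum(fits$maturity == "immature"),
              transitional = sum(fits$maturity == "transitional"),
              mature = sum(fits$maturity == "mature"))
  list(fits = fits, counts = counts,
       r2_summary = c(mean = mean(fits$r2_short), sd = stats::sd(fits$r2_short)))
}

#' Write classification results as TSV
#'
#' @param result Output of [classify_map()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fit_tsv <- function(result, path) {
  utils::write.table(result$fits, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
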