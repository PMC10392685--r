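# End-to-end study protocols for the idealised mature/immature vesicles:
# the quantities reported when the simulator is benchmarked (radial-profile
# peaks, cytoplasm level, membrane share, detection asymmetry).  Tests and
# the reproduction script call these with different simulation budgets.

#' Simulate an idealised vesicle and profile it
#'
#' Builds the reference vesicle (320 nm diameter, 200 nm crystal capacity)
#' at the given maturation step in 0.2 g ml^-1 cytoplasm, simulates the
#' reconstructed tomogram and returns the central-slice radial profile.
#'
#' @param step Maturation step (6 = mature, 1 = immature).
#' @param op A [projection_operator()].
#' @param seed Master seed.
#' @param embed_n Lateral embedding size in voxels (default 65).
#' @return List: `peak` (profile peak, micrometre^-1), `profile`,
#'   `cytoplasm_mean` (reconstructed LAC beyond 400 nm from the vesicle),
#'   `volume` (reconstruction), `n_instances` (molecular instances in the
#'   model; the model itself is released to bound memory use).
#' @export
study_vesicle_peak <- function(step, op = projection_operator(), seed = 1,
                               embed_n = 65) {
  model <- build_vesicle_model(step = step, seed = split_seed(seed, 10 + step))
  vox <- voxelize(model)
  n_instances <- nrow(model$placements)
  cyto <- model$cyto_concentration
  rm(model); gc(FALSE)
  emb <- embed_volume(vox, c(embed_n, dim(vox$data)[2], embed_n), cyto)
  rec <- simulate_tomogram(emb, op, seed = split_seed(seed, 20 + step))
  ctr <- (dim(rec$data) + 1) %/% 2
  prof <- radial_profile(rec, center = ctr)
  sl <- rec$data[, ctr[2], ]
  n1 <- nrow(sl)
  r <- sqrt(outer((seq_len(n1) - ctr[1])^2, (seq_len(n1) - ctr[3])^2, "+")) *
    rec$voxel_nm
  half_nm <- (n1 - 1) / 2 * rec$voxel_nm
  cyto_mean <- mean(sl[r > 400 & r < half_nm - 2 * rec$voxel_nm])
  list(peak = profile_peak(prof), profile = prof, cytoplasm_mean = cyto_mean,
       volume = rec, n_instances = n_instances)
}

#' Membrane-share study on the idealised mature vesicle
#'
#' Paired with/without-lipids simulations under a shared seed
#' (see [membrane_contribution()]).
#'
#' @param op A [projection_operator()].
#' @param seed Master seed.
#' @param step Maturation step (default 6).
#' @param statistic Passed to [membrane_contribution()].
#' @return Membrane share (fraction).
#' @export
study_membrane_share <- function(op = projection_operator(), seed = 1,
                                 step = 6, statistic = "contrast") {
  model <- build_vesicle_model(step = step, seed = split_seed(seed, 30))
  membrane_contribution(model, op, seed = split_seed(seed, 31),
                        statistic = statistic)
}

#' Detection-asymmetry study on a simulated two-vesicle tomogram
#'
#' Emulates the segmentation protocol: the detector threshold is tuned on
#' labelled training responses (planted, confidently visible mature
#' vesicles as positives; random cytoplasm sites as negatives), then
#' multi-scale blob detection runs on a simulated tomogram containing the
#' idealised mature and immature vesicles side by side.
#'
#' @param op A [projection_operator()] for the test scene.
#' @param train_op Operator for the training scenes (may use fewer
#'   replicates).
#' @param seed Master seed.
#' @param train_diameters Vesicle diameters (nm) of the planted training
#'   positives; defaults to six sizes spanning the confidently visible
#'   range 250-470 nm.
#' @param scales_nm Detection scale ladder (default 10 log-spaced scales,
#'   40-140 nm).
#' @param n_negatives Number of cytoplasm training sites (default 30).
#' @return List: `threshold`, `mature_detected`, `immature_detected`,
#'   `contour_diameter_nm` (PSF-corrected diameter of the detected mature
#'   blob), `blobs`, `responses` (training table).
#' @export
study_detection_asymmetry <- function(op = projection_operator(),
                                      train_op = op, seed = 1,
                                      train_diameters = round(seq(250, 470,
                                                                  length.out = 6)),
                                      scales_nm = exp(seq(log(40), log(140),
                                                          length.out = 10)),
                                      n_negatives = 30) {
  ## training scenes: planted mature vesicles of varied size
  train_specs <- lapply(train_diameters, function(d)
    phantom_spec(vesicle_diameter = d, crystal_diameter = round(0.625 * d),
                 step = 6, box_nm = max(636, (ceiling(d / 37.42) + 4) * 37.42)))
  pos_resp <- numeric(0)
  neg_resp <- numeric(0)
  for (chunk in split(seq_along(train_specs),
                      ceiling(seq_along(train_specs) / 4))) {
    sc <- generate_scene(train_specs[chunk], seed = split_seed(seed, 40 + chunk[1]))
    rec <- simulate_tomogram(sc$volume, train_op,
                             seed = split_seed(seed, 50 + chunk[1]))
    resp <- .log_response_stack(rec, scales_nm)
    for (j in seq_len(nrow(sc$centers_vox))) {
      pos_resp <- c(pos_resp, .max_response_near(resp, sc$centers_vox[j, ], 3))
    }
    ## negatives: cytoplasm sites away from every planted vesicle
    d <- dim(rec$data)
    set.seed(split_seed(seed, 60 + chunk[1]))
    want_neg <- ceiling(n_negatives * length(chunk) / length(train_specs))
    got_neg <- 0
    tries <- 0
    while (got_neg < want_neg && tries < 500) {
      tries <- tries + 1
      p <- c(sample(5:(d[1] - 4), 1), sample(3:(d[2] - 2), 1),
             sample(5:(d[3] - 4), 1))
      dist <- sqrt(rowSums(sweep(sc$centers_vox, 2, p)^2))
      if (min(dist) > 12) {
        neg_resp <- c(neg_resp, .max_response_near(resp, p, 1))
        got_neg <- got_neg + 1
      }
    }
    rm(sc, rec, resp); gc(FALSE)
  }
  neg_resp <- neg_resp[seq_len(min(length(neg_resp), n_negatives))]
  responses <- data.frame(
    response = c(pos_resp, neg_resp),
    positive = c(rep(TRUE, length(pos_resp)), rep(FALSE, length(neg_resp))))
  threshold <- tune_threshold(responses$response, responses$positive)
  ## test scene: idealised mature + immature side by side
  sc <- generate_scene(list(phantom_spec(step = 6), phantom_spec(step = 1)),
                       seed = split_seed(seed, 70))
  rec <- simulate_tomogram(sc$volume, op, seed = split_seed(seed, 71))
  d <- dim(rec$data)
  mask <- array(TRUE, d)
  mask[c(seq_len(4), d[1] - 0:3), , ] <- FALSE
  mask[, , c(seq_len(4), d[3] - 0:3)] <- FALSE
  blobs <- detect_blobs(rec, scales_nm, threshold = as.numeric(threshold),
                        mask = mask, psf_fwhm_nm = op$psf_fwhm_nm)
  near <- function(center) {
    if (nrow(blobs) == 0) return(integer(0))
    which(sqrt((blobs$x - center[1])^2 + (blobs$y - center[2])^2 +
                 (blobs$z - center[3])^2) <= 4)
  }
  im <- near(sc$centers_vox[1, ])
  ii <- near(sc$centers_vox[2, ])
  list(threshold = threshold,
       mature_detected = length(im) > 0,
       immature_detected = length(ii) > 0,
       contour_diameter_nm = if (length(im)) 2 * blobs$radius_nm[im[1]] else NA_real_,
       blobs = blobs, responses = responses, volume = rec,
       centers_vox = sc$centers_vox)
}

# stack of scale-normalised LoG responses (list of arrays, one per scale)
.log_response_stack <- function(volume, scales_nm) {
  lapply(scales_nm, function(s_nm) {
    s <- s_nm / volume$voxel_nm
    -s^2 * .laplacian3d(.blur3d(volume$data, s))
  })
}

.max_response_near <- function(resp_stack, center, radius_vox) {
  d <- dim(resp_stack[[1]])
  lo <- pmax(center - radius_vox, 1)
  hi <- pmin(center + radius_vox, d)
  max(vapply(resp_stack, function(r)
    max(r[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]]), numeric(1)))
}
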