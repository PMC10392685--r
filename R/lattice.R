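# Procedural placement of the insulin crystal.  Hexameric insulin packs in
# a rhombohedral lattice (hexagonal setting, three hexamers per cell at the
# centering translations); the crystal is carved by a spherical boundary.

#' Rhombohedral insulin lattice specification
#'
#' Hexagonal-setting cell with `a = b`, angles (90, 90, 120), and hexamers
#' at the centering translations (0,0,0), (2/3,1/3,1/3), (1/3,2/3,2/3).
#' Defaults come from the bundled rhombohedral crystal-form metadata
#' ([bundled_crystal_forms()], entry `1trz`).
#'
#' @param a,c_axis Hexagonal cell constants in Angstrom.
#' @param space_group Space-group label.
#' @return Object of class `lattice_spec` with cell vectors in nm.
#' @export
lattice_spec <- function(a = 80.70, c_axis = 37.78, space_group = "H3") {
  stopifnot(a > 0, c_axis > 0)
  a_nm <- a / 10; c_nm <- c_axis / 10
  # hexagonal basis vectors (nm)
  v1 <- c(a_nm, 0, 0)
  v2 <- c(-a_nm / 2, a_nm * sqrt(3) / 2, 0)
  v3 <- c(0, 0, c_nm)
  frac <- rbind(c(0, 0, 0), c(2 / 3, 1 / 3, 1 / 3), c(1 / 3, 2 / 3, 2 / 3))
  structure(list(a = a, c_axis = c_axis, space_group = space_group,
                 basis = rbind(v1, v2, v3), centering = frac,
                 cell_volume_A3 = sqrt(3) / 2 * a^2 * c_axis,
                 sites_per_cell = nrow(frac)),
            class = "lattice_spec")
}

#' Place crystal hexamers inside a spherical boundary
#'
#' Enumerates lattice sites (one per hexamer) whose centers fall inside the
#' boundary (`sdf <= 0`).  All placements share the identity orientation:
#' the crystal is a single coherent lattice.  Deterministic (no RNG).
#'
#' @param lattice A [lattice_spec()].
#' @param boundary A spherical [sdf_sphere()].
#' @return Data frame of placements: `ingredient`, `x`, `y`, `z` (nm),
#'   `qw`, `qx`, `qy`, `qz`.
#' @export
place_crystal <- function(lattice, boundary) {
  if (!identical(boundary$type, "sphere")) stop("crystal boundary must be a sphere")
  B <- lattice$basis
  if (abs(det(B)) < 1e-12) stop("degenerate lattice cell")
  r <- boundary$radius
  if (r <= 0) {
    return(data.frame(ingredient = character(0), x = numeric(0), y = numeric(0),
                      z = numeric(0), qw = numeric(0), qx = numeric(0),
                      qy = numeric(0), qz = numeric(0)))
  }
  # integer cell ranges wide enough to cover the bounding sphere
  lens <- sqrt(rowSums(B^2))
  nmax <- ceiling(r / lens * 2) + 2
  idx <- as.matrix(expand.grid(i = -nmax[1]:nmax[1], j = -nmax[2]:nmax[2],
                               k = -nmax[3]:nmax[3]))
  pts <- do.call(rbind, lapply(seq_len(nrow(lattice$centering)), function(s) {
    (idx + matrix(lattice$centering[s, ], nrow(idx), 3, byrow = TRUE)) %*% B
  }))
  # anchor the lattice at the boundary center so the origin site is inside
  pts <- pts + matrix(boundary$center, nrow(pts), 3, byrow = TRUE)
  keep <- sdf_eval(boundary, pts) <= 0
  pts <- pts[keep, , drop = FALSE]
  data.frame(ingredient = rep("insulin_hexamer", nrow(pts)),
             x = pts[, 1], y = pts[, 2], z = pts[, 3],
             qw = 1, qx = 0, qy = 0, qz = 0, stringsAsFactors = FALSE)
}
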