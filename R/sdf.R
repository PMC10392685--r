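# Signed distance fields describing vesicle ultrastructure.  The zero
# level set is the surface; negative values are inside.  Compartments are
# primitive spheres combined with boolean min/max operations.

#' Spherical signed distance field
#'
#' `sdf(x) = |x - center| - radius`.
#'
#' @param center Numeric length-3, nm.
#' @param radius Radius, nm.
#' @param role Compartment role label.
#' @return Object of class `sdf`.
#' @export
sdf_sphere <- function(center = c(0, 0, 0), radius,
                       role = c("lumen", "membrane-surface", "crystal-boundary", "exterior")) {
  role <- match.arg(role)
  stopifnot(length(center) == 3, radius >= 0)
  structure(list(
    type = "sphere", center = center, radius = radius, role = role,
    fun = function(p) sqrt(rowSums(sweep(p, 2, center)^2)) - radius
  ), class = "sdf")
}

#' Boolean combinations of signed distance fields
#'
#' `sdf_union` is the pointwise minimum, `sdf_intersect` the maximum and
#' `sdf_complement` the negation; `sdf_difference(a, b)` is
#' `intersect(a, complement(b))` (a with b carved out).
#'
#' @param a,b `sdf` objects.
#' @return An `sdf`.
#' @export
sdf_union <- function(a, b) {
  structure(list(type = "union", parts = list(a, b), role = a$role,
                 fun = function(p) pmin(a$fun(p), b$fun(p))), class = "sdf")
}

#' @rdname sdf_union
#' @export
sdf_intersect <- function(a, b) {
  structure(list(type = "intersect", parts = list(a, b), role = a$role,
                 fun = function(p) pmax(a$fun(p), b$fun(p))), class = "sdf")
}

#' @rdname sdf_union
#' @export
sdf_complement <- function(a) {
  structure(list(type = "complement", parts = list(a), role = a$role,
                 fun = function(p) -a$fun(p)), class = "sdf")
}

#' @rdname sdf_union
#' @export
sdf_difference <- function(a, b) sdf_intersect(a, sdf_complement(b))

#' Evaluate a signed distance field
#'
#' @param sdf An `sdf`.
#' @param points n x 3 matrix (or length-3 vector) of positions, nm.
#' @return Numeric vector of signed distances, nm.
#' @export
sdf_eval <- function(sdf, points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  sdf$fun(points)
}
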