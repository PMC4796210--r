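# Explicit three-site waters: construction, geometry, atom expansion.

.water_cols <- c("ox", "oy", "oz", "h1x", "h1y", "h1z",
                 "h2x", "h2y", "h2z", "placement_iteration",
                 "placement_energy")

#' Empty water table
#'
#' Waters are stored one per row with oxygen and the two hydrogen positions
#' plus placement metadata (iteration index and the hotspot energy at which
#' the water was accepted).
#'
#' @return zero-row water data frame.
#' @export
new_waters <- function() {
  out <- as.data.frame(matrix(numeric(0), ncol = length(.water_cols)))
  names(out) <- .water_cols
  out
}

water_row <- function(o, h1, h2, iteration = NA_integer_,
                      energy = NA_real_) {
  out <- data.frame(ox = o[1], oy = o[2], oz = o[3],
                    h1x = h1[1], h1y = h1[2], h1z = h1[3],
                    h2x = h2[1], h2y = h2[2], h2z = h2[3],
                    placement_iteration = iteration,
                    placement_energy = energy)
  out
}

# canonical hydrogen offsets for a water at the origin (bisector along +z)
.water_h_template <- local({
  half <- .tip3p_hoh / 2
  rbind(c(sin(half), 0, cos(half)) * .tip3p_oh,
        c(-sin(half), 0, cos(half)) * .tip3p_oh)
})

#' Axis-angle rotation matrix
#'
#' @param axis 3-vector (normalised internally).
#' @param angle radians.
#' @return 3x3 rotation matrix.
#' @export
rotation_matrix <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  c_ <- cos(angle); s <- sin(angle); C <- 1 - c_
  matrix(c(
    a[1] * a[1] * C + c_,      a[1] * a[2] * C - a[3] * s, a[1] * a[3] * C + a[2] * s,
    a[2] * a[1] * C + a[3] * s, a[2] * a[2] * C + c_,      a[2] * a[3] * C - a[1] * s,
    a[3] * a[1] * C - a[2] * s, a[3] * a[2] * C + a[1] * s, a[3] * a[3] * C + c_
  ), nrow = 3, byrow = TRUE)
}

euler_matrix <- function(ang) {
  rotation_matrix(c(0, 0, 1), ang[1]) %*%
    rotation_matrix(c(0, 1, 0), ang[2]) %*%
    rotation_matrix(c(1, 0, 0), ang[3])
}

#' Construct a water at a given oxygen position
#'
#' @param o oxygen position (3-vector, A).
#' @param rotation optional 3x3 rotation applied to the canonical hydrogen
#'   template.
#' @param iteration,energy placement metadata.
#' @return one-row water data frame.
#' @export
make_water <- function(o, rotation = diag(3), iteration = NA_integer_,
                       energy = NA_real_) {
  h <- .water_h_template %*% t(rotation)
  water_row(o, o + h[1, ], o + h[2, ], iteration, energy)
}

#' Water oxygen positions
#'
#' @param waters water data frame.
#' @return numeric matrix (n x 3), A.
#' @export
water_o <- function(waters) {
  as.matrix(waters[, c("ox", "oy", "oz"), drop = FALSE])
}

#' Expand a water table into typed atom records
#'
#' Each water becomes three atoms (O, H1, H2) of residue HOH with TIP3P-like
#' charges, typed through the packaged table.
#'
#' @param waters water data frame.
#' @return atom data frame.
#' @export
water_atoms <- function(waters) {
  n <- nrow(waters)
  if (n == 0) return(empty_atoms())
  idx <- seq_len(n)
  at <- data.frame(
    serial = seq_len(3 * n),
    name = rep(c("O", "H1", "H2"), n),
    element = rep(c("O", "H", "H"), n),
    resname = "HOH",
    resno = rep(idx, each = 3),
    chain = "W",
    x = as.vector(rbind(waters$ox, waters$h1x, waters$h2x)),
    y = as.vector(rbind(waters$oy, waters$h1y, waters$h2y)),
    z = as.vector(rbind(waters$oz, waters$h1z, waters$h2z)),
    stringsAsFactors = FALSE
  )
  st <- assign_atom_types(new_structure(at, role = "water",
                                        provenance = "water table"))
  st$atoms
}

#' Validate rigid water geometry
#'
#' TRUE when every water has O-H bonds of 0.9572 A (within `tol_bond`) and
#' an H-O-H angle of 104.52 degrees (within `tol_angle` degrees).
#'
#' @param waters water data frame.
#' @param tol_bond,tol_angle tolerances (A, degrees).
#' @export
check_water_geometry <- function(waters, tol_bond = 1e-3, tol_angle = 0.1) {
  if (nrow(waters) == 0) return(TRUE)
  o <- water_o(waters)
  h1 <- as.matrix(waters[, c("h1x", "h1y", "h1z")])
  h2 <- as.matrix(waters[, c("h2x", "h2y", "h2z")])
  d1 <- sqrt(rowSums((h1 - o)^2)); d2 <- sqrt(rowSums((h2 - o)^2))
  cosang <- rowSums((h1 - o) * (h2 - o)) / (d1 * d2)
  ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
  all(abs(d1 - .tip3p_oh) < tol_bond, abs(d2 - .tip3p_oh) < tol_bond,
      abs(ang - 104.52) < tol_angle)
}
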