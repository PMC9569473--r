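#' Rigid (or improper) poses
#'
#' A pose is the transform `x' = R x + t` placing a rigid domain model:
#' `R` a 3x3 orthonormal matrix, `t` a translation in Angstrom. A pose is
#' *improper* when `det(R) = -1`: it contains a reflection and inverts
#' chirality, which distance-only restraints cannot distinguish from the
#' proper solution. Improper poses are always flagged, never silently
#' applied.
#'
#' @param rotation 3x3 orthonormal matrix.
#' @param translation Numeric length-3 vector (Angstrom).
#' @return An `xl_pose`.
#' @export
pose <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  if (!all(dim(rotation) == c(3, 3)) ||
      max(abs(crossprod(rotation) - diag(3))) > 1e-8) {
    abort("`rotation` must be a 3x3 orthonormal matrix.",
          class = "xlinkr_pose_error")
  }
  structure(list(rotation = rotation,
                 translation = as.numeric(translation),
                 improper = det(rotation) < 0),
            class = "xl_pose")
}

#' @export
print.xl_pose <- function(x, ...) {
  cat(sprintf("<xl_pose>%s translation (%.2f, %.2f, %.2f) A\n",
              if (x$improper) " IMPROPER (chirality-inverting)" else "",
              x$translation[1], x$translation[2], x$translation[3]))
  print(round(x$rotation, 4))
  invisible(x)
}

pose_identity <- function() pose()

# uniform random rotation matrix from a random unit quaternion
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

rot_xyz <- function(a, b, c) {
  # small-angle composition used by the refiner: Rz(c) Ry(b) Rx(a)
  Rx <- matrix(c(1, 0, 0, 0, cos(a), -sin(a), 0, sin(a), cos(a)), 3, byrow = TRUE)
  Ry <- matrix(c(cos(b), 0, sin(b), 0, 1, 0, -sin(b), 0, cos(b)), 3, byrow = TRUE)
  Rz <- matrix(c(cos(c), -sin(c), 0, sin(c), cos(c), 0, 0, 0, 1), 3, byrow = TRUE)
  Rz %*% Ry %*% Rx
}

#' Apply a pose to a structure
#'
#' @param structure Atom table.
#' @param pose An [pose()] object.
#' @return The transformed atom table; all pairwise distances are preserved
#'   (a reflection additionally inverts chirality).
#' @export
transform_structure <- function(structure, pose) {
  stopifnot(inherits(pose, "xl_pose"))
  s <- as_structure(structure)
  xyz <- coords(s) %*% t(pose$rotation)
  xyz <- sweep(xyz, 2, pose$translation, "+")
  set_coords(s, xyz)
}

#' Reflect a structure across a plane
#'
#' Reflection across the plane through `point` with unit `normal`. The
#' result is the mirror image: pairwise distances are preserved but
#' chirality (the sign of every Calpha pseudo-dihedral) flips. Reflecting
#' real atomic coordinates produces a non-physical enantiomer; use it to
#' diagnose mirror-image ambiguity, not as a modeling move.
#'
#' @param structure Atom table.
#' @param point A point on the mirror plane (length-3).
#' @param normal Plane normal (length-3, non-zero).
#' @return The reflected atom table.
#' @export
mirror_structure <- function(structure, point = c(0, 0, 0),
                             normal = c(1, 0, 0)) {
  normal <- as.numeric(normal)
  nn <- sqrt(sum(normal^2))
  if (nn == 0) {
    abort("Mirror plane normal must be non-zero.", class = "xlinkr_pose_error")
  }
  n <- normal / nn
  s <- as_structure(structure)
  xyz <- coords(s)
  d <- (xyz - matrix(point, nrow(xyz), 3, byrow = TRUE)) %*% n
  set_coords(s, xyz - 2 * as.vector(d) %o% n)
}

reflection_matrix <- function(normal) {
  n <- normal / sqrt(sum(normal^2))
  diag(3) - 2 * (n %o% n)
}

#' Calpha pseudo-dihedrals of a trace
#'
#' The torsion over consecutive Calpha quadruplets (i, i+1, i+2, i+3); its
#' sign is a handedness probe: mirroring a trace flips every sign.
#'
#' @param structure Atom table (CA atoms are used, ordered by `resno`).
#' @return Numeric vector of dihedrals in degrees.
#' @export
ca_pseudo_dihedrals <- function(structure) {
  s <- as_structure(structure)
  ca <- s[s$atom == "CA", , drop = FALSE]
  ca <- ca[order(ca$resno), , drop = FALSE]
  p <- coords(ca)
  n <- nrow(p)
  if (n < 4) return(numeric())
  vapply(seq_len(n - 3), function(i) {
    b1 <- p[i + 1, ] - p[i, ]
    b2 <- p[i + 2, ] - p[i + 1, ]
    b3 <- p[i + 3, ] - p[i + 2, ]
    n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
            b1[3] * b2[1] - b1[1] * b2[3],
            b1[1] * b2[2] - b1[2] * b2[1])
    n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
            b2[3] * b3[1] - b2[1] * b3[3],
            b2[1] * b3[2] - b2[2] * b3[1])
    m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
            n1[3] * b2[1] - n1[1] * b2[3],
            n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
    # sign follows the usual convention: a right-handed ideal helix gives
    # uniformly positive virtual torsions (~ +50 degrees)
    -atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
  }, numeric(1))
}
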