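#' Quaternion helpers
#'
#' Unit quaternions `(w, x, y, z)` encode the rigid orientation of the
#' ligand. `quat_normalize()` maps any non-zero 4-vector to the unit sphere
#' (and the zero vector to the identity), `quat_from_axis_angle()` builds a
#' rotation about `axis` by `angle` radians, and `quat_multiply()` composes
#' rotations (`a` applied after `b`).
#'
#' @param q,a,b Numeric 4-vectors.
#' @param axis Numeric 3-vector (need not be unit length).
#' @param angle Rotation angle in radians.
#' @return A numeric 4-vector.
#' @export
quat_normalize <- function(q) {
  n <- sqrt(sum(q^2))
  if (n < 1e-12) return(c(1, 0, 0, 0))
  q / n
}

#' @rdname quat_normalize
#' @export
quat_from_axis_angle <- function(axis, angle) {
  n <- sqrt(sum(axis^2))
  if (n < 1e-12) return(c(1, 0, 0, 0))
  u <- axis / n
  c(cos(angle / 2), sin(angle / 2) * u)
}

#' @rdname quat_normalize
#' @export
quat_multiply <- function(a, b) {
  c(a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1])
}

#' Random uniform unit quaternion
#'
#' Drawn from the rotation-invariant (Haar) distribution via normalized
#' Gaussians; uses R's RNG.
#' @return A unit 4-vector.
#' @export
random_quaternion <- function() quat_normalize(rnorm(4))

#' Construct a ligand conformation
#'
#' A point in the docking search space: the Cartesian position of the ligand
#' root center (Angstrom), a unit quaternion for the rigid orientation, and
#' one torsion angle per rotatable bond (radians, wrapped to `(-pi, pi]`).
#' The search dimension is `D = 7 + n_torsions`.
#'
#' @param position Numeric 3-vector, Angstrom.
#' @param orientation Quaternion; normalized on construction.
#' @param torsions Numeric vector of torsion angles.
#' @return An object of class `conformation`.
#' @export
conformation <- function(position, orientation = c(1, 0, 0, 0),
                         torsions = numeric(0)) {
  stopifnot(length(position) == 3, length(orientation) == 4)
  out <- list(position = as.double(position),
              orientation = quat_normalize(as.double(orientation)),
              torsions = wrap_angle(as.double(torsions)))
  class(out) <- "conformation"
  out
}

#' @export
print.conformation <- function(x, ...) {
  cat("<conformation> D =", 7 + length(x$torsions),
      "| position", paste(sprintf("%.2f", x$position), collapse = " "), "\n")
  invisible(x)
}

conf_to_vec <- function(conf) {
  c(conf$position, conf$orientation, conf$torsions)
}

vec_to_conf <- function(x, n_torsions) {
  conformation(x[1:3], x[4:7],
               if (n_torsions > 0) x[7 + seq_len(n_torsions)] else numeric(0))
}

#' Map a conformation to Cartesian coordinates
#'
#' Applies, in order: the torsion rotations (depth-first, each branch
#' rotating its moved atoms about the parent-to-child bond axis,
#' right-handed), the rigid rotation about the ligand root center, and the
#' translation that puts the root center at `conf$position`.
#'
#' @param ligand A `ligand_model`.
#' @param conf A [conformation()] whose torsion count matches the ligand.
#' @return An N x 3 coordinate matrix (all atoms, file order).
#' @export
apply_conformation <- function(ligand, conf) {
  stopifnot(inherits(ligand, "ligand_model"), inherits(conf, "conformation"))
  if (length(conf$torsions) != ligand$n_torsions)
    stop("conformation has ", length(conf$torsions),
         " torsions but ligand has ", ligand$n_torsions)
  br <- ligand$tree$branches
  cpp_apply_conformation(
    as.matrix(ligand$atoms[, c("x", "y", "z")]),
    as.double(ligand$root_center),
    conf$orientation, conf$torsions,
    vapply(br, `[[`, 1L, "parent"),
    vapply(br, `[[`, 1L, "child"),
    lapply(br, `[[`, "moved"),
    conf$position)
}

#' Root-mean-square deviation between two coordinate sets
#'
#' Plain coordinate RMSD with atom-index matching and no superposition:
#' both sets live in the receptor frame, as in redocking evaluation. The
#' caller is responsible for passing matching (typically heavy-atom) subsets.
#'
#' @param coords_a,coords_b N x 3 matrices with identical atom order.
#' @return RMSD in Angstrom.
#' @export
rmsd <- function(coords_a, coords_b) {
  coords_a <- as.matrix(coords_a)
  coords_b <- as.matrix(coords_b)
  if (!all(dim(coords_a) == dim(coords_b)))
    stop("coordinate sets differ in dimension: ",
         paste(dim(coords_a), collapse = "x"), " vs ",
         paste(dim(coords_b), collapse = "x"))
  sqrt(mean(rowSums((coords_a - coords_b)^2)))
}

#' Heavy-atom RMSD between two poses of the same ligand
#'
#' @param ligand A `ligand_model`.
#' @param coords_a,coords_b Full N x 3 coordinate matrices of the ligand.
#' @return Heavy-atom RMSD in Angstrom.
#' @export
pose_rmsd <- function(ligand, coords_a, coords_b) {
  h <- ligand$atoms$heavy
  rmsd(coords_a[h, , drop = FALSE], coords_b[h, , drop = FALSE])
}

#' Docking success criterion
#'
#' A predicted pose counts as a success when its RMSD to the crystal pose is
#' 2 Angstrom or less (threshold inclusive).
#'
#' @param rmsd_value Non-negative RMSD value(s) in Angstrom.
#' @return Logical vector.
#' @export
is_success <- function(rmsd_value) rmsd_value <= 2.0
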