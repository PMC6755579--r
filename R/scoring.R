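#' Empirical scoring parameters
#'
#' Term weights and shape constants of the Vina-style empirical scoring
#' function shipped with the package: two attractive Gaussians of the
#' surface distance `d = r - R_i - R_j`, a quadratic steric repulsion for
#' overlapping atoms, a hydrophobic contact ramp, and a hydrogen-bond ramp,
#' plus the torsion penalty applied as the divisor
#' `1 + torsion_weight * n_torsions` when converting intermolecular energy
#' to the reported affinity. All fields can be overridden.
#'
#' @param gauss1,gauss2,repulsion,hydrophobic,hbond Term weights (kcal/mol).
#' @param torsion_weight Weight of the rotatable-bond penalty.
#' @param cutoff Pair interaction cutoff in Angstrom.
#' @return A list of class `scoring_params`.
#' @export
scoring_params <- function(gauss1 = -0.035579, gauss2 = -0.005156,
                           repulsion = 0.840245, hydrophobic = -0.035069,
                           hbond = -0.587439, torsion_weight = 0.05846,
                           cutoff = 8) {
  stopifnot(cutoff > 0)
  out <- list(weights = c(gauss1 = gauss1, gauss2 = gauss2,
                          repulsion = repulsion, hydrophobic = hydrophobic,
                          hbond = hbond),
              torsion_weight = torsion_weight, cutoff = cutoff)
  class(out) <- "scoring_params"
  out
}

#' Pairwise interaction energy at a given surface distance
#'
#' Evaluates the weighted sum of the scoring terms for one atom-type pair as
#' a function of the surface distance `d = r - R_i - R_j` (negative `d`
#' means overlapping van der Waals spheres). The hydrophobic term applies
#' only when both types are hydrophobic; the hydrogen-bond term only for a
#' donor/acceptor pair (type-level approximation: AD4 acceptor types accept,
#' and `type_i`/`type_j` may be given as `"don"`-suffixed donors via
#' `donor_i`/`donor_j`). Vectorized in `d`.
#'
#' @param d_surface Surface distance(s) in Angstrom.
#' @param type_i,type_j AD4 atom types.
#' @param params A [scoring_params()].
#' @param donor_i,donor_j Logical; whether each atom carries a polar
#'   hydrogen (donor status is a per-atom property, not a type property).
#' @return Energy in kcal/mol; exactly 0 beyond the cutoff.
#' @export
pair_potential <- function(d_surface, type_i, type_j,
                           params = scoring_params(),
                           donor_i = FALSE, donor_j = FALSE) {
  tab <- ad4_type_table()
  i <- match(type_i, tab$type)
  j <- match(type_j, tab$type)
  if (is.na(i) || is.na(j))
    stop("unknown AD4 atom type: ",
         paste(c(type_i, type_j)[is.na(c(i, j))], collapse = ", "))
  w <- params$weights
  d <- d_surface
  e <- w[["gauss1"]] * exp(-(d / 0.5)^2) +
    w[["gauss2"]] * exp(-((d - 3) / 2)^2) +
    w[["repulsion"]] * ifelse(d < 0, d^2, 0)
  if (tab$hydrophobic[i] && tab$hydrophobic[j])
    e <- e + w[["hydrophobic"]] * clamp(1.5 - d, 0, 1)
  hb <- (donor_i && tab$acceptor[j]) || (donor_j && tab$acceptor[i])
  if (hb)
    e <- e + w[["hbond"]] * clamp(-d / 0.7, 0, 1)
  # the pair interaction is truncated at the cutoff *center* distance;
  # convert to surface distance per pair
  r <- d + tab$radius[i] + tab$radius[j]
  e[r >= params$cutoff] <- 0
  unname(e)
}

lig_score_args <- function(ligand) {
  a <- ligand$atoms
  list(ref = as.matrix(a[, c("x", "y", "z")]),
       rad = a$radius, hyd = a$hydrophobic, don = a$donor,
       acc = a$acceptor, heavy = a$heavy)
}

rec_score_args <- function(receptor) {
  a <- receptor$atoms
  list(xyz = as.matrix(a[, c("x", "y", "z")]),
       rad = a$radius, hyd = a$hydrophobic, don = a$donor,
       acc = a$acceptor, heavy = a$heavy)
}

#' Intramolecular interaction pairs of a ligand
#'
#' Pairs of heavy atoms that belong to different rigid bodies of the torsion
#' tree and are at least four covalent bonds apart (1-2, 1-3 and 1-4 pairs
#' are excluded). Bonds are inferred from the reference geometry by
#' covalent-range distance thresholds; the rigid body of an atom is the
#' innermost `BRANCH` containing it (or the root).
#'
#' @param ligand A `ligand_model`.
#' @return A two-column integer matrix of atom indices (0 rows for rigid
#'   ligands).
#' @export
ligand_interaction_pairs <- function(ligand) {
  a <- ligand$atoms
  n <- nrow(a)
  xyz <- as.matrix(a[, c("x", "y", "z")])
  if (ligand$n_torsions == 0 || n < 2)
    return(matrix(integer(0), 0, 2))

  # bond inference by distance
  dmat <- as.matrix(stats::dist(xyz))
  thr <- outer(a$heavy, a$heavy, function(hi, hj) ifelse(hi & hj, 1.9, 1.3))
  sulfur <- a$type %in% c("S", "SA")
  thr[sulfur, ] <- pmax(thr[sulfur, ], 2.1)
  thr[, sulfur] <- pmax(thr[, sulfur], 2.1)
  bonded <- dmat < thr & dmat > 1e-6

  # BFS shortest path in bonds
  gd <- matrix(Inf, n, n)
  diag(gd) <- 0
  for (s in seq_len(n)) {
    frontier <- s
    depth <- 0
    while (length(frontier)) {
      depth <- depth + 1
      nxt <- which(apply(bonded[, frontier, drop = FALSE], 1, any) &
                     !is.finite(gd[, s]))
      nxt <- setdiff(nxt, s)
      if (!length(nxt)) break
      gd[nxt, s] <- depth
      frontier <- nxt
    }
  }

  # rigid body = innermost branch containing the atom
  body <- rep(0L, n)
  for (b in seq_along(ligand$tree$branches)) {
    body[ligand$tree$branches[[b]]$moved] <- b
  }

  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  keep <- a$heavy[pairs[, 1]] & a$heavy[pairs[, 2]] &
    body[pairs[, 1]] != body[pairs[, 2]] &
    gd[pairs] >= 4
  out <- pairs[keep, , drop = FALSE]
  storage.mode(out) <- "integer"
  dimnames(out) <- NULL
  out
}

#' Score a ligand conformation against a rigid receptor
#'
#' Computes the intermolecular energy (sum of [pair_potential()] over
#' receptor/ligand heavy-atom pairs within the cutoff), the intramolecular
#' energy over the ligand's flexible pairs (see
#' [ligand_interaction_pairs()]), and the reported affinity
#' `intermolecular / (1 + torsion_weight * n_torsions)`. The search
#' objective used by the optimizer is `(inter + intra)` under the same
#' divisor, so search and reporting share one convention.
#'
#' @param receptor A `receptor_model`.
#' @param ligand A `ligand_model`.
#' @param conf A [conformation()] (or an N x 3 coordinate matrix already in
#'   the receptor frame).
#' @param params [scoring_params()].
#' @param method `"celllist"` (default; receptor atoms binned at the cutoff
#'   length) or `"direct"` (plain double loop). Both give identical
#'   energies.
#' @param intra_pairs Optional precomputed pair matrix.
#' @return A list of class `energy_breakdown` with `intermolecular`,
#'   `intramolecular`, `torsion_penalty_divisor`, `affinity` (kcal/mol) and
#'   `total` (the search objective value).
#' @export
score_pose <- function(receptor, ligand, conf, params = scoring_params(),
                       method = c("celllist", "direct"),
                       intra_pairs = NULL) {
  method <- match.arg(method)
  if (inherits(conf, "conformation")) {
    coords <- apply_conformation(ligand, conf)
  } else {
    coords <- as.matrix(conf)
  }
  if (is.null(intra_pairs)) intra_pairs <- ligand_interaction_pairs(ligand)
  la <- lig_score_args(ligand)
  ra <- rec_score_args(receptor)
  res <- cpp_score_system(coords, la$rad, la$hyd, la$don, la$acc, la$heavy,
                          ra$xyz, ra$rad, ra$hyd, ra$don, ra$acc, ra$heavy,
                          intra_pairs, unname(params$weights), params$cutoff,
                          method == "celllist", FALSE)
  divisor <- 1 + params$torsion_weight * ligand$n_torsions
  out <- list(intermolecular = res$inter,
              intramolecular = res$intra,
              torsion_penalty_divisor = divisor,
              affinity = res$inter / divisor,
              total = (res$inter + res$intra) / divisor)
  class(out) <- "energy_breakdown"
  out
}

#' @export
print.energy_breakdown <- function(x, ...) {
  cat(sprintf("affinity %8.3f kcal/mol (inter %8.3f, intra %8.3f, 1/div %.4f)\n",
              x$affinity, x$intermolecular, x$intramolecular,
              1 / x$torsion_penalty_divisor))
  invisible(x)
}

#' Build the docking objective (value + gradient) for an optimizer
#'
#' Returns a closure `f(X, want_gradient = TRUE)` over the search vector
#' `X = (position, quaternion, torsions)` evaluating the scoring function
#' and its analytic gradient: translation block, orientation block (torque
#' pulled back through the normalized quaternion, so the closure is well
#' defined for any non-zero quaternion), and per-torsion derivatives.
#'
#' @param receptor A `receptor_model`.
#' @param ligand A `ligand_model`.
#' @param params [scoring_params()].
#' @param use_cells Use the cell-list neighbor search.
#' @return A function returning `list(value, gradient, inter, intra)`.
#' @export
dock_objective <- function(receptor, ligand, params = scoring_params(),
                           use_cells = TRUE) {
  la <- lig_score_args(ligand)
  ra <- rec_score_args(receptor)
  br <- ligand$tree$branches
  br_parent <- vapply(br, `[[`, 1L, "parent")
  br_child <- vapply(br, `[[`, 1L, "child")
  br_moved <- lapply(br, `[[`, "moved")
  intra_pairs <- ligand_interaction_pairs(ligand)
  root_center <- as.double(ligand$root_center)
  weights <- unname(params$weights)
  cutoff <- params$cutoff
  divisor <- 1 + params$torsion_weight * ligand$n_torsions
  function(X, want_gradient = TRUE) {
    cpp_dock_eval(as.double(X), la$ref, root_center,
                  br_parent, br_child, br_moved,
                  la$rad, la$hyd, la$don, la$acc, la$heavy,
                  ra$xyz, ra$rad, ra$hyd, ra$don, ra$acc, ra$heavy,
                  intra_pairs, weights, cutoff, divisor, use_cells,
                  want_gradient)
  }
}

#' Gradient of the docking objective at a conformation
#'
#' Convenience wrapper around [dock_objective()] returning the analytic
#' gradient blocks by name.
#'
#' @inheritParams score_pose
#' @return `list(value, position, orientation, torsions, gradient)` where
#'   `gradient` is the full `(7 + n_torsions)`-vector.
#' @export
score_gradient <- function(receptor, ligand, conf,
                           params = scoring_params()) {
  f <- dock_objective(receptor, ligand, params)
  res <- f(conf_to_vec(conf))
  g <- res$gradient
  nt <- ligand$n_torsions
  list(value = res$value,
       position = g[1:3],
       orientation = g[4:7],
       torsions = if (nt > 0) g[7 + seq_len(nt)] else numeric(0),
       gradient = g)
}
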