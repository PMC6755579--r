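#' Docking search box
#'
#' An axis-aligned box given by its center and per-axis edge lengths, both
#' in Angstrom.
#'
#' @param center Numeric 3-vector.
#' @param lengths Numeric 3-vector of positive edge lengths (a scalar is
#'   recycled).
#' @return An object of class `search_box`.
#' @export
search_box <- function(center, lengths) {
  if (length(lengths) == 1) lengths <- rep(lengths, 3)
  stopifnot(length(center) == 3, length(lengths) == 3)
  if (any(lengths <= 0)) stop("box lengths must be positive")
  out <- list(center = as.double(center), lengths = as.double(lengths))
  class(out) <- "search_box"
  out
}

#' @export
print.search_box <- function(x, ...) {
  cat(sprintf("<search_box> center (%.2f, %.2f, %.2f), size (%.1f, %.1f, %.1f) A\n",
              x$center[1], x$center[2], x$center[3],
              x$lengths[1], x$lengths[2], x$lengths[3]))
  invisible(x)
}

box_bounds <- function(box) {
  list(lower = box$center - box$lengths / 2,
       upper = box$center + box$lengths / 2)
}

coords_of <- function(x) {
  if (is.matrix(x)) return(x)
  if (inherits(x, "receptor_model") || inherits(x, "ligand_model"))
    return(as.matrix(x$atoms[, c("x", "y", "z")]))
  if (is.data.frame(x)) return(as.matrix(x[, c("x", "y", "z")]))
  stop("cannot extract coordinates from object of class ", class(x)[1])
}

#' Build the docking box from pocket atoms
#'
#' Center = geometric center of the pocket atoms; lengths = the largest
#' pocket-atom distances along X, Y and Z. Degenerate (near-flat) pockets
#' are padded to a minimum edge of 1 Angstrom with a warning.
#'
#' @param pocket_atoms Coordinate matrix, atoms data.frame, or a
#'   receptor/ligand model.
#' @return A [search_box()].
#' @export
box_from_pocket <- function(pocket_atoms) {
  xyz <- coords_of(pocket_atoms)
  if (nrow(xyz) < 2) stop("need at least 2 pocket atoms to define a box")
  lengths <- apply(xyz, 2, max) - apply(xyz, 2, min)
  if (any(lengths < 1)) {
    warning("degenerate pocket box; padding axis length(s) to 1 A")
    lengths <- pmax(lengths, 1)
  }
  search_box(colMeans(xyz), lengths)
}

#' Build the docking box from the bound ligand
#'
#' Center = geometric center of the (crystal) ligand; cubic box with the
#' given edge, 22.5 Angstrom by default.
#'
#' @param crystal_ligand A `ligand_model` or coordinate matrix.
#' @param edge Cube edge length in Angstrom.
#' @return A [search_box()].
#' @export
box_from_ligand <- function(crystal_ligand, edge = 22.5) {
  xyz <- coords_of(crystal_ligand)
  if (nrow(xyz) < 1) stop("empty ligand")
  search_box(colMeans(xyz), edge)
}

dock_project <- function(lower3, upper3, n_torsions) {
  function(X) {
    X[1:3] <- clamp(X[1:3], lower3, upper3)
    X[4:7] <- quat_normalize(X[4:7])
    if (n_torsions > 0) {
      idx <- 7 + seq_len(n_torsions)
      X[idx] <- wrap_angle(X[idx])
    }
    X
  }
}

dock_delta <- function(n_torsions) {
  function(X, target) {
    d <- target - X
    # q and -q are the same rotation: attract along the closer representative
    if (sum(X[4:7] * target[4:7]) < 0) d[4:7] <- -target[4:7] - X[4:7]
    if (n_torsions > 0) {
      idx <- 7 + seq_len(n_torsions)
      d[idx] <- wrap_angle(d[idx])
    }
    d
  }
}

dock_init <- function(lower3, upper3, n_torsions) {
  function(n) {
    t(vapply(seq_len(n), function(i) {
      c(runif(3, lower3, upper3),
        random_quaternion(),
        if (n_torsions > 0) runif(n_torsions, -pi, pi) else numeric(0))
    }, numeric(7 + n_torsions)))
  }
}

#' Dock a flexible ligand into a rigid receptor
#'
#' Runs `n_runs` independent chaos-embedded swarm searches (distinct
#' sub-seeds of `cfg$seed`), refines with the two-stage BFGS local search,
#' and returns the found poses de-duplicated (heavy-atom RMSD below
#' `dedup_rmsd` keeps the lower affinity) and ranked by affinity; the first
#' pose is the best-scoring solution, the protocol's final answer.
#'
#' @param receptor A `receptor_model` (or path to a receptor PDBQT).
#' @param ligand A `ligand_model` (or path to a ligand PDBQT).
#' @param box A [search_box()].
#' @param cfg A [swarm_config()].
#' @param n_runs Number of independent repetitions.
#' @param params [scoring_params()].
#' @param dedup_rmsd De-duplication threshold in Angstrom.
#' @param max_modes Maximum number of reported poses.
#' @return An object of class `dock_result`: list with `poses` (each a list
#'   with `conformation`, `coordinates`, `affinity`, `intermolecular`,
#'   `intramolecular`, `run_index`, `generations_used`), plus the inputs.
#' @export
dock <- function(receptor, ligand, box, cfg = swarm_config(), n_runs = 10,
                 params = scoring_params(), dedup_rmsd = 1.0,
                 max_modes = 9) {
  if (is.character(receptor)) receptor <- parse_pdbqt_receptor(receptor)
  if (is.character(ligand)) ligand <- parse_pdbqt_ligand(ligand)
  stopifnot(inherits(receptor, "receptor_model"),
            inherits(ligand, "ligand_model"), inherits(box, "search_box"))

  ref <- as.matrix(ligand$atoms[, c("x", "y", "z")])
  span <- apply(ref, 2, max) - apply(ref, 2, min)
  if (any(span > box$lengths))
    warning("ligand extent (", paste(sprintf("%.1f", span), collapse = ", "),
            " A) exceeds the box in at least one dimension")

  # receptor atoms that can never reach the cutoff of any in-box ligand atom
  # are dropped once up front
  bb <- box_bounds(box)
  reach <- sqrt(sum((box$lengths / 2)^2)) + params$cutoff +
    max(sqrt(rowSums(sweep(ref, 2, colMeans(ref))^2))) + 1
  rxyz <- as.matrix(receptor$atoms[, c("x", "y", "z")])
  keep <- sqrt(colSums((t(rxyz) - box$center)^2)) <= reach
  rec_use <- receptor
  rec_use$atoms <- receptor$atoms[keep, , drop = FALSE]

  nt <- ligand$n_torsions
  objective <- dock_objective(rec_use, ligand, params)
  project <- dock_project(bb$lower, bb$upper, nt)
  init <- dock_init(bb$lower, bb$upper, nt)
  vmax <- c(box$lengths / 2, rep(1, 4), rep(pi, max(0, nt)))[1:(7 + nt)]
  divisor <- 1 + params$torsion_weight * nt
  intra_pairs <- ligand_interaction_pairs(ligand)

  runs <- vector("list", n_runs)
  for (k in seq_len(n_runs)) {
    cfg_k <- cfg
    cfg_k$seed <- split_seed(cfg$seed, 7000L + k)
    res <- pso_search(objective, c(bb$lower, rep(-1, 4), rep(-pi, nt)),
                      c(bb$upper, rep(1, 4), rep(pi, nt)),
                      cfg_k, project = project, init = init, vmax = vmax,
                      delta = dock_delta(nt))
    if (!is.finite(res$value)) next
    conf <- vec_to_conf(res$par, nt)
    coords <- apply_conformation(ligand, conf)
    eb <- score_pose(rec_use, ligand, coords, params,
                     intra_pairs = intra_pairs)
    runs[[k]] <- list(conformation = conf, coordinates = coords,
                      affinity = eb$affinity,
                      intermolecular = eb$intermolecular,
                      intramolecular = eb$intramolecular,
                      run_index = k, generations_used = res$generations)
  }
  runs <- Filter(Negate(is.null), runs)
  if (!length(runs)) stop("no docking run produced a finite pose")

  runs <- runs[order(vapply(runs, `[[`, 0, "affinity"))]
  poses <- list()
  h <- ligand$atoms$heavy
  for (cand in runs) {
    dup <- FALSE
    for (p in poses) {
      if (rmsd(cand$coordinates[h, , drop = FALSE],
               p$coordinates[h, , drop = FALSE]) < dedup_rmsd) {
        dup <- TRUE
        break
      }
    }
    if (!dup) poses[[length(poses) + 1]] <- cand
    if (length(poses) >= max_modes) break
  }

  out <- list(poses = poses, ligand = ligand, box = box,
              n_runs = n_runs, seed = cfg$seed, chaos = cfg$chaos)
  class(out) <- "dock_result"
  out
}

#' @export
print.dock_result <- function(x, ...) {
  cat("<dock_result> ", length(x$poses), " pose(s) from ", x$n_runs,
      " run(s), chaos = ", x$chaos, "\n", sep = "")
  aff <- vapply(x$poses, `[[`, 0, "affinity")
  for (i in seq_along(aff))
    cat(sprintf("  mode %d: %8.3f kcal/mol (run %d, %d generations)\n", i,
                aff[i], x$poses[[i]]$run_index,
                x$poses[[i]]$generations_used))
  invisible(x)
}
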