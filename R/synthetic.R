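#' Synthetic toy receptor-ligand complex with a planted pose
#'
#' Generates a self-contained docking fixture: a branched heavy-atom ligand
#' with `n_torsions` rotatable bonds sitting at its crystal conformation
#' inside a concave shell of receptor atoms built to be shape- and
#' polarity-complementary to it. Hydrogen-bond donors and acceptors are
#' placed at matched distances in pocket and ligand, so the planted pose is
#' a deep minimum of the empirical scoring function (the "funnel"
#' property, verified at generation time against 1000 random poses in the
#' box). Only C/N/O AD4 types (plus polar hydrogens) are used.
#'
#' All geometry derives deterministically from `seed`; the same arguments
#' always produce byte-identical PDBQT text.
#'
#' @param n_pocket_atoms Number of receptor atoms (at least 8).
#' @param n_torsions Number of rotatable ligand bonds, 0 to 10.
#' @param seed Integer seed.
#' @param verify Verify the planted-funnel property (crystal pose scoring
#'   below the 5th percentile of 1000 random poses).
#' @return An object of class `toy_complex`: `receptor`, `ligand` (parsed
#'   models), `receptor_pdbqt`, `ligand_pdbqt` (text), the
#'   `crystal_conformation`, the `box`, and `seed`.
#' @export
make_toy_complex <- function(n_pocket_atoms = 30, n_torsions = 2, seed = 1,
                             verify = TRUE) {
  stopifnot(n_pocket_atoms >= 8, n_torsions >= 0, n_torsions <= 10)
  for (attempt in 0:4) {
    res <- try(build_toy_complex(n_pocket_atoms, n_torsions,
                                 split_seed(seed, attempt), verify),
               silent = TRUE)
    if (!inherits(res, "try-error")) {
      res$seed <- seed
      return(res)
    }
  }
  stop("could not generate a feasible toy complex: ",
       attr(res, "condition")$message)
}

rot_about <- function(v, axis, angle) {
  u <- axis / sqrt(sum(axis^2))
  ct <- cos(angle); st <- sin(angle)
  ct * v + st * c(u[2] * v[3] - u[3] * v[2],
                  u[3] * v[1] - u[1] * v[3],
                  u[1] * v[2] - u[2] * v[1]) +
    (1 - ct) * sum(u * v) * u
}

unit3 <- function(v) v / sqrt(sum(v^2))

rand_perp <- function(v) {
  repeat {
    w <- rnorm(3)
    w <- w - sum(w * unit3(v)) * unit3(v)
    if (sqrt(sum(w^2)) > 1e-6) return(unit3(w))
  }
}

build_toy_ligand <- function(n_torsions) {
  # rigid root: central carbon with four chemically distinct substituents
  # (two acceptor O, one carbon, one donor N-H), one of them out of plane,
  # so the crystal orientation is unique and mirror poses lose their
  # hydrogen bonds
  atoms <- data.frame(
    name = c("C1", "O1", "C2", "N1", "H1", "O2"),
    type = c("C", "OA", "C", "N", "HD", "OA"),
    x = c(0, 1.40, 1.50 * cos(2 * pi / 3), 1.50 * cos(4 * pi / 3),
          2.50 * cos(4 * pi / 3), 0),
    y = c(0, 0, 1.50 * sin(2 * pi / 3), 1.50 * sin(4 * pi / 3),
          2.50 * sin(4 * pi / 3), 0),
    z = c(0, 0, 0, 0, 0, 1.40),
    stringsAsFactors = FALSE
  )
  root_idx <- seq_len(nrow(atoms))
  branches <- list()
  bonds <- rbind(c(1, 2), c(1, 3), c(1, 4), c(4, 5), c(1, 6))

  parent <- 3L  # chain grows from C2
  dir_prev <- unit3(c(atoms$x[3], atoms$y[3], atoms$z[3]))
  for (j in seq_len(n_torsions)) {
    pxyz <- c(atoms$x[parent], atoms$y[parent], atoms$z[parent])
    placed <- FALSE
    for (try in 1:30) {
      d <- rot_about(dir_prev, rand_perp(dir_prev), 0.9 + runif(1, -0.2, 0.2))
      child_xyz <- pxyz + 1.5 * d
      s_dir <- rot_about(d, rand_perp(d), 1.2 + runif(1, -0.2, 0.2))
      sub_xyz <- child_xyz + 1.5 * s_dir
      # incremental steric check (direct bond partners excluded)
      xyz <- as.matrix(atoms[, c("x", "y", "z")])
      d_child <- sqrt(colSums((t(xyz) - child_xyz)^2))
      d_child[parent] <- Inf
      d_sub <- sqrt(colSums((t(xyz) - sub_xyz)^2))
      if (min(d_child) > 2.1 && min(d_sub) > 2.1 &&
          sqrt(sum((sub_xyz - child_xyz)^2)) > 1.0) {
        placed <- TRUE
        break
      }
    }
    if (!placed) stop("ligand self-clash")
    sub_type <- if (j %% 2 == 1) "OA" else "C"
    child <- nrow(atoms) + 1L
    atoms <- rbind(atoms,
                   data.frame(name = sprintf("C%d", child), type = "C",
                              x = child_xyz[1], y = child_xyz[2],
                              z = child_xyz[3], stringsAsFactors = FALSE),
                   data.frame(name = sprintf("%s%d",
                                             if (sub_type == "OA") "O" else "C",
                                             child + 1L),
                              type = sub_type,
                              x = sub_xyz[1], y = sub_xyz[2], z = sub_xyz[3],
                              stringsAsFactors = FALSE))
    branches[[j]] <- list(parent = parent, child = child)
    bonds <- rbind(bonds, c(parent, child), c(child, child + 1L))
    parent <- child
    dir_prev <- d
  }

  # reject geometries where atoms more than two bonds apart come too close
  n <- nrow(atoms)
  gd <- matrix(Inf, n, n)
  diag(gd) <- 0
  adj <- matrix(FALSE, n, n)
  adj[bonds] <- TRUE
  adj <- adj | t(adj)
  for (s in seq_len(n)) {
    frontier <- s
    depth <- 0
    while (length(frontier)) {
      depth <- depth + 1
      nxt <- which(apply(adj[, frontier, drop = FALSE], 1, any) &
                     !is.finite(gd[, s]))
      nxt <- setdiff(nxt, s)
      if (!length(nxt)) break
      gd[nxt, s] <- depth
      frontier <- nxt
    }
  }
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  dm <- as.matrix(stats::dist(xyz))
  if (any(dm < 2.2 & gd >= 3)) stop("ligand self-clash")

  list(atoms = atoms, branches = branches, root_idx = root_idx)
}

ligand_to_pdbqt <- function(lig) {
  fmt <- function(i) {
    sprintf("ATOM  %5d %-4s LIG A   1    %8.3f%8.3f%8.3f%6.2f%6.2f    %6.3f %-2s",
            i, lig$atoms$name[i], lig$atoms$x[i], lig$atoms$y[i],
            lig$atoms$z[i], 1.00, 0.00, 0.000, lig$atoms$type[i])
  }
  out <- c("ROOT", vapply(lig$root_idx, fmt, ""), "ENDROOT")
  nb <- length(lig$branches)
  for (j in seq_len(nb)) {
    b <- lig$branches[[j]]
    out <- c(out, sprintf("BRANCH %3d %3d", b$parent, b$child),
             fmt(b$child), fmt(b$child + 1L))
  }
  for (j in rev(seq_len(nb))) {
    b <- lig$branches[[j]]
    out <- c(out, sprintf("ENDBRANCH %3d %3d", b$parent, b$child))
  }
  c(out, sprintf("TORSDOF %d", nb))
}

build_toy_complex <- function(n_pocket_atoms, n_torsions, seed, verify) {
  set.seed(seed)
  lig_raw <- build_toy_ligand(n_torsions)
  lig_text <- paste(ligand_to_pdbqt(lig_raw), collapse = "\n")
  ligand <- parse_pdbqt_ligand(lig_text)

  a <- ligand$atoms
  heavy <- which(a$heavy)
  centroid <- colMeans(a[heavy, c("x", "y", "z")])
  tab <- ad4_type_table()

  rec <- list()
  add_rec <- function(type, xyz) {
    rec[[length(rec) + 1]] <<- data.frame(
      type = type, x = xyz[1], y = xyz[2], z = xyz[3],
      stringsAsFactors = FALSE)
  }

  # polar anchors first: each ligand donor/acceptor faces a matched partner
  # at hydrogen-bonding surface overlap along its outward direction
  lig_heavy_xyz <- as.matrix(a[heavy, c("x", "y", "z")])
  lig_heavy_rad <- a$radius[heavy]
  crad <- tab$radius[match("C", tab$type)]
  for (k in heavy) {
    if (!(a$acceptor[k] || a$donor[k])) next
    rk <- c(a$x[k], a$y[k], a$z[k])
    v <- rk - centroid
    if (sqrt(sum(v^2)) < 0.8) next
    u <- unit3(v)
    ptype <- if (a$acceptor[k]) "N" else "OA"
    prad <- tab$radius[match(ptype, tab$type)]
    p <- rk + u * (a$radius[k] + prad - 0.55)
    add_rec(ptype, p)
    if (ptype == "N") add_rec("HD", p - u * 1.0)
  }

  # snug carbon shell molded onto the ligand envelope: rays from the
  # centroid are marched outward until the closest ligand surface distance
  # reaches the contact optimum, so the planted pose is wrapped tightly and
  # displaced poses run into steric repulsion
  surf <- function(p) min(sqrt(colSums((t(lig_heavy_xyz) - p)^2)) -
                            lig_heavy_rad - crad)
  n_left <- n_pocket_atoms - length(rec)
  tries <- 0
  while (n_left > 0 && tries < 3000) {
    tries <- tries + 1
    w <- unit3(rnorm(3))
    target <- runif(1, 0.05, 0.25)
    t_step <- 2
    while (surf(centroid + t_step * w) < target) t_step <- t_step + 0.1
    p <- centroid + t_step * w
    cur <- do.call(rbind, rec)
    if (!is.null(cur) &&
        min(sqrt(colSums((t(as.matrix(cur[, c("x", "y", "z")])) - p)^2))) <
          2.5) next
    add_rec("C", p)
    n_left <- n_left - 1
  }

  rec_df <- do.call(rbind, rec)
  rec_lines <- vapply(seq_len(nrow(rec_df)), function(i) {
    sprintf("ATOM  %5d %-4s POC A%4d    %8.3f%8.3f%8.3f%6.2f%6.2f    %6.3f %-2s",
            i, paste0(substr(rec_df$type[i], 1, 1), i), i,
            rec_df$x[i], rec_df$y[i], rec_df$z[i], 1.00, 0.00, 0.000,
            rec_df$type[i])
  }, "")
  rec_text <- paste(rec_lines, collapse = "\n")
  receptor <- parse_pdbqt_receptor(rec_text)

  box <- box_from_pocket(rec_df[rec_df$type != "HD", c("x", "y", "z")])
  crystal <- conformation(ligand$root_center, c(1, 0, 0, 0),
                          rep(0, ligand$n_torsions))

  if (verify) {
    objective <- dock_objective(receptor, ligand)
    crystal_total <- objective(conf_to_vec(crystal), want_gradient = FALSE)$value
    set.seed(split_seed(seed, 777L))
    bb <- box_bounds(box)
    rand_vals <- vapply(seq_len(1000), function(i) {
      X <- c(runif(3, bb$lower, bb$upper), random_quaternion(),
             if (n_torsions > 0) runif(n_torsions, -pi, pi) else numeric(0))
      objective(X, want_gradient = FALSE)$value
    }, 0)
    if (crystal_total >= quantile(rand_vals, 0.05))
      stop("planted pose is not a deep enough minimum")
  }

  out <- list(receptor = receptor, ligand = ligand,
              receptor_pdbqt = rec_text, ligand_pdbqt = lig_text,
              crystal_conformation = crystal, box = box, seed = seed)
  class(out) <- "toy_complex"
  out
}

#' @export
print.toy_complex <- function(x, ...) {
  cat("<toy_complex> ligand:", nrow(x$ligand$atoms), "atoms,",
      x$ligand$n_torsions, "torsions; receptor:", nrow(x$receptor$atoms),
      "atoms\n")
  invisible(x)
}

#' Analytic test objectives for the optimizer
#'
#' Standard benchmark functions with known global minima, exposed through
#' the same value-plus-gradient interface as the docking objective.
#'
#' @param name `"sphere"` (optionally shifted to `center`),
#'   `"rosenbrock"`, or `"rastrigin"`.
#' @param dim Dimension.
#' @param lower,upper Box bounds (scalars recycled).
#' @param center Sphere center (defaults to the box midpoint).
#' @return List with `fn` (the objective closure), `lower`, `upper`,
#'   `minimum` (global minimum value) and `minimizer`.
#' @export
make_test_objective <- function(name = c("sphere", "rosenbrock", "rastrigin"),
                                dim = 2, lower = -5.12, upper = 5.12,
                                center = NULL) {
  name <- match.arg(name)
  stopifnot(dim >= 1)
  if (length(lower) == 1) lower <- rep(lower, dim)
  if (length(upper) == 1) upper <- rep(upper, dim)
  if (name == "sphere") {
    if (is.null(center)) center <- (lower + upper) / 2
    fn <- function(x, want_gradient = TRUE)
      list(value = sum((x - center)^2), gradient = 2 * (x - center))
    minimizer <- center
  } else if (name == "rosenbrock") {
    fn <- function(x, want_gradient = TRUE) {
      d <- length(x)
      i <- seq_len(d - 1)
      v <- sum(100 * (x[i + 1] - x[i]^2)^2 + (1 - x[i])^2)
      g <- numeric(d)
      g[i] <- -400 * x[i] * (x[i + 1] - x[i]^2) - 2 * (1 - x[i])
      g[i + 1] <- g[i + 1] + 200 * (x[i + 1] - x[i]^2)
      list(value = v, gradient = g)
    }
    minimizer <- rep(1, dim)
  } else {
    fn <- function(x, want_gradient = TRUE)
      list(value = 10 * length(x) + sum(x^2 - 10 * cos(2 * pi * x)),
           gradient = 2 * x + 20 * pi * sin(2 * pi * x))
    minimizer <- rep(0, dim)
  }
  list(fn = fn, lower = lower, upper = upper, minimum = 0,
       minimizer = minimizer)
}

#' Synthetic virtual-screening set
#'
#' Builds a shared toy pocket plus a set of actives (ligands whose
#' hydrogen-bonding pattern and shape match the pocket, each with small
#' geometric jitter) and property-matched decoys (identical atom counts and
#' torsion trees, but with their polar sites displaced by `separation`
#' Angstrom so the complementarity is broken). With `separation = 0` decoys
#' are statistically indistinguishable from actives.
#'
#' @param n_actives,n_decoys Set sizes (at least 1 each).
#' @param separation Polar-site displacement in Angstrom.
#' @param seed Integer seed.
#' @param dir Optional directory; if given, ligand PDBQT files and a
#'   `labels.csv` are written there.
#' @return List with `receptor`, `box`, `ligands` (named list of
#'   `ligand_model`s), `labels` (data.frame `ligand_id`, `label`), and
#'   `dir`.
#' @export
make_screening_set <- function(n_actives, n_decoys, separation = 3,
                               seed = 1, dir = NULL) {
  stopifnot(n_actives >= 1, n_decoys >= 1, separation >= 0)
  template <- make_toy_complex(n_pocket_atoms = 24, n_torsions = 2,
                               seed = split_seed(seed, 1L), verify = FALSE)
  lig <- template$ligand

  variant <- function(id, polar_shift) {
    set.seed(split_seed(seed, 100L + id))
    xyz <- as.matrix(lig$atoms[, c("x", "y", "z")])
    xyz <- xyz + matrix(rnorm(length(xyz), sd = 0.08), nrow(xyz), 3)
    if (polar_shift > 0) {
      polar <- which(lig$atoms$acceptor | lig$atoms$donor)
      for (k in polar) {
        shift <- polar_shift * unit3(rnorm(3))
        xyz[k, ] <- xyz[k, ] + shift
        # carry attached polar hydrogens along
        hd <- which(lig$atoms$type == "HD")
        for (h in hd) {
          if (sqrt(sum((as.matrix(lig$atoms[h, c("x", "y", "z")]) -
                          as.matrix(lig$atoms[k, c("x", "y", "z")]))^2)) < 1.3)
            xyz[h, ] <- xyz[h, ] + shift
        }
      }
    }
    parse_pdbqt_ligand(paste(write_pdbqt_ligand(lig, xyz), collapse = "\n"))
  }

  ligands <- list()
  labels <- data.frame(ligand_id = character(0), label = character(0),
                       stringsAsFactors = FALSE)
  for (i in seq_len(n_actives)) {
    id <- sprintf("active_%02d", i)
    ligands[[id]] <- variant(i, 0)
    labels <- rbind(labels, data.frame(ligand_id = id, label = "active",
                                       stringsAsFactors = FALSE))
  }
  for (i in seq_len(n_decoys)) {
    id <- sprintf("decoy_%02d", i)
    ligands[[id]] <- variant(1000L + i, separation)
    labels <- rbind(labels, data.frame(ligand_id = id, label = "decoy",
                                       stringsAsFactors = FALSE))
  }

  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    for (id in names(ligands))
      write_pdbqt_ligand(ligands[[id]],
                         file = file.path(dir, paste0(id, ".pdbqt")))
    write.csv(labels, file.path(dir, "labels.csv"), row.names = FALSE)
    writeLines(template$receptor_pdbqt, file.path(dir, "receptor.pdbqt"))
  }

  list(receptor = template$receptor, box = template$box, ligands = ligands,
       labels = labels, dir = dir)
}
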