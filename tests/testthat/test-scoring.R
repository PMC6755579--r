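test_that("pair potential matches hand evaluation of the functional forms", {
  p <- scoring_params()
  w <- unname(p$weights)
  # carbon-carbon at surface contact d = 0
  e <- pair_potential(0, "C", "C", p)
  expect_equal(e, w[1] + w[2] * exp(-(3 / 2)^2) + w[4] * 1, tolerance = 1e-12)
  # generic distances against the independent formula
  for (d in c(-0.9, -0.3, 0.25, 1.0, 2.7)) {
    expect_equal(pair_potential(d, "C", "C", p),
                 oracle_pair_energy(d, TRUE, FALSE, w), tolerance = 1e-12)
    expect_equal(pair_potential(d, "N", "OA", p, donor_i = TRUE),
                 oracle_pair_energy(d, FALSE, TRUE, w), tolerance = 1e-12)
  }
  # repulsion is d^2 only on overlap
  e_neg <- pair_potential(-0.5, "N", "N", p)
  e_ref <- w[1] * exp(-(-0.5 / 0.5)^2) + w[2] * exp(-((-0.5 - 3) / 2)^2) +
    w[3] * 0.25
  expect_equal(e_neg, e_ref, tolerance = 1e-12)
  # beyond the cutoff the interaction vanishes
  expect_equal(pair_potential(8, "C", "C", p), 0)
  expect_error(pair_potential(0, "C", "Xx", p), "Xx")
})

test_that("a distant receptor contributes nothing; rigid ligand has no intra", {
  lig <- parse_pdbqt_ligand(rigid3_pdbqt())
  rec <- one_atom_receptor(c(20, 0, 0))
  eb <- score_pose(rec, lig, conformation(lig$root_center))
  expect_equal(eb$intermolecular, 0)
  expect_equal(eb$intramolecular, 0)
  expect_equal(eb$torsion_penalty_divisor, 1)
  expect_equal(eb$affinity, 0)
})

test_that("affinity applies the torsion-count divisor to intermolecular energy", {
  lig <- parse_pdbqt_ligand(chain4_pdbqt())
  rec <- one_atom_receptor(c(0, 4, 0))
  eb <- score_pose(rec, lig, conformation(lig$root_center, torsions = 0))
  expect_equal(eb$torsion_penalty_divisor, 1 + 0.05846 * 1)
  expect_equal(eb$affinity,
               eb$intermolecular / (1 + 0.05846), tolerance = 1e-12)
})

test_that("cell-list scoring equals the O(N^2) oracle on random systems", {
  set.seed(99)
  p <- scoring_params()
  w <- unname(p$weights)
  tab <- ad4_type_table()
  types <- c("C", "N", "OA", "A", "S")
  for (rep in 1:5) {
    n <- 50
    rec_xyz <- matrix(runif(3 * n, -12, 12), n, 3)
    rec_t <- sample(types, n, replace = TRUE)
    ti <- match(rec_t, tab$type)
    rec_txt <- paste(vapply(1:n, function(i) sprintf(
      "ATOM  %5d  X%d  POC A   1    %8.3f%8.3f%8.3f  1.00  0.00     0.000 %-2s",
      i, i %% 10, rec_xyz[i, 1], rec_xyz[i, 2], rec_xyz[i, 3], rec_t[i]), ""),
      collapse = "\n")
    rec <- parse_pdbqt_receptor(rec_txt)
    lig <- parse_pdbqt_ligand(rigid3_pdbqt())
    conf <- random_conformation(0, -6, 6)

    eb_cell <- score_pose(rec, lig, conf, p, method = "celllist")
    eb_direct <- score_pose(rec, lig, conf, p, method = "direct")
    expect_equal(eb_cell$intermolecular, eb_direct$intermolecular,
                 tolerance = 1e-10)

    la <- lig$atoms
    coords <- apply_conformation(lig, conf)
    # parsed coordinates (PDBQT text carries 3 decimals)
    rxyz_parsed <- as.matrix(rec$atoms[, c("x", "y", "z")])
    e_oracle <- oracle_score(coords, la$radius, la$hydrophobic, la$donor,
                             la$acceptor, rxyz_parsed, tab$radius[ti],
                             tab$hydrophobic[ti], rep(FALSE, n),
                             tab$acceptor[ti], w, p$cutoff)
    expect_equal(eb_cell$intermolecular, e_oracle, tolerance = 1e-10)
  }
})

test_that("affinity is invariant under joint rigid motion of the system", {
  set.seed(7)
  tc <- make_toy_complex(20, 2, seed = 5, verify = FALSE)
  conf <- tc$crystal_conformation
  eb0 <- score_pose(tc$receptor, tc$ligand, conf)
  for (rep in 1:3) {
    m <- random_rigid_motion()
    rec2 <- tc$receptor
    rxyz <- apply_rigid(as.matrix(rec2$atoms[, c("x", "y", "z")]), m)
    rec2$atoms$x <- rxyz[, 1]; rec2$atoms$y <- rxyz[, 2]
    rec2$atoms$z <- rxyz[, 3]
    lig_coords <- apply_rigid(apply_conformation(tc$ligand, conf), m)
    eb2 <- score_pose(rec2, tc$ligand, lig_coords)
    expect_equal(eb2$affinity, eb0$affinity, tolerance = 1e-8)
    expect_equal(eb2$intramolecular, eb0$intramolecular, tolerance = 1e-8)
  }
})

test_that("analytic gradient matches central finite differences", {
  tc <- make_toy_complex(20, 3, seed = 8, verify = FALSE)
  f <- dock_objective(tc$receptor, tc$ligand)
  set.seed(31)
  h <- 1e-5
  for (rep in 1:4) {
    X <- c(tc$crystal_conformation$position + runif(3, -0.5, 0.5),
           quat_normalize(rnorm(4)), runif(3, -pi, pi))
    g <- f(X)$gradient
    fd <- vapply(seq_along(X), function(k) {
      Xp <- X; Xm <- X
      Xp[k] <- Xp[k] + h
      Xm[k] <- Xm[k] - h
      (f(Xp, want_gradient = FALSE)$value -
         f(Xm, want_gradient = FALSE)$value) / (2 * h)
    }, 0)
    expect_lt(max(abs(g - fd)), 1e-4)
  }
  # gradient is well defined for non-unit quaternions too
  X <- c(tc$crystal_conformation$position, 1.3 * quat_normalize(rnorm(4)),
         runif(3, -pi, pi))
  g <- f(X)$gradient
  fd <- vapply(seq_along(X), function(k) {
    Xp <- X; Xm <- X
    Xp[k] <- Xp[k] + h
    Xm[k] <- Xm[k] - h
    (f(Xp, want_gradient = FALSE)$value -
       f(Xm, want_gradient = FALSE)$value) / (2 * h)
  }, 0)
  expect_lt(max(abs(g - fd)), 1e-4)
})

test_that("an isolated rigid ligand has zero gradient", {
  lig <- parse_pdbqt_ligand(rigid3_pdbqt())
  rec <- one_atom_receptor(c(50, 50, 50))
  f <- dock_objective(rec, lig)
  g <- f(c(0, 0, 0, 1, 0, 0, 0))$gradient
  expect_equal(g, rep(0, 7))
})

test_that("translation gradient equals the sum of pairwise radial forces", {
  lig <- parse_pdbqt_ligand(rigid3_pdbqt())
  rec <- one_atom_receptor(c(0, 3.2, 0), type = "C")
  f <- dock_objective(rec, lig)
  X <- c(lig$root_center, 1, 0, 0, 0)
  g <- f(X)$gradient
  # independent per-pair differentiation: dE/dpos = sum_k (dE/dd) * u_k
  p <- scoring_params()
  w <- unname(p$weights)
  coords <- apply_conformation(lig, conformation(lig$root_center))
  gsum <- c(0, 0, 0)
  for (k in 1:3) {
    v <- coords[k, ] - c(0, 3.2, 0)
    r <- sqrt(sum(v^2))
    d <- r - lig$atoms$radius[k] - 1.9
    h <- 1e-7
    dEdd <- (oracle_pair_energy(d + h, lig$atoms$hydrophobic[k], FALSE, w) -
               oracle_pair_energy(d - h, lig$atoms$hydrophobic[k], FALSE, w)) /
      (2 * h)
    gsum <- gsum + dEdd * v / r
  }
  expect_equal(g[1:3], gsum, tolerance = 1e-6)
})

test_that("the objective is continuous in the conformation", {
  tc <- make_toy_complex(20, 2, seed = 9, verify = FALSE)
  f <- dock_objective(tc$receptor, tc$ligand)
  X <- c(tc$crystal_conformation$position, 1, 0, 0, 0, 0.2, -0.4)
  v0 <- f(X, want_gradient = FALSE)$value
  for (eps in c(1e-3, 1e-5, 1e-7)) {
    set.seed(1)
    dX <- runif(length(X), -eps, eps)
    v1 <- f(X + dX, want_gradient = FALSE)$value
    expect_lt(abs(v1 - v0), 1000 * eps + 1e-9)
  }
})

test_that("intramolecular pairs exclude near-bonded atoms and same bodies", {
  lig <- parse_pdbqt_ligand(nested_pdbqt())
  pairs <- ligand_interaction_pairs(lig)
  # atoms 1..6 in a chain: only pairs >= 4 bonds apart across bodies remain
  expect_true(all(pairs[, 2] - pairs[, 1] >= 4))
  expect_true(nrow(pairs) >= 1)
  lig0 <- parse_pdbqt_ligand(rigid3_pdbqt())
  expect_equal(nrow(ligand_interaction_pairs(lig0)), 0)
})
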