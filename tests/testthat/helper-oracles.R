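# Independent oracles used across the suite. These re-derive quantities from
# first principles (plain formulas, brute-force loops) and must stay
# independent of the package implementation paths they check.

# dihedral angle a-b-c-d in radians
dihedral <- function(a, b, c, d) {
  b1 <- b - a
  b2 <- c - b
  b3 <- d - c
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2], b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2], b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2], n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1]) / sqrt(sum(b2^2))
  atan2(sum(m1 * n2), sum(n1 * n2))
}

# brute-force Vina-style pair energy from the published functional forms
oracle_pair_energy <- function(d, both_hydrophobic, donor_acceptor, w) {
  e <- w[1] * exp(-(d / 0.5)^2) + w[2] * exp(-((d - 3) / 2)^2)
  if (d < 0) e <- e + w[3] * d^2
  if (both_hydrophobic) e <- e + w[4] * min(max(1.5 - d, 0), 1)
  if (donor_acceptor) e <- e + w[5] * min(max(-d / 0.7, 0), 1)
  e
}

# O(N^2) double-loop scorer over explicit atom property vectors
oracle_score <- function(lig_xyz, lig_rad, lig_hyd, lig_don, lig_acc,
                         rec_xyz, rec_rad, rec_hyd, rec_don, rec_acc,
                         w, cutoff) {
  total <- 0
  for (i in seq_len(nrow(lig_xyz))) {
    for (j in seq_len(nrow(rec_xyz))) {
      r <- sqrt(sum((lig_xyz[i, ] - rec_xyz[j, ])^2))
      if (r >= cutoff) next
      d <- r - lig_rad[i] - rec_rad[j]
      total <- total + oracle_pair_energy(
        d, lig_hyd[i] && rec_hyd[j],
        (lig_don[i] && rec_acc[j]) || (lig_acc[i] && rec_don[j]), w)
    }
  }
  total
}

# random rigid motion (rotation matrix + translation)
random_rigid_motion <- function() {
  q <- quat_normalize(rnorm(4))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
                2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
                2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
              3, 3, byrow = TRUE)
  list(R = R, t = rnorm(3, sd = 5))
}

apply_rigid <- function(xyz, motion) {
  sweep(xyz %*% t(motion$R), 2, -motion$t)
}

# a tiny hand-written flexible ligand: 4-atom chain with one rotatable bond
chain4_pdbqt <- function() {
  paste(c(
    "ROOT",
    "ATOM      1  C1  LIG A   1       0.000   0.000   0.000  1.00  0.00     0.000 C ",
    "ATOM      2  C2  LIG A   1       1.500   0.000   0.000  1.00  0.00     0.000 C ",
    "ENDROOT",
    "BRANCH   2   3",
    "ATOM      3  C3  LIG A   1       2.100   1.400   0.000  1.00  0.00     0.000 C ",
    "ATOM      4  O4  LIG A   1       3.600   1.500   0.000  1.00  0.00     0.000 OA",
    "ENDBRANCH   2   3",
    "TORSDOF 1"), collapse = "\n")
}

# rigid 3-atom ligand
rigid3_pdbqt <- function() {
  paste(c(
    "ROOT",
    "ATOM      1  C1  LIG A   1       0.000   0.000   0.000  1.00  0.00     0.000 C ",
    "ATOM      2  O2  LIG A   1       1.400   0.000   0.000  1.00  0.00     0.000 OA",
    "ATOM      3  N3  LIG A   1      -0.700   1.200   0.000  1.00  0.00     0.000 N ",
    "ENDROOT",
    "TORSDOF 0"), collapse = "\n")
}

# nested two-branch ligand (branch 2 inside branch 1)
nested_pdbqt <- function() {
  paste(c(
    "ROOT",
    "ATOM      1  C1  LIG A   1       0.000   0.000   0.000  1.00  0.00     0.000 C ",
    "ATOM      2  C2  LIG A   1       1.500   0.000   0.000  1.00  0.00     0.000 C ",
    "ENDROOT",
    "BRANCH   2   3",
    "ATOM      3  C3  LIG A   1       2.100   1.400   0.000  1.00  0.00     0.000 C ",
    "ATOM      4  C4  LIG A   1       3.600   1.500   0.000  1.00  0.00     0.000 C ",
    "BRANCH   4   5",
    "ATOM      5  C5  LIG A   1       4.200   2.800   0.300  1.00  0.00     0.000 C ",
    "ATOM      6  O6  LIG A   1       5.600   3.000   0.500  1.00  0.00     0.000 OA",
    "ENDBRANCH   4   5",
    "ENDBRANCH   2   3",
    "TORSDOF 2"), collapse = "\n")
}

# single-atom receptor at a given position
one_atom_receptor <- function(xyz, type = "C") {
  parse_pdbqt_receptor(sprintf(
    "ATOM      1  X1  POC A   1    %8.3f%8.3f%8.3f  1.00  0.00     0.000 %-2s",
    xyz[1], xyz[2], xyz[3], type))
}

random_conformation <- function(n_torsions, lower = -3, upper = 3) {
  conformation(runif(3, lower, upper), quat_normalize(rnorm(4)),
               if (n_torsions > 0) runif(n_torsions, -pi, pi) else numeric(0))
}
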