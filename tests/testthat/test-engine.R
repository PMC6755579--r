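test_that("pocket box matches per-axis min/max and pads flat pockets", {
  cube <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
  b <- box_from_pocket(cube)
  expect_equal(b$center, c(0.5, 0.5, 0.5))
  expect_equal(b$lengths, c(1, 1, 1))
  # two collinear atoms: degenerate axes padded with a warning
  expect_warning(b2 <- box_from_pocket(rbind(c(0, 0, 0), c(4, 0, 0))),
                 "degenerate")
  expect_equal(b2$center, c(2, 0, 0))
  expect_equal(b2$lengths, c(4, 1, 1))
  expect_error(box_from_pocket(matrix(0, 1, 3)), "at least 2")
  # random cloud equals the brute-force min/max
  set.seed(8)
  cloud <- matrix(rnorm(60, sd = 4), 20, 3)
  b3 <- box_from_pocket(cloud)
  expect_equal(b3$center, colMeans(cloud))
  expect_equal(b3$lengths, apply(cloud, 2, max) - apply(cloud, 2, min))
})

test_that("ligand box is a cube at the geometric center", {
  lig <- parse_pdbqt_ligand(rigid3_pdbqt())
  b <- box_from_ligand(lig)
  expect_equal(b$lengths, rep(22.5, 3))
  expect_equal(b$center,
               unname(colMeans(as.matrix(lig$atoms[, c("x", "y", "z")]))))
  b10 <- box_from_ligand(lig, edge = 10)
  expect_equal(b10$lengths, rep(10, 3))
  # single atom at the origin
  one <- parse_pdbqt_ligand(paste(c(
    "ROOT",
    "ATOM      1  C1  LIG A   1       0.000   0.000   0.000  1.00  0.00     0.000 C ",
    "ENDROOT", "TORSDOF 0"), collapse = "\n"))
  b1 <- box_from_ligand(one)
  expect_equal(b1$center, c(0, 0, 0))
  expect_error(search_box(c(0, 0, 0), c(1, -1, 1)), "positive")
})

test_that("docking returns ranked, de-duplicated, in-box poses deterministically", {
  tc <- make_toy_complex(24, 1, seed = 6)
  cfg <- swarm_config(seed = 42, max_generations = 80)
  res <- dock(tc$receptor, tc$ligand, tc$box, cfg, n_runs = 4)
  expect_s3_class(res, "dock_result")
  expect_gte(length(res$poses), 1)
  aff <- vapply(res$poses, `[[`, 0, "affinity")
  expect_true(all(diff(aff) >= 0))
  # pose coordinates equal the conformation mapping, root center in the box
  bb <- list(lower = tc$box$center - tc$box$lengths / 2,
             upper = tc$box$center + tc$box$lengths / 2)
  for (p in res$poses) {
    expect_equal(p$coordinates,
                 apply_conformation(tc$ligand, p$conformation))
    expect_true(all(p$conformation$position >= bb$lower - 1e-9) &&
                  all(p$conformation$position <= bb$upper + 1e-9))
  }
  # pairwise heavy-atom RMSD between reported modes >= dedup threshold
  h <- tc$ligand$atoms$heavy
  if (length(res$poses) > 1) {
    for (i in 1:(length(res$poses) - 1))
      for (j in (i + 1):length(res$poses))
        expect_gte(rmsd(res$poses[[i]]$coordinates[h, ],
                        res$poses[[j]]$coordinates[h, ]), 1.0)
  }
  # byte-identical repetition under the same master seed
  res2 <- dock(tc$receptor, tc$ligand, tc$box, cfg, n_runs = 4)
  expect_identical(vapply(res$poses, `[[`, 0, "affinity"),
                   vapply(res2$poses, `[[`, 0, "affinity"))
  expect_identical(res$poses[[1]]$coordinates, res2$poses[[1]]$coordinates)
})

test_that("best-of-runs pose equals the run minimum; single run works", {
  tc <- make_toy_complex(24, 0, seed = 12)
  res <- dock(tc$receptor, tc$ligand, tc$box,
              swarm_config(seed = 3, max_generations = 60), n_runs = 1)
  expect_gte(length(res$poses), 1)
  expect_equal(res$poses[[1]]$run_index, 1)
})

test_that("pose PDBQT output round-trips and carries affinity remarks", {
  tc <- make_toy_complex(24, 1, seed = 6)
  res <- dock(tc$receptor, tc$ligand, tc$box,
              swarm_config(seed = 42, max_generations = 50), n_runs = 2)
  tmp <- tempfile(fileext = ".pdbqt")
  write_poses_pdbqt(res, tmp)
  lines <- readLines(tmp)
  expect_equal(sum(grepl("^MODEL", lines)), length(res$poses))
  expect_true(any(grepl("REMARK VINA RESULT", lines)))
  # the first model parses back to the best pose's coordinates
  block <- lines[(which(lines == "MODEL 1") + 1):(which(lines == "ENDMDL")[1] - 1)]
  relig <- parse_pdbqt_ligand(block)
  expect_equal(as.matrix(relig$atoms[, c("x", "y", "z")]),
               res$poses[[1]]$coordinates, tolerance = 1e-3,
               ignore_attr = TRUE)
})

test_that("the CLI docks, reports errors, and exits accordingly", {
  tc <- make_toy_complex(24, 0, seed = 2)
  rec_f <- tempfile(fileext = ".pdbqt")
  lig_f <- tempfile(fileext = ".pdbqt")
  writeLines(tc$receptor_pdbqt, rec_f)
  writeLines(tc$ligand_pdbqt, lig_f)
  out <- tempfile()
  code <- chaosdock_cli(c("dock", "--receptor", rec_f, "--ligand", lig_f,
                          "--center",
                          paste(round(tc$box$center, 3), collapse = ","),
                          "--size",
                          paste(round(tc$box$lengths, 3), collapse = ","),
                          "--chaos", "singer", "--runs", "2", "--seed", "1",
                          "--out", out))
  expect_equal(code, 0L)
  expect_true(file.exists(paste0(out, "_poses.pdbqt")))
  summ <- jsonlite::read_json(paste0(out, "_summary.json"))
  expect_equal(summ$chaos, "singer")
  expect_true(length(summ$poses) >= 1)
  # missing file -> exit 2
  expect_message(
    code2 <- chaosdock_cli(c("dock", "--receptor", "nope.pdbqt",
                             "--ligand", lig_f, "--center", "0,0,0")),
    "no such file")
  expect_equal(code2, 2L)
  expect_message(code3 <- chaosdock_cli(character(0)), "usage")
  expect_equal(code3, 2L)
  # maps subcommand writes a diagnostics table
  mf <- tempfile(fileext = ".csv")
  expect_equal(chaosdock_cli(c("maps", "--map", "tent", "--n", "100",
                               "--seed", "3", "--out", mf)), 0L)
  d <- read.csv(mf)
  expect_equal(nrow(d), 100)
  expect_true(all(d$value > 0 & d$value < 1))
  # evaluate subcommand computes metrics from a table
  tf <- tempfile(fileext = ".csv")
  write.csv(data.frame(ligand_id = letters[1:6], affinity = 1:6,
                       label = c(rep("active", 3), rep("decoy", 3))),
            tf, row.names = FALSE)
  of <- tempfile(fileext = ".json")
  expect_equal(chaosdock_cli(c("evaluate", "--table", tf, "--out", of)), 0L)
  m <- jsonlite::read_json(of)
  expect_equal(m$auc, 1)
})
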