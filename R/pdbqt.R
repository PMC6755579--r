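#' AutoDock atom-type property table
#'
#' AD4 atom types with the van der Waals radii and interaction classes used
#' by the empirical scoring function. Hydrophobic types are carbons and
#' halogens; hydrogen-bond acceptors are the AD4 acceptor types. Donor heavy
#' atoms are not a type property: they are flagged per atom when a polar
#' hydrogen (`HD`) sits within covalent range (see [parse_pdbqt_ligand()]).
#'
#' @return A data.frame with columns `type`, `radius` (Angstrom),
#'   `hydrophobic`, `acceptor`, `heavy`.
#' @export
ad4_type_table <- function() {
  tab <- data.frame(
    type = c("H", "HD", "HS",
             "C", "A", "N", "NA", "NS", "OA", "OS", "S", "SA", "P",
             "F", "Cl", "Br", "I",
             "Mg", "Mn", "Zn", "Ca", "Fe"),
    radius = c(1.0, 1.0, 1.0,
               1.9, 1.9, 1.8, 1.8, 1.8, 1.7, 1.7, 2.0, 2.0, 2.1,
               1.5, 1.8, 2.0, 2.2,
               1.2, 1.2, 1.2, 1.2, 1.2),
    stringsAsFactors = FALSE
  )
  tab$hydrophobic <- tab$type %in% c("C", "A", "F", "Cl", "Br", "I")
  tab$acceptor <- tab$type %in% c("NA", "NS", "OA", "OS", "SA")
  tab$heavy <- !(tab$type %in% c("H", "HD", "HS"))
  tab
}

pdbqt_lines <- function(x) {
  if (length(x) == 1 && (grepl("\n", x) || file.exists(x))) {
    if (file.exists(x)) return(readLines(x, warn = FALSE))
    return(strsplit(x, "\n", fixed = TRUE)[[1]])
  }
  x
}

parse_atom_line <- function(line, lineno) {
  n <- nchar(line)
  serial <- suppressWarnings(as.integer(substr(line, 7, 11)))
  name <- trimws(substr(line, 13, 16))
  xyz <- suppressWarnings(as.numeric(c(substr(line, 31, 38),
                                       substr(line, 39, 46),
                                       substr(line, 47, 54))))
  if (anyNA(xyz) || any(!is.finite(xyz)))
    stop("malformed coordinates on PDBQT line ", lineno)
  # prepared files vary beyond column 54: take charge and AD4 type as the
  # last two whitespace-separated tokens
  toks <- strsplit(trimws(substr(line, 55, n)), "\\s+")[[1]]
  if (length(toks) < 2)
    stop("missing charge/type fields on PDBQT line ", lineno)
  type <- toks[length(toks)]
  charge <- suppressWarnings(as.numeric(toks[length(toks) - 1]))
  if (is.na(charge)) charge <- 0
  list(serial = serial, name = name, x = xyz[1], y = xyz[2], z = xyz[3],
       charge = charge, type = type)
}

finish_atoms <- function(recs) {
  tab <- ad4_type_table()
  types <- vapply(recs, `[[`, "", "type")
  unknown <- setdiff(unique(types), tab$type)
  if (length(unknown))
    stop("unknown AD4 atom type(s): ", paste(unknown, collapse = ", "))
  ti <- match(types, tab$type)
  atoms <- data.frame(
    serial = vapply(recs, `[[`, 1L, "serial"),
    name = vapply(recs, `[[`, "", "name"),
    type = types,
    x = vapply(recs, `[[`, 0, "x"),
    y = vapply(recs, `[[`, 0, "y"),
    z = vapply(recs, `[[`, 0, "z"),
    charge = vapply(recs, `[[`, 0, "charge"),
    radius = tab$radius[ti],
    hydrophobic = tab$hydrophobic[ti],
    acceptor = tab$acceptor[ti],
    heavy = tab$heavy[ti],
    stringsAsFactors = FALSE
  )
  # donor heavy atoms: N/O/S with a polar hydrogen within covalent range
  atoms$donor <- FALSE
  hd <- which(atoms$type == "HD")
  if (length(hd)) {
    xyz <- as.matrix(atoms[, c("x", "y", "z")])
    for (h in hd) {
      d2 <- colSums((t(xyz) - xyz[h, ])^2)
      cand <- which(atoms$heavy & d2 < 1.3^2)
      if (length(cand)) {
        atoms$donor[cand[which.min(d2[cand])]] <- TRUE
      }
    }
  }
  atoms
}

#' Parse a PDBQT ligand
#'
#' Reads a prepared AutoDock PDBQT ligand (`ROOT`/`BRANCH` torsion tree,
#' AD4 atom types, partial charges) into a `ligand_model`: the atom table
#' with reference (file) coordinates, the torsion tree, and the line skeleton
#' needed to write poses back out in the same dialect. Both `ATOM` and
#' `HETATM` records are accepted; `REMARK`/`TER`/`TORSDOF` lines are ignored
#' for geometry but the skeleton preserves the record order.
#'
#' @param x Path to a PDBQT file, a single string containing PDBQT text, or
#'   a character vector of lines.
#' @return An object of class `ligand_model` with elements `atoms`
#'   (data.frame), `tree` (list of branches, each with `parent`, `child`,
#'   `moved` atom indices in file order), `n_torsions`, `root_atoms`,
#'   `root_center`, and `skeleton`.
#' @export
parse_pdbqt_ligand <- function(x) {
  lines <- pdbqt_lines(x)
  recs <- list()
  skeleton <- list()
  branches <- list()
  stack <- integer(0)       # open branch indices
  root_atoms <- integer(0)
  in_root <- FALSE
  seen_root <- FALSE

  for (i in seq_along(lines)) {
    line <- lines[i]
    key <- trimws(substr(line, 1, 9))
    if (startsWith(key, "ROOT") && !startsWith(key, "ROOTS")) {
      in_root <- TRUE; seen_root <- TRUE
      skeleton[[length(skeleton) + 1]] <- list(kind = "ROOT")
    } else if (startsWith(key, "ENDROOT")) {
      in_root <- FALSE
      skeleton[[length(skeleton) + 1]] <- list(kind = "ENDROOT")
    } else if (startsWith(key, "BRANCH")) {
      toks <- strsplit(trimws(line), "\\s+")[[1]]
      if (length(toks) < 3)
        stop("malformed BRANCH record on line ", i)
      branches[[length(branches) + 1]] <-
        list(parent_serial = as.integer(toks[2]),
             child_serial = as.integer(toks[3]),
             moved = integer(0))
      stack <- c(stack, length(branches))
      skeleton[[length(skeleton) + 1]] <-
        list(kind = "BRANCH", branch = length(branches))
    } else if (startsWith(key, "ENDBRANCH")) {
      if (!length(stack))
        stop("unbalanced ENDBRANCH on line ", i)
      skeleton[[length(skeleton) + 1]] <-
        list(kind = "ENDBRANCH", branch = stack[length(stack)])
      stack <- stack[-length(stack)]
    } else if (startsWith(key, "ATOM") || startsWith(key, "HETATM")) {
      recs[[length(recs) + 1]] <- parse_atom_line(line, i)
      idx <- length(recs)
      if (in_root) root_atoms <- c(root_atoms, idx)
      for (b in stack) branches[[b]]$moved <- c(branches[[b]]$moved, idx)
      skeleton[[length(skeleton) + 1]] <- list(kind = "ATOM", atom = idx)
    } else if (startsWith(key, "TORSDOF")) {
      skeleton[[length(skeleton) + 1]] <- list(kind = "TORSDOF")
    }
    # REMARK, TER, MODEL etc.: ignored
  }
  if (length(stack))
    stop("unbalanced BRANCH: ", length(stack), " branch(es) never closed")
  if (!seen_root)
    stop("no ROOT record found; not a ligand PDBQT")
  if (!length(recs))
    stop("no atoms found in PDBQT input")

  atoms <- finish_atoms(recs)
  serial_of <- atoms$serial
  tree <- lapply(branches, function(b) {
    parent <- match(b$parent_serial, serial_of)
    child <- match(b$child_serial, serial_of)
    if (is.na(parent) || is.na(child))
      stop("BRANCH references unknown atom serial ",
           b$parent_serial, " or ", b$child_serial)
    list(parent = parent, child = child, moved = b$moved)
  })
  if (sum(atoms$heavy) < 1) stop("ligand has no heavy atoms")

  lig <- list(
    atoms = atoms,
    tree = list(branches = tree),
    n_torsions = length(tree),
    root_atoms = root_atoms,
    root_center = colMeans(atoms[root_atoms, c("x", "y", "z"), drop = FALSE]),
    skeleton = skeleton
  )
  class(lig) <- "ligand_model"
  lig
}

#' @export
print.ligand_model <- function(x, ...) {
  cat("<ligand_model> ", nrow(x$atoms), " atoms (",
      sum(x$atoms$heavy), " heavy), ", x$n_torsions,
      " rotatable bond(s), D = ", 7 + x$n_torsions, "\n", sep = "")
  invisible(x)
}

#' Parse a PDBQT receptor
#'
#' Flat atom list (no torsion tree); `ROOT`/`BRANCH` records, if present,
#' are ignored.
#'
#' @param x Path, PDBQT text, or lines, as in [parse_pdbqt_ligand()].
#' @return An object of class `receptor_model` with an `atoms` data.frame.
#' @export
parse_pdbqt_receptor <- function(x) {
  lines <- pdbqt_lines(x)
  recs <- list()
  for (i in seq_along(lines)) {
    key <- substr(lines[i], 1, 6)
    if (startsWith(key, "ATOM") || startsWith(key, "HETATM"))
      recs[[length(recs) + 1]] <- parse_atom_line(lines[i], i)
  }
  if (!length(recs)) stop("no atoms found in receptor PDBQT")
  rec <- list(atoms = finish_atoms(recs))
  class(rec) <- "receptor_model"
  rec
}

#' @export
print.receptor_model <- function(x, ...) {
  cat("<receptor_model> ", nrow(x$atoms), " atoms (",
      sum(x$atoms$heavy), " heavy)\n", sep = "")
  invisible(x)
}

format_atom_line <- function(atom, xyz) {
  sprintf("ATOM  %5d %-4s LIG A   1    %8.3f%8.3f%8.3f%6.2f%6.2f    %6.3f %-2s",
          atom$serial, atom$name, xyz[1], xyz[2], xyz[3], 1.00, 0.00,
          atom$charge, atom$type)
}

#' Write a ligand (or one pose of it) as PDBQT text
#'
#' Reproduces the parsed `ROOT`/`BRANCH` skeleton with the given
#' coordinates, so parse -> write -> parse round-trips the atom table and
#' torsion tree.
#'
#' @param ligand A `ligand_model`.
#' @param coords Optional N x 3 coordinate matrix (defaults to the reference
#'   coordinates).
#' @param file Optional path; if `NULL` the lines are returned invisibly.
#' @return Character vector of PDBQT lines, invisibly.
#' @export
write_pdbqt_ligand <- function(ligand, coords = NULL, file = NULL) {
  if (is.null(coords))
    coords <- as.matrix(ligand$atoms[, c("x", "y", "z")])
  out <- character(0)
  for (tok in ligand$skeleton) {
    out <- c(out, switch(tok$kind,
      ROOT = "ROOT",
      ENDROOT = "ENDROOT",
      BRANCH = {
        b <- ligand$tree$branches[[tok$branch]]
        sprintf("BRANCH %3d %3d", ligand$atoms$serial[b$parent],
                ligand$atoms$serial[b$child])
      },
      ENDBRANCH = {
        b <- ligand$tree$branches[[tok$branch]]
        sprintf("ENDBRANCH %3d %3d", ligand$atoms$serial[b$parent],
                ligand$atoms$serial[b$child])
      },
      ATOM = format_atom_line(ligand$atoms[tok$atom, ], coords[tok$atom, ]),
      TORSDOF = sprintf("TORSDOF %d", ligand$n_torsions)
    ))
  }
  if (!any(vapply(ligand$skeleton, `[[`, "", "kind") == "TORSDOF"))
    out <- c(out, sprintf("TORSDOF %d", ligand$n_torsions))
  if (!is.null(file)) writeLines(out, file)
  invisible(out)
}

#' Write ranked docking poses as a multi-model PDBQT
#'
#' One `MODEL` per pose with a `REMARK VINA RESULT` affinity line, the
#' format downstream pose viewers expect.
#'
#' @param result A `dock_result` from [dock()].
#' @param file Output path.
#' @return The path, invisibly.
#' @export
write_poses_pdbqt <- function(result, file) {
  stopifnot(inherits(result, "dock_result"))
  out <- character(0)
  for (i in seq_along(result$poses)) {
    p <- result$poses[[i]]
    out <- c(out,
             sprintf("MODEL %d", i),
             sprintf("REMARK VINA RESULT: %10.3f %10.3f %10.3f",
                     p$affinity, 0, 0),
             write_pdbqt_ligand(result$ligand, p$coordinates),
             "ENDMDL")
  }
  writeLines(out, file)
  invisible(file)
}
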