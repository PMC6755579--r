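#' Ranked virtual-screening table
#'
#' Rows of (ligand id, predicted affinity, active/decoy label) kept sorted
#' ascending by affinity (best binder first), with ties broken by ligand id
#' for determinism.
#'
#' @param ligand_id Character vector of unique ids.
#' @param affinity Numeric affinities in kcal/mol (lower is better).
#' @param label `"active"` or `"decoy"` per ligand.
#' @return A data.frame of class `screening_table`.
#' @export
screening_table <- function(ligand_id, affinity, label) {
  ligand_id <- as.character(ligand_id)
  label <- as.character(label)
  stopifnot(length(ligand_id) == length(affinity),
            length(label) == length(affinity))
  if (anyDuplicated(ligand_id)) stop("ligand ids must be unique")
  if (!all(label %in% c("active", "decoy")))
    stop("labels must be 'active' or 'decoy'")
  out <- data.frame(ligand_id = ligand_id, affinity = as.double(affinity),
                    label = label, stringsAsFactors = FALSE)
  out <- out[order(out$affinity, out$ligand_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("screening_table", "data.frame")
  out
}

#' Pose-prediction success rate
#'
#' Percentage of complexes whose best pose lies within 2 Angstrom of the
#' crystal pose.
#'
#' @param rmsds Non-negative best-pose RMSDs, one per complex.
#' @return Percentage in `[0, 100]`.
#' @export
success_rate <- function(rmsds) {
  stopifnot(length(rmsds) > 0, all(rmsds >= 0))
  100 * mean(is_success(rmsds))
}

#' Enrichment factor at the top x percent of a ranked screen
#'
#' `EF_x% = (actives in top bin / total actives) / (bin size / n)`, with
#' the top bin holding `floor(x% * n)` ligands (minimum 1). Equals 1 for a
#' ranking no better than random and `n / n_actives` at best.
#'
#' @param table A [screening_table()].
#' @param x_percent Top fraction in percent, in `(0, 100]`.
#' @return The enrichment factor.
#' @export
enrichment_factor <- function(table, x_percent) {
  stopifnot(inherits(table, "screening_table"), nrow(table) > 0,
            x_percent > 0, x_percent <= 100)
  n <- nrow(table)
  n_act <- sum(table$label == "active")
  if (n_act == 0) stop("no actives in the screening table")
  n_top <- max(1L, as.integer(floor(x_percent / 100 * n)))
  act_top <- sum(table$label[seq_len(n_top)] == "active")
  (act_top / n_act) / (n_top / n)
}

#' Area under the ROC curve of a ranked screen
#'
#' The probability that a randomly chosen active is ranked better (lower
#' affinity) than a randomly chosen decoy, with ties counted one half --
#' the rank-sum (Mann-Whitney) formulation, equivalent to the trapezoidal
#' area under the full-resolution ROC curve.
#'
#' @param table A [screening_table()].
#' @return AUC in `[0, 1]`; 1 is perfect separation, 0.5 random.
#' @export
auc_roc <- function(table) {
  stopifnot(inherits(table, "screening_table"))
  act <- table$label == "active"
  n_act <- sum(act)
  n_dec <- sum(!act)
  if (n_act == 0 || n_dec == 0)
    stop("both actives and decoys are required for AUC")
  # rank by classifier score = -affinity (higher is more active-like)
  r <- rank(-table$affinity, ties.method = "average")
  (sum(r[act]) - n_act * (n_act + 1) / 2) / (n_act * n_dec)
}

#' ROC curve points of a ranked screen
#'
#' @param table A [screening_table()].
#' @return A data.frame with columns `fpr`, `tpr` traced over the ranking.
#' @export
roc_points <- function(table) {
  stopifnot(inherits(table, "screening_table"))
  act <- table$label == "active"
  data.frame(fpr = c(0, cumsum(!act) / sum(!act)),
             tpr = c(0, cumsum(act) / sum(act)))
}

#' Virtual screening of a ligand set
#'
#' Docks every ligand once (`n_runs = 1`, the screening protocol) against
#' the receptor and returns the ranked [screening_table()] of best
#' affinities. Ligands that fail to parse or dock are recorded in the
#' `failures` attribute rather than aborting the screen.
#'
#' @param receptor A `receptor_model` or path.
#' @param ligand_set Named list of `ligand_model`s / PDBQT paths, or a
#'   directory containing `*.pdbqt` files.
#' @param box A [search_box()].
#' @param cfg A [swarm_config()]; screening defaults to 16 particles.
#' @param labels Optional data.frame `(ligand_id, label)`; unlabeled
#'   ligands are marked `"decoy"`.
#' @param params [scoring_params()].
#' @return A [screening_table()] with attribute `failures` (character
#'   vector of failed ligand ids, possibly empty).
#' @export
screen <- function(receptor, ligand_set, box,
                   cfg = swarm_config(n_particles = 16), labels = NULL,
                   params = scoring_params()) {
  if (is.character(receptor)) receptor <- parse_pdbqt_receptor(receptor)
  if (is.character(ligand_set) && length(ligand_set) == 1 &&
      dir.exists(ligand_set)) {
    paths <- sort(list.files(ligand_set, pattern = "\\.pdbqt$",
                             full.names = TRUE))
    ligand_set <- setNames(as.list(paths),
                           sub("\\.pdbqt$", "", basename(paths)))
  }
  if (is.null(names(ligand_set)) || any(names(ligand_set) == ""))
    stop("ligand_set must be named (ids are taken from the names)")

  ids <- names(ligand_set)
  affinity <- setNames(rep(NA_real_, length(ids)), ids)
  failures <- character(0)
  for (id in ids) {
    res <- tryCatch({
      lig <- ligand_set[[id]]
      if (is.character(lig)) lig <- parse_pdbqt_ligand(lig)
      cfg_l <- cfg
      cfg_l$seed <- split_seed(cfg$seed, 50000L + match(id, ids))
      d <- dock(receptor, lig, box, cfg_l, n_runs = 1, params = params)
      d$poses[[1]]$affinity
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures, id)
    } else {
      affinity[id] <- res
    }
  }

  ok <- !is.na(affinity)
  lab <- rep("decoy", sum(ok))
  if (!is.null(labels)) {
    m <- match(ids[ok], as.character(labels$ligand_id))
    lab[!is.na(m)] <- as.character(labels$label)[m[!is.na(m)]]
  }
  out <- screening_table(ids[ok], affinity[ok], lab)
  attr(out, "failures") <- failures
  out
}
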