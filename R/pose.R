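## Docking-pose ingestion and fixed-pose pharmacophore re-matching. The
## docking engine itself sits outside the computation boundary: poses enter
## as SDF records carrying a score property (lower = better by default), are
## grouped per molecule, sorted and truncated to the best `cap`, and are then
## re-matched against the partial-agonist pharmacophore with no
## re-orientation. A deterministic stub docker stands in for the engine in
## tests and synthetic benchmarks.

#' Construct a pose set
#'
#' @param mol_id Molecule id.
#' @param poses List of [vs_conformer()] with `pose_score` set.
#' @param cap Retain at most this many best (lowest-score) poses
#'   (default 32).
#' @return Object of class `pose_set`; poses sorted ascending by score,
#'   ties keeping their original order.
#' @export
pose_set <- function(mol_id, poses, cap = 32) {
  stopifnot(is_count(cap), cap >= 1)
  for (p in poses) {
    stopifnot(inherits(p, "vs_conformer"))
    if (is.null(p$pose_score)) stopf("pose of %s lacks a pose_score", mol_id)
  }
  scores <- vapply(poses, `[[`, numeric(1), "pose_score")
  poses <- poses[order(scores)]          # stable: ties keep input order
  poses <- head(poses, cap)
  structure(list(mol_id = as.character(mol_id), poses = poses,
                 cap = as.integer(cap)), class = "pose_set")
}

#' @export
print.pose_set <- function(x, ...) {
  cat(sprintf("pose set %s: %d poses (cap %d)\n", x$mol_id, length(x$poses), x$cap))
  invisible(x)
}

#' Load docking poses from an SDF file
#'
#' Records are grouped by molecule id (the SDF title line), sorted by the
#' named score property and truncated to the best `cap` poses per molecule.
#'
#' @param path SDF path.
#' @param score_property Data-block field holding the docking score.
#' @param cap Maximum poses kept per molecule (default 32).
#' @param lower_is_better Score direction (default TRUE).
#' @return Named list of [pose_set()] in first-seen molecule order.
#' @export
load_poses <- function(path, score_property = "pose_score", cap = 32,
                       lower_is_better = TRUE) {
  if (!file.exists(path)) stopf("cannot read poses: %s", path)
  sdfset <- suppressWarnings(ChemmineR::read.SDFset(path, skipErrors = TRUE))
  groups <- list()
  for (i in seq_along(sdfset)) {
    sdf <- sdfset[[i]]
    hdr <- ChemmineR::header(sdf)
    id <- hdr[["Molecule_Name"]]
    if (is.null(id) || !nzchar(id)) id <- sprintf("pose_mol_%d", i)
    db <- ChemmineR::datablock(sdf)
    if (is.null(db) || !(score_property %in% names(db))) {
      stopf("pose record %d (%s) lacks score property '%s'", i, id, score_property)
    }
    score <- as.numeric(db[[score_property]])
    if (is.na(score)) stopf("pose record %d: non-numeric score", i)
    ab <- ChemmineR::atomblock(sdf)
    charges <- NULL
    if ("partial_charges" %in% names(db)) {
      charges <- as.numeric(strsplit(db[["partial_charges"]], " ")[[1]])
    }
    conf <- vs_conformer(id, unname(ab[, 1:3, drop = FALSE]),
                         sub("_.*$", "", rownames(ab)),
                         index = length(groups[[id]]) %||% 0L,
                         charges = charges,
                         pose_score = if (lower_is_better) score else -score)
    groups[[id]] <- c(groups[[id]], list(conf))
  }
  out <- lapply(names(groups), function(id) pose_set(id, groups[[id]], cap = cap))
  names(out) <- names(groups)
  out
}

#' Feature perception for synthetic feature clouds
#'
#' The synthetic-benchmark convention: every O or N atom carries an acceptor
#' feature and every carbon a hydrophobic feature, each at the atom position.
#' Used as the default feature provider when re-matching cloud poses.
#'
#' @param conf A [vs_conformer()].
#' @return List of [feature_point()]s.
#' @export
cloud_features <- function(conf) {
  elem <- toupper(conf$elem)
  feats <- list()
  for (i in seq_along(elem)) {
    kind <- if (elem[i] %in% c("O", "N")) "acceptor"
            else if (elem[i] == "C") "hydrophobic"
            else next
    feats[[length(feats) + 1]] <- feature_point(kind, conf$coords[i, ], i)
  }
  feats
}

#' Re-match docking poses against the partial-agonist pharmacophore
#'
#' A molecule survives when at least one of its poses matches ALL model
#' sites in fixed-pose mode (identity transform; no re-orientation) without
#' penetrating the excluded volumes. The surviving pose with minimal rms is
#' recorded per molecule.
#'
#' @param pose_sets Named list of [pose_set()].
#' @param model Include-mode [pharmacophore_model()].
#' @param feature_provider Function mapping a pose conformer to its feature
#'   points; default [cloud_features()] (synthetic benchmarks). For real
#'   molecules supply a closure around [perceive_features()].
#' @return List with `survivors` (ids), `matches` (best `match_result` per
#'   survivor), `poses` (best matching pose per survivor) and `dropped`
#'   (data.frame id / reason, e.g. empty pose sets).
#' @export
rematch_poses <- function(pose_sets, model, feature_provider = cloud_features) {
  stopifnot(inherits(model, "pharmacophore_model"))
  if (model$mode != "include") {
    stopf("rematch_poses requires an include-mode model, got '%s'", model$mode)
  }
  survivors <- character(); matches <- list(); best_poses <- list()
  dropped <- list()
  for (id in names(pose_sets)) {
    ps <- pose_sets[[id]]
    if (length(ps$poses) == 0) {
      dropped[[length(dropped) + 1]] <- data.frame(id = id, reason = "empty pose set")
      vs_log("rematch_poses: ", id, " dropped (empty pose set)", level = "warn")
      next
    }
    best <- NULL; best_pose <- NULL
    for (p in ps$poses) {
      m <- match_conformer(p, feature_provider(p), model, reorient = FALSE)
      if (m$matched && (is.null(best) || m$rms < best$rms)) {
        best <- m; best_pose <- p
      }
    }
    if (!is.null(best)) {
      survivors <- c(survivors, id)
      matches[[id]] <- best
      best_poses[[id]] <- best_pose
    }
  }
  list(survivors = survivors, matches = matches, poses = best_poses,
       dropped = if (length(dropped)) do.call(rbind, dropped) else
         data.frame(id = character(), reason = character()))
}

#' Deterministic stub docker (test double for an external docking engine)
#'
#' For molecules whose entry is flagged docking-compatible
#' (`dockable = TRUE`) it emits one on-pharmacophore pose — the molecule's
#' best free-orientation match transformed into the model frame — among
#' randomly placed decoy poses; all other molecules receive random poses
#' only. Scores are drawn so the on-pharmacophore pose is not trivially the
#' best-scored one. Fully deterministic given `seed`.
#'
#' @param entries Named list of [screen_entry()].
#' @param model Include-mode [pharmacophore_model()].
#' @param seed Integer seed.
#' @param n_decoy_poses Random poses added per molecule (default 5).
#' @param cap Pose cap (default 32).
#' @return Named list of [pose_set()].
#' @export
stub_docker <- function(entries, model, seed = 1, n_decoy_poses = 5, cap = 32) {
  stopifnot(inherits(model, "pharmacophore_model"))
  with_seed(seed, {
    out <- list()
    for (e in entries) {
      poses <- list()
      idx <- 0L
      if (isTRUE(e$dockable)) {
        best <- NULL
        for (i in seq_along(e$conformers)) {
          m <- match_conformer(e$conformers[[i]], e$features[[i]], model,
                               reorient = TRUE)
          if (m$matched && (is.null(best) || m$rms < best$rms)) {
            best <- list(m = m, i = i)
          }
        }
        if (!is.null(best)) {
          cf <- e$conformers[[best$i]]
          placed <- vs_conformer(
            e$id,
            apply_rigid(cf$coords, best$m$transform$rotation,
                        best$m$transform$translation),
            cf$elem, index = idx, charges = cf$charges,
            pose_score = round(runif(1, 1, 5), 3))
          poses <- c(poses, list(placed)); idx <- idx + 1L
        }
      }
      for (k in seq_len(n_decoy_poses)) {
        cf <- e$conformers[[1]]
        rot <- random_rotation()
        shift <- runif(3, -8, 8)
        poses <- c(poses, list(vs_conformer(
          e$id, sweep(cf$coords %*% t(rot), 2, shift, `+`), cf$elem,
          index = idx, charges = cf$charges,
          pose_score = round(runif(1, 1, 10), 3))))
        idx <- idx + 1L
      }
      out[[e$id]] <- pose_set(e$id, poses, cap = cap)
    }
    out
  })
}
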