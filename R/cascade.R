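## Orchestration of the four-stage screening workflow with survivor
## bookkeeping, optional label-aware validation metrics, and natural-source
## annotation of the final hits. The output molecules of one stage are the
## input molecules of the next; survivor sets are therefore strictly nested.
## Ground-truth labels, when supplied, are used ONLY to tabulate counts and
## metrics after the fact — no filter ever sees them.

#' Cascade configuration
#'
#' @param antipharmacophore Exclude-mode [pharmacophore_model()] (or a path
#'   to its JSON file).
#' @param partial Include-mode [pharmacophore_model()] (or JSON path).
#' @param queries List of charged query [vs_conformer()]s in the model
#'   frame (or a path to an SDF written by [write_conformers_sdf()]).
#' @param field A [field_config()].
#' @param pose_source `"stub"` (the deterministic [stub_docker()]) or a
#'   path to an SDF of externally produced docking poses.
#' @param pose_cap Best poses retained per molecule (default 32).
#' @param stages Character vector of enabled stages, a subset of
#'   `c("antipharmacophore", "partial", "pose", "field")`, kept in this
#'   fixed order.
#' @param feature_provider Feature perception for pose re-matching
#'   (default [cloud_features()]).
#' @param seed Integer seed controlling every stochastic component.
#' @return Object of class `cascade_config`.
#' @export
cascade_config <- function(antipharmacophore, partial, queries,
                           field = field_config(), pose_source = "stub",
                           pose_cap = 32,
                           stages = c("antipharmacophore", "partial",
                                      "pose", "field"),
                           feature_provider = cloud_features, seed = 1) {
  if (is.character(antipharmacophore)) {
    antipharmacophore <- load_pharmacophore(antipharmacophore)
  }
  if (is.character(partial)) partial <- load_pharmacophore(partial)
  if (is.character(queries)) queries <- read_conformers_sdf(queries)
  stopifnot(inherits(antipharmacophore, "pharmacophore_model"),
            inherits(partial, "pharmacophore_model"),
            inherits(field, "field_config"))
  order_ref <- c("antipharmacophore", "partial", "pose", "field")
  stages <- order_ref[order_ref %in% match.arg(stages, order_ref,
                                               several.ok = TRUE)]
  if ("field" %in% stages && length(queries) == 0) {
    stopf("field stage enabled but no queries supplied")
  }
  structure(list(antipharmacophore = antipharmacophore, partial = partial,
                 queries = queries, field = field,
                 pose_source = pose_source, pose_cap = as.integer(pose_cap),
                 stages = stages, feature_provider = feature_provider,
                 seed = as.integer(seed)),
            class = "cascade_config")
}

#' Run the sequential virtual-screening cascade
#'
#' Stage order is fixed: antipharmacophore exclusion, partial-agonist
#' pharmacophore matching, docking-pose re-matching (no re-orientation),
#' shape/electrostatic field similarity. Each stage consumes the previous
#' stage's survivors.
#'
#' @param entries Named list of [screen_entry()].
#' @param cfg A [cascade_config()].
#' @param labels Optional named character vector (`"active"`/`"decoy"`) for
#'   validation bookkeeping; never consulted by any filter.
#' @return Object of class `cascade_report`: `stages` (named list with
#'   survivor ids and per-stage detail), `survivors` (final ids), `counts`
#'   and `metrics` (with labels), `hit_poses` (model-frame conformers of the
#'   final hits, where available), `config_snapshot` and `seed`.
#' @export
run_cascade <- function(entries, cfg, labels = NULL) {
  stopifnot(inherits(cfg, "cascade_config"))
  if (is.null(names(entries)) && length(entries) > 0) {
    names(entries) <- vapply(entries, `[[`, character(1), "id")
  }
  current <- names(entries)
  stages <- list()
  hit_poses <- NULL

  run_stage <- function(name, fn) {
    tryCatch(fn(), error = function(e) {
      stopf("cascade stage '%s' failed: %s", name, conditionMessage(e))
    })
  }

  if ("antipharmacophore" %in% cfg$stages) {
    res <- run_stage("antipharmacophore", function()
      screen_antipharmacophore(entries[current], cfg$antipharmacophore))
    stages$antipharmacophore <- list(survivors = res$survivors,
                                     detail = res$flags)
    current <- res$survivors
  }

  partial_matches <- NULL
  if ("partial" %in% cfg$stages) {
    res <- run_stage("partial", function()
      screen_partial_pharmacophore(entries[current], cfg$partial))
    stages$partial <- list(survivors = res$hits, detail = res)
    partial_matches <- res
    current <- res$hits
  }

  if ("pose" %in% cfg$stages) {
    res <- run_stage("pose", function() {
      pose_sets <- if (identical(cfg$pose_source, "stub")) {
        stub_docker(entries[current], cfg$partial, seed = cfg$seed,
                    cap = cfg$pose_cap)
      } else {
        ps <- load_poses(cfg$pose_source, cap = cfg$pose_cap)
        ps[names(ps) %in% current]
      }
      rematch_poses(pose_sets, cfg$partial,
                    feature_provider = cfg$feature_provider)
    })
    stages$pose <- list(survivors = res$survivors, detail = res)
    hit_poses <- res$poses
    current <- res$survivors
  } else if (!is.null(partial_matches)) {
    ## no docking stage: carry the best in-vacuo match into the model frame
    hit_poses <- lapply(current, function(id) {
      m <- partial_matches$matches[[id]]
      cf <- entries[[id]]$conformers[[partial_matches$conformer_index[[id]]]]
      vs_conformer(id, apply_rigid(cf$coords, m$transform$rotation,
                                   m$transform$translation),
                   cf$elem, charges = cf$charges)
    })
    names(hit_poses) <- current
  }

  if ("field" %in% cfg$stages) {
    res <- run_stage("field", function() {
      if (is.null(hit_poses) || length(hit_poses) == 0) {
        return(list(hits = character(), scores = data.frame()))
      }
      similarity_filter(hit_poses[current], cfg$queries, cfg$field)
    })
    stages$field <- list(survivors = res$hits, detail = res)
    current <- res$hits
  }

  counts <- NULL; metrics <- NULL
  if (!is.null(labels)) {
    counts <- list(); prev <- names(entries)
    for (s in names(stages)) {
      surv <- stages[[s]]$survivors
      counts[[s]] <- stage_counts(
        sum(labels[prev] == "active"), sum(labels[prev] == "decoy"),
        sum(labels[surv] == "active"), sum(labels[surv] == "decoy"))
      prev <- surv
    }
    metrics <- tryCatch(
      metrics_table(unname(counts), stage_names = names(counts),
                    score_first = !("antipharmacophore" %in% names(stages))),
      error = function(e) NULL)
  }

  structure(list(stages = stages, survivors = current,
                 hit_poses = if (!is.null(hit_poses))
                   hit_poses[names(hit_poses) %in% current] else NULL,
                 counts = counts, metrics = metrics,
                 config_snapshot = snapshot_config(cfg), seed = cfg$seed),
            class = "cascade_report")
}

## Config snapshot for the report: stable, serializable summary.
snapshot_config <- function(cfg) {
  list(
    stages = cfg$stages,
    antipharmacophore = cfg$antipharmacophore$name,
    partial = cfg$partial$name,
    n_queries = length(cfg$queries),
    pose_source = if (identical(cfg$pose_source, "stub")) "stub" else "sdf",
    pose_cap = cfg$pose_cap,
    st_threshold = cfg$field$st_threshold,
    et_threshold = cfg$field$et_threshold,
    seed = cfg$seed)
}

#' @export
print.cascade_report <- function(x, ...) {
  cat("virtual-screening cascade (seed ", x$seed, ")\n", sep = "")
  for (s in names(x$stages)) {
    cat(sprintf("  %-18s -> %d survivors\n", s, length(x$stages[[s]]$survivors)))
  }
  if (!is.null(x$metrics)) {
    cat("validation metrics:\n")
    print(x$metrics, row.names = FALSE)
  }
  invisible(x)
}

#' Annotate hits with their natural sources
#'
#' Left-joins the hit ids against a source table; hits without any source
#' row are kept and flagged unannotated; duplicate (id, organism) rows are
#' collapsed.
#'
#' @param hit_ids Character vector of hit molecule ids.
#' @param source_table A data.frame with columns `mol_id`, `organism`,
#'   `reference`, or a path to such a TSV.
#' @return data.frame (mol_id, organism, reference, annotated).
#' @export
annotate_sources <- function(hit_ids, source_table) {
  if (is.character(source_table) && length(source_table) == 1) {
    source_table <- read.delim(source_table, sep = "\t",
                               stringsAsFactors = FALSE)
  }
  if (!is.data.frame(source_table) ||
      !all(c("mol_id", "organism") %in% names(source_table))) {
    stopf("source table must have columns mol_id, organism[, reference]")
  }
  if (!"reference" %in% names(source_table)) {
    source_table$reference <- NA_character_
  }
  src <- source_table[!duplicated(source_table[c("mol_id", "organism")]), ]
  rows <- lapply(hit_ids, function(id) {
    hit_src <- src[src$mol_id == id, , drop = FALSE]
    if (nrow(hit_src) == 0) {
      data.frame(mol_id = id, organism = NA_character_,
                 reference = NA_character_, annotated = FALSE,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(mol_id = id, organism = hit_src$organism,
                 reference = hit_src$reference, annotated = TRUE,
                 stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}

#' Write a cascade report to a directory
#'
#' Emits per-stage survivor TSVs, the metrics table (when labels were
#' supplied), the config snapshot JSON, and the final hit poses as SDF.
#'
#' @param report A [run_cascade()] result.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cascade_report <- function(report, dir) {
  stopifnot(inherits(report, "cascade_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in names(report$stages)) {
    surv <- report$stages[[s]]$survivors
    write_report(data.frame(id = surv, stringsAsFactors = FALSE),
                 file.path(dir, sprintf("survivors_%s.tsv", s)))
  }
  if (!is.null(report$metrics)) {
    write_report(report$metrics, file.path(dir, "metrics.tsv"))
  }
  jsonlite::write_json(c(report$config_snapshot, list(seed = report$seed)),
                       file.path(dir, "config.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  if (!is.null(report$hit_poses) && length(report$hit_poses) > 0) {
    write_conformers_sdf(report$hit_poses, file.path(dir, "hit_poses.sdf"))
  }
  invisible(dir)
}
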