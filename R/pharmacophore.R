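## Pharmacophore models and conformer <-> model matching with excluded
## volumes. Matching enumerates kind-compatible injective assignments of
## model sites onto perceived features exactly (site counts are <= 5), with
## an optional closed-form rigid re-orientation of the conformer onto the
## model frame; in fixed-pose mode the conformer is tested in place.

#' Construct a pharmacophore site
#'
#' @param kind Feature kind the site requires. Hydrophobic sites also accept
#'   `aromatic_hydrophobic` features (aromatic rings treated as hydrophobic
#'   groups); aromatic sites accept `aromatic` and `aromatic_hydrophobic`.
#' @param position Length-3 numeric, Angstrom.
#' @param tolerance Matching radius in Angstrom (default 2.0).
#' @return Object of class `pharmacophore_site`.
#' @export
pharmacophore_site <- function(kind, position, tolerance = 2.0) {
  kind <- match.arg(kind, FEATURE_KINDS)
  stopifnot(length(position) == 3, is.numeric(tolerance), tolerance > 0)
  structure(list(kind = kind, position = as.numeric(position),
                 tolerance = tolerance), class = "pharmacophore_site")
}

#' Construct an excluded volume
#'
#' A sphere marking receptor-occupied space: a pharmacophore match is
#' invalidated if any ligand heavy atom falls inside it.
#'
#' @param position Sphere center, Angstrom.
#' @param radius Sphere radius, Angstrom (> 0).
#' @return Object of class `excluded_volume`.
#' @export
excluded_volume <- function(position, radius = 1.5) {
  stopifnot(length(position) == 3, is.numeric(radius), radius > 0)
  structure(list(position = as.numeric(position), radius = radius),
            class = "excluded_volume")
}

#' Construct a pharmacophore model
#'
#' @param name Model name.
#' @param sites List of [pharmacophore_site()] objects.
#' @param volumes List of [excluded_volume()] objects (may be empty).
#' @param min_match Minimum number of sites a conformer must satisfy.
#' @param mode `"include"` (matches are hits) or `"exclude"` (matches are
#'   discarded, as for the full-agonist antipharmacophore).
#' @param metadata Optional named list (e.g. `list(synthetic = TRUE)`).
#' @return Object of class `pharmacophore_model`.
#' @export
pharmacophore_model <- function(name, sites, volumes = list(),
                                min_match = length(sites),
                                mode = c("include", "exclude"),
                                metadata = list()) {
  mode <- match.arg(mode)
  if (length(sites) == 0) stopf("pharmacophore model must have >= 1 site")
  for (s in sites) stopifnot(inherits(s, "pharmacophore_site"))
  for (v in volumes) stopifnot(inherits(v, "excluded_volume"))
  if (!is_count(min_match) || min_match < 1 || min_match > length(sites)) {
    stopf("min_match must lie in 1..%d", length(sites))
  }
  structure(list(name = name, sites = sites, volumes = volumes,
                 min_match = as.integer(min_match), mode = mode,
                 metadata = metadata),
            class = "pharmacophore_model")
}

#' @export
print.pharmacophore_model <- function(x, ...) {
  kinds <- table(vapply(x$sites, `[[`, character(1), "kind"))
  cat(sprintf("pharmacophore '%s' (%s mode): %d sites [%s], %d excluded volumes, min_match %d\n",
              x$name, x$mode, length(x$sites),
              paste(sprintf("%s x%d", names(kinds), kinds), collapse = ", "),
              length(x$volumes), x$min_match))
  invisible(x)
}

## Which feature kinds satisfy a site of a given kind.
site_compatible_kinds <- function(site_kind) {
  switch(site_kind,
         hydrophobic = c("hydrophobic", "aromatic_hydrophobic"),
         aromatic = c("aromatic", "aromatic_hydrophobic"),
         site_kind)
}

model_site_positions <- function(model) {
  do.call(rbind, lapply(model$sites, `[[`, "position"))
}
model_volume_positions <- function(model) {
  if (length(model$volumes) == 0) return(matrix(numeric(0), 0, 3))
  do.call(rbind, lapply(model$volumes, `[[`, "position"))
}

## --- JSON persistence (pharmacophore-json v1) -------------------------------

PHARMACOPHORE_JSON_VERSION <- "pharmacophore-json v1"

#' Save a pharmacophore model as versioned JSON
#'
#' @param model A [pharmacophore_model()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_pharmacophore <- function(model, path) {
  stopifnot(inherits(model, "pharmacophore_model"))
  obj <- list(
    version = PHARMACOPHORE_JSON_VERSION,
    name = model$name,
    mode = model$mode,
    min_match = model$min_match,
    sites = lapply(model$sites, function(s)
      list(kind = s$kind, xyz = s$position, tolerance = s$tolerance)),
    excluded_volumes = lapply(model$volumes, function(v)
      list(xyz = v$position, radius = v$radius)),
    metadata = model$metadata
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Load a pharmacophore model from versioned JSON
#'
#' Validates the `pharmacophore-json v1` schema; violations raise an error
#' naming the offending JSON location.
#'
#' @param path JSON file path.
#' @return A [pharmacophore_model()].
#' @export
load_pharmacophore <- function(path) {
  if (!file.exists(path)) stopf("pharmacophore file not found: %s", path)
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  fail <- function(ptr, msg) {
    stopf("pharmacophore format error at %s: %s (in %s)", ptr, msg, path)
  }
  if (!identical(obj$version, PHARMACOPHORE_JSON_VERSION)) {
    fail("/version", sprintf("expected '%s'", PHARMACOPHORE_JSON_VERSION))
  }
  if (is.null(obj$name)) fail("/name", "missing")
  if (!identical(obj$mode, "include") && !identical(obj$mode, "exclude")) {
    fail("/mode", "must be 'include' or 'exclude'")
  }
  if (is.null(obj$sites) || length(obj$sites) == 0) fail("/sites", "empty")
  sites <- lapply(seq_along(obj$sites), function(i) {
    s <- obj$sites[[i]]
    ptr <- sprintf("/sites/%d", i - 1)
    if (is.null(s$kind) || !(s$kind %in% FEATURE_KINDS)) {
      fail(paste0(ptr, "/kind"), "unknown feature kind")
    }
    xyz <- unlist(s$xyz)
    if (length(xyz) != 3 || !is.numeric(xyz)) fail(paste0(ptr, "/xyz"), "need 3 numbers")
    tol <- s$tolerance %||% 2.0
    if (!is.numeric(tol) || tol <= 0) fail(paste0(ptr, "/tolerance"), "must be > 0")
    pharmacophore_site(s$kind, xyz, tol)
  })
  mm <- obj$min_match
  if (!is_count(mm %||% -1) || mm < 1 || mm > length(sites)) {
    fail("/min_match", sprintf("must lie in 1..%d", length(sites)))
  }
  vols <- lapply(seq_along(obj$excluded_volumes %||% list()), function(i) {
    v <- obj$excluded_volumes[[i]]
    ptr <- sprintf("/excluded_volumes/%d", i - 1)
    xyz <- unlist(v$xyz)
    if (length(xyz) != 3 || !is.numeric(xyz)) fail(paste0(ptr, "/xyz"), "need 3 numbers")
    if (!is.numeric(v$radius %||% -1) || v$radius <= 0) {
      fail(paste0(ptr, "/radius"), "must be > 0")
    }
    excluded_volume(xyz, v$radius)
  })
  pharmacophore_model(obj$name, sites, vols, mm, obj$mode,
                      metadata = obj$metadata %||% list())
}

## --- Matching ---------------------------------------------------------------

match_result <- function(matched = FALSE, assignment = integer(),
                         rms = NA_real_, transform = identity_transform(),
                         clash = FALSE, n_matched = length(assignment)) {
  structure(list(matched = matched, assignment = assignment, rms = rms,
                 transform = transform, clash = clash, n_matched = n_matched),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  if (x$matched) {
    cat(sprintf("match: %d sites, rms %.3f A\n", x$n_matched, x$rms))
  } else if (x$clash) {
    cat("no match (geometric fit exists but clashes with excluded volume)\n")
  } else cat("no match\n")
  invisible(x)
}

## Ordering over accepted assignments: lower rms; ties -> larger assignment,
## then lexicographically smallest site-index tuple, then feature tuple.
.better_candidate <- function(a, b, tol = 1e-12) {
  if (is.null(b)) return(TRUE)
  if (a$rms < b$rms - tol) return(TRUE)
  if (a$rms > b$rms + tol) return(FALSE)
  if (length(a$sites) != length(b$sites)) return(length(a$sites) > length(b$sites))
  for (i in seq_along(a$sites)) {
    if (a$sites[i] != b$sites[i]) return(a$sites[i] < b$sites[i])
  }
  for (i in seq_along(a$feats)) {
    if (a$feats[i] != b$feats[i]) return(a$feats[i] < b$feats[i])
  }
  FALSE
}

#' Match a conformer against a pharmacophore model
#'
#' Searches kind-compatible injective assignments of model sites onto the
#' conformer's features, of every size from `min_match` up to the full site
#' count. With `reorient = TRUE` each candidate assignment is superposed onto
#' the sites by closed-form least squares ([kabsch()]) and accepted if every
#' matched feature lies within its site's tolerance after the transform and
#' no heavy atom penetrates an excluded volume; with `reorient = FALSE`
#' (fixed-pose re-matching of docking poses) the identity transform is used
#' and the same tests are applied in place. Among accepting assignments the
#' one with minimal rms wins (ties: larger assignment, then lexicographically
#' smallest site indices).
#'
#' @param conf A [vs_conformer()].
#' @param feats List of [feature_point()] perceived from `conf`.
#' @param model A [pharmacophore_model()].
#' @param reorient Allow rigid re-orientation of the conformer? Default TRUE.
#' @return A `match_result`: `matched`, `assignment` (named integer vector,
#'   site index -> feature index), `rms` (Angstrom), `transform`
#'   (rotation + translation taking the conformer into the model frame;
#'   identity in fixed-pose mode), `clash` (TRUE when the only geometric
#'   fits penetrate excluded volumes).
#' @export
match_conformer <- function(conf, feats, model, reorient = TRUE) {
  stopifnot(inherits(conf, "vs_conformer"), inherits(model, "pharmacophore_model"))
  n_sites <- length(model$sites)
  site_pos <- model_site_positions(model)
  site_tol <- vapply(model$sites, `[[`, numeric(1), "tolerance")
  site_kind <- vapply(model$sites, `[[`, character(1), "kind")
  fk <- feature_kinds(feats)
  fpos <- feature_positions(feats)
  compat <- lapply(site_kind, function(k) which(fk %in% site_compatible_kinds(k)))

  vol_pos <- model_volume_positions(model)
  vol_rad <- vapply(model$volumes, `[[`, numeric(1), "radius")
  hv <- heavy_idx(conf)
  heavy <- conf$coords[hv, , drop = FALSE]

  check_clash <- function(transform) {
    if (length(model$volumes) == 0 || nrow(heavy) == 0) return(FALSE)
    xyz <- apply_rigid(heavy, transform$rotation, transform$translation)
    for (v in seq_len(nrow(vol_pos))) {
      d2 <- rowSums(sweep(xyz, 2, vol_pos[v, ])^2)
      if (any(d2 < vol_rad[v]^2)) return(TRUE)
    }
    FALSE
  }

  best <- NULL        # best clash-free accepted assignment
  best_any <- NULL    # best accepted assignment ignoring clash

  evaluate <- function(sites_sel, feats_sel) {
    sp <- site_pos[sites_sel, , drop = FALSE]
    fp <- fpos[feats_sel, , drop = FALSE]
    if (reorient) {
      fit <- kabsch(fp, sp)
      res <- apply_rigid(fp, fit$rotation, fit$translation) - sp
      transform <- fit[c("rotation", "translation")]
    } else {
      res <- fp - sp
      transform <- identity_transform()
    }
    d <- sqrt(rowSums(res^2))
    if (any(d > site_tol[sites_sel])) return()
    cand <- list(sites = sites_sel, feats = feats_sel,
                 rms = sqrt(mean(d^2)), transform = transform)
    if (.better_candidate(cand, best_any)) best_any <<- cand
    if (.better_candidate(cand, best)) {
      if (!check_clash(transform)) best <<- cand
    }
  }

  ## Depth-first injective assignment with pairwise-distance pruning
  ## (a rigid fit within tolerances implies |d_feat - d_site| <= tol_i + tol_j).
  assign_rec <- function(sites_sel, feats_sel, remaining_sites) {
    if (length(remaining_sites) == 0) {
      if (length(sites_sel) > 0) evaluate(sites_sel, feats_sel)
      return()
    }
    s <- remaining_sites[1]
    rest <- remaining_sites[-1]
    for (f in compat[[s]]) {
      if (f %in% feats_sel) next
      ok <- TRUE
      if (reorient && length(sites_sel) > 0) {
        for (j in seq_along(sites_sel)) {
          ds <- sqrt(sum((site_pos[s, ] - site_pos[sites_sel[j], ])^2))
          df <- sqrt(sum((fpos[f, ] - fpos[feats_sel[j], ])^2))
          if (abs(ds - df) > site_tol[s] + site_tol[sites_sel[j]]) { ok <- FALSE; break }
        }
      } else if (!reorient) {
        if (sqrt(sum((fpos[f, ] - site_pos[s, ])^2)) > site_tol[s]) ok <- FALSE
      }
      if (ok) assign_rec(c(sites_sel, s), c(feats_sel, f), rest)
    }
  }

  if (length(feats) > 0) {
    for (k in seq(n_sites, model$min_match)) {
      subsets <- combn(n_sites, k, simplify = FALSE)
      for (ss in subsets) assign_rec(integer(), integer(), ss)
    }
  }

  if (!is.null(best)) {
    assignment <- best$feats
    names(assignment) <- as.character(best$sites)
    match_result(TRUE, assignment, best$rms, best$transform, clash = FALSE)
  } else if (!is.null(best_any)) {
    assignment <- best_any$feats
    names(assignment) <- as.character(best_any$sites)
    match_result(FALSE, assignment, best_any$rms, best_any$transform, clash = TRUE)
  } else {
    match_result(FALSE)
  }
}

## --- Library-level screens --------------------------------------------------

#' Bundle a molecule's conformers and features for screening
#'
#' @param id Molecule id.
#' @param conformers List of [vs_conformer()].
#' @param features List (parallel to `conformers`) of feature-point lists.
#' @param label Optional `"active"` / `"decoy"` ground-truth label (never
#'   consulted by any filter; used only for validation bookkeeping).
#' @param dockable Hint consumed by [stub_docker()] test double.
#' @param sources Character vector of natural-source organisms.
#' @return Object of class `screen_entry`.
#' @export
screen_entry <- function(id, conformers, features, label = NA_character_,
                         dockable = NA, sources = character()) {
  stopifnot(length(conformers) == length(features))
  for (cf in conformers) stopifnot(inherits(cf, "vs_conformer"))
  structure(list(id = as.character(id), conformers = conformers,
                 features = features, label = label, dockable = dockable,
                 sources = sources),
            class = "screen_entry")
}

#' Antipharmacophore exclusion screen
#'
#' A molecule is discarded if and only if ANY of its conformers achieves a
#' clash-free match of at least `min_match` sites of the exclude-mode model
#' (putative full agonists). Everything else survives; molecules whose only
#' geometric fits clash with the excluded volumes survive and are flagged.
#'
#' @param entries List of [screen_entry()].
#' @param model Exclude-mode [pharmacophore_model()].
#' @return List with `survivors` (character ids), `discarded` (ids), and
#'   `flags` (data.frame id / clash_only).
#' @export
screen_antipharmacophore <- function(entries, model) {
  stopifnot(inherits(model, "pharmacophore_model"))
  if (model$mode != "exclude") {
    stopf("screen_antipharmacophore requires an exclude-mode model, got '%s'",
          model$mode)
  }
  surv <- character(); disc <- character(); clash_only <- logical()
  for (e in entries) {
    hit <- FALSE; clashed <- FALSE
    for (i in seq_along(e$conformers)) {
      m <- match_conformer(e$conformers[[i]], e$features[[i]], model,
                           reorient = TRUE)
      if (m$matched) { hit <- TRUE; break }
      if (m$clash) clashed <- TRUE
    }
    if (hit) {
      disc <- c(disc, e$id)
      vs_log("antipharmacophore: ", e$id, " discarded (full-agonist-like)")
    } else {
      surv <- c(surv, e$id)
      clash_only <- c(clash_only, clashed)
    }
  }
  list(survivors = surv, discarded = disc,
       flags = data.frame(id = surv, clash_only = clash_only,
                          stringsAsFactors = FALSE))
}

#' Partial-agonist pharmacophore screen
#'
#' A molecule is a hit if and only if ANY conformer matches ALL sites of the
#' include-mode model clash-free; the lowest-rms match per molecule is kept.
#'
#' @param entries List of [screen_entry()].
#' @param model Include-mode [pharmacophore_model()] with
#'   `min_match == length(sites)`.
#' @return List with `hits` (ids), `matches` (named list of the best
#'   `match_result` per hit) and `conformer_index` (named integer vector of
#'   the matching conformer per hit).
#' @export
screen_partial_pharmacophore <- function(entries, model) {
  stopifnot(inherits(model, "pharmacophore_model"))
  if (model$mode != "include") {
    stopf("screen_partial_pharmacophore requires an include-mode model, got '%s'",
          model$mode)
  }
  if (model$min_match != length(model$sites)) {
    stopf("partial-agonist screen expects min_match == number of sites")
  }
  hits <- character(); matches <- list(); conf_idx <- integer()
  for (e in entries) {
    best <- NULL; best_i <- NA_integer_
    for (i in seq_along(e$conformers)) {
      m <- match_conformer(e$conformers[[i]], e$features[[i]], model,
                           reorient = TRUE)
      if (m$matched && (is.null(best) || m$rms < best$rms)) {
        best <- m; best_i <- i
      }
    }
    if (!is.null(best)) {
      hits <- c(hits, e$id)
      matches[[e$id]] <- best
      conf_idx[e$id] <- best_i
    }
  }
  list(hits = hits, matches = matches, conformer_index = conf_idx)
}
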