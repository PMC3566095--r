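## Synthetic benchmark generator: pharmacophore fixtures with plausible
## ligand-scale geometries (flagged synthetic — the workflow's real site
## coordinates derive from receptor crystal structures and are config
## inputs, not shipped data) and labeled active/decoy libraries of feature
## clouds with planted geometric signal, so every cascade stage is testable
## offline.
##
## Planted structure, by construction:
##   actives           embed the partial-agonist model (4 sites) to within
##                     `embed_noise`, avoid the antipharmacophore's
##                     4-of-5 condition, carry query-like charges, and are
##                     docking-compatible -> survive every stage at noise 0
##   "field decoys"    embed the partial model geometrically but with
##                     negated charges -> a configurable fraction is
##                     docking-compatible; all fail the electrostatic
##                     threshold at the field stage
##   "anti decoys"     embed the antipharmacophore -> discarded at stage 1
##   plain decoys      random clouds rejection-sampled to NOT embed the
##                     partial model -> fail the partial-pharmacophore stage

#' Benchmark specification
#'
#' @param n_actives,n_decoys Library composition.
#' @param embed_noise Uniform-in-sphere jitter radius (Angstrom) applied to
#'   planted active feature positions (default 0).
#' @param seed Integer seed; the whole library is deterministic given it.
#' @param frac_decoys_embed Fraction of decoys that embed the partial model
#'   with opposing charges (default 0.125).
#' @param frac_embed_dockable Fraction of those that the stub docker treats
#'   as docking-compatible (default 0.5).
#' @param frac_decoys_anti Fraction of decoys planted as full-agonist-like
#'   antipharmacophore matchers (default 0.25).
#' @param max_attempts Rejection-sampling cap per decoy (default 10000).
#' @return Object of class `benchmark_spec`.
#' @export
benchmark_spec <- function(n_actives, n_decoys, embed_noise = 0, seed = 1,
                           frac_decoys_embed = 0.125,
                           frac_embed_dockable = 0.5,
                           frac_decoys_anti = 0.25,
                           max_attempts = 10000) {
  stopifnot(is_count(n_actives), is_count(n_decoys), embed_noise >= 0,
            frac_decoys_embed >= 0, frac_decoys_embed <= 1,
            frac_embed_dockable >= 0, frac_embed_dockable <= 1,
            frac_decoys_anti >= 0, frac_decoys_embed + frac_decoys_anti <= 1)
  structure(list(n_actives = as.integer(n_actives),
                 n_decoys = as.integer(n_decoys),
                 embed_noise = embed_noise, seed = as.integer(seed),
                 frac_decoys_embed = frac_decoys_embed,
                 frac_embed_dockable = frac_embed_dockable,
                 frac_decoys_anti = frac_decoys_anti,
                 max_attempts = as.integer(max_attempts)),
            class = "benchmark_spec")
}

#' Synthetic pharmacophore fixtures and query poses
#'
#' Builds geometrically consistent synthetic models honoring the workflow's
#' site compositions — an exclude-mode antipharmacophore of 5 sites (2
#' hydrogen-bond acceptors + 3 hydrophobics, `min_match` 4) and an
#' include-mode partial-agonist model of 4 sites (1 acceptor + 3
#' hydrophobics, `min_match` 4), both with receptor-like excluded volumes —
#' plus 5 query conformers embedding the partial model in its own frame.
#' The two geometries are deliberately incommensurate (the
#' antipharmacophore spans ~12 A, the partial model ~5 A) so that
#' partial-model embedders cannot satisfy 4 of 5 antipharmacophore sites;
#' this invariant is verified at generation time.
#'
#' @param seed Integer seed (query decoration jitter).
#' @return List with `antipharmacophore`, `partial` (models, metadata
#'   `synthetic = TRUE`) and `queries` (list of 5 charged [vs_conformer()]).
#' @export
make_pharmacophore_fixtures <- function(seed = 1) {
  partial <- pharmacophore_model(
    "partial_agonist_synthetic",
    sites = list(
      pharmacophore_site("acceptor",    c(0.0, 0.0, 0.0)),
      pharmacophore_site("hydrophobic", c(4.2, 0.0, 0.0)),
      pharmacophore_site("hydrophobic", c(1.8, 3.6, 0.0)),
      pharmacophore_site("hydrophobic", c(4.8, 2.4, 2.8))),
    volumes = list(
      excluded_volume(c(2.5, 1.5, -4.0), 1.5),
      excluded_volume(c(-3.5, -3.0, 2.5), 1.5)),
    min_match = 4, mode = "include",
    metadata = list(synthetic = TRUE))

  anti <- pharmacophore_model(
    "antipharmacophore_synthetic",
    sites = list(
      pharmacophore_site("acceptor",    c(0.0, 0.0, 0.0)),
      pharmacophore_site("acceptor",    c(11.0, 0.0, 0.0)),
      pharmacophore_site("hydrophobic", c(5.5, 6.0, 0.0)),
      pharmacophore_site("hydrophobic", c(2.0, -6.0, 2.0)),
      pharmacophore_site("hydrophobic", c(9.0, 5.0, -4.0))),
    volumes = list(
      excluded_volume(c(5.5, 0.0, 5.0), 1.5),
      excluded_volume(c(5.5, 0.0, -5.0), 1.5)),
    min_match = 4, mode = "exclude",
    metadata = list(synthetic = TRUE))

  queries <- with_seed(seed, {
    base <- active_template(partial)
    lapply(1:5, function(q) {
      coords <- base$coords
      if (q > 1) {
        ## small in-tolerance wobble plus a varying decoration atom
        coords[seq_len(4), ] <- coords[seq_len(4), ] +
          matrix(runif(12, -0.3, 0.3), 4, 3)
        coords[5, ] <- coords[5, ] + runif(3, -0.8, 0.8)
      }
      vs_conformer(sprintf("query_%d", q), coords, base$elem,
                   charges = base$charges)
    })
  })

  ## fixture invariant: partial-model embedders never trip the
  ## antipharmacophore, and always match the partial model
  for (q in queries) {
    fe <- cloud_features(q)
    if (match_conformer(q, fe, anti, reorient = TRUE)$matched) {
      stopf("fixture invariant violated: query matches the antipharmacophore")
    }
    if (!match_conformer(q, fe, partial, reorient = TRUE)$matched) {
      stopf("fixture invariant violated: query misses the partial model")
    }
  }
  list(antipharmacophore = anti, partial = partial, queries = queries)
}

## Template active in the partial-model frame: one acceptor-bearing oxygen
## on the acceptor site, carbons on the hydrophobic sites, one decoration
## carbon, and a fixed polar charge pattern shared with query 1.
active_template <- function(partial) {
  sites <- model_site_positions(partial)
  coords <- rbind(sites, c(2.7, 1.5, 0.7))
  elem <- c("O", "C", "C", "C", "C")
  charges <- c(-0.40, 0.15, 0.05, 0.10, 0.10)
  list(coords = coords, elem = elem, charges = charges)
}

## Uniform jitter inside a sphere of the given radius.
jitter_in_sphere <- function(n, radius) {
  if (radius <= 0) return(matrix(0, n, 3))
  out <- matrix(0, n, 3)
  for (i in seq_len(n)) {
    repeat {
      v <- runif(3, -radius, radius)
      if (sum(v^2) <= radius^2) break
    }
    out[i, ] <- v
  }
  out
}

#' Generate a labeled benchmark library with planted pharmacophore signal
#'
#' See the module comments for the construction; all placements are
#' rejection-verified with the package's own matcher, so the planted
#' properties hold exactly, not just in expectation. Feature clouds follow
#' the [cloud_features()] convention (O/N acceptors, C hydrophobics).
#'
#' @param spec A [benchmark_spec()].
#' @param models Fixtures from [make_pharmacophore_fixtures()].
#' @return List with `entries` (named list of [screen_entry()]),
#'   `labels` (named character vector, `"active"`/`"decoy"`) and `spec`.
#' @export
make_benchmark <- function(spec, models = make_pharmacophore_fixtures()) {
  stopifnot(inherits(spec, "benchmark_spec"))
  partial <- models$partial
  anti <- models$antipharmacophore
  min_tol <- min(vapply(partial$sites, `[[`, numeric(1), "tolerance"))
  if (spec$embed_noise > min_tol) {
    stopf("infeasible spec: embed_noise %.2f exceeds the site tolerance %.2f",
          spec$embed_noise, min_tol)
  }
  tmpl <- active_template(partial)

  with_seed(spec$seed, {
    entries <- list(); labels <- character()

    make_cloud_entry <- function(id, coords, elem, charges, dockable, label) {
      ## ship the cloud in a random frame so matching must re-orient
      rot <- random_rotation(); shift <- runif(3, -10, 10)
      moved <- sweep(coords %*% t(rot), 2, shift, `+`)
      conf <- vs_conformer(id, moved, elem, charges = charges)
      screen_entry(id, list(conf), list(cloud_features(conf)),
                   label = label, dockable = dockable)
    }

    sample_active <- function(id) {
      for (att in seq_len(spec$max_attempts)) {
        coords <- tmpl$coords
        coords[1:4, ] <- coords[1:4, ] + jitter_in_sphere(4, spec$embed_noise)
        probe <- vs_conformer(id, coords, tmpl$elem, charges = tmpl$charges)
        fe <- cloud_features(probe)
        if (!match_conformer(probe, fe, partial, reorient = TRUE)$matched) next
        if (match_conformer(probe, fe, anti, reorient = TRUE)$matched) next
        return(make_cloud_entry(id, coords, tmpl$elem, tmpl$charges,
                                dockable = TRUE, label = "active"))
      }
      stopf("could not place active %s in %d attempts", id, spec$max_attempts)
    }

    sample_plain_decoy <- function(id) {
      for (att in seq_len(spec$max_attempts)) {
        n_atoms <- sample(4:7, 1)
        coords <- matrix(runif(3 * n_atoms, -4, 4), n_atoms, 3)
        elem <- c("O", rep("C", n_atoms - 1))
        charges <- c(-0.2, rep(0.2 / (n_atoms - 1), n_atoms - 1))
        probe <- vs_conformer(id, coords, elem, charges = charges)
        fe <- cloud_features(probe)
        if (match_conformer(probe, fe, partial, reorient = TRUE)$matched) next
        if (match_conformer(probe, fe, anti, reorient = TRUE)$matched) next
        return(make_cloud_entry(id, coords, elem, charges,
                                dockable = FALSE, label = "decoy"))
      }
      stopf("could not place decoy %s in %d attempts", id, spec$max_attempts)
    }

    make_field_decoy <- function(id, dockable) {
      ## partial-model embedder with opposing charge pattern
      make_cloud_entry(id, tmpl$coords, tmpl$elem, -tmpl$charges,
                       dockable = dockable, label = "decoy")
    }

    make_anti_decoy <- function(id) {
      ## full-agonist-like cloud sitting on the antipharmacophore sites
      sites <- model_site_positions(anti)
      kinds <- vapply(anti$sites, `[[`, character(1), "kind")
      elem <- ifelse(kinds == "acceptor", "O", "C")
      charges <- ifelse(kinds == "acceptor", -0.3, 0.2)
      make_cloud_entry(id, sites, elem, charges,
                       dockable = FALSE, label = "decoy")
    }

    for (i in seq_len(spec$n_actives)) {
      id <- sprintf("active_%03d", i)
      entries[[id]] <- sample_active(id)
      labels[id] <- "active"
    }
    n_field <- round(spec$frac_decoys_embed * spec$n_decoys)
    n_dock <- round(spec$frac_embed_dockable * n_field)
    n_anti <- round(spec$frac_decoys_anti * spec$n_decoys)
    for (i in seq_len(spec$n_decoys)) {
      id <- sprintf("decoy_%03d", i)
      entries[[id]] <- if (i <= n_field) {
        make_field_decoy(id, dockable = i <= n_dock)
      } else if (i <= n_field + n_anti) {
        make_anti_decoy(id)
      } else {
        sample_plain_decoy(id)
      }
      labels[id] <- "decoy"
    }
    list(entries = entries, labels = labels, spec = spec)
  })
}

#' Write a benchmark to plain-text files
#'
#' Emits `library.sdf` (one record per conformer, cloud convention),
#' `labels.csv`, the two model JSON files and `queries.sdf` into `dir`.
#'
#' @param bench A [make_benchmark()] result.
#' @param models The fixtures used to build it.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_benchmark <- function(bench, models, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  confs <- unlist(lapply(bench$entries, `[[`, "conformers"), recursive = FALSE)
  dockable <- vapply(bench$entries, function(e) isTRUE(e$dockable), logical(1))
  extra <- lapply(names(bench$entries), function(id)
    c(dockable = as.character(dockable[[id]])))
  write_conformers_sdf(confs, file.path(dir, "library.sdf"), extra_props = extra)
  write.table(data.frame(mol_id = names(bench$labels), label = bench$labels),
              file.path(dir, "labels.csv"), sep = ",", row.names = FALSE,
              quote = FALSE)
  save_pharmacophore(models$antipharmacophore,
                     file.path(dir, "antipharmacophore.json"))
  save_pharmacophore(models$partial, file.path(dir, "partial.json"))
  write_conformers_sdf(models$queries, file.path(dir, "queries.sdf"))
  invisible(dir)
}

#' Re-load a benchmark directory written by [write_benchmark()]
#'
#' @param dir Benchmark directory.
#' @return List with `entries`, `labels`, `models` (antipharmacophore,
#'   partial, queries).
#' @export
read_benchmark <- function(dir) {
  confs <- read_conformers_sdf(file.path(dir, "library.sdf"))
  lab <- read.csv(file.path(dir, "labels.csv"), stringsAsFactors = FALSE)
  labels <- stats::setNames(lab$label, lab$mol_id)
  sdfset <- suppressWarnings(
    ChemmineR::read.SDFset(file.path(dir, "library.sdf"), skipErrors = TRUE))
  dockable <- vapply(seq_along(sdfset), function(i) {
    db <- ChemmineR::datablock(sdfset[[i]])
    identical(db[["dockable"]], "TRUE")
  }, logical(1))
  ids <- vapply(confs, `[[`, character(1), "mol_id")
  entries <- list()
  for (i in seq_along(confs)) {
    id <- ids[i]
    cf <- confs[[i]]
    if (is.null(entries[[id]])) {
      entries[[id]] <- screen_entry(id, list(cf), list(cloud_features(cf)),
                                    label = labels[[id]] %||% NA_character_,
                                    dockable = dockable[i])
    } else {
      e <- entries[[id]]
      entries[[id]] <- screen_entry(id, c(e$conformers, list(cf)),
                                    c(e$features, list(cloud_features(cf))),
                                    label = e$label, dockable = e$dockable)
    }
  }
  models <- list(
    antipharmacophore = load_pharmacophore(file.path(dir, "antipharmacophore.json")),
    partial = load_pharmacophore(file.path(dir, "partial.json")),
    queries = read_conformers_sdf(file.path(dir, "queries.sdf")))
  list(entries = entries, labels = labels, models = models)
}
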