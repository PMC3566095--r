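## Library preparation: drug-likeness filtering (rule-of-five with a
## configurable violation allowance plus a toxicophore substructure screen)
## and conformer-ensemble generation. Descriptors come from ChemmineR /
## ChemmineOB (Crippen-type atomic-contribution logP via Open Babel);
## conformers come from the Open Babel command-line tools: 3D embedding
## (--gen3d) followed by systematic diverse-conformer search (Confab) with
## an energy cutoff and RMSD duplicate removal, energies re-evaluated with
## MMFF94.

#' Library-preparation configuration
#'
#' @param max_conformers Conformer cap per molecule (default 200).
#' @param energy_window Energy window in kcal/mol above the ensemble minimum
#'   (default 25).
#' @param max_lipinski_violations Rule-of-five violations tolerated
#'   (default 1).
#' @param toxicophore_patterns Named character vector of SMARTS patterns;
#'   default is the editable list shipped in
#'   `inst/extdata/toxicophores.yaml`.
#' @param rms_dedup Heavy-atom RMSD (Angstrom) below which two conformers
#'   are duplicates (default 0.5).
#' @param rng_seed Seed recorded with every ensemble (the systematic search
#'   itself is deterministic).
#' @return Object of class `prep_config`.
#' @export
prep_config <- function(max_conformers = 200, energy_window = 25,
                        max_lipinski_violations = 1,
                        toxicophore_patterns = NULL,
                        rms_dedup = 0.5, rng_seed = 1) {
  stopifnot(max_conformers >= 1, energy_window > 0,
            max_lipinski_violations %in% 0:4, rms_dedup >= 0)
  if (is.null(toxicophore_patterns)) {
    toxicophore_patterns <- load_toxicophores()
  }
  structure(list(max_conformers = as.integer(max_conformers),
                 energy_window = energy_window,
                 max_lipinski_violations = as.integer(max_lipinski_violations),
                 toxicophore_patterns = toxicophore_patterns,
                 rms_dedup = rms_dedup, rng_seed = as.integer(rng_seed)),
            class = "prep_config")
}

#' Load the toxicophore SMARTS table
#'
#' @param path YAML file; default is the list shipped with the package.
#' @return Named character vector of SMARTS patterns.
#' @export
load_toxicophores <- function(path = NULL) {
  path <- path %||% system.file("extdata", "toxicophores.yaml",
                                package = "ppargscreen")
  obj <- yaml::read_yaml(path)
  unlist(obj$patterns)
}

#' Lipinski rule-of-five violation count
#'
#' Violations of: molecular weight <= 500 Da, computed logP <= 5, hydrogen
#' bond donors <= 5 (OH + NH count), acceptors <= 10 (N + O count).
#'
#' @param mol A [vs_molecule()] parsed from SMILES/SDF.
#' @return Integer in 0..4. The four descriptors are attached as attribute
#'   `descriptors`.
#' @export
lipinski_violations <- function(mol) {
  stopifnot(inherits(mol, "vs_molecule"))
  sdfset <- mol_sdfset(mol)
  mw <- unname(ChemmineR::MW(sdfset, addH = TRUE))
  logp <- tryCatch(ChemmineR::propOB(sdfset)$logP,
                   error = function(e) stopf("logP computation failed for %s", mol$id))
  elem <- toupper(mol$atoms$elem)
  hba <- sum(elem %in% c("N", "O"))
  adj <- adjacency_list(mol)
  nH_imp <- implicit_h(mol)
  hbd <- sum(vapply(which(elem %in% c("N", "O")), function(i) {
    sum(elem[adj[[i]]] == "H") + nH_imp[i]
  }, numeric(1)))
  v <- sum(mw > 500, logp > 5, hbd > 5, hba > 10)
  attr(v, "descriptors") <- c(mw = mw, logp = logp, hbd = hbd, hba = hba)
  v
}

#' Drug-likeness filter
#'
#' A molecule passes when its rule-of-five violation count does not exceed
#' the configured allowance AND no toxicophore pattern matches. Every
#' failure carries a machine-readable reason.
#'
#' @param lib List of [vs_molecule()] (as from [read_library()]).
#' @param cfg A [prep_config()].
#' @return List with `pass` (molecule list) and `fail`
#'   (data.frame id / reason).
#' @export
druglike_filter <- function(lib, cfg = prep_config()) {
  pass <- list(); fail <- list()
  for (mol in lib) {
    v <- lipinski_violations(mol)
    if (v > cfg$max_lipinski_violations) {
      fail[[length(fail) + 1]] <- data.frame(
        id = mol$id, reason = sprintf("lipinski:%d_violations", v))
      next
    }
    tox <- match_toxicophore(mol, cfg$toxicophore_patterns)
    if (!is.na(tox)) {
      fail[[length(fail) + 1]] <- data.frame(
        id = mol$id, reason = sprintf("toxicophore:%s", tox))
      next
    }
    pass[[length(pass) + 1]] <- mol
  }
  names(pass) <- vapply(pass, `[[`, character(1), "id")
  list(pass = pass,
       fail = if (length(fail)) do.call(rbind, fail) else
         data.frame(id = character(), reason = character()))
}

## First matching toxicophore name, or NA. SMARTS matching goes through the
## Open Babel CLI substructure filter.
match_toxicophore <- function(mol, patterns) {
  if (length(patterns) == 0) return(NA_character_)
  obabel <- require_tool("obabel")
  td <- tempfile("tox"); dir.create(td)
  on.exit(unlink(td, recursive = TRUE), add = TRUE)
  in_sdf <- file.path(td, "in.sdf")
  ChemmineR::write.SDF(mol_sdfset(mol), file = in_sdf)
  nms <- names(patterns) %||% as.character(seq_along(patterns))
  for (k in seq_along(patterns)) {
    out <- suppressWarnings(system2(
      obabel, c(in_sdf, "-osmi", paste0("-s", shQuote(patterns[[k]]))),
      stdout = TRUE, stderr = FALSE))
    if (any(nzchar(trimws(out)))) return(nms[k])
  }
  NA_character_
}

## --- Conformer generation ---------------------------------------------------

require_tool <- function(tool) {
  p <- Sys.which(tool)
  if (!nzchar(p)) stopf("external tool '%s' not found on PATH", tool)
  p
}

#' Generate a conformer ensemble for a molecule
#'
#' Embeds a 3D structure and runs a systematic diverse-conformer search
#' (Open Babel's Confab) bounded by the configured cap, energy window and
#' duplicate-RMSD threshold, then re-evaluates MMFF94 energies so the
#' ensemble contract (all energies within `energy_window` of the minimum)
#' is checkable. The search is systematic, so repeated calls return the
#' same ensemble.
#'
#' @param mol A [vs_molecule()] carrying its parsed record.
#' @param cfg A [prep_config()].
#' @return List of [vs_conformer()] with energies (kcal/mol); attribute
#'   `rng_seed` records the configured seed.
#' @export
generate_conformers <- function(mol, cfg = prep_config()) {
  stopifnot(inherits(mol, "vs_molecule"))
  if (nrow(mol$atoms) == 0) stopf("molecule %s has no atoms", mol$id)
  obabel <- require_tool("obabel")
  obenergy <- require_tool("obenergy")
  td <- tempfile("confsearch"); dir.create(td)
  on.exit(unlink(td, recursive = TRUE), add = TRUE)
  in_sdf <- file.path(td, "in.sdf")
  sdf3d <- file.path(td, "em3d.sdf")
  confs_sdf <- file.path(td, "confs.sdf")
  ChemmineR::write.SDF(mol_sdfset(mol), file = in_sdf)

  run <- function(args) {
    out <- suppressWarnings(system2(obabel, args, stdout = TRUE, stderr = TRUE))
    out
  }
  ## rule-based 3D build at the "fastest" level: it skips the stochastic
  ## rotor search (which would break run-to-run reproducibility); the
  ## systematic torsion search below does the conformational exploration
  run(c(in_sdf, "-O", sdf3d, "--gen3d", "fastest"))
  if (!file.exists(sdf3d) || file.info(sdf3d)$size == 0) {
    stopf("3D embedding failed for molecule %s", mol$id)
  }
  run(c(sdf3d, "-O", confs_sdf, "--confab",
        "--conf", cfg$max_conformers,
        "--ecutoff", cfg$energy_window,
        "--rcutoff", cfg$rms_dedup))
  if (!file.exists(confs_sdf) || file.info(confs_sdf)$size == 0) {
    stopf("conformer generation failed for molecule %s", mol$id)
  }
  sdfset <- suppressWarnings(ChemmineR::read.SDFset(confs_sdf, skipErrors = TRUE))
  n <- length(sdfset)
  eout <- suppressWarnings(system2(obenergy, c("-ff", "MMFF94", confs_sdf),
                                   stdout = TRUE, stderr = TRUE))
  en <- as.numeric(sub(".*TOTAL ENERGY =\\s*([-0-9.eE+]+).*", "\\1",
                       grep("TOTAL ENERGY", eout, value = TRUE)))
  if (length(en) != n) en <- rep(NA_real_, n)
  confs <- lapply(seq_len(n), function(i) {
    ab <- ChemmineR::atomblock(sdfset[[i]])
    bb <- ChemmineR::bondblock(sdfset[[i]])
    cf <- vs_conformer(mol$id, unname(ab[, 1:3, drop = FALSE]),
                       sub("_.*$", "", rownames(ab)),
                       index = i - 1L, energy = en[i])
    ## hydrogenated connection table, so the ensemble can be re-written as a
    ## chemically complete SDF (charges, force-field re-evaluation)
    attr(cf, "bonds") <- data.frame(a1 = as.integer(bb[, 1]),
                                    a2 = as.integer(bb[, 2]),
                                    order = as.integer(bb[, 3]))
    cf
  })
  ## enforce the energy window and cap (defensive: the search already bounds both)
  if (all(!is.na(en))) {
    keep <- which(en - min(en) <= cfg$energy_window)
    confs <- confs[keep]
  }
  confs <- head(confs, cfg$max_conformers)
  attr(confs, "rng_seed") <- cfg$rng_seed
  confs
}
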