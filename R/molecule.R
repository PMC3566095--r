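## Molecular data model and standard-format I/O. Parsing of SMILES and SDF
## V2000 is delegated to ChemmineR/ChemmineOB; this layer converts parsed
## records into a light graph representation (elements, bonds, aromaticity,
## inferred formal charges) that feature perception and fingerprints consume.

#' Construct a molecule
#'
#' @param id Unique identifier within a library.
#' @param atoms data.frame with columns `elem` (symbol), `charge` (formal),
#'   `arom` (logical aromatic flag).
#' @param bonds data.frame with columns `a1`, `a2` (atom indices), `order`.
#' @param name Human-readable name (defaults to the id).
#' @param rings Optional list with `atoms` (list of integer vectors) and
#'   `aromatic` (logical vector), as perceived by the parser.
#' @param sources Character vector of natural-source organisms (may be empty).
#' @param props Named list of free-form properties.
#' @return Object of class `vs_molecule`.
#' @export
vs_molecule <- function(id, atoms, bonds, name = id,
                        rings = list(atoms = list(), aromatic = logical()),
                        sources = character(), props = list()) {
  stopifnot(is.data.frame(atoms), all(c("elem", "charge", "arom") %in% names(atoms)))
  stopifnot(is.data.frame(bonds) || is.null(bonds))
  if (is.null(bonds) || nrow(bonds) == 0) {
    bonds <- data.frame(a1 = integer(), a2 = integer(), order = integer())
  }
  if (nrow(bonds) > 0 &&
      (max(bonds$a1, bonds$a2) > nrow(atoms) || min(bonds$a1, bonds$a2) < 1)) {
    stopf("molecule %s: bond references atom outside 1..%d", id, nrow(atoms))
  }
  structure(list(id = as.character(id), name = as.character(name),
                 atoms = atoms, bonds = bonds, rings = rings,
                 sources = sources, props = props),
            class = "vs_molecule")
}

#' @export
print.vs_molecule <- function(x, ...) {
  nh <- sum(toupper(x$atoms$elem) != "H")
  cat(sprintf("molecule %s: %d atoms (%d heavy), %d bonds, %d rings\n",
              x$id, nrow(x$atoms), nh, nrow(x$bonds),
              length(x$rings$atoms)))
  invisible(x)
}

DEFAULT_VALENCE <- c(C = 4, N = 3, O = 2, S = 2, P = 3, F = 1, CL = 1,
                     BR = 1, I = 1, B = 3, SI = 4, H = 1)

## Sum of bond orders at each atom.
bond_order_sums <- function(mol) {
  s <- numeric(nrow(mol$atoms))
  if (nrow(mol$bonds) > 0) {
    for (i in seq_len(nrow(mol$bonds))) {
      o <- mol$bonds$order[i]
      s[mol$bonds$a1[i]] <- s[mol$bonds$a1[i]] + o
      s[mol$bonds$a2[i]] <- s[mol$bonds$a2[i]] + o
    }
  }
  s
}

## Implicit hydrogen count from default valences (kekulized bond orders).
implicit_h <- function(mol) {
  bs <- bond_order_sums(mol)
  v <- DEFAULT_VALENCE[toupper(mol$atoms$elem)]
  v[is.na(v)] <- 0
  nH <- pmax(0, v - bs + mol$atoms$charge)
  nH[toupper(mol$atoms$elem) == "H"] <- 0
  ## explicit hydrogens already present satisfy the valence via bonds
  nH
}

## Formal charge inferred from hypervalence (quaternary N, oxonium O);
## used when the source format did not carry charge annotations.
infer_formal_charges <- function(elem, bond_sums, given = NULL) {
  ch <- given %||% rep(0, length(elem))
  e <- toupper(elem)
  ch[e == "N" & bond_sums >= 4 & ch == 0] <- 1
  ch[e == "O" & bond_sums >= 3 & ch == 0] <- 1
  ch
}

## --- Conversion from ChemmineR SDF objects ---------------------------------

## V2000 charge column codes: 1..7 -> +3 +2 +1 radical -1 -2 -3
v2000_charge <- function(code) {
  map <- c(`1` = 3, `2` = 2, `3` = 1, `4` = 0, `5` = -1, `6` = -2, `7` = -3)
  out <- map[as.character(code)]
  out[is.na(out)] <- 0
  unname(out)
}

#' Convert a ChemmineR SDF record to a molecule
#'
#' @param sdf A `ChemmineR::SDF` object.
#' @param id Identifier to assign.
#' @return A [vs_molecule()]; the record's 3D (or 2D) coordinates are
#'   attached as attribute `conformer`, a [vs_conformer()].
#' @export
as_vs_molecule <- function(sdf, id = NULL) {
  stopifnot(is(sdf, "SDF"))
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elem <- sub("_.*$", "", rownames(ab))
  coords <- unname(ab[, 1:3, drop = FALSE])
  charge <- if (ncol(ab) >= 5) v2000_charge(ab[, 5]) else rep(0, nrow(ab))
  bonds <- if (is.null(bb) || nrow(bb) == 0) {
    data.frame(a1 = integer(), a2 = integer(), order = integer())
  } else {
    data.frame(a1 = as.integer(bb[, 1]), a2 = as.integer(bb[, 2]),
               order = as.integer(bb[, 3]))
  }
  atoms <- data.frame(elem = elem, charge = charge, arom = FALSE,
                      stringsAsFactors = FALSE)
  rings <- perceive_rings(sdf, elem)
  for (k in seq_along(rings$atoms)) {
    if (rings$aromatic[k]) atoms$arom[rings$atoms[[k]]] <- TRUE
  }
  hdr <- tryCatch(ChemmineR::header(sdf), error = function(e) NULL)
  nm <- if (!is.null(hdr) && nzchar(hdr[["Molecule_Name"]] %||% "")) {
    hdr[["Molecule_Name"]]
  } else id %||% "unnamed"
  id <- id %||% nm
  bsum <- bond_order_sums(vs_molecule("tmp", atoms, bonds))
  atoms$charge <- infer_formal_charges(elem, bsum, atoms$charge)
  mol <- vs_molecule(id, atoms, bonds, name = nm, rings = rings)
  attr(mol, "conformer") <- vs_conformer(id, coords, elem, index = 0L)
  attr(mol, "sdf") <- sdf      # retained for descriptor/SMARTS backends
  mol
}

## ChemmineR's S4 classes resolved from its namespace (the package is a
## dependency, not attached).
new_chemmine <- function(class_name, ...) {
  methods::new(methods::getClass(class_name, where = asNamespace("ChemmineR")),
               ...)
}

## Single-molecule SDFset for ChemmineR/ChemmineOB backends.
mol_sdfset <- function(mol) {
  sdf <- attr(mol, "sdf")
  if (is.null(sdf)) stopf("molecule %s carries no parsed SDF record", mol$id)
  sdfs <- list(sdf); names(sdfs) <- mol$id
  new_chemmine("SDFset", SDF = sdfs, ID = mol$id)
}

## Ring perception with aromaticity, via ChemmineR; failures degrade to
## "no rings" rather than aborting a library read.
perceive_rings <- function(sdf, elem) {
  out <- tryCatch(
    ChemmineR::rings(sdf, upper = 8, type = "all", arom = TRUE),
    error = function(e) list(RINGS = list(), AROMATIC = logical()))
  ring_atoms <- lapply(out$RINGS, function(r) as.integer(sub("^.*_", "", r)))
  list(atoms = ring_atoms, aromatic = as.logical(out$AROMATIC))
}

## Fallback for bond-less (single-heavy-atom) V2000 records, which the
## ChemmineR parser flags invalid and mangles: read the fixed-format atom
## lines directly. Returns NULL when the record is genuinely unparseable.
parse_bondless_record <- function(lines, id) {
  if (length(lines) < 5) return(NULL)
  counts <- strsplit(trimws(lines[4]), "\\s+")[[1]]
  n_atoms <- suppressWarnings(as.integer(counts[1]))
  n_bonds <- suppressWarnings(as.integer(counts[2]))
  if (is.na(n_atoms) || is.na(n_bonds) || n_bonds != 0 || n_atoms < 1) {
    return(NULL)
  }
  if (length(lines) < 4 + n_atoms) return(NULL)
  fields <- strsplit(trimws(lines[5:(4 + n_atoms)]), "\\s+")
  coords <- t(vapply(fields, function(f) as.numeric(f[1:3]), numeric(3)))
  elem <- vapply(fields, `[`, character(1), 4)
  if (any(is.na(coords)) || any(is.na(elem))) return(NULL)
  atoms <- data.frame(elem = elem, charge = 0, arom = FALSE,
                      stringsAsFactors = FALSE)
  nm <- trimws(lines[1])
  mol <- vs_molecule(id, atoms, NULL, name = if (nzchar(nm)) nm else id)
  conf <- vs_conformer(id, coords, elem, index = 0L)
  attr(mol, "conformer") <- conf
  attr(mol, "sdf") <- conformer_to_sdf(conf, title = mol$name)
  mol
}

#' Read a compound library from SMILES or SDF
#'
#' Parse failures are collected per record (attribute `failures`), not fatal;
#' a file with zero valid records is an error.
#'
#' @param path File path. SMILES files are one record per line,
#'   whitespace-separated `SMILES [id]`; SDF is V2000.
#' @param format `"smiles"` or `"sdf"` (default guessed from the extension).
#' @return List of [vs_molecule()] with unique ids (record name where
#'   available, else a running index), each carrying its parsed coordinates
#'   as attribute `conformer`. Attribute `failures` is a data.frame of
#'   (record, reason) for unparseable records.
#' @export
read_library <- function(path, format = c("auto", "smiles", "sdf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("cannot read library: %s", path)
  if (format == "auto") {
    format <- if (grepl("\\.(smi|smiles|ism)$", path, ignore.case = TRUE))
      "smiles" else "sdf"
  }
  mols <- list()
  fails <- list()
  if (format == "smiles") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    for (i in seq_along(lines)) {
      tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
      smi <- tok[1]
      id <- if (length(tok) >= 2) tok[2] else sprintf("M%05d", i)
      sdf <- tryCatch({
        x <- smi; names(x) <- id
        suppressWarnings(ChemmineR::smiles2sdf(x))[[1]]
      }, error = function(e) e)
      parsed <- if (inherits(sdf, "error") ||
                    ncol(ChemmineR::atomblock(sdf)) < 3) {
        ## bond-less records mis-parse upstream; retry on the raw V2000 text
        txt <- tryCatch(
          ChemmineOB::convertFormat("SMI", "SDF", paste0(smi, " ", id, "\n")),
          error = function(e) "")
        parse_bondless_record(strsplit(txt, "\n")[[1]], id)
      } else {
        as_vs_molecule(sdf, id = id)
      }
      if (is.null(parsed)) {
        fails[[length(fails) + 1]] <- data.frame(
          record = i, reason = sprintf("unparseable SMILES '%s'", smi))
        next
      }
      mols[[length(mols) + 1]] <- parsed
    }
  } else {
    sdfset <- tryCatch(
      suppressWarnings(ChemmineR::read.SDFset(path, skipErrors = TRUE)),
      error = function(e) stopf("cannot parse SDF %s: %s", path, conditionMessage(e)))
    valid <- ChemmineR::validSDF(sdfset)
    ## raw record texts, for the bond-less fallback
    raw <- readLines(path, warn = FALSE)
    ends <- grep("^\\$\\$\\$\\$", raw)
    starts <- c(1, head(ends, -1) + 1)
    for (i in seq_along(sdfset)) {
      id <- sprintf("M%05d", i)
      if (!valid[i]) {
        parsed <- if (i <= length(starts)) {
          parse_bondless_record(raw[starts[i]:ends[i]], id)
        } else NULL
        if (is.null(parsed)) {
          fails[[length(fails) + 1]] <- data.frame(
            record = i, reason = "invalid SDF record")
        } else {
          mols[[length(mols) + 1]] <- parsed
        }
        next
      }
      mols[[length(mols) + 1]] <- as_vs_molecule(sdfset[[i]], id = id)
    }
  }
  if (length(mols) == 0) stopf("empty library: no valid records in %s", path)
  ## enforce unique ids
  ids <- vapply(mols, `[[`, character(1), "id")
  dup <- duplicated(ids)
  if (any(dup)) {
    for (i in which(dup)) mols[[i]]$id <- sprintf("%s_%d", mols[[i]]$id, i)
    ids <- vapply(mols, `[[`, character(1), "id")
  }
  names(mols) <- ids
  attr(mols, "failures") <- if (length(fails)) do.call(rbind, fails) else
    data.frame(record = integer(), reason = character())
  for (f in fails) vs_log("read_library: record ", f$record, " skipped: ",
                          f$reason, level = "warn")
  mols
}

## --- SDF writing ------------------------------------------------------------

## Build a ChemmineR SDF object from a conformer (+ optional bonds).
conformer_to_sdf <- function(conf, bonds = NULL, title = conf$mol_id,
                             datablock = character()) {
  n <- nrow(conf$coords)
  ab <- cbind(conf$coords, matrix(0, n, 13))
  rownames(ab) <- paste(conf$elem, seq_len(n), sep = "_")
  colnames(ab) <- c("C1", "C2", "C3", paste0("C", 5:17))
  if (is.null(bonds) || nrow(bonds) == 0) {
    bb <- matrix(0, 0, 7)
  } else {
    bb <- cbind(as.matrix(bonds[, c("a1", "a2", "order")]), matrix(0, nrow(bonds), 4))
  }
  colnames(bb) <- paste0("C", 1:7)
  if (nrow(bb) > 0) rownames(bb) <- seq_len(nrow(bb))
  header <- c(Molecule_Name = title, Source = "ppargscreen",
              Comment = "", Counts_Line = sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                                                  n, nrow(bb)))
  if (length(datablock) == 0) datablock <- c(ppargscreen = "1")
  new_chemmine("SDF", header = header, atomblock = ab, bondblock = bb,
               datablock = datablock)
}

#' Write conformers to a (multi-record) SDF file
#'
#' @param conformers List of [vs_conformer()].
#' @param path Output path.
#' @param bonds Optional list of bond data.frames, parallel to `conformers`.
#' @param extra_props Optional list of named character vectors per conformer
#'   written into the SDF data block (e.g. a docking score).
#' @return `path`, invisibly.
#' @export
write_conformers_sdf <- function(conformers, path, bonds = NULL,
                                 extra_props = NULL) {
  sdfs <- lapply(seq_along(conformers), function(i) {
    cf <- conformers[[i]]
    db <- c(conformer_index = as.character(cf$index))
    if (!is.null(cf$energy)) db <- c(db, energy_kcal = sprintf("%.6f", cf$energy))
    if (!is.null(cf$pose_score)) db <- c(db, pose_score = sprintf("%.6f", cf$pose_score))
    if (!is.null(cf$charges)) {
      db <- c(db, partial_charges = paste(sprintf("%.6f", cf$charges), collapse = " "))
    }
    if (!is.null(extra_props) && !is.null(extra_props[[i]])) db <- c(db, extra_props[[i]])
    conformer_to_sdf(cf, bonds = if (!is.null(bonds)) bonds[[i]] else NULL,
                     datablock = db)
  })
  ids <- make.unique(vapply(conformers, `[[`, character(1), "mol_id"))
  names(sdfs) <- ids
  sdfset <- new_chemmine("SDFset", SDF = sdfs, ID = ids)
  ChemmineR::write.SDF(sdfset, file = path)
  invisible(path)
}

#' Read conformers back from an SDF written by [write_conformers_sdf()]
#'
#' @param path SDF path.
#' @param score_property Optional data-block field to read into `pose_score`.
#' @return List of [vs_conformer()].
#' @export
read_conformers_sdf <- function(path, score_property = "pose_score") {
  sdfset <- suppressWarnings(ChemmineR::read.SDFset(path, skipErrors = TRUE))
  lapply(seq_along(sdfset), function(i) {
    sdf <- sdfset[[i]]
    ab <- ChemmineR::atomblock(sdf)
    db <- ChemmineR::datablock(sdf)
    hdr <- ChemmineR::header(sdf)
    elem <- sub("_.*$", "", rownames(ab))
    charges <- NULL
    if (!is.null(db) && "partial_charges" %in% names(db)) {
      charges <- as.numeric(strsplit(db[["partial_charges"]], " ")[[1]])
    }
    score <- if (!is.null(db) && score_property %in% names(db))
      as.numeric(db[[score_property]]) else NULL
    energy <- if (!is.null(db) && "energy_kcal" %in% names(db))
      as.numeric(db[["energy_kcal"]]) else NULL
    idx <- if (!is.null(db) && "conformer_index" %in% names(db))
      as.integer(db[["conformer_index"]]) else i - 1L
    vs_conformer(hdr[["Molecule_Name"]], unname(ab[, 1:3, drop = FALSE]),
                 elem, index = idx, energy = energy, charges = charges,
                 pose_score = score)
  })
}

## --- Tabular report I/O -----------------------------------------------------

#' Write a tabular report as TSV or JSON
#'
#' Numeric columns are serialized at full precision so the matching
#' [read_report()] round-trips losslessly.
#'
#' @param report A data.frame (all rows share the schema).
#' @param path Output path.
#' @param format `"tsv"` or `"json"` (default from extension).
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, format = c("auto", "tsv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "tsv"
  }
  stopifnot(is.data.frame(report))
  if (format == "json") {
    jsonlite::write_json(report, path, dataframe = "rows", digits = NA,
                         auto_unbox = TRUE, pretty = TRUE, na = "null")
  } else {
    out <- report
    for (j in seq_along(out)) {
      if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
    }
    ok <- tryCatch({
      write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
      TRUE
    }, error = function(e) FALSE, warning = function(w) FALSE)
    if (!ok) stopf("cannot write report to %s", path)
  }
  invisible(path)
}

#' Read a tabular report written by [write_report()]
#'
#' @param path Input path.
#' @param format `"tsv"` or `"json"` (default from extension).
#' @return A data.frame.
#' @export
read_report <- function(path, format = c("auto", "tsv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "tsv"
  }
  if (!file.exists(path)) stopf("cannot read report: %s", path)
  if (format == "json") {
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  } else {
    read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  }
}
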