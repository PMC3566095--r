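## Core value types shared across the cascade: conformers and feature points.
## Conformers carry their element symbols alongside the coordinates so that
## purely geometric stages (pharmacophore, shape, electrostatics) never need
## to walk back to the molecular graph; synthetic feature clouds use the same
## container.

#' Construct a conformer
#'
#' A single 3D realization of a molecule: Cartesian coordinates in Angstrom,
#' element symbols, and optional force-field energy (kcal/mol), per-atom
#' partial charges (elementary units) and docking pose score.
#'
#' @param mol_id Molecule identifier the conformer belongs to.
#' @param coords n x 3 numeric matrix of positions (Angstrom).
#' @param elem Character vector of element symbols, length n.
#' @param index Non-negative conformer index within the ensemble.
#' @param energy Optional energy in kcal/mol.
#' @param charges Optional numeric vector of partial charges, length n.
#' @param pose_score Optional dimensionless docking score (lower = better).
#' @return Object of class `vs_conformer`.
#' @export
vs_conformer <- function(mol_id, coords, elem, index = 0L, energy = NULL,
                         charges = NULL, pose_score = NULL) {
  coords <- as.matrix(coords)
  if (ncol(coords) != 3) stopf("coords must be an n x 3 matrix")
  storage.mode(coords) <- "double"
  n <- nrow(coords)
  if (length(elem) != n) stopf("elem length (%d) != atom count (%d)",
                               length(elem), n)
  if (!is_count(index)) stopf("index must be a non-negative integer")
  if (!is.null(charges) && length(charges) != n) {
    stopf("charges length (%d) != atom count (%d)", length(charges), n)
  }
  structure(
    list(mol_id = as.character(mol_id), index = as.integer(index),
         coords = coords, elem = as.character(elem),
         energy = energy, charges = charges, pose_score = pose_score),
    class = "vs_conformer"
  )
}

#' @export
print.vs_conformer <- function(x, ...) {
  cat(sprintf("conformer %s#%d: %d atoms%s%s%s\n", x$mol_id, x$index,
              nrow(x$coords),
              if (!is.null(x$energy)) sprintf(", E=%.2f kcal/mol", x$energy) else "",
              if (!is.null(x$charges)) ", charged" else "",
              if (!is.null(x$pose_score)) sprintf(", score=%.3f", x$pose_score) else ""))
  invisible(x)
}

## Heavy-atom (non-hydrogen) selector.
heavy_idx <- function(conf) which(toupper(conf$elem) != "H")

#' Construct a pharmacophore feature point
#'
#' @param kind One of `"acceptor"`, `"donor"`, `"hydrophobic"`,
#'   `"aromatic_hydrophobic"`, `"aromatic"`, `"positive"`, `"negative"`.
#' @param position Length-3 numeric, Angstrom.
#' @param atom_indices Integer indices of the contributing atoms.
#' @return Object of class `feature_point`.
#' @export
feature_point <- function(kind, position, atom_indices = integer()) {
  kind <- match.arg(kind, FEATURE_KINDS)
  position <- as.numeric(position)
  stopifnot(length(position) == 3)
  structure(list(kind = kind, position = position,
                 atom_indices = as.integer(atom_indices)),
            class = "feature_point")
}

#' Recognized feature kinds
#' @export
FEATURE_KINDS <- c("acceptor", "donor", "hydrophobic",
                   "aromatic_hydrophobic", "aromatic",
                   "positive", "negative")

## Feature list -> matrix of positions / vector of kinds.
feature_positions <- function(feats) {
  if (length(feats) == 0) return(matrix(numeric(0), 0, 3))
  do.call(rbind, lapply(feats, `[[`, "position"))
}
feature_kinds <- function(feats) vapply(feats, `[[`, character(1), "kind")

#' Bondi van der Waals radius by element
#'
#' @param elem Character vector of element symbols.
#' @return Numeric vector of radii (Angstrom); 1.70 for unknown elements.
#' @export
vdw_radius <- function(elem) {
  tab <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, F = 1.47, P = 1.80,
           S = 1.80, CL = 1.75, BR = 1.85, I = 1.98, SI = 2.10, B = 1.92)
  r <- tab[toupper(elem)]
  r[is.na(r)] <- 1.70
  unname(r)
}
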