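## Pharmacophore feature perception. The rule table is shipped as an
## editable YAML file (inst/extdata/feature_rules.yaml) mapping rule names to
## built-in perceivers with their parameters, a transparent surrogate for a
## modeling suite's proprietary feature definitions. The one behavior pinned
## by the workflow itself is the aromatic-ring amendment: with
## `aromatic_as_hydrophobic = TRUE` every aromatic ring contributes one
## hydrophobic-compatible feature at its centroid.

#' Load a feature-rule table
#'
#' @param path YAML rule file; default is the table shipped with the package.
#' @return List of rule descriptors (class `feature_rules`).
#' @export
load_feature_rules <- function(path = NULL) {
  path <- path %||% system.file("extdata", "feature_rules.yaml",
                                package = "ppargscreen")
  if (!nzchar(path) || !file.exists(path)) stopf("feature rule file not found")
  obj <- yaml::read_yaml(path)
  if (is.null(obj$rules)) stopf("feature rule file has no 'rules' entry")
  structure(obj$rules, class = "feature_rules")
}

#' Perceive pharmacophore features of a conformer
#'
#' Applies the rule table to the molecular graph and places features on the
#' conformer's coordinates: single-atom features at the atom, multi-atom
#' features (aromatic rings, aliphatic carbon groups) at the unweighted
#' centroid of their heavy atoms.
#'
#' @param conf A [vs_conformer()] belonging to `mol`.
#' @param mol The parsed [vs_molecule()].
#' @param rules A [load_feature_rules()] table (default: shipped table).
#' @param aromatic_as_hydrophobic Treat aromatic rings as hydrophobic groups?
#'   When `TRUE` (the workflow's setting) ring centroids are emitted as
#'   `aromatic_hydrophobic`, matchable by hydrophobic sites; when `FALSE`
#'   they are plain `aromatic` features.
#' @return List of [feature_point()]s.
#' @export
perceive_features <- function(conf, mol, rules = load_feature_rules(),
                              aromatic_as_hydrophobic = TRUE) {
  stopifnot(inherits(conf, "vs_conformer"), inherits(mol, "vs_molecule"))
  if (nrow(conf$coords) != nrow(mol$atoms) ||
      !identical(toupper(conf$elem), toupper(mol$atoms$elem))) {
    stopf("conformer does not belong to molecule %s (atom mismatch)", mol$id)
  }
  elem <- toupper(mol$atoms$elem)
  arom <- mol$atoms$arom
  charge <- mol$atoms$charge
  bsum <- bond_order_sums(mol)
  nH_imp <- implicit_h(mol)
  adj <- adjacency_list(mol)
  coords <- conf$coords

  feats <- list()
  add <- function(kind, idx) {
    pos <- colMeans(coords[idx, , drop = FALSE])
    feats[[length(feats) + 1]] <<- feature_point(kind, pos, idx)
  }

  for (rule in rules) {
    method <- rule$method %||% ""
    if (method == "lone_pair_n_o") {
      ## H-bond acceptor: N or O bearing a lone pair and no positive charge
      for (i in which((elem == "N" | elem == "O") & charge <= 0)) {
        if (elem[i] == "N" && bsum[i] >= 4) next
        if (elem[i] == "O" && bsum[i] >= 3) next
        add(rule$kind, i)
      }
    } else if (method == "h_on_n_o") {
      ## H-bond donor: N-H or O-H; hydrogens may be implicit
      for (i in which(elem == "N" | elem == "O")) {
        explicit_h <- sum(elem[adj[[i]]] == "H")
        if (explicit_h + nH_imp[i] > 0) add(rule$kind, i)
      }
    } else if (method == "aliphatic_carbon_group") {
      min_size <- rule$min_size %||% 3
      elig <- eligible_aliphatic_carbons(mol, elem, arom)
      for (comp in connected_components(adj, which(elig))) {
        if (length(comp) >= min_size) add(rule$kind, comp)
      }
    } else if (method == "halogen_on_aromatic") {
      for (i in which(elem %in% c("F", "CL", "BR", "I"))) {
        if (any(arom[adj[[i]]])) add(rule$kind, i)
      }
    } else if (method == "aromatic_ring_centroid") {
      kind <- if (aromatic_as_hydrophobic) "aromatic_hydrophobic" else "aromatic"
      for (k in seq_along(mol$rings$atoms)) {
        if (isTRUE(mol$rings$aromatic[k])) add(kind, mol$rings$atoms[[k]])
      }
    } else if (method == "formal_charge") {
      for (i in which(charge > 0)) add("positive", i)
      for (i in which(charge < 0)) add("negative", i)
    } else {
      stopf("unknown feature rule method '%s'", method)
    }
  }
  feats
}

## Aliphatic carbons eligible for hydrophobic grouping: non-aromatic C with
## no multiple bond to a heteroatom (excludes carbonyl/nitrile carbons).
eligible_aliphatic_carbons <- function(mol, elem, arom) {
  elig <- elem == "C" & !arom
  if (nrow(mol$bonds) > 0) {
    for (b in seq_len(nrow(mol$bonds))) {
      if (mol$bonds$order[b] < 2) next
      a1 <- mol$bonds$a1[b]; a2 <- mol$bonds$a2[b]
      if (elem[a1] == "C" && elem[a2] %in% c("N", "O", "S")) elig[a1] <- FALSE
      if (elem[a2] == "C" && elem[a1] %in% c("N", "O", "S")) elig[a2] <- FALSE
    }
  }
  elig
}

## Connected components of the subgraph induced by `nodes`.
connected_components <- function(adj, nodes) {
  comps <- list()
  seen <- logical(length(adj))
  for (s in nodes) {
    if (seen[s]) next
    comp <- integer(); frontier <- s; seen[s] <- TRUE
    while (length(frontier) > 0) {
      comp <- c(comp, frontier)
      nxt <- unique(unlist(adj[frontier]))
      nxt <- nxt[nxt %in% nodes & !seen[nxt]]
      seen[nxt] <- TRUE
      frontier <- nxt
    }
    comps[[length(comps) + 1]] <- sort(comp)
  }
  comps
}
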