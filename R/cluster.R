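## Scaffold analysis of screening hits: circular atom-environment
## fingerprints, set Tanimoto similarity, deterministic agglomerative
## clustering, and Kelley-criterion selection of the cluster count.

#' Circular atom-environment fingerprint
#'
#' For every heavy atom, the environments of radius 0, 1 and 2 bonds are
#' encoded as the center's atom type together with the sorted multiset of
#' (distance, neighbor type) pairs inside the radius, then hashed into a
#' `width`-bit address space. The fingerprint is the set of distinct hashed
#' environment identifiers, so two molecules are compared by set Tanimoto.
#'
#' @param mol A [vs_molecule()] (parsed graph with aromaticity flags).
#' @param width Hash precision in bits (default 32).
#' @return Object of class `vs_fingerprint`: sorted numeric vector of hashed
#'   identifiers plus the width.
#' @export
fingerprint <- function(mol, width = 32) {
  stopifnot(inherits(mol, "vs_molecule"), width >= 1, width <= 32)
  atoms <- mol$atoms
  hv <- which(toupper(atoms$elem) != "H")
  if (length(hv) == 0) stopf("fingerprint: molecule %s has no heavy atoms", mol$id)
  type <- paste0(toupper(atoms$elem), ifelse(atoms$arom, "ar", ""))
  adj <- adjacency_list(mol)
  feats <- character()
  for (a in hv) {
    dist_a <- bfs_distances(adj, a, max_depth = 2, keep = hv)
    for (r in 0:2) {
      inside <- which(dist_a >= 1 & dist_a <= r)
      shell <- sort(paste0(dist_a[inside], ";", type[inside]))
      feats <- c(feats, paste0("r", r, "|", type[a], "|",
                               paste(shell, collapse = ",")))
    }
  }
  hashes <- vapply(unique(feats), fnv1a32, numeric(1), USE.NAMES = FALSE)
  hashes <- sort(unique(hashes %% 2^width))
  structure(list(hashes = hashes, width = as.integer(width)),
            class = "vs_fingerprint")
}

adjacency_list <- function(mol) {
  n <- nrow(mol$atoms)
  adj <- vector("list", n)
  for (i in seq_len(nrow(mol$bonds))) {
    a <- mol$bonds$a1[i]; b <- mol$bonds$a2[i]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  adj
}

## Graph distances from a source atom, restricted to `keep` atoms (heavy).
bfs_distances <- function(adj, from, max_depth, keep) {
  n <- length(adj)
  d <- rep(Inf, n)
  d[from] <- 0
  frontier <- from
  depth <- 0
  while (length(frontier) > 0 && depth < max_depth) {
    depth <- depth + 1
    nxt <- unique(unlist(adj[frontier]))
    nxt <- nxt[nxt %in% keep & d[nxt] == Inf]
    d[nxt] <- depth
    frontier <- nxt
  }
  d
}

#' Set Tanimoto similarity of two fingerprints
#'
#' @param fa,fb [fingerprint()] objects of equal width.
#' @return `|A intersect B| / |A union B|` in `[0, 1]`.
#' @export
tanimoto <- function(fa, fb) {
  stopifnot(inherits(fa, "vs_fingerprint"), inherits(fb, "vs_fingerprint"))
  if (fa$width != fb$width) stopf("fingerprint widths differ (%d vs %d)",
                                  fa$width, fb$width)
  if (length(fa$hashes) == 0 && length(fb$hashes) == 0) {
    warning("both fingerprints empty; Tanimoto defined as 1")
    return(1.0)
  }
  inter <- length(intersect(fa$hashes, fb$hashes))
  inter / (length(fa$hashes) + length(fb$hashes) - inter)
}

#' Pairwise Tanimoto-distance matrix of a fingerprint list
#'
#' @param fps Named list of [fingerprint()]s.
#' @return Symmetric matrix of distances `1 - tanimoto`.
#' @export
tanimoto_distance_matrix <- function(fps) {
  n <- length(fps)
  ids <- names(fps) %||% as.character(seq_len(n))
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  if (n > 1) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <- 1 - tanimoto(fps[[i]], fps[[j]])
    }
  }
  d
}

#' Deterministic agglomerative clustering on Tanimoto distances
#'
#' Standard agglomeration with Lance-Williams distance updates and a fixed
#' tie-break: among minimum-distance cluster pairs, the pair whose
#' (lexicographically smallest member id, then second id) sorts first is
#' merged. The result is an `hclust`-compatible tree, so [stats::cutree()]
#' and [stats::cophenetic()] apply.
#'
#' @param x Named list of [fingerprint()]s, or a symmetric distance matrix
#'   with dimnames.
#' @param linkage `"average"` (default), `"complete"` or `"single"`.
#' @return Object of classes `vs_dendrogram` and `hclust`, with the original
#'   distance matrix attached as attribute `distances`.
#' @export
cluster_molecules <- function(x, linkage = c("average", "complete", "single")) {
  linkage <- match.arg(linkage)
  d0 <- if (is.matrix(x)) x else tanimoto_distance_matrix(x)
  n <- nrow(d0)
  if (n < 2) stopf("clustering needs at least 2 molecules")
  ids <- rownames(d0) %||% as.character(seq_len(n))

  d <- d0
  active <- seq_len(n)
  members <- as.list(seq_len(n))          # leaf indices per live cluster
  node <- -seq_len(n)                     # hclust merge codes
  sizes <- rep(1L, n)
  rep_id <- ids                           # lexicographically smallest member id
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)

  for (step in seq_len(n - 1)) {
    best <- NULL
    for (ii in seq_along(active)) {
      if (ii == length(active)) break
      for (jj in (ii + 1):length(active)) {
        i <- active[ii]; j <- active[jj]
        key_ids <- sort(c(rep_id[i], rep_id[j]))
        cand <- list(i = i, j = j, d = d[i, j], key = key_ids)
        if (is.null(best) || cand$d < best$d - 1e-12 ||
            (abs(cand$d - best$d) <= 1e-12 &&
             (cand$key[1] < best$key[1] ||
              (cand$key[1] == best$key[1] && cand$key[2] < best$key[2])))) {
          best <- cand
        }
      }
    }
    i <- best$i; j <- best$j
    merge[step, ] <- sort_merge_codes(node[i], node[j])
    height[step] <- best$d
    ## Lance-Williams update into slot i; retire slot j
    for (k in active) {
      if (k == i || k == j) next
      d[i, k] <- d[k, i] <- switch(linkage,
        average = (sizes[i] * d[i, k] + sizes[j] * d[j, k]) / (sizes[i] + sizes[j]),
        complete = max(d[i, k], d[j, k]),
        single = min(d[i, k], d[j, k]))
    }
    members[[i]] <- c(members[[i]], members[[j]])
    sizes[i] <- sizes[i] + sizes[j]
    rep_id[i] <- min(rep_id[i], rep_id[j])
    node[i] <- step
    active <- active[active != j]
  }

  tree <- structure(
    list(merge = merge, height = height, order = tree_order(merge, n),
         labels = ids, method = linkage,
         call = match.call(), dist.method = "1 - Tanimoto"),
    class = c("vs_dendrogram", "hclust"))
  attr(tree, "distances") <- d0
  tree
}

## hclust convention: two singletons ordered by leaf index (-1 before -2),
## singleton before cluster, two clusters by merge step.
sort_merge_codes <- function(a, b) {
  swap <- (a < 0 && b < 0 && a < b) || (a > 0 && b > 0 && a > b) ||
    (a > 0 && b < 0)
  if (swap) c(b, a) else c(a, b)
}

tree_order <- function(merge, n) {
  expand <- function(code) {
    if (code < 0) return(-code)
    c(expand(merge[code, 1]), expand(merge[code, 2]))
  }
  expand(n - 1)
}

#' Kelley-criterion selection of the number of clusters
#'
#' For each dendrogram level with `k` clusters (`k = 2 .. n-1`; the trivial
#' one-cluster and all-singleton levels are excluded), the spread is the mean
#' over clusters of size >= 2 of their mean pairwise distance (original
#' distances, not cophenetic). Spreads are min-max normalized onto
#' `[1, n-2]` so their range matches the range of `k`, and the level
#' minimizing `penalty(k) = normalized_spread(k) + k` is selected, ties going
#' to the smaller `k`.
#'
#' @param tree A [cluster_molecules()] result (or any `hclust` with a
#'   `distances` attribute).
#' @param distances Optional distance matrix overriding the attribute.
#' @return Object of class `cluster_selection`: `k`, `assignments` (named
#'   cluster ids at the selected level) and `levels`, a data.frame of
#'   (k, spread, normalized, penalty).
#' @export
kelley_select <- function(tree, distances = NULL) {
  stopifnot(inherits(tree, "hclust"))
  d <- distances %||% attr(tree, "distances")
  if (is.null(d)) stopf("kelley_select needs the original distance matrix")
  n <- length(tree$labels)
  if (n < 3) stopf("Kelley selection needs at least 3 leaves")
  if (all(d[upper.tri(d)] <= 1e-12)) {
    warning("all molecules identical; selecting a single cluster")
    asg <- rep(1L, n); names(asg) <- tree$labels
    return(structure(list(k = 1L, assignments = asg,
                          levels = data.frame()), class = "cluster_selection"))
  }
  ks <- 2:(n - 1)
  spread <- vapply(ks, function(k) {
    cl <- stats::cutree(tree, k = k)
    per <- vapply(unique(cl), function(g) {
      idx <- which(cl == g)
      if (length(idx) < 2) return(NA_real_)
      mean(d[idx, idx][upper.tri(d[idx, idx])])
    }, numeric(1))
    mean(per, na.rm = TRUE)
  }, numeric(1))
  rng <- range(spread)
  normalized <- if (diff(rng) < 1e-15) rep(1, length(ks)) else
    (spread - rng[1]) / diff(rng) * (n - 3) + 1
  penalty <- normalized + ks
  k_sel <- ks[which.min(penalty)]   # which.min takes the first = smallest k
  asg <- stats::cutree(tree, k = k_sel)
  structure(list(k = as.integer(k_sel), assignments = asg,
                 levels = data.frame(k = ks, spread = spread,
                                     normalized = normalized,
                                     penalty = penalty)),
            class = "cluster_selection")
}

#' @export
print.cluster_selection <- function(x, ...) {
  cat(sprintf("Kelley selection: k = %d clusters\n", x$k))
  invisible(x)
}

#' Novelty assessment of hits against reference actives
#'
#' Clusters hits and references together, selects the level by the Kelley
#' criterion, and flags each hit by whether any reference molecule falls in
#' its cluster (scaffolds shared with known actives) or not (novel).
#'
#' @param hit_fps Named list of hit [fingerprint()]s.
#' @param ref_fps Named list of reference [fingerprint()]s.
#' @param linkage Linkage passed to [cluster_molecules()].
#' @return List with `table` (data.frame: id, cluster, contains_reference),
#'   `selection` and `tree`.
#' @export
novelty_report <- function(hit_fps, ref_fps, linkage = "average") {
  if (length(intersect(names(hit_fps), names(ref_fps))) > 0) {
    stopf("hit and reference ids overlap")
  }
  all_fps <- c(hit_fps, ref_fps)
  tree <- cluster_molecules(all_fps, linkage = linkage)
  sel <- kelley_select(tree)
  cl <- sel$assignments
  ref_clusters <- unique(cl[names(ref_fps)])
  tab <- data.frame(
    id = names(hit_fps),
    cluster = unname(cl[names(hit_fps)]),
    contains_reference = unname(cl[names(hit_fps)] %in% ref_clusters),
    stringsAsFactors = FALSE)
  list(table = tab, selection = sel, tree = tree)
}
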