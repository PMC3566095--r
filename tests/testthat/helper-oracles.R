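# Independent oracles: plain, unoptimized re-derivations of the quantities
# the package computes, used to pin expected values. They deliberately avoid
# the package's internal code paths (no pruning, no incremental updates).

## --- Brute-force pharmacophore matching ------------------------------------

oracle_fit <- function(x, y) {
  cx <- colMeans(x); cy <- colMeans(y)
  h <- t(sweep(x, 2, cx)) %*% sweep(y, 2, cy)
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u))); if (d == 0) d <- 1
  r <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  tv <- cy - as.vector(r %*% cx)
  list(r = r, t = tv)
}

## Exhaustive enumeration over all site subsets of size >= min_match and all
## injective kind-compatible feature assignments; per-assignment rigid fit;
## same acceptance rules and tie-break order as the contract specifies.
oracle_match <- function(conf, feats, model, reorient = TRUE) {
  site_pos <- do.call(rbind, lapply(model$sites, `[[`, "position"))
  site_tol <- vapply(model$sites, `[[`, numeric(1), "tolerance")
  site_kind <- vapply(model$sites, `[[`, character(1), "kind")
  fk <- vapply(feats, `[[`, character(1), "kind")
  fpos <- do.call(rbind, lapply(feats, `[[`, "position"))
  heavy <- conf$coords[toupper(conf$elem) != "H", , drop = FALSE]
  compat_kinds <- function(sk) switch(sk,
    hydrophobic = c("hydrophobic", "aromatic_hydrophobic"),
    aromatic = c("aromatic", "aromatic_hydrophobic"), sk)

  all_assignments <- function(sites_sel) {
    acc <- list(integer(0))
    for (s in sites_sel) {
      ok <- which(fk %in% compat_kinds(site_kind[s]))
      acc <- unlist(lapply(acc, function(partial) {
        lapply(setdiff(ok, partial), function(f) c(partial, f))
      }), recursive = FALSE)
      if (length(acc) == 0) return(list())
    }
    acc
  }

  clashes <- function(r, tv) {
    if (length(model$volumes) == 0 || nrow(heavy) == 0) return(FALSE)
    xyz <- sweep(heavy %*% t(r), 2, tv, `+`)
    for (v in model$volumes) {
      if (any(rowSums(sweep(xyz, 2, v$position)^2) < v$radius^2)) return(TRUE)
    }
    FALSE
  }

  better <- function(a, b) {
    if (is.null(b)) return(TRUE)
    if (a$rms < b$rms - 1e-12) return(TRUE)
    if (a$rms > b$rms + 1e-12) return(FALSE)
    if (length(a$sites) != length(b$sites)) return(length(a$sites) > length(b$sites))
    for (i in seq_along(a$sites)) {
      if (a$sites[i] != b$sites[i]) return(a$sites[i] < b$sites[i])
    }
    for (i in seq_along(a$feats)) {
      if (a$feats[i] != b$feats[i]) return(a$feats[i] < b$feats[i])
    }
    FALSE
  }

  best <- NULL; best_any <- NULL
  n_sites <- length(model$sites)
  for (k in seq(model$min_match, n_sites)) {
    for (ss in utils::combn(n_sites, k, simplify = FALSE)) {
      for (fa in all_assignments(ss)) {
        fp <- fpos[fa, , drop = FALSE]; sp <- site_pos[ss, , drop = FALSE]
        if (reorient) {
          fit <- oracle_fit(fp, sp)
          moved <- sweep(fp %*% t(fit$r), 2, fit$t, `+`)
        } else {
          fit <- list(r = diag(3), t = c(0, 0, 0))
          moved <- fp
        }
        dd <- sqrt(rowSums((moved - sp)^2))
        if (any(dd > site_tol[ss])) next
        cand <- list(sites = ss, feats = fa, rms = sqrt(mean(dd^2)), fit = fit)
        if (better(cand, best_any)) best_any <- cand
        if (better(cand, best) && !clashes(fit$r, fit$t)) best <- cand
      }
    }
  }
  if (!is.null(best)) {
    list(matched = TRUE, clash = FALSE, sites = best$sites,
         feats = best$feats, rms = best$rms)
  } else if (!is.null(best_any)) {
    list(matched = FALSE, clash = TRUE, sites = best_any$sites,
         feats = best_any$feats, rms = best_any$rms)
  } else {
    list(matched = FALSE, clash = FALSE, sites = integer(), feats = integer(),
         rms = NA_real_)
  }
}

expect_match_equals_oracle <- function(conf, feats, model, reorient = TRUE) {
  got <- match_conformer(conf, feats, model, reorient = reorient)
  want <- oracle_match(conf, feats, model, reorient = reorient)
  expect_identical(got$matched, want$matched)
  expect_identical(got$clash, want$clash)
  if (want$matched || want$clash) {
    expect_equal(got$rms, want$rms, tolerance = 1e-9)
    expect_identical(as.integer(names(got$assignment)), as.integer(want$sites))
    expect_identical(unname(got$assignment), as.integer(want$feats))
  }
}

## --- Naive O(n^3) agglomeration ---------------------------------------------

## Cluster distances recomputed from the ORIGINAL distance matrix at every
## step (no Lance-Williams); same lexicographic tie-break as the contract.
naive_agglom <- function(d0, linkage = "average") {
  ids <- rownames(d0)
  clusters <- lapply(seq_along(ids), function(i) i)
  reps <- ids
  heights <- numeric(0)
  partitions <- list()
  cluster_dist <- function(a, b) {
    vals <- d0[a, b, drop = FALSE]
    switch(linkage, average = mean(vals), complete = max(vals),
           single = min(vals))
  }
  while (length(clusters) > 1) {
    best <- NULL
    for (i in seq_len(length(clusters) - 1)) {
      for (j in (i + 1):length(clusters)) {
        dv <- cluster_dist(clusters[[i]], clusters[[j]])
        key <- sort(c(reps[i], reps[j]))
        if (is.null(best) || dv < best$d - 1e-12 ||
            (abs(dv - best$d) <= 1e-12 &&
             (key[1] < best$key[1] ||
              (key[1] == best$key[1] && key[2] < best$key[2])))) {
          best <- list(i = i, j = j, d = dv, key = key)
        }
      }
    }
    merged <- c(clusters[[best$i]], clusters[[best$j]])
    heights <- c(heights, best$d)
    keep <- setdiff(seq_along(clusters), c(best$i, best$j))
    clusters <- c(clusters[keep], list(merged))
    reps <- c(reps[keep], min(best$key))
    partitions[[length(partitions) + 1]] <-
      canonical_partition(c(lapply(clusters, function(cl) ids[cl])))
  }
  list(heights = heights, partitions = partitions)
}

canonical_partition <- function(groups) {
  sorted <- lapply(groups, function(g) unname(sort(g)))
  unname(sorted[order(vapply(sorted, `[`, character(1), 1))])
}

## Partition of an hclust tree at k clusters, in canonical form.
tree_partition <- function(tree, k) {
  cl <- stats::cutree(tree, k = k)
  canonical_partition(split(names(cl), cl))
}

## --- Exhaustive Kelley penalty ----------------------------------------------

## Plain-loop penalty evaluation over all candidate levels k = 2..n-1.
oracle_kelley <- function(tree, d0) {
  n <- length(tree$labels)
  ks <- 2:(n - 1)
  spread <- numeric(length(ks))
  for (t in seq_along(ks)) {
    part <- tree_partition(tree, ks[t])
    per <- c()
    for (g in part) {
      if (length(g) < 2) next
      tot <- 0; cnt <- 0
      for (i in seq_len(length(g) - 1)) for (j in (i + 1):length(g)) {
        tot <- tot + d0[g[i], g[j]]; cnt <- cnt + 1
      }
      per <- c(per, tot / cnt)
    }
    spread[t] <- mean(per)
  }
  rng <- range(spread)
  norm <- if (diff(rng) < 1e-15) rep(1, length(ks)) else
    (spread - rng[1]) / diff(rng) * (n - 3) + 1
  pen <- norm + ks
  list(k = ks[which.min(pen)], penalty = pen)
}

## --- Random fixtures ---------------------------------------------------------

random_match_instance <- function(max_feats = 8) {
  n_sites <- sample(3:5, 1)
  kinds_pool <- c("acceptor", "donor", "hydrophobic", "aromatic_hydrophobic")
  sites <- lapply(seq_len(n_sites), function(i)
    pharmacophore_site(sample(c("acceptor", "donor", "hydrophobic"), 1),
                       runif(3, -5, 5)))
  vols <- if (runif(1) < 0.5) list(excluded_volume(runif(3, -5, 5), 1.5)) else list()
  model <- pharmacophore_model("rnd", sites, vols,
                               min_match = sample(seq(2, n_sites), 1),
                               mode = "include")
  n <- sample(4:max_feats, 1)
  coords <- matrix(runif(3 * n, -5, 5), n, 3)
  conf <- vs_conformer("x", coords, sample(c("C", "O", "N"), n, TRUE))
  feats <- lapply(seq_len(n), function(i)
    feature_point(sample(kinds_pool, 1), coords[i, ], i))
  list(conf = conf, feats = feats, model = model)
}

random_fps <- function(n, universe = 40, size = 8:14) {
  fps <- lapply(seq_len(n), function(i) {
    structure(list(hashes = sort(sample.int(universe, sample(size, 1))),
                   width = 32L), class = "vs_fingerprint")
  })
  names(fps) <- sprintf("m%02d", seq_len(n))
  fps
}

## A small charged feature cloud for field tests.
random_cloud <- function(id = "c", n = 4, box = 3) {
  coords <- matrix(runif(3 * n, -box, box), n, 3)
  q <- runif(n, -0.4, 0.4); q <- q - mean(q)
  vs_conformer(id, coords, sample(c("C", "O", "N"), n, TRUE), charges = q)
}

## Shared fixture models/benchmark, built once per test run.
fixture_env <- new.env()
get_fixtures <- function() {
  if (is.null(fixture_env$fx)) fixture_env$fx <- make_pharmacophore_fixtures(1)
  fixture_env$fx
}
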