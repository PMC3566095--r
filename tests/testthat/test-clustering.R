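# Fingerprints, Tanimoto, agglomerative clustering and Kelley selection.

smiles_fps <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      tf <- tempfile(fileext = ".smi")
      writeLines(c("C methane", "CC ethane", "CCO ethanol", "CCCO propanol",
                   "c1ccccc1 benzene", "c1ccccc1O phenol"), tf)
      cache <<- lapply(read_library(tf), fingerprint)
    }
    cache
  }
})

test_that("fingerprints are deterministic and discriminate environments", {
  tf <- tempfile(fileext = ".smi")
  writeLines(c("CCO a", "OCC b"), tf)   # same molecule, two writings
  lib <- read_library(tf)
  fa <- fingerprint(lib$a); fb <- fingerprint(lib$b)
  expect_identical(fa$hashes, fb$hashes)
  fps <- smiles_fps()
  expect_false(identical(fps$methane$hashes, fps$ethane$hashes))
  expect_equal(tanimoto(fps$ethanol, fps$ethanol), 1.0)
  ## all hashes live in the 32-bit address space
  expect_true(all(fps$benzene$hashes >= 0 & fps$benzene$hashes < 2^32))
})

test_that("fingerprint features equal a direct depth-2 environment enumeration", {
  tf <- tempfile(fileext = ".smi")
  writeLines("CC(=O)c1ccccc1 acetophenone", tf)
  mol <- read_library(tf)[[1]]
  got <- fingerprint(mol)
  ## oracle: Floyd-Warshall graph distances on the heavy-atom graph, then
  ## the same environment encoding, hashed with the same 32-bit hash
  elem <- toupper(mol$atoms$elem)
  hv <- which(elem != "H")
  n <- nrow(mol$atoms)
  dmat <- matrix(Inf, n, n); diag(dmat) <- 0
  for (b in seq_len(nrow(mol$bonds))) {
    dmat[mol$bonds$a1[b], mol$bonds$a2[b]] <- 1
    dmat[mol$bonds$a2[b], mol$bonds$a1[b]] <- 1
  }
  for (k in 1:n) for (i in 1:n) for (j in 1:n) {
    if (dmat[i, k] + dmat[k, j] < dmat[i, j]) dmat[i, j] <- dmat[i, k] + dmat[k, j]
  }
  type <- paste0(elem, ifelse(mol$atoms$arom, "ar", ""))
  feats <- character()
  for (a in hv) {
    for (r in 0:2) {
      inside <- hv[dmat[a, hv] >= 1 & dmat[a, hv] <= r]
      shell <- sort(paste0(dmat[a, inside], ";", type[inside]))
      feats <- c(feats, paste0("r", r, "|", type[a], "|",
                               paste(shell, collapse = ",")))
    }
  }
  want <- sort(unique(vapply(unique(feats), ppargscreen:::fnv1a32, numeric(1),
                             USE.NAMES = FALSE) %% 2^32))
  expect_equal(got$hashes, want)
})

test_that("set Tanimoto matches set arithmetic on random sets", {
  set.seed(71)
  for (r in 1:20) {
    fa <- random_fps(1)[[1]]; fb <- random_fps(1)[[1]]
    inter <- length(intersect(fa$hashes, fb$hashes))
    uni <- length(union(fa$hashes, fb$hashes))
    expect_equal(tanimoto(fa, fb), inter / uni)
    expect_equal(tanimoto(fa, fb), tanimoto(fb, fa))
  }
  disjoint_a <- structure(list(hashes = c(1, 2, 3), width = 32L),
                          class = "vs_fingerprint")
  disjoint_b <- structure(list(hashes = c(4, 5), width = 32L),
                          class = "vs_fingerprint")
  expect_equal(tanimoto(disjoint_a, disjoint_b), 0)
  empty <- structure(list(hashes = numeric(0), width = 32L),
                     class = "vs_fingerprint")
  expect_warning(t1 <- tanimoto(empty, empty), "empty")
  expect_equal(t1, 1.0)
  wide <- structure(list(hashes = 1, width = 16L), class = "vs_fingerprint")
  expect_error(tanimoto(disjoint_a, wide), "widths differ")
})

test_that("Tanimoto distance behaves like a metric on random triples", {
  set.seed(73)
  for (r in 1:25) {
    fps <- random_fps(3)
    d <- function(i, j) 1 - tanimoto(fps[[i]], fps[[j]])
    expect_lte(d(1, 3), d(1, 2) + d(2, 3) + 1e-12)
  }
})

test_that("agglomeration equals the naive from-scratch oracle", {
  set.seed(79)
  for (r in 1:12) {
    fps <- random_fps(6)
    d0 <- tanimoto_distance_matrix(fps)
    for (lk in c("average", "complete", "single")) {
      tree <- cluster_molecules(fps, lk)
      want <- naive_agglom(d0, lk)
      expect_equal(tree$height, want$heights, tolerance = 1e-12)
      for (step in seq_len(length(fps) - 1)) {
        expect_identical(tree_partition(tree, length(fps) - step),
                         want$partitions[[step]])
      }
    }
  }
})

test_that("agglomeration agrees with stats::hclust on tie-free distances", {
  set.seed(83)
  for (r in 1:8) {
    n <- 7
    d <- matrix(0, n, n)
    d[upper.tri(d)] <- runif(choose(n, 2))
    d <- d + t(d)
    dimnames(d) <- list(letters[1:n], letters[1:n])
    for (lk in c("average", "complete", "single")) {
      mine <- cluster_molecules(d, lk)
      ref <- stats::hclust(stats::as.dist(d), method = lk)
      expect_equal(mine$height, ref$height, tolerance = 1e-12)
      co_mine <- as.matrix(stats::cophenetic(mine))[letters[1:n], letters[1:n]]
      co_ref <- as.matrix(stats::cophenetic(ref))[letters[1:n], letters[1:n]]
      expect_equal(co_mine, co_ref, tolerance = 1e-9)
    }
  }
})

test_that("dendrogram basics: pair merge, duplicates first, monotone heights", {
  fps <- smiles_fps()
  two <- cluster_molecules(fps[c("ethanol", "benzene")])
  expect_equal(two$height, 1 - tanimoto(fps$ethanol, fps$benzene))
  dup <- c(fps[c("ethanol", "benzene")], list(ethanol2 = fps$ethanol))
  tree <- cluster_molecules(dup)
  expect_equal(tree$height[1], 0)
  expect_identical(tree_partition(tree, 2),
                   canonical_partition(list(c("ethanol", "ethanol2"), "benzene")))
  full <- cluster_molecules(fps)
  expect_true(all(diff(full$height) >= -1e-12))
  expect_error(cluster_molecules(fps[1]), "at least 2")
})

test_that("Kelley selection equals exhaustive penalty evaluation", {
  set.seed(89)
  for (r in 1:15) {
    n <- sample(5:10, 1)
    fps <- random_fps(n)
    d0 <- tanimoto_distance_matrix(fps)
    tree <- cluster_molecules(fps)
    sel <- kelley_select(tree)
    want <- oracle_kelley(tree, d0)
    expect_equal(sel$k, want$k)
    expect_equal(sel$levels$penalty, want$penalty, tolerance = 1e-12)
  }
})

test_that("Kelley selection resolves forced geometries", {
  ## two coincident leaves + one distant: the only candidate level is k = 2
  d3 <- matrix(c(0, 0, 1, 0, 0, 1, 1, 1, 0), 3, 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  expect_equal(kelley_select(cluster_molecules(d3))$k, 2L)
  ## two well-separated tight blobs of 5 -> k = 2
  ids <- c(sprintf("a%d", 1:5), sprintf("b%d", 1:5))
  d10 <- matrix(0.9, 10, 10, dimnames = list(ids, ids))
  d10[1:5, 1:5] <- 0; d10[6:10, 6:10] <- 0; diag(d10) <- 0
  sel <- kelley_select(cluster_molecules(d10))
  expect_equal(sel$k, 2L)
  expect_identical(tree_partition(cluster_molecules(d10), 2),
                   canonical_partition(list(ids[1:5], ids[6:10])))
  ## scaling all distances leaves the selection unchanged
  set.seed(97)
  fps <- random_fps(8)
  d0 <- tanimoto_distance_matrix(fps)
  k1 <- kelley_select(cluster_molecules(d0))$k
  k2 <- kelley_select(cluster_molecules(d0 * 7.3))$k
  expect_equal(k1, k2)
  ## all-identical leaves degenerate to a single cluster with a warning
  dz <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  expect_warning(selz <- kelley_select(cluster_molecules(dz)), "identical")
  expect_equal(selz$k, 1L)
})

test_that("novelty flags mark hit clusters that contain references", {
  fps <- smiles_fps()
  ## hits identical to references co-cluster and are flagged
  hits <- list(h1 = fps$ethanol, h2 = fps$benzene)
  refs <- list(r1 = fps$ethanol, r2 = fps$propanol, r3 = fps$phenol,
               r4 = fps$methane)
  nr <- novelty_report(hits, refs)
  expect_true(nr$table$contains_reference[nr$table$id == "h1"])
  ## oracle: direct membership check at the selected level
  cl <- nr$selection$assignments
  for (i in seq_len(nrow(nr$table))) {
    id <- nr$table$id[i]
    expect_equal(nr$table$contains_reference[i],
                 cl[id] %in% cl[names(refs)], ignore_attr = TRUE)
  }
  ## disjoint fingerprint spaces are never flagged
  far_hits <- random_fps(2); names(far_hits) <- c("x1", "x2")
  far_hits <- lapply(far_hits, function(f) {
    f$hashes <- f$hashes + 2^20; f
  })
  nr2 <- novelty_report(far_hits, refs)
  expect_false(any(nr2$table$contains_reference))
  expect_error(novelty_report(hits, c(refs, list(h1 = fps$ethane))),
               "overlap")
})
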