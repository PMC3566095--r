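# Shape and electrostatic field similarity.

test_that("self-similarity identities hold exactly", {
  set.seed(41)
  a <- random_cloud("a", n = 5)
  expect_equal(shape_tanimoto(a, a), 1.0, tolerance = 1e-9)
  expect_equal(electrostatic_tanimoto(a, a), 1.0, tolerance = 1e-9)
  sc <- field_score(a, a)
  expect_equal(sc$et_combo, 2.0, tolerance = 1e-9)
})

test_that("charge negation gives ET = -1/3 while the shape stays identical", {
  set.seed(43)
  a <- random_cloud("a", n = 6)
  neg <- a; neg$charges <- -a$charges
  expect_equal(electrostatic_tanimoto(a, neg), -1 / 3, tolerance = 1e-9)
  expect_equal(shape_tanimoto(a, neg), 1.0, tolerance = 1e-9)
})

test_that("a single-atom pair reproduces the closed-form Gaussian overlap", {
  mk <- function(x) vs_conformer("c", matrix(c(x, 0, 0), 1, 3), "C")
  p <- 2.7
  alpha <- pi * (3 * p / (4 * pi))^(2 / 3) / 1.70^2   # carbon vdW radius
  for (d in c(0.5, 1, 2)) {
    o_ab <- p^2 * (pi / (2 * alpha))^1.5 * exp(-alpha / 2 * d^2)
    o_self <- p^2 * (pi / (2 * alpha))^1.5
    expect_equal(shape_tanimoto(mk(0), mk(d)),
                 o_ab / (2 * o_self - o_ab), tolerance = 1e-9)
  }
  ## vanishing overlap at 50 Angstrom
  expect_lt(shape_tanimoto(mk(0), mk(50)), 1e-6)
  ## zero-atom conformer is a domain error
  h_only <- vs_conformer("h", matrix(0, 1, 3), "H")
  expect_error(shape_tanimoto(h_only, mk(0)), "no heavy atoms")
})

test_that("both scores are symmetric and ET never exceeds 1", {
  set.seed(47)
  for (r in 1:30) {
    a <- random_cloud("a", n = sample(3:6, 1))
    b <- random_cloud("b", n = sample(3:6, 1))
    st_ab <- shape_tanimoto(a, b); st_ba <- shape_tanimoto(b, a)
    et_ab <- electrostatic_tanimoto(a, b); et_ba <- electrostatic_tanimoto(b, a)
    expect_equal(st_ab, st_ba, tolerance = 1e-9)
    expect_equal(et_ab, et_ba, tolerance = 1e-9)
    expect_gt(st_ab, 0); expect_lte(st_ab, 1 + 1e-12)
    expect_lte(et_ab, 1 + 1e-12)
  }
})

test_that("shape similarity is invariant under a common rigid motion", {
  set.seed(53)
  a <- random_cloud("a", n = 5)
  b <- random_cloud("b", n = 4)
  base <- shape_tanimoto(a, b)
  for (r in 1:5) {
    rot <- ppargscreen:::random_rotation()
    shift <- runif(3, -20, 20)
    a2 <- a; a2$coords <- apply_rigid(a$coords, rot, shift)
    b2 <- b; b2$coords <- apply_rigid(b$coords, rot, shift)
    expect_equal(shape_tanimoto(a2, b2), base, tolerance = 1e-6)
  }
})

test_that("ET on a rotated dipole agrees with an independent fine-grid evaluation", {
  dip <- function(theta) {
    vs_conformer("d", rbind(c(-0.7 * cos(theta), -0.7 * sin(theta), 0),
                            c(0.7 * cos(theta), 0.7 * sin(theta), 0)),
                 c("C", "C"), charges = c(-0.3, 0.3))
  }
  a <- dip(0); b <- dip(pi / 3)
  got <- electrostatic_tanimoto(a, b, field_config(grid_spacing = 0.5))
  ## independent evaluation: plain per-point loop on a 0.1-Angstrom grid
  ref_grid <- function(a, b, h, margin, eps) {
    xyz <- rbind(a$coords, b$coords)
    ax <- lapply(1:3, function(k) seq(min(xyz[, k]) - margin,
                                      max(xyz[, k]) + margin, by = h))
    n_pts <- prod(lengths(ax))
    pa <- numeric(n_pts); pb <- numeric(n_pts)
    rv <- vdw_radius(c(a$elem, b$elem))
    qa <- a$charges; qb <- b$charges
    n_used <- 0L
    for (x in ax[[1]]) for (y in ax[[2]]) for (z in ax[[3]]) {
      d <- sqrt((xyz[, 1] - x)^2 + (xyz[, 2] - y)^2 + (xyz[, 3] - z)^2)
      if (any(d <= rv)) next
      n_used <- n_used + 1L
      pa[n_used] <- sum(qa / (eps * d[seq_along(qa)]))
      pb[n_used] <- sum(qb / (eps * d[-seq_along(qa)]))
    }
    pa <- pa[seq_len(n_used)]; pb <- pb[seq_len(n_used)]
    ab <- mean(pa * pb); aa <- mean(pa^2); bb <- mean(pb^2)
    ab / (aa + bb - ab)
  }
  ref <- ref_grid(a, b, 0.1, 4, 4)
  expect_equal(got, ref, tolerance = 0.02)
  ## grid-refinement stability of the packaged evaluator
  fine <- electrostatic_tanimoto(a, b, field_config(grid_spacing = 0.25))
  expect_lt(abs(got - fine), 0.02)
  ## missing charges are a precondition error
  nochg <- vs_conformer("n", a$coords, a$elem)
  expect_error(electrostatic_tanimoto(nochg, b), "partial charges")
})

test_that("the multi-query filter uses OR aggregation and both thresholds", {
  set.seed(59)
  fx <- get_fixtures()
  queries <- fx$queries
  q1 <- queries[[1]]
  negated <- vs_conformer("neg", q1$coords, q1$elem, charges = -q1$charges)
  far <- vs_conformer("far", q1$coords + 40, q1$elem, charges = q1$charges)
  cands <- list(same = q1, neg = negated, far = far)
  cfg <- field_config()
  res <- similarity_filter(cands, queries, cfg)
  expect_true("same" %in% res$hits)       # identical to query 1
  expect_false("neg" %in% res$hits)       # shape passes, ET fails
  expect_false("far" %in% res$hits)       # shape fails
  neg_rows <- res$scores[res$scores$candidate == "neg", ]
  expect_true(any(neg_rows$st >= cfg$st_threshold))
  expect_true(all(neg_rows$et_pb < cfg$et_threshold))
  ## hit set equals per-pair oracle evaluation with OR aggregation
  oracle_hits <- names(cands)[vapply(cands, function(cand) {
    any(vapply(queries, function(q) {
      shape_tanimoto(cand, q, cfg) >= cfg$st_threshold &&
        electrostatic_tanimoto(cand, q, cfg) >= cfg$et_threshold
    }, logical(1)))
  }, logical(1))]
  expect_setequal(res$hits, oracle_hits)
  ## tightening either threshold never enlarges the hit set
  tight_st <- similarity_filter(cands, queries,
                                field_config(st_threshold = 0.9))$hits
  tight_et <- similarity_filter(cands, queries,
                                field_config(et_threshold = 0.9))$hits
  expect_true(all(tight_st %in% res$hits))
  expect_true(all(tight_et %in% res$hits))
  expect_error(similarity_filter(cands, list()), "empty query")
})

test_that("the combined score is the exact sum of its parts", {
  set.seed(61)
  for (r in 1:5) {
    a <- random_cloud("a"); b <- random_cloud("b")
    sc <- field_score(a, b)
    expect_identical(sc$et_combo, sc$st + sc$et_pb)
    sc2 <- field_score(b, a)
    expect_equal(sc$et_combo, sc2$et_combo, tolerance = 1e-9)
  }
})
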