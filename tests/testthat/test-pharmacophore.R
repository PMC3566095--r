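# Pharmacophore models, JSON persistence and geometric matching.

test_that("an exact embed matches with zero rms and identity transform", {
  fx <- get_fixtures()
  q <- fx$queries[[1]]
  m <- match_conformer(q, cloud_features(q), fx$partial, reorient = TRUE)
  expect_true(m$matched)
  expect_equal(m$rms, 0, tolerance = 1e-9)
  expect_equal(m$n_matched, 4)
  expect_false(m$clash)
  ## identity up to numerical noise: the features already sit on the sites
  expect_equal(m$transform$rotation, diag(3), tolerance = 1e-6)
  expect_equal(m$transform$translation, c(0, 0, 0), tolerance = 1e-6)
})

test_that("a heavy atom inside an excluded volume invalidates the match", {
  ## scalene triangle with tight tolerances: only one assignment can accept,
  ## so the atom placed on the excluded volume cannot rotate out of it
  sites <- list(pharmacophore_site("acceptor", c(0, 0, 0), 0.5),
                pharmacophore_site("hydrophobic", c(3, 0, 0), 0.5),
                pharmacophore_site("hydrophobic", c(0, 5, 0), 0.5))
  vol_center <- c(1, 1, 2)
  model <- pharmacophore_model("rigid", sites,
                               list(excluded_volume(vol_center, 1.5)),
                               min_match = 3, mode = "include")
  clean <- vs_conformer("ok", rbind(c(0, 0, 0), c(3, 0, 0), c(0, 5, 0)),
                        c("O", "C", "C"))
  expect_true(match_conformer(clean, cloud_features(clean), model)$matched)
  ## sulfur carries no feature in the cloud convention: the feature set and
  ## hence the accepted geometry are unchanged, but the atom clashes
  clashed <- vs_conformer("bad", rbind(clean$coords, vol_center),
                          c("O", "C", "C", "S"))
  m <- match_conformer(clashed, cloud_features(clashed), model)
  expect_false(m$matched)
  expect_true(m$clash)
  expect_equal(m$rms, 0, tolerance = 1e-9)
})

test_that("matching equals brute-force assignment enumeration on random instances", {
  set.seed(101)
  for (r in 1:40) {
    inst <- random_match_instance()
    expect_match_equals_oracle(inst$conf, inst$feats, inst$model,
                               reorient = TRUE)
    expect_match_equals_oracle(inst$conf, inst$feats, inst$model,
                               reorient = FALSE)
  }
})

test_that("fixed-pose matches imply free-orientation matches, never the reverse", {
  set.seed(7)
  fx <- get_fixtures()
  for (r in 1:25) {
    inst <- random_match_instance()
    fixed <- match_conformer(inst$conf, inst$feats, inst$model, reorient = FALSE)
    if (fixed$matched) {
      free <- match_conformer(inst$conf, inst$feats, inst$model, reorient = TRUE)
      expect_true(free$matched)
      expect_lte(free$rms, fixed$rms + 1e-9)
    }
  }
  ## a query moved out of frame still matches free but not fixed
  q <- fx$queries[[1]]
  moved <- vs_conformer(q$mol_id, q$coords + 5, q$elem, charges = q$charges)
  expect_false(match_conformer(moved, cloud_features(moved), fx$partial,
                               reorient = FALSE)$matched)
  expect_true(match_conformer(moved, cloud_features(moved), fx$partial,
                              reorient = TRUE)$matched)
})

test_that("free-orientation matching is invariant under rigid motions of the conformer", {
  set.seed(23)
  fx <- get_fixtures()
  q <- fx$queries[[2]]
  base <- match_conformer(q, cloud_features(q), fx$partial, reorient = TRUE)
  for (r in 1:5) {
    rot <- ppargscreen:::random_rotation()
    shift <- runif(3, -10, 10)
    moved <- vs_conformer(q$mol_id, apply_rigid(q$coords, rot, shift), q$elem)
    m <- match_conformer(moved, cloud_features(moved), fx$partial,
                         reorient = TRUE)
    expect_equal(m$matched, base$matched)
    expect_equal(m$rms, base$rms, tolerance = 1e-6)
  }
})

test_that("exclude-mode screening discards embedders and respects the counting argument", {
  fx <- get_fixtures()
  anti <- fx$antipharmacophore
  ## a cloud sitting on all 5 antipharmacophore sites is discarded
  sites <- do.call(rbind, lapply(anti$sites, `[[`, "position"))
  kinds <- vapply(anti$sites, `[[`, character(1), "kind")
  full <- vs_conformer("full", sites, ifelse(kinds == "acceptor", "O", "C"))
  e_full <- screen_entry("full", list(full), list(cloud_features(full)))
  ## a cloud with no acceptor features cannot reach 4 of 5 (2 sites are
  ## acceptors, only 3 hydrophobics exist)
  noacc <- vs_conformer("noacc", sites, rep("C", 5))
  e_no <- screen_entry("noacc", list(noacc), list(cloud_features(noacc)))
  res <- screen_antipharmacophore(list(e_full, e_no), anti)
  expect_equal(res$discarded, "full")
  expect_equal(res$survivors, "noacc")
  expect_error(screen_antipharmacophore(list(e_full), fx$partial),
               "exclude-mode")
})

test_that("survivor sets shrink as min_match loosens (exclude mode)", {
  set.seed(5)
  fx <- get_fixtures()
  entries <- lapply(1:12, function(i) {
    n <- sample(5:7, 1)
    coords <- matrix(runif(3 * n, -6, 12), n, 3)
    elem <- c("O", "O", rep("C", n - 2))
    conf <- vs_conformer(paste0("m", i), coords, elem)
    screen_entry(paste0("m", i), list(conf), list(cloud_features(conf)))
  })
  surv <- lapply(3:5, function(mm) {
    model <- pharmacophore_model(fx$antipharmacophore$name,
                                 fx$antipharmacophore$sites,
                                 fx$antipharmacophore$volumes,
                                 min_match = mm, mode = "exclude")
    screen_antipharmacophore(entries, model)$survivors
  })
  expect_true(all(surv[[1]] %in% surv[[2]]))
  expect_true(all(surv[[2]] %in% surv[[3]]))
})

test_that("include-mode screening returns best matches and demands every site", {
  fx <- get_fixtures()
  q <- fx$queries[[1]]
  hit <- screen_entry("hit", list(q), list(cloud_features(q)))
  noacc <- vs_conformer("noacc", q$coords, rep("C", nrow(q$coords)))
  miss <- screen_entry("noacc", list(noacc), list(cloud_features(noacc)))
  res <- screen_partial_pharmacophore(list(hit, miss), fx$partial)
  expect_equal(res$hits, "hit")
  expect_equal(res$matches[["hit"]]$rms, 0, tolerance = 1e-9)
  expect_error(screen_partial_pharmacophore(list(hit), fx$antipharmacophore),
               "include-mode")
})

test_that("pharmacophore JSON round-trips and rejects schema violations", {
  fx <- get_fixtures()
  tf <- tempfile(fileext = ".json")
  save_pharmacophore(fx$antipharmacophore, tf)
  back <- load_pharmacophore(tf)
  expect_equal(back$min_match, 4)
  expect_equal(back$mode, "exclude")
  kinds <- vapply(back$sites, `[[`, character(1), "kind")
  expect_equal(sum(kinds == "acceptor"), 2)
  expect_equal(sum(kinds == "hydrophobic"), 3)
  expect_length(back$volumes, length(fx$antipharmacophore$volumes))
  expect_true(isTRUE(back$metadata$synthetic))
  for (i in seq_along(back$sites)) {
    expect_equal(back$sites[[i]]$position,
                 fx$antipharmacophore$sites[[i]]$position)
  }
  ## min_match > |sites| is a format error with a JSON location
  obj <- jsonlite::read_json(tf)
  obj$min_match <- 99
  bad <- tempfile(fileext = ".json")
  jsonlite::write_json(obj, bad, auto_unbox = TRUE)
  expect_error(load_pharmacophore(bad), "/min_match")
  obj$min_match <- 4; obj$sites[[1]]$kind <- "flavor"
  jsonlite::write_json(obj, bad, auto_unbox = TRUE)
  expect_error(load_pharmacophore(bad), "/sites/0/kind")
  expect_error(pharmacophore_model("x", list()), ">= 1 site")
})
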