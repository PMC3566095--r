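# Molecular model, library I/O and feature perception.

write_smiles <- function(lines) {
  tf <- tempfile(fileext = ".smi")
  writeLines(lines, tf)
  tf
}

test_that("SMILES libraries parse and collect failures without aborting", {
  lib <- read_library(write_smiles(c("c1ccccc1 benzene", "CC(=O)C acetone",
                                     "xx((bad corrupt", "CCO ethanol")))
  expect_named(lib, c("benzene", "acetone", "ethanol"))
  expect_equal(nrow(attr(lib, "failures")), 1)
  bz <- lib$benzene
  expect_equal(sum(toupper(bz$atoms$elem) == "C"), 6)
  expect_true(all(bz$atoms$arom[toupper(bz$atoms$elem) == "C"]))
  expect_error(read_library(tempfile()), "cannot read")
  empty <- write_smiles(character())
  expect_error(read_library(empty, "smiles"), "empty library")
})

test_that("SDF read/write round-trips molecule count, ids and heavy atoms", {
  lib <- read_library(write_smiles(c("CCO ethanol", "c1ccccc1 benzene",
                                     "CC(=O)OC aceticester")))
  confs <- lapply(lib, function(m) attr(m, "conformer"))
  tf <- tempfile(fileext = ".sdf")
  suppressWarnings(write_conformers_sdf(confs, tf,
                                        bonds = lapply(lib, `[[`, "bonds")))
  back <- read_library(tf, "sdf")
  expect_length(back, length(lib))
  expect_equal(vapply(back, `[[`, character(1), "name"),
               vapply(lib, `[[`, character(1), "id"),
               ignore_attr = TRUE)
  for (i in seq_along(lib)) {
    expect_equal(sum(toupper(back[[i]]$atoms$elem) != "H"),
                 sum(toupper(lib[[i]]$atoms$elem) != "H"))
  }
})

test_that("aromatic rings become hydrophobic-compatible features only under the amendment", {
  lib <- read_library(write_smiles("c1ccccc1 benzene"))
  bz <- lib$benzene
  conf <- attr(bz, "conformer")
  on <- perceive_features(conf, bz, aromatic_as_hydrophobic = TRUE)
  expect_length(on, 1)
  expect_equal(on[[1]]$kind, "aromatic_hydrophobic")
  centroid <- colMeans(conf$coords[toupper(conf$elem) == "C", ])
  expect_equal(on[[1]]$position, unname(centroid), tolerance = 1e-9)
  off <- perceive_features(conf, bz, aromatic_as_hydrophobic = FALSE)
  expect_length(off, 1)
  expect_equal(off[[1]]$kind, "aromatic")
  ## an "aromatic" feature cannot satisfy a hydrophobic site
  site <- pharmacophore_model("h", list(pharmacophore_site("hydrophobic",
                                                           centroid)),
                              min_match = 1, mode = "include")
  expect_false(match_conformer(conf, off, site)$matched)
  expect_true(match_conformer(conf, on, site)$matched)
})

test_that("feature perception matches a direct reading of the rule table", {
  lib <- read_library(write_smiles(c("CC(=O)C acetone", "CCO ethanol",
                                     "CCCC butane", "CCN ethylamine")))
  # acetone: single acceptor on the carbonyl oxygen, no donors, no
  # 3-carbon aliphatic component (carbonyl carbon is ineligible)
  fa <- perceive_features(attr(lib$acetone, "conformer"), lib$acetone)
  expect_equal(sort(vapply(fa, `[[`, character(1), "kind")), "acceptor")
  o_idx <- which(toupper(lib$acetone$atoms$elem) == "O")
  expect_equal(fa[[1]]$atom_indices, o_idx)
  # ethanol: hydroxyl O is both acceptor and donor; 2 carbons < min group size
  fe <- perceive_features(attr(lib$ethanol, "conformer"), lib$ethanol)
  expect_setequal(vapply(fe, `[[`, character(1), "kind"),
                  c("acceptor", "donor"))
  # butane: one hydrophobic group of all 4 carbons at their centroid
  fb <- perceive_features(attr(lib$butane, "conformer"), lib$butane)
  expect_equal(vapply(fb, `[[`, character(1), "kind"), "hydrophobic")
  expect_length(fb[[1]]$atom_indices, 4)
  # ethylamine: N is acceptor + donor
  fn <- perceive_features(attr(lib$ethylamine, "conformer"), lib$ethylamine)
  kinds <- vapply(fn, `[[`, character(1), "kind")
  expect_equal(sum(kinds == "acceptor"), 1)
  expect_equal(sum(kinds == "donor"), 1)
})

test_that("feature perception is invariant under atom renumbering and rigid motion", {
  lib <- read_library(write_smiles("CC(=O)c1ccccc1O hydroxyacetophenone"))
  mol <- lib[[1]]
  conf <- attr(mol, "conformer")
  base <- perceive_features(conf, mol)
  sig <- function(fs) {
    df <- data.frame(kind = vapply(fs, `[[`, character(1), "kind"),
                     x = round(vapply(fs, function(f) f$position[1], numeric(1)), 6),
                     y = round(vapply(fs, function(f) f$position[2], numeric(1)), 6),
                     z = round(vapply(fs, function(f) f$position[3], numeric(1)), 6))
    df[order(df$kind, df$x, df$y, df$z), ]
  }
  ## renumber: reverse atom order
  n <- nrow(mol$atoms)
  perm <- rev(seq_len(n)); inv <- order(perm)
  mol2 <- vs_molecule(mol$id, mol$atoms[perm, ],
                      data.frame(a1 = inv[mol$bonds$a1], a2 = inv[mol$bonds$a2],
                                 order = mol$bonds$order),
                      rings = list(atoms = lapply(mol$rings$atoms,
                                                  function(r) inv[r]),
                                   aromatic = mol$rings$aromatic))
  conf2 <- vs_conformer(mol$id, conf$coords[perm, ], conf$elem[perm])
  expect_equal(sig(perceive_features(conf2, mol2)), sig(base),
               ignore_attr = TRUE)
  ## rigid rotation: centroid features rotate along, to numerical tolerance
  set.seed(3)
  theta <- 0.7
  rot <- matrix(c(cos(theta), -sin(theta), 0, sin(theta), cos(theta), 0,
                  0, 0, 1), 3, 3, byrow = TRUE)
  shift <- c(1.5, -2, 0.5)
  conf3 <- vs_conformer(mol$id, apply_rigid(conf$coords, rot, shift), conf$elem)
  moved <- perceive_features(conf3, mol)
  back <- lapply(moved, function(f) {
    f$position <- as.vector(t(rot) %*% (f$position - shift)); f
  })
  expect_equal(sig(back), sig(base), tolerance = 1e-6, ignore_attr = TRUE)
  ## conformer/molecule mismatch is a consistency error
  bad <- vs_conformer("other", conf$coords[-1, ], conf$elem[-1])
  expect_error(perceive_features(bad, mol), "does not belong")
})

test_that("tabular reports round-trip losslessly in both formats", {
  rep <- data.frame(id = c("a", "b", "c"),
                    ef = c(1.79, 6.15, 1 / 3),
                    n = c(135L, 65L, 0L),
                    pass = c(TRUE, FALSE, TRUE),
                    stringsAsFactors = FALSE)
  for (fmt in c("tsv", "json")) {
    tf <- tempfile(fileext = paste0(".", fmt))
    write_report(rep, tf, fmt)
    back <- read_report(tf, fmt)
    expect_equal(back$id, rep$id)
    expect_equal(back$ef, rep$ef, tolerance = 1e-15)
    expect_equal(back$n, rep$n)
    expect_equal(as.logical(back$pass), rep$pass)
  }
  empty <- rep[0, ]
  tf <- tempfile(fileext = ".tsv")
  write_report(empty, tf)
  expect_equal(nrow(read_report(tf)), 0)
  expect_error(write_report(rep, file.path(tempfile(), "no", "dir.tsv")),
               "cannot write")
})
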