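## Shape and electrostatic field comparison of pre-aligned conformers.
##
## Shape: first-order Gaussian-volume overlap. Every heavy atom carries a
## spherical Gaussian p*exp(-alpha r^2) with amplitude p = 2.7 and a width
## chosen so the Gaussian encloses the same volume as a hard sphere of the
## element's van der Waals radius (the conventional hard-sphere-matching
## prefactor). The overlap of two molecules is the sum of analytic pairwise
## Gaussian product integrals, and the Shape Tanimoto is
## ST = O_ab / (O_aa + O_bb - O_ab), 1 for identical shapes.
##
## Electrostatics: a screened Coulomb potential phi(x) = sum_i q_i/(eps*r_i)
## sampled on a shared rectangular grid spanning both molecules, with points
## inside either molecular van der Waals volume masked out. The electrostatic
## Tanimoto ET = <ab> / (<aa> + <bb> - <ab>) equals 1 for identical fields
## and goes negative when positive and negative potential regions overlap.

#' Field-comparison configuration
#'
#' @param grid_spacing Grid step in Angstrom (default 0.5).
#' @param grid_margin Padding around the union bounding box, Angstrom
#'   (default 4.0).
#' @param gaussian_p Gaussian amplitude for shape overlap (default 2.7).
#' @param dielectric Uniform dielectric constant for the potential
#'   (default 4, a common effective value for buried small-molecule sites).
#' @param st_threshold Minimum Shape Tanimoto for the similarity filter
#'   (default 0.4).
#' @param et_threshold Minimum electrostatic Tanimoto (default 0.2).
#' @return Object of class `field_config`.
#' @export
field_config <- function(grid_spacing = 0.5, grid_margin = 4.0,
                         gaussian_p = 2.7, dielectric = 4,
                         st_threshold = 0.4, et_threshold = 0.2) {
  stopifnot(grid_spacing > 0, grid_margin >= 0, gaussian_p > 0, dielectric > 0,
            is.finite(st_threshold), is.finite(et_threshold))
  structure(list(grid_spacing = grid_spacing, grid_margin = grid_margin,
                 gaussian_p = gaussian_p, dielectric = dielectric,
                 st_threshold = st_threshold, et_threshold = et_threshold),
            class = "field_config")
}

## Gaussian width per atom: alpha = kappa / R_vdw^2 with
## kappa = pi * (3 p / (4 pi))^(2/3), so that integral of the Gaussian
## equals the hard-sphere volume (4/3) pi R^3.
gaussian_alpha <- function(elem, p = 2.7) {
  kappa <- pi * (3 * p / (4 * pi))^(2 / 3)
  kappa / vdw_radius(elem)^2
}

## Sum over atom pairs of the analytic overlap of two spherical Gaussians.
gaussian_overlap <- function(xa, alpha_a, xb, alpha_b, p = 2.7) {
  total <- 0
  for (i in seq_len(nrow(xa))) {
    d2 <- rowSums(sweep(xb, 2, xa[i, ])^2)
    ai <- alpha_a[i]
    s <- ai + alpha_b
    total <- total + sum(p * p * (pi / s)^1.5 * exp(-ai * alpha_b / s * d2))
  }
  total
}

#' Gaussian shape Tanimoto of two pre-aligned conformers
#'
#' @param a,b [vs_conformer()] objects in a common frame (the cascade
#'   guarantees pre-alignment from the pharmacophore and docking stages).
#' @param cfg A [field_config()].
#' @return Shape Tanimoto in (0, 1]; 1 means identical shape.
#' @export
shape_tanimoto <- function(a, b, cfg = field_config()) {
  xa <- a$coords[heavy_idx(a), , drop = FALSE]
  xb <- b$coords[heavy_idx(b), , drop = FALSE]
  if (nrow(xa) == 0 || nrow(xb) == 0) {
    stopf("shape_tanimoto: conformer with no heavy atoms")
  }
  aa <- gaussian_alpha(a$elem[heavy_idx(a)], cfg$gaussian_p)
  ab <- gaussian_alpha(b$elem[heavy_idx(b)], cfg$gaussian_p)
  o_ab <- gaussian_overlap(xa, aa, xb, ab, cfg$gaussian_p)
  o_aa <- gaussian_overlap(xa, aa, xa, aa, cfg$gaussian_p)
  o_bb <- gaussian_overlap(xb, ab, xb, ab, cfg$gaussian_p)
  o_ab / (o_aa + o_bb - o_ab)
}

## Shared evaluation grid over the union bounding box, minus points inside
## either molecular vdW volume. Returns an m x 3 matrix of grid points.
field_grid <- function(a, b, cfg) {
  all_xyz <- rbind(a$coords, b$coords)
  lo <- apply(all_xyz, 2, min) - cfg$grid_margin
  hi <- apply(all_xyz, 2, max) + cfg$grid_margin
  axes <- lapply(1:3, function(k) seq(lo[k], hi[k], by = cfg$grid_spacing))
  pts <- as.matrix(expand.grid(axes[[1]], axes[[2]], axes[[3]],
                               KEEP.OUT.ATTRS = FALSE))
  colnames(pts) <- NULL
  keep <- rep(TRUE, nrow(pts))
  for (conf in list(a, b)) {
    rad <- vdw_radius(conf$elem)
    for (i in seq_len(nrow(conf$coords))) {
      if (!any(keep)) break
      d2 <- rowSums(sweep(pts, 2, conf$coords[i, ])^2)
      keep <- keep & d2 > rad[i]^2
    }
  }
  pts[keep, , drop = FALSE]
}

## Screened Coulomb potential of a charged conformer at grid points.
coulomb_potential <- function(conf, pts, dielectric) {
  phi <- numeric(nrow(pts))
  for (i in seq_len(nrow(conf$coords))) {
    q <- conf$charges[i]
    if (q == 0) next
    r <- sqrt(rowSums(sweep(pts, 2, conf$coords[i, ])^2))
    phi <- phi + q / (dielectric * r)
  }
  phi
}

#' Electrostatic-potential Tanimoto of two pre-aligned conformers
#'
#' Both conformers must carry partial charges. Potentials are evaluated on a
#' shared rectangular grid (union bounding box plus margin; points inside
#' either molecular van der Waals volume are masked out) and compared by the
#' Tanimoto functional on field inner products, which is 1 for identical
#' fields and negative when the fields oppose (e.g. -1/3 for a field versus
#' its own negation).
#'
#' @inheritParams shape_tanimoto
#' @return Electrostatic Tanimoto, at most 1.
#' @export
electrostatic_tanimoto <- function(a, b, cfg = field_config()) {
  if (is.null(a$charges) || is.null(b$charges)) {
    stopf("electrostatic_tanimoto: both conformers must carry partial charges")
  }
  pts <- field_grid(a, b, cfg)
  if (nrow(pts) == 0) stopf("electrostatic_tanimoto: empty evaluation grid")
  pa <- coulomb_potential(a, pts, cfg$dielectric)
  pb <- coulomb_potential(b, pts, cfg$dielectric)
  ab <- mean(pa * pb); aa <- mean(pa * pa); bb <- mean(pb * pb)
  if (aa == 0 && bb == 0) {
    warning("both potential fields are identically zero; ET defined as 1")
    return(1.0)
  }
  ab / (aa + bb - ab)
}

#' Combined shape / electrostatic similarity score
#'
#' @inheritParams shape_tanimoto
#' @return Object of class `similarity_score` with `st`, `et_pb` and
#'   `et_combo = st + et_pb`.
#' @export
field_score <- function(a, b, cfg = field_config()) {
  st <- shape_tanimoto(a, b, cfg)
  et <- electrostatic_tanimoto(a, b, cfg)
  structure(list(st = st, et_pb = et, et_combo = st + et),
            class = "similarity_score")
}

#' @export
print.similarity_score <- function(x, ...) {
  cat(sprintf("ST %.3f  ET_pb %.3f  ET_combo %.3f\n", x$st, x$et_pb, x$et_combo))
  invisible(x)
}

#' Multi-query shape / electrostatic similarity filter
#'
#' A candidate passes if, against AT LEAST ONE query pose, both its Shape
#' Tanimoto and its electrostatic Tanimoto reach the configured thresholds.
#' The combined score is reported but is not itself a filter criterion.
#'
#' @param candidates Named list of candidate [vs_conformer()]s (model-frame
#'   poses surviving the docking re-match).
#' @param queries Non-empty list of query [vs_conformer()]s in the same frame.
#' @param cfg A [field_config()] carrying `st_threshold` and `et_threshold`.
#' @return List with `hits` (character ids) and `scores`, a data.frame of
#'   every candidate/query pair (candidate, query, st, et_pb, et_combo, pass)
#'   plus attribute `best`: per-candidate row index of the maximizing query.
#' @export
similarity_filter <- function(candidates, queries, cfg = field_config()) {
  if (length(queries) == 0) stopf("similarity_filter: empty query set")
  if (is.null(names(candidates)) || any(names(candidates) == "")) {
    stopf("similarity_filter: candidates must be a named list")
  }
  rows <- list()
  hits <- character()
  for (id in names(candidates)) {
    cand <- candidates[[id]]
    best_combo <- -Inf; passed <- FALSE
    for (qi in seq_along(queries)) {
      sc <- field_score(cand, queries[[qi]], cfg)
      ok <- sc$st >= cfg$st_threshold && sc$et_pb >= cfg$et_threshold
      rows[[length(rows) + 1]] <- data.frame(
        candidate = id, query = qi, st = sc$st, et_pb = sc$et_pb,
        et_combo = sc$et_combo, pass = ok, stringsAsFactors = FALSE)
      if (ok) passed <- TRUE
      if (sc$et_combo > best_combo) best_combo <- sc$et_combo
    }
    if (passed) hits <- c(hits, id)
  }
  scores <- do.call(rbind, rows)
  list(hits = hits, scores = scores)
}
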