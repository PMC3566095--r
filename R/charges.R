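## Partial-charge assignment for real molecules via the Gasteiger iterative
## partial-equalization method, delegated to Open Babel (deterministic).
## Synthetic feature clouds carry their charges directly.

#' Assign Gasteiger partial charges to a conformer
#'
#' Writes the molecule's connection table with the conformer's coordinates,
#' runs Open Babel's Gasteiger charge model, and returns the conformer with
#' `charges` populated.
#'
#' @param conf A [vs_conformer()].
#' @param mol The [vs_molecule()] providing the bond table.
#' @return `conf` with partial charges set.
#' @export
assign_gasteiger_charges <- function(conf, mol) {
  stopifnot(inherits(conf, "vs_conformer"), inherits(mol, "vs_molecule"))
  obabel <- require_tool("obabel")
  td <- tempfile("charges"); dir.create(td)
  on.exit(unlink(td, recursive = TRUE), add = TRUE)
  in_sdf <- file.path(td, "in.sdf")
  write_conformers_sdf(list(conf), in_sdf, bonds = list(mol$bonds))
  out <- suppressWarnings(system2(
    obabel, c(in_sdf, "-omol2", "--partialcharge", "gasteiger"),
    stdout = TRUE, stderr = FALSE))
  atom_start <- grep("@<TRIPOS>ATOM", out)
  atom_end <- grep("@<TRIPOS>BOND", out)
  if (length(atom_start) == 0 || length(atom_end) == 0) {
    stopf("charge assignment failed for %s", conf$mol_id)
  }
  lines <- out[(atom_start[1] + 1):(atom_end[1] - 1)]
  fields <- strsplit(trimws(lines), "\\s+")
  q <- vapply(fields, function(f) as.numeric(f[length(f)]), numeric(1))
  if (length(q) != nrow(conf$coords) || any(is.na(q))) {
    stopf("charge assignment returned %d charges for %d atoms (%s)",
          length(q), nrow(conf$coords), conf$mol_id)
  }
  conf$charges <- q
  conf
}
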