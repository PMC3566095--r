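---
title: "Methods: the ppargscreen virtual-screening cascade"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the ppargscreen virtual-screening cascade}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`ppargscreen` implements a sequential structure-based screening strategy
for PPARγ partial agonists: exclude full-agonist-like binders first, then
select partial-agonist-like ones, then confirm that the selection survives
receptor-docked geometry and field-level similarity to known partial
agonists. This vignette records the models behind each stage, the
parameters that matter, the numerical conventions, and the design choices
made where the design was genuinely open.

## Pharmacophore matching

A pharmacophore model is a set of typed sites (acceptor, donor,
hydrophobic, aromatic, charged) at fixed 3D positions with a spherical
matching tolerance per site, plus excluded volumes — spheres marking
receptor-occupied space. A conformer matches when an injective,
kind-compatible assignment of at least `min_match` sites onto its perceived
features exists such that, after a closed-form least-squares rigid
superposition (SVD-based, reflection-corrected), every matched feature lies
within its site's tolerance and no heavy atom penetrates an excluded
volume. Matching modes:

* **free orientation** (`reorient = TRUE`) for *in vacuo* conformers: the
  superposition is part of the search;
* **fixed pose** (`reorient = FALSE`) for docked poses: the identity
  transform is used, so a pose must already sit on the sites. Any fixed-pose
  match is therefore also a free-orientation match, never the reverse.

Assignments are enumerated exactly — site counts are at most 5, so the
search space is trivial — with two sound prunings: feature kinds must be
compatible with site kinds (hydrophobic sites also accept aromatic-ring
features when the aromatic-as-hydrophobic amendment is on), and a partial
assignment is abandoned when any feature–feature distance differs from the
corresponding site–site distance by more than the sum of the two
tolerances, a necessary condition for any rigid fit within tolerances.
Among accepting assignments the lowest-rms one wins; ties prefer the larger
assignment, then the lexicographically smallest site-index tuple. A
conformer whose only within-tolerance fits penetrate excluded volumes is
reported as `clash = TRUE` and, in the exclusion stage, *survives*: we
treat a clashing 4-of-5 geometric match as not a match, since the receptor
itself forbids that binding mode. This is a deliberate reading of an
underdetermined rule; the flag is kept in the report so the opposite
convention can be audited.

Default site tolerance is 2.0 Å (common pharmacophore practice; per-site
overrides live in the `pharmacophore-json v1` files) and default excluded
volume radii are 1.5 Å, a conservative clash radius for heavy atoms. The
antipharmacophore fixture has 5 sites (2 acceptors + 3 hydrophobics),
`min_match = 4`, exclude mode; the partial-agonist fixture has 4 sites
(1 acceptor + 3 hydrophobics), all required, include mode. **The shipped
geometries are synthetic**: the real models derive from superposed
agonist–receptor crystal complexes whose site coordinates are inputs, not
package data, so the fixtures only honor the site compositions, the
matching thresholds, and a deliberate scale separation (the
antipharmacophore spans ~12 Å versus ~5 Å for the partial model) that the
generator verifies at build time.

## Feature perception

Features are perceived from the molecular graph with an editable YAML rule
table (`inst/extdata/feature_rules.yaml`): acceptors are N/O atoms bearing
a lone pair and no positive charge; donors are N–H/O–H (hydrogens may be
implicit, inferred from default valences); hydrophobic groups are connected
components of ≥ 3 aliphatic carbons without multiple bonds to heteroatoms,
plus halogens on aromatic rings; each aromatic ring contributes one feature
at its unweighted centroid, emitted as hydrophobic-compatible when the
aromatic-as-hydrophobic amendment is enabled (the workflow's setting).
Single-atom features sit on the atom, multi-atom features on the unweighted
centroid. The table is a transparent surrogate for a commercial suite's
built-in definitions, which are not public; only the aromatic amendment is
pinned by the workflow itself.

## Library preparation

Drug-likeness follows the rule of five — MW ≤ 500 Da, logP ≤ 5,
donors ≤ 5, acceptors ≤ 10 — with **one violation allowed** by default.
Donor/acceptor counts use Lipinski's original N+O convention (acceptors =
N + O count; donors = OH + NH count) rather than pharmacophoric typing;
logP is the Crippen-type atomic-contribution estimate from Open Babel, and
MW comes from ChemmineR. A small editable SMARTS list of reactive
"warhead" groups (acyl/sulfonyl halides, epoxides, isocyanates, thiols,
peroxides, …) stands in for a full toxicophore catalogue; failures carry
machine-readable reasons.

Conformer ensembles are generated by a deterministic rule-based 3D build
followed by Open Babel's systematic diverse-conformer search (Confab) with
the workflow's parameters: at most **200 conformers** per molecule inside a
**25 kcal/mol** window, duplicates removed below 0.5 Å heavy-atom RMSD.
The build deliberately uses the non-stochastic construction level so
repeated runs give identical ensembles; the systematic torsion search, not
a random rotor search, provides the conformational coverage. MMFF94
energies are re-evaluated on the final ensemble so the window contract is
independently checkable.

## Docking poses

Docking itself is outside the computation boundary: the published workflow
used a commercial engine, and this package's contract is "poses in →
pharmacophore-consistent poses out". Poses enter as SDF records carrying a
score property (lower is better by default, configurable), are grouped by
molecule id, sorted stably (ties keep file order) and truncated to the best
**32** poses. Re-matching runs the partial pharmacophore in fixed-pose mode
against the model's excluded volumes. A deterministic stub docker generates
test poses: for molecules flagged docking-compatible it plants the
molecule's best free-orientation match, transformed into the model frame,
among randomly placed decoy poses with randomized scores.

## Shape and electrostatic similarity

Both scores assume the candidate and query are **pre-aligned** in the
pharmacophore frame, which the cascade guarantees (stage-2 matches are
transformed into the model frame; stage-3 poses are already there).

*Shape.* Every heavy atom carries a spherical Gaussian of amplitude
`p = 2.7` whose width is set so the Gaussian integrates to the volume of a
hard sphere with the element's Bondi van der Waals radius
(`α = π (3p/4π)^{2/3} / R²`). Molecular overlap is the analytic sum of
pairwise Gaussian product integrals (first-order approximation), and
`ST = O_ab / (O_aa + O_bb − O_ab)` lies in (0, 1], reaching 1 only for
identical shapes. Because the overlap depends only on interatomic
distances, ST is exactly invariant under a common rigid motion.

*Electrostatics.* Partial charges (Gasteiger for real molecules; explicit
for synthetic clouds) generate a screened Coulomb potential
`φ(x) = Σ qᵢ / (ε rᵢ)` with a uniform effective dielectric `ε = 4`,
evaluated on a shared rectangular grid: the union bounding box padded by
4 Å, spacing 0.5 Å, with points inside either molecule's van der Waals
volume masked out (the potential diverges at the nuclei; masked Tanimoto
comparison is standard for field similarity). Then
`ET_pb = ⟨φ_aφ_b⟩ / (⟨φ_a²⟩ + ⟨φ_b²⟩ − ⟨φ_aφ_b⟩)`, which is 1 for
identical fields, −1/3 for a field against its own negation, and ≤ 1
always. Two identically zero fields are defined as similarity 1 with a
warning. This screened-Coulomb model is the package's own, configurable
choice; it is not a Poisson–Boltzmann solver, but the Tanimoto functional
and its identities — which the tests pin — are solver-independent, and the
grid interface admits a different potential backend.

A candidate passes the filter when **ST ≥ 0.4 and ET_pb ≥ 0.2 against at
least one query** (OR aggregation over the five query poses). The
published workflow does not state whether one or all queries had to pass;
OR is the weaker and, we judge, intended reading — the queries are five
different known binding modes, and resembling any one suffices.
`ET_combo = ST + ET_pb` is reported per pair but is not itself a
criterion, matching the use of the two component thresholds.

## Validation arithmetic

For a stage with `a_in/d_in` actives/decoys entering and `a_out/d_out`
surviving: `EF = [a_out/(a_out+d_out)] / [a_in/(a_in+d_in)]`,
`Se = 100·a_out/a_in`, `Sp = 100·(d_in−d_out)/d_in`. Overall metrics use
the first stage's pool against the last stage's survivors;
`EF_max = (a_in+d_in)/a_in` is attained exactly when no decoy survives,
and the overall sensitivity factorizes into the product of stagewise
sensitivities — both identities are tested. The exclusion stage is
reported with counts only, following the convention that EF/Se/Sp are not
estimated for a step designed to remove actives' competitors rather than
select actives. Raw values are carried at full precision; table display
rounds half away from zero to 2 decimals.

## Fingerprints, clustering and the Kelley criterion

Scaffold analysis encodes, for every heavy atom, its circular environments
of radius 0, 1 and 2 bonds (center atom type plus the sorted multiset of
(distance, neighbor-type) pairs; types are element + aromatic flag) and
hashes each environment into a 32-bit address space with FNV-1a; a
molecule's fingerprint is the resulting identifier set, compared by set
Tanimoto. Hash collisions can only merge rare environment pairs and
perturb similarities slightly, which the tests tolerate by construction.

Clustering is agglomerative on `1 − Tanimoto` distances with
Lance–Williams updates (average linkage by default — the published
workflow does not name its linkage — with complete and single available)
and a fixed tie-break: among minimum-distance cluster pairs, merge the one
whose lexicographically smallest member ids sort first. The tree is
`hclust`-compatible, so `cutree`/`cophenetic` apply, and on tie-free
distances it agrees with `stats::hclust` exactly; the in-package
implementation exists because reproducible screening reports need a
*stated* tie-break, which `hclust` does not expose.

The number of clusters is chosen by the Kelley criterion: for each level
with `k` clusters, the spread is the mean over clusters of size ≥ 2 of
their mean pairwise (original, not cophenetic) distance; spreads are
min–max normalized onto `[1, n−2]` so their range matches the range of
`k`; the level minimizing `normalized spread + k` wins, ties going to the
smaller `k`. Candidate levels are `k = 2 … n−1`: both trivial ends are
excluded, the one-cluster level because its spread is not a within-cluster
quantity in any useful sense, the all-singleton level because no spread is
defined at all. With the one-cluster level included, the criterion's
penalty ties degenerate three-leaf cases toward `k = 1` and the criterion
stops resolving forced two-cluster geometries, so the classical convention
is the coherent one. All-identical inputs return `k = 1` with a warning.
The selection is invariant under scaling all distances, which the tests
assert.

## The synthetic benchmark

`make_benchmark()` plants geometric ground truth so the entire cascade is
exercisable offline, with known expected behavior at every stage:

* **actives** embed the partial model's sites (an acceptor-bearing oxygen
  plus three carbons, one decoration atom) to within `embed_noise`,
  verified not to trip the antipharmacophore, shipped in a random rigid
  frame, with query-like charges and the docking-compatible flag;
* **field decoys** (12.5 % of decoys by default) embed the partial model
  geometrically but carry negated charges — they survive the pharmacophore
  stages (half of them are docking-compatible) and fail the electrostatic
  threshold (`ET ≈ −1/3` against every query);
* **anti decoys** (25 %) sit on the antipharmacophore's sites and are
  removed at stage 1;
* **plain decoys** are random clouds rejection-sampled (cap 10⁴ attempts,
  failure raises) to embed neither model.

Entries are feature *clouds*: conformers whose atoms carry their features
directly (O/N → acceptor, C → hydrophobic), bypassing graph perception so
the geometric pipeline is testable in isolation; the chemistry path
(SMILES/SDF → perception → descriptors → conformers) is tested separately
on real small molecules. The defaults (20 actives / 80 decoys, noise 0,
the fractions above) are the package's benchmark study conditions: they
are large enough that every stage filters something and every planted
property is individually observable, and the stage composition — some
decoys failing at each successive stage — mirrors the qualitative shape of
a real labeled validation screen at roughly 1/40 scale of the published
211/3,122 pool. At `embed_noise = 0` planted actives achieve 100 %
sensitivity through every stage by construction; survival decays
monotonically as noise approaches the 2 Å site tolerance; a noise above
the tolerance is rejected as an infeasible specification rather than
producing a silently broken benchmark. Labels ride along for bookkeeping
only; tests scramble them and assert identical survivor sets.

What the generator does **not** emulate: property-matched decoy selection
(as in curated decoy collections), real conformational strain, tautomers
and protonation states, docking-score realism, and the structural
diversity of a natural-product library. Passing the planted benchmark
therefore demonstrates the correctness of the filters' geometry and
bookkeeping, not retrospective performance on real screening data.

## Problem sizes and numerical conventions

The test suite runs the planted cascade at 20/80, oracle-checks matching
on 200 random ≤ 8-feature instances against exhaustive enumeration,
clustering on 6-molecule sets against a from-scratch agglomerator, and
Kelley selection on ≤ 10-leaf trees against plain penalty evaluation —
sizes chosen so every oracle is exact and the full suite completes in a
few minutes on one core. Floating-point ties in matching are resolved at
1e−12; field identities hold to 1e−9; the electrostatic grid is considered
converged when halving the spacing moves ET by < 0.02 on the fixtures.
Degenerate inputs are contracts, not accidents: empty libraries produce
all-zero reports, empty survivor sets make EF an explicit error, zero-atom
conformers are domain errors, and bond-less single-atom records (which the
upstream SDF parser rejects) are recovered by a fixed-format fallback.

## Known limitations

Re-implementations of the commercial engines (conformer enumeration,
docking, field similarity, fingerprint software) are explicitly out of
scope, so numeric agreement with their outputs is neither expected nor
testable; the shipped pharmacophore geometries are synthetic; the
electrostatic model is screened-Coulomb, not Poisson–Boltzmann; Gasteiger
charges are a deterministic but simple charge model; and hit counts from
proprietary compound collections cannot be reproduced — the package
substitutes oracle equivalence and planted-signal recovery as its
verifiable claims.
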