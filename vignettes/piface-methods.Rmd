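---
title: "Interface extraction, similarity and community-based clustering: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interface extraction, similarity and community-based clustering: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(piface)
```

## The problem

Protein–protein interfaces — the contact regions through which two chains
associate — recur across unrelated complexes: structurally similar binding
architectures appear on proteins with different folds and different
sequences. A library of structurally *non-redundant* interface
architectures is the key input to template-based docking: a monomer surface
matched against a representative interface predicts a complex. `piface`
builds such a library from coordinate files: it extracts every two-chain
interface, scores all-against-all structural similarity with a
sequence-order-independent aligner, clusters the resulting similarity
network with an edge-betweenness community-finding algorithm accelerated by
node grouping, validates the clustering with the silhouette index, and
derives representatives, docking surfaces and multi-interface binding
profiles.

## Interface definition

Two residues on different chains are **contact residues** when any pair of
their heavy atoms lies closer than the sum of the atoms' van der Waals
radii plus 0.5 Å (strict `<`; Bondi-style radii, configurable via
`vdw_radius()`). **Nearby residues** are non-contact residues whose Cα lies
strictly within 6 Å of a contact residue's Cα on the same chain; they give
the interface a non-isolated architecture and take part in alignment. An
interface is retained only when each side contributes at least five
*contact* residues (whether the historical rule counted contact or
contact+nearby residues is not documented; contact-only is our reading and
the `min_rule` argument exposes the alternative). Interfaces are named
`<PDBID><chainA><chainB>`.

Chain pairs are pre-screened by buried surface area — ASA(A) + ASA(B) −
ASA(AB), computed with the pair isolated from all other chains — and pairs
burying ≤ 1 Å² are discarded before residue-level extraction. The
knife-edge equality at exactly 1 Å² is excluded by the `>` contract.

Input filtering is deliberately blunt and deterministic: first NMR model
only; highest-occupancy altloc (ties by letter); waters and non-polymeric
heteroatoms removed; nucleic-acid chains removed; any chain containing a
polymeric residue outside the 20 standard amino acids (e.g.
selenomethionine) dropped whole rather than trimmed — the stricter of the
two readings of the rule.

## Accessible surface area

ASA is computed with a Shrake–Rupley sphere-sampling engine
(`compute_asa()`): each atom's solvent-extended sphere (probe 1.4 Å, the
NACCESS default) is sampled at `n_points` golden-section-spiral points
(default 960) and the accessible fraction counted against neighbouring
extended spheres. The spiral is deterministic, so results are reproducible
without a seed, and converge to analytic values as `n_points` grows (the
test suite checks isolated spheres and the two-sphere spherical-cap
closed form at 1%). The contract is NACCESS-*equivalent*, not
bit-compatible; the Table-1-scale tolerance for buried areas is 5%.
Coincident equal atoms mutually occlude — the conservative convention for
duplicated coordinates.

Relative ASA (RASA, percent) divides a residue's ASA by NACCESS-style
Ala-X-Ala maxima (`default_max_asa_table()`, swappable). Values above 100%
(extended termini) are not clipped.

## Non-sequential alignment and similarity

Interfaces are discontinuous in sequence, so comparison must ignore residue
order. The external aligner used historically (MultiProt) is not available
as a library contract, so `align_interfaces()` implements a deterministic
seed-and-extend scheme over interface Cα sets: local triangles (each
residue with two of its five nearest neighbours) are matched across the two
interfaces by side-length congruence (≤ 1 Å per side), each seed's
three-point Kabsch transform is extended by mutual-nearest-neighbour
matching within the 3 Å threshold and refined to a fixed point, and the
transform with the most matched residues wins (ties: lower RMSD, then seed
order). Precomputed external similarity tables can be imported with
`read_similarity_tsv()` to bypass the engine entirely. Published similarity
values for specific PDB pairs are reference checks at engine-substitution
tolerance (±0.05), not bit-exact targets.

Similarity is the matched fraction of the smaller interface:
`n_matched / min(n1, n2)`, capped at 1, with `n` counting contact + nearby
residues (the aligner's input). The printed form of the similarity formula
in the source literature is typographically incomplete; the `min`
denominator is the completion consistent with the 1.25× size gate and with
clusters being called distinct below 75% similarity. `denom = "mean"|"max"`
and `residues = "contact"` are provided for sensitivity analyses.

Before alignment, pairs are gated by size compatibility: the larger contact
count may exceed the smaller by at most 25%, the larger total count by at
most 50%. Gated-out pairs never acquire a similarity value and are treated
downstream as maximally dissimilar.

## Network clustering

`build_network()` draws a node per interface and an edge when similarity
reaches the edge threshold. The threshold used to declare "similar" is not
printed in the source; 0.75 is adopted because clusters are described as
distinct below 75% similarity, and it is configurable.

`girvan_newman_divide()` repeatedly removes the edge with the highest
exact (Brandes) betweenness — ties broken by lexicographic endpoint names —
recomputing after each removal, until the component splits, and recurses.
Two stopping rules end recursion on a component:

* **Clustering coefficient**: the mean local coefficient
  `2eᵢ/(kᵢ(kᵢ−1))` (degree < 2 contributes 0) reaching the criterion
  `cc_stop`. The comparison is `≥`, not the literal "higher than": with the
  best-performing criterion equal to 1.0 and the coefficient capped at 1.0,
  a strict `>` would never stop on cliques.
* **Minimum cluster size** (5 interfaces): a component holding fewer than 5
  interfaces is not divided further, so the network does not fall apart
  into dust. We apply the rule to every component, not only to freshly
  split ones; the two readings differ only for inputs that start below the
  threshold.

`group_nodes()` condenses the network before division: while any edge
reaches the stage threshold, the highest-weight edge's endpoints merge into
a supernode whose edges take the maximum (or minimum) of the merged nodes'
weights to each neighbour. Max mode is the default (it validated better in
the source work). Grouping is pure run-time optimisation — betweenness is
computed on the much smaller condensed graph — and therefore **must not
change where division stops**: when dividing a condensed graph,
`cluster_interfaces()` evaluates the stopping coefficient on the underlying
interface subgraph, not on the condensed one. Without this, a clique whose
condensation happens to be two supernodes (coefficient 0) would be split —
an artefact of the acceleration, not a property of the data.

`cluster_interfaces()` stages the procedure at grouping thresholds 0.80,
0.85, 0.90, 0.95, 1.00 (processed in increasing order, per the source's
description), dividing after each grouping and expanding supernodes back to
interfaces between stages; a final division pass runs without any
grouping. The staged text is ambiguous about whether supernodes persist
across stages; persistence would make every stage after the first a no-op
(grouping-to-exhaustion leaves no edge above a *higher* threshold), so the
expand-and-refine reading is the one that gives all five stages effect.
Output order and every tie-break are deterministic, so identical inputs
reproduce identical clusterings. Parameter cells are tagged
`<100·cc_stop>_<step%>_<mode>`, e.g. `100_5_max`.

Representatives maximise mean similarity to their cluster's other members
(ties by name; singletons represent themselves).

## Validation

`silhouette_index()` uses dissimilarity `1 − similarity`, with pairs absent
from the similarity data (gated out or sub-threshold) treated as
dissimilarity 1 — the conservative completion of sparse similarity data.
Singleton clusters score 0 (Rousseeuw's convention); how the original
averaging handled its thousands of singletons is unstated, so both choices
are documented knobs rather than claims. A single-cluster partition has no
defined silhouette and errors; `parameter_grid_eval()` maps that case to
`NA` and ranks it last, with remaining ties broken by cell tag for a stable
ranking.

## Surfaces and multi-interface binding

`surface_residues()` keeps residues of an isolated monomer with RASA
strictly above the cutoff. The default cutoff is 40% — the level reported
to capture ~99% of average interface-residue exposure in representative
libraries — with the classical 5% exterior-residue convention available.
`rasa_statistics()` reports the mean/SD *across interfaces* of each
interface's average contact (and nearby) RASA, matching the
per-representative averaging convention.

Chains are grouped by **exact** sequence identity
(`sequence_identity_clusters()`): identical strings, ids in first-seen
order. This replaces the pre-clustered alignment downloads used
historically — identical semantics, no external dependency. Interfaces
sharing the unordered pair of sequence-cluster ids form a pair profile;
a profile spanning more than one structural cluster is a multi-interface
pair. Within such a profile, `classify_binding_sites()` maps contact
residues to sequence positions on the common monomer (valid at 100%
identity), measures pairwise overlap as the fraction of the smaller contact
set, and calls overlap ≥ 0.5 a shared site; binding sites are the connected
components of the shared relation. The published shared/distinct split does
not disclose its criterion — the 0.5 rule is an explicit stand-in exposed
as `overlap_threshold`, not a reconstruction.

## Synthetic fixtures: what they do and do not establish

`make_toy_complex()` builds two backbone-only (N, CA, C, O) poly-alanine
strands whose carbonyl oxygens face each other across a configurable gap;
residues inside the contact span satisfy the contact rule at the default
6.4 Å gap, flanking residues curve away and become nearby, remote residues
neither. `perturb_interface()` jitters a seed-chosen fraction of interface
residues to create families of similar-but-distinct interfaces, and
`planted_partition_graph()` draws Bernoulli similarity networks with known
communities. All randomness flows from one integer seed through a
save/restore RNG wrapper; no global state leaks.

These fixtures exercise every rule in the pipeline (contact arithmetic,
ASA, alignment, gating, clustering, silhouette) at desk scale, but they are
idealised: no side chains, no packing, no crystallographic noise, planted
communities are cliques or near-cliques. A green synthetic test establishes
that the rules are implemented as stated, not that the full-PDB library or
its headline counts are reproduced — those derive from a compute campaign
outside any test budget, and the per-entry worked-example checks require
deposited coordinates that an offline environment cannot fetch (they run
when the user drops the entries into `tests/testthat/reference_pdb/`).

## Numerical and degenerate-input conventions

* Strict `<` at the contact (vdW + 0.5 Å) and nearby (6 Å) thresholds;
  strict `>` for the 1 Å² prefilter and RASA cutoffs.
* Sphere sampling at 960 points bounds single-atom ASA error well under 1%;
  buried-area tolerance is sampling-limited, tested at 2% under
  point-doubling.
* Alignment needs ≥ 3 Cα per interface; degenerate seeds (collinear
  triangles pass through Kabsch unharmed) are ranked by side-length
  deviation, and a full-coverage match with RMSD < 0.1 Å short-circuits the
  seed loop.
* Structures with no surviving protein chain filter to an empty structure
  and are skipped, not errors; an empty pipeline input warns and writes
  empty products.
* All orderings (chain pairs, interface names, betweenness ties, grouping
  ties, cluster output) are lexicographic, making every stage reproducible
  byte-for-byte.

## Known limitations

* The built-in aligner is a pragmatic stand-in for geometric-hashing
  aligners; on real interfaces its matched counts can differ from
  MultiProt's by a few percent (hence the ±0.05 reference tolerance).
  Import of external similarity tables is first-class.
* ASA is numerical, not analytic; agreement with NACCESS is contract-level.
* mmCIF support reads a single `atom_site` loop (coordinates, occupancy,
  models); exotic CIF constructs are out of scope.
* Biological-unit expansion (BIOMT), symmetry mates, Voronoi- or ASA-based
  interface definitions, hot-spot energetics and external benchmark
  comparisons are out of scope by design.
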