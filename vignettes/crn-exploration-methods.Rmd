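---
title: "Methods: exploring DNA self-assembly reaction networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: exploring DNA self-assembly reaction networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crnscape)
```

## The problem

Small sets of DNA strands can self-assemble into whole families of
structures: hairpins, duplexes, linear polymers, branched junctions. At the
*domain level* a strand is a short list of abstract binding units
("domains", written `a`, `b*`, ...), where `x*` is the Watson–Crick
complement of `x` and distinct domains are assumed orthogonal. Given a set
of strands, the reachable structures and the reactions connecting them form
a chemical reaction network (CRN). `crnscape` provides the machinery to

1. model multistranded, pseudoknot-free complexes (kernel notation),
2. enumerate the CRN of a strand set under four reaction types,
3. search the space of strand subsets of a library with a
   quality-diversity (MAP-Elites) algorithm,
4. assign and optimize nucleotide sequences so that predicted
   minimum-free-energy (MFE) folds agree with the domain-level design
   ("well-formed" structures), and
5. analyse the resulting reaction graphs with network-science metrics.

## Complexes and kernel notation

A complex is a circularly ordered list of strands plus a set of pairings
between domain occurrences. Pairings must join complementary domains, be
non-crossing (pseudoknot-free) when the strands are laid out in the stored
order with `+` breaks, and connect all strands. Kernel notation writes
`d(` for a helix opener, a bare `)` for its implicit complement, and `+`
between strands:

```{r}
duplex <- parse_kernel("a( a*( + ) )")
duplex
canonical_kernel(rotate_complex(duplex, 1))
```

`canonical_form()` minimizes the written kernel string over all circular
rotations of strand order that keep the pairing non-crossing, so two
representations of the same complex compare equal by string. Arbitrary
strand permutations are *not* searched at canonicalization time (the
circular order is part of the representation, as in kernel files); product
construction after a reaction, however, does search orderings to find a
non-crossing embedding, and discards the move if none exists.

## Libraries and genomes

An (n, m) library is the exhaustive list of `(2m)^n` ordered strands of
`n` domains over `m` base domains and their complements. (The cardinality
follows the preset dimension table — 16, 256, 1728 — rather than the
`n^(2m)` sometimes quoted, which those dimensions contradict.) Presets:

```{r}
build_library(library_preset("L1"))
```

A *genome* is a Boolean membership vector over a library's strands, capped
by default at 7 selected strands.

## The enumerator

`enumerate_crn()` closes a strand set under four moves:

* **bind** — hybridization of an unpaired domain with an unpaired
  complement, intramolecular or intermolecular;
* **open** — removal of one existing pair, gated by `release_cutoff`
  (maximum nucleotide length of a domain that can spontaneously open; the
  default is the longest domain in the library, so the 10-nt hairpin of
  the worked example can re-open);
* **branch3** — three-way branch migration: an unpaired invader adjacent
  to an anchor helix displaces the incumbent paired to its complement on
  the opposite strand. Remote (non-adjacent) toeholds are excluded to keep
  move patterns local and finite;
* **branch4** — four-way branch migration: two helices of the same domain
  type meeting at a junction exchange partners. Two stacked rungs of a
  single helix are not a junction (otherwise every duplex would shear into
  hairpins).

Opens remove one pair per move; whole-helix opening is not modelled.
No-op reactions (product multiset equal to reactant multiset after
canonicalization) are discarded. Growth is bounded by `max_complex_size`,
`max_structures` and `max_reactions`; when a cap fires the CRN is returned
with `truncated = TRUE` rather than raising.

### Resting/transient condensation

Bimolecular reactions are slow, unimolecular ones fast. With
`transient_policy` on, only resting complexes take part in intermolecular
binds, and the returned CRN is condensed. The classification rule is
deliberately *per-complex* rather than the macrostate (SCC) condensation
used by some enumerators: a complex is **transient** iff

* it has a unimolecular 1→1 exit that leaves its strongly connected
  component in the 1→1 unimolecular reaction digraph (one-way decay), or
* it has a spontaneous unimolecular dissociation (1→2) exit *and* at least
  one other unimolecular exit (a fleeting on-pathway intermediate).

A lone dissociation exit does **not** make a complex transient: a duplex
held together by a single weak domain is a resting species whose
dissociation is an ordinary slow reaction. This rule was chosen because
strict macrostate condensation merges the open strand and its hairpin into
one macrostate and classifies the duplex as transient in the worked
single-strand example, leaving one species and no reactions — whereas the
intended condensed picture for `a a*` is three structures and two
reversible reactions, with only the half-paired two-strand intermediate
condensed away:

```{r}
crn <- enumerate_crn(list(c("a", "a*")), c(a = 10L),
                     enum_params(max_complex_size = 2, release_cutoff = 10))
crn
crn_metrics(crn)
```

Transient complexes are collapsed through their *fate multisets* (memoized
closure over unimolecular reactions); initial strands are kept even when
transient so that condensed pathways from the sources remain expressible.
Cycles among transients fall back to keeping the complex (rare, flagged by
construction).

CRN summary metrics: `mss`, the mean strand count over structures, and
`ert`, the Shannon entropy (base 2) of the reaction-type distribution
(0 when there is at most one reaction). Both refer to the condensed CRN by
default; whether a "number of reactions" axis should count condensed or
detailed reactions is genuinely ambiguous, and we default to condensed
(`detailed = TRUE` gives the other convention).

## MAP-Elites exploration

`run_map_elites()` maintains a 3 × 50 × 55 grid (8250 bins) over

* k, the number of selected strands, binned [1–2], [3–4], [5–7] (the grid
  depth of 3 is fixed by the reference layout; the edges are not published,
  so an even split of 1..7 is used),
* log10(#reactions + 1) over [0, 4] in 50 bins,
* #structures over [0, 2750] in 55 bins,

with out-of-range values clamped to boundary bins (clamping rather than
rejection keeps every evaluation informative). Fitness is MSS or ERT.
The loop is steady-state (batch size 1): initialize with `init_size`
(default 100) random genomes with popcount uniform in [1, max_strands],
then repeatedly mutate a uniformly chosen elite (1–3 bit flips with cap
repair) and offer the evaluated mutant to its bin. Replacement is strict
improvement; ties keep the incumbent so that reruns are bit-reproducible.
Evaluations are cached by genome, and every evaluation (cached or not)
counts against the budget. Independent runs are aggregated per-bin by
`aggregate_grids()`; `grid_report()` gives coverage counts, coverage
percentage (count over 8250 — reported as both count and computed
percentage, since published count/percentage pairs are not always
internally consistent) and grid intersections.

`exhaustive = TRUE` instead evaluates every non-empty subset of at most
`max_strands` strands exactly once (26 332 subsets for the 16-strand L1
preset under the 7-strand cap).

## Folding and well-formedness

The external thermodynamic engine is replaced by a pluggable oracle
contract: given a strand multiset with sequences, return one non-crossing
pairing. The bundled deterministic stand-in maximizes the total number of
paired nucleotides over *aligned pairings of fully sequence-complementary
domains*: a Nussinov-style dynamic program over domain tokens, maximized
over strand orderings distinct up to rotation. Among co-optimal pairings a
connected one is preferred (the multiset is being folded *as one
complex*); remaining ties break on the lexicographically smallest sorted
pair list. Watson–Crick complementarity only — G·T wobbles do not count as
hybridized. Free-energy models, partition functions and concentrations are
out of scope; an external MFE engine can be plugged in via the `engine`
argument of `fold_mfe()`.

`wellformed_domains()` maps nucleotide pairs back to the domain design:
any pairing between non-complementary domain types, or at mis-aligned
offsets (position i of `d` must pair position len−1−i of `d*`), rejects
the structure. A domain-occurrence pair with at least
`hybridization_fraction` (default 0.5; the reference thresholds are
unpublished, so the value is exposed and echoed in reports) of its
nucleotides paired becomes a domain-level pair. The resulting domain-level
complex must be connected — a fold that separates into independent pieces
is not a structure of that multiset (its pieces are folded as their own
multisets).

`match_overlap()` counts canonical structures agreed by the folding side
and the enumerator. The denominator is the number of enumerated structures
with strand count within the folding size cap, since only those are
observable by the folding side.

## Sequence optimization

`optimize_sequences()` maximizes the overlap count at a folding cap of 3,
by random search or an elitist, mutation-only GA (defaults: population 32,
elite keep 8, no crossover — the reference hyperparameters are
unpublished; these match a mutation-centric description and are echoed in
the run metadata). Mutations change 1–3 bases; complements follow
automatically since complement sequences are always derived as reverse
complements. The winner is re-evaluated at a cap of 8
(`reevaluate_overlap()`), and `compare_optimizers()` selects the algorithm
with the higher re-evaluated proportion per CRN. Objective values are
cached by assignment, ties keep the earlier-evaluated individual, and all
runs are reproducible from (seed, run index).

## Network analysis

`build_graph()` renders a CRN as a directed graph: structures are regular
nodes; a 1-reactant-1-product reaction is a single edge; any reaction with
more than two participants becomes a reaction node with reactant→reaction
and reaction→product edges. Reactant multiplicity (2X → Y) is collapsed to
one edge with a `multiplicity` attribute. Node kinds: source, wellformed,
intermediary, reaction.

`overlap_network()` extracts, for every ordered (source, well-formed)
pair, up to `k_paths` (default 6) shortest simple directed paths — Yen's
algorithm with deterministic (length, lexicographic) tie-breaks — and keeps
exactly the nodes and edges on those paths. The "six paths" figure is an
interpretation of an ambiguous prose constraint; it is configurable and
echoed in reports.

Statistics (`graph_stats()`):

* **density** m/(n(n−1)) on the directed graph;
* **assortativity**: Pearson correlation of total degrees across edge
  endpoints on the undirected projection (the directed variants are
  unspecified in the reference tables; the convention is declared here);
* **discrete power-law KS fit** of the total-degree sequence: `xmin` by KS
  minimization, alpha by maximum likelihood, p-value by semi-parametric
  bootstrap (default 100 replicates — a desk-scale default; the literature
  recommends ≥ 1000, and results carry a `reps_caveat` flag). "Scale-free"
  is declared at p ≥ 0.1. No power-law package ships in this R stack, so
  the fit is implemented natively and guarded by parameter-recovery tests
  (alpha bias < 0.2 at n = 2000);
* **clustering**: mean ± sd of local clustering on the undirected
  projection, degree-<2 nodes counting 0;
* **global reaching centrality** and **flow hierarchy** (fraction of edges
  not on any cycle, computed via strongly connected components);
* **centralities**: unnormalized node and edge betweenness on the directed
  graph; eigenvector centrality by shifted power iteration (tolerance
  1e−8, ≤ 1e4 iterations) on the adjacency matrix, falling back to the
  undirected projection (flagged) when the directed iteration degenerates,
  as it typically does on reaction DAGs.

## What the tests establish (and what they do not)

The synthetic world used in tests is deliberately tiny: a (2, 1) toy
library (4 strands), the L1/L2/L3 presets for cardinalities only, and toy
CRNs of 1–2 strand types. Within that world the test suite checks the
worked single-strand example end to end, move-generator equivalence
against exhaustive rewrite oracles, strand-multiset conservation,
reversibility under a permissive release cutoff, enumeration determinism,
MAP-Elites self-consistency and reproducibility, folding/well-formedness
arithmetic, planted-optimum recovery, and graph-metric equivalence against
brute-force path-enumeration oracles on ≤ 12-node graphs. A green suite
does **not** establish agreement with any published quantitative table:
those values depend on an external enumerator's unpublished
hyperparameters and sequence sets, which is also why the acceptance-target
list of this package is empty. The exchange-move oracles re-encode the
same locality definitions (adjacent anchor, junction adjacency) through an
independent code path; bind/open oracles are fully naive.

## Known limitations

* Pseudoknotted intermediates are excluded by construction.
* Reaction rates/kinetics are not modelled; graph edges are unweighted.
* The bundled folding stand-in knows nothing about partial domain
  complementarity or thermodynamics — it is a contract stand-in, not a
  replacement for a real MFE engine.
* Enumeration is exact but exponential in spirit: large strand sets hit
  the structure/reaction caps and return truncated CRNs.
* Strand libraries are homogeneous in n (per-strand heterogeneous lengths
  are not generated, though complexes over such strands are handled).
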