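---
title: "Measuring and optimizing the structural diversity of fragment libraries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring and optimizing the structural diversity of fragment libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Fragment-based drug discovery (FBDD) screens small compounds (MW ≤ 300 Da)
against a target and grows the best binders into leads. Because a fragment
library is screened in full, its composition — and above all its structural
diversity — determines how efficiently it samples chemical space. Yet
"diversity" is usually asserted, not measured. `fragdiv` implements three
complementary, quantitative diversity metrics over radial fingerprints,
diversity-based and random selection methods to build size ladders of
candidate libraries, and spline machinery to convert size–diversity curves
into concrete purchasing guidance: the minimum library size achieving a
stated coverage of the available structural features.

## Metrics

All metrics are computed from radial (extended-connectivity)
fingerprints. Each molecule is represented by the **set** of its atom
environments at bond radii 0–3; an environment identifier is a 64-bit hash
of the atom's connectivity invariants (element, heavy-atom degree, formal
charge, attached hydrogens, ring membership) combined iteratively with its
neighbors' previous-iteration identifiers and the connecting bond orders.
Identifiers are kept in the full 2⁶⁴ space — they are never folded to a
short bit vector, so distinct environments collide with negligible
probability and feature counting is exact.

1. **Mean nearest-neighbor similarity.** For each library member, the
   maximum Tanimoto similarity `|A∩B| / |A∪B|` to any other member;
   averaged over the library. Low values mean members are mutually
   dissimilar. Self-comparison is excluded (otherwise the metric is
   identically 1), so a library must have at least two members.
2. **Richness** `R`: the number of distinct features present in the pooled
   library. A coverage-type metric: how much of feature space the library
   touches at all.
3. **True diversity** `D = 1/∏ pᵢ^pᵢ = exp(−Σ pᵢ ln pᵢ)`: the effective
   number of equally common features, where `pᵢ = nᵢ/Σnⱼ` and `nᵢ` counts
   the library molecules containing feature `i` (presence counting: a
   molecule contributes each distinct feature once, keeping `R` and the
   `pᵢ` on the same footing). `D` obeys `1 ≤ D ≤ R`, equals `R` exactly
   for perfectly even feature usage, and decreases whenever abundance
   is transferred from a rare to a common feature. It is computed in log
   space; the direct product underflows double precision already at a few
   thousand features.

Marginal versions of the metrics — the gain per added compound between two
ladder sizes — expose the diminishing returns of growing a library, and
can go negative for true diversity when added compounds make the feature
distribution less even.

## Selection methods

**Directed sphere exclusion.** Candidates are visited in a fixed order; a
candidate is selected iff its Tanimoto distance (1 − similarity) to every
already-selected compound is at least the exclusion sphere size (default
0.4; the boundary counts as selectable, making the pairwise invariant
closed and testable). The selection order is the output order, so the
first `k` selections are the size-`k` library and all ladder libraries are
nested prefixes of one run — which makes size–diversity curves internally
consistent. The default visit order sorts candidates by a fixed 64-bit
hash of their canonical SMILES: deterministic and independent of file
order, like a lexicographic sort, but structurally uncorrelated. We chose
this over lexicographic order after observing that SMILES sort order
clusters structurally related compounds (shared prefixes encode shared
substructure), which concentrates early visits in one region of chemical
space and makes small selection prefixes *less* diverse than random
sampling — the opposite of the method's purpose. Lexicographic,
input-order, and probe-similarity orders remain available as options.

**Random control.** A seeded pseudorandom permutation of the pool,
truncated to the requested size, run in triplicate with distinct seeds and
averaged (per-replicate values are retained for error bars). The
calling session's RNG state is saved and restored, so library code never
perturbs user randomness.

The exclusion sphere of 0.4 is interpreted as a minimum Tanimoto
**distance** between any two selected compounds (equivalently, no two
selected compounds more similar than 0.6) — the standard sphere-exclusion
reading; it is an explicit argument, not a constant.

## Sizing

Size–metric knots from a ladder are interpolated with a natural cubic
spline (boundary condition exposed; natural chosen as the
fewest-assumptions default) and evaluated on the dense integer grid from
the smallest to the largest knot at step 1 — for a 100–100,000 ladder that
grid has exactly 99,901 points. The minimum size achieving a threshold is
the first grid point whose interpolated value reaches it (so answers fall
between knots, as they should), the curve peak is the grid argmax, and
extrapolation beyond the knot range is refused: splines are untrustworthy
outside their data. Standard coverage targets are fractions of the pool's
total richness (5% and 10% by convention) and the pool's overall true
diversity.

## The synthetic catalogue generator

Real fragment catalogues cannot be redistributed, so the package ships a
seeded generator that emulates their statistical structure rather than
their exact chemistry. Its default settings are the package's benchmark
conditions: 5,000 unique fragments, 400 analog families, 10% singletons, a
30% fluorination rate (fluorinated fragments carry 1–3 fluorines, the
range useful for ¹⁹F NMR screening).

A family is a distinct (scaffold, family substituent) pair drawn from ~45
fragment scaffolds (benzene and azine variants, five-membered
heteroaromatics, benzofused systems, saturated rings) and ~20 substantial
substituents, screened once so the undecorated base leaves physicochemical
headroom for decoration. Members of a family walk **complete homolog
ladders**: for each of a few decoration values on the family substituent,
every rung of a short homologous series (alkyl, alkoxy, hydroxyalkyl,
aminoalkyl, nitrile, or halogen-swap) is emitted at the analog site. This
design is deliberate: under radial fingerprints on fragment-sized
molecules, one-step homologs are the only analog relationship that
reliably produces Tanimoto similarity above 0.6 (a single CH₂ insertion
preserves most atom environments, ~0.75–0.85 similarity; swapping a ring
substituent re-hashes a large share of a small molecule's environments and
caps near 0.55). Complete ladders therefore give almost every family
member a near-duplicate neighbor — the redundancy texture of commercial
catalogues that diversity-based selection exists to exploit. Every
candidate is canonicalized, checked against the default Rule-of-3 bounds,
and deduplicated; generation proceeds in rounds until the target count is
reached and fails loudly if the combinatorial space is exhausted.

What the generator does *not* emulate: catalogue-scale pool sizes (it is
capped at 20,000; the interesting regime for a desk-scale benchmark),
realistic property *distributions* (only compliance with the filter
bounds), stereochemistry, tautomerism, and salt forms. Consequently,
passing benchmarks demonstrate the pipeline's correctness and the
qualitative size–diversity relationships — lower nearest-neighbor
similarity and higher richness for diversity-based selection, declining
marginal richness, spline-based size estimation — but absolute numbers
(richness values, minimum sizes, peak positions) are properties of the
synthetic catalogue, not predictions for any real vendor catalogue. On a
real catalogue the same code applies unchanged from `read_smiles()`
onward.

## Descriptors and filters

Physicochemical descriptors come from OpenBabel (via ChemmineOB): exact
MW, atom-contribution logP, topological PSA (the only PSA computable from
connectivity), and Lipinski-style donor/acceptor counts. Ring count is the
circuit rank of the heavy-atom graph (equivalently the SSSR size).
Rotatable bonds use a strict SMARTS definition — non-ring single bonds
between non-terminal heavy atoms, excluding triple-bond termini and amide
C–N bonds. Donor/acceptor/rotatable counters are pluggable arguments of
`compute_properties()`, because fragment-filter definitions vary between
groups and toolkits; counts near the ≤3 boundaries can legitimately differ
by one between toolkits. The reactive-group filter ships as an editable
SMARTS file (acyl halides, aldehydes, Michael acceptors, alkyl halides,
anhydrides, isocyanates, strained heterocycles, peroxides, thioesters,
azides, thiols); aryl halides and aliphatic fluorides are deliberately not
listed, as fluorinated fragments are a first-class library class here.

## Numerical and design choices

* Tanimoto similarity on empty-vs-empty sets is an error (undefined), not
  0 or 1; a candidate exactly on the exclusion boundary is selectable.
* All heavy similarity work (all-pairs nearest neighbor, sphere exclusion,
  post-hoc audits) runs in C++ on integer-indexed sorted feature sets;
  mean nearest-neighbor similarity is brute-force all-pairs, so reported
  values are exact, not approximations.
* Selection determinism is a contract: identical inputs and parameters
  reproduce identical selections, and every pipeline command writes a JSON
  manifest (parameters, seeds, input checksums) with CSVs formatted at
  fixed precision, so re-runs are byte-identical.
* Degenerate inputs are errors with explicit messages: empty collections,
  libraries of size 1 for nearest-neighbor similarity, thresholds beyond a
  curve's attained range ("not attained", not extrapolation), infeasible
  generator specifications.
* Benchmark problem sizes: the package's standard benchmark evaluates
  ladders up to 2,000 compounds from the 5,000-compound default catalogue,
  with triplicate random controls — large enough for stable metric
  separation, small enough for interactive use.

## Known limitations

* Canonicalization and descriptors are OpenBabel's; other toolkits'
  canonical forms and logP/HBA counts differ in edge cases, so filter
  decisions within one unit of a boundary are toolkit-dependent.
* The 64-bit radial fingerprint uses generic connectivity invariants;
  fingerprints from other software are not numerically comparable, though
  all similarity-based conclusions are.
* True diversity is the Shannon-order effective number only; other Hill
  orders are out of scope.
* Sphere exclusion is greedy: it guarantees the pairwise-distance
  invariant and maximality at exhaustion, not global optimality of any
  diversity metric.
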