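---
title: "Two-level reconstruction and comparison of metabolic networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-level reconstruction and comparison of metabolic networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(keggsim)
```

## The model

KEGG decomposes the metabolism of every organism into *reference pathways*:
organism-independent modules, one per metabolic function, identified by a
5-digit number. An organism's instance of pathway `00010` (glycolysis) is
encoded in a KGML file; if the organism lacks the function, the file does
not exist. `keggsim` represents one organism's metabolism at two levels
built from those files:

* **Functional level.** Each pathway is reduced to the collection of its
  reaction accessions (R-numbers), kept either as a set or as a multiset
  (accession with multiplicity). A KGML file that exists but contains no
  reactions is a *physical* (membrane-mechanism) pathway: a node with an
  empty reaction collection. Reaction identity is the R-number alone;
  direction and reversibility are ignored, because the comparison treats
  reactions as unordered collection members.

* **Structural level.** A graph whose nodes are the organism's present
  pathways; two nodes are joined when the pathways share at least one
  *non-ubiquitous* compound. Compounds are taken from the compound-type
  entries of the KGML — the map-level compound inventory — not from
  reaction substrate/product fields; the alternative reading (pooling
  substrates and products) would add compounds that never appear on the
  map and is deliberately not used. Maplink relations, KEGG's own
  display-oriented pathway cross-references, are parsed and discarded as
  unreliable.

The structural graph is stored as a square integer matrix over the whole
configured pathway universe, in ascending pathway-number order, so that the
matrices of different organisms are position-aligned. Off-diagonal cells
hold the count of shared non-ubiquitous compounds; the diagonal encodes
presence: `-1` absent, `0` present but isolated, `k > 0` present with `k`
neighbours.

### Ubiquitous compounds

Water (C00001), ATP (C00002), ADP (C00008) and phosphate (C00009) occur in
nearly every pathway; left in place they would connect almost every node to
every other and drown the structural signal. They are excluded from the
edge rule by default. The list is a tunable parameter of `build_network()`
— currency metabolites beyond these four (NAD/NADH, CoA, CO2, ...) are
plausible additions depending on the organisms studied — and the exclusion
is monotone: enlarging the list can only remove edges, never add them (a
tested invariant). Both organisms of a comparison must be built with the
same list.

## Similarity indexes

For two organisms $O$ and $O'$ and a reference pathway $P_i$ present in at
least one of them, two local indexes are computed by case analysis.

**Pathway similarity** $SimP_i$ (functional level):

| case | condition | value |
|------|-----------|-------|
| 1 | $P_i$ present in exactly one organism | $0$ |
| 2 | physical pathway in both | $1$ |
| 3 | reaction pathway in both | $|R_i \cap R_i'| / |R_i \cup R_i'|$ |
| 3-mixed | physical in one, reaction in the other | $0$, flagged |

In multiset mode the intersection takes the per-accession minimum of
counts, the union the maximum, and cardinality is the sum of counts — the
standard multiset Jaccard. Set and multiset modes coincide whenever all
multiplicities are 1 (tested). The mixed physical/reaction case is not
covered by the published case table; scoring it as the empty-versus-nonempty
Jaccard ($0$) is the conservative extension of case 3, and the distinct
`case3_mixed` label is persisted in every report so these rows can be
audited. Case labels are kept for all rows because a value of $1$ is
deliberately ambiguous between "physical in both" and "identical reaction
collections".

**Structure similarity** $SimS_i$ (structural level):

| case | condition | value |
|------|-----------|-------|
| 1 | node in exactly one graph | $0$ |
| 2 | isolated in both graphs | $1$ |
| 3 | isolated in one, degree $k>0$ in the other | $1/(1+k)$ |
| 4 | connected in both | $|E_i \cap E_i'| / |E_i \cup E_i'|$ |

Edges incident to $P_i$ are identified by their far-endpoint pathway
number, which is meaningful across organisms precisely because the universe
is the shared reference-pathway list. In case 3, $k$ is the degree in
whichever graph the node is connected — the only reading under which the
case differs from case 2.

Four global indexes aggregate the local ones over the $n$ pathways present
in at least one organism (universe pathways absent from both are in no sum
and no denominator):

$$Psim = \frac{1}{n}\sum_i SimP_i, \qquad
  PsimW = \frac{\sum_i SimP_i\,|R_i \cup R_i'|}{\sum_i |R_i \cup R_i'|},$$
$$Ssim = \frac{1}{n}\sum_i SimS_i, \qquad
  Csim = \frac{1}{n}\sum_i SimS_i \cdot SimP_i.$$

$PsimW$ weights each pathway by its combined reaction count, so physical
pathways (weight 0) drop out and small reaction pathways count less; when
no reaction pathway exists anywhere in the pair it is undefined and
reported as `NA` with a warning, never silently imputed. $Csim$ is a mean
of products of values in $[0,1]$, hence $Csim \le \min(Psim, Ssim)$ always
— a tested invariant, useful as an internal consistency check.

All four indexes are symmetric in the two organisms, equal 1 on
self-comparison, and live in $[0,1]$. Values are computed and serialised at
full precision; 4-decimal (or percentage) rounding is applied only in
printed output.

```{r example}
# a seeded synthetic pair, end to end
spec <- random_fixture_spec(seed = 1, n_organisms = 2, n_pathways = 6)
nets <- fixture_networks(spec)
compare_pair(nets$zaa, nets$zab, mode = "set")
```

## Group analysis

`similarity_matrix()` runs every unordered pairwise comparison of a set of
organisms and assembles the symmetric matrix of one global index (diagonal
1 by definition). `cluster_organisms()` converts similarities to distances
as $d = 1 - s$ — the minimal monotone transform keeping $d \in [0,1]$; the
published method names complete linkage but no transform, so this choice is
the package's own — and agglomerates with complete linkage. Ties in the
minimal linkage distance are broken by the lexicographically smallest
organism-code pair, making dendrograms reproducible; `stats::hclust` does
not expose its tie policy, which is why the agglomeration loop lives in the
package, with `stats::hclust` serving as an independent cross-check on
tie-free inputs in the test suite. Heatmaps map similarity 1 to yellow and
0 to blue, rows and columns in organism order.

```{r cluster, fig.width = 5, fig.height = 4}
pl <- planted_similarity_matrix(seed = 5, block_sizes = c(4, 4))
hc <- cluster_organisms(pl$matrix)
plot(hc, hang = -1, main = "planted two-block structure")
```

## What the synthetic generator emulates — and what it does not

`random_fixture_spec()` draws organism groups with the ingredients the
method is sensitive to: per-(organism, pathway) presence (default 15%
absent), physical pathways (15%, KEGG-realistic for membrane-mechanism
maps), per-pathway reaction pools sampled with a 60% retention probability
per organism (so conspecific pathway instances overlap strongly but not
perfectly), occasional multiplicity-2 reactions (25%, to exercise multiset
mode), planted pairwise linking compounds (50% of pathway pairs), and
ubiquitous decoys sprinkled into half the compound sets so the exclusion
filter does real work. Accessions use the high ranges (`R9xxxx`/`R8xxxx`,
`C9xxxx`/`C8xxxx`, pathway numbers `9xxxx`) that cannot collide with real
KEGG identifiers in a mixed cache. These defaults were fixed once as a
plausible miniature of cross-organism KEGG annotation; they are parameters
of the generator, not calibrated quantities.

What passing on these fixtures shows: the parser, reconstruction, index
arithmetic, case analysis, aggregation, serialisation and clustering are
correct against an independent brute-force oracle, across presence
patterns, multiplicities and decoys. What it does not show: anything about
real KEGG curation — annotation depth varies by organism popularity,
reaction overlap between related organisms is far more structured than a
retention probability, and compound sharing follows biochemistry rather
than a planted-pair design. Index *values* on real organisms therefore
depend on the KEGG release consulted, and no published organism-pair value
is asserted by the tests.

## Numerical choices and edge cases

* Comparisons in tests use absolute tolerance $10^{-9}$; the arithmetic is
  plain sums and ratios of small integers, so agreement is in practice
  exact.
* An organism-pathway present in the universe but absent from both
  organisms of a pair raises an error from the local index functions
  (callers iterate over the presence domain, so reports never contain such
  rows).
* An empty comparison domain (no pathway present in either organism) is an
  error, not an all-zero report.
* Degenerate clustering inputs: matrices with `NA` (undefined $PsimW$) are
  refused with the offending pairs named; two organisms merge at height
  $1 - s$; an all-equal matrix yields the documented lexicographic tree.
* Perturbation behaviour worth knowing: removing a shared reaction
  occurrence lowers $SimP_i$ in set mode, but in multiset mode removing a
  *surplus* occurrence (count above the partner's) shrinks the union while
  leaving the min-count intersection intact, so the value can legitimately
  rise. The property tests assert monotonicity exactly where it holds.
* The test suite and examples use fixture sizes of 2–8 pathways and up to
  15 reactions per pathway with 100 random seeds for the oracle-equivalence
  property, and 20 seeded planted matrices per index for cluster recovery —
  sizes at which the brute-force oracle is itself trivially auditable.

## Known limitations

* Compound identity is string equality of C-numbers; stereochemistry or
  glycan accessions (`G*`) are out of scope, and non-compound entry types
  are ignored.
* The structural edge collapses three biological situations (metabolite
  handoff, pathway overlap, incidental co-occurrence) into one edge type,
  by design.
* The KEGG client is a convenience: it serialises requests with a 350 ms
  politeness delay and caches absence markers, but live retrieval depends
  on the service's availability and current list formats; all analysis
  functions consume only the on-disk cache.
* Only complete linkage is validated; the distance transform and tie
  policy are package choices, so dendrograms are comparable between runs
  of this package but not necessarily with other implementations.
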