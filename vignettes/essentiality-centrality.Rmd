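---
title: "Essentiality and centrality at three scales: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Essentiality and centrality at three scales: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of the science it implements:
what each stage computes, the assumptions behind it, the parameters
that matter, and the choices we made where the design was genuinely
open. The worked numbers that accompany these methods are produced by
the test suite and by `scripts/acceptance.R`; nothing here asserts an
empirical result those runs do not themselves compute.

## The question and the overall procedure

Essential proteins tend to be network hubs, but degree is a composite
quantity. The package decomposes it using functional modules — protein
complexes, specific Gene Ontology biological-process (BP) terms, or
processes filtered of their complex content — and measures the
essentiality–centrality relationship at three scales:

* **protein level** — is intramodular degree (partners sharing a
  module) a better essentiality correlate than intermodular or total
  annotated degree?
* **within complexes** — inside complexes that contain both essential
  and non-essential proteins, are the essential members the more
  connected ones?
* **module level** — do modules containing essential proteins have
  more inferred cross-talks with other modules?

The pipeline (`runPipeline()`) answers all three per module universe,
with Spearman rank correlations (SRCC), partial SRCCs, Wilcoxon
rank-sum comparisons, hub-fraction curves, a per-complex permutation
test and a randomisation-calibrated module network.

## Building networks and catalogues

Interaction records are read from tab-delimited tables and pass three
provenance filters, each with a strict, documented boundary:

* **sticky proteins** (`filterStickyProteins`): a protein with *more
  than* 30 records from a single source loses all records from that
  source. Thirty exactly is kept. We count records by default;
  counting distinct partners is available (`countUniquePartners`)
  because "interactions from a source" is ambiguous between the two
  readings, and the choice is surfaced rather than buried.
* **evidence classes** (`selectEvidenceClass`): `direct` admits the
  direct-contact systems (two-hybrid, reconstituted complex, FRET,
  ...), `pulldown` the affinity-capture systems, `full` everything
  except RNA-mediated evidence. Vocabularies are arguments, matched
  case-insensitively; systems not in any list fall only into `full`.
* **high throughput** (`filterHighThroughput`): sources with at least
  50 records and more than 10 distinct baits.

Graphs are undirected and simple: records symmetrise, duplicates
collapse into one edge with merged provenance, bait/prey survive only
as provenance. All downstream analyses run on the subgraph induced by
the essentiality-tested proteins (`restrictToTested`).

Complex catalogues are deduplicated (`deduplicateComplexes`) in three
ordered passes: strict subsets removed; then, of any pair with Jaccard
index at or above a threshold, the smaller removed; then the listed
ribosomal complexes dropped. The Jaccard threshold defaults to 0.5 — a
conventional "mostly the same set" cut; results should be read as
conditional on it, and it is a plain argument. Removal is greedy in a
deterministic order (descending size, ties by ascending id, equal sets
drop the lexicographically larger id) against the already-retained
set; this needs no fixpoint iteration and makes catalogues independent
of input order.

Filtered processes (`filterProcessesAgainstComplexes`) subtract from
each BP-term module every intersection of at least
`intersectionThreshold` proteins (default 2) with the *original*,
pre-deduplication complex catalogue; subtraction is assessed against
the process's original membership so the outcome cannot depend on
complex order. A process is dropped when fewer than 2 proteins remain
or fewer than half the term's full annotation count; survivors are
deduplicated like complexes. Subtraction runs before dedup — the
natural reading of the construction, since dedup on unsubtracted
processes would remove terms on the strength of members about to be
deleted.

## Annotations and semantic similarity

OBO 1.2 ontologies are parsed with `is_a` and (by default) `part_of`
parentage — standard true-path practice; annotations propagate to all
ancestors, and a term's probability is its propagated annotation count
over a reference proteome. Two defaults deserve note:

* **proteome size** defaults to the number of annotated proteins, but
  the pipeline passes the essentiality-tested universe; "total number
  of proteins" is genuinely ambiguous and the parameter is explicit.
* **evidence codes** are not filtered; all non-`NOT` GAF rows count.

Lin term similarity is
`tSS(t1, t2) = 2 log p(a*) / (log p(t1) + log p(t2))` with `a*` the
minimum-probability (most informative) common ancestor — the standard
resolution of "a least common ancestor" in a DAG, where ancestors are
not totally ordered. Identical non-root terms score exactly 1. When
the *only* common ancestors are roots the similarity is exactly 0;
this is enforced structurally, not via `p(root) == 1`, because with a
tested-universe proteome the root's probability can be slightly below
one and the zero contract should not silently fail. The log base
cancels; values are clamped to [0, 1]; a zero-probability term is an
error rather than a silent 0, since it means the annotation set and
ontology disagree.

Protein-level similarity aggregates term similarity over propagated
annotation sets. The default (`"most-specific"`) scores
`2 log p(s*) / (log p(m1) + log p(m2))` with `s*` the most informative
shared term and `m1`, `m2` each protein's own most informative term. A
naive maximum of `tSS` over term pairs degenerates to 1 whenever any
term is shared (the pair (t, t) is always available), so it is not
offered; a best-match-average over direct annotations is the
alternative (`aggregation = "bma"`), and the variant used is recorded
on the output. Unannotated proteins yield `NA` — missing, not zero —
and contribute 0 to the semantic-similarity-weighted degree with a
count kept in a coverage column.

## Rank statistics and the per-complex test

SRCCs are Pearson correlations of average-tied ranks with a
t-approximate p-value; partial SRCCs rank-transform all three vectors
and apply the first-order partial formula. Degenerate inputs are
flagged, not guessed: constant vectors give `NA`, and a control
collinear with an argument gives the degenerate value 0 (the numerator
vanishes identically with the denominator) plus an `undefined` flag.
Because essentiality is binary and massively tied, the package also
reports the maximum SRCC attainable by rearranging labels onto the
highest degree ranks (`maxAttainableSrcc`), which calibrates how large
an observed correlation can possibly be. Wilcoxon comparisons use the
exact null for small tie-free samples (combined n ≤ 20 by default)
and the tie-corrected normal approximation otherwise.

The per-complex permutation test conditions on complex composition: a
complex qualifies with at least two essential and two non-essential
tested members, each with at least one intracomplex interaction; the
statistic is the number of qualifying complexes whose essential
members have *strictly* higher mean intracomplex degree (ties count
against the alternative); the null shuffles labels within each complex
independently, preserving per-complex essential counts. Shuffling
*within* complexes isolates the degree–label association from complex
composition, which is what the hypothesis is about; a global-shuffle
mode (`scheme = "global"`) is provided since the alternative reading
is defensible. The empirical p-value uses the add-one correction
`(#{perm ≥ obs} + 1)/(nPerm + 1)` and so is never zero. No
multiple-testing correction applies — one test per network.

## Cross-talk inference

For module pairs, cross-talk interactions are edges between the two
member sets excluding any edge with an endpoint annotated to both
modules. Inference counts over the globally intermodular edge set
(edges whose endpoints share no module at all); the null rewires
exactly that edge set by double-edge swaps — 10 × |E| proposals per
round, rejecting any proposal creating a self-loop, duplicate edge or
intramodular edge — preserving every protein's intermodular degree,
the module annotation and the edge total. Rounds are independent
restarts from the observed edges, so the 100 rounds are i.i.d. draws;
proposals are symmetric, making the stationary distribution uniform
over reachable configurations (verified by exhaustive enumeration and
a chi-squared test on a toy instance in the test suite). A rejected
proposal is simply skipped — with a fixed proposal budget there is no
retry loop to exhaust. All pairs share the same randomised rounds, and
a pair's null mean averages over *all* rounds, counting rounds where
it has no edges as zeros.

A pair becomes a module-network edge iff (i) it has at least two
vertex-disjoint supporting interactions — an edge set lacks such a
pair exactly when it is a star or a triangle, which is how the check
is implemented — and (ii) its pseudocounted odds-score
`(n_real + 1)/(n_rand + 1)` reaches the threshold. The threshold
defaults to 5.0: a value high enough that, at the background densities
the generator emulates, pseudocounted background pairs (odds near 1)
cannot pass, while planted enrichments an order of magnitude above
their null mean do; `applyOddsThreshold()` re-thresholds without
re-randomising so the sensitivity of any conclusion to this choice can
be swept cheaply (raising it can only remove edges). Module nodes
carry binary essentiality (any essential member), fraction essential,
and raw and size-normalised cross-talk degrees; summary tables count
modules with at least one cross-talk, while the node table keeps all.
The functional-relatedness filter annotates a module with an
expert-selected term when at least half its members carry it
(`annotationFraction = 0.5` — a module-majority rule; configurable)
and drops cross-talks between modules sharing such a term.

One structural caveat surfaced by testing: if planted (or real)
enriched pairs dominate the intermodular degree sequence — many
enriched pairs among few modules — the degree-preserving null itself
reproduces the enrichment and no odds-score can be large. This is a
property of the method, not a defect of the implementation; detection
requires enrichment sparse relative to the module count, which the
default study conditions respect.

## The synthetic study conditions

`generatorConfig()` defines the conditions every seeded study uses:
2000 proteins; 40 disjoint complexes of 30–50 proteins (about 1600
proteins in modules, the rest unannotated, exercising the unannotated
paths); intramodule edge probability `pIn = 0.3`; background
intermodule probability `pOut = 0.005`; 20 planted module pairs wired
at `pCrosstalk = 0.15`, drawn with probability 0.75 per endpoint from
the essential modules so module-level essentiality and cross-talk are
coupled with a controllable bias; half the modules essential. Protein
essentiality inside essential modules follows
`logistic(alpha + beta * d_intra)` with `alpha = -5`, `beta = 0.4`:
the probability is centred near 0.5 at the typical intramodular degree
(≈ 0.3 × 39 ≈ 12) and spans roughly 0.07–0.93 over the realistic
degree range, a gradient strong enough to be detected but far from
deterministic. Outside essential modules the rate is `baseRate =
0.01`, deliberately small so module essentiality is module-driven; a
large background rate would give nearly every 40-protein module an
essential member and empty the binary label of meaning. An
`overlapFraction` knob plants multi-complex membership to exercise the
union-of-partners degree counting and the largest-complex tie-breaks.

One consequence of the design is worth keeping in mind when reading
protein-level numbers: because planted cross-talk pairs preferentially
join essential modules, members of essential modules also carry excess
*intermodular* degree, so essentiality correlates with both degree
components and the intra-versus-inter contrast is attenuated relative
to a study without module-level coupling — its margin varies with the
seed. The within-complex permutation test and the module-level
correlation are insensitive to this and are the sharper readouts under
these conditions.

The generator reproduces the *structure* the analyses assume — modular
wiring, degree-coupled essentiality, planted cross-talk — not real
yeast data: degree distributions are binomial rather than heavy-
tailed, complexes are (by default) disjoint, the toy ontology is a
shallow tree with one leaf per module, and annotation noise, study
bias and literature-derived provenance artefacts are absent. Passing
tests therefore demonstrate that the machinery recovers known planted
structure under its own assumptions; they say nothing about effect
sizes in real interactomes, where the input filters exist precisely
because those assumptions fail.

Determinism: every stochastic stage takes a seed; the generator
derives per-stage seeds from one master seed (kept within 32-bit
range), integer sampling drives all structural choices, and writing a
study to disk twice from the same configuration yields byte-identical
files. Edge sampling draws the number of edges per pair-block from the
binomial and then samples that many distinct pairs, so dense and
sparse blocks cost the same.

## Numerical choices, tie-breaks, degenerate inputs

* Protein ids are upper-cased; unordered pairs are stored
  lexicographically; module processing order is descending size then
  ascending id; the largest-module tie-break is the lexicographically
  smallest id.
* Normalised intracomplex degree divides by the complex size
  *including* the protein itself, and is computed in the protein's
  largest complex.
* Hub curves add proteins in groups (50 for proteins, 20 for modules),
  include the final partial group, and can extend groups so tied
  degrees never straddle a boundary.
* Similarities are clamped to [0, 1]; equality tests in the suite use
  1e-10 to 1e-12 tolerances; rank statistics are validated against
  longhand oracles (hand-computed average ranks and the explicit
  Pearson sum formula; residual correlations; exhaustive label
  enumeration).
* Empty inputs return empty, typed results (empty curve, empty record
  list with a warning); contradictory inputs (min above max, two empty
  sets for a Jaccard index, a cyclic ontology) are errors that name
  the problem.

The test suite runs the full default study once (2000 proteins, 100
randomisation rounds, 10,000 permutations) plus many small fixtures;
those sizes keep the default suite to a few minutes while the
uniformity and calibration checks still use 10,000 draws where the
statistics demand it.

## Limitations

* The exact protein-similarity aggregation, the catalogue Jaccard
  threshold, the process-subtraction trigger, the odds threshold and
  the slim-annotation fraction are all parameters with documented
  defaults; conclusions should be checked across their ranges (the
  threshold sweep exists for exactly this).
* The module network treats cross-talk acceptance as binary; edge
  weights (odds) are reported but not propagated into the degree.
* Betweenness and other global centralities, clustering-derived
  modules, and machine-learning essentiality prediction are out of
  scope; the module universes come from catalogues and annotations,
  not from network clustering.
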