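---
title: "Methods: graph model, comparative algorithms and their validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: graph model, comparative algorithms and their validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(omicsgraph)
```

## The data model

Biological annotation is naturally a network: genes sit on chromosomes,
carry protein domains, point at ontology terms, correlate in expression and
pair up with orthologs in other genomes. omicsgraph stores all of this in
one embedded **property graph** — labeled nodes (`Gene`, `Landmark`,
`Species`, `Domain`, `GOTerm`, `Pathway`, `Condition`, ...) with scalar
attribute maps, connected by typed, attributed, directed edges
(`LOCATED_ON`, `NEXT_GENE`, `HAS_DOMAIN`, `HAS_GO_TERM`, `IS_A`,
`BLASTP_HIT`, `BEST_HIT`, `RECIPROCAL_BEST_HIT`, `COEXPRESSED_WITH`,
`TRANSLATES_TO`, ...). Every importer writes into this one container and
every query is a traversal over it, so adding a data layer automatically
enriches what every other layer can reach.

Three container decisions shape everything else:

* **Edge identity is the triple `(source, target, rel_type)`.** Re-importing
  a file merges attributes instead of accumulating parallel edges, which is
  what makes every importer idempotent and builds resumable.
* **Undirected relations are stored once.** A reciprocal best hit or a
  co-expression link is symmetric; it is stored with the lexicographically
  smaller endpoint as source and retrieved from either side via
  `neighbors(..., direction = "both")`. This keeps counts meaningful
  (one biological relation, one edge).
* **Iteration is sorted everywhere.** Node listings, neighbor lists and
  reports are ordered by identifier, so a query run twice prints
  byte-identical output.

The graph is environment-backed and mutated in place; at the desk scale the
package targets (tens of genomes of toy-to-bacterial size, thousands of
genes) this keeps importer code straightforward. Durable storage is JSON
Lines, one record per node/edge behind a header record: diff-able,
streamable, and lossless — doubles are written at 17 significant digits
with an explicit decimal point so a round trip preserves both value and
scalar type exactly.

Coordinates are converted to 0-based half-open intervals at every parser
boundary (GFF3 and SNP TSVs arrive 1-based inclusive) because interval
arithmetic — gene length, SNP distance, overlap — is then free of the
`+1/-1` bookkeeping that breeds off-by-one errors. BLAST alignment
coordinates are kept 1-based as printed, since they are only ever used as
coverage fractions.

## Gene order as a first-class relation

`import_genome()` chains the genes of each landmark in physical order
(sorted by start, ties by end then id; strand deliberately ignored) with
`NEXT_GENE` edges. This backbone is what both synteny consumers walk:

* the annotation-translation disambiguator counts neighbor support within a
  window of the backbone;
* the syntenic-region search slides along it.

Ties on identical starts are resolved deterministically so rebuilding the
same genome always yields the same chain.

## Homology: best hits, reciprocal best hits, BSR

Similarity searches arrive as BLAST+ tabular files (the fixed 12-column
`-outfmt 6` dialect only; anything else is rejected loudly, since the
package also generates the BLAST driver scripts and can therefore guarantee
the dialect). Per query, the **best hit** is the subject with the highest
bit score; ties fall through e-value, then percent identity, then
lexicographic subject id, and a winner decided only at the lexicographic
level carries `ambiguous = TRUE` — recent duplications and gene families
produce exactly such ties, and downstream logic must know the winner was
arbitrary. Bit score (not e-value) is the primary key: e-values saturate at
zero for strong hits, where bit scores still rank.

A **reciprocal best hit** (RBH) pair requires each side to be the other's
best hit — the standard conservative ortholog proxy; no orthogroup
clustering is attempted. Every stored hit carries the **BLAST Score
Ratio**: its bit score divided by the query's self-hit bit score (hence the
generated scripts include self-vs-self searches). BSR is
length-normalized — 1.0 means "as strong as self" — which makes one floor
value meaningful across genes of different lengths. Hits are pre-filtered
at an e-value ceiling of `1e-5` (configurable) before selection.

## Annotation translation between genome versions

Given an old and a new annotation and an old-vs-new all-vs-all nucleotide
search, each old gene receives one of five statuses:

| status | criterion (defaults) |
|---|---|
| `one_to_one` | a single candidate in the top score band with mutual coverage ≥ 0.8 |
| `split` | ≥ 2 pieces, each covering ≥ 0.5 of itself, jointly ≥ 0.8 of the old gene, adjacent (within the window) in the new order |
| `merge` | ≥ 2 old genes electing the same partial new gene, each covering ≥ 0.5 of itself |
| `missing` | no candidate survives the BSR floor |
| `ambiguous` | anything unresolvable, including equal-support ties |

Candidates below a BSR floor of 0.4 are dropped; the "top score band" is
everything within 98% of the best bit score, because bit scores of
effectively identical matches differ only by rounding. When several
full-coverage candidates tie — tandem or dispersed duplicates — **genic
synteny** decides: for each candidate, count the old gene's neighbors
(±5 genes) whose own unambiguous translation lands within ±5 genes of that
candidate in the new order. A strict support winner is accepted (the
support count is reported as evidence); equal support stays `ambiguous`,
because guessing between identical duplicates would silently corrupt any
downstream identifier mapping. One-to-one calls settled *without* synteny
are the anchors for this computation, so anchor status can never depend on
the ties being resolved.

The classification order matters and is deliberate: full-coverage
candidates are considered before split pieces, because two tandem
duplicates also satisfy a literal reading of the split criterion (each
covers itself fully and jointly they cover the old gene) — the
full-coverage test separates "two complete copies" from "two halves".
Merge grouping runs last, across genes, since a merge is only visible when
several old genes point at one new model.

All five thresholds (BSR floor 0.4, tie band 0.98, mutual coverage 0.8,
piece coverage 0.5, window ±5) are configuration with these defaults. They
are deliberately conservative: they trade a few extra `ambiguous` calls for
never mislabeling an event, and the planted-event fixtures confirm that at
these values every planted rename, split, merge and deletion is recovered
exactly while the planted equal-support duplicate stays `ambiguous`.

## Gap-tolerant syntenic search

A query is an ordered colinear run of genes; a target window matches when
an order-preserving pairing through homology edges covers at least
`length(query) − max_gaps` query genes with at most `max_gaps` unpaired
target genes interleaved — so one inserted unrelated gene, or one deleted
homolog, does not break the block. Both orientations are scanned (inverted
blocks are common across species). The pairing inside a candidate span is
found with an LCS-style dynamic program requiring both span endpoints to be
paired; matches score `paired − 0.5·(insertions + deletions)` and
overlapping matches on one landmark keep only the best (ties to the
leftmost start). A gene counts as its own homolog, so the query's own
species can be scanned symmetrically with the others. With `max_gaps = 0`
the search degenerates, by construction, to exact homolog-substring
matching — a property the tests assert.

## Co-expression

Expression matrices (gene × condition FPKM) are stored as `Condition`
nodes plus per-condition `EXPRESSED_IN` edges, and gene pairs with
`|Pearson r| ≥ 0.9` (default) across conditions become `COEXPRESSED_WITH`
edges carrying the signed `r`. Correlation is computed on `log2(FPKM + 1)`
by default — FPKM spans orders of magnitude and the log keeps single
high-expression conditions from dominating — with a raw-FPKM option.
Thresholding is on `|r|` because anticorrelation is biologically
informative; the sign is preserved on the edge. Zero-variance genes are
excluded with a warning (their correlation is undefined), at least four
conditions are required, and the all-pairs scan warns above 5,000 genes —
this is a desk-scale tool, not a WGCNA replacement (no soft thresholding,
no normalization beyond the log).

## Ontology propagation and inferred annotation

`is_a` generalization means annotation to a term implies annotation to all
its ancestors; `effective_go_terms()` computes that closure (cycles are a
data error and abort, naming the cycle). The closure is query-time by
default and can be materialized as `INFERRED_GO_TERM` edges — inferred
annotation is *always* distinguishable from direct annotation, either by
edge type or by provenance attributes.

`infer_from_homolog()` transfers GO terms, domains and pathway memberships
across exactly one homology hop (RBH and best hits by default, BSR ≥ 0.4),
never chaining homology — two hops of "my ortholog's ortholog" is how
annotation errors percolate through databases. Transfers are reported with
full provenance (source gene, path, BSR) plus a co-expression co-membership
flag as evidence, and are written to the graph only on explicit request:
they are possible annotations, not assertions.

## Built-in queries

* **Enrichment** is the one-sided hypergeometric upper tail per term over
  effective term sets, with Benjamini–Hochberg adjustment across all terms
  observed in the query (`k ≥ 1`); the background defaults to all genes of
  the query's species.
* **Nearest gene / GWAS annotation** uses edge-to-edge distances on
  half-open intervals (0 inside a gene), ranked ascending with id
  tie-breaks, and joins GO/EC/expression layers onto the nearest gene. A
  layer that was never imported yields empty columns, never an error — the
  dependency contract is that queries degrade gracefully to
  empty-but-valid output.
* **Presence/absence** lists focal-species genes whose effective term set
  contains all query terms, with each other species' RBH ortholog or its
  absence.
* **Gene report** renders attributes, relationship counts, direct and
  inferred GO terms, and the homology table (partner, relation, BSR,
  identity, e-value) deterministically.

## What the synthetic fixtures emulate — and what they do not

The generators produce every input format the package reads, with planted
truth for every algorithm:

* `generate_genome_version_pair()` builds an old genome of random
  nucleotide gene models (uniform base composition, even lengths 300–900
  bp) and derives the new version by renaming, splitting (two adjacent
  halves), merging (adjacent pairs), deleting, inserting novel genes, and
  duplicating. Events are laid out in blocks separated by at least one
  rename so every event has one-to-one synteny context; duplicate families
  keep one copy at the original locus and disperse the other, making the
  tie resolvable only by neighbors; the equal-support family disperses
  *both* copies among novel genes on their own landmark, so the correct
  call is provably `ambiguous`.
* The similarity table is produced by an exact-substring surrogate scorer:
  a hit exists iff one sequence contains the other, with bit score twice
  the matched length and self scores to match. Crucially this scorer scans
  all sequence pairs — it never reads the planting bookkeeping — so
  planted-recovery tests remain genuine oracle checks. The surrogate
  preserves exactly the structure the algorithms consume (score ranks,
  ratios, coverage fractions); it does not emulate partial identity,
  gapped alignments or compositional bias.
* `generate_multi_species_fixture()` plants: identical-sequence one-to-one
  orthologs across three ~30-gene species (RBH truth), a three-gene
  syntenic block with one unrelated insertion in one species, a shared
  domain on two genes of one species and one of another wired to the leaf
  of a seven-term `is_a` chain, a six-gene co-expression module driven by
  a latent condition profile (multiplicative gain 0.5–2, 2% noise) against
  a uniform-noise background, ten SNPs whose nearest genes are known from
  the fixed 200-bp inter-gene gap, and pathway/EC tables.

Passing on these fixtures demonstrates algorithmic correctness — agreement
with brute-force oracles and exact recovery of planted events — not
robustness to the messiness of real data: fragmented assemblies, partial
homology, paralog-rich families with unequal copies, non-uniform coverage,
or noisy expression replicates. The thresholds' defaults are starting
points for real genomes, not validated optima.

## Problem sizes and numerical choices

The test suite and the reproduction script run entirely on generated data:
three species of ~30 genes for the pipeline checks, version pairs of
40–100 genes for translation, 20 random seeds per brute-force oracle
family (graphs ≤ 50 nodes, score tables ≤ 40×40, ontologies ≤ 20 terms,
enrichment backgrounds ≤ 15 genes so exhaustive draw enumeration stays
exact). These sizes were chosen so every expected value can be computed by
full enumeration; the algorithms themselves have no size-dependent
branches. Exact-equality comparisons are used wherever both sides are
discrete (edge sets, pairings, statuses); enrichment p-values are compared
to the enumeration oracle at `1e-12`.

## Known limitations

* One annotation version per graph species: translating across three or
  more versions means chaining pairwise runs.
* Synteny search enumerates candidate spans; it is quadratic in landmark
  length per query and intended for gene-scale queries (≤ ~10 genes), not
  whole-chromosome alignment.
* No coordinate liftover: the translation module maps gene *models*, not
  arbitrary intervals.
* Protein-to-gene id resolution is a configurable suffix-strip heuristic;
  genome projects with unrelated protein/gene namespaces need an explicit
  mapping imported as generic tuples.
* The embedded store holds everything in memory; there is no transactional
  concurrency, no query language, no server.
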