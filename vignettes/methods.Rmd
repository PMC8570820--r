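---
title: "Methods: seed-and-extend protein search against sample-annotated metagenome references"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: seed-and-extend protein search}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pzsearch)
```

## The problem

Amino-acid similarity searches against large public metagenome collections
let a user ask *where in the environment* homologs of a protein occur: each
reference sequence belongs to a sequenced sample, and each sample carries an
environment-ontology annotation, an optional body-site annotation and
sampling coordinates.  Collections of this kind reach trillions of residues,
so the standard trick of indexing the reference is expensive; `pzsearch`
instead indexes the *query* set — which is small, at most 10 000 sequences
per submission — and streams the reference past it in chunks.  This
query/reference swap is the central speed device the package implements, and
it makes the search embarrassingly data-parallel over reference chunks: a
chunk search never needs to see any other chunk, and a deterministic merge
reproduces the single-pass result exactly.

The package provides four layers:

1. a heuristic seed-and-extend local aligner (`pzsearch()`) with BLAST-style
   tabular output and Karlin–Altschul E-values;
2. an exact Smith–Waterman oracle (`smith_waterman()`,
   `make_ground_truth()`) for building ground-truth hit sets the way an
   exhaustive SSEARCH run would, plus precision/recall reporting
   (`precision_recall()`, `evaluate_tool()`);
3. hit summarization by environment class, body-site class and geography
   (`summarize_by_class()`, `summarize_geography()`);
4. a deterministic simulator of a sample-annotated reference with planted
   homologs (`generate_reference()`), so every layer is testable without
   downloading any external collection.

## The alignment model

Alignments are local, protein–protein, scored with a substitution matrix
(BLOSUM62 by default, BLOSUM50 built in, arbitrary NCBI-format files
loadable) and affine gap costs.  A gap of length $L$ costs
$\mathrm{open} + (L-1)\cdot\mathrm{extend}$, with the defaults
$\mathrm{open}=11$, $\mathrm{extend}=1$; the first gap residue carries the
opening cost.  The alphabet is the 20 canonical residues plus B, Z, X, U
and `*`; U scores through the matrix's X entries, and `*` scores through
the matrix's own `*` row (strongly negative against everything), which in
practice walls alignments off at translated stop codons.

### Seeding

The index maps every length-$k$ word of every query to its (query, offset)
postings; the default $k = 4$ with exact matching on the full alphabet and
one-hit triggering.  Words containing `*` are never indexed; words
containing X are skipped by default.  Scanning a reference sequence is a
hash lookup per reference word.  Seeds that land within $2k$ residues of an
already-kept seed on the same (query, diagonal) collapse onto the leftmost,
and single-word postings scanned within one reference sequence are capped
at 10 000 as a low-complexity guard.  Exact 4-mers keep the index tiny and
are sensitive at the operating point the package targets (moderately to
highly similar sequences at E ≤ 1e−8): at 60 % identity a 300-residue
homolog still shares dozens of exact 4-mers with its query, so the chance
that no seed survives is negligible.

### Extension

Each surviving seed is extended in two stages.

* **Ungapped X-drop.**  The seed grows along its diagonal in both
  directions; a direction stops once the running score falls more than
  `x_drop_ungapped = 20` below the best score seen, and the best-scoring
  prefix/suffix pair is kept.
* **Banded gapped extension.**  If the ungapped score reaches the trigger
  (22 bits under the configured statistics, ≈ raw 46 for BLOSUM62/11/1),
  the aligner anchors at the midpoint column of the ungapped segment and
  runs an exact banded affine-gap extension to each side, exploring
  `band_width = 64` diagonals around the anchor; a side stops when every
  in-band cell of a row falls more than `x_drop_gapped = 38` below the
  running best.  The two half-paths and the anchor column are concatenated,
  and the HSP's raw score is defined as the *replay* of that combined path
  (this merges any gap runs abutting the anchor, so the stored score always
  equals the path's score bit-exactly — an invariant the test-suite asserts
  for every emitted HSP).

Seeds that fall entirely inside an HSP already found for the same query and
subject are skipped rather than re-extended.  The best HSP per
(query, subject) pair defines the hit; a hit is therefore a sequence pair,
not an HSP, which is also how the evaluation layer counts.

These extension parameters (X-drops, trigger, band) are conventional
BLAST-family operating points, declared here as the package's own defaults;
they are exposed in `search_config()` for calibration.

### Statistics

Raw scores convert to bit scores and E-values through the Karlin–Altschul
forms $\mathrm{bits} = (\lambda S - \ln K)/\ln 2$ and
$E = K m n e^{-\lambda S}$ with the standard published gapped constants for
BLOSUM62/11/1, $\lambda = 0.267$, $K = 0.041$.  The search space is the raw
product of the query length $m$ and the grand-total reference residue count
$n$ over *all* chunks — no finite-size length adjustment.  That choice is
deliberately the simplest defensible one: it is documented, monotone, and
(critically) chunk-independent, so E-values computed inside any worker
equal those of a single-pass run and the merged ranking is byte-identical
to the unchunked ranking.  Hits are reported at `evalue_max = 1e-8` by
default — the operating point at which heuristic aligners of this family
are conventionally benchmarked — ranked by (E-value, bit score, subject
id) and truncated to 10 000 hits per query.

### Tie-breaking and determinism

All orderings are radix sorts free of locale effects.  In the exact
Smith–Waterman traceback, ties between equal-scoring cells keep the first
maximum in row-major scan order (smallest query end, then subject end) and
the traceback prefers an aligned column over a gap in the subject over a
gap in the query.  This is simpler than preferring the smallest start
coordinate (which would need a second pass or reversed DP) and equally
deterministic, which is all downstream consumers require.  Worker
parallelism uses forked workers over chunks with a deterministic merge;
results for 1, 2 or 4 workers are byte-identical, which the acceptance
tests assert on serialized tables.

## The evaluation protocol

`make_ground_truth()` runs the exact Smith–Waterman scorer over *every*
(query, subject) pair — feasible at desk scale — and keeps pairs with
$E \le$ threshold (default 1e−8), using the same E-value convention as the
search so the two sides are commensurable.  `precision_recall()` compares
deduplicated (query, subject) pair sets and reports percentages
**truncated** (floored) at the second decimal.  Truncation, not rounding,
is the convention that reproduces published benchmark tables of this kind
exactly: 215/303, 221/303 and 224/303 print as 70.95, 72.93 and 73.92,
where rounding would give 70.96, 72.94 and 73.93.  Display trims trailing
zeros (91.80 prints as "91.8", 100.00 as "100") while stored values keep
two decimals.  Degenerate sets follow fixed conventions: empty predictions
give precision NA (100 when the truth is empty too) and recall against an
empty truth is 100.

Because every heuristic HSP's score is bounded above by the Smith–Waterman
optimum for its pair, a heuristic hit at $E \le$ threshold implies the pair
is in the truth set at the same threshold — the search's precision against
the oracle is structurally 100 % and only recall is at stake.  The test
suite verifies the dominance bound on a thousand random and homologous
pairs per run.

## The synthetic reference

`generate_reference()` emulates the *product* of a large
metagenome-derived protein collection at desk scale, not its construction
pipeline (no read simulation, no gene prediction).  Decoy sequences are
i.i.d. draws from the Robinson–Robinson background frequencies — the
standard protein null model, which keeps the E-value statistics of decoy
scores analytically clean.  Planted homologs are made by substituting each
query position with probability $1 - \mathrm{identity}$ to a uniformly
chosen different residue, then applying per-column indel events
(probability `indel_rate`, geometric lengths of mean 1.5, insertions drawn
from the background); the realized identity recorded in the truth table is
the per-column recount on the pre-indel sequence.  Samples receive one
environment class each by default (multi-class behind a flag) so the
conservation invariant $\sum \mathrm{fraction} = 1$ is testable, plus an
optional body-site class for the human-associated class and coordinates
from a small pool with a deliberate no-location entry.  Class identifiers
in the default pools are illustrative placeholders, not resolved ontology
terms.  Everything is driven by one RNG seed; the same seed yields
byte-identical files.

### Benchmark conditions

The package's standing benchmark, used by the acceptance tests and the
acceptance script, is: 20 samples × 250 decoys (lengths uniform on 100–350
residues, a realistic range for proteins predicted from short-read
metagenome assemblies), with 60 copies of one 300-residue query planted at
identities 0.9, 0.8, 0.7 and 0.6 (15 each) with indel rate 0.01, generator
seed 42 — roughly 1.2 million reference residues, small enough that the
exhaustive Smith–Waterman ground truth takes seconds.  At these conditions
the search at E ≤ 1e−8 is expected to recover essentially all planted
homologs (even the 0.6-identity tier scores far above the E cutoff over
300 columns), and the test floor is recall ≥ 0.90 and precision ≥ 0.95
against the oracle truth.

## What the synthetic fixtures do and do not show

Passing on these fixtures demonstrates correctness of the machinery —
seeding equals the brute-force word comparison, extension is dominated by
and usually ties the exact DP on homologs, statistics are self-consistent,
chunking/workers are invisible, summaries conserve counts.  It does *not*
demonstrate sensitivity on real metagenomes: real protein families have
conserved motifs, compositional bias and indel clustering that an i.i.d.
substitution model lacks, and real collections have low-complexity and
repetitive sequence that stress masking policies harder than background
decoys do.  Terabyte-scale throughput claims are likewise out of scope:
this implementation targets desk-scale correctness, with the chunk
contract as the portable seam where large-scale parallelism would attach.

## Known limitations and open choices

* Seeding is exact-match only; neighborhood-word expansion (seeding on
  words scoring ≥ T under the matrix) is a documented extension point that
  would raise sensitivity below ~50 % identity.
* One HSP per pair feeds the statistics; there is no sum-statistics
  treatment of multiple HSPs and no composition-based score adjustment.
* E-values use the raw $m \cdot n$ space; against very large references
  they are mildly conservative relative to length-adjusted conventions.
  Users calibrating against other tools should compare at matched
  thresholds.
* Ontology classes are flat labels from the metadata table; counts are not
  propagated to ancestor classes.  Rollup over a real ontology graph is an
  extension point.
* The sample-of-origin convention (`sampleID|sequenceID` headers,
  overridable by a two-column map) is the package's own; collections with
  different conventions need the map.
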