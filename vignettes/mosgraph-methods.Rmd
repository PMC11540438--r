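---
title: "Harmonizing multi-omics cohorts into per-sample signaling graphs"
author: "mosgraphr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Harmonizing multi-omics cohorts into per-sample signaling graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mosgraphr)
```

## The problem

A multi-omics cohort arrives as a stack of matrices that disagree about
everything: methylation rows are CpG probe IDs, copy-number variants are
genomic intervals, transcript rows are versioned Ensembl IDs, protein rows
are accession-tagged symbols, and every assay keys its columns by a
different sample alias. A graph neural network, by contrast, wants one
fixed node set, one adjacency, and a dense per-sample feature tensor in
which every cell has a defined meaning. `mosgraphr` is the bridge: a
deterministic, fully specified harmonization pipeline whose output is a
per-sample multi-omics signaling graph (mos-graph).

This vignette explains the model of the data, the mapping rules and their
parameters, the places where the design was genuinely open and what we
chose, and what the synthetic-study tests do and do not establish about
real cohorts.

## Sample identity and labels

Cohorts such as ROSMAP identify the same individual differently in each
assay (a methylation ID like `PT-M5AF`, an RNA library ID, a CNV sequencing
ID). `resolve_aliases()` rewrites each table's sample IDs to stable
individual IDs through a crosswalk table; samples without a crosswalk entry
are dropped and counted, and two table samples resolving to one individual
is an error rather than a silent merge.

`align_samples()` then intersects the omics sample sets with the clinical
table. Two ordering decisions are deliberate:

* The intersection is sorted lexicographically (radix order, locale
  independent). Some order had to be fixed for the feature tensor and fold
  assignment to be reproducible across machines.
* Clinical features are filtered *after* intersection, so the missing
  fraction is computed on the samples that can actually enter the model. A
  feature is dropped when its missing fraction strictly exceeds the
  threshold (default 0.30, i.e. the ">30% missing" rule); "exactly 30%"
  survives.
* Samples whose label is missing are dropped after the omics/clinical
  intersection, and M counts only labelled samples. Labels become 0-based
  class indices in the order of a user-supplied class map, so C and the
  index meaning are explicit rather than inferred from factor levels.

## Methylation: five TSS-anchored promoter regions

Probe-level methylation is mapped to gene level through the probe
annotation (closest TSS gene + signed distance) over the −6 kb…+3 kb window
around the TSS, split into five regions: core promoter (0–50 bp upstream),
proximal promoter (50–250), distal promoter (250–3000), upstream
(3000–6000) and downstream (0–3000 bp downstream). Probes outside the
window are excluded.

Three conventions are not derivable from the region names alone and are
fixed here:

* **Sign.** Negative distance means upstream of the TSS. Annotation
  platforms are not unanimous here, so `region_scheme(upstream_negative =
  FALSE)` flips the convention.
* **Boundaries.** The printed region bounds touch (…50, 50–250, …). We use
  half-open upstream bins — core (0, 50], proximal (50, 250], distal
  (250, 3000], upstream (3000, 6000] — and a closed downstream interval
  [0, 3000], so distance 0 (a probe at the TSS) is downstream. This makes
  the five regions a true partition: every in-window distance lands in
  exactly one bin, which the test suite checks over the full window.
* **"Upstream" anchor.** The upstream region is read as 3000–6000 bp
  upstream *of the TSS*, not of the distal promoter's far edge; the latter
  reading would extend to −9 kb and contradict the stated −6 kb window.

Aggregation is the arithmetic mean of observed probe values per (gene,
region, sample). A gene-region whose probes are all missing for a sample
yields a missing cell, which region unification zero-pads and marks
imputed; measured cells are never rewritten, a property asserted via the
per-cell measured/imputed mask every matrix carries.

## Genetic variation: means for mutations, sums for CNVs, −1 fill

Gene-level binary mutation matrices (0 wild-type, 1 nonsilent) may carry
duplicate gene rows; they collapse by mean, so collapsed values can be
fractional — a deliberate retention of the duplicate disagreement rather
than a vote.

CNV segments are assigned to genes by genomic overlap: a segment maps to
every reference gene it shares ≥1 bp with on the same chromosome (closed
1-based intervals, strand ignored — CNVs are strand-agnostic). Overlap
search uses `GenomicRanges::findOverlaps`; the test suite checks it against
an all-pairs interval scan. Segments overlapping several genes contribute
to each (a `nearest_only` switch keeps only the largest overlap). Per-type
sums (DEL, DUP, mCNV) capture cumulative burden per gene.

Variation matrices pad with **−1**, not 0, both when unifying the three
type blocks and at the cross-omics union: 0 is a meaningful measured value
(no mutation), and the fill must stay distinguishable from it. All other
omics pad with 0. The mask makes this checkable: an imputed variation cell
is exactly −1.0, an imputed methylation/expression/protein cell exactly
0.0, and measured cells are bit-identical to their pre-padding values.

## Transcriptomics and proteomics

The fixed order is: strip the version suffix (only when everything after
the last dot is digits, so `ENSG00000167578.11` loses `.11` but
`GENE.ALPHA` is untouched) → map stable IDs to symbols through a two-column
table, dropping unmapped rows with a count → collapse duplicate symbols by
mean over observed values → replace remaining nulls with 0. Zero imputation
after duplicate averaging means a duplicate group with one observed value
keeps that value rather than averaging it against an imputed 0; the
opposite order would shrink every partially-missing group toward zero.
Protein tags keep the substring before the first `|`; a tag with an empty
symbol is dropped with a warning.

## Harmonization and the final gene set

Gene-level blocks are filtered to the reference catalog (symbol-level,
case-sensitive after whitespace trimming — HGNC symbols are
case-meaningful), reindexed onto the lexicographic cross-omics union with
per-omics fill, and intersected with the regulatory network's node set.
Edges with a dropped endpoint are removed (induced subgraph); the surviving
gene list, again lexicographic, fixes node order, and with it the edge
index, permanently. Reference filtering and union formation commute (set
algebra), which the tests verify on random fixtures; the pipeline filters
first so per-omics survivor counts are observable.

## Graph assembly

Flat mode gives one node per gene with feature columns
`[methyl_region_1..5, variant_1..k, rnaseq, proteomics]`, so
`d = 5 + k + 2` (10 with three CNV types, 8 with one mutation block).

Multi-level mode expresses the biology of the flow promoter → transcription
→ protein explicitly: per gene, five region nodes each feed a gene node,
which feeds a protein node; protein nodes carry the PPI edges. That is a
fixed 7-node, 6-edge motif per gene, so a study with n genes and p directed
induced PPI edges yields exactly 7n nodes and 6n + p edges. Three choices
here were open and are ours:

* Intra-gene edges are directed region→gene→protein by default
  (`undirected_internal` mirrors them), encoding the causal reading of the
  flow.
* Undirected PPI edges are materialized as two directed edges, because an
  edge index has no "undirected" representation; directed networks keep
  their orientation.
* Every node row is width d with zeros outside its own columns, so one
  tensor serves all node types; variation features sit on the gene node
  (mutations act on the gene body), configurable in principle to the
  protein node. The cost is sparsity; the benefit is that no per-type
  feature bookkeeping leaks into the model interface.

The edge index lists the nonzeros of A in row-major order with 0-based
indices — the convention of graph deep-learning frameworks — and the
conversion is exactly invertible, which both the unit tests and the
serialization round trip assert.

## Export and cross-validation

`stack_features()` builds `X` of shape (M, n_nodes, d) in aligned sample
order. `make_folds()` shuffles sample order by a seeded Fisher–Yates
permutation and cuts contiguous chunks whose sizes differ by at most one;
folds are unstratified by default (the 5-fold protocol this mirrors is
unstratified), deterministic per seed, and each held-out fold's complement
is the training set. Labels are stored as integer class indices plus a
class-name table — a one-hot `R^(M×C)` matrix is derivable and the indices
are lossless and smaller.

Serialization is plain text: long-format CSV for X, CSVs for Y, edge index,
node map and folds, and a JSON manifest recording shapes, fill values, the
fold seed, stage counts and per-file md5 checksums. Numerics are written at
17 significant digits, so a write–read round trip reproduces every double
bit-exactly; a corrupted file fails the checksum on reload.

## The synthetic-study generator

`gen_study(fixture_spec())` fabricates a complete toy cohort: a reference
catalog (with a deliberate handful of genes missing from it), probe
annotation covering all five regions plus out-of-range and unannotated
probes, CNV segments of all three types including a segment overlapping two
genes, a gene-desert segment and one on a chromosome absent from the
reference, versioned and unmapped transcript IDs, accession-tagged and
duplicate protein rows, a crosswalk with per-omics aliases plus junk
aliases, partial sample overlap between layers, a clinical feature planted
above the missingness threshold, and label-missing samples.

Ground truth is computed by forward bookkeeping during generation —
straightforward set algebra and group-by arithmetic over the planted values
(the CNV truth uses a brute-force all-pairs overlap scan) — never by
calling the pipeline. End-to-end tests therefore compare two independent
computations, cell for cell, masks included, across seeded studies.

Default study conditions: 30 genes, 12 core samples (11 after the planted
missing label), 4 in-range probes per methylation gene, 5% missing cells,
two private samples per omics layer, a 15% out-of-range probe fraction, and
a PPI network over ~80% of the universe at 15% edge density. Values are
drawn uniform [0,1] for methylation, log-normal for expression and protein
abundance, and small non-negative integers for CNV dosage — test
scaffolding distributions chosen to be plausible in range, not biological
claims. The generator does **not** emulate covariance between omics layers,
batch structure, genome-scale cardinalities, or assay-specific noise; a
passing end-to-end suite certifies the mapping, aggregation, padding,
intersection and export rules, not statistical behavior on real cohorts.

## Numerical and degenerate-input choices

* Missing tokens on read: empty string, `NA`, `NaN`, `null`,
  case-insensitive; non-numeric cells in value matrices also become
  missing.
* Duplicate probe annotation rows keep the first occurrence with a warning;
  duplicate network edges deduplicate (unordered comparison for undirected
  edges).
* Empty intersections — samples across layers, genes against the reference,
  genes against the network — are hard errors, not empty outputs.
* Aggregation over an all-missing group yields a missing cell that the
  declared fill later replaces; sums treat missing contributions as absent
  (a gene-type with only missing segment values sums to a measured 0).
* Means are permutation-invariant in row order and bounded by the
  contributing values; sums conserve the per-(gene, sample, type) total.
  Both are asserted as properties, not single examples.

## Problem sizes

The shipped tests run studies of ~30 genes × ~12 samples (20 seeded studies
end-to-end, 100 random aggregation fixtures, 10,000-point region-partition
sweeps), sizes at which every expected matrix is computable by independent
arithmetic and the whole suite completes in well under a minute. The
pipeline itself is vectorized over samples and linear in rows for every
mapping stage; the only superlinear step, interval overlap, is delegated to
`GenomicRanges`.

## Known limitations

* Input matrices are dense in memory; genome-scale cohorts (400k probes ×
  thousands of samples) would want chunked readers behind the same
  interfaces.
* The multi-level wiring commits to one reading of the promoter →
  transcription → protein flow; alternatives (e.g. region→protein shortcuts
  or TF–target edges) would be new construction functions, which is why the
  motif construction is isolated in `build_multilevel_graph()`.
* No liftover: segment and reference coordinates are trusted to share an
  assembly, and no beta/M-value conversion or expression normalization is
  applied — inputs are taken as already normalized.
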