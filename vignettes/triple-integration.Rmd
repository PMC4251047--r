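---
title: "Triple integration of variant, expression and microarray data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Triple integration of variant, expression and microarray data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triomics)
```

## Overview

`triomics` joins three molecular-profiling modalities of one tumor sample —
whole-exome somatic variant calls, Cuffdiff RNA-seq differential
expression, and microarray probe intensities — into a single ordered
per-gene table, and checks whether DNA-called point mutations are actually
present in the transcriptome. This vignette describes the model behind
each step, the tunable parameters, the numerical conventions, and what the
synthetic test scenario does and does not demonstrate.

## The identifier switching center

Every gene identifier in the system is tagged with exactly one namespace
from a closed set: `entrez`, `ensembl_gene`, `ensembl_transcript`,
`genbank`, `symbol`, `affy_probeset`, `locus`. Association tables
contribute undirected edges between `(identifier, namespace)` nodes;
conversion from a source to a target namespace is defined as *graph
reachability* — a direct edge or any indirect path — so a probe set maps
to an Entrez id through its symbol without a dedicated table. Three
consequences of this definition are worth stating:

- Conversion is inherently one-to-many. `convert_id()` returns the full
  set of reachable target identifiers; collapsing to one is a caller
  policy, because probe sets and symbols are legitimately multi-mapped.
- Reachability is symmetric: `y ∈ convert(x, s→d)` iff
  `x ∈ convert(y, d→s)`. The test suite asserts this, and checks the whole
  operation against a brute-force transitive-closure oracle on random
  graphs of up to 50 nodes.
- Path choice is irrelevant; cycles are harmless (the implementation
  delegates reachability to connected components in `igraph`).

Genomic loci are kept out of the edge set. A separate interval index
(backed by `IRanges`) maps coordinate ranges to gene nodes;
`map_locus_to_genes()` ignores strand and uses the package's internal
coordinate convention.

**Coordinates.** Internally all loci are 0-based half-open, so width is
`end − start` with no ±1 arithmetic. Everything user-facing — locus
strings, the VCF column, IGV `goto` commands — is 1-based fully inclusive.
The two conventions meet only in `locus_from_string()` /
`locus_to_string()`. Protein positions are a third, independent system:
1-based inclusive amino-acid coordinates (a domain spanning 102–292
contains both 102 and 292); these are never mixed with genomic arithmetic.

**Row resolution.** Generic three-column inputs (gene id, symbol, locus)
resolve with a fixed precedence: the id is tried first (its namespace
auto-detected: digits → Entrez, `ENSG`/`ENST` prefix → Ensembl, otherwise
GenBank), then the symbol, then the locus. The first key found in the
graph wins and populates every reachable field of the returned identity; a
row resolving nowhere yields a stub identity flagged `unresolved` that
keeps the supplied fields. Symbols are upper-cased at load and at query,
which tolerates source-case drift without fuzzy matching.

## Ingest and validation

Each parser applies explicit typing and range checks, and returns its
records together with an import report. The report satisfies
`rows_read = rows_accepted + rows_rejected` on every input — corrupt rows
land in the report with the violated rule, never in the record list. The
fuzz tests corrupt random lines of every file family and assert exactly
this.

Cuffdiff files are consumed as produced by Cuffdiff 2.x (`test_id`,
`gene_id`, `gene`, `locus`, `value_1`, `value_2`, `log2(fold_change)`,
`p_value`, `q_value`, `significant`). Two policies matter:

- The `significant` yes/no column is authoritative; the package never
  recomputes an FDR. The upstream tool's decision is part of the data.
- Infinite log2 fold changes — printed `inf`/`-inf` or as the
  `1.79769e+308` sentinel — are stored as signed R infinities, never as
  finite numbers, because zero-FPKM denominators are common and
  meaningful.

Variant files may be VCF 4.x with SnpEff classic `EFF` annotations (the
`Effect`, `Codon_Change`, `Amino_Acid_Change` and `Gene_Name` subfields
are extracted) or a tab-delimited export mirroring the integrated table's
WES columns. Multi-allelic records split into one record per alternate
allele, since all downstream logic is per-allele. Allelic-frequency
columns may arrive as fractions or percents; detection is file-level — the
column is treated as percent only when the majority of its finite values
exceed 1, in which case all values are divided by 100 and the report notes
it. Under this rule a lone `1.5` in an otherwise fractional column is a
range violation and is rejected, while a column of values like `14.16`
imports as percentages.

Two small numeric helpers belong to this layer. `allelic_frequency()` is
`alt/depth` (undefined at zero depth, by error rather than `NaN`), and
`inner_mate_distance()` is the paired-end library identity
`fragment − 2 × read length`: a 300–350 bp library sequenced 2 × 101 bp
has a 98–148 bp inner mate distance, and a negative result is flagged as
overlapping mates rather than returned.

## Integrated views

`associate()` keys each record by its resolved identity's canonical key —
Entrez id when present, else Ensembl gene id, else upper-cased symbol,
else locus string. Entrez-first matches the table's leading column and
makes merges deterministic. Records whose identity cannot be resolved go
to an unresolved bucket that is preserved and reported, never silently
dropped; every input record is accounted for exactly once.

`build_view()` is a full outer join over gene keys: a gene present in any
selected modality yields a row with empty cells elsewhere. The paper-shaped
alternative (inner join) was rejected because it hides exactly the
interesting cases — a mutated gene with no expression data, an expressed
gene with no variant. Column blocks always appear in the fixed order core
→ WES → RNA-seq → microarray → member list, regardless of which studies
are loaded, and the block colors (grey, green, light red, blue, grey)
travel as metadata in the table attributes and the `#blocks:` header of
the TSV export, not as rendering.

`minimal` mode restricts each block to its headline columns (WES: Effect,
Codon Change, AA Change, Tumor DP, Tumor AF; RNA: Sample 1 FPKM, Sample 2
FPKM, p-value; microarray: Affy Probes, Avg Probe Values — the mean of the
gene's probe values, with an empty cell rather than a value when no probe
maps). `maximal` exposes everything parsed.

When an isoform-level dataset is included, the view emits one row per
isoform and repeats the gene-level WES and microarray cells on each row,
so a single variant annotation appears against each of a gene's
transcripts. When a gene carries several variants *and* several isoforms
the rows are the cross product; the typical somatic case (one variant) is
unaffected, and no record is ever lost. Rows are ordered by chromosome and
start where loci are known, unresolved rows last, symbols breaking ties —
genomic order makes browser navigation natural.

Gene groups are named member sets in any namespace; membership matching
converts members through the graph, so a group listing Entrez `7157`
matches a row keyed by symbol `TP53`. Filtering preserves order, returns a
subset, and is idempotent.

## DNA→RNA concordance

`count_alleles()` is a single-position pileup over a SAM/BAM source:
unmapped, secondary, supplementary, QC-fail and (by default)
duplicate-marked reads are excluded, as are reads under the mapping- or
base-quality cutoffs (defaults: base quality 13, mapping quality 0); a
deletion or N at the position counts as `other`. Counting is
fragment-level: when both mates of a pair overlap the position, the base
with the higher base quality is used once — with ~100–150 bp inner mate
distances, mate overlap at the locus is routine and would otherwise
double-count. Bases are compared on the genomic forward strand; the fact
that a reverse-strand gene's mutation "looks like" the complementary base
in a browser is purely presentational.

`classify_concordance()` partitions every input into exactly one status:

| status | condition |
|---|---|
| `no_rna_data` | no RNA experiment supplied |
| `insufficient_coverage` | RNA depth < `min_rna_depth` (default 10) |
| `expressed_concordant` | alt reads ≥ `min_alt_reads` (2) and RNA AF ≥ `min_rna_af` (0.01) |
| `not_expressed` | otherwise |

The thresholds are explicit, configurable stand-ins for what is otherwise
a visual judgement in a genome browser; they are recorded in the
`#thresholds:` header of every concordance report so a reader can see the
criterion alongside the calls. The classification is monotone — more
alternate reads never flip a call away from `expressed_concordant` — and
the pileup itself is checked against a naive per-read re-scan oracle on
randomly generated reads with mixed CIGARs.

## The synthetic scenario

No patient sequencing data ships with the package; `preset_mm_case()`
defines a deterministic single-patient multiple-myeloma scenario and
`generate_fixtures()` writes it as real files (VCF, SAM, Cuffdiff TSVs,
probe and association tables) on a tiny invented two-contig reference
(2 × 50 kb). The scenario facts are the interesting ones for the method:

- **KRAS G13D**: tumor depth 113, alternate count 16 — the unique integer
  count at that depth whose fraction displays as 14% — and 0 alternate
  reads in 200× RNA coverage, so the hotspot classifies `not_expressed`.
- **TP53 C277F**: depth 82, alternate count 78 (the unique count
  displaying as 95%), with 90/100 alternate RNA reads —
  `expressed_concordant`. The change sits inside the DNA-binding domain
  (102–292), where most TP53 missense mutations fall.
- Four KRAS isoform records (two annotated transcripts with non-zero
  tumor FPKM, one zero, one novel `CUFF.*` assembly product; only
  ENST00000311936 significant) and seven TP53 isoforms.
- A five-gene user group (KRAS, TP53, NRAS, MYC, BRAF) exercising group
  filtering and the member-list column.

Reads are generated with uniform high base qualities, single-end, all-`M`
CIGARs, and exactly the configured ref/alt counts at each variant
position; the same seed yields byte-identical bundles. This is
deliberately *not* a sequencing simulator: there are no error profiles, no
coverage ripple, no mapping ambiguity, no multi-mapping isoform
uncertainty. Passing tests therefore demonstrate the correctness of the
integration, counting and classification logic under clean inputs — not
robustness to the full messiness of real alignments, which enters only
through the quality/duplicate/CIGAR handling exercised by the randomized
oracle tests.

## The store and CLI

The study store collapses a three-tier web deployment into a single state
file: studies keyed uniquely by (subject, modality, date), a synchronous
FIFO import queue (`process_next()` / `run_queue()`; no daemon, for
testability), staging (raw parsed records plus report) and associated
(gene-keyed) tables per study. A failed import keeps its staging detail
for inspection and the queue advances. `cascade_delete()` removes a study
or a whole subject from every table; `store_orphan_scan()` is the
referential check that afterwards finds zero rows keyed to missing
studies. The `triomics` executable is a thin dispatcher over these
functions.

## Problem sizes and numerical choices

The randomized suites run 100 trials each for graph-conversion,
locus-overlap and pileup oracle equivalence (graphs ≤ 50 nodes, ≤ 30
intervals, ≤ 20 mixed-CIGAR reads), chosen to exercise the combinatorics
while keeping the default test run around a minute. Ties in
fragment-level mate selection go to the first-seen mate at equal quality.
Degenerate inputs are defined rather than accidental: empty files parse to
empty record lists with zero-row reports, zero-depth pileups have an
absent (`NA`) allelic frequency, an empty probe list yields an absent
average, and a zero-width locus query overlaps nothing.

## Limitations

- Concordance handles SNVs only; indel concordance would need gapped
  allele matching.
- One gene-level expression record per gene is rendered per row; competing
  gene-level records (unusual in Cuffdiff output) beyond the first are
  retained in the dataset but not spread across extra rows.
- The drug–gene table and canonical-mutation lists are local editable
  TSVs; no live database queries are made.
- Genome-build liftover, alias/fuzzy symbol matching and novel-isoform
  discovery are out of scope; `CUFF.*` records are consumed, not computed.
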