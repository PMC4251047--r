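# triomics

Triple integration of somatic variant calls, RNA-seq differential
expression and microarray probe values into unified per-gene views.

## The problem

Cancer molecular-profiling studies routinely produce three kinds of
evidence about the same tumor: whole-exome sequencing (WES) somatic variant
calls, RNA-seq differential expression (Cuffdiff gene- and isoform-level
FPKM tables), and microarray probe intensities. Each arrives in its own
file format, keyed by its own gene identifier namespace (Entrez ids,
Ensembl gene/transcript ids, GenBank accessions, HGNC symbols, Affymetrix
probe sets), and conclusions drawn from any single modality can mislead: a
druggable DNA hotspot mutation that is never transcribed will not be
translated into a drug target.

`triomics` is a headless library + CLI for exactly this integration step.
It provides:

- **A gene-identifier "switching center"** — an undirected association
  graph over `(identifier, namespace)` nodes. Conversion between
  namespaces is reachability in this graph (direct edge or any indirect
  path), and an interval index additionally maps genomic loci to genes.
  Internally all coordinates are 0-based half-open; every displayed string
  (`chr:start-end`, IGV `goto`) is 1-based inclusive.
- **Typed, validated ingest** of SnpEff-annotated VCFs (or tab-delimited
  exports), Cuffdiff `gene_exp.diff` / `isoform_exp.diff` tables, and
  `gene, probeID, value` microarray tables, with row-level rejection
  reports satisfying `rows_read = rows_accepted + rows_rejected`.
- **Integrated views**: full outer joins over resolved genes with a fixed
  column-block schema — core (Entrez ID, Gene Symbol, Gene Name; grey),
  WES (green), RNA-seq (light red), microarray (blue), Member List (grey)
  — filterable by user-defined gene groups.
- **DNA→RNA concordance**: pileup allele counting at a DNA-called SNV
  position in RNA alignments (fragment-level, quality- and
  duplicate-aware), classified into `expressed_concordant` /
  `not_expressed` / `insufficient_coverage` / `no_rna_data` under explicit
  thresholds. The allelic frequency of an alternate allele is
  `AF = alt_count / depth`.
- **Annotation products**: protein-domain containment (1-based inclusive
  amino-acid coordinates), lolliplot data (observed mutations red,
  canonical blue, domains green), FPKM bar/donut chart data, and drug–gene
  interaction lookup with a deterministic DGIdb URL builder.
- **IGV batch automation** (`new` / `genome` / `load` / `goto` /
  `snapshot` over TCP, default port 60151).
- **A study store** with a synchronous FIFO import queue, per-study
  staging and associated tables, an executive console summary, and
  cascading delete that leaves zero orphaned rows.
- **A deterministic fixture generator** whose preset emulates a
  single-patient multiple-myeloma case: a KRAS G13D hotspot (113 reads,
  14% AF — 16/113) absent from 200× RNA coverage, and a TP53 C277F
  (82 reads, 95% AF — 78/82) confirmed by RNA, inside the TP53 DNA-binding
  domain (amino acids 102–292).

## Worked example

```r
library(triomics)

bundle <- generate_fixtures(preset_mm_case(), "bundle")
graph  <- build_graph(bundle$associations, bundle$loci)

pv <- parse_variants(bundle$vcf, graph)
pg <- parse_cuffdiff_genes(bundle$gene_diff, graph)
pr <- parse_probe_table(bundle$probes)

tab <- build_view(list(associate(pv$records, graph, "wes"),
                       associate(pg$records, graph, "rnaseq_gene"),
                       associate(pr$records, graph, "microarray")),
                  groups = read_groups_table(bundle$groups), graph = graph)
print(tab)
```

```
<integrated_table> 5 rows, mode=minimal, blocks: core | wes | rna | array | member
  entrez_id gene_symbol                   gene_name            wes.effect
1      3845        KRAS KRAS proto-oncogene, GTPase NON_SYNONYMOUS_CODING
2      4893        NRAS NRAS proto-oncogene, GTPase                  <NA>
...
  wes.codon_change wes.aa_change wes.tumor_dp wes.tumor_af rna.sample1_fpkm
1          gGt/gAt          G13D          113     0.141593             21.7
...
```

The KRAS row carries the G13D annotation at 113 reads depth and
`0.141593` allelic frequency (displayed 14%); genes without a variant show
empty (outer-joined) WES cells. Checking whether that DNA mutation is
actually transcribed:

```r
conc <- concordance_report(pv$records, bundle$rna_sam)
conc[, c("gene", "dna_af", "rna_depth", "rna_alt", "status")]
```

```
  gene    dna_af rna_depth rna_alt               status
1 KRAS 0.1415929       200       0        not_expressed
2 TP53 0.9512195       100      90 expressed_concordant
```

KRAS shows 0 alternate reads in 200× RNA coverage — the hotspot is not
expressed, so a therapy targeting mutant KRAS protein would miss. The TP53
mutation is concordant between DNA (95%) and RNA (90%).

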