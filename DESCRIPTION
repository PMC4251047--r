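Package: triomics
Title: Triple Integration of Somatic Variants, RNA-Seq Expression and Microarray Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates whole-exome somatic variant calls, Cuffdiff RNA-seq
    differential expression (gene and isoform level) and microarray probe
    values into unified per-gene tables. Provides a gene identifier
    "switching center" graph for conversion among Entrez, Ensembl, GenBank,
    symbol and probe-set namespaces (directly, indirectly or by genomic
    coordinates), DNA-to-RNA variant expression concordance calling from
    aligned reads, gene-group filtering, chart and lolliplot data
    generation, drug-gene interaction linkage, IGV batch automation over
    TCP, a deterministic multi-modality fixture generator, and a persistent
    study store with an import job queue and cascading delete, all exposed
    through a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Rsamtools,
    vcfR,
    jsonlite,
    methods,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
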