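## Deterministic synthetic multi-modality bundle generator. Produces, from a
## scenario configuration, every file family the ingest/concordance modules
## consume (association + locus TSVs, SnpEff-style VCF, RNA and DNA SAM,
## Cuffdiff gene/isoform diff tables, probe table, domain/canonical/drug
## tables, group table) on a tiny invented reference (two contigs). The
## preset scenario emulates a single-patient multiple myeloma case: a KRAS
## G13D hotspot (113 reads, 14% AF) that is absent from RNA, and a TP53
## C277F (82 reads, 95% AF) that RNA confirms, plus a five-gene user group.

#' Build a scenario configuration
#'
#' All randomness downstream is fixed by `seed`; the same configuration
#' always generates a byte-identical bundle. Validation happens here:
#' variants must reference defined genes, lie inside their gene's locus and
#' never claim more alternate reads than depth.
#'
#' @param seed Integer seed.
#' @param contigs Named integer vector of contig lengths.
#' @param genes List of gene specs: `list(symbol, entrez, ensembl_gene,
#'   genbank, probesets, chrom, start, end, strand, name, protein_length)`
#'   (`start`/`end` 1-based inclusive as displayed).
#' @param variants List of `list(gene, pos, ref, alt, effect, codon_change,
#'   aa_change, tumor_depth, tumor_alt, normal_depth, normal_alt,
#'   rna_depth, rna_alt)`.
#' @param gene_expression List of `list(gene, normal_fpkm, tumor_fpkm,
#'   p_value, q_value, significant)`.
#' @param isoforms List of `list(gene, transcript_id, normal_fpkm,
#'   tumor_fpkm, p_value, q_value, significant)`.
#' @param probes List of `list(gene, probe_id, value)`.
#' @param groups Named list of member identifier vectors.
#' @param domains List of `list(gene, domain_name, start_aa, end_aa)`.
#' @param canonical List of `list(gene, label)` known mutations.
#' @param drugs List of `list(gene, drug, interaction_type, source)`.
#' @return A validated `scenario_config`.
#' @export
scenario_config <- function(seed, contigs, genes, variants = list(),
                            gene_expression = list(), isoforms = list(),
                            probes = list(), groups = list(),
                            domains = list(), canonical = list(),
                            drugs = list()) {
  seed <- as.integer(seed)
  stopifnot(!is.na(seed), length(contigs) >= 1L, !is.null(names(contigs)))
  syms <- vapply(genes, `[[`, "", "symbol")
  if (anyDuplicated(syms)) stop("duplicate gene symbols in config")
  gmap <- stats::setNames(genes, syms)
  for (g in genes) {
    if (!g$chrom %in% names(contigs)) stop("gene ", g$symbol, ": unknown contig")
    if (g$start < 1L || g$end > contigs[[g$chrom]] || g$start > g$end)
      stop("gene ", g$symbol, ": locus outside contig")
  }
  for (v in variants) {
    g <- gmap[[v$gene]]
    if (is.null(g)) stop("variant references undefined gene: ", v$gene)
    if (v$pos < g$start || v$pos > g$end)
      stop("variant position outside gene ", v$gene)
    if (v$tumor_alt > v$tumor_depth || v$rna_alt > v$rna_depth ||
        (v$normal_alt %||% 0) > (v$normal_depth %||% 0))
      stop("variant for ", v$gene, ": alt reads exceed depth")
    if (identical(v$ref, v$alt)) stop("variant for ", v$gene, ": ref equals alt")
  }
  for (x in c(gene_expression, isoforms, probes, domains, canonical, drugs))
    if (is.null(gmap[[x$gene]])) stop("record references undefined gene: ", x$gene)
  structure(list(seed = seed, contigs = contigs, genes = gmap,
                 variants = variants, gene_expression = gene_expression,
                 isoforms = isoforms, probes = probes, groups = groups,
                 domains = domains, canonical = canonical, drugs = drugs),
            class = "scenario_config")
}

## Deterministic invented reference: one base vector per contig, with every
## variant's ref base patched in so generated reads are self-consistent.
fixture_reference <- function(config) {
  ref <- list()
  for (chrom in names(config$contigs)) {
    set.seed(config$seed + utf8ToInt(substr(chrom, nchar(chrom), nchar(chrom))))
    ref[[chrom]] <- sample(c("A", "C", "G", "T"), config$contigs[[chrom]],
                           replace = TRUE)
  }
  for (v in config$variants) {
    chrom <- config$genes[[v$gene]]$chrom
    ref[[chrom]][v$pos] <- v$ref
  }
  ref
}

write_sam_reads <- function(path, config, reference, depth_field, alt_field,
                            read_prefix, read_len = 75L) {
  lines <- c("@HD\tVN:1.6\tSO:coordinate")
  for (chrom in names(config$contigs))
    lines <- c(lines, sprintf("@SQ\tSN:%s\tLN:%d", chrom, config$contigs[[chrom]]))
  recs <- list()
  for (vi in seq_along(config$variants)) {
    v <- config$variants[[vi]]
    chrom <- config$genes[[v$gene]]$chrom
    depth <- v[[depth_field]]; nalt <- v[[alt_field]]
    if (depth == 0L) next
    for (i in seq_len(depth)) {
      offset <- (i - 1L) %% read_len
      start <- max(1L, v$pos - offset)
      start <- min(start, config$contigs[[chrom]] - read_len + 1L)
      bases <- reference[[chrom]][start:(start + read_len - 1L)]
      if (i <= nalt) bases[v$pos - start + 1L] <- v$alt
      recs[[length(recs) + 1L]] <- list(
        qname = sprintf("%s_v%d_r%04d", read_prefix, vi, i),
        chrom = chrom, pos = start,
        seq = paste(bases, collapse = ""))
    }
  }
  ord <- order(vapply(recs, `[[`, "", "chrom"),
               vapply(recs, `[[`, 0, "pos"))
  for (r in recs[ord])
    lines <- c(lines, sprintf("%s\t0\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t%s",
                              r$qname, r$chrom, r$pos, read_len, r$seq,
                              strrep("I", read_len)))
  writeLines(lines, path)
}

write_vcf <- function(path, config) {
  lines <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", names(config$contigs),
            unname(config$contigs)),
    "##INFO=<ID=EFF,Number=.,Type=String,Description=\"Predicted effects\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=AF,Number=A,Type=Float,Description=\"Allele fraction\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tTUMOR\tNORMAL")
  for (v in config$variants) {
    g <- config$genes[[v$gene]]
    eff <- sprintf("EFF=%s(MODERATE|MISSENSE|%s|%s|%d|%s|protein_coding|CODING|%s|1)",
                   v$effect, v$codon_change %||% "", v$aa_change %||% "",
                   g$protein_length %||% 0L, g$symbol,
                   if (length(g$transcripts %||% character()))
                     g$transcripts[[1]] else "")
    taf <- v$tumor_alt / v$tumor_depth
    ndp <- v$normal_depth %||% v$tumor_depth
    naf <- (v$normal_alt %||% 0L) / max(ndp, 1L)
    lines <- c(lines, sprintf("%s\t%d\t.\t%s\t%s\t100\tPASS\t%s\tDP:AF\t%d:%.6g\t%d:%.6g",
                              g$chrom, v$pos, v$ref, v$alt, eff,
                              v$tumor_depth, taf, ndp, naf))
  }
  writeLines(lines, path)
}

cuffdiff_header <- paste("test_id", "gene_id", "gene", "locus", "sample_1",
                         "sample_2", "status", "value_1", "value_2",
                         "log2(fold_change)", "test_stat", "p_value",
                         "q_value", "significant", sep = "\t")

cuffdiff_line <- function(test_id, gene_id, gene, locus, v1, v2, p, q, sig) {
  l2fc <- if (v1 == 0 && v2 == 0) "0" else if (v1 == 0) "inf"
          else if (v2 == 0) "-inf" else sprintf("%.6g", log2(v2 / v1))
  paste(test_id, gene_id, gene, locus, "Normal", "Tumor", "OK",
        sprintf("%.6g", v1), sprintf("%.6g", v2), l2fc, "0",
        sprintf("%.6g", p), sprintf("%.6g", q),
        if (sig) "yes" else "no", sep = "\t")
}

gene_locus_string <- function(g) sprintf("%s:%d-%d", g$chrom, g$start, g$end)

#' Generate a fixture bundle from a scenario configuration
#'
#' Writes every file family into `out_dir`. Read sets are constructed so
#' that [count_alleles()] recovers exactly the configured ref/alt counts at
#' each variant position; the same seed always yields byte-identical files.
#'
#' @param config A [scenario_config()].
#' @param out_dir Writable output directory (created if missing).
#' @return A `fixture_bundle`: named list of generated paths plus the config.
#' @export
generate_fixtures <- function(config, out_dir) {
  stopifnot(inherits(config, "scenario_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  reference <- fixture_reference(config)

  ## association + locus tables
  assoc <- c("id_a\tns_a\tid_b\tns_b")
  for (g in config$genes) {
    add <- function(a, na, b, nb) assoc <<- c(assoc, paste(a, na, b, nb, sep = "\t"))
    add(g$symbol, "symbol", g$entrez, "entrez")
    if (!is.null(g$ensembl_gene)) add(g$symbol, "symbol", g$ensembl_gene, "ensembl_gene")
    for (acc in g$genbank %||% character()) add(g$entrez, "entrez", acc, "genbank")
    for (ps in g$probesets %||% character()) add(g$symbol, "symbol", ps, "affy_probeset")
  }
  for (iso in config$isoforms)
    if (!startsWith(iso$transcript_id, "CUFF.")) {
      g <- config$genes[[iso$gene]]
      if (!is.null(g$ensembl_gene))
        assoc <- c(assoc, paste(g$ensembl_gene, "ensembl_gene",
                                iso$transcript_id, "ensembl_transcript",
                                sep = "\t"))
    }
  writeLines(unique(assoc), p("associations.tsv"))

  loci <- c("gene_id\tchrom\tstart\tend\tstrand\tname")
  for (g in config$genes)
    loci <- c(loci, paste(g$entrez, g$chrom, g$start, g$end, g$strand,
                          g$name %||% g$symbol, sep = "\t"))
  writeLines(loci, p("loci.tsv"))

  write_vcf(p("variants.vcf"), config)
  write_sam_reads(p("dna.sam"), config, reference, "tumor_depth", "tumor_alt", "dna")
  write_sam_reads(p("rna.sam"), config, reference, "rna_depth", "rna_alt", "rna")

  gd <- c(cuffdiff_header)
  for (i in seq_along(config$gene_expression)) {
    e <- config$gene_expression[[i]]
    g <- config$genes[[e$gene]]
    gd <- c(gd, cuffdiff_line(sprintf("XLOC_%06d", i), g$ensembl_gene %||% g$symbol,
                              g$symbol, gene_locus_string(g), e$normal_fpkm,
                              e$tumor_fpkm, e$p_value, e$q_value %||% e$p_value,
                              e$significant))
  }
  writeLines(gd, p("gene_exp.diff"))

  iso <- c(cuffdiff_header)
  for (e in config$isoforms) {
    g <- config$genes[[e$gene]]
    iso <- c(iso, cuffdiff_line(e$transcript_id, g$ensembl_gene %||% g$symbol,
                                g$symbol, gene_locus_string(g), e$normal_fpkm,
                                e$tumor_fpkm, e$p_value, e$q_value %||% e$p_value,
                                e$significant))
  }
  writeLines(iso, p("isoform_exp.diff"))

  pr <- c("gene\tprobeID\tvalue")
  for (m in config$probes)
    pr <- c(pr, paste(m$gene, m$probe_id, sprintf("%.6g", m$value), sep = "\t"))
  writeLines(pr, p("probes.tsv"))

  grp <- c("group\tmember")
  for (nm in names(config$groups))
    for (m in config$groups[[nm]]) grp <- c(grp, paste(nm, m, sep = "\t"))
  writeLines(grp, p("groups.tsv"))

  dom <- c("protein_symbol\tdomain_name\tstart_aa\tend_aa\tprotein_length")
  for (d in config$domains) {
    g <- config$genes[[d$gene]]
    dom <- c(dom, paste(g$symbol, d$domain_name, d$start_aa, d$end_aa,
                        g$protein_length, sep = "\t"))
  }
  writeLines(dom, p("domains.tsv"))

  can <- c("protein_symbol\tlabel")
  for (cm in config$canonical)
    can <- c(can, paste(config$genes[[cm$gene]]$symbol, cm$label, sep = "\t"))
  writeLines(can, p("canonical_mutations.tsv"))

  dr <- c("gene\tdrug\tinteraction_type\tsource")
  for (d in config$drugs)
    dr <- c(dr, paste(config$genes[[d$gene]]$symbol, d$drug,
                      d$interaction_type, d$source, sep = "\t"))
  writeLines(dr, p("drugs.tsv"))

  structure(list(associations = p("associations.tsv"), loci = p("loci.tsv"),
                 vcf = p("variants.vcf"), dna_sam = p("dna.sam"),
                 rna_sam = p("rna.sam"), gene_diff = p("gene_exp.diff"),
                 isoform_diff = p("isoform_exp.diff"),
                 probes = p("probes.tsv"), groups = p("groups.tsv"),
                 domains = p("domains.tsv"),
                 canonical = p("canonical_mutations.tsv"),
                 drugs = p("drugs.tsv"), config = config, dir = out_dir),
            class = "fixture_bundle")
}

#' Load gene groups from a `group, member` TSV
#'
#' @param path TSV path with header `group member`.
#' @return List of `gene_group`s.
#' @export
read_groups_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  grps <- split(tab$member, tab$group)
  unname(Map(function(nm, m) gene_group(name = nm, members = m),
             names(grps), grps))
}

#' The multiple-myeloma case-study preset
#'
#' A single-patient scenario with the findings the integrated views are
#' designed to surface: a KRAS G13D hotspot at 113 reads tumor depth and 14%
#' allelic frequency (16/113) that RNA-seq reads do not support
#' (not expressed); a TP53 C277F at 82 reads and 95% AF (78/82) that RNA-seq
#' confirms; two annotated KRAS isoforms with non-zero tumor FPKM plus the
#' novel CUFF.19733.1 assembly product (only ENST00000311936 significant);
#' seven TP53 transcript isoforms; significant over-expression of TP53; and
#' a five-gene user group. Loci live on a tiny invented two-contig
#' reference, not real genome coordinates.
#'
#' @param seed Integer seed fixing all generated randomness.
#' @return A `scenario_config`.
#' @export
preset_mm_case <- function(seed = 20140326L) {
  genes <- list(
    list(symbol = "KRAS", entrez = 3845L, ensembl_gene = "ENSG00000133703",
         genbank = c("NM_004985"), probesets = c("214352_s_at", "1559204_x_at"),
         chrom = "chr1", start = 10001L, end = 15000L, strand = "-",
         name = "KRAS proto-oncogene, GTPase", protein_length = 189L),
    list(symbol = "TP53", entrez = 7157L, ensembl_gene = "ENSG00000141510",
         genbank = c("NM_000546"), probesets = c("201746_at"),
         chrom = "chr2", start = 20001L, end = 28000L, strand = "-",
         name = "tumor protein p53", protein_length = 393L),
    list(symbol = "NRAS", entrez = 4893L, ensembl_gene = "ENSG00000213281",
         genbank = character(), probesets = c("202647_s_at"),
         chrom = "chr1", start = 30001L, end = 34000L, strand = "-",
         name = "NRAS proto-oncogene, GTPase", protein_length = 189L),
    list(symbol = "MYC", entrez = 4609L, ensembl_gene = "ENSG00000136997",
         genbank = character(), probesets = c("202431_s_at"),
         chrom = "chr1", start = 40001L, end = 44000L, strand = "+",
         name = "MYC proto-oncogene", protein_length = 439L),
    list(symbol = "BRAF", entrez = 673L, ensembl_gene = "ENSG00000157764",
         genbank = character(), probesets = c("243829_at"),
         chrom = "chr2", start = 40001L, end = 46000L, strand = "-",
         name = "B-Raf proto-oncogene", protein_length = 766L))
  variants <- list(
    ## 16/113 is the unique integer alt count at depth 113 displaying as 14%
    list(gene = "KRAS", pos = 12500L, ref = "C", alt = "T",
         effect = "NON_SYNONYMOUS_CODING", codon_change = "gGt/gAt",
         aa_change = "G13D", tumor_depth = 113L, tumor_alt = 16L,
         normal_depth = 108L, normal_alt = 0L, rna_depth = 200L,
         rna_alt = 0L),
    ## 78/82 is the unique integer alt count at depth 82 displaying as 95%
    list(gene = "TP53", pos = 24000L, ref = "C", alt = "A",
         effect = "NON_SYNONYMOUS_CODING", codon_change = "tGc/tTc",
         aa_change = "C277F", tumor_depth = 82L, tumor_alt = 78L,
         normal_depth = 95L, normal_alt = 0L, rna_depth = 100L,
         rna_alt = 90L))
  gene_expression <- list(
    list(gene = "KRAS", normal_fpkm = 21.7, tumor_fpkm = 48.3,
         p_value = 5e-5, q_value = 1e-3, significant = TRUE),
    list(gene = "TP53", normal_fpkm = 10.2, tumor_fpkm = 121.5,
         p_value = 5e-5, q_value = 1e-3, significant = TRUE),
    list(gene = "NRAS", normal_fpkm = 18.9, tumor_fpkm = 20.3,
         p_value = 0.62, q_value = 0.81, significant = FALSE),
    list(gene = "MYC", normal_fpkm = 30.4, tumor_fpkm = 42.8,
         p_value = 0.08, q_value = 0.21, significant = FALSE),
    list(gene = "BRAF", normal_fpkm = 7.5, tumor_fpkm = 8.1,
         p_value = 0.77, q_value = 0.9, significant = FALSE))
  isoforms <- list(
    list(gene = "KRAS", transcript_id = "ENST00000311936",
         normal_fpkm = 15.0, tumor_fpkm = 30.1, p_value = 5e-5,
         q_value = 1e-3, significant = TRUE),
    list(gene = "KRAS", transcript_id = "ENST00000556131",
         normal_fpkm = 6.2, tumor_fpkm = 12.4, p_value = 0.31,
         q_value = 0.55, significant = FALSE),
    list(gene = "KRAS", transcript_id = "ENST00000256078",
         normal_fpkm = 2.0, tumor_fpkm = 0.0, p_value = 0.48,
         q_value = 0.7, significant = FALSE),
    list(gene = "KRAS", transcript_id = "CUFF.19733.1",
         normal_fpkm = 3.3, tumor_fpkm = 0.0, p_value = 0.42,
         q_value = 0.66, significant = FALSE),
    list(gene = "TP53", transcript_id = "ENST00000269305",
         normal_fpkm = 8.1, tumor_fpkm = 96.3, p_value = 5e-5,
         q_value = 1e-3, significant = TRUE),
    list(gene = "TP53", transcript_id = "ENST00000445888",
         normal_fpkm = 0.9, tumor_fpkm = 9.6, p_value = 0.02,
         q_value = 0.09, significant = FALSE),
    list(gene = "TP53", transcript_id = "ENST00000420246",
         normal_fpkm = 0.5, tumor_fpkm = 5.8, p_value = 0.06,
         q_value = 0.18, significant = FALSE),
    list(gene = "TP53", transcript_id = "ENST00000455263",
         normal_fpkm = 0.3, tumor_fpkm = 3.9, p_value = 0.11,
         q_value = 0.3, significant = FALSE),
    list(gene = "TP53", transcript_id = "ENST00000414315",
         normal_fpkm = 0.2, tumor_fpkm = 2.5, p_value = 0.2,
         q_value = 0.41, significant = FALSE),
    list(gene = "TP53", transcript_id = "ENST00000610292",
         normal_fpkm = 0.1, tumor_fpkm = 1.8, p_value = 0.33,
         q_value = 0.57, significant = FALSE),
    list(gene = "TP53", transcript_id = "ENST00000635293",
         normal_fpkm = 0.1, tumor_fpkm = 1.2, p_value = 0.47,
         q_value = 0.69, significant = FALSE))
  probes <- list(
    list(gene = "KRAS", probe_id = "214352_s_at", value = 9.1),
    list(gene = "KRAS", probe_id = "1559204_x_at", value = 8.3),
    list(gene = "TP53", probe_id = "201746_at", value = 10.8),
    list(gene = "NRAS", probe_id = "202647_s_at", value = 8.9),
    list(gene = "MYC", probe_id = "202431_s_at", value = 11.2),
    list(gene = "BRAF", probe_id = "243829_at", value = 6.4))
  domains <- list(
    list(gene = "TP53", domain_name = "DNA binding domain",
         start_aa = 102L, end_aa = 292L),
    list(gene = "KRAS", domain_name = "RAS domain",
         start_aa = 1L, end_aa = 166L))
  canonical <- list(
    list(gene = "KRAS", label = "G12D"), list(gene = "KRAS", label = "G12V"),
    list(gene = "KRAS", label = "G12C"), list(gene = "KRAS", label = "Q61H"),
    list(gene = "TP53", label = "R175H"), list(gene = "TP53", label = "R248Q"),
    list(gene = "TP53", label = "R273H"))
  drugs <- list(
    list(gene = "KRAS", drug = "Reolysin", interaction_type = "inhibitor",
         source = "TTD"),
    list(gene = "KRAS", drug = "AZD4785", interaction_type = "antisense",
         source = "local"),
    list(gene = "TP53", drug = "APR-246", interaction_type = "reactivator",
         source = "local"))
  scenario_config(
    seed = seed,
    contigs = c(chr1 = 50000L, chr2 = 50000L),
    genes = genes, variants = variants, gene_expression = gene_expression,
    isoforms = isoforms, probes = probes,
    groups = list(KeyGenes = c("KRAS", "TP53", "NRAS", "MYC", "BRAF")),
    domains = domains, canonical = canonical, drugs = drugs)
}
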