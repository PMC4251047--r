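test_that("associate groups records by resolved gene and preserves unresolved ones", {
  pp <- preset_pipeline()
  dm <- pp$ds$microarray
  # two KRAS probe measurements resolve to the same entrez key
  expect_length(dm$keyed[["entrez:3845"]], 2)
  expect_length(dm$unresolved, 0)

  # a probe with an unknown symbol lands in the unresolved bucket, not dropped
  bad <- structure(list(probe_id = "999_at", gene_symbol = "NOSUCH",
                        value = 1.5), class = "probe_measurement")
  dm2 <- associate(c(pp$probes$records, list(bad)), pp$graph, "microarray")
  expect_length(dm2$unresolved, 1)
  expect_equal(sum(lengths(dm2$keyed)) + length(dm2$unresolved),
               length(pp$probes$records) + 1L)

  # a variant carrying only a locus resolves through the interval index
  v <- pp$variants$records[[1]]
  v$gene <- NULL
  naked <- structure(list(locus = v$locus, ref_allele = v$ref_allele,
                          alt_allele = v$alt_allele, effect = v$effect,
                          codon_change = v$codon_change, aa_change = v$aa_change,
                          tumor_depth = v$tumor_depth, tumor_af = v$tumor_af,
                          normal_depth = NA_integer_, normal_af = NA_real_,
                          gene = resolve_row_identity(locus = v$locus,
                                                      graph = pp$graph)),
                     class = "variant_record")
  dv <- associate(list(naked), pp$graph, "wes")
  expect_equal(names(dv$keyed), "entrez:3845")
})

test_that("the triple view outer-joins all modalities with the fixed block schema", {
  pp <- preset_pipeline()
  tab <- build_view(list(pp$ds$wes, pp$ds$rnaseq_gene, pp$ds$microarray),
                    groups = pp$groups, graph = pp$graph)
  expect_s3_class(tab, "integrated_table")
  # first three columns and the last are fixed
  expect_equal(names(tab)[1:3], c("entrez_id", "gene_symbol", "gene_name"))
  expect_equal(names(tab)[ncol(tab)], "member_list")
  expect_equal(attr(tab, "blocks")$block,
               c("core", "wes", "rna", "array", "member"))
  expect_equal(attr(tab, "blocks")$color,
               c("grey", "green", "light red", "blue", "grey"))

  kras <- tab[tab$gene_symbol == "KRAS", ]
  expect_equal(kras$wes.tumor_dp, 113L)
  expect_equal(round(kras$wes.tumor_af * 100), 14)
  expect_equal(kras$rna.sample2_fpkm, 48.3)
  expect_equal(kras$array.avg_probe_value, mean(c(9.1, 8.3)))
  # genes without a variant have empty WES cells (outer join)
  myc <- tab[tab$gene_symbol == "MYC", ]
  expect_true(is.na(myc$wes.effect))
  expect_equal(myc$array.avg_probe_value, 11.2)
})

test_that("a gene present only in one modality still yields a row", {
  pp <- preset_pipeline()
  only_array <- structure(list(probe_id = "55555_at", gene_symbol = "BRAF",
                               value = 3.3), class = "probe_measurement")
  dm <- associate(list(only_array), pp$graph, "microarray")
  tab <- build_view(list(pp$ds$wes, dm), graph = pp$graph)
  expect_true("BRAF" %in% tab$gene_symbol)
  braf <- tab[tab$gene_symbol == "BRAF", ]
  expect_true(is.na(braf$wes.effect))
  expect_equal(braf$array.avg_probe_value, 3.3)
})

test_that("view construction conserves records across all seven modality subsets", {
  pp <- preset_pipeline()
  all_ds <- pp$ds[c("wes", "rnaseq_gene", "microarray")]
  subsets <- unlist(lapply(1:3, function(k)
    combn(names(all_ds), k, simplify = FALSE)), recursive = FALSE)
  expect_length(subsets, 7)
  prev_order <- NULL
  for (sub in subsets) {
    tab <- build_view(all_ds[sub], graph = pp$graph)
    # conservation: every keyed gene of every chosen dataset appears
    for (m in sub) {
      for (key in names(all_ds[[m]]$identities)) {
        sym <- all_ds[[m]]$identities[[key]]$symbol
        expect_true(sym %in% tab$gene_symbol,
                    info = paste(m, sym, "missing in subset",
                                 paste(sub, collapse = "+")))
      }
      # each record lands in exactly one row for these gene-level datasets
      nrec <- sum(lengths(all_ds[[m]]$keyed))
      if (m == "wes")
        expect_equal(sum(!is.na(tab$wes.effect)), nrec)
      if (m == "rnaseq_gene")
        expect_equal(sum(!is.na(tab$rna.sample1_fpkm)), nrec)
    }
    # block order invariant across subsets
    blocks <- attr(tab, "blocks")$block
    expect_equal(blocks, intersect(c("core", "wes", "rna", "array", "member"),
                                   blocks))
  }
})

test_that("outer join is symmetric in dataset order", {
  pp <- preset_pipeline()
  t1 <- build_view(list(pp$ds$wes, pp$ds$microarray), graph = pp$graph)
  t2 <- build_view(list(pp$ds$microarray, pp$ds$wes), graph = pp$graph)
  expect_setequal(t1$gene_symbol, t2$gene_symbol)
  expect_equal(names(t1), names(t2))
  expect_equal(t1, t2)
})

test_that("two datasets of the same modality are refused", {
  pp <- preset_pipeline()
  expect_error(build_view(list(pp$ds$wes, pp$ds$wes)), "share modality")
})

test_that("isoform-level integration emits one row per isoform with gene cells repeated", {
  pp <- preset_pipeline()
  tab <- build_view(list(pp$ds$wes, pp$ds$rnaseq_isoform, pp$ds$microarray),
                    graph = pp$graph)
  tp53 <- tab[tab$gene_symbol == "TP53" & !is.na(tab$rna.transcript_id), ]
  expect_equal(nrow(tp53), 7)
  # the single TP53 variant annotation repeats on every isoform row
  expect_true(all(tp53$wes.aa_change == "C277F"))
  expect_true(all(tp53$wes.tumor_dp == 82L))
  kras <- tab[tab$gene_symbol == "KRAS" & !is.na(tab$rna.transcript_id), ]
  expect_equal(sum(!startsWith(kras$rna.transcript_id, "CUFF.") &
                     kras$rna.iso_sample2_fpkm > 0), 2)
})

test_that("group filtering restricts, preserves order, and is idempotent", {
  pp <- preset_pipeline()
  tab <- build_view(list(pp$ds$rnaseq_gene, pp$ds$microarray),
                    groups = pp$groups, graph = pp$graph)
  grp <- gene_group("pair", c("KRAS", "7157"))  # symbol and entrez member
  f1 <- filter_by_group(tab, grp, pp$graph)
  expect_setequal(f1$gene_symbol, c("KRAS", "TP53"))
  expect_equal(f1$gene_symbol, tab$gene_symbol[tab$gene_symbol %in% f1$gene_symbol])
  f2 <- filter_by_group(f1, grp, pp$graph)
  expect_equal(f1, f2)
  # subset relation always holds
  expect_true(all(f1$gene_symbol %in% tab$gene_symbol))
  # members absent from the table produce an empty result, not an error
  f3 <- filter_by_group(tab, gene_group("ghost", "NOSUCHGENE"), pp$graph)
  expect_equal(nrow(f3), 0)
  # restricting at build time matches filtering afterwards
  built <- build_view(list(pp$ds$rnaseq_gene, pp$ds$microarray), group = grp,
                      groups = pp$groups, graph = pp$graph)
  expect_setequal(built$gene_symbol, f1$gene_symbol)
})

test_that("member_list reports sorted group names across namespaces", {
  pp <- preset_pipeline()
  g1 <- gene_group("zgroup", "KRAS")
  g2 <- gene_group("agroup", "3845")      # entrez id of KRAS
  g3 <- gene_group("other", "TP53")
  kras <- resolve_row_identity(symbol = "KRAS", graph = pp$graph)
  expect_equal(member_list(kras, list(g1, g2, g3), pp$graph),
               c("agroup", "zgroup"))
  braf <- resolve_row_identity(symbol = "BRAF", graph = pp$graph)
  expect_equal(member_list(braf, list(g1, g2, g3), pp$graph), character(0))
})

test_that("TSV and JSON exports carry the block color metadata", {
  pp <- preset_pipeline()
  tab <- build_view(list(pp$ds$wes, pp$ds$rnaseq_gene, pp$ds$microarray),
                    groups = pp$groups, graph = pp$graph)
  tsv <- tempfile(fileext = ".tsv")
  write_integrated_tsv(tab, tsv)
  lines <- readLines(tsv)
  expect_match(lines[1], "^#blocks: core=grey;wes=green;rna=light red;array=blue")
  body <- read.delim(text = lines[-1], check.names = FALSE)
  expect_equal(nrow(body), nrow(tab))

  js <- tempfile(fileext = ".json")
  write_integrated_json(tab, js)
  obj <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(obj$blocks$color,
               c("grey", "green", "light red", "blue", "grey"))
  expect_equal(nrow(obj$rows), nrow(tab))
})
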