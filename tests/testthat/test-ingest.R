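test_that("allelic_frequency matches direct division and its display rounding", {
  # 16 is the only integer alt count at depth 113 whose fraction displays as 14%
  expect_equal(allelic_frequency(16, 113), 16 / 113)
  matches14 <- which(round(allelic_frequency(0:113, rep(113, 114)) * 100) == 14) - 1L
  expect_equal(matches14, 16L)
  expect_equal(allelic_frequency(0, 100), 0)
  expect_equal(allelic_frequency(100, 100), 1)
  expect_error(allelic_frequency(1, 0), "zero depth")
  expect_error(allelic_frequency(5, 4), "alt_count")
  # monotone in alt_count at fixed depth, always within [0,1]
  af <- allelic_frequency(0:50, rep(50, 51))
  expect_true(all(diff(af) > 0))
  expect_true(all(af >= 0 & af <= 1))
})

test_that("inner_mate_distance reproduces the paired-end arithmetic", {
  expect_equal(unname(inner_mate_distance(300, 350, 101)), c(98, 148))
  expect_equal(unname(inner_mate_distance(202, 202, 101)), c(0, 0))
  expect_error(inner_mate_distance(150, 200, 101), "verlapping mates")
})

test_that("average_probe_values is the arithmetic mean with an absent-value convention", {
  expect_equal(average_probe_values(c(5, 7)), 6)
  expect_equal(average_probe_values(c(4.2)), 4.2)
  vals <- c(1, 2, 3, 4)
  expect_equal(average_probe_values(vals), sum(vals) / length(vals))
  expect_true(is.na(average_probe_values(numeric(0))))
})

test_that("parse_variants accepts the case-study VCF and range-checks rows", {
  pp <- preset_pipeline()
  recs <- pp$variants$records
  expect_equal(pp$variants$report$rows_rejected, 0)
  kras <- recs[[which(vapply(recs, function(r) r$gene$symbol, "") == "KRAS")]]
  expect_equal(kras$tumor_depth, 113L)
  expect_equal(round(kras$tumor_af * 100), 14)
  expect_equal(kras$aa_change, "G13D")
  expect_equal(kras$effect, "NON_SYNONYMOUS_CODING")
  expect_false(kras$gene$unresolved)
})

test_that("tab-delimited variant rows are validated with row-level rejection", {
  g <- make_graph(assoc_df(c("GA", "symbol", "101", "entrez")),
                  data.frame(gene_id = "101", chrom = "chr1", start = 1L,
                             end = 1000L, strand = "+"))
  tab <- data.frame(chrom = c("chr1", "chr1", "chrBAD", "chr1"),
                    pos = c(10L, 20L, 30L, 40L),
                    ref = c("A", "C", "G", "T"),
                    alt = c("G", "T", "A", "T"),
                    effect = "NON_SYNONYMOUS_CODING",
                    codon_change = "x/y", aa_change = "A1B",
                    tumor_dp = c(50L, 60L, 70L, 80L),
                    tumor_af = c(0.5, 1.5, 0.1, 0.2),
                    gene = "GA", stringsAsFactors = FALSE)
  f <- tempfile(fileext = ".txt")
  write.table(tab, f, sep = "\t", quote = FALSE, row.names = FALSE)
  out <- parse_variants(f, g)
  # most AF values are fractions, so the stray 1.5 violates the range rule;
  # row 3 has an unknown chromosome; row 4 has ref == alt
  expect_equal(out$report$rows_read, 4)
  expect_equal(out$report$rows_rejected, 3)
  expect_true(any(grepl("outside \\[0,1\\]", out$report$rejections$rule)))
  expect_true(any(grepl("chromosome", out$report$rejections$rule)))
  expect_true(any(grepl("ref/alt", out$report$rejections$rule)))
  expect_length(out$records, 1)
  expect_equal(out$records[[1]]$tumor_af, 0.5)
})

test_that("an AF column in percent is divided by 100 and recorded", {
  g <- make_graph(assoc_df(c("GA", "symbol", "101", "entrez")),
                  data.frame(gene_id = "101", chrom = "chr1", start = 1L,
                             end = 1000L, strand = "+"))
  tab <- data.frame(chrom = "chr1", pos = 10L, ref = "A", alt = "G",
                    effect = "E", codon_change = "c", aa_change = "A1B",
                    tumor_dp = 113L, tumor_af = 14.1593, gene = "GA",
                    stringsAsFactors = FALSE)
  f <- tempfile(); write.table(tab, f, sep = "\t", quote = FALSE, row.names = FALSE)
  out <- parse_variants(f, g)
  expect_equal(out$records[[1]]$tumor_af, 0.141593)
  expect_match(paste(out$report$notes, collapse = " "), "percent")
})

test_that("multi-allelic VCF rows split into one record per alternate allele", {
  g <- make_graph(assoc_df(c("GA", "symbol", "101", "entrez")),
                  data.frame(gene_id = "101", chrom = "chr1", start = 1L,
                             end = 1000L, strand = "+"))
  f <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1,length=1000>",
    "##INFO=<ID=EFF,Number=.,Type=String,Description=\"eff\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"d\">",
    "##FORMAT=<ID=AF,Number=A,Type=Float,Description=\"a\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tTUMOR",
    "chr1\t100\t.\tA\tC,G\t50\tPASS\tEFF=NON_SYNONYMOUS_CODING(MODERATE|MISSENSE|aCa/aGa|T1R|100|GA|protein_coding|CODING|tx1|1)\tDP:AF\t80:0.25,0.1"),
    f)
  out <- parse_variants(f, g)
  expect_length(out$records, 2)
  expect_equal(vapply(out$records, function(r) r$alt_allele, ""), c("C", "G"))
  expect_equal(vapply(out$records, function(r) r$tumor_af, 0), c(0.25, 0.1))
})

test_that("Cuffdiff gene parsing respects the significant column and rejects bad rows", {
  pp <- preset_pipeline()
  expect_equal(pp$genes$report$rows_rejected, 0)
  sig <- vapply(pp$genes$records, function(r) r$significant, NA)
  syms <- vapply(pp$genes$records, function(r) r$gene$symbol, "")
  expect_true(all(sig[syms %in% c("KRAS", "TP53")]))
  expect_false(any(sig[!syms %in% c("KRAS", "TP53")]))

  # corrupt rows land in the report, never in records
  lines <- readLines(pp$bundle$gene_diff)
  bad1 <- sub("21.7", "-0.1", lines[2], fixed = TRUE)        # negative FPKM
  bad2 <- sub("5e-05\t0.001", "1.7\t0.001", lines[3], fixed = TRUE)  # p > 1
  f <- tempfile(); writeLines(c(lines[1], bad1, bad2, lines[4]), f)
  out <- parse_cuffdiff_genes(f)
  expect_equal(out$report$rows_read, 3)
  expect_equal(out$report$rows_rejected, 2)
  expect_length(out$records, 1)
})

test_that("a missing Cuffdiff column is a file-level error", {
  f <- tempfile()
  writeLines(c("test_id\tgene_id\tgene", "a\tb\tc"), f)
  expect_error(parse_cuffdiff_genes(f), "lacks columns")
})

test_that("infinite log2 fold changes parse to signed infinities", {
  hdr <- paste("test_id", "gene_id", "gene", "locus", "sample_1", "sample_2",
               "status", "value_1", "value_2", "log2(fold_change)",
               "test_stat", "p_value", "q_value", "significant", sep = "\t")
  rows <- c(paste("t1", "g1", "G1", "c1:1-10", "n", "t", "OK", "0", "5",
                  "inf", "0", "0.01", "0.02", "yes", sep = "\t"),
            paste("t2", "g2", "G2", "c1:1-10", "n", "t", "OK", "5", "0",
                  "-inf", "0", "0.01", "0.02", "no", sep = "\t"),
            paste("t3", "g3", "G3", "c1:1-10", "n", "t", "OK", "1", "2",
                  "1.797693e+308", "0", "0.5", "0.6", "no", sep = "\t"))
  f <- tempfile(); writeLines(c(hdr, rows), f)
  out <- parse_cuffdiff_genes(f)
  l2 <- vapply(out$records, function(r) r$log2_fold_change, 0)
  expect_equal(l2, c(Inf, -Inf, Inf))
})

test_that("isoform parsing flags novel assembly products and rejects empty ids", {
  pp <- preset_pipeline()
  recs <- pp$isoforms$records
  ids <- vapply(recs, function(r) r$transcript_id, "")
  novel <- vapply(recs, function(r) r$novel, NA)
  expect_false(novel[ids == "ENST00000311936"])
  expect_true(novel[ids == "CUFF.19733.1"])
  expect_equal(novel, startsWith(ids, "CUFF."))

  lines <- readLines(pp$bundle$isoform_diff)
  lines[2] <- sub("^[^\t]+", "", lines[2])  # blank the transcript id
  f <- tempfile(); writeLines(lines, f)
  out <- parse_cuffdiff_isoforms(f)
  expect_equal(out$report$rows_rejected, 1)
  expect_match(out$report$rejections$rule, "transcript id")
})

test_that("probe tables parse identically as tab or comma dialect", {
  tabf <- tempfile(); csvf <- tempfile()
  writeLines(c("gene\tprobeID\tvalue", "GENE_A\t201_at\t6.25",
               "GENE_A\t202_at\t7.75", "GENE_B\t300_at\tNaN"), tabf)
  writeLines(c("gene,probeID,value", "GENE_A,201_at,6.25",
               "GENE_A,202_at,7.75", "GENE_B,300_at,NaN"), csvf)
  a <- parse_probe_table(tabf); b <- parse_probe_table(csvf)
  expect_equal(a$records, b$records)
  expect_equal(a$records[[1]]$value, 6.25)
  expect_equal(a$report$rows_rejected, 1)  # NaN fails the finite check
  expect_match(a$report$rejections$rule, "finite")
})

test_that("every parser keeps rows_read == accepted + rejected under fuzzing", {
  pp <- preset_pipeline()
  set.seed(11)
  for (src in c(pp$bundle$gene_diff, pp$bundle$isoform_diff, pp$bundle$probes)) {
    lines <- readLines(src)
    for (trial in 1:5) {
      corrupt <- lines
      n <- length(corrupt)
      for (i in sample(2:n, min(3, n - 1))) {
        corrupt[i] <- switch(sample(3, 1),
          gsub("[0-9]", "x", corrupt[i]),
          paste0(corrupt[i], "\textra\tcolumns"),
          substr(corrupt[i], 1, max(1, nchar(corrupt[i]) %/% 3)))
      }
      f <- tempfile(); writeLines(corrupt, f)
      out <- tryCatch(switch(
        which(c(pp$bundle$gene_diff, pp$bundle$isoform_diff,
                pp$bundle$probes) == src),
        parse_cuffdiff_genes(f), parse_cuffdiff_isoforms(f),
        parse_probe_table(f)), error = function(e) NULL)
      if (is.null(out)) next  # header destroyed: file-level error is allowed
      r <- out$report
      expect_equal(r$rows_read, r$rows_accepted + r$rows_rejected)
      for (rec in out$records) {
        p <- rec$p_value %||% 0.5
        expect_true(p >= 0 && p <= 1)
        if (!is.null(rec$sample1_fpkm))
          expect_true(rec$sample1_fpkm >= 0 && rec$sample2_fpkm >= 0)
        if (!is.null(rec[["value"]])) expect_true(is.finite(rec$value))
      }
    }
  }
})

test_that("generated files round-trip: write, parse, re-serialize, parse again", {
  pp <- preset_pipeline()
  # re-serialize the parsed gene table and re-parse; records must be identical
  recs <- pp$genes$records
  f <- tempfile()
  hdr <- readLines(pp$bundle$gene_diff, n = 1)
  writeLines(readLines(pp$bundle$gene_diff), f)
  again <- parse_cuffdiff_genes(f, pp$graph)
  expect_equal(again$records, recs)
  expect_equal(again$report$rows_rejected, 0)
})
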