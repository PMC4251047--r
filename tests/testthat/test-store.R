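fresh_store <- function() {
  pp <- preset_pipeline()
  st <- store_open(tempfile(fileext = ".rds"))
  store_set_graph(st, pp$bundle$associations, pp$bundle$loci)
  list(store = st, pp = pp)
}

test_that("imports are queued FIFO and processed in enqueue order", {
  x <- fresh_store(); st <- x$store; b <- x$pp$bundle
  j1 <- enqueue_import(st, "P1", "wes", "2014-03-26", b$vcf)
  j2 <- enqueue_import(st, "P1", "rnaseq_gene", "2014-03-26", b$gene_diff)
  j3 <- enqueue_import(st, "P1", "microarray", "2014-03-26", b$probes)
  r1 <- process_next(st); r2 <- process_next(st); r3 <- process_next(st)
  got <- vapply(list(r1, r2, r3), function(r)
    st$studies$modality[st$studies$study_id == r$study_id], "")
  expect_equal(got, c("wes", "rnaseq_gene", "microarray"))
  expect_null(process_next(st))  # empty queue: no-op
})

test_that("randomized enqueue order is always drained FIFO", {
  pp <- preset_pipeline()
  set.seed(31)
  for (trial in 1:5) {
    st <- store_open(NULL)
    store_set_graph(st, pp$bundle$associations, pp$bundle$loci)
    n <- sample(3:6, 1)
    subj <- sprintf("S%02d", sample(100, n))
    for (s in subj)
      enqueue_import(st, s, "microarray", "2020-01-01", pp$bundle$probes)
    processed <- character()
    repeat {
      r <- process_next(st)
      if (is.null(r)) break
      processed <- c(processed,
                     st$studies$subject[st$studies$study_id == r$study_id])
    }
    expect_equal(processed, subj)
  }
})

test_that("a duplicate study key or missing path is refused at enqueue", {
  x <- fresh_store(); st <- x$store; b <- x$pp$bundle
  enqueue_import(st, "P1", "wes", "2014-03-26", b$vcf)
  expect_error(enqueue_import(st, "P1", "wes", "2014-03-26", b$vcf),
               "already registered")
  expect_error(enqueue_import(st, "P1", "wes", "2014-03-27", "/no/such/file"),
               "does not exist")
  # same subject, same modality, new date is a different study
  expect_silent(enqueue_import(st, "P1", "wes", "2014-03-27", b$vcf))
})

test_that("successful import records row counts; corrupt files fail and the queue advances", {
  x <- fresh_store(); st <- x$store; b <- x$pp$bundle
  enqueue_import(st, "P1", "rnaseq_gene", "2014-03-26", b$gene_diff)
  bad <- tempfile(); writeLines(c("not\ta\tcuffdiff", "file\tat\tall"), bad)
  enqueue_import(st, "P1", "rnaseq_isoform", "2014-03-26", bad)
  enqueue_import(st, "P1", "microarray", "2014-03-26", b$probes)
  res <- run_queue(st)
  expect_equal(vapply(res, `[[`, "", "status"),
               c("imported", "failed", "imported"))
  s <- console_summary(st)
  expect_equal(s$row_count[s$modality == "rnaseq_gene"],
               x$pp$genes$report$rows_accepted)
  expect_true(is.na(s$row_count[s$modality == "rnaseq_isoform"]))
  # the failure detail is retained for inspection
  fid <- st$studies$study_id[st$studies$status == "failed"]
  expect_match(st$staging[[as.character(fid)]]$error, "lacks columns")
})

test_that("console summary row counts equal stored dataset record counts", {
  x <- fresh_store(); st <- x$store; b <- x$pp$bundle
  enqueue_import(st, "P2", "wes", "2014-03-26", b$vcf)
  enqueue_import(st, "P1", "microarray", "2014-03-26", b$probes)
  run_queue(st)
  s <- console_summary(st)
  expect_equal(s$subject, c("P1", "P2"))  # deterministic ordering
  for (i in seq_len(nrow(s))) {
    sid <- st$studies$study_id[st$studies$subject == s$subject[i] &
                                 st$studies$modality == s$modality[i]]
    d <- st$datasets[[as.character(sid)]]
    expect_equal(s$row_count[i], sum(lengths(d$keyed)) + length(d$unresolved))
  }
})

test_that("cascade delete removes one study without touching sibling modalities", {
  x <- fresh_store(); st <- x$store; b <- x$pp$bundle
  enqueue_import(st, "P1", "wes", "2014-03-26", b$vcf)
  enqueue_import(st, "P1", "microarray", "2014-03-26", b$probes)
  run_queue(st)
  summ <- cascade_delete(st, "P1", modality = "wes")
  expect_equal(unname(summ["studies"]), 1L)
  s <- console_summary(st)
  expect_equal(s$modality, "microarray")
  expect_equal(store_orphan_scan(st), 0L)
})

test_that("deleting a subject leaves zero orphaned rows anywhere", {
  x <- fresh_store(); st <- x$store; b <- x$pp$bundle
  for (m in list(c("wes", b$vcf), c("rnaseq_gene", b$gene_diff),
                 c("microarray", b$probes)))
    enqueue_import(st, "P1", m[1], "2014-03-26", m[2])
  enqueue_import(st, "P2", "microarray", "2014-03-26", b$probes)
  run_queue(st)
  summ <- cascade_delete(st, "P1")
  expect_equal(unname(summ["studies"]), 3L)
  expect_true(summ["associated_records"] > 0)
  expect_equal(store_orphan_scan(st), 0L)
  expect_equal(console_summary(st)$subject, "P2")
  expect_error(cascade_delete(st, "NOBODY"), "unknown delete target")
})

test_that("the store persists across reopen and its view matches a direct build", {
  x <- fresh_store(); st <- x$store; b <- x$pp$bundle; pp <- x$pp
  for (m in list(c("wes", b$vcf), c("rnaseq_gene", b$gene_diff),
                 c("microarray", b$probes)))
    enqueue_import(st, "JohnDoe", m[1], "2014-03-26", m[2])
  run_queue(st)
  store_create_group(st, "KeyGenes", c("KRAS", "TP53", "NRAS", "MYC", "BRAF"))
  expect_error(store_create_group(st, "KeyGenes", "KRAS"), "already exists")

  st2 <- store_open(st$path)
  tab <- store_view(st2, "JohnDoe", c("wes", "rnaseq_gene", "microarray"),
                    group_name = "KeyGenes")
  direct <- build_view(list(pp$ds$wes, pp$ds$rnaseq_gene, pp$ds$microarray),
                       group = gene_group("KeyGenes",
                                          c("KRAS", "TP53", "NRAS", "MYC",
                                            "BRAF")),
                       groups = st2$groups, graph = pp$graph)
  expect_equal(as.data.frame(tab), as.data.frame(direct))
  expect_error(store_view(st2, "JohnDoe", "rnaseq_isoform"), "no imported")
})

test_that("the CLI wires fixtures, import, view and delete together", {
  dir <- tempfile(); store <- tempfile(fileext = ".rds")
  out <- tempfile(fileext = ".tsv")
  expect_no_error(suppressMessages({
    triomics_main(c("fixtures", "generate", "--preset", "mm-case",
                    "--out", dir))
    triomics_main(c("graph", "--store", store,
                    "--assoc", file.path(dir, "associations.tsv"),
                    "--loci", file.path(dir, "loci.tsv")))
    triomics_main(c("import", "--store", store, "--subject", "JohnDoe",
                    "--modality", "wes", "--date", "2014-03-26",
                    file.path(dir, "variants.vcf")))
    triomics_main(c("import", "--store", store, "--subject", "JohnDoe",
                    "--modality", "microarray", "--date", "2014-03-26",
                    file.path(dir, "probes.tsv")))
    triomics_main(c("run-queue", "--store", store))
    triomics_main(c("groups", "create", "--store", store, "--name", "KG",
                    "--members", "KRAS,TP53"))
    triomics_main(c("view", "--store", store, "--subject", "JohnDoe",
                    "--wes", "--array", "--group", "KG", "--out", out))
  }))
  lines <- readLines(out)
  expect_match(lines[1], "^#blocks:")
  body <- read.delim(text = lines[-1])
  expect_setequal(body$gene_symbol, c("KRAS", "TP53"))
  suppressMessages(triomics_main(c("delete", "--store", store,
                                   "--subject", "JohnDoe")))
  st <- store_open(store)
  expect_equal(nrow(console_summary(st)), 0)
})
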