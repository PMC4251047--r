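## Persistent study store: registered studies keyed by (subject, modality,
## date), a synchronous FIFO import queue, staging (raw parsed records +
## import report) and associated (gene-keyed) tables per study, user gene
## groups, and cascading delete with a referential orphan scan. State lives
## in a single file reloaded/saved around each operation; the queue is
## drained explicitly (process_next / run_queue) rather than by a daemon.

#' Open (or create) a study store
#'
#' @param path State file path, or `NULL` for an in-memory store.
#' @return A `triomics_store` (environment).
#' @export
store_open <- function(path = NULL) {
  store <- new.env(parent = emptyenv())
  store$path <- path
  store$studies <- data.frame(
    study_id = integer(), subject = character(), modality = character(),
    study_date = character(), status = character(), row_count = integer(),
    stringsAsFactors = FALSE)
  store$jobs <- data.frame(
    job_id = integer(), study_id = integer(), paths = character(),
    enqueue_time = integer(), done = logical(), stringsAsFactors = FALSE)
  store$staging <- list()     # study_id -> list(records, report, error)
  store$datasets <- list()    # study_id -> modality_dataset
  store$groups <- list()
  store$graph <- NULL
  store$next_id <- 1L
  store$clock <- 0L
  class(store) <- "triomics_store"
  if (!is.null(path) && file.exists(path)) {
    st <- readRDS(path)
    for (nm in setdiff(names(st), "path")) store[[nm]] <- st[[nm]]
  }
  store
}

store_save <- function(store) {
  if (is.null(store$path)) return(invisible(store))
  st <- as.list.environment(store, all.names = TRUE)
  saveRDS(st[setdiff(names(st), "path")], store$path)
  invisible(store)
}

#' @export
print.triomics_store <- function(x, ...) {
  cat("<triomics_store> ", nrow(x$studies), " studies, ",
      sum(!x$jobs$done), " queued jobs, ", length(x$groups), " groups\n",
      sep = "")
  invisible(x)
}

#' Attach an identifier graph to the store
#'
#' @param store A `triomics_store`.
#' @param association_tables,locus_tables Paths passed to [build_graph()].
#' @return The store, invisibly.
#' @export
store_set_graph <- function(store, association_tables, locus_tables = character()) {
  store$graph <- build_graph(association_tables, locus_tables)
  store_save(store)
}

study_key_exists <- function(store, subject, modality, study_date) {
  any(store$studies$subject == subject & store$studies$modality == modality &
        store$studies$study_date == study_date)
}

#' Register a study and queue its import
#'
#' Registers the `(subject, modality, date)` study — the key must be new —
#' checks that every source path exists, and appends a FIFO import job.
#' The study starts in status `queued`.
#'
#' @param store A `triomics_store`.
#' @param subject Patient / study label.
#' @param modality One of `"wes"`, `"rnaseq_gene"`, `"rnaseq_isoform"`,
#'   `"microarray"`.
#' @param study_date Date label (string).
#' @param paths Source file paths.
#' @return The job id, invisibly.
#' @export
enqueue_import <- function(store, subject, modality, study_date, paths) {
  modality <- match.arg(modality, MODALITIES)
  if (study_key_exists(store, subject, modality, study_date))
    stop("study already registered: ", subject, " / ", modality, " / ",
         study_date)
  missing <- paths[!file.exists(paths)]
  if (length(missing)) stop("source path does not exist: ", missing[1])
  sid <- store$next_id; store$next_id <- store$next_id + 1L
  jid <- store$next_id; store$next_id <- store$next_id + 1L
  store$clock <- store$clock + 1L
  store$studies <- rbind(store$studies, data.frame(
    study_id = sid, subject = subject, modality = modality,
    study_date = study_date, status = "queued", row_count = NA_integer_,
    stringsAsFactors = FALSE))
  store$jobs <- rbind(store$jobs, data.frame(
    job_id = jid, study_id = sid, paths = paste(paths, collapse = ";"),
    enqueue_time = store$clock, done = FALSE, stringsAsFactors = FALSE))
  store_save(store)
  invisible(jid)
}

#' Process the next queued import job
#'
#' Takes the oldest pending job (FIFO by enqueue time, then job id), parses
#' its files through the matching ingest parser into the staging table, then
#' associates records onto gene identities. On success the study becomes
#' `imported` with `row_count` set to the accepted rows; on a parse failure
#' it becomes `failed` with the report/error retained in staging for
#' inspection, and the queue advances either way.
#'
#' @param store A `triomics_store`.
#' @return `NULL` when the queue is empty (no-op), otherwise a list with the
#'   processed `study_id`, `status` and `report`.
#' @export
process_next <- function(store) {
  pending <- store$jobs[!store$jobs$done, , drop = FALSE]
  if (nrow(pending) == 0L) return(NULL)
  pending <- pending[order(pending$enqueue_time, pending$job_id), , drop = FALSE]
  job <- pending[1L, ]
  store$jobs$done[store$jobs$job_id == job$job_id] <- TRUE
  srow <- which(store$studies$study_id == job$study_id)
  store$studies$status[srow] <- "importing"
  modality <- store$studies$modality[srow]
  paths <- strsplit(job$paths, ";", fixed = TRUE)[[1]]

  res <- tryCatch({
    parsed <- switch(modality,
      wes = parse_variants(paths[1], store$graph),
      rnaseq_gene = parse_cuffdiff_genes(paths[1], store$graph),
      rnaseq_isoform = parse_cuffdiff_isoforms(paths[1], store$graph),
      microarray = parse_probe_table(paths[1]))
    if (length(paths) > 1L) for (pp in paths[-1]) {
      more <- switch(modality,
        wes = parse_variants(pp, store$graph),
        rnaseq_gene = parse_cuffdiff_genes(pp, store$graph),
        rnaseq_isoform = parse_cuffdiff_isoforms(pp, store$graph),
        microarray = parse_probe_table(pp))
      parsed$records <- c(parsed$records, more$records)
      parsed$report <- import_report(
        parsed$report$rows_read + more$report$rows_read,
        parsed$report$rows_accepted + more$report$rows_accepted,
        rbind(parsed$report$rejections, more$report$rejections),
        c(parsed$report$notes, more$report$notes))
    }
    parsed
  }, error = function(e) e)

  key <- as.character(job$study_id)
  if (inherits(res, "error")) {
    store$studies$status[srow] <- "failed"
    store$staging[[key]] <- list(records = list(), report = NULL,
                                 error = conditionMessage(res))
    out <- list(study_id = job$study_id, status = "failed",
                report = NULL, error = conditionMessage(res))
  } else {
    store$staging[[key]] <- list(records = res$records, report = res$report,
                                 error = NULL)
    store$datasets[[key]] <- associate(res$records, store$graph, modality,
                                       store$studies$study_date[srow])
    store$studies$status[srow] <- "imported"
    store$studies$row_count[srow] <- res$report$rows_accepted
    out <- list(study_id = job$study_id, status = "imported",
                report = res$report)
  }
  store_save(store)
  out
}

#' Drain the import queue
#'
#' @param store A `triomics_store`.
#' @return List of per-job outcomes (possibly empty).
#' @export
run_queue <- function(store) {
  out <- list()
  repeat {
    r <- process_next(store)
    if (is.null(r)) break
    out[[length(out) + 1L]] <- r
  }
  out
}

#' Cascading delete of a study or a whole subject
#'
#' Removes every row belonging to the target from the studies, jobs,
#' staging and associated tables; afterwards a full referential scan finds
#' zero rows keyed to the deleted study ids. Other modalities/dates of the
#' same subject are untouched when a specific study is targeted.
#'
#' @param store A `triomics_store`.
#' @param subject Subject label.
#' @param modality,study_date Optional: restrict to one study.
#' @return Named integer summary of rows removed per table.
#' @export
cascade_delete <- function(store, subject, modality = NULL, study_date = NULL) {
  sel <- store$studies$subject == subject
  if (!is.null(modality)) sel <- sel & store$studies$modality == modality
  if (!is.null(study_date)) sel <- sel & store$studies$study_date == study_date
  if (!any(sel)) stop("unknown delete target: ", subject,
                      if (!is.null(modality)) paste0(" / ", modality) else "")
  ids <- store$studies$study_id[sel]
  keys <- as.character(ids)
  summary <- c(
    studies = sum(sel),
    jobs = sum(store$jobs$study_id %in% ids),
    staging_records = sum(vapply(store$staging[intersect(keys, names(store$staging))],
                                 function(s) length(s$records), integer(1))),
    associated_records = sum(vapply(store$datasets[intersect(keys, names(store$datasets))],
                                    function(d) sum(lengths(d$keyed)) +
                                      length(d$unresolved), integer(1))))
  store$studies <- store$studies[!sel, , drop = FALSE]
  store$jobs <- store$jobs[!store$jobs$study_id %in% ids, , drop = FALSE]
  store$staging <- store$staging[setdiff(names(store$staging), keys)]
  store$datasets <- store$datasets[setdiff(names(store$datasets), keys)]
  store_save(store)
  summary
}

#' Scan the store for rows referencing missing studies
#'
#' Referential integrity check used after deletes: counts rows in every
#' table whose study id is no longer registered.
#'
#' @param store A `triomics_store`.
#' @return Integer count of orphaned rows (0 when the store is consistent).
#' @export
store_orphan_scan <- function(store) {
  ids <- store$studies$study_id
  orphans <- sum(!store$jobs$study_id %in% ids) +
    sum(!as.integer(names(store$staging)) %in% ids) +
    sum(!as.integer(names(store$datasets)) %in% ids)
  as.integer(orphans)
}

#' Aggregate per-study console listing
#'
#' One row per study — subject, modality, date, status, row count — in
#' deterministic order (subject, then date, then modality).
#'
#' @param store A `triomics_store`.
#' @return Data frame.
#' @export
console_summary <- function(store) {
  s <- store$studies
  s <- s[order(s$subject, s$study_date, s$modality),
         c("subject", "modality", "study_date", "status", "row_count"),
         drop = FALSE]
  rownames(s) <- NULL
  s
}

#' Create a gene group in the store
#'
#' @param store A `triomics_store`.
#' @param name Group name (must be new for the owner).
#' @param members Member identifiers.
#' @param owner Owner label.
#' @return The store, invisibly.
#' @export
store_create_group <- function(store, name, members, owner = "default") {
  for (g in store$groups)
    if (g$name == name && g$owner == owner)
      stop("group already exists: ", name)
  store$groups <- c(store$groups, list(gene_group(name, members, owner)))
  store_save(store)
}

#' Build an integrated view from imported studies
#'
#' Selects, for one subject, the most recently dated imported study per
#' requested modality and delegates to [build_view()].
#'
#' @param store A `triomics_store`.
#' @param subject Subject label.
#' @param modalities Character vector of modalities to include.
#' @param mode `"minimal"` or `"maximal"`.
#' @param group_name Optional name of a stored group to filter by.
#' @return An `integrated_table`.
#' @export
store_view <- function(store, subject, modalities, mode = "minimal",
                       group_name = NULL) {
  datasets <- list()
  for (m in modalities) {
    cand <- store$studies[store$studies$subject == subject &
                            store$studies$modality == m &
                            store$studies$status == "imported", , drop = FALSE]
    if (nrow(cand) == 0L)
      stop("no imported ", m, " study for subject ", subject)
    cand <- cand[order(cand$study_date, decreasing = TRUE), , drop = FALSE]
    datasets[[length(datasets) + 1L]] <-
      store$datasets[[as.character(cand$study_id[1])]]
  }
  group <- NULL
  if (!is.null(group_name)) {
    for (g in store$groups) if (g$name == group_name) group <- g
    if (is.null(group)) stop("unknown group: ", group_name)
  }
  build_view(datasets, mode = mode, group = group, groups = store$groups,
             graph = store$graph)
}
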