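## Set-based association of modality records onto resolved gene identities,
## and construction of the ordered, column-blocked integrated views
## (single, pairwise, or the triple WES + RNA-seq + microarray view).

MODALITIES <- c("wes", "rnaseq_gene", "rnaseq_isoform", "microarray")

BLOCK_COLORS <- c(core = "grey", wes = "green", rna = "light red",
                  array = "blue", member = "grey")

#' Create a user-defined gene group
#'
#' Named gene sets drive search strategies: the integrated view can be
#' filtered to a group, and the Member List column reports memberships.
#' Members may be expressed in any namespace (symbols, Entrez ids, ...).
#'
#' @param name Group name (unique per owner).
#' @param members Non-empty character vector of gene identifiers.
#' @param owner Owner label.
#' @return A `gene_group`.
#' @export
gene_group <- function(name, members, owner = "default") {
  members <- unique(trimws(as.character(members)))
  stopifnot(nzchar(name), length(members) > 0L, all(nzchar(members)))
  structure(list(name = name, owner = owner, members = members),
            class = "gene_group")
}

## Resolve a group member given in any namespace to a canonical key.
member_key <- function(member, graph) {
  id <- resolve_row_identity(gene_id = member, graph = graph)
  if (id$unresolved) {
    alt <- tryCatch(resolve_row_identity(symbol = member, graph = graph),
                    error = function(e) id)
    if (!alt$unresolved) id <- alt
  }
  canonical_key(id)
}

group_keys <- function(group, graph) {
  vapply(group$members, member_key, character(1), graph = graph, USE.NAMES = FALSE)
}

#' Associate parsed records with resolved gene identities
#'
#' Each record is keyed by its resolved identity's canonical key; records
#' resolving to the same gene are grouped under one key. Records whose
#' identity could not be resolved through the graph land in the unresolved
#' bucket — preserved, never dropped — so every input record appears exactly
#' once, either keyed or in the bucket.
#'
#' @param records List of parsed records (`variant_record`,
#'   `expression_diff_record`, `isoform_record` or `probe_measurement`).
#' @param graph An `id_graph`.
#' @param modality One of `"wes"`, `"rnaseq_gene"`, `"rnaseq_isoform"`,
#'   `"microarray"`.
#' @param study_date Date label for the study (string).
#' @return A `modality_dataset`.
#' @export
associate <- function(records, graph, modality, study_date = NA_character_) {
  modality <- match.arg(modality, MODALITIES)
  keyed <- list(); identities <- list(); unresolved <- list()
  for (rec in records) {
    gid <- if (!is.null(rec[["gene"]])) rec[["gene"]]
           else resolve_row_identity(symbol = rec$gene_symbol, graph = graph)
    if (gid$unresolved) {
      unresolved[[length(unresolved) + 1L]] <- rec
      next
    }
    key <- canonical_key(gid)
    if (is.null(keyed[[key]])) { keyed[[key]] <- list(); identities[[key]] <- gid }
    keyed[[key]][[length(keyed[[key]]) + 1L]] <- rec
  }
  structure(list(modality = modality, study_date = study_date, keyed = keyed,
                 identities = identities, unresolved = unresolved),
            class = "modality_dataset")
}

#' @export
print.modality_dataset <- function(x, ...) {
  cat("<modality_dataset> ", x$modality, ": ", length(x$identities), " genes, ",
      sum(lengths(x$keyed)), " records (", length(x$unresolved),
      " unresolved)\n", sep = "")
  invisible(x)
}

row_sort_order <- function(identities) {
  chrom <- vapply(identities, function(g)
    if (!is.null(g$locus)) g$locus$chrom else "~", character(1))
  start <- vapply(identities, function(g)
    if (!is.null(g$locus)) g$locus$start else .Machine$integer.max, numeric(1))
  sym <- vapply(identities, function(g)
    if (!is.na(g$symbol)) g$symbol else "~", character(1))
  order(chrom, start, sym)
}

wes_cells <- function(v, mode) {
  cells <- list(wes.effect = v$effect, wes.codon_change = v$codon_change,
                wes.aa_change = v$aa_change, wes.tumor_dp = v$tumor_depth,
                wes.tumor_af = v$tumor_af)
  if (mode == "maximal")
    cells <- c(cells, list(wes.chrom = v$locus$chrom,
                           wes.pos = v$locus$start + 1L,
                           wes.ref = v$ref_allele, wes.alt = v$alt_allele,
                           wes.normal_dp = v$normal_depth,
                           wes.normal_af = v$normal_af))
  cells
}

rna_gene_cells <- function(r, mode) {
  cells <- list(rna.sample1_fpkm = r$sample1_fpkm,
                rna.sample2_fpkm = r$sample2_fpkm, rna.p_value = r$p_value)
  if (mode == "maximal")
    cells <- c(cells, list(rna.log2_fold_change = r$log2_fold_change,
                           rna.q_value = r$q_value,
                           rna.significant = r$significant))
  cells
}

rna_iso_cells <- function(r, mode) {
  cells <- list(rna.transcript_id = r$transcript_id,
                rna.iso_sample1_fpkm = r$sample1_fpkm,
                rna.iso_sample2_fpkm = r$sample2_fpkm,
                rna.iso_p_value = r$p_value)
  if (mode == "maximal")
    cells <- c(cells, list(rna.iso_q_value = r$q_value,
                           rna.iso_significant = r$significant,
                           rna.novel = r$novel))
  cells
}

array_cells <- function(probes, mode) {
  cells <- list(
    array.affy_probes = paste(vapply(probes, `[[`, "", "probe_id"),
                              collapse = ","),
    array.avg_probe_value = average_probe_values(probes))
  if (mode == "maximal") cells <- c(cells, list(array.n_probes = length(probes)))
  cells
}

na_cells <- function(template) {
  out <- lapply(template, function(x) NA)
  out
}

#' Build an integrated per-gene view
#'
#' Performs a full outer join over gene keys: a gene present in any selected
#' dataset yields a row, with empty cells for modalities where it is absent.
#' Column blocks always follow the fixed order core (Entrez ID, Gene
#' Symbol, Gene Name), WES, RNA-seq, microarray, Member List, regardless of
#' which studies are loaded; the block colors (grey / green / light red /
#' blue / grey) travel as metadata. When an isoform-level dataset is
#' included the view emits one row per isoform, repeating the gene-level
#' cells on each row. `minimal` mode restricts each block to its headline
#' columns; `maximal` exposes everything parsed.
#'
#' @param datasets List of 1-3 `modality_dataset`s (at most one per modality).
#' @param mode `"minimal"` or `"maximal"`.
#' @param group Optional `gene_group`: restrict rows to member genes.
#' @param groups List of all `gene_group`s, used to fill the Member List
#'   column.
#' @param graph An `id_graph` (needed to match group members given in other
#'   namespaces).
#' @return An `integrated_table` (a data frame with block metadata in
#'   attributes).
#' @export
build_view <- function(datasets, mode = c("minimal", "maximal"), group = NULL,
                       groups = list(), graph = NULL) {
  mode <- match.arg(mode)
  if (inherits(datasets, "modality_dataset")) datasets <- list(datasets)
  mods <- vapply(datasets, `[[`, "", "modality")
  if (anyDuplicated(mods))
    stop("two datasets share modality: ", mods[duplicated(mods)][1])
  ds <- stats::setNames(datasets, mods)

  keys <- unique(unlist(lapply(datasets, function(d) names(d$identities))))
  identities <- list()
  for (d in datasets) for (k in names(d$identities))
    if (is.null(identities[[k]])) identities[[k]] <- d$identities[[k]]

  if (!is.null(group)) {
    gk <- if (!is.null(graph)) group_keys(group, graph) else group$members
    keys <- keys[keys %in% gk]
  }
  identities <- identities[keys]
  keys <- keys[row_sort_order(identities)]

  tmpl_wes <- wes_cells(list(locus = genomic_locus("x", 0, 1),
                             ref_allele = "A", alt_allele = "C",
                             effect = NA, codon_change = NA, aa_change = NA,
                             tumor_depth = 0L, tumor_af = 0,
                             normal_depth = NA_integer_,
                             normal_af = NA_real_), mode = mode)
  tmpl_rna <- rna_gene_cells(list(sample1_fpkm = 0, sample2_fpkm = 0,
                                  p_value = 0, q_value = 0,
                                  log2_fold_change = 0, significant = FALSE),
                             mode)
  tmpl_iso <- rna_iso_cells(list(transcript_id = "", sample1_fpkm = 0,
                                 sample2_fpkm = 0, p_value = 0, q_value = 0,
                                 significant = FALSE, novel = FALSE), mode)
  tmpl_arr <- array_cells(list(structure(list(probe_id = "", gene_symbol = "",
                                              value = 0),
                                         class = "probe_measurement")), mode)

  rows <- list()
  for (k in keys) {
    g <- identities[[k]]
    core <- list(entrez_id = g$entrez_id, gene_symbol = g$symbol,
                 gene_name = g$gene_name)
    vars <- if (!is.null(ds$wes)) ds$wes$keyed[[k]] else NULL
    rnag <- if (!is.null(ds$rnaseq_gene)) ds$rnaseq_gene$keyed[[k]] else NULL
    isos <- if (!is.null(ds$rnaseq_isoform)) ds$rnaseq_isoform$keyed[[k]] else NULL
    prbs <- if (!is.null(ds$microarray)) ds$microarray$keyed[[k]] else NULL

    wes_list <- if (!is.null(ds$wes)) {
      if (length(vars)) lapply(vars, wes_cells, mode = mode)
      else list(na_cells(tmpl_wes))
    } else list(NULL)
    iso_list <- if (!is.null(ds$rnaseq_isoform)) {
      if (length(isos)) lapply(isos, rna_iso_cells, mode = mode)
      else list(na_cells(tmpl_iso))
    } else list(NULL)
    rna_cell <- if (!is.null(ds$rnaseq_gene)) {
      if (length(rnag)) rna_gene_cells(rnag[[1]], mode) else na_cells(tmpl_rna)
    } else NULL
    arr_cell <- if (!is.null(ds$microarray)) {
      if (length(prbs)) array_cells(prbs, mode) else na_cells(tmpl_arr)
    } else NULL
    member <- list(member_list = paste(member_list(g, groups, graph),
                                       collapse = ","))

    for (w in wes_list) for (iso in iso_list)
      rows[[length(rows) + 1L]] <- c(core, w, rna_cell, iso, arr_cell, member)
  }

  cols <- c(list(entrez_id = NA_integer_, gene_symbol = NA_character_,
                 gene_name = NA_character_),
            if (!is.null(ds$wes)) tmpl_wes,
            if (!is.null(ds$rnaseq_gene)) tmpl_rna,
            if (!is.null(ds$rnaseq_isoform)) tmpl_iso,
            if (!is.null(ds$microarray)) tmpl_arr,
            list(member_list = NA_character_))
  tab <- if (length(rows)) {
    do.call(rbind, lapply(rows, function(r)
      as.data.frame(r, stringsAsFactors = FALSE, check.names = FALSE)))
  } else {
    as.data.frame(cols, check.names = FALSE)[0, , drop = FALSE]
  }

  blocks <- data.frame(
    block = c("core",
              if (!is.null(ds$wes)) "wes",
              if (!is.null(ds$rnaseq_gene) || !is.null(ds$rnaseq_isoform)) "rna",
              if (!is.null(ds$microarray)) "array", "member"),
    stringsAsFactors = FALSE)
  blocks$color <- BLOCK_COLORS[blocks$block]

  unresolved <- stats::setNames(
    vapply(datasets, function(d) length(d$unresolved), integer(1)), mods)
  unresolved <- unresolved[order(names(unresolved))]

  structure(tab, class = c("integrated_table", "data.frame"),
            blocks = blocks, view_mode = mode, unresolved = unresolved)
}

#' Filter an integrated table by a gene group
#'
#' Keeps rows whose gene matches any group member under any of its
#' identifiers; ordering is preserved and the operation is idempotent.
#'
#' @param table An `integrated_table`.
#' @param group A `gene_group`.
#' @param graph Optional `id_graph` for cross-namespace member matching.
#' @return The filtered `integrated_table`.
#' @export
filter_by_group <- function(table, group, graph = NULL) {
  stopifnot(inherits(table, "integrated_table"))
  members <- group$members
  syms <- ids <- toupper(members)
  if (!is.null(graph)) {
    extra <- unlist(lapply(members, function(m) {
      id <- resolve_row_identity(gene_id = m, graph = graph)
      if (id$unresolved)
        id <- tryCatch(resolve_row_identity(symbol = m, graph = graph),
                       error = function(e) id)
      c(id$entrez_id, id$symbol)
    }))
    syms <- unique(c(syms, toupper(stats::na.omit(as.character(extra)))))
  }
  keep <- toupper(as.character(table$gene_symbol)) %in% syms |
    as.character(table$entrez_id) %in% syms
  out <- table[which(keep), , drop = FALSE]
  attributes(out)$blocks <- attr(table, "blocks")
  attributes(out)$view_mode <- attr(table, "view_mode")
  attributes(out)$unresolved <- attr(table, "unresolved")
  class(out) <- class(table)
  out
}

#' Groups a gene belongs to
#'
#' @param gene A `gene_identity`.
#' @param groups List of `gene_group`s.
#' @param graph Optional `id_graph`: membership matches under any of the
#'   gene's identifiers (a group listing the Entrez id still matches a table
#'   row keyed by symbol).
#' @return Sorted character vector of group names (possibly empty).
#' @export
member_list <- function(gene, groups, graph = NULL) {
  if (length(groups) == 0L) return(character(0))
  mine <- c(as.character(gene$entrez_id), gene$ensembl_gene_id, gene$symbol,
            gene$genbank_accessions, gene$affy_probesets)
  mine <- toupper(stats::na.omit(mine))
  hits <- vapply(groups, function(g) {
    mem <- toupper(g$members)
    if (any(mem %in% mine)) return(TRUE)
    if (!is.null(graph)) {
      keys <- group_keys(g, graph)
      return(canonical_key(gene) %in% keys)
    }
    FALSE
  }, logical(1))
  sort(vapply(groups[hits], `[[`, "", "name"))
}

#' @export
print.integrated_table <- function(x, ...) {
  blocks <- attr(x, "blocks")
  cat("<integrated_table> ", nrow(x), " rows, mode=", attr(x, "view_mode"),
      ", blocks: ", paste(blocks$block, collapse = " | "), "\n", sep = "")
  print.data.frame(utils::head(as.data.frame(x), 10))
  invisible(x)
}

#' Export an integrated table as TSV
#'
#' Writes a sidecar header line `#blocks: block=color;...` carrying the
#' column-block color metadata, then the table.
#'
#' @param table An `integrated_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_integrated_tsv <- function(table, path) {
  blocks <- attr(table, "blocks")
  hdr <- paste0("#blocks: ",
                paste(blocks$block, blocks$color, sep = "=", collapse = ";"))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(as.data.frame(table), con, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Export an integrated table as JSON
#'
#' @param table An `integrated_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_integrated_json <- function(table, path) {
  obj <- list(blocks = attr(table, "blocks"),
              view_mode = attr(table, "view_mode"),
              rows = as.data.frame(table))
  jsonlite::write_json(obj, path, dataframe = "rows", auto_unbox = TRUE,
                       na = "null", digits = NA)
  invisible(path)
}
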