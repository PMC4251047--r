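## The identifier "switching center": an undirected association graph over
## (identifier, namespace) nodes plus an interval index from genomic loci to
## gene nodes. Conversion between namespaces is reachability in the graph
## (direct = one edge, indirect = any path); locus lookups go through the
## interval index instead.

SEP <- "\x1f"  # vertex key separator; never appears in identifiers

node_key <- function(id, ns) paste(ns, id, sep = SEP)

norm_id <- function(id, ns) {
  id <- trimws(as.character(id))
  if (ns == "symbol") toupper(id) else id
}

#' Build the identifier association graph
#'
#' Reads association tables (TSV, header `id_a ns_a id_b ns_b`) and locus
#' tables (TSV, header `gene_id chrom start end strand` with an optional
#' `name` column giving the gene's descriptive name; coordinates 1-based
#' inclusive as displayed). Association rows whose `ns_b` is `locus` carry a
#' `"chr:start-end"` string in `id_b` and attach a locus to the `id_a` gene
#' node. Malformed rows (wrong column count, unknown namespace, bad
#' coordinates) are rejected row-by-row and recorded in the attached import
#' report; duplicate association rows collapse to a single edge.
#'
#' @param association_tables Character vector of association TSV paths.
#' @param locus_tables Character vector of locus TSV paths (optional).
#' @return An `id_graph` with components `graph` (igraph), `loci`
#'   (data.frame), an interval index, and `report` (an [import_report]).
#' @export
build_graph <- function(association_tables = character(), locus_tables = character()) {
  edges <- list(); loci <- list(); rej <- list(); nread <- 0L
  ns_ok <- namespaces()

  add_rej <- function(file, line, rule) {
    rej[[length(rej) + 1L]] <<- data.frame(
      file = file, line = line, rule = rule, stringsAsFactors = FALSE)
  }
  add_locus <- function(gene_id, ns, loc, name = NA_character_) {
    loci[[length(loci) + 1L]] <<- data.frame(
      gene_id = gene_id, ns = ns, chrom = loc$chrom, start = loc$start,
      end = loc$end, strand = loc$strand, gene_name = name,
      stringsAsFactors = FALSE)
  }

  for (f in association_tables) {
    lines <- readLines(f)
    if (length(lines) == 0L) next
    for (i in seq_along(lines)[-1]) {           # skip header
      nread <- nread + 1L
      if (!nzchar(trimws(lines[i]))) next
      parts <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
      if (length(parts) != 4L) { add_rej(f, i, "wrong column count"); next }
      ns_a <- trimws(parts[2]); ns_b <- trimws(parts[4])
      if (!ns_a %in% setdiff(ns_ok, "locus") || !ns_b %in% ns_ok) {
        add_rej(f, i, "unknown namespace"); next
      }
      id_a <- norm_id(parts[1], ns_a)
      if (!nzchar(id_a) || !nzchar(trimws(parts[3]))) {
        add_rej(f, i, "empty identifier"); next
      }
      if (ns_b == "locus") {
        loc <- tryCatch(locus_from_string(trimws(parts[3])), error = function(e) NULL)
        if (is.null(loc)) { add_rej(f, i, "malformed locus"); next }
        add_locus(id_a, ns_a, loc)
      } else {
        id_b <- norm_id(parts[3], ns_b)
        a <- node_key(id_a, ns_a); b <- node_key(id_b, ns_b)
        if (a == b) { add_rej(f, i, "self loop"); next }
        edges[[length(edges) + 1L]] <- c(a, b)
      }
    }
  }

  for (f in locus_tables) {
    tab <- utils::read.delim(f, stringsAsFactors = FALSE, check.names = FALSE)
    need <- c("gene_id", "chrom", "start", "end", "strand")
    if (!all(need %in% names(tab)))
      stop("locus table ", f, " lacks columns: ",
           paste(setdiff(need, names(tab)), collapse = ", "))
    for (i in seq_len(nrow(tab))) {
      nread <- nread + 1L
      loc <- tryCatch(
        genomic_locus(tab$chrom[i], as.integer(tab$start[i]) - 1L,
                      as.integer(tab$end[i]),
                      if (tab$strand[i] %in% c("+", "-")) tab$strand[i] else "*"),
        error = function(e) NULL)
      if (is.null(loc)) { add_rej(f, i + 1L, "bad coordinates"); next }
      ns <- detect_namespace(tab$gene_id[i])
      nm <- if ("name" %in% names(tab)) as.character(tab$name[i]) else NA_character_
      add_locus(norm_id(tab$gene_id[i], ns), ns, loc, nm)
    }
  }

  edf <- if (length(edges)) unique(do.call(rbind, edges)) else
    matrix(character(), ncol = 2)
  g <- igraph::graph_from_data_frame(
    data.frame(from = edf[, 1], to = edf[, 2], stringsAsFactors = FALSE),
    directed = FALSE)
  g <- igraph::simplify(g)

  ldf <- if (length(loci)) do.call(rbind, loci) else
    data.frame(gene_id = character(), ns = character(), chrom = character(),
               start = integer(), end = integer(), strand = character(),
               gene_name = character(), stringsAsFactors = FALSE)
  ldf <- ldf[!duplicated(ldf[c("gene_id", "ns", "chrom", "start", "end")]), , drop = FALSE]
  rownames(ldf) <- NULL
  # make sure every locus-bearing gene is a vertex even if it has no edges
  miss <- setdiff(node_key(ldf$gene_id, ldf$ns), igraph::V(g)$name)
  if (length(miss)) g <- igraph::add_vertices(g, length(miss), name = miss)

  index <- GenomicRanges::GRanges(
    seqnames = ldf$chrom,
    ranges = IRanges::IRanges(start = ldf$start + 1L, end = pmax(ldf$end, ldf$start + 1L)))

  rejdf <- if (length(rej)) do.call(rbind, rej) else
    data.frame(file = character(), line = integer(), rule = character(),
               stringsAsFactors = FALSE)
  rep <- import_report(rows_read = nread,
                       rows_accepted = nread - nrow(rejdf),
                       rejections = rejdf)
  structure(list(graph = g, loci = ldf, index = index, report = rep),
            class = "id_graph")
}

#' @export
print.id_graph <- function(x, ...) {
  cat("<id_graph> ", igraph::vcount(x$graph), " identifiers, ",
      igraph::ecount(x$graph), " associations, ",
      nrow(x$loci), " loci\n", sep = "")
  invisible(x)
}

#' Guess the namespace of a bare gene identifier
#'
#' Generic three-column inputs give "a Gene ID" without saying which kind;
#' all-digit ids are Entrez, `ENSG`/`ENST` prefixes are Ensembl, anything
#' else is treated as a GenBank accession.
#'
#' @param id Identifier string.
#' @return A namespace name.
#' @export
detect_namespace <- function(id) {
  id <- trimws(as.character(id))
  if (grepl("^[0-9]+$", id)) return("entrez")
  if (grepl("^ENSG", id)) return("ensembl_gene")
  if (grepl("^ENST", id)) return("ensembl_transcript")
  "genbank"
}

#' Convert an identifier between namespaces
#'
#' Returns every identifier of the target namespace reachable from
#' `(id, src)` through the association graph, whether directly (one edge)
#' or indirectly (any path). One-to-many conversions return the full set;
#' an unknown source id yields an empty set.
#'
#' @param id Identifier to convert.
#' @param src,dst Source and target namespaces (see [namespaces()]); `src`
#'   may not be `locus` — use [map_locus_to_genes()] for coordinate lookups.
#' @param graph An `id_graph` from [build_graph()].
#' @return Character vector (sorted, possibly empty) of target identifiers.
#' @export
convert_id <- function(id, src, dst, graph) {
  stopifnot(inherits(graph, "id_graph"))
  if (!src %in% setdiff(namespaces(), "locus"))
    stop("unknown or unsupported source namespace: ", src)
  if (!dst %in% setdiff(namespaces(), "locus"))
    stop("unknown or unsupported target namespace: ", dst)
  key <- node_key(norm_id(id, src), src)
  if (!key %in% igraph::V(graph$graph)$name) return(character(0))
  comp <- igraph::subcomponent(graph$graph, key)$name
  hits <- comp[startsWith(comp, paste0(dst, SEP))]
  sort(substring(hits, nchar(dst) + 2L))
}

#' Find genes overlapping a genomic locus
#'
#' Overlap uses the internal half-open convention: a query starting at a
#' gene's (exclusive) end does not overlap it. Strand is ignored.
#'
#' @param locus A `genomic_locus` query.
#' @param graph An `id_graph`.
#' @return List of `gene_identity` objects (possibly empty), ordered by the
#'   indexed gene position.
#' @export
map_locus_to_genes <- function(locus, graph) {
  stopifnot(inherits(locus, "genomic_locus"), inherits(graph, "id_graph"))
  if (nrow(graph$loci) == 0L || !locus$chrom %in% graph$loci$chrom) return(list())
  if (locus$end <= locus$start) return(list())
  q <- GenomicRanges::GRanges(locus$chrom,
                              IRanges::IRanges(locus$start + 1L, locus$end))
  hits <- S4Vectors::subjectHits(
    GenomicRanges::findOverlaps(q, graph$index, ignore.strand = TRUE))
  hits <- sort(unique(hits))
  lapply(hits, function(i)
    gene_identity_from_node(graph$loci$gene_id[i], graph$loci$ns[i], graph))
}

## Collect every identifier reachable from one node into a gene_identity.
gene_identity_from_node <- function(id, ns, graph) {
  key <- node_key(norm_id(id, ns), ns)
  comp <- if (key %in% igraph::V(graph$graph)$name)
    igraph::subcomponent(graph$graph, key)$name else key
  split_ns <- sub(paste0(SEP, ".*$"), "", comp)
  split_id <- sub(paste0("^[^", SEP, "]*", SEP), "", comp)
  pick1 <- function(nsname) {
    v <- sort(split_id[split_ns == nsname])
    if (length(v)) v[[1]] else NA_character_
  }
  loci <- graph$loci
  lrow <- which(node_key(loci$gene_id, loci$ns) %in% comp)
  loc <- if (length(lrow)) {
    i <- lrow[[1]]
    genomic_locus(loci$chrom[i], loci$start[i], loci$end[i], loci$strand[i])
  } else NULL
  nm <- if (length(lrow)) {
    nms <- stats::na.omit(loci$gene_name[lrow])
    if (length(nms)) nms[[1]] else NA_character_
  } else NA_character_
  entrez <- pick1("entrez")
  gene_identity(
    entrez_id = if (is.na(entrez)) NA_integer_ else as.integer(entrez),
    ensembl_gene_id = pick1("ensembl_gene"),
    symbol = pick1("symbol"),
    gene_name = nm,
    genbank_accessions = sort(split_id[split_ns == "genbank"]),
    affy_probesets = sort(split_id[split_ns == "affy_probeset"]),
    ensembl_transcripts = sort(split_id[split_ns == "ensembl_transcript"]),
    locus = loc,
    unresolved = FALSE)
}

#' Construct a gene identity
#'
#' A resolved (or stub) gene carrying every namespace identifier reachable
#' in the association graph. At least one identifier field must be present.
#'
#' @param entrez_id Integer or `NA`.
#' @param ensembl_gene_id,symbol,gene_name Character or `NA`.
#' @param genbank_accessions,affy_probesets,ensembl_transcripts Character
#'   vectors (possibly empty).
#' @param locus Optional `genomic_locus`.
#' @param unresolved `TRUE` for stub identities the graph could not resolve.
#' @return A `gene_identity` object.
#' @export
gene_identity <- function(entrez_id = NA_integer_, ensembl_gene_id = NA_character_,
                          symbol = NA_character_, gene_name = NA_character_,
                          genbank_accessions = character(),
                          affy_probesets = character(),
                          ensembl_transcripts = character(),
                          locus = NULL, unresolved = FALSE) {
  has_any <- !is.na(entrez_id) || !is.na(ensembl_gene_id) || !is.na(symbol) ||
    length(genbank_accessions) > 0L || length(affy_probesets) > 0L ||
    length(ensembl_transcripts) > 0L || !is.null(locus)
  if (!has_any) stop("gene_identity needs at least one identifier")
  structure(list(entrez_id = as.integer(entrez_id),
                 ensembl_gene_id = as.character(ensembl_gene_id),
                 symbol = if (is.na(symbol)) NA_character_ else toupper(symbol),
                 gene_name = as.character(gene_name),
                 genbank_accessions = as.character(genbank_accessions),
                 affy_probesets = as.character(affy_probesets),
                 ensembl_transcripts = as.character(ensembl_transcripts),
                 locus = locus, unresolved = isTRUE(unresolved)),
            class = "gene_identity")
}

#' @export
print.gene_identity <- function(x, ...) {
  cat("<gene> ", if (!is.na(x$symbol)) x$symbol else "?",
      " entrez=", x$entrez_id,
      if (!is.null(x$locus)) paste0(" ", locus_to_string(x$locus)) else "",
      if (x$unresolved) " [unresolved]" else "", "\n", sep = "")
  invisible(x)
}

#' Canonical join key for a gene identity
#'
#' Entrez id when present, else Ensembl gene id, else upper-cased symbol,
#' else the locus string — deterministic and Entrez-first, matching the
#' integrated table's leading column.
#'
#' @param identity A `gene_identity`.
#' @return Character scalar key, namespace-prefixed.
#' @export
canonical_key <- function(identity) {
  stopifnot(inherits(identity, "gene_identity"))
  if (!is.na(identity$entrez_id)) return(paste0("entrez:", identity$entrez_id))
  if (!is.na(identity$ensembl_gene_id) && nzchar(identity$ensembl_gene_id) &&
      identity$ensembl_gene_id != "NA")
    return(paste0("ensembl:", identity$ensembl_gene_id))
  if (!is.na(identity$symbol)) return(paste0("symbol:", identity$symbol))
  if (!is.null(identity$locus)) return(paste0("locus:", locus_to_string(identity$locus)))
  if (length(identity$genbank_accessions))
    return(paste0("genbank:", identity$genbank_accessions[[1]]))
  paste0("probe:", identity$affy_probesets[[1]])
}

#' Resolve a generic three-column row to a gene identity
#'
#' Resolution precedence is gene id, then symbol, then locus: the first key
#' that resolves in the graph populates all reachable namespace fields.
#' Inputs that resolve nowhere yield a stub identity carrying only the
#' supplied fields, flagged `unresolved`.
#'
#' @param gene_id Optional identifier (Entrez / Ensembl / GenBank,
#'   namespace auto-detected via [detect_namespace()]).
#' @param symbol Optional gene symbol.
#' @param locus Optional `genomic_locus` or `"chr:start-end"` string.
#' @param graph An `id_graph`.
#' @return A `gene_identity`.
#' @export
resolve_row_identity <- function(gene_id = NULL, symbol = NULL, locus = NULL, graph) {
  blank <- function(x) is.null(x) || length(x) == 0L || is.na(x) || !nzchar(as.character(x))
  if (is.character(locus)) locus <- locus_from_string(locus)
  if (blank(gene_id) && blank(symbol) && is.null(locus))
    stop("resolve_row_identity: all arguments empty")

  if (!blank(gene_id)) {
    ns <- detect_namespace(gene_id)
    if (node_key(norm_id(gene_id, ns), ns) %in% igraph::V(graph$graph)$name)
      return(gene_identity_from_node(gene_id, ns, graph))
  }
  if (!blank(symbol)) {
    if (node_key(norm_id(symbol, "symbol"), "symbol") %in% igraph::V(graph$graph)$name)
      return(gene_identity_from_node(symbol, "symbol", graph))
  }
  if (!is.null(locus)) {
    hits <- map_locus_to_genes(locus, graph)
    if (length(hits)) return(hits[[1]])
  }
  gene_identity(
    entrez_id = if (!blank(gene_id) && grepl("^[0-9]+$", gene_id))
      as.integer(gene_id) else NA_integer_,
    ensembl_gene_id = if (!blank(gene_id) && grepl("^ENSG", gene_id))
      as.character(gene_id) else NA_character_,
    genbank_accessions = if (!blank(gene_id) &&
                             detect_namespace(gene_id) == "genbank")
      as.character(gene_id) else character(),
    symbol = if (!blank(symbol)) toupper(symbol) else NA_character_,
    locus = locus, unresolved = TRUE)
}
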