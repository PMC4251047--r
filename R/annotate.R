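## Protein/gene annotation products: domain containment (1-based inclusive
## amino-acid coordinates -- the protein convention, never mixed with the
## half-open genomic one), lolliplot data, FPKM chart data, and drug-gene
## interaction linkage via a local table plus a deterministic DGIdb URL.

#' Construct a protein domain annotation
#'
#' @param protein_symbol Gene/protein symbol.
#' @param domain_name Domain name, e.g. `"DNA binding domain"`.
#' @param start_aa,end_aa 1-based inclusive amino-acid bounds.
#' @return A `domain_annotation`.
#' @export
domain_annotation <- function(protein_symbol, domain_name, start_aa, end_aa) {
  start_aa <- as.integer(start_aa); end_aa <- as.integer(end_aa)
  stopifnot(start_aa >= 1L, start_aa <= end_aa)
  structure(list(protein_symbol = toupper(protein_symbol),
                 domain_name = domain_name,
                 start_aa = start_aa, end_aa = end_aa),
            class = "domain_annotation")
}

#' Is an amino-acid position inside a domain?
#'
#' Inclusive at both ends: position 292 lies inside a 102-292 domain,
#' position 101 does not.
#'
#' @param aa_pos Positive integer amino-acid position.
#' @param domain A `domain_annotation`.
#' @return Logical.
#' @export
in_domain <- function(aa_pos, domain) {
  stopifnot(aa_pos >= 1L)
  aa_pos >= domain$start_aa & aa_pos <= domain$end_aa
}

#' Parse a single-letter amino-acid change string
#'
#' `"G13D"` (glycine to aspartic acid at position 13) parses to its three
#' components; anything not of the form `XnY` is an error.
#'
#' @param aa_change String like `"G13D"`.
#' @return `list(ref_aa, position, alt_aa)`.
#' @export
parse_aa_change <- function(aa_change) {
  m <- regmatches(aa_change,
                  regexec("^([A-Za-z])([0-9]+)([A-Za-z*])$", aa_change))[[1]]
  if (length(m) == 0L) stop("malformed amino-acid change: ", aa_change)
  pos <- as.integer(m[3])
  if (pos < 1L) stop("amino-acid position must be positive: ", aa_change)
  list(ref_aa = toupper(m[2]), position = pos, alt_aa = toupper(m[4]))
}

#' Build lolliplot data for one protein
#'
#' Places the experiment's observed amino-acid changes (red) alongside
#' previously reported canonical mutations (blue) and protein domains
#' (green) on the protein backbone, as data for a plotting front-end.
#' Variants whose `aa_change` does not parse are excluded with a warning; a
#' parsed position beyond the protein length is an error naming the variant.
#'
#' @param variants List of `variant_record`s for one gene.
#' @param canonical Data frame with columns `position`, `label` of known
#'   mutations (may be empty).
#' @param domains List of `domain_annotation`s.
#' @param protein_length Protein length in amino acids.
#' @return A `lolliplot_data` object with `observed`, `canonical` and
#'   `domains` elements carrying fixed color tags.
#' @export
lolliplot_data <- function(variants, canonical = NULL, domains = list(),
                           protein_length) {
  protein_length <- as.integer(protein_length)
  stopifnot(protein_length >= 1L)
  obs <- list()
  sym <- NA_character_
  for (v in variants) {
    if (!is.na(v$gene$symbol)) sym <- v$gene$symbol
    p <- tryCatch(parse_aa_change(v$aa_change), error = function(e) NULL)
    if (is.null(p)) {
      warning("skipping variant with unparseable aa_change: ",
              v$aa_change %||% "NA")
      next
    }
    if (p$position > protein_length)
      stop("variant ", v$aa_change, " position ", p$position,
           " exceeds protein length ", protein_length)
    obs[[length(obs) + 1L]] <- data.frame(position = p$position,
                                          label = v$aa_change,
                                          category = "observed",
                                          color = "red",
                                          stringsAsFactors = FALSE)
  }
  obs <- if (length(obs)) do.call(rbind, obs) else
    data.frame(position = integer(), label = character(),
               category = character(), color = character())
  can <- if (!is.null(canonical) && nrow(canonical)) {
    bad <- canonical$position > protein_length
    if (any(bad)) stop("canonical mutation beyond protein length: ",
                       paste(canonical$label[bad], collapse = ", "))
    data.frame(position = as.integer(canonical$position),
               label = canonical$label, category = "canonical",
               color = "blue", stringsAsFactors = FALSE)
  } else data.frame(position = integer(), label = character(),
                    category = character(), color = character())
  doms <- lapply(domains, function(d) {
    if (d$end_aa > protein_length)
      stop("domain ", d$domain_name, " exceeds protein length")
    c(d, list(color = "green"))
  })
  structure(list(protein_symbol = sym, protein_length = protein_length,
                 observed = obs, canonical = can, domains = doms),
            class = "lolliplot_data")
}

#' @export
print.lolliplot_data <- function(x, ...) {
  cat("<lolliplot> ", x$protein_symbol, " (", x$protein_length, " aa): ",
      nrow(x$observed), " observed, ", nrow(x$canonical), " canonical, ",
      length(x$domains), " domains\n", sep = "")
  invisible(x)
}

#' Serialize lolliplot data to JSON
#'
#' @param data A `lolliplot_data`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_lolliplot_json <- function(data, path) {
  obj <- list(protein_symbol = data$protein_symbol,
              protein_length = data$protein_length,
              observed = data$observed, canonical = data$canonical,
              domains = lapply(data$domains, function(d)
                list(name = d$domain_name, start_aa = d$start_aa,
                     end_aa = d$end_aa, color = d$color)))
  jsonlite::write_json(obj, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Build chart data from Cuffdiff records
#'
#' Gene-level records yield a bar chart (normal vs tumor FPKM per gene);
#' isoform records of a single gene yield a donut chart with a tumor ring
#' and a normal ring, one segment per isoform. Every input FPKM appears
#' exactly once in the output series.
#'
#' @param records List of `expression_diff_record`s or `isoform_record`s
#'   (one gene only for the donut).
#' @return A `chart_data` with `kind` (`"bar"` or `"donut"`) and `series`.
#' @export
chart_data <- function(records) {
  stopifnot(length(records) >= 1L)
  iso <- inherits(records[[1]], "isoform_record")
  if (iso) {
    syms <- unique(vapply(records, function(r)
      r$gene$symbol %||% NA_character_, character(1)))
    syms <- syms[!is.na(syms)]
    if (length(syms) > 1L)
      stop("donut chart requires isoforms of a single gene, got: ",
           paste(syms, collapse = ", "))
    series <- data.frame(
      label = vapply(records, `[[`, "", "transcript_id"),
      tumor_fpkm = vapply(records, `[[`, 0, "sample2_fpkm"),
      normal_fpkm = vapply(records, `[[`, 0, "sample1_fpkm"),
      novel = vapply(records, `[[`, NA, "novel"),
      stringsAsFactors = FALSE)
    structure(list(kind = "donut", gene = if (length(syms)) syms else NA,
                   series = series), class = "chart_data")
  } else {
    series <- data.frame(
      label = vapply(records, function(r) r$gene$symbol %||% NA_character_,
                     character(1)),
      normal_fpkm = vapply(records, `[[`, 0, "sample1_fpkm"),
      tumor_fpkm = vapply(records, `[[`, 0, "sample2_fpkm"),
      stringsAsFactors = FALSE)
    structure(list(kind = "bar", series = series), class = "chart_data")
  }
}

#' @export
print.chart_data <- function(x, ...) {
  cat("<chart_data> ", x$kind, ", ", nrow(x$series), " series entries\n", sep = "")
  invisible(x)
}

#' Read a domain table
#'
#' TSV with columns `protein_symbol, domain_name, start_aa, end_aa,
#' protein_length`.
#'
#' @param path TSV path.
#' @return List with `domains` (list of `domain_annotation`) and `lengths`
#'   (named integer vector of protein lengths).
#' @export
read_domain_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  doms <- lapply(seq_len(nrow(tab)), function(i)
    domain_annotation(tab$protein_symbol[i], tab$domain_name[i],
                      tab$start_aa[i], tab$end_aa[i]))
  lens <- stats::setNames(as.integer(tab$protein_length),
                          toupper(tab$protein_symbol))
  list(domains = doms, lengths = lens[!duplicated(names(lens))])
}

#' Read a canonical mutation table
#'
#' TSV with columns `protein_symbol, label` (single-letter change, e.g.
#' `G12D`); positions derive from the labels.
#'
#' @param path TSV path.
#' @return Data frame with `protein_symbol, position, label`.
#' @export
read_canonical_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  tab$position <- vapply(tab$label,
                         function(l) parse_aa_change(l)$position, integer(1),
                         USE.NAMES = FALSE)
  tab$protein_symbol <- toupper(tab$protein_symbol)
  tab[c("protein_symbol", "position", "label")]
}

#' Read a local drug-gene interaction table
#'
#' TSV with columns `gene, drug, interaction_type, source`.
#'
#' @param path TSV path.
#' @return A `drug_gene_table` (data frame).
#' @export
read_drug_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "drug", "interaction_type", "source")
  if (!all(need %in% names(tab)))
    stop("drug table lacks columns: ",
         paste(setdiff(need, names(tab)), collapse = ", "))
  tab$gene <- toupper(tab$gene)
  structure(tab, class = c("drug_gene_table", "data.frame"))
}

#' Look up drug interactions for a gene
#'
#' Matches the local table by any resolvable identifier of the gene
#' (symbol, Entrez id, Ensembl gene id); unknown genes yield an empty
#' result, never an error.
#'
#' @param gene A `gene_identity` or bare symbol string.
#' @param table A `drug_gene_table`.
#' @return Data frame of matching interactions.
#' @export
drug_interactions <- function(gene, table) {
  ids <- if (inherits(gene, "gene_identity"))
    c(gene$symbol, as.character(gene$entrez_id), gene$ensembl_gene_id)
  else as.character(gene)
  ids <- toupper(stats::na.omit(ids))
  out <- table[table$gene %in% ids, , drop = FALSE]
  rownames(out) <- NULL
  as.data.frame(out)
}

#' Build a deterministic DGIdb query URL
#'
#' No network access is performed; the URL lists the gene symbols
#' comma-separated in sorted order.
#'
#' @param genes Character vector of symbols or list of `gene_identity`s.
#' @return URL string.
#' @export
dgidb_url <- function(genes) {
  syms <- vapply(genes, function(g)
    if (inherits(g, "gene_identity")) g$symbol else toupper(as.character(g)),
    character(1))
  syms <- sort(unique(stats::na.omit(syms)))
  paste0("https://dgidb.org/results?searchType=gene&searchTerms=",
         paste(syms, collapse = ","))
}
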