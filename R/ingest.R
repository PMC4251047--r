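## Typed parsing, cleaning and validation for the three modality families.
## Every parser returns list(records, report): accepted rows become fully
## typed records; each rejected row is enumerated in the report with the
## rule it violated, so rows_read == rows_accepted + rows_rejected always.

#' Construct an import report
#'
#' @param rows_read Total data rows inspected.
#' @param rows_accepted Rows that became records.
#' @param rejections Data frame with at least `line` and `rule` columns.
#' @param notes Optional character notes (e.g. auto-detected conventions).
#' @return An `import_report` object.
#' @export
import_report <- function(rows_read, rows_accepted,
                          rejections = data.frame(line = integer(),
                                                  rule = character()),
                          notes = character()) {
  rows_read <- as.integer(rows_read); rows_accepted <- as.integer(rows_accepted)
  rows_rejected <- nrow(rejections)
  stopifnot(rows_read == rows_accepted + rows_rejected)
  structure(list(rows_read = rows_read, rows_accepted = rows_accepted,
                 rows_rejected = rows_rejected,
                 rejections = rejections, notes = notes),
            class = "import_report")
}

#' @export
print.import_report <- function(x, ...) {
  cat("<import_report> read=", x$rows_read, " accepted=", x$rows_accepted,
      " rejected=", x$rows_rejected, "\n", sep = "")
  if (x$rows_rejected > 0)
    for (i in seq_len(min(5L, x$rows_rejected)))
      cat("  line ", x$rejections$line[i], ": ", x$rejections$rule[i], "\n", sep = "")
  for (n in x$notes) cat("  note: ", n, "\n", sep = "")
  invisible(x)
}

new_rejector <- function() {
  env <- new.env(parent = emptyenv()); env$rows <- list()
  env
}
reject <- function(env, line, rule) {
  env$rows[[length(env$rows) + 1L]] <- data.frame(line = as.integer(line),
                                                  rule = rule,
                                                  stringsAsFactors = FALSE)
}
rejections_df <- function(env) {
  if (length(env$rows)) do.call(rbind, env$rows) else
    data.frame(line = integer(), rule = character(), stringsAsFactors = FALSE)
}

#' Allelic frequency of an alternate allele
#'
#' @param alt_count Reads supporting the alternate allele.
#' @param depth Total read depth (> 0).
#' @return `alt_count / depth`, a fraction in \[0, 1\].
#' @export
allelic_frequency <- function(alt_count, depth) {
  alt_count <- as.integer(alt_count); depth <- as.integer(depth)
  if (any(is.na(alt_count)) || any(is.na(depth))) stop("counts must be integers")
  if (any(depth == 0L)) stop("allelic frequency undefined at zero depth")
  if (any(alt_count < 0L) || any(alt_count > depth))
    stop("need 0 <= alt_count <= depth")
  alt_count / depth
}

#' Inner mate distance of a paired-end library
#'
#' The unsequenced gap between read pairs: fragment length minus twice the
#' read length. A 300-350 bp library sequenced 2 x 101 bp has an inner mate
#' distance of 98-148 bp.
#'
#' @param fragment_min,fragment_max Fragment size range in bp.
#' @param read_length Read length in bp.
#' @return Named numeric `c(min=, max=)` in bp.
#' @export
inner_mate_distance <- function(fragment_min, fragment_max, read_length) {
  stopifnot(fragment_min <= fragment_max, read_length > 0)
  lo <- fragment_min - 2 * read_length
  hi <- fragment_max - 2 * read_length
  if (lo < 0) stop("overlapping mates: fragment shorter than twice the read length")
  c(min = lo, max = hi)
}

#' Average microarray probe values for one gene
#'
#' @param measurements List of `probe_measurement`s, all for the same gene,
#'   or a numeric vector of values.
#' @return Arithmetic mean, or `NA_real_` for an empty input (the gene is
#'   shown with an empty microarray cell).
#' @export
average_probe_values <- function(measurements) {
  vals <- if (is.numeric(measurements)) measurements else
    vapply(measurements, function(m) m$value, numeric(1))
  if (length(vals) == 0L) return(NA_real_)
  mean(vals)
}

## ---- variants -------------------------------------------------------------

variant_record <- function(locus, ref, alt, effect, codon_change, aa_change,
                           tumor_depth, tumor_af, normal_depth = NA_integer_,
                           normal_af = NA_real_, gene) {
  structure(list(locus = locus, ref_allele = ref, alt_allele = alt,
                 effect = effect, codon_change = codon_change,
                 aa_change = aa_change,
                 tumor_depth = as.integer(tumor_depth),
                 tumor_af = as.numeric(tumor_af),
                 normal_depth = as.integer(normal_depth),
                 normal_af = as.numeric(normal_af), gene = gene),
            class = "variant_record")
}

#' @export
print.variant_record <- function(x, ...) {
  cat("<variant> ", locus_to_string(x$locus), " ", x$ref_allele, ">",
      x$alt_allele, " ", x$effect,
      if (!is.na(x$aa_change)) paste0(" ", x$aa_change) else "",
      " DP=", x$tumor_depth, " AF=", round(x$tumor_af, 4), "\n", sep = "")
  invisible(x)
}

## AF columns may arrive as fractions or percents. Detection is file-level:
## the column is percent only when the majority of its finite values exceed
## 1 (then everything is divided by 100 and the report notes it); otherwise
## a stray value > 1 fails the [0,1] range check for its row.
detect_percent_mode <- function(afs) {
  afs <- afs[is.finite(afs)]
  length(afs) > 0 && sum(afs > 1) > length(afs) / 2
}

normalize_af <- function(af, percent_mode = FALSE) {
  if (is.na(af)) return(NA_real_)
  if (percent_mode) af / 100 else af
}

#' Parse an annotated somatic variant file
#'
#' Accepts either a VCF 4.x file carrying SnpEff classic `EFF` annotations
#' (`EFF=Effect(Impact|Class|Codon_Change|AA_Change|...|Gene_Name|...)`)
#' with `DP`/`AF` per-sample fields for `TUMOR` (and optionally `NORMAL`),
#' or a tab-delimited export with columns
#' `chrom pos ref alt effect codon_change aa_change tumor_dp tumor_af`
#' (optional `normal_dp normal_af gene`). Format is chosen by extension /
#' header sniffing. Multi-allelic VCF rows split into one record per
#' alternate allele. Allelic frequencies given as percent are auto-detected
#' (values > 1) and noted in the report.
#'
#' @param source Path to the variant file.
#' @param graph An `id_graph` used to resolve each row's gene via
#'   [resolve_row_identity()].
#' @param chromosomes Optional character vector restricting accepted
#'   chromosome names; defaults to those in `graph`'s locus table (or any).
#' @return `list(records, report)`.
#' @export
parse_variants <- function(source, graph, chromosomes = NULL) {
  if (!file.exists(source)) stop("cannot read variant file: ", source)
  if (is.null(chromosomes) && nrow(graph$loci) > 0L)
    chromosomes <- unique(graph$loci$chrom)
  first <- readLines(source, n = 1L)
  is_vcf <- grepl("\\.vcf(\\.gz)?$", source) || startsWith(first, "##fileformat=VCF")
  if (is_vcf) parse_variants_vcf(source, graph, chromosomes)
  else parse_variants_tab(source, graph, chromosomes)
}

parse_variants_vcf <- function(source, graph, chromosomes) {
  v <- suppressWarnings(vcfR::read.vcfR(source, verbose = FALSE))
  fix <- as.data.frame(vcfR::getFIX(v, getINFO = TRUE), stringsAsFactors = FALSE)
  gt <- v@gt
  rej <- new_rejector(); recs <- list()
  n <- nrow(fix); nread <- 0L
  rowdat <- lapply(seq_len(n), function(i) {
    fmt <- strsplit(gt[i, "FORMAT"], ":", fixed = TRUE)[[1]]
    list(alts = strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]],
         eff = parse_eff(parse_info(fix$INFO[i])[["EFF"]]),
         tum = parse_sample(gt[i, "TUMOR"], fmt),
         nor = if ("NORMAL" %in% colnames(gt))
           parse_sample(gt[i, "NORMAL"], fmt) else NULL)
  })
  percent_mode <- detect_percent_mode(
    unlist(lapply(rowdat, function(r) r$tum$af)))
  for (i in seq_len(n)) {
    r <- rowdat[[i]]
    tafs <- rep(r$tum$af, length.out = length(r$alts))
    for (k in seq_along(r$alts)) {
      nread <- nread + 1L
      ok <- validate_variant_row(fix$CHROM[i], fix$POS[i], fix$REF[i],
                                 r$alts[k], r$tum$dp, tafs[k], chromosomes,
                                 rej, i, percent_mode)
      if (is.null(ok)) next
      gid <- resolve_row_identity(gene_id = NULL,
                                  symbol = if (nzchar(r$eff$gene)) r$eff$gene else NULL,
                                  locus = ok$locus, graph = graph)
      recs[[length(recs) + 1L]] <- variant_record(
        ok$locus, fix$REF[i], r$alts[k], r$eff$effect, r$eff$codon_change,
        r$eff$aa_change, r$tum$dp, ok$af,
        if (!is.null(r$nor)) r$nor$dp else NA_integer_,
        if (!is.null(r$nor)) normalize_af(r$nor$af[1], percent_mode)
        else NA_real_, gid)
    }
  }
  notes <- c(if (percent_mode) "tumor AF supplied as percent; divided by 100")
  list(records = recs,
       report = import_report(nread, length(recs), rejections_df(rej),
                              notes = notes %||% character()))
}

parse_variants_tab <- function(source, graph, chromosomes) {
  tab <- utils::read.delim(source, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("chrom", "pos", "ref", "alt", "effect", "codon_change",
            "aa_change", "tumor_dp", "tumor_af")
  if (!all(need %in% names(tab)))
    stop("variant table lacks columns: ",
         paste(setdiff(need, names(tab)), collapse = ", "))
  rej <- new_rejector(); recs <- list()
  percent_mode <- detect_percent_mode(suppressWarnings(as.numeric(tab$tumor_af)))
  for (i in seq_len(nrow(tab))) {
    line <- i + 1L
    ok <- validate_variant_row(tab$chrom[i], tab$pos[i], tab$ref[i], tab$alt[i],
                               suppressWarnings(as.integer(tab$tumor_dp[i])),
                               suppressWarnings(as.numeric(tab$tumor_af[i])),
                               chromosomes, rej, line, percent_mode)
    if (is.null(ok)) next
    gid <- resolve_row_identity(
      gene_id = if ("gene_id" %in% names(tab) && nzchar(tab$gene_id[i]))
        tab$gene_id[i] else NULL,
      symbol = if ("gene" %in% names(tab) && nzchar(tab$gene[i]))
        tab$gene[i] else NULL,
      locus = ok$locus, graph = graph)
    recs[[length(recs) + 1L]] <- variant_record(
      ok$locus, tab$ref[i], tab$alt[i], tab$effect[i], tab$codon_change[i],
      tab$aa_change[i], as.integer(tab$tumor_dp[i]), ok$af,
      if ("normal_dp" %in% names(tab)) as.integer(tab$normal_dp[i]) else NA_integer_,
      if ("normal_af" %in% names(tab))
        normalize_af(as.numeric(tab$normal_af[i]), percent_mode)
      else NA_real_, gid)
  }
  notes <- c(if (percent_mode) "tumor AF supplied as percent; divided by 100")
  list(records = recs,
       report = import_report(nrow(tab), length(recs), rejections_df(rej),
                              notes = notes %||% character()))
}

validate_variant_row <- function(chrom, pos, ref, alt, dp, af, chromosomes,
                                 rej, line, percent_mode = FALSE) {
  pos <- suppressWarnings(as.integer(pos))
  if (is.na(pos) || pos < 1L) { reject(rej, line, "bad position"); return(NULL) }
  if (!is.null(chromosomes) && !chrom %in% chromosomes) {
    reject(rej, line, "unknown chromosome"); return(NULL)
  }
  if (is.na(ref) || is.na(alt) || !nzchar(ref) || !nzchar(alt) ||
      identical(ref, alt)) {
    reject(rej, line, "ref/alt invalid"); return(NULL)
  }
  if (is.na(dp) || dp < 0L) { reject(rej, line, "negative or missing depth"); return(NULL) }
  naf <- normalize_af(af, percent_mode)
  if (is.na(naf) || naf < 0 || naf > 1) {
    reject(rej, line, "allelic frequency outside [0,1]"); return(NULL)
  }
  # VCF positions are 1-based; internal loci half-open 0-based
  list(locus = genomic_locus(chrom, pos - 1L, pos - 1L + nchar(ref)), af = naf)
}

parse_info <- function(info) {
  if (is.na(info) || !nzchar(info)) return(list())
  parts <- strsplit(info, ";", fixed = TRUE)[[1]]
  kv <- strsplit(parts, "=", fixed = TRUE)
  out <- lapply(kv, function(p) if (length(p) > 1) p[[2]] else TRUE)
  names(out) <- vapply(kv, `[[`, "", 1L)
  out
}

## SnpEff classic EFF subfields:
## Effect(Impact|Class|Codon_Change|AA_Change|AA_len|Gene_Name|...)
parse_eff <- function(eff) {
  empty <- list(effect = NA_character_, codon_change = NA_character_,
                aa_change = NA_character_, gene = "")
  if (is.null(eff) || isTRUE(eff) || is.na(eff) || !nzchar(eff)) return(empty)
  eff <- strsplit(eff, ",", fixed = TRUE)[[1]][[1]]  # first (highest-impact) entry
  m <- regmatches(eff, regexec("^([^(]+)\\(([^)]*)\\)$", eff))[[1]]
  if (length(m) == 0L) return(empty)
  sub <- strsplit(m[3], "|", fixed = TRUE)[[1]]
  getf <- function(i) if (length(sub) >= i && nzchar(sub[i])) sub[i] else NA_character_
  list(effect = m[2], codon_change = getf(3L), aa_change = getf(4L),
       gene = if (!is.na(getf(6L))) getf(6L) else "")
}

parse_sample <- function(s, fmt) {
  vals <- strsplit(s, ":", fixed = TRUE)[[1]]
  names(vals) <- fmt[seq_along(vals)]
  dp <- suppressWarnings(as.integer(vals[["DP"]]))
  af <- if ("AF" %in% names(vals))
    suppressWarnings(as.numeric(strsplit(vals[["AF"]], ",", fixed = TRUE)[[1]]))
  else NA_real_
  list(dp = dp, af = af)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## ---- Cuffdiff -------------------------------------------------------------

## Cuffdiff prints +/-infinite log2 fold changes either as "inf"/"-inf" or as
## the 1.79769e+308 double sentinel; both are stored as signed R infinities.
parse_l2fc <- function(x) {
  v <- suppressWarnings(as.numeric(x))
  if (is.na(v)) {
    if (grepl("^-?inf$", tolower(trimws(x)))) return(ifelse(startsWith(trimws(x), "-"), -Inf, Inf))
    return(NA_real_)
  }
  if (abs(v) >= 1.7e308) return(sign(v) * Inf)
  v
}

cuffdiff_required <- c("test_id", "gene_id", "gene", "locus", "value_1",
                       "value_2", "log2(fold_change)", "p_value", "q_value",
                       "significant")

read_cuffdiff <- function(source) {
  tab <- utils::read.delim(source, stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(cuffdiff_required, names(tab))
  if (length(missing))
    stop("Cuffdiff file ", source, " lacks columns: ",
         paste(missing, collapse = ", "))
  tab
}

validate_cuffdiff_row <- function(tab, i, rej, line) {
  v1 <- suppressWarnings(as.numeric(tab$value_1[i]))
  v2 <- suppressWarnings(as.numeric(tab$value_2[i]))
  p <- suppressWarnings(as.numeric(tab$p_value[i]))
  q <- suppressWarnings(as.numeric(tab$q_value[i]))
  if (is.na(v1) || is.na(v2) || v1 < 0 || v2 < 0) {
    reject(rej, line, "FPKM negative or non-numeric"); return(NULL)
  }
  if (is.na(p) || p < 0 || p > 1) { reject(rej, line, "p-value outside [0,1]"); return(NULL) }
  if (is.na(q) || q < 0 || q > 1) { reject(rej, line, "q-value outside [0,1]"); return(NULL) }
  list(v1 = v1, v2 = v2, p = p, q = q,
       sig = identical(tolower(trimws(tab$significant[i])), "yes"),
       l2fc = parse_l2fc(tab[["log2(fold_change)"]][i]))
}

#' Parse a Cuffdiff `gene_exp.diff`-style file
#'
#' Range-checks FPKMs and p/q-values; the `significant` yes/no column is
#' authoritative and is never recomputed. Infinite log2 fold changes
#' (`inf`, `-inf` or the 1.8e308 sentinel) are stored as signed infinities.
#'
#' @param source Path to the TSV.
#' @param graph Optional `id_graph` for gene resolution; without it, stub
#'   identities are built from the `gene` / `gene_id` columns.
#' @return `list(records, report)` of `expression_diff_record`s.
#' @export
parse_cuffdiff_genes <- function(source, graph = NULL) {
  tab <- read_cuffdiff(source)
  rej <- new_rejector(); recs <- list()
  for (i in seq_len(nrow(tab))) {
    line <- i + 1L
    ok <- validate_cuffdiff_row(tab, i, rej, line)
    if (is.null(ok)) next
    loc <- tryCatch(locus_from_string(tab$locus[i]), error = function(e) NULL)
    gid <- resolve_cuffdiff_gene(tab$gene_id[i], tab$gene[i], loc, graph)
    recs[[length(recs) + 1L]] <- structure(
      list(gene = gid, locus = loc, sample1_fpkm = ok$v1, sample2_fpkm = ok$v2,
           log2_fold_change = ok$l2fc, p_value = ok$p, q_value = ok$q,
           significant = ok$sig),
      class = "expression_diff_record")
  }
  list(records = recs,
       report = import_report(nrow(tab), length(recs), rejections_df(rej)))
}

resolve_cuffdiff_gene <- function(gene_id, gene, loc, graph) {
  gene_id <- if (!is.na(gene_id) && nzchar(gene_id) &&
                 !startsWith(gene_id, "XLOC") && !startsWith(gene_id, "CUFF"))
    gene_id else NULL
  gene <- if (!is.na(gene) && nzchar(gene) && gene != "-") gene else NULL
  if (!is.null(graph))
    resolve_row_identity(gene_id = gene_id, symbol = gene, locus = loc,
                         graph = graph)
  else gene_identity(symbol = gene %||% NA_character_,
                     ensembl_gene_id = if (!is.null(gene_id) &&
                                           grepl("^ENSG", gene_id)) gene_id
                     else NA_character_,
                     locus = loc, unresolved = TRUE)
}

#' Parse a Cuffdiff `isoform_exp.diff`-style file
#'
#' As [parse_cuffdiff_genes()], one record per transcript; transcripts with
#' the assembler's `CUFF.` prefix are flagged novel.
#'
#' @inheritParams parse_cuffdiff_genes
#' @return `list(records, report)` of `isoform_record`s.
#' @export
parse_cuffdiff_isoforms <- function(source, graph = NULL) {
  tab <- read_cuffdiff(source)
  rej <- new_rejector(); recs <- list()
  for (i in seq_len(nrow(tab))) {
    line <- i + 1L
    tid <- trimws(tab$test_id[i])
    if (!nzchar(tid) || is.na(tid)) { reject(rej, line, "empty transcript id"); next }
    ok <- validate_cuffdiff_row(tab, i, rej, line)
    if (is.null(ok)) next
    loc <- tryCatch(locus_from_string(tab$locus[i]), error = function(e) NULL)
    gid <- resolve_cuffdiff_gene(tab$gene_id[i], tab$gene[i], loc, graph)
    recs[[length(recs) + 1L]] <- structure(
      list(transcript_id = tid, gene = gid, sample1_fpkm = ok$v1,
           sample2_fpkm = ok$v2, log2_fold_change = ok$l2fc,
           p_value = ok$p, q_value = ok$q, significant = ok$sig,
           novel = startsWith(tid, "CUFF.")),
      class = "isoform_record")
  }
  list(records = recs,
       report = import_report(nrow(tab), length(recs), rejections_df(rej)))
}

## ---- microarray probes ----------------------------------------------------

#' Parse a `gene, probeID, value` microarray probe table
#'
#' Tab- or comma-delimited, auto-detected from the header line. Duplicate
#' (gene, probe) rows are all kept; averaging happens downstream.
#'
#' @param source Path to the table.
#' @return `list(records, report)` of `probe_measurement`s.
#' @export
parse_probe_table <- function(source) {
  first <- readLines(source, n = 1L)
  sep <- if (lengths(regmatches(first, gregexpr("\t", first))) > 0) "\t" else ","
  tab <- utils::read.table(source, sep = sep, header = TRUE,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character")
  if (ncol(tab) < 3L) stop("probe table needs three columns: gene, probeID, value")
  rej <- new_rejector(); recs <- list()
  for (i in seq_len(nrow(tab))) {
    line <- i + 1L
    val <- suppressWarnings(as.numeric(tab[i, 3]))
    if (is.na(val) || !is.finite(val)) { reject(rej, line, "non-finite value"); next }
    if (!nzchar(trimws(tab[i, 2]))) { reject(rej, line, "empty probe id"); next }
    recs[[length(recs) + 1L]] <- structure(
      list(probe_id = trimws(tab[i, 2]), gene_symbol = toupper(trimws(tab[i, 1])),
           value = val),
      class = "probe_measurement")
  }
  list(records = recs,
       report = import_report(nrow(tab), length(recs), rejections_df(rej)))
}
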