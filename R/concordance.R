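## DNA -> RNA variant-expression concordance: count ref/alt alleles in
## RNA-seq alignments at a DNA-called SNV position and classify whether the
## mutation is expressed in the transcriptome (e.g. a KRAS hotspot present
## in DNA but absent from RNA reads is called not_expressed; a TP53
## mutation seen in both is expressed_concordant).

#' Concordance decision thresholds
#'
#' Explicit numeric stand-ins for what is otherwise a visual judgement in a
#' genome browser; all are configurable and reported in output headers.
#'
#' @param min_rna_depth Minimum RNA read depth to attempt a call (reads).
#' @param min_alt_reads Minimum alternate-allele reads to call expression.
#' @param min_rna_af Minimum RNA allelic frequency to call expression.
#' @return A `concordance_thresholds` object.
#' @export
concordance_thresholds <- function(min_rna_depth = 10L, min_alt_reads = 2L,
                                   min_rna_af = 0.01) {
  stopifnot(min_rna_depth >= 0, min_alt_reads >= 0, min_rna_af >= 0)
  structure(list(min_rna_depth = as.integer(min_rna_depth),
                 min_alt_reads = as.integer(min_alt_reads),
                 min_rna_af = as.numeric(min_rna_af)),
            class = "concordance_thresholds")
}

## SAM flag bits
FLAG_UNMAPPED <- 0x4L; FLAG_SECONDARY <- 0x100L; FLAG_QCFAIL <- 0x200L
FLAG_DUP <- 0x400L; FLAG_SUPPLEMENTARY <- 0x800L

## Ensure a BAM + index exists for a SAM/BAM source (converted lazily,
## cached next to a tempdir key on the source path).
as_indexed_bam <- function(source) {
  if (grepl("\\.bam$", source)) {
    if (!file.exists(paste0(source, ".bai")))
      Rsamtools::indexBam(source)
    return(source)
  }
  dest <- file.path(tempdir(),
                    paste0("triomics_", substr(tools::md5sum(source), 1, 12)))
  bam <- paste0(dest, ".bam")
  if (!file.exists(bam))
    Rsamtools::asBam(source, destination = dest, overwrite = TRUE,
                     indexDestination = TRUE)
  bam
}

## Walk a CIGAR string to find the query offset aligned to genomic position
## `target` (1-based) for a read starting at `pos`. Returns the 1-based
## query index, "del" if a deletion/skip spans the target, or NA if the
## read's aligned span does not reach the target.
query_offset_at <- function(pos, cigar, target) {
  ops <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  rpos <- pos; qpos <- 1L
  for (op in ops) {
    n <- as.integer(sub("[MIDNSHP=X]$", "", op))
    type <- sub("^[0-9]+", "", op)
    if (type %in% c("M", "=", "X")) {
      if (target < rpos + n) {
        if (target >= rpos) return(qpos + (target - rpos))
        return(NA_integer_)
      }
      rpos <- rpos + n; qpos <- qpos + n
    } else if (type %in% c("I", "S")) {
      qpos <- qpos + n
    } else if (type %in% c("D", "N")) {
      if (target >= rpos && target < rpos + n) return("del")
      rpos <- rpos + n
    }
    # H and P consume neither
  }
  NA_integer_
}

#' Count alleles at a single base from aligned reads
#'
#' Pileup-style allele counting at one genomic position. Each fragment
#' contributes at most once: unmapped, secondary, supplementary, QC-fail
#' and (by default) duplicate-marked reads are excluded, as are reads below
#' the mapping- or base-quality cutoffs; when both mates of a pair overlap
#' the position the base with the higher base quality is used. Bases are
#' compared on the genomic forward strand (SAM stores reverse-strand reads
#' already forward). Deletions and N bases at the position count toward
#' `other_count`.
#'
#' @param alignments Path to a SAM or BAM file (converted/indexed as needed).
#' @param locus Single-base `genomic_locus` of the SNV.
#' @param ref,alt Single reference / alternate bases.
#' @param min_base_quality Minimum Phred base quality (default 13).
#' @param min_mapping_quality Minimum mapping quality (default 0).
#' @param exclude_duplicates Drop duplicate-marked reads (default `TRUE`).
#' @return A `pileup_allele_count` with `ref_count`, `alt_count`,
#'   `other_count`, `depth` and `rna_af` (`NA` at zero depth).
#' @export
count_alleles <- function(alignments, locus, ref, alt, min_base_quality = 13L,
                          min_mapping_quality = 0L, exclude_duplicates = TRUE) {
  stopifnot(inherits(locus, "genomic_locus"),
            nchar(ref) == 1L, nchar(alt) == 1L)
  target <- locus$start + 1L  # 1-based position
  bam <- as_indexed_bam(alignments)
  hdr <- Rsamtools::scanBamHeader(bam)[[1]]$targets
  if (!locus$chrom %in% names(hdr))
    stop("locus chromosome ", locus$chrom, " not in alignment header")
  if (target > hdr[[locus$chrom]])
    stop("locus position beyond end of ", locus$chrom)
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "pos", "mapq", "cigar", "seq", "qual"),
    which = GenomicRanges::GRanges(locus$chrom,
                                   IRanges::IRanges(target, target)))
  x <- Rsamtools::scanBam(bam, param = param)[[1]]

  best <- new.env(parent = emptyenv())  # qname -> c(base, qual)
  n <- length(x$pos)
  for (i in seq_len(n)) {
    fl <- x$flag[i]
    if (bitwAnd(fl, FLAG_UNMAPPED) || bitwAnd(fl, FLAG_SECONDARY) ||
        bitwAnd(fl, FLAG_QCFAIL) || bitwAnd(fl, FLAG_SUPPLEMENTARY)) next
    if (exclude_duplicates && bitwAnd(fl, FLAG_DUP)) next
    if (!is.na(x$mapq[i]) && x$mapq[i] < min_mapping_quality) next
    off <- query_offset_at(x$pos[i], x$cigar[i], target)
    if (length(off) == 1L && is.na(off)) next
    if (identical(off, "del")) { base <- "-"; bq <- Inf }
    else {
      base <- toupper(substr(as.character(x$seq[i]), off, off))
      q <- as.character(x$qual[i])
      bq <- if (nzchar(q) && q != "*") utf8ToInt(substr(q, off, off)) - 33L else Inf
      if (bq < min_base_quality) next
    }
    key <- x$qname[i]
    prev <- best[[key]]
    if (is.null(prev) || bq > prev$bq) best[[key]] <- list(base = base, bq = bq)
  }

  refc <- altc <- othc <- 0L
  for (key in ls(best)) {
    b <- best[[key]]$base
    if (b == toupper(ref)) refc <- refc + 1L
    else if (b == toupper(alt)) altc <- altc + 1L
    else othc <- othc + 1L
  }
  depth <- refc + altc + othc
  structure(list(locus = locus, ref = toupper(ref), alt = toupper(alt),
                 ref_count = refc, alt_count = altc, other_count = othc,
                 depth = depth,
                 rna_af = if (depth > 0L) altc / depth else NA_real_),
            class = "pileup_allele_count")
}

#' @export
print.pileup_allele_count <- function(x, ...) {
  cat("<pileup> ", locus_to_string(x$locus), " ", x$ref, ">", x$alt,
      " depth=", x$depth, " ref=", x$ref_count, " alt=", x$alt_count,
      " other=", x$other_count,
      " af=", if (is.na(x$rna_af)) "NA" else round(x$rna_af, 4), "\n", sep = "")
  invisible(x)
}

#' Classify DNA-to-RNA variant expression concordance
#'
#' Exactly one status applies: `no_rna_data` when no RNA experiment was
#' supplied; `insufficient_coverage` below the depth threshold;
#' `expressed_concordant` when both the alternate-read and allelic-frequency
#' thresholds are met; otherwise `not_expressed`.
#'
#' @param variant A `variant_record` (SNV).
#' @param rna A `pileup_allele_count` at the variant position, or `NULL`
#'   when no RNA data exists.
#' @param thresholds A [concordance_thresholds()].
#' @return A `concordance_call` with `status`, `evidence` and `dna_af`.
#' @export
classify_concordance <- function(variant, rna = NULL,
                                 thresholds = concordance_thresholds()) {
  status <- if (is.null(rna)) "no_rna_data" else {
    if (!identical(variant$locus$chrom, rna$locus$chrom) ||
        variant$locus$start != rna$locus$start)
      stop("variant and pileup loci differ")
    if (rna$depth < thresholds$min_rna_depth) "insufficient_coverage"
    else if (rna$alt_count >= thresholds$min_alt_reads &&
             rna$rna_af >= thresholds$min_rna_af) "expressed_concordant"
    else "not_expressed"
  }
  structure(list(status = status, evidence = rna, dna_af = variant$tumor_af,
                 variant = variant, thresholds = thresholds),
            class = "concordance_call")
}

#' @export
print.concordance_call <- function(x, ...) {
  cat("<concordance> ", x$variant$gene$symbol %||% "?", " ",
      locus_to_string(x$variant$locus), " ", x$status,
      " (dna_af=", round(x$dna_af, 3),
      if (!is.null(x$evidence))
        paste0(", rna ", x$evidence$alt_count, "/", x$evidence$depth) else "",
      ")\n", sep = "")
  invisible(x)
}

#' Run concordance across a variant list and write a TSV report
#'
#' One row per SNV: `chrom, pos, ref, alt, dna_af, rna_depth, rna_alt,
#' rna_af, status`, preceded by `#` header lines recording the thresholds
#' used.
#'
#' @param variants List of `variant_record`s (non-SNVs are skipped with a
#'   note).
#' @param rna_alignments Path to the RNA SAM/BAM, or `NULL` for no RNA data.
#' @param thresholds A [concordance_thresholds()].
#' @param path Optional output TSV path.
#' @param ... Passed to [count_alleles()].
#' @return Data frame of calls (invisibly returns `path` attribute set).
#' @export
concordance_report <- function(variants, rna_alignments = NULL,
                               thresholds = concordance_thresholds(),
                               path = NULL, ...) {
  rows <- list()
  for (v in variants) {
    if (nchar(v$ref_allele) != 1L || nchar(v$alt_allele) != 1L) next
    rna <- if (!is.null(rna_alignments))
      count_alleles(rna_alignments,
                    genomic_locus(v$locus$chrom, v$locus$start,
                                  v$locus$start + 1L),
                    v$ref_allele, v$alt_allele, ...)
    else NULL
    call <- classify_concordance(v, rna, thresholds)
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = v$locus$chrom, pos = v$locus$start + 1L, ref = v$ref_allele,
      alt = v$alt_allele, gene = v$gene$symbol %||% NA_character_,
      dna_af = v$tumor_af,
      rna_depth = if (!is.null(rna)) rna$depth else NA_integer_,
      rna_alt = if (!is.null(rna)) rna$alt_count else NA_integer_,
      rna_af = if (!is.null(rna)) rna$rna_af else NA_real_,
      status = call$status, stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(), pos = integer(), ref = character(),
               alt = character(), gene = character(), dna_af = numeric(),
               rna_depth = integer(), rna_alt = integer(), rna_af = numeric(),
               status = character(), stringsAsFactors = FALSE)
  if (!is.null(path)) {
    con <- file(path, "w"); on.exit(close(con))
    writeLines(sprintf("#thresholds: min_rna_depth=%d min_alt_reads=%d min_rna_af=%g",
                       thresholds$min_rna_depth, thresholds$min_alt_reads,
                       thresholds$min_rna_af), con)
    utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}
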