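#' @keywords internal
"_PACKAGE"

## Coordinate convention: loci are 0-based half-open internally
## ([start, end)); every user-facing string (IGV goto, display, the
## "chr:start-end" import syntax) is 1-based fully-closed. The two never mix:
## conversion happens only in locus_from_string() / locus_to_string().

#' Gene identifier namespaces
#'
#' The closed set of identifier namespaces known to the association graph.
#' Every identifier in the system is tagged with exactly one of these.
#'
#' @return Character vector of namespace names.
#' @export
namespaces <- function() {
  c("entrez", "ensembl_gene", "ensembl_transcript", "genbank",
    "symbol", "affy_probeset", "locus")
}

#' Construct a genomic locus
#'
#' Loci use 0-based half-open coordinates internally; see
#' [locus_to_string()] for the 1-based inclusive display form.
#'
#' @param chrom Chromosome name, e.g. `"chr1"`.
#' @param start 0-based start (integer, inclusive).
#' @param end 0-based end (integer, exclusive); must satisfy `start <= end`.
#' @param strand One of `"+"`, `"-"`, `"*"` (unknown).
#' @return A `genomic_locus` object.
#' @export
genomic_locus <- function(chrom, start, end, strand = "*") {
  stopifnot(is.character(chrom), length(chrom) == 1L, nzchar(chrom))
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 0L || start > end)
    stop("invalid locus: need 0 <= start <= end")
  if (!strand %in% c("+", "-", "*"))
    stop("strand must be one of '+', '-', '*'")
  structure(list(chrom = chrom, start = start, end = end, strand = strand),
            class = "genomic_locus")
}

#' @export
print.genomic_locus <- function(x, ...) {
  cat("<locus> ", locus_to_string(x), " (", x$strand, ")\n", sep = "")
  invisible(x)
}

#' Render a locus as a 1-based inclusive "chr:start-end" string
#'
#' @param locus A `genomic_locus`.
#' @return Character scalar, e.g. `"chr1:101-200"` for the internal
#'   half-open interval \[100, 200).
#' @export
locus_to_string <- function(locus) {
  stopifnot(inherits(locus, "genomic_locus"))
  sprintf("%s:%d-%d", locus$chrom, locus$start + 1L, max(locus$end, locus$start + 1L))
}

#' Parse a 1-based inclusive "chr:start-end" string into a locus
#'
#' Accepts the generic three-column import syntax, e.g. `"chr12:100-200"`.
#' A bare position `"chr12:100"` denotes a single base.
#'
#' @param s Character scalar.
#' @param strand Strand to attach (default unknown).
#' @return A `genomic_locus` (0-based half-open internally).
#' @export
locus_from_string <- function(s, strand = "*") {
  m <- regmatches(s, regexec("^([^:]+):([0-9]+)(?:-([0-9]+))?$", s))[[1]]
  if (length(m) == 0L) stop("malformed locus string: ", s)
  start1 <- as.integer(m[3])
  end1 <- if (nzchar(m[4])) as.integer(m[4]) else start1
  if (start1 < 1L || end1 < start1) stop("malformed locus string: ", s)
  genomic_locus(m[2], start1 - 1L, end1, strand)
}

loci_overlap <- function(a, b) {
  identical(a$chrom, b$chrom) && a$start < b$end && b$start < a$end
}
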