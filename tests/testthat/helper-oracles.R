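## Test helpers: tiny fixture builders and independent brute-force oracles.
## The oracles deliberately share no code with the implementation: closure
## by fixpoint iteration over the raw edge list, overlap by linear scan,
## pileups by a naive text-level SAM walk.

## ---- graph fixtures -------------------------------------------------------

## assoc: data.frame(id_a, ns_a, id_b, ns_b); loci: data.frame(gene_id,
## chrom, start, end, strand[, name]) with 1-based inclusive coordinates.
make_graph <- function(assoc = NULL, loci = NULL) {
  af <- character(); lf <- character()
  if (!is.null(assoc) && nrow(assoc)) {
    af <- tempfile(fileext = ".tsv")
    write.table(assoc, af, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(loci) && nrow(loci)) {
    lf <- tempfile(fileext = ".tsv")
    write.table(loci, lf, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  build_graph(af, lf)
}

assoc_df <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(id_a = r[1], ns_a = r[2], id_b = r[3], ns_b = r[4],
               stringsAsFactors = FALSE)))
}

## Brute-force transitive closure over an undirected edge list: which ids of
## namespace dst are reachable from (id, src)?
oracle_convert <- function(assoc, id, src, dst) {
  a <- paste(assoc$ns_a, toupper_if(assoc$id_a, assoc$ns_a), sep = "/")
  b <- paste(assoc$ns_b, toupper_if(assoc$id_b, assoc$ns_b), sep = "/")
  start <- paste(src, toupper_if(id, src), sep = "/")
  if (!start %in% c(a, b)) return(character(0))  # unknown id: empty set
  reach <- start
  repeat {
    nxt <- unique(c(reach, b[a %in% reach], a[b %in% reach]))
    if (length(nxt) == length(reach)) break
    reach <- nxt
  }
  hits <- reach[startsWith(reach, paste0(dst, "/"))]
  sort(sub("^[^/]+/", "", hits))
}

toupper_if <- function(id, ns) ifelse(ns == "symbol", toupper(id), as.character(id))

## Linear-scan overlap oracle over 1-based inclusive gene intervals,
## query given 0-based half-open.
oracle_overlap <- function(loci, chrom, start0, end0) {
  hit <- loci$chrom == chrom &
    (loci$start - 1L) < end0 & start0 < loci$end
  sort(loci$gene_id[hit])
}

## ---- SAM fixtures ---------------------------------------------------------

## reads: list of lists with qname, flag, chrom, pos, mapq, cigar, seq, qual
write_sam <- function(path, reads, contigs = c(chrT = 10000L)) {
  lines <- c("@HD\tVN:1.6\tSO:unsorted",
             sprintf("@SQ\tSN:%s\tLN:%d", names(contigs), unname(contigs)))
  for (r in reads)
    lines <- c(lines, paste(r$qname, r$flag, r$chrom, r$pos,
                            r$mapq %||% 60L, r$cigar, "*", 0, 0, r$seq,
                            r$qual %||% strrep("I", nchar(r$seq)), sep = "\t"))
  writeLines(lines, path)
  path
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Naive per-read re-scan oracle: parse the SAM text, walk each CIGAR into
## explicit (refpos, base) pairs, then tally at the target position. Applies
## the same filtering contract (flags, mapq, base quality, fragment-level
## best-quality dedup by qname) by direct enumeration.
oracle_pileup <- function(sam_path, chrom, pos1, ref, alt,
                          min_base_quality = 13L, min_mapping_quality = 0L,
                          exclude_duplicates = TRUE) {
  lines <- readLines(sam_path)
  lines <- lines[!startsWith(lines, "@")]
  frag <- list()
  for (ln in lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    flag <- as.integer(f[2])
    if (f[3] != chrom) next
    if (bitwAnd(flag, 0x4) || bitwAnd(flag, 0x100) || bitwAnd(flag, 0x200) ||
        bitwAnd(flag, 0x800)) next
    if (exclude_duplicates && bitwAnd(flag, 0x400)) next
    if (as.integer(f[5]) < min_mapping_quality) next
    rpos <- as.integer(f[4]); qpos <- 1L
    ops <- regmatches(f[6], gregexpr("[0-9]+[A-Z=]", f[6]))[[1]]
    base <- NULL; bq <- NULL
    for (op in ops) {
      n <- as.integer(substr(op, 1, nchar(op) - 1L))
      t <- substr(op, nchar(op), nchar(op))
      if (t %in% c("M", "=", "X")) {
        for (k in seq_len(n)) {
          if (rpos == pos1) {
            base <- substr(f[10], qpos, qpos)
            bq <- if (f[11] == "*") Inf else utf8ToInt(substr(f[11], qpos, qpos)) - 33L
          }
          rpos <- rpos + 1L; qpos <- qpos + 1L
        }
      } else if (t %in% c("I", "S")) qpos <- qpos + n
      else if (t %in% c("D", "N")) {
        for (k in seq_len(n)) {
          if (rpos == pos1) { base <- "-"; bq <- Inf }
          rpos <- rpos + 1L
        }
      }
    }
    if (is.null(base)) next
    if (base != "-" && bq < min_base_quality) next
    prev <- frag[[f[1]]]
    if (is.null(prev) || bq > prev$bq) frag[[f[1]]] <- list(base = base, bq = bq)
  }
  refc <- altc <- othc <- 0L
  for (x in frag) {
    if (x$base == toupper(ref)) refc <- refc + 1L
    else if (x$base == toupper(alt)) altc <- altc + 1L
    else othc <- othc + 1L
  }
  list(ref = refc, alt = altc, other = othc, depth = refc + altc + othc)
}

## Random single-end read with a CIGAR mixing matches, insertions,
## deletions and soft clips, guaranteed to start at `pos`.
random_read <- function(i, chrom, pos, rng_bases = c("A", "C", "G", "T")) {
  nops <- sample(1:3, 1)
  cig <- ""; qlen <- 0L
  lead <- sample(c(0L, 3L), 1, prob = c(0.8, 0.2))
  if (lead > 0L) { cig <- paste0(lead, "S"); qlen <- qlen + lead }
  for (k in seq_len(nops)) {
    m <- sample(10:40, 1)
    cig <- paste0(cig, m, "M"); qlen <- qlen + m
    if (k < nops) {
      t <- sample(c("I", "D"), 1)
      n <- sample(1:5, 1)
      cig <- paste0(cig, n, t)
      if (t == "I") qlen <- qlen + n
    }
  }
  seq <- paste(sample(rng_bases, qlen, replace = TRUE), collapse = "")
  list(qname = sprintf("rr%04d", i), flag = 0L, chrom = chrom, pos = pos,
       mapq = 60L, cigar = cig, seq = seq)
}

## ---- preset pipeline cache ------------------------------------------------

## One generated preset bundle + parsed modalities shared across tests.
preset_pipeline <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    dir <- file.path(tempdir(), "triomics-preset")
    b <- generate_fixtures(preset_mm_case(), dir)
    g <- build_graph(b$associations, b$loci)
    pv <- parse_variants(b$vcf, g)
    pg <- parse_cuffdiff_genes(b$gene_diff, g)
    pi <- parse_cuffdiff_isoforms(b$isoform_diff, g)
    pp <- parse_probe_table(b$probes)
    cache <<- list(
      bundle = b, graph = g,
      variants = pv, genes = pg, isoforms = pi, probes = pp,
      groups = read_groups_table(b$groups),
      ds = list(
        wes = associate(pv$records, g, "wes"),
        rnaseq_gene = associate(pg$records, g, "rnaseq_gene"),
        rnaseq_isoform = associate(pi$records, g, "rnaseq_isoform"),
        microarray = associate(pp$records, g, "microarray")))
    cache
  }
})
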