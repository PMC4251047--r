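## IGV batch automation: one call builds the command script that loads every
## track for an experiment (variants, RNA alignments, DNA alignments,
## assembly GTF) and jumps to the gene of interest, then ships it over IGV's
## plain-text TCP batch port.

#' Describe an IGV session
#'
#' @param genome_id IGV genome id, e.g. `"hg19"`.
#' @param tracks Ordered character vector of track file paths (VCF / BAM /
#'   GTF), loaded in order.
#' @param target Optional jump target: a `genomic_locus`, a
#'   `gene_identity`, or a gene identifier string resolved through `graph`.
#' @param snapshot_path Optional path for a `snapshot` command.
#' @param graph Optional `id_graph` used to resolve a gene target's locus.
#' @return An `igv_session`.
#' @export
igv_session <- function(genome_id = "hg19", tracks = character(),
                        target = NULL, snapshot_path = NULL, graph = NULL) {
  stopifnot(nzchar(genome_id), all(nzchar(tracks)))
  if (is.character(target)) {
    if (is.null(graph)) stop("a gene target needs an id_graph to resolve its locus")
    gid <- resolve_row_identity(gene_id = target, graph = graph)
    if (gid$unresolved)
      gid <- resolve_row_identity(symbol = target, graph = graph)
    if (gid$unresolved || is.null(gid$locus))
      stop("cannot resolve a locus for gene target: ", target)
    target <- gid$locus
  }
  if (inherits(target, "gene_identity")) {
    if (is.null(target$locus)) stop("gene target carries no locus")
    target <- target$locus
  }
  if (!is.null(target)) stopifnot(inherits(target, "genomic_locus"))
  structure(list(genome_id = genome_id, tracks = as.character(tracks),
                 target = target, snapshot_path = snapshot_path),
            class = "igv_session")
}

#' Build an IGV batch command script
#'
#' Deterministic line sequence: `new`; `genome <id>`; one `load <path>` per
#' track in order; `goto chr:start-end` (1-based inclusive, no thousands
#' separators) if a target is set; `snapshot <path>` if requested. Paths are
#' passed verbatim; no line is ever empty.
#'
#' @param session An `igv_session`.
#' @return An `igv_command_script` (list with `lines`).
#' @export
build_script <- function(session) {
  stopifnot(inherits(session, "igv_session"))
  lines <- c("new", paste("genome", session$genome_id))
  for (tr in session$tracks) lines <- c(lines, paste("load", tr))
  if (!is.null(session$target))
    lines <- c(lines, paste("goto", locus_to_string(session$target)))
  if (!is.null(session$snapshot_path))
    lines <- c(lines, paste("snapshot", session$snapshot_path))
  structure(list(lines = lines), class = "igv_command_script")
}

#' @export
print.igv_command_script <- function(x, ...) {
  cat(x$lines, sep = "\n"); cat("\n")
  invisible(x)
}

#' Send an IGV batch script over TCP
#'
#' Opens a plain text socket to a running IGV instance (default batch port
#' 60151), sends each command line terminated by a newline, and reads one
#' response line per command. A non-`OK` response aborts with a message
#' citing the offending command.
#'
#' @param script An `igv_command_script`.
#' @param host Host name (default `"127.0.0.1"`).
#' @param port TCP port (default 60151, IGV's documented batch port).
#' @param timeout Per-response timeout in seconds.
#' @return Character vector of per-line acknowledgements.
#' @export
igv_send <- function(script, host = "127.0.0.1", port = 60151L, timeout = 10) {
  stopifnot(inherits(script, "igv_command_script"))
  con <- tryCatch(
    socketConnection(host = host, port = port, blocking = TRUE,
                     open = "r+", timeout = timeout),
    error = function(e) stop("cannot connect to IGV at ", host, ":", port,
                             " (", conditionMessage(e), ")", call. = FALSE),
    warning = function(w) stop("cannot connect to IGV at ", host, ":", port,
                               " (", conditionMessage(w), ")", call. = FALSE))
  on.exit(close(con))
  acks <- character(length(script$lines))
  for (i in seq_along(script$lines)) {
    writeLines(script$lines[i], con)
    flush(con)
    resp <- readLines(con, n = 1L)
    if (length(resp) == 0L) resp <- ""
    acks[i] <- resp
    if (!identical(resp, "OK"))
      stop("IGV rejected command ", i, " ('", script$lines[i], "'): ",
           resp, call. = FALSE)
  }
  acks
}
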