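#' Read a FASTA file with soft-mask capture
#'
#' Standard FASTA with LF or CRLF line endings.  Lowercase runs are recorded
#' as soft-mask intervals (0-based half-open).  IUPAC ambiguity codes are
#' accepted and flagged; symbols outside the IUPAC nucleotide alphabet are
#' rejected with the offending line number.  Duplicate identifiers are an
#' error in database mode.
#'
#' Sequence case matters here (lowercase marks low-complexity regions), so
#' parsing is done directly rather than through containers that normalise
#' case.
#'
#' @param path FASTA file.
#' @param mode `"database"` or `"query"`.
#' @return list with `records` (data.frame: `id`, `seq`, `has_ambiguous`)
#'   and `masks` (list of per-record two-column interval matrices).
#' @export
read_fasta <- function(path, mode = c("database", "query")) {
  mode <- match.arg(mode)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  if (!length(lines) || !any(nzchar(lines)))
    stop("empty FASTA file: ", path)
  ids <- character(0); seqs <- character(0)
  cur <- NULL; buf <- character(0)
  flush <- function() {
    if (!is.null(cur)) {
      ids <<- c(ids, cur)
      seqs <<- c(seqs, paste(buf, collapse = ""))
    }
  }
  for (ln in seq_along(lines)) {
    line <- lines[ln]
    if (!nzchar(line)) next
    if (startsWith(line, ">")) {
      flush()
      cur <- sub("\\s.*$", "", substring(line, 2))
      if (!nzchar(cur))
        stop("malformed FASTA header at line ", ln, " of ", path)
      buf <- character(0)
    } else {
      if (is.null(cur))
        stop("sequence data before any header at line ", ln, " of ", path)
      if (grepl("[^ACGTRYSWKMBDHVNacgtryswkmbdhvn]", line))
        stop("non-IUPAC nucleotide symbol at line ", ln, " of ", path)
      buf <- c(buf, line)
    }
  }
  flush()
  if (!length(ids)) stop("no FASTA records in ", path)
  if (mode == "database" && anyDuplicated(ids))
    stop("duplicate sequence identifier in database FASTA: ",
         ids[duplicated(ids)][1])
  masks <- lapply(seqs, function(s) {
    lower <- grepl("[a-z]", strsplit(s, "")[[1]])
    r <- rle(lower)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    cbind(start = starts[r$values], end = ends[r$values])
  })
  has_amb <- grepl("[RYSWKMBDHVNryswkmbdhvn]", seqs)
  list(records = data.frame(id = ids, seq = toupper(seqs),
                            has_ambiguous = has_amb,
                            stringsAsFactors = FALSE),
       masks = masks)
}

.fmt_evalue <- function(e) {
  vapply(e, function(x) {
    if (x < 1e-179) "0.0"
    else if (x < 1e-3) sprintf("%.2e", x)
    else sprintf("%.3g", x)
  }, character(1))
}

# One tabular line per HSP; coordinates converted to 1-based inclusive with
# sstart > send on the minus strand (BLAST convention).
.tabular_rows <- function(h, subject_len) {
  L <- subject_len[h$subject]
  sstart <- ifelse(h$strand == "+", h$s_start + 1L, L - h$s_start)
  send <- ifelse(h$strand == "+", h$s_end + 1L, L - h$s_end)
  sprintf("%s\t%s\t%.3f\t%d\t%d\t%d\t%d\t%d\t%d\t%d\t%s\t%.1f",
          h$query_id, h$subject_id, 100 * h$nid / h$aln_len,
          as.integer(h$aln_len), as.integer(h$nmis), as.integer(h$ngapopen),
          h$q_start + 1L, h$q_end + 1L, as.integer(sstart), as.integer(send),
          .fmt_evalue(h$evalue), h$bitscore)
}

#' Write BLAST-style tabular output (formats 6 and 7)
#'
#' Twelve standard columns: qseqid, sseqid, pident, length, mismatch,
#' gapopen, qstart, qend, sstart, send, evalue, bitscore.  Hits are sorted
#' per query by (evalue ascending, bitscore descending, sseqid, sstart);
#' format 7 adds per-query comment headers and a hit-count footer.
#'
#' @param hsps HSP data.frame (frame coordinates, as from [extend_seeds()]).
#' @param query_ids character vector of all query ids, in input order (so
#'   zero-hit queries still get format-7 headers).
#' @param index the `fmd_index` searched (for subject lengths and the
#'   database name).
#' @param format 6 (plain) or 7 (commented).
#' @param db_name database label for format-7 headers.
#' @return character vector of output lines.
#' @export
write_tabular <- function(hsps, query_ids, index, format = 7L,
                          db_name = "db") {
  format <- as.integer(format)
  if (!format %in% c(6L, 7L)) stop("output format must be 6 or 7")
  subject_len <- index$layout$len[index$layout$strand == "+"]
  lines <- character(0)
  for (qid in query_ids) {
    h <- hsps[hsps$query_id == qid, , drop = FALSE]
    if (nrow(h)) {
      L <- subject_len[h$subject]
      sstart <- ifelse(h$strand == "+", h$s_start + 1L, L - h$s_start)
      o <- order(h$evalue, -h$bitscore, h$subject_id, sstart,
                 method = "radix")
      h <- h[o, , drop = FALSE]
    }
    if (format == 7L) {
      lines <- c(lines,
                 paste0("# fmdblast ", as.character(utils::packageVersion("fmdblast"))),
                 paste0("# Query: ", qid),
                 paste0("# Database: ", db_name))
      if (nrow(h))
        lines <- c(lines, paste0("# Fields: query id, subject id, ",
                                 "% identity, alignment length, mismatches, ",
                                 "gap opens, q. start, q. end, s. start, ",
                                 "s. end, evalue, bit score"))
      lines <- c(lines, sprintf("# %d hits found", nrow(h)))
    }
    if (nrow(h)) lines <- c(lines, .tabular_rows(h, subject_len))
  }
  lines
}
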