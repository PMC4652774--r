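#' Build the bidirectional sequence text for indexing
#'
#' Concatenates every subject with its reverse complement, each segment
#' terminated by the sentinel `$`.  Ambiguous IUPAC symbols are replaced by
#' uniform draws from A/C/G/T under `seed` and logged, so an index built from
#' the same input and seed is reproducible.  Soft-mask intervals (from
#' lowercase FASTA runs) are carried along for use at seeding time.
#'
#' @param seqs named character vector of subject sequences (names are subject
#'   ids), or a data.frame with columns `id` and `seq`.
#' @param masks optional list, one element per subject, each a two-column
#'   matrix of 0-based half-open `[start, end)` soft-masked intervals.
#' @param seed integer seed for ambiguity replacement.
#' @return an object of class `fmd_text` with elements `codes` (the full
#'   concatenated symbol codes including sentinels), `layout` (one row per
#'   segment: subject index, id, strand, 0-based global start, length),
#'   `subjects` (per-subject plus-strand code vectors after replacement),
#'   `ambiguity_log`, `mask` and `seed`.
#' @export
fmd_text <- function(seqs, masks = NULL, seed = 1L) {
  if (is.data.frame(seqs)) {
    ids <- as.character(seqs$id)
    seqs <- as.character(seqs$seq)
  } else {
    ids <- names(seqs)
    seqs <- as.character(seqs)
  }
  if (length(seqs) == 0L) stop("empty input: at least one subject is required")
  if (is.null(ids) || any(!nzchar(ids)))
    stop("every subject must have a non-empty id")
  if (anyDuplicated(ids)) stop("duplicate subject ids: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (any(nchar(seqs) == 0L))
    stop("empty subject sequence: ", ids[which(nchar(seqs) == 0L)[1]])

  subjects <- vector("list", length(seqs))
  amb <- list()
  for (i in seq_along(seqs)) {
    codes <- dna_codes(seqs[[i]])
    bad <- which(is.na(codes))
    if (length(bad))
      stop("subject '", ids[i], "' has a symbol outside the IUPAC nucleotide ",
           "alphabet at position ", bad[1], " ('",
           substr(seqs[[i]], bad[1], bad[1]), "')")
    ambi <- which(codes == 0L)
    if (length(ambi))
      amb[[length(amb) + 1L]] <- data.frame(
        subject_id = ids[i], offset = ambi - 1L,
        original = substring(seqs[[i]], ambi, ambi),
        stringsAsFactors = FALSE)
    subjects[[i]] <- codes
  }
  amb <- if (length(amb)) do.call(rbind, amb) else
    data.frame(subject_id = character(0), offset = integer(0),
               original = character(0), stringsAsFactors = FALSE)

  # seeded replacement, in subject order then position order
  n_amb <- nrow(amb)
  repl <- if (n_amb) with_rng_seed(seed, sample.int(4L, n_amb, replace = TRUE))
          else integer(0)
  amb$replacement <- ALPHABET[repl + 1L]
  j <- 0L
  for (i in seq_along(subjects)) {
    k <- which(amb$subject_id == ids[i])
    if (length(k)) subjects[[i]][amb$offset[k] + 1L] <- repl[k]
  }

  lens <- lengths(subjects)
  pieces <- vector("list", 2L * length(subjects))
  layout <- data.frame(subject = rep(seq_along(subjects), each = 2L),
                       id = rep(ids, each = 2L),
                       strand = rep(c("+", "-"), length(subjects)),
                       start = 0L, len = rep(lens, each = 2L),
                       stringsAsFactors = FALSE)
  pos <- 0L
  for (i in seq_along(subjects)) {
    fw <- c(subjects[[i]], 0L)
    rc <- c(revcomp_codes(subjects[[i]]), 0L)
    pieces[[2L * i - 1L]] <- fw
    pieces[[2L * i]] <- rc
    layout$start[2L * i - 1L] <- pos
    pos <- pos + length(fw)
    layout$start[2L * i] <- pos
    pos <- pos + length(rc)
  }

  mask <- if (is.null(masks)) {
    data.frame(subject_id = character(0), start = integer(0),
               end = integer(0), stringsAsFactors = FALSE)
  } else {
    rows <- list()
    for (i in seq_along(masks)) {
      mi <- masks[[i]]
      if (is.null(mi) || NROW(mi) == 0L) next
      mi <- matrix(as.integer(mi), ncol = 2L)
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = ids[i], start = mi[, 1L], end = mi[, 2L],
        stringsAsFactors = FALSE)
    }
    if (length(rows)) do.call(rbind, rows) else
      data.frame(subject_id = character(0), start = integer(0),
                 end = integer(0), stringsAsFactors = FALSE)
  }

  structure(list(codes = unlist(pieces), layout = layout, subjects = subjects,
                 ids = ids, ambiguity_log = amb, mask = mask,
                 seed = as.integer(seed)),
            class = "fmd_text")
}

#' @export
print.fmd_text <- function(x, ...) {
  cat("fmd_text:", length(x$ids), "subject(s),", length(x$codes),
      "symbols (both strands, sentinels included),",
      nrow(x$ambiguity_log), "ambiguous position(s) replaced\n")
  invisible(x)
}
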