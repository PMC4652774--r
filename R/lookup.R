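#' 2-bit integer code of a k-mer
#'
#' A=0, C=1, G=2, T=3, leftmost symbol most significant; bijective on k-mers
#' over A/C/G/T.  Words containing ambiguous symbols are uncodable and yield
#' `NA` (callers skip those positions).
#'
#' @param word character vector of equal-length words, or an integer vector
#'   of symbol codes (1..4) for a single word.
#' @return integer vector of 0-based codes, `NA` where uncodable.
#' @export
kmer_code <- function(word) {
  one <- function(codes) {
    if (any(is.na(codes)) || any(codes < 1L | codes > 4L)) return(NA_integer_)
    k <- length(codes)
    as.integer(sum((codes - 1L) * 4^(k - seq_len(k))))
  }
  if (is.character(word)) {
    vapply(word, function(wd) one(dna_codes(wd)), integer(1), USE.NAMES = FALSE)
  } else {
    one(as.integer(word))
  }
}

# Inverse of kmer_code for a fixed k (used by tests and hard exclusion).
kmer_decode <- function(code, k) {
  out <- character(length(code))
  for (t in seq_along(code)) {
    c0 <- code[t]
    syms <- integer(k)
    for (i in k:1) { syms[i] <- c0 %% 4L; c0 <- c0 %/% 4L }
    out[t] <- paste(c("A", "C", "G", "T")[syms + 1L], collapse = "")
  }
  out
}

#' Build the 4^k-entry k-mer lookup table
#'
#' Each entry stores the bi-interval of one k-mer, equal to k successive
#' backward extensions from the empty-pattern interval.  The table is filled
#' by a depth-first walk of the 4-ary k-mer trie that prunes empty intervals,
#' so the cost is proportional to the number of distinct k-mers present.
#'
#' @param index an `fmd_index`.
#' @param k word length, `1 <= k <= 14`.
#' @param hard_exclude_masked if `TRUE`, zero the entries of k-mers whose
#'   database occurrences all lie inside soft-masked spans.  Off by default:
#'   masking is normally applied on the query side at seeding time.
#' @return an object of class `kmer_table` with fields `k`, `lower`,
#'   `lower_rc`, `size` (each of length 4^k) and `hard_excluded`.
#' @export
build_lookup <- function(index, k, hard_exclude_masked = FALSE) {
  k <- as.integer(k)
  if (is.na(k) || k < 1L || k > 14L)
    stop("k must be in 1..14; a table with k = ", k, " would need about ",
         format(3 * 4 * 4^max(k, 1, na.rm = TRUE) / 2^30, digits = 3),
         " GiB for its 4^k entries")
  ent <- build_lookup_cpp(index$bwt, index$cp, index$cprate, index$C,
                          k, index$n)
  tab <- structure(list(k = k, lower = ent$lower, lower_rc = ent$lower_rc,
                        size = ent$size, hard_excluded = hard_exclude_masked),
                   class = "kmer_table")
  if (hard_exclude_masked && nrow(index$text$mask) > 0L) {
    present <- which(tab$size > 0L)
    for (ci in present) {
      bi <- bi_interval(tab$lower[ci], tab$lower_rc[ci], tab$size[ci])
      hits <- fmd_locate(index, bi, plen = k)
      if (all(.in_mask(index$text$mask, hits, k)))
        tab$size[ci] <- 0L
    }
  }
  tab
}

# TRUE per hit when the k-length window lies entirely inside a masked span
# of its subject (plus-strand coordinates).
.in_mask <- function(mask, hits, k) {
  vapply(seq_len(nrow(hits)), function(i) {
    m <- mask[mask$subject_id == hits$subject_id[i], , drop = FALSE]
    any(m$start <= hits$offset[i] & hits$offset[i] + k <= m$end)
  }, logical(1))
}

#' @export
print.kmer_table <- function(x, ...) {
  occ <- sum(x$size > 0L)
  cat(sprintf("kmer_table: k=%d, %d/%d entries occupied (%.2f%%)\n",
              x$k, occ, length(x$size), 100 * occ / length(x$size)))
  invisible(x)
}

#' Fetch the bi-interval of a word from the lookup table
#'
#' Constant-time fetch; absent or uncodable words give the empty interval.
#'
#' @param table a `kmer_table`.
#' @param word a k-length word (character) or its integer code.
#' @return a `bi_interval`.
#' @export
lookup <- function(table, word) {
  code <- if (is.numeric(word) && length(word) == 1L && is.na(word))
    NA_integer_
  else if (is.numeric(word) && length(word) == 1L)
    as.integer(word)
  else kmer_code(word)
  if (is.na(code)) return(bi_empty())
  if (code < 0L || code >= length(table$size))
    stop("k-mer code out of range for k = ", table$k)
  bi_interval(table$lower[code + 1L], table$lower_rc[code + 1L],
              table$size[code + 1L])
}
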