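CHECKPOINT_RATE <- 128L
INDEX_MAGIC <- "FMDBLAST-INDEX"
INDEX_VERSION <- 1L

#' Bi-interval constructor
#'
#' The triple `[lower, lower_rc, size]` locating a pattern P in the FMD-index:
#' `lower` is the lower bound of P's suffix-array interval, `lower_rc` the
#' lower bound of the interval of P's reverse complement, and `size` the
#' (shared) interval size.  `size == 0` means the pattern is absent.
#'
#' @param lower,lower_rc,size integers.
#' @return a list of class `bi_interval`.
#' @export
bi_interval <- function(lower, lower_rc, size) {
  structure(list(lower = as.integer(lower), lower_rc = as.integer(lower_rc),
                 size = as.integer(size)), class = "bi_interval")
}

#' @rdname bi_interval
#' @export
bi_empty <- function() bi_interval(0L, 0L, 0L)

#' @rdname bi_interval
#' @param index an `fmd_index`.
#' @export
bi_root <- function(index) bi_interval(0L, 0L, index$n)

#' Swap a bi-interval with that of its reverse complement
#' @param bi a `bi_interval`.
#' @keywords internal
bi_swap <- function(bi) bi_interval(bi$lower_rc, bi$lower, bi$size)

#' @export
print.bi_interval <- function(x, ...) {
  cat(sprintf("bi_interval [lower=%d, lower_rc=%d, size=%d]\n",
              x$lower, x$lower_rc, x$size))
  invisible(x)
}

# Core FM-index construction over an arbitrary code vector (sentinel = 0).
# Sentinels are disambiguated by text position when sorting suffixes; an
# exact LF target is recorded for every sentinel occurrence in the BWT so
# that the sampled-SA walk stays correct across segment boundaries.
.build_fm <- function(codes, layout, r) {
  n <- length(codes)
  is_dollar <- codes == 0L
  nsent <- sum(is_dollar)
  keys <- integer(n)
  keys[is_dollar] <- seq_len(nsent) - 1L
  keys[!is_dollar] <- nsent + codes[!is_dollar] - 1L
  sa <- sa_prefix_doubling(keys)          # 0-based
  isa <- integer(n)
  isa[sa + 1L] <- seq_len(n) - 1L

  bwt <- integer(n)                        # B[i] = T[SA[i]-1], else $
  nz <- sa > 0L
  bwt[nz] <- codes[sa[nz]]
  counts <- tabulate(codes + 1L, nbins = 5L)
  C <- c(0L, cumsum(counts)[1:4])

  nb <- n %/% CHECKPOINT_RATE
  cp <- matrix(0L, nrow = 5L, ncol = nb + 1L)
  if (nb > 0L) {
    for (a in 0:4) {
      cs <- cumsum(bwt == a)
      cp[a + 1L, 2:(nb + 1L)] <- cs[seq_len(nb) * CHECKPOINT_RATE]
    }
  }

  dollar_pos <- which(bwt == 0L) - 1L     # ranks with a sentinel in the BWT
  dollar_lf <- integer(length(dollar_pos))
  for (t in seq_along(dollar_pos)) {
    sv <- sa[dollar_pos[t] + 1L]
    dollar_lf[t] <- if (sv > 0L) isa[sv] else isa[n]  # wrap at suffix 0
  }
  rank0 <- isa[1L]
  rank_last <- isa[n]
  sampled <- sa[seq(1L, n, by = r)]

  list(bwt = bwt, cp = cp, cprate = CHECKPOINT_RATE, C = C,
       dollar_pos = dollar_pos, dollar_lf = dollar_lf,
       rank0 = rank0, rank_last = rank_last,
       sampled = sampled, r = as.integer(r), n = n, layout = layout)
}

#' Build the FMD-index of a sequence text
#'
#' Constructs the suffix array (prefix doubling), BWT, cumulative counts C,
#' checkpointed occurrence array and a rank-sampled suffix array over the
#' bidirectional text produced by [fmd_text()].
#'
#' @param text an `fmd_text`.
#' @param r suffix-array sampling interval; every r-th rank of the suffix
#'   array is stored explicitly (default 8).
#' @return an object of class `fmd_index`.
#' @export
fmd_index <- function(text, r = 8L) {
  stopifnot(inherits(text, "fmd_text"))
  r <- as.integer(r)
  if (is.na(r) || r < 1L) stop("sampling interval r must be a positive integer")
  fm <- .build_fm(text$codes, text$layout, r)
  fm$text <- text
  fm$lookup <- NULL
  class(fm) <- "fmd_index"
  fm
}

#' @export
print.fmd_index <- function(x, ...) {
  cat(sprintf("fmd_index: n=%d, r=%d, %d subject(s)%s\n", x$n, x$r,
              length(x$text$ids),
              if (!is.null(x$lookup)) sprintf(", k-mer table (k=%d) attached",
                                              x$lookup$k) else ""))
  invisible(x)
}

#' Backward extension of a bi-interval
#'
#' Given `bi` = omega(P), returns omega(aP).  The size can only shrink; it
#' becomes 0 when aP is absent from the bidirectional text.
#'
#' @param index an `fmd_index`.
#' @param bi a `bi_interval` valid for this index.
#' @param a a symbol in `{$,A,C,G,T}` (character) or its code 0..4.
#' @return a `bi_interval` for aP.
#' @export
backward_ext <- function(index, bi, a) {
  code <- sym_code(a)
  if (bi$size == 0L) return(bi_empty())
  m <- fmd_ext_all_cpp(index$bwt, index$cp, index$cprate, index$C,
                       bi$lower, bi$lower_rc, bi$size)
  bi_interval(m[code + 1L, 1L], m[code + 1L, 2L], m[code + 1L, 3L])
}

#' Forward extension of a bi-interval
#'
#' Returns omega(Pa) via the bi-interval symmetry: backward-extend the
#' reverse complement by the complement symbol and swap the bounds.
#'
#' @inheritParams backward_ext
#' @export
forward_ext <- function(index, bi, a) {
  code <- sym_code(a)
  bi_swap(backward_ext(index, bi_swap(bi), comp_codes(code)))
}

# All five backward extensions at once (rows $,A,C,G,T); internal fast path.
.ext_all <- function(index, bi) {
  fmd_ext_all_cpp(index$bwt, index$cp, index$cprate, index$C,
                  bi$lower, bi$lower_rc, bi$size)
}

#' Suffix array lookup through the sampled SA
#'
#' Returns SA[k] by walking the LF-mapping from rank k until a rank divisible
#' by the sampling interval r is reached (at most r-1 steps), then adding the
#' number of steps to the stored sample.
#'
#' @param index an `fmd_index`.
#' @param k integer vector of ranks in `[0, n)`.
#' @return integer vector of text positions.
#' @export
sa_lookup <- function(index, k) {
  k <- as.integer(k)
  if (any(is.na(k)) || any(k < 0L) || any(k >= index$n))
    stop("rank out of range [0, ", index$n, ")")
  fmd_sa_lookup_cpp(index$bwt, index$cp, index$cprate, index$C,
                    index$dollar_pos, index$dollar_lf, index$rank0,
                    index$sampled, index$r, k)
}

#' One LF-mapping step
#'
#' Maps each rank to the rank of the suffix starting one text position
#' earlier; the rank of suffix 0 wraps to the rank of the last suffix, making
#' LF a permutation of `[0, n)`.
#'
#' @inheritParams sa_lookup
#' @export
lf_map <- function(index, k) {
  k <- as.integer(k)
  if (any(k < 0L) || any(k >= index$n)) stop("rank out of range")
  fmd_lf_cpp(index$bwt, index$cp, index$cprate, index$C,
             index$dollar_pos, index$dollar_lf, index$rank0,
             index$rank_last, k)
}

#' Locate all occurrences of a bi-interval
#'
#' Maps every rank in the interval through the sampled suffix array and the
#' segment layout to per-subject coordinates.  Hits found in a
#' reverse-complement segment are reported on the minus strand; when the
#' pattern length `plen` is supplied their offset is converted to the
#' plus-strand start `L - p - plen` (subject length L, segment offset p),
#' otherwise the raw segment offset is returned.
#'
#' @param index an `fmd_index`.
#' @param bi a `bi_interval`; an empty interval yields zero rows.
#' @param plen optional pattern length for minus-strand coordinate conversion.
#' @return data.frame with columns `subject_id`, `subject` (index), `offset`
#'   (0-based) and `strand`.
#' @export
fmd_locate <- function(index, bi, plen = NULL) {
  if (bi$size == 0L)
    return(data.frame(subject_id = character(0), subject = integer(0),
                      offset = integer(0), strand = character(0),
                      stringsAsFactors = FALSE))
  ranks <- seq.int(bi$lower, bi$lower + bi$size - 1L)
  pos <- sa_lookup(index, ranks)
  lay <- index$layout
  seg <- findInterval(pos, lay$start)
  offset <- pos - lay$start[seg]
  strand <- lay$strand[seg]
  if (!is.null(plen)) {
    m <- strand == "-"
    offset[m] <- lay$len[seg[m]] - offset[m] - as.integer(plen)
  }
  data.frame(subject_id = lay$id[seg], subject = lay$subject[seg],
             offset = offset, strand = strand, stringsAsFactors = FALSE)
}

# omega(P) by |P| successive backward extensions from the root interval.
# Ambiguous or invalid symbols make the interval empty.
bi_from_pattern <- function(index, pattern) {
  codes <- if (is.character(pattern)) dna_codes(pattern) else as.integer(pattern)
  bi <- bi_root(index)
  for (a in rev(codes)) {
    if (is.na(a) || a < 1L || a > 4L) return(bi_empty())
    bi <- backward_ext(index, bi, a)
    if (bi$size == 0L) return(bi_empty())
  }
  bi
}

#' Save an FMD-index bundle to disk
#'
#' The bundle is a single serialized file carrying a magic string, a format
#' version, the sampling interval, the ambiguity-replacement seed, the layout
#' table, the ambiguity log and (if built) the k-mer lookup table.  Saving is
#' deterministic: the same index yields byte-identical files.
#'
#' @param index an `fmd_index` (optionally with a lookup table attached).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_index <- function(index, path) {
  stopifnot(inherits(index, "fmd_index"))
  payload <- unclass(index)
  obj <- list(magic = INDEX_MAGIC, version = INDEX_VERSION,
              r = index$r, seed = index$text$seed,
              k = if (!is.null(index$lookup)) index$lookup$k else NA_integer_,
              payload = payload)
  saveRDS(obj, path, version = 2L, compress = FALSE)
  invisible(path)
}

#' @rdname save_index
#' @export
load_index <- function(path) {
  if (!file.exists(path)) stop("index bundle not found: ", path)
  obj <- tryCatch(readRDS(path), error = function(e)
    stop("corrupt or truncated index bundle: ", path))
  if (!is.list(obj) || !identical(obj$magic, INDEX_MAGIC))
    stop("not an fmdblast index bundle (bad magic): ", path)
  if (!identical(obj$version, INDEX_VERSION))
    stop("index bundle version ", obj$version, " is not supported (expected ",
         INDEX_VERSION, ")")
  idx <- obj$payload
  class(idx) <- "fmd_index"
  class(idx$text) <- "fmd_text"
  idx
}
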