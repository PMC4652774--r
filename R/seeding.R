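#' Seeding parameters
#'
#' @param w seed length (exact-match length reported as a seed), `w >= k`.
#' @param k word length of the lookup table.
#' @param stride scan step between sampled query positions; the default
#'   `w - k + 1` is the largest stride that still guarantees every w-length
#'   exact match is found.
#' @return a list of class `seeding_params`.
#' @export
seeding_params <- function(w = 28L, k = 11L, stride = w - k + 1L) {
  w <- as.integer(w); k <- as.integer(k); stride <- as.integer(stride)
  if (k < 1L) stop("k must be >= 1")
  if (w < k) stop("seed length w (", w, ") must be >= table word length k (",
                  k, ")")
  if (stride < 1L || stride > w - k + 1L)
    stop("stride must be in [1, w - k + 1]")
  structure(list(w = w, k = k, stride = stride), class = "seeding_params")
}

#' Find the bi-intervals of all w-length exact matches of a query
#'
#' Scans the query at positions 0, stride, 2*stride, ...; for each codable
#' k-mer the bi-interval is fetched from the lookup table, extended backward
#' symbol by symbol, and each backward prefix is completed rightward by
#' forward extension to the full window length w.  Every window of length w
#' whose bi-interval is non-empty is emitted exactly once, which makes the
#' located seed set complete (every exact w-match on either strand is found)
#' and sound (nothing else is).  Ambiguous query symbols terminate
#' extensions as mismatches; stride positions whose k-mer is uncodable or
#' lies entirely inside a soft-masked query span are skipped.
#'
#' @param query query sequence (character string) or its symbol codes.
#' @param index an `fmd_index`.
#' @param table the `kmer_table` of the index; its `k` must match `params$k`.
#' @param params a [seeding_params()] object.
#' @param query_mask optional two-column matrix of 0-based half-open masked
#'   intervals on the query.
#' @return data.frame of seed intervals: `q_start` (0-based query offset of
#'   the w-window), `length` (= w), `lower`, `lower_rc`, `size`.
#' @export
find_seed_intervals <- function(query, index, table, params,
                                query_mask = NULL) {
  stopifnot(inherits(params, "seeding_params"))
  if (table$k != params$k)
    stop("lookup table word length (", table$k, ") does not match params$k (",
         params$k, ")")
  q <- if (is.character(query)) dna_codes(query) else as.integer(query)
  q[is.na(q)] <- 0L
  n <- length(q)
  w <- params$w; k <- params$k; stride <- params$stride
  empty <- data.frame(q_start = integer(0), length = integer(0),
                      lower = integer(0), lower_rc = integer(0),
                      size = integer(0))
  if (n < w) return(empty)

  masked_pos <- if (!is.null(query_mask) && NROW(query_mask) > 0L) {
    qm <- matrix(as.integer(query_mask), ncol = 2L)
    function(i) any(qm[, 1L] <= i & i + k <= qm[, 2L])
  } else function(i) FALSE

  done <- logical(n - w + 1L)    # done[a+1]: window at a emitted or ruled out
  res <- list(); nres <- 0L

  for (i in seq.int(0L, n - k, by = stride)) {
    kcodes <- q[(i + 1L):(i + k)]
    if (any(kcodes < 1L | kcodes > 4L)) next
    if (masked_pos(i)) next
    code <- kmer_code(kcodes)
    bi <- lookup(table, code)
    if (bi$size == 0L) {
      # windows containing this k-mer cannot match
      a_lo <- max(0L, i + k - w); a_hi <- min(i, n - w)
      if (a_hi >= a_lo) done[(a_lo:a_hi) + 1L] <- TRUE
      next
    }
    a_lo <- max(0L, i + k - w); a_hi <- min(i, n - w)
    if (a_hi < a_lo) next
    cur <- bi
    j <- i
    repeat {
      if (j <= a_hi && j >= a_lo && !done[j + 1L]) {
        # complete the window [j, j+w) rightward from omega(Q[j, i+k-1])
        win <- cur
        ok <- TRUE
        ext_to <- j + w - 1L
        if (ext_to > i + k - 1L) {
          for (t in (i + k):ext_to) {
            sym <- q[t + 1L]
            if (sym < 1L || sym > 4L) { ok <- FALSE; break }
            win <- forward_ext(index, win, sym)
            if (win$size == 0L) { ok <- FALSE; break }
          }
        }
        if (ok && win$size > 0L) {
          nres <- nres + 1L
          res[[nres]] <- c(j, win$lower, win$lower_rc, win$size)
        }
        done[j + 1L] <- TRUE
      }
      if (j == a_lo) break
      j <- j - 1L
      sym <- q[j + 1L]
      if (sym < 1L || sym > 4L) {
        # an ambiguous symbol sits inside every remaining window
        done[(a_lo:min(j, a_hi)) + 1L] <- TRUE
        break
      }
      cur <- backward_ext(index, cur, sym)
      if (cur$size == 0L) {
        done[(a_lo:min(j, a_hi)) + 1L] <- TRUE
        break
      }
    }
  }
  if (nres == 0L) return(empty)
  m <- do.call(rbind, res)
  data.frame(q_start = m[, 1L], length = w, lower = m[, 2L],
             lower_rc = m[, 3L], size = m[, 4L])
}

#' Resolve seed intervals to exact seed positions
#'
#' Applies the sampled-suffix-array locate step to every seed interval and
#' converts global text positions to per-subject, per-strand coordinates.
#' Minus-strand hits are expressed as the plus-strand start of the matching
#' window (`L - p - w`); `s_frame` keeps the offset in the strand frame the
#' extension stage walks (the reverse-complemented subject for minus hits),
#' and `diag = s_frame - q_offset` is the seed's diagonal in that frame.
#'
#' @param index an `fmd_index`.
#' @param intervals data.frame from [find_seed_intervals()].
#' @param query_id identifier attached to the seeds.
#' @param dedupe drop duplicate `(q_offset, subject, strand, s_offset)` rows
#'   (default `TRUE`).
#' @return data.frame of seeds with columns `query_id`, `q_offset`,
#'   `subject`, `subject_id`, `s_offset`, `strand`, `length`, `s_frame`,
#'   `diag`.
#' @export
resolve_seeds <- function(index, intervals, query_id = "query",
                          dedupe = TRUE) {
  cols <- c("query_id", "q_offset", "subject", "subject_id", "s_offset",
            "strand", "length", "s_frame", "diag")
  if (nrow(intervals) == 0L) {
    out <- data.frame(query_id = character(0), q_offset = integer(0),
                      subject = integer(0), subject_id = character(0),
                      s_offset = integer(0), strand = character(0),
                      length = integer(0), s_frame = integer(0),
                      diag = integer(0), stringsAsFactors = FALSE)
    return(out[, cols])
  }
  parts <- vector("list", nrow(intervals))
  for (t in seq_len(nrow(intervals))) {
    w <- intervals$length[t]
    bi <- bi_interval(intervals$lower[t], intervals$lower_rc[t],
                      intervals$size[t])
    hits <- fmd_locate(index, bi, plen = w)
    if (nrow(hits) == 0L) next
    L <- index$layout$len[match(hits$subject, index$layout$subject)]
    s_frame <- ifelse(hits$strand == "+", hits$offset,
                      L - hits$offset - w)
    parts[[t]] <- data.frame(query_id = query_id,
                             q_offset = intervals$q_start[t],
                             subject = hits$subject,
                             subject_id = hits$subject_id,
                             s_offset = hits$offset, strand = hits$strand,
                             length = w, s_frame = as.integer(s_frame),
                             diag = as.integer(s_frame) - intervals$q_start[t],
                             stringsAsFactors = FALSE)
  }
  parts <- parts[!vapply(parts, is.null, logical(1))]
  if (!length(parts)) return(resolve_seeds(index, intervals[0, ], query_id))
  out <- do.call(rbind, parts)
  if (dedupe) {
    key <- paste(out$q_offset, out$subject, out$strand, out$s_offset,
                 sep = "\r")
    out <- out[!duplicated(key), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Sort seeds into extension order
#'
#' Orders by (query_id, subject, strand, diagonal, frame subject offset)
#' ascending, so seeds on the same diagonal cluster together with smaller
#' subject offsets first.  Stable and deterministic.
#'
#' @param seeds data.frame from [resolve_seeds()].
#' @return the sorted data.frame.
#' @export
sort_seeds <- function(seeds) {
  if (nrow(seeds) == 0L) return(seeds)
  o <- order(seeds$query_id, seeds$subject, match(seeds$strand, c("+", "-")),
             seeds$diag, seeds$s_frame, method = "radix")
  out <- seeds[o, , drop = FALSE]
  rownames(out) <- NULL
  out
}
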