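#' Scoring and cutoff parameters for extension
#'
#' Defaults follow common BLASTN-style nucleotide scoring: match +1,
#' mismatch -2, affine gaps costing `gap_open + g * gap_extend` for a gap of
#' length g.  X-drop values are raw scores.  The ungapped score that
#' triggers a gapped extension is derived from `gap_trigger_bits` via
#' Karlin-Altschul inversion, and the final cutoff keeps HSPs with E-value
#' at most `evalue_cutoff`.
#'
#' @param reward match reward (> 0).
#' @param penalty mismatch penalty (< 0).
#' @param gap_open,gap_extend affine gap costs (non-negative).
#' @param xdrop_ungapped,xdrop_gapped X-drop termination thresholds (> 0).
#' @param gap_trigger_bits bit score whose raw equivalent triggers gapped
#'   extension.
#' @param evalue_cutoff final E-value cutoff.
#' @return a list of class `scoring_params`.
#' @export
scoring_params <- function(reward = 1L, penalty = -2L, gap_open = 5L,
                           gap_extend = 2L, xdrop_ungapped = 20L,
                           xdrop_gapped = 30L, gap_trigger_bits = 25,
                           evalue_cutoff = 10) {
  reward <- as.integer(reward); penalty <- as.integer(penalty)
  if (!(reward > 0L && penalty < 0L))
    stop("need reward > 0 > penalty")
  if (xdrop_ungapped <= 0L || xdrop_gapped <= 0L)
    stop("X-drop thresholds must be positive")
  structure(list(reward = reward, penalty = penalty,
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 xdrop_ungapped = as.integer(xdrop_ungapped),
                 xdrop_gapped = as.integer(xdrop_gapped),
                 gap_trigger_bits = gap_trigger_bits,
                 evalue_cutoff = evalue_cutoff),
            class = "scoring_params")
}

#' Diagonal of a seed
#'
#' `s_offset - q_offset`, computed within the seed's (subject, strand)
#' coordinate frame; seeds on one diagonal describe gap-free co-linear
#' matches.
#'
#' @param q_offset,s_offset 0-based offsets.
#' @return integer diagonal.
#' @export
seed_diagonal <- function(q_offset, s_offset) {
  as.integer(s_offset) - as.integer(q_offset)
}

#' Diagonal tracker for redundant-extension filtering
#'
#' Keeps, for every (query, subject, strand, diagonal), the diagonal offset
#' D produced by the last extended seed: the end subject offset of its
#' ungapped alignment.  Seeds arriving (in [sort_seeds()] order) with a
#' subject offset strictly smaller than D are redundant and are skipped;
#' an offset equal to D still triggers extension.
#'
#' @return an environment of class `diagonal_tracker`.
#' @export
diagonal_tracker <- function() {
  e <- new.env(parent = emptyenv())
  e$D <- new.env(parent = emptyenv())
  e$last <- NULL
  class(e) <- "diagonal_tracker"
  e
}

.seed_key <- function(seed) {
  paste(seed$query_id, seed$subject, seed$strand, seed$diag, sep = "\r")
}

.seed_rank <- function(seed) {
  c(seed$subject, match(seed$strand, c("+", "-")), seed$diag, seed$s_frame)
}

#' @rdname diagonal_tracker
#' @param tracker a `diagonal_tracker`.
#' @param seed a one-row seed (list or data.frame row) with fields
#'   `query_id`, `subject`, `strand`, `diag`, `s_frame`.
#' @return `should_extend`: `TRUE` if the seed must be extended.
#' @export
should_extend <- function(tracker, seed) {
  rk <- .seed_rank(seed)
  if (!is.null(tracker$last) && identical(tracker$last_q, seed$query_id)) {
    prev <- tracker$last
    cmp <- rk - prev
    nz <- which(cmp != 0)
    if (length(nz) && cmp[nz[1]] < 0)
      stop("seeds arrived out of sort order; run sort_seeds() first")
  }
  tracker$last <- rk
  tracker$last_q <- seed$query_id
  key <- .seed_key(seed)
  D <- tracker$D[[key]]
  is.null(D) || seed$s_frame >= D
}

#' @rdname diagonal_tracker
#' @param end_offset end subject offset (frame coordinates) of the ungapped
#'   alignment the seed produced.
#' @export
tracker_update <- function(tracker, seed, end_offset) {
  tracker$D[[.seed_key(seed)]] <- as.integer(end_offset)
  invisible(tracker)
}

#' Ungapped X-drop extension of a seed
#'
#' Classic two-sided extension: walk left then right from the exact seed,
#' tracking the best running score in each direction and stopping a
#' direction once the running score falls more than `xdrop_ungapped` below
#' its best.  Returns the best-scoring gap-free segment containing the seed.
#'
#' @param qcodes,scodes integer symbol codes of the query and the subject
#'   view (the reverse-complemented subject for minus-strand seeds).
#' @param seed list with `q_offset`, `s_frame` and `length`.
#' @param scoring a [scoring_params()] object.
#' @return list `(q_start, s_start, length, score)`, 0-based frame
#'   coordinates.
#' @export
ungapped_extend <- function(qcodes, scodes, seed, scoring) {
  ungapped_xdrop_cpp(qcodes, scodes, seed$q_offset, seed$s_frame,
                     seed$length, scoring$reward, scoring$penalty,
                     scoring$xdrop_ungapped)
}

#' Gapped X-drop extension of an ungapped anchor
#'
#' Banded affine-gap dynamic programming seeded at the anchor midpoint and
#' extended in both directions; cells falling more than `xdrop_gapped` below
#' the running best are pruned.  Traceback supplies identity, mismatch and
#' gap counts, so the recomputed score always equals the stored score.
#'
#' @inheritParams ungapped_extend
#' @param anchor list from [ungapped_extend()] (`q_start`, `s_start`,
#'   `length`, `score`).
#' @return list with 0-based inclusive frame coordinates `q_start`, `q_end`,
#'   `s_start`, `s_end` and `score`, `nid`, `nmis`, `ngapopen`,
#'   `ngapletters`, `aln_len`.
#' @export
gapped_extend <- function(qcodes, scodes, anchor, scoring) {
  qm <- anchor$q_start + anchor$length %/% 2L
  sm <- anchor$s_start + anchor$length %/% 2L
  nq <- length(qcodes); ns <- length(scodes)
  # subject view is clipped to the reachable band around the anchor diagonal
  span_r <- min(ns - sm, (nq - qm) + 256L)
  right <- gapped_xdrop_cpp(qcodes[(qm + 1L):nq],
                            scodes[(sm + 1L):ns][seq_len(span_r)],
                            scoring$reward, scoring$penalty, scoring$gap_open,
                            scoring$gap_extend, scoring$xdrop_gapped)
  span_l <- min(sm, qm + 256L)
  left <- gapped_xdrop_cpp(rev(qcodes[seq_len(qm)]),
                           rev(scodes[seq_len(sm)])[seq_len(span_l)],
                           scoring$reward, scoring$penalty, scoring$gap_open,
                           scoring$gap_extend, scoring$xdrop_gapped)
  list(q_start = qm - left$q_used, q_end = qm + right$q_used - 1L,
       s_start = sm - left$s_used, s_end = sm + right$s_used - 1L,
       score = left$score + right$score,
       nid = left$nid + right$nid, nmis = left$nmis + right$nmis,
       ngapopen = left$ngapopen + right$ngapopen,
       ngapletters = left$ngapletters + right$ngapletters,
       aln_len = left$nid + right$nid + left$nmis + right$nmis +
         left$ngapletters + right$ngapletters)
}

# Drop HSPs fully contained in a higher-scoring HSP on the same
# (query, subject, strand); ties broken by (s_start, q_start) order.
.filter_contained <- function(h) {
  if (nrow(h) <= 1L) return(h)
  keep <- rep(TRUE, nrow(h))
  grp <- paste(h$query_id, h$subject, h$strand, sep = "\r")
  for (g in unique(grp)) {
    idx <- which(grp == g)
    if (length(idx) < 2L) next
    o <- idx[order(-h$score[idx], h$s_start[idx], h$q_start[idx])]
    for (t in seq_along(o)[-1]) {
      i <- o[t]
      for (s in seq_len(t - 1L)) {
        jj <- o[s]
        if (!keep[jj]) next
        if (h$q_start[i] >= h$q_start[jj] && h$q_end[i] <= h$q_end[jj] &&
            h$s_start[i] >= h$s_start[jj] && h$s_end[i] <= h$s_end[jj] &&
            h$score[jj] >= h$score[i]) { keep[i] <- FALSE; break }
      }
    }
  }
  h[keep, , drop = FALSE]
}

.empty_hsps <- function() {
  data.frame(query_id = character(0), subject = integer(0),
             subject_id = character(0), strand = character(0),
             q_start = integer(0), q_end = integer(0),
             s_start = integer(0), s_end = integer(0),
             score = numeric(0), nid = numeric(0), nmis = numeric(0),
             ngapopen = numeric(0), ngapletters = numeric(0),
             aln_len = numeric(0), evalue = numeric(0),
             bitscore = numeric(0), stringsAsFactors = FALSE)
}

#' Extend sorted seeds into gapped HSPs
#'
#' Walks the sorted seed list, skipping seeds made redundant by the diagonal
#' offset filter (unless `use_filter = FALSE`, in which case every seed is
#' extended and identical HSPs deduplicated -- the two modes produce the
#' same final HSP set).  Each surviving seed is extended ungapped; anchors
#' reaching the gapped trigger score are extended with the banded gapped
#' aligner.  HSPs are deduplicated, containment-filtered, scored with
#' E-values and cut at the E-value threshold.
#'
#' @param qcodes integer codes of the query.
#' @param index an `fmd_index`.
#' @param seeds sorted seed data.frame from [sort_seeds()].
#' @param scoring a [scoring_params()] object.
#' @param ka Karlin-Altschul parameters (from [karlin_altschul_params()]).
#' @param use_filter apply the diagonal offset filter (default `TRUE`).
#' @return HSP data.frame in frame coordinates (0-based inclusive).
#' @export
extend_seeds <- function(qcodes, index, seeds, scoring, ka,
                         use_filter = TRUE) {
  if (nrow(seeds) == 0L) return(.empty_hsps())
  m <- length(qcodes)
  n_db <- sum(index$layout$len[index$layout$strand == "+"])
  trigger <- score_for_bits(scoring$gap_trigger_bits, ka)

  # per-(subject, strand) frame code cache
  frames <- new.env(parent = emptyenv())
  frame_codes <- function(subject, strand) {
    key <- paste0(subject, strand)
    v <- frames[[key]]
    if (is.null(v)) {
      v <- index$text$subjects[[subject]]
      if (strand == "-") v <- revcomp_codes(v)
      frames[[key]] <- v
    }
    v
  }

  tracker <- diagonal_tracker()
  rows <- list(); nr <- 0L
  for (t in seq_len(nrow(seeds))) {
    seed <- seeds[t, ]
    go <- should_extend(tracker, seed)
    if (use_filter && !go) next
    sc <- frame_codes(seed$subject, seed$strand)
    ug <- ungapped_extend(qcodes, sc, seed, scoring)
    tracker_update(tracker, seed, ug$s_start + ug$length - 1L)
    if (ug$score < trigger) next
    hsp <- gapped_extend(qcodes, sc, ug, scoring)
    nr <- nr + 1L
    rows[[nr]] <- data.frame(query_id = seed$query_id,
                             subject = seed$subject,
                             subject_id = seed$subject_id,
                             strand = seed$strand,
                             q_start = hsp$q_start, q_end = hsp$q_end,
                             s_start = hsp$s_start, s_end = hsp$s_end,
                             score = hsp$score, nid = hsp$nid,
                             nmis = hsp$nmis, ngapopen = hsp$ngapopen,
                             ngapletters = hsp$ngapletters,
                             aln_len = hsp$aln_len,
                             stringsAsFactors = FALSE)
  }
  if (nr == 0L) return(.empty_hsps())
  h <- do.call(rbind, rows)
  key <- paste(h$query_id, h$subject, h$strand, h$q_start, h$q_end,
               h$s_start, h$s_end, h$score, sep = "\r")
  h <- h[!duplicated(key), , drop = FALSE]
  h <- .filter_contained(h)
  h$evalue <- hit_evalue(h$score, ka, m, n_db)
  h$bitscore <- hit_bitscore(h$score, ka)
  h <- h[h$evalue <= scoring$evalue_cutoff, , drop = FALSE]
  rownames(h) <- NULL
  h
}
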