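# Independent oracles and small generators shared by the tests.  Everything
# here is deliberately naive (string sorts, quadratic scans, full DP) so it
# cannot share a defect with the implementation under test.

rand_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Brute-force suffix array of a code vector, sentinels disambiguated by text
# position (the same convention the index states, realised via string sort).
brute_sa <- function(codes) {
  n <- length(codes)
  nsent <- sum(codes == 0L)
  keys <- integer(n)
  keys[codes == 0L] <- seq_len(nsent) - 1L
  keys[codes != 0L] <- nsent + codes[codes != 0L] - 1L
  suf <- vapply(seq_len(n), function(i)
    paste(sprintf("%04d", keys[i:n]), collapse = ""), character(1))
  order(suf, method = "radix") - 1L
}

# All occurrences of `pat` over both strands of a subject set, in the
# package's reporting convention (minus hits as plus-strand window starts).
naive_hits <- function(subjects, pat) {
  out <- list()
  rc <- revcomp(pat)
  w <- nchar(pat)
  for (i in seq_along(subjects)) {
    s <- subjects[[i]]
    L <- nchar(s)
    if (L < w) next
    wins <- substring(s, 1:(L - w + 1), w:L)
    p <- which(wins == pat)
    if (length(p))
      out[[length(out) + 1]] <- data.frame(subject = i, offset = p - 1L,
                                           strand = "+")
    m <- which(wins == rc)
    if (length(m))
      out[[length(out) + 1]] <- data.frame(subject = i, offset = m - 1L,
                                           strand = "-")
  }
  if (!length(out))
    return(data.frame(subject = integer(0), offset = integer(0),
                      strand = character(0)))
  do.call(rbind, out)
}

hit_keys <- function(df) sort(paste(df$subject, df$offset, df$strand))

# Quadratic all-w-hits oracle: every (q, subject, s, strand) with an exact
# w-length match, via hashed database windows on both strands.
all_w_hits <- function(subjects, query, w) {
  qn <- nchar(query)
  if (qn < w) return(character(0))
  qwins <- substring(query, 1:(qn - w + 1), w:qn)
  out <- character(0)
  for (i in seq_along(subjects)) {
    s <- subjects[[i]]
    L <- nchar(s)
    if (L < w) next
    wins <- substring(s, 1:(L - w + 1), w:L)
    ix <- split(seq_along(wins) - 1L, wins)
    rcwins <- substring(revcomp(s), 1:(L - w + 1), w:L)
    rix <- split(seq_along(rcwins) - 1L, rcwins)
    for (q in seq_along(qwins)) {
      p <- ix[[qwins[q]]]
      if (!is.null(p)) out <- c(out, paste(q - 1L, i, p, "+"))
      m <- rix[[qwins[q]]]
      if (!is.null(m)) out <- c(out, paste(q - 1L, i, L - m - w, "-"))
    }
  }
  sort(out)
}

seed_keys <- function(seeds) {
  sort(paste(seeds$q_offset, seeds$subject, seeds$s_offset, seeds$strand))
}

# Best score over all gap-free segments on the seed diagonal that contain
# the seed (exhaustive).
seg_oracle <- function(q, s, qpos, spos, len, reward, penalty) {
  off <- spos - qpos
  n <- min(length(q), length(s) - off)
  sc <- ifelse(q[1:n] >= 1 & q[1:n] <= 4 & q[1:n] == s[(1:n) + off],
               reward, penalty)
  cs <- cumsum(sc)
  best <- -Inf
  for (a in 0:qpos) {
    for (b in (qpos + len - 1):(n - 1)) {
      v <- cs[b + 1] - if (a > 0) cs[a] else 0
      if (v > best) best <- v
    }
  }
  best
}

# TRUE when reaching the oracle-optimal segment ends from the seed violates
# the X-drop rule at some prefix (the documented clipping caveat).
xdrop_clipped <- function(q, s, qpos, spos, len, reward, penalty, xdrop) {
  off <- spos - qpos
  walk <- function(idx) {
    run <- 0; best <- 0
    for (i in idx) {
      run <- run + if (q[i] >= 1 && q[i] <= 4 && q[i] == s[i + off])
        reward else penalty
      if (run > best) best <- run
      if (best - run > xdrop) return(TRUE)
    }
    FALSE
  }
  nmax <- min(length(q), length(s) - off)
  left <- if (qpos >= 1) walk(qpos:1) else FALSE
  right <- if (qpos + len + 1 <= nmax) walk((qpos + len + 1):nmax) else FALSE
  left || right
}

# Full affine-gap Smith-Waterman score (unbanded local DP oracle).
sw_affine <- function(q, s, reward, penalty, gopen, gext) {
  nq <- length(q); ns <- length(s); NEG <- -1e9
  H <- matrix(0, nq + 1, ns + 1)
  E <- matrix(NEG, nq + 1, ns + 1)
  F <- matrix(NEG, nq + 1, ns + 1)
  best <- 0
  for (i in 2:(nq + 1)) {
    for (j in 2:(ns + 1)) {
      E[i, j] <- max(H[i, j - 1] - gopen - gext, E[i, j - 1] - gext)
      F[i, j] <- max(H[i - 1, j] - gopen - gext, F[i - 1, j] - gext)
      sub <- if (q[i - 1] == s[j - 1]) reward else penalty
      H[i, j] <- max(0, H[i - 1, j - 1] + sub, E[i, j], F[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

mutate_sub <- function(s, rate) {
  ch <- strsplit(s, "")[[1]]
  at <- which(runif(length(ch)) < rate)
  for (a in at) ch[a] <- sample(setdiff(c("A", "C", "G", "T"), ch[a]), 1)
  paste(ch, collapse = "")
}

hsp_keys <- function(h) {
  sort(paste(h$query_id, h$subject, h$strand, h$q_start, h$q_end,
             h$s_start, h$s_end, h$score))
}

# One full query-vs-database search at the module level (no CLI / no files).
search_codes <- function(qcodes, idx, tab, params, scoring, ka,
                         use_filter = TRUE, query_id = "q",
                         query_mask = NULL) {
  si <- find_seed_intervals(qcodes, idx, tab, params, query_mask = query_mask)
  seeds <- sort_seeds(resolve_seeds(idx, si, query_id = query_id))
  extend_seeds(qcodes, idx, seeds, scoring, ka, use_filter = use_filter)
}

codes_of <- function(seq) {
  x <- fmdblast:::dna_codes(seq)
  x[is.na(x)] <- 0L
  x
}
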