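#' Specification for seeded synthetic test data
#'
#' Defaults emulate a desk-scale genomic search workload: a database of a
#' few multi-kilobase subjects with roughly uniform base composition, and a
#' query set in the short-query regime (100-500 bp), most queries being
#' mutated copies of database windows (either strand) and the rest random
#' background.  The same spec always generates identical data.
#'
#' @param seed master RNG seed; all randomness flows through it.
#' @param n_subjects number of database subjects.
#' @param subject_len two-element range of subject lengths (bp).
#' @param composition base frequencies of A, C, G, T.
#' @param n_queries number of queries.
#' @param query_len two-element range of query lengths (bp).
#' @param planted_frac fraction of queries that are mutated database copies.
#' @param substitution_rate per-base substitution probability in planted
#'   queries.
#' @param indel_rate per-base indel initiation probability.
#' @param indel_max maximum indel length (lengths uniform on 1..indel_max).
#' @param ambiguity_rate per-base probability of an N in database subjects.
#' @param mask_rate expected fraction of each subject under soft-mask spans.
#' @return a list of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L, n_subjects = 4L,
                         subject_len = c(2000L, 8000L),
                         composition = rep(0.25, 4), n_queries = 20L,
                         query_len = c(100L, 500L), planted_frac = 0.75,
                         substitution_rate = 0.03, indel_rate = 0.005,
                         indel_max = 5L, ambiguity_rate = 0.001,
                         mask_rate = 0.05) {
  stopifnot(abs(sum(composition) - 1) < 1e-8, length(composition) == 4L)
  structure(list(seed = as.integer(seed), n_subjects = as.integer(n_subjects),
                 subject_len = as.integer(subject_len),
                 composition = composition, n_queries = as.integer(n_queries),
                 query_len = as.integer(query_len),
                 planted_frac = planted_frac,
                 substitution_rate = substitution_rate,
                 indel_rate = indel_rate, indel_max = as.integer(indel_max),
                 ambiguity_rate = ambiguity_rate, mask_rate = mask_rate),
            class = "fixture_spec")
}

.rand_seq <- function(n, composition) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = composition),
        collapse = "")
}

#' Generate a synthetic database FASTA
#'
#' Random subjects with the requested composition, N injections at
#' `ambiguity_rate` and lowercase soft-mask spans covering about
#' `mask_rate` of each subject.  A manifest records every planted feature.
#'
#' @param spec a [fixture_spec()].
#' @param path optional file path; when given, the FASTA is written there.
#' @return list with `records` (id, seq), `manifest` (data.frame of
#'   injected N positions and mask spans) and `path`.
#' @export
gen_database <- function(spec, path = NULL) {
  with_rng_seed(spec$seed, {
    ids <- sprintf("subj%02d", seq_len(spec$n_subjects))
    lens <- sample(spec$subject_len[1]:spec$subject_len[2], spec$n_subjects,
                   replace = TRUE)
    seqs <- character(spec$n_subjects)
    feats <- list()
    for (i in seq_len(spec$n_subjects)) {
      s <- strsplit(.rand_seq(lens[i], spec$composition), "")[[1]]
      n_amb <- rbinom(1, lens[i], spec$ambiguity_rate)
      if (n_amb > 0) {
        at <- sort(sample.int(lens[i], n_amb))
        s[at] <- "N"
        feats[[length(feats) + 1L]] <- data.frame(
          subject_id = ids[i], feature = "ambiguous", start = at - 1L,
          end = at, stringsAsFactors = FALSE)
      }
      # mask spans of mean length 50 until the target fraction is covered
      target <- spec$mask_rate * lens[i]
      covered <- 0
      while (covered < target) {
        len <- min(sample(20:80, 1), lens[i])
        at <- sample.int(lens[i] - len + 1L, 1L)
        s[at:(at + len - 1L)] <- tolower(s[at:(at + len - 1L)])
        feats[[length(feats) + 1L]] <- data.frame(
          subject_id = ids[i], feature = "mask", start = at - 1L,
          end = at + len - 1L, stringsAsFactors = FALSE)
        covered <- covered + len
        if (spec$mask_rate <= 0) break
      }
      seqs[i] <- paste(s, collapse = "")
    }
    manifest <- if (length(feats)) do.call(rbind, feats) else
      data.frame(subject_id = character(0), feature = character(0),
                 start = integer(0), end = integer(0),
                 stringsAsFactors = FALSE)
    records <- data.frame(id = ids, seq = seqs, stringsAsFactors = FALSE)
    if (!is.null(path)) .write_fasta(records, path)
    list(records = records, manifest = manifest, path = path)
  })
}

.write_fasta <- function(records, path, width = 70L) {
  con <- file(path, "wb")  # binary mode: LF endings on every platform
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    writeLines(paste0(">", records$id[i]), con, sep = "\n")
    s <- records$seq[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))),
               con, sep = "\n")
  }
  invisible(path)
}

# Apply substitutions and indels to an upper-case sequence; returns the
# mutated string plus the edit list.
.mutate <- function(s, sub_rate, indel_rate, indel_max) {
  chars <- strsplit(s, "")[[1]]
  edits <- list()
  n <- length(chars)
  subs <- which(runif(n) < sub_rate)
  for (at in subs) {
    alt <- sample(setdiff(c("A", "C", "G", "T"), chars[at]), 1L)
    edits[[length(edits) + 1L]] <- data.frame(op = "sub", pos = at - 1L,
                                              len = 1L,
                                              stringsAsFactors = FALSE)
    chars[at] <- alt
  }
  if (indel_rate > 0) {
    out <- character(0)
    i <- 1L
    while (i <= length(chars)) {
      if (runif(1) < indel_rate) {
        len <- sample.int(indel_max, 1L)
        if (runif(1) < 0.5) {                      # insertion
          out <- c(out, sample(c("A", "C", "G", "T"), len, replace = TRUE))
          edits[[length(edits) + 1L]] <- data.frame(op = "ins", pos = i - 1L,
                                                    len = len,
                                                    stringsAsFactors = FALSE)
          out <- c(out, chars[i]); i <- i + 1L
        } else {                                   # deletion
          edits[[length(edits) + 1L]] <- data.frame(op = "del", pos = i - 1L,
                                                    len = len,
                                                    stringsAsFactors = FALSE)
          i <- i + len
        }
      } else {
        out <- c(out, chars[i]); i <- i + 1L
      }
    }
    chars <- out
  }
  list(seq = paste(chars, collapse = ""),
       edits = if (length(edits)) do.call(rbind, edits) else NULL)
}

#' Generate a query set with a truth manifest
#'
#' Each query is either background (no planted hit) or a mutated copy of a
#' database window on either strand, with every edit recorded.  The truth
#' manifest lists the expected subject, strand and window coordinates per
#' planted query and is written as JSON-lines when `path` is given.
#'
#' @param spec a [fixture_spec()].
#' @param database result of [gen_database()].
#' @param path optional FASTA output path; the manifest is written next to
#'   it with extension `.truth.jsonl`.
#' @return list with `records`, `truth` (data.frame: query_id, type,
#'   subject_id, strand, s_start, s_end, n_sub, n_indel) and `path`.
#' @export
gen_queries <- function(spec, database, path = NULL) {
  with_rng_seed(spec$seed + 1L, {
    db <- database$records
    db_upper <- toupper(db$seq)
    recs <- list(); truth <- list()
    for (qi in seq_len(spec$n_queries)) {
      qid <- sprintf("query%03d", qi)
      qlen <- sample(spec$query_len[1]:spec$query_len[2], 1L)
      planted <- runif(1) < spec$planted_frac
      if (planted) {
        si <- sample.int(nrow(db), 1L)
        L <- nchar(db_upper[si])
        qlen <- min(qlen, L)
        at <- sample.int(L - qlen + 1L, 1L)
        window <- substr(db_upper[si], at, at + qlen - 1L)
        strand <- sample(c("+", "-"), 1L)
        if (strand == "-") window <- revcomp(window)
        mut <- .mutate(window, spec$substitution_rate, spec$indel_rate,
                       spec$indel_max)
        recs[[qi]] <- data.frame(id = qid, seq = mut$seq,
                                 stringsAsFactors = FALSE)
        ed <- mut$edits
        truth[[qi]] <- data.frame(
          query_id = qid, type = "planted", subject_id = db$id[si],
          strand = strand, s_start = at - 1L, s_end = at + qlen - 1L,
          n_sub = if (is.null(ed)) 0L else sum(ed$op == "sub"),
          n_indel = if (is.null(ed)) 0L else sum(ed$op != "sub"),
          stringsAsFactors = FALSE)
      } else {
        recs[[qi]] <- data.frame(id = qid,
                                 seq = .rand_seq(qlen, spec$composition),
                                 stringsAsFactors = FALSE)
        truth[[qi]] <- data.frame(query_id = qid, type = "background",
                                  subject_id = NA_character_,
                                  strand = NA_character_, s_start = NA_integer_,
                                  s_end = NA_integer_, n_sub = 0L,
                                  n_indel = 0L, stringsAsFactors = FALSE)
      }
    }
    records <- do.call(rbind, recs)
    truth <- do.call(rbind, truth)
    if (!is.null(path)) {
      .write_fasta(records, path)
      tp <- paste0(path, ".truth.jsonl")
      writeLines(vapply(seq_len(nrow(truth)), function(i)
        as.character(jsonlite::toJSON(as.list(truth[i, ]),
                                      auto_unbox = TRUE, na = "null")),
        character(1)), tp)
    }
    list(records = records, truth = truth, path = path)
  })
}

#' Deterministic adversarial database/query constructions
#'
#' Cases exercising seeding and filtering corner cases:
#' \describe{
#'   \item{`stride_witness`}{exactly one w-hit placed so the maximal stride
#'     `w - k + 1` finds it and stride `w - k + 2` misses it.}
#'   \item{`tandem_repeat`}{a repeat of period p < w producing many seeds on
#'     a single diagonal, so the diagonal filter triggers exactly one
#'     ungapped extension.}
#'   \item{`palindrome`}{a reverse-complement-palindromic window matching
#'     both strands at the same location.}
#'   \item{`query_edge`}{the only w-hit ends at the last query symbol.}
#'   \item{`masked_seed`}{the matching window straddles a soft-masked query
#'     span; only its unmasked k-mers may seed it.}
#' }
#'
#' @param case_id one of the case names above.
#' @param w,k seeding parameters the case is built for.
#' @return list with `db` (records data.frame), `query` (records
#'   data.frame), `w`, `k` and case-specific expectation fields.
#' @export
gen_adversarial <- function(case_id = c("stride_witness", "tandem_repeat",
                                        "palindrome", "query_edge",
                                        "masked_seed"),
                            w = 28L, k = 11L) {
  case_id <- match.arg(case_id)
  w <- as.integer(w); k <- as.integer(k)
  base <- function(n, seed) with_rng_seed(seed, .rand_seq(n, rep(0.25, 4)))
  mk <- function(db_seq, q_seq, ...) {
    list(db = data.frame(id = "adv_subj", seq = db_seq,
                         stringsAsFactors = FALSE),
         query = data.frame(id = "adv_query", seq = q_seq,
                            stringsAsFactors = FALSE),
         w = w, k = k, ...)
  }
  if (case_id == "stride_witness") {
    # single w-hit at query offset 1, which sits between the sample points
    # of stride w-k+2; boundary characters are forced to differ ("T" in the
    # database vs "A" in the query) so the hit cannot slide by one
    M <- base(w, 101L)
    mk(paste0(base(59L, 104L), "T", M, "T", base(59L, 105L)),
       paste0("A", M, "A", base(26L, 103L)),
       q_offset = 1L, db_offset = 60L)
  } else if (case_id == "tandem_repeat") {
    p <- 7L
    qlen <- w + p - 1L   # < w + p, so only diagonal 0 carries full windows
    # unit over {A,C,G}; flank boundaries forced to T so the repeat cannot
    # bleed across the junctions on shifted diagonals
    unit <- with_rng_seed(111L, paste(sample(c("A", "C", "G"), p,
                                             replace = TRUE), collapse = ""))
    R <- substr(strrep(unit, ceiling(qlen / p)), 1L, qlen)
    mk(paste0(base(49L, 112L), "T", R, "T", base(49L, 113L)), R, period = p,
       db_offset = 50L)
  } else if (case_id == "palindrome") {
    stopifnot(w %% 2L == 0L)
    M <- base(w %/% 2L, 121L)
    P <- paste0(M, revcomp(M))
    mk(paste0(base(40L, 122L), P, base(40L, 123L)), P, db_offset = 40L)
  } else if (case_id == "query_edge") {
    M <- base(w, 131L)
    mk(paste0(base(50L, 132L), M, base(50L, 133L)),
       paste0(base(30L, 134L), M), q_offset = 30L)
  } else {
    M <- base(w, 141L)
    qseq <- paste0(base(20L, 142L), M, base(20L, 143L))
    # mask the left half of the matching window (lowercase)
    m0 <- 21L; m1 <- 20L + w %/% 2L
    substr(qseq, m0, m1) <- tolower(substr(qseq, m0, m1))
    mk(paste0(base(50L, 144L), M, base(50L, 145L)), qseq,
       q_offset = 20L, mask = c(20L, 20L + w %/% 2L))
  }
}
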