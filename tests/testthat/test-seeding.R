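make_search <- function(subjects, r = 8L, k = 11L) {
  tx <- fmd_text(subjects)
  idx <- fmd_index(tx, r = r)
  list(idx = idx, tab = build_lookup(idx, k))
}

test_that("seeding parameters are validated", {
  p <- seeding_params(w = 28, k = 11)
  expect_identical(p$stride, 18L)
  expect_error(seeding_params(w = 10, k = 11), "w .* >= .*k")
  expect_error(seeding_params(w = 28, k = 11, stride = 19), "stride")
  expect_error(seeding_params(w = 28, k = 11, stride = 0), "stride")
})

test_that("a unique planted window yields exactly one located seed", {
  set.seed(41)
  M <- rand_seq(28)
  db <- paste0(rand_seq(200), M, rand_seq(200))
  se <- make_search(c(s = db))
  q <- paste0(rand_seq(50), M, rand_seq(50))
  si <- find_seed_intervals(q, se$idx, se$tab, seeding_params(28, 11))
  seeds <- resolve_seeds(se$idx, si)
  expect_identical(nrow(seeds), 1L)
  expect_identical(seeds$q_offset, 50L)
  expect_identical(seeds$s_offset, 200L)
  expect_identical(seeds$strand, "+")

  # no w-length match anywhere -> empty
  si0 <- find_seed_intervals(rand_seq(120), se$idx, se$tab,
                             seeding_params(28, 11))
  expect_identical(nrow(si0), 0L)
  # query shorter than w -> empty
  expect_identical(nrow(find_seed_intervals(rand_seq(20), se$idx, se$tab,
                                            seeding_params(28, 11))), 0L)
})

test_that("located seeds equal the quadratic all-w-hits oracle", {
  set.seed(43)
  for (trial in 1:4) {
    subjects <- lapply(sample(400:2500, sample(1:2, 1), replace = TRUE),
                       rand_seq)
    names(subjects) <- paste0("s", seq_along(subjects))
    se <- make_search(unlist(subjects))
    si <- sample(length(subjects), 1)
    L <- nchar(subjects[[si]])
    wlen <- min(L, sample(150:500, 1))
    at <- sample(L - wlen + 1, 1)
    copy <- mutate_sub(substr(subjects[[si]], at, at + wlen - 1), 0.03)
    if (runif(1) < 0.5) copy <- revcomp(copy)
    query <- paste0(rand_seq(60), copy, rand_seq(60))
    for (w in c(12L, 20L, 28L)) {
      seeds <- resolve_seeds(se$idx,
                             find_seed_intervals(query, se$idx, se$tab,
                                                 seeding_params(w, 11)))
      expect_identical(seed_keys(seeds), all_w_hits(subjects, query, w))
    }
  }
})

test_that("ambiguous query symbols act as mismatches", {
  set.seed(47)
  M <- rand_seq(40)
  se <- make_search(c(s = paste0(rand_seq(100), M, rand_seq(100))))
  # an N inside the only matching region truncates the seed set accordingly
  qN <- paste0(substr(M, 1, 18), "N", substr(M, 20, 40))
  seeds <- resolve_seeds(se$idx,
                         find_seed_intervals(qN, se$idx, se$tab,
                                             seeding_params(12, 11)))
  # windows overlapping the N (query offsets 7..18) must be absent
  expect_true(all(seeds$q_offset > 18 | seeds$q_offset < 7))
  expect_gt(nrow(seeds), 0L)
})

test_that("resolution is independent of r and of hard exclusion", {
  set.seed(53)
  db <- c(s1 = rand_seq(900), s2 = rand_seq(500))
  query <- paste0(rand_seq(40), substr(db[[1]], 101, 220), rand_seq(40))
  ref <- NULL
  for (r in c(1L, 8L)) {
    se <- make_search(db, r = r)
    seeds <- resolve_seeds(se$idx,
                           find_seed_intervals(query, se$idx, se$tab,
                                               seeding_params(28, 11)))
    if (is.null(ref)) ref <- seed_keys(seeds)
    else expect_identical(seed_keys(seeds), ref)
  }
  # interval of size m gives m rows before deduplication
  se <- make_search(c(a = "AAAAAAAAAAAAAAAA"), k = 4L)
  si <- find_seed_intervals("AAAAAA", se$idx, se$tab, seeding_params(6, 4))
  expect_identical(nrow(resolve_seeds(se$idx, si, dedupe = FALSE)),
                   sum(si$size))
})

test_that("palindromic-complement windows are reported once per strand", {
  set.seed(59)
  M <- rand_seq(14)
  P <- paste0(M, revcomp(M))
  se <- make_search(c(s = paste0(rand_seq(80), P, rand_seq(80))))
  seeds <- resolve_seeds(se$idx,
                         find_seed_intervals(P, se$idx, se$tab,
                                             seeding_params(28, 11)))
  expect_identical(nrow(seeds), 2L)
  expect_identical(sort(seeds$strand), c("+", "-"))
  expect_identical(unique(seeds$s_offset), 80L)
})

test_that("with w = k the scan reduces to per-position table lookups", {
  set.seed(61)
  subjects <- list(rand_seq(600))
  se <- make_search(c(s = subjects[[1]]), k = 11L)
  query <- paste0(rand_seq(20), substr(subjects[[1]], 50, 120), rand_seq(20))
  p <- seeding_params(w = 11, k = 11)
  expect_identical(p$stride, 1L)
  seeds <- resolve_seeds(se$idx,
                         find_seed_intervals(query, se$idx, se$tab, p))
  expect_identical(seed_keys(seeds), all_w_hits(subjects, query, 11))
})

test_that("stride w-k+1 is maximal: the witness shows w-k+2 misses", {
  adv <- gen_adversarial("stride_witness", w = 28, k = 11)
  se <- make_search(stats::setNames(adv$db$seq, adv$db$id))
  found <- find_seed_intervals(adv$query$seq, se$idx, se$tab,
                               seeding_params(28, 11, stride = 18))
  expect_identical(found$q_start, adv$q_offset)
  # construct the over-wide stride directly (the constructor forbids it)
  p2 <- structure(list(w = 28L, k = 11L, stride = 19L),
                  class = "seeding_params")
  expect_identical(nrow(find_seed_intervals(adv$query$seq, se$idx, se$tab,
                                            p2)), 0L)
  # verified against the window oracle
  expect_identical(all_w_hits(list(adv$db$seq), adv$query$seq, 28),
                   paste(adv$q_offset, 1L, adv$db_offset, "+"))
})

test_that("sort_seeds orders by diagonal then subject offset, stably", {
  seeds <- data.frame(query_id = "q", q_offset = c(10L, 5L, 0L, 3L),
                      subject = c(1L, 1L, 1L, 1L),
                      subject_id = "s", s_offset = c(40L, 10L, 7L, 30L),
                      strand = c("+", "+", "-", "+"), length = 28L,
                      s_frame = c(40L, 10L, 7L, 30L),
                      diag = c(30L, 5L, 7L, 27L), stringsAsFactors = FALSE)
  out <- sort_seeds(seeds)
  expect_identical(out$strand, c("+", "+", "+", "-"))
  expect_identical(out$diag[1:3], c(5L, 27L, 30L))

  # same diagonal: smaller subject offset first
  two <- data.frame(query_id = "q", q_offset = c(25L, 5L), subject = 1L,
                    subject_id = "s", s_offset = c(30L, 10L), strand = "+",
                    length = 28L, s_frame = c(30L, 10L), diag = 5L,
                    stringsAsFactors = FALSE)
  expect_identical(sort_seeds(two)$s_frame, c(10L, 30L))
  # idempotent and permutation invariant
  expect_identical(sort_seeds(out), out)
  set.seed(67)
  perm <- seeds[sample(nrow(seeds)), ]
  expect_identical(sort_seeds(perm), out)
})

test_that("masked query spans suppress seeding but not extension across", {
  adv <- gen_adversarial("masked_seed", w = 28, k = 11)
  se <- make_search(stats::setNames(toupper(adv$db$seq), adv$db$id))
  qmask <- matrix(adv$mask, ncol = 2)
  si <- find_seed_intervals(toupper(adv$query$seq), se$idx, se$tab,
                            seeding_params(28, 11), query_mask = qmask)
  expect_true(adv$q_offset %in% si$q_start)
  # a k-mer entirely inside the mask does not start a scan: a fully masked
  # query region with no other anchor yields nothing
  Mfull <- substr(adv$db$seq, 51, 78)
  full_mask <- matrix(c(0L, 28L), ncol = 2)
  si2 <- find_seed_intervals(toupper(Mfull), se$idx, se$tab,
                             seeding_params(28, 11), query_mask = full_mask)
  expect_identical(nrow(si2), 0L)
})
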