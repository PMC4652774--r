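test_that("fmd_text builds both strands, logs ambiguity, validates input", {
  tx <- fmd_text(c(s1 = "ACGT"))
  # ACGT is its own reverse complement: both segments identical
  expect_identical(tx$codes, c(1L, 2L, 3L, 4L, 0L, 1L, 2L, 3L, 4L, 0L))
  expect_identical(tx$layout$strand, c("+", "-"))

  tx2 <- fmd_text(c(s1 = "GGC"))
  minus <- tx2$codes[(tx2$layout$start[2] + 1):(tx2$layout$start[2] + 4)]
  expect_identical(fmdblast:::codes_to_dna(minus), "GCC$")

  tx3 <- fmd_text(c(s1 = "AAN"), seed = 7)
  expect_identical(tx3$ambiguity_log$offset, 2L)
  expect_identical(tx3$ambiguity_log$original, "N")
  expect_true(tx3$ambiguity_log$replacement %in% c("A", "C", "G", "T"))
  # deterministic for a fixed seed
  expect_identical(fmd_text(c(s1 = "AAN"), seed = 7)$subjects,
                   tx3$subjects)

  expect_error(fmd_text(character(0)), "empty input")
  expect_error(fmd_text(c(s1 = "ACXG")), "position 3")
})

test_that("build_index satisfies the SA/BWT/C invariants on ACG$", {
  # single $-terminated segment, constructed through the internal builder so
  # the unit example is free of the reverse-complement segment
  codes <- c(1L, 2L, 3L, 0L)
  lay <- data.frame(subject = 1L, id = "s", strand = "+", start = 0L, len = 3L)
  fm <- fmdblast:::.build_fm(codes, lay, r = 1L)
  full_sa <- fm$sampled                       # r = 1: sampled == full SA
  expect_identical(full_sa, c(3L, 0L, 1L, 2L))
  expect_identical(fmdblast:::codes_to_dna(fm$bwt), "G$AC")
  expect_identical(fm$C, c(0L, 1L, 2L, 3L, 4L))  # C[A] = 1: only $ smaller

  fm2 <- fmdblast:::.build_fm(codes, lay, r = 2L)
  class(fm2) <- "fmd_index"
  expect_identical(sa_lookup(fm2, 0:3), full_sa)
})

test_that("index construction matches the brute-force suffix sort oracle", {
  set.seed(101)
  for (trial in 1:3) {
    tx <- fmd_text(c(a = rand_seq(sample(50:250, 1))))
    sao <- brute_sa(tx$codes)
    idx <- fmd_index(tx, r = 1L)
    expect_identical(idx$sampled, sao)
    # BWT invariant: B[i] = T[SA[i]-1] for SA[i] > 0, else $
    expect_identical(idx$bwt[sao > 0], tx$codes[sao[sao > 0]])
    expect_true(all(idx$bwt[sao == 0] == 0L))
    # C non-decreasing and occupancy totals
    expect_true(all(diff(idx$C) >= 0))
    expect_identical(sum(tabulate(idx$bwt + 1L, 5L)), idx$n)
  }
})

test_that("backward extension partitions suffixes and absorbs emptiness", {
  tx <- fmd_text(c(a = rand_seq(120), b = rand_seq(60)))
  idx <- fmd_index(tx, r = 4L)
  root <- bi_root(idx)
  sizes <- vapply(c("A", "C", "G", "T"),
                  function(a) backward_ext(idx, root, a)$size, integer(1))
  nsent <- sum(tx$codes == 0L)
  expect_identical(sum(sizes), idx$n - nsent)

  expect_identical(backward_ext(idx, bi_empty(), "A")$size, 0L)
  expect_error(backward_ext(idx, root, "N"), "not in the alphabet")
})

test_that("backward extension counts match naive substring counting", {
  tx <- fmd_text(c(a = "AAAA"))
  idx <- fmd_index(tx, r = 1L)
  biA <- backward_ext(idx, bi_root(idx), "A")
  biAA <- backward_ext(idx, biA, "A")
  # bidirectional text AAAA$TTTT$: "AA" occurs 3 times
  expect_identical(biAA$size, 3L)
})

test_that("forward extension is the reverse-complement mirror of backward", {
  tx <- fmd_text(c(t = "ACGTACGGTTAC"))
  idx <- fmd_index(tx, r = 2L)
  root <- bi_root(idx)
  for (a in c("A", "C", "G", "T")) {
    expect_identical(forward_ext(idx, root, a)$size,
                     backward_ext(idx, root,
                                  chartr("ACGT", "TGCA", a))$size)
  }
  # forward/backward commute: omega(aPb) from either order, all |P| <= 3
  alpha <- c("A", "C", "G", "T")
  pats <- c("", alpha,
            apply(expand.grid(alpha, alpha), 1, paste, collapse = ""),
            apply(expand.grid(alpha, alpha, alpha), 1, paste, collapse = ""))
  for (P in pats) {
    for (a in alpha) for (b in alpha) {
      direct <- fmdblast:::bi_from_pattern(idx, paste0(a, P, b))
      aP <- fmdblast:::bi_from_pattern(idx, paste0(a, P))
      via_f <- forward_ext(idx, aP, b)
      Pb <- if (nchar(P)) forward_ext(idx, fmdblast:::bi_from_pattern(idx, P), b)
            else fmdblast:::bi_from_pattern(idx, b)
      via_b <- backward_ext(idx, Pb, a)
      expect_identical(via_f$size, direct$size)
      expect_identical(via_b$size, direct$size)
      if (direct$size > 0) {
        expect_identical(via_f$lower, direct$lower)
        expect_identical(via_b$lower, direct$lower)
      }
      # monotone refinement
      expect_lte(via_f$size, aP$size)
    }
  }
})

test_that("sa_lookup equals the full suffix array for r in {1,2,8,32}", {
  set.seed(77)
  tx <- fmd_text(c(a = rand_seq(250)))   # ~500 symbols bidirectional
  sao <- brute_sa(tx$codes)
  n <- length(tx$codes)
  for (r in c(1L, 2L, 8L, 32L)) {
    idx <- fmd_index(tx, r = r)
    expect_identical(sa_lookup(idx, 0:(n - 1)), sao)
  }
  idx <- fmd_index(tx, r = 8L)
  expect_error(sa_lookup(idx, n), "out of range")
  expect_error(sa_lookup(idx, -1L), "out of range")
})

test_that("LF-mapping visits every text position exactly once", {
  set.seed(13)
  tx <- fmd_text(c(a = rand_seq(90), b = rand_seq(40)))
  idx <- fmd_index(tx, r = 4L)
  k <- idx$rank0
  seen <- integer(idx$n)
  for (t in seq_len(idx$n)) { seen[t] <- k; k <- lf_map(idx, k) }
  expect_identical(sort(seen), 0:(idx$n - 1))
  expect_identical(k, idx$rank0)
})

test_that("locate maps interval ranks to subject/strand coordinates", {
  tx <- fmd_text(c(a = "AAAA"))
  idx <- fmd_index(tx, r = 2L)
  bi <- fmdblast:::bi_from_pattern(idx, "AA")
  hits <- fmd_locate(idx, bi, plen = 2)
  expect_identical(sort(hits$offset[hits$strand == "+"]), c(0L, 1L, 2L))
  expect_identical(sum(hits$strand == "-"), 0L)   # rc segment is TTTT

  expect_identical(nrow(fmd_locate(idx, bi_empty())), 0L)

  # pattern equal to a full unique subject: one literal plus-strand hit at
  # offset 0; its reverse complement is found at the same spot on the minus
  # strand (locate reports literal pattern occurrences per strand)
  set.seed(3)
  s <- rand_seq(60)
  tx2 <- fmd_text(c(u = s, v = rand_seq(80)))
  idx2 <- fmd_index(tx2, r = 8L)
  bi2 <- fmdblast:::bi_from_pattern(idx2, s)
  hits2 <- fmd_locate(idx2, bi2, plen = nchar(s))
  expect_identical(nrow(hits2), 1L)
  expect_identical(hits2$strand, "+")
  expect_true(hits2$offset == 0L && hits2$subject == 1L)
  mirror <- fmd_locate(idx2, fmdblast:::bi_from_pattern(idx2, revcomp(s)),
                       plen = nchar(s))
  expect_identical(mirror$strand, "-")
  expect_true(mirror$offset == 0L && mirror$subject == 1L)
})

test_that("locate agrees with naive bidirectional scanning", {
  set.seed(19)
  subjects <- list(rand_seq(180), rand_seq(90))
  tx <- fmd_text(c(s1 = subjects[[1]], s2 = subjects[[2]]))
  idx <- fmd_index(tx, r = 8L)
  for (t in 1:40) {
    L <- sample(1:15, 1)
    si <- sample(2, 1)
    at <- sample(nchar(subjects[[si]]) - L + 1, 1)
    pat <- substr(subjects[[si]], at, at + L - 1)
    bi <- fmdblast:::bi_from_pattern(idx, pat)
    expect_identical(hit_keys(fmd_locate(idx, bi, plen = L)),
                     hit_keys(naive_hits(subjects, pat)))
    bir <- fmdblast:::bi_from_pattern(idx, revcomp(pat))
    expect_identical(bi$size, bir$size)
    expect_identical(bi$lower_rc, bir$lower)
  }
})

test_that("index bundles round-trip, detect corruption, and are deterministic", {
  set.seed(23)
  tx <- fmd_text(c(a = paste0(rand_seq(500), "N", rand_seq(499))), seed = 9)
  idx <- fmd_index(tx, r = 8L)
  idx$lookup <- build_lookup(idx, 5L)
  p1 <- tempfile(); p2 <- tempfile()
  save_index(idx, p1)
  save_index(idx, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))

  idx2 <- load_index(p1)
  ks <- sample(0:(idx$n - 1), 50)
  expect_identical(sa_lookup(idx2, ks), sa_lookup(idx, ks))
  for (pat in c("ACGTA", "TTT", "GAGA")) {
    a <- fmdblast:::bi_from_pattern(idx, pat)
    b <- fmdblast:::bi_from_pattern(idx2, pat)
    expect_identical(unclass(a), unclass(b))
  }
  expect_identical(idx2$lookup$size, idx$lookup$size)

  bad <- tempfile()
  writeBin(as.raw(c(0xde, 0xad, 0xbe, 0xef)), bad)
  expect_error(load_index(bad), "corrupt|magic")
  expect_error(load_index(tempfile()), "not found")
})
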