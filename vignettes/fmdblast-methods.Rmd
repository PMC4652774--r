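---
title: "Methods: FMD-index seeding and seed-and-extend alignment in fmdblast"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: FMD-index seeding and seed-and-extend alignment in fmdblast}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

`fmdblast` searches a nucleotide query set against a nucleotide database and
reports statistically scored local alignments in BLAST tabular form.  The
classical seed-and-extend heuristic applies: find short exact matches
(*seeds*) between query and database, extend promising seeds into gap-free
alignments, and extend high-scoring gap-free anchors into gapped alignments
(HSPs).

The distinguishing design is that the **database**, not the query, is
indexed, using the FMD-index: the FM-index (suffix array `SA`, BWT `B`,
cumulative counts `C`, occurrence array `O`) built over the concatenation of
every subject with its reverse complement, each segment `$`-terminated, with
alphabet order `$ < A < C < G < T`.  A pattern `P` is represented by its
*bi-interval* `[I_l(P), I_l(P̄), I_s(P)]`: the lower bound of its
suffix-array interval, the lower bound of the interval of its reverse
complement, and their common size.  Backward extension maps `ω(P)` to
`ω(aP)` in constant time from `C` and `O`; forward extension to `ω(Pa)` is
the mirror operation (backward-extend the reverse complement by the
complement symbol and swap the bounds).  Because both strands live in one
text, a single search finds plus- and minus-strand matches simultaneously.

Attached to the index is a `4^k`-entry lookup table holding the bi-interval
of every k-mer, filled once at index time by a depth-first walk of the
4-ary k-mer trie that prunes empty intervals; its cost is proportional to
the number of distinct k-mers actually present.  The table never has to be
rebuilt per search, which is the point of indexing the database side.

## Seeding

A *w-seed* is a triple `(q, s, w)`: the query window of length `w` at `q`
exactly matches a database window at `s` on one strand.  The query is
scanned at positions `0, stride, 2·stride, …`; `stride = w − k + 1` is the
largest step that still places a table k-mer inside every w-window, so no
w-seed can be missed.  For each codable k-mer the table yields a
bi-interval, which is extended backward one symbol at a time; every backward
prefix that can begin a w-window is then completed rightward by forward
extension to length `w`, and non-empty windows are emitted (each window at
most once, tracked per query offset).

This emission rule is deliberately stronger than emitting only where the
interval shrinks during backward extension.  Shrink-only emission misses
*shadowed* seeds: when every occurrence of a partial match extends one
symbol further left, the window one position to the right still has its own
`(q, s)` pair on the same diagonal.  A diagonal filter downstream makes
those seeds redundant for alignment, but the seeding contract here is
set-level: the located seed set must equal, exactly, the set of all
`(q, s)` pairs with a w-length exact match on either strand.  The test
suite enforces that contract against a quadratic hashed-window oracle on
randomized planted-homology pairs, and checks the stride bound is sharp
with a constructed witness that `stride = w − k + 1` finds and
`w − k + 2` misses.

Positions are recovered through a rank-sampled suffix array: only
`SA[0], SA[r], SA[2r], …` are stored, and `SA[k]` is reached by at most
`r − 1` LF-mapping steps.  `r` trades memory for locate speed; the default
is `r = 8` (a build-time option), reflecting that seeding-heavy workloads
are dominated by locate calls.

Ambiguity and masking: ambiguous IUPAC symbols in database subjects are
replaced by seeded uniform draws from `{A,C,G,T}` at text-build time and
logged (the index records the seed, so rebuilds are reproducible).
Ambiguous query symbols are treated as mismatches: they make a k-mer
uncodable and empty any extension crossing them.  Soft-masking (lowercase
FASTA) is honored on the query side at seeding: a stride k-mer lying
entirely inside a masked span is skipped, while extensions may cross mask
boundaries — standard soft-mask semantics.  An optional hard-exclusion
mode zeroes table entries whose database occurrences all fall inside
masked spans; since a bi-interval cannot exclude individual occurrences,
partially masked k-mers always stay.

## From seeds to HSPs

Seeds are sorted by (query, subject, strand, diagonal `d = s − q`, subject
offset), so co-linear seeds cluster and smaller subject offsets come first.
Per diagonal, a running *diagonal offset* `D` — the end subject offset of
the last ungapped alignment — suppresses redundant work: a later seed on
the same diagonal is discarded if its subject offset is strictly below `D`
(an offset equal to `D` still extends; the filter's stated rule is "less
than").  The filter is required to be result-neutral: extending every seed
and deduplicating must give the identical final HSP set, and a dedicated
test asserts exactly that on mutated-homology and tandem-repeat fixtures.

Minus-strand seeds are extended in the frame of the reverse-complemented
subject (where diagonals behave like plus-strand diagonals) and converted
to plus-strand coordinates only at output, where `sstart > send` marks the
minus strand.

Ungapped extension is the classic two-sided X-drop scan: extend left, then
right, tracking the best running score per direction, stopping a direction
when the running score falls more than `xdrop_ungapped` below its best.
Anchors reaching the gapped trigger score are passed to a gapped X-drop
extension: affine-gap dynamic programming (`gap_open + g·gap_extend` for a
gap of length `g`) started at the **midpoint** of the anchor and run
outward in both directions, pruning any cell more than `xdrop_gapped`
below the running best — the pruning keeps the explored band narrow
without a fixed band width.  Traceback yields identity/mismatch/gap
counts, so every HSP's score is reproducible from its own counts (an
invariant the tests recompute).  The midpoint (rather than the
best-scoring column) was chosen as the anchor entry point: for the
high-identity anchors that reach the trigger the two coincide in practice,
and the midpoint is deterministic without extra bookkeeping.

HSPs fully contained in a higher-scoring HSP on the same
(query, subject, strand) are dropped; ties are broken by
`(s_start, q_start)` order, so the outcome is deterministic.

## Statistics

E-values use ungapped Karlin–Altschul statistics: `lambda` is the unique
positive root of `Σ p_i p_j e^{λ s(i,j)} = 1` (root-finding to 1e-12);
`K` uses the lattice-case series with span `δ` (gcd of attainable scores),
relative entropy `H = λ Σ x p(x) e^{λx}`, and the Spitzer-type sum over
j-fold convolutions of the per-position score distribution,
`K = δ λ e^{−2σ} / (H (1 − e^{−λδ}))`, truncated when terms fall below
1e-12.  `E = K m n e^{−λS}` with `m` the raw query length and `n` the
total plus-strand database length — no edge correction, a documented
simplification, as is applying ungapped statistics to gapped scores.  The
bit score is `(λS − ln K)/ln 2`, so `E = m n 2^{−bits}` exactly.

Thresholds: the gapped trigger defaults to the raw score worth 25 bits;
the final cutoff keeps HSPs with `E ≤ 10`.  Both derive from the
Karlin–Altschul parameters of the active scoring scheme and are
CLI-overridable.  Ungapped anchors below the trigger are dropped rather
than reported, keeping the output a single species of gapped HSP.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `w` (`-word_size`) | 28 | seed length; MegaBLAST-style default |
| `k` (`--k`) | 11 | lookup-table word length; `k ≤ w ≤ 14` guard on memory |
| `stride` | `w − k + 1` | query scan step; the maximal lossless value |
| `r` (`--r`) | 8 | SA sampling interval; locate cost ≤ `r − 1` LF steps |
| reward / penalty | +1 / −2 | match/mismatch scores |
| gap open / extend | 5 / 2 | affine gap costs (`open + g·extend`) |
| X-drop ungapped / gapped | 20 / 30 | raw-score termination margins |
| gap trigger | 25 bits | ungapped score starting a gapped extension |
| E-value cutoff | 10 | final report threshold |

## The synthetic world

The generator (`fixture_spec`, `gen_database`, `gen_queries`,
`gen_adversarial`) stands in for a genomic database plus UniGene-style
query sets.  Defaults: 4 subjects of 2–8 kb with uniform base composition
(a desk-scale stand-in for a genome assembly), N injection at 0.1%, ~5% of
each subject under soft-mask spans of 20–80 bp; 20 queries in the
short-query regime (100–500 bp), 75% of them mutated copies of database
windows on a random strand (3% substitutions, 0.5% indel initiation,
indels ≤ 5 bp — moderate intra-species divergence), the rest random
background.  All randomness flows through one seed; the same spec yields
byte-identical files, and a JSON-lines truth manifest records every
planted feature, so tests assert recall against ground truth.

What a green suite establishes — and what it does not: correctness of the
index, seeding and extension machinery on uniform-composition sequence
with planted homologies.  It does not establish behavior on real genomes
(repeat families, GC skew, low-complexity tracts are absent beyond the
tandem-repeat construction), nor NCBI-byte-compatible output, nor any
performance property.

Adversarial constructions are deterministic, with boundary characters
forced (e.g. `T` junctions around a 3-letter-alphabet repeat unit) so that
the intended hit set is exact rather than probable: the stride-maximality
witness, a period-7 tandem repeat whose full-length windows all sit on one
diagonal (exactly one ungapped extension through the filter), a
reverse-complement-palindromic window (one hit per strand), a w-hit ending
on the last query symbol, and a window straddling a masked query span.

## Numerical and degenerate-input choices

* Multiple sentinels are disambiguated by text position during suffix
  sorting; for BWT cells holding a sentinel, the exact LF target is stored
  in a small map built from the full SA (one entry per segment), keeping
  sampled-SA walks correct across segment boundaries.  The rank of suffix 0
  short-circuits the walk.
* Suffix sorting is prefix doubling (O(n log² n)), validated against a
  brute-force string sort oracle; correctness, not asymptotics, is the
  contract.
* The occurrence array is checkpointed every 128 symbols with on-the-fly
  counting in between — chosen for simplicity over bit-packing.
* Coordinates are 0-based half-open internally; 1-based inclusive only in
  tabular output.  pident prints with 3 decimals, bit scores with 1, and
  E-values as `0.0` below 1e-179, `%.2e` below 1e-3, `%.3g` otherwise, so
  golden-file comparisons are byte-stable.
* Empty inputs error early with named positions; a query shorter than `w`
  yields an empty (not erroneous) result; an empty bi-interval locates to
  zero rows.
* Worker parallelism is an orchestration contract: the loaded index is
  shared read-only, queries are partitioned, and results are merged in
  input order, so output is byte-identical for any worker count (forked
  workers on Unix; sequential fallback elsewhere).

## Known limitations

* No DUST/WindowMasker implementation: `-dust yes` is accepted for
  compatibility but only honors soft-masking present in the input, with a
  warning.
* No traceback-stage restoration of ambiguous database symbols: replaced
  bases stay replaced in reported alignments (the replacement log is kept
  in the bundle).
* Ungapped statistics on gapped scores, raw search-space lengths, no
  linked-HSP sum statistics.
* The X-drop rules can clip pathological extensions whose optimal segment
  requires passing through a deep score valley; the oracle tests state and
  tolerate exactly this caveat.
* The index is plain integer vectors, not 2-bit-packed: desk-scale
  databases are the target, not a 16 GB-RAM human-genome build.
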