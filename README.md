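# fmdblast

Nucleotide database search the BLAST way, indexed the BWT way.

`fmdblast` is an R package implementing a seed-and-extend local aligner
whose seeding stage runs on an **FMD-index** of the database: the FM-index
(suffix array, Burrows–Wheeler transform, cumulative counts `C`,
occurrence array `O`) of every subject concatenated with its reverse
complement.  A pattern `P` is carried as a *bi-interval*
`ω(P) = [I_l(P), I_l(P̄), I_s(P)]` — its suffix-array interval together
with that of its reverse complement — so one backward/forward extension
step per symbol searches both strands at once.  A `4^k`-entry lookup table
stores `ω` for every k-mer; queries are scanned at stride `w − k + 1` (the
largest stride that cannot miss a `w`-length exact match), backward and
forward extension recover the bi-interval of **every** matching w-window,
and a rank-sampled suffix array (`SA[0], SA[r], SA[2r], …`, default
`r = 8`, locate by ≤ `r − 1` LF-mapping steps) turns intervals into
(subject, strand, offset) seeds.

Seeds are sorted by (query, subject, strand, diagonal `d = s − q`, subject
offset); a per-diagonal offset `D` (the end of the last ungapped
alignment) discards redundant seeds — provably without changing the final
result.  Surviving seeds get classic two-sided ungapped X-drop extension;
anchors above a bit-score trigger get banded affine-gap X-drop DP from the
anchor midpoint, with traceback-derived identity/mismatch/gap counts.
HSPs are scored with Karlin–Altschul statistics
(`E = K·m·n·e^{−λS}`, λ from root-finding, K from the lattice series) and
printed as BLAST tabular output (formats 6 and 7, 12 standard columns,
`sstart > send` on the minus strand).

Who this is for: anyone needing a transparent, fully tested, desk-scale
reference implementation of database-indexed MegaBLAST-style search —
bi-interval seeding, diagonal filtering, X-drop extension — in idiomatic
R with the hot kernels in C++.

## Worked example

```r
library(fmdblast)

spec <- fixture_spec(seed = 42, n_subjects = 2, subject_len = c(2000, 3000),
                     n_queries = 4, planted_frac = 1,
                     substitution_rate = 0.02, indel_rate = 0.005,
                     ambiguity_rate = 0, mask_rate = 0)
db <- gen_database(spec, "db.fa")          # FASTA + feature manifest
qs <- gen_queries(spec, db, "queries.fa")  # FASTA + truth manifest (JSONL)

cmd_index(c("db.fa", "--k", "11"))
#> indexed 2 subject(s), 11116 symbols; r=8, k=11, 11046/4194304 k-mers present (0.26%)

out <- cmd_align(c("-db", "db.fa.fmdidx", "-query", "queries.fa",
                   "-word_size", "12", "-outfmt", "7"))
cat(out[1:7], sep = "\n")
#> # fmdblast 0.1.0
#> # Query: query001
#> # Database: db.fa.fmdidx
#> # Fields: query id, subject id, % identity, alignment length, mismatches, gap opens, q. start, q. end, s. start, s. end, evalue, bit score
#> # 1 hits found
#> query001	subj02	96.503	143	2	1	1	140	1315	1173	3.11e-66	237.2
#> # fmdblast 0.1.0
```

Reading the hit line: `query001` aligns to `subj02` at 96.503% identity
over 143 columns (2 mismatches, 1 gap open), covering query 1–140;
subject coordinates 1315 → 1173 run backwards, so the match is on the
minus strand; the E-value 3.11e-66 is the expected number of chance hits
of at least this score (raw score mapped to 237.2 bits) in a search space
of query length × database length.  Each of the four generated queries is
a mutated copy of a database window, and each is recovered as exactly one
HSP overlapping its planted location — the truth manifest in
`queries.fa.truth.jsonl` carries the planted coordinates the test suite
asserts against.

The same search runs from a shell via `inst/cli/fmdblast.R`:

```sh
Rscript inst/cli/fmdblast.R index db.fa --k 11
Rscript inst/cli/fmdblast.R align -db db.fa.fmdidx -query queries.fa \
        -outfmt 7 -num_threads 4
```

Output is byte-identical for any `-num_threads` value: the index is loaded
once and shared, queries are partitioned across workers, and results are
merged in input order.

## Package layout

* `R/text.R`, `R/index.R` — bidirectional text construction; suffix array
  (prefix doubling), BWT, checkpointed occurrences, sampled SA, locate,
  bundle save/load.
* `R/lookup.R` — 2-bit k-mer coding and the `4^k` bi-interval table.
* `R/seeding.R` — stride scan, backward/forward interval extension, seed
  resolution and sorting.
* `R/extension.R`, `R/stats.R` — diagonal filter, ungapped/gapped X-drop
  extension, containment filtering, Karlin–Altschul statistics.
* `R/io.R`, `R/cli.R` — FASTA with soft-mask capture, tabular formats 6/7,
  `index`/`align` commands, worker orchestration.
* `R/fixtures.R` — the seeded synthetic-data generator and adversarial
  constructions.
* `src/fmd.cpp` — the C++ kernels (suffix sort, occurrence counting,
  extensions, SA walks, alignment DP).

See `vignettes/fmdblast-methods.Rmd` for the full methods account:
parameter semantics and defaults, what the synthetic world does and does
not establish, numerical choices and known limitations.
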