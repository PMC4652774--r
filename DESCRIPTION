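Package: fmdblast
Title: FMD-Index Seed-and-Extend Nucleotide Database Search
Version: 0.1.0
Authors@R:
    person("fmdblast", "maintainers", email = "fmdblast@example.org",
           role = c("aut", "cre"))
Description: Nucleotide database search built on the FMD-index: the
    Burrows-Wheeler transform of a database concatenated with its reverse
    complement, queried through bi-intervals that track a pattern and its
    reverse complement simultaneously.  A 4^k-entry lookup table stores the
    bi-interval of every k-mer; queries are scanned in strides, exact
    w-length seeds are recovered by backward/forward bi-interval extension
    and a sampled-suffix-array locate step, and seeds are extended through
    diagonal-filtered ungapped and banded gapped X-drop alignment into
    BLAST-style tabular hits with Karlin-Altschul E-values.  Includes an
    index/align command-line workflow and a seeded synthetic-data generator
    for databases, query sets and adversarial constructions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    parallel,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
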