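# Alphabet: $ < A < C < G < T, coded 0..4.  Ambiguous IUPAC symbols in
# queries are kept as code 0 at the search layer (they match nothing);
# database ambiguity is resolved at text-build time.

ALPHABET <- c("$", "A", "C", "G", "T")
IUPAC_DNA <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
               "B", "D", "H", "V", "N")

.code_map <- local({
  m <- rep(NA_integer_, 256)
  bases <- c(A = 1L, C = 2L, G = 3L, T = 4L)
  for (b in names(bases)) {
    m[utf8ToInt(b)] <- bases[[b]]
    m[utf8ToInt(tolower(b))] <- bases[[b]]
  }
  amb <- setdiff(IUPAC_DNA, names(bases))
  for (b in amb) {
    m[utf8ToInt(b)] <- 0L
    m[utf8ToInt(tolower(b))] <- 0L
  }
  m
})

#' Encode a DNA string as integer symbol codes
#'
#' @param x a single character string over the IUPAC nucleotide alphabet.
#' @return integer vector with A,C,G,T as 1..4; ambiguous IUPAC codes as 0;
#'   symbols outside the IUPAC alphabet as `NA`.
#' @keywords internal
dna_codes <- function(x) {
  if (nchar(x) == 0L) return(integer(0))
  .code_map[utf8ToInt(x)]
}

codes_to_dna <- function(codes) {
  paste(ALPHABET[codes + 1L], collapse = "")
}

#' Complement of symbol codes (A<->T, C<->G); the sentinel maps to itself.
#' @keywords internal
comp_codes <- function(codes) {
  ifelse(codes >= 1L & codes <= 4L, 5L - codes, codes)
}

revcomp_codes <- function(codes) rev(comp_codes(codes))

#' Reverse complement of a DNA string
#' @param x a character string over A/C/G/T (case preserved as upper).
#' @return the reverse complement string.
#' @export
revcomp <- function(x) {
  chartr("ACGTacgt", "TGCAtgca", paste(rev(strsplit(x, "")[[1]]), collapse = ""))
}

# Evaluate `expr` under a fixed RNG seed without clobbering the caller's
# random stream.
with_rng_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

sym_code <- function(a) {
  if (is.character(a)) {
    stopifnot(nchar(a) == 1L)
    code <- match(toupper(a), ALPHABET) - 1L
    if (is.na(code)) stop("symbol '", a, "' is not in the alphabet {$,A,C,G,T}")
    code
  } else {
    a <- as.integer(a)
    if (is.na(a) || a < 0L || a > 4L)
      stop("symbol code must be in 0..4 ($,A,C,G,T)")
    a
  }
}
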