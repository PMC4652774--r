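#' Karlin-Altschul parameters for an ungapped scoring scheme
#'
#' `lambda` is the unique positive root of
#' `sum_{i,j} p_i p_j exp(lambda * s(i,j)) = 1` for the match/mismatch scheme
#' and background base frequencies `bg`.  `K` is computed by the standard
#' lattice series: with score span delta (gcd of attainable scores), relative
#' entropy `H = lambda * sum_x x p(x) exp(lambda x)`, and Spitzer-type sum
#' `sigma = sum_j (1/j) * [P(S_j >= 0) + E(exp(lambda S_j); S_j < 0)]` over
#' j-fold convolutions of the per-position score distribution,
#' `K = delta * lambda * exp(-2 sigma) / (H * (1 - exp(-lambda delta)))`.
#' Both are deterministic to better than 1e-6.
#'
#' @param scoring a [scoring_params()] object (only `reward` and `penalty`
#'   are used; E-values use ungapped statistics, a documented
#'   simplification).
#' @param bg background frequencies of A, C, G, T (must sum to 1).
#' @return list with `lambda`, `K` and `H`.
#' @export
karlin_altschul_params <- function(scoring, bg = rep(0.25, 4)) {
  stopifnot(length(bg) == 4L, abs(sum(bg) - 1) < 1e-8)
  reward <- scoring$reward; penalty <- scoring$penalty
  p_match <- sum(bg^2)
  # per-position score distribution on the integer lattice penalty..reward
  lo <- penalty; hi <- reward
  probs <- numeric(hi - lo + 1L)
  probs[reward - lo + 1L] <- p_match
  probs[penalty - lo + 1L] <- probs[penalty - lo + 1L] + (1 - p_match)
  vals <- lo:hi
  mean_score <- sum(vals * probs)
  if (mean_score >= 0)
    stop("expected per-position score must be negative for local statistics")
  if (max(vals[probs > 0]) <= 0)
    stop("a positive score must be achievable")

  f <- function(l) sum(probs * exp(l * vals)) - 1
  up <- 1
  while (f(up) < 0) up <- up * 2
  lambda <- uniroot(f, c(1e-10, up), tol = 1e-12)$root

  present <- vals[probs > 0]
  delta <- Reduce(function(a, b) {
    while (b) { t <- a %% b; a <- b; b <- t }; a
  }, abs(present[present != 0]))
  H <- lambda * sum(vals * probs * exp(lambda * vals))

  # sigma by direct convolution of the score distribution
  sigma <- 0
  conv <- probs
  cvals <- vals
  for (j in 1:200) {
    term <- sum(conv[cvals >= 0]) +
      sum(conv[cvals < 0] * exp(lambda * cvals[cvals < 0]))
    sigma <- sigma + term / j
    if (term < 1e-12) break
    # convolve with the base distribution
    newlo <- cvals[1] + lo; newhi <- cvals[length(cvals)] + hi
    nc <- numeric(newhi - newlo + 1L)
    nz <- which(conv > 0)
    for (t in nz) {
      idx <- (cvals[t] + lo - newlo + 1L):(cvals[t] + hi - newlo + 1L)
      nc[idx] <- nc[idx] + conv[t] * probs
    }
    conv <- nc
    cvals <- newlo:newhi
  }
  K <- delta * lambda * exp(-2 * sigma) / (H * (1 - exp(-lambda * delta)))
  list(lambda = lambda, K = K, H = H)
}

#' E-value of a raw alignment score
#'
#' `E = K * m * n * exp(-lambda * score)` with effective lengths `m`
#' (query) and `n` (total database residues, plus strand).
#'
#' @param score raw score.
#' @param ka list from [karlin_altschul_params()].
#' @param m,n effective query and database lengths.
#' @return the expected number of chance alignments with at least this score.
#' @export
hit_evalue <- function(score, ka, m, n) {
  ka$K * as.numeric(m) * as.numeric(n) * exp(-ka$lambda * score)
}

#' Bit score of a raw alignment score
#'
#' `(lambda * score - ln K) / ln 2`, so that `E = m * n * 2^(-bitscore)`.
#'
#' @inheritParams hit_evalue
#' @export
hit_bitscore <- function(score, ka) {
  (ka$lambda * score - log(ka$K)) / log(2)
}

# Smallest raw score whose E-value is <= E on an m x n search space.
score_for_evalue <- function(E, ka, m, n) {
  as.integer(ceiling(log(ka$K * as.numeric(m) * as.numeric(n) / E) /
                       ka$lambda))
}

# Raw score corresponding to a bit-score threshold.
score_for_bits <- function(bits, ka) {
  as.integer(ceiling((bits * log(2) + log(ka$K)) / ka$lambda))
}
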