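# Internal helpers.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards. All randomised venomscan functions use
# this so they never clobber the user's random stream.
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

# Gini coefficient of a non-negative vector (0 = perfectly even).
giniCoefficient <- function(x) {
  stopifnot(all(x >= 0), sum(x) > 0)
  x <- sort(as.numeric(x))
  n <- length(x)
  2 * sum(seq_len(n) * x) / (n * sum(x)) - (n + 1) / n
}

# Kyte-Doolittle hydropathy scale.
KD_SCALE <- c(
  A = 1.8,  R = -4.5, N = -3.5, D = -3.5, C = 2.5,
  Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I = 4.5,
  L = 3.8,  K = -3.9, M = 1.9,  F = 2.8,  P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2
)

# Small residues compatible with the (-3,-1) signal-peptidase rule.
SMALL_RESIDUES <- c("A", "G", "S", "C", "T")

AA20 <- c("A","R","N","D","C","Q","E","G","H","I",
          "L","K","M","F","P","S","T","W","Y","V")

# BLOSUM62 with X (and ambiguity codes) rescored to 0, cached per session.
.venomscan_cache <- new.env(parent = emptyenv())

blosum62x <- function() {
  if (is.null(.venomscan_cache$blosum62x)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    M <- e$BLOSUM62
    for (a in c("X", "B", "Z", "J")) {
      if (a %in% rownames(M)) {
        M[a, ] <- 0L
        M[, a] <- 0L
      }
    }
    .venomscan_cache$blosum62x <- M
  }
  .venomscan_cache$blosum62x
}

# Reverse-complement for plain character vectors.
revcompChar <- function(x) {
  as.character(reverseComplement(DNAStringSet(x)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Split a character string into codons; `gapped` keeps '-' columns.
codonSplit <- function(s) {
  n <- nchar(s)
  stopifnot(n %% 3 == 0)
  substring(s, seq(1, n, 3), seq(3, n, 3))
}

# Codon -> amino acid under the standard code ('*' for stops).
codonTranslate <- function(codons) {
  unname(GENETIC_CODE[codons])
}
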