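# Independent oracle implementations used to verify the package's
# machinery. These deliberately share no code with the implementation
# paths they check.

# Full-matrix Smith-Waterman (affine gaps, three-state DP) returning the
# best local score only.
oracleSW <- function(a, b, M = venomscan:::blosum62x(), open = 11,
                     ext = 1) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)
  FF <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(H[i, j - 1] - open - ext, E[i, j - 1] - ext)
      FF[i, j] <- max(H[i - 1, j] - open - ext, FF[i - 1, j] - ext)
      H[i, j] <- max(0, H[i - 1, j - 1] + M[A[i - 1], B[j - 1]],
                     E[i, j], FF[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

# Brute-force 6-frame ORF enumeration: walk forward from every ATG to the
# first in-frame stop; keep maximal ORFs (the earliest ATG per stop).
oracleOrfs <- function(seq, minLen) {
  seq <- toupper(seq)
  out <- list()
  strands <- list(`+` = seq,
                  `-` = as.character(Biostrings::reverseComplement(
                    Biostrings::DNAString(seq))))
  for (st in names(strands)) {
    s <- strands[[st]]
    L <- nchar(s)
    for (off in 0:2) {
      byStop <- list()
      pos <- off + 1
      while (pos + 2 <= L) {
        if (substring(s, pos, pos + 2) == "ATG") {
          # walk to the first in-frame stop
          p <- pos
          stopAt <- NA
          while (p + 2 <= L) {
            cod <- substring(s, p, p + 2)
            if (cod %in% c("TAA", "TAG", "TGA") && p > pos) {
              stopAt <- p
              break
            }
            p <- p + 3
          }
          if (!is.na(stopAt)) {
            key <- as.character(stopAt)
            if (is.null(byStop[[key]]) || pos < byStop[[key]])
              byStop[[key]] <- pos
          }
        }
        pos <- pos + 3
      }
      for (key in names(byStop)) {
        start <- byStop[[key]]
        stopAt <- as.integer(key)
        nAA <- (stopAt - start) / 3
        if (nAA >= minLen) {
          cds <- substring(s, start, stopAt - 1)
          aa <- as.character(Biostrings::translate(
            Biostrings::DNAString(cds)))
          out[[length(out) + 1]] <- list(strand = st, frame = off + 1,
                                         aa = aa)
        }
      }
    }
  }
  out
}

# Union-find connected components over an edge list.
oracleComponents <- function(nodes, edges) {
  parent <- stats::setNames(nodes, nodes)
  find <- function(x) {
    while (parent[[x]] != x) x <- parent[[x]]
    x
  }
  if (nrow(edges)) {
    for (k in seq_len(nrow(edges))) {
      ra <- find(edges[k, 1]); rb <- find(edges[k, 2])
      if (ra != rb) parent[[ra]] <- rb
    }
  }
  roots <- vapply(nodes, find, character(1))
  unname(lapply(split(nodes, roots), sort))
}

# Per-codon enumeration of synonymous site fractions, written against the
# raw genetic code table.
oracleSynSites <- function(codon) {
  gc <- Biostrings::GENETIC_CODE
  ch <- strsplit(codon, "")[[1]]
  s <- 0
  for (p in 1:3) {
    for (b in setdiff(c("A", "C", "G", "T"), ch[p])) {
      alt <- ch; alt[p] <- b
      if (gc[[paste(alt, collapse = "")]] == gc[[codon]]) s <- s + 1 / 3
    }
  }
  s
}

oracleSiteCounts <- function(a, b) {
  ca <- substring(a, seq(1, nchar(a), 3), seq(3, nchar(a), 3))
  cb <- substring(b, seq(1, nchar(b), 3), seq(3, nchar(b), 3))
  sA <- sum(vapply(ca, oracleSynSites, numeric(1)))
  sB <- sum(vapply(cb, oracleSynSites, numeric(1)))
  s <- (sA + sB) / 2
  c(s = s, n = 3 * length(ca) - s)
}

# Direct Gini computation from the mean-absolute-difference definition.
oracleGini <- function(x) {
  n <- length(x)
  sum(abs(outer(x, x, "-"))) / (2 * n^2 * mean(x))
}

randomProtein <- function(len) {
  paste(sample(c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L",
                 "K", "M", "F", "P", "S", "T", "W", "Y", "V"),
               len, replace = TRUE), collapse = "")
}

randomDNA <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

randomCodons <- function(nCodons) {
  sense <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
  paste(sample(sense, nCodons, replace = TRUE), collapse = "")
}
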