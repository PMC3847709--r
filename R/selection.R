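# Lightweight pairwise dN/dS screen: Nei-Gojobori (1986) site and
# difference counting with equal-weight minimal-pathway averaging and
# Jukes-Cantor correction. Mutations to stop codons count as
# nonsynonymous in site counting (keeping sites conserved at 3 per
# codon); mutational pathways passing through a stop codon are excluded
# and the pathway weights renormalised.

#' Construct a codon alignment
#'
#' @param seqs a named [Biostrings::DNAStringSet] or named character
#'   vector of equal-length aligned coding sequences (ACGT and `-`), with
#'   gaps in frame-preserving codon-aligned triplets.
#' @return a [CodonAlignment-class].
#' @export
codonAlignment <- function(seqs) {
  x <- DNAStringSet(seqs)
  if (is.null(names(x))) names(x) <- paste0("seq", seq_along(x))
  new("CodonAlignment", seqs = x)
}

# Per-codon synonymous site fraction lookup (sum over the 3 positions of
# the fraction of single-nucleotide changes that are synonymous).
synSitesPerCodon <- function() {
  if (!is.null(.venomscan_cache$synSites)) return(.venomscan_cache$synSites)
  bases <- c("A", "C", "G", "T")
  sense <- names(GENETIC_CODE)[GENETIC_CODE != "*"]
  syn <- setNames(numeric(length(sense)), sense)
  for (cod in sense) {
    ch <- strsplit(cod, "")[[1]]
    s <- 0
    for (p in 1:3) {
      for (b in setdiff(bases, ch[p])) {
        alt <- ch
        alt[p] <- b
        altc <- paste(alt, collapse = "")
        if (GENETIC_CODE[[altc]] == GENETIC_CODE[[cod]]) s <- s + 1 / 3
      }
    }
    syn[cod] <- s
  }
  .venomscan_cache$synSites <- syn
  syn
}

# Synonymous/nonsynonymous differences between two codons, averaged over
# all minimal mutational pathways with equal weights; pathways through
# stop codons are dropped (weights renormalised; if every pathway is
# blocked, all pathways are used unweighted).
codonPathDiffs <- function(c1, c2) {
  if (c1 == c2) return(c(s = 0, n = 0))
  x1 <- strsplit(c1, "")[[1]]
  x2 <- strsplit(c2, "")[[1]]
  pos <- which(x1 != x2)
  perms <- switch(as.character(length(pos)),
    "1" = list(pos),
    "2" = list(pos, rev(pos)),
    "3" = {
      p <- pos
      list(p[c(1, 2, 3)], p[c(1, 3, 2)], p[c(2, 1, 3)],
           p[c(2, 3, 1)], p[c(3, 1, 2)], p[c(3, 2, 1)])
    })
  evalPath <- function(order) {
    cur <- x1
    s <- 0; n <- 0
    for (p in order) {
      nxt <- cur
      nxt[p] <- x2[p]
      a1 <- GENETIC_CODE[[paste(cur, collapse = "")]]
      a2 <- GENETIC_CODE[[paste(nxt, collapse = "")]]
      if (a2 == "*") return(NULL)  # pathway through a stop codon
      if (a1 == a2) s <- s + 1 else n <- n + 1
      cur <- nxt
    }
    c(s = s, n = n)
  }
  res <- lapply(perms, evalPath)
  ok <- !vapply(res, is.null, logical(1))
  if (any(ok)) {
    res <- res[ok]
  } else {
    # all pathways blocked: fall back to unweighted counting ignoring
    # intermediate stops
    res <- lapply(perms, function(order) {
      cur <- x1
      s <- 0; n <- 0
      for (p in order) {
        nxt <- cur
        nxt[p] <- x2[p]
        a1 <- GENETIC_CODE[[paste(cur, collapse = "")]]
        a2 <- GENETIC_CODE[[paste(nxt, collapse = "")]]
        if (!is.na(a1) && !is.na(a2) && a1 == a2) s <- s + 1 else n <- n + 1
        cur <- nxt
      }
      c(s = s, n = n)
    })
  }
  Reduce(`+`, res) / length(res)
}

jukesCantor <- function(p) {
  arg <- 1 - 4 * p / 3
  if (arg <= 0) return(NA_real_)  # saturated
  -3 / 4 * log(arg)
}

#' Pairwise Nei-Gojobori dN/dS estimate
#'
#' Counts synonymous and nonsynonymous sites (averaged over both
#' sequences) and differences (equal-weight averaging over minimal
#' mutational pathways for multi-hit codons), applies the Jukes-Cantor
#' multiple-hit correction to the proportions, and reports
#' `omega = dN/dS` (undefined when `dS = 0`). Codon columns containing a
#' gap in either sequence are removed before counting.
#'
#' @param a,b equal-length in-frame coding sequences (character or
#'   [Biostrings::DNAString]); internal stop codons are an error.
#' @param idA,idB ids used in the output row.
#' @return one-row [S4Vectors::DataFrame]: `idA`, `idB`, `nCodons`,
#'   `sSites`, `nSites`, `sDiff`, `nDiff`, `pS`, `pN`, `dS`, `dN`,
#'   `omega`, `omegaDefined`, `saturated`.
#' @export
#' @examples
#' ng86Pairwise("TTTTGG", "TTATGG")
ng86Pairwise <- function(a, b, idA = "a", idB = "b") {
  sa <- toupper(as.character(a))
  sb <- toupper(as.character(b))
  if (nchar(sa) != nchar(sb))
    stop("sequences must have equal length (", nchar(sa), " vs ",
         nchar(sb), ")")
  if (nchar(sa) %% 3 != 0) stop("sequence length must be a multiple of 3")
  ca <- codonSplit(sa)
  cb <- codonSplit(sb)
  gap <- grepl("-", ca, fixed = TRUE) | grepl("-", cb, fixed = TRUE)
  ca <- ca[!gap]; cb <- cb[!gap]
  if (!length(ca)) stop("no ungapped codon columns to compare")
  aaA <- GENETIC_CODE[ca]
  aaB <- GENETIC_CODE[cb]
  if (any(is.na(aaA)) || any(is.na(aaB)))
    stop("non-ACGT characters in codons")
  if (any(aaA == "*"))
    stop("internal stop codon in first sequence at codon ",
         which(aaA == "*")[1])
  if (any(aaB == "*"))
    stop("internal stop codon in second sequence at codon ",
         which(aaB == "*")[1])
  syn <- synSitesPerCodon()
  sA <- sum(syn[ca]); sB <- sum(syn[cb])
  sSites <- (sA + sB) / 2
  nSites <- 3 * length(ca) - sSites
  diffs <- c(s = 0, n = 0)
  for (i in which(ca != cb)) diffs <- diffs + codonPathDiffs(ca[i], cb[i])
  pS <- if (sSites > 0) diffs[["s"]] / sSites else 0
  pN <- if (nSites > 0) diffs[["n"]] / nSites else 0
  dS <- jukesCantor(pS)
  dN <- jukesCantor(pN)
  saturated <- is.na(dS) || is.na(dN)
  omegaDefined <- !saturated && !is.na(dS) && dS > 0
  omega <- if (omegaDefined) dN / dS else NA_real_
  DataFrame(idA = idA, idB = idB, nCodons = length(ca),
            sSites = sSites, nSites = nSites,
            sDiff = diffs[["s"]], nDiff = diffs[["n"]],
            pS = pS, pN = pN, dS = dS, dN = dN, omega = omega,
            omegaDefined = omegaDefined, saturated = saturated)
}

#' Group-level dN/dS screen over a codon alignment
#'
#' Runs [ng86Pairwise()] on every sequence pair (gapped codon columns are
#' stripped per pair) and summarises the group: the mean omega over pairs
#' with `dS > 0` (saturated pairs excluded), and a `diversifying` flag
#' raised when the mean omega exceeds 1.
#'
#' @param alignment a [CodonAlignment-class] (or anything accepted by
#'   [codonAlignment()]) with at least 2 sequences.
#' @return list with `pairs` (a [S4Vectors::DataFrame]), `meanOmega`, and
#'   `diversifying`.
#' @export
groupOmegaScreen <- function(alignment) {
  if (!is(alignment, "CodonAlignment")) alignment <- codonAlignment(alignment)
  seqs <- as.character(alignedSeqs(alignment))
  if (length(seqs) < 2) stop("need at least 2 sequences")
  ids <- names(seqs)
  rows <- list()
  for (i in seq_len(length(seqs) - 1)) {
    for (j in (i + 1):length(seqs)) {
      rows[[length(rows) + 1L]] <-
        ng86Pairwise(seqs[[i]], seqs[[j]], ids[i], ids[j])
    }
  }
  pairs <- do.call(rbind, rows)
  valid <- pairs$omegaDefined
  meanOmega <- if (any(valid)) mean(pairs$omega[valid]) else NA_real_
  list(pairs = pairs, meanOmega = meanOmega,
       diversifying = isTRUE(meanOmega > 1))
}

#' Simulate a codon alignment under a fixed dN/dS
#'
#' Star-tree simulation used for estimator-recovery tests and as the
#' elevated-nonsynonymous-rate family generator: a random ancestor of
#' sense codons evolves independently along `nSeq` branches under a
#' continuous-time model where each nucleotide position mutates at rate
#' `mu/3` to each alternative base and changes are accepted at relative
#' rate 1 (synonymous), `omega` (nonsynonymous) or 0 (stop).
#'
#' @param nSeq number of sequences.
#' @param nCodons alignment length in codons.
#' @param omega simulated dN/dS.
#' @param divergence expected number of neutral substitutions per
#'   nucleotide site per branch (default 0.03: counting estimators are
#'   consistent in the low-divergence regime typical of within-family
#'   isoform comparisons).
#' @param seed integer seed.
#' @return a [CodonAlignment-class] (ungapped).
#' @export
simulateCodonAlignment <- function(nSeq = 4, nCodons = 500, omega = 1,
                                   divergence = 0.03, seed = 1L) {
  stopifnot(nSeq >= 2, nCodons >= 1, omega >= 0, divergence >= 0)
  bases <- c("A", "C", "G", "T")
  sense <- names(GENETIC_CODE)[GENETIC_CODE != "*"]
  withSeed(seed, {
    anc <- sample(sense, nCodons, replace = TRUE)
    evolve <- function(cod) {
      # per-codon list of possible single-nt changes with relative rates
      codRates <- function(cc) {
        ch <- strsplit(cc, "")[[1]]
        alts <- character(); rates <- numeric()
        for (p in 1:3) {
          for (b in setdiff(bases, ch[p])) {
            alt <- ch; alt[p] <- b
            altc <- paste(alt, collapse = "")
            r <- if (GENETIC_CODE[[altc]] == "*") 0
              else if (GENETIC_CODE[[altc]] == GENETIC_CODE[[cc]]) 1
              else omega
            if (r > 0) { alts <- c(alts, altc); rates <- c(rates, r) }
          }
        }
        list(alts = alts, rates = rates / 3)
      }
      rl <- lapply(cod, codRates)
      tot <- vapply(rl, function(x) sum(x$rates), numeric(1))
      t <- 0
      repeat {
        R <- sum(tot) * divergence  # time scaled so mu*t = divergence at t=1
        if (R <= 0) break
        t <- t + rexp(1, R)
        if (t >= 1) break
        i <- sample.int(length(cod), 1, prob = tot)
        pick <- sample.int(length(rl[[i]]$alts), 1, prob = rl[[i]]$rates)
        cod[i] <- rl[[i]]$alts[pick]
        rl[[i]] <- codRates(cod[i])
        tot[i] <- sum(rl[[i]]$rates)
      }
      cod
    }
    seqs <- vapply(seq_len(nSeq), function(k)
      paste(evolve(anc), collapse = ""), character(1))
    codonAlignment(setNames(seqs, sprintf("sim_%02d", seq_len(nSeq))))
  })
}
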