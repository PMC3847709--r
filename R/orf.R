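# Six-frame ORF discovery, rule-based signal-peptide prediction and
# cysteine profiling.

#' Find open reading frames in all six frames
#'
#' Scans a nucleotide sequence in all six frames and reports maximal ORFs:
#' the first ATG after the previous in-frame stop, read through to the next
#' in-frame stop (the stop is required and is not part of the translated
#' product). ORFs shorter than `minLen` amino acids are dropped. With
#' `includeTruncated = TRUE`, partial ORFs clipped by the sequence ends are
#' also reported and flagged: `no_stop` (an ATG-initiated frame running off
#' the 3' end) and `no_start` (a frame entering from the 5' end that hits a
#' stop without any upstream ATG). These feed the truncation stringency
#' filter of the annotation workflow; they are excluded by default.
#'
#' Coordinates are 1-based inclusive on the input (plus) strand; `frame` is
#' `+1,+2,+3` or `-1,-2,-3`. ORFs are returned in descending amino-acid
#' length order (ties: by start coordinate, then frame).
#'
#' @param seq a single nucleotide sequence (character or
#'   [Biostrings::DNAString]), or a named character vector /
#'   [Biostrings::DNAStringSet] of sequences.
#' @param minLen minimum protein length in amino acids (default 60).
#' @param includeTruncated also report end-truncated partial ORFs.
#' @param id source id used when `seq` is a single unnamed sequence.
#'
#' @return A [S4Vectors::DataFrame] with columns `id`, `sourceId`, `frame`,
#'   `start`, `end`, `aaLength`, `aa`, `truncated`, `truncReason`.
#' @export
#' @examples
#' orfs <- findOrfs("AAATGGCTATGTTTAAGCTTTAA", minLen = 2)
findOrfs <- function(seq, minLen = 60, includeTruncated = FALSE, id = NULL) {
  stopifnot(minLen >= 1)
  if (is(seq, "DNAStringSet") ||
      (is.character(seq) && length(seq) > 1)) {
    seqs <- as.character(seq)
    ids <- names(seqs) %||% paste0("seq_", seq_along(seqs))
    res <- lapply(seq_along(seqs), function(i)
      findOrfs(seqs[[i]], minLen, includeTruncated, id = ids[[i]]))
    return(do.call(rbind, res))
  }
  s <- toupper(as.character(seq))
  id <- id %||% (names(s) %||% "seq")
  s <- unname(s)
  L <- nchar(s)
  empty <- DataFrame(id = character(), sourceId = character(),
                     frame = character(), start = integer(),
                     end = integer(), aaLength = integer(),
                     aa = character(), truncated = logical(),
                     truncReason = character())
  if (L < 3) return(empty)
  rows <- list()
  strands <- list(`+` = s, `-` = revcompChar(s))
  for (strand in names(strands)) {
    ss <- strands[[strand]]
    for (off in 0:2) {
      ncod <- (L - off) %/% 3
      if (ncod < 1) next
      cod <- substring(ss, off + seq(1, by = 3, length.out = ncod),
                       off + seq(3, by = 3, length.out = ncod))
      aa <- codonTranslate(cod)
      aa[is.na(aa)] <- "X"           # codons containing N
      stops <- which(aa == "*")
      starts <- which(cod == "ATG")
      segStart <- c(1L, stops + 1L)  # first codon index of each segment
      segStop <- c(stops, ncod + 1L) # the terminating stop (ncod+1 = none)
      for (k in seq_along(segStart)) {
        a <- segStart[k]; z <- segStop[k]
        atg <- starts[starts >= a & starts < z]
        hasStop <- z <= ncod
        if (length(atg) && hasStop) {
          i0 <- atg[1]
          nAA <- z - i0
          if (nAA >= minLen) {
            rows[[length(rows) + 1L]] <- list(
              strand, off, i0, z, paste(aa[i0:(z - 1)], collapse = ""),
              FALSE, NA_character_)
          }
        } else if (includeTruncated) {
          if (length(atg) && !hasStop) {
            i0 <- atg[1]
            nAA <- ncod - i0 + 1L
            if (nAA >= minLen)
              rows[[length(rows) + 1L]] <- list(
                strand, off, i0, z, paste(aa[i0:ncod], collapse = ""),
                TRUE, "no_stop")
          } else if (!length(atg) && hasStop && a == 1L && z - a >= minLen) {
            # open frame entering from the sequence edge
            rows[[length(rows) + 1L]] <- list(
              strand, off, a, z, paste(aa[a:(z - 1)], collapse = ""),
              TRUE, "no_start")
          }
        }
      }
    }
  }
  if (!length(rows)) return(empty)
  strand <- vapply(rows, `[[`, character(1), 1)
  off <- vapply(rows, `[[`, numeric(1), 2)
  i0 <- vapply(rows, `[[`, numeric(1), 3)
  z <- vapply(rows, `[[`, numeric(1), 4)
  aaSeq <- vapply(rows, `[[`, character(1), 5)
  trunc <- vapply(rows, `[[`, logical(1), 6)
  reason <- vapply(rows, `[[`, character(1), 7)
  # codon indices -> 1-based plus-strand nucleotide coordinates of the CDS
  # (including the stop codon when present)
  ncodEnd <- ifelse(trunc & reason == "no_stop", z - 1, z)
  s1 <- off + (i0 - 1) * 3 + 1     # on the scanned strand
  e1 <- off + ncodEnd * 3
  e1 <- pmin(e1, L)
  startPlus <- ifelse(strand == "+", s1, L - e1 + 1)
  endPlus <- ifelse(strand == "+", e1, L - s1 + 1)
  frame <- ifelse(strand == "+", paste0("+", off + 1), paste0("-", off + 1))
  out <- DataFrame(
    id = character(length(rows)), sourceId = id, frame = frame,
    start = as.integer(startPlus), end = as.integer(endPlus),
    aaLength = nchar(aaSeq), aa = aaSeq, truncated = trunc,
    truncReason = reason)
  ord <- order(-out$aaLength, out$start, out$frame)
  out <- out[ord, ]
  out$id <- sprintf("%s|orf%02d", id, seq_len(nrow(out)))
  out
}

#' Rule-based signal-peptide prediction
#'
#' A deterministic stand-in for an HMM/neural signal-peptide predictor,
#' encoding the three canonical features of secretory signal peptides: a
#' positively charged n-region, a hydrophobic h-region, and small residues
#' at the -3/-1 positions of the signal-peptidase cleavage site. A cleavage
#' site after residue `c` (mature peptide starting at `c + 1`) is accepted
#' iff, for some `c` in `[15, 35]`:
#'
#' * at least one K or R occurs among residues 1-5;
#' * some window of >= `hWindow` residues lying within positions
#'   `3 .. c - 3` has mean Kyte-Doolittle hydropathy >= `hMin`;
#' * residues `c - 2` and `c` (the -3 and -1 positions) are small
#'   (A, G, S, C or T).
#'
#' The reported score is the best qualifying window's mean hydropathy and
#' the reported cleavage site is the accepted `c` with the highest score
#' (ties: smallest `c`). Inputs shorter than 25 residues are not evaluable
#' (`evaluable = FALSE`, distinct from a rejection).
#'
#' @param aa amino-acid sequence(s): character vector or
#'   [Biostrings::AAStringSet].
#' @param hMin minimum mean hydropathy of the h-region window (default 1.6).
#' @param hWindow minimum h-region window length (default 6).
#' @param cleavageRange allowed signal peptide lengths (default `c(15, 35)`).
#'
#' @return A [S4Vectors::DataFrame] with one row per input: `id`,
#'   `accepted`, `cleavageSite` (number of signal residues; the mature
#'   region starts at `cleavageSite + 1`), `score`, `evaluable`.
#' @export
predictSignalPeptide <- function(aa, hMin = 1.6, hWindow = 6,
                                 cleavageRange = c(15L, 35L)) {
  seqs <- as.character(aa)
  ids <- names(seqs) %||% paste0("prot_", seq_along(seqs))
  one <- function(s) {
    n <- nchar(s)
    if (n < 25)
      return(list(FALSE, NA_integer_, NA_real_, FALSE))
    ch <- strsplit(s, "")[[1]]
    if (!any(ch[1:5] %in% c("K", "R")))
      return(list(FALSE, NA_integer_, NA_real_, TRUE))
    kd <- unname(KD_SCALE[ch])
    kd[is.na(kd)] <- 0
    bestC <- NA_integer_; bestScore <- -Inf
    for (cc in seq(cleavageRange[1], min(cleavageRange[2], n - 1))) {
      if (!(ch[cc - 2] %in% SMALL_RESIDUES && ch[cc] %in% SMALL_RESIDUES))
        next
      hi <- cc - 3
      if (hi - 3 + 1 < hWindow) next
      sc <- bestWindowMean(kd, 3L, hi, hWindow)
      if (is.finite(sc) && sc >= hMin && sc > bestScore) {
        bestScore <- sc
        bestC <- cc
      }
    }
    if (is.na(bestC)) list(FALSE, NA_integer_, NA_real_, TRUE)
    else list(TRUE, bestC, bestScore, TRUE)
  }
  res <- lapply(seqs, one)
  DataFrame(
    id = ids,
    accepted = vapply(res, `[[`, logical(1), 1),
    cleavageSite = vapply(res, `[[`, integer(1), 2),
    score = vapply(res, `[[`, numeric(1), 3),
    evaluable = vapply(res, `[[`, logical(1), 4)
  )
}

# Best mean over all windows of length >= w within positions [a, b].
bestWindowMean <- function(x, a, b, w) {
  if (b - a + 1 < w) return(-Inf)
  cs <- c(0, cumsum(x))
  best <- -Inf
  for (len in w:(b - a + 1)) {
    for (i in a:(b - len + 1)) {
      m <- (cs[i + len] - cs[i]) / len
      if (m > best) best <- m
    }
  }
  best
}

#' Cysteine profile of a mature region
#'
#' Positions (1-based, relative to the mature region) and count of cysteine
#' residues downstream of a signal-peptide cleavage site. The plesiotypic
#' three-finger toxin scaffold, for example, carries ten mature cysteines.
#'
#' @param aa a single amino-acid sequence (character or
#'   [Biostrings::AAString]).
#' @param matureStart 1-based index of the first mature residue (use
#'   `cleavageSite + 1` from [predictSignalPeptide()]; 1 profiles the whole
#'   protein).
#'
#' @return `list(positions = <integer>, count = <integer>)`.
#' @export
cysteineProfile <- function(aa, matureStart = 1L) {
  s <- as.character(aa)
  stopifnot(length(s) == 1, matureStart >= 1, matureStart <= nchar(s))
  mat <- substring(s, matureStart)
  pos <- which(strsplit(mat, "")[[1]] == "C")
  list(positions = as.integer(pos), count = length(pos))
}
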