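# All-vs-all protein similarity: local alignment scores, Karlin-Altschul
# E-values, best-hit / reciprocal-best-hit extraction, and greedy
# non-redundant clustering.

#' Create an alignment scoring scheme
#'
#' @param matrixName substitution matrix (only `"BLOSUM62"` is shipped;
#'   ambiguity codes including X are rescored to 0).
#' @param gapOpen,gapExtend affine gap penalties; a gap of length L costs
#'   `gapOpen + L * gapExtend`.
#' @param lambda,K Karlin-Altschul parameters for
#'   `E = K * m * n * exp(-lambda * S)`; defaults are the standard gapped
#'   BLOSUM62-11-1 constants.
#' @param dbSize total residue count of the search database (`NA` =
#'   pairwise mode: the subject length is used as `n`).
#' @return a [ScoringScheme-class].
#' @export
#' @examples
#' scoringScheme()
scoringScheme <- function(matrixName = "BLOSUM62", gapOpen = 11,
                          gapExtend = 1, lambda = 0.267, K = 0.041,
                          dbSize = NA_real_) {
  if (!identical(matrixName, "BLOSUM62"))
    stop("only BLOSUM62 is shipped")
  new("ScoringScheme", matrixName = matrixName, gapOpen = gapOpen,
      gapExtend = gapExtend, lambda = lambda, K = K,
      dbSize = as.numeric(dbSize))
}

# E-value from a raw score: E = K * m * n * exp(-lambda * S).
karlinAltschulE <- function(score, m, n, scheme) {
  scheme@K * m * n * exp(-scheme@lambda * score)
}

checkProtein <- function(x, what = "sequence") {
  bad <- !grepl("^[ACDEFGHIKLMNPQRSTVWYX]+$", x)
  if (any(bad))
    stop(what, " contains empty or non-amino-acid input: ",
         paste(head(which(bad)), collapse = ", "))
  invisible(x)
}

#' Align two proteins and report a similarity hit
#'
#' Smith-Waterman local alignment under the scheme's substitution matrix
#' and affine gap penalties, with the raw score converted to an E-value via
#' the Karlin-Altschul formula `E = K * m * n * exp(-lambda * S)` where `m`
#' is the query length and `n` is the database size (or the subject length
#' in pairwise mode).
#'
#' @param a,b query and subject protein sequences (character or
#'   [Biostrings::AAString]); 20-letter alphabet, X allowed (scored 0).
#' @param scheme a [ScoringScheme-class].
#' @param dbSize override the scheme's database size for this call.
#' @return one-row [S4Vectors::DataFrame]: `query`, `subject`, `rawScore`,
#'   `identity` (matches / alignment columns), `alnLength`, `evalue`.
#' @export
#' @examples
#' alignPair("MKWVTFISLLLLFSSAYS", "MKWVTFISLLLLFSSAYS")
alignPair <- function(a, b, scheme = scoringScheme(), dbSize = NULL) {
  qa <- as.character(a); sb <- as.character(b)
  stopifnot(length(qa) == 1, length(sb) == 1)
  checkProtein(c(qa, sb))
  r <- swBatch(qa, sb, scheme)
  n <- dbSize %||% scheme@dbSize
  if (is.na(n)) n <- nchar(sb)
  DataFrame(query = names(a) %||% "query", subject = names(b) %||% "subject",
            rawScore = r$score, identity = r$matches / r$alnCols,
            alnLength = r$alnCols,
            evalue = karlinAltschulE(r$score, nchar(qa), n, scheme))
}

# Compiled Smith-Waterman batch: all queries against one subject.
swBatch <- function(queries, subjectSeq, scheme) {
  M <- blosum62x()
  cpp_sw_batch(queries, subjectSeq, M, paste(rownames(M), collapse = ""),
               as.integer(scheme@gapOpen), as.integer(scheme@gapExtend))
}

# Full score/matches/alnCols matrices between two sequence sets (rows =
# setA, cols = setB). The raw SW score is symmetric, so callers can reuse
# one matrix for both search directions.
swMatrix <- function(setA, setB, scheme) {
  a <- as.character(setA); b <- as.character(setB)
  score <- matrix(0, length(a), length(b),
                  dimnames = list(names(a), names(b)))
  matches <- score; alnCols <- score
  for (j in seq_along(b)) {
    r <- swBatch(a, b[[j]], scheme)
    score[, j] <- r$score
    matches[, j] <- r$matches
    alnCols[, j] <- r$alnCols
  }
  list(score = score, matches = matches, alnCols = alnCols)
}

#' All-vs-all similarity search against a panel
#'
#' Aligns every query against every panel sequence and keeps hits with
#' `evalue <= evalueMax` (default 1e-5, the classic annotation cutoff).
#' E-values are computed in database mode against the panel's total residue
#' count unless the scheme fixes `dbSize`. Self-pairs (same id) are
#' skipped. Hits are sorted per query by ascending E-value, then descending
#' raw score, then subject id.
#'
#' @param queries,panel named [Biostrings::AAStringSet] (or named character
#'   vectors).
#' @param scheme a [ScoringScheme-class].
#' @param evalueMax E-value ceiling.
#' @return [S4Vectors::DataFrame] of hits with columns as in [alignPair()].
#' @export
searchAllVsAll <- function(queries, panel, scheme = scoringScheme(),
                           evalueMax = 1e-5) {
  if (!is(queries, "AAStringSet")) queries <- AAStringSet(queries)
  if (!is(panel, "AAStringSet")) panel <- AAStringSet(panel)
  emptyHits <- DataFrame(query = character(), subject = character(),
                         rawScore = numeric(), identity = numeric(),
                         alnLength = integer(), evalue = numeric())
  if (length(panel) == 0) {
    warning("empty panel: no hits")
    return(emptyHits)
  }
  if (is.null(names(queries)))
    names(queries) <- paste0("q", seq_along(queries))
  if (is.null(names(panel))) names(panel) <- paste0("s", seq_along(panel))
  qc <- as.character(queries); pc <- as.character(panel)
  checkProtein(qc, "query")
  checkProtein(pc, "panel")
  dbSize <- scheme@dbSize
  if (is.na(dbSize)) dbSize <- sum(nchar(pc))
  sw <- swMatrix(queries, panel, scheme)
  ev <- sw$score
  for (j in seq_len(ncol(ev)))
    ev[, j] <- karlinAltschulE(sw$score[, j], nchar(qc), dbSize, scheme)
  keep <- which(ev <= evalueMax & outer(names(queries), names(panel), "!="),
                arr.ind = TRUE)
  if (nrow(keep) == 0) return(emptyHits)
  hits <- DataFrame(query = names(queries)[keep[, 1]],
                    subject = names(panel)[keep[, 2]],
                    rawScore = sw$score[keep],
                    identity = sw$matches[keep] / pmax(1, sw$alnCols[keep]),
                    alnLength = as.integer(sw$alnCols[keep]),
                    evalue = ev[keep])
  hits[order(hits$query, hits$evalue, -hits$rawScore, hits$subject), ]
}

# Best hit per query from a hit table (ascending evalue, descending raw
# score, subject id). Returns NA subject for queries with ambiguous top
# (tied evalue AND raw score across different subjects).
bestHitPerQuery <- function(hits, queries) {
  top <- setNames(rep(NA_character_, length(queries)), queries)
  ambiguous <- setNames(logical(length(queries)), queries)
  for (q in unique(hits$query)) {
    h <- hits[hits$query == q, ]
    h <- h[order(h$evalue, -h$rawScore, h$subject), ]
    top[q] <- h$subject[1]
    if (nrow(h) > 1 && h$evalue[2] == h$evalue[1] &&
        h$rawScore[2] == h$rawScore[1]) {
      ambiguous[q] <- TRUE
      top[q] <- NA_character_
    }
  }
  list(top = top, ambiguous = ambiguous)
}

#' Reciprocal best hits between two protein sets
#'
#' A pair `(a, b)` is reported iff `b` is `a`'s unique top hit in `setB`
#' and `a` is `b`'s unique top hit in `setA` (ranking by E-value, then raw
#' score, then id; queries whose top hit is tied on both E-value and raw
#' score are excluded and reported via a message).
#'
#' @param setA,setB named [Biostrings::AAStringSet] (or named character
#'   vectors).
#' @param scheme a [ScoringScheme-class].
#' @param evalueMax hit ceiling applied in both directions.
#' @return [S4Vectors::DataFrame] with columns `idA`, `idB`, `rawScore`,
#'   `evalueAB`, `evalueBA`.
#' @export
reciprocalBestHits <- function(setA, setB, scheme = scoringScheme(),
                               evalueMax = 1e-5) {
  if (!is(setA, "AAStringSet")) setA <- AAStringSet(setA)
  if (!is(setB, "AAStringSet")) setB <- AAStringSet(setB)
  if (is.null(names(setA))) names(setA) <- paste0("a", seq_along(setA))
  if (is.null(names(setB))) names(setB) <- paste0("b", seq_along(setB))
  ac <- as.character(setA); bc <- as.character(setB)
  checkProtein(ac, "setA"); checkProtein(bc, "setB")
  sw <- swMatrix(setA, setB, scheme)
  evAB <- sw$score; evBA <- t(sw$score)
  for (j in seq_len(ncol(evAB)))
    evAB[, j] <- karlinAltschulE(sw$score[, j], nchar(ac), sum(nchar(bc)),
                                 scheme)
  for (j in seq_len(ncol(evBA)))
    evBA[, j] <- karlinAltschulE(t(sw$score)[, j], nchar(bc),
                                 sum(nchar(ac)), scheme)
  topOf <- function(evRow, scoreRow, ids) {
    ok <- which(evRow <= evalueMax)
    if (!length(ok)) return(NA_character_)
    ord <- ok[order(evRow[ok], -scoreRow[ok], ids[ok])]
    if (length(ord) > 1 &&
        evRow[ord[2]] == evRow[ord[1]] &&
        scoreRow[ord[2]] == scoreRow[ord[1]])
      return(NA_character_)  # unresolved tie
    ids[ord[1]]
  }
  topA <- vapply(seq_along(setA), function(i)
    topOf(evAB[i, ], sw$score[i, ], names(setB)), character(1))
  topB <- vapply(seq_along(setB), function(j)
    topOf(evBA[j, ], sw$score[, j], names(setA)), character(1))
  names(topA) <- names(setA); names(topB) <- names(setB)
  nAmb <- sum(is.na(topA) & apply(evAB <= evalueMax, 1, any)) +
    sum(is.na(topB) & apply(evBA <= evalueMax, 1, any))
  if (nAmb > 0)
    message(nAmb, " sequences with unresolved top-hit ties excluded",
            " from RBH")
  rows <- list()
  for (a in names(setA)) {
    b <- topA[[a]]
    if (is.na(b)) next
    if (!is.na(topB[[b]]) && topB[[b]] == a) {
      rows[[length(rows) + 1L]] <- DataFrame(
        idA = a, idB = b, rawScore = sw$score[a, b],
        evalueAB = evAB[a, b], evalueBA = evBA[b, a])
    }
  }
  if (!length(rows))
    return(DataFrame(idA = character(), idB = character(),
                     rawScore = numeric(), evalueAB = numeric(),
                     evalueBA = numeric()))
  do.call(rbind, rows)
}

#' Greedy non-redundant clustering of a sequence panel
#'
#' cd-hit-style greedy incremental clustering: sequences are processed
#' longest-first; each sequence joins the first existing representative to
#' which its local-alignment identity over the shorter sequence length
#' reaches `identityThreshold`, otherwise it founds a new cluster.
#' Re-clustering the representatives is a fixed point.
#'
#' @param panel named [Biostrings::AAStringSet] (or named character vector).
#' @param identityThreshold fraction in (0, 1] (default 0.9).
#' @param scheme a [ScoringScheme-class] (alignment parameters only).
#' @return list with `representatives` (an [Biostrings::AAStringSet]) and
#'   `members` (named list: representative id -> member ids, including the
#'   representative itself).
#' @export
clusterNonredundant <- function(panel, identityThreshold = 0.9,
                                scheme = scoringScheme()) {
  if (identityThreshold <= 0 || identityThreshold > 1)
    stop("identityThreshold must be in (0, 1]")
  panel <- AAStringSet(panel)
  if (is.null(names(panel))) names(panel) <- paste0("s", seq_along(panel))
  checkProtein(as.character(panel), "panel")
  ord <- order(-nchar(as.character(panel)), names(panel))
  panel <- panel[ord]
  reps <- character()
  members <- list()
  for (i in seq_along(panel)) {
    s <- as.character(panel[[i]])
    placed <- FALSE
    for (r in reps) {
      rSeq <- as.character(panel[[match(r, names(panel))]])
      r2 <- swBatch(s, rSeq, scheme)
      ident <- r2$matches / min(nchar(s), nchar(rSeq))
      if (ident >= identityThreshold) {
        members[[r]] <- c(members[[r]], names(panel)[i])
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps <- c(reps, names(panel)[i])
      members[[names(panel)[i]]] <- names(panel)[i]
    }
  }
  list(representatives = panel[reps], members = members)
}

#' Write hits in 12-column tabular search format
#'
#' Mirrors the classic tab-separated hit table (query, subject, %identity,
#' alignment length, mismatches, gap opens, qstart, qend, sstart, send,
#' evalue, bitscore). Coordinate columns are reported as 0 (not tracked by
#' the hit container); the bit score uses the scheme's lambda/K.
#'
#' @param hits a hit [S4Vectors::DataFrame] from [searchAllVsAll()].
#' @param path output TSV path.
#' @param scheme the [ScoringScheme-class] used for the search.
#' @return `path`, invisibly.
#' @export
writeHitTable <- function(hits, path, scheme = scoringScheme()) {
  bit <- (scheme@lambda * hits$rawScore - log(scheme@K)) / log(2)
  df <- data.frame(hits$query, hits$subject,
                   round(100 * hits$identity, 2), hits$alnLength,
                   round((1 - hits$identity) * hits$alnLength), 0, 0, 0, 0,
                   0, format(hits$evalue, digits = 3), round(bit, 1))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
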