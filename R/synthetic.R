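# Synthetic venom-gland transcriptome generator.
#
# The planted protein repertoire (family ancestors, isoform amino-acid
# sequences, signal peptides, and the matching reference panel) is built
# from a fixed internal RNG stream so that the engineered family structure
# (similarity clusters, per-isoform panel orthologs) and the packaged panel
# FASTA are identical across user seeds. The user seed controls everything
# library-specific: synonymous codon choice, UTRs, the abundance
# permutation of background transcripts, and read sampling.

REPERTOIRE_SEED <- 9151L

# Mature-region composition of secreted venom proteins: hydrophilic-leaning
# (toxins are small soluble secreted proteins), cysteines placed explicitly.
AA_COMPO_SECRETED <- c(
  A = 0.055, R = 0.065, N = 0.055, D = 0.065, E = 0.075, Q = 0.055,
  G = 0.060, H = 0.030, I = 0.030, L = 0.050, K = 0.075, F = 0.030,
  P = 0.050, S = 0.065, T = 0.055, W = 0.012, Y = 0.040, V = 0.040,
  M = 0.020)

# Generic globular-protein composition for housekeeping transcripts.
AA_COMPO_GENERIC <- c(
  A = 0.074, R = 0.052, N = 0.045, D = 0.054, C = 0.025, Q = 0.034,
  E = 0.054, G = 0.074, H = 0.026, I = 0.068, L = 0.099, K = 0.058,
  M = 0.025, F = 0.047, P = 0.039, S = 0.057, T = 0.051, W = 0.013,
  Y = 0.032, V = 0.073)

# Alphabet for the first 16 mature residues of secreted templates: no small
# residues, so the signal-peptidase (-3,-1) rule cannot fire at a spurious
# downstream cleavage position.
AA_NONSMALL <- setdiff(names(AA_COMPO_SECRETED), SMALL_RESIDUES)

CYS_3FTX <- c(18L, 24L, 30L, 36L, 43L, 47L, 52L, 58L, 62L, 66L)
CYS_NOVEL <- c(60L, 120L)
CYS_LIPOCALIN <- c(68L, 132L)
CYS_CRISP <- c(24L, 36L, 48L, 60L, 72L, 84L, 96L, 108L, 120L, 132L,
               144L, 156L, 168L, 180L, 188L, 196L)

sampleAA <- function(n, compo) {
  sample(names(compo), n, replace = TRUE, prob = compo)
}

# Random mature region with fixed cysteine positions; the first 16 residues
# avoid small residues (see AA_NONSMALL).
buildMature <- function(len, cysPos = integer()) {
  stopifnot(all(cysPos > 16), all(cysPos <= len))
  head16 <- sampleAA(min(16, len), AA_COMPO_SECRETED[AA_NONSMALL])
  rest <- if (len > 16) sampleAA(len - 16, AA_COMPO_SECRETED) else character()
  x <- c(head16, rest)
  x[cysPos] <- "C"
  paste(x, collapse = "")
}

# Substitute `rate` of the free positions, preserving cysteines and the
# no-small-residue rule of the first 16 positions; never introduces C.
mutateMature <- function(m, rate, cysPos = integer()) {
  x <- strsplit(m, "")[[1]]
  free <- setdiff(seq_along(x), cysPos)
  k <- max(1L, round(rate * length(free)))
  pos <- sample(free, k)
  for (p in pos) {
    alpha <- if (p <= 16) AA_NONSMALL else names(AA_COMPO_SECRETED)
    alpha <- setdiff(alpha, c(x[p], "C"))
    x[p] <- sample(alpha, 1)
  }
  paste(x, collapse = "")
}

# Unconstrained substitutions (panel orthologs), preserving cysteines.
mutateFree <- function(m, rate) {
  x <- strsplit(m, "")[[1]]
  free <- which(x != "C")
  k <- max(1L, round(rate * length(free)))
  pos <- sample(free, k)
  for (p in pos) x[p] <- sample(setdiff(AA20, c(x[p], "C")), 1)
  paste(x, collapse = "")
}

# A 19-residue signal peptide the heuristic predictor accepts with a unique
# cleavage site after residue 19: M, K (n-region charge), three polar
# residues, an 8-residue hydrophobic h-region, a proline breaker, two polar
# residues, then A-x-A across the -3/-1 positions.
buildSignalPeptide <- function() {
  paste(c("M", "K", sample(c("N", "D", "E", "Q", "H", "Y"), 3, TRUE),
          sample(c("L", "I", "V", "F"), 8, TRUE),
          "P", sample(c("N", "Q", "H", "E", "D"), 2, TRUE),
          "A", sample(c("H", "N", "Q", "E", "D"), 1), "A"),
        collapse = "")
}

SRTX_SPACER_ALPHABET <- c("N", "Q", "H", "I", "L", "F", "W", "Y", "V", "M")

# 21-residue endothelin-like sarafotoxin core: C at positions 1 and 7,
# no R (so no spurious dibasic KR boundary can form), no extra C.
buildSrtxCore <- function() {
  compo <- AA_COMPO_SECRETED[setdiff(names(AA_COMPO_SECRETED), "R")]
  x <- sampleAA(21, compo)
  x[c(1, 7)] <- "C"
  paste(x, collapse = "")
}

buildSrtxSpacer <- function(len = 12) {
  paste(sample(SRTX_SPACER_ALPHABET, len, TRUE), collapse = "")
}

# ---------------------------------------------------------------------------
# Fixed repertoire

# Builds (and caches) the full planted repertoire: a data.frame of proteins
# (id, family, cluster, signal length, mature length, cysteine count,
# protein sequence, expected verdict) plus the matching reference panel.
venomRepertoire <- function() {
  if (!is.null(.venomscan_cache$repertoire))
    return(.venomscan_cache$repertoire)
  rep <- withSeed(REPERTOIRE_SEED, {
    rows <- list()
    addRow <- function(id, family, cluster, signal, mature, cys) {
      rows[[length(rows) + 1L]] <<- data.frame(
        id = id, family = family, cluster = cluster,
        signalLength = ifelse(nzchar(signal), nchar(signal), NA_integer_),
        matureLength = nchar(mature), cysCountMature = cys,
        protein = paste0(signal, mature), stringsAsFactors = FALSE)
    }

    # -- three-finger toxins: 4 similarity clusters (4+4+2+2) + 1 outlier
    scaffolds <- replicate(5, buildMature(68, CYS_3FTX))
    sizes <- c(4L, 4L, 2L, 2L)
    iso <- 0L
    tftx <- character()
    for (cl in seq_along(sizes)) {
      for (j in seq_len(sizes[cl])) {
        iso <- iso + 1L
        m <- mutateMature(scaffolds[cl], 0.10, CYS_3FTX)
        addRow(sprintf("tpl_3ftx_%02d", iso), "3FTx", sprintf("G%d", cl),
               buildSignalPeptide(), m, 10L)
        tftx[iso] <- m
      }
    }
    iso <- iso + 1L
    addRow(sprintf("tpl_3ftx_%02d", iso), "3FTx", "outlier",
           buildSignalPeptide(), scaffolds[5], 10L)
    tftx[iso] <- scaffolds[5]

    # -- sarafotoxin precursors: polycistronic cassettes behind KR boundaries
    coreA <- buildSrtxCore()            # long isoform: core + DEP
    coreB <- buildSrtxCore()
    coreC <- buildSrtxCore()            # short isoform: bare 21-mer core
    srtx1mat <- paste0(
      buildSrtxSpacer(), "KR", coreA, "DEP",
      buildSrtxSpacer(), "KR", coreA, "DEP",
      buildSrtxSpacer(), "KR", coreA, "DEP")
    srtx2mat <- paste0(
      buildSrtxSpacer(), "KR", coreB, "DEP",
      buildSrtxSpacer(), "KR", coreC)
    addRow("tpl_srtx_01", "SRTX", "long3",
           buildSignalPeptide(), srtx1mat,
           cysteineProfile(srtx1mat)$count)
    addRow("tpl_srtx_02", "SRTX", "mixed2",
           buildSignalPeptide(), srtx2mat,
           cysteineProfile(srtx2mat)$count)

    # -- lipocalins
    lipoAnc <- buildMature(158, CYS_LIPOCALIN)
    lipo <- character(3)
    for (j in 1:3) {
      lipo[j] <- mutateMature(lipoAnc, 0.08, CYS_LIPOCALIN)
      addRow(sprintf("tpl_lipo_%02d", j), "lipocalin", "L1",
             buildSignalPeptide(), lipo[j], 2L)
    }

    # -- CRISP
    crispM <- buildMature(200, CYS_CRISP)
    addRow("tpl_crisp_01", "CRISP", "C1",
           buildSignalPeptide(), crispM, length(CYS_CRISP))

    # -- novel secreted proteins: 173-aa mature, two conserved cysteines,
    #    deliberately absent from the reference panel
    novelAnc <- buildMature(173, CYS_NOVEL)
    novel <- character(10)
    for (j in 1:10) {
      novel[j] <- mutateMature(novelAnc, 0.05, CYS_NOVEL)
      addRow(sprintf("tpl_novel_%02d", j), "novel_secreted", "N1",
             buildSignalPeptide(), novel[j], 2L)
    }

    # -- background: housekeeping, transposon-like, orphan controls
    for (j in seq_len(200)) {
      len <- sample(150:400, 1)
      addRow(sprintf("tpl_hk_%03d", j), "housekeeping", NA_character_,
             "", paste0("M", paste(sampleAA(len - 1, AA_COMPO_GENERIC),
                                   collapse = "")), NA_integer_)
    }
    for (j in seq_len(5)) {
      len <- sample(200:500, 1)
      addRow(sprintf("tpl_te_%02d", j), "TE_like", NA_character_,
             "", paste0("M", paste(sampleAA(len - 1, AA_COMPO_GENERIC),
                                   collapse = "")), NA_integer_)
    }
    # highly expressed orphan with NO signal peptide: the negative control
    # for the novel-candidate screen (resample until the predictor rejects)
    repeat {
      orph <- paste0("M", paste(sampleAA(190, AA_COMPO_GENERIC),
                                collapse = ""))
      if (!predictSignalPeptide(orph)$accepted) break
    }
    addRow("tpl_orph_01", "other", NA_character_, "", orph, NA_integer_)
    addRow("tpl_other_02", "other", NA_character_, "",
           paste0("M", paste(sampleAA(160, AA_COMPO_GENERIC),
                             collapse = "")), NA_integer_)

    proteins <- do.call(rbind, rows)
    proteins$expectedVerdict <- c(
      `3FTx` = "known_toxin", SRTX = "known_toxin",
      lipocalin = "known_toxin", CRISP = "known_toxin",
      novel_secreted = "novel_candidate", housekeeping = "non_toxin",
      TE_like = "non_toxin", other = "non_toxin")[proteins$family]

    # -- reference panel: one diverged ortholog per planted toxin isoform
    #    (ToxProt-style: the big families have many entries), plus decoy
    #    entries from toxin families not planted in the transcriptome.
    pan <- list()
    addPanel <- function(id, family, keywords, description, seq) {
      pan[[length(pan) + 1L]] <<- data.frame(
        id = id, family = family, keywords = keywords,
        description = description, seq = seq, stringsAsFactors = FALSE)
    }
    for (j in seq_along(tftx))
      addPanel(sprintf("TP_3ftx_%02d", j), "3FTx",
               "three-finger toxin|3FTx",
               "Three-finger toxin, synthetic ToxProt-style ortholog",
               mutateFree(tftx[j], 0.05))
    addPanel("TP_srtx_01", "sarafotoxin", "sarafotoxin|endothelin",
             "Sarafotoxin polycistronic precursor, synthetic ortholog",
             mutateFree(srtx1mat, 0.05))
    addPanel("TP_srtx_02", "sarafotoxin", "sarafotoxin|endothelin",
             "Sarafotoxin polycistronic precursor, synthetic ortholog",
             mutateFree(srtx2mat, 0.05))
    for (j in 1:3)
      addPanel(sprintf("TP_lipo_%02d", j), "lipocalin", "lipocalin",
               "Venom lipocalin, synthetic ortholog",
               mutateFree(lipo[j], 0.05))
    addPanel("TP_crisp_01", "CRISP", "CRISP|cysteine-rich secretory protein",
             "Cysteine-rich secretory protein, synthetic ortholog",
             mutateFree(crispM, 0.05))
    decoys <- list(
      c("kunitz", "kunitz|TFPI", "Kunitz-type protease inhibitor", 58),
      c("kunitz", "kunitz|TFPI", "Kunitz-type protease inhibitor", 60),
      c("PLA2", "PLA2|phospholipase", "Phospholipase A2", 122),
      c("SVMP", "SVMP|metalloproteinase|disintegrin",
        "Snake venom metalloproteinase", 205),
      c("waprin", "waprin", "Waprin", 50),
      c("lectin", "lectin", "C-type lectin", 129),
      c("lectin", "lectin", "C-type lectin", 133),
      c("kallikrein", "kallikrein|serine protease",
        "Venom kallikrein / serine protease", 232),
      c("AVIT", "AVIT", "AVIT venom protein", 81),
      c("crotamine", "crotamine", "Crotamine-like myotoxin", 42),
      c("cystatin", "cystatin", "Venom cystatin", 110),
      c("natriuretic", "natriuretic", "Natriuretic peptide precursor", 100),
      c("VNGF", "nerve growth factor|VNGF", "Venom nerve growth factor", 118),
      c("cholinesterase", "cholinesterase|choline esterase",
        "Venom cholinesterase", 248))
    for (j in seq_along(decoys)) {
      d <- decoys[[j]]
      addPanel(sprintf("TP_decoy_%02d", j), d[1], d[2],
               paste0(d[3], ", synthetic decoy"),
               paste(sampleAA(as.integer(d[4]), AA_COMPO_GENERIC),
                     collapse = ""))
    }
    panel <- do.call(rbind, pan)
    list(proteins = proteins, panel = panel)
  })
  # generator-detector consistency: every secreted template's own
  # translation must be accepted with cleavage after residue 19
  sec <- rep$proteins[!is.na(rep$proteins$signalLength), ]
  sig <- predictSignalPeptide(setNames(sec$protein, sec$id))
  stopifnot(all(sig$accepted), all(sig$cleavageSite == 19L))
  .venomscan_cache$repertoire <- rep
  rep
}

# ---------------------------------------------------------------------------
# Configuration

#' Generator settings for the synthetic transcriptome
#'
#' Counts per planted family and abundance-law settings. The engineered
#' toxin families are drawn from a fixed repertoire, so counts can be
#' reduced but not increased beyond the repertoire sizes (13 3FTx, 2 SRTX,
#' 3 lipocalins, 1 CRISP, 10 novel secreted, 200 housekeeping, 5
#' transposon-like, 2 orphan controls).
#'
#' @param n3FTx,nSRTX,nLipocalin,nCRISP,nNovel,nHousekeeping,nTE,nOther
#'   per-family template counts.
#' @param topK,topShare the abundance power law exponent is fitted so the
#'   `topK` highest-weight templates carry `topShare` of the total weight
#'   in expectation (the venom-gland situation: a small set of transcripts
#'   dominates the library).
#' @param utrLength integer range of UTR lengths flanking each CDS.
#' @return a list of class `transcriptomeConfig`.
#' @export
transcriptomeConfig <- function(n3FTx = 13, nSRTX = 2, nLipocalin = 3,
                                nCRISP = 1, nNovel = 10,
                                nHousekeeping = 200, nTE = 5, nOther = 2,
                                topK = 57, topShare = 0.55,
                                utrLength = c(45L, 60L)) {
  counts <- c(n3FTx = n3FTx, nSRTX = nSRTX, nLipocalin = nLipocalin,
              nCRISP = nCRISP, nNovel = nNovel,
              nHousekeeping = nHousekeeping, nTE = nTE, nOther = nOther)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("family counts must be non-negative integers")
  maxima <- c(13, 2, 3, 1, 10, 200, 5, 2)
  if (any(counts > maxima))
    stop("family counts exceed the fixed repertoire sizes (",
         paste(maxima, collapse = ","), ")")
  if (topShare <= 0 || topShare >= 1) stop("topShare must be in (0,1)")
  structure(list(counts = counts, topK = topK, topShare = topShare,
                 utrLength = utrLength),
            class = "transcriptomeConfig")
}

# Fit the discrete power-law exponent so the topK share equals the target.
fitPowerLawExponent <- function(n, topK, topShare) {
  if (n <= topK) return(1)
  f <- function(a) {
    w <- seq_len(n)^(-a)
    sum(w[seq_len(topK)]) / sum(w) - topShare
  }
  uniroot(f, c(1e-6, 6))$root
}

# Fixed abundance ranks of the planted transcripts (the venom-gland layout:
# the top transcript is the novel secreted protein, a signal-negative
# orphan sits at rank 2, lipocalins at ranks 3/18/27, novel isoforms and
# 3FTxs spread through the top 57, sarafotoxins weakly expressed near the
# bottom of the top set).
SPECIAL_RANKS <- c(
  tpl_novel_01 = 1, tpl_orph_01 = 2, tpl_lipo_01 = 3,
  tpl_novel_02 = 6, tpl_novel_03 = 9, tpl_novel_04 = 10,
  tpl_3ftx_01 = 12, tpl_3ftx_02 = 14, tpl_3ftx_03 = 16,
  tpl_lipo_02 = 18, tpl_3ftx_04 = 20, tpl_3ftx_05 = 22,
  tpl_3ftx_06 = 24, tpl_novel_05 = 25, tpl_lipo_03 = 27,
  tpl_3ftx_07 = 28, tpl_novel_06 = 30, tpl_3ftx_08 = 31,
  tpl_novel_07 = 33, tpl_3ftx_09 = 34, tpl_novel_08 = 36,
  tpl_3ftx_10 = 37, tpl_novel_09 = 39, tpl_3ftx_11 = 40,
  tpl_novel_10 = 42, tpl_3ftx_12 = 43, tpl_3ftx_13 = 45,
  tpl_crisp_01 = 47, tpl_srtx_01 = 50, tpl_srtx_02 = 53)

# ---------------------------------------------------------------------------
# Generation

#' Generate a synthetic venom-gland transcriptome with ground truth
#'
#' Builds transcript templates (5' UTR + CDS + 3' UTR) for a fixed planted
#' protein repertoire emulating a venom-gland transcriptome: 13 plesiotypic
#' ten-cysteine three-finger toxin isoforms engineered into 4 similarity
#' clusters plus one outlier, 2 polycistronic sarafotoxin precursors, 3
#' lipocalins, 1 CRISP, 10 novel secreted isoforms (173-aa mature, two
#' conserved cysteines, no counterpart in the reference panel), and
#' hundreds of background transcripts. Abundance weights follow a discrete
#' truncated power law whose exponent is fitted at generation time so the
#' 57 highest-weight templates carry a majority of the total weight.
#'
#' The amino-acid repertoire is identical across seeds (so the packaged
#' reference panel always matches); the seed drives synonymous codon
#' choice, UTR sequence, the abundance permutation of background
#' transcripts, and everything downstream. Fixed seed implies bit-identical
#' output.
#'
#' @param config a [transcriptomeConfig()].
#' @param seed integer seed.
#' @return a [VenomTemplateSet-class].
#' @export
#' @examples
#' tset <- generateTranscriptome(seed = 1)
#' tset
generateTranscriptome <- function(config = transcriptomeConfig(), seed = 1L) {
  if (!inherits(config, "transcriptomeConfig"))
    stop("config must come from transcriptomeConfig()")
  rep <- venomRepertoire()
  prot <- rep$proteins
  keep <- c(
    head(which(prot$family == "3FTx"), config$counts["n3FTx"]),
    head(which(prot$family == "SRTX"), config$counts["nSRTX"]),
    head(which(prot$family == "lipocalin"), config$counts["nLipocalin"]),
    head(which(prot$family == "CRISP"), config$counts["nCRISP"]),
    head(which(prot$family == "novel_secreted"), config$counts["nNovel"]),
    head(which(prot$family == "housekeeping"),
         config$counts["nHousekeeping"]),
    head(which(prot$family == "TE_like"), config$counts["nTE"]),
    head(which(prot$family == "other"), config$counts["nOther"]))
  prot <- prot[keep, ]
  n <- nrow(prot)
  if (n < 1) stop("empty transcriptome configuration")

  codonsByAA <- split(names(GENETIC_CODE), GENETIC_CODE)
  stopCodons <- codonsByAA[["*"]]

  withSeed(seed, {
    tpl <- character(n)
    cdsStart <- integer(n)
    cdsEnd <- integer(n)
    for (i in seq_len(n)) {
      aa <- strsplit(prot$protein[i], "")[[1]]
      for (attempt in 1:50) {
        cds <- paste(vapply(aa, function(a) {
          cc <- codonsByAA[[a]]
          if (length(cc) == 1) cc else sample(cc, 1)
        }, character(1)), collapse = "")
        cds <- paste0(cds, sample(stopCodons, 1))
        repeat {
          u5 <- paste(sample(c("A", "C", "G", "T"),
                             sample(config$utrLength[1]:config$utrLength[2],
                                    1), TRUE), collapse = "")
          if (!grepl("ATG", u5, fixed = TRUE)) break
        }
        u3 <- paste(sample(c("A", "C", "G", "T"),
                           sample(config$utrLength[1]:config$utrLength[2],
                                  1), TRUE), collapse = "")
        cand <- paste0(u5, cds, u3)
        # the planted CDS must be the unique longest complete ORF
        orfs <- findOrfs(cand, minLen = 60)
        ok <- nrow(orfs) >= 1 && orfs$aa[1] == prot$protein[i] &&
          orfs$frame[1] == "+1" &&
          (nrow(orfs) == 1 || orfs$aaLength[2] < orfs$aaLength[1])
        if (ok) break
      }
      if (!ok) stop("could not embed CDS for ", prot$id[i])
      tpl[i] <- cand
      cdsStart[i] <- nchar(u5) + 1L
      cdsEnd[i] <- nchar(u5) + nchar(cds)
    }

    # abundance: truncated power law over ranks; engineered transcripts sit
    # at fixed ranks, background fills the rest in seeded random order
    a <- fitPowerLawExponent(n, config$topK, config$topShare)
    w <- seq_len(n)^(-a)
    special <- SPECIAL_RANKS[names(SPECIAL_RANKS) %in% prot$id]
    special <- special[special <= n]
    rankOf <- integer(n)
    names(rankOf) <- prot$id
    rankOf[names(special)] <- as.integer(special)
    restIds <- setdiff(prot$id, names(special))
    restRanks <- setdiff(seq_len(n), special)
    rankOf[restIds] <- sample(restRanks)
    fraction <- w[rankOf] / sum(w)

    truth <- DataFrame(
      id = prot$id, family = prot$family,
      fraction = unname(fraction), rank = unname(rankOf[prot$id]),
      expectedVerdict = prot$expectedVerdict)
    features <- DataFrame(
      id = prot$id, protein = prot$protein,
      signalLength = prot$signalLength,
      matureLength = ifelse(is.na(prot$signalLength), NA_integer_,
                            prot$matureLength),
      cysCountMature = prot$cysCountMature,
      cdsStart = cdsStart, cdsEnd = cdsEnd, cluster = prot$cluster)
    seqs <- DNAStringSet(setNames(tpl, prot$id))
    new("VenomTemplateSet", templates = seqs, truth = truth,
        features = features, config = unclass(config),
        seed = as.integer(seed))
  })
}

#' Library settings for read simulation
#'
#' Defaults mirror a 454-style venom-gland run: mean read length 315 nt for
#' the non-normalized library and 344 nt for the normalized one, and a
#' substitution error rate of 0.5%.
#'
#' @param mode `"non_normalized"` (reads sampled proportionally to template
#'   abundance weight) or `"normalized"` (weights flattened as `w^0.25`,
#'   emulating duplex-specific normalization).
#' @param nReads number of reads.
#' @param readLengthMean mean read length in nt (default by mode: 315 /
#'   344).
#' @param readLengthSd read length standard deviation (normal, truncated at
#'   50 nt and at the transcript length).
#' @param errorRate per-base substitution probability, in `[0, 0.05]`.
#' @param seed integer seed for the library draw.
#' @return a list of class `librarySpec`.
#' @export
librarySpec <- function(mode = c("non_normalized", "normalized"),
                        nReads = 10000L, readLengthMean = NULL,
                        readLengthSd = 60, errorRate = 0.005, seed = 1L) {
  mode <- match.arg(mode)
  if (is.null(readLengthMean))
    readLengthMean <- if (mode == "normalized") 344L else 315L
  if (errorRate < 0 || errorRate > 0.05)
    stop("errorRate must be in [0, 0.05]")
  if (nReads < 0) stop("nReads must be >= 0")
  structure(list(mode = mode, nReads = as.integer(nReads),
                 readLengthMean = readLengthMean,
                 readLengthSd = readLengthSd, errorRate = errorRate,
                 seed = as.integer(seed)),
            class = "librarySpec")
}

#' Simulate a sequencing library from transcript templates
#'
#' Samples reads from the templates proportionally to the truth abundance
#' weights (`non_normalized`) or to `weight^0.25` renormalized
#' (`normalized`), with uniform start positions, random strand, normally
#' distributed lengths truncated to `[50, transcript length]`, and i.i.d.
#' substitution errors. Per-read provenance (source template, start,
#' strand, error count) is recorded for oracle-style recovery tests.
#'
#' @param tset a [VenomTemplateSet-class].
#' @param spec a [librarySpec()].
#' @return a [ReadLibrary-class].
#' @export
#' @examples
#' tset <- generateTranscriptome(seed = 1)
#' lib <- simulateReads(tset, librarySpec(nReads = 200, seed = 7))
simulateReads <- function(tset, spec = librarySpec()) {
  stopifnot(is(tset, "VenomTemplateSet"), inherits(spec, "librarySpec"))
  n <- spec$nReads
  tchar <- as.character(tset@templates)
  tlen <- nchar(tchar)
  ids <- names(tchar)
  if (n == 0) {
    warning("nReads = 0: returning an empty library")
    return(new("ReadLibrary", reads = DNAStringSet(),
               provenance = DataFrame(id = character(),
                                      template = character(),
                                      start = integer(),
                                      strand = character(),
                                      nErrors = integer()),
               spec = unclass(spec)))
  }
  wt <- tset@truth$fraction
  if (spec$mode == "normalized") wt <- wt^0.25
  wt <- wt / sum(wt)
  withSeed(spec$seed, {
    tidx <- sample.int(length(tchar), n, replace = TRUE, prob = wt)
    rl <- round(rnorm(n, spec$readLengthMean, spec$readLengthSd))
    rl <- pmax(50L, pmin(as.integer(rl), tlen[tidx]))
    start <- floor(runif(n) * (tlen[tidx] - rl + 1)) + 1L
    seqs <- substring(tchar[tidx], start, start + rl - 1L)
    nErr <- rbinom(n, rl, spec$errorRate)
    for (i in which(nErr > 0)) {
      x <- strsplit(seqs[i], "")[[1]]
      pos <- sample.int(rl[i], nErr[i])
      for (p in pos) x[p] <- sample(setdiff(c("A", "C", "G", "T"), x[p]), 1)
      seqs[i] <- paste(x, collapse = "")
    }
    rev <- runif(n) < 0.5
    if (any(rev)) seqs[rev] <- revcompChar(seqs[rev])
    rids <- sprintf("read_%06d", seq_len(n))
    reads <- DNAStringSet(setNames(seqs, rids))
    prov <- DataFrame(id = rids, template = ids[tidx],
                      start = as.integer(start),
                      strand = ifelse(rev, "-", "+"),
                      nErrors = as.integer(nErr))
    new("ReadLibrary", reads = reads, provenance = prov,
        spec = unclass(spec))
  })
}

# ---------------------------------------------------------------------------
# Reference panel and keywords

#' Build the synthetic toxin reference panel
#'
#' Deterministically rebuilds the ToxProt-style reference panel that ships
#' with the package: one diverged synthetic ortholog per planted toxin
#' isoform plus decoy entries for venom-protein families not planted in
#' the transcriptome. The novel secreted family is deliberately absent.
#'
#' @return an [Biostrings::AAStringSet] named by panel id, with `family`,
#'   `keywords` and `description` metadata columns.
#' @seealso [toxinPanel()] for the packaged copy.
#' @export
buildToxinPanel <- function() {
  pan <- venomRepertoire()$panel
  x <- AAStringSet(setNames(pan$seq, pan$id))
  mcols(x) <- DataFrame(family = pan$family, keywords = pan$keywords,
                        description = pan$description)
  x
}

#' Load the packaged toxin reference panel
#'
#' Reads `inst/extdata/toxin_panel_synthetic.fasta`, a small synthetic
#' stand-in for a curated toxin database (one entry per planted toxin
#' isoform plus decoy families), with `family=`/`keywords=`/`description=`
#' tags parsed from the FASTA headers into metadata columns.
#'
#' @param path path to a panel FASTA; defaults to the packaged file.
#' @return an [Biostrings::AAStringSet] with metadata columns.
#' @export
toxinPanel <- function(path = system.file("extdata",
                                          "toxin_panel_synthetic.fasta",
                                          package = "venomscan")) {
  x <- readAAStringSet(path)
  hdr <- names(x)
  id <- sub("^(\\S+).*$", "\\1", hdr)
  getTag <- function(tag) {
    m <- regmatches(hdr, regexpr(paste0(tag, "=\\S+"), hdr))
    val <- rep(NA_character_, length(hdr))
    hit <- grepl(paste0(tag, "="), hdr)
    val[hit] <- sub(paste0("^", tag, "="), "", m)
    val
  }
  desc <- sub("^.*description=", "", hdr)
  names(x) <- id
  mcols(x) <- DataFrame(family = getTag("family"),
                        keywords = getTag("keywords"),
                        description = desc)
  x
}

#' Write a panel AAStringSet with metadata tags to FASTA
#'
#' @param panel an [Biostrings::AAStringSet] with `family`, `keywords`,
#'   `description` metadata columns.
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
writeToxinPanel <- function(panel, path) {
  md <- mcols(panel)
  hdr <- sprintf("%s family=%s keywords=%s description=%s",
                 names(panel), md$family,
                 gsub(" ", "_", md$keywords), md$description)
  lines <- as.vector(rbind(paste0(">", hdr), as.character(panel)))
  writeLines(lines, path)
  invisible(path)
}

#' Toxin-family keywords for hit-description matching
#'
#' The packaged keyword list used to pre-select toxin candidates from
#' best-hit descriptions, mirroring the classic list of snake-venom protein
#' families. Matching is case-insensitive substring matching.
#'
#' @return character vector of keywords.
#' @export
toxinKeywords <- function() {
  c("three-finger", "three finger", "3FTx", "kunitz", "TFPI", "AVIT",
    "waprin", "CRISP", "cysteine-rich secretory", "lectin", "PLA2",
    "phospholipase", "metalloprote", "SVMP", "disintegrin", "kallikrein",
    "serine protease", "lipocalin", "sarafotoxin", "endothelin",
    "crotamine", "cystatin", "natriuretic", "nerve growth factor", "VNGF",
    "cholinesterase", "choline esterase", "calglandulin", "defensin",
    "vespryn", "veficolin", "hyaluronidase", "amino acid oxidase")
}

# ---------------------------------------------------------------------------
# I/O helpers and evaluation utilities

#' Write templates (FASTA) and the truth table (TSV)
#'
#' @param tset a [VenomTemplateSet-class].
#' @param fastaPath output FASTA path.
#' @param truthPath optional output TSV path for the truth table.
#' @return `fastaPath`, invisibly.
#' @export
writeTemplates <- function(tset, fastaPath, truthPath = NULL) {
  writeXStringSet(tset@templates, fastaPath)
  if (!is.null(truthPath))
    write.table(as.data.frame(tset@truth), truthPath, sep = "\t",
                quote = FALSE, row.names = FALSE)
  invisible(fastaPath)
}

#' Write a read library to FASTQ (Sanger-scaled qualities)
#'
#' @param lib a [ReadLibrary-class].
#' @param fastqPath output FASTQ path.
#' @return `fastqPath`, invisibly.
#' @export
writeReadLibrary <- function(lib, fastqPath) {
  seqs <- as.character(lib@reads)
  quals <- strrep("I", nchar(seqs))
  lines <- as.vector(rbind(paste0("@", names(seqs)), seqs, "+", quals))
  writeLines(lines, fastqPath)
  invisible(fastqPath)
}

#' Assign contigs to their source templates via read provenance
#'
#' Evaluation helper for simulated data: each contig is attributed to the
#' template from which the majority of its member reads were drawn (ties:
#' alphabetically first template).
#'
#' @param contigs a [ContigSet-class].
#' @param lib the [ReadLibrary-class] the contigs were assembled from.
#' @return named character vector: contig id -> template id.
#' @export
matchContigsToTruth <- function(contigs, lib) {
  prov <- setNames(lib@provenance$template, lib@provenance$id)
  vapply(seq_along(contigs@members), function(i) {
    tab <- sort(table(prov[contigs@members[[i]]]), decreasing = TRUE)
    names(tab)[1]
  }, character(1)) |> setNames(names(contigs@consensus))
}
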