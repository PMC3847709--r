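# Central S4 containers. Tabular results (similarity hits, annotation
# records, abundance tables) are returned as S4Vectors DataFrame objects so
# they compose with the rest of the Bioconductor ecosystem.

#' VenomTemplateSet: synthetic venom-gland transcript templates with truth
#'
#' Container for the output of [generateTranscriptome()]: the transcript
#' template sequences (5' UTR + CDS + 3' UTR), a ground-truth table giving
#' each template's family, true abundance fraction and the verdict the
#' annotation pipeline is expected to reach, and per-template structural
#' features (signal peptide length, mature length, cysteine count, CDS
#' coordinates, translated protein).
#'
#' @slot templates [Biostrings::DNAStringSet] of transcript sequences, named
#'   by template id.
#' @slot truth `DataFrame` with columns `id`, `family`, `fraction`,
#'   `rank`, `expectedVerdict`. Fractions sum to 1.
#' @slot features `DataFrame` with columns `id`, `protein`, `signalLength`,
#'   `matureLength`, `cysCountMature`, `cdsStart`, `cdsEnd`.
#' @slot config `list` of generator settings.
#' @slot seed `integer` seed the set was generated with.
#'
#' @aliases VenomTemplateSet-class
#' @exportClass VenomTemplateSet
setClass("VenomTemplateSet",
  representation(
    templates = "DNAStringSet",
    truth     = "DataFrame",
    features  = "DataFrame",
    config    = "list",
    seed      = "integer"
  )
)

setValidity("VenomTemplateSet", function(object) {
  msg <- character()
  ids <- names(object@templates)
  if (is.null(ids) || anyDuplicated(ids))
    msg <- c(msg, "templates must be uniquely named")
  if (!identical(ids, object@truth$id))
    msg <- c(msg, "truth table rows must match template names")
  if (abs(sum(object@truth$fraction) - 1) > 1e-9)
    msg <- c(msg, "truth abundance fractions must sum to 1")
  if (length(msg)) msg else TRUE
})

#' ReadLibrary: a simulated sequencing library with provenance
#'
#' Output of [simulateReads()]: the reads, the library settings, and a
#' per-read provenance table (source template, start position, strand,
#' number of injected substitution errors) that downstream recovery tests
#' use as an oracle.
#'
#' @slot reads [Biostrings::DNAStringSet] named by read id.
#' @slot provenance `DataFrame` with columns `id`, `template`, `start`,
#'   `strand`, `nErrors`.
#' @slot spec `list` as returned by [librarySpec()].
#'
#' @aliases ReadLibrary-class
#' @exportClass ReadLibrary
setClass("ReadLibrary",
  representation(
    reads      = "DNAStringSet",
    provenance = "DataFrame",
    spec       = "list"
  )
)

setValidity("ReadLibrary", function(object) {
  msg <- character()
  if (length(object@reads) != nrow(object@provenance))
    msg <- c(msg, "provenance must have one row per read")
  if (length(object@reads) &&
      !identical(names(object@reads), object@provenance$id))
    msg <- c(msg, "provenance ids must match read names")
  if (length(msg)) msg else TRUE
})

#' ContigSet: contigs from the greedy overlap-consensus assembler
#'
#' Output of [assembleReads()]. Every input read is assigned to exactly one
#' contig or to the singleton set; `readCount(x)` equals the number of
#' member reads of each contig.
#'
#' @slot consensus [Biostrings::DNAStringSet] of contig consensus sequences,
#'   named by contig id.
#' @slot members `list` of character vectors of member read ids, parallel to
#'   `consensus`.
#' @slot singletons `character` of read ids that joined no contig.
#' @slot params `list` of assembly parameters (see [assemblyParams()]).
#' @slot droppedReads `character` of read ids dropped before assembly for
#'   being shorter than the minimum usable read length.
#'
#' @aliases ContigSet-class
#' @exportClass ContigSet
setClass("ContigSet",
  representation(
    consensus    = "DNAStringSet",
    members      = "list",
    singletons   = "character",
    params       = "list",
    droppedReads = "character"
  )
)

setValidity("ContigSet", function(object) {
  msg <- character()
  if (length(object@consensus) != length(object@members))
    msg <- c(msg, "one member list per contig required")
  n <- lengths(object@members)
  if (length(n) && any(n < 2))
    msg <- c(msg, "every contig must have at least 2 member reads")
  all_ids <- c(unlist(object@members, use.names = FALSE), object@singletons)
  if (anyDuplicated(all_ids))
    msg <- c(msg, "contig members and singletons must partition read ids")
  if (length(msg)) msg else TRUE
})

#' ScoringScheme: alignment scoring and E-value parameters
#'
#' Holds the substitution matrix name, affine gap penalties and the
#' Karlin-Altschul parameters used to convert raw local-alignment scores
#' into E-values via `E = K * m * n * exp(-lambda * S)`. Defaults are the
#' standard gapped BLOSUM62-11-1 constants (lambda = 0.267, K = 0.041).
#'
#' @slot matrixName substitution matrix name (only "BLOSUM62" is shipped).
#' @slot gapOpen,gapExtend non-negative affine gap penalties; a gap of
#'   length L costs `gapOpen + L * gapExtend`.
#' @slot lambda,K positive Karlin-Altschul parameters.
#' @slot dbSize total residue count of the search database; `NA` means
#'   pairwise mode (the subject length is used).
#'
#' @aliases ScoringScheme-class
#' @exportClass ScoringScheme
setClass("ScoringScheme",
  representation(
    matrixName = "character",
    gapOpen    = "numeric",
    gapExtend  = "numeric",
    lambda     = "numeric",
    K          = "numeric",
    dbSize     = "numeric"
  )
)

setValidity("ScoringScheme", function(object) {
  msg <- character()
  if (object@lambda <= 0 || object@K <= 0)
    msg <- c(msg, "lambda and K must be positive")
  if (object@gapOpen < 0 || object@gapExtend < 0)
    msg <- c(msg, "gap penalties must be non-negative")
  if (length(msg)) msg else TRUE
})

#' CodonAlignment: a gap-aware in-frame codon alignment
#'
#' Aligned coding sequences for the dN/dS screen. All sequences have equal
#' width, the width is a multiple of 3, and gaps come in runs whose length
#' is a multiple of 3 aligned to codon boundaries, so that removing gapped
#' codon columns never breaks the reading frame.
#'
#' @slot seqs [Biostrings::DNAStringSet] of aligned coding sequences
#'   (alphabet ACGT plus `-`), named by sequence id.
#'
#' @aliases CodonAlignment-class
#' @exportClass CodonAlignment
setClass("CodonAlignment", representation(seqs = "DNAStringSet"))

setValidity("CodonAlignment", function(object) {
  msg <- character()
  w <- unique(Biostrings::width(object@seqs))
  if (length(w) > 1) msg <- c(msg, "aligned sequences must have equal length")
  if (length(w) == 1 && w %% 3 != 0)
    msg <- c(msg, "alignment width must be a multiple of 3")
  if (is.null(names(object@seqs)) || anyDuplicated(names(object@seqs)))
    msg <- c(msg, "sequences must be uniquely named")
  if (length(w) == 1) {
    chs <- as.character(object@seqs)
    for (s in chs) {
      cod <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
      ng <- vapply(strsplit(cod, ""), function(x) sum(x == "-"), integer(1))
      if (any(ng %in% c(1L, 2L))) {
        msg <- c(msg, "gaps must fill whole codon columns (frame-preserving)")
        break
      }
    }
  }
  if (length(msg)) msg else TRUE
})
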