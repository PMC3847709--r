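# Greedy overlap-consensus mini-assembly and read-to-contig mapping.

#' Assembly parameters
#'
#' The merge thresholds follow the classic contig-building settings for
#' long cDNA reads: a minimal overlap of 40 bp at 98% identity. Overlap
#' candidates are located by exact k-mer seeding with diagonal voting and
#' verified by a banded free-end-gap alignment (band 10) before any merge
#' decision is taken.
#'
#' @param minOverlap minimum verified overlap length in alignment columns
#'   (default 40).
#' @param minIdentity minimum overlap identity fraction (default 0.98).
#' @param band half-width of the banded overlap alignment (default 10).
#' @param k seed k-mer length (default 16; must be below `minOverlap`).
#' @param kmerStride store every `kmerStride`-th read k-mer in the seed
#'   index (candidate discovery only; verification is always exhaustive
#'   over the voted diagonal).
#' @param minReadLength reads shorter than this are dropped before
#'   assembly with a logged count (default 50 nt).
#' @return a list of class `assemblyParams`.
#' @export
assemblyParams <- function(minOverlap = 40L, minIdentity = 0.98,
                           band = 10L, k = 16L, kmerStride = 4L,
                           minReadLength = 50L) {
  if (minOverlap < 1) stop("minOverlap must be >= 1")
  if (minIdentity <= 0 || minIdentity > 1)
    stop("minIdentity must be in (0, 1]")
  if (k >= minOverlap) stop("k must be smaller than minOverlap")
  structure(list(minOverlap = as.integer(minOverlap),
                 minIdentity = minIdentity, band = as.integer(band),
                 k = as.integer(k), kmerStride = as.integer(kmerStride),
                 minReadLength = as.integer(minReadLength)),
            class = "assemblyParams")
}

asReadSet <- function(reads) {
  if (is(reads, "ReadLibrary")) reads <- readSeqs(reads)
  if (is.character(reads)) {
    if (is.null(names(reads)))
      names(reads) <- sprintf("read_%06d", seq_along(reads))
    bad <- grepl("[^ACGTN]", toupper(reads))
    if (any(bad))
      stop("non-nucleotide characters in read(s): ",
           paste(head(names(reads)[bad], 5), collapse = ", "))
    reads <- DNAStringSet(toupper(reads))
  } else {
    reads <- DNAStringSet(reads)
    if (is.null(names(reads)))
      names(reads) <- sprintf("read_%06d", seq_along(reads))
  }
  reads
}

#' Greedy overlap-consensus assembly
#'
#' Seeds each contig with the longest unassigned read and iteratively
#' merges the unassigned read whose verified overlap with the growing
#' consensus is best (most matching columns; ties broken by longer
#' overlap, then lexicographic read id), provided the overlap reaches
#' `minOverlap` columns at `minIdentity`. Reads are reverse-complemented
#' when their best overlap is on the reverse strand. The consensus is a
#' per-column majority vote (ties: base from the earlier-joined read).
#' Reads that merge with nothing become singletons; every read is assigned
#' to exactly one contig or to the singleton set.
#'
#' @param reads a [ReadLibrary-class], [Biostrings::DNAStringSet] or named
#'   character vector (uppercase ACGTN).
#' @param params an [assemblyParams()].
#' @return a [ContigSet-class]. Contigs are named `contig_00001`, ... in
#'   creation order (longest seed first).
#' @export
#' @examples
#' r <- c(r1 = strrep("ACGTT", 40), r2 = substring(strrep("ACGTT", 60), 151))
#' assembleReads(r, assemblyParams(minOverlap = 30))
assembleReads <- function(reads, params = assemblyParams()) {
  stopifnot(inherits(params, "assemblyParams"))
  reads <- asReadSet(reads)
  if (length(reads) == 0) stop("reads must be non-empty")
  rchar <- as.character(reads)
  bad <- grepl("[^ACGTN]", rchar)
  if (any(bad))
    stop("non-nucleotide characters in read(s): ",
         paste(head(names(reads)[bad], 5), collapse = ", "))
  short <- nchar(rchar) < params$minReadLength
  dropped <- names(reads)[short]
  if (any(short)) {
    message(sum(short), " reads shorter than ", params$minReadLength,
            " nt dropped before assembly")
    rchar <- rchar[!short]
  }
  if (length(rchar) == 0)
    return(new("ContigSet", consensus = DNAStringSet(), members = list(),
               singletons = character(), params = unclass(params),
               droppedReads = dropped))
  res <- cpp_assemble(unname(rchar), names(rchar), params$minOverlap,
                      params$minIdentity, params$band, params$k,
                      params$kmerStride)
  cons <- DNAStringSet(res$consensus)
  names(cons) <- sprintf("contig_%05d", seq_along(cons))
  new("ContigSet", consensus = cons,
      members = as.list(res$members),
      singletons = as.character(res$singletons),
      params = unclass(params), droppedReads = dropped)
}

#' Map reads to contigs and count per-contig abundance
#'
#' Each read is assigned to the contig with the best verified alignment
#' passing the overlap thresholds (most matching columns, ties by longer
#' alignment then lexicographically smaller contig id; equal-best hits on
#' different contigs are flagged ambiguous), or left unmapped. Counts are
#' conserved: `sum(counts) + unmapped = number of reads`.
#'
#' @param reads a [ReadLibrary-class], [Biostrings::DNAStringSet] or named
#'   character vector.
#' @param contigs a [ContigSet-class] or any named
#'   [Biostrings::DNAStringSet] (e.g. reference transcripts).
#' @param params an [assemblyParams()]; `minOverlap`/`minIdentity` act as
#'   the mapping thresholds.
#' @return list with `assignments` (a [S4Vectors::DataFrame]: `id`,
#'   `contig` (NA if unmapped), `ambiguous`) and `counts` (named integer,
#'   one entry per contig including zeros).
#' @export
mapReadsToContigs <- function(reads, contigs, params = assemblyParams()) {
  reads <- asReadSet(reads)
  if (is(contigs, "ContigSet")) contigs <- consensusSeqs(contigs)
  contigs <- DNAStringSet(contigs)
  if (is.null(names(contigs)))
    names(contigs) <- sprintf("contig_%05d", seq_along(contigs))
  if (length(contigs) == 0) {
    warning("empty contig set: all reads unmapped")
    return(list(
      assignments = DataFrame(id = names(reads),
                              contig = rep(NA_character_, length(reads)),
                              ambiguous = rep(FALSE, length(reads))),
      counts = integer()))
  }
  res <- cpp_map_reads(as.character(reads), names(reads),
                       as.character(contigs), names(contigs),
                       params$minOverlap, params$minIdentity,
                       params$band, params$k)
  contig <- ifelse(is.na(res$contig), NA_character_,
                   names(contigs)[res$contig])
  counts <- setNames(integer(length(contigs)), names(contigs))
  tab <- table(contig[!is.na(contig)])
  counts[names(tab)] <- as.integer(tab)
  list(assignments = DataFrame(id = names(reads), contig = contig,
                               ambiguous = res$ambiguous),
       counts = counts)
}
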