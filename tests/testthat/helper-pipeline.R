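# Shared heavyweight fixtures, built once per test session. The study
# conditions are the generator defaults: seed 1, a non-normalized library
# of 1e5 reads.

.fixtures <- new.env(parent = emptyenv())

getTset <- function() {
  if (is.null(.fixtures$tset))
    .fixtures$tset <- generateTranscriptome(seed = 1)
  .fixtures$tset
}

getLib <- function() {
  if (is.null(.fixtures$lib))
    .fixtures$lib <- simulateReads(
      getTset(), librarySpec(mode = "non_normalized", nReads = 100000,
                             seed = 1))
  .fixtures$lib
}

# Full pipeline: assemble the 1e5-read library, annotate contigs using the
# assembler's member-read counts as abundance, and map contigs back to
# truth templates via read provenance.
getPipeline <- function() {
  if (is.null(.fixtures$pipeline)) {
    ctg <- assembleReads(getLib())
    ann <- annotateTranscriptome(ctg, readCount(ctg), toxinPanel())
    .fixtures$pipeline <- list(
      ctg = ctg, ann = ann,
      truthMap = matchContigsToTruth(ctg, getLib()))
  }
  .fixtures$pipeline
}

# Lightweight workflow run on the templates themselves (no assembly), with
# expected read counts derived from the truth fractions.
getTemplateAnnotation <- function() {
  if (is.null(.fixtures$tplAnn)) {
    tset <- getTset()
    counts <- stats::setNames(round(truthTable(tset)$fraction * 1e5),
                              truthTable(tset)$id)
    .fixtures$tplAnn <- annotateTranscriptome(templates(tset), counts,
                                              toxinPanel())
  }
  .fixtures$tplAnn
}

# Planted repertoire proteins of one family as a named AAStringSet.
familyProteins <- function(family) {
  ft <- templateFeatures(getTset())
  tr <- truthTable(getTset())
  idx <- tr$family == family
  Biostrings::AAStringSet(stats::setNames(ft$protein[idx], ft$id[idx]))
}
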