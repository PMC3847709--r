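# Accessor generics and show methods.

#' @rdname VenomTemplateSet-class
#' @param x,object a `VenomTemplateSet`, `ReadLibrary` or `ContigSet`.
#' @export
setGeneric("templates", function(x) standardGeneric("templates"))
#' @rdname VenomTemplateSet-class
#' @export
setGeneric("truthTable", function(x) standardGeneric("truthTable"))
#' @rdname VenomTemplateSet-class
#' @export
setGeneric("templateFeatures", function(x) standardGeneric("templateFeatures"))
#' @rdname ReadLibrary-class
#' @param x,object a `ReadLibrary`.
#' @export
setGeneric("readSeqs", function(x) standardGeneric("readSeqs"))
#' @rdname ReadLibrary-class
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))
#' @rdname ReadLibrary-class
#' @export
setGeneric("libraryMode", function(x) standardGeneric("libraryMode"))
#' @rdname ContigSet-class
#' @param x,object a `ContigSet`.
#' @export
setGeneric("consensusSeqs", function(x) standardGeneric("consensusSeqs"))
#' @rdname ContigSet-class
#' @export
setGeneric("contigMembers", function(x) standardGeneric("contigMembers"))
#' @rdname ContigSet-class
#' @export
setGeneric("singletonIds", function(x) standardGeneric("singletonIds"))
#' @rdname ContigSet-class
#' @export
setGeneric("readCount", function(x) standardGeneric("readCount"))
#' @rdname CodonAlignment-class
#' @param x,object a `CodonAlignment`.
#' @export
setGeneric("alignedSeqs", function(x) standardGeneric("alignedSeqs"))

#' @rdname VenomTemplateSet-class
#' @export
setMethod("templates", "VenomTemplateSet", function(x) x@templates)
#' @rdname VenomTemplateSet-class
#' @export
setMethod("truthTable", "VenomTemplateSet", function(x) x@truth)
#' @rdname VenomTemplateSet-class
#' @export
setMethod("templateFeatures", "VenomTemplateSet", function(x) x@features)

#' @rdname ReadLibrary-class
#' @export
setMethod("readSeqs", "ReadLibrary", function(x) x@reads)
#' @rdname ReadLibrary-class
#' @export
setMethod("provenance", "ReadLibrary", function(x) x@provenance)
#' @rdname ReadLibrary-class
#' @export
setMethod("libraryMode", "ReadLibrary", function(x) x@spec$mode)

#' @rdname ContigSet-class
#' @export
setMethod("consensusSeqs", "ContigSet", function(x) x@consensus)
#' @rdname ContigSet-class
#' @export
setMethod("contigMembers", "ContigSet", function(x) x@members)
#' @rdname ContigSet-class
#' @export
setMethod("singletonIds", "ContigSet", function(x) x@singletons)
#' @rdname ContigSet-class
#' @export
setMethod("readCount", "ContigSet", function(x)
  setNames(lengths(x@members), names(x@consensus)))
#' @rdname CodonAlignment-class
#' @export
setMethod("alignedSeqs", "CodonAlignment", function(x) x@seqs)

#' @export
setMethod("show", "VenomTemplateSet", function(object) {
  fam <- table(object@truth$family)
  cat("VenomTemplateSet with", length(object@templates), "templates",
      "(seed", object@seed, ")\n")
  cat("  families:",
      paste(sprintf("%s=%d", names(fam), as.integer(fam)), collapse = ", "),
      "\n")
  cat("  top-57 truth abundance share:",
      sprintf("%.3f", sum(sort(object@truth$fraction,
                               decreasing = TRUE)[seq_len(min(57,
                                 nrow(object@truth)))])), "\n")
})

setMethod("show", "ReadLibrary", function(object) {
  cat("ReadLibrary:", length(object@reads), "reads,",
      object@spec$mode, "mode\n")
  if (length(object@reads))
    cat("  mean read length:",
        round(mean(Biostrings::width(object@reads)), 1), "nt\n")
})

setMethod("show", "ContigSet", function(object) {
  cat("ContigSet:", length(object@consensus), "contigs,",
      length(object@singletons), "singletons\n")
  if (length(object@consensus)) {
    cat("  consensus lengths:",
        paste(range(Biostrings::width(object@consensus)), collapse = "-"),
        "nt; total member reads:",
        sum(lengths(object@members)), "\n")
  }
})

setMethod("show", "ScoringScheme", function(object) {
  cat(sprintf(
    "ScoringScheme: %s, gap %g/%g, lambda=%g K=%g, dbSize=%s\n",
    object@matrixName, object@gapOpen, object@gapExtend,
    object@lambda, object@K,
    ifelse(is.na(object@dbSize), "pairwise", format(object@dbSize))))
})

setMethod("show", "CodonAlignment", function(object) {
  cat("CodonAlignment:", length(object@seqs), "sequences x",
      unique(Biostrings::width(object@seqs)) / 3, "codons\n")
})
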