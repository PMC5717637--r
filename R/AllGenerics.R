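#' Accessors for haplodrift classes
#'
#' Accessor generics: \code{sampleIDs} returns sample identifiers,
#' \code{lociNames} the locus names, \code{genotypeCalls} the canonical
#' call matrix, \code{haplotypeFreq} haplotype sample counts,
#' \code{networkEdges}/\code{networkNodes} the network tables, and
#' \code{gridValues} the interpolated surface matrix.
#'
#' @param x an object of the matching haplodrift class.
#' @return The stored component (vector, matrix or data.frame).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("sampleIDs", function(x) standardGeneric("sampleIDs"))
#' @rdname accessors
#' @export
setGeneric("lociNames", function(x) standardGeneric("lociNames"))
#' @rdname accessors
#' @export
setGeneric("genotypeCalls", function(x) standardGeneric("genotypeCalls"))
#' @rdname accessors
#' @export
setGeneric("haplotypeFreq", function(x) standardGeneric("haplotypeFreq"))
#' @rdname accessors
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))
#' @rdname accessors
#' @export
setGeneric("networkNodes", function(x) standardGeneric("networkNodes"))
#' @rdname accessors
#' @export
setGeneric("gridValues", function(x) standardGeneric("gridValues"))

#' @rdname accessors
#' @export
setMethod("sampleIDs", "GenotypeTable", function(x) x@samples)
#' @rdname accessors
#' @export
setMethod("lociNames", "GenotypeTable", function(x) x@loci)
#' @rdname accessors
#' @export
setMethod("genotypeCalls", "GenotypeTable", function(x) {
  m <- x@calls
  dimnames(m) <- list(x@samples, x@loci)
  m
})
#' @rdname accessors
#' @export
setMethod("haplotypeFreq", "HaplotypeSet", function(x) {
  setNames(x@freq, names(x@haplotypes))
})
#' @rdname accessors
#' @export
setMethod("networkEdges", "HaploNetwork", function(x) x@edges)
#' @rdname accessors
#' @export
setMethod("networkNodes", "HaploNetwork", function(x) x@nodes)
#' @rdname accessors
#' @export
setMethod("gridValues", "LandscapeGrid", function(x) x@values)

setMethod("show", "GenotypeTable", function(object) {
  cat("GenotypeTable:", length(object@samples), "samples x",
      length(object@loci), "loci\n")
  nmiss <- sum(is.na(object@calls))
  cat("  loci:", paste(head(object@loci, 8), collapse = ", "),
      if (length(object@loci) > 8) "..." else "", "\n")
  cat("  missing calls:", nmiss, "\n")
})

setMethod("show", "HaplotypeSet", function(object) {
  cat("HaplotypeSet:", length(object@haplotypes), "haplotypes from",
      sum(object@freq), "samples\n")
  cat("  frequencies:", paste(object@freq, collapse = ", "), "\n")
})

setMethod("show", "HaploNetwork", function(object) {
  cat("HaploNetwork:", nrow(object@nodes), "haplotypes,",
      nrow(object@edges), "edges (union of all minimum spanning trees)\n")
})

setMethod("show", "LandscapeGrid", function(object) {
  cat("LandscapeGrid:", length(object@x), "x", length(object@y),
      "nodes, a =", object@a, "\n")
  cat("  value range:", format(range(object@values), digits = 4), "\n")
})

setMethod("show", "RunConfig", function(object) {
  cat("RunConfig: seed", object@seed, "| grid",
      paste(object@gridSize, collapse = "x"), "| a =", object@weightA, "\n")
  cat("  chain:", paste(object@chain, collapse = "/"),
      "| LD permutations:", object@ldPermutations, "\n")
  cat("  components tried:", paste(range(object@kRange), collapse = "-"),
      "| stages:", paste(object@stages, collapse = ", "), "\n")
})

setMethod("show", "EvidenceSummary", function(object) {
  cat("EvidenceSummary -> verdict:", object@verdict, "\n")
  fl <- object@flags
  cat("  Ka/Ks:", format(object@kaksRatio, digits = 3), "|",
      paste(names(fl), ifelse(is.na(fl), "?", ifelse(fl, "yes", "no")),
            sep = "=", collapse = " "), "\n")
  for (r in object@rationale) cat("  -", r, "\n")
})
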