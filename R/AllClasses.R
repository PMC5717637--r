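#' @import methods
#' @importFrom stats lm coef resid prcomp dist hclust cutree rbinom rpois
#'   rnorm runif rexp rbeta rgamma setNames p.adjust ks.test sd var
#'   quantile as.dist pchisq
#' @importFrom utils head read.table write.table combn
NULL

#' Class "GenotypeTable": co-dominant diploid genotypes, sample x locus
#'
#' Stores unordered diploid allele pairs for a set of samples at a set of
#' nuclear loci.  Calls are kept as canonicalised strings \code{"a/b"} with
#' the two allele labels sorted, so \code{"124/120"} and \code{"120/124"}
#' are the same genotype.  Missing calls are \code{NA}; missing individuals
#' are excluded per locus (never listwise) by the analysis functions.
#'
#' @slot samples character vector of unique sample identifiers (row order).
#' @slot loci character vector of unique locus names (column order).
#' @slot calls character matrix (samples x loci) of canonical "a/b" strings,
#'   \code{NA} for missing.
#' @exportClass GenotypeTable
setClass("GenotypeTable",
  representation(samples = "character", loci = "character",
                 calls = "matrix"))

setValidity("GenotypeTable", function(object) {
  msg <- character()
  if (anyDuplicated(object@samples)) msg <- c(msg, "duplicate sample ids")
  if (anyDuplicated(object@loci)) msg <- c(msg, "duplicate locus names")
  if (!identical(dim(object@calls),
                 c(length(object@samples), length(object@loci))))
    msg <- c(msg, "calls matrix dimensions do not match samples x loci")
  ok <- is.na(object@calls) | grepl("^[^/]+/[^/]+$", object@calls)
  if (!all(ok)) msg <- c(msg, "calls must be 'a/b' strings or NA")
  if (length(msg)) msg else TRUE
})

#' Class "HaplotypeSet": collapsed unique haplotypes with frequencies
#'
#' @slot haplotypes \code{DNAStringSet} of distinct sequences, named h1, h2, ...
#' @slot freq integer count of samples carrying each haplotype.
#' @slot members list of character vectors: sample ids per haplotype.
#' @exportClass HaplotypeSet
setClass("HaplotypeSet",
  representation(haplotypes = "ANY", freq = "integer", members = "list"))

setValidity("HaplotypeSet", function(object) {
  msg <- character()
  nh <- length(object@haplotypes)
  if (length(object@freq) != nh || length(object@members) != nh)
    msg <- c(msg, "freq/members length must equal number of haplotypes")
  if (anyDuplicated(as.character(object@haplotypes)))
    msg <- c(msg, "haplotypes must be pairwise distinct")
  if (any(object@freq != lengths(object@members)))
    msg <- c(msg, "freq must equal number of member samples")
  if (length(msg)) msg else TRUE
})

#' Class "HaploNetwork": minimum spanning network over haplotypes
#'
#' Nodes are haplotypes with sample frequencies; edges carry integer
#' substitution step counts.  The edge set is the union of all minimum
#' spanning trees (epsilon = 0), so tied alternative connections are kept.
#'
#' @slot nodes data.frame with columns \code{haplotype}, \code{freq}.
#' @slot edges data.frame with columns \code{from}, \code{to}, \code{steps}.
#' @exportClass HaploNetwork
setClass("HaploNetwork",
  representation(nodes = "data.frame", edges = "data.frame"))

setValidity("HaploNetwork", function(object) {
  msg <- character()
  if (!all(c("haplotype", "freq") %in% names(object@nodes)))
    msg <- c(msg, "nodes needs haplotype and freq columns")
  if (nrow(object@edges) &&
      !all(c("from", "to", "steps") %in% names(object@edges)))
    msg <- c(msg, "edges needs from, to and steps columns")
  if (nrow(object@edges) && !all(object@edges$steps >= 1))
    msg <- c(msg, "edge steps must be positive integers")
  if (length(msg)) msg else TRUE
})

#' Class "LandscapeGrid": interpolated genetic landscape surface
#'
#' A uniform nx x ny grid over the sampled bounding box (expanded 2.5% per
#' side) whose node values are inverse-distance-weighted genetic distances
#' assigned to connectivity-edge midpoints.
#'
#' @slot x,y numeric vectors of grid node coordinates (length nx, ny).
#' @slot values numeric matrix (nx x ny) of interpolated values.
#' @slot a numeric distance weighting exponent used.
#' @slot midpoints data.frame with columns \code{x}, \code{y}, \code{z}.
#' @exportClass LandscapeGrid
setClass("LandscapeGrid",
  representation(x = "numeric", y = "numeric", values = "matrix",
                 a = "numeric", midpoints = "data.frame"))

setValidity("LandscapeGrid", function(object) {
  msg <- character()
  if (length(object@x) < 2 || length(object@y) < 2)
    msg <- c(msg, "grid must be at least 2 x 2")
  if (!identical(dim(object@values),
                 c(length(object@x), length(object@y))))
    msg <- c(msg, "values matrix must be nx x ny")
  if (!all(is.finite(object@values)))
    msg <- c(msg, "all node values must be finite")
  if (length(object@a) != 1 || object@a <= 0)
    msg <- c(msg, "weighting exponent a must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' Class "RunConfig": validated pipeline configuration
#'
#' @slot seed integer random seed, echoed in every report.
#' @slot gridSize integer length-2 (nx, ny), both >= 2.
#' @slot weightA numeric IDW exponent a > 0.
#' @slot chain numeric length-3: dememorization, batches, iterations/batch.
#' @slot ldPermutations integer number of permutations for the LD G test.
#' @slot kRange integer range of mixture components tried (e.g. 1:9).
#' @slot mutationRates named numeric per-site per-generation rates u.
#' @slot stages character subset of the known stage names to run.
#' @exportClass RunConfig
setClass("RunConfig",
  representation(seed = "integer", gridSize = "integer", weightA = "numeric",
                 chain = "numeric", ldPermutations = "integer",
                 kRange = "integer", mutationRates = "numeric",
                 stages = "character"))

.KNOWN_STAGES <- c("mtdna", "kaks", "landscape", "nuclear", "concordance",
                   "verdict")

setValidity("RunConfig", function(object) {
  msg <- character()
  if (length(object@seed) != 1 || is.na(object@seed))
    msg <- c(msg, "seed must be a single integer")
  if (length(object@gridSize) != 2 || any(object@gridSize < 2))
    msg <- c(msg, "gridSize must be two integers >= 2")
  if (length(object@weightA) != 1 || object@weightA <= 0)
    msg <- c(msg, "weightA must be a single positive number")
  if (length(object@chain) != 3 || any(object@chain < 1))
    msg <- c(msg, "chain must be (dememorization, batches, iterations)")
  if (object@ldPermutations < 10)
    msg <- c(msg, "ldPermutations must be >= 10")
  if (length(object@kRange) < 1 || any(object@kRange < 1))
    msg <- c(msg, "kRange must be positive integers")
  if (any(object@mutationRates <= 0))
    msg <- c(msg, "mutation rates must be positive")
  bad <- setdiff(object@stages, .KNOWN_STAGES)
  if (length(bad))
    msg <- c(msg, paste("unknown stages:", paste(bad, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Class "EvidenceSummary": per-hypothesis flags and the verdict
#'
#' Collects the boolean evidence flags produced by the pipeline stages
#' together with the Ka/Ks ratio, and the verdict derived from them.
#' Each flag records its provenance (which stage output it came from).
#'
#' @slot flags named logical vector: spatial_partition, hwe_ok, ld_free,
#'   fst_zero, kappa_concordant, traits_bimodal (NA = stage not run).
#' @slot kaksRatio numeric Ka/Ks ratio (NA if the stage was not run).
#' @slot verdict character, one of large_population, balancing_selection,
#'   cryptic_species, introgression, inconclusive.
#' @slot rationale character lines explaining the decision.
#' @slot provenance named character: stage of origin per flag.
#' @exportClass EvidenceSummary
setClass("EvidenceSummary",
  representation(flags = "logical", kaksRatio = "numeric",
                 verdict = "character", rationale = "character",
                 provenance = "character"))

.EVIDENCE_FLAGS <- c("spatial_partition", "hwe_ok", "ld_free", "fst_zero",
                     "kappa_concordant", "traits_bimodal")
.VERDICTS <- c("large_population", "balancing_selection", "cryptic_species",
               "introgression", "inconclusive")

setValidity("EvidenceSummary", function(object) {
  msg <- character()
  if (!all(.EVIDENCE_FLAGS %in% names(object@flags)))
    msg <- c(msg, paste("flags must be named:",
                        paste(.EVIDENCE_FLAGS, collapse = ", ")))
  if (length(object@verdict) != 1 || !(object@verdict %in% .VERDICTS))
    msg <- c(msg, "verdict must be one of the five defined outcomes")
  if (length(msg)) msg else TRUE
})
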