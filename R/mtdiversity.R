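#' Pairwise uncorrected p-distances
#'
#' Computes, for every unordered pair of sequences, the proportion of
#' differing sites among comparable sites (uncorrected p-distance, no
#' multiple-hit correction) together with the integer difference count and
#' the number of sites compared.  Sites holding N or a gap in either
#' sequence of a pair are excluded under \code{"pairwise_deletion"};
#' \code{"complete_deletion"} drops such sites across the whole alignment
#' first.
#'
#' @param aln \code{DNAStringSet} alignment (>= 2 sequences).
#' @param gapPolicy "pairwise_deletion" (default) or "complete_deletion".
#' @return list with matrices \code{d} (proportion), \code{k} (count) and
#'   \code{sites} (comparable sites), all symmetric with zero diagonal and
#'   dimnames = sequence ids.
#' @examples
#' aln <- validateAlignment(c(s1 = "AAAA", s2 = "AATT"))
#' pairwisePDistance(aln)$d["s1", "s2"]   # 0.5
#' @export
pairwisePDistance <- function(aln,
                              gapPolicy = c("pairwise_deletion",
                                            "complete_deletion")) {
  gapPolicy <- match.arg(gapPolicy)
  aln <- validateAlignment(aln)
  n <- length(aln)
  if (n < 2L) stop("need at least 2 sequences for distances")
  m <- .alnMatrix(aln)
  good <- m == "A" | m == "C" | m == "G" | m == "T"
  if (gapPolicy == "complete_deletion") {
    keep <- colSums(good) == n
    m <- m[, keep, drop = FALSE]
    good <- good[, keep, drop = FALSE]
  }
  ids <- names(aln)
  d <- k <- s <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    comp <- good[i, ] & good[j, ]
    nc <- sum(comp)
    if (nc == 0L)
      stop("undefined-distance error: no comparable sites for pair ",
           ids[i], " / ", ids[j])
    kk <- sum(m[i, comp] != m[j, comp])
    k[i, j] <- k[j, i] <- kk
    s[i, j] <- s[j, i] <- nc
    d[i, j] <- d[j, i] <- kk / nc
  }
  list(d = d, k = k, sites = s)
}

.alnMatrix <- function(aln) {
  do.call(rbind, strsplit(as.character(aln), "", fixed = TRUE))
}

#' Collapse identical sequences into haplotypes
#'
#' Exact-match collapsing over the full sequence; N is treated as a
#' distinct character (two sequences differing only by an N are distinct
#' haplotypes).  Haplotypes are named h1, h2, ... in order of first
#' appearance.
#'
#' @param aln \code{DNAStringSet}.
#' @return A \code{\link{HaplotypeSet}}.
#' @export
collapseHaplotypes <- function(aln) {
  aln <- validateAlignment(aln)
  seqs <- as.character(aln)
  first <- !duplicated(seqs)
  uniq <- seqs[first]
  idx <- match(seqs, uniq)
  members <- split(names(aln), idx)
  hs <- Biostrings::DNAStringSet(uniq)
  names(hs) <- paste0("h", seq_along(uniq))
  names(members) <- names(hs)
  new("HaplotypeSet", haplotypes = hs,
      freq = as.integer(lengths(members)), members = as.list(members))
}

#' Nucleotide diversity (pi)
#'
#' Tajima's estimator: the mean over all unordered sequence pairs of the
#' per-site p-distance (pairwise deletion).
#'
#' @param aln \code{DNAStringSet} with >= 2 sequences.
#' @return numeric pi (unitless, per site).
#' @export
nucleotideDiversity <- function(aln) {
  pd <- pairwisePDistance(aln)
  mean(pd$d[upper.tri(pd$d)])
}

#' Equilibrium population size from diversity
#'
#' Under drift-mutation equilibrium N = pi / (4 u), with u the per-site
#' per-generation mutation rate.  Returned both raw and truncated to an
#' integer (the conventional way such estimates are printed).
#'
#' @param pi nucleotide diversity (>= 0).
#' @param u mutation rate (> 0), possibly a named vector of several rates.
#' @return data.frame with columns \code{u}, \code{pi}, \code{N} (raw) and
#'   \code{N_int} (integer part).
#' @examples
#' populationSize(0.1035, c(drosophila = 6.2e-8, daphnia = 1.5e-7))
#' @export
populationSize <- function(pi, u) {
  if (length(pi) != 1 || pi < 0) stop("pi must be a single value >= 0")
  if (any(u <= 0)) stop("domain error: mutation rate u must be > 0")
  N <- pi / (4 * u)
  data.frame(rate = if (is.null(names(u))) as.character(u) else names(u),
             u = unname(u), pi = pi, N = unname(N),
             N_int = unname(trunc(N)))
}

#' Mismatch distribution
#'
#' Histogram of the integer pairwise difference counts k over all
#' unordered pairs of sequences.
#'
#' @param pd result of \code{\link{pairwisePDistance}} (or a list with an
#'   integer matrix \code{k}).
#' @return list with \code{counts} (named integer vector over observed k),
#'   \code{k} (the per-pair values) and \code{n_pairs}.
#' @export
mismatchDistribution <- function(pd) {
  kv <- pd$k[upper.tri(pd$k)]
  tb <- table(factor(kv, levels = 0:max(kv)))
  list(counts = setNames(as.integer(tb), names(tb)),
       k = as.integer(kv), n_pairs = length(kv))
}

#' Bimodality assessment of a mismatch (or trait) distribution
#'
#' Fits one- and two-component univariate Gaussian mixtures to the values
#' and compares them by BIC (2 log L - m log n; larger is better).  The
#' distribution is called bimodal when the two-component model wins
#' (delta BIC > 0) \emph{and} the fitted two-component density actually
#' has two local maxima — a two-component fit with heavily overlapping
#' components (common with tied, half-unit-rounded counts) describes a
#' unimodal density and is not evidence of two modes.  A degenerate
#' input (all values equal) is unimodal by convention.
#'
#' @param x numeric values: pairwise difference counts from
#'   \code{\link{mismatchDistribution}} (component \code{k}) or a trait
#'   vector.
#' @return list with \code{call} ("unimodal"/"bimodal"), \code{deltaBIC}
#'   (BIC2 - BIC1) and the two BIC values.
#' @export
bimodalityTest <- function(x) {
  if (is.list(x)) x <- x$k
  x <- as.numeric(x)
  if (length(x) < 10L) stop("need at least 10 values")
  if (length(unique(x)) == 1L)
    return(list(call = "unimodal", deltaBIC = -Inf, BIC1 = NA, BIC2 = NA))
  fit <- mclust::mclustBIC(x, G = 1:2, modelNames = c("E", "V"),
                           verbose = FALSE)
  b1 <- suppressWarnings(max(fit["1", ], na.rm = TRUE))
  b2 <- suppressWarnings(max(fit["2", ], na.rm = TRUE))
  if (!is.finite(b2))
    return(list(call = "unimodal", deltaBIC = -Inf, BIC1 = b1, BIC2 = b2))
  delta <- b2 - b1
  twoModes <- FALSE
  if (delta > 0) {
    m2 <- mclust::Mclust(x, G = 2, modelNames = colnames(fit)[
      which.max(fit["2", ])], verbose = FALSE)
    if (!is.null(m2)) {
      p <- m2$parameters
      sig <- sqrt(if (length(p$variance$sigmasq) == 1)
        rep(p$variance$sigmasq, 2) else p$variance$sigmasq)
      sig <- pmax(sig, 1e-8)
      grid <- seq(min(x), max(x), length.out = 512)
      dens <- p$pro[1] * stats::dnorm(grid, p$mean[1], sig[1]) +
              p$pro[2] * stats::dnorm(grid, p$mean[2], sig[2])
      dd <- diff(dens)
      twoModes <- sum(diff(sign(dd)) < 0) >= 2
    }
  }
  list(call = if (delta > 0 && twoModes) "bimodal" else "unimodal",
       deltaBIC = delta, BIC1 = b1, BIC2 = b2)
}

#' Minimum spanning network over haplotypes
#'
#' Builds the epsilon = 0 minimum spanning network: the union of all
#' minimum spanning trees over the haplotypes under integer substitution
#' step distances.  Edge-weight classes are processed in ascending order;
#' within a class an edge is included iff its endpoints lay in different
#' components as they stood before the class began, so tied alternative
#' connections are all retained (never broken arbitrarily).
#'
#' @param hs \code{\link{HaplotypeSet}}.
#' @param k optional integer distance matrix over the haplotypes (defaults
#'   to Hamming distances of the haplotype sequences, pairwise deletion).
#' @return A \code{\link{HaploNetwork}}.
#' @export
minimumSpanningNetwork <- function(hs, k = NULL) {
  nh <- length(hs@haplotypes)
  ids <- names(hs@haplotypes)
  nodes <- data.frame(haplotype = ids, freq = hs@freq)
  if (nh <= 1L)
    return(new("HaploNetwork", nodes = nodes,
               edges = data.frame(from = character(), to = character(),
                                  steps = integer())))
  if (is.null(k)) k <- pairwisePDistance(hs@haplotypes)$k
  edges <- .msnEdges(k)
  edges$from <- ids[edges$from]
  edges$to <- ids[edges$to]
  new("HaploNetwork", nodes = nodes, edges = edges)
}

# Union of all MSTs: ascending weight classes over a components snapshot.
.msnEdges <- function(k) {
  nh <- nrow(k)
  comp <- seq_len(nh)                    # union-find parent-free labels
  pairs <- which(upper.tri(k), arr.ind = TRUE)
  w <- k[pairs]
  out <- list()
  for (cls in sort(unique(w))) {
    snap <- comp                         # components before this class
    sel <- which(w == cls)
    keep <- sel[snap[pairs[sel, 1]] != snap[pairs[sel, 2]]]
    if (length(keep)) {
      out[[length(out) + 1L]] <-
        data.frame(from = pairs[keep, 1], to = pairs[keep, 2],
                   steps = as.integer(cls))
      for (e in keep) {                  # merge after the whole class
        ci <- comp[pairs[e, 1]]; cj <- comp[pairs[e, 2]]
        if (ci != cj) comp[comp == cj] <- ci
      }
    }
    if (length(unique(comp)) == 1L) break
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(from = integer(), to = integer(), steps = integer())
}

#' Assign haplogroups by distance clustering
#'
#' Partitions the samples into k haplogroups by average-linkage
#' hierarchical clustering of the pairwise p-distance matrix — the
#' conventional way deep mtDNA clusters ("haplogroups") are labelled when
#' two divergent clades co-occur in one sample.
#'
#' @param pd result of \code{\link{pairwisePDistance}}.
#' @param k number of groups (default 2).
#' @return named integer vector of group labels (1..k), ordered so group 1
#'   is the largest.
#' @export
assignHaplogroups <- function(pd, k = 2) {
  hc <- hclust(stats::as.dist(pd$d), method = "average")
  g <- cutree(hc, k = k)
  ord <- order(-tabulate(g, k))
  setNames(match(g, ord), names(g))
}
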