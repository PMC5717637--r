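#' Genotypic linkage-disequilibrium test for a locus pair
#'
#' Builds the genotype x genotype contingency table for individuals
#' genotyped at both loci and evaluates the log-likelihood-ratio G
#' statistic by Monte Carlo permutation: one locus's genotypes are
#' shuffled across individuals and the tail probability of G is reported
#' (with the add-one correction (1 + #{G* >= G}) / (nperm + 1)).  Under a
#' pooled sample of two non-interbreeding species, unlinked loci show
#' strong association; under a single randomly mating population the
#' p-values are uniform.
#'
#' @param gt \code{GenotypeTable}.
#' @param locusA,locusB locus names.
#' @param nperm number of permutations.
#' @return list with \code{p}, \code{G}, \code{df}, \code{flag}.
#' @export
ldTest <- function(gt, locusA, locusB, nperm = 10000) {
  calls <- genotypeCalls(gt)
  a <- calls[, locusA]; b <- calls[, locusB]
  keep <- !is.na(a) & !is.na(b)
  a <- factor(a[keep]); b <- factor(b[keep])
  if (nlevels(a) < 2 || nlevels(b) < 2)
    return(list(p = 1, G = 0, df = 0, flag = "monomorphic: test undefined"))
  gstat <- function(ai, bi, ka, kb) {
    tab <- tabulate(ai + ka * (bi - 1L), ka * kb)
    E <- outer(tabulate(ai, ka), tabulate(bi, kb)) / length(ai)
    o <- tab[tab > 0]
    2 * sum(o * log(o / E[tab > 0]))
  }
  ai <- as.integer(a); bi <- as.integer(b)
  ka <- nlevels(a); kb <- nlevels(b)
  G <- gstat(ai, bi, ka, kb)
  ge <- 0L
  for (p in seq_len(nperm)) {
    Gp <- gstat(ai, bi[sample.int(length(bi))], ka, kb)
    if (Gp >= G - 1e-12) ge <- ge + 1L
  }
  list(p = (1 + ge) / (nperm + 1), G = G,
       df = (ka - 1L) * (kb - 1L), flag = "ok")
}

#' Pairwise LD tests over all locus pairs
#'
#' @param gt \code{GenotypeTable}.
#' @param nperm permutations per pair.
#' @return data.frame with columns locusA, locusB, G, p, flag.
#' @export
ldTable <- function(gt, nperm = 10000) {
  prs <- combn(gt@loci, 2)
  rows <- apply(prs, 2, function(pr) {
    r <- ldTest(gt, pr[1], pr[2], nperm = nperm)
    data.frame(locusA = pr[1], locusB = pr[2], G = r$G, p = r$p,
               flag = r$flag)
  })
  do.call(rbind, rows)
}

#' Bonferroni correction
#'
#' @param pvals numeric p-values.
#' @param alpha family-wise error rate (default 0.05).
#' @param m number of tests (defaults to \code{length(pvals)}).
#' @return list with \code{threshold} = alpha/m, \code{significant}
#'   logical vector, \code{m} and \code{alpha}.
#' @examples
#' bonferroni(rep(0.004, 10))$threshold  # 0.005
#' @export
bonferroni <- function(pvals, alpha = 0.05, m = length(pvals)) {
  if (m < 1) stop("need at least one test")
  thr <- alpha / m
  list(threshold = thr, significant = pvals < thr, m = m, alpha = alpha)
}

#' Weir-Cockerham F_ST (theta)
#'
#' Estimates the Weir & Cockerham (1984) variance components a (among
#' demes), b (among individuals within demes) and c (within individuals)
#' per allele, summed within loci, and the multilocus estimate
#' theta = sum(a) / sum(a + b + c).  Missing genotypes are excluded per
#' locus.  The estimator is unbiased but not constrained to be positive:
#' identical demes typically yield small negative values, and demes fixed
#' for different alleles yield exactly 1.
#'
#' @param gt \code{GenotypeTable}.
#' @param partition named character/integer vector mapping each sample id
#'   to a deme label (e.g. its mtDNA haplogroup).
#' @return list with \code{theta} (multilocus), \code{perLocus}
#'   data.frame (locus, a, b, c, theta) and \code{demes}.
#' @export
weirCockerhamFst <- function(gt, partition) {
  calls <- genotypeCalls(gt)
  part <- partition[gt@samples]
  if (anyNA(part))
    stop("partition must label every sample: missing ",
         paste(gt@samples[is.na(part)], collapse = ", "))
  demes <- sort(unique(as.character(part)))
  r0 <- length(demes)
  if (r0 < 2) stop("need at least 2 demes")
  anyData <- vapply(demes, function(dm)
    any(!is.na(calls[part == dm, , drop = FALSE])), TRUE)
  if (!all(anyData))
    stop("deme with zero genotype data: ",
         paste(demes[!anyData], collapse = ", "))
  per <- lapply(gt@loci, function(l) {
    cell <- calls[, l]
    keep <- !is.na(cell)
    if (sum(keep) == 0) return(NULL)
    dm <- as.character(part[keep])
    parts <- strsplit(cell[keep], "/", fixed = TRUE)
    a1 <- vapply(parts, `[`, "", 1L); a2 <- vapply(parts, `[`, "", 2L)
    use <- intersect(demes, unique(dm))
    if (length(use) < 2) return(NULL)
    r <- length(use)
    ni <- vapply(use, function(d) sum(dm == d), 0)
    nbar <- mean(ni)
    nc <- (r * nbar - sum(ni^2) / (r * nbar)) / (r - 1)
    alleles <- unique(c(a1, a2))
    A <- B <- C <- 0
    for (al in alleles) {
      pi <- vapply(use, function(d) {
        sel <- dm == d
        (sum(a1[sel] == al) + sum(a2[sel] == al)) / (2 * sum(sel))
      }, 0)
      hi <- vapply(use, function(d) {
        sel <- dm == d
        sum(xor(a1[sel] == al, a2[sel] == al)) / sum(sel)
      }, 0)
      pbar <- sum(ni * pi) / (r * nbar)
      s2 <- sum(ni * (pi - pbar)^2) / ((r - 1) * nbar)
      hbar <- sum(ni * hi) / (r * nbar)
      aa <- (nbar / nc) *
        (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
      bb <- (nbar / (nbar - 1)) *
        (pbar * (1 - pbar) - s2 * (r - 1) / r -
         hbar * (2 * nbar - 1) / (4 * nbar))
      cc <- hbar / 2
      A <- A + aa; B <- B + bb; C <- C + cc
    }
    data.frame(locus = l, a = A, b = B, c = C,
               theta = if (A + B + C != 0) A / (A + B + C) else NA_real_)
  })
  per <- do.call(rbind, per)
  if (is.null(per) || nrow(per) == 0) stop("no locus usable for F_ST")
  theta <- sum(per$a) / sum(per$a + per$b + per$c)
  list(theta = theta, perLocus = per, demes = demes)
}

#' Permutation test for departure of F_ST from zero
#'
#' Permutes the deme labels across individuals and reports the upper tail
#' probability of the observed multilocus theta.
#'
#' @param gt \code{GenotypeTable}.
#' @param partition see \code{\link{weirCockerhamFst}}.
#' @param nperm permutations.
#' @return list with \code{theta}, \code{p}.
#' @export
fstPermutationTest <- function(gt, partition, nperm = 1000) {
  obs <- weirCockerhamFst(gt, partition)$theta
  part <- partition[gt@samples]
  ge <- 0L
  for (i in seq_len(nperm)) {
    pp <- setNames(sample(part), gt@samples)
    th <- tryCatch(weirCockerhamFst(gt, pp)$theta,
                   error = function(e) NA_real_)
    if (!is.na(th) && th >= obs - 1e-12) ge <- ge + 1L
  }
  list(theta = obs, p = (1 + ge) / (nperm + 1))
}

#' Genotypic differentiation exact G test
#'
#' Deme x genotype contingency table per locus, evaluated with the same
#' permutation-G machinery as the LD test; per-locus p-values are combined
#' across loci by Fisher's method.
#'
#' @param gt \code{GenotypeTable}.
#' @param partition deme labels per sample (named).
#' @param nperm permutations per locus.
#' @return list with \code{perLocus} data.frame and \code{p_fisher}.
#' @export
genotypicDifferentiation <- function(gt, partition, nperm = 10000) {
  calls <- genotypeCalls(gt)
  part <- partition[gt@samples]
  rows <- lapply(gt@loci, function(l) {
    cell <- calls[, l]
    keep <- !is.na(cell)
    g <- factor(cell[keep]); d <- factor(as.character(part[keep]))
    if (nlevels(g) < 2 || nlevels(d) < 2)
      return(data.frame(locus = l, G = 0, p = 1,
                        flag = "undefined (monomorphic or single deme)"))
    gi <- as.integer(g); di <- as.integer(d)
    kg <- nlevels(g); kd <- nlevels(d)
    gstat <- function(gi2) {
      tab <- tabulate(gi2 + kg * (di - 1L), kg * kd)
      E <- outer(tabulate(gi2, kg), tabulate(di, kd)) / length(gi2)
      o <- tab[tab > 0]
      2 * sum(o * log(o / E[tab > 0]))
    }
    G <- gstat(gi)
    ge <- 0L
    for (i in seq_len(nperm))
      if (gstat(gi[sample.int(length(gi))]) >= G - 1e-12) ge <- ge + 1L
    data.frame(locus = l, G = G, p = (1 + ge) / (nperm + 1), flag = "ok")
  })
  per <- do.call(rbind, rows)
  usable <- per$flag == "ok"
  pf <- if (any(usable)) fisherCombine(per$p[usable]) else 1
  list(perLocus = per, p_fisher = pf)
}

#' Fisher's combination of independent p-values
#'
#' @param pvals p-values from independent tests.
#' @return Combined p-value from the chi-squared distribution with
#'   2k degrees of freedom.
#' @export
fisherCombine <- function(pvals) {
  stats::pchisq(-2 * sum(log(pvals)), df = 2 * length(pvals),
                lower.tail = FALSE)
}
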