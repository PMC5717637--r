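#' Coalescent simulation of a non-recombining mtDNA locus
#'
#' Simulates a Kingman coalescent genealogy for \code{n} lineages
#' (exponential waiting times with rate k(k-1)/2 while k lineages remain,
#' time in units of the locus's effective timescale) and drops mutations
#' on the branches as a Poisson process with rate theta_site * L / 2 per
#' unit time.  Under the finite-sites model each mutation hits a uniform
#' site and changes it to a uniformly chosen different base; the
#' infinite-sites projection gives every mutation a fresh site.  An
#' optional ancient two-deme split (\code{splitDepth} coalescent units,
#' samples \code{nA}/\code{nB}) restricts coalescences to within demes
#' until the split time, producing the deep bimodal structure that a
#' large constant population also generates at its root.
#'
#' The scaled mutation rate follows the theta = 4 N u convention so that
#' N = pi / (4 u) recovers the simulated population size; expected
#' diversity is E(pi * L) = theta_site * L.
#'
#' @param n sample size (>= 2); ignored when nA/nB are given.
#' @param thetaSite scaled mutation rate per site (4Nu).
#' @param L sites (bp).
#' @param model "finite_sites" (default) or "infinite_sites_projected".
#' @param nA,nB optional per-deme sample sizes for the two-deme variant.
#' @param splitDepth split time in coalescent units (two-deme variant).
#' @return list with \code{aln} (\code{DNAStringSet}, ids s1..sn; the
#'   two-deme variant prefixes A/B), \code{tree} (parent/time vectors),
#'   \code{n_mutations} and \code{tmrca}.
#' @export
simulateMtdna <- function(n = 20, thetaSite = 0.01, L = 1000,
                          model = c("finite_sites",
                                    "infinite_sites_projected"),
                          nA = NULL, nB = NULL, splitDepth = NULL) {
  model <- match.arg(model)
  if (thetaSite < 0 || L < 1) stop("invalid coalescent parameters")
  twoDeme <- !is.null(nA)
  if (twoDeme) {
    stopifnot(!is.null(nB), !is.null(splitDepth))
    n <- nA + nB
    deme <- c(rep(1L, nA), rep(2L, nB))
  } else {
    deme <- rep(1L, n)
  }
  if (n < 2) stop("need n >= 2")
  ntot <- 2L * n - 1L
  parent <- integer(ntot); time <- numeric(ntot)
  active <- seq_len(n); ademe <- deme
  t <- 0; nxt <- n + 1L
  repeat {
    k <- length(active)
    if (k == 1L) break
    if (twoDeme && t < splitDepth) {
      kA <- sum(ademe == 1L); kB <- sum(ademe == 2L)
      rA <- kA * (kA - 1) / 2; rB <- kB * (kB - 1) / 2
      if (rA + rB == 0) { t <- splitDepth; ademe[] <- 1L; next }
      wait <- rexp(1, rA + rB)
      if (t + wait > splitDepth) { t <- splitDepth; ademe[] <- 1L; next }
      t <- t + wait
      dm <- if (runif(1) < rA / (rA + rB)) 1L else 2L
      pool <- which(ademe == dm)
    } else {
      t <- t + rexp(1, k * (k - 1) / 2)
      pool <- seq_len(k)
    }
    pick <- sample(pool, 2L)
    ch <- active[pick]
    parent[ch] <- nxt
    time[nxt] <- t
    active <- c(active[-pick], nxt)
    ademe <- c(ademe[-pick], ademe[pick[1]])
    nxt <- nxt + 1L
  }
  root <- ntot
  blen <- time[parent[-root]] - time[-root]   # branch above each node
  totalLen <- sum(blen)
  nmut <- rpois(1, thetaSite * L / 2 * totalLen)
  nt <- c("A", "C", "G", "T")
  rootSeq <- sample(nt, L, replace = TRUE)
  seqs <- matrix(rootSeq, nrow = ntot, ncol = L, byrow = TRUE)
  if (nmut > 0) {
    onBranch <- sample.int(ntot - 1L, nmut, replace = TRUE,
                           prob = blen / totalLen)
    sites <- if (model == "finite_sites")
      sample.int(L, nmut, replace = TRUE)
    else {
      if (nmut > L) stop("infinite-sites projection needs L >= mutations")
      sample.int(L, nmut)
    }
    # order nodes root-down and propagate sequence, applying mutations
    ord <- order(time[seq_len(ntot)], decreasing = TRUE)
    mutByNode <- split(seq_len(nmut), onBranch)
    for (v in ord) {
      if (v == root) next
      seqs[v, ] <- seqs[parent[v], ]
      mu <- mutByNode[[as.character(v)]]
      if (!is.null(mu)) for (i in mu) {
        s <- sites[i]
        seqs[v, s] <- sample(setdiff(nt, seqs[v, s]), 1L)
      }
    }
  }
  ids <- if (twoDeme)
    c(sprintf("A%d", seq_len(nA)), sprintf("B%d", seq_len(nB)))
  else sprintf("s%d", seq_len(n))
  aln <- Biostrings::DNAStringSet(
    apply(seqs[seq_len(n), , drop = FALSE], 1, paste, collapse = ""))
  names(aln) <- ids
  list(aln = aln, tree = list(parent = parent, time = time),
       n_mutations = nmut, tmrca = time[root])
}

#' Scenario specification for the synthetic generators
#'
#' Bundles population parameters for the four scenarios the pipeline is
#' meant to tell apart.  Defaults mirror the study conditions: 29 samples
#' genotyped at five nuclear loci with allele counts 2-12, a deep mtDNA
#' coalescent at a single locality sample, and trait count scales of the
#' stridulatory-ridge / tibia-spine kind.
#'
#' @param scenario one of "panmictic_large_N", "cryptic_pair",
#'   "hybrid_zone", "balancing_like".
#' @param n diploid sample size.
#' @param nLoci number of nuclear loci.
#' @param nAlleles integer vector (recycled) of allele counts per locus.
#' @param F Balding-Nichols divergence between demes; default 0.7 for the
#'   cryptic pair (ancient isolation), 0.3 otherwise.
#' @param splitDepth mtDNA deme split depth in coalescent units.
#' @param thetaSite per-site 4Nu for the mtDNA locus.
#' @param L mtDNA sites.
#' @param hybridFraction fraction of mixed-ancestry (F1/backcross)
#'   individuals in the hybrid zone scenario.
#' @param traitMeans length-2 per-deme trait means (equal = unimodal).
#' @param traitSD trait standard deviation.
#' @param nLocalities number of sampling localities.
#' @return A validated list of class \code{"ScenarioSpec"}.
#' @export
scenarioSpec <- function(scenario = c("panmictic_large_N", "cryptic_pair",
                                      "hybrid_zone", "balancing_like"),
                         n = 58, nLoci = 5,
                         nAlleles = c(2, 2, 12, 3, 3),
                         F = NULL, splitDepth = 10,
                         thetaSite = 0.05, L = 702,
                         hybridFraction = 0.3,
                         traitMeans = NULL, traitSD = 1,
                         nLocalities = 8) {
  scenario <- match.arg(scenario)
  if (is.null(traitMeans))
    traitMeans <- switch(scenario,
                         hybrid_zone = c(10, 20),
                         c(11, 11))
  # cryptic species imply ancient isolation (the same depth that makes the
  # mtDNA clades reciprocally monophyletic), hence strong nuclear allele
  # frequency divergence; hybrid-zone parentals are younger lineages in
  # secondary contact, with moderate divergence
  if (is.null(F))
    F <- if (scenario == "cryptic_pair") 0.7 else 0.3
  stopifnot(n >= 4, nLoci >= 1, all(nAlleles >= 2), F > 0, F < 1,
            splitDepth >= 0, thetaSite >= 0, L >= 1,
            hybridFraction >= 0, hybridFraction <= 1, traitSD >= 0,
            nLocalities >= 1)
  structure(list(scenario = scenario, n = n, nLoci = nLoci,
                 nAlleles = rep_len(nAlleles, nLoci), F = F,
                 splitDepth = splitDepth, thetaSite = thetaSite, L = L,
                 hybridFraction = hybridFraction,
                 traitMeans = traitMeans, traitSD = traitSD,
                 nLocalities = nLocalities),
            class = "ScenarioSpec")
}

.rdirichlet1 <- function(k, alpha = 1) {
  g <- rgamma(k, alpha)
  g / sum(g)
}

# Balding-Nichols style deme frequencies around ancestral p with
# divergence F: Dirichlet(p * (1 - F) / F)
.bnDeme <- function(p, F) {
  g <- rgamma(length(p), shape = p * (1 - F) / F)
  if (sum(g) == 0) return(p)
  g / sum(g)
}

.mateHWE <- function(freqs, n, labels) {
  a1 <- sample(labels, n, replace = TRUE, prob = freqs)
  a2 <- sample(labels, n, replace = TRUE, prob = freqs)
  paste(pmin(a1, a2), pmax(a1, a2), sep = "/")
}

#' Simulate nuclear genotypes under a scenario
#'
#' \code{panmictic_large_N} (and \code{balancing_like}, whose nuclear
#' genome is exchanged freely): allele frequencies drawn from a symmetric
#' Dirichlet, genotypes by random mating — exactly Hardy-Weinberg.
#' \code{cryptic_pair}: two reproductively isolated demes whose
#' frequencies diverge by a Balding-Nichols construction with parameter
#' \code{F}; the pooled sample shows heterozygote deficit (Wahlund
#' effect) and inter-locus association.  \code{hybrid_zone}: two parental
#' pools plus a fraction of F1/backcross individuals drawing alleles from
#' both pools.
#'
#' @param spec a \code{\link{scenarioSpec}}.
#' @return list with \code{gt} (\code{GenotypeTable}), \code{deme}
#'   (named true labels) and \code{ancestry} ("pure1", "pure2", "F1",
#'   "backcross").
#' @export
simulateGenotypes <- function(spec) {
  n <- spec$n
  half <- n %/% 2
  deme <- c(rep(1L, half), rep(2L, n - half))
  ancestry <- ifelse(deme == 1L, "pure1", "pure2")
  ids <- sprintf("i%03d", seq_len(n))
  calls <- matrix(NA_character_, n, spec$nLoci,
                  dimnames = list(ids, paste0("L", seq_len(spec$nLoci))))
  labels <- function(k) sprintf("%02d", seq_len(k))
  if (spec$scenario %in% c("panmictic_large_N", "balancing_like")) {
    deme <- rep(1L, n)
    for (j in seq_len(spec$nLoci)) {
      k <- spec$nAlleles[j]
      calls[, j] <- .mateHWE(.rdirichlet1(k), n, labels(k))
    }
  } else if (spec$scenario == "cryptic_pair") {
    for (j in seq_len(spec$nLoci)) {
      k <- spec$nAlleles[j]
      anc <- .rdirichlet1(k)
      f1 <- .bnDeme(anc, spec$F); f2 <- .bnDeme(anc, spec$F)
      calls[deme == 1L, j] <- .mateHWE(f1, half, labels(k))
      calls[deme == 2L, j] <- .mateHWE(f2, n - half, labels(k))
    }
  } else { # hybrid_zone
    nh <- round(n * spec$hybridFraction)
    hy <- sample.int(n, nh)
    ancestry[hy] <- sample(c("F1", "backcross"), nh, replace = TRUE)
    for (j in seq_len(spec$nLoci)) {
      k <- spec$nAlleles[j]
      anc <- .rdirichlet1(k)
      f1 <- .bnDeme(anc, spec$F); f2 <- .bnDeme(anc, spec$F)
      lab <- labels(k)
      for (i in seq_len(n)) {
        fpair <- switch(ancestry[i],
          pure1 = list(f1, f1), pure2 = list(f2, f2),
          F1 = list(f1, f2),
          backcross = if (deme[i] == 1L) list(f1, if (runif(1) < 0.5) f1
                                              else f2)
                      else list(f2, if (runif(1) < 0.5) f1 else f2))
        a1 <- sample(lab, 1, prob = fpair[[1]])
        a2 <- sample(lab, 1, prob = fpair[[2]])
        calls[i, j] <- paste(min(a1, a2), max(a1, a2), sep = "/")
      }
    }
  }
  list(gt = genotypeTable(calls), deme = setNames(deme, ids),
       ancestry = setNames(ancestry, ids))
}

#' Simulate morphometric traits under a scenario
#'
#' Per-deme normal draws rounded to half units (counts such as
#' stridulatory ridges are scored to the half).  Equal deme means give a
#' unimodal distribution; separated means (hybrid-zone parentals) a
#' bimodal one.  sd = 0 gives constant traits (unimodal by convention).
#'
#' @param spec a \code{\link{scenarioSpec}}.
#' @param deme named deme labels (from \code{\link{simulateGenotypes}});
#'   defaults to a half/half split.
#' @param traits number of trait columns.
#' @return data.frame of traits, rownames = sample ids.
#' @export
simulateTraits <- function(spec, deme = NULL, traits = 2) {
  n <- spec$n
  if (is.null(deme)) {
    half <- n %/% 2
    deme <- setNames(c(rep(1L, half), rep(2L, n - half)),
                     sprintf("i%03d", seq_len(n)))
  }
  mu <- spec$traitMeans[pmin(as.integer(deme), length(spec$traitMeans))]
  out <- lapply(seq_len(traits), function(tr)
    round(rnorm(n, mu, spec$traitSD) * 2) / 2)
  df <- as.data.frame(setNames(out, paste0("trait", seq_len(traits))))
  rownames(df) <- names(deme)
  df
}

#' Simulate sampling coordinates under a scenario
#'
#' Localities are spread over a unit rectangle and samples assigned to
#' them.  In the hybrid-zone scenario deme-1 individuals go to western
#' localities, deme-2 to eastern ones, and mixed-ancestry individuals to
#' a central band, so the genetic landscape surface develops a ridge
#' there; other scenarios mix demes across localities (sympatry).
#'
#' @param spec a \code{\link{scenarioSpec}}.
#' @param deme named true deme labels.
#' @param ancestry named ancestry labels (hybrid zone only).
#' @return data.frame sample, x, y, locality, haplogroup (= deme label).
#' @export
simulateCoordinates <- function(spec, deme, ancestry = NULL) {
  nl <- spec$nLocalities
  locx <- runif(nl); locy <- runif(nl)
  ids <- names(deme)
  if (spec$scenario == "hybrid_zone" && nl >= 3) {
    band <- cut(locx, quantile(locx, c(0, 1 / 3, 2 / 3, 1)),
                include.lowest = TRUE, labels = FALSE)
    west <- which(band == 1); mid <- which(band == 2); east <- which(band == 3)
    if (!length(west)) west <- which.min(locx)
    if (!length(east)) east <- which.max(locx)
    if (!length(mid)) mid <- setdiff(seq_len(nl), c(west, east))[1]
    if (is.na(mid[1])) mid <- c(west[1], east[1])
    pickFrom <- function(pool, k) pool[sample.int(length(pool), k,
                                                  replace = TRUE)]
    loc <- integer(length(ids))
    mixed <- !is.null(ancestry) & ancestry %in% c("F1", "backcross")
    loc[mixed] <- pickFrom(mid, sum(mixed))
    loc[!mixed & deme == 1L] <- pickFrom(west, sum(!mixed & deme == 1L))
    loc[!mixed & deme == 2L] <- pickFrom(east, sum(!mixed & deme == 2L))
  } else {
    # balanced sampling design: localities contribute near-equal numbers
    loc <- sample(rep_len(seq_len(nl), length(ids)))
  }
  data.frame(sample = ids, x = locx[loc], y = locy[loc],
             locality = paste0("loc", loc), haplogroup = as.integer(deme))
}

#' Simulate a pair of coding sequences with a chosen selective regime
#'
#' Generates one random in-frame coding sequence (no stop codons under
#' the invertebrate mitochondrial code) and a diverged copy carrying
#' \code{nSub} substitutions.  Under \code{regime = "purifying"} proposed
#' changes are accepted only if synonymous with probability
#' \code{1 - nonsynFraction}, mimicking the constraint expected in a
#' large population; \code{"diversifying"} prefers nonsynonymous changes,
#' mimicking the balancing-selection alternative.
#'
#' @param nCodons codons in the sequence.
#' @param nSub substitutions to apply.
#' @param regime "purifying" or "diversifying".
#' @param nonsynFraction target fraction of nonsynonymous substitutions
#'   (default 0.05 purifying, 0.8 diversifying).
#' @param code genetic code.
#' @return \code{DNAStringSet} of the two sequences (ref, div).
#' @export
simulateCodingPair <- function(nCodons = 300, nSub = 30,
                               regime = c("purifying", "diversifying"),
                               nonsynFraction = NULL,
                               code = invertMitoCode()) {
  regime <- match.arg(regime)
  if (is.null(nonsynFraction))
    nonsynFraction <- if (regime == "purifying") 0.05 else 0.8
  sense <- names(code)[code != "*"]
  ref <- sample(sense, nCodons, replace = TRUE)
  div <- ref
  nt <- c("A", "C", "G", "T")
  placed <- 0L; guard <- 0L
  while (placed < nSub && guard < nSub * 1000L) {
    guard <- guard + 1L
    i <- sample.int(nCodons, 1L)
    cd <- strsplit(div[i], "")[[1]]
    pos <- sample.int(3L, 1L)
    alt <- sample(setdiff(nt, cd[pos]), 1L)
    new <- cd; new[pos] <- alt
    newc <- paste(new, collapse = "")
    if (code[[newc]] == "*") next
    syn <- code[[newc]] == code[[div[i]]]
    wantNonsyn <- runif(1) < nonsynFraction
    if (syn == !wantNonsyn) {
      div[i] <- newc
      placed <- placed + 1L
    }
  }
  out <- Biostrings::DNAStringSet(c(ref = paste(ref, collapse = ""),
                                    div = paste(div, collapse = "")))
  out
}
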